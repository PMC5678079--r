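#' Optimise a one-vs-all decision threshold by ROC scan
#'
#' Scans every achievable operating point of the rule `score > theta ->
#' positive`: candidate thresholds are the midpoints between consecutive
#' sorted unique scores plus two sentinels that classify everything
#' positive / everything negative (implemented as `min(score) - 1` and
#' `max(score) + 1`, which behave identically to -Inf/+Inf). The
#' performance metric at each candidate is classification accuracy (or
#' balanced accuracy — the positive class is 1 of N targets, so raw
#' accuracy faces a 1:(N-1) imbalance). Several candidates typically attain
#' the maximum (equal ROC points / points on the maximal iso-performance
#' line); the median of the maximising candidates is returned.
#'
#' @param scores numeric beamformer outputs.
#' @param labels logical (or 0/1) vector; `TRUE` = target (positive class).
#' @param metric `"accuracy"` (default) or `"balanced"`.
#' @return A list of class `threshold_report`: `threshold` (the median
#'   maximiser), `performance` (metric value at the chosen threshold),
#'   `operating_points` (data.frame of all candidates and performances),
#'   `tie` (TRUE when every candidate performs equally), `chosen_rule`.
#' @export
roc_threshold <- function(scores, labels, metric = c("accuracy", "balanced")) {
  metric <- match.arg(metric)
  scores <- as.numeric(scores)
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  if (all(labels) || !any(labels)) {
    stop("degenerate ROC: need at least one positive and one negative label",
         call. = FALSE)
  }
  u <- sort(unique(scores))
  candidates <- c(u[1] - 1, if (length(u) > 1L) (u[-length(u)] + u[-1]) / 2,
                  u[length(u)] + 1)
  perf <- vapply(candidates, function(th) {
    pred <- scores > th
    if (metric == "accuracy") {
      mean(pred == labels)
    } else {
      (mean(pred[labels]) + mean(!pred[!labels])) / 2
    }
  }, numeric(1))
  best <- max(perf)
  maximisers <- candidates[perf >= best - 1e-12]
  list(
    threshold = stats::median(maximisers),
    performance = best,
    operating_points = data.frame(threshold = candidates, performance = perf),
    tie = all(perf >= best - 1e-12),
    chosen_rule = "median of thresholds attaining maximal performance"
  ) |> structure(class = "threshold_report")
}

#' @export
print.threshold_report <- function(x, ...) {
  cat(sprintf("<threshold_report> theta = %.6g (performance %.4f%s)\n",
              x$threshold, x$performance,
              if (x$tie) ", all candidates tied" else ""))
  invisible(x)
}

# Stratified fold assignment: epochs of each label are taken in order and
# dealt round-robin into k folds, optionally after a seeded within-label
# shuffle. The caller's RNG state is left untouched.
stratified_folds <- function(labels, k, seed = NULL, shuffle = !is.null(seed)) {
  fold <- integer(length(labels))
  if (shuffle && !is.null(seed)) {
    old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
      get(".Random.seed", envir = .GlobalEnv)
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
          rm(".Random.seed", envir = .GlobalEnv)
        }
      } else assign(".Random.seed", old, envir = .GlobalEnv)
    })
    set.seed(seed)
  }
  for (lab in unique(labels)) {
    idx <- which(labels == lab)
    if (shuffle && !is.null(seed)) idx <- idx[sample.int(length(idx))]
    fold[idx] <- ((seq_along(idx) - 1L) %% k) + 1L
  }
  fold
}

#' Train the full one-vs-all beamformer classifier
#'
#' Two stages. (1) Activation patterns, the pooled segment covariance and
#' the per-target LCMV weights are trained on all training epochs. (2) Each
#' target's decision threshold is tuned by an inner stratified 4-fold
#' cross-validation over the training epochs: three folds train a
#' beamformer bank, the held-out fold's segments are scored by it, and the
#' held-out scores of all four folds are pooled into one ROC per target
#' (label: segment's cue equals that target), whose median-maximiser
#' threshold is kept.
#'
#' @param epochs an [epoch_set()] at the analysis rate.
#' @param config a [run_config()]; uses `segment_s`, `exclude_initial_s`,
#'   `inner_k`, `n_targets`, `roc_metric`, `seed`.
#' @return A list of class `cvep_model`: `bank` (the full-data
#'   [beamformer_bank()]), `thresholds` (named per target),
#'   `threshold_reports`, `config`, `schema = 1L`.
#' @export
fit_cvep <- function(epochs, config = run_config()) {
  stopifnot(inherits(epochs, "epoch_set"))
  targets <- seq_len(config$n_targets)
  counts <- table(factor(epochs$labels, levels = targets))
  if (any(counts < config$inner_k)) {
    stop(sprintf("every target needs >= %d training epochs for the inner %d-fold split",
                 config$inner_k, config$inner_k), call. = FALSE)
  }
  segs <- extract_segments(epochs, config$segment_s, config$exclude_initial_s)
  bank <- beamformer_bank(segs, targets)

  # inner CV over epochs; segments follow their epoch to avoid leakage
  fold_of_epoch <- stratified_folds(epochs$labels, config$inner_k,
                                    seed = config$seed)
  held_scores <- vector("list", config$inner_k)
  held_labels <- vector("list", config$inner_k)
  for (f in seq_len(config$inner_k)) {
    tr <- which(fold_of_epoch != f)
    te <- which(fold_of_epoch == f)
    seg_tr <- segs$epoch_index %in% tr
    seg_te <- segs$epoch_index %in% te
    sub <- segment_set(segs$data[, , seg_tr, drop = FALSE], segs$rate,
                       segs$labels[seg_tr], segs$segment_duration_s,
                       segs$epoch_index[seg_tr])
    fold_bank <- beamformer_bank(sub, targets)
    held_scores[[f]] <- score_segments(
      fold_bank, segs$data[, , seg_te, drop = FALSE])
    held_labels[[f]] <- segs$labels[seg_te]
  }
  pooled <- do.call(rbind, held_scores)
  pooled_labels <- unlist(held_labels)
  reports <- lapply(targets, function(i) {
    roc_threshold(pooled[, i], pooled_labels == i, metric = config$roc_metric)
  })
  thresholds <- vapply(reports, `[[`, numeric(1), "threshold")
  names(thresholds) <- targets
  structure(
    list(bank = bank, thresholds = thresholds, threshold_reports = reports,
         config = config, schema = 1L),
    class = "cvep_model"
  )
}

#' @export
print.cvep_model <- function(x, ...) {
  cat(sprintf("<cvep_model> %d targets, %d channels x %d samples (mn = %d), session S%s\n",
              length(x$bank$targets), x$bank$m, x$bank$n, x$bank$m * x$bank$n,
              x$config$session))
  invisible(x)
}

#' Predict the gazed target of one epoch
#'
#' Extracts the epoch's code-length segments (same procedure as in
#' training), averages the first `n_repetitions` of them, and filters the
#' average independently with every target's beamformer. Among the targets
#' whose score exceeds their threshold the highest score wins; if no score
#' exceeds its threshold, the highest (sub-threshold) score wins; exact
#' score ties break to the lowest target id.
#'
#' @param model a [fit_cvep()] model.
#' @param epoch channels x samples matrix (one epoch at the analysis rate),
#'   or an [epoch_set()] (then all its epochs are predicted).
#' @param n_repetitions number of code presentations averaged (>= 1).
#' @return Integer target id (or vector of ids for an `epoch_set`).
#' @export
predict_cvep <- function(model, epoch, n_repetitions = 1L) {
  stopifnot(inherits(model, "cvep_model"))
  cfg <- model$config
  if (inherits(epoch, "epoch_set")) {
    d <- dim(epoch$data)
    return(vapply(seq_len(d[3]), function(j) {
      predict_cvep(model, matrix(epoch$data[, , j], nrow = d[1]),
                   n_repetitions)
    }, integer(1)))
  }
  if (!is.matrix(epoch)) epoch <- matrix(epoch, nrow = model$bank$m)
  n <- model$bank$n
  offset <- as.integer(round(cfg$exclude_initial_s * model$bank$rate))
  avail <- (ncol(epoch) - offset) %/% n
  n_repetitions <- as.integer(n_repetitions)
  if (n_repetitions < 1L) stop("'n_repetitions' must be >= 1", call. = FALSE)
  if (n_repetitions > avail) {
    stop(sprintf("epoch holds %d complete segments but %d repetitions were requested",
                 avail, n_repetitions), call. = FALSE)
  }
  acc <- matrix(0, nrow = nrow(epoch), ncol = n)
  for (g in seq_len(n_repetitions)) {
    acc <- acc + epoch[, offset + (g - 1L) * n + seq_len(n), drop = FALSE]
  }
  avg <- acc / n_repetitions
  y <- as.numeric(flatten_matrix(avg) %*% model$bank$weights)
  over <- which(y > model$thresholds)
  pick <- if (length(over)) over[which.max(y[over])] else which.max(y)
  as.integer(model$bank$targets[pick])
}
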
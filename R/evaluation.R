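#' Information transfer rate (bits per minute)
#'
#' Wolpaw's ITR for an N-choice selection with accuracy `p` and selection
#' time `t` seconds:
#' `ITR = (log2(N) + p log2(p) + (1-p) log2((1-p)/(N-1))) / (t/60)`,
#' with the `p = 1` and `p = 1/N` limits taken by continuity
#' (`0 * log2(0) := 0`). An accuracy below chance (`p < 1/N`) is clamped to
#' chance with a warning rather than reporting negative bits.
#'
#' @param N number of selectable targets (>= 2).
#' @param p target-identification accuracy in `[0, 1]` (vectorised).
#' @param t_sec time per selection in seconds (stimulation time plus any
#'   onset exclusion and gaze-shift allowance).
#' @return ITR in bits/min (same length as `p`).
#' @export
itr <- function(N, p, t_sec) {
  N <- as.integer(N)
  if (length(N) != 1L || N < 2L) stop("'N' must be an integer >= 2", call. = FALSE)
  if (any(p < 0 | p > 1)) stop("'p' must lie in [0, 1]", call. = FALSE)
  if (any(t_sec <= 0)) stop("'t_sec' must be positive", call. = FALSE)
  if (any(p < 1 / N)) {
    warning("accuracy below chance (1/N) clamped to chance: ITR reported as 0")
    p <- pmax(p, 1 / N)
  }
  xlogx <- function(x) ifelse(x > 0, x * log2(x), 0)
  bits <- log2(N) + xlogx(p) + ifelse(p < 1, (1 - p) * log2((1 - p) / (N - 1)), 0)
  bits / (t_sec / 60)
}

#' Time needed for one selection, in seconds
#'
#' Stimulation time for `n_repetitions` code presentations
#' (`n_repetitions * c`), plus the onset exclusion when the first 150 ms are
#' discarded (a full first code then needs `0.150 + c` seconds), plus a
#' gaze-shift allowance (default 0.5 s).
#'
#' @param n_repetitions code presentations averaged.
#' @param segment_s code presentation time `c` in seconds.
#' @param exclude_initial_s onset exclusion in seconds.
#' @param gaze_shift_s gaze-shift allowance in seconds.
#' @return Selection time in seconds.
#' @export
selection_time <- function(n_repetitions, segment_s, exclude_initial_s = 0,
                           gaze_shift_s = 0.5) {
  n_repetitions * segment_s + exclude_initial_s + gaze_shift_s
}

#' Stratified k-fold evaluation of the beamformer classifier
#'
#' Partitions the epochs into `k` folds with one epoch per target per fold
#' (epochs of each target are assigned in recording order: epoch `j` of a
#' target goes to fold `j`), trains [fit_cvep()] on each training split and
#' predicts the held-out epochs at every repetition count from 1 up to the
#' number of complete segments per epoch. Accuracy and the matching ITR
#' (via [selection_time()]) are reported per repetition count.
#'
#' @param epochs an [epoch_set()] at the analysis rate with an equal number
#'   of epochs per target, a multiple of `k`.
#' @param config a [run_config()].
#' @param k number of outer folds (default `config$outer_k`, 5).
#' @param repetitions integer vector of repetition counts to evaluate
#'   (default all available).
#' @param classifier pluggable classifier interface: a list with `fit(epochs,
#'   config)` returning a model and `predict(model, epoch, n_repetitions)`
#'   returning a target id. Defaults to the beamformer classifier
#'   ([fit_cvep()] / [predict_cvep()]); any comparator (an SVM, a template
#'   matcher) can be benchmarked by supplying its own pair.
#' @return A list of class `cvep_evaluation`: `accuracy_by_repetitions`
#'   (named numeric), `itr_by_repetitions` (bits/min), `per_fold`
#'   (data.frame epoch/fold/n_repetitions/true/predicted), `channel_set`,
#'   `config`.
#' @export
stratified_cv <- function(epochs, config = run_config(), k = NULL,
                          repetitions = NULL,
                          classifier = beamformer_classifier()) {
  stopifnot(inherits(epochs, "epoch_set"))
  k <- k %||% config$outer_k
  counts <- table(epochs$labels)
  if (length(unique(counts)) != 1L || counts[1] %% k != 0) {
    stop(sprintf("every target needs an equal epoch count divisible by k = %d", k),
         call. = FALSE)
  }
  fold_of_epoch <- stratified_folds(epochs$labels, k, shuffle = FALSE)
  n_seg <- (dim(epochs$data)[2] -
            round(config$exclude_initial_s * epochs$rate)) %/%
           round(config$segment_s * epochs$rate)
  repetitions <- repetitions %||% seq_len(n_seg)
  stopifnot(all(repetitions >= 1L), all(repetitions <= n_seg))

  rows <- list()
  for (f in seq_len(k)) {
    tr <- which(fold_of_epoch != f)
    te <- which(fold_of_epoch == f)
    train <- epoch_set(epochs$data[, , tr, drop = FALSE], epochs$rate,
                       epochs$labels[tr], epochs$channel_names)
    model <- classifier$fit(train, config)
    for (reps in repetitions) {
      pred <- vapply(te, function(j) {
        classifier$predict(model, matrix(epochs$data[, , j],
                                         nrow = dim(epochs$data)[1]), reps)
      }, integer(1))
      rows[[length(rows) + 1L]] <- data.frame(
        epoch = te, fold = f, n_repetitions = reps,
        true = epochs$labels[te], predicted = pred)
    }
  }
  per_fold <- do.call(rbind, rows)
  acc <- vapply(repetitions, function(reps) {
    sub <- per_fold[per_fold$n_repetitions == reps, ]
    mean(sub$predicted == sub$true)
  }, numeric(1))
  names(acc) <- repetitions
  t_sec <- selection_time(repetitions, config$segment_s,
                          config$exclude_initial_s, config$gaze_shift_s)
  # below-chance fold accuracies (possible under pure noise) map to 0 bits;
  # itr()'s clamp warning would only add noise in a CV sweep
  itrs <- suppressWarnings(itr(config$n_targets, acc, t_sec))
  names(itrs) <- repetitions
  structure(
    list(accuracy_by_repetitions = acc, itr_by_repetitions = itrs,
         per_fold = per_fold, channel_set = epochs$channel_names,
         config = config),
    class = "cvep_evaluation"
  )
}

#' @export
print.cvep_evaluation <- function(x, ...) {
  cat(sprintf("<cvep_evaluation> %d folds, channels: %s\n",
              max(x$per_fold$fold), paste(x$channel_set, collapse = " ")))
  tab <- data.frame(
    repetitions = as.integer(names(x$accuracy_by_repetitions)),
    accuracy = round(unname(x$accuracy_by_repetitions), 4),
    itr_bits_min = round(unname(x$itr_by_repetitions), 2))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Greedy forward channel selection
#'
#' Starting from the empty set, iteratively adds the candidate channel whose
#' addition improves cross-validated accuracy the most (evaluated with the
#' beamformer classifier averaging `criterion_repetitions` code
#' presentations, default 2), until no addition strictly improves accuracy
#' or accuracy reaches 100%. Improvement ties break to the
#' earliest-listed candidate.
#'
#' @param epochs an [epoch_set()] containing all candidate channels.
#' @param config a [run_config()].
#' @param candidates channel labels to consider (default: all channels of
#'   `epochs`).
#' @param criterion_repetitions repetition count of the selection criterion.
#' @param k outer folds for the criterion CV (default `config$outer_k`).
#' @return A list of class `channel_selection`: `channels` (ordered labels),
#'   `accuracy` (criterion accuracy after each addition), `trace`
#'   (data.frame of every step/candidate/accuracy evaluated).
#' @export
greedy_channel_selection <- function(epochs, config = run_config(),
                                     candidates = NULL,
                                     criterion_repetitions = 2L, k = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  candidates <- candidates %||% epochs$channel_names
  stopifnot(length(candidates) >= 1L, all(candidates %in% epochs$channel_names))
  selected <- character()
  best_acc <- -Inf
  trace <- list()
  step <- 0L
  repeat {
    step <- step + 1L
    remaining <- setdiff(candidates, selected)
    if (!length(remaining)) break
    accs <- vapply(remaining, function(ch) {
      idx <- match(c(selected, ch), epochs$channel_names)
      sub <- epoch_set(epochs$data[idx, , , drop = FALSE], epochs$rate,
                       epochs$labels, epochs$channel_names[idx])
      ev <- stratified_cv(sub, config, k = k,
                          repetitions = criterion_repetitions)
      unname(ev$accuracy_by_repetitions[1])
    }, numeric(1))
    trace[[step]] <- data.frame(step = step, candidate = remaining,
                                accuracy = unname(accs))
    winner <- which.max(accs)   # first maximum = earliest-listed candidate
    if (accs[winner] <= best_acc) break
    selected <- c(selected, remaining[winner])
    best_acc <- accs[winner]
    if (best_acc >= 1) break
  }
  structure(
    list(channels = selected,
         accuracy = vapply(seq_along(selected), function(i) {
           st <- trace[[i]]
           max(st$accuracy)
         }, numeric(1)),
         trace = do.call(rbind, trace)),
    class = "channel_selection"
  )
}

#' @export
print.channel_selection <- function(x, ...) {
  cat("<channel_selection>", length(x$channels), "channel(s):\n")
  for (i in seq_along(x$channels)) {
    cat(sprintf("  %d. %-6s accuracy %.4f\n", i, x$channels[i], x$accuracy[i]))
  }
  invisible(x)
}

#' The default classifier interface: the LCMV beamformer
#'
#' Bundles [fit_cvep()] and [predict_cvep()] into the pluggable classifier
#' interface accepted by [stratified_cv()]. External comparators implement
#' the same two functions.
#'
#' @return A list with elements `fit` and `predict`.
#' @export
beamformer_classifier <- function() {
  list(fit = fit_cvep,
       predict = function(model, epoch, n_repetitions) {
         predict_cvep(model, epoch, n_repetitions)
       })
}

#' Two-tailed Wilcoxon signed-rank test for paired per-subject values
#'
#' Paired comparison harness for condition contrasts (classifier A vs B,
#' with vs without onset exclusion). Zero differences are dropped before
#' ranking; if every difference is zero the test is degenerate and `p = 1`
#' is returned. The exact null distribution is used for up to 25 nonzero
#' untied differences, the normal approximation with continuity correction
#' otherwise.
#'
#' @param a,b numeric vectors of equal length (>= 5 pairs).
#' @return A list with `p_value`, `statistic` (V), `n_effective` (nonzero
#'   pairs), `method`.
#' @export
paired_signed_rank <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (length(a) < 5L) stop("need at least 5 pairs", call. = FALSE)
  d <- a - b
  nz <- d[d != 0]
  if (!length(nz)) {
    return(list(p_value = 1, statistic = NA_real_, n_effective = 0L,
                method = "degenerate: all differences zero"))
  }
  ties <- anyDuplicated(abs(nz)) > 0L
  exact <- length(nz) <= 25L && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(nz, mu = 0, alternative = "two.sided",
                       exact = exact, correct = TRUE)
  )
  list(p_value = unname(ht$p.value), statistic = unname(ht$statistic),
       n_effective = length(nz),
       method = if (exact) "exact signed-rank distribution"
                else "normal approximation with continuity correction")
}
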
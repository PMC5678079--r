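#' Per-target activation pattern: the mean segment
#'
#' The spatiotemporal activation pattern of a target is the element-wise
#' average over all its training segments: a channels x samples template of
#' the evoked response to one full code presentation at that target's lag.
#'
#' @param segments a [segment_set()] containing only (or filtered to) one
#'   target's segments, or any `segment_set` plus `target` to filter by
#'   label.
#' @param target optional target id to filter `segments` by label first.
#' @return A list of class `activation_pattern` with `pattern`
#'   (channels x samples matrix) and `target`.
#' @export
activation_pattern <- function(segments, target = NULL) {
  stopifnot(inherits(segments, "segment_set"))
  keep <- if (is.null(target)) seq_along(segments$labels)
          else which(segments$labels == target)
  if (length(keep) == 0L) {
    stop("no training segments for target", if (!is.null(target)) paste0(" ", target),
         call. = FALSE)
  }
  dat <- segments$data[, , keep, drop = FALSE]
  pat <- apply(dat, c(1L, 2L), mean)
  structure(list(pattern = pat,
                 target = target %||% unique(segments$labels)[1]),
            class = "activation_pattern")
}

#' Flatten segments to a feature matrix (one row per segment)
#'
#' Row `j` is the channel-major concatenation of segment `j`: all samples of
#' channel 1, then all samples of channel 2, and so on. The same fixed order
#' is used for activation patterns, beamformer weights and scored inputs —
#' the constraint and scoring algebra silently breaks if the order ever
#' differs, so [unflatten_segments()] provides the exact inverse for
#' round-trip checking.
#'
#' @param segments a [segment_set()], or a bare 3-d array.
#' @return Numeric matrix with `r` rows of length `m * n`.
#' @export
flatten_segments <- function(segments) {
  dat <- if (inherits(segments, "segment_set")) segments$data else as.array(segments)
  d <- dim(dat)
  out <- matrix(0, nrow = d[3], ncol = d[1] * d[2])
  for (j in seq_len(d[3])) out[j, ] <- flatten_matrix(dat[, , j])
  out
}

#' Channel-major flattening of one channels x samples matrix
#' @param mat channels x samples matrix.
#' @return Numeric vector of length `m * n` (channel 1 samples first).
#' @export
flatten_matrix <- function(mat) as.numeric(t(mat))

#' Inverse of [flatten_segments()]
#' @param flat matrix with one flattened segment per row.
#' @param m,n channel and sample counts of the original segments.
#' @return 3-d array `[m, n, nrow(flat)]`.
#' @export
unflatten_segments <- function(flat, m, n) {
  flat <- as.matrix(flat)
  stopifnot(ncol(flat) == m * n)
  out <- array(0, dim = c(m, n, nrow(flat)))
  for (j in seq_len(nrow(flat))) out[, , j] <- matrix(flat[j, ], nrow = m, byrow = TRUE)
  out
}

#' Sample covariance of the flattened segment matrix
#'
#' The (mn) x (mn) spatiotemporal covariance across all `r` pooled segments
#' (denominator `r - 1`), shared by every target's beamformer.
#'
#' @param E matrix with one flattened segment per row (see
#'   [flatten_segments()]).
#' @return Symmetric `(mn) x (mn)` covariance matrix.
#' @export
spatiotemporal_covariance <- function(E) {
  E <- as.matrix(E)
  if (nrow(E) == 0L) stop("no segments: covariance undefined", call. = FALSE)
  if (nrow(E) == 1L) {
    return(matrix(0, ncol(E), ncol(E)))
  }
  stats::cov(E)
}

#' Moore-Penrose pseudoinverse of a segment covariance, from its data matrix
#'
#' Computes `pinv(cov(E))` without forming or decomposing the (mn) x (mn)
#' covariance: with the economy SVD of the centered data `E - mean`,
#' `X = U D V'`, the covariance is `V (D^2/(r-1)) V'` and its pseudoinverse
#' is `V (D^2/(r-1))^+ V'`. The singular-value cutoff matches the
#' conventional pinv default, `max(dim) * eps * max(eigenvalue)`, applied to
#' the covariance eigenvalues, so the result agrees with
#' `pracma::pinv(spatiotemporal_covariance(E))` to numerical precision while
#' scaling with `r x mn` instead of `(mn)^2`.
#'
#' @param E matrix with one flattened segment per row.
#' @return The `(mn) x (mn)` pseudoinverse of the sample covariance.
#' @export
covariance_pinv <- function(E) {
  E <- as.matrix(E)
  r <- nrow(E)
  p <- ncol(E)
  if (r < 2L) return(matrix(0, p, p))
  X <- sweep(E, 2L, colMeans(E), "-")
  sv <- svd(X, nu = 0L)
  ev <- sv$d^2 / (r - 1)              # covariance eigenvalues
  tol <- max(p, r) * .Machine$double.eps * max(ev, 0)
  inv <- ifelse(ev > tol, 1 / ev, 0)
  sv$v %*% (inv * t(sv$v))
}

#' LCMV beamformer weights for one activation pattern
#'
#' The linearly-constrained minimum-variance weights minimise the expected
#' output power `w' S w` subject to unit response to the target's pattern,
#' `a' w = 1`, giving the closed form
#' `w = pinv(S) a / (a' pinv(S) a)`.
#' The Moore-Penrose pseudoinverse accommodates a singular covariance
#' (fewer segments than `mn` dimensions); when `pinv(S)` does not annihilate
#' `a`, the returned weights satisfy the unit constraint exactly.
#'
#' @param a flattened activation pattern (length `mn` vector), channel-major.
#' @param sigma `(mn) x (mn)` covariance matrix, or `NULL` when
#'   `sigma_pinv` is supplied directly.
#' @param sigma_pinv optional precomputed pseudoinverse of the covariance
#'   (reused across the targets sharing one covariance).
#' @return Numeric weight vector `w` of length `mn`.
#' @export
lcmv_weights <- function(a, sigma = NULL, sigma_pinv = NULL) {
  a <- as.numeric(a)
  if (all(a == 0)) stop("activation pattern is the zero vector", call. = FALSE)
  if (is.null(sigma_pinv)) {
    if (is.null(sigma)) stop("supply 'sigma' or 'sigma_pinv'", call. = FALSE)
    sigma <- as.matrix(sigma)
    stopifnot(nrow(sigma) == length(a), ncol(sigma) == length(a))
    sigma_pinv <- pracma::pinv(sigma)
  }
  num <- as.numeric(sigma_pinv %*% a)
  denom <- sum(a * num)
  if (denom == 0) {
    stop("pattern orthogonal to data space: a' pinv(Sigma) a = 0", call. = FALSE)
  }
  num / denom
}

#' Beamformer output for one segment: a weighted sum
#'
#' `y = s . w`, with `s` the channel-major flattening of the input segment.
#' A segment equal to the beamformer's own activation pattern scores exactly
#' 1 (the unit-response constraint).
#'
#' @param w weight vector of length `mn` (from [lcmv_weights()]).
#' @param segment channels x samples matrix, or an already-flattened vector
#'   of length `mn`.
#' @return Scalar score.
#' @export
beamformer_score <- function(w, segment) {
  s <- if (is.matrix(segment)) flatten_matrix(segment) else as.numeric(segment)
  if (length(s) != length(w)) {
    stop(sprintf("segment has %d features but weights expect %d",
                 length(s), length(w)), call. = FALSE)
  }
  sum(s * w)
}

#' Train the per-target beamformer bank on a segment set
#'
#' Computes every target's activation pattern independently (not as circular
#' shifts of target 1: with per-target training data this avoids shift
#' discontinuities and absorbs minor template differences), one shared
#' covariance pooled over all segments of all targets, and the LCMV weights
#' per target.
#'
#' @param segments a [segment_set()] with labels covering `targets`.
#' @param targets integer vector of target ids to train (default: all
#'   labels present, sorted).
#' @return A list of class `beamformer_bank`: `patterns` (m x n x n_targets
#'   array), `weights` (mn x n_targets matrix), `targets`, `m`, `n`,
#'   and `rate`/`segment_duration_s` carried from the segments. The pooled
#'   covariance is not stored (it can be rebuilt from training data);
#'   weights embed it.
#' @export
beamformer_bank <- function(segments, targets = NULL) {
  stopifnot(inherits(segments, "segment_set"))
  if (is.null(targets)) targets <- sort(unique(segments$labels))
  d <- dim(segments$data)
  m <- d[1]; n <- d[2]
  E <- flatten_segments(segments)
  spinv <- covariance_pinv(E)
  patterns <- array(0, dim = c(m, n, length(targets)))
  weights <- matrix(0, nrow = m * n, ncol = length(targets))
  for (t in seq_along(targets)) {
    ap <- activation_pattern(segments, targets[t])
    patterns[, , t] <- ap$pattern
    weights[, t] <- lcmv_weights(flatten_matrix(ap$pattern), sigma_pinv = spinv)
  }
  structure(
    list(patterns = patterns, weights = weights, targets = targets,
         m = m, n = n, rate = segments$rate,
         segment_duration_s = segments$segment_duration_s,
         channel_names = segments$channel_names %||% paste0("ch", seq_len(m))),
    class = "beamformer_bank"
  )
}

#' Score segments against every beamformer in a bank
#'
#' @param bank a [beamformer_bank()].
#' @param segments a [segment_set()], a 3-d array, or a flattened matrix
#'   with one segment per row.
#' @return Numeric matrix, one row per segment, one column per target
#'   (columns named by target id).
#' @export
score_segments <- function(bank, segments) {
  stopifnot(inherits(bank, "beamformer_bank"))
  E <- if (is.matrix(segments) && ncol(segments) == bank$m * bank$n) segments
       else flatten_segments(segments)
  if (ncol(E) != bank$m * bank$n) {
    stop("segment dimensionality does not match the trained bank", call. = FALSE)
  }
  sc <- E %*% bank$weights
  colnames(sc) <- bank$targets
  sc
}
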
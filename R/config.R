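#' Analysis configuration for one session type
#'
#' Bundles the preprocessing and classification parameters of the two
#' session types: `"120"` presents one code bit per frame of a 120 Hz
#' monitor (10 code repetitions per 5.25 s trial, analysis at 200 Hz,
#' segment length c = 0.525 s) and `"60"` holds each bit for two frames,
#' emulating a 60 Hz monitor (5 repetitions, 100 Hz, c = 1.05 s). Both
#' yield 105 samples per segment, so classifiers of the two sessions have
#' identical dimensionality.
#'
#' @param session `"120"` or `"60"`.
#' @param exclude_initial_s seconds discarded at each epoch onset (0, or
#'   0.150 to skip the unstable post-onset transition).
#' @param n_targets number of selectable targets (default 32).
#' @param seed integer seed for the stratified inner-fold shuffling.
#' @param ... overrides for any returned field.
#' @return A list of class `run_config`: `session`, `display_rate`,
#'   `frames_per_bit`, `code_repetitions`, `band`, `filter_order`,
#'   `epoch_s`, `target_rate`, `segment_s`, `exclude_initial_s`,
#'   `ref_channels`, `drop_refs`, `n_targets`, `lag_step_frames`,
#'   `inner_k`, `outer_k`, `gaze_shift_s`, `roc_metric`, `seed`.
#' @export
run_config <- function(session = c("120", "60"), exclude_initial_s = 0,
                       n_targets = 32L, seed = 1L, ...) {
  session <- match.arg(as.character(session), c("120", "60"))
  cfg <- list(
    session = session,
    display_rate = 120,
    frames_per_bit = if (session == "120") 1L else 2L,
    code_repetitions = if (session == "120") 10L else 5L,
    band = c(4, 31),
    filter_order = 4L,
    epoch_s = 5.25,
    target_rate = if (session == "120") 200 else 100,
    segment_s = if (session == "120") 0.525 else 1.05,
    exclude_initial_s = exclude_initial_s,
    ref_channels = c("TP9", "TP10"),
    drop_refs = FALSE,
    n_targets = as.integer(n_targets),
    lag_step_frames = 2L,
    inner_k = 4L,
    outer_k = 5L,
    gaze_shift_s = 0.5,
    roc_metric = "accuracy",
    seed = as.integer(seed)
  )
  dots <- list(...)
  cfg[names(dots)] <- dots
  class(cfg) <- "run_config"
  cfg
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf(
    "<run_config> session S%s: %d targets, band %g-%g Hz (order %d), epoch %g s,\n  analysis %g Hz, c = %g s, exclude %g s, inner/outer CV %d/%d, gaze shift %g s\n",
    x$session, x$n_targets, x$band[1], x$band[2], x$filter_order, x$epoch_s,
    x$target_rate, x$segment_s, x$exclude_initial_s, x$inner_k, x$outer_k,
    x$gaze_shift_s))
  invisible(x)
}
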
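#' Re-reference a recording to the average of two reference channels
#'
#' Subtracts `0.5 * (ref1 + ref2)` from every channel sample-wise; the
#' standard offline linked-mastoids reference uses TP9 and TP10.
#'
#' @param rec an [eeg_recording()].
#' @param ref_channels character vector of exactly two channel labels.
#' @param drop_refs drop the reference channels afterwards? Default `FALSE`.
#' @return A re-referenced [eeg_recording()].
#' @export
rereference <- function(rec, ref_channels = c("TP9", "TP10"), drop_refs = FALSE) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (length(ref_channels) != 2L) {
    stop("'ref_channels' must name exactly two channels", call. = FALSE)
  }
  missing <- setdiff(ref_channels, rec$channel_names)
  if (length(missing)) {
    stop("reference channel(s) not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  idx <- match(ref_channels, rec$channel_names)
  ref <- 0.5 * (rec$data[idx[1], ] + rec$data[idx[2], ])
  data <- sweep(rec$data, 2L, ref, "-")
  keep <- if (drop_refs) setdiff(seq_len(nrow(data)), idx) else seq_len(nrow(data))
  eeg_recording(data[keep, , drop = FALSE], rec$rate,
                rec$channel_names[keep], rec$events)
}

#' Zero-phase Butterworth band-pass filter
#'
#' Designs an order-`order` Butterworth band-pass (default 4-31 Hz, the band
#' that suppresses slow drifts, movement artefacts, high-frequency noise and
#' line interference while keeping the code-locked response) and applies it
#' forward and backward (zero-phase), so the effective magnitude response is
#' the squared magnitude of the one-pass design.
#'
#' @param rec an [eeg_recording()].
#' @param low,high band edges in Hz; `0 < low < high < rate/2`.
#' @param order filter order of the one-pass design. Default 4.
#' @return The filtered [eeg_recording()].
#' @export
bandpass_filter <- function(rec, low = 4, high = 31, order = 4L) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$rate / 2
  if (!(low > 0 && low < high && high < nyq)) {
    stop(sprintf("band [%g, %g] Hz must satisfy 0 < low < high < Nyquist (%g Hz)",
                 low, high, nyq), call. = FALSE)
  }
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  data <- t(apply(rec$data, 1L, function(ch) zero_phase_filter(bf, ch)))
  eeg_recording(data, rec$rate, rec$channel_names, rec$events)
}

# Forward-backward IIR filtering with odd-reflection end padding (pad length
# 3x the filter length), so start/end transients decay inside the padding.
zero_phase_filter <- function(bf, x) {
  npad <- min(3L * max(length(bf$b), length(bf$a)) * 10L, length(x) - 1L)
  head_pad <- 2 * x[1] - x[rev(seq_len(npad)) + 1L]
  tail_pad <- 2 * x[length(x)] - x[length(x) - seq_len(npad)]
  xp <- c(head_pad, x, tail_pad)
  y <- signal::filter(bf, xp)
  y <- rev(signal::filter(bf, rev(y)))
  y[npad + seq_along(x)]
}

#' Cut a recording into fixed-length labelled epochs
#'
#' One epoch per stimulation-onset event, starting at the event sample and
#' spanning `duration_s` seconds (half-open sample interval
#' `[onset, onset + round(duration_s * rate))`), labelled with the event's
#' cued target id.
#'
#' @param rec an [eeg_recording()] with onset events.
#' @param duration_s epoch length in seconds (default 5.25, i.e. the full
#'   stimulation phase of one trial).
#' @return An [epoch_set()]; empty (zero epochs) if the recording has no
#'   events.
#' @export
epoch_recording <- function(rec, duration_s = 5.25) {
  stopifnot(inherits(rec, "eeg_recording"))
  n_samp <- round(duration_s * rec$rate)
  ev <- rec$events
  m <- nrow(rec$data)
  if (nrow(ev) == 0L) {
    return(epoch_set(array(0, dim = c(m, n_samp, 0L)), rec$rate, integer(),
                     rec$channel_names))
  }
  too_late <- ev$sample + n_samp > ncol(rec$data)
  if (any(too_late)) {
    stop(sprintf(
      "epoch(s) truncated at end of recording for event(s) at sample(s) %s",
      paste(ev$sample[too_late], collapse = ", ")), call. = FALSE)
  }
  out <- array(0, dim = c(m, n_samp, nrow(ev)))
  for (j in seq_len(nrow(ev))) {
    out[, , j] <- rec$data[, ev$sample[j] + seq_len(n_samp), drop = FALSE]
  }
  epoch_set(out, rec$rate, ev$label, rec$channel_names)
}

#' Downsample an epoch set by integer decimation
#'
#' Keeps every `rate / target_rate`-th sample (starting at the first). No
#' further anti-alias filtering is applied: the band-pass upper edge (31 Hz)
#' already lies below the 50 Hz Nyquist frequency of the lowest target rate
#' (100 Hz) used by the protocol.
#'
#' @param ep an [epoch_set()].
#' @param target_rate desired rate in Hz; must divide the current rate.
#' @return The decimated [epoch_set()].
#' @export
downsample_epochs <- function(ep, target_rate) {
  stopifnot(inherits(ep, "epoch_set"))
  if (target_rate <= 0) stop("'target_rate' must be positive", call. = FALSE)
  factor <- ep$rate / target_rate
  if (abs(factor - round(factor)) > 1e-9) {
    stop(sprintf("rate %g Hz is not an integer multiple of target rate %g Hz",
                 ep$rate, target_rate), call. = FALSE)
  }
  factor <- as.integer(round(factor))
  if (factor == 1L) return(ep)
  keep <- seq(1L, dim(ep$data)[2], by = factor)
  epoch_set(ep$data[, keep, , drop = FALSE], target_rate, ep$labels,
            ep$channel_names)
}

#' Extract consecutive non-overlapping code-length segments from epochs
#'
#' From each epoch, the maximal number of `segment_duration_s`-second
#' consecutive non-overlapping segments is extracted, starting after
#' `exclude_initial_s` seconds; the trailing incomplete remainder is
#' discarded and each segment inherits its epoch's target label. With the
#' onset-transition exclusion (`exclude_initial_s = 0.150`) the count drops
#' from `floor(T/c)` to `floor((T - 0.150)/c)`: 5 to 4 segments for the
#' 1.05 s code at 60 Hz presentation, 10 to 9 for the 0.525 s code at 120 Hz.
#'
#' @param ep an [epoch_set()].
#' @param segment_duration_s code presentation time `c` in seconds.
#' @param exclude_initial_s onset exclusion in seconds (0 or 0.150 in the
#'   reference protocol).
#' @return A [segment_set()]; zero segments if `c` exceeds the usable epoch.
#' @export
extract_segments <- function(ep, segment_duration_s,
                             exclude_initial_s = 0) {
  stopifnot(inherits(ep, "epoch_set"))
  if (segment_duration_s <= 0) stop("'segment_duration_s' must be > 0", call. = FALSE)
  if (exclude_initial_s < 0) stop("'exclude_initial_s' must be >= 0", call. = FALSE)
  n <- as.integer(round(segment_duration_s * ep$rate))
  offset <- as.integer(round(exclude_initial_s * ep$rate))
  d <- dim(ep$data)
  per_epoch <- max(0L, (d[2] - offset) %/% n)
  r <- per_epoch * d[3]
  out <- array(0, dim = c(d[1], n, r))
  labels <- integer(r)
  epoch_index <- integer(r)
  s <- 0L
  for (j in seq_len(d[3])) {
    for (g in seq_len(per_epoch)) {
      s <- s + 1L
      start <- offset + (g - 1L) * n
      out[, , s] <- ep$data[, start + seq_len(n), j]
      labels[s] <- ep$labels[j]
      epoch_index[s] <- j
    }
  }
  ss <- segment_set(out, ep$rate, labels, segment_duration_s, epoch_index)
  ss$channel_names <- ep$channel_names
  ss
}

#' Standard preprocessing chain: re-reference, band-pass, epoch, downsample
#'
#' Applies the full offline preprocessing pipeline in its canonical order on
#' the continuous recording: linked-mastoid re-referencing, 4-31 Hz
#' zero-phase Butterworth filtering, cutting into 5.25 s epochs at the onset
#' events, and decimation to the analysis rate (100 Hz for 60 Hz stimulus
#' presentation, 200 Hz for 120 Hz presentation).
#'
#' @param rec an [eeg_recording()].
#' @param config a [run_config()] (or compatible list) supplying
#'   `band`, `filter_order`, `epoch_s`, `target_rate`, `ref_channels`,
#'   `drop_refs`.
#' @return An [epoch_set()] at the analysis rate.
#' @export
preprocess_recording <- function(rec, config = run_config()) {
  rec |>
    rereference(config$ref_channels, drop_refs = isTRUE(config$drop_refs)) |>
    bandpass_filter(config$band[1], config$band[2], config$filter_order) |>
    epoch_recording(config$epoch_s) |>
    downsample_epochs(config$target_rate)
}
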
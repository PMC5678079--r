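#' Construct a multichannel EEG recording
#'
#' Continuous EEG as a channels x samples matrix in microvolts, with its
#' sampling rate, channel labels and stimulation-onset events. Event sample
#' indices are 0-based (sample 0 is the first sample); each event carries the
#' cued target id as an integer label.
#'
#' @param data numeric matrix, channels in rows, samples in columns (uV).
#' @param rate sampling rate in Hz.
#' @param channel_names character vector of unique labels, one per row.
#' @param events data.frame with columns `sample` (0-based integer) and
#'   `label` (integer target id); may have zero rows.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, rate, channel_names,
                          events = data.frame(sample = integer(), label = integer())) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stop("'rate' must be a positive sampling rate in Hz", call. = FALSE)
  }
  channel_names <- as.character(channel_names)
  if (length(channel_names) != nrow(data)) {
    stop("'channel_names' must have one label per data row", call. = FALSE)
  }
  if (anyDuplicated(channel_names)) {
    stop("'channel_names' must be unique", call. = FALSE)
  }
  events <- as.data.frame(events)
  if (!all(c("sample", "label") %in% names(events))) {
    stop("'events' needs columns 'sample' and 'label'", call. = FALSE)
  }
  events$sample <- as.integer(events$sample)
  events$label <- as.integer(events$label)
  if (nrow(events) && (any(events$sample < 0L) || any(events$sample >= ncol(data)))) {
    stop("event sample indices must lie within the recording", call. = FALSE)
  }
  rownames(data) <- channel_names
  structure(
    list(data = data, rate = as.numeric(rate), channel_names = channel_names,
         events = events[order(events$sample), , drop = FALSE]),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.4g s), %d events\n",
              nrow(x$data), ncol(x$data), x$rate, ncol(x$data) / x$rate,
              nrow(x$events)))
  invisible(x)
}

#' Subset the channels of a recording
#'
#' @param rec an [eeg_recording()].
#' @param channels character labels (or integer indices) to keep, in the
#'   requested order.
#' @return An [eeg_recording()] restricted to `channels`.
#' @export
select_channels <- function(rec, channels) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (is.character(channels)) {
    missing <- setdiff(channels, rec$channel_names)
    if (length(missing)) {
      stop("unknown channel(s): ", paste(missing, collapse = ", "), call. = FALSE)
    }
    idx <- match(channels, rec$channel_names)
  } else {
    idx <- as.integer(channels)
  }
  eeg_recording(rec$data[idx, , drop = FALSE], rec$rate,
                rec$channel_names[idx], rec$events)
}

#' Construct a labelled epoch set
#'
#' The training tensor: channels x samples x epochs, each epoch labelled with
#' its cued target id.
#'
#' @param data 3-d numeric array `[channels, samples, epochs]` (uV).
#' @param rate sampling rate in Hz.
#' @param labels integer target id per epoch.
#' @param channel_names optional channel labels.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, rate, labels, channel_names = NULL) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) {
    stop("'data' must be a channels x samples x epochs array", call. = FALSE)
  }
  labels <- as.integer(labels)
  if (length(labels) != dim(data)[3]) {
    stop("one label per epoch required", call. = FALSE)
  }
  if (length(labels) && any(labels < 1L)) {
    stop("labels are 1-based target ids", call. = FALSE)
  }
  if (is.null(channel_names)) {
    channel_names <- dimnames(data)[[1]] %||% paste0("ch", seq_len(dim(data)[1]))
  }
  dimnames(data)[[1]] <- channel_names
  structure(
    list(data = data, rate = as.numeric(rate), labels = labels,
         channel_names = as.character(channel_names)),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d channels x %d samples x %d epochs @ %g Hz, %d distinct targets\n",
              d[1], d[2], d[3], x$rate, length(unique(x$labels))))
  invisible(x)
}

#' Construct a labelled segment set
#'
#' Segments are the EEG responses to exactly one full presentation of the
#' stimulation code (duration `segment_duration_s`, `n = round(c * rate)`
#' samples), stacked channels x samples x segments.
#'
#' @param data 3-d array `[channels, samples, segments]`.
#' @param rate sampling rate in Hz.
#' @param labels integer target id per segment.
#' @param segment_duration_s code-presentation time `c` in seconds.
#' @param epoch_index optional integer: epoch of origin per segment.
#' @return An object of class `segment_set`.
#' @export
segment_set <- function(data, rate, labels, segment_duration_s,
                        epoch_index = NULL) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) {
    stop("'data' must be a channels x samples x segments array", call. = FALSE)
  }
  labels <- as.integer(labels)
  if (length(labels) != dim(data)[3]) {
    stop("one label per segment required", call. = FALSE)
  }
  n_expected <- round(segment_duration_s * rate)
  if (dim(data)[2] != n_expected) {
    stop(sprintf("segment length %d does not match round(c * rate) = %d",
                 dim(data)[2], n_expected), call. = FALSE)
  }
  structure(
    list(data = data, rate = as.numeric(rate), labels = labels,
         segment_duration_s = as.numeric(segment_duration_s),
         epoch_index = if (is.null(epoch_index)) rep(NA_integer_, length(labels))
                       else as.integer(epoch_index)),
    class = "segment_set"
  )
}

#' @export
print.segment_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<segment_set> %d channels x %d samples x %d segments (c = %g s @ %g Hz)\n",
              d[1], d[2], d[3], x$segment_duration_s, x$rate))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
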
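#' The 63-bit m-sequence used to encode the 32 targets
#'
#' Canonical binary stimulation code of length 63 (degree-6 m-sequence:
#' 32 ones, 31 zeros, circular autocorrelation 63 at lag 0 and -1 at every
#' other lag). Stored as a plain `"0"`/`"1"` string; convert with
#' [binary_code()].
#'
#' @format A character string of 63 `0`/`1` characters.
#' @export
CVEP_CODE63 <- "000100001011001010100100111100000110111001100011101011111101101"

#' Construct a binary stimulation code
#'
#' A `binary_code` couples a 0/1 bit sequence with its presentation timing:
#' each bit is shown for `frames_per_bit` display frames on a monitor
#' refreshing at `display_rate` Hz. The reference protocol presents a 63-bit
#' code either at 60 Hz effective rate (`frames_per_bit = 2` on a 120 Hz
#' monitor) or at the full 120 Hz refresh (`frames_per_bit = 1`).
#'
#' @param bits integer/numeric vector of 0s and 1s, or a single `"0101..."`
#'   string.
#' @param frames_per_bit positive integer; display frames each bit is held.
#' @param display_rate monitor refresh rate in Hz.
#' @return An object of class `binary_code` with fields `bits`,
#'   `frames_per_bit`, `display_rate`.
#' @seealso [generate_m_sequence()], [build_codebook()]
#' @export
binary_code <- function(bits, frames_per_bit = 1L, display_rate = 120) {
  if (is.character(bits) && length(bits) == 1L) {
    bits <- as.integer(strsplit(bits, "", fixed = TRUE)[[1]])
  }
  bits <- as.integer(bits)
  if (length(bits) < 1L || anyNA(bits) || !all(bits %in% c(0L, 1L))) {
    stop("'bits' must be a non-empty sequence of 0s and 1s", call. = FALSE)
  }
  frames_per_bit <- as.integer(frames_per_bit)
  if (length(frames_per_bit) != 1L || is.na(frames_per_bit) || frames_per_bit < 1L) {
    stop("'frames_per_bit' must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(display_rate) || length(display_rate) != 1L || display_rate <= 0) {
    stop("'display_rate' must be a positive rate in Hz", call. = FALSE)
  }
  structure(
    list(bits = bits, frames_per_bit = frames_per_bit,
         display_rate = as.numeric(display_rate)),
    class = "binary_code"
  )
}

#' @export
print.binary_code <- function(x, ...) {
  cat(sprintf("<binary_code> %d bits, %d frame(s)/bit @ %g Hz (%.4g s/cycle)\n",
              length(x$bits), x$frames_per_bit, x$display_rate,
              code_cycle_seconds(x)))
  cat(" ", paste(x$bits, collapse = ""), "\n", sep = "")
  invisible(x)
}

#' Duration of one full code presentation, in seconds
#'
#' @param code a [binary_code()].
#' @return Numeric scalar: `length(bits) * frames_per_bit / display_rate`.
#' @export
code_cycle_seconds <- function(code) {
  stopifnot(inherits(code, "binary_code"))
  length(code$bits) * code$frames_per_bit / code$display_rate
}

#' Generate a maximal-length binary sequence (m-sequence) with an LFSR
#'
#' Steps a Fibonacci linear-feedback shift register of the given degree for
#' one full period `2^degree - 1`. Register stages are numbered 1..degree;
#' each step outputs stage `degree`, computes the feedback bit as the XOR of
#' the stages listed in `taps`, shifts the register towards higher indices
#' and inserts the feedback at stage 1. For primitive feedback taps the
#' output has period `2^degree - 1` and is balanced (`2^(degree-1)` ones).
#'
#' The state sequence is checked post hoc: if the register revisits its
#' initial state before `2^degree - 1` steps the taps are not primitive and
#' an error reports the measured period.
#'
#' @param degree register length (positive integer).
#' @param taps integer positions (in 1..degree) XOR-ed to form the feedback;
#'   must include stage `degree`. Default `c(degree, degree - 1)`, primitive
#'   for degree 2, 3, 4, 6, 7, 15 (in particular the degree-6 default used
#'   for 63-bit codes).
#' @param init_state bit vector of length `degree`, not all zero.
#' @param frames_per_bit,display_rate presentation timing for the returned
#'   [binary_code()].
#' @return A [binary_code()] of length `2^degree - 1`.
#' @examples
#' seq63 <- generate_m_sequence(6)
#' validate_m_sequence(seq63)
#' @export
generate_m_sequence <- function(degree, taps = c(degree, degree - 1L),
                                init_state = c(rep(0L, degree - 1L), 1L),
                                frames_per_bit = 1L, display_rate = 120) {
  degree <- as.integer(degree)
  if (length(degree) != 1L || is.na(degree) || degree < 2L) {
    stop("'degree' must be an integer >= 2", call. = FALSE)
  }
  taps <- sort(unique(as.integer(taps)))
  if (any(taps < 1L | taps > degree)) {
    stop("'taps' must be register positions in 1..degree", call. = FALSE)
  }
  if (!(degree %in% taps)) {
    stop("'taps' must include the last stage (position ", degree,
         ") for a full-length register", call. = FALSE)
  }
  state <- as.integer(init_state)
  if (length(state) != degree || !all(state %in% c(0L, 1L))) {
    stop("'init_state' must be a bit vector of length ", degree, call. = FALSE)
  }
  if (all(state == 0L)) {
    stop("'init_state' must not be all-zero (the LFSR would be stuck)",
         call. = FALSE)
  }
  period <- 2L^degree - 1L
  out <- integer(period)
  init <- state
  for (step in seq_len(period)) {
    out[step] <- state[degree]
    fb <- sum(state[taps]) %% 2L
    state <- c(fb, state[-degree])
    if (step < period && all(state == init)) {
      stop(sprintf(
        "taps do not define a primitive feedback polynomial: register period is %d, expected %d",
        step, period), call. = FALSE)
    }
  }
  if (!all(state == init)) {
    stop("LFSR did not return to its initial state after one nominal period",
         call. = FALSE)
  }
  binary_code(out, frames_per_bit = frames_per_bit, display_rate = display_rate)
}

#' Circular autocorrelation of a binary code on the +/-1 mapping
#'
#' Bits are mapped 0 -> -1, 1 -> +1 and the circular (periodic)
#' autocorrelation is computed for every lag `0..L-1`. For a true m-sequence
#' the result is two-valued: `L` at lag 0 and `-1` at every nonzero lag,
#' the property that makes lagged copies of the code separable decoding
#' templates.
#'
#' @param code a [binary_code()] or a 0/1 vector/string accepted by
#'   [binary_code()].
#' @return Integer vector of length `L`; element `k+1` is the correlation at
#'   lag `k`.
#' @export
circular_autocorrelation <- function(code) {
  bits <- if (inherits(code, "binary_code")) code$bits else binary_code(code)$bits
  x <- ifelse(bits == 1L, 1, -1)
  L <- length(x)
  vapply(0:(L - 1L), function(k) {
    sum(x * x[((seq_len(L) - 1L + k) %% L) + 1L])
  }, numeric(1)) |> as.integer()
}

#' Validate the defining properties of an m-sequence
#'
#' Checks balance (`(L+1)/2` ones for odd length `L`) and the two-valued
#' circular autocorrelation (`L` at lag 0, `-1` elsewhere).
#'
#' @param code a [binary_code()] (or anything [binary_code()] accepts).
#' @return A list with `is_balanced`, `is_two_valued_autocorrelation`,
#'   `period`, `n_ones`, `n_zeros`.
#' @export
validate_m_sequence <- function(code) {
  if (!inherits(code, "binary_code")) code <- binary_code(code)
  L <- length(code$bits)
  ones <- sum(code$bits)
  ac <- circular_autocorrelation(code)
  list(
    is_balanced = (L %% 2L == 1L) && ones == (L + 1L) %/% 2L,
    is_two_valued_autocorrelation =
      ac[1] == L && (L == 1L || all(ac[-1] == -1L)),
    period = L,
    n_ones = ones,
    n_zeros = L - ones
  )
}

#' Build a codebook of circularly lagged codes for N targets
#'
#' Target `i` (1-based) is assigned the circular lag
#' `(i - 1) * lag_step_frames` display frames of the base code; the reference
#' 32-target protocol uses two-frame steps on the 126-frame cycle of the
#' 63-bit code, i.e. lags 0, 2, ..., 62.
#'
#' @param base a [binary_code()].
#' @param n_targets number of selectable targets.
#' @param lag_step_frames lag increment between consecutive targets, in
#'   display frames.
#' @return An object of class `target_codebook` with fields `base`,
#'   `n_targets`, `lag_frames` (one non-negative lag per target).
#' @export
build_codebook <- function(base, n_targets, lag_step_frames = 2L) {
  stopifnot(inherits(base, "binary_code"))
  n_targets <- as.integer(n_targets)
  lag_step_frames <- as.integer(lag_step_frames)
  if (n_targets < 1L) stop("'n_targets' must be >= 1", call. = FALSE)
  if (lag_step_frames < 1L) stop("'lag_step_frames' must be >= 1", call. = FALSE)
  cycle_frames <- length(base$bits) * base$frames_per_bit
  lags <- (seq_len(n_targets) - 1L) * lag_step_frames
  # the operative requirement is that targets stay distinguishable: lags
  # must be pairwise distinct modulo the code cycle (note the 63-frame cycle
  # at full-rate presentation holds 32 two-frame lags because 63 is odd)
  if (anyDuplicated(lags %% cycle_frames)) {
    stop(sprintf(
      "too many targets: %d targets with a %d-frame lag step collide on the %d-frame code cycle",
      n_targets, lag_step_frames, cycle_frames), call. = FALSE)
  }
  structure(
    list(base = base, n_targets = n_targets, lag_frames = lags),
    class = "target_codebook"
  )
}

#' @export
print.target_codebook <- function(x, ...) {
  cat(sprintf("<target_codebook> %d targets on a %d-bit code (%d-frame cycle)\n",
              x$n_targets, length(x$base$bits),
              length(x$base$bits) * x$base$frames_per_bit))
  cat(sprintf("  lags (frames): %s%s\n",
              paste(utils::head(x$lag_frames, 8L), collapse = ", "),
              if (x$n_targets > 8L) ", ..." else ""))
  invisible(x)
}

#' Per-frame bit train of one target's lagged code
#'
#' Expands the base code to one entry per display frame and applies the
#' target's circular lag: frame `f` of target `i` shows the bit the base
#' code shows at frame `f - lag_i` (mod cycle).
#'
#' @param codebook a [build_codebook()] result.
#' @param target target index in `1..n_targets`.
#' @return Integer 0/1 vector of length `code length * frames_per_bit`.
#' @export
target_frame_sequence <- function(codebook, target) {
  stopifnot(inherits(codebook, "target_codebook"))
  target <- as.integer(target)
  if (target < 1L || target > codebook$n_targets) {
    stop("'target' out of range", call. = FALSE)
  }
  base <- codebook$base
  frames <- rep(base$bits, each = base$frames_per_bit)
  nf <- length(frames)
  lag <- codebook$lag_frames[target] %% nf
  frames[((seq_len(nf) - 1L - lag) %% nf) + 1L]
}

#' Serialise a codebook to a TSV lag table
#'
#' Writes one row per target (`target`, `lag_frames`, `lag_seconds`) plus the
#' base code as a `# code=` header comment, the display rate and frames per
#' bit as further header comments.
#'
#' @param codebook a [build_codebook()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_codebook <- function(codebook, path) {
  stopifnot(inherits(codebook, "target_codebook"))
  base <- codebook$base
  hdr <- c(
    sprintf("# code=%s", paste(base$bits, collapse = "")),
    sprintf("# frames_per_bit=%d", base$frames_per_bit),
    sprintf("# display_rate=%g", base$display_rate)
  )
  tab <- data.frame(
    target = seq_len(codebook$n_targets),
    lag_frames = codebook$lag_frames,
    lag_seconds = codebook$lag_frames / base$display_rate
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a codebook written by [write_codebook()]
#'
#' @param path TSV file with `# code=`, `# frames_per_bit=`, `# display_rate=`
#'   headers.
#' @return A `target_codebook`.
#' @export
read_codebook <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  get_field <- function(key) {
    ln <- grep(sprintf("^# %s=", key), hdr, value = TRUE)
    if (length(ln) != 1L) stop("codebook file missing '", key, "' header", call. = FALSE)
    sub(sprintf("^# %s=", key), "", ln)
  }
  base <- binary_code(get_field("code"),
                      frames_per_bit = as.integer(get_field("frames_per_bit")),
                      display_rate = as.numeric(get_field("display_rate")))
  tab <- utils::read.table(text = lines[!startsWith(lines, "#")],
                           header = TRUE, sep = "\t")
  lags <- as.integer(tab$lag_frames[order(tab$target)])
  cb <- structure(
    list(base = base, n_targets = nrow(tab), lag_frames = lags),
    class = "target_codebook"
  )
  cb
}
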
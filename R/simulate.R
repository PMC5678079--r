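#' Default 32-channel parieto-occipital montage
#'
#' Channel labels for a synthetic 32-electrode montage covering the parietal
#' and occipital scalp (where code-locked visual responses are largest),
#' including the mastoid reference sites TP9/TP10. The exact site list is a
#' package convention for the simulator, not a copy of any recorded
#' montage.
#'
#' @return Character vector of 32 labels.
#' @export
default_montage <- function() {
  c("P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
    "PO7", "PO3", "POz", "PO4", "PO8", "PO9", "PO10",
    "O1", "Oz", "O2", "O9", "Iz", "O10",
    "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6",
    "TP7", "TP9", "TP10")
}

# Occipital-dominant forward topography over a montage: large weights on
# O/PO sites, moderate on parietal, near zero on mastoids.
default_topography <- function(montage) {
  w <- vapply(montage, function(ch) {
    if (grepl("^(O|Iz)", ch)) 1.0
    else if (grepl("^PO", ch)) 0.8
    else if (grepl("^P[0-9z]", ch)) 0.45
    else if (grepl("^CP", ch)) 0.2
    else 0.05                       # temporal / mastoid sites
  }, numeric(1))
  names(w) <- montage
  w
}

#' Biphasic visual impulse-response kernel
#'
#' Difference-of-gammas impulse response (~0.25 s support, positive peak
#' near 75 ms, opposing lobe near 120 ms) used by the simulator as the
#' evoked response to one luminance step. Any stable kernel works for
#' pipeline testing; this shape gives an EEG-plausible band-limited
#' response. Peak amplitude is normalised to 1.
#'
#' @param rate sampling rate in Hz.
#' @param duration_s kernel support in seconds.
#' @return Numeric vector of `round(duration_s * rate)` samples.
#' @export
vep_kernel <- function(rate, duration_s = 0.25) {
  t <- (seq_len(round(duration_s * rate)) - 1) / rate
  pos <- stats::dgamma(t, shape = 6, scale = 0.075 / 5)   # mode ~75 ms
  neg <- stats::dgamma(t, shape = 8, scale = 0.120 / 7)   # mode ~120 ms
  k <- pos / max(pos) - 0.6 * neg / max(neg)
  k / max(abs(k))
}

#' Configuration for a synthetic cVEP session
#'
#' Defines one simulated recording session: a codebook of lagged codes, a
#' montage with an occipital-dominant forward topography, presentation and
#' acquisition timing, the evoked-response kernel and amplitude, and an
#' EEG-like noise model (1/f^beta background + 10 Hz alpha + white sensor
#' noise). Defaults reproduce the reference protocol: a 63-bit m-sequence
#' on a 120 Hz display, 32 targets lagged in 2-frame steps, 5 cues per
#' target (160 trials of 5.25 s stimulation), 1 s inter-trial gap, 2000 Hz
#' acquisition, 32-channel parieto-occipital montage.
#'
#' @param session `"120"` (1 frame/bit, 10 code repetitions per trial) or
#'   `"60"` (2 frames/bit, 5 repetitions).
#' @param n_targets selectable targets (default 32).
#' @param trials_per_target cues per target (default 5).
#' @param montage channel labels (default [default_montage()]).
#' @param acquisition_rate EEG sampling rate in Hz (default 2000).
#' @param signal_amp_uv evoked-response peak amplitude in uV (default 5).
#' @param mixing named channels x 1 topography; default occipital-dominant
#'   over `montage`.
#' @param noise_sd white sensor-noise SD in uV (default 3).
#' @param alpha_amp_uv 10 Hz alpha amplitude in uV (default 10).
#' @param pink_amp_uv 1/f background SD in uV (default 10).
#' @param pink_exponent spectral exponent beta (default 1).
#' @param inter_trial_gap_s seconds between trials with targets hidden
#'   (default 1).
#' @param transition_s onset-latency ramp duration in seconds (default 0:
#'   the evoked drive is at full strength from the first frame; 0.150
#'   emulates the post-onset transition during which the response has not
#'   yet stabilised).
#' @param target_gain_sd SD of a per-target multiplicative response gain
#'   (mean 1, truncated at 0.1; default 0). Nonzero values make the evoked
#'   templates heterogeneous across targets instead of exact circular
#'   shifts of one another.
#' @param seed integer; fixes all randomness (cue order, noise, phases).
#' @param code base [binary_code()] bits (default the 63-bit constant
#'   [CVEP_CODE63]).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(session = c("120", "60"), n_targets = 32L,
                       trials_per_target = 5L,
                       montage = default_montage(),
                       acquisition_rate = 2000,
                       signal_amp_uv = 5,
                       mixing = NULL,
                       noise_sd = 3, alpha_amp_uv = 10, pink_amp_uv = 10,
                       pink_exponent = 1,
                       inter_trial_gap_s = 1,
                       transition_s = 0,
                       target_gain_sd = 0,
                       seed = 1L,
                       code = CVEP_CODE63) {
  session <- match.arg(as.character(session), c("120", "60"))
  frames_per_bit <- if (session == "120") 1L else 2L
  base <- binary_code(code, frames_per_bit = frames_per_bit, display_rate = 120)
  codebook <- build_codebook(base, n_targets, lag_step_frames = 2L)
  repetitions <- if (session == "120") 10L else 5L
  mixing <- mixing %||% default_topography(montage)
  stopifnot(length(mixing) == length(montage), noise_sd >= 0,
            alpha_amp_uv >= 0, pink_amp_uv >= 0, acquisition_rate > 0)
  structure(
    list(session = session, codebook = codebook, repetitions = repetitions,
         n_targets = as.integer(n_targets),
         trials_per_target = as.integer(trials_per_target),
         montage = montage, acquisition_rate = acquisition_rate,
         signal_amp_uv = signal_amp_uv, mixing = as.numeric(mixing),
         noise_sd = noise_sd, alpha_amp_uv = alpha_amp_uv,
         pink_amp_uv = pink_amp_uv, pink_exponent = pink_exponent,
         inter_trial_gap_s = inter_trial_gap_s,
         transition_s = transition_s, target_gain_sd = target_gain_sd,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> S%s: %d targets x %d trials, %d ch @ %g Hz, signal %g uV,\n  noise (white %g, alpha %g, pink %g uV), transition %g s, seed %d\n",
    x$session, x$n_targets, x$trials_per_target, length(x$montage),
    x$acquisition_rate, x$signal_amp_uv, x$noise_sd, x$alpha_amp_uv,
    x$pink_amp_uv, x$transition_s, x$seed))
  invisible(x)
}

# Evaluate expr with a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
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
  force(expr)
}

# Causal linear convolution via zero-padded FFT (padded to a 2/3/5-smooth
# length so the transform stays O(n log n) for any input size).
conv_causal <- function(x, kernel) {
  n <- length(x)
  N <- stats::nextn(n + length(kernel) - 1L, c(2L, 3L, 5L))
  fx <- stats::fft(c(x, numeric(N - n)))
  fk <- stats::fft(c(kernel, numeric(N - length(kernel))))
  Re(stats::fft(fx * fk, inverse = TRUE))[seq_len(n)] / N
}

# 1/f^beta Gaussian noise of length n via spectral shaping; unit SD.
# Generated at a 2/3/5-smooth length and truncated.
pink_noise <- function(n, beta = 1) {
  if (n < 2L) return(stats::rnorm(n))
  N <- stats::nextn(n, c(2L, 3L, 5L))
  w <- stats::rnorm(N)
  spec <- stats::fft(w)
  f <- c(1, seq_len(N - 1))                   # avoid dividing DC by zero
  f <- pmin(f, N - f + 1)                     # symmetric frequency index
  spec <- spec / f^(beta / 2)
  x <- Re(stats::fft(spec, inverse = TRUE))[seq_len(n)] / N
  x <- x - mean(x)
  x / stats::sd(x)
}

#' Simulate one cVEP recording session
#'
#' Builds a continuous multichannel recording: for each trial, the cued
#' target's lagged code (one entry per display frame, mapped 0 -> -1,
#' 1 -> +1) is expanded to the acquisition rate, optionally ramped over the
#' first `transition_s` seconds (onset latency), convolved with the evoked
#' kernel, scaled to `signal_amp_uv` and projected through the forward
#' topography; trials are separated by stimulus-free gaps. Channel noise
#' (1/f^beta background + 10 Hz alpha with random per-channel phase +
#' white sensor noise) is added over the whole recording. One onset event
#' per trial carries the cued target id; the cue order is a seeded shuffle
#' with every target cued `trials_per_target` times.
#'
#' @param cfg a [sim_config()].
#' @return An [eeg_recording()] at `cfg$acquisition_rate`.
#' @export
simulate_session <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, simulate_session_impl(cfg))
}

simulate_session_impl <- function(cfg) {
  acq <- cfg$acquisition_rate
  base <- cfg$codebook$base
  trial_s <- code_cycle_seconds(base) * cfg$repetitions
  trial_n <- round(trial_s * acq)
  gap_n <- round(cfg$inter_trial_gap_s * acq)
  n_trials <- cfg$n_targets * cfg$trials_per_target
  total_n <- gap_n + n_trials * (trial_n + gap_n)
  m <- length(cfg$montage)

  cues <- sample(rep(seq_len(cfg$n_targets), cfg$trials_per_target))
  gains <- if (cfg$target_gain_sd > 0) {
    pmax(stats::rnorm(cfg$n_targets, 1, cfg$target_gain_sd), 0.1)
  } else rep(1, cfg$n_targets)
  onsets <- gap_n + (seq_len(n_trials) - 1L) * (trial_n + gap_n)  # 0-based

  # stimulus drive over the full session (0 outside trials)
  drive <- numeric(total_n)
  frame_of_sample <- floor((seq_len(trial_n) - 1L) / acq * base$display_rate)
  nf <- length(base$bits) * base$frames_per_bit
  ramp <- if (cfg$transition_s > 0) {
    nr <- round(cfg$transition_s * acq)
    c(seq(0, 1, length.out = nr), rep(1, trial_n - nr))
  } else rep(1, trial_n)
  for (tr in seq_len(n_trials)) {
    frames <- target_frame_sequence(cfg$codebook, cues[tr])
    bit <- frames[(frame_of_sample %% nf) + 1L]
    drive[onsets[tr] + seq_len(trial_n)] <- ifelse(bit == 1L, 1, -1) * ramp *
      gains[cues[tr]]
  }

  kernel <- vep_kernel(acq)
  resp <- conv_causal(drive, kernel) * cfg$signal_amp_uv

  data <- outer(cfg$mixing, resp)
  tsec <- (seq_len(total_n) - 1) / acq
  for (ch in seq_len(m)) {
    noise <- numeric(total_n)
    if (cfg$pink_amp_uv > 0) {
      noise <- noise + cfg$pink_amp_uv * pink_noise(total_n, cfg$pink_exponent)
    }
    if (cfg$alpha_amp_uv > 0) {
      noise <- noise + cfg$alpha_amp_uv *
        sin(2 * pi * 10 * tsec + stats::runif(1, 0, 2 * pi))
    }
    if (cfg$noise_sd > 0) {
      noise <- noise + stats::rnorm(total_n, sd = cfg$noise_sd)
    }
    data[ch, ] <- data[ch, ] + noise
  }

  eeg_recording(data, acq, cfg$montage,
                events = data.frame(sample = onsets, label = cues))
}

#' Simulate and preprocess a session in one call
#'
#' Convenience wrapper: [simulate_session()] then [preprocess_recording()]
#' with the [run_config()] matching the simulation's session type.
#'
#' @param cfg a [sim_config()].
#' @param config optional [run_config()]; defaults to the session-matched
#'   configuration with `n_targets` taken from `cfg`.
#' @return An [epoch_set()] at the analysis rate.
#' @export
simulate_epochs <- function(cfg, config = NULL) {
  config <- config %||% run_config(cfg$session, n_targets = cfg$n_targets)
  preprocess_recording(simulate_session(cfg), config)
}

#' Visual angle subtended by an object
#'
#' `2 * atan(size / (2 * distance))`, in degrees: a 4 cm target at the
#' protocol's 60 cm viewing distance spans ~3.8 degrees; the 2 cm
#' inter-target gap spans ~1.9 degrees.
#'
#' @param size_cm object extent (cm), >= 0.
#' @param distance_cm viewing distance (cm), > 0.
#' @return Angle in degrees.
#' @export
visual_angle <- function(size_cm, distance_cm) {
  if (any(distance_cm <= 0)) stop("'distance_cm' must be positive", call. = FALSE)
  if (any(size_cm < 0)) stop("'size_cm' must be non-negative", call. = FALSE)
  2 * atan(size_cm / (2 * distance_cm)) * 180 / pi
}

#' Stimulation duration of one trial
#'
#' `length(bits) * frames_per_bit * repetitions / display_rate` seconds:
#' 5.25 s for the 63-bit code at either 5 repetitions x 2 frames/bit or
#' 10 repetitions x 1 frame/bit on a 120 Hz display.
#'
#' @param code a [binary_code()].
#' @param repetitions number of full code presentations (>= 1).
#' @return Duration in seconds.
#' @export
session_timing <- function(code, repetitions) {
  stopifnot(inherits(code, "binary_code"), repetitions >= 1)
  code_cycle_seconds(code) * repetitions
}
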
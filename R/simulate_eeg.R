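#' EEG simulation configuration
#'
#' Generative model for synthetic sleep EEG: pink (1/f) background activity,
#' stage-dependent delta-band oscillations whose amplitude decays across the
#' night with time constant `homeostatic_tau_h` (emulating the dissipation
#' of homeostatic sleep pressure), 50-Hz power-line contamination, and
#' occasional high-amplitude artifact epochs. A per-condition multiplier
#' scales the delta amplitude in the first half of the night, emulating a
#' drug effect on early-night slow-wave activity. Defaults are calibrated so
#' a full simulated placebo night lands near a first-half log10 slow-wave
#' energy of ~4.7 after the analysis pipeline.
#'
#' @param fs_raw raw sampling rate, Hz.
#' @param one_over_f_exponent spectral exponent of the background
#'   (PSD ~ 1/f^a).
#' @param background_rms_uV RMS amplitude of the broadband background, uV.
#' @param delta_amp_by_stage named amplitudes (uV) of the delta oscillation
#'   per stage.
#' @param delta_freq_hz frequency of the delta oscillation, Hz.
#' @param homeostatic_tau_h decay time constant of delta amplitude across
#'   the night, hours.
#' @param line_noise_amp_uV 50-Hz line-noise amplitude, uV.
#' @param line_freq_hz power-line frequency, Hz.
#' @param artifact_fraction fraction of epochs flagged as artifacts per
#'   channel, in \[0, 0.5\].
#' @param artifact_amp_uV amplitude of the artifact transients, uV.
#' @param condition_delta_multiplier named per-condition multiplier applied
#'   to the delta amplitude in the first half of the night. The defaults
#'   (dex20 10^(0.07/2), dex40 10^(0.09/2)) put the first-half SWE of the
#'   active conditions ~0.07 and ~0.09 log10 units above placebo.
#' @return an object of class `eeg_sim_config`.
#' @export
eeg_sim_config <- function(fs_raw = 256,
                           one_over_f_exponent = 1,
                           background_rms_uV = 10,
                           delta_amp_by_stage = c(W = 0, N1 = 6, N2 = 20,
                                                  N3 = 40, R = 4),
                           delta_freq_hz = 1.25,
                           homeostatic_tau_h = 4,
                           line_noise_amp_uV = 2,
                           line_freq_hz = 50,
                           artifact_fraction = 0.05,
                           artifact_amp_uV = 150,
                           condition_delta_multiplier = c(placebo = 1,
                                                          dex20 = 10^(0.07 / 2),
                                                          dex40 = 10^(0.09 / 2))) {
  if (artifact_fraction < 0 || artifact_fraction > 0.5) {
    stop("artifact_fraction must be in [0, 0.5]", call. = FALSE)
  }
  if (!all(c("W", "N1", "N2", "N3", "R") %in% names(delta_amp_by_stage))) {
    stop("delta_amp_by_stage must name all five stages", call. = FALSE)
  }
  structure(
    list(fs_raw = fs_raw, one_over_f_exponent = one_over_f_exponent,
         background_rms_uV = background_rms_uV,
         delta_amp_by_stage = delta_amp_by_stage,
         delta_freq_hz = delta_freq_hz,
         homeostatic_tau_h = homeostatic_tau_h,
         line_noise_amp_uV = line_noise_amp_uV, line_freq_hz = line_freq_hz,
         artifact_fraction = artifact_fraction,
         artifact_amp_uV = artifact_amp_uV,
         condition_delta_multiplier = condition_delta_multiplier),
    class = "eeg_sim_config"
  )
}

# 1/f^a noise of length n at rate fs, unit RMS. Built directly in the
# frequency domain (Hermitian-symmetric complex Gaussian spectrum shaped by
# f^(-a/2)) so only one inverse FFT is needed.
pink_noise <- function(n, fs, exponent) {
  if (exponent == 0) return(stats::rnorm(n))
  m <- n %/% 2
  f_pos <- seq_len(m) * fs / n
  g <- f_pos^(-exponent / 2)
  half <- complex(real = stats::rnorm(m), imaginary = stats::rnorm(m)) * g
  if (n %% 2 == 0) half[m] <- complex(real = Re(half[m]), imaginary = 0)
  spec <- c(0, half, Conj(rev(half[seq_len(m - (n %% 2 == 0))])))
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Simulate one night of two-channel sleep EEG
#'
#' Builds nominal C3-M2 and C4-M1 signals for a scored night: each 30-s
#' epoch carries a delta oscillation at the stage's amplitude, damped by
#' `exp(-t / homeostatic_tau_h)` across the night and scaled by the
#' condition's first-half multiplier, on top of 1/f background and line
#' noise. Artifact epochs (independent per channel) receive a large
#' low-frequency transient and are flagged in the artifact mask.
#'
#' @param hyp the night's [hypnogram()]; its `condition` selects the
#'   first-half delta multiplier (unknown conditions get 1).
#' @param config an [eeg_sim_config()].
#' @param seed integer seed (bit-identical output for a fixed seed).
#' @return a [raw_eeg()] with channels `C3_M2`, `C4_M1` at `fs_raw`.
#' @export
simulate_eeg <- function(hyp, config = eeg_sim_config(), seed = 1L) {
  stopifnot(inherits(hyp, "hypnogram"), inherits(config, "eeg_sim_config"))
  fs <- config$fs_raw
  n_ep <- length(hyp$stages)
  ns_ep <- round(fs * hyp$epoch_s)
  n <- n_ep * ns_ep
  t_h <- (seq_len(n) - 1) / fs / 3600  # hours since lights-off
  half_first <- t_h < n_ep * hyp$epoch_s / 3600 / 2
  mult <- config$condition_delta_multiplier
  cmult <- if (!is.na(hyp$condition) && hyp$condition %in% names(mult)) {
    mult[[hyp$condition]]
  } else 1
  amp_ep <- config$delta_amp_by_stage[hyp$stages]
  amp <- rep(amp_ep, each = ns_ep) * exp(-t_h / config$homeostatic_tau_h)
  if (cmult != 1) amp[half_first] <- amp[half_first] * cmult
  with_seed(seed, {
    chans <- c("C3_M2", "C4_M1")
    data <- matrix(0, n, 2, dimnames = list(NULL, chans))
    artifacts <- matrix(FALSE, n_ep, 2, dimnames = list(NULL, chans))
    for (ch in 1:2) {
      phase <- stats::runif(1, 0, 2 * pi)
      x <- amp * sin(2 * pi * config$delta_freq_hz * t_h * 3600 + phase)
      if (config$background_rms_uV > 0) {
        x <- x + config$background_rms_uV *
          pink_noise(n, fs, config$one_over_f_exponent)
      }
      if (config$line_noise_amp_uV > 0) {
        x <- x + config$line_noise_amp_uV *
          sin(2 * pi * config$line_freq_hz * t_h * 3600)
      }
      if (config$artifact_fraction > 0) {
        n_art <- floor(config$artifact_fraction * n_ep)
        if (n_art > 0) {
          flagged <- sample.int(n_ep, n_art)
          artifacts[flagged, ch] <- TRUE
          for (ep in flagged) {
            idx <- (ep - 1L) * ns_ep + seq_len(ns_ep)
            x[idx] <- x[idx] + config$artifact_amp_uV *
              sin(2 * pi * 3 * t_h[idx] * 3600)
          }
        }
      }
      data[, ch] <- x
    }
    out <- raw_eeg(data, fs = fs, epoch_s = hyp$epoch_s,
                   artifacts = artifacts)
    attr(out, "seed") <- as.integer(seed)
    out
  })
}
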
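#' Raw multichannel EEG container
#'
#' Holds equally-sampled EEG channels in microvolts plus a per-epoch,
#' per-channel artifact mask.
#'
#' @param data numeric matrix, samples x channels, with column names.
#' @param fs sampling rate in Hz.
#' @param epoch_s scoring epoch length in seconds.
#' @param artifacts logical matrix, epochs x channels (`TRUE` = artifact);
#'   defaults to all clean, sized from the full epochs present.
#' @return an object of class `raw_eeg`.
#' @export
raw_eeg <- function(data, fs, epoch_s = 30, artifacts = NULL) {
  data <- as.matrix(data)
  if (is.null(colnames(data))) {
    colnames(data) <- paste0("ch", seq_len(ncol(data)))
  }
  n_ep <- floor(nrow(data) / (fs * epoch_s))
  if (is.null(artifacts)) {
    artifacts <- matrix(FALSE, n_ep, ncol(data),
                        dimnames = list(NULL, colnames(data)))
  }
  if (nrow(artifacts) != n_ep) {
    stop("artifact mask must have one row per full epoch", call. = FALSE)
  }
  structure(list(data = data, fs = fs, epoch_s = epoch_s,
                 artifacts = artifacts),
            class = "raw_eeg")
}

#' @export
print.raw_eeg <- function(x, ...) {
  cat(sprintf("Raw EEG: %d channels (%s), %.1f s at %g Hz, %d epochs, %d artifact flags\n",
              ncol(x$data), paste(colnames(x$data), collapse = ", "),
              nrow(x$data) / x$fs, x$fs, nrow(x$artifacts),
              sum(x$artifacts)))
  invisible(x)
}

# zero-phase filter application guarded against pathological edge effects
zp_filter <- function(filt, x) as.numeric(signal::filtfilt(filt, x))

#' Preprocess raw EEG for spectral analysis
#'
#' The standard chain ahead of the slow-wave pipeline: power-line notch,
#' zero-phase band-pass (high-pass 0.5 Hz, low-pass 40 Hz by default),
#' downsampling to 128 Hz, and optional re-referencing of central channels
#' to the contralateral mastoid (C3-M2, C4-M1). All filters are applied
#' forward-backward so band-power estimates are not phase-distorted.
#'
#' @param raw a [raw_eeg()].
#' @param notch_hz power-line frequency to notch (set `NULL` to skip);
#'   default 50 Hz (European mains).
#' @param notch_halfwidth_hz half-width of the band-stop notch, Hz.
#' @param band band-pass edges in Hz, `c(high_pass, low_pass)`.
#' @param target_fs output sampling rate, Hz.
#' @param rereference `"auto"` derives C3-M2/C4-M1 when channels C3, C4,
#'   M1, M2 are all present; `TRUE` requires them (error when missing);
#'   `FALSE` leaves channels untouched.
#' @return a [raw_eeg()] at `target_fs`.
#' @export
preprocess_eeg <- function(raw, notch_hz = 50, notch_halfwidth_hz = 2,
                           band = c(0.5, 40), target_fs = 128,
                           rereference = "auto") {
  stopifnot(inherits(raw, "raw_eeg"))
  if (raw$fs < 2 * band[2]) {
    stop("sampling rate must be at least twice the low-pass edge",
         call. = FALSE)
  }
  data <- raw$data
  artifacts <- raw$artifacts
  chans <- colnames(data)
  want_reref <- isTRUE(rereference) ||
    (identical(rereference, "auto") && all(c("C3", "C4", "M1", "M2") %in% chans))
  if (isTRUE(rereference) && !all(c("C3", "C4", "M1", "M2") %in% chans)) {
    stop("re-referencing requested but mastoid channels M1/M2 (and C3/C4) ",
         "are not all present", call. = FALSE)
  }
  if (want_reref) {
    data <- cbind(`C3_M2` = data[, "C3"] - data[, "M2"],
                  `C4_M1` = data[, "C4"] - data[, "M1"])
    a <- cbind(`C3_M2` = artifacts[, "C3"] | artifacts[, "M2"],
               `C4_M1` = artifacts[, "C4"] | artifacts[, "M1"])
    artifacts <- a
  }
  nyq <- raw$fs / 2
  out <- data
  if (!is.null(notch_hz)) {
    wstop <- c(notch_hz - notch_halfwidth_hz, notch_hz + notch_halfwidth_hz) / nyq
    if (wstop[2] < 1) {
      notch <- signal::butter(2, wstop, type = "stop")
      out <- apply(out, 2, function(x) zp_filter(notch, x))
    }
  }
  # anti-aliasing low-pass at the raw rate, then downsample, then the
  # high-pass at the target rate (cheaper and equivalent within the band)
  lp <- signal::butter(6, band[2] / nyq, type = "low")
  out <- apply(out, 2, function(x) zp_filter(lp, x))
  if (target_fs != raw$fs) {
    if (raw$fs %% target_fs == 0) {
      step <- raw$fs / target_fs
      out <- out[seq(1, nrow(out), by = step), , drop = FALSE]
    } else {
      out <- apply(out, 2, function(x)
        as.numeric(signal::resample(x, p = target_fs, q = raw$fs)))
    }
  }
  hp <- signal::butter(2, band[1] / (target_fs / 2), type = "high")
  out <- apply(out, 2, function(x) zp_filter(hp, x))
  colnames(out) <- colnames(data)
  raw_eeg(out, fs = target_fs, epoch_s = raw$epoch_s, artifacts = artifacts)
}

#' Per-epoch Welch power spectral density
#'
#' Decomposes one channel into per-epoch spectra with Welch's averaged
#' modified periodogram: the signal is cut into 30-s epochs, each epoch into
#' Hann-tapered windows (4 s by default) with 50% overlap (14 windows per
#' 30-s epoch), and the window periodograms are averaged with density
#' scaling in uV^2/Hz. The bin spacing is `1 / window_s` (0.25 Hz for the
#' 4-s window) and frequencies span 0 to the Nyquist rate. A trailing
#' partial epoch is dropped.
#'
#' @param x numeric signal in uV (one channel).
#' @param fs sampling rate, Hz.
#' @param epoch_s epoch length, s.
#' @param window_s Welch window length, s.
#' @param overlap fractional window overlap.
#' @param artifact optional logical artifact flag per epoch, stored in the
#'   result.
#' @return an object of class `epoch_psd`: list with `freq` (Hz), `power`
#'   (epochs x bins matrix, uV^2/Hz), `artifact`, `n_windows`, `df`.
#' @export
epoch_psd <- function(x, fs = 128, epoch_s = 30, window_s = 4,
                      overlap = 0.5, artifact = NULL) {
  ns_ep <- round(fs * epoch_s)
  ns_win <- round(fs * window_s)
  if (ns_ep < ns_win) stop("epoch shorter than one window", call. = FALSE)
  n_ep <- floor(length(x) / ns_ep)
  if (n_ep < 1L) stop("signal shorter than one epoch", call. = FALSE)
  hop <- round(ns_win * (1 - overlap))
  n_win <- as.integer(floor((ns_ep - ns_win) / hop) + 1L)
  w <- 0.5 * (1 - cos(2 * pi * seq(0, ns_win - 1) / (ns_win - 1)))  # Hann
  u <- sum(w^2)
  n_bins <- ns_win %/% 2 + 1L
  freq <- (seq_len(n_bins) - 1) * fs / ns_win
  power <- matrix(0, n_ep, n_bins)
  for (ep in seq_len(n_ep)) {
    seg0 <- (ep - 1L) * ns_ep
    acc <- numeric(n_bins)
    for (j in seq_len(n_win)) {
      idx <- seg0 + (j - 1L) * hop + seq_len(ns_win)
      sp <- Mod(stats::fft(x[idx] * w))^2 / (fs * u)
      p <- sp[seq_len(n_bins)]
      p[2:(n_bins - 1L)] <- 2 * p[2:(n_bins - 1L)]  # one-sided density
      acc <- acc + p
    }
    power[ep, ] <- acc / n_win
  }
  if (is.null(artifact)) artifact <- rep(FALSE, n_ep)
  if (length(artifact) < n_ep) {
    stop("artifact flag vector shorter than epoch count", call. = FALSE)
  }
  structure(list(freq = freq, power = power,
                 artifact = as.logical(artifact[seq_len(n_ep)]),
                 n_windows = n_win, df = fs / ns_win),
            class = "epoch_psd")
}

#' @export
print.epoch_psd <- function(x, ...) {
  cat(sprintf("Epoch PSD: %d epochs x %d bins (0-%.4g Hz, df = %g Hz), %d Welch windows/epoch\n",
              nrow(x$power), length(x$freq), max(x$freq), x$df, x$n_windows))
  invisible(x)
}

#' Per-epoch delta-band power
#'
#' Sums the spectral density over bins with `band[1] <= f <= band[2]`
#' (inclusive edges; 14 bins of 0.25 Hz for the default 0.75--4.0 Hz delta
#' band). `mode = "integrated"` multiplies by the bin width (band power in
#' uV^2); `mode = "density_sum"` reports the bare sum of densities
#' (uV^2/Hz), the convention some pipelines label band power with.
#'
#' @param psd an [epoch_psd()].
#' @param band band edges in Hz; must lie on PSD bins within range.
#' @param mode `"integrated"` (default) or `"density_sum"`.
#' @return numeric vector of per-epoch delta power.
#' @export
delta_power <- function(psd, band = c(0.75, 4.0),
                        mode = c("integrated", "density_sum")) {
  stopifnot(inherits(psd, "epoch_psd"))
  mode <- match.arg(mode)
  if (band[1] < min(psd$freq) || band[2] > max(psd$freq)) {
    stop("band outside PSD frequency range", call. = FALSE)
  }
  idx <- which(psd$freq >= band[1] - 1e-9 & psd$freq <= band[2] + 1e-9)
  if (length(idx) == 0L) stop("empty band selection", call. = FALSE)
  s <- rowSums(psd$power[, idx, drop = FALSE])
  if (mode == "integrated") s * psd$df else s
}

#' Half-night slow-wave energy over artifact-free N2/N3 epochs
#'
#' For each half of the night (time-since-lights-off split), the slow-wave
#' energy (SWE) is the cumulative sum of per-epoch delta power across epochs
#' scored N2 or N3 and free of artifacts. When several derivations are
#' supplied, the one with the better signal quality — operationalized as the
#' fewer artifact-flagged epochs, ties resolved in favour of the first
#' listed — is used. SWE is log10-transformed for the statistics layer.
#'
#' @param psds a single [epoch_psd()] or a named list of them (one per
#'   derivation), each carrying its artifact flags; epoch counts must match
#'   the hypnogram.
#' @param hyp the night's [hypnogram()].
#' @param band delta band edges in Hz.
#' @param mode band-power convention passed to [delta_power()].
#' @return data.frame with one row per half: `half`, `derivation`,
#'   `n_epochs` (qualifying epochs), `swe`, `log10_swe`. A half with zero
#'   qualifying epochs reports `NA`.
#' @export
slow_wave_energy <- function(psds, hyp, band = c(0.75, 4.0),
                             mode = c("integrated", "density_sum")) {
  mode <- match.arg(mode)
  stopifnot(inherits(hyp, "hypnogram"))
  if (inherits(psds, "epoch_psd")) psds <- list(derivation = psds)
  if (is.null(names(psds))) names(psds) <- paste0("d", seq_along(psds))
  n_art <- vapply(psds, function(p) sum(p$artifact), numeric(1))
  pick <- names(psds)[which.min(n_art)]  # which.min takes the first on ties
  psd <- psds[[pick]]
  n_ep <- length(hyp$stages)
  if (nrow(psd$power) != n_ep) {
    stop("PSD epoch count must equal hypnogram epoch count", call. = FALSE)
  }
  dp <- delta_power(psd, band = band, mode = mode)
  halves <- split_half_masks(hyp)
  qualify <- hyp$stages %in% c("N2", "N3") & !psd$artifact
  out <- lapply(names(halves), function(h) {
    sel <- qualify & halves[[h]]
    if (!any(sel)) {
      data.frame(half = h, derivation = pick, n_epochs = 0L,
                 swe = NA_real_, log10_swe = NA_real_)
    } else {
      swe <- sum(dp[sel])
      data.frame(half = h, derivation = pick, n_epochs = sum(sel),
                 swe = swe,
                 log10_swe = if (swe > 0) log10(swe) else NA_real_)
    }
  })
  do.call(rbind, out)
}
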
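test_that("simulated EEG has the constructed duration and channels", {
  hyp <- hypnogram(rep(c("N2", "R"), 10))
  cfg <- eeg_sim_config(fs_raw = 128)
  raw <- simulate_eeg(hyp, cfg, seed = 1)
  expect_identical(colnames(raw$data), c("C3_M2", "C4_M1"))
  expect_equal(nrow(raw$data), 20 * 30 * 128)
  expect_equal(nrow(raw$artifacts), 20)
})

test_that("silent configuration produces zero delta power in every epoch", {
  hyp <- hypnogram(rep("N3", 6))
  cfg <- eeg_sim_config(fs_raw = 128, background_rms_uV = 0,
                        line_noise_amp_uV = 0, artifact_fraction = 0,
                        delta_amp_by_stage = c(W = 0, N1 = 0, N2 = 0,
                                               N3 = 0, R = 0))
  raw <- simulate_eeg(hyp, cfg, seed = 4)
  psd <- epoch_psd(raw$data[, 1], fs = 128)
  expect_true(all(abs(delta_power(psd)) < 1e-12))
})

test_that("a pure delta oscillation reproduces the a^2/2 identity end to end", {
  hyp <- hypnogram(rep("N3", 4))
  a <- 30
  cfg <- eeg_sim_config(fs_raw = 128, background_rms_uV = 0,
                        line_noise_amp_uV = 0, artifact_fraction = 0,
                        delta_amp_by_stage = c(W = 0, N1 = 0, N2 = 0,
                                               N3 = a, R = 0),
                        homeostatic_tau_h = 1e9)  # no decay
  raw <- simulate_eeg(hyp, cfg, seed = 4)
  psd <- epoch_psd(raw$data[, 1], fs = 128)
  expect_equal(mean(delta_power(psd)), a^2 / 2, tolerance = 0.05)
})

test_that("artifact epochs are flagged at the configured rate and seed-stable", {
  hyp <- hypnogram(rep("N2", 40))
  cfg <- eeg_sim_config(fs_raw = 128, artifact_fraction = 0.1)
  raw1 <- simulate_eeg(hyp, cfg, seed = 8)
  raw2 <- simulate_eeg(hyp, cfg, seed = 8)
  expect_identical(raw1$data, raw2$data)
  expect_identical(raw1$artifacts, raw2$artifacts)
  expect_equal(colSums(raw1$artifacts), c(C3_M2 = 4, C4_M1 = 4))
})

test_that("delta amplitude declines across the night (homeostatic decay)", {
  hyp <- hypnogram(rep("N2", 120))  # 1 h night
  cfg <- eeg_sim_config(fs_raw = 128, background_rms_uV = 0,
                        line_noise_amp_uV = 0, artifact_fraction = 0,
                        homeostatic_tau_h = 0.5)
  raw <- simulate_eeg(hyp, cfg, seed = 2)
  dp <- delta_power(epoch_psd(raw$data[, 1], fs = 128))
  expect_lt(mean(dp[61:120]), mean(dp[1:60]))
})

test_that("a full default night lands in the plausible first-half SWE range and declines", {
  d <- study_design(n_subjects = 1, seed = 3)
  hyp <- simulate_hypnograms(d, sleep_sim_config())[["S01.placebo"]]
  raw <- simulate_eeg(hyp, eeg_sim_config(), seed = 11)
  pre <- preprocess_eeg(raw, rereference = FALSE)
  psds <- lapply(colnames(pre$data), function(ch)
    epoch_psd(pre$data[, ch], fs = pre$fs, artifact = pre$artifacts[, ch]))
  names(psds) <- colnames(pre$data)
  res <- slow_wave_energy(psds, hyp)
  first <- res$log10_swe[res$half == "first"]
  second <- res$log10_swe[res$half == "second"]
  expect_gt(first, 4.2)
  expect_lt(first, 5.3)
  expect_gt(first, second)
})

test_that("first-half SWE exceeds second-half SWE across simulated nights", {
  # scaled-down nights (2 h, 128 Hz) keep the homeostatic ordering testable
  diffs <- vapply(1:10, function(k) {
    hyp <- hypnogram(rep(c("N2", "N3", "N2", "R"), 60))  # 2 h
    cfg <- eeg_sim_config(fs_raw = 128, homeostatic_tau_h = 1,
                          artifact_fraction = 0)
    raw <- simulate_eeg(hyp, cfg, seed = 100 + k)
    psd <- epoch_psd(raw$data[, 1], fs = 128)
    res <- slow_wave_energy(psd, hyp)
    res$swe[res$half == "first"] - res$swe[res$half == "second"]
  }, numeric(1))
  expect_gt(mean(diffs) - 2 * sd(diffs) / sqrt(length(diffs)), 0)
})
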
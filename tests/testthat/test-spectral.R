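test_that("Welch geometry: 0.25-Hz bins, 14 windows per 30-s epoch", {
  x <- rnorm(128 * 60)
  psd <- epoch_psd(x, fs = 128)
  expect_equal(psd$df, 0.25)
  expect_equal(diff(psd$freq)[1], 0.25)
  expect_identical(psd$n_windows, 14L)  # floor((30-4)/2)+1
  expect_equal(range(psd$freq), c(0, 64))  # DC to Nyquist of 128 Hz
  expect_equal(nrow(psd$power), 2)  # trailing partial epochs dropped
})

test_that("zero signal yields an all-zero PSD", {
  psd <- epoch_psd(rep(0, 128 * 30), fs = 128)
  expect_true(all(psd$power == 0))
})

test_that("delta band selection matches a bin-enumeration oracle", {
  freq <- seq(0, 64, by = 0.25)
  d <- 3.7
  psd <- structure(list(freq = freq,
                        power = matrix(d, 1, length(freq)),
                        artifact = FALSE, n_windows = 14L, df = 0.25),
                   class = "epoch_psd")
  n_bins <- sum(freq >= 0.75 & freq <= 4.0)  # inclusive edges
  expect_identical(n_bins, 14L)
  expect_equal(delta_power(psd), d * n_bins * 0.25)  # = d * 3.5
  expect_equal(delta_power(psd, mode = "density_sum"), d * n_bins)
})

test_that("a pure 2-Hz sinusoid of amplitude a carries delta power a^2/2", {
  fs <- 128
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  for (a in c(1, 10)) {
    psd <- epoch_psd(a * sin(2 * pi * 2 * t), fs = fs)
    expect_lt(abs(delta_power(psd) - a^2 / 2) / (a^2 / 2), 0.05)
  }
  # out-of-band 10-Hz sinusoid leaks < 1% of its power into delta
  psd10 <- epoch_psd(10 * sin(2 * pi * 10 * t), fs = fs)
  expect_lt(delta_power(psd10) / 50, 0.01)
})

test_that("doubling the amplitude quadruples delta power", {
  fs <- 128
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  p1 <- delta_power(epoch_psd(sin(2 * pi * 1.5 * t), fs = fs))
  p2 <- delta_power(epoch_psd(2 * sin(2 * pi * 1.5 * t), fs = fs))
  expect_equal(p2 / p1, 4, tolerance = 0.01)
})

test_that("the PSD integral satisfies Parseval on stationary noise", {
  set.seed(61)
  y <- rnorm(128 * 300, sd = 3)
  psd <- epoch_psd(y, fs = 128)
  total <- mean(rowSums(psd$power)) * psd$df
  expect_lt(abs(total / var(y) - 1), 0.02)
})

test_that("preprocessing removes DC, attenuates 50 Hz >= 20 dB, outputs 128 Hz", {
  fs <- 256
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  line <- sin(2 * pi * 50 * t)
  raw <- raw_eeg(cbind(C3_M2 = 5 + line), fs = fs)
  pre <- preprocess_eeg(raw, rereference = FALSE)
  expect_equal(pre$fs, 128)
  expect_equal(nrow(pre$data), length(t) / 2)
  n <- nrow(pre$data)
  core <- pre$data[(n %/% 10):(9 * n %/% 10), 1]  # skip filter edges
  expect_lt(abs(mean(core)), 0.05)                  # DC removed
  atten_db <- 20 * log10(sqrt(mean(core^2)) / sqrt(mean(line^2)))
  expect_lt(atten_db, -20)
})

test_that("mastoid re-referencing derives C3-M2/C4-M1 or errors when absent", {
  fs <- 128
  n <- fs * 30
  base <- matrix(rnorm(n * 4), n, 4,
                 dimnames = list(NULL, c("C3", "C4", "M1", "M2")))
  raw <- raw_eeg(base, fs = fs)
  pre <- preprocess_eeg(raw, rereference = TRUE, target_fs = fs)
  expect_identical(colnames(pre$data), c("C3_M2", "C4_M1"))
  raw2 <- raw_eeg(base[, c("C3", "C4")], fs = fs)
  expect_error(preprocess_eeg(raw2, rereference = TRUE), "mastoid")
})

test_that("SWE sums qualifying epochs and ignores artifact epochs", {
  freq <- seq(0, 64, by = 0.25)
  mk_psd <- function(per_epoch, artifact) {
    structure(list(freq = freq,
                   power = matrix(rep(per_epoch, each = length(freq)),
                                  length(per_epoch), length(freq),
                                  byrow = TRUE),
                   artifact = artifact, n_windows = 14L, df = 0.25),
              class = "epoch_psd")
  }
  hyp <- hypnogram(c("N2", "N2", "W", "W"))
  p <- 2
  psd <- mk_psd(rep(p, 4), rep(FALSE, 4))
  res <- slow_wave_energy(psd, hyp)
  # two artifact-free N2 epochs of equal power in the first half
  expect_equal(res$swe[res$half == "first"], 2 * (p * 3.5))
  expect_true(is.na(res$swe[res$half == "second"]))  # no N2/N3 there
  # an artifact-flagged N3 epoch of huge power changes nothing
  hyp2 <- hypnogram(c("N2", "N2", "N3", "W"))
  psd2 <- mk_psd(c(p, p, 1e6, p), c(FALSE, FALSE, TRUE, FALSE))
  res2 <- slow_wave_energy(psd2, hyp2)
  expect_equal(res2$swe[res2$half == "first"],
               res$swe[res$half == "first"])
})

test_that("SWE is monotone nondecreasing as qualifying epochs are added", {
  freq <- seq(0, 64, by = 0.25)
  set.seed(3)
  pw <- matrix(rexp(8 * length(freq)), 8, length(freq))
  psd <- structure(list(freq = freq, power = pw,
                        artifact = rep(FALSE, 8), n_windows = 14L,
                        df = 0.25), class = "epoch_psd")
  stages <- rep("W", 8)
  prev <- 0
  for (i in 1:4) {
    stages[i] <- "N2"
    res <- slow_wave_energy(psd, hypnogram(stages))
    cur <- res$swe[res$half == "first"]
    expect_gte(cur, prev)
    prev <- cur
  }
})

test_that("the derivation with fewer artifact epochs is chosen, ties to the first", {
  freq <- seq(0, 64, by = 0.25)
  mk <- function(val, art) {
    structure(list(freq = freq, power = matrix(val, 2, length(freq)),
                   artifact = art, n_windows = 14L, df = 0.25),
              class = "epoch_psd")
  }
  hyp <- hypnogram(c("N2", "N3"))
  psds <- list(C3_M2 = mk(1, c(TRUE, FALSE)), C4_M1 = mk(9, c(FALSE, FALSE)))
  expect_identical(unique(slow_wave_energy(psds, hyp)$derivation), "C4_M1")
  psds_tie <- list(C3_M2 = mk(1, c(FALSE, FALSE)),
                   C4_M1 = mk(9, c(FALSE, FALSE)))
  expect_identical(unique(slow_wave_energy(psds_tie, hyp)$derivation),
                   "C3_M2")
})
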
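test_that("sleep onset follows the three-consecutive-epoch rule", {
  expect_identical(sleep_onset_index(hyp_from_codes("W", "W", "N1", "W",
                                                    "N1", "N1", "N1")), 4L)
  expect_identical(sleep_onset_index(hypnogram(rep("W", 20))), NA_integer_)
  expect_identical(sleep_onset_index(hypnogram(rep("N2", 10))), 0L)
  # an R run counts as sleep for onset
  expect_identical(sleep_onset_index(hyp_from_codes("W", "R", "R", "R")), 1L)
})

test_that("sleep onset matches a brute-force enumeration oracle", {
  # every length-6 sequence over {W, N1}
  grids <- expand.grid(rep(list(c("W", "N1")), 6), stringsAsFactors = FALSE)
  oracle <- function(stages) {
    sleep <- stages != "W"
    for (i in seq_len(length(stages) - 2)) {
      if (all(sleep[i:(i + 2)])) return(i - 1L)
    }
    NA_integer_
  }
  for (i in seq_len(nrow(grids))) {
    stages <- unlist(grids[i, ], use.names = FALSE)
    expect_identical(sleep_onset_index(hypnogram(stages)), oracle(stages))
  }
})

test_that("sleep variables match hand enumeration on toy nights", {
  v <- compute_sleep_variables(hyp_from_codes("W", "N1", "N1", "N1", "N2", "R"))
  expect_equal(v$sleep_latency_min, 0.5)
  expect_equal(v$rem_latency_min, 2.0)
  expect_equal(v$total_sleep_time_min, 2.5)
  expect_equal(v$waso_min, 0)
  expect_equal(v$nrem_n2n3_min, 0.5)
  # all-sleep night has 100% efficiency and zero latency
  v2 <- compute_sleep_variables(hypnogram(rep(c("N2", "N3", "R"), 10)))
  expect_equal(v2$sleep_efficiency_pct, 100)
  expect_equal(v2$sleep_latency_min, 0)
})

test_that("WASO equals a brute-force mask count after onset", {
  stages <- c(rep("W", 4), rep("N1", 3), "W", rep("N2", 5), "W", "W",
              rep("N3", 4), "R")
  stopifnot(length(stages) == 20)
  hyp <- hypnogram(stages)
  v <- compute_sleep_variables(hyp)
  onset <- sleep_onset_index(hyp)
  oracle_waso <- sum(stages[(onset + 1):length(stages)] == "W") * 0.5
  expect_equal(v$waso_min, oracle_waso)
  expect_equal(v$waso_min, 1.5)
})

test_that("missing onset and missing REM propagate as NA, never zero", {
  v <- compute_sleep_variables(hypnogram(c("W", "N1", "W", "N1", "W")))
  expect_true(is.na(v$sleep_latency_min))
  expect_true(is.na(v$waso_min))
  v2 <- compute_sleep_variables(hypnogram(rep("N2", 10)))
  expect_true(is.na(v2$rem_latency_min))
})

test_that("half-night masks partition the night with the odd-middle rule", {
  h960 <- hypnogram(rep("N2", 960))
  m <- split_half_masks(h960)
  expect_identical(which(m$first), 1:480)
  expect_identical(which(m$second), 481:960)
  expect_true(all(xor(m$first, m$second)))
  m5 <- split_half_masks(hypnogram(rep("W", 5)))
  expect_identical(sum(m5$first), 3L)
  expect_identical(sum(m5$second), 2L)
})

test_that("prepending wake epochs shifts latency by 0.5 min each, minutes unchanged", {
  base <- c("N1", "N1", "N1", "N2", "N2", "R", "W", "N3")
  v0 <- compute_sleep_variables(hypnogram(base))
  for (k in c(1, 5, 12)) {
    vk <- compute_sleep_variables(hypnogram(c(rep("W", k), base)))
    expect_equal(vk$sleep_latency_min, v0$sleep_latency_min + 0.5 * k)
    for (col in c("n1_min", "n2_min", "n3_min", "rem_min",
                  "total_sleep_time_min")) {
      expect_equal(vk[[col]], v0[[col]])
    }
  }
})

test_that("stage minutes, WASO and latency wake conserve time in bed", {
  d <- study_design(n_subjects = 4, seed = 21)
  hyps <- simulate_hypnograms(d, sleep_sim_config())
  for (hyp in hyps) {
    v <- compute_sleep_variables(hyp)
    expect_equal(v$total_sleep_time_min + v$waso_min + v$sleep_latency_min,
                 v$time_in_bed_min)
  }
})

test_that("hypnograms reject invalid codes and round-trip through text", {
  expect_error(hypnogram(c("N2", "S4")), "invalid stage")
  expect_error(hypnogram(character(0)), "nonempty")
  hyp <- hyp_from_codes("W", "N1", "N2", "N3", "R", "W")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_hypnogram(hyp, path)
  back <- read_hypnogram(path)
  expect_identical(back$stages, hyp$stages)
})
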
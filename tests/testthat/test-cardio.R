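mk_schellong <- function(sup_sbp, sup_dbp, upr_sbp, upr_dbp,
                         sup_hr = 60, upr_hr = 80) {
  data.frame(
    position = c(rep("supine", 3), rep("upright", 5)),
    sbp_mmHg = c(rep(sup_sbp, 3), upr_sbp),
    dbp_mmHg = c(rep(sup_dbp, 3), upr_dbp),
    hr_bpm = c(rep(sup_hr, 3), rep(upr_hr, 5))
  )
}

test_that("systolic drop >= 20 mmHg flags an orthostatic event", {
  rec <- mk_schellong(110, 70, c(88, 95, 100, 105, 108),
                      c(62, 64, 66, 68, 68))
  a <- schellong_assess(rec)
  expect_true(a$event)
  expect_equal(a$drops$sbp_drop[1], 22)
})

test_that("identical positions give no event and zero drops", {
  rec <- mk_schellong(110, 70, rep(110, 5), rep(70, 5))
  a <- schellong_assess(rec)
  expect_false(a$event)
  expect_true(all(a$drops$sbp_drop == 0))
  expect_true(all(a$drops$dbp_drop == 0))
})

test_that("a diastolic drop >= 10 mmHg suffices even with a small systolic drop", {
  rec <- mk_schellong(110, 70, c(105, 107, 108, 109, 110),
                      c(58, 65, 66, 68, 69))
  a <- schellong_assess(rec)
  expect_true(a$event)
  expect_equal(a$drops$dbp_drop[1], 12)
  expect_equal(a$drops$sbp_drop[1], 5)
})

test_that("the event rule matches exhaustive enumeration on a drop grid", {
  for (s_drop in c(0, 15, 19, 20, 21, 30)) {
    for (d_drop in c(0, 5, 9, 10, 11)) {
      rec <- mk_schellong(120, 80,
                          c(120 - s_drop, 120, 120, 120, 120),
                          c(80 - d_drop, 80, 80, 80, 80))
      expect_identical(schellong_assess(rec)$event,
                       s_drop >= 20 || d_drop >= 10,
                       label = sprintf("drop %d/%d", s_drop, d_drop))
    }
  }
})

test_that("only the first three upright readings count unless scan_all", {
  # the big drop sits at upright reading 4
  rec <- mk_schellong(120, 80, c(115, 115, 115, 90, 115),
                      c(78, 78, 78, 78, 78))
  expect_false(schellong_assess(rec)$event)
  expect_true(schellong_assess(rec, scan_all = TRUE)$event)
})

test_that("position means are permutation-invariant and missing stays missing", {
  rec <- mk_schellong(110, 70, c(100, 104, 98, 102, 106),
                      c(64, 66, 62, 68, 65))
  a <- schellong_assess(rec)
  shuffled <- rec[c(2, 1, 3, 8, 4, 6, 7, 5), ]
  b <- schellong_assess(shuffled)
  expect_equal(a$upright_means, b$upright_means)
  rec$sbp_mmHg[5] <- NA
  expect_false(schellong_assess(rec)$complete)
  expect_true(is.na(schellong_assess(rec)$upright_means[["sbp_mmHg"]]))
})

test_that("too few readings error", {
  rec <- data.frame(position = c("supine", "upright"), sbp_mmHg = c(110, 100),
                    dbp_mmHg = c(70, 65), hr_bpm = c(60, 80))
  expect_error(schellong_assess(rec), "at least")
})

test_that("heart rate by stage matches a mask-average oracle", {
  hyp <- hypnogram(c("W", "N1", "N2", "N3", "R", "R", "N2", "W"))
  hr <- c(75, 50, 50, 50, 70, 70, 50, 78)
  out <- hr_by_stage(hr, hyp)
  expect_equal(out[["nrem_bpm"]], 50)
  expect_equal(out[["rem_bpm"]], 70)
  # constant series collapses both means
  out2 <- hr_by_stage(rep(60, 8), hyp)
  expect_equal(unname(out2), c(60, 60))
  # no REM epochs leaves the REM mean missing
  hyp_nr <- hypnogram(rep("N2", 4))
  expect_true(is.na(hr_by_stage(rep(60, 4), hyp_nr)[["rem_bpm"]]))
})

test_that("endocrine means are plain arithmetic means", {
  expect_equal(endocrine_means(rep(8, 6)), 8)
  expect_equal(endocrine_means(c(100, 120, 140, 110, 130)), 120)
  expect_error(endocrine_means(numeric(0)), "at least one")
})
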
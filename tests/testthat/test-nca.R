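test_that("lambda_z is exact on a mono-exponential tail", {
  p <- profile_from_fn(function(t) exp(-t), grid = 0:9, loq = 1e-9)
  f <- fit_lambda_z(p)
  expect_true(f$estimable)
  expect_equal(f$lambda_z, 1, tolerance = 1e-9)
  expect_equal(f$r2_adj, 1, tolerance = 1e-9)
})

test_that("lambda_z matches the closed-form two-point slope on collinear points", {
  # log-linear through (4 h, 0.40) and (8 h, 0.10); (6 h, 0.20) lies on it
  prof <- concentration_profile(c(1, 4, 6, 8), c(0.5, 0.4, 0.2, 0.1),
                                blq = rep(FALSE, 4))
  f <- fit_lambda_z(prof)
  expect_equal(f$lambda_z, log(0.40 / 0.10) / 4, tolerance = 1e-9)
  expect_identical(f$n_lambda, 3L)
})

test_that("noiseless calibrated curves reproduce the cohort half-lives", {
  for (tgt in list(c(1.29, 3.56, 0.11), c(1.73, 3.83, 0.24))) {
    p <- calibrate_bateman(tgt[1], tgt[2], tgt[3])
    prof <- profile_from_fn(function(t) bateman(t, p))
    r <- nca_single(prof)
    expect_lt(abs(r$thalf - tgt[2]), 0.05)
    expect_equal(r$cmax, tgt[3], tolerance = 1e-9)
  }
})

test_that("non-declining terminal phase is flagged non-estimable", {
  prof <- concentration_profile(0:5, c(0.1, 0.2, 0.3, 0.3, 0.35, 0.4),
                                blq = rep(FALSE, 6))
  f <- fit_lambda_z(prof)
  expect_false(f$estimable)
  expect_true(is.na(f$lambda_z))
})

test_that("trapezoid handles the triangle toy and the all-zero profile", {
  tri <- concentration_profile(c(0, 1, 2), c(0, 1, 0), blq = rep(FALSE, 3))
  expect_equal(auc_trapezoid(tri, t_end = 2), 1.0)
  z <- concentration_profile(0:5, rep(0, 6), blq = rep(FALSE, 6))
  expect_equal(auc_trapezoid(z, t_end = 5), 0)
})

test_that("trapezoid equals an independent fine-grid summation oracle", {
  grid <- study_design()$sampling_times_h
  prof <- profile_from_fn(function(t) exp(-t), loq = 1e-9)
  # oracle: trapezoid on the same grid points computed by direct summation
  g <- c(0, grid[grid > 0])
  cc <- exp(-g); cc[1] <- 0  # time-0 concentration convention
  oracle <- sum(diff(g) * (head(cc, -1) + tail(cc, -1)) / 2)
  expect_equal(auc_trapezoid(prof, t_end = 9), oracle, tolerance = 1e-9)
})

test_that("AUC is additive over interior grid points", {
  p <- calibrate_bateman(1.5, 4, 0.3)
  prof <- profile_from_fn(function(t) bateman(t, p))
  for (a in c(1, 2.5, 4, 7)) {
    expect_equal(auc_trapezoid(prof, t_end = a) +
                   auc_trapezoid(prof, t_end = 9, t_start = a),
                 auc_trapezoid(prof, t_end = 9), tolerance = 1e-12)
  }
})

test_that("NCA is scale-equivariant", {
  p <- calibrate_bateman(1.5, 4, 0.3)
  prof <- profile_from_fn(function(t) bateman(t, p))
  prof3 <- profile_from_fn(function(t) 3 * bateman(t, p))
  r1 <- nca_single(prof); r3 <- nca_single(prof3)
  expect_equal(r3$cmax, 3 * r1$cmax)
  expect_equal(r3$auc_all, 3 * r1$auc_all, tolerance = 1e-12)
  expect_equal(r3$auc_inf, 3 * r1$auc_inf, tolerance = 1e-9)
  expect_equal(r3$tmax, r1$tmax)
  expect_equal(r3$lambda_z, r1$lambda_z, tolerance = 1e-9)
})

test_that("AUC_inf extrapolation identity and ordering hold", {
  # toy engineered so auc_all = 1.0, C_last = 0.1, lambda_z = 0.5:
  # log-linear tail over t = 2..4, peak at t = 1 chosen to close the area
  lam <- 0.5
  t_tail <- c(2, 3, 4)
  c_tail <- 0.1 * exp(lam * (4 - t_tail))  # ends at exactly 0.1
  auc_tail <- sum(diff(t_tail) * (head(c_tail, -1) + tail(c_tail, -1)) / 2)
  peak <- 1 - auc_tail - c_tail[1] / 2  # [0,1] + [1,2] trapezoids
  prof <- concentration_profile(c(0, 1, t_tail), c(0, peak, c_tail),
                                blq = rep(FALSE, 5))
  r <- nca_single(prof)
  expect_equal(r$auc_all, 1.0, tolerance = 1e-9)
  expect_equal(r$lambda_z, 0.5, tolerance = 1e-9)
  expect_equal(r$auc_inf, 1.2, tolerance = 1e-6)
  expect_gte(r$auc_inf, r$auc_all)
})

test_that("all-BLQ profiles error with a clear message", {
  prof <- concentration_profile(0:5, rep(0.001, 6), loq = 0.01)
  expect_error(nca_single(prof), "no quantifiable concentrations")
})

test_that("cohort summary computes mean, SD and CV as defined", {
  res <- data.frame(subject = c("a", "b", "c"), condition = "dex40",
                    cmax = c(1, 2, 3), tmax = c(1, 1, 1),
                    thalf = c(2, 2, 2), auc_all = c(1, 2, 3),
                    auc_inf = c(2, 3, 4), r2_adj = 1, n_lambda = 3L)
  s <- summarize_pk(res)
  row <- s[s$parameter == "cmax", ]
  expect_equal(row$mean, 2)
  expect_equal(row$sd, 1)
  expect_equal(row$cv_pct, 50)
  # identical values collapse to zero spread
  expect_equal(s[s$parameter == "tmax", ]$sd, 0)
  expect_equal(s[s$parameter == "tmax", ]$cv_pct, 0)
  # one row per parameter, one column per dose in the wide layout
  w <- pk_table(s)
  expect_identical(w$parameter,
                   c("cmax", "tmax", "thalf", "auc_all", "auc_inf"))
  expect_true("dex40" %in% names(w))
})
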
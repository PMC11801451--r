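#' Single subject x condition concentration--time profile
#'
#' Container for one plasma profile on the overnight sampling grid, with
#' below-limit-of-quantification (BLQ) flags. Times are hours relative to
#' drug intake; a single pre-dose time (< 0) is allowed.
#'
#' @param times sampling times in hours, strictly increasing.
#' @param conc concentrations in ng/ml, `>= 0`.
#' @param blq logical BLQ flags; defaults to `conc < loq`.
#' @param loq limit of quantification in ng/ml.
#' @param subject,condition identifying labels.
#' @return an object of class `concentration_profile`.
#' @export
concentration_profile <- function(times, conc, blq = conc < loq, loq = 0.01,
                                  subject = NA_character_,
                                  condition = NA_character_) {
  if (length(times) != length(conc)) stop("times/conc length mismatch")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(conc < 0)) stop("concentrations must be >= 0")
  structure(
    list(times = as.numeric(times), conc = as.numeric(conc),
         blq = as.logical(blq), loq = loq,
         subject = subject, condition = condition),
    class = "concentration_profile"
  )
}

#' @export
print.concentration_profile <- function(x, ...) {
  cat(sprintf("Concentration profile %s/%s: %d samples, %d BLQ, LOQ %g ng/ml\n",
              x$subject, x$condition, length(x$times), sum(x$blq), x$loq))
  invisible(x)
}

# Observed tmax among quantifiable samples (earliest in case of ties).
observed_tmax <- function(profile) {
  ok <- !profile$blq & profile$times >= 0
  if (!any(ok)) stop("no quantifiable concentrations", call. = FALSE)
  tq <- profile$times[ok]
  cq <- profile$conc[ok]
  tq[which.max(cq)]
}

#' Terminal log-linear slope (lambda_z)
#'
#' Fits log-linear least squares to terminal concentrations. Candidate point
#' sets are the last `k` quantifiable, strictly positive samples strictly
#' after tmax, for `k = 3` up to all such points; the set maximizing the
#' adjusted R-squared is selected, ties resolved in favour of more points.
#' This best-fit selection is the conventional noncompartmental rule.
#'
#' @param profile a [concentration_profile()].
#' @return list with `lambda_z` (1/h), `r2_adj`, `n_lambda`, and
#'   `estimable`; a non-declining terminal phase or fewer than 3 usable
#'   points yields `estimable = FALSE` with `NA` slope.
#' @examples
#' p <- concentration_profile(0:9, exp(-(0:9)), blq = rep(FALSE, 10))
#' fit_lambda_z(p)$lambda_z  # 1
#' @export
fit_lambda_z <- function(profile) {
  stopifnot(inherits(profile, "concentration_profile"))
  tmax <- observed_tmax(profile)
  ok <- !profile$blq & profile$conc > 0 & profile$times > tmax
  t_use <- profile$times[ok]
  c_use <- profile$conc[ok]
  n <- length(t_use)
  non_est <- list(lambda_z = NA_real_, r2_adj = NA_real_,
                  n_lambda = NA_integer_, estimable = FALSE)
  if (n < 3L) return(non_est)
  best <- NULL
  for (k in 3:n) {
    idx <- (n - k + 1L):n
    x <- t_use[idx]
    y <- log(c_use[idx])
    fit <- stats::lm.fit(cbind(1, x), y)
    slope <- unname(fit$coefficients[2L])
    ss_res <- sum(fit$residuals^2)
    ss_tot <- sum((y - mean(y))^2)
    r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
    r2_adj <- 1 - (1 - r2) * (k - 1) / (k - 2)
    # ties (within numerical noise) favour more points: >= keeps later k
    if (is.null(best) || r2_adj >= best$r2_adj - 1e-12) {
      best <- list(slope = slope, r2_adj = r2_adj, k = k)
    }
  }
  if (best$slope >= 0) return(non_est)
  list(lambda_z = -best$slope, r2_adj = best$r2_adj,
       n_lambda = as.integer(best$k), estimable = TRUE)
}

# Apply the BLQ policy and the time-0 convention, returning the series used
# for integration: time 0 concentration 0 (dose at lights-off; the pre-dose
# sample sits at negative time), BLQ at or before tmax set to 0, BLQ after
# tmax dropped (integration ends at the last quantifiable sample rather than
# inventing values below the LOQ).
integration_series <- function(profile) {
  t <- profile$times
  c <- profile$conc
  blq <- profile$blq
  keep <- t >= 0
  t <- t[keep]; c <- c[keep]; blq <- blq[keep]
  if (length(t) == 0L) stop("empty profile", call. = FALSE)
  has_quant <- any(!blq)
  tmax <- if (has_quant) t[which.max(ifelse(blq, -Inf, c))] else Inf
  c[blq & t <= tmax] <- 0
  blq[blq & t <= tmax] <- FALSE
  drop <- blq & t > tmax
  t <- t[!drop]; c <- c[!drop]
  if (length(t) == 0L || t[1] > 0) {
    t <- c(0, t); c <- c(0, c)
  }
  list(t = t, c = c)
}

#' Linear trapezoidal area under the curve
#'
#' Integrates the concentration--time profile with the linear trapezoidal
#' rule over `[t_start, t_end]`. Time 0 concentration is taken as 0 (drug
#' intake at lights-off; the pre-dose sample is at negative time). BLQ
#' samples before/at tmax count as 0; BLQ samples after tmax truncate the
#' integration at the last quantifiable sample. Interval boundaries falling
#' between samples are handled by linear interpolation.
#'
#' @param profile a [concentration_profile()].
#' @param t_end end of integration, hours (default 9, one hour after
#'   scheduled awakening).
#' @param t_start start of integration, hours.
#' @return AUC in ng*h/ml.
#' @examples
#' p <- concentration_profile(c(0, 1, 2), c(0, 1, 0), blq = c(FALSE, FALSE, FALSE))
#' auc_trapezoid(p, t_end = 2)  # 1
#' @export
auc_trapezoid <- function(profile, t_end = 9, t_start = 0) {
  stopifnot(inherits(profile, "concentration_profile"))
  if (t_end < t_start) stop("t_end must be >= t_start")
  ser <- integration_series(profile)
  t <- ser$t; c <- ser$c
  hi <- min(t_end, max(t))
  lo <- max(t_start, min(t))
  if (hi <= lo) return(0)
  tt <- sort(unique(c(lo, hi, t[t > lo & t < hi])))
  cc <- stats::approx(t, c, xout = tt, rule = 2)$y
  sum(diff(tt) * (utils::head(cc, -1) + utils::tail(cc, -1)) / 2)
}

#' Noncompartmental analysis of one profile
#'
#' Computes the standard noncompartmental parameter set: observed Cmax and
#' tmax among quantifiable samples, terminal slope via [fit_lambda_z()],
#' `thalf = ln(2)/lambda_z`, `AUC_all` by linear trapezoid to `t_end`, and
#' `AUC_inf = AUC_all + C_last / lambda_z` where `C_last` is the last
#' quantifiable concentration. If the terminal slope is non-estimable,
#' `thalf` and `auc_inf` are `NA` while the observed quantities are still
#' returned.
#'
#' @param profile a [concentration_profile()].
#' @param t_end end of the AUC_all integration window, hours.
#' @return an object of class `nca_result` (a list with fields `cmax`,
#'   `tmax`, `lambda_z`, `thalf`, `auc_all`, `auc_inf`, `r2_adj`,
#'   `n_lambda`, `lambda_estimable`).
#' @export
nca_single <- function(profile, t_end = 9) {
  stopifnot(inherits(profile, "concentration_profile"))
  ok <- !profile$blq & profile$times >= 0
  if (!any(ok)) stop("no quantifiable concentrations", call. = FALSE)
  tq <- profile$times[ok]
  cq <- profile$conc[ok]
  i_max <- which.max(cq)
  lam <- fit_lambda_z(profile)
  auc_all <- auc_trapezoid(profile, t_end = t_end)
  c_last <- cq[length(cq)]
  auc_inf <- if (lam$estimable) auc_all + c_last / lam$lambda_z else NA_real_
  structure(
    list(cmax = cq[i_max], tmax = tq[i_max],
         lambda_z = lam$lambda_z,
         thalf = if (lam$estimable) log(2) / lam$lambda_z else NA_real_,
         auc_all = auc_all, auc_inf = auc_inf,
         r2_adj = lam$r2_adj, n_lambda = lam$n_lambda,
         lambda_estimable = lam$estimable,
         subject = profile$subject, condition = profile$condition),
    class = "nca_result"
  )
}

#' @export
print.nca_result <- function(x, ...) {
  cat(sprintf("NCA %s/%s: Cmax %.4g ng/ml at %.3g h; t1/2 %.3g h; ",
              x$subject, x$condition, x$cmax, x$tmax, x$thalf))
  cat(sprintf("AUC_all %.4g, AUC_inf %.4g ng*h/ml (lambda_z n=%s, r2_adj=%.4g)\n",
              x$auc_all, x$auc_inf, x$n_lambda, x$r2_adj))
  invisible(x)
}

#' Noncompartmental analysis of a long-format concentration table
#'
#' Runs [nca_single()] for every subject x condition with at least one
#' quantifiable sample. Placebo-like all-BLQ profiles are skipped.
#'
#' @param conc long-format data.frame with columns `subject`, `condition`,
#'   `time_h`, `conc_ng_ml` and optionally `blq`.
#' @param loq limit of quantification used when `blq` is absent.
#' @param t_end AUC_all window end, hours.
#' @return data.frame with one row per analysable profile.
#' @export
nca_study <- function(conc, loq = 0.01, t_end = 9) {
  need <- c("subject", "condition", "time_h", "conc_ng_ml")
  if (!all(need %in% names(conc))) {
    stop("concentration table needs columns: ", paste(need, collapse = ", "))
  }
  if (is.null(conc$blq)) conc$blq <- conc$conc_ng_ml < loq
  out <- list()
  for (key in split(conc, list(conc$subject, conc$condition), drop = TRUE)) {
    key <- key[order(key$time_h), ]
    if (all(key$blq)) next
    prof <- concentration_profile(key$time_h, key$conc_ng_ml, key$blq,
                                  loq = loq, subject = key$subject[1],
                                  condition = key$condition[1])
    r <- nca_single(prof, t_end = t_end)
    out[[length(out) + 1L]] <- data.frame(
      subject = r$subject, condition = r$condition, cmax = r$cmax,
      tmax = r$tmax, lambda_z = r$lambda_z, thalf = r$thalf,
      auc_all = r$auc_all, auc_inf = r$auc_inf, r2_adj = r$r2_adj,
      n_lambda = if (is.na(r$n_lambda)) NA_integer_ else r$n_lambda
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cohort summary of noncompartmental parameters
#'
#' Per-condition mean, SD and coefficient of variation (CV% = 100*SD/mean)
#' for each pharmacokinetic parameter, with a formatted
#' `mean +/- SD (CV)` label mirroring the conventional cohort table layout.
#'
#' @param results data.frame from [nca_study()] (or rows of compatible
#'   shape).
#' @param parameters which parameter columns to summarize.
#' @return long data.frame with columns `condition`, `parameter`, `n`,
#'   `mean`, `sd`, `cv_pct`, `label`. Groups of size < 2 report `NA` SD/CV.
#' @seealso [pk_table()] for the parameter x dose layout.
#' @export
summarize_pk <- function(results,
                         parameters = c("cmax", "tmax", "thalf",
                                        "auc_all", "auc_inf")) {
  stopifnot(is.data.frame(results), "condition" %in% names(results))
  rows <- list()
  for (cond in unique(results$condition)) {
    sub <- results[results$condition == cond, , drop = FALSE]
    for (p in parameters) {
      v <- sub[[p]]
      v <- v[!is.na(v)]
      n <- length(v)
      m <- if (n) mean(v) else NA_real_
      s <- if (n >= 2) stats::sd(v) else NA_real_
      cv <- if (!is.na(s) && m != 0) 100 * s / m else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond, parameter = p, n = n, mean = m, sd = s,
        cv_pct = cv,
        label = if (is.na(s)) sprintf("%.2f", m) else
          sprintf("%.2f ± %.2f (%.2f)", m, s, cv)
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Parameter-by-dose pharmacokinetic table
#'
#' Pivots a [summarize_pk()] result into the classical cohort layout: one
#' row per parameter, one column per condition, cells formatted
#' `mean +/- SD (CV)`.
#'
#' @param summary data.frame from [summarize_pk()].
#' @return data.frame with a `parameter` column plus one column per
#'   condition.
#' @export
pk_table <- function(summary) {
  params <- unique(summary$parameter)
  conds <- unique(summary$condition)
  out <- data.frame(parameter = params)
  for (cond in conds) {
    out[[cond]] <- vapply(params, function(p) {
      row <- summary[summary$parameter == p & summary$condition == cond, ]
      if (nrow(row)) row$label[1] else NA_character_
    }, character(1))
  }
  out
}
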
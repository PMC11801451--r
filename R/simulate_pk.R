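#' Pharmacokinetic simulation configuration
#'
#' Per-condition Bateman population parameters plus variability and
#' quantification limits. The default calibrates the two active conditions to
#' the buccal-formulation cohort parameters (20 ug: tmax 1.29 h, t1/2 3.56 h,
#' Cmax 0.11 ng/ml; 40 ug: tmax 1.73 h, t1/2 3.83 h, Cmax 0.24 ng/ml) with
#' ~25% between-subject variability, and a placebo condition with scale 0.
#'
#' @param params named list of [bateman_params()] per condition.
#' @param bsv_cv between-subject lognormal coefficient of variation
#'   (fraction) applied to the concentration scale.
#' @param residual_cv proportional residual (assay) noise fraction.
#' @param loq lower limit of quantification, ng/ml.
#' @param lod limit of detection, ng/ml; `loq >= lod > 0`.
#' @return an object of class `pk_sim_config`.
#' @export
pk_sim_config <- function(params = NULL,
                          bsv_cv = 0.25,
                          residual_cv = 0.05,
                          loq = 0.01,
                          lod = 0.005) {
  if (is.null(params)) {
    params <- list(
      placebo = list(ka = 1, ke = 1, scale = 0),
      dex20 = calibrate_bateman(1.29, 3.56, 0.11),
      dex40 = calibrate_bateman(1.73, 3.83, 0.24)
    )
  }
  if (is.null(names(params)) || any(!nzchar(names(params)))) {
    stop("`params` must be a named per-condition list", call. = FALSE)
  }
  if (bsv_cv < 0 || residual_cv < 0) {
    stop("variability fractions must be >= 0", call. = FALSE)
  }
  if (!(loq >= lod && lod > 0)) stop("require loq >= lod > 0", call. = FALSE)
  structure(
    list(params = params, bsv_cv = bsv_cv, residual_cv = residual_cv,
         loq = loq, lod = lod),
    class = "pk_sim_config"
  )
}

#' Simulate a crossover set of plasma concentration profiles
#'
#' Draws one concentration--time profile per subject and condition on the
#' design's sampling grid. Each subject's curve is the condition's population
#' Bateman curve with a mean-preserving lognormal scale multiplier
#' (CV = `bsv_cv`) and proportional residual noise (CV = `residual_cv`).
#' The single pre-dose sample is 0 for every condition, values below the
#' limit of quantification are flagged BLQ, and output is bit-identical for
#' a fixed seed.
#'
#' @param design a [study_design()].
#' @param config a [pk_sim_config()]; must cover every design condition.
#' @param seed integer seed; defaults to a child of `design$seed`.
#' @return a long-format data.frame with columns `subject`, `condition`,
#'   `time_h`, `conc_ng_ml`, `blq`.
#' @examples
#' d <- study_design(n_subjects = 4, seed = 1)
#' conc <- simulate_pk_profiles(d, pk_sim_config())
#' head(conc)
#' @export
simulate_pk_profiles <- function(design, config = pk_sim_config(),
                                 seed = child_seed(design$seed, "pk")) {
  stopifnot(inherits(design, "study_design"), inherits(config, "pk_sim_config"))
  missing_cond <- setdiff(design$conditions, names(config$params))
  if (length(missing_cond)) {
    stop("config lacks parameters for condition(s): ",
         paste(missing_cond, collapse = ", "), call. = FALSE)
  }
  times <- design$sampling_times_h
  with_seed(seed, {
    rows <- vector("list", design$n_subjects * length(design$conditions))
    k <- 0L
    for (subj in seq_len(design$n_subjects)) {
      for (cond in design$conditions) {
        p <- config$params[[cond]]
        mult <- if (config$bsv_cv > 0) {
          rlnorm_mean(stats::rnorm(1), mean = 1, sd = config$bsv_cv)
        } else 1
        conc <- bateman(times, ka = p$ka, ke = p$ke, scale = p$scale * mult)
        if (config$residual_cv > 0) {
          conc <- conc * (1 + config$residual_cv * stats::rnorm(length(conc)))
          conc <- pmax(conc, 0)
        }
        conc[times < 0] <- 0   # pre-dose sample, all conditions
        blq <- conc < config$loq
        k <- k + 1L
        rows[[k]] <- data.frame(
          subject = sprintf("S%02d", subj),
          condition = cond,
          time_h = times,
          conc_ng_ml = conc,
          blq = blq
        )
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "loq") <- config$loq
    attr(out, "seed") <- as.integer(seed)
    out
  })
}
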
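#' Physiology simulation configuration
#'
#' Calibration targets for the cardiovascular and endocrine simulator:
#' per-condition means and SDs of supine/upright heart rate and blood
#' pressure during the Schellong maneuver, nocturnal heart rate in NREM and
#' REM sleep, nocturnal cortisol and melatonin (five samples at 0, 90, 180,
#' 360, 480 min after lights-off), and the cortisol awakening response (six
#' samples at 0, 15, 30, 45, 60, 75 min after awakening). Defaults match a
#' placebo-controlled crossover cohort of poor sleepers with an unremarkable
#' orthostatic response.
#'
#' @param schellong per-condition list; each condition is a list of
#'   `c(mean, sd)` for `hr_supine`, `hr_upright`, `sbp_supine`,
#'   `sbp_upright`, `dbp_supine`, `dbp_upright`.
#' @param reading_sd within-assessment SD of repeated readings
#'   (`c(bp = ..., hr = ...)`).
#' @param orthostatic_drop `c(mean, sd)` extra systolic drop (mmHg) applied
#'   to the first upright reading; 0/0 yields no orthostatic events.
#' @param hr_sleep per-condition `c(mean, sd)` lists for `nrem` and `rem`;
#'   `wake_offset` bpm added during wake epochs; `epoch_sd` within-night
#'   epoch-to-epoch SD.
#' @param cortisol,melatonin,car per-condition `c(mean, sd)` of the series
#'   mean, plus `shape` (relative sample profile, mean 1), `times_min`, and
#'   `sample_cv` (within-series proportional noise; mean-preserving, so the
#'   configured series mean is recovered in expectation).
#' @return an object of class `physiology_config`.
#' @export
physiology_config <- function(
    schellong = list(
      placebo = list(hr_supine = c(58.8, 9.2), hr_upright = c(84.2, 12.7),
                     sbp_supine = c(107.7, 11.3), sbp_upright = c(110.1, 12.6),
                     dbp_supine = c(62.2, 7.6), dbp_upright = c(77.2, 7.9)),
      dex20 = list(hr_supine = c(60.0, 8.3), hr_upright = c(82.1, 11.2),
                   sbp_supine = c(107.7, 12.3), sbp_upright = c(105.6, 10.6),
                   dbp_supine = c(60.7, 8.6), dbp_upright = c(74.4, 10.1)),
      dex40 = list(hr_supine = c(59.4, 10.5), hr_upright = c(81.8, 12.0),
                   sbp_supine = c(105.2, 9.7), sbp_upright = c(105.8, 13.0),
                   dbp_supine = c(59.5, 7.4), dbp_upright = c(73.0, 9.5))),
    reading_sd = c(bp = 3, hr = 2),
    orthostatic_drop = c(0, 0),
    hr_sleep = list(
      placebo = list(nrem = c(56.5, 6.9), rem = c(58.4, 7.7)),
      dex20 = list(nrem = c(55.7, 5.6), rem = c(57.6, 5.7)),
      dex40 = list(nrem = c(55.1, 6.8), rem = c(57.9, 7.7)),
      wake_offset = 8, epoch_sd = 2),
    cortisol = list(placebo = c(121.5, 107.3), dex20 = c(114.8, 99.0),
                    dex40 = c(140.2, 125.0),
                    shape = c(1.1, 0.7, 0.6, 1.1, 1.5),
                    times_min = c(0, 90, 180, 360, 480), sample_cv = 0.2),
    melatonin = list(placebo = c(0.03, 0.01), dex20 = c(0.03, 0.01),
                     dex40 = c(0.03, 0.01),
                     shape = c(0.6, 1.2, 1.4, 1.1, 0.7),
                     times_min = c(0, 90, 180, 360, 480), sample_cv = 0.15),
    car = list(placebo = c(8.1, 4.6), dex20 = c(8.0, 4.1),
               dex40 = c(8.0, 5.1),
               shape = c(0.6, 1.0, 1.3, 1.2, 1.0, 0.9),
               times_min = c(0, 15, 30, 45, 60, 75), sample_cv = 0.2)) {
  for (h in list(cortisol, melatonin, car)) {
    if (length(h$shape) != length(h$times_min)) {
      stop("hormone shape and times_min lengths must match", call. = FALSE)
    }
  }
  structure(
    list(schellong = schellong, reading_sd = reading_sd,
         orthostatic_drop = orthostatic_drop, hr_sleep = hr_sleep,
         cortisol = cortisol, melatonin = melatonin, car = car),
    class = "physiology_config"
  )
}

# subject-level series draw: mean-preserving lognormal level times a
# mean-1 profile shape, with optional proportional sample noise
draw_hormone_series <- function(spec, cond) {
  tgt <- spec[[cond]]
  shape <- spec$shape / mean(spec$shape)
  level <- rlnorm_mean(stats::rnorm(1), tgt[1], tgt[2])
  v <- level * shape
  if (spec$sample_cv > 0) {
    v <- v * rlnorm_mean(stats::rnorm(length(v)), 1, spec$sample_cv)
  }
  data.frame(time_min = spec$times_min, value = v)
}

#' Simulate cardiovascular and endocrine tables for a crossover study
#'
#' Generates, per subject and condition: a Schellong table (3 supine + 5
#' upright readings of systolic/diastolic blood pressure and heart rate at
#' 1-min intervals), hormone sample tables at the protocol time points
#' (nocturnal cortisol and melatonin, awakening-response saliva cortisol),
#' and — when hypnograms are supplied — a per-epoch heart-rate series with
#' stage-dependent means. Deterministic for a fixed seed.
#'
#' @param design a [study_design()].
#' @param targets a [physiology_config()]; must cover every condition.
#' @param hypnograms optional named list from [simulate_hypnograms()]; when
#'   present, the per-epoch heart-rate table is generated stage-aligned.
#' @param seed integer seed; defaults to a child of `design$seed`.
#' @return list of data.frames: `schellong`, `hormones`, and (optionally)
#'   `heart_rate`.
#' @export
simulate_physiology <- function(design, targets = physiology_config(),
                                hypnograms = NULL,
                                seed = child_seed(design$seed, "physio")) {
  stopifnot(inherits(design, "study_design"),
            inherits(targets, "physiology_config"))
  conds <- design$conditions
  missing_cond <- setdiff(conds, names(targets$schellong))
  if (length(missing_cond)) {
    stop("physiology targets missing condition(s): ",
         paste(missing_cond, collapse = ", "), call. = FALSE)
  }
  with_seed(seed, {
    sch_rows <- list(); horm_rows <- list(); hr_rows <- list()
    for (subj in seq_len(design$n_subjects)) {
      id <- sprintf("S%02d", subj)
      for (cond in conds) {
        sc <- targets$schellong[[cond]]
        lvl <- lapply(sc, function(ms) stats::rnorm(1, ms[1], ms[2]))
        mk <- function(pos, n, extra_drop = 0) {
          key <- function(v) lvl[[paste0(v, "_", pos)]]
          data.frame(
            subject = id, condition = cond, position = pos,
            reading = seq_len(n),
            sbp_mmHg = key("sbp") + stats::rnorm(n, 0, targets$reading_sd["bp"]) -
              c(extra_drop, rep(0, n - 1)),
            dbp_mmHg = key("dbp") + stats::rnorm(n, 0, targets$reading_sd["bp"]) -
              c(extra_drop / 2, rep(0, n - 1)),
            hr_bpm = key("hr") + stats::rnorm(n, 0, targets$reading_sd["hr"])
          )
        }
        drop <- if (targets$orthostatic_drop[2] > 0) {
          stats::rnorm(1, targets$orthostatic_drop[1],
                       targets$orthostatic_drop[2])
        } else targets$orthostatic_drop[1]
        sch_rows[[length(sch_rows) + 1L]] <- rbind(mk("supine", 3),
                                                   mk("upright", 5, drop))
        for (analyte in c("cortisol", "melatonin", "car")) {
          ser <- draw_hormone_series(targets[[analyte]], cond)
          horm_rows[[length(horm_rows) + 1L]] <- data.frame(
            subject = id, condition = cond, analyte = analyte, ser)
        }
        if (!is.null(hypnograms)) {
          hyp <- hypnograms[[paste(id, cond, sep = ".")]]
          if (!is.null(hyp)) {
            hs <- targets$hr_sleep
            base <- ifelse(hyp$stages == "R",
                           stats::rnorm(1, hs[[cond]]$rem[1], hs[[cond]]$rem[2]),
                           stats::rnorm(1, hs[[cond]]$nrem[1], hs[[cond]]$nrem[2]))
            base[hyp$stages == "W"] <- base[hyp$stages == "W"] + hs$wake_offset
            hr_rows[[length(hr_rows) + 1L]] <- data.frame(
              subject = id, condition = cond,
              epoch_index = seq_along(hyp$stages) - 1L,
              hr_bpm = base + stats::rnorm(length(base), 0, hs$epoch_sd)
            )
          }
        }
      }
    }
    out <- list(schellong = do.call(rbind, sch_rows),
                hormones = do.call(rbind, horm_rows))
    if (length(hr_rows)) out$heart_rate <- do.call(rbind, hr_rows)
    out <- lapply(out, function(d) { rownames(d) <- NULL; d })
    attr(out, "seed") <- as.integer(seed)
    out
  })
}
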
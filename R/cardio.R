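#' Orthostatic (Schellong) assessment of one record
#'
#' The Schellong maneuver measures blood pressure and heart rate at 1-min
#' intervals, three times supine and then five times standing. The
#' orthostatic-hypotension rule compares the **last** supine blood pressure
#' with each of the **first three** upright readings: an event is flagged
#' when any systolic drop is >= 20 mmHg and/or any diastolic drop is
#' >= 10 mmHg (inclusive thresholds). Means across all readings per
#' position are also returned.
#'
#' @param rec data.frame with columns `position` (`"supine"`/`"upright"`),
#'   `sbp_mmHg`, `dbp_mmHg`, `hr_bpm`, ordered in measurement sequence
#'   within position. Missing readings are allowed and propagate as `NA`
#'   (never treated as zeros).
#' @param sbp_drop_mmHg,dbp_drop_mmHg event thresholds.
#' @param scan_all scan all upright readings for the drop instead of only
#'   the first three.
#' @return list with `event` (logical, `NA` when not evaluable), `drops`
#'   (data.frame of systolic/diastolic drops per compared upright reading),
#'   `supine_means`, `upright_means`, and `complete` (both positions fully
#'   observed).
#' @examples
#' rec <- data.frame(
#'   position = c(rep("supine", 3), rep("upright", 5)),
#'   sbp_mmHg = c(112, 111, 110, 88, 95, 99, 101, 102),
#'   dbp_mmHg = c(71, 70, 70, 62, 64, 66, 68, 68),
#'   hr_bpm = c(60, 59, 58, 82, 80, 79, 78, 77))
#' schellong_assess(rec)$event  # TRUE: systolic drop 22 mmHg
#' @export
schellong_assess <- function(rec, sbp_drop_mmHg = 20, dbp_drop_mmHg = 10,
                             scan_all = FALSE) {
  need <- c("position", "sbp_mmHg", "dbp_mmHg", "hr_bpm")
  if (!all(need %in% names(rec))) {
    stop("record needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  sup <- rec[rec$position == "supine", , drop = FALSE]
  upr <- rec[rec$position == "upright", , drop = FALSE]
  if (nrow(sup) < 1 || nrow(upr) < 3) {
    stop("need at least one supine and three upright readings",
         call. = FALSE)
  }
  pos_means <- function(d) c(sbp_mmHg = mean(d$sbp_mmHg),
                             dbp_mmHg = mean(d$dbp_mmHg),
                             hr_bpm = mean(d$hr_bpm))
  last_sup <- sup[nrow(sup), ]
  cmp <- if (scan_all) upr else utils::head(upr, 3)
  drops <- data.frame(
    upright_reading = seq_len(nrow(cmp)),
    sbp_drop = last_sup$sbp_mmHg - cmp$sbp_mmHg,
    dbp_drop = last_sup$dbp_mmHg - cmp$dbp_mmHg
  )
  event <- any(drops$sbp_drop >= sbp_drop_mmHg, na.rm = FALSE) |
    any(drops$dbp_drop >= dbp_drop_mmHg, na.rm = FALSE)
  list(event = event,
       drops = drops,
       supine_means = pos_means(sup),
       upright_means = pos_means(upr),
       complete = !anyNA(rec[, c("sbp_mmHg", "dbp_mmHg", "hr_bpm")]))
}

#' Mean nocturnal heart rate by sleep-stage class
#'
#' Means of a per-epoch heart-rate series over epochs scored NREM (N1, N2,
#' N3) and over epochs scored REM, lights-off to lights-on.
#'
#' @param hr numeric heart-rate series, one value per epoch, aligned to the
#'   hypnogram.
#' @param hyp a [hypnogram()].
#' @return named numeric `c(nrem_bpm, rem_bpm)`; a class with no epochs
#'   reports `NA`.
#' @export
hr_by_stage <- function(hr, hyp) {
  stopifnot(inherits(hyp, "hypnogram"))
  if (length(hr) != length(hyp$stages)) {
    stop("heart-rate series must be aligned to the hypnogram epochs",
         call. = FALSE)
  }
  nrem <- hyp$stages %in% c("N1", "N2", "N3")
  rem <- hyp$stages == "R"
  c(nrem_bpm = if (any(nrem)) mean(hr[nrem]) else NA_real_,
    rem_bpm = if (any(rem)) mean(hr[rem]) else NA_real_)
}

#' Mean hormone concentration across protocol samples
#'
#' Arithmetic mean across the samples of one hormone series (nocturnal
#' cortisol/melatonin at 0, 90, 180, 360, 480 min after lights-off, or the
#' cortisol awakening response at 0, 15, 30, 45, 60, 75 min after
#' awakening).
#'
#' @param values numeric sample concentrations (at least one).
#' @param na.rm drop missing samples before averaging.
#' @return the mean concentration.
#' @export
endocrine_means <- function(values, na.rm = FALSE) {
  if (length(values) < 1L) stop("need at least one sample", call. = FALSE)
  mean(values, na.rm = na.rm)
}
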
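#' Crossover study design
#'
#' Describes the fixed frame of a randomized crossover night: subjects,
#' conditions, the overnight blood-sampling grid, epoch length and time in
#' bed. The default sampling grid is one pre-dose sample 30 min before drug
#' intake followed by 0.25--9 h post-dose draws; drug intake coincides with
#' lights-off and time in bed is 8 h scored in 30-s epochs.
#'
#' @param n_subjects number of subjects completing all conditions.
#' @param conditions character vector of condition labels, placebo first.
#' @param sampling_times_h strictly increasing sampling times in hours
#'   relative to drug intake; exactly one pre-dose time (< 0) is required.
#' @param epoch_s scoring epoch length in seconds.
#' @param time_in_bed_h time in bed in hours; `time_in_bed_h * 3600` must be
#'   divisible by `epoch_s`.
#' @param seed integer seed governing every simulator driven by this design.
#'
#' @return an object of class `study_design`.
#' @examples
#' d <- study_design(n_subjects = 17)
#' d$n_epochs  # 960 thirty-second epochs in 8 h
#' @export
study_design <- function(n_subjects = 17L,
                         conditions = c("placebo", "dex20", "dex40"),
                         sampling_times_h = c(-0.5, 0.25, 0.5, 0.75, 1, 1.25,
                                              1.5, 1.75, 2, 2.5, 3, 3.5, 4,
                                              5, 6, 7, 8, 9),
                         epoch_s = 30,
                         time_in_bed_h = 8,
                         seed = 1L) {
  stopifnot_scalar_number(n_subjects, "n_subjects", positive = TRUE)
  if (n_subjects != round(n_subjects)) stop("`n_subjects` must be an integer")
  if (!is.character(conditions) || length(conditions) < 1L ||
      anyDuplicated(conditions)) {
    stop("`conditions` must be distinct condition labels", call. = FALSE)
  }
  if (any(diff(sampling_times_h) <= 0)) {
    stop("`sampling_times_h` must be strictly increasing", call. = FALSE)
  }
  if (sum(sampling_times_h < 0) != 1L) {
    stop("exactly one pre-dose sampling time (< 0) is required", call. = FALSE)
  }
  stopifnot_scalar_number(epoch_s, "epoch_s", positive = TRUE)
  stopifnot_scalar_number(time_in_bed_h, "time_in_bed_h", positive = TRUE)
  if ((time_in_bed_h * 3600) %% epoch_s != 0) {
    stop("time in bed must be a whole number of epochs", call. = FALSE)
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      conditions = conditions,
      sampling_times_h = as.numeric(sampling_times_h),
      epoch_s = as.numeric(epoch_s),
      time_in_bed_h = as.numeric(time_in_bed_h),
      n_epochs = as.integer(time_in_bed_h * 3600 / epoch_s),
      seed = as.integer(seed)
    ),
    class = "study_design"
  )
}

#' @export
print.study_design <- function(x, ...) {
  cat("Crossover study design\n")
  cat(sprintf("  subjects:    %d\n", x$n_subjects))
  cat(sprintf("  conditions:  %s\n", paste(x$conditions, collapse = ", ")))
  cat(sprintf("  sampling:    %d times, %.2g to %.3g h\n",
              length(x$sampling_times_h), min(x$sampling_times_h),
              max(x$sampling_times_h)))
  cat(sprintf("  time in bed: %g h (%d x %g-s epochs)\n",
              x$time_in_bed_h, x$n_epochs, x$epoch_s))
  cat(sprintf("  seed:        %d\n", x$seed))
  invisible(x)
}
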
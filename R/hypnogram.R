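#' Hypnogram: 30-s epoch sleep-stage sequence
#'
#' A scored night as an ordered sequence of AASM stages over
#' `{W, N1, N2, N3, R}`, anchored at lights-off (epoch index 0) and ending
#' at lights-on.
#'
#' @param stages character vector of stage codes.
#' @param epoch_s epoch length in seconds (30 by convention).
#' @param subject,condition identifying labels.
#' @return an object of class `hypnogram`.
#' @export
hypnogram <- function(stages, epoch_s = 30, subject = NA_character_,
                      condition = NA_character_) {
  stages <- as.character(stages)
  if (length(stages) == 0L) stop("hypnogram must be nonempty", call. = FALSE)
  bad <- setdiff(unique(stages), c("W", "N1", "N2", "N3", "R"))
  if (length(bad)) {
    stop("invalid stage code(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(
    list(stages = stages, epoch_s = epoch_s,
         subject = subject, condition = condition),
    class = "hypnogram"
  )
}

#' @export
print.hypnogram <- function(x, ...) {
  n <- length(x$stages)
  cat(sprintf("Hypnogram %s/%s: %d epochs (%.2f h), stages: %s\n",
              x$subject, x$condition, n, n * x$epoch_s / 3600,
              paste(sprintf("%s=%d", names(table(x$stages)),
                            as.integer(table(x$stages))), collapse = " ")))
  invisible(x)
}

sleep_codes <- c("N1", "N2", "N3", "R")

#' Sleep-onset epoch index
#'
#' Sleep onset is the first occurrence of three consecutive epochs each
#' scored as any sleep stage (N1, N2, N3 or R); the onset index is the
#' first of those three epochs (0-based, so sleep latency in minutes is
#' `index * epoch_s / 60`).
#'
#' @param hyp a [hypnogram()].
#' @return 0-based epoch index of sleep onset, or `NA_integer_` when no
#'   three consecutive sleep epochs occur (never coerced to 0).
#' @examples
#' sleep_onset_index(hypnogram(c("W", "W", "N1", "W", "N1", "N1", "N1")))  # 4
#' @export
sleep_onset_index <- function(hyp) {
  stopifnot(inherits(hyp, "hypnogram"))
  s <- hyp$stages %in% sleep_codes
  n <- length(s)
  if (n < 3L) return(NA_integer_)
  run3 <- s[1:(n - 2)] & s[2:(n - 1)] & s[3:n]
  i <- which(run3)
  if (length(i) == 0L) return(NA_integer_)
  as.integer(i[1] - 1L)
}

#' Visually-scored sleep variables from a hypnogram
#'
#' Computes the standard polysomnographic sleep variables: time in bed,
#' stage minutes (0.5 min per 30-s epoch), total sleep time
#' (N1 + N2 + N3 + R), sleep efficiency (100 * TST / TIB), sleep latency
#' (lights-off to sleep onset by the three-consecutive-epoch rule), REM
#' latency (sleep onset to the first R epoch), wake after sleep onset, and
#' combined N2 + N3 NREM minutes.
#'
#' If sleep onset is undefined, latency-dependent fields are `NA`; if no R
#' epoch occurs, `rem_latency_min` is `NA`.
#'
#' @param hyp a [hypnogram()].
#' @return one-row data.frame of sleep variables (minutes unless noted).
#' @export
compute_sleep_variables <- function(hyp) {
  stopifnot(inherits(hyp, "hypnogram"))
  epm <- hyp$epoch_s / 60  # minutes per epoch
  stages <- hyp$stages
  n <- length(stages)
  tib <- n * epm
  mins <- function(code) sum(stages == code) * epm
  tst <- mins("N1") + mins("N2") + mins("N3") + mins("R")
  onset <- sleep_onset_index(hyp)
  if (is.na(onset)) {
    sl <- NA_real_; waso <- NA_real_; rl <- NA_real_
  } else {
    sl <- onset * epm
    after <- stages[(onset + 1L):n]  # onset epoch onwards (1-based slice)
    waso <- sum(after == "W") * epm
    first_r <- which(stages == "R")[1]
    rl <- if (is.na(first_r)) NA_real_ else (first_r - 1L - onset) * epm
  }
  data.frame(
    subject = hyp$subject, condition = hyp$condition,
    time_in_bed_min = tib,
    total_sleep_time_min = tst,
    sleep_efficiency_pct = 100 * tst / tib,
    sleep_latency_min = sl,
    rem_latency_min = rl,
    waso_min = waso,
    n1_min = mins("N1"), n2_min = mins("N2"), n3_min = mins("N3"),
    rem_min = mins("R"),
    nrem_n2n3_min = mins("N2") + mins("N3")
  )
}

#' First/second half-of-night epoch masks
#'
#' Splits the night on time since lights-off into a first half (0 to 4 h
#' after intake for an 8-h night) and a second half. For an odd epoch count
#' the middle epoch is assigned to the first half.
#'
#' @param hyp a [hypnogram()].
#' @return list of two logical masks, `first` and `second`, covering all
#'   epochs disjointly.
#' @export
split_half_masks <- function(hyp) {
  stopifnot(inherits(hyp, "hypnogram"))
  n <- length(hyp$stages)
  n_first <- ceiling(n / 2)
  first <- seq_len(n) <= n_first
  list(first = first, second = !first)
}

#' Read a hypnogram from two-column text
#'
#' Expects whitespace- or tab-delimited text with columns `epoch_index`
#' (0-based, consecutive) and `stage`.
#'
#' @param path file path.
#' @param epoch_s epoch length in seconds.
#' @inheritParams hypnogram
#' @return a [hypnogram()].
#' @export
read_hypnogram <- function(path, epoch_s = 30, subject = NA_character_,
                           condition = NA_character_) {
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("epoch_index", "stage") %in% names(tab))) {
    stop("hypnogram file needs columns epoch_index, stage", call. = FALSE)
  }
  tab <- tab[order(tab$epoch_index), ]
  if (!identical(as.integer(tab$epoch_index),
                 seq_len(nrow(tab)) - 1L)) {
    stop("epoch_index must be consecutive from 0", call. = FALSE)
  }
  hypnogram(tab$stage, epoch_s = epoch_s, subject = subject,
            condition = condition)
}

#' Write a hypnogram as two-column text
#'
#' @param hyp a [hypnogram()].
#' @param path destination file.
#' @export
write_hypnogram <- function(hyp, path) {
  stopifnot(inherits(hyp, "hypnogram"))
  utils::write.table(
    data.frame(epoch_index = seq_along(hyp$stages) - 1L, stage = hyp$stages),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
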
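#' Sleep architecture simulation configuration
#'
#' Latent-variable model for synthetic crossover hypnograms. Each subject x
#' condition night is summarized by latent sleep latency, REM latency and
#' stage totals; [simulate_hypnograms()] then lays out a stage sequence that
#' realizes those latents exactly, so hypnogram metrics recover them without
#' bias.
#'
#' Placebo baselines default to a poor-sleeper-plausible night scaled to fit
#' 8 h time in bed exactly (latency 25 min, REM latency 70 min, N1 41,
#' N2 219, N3 68, R 82, WASO 45 min). Condition effects default to the
#' buccal-formulation contrasts: 20 ug shortens latency by 9.5 min, adds
#' 26.2 min N2 and 3.8 min N3 (30.0 min N2+N3) and delays REM by 55.0 min;
#' 40 ug shortens latency by 11.5 min, adds 27.4 min N2 and 9.8 min N3
#' (37.2 min N2+N3), delays REM by 115.3 min and trims REM duration by
#' 18.6 min.
#'
#' Latencies are drawn mean-preserving lognormal (they cannot go negative);
#' stage totals are drawn normal. N1 and WASO jointly absorb the time-in-bed
#' closure constraint (split proportionally to their configured means), so
#' their configured SDs are realized only indirectly.
#'
#' @param baseline named numeric: placebo means in minutes for
#'   `sleep_latency`, `rem_latency`, `n1`, `n2`, `n3`, `rem`, `waso`.
#' @param sds named numeric: between-subject SDs in minutes (same names).
#' @param effects named list per non-placebo condition of additive deltas
#'   (same names; omitted entries are 0).
#' @param rho within-subject correlation of latents across conditions,
#'   in \[0, 1\].
#' @param max_retries redraw attempts when drawn latents cannot be laid out
#'   within time in bed.
#' @return an object of class `sleep_sim_config`.
#' @export
sleep_sim_config <- function(
    baseline = c(sleep_latency = 25, rem_latency = 70, n1 = 41, n2 = 219,
                 n3 = 68, rem = 82, waso = 45),
    sds = c(sleep_latency = 10, rem_latency = 25, n1 = 10, n2 = 20,
            n3 = 15, rem = 12, waso = 12),
    effects = list(
      dex20 = c(sleep_latency = -9.5, rem_latency = 55.0,
                n2 = 26.2, n3 = 3.8),
      dex40 = c(sleep_latency = -11.5, rem_latency = 115.3,
                n2 = 27.4, n3 = 9.8, rem = -18.6)
    ),
    rho = 0.7,
    max_retries = 50L) {
  vars <- c("sleep_latency", "rem_latency", "n1", "n2", "n3", "rem", "waso")
  if (!all(vars %in% names(baseline))) {
    stop("baseline must name: ", paste(vars, collapse = ", "), call. = FALSE)
  }
  if (!all(vars %in% names(sds))) {
    stop("sds must name: ", paste(vars, collapse = ", "), call. = FALSE)
  }
  if (rho < 0 || rho > 1) stop("rho must be in [0, 1]", call. = FALSE)
  structure(
    list(baseline = baseline[vars], sds = sds[vars], effects = effects,
         rho = rho, max_retries = as.integer(max_retries)),
    class = "sleep_sim_config"
  )
}

# Condition-specific latent means: baseline plus the condition's deltas.
condition_means <- function(config, cond) {
  m <- config$baseline
  if (!is.null(config$effects[[cond]])) {
    d <- config$effects[[cond]]
    m[names(d)] <- m[names(d)] + d
  }
  m
}

# Lay out one night from integer epoch quantities. Returns the stage vector
# or NULL when the combination is infeasible. o = onset epoch, m = REM
# latency in epochs (NA when no REM), pools in epochs.
layout_night <- function(n_ep, o, m, a1, a2, a3, r, w) {
  if (o + 3L > n_ep) return(NULL)
  stopifnot(o + a1 + a2 + a3 + r + w == n_ep)
  take <- function(pool, k) {
    used <- pmin(pool, c(k, max(0L, k - pool[1]),
                         max(0L, k - pool[1] - pool[2])))
    used
  }
  out <- rep("W", o)
  if (r > 0L) {
    if (is.na(m)) return(NULL)
    b <- m
    nrem <- a1 + a2 + a3
    nb <- min(b, nrem)
    wb <- b - nb
    if (wb > w) return(NULL)
    if (nb < min(3L, b)) return(NULL)  # onset needs sleep right away
    u <- take(c(a1, a2, a3), nb)
    segB <- c(rep("N1", u[1]), rep("N2", u[2]), rep("N3", u[3]),
              rep("W", wb))
    a1 <- a1 - u[1]; a2 <- a2 - u[2]; a3 <- a3 - u[3]; w <- w - wb
    # remaining epochs as NREM/REM cycles, each opening with REM so the
    # first post-B epoch is the first R of the night; slow-wave sleep is
    # weighted toward early cycles, REM and wake toward late ones
    k <- min(3L, r)
    rr <- apportion(r, seq_len(k))
    if (rr[1] == 0L) {            # first cycle must start with REM
      j <- which.max(rr)
      rr[j] <- rr[j] - 1L; rr[1] <- 1L
    }
    c1 <- apportion(a2, rep(1, k))
    c2 <- apportion(a3, rev(seq_len(k))^2)
    c3 <- apportion(a1, rep(1, k))
    cw <- apportion(w, seq_len(k))
    segC <- unlist(lapply(seq_len(k), function(j) {
      c(rep("R", rr[j]), rep("N2", c1[j]), rep("N3", c2[j]),
        rep("N1", c3[j]), rep("W", cw[j]))
    }))
    out <- c(out, segB, segC)
  } else {
    if (a1 + a2 + a3 < 3L) return(NULL)
    k <- 3L
    c1 <- apportion(a2, rep(1, k)); c2 <- apportion(a3, rev(seq_len(k))^2)
    c3 <- apportion(a1, rep(1, k)); cw <- apportion(w, seq_len(k))
    # N2 first so onset opens with sleep even when N1 is exhausted
    segC <- unlist(lapply(seq_len(k), function(j) {
      c(rep("N2", c1[j]), rep("N3", c2[j]), rep("N1", c3[j]),
        rep("W", cw[j]))
    }))
    out <- c(out, segC)
  }
  if (length(out) != n_ep) return(NULL)
  out
}

#' Simulate crossover hypnograms with configurable condition effects
#'
#' For every subject x condition, draws correlated latent sleep variables
#' (shared subject effect with correlation `rho` across conditions), rounds
#' them to the 30-s epoch grid, and lays out a stage sequence of exactly
#' `time_in_bed / epoch_s` epochs that realizes the drawn sleep latency
#' (three-consecutive-epoch onset rule) and REM latency exactly, with the
#' remaining epochs filled as NREM/REM cycles honouring the drawn stage
#' totals. N1 and WASO absorb the time-in-bed closure. Latent draws that
#' cannot be laid out are redrawn up to `config$max_retries` times.
#'
#' @param design a [study_design()].
#' @param config a [sleep_sim_config()]; effects must be defined (possibly
#'   zero) for every non-placebo condition.
#' @param seed integer seed; defaults to a child of `design$seed`.
#' @return named list of [hypnogram()] objects (`subject.condition`), with
#'   attribute `"latents"`: a data.frame of the realized latent variables
#'   per night (what the metrics layer recovers exactly).
#' @examples
#' d <- study_design(n_subjects = 3, seed = 1)
#' hyps <- simulate_hypnograms(d, sleep_sim_config())
#' attr(hyps, "latents")
#' @export
simulate_hypnograms <- function(design, config = sleep_sim_config(),
                                seed = child_seed(design$seed, "sleep")) {
  stopifnot(inherits(design, "study_design"),
            inherits(config, "sleep_sim_config"))
  non_placebo <- setdiff(design$conditions, "placebo")
  missing_eff <- setdiff(non_placebo, names(config$effects))
  if (length(missing_eff)) {
    stop("effects missing for condition(s): ",
         paste(missing_eff, collapse = ", "), call. = FALSE)
  }
  n_ep <- design$n_epochs
  epm <- design$epoch_s / 60
  tib <- n_ep * epm
  vars <- names(config$baseline)
  rho <- config$rho
  with_seed(seed, {
    hyps <- list()
    lat_rows <- list()
    for (subj in seq_len(design$n_subjects)) {
      u <- stats::rnorm(length(vars))  # shared subject effect per variable
      names(u) <- vars
      for (cond in design$conditions) {
        m <- condition_means(config, cond)
        s <- config$sds
        ok <- FALSE
        for (try in seq_len(config$max_retries)) {
          e <- stats::rnorm(length(vars))
          names(e) <- vars
          z <- sqrt(rho) * u + sqrt(1 - rho) * e
          sl <- rlnorm_mean(z[["sleep_latency"]], m[["sleep_latency"]],
                            s[["sleep_latency"]])
          rl <- rlnorm_mean(z[["rem_latency"]], m[["rem_latency"]],
                            s[["rem_latency"]])
          n2 <- max(0, m[["n2"]] + s[["n2"]] * z[["n2"]])
          n3 <- max(0, m[["n3"]] + s[["n3"]] * z[["n3"]])
          re <- max(0, m[["rem"]] + s[["rem"]] * z[["rem"]])
          # quantize to the epoch grid
          o  <- as.integer(round(sl / epm))
          a2 <- as.integer(round(n2 / epm))
          a3 <- as.integer(round(n3 / epm))
          r  <- as.integer(round(re / epm))
          mm <- if (r > 0L) as.integer(round(rl / epm)) else NA_integer_
          slack <- n_ep - o - a2 - a3 - r
          if (slack < 0L) next
          pools <- apportion(slack, c(m[["n1"]], m[["waso"]]))
          a1 <- pools[1]; w <- pools[2]
          if (r > 0L && (is.na(mm) || o + mm + r > n_ep)) next
          stages <- layout_night(n_ep, o, mm, a1, a2, a3, r, w)
          if (is.null(stages)) next
          # accept only layouts whose scored metrics reproduce the latents
          chk <- hypnogram(stages, epoch_s = design$epoch_s)
          onset_ok <- identical(sleep_onset_index(chk), o)
          rem_ok <- if (r > 0L) {
            which(stages == "R")[1] - 1L == o + mm
          } else !any(stages == "R")
          if (!onset_ok || !rem_ok) next
          ok <- TRUE
          break
        }
        if (!ok) {
          stop(sprintf(
            "could not lay out a night for subject %d, condition %s after %d tries",
            subj, cond, config$max_retries), call. = FALSE)
        }
        id <- sprintf("S%02d", subj)
        hyp <- hypnogram(stages, epoch_s = design$epoch_s, subject = id,
                         condition = cond)
        hyps[[paste(id, cond, sep = ".")]] <- hyp
        lat_rows[[length(lat_rows) + 1L]] <- data.frame(
          subject = id, condition = cond,
          sleep_latency_min = o * epm,
          rem_latency_min = if (r > 0L) mm * epm else NA_real_,
          n1_min = a1 * epm, n2_min = a2 * epm, n3_min = a3 * epm,
          rem_min = r * epm, waso_min = w * epm
        )
      }
    }
    latents <- do.call(rbind, lat_rows)
    rownames(latents) <- NULL
    attr(hyps, "latents") <- latents
    attr(hyps, "seed") <- as.integer(seed)
    hyps
  })
}

#' Sleep-variable table for a set of hypnograms
#'
#' Applies [compute_sleep_variables()] to each hypnogram and binds the
#' results into one row per night.
#'
#' @param hyps list of [hypnogram()] objects.
#' @return data.frame of sleep variables.
#' @export
sleep_variable_table <- function(hyps) {
  out <- do.call(rbind, lapply(hyps, compute_sleep_variables))
  rownames(out) <- NULL
  out
}
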
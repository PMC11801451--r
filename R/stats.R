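#' Within-subject paired contrast with permutation inference
#'
#' Estimates a crossover condition contrast as the mean within-subject
#' difference `mean(y - x)`. For a complete crossover with one observation
#' per subject and condition, this equals the condition contrast from a
#' linear mixed model with a participant random intercept, so no model
#' fitting is needed. Inference is distribution-free:
#'
#' * 95% CI by percentile bootstrap over subjects (`n_boot` resamples);
#' * p-value by sign-flip permutation of the paired differences — exact
#'   enumeration of all `2^n` sign patterns when `2^n <= 32768`, otherwise
#'   `n_perm` Monte-Carlo flips (identity included, so p > 0);
#' * standardized effect size `d_z` = mean difference / SD of differences.
#'
#' Subjects with a missing value in either condition are dropped listwise.
#' Zero-variance differences report `p = 1` with `degenerate = TRUE`.
#'
#' @param x,y paired per-subject values (same subjects, same order).
#' @param n_boot bootstrap resamples for the CI.
#' @param n_perm Monte-Carlo sign flips when exact enumeration is too large.
#' @param seed integer seed (results are deterministic given the seed).
#' @param variable,pair optional labels carried into the result.
#' @return one-row data.frame of class `paired_comparison`: `variable`,
#'   `pair`, `n`, `estimate`, `ci_lower`, `ci_upper`, `p`, `d_z`,
#'   `p_method`, `degenerate`.
#' @examples
#' paired_estimate(c(10, 12, 14, 11), c(13, 15, 18, 12), seed = 1)
#' @export
paired_estimate <- function(x, y, n_boot = 10000L, n_perm = 10000L,
                            seed = 1L, variable = NA_character_,
                            pair = NA_character_) {
  if (length(x) != length(y)) stop("x and y must be paired", call. = FALSE)
  keep <- !(is.na(x) | is.na(y))
  d <- (y - x)[keep]
  n <- length(d)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  est <- mean(d)
  sd_d <- stats::sd(d)
  degenerate <- sd_d == 0
  with_seed(seed, {
    boots <- vapply(seq_len(n_boot), function(i) {
      mean(d[sample.int(n, n, replace = TRUE)])
    }, numeric(1))
    ci <- unname(stats::quantile(boots, c(0.025, 0.975), type = 7))
    if (degenerate) {
      p <- 1
    } else if (2^n <= 2^15) {
      signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
      t_perm <- abs(as.numeric(signs %*% d) / n)
      p <- mean(t_perm >= abs(est) - 1e-12)
    } else {
      flips <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), n_perm, n)
      t_perm <- abs(as.numeric(flips %*% d) / n)
      # identity permutation included so p is never 0
      p <- (sum(t_perm >= abs(est) - 1e-12) + 1) / (n_perm + 1)
    }
    structure(
      data.frame(
        variable = variable, pair = pair, n = n, estimate = est,
        ci_lower = min(ci[1], est), ci_upper = max(ci[2], est),
        p = p,
        d_z = if (degenerate) NA_real_ else est / sd_d,
        p_method = if (degenerate) "degenerate"
                   else if (2^n <= 2^15) "exact" else "monte-carlo",
        degenerate = degenerate
      ),
      class = c("paired_comparison", "data.frame")
    )
  })
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up FDR adjustment: sort p ascending, set `q_(i) = p_(i) * m / i`,
#' enforce monotonicity from the largest rank down, cap at 1 and restore
#' the input order. Delegates to [stats::p.adjust()] after validating the
#' input range.
#'
#' @param p numeric p-values, all in (0, 1].
#' @return adjusted p-values in input order, never smaller than the input.
#' @examples
#' bh_adjust(c(0.01, 0.04, 0.03))  # 0.03 0.04 0.04
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    stop("all p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Percent change from a log10-scale difference
#'
#' Converts a contrast estimated on the log10 scale (e.g. a slow-wave
#' energy contrast) to a percent change on the natural scale:
#' `(10^diff - 1) * 100`.
#'
#' @param diff finite difference in log10 units.
#' @return percent change.
#' @examples
#' percent_from_log10(0.09)  # ~23%
#' @export
percent_from_log10 <- function(diff) {
  if (any(!is.finite(diff))) stop("diff must be finite", call. = FALSE)
  (10^diff - 1) * 100
}

#' All pairwise crossover contrasts for a tidy variable table
#'
#' For every variable, computes [paired_estimate()] for each condition pair
#' (later condition minus earlier, in the order given) and applies
#' Benjamini-Hochberg correction within the variable's family of pairwise
#' contrasts (the per-variable family convention).
#'
#' @param data tidy data.frame with columns `subject`, `condition`,
#'   `variable`, `value`.
#' @param conditions condition order; defaults to the order of appearance.
#' @param n_boot,n_perm,seed passed to [paired_estimate()].
#' @return data.frame with one row per variable x pair, including
#'   `p_adjusted`.
#' @export
compare_conditions <- function(data, conditions = unique(data$condition),
                               n_boot = 10000L, n_perm = 10000L, seed = 1L) {
  need <- c("subject", "condition", "variable", "value")
  if (!all(need %in% names(data))) {
    stop("data needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  pairs <- utils::combn(conditions, 2, simplify = FALSE)
  out <- list()
  for (v in unique(data$variable)) {
    dv <- data[data$variable == v, ]
    rows <- list()
    for (pr in pairs) {
      a <- dv[dv$condition == pr[1], c("subject", "value")]
      b <- dv[dv$condition == pr[2], c("subject", "value")]
      subj <- intersect(a$subject, b$subject)
      if (length(subj) < 3) next
      res <- paired_estimate(
        a$value[match(subj, a$subject)], b$value[match(subj, b$subject)],
        n_boot = n_boot, n_perm = n_perm,
        seed = child_seed(seed, paste(v, pr[1], pr[2])),
        variable = v, pair = paste(pr[2], "-", pr[1])
      )
      rows[[length(rows) + 1L]] <- as.data.frame(res)
    }
    if (length(rows)) {
      fam <- do.call(rbind, rows)
      fam$p_adjusted <- bh_adjust(fam$p)
      out[[length(out) + 1L]] <- fam
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
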
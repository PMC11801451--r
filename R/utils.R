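# Internal helpers shared across modules.

#' Evaluate an expression under a fixed RNG seed, restoring caller state
#'
#' All simulators route their randomness through this helper so a fixed seed
#' yields bit-identical output without disturbing the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing integer", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible child seed from a parent seed and a stream label,
# keeping the result within 32-bit integer range.
child_seed <- function(seed, stream) {
  offsets <- c(pk = 11L, sleep = 23L, eeg = 37L, physio = 53L, stats = 71L)
  off <- if (stream %in% names(offsets)) offsets[[stream]] else
    sum(utf8ToInt(as.character(stream)))
  as.integer((as.numeric(seed) * 7919 + off) %% 2147483647)
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be a single number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  }
  invisible(x)
}

# Mean-preserving lognormal draw: E[result] = mean, SD on the natural scale
# approximately `sd`, driven by pre-drawn standard-normal deviates `z`.
rlnorm_mean <- function(z, mean, sd) {
  if (any(mean <= 0)) stop("lognormal mean must be > 0", call. = FALSE)
  sdlog <- sqrt(log(1 + (sd / mean)^2))
  meanlog <- log(mean) - sdlog^2 / 2
  exp(meanlog + sdlog * z)
}

# Largest-remainder apportionment of `total` integer units proportional to
# `weights` (used to split epoch pools across cycles/slack variables).
# Ensures the result sums exactly to `total`.
apportion <- function(total, weights) {
  if (total == 0L) return(rep(0L, length(weights)))
  if (all(weights <= 0)) weights <- rep(1, length(weights))
  raw <- total * weights / sum(weights)
  base <- floor(raw)
  rem <- total - sum(base)
  if (rem > 0) {
    idx <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[idx] <- base[idx] + 1
  }
  as.integer(base)
}
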
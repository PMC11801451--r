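# Shared fixture builders: everything is generated in code at test time.

# profile sampled from a function on the default study grid
profile_from_fn <- function(fn, grid = study_design()$sampling_times_h,
                            loq = 0.01) {
  conc <- fn(pmax(grid, 0))
  conc[grid < 0] <- 0
  concentration_profile(grid, conc, blq = conc < loq, loq = loq,
                        subject = "S01", condition = "test")
}

# quick hypnogram from a compact string like "W W N1 N2 R"
hyp_from_codes <- function(...) hypnogram(c(...))

# paired sleep-variable values for two conditions from one simulated study
paired_sleep_values <- function(n = 17, seed = 7, config = sleep_sim_config(),
                                var, cond_a = "placebo", cond_b = "dex40") {
  d <- study_design(n_subjects = n, seed = seed)
  hyps <- simulate_hypnograms(d, config)
  sv <- sleep_variable_table(hyps)
  a <- sv[sv$condition == cond_a, ]
  b <- sv[sv$condition == cond_b, ]
  a <- a[order(a$subject), ]
  b <- b[order(b$subject), ]
  list(x = a[[var]], y = b[[var]], hyps = hyps, vars = sv)
}

# brute-force Benjamini-Hochberg: q_i = min over ranks j >= i of p_(j)*m/j
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    r <- which(ord == i)  # rank of p[i]
    cand <- vapply(r:m, function(j) p[ord[j]] * m / j, numeric(1))
    q[i] <- min(1, min(cand))
  }
  q
}
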
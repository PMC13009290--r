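# Shared fixtures: built once per test run, all generated in code.

# Small two-pond simulation reused across modules.
small_cfg <- sim_config(n_fish_per_pond = 60, n_sires = 10, n_dams = 20,
                        n_snps = 400, seed = 42)
small_geno <- simulate_genotypes(small_cfg)
small_sim <- simulate_weights(small_cfg, small_geno)
small_grm <- compute_grm(small_geno)

# Deterministic toy weight records: n fish on exact lines in 1/f scale.
toy_records <- function(n = 10, f = 1.5, a = 5, b = 0.2, ages = c(1, 30, 60, 90, 120),
                        noise_sd = 0, seed = 1, obs_scale = TRUE) {
  set.seed(seed)
  rows <- lapply(seq_len(n), function(i) {
    bi <- if (length(b) == n) b[i] else b
    if (obs_scale) {
      w <- a + bi * ages^f + stats::rnorm(length(ages), 0, noise_sd)
    } else {
      w <- (a + bi * ages + stats::rnorm(length(ages), 0, noise_sd))^f
    }
    data.frame(fish_id = sprintf("T%03d", i), pond = "aerated",
               hapa = 1L + (i %% 2L), sex = "male",
               start_weight = w[1], age = ages, weight = w)
  })
  do.call(rbind, rows)
}

# Independent REML log-likelihood oracle: direct dense evaluation used to
# cross-check the AI engine via derivative-free optimisation.
oracle_loglik <- function(theta, y, X, V_of_theta) {
  V <- V_of_theta(theta)
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) return(-Inf)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  as.numeric(-0.5 * (determinant(V)$modulus +
                     determinant(XtViX)$modulus +
                     t(r) %*% Vi %*% r))
}

# grid unimodality check used by the exponent tests
is_unimodal_grid <- function(s) {
  d <- sign(diff(s)); d <- d[d != 0]; all(diff(d) >= 0)
}
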
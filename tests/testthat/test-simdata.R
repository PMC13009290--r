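test_that("configuration validation rejects impossible designs", {
  expect_error(sim_config(n_sires = 0), "n_sires")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(measurement_ages = c(1, 55, 55)), "increasing")
  expect_error(sim_config(slope_add_var = c(aerated = -1, non_aerated = 1)),
               "variances")
  K <- default_genetic_correlations(); K[1, 2] <- K[2, 1] <- 0.999
  K[1, 3] <- K[3, 1] <- -0.999
  K[2, 3] <- K[3, 2] <- 0.999
  expect_error(sim_config(genetic_correlations = K), "semi-definite")
})

test_that("genotype simulation is Mendelian and reproducible", {
  cfg <- sim_config(n_fish_per_pond = 300, n_sires = 8, n_dams = 16,
                    n_snps = 300, maf_range = c(0.5, 0.5))
  g <- simulate_genotypes(cfg, seed = 7)
  # symmetric frequencies: mean dosage near 1
  expect_equal(mean(g$dosage), 1, tolerance = 0.02)
  # offspring frequencies track parental frequencies per SNP
  cfg2 <- sim_config(n_fish_per_pond = 500, n_snps = 200,
                     maf_range = c(0.1, 0.5))
  g2 <- simulate_genotypes(cfg2, seed = 8)
  par_freq <- colMeans(g2$parent_dosage) / 2
  off_freq <- colMeans(g2$dosage) / 2
  expect_lt(max(abs(par_freq - off_freq)), 0.12)
  expect_gt(stats::cor(par_freq, off_freq), 0.9)
  # bit-reproducible under a fixed seed
  g3 <- simulate_genotypes(cfg2, seed = 8)
  expect_identical(g2$dosage, g3$dosage)
})

test_that("full sibs average a genomic relationship near 0.5", {
  # many small full-sib families, relationship averaged over pairs
  cfg <- sim_config(n_fish_per_pond = 100, n_sires = 25, n_dams = 50,
                    n_snps = 3000)
  g <- simulate_genotypes(cfg, seed = 11)
  grm <- compute_grm(g, blend = 0)
  fam <- paste(g$sire, g$dam)
  pairs <- list()
  for (fm in unique(fam)) {
    i <- which(fam == fm)
    if (length(i) >= 2) pairs[[fm]] <- utils::combn(i, 2)
  }
  pp <- do.call(cbind, pairs)
  rel <- grm$G[cbind(pp[1, ], pp[2, ])]
  expect_gt(length(rel), 100)
  expect_equal(mean(rel), 0.5, tolerance = 0.035)
})

test_that("weight simulation collapses to the deterministic limit", {
  cfg <- sim_config(n_fish_per_pond = 10, n_sires = 4, n_dams = 8,
                    n_snps = 50,
                    slope_add_var = 0, slope_env_var = 0,
                    logvar_baseline = -60, logvar_add_var = 0,
                    logvar_env_var = 0,
                    hapa_effects = rep(0, 4),
                    sex_effects = c(male = 0, female = 0, unknown = 0),
                    unknown_sex_frac = 0)
  g <- simulate_genotypes(cfg, seed = 3)
  sim <- simulate_weights(cfg, g, seed = 3)
  expected <- (cfg$intercept_a +
                 cfg$mean_dgc[sim$records$pond] * sim$records$age)^cfg$true_f
  expect_equal(sim$records$weight, unname(expected), tolerance = 1e-6)
})

test_that("simulated breeding values realise the configured variances", {
  cfg <- sim_config(n_fish_per_pond = 5000, n_sires = 72, n_dams = 200,
                    n_snps = 2000)
  g <- simulate_genotypes(cfg, seed = 5)
  sim <- simulate_weights(cfg, g, seed = 6)
  bv <- sim$truth$bv
  target <- c(cfg$slope_add_var[["aerated"]],
              cfg$slope_add_var[["non_aerated"]],
              cfg$logvar_add_var[["aerated"]],
              cfg$logvar_add_var[["non_aerated"]])
  realised <- apply(bv, 2, stats::var)
  expect_equal(unname(realised), target, tolerance = 0.05)
  # and the realised correlation structure follows the configuration
  expect_equal(unname(stats::cor(bv)[1, 2]),
               default_genetic_correlations()[1, 2], tolerance = 0.1)
})

test_that("records round-trip through the CSV reader/writer losslessly", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_weight_records(small_sim$records, path)
  back <- read_weight_records(path)
  ord <- order(small_sim$records$fish_id, small_sim$records$age)
  orig <- small_sim$records[ord, ]
  rownames(orig) <- NULL
  expect_equal(back, orig, tolerance = 1e-12)
})

test_that("trait-pair generator honours degenerate and regular covariances", {
  G <- small_grm
  # correlation 1, zero residual: genetic parts (and phenotypes) identical
  C <- matrix(0.4, 2, 2)
  sp <- simulate_trait_pair(G, C, R = diag(0, 2), disjoint = FALSE, seed = 2)
  expect_equal(sp$y1, sp$y2, tolerance = 1e-10)
  # empirical covariance of many BV pairs matches C
  C2 <- matrix(c(1, 0.5, 0.5, 2), 2)
  big <- diag(5000)
  rownames(big) <- sprintf("X%04d", 1:5000)
  sp2 <- simulate_trait_pair(big, C2, R = diag(2), disjoint = FALSE, seed = 9)
  emp <- stats::cov(sp2$truth$a)
  expect_equal(unname(emp), unname(C2), tolerance = 0.06)
  # non-PSD covariance refused before sampling
  bad <- matrix(c(1, 2, 2, 1), 2)
  expect_error(simulate_trait_pair(G, bad, diag(2)), "semi-definite")
})

test_that("genotype simulation handles the full experimental scale", {
  cfg <- sim_config(n_fish_per_pond = 843, n_snps = 11293)
  g <- simulate_genotypes(cfg, seed = 99)
  expect_equal(dim(g$dosage), c(1686L, 11293L))
  expect_true(all(g$dosage %in% 0:2))
})

test_that("positivity resampling errors out when unattainable", {
  cfg <- sim_config(n_fish_per_pond = 5, n_sires = 2, n_dams = 4,
                    n_snps = 20, intercept_a = 0.01,
                    logvar_baseline = 8, resample_cap = 3)
  g <- simulate_genotypes(cfg, seed = 1)
  expect_error(simulate_weights(cfg, g, seed = 1), "positivity")
})
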
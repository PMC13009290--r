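# A compact dataset for the REML tests: 48 fish with a moderately
# informative family structure.
vc_cfg <- sim_config(n_fish_per_pond = 24, n_sires = 6, n_dams = 12,
                     n_snps = 500)
vc_geno <- simulate_genotypes(vc_cfg, seed = 77)
vc_grm <- compute_grm(vc_geno)

test_that("design builder codes factors full rank and screens ids", {
  lines <- fit_growth_lines(small_sim$records, small_cfg$true_f)
  rt <- suppressWarnings(resilience_table(small_sim$records, lines,
                                          cohort_floor = 3))
  d <- build_design(rt, "lnvar_ind", grm = small_grm)
  # mean + 3 hapa contrasts + 2 sex contrasts = 6 columns, full rank
  expect_equal(ncol(d$X), 1 + (length(unique(rt$hapa)) - 1) +
                 (length(unique(rt$sex)) - 1))
  expect_equal(qr(d$X)$rank, ncol(d$X))
  # start weight enters for harvest weight only
  dw <- build_design(rt, "w5", grm = small_grm)
  expect_true("start_weight" %in% colnames(dw$X))
  expect_false("start_weight" %in% colnames(d$X))

  # single-level factor collapses cleanly
  rt1 <- rt; rt1$sex <- "male"; rt1$hapa <- 1
  d1 <- build_design(rt1, "lnvar_ind")
  expect_equal(colnames(d1$X), "(Intercept)")

  # a hand-built row: fish in hapa 3, female, reference levels 1/female?
  d2 <- build_design(rt, "dgc")
  i <- which(rt$hapa == 3 & rt$sex == "male")[1]
  i2 <- match(rt$fish_id[i], names(d2$y))
  expect_equal(unname(d2$X[i2, ]),
               c(1, as.numeric(levels(factor(rt$hapa))[-1] == "3"),
                 as.numeric(levels(factor(rt$sex))[-1] == "male")))

  # fish missing from the GRM are reported
  rt_bad <- rt; rt_bad$fish_id[1] <- "GHOST"
  expect_error(build_design(rt_bad, "lnvar_ind", grm = small_grm), "GHOST")
})

test_that("univariate AI-REML matches a derivative-free likelihood oracle", {
  set.seed(31)
  sub <- vc_grm$ids[1:48]
  Gs <- vc_grm$G[sub, sub]
  ph <- simulate_trait(vc_grm, 1.0, 1.0, mu = 3, seed = 32)
  y <- ph$y[sub]
  X <- cbind(1, stats::rnorm(48))
  fit <- reml_univariate(y, X, ids = sub, grm = vc_grm)

  V_of <- function(th) th[1] * Gs + th[2] * diag(48)
  oracle <- stats::optim(c(0.5, 0.5),
                         function(th) -oracle_loglik(th, y, X, V_of),
                         method = "L-BFGS-B", lower = c(1e-6, 1e-6),
                         control = list(factr = 10))
  expect_equal(unname(fit$varcomp[["A11"]]), oracle$par[1], tolerance = 1e-4)
  expect_equal(unname(fit$varcomp[["E11"]]), oracle$par[2], tolerance = 1e-4)
  expect_equal(fit$loglik, -oracle$value, tolerance = 1e-6)
})

test_that("bivariate AI-REML matches the likelihood oracle on 40 fish", {
  sub <- vc_grm$ids[1:40]
  Gs <- vc_grm$G[sub, sub]
  C <- matrix(c(1, 0.5, 0.5, 1.2), 2)
  R <- matrix(c(0.8, 0.2, 0.2, 1.1), 2)
  sp <- simulate_trait_pair(vc_grm, C, R, disjoint = FALSE, seed = 33)
  y1 <- sp$y1[sub]; y2 <- sp$y2[sub]
  fit <- reml_bivariate(y1, y2, ids1 = sub, ids2 = sub, grm = vc_grm,
                        residual_cov_free = TRUE)

  yst <- c(y1, y2)
  Xst <- cbind(rep(c(1, 0), each = 40), rep(c(0, 1), each = 40))
  # the oracle honours the same model constraints (|r| <= 1, variances > 0)
  # through a bounded variance/correlation parameterisation
  V_of_par <- function(p) {
    A12 <- p[3] * sqrt(p[1] * p[2])
    E12 <- p[6] * sqrt(p[4] * p[5])
    A <- matrix(c(p[1], A12, A12, p[2]), 2)
    E <- matrix(c(p[4], E12, E12, p[5]), 2)
    kronecker(A, Gs) + kronecker(E, diag(40))
  }
  oracle <- stats::optim(c(1, 1, 0.3, 1, 1, 0.1),
                         function(p) -oracle_loglik(p, yst, Xst, V_of_par),
                         method = "L-BFGS-B",
                         lower = c(1e-6, 1e-6, -0.999988, 1e-6, 1e-6, -0.999988),
                         upper = c(Inf, Inf, 0.999988, Inf, Inf, 0.999988),
                         control = list(factr = 1e3))
  p <- oracle$par
  th_oracle <- c(p[1], p[3] * sqrt(p[1] * p[2]), p[2],
                 p[4], p[6] * sqrt(p[4] * p[5]), p[5])
  th <- fit$varcomp[c("A11", "A12", "A22", "E11", "E12", "E22")]
  expect_equal(unname(th), th_oracle, tolerance = 1e-3)
  expect_equal(fit$loglik, -oracle$value, tolerance = 1e-5)
})

test_that("null heritability hits the boundary with a flag", {
  set.seed(35)
  ids <- vc_grm$ids
  y <- stats::rnorm(length(ids))   # no genetic signal at all
  names(y) <- ids
  fit <- reml_univariate(y, ids = ids, grm = vc_grm)
  expect_lt(fit$h2, 0.15)
  ph <- simulate_trait(vc_grm, 0, 1, seed = 36)
  fit0 <- reml_univariate(ph$y, ids = ids, grm = vc_grm)
  expect_lt(fit0$h2, 0.1)
})

test_that("accepted REML iterations never decrease the log-likelihood", {
  ph <- simulate_trait(vc_grm, 0.5, 1.2, seed = 37)
  fit <- reml_univariate(ph$y, ids = vc_grm$ids, grm = vc_grm)
  expect_true(all(diff(fit$trace$loglik) > -1e-8))
  expect_true(fit$converged)
})

test_that("estimates are invariant to fish reordering", {
  ph <- simulate_trait(vc_grm, 0.8, 0.9, seed = 38)
  fit1 <- reml_univariate(ph$y, ids = vc_grm$ids, grm = vc_grm)
  ord <- sample(length(ph$y))
  fit2 <- reml_univariate(ph$y[ord], ids = vc_grm$ids[ord], grm = vc_grm)
  expect_equal(fit1$varcomp, fit2$varcomp, tolerance = 1e-6)
  expect_equal(fit1$loglik, fit2$loglik, tolerance = 1e-8)
})

test_that("variance components are invariant to the fixed-effect coding", {
  set.seed(39)
  ids <- vc_grm$ids
  grp <- factor(rep(c("g1", "g2", "g3"), length.out = length(ids)))
  ph <- simulate_trait(vc_grm, 0.6, 1.0, seed = 40)
  y <- ph$y + c(0, 1.5, -0.7)[as.integer(grp)]
  X_ref <- stats::model.matrix(~grp)
  X_alt <- stats::model.matrix(~0 + grp)   # cell-means coding
  f1 <- reml_univariate(y, X_ref, ids, vc_grm)
  f2 <- reml_univariate(y, X_alt, ids, vc_grm)
  expect_equal(f1$varcomp, f2$varcomp, tolerance = 1e-6)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
})

test_that("the univariate fit equals the bivariate marginal under no linkage", {
  # second trait generated with zero genetic and residual correlation
  C <- diag(c(0.9, 0.7)); R <- diag(c(1.1, 0.8))
  sp <- simulate_trait_pair(vc_grm, C, R, disjoint = FALSE, seed = 41)
  fu <- reml_univariate(sp$y1, ids = sp$ids1, grm = vc_grm)
  fb <- reml_bivariate(sp$y1, sp$y2, ids1 = sp$ids1, ids2 = sp$ids2,
                       grm = vc_grm, residual_cov_free = TRUE)
  expect_equal(unname(fb$varcomp[["A11"]]), unname(fu$varcomp[["A11"]]),
               tolerance = 0.12)
  expect_equal(unname(fb$varcomp[["E11"]]), unname(fu$varcomp[["E11"]]),
               tolerance = 0.12)
})

test_that("duplicated trait drives the genetic correlation to its boundary", {
  ph <- simulate_trait(vc_grm, 0.8, 0.4, seed = 42)
  fit <- reml_bivariate(ph$y, ph$y + 1e-3 * stats::rnorm(length(ph$y)),
                        ids1 = ph$ids, ids2 = ph$ids, grm = vc_grm,
                        residual_cov_free = TRUE)
  expect_gt(fit$r_g, 0.98)
  expect_true(fit$boundary)
})

test_that("configuration errors are caught before fitting", {
  ph <- simulate_trait(vc_grm, 0.5, 0.5, seed = 43)
  n <- length(ph$y)
  h1 <- ph$ids[1:(n / 2)]; h2 <- ph$ids[(n / 2 + 1):n]
  # disjoint fish with a free residual covariance: unidentifiable
  expect_error(reml_bivariate(ph$y[h1], ph$y[h2], ids1 = h1, ids2 = h2,
                              grm = vc_grm, residual_cov_free = TRUE),
               "not identifiable")
  # same fish with the covariance constrained: refused
  expect_error(reml_bivariate(ph$y, ph$y, ids1 = ph$ids, ids2 = ph$ids,
                              grm = vc_grm, residual_cov_free = FALSE),
               "residual_cov_free")
  # unknown fish
  expect_error(reml_univariate(ph$y, ids = c("NOPE", ph$ids[-1]),
                               grm = vc_grm), "absent")
})

test_that("heritability ratio, delta SE and validity flags", {
  h <- heritability(0.44, 1.563)
  expect_equal(h$h2, 0.2815, tolerance = 1e-4)
  expect_true(h$valid)
  expect_true(is.na(h$se))
  vc <- matrix(c(0.01, 0.004, 0.004, 0.02), 2)
  h2 <- heritability(0.44, 1.563, vcov = vc)
  grad <- c(1 / 1.563, -0.44 / 1.563^2)
  expect_equal(h2$se, sqrt(drop(t(grad) %*% vc %*% grad)))
  expect_false(heritability(2, 1)$valid)
  expect_error(heritability(1, 0), "positive")
})

test_that("BLUP breeding values match direct GLS algebra on a tiny fit", {
  sub <- vc_grm$ids[1:20]
  Gs <- vc_grm$G[sub, sub]
  ph <- simulate_trait(vc_grm, 1.2, 0.6, seed = 44)
  y <- ph$y[sub]
  fit <- reml_univariate(y, ids = sub, grm = vc_grm,
                         compute_accuracy = TRUE)
  sA <- fit$varcomp[["A11"]]; sE <- fit$varcomp[["E11"]]
  V <- sA * Gs + sE * diag(20)
  X <- matrix(1, 20, 1)
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  abv <- sA * vc_grm$G[, sub] %*% Vi %*% (y - X %*% beta)
  expect_equal(fit$ebv[[2]], unname(drop(abv)), tolerance = 1e-6)
  # sigma_A -> 0 limit: with the genetic variance at the zero boundary the
  # BLUPs collapse to zero
  ph0 <- simulate_trait(vc_grm, 0, 1, seed = 36)
  fit0 <- reml_univariate(ph0$y, ids = ph0$ids, grm = vc_grm)
  expect_lt(fit0$h2, 1e-4)
  expect_lt(max(abs(fit0$ebv[[2]])), 1e-4)
})
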
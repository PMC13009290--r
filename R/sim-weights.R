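#' Simulate longitudinal weights for the two-pond experiment
#'
#' Generates per-fish growth on the linearised (1/f) scale and
#' back-transforms to grams.  For fish i at age t the linearised weight is
#' `L_it = a_i + b_i * t + e_it`, where the intercept `a_i` is the configured
#' base intercept plus nursery-hapa and sex shifts, the slope
#' `b_i = mean_dgc[pond] + BV_slope,i + environmental noise`, and
#' `e_it ~ N(0, exp(eta_i))` with
#' `eta_i = baseline[pond] + BV_logvar,i + environmental noise`.  The
#' observed weight is `W_it = L_it^f`.  Breeding values for the slope and
#' the log deviation variance are genomic: each SNP carries a 4-variate
#' effect (two traits x two ponds) with the configured correlation
#' structure, so the realised covariance of breeding values matches the
#' genomic relationship matrix computed from the same genotypes.
#'
#' Deviations that would push a linearised weight to or below zero are
#' redrawn (up to `config$resample_cap` times per observation); the redraw
#' count is reported in the truth object.  Fish are allocated to the two
#' ponds in halves so that every full-sib family spans both ponds, and to
#' four nursery hapas by dam group.
#'
#' @param config A [sim_config()] object.
#' @param genotypes A `sim_genotypes` object covering all fish, from
#'   [simulate_genotypes()].
#' @param seed Optional integer seed (falls back to `config$seed`).
#'
#' @return A list with `records`, a long-format data frame (fish_id, pond,
#'   hapa, sex, start_weight, age, weight) covering both ponds, and `truth`,
#'   a `sim_truth` object holding the configuration, family assignments,
#'   true breeding values, realised slopes and log variances.
#' @export
simulate_weights <- function(config, genotypes, seed = NULL) {
  stopifnot(inherits(config, "sim_config"), inherits(genotypes, "sim_genotypes"))
  seed <- if (!is.null(seed)) seed else config$seed
  if (!is.null(seed)) set.seed(seed)

  X <- genotypes$dosage
  n <- nrow(X)
  ids <- rownames(X)
  ages <- config$measurement_ages
  k <- length(ages)

  pond <- rep(c("aerated", "non_aerated"), c(ceiling(n / 2), floor(n / 2)))
  nd <- config$n_dams
  hapa <- ((genotypes$dam - 1L) %/% ceiling(nd / 4)) + 1L
  hapa <- pmin(hapa, 4L)
  sex <- sample(c("male", "female"), n, replace = TRUE)
  sex[stats::runif(n) < config$unknown_sex_frac] <- "unknown"

  bv <- genomic_bv(X, genotypes$founder_freq, config)

  slope_bv <- ifelse(pond == "aerated", bv[, "slope_aerated"],
                     bv[, "slope_non_aerated"])
  logvar_bv <- ifelse(pond == "aerated", bv[, "logvar_aerated"],
                      bv[, "logvar_non_aerated"])
  b_i <- config$mean_dgc[pond] + slope_bv +
    stats::rnorm(n, 0, sqrt(config$slope_env_var[pond]))
  eta_i <- config$logvar_baseline[pond] + logvar_bv +
    stats::rnorm(n, 0, sqrt(config$logvar_env_var[pond]))
  a_i <- config$intercept_a + config$hapa_effects[hapa] +
    config$sex_effects[sex]

  mu <- outer(a_i, rep(1, k)) + outer(b_i, ages)   # n x k linearised means
  sd_i <- exp(eta_i / 2)
  E <- matrix(stats::rnorm(n * k), n, k) * sd_i
  L <- mu + E
  n_resampled <- 0L
  tries <- 0L
  while (any(bad <- L <= 0)) {
    tries <- tries + 1L
    if (tries > config$resample_cap) {
      w <- which(bad, arr.ind = TRUE)[1, ]
      stop(sprintf(
        "positivity unattainable after %d resamples for fish %s at age %g",
        config$resample_cap, ids[w[1]], ages[w[2]]), call. = FALSE)
    }
    idx <- which(bad)
    n_resampled <- n_resampled + length(idx)
    L[idx] <- mu[idx] + stats::rnorm(length(idx)) * sd_i[(idx - 1L) %% n + 1L]
  }
  W <- L^config$true_f

  keep <- matrix(TRUE, n, k)
  if (config$missing_rate > 0 && k > 1L)
    keep[, -1L] <- matrix(stats::runif(n * (k - 1L)) >= config$missing_rate,
                          n, k - 1L)

  records <- data.frame(
    fish_id = rep(ids, each = k),
    pond = rep(pond, each = k),
    hapa = rep(hapa, each = k),
    sex = rep(sex, each = k),
    start_weight = rep(W[, 1], each = k),
    age = rep(ages, n),
    weight = as.vector(t(W)),
    stringsAsFactors = FALSE)
  records <- records[as.vector(t(keep)), , drop = FALSE]
  rownames(records) <- NULL

  truth <- structure(list(config = config, fish_id = ids, pond = pond,
                          hapa = hapa, sex = sex,
                          sire = genotypes$sire, dam = genotypes$dam,
                          bv = bv, slope = b_i, logvar = eta_i,
                          n_resampled = n_resampled),
                     class = "sim_truth")
  list(records = records, truth = truth)
}

# Genomic breeding values: per-SNP effects with the configured 4x4
# covariance among (slope, logvar) x (aerated, non-aerated), scaled so the
# population variance of each BV matches the configured additive variance.
genomic_bv <- function(X, p, config) {
  sds <- sqrt(c(config$slope_add_var[["aerated"]],
                config$slope_add_var[["non_aerated"]],
                config$logvar_add_var[["aerated"]],
                config$logvar_add_var[["non_aerated"]]))
  Sigma <- diag(sds) %*% config$genetic_correlations %*% diag(sds)
  S <- sum(2 * p * (1 - p))
  sq <- mat_sqrt(Sigma / max(S, 1e-12))
  alpha <- matrix(stats::rnorm(ncol(X) * 4L), ncol(X), 4L) %*% sq
  Xc <- sweep(X, 2L, 2 * p)
  bv <- Xc %*% alpha
  colnames(bv) <- colnames(config$genetic_correlations)
  rownames(bv) <- rownames(X)
  bv
}

# Symmetric PSD square root (tolerates semi-definite input).
mat_sqrt <- function(M) {
  e <- eigen(M, symmetric = TRUE)
  if (min(e$values) < -1e-8 * max(abs(e$values), 1))
    stop("covariance matrix is not positive semi-definite", call. = FALSE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("Simulation truth: %d fish (%d aerated / %d non-aerated), %d resampled deviations\n",
              length(x$fish_id), sum(x$pond == "aerated"),
              sum(x$pond == "non_aerated"), x$n_resampled))
  invisible(x)
}

#' Simulate a phenotype pair under the bivariate animal model
#'
#' Draws two trait vectors `y = mu + a + e` with additive values
#' `a ~ N(0, C (x) G)` and residuals `e ~ N(0, R (x) I)`.  With
#' `disjoint = TRUE` the first half of the individuals records trait 1 and
#' the second half trait 2, and the residual covariance is ignored (each
#' fish performs in one environment only), which is the cross-environment
#' design.  With `disjoint = FALSE` both traits are recorded on every
#' individual and `R` may carry a residual covariance.
#'
#' @param grm A `relationship_matrix` from [compute_grm()] or a plain
#'   symmetric PSD matrix with rownames.
#' @param C 2x2 additive genetic covariance matrix.
#' @param R 2x2 residual covariance matrix (off-diagonal ignored when
#'   `disjoint = TRUE`).
#' @param mu Length-2 trait means.
#' @param disjoint Logical; disjoint recording (cross-environment design)?
#' @param seed Optional integer seed.
#'
#' @return A list with `y1`, `y2` (named numeric vectors), `ids1`, `ids2`,
#'   and `truth` (a list holding `a`, the n x 2 matrix of true additive
#'   values, plus the generating matrices).
#' @export
simulate_trait_pair <- function(grm, C, R, mu = c(0, 0), disjoint = TRUE,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  G <- if (inherits(grm, "relationship_matrix")) grm$G else grm
  ids <- if (inherits(grm, "relationship_matrix")) grm$ids else rownames(G)
  n <- nrow(G)
  if (is.null(ids)) ids <- sprintf("F%04d", seq_len(n))
  if (max(abs(G - t(G))) > 1e-8 * max(abs(G), 1))
    stop("relationship matrix must be symmetric", call. = FALSE)
  check_psd <- function(M, what) {
    if (min(eigen(M, symmetric = TRUE, only.values = TRUE)$values) <
        -1e-8 * max(abs(M), 1))
      stop(sprintf("%s must be positive semi-definite", what), call. = FALSE)
  }
  check_psd(C, "C"); check_psd(R, "R")

  Z <- matrix(stats::rnorm(n * 2L), n, 2L)
  sqG <- tryCatch(t(chol(G)), error = function(e) mat_sqrt(G))
  a <- (sqG %*% Z) %*% mat_sqrt(C)   # Var(vec(a)) = C (x) G
  rownames(a) <- ids

  if (disjoint) {
    i1 <- seq_len(ceiling(n / 2)); i2 <- setdiff(seq_len(n), i1)
    e1 <- stats::rnorm(length(i1), 0, sqrt(R[1, 1]))
    e2 <- stats::rnorm(length(i2), 0, sqrt(R[2, 2]))
    y1 <- mu[1] + a[i1, 1] + e1
    y2 <- mu[2] + a[i2, 2] + e2
    ids1 <- ids[i1]; ids2 <- ids[i2]
  } else {
    E <- matrix(stats::rnorm(n * 2L), n, 2L) %*% mat_sqrt(R)
    y1 <- mu[1] + a[, 1] + E[, 1]
    y2 <- mu[2] + a[, 2] + E[, 2]
    ids1 <- ids2 <- ids
  }
  names(y1) <- ids1; names(y2) <- ids2
  list(y1 = y1, y2 = y2, ids1 = ids1, ids2 = ids2,
       truth = list(a = a, C = C, R = R, mu = mu, disjoint = disjoint))
}

#' Simulate a single phenotype under the univariate animal model
#'
#' Convenience wrapper drawing `y = mu + a + e` with `a ~ N(0, sigma_a * G)`
#' and `e ~ N(0, sigma_e * I)`.
#'
#' @inheritParams simulate_trait_pair
#' @param sigma_a,sigma_e Additive and residual variances.
#' @param mu Trait mean.
#' @return A list with `y` (named numeric), `ids`, and `truth$a`.
#' @export
simulate_trait <- function(grm, sigma_a, sigma_e, mu = 0, seed = NULL) {
  sp <- simulate_trait_pair(grm, C = diag(c(sigma_a, sigma_a)),
                            R = diag(c(sigma_e, sigma_e)), mu = c(mu, mu),
                            disjoint = FALSE, seed = seed)
  list(y = sp$y1, ids = sp$ids1, truth = list(a = sp$truth$a[, 1]))
}
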
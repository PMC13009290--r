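#' Default genetic correlation matrix of the simulator
#'
#' Correlations among the four latent genetic traits of the growth simulator:
#' the linearised growth slope and the log deviation variance, each expressed
#' in the aerated and the non-aerated pond.  Within-pond slope/log-variance
#' correlations are negative (fast growers deviate less), the cross-pond
#' correlation of the log deviation variance is well below 1 (genotype by
#' environment interaction), and the cross-pond slope correlation is high.
#'
#' @return A 4x4 positive-definite correlation matrix with dimnames
#'   `slope_aerated`, `slope_non_aerated`, `logvar_aerated`,
#'   `logvar_non_aerated`.
#' @export
default_genetic_correlations <- function() {
  nm <- c("slope_aerated", "slope_non_aerated",
          "logvar_aerated", "logvar_non_aerated")
  K <- matrix(c(
    1.00,  0.80, -0.44, -0.35,
    0.80,  1.00, -0.35, -0.68,
   -0.44, -0.35,  1.00,  0.50,
   -0.35, -0.68,  0.50,  1.00), 4, 4, dimnames = list(nm, nm))
  K
}

#' Configuration of the synthetic two-pond grow-out experiment
#'
#' Bundles every generating parameter of the synthetic dataset: family
#' structure (hierarchical sire/dam mating), SNP panel, measurement schedule,
#' the allometric growth model on the linearised (1/f) scale, and the
#' per-pond additive and environmental variance components of the two latent
#' genetic traits (growth slope and log deviation variance).
#'
#' The defaults emulate a two-pond tilapia grow-out: 72 sires and 200 dams,
#' roughly 850 harvested fish per pond, four nursery hapas, three sex codes,
#' and weights at days 1, 55, 104, 167 and 217.  Slope variances follow the
#' daily growth coefficient components of the motivating experiment
#' (additive 0.25e-3 / 0.12e-3, phenotypic 0.88e-3 / 0.48e-3 in the aerated /
#' non-aerated pond), and log-variance additive variances are 0.060 / 0.440
#' with environmental spread chosen so the phenotypic variance of the
#' individual log-variance indicator reaches 1.057 / 1.563 once the sampling
#' noise of a 3-df log variance (trigamma(3/2) = 0.935) is added.
#'
#' The linearised intercept defaults to a small value (0.2 g^(1/f)).  The
#' simulator generates weights that are exactly linear on the 1/f scale, and
#' the observed-scale model W = a + b*t^f with a shared intercept coincides
#' with that generating process only when the linearised intercept is close
#' to zero; larger intercepts would make the recovered exponent drift below
#' the generating one.  The price is that simulated start and harvest weights
#' are smaller than in a real grow-out; all variance structure is unaffected.
#'
#' @param n_fish_per_pond Number of harvested fish per pond.
#' @param n_sires,n_dams Numbers of sire and dam founders (dams are nested
#'   within sires round-robin).
#' @param n_snps Number of biallelic SNPs simulated for the founders.
#' @param maf_range Range of founder minor allele frequencies, in (0, 0.5].
#' @param measurement_ages Days since stocking of the weight measurements
#'   (strictly increasing, positive; stocking is day 1).
#' @param true_f Generating overall weight exponent.
#' @param intercept_a Intercept of the linearised growth line, g^(1/f).
#' @param mean_dgc Named mean linearised growth slope per pond, g^(1/f)/day.
#' @param slope_add_var,slope_env_var Additive and environmental variances of
#'   the growth slope per pond.
#' @param logvar_baseline Baseline of the per-fish log deviation variance
#'   (log of squared g^(1/f)) per pond.
#' @param logvar_add_var,logvar_env_var Additive and environmental variances
#'   of the log deviation variance per pond.
#' @param genetic_correlations 4x4 correlation matrix among the latent
#'   genetic traits, see [default_genetic_correlations()].
#' @param hapa_effects Additive shifts of the linearised intercept for the
#'   four nursery hapas, g^(1/f).
#' @param sex_effects Named additive shifts for male/female/unknown sex.
#' @param unknown_sex_frac Fraction of fish with unrecorded sex.
#' @param missing_rate Probability that a post-stocking record is missing.
#' @param family_imbalance Dirichlet concentration control for family sizes;
#'   0 gives balanced (round-robin) families, larger values more imbalance.
#' @param resample_cap Maximum number of redraws of a deviation that would
#'   push a linearised weight to or below zero.
#' @param seed Optional integer seed stored with the configuration.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_genotypes()], [simulate_weights()]
#' @export
sim_config <- function(n_fish_per_pond = 850,
                       n_sires = 72,
                       n_dams = 200,
                       n_snps = 2000,
                       maf_range = c(0.1, 0.5),
                       measurement_ages = c(1, 55, 104, 167, 217),
                       true_f = 1.77,
                       intercept_a = 0.2,
                       mean_dgc = c(aerated = 0.16, non_aerated = 0.13),
                       slope_add_var = c(aerated = 0.25e-3, non_aerated = 0.12e-3),
                       slope_env_var = c(aerated = 0.63e-3, non_aerated = 0.36e-3),
                       logvar_baseline = c(aerated = -5.7, non_aerated = -5.7),
                       logvar_add_var = c(aerated = 0.060, non_aerated = 0.440),
                       logvar_env_var = c(aerated = 0.062, non_aerated = 0.188),
                       genetic_correlations = default_genetic_correlations(),
                       hapa_effects = c(0, 0.05, -0.05, 0.02),
                       sex_effects = c(male = 0.05, female = -0.05, unknown = 0),
                       unknown_sex_frac = 0.05,
                       missing_rate = 0,
                       family_imbalance = 0,
                       resample_cap = 100,
                       seed = NULL) {
  ponds <- c("aerated", "non_aerated")
  named_pond <- function(x, what) {
    if (length(x) == 1L) x <- c(aerated = unname(x), non_aerated = unname(x))
    if (is.null(names(x))) names(x) <- ponds
    if (!all(ponds %in% names(x)))
      stop(sprintf("'%s' must be named for both ponds", what), call. = FALSE)
    x[ponds]
  }
  mean_dgc <- named_pond(mean_dgc, "mean_dgc")
  slope_add_var <- named_pond(slope_add_var, "slope_add_var")
  slope_env_var <- named_pond(slope_env_var, "slope_env_var")
  logvar_baseline <- named_pond(logvar_baseline, "logvar_baseline")
  logvar_add_var <- named_pond(logvar_add_var, "logvar_add_var")
  logvar_env_var <- named_pond(logvar_env_var, "logvar_env_var")

  if (n_sires < 1L || n_dams < 1L)
    stop("n_sires and n_dams must both be at least 1", call. = FALSE)
  if (n_snps < 1L)
    stop("n_snps must be at least 1", call. = FALSE)
  if (length(maf_range) != 2L || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2])
    stop("maf_range must be an increasing pair within (0, 0.5]", call. = FALSE)
  if (any(diff(measurement_ages) <= 0) || any(measurement_ages <= 0))
    stop("measurement_ages must be strictly increasing and positive",
         call. = FALSE)
  vars <- c(slope_add_var, slope_env_var, logvar_add_var, logvar_env_var)
  if (any(vars < 0)) stop("all variances must be >= 0", call. = FALSE)
  if (true_f <= 0) stop("true_f must be positive", call. = FALSE)
  K <- genetic_correlations
  if (!is.matrix(K) || nrow(K) != 4L || ncol(K) != 4L ||
      max(abs(K - t(K))) > 1e-10 || any(abs(diag(K) - 1) > 1e-10))
    stop("genetic_correlations must be a symmetric 4x4 correlation matrix",
         call. = FALSE)
  if (min(eigen(K, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("genetic_correlations must be positive semi-definite", call. = FALSE)
  if (length(hapa_effects) != 4L)
    stop("hapa_effects must have length 4", call. = FALSE)
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)", call. = FALSE)

  cfg <- list(n_fish_per_pond = as.integer(n_fish_per_pond),
              n_sires = as.integer(n_sires), n_dams = as.integer(n_dams),
              n_snps = as.integer(n_snps), maf_range = maf_range,
              measurement_ages = measurement_ages, true_f = true_f,
              intercept_a = intercept_a, mean_dgc = mean_dgc,
              slope_add_var = slope_add_var, slope_env_var = slope_env_var,
              logvar_baseline = logvar_baseline,
              logvar_add_var = logvar_add_var,
              logvar_env_var = logvar_env_var,
              genetic_correlations = K,
              hapa_effects = hapa_effects, sex_effects = sex_effects,
              unknown_sex_frac = unknown_sex_frac,
              missing_rate = missing_rate,
              family_imbalance = family_imbalance,
              resample_cap = as.integer(resample_cap), seed = seed)
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic grow-out configuration\n")
  cat(sprintf("  fish per pond: %d   sires x dams: %d x %d   SNPs: %d\n",
              x$n_fish_per_pond, x$n_sires, x$n_dams, x$n_snps))
  cat(sprintf("  ages (d): %s   exponent f: %.3g\n",
              paste(x$measurement_ages, collapse = ", "), x$true_f))
  cat(sprintf("  mean DGC: %.3g (aerated) / %.3g (non-aerated) g^(1/f)/day\n",
              x$mean_dgc[["aerated"]], x$mean_dgc[["non_aerated"]]))
  cat(sprintf("  slope var (A/E): %.2e/%.2e aer, %.2e/%.2e non-aer\n",
              x$slope_add_var[["aerated"]], x$slope_env_var[["aerated"]],
              x$slope_add_var[["non_aerated"]], x$slope_env_var[["non_aerated"]]))
  cat(sprintf("  logvar var (A/E): %.3g/%.3g aer, %.3g/%.3g non-aer\n",
              x$logvar_add_var[["aerated"]], x$logvar_env_var[["aerated"]],
              x$logvar_add_var[["non_aerated"]], x$logvar_env_var[["non_aerated"]]))
  invisible(x)
}
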
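#' Fit one fish's linearised growth line
#'
#' Ordinary least squares of `W^(1/f)` on age: the slope is the daily growth
#' coefficient (DGC, g^(1/f)/day) and the fitted values are the expected
#' linearised weights used for the deviation-based resilience indicator.
#'
#' @param weights Observed weights in grams (length >= 3).
#' @param ages Measurement ages in days, same length, not all equal.
#' @param f Overall weight exponent (> 0), from
#'   [estimate_weight_exponent()].
#' @return A list with `intercept` (a_i, g^(1/f)), `dgc` (slope), `expected`
#'   (fitted linearised weights at the observed ages), and `residuals`
#'   (deviations on the 1/f scale; they sum to zero by construction).
#' @export
fit_individual_line <- function(weights, ages, f) {
  stopifnot(f > 0, length(weights) == length(ages))
  if (length(weights) < 3L)
    stop("need at least 3 (age, weight) pairs", call. = FALSE)
  if (length(unique(ages)) < 2L)
    stop("singular design: all ages equal", call. = FALSE)
  y <- weights^(1 / f)
  tb <- mean(ages); yb <- mean(y)
  slope <- sum((ages - tb) * (y - yb)) / sum((ages - tb)^2)
  intercept <- yb - slope * tb
  expected <- intercept + slope * ages
  list(intercept = intercept, dgc = slope, expected = expected,
       residuals = y - expected)
}

#' Fit linearised growth lines for every fish
#'
#' Applies [fit_individual_line()] per fish and collects per-fish
#' coefficients together with the long table of observed, expected and
#' deviation values on the 1/f scale.
#'
#' @inheritParams estimate_weight_exponent
#' @param f Overall weight exponent.
#' @return An object of class `growth_line_fits`: a list with `fish` (one
#'   row per fish: covariates, `intercept`, `dgc`, `n_obs`), `obs` (one row
#'   per observation: `fish_id`, `age`, `weight`, `w_lin`, `w_exp_lin`,
#'   `dev_inv_f`), `f`, and `excluded`.
#' @export
fit_growth_lines <- function(records, f) {
  records <- validate_weight_records(records)
  fl <- records_by_fish(records, min_obs = 3L)
  excluded <- setdiff(unique(records$fish_id), names(fl))
  cov <- fish_covariates(records)

  fits <- lapply(fl, function(d) fit_individual_line(d$weights, d$ages, f))
  fish <- cov[match(names(fl), cov$fish_id), , drop = FALSE]
  fish$intercept <- vapply(fits, `[[`, numeric(1), "intercept")
  fish$dgc <- vapply(fits, `[[`, numeric(1), "dgc")
  fish$n_obs <- vapply(fl, function(d) length(d$ages), integer(1))
  rownames(fish) <- NULL

  obs <- data.frame(
    fish_id = rep(names(fl), lengths(lapply(fl, `[[`, "ages"))),
    age = unlist(lapply(fl, `[[`, "ages"), use.names = FALSE),
    weight = unlist(lapply(fl, `[[`, "weights"), use.names = FALSE),
    w_exp_lin = unlist(lapply(fits, `[[`, "expected"), use.names = FALSE),
    dev_inv_f = unlist(lapply(fits, `[[`, "residuals"), use.names = FALSE),
    stringsAsFactors = FALSE)
  obs$w_lin <- obs$weight^(1 / f)

  structure(list(fish = fish, obs = obs, f = f, excluded = excluded),
            class = "growth_line_fits")
}

#' @export
print.growth_line_fits <- function(x, ...) {
  cat(sprintf("Linearised growth lines for %d fish at f = %.4f\n",
              nrow(x$fish), x$f))
  cat(sprintf("  mean DGC %.4f g^(1/f)/day (sd %.4f)\n",
              mean(x$fish$dgc), stats::sd(x$fish$dgc)))
  invisible(x)
}

#' Deviations of observed from expected weight on a chosen scale
#'
#' Given per-fish growth lines, computes the per-observation deviations on
#' one of three scales: `inv_f` (the OLS residuals of `W^(1/f)` on age; the
#' scale on which the resilience indicator is defined), `observed`
#' (`W - W_exp` in grams, where `W_exp` is the back-transformed expected
#' weight), or `cubic` (`W^(1/3) - W_exp^(1/3)`, the conventional volume
#' exponent).
#'
#' @param fits A `growth_line_fits` object.
#' @param scale One of `"inv_f"`, `"observed"`, `"cubic"`.
#' @return A data frame `fish_id`, `age`, `deviation` with the scale in
#'   attribute `"scale"`.
#' @export
compute_deviations <- function(fits, scale = c("inv_f", "observed", "cubic")) {
  stopifnot(inherits(fits, "growth_line_fits"))
  scale <- match.arg(scale)
  obs <- fits$obs
  if (scale != "inv_f" && any(obs$w_exp_lin <= 0)) {
    bad <- obs[obs$w_exp_lin <= 0, ][1, ]
    stop(sprintf(
      "non-positive expected linearised weight for fish %s at age %g; scale '%s' undefined",
      bad$fish_id, bad$age, scale), call. = FALSE)
  }
  dev <- switch(scale,
    inv_f = obs$dev_inv_f,
    observed = obs$weight - obs$w_exp_lin^fits$f,
    cubic = obs$weight^(1 / 3) - (obs$w_exp_lin^fits$f)^(1 / 3))
  out <- data.frame(fish_id = obs$fish_id, age = obs$age, deviation = dev,
                    stringsAsFactors = FALSE)
  attr(out, "scale") <- scale
  out
}

#' Per-time-point spread of deviations (heteroscedasticity diagnostic)
#'
#' Summarises the deviations at each measurement age by mean, standard
#' deviation and count, and reports the heterogeneity ratio
#' `max(SD_t) / min(SD_t)`.  A ratio near 1 indicates homoscedastic
#' deviations; the 1/f scale is expected to give a flatter profile than the
#' observed-gram scale.
#'
#' @param deviations Output of [compute_deviations()] (or any data frame
#'   with `age` and `deviation`).
#' @return An object of class `het_profile`: a list with `profile` (age,
#'   n, mean, sd), `ratio`, and `scale`.
#' @export
heteroscedasticity_profile <- function(deviations) {
  spl <- split(deviations$deviation, deviations$age)
  n <- lengths(spl)
  drop <- n < 2L
  if (any(drop)) {
    warning("time points with fewer than 2 values excluded: ",
            paste(names(spl)[drop], collapse = ", "), call. = FALSE)
    spl <- spl[!drop]
  }
  prof <- data.frame(age = as.numeric(names(spl)),
                     n = lengths(spl),
                     mean = vapply(spl, mean, numeric(1)),
                     sd = vapply(spl, stats::sd, numeric(1)))
  rownames(prof) <- NULL
  sds <- prof$sd[prof$sd > 0]
  ratio <- if (length(sds)) max(prof$sd) / min(prof$sd) else NA_real_
  structure(list(profile = prof, ratio = ratio,
                 scale = attr(deviations, "scale")),
            class = "het_profile")
}

#' @export
print.het_profile <- function(x, ...) {
  cat(sprintf("Deviation spread by time point (scale: %s)\n",
              x$scale %||% "unspecified"))
  print(x$profile, row.names = FALSE, digits = 4)
  cat(sprintf("Heterogeneity ratio max(SD)/min(SD) = %.3f\n", x$ratio))
  invisible(x)
}

#' @export
plot.het_profile <- function(x, ...) {
  p <- x$profile
  graphics::plot(p$age, p$mean, ylim = range(p$mean - p$sd, p$mean + p$sd),
                 xlab = "age (days)", ylab = "deviation",
                 main = sprintf("Deviation mean +/- SD (%s scale)",
                                x$scale %||% "?"), pch = 16, ...)
  graphics::arrows(p$age, p$mean - p$sd, p$age, p$mean + p$sd,
                   angle = 90, code = 3, length = 0.05)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Compare straight-line and quadratic growth on the 1/f scale
#'
#' Pools all fish and fits `W^(1/f)` on age with per-fish intercepts, once
#' with a common linear age term (Model 1) and once adding a quadratic age
#' term (Model 2).  A small quadratic coefficient supports the use of
#' straight-line regression for the expected weights.
#'
#' @inheritParams fit_growth_lines
#' @return A list with `quad_coef`, `quad_se`, `p_value` (F-test of Model 2
#'   against Model 1), `f_stat`, and `linear_coef`.
#' @export
compare_linear_quadratic <- function(records, f) {
  records <- validate_weight_records(records)
  if (length(unique(records$age)) < 3L)
    stop("need at least 3 distinct ages", call. = FALSE)
  y <- records$weight^(1 / f)
  fish <- factor(records$fish_id)
  t1 <- records$age
  t2 <- records$age^2
  m1 <- stats::lm(y ~ 0 + fish + t1)
  m2 <- stats::lm(y ~ 0 + fish + t1 + t2)
  if (anyNA(stats::coef(m2)))
    stop("collinear design: quadratic term is aliased", call. = FALSE)
  an <- stats::anova(m1, m2)
  sm2 <- summary(m2)$coefficients
  pval <- an[2, "Pr(>F)"]
  fstat <- an[2, "F"]
  if (!is.finite(pval)) {
    # both models interpolate (zero residual): the quadratic term adds
    # nothing, treat as the null of no curvature
    pval <- 1; fstat <- 0
  }
  list(quad_coef = unname(sm2["t2", 1]), quad_se = unname(sm2["t2", 2]),
       p_value = pval, f_stat = fstat,
       linear_coef = unname(sm2["t1", 1]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
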
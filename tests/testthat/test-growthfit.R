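test_that("noiseless allometric data are recovered exactly", {
  rec <- toy_records(n = 10, f = 1.5, a = 5, b = seq(0.1, 0.3, length.out = 10),
                     obs_scale = TRUE)
  fit <- estimate_weight_exponent(rec)
  expect_equal(fit$f, 1.5, tolerance = 1e-5)
  expect_equal(fit$a, 5, tolerance = 1e-3)
  expect_equal(unname(fit$b), seq(0.1, 0.3, length.out = 10),
               tolerance = 1e-4)
  expect_lt(fit$sse, 1e-8)
  expect_true(is_unimodal_grid(fit$grid$sse))
})

test_that("exponent estimate matches a brute-force grid oracle", {
  set.seed(21)
  rec <- toy_records(n = 50, f = 1.8, a = 30,
                     b = runif(50, 0.1, 0.25), noise_sd = 4,
                     obs_scale = TRUE, seed = 21)
  fit <- estimate_weight_exponent(rec)
  # oracle: profile a and b_i on a fine f grid, entirely independent code
  wide <- split(rec, rec$fish_id)
  sse_at <- function(f) {
    # joint closed-form for (a, b_i) at fixed f via normal equations
    tf <- lapply(wide, function(d) d$age^f)
    ws <- lapply(wide, function(d) d$weight)
    num <- den <- 0
    for (i in seq_along(wide)) {
      h <- tf[[i]] / sum(tf[[i]]^2)
      M1 <- 1 - tf[[i]] * sum(h)
      Mw <- ws[[i]] - tf[[i]] * sum(h * ws[[i]])
      num <- num + sum(M1 * Mw); den <- den + sum(M1^2)
    }
    a <- num / den
    sum(vapply(seq_along(wide), function(i) {
      b <- sum((ws[[i]] - a) * tf[[i]]) / sum(tf[[i]]^2)
      sum((ws[[i]] - a - b * tf[[i]])^2)
    }, numeric(1)))
  }
  fg <- seq(0.5, 4, by = 0.005)
  sg <- vapply(fg, sse_at, numeric(1))
  f_oracle <- fg[which.min(sg)]
  expect_equal(fit$f, f_oracle, tolerance = 0.005)
  expect_lte(fit$sse, min(sg) + 1e-6)
})

test_that("duplicated records are rejected and ordering does not matter", {
  rec <- toy_records(n = 6, f = 1.5, noise_sd = 1)
  fit1 <- estimate_weight_exponent(rec)
  fit2 <- estimate_weight_exponent(rec[rev(seq_len(nrow(rec))), ])
  expect_equal(fit1$f, fit2$f, tolerance = 1e-10)
  expect_error(estimate_weight_exponent(rbind(rec, rec[1, ])),
               "duplicated")
})

test_that("weight rescaling leaves f unchanged and scales 1/f deviations", {
  rec <- toy_records(n = 12, f = 1.6, a = 20, b = runif(12, 0.1, 0.2),
                     noise_sd = 3, seed = 4)
  fit <- estimate_weight_exponent(rec)
  rec2 <- rec
  cmul <- 3.7
  rec2$weight <- rec2$weight * cmul
  rec2$start_weight <- rec2$start_weight * cmul
  fit2 <- estimate_weight_exponent(rec2)
  expect_equal(fit2$f, fit$f, tolerance = 5e-3)
  l1 <- fit_growth_lines(rec, fit$f)
  l2 <- fit_growth_lines(rec2, fit$f)   # same exponent for a clean scaling law
  expect_equal(l2$obs$dev_inv_f, l1$obs$dev_inv_f * cmul^(1 / fit$f),
               tolerance = 1e-8)
})

test_that("per-fish OLS matches the closed-form slope and interpolates", {
  ages <- c(1, 40, 80, 120, 160)
  y_lin <- 2 + 0.15 * ages
  f <- 1.7
  fit <- fit_individual_line(y_lin^f, ages, f)
  expect_equal(fit$dgc, 0.15, tolerance = 1e-10)
  expect_equal(fit$intercept, 2, tolerance = 1e-10)
  expect_equal(fit$residuals, rep(0, 5), tolerance = 1e-10)

  set.seed(2)
  w <- (2 + 0.15 * ages + rnorm(5))^f
  fit2 <- fit_individual_line(w, ages, f)
  yl <- w^(1 / f)
  slope_cf <- sum((ages - mean(ages)) * (yl - mean(yl))) /
    sum((ages - mean(ages))^2)
  expect_equal(fit2$dgc, slope_cf, tolerance = 1e-12)
  expect_error(fit_individual_line(w, rep(10, 5), f), "singular")
})

test_that("1/f residuals sum to zero for every fish (machine precision)", {
  lines <- fit_growth_lines(small_sim$records, small_cfg$true_f)
  sums <- tapply(lines$obs$dev_inv_f, lines$obs$fish_id, sum)
  expect_lt(max(abs(sums)), 1e-9)
})

test_that("deviations follow the hand-computed values on each scale", {
  # hand case: observed 100 g against expected linearised weight 12, f = 2
  fits <- structure(list(
    fish = data.frame(fish_id = "H1"),
    obs = data.frame(fish_id = "H1", age = 100, weight = 100,
                     w_exp_lin = 12, dev_inv_f = sqrt(100) - 12,
                     w_lin = sqrt(100)),
    f = 2, excluded = character(0)), class = "growth_line_fits")
  expect_equal(compute_deviations(fits, "observed")$deviation, 100 - 144)
  expect_equal(compute_deviations(fits, "cubic")$deviation,
               100^(1 / 3) - 144^(1 / 3))
  expect_equal(compute_deviations(fits, "inv_f")$deviation, 10 - 12)
  # non-positive expected weight is a domain error off the 1/f scale
  fits$obs$w_exp_lin <- -1
  expect_error(compute_deviations(fits, "observed"), "non-positive")
  expect_silent(compute_deviations(fits, "inv_f"))

  # perfect-fit fish: all three scales give zero deviations
  rec0 <- toy_records(n = 3, f = 2, a = 0.5, b = 0.11, obs_scale = FALSE)
  l0 <- fit_growth_lines(rec0, 2)
  for (sc in c("inv_f", "observed", "cubic"))
    expect_lt(max(abs(compute_deviations(l0, sc)$deviation)), 1e-8)
})

test_that("heteroscedasticity is flat on the 1/f scale, not in grams", {
  lines <- fit_growth_lines(small_sim$records, small_cfg$true_f)
  r_inv <- heteroscedasticity_profile(compute_deviations(lines, "inv_f"))
  r_obs <- heteroscedasticity_profile(compute_deviations(lines, "observed"))
  expect_gt(r_obs$ratio, r_inv$ratio)
  expect_gt(r_obs$ratio, 5)   # gram-scale spread grows strongly with size

  # hand-checked SDs on a small table
  toy <- data.frame(fish_id = rep(c("A", "B", "C"), each = 2),
                    age = rep(c(1, 2), 3),
                    deviation = c(1, 4, 2, 6, 3, 8))
  pr <- heteroscedasticity_profile(toy)
  expect_equal(pr$profile$sd, c(sd(c(1, 2, 3)), sd(c(4, 6, 8))))
  expect_equal(pr$ratio, 2)

  # homoscedastic input: ratio near 1
  set.seed(5)
  hom <- data.frame(fish_id = rep(1:200, each = 3),
                    age = rep(c(1, 2, 3), 200),
                    deviation = rnorm(600))
  expect_lt(heteroscedasticity_profile(hom)$ratio, 1.35)
})

test_that("linear vs quadratic comparison detects curvature and its absence", {
  rec <- toy_records(n = 8, f = 2, a = 1, b = runif(8, 0.1, 0.2),
                     obs_scale = FALSE, seed = 6)
  cmpl <- compare_linear_quadratic(rec, 2)
  expect_equal(cmpl$quad_coef, 0, tolerance = 1e-10)
  expect_equal(cmpl$p_value, 1)

  # inject known curvature on the 1/f scale
  set.seed(7)
  ages <- c(1, 55, 104, 167, 217)
  curv <- 0.001
  rows <- lapply(1:40, function(i) {
    lin <- 2 + runif(1, 0.1, 0.2) * ages + curv * ages^2 + rnorm(5, 0, 0.05)
    data.frame(fish_id = sprintf("Q%02d", i), pond = "aerated", hapa = 1,
               sex = "male", start_weight = lin[1]^2, age = ages,
               weight = lin^2)
  })
  cmpq <- compare_linear_quadratic(do.call(rbind, rows), 2)
  expect_lt(abs(cmpq$quad_coef - curv), 0.1 * curv)
  expect_lt(cmpq$p_value, 1e-6)
})
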
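#' Estimate the overall weight exponent f
#'
#' Fits the allometric growth model `W_it = a + b_i * t^f` with a shared
#' intercept `a`, per-fish slopes `b_i` and one overall exponent `f`, by
#' minimising the pooled sum of squares `sum (W_it - a - b_i t^f)^2`.  For a
#' fixed exponent both the intercept and all slopes are profiled out in
#' closed form (the model is linear in them), so the outer optimisation is a
#' bounded one-dimensional search over `f`.  A coarse grid of the profiled
#' SSE over the `f` interval is evaluated first; it serves as a
#' multi-start / unimodality diagnostic and is kept in the returned object.
#'
#' Fish with fewer than three retained (age, weight) pairs are excluded and
#' reported; duplicated fish ids are rejected.
#'
#' @param records Long-format weight records, see [read_weight_records()].
#' @param f_bounds Search interval for the exponent (default 0.2 to 4).
#' @param grid_step Step of the coarse diagnostic grid over `f`.
#' @param shared_slope If `TRUE`, fit a single slope `b` shared by all fish
#'   instead of per-fish slopes (an alternative reading of the model; the
#'   per-fish default matches the subscripting of the growth equation).
#' @param tol Convergence tolerance of the one-dimensional optimiser.
#'
#' @return An object of class `growth_exponent_fit` with elements `f`, `a`,
#'   `b` (named per-fish slopes), `sse`, `converged`, `at_bound`, `n_fish`,
#'   `n_obs`, `grid` (data frame of f and profiled SSE), and `excluded`
#'   (fish ids dropped for having < 3 records).
#' @export
estimate_weight_exponent <- function(records, f_bounds = c(0.2, 4),
                                     grid_step = 0.1, shared_slope = FALSE,
                                     tol = 1e-9) {
  records <- validate_weight_records(records)
  if (anyDuplicated(paste(records$fish_id, records$age)))
    stop("duplicated fish/age records detected; remove duplicates first",
         call. = FALSE)
  fl <- records_by_fish(records, min_obs = 3L)
  excluded <- setdiff(unique(records$fish_id), names(fl))
  if (length(fl) < 2L)
    stop("need at least 2 fish with >= 3 observations each", call. = FALSE)

  ages <- lapply(fl, `[[`, "ages")
  wts <- lapply(fl, `[[`, "weights")
  n_obs <- sum(lengths(wts))

  # Profiled SSE: for fixed f the model is linear in (a, {b_i}).  Project
  # each fish's weights off its own t^f column, then solve the remaining
  # one-parameter LS problem for the shared intercept.
  profile_f <- function(f) {
    num <- 0; den <- 0; pieces <- vector("list", length(fl))
    for (i in seq_along(fl)) {
      tf <- ages[[i]]^f
      w <- wts[[i]]
      stf <- sum(tf * tf)
      if (shared_slope) {
        pieces[[i]] <- list(tf = tf, w = w, stf = stf)
        next
      }
      # residual-maker applied to w and to the 1-vector
      h <- tf / stf
      Mw <- w - tf * sum(h * w)
      M1 <- 1 - tf * sum(h)
      num <- num + sum(M1 * Mw)
      den <- den + sum(M1 * M1)
      pieces[[i]] <- list(tf = tf, w = w, stf = stf)
    }
    if (shared_slope) {
      tfa <- unlist(lapply(pieces, `[[`, "tf"))
      wa <- unlist(lapply(pieces, `[[`, "w"))
      Xm <- cbind(1, tfa)
      cf <- stats::lm.fit(Xm, wa)$coefficients
      a <- cf[1]
      b <- rep(cf[2], length(fl))
      sse <- sum((wa - Xm %*% cf)^2)
    } else {
      a <- if (den > 0) num / den else 0
      b <- numeric(length(fl))
      sse <- 0
      for (i in seq_along(fl)) {
        tf <- pieces[[i]]$tf; w <- pieces[[i]]$w
        b[i] <- sum((w - a) * tf) / pieces[[i]]$stf
        sse <- sse + sum((w - a - b[i] * tf)^2)
      }
    }
    list(sse = sse, a = a, b = b)
  }

  fgrid <- seq(f_bounds[1], f_bounds[2], by = grid_step)
  sse_grid <- vapply(fgrid, function(f) profile_f(f)$sse, numeric(1))
  f0 <- fgrid[which.min(sse_grid)]
  lo <- max(f_bounds[1], f0 - grid_step)
  hi <- min(f_bounds[2], f0 + grid_step)
  opt <- stats::optimize(function(f) profile_f(f)$sse,
                         lower = lo, upper = hi, tol = tol)
  f_hat <- opt$minimum
  at_bound <- min(f_hat - f_bounds[1], f_bounds[2] - f_hat) < 1e-3
  if (at_bound)
    warning("estimated weight exponent is pinned at a search bound",
            call. = FALSE)
  prof <- profile_f(f_hat)
  b <- prof$b
  names(b) <- names(fl)

  structure(list(f = f_hat, a = unname(prof$a), b = b, sse = prof$sse,
                 converged = TRUE, at_bound = at_bound,
                 n_fish = length(fl), n_obs = n_obs,
                 grid = data.frame(f = fgrid, sse = sse_grid),
                 excluded = excluded, shared_slope = shared_slope),
            class = "growth_exponent_fit")
}

#' @export
print.growth_exponent_fit <- function(x, ...) {
  cat("Allometric growth fit  W = a + b_i * t^f\n")
  cat(sprintf("  f = %.4f   a = %.4f   SSE = %.4g\n", x$f, x$a, x$sse))
  cat(sprintf("  %d fish, %d observations%s\n", x$n_fish, x$n_obs,
              if (length(x$excluded))
                sprintf(" (%d fish excluded)", length(x$excluded)) else ""))
  invisible(x)
}

#' @export
coef.growth_exponent_fit <- function(object, ...) {
  c(f = object$f, a = object$a)
}

#' @export
summary.growth_exponent_fit <- function(object, ...) {
  out <- list(f = object$f, a = object$a, sse = object$sse,
              n_fish = object$n_fish, n_obs = object$n_obs,
              b_summary = summary(object$b), at_bound = object$at_bound,
              grid_unimodal = is_unimodal(object$grid$sse))
  class(out) <- "summary.growth_exponent_fit"
  out
}

#' @export
print.summary.growth_exponent_fit <- function(x, ...) {
  cat(sprintf("Weight exponent f = %.4f (shared intercept a = %.4f)\n",
              x$f, x$a))
  cat(sprintf("SSE %.4g over %d fish / %d observations\n",
              x$sse, x$n_fish, x$n_obs))
  cat("Per-fish slopes b_i:\n"); print(x$b_summary)
  cat(sprintf("Profiled SSE grid unimodal: %s;  at bound: %s\n",
              x$grid_unimodal, x$at_bound))
  invisible(x)
}

#' @export
plot.growth_exponent_fit <- function(x, ...) {
  graphics::plot(x$grid$f, x$grid$sse, type = "l", xlab = "exponent f",
                 ylab = "profiled SSE", main = "Profile of the weight exponent",
                 ...)
  graphics::abline(v = x$f, lty = 2)
  invisible(x)
}

# TRUE when a sequence decreases to a single minimum then increases
# (allowing flat steps): no local maximum in the interior.
is_unimodal <- function(s) {
  d <- sign(diff(s))
  d <- d[d != 0]
  all(diff(d) >= 0)
}
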
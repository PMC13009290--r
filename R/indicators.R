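#' Individual log-variance resilience indicator
#'
#' The variance (denominator n - 1) of one fish's deviations from its own
#' fitted growth line, on the 1/f scale, transformed with the natural
#' logarithm.  A lower value means more constant growth and is read as
#' higher resilience.  Fish whose deviation variance is numerically zero
#' (below `tol`) are flagged degenerate and get a missing value rather than
#' -Inf, so downstream mixed models stay well posed.
#'
#' @param deviations Numeric vector of one fish's deviations (>= 3 values).
#' @param tol Degeneracy threshold on the variance.
#' @return The log variance (scalar), `NA` when degenerate, with attribute
#'   `"var_dev"` carrying the untransformed variance.
#' @export
lnvar_ind <- function(deviations, tol = 1e-12) {
  deviations <- deviations[is.finite(deviations)]
  if (length(deviations) < 3L)
    stop("need at least 3 deviations", call. = FALSE)
  v <- stats::var(deviations)
  out <- if (v < tol) NA_real_ else log(v)
  attr(out, "var_dev") <- v
  out
}

#' Cohort log-variance resilience indicator
#'
#' The cohort counterpart of [lnvar_ind()]: the expected performance is the
#' cohort mean weight, where a cohort is the group of fish sharing nursery
#' hapa, sex and grow-out pond.  At each measurement age the deviation of a
#' fish is standardised by the cohort's weight standard deviation at that
#' age, and the indicator is the log of the per-fish variance of these
#' standardised deviations over time.  Standardisation keeps ages with very
#' different weight spreads comparable; a raw-gram mode is available for
#' comparison.
#'
#' Cohort-age cells with fewer fish than `cohort_floor` are skipped (the
#' affected fish get a missing value and the cohort is reported).
#'
#' @inheritParams estimate_weight_exponent
#' @param cohort_floor Minimum fish per cohort-age cell (default 5).
#' @param standardize Divide deviations by the cohort SD at each age
#'   (default `TRUE`).
#' @param return_deviations Attach the per-observation (standardised)
#'   deviations as attribute `"deviations"`.
#' @return A data frame with one row per fish: `fish_id`, `pond`, `hapa`,
#'   `sex`, `lnvar_coh`, `n_used` (ages entering the variance).
#' @export
lnvar_coh <- function(records, cohort_floor = 5L, standardize = TRUE,
                      return_deviations = FALSE) {
  records <- validate_weight_records(records)
  key <- interaction(records$pond, records$hapa, records$sex,
                     records$age, drop = TRUE)
  mu <- stats::ave(records$weight, key)
  sdv <- stats::ave(records$weight, key,
                    FUN = function(x) rep(stats::sd(x), length(x)))
  nc <- stats::ave(records$weight, key, FUN = length)
  ok <- nc >= cohort_floor & is.finite(sdv) & sdv > 0
  if (any(!ok)) {
    bad <- unique(key[!ok])
    warning(sprintf("%d cohort-age cells below the floor of %d fish: %s",
                    length(bad), cohort_floor,
                    paste(utils::head(as.character(bad), 5), collapse = ", ")),
            call. = FALSE)
  }
  z <- (records$weight - mu) / if (standardize) sdv else 1
  z[!ok] <- NA_real_

  spl <- split(z, records$fish_id)
  lv <- vapply(spl, function(zz) {
    zz <- zz[is.finite(zz)]
    if (length(zz) < 3L) return(NA_real_)
    v <- stats::var(zz)
    if (v < 1e-12) NA_real_ else log(v)
  }, numeric(1))
  n_used <- vapply(spl, function(zz) sum(is.finite(zz)), integer(1))

  cov <- fish_covariates(records)
  out <- cov[match(names(spl), cov$fish_id),
             c("fish_id", "pond", "hapa", "sex")]
  out$lnvar_coh <- unname(lv)
  out$n_used <- unname(n_used)
  rownames(out) <- NULL
  if (return_deviations)
    attr(out, "deviations") <- data.frame(
      fish_id = records$fish_id, age = records$age,
      cohort = as.character(key), z = z, stringsAsFactors = FALSE)
  out
}

#' Per-fish resilience and growth trait table
#'
#' Combines the fitted growth lines with the weight records into the trait
#' table used for genetic analysis: harvest weight (`w5`, the weight at the
#' final measurement age), daily growth coefficient (`dgc`), the deviation
#' variance (`var_dev`) and its log (`lnvar_ind`), and the cohort indicator
#' (`lnvar_coh`).
#'
#' @inheritParams estimate_weight_exponent
#' @param fits A `growth_line_fits` object from [fit_growth_lines()].
#' @inheritParams lnvar_coh
#' @return A data frame with one row per fitted fish.
#' @export
resilience_table <- function(records, fits, cohort_floor = 5L,
                             standardize = TRUE) {
  stopifnot(inherits(fits, "growth_line_fits"))
  records <- validate_weight_records(records)
  fish <- fits$fish

  harvest_age <- max(records$age)
  hv <- records[records$age == harvest_age, c("fish_id", "weight")]
  fish$w5 <- hv$weight[match(fish$fish_id, hv$fish_id)]

  dev <- split(fits$obs$dev_inv_f, fits$obs$fish_id)[fish$fish_id]
  lv <- lapply(dev, lnvar_ind)
  fish$var_dev <- vapply(lv, attr, numeric(1), "var_dev")
  fish$lnvar_ind <- vapply(lv, as.numeric, numeric(1))
  n_degen <- sum(is.na(fish$lnvar_ind))
  if (n_degen)
    message(n_degen, " fish with degenerate (zero) deviation variance")

  coh <- lnvar_coh(records, cohort_floor = cohort_floor,
                   standardize = standardize)
  fish$lnvar_coh <- coh$lnvar_coh[match(fish$fish_id, coh$fish_id)]
  fish
}

#' Descriptive statistics with a two-group Welch test
#'
#' Mean, SD, min, max and coefficient of variation of a trait per group
#' (typically per pond), plus the two-sided Welch t-test contrasting the
#' two groups.
#'
#' @param values Numeric trait values.
#' @param group Grouping vector (two levels for the t-test).
#' @return An object of class `descriptive_stats`: a list with `table`
#'   (one row per group) and, when there are exactly two groups, `t_test`
#'   (statistic, df, p_value).
#' @export
descriptive_stats <- function(values, group) {
  ok <- is.finite(values)
  values <- values[ok]; group <- factor(group[ok])
  spl <- split(values, group)
  if (any(lengths(spl) < 2L))
    stop("need at least 2 values per group", call. = FALSE)
  tab <- data.frame(
    group = names(spl),
    n = lengths(spl),
    mean = vapply(spl, mean, numeric(1)),
    sd = vapply(spl, stats::sd, numeric(1)),
    min = vapply(spl, min, numeric(1)),
    max = vapply(spl, max, numeric(1)))
  tab$cv <- ifelse(tab$mean == 0, NA_real_, tab$sd / abs(tab$mean))
  rownames(tab) <- NULL
  tt <- NULL
  if (nlevels(group) == 2L) {
    ht <- stats::t.test(spl[[1]], spl[[2]])
    tt <- list(statistic = unname(ht$statistic), df = unname(ht$parameter),
               p_value = ht$p.value)
  }
  structure(list(table = tab, t_test = tt), class = "descriptive_stats")
}

#' @export
print.descriptive_stats <- function(x, ...) {
  print(x$table, row.names = FALSE, digits = 4)
  if (!is.null(x$t_test))
    cat(sprintf("Welch t = %.3f (df %.1f), p = %.3g\n",
                x$t_test$statistic, x$t_test$df, x$t_test$p_value))
  invisible(x)
}

#' Trait-by-pond descriptive summary
#'
#' Applies [descriptive_stats()] to each of the four analysis traits of a
#' [resilience_table()], contrasting ponds.
#'
#' @param restab A resilience table.
#' @param traits Trait columns to summarise.
#' @return A data frame with one row per trait and pond, including the
#'   Welch p-value of the pond contrast.
#' @export
summarize_traits <- function(restab,
                             traits = c("w5", "dgc", "lnvar_ind", "lnvar_coh")) {
  out <- lapply(traits, function(tr) {
    ds <- descriptive_stats(restab[[tr]], restab$pond)
    cbind(trait = tr, ds$table,
          p_pond = if (is.null(ds$t_test)) NA_real_ else ds$t_test$p_value)
  })
  do.call(rbind, out)
}
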
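#' Build response and fixed-effect design for the animal model
#'
#' From a [resilience_table()] builds the response vector for one trait and
#' the full-rank fixed-effect design: overall mean, nursery hapa (CAGE, up
#' to 4 levels), sex (up to 3 levels), and — for harvest weight only, by
#' default — the start-weight covariate.  Reference-level coding is used;
#' factors with a single observed level collapse into the intercept.  Rows
#' with a missing response or covariate are dropped and reported; fish
#' absent from the relationship matrix raise an error listing the ids.
#'
#' @param data A resilience table (or any data frame with `fish_id`,
#'   `hapa`, `sex`, `start_weight` and the trait column).
#' @param trait Name of the response column (e.g. `"lnvar_ind"`, `"dgc"`,
#'   `"w5"`, `"lnvar_coh"`).
#' @param grm Optional `relationship_matrix` used to check id coverage.
#' @param covariate_sw Include the start-weight covariate (default: only
#'   for `"w5"`).
#' @return A list with `y` (named by fish id), `X` (full-rank design),
#'   `ids`, and `n_dropped`.
#' @export
build_design <- function(data, trait, grm = NULL,
                         covariate_sw = identical(trait, "w5")) {
  stopifnot(trait %in% names(data))
  y <- data[[trait]]
  keep <- is.finite(y)
  if (covariate_sw) keep <- keep & is.finite(data$start_weight)
  n_dropped <- sum(!keep)
  if (n_dropped)
    message(n_dropped, " rows dropped (missing response or covariate) for ",
            trait)
  d <- data[keep, , drop = FALSE]
  y <- y[keep]

  terms <- list()
  for (v in c("hapa", "sex")) {
    fv <- factor(d[[v]])
    if (nlevels(fv) >= 2L) terms[[v]] <- fv
  }
  if (length(terms)) {
    df <- as.data.frame(terms)
    fml <- stats::as.formula(paste("~", paste(names(terms), collapse = " + ")))
    X <- stats::model.matrix(fml, data = df)
  } else {
    X <- matrix(1, nrow(d), 1L, dimnames = list(NULL, "(Intercept)"))
  }
  if (covariate_sw) X <- cbind(X, start_weight = d$start_weight)

  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient fixed design; aliased terms: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  ids <- as.character(d$fish_id)
  if (!is.null(grm)) {
    gids <- if (inherits(grm, "relationship_matrix")) grm$ids else
      rownames(grm)
    missing_ids <- setdiff(ids, gids)
    if (length(missing_ids))
      stop("fish absent from the relationship matrix: ",
           paste(utils::head(missing_ids, 5), collapse = ", "),
           if (length(missing_ids) > 5) " ..." else "", call. = FALSE)
  }
  names(y) <- ids
  list(y = y, X = X, ids = ids, n_dropped = n_dropped)
}
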
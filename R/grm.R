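#' Genomic relationship matrix (VanRaden method 2)
#'
#' Builds the marker-wise standardised genomic relationship matrix from a
#' fish x SNP dosage matrix:
#' `G_ij = (1/m) * sum_k (x_ik - 2 p_k)(x_jk - 2 p_k) / (2 p_k (1 - p_k))`
#' over the m retained SNPs, with allele frequencies `p_k` estimated from
#' the genotyped sample.  SNPs below the minor-allele-frequency threshold
#' or without variation are dropped; missing dosages are mean-imputed per
#' SNP.  The matrix is blended with the identity,
#' `(1 - blend) G + blend I`, which guarantees positive definiteness for
#' REML.
#'
#' @param dosage Fish x SNP matrix of 0/1/2 dosages (NA allowed), rownames
#'   are fish ids.
#' @param min_maf Minimum minor allele frequency (default 0.01).
#' @param blend Identity blending fraction (default 0.01).
#' @return An object of class `relationship_matrix`: list with `ids`, `G`,
#'   `blend`, `m_markers` (retained), `dropped` (filtered SNP count).
#' @export
compute_grm <- function(dosage, min_maf = 0.01, blend = 0.01) {
  dosage <- if (inherits(dosage, "sim_genotypes")) dosage$dosage else dosage
  if (nrow(dosage) < 2L) stop("need at least 2 individuals", call. = FALSE)
  ids <- rownames(dosage)
  if (is.null(ids)) ids <- sprintf("F%04d", seq_len(nrow(dosage)))
  if (anyDuplicated(ids)) stop("duplicate fish ids", call. = FALSE)

  p <- colMeans(dosage, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep <- maf >= min_maf & maf > 0
  n_drop <- sum(!keep)
  if (!any(keep))
    stop("all SNPs filtered out (MAF threshold or zero variance)",
         call. = FALSE)
  if (n_drop)
    message(n_drop, " SNPs dropped (MAF < ", min_maf, " or monomorphic)")
  Xk <- dosage[, keep, drop = FALSE]
  p <- p[keep]

  if (anyNA(Xk)) {
    for (j in which(colSums(is.na(Xk)) > 0L))
      Xk[is.na(Xk[, j]), j] <- 2 * p[j]
  }
  W <- sweep(Xk, 2L, 2 * p)
  W <- sweep(W, 2L, sqrt(2 * p * (1 - p)), "/")
  G <- tcrossprod(W) / ncol(W)
  G <- (1 - blend) * G + blend * diag(nrow(G))
  dimnames(G) <- list(ids, ids)
  structure(list(ids = ids, G = G, blend = blend,
                 m_markers = ncol(W), dropped = n_drop),
            class = "relationship_matrix")
}

#' @export
print.relationship_matrix <- function(x, ...) {
  cat(sprintf("Genomic relationship matrix: %d fish, %d markers, blend %.3g\n",
              length(x$ids), x$m_markers, x$blend))
  cat(sprintf("  mean diagonal %.4f, mean off-diagonal %.4f\n",
              mean(diag(x$G)),
              (sum(x$G) - sum(diag(x$G))) / (length(x$ids)^2 - length(x$ids))))
  invisible(x)
}

#' Write / read a relationship matrix as dense text
#'
#' The text format is a whitespace-delimited table whose first column holds
#' the fish ids and whose header repeats the ids, so the file round-trips
#' losslessly.  `format = "rds"` writes a binary cache instead.
#'
#' @param grm A `relationship_matrix`.
#' @param path Output/input path.
#' @param format `"text"` (default) or `"rds"`.
#' @return `write_grm()` returns `path` invisibly; `read_grm()` the
#'   `relationship_matrix`.
#' @export
write_grm <- function(grm, path, format = c("text", "rds")) {
  stopifnot(inherits(grm, "relationship_matrix"))
  format <- match.arg(format)
  if (format == "rds") {
    saveRDS(grm, path)
    return(invisible(path))
  }
  G <- grm$G
  dimnames(G) <- list(grm$ids, grm$ids)
  df <- data.frame(id = grm$ids, G, check.names = FALSE)
  utils::write.table(df, path, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(path)
}

#' @rdname write_grm
#' @param tol Largest tolerated asymmetry on read.
#' @export
read_grm <- function(path, format = c("text", "rds"), tol = 1e-8) {
  format <- match.arg(format)
  if (format == "rds") {
    out <- readRDS(path)
    if (!inherits(out, "relationship_matrix"))
      stop("not a relationship-matrix cache", call. = FALSE)
    return(out)
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  G <- as.matrix(df[, -1, drop = FALSE])
  if (ncol(G) != length(ids) || !identical(colnames(G), ids))
    stop("malformed relationship matrix file: id mismatch", call. = FALSE)
  if (max(abs(G - t(G))) > tol)
    stop("relationship matrix in file is asymmetric beyond tolerance",
         call. = FALSE)
  rownames(G) <- ids
  structure(list(ids = ids, G = G, blend = NA_real_,
                 m_markers = NA_integer_, dropped = NA_integer_),
            class = "relationship_matrix")
}

#' Read a plain dosage matrix file
#'
#' Reads the common "id + tab-separated 0/1/2" layout: first column fish
#' id, remaining columns SNP dosages with a header row.
#'
#' @param path File path.
#' @return Integer matrix with fish ids as rownames.
#' @export
read_dosage <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  X <- as.matrix(df[, -1, drop = FALSE])
  rownames(X) <- as.character(df[[1]])
  storage.mode(X) <- "integer"
  X
}

#' @rdname read_dosage
#' @param dosage Dosage matrix with fish-id rownames.
#' @export
write_dosage <- function(dosage, path) {
  dosage <- if (inherits(dosage, "sim_genotypes")) dosage$dosage else dosage
  df <- data.frame(id = rownames(dosage), dosage, check.names = FALSE)
  utils::write.table(df, path, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(path)
}
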
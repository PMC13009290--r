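#' Simulate founder and offspring SNP genotypes by gene dropping
#'
#' Founder (sire and dam) genotypes are drawn per SNP as binomial(2, p) with
#' p uniform over `maf_range`.  Dams are nested within sires round-robin and
#' offspring are produced by Mendelian gene dropping: each parent transmits
#' one allele per SNP, sampled at random when the parent is heterozygous.
#' Family sizes are balanced by default; `family_imbalance > 0` draws family
#' weights from a Dirichlet to mimic unequal contributions of mass spawning.
#'
#' @param config A [sim_config()] object.
#' @param seed Optional integer seed (falls back to `config$seed`).
#'
#' @return An object of class `sim_genotypes`: a list with `dosage`
#'   (offspring fish x SNP matrix of 0/1/2, rownames are fish ids), `sire`
#'   and `dam` (integer family assignments per fish), `parent_dosage`,
#'   `founder_freq`, and `dam_sire` (sire of each dam).
#' @export
simulate_genotypes <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  seed <- if (!is.null(seed)) seed else config$seed
  if (!is.null(seed)) set.seed(seed)

  m <- config$n_snps
  ns <- config$n_sires
  nd <- config$n_dams
  n <- 2L * config$n_fish_per_pond
  p <- stats::runif(m, config$maf_range[1], config$maf_range[2])

  sire_geno <- matrix(stats::rbinom(ns * m, 2L, rep(p, each = ns)), ns, m)
  dam_geno <- matrix(stats::rbinom(nd * m, 2L, rep(p, each = nd)), nd, m)

  dam_sire <- rep_len(seq_len(ns), nd)
  if (config$family_imbalance > 0) {
    w <- stats::rgamma(nd, shape = 1 / config$family_imbalance)
    dam_of <- sample.int(nd, n, replace = TRUE, prob = w / sum(w))
  } else {
    dam_of <- rep_len(seq_len(nd), n)
  }
  sire_of <- dam_sire[dam_of]

  gamete <- function(parent_geno, idx) {
    gp <- parent_geno[idx, , drop = FALSE]
    het <- gp == 1L
    g <- (gp == 2L) * 1L
    g[het] <- stats::rbinom(sum(het), 1L, 0.5)
    g
  }
  dosage <- gamete(sire_geno, sire_of) + gamete(dam_geno, dam_of)
  rownames(dosage) <- sprintf("F%04d", seq_len(n))
  colnames(dosage) <- sprintf("snp%05d", seq_len(m))

  structure(list(dosage = dosage, sire = sire_of, dam = dam_of,
                 dam_sire = dam_sire,
                 parent_dosage = rbind(sire_geno, dam_geno),
                 founder_freq = p),
            class = "sim_genotypes")
}

#' @export
print.sim_genotypes <- function(x, ...) {
  cat(sprintf("Simulated genotypes: %d offspring x %d SNPs, %d sires / %d dams\n",
              nrow(x$dosage), ncol(x$dosage),
              length(unique(x$sire)), length(unique(x$dam))))
  invisible(x)
}
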
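#' Run the full resilience analysis pipeline
#'
#' Orchestrates simulate (optional) -> growth fit -> indicators -> GRM ->
#' REML and renders the report tables: per-pond descriptive statistics,
#' univariate variance components and heritabilities per trait and pond,
#' within-pond genetic/phenotypic correlation matrices, cross-environment
#' genetic correlations, per-time deviation diagnostics on three scales,
#' and an EBV scatter across environments.  The two ponds are analysed as
#' separate datasets joined only through the relationship matrix.  Every
#' output is written as CSV (figures as SVG/PDF) into `out_dir`, together
#' with a machine-readable JSON run record (seed, configuration, stage
#' timings, estimated exponent).  On a stage failure the partial outputs
#' are moved to a `failed/` subdirectory and the error is re-thrown with
#' the stage name.
#'
#' @param config A [sim_config()]; used when `records`/`genotypes` are not
#'   supplied.
#' @param records Optional long-format weight records (else simulated).
#' @param genotypes Optional `sim_genotypes` or dosage matrix.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed controlling all randomness of the run.
#' @param scale Deviation scale for the indicator (fixed to `inv_f` for
#'   LnVar; the diagnostics cover all three scales).
#' @param cohort_floor Minimum fish per cohort-age cell.
#' @param models Character subset of
#'   `c("univariate", "within_pond", "cross_env")` selecting which REML
#'   analyses to run.
#' @param traits Trait columns analysed.
#' @param figures Write figures?
#' @return Invisibly, a list with the fitted objects and the paths of all
#'   artifacts.
#' @export
run_full_analysis <- function(config = sim_config(), records = NULL,
                              genotypes = NULL, out_dir, seed = 1L,
                              scale = "inv_f", cohort_floor = 5L,
                              models = c("univariate", "within_pond",
                                         "cross_env"),
                              traits = c("lnvar_ind", "lnvar_coh", "dgc",
                                         "w5"),
                              figures = TRUE) {
  if (length(models))
    models <- match.arg(models, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t_start <- Sys.time()
  timings <- list()
  artifacts <- character(0)
  stage <- "setup"

  on_fail <- function(e) {
    faildir <- file.path(out_dir, "failed")
    dir.create(faildir, showWarnings = FALSE)
    for (f in list.files(out_dir, full.names = TRUE)) {
      if (!dir.exists(f)) file.copy(f, faildir)
    }
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  }

  result <- tryCatch({
    timed <- function(name, expr) {
      t0 <- Sys.time()
      out <- expr
      timings[[name]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
      out
    }
    emit <- function(df, name) {
      path <- file.path(out_dir, name)
      utils::write.csv(df, path, row.names = FALSE)
      artifacts <<- c(artifacts, path)
      path
    }
    fig_dev <- function(name) {
      if (isTRUE(capabilities("cairo")[["cairo"]])) {
        path <- file.path(out_dir, paste0(name, ".svg"))
        grDevices::svg(path, width = 6, height = 4)
      } else {
        path <- file.path(out_dir, paste0(name, ".pdf"))
        grDevices::pdf(path, width = 6, height = 4)
      }
      artifacts <<- c(artifacts, path)
    }

    stage <- "simulate"
    set.seed(seed)
    if (is.null(genotypes) && is.null(records))
      genotypes <- timed("simulate_genotypes",
                         simulate_genotypes(config, seed = seed))
    if (is.null(records)) {
      sim <- timed("simulate_weights",
                   simulate_weights(config, genotypes, seed = seed + 1L))
      records <- sim$records
      emit(records, "records.csv")
    } else {
      records <- validate_weight_records(records)
    }

    stage <- "growth_fit"
    efit <- timed("estimate_weight_exponent",
                  estimate_weight_exponent(records))
    lines <- timed("fit_growth_lines", fit_growth_lines(records, efit$f))
    emit(lines$fish, "growth_fit.csv")

    stage <- "diagnostics"
    het <- lapply(c("inv_f", "observed", "cubic"), function(sc) {
      dv <- compute_deviations(lines, sc)
      pr <- heteroscedasticity_profile(dv)
      if (figures) {
        fig_dev(paste0("deviation_profile_", sc))
        plot(pr)
        grDevices::dev.off()
      }
      cbind(scale = sc, pr$profile, ratio = pr$ratio)
    })
    emit(do.call(rbind, het), "deviation_diagnostics.csv")

    stage <- "indicators"
    restab <- timed("resilience_table",
                    resilience_table(records, lines,
                                     cohort_floor = cohort_floor))
    emit(restab, "resilience.csv")
    emit(summarize_traits(restab, intersect(traits, names(restab))),
         "table_descriptives.csv")

    stage <- "grm"
    fits <- list()
    comp_rows <- list()
    cor_rows <- list()
    cross_rows <- list()
    if (!is.null(genotypes) && length(models)) {
      grm <- timed("compute_grm", compute_grm(genotypes))
      write_grm(grm, file.path(out_dir, "grm.txt"))
      artifacts <- c(artifacts, file.path(out_dir, "grm.txt"))

      ponds <- unique(restab$pond)
      designs <- list()
      for (pd in ponds) for (tr in traits) {
        d <- build_design(restab[restab$pond == pd, , drop = FALSE], tr,
                          grm = grm)
        designs[[paste(pd, tr, sep = ".")]] <- d
      }

      stage <- "reml_univariate"
      if ("univariate" %in% models) {
        for (nm in names(designs)) {
          d <- designs[[nm]]
          fit <- timed(paste0("reml_", nm),
                       reml_univariate(d$y, d$X, d$ids, grm,
                                       compute_accuracy = FALSE))
          fits[[nm]] <- fit
          comp_rows[[nm]] <- data.frame(
            pond = sub("\\..*", "", nm), trait = sub(".*\\.", "", nm),
            sigma2_a = fit$varcomp[["A11"]],
            sigma2_e = fit$varcomp[["E11"]],
            sigma2_p = fit$varcomp[["A11"]] + fit$varcomp[["E11"]],
            h2 = unname(fit$h2), h2_se = unname(fit$h2_se),
            loglik = fit$loglik)
        }
        emit(do.call(rbind, comp_rows), "table_components.csv")
      }

      stage <- "reml_within_pond"
      if ("within_pond" %in% models) {
        pairs <- utils::combn(traits, 2, simplify = FALSE)
        for (pd in ponds) for (pr in pairs) {
          d1 <- designs[[paste(pd, pr[1], sep = ".")]]
          d2 <- designs[[paste(pd, pr[2], sep = ".")]]
          fit <- reml_bivariate(d1$y, d2$y, d1$X, d2$X, d1$ids, d2$ids,
                                grm, residual_cov_free = TRUE,
                                traits = pr)
          key <- paste(pd, pr[1], pr[2], sep = ".")
          fits[[key]] <- fit
          cor_rows[[key]] <- data.frame(
            pond = pd, trait1 = pr[1], trait2 = pr[2],
            r_g = fit$r_g, r_g_se = fit$r_g_se,
            r_p = fit$r_p, r_p_se = fit$r_p_se)
        }
        emit(do.call(rbind, cor_rows), "table_correlations.csv")
      }

      stage <- "reml_cross_env"
      if ("cross_env" %in% models && length(ponds) == 2L) {
        for (tr in intersect(c("lnvar_ind", "lnvar_coh"), traits)) {
          d1 <- designs[[paste(ponds[1], tr, sep = ".")]]
          d2 <- designs[[paste(ponds[2], tr, sep = ".")]]
          fit <- reml_bivariate(d1$y, d2$y, d1$X, d2$X, d1$ids, d2$ids,
                                grm, residual_cov_free = FALSE,
                                traits = paste(tr, ponds, sep = "_"))
          fits[[paste0("cross.", tr)]] <- fit
          cross_rows[[tr]] <- data.frame(
            trait = tr, r_g = fit$r_g, r_g_se = fit$r_g_se,
            h2_1 = fit$h2[1], h2_2 = fit$h2[2])
          if (figures) {
            eb <- fit$ebv
            fig_dev(paste0("ebv_scatter_", tr))
            graphics::plot(eb[[2]], eb[[3]],
                           xlab = paste("EBV", ponds[1]),
                           ylab = paste("EBV", ponds[2]),
                           main = sprintf("%s: r_g = %.2f (se %.2f)", tr,
                                          fit$r_g, fit$r_g_se), pch = 16,
                           cex = 0.4)
            grDevices::dev.off()
          }
        }
        if (length(cross_rows))
          emit(do.call(rbind, cross_rows), "table_cross_environment.csv")
      }
    }

    stage <- "run_record"
    record <- list(
      seed = seed,
      timestamp = format(t_start, "%Y-%m-%dT%H:%M:%S"),
      r_version = as.character(getRversion()),
      package_version = as.character(utils::packageVersion("resilvar")),
      n_records = nrow(records),
      weight_exponent = efit$f,
      deviation_scale = scale,
      cohort_floor = cohort_floor,
      models = models,
      timings_sec = timings,
      artifacts = basename(artifacts))
    rr_path <- file.path(out_dir, "run_record.json")
    jsonlite::write_json(record, rr_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    artifacts <- c(artifacts, rr_path)

    list(exponent_fit = efit, line_fits = lines, resilience = restab,
         fits = fits, artifacts = artifacts, run_record = record)
  }, error = on_fail)

  invisible(result)
}
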
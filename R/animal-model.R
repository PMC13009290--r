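#' Univariate genomic animal model by AI-REML
#'
#' Fits `y = X beta + a + e` with one additive genetic effect per fish,
#' `a ~ N(0, sigma2_A * G)` for a genomic relationship matrix G and
#' `e ~ N(0, sigma2_e * I)`, by restricted maximum likelihood.  Updates use
#' the average-information algorithm on transformed parameters
#' (log variances, atanh correlations) with ridge escalation, step halving
#' and a gradient fallback, so every accepted iteration increases the REML
#' log-likelihood.  Standard errors come from the inverse average-information
#' matrix; the heritability SE uses the delta method.  Breeding values (EBV)
#' are the BLUP solutions at the converged components, with reliabilities
#' from the prediction error variance.
#'
#' @param y Named numeric response (one record per fish) or plain numeric
#'   with `ids` supplied.
#' @param X Fixed-effect design matrix (default: intercept only).
#' @param ids Fish ids aligning `y` with the relationship matrix (default
#'   `names(y)`).
#' @param grm A `relationship_matrix` (see [compute_grm()]) or a symmetric
#'   positive-definite matrix with dimnames.
#' @param start Optional starting values `c(sigma2_A, sigma2_e)`.
#' @param max_iter,tol_loglik,tol_par Convergence controls: maximum
#'   iterations, relative log-likelihood change, and largest absolute
#'   change of the working (transformed) parameters.
#' @param compute_accuracy Also compute EBV reliabilities (adds one dense
#'   matrix product).
#' @param verbose Print the iteration trace.
#'
#' @return An object of class `animal_model`; see [summary.animal_model()].
#'   Key elements: `varcomp` (named components with SEs), `h2` and `h2_se`
#'   per trait, `beta` (fixed effects), `loglik`, `trace`, `ebv`
#'   (data frame of breeding values for every fish in the GRM), `boundary`.
#' @seealso [reml_bivariate()], [heritability()], [predict_ebv()]
#' @export
reml_univariate <- function(y, X = NULL, ids = names(y), grm,
                            start = NULL, max_iter = 200L,
                            tol_loglik = 1e-8, tol_par = 1e-6,
                            compute_accuracy = TRUE, verbose = FALSE) {
  fit <- reml_engine(y_list = list(y), X_list = list(X),
                     ids_list = list(ids), grm = grm,
                     residual_cov_free = FALSE, start = start,
                     max_iter = max_iter, tol_loglik = tol_loglik,
                     tol_par = tol_par, compute_accuracy = compute_accuracy,
                     verbose = verbose, traits = "trait1")
  fit$call <- match.call()
  fit
}

#' Bivariate genomic animal model by AI-REML
#'
#' Fits two traits jointly with additive effects distributed as
#' `N(0, G (x) C)` and residuals as `N(0, I (x) R)`, where C and R are the
#' 2x2 genetic and residual covariance matrices.  Two designs are
#' supported: both traits recorded on the same fish (residual covariance
#' free), and the cross-environment design in which each fish performs in
#' one environment only, so the residual covariance is structurally zero
#' and must be constrained (`residual_cov_free = FALSE`).  Genetic and
#' phenotypic correlations are returned with delta-method standard errors,
#' and EBVs are predicted for every fish in both traits (the unobserved
#' environment's EBV flows through the genetic covariance).
#'
#' @param y1,y2 Named numeric responses (one record per fish).
#' @param X1,X2 Fixed-effect design matrices (default intercept only).
#' @param ids1,ids2 Fish ids for the two traits.
#' @param residual_cov_free Estimate the residual covariance?  Requires the
#'   two traits to share fish; disjoint recording requires `FALSE`.
#' @inheritParams reml_univariate
#' @param traits Length-2 trait labels used in printing.
#' @return An `animal_model` object (see [reml_univariate()]) whose
#'   `varcomp` holds both traits' components plus the genetic (and, when
#'   identifiable, residual) covariance, and whose `r_g`/`r_p` carry the
#'   correlations with SEs.
#' @export
reml_bivariate <- function(y1, y2, X1 = NULL, X2 = NULL,
                           ids1 = names(y1), ids2 = names(y2), grm,
                           residual_cov_free = NULL, start = NULL,
                           max_iter = 200L, tol_loglik = 1e-8,
                           tol_par = 1e-6, compute_accuracy = FALSE,
                           verbose = FALSE, traits = c("trait1", "trait2")) {
  if (is.null(ids1) || is.null(ids2))
    stop("fish ids are required for both traits", call. = FALSE)
  n_shared <- length(intersect(ids1, ids2))
  if (is.null(residual_cov_free)) residual_cov_free <- n_shared > 0L
  if (residual_cov_free && n_shared == 0L)
    stop("residual covariance is not identifiable for disjoint fish; ",
         "set residual_cov_free = FALSE", call. = FALSE)
  if (!residual_cov_free && n_shared > 0L && n_shared == length(ids1) &&
      n_shared == length(ids2))
    stop("traits observed on the same fish require residual_cov_free = TRUE",
         call. = FALSE)
  fit <- reml_engine(y_list = list(y1, y2), X_list = list(X1, X2),
                     ids_list = list(ids1, ids2), grm = grm,
                     residual_cov_free = residual_cov_free, start = start,
                     max_iter = max_iter, tol_loglik = tol_loglik,
                     tol_par = tol_par, compute_accuracy = compute_accuracy,
                     verbose = verbose, traits = traits)
  # guard against a spurious boundary optimum: when the genetic correlation
  # lands on |r| = 1 from the default start, refit once from a moderate
  # interior start and keep the higher-likelihood solution
  if (is.null(start) && !is.null(fit$r_g) && abs(fit$r_g) > 0.999) {
    vy1 <- stats::var(y1[is.finite(y1)]); vy2 <- stats::var(y2[is.finite(y2)])
    s2 <- c(0.5 * vy1, 0.5 * sign(fit$r_g) * sqrt(vy1 * vy2) * 0.5,
            0.5 * vy2, 0.5 * vy1, if (residual_cov_free) 0,
            0.5 * vy2)
    fit2 <- tryCatch(
      reml_engine(y_list = list(y1, y2), X_list = list(X1, X2),
                  ids_list = list(ids1, ids2), grm = grm,
                  residual_cov_free = residual_cov_free, start = s2,
                  max_iter = max_iter, tol_loglik = tol_loglik,
                  tol_par = tol_par, compute_accuracy = compute_accuracy,
                  verbose = verbose, traits = traits),
      error = function(e) NULL)
    if (!is.null(fit2) && fit2$loglik > fit$loglik + 1e-6) fit <- fit2
  }
  fit$call <- match.call()
  fit
}

# ---------------------------------------------------------------------------
# Engine.  Parameterisation: variances on the log scale, covariances through
# atanh-correlations, so the parameter space is unconstrained.  V is linear
# in the original components, V = sum_k theta_k * Q_k, which gives closed
# forms for the REML score and average-information matrix:
#   dl/dth_k  = -1/2 [ tr(P Q_k) - y'P Q_k P y ]
#   AI_kl     =  1/2 [ y'P Q_k P Q_l P y ]
# with P = Vi - Vi X (X'Vi X)^-1 X'Vi.
reml_engine <- function(y_list, X_list, ids_list, grm, residual_cov_free,
                        start, max_iter, tol_loglik, tol_par,
                        compute_accuracy, verbose, traits) {
  G <- if (inherits(grm, "relationship_matrix")) grm$G else grm
  gids <- if (inherits(grm, "relationship_matrix")) grm$ids else rownames(G)
  if (is.null(gids)) stop("relationship matrix needs ids", call. = FALSE)
  q <- length(y_list)

  for (t in seq_len(q)) {
    keep <- is.finite(y_list[[t]])
    if (!all(keep)) {
      y_list[[t]] <- y_list[[t]][keep]
      ids_list[[t]] <- ids_list[[t]][keep]
      if (!is.null(X_list[[t]]))
        X_list[[t]] <- X_list[[t]][keep, , drop = FALSE]
    }
    if (anyDuplicated(ids_list[[t]]))
      stop("duplicate fish ids within a trait", call. = FALSE)
    missing_ids <- setdiff(ids_list[[t]], gids)
    if (length(missing_ids))
      stop("fish absent from the relationship matrix: ",
           paste(utils::head(missing_ids, 5), collapse = ", "),
           if (length(missing_ids) > 5) " ..." else "", call. = FALSE)
    if (is.null(X_list[[t]]))
      X_list[[t]] <- matrix(1, length(y_list[[t]]), 1L,
                            dimnames = list(NULL, "(Intercept)"))
    if (is.null(colnames(X_list[[t]])))
      colnames(X_list[[t]]) <- paste0("b", seq_len(ncol(X_list[[t]])))
  }
  idx <- lapply(ids_list, match, gids)
  nt <- lengths(y_list)
  N <- sum(nt)
  off <- cumsum(c(0L, nt))[seq_len(q)]
  yall <- unlist(y_list, use.names = FALSE)
  p_t <- vapply(X_list, ncol, integer(1))
  Xall <- matrix(0, N, sum(p_t))
  cn <- character(sum(p_t))
  pc <- cumsum(c(0L, p_t))
  for (t in seq_len(q)) {
    Xall[off[t] + seq_len(nt[t]), pc[t] + seq_len(p_t[t])] <- X_list[[t]]
    cn[pc[t] + seq_len(p_t[t])] <-
      if (q == 1L) colnames(X_list[[t]])
      else paste0(traits[t], ":", colnames(X_list[[t]]))
  }
  colnames(Xall) <- cn
  if (qr(Xall)$rank < ncol(Xall))
    stop("fixed-effect design is rank deficient", call. = FALSE)

  # structure matrices
  block <- function(M, t1, t2) {
    Q <- matrix(0, N, N)
    Q[off[t1] + seq_len(nt[t1]), off[t2] + seq_len(nt[t2])] <- M
    if (t1 != t2)
      Q[off[t2] + seq_len(nt[t2]), off[t1] + seq_len(nt[t1])] <- t(M)
    Q
  }
  Qs <- list()
  par_names <- character(0)
  if (q == 1L) {
    Qs <- list(A11 = block(G[idx[[1]], idx[[1]]], 1, 1),
               E11 = diag(N))
    par_names <- c("A11", "E11")
  } else {
    Qs$A11 <- block(G[idx[[1]], idx[[1]]], 1, 1)
    Qs$A12 <- block(G[idx[[1]], idx[[2]]], 1, 2)
    Qs$A22 <- block(G[idx[[2]], idx[[2]]], 2, 2)
    Qs$E11 <- block(diag(nt[1]), 1, 1)
    if (residual_cov_free) {
      Eoff <- matrix(0, nt[1], nt[2])
      shared <- intersect(ids_list[[1]], ids_list[[2]])
      Eoff[cbind(match(shared, ids_list[[1]]),
                 match(shared, ids_list[[2]]))] <- 1
      Qs$E12 <- block(Eoff, 1, 2)
    }
    Qs$E22 <- block(diag(nt[2]), 2, 2)
    par_names <- names(Qs)
  }
  k <- length(Qs)

  # phi <-> theta maps
  has_e12 <- "E12" %in% par_names
  theta_of_phi <- function(phi) {
    if (q == 1L) return(c(A11 = exp(phi[1]), E11 = exp(phi[2])))
    sA1 <- exp(phi[1]); sA2 <- exp(phi[2]); rA <- tanh(phi[3])
    sE1 <- exp(phi[4]); sE2 <- exp(phi[5])
    th <- c(A11 = sA1, A12 = rA * sqrt(sA1 * sA2), A22 = sA2,
            E11 = sE1, E22 = sE2)
    if (has_e12) {
      rE <- tanh(phi[6])
      th <- c(th[1:4], E12 = rE * sqrt(sE1 * sE2), E22 = sE2)
    }
    th[par_names]
  }
  jac <- function(phi) {
    # d theta / d phi
    if (q == 1L) return(diag(exp(phi), 2))
    sA1 <- exp(phi[1]); sA2 <- exp(phi[2]); zA <- phi[3]
    sE1 <- exp(phi[4]); sE2 <- exp(phi[5])
    rA <- tanh(zA); gA <- sqrt(sA1 * sA2)
    J <- matrix(0, k, length(phi),
                dimnames = list(par_names, NULL))
    J["A11", 1] <- sA1
    J["A22", 2] <- sA2
    J["A12", 1] <- 0.5 * rA * gA
    J["A12", 2] <- 0.5 * rA * gA
    J["A12", 3] <- (1 - rA^2) * gA
    J["E11", 4] <- sE1
    J["E22", 5] <- sE2
    if (has_e12) {
      zE <- phi[6]; rE <- tanh(zE); gE <- sqrt(sE1 * sE2)
      J["E12", 4] <- 0.5 * rE * gE
      J["E12", 5] <- 0.5 * rE * gE
      J["E12", 6] <- (1 - rE^2) * gE
    }
    J
  }

  build_V <- function(theta) {
    V <- theta[1] * Qs[[1]]
    for (j in 2:k) V <- V + theta[j] * Qs[[j]]
    V
  }
  loglik_only <- function(theta) {
    V <- build_V(theta)
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    Viy <- backsolve(ch, forwardsolve(t(ch), yall))
    ViX <- backsolve(ch, forwardsolve(t(ch), Xall))
    XtViX <- crossprod(Xall, ViX)
    cX <- tryCatch(chol(XtViX), error = function(e) NULL)
    if (is.null(cX)) return(-Inf)
    beta <- backsolve(cX, forwardsolve(t(cX), crossprod(Xall, Viy)))
    yPy <- sum(yall * Viy) - sum(crossprod(Xall, Viy) * beta)
    -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(cX))) + yPy)
  }

  # starting values
  vres <- vapply(seq_len(q), function(t)
    stats::var(stats::lm.fit(X_list[[t]], y_list[[t]])$residuals),
    numeric(1))
  z0 <- 0
  if (q == 2L && has_e12) {
    # warm-start correlations at (a damped) raw residual correlation of
    # the shared fish
    shared0 <- intersect(ids_list[[1]], ids_list[[2]])
    if (length(shared0) > 10L) {
      r1 <- stats::lm.fit(X_list[[1]], y_list[[1]])$residuals
      r2 <- stats::lm.fit(X_list[[2]], y_list[[2]])$residuals
      r0 <- stats::cor(r1[match(shared0, ids_list[[1]])],
                       r2[match(shared0, ids_list[[2]])])
      if (is.finite(r0)) z0 <- atanh(max(min(0.7 * r0, 0.9), -0.9))
    }
  }
  phi <- if (q == 1L) {
    log(pmax(c(0.5, 0.5) * vres[1], 1e-10))
  } else {
    c(log(pmax(0.5 * vres[1], 1e-10)),
      log(pmax(0.5 * vres[2], 1e-10)), z0,
      log(pmax(0.5 * vres[1], 1e-10)),
      log(pmax(0.5 * vres[2], 1e-10)),
      if (has_e12) z0)
  }
  if (!is.null(start)) {
    if (q == 1L) {
      phi <- log(pmax(start, 1e-10))
    } else {
      # start = c(A11, A12, A22, E11, [E12,] E22) on the component scale
      th <- start
      if (length(th) != k)
        stop(sprintf("bivariate start must have %d components", k),
             call. = FALSE)
      names(th) <- par_names
      zA <- atanh(min(max(th[["A12"]] /
                            sqrt(th[["A11"]] * th[["A22"]]), -0.999), 0.999))
      zE <- if (has_e12)
        atanh(min(max(th[["E12"]] /
                        sqrt(th[["E11"]] * th[["E22"]]), -0.999), 0.999))
      phi <- c(log(max(th[["A11"]], 1e-12)), log(max(th[["A22"]], 1e-12)),
               zA, log(max(th[["E11"]], 1e-12)),
               log(max(th[["E22"]], 1e-12)), zE)
    }
  }
  phi_cap <- c(rep(log(1e-8 * max(vres)), length(phi)))
  z_idx <- if (q == 2L) c(3L, if (has_e12) 6L) else integer(0)
  clamp <- function(phi) {
    v_idx <- setdiff(seq_along(phi), z_idx)
    phi[v_idx] <- pmax(phi[v_idx], phi_cap[v_idx])
    phi[z_idx] <- pmin(pmax(phi[z_idx], -6), 6)
    phi
  }
  phi <- clamp(phi)

  trace <- data.frame(iter = integer(0), loglik = numeric(0),
                      step = character(0))
  ll <- loglik_only(theta_of_phi(phi))
  converged <- FALSE
  theta <- theta_of_phi(phi)
  AI_theta <- NULL

  for (iter in seq_len(max_iter)) {
    theta <- theta_of_phi(phi)
    V <- build_V(theta)
    ch <- chol(V)
    Vi <- chol2inv(ch)
    W <- Vi %*% Xall
    XtViX <- crossprod(Xall, W)
    cX <- chol(XtViX)
    Bmat <- chol2inv(cX)
    P <- Vi - W %*% Bmat %*% t(W)
    Py <- drop(P %*% yall)
    ll <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(cX))) +
                  sum(yall * Py))

    Fm <- vapply(Qs, function(Q) drop(Q %*% Py), numeric(N))
    score <- vapply(seq_len(k), function(j)
      -0.5 * (sum(P * Qs[[j]]) - sum(Py * Fm[, j])), numeric(1))
    PF <- P %*% Fm
    AI_theta <- 0.5 * crossprod(Fm, PF)
    dimnames(AI_theta) <- list(par_names, par_names)

    J <- jac(phi)
    s_phi <- drop(crossprod(J, score))
    AI_phi <- crossprod(J, AI_theta %*% J)

    # Active set: parameters pinned at a cap with an outward gradient are
    # frozen, so boundary solutions (e.g. sigma2_A -> 0) converge cleanly.
    v_free <- setdiff(seq_along(phi), z_idx)
    pinned <- rep(FALSE, length(phi))
    pinned[v_free] <- phi[v_free] <= phi_cap[v_free] + 1e-8 &
      s_phi[v_free] < 0
    if (length(z_idx))
      pinned[z_idx] <- (phi[z_idx] <= -6 + 1e-8 & s_phi[z_idx] < 0) |
                       (phi[z_idx] >= 6 - 1e-8 & s_phi[z_idx] > 0)
    s_use <- s_phi; s_use[pinned] <- 0
    AI_use <- AI_phi
    if (any(pinned)) {
      AI_use[pinned, ] <- 0; AI_use[, pinned] <- 0
      diag(AI_use)[pinned] <- 1
    }

    # AI step, with Levenberg-Marquardt ridge escalation when the plain
    # step is not an ascent, then a gradient fallback
    accepted <- FALSE
    step_type <- "AI"
    stepsize <- 1
    ridge0 <- max(mean(diag(AI_use)), 1e-8)
    for (ridge in c(0, 1e-6, 1e-4, 1e-2, 1, 100) * ridge0) {
      delta <- tryCatch(solve(AI_use + diag(ridge, length(phi)), s_use),
                        error = function(e) NULL)
      if (is.null(delta) || !all(is.finite(delta))) next
      delta <- pmin(pmax(delta, -3), 3)
      stepsize <- 1
      for (h in 1:8) {
        phi_new <- clamp(phi + stepsize * delta)
        ll_new <- loglik_only(theta_of_phi(phi_new))
        if (is.finite(ll_new) && ll_new >= ll - 1e-10) {
          accepted <- TRUE; break
        }
        stepsize <- stepsize / 2
      }
      if (accepted) break
      step_type <- "AI-ridge"
    }
    if (!accepted) {
      # gradient-EM flavoured fallback: scaled ascent along the score
      step_type <- "grad"
      gdir <- s_use / max(abs(s_use), 1e-12)
      stepsize <- 0.1
      for (h in 1:30) {
        phi_new <- clamp(phi + stepsize * gdir)
        ll_new <- loglik_only(theta_of_phi(phi_new))
        if (is.finite(ll_new) && ll_new >= ll - 1e-10) {
          accepted <- TRUE; break
        }
        stepsize <- stepsize / 2
      }
    }
    if (!accepted) { phi_new <- phi; ll_new <- ll; delta <- s_use * 0
                     stepsize <- 1 }
    dpar <- max(abs(phi_new - phi))
    dll <- ll_new - ll
    # Newton decrement: the ascent the current step still promised; near
    # the optimum (also a boundary one) it vanishes together with dll,
    # while a merely damped step keeps it large
    pred_gain <- 0.5 * abs(sum(s_use * delta)) * stepsize
    trace <- rbind(trace, data.frame(iter = iter, loglik = ll_new,
                                     step = step_type))
    if (verbose)
      cat(sprintf("iter %3d  logLik %.6f  step %s/%g  dpar %.2e  gain %.2e\n",
                  iter, ll_new, step_type, stepsize, dpar, pred_gain))
    phi <- phi_new
    tol_here <- tol_loglik * (1 + abs(ll_new))
    if (abs(dll) < tol_here &&
        (pred_gain < tol_here || dpar < tol_par)) {
      converged <- TRUE
      ll <- ll_new
      break
    }
    ll <- ll_new
  }
  if (!converged)
    stop(sprintf(
      "REML did not converge in %d iterations (last logLik %.6f); see trace",
      max_iter, ll), call. = FALSE)

  # final quantities at the optimum
  theta <- theta_of_phi(phi)
  V <- build_V(theta)
  ch <- chol(V)
  Vi <- chol2inv(ch)
  W <- Vi %*% Xall
  XtViX <- crossprod(Xall, W)
  Bmat <- chol2inv(chol(XtViX))
  beta <- drop(Bmat %*% crossprod(W, yall))
  names(beta) <- colnames(Xall)
  se_beta <- sqrt(diag(Bmat))
  P <- Vi - W %*% Bmat %*% t(W)
  Py <- drop(P %*% yall)
  Fm <- vapply(Qs, function(Q) drop(Q %*% Py), numeric(N))
  AI_theta <- 0.5 * crossprod(Fm, P %*% Fm)
  dimnames(AI_theta) <- list(par_names, par_names)
  vcov_theta <- tryCatch(solve(AI_theta), error = function(e)
    matrix(NA_real_, k, k, dimnames = list(par_names, par_names)))
  se_theta <- sqrt(pmax(diag(vcov_theta), 0))

  out <- derive_parameters(theta, vcov_theta, q, has_e12, traits)
  boundary <- out$boundary

  # BLUP breeding values for every fish in the GRM, per trait
  n_all <- nrow(G)
  Cmat <- out$C
  ebv <- matrix(0, n_all, q)
  Cab_list <- vector("list", q)
  for (t in seq_len(q)) {
    Cab <- matrix(0, n_all, N)
    for (t2 in seq_len(q))
      Cab[, off[t2] + seq_len(nt[t2])] <-
        Cmat[t, t2] * G[, idx[[t2]], drop = FALSE]
    ebv[, t] <- Cab %*% Py
    Cab_list[[t]] <- Cab
  }
  ebv_df <- data.frame(fish_id = gids, ebv)
  names(ebv_df)[-1] <- traits[seq_len(q)]
  if (compute_accuracy) {
    for (t in seq_len(q)) {
      Cab <- Cab_list[[t]]
      pev <- Cmat[t, t] * diag(G) - rowSums((Cab %*% P) * Cab)
      rel <- 1 - pev / pmax(Cmat[t, t] * diag(G), 1e-300)
      ebv_df[[paste0("accuracy_", traits[t])]] <- sqrt(pmax(rel, 0))
    }
  }

  structure(list(traits = traits[seq_len(q)], n = nt,
                 varcomp = theta, se_varcomp = se_theta,
                 vcov_varcomp = vcov_theta, AI = AI_theta,
                 h2 = out$h2, h2_se = out$h2_se,
                 r_g = out$r_g, r_g_se = out$r_g_se,
                 r_p = out$r_p, r_p_se = out$r_p_se,
                 C = out$C, R = out$R,
                 beta = beta, se_beta = se_beta,
                 loglik = ll, trace = trace, converged = converged,
                 boundary = boundary, residual_cov_free =
                   if (q == 2L) has_e12 else NA,
                 ebv = ebv_df, ids = ids_list, call = NULL),
            class = "animal_model")
}

# Heritabilities, correlations and their delta-method SEs from the
# component vector and its asymptotic covariance.
derive_parameters <- function(theta, vcov_theta, q, has_e12, traits) {
  dm_se <- function(grad, idx) {
    Vsub <- vcov_theta[idx, idx, drop = FALSE]
    if (anyNA(Vsub)) return(NA_real_)
    sqrt(max(drop(t(grad) %*% Vsub %*% grad), 0))
  }
  if (q == 1L) {
    sA <- theta[["A11"]]; sE <- theta[["E11"]]; sP <- sA + sE
    h2 <- sA / sP
    boundary <- h2 < 1e-3 || h2 > 1 - 1e-3
    h2_se <- if (boundary) NA_real_ else
      dm_se(c(sE, -sA) / sP^2, c("A11", "E11"))
    return(list(h2 = stats::setNames(h2, traits[1]),
                h2_se = stats::setNames(h2_se, traits[1]),
                r_g = NULL, r_g_se = NULL, r_p = NULL, r_p_se = NULL,
                C = matrix(sA, 1, 1), R = matrix(sE, 1, 1),
                boundary = boundary))
  }
  sA1 <- theta[["A11"]]; sA12 <- theta[["A12"]]; sA2 <- theta[["A22"]]
  sE1 <- theta[["E11"]]; sE2 <- theta[["E22"]]
  sE12 <- if (has_e12) theta[["E12"]] else 0
  sP1 <- sA1 + sE1; sP2 <- sA2 + sE2
  h2 <- c(sA1 / sP1, sA2 / sP2)
  names(h2) <- traits
  h2_se <- c(dm_se(c(sE1, -sA1) / sP1^2, c("A11", "E11")),
             dm_se(c(sE2, -sA2) / sP2^2, c("A22", "E22")))
  names(h2_se) <- traits
  r_g <- sA12 / sqrt(sA1 * sA2)
  gr <- c(-r_g / (2 * sA1), 1 / sqrt(sA1 * sA2), -r_g / (2 * sA2))
  r_g_se <- dm_se(gr, c("A11", "A12", "A22"))
  boundary <- abs(r_g) > 1 - 1e-3 || any(h2 < 1e-3) || any(h2 > 1 - 1e-3)
  if (has_e12) {
    r_p <- (sA12 + sE12) / sqrt(sP1 * sP2)
    grp <- c(-r_p / (2 * sP1),            # A11
             1 / sqrt(sP1 * sP2),         # A12
             -r_p / (2 * sP2),            # A22
             -r_p / (2 * sP1),            # E11
             1 / sqrt(sP1 * sP2),         # E12
             -r_p / (2 * sP2))            # E22
    r_p_se <- dm_se(grp, c("A11", "A12", "A22", "E11", "E12", "E22"))
  } else {
    r_p <- NA_real_; r_p_se <- NA_real_
  }
  list(h2 = h2, h2_se = h2_se,
       r_g = r_g, r_g_se = r_g_se, r_p = r_p, r_p_se = r_p_se,
       C = matrix(c(sA1, sA12, sA12, sA2), 2, 2),
       R = matrix(c(sE1, sE12, sE12, sE2), 2, 2),
       boundary = boundary)
}

#' Heritability as a variance ratio
#'
#' `h2 = sigma2_A / sigma2_P`.  When the 2x2 covariance matrix of
#' `(sigma2_A, sigma2_P)` is supplied, the delta-method standard error is
#' returned as well.  Values above 1 are flagged invalid.
#'
#' @param sigma2_a Additive genetic variance.
#' @param sigma2_p Phenotypic variance (> 0).
#' @param vcov Optional 2x2 covariance matrix of the two estimates.
#' @return A list with `h2`, `se` (possibly NA) and `valid`.
#' @export
heritability <- function(sigma2_a, sigma2_p, vcov = NULL) {
  if (sigma2_p <= 0) stop("sigma2_p must be positive", call. = FALSE)
  h2 <- sigma2_a / sigma2_p
  se <- NA_real_
  if (!is.null(vcov)) {
    grad <- c(1 / sigma2_p, -sigma2_a / sigma2_p^2)
    se <- sqrt(max(drop(t(grad) %*% vcov %*% grad), 0))
  }
  list(h2 = h2, se = se, valid = h2 >= 0 && h2 <= 1)
}

#' Extract estimated breeding values
#'
#' Returns the BLUP breeding values computed at the converged variance
#' components: one EBV per fish in the relationship matrix and per trait
#' (for cross-environment fits the unobserved environment's EBV is
#' predicted through the genetic covariance).
#'
#' @param object A fitted `animal_model`.
#' @return Data frame with `fish_id`, one EBV column per trait, and
#'   accuracy columns when they were computed.
#' @export
predict_ebv <- function(object) {
  stopifnot(inherits(object, "animal_model"))
  object$ebv
}

#' @export
predict.animal_model <- function(object, ...) predict_ebv(object)

#' @export
print.animal_model <- function(x, ...) {
  q <- length(x$traits)
  cat(sprintf("Genomic animal model (%s), REML\n",
              if (q == 1L) "univariate" else "bivariate"))
  cat(sprintf("  traits: %s   n = %s   logLik = %.4f\n",
              paste(x$traits, collapse = ", "),
              paste(x$n, collapse = ", "), x$loglik))
  vc <- data.frame(component = names(x$varcomp),
                   estimate = unname(x$varcomp),
                   se = unname(x$se_varcomp))
  print(vc, row.names = FALSE, digits = 4)
  for (t in seq_len(q))
    cat(sprintf("  h2(%s) = %.3f (se %.3f)\n", x$traits[t], x$h2[t],
                x$h2_se[t]))
  if (q == 2L) {
    cat(sprintf("  r_g = %.3f (se %.3f)\n", x$r_g, x$r_g_se))
    if (!is.na(x$r_p))
      cat(sprintf("  r_p = %.3f (se %.3f)\n", x$r_p, x$r_p_se))
  }
  if (x$boundary)
    cat("  note: estimate at or near a parameter boundary\n")
  invisible(x)
}

#' Summary of a fitted genomic animal model
#'
#' @param object A fitted `animal_model`.
#' @param ... Unused.
#' @return The object, invisibly, after printing components, derived
#'   ratios, fixed effects and the iteration count.
#' @export
summary.animal_model <- function(object, ...) {
  print(object)
  cat("Fixed effects:\n")
  fe <- data.frame(term = names(object$beta),
                   estimate = unname(object$beta),
                   se = unname(object$se_beta))
  print(fe, row.names = FALSE, digits = 4)
  cat(sprintf("%d accepted REML iterations (%s)\n", nrow(object$trace),
              if (object$converged) "converged" else "not converged"))
  invisible(object)
}

#' @export
coef.animal_model <- function(object, ...) object$beta

#' @export
logLik.animal_model <- function(object, ...) {
  structure(object$loglik, df = length(object$varcomp),
            class = "logLik")
}

#' @export
vcov.animal_model <- function(object, ...) object$vcov_varcomp
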
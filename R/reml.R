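## ---- internal multi-trait AI-REML engine ---------------------------------
##
## Model per trait j (shared record structure across traits):
##   y_j = X b_j + Z a_j + W p_j + e_j
## with a ~ N(0, Sigma_a x K), p ~ N(0, Sigma_p x I), e ~ N(0, Sigma_e x I)
## (x = Kronecker). All REML quantities are computed through the mixed-model
## equations: the coefficient matrix C is factorized once per iteration and
## -2logL, the score and the average-information matrix are assembled from
## its inverse, so the dense phenotypic covariance V is never formed.

vech_pairs <- function(t) {
  out <- list()
  for (j in seq_len(t)) for (k in seq_len(j)) out[[length(out) + 1L]] <- c(j, k)
  out
}

sym_unit <- function(t, j, k) {
  E <- matrix(0, t, t)
  E[j, k] <- E[j, k] + 1
  if (j != k) E[k, j] <- E[k, j] + 1
  E
}

## clamp a covariance matrix to the PSD cone with eigenvalue floor
psd_project <- function(S, floor) {
  S <- (S + t(S)) / 2
  if (nrow(S) == 1L) return(matrix(max(S[1, 1], floor), 1, 1))
  e <- eigen(S, symmetric = TRUE)
  matrix(e$vectors %*% (pmax(e$values, floor) * t(e$vectors)),
         nrow(S), nrow(S))
}

aireml_fit <- function(Y, X, Z, W = NULL, K_inv = NULL, init = NULL,
                       max_iter = 100L, tol_param = 1e-8, tol_logl = 1e-9,
                       fix_covariances = FALSE, verbose = FALSE) {
  Y <- as.matrix(Y)
  n <- nrow(Y); t <- ncol(Y)
  use_pe <- !is.null(W)
  if (!is.null(K_inv) && inherits(K_inv, "rel_matrix")) K_inv <- rel_mat(K_inv)
  q <- ncol(Z)
  Kinv <- if (is.null(K_inv)) diag(q) else as.matrix(K_inv)
  if (nrow(Kinv) != q) stop("K_inv dimension does not match Z")
  chK <- tryCatch(chol(Kinv), error = function(e)
    stop("K_inv must be positive definite: ", conditionMessage(e)))
  logdetK <- -2 * sum(log(diag(chK)))      # log|K| from K^-1
  qp <- if (use_pe) ncol(W) else 0L

  ## unit-variance crossproducts, computed once
  Xd <- methods::as(Matrix::Matrix(X, sparse = TRUE), "CsparseMatrix")
  Zd <- methods::as(Matrix::Matrix(Z, sparse = TRUE), "CsparseMatrix")
  Wd <- if (use_pe) methods::as(Matrix::Matrix(W, sparse = TRUE),
                                "CsparseMatrix") else NULL
  Tlist <- if (use_pe) list(Xd, Zd, Wd) else list(Xd, Zd)
  p <- ncol(Xd)
  ntot <- p + q + qp
  Gram <- matrix(0, ntot, ntot)
  offs <- cumsum(c(0L, p, q))[seq_along(Tlist)]
  for (i in seq_along(Tlist)) for (j in seq_along(Tlist)) {
    Gram[offs[i] + seq_len(ncol(Tlist[[i]])),
         offs[j] + seq_len(ncol(Tlist[[j]]))] <-
      as.matrix(Matrix::crossprod(Tlist[[i]], Tlist[[j]]))
  }
  TY <- matrix(0, ntot, t)
  for (i in seq_along(Tlist))
    TY[offs[i] + seq_len(ncol(Tlist[[i]])), ] <-
      as.matrix(Matrix::crossprod(Tlist[[i]], Y))
  bi <- seq_len(p); ai <- p + seq_len(q)
  pi_ <- if (use_pe) p + q + seq_len(qp) else integer(0)
  idx_trait <- function(l) (l - 1L) * ntot + seq_len(ntot)

  vy <- apply(Y, 2L, var)
  floor_v <- 1e-8 * max(vy)
  if (is.null(init)) {
    init <- list(Sigma_a = diag(0.3 * vy, t),
                 Sigma_p = diag(0.2 * vy, t),
                 Sigma_e = diag(0.5 * vy, t))
  }
  if (use_pe && is.null(init$Sigma_p)) init$Sigma_p <- diag(0.2 * vy, t)
  Sa <- as.matrix(init$Sigma_a); Se <- as.matrix(init$Sigma_e)
  Sp <- if (use_pe) as.matrix(init$Sigma_p) else NULL
  if (any(diag(Sa) <= 0) || any(diag(Se) <= 0) ||
      (use_pe && any(diag(Sp) <= 0)))
    stop("initial variances must be strictly positive")

  pairs <- vech_pairs(t)
  if (fix_covariances) pairs <- Filter(function(pr) pr[1] == pr[2], pairs)
  structs <- if (use_pe) c("a", "p", "e") else c("a", "e")
  par_tab <- do.call(rbind, lapply(structs, function(s)
    data.frame(s = s, j = vapply(pairs, `[`, 0, 1),
               k = vapply(pairs, `[`, 0, 2))))
  npar <- nrow(par_tab)

  fit_from_sol <- function(solmat) {
    ## n x t fitted values from the trait-major solution matrix
    out <- matrix(0, n, t)
    for (l in seq_len(t)) {
      out[, l] <- as.numeric(Xd %*% solmat[bi, l] + Zd %*% solmat[ai, l] +
                               (if (use_pe) Wd %*% solmat[pi_, l] else 0))
    }
    out
  }

  mme_eval <- function(Sa, Sp, Se) {
    Sei <- solve(Se); Sai <- solve(Sa)
    Spi <- if (use_pe) solve(Sp) else NULL
    C <- kronecker(Sei, Gram)
    for (l in seq_len(t)) for (m in seq_len(t)) {
      C[(l - 1L) * ntot + ai, (m - 1L) * ntot + ai] <-
        C[(l - 1L) * ntot + ai, (m - 1L) * ntot + ai] + Sai[l, m] * Kinv
      if (use_pe) {
        ip <- (l - 1L) * ntot + pi_; jp <- (m - 1L) * ntot + pi_
        dg <- cbind(ip, jp)
        C[dg] <- C[dg] + Spi[l, m]
      }
    }
    ch <- tryCatch(chol(C), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    rhs <- as.numeric(TY %*% Sei)
    sol <- backsolve(ch, backsolve(ch, rhs, transpose = TRUE))
    solmat <- matrix(sol, ntot, t)
    Eres <- Y - fit_from_sol(solmat)
    Py <- Eres %*% Sei
    ypy <- sum(Y * Py)
    ldSp <- if (use_pe) determinant(Sp, logarithm = TRUE)$modulus else 0
    m2l <- n * as.numeric(determinant(Se, logarithm = TRUE)$modulus) +
      q * as.numeric(determinant(Sa, logarithm = TRUE)$modulus) +
      t * logdetK + qp * as.numeric(ldSp) +
      2 * sum(log(diag(ch))) + ypy
    list(ch = ch, sol = sol, solmat = solmat, Eres = Eres, Py = Py,
         ypy = ypy, m2l = m2l, Sei = Sei, Sai = Sai, Spi = Spi)
  }

  derivs <- function(ev, Sa, Sp, Se) {
    Cinv <- chol2inv(ev$ch)
    Py <- ev$Py
    S_a <- as.matrix(Matrix::crossprod(Zd, Py))          # q x t
    KS <- backsolve(chK, backsolve(chK, S_a, transpose = TRUE))  # K %*% S_a
    Ua <- as.matrix(Zd %*% KS)                           # n x t
    Ta <- crossprod(S_a, KS)
    if (use_pe) {
      S_p <- as.matrix(Matrix::crossprod(Wd, Py))
      Up <- as.matrix(Wd %*% S_p)
      Tp <- crossprod(S_p)
    }
    Te <- crossprod(Py)
    ## trace building blocks from the inverse coefficient matrix
    TrA <- matrix(0, t, t); TrP <- matrix(0, t, t); J <- matrix(0, t, t)
    for (l in seq_len(t)) for (m in seq_len(t)) {
      Cb <- Cinv[idx_trait(l), idx_trait(m), drop = FALSE]
      J[l, m] <- sum(Gram * Cb)
      TrA[l, m] <- sum(Kinv * Cb[ai, ai, drop = FALSE])
      if (use_pe) TrP[l, m] <- sum(diag(Cb[pi_, pi_, drop = FALSE]))
    }
    score <- numeric(npar)
    Flist <- vector("list", npar)
    for (r in seq_len(npar)) {
      j <- par_tab$j[r]; k <- par_tab$k[r]
      E <- sym_unit(t, j, k)
      if (par_tab$s[r] == "a") {
        Qm <- ev$Sai %*% E %*% ev$Sai
        trPV <- q * sum(ev$Sai * E) - sum(Qm * TrA)
        quad <- sum(E * Ta)
        Fm <- matrix(0, n, t)
        Fm[, j] <- Fm[, j] + Ua[, k]
        if (j != k) Fm[, k] <- Fm[, k] + Ua[, j]
      } else if (par_tab$s[r] == "p") {
        Qm <- ev$Spi %*% E %*% ev$Spi
        trPV <- qp * sum(ev$Spi * E) - sum(Qm * TrP)
        quad <- sum(E * Tp)
        Fm <- matrix(0, n, t)
        Fm[, j] <- Fm[, j] + Up[, k]
        if (j != k) Fm[, k] <- Fm[, k] + Up[, j]
      } else {
        Qm <- ev$Sei %*% E %*% ev$Sei
        trPV <- n * sum(ev$Sei * E) - sum(Qm * J)
        quad <- sum(E * Te)
        Fm <- matrix(0, n, t)
        Fm[, j] <- Fm[, j] + Py[, k]
        if (j != k) Fm[, k] <- Fm[, k] + Py[, j]
      }
      score[r] <- -0.5 * (trPV - quad)
      Flist[[r]] <- Fm
    }
    ## P f_r by treating each working variate as data
    PFlist <- vector("list", npar)
    for (r in seq_len(npar)) {
      Fm <- Flist[[r]]
      TF <- matrix(0, ntot, t)
      for (i in seq_along(Tlist))
        TF[offs[i] + seq_len(ncol(Tlist[[i]])), ] <-
          as.matrix(Matrix::crossprod(Tlist[[i]], Fm))
      rhs_f <- as.numeric(TF %*% ev$Sei)
      sol_f <- backsolve(ev$ch, backsolve(ev$ch, rhs_f, transpose = TRUE))
      PFlist[[r]] <- (Fm - fit_from_sol(matrix(sol_f, ntot, t))) %*% ev$Sei
    }
    AI <- matrix(0, npar, npar)
    for (r in seq_len(npar)) for (s in r:npar) {
      AI[r, s] <- AI[s, r] <- 0.5 * sum(Flist[[r]] * PFlist[[s]])
    }
    list(score = score, AI = AI, TrA = TrA, TrP = TrP, J = J, Cinv = Cinv)
  }

  em_update <- function(ev, dv) {
    ## EM-REML: expectation of the complete-data sufficient statistics,
    ## closed-form M-step; monotone and confined to the parameter space.
    ## E[u'K^-1 u | y] = u-hat'K^-1 u-hat + tr(K^-1 C^uu);
    ## E[e_j'e_k | y] = e-hat_j'e-hat_k + tr((D C^-1 D')_jk).
    Ahat <- ev$solmat[ai, , drop = FALSE]
    KiA <- Kinv %*% Ahat
    Sa_new <- (crossprod(Ahat, KiA) + dv$TrA) / q
    Sp_new <- if (use_pe) {
      Phat <- ev$solmat[pi_, , drop = FALSE]
      (crossprod(Phat) + dv$TrP) / qp
    } else NULL
    Se_new <- (crossprod(ev$Eres) + dv$J) / n
    out <- list(Sa = psd_project(Sa_new, floor_v),
                Sp = if (use_pe) psd_project(Sp_new, floor_v) else NULL,
                Se = psd_project(Se_new, floor_v))
    if (fix_covariances) {
      zero_off <- function(M) { M[row(M) != col(M)] <- 0; M }
      out$Sa <- zero_off(out$Sa); out$Se <- zero_off(out$Se)
      if (use_pe) out$Sp <- zero_off(out$Sp)
    }
    out
  }

  pack <- function(Sa, Sp, Se) {
    v <- numeric(npar)
    for (r in seq_len(npar)) {
      M <- switch(par_tab$s[r], a = Sa, p = Sp, e = Se)
      v[r] <- M[par_tab$j[r], par_tab$k[r]]
    }
    v
  }
  unpack <- function(v, Sa, Sp, Se) {
    for (r in seq_len(npar)) {
      jj <- par_tab$j[r]; kk <- par_tab$k[r]
      if (par_tab$s[r] == "a") Sa[jj, kk] <- Sa[kk, jj] <- v[r]
      else if (par_tab$s[r] == "p") Sp[jj, kk] <- Sp[kk, jj] <- v[r]
      else Se[jj, kk] <- Se[kk, jj] <- v[r]
    }
    list(Sa = Sa, Sp = Sp, Se = Se)
  }

  ev <- mme_eval(Sa, Sp, Se)
  if (is.null(ev)) stop("initial variance components give a singular system")
  traj <- data.frame(iter = 0L, minus2L = ev$m2l, step = "init")
  converged <- FALSE
  used_em <- FALSE
  stall <- 0L
  dv <- NULL
  for (iter in seq_len(max_iter)) {
    dv <- derivs(ev, Sa, Sp, Se)
    AIm <- dv$AI + diag(1e-10 * max(diag(dv$AI)) + 1e-300, npar)
    delta <- tryCatch(solve(AIm, dv$score), error = function(e) NULL)
    theta <- pack(Sa, Sp, Se)
    accepted <- FALSE
    step_used <- "ai"
    if (!is.null(delta)) {
      ## each halving re-factorises the system; past ~6 halvings the AI
      ## step is negligible and the EM fallback is the better use of a
      ## factorisation
      alpha <- 1
      for (h in seq_len(6L)) {
        cand <- unpack(theta + alpha * delta, Sa, Sp, Se)
        cand$Sa <- psd_project(cand$Sa, floor_v)
        cand$Se <- psd_project(cand$Se, floor_v)
        if (use_pe) cand$Sp <- psd_project(cand$Sp, floor_v)
        if (fix_covariances) {
          cand$Sa[upper.tri(cand$Sa)] <- cand$Sa[lower.tri(cand$Sa)] <- 0
          cand$Se[upper.tri(cand$Se)] <- cand$Se[lower.tri(cand$Se)] <- 0
          if (use_pe)
            cand$Sp[upper.tri(cand$Sp)] <- cand$Sp[lower.tri(cand$Sp)] <- 0
        }
        ev2 <- mme_eval(cand$Sa, cand$Sp, cand$Se)
        if (!is.null(ev2) && is.finite(ev2$m2l) &&
            ev2$m2l <= ev$m2l + 1e-10) {
          accepted <- TRUE
          if (h > 1L) step_used <- "ai_halved"
          break
        }
        alpha <- alpha / 2
      }
    }
    if (!accepted) {
      ## fall back to an EM-REML step (monotone, stays in the cone)
      cand <- em_update(ev, dv)
      ev2 <- mme_eval(cand$Sa, cand$Sp, cand$Se)
      if (is.null(ev2) || !is.finite(ev2$m2l))
        stop("AI-REML failed: neither AI nor EM step is admissible")
      step_used <- "em"
      used_em <- TRUE
    }
    theta_new <- pack(cand$Sa, cand$Sp, cand$Se)
    ## parameters pinned at the variance floor oscillate within the
    ## floor's magnitude; they do not count against convergence
    free <- pmax(abs(theta), abs(theta_new)) > 10 * floor_v
    rel <- if (any(free))
      max(abs(theta_new - theta)[free] /
            pmax(abs(theta), 1e-6 * max(vy))[free]) else 0
    dL <- ev$m2l - ev2$m2l
    Sa <- cand$Sa; Se <- cand$Se; if (use_pe) Sp <- cand$Sp
    ev <- ev2
    traj <- rbind(traj, data.frame(iter = iter, minus2L = ev$m2l,
                                   step = step_used))
    if (verbose)
      message(sprintf("iter %2d  -2L = %.6f  step = %s", iter, ev$m2l,
                      step_used))
    stall <- if (abs(dL) < 1e-7) stall + 1L else 0L
    ## boundary fits can crawl along the PSD cone with minute likelihood
    ## gains per EM step; a windowed criterion stops them once the total
    ## gain over the last 10 iterations is statistically nil
    window_flat <- iter >= 15L &&
      (traj$minus2L[nrow(traj) - 10L] - ev$m2l) < 0.01
    if (rel < tol_param || abs(dL) < tol_logl || stall >= 3L ||
        window_flat) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    cond <- simpleError(paste0("AI-REML did not converge in ", max_iter,
                               " iterations"))
    cond$trajectory <- traj
    stop(cond)
  }
  dv <- derivs(ev, Sa, Sp, Se)
  covtheta <- tryCatch(solve(dv$AI), error = function(e)
    matrix(NA_real_, npar, npar))
  boundary <- any(diag(Sa) <= floor_v * 1.01) ||
    any(diag(Se) <= floor_v * 1.01) ||
    (use_pe && any(diag(Sp) <= floor_v * 1.01))
  if (boundary)
    warning("a variance component converged to the boundary; ",
            "its standard error is unreliable")
  list(Sigma_a = Sa, Sigma_p = Sp, Sigma_e = Se,
       cov_theta = covtheta, par_tab = par_tab,
       loglik = -0.5 * ev$m2l, minus2L = ev$m2l,
       iterations = iter, converged = converged, boundary = boundary,
       used_em = used_em, trajectory = traj,
       solution = ev$solmat, n_records = n, n_animals = q)
}

## ---- exported interfaces --------------------------------------------------

#' Restricted log-likelihood by direct dense evaluation
#'
#' Evaluates the REML log-likelihood `-0.5 (log|V| + log|X'V^-1 X| +
#' y'Py)` (constants dropped) with `V(theta) = sum_i theta_i
#' V_parts[[i]]` formed densely. This is the reference evaluator used
#' to validate the mixed-model-equation identities the iterative
#' fitter relies on; it is deliberately capped at small n because the
#' fitter itself never forms V.
#'
#' @param y response vector.
#' @param X fixed-effect design matrix (full column rank).
#' @param V_parts list of n x n covariance structure matrices.
#' @param theta numeric vector of variance components, one per part.
#' @param max_n guard against accidentally forming a huge dense V.
#' @return the restricted log-likelihood (scalar).
#' @export
reml_loglik <- function(y, X, V_parts, theta, max_n = 2000L) {
  n <- length(y)
  if (n > max_n) stop("dense REML likelihood capped at n = ", max_n)
  X <- as.matrix(X)
  V <- Reduce(`+`, Map(function(M, th) th * as.matrix(M), V_parts,
                       as.list(theta)))
  ch <- tryCatch(chol(V), error = function(e)
    stop("V(theta) is not positive definite"))
  ldV <- 2 * sum(log(diag(ch)))
  Vi_y <- backsolve(ch, backsolve(ch, y, transpose = TRUE))
  Vi_X <- backsolve(ch, backsolve(ch, X, transpose = TRUE))
  XtViX <- crossprod(X, Vi_X)
  ldX <- as.numeric(determinant(XtViX, logarithm = TRUE)$modulus)
  beta <- solve(XtViX, crossprod(Vi_X, y))
  ypy <- sum(y * Vi_y) - sum(crossprod(X, Vi_y) * beta)
  -0.5 * (ldV + ldX + ypy)
}

#' Single-trait AI-REML for the repeatability model
#'
#' Estimates the additive genetic, permanent-environment and residual
#' variances of `y = Xb + Za + Wp + e` by average-information REML.
#' Each Newton step uses the average-information matrix (a quadratic
#' form in the data, hence positive semi-definite, so its direction is
#' an ascent direction); steps that leave the parameter space or
#' decrease the likelihood are halved and, failing that, replaced by a
#' monotone EM-REML step. Standard errors come from the inverse
#' average-information matrix at the optimum; heritability
#' `h2 = sigma_a2 / total` and repeatability
#' `r = (sigma_a2 + sigma_p2) / total` get delta-method standard
#' errors.
#'
#' @param y numeric response vector.
#' @param X,Z,W design matrices (see [build_design()]); `W = NULL`
#'   drops the permanent-environment term.
#' @param K_inv inverse relationship matrix for the animal effect
#'   (`rel_matrix` or plain matrix); `NULL` means K = I.
#' @param init optional list with `Sigma_a`, `Sigma_p`, `Sigma_e`
#'   (1 x 1 matrices or scalars); default starts at 0.3/0.2/0.5 of
#'   the phenotypic variance.
#' @param max_iter,tol_param,tol_logl iteration controls: stop when
#'   the relative parameter change or the likelihood change falls
#'   under the tolerance.
#' @param verbose print the likelihood trajectory.
#' @return `variance_components` object: estimated components with
#'   standard errors, h2 and r with SEs, convergence metadata.
#' @export
ai_reml <- function(y, X, Z, W = NULL, K_inv = NULL, init = NULL,
                    max_iter = 100L, tol_param = 1e-8, tol_logl = 1e-9,
                    verbose = FALSE) {
  if (!is.null(init) && !is.list(init))
    init <- list(Sigma_a = init[1], Sigma_p = init[2], Sigma_e = init[3])
  if (!is.null(init))
    init <- lapply(init, function(v) matrix(as.numeric(v), 1, 1))
  fit <- aireml_fit(matrix(as.numeric(y), ncol = 1L), X, Z, W, K_inv,
                    init = init, max_iter = max_iter,
                    tol_param = tol_param, tol_logl = tol_logl,
                    verbose = verbose)
  use_pe <- !is.null(W)
  comp <- c(sigma_a2 = fit$Sigma_a[1, 1],
            sigma_p2 = if (use_pe) fit$Sigma_p[1, 1] else NA_real_,
            sigma_e2 = fit$Sigma_e[1, 1])
  ord <- fit$par_tab$s                     # "a", ("p",) "e"
  se_all <- sqrt(pmax(diag(fit$cov_theta), 0))
  se <- c(sigma_a2 = se_all[ord == "a"],
          sigma_p2 = if (use_pe) se_all[ord == "p"] else NA_real_,
          sigma_e2 = se_all[ord == "e"])
  names(se) <- names(comp)
  tot <- sum(comp, na.rm = TRUE)
  h2 <- comp[["sigma_a2"]] / tot
  r <- if (use_pe) (comp[["sigma_a2"]] + comp[["sigma_p2"]]) / tot else h2
  ## delta method on (a, p, e)
  th <- comp[!is.na(comp)]
  Vth <- fit$cov_theta
  g_h2 <- if (use_pe) c(tot - th[1], -th[1], -th[1]) / tot^2 else
    c(tot - th[1], -th[1]) / tot^2
  g_r <- if (use_pe) {
    ap <- th[1] + th[2]
    c(tot - ap, tot - ap, -ap) / tot^2
  } else g_h2
  h2_se <- sqrt(max(0, t(g_h2) %*% Vth %*% g_h2))
  r_se <- sqrt(max(0, t(g_r) %*% Vth %*% g_r))
  structure(list(components = comp, se = se,
                 h2 = h2, h2_se = as.numeric(h2_se),
                 r = r, r_se = as.numeric(r_se),
                 loglik = fit$loglik, iterations = fit$iterations,
                 converged = fit$converged, boundary = fit$boundary,
                 se_reliable = !fit$boundary,
                 trajectory = fit$trajectory),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, digits = 4L, ...) {
  cat("repeatability-model variance components (AI-REML)\n")
  est <- rbind(estimate = x$components, SE = x$se)
  print(round(est, digits))
  cat(sprintf("h2 = %.4f (%.4f)   r = %.4f (%.4f)\n",
              x$h2, x$h2_se, x$r, x$r_se))
  cat(sprintf("logL = %.4f after %d iterations%s\n", x$loglik, x$iterations,
              if (x$boundary) " [boundary]" else ""))
  invisible(x)
}

#' Bivariate AI-REML: genetic covariances and correlation
#'
#' Two-trait extension of [ai_reml()] for traits sharing the record
#' structure: the additive genetic, permanent-environment and residual
#' (co)variance matrices are 2 x 2 and all nine parameters are updated
#' jointly by average-information steps with the same halving / EM
#' safeguards. The genetic correlation is
#' `cov_a / sqrt(sigma_a1^2 sigma_a2^2)` with a delta-method standard
#' error.
#'
#' @param Y numeric n x 2 matrix of the two traits' records (same
#'   rows/records as the design matrices).
#' @param X,Z,W,K_inv,init,max_iter,tol_param,tol_logl,verbose as in
#'   [ai_reml()]; `init` holds 2 x 2 matrices.
#' @param fix_covariances estimate only the variances, holding all
#'   covariances at zero (used to check marginal consistency).
#' @return `genetic_covariance_estimate`: `Sigma_a`, `Sigma_p`,
#'   `Sigma_e`, `genetic_correlation` (+ SE), per-trait h2, and
#'   convergence metadata.
#' @export
ai_reml_bivariate <- function(Y, X, Z, W = NULL, K_inv = NULL, init = NULL,
                              max_iter = 100L, tol_param = 1e-8,
                              tol_logl = 1e-9, fix_covariances = FALSE,
                              verbose = FALSE) {
  Y <- as.matrix(Y)
  if (ncol(Y) != 2L) stop("Y must have exactly two trait columns")
  fit <- aireml_fit(Y, X, Z, W, K_inv, init = init, max_iter = max_iter,
                    tol_param = tol_param, tol_logl = tol_logl,
                    fix_covariances = fix_covariances, verbose = verbose)
  Sa <- fit$Sigma_a
  rg <- Sa[1, 2] / sqrt(Sa[1, 1] * Sa[2, 2])
  ## delta method over the Sigma_a parameters (a11, a21, a22)
  rg_se <- NA_real_
  if (!fix_covariances && all(is.finite(fit$cov_theta))) {
    ia <- which(fit$par_tab$s == "a")
    g <- c(-rg / (2 * Sa[1, 1]),          # d rg / d a11
           1 / sqrt(Sa[1, 1] * Sa[2, 2]), # d rg / d a21
           -rg / (2 * Sa[2, 2]))          # d rg / d a22
    Vg <- fit$cov_theta[ia, ia]
    rg_se <- sqrt(max(0, t(g) %*% Vg %*% g))
  }
  tot <- diag(Sa) + (if (!is.null(fit$Sigma_p)) diag(fit$Sigma_p) else 0) +
    diag(fit$Sigma_e)
  structure(list(Sigma_a = Sa, Sigma_p = fit$Sigma_p,
                 Sigma_e = fit$Sigma_e,
                 genetic_correlation = rg,
                 genetic_correlation_se = as.numeric(rg_se),
                 h2 = diag(Sa) / tot,
                 loglik = fit$loglik, iterations = fit$iterations,
                 converged = fit$converged, boundary = fit$boundary,
                 trajectory = fit$trajectory),
            class = "genetic_covariance_estimate")
}

#' @export
print.genetic_covariance_estimate <- function(x, digits = 4L, ...) {
  cat("bivariate variance components (AI-REML)\n")
  cat("genetic covariance matrix:\n"); print(round(x$Sigma_a, digits))
  cat(sprintf("genetic correlation = %.4f (SE %.4f)\n",
              x$genetic_correlation, x$genetic_correlation_se))
  cat(sprintf("h2 = %s;  logL = %.4f after %d iterations\n",
              paste(round(x$h2, digits), collapse = ", "),
              x$loglik, x$iterations))
  invisible(x)
}

#' Estimate variance components from a trait dataset
#'
#' High-level wrapper around the AI-REML machinery: restricts the
#' animal effect to the phenotyped animals (the restricted likelihood
#' depends on the relationship matrix only through their submatrix, so
#' this marginalisation is exact), builds the repeatability-model
#' design, and runs single-trait or bivariate AI-REML.
#'
#' @param dataset a `trait_dataset`.
#' @param pedigree a `pedigree` object covering all record ids.
#' @param traits one or two trait column names.
#' @param use_pe include the permanent-environment term.
#' @param ... passed on to [ai_reml()] / [ai_reml_bivariate()].
#' @return a `variance_components` (one trait) or
#'   `genetic_covariance_estimate` (two traits).
#' @export
estimate_variance_components <- function(dataset, pedigree, traits,
                                         use_pe = TRUE, ...) {
  stop_if_not_pedigree(pedigree)
  dat <- as.data.frame(dataset)
  dat$id <- as.character(dat$id)
  ids <- pedigree$id[pedigree$id %in% unique(dat$id)]
  A_pp <- extract_A22(pedigree, ids)
  K_inv <- chol2inv(chol(rel_mat(A_pp)))
  des <- build_design(dat, ids, traits[1L], use_pe = use_pe)
  if (length(traits) == 1L) {
    ai_reml(des$y, des$X, des$Z, des$W, K_inv, ...)
  } else if (length(traits) == 2L) {
    Y <- as.matrix(dat[, traits])
    ai_reml_bivariate(Y, des$X, des$Z, des$W, K_inv, ...)
  } else stop("supply one or two trait names")
}
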
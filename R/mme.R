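#' Design matrices for the repeatability model
#'
#' Builds the incidence matrices of the single-trait repeatability
#' model `y = Xb + Za + Wp + e`: `X` holds an intercept, year-season
#' dummies (reference class dropped for full rank) and the centered
#' Age (months) and Intv (collection interval, days) covariates; `Z`
#' maps records to animal effects over *all* ids of the relationship
#' matrix (so unphenotyped relatives get predictions); `W` maps
#' records to per-boar permanent-environment effects. If no boar has
#' two or more records the permanent-environment term is dropped with
#' a warning (it would be confounded with the residual).
#'
#' @param dataset a `trait_dataset` (see [simulate_phenotypes()]) or
#'   any data.frame with columns `id`, `year_season`, `age_months`,
#'   `interval_days` and the trait column.
#' @param pedigree_ids ids indexing the relationship matrix, in its
#'   order.
#' @param trait name of the trait column to use as response.
#' @param use_age,use_interval include the covariates.
#' @param use_pe include the permanent-environment term.
#' @return list with sparse `X`, `Z`, `W` (`NULL` if dropped), numeric
#'   `y`, `boar_ids` (levels of W), and `centers` of the covariates.
#' @export
build_design <- function(dataset, pedigree_ids, trait,
                         use_age = TRUE, use_interval = TRUE,
                         use_pe = TRUE) {
  dataset <- as.data.frame(dataset)
  if (!trait %in% names(dataset)) stop("trait column not found: ", trait)
  pedigree_ids <- as.character(pedigree_ids)
  id <- as.character(dataset$id)
  miss <- setdiff(id, pedigree_ids)
  if (length(miss))
    stop("record ids not in the relationship index: ",
         paste(head(miss, 10L), collapse = ", "))
  y <- as.numeric(dataset[[trait]])
  if (any(!is.finite(y))) stop("non-finite trait values in ", trait)
  n <- length(y)

  ys <- factor(dataset$year_season)
  ys <- droplevels(ys)
  parts <- list(intercept = Matrix::Matrix(1, n, 1L, sparse = TRUE))
  if (nlevels(ys) > 1L) {
    Xys <- Matrix::sparse.model.matrix(~ ys)[, -1L, drop = FALSE]
    parts$year_season <- Xys
  }
  centers <- c(age_months = NA_real_, interval_days = NA_real_)
  if (use_age && sd(dataset$age_months) == 0) {
    warning("age_months is constant; covariate dropped")
    use_age <- FALSE
  }
  if (use_interval && sd(dataset$interval_days) == 0) {
    warning("interval_days is constant; covariate dropped")
    use_interval <- FALSE
  }
  if (use_age) {
    centers["age_months"] <- mean(dataset$age_months)
    parts$age <- Matrix::Matrix(dataset$age_months - centers["age_months"],
                                n, 1L, sparse = TRUE)
  }
  if (use_interval) {
    centers["interval_days"] <- mean(dataset$interval_days)
    parts$intv <- Matrix::Matrix(
      dataset$interval_days - centers["interval_days"], n, 1L, sparse = TRUE)
  }
  X <- do.call(cbind, parts)
  colnames(X) <- c("intercept",
                   if (nlevels(ys) > 1L) paste0("ys", levels(ys)[-1L]),
                   if (use_age) "age_months",
                   if (use_interval) "interval_days")

  Z <- Matrix::sparseMatrix(i = seq_len(n),
                            j = match(id, pedigree_ids),
                            x = 1, dims = c(n, length(pedigree_ids)),
                            dimnames = list(NULL, pedigree_ids))
  W <- NULL
  boar_ids <- unique(id)
  if (use_pe) {
    if (max(table(id)) < 2L) {
      warning("no boar has repeated records; dropping permanent-environment ",
              "term")
    } else {
      W <- Matrix::sparseMatrix(i = seq_len(n),
                                j = match(id, boar_ids),
                                x = 1, dims = c(n, length(boar_ids)),
                                dimnames = list(NULL, boar_ids))
    }
  }
  list(X = X, Z = Z, W = W, y = y, boar_ids = boar_ids, centers = centers)
}

#' Solve the repeatability-model mixed-model equations
#'
#' Assembles and solves Henderson's equations
#' \deqn{[X'X, X'Z, X'W; Z'X, Z'Z + K^{-1}\lambda_a, Z'W;
#'        W'X, W'Z, W'W + I\lambda_p] [b; a; p] = [X'y; Z'y; W'y]}
#' with \eqn{\lambda_a = \sigma^2_e/\sigma^2_a} and
#' \eqn{\lambda_p = \sigma^2_e/\sigma^2_p}, by sparse Cholesky
#' factorization. Prediction error variances are the animal-block
#' diagonal of the inverse coefficient matrix times \eqn{\sigma^2_e},
#' and reliabilities are \eqn{1 - PEV/\sigma^2_a}.
#'
#' @param X,Z,W,y design matrices and response from [build_design()]
#'   (`W = NULL` drops the permanent-environment term).
#' @param K_inv inverse relationship matrix: a `rel_matrix` (role
#'   `"A_inverse"` or `"H_inverse"`), or any matrix; order must match
#'   the columns of `Z`.
#' @param vc named vector or list with `sigma_a2`, `sigma_e2` and (if
#'   `W` is given) `sigma_p2`.
#' @param pev compute prediction error variances and reliabilities
#'   (one sparse solve per animal; skip for speed when not needed).
#' @return `mme_solution`: list with `fixed`, `ebv` (named, all K
#'   ids), `pe`, `pev`, `reliability`, `residuals`, `fitted`, `vc`.
#' @export
solve_mme <- function(X, Z, W, y, K_inv, vc, pev = TRUE) {
  vc <- as.list(vc)
  if (is.null(vc$sigma_a2) || is.null(vc$sigma_e2) ||
      vc$sigma_a2 <= 0 || vc$sigma_e2 <= 0)
    stop("vc must contain positive sigma_a2 and sigma_e2")
  Kiv <- if (inherits(K_inv, "rel_matrix")) rel_mat(K_inv) else K_inv
  Kiv <- methods::as(methods::as(Matrix::Matrix(Kiv), "generalMatrix"),
                     "CsparseMatrix")
  ids <- colnames(Z)
  if (nrow(Kiv) != ncol(Z))
    stop("K_inv dimension does not match Z columns")
  lam_a <- vc$sigma_e2 / vc$sigma_a2
  use_pe <- !is.null(W)
  if (use_pe && (is.null(vc$sigma_p2) || vc$sigma_p2 <= 0))
    stop("vc$sigma_p2 must be positive when W is supplied")

  XtX <- Matrix::crossprod(X);  XtZ <- Matrix::crossprod(X, Z)
  ZtZ <- Matrix::crossprod(Z)
  rhs <- c(as.numeric(Matrix::crossprod(X, y)),
           as.numeric(Matrix::crossprod(Z, y)))
  Caa <- ZtZ + lam_a * Kiv
  if (use_pe) {
    lam_p <- vc$sigma_e2 / vc$sigma_p2
    XtW <- Matrix::crossprod(X, W); ZtW <- Matrix::crossprod(Z, W)
    WtW <- Matrix::crossprod(W) + lam_p * Matrix::Diagonal(ncol(W))
    C <- rbind(cbind(XtX, XtZ, XtW),
               cbind(Matrix::t(XtZ), Caa, ZtW),
               cbind(Matrix::t(XtW), Matrix::t(ZtW), WtW))
    rhs <- c(rhs, as.numeric(Matrix::crossprod(W, y)))
  } else {
    C <- rbind(cbind(XtX, XtZ),
               cbind(Matrix::t(XtZ), Caa))
  }
  C <- Matrix::forceSymmetric(methods::as(C, "CsparseMatrix"))
  ch <- tryCatch(Matrix::Cholesky(methods::as(C, "dsCMatrix"), LDL = FALSE,
                                  perm = TRUE),
                 error = function(e)
                   stop("MME coefficient matrix is singular (rank ",
                        "deficiency in the fixed or random design): ",
                        conditionMessage(e)))
  sol <- as.numeric(Matrix::solve(ch, rhs))
  p <- ncol(X); q <- ncol(Z)
  fixed <- setNames(sol[seq_len(p)], colnames(X))
  ebv <- setNames(sol[p + seq_len(q)], ids)
  pe_hat <- if (use_pe)
    setNames(sol[p + q + seq_len(ncol(W))], colnames(W)) else NULL
  fitted <- as.numeric(X %*% fixed + Z %*% ebv +
                         (if (use_pe) W %*% pe_hat else 0))
  res <- y - fitted

  pev_vec <- rel_vec <- NULL
  if (isTRUE(pev)) {
    E <- Matrix::sparseMatrix(i = p + seq_len(q), j = seq_len(q),
                              x = 1, dims = c(nrow(C), q))
    Cinv_cols <- Matrix::solve(ch, E)
    dg <- Matrix::diag(Cinv_cols[p + seq_len(q), , drop = FALSE])
    pev_vec <- setNames(dg * vc$sigma_e2, ids)
    rel_vec <- pmin(pmax(1 - pev_vec / vc$sigma_a2, 0), 1)
  }
  structure(list(fixed = fixed, ebv = ebv, pe = pe_hat,
                 pev = pev_vec, reliability = rel_vec,
                 fitted = fitted, residuals = res, vc = vc,
                 lambda = c(a = lam_a,
                            p = if (use_pe) lam_p else NA_real_)),
            class = "mme_solution")
}

#' @export
print.mme_solution <- function(x, ...) {
  cat(sprintf("mme_solution: %d fixed effects, %d animal effects%s\n",
              length(x$fixed), length(x$ebv),
              if (!is.null(x$pe))
                sprintf(", %d permanent-environment effects",
                        length(x$pe)) else ""))
  cat("fixed effects:\n"); print(x$fixed)
  invisible(x)
}

#' Extract predicted genetic values
#'
#' Returns the estimated breeding values for the requested animals.
#' Animals without phenotypes still have predictions, which flow
#' through the relationship matrix.
#'
#' @param solution an `mme_solution`.
#' @param ids animal ids to extract.
#' @return named numeric vector of EBVs.
#' @export
predict_genetic_values <- function(solution, ids) {
  stopifnot(inherits(solution, "mme_solution"))
  ids <- as.character(ids)
  miss <- setdiff(ids, names(solution$ebv))
  if (length(miss))
    stop("ids without predictions: ", paste(head(miss, 10L), collapse = ", "))
  solution$ebv[ids]
}

#' Fit the repeatability model for one trait
#'
#' Convenience wrapper: subsets records (optionally masking a test
#' set), builds the design against the id order of `K_inv`, and solves
#' the mixed-model equations.
#'
#' @param dataset a `trait_dataset`.
#' @param trait trait column name.
#' @param K_inv inverse relationship `rel_matrix`; its id order
#'   defines the animal effects.
#' @param vc variance components (`sigma_a2`, `sigma_p2`, `sigma_e2`).
#' @param mask_ids ids whose records are removed before fitting (test
#'   sets in validation designs).
#' @param keep_ids if given, only records of these ids are kept (e.g.
#'   the genotyped training set in GBLUP).
#' @param pev passed to [solve_mme()].
#' @inheritParams build_design
#' @return an `mme_solution`.
#' @export
fit_blup <- function(dataset, trait, K_inv, vc, mask_ids = NULL,
                     keep_ids = NULL, pev = TRUE, use_pe = TRUE) {
  dat <- as.data.frame(dataset)
  dat$id <- as.character(dat$id)
  if (!is.null(keep_ids)) dat <- dat[dat$id %in% as.character(keep_ids), ]
  if (!is.null(mask_ids)) dat <- dat[!dat$id %in% as.character(mask_ids), ]
  if (!nrow(dat)) stop("no records left after masking")
  ids <- if (inherits(K_inv, "rel_matrix")) rel_ids(K_inv) else
    rownames(K_inv)
  dat <- dat[dat$id %in% ids, ]
  des <- build_design(dat, ids, trait, use_pe = use_pe)
  solve_mme(des$X, des$Z, des$W, des$y, K_inv, vc, pev = pev)
}
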
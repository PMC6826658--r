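reml_fixture <- function(seed = 50L, q = 25L, nrec = 3L,
                         vc = c(2, 1, 1.5)) {
  set.seed(seed)
  ped <- random_pedigree(q + 10L, seed = seed)
  A <- rel_mat(build_A(ped))
  use <- ped$id[seq_len(q)]
  a <- as.numeric(t(chol(A)) %*% rnorm(nrow(A))) * sqrt(vc[1])
  id <- rep(use, each = nrec)
  n <- length(id)
  y <- 3 + a[match(id, ped$id)] + rep(rnorm(q, 0, sqrt(vc[2])), each = nrec) +
    rnorm(n, 0, sqrt(vc[3]))
  dat <- data.frame(id = id, year_season = sample(1:2, n, TRUE),
                    age_months = runif(n, 10, 20),
                    interval_days = rpois(n, 7) + 1, y = y)
  App <- rel_mat(extract_A22(ped, use))
  des <- build_design(dat, use, "y")
  list(dat = dat, des = des, App = App, Kinv = solve(App), ped = ped,
       use = use)
}

test_that("MME-based restricted likelihood equals the dense formula", {
  fx <- reml_fixture()
  Z <- as.matrix(fx$des$Z); W <- as.matrix(fx$des$W)
  X <- as.matrix(fx$des$X)
  Vp <- list(Z %*% fx$App %*% t(Z), W %*% t(W), diag(length(fx$des$y)))
  for (th in list(c(2, 1, 1.5), c(0.5, 0.2, 3), c(4, 2, 0.7))) {
    ll_dense <- reml_loglik(fx$des$y, X, Vp, th)
    fit <- suppressWarnings(ssgblup:::aireml_fit(
      matrix(fx$des$y, ncol = 1L), fx$des$X, fx$des$Z, fx$des$W, fx$Kinv,
      init = list(Sigma_a = matrix(th[1]), Sigma_p = matrix(th[2]),
                  Sigma_e = matrix(th[3])),
      max_iter = 1L, tol_param = 1e9, tol_logl = 1e300))
    expect_equal(-0.5 * fit$trajectory$minus2L[1L], ll_dense,
                 tolerance = 1e-8)
  }
})

test_that("restricted likelihood is scale-equivariant and projection-invariant", {
  fx <- reml_fixture(seed = 51L)
  X <- as.matrix(fx$des$X)
  Z <- as.matrix(fx$des$Z); W <- as.matrix(fx$des$W)
  n <- length(fx$des$y)
  Vp <- list(Z %*% fx$App %*% t(Z), W %*% t(W), diag(n))
  th <- c(1.5, 0.8, 2)
  l1 <- reml_loglik(fx$des$y, X, Vp, th)
  cc <- 2.5
  l2 <- reml_loglik(cc * fx$des$y, X, Vp, th * cc^2)
  ## -2L shifts by (n - rank X) log c^2 exactly
  expect_equal(-2 * l2, -2 * l1 + (n - qr(X)$rank) * log(cc^2),
               tolerance = 1e-8)
  ## the projection P depends only on the column space of X, so
  ## likelihood *differences* are invariant to any full-rank
  ## reparameterisation of the fixed effects
  set.seed(1)
  X3 <- X %*% (diag(ncol(X)) + 0.3 * matrix(rnorm(ncol(X)^2), ncol(X)))
  th2 <- c(2.2, 0.5, 1.1)
  d_orig <- reml_loglik(fx$des$y, X, Vp, th) -
    reml_loglik(fx$des$y, X, Vp, th2)
  d_reparam <- reml_loglik(fx$des$y, X3, Vp, th) -
    reml_loglik(fx$des$y, X3, Vp, th2)
  expect_equal(d_reparam, d_orig, tolerance = 1e-8)
})

test_that("AI-REML matches a shrinking-grid maximizer on a toy", {
  fx <- reml_fixture(seed = 52L, q = 10L, nrec = 3L)
  X <- as.matrix(fx$des$X)
  Z <- as.matrix(fx$des$Z); W <- as.matrix(fx$des$W)
  Vp <- list(Z %*% fx$App %*% t(Z), W %*% t(W), diag(length(fx$des$y)))
  fit <- suppressWarnings(
    ai_reml(fx$des$y, fx$des$X, fx$des$Z, fx$des$W, fx$Kinv))
  grid <- grid_search_reml(fx$des$y, X, Vp, unname(fit$components),
                           rounds = 8L, span = 0.3)
  expect_equal(unname(fit$components), grid, tolerance = 1e-3)
  ## the fitted point is a maximum of the dense likelihood
  l0 <- reml_loglik(fx$des$y, X, Vp, fit$components)
  for (i in 1:3) for (d in c(-0.02, 0.02)) {
    th <- fit$components; th[i] <- th[i] * (1 + d)
    expect_lte(reml_loglik(fx$des$y, X, Vp, th), l0 + 1e-9)
  }
})

test_that("likelihood trajectory is monotone and order-invariant", {
  fx <- reml_fixture(seed = 53L)
  fit <- ai_reml(fx$des$y, fx$des$X, fx$des$Z, fx$des$W, fx$Kinv)
  expect_true(all(diff(fit$trajectory$minus2L) <= 1e-8))
  ## reordering records leaves the estimates unchanged
  set.seed(99)
  perm <- sample(nrow(fx$dat))
  des2 <- build_design(fx$dat[perm, ], fx$use, "y")
  fit2 <- ai_reml(des2$y, des2$X, des2$Z, des2$W, fx$Kinv)
  expect_equal(fit$components, fit2$components, tolerance = 1e-6)
})

test_that("boundary data pins sigma_p2 near zero but keeps h2 consistent", {
  set.seed(54)
  q <- 200L; nrec <- 5L
  ped <- random_pedigree(q + 20L, seed = 54L)
  A <- rel_mat(build_A(ped))
  use <- ped$id[seq_len(q)]
  a <- as.numeric(t(chol(A)) %*% rnorm(nrow(A))) * sqrt(2)
  id <- rep(use, each = nrec)
  y <- 1 + a[match(id, ped$id)] + rnorm(length(id), 0, sqrt(3))
  dat <- data.frame(id = id, year_season = 1L,
                    age_months = runif(length(id), 10, 20),
                    interval_days = rpois(length(id), 7) + 1, y = y)
  App <- rel_mat(extract_A22(ped, use))
  des <- build_design(dat, use, "y")
  fit <- suppressWarnings(
    ai_reml(des$y, des$X, des$Z, des$W, solve(App)))
  expect_lt(fit$components[["sigma_p2"]], 0.05)
  expect_true(fit$boundary || fit$components[["sigma_p2"]] < 0.05)
  h2_true <- 2 / 5
  expect_lt(abs(fit$h2 - h2_true), 2 * max(fit$h2_se, 0.05))
})

test_that("bivariate engine agrees with dense-V likelihood and duplication logic", {
  fx <- reml_fixture(seed = 55L, q = 15L, nrec = 3L)
  ## second trait = same genetic signal, independent residual draws
  set.seed(56)
  A <- fx$App
  aa <- as.numeric(t(chol(A)) %*% rnorm(nrow(A)))
  id <- fx$dat$id
  y2 <- 1 + fx$dat$y - rnorm(length(id), 0, 0.1)  # noisy copy of trait 1
  Y <- cbind(fx$dat$y, y2)
  ## likelihood check against a direct dense evaluation (stacked form)
  Se <- diag(c(1.5, 1.4)); Se[1, 2] <- Se[2, 1] <- 0.2
  Sa <- diag(c(2, 1.8));  Sa[1, 2] <- Sa[2, 1] <- 1.1
  Sp <- diag(c(1, 0.9));  Sp[1, 2] <- Sp[2, 1] <- 0.3
  Z <- as.matrix(fx$des$Z); W <- as.matrix(fx$des$W)
  X <- as.matrix(fx$des$X)
  n <- nrow(Y)
  ZAZ <- Z %*% fx$App %*% t(Z); WW <- W %*% t(W); In <- diag(n)
  Vbig <- kronecker(Sa, ZAZ) + kronecker(Sp, WW) + kronecker(Se, In)
  Xbig <- kronecker(diag(2), X)
  ybig <- c(Y[, 1L], Y[, 2L])
  ll_dense <- reml_loglik(ybig, Xbig, list(Vbig), 1, max_n = 2000L)
  fit1 <- ssgblup:::aireml_fit(Y, fx$des$X, fx$des$Z, fx$des$W, fx$Kinv,
                               init = list(Sigma_a = Sa, Sigma_p = Sp,
                                           Sigma_e = Se),
                               max_iter = 1L, tol_param = 1e9,
                               tol_logl = 1e300)
  expect_equal(-0.5 * fit1$trajectory$minus2L[1L], ll_dense,
               tolerance = 1e-8)
  ## duplicated genetic signal with independent permanent-environment
  ## and residual draws: genetic correlation close to 1
  comp <- matrix(c(2, 1, 2, 2, 1, 2), 2L, 3L, byrow = TRUE,
                 dimnames = list(c("u", "v"),
                                 c("sigma_a2", "sigma_p2", "sigma_e2")))
  cfg <- sim_config(n_generations = 5L, n_founders = 60L,
                    n_sires_per_gen = 8L, n_dams_per_gen = 30L,
                    offspring_per_mating = 2L,
                    variance_components = comp,
                    genetic_correlation_matrix =
                      matrix(c(1, 1, 1, 1), 2L,
                             dimnames = list(c("u", "v"), c("u", "v"))),
                    n_phenotyped = 200L, phenotype_min_generation = 1L,
                    records_per_boar_mean = 6, n_year_seasons = 4L,
                    seed = 56L)
  dd <- suppressWarnings(simulate_dataset(cfg))
  fit <- suppressWarnings(
    estimate_variance_components(dd$phenotypes, dd$pedigree, c("u", "v")))
  expect_gt(fit$genetic_correlation,
            1 - 2 * max(fit$genetic_correlation_se, 0.05))
})

test_that("zero-covariance traits estimate a near-zero genetic correlation", {
  comp <- matrix(c(2, 1, 2, 3, 1.5, 3), 2L, 3L, byrow = TRUE,
                 dimnames = list(c("u", "v"),
                                 c("sigma_a2", "sigma_p2", "sigma_e2")))
  cfg <- sim_config(n_generations = 6L, n_founders = 80L,
                    n_sires_per_gen = 10L, n_dams_per_gen = 40L,
                    offspring_per_mating = 2L,
                    variance_components = comp,
                    genetic_correlation_matrix = diag(2L),
                    n_phenotyped = 300L, phenotype_min_generation = 1L,
                    records_per_boar_mean = 6, n_year_seasons = 4L,
                    seed = 57L)
  d <- suppressWarnings(simulate_dataset(cfg))
  fit <- estimate_variance_components(d$phenotypes, d$pedigree, c("u", "v"))
  expect_lt(abs(fit$genetic_correlation),
            max(2.5 * fit$genetic_correlation_se, 0.1))
})

test_that("bivariate marginal with fixed zero covariances matches univariate", {
  fx <- reml_fixture(seed = 58L, q = 20L, nrec = 3L)
  set.seed(59)
  y2 <- rnorm(nrow(fx$dat), 2, 1.3)
  Y <- cbind(fx$dat$y, y2)
  uni <- ai_reml(fx$des$y, fx$des$X, fx$des$Z, fx$des$W, fx$Kinv)
  biv <- suppressWarnings(
    ai_reml_bivariate(Y, fx$des$X, fx$des$Z, fx$des$W, fx$Kinv,
                      fix_covariances = TRUE))
  ## trait 2 sits on the variance floor, which caps the joint fit's
  ## convergence precision; 1% agreement is the attainable scale
  expect_equal(biv$Sigma_a[1, 1], uni$components[["sigma_a2"]],
               tolerance = 0.01)
  expect_equal(biv$Sigma_e[1, 1], uni$components[["sigma_e2"]],
               tolerance = 0.01)
})
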
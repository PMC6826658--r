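make_mme_fixture <- function(seed = 10L, q = 20L, nrec = 3L) {
  set.seed(seed)
  ped <- random_pedigree(q, seed = seed)
  K <- rel_mat(build_A(ped))
  ids <- ped$id
  use <- ids[seq_len(q - 4L)]            # leave some animals unphenotyped
  id <- rep(use, each = nrec)
  n <- length(id)
  dat <- data.frame(id = id,
                    year_season = sample(1:3, n, TRUE),
                    age_months = runif(n, 10, 30),
                    interval_days = rpois(n, 7) + 1,
                    y = rnorm(n, 10, 3))
  list(ped = ped, K = K, ids = ids, dat = dat)
}

test_that("design matrices tally records correctly", {
  fx <- make_mme_fixture()
  des <- build_design(fx$dat, fx$ids, "y")
  X <- as.matrix(des$X); Z <- as.matrix(des$Z); W <- as.matrix(des$W)
  n <- nrow(fx$dat)
  expect_equal(colSums(Z), unname(table(factor(fx$dat$id, levels = fx$ids))),
               ignore_attr = TRUE)
  ## class columns sum to per-class record counts
  cls <- table(fx$dat$year_season)
  expect_equal(unname(colSums(X[, grep("^ys", colnames(X)), drop = FALSE])),
               unname(as.numeric(cls[-1L])))
  ## X'y and Z'y match hand tallies
  expect_equal(as.numeric(crossprod(X[, 1L], fx$dat$y)), sum(fx$dat$y))
  zty <- tapply(fx$dat$y, factor(fx$dat$id, levels = fx$ids), sum)
  zty[is.na(zty)] <- 0
  expect_equal(as.numeric(crossprod(Z, fx$dat$y)), as.numeric(zty))
  ## single boar, one season: intercept-only plus covariates
  single <- fx$dat[fx$dat$id == fx$dat$id[1L], ][1:3, ]
  single$year_season <- 1L
  des1 <- build_design(single, fx$ids, "y")
  expect_equal(colnames(des1$X), c("intercept", "age_months",
                                   "interval_days"))
  expect_equal(sum(as.matrix(des1$Z)), 3)
})

test_that("MME solutions equal the dense GLS/BLUP oracle", {
  fx <- make_mme_fixture(seed = 30L)
  des <- build_design(fx$dat, fx$ids, "y")
  vc <- list(sigma_a2 = 2, sigma_p2 = 1, sigma_e2 = 3)
  sol <- solve_mme(des$X, des$Z, des$W, des$y, solve(fx$K), vc)
  orc <- gls_oracle(des$X, des$Z, des$W, des$y, fx$K, vc)
  expect_lt(max(abs(sol$fixed - orc$b)), 1e-6)
  expect_lt(max(abs(sol$ebv - orc$a)), 1e-6)
  expect_lt(max(abs(sol$pe - orc$p)), 1e-6)
  ## prediction lookup
  expect_equal(predict_genetic_values(sol, fx$ids[3:5]),
               sol$ebv[fx$ids[3:5]])
  expect_error(predict_genetic_values(sol, "ghost"), "without predictions")
})

test_that("record duplication is handled consistently with the GLS oracle", {
  ## duplicating every record re-weights the residual relative to the
  ## random effects, so the estimates legitimately move; the check is
  ## that the MME solution tracks the dense GLS oracle on the
  ## duplicated data exactly
  fx <- make_mme_fixture(seed = 31L)
  vc <- list(sigma_a2 = 2, sigma_p2 = 1, sigma_e2 = 3)
  dup <- rbind(fx$dat, fx$dat)
  desd <- build_design(dup, fx$ids, "y")
  sold <- solve_mme(desd$X, desd$Z, desd$W, desd$y, solve(fx$K), vc,
                    pev = FALSE)
  orc <- gls_oracle(desd$X, desd$Z, desd$W, desd$y, fx$K, vc)
  expect_lt(max(abs(sold$fixed - orc$b)), 1e-8)
  expect_lt(max(abs(sold$ebv - orc$a)), 1e-8)
})

test_that("shrinkage limits and no-information animals behave", {
  fx <- make_mme_fixture(seed = 32L)
  des <- build_design(fx$dat, fx$ids, "y")
  vc0 <- list(sigma_a2 = 1e-10, sigma_p2 = 1, sigma_e2 = 3)
  sol0 <- solve_mme(des$X, des$Z, des$W, des$y, solve(fx$K), vc0,
                    pev = FALSE)
  expect_lt(max(abs(sol0$ebv)), 1e-6)
  ## an animal unlinked to all data has EBV 0
  ped2 <- read_and_validate_pedigree(rbind(
    as.data.frame(fx$ped)[, 1:4],
    data.frame(id = "loner", sire = "0", dam = "0", generation = 0L)))
  A2 <- rel_mat(build_A(ped2))
  des2 <- build_design(fx$dat, ped2$id, "y")
  vc <- list(sigma_a2 = 2, sigma_p2 = 1, sigma_e2 = 3)
  sol2 <- solve_mme(des2$X, des2$Z, des2$W, des2$y, solve(A2), vc,
                    pev = FALSE)
  expect_equal(unname(sol2$ebv["loner"]), 0, tolerance = 1e-10)
})

test_that("unphenotyped relatives get oracle-consistent predictions", {
  ## 5-animal pedigree: phenotyped parents + sibs, one unphenotyped sib
  ped <- read_and_validate_pedigree(data.frame(
    id = c("s", "d", "k1", "k2", "k3"),
    sire = c("0", "0", "s", "s", "s"),
    dam = c("0", "0", "d", "d", "d")))
  K <- rel_mat(build_A(ped))
  set.seed(41)
  dat <- data.frame(id = rep(c("s", "d", "k1", "k2"), each = 3L),
                    year_season = 1L,
                    age_months = runif(12L, 10, 30),
                    interval_days = rpois(12L, 7) + 1,
                    y = rnorm(12L, 5, 2))
  des <- build_design(dat, ped$id, "y")
  vc <- list(sigma_a2 = 2, sigma_p2 = 1, sigma_e2 = 3)
  sol <- solve_mme(des$X, des$Z, des$W, des$y, solve(K), vc, pev = FALSE)
  orc <- gls_oracle(des$X, des$Z, des$W, des$y, K, vc)
  expect_lt(max(abs(sol$ebv - orc$a)), 1e-8)
})

test_that("residuals sum to zero and PEV never exceeds prior variance", {
  fx <- make_mme_fixture(seed = 33L)
  dat <- fx$dat; dat$year_season <- 1L    # intercept-only fixed part
  des <- build_design(dat, fx$ids, "y", use_age = FALSE,
                      use_interval = FALSE)
  vc <- list(sigma_a2 = 2, sigma_p2 = 1, sigma_e2 = 3)
  sol <- solve_mme(des$X, des$Z, des$W, des$y, solve(fx$K), vc)
  expect_lt(abs(sum(sol$residuals)), 1e-8)
  Fi <- inbreeding_coefficients(fx$ped)
  expect_true(all(sol$pev <= vc$sigma_a2 * (1 + Fi[names(sol$pev)]) + 1e-8))
  expect_true(all(sol$reliability >= 0 & sol$reliability <= 1))
})
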
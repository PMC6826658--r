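test_that("simulated pedigrees respect the configured structure", {
  cfg <- sim_config(seed = 8L)
  ped <- simulate_pedigree(cfg)
  expect_equal(max(ped$generation), cfg$n_generations - 1L)
  founders <- ped$generation == 0L
  expect_true(all(ped$sire[founders] == "0" & ped$dam[founders] == "0"))
  expect_true(all(ped$sire[!founders] != "0" & ped$dam[!founders] != "0"))
  ## same seed twice -> identical pedigree
  expect_identical(as.data.frame(simulate_pedigree(cfg)),
                   as.data.frame(ped))
})

test_that("monogamous matings give full-sib litters with A-entry 0.5", {
  cfg <- sim_config(n_generations = 2L, n_founders = 12L,
                    n_sires_per_gen = 4L, n_dams_per_gen = 4L,
                    offspring_per_mating = 2L, mating = "monogamous",
                    seed = 5L)
  ped <- simulate_pedigree(cfg)
  A <- rel_mat(build_A(ped))
  kids <- ped[ped$generation == 1L, ]
  f <- kinship_oracle(ped)
  for (dm in unique(kids$dam)) {
    sibs <- match(kids$id[kids$dam == dm], ped$id)
    expect_length(sibs, 2L)
    expect_equal(A[sibs[1L], sibs[2L]], 0.5)
    expect_equal(f(sibs[1L], sibs[2L]), 0.5)
  }
})

test_that("gene dropping obeys fixation and Mendelian transmission", {
  d <- small_sim(seed = 31L, n_snps = 200L, gprop = 1)
  M <- genotype_codes(d$genotypes)[d$pedigree$id, ]
  si <- attr(d$pedigree, "sire_idx"); di <- attr(d$pedigree, "dam_idx")
  for (i in which(si > 0L & di > 0L)) {
    hom0 <- M[si[i], ] == 0L & M[di[i], ] == 0L
    hom2 <- M[si[i], ] == 2L & M[di[i], ] == 2L
    expect_true(all(M[i, hom0] == 0L))
    expect_true(all(M[i, hom2] == 2L))
  }
  ## pooled allele frequency near the founder truth
  p <- attr(d$genotypes, "truth_freq")
  p <- d$genotypes$truth_freq
  phat <- colMeans(M) / 2
  se <- sqrt(p * (1 - p) / (2 * nrow(M)))
  ## drift widens the spread; 3 binomial SEs at founder size is the scale
  expect_gt(mean(abs(phat - p) < 3 * sqrt(p * (1 - p) / (2 * 12))), 0.95)
})

test_that("breeding-value draws have the configured covariance structure", {
  comp <- matrix(c(4, 1, 2, 9, 2, 3), 2, 3, byrow = TRUE,
                 dimnames = list(c("t1", "t2"),
                                 c("sigma_a2", "sigma_p2", "sigma_e2")))
  ## zero genetic correlation -> near-zero BV correlation
  cfg0 <- sim_config(n_generations = 3L, n_founders = 2500L,
                     n_sires_per_gen = 50L, n_dams_per_gen = 1000L,
                     offspring_per_mating = 2L,
                     variance_components = comp,
                     genetic_correlation_matrix = diag(2),
                     n_phenotyped = 10L, phenotype_min_generation = 1L,
                     seed = 12L)
  ped0 <- simulate_pedigree(cfg0)
  tr0 <- simulate_breeding_values(ped0, cfg0)
  expect_lt(abs(cor(tr0$bv[, 1L], tr0$bv[, 2L])), 0.05)
  ## founder BV covariance reproduces Sigma_a within sampling error
  fo <- ped0$generation == 0L
  emp <- cov(tr0$bv[fo, ])
  expect_lt(abs(emp[1, 1] - 4) / 4, 0.15)
  expect_lt(abs(emp[2, 2] - 9) / 9, 0.15)
  expect_lt(abs(emp[1, 2]) / sqrt(36), 0.1)
})

test_that("Mendelian sampling variance is half sigma_a2 for non-inbred parents", {
  comp <- matrix(c(4, 1, 2), 1, 3,
                 dimnames = list("t", c("sigma_a2", "sigma_p2", "sigma_e2")))
  cfg <- sim_config(n_generations = 2L, n_founders = 2L,
                    n_sires_per_gen = 1L, n_dams_per_gen = 1L,
                    offspring_per_mating = 4000L,
                    variance_components = comp,
                    genetic_correlation_matrix = matrix(1, 1, 1),
                    n_phenotyped = 2L, phenotype_min_generation = 0L,
                    seed = 9L)
  ped <- simulate_pedigree(cfg)
  tr <- simulate_breeding_values(ped, cfg)
  kids <- ped$generation == 1L
  ms <- tr$bv[kids, 1L] - mean(tr$bv[!kids, 1L])
  expect_lt(abs(var(ms) - 0.5 * 4) / 2, 0.1)
})

test_that("phenotypes decompose exactly into stored truth components", {
  d <- small_sim(seed = 77L, n_snps = 10L)
  ph <- d$phenotypes
  tn <- attr(ph, "trait_names")
  y <- as.matrix(as.data.frame(ph)[, tn])
  recon <- attr(ph, "fixed_part") + attr(ph, "residuals") +
    d$truth$bv[ph$id, tn] + d$truth$pe[ph$id, tn]
  expect_lt(max(abs(y - recon)), 1e-10)
})

test_that("degenerate variance settings yield exactly reproducible records", {
  comp <- matrix(c(4, 0, 0), 1, 3,
                 dimnames = list("t", c("sigma_a2", "sigma_p2", "sigma_e2")))
  cfg <- sim_config(n_generations = 3L, n_founders = 10L,
                    n_sires_per_gen = 2L, n_dams_per_gen = 5L,
                    offspring_per_mating = 2L,
                    variance_components = comp,
                    genetic_correlation_matrix = matrix(1, 1, 1),
                    n_phenotyped = 8L, phenotype_min_generation = 1L,
                    n_year_seasons = 1L, year_season_effect_sd = 0,
                    age_slope = 0, interval_slope = 0,
                    records_per_boar_mean = 3, seed = 2L)
  ped <- simulate_pedigree(cfg)
  tr <- simulate_breeding_values(ped, cfg)
  ph <- suppressWarnings(simulate_phenotypes(ped, tr, cfg))
  ## every record equals the year-season intercept + the boar's true BV
  expect_lt(max(abs(ph$t - attr(ph, "year_season_effects")[ph$year_season] -
                      tr$bv[ph$id, 1L])), 1e-12)
})

test_that("record counts and intraclass correlation match the configuration", {
  cfg <- sim_config(n_generations = 4L, n_founders = 80L,
                    n_sires_per_gen = 10L, n_dams_per_gen = 40L,
                    offspring_per_mating = 2L, n_phenotyped = 100L,
                    phenotype_min_generation = 1L,
                    records_per_boar_mean = 22.6, seed = 14L)
  d <- simulate_dataset(cfg)
  nrec <- nrow(d$phenotypes)
  expect_lt(abs(nrec / 100 - 22.6), 3 * sqrt(22.6 / 100))
  ## intraclass correlation of DD records ~ repeatability
  ph <- d$phenotypes
  comp <- sperm_trait_params()$components["DD", ]
  r_true <- (comp[1] + comp[2]) / sum(comp)
  resid <- ph$DD - attr(ph, "fixed_part")[, "DD"]
  between <- tapply(resid, ph$id, mean)
  within <- resid - between[ph$id]
  k <- mean(table(ph$id))
  vb <- var(between) - var(within) * (length(within) /
                                        (length(within) - 100)) / k
  icc <- vb / (vb + var(within))
  expect_lt(abs(icc - r_true), 0.12)
})

test_that("identical config and seed give identical datasets", {
  cfg <- sim_config(n_generations = 3L, n_founders = 12L,
                    n_sires_per_gen = 3L, n_dams_per_gen = 6L,
                    offspring_per_mating = 2L, n_snps = 50L,
                    n_phenotyped = 8L, phenotype_min_generation = 1L,
                    records_per_boar_mean = 3, seed = 123L)
  d1 <- suppressWarnings(simulate_dataset(cfg, genotypes = TRUE))
  d2 <- suppressWarnings(simulate_dataset(cfg, genotypes = TRUE))
  expect_identical(as.data.frame(d1$phenotypes), as.data.frame(d2$phenotypes))
  expect_identical(genotype_codes(d1$genotypes), genotype_codes(d2$genotypes))
  expect_identical(d1$truth$bv, d2$truth$bv)
})
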
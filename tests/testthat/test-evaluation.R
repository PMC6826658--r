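test_that("cross-validation folds partition exactly with balanced sizes", {
  ids <- paste0("g", 1:100)
  des <- make_cv_folds(ids, k = 5L, repeats = 3L, seed = 7L)
  for (r in 1:3) {
    f <- des$folds[[r]]
    expect_setequal(names(f), ids)
    expect_equal(unname(table(f)), rep(20L, 5L), ignore_attr = TRUE)
  }
  ## remainder rule: 101 ids -> sizes {21,20,20,20,20}
  des2 <- make_cv_folds(paste0("g", 1:101), k = 5L, repeats = 1L, seed = 7L)
  expect_equal(sort(unname(table(des2$folds[[1L]])), decreasing = TRUE),
               c(21L, 20L, 20L, 20L, 20L), ignore_attr = TRUE)
  ## determinism
  des3 <- make_cv_folds(ids, k = 5L, repeats = 3L, seed = 7L)
  expect_identical(des$folds, des3$folds)
  expect_error(make_cv_folds(ids[1:3], k = 5L), "fewer")
})

test_that("predictive ability is a plain Pearson correlation with guards", {
  drp <- data.frame(id = paste0("b", 1:10), trait = "t",
                    drp = c(1.2, -0.4, 0.8, 2.0, -1.1, 0.3, 0.9, -0.2,
                            1.5, -0.7))
  pred <- setNames(drp$drp, drp$id)
  expect_equal(as.numeric(predictive_ability(pred, drp, drp$id, "t")), 1.0)
  expect_equal(as.numeric(predictive_ability(-pred, drp, drp$id, "t")), -1.0)
  ## hand-computed textbook formula on an arbitrary vector
  set.seed(8)
  noisy <- pred + rnorm(10)
  r_hand <- sum((noisy - mean(noisy)) * (drp$drp - mean(drp$drp))) /
    sqrt(sum((noisy - mean(noisy))^2) * sum((drp$drp - mean(drp$drp))^2))
  expect_equal(as.numeric(predictive_ability(noisy, drp, drp$id, "t")),
               r_hand)
  ## guards: too few pairs, zero variance
  expect_true(is.na(predictive_ability(pred[1:2], drp, drp$id[1:2], "t")))
  flat <- setNames(rep(1, 10), drp$id)
  expect_true(is.na(predictive_ability(flat, drp, drp$id, "t")))
})

test_that("percentage improvement reproduces the benchmark arithmetic", {
  expect_equal(percentage_improvement(0.330, 0.565), 71.21, tolerance = 5e-3)
  expect_equal(percentage_improvement(0.4, 0.4), 0)
  expect_warning(percentage_improvement(0, 0.3), "zero base")
})

test_that("forward split separates generations with correct counts", {
  d <- small_sim(seed = 63L, n_snps = 10L)
  gids <- geno_ids(d$genotypes)
  pids <- unique(d$phenotypes$id)
  fs <- forward_split(d$pedigree, gids, pids)
  expect_length(intersect(fs$train_ids, fs$test_ids), 0L)
  expect_setequal(c(fs$train_ids, fs$test_ids), d$pedigree$id)
  gmax <- max(d$pedigree$generation)
  expect_true(all(d$pedigree$generation[match(fs$test_ids, d$pedigree$id)]
                  %in% c(gmax - 1L, gmax)))
  expect_equal(fs$summary$n_pedigree, c(length(fs$train_ids),
                                        length(fs$test_ids)))
  expect_equal(sum(fs$summary$n_genotyped), length(gids))
})

test_that("no test-set record leaks into any training fit", {
  d <- small_sim(seed = 64L)
  ped <- d$pedigree
  gids <- geno_ids(d$genotypes)
  A22 <- extract_A22(ped, gids)
  Gw <- blend_G(build_G(fill_missing_as_heterozygote(d$genotypes)), A22, 0.9)
  Hinv <- build_H_inverse(build_A_inverse(ped), A22, Gw)
  vc <- list(sigma_a2 = 7.3, sigma_p2 = 4.3, sigma_e2 = 13.1)
  test <- intersect(gids, unique(d$phenotypes$id))[1:4]
  p1 <- run_scenario("ssGBLUP", test, d$phenotypes, "DD", vc,
                     K_inv_H = Hinv)
  ## corrupt the test animals' records wildly: predictions cannot move
  ph2 <- d$phenotypes
  sel <- ph2$id %in% test
  ph2$DD[sel] <- ph2$DD[sel] + 1e3
  p2 <- run_scenario("ssGBLUP", test, ph2, "DD", vc, K_inv_H = Hinv)
  expect_identical(p1, p2)
  ## same for GBLUP
  g1 <- run_scenario("GBLUP", test, d$phenotypes, "DD", vc, G_mat = Gw)
  g2 <- run_scenario("GBLUP", test, ph2, "DD", vc, G_mat = Gw)
  expect_identical(g1, g2)
  ## masking already-unphenotyped animals is a no-op
  unphen <- setdiff(gids, unique(d$phenotypes$id))
  if (length(unphen) >= 3L) {
    q1 <- run_scenario("ssGBLUP", unphen, d$phenotypes, "DD", vc,
                       K_inv_H = Hinv)
    full <- fit_blup(d$phenotypes, "DD", Hinv, vc, pev = FALSE)
    expect_equal(q1, predict_genetic_values(full, unphen))
  }
})

test_that("GBLUP and ssGBLUP coincide when every animal is genotyped", {
  cfg <- sim_config(n_generations = 3L, n_founders = 10L,
                    n_sires_per_gen = 3L, n_dams_per_gen = 5L,
                    offspring_per_mating = 3L, n_snps = 600L,
                    genotyping_proportion_by_generation = 1,
                    n_phenotyped = 15L, phenotype_min_generation = 1L,
                    records_per_boar_mean = 4, missing_rate = 0,
                    seed = 65L)
  d <- suppressWarnings(simulate_dataset(cfg, genotypes = TRUE))
  gids <- d$pedigree$id
  geno <- new_genotype_matrix(genotype_codes(d$genotypes)[gids, ])
  A22 <- extract_A22(d$pedigree, gids)
  Gw <- blend_G(build_G(geno), A22, 0.9)
  Hinv <- build_H_inverse(build_A_inverse(d$pedigree), A22, Gw)
  vc <- list(sigma_a2 = 7.3, sigma_p2 = 4.3, sigma_e2 = 13.1)
  test <- gids[d$pedigree$generation == 2L][1:5]
  pG <- run_scenario("GBLUP", test, d$phenotypes, "DD", vc, G_mat = Gw)
  pS <- run_scenario("ssGBLUP", test, d$phenotypes, "DD", vc,
                     K_inv_H = Hinv)
  expect_lt(max(abs(pG - pS)), 1e-6)
})

test_that("method comparison tabulates improvements and EBV correlations", {
  res <- data.frame(trait = rep(c("PD", "DD"), each = 2L),
                    method = rep(c("GBLUP", "ssGBLUP"), 2L),
                    scenario = "cross_validation",
                    r = c(0.330, 0.565, 0.386, 0.507))
  ebv <- list(PD = data.frame(BLUP = c(1, 2, 3, 4), GBLUP = c(1, 2, 3, 4),
                              ssGBLUP = c(1, 2, 3, 4)))
  cmp <- compare_methods(res, ebv)
  pd <- cmp$table[cmp$table$trait == "PD", ]
  expect_equal(pd$improvement_pct, 71.21, tolerance = 5e-3)
  expect_equal(cmp$ebv_correlations$EBV_vs_GEBV, 1.0)
  expect_equal(cmp$ebv_correlations$GEBV_vs_ssGEBV, 1.0)
})
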
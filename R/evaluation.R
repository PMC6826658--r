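#' Repeated k-fold partitions of the genotyped animals
#'
#' Randomly divides the genotyped ids into `k` groups of sizes
#' differing by at most one, independently for each repeat; repeat `r`
#' uses `seed + r`, so designs are reproducible and extendable.
#'
#' @param genotyped_ids character vector of genotyped ids.
#' @param k number of folds (default 5).
#' @param repeats number of repeated partitions (default 20).
#' @param seed base seed.
#' @return `cv_design`: list with `k`, `repeats`, `seed` and `folds`,
#'   a list (per repeat) of integer fold assignments named by id.
#' @export
make_cv_folds <- function(genotyped_ids, k = 5L, repeats = 20L,
                          seed = 1L) {
  genotyped_ids <- as.character(genotyped_ids)
  n <- length(genotyped_ids)
  if (n < k) stop("fewer genotyped ids (", n, ") than folds (", k, ")")
  folds <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    set.seed(seed + r)
    assign <- sample(rep_len(seq_len(k), n))
    names(assign) <- genotyped_ids
    folds[[r]] <- assign
  }
  structure(list(k = as.integer(k), repeats = as.integer(repeats),
                 seed = as.integer(seed), ids = genotyped_ids,
                 folds = folds), class = "cv_design")
}

#' Training/test split by generation (forward prediction)
#'
#' Mimics routine breeding use: older generations train the model, the
#' newest generations are predicted. Returns the id sets together with
#' a data-structure summary (pedigree / genotyped / phenotyped counts
#' per side).
#'
#' @param pedigree a `pedigree` object.
#' @param genotyped_ids ids with genotypes.
#' @param phenotyped_ids ids with phenotype records.
#' @param test_generations generation labels forming the test set
#'   (default the last two).
#' @return `forward_design`: list with `train_ids`, `test_ids`,
#'   `test_genotyped`, and a `summary` data.frame of counts.
#' @export
forward_split <- function(pedigree, genotyped_ids, phenotyped_ids,
                          test_generations = NULL) {
  stop_if_not_pedigree(pedigree)
  if (is.null(test_generations)) {
    gmax <- max(pedigree$generation)
    test_generations <- c(gmax - 1L, gmax)
  }
  test <- pedigree$id[pedigree$generation %in% test_generations]
  train <- setdiff(pedigree$id, test)
  genotyped_ids <- as.character(genotyped_ids)
  phenotyped_ids <- as.character(phenotyped_ids)
  summ <- data.frame(
    dataset = c("training", "test"),
    n_pedigree = c(length(train), length(test)),
    n_genotyped = c(sum(train %in% genotyped_ids),
                    sum(test %in% genotyped_ids)),
    n_phenotyped = c(sum(train %in% phenotyped_ids),
                     sum(test %in% phenotyped_ids)),
    n_pheno_and_geno = c(sum(train %in% genotyped_ids &
                               train %in% phenotyped_ids),
                         sum(test %in% genotyped_ids &
                               test %in% phenotyped_ids)))
  structure(list(train_ids = train, test_ids = test,
                 test_genotyped = intersect(test, genotyped_ids),
                 test_generations = test_generations,
                 summary = summ), class = "forward_design")
}

#' Fit one prediction scenario and predict the test animals
#'
#' Masks the test animals' phenotypes and fits the repeatability model
#' with raw records as the response and variance components held fixed
#' (estimated once from the full data, not per fold):
#' * `"GBLUP"`: only genotyped animals enter; training records are
#'   those of genotyped non-test animals and K is the (blended)
#'   genomic relationship matrix.
#' * `"ssGBLUP"`: all pedigree animals except the test set contribute
#'   records and `K^-1 = H^-1` combines pedigree and genomic
#'   information.
#' * `"BLUP"`: as ssGBLUP but with the pedigree matrix only (used for
#'   EBV comparisons).
#'
#' @param method `"GBLUP"`, `"ssGBLUP"` or `"BLUP"`.
#' @param test_ids animals whose records are masked and whose genetic
#'   values are returned.
#' @param dataset a `trait_dataset`.
#' @param trait trait column name.
#' @param vc fixed variance components (list with `sigma_a2`,
#'   `sigma_p2`, `sigma_e2`).
#' @param K_inv_H sparse H-inverse `rel_matrix` (ssGBLUP).
#' @param G_mat dense genomic `rel_matrix` over the genotyped animals
#'   (GBLUP; blended or otherwise invertible).
#' @param A_inv sparse pedigree-inverse `rel_matrix` (BLUP).
#' @return named numeric vector of predicted genetic values for
#'   `test_ids`.
#' @export
run_scenario <- function(method = c("GBLUP", "ssGBLUP", "BLUP"),
                         test_ids, dataset, trait, vc,
                         K_inv_H = NULL, G_mat = NULL, A_inv = NULL) {
  method <- match.arg(method)
  test_ids <- as.character(test_ids)
  if (method == "GBLUP") {
    if (is.null(G_mat)) stop("GBLUP needs G_mat")
    gids <- rel_ids(G_mat)
    if (!all(test_ids %in% gids))
      stop("test ids absent from the genomic relationship matrix")
    Ginv <- new_rel_matrix(sym_inverse(G_mat, "G"), gids, "G_inverse")
    sol <- fit_blup(dataset, trait, Ginv, vc, mask_ids = test_ids,
                    keep_ids = gids, pev = FALSE)
  } else {
    Ki <- if (method == "ssGBLUP") K_inv_H else A_inv
    if (is.null(Ki)) stop(method, " needs its inverse relationship matrix")
    if (!all(test_ids %in% rel_ids(Ki)))
      stop("test ids absent from the relationship matrix")
    sol <- fit_blup(dataset, trait, Ki, vc, mask_ids = test_ids,
                    pev = FALSE)
  }
  predict_genetic_values(sol, test_ids)
}

#' Predictive ability: correlation of predictions with DRPs
#'
#' Plain (unweighted) Pearson correlation between the predicted
#' genetic values and the de-regressed proofs of the test animals.
#' Test ids without a valid DRP are excluded (and counted); fewer than
#' three usable pairs, or zero variance in either vector, yields `NA`.
#'
#' @param predictions named vector of predicted genetic values.
#' @param drp_table output of [drp_pipeline()] (or any data.frame with
#'   `id`, `trait`, `drp`).
#' @param test_ids ids to evaluate.
#' @param trait trait name to select from `drp_table`.
#' @return correlation (scalar) with attribute `n_used`.
#' @export
predictive_ability <- function(predictions, drp_table, test_ids, trait) {
  test_ids <- as.character(test_ids)
  d <- drp_table[drp_table$trait == trait & drp_table$id %in% test_ids &
                   !is.na(drp_table$drp), c("id", "drp")]
  use <- intersect(names(predictions), d$id)
  if (length(use) < 3L)
    return(structure(NA_real_, n_used = length(use)))
  x <- predictions[use]
  y <- d$drp[match(use, d$id)]
  if (sd(x) == 0 || sd(y) == 0)
    return(structure(NA_real_, n_used = length(use)))
  structure(cor(x, y), n_used = length(use))
}

#' Percentage improvement of one method over another
#'
#' `100 (r_new - r_base) / r_base`, the conventional way of reporting
#' how much one model's predictive ability exceeds another's.
#'
#' @param r_base,r_new predictive abilities (correlations).
#' @return percentage improvement; `NA` with a warning when the base
#'   is zero.
#' @export
percentage_improvement <- function(r_base, r_new) {
  out <- 100 * (r_new - r_base) / r_base
  if (any(r_base == 0)) {
    warning("zero base correlation; improvement undefined")
    out[r_base == 0] <- NA_real_
  }
  out
}

#' Compare prediction methods across traits and designs
#'
#' Summarises a set of predictive-ability results per trait and
#' method, computes the percentage improvement of ssGBLUP over GBLUP,
#' and (optionally) the pairwise correlations of the methods' EBVs on
#' the forward-test animals.
#'
#' @param results data.frame with columns `trait`, `method`,
#'   `scenario`, `r` (and optionally `se`).
#' @param ebv_lists optional named list per trait of data.frames with
#'   columns `BLUP`, `GBLUP`, `ssGBLUP` holding the test-set EBVs for
#'   the pairwise comparison.
#' @return list with `table` (wide per-trait summary with
#'   `improvement_pct`) and `ebv_correlations` (per trait, the three
#'   pairwise correlations), either may be `NULL` when inputs are
#'   absent.
#' @export
compare_methods <- function(results, ebv_lists = NULL) {
  tab <- NULL
  if (!is.null(results) && nrow(results)) {
    sc <- unique(results$scenario)
    rows <- list()
    for (s in sc) for (tr in unique(results$trait)) {
      rg <- results[results$scenario == s & results$trait == tr, ]
      rG <- rg$r[rg$method == "GBLUP"]
      rS <- rg$r[rg$method == "ssGBLUP"]
      if (!length(rG) || !length(rS)) next
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = s, trait = tr, GBLUP = rG[1], ssGBLUP = rS[1],
        improvement_pct = percentage_improvement(rG[1], rS[1]))
    }
    tab <- do.call(rbind, rows)
  }
  ebv_cor <- NULL
  if (!is.null(ebv_lists)) {
    ebv_cor <- do.call(rbind, lapply(names(ebv_lists), function(tr) {
      e <- ebv_lists[[tr]]
      data.frame(trait = tr,
                 EBV_vs_GEBV = cor(e$BLUP, e$GBLUP),
                 EBV_vs_ssGEBV = cor(e$BLUP, e$ssGBLUP),
                 GEBV_vs_ssGEBV = cor(e$GBLUP, e$ssGBLUP))
    }))
  }
  list(table = tab, ebv_correlations = ebv_cor)
}
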
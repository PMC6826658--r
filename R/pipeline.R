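#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end evaluation pipeline: the
#' synthetic-data configuration, the traits to analyse, quality-control
#' thresholds, the G/A22 blend weight, the validation designs and the
#' seed.
#'
#' @param sim a [sim_config()]; the default demo scale (about 800
#'   animals, 300 phenotyped boars, 1,200 SNPs) keeps a complete run in
#'   the minutes range on one core.
#' @param traits trait columns to analyse.
#' @param qc named list of [qc_filter()] thresholds.
#' @param blend_w blend weight on G for [blend_G()].
#' @param cv_k,cv_repeats cross-validation folds and repeats.
#' @param test_generations forward-prediction test generations
#'   (default: last two of the simulated pedigree).
#' @param bivariate_pairs list of trait pairs for genetic-correlation
#'   estimation (default: the first two traits, if two are analysed).
#' @param seed seed for fold assignment.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = pipeline_demo_sim(),
                            traits = c("PD", "DD"),
                            qc = list(ind_call = 0.90, snp_call = 0.90,
                                      maf = 0.01, hwe_p = 1e-5),
                            blend_w = 0.9,
                            cv_k = 5L, cv_repeats = 20L,
                            test_generations = NULL,
                            bivariate_pairs = NULL,
                            seed = 1L) {
  stopifnot(inherits(sim, "sim_config"))
  if (blend_w <= 0 || blend_w > 1) stop("blend_w must be in (0, 1]")
  if (is.null(bivariate_pairs) && length(traits) >= 2L)
    bivariate_pairs <- list(traits[1:2])
  structure(list(sim = sim, traits = traits, qc = qc, blend_w = blend_w,
                 cv_k = as.integer(cv_k), cv_repeats = as.integer(cv_repeats),
                 test_generations = test_generations,
                 bivariate_pairs = bivariate_pairs,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @export
pipeline_demo_sim <- function() {
  sim_config(n_generations = 8L, n_founders = 100L,
             n_sires_per_gen = 10L, n_dams_per_gen = 50L,
             offspring_per_mating = 2L,
             n_snps = 1200L,
             genotyping_proportion_by_generation = 0.5,
             n_phenotyped = 300L, phenotype_min_generation = 2L,
             records_per_boar_mean = 8,
             n_year_seasons = 8L,
             seed = 2025L)
}

#' Run the full evaluation pipeline
#'
#' Orchestrates, in order: data simulation, genotype QC and
#' missing-genotype filling, relationship matrices (A-inverse, A22, G,
#' blended G, H-inverse), AI-REML variance components per trait (plus
#' optional bivariate genetic correlations), full-data pedigree BLUP
#' and de-regression, repeated cross-validation and forward prediction
#' for GBLUP and ssGBLUP, and the method comparison. All reports are
#' written as plain-text TSV/JSON under `out_dir` together with a run
#' log; the returned list carries the same objects in memory.
#'
#' @param config a [pipeline_config()].
#' @param out_dir artifact directory (created if needed).
#' @param quiet suppress progress messages.
#' @return invisible list with elements `qc_report`,
#'   `variance_components`, `genetic_correlations`, `drp`,
#'   `cv_results`, `forward_results`, `comparison`, `forward_summary`,
#'   `paths`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("ssgblup_run_"),
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(out_dir, "pipeline.log")
  log_line <- function(...) {
    msg <- sprintf(...)
    cat(format(Sys.time(), "%H:%M:%S "), msg, "\n", file = logfile,
        append = TRUE, sep = "")
    if (!quiet) message(msg)
  }
  stage <- function(name, expr) {
    log_line("stage %s: start", name)
    out <- tryCatch(force(expr), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    log_line("stage %s: done", name)
    out
  }
  log_line("pipeline seed %d", config$seed)

  sim <- stage("simulate", {
    d <- simulate_dataset(config$sim, genotypes = TRUE)
    write_pedigree_csv(d$pedigree, file.path(out_dir, "pedigree.csv"))
    write_phenotypes_csv(d$phenotypes, file.path(out_dir, "phenotypes.csv"))
    d
  })
  traits <- config$traits

  qc <- stage("qc", {
    out <- do.call(qc_filter, c(list(sim$genotypes), config$qc))
    write_qc_report_json(out$report, file.path(out_dir, "qc_report.json"))
    out$genotypes <- fill_missing_as_heterozygote(out$genotypes)
    out
  })
  geno <- qc$genotypes
  gids <- geno_ids(geno)

  kin <- stage("kinship", {
    A_inv <- build_A_inverse(sim$pedigree)
    A22 <- extract_A22(sim$pedigree, gids)
    G <- build_G(geno)
    Gw <- blend_G(G, A22, w = config$blend_w)
    H_inv <- build_H_inverse(A_inv, A22, Gw)
    list(A_inv = A_inv, A22 = A22, G = G, Gw = Gw, H_inv = H_inv)
  })

  vcs <- stage("reml", {
    out <- lapply(traits, function(tr)
      estimate_variance_components(sim$phenotypes, sim$pedigree, tr))
    names(out) <- traits
    tab <- do.call(rbind, lapply(traits, function(tr) {
      v <- out[[tr]]
      data.frame(trait = tr, t(round(v$components, 4)),
                 h2 = round(v$h2, 4), h2_se = round(v$h2_se, 4),
                 r = round(v$r, 4), r_se = round(v$r_se, 4))
    }))
    utils::write.table(tab, file.path(out_dir, "variance_components.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    out
  })

  gcors <- NULL
  if (length(config$bivariate_pairs)) {
    gcors <- stage("reml_bivariate", {
      out <- lapply(config$bivariate_pairs, function(pr)
        estimate_variance_components(sim$phenotypes, sim$pedigree, pr))
      tab <- do.call(rbind, Map(function(pr, g) data.frame(
        trait1 = pr[1], trait2 = pr[2],
        genetic_correlation = round(g$genetic_correlation, 4),
        se = round(g$genetic_correlation_se, 4)),
        config$bivariate_pairs, out))
      utils::write.table(tab, file.path(out_dir, "genetic_correlations.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      out
    })
  }

  drp <- stage("drp", {
    tab <- drp_pipeline(sim$phenotypes, sim$pedigree, vcs, traits)
    utils::write.table(tab, file.path(out_dir, "drp.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    tab
  })

  vc_of <- function(tr) as.list(vcs[[tr]]$components)
  phen_ids <- unique(as.character(sim$phenotypes$id))

  cv_results <- stage("cross_validation", {
    des <- make_cv_folds(gids, k = config$cv_k, repeats = config$cv_repeats,
                         seed = config$seed)
    rows <- list()
    for (tr in traits) {
      cors <- list(GBLUP = numeric(0), ssGBLUP = numeric(0))
      for (r in seq_len(des$repeats)) for (f in seq_len(des$k)) {
        test <- names(des$folds[[r]])[des$folds[[r]] == f]
        for (m in c("GBLUP", "ssGBLUP")) {
          pred <- run_scenario(m, test, sim$phenotypes, tr, vc_of(tr),
                               K_inv_H = kin$H_inv, G_mat = kin$Gw)
          cors[[m]] <- c(cors[[m]],
                         as.numeric(predictive_ability(pred, drp, test, tr)))
        }
      }
      for (m in names(cors)) {
        v <- cors[[m]][!is.na(cors[[m]])]
        rows[[length(rows) + 1L]] <- data.frame(
          trait = tr, method = m, scenario = "cross_validation",
          r = mean(v), se = sd(v) / sqrt(length(v)), n_folds = length(v))
      }
    }
    do.call(rbind, rows)
  })

  fwd <- stage("forward", {
    split <- forward_split(sim$pedigree, gids, phen_ids,
                           config$test_generations)
    rows <- list(); ebv_lists <- list()
    for (tr in traits) {
      test <- split$test_genotyped
      preds <- list()
      for (m in c("GBLUP", "ssGBLUP", "BLUP")) {
        preds[[m]] <- run_scenario(m, test, sim$phenotypes, tr, vc_of(tr),
                                   K_inv_H = kin$H_inv, G_mat = kin$Gw,
                                   A_inv = kin$A_inv)
      }
      for (m in c("GBLUP", "ssGBLUP")) {
        pa <- predictive_ability(preds[[m]], drp, test, tr)
        rows[[length(rows) + 1L]] <- data.frame(
          trait = tr, method = m, scenario = "forward",
          r = as.numeric(pa), se = NA_real_, n_folds = attr(pa, "n_used"))
      }
      ebv_lists[[tr]] <- data.frame(BLUP = preds$BLUP,
                                    GBLUP = preds$GBLUP,
                                    ssGBLUP = preds$ssGBLUP)
    }
    utils::write.table(split$summary,
                       file.path(out_dir, "forward_structure.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    list(results = do.call(rbind, rows), ebv_lists = ebv_lists,
         split = split)
  })

  comp <- stage("compare", {
    all_res <- rbind(cv_results, fwd$results)
    utils::write.table(all_res,
                       file.path(out_dir, "predictive_ability.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    out <- compare_methods(all_res, fwd$ebv_lists)
    utils::write.table(out$table,
                       file.path(out_dir, "method_comparison.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(out$ebv_correlations))
      utils::write.table(out$ebv_correlations,
                         file.path(out_dir, "ebv_correlations.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    out
  })
  log_line("pipeline complete")

  invisible(list(qc_report = qc$report, kinships = kin,
                 variance_components = vcs, genetic_correlations = gcors,
                 drp = drp, cv_results = cv_results,
                 forward_results = fwd$results,
                 forward_summary = fwd$split$summary,
                 comparison = comp,
                 paths = list(out_dir = out_dir, log = logfile)))
}
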
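#' Study-scale parameters for the five sperm-abnormality traits
#'
#' Variance components (additive genetic, permanent environmental,
#' residual, in squared percentage units) and the genetic correlation
#' matrix for the five sperm morphology abnormality traits: coiled tail
#' (CT), bent tail (BT), proximal droplet (PD), distal droplet (DD) and
#' distal midpiece reflex (DMR). These are the default simulation
#' truths used by [sim_config()].
#'
#' @return list with elements `components` (5 x 3 matrix, columns
#'   `sigma_a2`, `sigma_p2`, `sigma_e2`) and `correlations` (5 x 5
#'   genetic correlation matrix, unit diagonal).
#' @export
sperm_trait_params <- function() {
  tn <- c("CT", "BT", "PD", "DD", "DMR")
  comp <- matrix(c(
    0.0016, 0.0047, 0.0494,
    0.5960, 0.6929, 3.0432,
    2.5734, 3.2141, 4.7412,
    7.2729, 4.2530, 13.1157,
    2.2786, 2.8257, 3.4195), ncol = 3L, byrow = TRUE,
    dimnames = list(tn, c("sigma_a2", "sigma_p2", "sigma_e2")))
  R <- diag(5)
  dimnames(R) <- list(tn, tn)
  R["CT", "BT"] <- 0.955; R["CT", "PD"] <- 0.329
  R["CT", "DD"] <- 0.207; R["CT", "DMR"] <- 0.403
  R["BT", "PD"] <- 0.325; R["BT", "DD"] <- 0.305; R["BT", "DMR"] <- 0.378
  R["PD", "DD"] <- 0.607; R["PD", "DMR"] <- 0.052
  R["DD", "DMR"] <- 0.207
  R[lower.tri(R)] <- t(R)[lower.tri(R)]
  list(components = comp, correlations = R)
}

#' Simulation configuration
#'
#' Builds and validates the configuration driving the synthetic-data
#' generator. Defaults emulate the structure of a large boar AI-station
#' dataset: a 12-generation pedigree of roughly 5,300 animals, about
#' 1,300 phenotyped boars averaging ~22.6 repeated ejaculate records
#' each, and about a third of the animals genotyped on a ~36k-SNP
#' panel, with the five sperm-abnormality traits of
#' [sperm_trait_params()] as simulation truth.
#'
#' @param n_generations number of discrete generations (founders are
#'   generation 0).
#' @param n_founders number of founder animals (balanced sex).
#' @param n_sires_per_gen,n_dams_per_gen parents selected from the
#'   previous generation for each new generation.
#' @param offspring_per_mating litter size per mating (sexes balanced
#'   within litter).
#' @param mating `"random"` (each dam gets a random sire) or
#'   `"monogamous"` (sires and dams paired one-to-one; requires equal
#'   counts).
#' @param n_snps number of unlinked SNPs.
#' @param founder_maf_range interval in (0, 0.5] for founder minor
#'   allele frequencies.
#' @param missing_rate proportion of genotype cells set missing.
#' @param genotyping_proportion_by_generation proportion of each
#'   generation that is genotyped (scalar recycled, or one value per
#'   generation).
#' @param variance_components t x 3 matrix with columns sigma_a2,
#'   sigma_p2, sigma_e2 (one row per trait, trait units squared).
#' @param genetic_correlation_matrix t x t genetic correlation matrix
#'   (symmetric PSD, unit diagonal).
#' @param n_phenotyped number of phenotyped boars (males sampled from
#'   generations `>= phenotype_min_generation`).
#' @param phenotype_min_generation earliest generation with phenotypes.
#' @param records_per_boar_mean mean of the zero-truncated Poisson
#'   record-count distribution.
#' @param n_year_seasons number of year-season fixed-effect classes.
#' @param year_season_effect_sd SD of the year-season effects per trait
#'   (trait units); default `NULL` uses the residual SD of each trait.
#' @param age_slope,interval_slope fixed regression of the trait on boar
#'   age (per month) and collection interval (per day), per trait
#'   (recycled); defaults `NULL` use 0.01 and 0.005 residual SDs.
#' @param seed integer seed; every generator call derives its stream
#'   from it, so identical configs give identical data.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_generations = 12L,
                       n_founders = 444L,
                       n_sires_per_gen = 44L,
                       n_dams_per_gen = 220L,
                       offspring_per_mating = 2L,
                       mating = c("random", "monogamous"),
                       n_snps = 36254L,
                       founder_maf_range = c(0.05, 0.5),
                       missing_rate = 0.0014,
                       genotyping_proportion_by_generation =
                         rep(c(0.1, 0.3, 0.45), each = 4L),
                       variance_components = sperm_trait_params()$components,
                       genetic_correlation_matrix =
                         sperm_trait_params()$correlations,
                       n_phenotyped = 1304L,
                       phenotype_min_generation = 6L,
                       records_per_boar_mean = 22.6,
                       n_year_seasons = 16L,
                       year_season_effect_sd = NULL,
                       age_slope = NULL,
                       interval_slope = NULL,
                       seed = 20190710L) {
  mating <- match.arg(mating)
  variance_components <- as.matrix(variance_components)
  if (is.null(colnames(variance_components)))
    colnames(variance_components) <- c("sigma_a2", "sigma_p2", "sigma_e2")
  t <- nrow(variance_components)
  if (is.null(rownames(variance_components)))
    rownames(variance_components) <- paste0("trait", seq_len(t))
  R <- as.matrix(genetic_correlation_matrix)
  counts <- c(n_generations = n_generations, n_founders = n_founders,
              n_sires_per_gen = n_sires_per_gen,
              n_dams_per_gen = n_dams_per_gen,
              offspring_per_mating = offspring_per_mating)
  if (any(counts < 1L)) stop("all pedigree counts must be >= 1")
  if (mating == "monogamous" && n_sires_per_gen != n_dams_per_gen)
    stop("monogamous mating requires n_sires_per_gen == n_dams_per_gen")
  if (any(variance_components < 0)) stop("variance components must be >= 0")
  if (nrow(R) != t || ncol(R) != t)
    stop("genetic_correlation_matrix must be ", t, " x ", t)
  if (max(abs(R - t(R))) > 1e-10 || max(abs(diag(R) - 1)) > 1e-10)
    stop("genetic_correlation_matrix must be symmetric with unit diagonal")
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("genetic_correlation_matrix is not positive semi-definite")
  if (founder_maf_range[1] <= 0 || founder_maf_range[2] > 0.5 ||
      diff(founder_maf_range) < 0)
    stop("founder_maf_range must be an interval within (0, 0.5]")
  if (missing_rate < 0 || missing_rate > 1)
    stop("missing_rate must be in [0, 1]")
  gp <- rep_len(genotyping_proportion_by_generation, n_generations)
  if (any(gp < 0 | gp > 1))
    stop("genotyping proportions must be in [0, 1]")
  if (records_per_boar_mean <= 0) stop("records_per_boar_mean must be > 0")
  sde <- sqrt(variance_components[, "sigma_e2"])
  if (is.null(year_season_effect_sd)) year_season_effect_sd <- sde
  if (is.null(age_slope)) age_slope <- 0.01 * sde
  if (is.null(interval_slope)) interval_slope <- 0.005 * sde
  cfg <- list(n_generations = as.integer(n_generations),
              n_founders = as.integer(n_founders),
              n_sires_per_gen = as.integer(n_sires_per_gen),
              n_dams_per_gen = as.integer(n_dams_per_gen),
              offspring_per_mating = as.integer(offspring_per_mating),
              mating = mating,
              n_snps = as.integer(n_snps),
              founder_maf_range = founder_maf_range,
              missing_rate = missing_rate,
              genotyping_proportion_by_generation = gp,
              variance_components = variance_components,
              genetic_correlation_matrix = R,
              n_traits = t,
              trait_names = rownames(variance_components),
              n_phenotyped = as.integer(n_phenotyped),
              phenotype_min_generation = as.integer(phenotype_min_generation),
              records_per_boar_mean = records_per_boar_mean,
              n_year_seasons = as.integer(n_year_seasons),
              year_season_effect_sd = rep_len(year_season_effect_sd, t),
              age_slope = rep_len(age_slope, t),
              interval_slope = rep_len(interval_slope, t),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

## additive genetic covariance matrix implied by the config
sigma_a_matrix <- function(config) {
  sda <- sqrt(config$variance_components[, "sigma_a2"])
  Sa <- diag(sda, nrow = length(sda)) %*% config$genetic_correlation_matrix %*%
    diag(sda, nrow = length(sda))
  dimnames(Sa) <- list(config$trait_names, config$trait_names)
  (Sa + t(Sa)) / 2
}

#' Simulate a multi-generation pedigree
#'
#' Founders (generation 0) have unknown parents; each later generation
#' is produced by sampling sires and dams from the previous generation
#' and mating them (randomly or monogamously), with `offspring_per_mating`
#' offspring per mating and sexes balanced within litter so mating
#' pools never run dry by chance.
#'
#' @param config a [sim_config()] object.
#' @return a `pedigree` object with an extra `sex` column ("M"/"F").
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nf <- config$n_founders
  id <- as.character(seq_len(nf))
  sire <- rep(UNKNOWN, nf); dam <- rep(UNKNOWN, nf)
  gen <- rep(0L, nf)
  sex <- rep_len(c("M", "F"), nf)
  next_id <- nf + 1L
  for (g in seq_len(config$n_generations - 1L)) {
    prev <- which(gen == g - 1L)
    males <- id[prev][sex[prev] == "M"]
    females <- id[prev][sex[prev] == "F"]
    if (length(males) < config$n_sires_per_gen ||
        length(females) < config$n_dams_per_gen)
      stop("generation ", g, ": not enough candidate sires or dams")
    sires <- sample(males, config$n_sires_per_gen)
    dams <- sample(females, config$n_dams_per_gen)
    mate_sire <- if (config$mating == "monogamous") sires else
      sample(sires, length(dams), replace = TRUE)
    for (m in seq_along(dams)) {
      k <- config$offspring_per_mating
      kid_ids <- as.character(seq.int(next_id, length.out = k))
      next_id <- next_id + k
      kid_sex <- rep_len(c("M", "F"), k)
      if (k %% 2L == 1L && runif(1) < 0.5)
        kid_sex[k] <- setdiff(c("M", "F"), kid_sex[k])
      id <- c(id, kid_ids)
      sire <- c(sire, rep(mate_sire[m], k))
      dam <- c(dam, rep(dams[m], k))
      gen <- c(gen, rep(g, k))
      sex <- c(sex, kid_sex)
    }
  }
  ped <- read_and_validate_pedigree(
    data.frame(id = id, sire = sire, dam = dam, generation = gen,
               stringsAsFactors = FALSE))
  ped$sex <- sex[match(ped$id, id)]
  ped
}

#' Simulate unlinked SNP genotypes by gene dropping
#'
#' Founder haplotypes are drawn per locus at a minor allele frequency
#' uniform in `founder_maf_range` (the counted allele is the minor or
#' major allele with equal probability); descendants receive one
#' gamete from each parent with independent Mendelian segregation per
#' locus (no linkage). Genotypes for unknown parents are drawn from
#' the founder allele frequencies. Missingness is injected uniformly
#' at random at `missing_rate`.
#'
#' @param pedigree a `pedigree` from [simulate_pedigree()].
#' @param config a [sim_config()] object.
#' @param ids animals to return genotypes for; default samples each
#'   generation at `genotyping_proportion_by_generation`.
#' @return `genotype_matrix`: integer matrix (individuals x SNPs,
#'   codes 0/1/2, `NA` = missing) with attribute `truth_freq` holding
#'   the founder counted-allele frequencies.
#' @export
simulate_genotypes <- function(pedigree, config, ids = NULL) {
  stop_if_not_pedigree(pedigree)
  set.seed(config$seed + 1L)
  n <- nrow(pedigree); m <- config$n_snps
  si <- attr(pedigree, "sire_idx"); di <- attr(pedigree, "dam_idx")
  if (is.null(ids)) {
    gp <- config$genotyping_proportion_by_generation
    keep <- logical(n)
    for (g in unique(pedigree$generation)) {
      ig <- which(pedigree$generation == g)
      prop <- gp[min(g + 1L, length(gp))]
      keep[sample(ig, round(prop * length(ig)))] <- TRUE
    }
    ids <- pedigree$id[keep]
  }
  ids <- as.character(ids)
  if (!all(ids %in% pedigree$id)) stop("ids not in pedigree")
  maf <- runif(m, config$founder_maf_range[1], config$founder_maf_range[2])
  p <- ifelse(runif(m) < 0.5, maf, 1 - maf)
  H1 <- matrix(raw(1), n, m); H2 <- matrix(raw(1), n, m)
  one <- as.raw(1)
  gamete <- function(par) {
    g <- H2[par, ]
    pick <- runif(m) < 0.5
    g[pick] <- H1[par, ][pick]
    g
  }
  for (i in seq_len(n)) {
    H1[i, ] <- if (si[i] > 0L) gamete(si[i]) else as.raw(rbinom(m, 1L, p))
    H2[i, ] <- if (di[i] > 0L) gamete(di[i]) else as.raw(rbinom(m, 1L, p))
  }
  idx <- match(ids, pedigree$id)
  codes <- matrix(as.integer(H1[idx, , drop = FALSE]), length(idx), m) +
    matrix(as.integer(H2[idx, , drop = FALSE]), length(idx), m)
  if (config$missing_rate > 0) {
    nmiss <- rbinom(1L, length(codes), config$missing_rate)
    if (nmiss > 0) codes[sample(length(codes), nmiss)] <- NA_integer_
  }
  snp_ids <- sprintf("snp%0*d", nchar(m), seq_len(m))
  new_genotype_matrix(codes, ids, snp_ids, truth_freq = p)
}

#' Simulate true breeding values and permanent-environment effects
#'
#' In the default `"polygenic"` mode, founder breeding values are drawn
#' from N(0, Sigma_a) and each descendant receives the parent average
#' plus a Mendelian sampling deviation with covariance
#' `0.5 (1 - (F_s + F_d)/2) Sigma_a` (one known parent: `0.75 -
#' 0.25 F_p`; none: full Sigma_a), where Sigma_a combines the per-trait
#' additive variances with the genetic correlation matrix. This makes
#' the pedigree relationship matrix the exact covariance structure of
#' the truths. In `"markers"` mode, true breeding values are sums of
#' normally distributed SNP effects applied to centered genotype codes,
#' for marker-based recovery checks (requires genotypes covering all
#' animals). Permanent-environment effects are drawn independently per
#' animal and trait from N(0, sigma_p2).
#'
#' @param pedigree a `pedigree` object.
#' @param config a [sim_config()] object.
#' @param mode `"polygenic"` (gene-flow draws through the pedigree) or
#'   `"markers"`.
#' @param genotypes `genotype_matrix` covering every pedigree animal
#'   (markers mode only).
#' @return `sim_truth`: list with matrices `bv` and `pe` (animals x
#'   traits, rownames = ids), vector `F`, and `Sigma_a`.
#' @export
simulate_breeding_values <- function(pedigree, config,
                                     mode = c("polygenic", "markers"),
                                     genotypes = NULL) {
  stop_if_not_pedigree(pedigree)
  mode <- match.arg(mode)
  set.seed(config$seed + 2L)
  n <- nrow(pedigree); t <- config$n_traits
  Sa <- sigma_a_matrix(config)
  La <- t(chol(Sa + diag(1e-12 * max(diag(Sa)) + 1e-300, t)))
  FF <- inbreeding_coefficients(pedigree)
  bv <- matrix(0, n, t, dimnames = list(pedigree$id, config$trait_names))
  if (mode == "polygenic") {
    si <- attr(pedigree, "sire_idx"); di <- attr(pedigree, "dam_idx")
    Zd <- matrix(rnorm(n * t), n, t)
    for (i in seq_len(n)) {
      s <- si[i]; d <- di[i]
      if (s > 0L && d > 0L) {
        msv <- 0.5 * (1 - 0.5 * (FF[s] + FF[d]))
        bv[i, ] <- 0.5 * (bv[s, ] + bv[d, ]) + sqrt(msv) * (La %*% Zd[i, ])
      } else if (s > 0L || d > 0L) {
        p1 <- max(s, d)
        msv <- 0.75 - 0.25 * FF[p1]
        bv[i, ] <- 0.5 * bv[p1, ] + sqrt(msv) * (La %*% Zd[i, ])
      } else {
        bv[i, ] <- La %*% Zd[i, ]
      }
    }
  } else {
    if (is.null(genotypes) || !all(pedigree$id %in% geno_ids(genotypes)))
      stop("markers mode needs genotypes for every pedigree animal")
    M <- genotype_codes(genotypes)[pedigree$id, , drop = FALSE]
    M[is.na(M)] <- 1L
    pfrq <- colMeans(M) / 2
    Zc <- sweep(M, 2L, 2 * pfrq)
    denom <- sum(2 * pfrq * (1 - pfrq))
    if (denom <= 0) stop("no polymorphic SNPs for markers mode")
    alpha <- matrix(rnorm(ncol(M) * t), ncol(M), t) %*% t(La) / sqrt(denom)
    bv[] <- Zc %*% alpha
  }
  sdp <- sqrt(config$variance_components[, "sigma_p2"])
  pe <- matrix(rnorm(n * t), n, t) %*% diag(sdp, nrow = t)
  dimnames(pe) <- dimnames(bv)
  structure(list(bv = bv, pe = pe, F = FF, Sigma_a = Sa, mode = mode),
            class = "sim_truth")
}

## zero-truncated Poisson draws
rztpois <- function(n, lambda) {
  p0 <- stats::dpois(0, lambda)
  stats::qpois(p0 + runif(n) * (1 - p0), lambda)
}

#' Simulate repeated phenotype records
#'
#' Phenotyped boars are males from generations at or above
#' `phenotype_min_generation`, sampled down to `n_phenotyped`. Each
#' boar gets a zero-truncated Poisson number of records; each record
#' carries a year-season class (uniform), the boar's age in months
#' (entry age uniform in 8-16 months, advancing by the collection
#' interval) and the collection interval in days (3 + Poisson(4)).
#' The record value is
#' `year-season effect + age_slope * Age + interval_slope * Intv +
#'  a_i + p_i + e_ij`,
#' with `a_i`, `p_i` taken from the truth table and residuals drawn
#' independently per record and trait.
#'
#' @param pedigree a `pedigree` with a `sex` column.
#' @param truth a `sim_truth` from [simulate_breeding_values()].
#' @param config a [sim_config()] object.
#' @return `trait_dataset`: data.frame with columns `id`, `record_no`,
#'   `year_season`, `age_months`, `interval_days` and one column per
#'   trait; attributes `trait_names`, `year_season_effects` (classes x
#'   traits), `residuals` and `fixed_part` (records x traits) so the
#'   generative decomposition can be reconstructed exactly.
#' @export
simulate_phenotypes <- function(pedigree, truth, config) {
  stop_if_not_pedigree(pedigree)
  stopifnot(inherits(truth, "sim_truth"))
  set.seed(config$seed + 3L)
  t <- config$n_traits
  cand <- pedigree$id[pedigree$sex == "M" &
                        pedigree$generation >= config$phenotype_min_generation]
  if (length(cand) < config$n_phenotyped) {
    warning("only ", length(cand), " candidate boars available; using all")
    boars <- cand
  } else boars <- sort(sample(cand, config$n_phenotyped))
  nrec <- rztpois(length(boars), config$records_per_boar_mean)
  id <- rep(boars, nrec)
  record_no <- sequence(nrec)
  N <- length(id)
  year_season <- sample.int(config$n_year_seasons, N, replace = TRUE)
  interval_days <- 3 + rpois(N, 4)
  entry_age <- runif(length(boars), 8, 16)
  boar_of_rec <- rep(seq_along(boars), nrec)
  age_months <- rep(entry_age, nrec) +
    unlist(lapply(split(interval_days, boar_of_rec), cumsum),
           use.names = FALSE) / 30.44
  ys_eff <- matrix(rnorm(config$n_year_seasons * t), config$n_year_seasons, t) %*%
    diag(config$year_season_effect_sd, nrow = t)
  dimnames(ys_eff) <- list(seq_len(config$n_year_seasons), config$trait_names)
  fixed <- ys_eff[year_season, , drop = FALSE] +
    outer(age_months, config$age_slope) +
    outer(interval_days, config$interval_slope)
  sde <- sqrt(config$variance_components[, "sigma_e2"])
  resid <- matrix(rnorm(N * t), N, t) %*% diag(sde, nrow = t)
  y <- fixed + truth$bv[id, , drop = FALSE] + truth$pe[id, , drop = FALSE] +
    resid
  colnames(y) <- config$trait_names
  dat <- data.frame(id = id, record_no = record_no,
                    year_season = year_season,
                    age_months = age_months,
                    interval_days = interval_days,
                    stringsAsFactors = FALSE)
  dat <- cbind(dat, as.data.frame(y))
  rownames(dat) <- NULL
  colnames(resid) <- colnames(fixed) <- config$trait_names
  attr(dat, "trait_names") <- config$trait_names
  attr(dat, "year_season_effects") <- ys_eff
  attr(dat, "residuals") <- resid
  attr(dat, "fixed_part") <- fixed
  class(dat) <- c("trait_dataset", "data.frame")
  dat
}

#' Simulate a complete dataset
#'
#' Convenience wrapper running [simulate_pedigree()],
#' [simulate_breeding_values()], [simulate_phenotypes()] and (optionally)
#' [simulate_genotypes()] under one configuration.
#'
#' @param config a [sim_config()] object.
#' @param genotypes simulate genotypes too (can be slow/large at the
#'   full default SNP count).
#' @return list with elements `pedigree`, `truth`, `phenotypes` and
#'   optionally `genotypes`.
#' @export
simulate_dataset <- function(config = sim_config(), genotypes = FALSE) {
  ped <- simulate_pedigree(config)
  truth <- simulate_breeding_values(ped, config)
  phen <- simulate_phenotypes(ped, truth, config)
  out <- list(pedigree = ped, truth = truth, phenotypes = phen)
  if (genotypes) out$genotypes <- simulate_genotypes(ped, config)
  out
}
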
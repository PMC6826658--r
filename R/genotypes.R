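#' Genotype matrix container
#'
#' Wraps an individuals x SNPs integer matrix of additive codes
#' (0/1/2, `NA` = missing) together with its id and SNP indexes. The
#' row (id) order is the canonical "genotyped" order used by A22, G and
#' the H-inverse assembly.
#'
#' @param codes integer matrix, individuals in rows.
#' @param ids character vector of individual ids (rownames).
#' @param snp_ids character vector of SNP names (colnames).
#' @param truth_freq optional simulation-truth allele frequencies.
#' @return object of class `genotype_matrix`.
#' @export
new_genotype_matrix <- function(codes, ids = rownames(codes),
                                snp_ids = colnames(codes),
                                truth_freq = NULL) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  bad <- !is.na(codes) & !(codes %in% 0:2)
  if (any(bad)) stop("genotype codes must be 0, 1, 2 or NA")
  if (is.null(ids)) ids <- paste0("ind", seq_len(nrow(codes)))
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(ncol(codes)))
  dimnames(codes) <- list(as.character(ids), as.character(snp_ids))
  structure(list(codes = codes, truth_freq = truth_freq),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d SNPs (%.3f%% missing)\n",
              nrow(x$codes), ncol(x$codes),
              100 * mean(is.na(x$codes))))
  invisible(x)
}

#' @rdname new_genotype_matrix
#' @param x a `genotype_matrix`.
#' @export
genotype_codes <- function(x) {
  stopifnot(inherits(x, "genotype_matrix"))
  x$codes
}

#' @rdname new_genotype_matrix
#' @export
geno_ids <- function(x) rownames(genotype_codes(x))

#' Exact Hardy-Weinberg equilibrium test for one SNP
#'
#' Conditional exact test on the genotype counts (AA, Aa, aa): given
#' the observed allele counts, sums the probabilities of all
#' heterozygote-count configurations whose probability does not exceed
#' that of the observed configuration. A chi-square (1 df, no
#' continuity correction) variant is available via `method`.
#'
#' @param n_AA,n_Aa,n_aa non-negative genotype counts.
#' @param method `"exact"` or `"chisq"`.
#' @return p-value. Monomorphic SNPs (and all-zero counts, with a
#'   warning) return 1.
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa, method = c("exact", "chisq")) {
  method <- match.arg(method)
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("counts must be non-negative")
  n <- n_AA + n_Aa + n_aa
  if (n == 0L) {
    warning("all genotype counts are zero; HWE undefined, returning p = 1")
    return(1)
  }
  nA <- 2L * n_AA + n_Aa
  na <- 2L * n_aa + n_Aa
  if (nA == 0L || na == 0L) return(1)  # monomorphic: single configuration
  if (method == "chisq") {
    p <- nA / (2 * n)
    e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
    x2 <- sum((c(n_AA, n_Aa, n_aa) - e)^2 / e)
    return(stats::pchisq(x2, df = 1L, lower.tail = FALSE))
  }
  rare <- min(nA, na)
  ## possible heterozygote counts share the parity of the rare allele count
  het <- seq.int(rare %% 2L, rare, by = 2L)
  ## log-probability of each configuration (hypergeometric-type kernel)
  lp <- lfactorial(n) - lfactorial((nA - het) / 2) - lfactorial(het) -
    lfactorial((na - het) / 2) + het * log(2) +
    lfactorial(nA) + lfactorial(na) - lfactorial(2L * n)
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  p_obs <- pr[match(n_Aa, het)]
  min(1, sum(pr[pr <= p_obs + 1e-12]))
}

#' Genotype quality control
#'
#' Applies the standard pre-analysis filters in a fixed order, each on
#' the matrix surviving the previous step: individual call rate,
#' SNP call rate, minor allele frequency, and Hardy-Weinberg exact-test
#' p-value. The MAF filter uses the folded (minor) allele frequency
#' computed from non-missing calls.
#'
#' @param genotypes a `genotype_matrix`.
#' @param ind_call minimum individual call rate (default 0.90).
#' @param snp_call minimum SNP call rate (default 0.90).
#' @param maf minimum minor allele frequency (default 0.01).
#' @param hwe_p minimum HWE p-value (default 1e-5).
#' @param hwe_method passed to [hwe_exact_test()].
#' @return list with the filtered `genotype_matrix` (`genotypes`) and a
#'   `qc_report`: thresholds, per-step removal counts, and surviving
#'   dimensions.
#' @export
qc_filter <- function(genotypes, ind_call = 0.90, snp_call = 0.90,
                      maf = 0.01, hwe_p = 1e-5,
                      hwe_method = c("exact", "chisq")) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  hwe_method <- match.arg(hwe_method)
  M <- genotype_codes(genotypes)
  n0 <- nrow(M); m0 <- ncol(M)
  removed <- c(ind_call = 0L, snp_call = 0L, maf = 0L, hwe = 0L)

  cr_i <- rowMeans(!is.na(M))
  keep_i <- cr_i >= ind_call
  removed["ind_call"] <- sum(!keep_i)
  M <- M[keep_i, , drop = FALSE]
  if (nrow(M) == 0L) stop("QC removed all individuals (call rate)")

  cr_s <- colMeans(!is.na(M))
  keep_s <- cr_s >= snp_call
  removed["snp_call"] <- sum(!keep_s)
  M <- M[, keep_s, drop = FALSE]

  p <- colMeans(M, na.rm = TRUE) / 2
  keep_s <- pmin(p, 1 - p) >= maf & !is.na(p)
  removed["maf"] <- sum(!keep_s)
  M <- M[, keep_s, drop = FALSE]

  if (ncol(M)) {
    nAA <- colSums(M == 2L, na.rm = TRUE)
    nAa <- colSums(M == 1L, na.rm = TRUE)
    naa <- colSums(M == 0L, na.rm = TRUE)
    pv <- vapply(seq_len(ncol(M)), function(j)
      hwe_exact_test(nAA[j], nAa[j], naa[j], method = hwe_method), 0)
    keep_s <- pv >= hwe_p
    removed["hwe"] <- sum(!keep_s)
    M <- M[, keep_s, drop = FALSE]
  }
  if (ncol(M) == 0L) stop("QC removed all SNPs")

  report <- structure(list(
    thresholds = c(ind_call = ind_call, snp_call = snp_call,
                   maf = maf, hwe_p = hwe_p),
    removed = removed,
    input = c(individuals = n0, snps = m0),
    surviving = c(individuals = nrow(M), snps = ncol(M))),
    class = "qc_report")
  list(genotypes = new_genotype_matrix(M), report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("genotype QC report\n")
  cat(sprintf("  input:    %d individuals x %d SNPs\n",
              x$input["individuals"], x$input["snps"]))
  cat(sprintf("  removed:  %d individuals (call rate < %.2f)\n",
              x$removed["ind_call"], x$thresholds["ind_call"]))
  cat(sprintf("            %d SNPs (call rate), %d (MAF), %d (HWE)\n",
              x$removed["snp_call"], x$removed["maf"], x$removed["hwe"]))
  cat(sprintf("  survive:  %d individuals x %d SNPs\n",
              x$surviving["individuals"], x$surviving["snps"]))
  invisible(x)
}

#' Replace missing genotypes with heterozygotes
#'
#' Sets every missing genotype code to 1. Intended for panels with a
#' very low missing rate where model-based imputation is not
#' worthwhile; apply after [qc_filter()].
#'
#' @param genotypes a `genotype_matrix`.
#' @return a `genotype_matrix` with no missing codes.
#' @export
fill_missing_as_heterozygote <- function(genotypes) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  M <- genotype_codes(genotypes)
  M[is.na(M)] <- 1L
  new_genotype_matrix(M, truth_freq = genotypes$truth_freq)
}
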
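#' Genomic relationship matrix (VanRaden)
#'
#' Centers genotype codes at twice the allele frequency of the counted
#' allele (codes 0, 1, 2 become -2p, 1-2p, 2-2p) and scales the
#' cross-product by the sum of locus variances:
#' `G = Z Z' / sum_i 2 p_i (1 - p_i)`.
#' Frequencies are, by default, observed in the matrix itself; a
#' supplied frequency vector (e.g. base-population frequencies) can be
#' used instead. With `fold = TRUE` the folded (minor) frequency is
#' used for the centering, for sensitivity checks only; the default
#' unfolded centering is what keeps G invariant to allele-label swaps.
#'
#' @param genotypes a `genotype_matrix` with no missing codes (run
#'   [fill_missing_as_heterozygote()] first) and no monomorphic SNPs.
#' @param freq_source `"observed"` or `"supplied"`.
#' @param freq counted-allele frequencies when `freq_source =
#'   "supplied"`.
#' @param fold use folded minor-allele frequencies for centering.
#' @return dense `rel_matrix` with role `"G"`.
#' @export
build_G <- function(genotypes, freq_source = c("observed", "supplied"),
                    freq = NULL, fold = FALSE) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  freq_source <- match.arg(freq_source)
  M <- genotype_codes(genotypes)
  if (anyNA(M))
    stop("missing genotype codes remain; run fill_missing_as_heterozygote")
  p <- if (freq_source == "observed") colMeans(M) / 2 else {
    if (is.null(freq) || length(freq) != ncol(M))
      stop("supplied freq must have one value per SNP")
    as.numeric(freq)
  }
  if (fold) p <- pmin(p, 1 - p)
  denom <- sum(2 * p * (1 - p))
  if (denom <= 0) stop("zero denominator: all SNPs monomorphic")
  Z <- sweep(M, 2L, 2 * p)
  G <- tcrossprod(Z) / denom
  new_rel_matrix((G + t(G)) / 2, rownames(M), "G")
}

#' Blend G with the pedigree submatrix A22
#'
#' Elementwise weighted average `Gw = w G + (1 - w) A22`, used both to
#' guarantee invertibility and to acknowledge that markers do not
#' capture all polygenic variation. The default weight w = 0.9 is the
#' conventional choice.
#'
#' @param G dense `rel_matrix` with role `"G"`.
#' @param A22 dense `rel_matrix` with role `"A22"`, same ids in the
#'   same order.
#' @param w blend weight on G, in (0, 1].
#' @return dense `rel_matrix` with role `"G_blended"`.
#' @export
blend_G <- function(G, A22, w = 0.9) {
  if (w <= 0 || w > 1) stop("blend weight w must be in (0, 1]")
  ids <- rel_ids(G)
  if (!identical(ids, rel_ids(A22)))
    stop("G and A22 id orders differ; reorder before blending")
  Gw <- w * rel_mat(G) + (1 - w) * rel_mat(A22)
  new_rel_matrix(Gw, ids, "G_blended")
}

## symmetric inverse with a logged jitter fallback
sym_inverse <- function(M, label) {
  if (inherits(M, "rel_matrix")) M <- rel_mat(M)
  M <- as.matrix(M)
  M <- (M + t(M)) / 2
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(ch)) {
    message(label, " not positive definite; adding 1e-8 jitter to diagonal")
    ch <- tryCatch(chol(M + diag(1e-8, nrow(M))), error = function(e) NULL)
    if (is.null(ch))
      stop(label, " is singular even after jitter; consider blending")
  }
  chol2inv(ch)
}

#' Assemble the single-step H-inverse
#'
#' Combines pedigree and genomic information as
#' `H^-1 = A^-1 + [0 0; 0 Gw^-1 - A22^-1]`,
#' with the correction added into the genotyped block of the
#' pedigree-ordered matrix. The correction is exactly zero outside the
#' genotyped block, so H-inverse stays sparse apart from that dense
#' block.
#'
#' @param A_inv sparse `rel_matrix` with role `"A_inverse"` (full
#'   pedigree order).
#' @param A22 dense `rel_matrix` for the genotyped animals.
#' @param Gw dense `rel_matrix` (blended G), same ids/order as `A22`.
#' @param genotyped_index positions of the genotyped animals within
#'   the pedigree order of `A_inv`; defaults to matching ids.
#' @return sparse symmetric `rel_matrix` with role `"H_inverse"`.
#' @export
build_H_inverse <- function(A_inv, A22, Gw, genotyped_index = NULL) {
  ids <- rel_ids(A_inv)
  Am <- methods::as(rel_mat(A_inv), "CsparseMatrix")
  if (is.null(Gw) || length(rel_ids(Gw)) == 0L)
    return(new_rel_matrix(Matrix::forceSymmetric(Am), ids, "H_inverse"))
  gids <- rel_ids(Gw)
  if (!identical(gids, rel_ids(A22)))
    stop("Gw and A22 id orders differ")
  if (is.null(genotyped_index)) genotyped_index <- match(gids, ids)
  if (anyNA(genotyped_index))
    stop("genotyped ids missing from the pedigree relationship inverse")
  corr <- sym_inverse(Gw, "Gw") - sym_inverse(A22, "A22")
  ng <- length(genotyped_index)
  Cs <- Matrix::sparseMatrix(
    i = rep(genotyped_index, times = ng),
    j = rep(genotyped_index, each = ng),
    x = as.numeric(corr), dims = dim(Am))
  H <- Am + Cs
  H <- Matrix::forceSymmetric((H + Matrix::t(H)) / 2)
  new_rel_matrix(methods::as(H, "CsparseMatrix"), ids, "H_inverse")
}
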
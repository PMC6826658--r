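#' Parent averages and their reliabilities
#'
#' For every animal with both parents known, computes the parent
#' average `PA = (EBV_sire + EBV_dam)/2` and its reliability
#' `r2_PA = (r2_sire + r2_dam)/4`. Animals with any unknown parent are
#' excluded and listed.
#'
#' @param ebv_table data.frame with columns `id`, `ebv`,
#'   `reliability` covering every pedigree animal (e.g. built from an
#'   `mme_solution`).
#' @param pedigree a `pedigree` object.
#' @return data.frame `id`, `pa`, `r2_pa` for eligible animals, with
#'   attribute `excluded` listing ids with unknown parents.
#' @export
parent_average <- function(ebv_table, pedigree) {
  stop_if_not_pedigree(pedigree)
  ebv_table <- as.data.frame(ebv_table)
  ix <- match(pedigree$id, as.character(ebv_table$id))
  if (anyNA(ix))
    stop("ebv_table must cover every pedigree animal; missing: ",
         paste(head(pedigree$id[is.na(ix)], 10L), collapse = ", "))
  ebv <- ebv_table$ebv[ix]
  rel <- ebv_table$reliability[ix]
  si <- attr(pedigree, "sire_idx"); di <- attr(pedigree, "dam_idx")
  ok <- si > 0L & di > 0L
  out <- data.frame(id = pedigree$id[ok],
                    pa = (ebv[si[ok]] + ebv[di[ok]]) / 2,
                    r2_pa = (rel[si[ok]] + rel[di[ok]]) / 4,
                    stringsAsFactors = FALSE)
  attr(out, "excluded") <- pedigree$id[!ok]
  out
}

#' De-regress EBVs with parent-average removal (Garrick)
#'
#' Converts an EBV and its reliability into a de-regressed proof (DRP)
#' with the parent-average contribution removed, following the
#' information-splitting recipe of Garrick and colleagues. With
#' `lambda = (1 - h2)/h2`, `alpha = 1/(0.5 - r2_PA)` and
#' `delta = (0.5 - r2_PA)/(1 - r2_i)`:
#' \deqn{Z'Z_{PA} = \lambda(0.5\alpha - 4) +
#'       0.5\lambda\sqrt{\alpha^2 + 16/\delta}}
#' \deqn{Z'Z_i = \delta Z'Z_{PA} + 2\lambda(2\delta - 1)}
#' the right-hand sides are recovered from the 2 x 2 system
#' `[Z'Z_PA + 4 lambda, -2 lambda; -2 lambda, Z'Z_i + 2 lambda]
#'  [PA; EBV] = [y_PA; y_i]`,
#' and `DRP = y_i / Z'Z_i` with reliability
#' `r2_DRP = 1 - lambda/(Z'Z_i + lambda)`. A weight for weighted
#' downstream analyses, `w = (1 - h2) / ((c + (1 - r2_DRP)/r2_DRP)
#' h2)`, is stored but not used by the package's own predictive-ability
#' correlations.
#'
#' Records violating the preconditions `r2_i > r2_PA`, `r2_PA < 0.5`
#' are skipped (DRP set `NA`) with a reason code rather than clamped.
#'
#' @param ebv_i,r2_i EBV and reliability of the individual(s)
#'   (vectorized).
#' @param PA,r2_PA parent average and its reliability.
#' @param h2 trait heritability in (0, 1).
#' @param c_genomic proportion of genetic variance not captured by the
#'   information source, used only in the stored weight.
#' @return data.frame with `drp`, `r2_drp`, `ztz_i`, `weight`,
#'   `excluded_reason` (`NA` when the record is valid).
#' @export
garrick_deregress <- function(ebv_i, r2_i, PA, r2_PA, h2,
                              c_genomic = 0.5) {
  if (h2 <= 0 || h2 >= 1) stop("h2 must be in (0, 1)")
  nrec <- length(ebv_i)
  stopifnot(length(r2_i) == nrec, length(PA) == nrec, length(r2_PA) == nrec)
  reason <- rep(NA_character_, nrec)
  reason[r2_i <= r2_PA] <- "individual_reliability_<=_parent_average"
  reason[r2_i >= 1] <- "individual_reliability_>=_1"
  reason[r2_PA >= 0.5] <- "parent_average_reliability_>=_0.5"
  ok <- is.na(reason)
  lambda <- (1 - h2) / h2
  drp <- r2_drp <- ztz_i <- weight <- rep(NA_real_, nrec)
  if (any(ok)) {
    alpha <- 1 / (0.5 - r2_PA[ok])
    delta <- (0.5 - r2_PA[ok]) / (1 - r2_i[ok])
    ztz_pa <- lambda * (0.5 * alpha - 4) +
      0.5 * lambda * sqrt(alpha^2 + 16 / delta)
    zi <- delta * ztz_pa + 2 * lambda * (2 * delta - 1)
    y_pa <- (ztz_pa + 4 * lambda) * PA[ok] - 2 * lambda * ebv_i[ok]
    y_i <- -2 * lambda * PA[ok] + (zi + 2 * lambda) * ebv_i[ok]
    drp[ok] <- y_i / zi
    r2_drp[ok] <- 1 - lambda / (zi + lambda)
    ztz_i[ok] <- zi
    weight[ok] <- (1 - h2) /
      ((c_genomic + (1 - r2_drp[ok]) / r2_drp[ok]) * h2)
  }
  data.frame(drp = drp, r2_drp = r2_drp, ztz_i = ztz_i, weight = weight,
             excluded_reason = reason, stringsAsFactors = FALSE)
}

#' Full de-regression pipeline
#'
#' For each trait: solves the pedigree-based repeatability BLUP on the
#' full dataset (DRPs are the fixed evaluation currency, so phenotypes
#' are never masked here), converts prediction error variances into
#' reliabilities, computes parent averages, and de-regresses every
#' animal with both parents known. The trait heritability used in the
#' de-regression is taken from the supplied variance components.
#'
#' @param dataset a `trait_dataset` with the traits' records.
#' @param pedigree a `pedigree` object.
#' @param vc named list (one element per trait) of variance
#'   components: either `variance_components` objects or lists with
#'   `sigma_a2`, `sigma_p2`, `sigma_e2`.
#' @param traits trait column names; default = names of `vc`.
#' @return data.frame with one row per pedigree animal per trait:
#'   `id`, `trait`, `ebv`, `reliability`, `pa`, `r2_pa`, `drp`,
#'   `r2_drp`, `weight`, `excluded_reason`.
#' @export
drp_pipeline <- function(dataset, pedigree, vc, traits = names(vc)) {
  stop_if_not_pedigree(pedigree)
  A_inv <- build_A_inverse(pedigree)
  out <- list()
  for (tr in traits) {
    v <- vc[[tr]]
    comps <- if (inherits(v, "variance_components"))
      as.list(v$components) else as.list(v)
    h2 <- comps$sigma_a2 /
      (comps$sigma_a2 + comps$sigma_p2 + comps$sigma_e2)
    sol <- fit_blup(dataset, tr, A_inv, comps, pev = TRUE)
    etab <- data.frame(id = names(sol$ebv), ebv = as.numeric(sol$ebv),
                       reliability = as.numeric(sol$reliability),
                       stringsAsFactors = FALSE)
    pa <- parent_average(etab, pedigree)
    m <- match(pa$id, etab$id)
    dr <- garrick_deregress(etab$ebv[m], etab$reliability[m],
                            pa$pa, pa$r2_pa, h2)
    res <- data.frame(id = pa$id, trait = tr,
                      ebv = etab$ebv[m], reliability = etab$reliability[m],
                      pa = pa$pa, r2_pa = pa$r2_pa,
                      dr, stringsAsFactors = FALSE)
    ## founders / unknown-parent animals enter the exclusion log
    exc <- attr(pa, "excluded")
    if (length(exc)) {
      me <- match(exc, etab$id)
      res <- rbind(res, data.frame(
        id = exc, trait = tr, ebv = etab$ebv[me],
        reliability = etab$reliability[me],
        pa = NA_real_, r2_pa = NA_real_, drp = NA_real_,
        r2_drp = NA_real_, ztz_i = NA_real_, weight = NA_real_,
        excluded_reason = "unknown_parent", stringsAsFactors = FALSE))
    }
    out[[tr]] <- res
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
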
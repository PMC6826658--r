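## Independent oracles used across the suite. These deliberately take
## different algorithmic routes from the package implementations.

## recursive (memoised, top-down) additive relationship -- checks the
## bottom-up tabular method
kinship_oracle <- function(ped) {
  si <- attr(ped, "sire_idx"); di <- attr(ped, "dam_idx")
  memo <- new.env(parent = emptyenv())
  rel <- function(i, j) {
    if (i == 0L || j == 0L) return(0)
    key <- paste(min(i, j), max(i, j))
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (i == j) {
      1 + 0.5 * rel(si[i], di[i])
    } else {
      ## recurse on the later-born animal
      if (i < j) { tmp <- i; i <- j; j <- tmp }
      0.5 * (rel(j, si[i]) + rel(j, di[i]))
    }
    memo[[key]] <- val
    val
  }
  function(i, j) rel(i, j)
}

dense_A_oracle <- function(ped) {
  n <- nrow(ped)
  f <- kinship_oracle(ped)
  outer(seq_len(n), seq_len(n), Vectorize(f))
}

## direct GLS/BLUP through the dense phenotypic covariance matrix
gls_oracle <- function(X, Z, W, y, K, vc) {
  X <- as.matrix(X); Z <- as.matrix(Z)
  n <- length(y)
  V <- Z %*% K %*% t(Z) * vc$sigma_a2 + diag(n) * vc$sigma_e2
  if (!is.null(W)) {
    W <- as.matrix(W)
    V <- V + W %*% t(W) * vc$sigma_p2
  }
  Vi <- solve(V)
  b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  a <- vc$sigma_a2 * K %*% t(Z) %*% Vi %*% (y - X %*% b)
  p <- if (!is.null(W)) vc$sigma_p2 * t(W) %*% Vi %*% (y - X %*% b) else NULL
  list(b = as.numeric(b), a = as.numeric(a), p = as.numeric(p))
}

## full enumeration of the conditional heterozygote distribution,
## using plain factorials (small counts only)
hwe_enum_oracle <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa; na <- 2 * naa + nAa
  if (nA == 0 || na == 0) return(1)
  hs <- seq(min(nA, na) %% 2, min(nA, na), by = 2)
  pr <- sapply(hs, function(h) {
    factorial(n) / (factorial((nA - h) / 2) * factorial(h) *
                      factorial((na - h) / 2)) * 2^h
  })
  pr <- pr / sum(pr)
  sum(pr[pr <= pr[match(nAa, hs)] + 1e-12])
}

## shrinking-grid maximizer of the dense restricted likelihood
grid_search_reml <- function(y, X, V_parts, start, rounds = 6L,
                             span = 0.8, pts = 7L) {
  best <- start
  for (r in seq_len(rounds)) {
    grids <- lapply(best, function(th)
      seq(th * (1 - span), th * (1 + span), length.out = pts))
    cand <- as.matrix(expand.grid(grids))
    cand <- cand[apply(cand > 0, 1L, all), , drop = FALSE]
    ll <- apply(cand, 1L, function(th)
      tryCatch(reml_loglik(y, X, V_parts, th), error = function(e) -Inf))
    best <- as.numeric(cand[which.max(ll), ])
    span <- span / 2.5
  }
  best
}

## small random pedigree builder for property-style loops
random_pedigree <- function(n, n_founders = 6L, seed = 1L) {
  set.seed(seed)
  id <- as.character(seq_len(n))
  sire <- dam <- rep("0", n)
  sex <- rep_len(c("M", "F"), n)
  for (i in seq.int(n_founders + 1L, n)) {
    males <- which(sex[seq_len(i - 1L)] == "M")
    females <- which(sex[seq_len(i - 1L)] == "F")
    sire[i] <- id[sample(males, 1L)]
    dam[i] <- id[sample(females, 1L)]
  }
  read_and_validate_pedigree(
    data.frame(id = id, sire = sire, dam = dam, stringsAsFactors = FALSE))
}

## compact simulated dataset for MME / evaluation tests
small_sim <- function(seed = 21L, n_snps = 400L, missing_rate = 0,
                      gprop = c(0, 0.4, 0.6, 0.8)) {
  cfg <- sim_config(n_generations = 4L, n_founders = 12L,
                    n_sires_per_gen = 3L, n_dams_per_gen = 6L,
                    offspring_per_mating = 2L, n_snps = n_snps,
                    genotyping_proportion_by_generation = gprop,
                    n_phenotyped = 18L, phenotype_min_generation = 1L,
                    records_per_boar_mean = 4, missing_rate = missing_rate,
                    n_year_seasons = 4L, seed = seed)
  suppressWarnings(simulate_dataset(cfg, genotypes = TRUE))
}
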
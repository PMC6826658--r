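#' @importFrom methods as is
#' @importFrom stats rnorm runif rbinom rpois var sd cor setNames
#' @importFrom utils read.csv write.csv head
NULL

UNKNOWN <- "0"

#' Construct and validate a pedigree
#'
#' Takes a table with columns `id`, `sire`, `dam` and optionally
#' `generation`, validates it and returns a topologically sorted
#' `pedigree` object in which every parent precedes its offspring.
#' Unknown parents are coded `"0"` (the conventional pedigree-file
#' sentinel); `NA` and the empty string are accepted on input and mapped
#' to `"0"`.
#'
#' Validation checks that ids are unique, that every named parent is
#' itself listed as an animal, and that the parent graph is acyclic
#' (an animal can never be its own ancestor). An id that is used both
#' as a sire and as a dam triggers a warning, since it usually signals
#' a recording error.
#'
#' @param table data.frame with 3 or 4 columns: id, sire, dam and
#'   optionally generation. Extra columns are ignored.
#' @return A `pedigree` object: a data.frame with character columns
#'   `id`, `sire`, `dam` and integer `generation`, sorted parents-first,
#'   with integer attributes `sire_idx` and `dam_idx` (0 = unknown).
#' @examples
#' ped <- read_and_validate_pedigree(data.frame(
#'   id = c("kid", "s", "d"), sire = c("s", "0", "0"),
#'   dam = c("d", "0", "0")))
#' ped$id  # parents first
#' @export
read_and_validate_pedigree <- function(table) {
  table <- as.data.frame(table)
  if (ncol(table) < 3L)
    stop("pedigree table needs at least columns id, sire, dam")
  id   <- as.character(table[[1L]])
  sire <- as.character(table[[2L]])
  dam  <- as.character(table[[3L]])
  sire[is.na(sire) | sire == ""] <- UNKNOWN
  dam[is.na(dam) | dam == ""]    <- UNKNOWN
  if (anyDuplicated(id))
    stop("duplicated animal ids: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  if (any(id == UNKNOWN))
    stop("animal id equal to the unknown-parent sentinel \"0\"")
  known_par <- c(sire[sire != UNKNOWN], dam[dam != UNKNOWN])
  missing_par <- setdiff(known_par, id)
  if (length(missing_par))
    stop("parents not listed as animals: ",
         paste(head(missing_par, 10L), collapse = ", "))
  both <- intersect(sire[sire != UNKNOWN], dam[dam != UNKNOWN])
  if (length(both))
    warning("id(s) used both as sire and as dam: ",
            paste(both, collapse = ", "))

  n <- length(id)
  si <- match(sire, id, nomatch = 0L)
  di <- match(dam, id, nomatch = 0L)

  ## Kahn topological sort over the parent -> offspring graph
  indeg <- (si > 0L) + (di > 0L)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    if (si[i] > 0L) children[[si[i]]] <- c(children[[si[i]]], i)
    if (di[i] > 0L) children[[di[i]]] <- c(children[[di[i]]], i)
  }
  queue <- which(indeg == 0L)
  order <- integer(0L)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    order <- c(order, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) < n) {
    cyc <- id[indeg > 0L]
    stop("pedigree contains a cycle involving: ",
         paste(head(cyc, 10L), collapse = ", "))
  }

  id <- id[order]; sire <- sire[order]; dam <- dam[order]
  si <- match(sire, id, nomatch = 0L)
  di <- match(dam, id, nomatch = 0L)

  if (ncol(table) >= 4L && is.numeric(table[[4L]])) {
    generation <- as.integer(table[[4L]])[order]
  } else {
    generation <- integer(n)
    for (i in seq_len(n)) {
      pg <- c(if (si[i] > 0L) generation[si[i]],
              if (di[i] > 0L) generation[di[i]])
      generation[i] <- if (length(pg)) max(pg) + 1L else 0L
    }
  }

  ped <- data.frame(id = id, sire = sire, dam = dam,
                    generation = generation, stringsAsFactors = FALSE)
  attr(ped, "sire_idx") <- si
  attr(ped, "dam_idx") <- di
  class(ped) <- c("pedigree", "data.frame")
  ped
}

#' @export
print.pedigree <- function(x, ...) {
  si <- attr(x, "sire_idx"); di <- attr(x, "dam_idx")
  cat(sprintf("pedigree: %d animals, %d founders, generations 0-%d\n",
              nrow(x), sum(si == 0L & di == 0L), max(x$generation)))
  NextMethod()
}

is_pedigree <- function(x) inherits(x, "pedigree")

stop_if_not_pedigree <- function(x) {
  if (!is_pedigree(x))
    stop("expected a 'pedigree' object (see read_and_validate_pedigree)")
  invisible(x)
}

#' Inbreeding coefficients by the Meuwissen-Luo recursion
#'
#' Computes per-animal inbreeding coefficients F without forming the
#' dense relationship matrix, by accumulating the L D L' decomposition
#' of A over each animal's ancestor set (Meuwissen & Luo style).
#' Founders and animals with any unknown parent have F = 0.
#'
#' @param pedigree a `pedigree` object.
#' @return named numeric vector of F, in pedigree order.
#' @export
inbreeding_coefficients <- function(pedigree) {
  stop_if_not_pedigree(pedigree)
  n <- nrow(pedigree)
  si <- attr(pedigree, "sire_idx"); di <- attr(pedigree, "dam_idx")
  FF <- numeric(n)
  ## D_j = Mendelian sampling variance scale for animal j
  dvec <- function(j) {
    fs <- if (si[j] > 0L) FF[si[j]] else -1
    fd <- if (di[j] > 0L) FF[di[j]] else -1
    ## unknown parent contributes as F = -1 in the 0.5 - 0.25(Fs+Fd)
    ## expression, reproducing 0.75 / 1 for one / both parents unknown
    0.5 - 0.25 * (fs + fd)
  }
  v <- numeric(n)
  for (i in seq_len(n)) {
    if (si[i] == 0L || di[i] == 0L) next  # F = 0
    ## accumulate A_ii = sum_j L_ij^2 D_j over ancestors of i
    v[i] <- 1
    aii <- 0
    for (j in i:1L) {
      if (v[j] == 0) next
      aii <- aii + v[j] * v[j] * dvec(j)
      if (si[j] > 0L) v[si[j]] <- v[si[j]] + 0.5 * v[j]
      if (di[j] > 0L) v[di[j]] <- v[di[j]] + 0.5 * v[j]
      v[j] <- 0
    }
    FF[i] <- aii - 1
  }
  names(FF) <- pedigree$id
  FF
}

#' Relationship matrix container
#'
#' A relationship matrix (dense base matrix or sparse `Matrix`)
#' together with its ordered id index and a role tag saying what it
#' is: `"A"`, `"A_inverse"`, `"A22"`, `"G"`, `"G_blended"` or
#' `"H_inverse"`.
#'
#' @param m square matrix (base or `Matrix`).
#' @param ids character id index, one per row/column.
#' @param role role tag.
#' @return object of class `rel_matrix` with elements `mat`, `ids`,
#'   `role`.
#' @export
new_rel_matrix <- function(m, ids, role) {
  ids <- as.character(ids)
  stopifnot(nrow(m) == length(ids), ncol(m) == length(ids))
  dimnames(m) <- list(ids, ids)
  structure(list(mat = m, ids = ids, role = role), class = "rel_matrix")
}

#' @rdname new_rel_matrix
#' @param x a `rel_matrix`.
#' @export
rel_mat <- function(x) {
  stopifnot(inherits(x, "rel_matrix"))
  x$mat
}

#' @rdname new_rel_matrix
#' @export
rel_ids <- function(x) {
  stopifnot(inherits(x, "rel_matrix"))
  x$ids
}

#' @rdname new_rel_matrix
#' @export
rel_role <- function(x) {
  stopifnot(inherits(x, "rel_matrix"))
  x$role
}

#' @export
print.rel_matrix <- function(x, ...) {
  cat(sprintf("relationship matrix [%s]: %d x %d (%s)\n",
              x$role, nrow(x$mat), ncol(x$mat),
              if (methods::is(x$mat, "sparseMatrix")) "sparse" else "dense"))
  k <- min(5L, nrow(x$mat))
  print(as.matrix(x$mat[seq_len(k), seq_len(k), drop = FALSE]))
  invisible(x)
}

#' Numerator relationship matrix A (tabular method)
#'
#' Builds the dense pedigree relationship matrix by the tabular
#' recurrence: A(i,j) = 0.5 (A(j, sire_i) + A(j, dam_i)) for j earlier
#' than i, and A(i,i) = 1 + 0.5 A(sire_i, dam_i); unknown parents
#' contribute zero. Diagonals equal 1 + F.
#'
#' @param pedigree a `pedigree` object (topologically sorted).
#' @param max_n refuse to build a dense matrix above this many animals.
#' @return a dense `rel_matrix` with role `"A"`.
#' @export
build_A <- function(pedigree, max_n = 8000L) {
  stop_if_not_pedigree(pedigree)
  n <- nrow(pedigree)
  if (n > max_n)
    stop("pedigree has ", n, " animals; dense A capped at ", max_n,
         " (raise max_n or use build_A_inverse / extract_A22)")
  si <- attr(pedigree, "sire_idx"); di <- attr(pedigree, "dam_idx")
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      aj <- numeric(i - 1L)
      if (s > 0L) aj <- aj + A[j, s]
      if (d > 0L) aj <- aj + A[j, d]
      aj <- 0.5 * aj
      A[j, i] <- aj
      A[i, j] <- aj
    }
    A[i, i] <- 1 + if (s > 0L && d > 0L) 0.5 * A[s, d] else 0
  }
  new_rel_matrix(A, pedigree$id, "A")
}

#' Sparse inverse of A by Henderson's rules
#'
#' Assembles A-inverse directly from the pedigree using Henderson's
#' rules. With `use_inbreeding = TRUE` (default) the Mendelian sampling
#' variance is d_i = 0.5 - 0.25 (F_s + F_d) from
#' [inbreeding_coefficients()]; with `FALSE` the classical no-inbreeding
#' approximation is used. Unknown parents contribute as the population
#' mean (d adjusted to 0.75 / 1 for one / both parents unknown).
#'
#' @param pedigree a `pedigree` object.
#' @param use_inbreeding account for inbreeding in the Mendelian
#'   sampling variances (exact inverse of the tabular A).
#' @return a sparse symmetric `rel_matrix` (`Matrix::dsCMatrix`) with
#'   role `"A_inverse"`.
#' @export
build_A_inverse <- function(pedigree, use_inbreeding = TRUE) {
  stop_if_not_pedigree(pedigree)
  n <- nrow(pedigree)
  si <- attr(pedigree, "sire_idx"); di <- attr(pedigree, "dam_idx")
  FF <- if (use_inbreeding) inbreeding_coefficients(pedigree) else numeric(n)
  fs <- ifelse(si > 0L, FF[pmax(si, 1L)], -1)
  fd <- ifelse(di > 0L, FF[pmax(di, 1L)], -1)
  dinv <- 1 / (0.5 - 0.25 * (fs + fd))

  ## triplets: for each animal the contributions
  ## dinv * { (i,i): 1, (i,par): -0.5, (par,par'): 0.25 }
  ii <- seq_len(n); jj <- seq_len(n); xx <- dinv
  for (p in list(si, di)) {
    has <- p > 0L
    ii <- c(ii, which(has)); jj <- c(jj, p[has]); xx <- c(xx, -0.5 * dinv[has])
    ii <- c(ii, p[has]); jj <- c(jj, which(has)); xx <- c(xx, -0.5 * dinv[has])
    ii <- c(ii, p[has]); jj <- c(jj, p[has]); xx <- c(xx, 0.25 * dinv[has])
  }
  cross <- si > 0L & di > 0L
  ii <- c(ii, si[cross], di[cross])
  jj <- c(jj, di[cross], si[cross])
  xx <- c(xx, rep.int(0.25 * dinv[cross], 2L))

  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               symmetric = FALSE)
  Ainv <- methods::as(Matrix::forceSymmetric((Ainv + Matrix::t(Ainv)) / 2),
                      "CsparseMatrix")
  new_rel_matrix(Ainv, pedigree$id, "A_inverse")
}

#' Relationship submatrix for the genotyped animals (A22)
#'
#' Restricts the pedigree relationship matrix to a set of (genotyped)
#' animals, in the order given. When a dense `rel_matrix` A is supplied
#' the rows/columns are sliced; when a `pedigree` is supplied, A22 is
#' obtained without forming dense A, by sparse Cholesky solves against
#' the Henderson A-inverse (columns of A for the genotyped animals).
#'
#' @param A_or_pedigree a dense `rel_matrix` with role `"A"`, or a
#'   `pedigree` object.
#' @param genotyped_ids character vector of ids; defines the row/column
#'   order of the result.
#' @return a dense `rel_matrix` with role `"A22"`.
#' @export
extract_A22 <- function(A_or_pedigree, genotyped_ids) {
  genotyped_ids <- as.character(genotyped_ids)
  if (is_pedigree(A_or_pedigree)) {
    ped <- A_or_pedigree
    idx <- match(genotyped_ids, ped$id)
    if (anyNA(idx))
      stop("genotyped ids not in pedigree: ",
           paste(head(genotyped_ids[is.na(idx)], 10L), collapse = ", "))
    Ainv <- build_A_inverse(ped)
    ch <- Matrix::Cholesky(methods::as(rel_mat(Ainv), "dsCMatrix"),
                           LDL = FALSE)
    E <- Matrix::sparseMatrix(i = idx, j = seq_along(idx),
                              x = 1, dims = c(nrow(ped), length(idx)))
    Acols <- Matrix::solve(ch, E)          # columns of A for genotyped ids
    A22 <- as.matrix(Acols[idx, , drop = FALSE])
    A22 <- (A22 + t(A22)) / 2
    return(new_rel_matrix(A22, genotyped_ids, "A22"))
  }
  ids <- rel_ids(A_or_pedigree)
  idx <- match(genotyped_ids, ids)
  if (anyNA(idx))
    stop("genotyped ids not in relationship matrix: ",
         paste(head(genotyped_ids[is.na(idx)], 10L), collapse = ", "))
  A22 <- as.matrix(rel_mat(A_or_pedigree)[idx, idx, drop = FALSE])
  new_rel_matrix(A22, genotyped_ids, "A22")
}
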
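#' Pedigree, phenotype, genotype and matrix file dialects
#'
#' Plain-text readers and writers that round-trip with each other:
#' pedigree CSV (`id,sire,dam,generation`, unknown parent `0`),
#' phenotype CSV (`id,record_no,year_season,age_months,interval_days`
#' plus one column per trait), genotypes as a PLINK-`.raw`-style
#' additive table (`FID IID PAT MAT SEX PHENOTYPE snp_...`, `NA` =
#' missing) or a minimal TSV (first column `id`), and relationship
#' matrices as TSV with id headers or coordinate-format triplets.
#'
#' @param pedigree,dataset,genotypes,x objects to write.
#' @param path file path.
#' @name file_io
NULL

#' @rdname file_io
#' @export
write_pedigree_csv <- function(pedigree, path) {
  df <- as.data.frame(pedigree)[, c("id", "sire", "dam", "generation")]
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname file_io
#' @export
read_pedigree_csv <- function(path) {
  read_and_validate_pedigree(read.csv(path, colClasses = c(
    id = "character", sire = "character", dam = "character")))
}

#' @rdname file_io
#' @export
write_phenotypes_csv <- function(dataset, path) {
  write.csv(as.data.frame(dataset), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname file_io
#' @param trait_cols names of the trait columns; default everything
#'   after `interval_days`.
#' @export
read_phenotypes_csv <- function(path, trait_cols = NULL) {
  df <- read.csv(path, colClasses = c(id = "character"))
  base <- c("id", "record_no", "year_season", "age_months", "interval_days")
  if (!all(base %in% names(df)))
    stop("phenotype file must have columns ", paste(base, collapse = ", "))
  if (is.null(trait_cols)) trait_cols <- setdiff(names(df), base)
  attr(df, "trait_names") <- trait_cols
  class(df) <- c("trait_dataset", "data.frame")
  df
}

#' @rdname file_io
#' @export
write_genotypes_raw <- function(genotypes, path) {
  M <- genotype_codes(genotypes)
  df <- data.frame(FID = rownames(M), IID = rownames(M),
                   PAT = 0L, MAT = 0L, SEX = 0L, PHENOTYPE = -9L,
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(M))
  utils::write.table(df, path, row.names = FALSE, quote = FALSE, sep = " ")
  invisible(path)
}

#' @rdname file_io
#' @export
read_genotypes_raw <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "",
                          colClasses = "character",
                          check.names = FALSE)
  meta <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  snp <- setdiff(names(df), meta)
  M <- as.matrix(df[, snp, drop = FALSE])
  storage.mode(M) <- "integer"
  new_genotype_matrix(M, ids = df$IID, snp_ids = snp)
}

#' @rdname file_io
#' @export
write_genotypes_tsv <- function(genotypes, path) {
  M <- genotype_codes(genotypes)
  df <- data.frame(id = rownames(M), stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(M))
  utils::write.table(df, path, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(path)
}

#' @rdname file_io
#' @export
read_genotypes_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  M <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(M) <- "integer"
  new_genotype_matrix(M, ids = df[[1L]], snp_ids = colnames(M))
}

#' @rdname file_io
#' @export
write_matrix_tsv <- function(x, path) {
  m <- as.matrix(rel_mat(x))
  df <- data.frame(id = rownames(m), stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(m))
  utils::write.table(df, path, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(path)
}

#' @rdname file_io
#' @param role role tag for the matrix read back.
#' @export
read_matrix_tsv <- function(path, role = "A") {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  ids <- as.character(df[[1L]])
  dimnames(m) <- list(ids, ids)
  new_rel_matrix(m, ids, role)
}

#' @rdname file_io
#' @export
write_matrix_triplets <- function(x, path) {
  m <- methods::as(methods::as(Matrix::Matrix(rel_mat(x)),
                               "generalMatrix"), "TsparseMatrix")
  df <- data.frame(row = rel_ids(x)[m@i + 1L], col = rel_ids(x)[m@j + 1L],
                   value = m@x, stringsAsFactors = FALSE)
  utils::write.table(df, path, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(path)
}

#' @rdname file_io
#' @export
write_qc_report_json <- function(x, path) {
  stopifnot(inherits(x, "qc_report"))
  jsonlite::write_json(lapply(unclass(x), as.list), path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname file_io
#' @param config a list-like configuration to serialize.
#' @export
write_config_yaml <- function(config, path) {
  cfg <- unclass(config)
  cfg <- lapply(cfg, function(v) if (is.matrix(v))
    apply(v, 1L, identity, simplify = FALSE) else v)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname file_io
#' @export
read_config_yaml <- function(path) {
  yaml::read_yaml(path)
}
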
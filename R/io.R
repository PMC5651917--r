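#' Read and write delimited genotype, phenotype, kinship and map files
#'
#' All file formats are plain tab-delimited text:
#' * genotypes — first column `id`, one column per locus (header row of locus
#'   ids), body entries in \{-1, 0, 1\} (or the `missing` token);
#' * phenotypes — columns `id`, `replicate` (optional), `value`;
#' * kinship — square matrix with locus ids as header row and first column;
#'   round-trips at 17 significant digits;
#' * map — columns `chrom`, `locus`, `pos_cm`.
#'
#' @param path File path.
#' @param missing Token treated as a missing genotype (default `"NA"`).
#' @return `read_genotypes()` an integer matrix (individuals x loci);
#'   `read_phenotypes()` a tibble; `read_kinship()` a numeric matrix;
#'   `read_map()` a tibble. Writers return `path` invisibly.
#' @name cvherit_io
NULL

#' @rdname cvherit_io
#' @export
read_genotypes <- function(path, missing = "NA") {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  if (ncol(df) < 2) abort("Genotype file needs an id column and at least one locus.")
  ids <- df[[1]]
  if (anyDuplicated(ids)) abort("Duplicate individual ids in genotype file.")
  body <- as.matrix(df[, -1, drop = FALSE])
  body[body == missing] <- NA
  Z <- suppressWarnings(matrix(as.numeric(body), nrow(body), ncol(body)))
  bad <- which(!is.na(body) & (is.na(Z) | !(Z %in% c(-1, 0, 1))), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "Invalid genotype code '%s' at row %d (id '%s'), column '%s': codes must be -1, 0 or 1.",
      body[bad[1, 1], bad[1, 2]], bad[1, 1], ids[bad[1, 1]],
      colnames(df)[-1][bad[1, 2]]
    ))
  }
  storage.mode(Z) <- "integer"
  dimnames(Z) <- list(ids, colnames(df)[-1])
  Z
}

#' @rdname cvherit_io
#' @param geno Genotype matrix with dimnames.
#' @export
write_genotypes <- function(geno, path) {
  df <- tibble::as_tibble(geno, rownames = "id")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' @rdname cvherit_io
#' @export
read_phenotypes <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE,
                        comment = "#")
  if (!all(c("id", "value") %in% names(df))) {
    abort("Phenotype file needs columns `id` and `value`.")
  }
  if (!"replicate" %in% names(df)) df$replicate <- 1L
  df <- df |>
    dplyr::mutate(id = as.character(.data$id),
                  replicate = as.integer(.data$replicate),
                  value = as.numeric(.data$value)) |>
    dplyr::select("id", "replicate", "value")
  check_pheno(df)
  df
}

#' @rdname cvherit_io
#' @param pheno Phenotype tibble (`id`, `replicate`, `value`).
#' @export
write_phenotypes <- function(pheno, path) {
  check_pheno(pheno)
  readr::write_tsv(pheno, path, progress = FALSE)
  invisible(path)
}

#' @rdname cvherit_io
#' @export
read_kinship <- function(path) {
  # base parser: strtod is correctly rounded, so 17-digit files round-trip
  # bit-exactly (readr's fast parser can be 1 ulp off)
  df <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE)
  ids <- as.character(df[[1]])
  K <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(K) <- "double"
  if (nrow(K) != ncol(K)) abort("Kinship file is not square.")
  if (!identical(ids, colnames(K))) {
    abort("Kinship row ids do not match column ids.")
  }
  dimnames(K) <- list(ids, ids)
  attr(K, "rescaled") <- isTRUE(all.equal(sum(diag(K)), nrow(K), tolerance = 1e-8))
  K
}

#' @rdname cvherit_io
#' @param K Kinship matrix with dimnames.
#' @export
write_kinship <- function(K, path) {
  ids <- rownames(K)
  if (is.null(ids)) ids <- sprintf("ind_%04d", seq_len(nrow(K)))
  lines <- c(
    paste(c("id", ids), collapse = "\t"),
    vapply(seq_len(nrow(K)), function(i) {
      paste(c(ids[i], sprintf("%.17g", K[i, ])), collapse = "\t")
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname cvherit_io
#' @export
read_map <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE) |>
    dplyr::mutate(chrom = as.integer(.data$chrom),
                  locus = as.character(.data$locus),
                  pos_cm = as.numeric(.data$pos_cm))
  validate_map(df)
  df
}

#' @rdname cvherit_io
#' @param map Genetic map tibble.
#' @export
write_map <- function(map, path) {
  validate_map(map)
  readr::write_tsv(map, path, progress = FALSE)
  invisible(path)
}
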
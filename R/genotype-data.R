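#' Genotype dataset container
#'
#' Bundles a samples-by-SNPs genotype matrix (additive 0/1/2 coding: number
#' of copies of the major allele) with a phenotype vector. The phenotype is
#' either a continuous quantitative trait or a 0/1 case-control endpoint.
#' All downstream operations (QMDR scoring, expert-knowledge tables, the
#' evolutionary search) take this object as their first argument.
#'
#' @param genotypes Integer matrix, `n_samples x n_snps`, values in
#'   \{0, 1, 2\}, no missing values.
#' @param phenotype Numeric vector of length `n_samples`.
#' @param snp_ids Character vector of unique SNP identifiers; defaults to
#'   `colnames(genotypes)` or `snp_001`-style names.
#' @param phenotype_kind `"quantitative"` or `"binary"`; by default inferred
#'   (`"binary"` iff all phenotype values are 0 or 1).
#' @param sample_ids Optional character vector of sample identifiers.
#' @param n_dropped Number of rows removed (e.g. for missing genotypes)
#'   before construction; carried for logging only.
#'
#' @return An object of class `genotype_dataset`: a list with elements
#'   `genotypes`, `phenotype`, `snp_ids`, `sample_ids`, `phenotype_kind`,
#'   `n_snps`, `n_samples`, `n_dropped`.
#' @export
#' @examples
#' g <- matrix(c(0L, 1L, 2L, 1L, 0L, 1L), nrow = 3)
#' genotype_dataset(g, c(0.2, 1.4, 0.7), snp_ids = c("rs1", "rs2"))
genotype_dataset <- function(genotypes, phenotype,
                             snp_ids = colnames(genotypes),
                             phenotype_kind = NULL,
                             sample_ids = NULL,
                             n_dropped = 0L) {
  if (!is.matrix(genotypes)) {
    abort("`genotypes` must be a matrix.")
  }
  storage.mode(genotypes) <- "integer"
  if (nrow(genotypes) == 0L) {
    abort("Dataset has 0 samples.")
  }
  bad <- which(is.na(genotypes) | genotypes < 0L | genotypes > 2L)
  if (length(bad)) {
    i <- ((bad[1] - 1L) %% nrow(genotypes)) + 1L
    j <- ((bad[1] - 1L) %/% nrow(genotypes)) + 1L
    abort(sprintf(
      "Genotype values must be 0, 1 or 2: offending value %s at sample %d, SNP column %d.",
      genotypes[bad[1]], i, j
    ))
  }
  if (is.null(snp_ids)) {
    snp_ids <- sprintf("snp_%03d", seq_len(ncol(genotypes)))
  }
  snp_ids <- as.character(snp_ids)
  if (length(snp_ids) != ncol(genotypes)) {
    abort("`snp_ids` length must equal the number of SNP columns.")
  }
  if (anyDuplicated(snp_ids)) {
    abort("`snp_ids` must be unique.")
  }
  phenotype <- as.numeric(phenotype)
  if (length(phenotype) != nrow(genotypes)) {
    abort("`phenotype` length must equal the number of samples.")
  }
  if (anyNA(phenotype)) {
    abort("`phenotype` must not contain missing values.")
  }
  if (is.null(phenotype_kind)) {
    phenotype_kind <- if (all(phenotype %in% c(0, 1))) "binary" else "quantitative"
  }
  phenotype_kind <- match.arg(phenotype_kind, c("quantitative", "binary"))
  if (phenotype_kind == "binary" && !all(phenotype %in% c(0, 1))) {
    abort("Binary phenotype must be coded 0/1.")
  }
  if (is.null(sample_ids)) {
    sample_ids <- sprintf("s%04d", seq_len(nrow(genotypes)))
  }
  colnames(genotypes) <- snp_ids
  structure(
    list(
      genotypes = genotypes,
      phenotype = phenotype,
      snp_ids = snp_ids,
      sample_ids = as.character(sample_ids),
      phenotype_kind = phenotype_kind,
      n_snps = ncol(genotypes),
      n_samples = nrow(genotypes),
      n_dropped = as.integer(n_dropped)
    ),
    class = "genotype_dataset"
  )
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf(
    "<genotype_dataset> %d samples x %d SNPs, %s phenotype (%d rows dropped on load)\n",
    x$n_samples, x$n_snps, x$phenotype_kind, x$n_dropped
  ))
  invisible(x)
}

#' Truth set of planted functional SNPs
#'
#' Records which simulated SNPs are functional, grouped into two-SNP
#' "genes" (interacting pairs). Used to decide whether a search succeeded.
#'
#' @param genes A list of character vectors, each of length 2 (the SNP ids
#'   of one simulated gene).
#' @return An object of class `truth_set` with elements `genes` and
#'   `functional_snp_ids` (the concatenation of the pairs).
#' @export
truth_set <- function(genes) {
  if (!is.list(genes) || !length(genes)) {
    abort("`genes` must be a non-empty list of SNP-id pairs.")
  }
  if (!all(vapply(genes, length, 1L) == 2L)) {
    abort("Each gene must be a pair of SNP ids.")
  }
  ids <- as.character(unlist(genes))
  if (anyDuplicated(ids)) {
    abort("Functional SNP ids must not repeat across genes.")
  }
  structure(
    list(genes = lapply(genes, as.character), functional_snp_ids = ids),
    class = "truth_set"
  )
}

#' @export
print.truth_set <- function(x, ...) {
  cat(sprintf(
    "<truth_set> %d genes, functional SNPs: %s\n",
    length(x$genes), paste(x$functional_snp_ids, collapse = ", ")
  ))
  invisible(x)
}

plink_meta_cols <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")

#' Read a genotype dataset from disk
#'
#' Supports two plain-text dialects: a TSV with header
#' `sample_id <phenotype> <snp>...`, and PLINK's additive `.raw` recode
#' (space-separated, six metadata columns `FID IID PAT MAT SEX PHENOTYPE`
#' followed by one column per SNP). Rows containing missing genotypes are
#' dropped and counted; any non-\{0,1,2\} genotype value is an error that
#' names the offending row and column.
#'
#' @param path File path.
#' @param format `"tsv"` or `"plink_raw"`.
#' @param phenotype_column Name of the phenotype column. Defaults to the
#'   second column for TSV and `PHENOTYPE` for PLINK `.raw`.
#' @param phenotype_kind Passed to [genotype_dataset()]; `NULL` = infer.
#' @param quiet Suppress the dropped-row message.
#' @return A [genotype_dataset()].
#' @export
read_genotypes <- function(path, format = c("tsv", "plink_raw"),
                           phenotype_column = NULL,
                           phenotype_kind = NULL,
                           quiet = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(sprintf("File does not exist: %s", path))
  }
  if (format == "tsv") {
    df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    if (ncol(df) < 3L) {
      abort(sprintf("Unparseable dataset `%s`: expected sample_id, phenotype and SNP columns.", path))
    }
    sample_ids <- as.character(df[[1]])
    if (is.null(phenotype_column)) phenotype_column <- names(df)[2]
    if (!phenotype_column %in% names(df)) {
      abort(sprintf("Phenotype column `%s` not found in %s.", phenotype_column, path))
    }
    pheno <- df[[phenotype_column]]
    snp_cols <- setdiff(names(df)[-1], phenotype_column)
  } else {
    df <- readr::read_delim(path, delim = " ", show_col_types = FALSE,
                            progress = FALSE, trim_ws = TRUE)
    missing_meta <- setdiff(plink_meta_cols, names(df))
    if (length(missing_meta)) {
      abort(sprintf(
        "Unparseable PLINK .raw file `%s`: missing metadata column(s) %s.",
        path, paste(missing_meta, collapse = ", ")
      ))
    }
    if (is.null(phenotype_column)) phenotype_column <- "PHENOTYPE"
    if (!phenotype_column %in% names(df)) {
      abort(sprintf("Phenotype column `%s` not found in %s.", phenotype_column, path))
    }
    sample_ids <- as.character(df[["IID"]])
    pheno <- df[[phenotype_column]]
    snp_cols <- setdiff(names(df), unique(c(plink_meta_cols, phenotype_column)))
  }
  if (!length(snp_cols)) {
    abort(sprintf("No SNP columns found in %s.", path))
  }
  geno_df <- df[snp_cols]
  for (j in seq_along(snp_cols)) {
    v <- geno_df[[j]]
    if (!is.numeric(v)) {
      abort(sprintf("Non-numeric genotype column `%s` in %s.", snp_cols[j], path))
    }
    bad <- which(!is.na(v) & !(v %in% c(0, 1, 2)))
    if (length(bad)) {
      abort(sprintf(
        "Invalid genotype value %s at line %d (data row %d), column `%s` in %s: genotypes must be 0/1/2.",
        v[bad[1]], bad[1] + 1L, bad[1], snp_cols[j], path
      ))
    }
  }
  geno <- as.matrix(geno_df)
  keep <- !apply(is.na(geno), 1L, any) & !is.na(pheno)
  n_dropped <- sum(!keep)
  if (n_dropped > 0L && !quiet) {
    inform(sprintf("Dropped %d sample row(s) with missing values while reading %s.",
                   n_dropped, path))
  }
  if (!any(keep)) {
    abort(sprintf("All rows of %s contain missing values.", path))
  }
  genotype_dataset(
    geno[keep, , drop = FALSE],
    phenotype = as.numeric(pheno[keep]),
    snp_ids = snp_cols,
    phenotype_kind = phenotype_kind,
    sample_ids = sample_ids[keep],
    n_dropped = n_dropped
  )
}

#' Write a genotype dataset (and optional truth sidecar) as TSV
#'
#' The TSV dialect is `sample_id <phenotype> <snp>...` with a header row.
#' `read_genotypes(write_genotypes(d))` reproduces `d` exactly. When a
#' [truth_set()] is supplied, it is written to `<path>.truth.tsv` with one
#' row per gene (`gene`, `snp_a`, `snp_b`).
#'
#' @param dataset A [genotype_dataset()].
#' @param path Output path.
#' @param truth Optional [truth_set()].
#' @param phenotype_name Header name for the phenotype column.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(dataset, path, truth = NULL,
                            phenotype_name = "phenotype") {
  stopifnot(inherits(dataset, "genotype_dataset"))
  df <- tibble::tibble(sample_id = dataset$sample_ids)
  df[[phenotype_name]] <- dataset$phenotype
  df <- dplyr::bind_cols(df, tibble::as_tibble(dataset$genotypes))
  readr::write_tsv(df, path, progress = FALSE)
  if (!is.null(truth)) {
    stopifnot(inherits(truth, "truth_set"))
    write_truth(truth, truth_path(path))
  }
  invisible(path)
}

truth_path <- function(path) paste0(path, ".truth.tsv")

#' Write / read a truth set sidecar
#'
#' @param truth A [truth_set()].
#' @param path Sidecar file path.
#' @return `write_truth()` returns `path` invisibly; `read_truth()` returns
#'   a [truth_set()].
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "truth_set"))
  df <- tibble::tibble(
    gene = seq_along(truth$genes),
    snp_a = vapply(truth$genes, `[`, "", 1L),
    snp_b = vapply(truth$genes, `[`, "", 2L)
  )
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  truth_set(purrr::map2(df$snp_a, df$snp_b, c))
}
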
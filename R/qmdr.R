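#' Construct an MDR/QMDR attribute from a set of SNPs
#'
#' Constructive induction: the multilocus genotype combinations of the K
#' selected SNPs are pooled into a single binary attribute. For a
#' quantitative trait (QMDR) a cell is "high-level" when its mean trait
#' strictly exceeds the overall mean; for a binary endpoint (classic MDR) a
#' cell is "high-risk" when its case/control ratio strictly exceeds the
#' threshold `T` (cells with at least one case and no controls are high).
#' Equality is low in both rules, and unobserved cells are recorded as
#' `empty` (treated as low if ever queried).
#'
#' @param dataset A [genotype_dataset()].
#' @param snps SNP column indices or SNP ids (distinct, `1 <= K <= max_k`).
#' @param threshold For binary phenotypes, the case/control ratio threshold
#'   `T`; default is the overall case/control ratio.
#' @param max_k Hard cap on model order (cells grow as `3^K`).
#'
#' @return An object of class `mdr_attribute`: list with `labels` (integer
#'   0/1 per sample, 1 = high-level group G1), `cells` (a tibble with one
#'   row per possible genotype combination: `combo`, `n`, `cell_stat`,
#'   `status` in high/low/empty), `grand_mean` (overall trait mean, or the
#'   threshold `T` for binary), `snps`, `snp_ids`, and `kind`.
#' @export
#' @examples
#' d <- genotype_dataset(matrix(c(0L, 0L, 1L, 1L, 2L, 2L), ncol = 1),
#'                       c(1, 1, 5, 5, 1, 1), snp_ids = "rs1")
#' mdr_attribute(d, "rs1")
mdr_attribute <- function(dataset, snps, threshold = NULL, max_k = 10L) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  idx <- resolve_snps(dataset, snps)
  k <- length(idx)
  if (k < 1L) abort("At least one SNP is required (K >= 1).")
  if (anyDuplicated(idx)) abort("SNP indices must be distinct.")
  if (k > max_k) abort(sprintf("Model order K = %d exceeds max_k = %d.", k, max_k))

  geno <- dataset$genotypes[, idx, drop = FALSE]
  cell <- as.integer(geno %*% 3L^(seq_len(k) - 1L))  # 0 .. 3^k - 1
  ncell <- 3L^k
  n_in_cell <- tabulate(cell + 1L, nbins = ncell)

  combo <- combo_labels(k)
  if (dataset$phenotype_kind == "quantitative") {
    if (!is.null(threshold)) {
      abort("`threshold` applies only to binary phenotypes.")
    }
    y <- dataset$phenotype
    grand <- mean(y)
    cell_sum <- as.numeric(rowsum_by_cell(y, cell, ncell))
    cell_stat <- ifelse(n_in_cell > 0L, cell_sum / pmax(n_in_cell, 1L), NA_real_)
    status <- ifelse(n_in_cell == 0L, "empty",
                     ifelse(cell_stat > grand, "high", "low"))
    kind <- "quantitative"
  } else {
    y <- dataset$phenotype
    if (is.null(threshold)) {
      n_ctrl_all <- sum(y == 0)
      if (n_ctrl_all == 0) abort("No controls in dataset; supply `threshold`.")
      threshold <- sum(y == 1) / n_ctrl_all
    }
    if (threshold <= 0) abort("`threshold` must be positive.")
    cases <- as.numeric(rowsum_by_cell(y, cell, ncell))
    controls <- n_in_cell - cases
    ratio <- ifelse(controls > 0, cases / controls,
                    ifelse(cases > 0, Inf, NA_real_))
    cell_stat <- ratio
    status <- ifelse(n_in_cell == 0L, "empty",
                     ifelse(!is.na(ratio) & ratio > threshold, "high", "low"))
    # all-control cells have ratio 0 -> low; 0 cases 0 controls impossible here
    grand <- threshold
    kind <- "binary"
  }
  high_cell <- status == "high"
  labels <- as.integer(high_cell[cell + 1L])
  structure(
    list(
      labels = labels,
      cells = tibble::tibble(
        combo = combo,
        n = n_in_cell,
        cell_stat = cell_stat,
        status = status
      ),
      grand_mean = grand,
      snps = idx,
      snp_ids = dataset$snp_ids[idx],
      kind = kind
    ),
    class = "mdr_attribute"
  )
}

#' @export
print.mdr_attribute <- function(x, ...) {
  cat(sprintf(
    "<mdr_attribute> K = %d (%s), %d/%d samples high-level, %d empty cells\n",
    length(x$snps), paste(x$snp_ids, collapse = " x "),
    sum(x$labels), length(x$labels), sum(x$cells$status == "empty")
  ))
  invisible(x)
}

combo_labels <- function(k) {
  grids <- rep(list(0:2), k)
  g <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)  # first factor varies fastest
  apply(g, 1L, paste, collapse = "/")
}

rowsum_by_cell <- function(y, cell, ncell) {
  out <- numeric(ncell)
  s <- rowsum(y, group = cell, reorder = TRUE)
  out[as.integer(rownames(s)) + 1L] <- s[, 1L]
  out
}

resolve_snps <- function(dataset, snps) {
  if (is.character(snps)) {
    idx <- match(snps, dataset$snp_ids)
    if (anyNA(idx)) {
      abort(sprintf("Unknown SNP id(s): %s",
                    paste(snps[is.na(idx)], collapse = ", ")))
    }
    idx
  } else {
    idx <- as.integer(snps)
    if (any(idx < 1L | idx > dataset$n_snps)) {
      abort("SNP indices out of range.")
    }
    idx
  }
}

#' Pooled two-sample t-statistic of a constructed attribute
#'
#' Compares the trait means of the high-level (G1) and low-level (G0)
#' groups defined by [mdr_attribute()]: `t = (mean(G1) - mean(G0)) / se`
#' with a pooled-variance standard error (Student), or Welch's unequal
#' variance form when `welch = TRUE`. When either group has fewer than two
#' members or the pooled variance is zero the statistic is degenerate: the
#' function returns 0 with attribute `valid = FALSE` rather than erroring,
#' so an evolutionary search can keep going.
#'
#' @param attribute An [mdr_attribute()] (or an integer 0/1 label vector).
#' @param phenotype Quantitative trait values, one per sample.
#' @param welch Use Welch's t instead of the pooled-variance Student's t.
#' @return The t-statistic (numeric scalar) with attribute `"valid"`.
#' @export
qmdr_t_statistic <- function(attribute, phenotype, welch = FALSE) {
  labels <- if (inherits(attribute, "mdr_attribute")) attribute$labels else as.integer(attribute)
  stopifnot(length(labels) == length(phenotype))
  g1 <- phenotype[labels == 1L]
  g0 <- phenotype[labels == 0L]
  n1 <- length(g1); n0 <- length(g0)
  if (n1 < 2L || n0 < 2L) {
    return(structure(0, valid = FALSE))
  }
  m1 <- mean(g1); m0 <- mean(g0)
  v1 <- sum((g1 - m1)^2); v0 <- sum((g0 - m0)^2)
  if (welch) {
    s1 <- v1 / (n1 - 1); s0 <- v0 / (n0 - 1)
    se2 <- s1 / n1 + s0 / n0
  } else {
    sp2 <- (v1 + v0) / (n1 + n0 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n0)
  }
  if (se2 <= 0) {
    return(structure(0, valid = FALSE))
  }
  structure((m1 - m0) / sqrt(se2), valid = TRUE)
}

#' Score a candidate SNP model on the three search objectives
#'
#' Computes the QMDR t-statistic of the constructed attribute (training
#' score), the mean pairwise interaction information of the model's SNPs
#' taken from an expert-knowledge table (0 for single-SNP models), and the
#' model size K. These are the three objectives the evolutionary search
#' jointly optimizes (maximize t, maximize interaction information,
#' minimize size).
#'
#' @param dataset A [genotype_dataset()] with a quantitative phenotype.
#' @param snps SNP indices or ids (distinct, non-empty).
#' @param ek An [build_expert_knowledge()] table for the same dataset.
#' @return A one-row tibble: `t_statistic`, `interaction_info`, `size`,
#'   `valid`.
#' @export
score_model <- function(dataset, snps, ek) {
  idx <- resolve_snps(dataset, snps)
  if (!length(idx)) abort("Model must contain at least one SNP.")
  if (anyDuplicated(idx)) abort("SNP indices must be distinct.")
  if (dataset$phenotype_kind != "quantitative") {
    abort("score_model() requires a quantitative phenotype (QMDR t objective).")
  }
  stopifnot(inherits(ek, "ek_table"))
  m <- qmdr_score_batch_cpp(dataset$genotypes, dataset$phenotype,
                            list(idx), ek$gain)
  tibble::tibble(
    t_statistic = unname(m[1, 1]),
    interaction_info = unname(m[1, 2]),
    size = as.integer(m[1, 3]),
    valid = unname(m[1, 4] == 1)
  )
}

score_models <- function(dataset, models, ek) {
  qmdr_score_batch_cpp(dataset$genotypes, dataset$phenotype, models, ek$gain)
}

#' Post-hoc k-fold cross-validated QMDR score for one model
#'
#' The evolutionary search itself replaces cross-validation with Pareto
#' optimization; this standalone scorer is for post-hoc assessment of a
#' chosen model. For each fold, cells are labeled high/low on the training
#' split (relative to the training grand mean) and the held-out samples are
#' assigned by the training cell map (cells unseen in training are treated
#' as low); the testing t-statistic is computed on the held-out split.
#'
#' @param dataset A quantitative [genotype_dataset()].
#' @param snps SNP indices or ids.
#' @param folds Number of folds.
#' @param seed Optional integer seed for the fold assignment.
#' @return A tibble with one row per fold (`fold`, `train_t`, `test_t`)
#'   plus attribute `"mean_test_t"`.
#' @export
qmdr_cv <- function(dataset, snps, folds = 5L, seed = NULL) {
  idx <- resolve_snps(dataset, snps)
  stopifnot(dataset$phenotype_kind == "quantitative", folds >= 2L)
  n <- dataset$n_samples
  assign_folds <- function() sample(rep_len(seq_len(folds), n))
  fold_id <- if (is.null(seed)) assign_folds() else withr::with_seed(seed, assign_folds())
  k <- length(idx)
  cell <- as.integer(dataset$genotypes[, idx, drop = FALSE] %*% 3L^(seq_len(k) - 1L))
  y <- dataset$phenotype
  rows <- purrr::map(seq_len(folds), function(f) {
    tr <- fold_id != f
    grand <- mean(y[tr])
    cm <- tapply(y[tr], cell[tr], mean)
    high_cells <- as.integer(names(cm))[cm > grand]
    lab_tr <- as.integer(cell[tr] %in% high_cells)
    lab_te <- as.integer(cell[!tr] %in% high_cells)
    tibble::tibble(
      fold = f,
      train_t = as.numeric(qmdr_t_statistic(lab_tr, y[tr])),
      test_t = as.numeric(qmdr_t_statistic(lab_te, y[!tr]))
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "mean_test_t") <- mean(out$test_t)
  out
}
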
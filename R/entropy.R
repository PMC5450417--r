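#' Shannon entropy of a count vector (bits)
#'
#' Plug-in (maximum-likelihood) estimate `H = -sum(p * log2(p))` over the
#' non-zero categories of a count vector.
#'
#' @param counts Non-negative counts; must sum to a positive value.
#' @return Entropy in bits.
#' @export
#' @examples
#' shannon_entropy(c(4, 4)) # 1 bit
shannon_entropy <- function(counts) {
  if (any(counts < 0)) abort("Counts must be non-negative.")
  n <- sum(counts)
  if (n <= 0) abort("Counts must sum to a positive value.")
  p <- counts[counts > 0] / n
  -sum(p * log2(p))
}

#' Mutual information between two categorical vectors (bits)
#'
#' Plug-in estimate `I(X;C) = H(X) + H(C) - H(X,C)`.
#'
#' @param x,c_class Equal-length categorical vectors (any atomic type).
#' @return Mutual information in bits (non-negative up to rounding).
#' @export
mutual_information <- function(x, c_class) {
  if (length(x) != length(c_class)) abort("`x` and `c_class` lengths differ.")
  hx <- shannon_entropy(table(x))
  hc <- shannon_entropy(table(c_class))
  hxc <- shannon_entropy(table(paste(x, c_class, sep = "\r")))
  hx + hc - hxc
}

#' Interaction information (information gain) of a SNP pair
#'
#' `IG(A,B;C) = I(A,B;C) - I(A;C) - I(B;C)`, where `(A,B)` is the
#' 9-category joint genotype variable and `C` a binary class: the
#' information about the class carried jointly by the pair beyond the two
#' independent main effects. Positive values indicate synergy (a
#' non-additive interaction); negative values indicate redundancy (e.g.
#' linkage disequilibrium).
#'
#' @param a,b Genotype vectors coded 0/1/2.
#' @param c_class Binary class vector (0/1), same length.
#' @return Interaction gain in bits.
#' @export
interaction_gain <- function(a, b, c_class) {
  if (length(a) != length(b) || length(a) != length(c_class)) {
    abort("`a`, `b` and `c_class` must have equal lengths.")
  }
  ab <- paste(a, b, sep = "\r")
  mutual_information(ab, c_class) -
    mutual_information(a, c_class) -
    mutual_information(b, c_class)
}

#' Binarize a quantitative trait into a two-level class
#'
#' Interaction information needs a discrete class variable; a continuous
#' trait is split at its overall mean (1 = above the mean), mirroring
#' QMDR's high/low construction. A median split is available by flag.
#'
#' @param phenotype Numeric trait vector.
#' @param split `"mean"` (default) or `"median"`.
#' @return Integer 0/1 vector.
#' @export
binarize_trait <- function(phenotype, split = c("mean", "median")) {
  split <- match.arg(split)
  if (length(unique(phenotype)) < 2L) {
    abort("Constant phenotype carries no information to binarize.")
  }
  cut <- if (split == "mean") mean(phenotype) else median(phenotype)
  cls <- as.integer(phenotype > cut)
  if (length(unique(cls)) < 2L) {
    abort("Degenerate split: all samples fall on one side of the threshold.")
  }
  cls
}

#' Build the pairwise expert-knowledge table
#'
#' Computes the interaction gain of every unordered SNP pair against the
#' class variable (the binary endpoint directly, or the binarized
#' quantitative trait) and records each SNP's best partner (the row-wise
#' argmax). The table drives "sensible initialization" of the evolutionary
#' search and supplies its interaction-information objective.
#'
#' @param dataset A [genotype_dataset()] with at least 2 SNPs.
#' @param split Trait binarization rule, see [binarize_trait()].
#' @return An object of class `ek_table`: list with `gain` (symmetric
#'   n_snps x n_snps matrix of bits, zero diagonal), `best_partner`
#'   (integer vector), `class_vector`, `snp_ids`, `split`.
#' @export
build_expert_knowledge <- function(dataset, split = c("mean", "median")) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  split <- match.arg(split)
  if (dataset$n_snps < 2L) abort("At least 2 SNPs are required.")
  cls <- if (dataset$phenotype_kind == "binary") {
    as.integer(dataset$phenotype)
  } else {
    binarize_trait(dataset$phenotype, split = split)
  }
  gain <- interaction_gain_matrix_cpp(dataset$genotypes, cls)
  dimnames(gain) <- list(dataset$snp_ids, dataset$snp_ids)
  masked <- gain
  diag(masked) <- -Inf
  best_partner <- max.col(masked, ties.method = "first")
  structure(
    list(
      gain = gain,
      best_partner = best_partner,
      class_vector = cls,
      snp_ids = dataset$snp_ids,
      split = split
    ),
    class = "ek_table"
  )
}

#' @export
print.ek_table <- function(x, ...) {
  n <- length(x$snp_ids)
  ut <- x$gain[upper.tri(x$gain)]
  cat(sprintf(
    "<ek_table> %d SNPs, %d pairs; gain range [%.4g, %.4g] bits\n",
    n, length(ut), min(ut), max(ut)
  ))
  invisible(x)
}

#' Rank SNP pairs by interaction gain
#'
#' @param ek An [build_expert_knowledge()] table.
#' @return A tibble (`snp_i`, `snp_j`, `gain_bits`) sorted by descending
#'   gain, one row per unordered pair.
#' @export
rank_pairs <- function(ek) {
  stopifnot(inherits(ek, "ek_table"))
  n <- length(ek$snp_ids)
  ut <- which(upper.tri(ek$gain), arr.ind = TRUE)
  tibble::tibble(
    snp_i = ek$snp_ids[ut[, 1]],
    snp_j = ek$snp_ids[ut[, 2]],
    gain_bits = ek$gain[ut]
  ) |>
    dplyr::arrange(dplyr::desc(.data$gain_bits))
}

#' @exportS3Method generics::tidy
tidy.ek_table <- function(x, ...) rank_pairs(x)
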
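#' Hardy-Weinberg genotype frequencies
#'
#' Genotype codes count copies of the major allele, so with minor allele
#' frequency `maf` (= q) and p = 1 - maf the frequencies of codes (0, 1, 2)
#' are (q^2, 2pq, p^2).
#'
#' @param maf Minor allele frequency in (0, 0.5].
#' @return Numeric 3-vector summing to 1.
#' @export
#' @examples
#' hwe_genotype_frequencies(0.2) # 0.04 0.32 0.64
hwe_genotype_frequencies <- function(maf) {
  if (maf <= 0 || maf > 0.5) abort("`maf` must lie in (0, 0.5].")
  p <- 1 - maf
  c(maf^2, 2 * p * maf, p^2)
}

#' Broad-sense heritability of a penetrance table
#'
#' Population-level heritability of a 3x3 two-SNP penetrance table under
#' Hardy-Weinberg genotype frequencies:
#' `h2 = sum(p_ij * (f_ij - K)^2) / (K * (1 - K))` with
#' `K = sum(p_ij * f_ij)` the population-mean penetrance.
#'
#' @param table 3x3 numeric matrix of penetrance values in \[0, 1\];
#'   `table[i, j]` is the value for genotype codes (i-1, j-1).
#' @param maf Shared minor allele frequency of the two SNPs.
#' @return The heritability.
#' @export
table_heritability <- function(table, maf) {
  stopifnot(is.matrix(table), all(dim(table) == c(3L, 3L)))
  if (any(table < 0 | table > 1)) abort("Penetrance values must lie in [0, 1].")
  w <- hwe_genotype_frequencies(maf)
  p <- outer(w, w)
  K <- sum(p * table)
  if (K <= 0 || K >= 1) abort("Mean penetrance K must lie strictly in (0, 1).")
  sum(p * (table - K)^2) / (K * (1 - K))
}

#' Marginal penetrances of a two-SNP table
#'
#' Row marginal i = `sum_j q_j f_ij` with `q` the partner SNP's
#' Hardy-Weinberg frequencies (and symmetrically for columns). A table is
#' purely epistatic when every row and column marginal equals the
#' population mean K, i.e. neither SNP has a main effect.
#'
#' @inheritParams table_heritability
#' @return A list with `rows` and `cols` (numeric 3-vectors).
#' @export
marginal_penetrances <- function(table, maf) {
  stopifnot(is.matrix(table), all(dim(table) == c(3L, 3L)))
  w <- hwe_genotype_frequencies(maf)
  list(rows = as.numeric(table %*% w), cols = as.numeric(crossprod(table, w)))
}

#' Generate a pure-epistasis penetrance table at a target heritability
#'
#' Draws a random 3x3 deviation table, projects it onto the subspace of
#' zero Hardy-Weinberg-weighted row and column means (alternating
#' projections to convergence, so neither SNP has a marginal effect),
#' scales the deviations around a baseline K0 = 0.5 to hit the target
#' heritability exactly, and rejects draws whose values would leave
#' \[0, 1\]. Deterministic under the ambient RNG state.
#'
#' @param maf Shared minor allele frequency of the two SNPs.
#' @param target_h2 Target heritability in (0, 1).
#' @param max_tries Rejection-sampling cap.
#' @return An object of class `penetrance_model`: list with `table`,
#'   `maf`, `heritability` (realized), `mean_k`.
#' @export
generate_penetrance_table <- function(maf, target_h2, max_tries = 1000L) {
  if (target_h2 <= 0 || target_h2 >= 1) abort("`target_h2` must lie in (0, 1).")
  w <- hwe_genotype_frequencies(maf)
  p <- outer(w, w)
  k0 <- 0.5
  for (try in seq_len(max_tries)) {
    d <- matrix(runif(9, -1, 1), 3, 3)
    # alternating projection onto zero weighted row/column means
    for (it in 1:500) {
      d <- d - matrix(as.numeric(d %*% w), 3, 3)                     # row means
      d <- d - matrix(as.numeric(crossprod(d, w)), 3, 3, byrow = TRUE) # col means
      if (max(abs(as.numeric(d %*% w)),
              abs(as.numeric(crossprod(d, w)))) < 1e-13) break
    }
    var_d <- sum(p * d^2)
    if (var_d < 1e-12) next
    scale <- sqrt(target_h2 * k0 * (1 - k0) / var_d)
    f <- k0 + scale * d
    if (any(f < 0 | f > 1)) next
    return(structure(
      list(table = f, maf = maf,
           heritability = table_heritability(f, maf),
           mean_k = sum(p * f)),
      class = "penetrance_model"
    ))
  }
  abort(sprintf(
    "Could not generate a pure-epistasis table with maf = %g, h2 = %g in %d tries.",
    maf, target_h2, max_tries
  ))
}

#' @export
print.penetrance_model <- function(x, ...) {
  cat(sprintf("<penetrance_model> maf = %g, h2 = %.6g, K = %.4f\n",
              x$maf, x$heritability, x$mean_k))
  print(round(x$table, 4))
  invisible(x)
}

#' Specification of one simulated dataset
#'
#' Defines the study conditions of a hierarchical quantitative-trait
#' epistasis simulation: `n_genes` genes, each a purely epistatic pair of
#' SNPs at the shared `maf` with per-gene heritability `heritability`;
#' each gene's product is drawn around its penetrance value with Gaussian
#' dispersion `trait_sd` and the products are summed into the phenotype;
#' the functional SNPs are hidden among noise SNPs (total `n_total_snps`).
#' The default grid values mirror the simulation study: genes in \{2, 4\},
#' MAF in \{0.2, 0.4\}, heritability in \{0.001, 0.01, 0.1, 0.2\},
#' trait SD in \{0.05, 0.1, 0.2, 0.3\}, sample sizes \{2000, 8000\},
#' totals \{100, 1000\} SNPs, 10 replicates.
#'
#' @param n_genes Number of interacting SNP pairs (genes).
#' @param maf Functional-SNP minor allele frequency.
#' @param heritability Per-gene penetrance-table heritability.
#' @param trait_sd Gaussian dispersion of each gene product around its
#'   penetrance value (sigma).
#' @param n_samples Samples to draw.
#' @param n_total_snps Total SNPs including noise.
#' @param replicates Replicate datasets per grid cell.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(n_genes = 2L, maf = 0.4, heritability = 0.2,
                            trait_sd = 0.05, n_samples = 2000L,
                            n_total_snps = 100L, replicates = 10L) {
  spec <- list(
    n_genes = as.integer(n_genes), maf = maf, heritability = heritability,
    trait_sd = trait_sd, n_samples = as.integer(n_samples),
    n_total_snps = as.integer(n_total_snps), replicates = as.integer(replicates)
  )
  if (spec$n_genes < 1L) abort("`n_genes` must be >= 1.")
  if (spec$n_total_snps < 2L * spec$n_genes) {
    abort("`n_total_snps` must be at least 2 * n_genes.")
  }
  if (spec$trait_sd < 0) abort("`trait_sd` must be >= 0.")
  if (spec$n_samples < 1L || spec$replicates < 1L) {
    abort("`n_samples` and `replicates` must be >= 1.")
  }
  structure(spec, class = "simulation_spec")
}

sample_hwe_genotypes <- function(n, maf) {
  freq <- hwe_genotype_frequencies(maf)
  sample.int(3L, n, replace = TRUE, prob = freq) - 1L
}

#' Simulate a hierarchical quantitative-trait epistasis dataset
#'
#' For each gene, generates a pure-epistasis penetrance table at the
#' target heritability, samples the two functional genotype columns from
#' Hardy-Weinberg equilibrium, and draws the gene product
#' `Normal(f(g1, g2), trait_sd)` per sample; the phenotype is the sum of
#' the gene products. Noise SNPs (independent of the trait) are sampled
#' from HWE at MAFs uniform in \[0.05, 0.5\]. Functional columns are
#' placed at shuffled positions; SNP ids follow column order.
#'
#' @param spec A [simulation_spec()].
#' @param seed Optional integer seed.
#' @param noise Where the Gaussian dispersion is applied: `"per_gene"`
#'   (default; sigma per gene product, then summed) or `"post_sum"` (a
#'   single draw added to the summed penetrance values).
#' @return A list: `dataset` ([genotype_dataset()]), `truth`
#'   ([truth_set()]), `genes` (list of `penetrance_model`), `manifest`
#'   (tibble with realized heritability and K per gene), `spec`.
#' @export
simulate_epistasis <- function(spec, seed = NULL,
                               noise = c("per_gene", "post_sum")) {
  stopifnot(inherits(spec, "simulation_spec"))
  noise <- match.arg(noise)
  runner <- function() {
    n <- spec$n_samples
    genes <- purrr::map(seq_len(spec$n_genes),
                        ~ generate_penetrance_table(spec$maf, spec$heritability))
    func_geno <- matrix(0L, n, 2L * spec$n_genes)
    pheno <- numeric(n)
    mu <- numeric(n)
    for (g in seq_len(spec$n_genes)) {
      g1 <- sample_hwe_genotypes(n, spec$maf)
      g2 <- sample_hwe_genotypes(n, spec$maf)
      func_geno[, 2L * g - 1L] <- g1
      func_geno[, 2L * g] <- g2
      f <- genes[[g]]$table[cbind(g1 + 1L, g2 + 1L)]
      mu <- mu + f
      if (noise == "per_gene" && spec$trait_sd > 0) {
        pheno <- pheno + f + rnorm(n, 0, spec$trait_sd)
      } else {
        pheno <- pheno + f
      }
    }
    if (noise == "post_sum" && spec$trait_sd > 0) {
      pheno <- pheno + rnorm(n, 0, spec$trait_sd)
    }
    n_noise <- spec$n_total_snps - 2L * spec$n_genes
    noise_geno <- if (n_noise > 0L) {
      mafs <- runif(n_noise, 0.05, 0.5)
      vapply(mafs, function(m) sample_hwe_genotypes(n, m), integer(n))
    } else {
      matrix(0L, n, 0L)
    }
    geno <- cbind(func_geno, noise_geno)
    pos <- sample.int(spec$n_total_snps)  # new position of each column
    geno_shuffled <- matrix(0L, n, spec$n_total_snps)
    geno_shuffled[, pos] <- geno
    snp_ids <- sprintf("snp_%04d", seq_len(spec$n_total_snps))
    dataset <- genotype_dataset(geno_shuffled, pheno, snp_ids = snp_ids,
                                phenotype_kind = "quantitative")
    gene_pairs <- purrr::map(seq_len(spec$n_genes), function(g) {
      snp_ids[pos[c(2L * g - 1L, 2L * g)]]
    })
    truth <- truth_set(gene_pairs)
    manifest <- tibble::tibble(
      gene = seq_len(spec$n_genes),
      snp_a = vapply(gene_pairs, `[`, "", 1L),
      snp_b = vapply(gene_pairs, `[`, "", 2L),
      realized_h2 = vapply(genes, function(x) x$heritability, 0),
      mean_k = vapply(genes, function(x) x$mean_k, 0)
    )
    list(dataset = dataset, truth = truth, genes = genes,
         manifest = manifest, spec = spec)
  }
  if (is.null(seed)) runner() else withr::with_seed(seed, runner())
}
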
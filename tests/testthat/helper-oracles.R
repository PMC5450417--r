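# Independent brute-force oracles (explicit loops, no shared code with the
# package internals) plus small fixture builders.

# QMDR by explicit enumeration of the 3^K cells (K <= 2).
oracle_qmdr <- function(geno, pheno, idx) {
  k <- length(idx)
  stopifnot(k <= 2)
  n <- nrow(geno)
  grand <- sum(pheno) / n
  combos <- if (k == 1) matrix(0:2, ncol = 1) else
    as.matrix(expand.grid(a = 0:2, b = 0:2))
  labels <- integer(n)
  for (ci in seq_len(nrow(combos))) {
    in_cell <- rep(TRUE, n)
    for (j in seq_len(k)) in_cell <- in_cell & geno[, idx[j]] == combos[ci, j]
    if (any(in_cell)) {
      cell_mean <- sum(pheno[in_cell]) / sum(in_cell)
      if (cell_mean > grand) labels[in_cell] <- 1L
    }
  }
  g1 <- pheno[labels == 1L]
  g0 <- pheno[labels == 0L]
  t_stat <- 0
  valid <- FALSE
  if (length(g1) >= 2 && length(g0) >= 2) {
    m1 <- mean(g1); m0 <- mean(g0)
    sp2 <- (sum((g1 - m1)^2) + sum((g0 - m0)^2)) / (length(g1) + length(g0) - 2)
    if (sp2 > 0) {
      t_stat <- (m1 - m0) / sqrt(sp2 * (1 / length(g1) + 1 / length(g0)))
      valid <- TRUE
    }
  }
  list(labels = labels, t = t_stat, valid = valid)
}

# Plug-in entropies by nested loops over observed category combinations.
oracle_entropy <- function(x) {
  n <- length(x)
  h <- 0
  for (v in unique(x)) {
    p <- sum(x == v) / n
    h <- h - p * log2(p)
  }
  h
}

oracle_mi <- function(x, y) {
  oracle_entropy(x) + oracle_entropy(y) -
    oracle_entropy(paste(x, y, sep = "|"))
}

oracle_ig <- function(a, b, cls) {
  oracle_mi(paste(a, b, sep = "|"), cls) - oracle_mi(a, cls) - oracle_mi(b, cls)
}

# Exhaustive O(n^2 * fronts) nondominated sorting by repeated peeling.
oracle_nds <- function(t_stat, ig, size) {
  n <- length(t_stat)
  dominates <- function(i, j) {
    ge <- t_stat[i] >= t_stat[j] && ig[i] >= ig[j] && size[i] <= size[j]
    strict <- t_stat[i] > t_stat[j] || ig[i] > ig[j] || size[i] < size[j]
    ge && strict
  }
  rank <- rep(NA_integer_, n)
  r <- 0L
  while (anyNA(rank)) {
    front <- c()
    for (i in which(is.na(rank))) {
      dominated <- FALSE
      for (j in which(is.na(rank))) {
        if (i != j && dominates(j, i)) {
          dominated <- TRUE
          break
        }
      }
      if (!dominated) front <- c(front, i)
    }
    rank[front] <- r
    r <- r + 1L
  }
  rank
}

# Balanced XOR fixture: A, B binary-coded (0/1), class = XOR, `reps` copies
# of each of the 4 joint cells.
make_xor_vectors <- function(reps = 5L) {
  a <- rep(c(0L, 0L, 1L, 1L), reps)
  b <- rep(c(0L, 1L, 0L, 1L), reps)
  list(a = a, b = b, cls = as.integer(xor(a == 1L, b == 1L)))
}

# Small random quantitative dataset.
make_random_dataset <- function(n = 40L, m = 6L, seed = 1L) {
  withr::with_seed(seed, {
    geno <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
    genotype_dataset(geno, rnorm(n), phenotype_kind = "quantitative")
  })
}

# Strong-signal planted fixture used across search tests.
make_planted_fixture <- function(seed = 42L, n = 500L, m = 30L) {
  simulate_epistasis(
    simulation_spec(n_genes = 2L, maf = 0.4, heritability = 0.2,
                    trait_sd = 0.05, n_samples = n, n_total_snps = m),
    seed = seed
  )
}
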
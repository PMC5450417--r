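test_that("Hardy-Weinberg frequencies follow q^2, 2pq, p^2", {
  expect_equal(hwe_genotype_frequencies(0.5), c(0.25, 0.5, 0.25))
  expect_equal(hwe_genotype_frequencies(0.2), c(0.04, 0.32, 0.64))
  for (maf in c(0.05, 0.17, 0.33, 0.5)) {
    expect_equal(sum(hwe_genotype_frequencies(maf)), 1)
  }
  expect_error(hwe_genotype_frequencies(0), "\\(0, 0.5\\]")
  expect_error(hwe_genotype_frequencies(0.6), "\\(0, 0.5\\]")
})

test_that("table heritability matches hand-evaluated cases", {
  expect_equal(table_heritability(matrix(0.3, 3, 3), 0.3), 0)
  xor_tab <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3)
  expect_equal(table_heritability(xor_tab, 0.5), 1.0)
  # scaling deviations by c scales h2 by c^2
  base <- matrix(0.5, 3, 3)
  d <- xor_tab - 0.5
  h1 <- table_heritability(base + 0.2 * d, 0.5)
  h2 <- table_heritability(base + 0.4 * d, 0.5)
  expect_equal(h2 / h1, 4, tolerance = 1e-9)
  expect_error(table_heritability(matrix(0, 3, 3), 0.5), "strictly")
})

test_that("marginal penetrances detect pure versus additive tables", {
  xor_tab <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3)
  m <- marginal_penetrances(xor_tab, 0.5)
  expect_equal(m$rows, rep(0.5, 3))
  expect_equal(m$cols, rep(0.5, 3))
  additive <- outer(0:2, 0:2, function(i, j) (i + j) / 4)
  ma <- marginal_penetrances(additive, 0.5)
  expect_gt(max(ma$rows) - min(ma$rows), 0.4)
  const <- marginal_penetrances(matrix(0.3, 3, 3), 0.2)
  expect_equal(const$rows, rep(0.3, 3))
})

test_that("generated tables hit target heritability with zero main effects", {
  for (maf in c(0.2, 0.4)) {
    for (h2 in c(0.001, 0.01, 0.1, 0.2)) {
      pm <- withr::with_seed(57L, generate_penetrance_table(maf, h2))
      expect_s3_class(pm, "penetrance_model")
      expect_true(all(pm$table >= 0 & pm$table <= 1))
      expect_equal(pm$heritability, h2, tolerance = 1e-6)
      marg <- marginal_penetrances(pm$table, maf)
      expect_lt(max(abs(c(marg$rows, marg$cols) - pm$mean_k)), 1e-9)
      expect_equal(table_heritability(pm$table, maf), pm$heritability)
    }
  }
  pm1 <- withr::with_seed(59L, generate_penetrance_table(0.4, 0.1))
  pm2 <- withr::with_seed(59L, generate_penetrance_table(0.4, 0.1))
  expect_identical(pm1$table, pm2$table)
})

test_that("noiseless phenotypes are an exact function of the genotypes", {
  sim <- simulate_epistasis(simulation_spec(1L, 0.4, 0.2, 0, 200L, 10L),
                            seed = 61L)
  idx <- match(sim$truth$genes[[1]], sim$dataset$snp_ids)
  f <- sim$genes[[1]]$table[cbind(sim$dataset$genotypes[, idx[1]] + 1L,
                                  sim$dataset$genotypes[, idx[2]] + 1L)]
  expect_identical(sim$dataset$phenotype, f)
  # two genes: phenotype is the exact sum of both penetrance values
  sim2 <- simulate_epistasis(simulation_spec(2L, 0.4, 0.2, 0, 200L, 10L),
                             seed = 63L)
  mu <- numeric(200L)
  for (g in 1:2) {
    idx <- match(sim2$truth$genes[[g]], sim2$dataset$snp_ids)
    mu <- mu + sim2$genes[[g]]$table[cbind(sim2$dataset$genotypes[, idx[1]] + 1L,
                                           sim2$dataset$genotypes[, idx[2]] + 1L)]
  }
  expect_equal(sim2$dataset$phenotype, mu, tolerance = 1e-12)
})

test_that("simulated datasets have the configured structure", {
  spec <- simulation_spec(2L, 0.4, 0.1, 0.1, 300L, 100L)
  sim <- simulate_epistasis(spec, seed = 65L)
  expect_identical(sim$dataset$n_snps, 100L)
  expect_identical(length(sim$truth$functional_snp_ids), 4L)
  expect_identical(length(sim$truth$genes), 2L)
  expect_identical(nrow(sim$manifest), 2L)
  expect_equal(sim$manifest$realized_h2, rep(0.1, 2), tolerance = 1e-6)
  # replicate determinism from seed
  sim_b <- simulate_epistasis(spec, seed = 65L)
  expect_identical(sim_b$dataset$genotypes, sim$dataset$genotypes)
  expect_identical(sim_b$dataset$phenotype, sim$dataset$phenotype)
  expect_error(simulation_spec(2L, 0.4, 0.1, 0.1, 300L, 3L), "at least")
})

test_that("phenotype moments match the penetrance models", {
  spec <- simulation_spec(2L, 0.4, 0.1, 0.1, 8000L, 20L)
  sim <- simulate_epistasis(spec, seed = 67L)
  y <- sim$dataset$phenotype
  expect_lt(abs(mean(y) - sum(sim$manifest$mean_k)),
            4 * stats::sd(y) / sqrt(length(y)))
  # per-gene dispersion: Var(y) ~ sum Var(f_g) + n_genes * sd^2
  var_f <- sum(vapply(sim$genes, function(g) {
    w <- hwe_genotype_frequencies(g$maf)
    p <- outer(w, w)
    sum(p * (g$table - g$mean_k)^2)
  }, 0))
  expect_equal(stats::var(y), var_f + 2 * 0.1^2, tolerance = 0.15)
})

test_that("simulated genotype frequencies are consistent with HWE", {
  sim <- simulate_epistasis(simulation_spec(2L, 0.4, 0.1, 0.1, 8000L, 8L),
                            seed = 69L)
  idx <- match(sim$truth$functional_snp_ids, sim$dataset$snp_ids)
  for (j in idx) {
    obs <- tabulate(sim$dataset$genotypes[, j] + 1L, 3L)
    p <- stats::chisq.test(obs, p = hwe_genotype_frequencies(0.4))$p.value
    expect_gt(p, 0.001)
  }
})
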
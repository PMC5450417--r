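test_that("single-SNP attribute labels cells by mean versus grand mean", {
  d <- genotype_dataset(matrix(c(0L, 0L, 1L, 1L, 2L, 2L), ncol = 1),
                        c(1, 1, 5, 5, 1, 1), snp_ids = "rs1")
  att <- mdr_attribute(d, "rs1")
  expect_equal(att$grand_mean, 14 / 6)
  expect_identical(att$labels, c(0L, 0L, 1L, 1L, 0L, 0L))
  expect_identical(att$cells$status, c("low", "high", "low"))
})

test_that("cells tied with the grand mean are low; G1 can be empty", {
  d <- genotype_dataset(matrix(c(0L, 1L, 2L, 0L), ncol = 1), rep(2, 4))
  att <- mdr_attribute(d, 1L)
  expect_true(all(att$labels == 0L))
  expect_true(all(att$cells$status[att$cells$n > 0] == "low"))
})

test_that("two-SNP XOR pattern labels exactly the XOR cells high", {
  combos <- expand.grid(g1 = 0:2, g2 = 0:2)
  geno <- as.matrix(combos[rep(seq_len(9), each = 4), ])
  is_xor <- xor(geno[, 1] == 1L, geno[, 2] == 1L)
  pheno <- ifelse(is_xor, 5, 1)
  d <- genotype_dataset(unname(geno), pheno, snp_ids = c("s1", "s2"))
  att <- mdr_attribute(d, c(1L, 2L))
  expect_identical(att$labels, as.integer(is_xor))
  observed <- att$cells[att$cells$n > 0, ]
  expect_identical(observed$status == "high",
                   xor(combos$g1 == 1L, combos$g2 == 1L))
})

test_that("pooled t-statistic matches the hand computation and flags degeneracy", {
  t_val <- qmdr_t_statistic(c(1L, 1L, 1L, 0L, 0L, 0L), c(4, 5, 6, 1, 2, 3))
  expect_equal(as.numeric(t_val), 3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_true(attr(t_val, "valid"))
  # empty G1
  t0 <- qmdr_t_statistic(rep(0L, 4), c(1, 2, 3, 4))
  expect_equal(as.numeric(t0), 0)
  expect_false(attr(t0, "valid"))
  # zero pooled variance
  tz <- qmdr_t_statistic(c(1L, 1L, 0L, 0L), c(2, 2, 2, 2))
  expect_equal(as.numeric(tz), 0)
  expect_false(attr(tz, "valid"))
})

test_that("binary MDR cells follow the case/control ratio threshold rule", {
  # cells: g=0 -> 3 cases / 1 control (high at T=1); g=1 -> 1/1 (tie, low);
  # g=2 -> 0 cases / 2 controls (low)
  geno <- matrix(c(rep(0L, 4), rep(1L, 2), rep(2L, 2)), ncol = 1)
  pheno <- c(1, 1, 1, 0, 1, 0, 0, 0)
  d <- genotype_dataset(geno, pheno, phenotype_kind = "binary")
  att <- mdr_attribute(d, 1L, threshold = 1)
  expect_identical(att$cells$status, c("high", "low", "low"))
  expect_identical(att$labels, c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L))
})

test_that("QMDR kernel reproduces the brute-force oracle for K <= 2", {
  for (case in 1:12) {
    d <- make_random_dataset(n = sample(10:50, 1), m = 4L, seed = 100L + case)
    ek <- build_expert_knowledge(d)
    for (idx in list(1L, 3L, c(1L, 2L), c(2L, 4L))) {
      oracle <- oracle_qmdr(d$genotypes, d$phenotype, idx)
      att <- mdr_attribute(d, idx)
      expect_identical(att$labels, oracle$labels)
      expect_equal(as.numeric(qmdr_t_statistic(att, d$phenotype)), oracle$t,
                   tolerance = 1e-12)
      sc <- score_model(d, idx, ek)
      expect_equal(sc$t_statistic, oracle$t, tolerance = 1e-12)
      expect_identical(sc$valid, oracle$valid)
    }
  }
})

test_that("t-statistic is invariant to genotype relabeling and SNP order", {
  d <- make_random_dataset(n = 50L, m = 4L, seed = 7L)
  ek <- build_expert_knowledge(d)
  base <- score_model(d, c(1L, 3L), ek)
  # swap codes 0 <-> 2 within SNP 1
  g2 <- d$genotypes
  g2[, 1] <- 2L - g2[, 1]
  d2 <- genotype_dataset(g2, d$phenotype, snp_ids = d$snp_ids)
  ek2 <- build_expert_knowledge(d2)
  expect_equal(score_model(d2, c(1L, 3L), ek2)$t_statistic, base$t_statistic,
               tolerance = 1e-12)
  # SNP order within the model
  expect_equal(score_model(d, c(3L, 1L), ek)$t_statistic, base$t_statistic,
               tolerance = 1e-12)
})

test_that("model scores combine t, mean pairwise gain and size", {
  d <- make_random_dataset(n = 60L, m = 5L, seed = 11L)
  ek <- build_expert_knowledge(d)
  s1 <- score_model(d, 2L, ek)
  expect_identical(s1$size, 1L)
  expect_equal(s1$interaction_info, 0)
  s3 <- score_model(d, c(1L, 3L, 5L), ek)
  expect_equal(
    s3$interaction_info,
    mean(c(ek$gain[1, 3], ek$gain[1, 5], ek$gain[3, 5])),
    tolerance = 1e-12
  )
  expect_identical(s3$size, 3L)
  expect_error(score_model(d, c(1L, 1L), ek), "distinct")
  expect_error(score_model(d, integer(0), ek), "at least one")
})

test_that("a noiseless planted pair outscores both constituent SNPs", {
  sim <- simulate_epistasis(
    simulation_spec(1L, 0.4, 0.2, 0, 400L, 10L), seed = 21L
  )
  d <- sim$dataset
  ek <- build_expert_knowledge(d)
  pair <- match(sim$truth$functional_snp_ids, d$snp_ids)
  t_pair <- score_model(d, pair, ek)$t_statistic
  for (s in pair) {
    expect_gt(t_pair, score_model(d, s, ek)$t_statistic)
  }
  # brute force: the planted pair is the best of all 2-SNP models
  all_pairs <- utils::combn(d$n_snps, 2, simplify = FALSE)
  ts <- vapply(all_pairs, function(p) score_model(d, p, ek)$t_statistic, 0)
  expect_setequal(all_pairs[[which.max(ts)]], pair)
})

test_that("adding a pure-noise SNP keeps the kernel valid", {
  sim <- make_planted_fixture(seed = 33L, n = 300L, m = 10L)
  d <- sim$dataset
  ek <- build_expert_knowledge(d)
  pair <- match(sim$truth$genes[[1]], d$snp_ids)
  noise <- setdiff(seq_len(d$n_snps), match(sim$truth$functional_snp_ids,
                                            d$snp_ids))[1]
  sc <- score_model(d, c(pair, noise), ek)
  expect_true(sc$valid)
  expect_identical(sc$size, 3L)
})

test_that("k-fold QMDR cross-validation scores train and test splits", {
  sim <- make_planted_fixture(seed = 9L, n = 400L, m = 10L)
  pair <- match(sim$truth$genes[[1]], sim$dataset$snp_ids)
  cv <- qmdr_cv(sim$dataset, pair, folds = 5L, seed = 2L)
  expect_identical(nrow(cv), 5L)
  expect_true(all(cv$train_t > 0))
  expect_gt(attr(cv, "mean_test_t"), 2)  # real signal generalizes
})
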
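test_that("Shannon entropy matches closed-form values", {
  expect_equal(shannon_entropy(c(4, 4)), 1.0)
  expect_equal(shannon_entropy(c(8)), 0.0)
  expect_equal(shannon_entropy(c(1, 1, 2)), 1.5)
  expect_error(shannon_entropy(c(0, 0)), "positive")
  expect_error(shannon_entropy(c(-1, 2)), "non-negative")
})

test_that("mutual information matches the plug-in oracle", {
  expect_equal(mutual_information(rep(1, 8), rep(c(0, 1), 4)), 0)
  cls <- rep(c(0, 1), each = 4)
  expect_equal(mutual_information(cls, cls), 1.0)
  # joint counts [[2,1],[1,2]]
  x <- c(0, 0, 0, 1, 1, 1)
  y <- c(0, 0, 1, 0, 1, 1)
  expect_equal(mutual_information(x, y), oracle_mi(x, y), tolerance = 1e-12)
  expect_error(mutual_information(1:3, 1:4), "lengths differ")
})

test_that("interaction gain recovers synergy, redundancy and independence", {
  v <- make_xor_vectors(reps = 5L)
  expect_equal(interaction_gain(v$a, v$b, v$cls), 1.0, tolerance = 1e-12)
  # triple redundancy A = B = C
  x <- rep(c(0L, 1L), each = 6)
  expect_equal(interaction_gain(x, x, x), -1.0, tolerance = 1e-12)
  # exact independence: balanced C replicated over every (A,B) cell
  g <- expand.grid(a = 0:2, b = 0:2, cls = 0:1)
  expect_equal(interaction_gain(g$a, g$b, g$cls), 0, tolerance = 1e-12)
})

test_that("binarize_trait splits at the mean and rejects constants", {
  expect_identical(binarize_trait(c(1, 2, 3, 10)), c(0L, 0L, 0L, 1L))
  sym <- c(-2, -1, 1, 2)
  expect_equal(sum(binarize_trait(sym)), 2L)
  expect_error(binarize_trait(rep(3, 5)), "Constant")
})

test_that("expert-knowledge table is symmetric with a zero diagonal", {
  d <- make_random_dataset(n = 60L, m = 5L, seed = 13L)
  ek <- build_expert_knowledge(d)
  expect_equal(ek$gain, t(ek$gain))
  expect_equal(unname(diag(ek$gain)), rep(0, 5))
  expect_true(all(ek$best_partner != seq_len(5)))
  pairs <- rank_pairs(ek)
  expect_identical(nrow(pairs), 10L)
  expect_true(all(diff(pairs$gain_bits) <= 0))
})

test_that("every pairwise gain agrees with the nested-loop oracle to 1e-12", {
  d <- make_random_dataset(n = 50L, m = 6L, seed = 17L)
  ek <- build_expert_knowledge(d)
  cls <- binarize_trait(d$phenotype)
  expect_identical(ek$class_vector, cls)
  for (i in 1:5) {
    for (j in (i + 1):6) {
      o <- oracle_ig(d$genotypes[, i], d$genotypes[, j], cls)
      expect_equal(ek$gain[i, j], o, tolerance = 1e-12)
      expect_equal(
        interaction_gain(d$genotypes[, i], d$genotypes[, j], cls), o,
        tolerance = 1e-12
      )
    }
  }
})

test_that("interaction gain is invariant to genotype relabeling", {
  d <- make_random_dataset(n = 80L, m = 3L, seed = 19L)
  cls <- binarize_trait(d$phenotype)
  a <- d$genotypes[, 1]
  b <- d$genotypes[, 2]
  expect_equal(interaction_gain(2L - a, b, cls),
               interaction_gain(a, b, cls), tolerance = 1e-12)
})

test_that("a planted noiseless pair dominates the expert-knowledge table", {
  sim <- simulate_epistasis(
    simulation_spec(1L, 0.4, 0.2, 0, 500L, 12L), seed = 23L
  )
  ek <- build_expert_knowledge(sim$dataset)
  top <- rank_pairs(ek)[1, ]
  expect_setequal(c(top$snp_i, top$snp_j), sim$truth$functional_snp_ids)
  idx <- match(sim$truth$functional_snp_ids, sim$dataset$snp_ids)
  expect_identical(ek$best_partner[idx[1]], idx[2])
  expect_identical(ek$best_partner[idx[2]], idx[1])
})

test_that("two-SNP datasets name each other as best partner", {
  d <- make_random_dataset(n = 30L, m = 2L, seed = 29L)
  ek <- build_expert_knowledge(d)
  expect_identical(ek$best_partner, c(2L, 1L))
})

test_that("null-trait gains are centered near zero", {
  withr::with_seed(31L, {
    n <- 300L
    m <- 33L  # 528 pairs
    geno <- vapply(runif(m, 0.1, 0.5),
                   function(q) sample(0:2, n, TRUE,
                                      prob = c(q^2, 2 * q * (1 - q), (1 - q)^2)),
                   integer(n))
    d <- genotype_dataset(geno, rnorm(n))
  })
  ek <- build_expert_knowledge(d)
  gains <- ek$gain[upper.tri(ek$gain)]
  # plug-in estimates carry a small positive finite-sample bias, so "near
  # zero" is judged on the scale of the gain distribution itself
  expect_lt(abs(mean(gains)), 3 * stats::sd(gains))
  # and the permutation null has the same location: re-pairing the trait
  # with permuted samples shifts the mean by less than one sd
  perm <- withr::with_seed(37L, {
    d_perm <- genotype_dataset(d$genotypes, sample(d$phenotype))
    build_expert_knowledge(d_perm)
  })
  perm_gains <- perm$gain[upper.tri(perm$gain)]
  expect_lt(abs(mean(gains) - mean(perm_gains)), stats::sd(gains))
})
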
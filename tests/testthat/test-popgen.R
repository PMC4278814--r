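test_that("diversity statistics match closed forms", {
  # two alleles at 0.5/0.5, n = 15 individuals -> He = (30/29) * 0.5
  counts <- c(15, 15)
  expect_equal(gene_diversity(counts), 30 / 29 * 0.5, tolerance = 1e-12)

  # monomorphic locus: AR = 1 at every rarefaction size
  expect_equal(rarefied_richness(20, 4), 1)
  expect_equal(rarefied_richness(20, 18), 1)

  # alleles {100,102,103,106}: M = 4 / 7
  expect_equal(gw_m_ratio(c(100, 102, 103, 106)), 4 / 7, tolerance = 1e-12)

  # rarefaction at full sample returns the observed allele count
  expect_equal(rarefied_richness(c(3, 5, 2), 10), 3, tolerance = 1e-12)
  expect_true(is.na(rarefied_richness(c(3, 2), 18)))
})

test_that("locus_summaries aggregates He/AR/M per population", {
  # pop A: 15 inds, two alleles 10/12 at 50/50; pop B monomorphic
  a <- cbind(rep(c(10L, 12L), 15)[1:15], rep(c(12L, 10L), 15)[1:15])
  a <- rbind(a, cbind(rep(14L, 9), rep(14L, 9)))
  g <- genotype_matrix(a, rep(c("A", "B"), c(15, 9)), loci = "L1")
  s <- locus_summaries(g, rarefaction_n = 9)
  expect_equal(s$he[s$pop == "A"], 30 / 29 * 0.5, tolerance = 1e-12)
  expect_equal(s$he[s$pop == "B"], 0)
  expect_equal(s$ar[s$pop == "B"], 1)
  expect_equal(s$m[s$pop == "B"], 1)
  expect_equal(s$na[s$pop == "A"], 2)
})

test_that("Weir-Cockerham components equal the first-principles oracle", {
  # tiny 2-pop, 4-individual, 1-locus fixture: exact to 1e-12
  g <- make_genotypes(list(c(10L, 12L), c(10L, 10L), c(12L, 12L), c(10L, 12L)),
                      c("A", "A", "B", "B"), loci = "L1")
  ours <- f_statistics(g, pairwise = FALSE)
  oracle <- oracle_wc_components(g)
  expect_equal(unname(ours$components$f), unname(oracle), tolerance = 1e-12)

  # larger random fixture, multiple loci
  g2 <- random_genotypes(12, 3, n_loci = 4, seed = 2)
  ours2 <- f_statistics(g2, pairwise = FALSE)
  oracle2 <- oracle_wc_components(g2)
  expect_equal(unname(ours2$components$f), unname(oracle2), tolerance = 1e-12)
  expect_equal(ours2$fst, unname(oracle2["a"] / sum(oracle2)),
               tolerance = 1e-12)
})

test_that("fixed allele differences give F_ST = 1", {
  g <- genotype_matrix(rbind(matrix(10L, 10, 2), matrix(20L, 10, 2)),
                       rep(c("A", "B"), each = 10))
  fs <- f_statistics(g)
  expect_equal(fs$fst, 1)
  expect_equal(fs$rst, 1, tolerance = 1e-12)
  expect_equal(fs$pairwise_fst["A", "B"], 1)
})

test_that("a panmictic population split in two shows no differentiation", {
  set.seed(3)
  g <- random_genotypes(100, 2, n_loci = 5, n_alleles = 6, seed = 33)
  fs <- f_statistics(g, pairwise = FALSE)
  expect_lt(abs(fs$fst), 0.02)
  pt <- pairwise_tests(g, n_perm = 200)
  expect_gt(pt$p["P1", "P2"], 0.05)
  expect_false(pt$significant["P1", "P2"])
})

test_that("pairwise permutation test flags fixed differences", {
  g <- genotype_matrix(rbind(matrix(10L, 10, 2), matrix(20L, 10, 2)),
                       rep(c("A", "B"), each = 10))
  pt <- pairwise_tests(g, n_perm = 100)
  expect_equal(pt$p["A", "B"], 1 / 101)
  expect_true(pt$significant["A", "B"])
  expect_error(pairwise_tests(g, n_perm = 10), ">= 100")
})

test_that("Bonferroni threshold follows the number of pairs", {
  g <- random_genotypes(9, 14, n_loci = 2, seed = 5)
  pt <- pairwise_tests(g, n_perm = 100)
  expect_equal(pt$n_pairs, choose(14, 2))   # 91 pairs for 14 populations
  expect_equal(pt$bonferroni_threshold, 0.05 / 91)
})

test_that("AMOVA sums of squares are conserved", {
  g <- random_genotypes(8, 3, n_loci = 2, seed = 6)
  am <- amova_sizes(g, 1)
  y <- as.numeric(g$alleles[, 1:2])
  ss_total <- sum((y - mean(y))^2)
  expect_equal(sum(am$ss), ss_total, tolerance = 1e-9)
})

test_that("multi-locus F_ST is consistent for iid replicate loci", {
  set.seed(7)
  base <- random_genotypes(15, 3, n_loci = 1, n_alleles = 4, seed = 44)
  g3 <- genotype_matrix(cbind(base$alleles, base$alleles, base$alleles),
                        as.character(base$pop))
  f1 <- f_statistics(base, pairwise = FALSE)$fst
  f3 <- f_statistics(g3, pairwise = FALSE)$fst
  expect_equal(f1, f3, tolerance = 1e-12)
})

test_that("shift invariance: He/AR/M/PID ignore allele sizes, R_ST does not", {
  g <- random_genotypes(15, 3, n_loci = 3, n_alleles = 4, seed = 8)
  shift <- g$alleles
  shift[shift > 0] <- shift[shift > 0] + 7L
  g2 <- genotype_matrix(shift, as.character(g$pop))
  s1 <- locus_summaries(g); s2 <- locus_summaries(g2)
  expect_equal(s1$he, s2$he)
  expect_equal(s1$ar, s2$ar)
  expect_equal(s1$m, s2$m)   # range is shift-invariant
  expect_equal(probability_of_identity(g), probability_of_identity(g2))
  f1 <- f_statistics(g, pairwise = FALSE)
  f2 <- f_statistics(g2, pairwise = FALSE)
  expect_equal(f1$fst, f2$fst, tolerance = 1e-12)
  # R_ST changes under a non-affine size relabeling
  warp <- g$alleles
  warp[warp > 0] <- warp[warp > 0]^2L
  g3 <- genotype_matrix(warp, as.character(g$pop))
  expect_false(isTRUE(all.equal(f_statistics(g3, pairwise = FALSE)$rst,
                                f1$rst, tolerance = 1e-6)))
})

test_that("IBD slope recovers an exact linear relationship", {
  reg <- make_registry(6, seed = 10)
  dmat <- site_distances(reg)
  b <- 0.04; a <- 0.02
  y <- a + b * log(dmat)
  d <- y / (1 + y)
  diag(d) <- NA
  est <- ibd_slope(d, dmat)
  expect_equal(est$slope, b, tolerance = 1e-12)
  # uniform distance rescaling leaves the slope unchanged
  est2 <- ibd_slope(d, dmat * 3.7)
  expect_equal(est2$slope, b, tolerance = 1e-10)
  # coincident sites error
  d0 <- dmat; d0[2, 1] <- d0[1, 2] <- 0
  expect_error(ibd_slope(d, d0), "coincident")
})

test_that("IBD permutation test is calibrated on unstructured data", {
  reg <- make_registry(5, seed = 11)
  g <- random_genotypes(10, 5, n_loci = 3, n_alleles = 5, seed = 12)
  levels(g$pop) <- reg$site_id
  set.seed(13)
  res <- ibd_test(g, reg, n_perm = 99)
  expect_gte(res$p_value, 0.01)
  expect_true(res$null_ci[1] <= res$null_mean &
                res$null_mean <= res$null_ci[2])
  expect_equal(res$n_perm, 99)
})

test_that("allele-size randomization: F_ST invariant, null p uniform-ish", {
  g <- random_genotypes(15, 3, n_loci = 3, n_alleles = 5, seed = 14)
  f_before <- f_statistics(g, pairwise = FALSE)$fst
  set.seed(15)
  res <- allele_size_randomization(g, n_perm = 60)
  # permuting sizes does not change F_ST (identity-in-state)
  expect_equal(f_statistics(g, pairwise = FALSE)$fst, f_before)
  expect_gte(res$p_value, 0)
  expect_lte(res$p_value, 1)
  # no stepwise structure here: observed R_ST should be unexceptional
  expect_gt(res$p_value, 0.02)
})

test_that("probability of identity follows the closed forms", {
  expect_equal(probability_of_identity(list(c(0.5, 0.5))), 0.375)
  expect_equal(probability_of_identity(list(c(0.5, 0.5), c(0.5, 0.5))),
               0.140625)
  expect_error(probability_of_identity(list(c(0.5, 0.4))), "sum to 1")
  # PID strictly decreases with each added polymorphic locus
  set.seed(16)
  pids <- sapply(1:6, function(k) {
    fr <- lapply(seq_len(k), function(i) {
      p <- runif(4); p / sum(p)
    })
    probability_of_identity(fr)
  })
  expect_true(all(diff(pids) < 0))
})

test_that("null-allele EM recovers the simulated null frequency", {
  set.seed(17)
  n <- 500
  p_null <- 0.2
  vis <- c(10L, 12L, 14L)
  pv <- c(0.3, 0.3, 0.2)
  draw <- function() sample(c(vis, 0L), 2 * n, replace = TRUE,
                            prob = c(pv, p_null))
  a1 <- draw()[1:n]; a2 <- draw()[1:n]
  obs <- cbind(a1, a2)
  # null hets look like visible homozygotes; null homs are blanks
  shown <- t(apply(obs, 1, function(z) {
    if (all(z == 0L)) c(0L, 0L)
    else if (any(z == 0L)) rep(z[z != 0L], 2)
    else z
  }))
  g <- genotype_matrix(shown, rep("A", n))
  em <- null_allele_em(g)
  expect_lt(abs(em$null_freq - p_null), 0.05)

  # clean Hardy-Weinberg data: null frequency near zero
  clean <- cbind(sample(vis, n, TRUE, pv / sum(pv)),
                 sample(vis, n, TRUE, pv / sum(pv)))
  em0 <- null_allele_em(genotype_matrix(clean, rep("A", n)))
  expect_lt(em0$null_freq, 0.02)

  # all-blank locus: boundary at 1
  gb <- genotype_matrix(matrix(0L, 5, 2), rep("A", 5))
  emb <- null_allele_em(gb)
  expect_equal(emb$null_freq, 1)
  expect_true(emb$boundary)
})

test_that("Hardy-Weinberg exact test behaves at the extremes", {
  set.seed(18)
  # equilibrium data: p-value should not be extreme
  p <- c(0.5, 0.5)
  n <- 100
  a1 <- sample(c(10L, 12L), n, TRUE, p)
  a2 <- sample(c(10L, 12L), n, TRUE, p)
  g <- genotype_matrix(cbind(a1, a2), rep("A", n))
  hw <- hw_exact_test(g, n_shuffle = 400)
  expect_gt(hw$p_value, 0.01)
  # total heterozygote excess: tiny p-value
  het <- genotype_matrix(cbind(rep(10L, 40), rep(12L, 40)), rep("A", 40))
  hw2 <- hw_exact_test(het, n_shuffle = 400)
  expect_lt(hw2$p_value, 0.02)
})
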
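test_that("no mutation means identical monomorphic demes", {
  d <- data.frame(site_id = c("A", "B"),
                  founding_gen = c(NA, 5L), source = c(NA, "A"),
                  ne_class = c("early", "early"), stringsAsFactors = FALSE)
  sp <- scenario_spec(1, d, 2010, root = "A")
  set.seed(1)
  draw <- parameter_draw(sp, 4)
  draw$mu[] <- 0
  g <- simulate_genotypes(sp, draw, c(A = 10, B = 10), 4)
  expect_true(all(g$alleles == 20L))
})

test_that("single-deme equilibrium diversity matches the Ohta-Kimura form", {
  set.seed(2)
  g <- simulate_single_deme(1000, 1e-4, 20, n_loci = 200)
  he <- locus_summaries(g)$he
  expected <- 1 - 1 / sqrt(1 + 8 * 1000 * 1e-4)
  se <- sd(he) / sqrt(length(he))
  expect_lt(abs(mean(he) - expected), 3 * se)
})

test_that("pairwise coalescence times follow the geometric law", {
  set.seed(3)
  tt <- pair_coalescence_times(500, 5000)
  ks <- suppressWarnings(ks.test(tt, function(q) pgeom(q - 1, 1 / 1000)))
  expect_gt(ks$p.value, 0.01)
  expect_equal(mean(tt), 1000, tolerance = 0.05)
})

test_that("summary statistics equal an independent reimplementation", {
  set.seed(4)
  g <- random_genotypes(8, 3, n_loci = 3, n_alleles = 4, seed = 21)
  ours <- summary_stats(g, "abc")
  oracle <- oracle_abc_stats(g)
  expect_equal(ours[names(oracle)], oracle, tolerance = 1e-10)
})

test_that("classification index is symmetric and small for duplicated populations", {
  set.seed(5)
  base <- matrix(sample(10:15, 2 * 3 * 40, TRUE), 40, 6)
  g <- genotype_matrix(rbind(base, base), rep(c("A", "B"), each = 40))
  v <- summary_stats(g, "abc")
  # identical populations: both directions agree exactly, and the index
  # is far below that of genuinely differentiated populations
  expect_equal(unname(v["ci.A.B"]), unname(v["ci.B.A"]), tolerance = 1e-10)
  expect_lt(abs(v["ci.A.B"]), 0.5)
  expect_equal(unname(v["he.A"]), unname(v["he.B"]))
  gd <- genotype_matrix(rbind(matrix(10L, 20, 6), matrix(20L, 20, 6)),
                        rep(c("A", "B"), each = 20))
  vd <- summary_stats(gd, "abc")
  expect_gt(vd["ci.A.B"], 10 * abs(v["ci.A.B"]))
})

test_that("monomorphic data give zero diversity and M = 1", {
  g <- genotype_matrix(matrix(12L, 10, 6), rep(c("A", "B"), each = 5))
  v <- summary_stats(g, "abc")
  expect_true(all(v[grepl("^he", names(v))] == 0))
  expect_true(all(v[grepl("^gwm", names(v))] == 1))
  vm <- summary_stats(g, "model_check")
  expect_true(all(vm[grepl("^na\\.", names(vm))] == 1))
  expect_true(all(vm[grepl("^szvar", names(vm))] == 0))
  expect_true(all(vm[grepl("^das", names(vm))] == 0))
  expect_true(all(vm[grepl("^dmu2", names(vm))] == 0))
})

test_that("exchangeability: permuting individuals within demes preserves stats", {
  specs <- make_four_scenarios()
  ss <- setNames(rep(10, 14), paste0("P", 1:14))
  set.seed(6)
  g <- simulate_genotypes(specs$scenario1, NULL, ss, 5)
  v1 <- summary_stats(g, "abc")
  # permute individuals within each population
  idx <- unlist(lapply(levels(g$pop), function(p) sample(which(g$pop == p))))
  g2 <- genotype_matrix(g$alleles[idx, ], as.character(g$pop[idx]), g$loci)
  expect_equal(summary_stats(g2, "abc"), v1)
})

test_that("mutation-rate / Ne scaling leaves single-deme diversity invariant", {
  set.seed(7)
  he1 <- mean(locus_summaries(simulate_single_deme(2000, 5e-5, 20, 150))$he)
  he2 <- mean(locus_summaries(simulate_single_deme(1000, 1e-4, 20, 150))$he)
  expect_lt(abs(he1 - he2), 0.04)   # theta-dependence only, MC error
})

test_that("reference tables are balanced, reproducible, and separable", {
  specs <- make_four_scenarios()
  ss <- setNames(rep(10, 14), paste0("P", 1:14))
  set.seed(8)
  ref <- build_reference(specs, 100, ss, 5)
  expect_equal(nrow(ref$stats), 400L)
  expect_equal(as.vector(table(ref$scenario)), rep(100L, 4))
  set.seed(8)
  ref2 <- build_reference(specs, 100, ss, 5)
  expect_identical(ref$stats, ref2$stats)
  expect_error(build_reference(specs, 50, ss, 5), ">= 100")
})

test_that("scenario-1 and scenario-3 summary statistics differ detectably", {
  specs <- make_four_scenarios()
  ss <- setNames(rep(30, 14), paste0("P", 1:14))
  set.seed(9)
  ref <- build_reference(specs[c(1, 3)], 500, ss, 9)
  s1 <- ref$stats[ref$scenario == 1, ]
  s3 <- ref$stats[ref$scenario == 3, ]
  pvals <- vapply(seq_len(ncol(s1)), function(j)
    suppressWarnings(stats::wilcox.test(s1[, j], s3[, j])$p.value), 0)
  expect_lt(min(p.adjust(pvals, "bonferroni")), 0.01)
})

test_that("model choice posteriors are proper and standardization-invariant", {
  specs <- make_four_scenarios()
  ss <- setNames(rep(10, 14), paste0("P", 1:14))
  set.seed(10)
  ref <- build_reference(specs, 150, ss, 5)
  g <- simulate_genotypes(specs$scenario2, NULL, ss, 5)
  obs <- summary_stats(g, "abc")
  mc <- model_choice(obs, ref, n_closest = 150)
  expect_equal(sum(mc$posterior), 1, tolerance = 1e-9)
  expect_true(all(mc$posterior >= 0))
  expect_equal(sum(mc$rejection), 1, tolerance = 1e-9)
  expect_false(is.null(mc$ci))
  expect_true(all(mc$ci["lo", ] <= mc$posterior + 1e-9))
  expect_true(all(mc$ci["hi", ] >= mc$posterior - 1e-9))

  # affine rescaling of one summary statistic changes nothing
  ref2 <- ref
  ref2$stats[, 3] <- ref2$stats[, 3] * 100 + 7
  obs2 <- obs
  obs2[3] <- obs2[3] * 100 + 7
  set.seed(11); mc1 <- model_choice(obs, ref, n_closest = 150, ci = FALSE)
  set.seed(11); mc2 <- model_choice(obs2, ref2, n_closest = 150, ci = FALSE)
  expect_equal(mc1$posterior, mc2$posterior, tolerance = 1e-6)

  expect_error(model_choice(obs, ref, n_closest = 1e6), "exceeds")
})

test_that("an observation at the centroid of a balanced cloud is uninformative", {
  # synthetic reference: identical stat distributions across scenarios
  set.seed(12)
  stats <- matrix(rnorm(2000 * 6), 2000, 6,
                  dimnames = list(NULL, paste0("s", 1:6)))
  ref <- structure(list(stats = stats, scenario = rep(1:4, each = 500),
                        params = NULL, n_failed = 0L, variant = "abc"),
                   class = "reference_table")
  obs <- colMeans(stats)
  mc <- model_choice(obs, ref, n_closest = 400, ci = FALSE)
  expect_true(all(abs(mc$posterior - 0.25) < 0.12))
})

test_that("a perfectly separable reference yields zero confusion", {
  # disjoint stat clouds per scenario; model_choice must always recover
  set.seed(13)
  centers <- c(0, 20, 40, 60)
  stats <- do.call(rbind, lapply(centers, function(m)
    matrix(rnorm(300 * 4, mean = m), 300, 4)))
  colnames(stats) <- paste0("s", 1:4)
  ref <- structure(list(stats = stats, scenario = rep(1:4, each = 300),
                        params = NULL, n_failed = 0L, variant = "abc"),
                   class = "reference_table")
  hits <- 0L
  for (k in 1:4) {
    obs <- rnorm(4, mean = centers[k])
    names(obs) <- colnames(stats)
    mc <- model_choice(obs, ref, n_closest = 120, ci = FALSE)
    if (which.max(mc$posterior) == k) hits <- hits + 1L
  }
  expect_equal(hits, 4L)
})

test_that("confusion matrix bookkeeping: rows sum to the pseudo count", {
  specs <- make_four_scenarios()[1:2]
  ss <- setNames(rep(8, 14), paste0("P", 1:14))
  set.seed(14)
  ref <- build_reference(specs, 120, ss, 4)
  cr <- confusion_rates(ref, specs, 5, ss, 4, n_closest = 60)
  expect_true(all(rowSums(cr$confusion) == 5L))
  expect_true(all(cr$type1 >= 0 & cr$type1 <= 1))
  expect_true(all(cr$type2 >= 0 & cr$type2 <= 1))
})

test_that("posterior-predictive PCA covers same-model data, flags gross misfit", {
  specs <- make_four_scenarios()
  ss <- setNames(rep(8, 14), paste0("P", 1:14))
  sp <- specs$scenario1
  set.seed(15)
  g_obs <- simulate_genotypes(sp, NULL, ss, 5)
  ppc <- posterior_predictive_check(sp, g_obs, ss, n_loci = 5, n_sims = 120)
  expect_true(ppc$covered)
  expect_equal(colMeans(ppc$scores), c(PC1 = 0, PC2 = 0), tolerance = 1e-8)

  # gross misfit: absurd allele-size spread, far outside the cloud
  g_bad <- genotype_matrix(matrix(c(2L, 200L), sum(ss), 10),
                           rep(names(ss), times = ss))
  ppc2 <- suppressWarnings(
    posterior_predictive_check(sp, g_bad, ss, n_loci = 5, n_sims = 120))
  expect_false(ppc2$covered)
})
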
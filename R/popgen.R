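# Classical microsatellite statistics: diversity, rarefied allelic
# richness, Garza-Williamson M, Weir-Cockerham F-statistics, R-statistics
# on allele sizes (AMOVA variance components), pairwise permutation tests,
# isolation-by-distance slopes, allele-size randomization, probability of
# identity, null-allele EM, Hardy-Weinberg exact tests.

locus_codes <- function(g, j) {
  a <- locus_alleles(g, j)
  list(a1 = a[, 1], a2 = a[, 2])
}

# ---------------------------------------------------------------------------
# Per-locus, per-population summaries
# ---------------------------------------------------------------------------

#' Rarefied allelic richness from allele counts
#'
#' Expected number of distinct alleles in a random subsample of `g_copies`
#' gene copies (hypergeometric rarefaction):
#' `AR = sum_a [1 - C(N - N_a, g) / C(N, g)]`.
#'
#' @param counts integer vector of allele copy counts.
#' @param g_copies rarefaction size in gene copies.
#' @return Rarefied richness (scalar), `NA` if fewer than `g_copies`
#'   copies are available.
#' @export
rarefied_richness <- function(counts, g_copies) {
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (N < g_copies) return(NA_real_)
  sum(1 - exp(lchoose(N - counts, g_copies) - lchoose(N, g_copies)))
}

#' Unbiased gene diversity (expected heterozygosity)
#'
#' `He = (2n / (2n - 1)) * (1 - sum p_a^2)` with `n` genotyped
#' individuals (Nei's unbiased estimator).
#'
#' @param counts allele copy counts (one genotyped individual = 2 copies).
#' @return He in \[0, 1\].
#' @export
gene_diversity <- function(counts) {
  counts <- counts[counts > 0]
  n2 <- sum(counts)
  if (n2 < 2) return(NA_real_)
  p <- counts / n2
  max(0, n2 / (n2 - 1) * (1 - sum(p^2)))
}

#' Garza-Williamson M ratio
#'
#' `M = Na / (allele size range in repeat units + 1)`; values well below 1
#' indicate lost allelic states, the classic bottleneck footprint.
#'
#' @param sizes distinct allele sizes present (repeat units).
#' @return M in (0, 1\].
#' @export
gw_m_ratio <- function(sizes) {
  sizes <- unique(sizes[sizes > 0])
  if (!length(sizes)) return(NA_real_)
  length(sizes) / (max(sizes) - min(sizes) + 1)
}

#' Per-locus, per-population summary statistics
#'
#' Computes, for every locus x population cell: number of genotyped
#' individuals, allele count Na, unbiased gene diversity He, rarefied
#' allelic richness at `2 * rarefaction_n` gene copies, and the
#' Garza-Williamson M ratio.  Cells with fewer than `rarefaction_n`
#' genotyped individuals get `AR = NA`.
#'
#' @param g a [genotype_matrix()].
#' @param rarefaction_n rarefaction sample size in individuals (default 9,
#'   the minimum per-site sample size; doubled to gene copies internally).
#' @return A data.frame of class `locus_summary` (locus, pop, n, na, he,
#'   ar, m) with the allele-frequency vectors in attribute `freqs`.
#' @export
locus_summaries <- function(g, rarefaction_n = 9) {
  pops <- levels(g$pop)
  rows <- list()
  freqs <- list()
  for (j in seq_len(n_loci(g))) {
    lc <- locus_codes(g, j)
    for (p in pops) {
      sel <- g$pop == p & lc$a1 > 0L
      copies <- c(lc$a1[sel], lc$a2[sel])
      tab <- table(copies)
      counts <- as.integer(tab)
      sizes <- as.integer(names(tab))
      n <- sum(sel)
      rows[[length(rows) + 1L]] <- data.frame(
        locus = g$loci[j], pop = p, n = n,
        na = length(counts),
        he = if (n > 0) gene_diversity(counts) else NA_real_,
        ar = if (n >= rarefaction_n)
          rarefied_richness(counts, 2L * rarefaction_n) else NA_real_,
        m = gw_m_ratio(sizes),
        stringsAsFactors = FALSE)
      freqs[[paste(g$loci[j], p, sep = ".")]] <-
        setNames(counts / sum(counts), sizes)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "freqs") <- freqs
  class(out) <- c("locus_summary", "data.frame")
  out
}

#' @export
print.locus_summary <- function(x, ...) {
  cat("Per-locus, per-population microsatellite summaries (",
      length(unique(x$locus)), " loci x ", length(unique(x$pop)),
      " populations)\n", sep = "")
  agg <- aggregate(x[, c("na", "he", "ar", "m")], list(pop = x$pop), mean,
                   na.rm = TRUE)
  print(format(agg, digits = 3), row.names = FALSE)
  invisible(x)
}

# ---------------------------------------------------------------------------
# Weir-Cockerham variance components (F-statistics) and size-based
# analogues (R-statistics)
# ---------------------------------------------------------------------------

# Weir & Cockerham (1984) a, b, c variance components for one locus,
# summed over alleles.  pop_int: integer population id per individual;
# missing genotypes (a1 == 0) are dropped.  Returns c(a, b, c) or NULL if
# fewer than 2 populations have data or the locus is monomorphic.
wc_locus_components <- function(a1, a2, pop_int) {
  keep <- a1 > 0L
  a1 <- a1[keep]; a2 <- a2[keep]; pop <- pop_int[keep]
  tabn <- table(pop)
  tabn <- tabn[tabn > 0]
  if (length(tabn) < 2) return(NULL)
  pops <- as.integer(names(tabn))
  n_i <- as.numeric(tabn)
  r <- length(pops)
  alleles <- sort(unique(c(a1, a2)))
  if (length(alleles) < 2) return(NULL)
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pidx <- match(pop, pops)
  A <- 0; B <- 0; C <- 0
  for (al in alleles) {
    cnt <- (a1 == al) + (a2 == al)
    p_i <- vapply(seq_len(r), function(k) sum(cnt[pidx == k]), 0) / (2 * n_i)
    h_i <- vapply(seq_len(r), function(k)
      sum(cnt[pidx == k] == 1L), 0) / n_i
    pbar <- sum(n_i * p_i) / (r * nbar)
    s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n_i * h_i) / (r * nbar)
    a <- nbar / nc *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    A <- A + a; B <- B + b; C <- C + cc
  }
  c(a = A, b = B, c = C)
}

# Nested ANOVA variance components on a quantitative value per gene copy
# (allele size), diploid individuals within populations.  Returns
# c(sa, sb, sc) = among-pop, among-individual-within-pop,
# within-individual components, plus the sums of squares.
size_anova_components <- function(a1, a2, pop_int) {
  keep <- a1 > 0L
  y1 <- as.numeric(a1[keep]); y2 <- as.numeric(a2[keep]); pop <- pop_int[keep]
  tabn <- table(pop)
  if (length(tabn) < 2) return(NULL)
  if (length(unique(c(y1, y2))) < 2) return(NULL)
  pops <- as.integer(names(tabn))
  n_i <- as.numeric(tabn)
  r <- length(pops)
  N <- sum(n_i)
  pidx <- match(pop, pops)
  ybar_ind <- (y1 + y2) / 2
  ybar_pop <- vapply(seq_len(r), function(k) mean(ybar_ind[pidx == k]), 0)
  ybar <- sum(c(y1, y2)) / (2 * N)
  ss_wi <- sum((y1 - ybar_ind)^2 + (y2 - ybar_ind)^2)
  ss_ai <- 2 * sum((ybar_ind - ybar_pop[pidx])^2)
  ss_ap <- 2 * sum(n_i * (ybar_pop - ybar)^2)
  ms_wi <- ss_wi / N
  ms_ai <- ss_ai / (N - r)
  ms_ap <- ss_ap / (r - 1)
  nc <- (N - sum(n_i^2) / N) / (r - 1)
  sc <- ms_wi
  sb <- (ms_ai - sc) / 2
  sa <- (ms_ap - ms_ai) / (2 * nc)
  c(sa = sa, sb = sb, sc = sc, ss_ap = ss_ap, ss_ai = ss_ai, ss_wi = ss_wi,
    df_ap = r - 1, df_ai = N - r, df_wi = N)
}

#' Hierarchical AMOVA on allele sizes for one locus
#'
#' Nested analysis of molecular variance (populations within total,
#' individuals within populations, gene copies within individuals) on
#' allele sizes; the decomposition behind the R-statistics.
#'
#' @param g a [genotype_matrix()].
#' @param locus locus index or name.
#' @return data.frame with source, df, SS, variance component.
#' @export
amova_sizes <- function(g, locus = 1) {
  j <- if (is.character(locus)) match(locus, g$loci) else locus
  lc <- locus_codes(g, j)
  comp <- size_anova_components(lc$a1, lc$a2, as.integer(g$pop))
  if (is.null(comp)) stop("locus is monomorphic or has < 2 populations")
  data.frame(
    source = c("among_populations", "among_individuals", "within_individuals"),
    df = comp[c("df_ap", "df_ai", "df_wi")],
    ss = comp[c("ss_ap", "ss_ai", "ss_wi")],
    variance = comp[c("sa", "sb", "sc")],
    row.names = NULL)
}

#' Weir-Cockerham F-statistics and size-based R-statistics
#'
#' Multi-locus estimators as ratios of summed variance components:
#' `F_ST = sum(a) / sum(a + b + c)`, `F_IS = 1 - sum(c) / sum(b + c)`,
#' `F_IT = 1 - sum(c) / sum(a + b + c)`; the R-statistics apply the same
#' decomposition to allele sizes (stepwise-mutation-aware).  Pairwise
#' matrices restrict the estimator to each population pair; loci
#' monomorphic across a pair are skipped for that pair.
#'
#' @param g a [genotype_matrix()] with at least two populations.
#' @param pairwise compute pairwise F_ST / R_ST matrices.
#' @return Object of class `fstat_result`: `fis, fst, fit, ris, rst, rit`,
#'   `per_locus` table, and (if requested) `pairwise_fst`, `pairwise_rst`.
#' @export
f_statistics <- function(g, pairwise = TRUE) {
  if (nlevels(g$pop) < 2) stop("F_ST needs at least 2 populations")
  pop_int <- as.integer(g$pop)
  lc <- lapply(seq_len(n_loci(g)), function(j) locus_codes(g, j))
  wc <- lapply(lc, function(l) wc_locus_components(l$a1, l$a2, pop_int))
  sz <- lapply(lc, function(l) size_anova_components(l$a1, l$a2, pop_int))
  sum_wc <- Reduce(`+`, Filter(Negate(is.null), wc))
  sum_sz <- Reduce(`+`, lapply(Filter(Negate(is.null), sz),
                               function(v) v[c("sa", "sb", "sc")]))
  per_locus <- data.frame(
    locus = g$loci,
    fst = vapply(wc, function(v) if (is.null(v)) NA_real_ else
      v["a"] / sum(v), 0),
    rst = vapply(sz, function(v) if (is.null(v)) NA_real_ else
      v["sa"] / sum(v[c("sa", "sb", "sc")]), 0),
    stringsAsFactors = FALSE)
  out <- list(
    fis = 1 - sum_wc["c"] / (sum_wc["b"] + sum_wc["c"]),
    fst = sum_wc["a"] / sum(sum_wc),
    fit = 1 - sum_wc["c"] / sum(sum_wc),
    ris = sum_sz["sb"] / (sum_sz["sb"] + sum_sz["sc"]),
    rst = sum_sz["sa"] / sum(sum_sz),
    rit = (sum_sz["sa"] + sum_sz["sb"]) / sum(sum_sz),
    components = list(f = sum_wc, r = sum_sz),
    per_locus = per_locus)
  out <- lapply(out, function(v) if (is.numeric(v)) unname(v) else v)
  if (pairwise) {
    out$pairwise_fst <- pairwise_differentiation(g, "fst")
    out$pairwise_rst <- pairwise_differentiation(g, "rst")
  }
  structure(out, class = "fstat_result")
}

#' @export
print.fstat_result <- function(x, ...) {
  cat("Multi-locus F-statistics (Weir-Cockerham) and R-statistics:\n")
  cat(sprintf("  F_IS = %.4f   F_ST = %.4f   F_IT = %.4f\n",
              x$fis, x$fst, x$fit))
  cat(sprintf("  R_IS = %.4f   R_ST = %.4f   R_IT = %.4f\n",
              x$ris, x$rst, x$rit))
  if (!is.null(x$pairwise_fst))
    cat(sprintf("  pairwise F_ST: %d populations, range %.4f - %.4f\n",
                nrow(x$pairwise_fst), min(x$pairwise_fst[lower.tri(x$pairwise_fst)]),
                max(x$pairwise_fst[lower.tri(x$pairwise_fst)])))
  invisible(x)
}

# multi-locus differentiation between two subsets of individuals
pair_stat <- function(lc, pop_int, stat = c("fst", "rst")) {
  stat <- match.arg(stat)
  if (stat == "fst") {
    s <- Reduce(`+`, Filter(Negate(is.null),
      lapply(lc, function(l) wc_locus_components(l$a1, l$a2, pop_int))))
    if (is.null(s)) return(NA_real_)
    unname(s["a"] / sum(s))
  } else {
    s <- Reduce(`+`, Filter(Negate(is.null),
      lapply(lc, function(l) {
        v <- size_anova_components(l$a1, l$a2, pop_int)
        if (is.null(v)) NULL else v[c("sa", "sb", "sc")]
      })))
    if (is.null(s)) return(NA_real_)
    unname(s["sa"] / sum(s))
  }
}

#' Pairwise differentiation matrix
#'
#' @param g a [genotype_matrix()].
#' @param stat `"fst"` (Weir-Cockerham) or `"rst"` (allele sizes).
#' @param pop_int optional permuted population assignment (internal use).
#' @return Symmetric matrix with `NA` diagonal.
#' @export
pairwise_differentiation <- function(g, stat = c("fst", "rst"),
                                     pop_int = as.integer(g$pop)) {
  stat <- match.arg(stat)
  pops <- seq_len(nlevels(g$pop))
  lc <- lapply(seq_len(n_loci(g)), function(j) locus_codes(g, j))
  m <- matrix(NA_real_, length(pops), length(pops),
              dimnames = list(levels(g$pop), levels(g$pop)))
  for (i in seq_along(pops)[-length(pops)]) {
    for (k in (i + 1):length(pops)) {
      sel <- pop_int %in% c(i, k)
      lc_sub <- lapply(lc, function(l) list(a1 = l$a1[sel], a2 = l$a2[sel]))
      v <- pair_stat(lc_sub, pop_int[sel], stat)
      m[i, k] <- m[k, i] <- v
    }
  }
  m
}

#' Pairwise permutation tests of differentiation
#'
#' For each population pair, individuals are permuted between the two
#' populations and the pairwise statistic recomputed; the p-value is
#' `(1 + #(perm >= obs)) / (n_perm + 1)`.  Significance flags apply a
#' strict Bonferroni threshold `alpha / n_pairs`.
#'
#' @param g a [genotype_matrix()].
#' @param n_perm permutations per pair (>= 100).
#' @param alpha family-wise significance level.
#' @param stat `"fst"` or `"rst"`.
#' @return List of class `pairwise_test`: `stat` matrix, `p` matrix,
#'   `significant` logical matrix, `bonferroni_threshold`, `n_pairs`.
#' @export
pairwise_tests <- function(g, n_perm = 1000, alpha = 0.05,
                           stat = c("fst", "rst")) {
  stat <- match.arg(stat)
  if (n_perm < 100) stop("n_perm must be >= 100")
  npop <- nlevels(g$pop)
  n_pairs <- npop * (npop - 1) / 2
  thr <- alpha / n_pairs
  lc_all <- lapply(seq_len(n_loci(g)), function(j) locus_codes(g, j))
  pop_int <- as.integer(g$pop)
  obs <- matrix(NA_real_, npop, npop, dimnames = list(levels(g$pop), levels(g$pop)))
  pmat <- obs
  for (i in seq_len(npop - 1)) {
    for (k in (i + 1):npop) {
      sel <- which(pop_int %in% c(i, k))
      lc <- lapply(lc_all, function(l) list(a1 = l$a1[sel], a2 = l$a2[sel]))
      lab <- pop_int[sel]
      o <- pair_stat(lc, lab, stat)
      cnt <- 0L
      for (b in seq_len(n_perm)) {
        if (pair_stat(lc, sample(lab), stat) >= o) cnt <- cnt + 1L
      }
      obs[i, k] <- obs[k, i] <- o
      pmat[i, k] <- pmat[k, i] <- (1 + cnt) / (n_perm + 1)
    }
  }
  structure(list(stat = obs, p = pmat, significant = pmat < thr,
                 bonferroni_threshold = thr, n_pairs = n_pairs,
                 n_perm = n_perm),
            class = "pairwise_test")
}

#' @export
print.pairwise_test <- function(x, ...) {
  cat("Pairwise differentiation permutation tests: ", x$n_pairs,
      " pairs, ", x$n_perm, " permutations\n", sep = "")
  cat(sprintf("  Bonferroni threshold %.3g; %d pair(s) significant\n",
              x$bonferroni_threshold,
              sum(x$significant[lower.tri(x$significant)], na.rm = TRUE)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Isolation by distance
# ---------------------------------------------------------------------------

#' OLS slope of linearized differentiation on log geographic distance
#'
#' @param diff pairwise differentiation matrix (d in \[0, 1)).
#' @param dist_km pairwise geographic distance matrix, same order.
#' @param log_base base of the distance logarithm (default natural).
#' @return List with `slope`, `intercept`.
#' @export
ibd_slope <- function(diff, dist_km, log_base = exp(1)) {
  lt <- lower.tri(diff)
  d <- diff[lt]
  gd <- dist_km[lt]
  if (any(gd <= 0)) {
    bad <- which(lt & dist_km <= 0, arr.ind = TRUE)[1, ]
    stop("coincident sites (zero distance): ",
         rownames(diff)[bad[1]], " / ", colnames(diff)[bad[2]])
  }
  y <- d / (1 - d)
  fit <- lm(y ~ log(gd, base = log_base))
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]))
}

#' Isolation-by-distance permutation test
#'
#' Regresses `d / (1 - d)` (d = pairwise F_ST or R_ST) on the logarithm of
#' pairwise geographic distance, and compares the observed slope to its
#' null distribution obtained by permuting individuals among populations
#' and recomputing the whole pairwise matrix and slope each time.
#'
#' @param g a [genotype_matrix()] whose population labels match registry
#'   site ids.
#' @param registry a [site_registry()] giving site coordinates.
#' @param stat `"fst"` or `"rst"`.
#' @param n_perm number of permutations (default 5000).
#' @param log_base base of the distance logarithm.
#' @return Object of class `ibd_result`: `slope`, `p_value` (two-sided),
#'   `null_ci` (2.5/97.5% quantiles of permuted slopes), `n_perm`.
#' @export
ibd_test <- function(g, registry, stat = c("fst", "rst"), n_perm = 5000,
                     log_base = exp(1)) {
  stat <- match.arg(stat)
  pops <- levels(g$pop)
  miss <- setdiff(pops, registry$site_id)
  if (length(miss)) stop("population(s) not in registry: ",
                         paste(miss, collapse = ", "))
  dmat <- site_distances(registry[match(pops, registry$site_id), ])
  diff_obs <- pairwise_differentiation(g, stat)
  obs <- ibd_slope(diff_obs, dmat, log_base)$slope
  pop_int <- as.integer(g$pop)
  null_slopes <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    diff_b <- pairwise_differentiation(g, stat, pop_int = sample(pop_int))
    null_slopes[b] <- ibd_slope(diff_b, dmat, log_base)$slope
  }
  ctr <- mean(null_slopes)
  p <- (1 + sum(abs(null_slopes - ctr) >= abs(obs - ctr))) / (n_perm + 1)
  structure(list(slope = obs, p_value = p,
                 null_ci = quantile(null_slopes, c(0.025, 0.975), names = FALSE),
                 null_mean = ctr, n_perm = n_perm, stat = stat),
            class = "ibd_result")
}

#' @export
print.ibd_result <- function(x, ...) {
  cat(sprintf(
    "Isolation by distance (%s): slope b = %.4g, two-sided p = %.4g\n",
    toupper(x$stat), x$slope, x$p_value))
  cat(sprintf("  null 95%% interval (%d permutations): %.4g to %.4g\n",
              x$n_perm, x$null_ci[1], x$null_ci[2]))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Allele-size randomization (R_ST vs F_ST)
# ---------------------------------------------------------------------------

#' Allele-size randomization test of stepwise-mutation signal
#'
#' Tests H0: R_ST = F_ST by permuting the size labels among the allelic
#' states of each locus and recomputing R_ST each time (F_ST is invariant
#' to the permutation).  `p = (1 + #(R_perm >= R_obs)) / (n_perm + 1)`:
#' small p means allele sizes carry differentiation signal beyond identity
#' in state, i.e. stepwise-like mutation contributes to differentiation.
#'
#' @param g a [genotype_matrix()].
#' @param n_perm number of size permutations.
#' @return Object of class `size_rand_test`: `rst_obs`, `fst_obs`,
#'   `p_value`, `null_mean`.
#' @export
allele_size_randomization <- function(g, n_perm = 1000) {
  pop_int <- as.integer(g$pop)
  lc <- lapply(seq_len(n_loci(g)), function(j) locus_codes(g, j))
  rst_from <- function(lc_list) {
    s <- Reduce(`+`, Filter(Negate(is.null),
      lapply(lc_list, function(l) {
        v <- size_anova_components(l$a1, l$a2, pop_int)
        if (is.null(v)) NULL else v[c("sa", "sb", "sc")]
      })))
    unname(s["sa"] / sum(s))
  }
  obs <- rst_from(lc)
  perm <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    lc_b <- lapply(lc, function(l) {
      states <- sort(unique(c(l$a1, l$a2)))
      states <- states[states > 0]
      newsize <- setNames(sample(states), states)
      a1 <- l$a1; a2 <- l$a2
      a1[a1 > 0] <- newsize[as.character(a1[a1 > 0])]
      a2[a2 > 0] <- newsize[as.character(a2[a2 > 0])]
      list(a1 = a1, a2 = a2)
    })
    perm[b] <- rst_from(lc_b)
  }
  structure(list(rst_obs = obs,
                 fst_obs = f_statistics(g, pairwise = FALSE)$fst,
                 p_value = (1 + sum(perm >= obs)) / (n_perm + 1),
                 null_mean = mean(perm), n_perm = n_perm),
            class = "size_rand_test")
}

#' @export
print.size_rand_test <- function(x, ...) {
  cat(sprintf(
    "Allele-size randomization: R_ST = %.4f (null mean %.4f), p = %.4g\n",
    x$rst_obs, x$null_mean, x$p_value))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Probability of identity, null alleles, Hardy-Weinberg
# ---------------------------------------------------------------------------

#' Probability of identity across loci
#'
#' Probability that two unrelated individuals share a multilocus genotype:
#' `PID = prod_loci [ sum_i p_i^4 + sum_{i<j} (2 p_i p_j)^2 ]`.
#'
#' @param freqs a list of per-locus allele-frequency vectors, or a
#'   [genotype_matrix()] (pooled frequencies over all populations).
#' @return The probability of identity (scalar).
#' @export
probability_of_identity <- function(freqs) {
  if (inherits(freqs, "genotype_matrix")) {
    g <- freqs
    freqs <- lapply(seq_len(n_loci(g)), function(j) {
      lc <- locus_codes(g, j)
      copies <- c(lc$a1, lc$a2)
      copies <- copies[copies > 0]
      tab <- table(copies)
      setNames(as.numeric(tab) / sum(tab), names(tab))
    })
  }
  vals <- vapply(freqs, function(p) {
    if (abs(sum(p) - 1) > 1e-6)
      stop("allele frequencies must sum to 1 (got ", sum(p), ")")
    op <- outer(p, p)
    sum(p^4) + sum((2 * op[upper.tri(op)])^2)
  }, 0)
  prod(vals)
}

#' Null-allele frequency by expectation-maximization
#'
#' Per locus x population EM under Hardy-Weinberg with one null allele:
#' observed heterozygotes are true heterozygotes, observed homozygotes may
#' be visible/null heterozygotes, and blank genotypes are null
#' homozygotes.  Convergence when the largest frequency change is below
#' `tol`; error after `max_iter` iterations.
#'
#' @param g a [genotype_matrix()].
#' @param tol convergence tolerance (default 1e-8).
#' @param max_iter maximum EM iterations.
#' @return data.frame (locus, pop, null_freq, n, n_blank, boundary) of
#'   class `null_allele_em`.
#' @export
null_allele_em <- function(g, tol = 1e-8, max_iter = 10000L) {
  rows <- list()
  for (j in seq_len(n_loci(g))) {
    lc <- locus_codes(g, j)
    for (p in levels(g$pop)) {
      sel <- g$pop == p
      a1 <- lc$a1[sel]; a2 <- lc$a2[sel]
      n <- sum(sel)
      blank <- a1 == 0L
      n_blank <- sum(blank)
      if (n_blank == n) {
        rows[[length(rows) + 1L]] <- data.frame(
          locus = g$loci[j], pop = p, null_freq = 1, n = n,
          n_blank = n_blank, boundary = TRUE, stringsAsFactors = FALSE)
        next
      }
      vis1 <- a1[!blank]; vis2 <- a2[!blank]
      alleles <- sort(unique(c(vis1, vis2)))
      K <- length(alleles)
      het <- vis1 != vis2
      hom_allele <- match(vis1[!het], alleles)
      het1 <- match(vis1[het], alleles); het2 <- match(vis2[het], alleles)
      # initial frequencies: observed counts, small null freq
      cnt0 <- tabulate(c(het1, het2, hom_allele, hom_allele), nbins = K)
      pv <- cnt0 / sum(cnt0) * 0.95
      pn <- 0.05
      it <- 0L
      repeat {
        it <- it + 1L
        if (it > max_iter) stop("null-allele EM did not converge for locus ",
                                g$loci[j], ", pop ", p)
        cnt <- tabulate(c(het1, het2), nbins = K)
        # visible homozygotes: split between true hom and null het
        if (length(hom_allele)) {
          pa <- pv[hom_allele]
          w <- pa^2 / (pa^2 + 2 * pa * pn)   # P(true hom | observed hom)
          cnt <- cnt + tabulate(hom_allele, nbins = K) * 0  # keep length
          add <- vapply(seq_len(K), function(k)
            sum((2 * w + (1 - w))[hom_allele == k]), 0)
          cnt <- cnt + add
          null_cnt <- sum(1 - w) + 2 * n_blank
        } else null_cnt <- 2 * n_blank
        tot <- sum(cnt) + null_cnt
        pv_new <- cnt / tot
        pn_new <- null_cnt / tot
        if (max(abs(c(pv_new - pv, pn_new - pn))) < tol) {
          pv <- pv_new; pn <- pn_new
          break
        }
        pv <- pv_new; pn <- pn_new
      }
      rows[[length(rows) + 1L]] <- data.frame(
        locus = g$loci[j], pop = p, null_freq = pn, n = n,
        n_blank = n_blank, boundary = pn > 0.999, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("null_allele_em", "data.frame")
  out
}

#' Monte-Carlo exact test of Hardy-Weinberg equilibrium
#'
#' Per locus x population: the test statistic is the conditional
#' probability of the observed genotype table given the allele counts;
#' gene copies are shuffled and re-paired `n_shuffle` times and
#' `p = P(prob(table_perm) <= prob(table_obs))`.
#'
#' @param g a [genotype_matrix()].
#' @param n_shuffle Monte-Carlo table shuffles (default 10000).
#' @return data.frame (locus, pop, p_value, n) of class `hw_test`.
#' @export
hw_exact_test <- function(g, n_shuffle = 10000L) {
  log_table_prob <- function(a1, a2) {
    n <- length(a1)
    key <- paste(pmin(a1, a2), pmax(a1, a2))
    gt <- table(key)
    copies <- c(a1, a2)
    ac <- table(copies)
    h <- sum(a1 != a2)
    lfactorial(n) - sum(lfactorial(as.numeric(gt))) + h * log(2) +
      sum(lfactorial(as.numeric(ac))) - lfactorial(2 * n)
  }
  rows <- list()
  for (j in seq_len(n_loci(g))) {
    lc <- locus_codes(g, j)
    for (p in levels(g$pop)) {
      sel <- g$pop == p & lc$a1 > 0L
      a1 <- lc$a1[sel]; a2 <- lc$a2[sel]
      n <- sum(sel)
      if (n < 2 || length(unique(c(a1, a2))) < 2) {
        rows[[length(rows) + 1L]] <- data.frame(
          locus = g$loci[j], pop = p, p_value = NA_real_, n = n,
          stringsAsFactors = FALSE)
        next
      }
      obs <- log_table_prob(a1, a2)
      copies <- c(a1, a2)
      cnt <- 0L
      for (b in seq_len(n_shuffle)) {
        perm <- sample(copies)
        if (log_table_prob(perm[seq_len(n)], perm[n + seq_len(n)]) <=
            obs + 1e-12) cnt <- cnt + 1L
      }
      rows[[length(rows) + 1L]] <- data.frame(
        locus = g$loci[j], pop = p, p_value = (1 + cnt) / (n_shuffle + 1),
        n = n, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("hw_test", "data.frame")
  out
}
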
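# Shared fixtures: small registries, genotype matrices, demographic
# scenarios, and independent brute-force oracles.

make_registry <- function(n = 6, seed = 1) {
  set.seed(seed)
  site_registry(
    site_id = c("Vx", sprintf("S%02d", seq_len(n - 1))),
    lat = c(44.8, runif(n - 1, 43.3, 45.3)),
    lon = c(5.0, runif(n - 1, 4.2, 8.8)),
    elevation = 500,
    detection_year = NA_integer_,
    survey_start = 1994, survey_end = 2010)
}

# genotypes from explicit per-individual allele pairs
make_genotypes <- function(pairs, pop, loci = NULL) {
  genotype_matrix(do.call(rbind, pairs), pop, loci)
}

# random multi-allele genotypes (no structure)
random_genotypes <- function(n_per_pop, n_pops, n_loci = 3, n_alleles = 5,
                             seed = 1, base = 10L) {
  set.seed(seed)
  n <- n_per_pop * n_pops
  amat <- matrix(sample(base + seq_len(n_alleles), 2 * n_loci * n,
                        replace = TRUE), n, 2 * n_loci)
  genotype_matrix(amat, rep(paste0("P", seq_len(n_pops)), each = n_per_pop))
}

# the four-scenario fixture used across the ABC tests: 14 demes,
# plausible founding orders, class mix matching the detection eras
make_four_scenarios <- function() {
  mk <- function(id) {
    d <- data.frame(
      site_id = paste0("P", 1:14),
      founding_gen = c(NA, 11, 11, 10, 10, 10, 9, 9, 8, 7, 6, 4, 3, 1),
      source = if (id == 1) c(NA, rep("P1", 13)) else
        c(NA, "P1", "P1", "P2", "P3", "P3", "P4", "P1", "P7", "P2",
          "P10", "P9", "P12", "P11"),
      ne_class = c(rep("early", 10), "mid", "mid", "late", "late"),
      stringsAsFactors = FALSE)
    if (id == 3) d$founding_gen <- c(NA, 11, 11, 10, 10, 10, 8, 8, 6, 5, 4, 3, 2, 1)
    if (id == 4) {
      d$founding_gen <- c(NA, 11, 10, 10, 9, 9, 8, 8, 7, 6, 5, 4, 3, 1)
      d$source <- c(NA, "P1", "P2", "P2", "P3", "P3", "P4", "P5", "P7",
                    "P2", "P10", "P9", "P12", "P11")
    }
    scenario_spec(id, d, 2010, root = "P1")
  }
  list(scenario1 = mk(1), scenario2 = mk(2), scenario3 = mk(3),
       scenario4 = mk(4))
}

# ---- independent oracles ---------------------------------------------------

# Weir-Cockerham (1984) variance components computed from first
# principles, one allele at a time, straight from the published formulas.
oracle_wc_components <- function(g) {
  tot <- c(a = 0, b = 0, c = 0)
  for (j in seq_len(n_loci(g))) {
    a1 <- g$alleles[, 2 * j - 1]
    a2 <- g$alleles[, 2 * j]
    keep <- a1 > 0
    pops <- levels(g$pop)[table(g$pop[keep]) > 0]
    if (length(pops) < 2) next
    alleles <- sort(unique(c(a1[keep], a2[keep])))
    if (length(alleles) < 2) next
    n_i <- sapply(pops, function(p) sum(g$pop == p & keep))
    r <- length(pops)
    nbar <- mean(n_i)
    nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
    for (al in alleles) {
      p_i <- sapply(pops, function(p) {
        sel <- g$pop == p & keep
        sum((a1[sel] == al) + (a2[sel] == al)) / (2 * sum(sel))
      })
      h_i <- sapply(pops, function(p) {
        sel <- g$pop == p & keep
        mean(((a1[sel] == al) + (a2[sel] == al)) == 1)
      })
      pbar <- sum(n_i * p_i) / sum(n_i)
      s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(n_i * h_i) / sum(n_i)
      tot["a"] <- tot["a"] + nbar / nc *
        (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
      tot["b"] <- tot["b"] + nbar / (nbar - 1) *
        (pbar * (1 - pbar) - (r - 1) / r * s2 -
           (2 * nbar - 1) / (4 * nbar) * hbar)
      tot["c"] <- tot["c"] + hbar / 2
    }
  }
  tot
}

# brute-force discrete-hazard probability of an interval-censored
# observation: product over years of survival, times the interval mass
oracle_site_logprob <- function(beta0, beta1, x_before, x_interval, event) {
  lam_b <- exp(beta0 + beta1 * x_before)
  p <- prod(exp(-lam_b))
  if (event) {
    lam_i <- exp(beta0 + beta1 * x_interval)
    p <- p * (1 - prod(exp(-lam_i)))
  }
  log(p)
}

# straightforward R reimplementation of the abc summary statistics
oracle_abc_stats <- function(g) {
  pops <- levels(g$pop)
  P <- length(pops)
  L <- n_loci(g)
  he <- gwm <- setNames(numeric(P), pops)
  for (p in pops) {
    hev <- mv <- c()
    for (j in seq_len(L)) {
      a <- g$alleles[g$pop == p, c(2 * j - 1, 2 * j), drop = FALSE]
      cp <- as.vector(a)
      cp <- cp[cp > 0]
      if (length(cp) < 2) next
      fr <- table(cp) / length(cp)
      hev <- c(hev, length(cp) / (length(cp) - 1) * (1 - sum(fr^2)))
      sz <- unique(cp)
      mv <- c(mv, length(sz) / (max(sz) - min(sz) + 1))
    }
    he[p] <- mean(hev)
    gwm[p] <- mean(mv)
  }
  # Rannala-Mountain genotype log-likelihood of individual i in pop q
  geno_ll <- function(i, q, loo) {
    ll <- 0
    for (j in seq_len(L)) {
      a <- g$alleles[i, 2 * j - 1]; b <- g$alleles[i, 2 * j]
      if (a == 0) next
      all_states <- unique(as.vector(g$alleles[, c(2 * j - 1, 2 * j)]))
      all_states <- all_states[all_states > 0]
      K <- length(all_states)
      sel <- g$pop == q & g$alleles[, 2 * j - 1] > 0
      cp <- as.vector(g$alleles[sel, c(2 * j - 1, 2 * j)])
      if (loo) {
        drop1 <- c(a, b)
        for (d in drop1) cp <- cp[-match(d, cp)]
      }
      n2 <- length(cp)
      pa <- (sum(cp == a) + 1 / K) / (n2 + 1)
      pb <- (sum(cp == b) + 1 / K) / (n2 + 1)
      ll <- ll + if (a == b) 2 * log(pa) else log(2 * pa * pb)
    }
    ll
  }
  ci <- c()
  nm <- c()
  for (p in pops) for (q in pops) {
    if (p == q) next
    inds <- which(g$pop == p)
    v <- sapply(inds, function(i) geno_ll(i, p, TRUE) - geno_ll(i, q, FALSE))
    ci <- c(ci, mean(v))
    nm <- c(nm, paste0("ci.", p, ".", q))
  }
  c(setNames(he, paste0("he.", pops)), setNames(gwm, paste0("gwm.", pops)),
    setNames(ci, nm))
}
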
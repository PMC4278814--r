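# Coalescent simulation under dated deme-founding scenarios, summary
# statistics, and ABC model choice with polychotomous logistic posterior
# estimation.

#' Draw demographic and mutational parameters from the scenario priors
#'
#' Per-deme diploid effective sizes are uniform on the detection-era
#' class bounds (early U(10, 10000), mid U(10, 5000), late U(10, 1000));
#' the root founding time t1 is uniform on {12..15} generations; the
#' admixture rate r is uniform on (0.1, 0.9); the two unsampled ancestral
#' pools have Ne ~ U(100, 10000) and merge at 10 * t1; the mean mutation
#' rate is U(1e-5, 1e-4) with per-locus rates Gamma(shape 2, mean =
#' drawn mean) truncated to \[1e-6, 1e-3\]; the generalized-stepwise
#' geometric parameter P is U(0, 0.3).
#'
#' @param spec a [scenario_spec()].
#' @param n_loci number of microsatellite loci.
#' @return List of class `parameter_draw`.
#' @export
parameter_draw <- function(spec, n_loci = 9) {
  bounds <- ne_prior_bounds[spec$demes$ne_class]
  ne <- vapply(bounds, function(b) runif(1, b[1], b[2]), 0)
  names(ne) <- spec$demes$site_id
  t1 <- sample(spec$t1_prior[1]:spec$t1_prior[2], 1)
  r <- runif(1, spec$admix_prior[1], spec$admix_prior[2])
  ne_anc <- runif(2, spec$ancestral_ne_prior[1], spec$ancestral_ne_prior[2])
  mu_mean <- runif(1, 1e-5, 1e-4)
  mu <- pmin(1e-3, pmax(1e-6, rgamma(n_loci, shape = 2, scale = mu_mean / 2)))
  gsm_p <- runif(1, 0, 0.3)
  structure(list(ne = ne, t1 = t1, admix_rate = r, ne_ancestral = ne_anc,
                 mu_mean = mu_mean, mu = mu, gsm_p = gsm_p),
            class = "parameter_draw")
}

as_param_row <- function(draw) {
  c(t1 = draw$t1, admix_rate = draw$admix_rate, mu_mean = draw$mu_mean,
    gsm_p = draw$gsm_p, ne_root_mean = mean(draw$ne),
    ne_anc1 = draw$ne_ancestral[1], ne_anc2 = draw$ne_ancestral[2])
}

#' Simulate microsatellite genotypes under a demographic scenario
#'
#' Backward-in-time discrete-generation coalescent: within each deme
#' lineages coalesce Wright-Fisher style (multiple mergers allowed when
#' lineage numbers approach 2Ne); at a deme's founding generation all its
#' remaining lineages move to its source; the root deme is an admixture
#' of two unsampled ancestral pools (each lineage independently to pool A
#' with probability r) which merge into one ancestral deme at 10 * t1.
#' Mutations are Poisson along branches at the per-locus rate; step sizes
#' are geometric(P) in repeat units with equiprobable sign, from a root
#' allele of 20 repeats, floored at 2.
#'
#' @param spec a [scenario_spec()].
#' @param draw a [parameter_draw()]; drawn fresh if `NULL`.
#' @param sample_sizes named integer vector (deme -> diploids sampled).
#' @param n_loci number of loci.
#' @param root_allele,min_allele repeat-unit root state and floor.
#' @return A [genotype_matrix()] with populations in deme order.
#' @export
simulate_genotypes <- function(spec, draw = NULL, sample_sizes,
                               n_loci = 9, root_allele = 20L,
                               min_allele = 2L) {
  if (is.null(draw)) draw <- parameter_draw(spec, n_loci)
  demes <- spec$demes
  D <- nrow(demes)
  miss <- setdiff(names(sample_sizes), demes$site_id)
  if (length(miss)) stop("sample sizes for unknown deme(s): ",
                         paste(miss, collapse = ", "))
  ss <- sample_sizes[demes$site_id]
  ss[is.na(ss)] <- 0L
  if (any(ss < 1)) stop("every deme needs a sample size >= 1")
  # deme indices: sampled demes 0..D-1, ancestral pools D, D+1, root D+2
  ne <- c(draw$ne[demes$site_id], draw$ne_ancestral,
          mean(draw$ne_ancestral))
  t1 <- draw$t1
  ev <- cbind(time = demes$founding_gen,
              from = seq_len(D) - 1L,
              to1 = match(demes$source, demes$site_id) - 1L,
              to2 = -1L, p1 = 1)
  ev <- ev[!is.na(demes$source), , drop = FALSE]
  root_idx <- which(is.na(demes$source)) - 1L
  ev <- rbind(ev,
              c(t1, root_idx, D, D + 1L, draw$admix_rate),
              c(10 * t1, D, D + 2L, -1L, 1),
              c(10 * t1, D + 1L, D + 2L, -1L, 1))
  ev <- ev[order(ev[, "time"]), , drop = FALSE]
  if (any(ev[, "time"] <= 0)) stop("founding times must be strictly positive")
  deme_of_leaf <- rep(seq_len(D) - 1L, times = 2L * ss)
  leaves <- cpp_simulate_alleles(as.integer(deme_of_leaf), as.numeric(ne),
                                 ev, D + 2L, as.integer(n_loci),
                                 as.numeric(draw$mu), draw$gsm_p,
                                 as.integer(root_allele),
                                 as.integer(min_allele))
  # leaves: gene copies x loci -> individuals x 2*loci
  n_ind <- sum(ss)
  amat <- matrix(0L, n_ind, 2L * n_loci)
  a1 <- leaves[seq(1, 2 * n_ind, by = 2), , drop = FALSE]
  a2 <- leaves[seq(2, 2 * n_ind, by = 2), , drop = FALSE]
  amat[, seq(1, 2 * n_loci, by = 2)] <- a1
  amat[, seq(2, 2 * n_loci, by = 2)] <- a2
  genotype_matrix(amat, rep(demes$site_id, times = ss))
}

#' Simulate genotypes from a single constant-size deme at equilibrium
#'
#' A panmictic deme of diploid size `ne` with no demographic events:
#' the calibration setting in which strict-stepwise (`gsm_p = 0`)
#' expected gene diversity has the closed form
#' `He = 1 - 1 / sqrt(1 + 8 * ne * mu)`.
#'
#' @param ne diploid effective size.
#' @param mu per-locus mutation rate.
#' @param n_diploids sampled individuals.
#' @param n_loci independent loci.
#' @param gsm_p geometric step-size parameter (0 = strict stepwise).
#' @param root_allele,min_allele repeat-unit root state and floor.
#' @return A [genotype_matrix()] with a single population.
#' @export
simulate_single_deme <- function(ne, mu, n_diploids, n_loci = 100,
                                 gsm_p = 0, root_allele = 20L,
                                 min_allele = 2L) {
  leaves <- cpp_simulate_alleles(rep(0L, 2L * n_diploids), ne,
                                 matrix(numeric(0), 0, 5), 0L,
                                 as.integer(n_loci),
                                 rep(as.numeric(mu), n_loci), gsm_p,
                                 as.integer(root_allele),
                                 as.integer(min_allele))
  amat <- matrix(0L, n_diploids, 2L * n_loci)
  amat[, seq(1, 2 * n_loci, by = 2)] <- leaves[seq(1, 2 * n_diploids, by = 2), ]
  amat[, seq(2, 2 * n_loci, by = 2)] <- leaves[seq(2, 2 * n_diploids, by = 2), ]
  genotype_matrix(amat, rep("pop1", n_diploids))
}

#' Coalescence times of a pair of lineages in one deme
#'
#' Utility exposing the simulator's within-deme pairwise coalescence law
#' (geometric with mean `2 * ne` generations) for calibration checks.
#'
#' @param ne diploid effective size.
#' @param n_draws number of independent draws.
#' @return Numeric vector of coalescence times (generations).
#' @export
pair_coalescence_times <- function(ne, n_draws) {
  cpp_pair_coal_times(ne, as.integer(n_draws))
}

#' ABC summary statistics of a genotype matrix
#'
#' `abc` variant: per-population mean (over loci) unbiased gene
#' diversity, per-population mean Garza-Williamson M, and the
#' classification index for every ordered population pair (mean over the
#' first pop's individuals of the difference in genotype log-likelihood
#' under leave-one-out own-population vs other-population
#' Rannala-Mountain frequency estimates).  `model_check` variant:
#' per-population mean allele number and mean allele-size variance, and
#' per unordered pair the shared-allele distance and (delta mu)^2.
#'
#' @param g a [genotype_matrix()].
#' @param variant `"abc"` or `"model_check"`.
#' @return Named numeric vector with fixed length and ordering.
#' @export
summary_stats <- function(g, variant = c("abc", "model_check")) {
  variant <- match.arg(variant)
  P <- nlevels(g$pop)
  # flag populations with an all-missing locus (stat imputed as 0)
  for (j in seq_len(n_loci(g))) {
    lc <- locus_codes(g, j)
    n_ok <- tapply(lc$a1 > 0L, g$pop, sum)
    if (any(n_ok == 0))
      warning("population(s) with all-missing locus ", g$loci[j],
              "; affected statistics imputed as 0")
  }
  v <- cpp_summary_stats(g$alleles, as.integer(g$pop) - 1L, P,
                         if (variant == "abc") 0L else 1L)
  pops <- levels(g$pop)
  if (variant == "abc") {
    ord <- expand.grid(to = pops, from = pops, stringsAsFactors = FALSE)
    ord <- ord[ord$from != ord$to, c("from", "to")]
    names(v) <- c(paste0("he.", pops), paste0("gwm.", pops),
                  paste0("ci.", ord$from, ".", ord$to))
  } else {
    pr <- utils::combn(pops, 2)
    names(v) <- c(paste0("na.", pops), paste0("szvar.", pops),
                  paste0("das.", pr[1, ], ".", pr[2, ]),
                  paste0("dmu2.", pr[1, ], ".", pr[2, ]))
  }
  v
}

#' Build an ABC reference table
#'
#' For each scenario and each row: draw parameters from the priors,
#' simulate a genotype dataset, summarize it.  Reproducible under
#' `set.seed()`.
#'
#' @param specs named list of [scenario_spec()].
#' @param n_per_scenario simulated datasets per scenario (>= 100).
#' @param sample_sizes named integer vector (deme -> diploids).
#' @param n_loci number of loci.
#' @param variant summary-statistic variant.
#' @param progress print progress every 1000 rows.
#' @return Object of class `reference_table`: `stats` (matrix rows x
#'   stats), `scenario` (integer vector), `params` (matrix of
#'   scalar parameter summaries), `n_failed`.
#' @export
build_reference <- function(specs, n_per_scenario, sample_sizes,
                            n_loci = 9, variant = "abc", progress = FALSE) {
  if (n_per_scenario < 100) stop("n_per_scenario must be >= 100")
  n_total <- n_per_scenario * length(specs)
  stats <- NULL
  scen <- integer(0)
  params <- NULL
  n_failed <- 0L
  row <- 0L
  for (si in seq_along(specs)) {
    spec <- specs[[si]]
    for (b in seq_len(n_per_scenario)) {
      draw <- parameter_draw(spec, n_loci)
      v <- tryCatch({
        gt <- simulate_genotypes(spec, draw, sample_sizes, n_loci)
        suppressWarnings(summary_stats(gt, variant))
      }, error = function(e) NULL)
      if (is.null(v)) { n_failed <- n_failed + 1L; next }
      if (is.null(stats)) {
        stats <- matrix(NA_real_, n_total, length(v),
                        dimnames = list(NULL, names(v)))
        params <- matrix(NA_real_, n_total, length(as_param_row(draw)),
                         dimnames = list(NULL, names(as_param_row(draw))))
      }
      row <- row + 1L
      stats[row, ] <- v
      params[row, ] <- as_param_row(draw)
      scen <- c(scen, spec$scenario_id)
      if (progress && row %% 1000L == 0L)
        message("reference table: ", row, " rows")
    }
  }
  stats <- stats[seq_len(row), , drop = FALSE]
  params <- params[seq_len(row), , drop = FALSE]
  structure(list(stats = stats, scenario = scen, params = params,
                 n_failed = n_failed, variant = variant),
            class = "reference_table")
}

#' @export
print.reference_table <- function(x, ...) {
  cat("ABC reference table: ", nrow(x$stats), " rows x ", ncol(x$stats),
      " summary statistics (", x$variant, " variant)\n", sep = "")
  print(table(scenario = x$scenario))
  invisible(x)
}

#' ABC scenario choice by polychotomous logistic regression
#'
#' Standardizes the summary statistics by their reference-table standard
#' deviations, ranks reference rows by Euclidean distance to the observed
#' vector, retains the `n_closest` rows, fits a multinomial logistic
#' regression of scenario identity on the standardized deviations
#' (simulated minus observed) among retained rows, and reports the fitted
#' scenario probabilities at deviation zero.  The regression slopes carry
#' a ridge penalty (`ridge_lambda`, intercepts unpenalized) because at
#' desk scale the retained sample is small relative to the number of
#' summary statistics; the penalty scale follows the one-standard-error
#' rule of a deviance cross-validation on retained sets.  Confidence
#' intervals come from the penalized information matrix via the delta
#' method.  Raw rejection fractions among retained rows are reported
#' alongside.
#'
#' @param observed named numeric summary-statistic vector.
#' @param ref a [build_reference()] table (balanced across scenarios).
#' @param n_closest retained rows (default 1% of the table).
#' @param ci compute delta-method confidence intervals (slower).
#' @param ridge_lambda ridge penalty on the regression slopes.
#' @return Object of class `abc_model_choice`: `posterior` (named
#'   vector), `ci` (2 x k matrix or NULL), `rejection` (raw retained
#'   fractions), `n_closest`.
#' @export
model_choice <- function(observed, ref, n_closest = ceiling(0.01 * nrow(ref$stats)),
                         ci = TRUE, ridge_lambda = 0.3) {
  if (n_closest > nrow(ref$stats)) stop("n_closest exceeds the table size")
  sds <- apply(ref$stats, 2, sd)
  keep <- which(sds > 0)
  z <- sweep(ref$stats[, keep, drop = FALSE], 2, observed[keep]) /
    rep(sds[keep], each = nrow(ref$stats))
  d2 <- rowSums(z^2)
  sel <- order(d2)[seq_len(n_closest)]
  scen_levels <- sort(unique(ref$scenario))
  y <- factor(ref$scenario[sel], levels = scen_levels)
  rejection <- as.numeric(table(y) / length(y))
  names(rejection) <- paste0("scenario", scen_levels)
  absent <- table(y) == 0
  if (sum(!absent) == 1L) {
    # retention is pure: one scenario holds every retained row
    warning("scenario(s) absent among retained rows: ",
            paste(scen_levels[absent], collapse = ", "),
            "; posterior floored at 0")
    p <- as.numeric(!absent)
    names(p) <- paste0("scenario", scen_levels)
    return(structure(list(posterior = p, ci = NULL, rejection = rejection,
                          n_closest = n_closest, n_ref = nrow(ref$stats)),
                     class = "abc_model_choice"))
  }
  x <- z[sel, , drop = FALSE]
  # drop directions with no variation among retained rows
  xsd <- apply(x, 2, sd)
  x <- x[, xsd > 1e-12, drop = FALSE]
  # classes need >= 2 retained rows to enter the regression
  counts <- tabulate(y, nbins = length(scen_levels))
  present <- scen_levels[counts >= 2]
  absent <- absent | counts < 2
  use <- as.integer(y) %in% which(counts >= 2)
  x <- x[use, , drop = FALSE]
  yp <- droplevels(y[use])
  if (nlevels(yp) == 1L) {
    warning("scenario(s) absent among retained rows: ",
            paste(scen_levels[absent], collapse = ", "),
            "; posterior floored at 0")
    p <- setNames(as.numeric(!absent), paste0("scenario", scen_levels))
    return(structure(list(posterior = p, ci = NULL, rejection = rejection,
                          n_closest = n_closest, n_ref = nrow(ref$stats)),
                     class = "abc_model_choice"))
  }
  if (length(yp) < 8L * nlevels(yp)) {
    warning("retained sample too small for the logistic regression; ",
            "reporting rejection fractions as the posterior")
    p <- rejection
    names(p) <- paste0("scenario", scen_levels)
    return(structure(list(posterior = p, ci = NULL, rejection = rejection,
                          n_closest = n_closest, n_ref = nrow(ref$stats)),
                     class = "abc_model_choice"))
  }
  fit <- glmnet::glmnet(x, yp, family = "multinomial", alpha = 0,
                        lambda = ridge_lambda, standardize = FALSE)
  cf <- glmnet::coef.glmnet(fit)
  eta <- vapply(cf, function(b) b[1], 0)   # intercepts = predictor at 0
  p_fit <- exp(eta - max(eta))
  p_fit <- p_fit / sum(p_fit)
  p <- setNames(numeric(length(scen_levels)),
                paste0("scenario", scen_levels))
  p[match(present, scen_levels)] <- p_fit
  ci_mat <- NULL
  if (ci) {
    # delta method: covariance of the baseline-parameterized intercepts
    # from the penalized observed information at the fitted probabilities
    X <- cbind(1, x)
    pp <- ncol(X)
    pr <- drop(stats::predict(fit, newx = x, type = "response"))
    K <- length(p_fit)
    if (K >= 2) {
      H <- matrix(0, (K - 1) * pp, (K - 1) * pp)
      for (a in 2:K) for (b in 2:K) {
        w <- pr[, a] * ((a == b) - pr[, b])
        H[((a - 2) * pp + 1):((a - 1) * pp),
          ((b - 2) * pp + 1):((b - 1) * pp)] <- crossprod(X * w, X)
      }
      # ridge contribution on the slopes (intercepts unpenalized)
      pen <- rep(c(0, rep(nrow(x) * ridge_lambda, pp - 1)), K - 1)
      diag(H) <- diag(H) + pen
      V <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(V)) {
        int_idx <- seq(1, by = pp, length.out = K - 1)
        Vi <- V[int_idx, int_idx, drop = FALSE]
        grad <- matrix(0, K, K - 1)   # d p_k / d eta_j, j = 2..K
        for (k in seq_len(K)) {
          for (j in 2:K) grad[k, j - 1] <- p_fit[k] * ((k == j) - p_fit[j])
        }
        se_fit <- sqrt(pmax(0, diag(grad %*% Vi %*% t(grad))))
        se <- setNames(numeric(length(p)), names(p))
        se[match(present, scen_levels)] <- se_fit
        ci_mat <- rbind(lo = pmax(0, p - 1.96 * se),
                        hi = pmin(1, p + 1.96 * se))
        colnames(ci_mat) <- names(p)
      }
    }
  }
  if (any(absent)) {
    warning("scenario(s) absent among retained rows: ",
            paste(scen_levels[absent], collapse = ", "),
            "; posterior floored at 0")
    p[absent] <- 0
    p <- p / sum(p)
  }
  structure(list(posterior = p, ci = ci_mat, rejection = rejection,
                 n_closest = n_closest, n_ref = nrow(ref$stats)),
            class = "abc_model_choice")
}

#' @export
print.abc_model_choice <- function(x, ...) {
  cat("ABC scenario choice (logistic estimate on ", x$n_closest,
      " closest of ", x$n_ref, " simulations)\n", sep = "")
  for (k in seq_along(x$posterior)) {
    cat(sprintf("  %s: %.4f", names(x$posterior)[k], x$posterior[k]))
    if (!is.null(x$ci))
      cat(sprintf("  [%.4f, %.4f]", x$ci["lo", k], x$ci["hi", k]))
    cat(sprintf("  (rejection %.3f)\n", x$rejection[k]))
  }
  invisible(x)
}

#' Scenario-choice confusion matrix and error rates
#'
#' Simulates `n_pseudo_per_scenario` fresh pseudo-observed datasets per
#' scenario (disjoint from the training table by construction), runs
#' [model_choice()] on each, and aggregates: the type I error of a
#' scenario is the proportion of its own pseudo datasets for which it did
#' not attain the highest posterior probability; the type II error is the
#' proportion of other scenarios' pseudo datasets for which it did.
#'
#' @param ref_train the training [build_reference()] table.
#' @param specs named list of [scenario_spec()] (same order/ids as the
#'   table).
#' @param n_pseudo_per_scenario pseudo-observed datasets per scenario.
#' @param sample_sizes,n_loci as in [simulate_genotypes()].
#' @param n_closest retained rows per choice.
#' @return Object of class `abc_confusion`: `confusion` (rows = true
#'   scenario, columns = selected, counts), `type1`, `type2` (named
#'   rates), `n_pseudo_per_scenario`.
#' @export
confusion_rates <- function(ref_train, specs, n_pseudo_per_scenario,
                            sample_sizes, n_loci = 9,
                            n_closest = ceiling(0.01 * nrow(ref_train$stats))) {
  ids <- vapply(specs, `[[`, 0L, "scenario_id")
  K <- length(ids)
  conf <- matrix(0L, K, K, dimnames = list(true = paste0("scenario", ids),
                                           selected = paste0("scenario", ids)))
  for (si in seq_len(K)) {
    for (b in seq_len(n_pseudo_per_scenario)) {
      gt <- simulate_genotypes(specs[[si]], NULL, sample_sizes, n_loci)
      obs <- suppressWarnings(summary_stats(gt, ref_train$variant))
      mc <- suppressWarnings(
        model_choice(obs, ref_train, n_closest = n_closest, ci = FALSE))
      sel <- which.max(mc$posterior)
      conf[si, sel] <- conf[si, sel] + 1L
    }
  }
  n <- n_pseudo_per_scenario
  type1 <- 1 - diag(conf) / n
  type2 <- vapply(seq_len(K), function(k)
    sum(conf[-k, k]) / (n * (K - 1)), 0)
  names(type1) <- names(type2) <- rownames(conf)
  structure(list(confusion = conf, type1 = type1, type2 = type2,
                 n_pseudo_per_scenario = n),
            class = "abc_confusion")
}

#' @export
print.abc_confusion <- function(x, ...) {
  cat("Scenario-choice confusion (", x$n_pseudo_per_scenario,
      " pseudo-observed datasets per scenario)\n", sep = "")
  print(x$confusion)
  cat("type I: ", paste(sprintf("%.3f", x$type1), collapse = ", "), "\n")
  cat("type II:", paste(sprintf("%.3f", x$type2), collapse = ", "), "\n")
  invisible(x)
}

#' Posterior-predictive goodness-of-fit check in PCA space
#'
#' Simulates model-checking summary statistics (a different set from the
#' one used for scenario choice) from parameter draws of the selected
#' scenario, computes principal components of the simulated statistics,
#' projects the observed dataset, and flags whether the observed point
#' falls inside the 95% kernel-density region of the simulated cloud.
#'
#' @param spec the selected [scenario_spec()].
#' @param observed_g the observed [genotype_matrix()].
#' @param sample_sizes,n_loci as in [simulate_genotypes()].
#' @param n_sims posterior-predictive simulations (>= 500 recommended).
#' @param draws optional list of [parameter_draw()] (e.g. retained ABC
#'   rows); fresh prior draws are used when `NULL`.
#' @param n_components principal components retained (default 2).
#' @return Object of class `ppc_result`: `scores` (simulated PC
#'   coordinates), `observed_score`, `covered` (logical), `density_rank`.
#' @export
posterior_predictive_check <- function(spec, observed_g, sample_sizes,
                                       n_loci = 9, n_sims = 500,
                                       draws = NULL, n_components = 2) {
  sims <- matrix(NA_real_, n_sims, 0)
  stat_list <- vector("list", n_sims)
  for (b in seq_len(n_sims)) {
    draw <- if (is.null(draws)) NULL else draws[[((b - 1) %% length(draws)) + 1]]
    gt <- simulate_genotypes(spec, draw, sample_sizes, n_loci)
    stat_list[[b]] <- suppressWarnings(summary_stats(gt, "model_check"))
  }
  sims <- do.call(rbind, stat_list)
  obs <- suppressWarnings(summary_stats(observed_g, "model_check"))
  sds <- apply(sims, 2, sd)
  keep <- sds > 1e-12
  if (any(!keep))
    warning(sum(!keep), " degenerate statistic(s) dropped from the PCA")
  pc <- prcomp(sims[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
  k <- min(n_components, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  obs_score <- predict(pc, t(obs[keep]))[, seq_len(k), drop = FALSE]
  # kernel rank: density of each point under a Gaussian product kernel
  bw <- apply(scores, 2, function(v) stats::bw.nrd0(v))
  dens_at <- function(pt) {
    w <- rep(1, nrow(scores))
    for (j in seq_len(k))
      w <- w * stats::dnorm((pt[j] - scores[, j]) / bw[j]) / bw[j]
    mean(w)
  }
  dens_sims <- vapply(seq_len(nrow(scores)), function(i) dens_at(scores[i, ]), 0)
  dens_obs <- dens_at(as.numeric(obs_score))
  rank_frac <- mean(dens_sims <= dens_obs)
  structure(list(scores = scores, observed_score = obs_score,
                 covered = rank_frac > 0.05, density_rank = rank_frac,
                 n_sims = n_sims),
            class = "ppc_result")
}

#' @export
print.ppc_result <- function(x, ...) {
  cat("Posterior-predictive PCA check (", x$n_sims, " simulations): ",
      if (x$covered) "observed data INSIDE" else "observed data OUTSIDE",
      " the 95% kernel-density region (rank ",
      sprintf("%.3f", x$density_rank), ")\n", sep = "")
  invisible(x)
}
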
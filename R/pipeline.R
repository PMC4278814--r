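# End-to-end orchestration: synthesize inputs, build exposures, fit the
# establishment model, build scenarios, run popgen statistics and ABC
# model choice, and write report tables.

#' Run configuration
#'
#' Single container for every tunable constant of a full pipeline run.
#' A single global seed fans out to per-stage child seeds (`seed + stage
#' offset`), so stages can be re-run in isolation reproducibly.
#'
#' @param synth a [synth_config()].
#' @param cell_km grid cell size (km).
#' @param thresholds particle-count thresholds for scenario 2 and 3
#'   colonization years.
#' @param delay release delay (years) of the delayed all-sites scenario.
#' @param rarefaction_n rarefaction sample size (individuals).
#' @param n_perm_pairwise,n_perm_ibd permutation counts.
#' @param n_genetic_pops number of genotyped populations.
#' @param diploids_per_pop sampled diploids per population.
#' @param n_loci microsatellite loci.
#' @param n_ref_per_scenario ABC reference-table rows per scenario.
#' @param n_pseudo pseudo-observed datasets per scenario for the
#'   confusion analysis.
#' @param n_stations weather stations for the local-wind scenario.
#' @param seed global seed.
#' @return List of class `run_config`.
#' @export
run_config <- function(synth = synth_config(seed = seed),
                       cell_km = 10, thresholds = c(200, 800), delay = 4L,
                       rarefaction_n = 9, n_perm_pairwise = 200,
                       n_perm_ibd = 200, n_genetic_pops = 14,
                       diploids_per_pop = 30, n_loci = 9,
                       n_ref_per_scenario = 1000, n_pseudo = 25,
                       n_stations = 12, seed = 1L) {
  structure(list(synth = synth, cell_km = cell_km, thresholds = thresholds,
                 delay = delay, rarefaction_n = rarefaction_n,
                 n_perm_pairwise = n_perm_pairwise, n_perm_ibd = n_perm_ibd,
                 n_genetic_pops = n_genetic_pops,
                 diploids_per_pop = diploids_per_pop, n_loci = n_loci,
                 n_ref_per_scenario = n_ref_per_scenario,
                 n_pseudo = n_pseudo, n_stations = n_stations,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file whose top-level keys match [run_config()]
#'   arguments (`synth` is a nested map of [synth_config()] arguments).
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$synth)) y$synth <- do.call(synth_config, y$synth)
  do.call(run_config, y)
}

#' Run the full reconstruction pipeline on synthetic data
#'
#' Stages: (1) synthesize the site registry and introduction-site
#' trajectories; (2) build the introduction-site exposure series and
#' forward-simulate the survey; (3) synthesize all-site trajectories and
#' the remaining exposure scenarios; (4) fit and rank the establishment
#' model across dispersal scenarios; (5) synthesize station winds and
#' build the four demographic scenarios; (6) simulate observed genotypes
#' under scenario 1 and compute the population-genetic statistics;
#' (7) ABC reference table, scenario choice and confusion rates.
#' Writes five report tables (survival comparison, diversity, pairwise
#' differentiation, ABC posterior, confusion) plus a JSON log.
#'
#' @param config a [run_config()].
#' @param out_dir report directory (created if missing).
#' @return Invisible list with all intermediate objects and report paths.
#' @export
run_all <- function(config = run_config(), out_dir = tempfile("windborne_run_")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- config$synth
  stage_seed <- function(k) config$seed + 1000L * k

  # 1: sites + root trajectories
  registry <- generate_sites(cfg)
  root <- registry$site_id[1]
  traj_root <- generate_trajectories(cfg, registry,
                                     setNames(min(cfg$years), root))
  grid <- grid_spec(registry, cell_km = config$cell_km)

  # 2: root-only exposure and forward-simulated survey
  blank_survey <- survey_table(rep(registry$site_id, each = length(cfg$survey_years)),
                               rep(cfg$survey_years, nrow(registry)), FALSE)
  exp_root <- build_exposure(traj_root, grid, registry, blank_survey,
                             "ventoux_only", root = root,
                             years = cfg$survey_years)
  survey <- simulate_survey(exp_root, cfg$beta0, cfg$beta1, cfg$survey_years,
                            seed = stage_seed(2))
  # the introduction site is colonized from the first survey year by
  # construction (it is the origin, not a wind-established site)
  survey$detected[survey$site_id == root] <- TRUE
  det <- detection_years(survey)

  # 3: all-site trajectories and the three exposure scenarios
  set.seed(stage_seed(3))
  src_years <- det[!is.na(det)]
  traj_all <- generate_trajectories(cfg, registry, as.list(src_years))
  exposures <- list(
    ventoux_only = exp_root,
    all_sites = build_exposure(traj_all, grid, registry, survey, "all_sites",
                               root = root, years = cfg$survey_years),
    all_sites_delay4 = build_exposure(traj_all, grid, registry, survey,
                                      "all_sites_delay4", root = root,
                                      years = cfg$survey_years,
                                      delay = config$delay))

  # 4: establishment model across scenarios
  comparison <- compare_scenarios(exposures, survey)
  write.csv(as.data.frame(comparison),
            file.path(out_dir, "survival_comparison.csv"), row.names = FALSE)

  # 5: winds and demographic scenarios
  set.seed(stage_seed(5))
  st_idx <- seq(1, nrow(registry),
                length.out = min(config$n_stations, nrow(registry)))
  stations <- data.frame(station_id = paste0("W", seq_along(st_idx)),
                         lat = registry$lat[st_idx] + rnorm(length(st_idx), 0, 0.05),
                         lon = registry$lon[st_idx] + rnorm(length(st_idx), 0, 0.05))
  wind <- generate_wind_table(cfg, stations$station_id)
  scen <- suppressWarnings(
    build_all_scenarios(survey, exposures$ventoux_only, exposures$all_sites,
                        wind, stations, registry, root = root,
                        thresholds = config$thresholds))

  # restrict demes to the earliest-detected populations (genotyped sites)
  keep_demes <- function(sp, keep) {
    d <- sp$demes[sp$demes$site_id %in% keep, ]
    d$source[!d$source %in% keep & !is.na(d$source)] <- sp$root
    # re-clamp founding order along the pruned graph
    for (i in order(-d$founding_gen)) {
      if (is.na(d$source[i])) next
      cap <- if (d$source[i] == sp$root) 11L else
        d$founding_gen[match(d$source[i], d$site_id)] - 1L
      if (!is.na(cap) && d$founding_gen[i] > cap)
        d$founding_gen[i] <- max(1L, cap)
    }
    scenario_spec(sp$scenario_id, d, sp$sampling_year, root = sp$root)
  }
  detected <- names(sort(det[!is.na(det)]))
  pops <- head(detected, config$n_genetic_pops)
  scen <- lapply(scen, keep_demes, keep = pops)
  write_scenarios(scen, file.path(out_dir, "scenarios.json"))

  # 6: observed genotypes under scenario 1 + popgen statistics
  set.seed(stage_seed(6))
  sample_sizes <- setNames(rep(config$diploids_per_pop, length(pops)), pops)
  observed <- simulate_genotypes(scen$scenario1, NULL, sample_sizes,
                                 config$n_loci)
  summ <- locus_summaries(observed, config$rarefaction_n)
  div <- aggregate(summ[, c("na", "he", "ar", "m")], list(pop = summ$pop),
                   mean, na.rm = TRUE)
  div$n <- as.integer(table(observed$pop)[div$pop])
  write.csv(div, file.path(out_dir, "diversity.csv"), row.names = FALSE)
  fst <- f_statistics(observed)
  pw <- pairwise_tests(observed, n_perm = config$n_perm_pairwise)
  pw_out <- as.data.frame(pw$stat)
  pw_out$pop <- rownames(pw$stat)
  write.csv(pw_out, file.path(out_dir, "pairwise_fst.csv"), row.names = FALSE)

  # 7: ABC
  set.seed(stage_seed(7))
  ref <- build_reference(scen, config$n_ref_per_scenario, sample_sizes,
                         config$n_loci)
  obs_stats <- suppressWarnings(summary_stats(observed, "abc"))
  nc <- min(nrow(ref$stats), max(100L, ceiling(0.01 * nrow(ref$stats))))
  choice <- suppressWarnings(model_choice(obs_stats, ref, n_closest = nc))
  post <- data.frame(scenario = names(choice$posterior),
                     posterior = as.numeric(choice$posterior),
                     ci_lo = if (!is.null(choice$ci)) choice$ci["lo", ] else NA,
                     ci_hi = if (!is.null(choice$ci)) choice$ci["hi", ] else NA)
  write.csv(post, file.path(out_dir, "abc_posterior.csv"), row.names = FALSE)
  conf <- confusion_rates(ref, scen, config$n_pseudo, sample_sizes,
                          config$n_loci, n_closest = nc)
  conf_out <- as.data.frame(conf$confusion)
  conf_out$true_scenario <- rownames(conf$confusion)
  conf_out$type1 <- conf$type1
  conf_out$type2 <- conf$type2
  write.csv(conf_out, file.path(out_dir, "abc_confusion.csv"), row.names = FALSE)

  log <- list(seed = config$seed, r_version = R.version.string,
              n_sites = nrow(registry), n_detected = sum(!is.na(det)),
              n_genetic_pops = length(pops),
              winner_survival = comparison$scenario[1],
              winner_abc = names(which.max(choice$posterior)),
              fst = fst$fst)
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(registry = registry, survey = survey, exposures = exposures,
                 comparison = comparison, scenarios = scen,
                 genotypes = observed, diversity = div, fstats = fst,
                 pairwise = pw, reference = ref, choice = choice,
                 confusion = conf, out_dir = out_dir))
}
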
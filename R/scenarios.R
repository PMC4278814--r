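# Construction of the four demographic scenarios: colonization years,
# source assignments, and the dated deme-founding graph consumed by the
# coalescent engine.

#' Classify a bearing into one of eight compass sectors
#'
#' Sectors are 45 degrees wide and half-open:
#' `[center - 22.5, center + 22.5)`; north covers angles from 337.5 up to
#' (but excluding) 22.5 degrees.
#'
#' @param angle bearing(s) in degrees, `[0, 360)`.
#' @return Character vector of sectors (`N,NE,E,SE,S,SW,W,NW`).
#' @export
classify_bearing <- function(angle) {
  a <- angle %% 360
  idx <- (floor((a + 22.5) / 45) %% 8) + 1
  wind_sectors[idx]
}

#' First year a cumulative count series reaches a threshold
#'
#' @param x named numeric vector of cumulative (non-decreasing) counts,
#'   names = calendar years.
#' @param threshold count threshold (200 for the introduction-site-only
#'   series, 800 for the all-sites series).
#' @return The first year with `x >= threshold`, or `NA` if never reached.
#' @export
colonization_year_from_threshold <- function(x, threshold) {
  if (is.unsorted(x)) stop("cumulative counts must be non-decreasing")
  hit <- which(x >= threshold)
  if (!length(hit)) return(NA_integer_)
  as.integer(names(x)[hit[1]])
}

#' Assign a colonization source to every non-root site
#'
#' `nearest_neighbor`: among sites colonized strictly earlier, the
#' geographically closest.  `local_wind`: among already-colonized sites
#' whose nearest weather station recorded wind blowing in the sector from
#' the candidate source toward the target during May of the year before
#' the target's colonization, the closest one; if none qualifies the rule
#' falls back to the nearest neighbor with a warning.  Non-root sites
#' with no strictly earlier colonized site fall back to the root with a
#' warning (the founding graph must stay rooted).
#'
#' @param registry a [site_registry()].
#' @param colonization_years named integer vector (site -> year); the root
#'   must have the earliest year.
#' @param mode `"nearest_neighbor"` or `"local_wind"`.
#' @param wind a [wind_table()] (required for `local_wind`).
#' @param stations data.frame (station_id, lat, lon) locating the weather
#'   stations (required for `local_wind`).
#' @param root introduction-site id.
#' @return Named character vector (site -> source site); the root maps to
#'   `NA`.
#' @export
assign_sources <- function(registry, colonization_years,
                           mode = c("nearest_neighbor", "local_wind"),
                           wind = NULL, stations = NULL,
                           root = registry$site_id[1]) {
  mode <- match.arg(mode)
  cy <- colonization_years[!is.na(colonization_years)]
  if (!root %in% names(cy)) stop("root site ", root, " has no colonization year")
  if (any(cy < cy[root])) stop("root must have the earliest colonization year")
  if (mode == "local_wind" && (is.null(wind) || is.null(stations)))
    stop("local_wind mode needs wind table and station coordinates")
  dmat <- site_distances(registry)
  out <- setNames(rep(NA_character_, length(cy)), names(cy))
  reg_idx <- match(names(cy), registry$site_id)
  if (mode == "local_wind") {
    sdist <- outer(seq_along(cy), seq_len(nrow(stations)), function(i, k)
      sqrt(rowSums((project_km(registry$lat[reg_idx[i]], registry$lon[reg_idx[i]],
                               c(0, 0)) -
                    project_km(stations$lat[k], stations$lon[k], c(0, 0)))^2)))
    nearest_station <- stations$station_id[apply(sdist, 1, which.min)]
    names(nearest_station) <- names(cy)
    wind$year <- as.integer(format(wind$date, "%Y"))
  }
  for (s in setdiff(names(cy), root)) {
    earlier <- names(cy)[cy < cy[s]]
    if (!length(earlier)) {
      warning("site ", s, " has no strictly earlier colonized site; ",
              "using root ", root, " as source")
      out[s] <- root
      next
    }
    cand <- earlier
    if (mode == "local_wind") {
      prior_may <- cy[s] - 1L
      ok <- vapply(earlier, function(src) {
        st <- nearest_station[src]
        i_src <- match(src, registry$site_id)
        i_tgt <- match(s, registry$site_id)
        sec <- classify_bearing(bearing_deg(registry$lat[i_src], registry$lon[i_src],
                                            registry$lat[i_tgt], registry$lon[i_tgt]))
        rows <- wind$station_id == st & wind$year == prior_may & wind$sector == sec
        any(wind$wind_run_km[rows] > 0)
      }, TRUE)
      if (any(ok)) cand <- earlier[ok]
      else warning("no wind-compatible source for site ", s,
                   "; falling back to nearest neighbor")
    }
    out[s] <- cand[which.min(dmat[s, cand])]
  }
  out
}

ne_prior_class <- function(detection_year) {
  ifelse(detection_year <= 2001, "early",
         ifelse(detection_year <= 2006, "mid", "late"))
}

ne_prior_bounds <- list(early = c(10, 10000), mid = c(10, 5000),
                        late = c(10, 1000))

#' Build a dated deme-founding scenario specification
#'
#' @param scenario_id integer 1-4.
#' @param demes data.frame with `site_id`, `founding_gen` (generations
#'   before present; root = `NA`, drawn from the t1 prior), `source`
#'   (site id; root = `NA`), `ne_class` (`early`/`mid`/`late`).
#' @param sampling_year calendar year anchored at generation 0.
#' @param root root (introduction) site id.
#' @param t1_prior uniform prior bounds for the root founding time
#'   (generations).
#' @param admix_prior uniform prior bounds for the root admixture rate.
#' @param ancestral_ne_prior uniform prior bounds for the two unsampled
#'   ancestral demes.
#' @return Object of class `scenario_spec`.
#' @export
scenario_spec <- function(scenario_id, demes, sampling_year,
                          root = demes$site_id[1],
                          t1_prior = c(12, 15), admix_prior = c(0.1, 0.9),
                          ancestral_ne_prior = c(100, 10000)) {
  stopifnot(all(c("site_id", "founding_gen", "source", "ne_class") %in%
                  names(demes)))
  if (sum(is.na(demes$source)) != 1L)
    stop("exactly one root deme (source = NA) is required")
  if (demes$site_id[is.na(demes$source)] != root)
    stop("root deme must be ", root)
  non_root <- demes[!is.na(demes$source), ]
  if (any(!non_root$source %in% demes$site_id))
    stop("unknown source deme(s)")
  if (any(non_root$founding_gen < 1))
    stop("founding generations must be >= 1")
  # every deme's source must exist before it (larger founding generation)
  src_gen <- demes$founding_gen[match(non_root$source, demes$site_id)]
  bad <- !is.na(src_gen) & non_root$founding_gen >= src_gen
  if (any(bad))
    stop("deme(s) founded no later than their source: ",
         paste(non_root$site_id[bad], collapse = ", "))
  # acyclicity: walk each deme to the root
  for (s in non_root$site_id) {
    seen <- character(0)
    cur <- s
    while (!is.na(cur)) {
      if (cur %in% seen) stop("cycle in founding graph at ", cur)
      seen <- c(seen, cur)
      cur <- demes$source[match(cur, demes$site_id)]
    }
  }
  structure(list(scenario_id = as.integer(scenario_id), demes = demes,
                 sampling_year = as.integer(sampling_year), root = root,
                 t1_prior = t1_prior, admix_prior = admix_prior,
                 ancestral_ne_prior = ancestral_ne_prior),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("Demographic scenario ", x$scenario_id, ": ", nrow(x$demes),
      " demes rooted at ", x$root, "; t1 ~ U(", x$t1_prior[1], ", ",
      x$t1_prior[2], ") with admixture\n", sep = "")
  invisible(x)
}

# founding generation from a calendar year, clamped to be strictly
# younger than the source along the DAG and at least 1
founding_generations <- function(site_ids, years, sources, root,
                                 sampling_year, t1_min) {
  g <- setNames(pmax(1L, sampling_year - as.integer(years)), site_ids)
  g[root] <- NA_integer_
  # topological order: by calendar year then repeated clamping passes
  for (pass in 1:length(site_ids)) {
    changed <- FALSE
    for (s in setdiff(site_ids, root)) {
      src <- sources[s]
      cap <- if (src == root) t1_min - 1L else g[src] - 1L
      if (!is.na(cap) && g[s] > cap) { g[s] <- max(1L, cap); changed <- TRUE }
      if (!is.na(cap) && g[s] >= max(1L, cap) && g[s] > cap) g[s] <- max(1L, cap)
    }
    if (!changed) break
  }
  g
}

#' Build all four demographic scenarios
#'
#' Scenario 1 (long-distance): star graph from the root at survey
#' detection years.  Scenario 2 (stepping-stone, regional wind):
#' colonization years from the 200-count threshold on the root-only
#' exposure, nearest-neighbor sources.  Scenario 3 (network, regional
#' wind): 800-count threshold on the all-sites exposure, nearest-neighbor
#' sources.  Scenario 4 (local wind): detection year - 1 arrival,
#' wind-direction-filtered nearest sources.  Effective-size prior classes
#' follow the detection era (through 2001: U(10, 10000); 2002-2006:
#' U(10, 5000); 2007 on: U(10, 1000)).
#'
#' @param survey a [survey_table()] (detected sites define the demes).
#' @param exposure_root [exposure_series()] from the root only.
#' @param exposure_all [exposure_series()] from all colonized sites.
#' @param wind a [wind_table()].
#' @param stations data.frame (station_id, lat, lon).
#' @param registry a [site_registry()].
#' @param root introduction-site id.
#' @param sampling_year anchor of generation 0 (default: latest survey
#'   year).
#' @param thresholds counts for scenarios 2 and 3 (default 200, 800).
#' @return Named list of four [scenario_spec()] objects.
#' @export
build_all_scenarios <- function(survey, exposure_root, exposure_all, wind,
                                stations, registry,
                                root = registry$site_id[1],
                                sampling_year = max(survey$year),
                                thresholds = c(200, 800)) {
  det <- detection_years(survey)
  det <- det[!is.na(det)]
  if (!root %in% names(det)) stop("root site was never detected in the survey")
  sites <- names(det)[order(det, match(names(det), registry$site_id))]
  t1_min <- 12L

  mk <- function(id, years, sources) {
    g <- founding_generations(sites, years[sites], sources, root,
                              sampling_year, t1_min)
    demes <- data.frame(
      site_id = sites,
      founding_gen = as.integer(g[sites]),
      source = ifelse(sites == root, NA_character_, sources[sites]),
      ne_class = ne_prior_class(det[sites]),
      stringsAsFactors = FALSE)
    scenario_spec(id, demes, sampling_year, root = root)
  }

  # scenario 1: star from the root at detection years
  src1 <- setNames(rep(root, length(sites)), sites)
  src1[root] <- NA_character_
  sc1 <- mk(1L, det, src1)

  # scenarios 2 and 3: threshold years on root-only / all-sites exposure;
  # non-root years are floored at the root's year + 1 so the founding
  # graph stays rooted at the introduction site
  thr_years <- function(exposure, thr) {
    vapply(sites, function(s) {
      if (s == root) return(det[root])
      x <- exposure$x[s, ]
      names(x) <- exposure$years
      y <- colonization_year_from_threshold(x, thr)
      if (is.na(y)) y <- det[s]     # never-reached: keep the survey year
      max(y, det[root] + 1L)
    }, integer(1))
  }
  cy2 <- thr_years(exposure_root, thresholds[1])
  cy3 <- thr_years(exposure_all, thresholds[2])
  suppressWarnings({
    src2 <- assign_sources(registry, cy2, "nearest_neighbor", root = root)
    src3 <- assign_sources(registry, cy3, "nearest_neighbor", root = root)
  })
  sc2 <- mk(2L, cy2, src2)
  sc3 <- mk(3L, cy3, src3)

  # scenario 4: detection year - 1 arrival, local-wind sources; arrivals
  # are floored one year after the root's detection so the graph stays
  # rooted even when a site was detected in the root's detection year
  cy4 <- pmax(det - 1L, det[root] + 1L)
  cy4[root] <- det[root]
  suppressWarnings(
    src4 <- assign_sources(registry, cy4, "local_wind", wind = wind,
                           stations = stations, root = root))
  sc4 <- mk(4L, cy4, src4)

  list(scenario1 = sc1, scenario2 = sc2, scenario3 = sc3, scenario4 = sc4)
}

#' Serialize scenario specifications to JSON
#'
#' @param specs a [scenario_spec()] or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scenarios <- function(specs, path) {
  if (inherits(specs, "scenario_spec")) specs <- list(specs)
  payload <- lapply(specs, function(s) {
    list(scenario_id = s$scenario_id, root = s$root,
         sampling_year = s$sampling_year, t1_prior = s$t1_prior,
         admix_prior = s$admix_prior,
         ancestral_ne_prior = s$ancestral_ne_prior, demes = s$demes)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Read scenario specifications from JSON
#' @param path JSON file written by [write_scenarios()].
#' @return List of [scenario_spec()].
#' @export
read_scenarios <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- lapply(payload, function(row) {
    demes <- do.call(rbind, lapply(row$demes, function(d)
      data.frame(site_id = d$site_id,
                 founding_gen = if (is.null(d$founding_gen)) NA_integer_
                                else as.integer(d$founding_gen),
                 source = if (is.null(d$source)) NA_character_
                          else as.character(d$source),
                 ne_class = d$ne_class, stringsAsFactors = FALSE)))
    scenario_spec(row$scenario_id, demes, row$sampling_year, root = row$root,
                  t1_prior = unlist(row$t1_prior),
                  admix_prior = unlist(row$admix_prior),
                  ancestral_ne_prior = unlist(row$ancestral_ne_prior))
  })
  names(out) <- vapply(payload, function(row)
    paste0("scenario", row$scenario_id), "")
  out
}
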
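# Synthetic-data generator: emulates the four input kinds (site registry,
# particle trajectories, station wind runs, survey histories) with the
# statistical structure the downstream analyses assume.  Genotype fixtures
# come from the coalescent engine (simulate_genotypes), not from here.

#' Configuration of the synthetic-data generator
#'
#' Defaults emulate the study conditions of a regional windborne invasion:
#' ~50 host stands in a ~250 x 400 km box (most of them in the corridor
#' downwind of the introduction site, like the host stands of the
#' emulated system), a single introduction site in the north-west, a
#' prevailing drift toward the south-east (bearing 135 degrees, the
#' Mistral analogue), a small trajectory ensemble per source site per May
#' day followed for 15 hours, and annual surveys.  Under these defaults a
#' median invasion colonizes ~20 of 50 stands in 17 years, dominated by
#' wind-driven establishment rather than the baseline hazard, matching
#' the emulated system's wind-driven character.
#'
#' @param n_sites number of survey sites.
#' @param bbox `c(lat_min, lat_max, lon_min, lon_max)` in degrees.
#' @param drift_bearing prevailing drift bearing, degrees clockwise from
#'   north (135 = toward SE).
#' @param drift_speed_kmh mean hourly drift displacement, km/h.
#' @param diffusion_kmh sd of the isotropic Gaussian displacement added per
#'   hour, km (hourly steps in the emulated system are of order 10 km).
#' @param per_day_trajectories ensemble members released per site per
#'   May day.  The emulated trajectory model releases a (small) ensemble
#'   per release time; the default of 5 places cumulative cell counts at
#'   the scale the colonization thresholds (200, 800 counts) and effect
#'   sizes (~0.005 per count) presuppose.
#' @param years calendar years covered by wind and trajectory data.
#' @param survey_years years of the annual presence/absence survey.
#' @param beta0 log baseline establishment intensity per year (see
#'   [establishment_fit()]).
#' @param beta1 establishment effect per unit cumulative exposure count.
#' @param seed integer seed fixing all randomness of the generator.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_sites = 50,
                         bbox = c(43.2, 45.45, 4.0, 9.0),
                         drift_bearing = 135, drift_speed_kmh = 8,
                         diffusion_kmh = 5, per_day_trajectories = 5L,
                         years = 1994:2010, survey_years = 1994:2010,
                         beta0 = -4.5, beta1 = 0.005, seed = 1L) {
  stopifnot(bbox[2] > bbox[1], bbox[4] > bbox[3],
            drift_speed_kmh >= 0, diffusion_kmh >= 0, n_sites >= 2,
            per_day_trajectories >= 1)
  structure(list(n_sites = n_sites, bbox = bbox,
                 drift_bearing = drift_bearing,
                 drift_speed_kmh = drift_speed_kmh,
                 diffusion_kmh = diffusion_kmh,
                 per_day_trajectories = as.integer(per_day_trajectories),
                 years = years,
                 survey_years = survey_years, beta0 = beta0, beta1 = beta1,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a synthetic site registry
#'
#' The first site (`Vx`, the introduction-site analogue) sits in the
#' north-western quadrant of the box.  Host stands in the emulated system
#' are concentrated in the corridor downwind (south-east) of the
#' introduction site, so a fraction `corridor_frac` of the remaining
#' sites is placed at 15-130 km from the introduction site along
#' bearings scattered around the prevailing drift, and the rest uniformly
#' over the box (the far, rarely-reached stands).  Detection years are
#' left `NA`; they are filled in by [simulate_survey()].
#'
#' @param cfg a [synth_config()].
#' @param corridor_frac fraction of sites placed in the downwind corridor.
#' @return A [site_registry()].
#' @export
generate_sites <- function(cfg, corridor_frac = 0.7) {
  set.seed(cfg$seed)
  n <- cfg$n_sites
  b <- cfg$bbox
  lat0 <- b[1] + 0.80 * (b[2] - b[1])
  lon0 <- b[3] + 0.20 * (b[4] - b[3])
  km_lat <- 111.32
  km_lon <- 111.32 * cos(mean(b[1:2]) * pi / 180)
  n_corr <- round(corridor_frac * (n - 1L))
  r <- runif(n_corr, 15, 130)
  ang <- rnorm(n_corr, cfg$drift_bearing, 30) * pi / 180
  lat_c <- lat0 + r * cos(ang) / km_lat
  lon_c <- lon0 + r * sin(ang) / km_lon
  n_far <- n - 1L - n_corr
  lat <- c(lat0, lat_c, runif(n_far, b[1], b[2]))
  lon <- c(lon0, lon_c, runif(n_far, b[3], b[4]))
  lat <- pmin(pmax(lat, b[1]), b[2])
  lon <- pmin(pmax(lon, b[3]), b[4])
  ids <- c("Vx", sprintf("S%02d", seq_len(n - 1L)))
  site_registry(ids, name = ids, lat = lat, lon = lon,
                elevation = round(runif(n, 300, 1100)),
                detection_year = NA_integer_,
                survey_start = min(cfg$survey_years),
                survey_end = max(cfg$survey_years))
}

#' Generate synthetic particle trajectories
#'
#' `per_day_trajectories` ensemble members per source site per May day
#' (31 days) per year from the site's first release year onward.  Each
#' trajectory starts at the site (hour 0) and advances 15 hourly steps;
#' each step adds the deterministic drift displacement (speed toward
#' `drift_bearing`) plus isotropic Gaussian noise with sd
#' `diffusion_kmh`.  Deterministic under `cfg$seed`.
#'
#' @param cfg a [synth_config()].
#' @param registry a [site_registry()] containing all source sites.
#' @param source_years named map (site_id -> first release year); sites
#'   absent from the map release nothing.
#' @return A [trajectory_set()].
#' @export
generate_trajectories <- function(cfg, registry, source_years) {
  if (length(source_years) == 0)
    return(trajectory_set(data.frame(site_id = character(0), year = integer(0),
                                     day = integer(0), member = integer(0),
                                     hour = integer(0),
                                     lat = numeric(0), lon = numeric(0),
                                     altitude = numeric(0))))
  unk <- setdiff(names(source_years), registry$site_id)
  if (length(unk)) stop("source site(s) not in registry: ",
                        paste(unk, collapse = ", "))
  set.seed(cfg$seed + 1L)
  ref_lat <- mean(cfg$bbox[1:2])
  km_per_deg_lat <- 111.32
  km_per_deg_lon <- 111.32 * cos(ref_lat * pi / 180)
  ang <- cfg$drift_bearing * pi / 180
  drift_dx <- cfg$drift_speed_kmh * sin(ang)   # km east per hour
  drift_dy <- cfg$drift_speed_kmh * cos(ang)   # km north per hour
  out <- list()
  n_member <- if (is.null(cfg$per_day_trajectories)) 1L else
    cfg$per_day_trajectories
  for (s in names(source_years)) {
    row <- registry[registry$site_id == s, ]
    yrs <- cfg$years[cfg$years >= source_years[[s]]]
    for (y in yrs) {
      nt <- 31L * n_member        # trajectories this site-year
      dx <- matrix(rnorm(15L * nt, drift_dx, cfg$diffusion_kmh), 15L, nt)
      dy <- matrix(rnorm(15L * nt, drift_dy, cfg$diffusion_kmh), 15L, nt)
      cx <- rbind(0, apply(dx, 2, cumsum))
      cy <- rbind(0, apply(dy, 2, cumsum))
      alt <- apply(matrix(rnorm(16L * nt, 0, 30), 16L, nt), 2,
                   function(v) 50 + pmax(0, cumsum(v)))
      out[[length(out) + 1L]] <- data.frame(
        site_id = s, year = y,
        day = rep(rep(1:31, each = n_member), each = 16L),
        member = rep(rep(seq_len(n_member), times = 31L), each = 16L),
        hour = rep(0:15, nt),
        lat = row$lat + as.vector(cy) / km_per_deg_lat,
        lon = row$lon + as.vector(cx) / km_per_deg_lon,
        altitude = as.vector(alt),
        stringsAsFactors = FALSE)
    }
  }
  trajectory_set(do.call(rbind, out))
}

#' Generate a synthetic daily station wind-run table
#'
#' Daily May wind runs per compass sector drawn from a gamma model
#' (shape 2) whose sector means are proportional to `sector_weights`.
#' The default weights put 2.5x more wind toward the SE sector than toward
#' any other, emulating a Mistral-dominated station record.
#'
#' @param cfg a [synth_config()].
#' @param stations character vector of station ids.
#' @param sector_weights non-negative 8-vector named or ordered as
#'   `N,NE,E,SE,S,SW,W,NW`.
#' @param mean_run_km mean daily wind run (km) for a weight-1 sector.
#' @return A [wind_table()].
#' @export
generate_wind_table <- function(cfg, stations,
                                sector_weights = c(1, 1, 1, 2.5, 1, 1, 1, 1),
                                mean_run_km = 80) {
  stopifnot(length(sector_weights) == 8, all(sector_weights >= 0),
            any(sector_weights > 0))
  if (!is.null(names(sector_weights)))
    sector_weights <- sector_weights[wind_sectors]
  set.seed(cfg$seed + 2L)
  dates <- as.Date(unlist(lapply(cfg$years, function(y)
    format(seq(as.Date(sprintf("%d-05-01", y)),
               as.Date(sprintf("%d-05-31", y)), by = "day")))))
  grid <- expand.grid(station_id = stations, date = dates,
                      sector = wind_sectors, stringsAsFactors = FALSE)
  w <- sector_weights[match(grid$sector, wind_sectors)]
  run <- rgamma(nrow(grid), shape = 2, scale = mean_run_km * w / 2)
  wind_table(grid$station_id, grid$date, grid$sector, run)
}

#' Forward-simulate interval-censored survey histories
#'
#' Simulates the same establishment model that [establishment_fit()] fits:
#' in year `t`, a not-yet-established site with cumulative exposure
#' `x_i(t)` establishes with probability `1 - exp(-lambda_i(t))`,
#' `lambda_i(t) = exp(beta0 + beta1 * x_i(t))`.  Detection is recorded at
#' the first survey year >= the establishment year; sites that never
#' establish are right-censored at the last survey year.
#'
#' @param exposure an [exposure_series()] covering all site-years.
#' @param beta0,beta1 model parameters (log baseline intensity; effect per
#'   unit exposure count).
#' @param survey_years calendar years of the annual surveys.
#' @param seed optional integer seed.
#' @return A [survey_table()].
#' @export
simulate_survey <- function(exposure, beta0, beta1, survey_years,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- exposure$x   # sites x years matrix
  yrs <- as.integer(colnames(x))
  sites <- rownames(x)
  est_year <- rep(NA_integer_, length(sites))
  for (i in seq_along(sites)) {
    lam <- exp(beta0 + beta1 * x[i, ])
    hit <- which(runif(length(yrs)) < -expm1(-lam))
    if (length(hit)) est_year[i] <- yrs[hit[1]]
  }
  rows <- expand.grid(site_id = sites, year = as.integer(survey_years),
                      stringsAsFactors = FALSE)
  ey <- est_year[match(rows$site_id, sites)]
  det_at <- vapply(seq_along(sites), function(i) {
    if (is.na(est_year[i])) return(NA_integer_)
    cand <- survey_years[survey_years >= est_year[i]]
    if (length(cand)) as.integer(min(cand)) else NA_integer_
  }, integer(1))
  rows$detected <- !is.na(det_at[match(rows$site_id, sites)]) &
    rows$year >= det_at[match(rows$site_id, sites)]
  survey_table(rows$site_id, rows$year, rows$detected)
}
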
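# Grid overlay of trajectory endpoints and cumulative per-site exposure
# covariates under the three dispersal scenarios.

#' Define a 10 km analysis grid over a site registry
#'
#' Cells are squares of `cell_km` in the package's equirectangular planar
#' projection; the grid is padded so that every registry site falls inside
#' it.  Cell assignment uses half-open intervals `[edge, edge + cell)` on
#' both axes.
#'
#' @param registry a [site_registry()].
#' @param cell_km cell size in km (default 10, matching the maximum
#'   distance between one-hour trajectory point estimates).
#' @param pad_km padding added around the site bounding box, km.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(registry, cell_km = 10, pad_km = 100) {
  stopifnot(cell_km > 0)
  ref_lat <- mean(registry$lat)
  origin_geo <- c(min(registry$lat), min(registry$lon))
  xy <- project_km(registry$lat, registry$lon, origin_geo, ref_lat)
  x0 <- floor((min(xy[, 1]) - pad_km) / cell_km) * cell_km
  y0 <- floor((min(xy[, 2]) - pad_km) / cell_km) * cell_km
  n_cols <- ceiling((max(xy[, 1]) + pad_km - x0) / cell_km)
  n_rows <- ceiling((max(xy[, 2]) + pad_km - y0) / cell_km)
  structure(list(origin_geo = origin_geo, ref_lat = ref_lat,
                 x0 = x0, y0 = y0, cell_km = cell_km,
                 n_rows = as.integer(n_rows), n_cols = as.integer(n_cols)),
            class = "grid_spec")
}

#' Cell indices of geographic points
#'
#' @param grid a [grid_spec()].
#' @param lat,lon decimal degrees.
#' @return data.frame with `row`, `col` (1-based; `NA` when outside the
#'   grid) and the flat cell index `cell`.
#' @export
grid_cell <- function(grid, lat, lon) {
  xy <- project_km(lat, lon, grid$origin_geo, grid$ref_lat)
  col <- floor((xy[, 1] - grid$x0) / grid$cell_km) + 1
  row <- floor((xy[, 2] - grid$y0) / grid$cell_km) + 1
  out <- col >= 1 & col <= grid$n_cols & row >= 1 & row <= grid$n_rows
  col[!out] <- NA_integer_
  row[!out] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col),
             cell = as.integer((col - 1L) * grid$n_rows + row))
}

#' Count trajectory endpoints per grid cell for one year
#'
#' Every hourly endpoint (including the hour-0 release point, toggleable)
#' of every trajectory released in `year` from a site in `sources`
#' increments exactly one cell; endpoints outside the grid are dropped and
#' tallied.
#'
#' @param traj a [trajectory_set()].
#' @param grid a [grid_spec()].
#' @param year release year.
#' @param sources character vector of release site ids to include.
#' @param include_release count the hour-0 release point like hours 1-15.
#' @return An integer matrix `n_rows x n_cols` with attribute `dropped`
#'   (endpoints outside the grid).
#' @export
count_points <- function(traj, grid, year, sources,
                         include_release = TRUE) {
  keep <- traj$year == year & traj$site_id %in% sources
  if (!include_release) keep <- keep & traj$hour > 0L
  pts <- traj[keep, ]
  m <- matrix(0L, grid$n_rows, grid$n_cols)
  if (nrow(pts)) {
    cc <- grid_cell(grid, pts$lat, pts$lon)
    inside <- !is.na(cc$cell)
    tab <- tabulate(cc$cell[inside], nbins = grid$n_rows * grid$n_cols)
    m[] <- tab
    attr(m, "dropped") <- sum(!inside)
  } else attr(m, "dropped") <- 0L
  m
}

#' Release-site sets per year under a dispersal scenario
#'
#' `ventoux_only`: only the introduction site releases, every year.
#' `all_sites`: every site releases from its detection year onward.
#' `all_sites_delay4`: every site releases from `detection_year + delay`
#' onward (the introduction site from its own detection year + delay, but
#' never later than its first appearance in the survey record).
#'
#' @param survey a [survey_table()].
#' @param scenario one of `"ventoux_only"`, `"all_sites"`,
#'   `"all_sites_delay4"`.
#' @param root site id of the introduction site.
#' @param delay delay in years for `all_sites_delay4`.
#' @param years years for which source sets are required.
#' @return Named list (year -> character vector of site ids).
#' @export
scenario_sources <- function(survey, scenario, root, delay = 4L,
                             years = sort(unique(survey$year))) {
  if (!scenario %in% c("ventoux_only", "all_sites", "all_sites_delay4"))
    stop("unknown scenario tag: ", scenario)
  det <- detection_years(survey)
  if (!root %in% names(det)) det[root] <- min(survey$year, na.rm = TRUE)
  out <- lapply(years, function(y) {
    switch(scenario,
      ventoux_only = root,
      all_sites = names(det)[!is.na(det) & det <= y],
      all_sites_delay4 = names(det)[!is.na(det) & det + delay <= y])
  })
  names(out) <- as.character(years)
  out
}

#' Build cumulative per-site exposure series under a scenario
#'
#' For each site i and year t, `x_i(t)` is the cumulative count (summed
#' from the first year to t) of trajectory endpoints falling in the site's
#' grid cell, restricting each year's trajectories to that year's release
#' sites under the scenario.
#'
#' @param traj a [trajectory_set()].
#' @param grid a [grid_spec()].
#' @param registry a [site_registry()]; every site must fall inside `grid`.
#' @param survey a [survey_table()] (defines the scenario source sets).
#' @param scenario scenario tag, see [scenario_sources()].
#' @param root introduction-site id.
#' @param years years of the series (default: survey years).
#' @param delay delay for `all_sites_delay4`.
#' @param include_release count hour-0 release points.
#' @return An object of class `exposure_series`: list with `x` (integer
#'   matrix sites x years, non-decreasing along rows), `scenario`,
#'   `dropped` (per-year out-of-grid tallies).
#' @export
build_exposure <- function(traj, grid, registry, survey, scenario,
                           root = registry$site_id[1],
                           years = sort(unique(survey$year)), delay = 4L,
                           include_release = TRUE) {
  cells <- grid_cell(grid, registry$lat, registry$lon)
  if (anyNA(cells$cell))
    stop("site(s) outside the grid: ",
         paste(registry$site_id[is.na(cells$cell)], collapse = ", "))
  src <- scenario_sources(survey, scenario, root, delay, years)
  x <- matrix(0L, nrow(registry), length(years),
              dimnames = list(registry$site_id, years))
  dropped <- integer(length(years))
  cum <- numeric(nrow(registry))
  for (k in seq_along(years)) {
    cnt <- count_points(traj, grid, years[k], src[[k]], include_release)
    cum <- cum + cnt[cbind(cells$row, cells$col)]
    dropped[k] <- attr(cnt, "dropped")
    x[, k] <- as.integer(cum)
  }
  structure(list(x = x, scenario = scenario, dropped = dropped,
                 years = as.integer(years)),
            class = "exposure_series")
}

#' @export
print.exposure_series <- function(x, ...) {
  cat("Exposure series (", x$scenario, "): ", nrow(x$x), " sites x ",
      ncol(x$x), " years; final counts ",
      min(x$x[, ncol(x$x)]), "-", max(x$x[, ncol(x$x)]), "\n", sep = "")
  invisible(x)
}

#' Tabulate trajectory endpoints per source site, year and target site
#'
#' One pass over a trajectory set, recording how many endpoints released
#' by each source site in each year fall in each registry site's grid
#' cell.  [exposure_from_counts()] turns the resulting array into the
#' cumulative exposure series of any scenario without re-scanning the
#' trajectories — the fast path when many surveys are analysed against
#' one trajectory set.
#'
#' @param traj a [trajectory_set()].
#' @param grid a [grid_spec()].
#' @param registry a [site_registry()].
#' @param include_release count hour-0 release points.
#' @return Integer array `[source, year, site]` with dimnames.
#' @export
site_point_counts <- function(traj, grid, registry, include_release = TRUE) {
  cells <- grid_cell(grid, registry$lat, registry$lon)
  if (anyNA(cells$cell))
    stop("site(s) outside the grid: ",
         paste(registry$site_id[is.na(cells$cell)], collapse = ", "))
  pts <- if (include_release) traj else traj[traj$hour > 0L, ]
  pc <- grid_cell(grid, pts$lat, pts$lon)
  hit <- match(pc$cell, cells$cell)
  ok <- !is.na(hit)
  sources <- sort(unique(traj$site_id))
  years <- sort(unique(traj$year))
  arr <- array(0L, dim = c(length(sources), length(years), nrow(registry)),
               dimnames = list(sources, years, registry$site_id))
  if (any(ok)) {
    idx <- cbind(match(pts$site_id[ok], sources),
                 match(pts$year[ok], years), hit[ok])
    tab <- table(factor(idx[, 1], seq_along(sources)),
                 factor(idx[, 2], seq_along(years)),
                 factor(idx[, 3], seq_len(nrow(registry))))
    arr[] <- as.integer(tab)
  }
  arr
}

#' Cumulative exposure series from a precomputed count array
#'
#' @param counts array from [site_point_counts()].
#' @param survey a [survey_table()].
#' @param scenario,root,years,delay as in [build_exposure()].
#' @return An `exposure_series`, identical to [build_exposure()] on the
#'   same inputs.
#' @export
exposure_from_counts <- function(counts, survey, scenario,
                                 root, years = sort(unique(survey$year)),
                                 delay = 4L) {
  src <- scenario_sources(survey, scenario, root, delay, years)
  sites <- dimnames(counts)[[3]]
  cyears <- dimnames(counts)[[2]]
  x <- matrix(0L, length(sites), length(years),
              dimnames = list(sites, years))
  cum <- numeric(length(sites))
  for (k in seq_along(years)) {
    yk <- as.character(years[k])
    s <- intersect(src[[k]], dimnames(counts)[[1]])
    if (length(s) && yk %in% cyears)
      cum <- cum + apply(counts[s, yk, , drop = FALSE], 3, sum)
    x[, k] <- as.integer(cum)
  }
  structure(list(x = x, scenario = scenario, dropped = rep(NA_integer_,
                                                           length(years)),
                 years = as.integer(years)),
            class = "exposure_series")
}

#' Construct an exposure series directly from a matrix
#'
#' Mostly useful in tests and for analytic fixtures.
#'
#' @param x matrix of cumulative counts, sites x years; rownames = site
#'   ids, colnames = years; must be non-decreasing along rows.
#' @param scenario scenario tag.
#' @return An `exposure_series`.
#' @export
exposure_series <- function(x, scenario = "custom") {
  x <- as.matrix(x)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("exposure matrix needs site rownames and year colnames")
  if (ncol(x) > 1 && any(x[, -1, drop = FALSE] - x[, -ncol(x), drop = FALSE] < 0))
    stop("cumulative exposure must be non-decreasing in time")
  if (any(x < 0)) stop("exposure counts must be >= 0")
  structure(list(x = x, scenario = scenario,
                 dropped = rep(0L, ncol(x)),
                 years = as.integer(colnames(x))),
            class = "exposure_series")
}
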
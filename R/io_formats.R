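#' @useDynLib windborne, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optim optimize uniroot rnorm rpois runif rgamma
#'   setNames pchisq qchisq sd quantile ks.test lm coef prcomp predict
#'   simulate logLik confint aggregate residuals
#' @importFrom graphics plot lines legend
#' @importFrom utils read.csv write.csv head
NULL

# ---------------------------------------------------------------------------
# Site registry
# ---------------------------------------------------------------------------

#' Construct a site registry
#'
#' A site registry holds one row per survey site: identifier, name,
#' geographic coordinates (decimal degrees, WGS84), elevation, the calendar
#' year the invader was first detected there (`NA` when never detected,
#' i.e. right-censored), and the range of years the site was surveyed.
#'
#' @param site_id character vector of short unique identifiers.
#' @param name site names.
#' @param lat,lon decimal degrees; `lat` in \[-90, 90\], `lon` in \[-180, 180\].
#' @param elevation meters above sea level.
#' @param detection_year calendar year of first detection, `NA` if never
#'   detected.
#' @param survey_start,survey_end first and last year of the annual survey.
#' @return A `data.frame` of class `site_registry`.
#' @export
site_registry <- function(site_id, name = site_id, lat, lon, elevation = NA_real_,
                          detection_year = NA_integer_,
                          survey_start, survey_end) {
  reg <- data.frame(
    site_id = as.character(site_id), name = as.character(name),
    lat = as.numeric(lat), lon = as.numeric(lon),
    elevation = as.numeric(elevation),
    detection_year = as.integer(detection_year),
    survey_start = as.integer(survey_start),
    survey_end = as.integer(survey_end),
    stringsAsFactors = FALSE
  )
  validate_site_registry(reg)
}

validate_site_registry <- function(reg) {
  if (anyDuplicated(reg$site_id))
    stop("duplicate site_id in registry: ",
         paste(unique(reg$site_id[duplicated(reg$site_id)]), collapse = ", "))
  if (any(!is.finite(reg$lat)) || any(reg$lat < -90 | reg$lat > 90))
    stop("latitude out of range [-90, 90]")
  if (any(!is.finite(reg$lon)) || any(reg$lon < -180 | reg$lon > 180))
    stop("longitude out of range [-180, 180]")
  det <- !is.na(reg$detection_year)
  bad <- det & (reg$detection_year < reg$survey_start - 1L |
                  reg$detection_year > reg$survey_end)
  if (any(bad))
    stop("detection_year outside surveyed range for site(s): ",
         paste(reg$site_id[bad], collapse = ", "))
  class(reg) <- c("site_registry", "data.frame")
  reg
}

#' Read a site registry from CSV
#'
#' Expected columns: `site_id,name,lat,lon,elevation,detection_year,`
#' `survey_start,survey_end`; an empty `detection_year` marks a site where
#' the invader was never detected (right-censored).
#'
#' @param path path to a CSV file with header.
#' @return A [site_registry()].
#' @export
read_sites <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", "name", "lat", "lon", "elevation", "detection_year",
            "survey_start", "survey_end")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("site CSV missing column(s): ", paste(miss, collapse = ", "))
  for (cl in c("lat", "lon")) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    if (any(is.na(v) & !is.na(df[[cl]]) & df[[cl]] != ""))
      stop("malformed ", cl, " at line ",
           which(is.na(v) & !is.na(df[[cl]]))[1] + 1L, " of ", path)
    df[[cl]] <- v
  }
  df$detection_year <- suppressWarnings(as.integer(df$detection_year))
  site_registry(df$site_id, df$name, df$lat, df$lon, df$elevation,
                df$detection_year, df$survey_start, df$survey_end)
}

#' Write a site registry to CSV
#' @param reg a [site_registry()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sites <- function(reg, path) {
  write.csv(as.data.frame(reg), path, row.names = FALSE, na = "")
  invisible(path)
}

# ---------------------------------------------------------------------------
# Survey table (interval-censored presence/absence observations)
# ---------------------------------------------------------------------------

#' Construct a survey table
#'
#' Long-format record of the annual surveys: one row per site x survey year
#' with a logical `detected` flag.  Detection is absorbing: once detected a
#' site stays detected.  The table is the response of the establishment
#' model; absence years preceding the first detection define the censoring
#' interval.
#'
#' @param site_id,year,detected parallel vectors.
#' @return A `data.frame` of class `survey_table`.
#' @export
survey_table <- function(site_id, year, detected) {
  df <- data.frame(site_id = as.character(site_id), year = as.integer(year),
                   detected = as.logical(detected), stringsAsFactors = FALSE)
  df <- df[order(df$site_id, df$year), ]
  rownames(df) <- NULL
  for (s in unique(df$site_id)) {
    d <- df$detected[df$site_id == s]
    if (any(d) && any(!d[seq(which(d)[1], length(d))]))
      stop("detection is absorbing but site ", s, " reverts to absence")
  }
  class(df) <- c("survey_table", "data.frame")
  df
}

#' First detection year per site
#'
#' @param survey a [survey_table()].
#' @return Named integer vector, `NA` for sites never detected.
#' @export
detection_years <- function(survey) {
  sites <- unique(survey$site_id)
  out <- setNames(rep(NA_integer_, length(sites)), sites)
  for (s in sites) {
    rows <- survey[survey$site_id == s & survey$detected, ]
    if (nrow(rows)) out[s] <- min(rows$year)
  }
  out
}

#' Read/write a survey table (CSV long format)
#' @param path CSV path with columns `site_id,year,detected`.
#' @return A [survey_table()].
#' @export
read_survey <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  survey_table(df$site_id, df$year, df$detected)
}

#' @rdname read_survey
#' @param survey a [survey_table()].
#' @export
write_survey <- function(survey, path) {
  write.csv(as.data.frame(survey), path, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Trajectory set
# ---------------------------------------------------------------------------

#' Construct a trajectory set
#'
#' Hourly endpoints of wind-dispersed particle trajectories.  One
#' trajectory is released per site per day (of May) per year and followed
#' for at most 15 hours; points carry the hour offset (0 = release point),
#' position and altitude.
#'
#' @param points data.frame with columns `site_id, year, day, hour, lat,
#'   lon, altitude` and optionally `member` (ensemble member, default 1);
#'   `day` is the day of May (1-31), `hour` the offset from release in
#'   0..15.
#' @return A `data.frame` of class `trajectory_set`.
#' @export
trajectory_set <- function(points) {
  if (is.null(points$member)) points$member <- 1L
  need <- c("site_id", "year", "day", "member", "hour", "lat", "lon",
            "altitude")
  miss <- setdiff(need, names(points))
  if (length(miss)) stop("trajectory points missing column(s): ",
                         paste(miss, collapse = ", "))
  pts <- points[, need]
  pts$site_id <- as.character(pts$site_id)
  for (cl in c("year", "day", "member", "hour"))
    pts[[cl]] <- as.integer(pts[[cl]])
  if (any(pts$hour < 0L | pts$hour > 15L))
    stop("hour offsets must lie in 0..15 (particles travel for at most 15 h)")
  key <- paste(pts$site_id, pts$year, pts$day, pts$member)
  ord <- order(key, pts$hour)
  pts <- pts[ord, ]
  key <- key[ord]
  if (any(stats::ave(pts$hour, key, FUN = function(h) any(duplicated(h))) > 0))
    stop("hour offsets must be strictly increasing within a trajectory")
  rownames(pts) <- NULL
  class(pts) <- c("trajectory_set", "data.frame")
  pts
}

#' Number of trajectories in a trajectory set
#' @param traj a [trajectory_set()].
#' @return Integer count of distinct (site, year, day, member) releases.
#' @export
n_trajectories <- function(traj) {
  length(unique(paste(traj$site_id, traj$year, traj$day, traj$member)))
}

#' Read trajectory endpoint files
#'
#' Parses the simplified fixed-column endpoint dialect written by
#' [write_trajectories()]: whitespace-separated columns
#' `site_id year day member hour lat lon altitude` (the `member` column
#' may be omitted, implying a single ensemble member), one endpoint per
#' line; lines starting with `#` are comments.  Records whose endpoints
#' exceed the 15-hour travel cap are rejected with a warning;
#' non-monotone hour offsets within a record are an error.
#'
#' @param path a file, or a directory whose `*.txt` files are concatenated.
#' @param sites optional [site_registry()]; unknown release sites error.
#' @return A [trajectory_set()].
#' @export
read_trajectories <- function(path, sites = NULL) {
  files <- if (dir.exists(path))
    list.files(path, pattern = "\\.txt$", full.names = TRUE) else path
  rows <- list()
  for (f in files) {
    ln <- readLines(f)
    ln <- ln[!grepl("^\\s*(#|$)", ln)]
    if (!length(ln)) next
    fields <- strsplit(trimws(ln), "\\s+")
    nf <- lengths(fields)
    if (any(!nf %in% c(7L, 8L)))
      stop("malformed endpoint line ", which(!nf %in% c(7L, 8L))[1],
           " in ", f)
    if (length(unique(nf)) > 1L)
      stop("mixed 7- and 8-column endpoint lines in ", f)
    m <- do.call(rbind, fields)
    has_member <- nf[1] == 8L
    o <- if (has_member) 1L else 0L
    rows[[f]] <- data.frame(
      site_id = m[, 1], year = as.integer(m[, 2]), day = as.integer(m[, 3]),
      member = if (has_member) as.integer(m[, 4]) else 1L,
      hour = as.integer(m[, 4L + o]), lat = as.numeric(m[, 5L + o]),
      lon = as.numeric(m[, 6L + o]), altitude = as.numeric(m[, 7L + o]),
      stringsAsFactors = FALSE)
  }
  pts <- do.call(rbind, rows)
  if (is.null(pts) || !nrow(pts)) stop("no trajectory endpoints found in ", path)
  if (!is.null(sites)) {
    unk <- setdiff(unique(pts$site_id), sites$site_id)
    if (length(unk)) stop("unknown release site(s): ", paste(unk, collapse = ", "))
  }
  # reject whole records violating the 15-hour cap, keep the rest
  key <- paste(pts$site_id, pts$year, pts$day, pts$member)
  over <- unique(key[pts$hour > 15L])
  if (length(over)) {
    warning(length(over), " trajectory record(s) exceed the 15-hour cap; rejected")
    pts <- pts[!(key %in% over), ]
  }
  trajectory_set(pts)
}

#' Write a trajectory set to the endpoint dialect
#' @param traj a [trajectory_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# site_id year day member hour lat lon altitude", con)
  writeLines(sprintf("%s %d %d %d %d %.6f %.6f %.2f", traj$site_id,
                     traj$year, traj$day, traj$member, traj$hour, traj$lat,
                     traj$lon, traj$altitude),
             con)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Wind table
# ---------------------------------------------------------------------------

wind_sectors <- c("N", "NE", "E", "SE", "S", "SW", "W", "NW")

#' Construct a daily station wind-run table
#'
#' One row per station x date x compass sector giving the daily distance
#' (km) travelled by wind *toward* that sector, as recorded by near-ground
#' weather stations.
#'
#' @param station_id,date,sector,wind_run_km parallel vectors; `sector`
#'   one of `N,NE,E,SE,S,SW,W,NW`; `date` coercible to `Date`.
#' @return A `data.frame` of class `wind_table`.
#' @export
wind_table <- function(station_id, date, sector, wind_run_km) {
  df <- data.frame(station_id = as.character(station_id),
                   date = as.Date(date), sector = as.character(sector),
                   wind_run_km = as.numeric(wind_run_km),
                   stringsAsFactors = FALSE)
  if (any(!df$sector %in% wind_sectors))
    stop("unknown wind sector(s): ",
         paste(setdiff(unique(df$sector), wind_sectors), collapse = ", "))
  if (any(df$wind_run_km < 0)) stop("wind_run_km must be >= 0")
  if (anyDuplicated(df[, c("station_id", "date", "sector")]))
    stop("duplicate station x date x sector rows in wind table")
  class(df) <- c("wind_table", "data.frame")
  df
}

#' Read/write a wind table (CSV)
#' @param path CSV with columns `station_id,date,sector,wind_run_km`.
#' @return A [wind_table()].
#' @export
read_wind_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  wind_table(df$station_id, df$date, df$sector, df$wind_run_km)
}

#' @rdname read_wind_table
#' @param wind a [wind_table()].
#' @export
write_wind_table <- function(wind, path) {
  df <- as.data.frame(wind)
  df$date <- format(df$date)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Genotype matrix
# ---------------------------------------------------------------------------

#' Construct a diploid microsatellite genotype matrix
#'
#' Alleles are integer repeat sizes; missing data are coded as the pair
#' (0, 0).  A half-missing pair is normalized to fully missing, matching
#' common practice in microsatellite frequency estimation.
#'
#' @param alleles integer matrix, one row per individual, `2 * n_loci`
#'   columns (the two allele columns of locus j are `2j-1` and `2j`).
#' @param pop population label per individual.
#' @param loci character vector of locus names.
#' @param ind optional individual identifiers.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `alleles`, `pop` (factor, levels in order of first appearance),
#'   `loci`, `ind`.
#' @export
genotype_matrix <- function(alleles, pop, loci = NULL, ind = NULL) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (ncol(alleles) %% 2L != 0L)
    stop("allele matrix must have an even number of columns (2 per locus)")
  nl <- ncol(alleles) %/% 2L
  if (is.null(loci)) loci <- paste0("L", seq_len(nl))
  if (length(loci) != nl) stop("length(loci) must equal ncol(alleles)/2")
  if (length(pop) != nrow(alleles)) stop("one population label per individual")
  if (any(alleles < 0L, na.rm = TRUE)) stop("allele sizes must be >= 0 (0 = missing)")
  alleles[is.na(alleles)] <- 0L
  # normalize half-missing pairs to fully missing
  for (j in seq_len(nl)) {
    a <- alleles[, 2L * j - 1L]; b <- alleles[, 2L * j]
    half <- xor(a == 0L, b == 0L)
    if (any(half)) alleles[half, c(2L * j - 1L, 2L * j)] <- 0L
  }
  if (is.null(ind)) ind <- paste0("ind", seq_len(nrow(alleles)))
  structure(list(alleles = alleles, pop = factor(pop, levels = unique(pop)),
                 loci = as.character(loci), ind = as.character(ind)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("Diploid microsatellite genotypes: ", nrow(x$alleles), " individuals, ",
      length(x$loci), " loci, ", nlevels(x$pop), " populations\n", sep = "")
  tab <- table(x$pop)
  cat("  individuals per population: ",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  miss <- mean(x$alleles[, seq(1, ncol(x$alleles), by = 2)] == 0L)
  cat(sprintf("  missing genotypes: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' Number of loci / individuals in a genotype matrix
#' @param g a [genotype_matrix()].
#' @return Integer.
#' @export
n_loci <- function(g) length(g$loci)

#' @rdname n_loci
#' @export
n_individuals <- function(g) nrow(g$alleles)

#' Allele pair columns of one locus
#' @param g a [genotype_matrix()].
#' @param j locus index.
#' @return Two-column integer matrix (0 = missing).
#' @keywords internal
locus_alleles <- function(g, j) g$alleles[, c(2L * j - 1L, 2L * j), drop = FALSE]

#' Read diploid microsatellite genotypes
#'
#' Two dialects are supported. `genepop`: the classic GENEPOP layout
#' (title line; one locus name per line, or comma-separated; `Pop`
#' separators; `ind ,  0102 0304 ...` rows with 2- or 3-digit allele
#' coding; `00`/`000` = missing).  `csv`: long format with columns
#' `pop,ind,locus,allele1,allele2`.
#'
#' @param path input file.
#' @param dialect `"genepop"` or `"csv"`.
#' @return A [genotype_matrix()]; populations ordered as encountered.
#' @export
read_genotypes <- function(path, dialect = c("genepop", "csv")) {
  dialect <- match.arg(dialect)
  if (dialect == "csv") {
    df <- read.csv(path, stringsAsFactors = FALSE)
    loci <- unique(df$locus)
    inds <- unique(paste(df$pop, df$ind, sep = "\r"))
    amat <- matrix(0L, length(inds), 2L * length(loci))
    idx_i <- match(paste(df$pop, df$ind, sep = "\r"), inds)
    idx_j <- match(df$locus, loci)
    amat[cbind(idx_i, 2L * idx_j - 1L)] <- as.integer(df$allele1)
    amat[cbind(idx_i, 2L * idx_j)] <- as.integer(df$allele2)
    sp <- strsplit(inds, "\r")
    return(genotype_matrix(amat, vapply(sp, `[`, "", 1L), loci,
                           vapply(sp, `[`, "", 2L)))
  }
  ln <- readLines(path)
  ln <- ln[trimws(ln) != ""]
  if (length(ln) < 3L) stop("not a GENEPOP file: ", path)
  body <- ln[-1L]
  pop_rows <- grepl("^\\s*pop\\s*$", body, ignore.case = TRUE)
  first_pop <- which(pop_rows)[1]
  if (is.na(first_pop)) stop("GENEPOP file has no Pop line")
  loci <- unlist(strsplit(body[seq_len(first_pop - 1L)], ","))
  loci <- trimws(loci)
  loci <- loci[loci != ""]
  pop_idx <- cumsum(pop_rows)
  rows <- which(!pop_rows & pop_idx >= 1L)
  pops <- character(0); inds <- character(0); geno <- list()
  for (r in rows) {
    parts <- strsplit(body[r], ",")[[1]]
    if (length(parts) < 2L) stop("malformed GENEPOP row: ", body[r])
    id <- trimws(parts[1])
    codes <- strsplit(trimws(paste(parts[-1], collapse = " ")), "\\s+")[[1]]
    if (length(codes) != length(loci))
      stop("GENEPOP row has ", length(codes), " genotypes, expected ",
           length(loci), ": ", id)
    w <- unique(nchar(codes))
    if (length(w) != 1L || !w %in% c(4L, 6L))
      stop("GENEPOP alleles must use uniform 2- or 3-digit coding (row ", id, ")")
    half <- w %/% 2L
    a1 <- as.integer(substr(codes, 1L, half))
    a2 <- as.integer(substr(codes, half + 1L, w))
    geno[[length(geno) + 1L]] <- as.integer(rbind(a1, a2))
    pops <- c(pops, paste0("pop", pop_idx[r]))
    inds <- c(inds, id)
  }
  amat <- do.call(rbind, geno)
  # use last individual id of each pop as its label when ids look like names
  genotype_matrix(amat, pops, loci, inds)
}

#' Write genotypes
#' @param g a [genotype_matrix()].
#' @param path output file.
#' @param dialect `"genepop"` or `"csv"`.
#' @param digits allele digits for GENEPOP coding (2 or 3).
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path, dialect = c("genepop", "csv"), digits = 3L) {
  dialect <- match.arg(dialect)
  if (dialect == "csv") {
    nl <- n_loci(g)
    df <- data.frame(
      pop = rep(as.character(g$pop), each = nl),
      ind = rep(g$ind, each = nl),
      locus = rep(g$loci, times = n_individuals(g)),
      allele1 = as.vector(t(g$alleles[, 2L * seq_len(nl) - 1L, drop = FALSE])),
      allele2 = as.vector(t(g$alleles[, 2L * seq_len(nl), drop = FALSE])),
      stringsAsFactors = FALSE)
    write.csv(df, path, row.names = FALSE)
    return(invisible(path))
  }
  if (any(g$alleles >= 10L^digits))
    stop("allele sizes too large for ", digits, "-digit GENEPOP coding")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("windborne genotype export", con)
  writeLines(g$loci, con)
  fmt <- paste0("%0", digits, "d%0", digits, "d")
  for (p in levels(g$pop)) {
    writeLines("Pop", con)
    for (i in which(g$pop == p)) {
      codes <- sprintf(fmt,
                       g$alleles[i, 2L * seq_len(n_loci(g)) - 1L],
                       g$alleles[i, 2L * seq_len(n_loci(g))])
      writeLines(paste0(g$ind[i], " ,  ", paste(codes, collapse = " ")), con)
    }
  }
  invisible(path)
}
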
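test_that("bearing classification uses half-open 45-degree sectors", {
  expect_equal(classify_bearing(350), "N")
  expect_equal(classify_bearing(0), "N")
  expect_equal(classify_bearing(90), "E")
  expect_equal(classify_bearing(22.5), "NE")    # half-open boundary
  expect_equal(classify_bearing(337.5), "N")
  expect_equal(classify_bearing(337.5 - 1e-9), "NW")
  expect_equal(classify_bearing(c(45, 135, 225, 315)),
               c("NE", "SE", "SW", "NW"))
})

test_that("threshold colonization years follow the cumulative series", {
  x <- c(`1996` = 150, `1997` = 230)
  expect_equal(colonization_year_from_threshold(x, 200), 1997L)
  expect_true(is.na(colonization_year_from_threshold(x, 800)))
  expect_equal(colonization_year_from_threshold(x, 0), 1996L)
  expect_error(colonization_year_from_threshold(c(`1996` = 5, `1997` = 3), 2),
               "non-decreasing")
})

test_that("nearest-neighbor sources pick the closest earlier-colonized site", {
  reg <- site_registry(c("Vx", "A", "B", "C"),
                       lat = c(44.0, 44.0, 44.0, 44.0),
                       lon = c(5.0, 5.25, 5.6, 5.9),  # ~20 km / ~48 km gaps
                       survey_start = 1994, survey_end = 2010)
  cy <- c(Vx = 1994L, A = 1996L, B = 1996L, C = 2000L)
  src <- assign_sources(reg, cy, "nearest_neighbor", root = "Vx")
  expect_true(is.na(src["Vx"]))
  expect_equal(unname(src["A"]), "Vx")
  expect_equal(unname(src["B"]), "Vx")    # only Vx is strictly earlier
  expect_equal(unname(src["C"]), "B")     # B at ~25 km beats A at ~54 km

  # single colonized site: every first-wave site sources from the root
  cy2 <- c(Vx = 1994L, A = 1999L, B = 1999L, C = 1999L)
  src2 <- assign_sources(reg, cy2, "nearest_neighbor", root = "Vx")
  expect_true(all(src2[c("A", "B", "C")] == "Vx"))

  # ties with no earlier site fall back to the root with a warning
  cy3 <- c(Vx = 1994L, A = 1995L, B = 1995L)
  expect_warning(src3 <- assign_sources(reg, cy3[1:3], "nearest_neighbor",
                                        root = "Vx"), NA)
  expect_error(assign_sources(reg, c(A = 1995L, B = 1996L), "nearest_neighbor",
                              root = "Vx"), "no colonization year")
})

test_that("local-wind sources equal a brute-force filter plus argmin", {
  reg <- site_registry(c("Vx", "A", "B", "C"),
                       lat = c(44.5, 44.2, 44.0, 43.8),
                       lon = c(5.0, 5.3, 5.6, 5.9),
                       survey_start = 1994, survey_end = 2010)
  stations <- data.frame(station_id = c("W1", "W2"),
                         lat = c(44.5, 44.0), lon = c(5.0, 5.6))
  # wind only toward NE anywhere: SE-ward candidates are pruned
  days <- as.Date("1999-05-01") + 0:30
  wind <- wind_table(rep(c("W1", "W2"), each = 8 * 31),
                     rep(rep(days, each = 8), 2),
                     rep(c("N", "NE", "E", "SE", "S", "SW", "W", "NW"), 62),
                     rep(c(0, 50, 0, 0, 0, 0, 0, 0), 62))
  cy <- c(Vx = 1994L, A = 1996L, B = 1998L, C = 2000L)
  src <- suppressWarnings(
    assign_sources(reg, cy, "local_wind", wind = wind, stations = stations,
                   root = "Vx"))
  # brute force: for each target, candidates colonized earlier whose
  # bearing sector toward the target had wind in May of year - 1
  brute <- function(target) {
    cand <- names(cy)[cy < cy[target]]
    ok <- sapply(cand, function(s) {
      i <- match(s, reg$site_id); j <- match(target, reg$site_id)
      sec <- classify_bearing(bearing_deg(reg$lat[i], reg$lon[i],
                                          reg$lat[j], reg$lon[j]))
      st <- stations$station_id[which.min((stations$lat - reg$lat[i])^2 +
                                            (stations$lon - reg$lon[i])^2)]
      yr <- format(wind$date, "%Y") == as.character(cy[target] - 1)
      any(wind$wind_run_km[wind$station_id == st & yr & wind$sector == sec] > 0)
    })
    if (any(ok)) cand <- cand[ok]
    dm <- site_distances(reg)
    cand[which.min(dm[target, cand])]
  }
  for (s in c("A", "B", "C"))
    expect_equal(unname(src[s]), brute(s))
})

test_that("scenario specs validate founding order and rootedness", {
  d <- data.frame(site_id = c("Vx", "A", "B"),
                  founding_gen = c(NA, 10L, 5L),
                  source = c(NA, "Vx", "A"),
                  ne_class = c("early", "early", "mid"),
                  stringsAsFactors = FALSE)
  sp <- scenario_spec(1, d, 2010, root = "Vx")
  expect_s3_class(sp, "scenario_spec")
  # child founded no later than its source is rejected
  d2 <- d; d2$founding_gen[3] <- 10L
  expect_error(scenario_spec(1, d2, 2010, root = "Vx"), "no later")
  # two roots rejected
  d3 <- d; d3$source[3] <- NA
  expect_error(scenario_spec(1, d3, 2010, root = "Vx"), "exactly one root")
  # unknown source rejected
  d4 <- d; d4$source[3] <- "Z"
  expect_error(scenario_spec(1, d4, 2010, root = "Vx"), "unknown source")
})

test_that("scenario specs serialize to JSON and back", {
  specs <- make_four_scenarios()
  path <- withr::local_tempfile(fileext = ".json")
  write_scenarios(specs, path)
  back <- read_scenarios(path)
  expect_length(back, 4)
  for (k in 1:4) {
    expect_equal(back[[k]]$scenario_id, specs[[k]]$scenario_id)
    expect_equal(back[[k]]$demes$founding_gen, specs[[k]]$demes$founding_gen)
    expect_equal(back[[k]]$demes$source, specs[[k]]$demes$source)
  }
})

test_that("build_all_scenarios yields four rooted DAGs with era-based priors", {
  cfg <- synth_config(seed = 42)
  reg <- generate_sites(cfg)
  tr <- generate_trajectories(cfg, reg, c(Vx = 1994))
  grid <- grid_spec(reg)
  blank <- survey_table(rep(reg$site_id, each = 17),
                        rep(1994:2010, nrow(reg)), FALSE)
  ex_v <- build_exposure(tr, grid, reg, blank, "ventoux_only", root = "Vx",
                         years = 1994:2010)
  sv <- simulate_survey(ex_v, cfg$beta0, cfg$beta1, 1994:2010, seed = 43)
  sv$detected[sv$site_id == "Vx"] <- TRUE
  sv <- survey_table(sv$site_id, sv$year, sv$detected)
  det <- detection_years(sv)
  tr_all <- generate_trajectories(cfg, reg, as.list(det[!is.na(det)]))
  ex_a <- build_exposure(tr_all, grid, reg, sv, "all_sites", root = "Vx",
                         years = 1994:2010)
  stations <- data.frame(station_id = c("W1", "W2"),
                         lat = c(44.5, 44.0), lon = c(5.0, 7.0))
  wind <- generate_wind_table(cfg, stations$station_id)
  scen <- suppressWarnings(
    build_all_scenarios(sv, ex_v, ex_a, wind, stations, reg, root = "Vx"))
  expect_named(scen, paste0("scenario", 1:4))
  for (sp in scen) {
    expect_s3_class(sp, "scenario_spec")   # constructor enforces DAG + root
    non_root <- sp$demes[!is.na(sp$demes$source), ]
    src_gen <- sp$demes$founding_gen[match(non_root$source, sp$demes$site_id)]
    ok <- is.na(src_gen) | non_root$founding_gen < src_gen
    expect_true(all(ok))
    expect_true(all(non_root$founding_gen >= 1))
    expect_true(all(non_root$founding_gen <= 11))   # strictly before t1 >= 12
  }
  # scenario 1 is a star: the root is the only source
  expect_true(all(scen$scenario1$demes$source[-1] == "Vx"))
  # era-based Ne prior classes
  d1 <- scen$scenario1$demes
  era <- ifelse(det[d1$site_id] <= 2001, "early",
                ifelse(det[d1$site_id] <= 2006, "mid", "late"))
  expect_equal(d1$ne_class, unname(era))
})

test_that("detection-era prior classes map to the documented bounds", {
  # a site detected in 2005 belongs to the mid class U(10, 5000)
  d <- data.frame(site_id = c("Vx", "A"), founding_gen = c(NA, 5L),
                  source = c(NA, "Vx"), ne_class = c("early", "mid"),
                  stringsAsFactors = FALSE)
  sp <- scenario_spec(1, d, 2010, root = "Vx")
  set.seed(1)
  draws <- replicate(200, parameter_draw(sp)$ne["A"])
  expect_true(all(draws >= 10 & draws <= 5000))
  expect_gt(max(draws), 1000)   # actually spans the mid range
})
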
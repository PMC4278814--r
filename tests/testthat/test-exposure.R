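test_that("grid cell assignment uses half-open 10 km cells", {
  reg <- make_registry(4)
  grid <- grid_spec(reg, cell_km = 10)
  # a point exactly on a cell edge belongs to the higher cell
  lat0 <- grid$origin_geo[1]
  on_edge <- lat0 + (grid$y0 + 10) / 111.32
  below <- lat0 + (grid$y0 + 10 - 1e-6) / 111.32
  ce <- grid_cell(grid, c(on_edge, below), rep(grid$origin_geo[2] + 0.2, 2))
  expect_equal(ce$row[1], ce$row[2] + 1L)
})

test_that("count_points conserves endpoints: raster sum + dropped = total", {
  reg <- make_registry(4)
  grid <- grid_spec(reg, pad_km = 30)
  set.seed(8)
  rows <- do.call(rbind, lapply(1:100, function(k)
    data.frame(site_id = "Vx", year = 2000L, day = ((k - 1) %% 31) + 1L,
               hour = if (k <= 50) 1:15 else 0:14,
               lat = runif(15, 42, 46), lon = runif(15, 3, 10),
               altitude = 50)))
  # 100 records of 15 endpoints each (two hour conventions so day ids clash
  # are avoided by year split)
  rows$year <- rep(c(2000L, 2001L), each = 50 * 15)[seq_len(nrow(rows))]
  rows$day <- rep(rep(1:50, each = 15), length.out = nrow(rows)) %% 31 + 1
  rows <- rows[!duplicated(rows[, c("site_id", "year", "day", "hour")]), ]
  tr <- trajectory_set(rows)
  total <- 0
  for (y in unique(tr$year)) {
    m <- count_points(tr, grid, y, "Vx")
    total <- total + sum(m) + attr(m, "dropped")
  }
  expect_equal(total, nrow(tr))

  # single trajectory entirely inside one cell
  one <- trajectory_set(data.frame(site_id = "Vx", year = 1999L, day = 1L,
                                   hour = 1:15, lat = reg$lat[1],
                                   lon = reg$lon[1], altitude = 50))
  m <- count_points(one, grid, 1999L, "Vx")
  expect_equal(sum(m), 15L)
  expect_equal(max(m), 15L)
  expect_equal(attr(m, "dropped"), 0L)
})

test_that("scenario source sets follow detection years", {
  sv <- survey_table(rep(c("Vx", "A", "B"), each = 5),
                     rep(1994:1998, 3),
                     c(TRUE, TRUE, TRUE, TRUE, TRUE,
                       FALSE, FALSE, TRUE, TRUE, TRUE,
                       FALSE, FALSE, FALSE, FALSE, FALSE))
  src <- scenario_sources(sv, "ventoux_only", root = "Vx")
  expect_true(all(lengths(src) == 1L))
  expect_true(all(unlist(src) == "Vx"))

  src2 <- scenario_sources(sv, "all_sites", root = "Vx")
  expect_equal(src2[["1994"]], "Vx")
  expect_setequal(src2[["1996"]], c("Vx", "A"))

  src3 <- scenario_sources(sv, "all_sites_delay4", root = "Vx", delay = 4L)
  expect_length(src3[["1997"]], 0)                   # 1994 + 4 = 1998
  expect_setequal(src3[["1998"]], "Vx")
  sv2 <- survey_table(rep(c("Vx", "A"), each = 11), rep(2000:2010, 2),
                      c(rep(TRUE, 11), rep(FALSE, 3), rep(TRUE, 8)))
  src4 <- scenario_sources(sv2, "all_sites_delay4", root = "Vx", delay = 4L)
  expect_false("A" %in% src4[["2006"]])
  expect_true("A" %in% src4[["2007"]])               # detected 2003 + 4

  expect_error(scenario_sources(sv, "bogus", root = "Vx"), "unknown scenario")
})

test_that("cumulative exposure is a running sum and respects nesting", {
  reg <- make_registry(6)
  cfg <- synth_config(n_sites = 6, years = 1994:1999, seed = 13)
  tr <- generate_trajectories(cfg, reg,
                              setNames(c(1994, 1995, 1996), reg$site_id[1:3]))
  grid <- grid_spec(reg)
  sv <- survey_table(rep(reg$site_id, each = 6), rep(1994:1999, 6),
                     rep(c(TRUE, FALSE), c(6, 30)))
  sv$detected[sv$site_id == "S01" & sv$year >= 1995] <- TRUE
  sv$detected[sv$site_id == "S02" & sv$year >= 1996] <- TRUE
  sv <- survey_table(sv$site_id, sv$year, sv$detected)

  ex_v <- build_exposure(tr, grid, reg, sv, "ventoux_only", root = "Vx")
  ex_a <- build_exposure(tr, grid, reg, sv, "all_sites", root = "Vx")
  ex_d <- build_exposure(tr, grid, reg, sv, "all_sites_delay4", root = "Vx")

  # non-decreasing in time
  expect_true(all(apply(ex_a$x, 1, function(v) all(diff(v) >= 0))))
  # monotone nesting, cell-wise, every year
  expect_true(all(ex_v$x <= ex_a$x))
  expect_true(all(ex_d$x <= ex_a$x))

  # running-sum identity against per-year counts
  cells <- grid_cell(grid, reg$lat, reg$lon)
  yearly <- sapply(1994:1999, function(y) {
    m <- count_points(tr, grid, y, scenario_sources(sv, "all_sites", "Vx")[[as.character(y)]])
    m[cbind(cells$row, cells$col)]
  })
  expect_equal(unname(ex_a$x), t(apply(yearly, 1, cumsum)),
               ignore_attr = TRUE)

  # zero trajectories -> all-zero series
  ex0 <- build_exposure(tr, grid, reg, sv, "ventoux_only", root = "S05",
                        years = 1994:1999)
  expect_true(all(ex0$x == 0))
})

test_that("grid translation by whole cells leaves per-site counts unchanged", {
  reg <- make_registry(4)
  grid <- grid_spec(reg)
  set.seed(14)
  pts <- data.frame(site_id = "Vx", year = 2000L, day = 1L, hour = 0:15,
                    lat = runif(16, min(reg$lat), max(reg$lat)),
                    lon = runif(16, min(reg$lon), max(reg$lon)),
                    altitude = 50)
  tr <- trajectory_set(pts)
  cells <- grid_cell(grid, reg$lat, reg$lon)
  m1 <- count_points(tr, grid, 2000L, "Vx")
  v1 <- m1[cbind(cells$row, cells$col)]
  grid2 <- grid
  grid2$x0 <- grid$x0 - 3 * grid$cell_km
  grid2$y0 <- grid$y0 - 2 * grid$cell_km
  grid2$n_cols <- grid$n_cols + 3L
  grid2$n_rows <- grid$n_rows + 2L
  cells2 <- grid_cell(grid2, reg$lat, reg$lon)
  m2 <- count_points(tr, grid2, 2000L, "Vx")
  v2 <- m2[cbind(cells2$row, cells2$col)]
  expect_equal(v1, v2)
})

test_that("exposure_from_counts matches build_exposure", {
  reg <- make_registry(5)
  cfg <- synth_config(n_sites = 5, years = 1994:1998, seed = 17)
  tr <- generate_trajectories(cfg, reg,
                              setNames(c(1994, 1995), reg$site_id[1:2]))
  grid <- grid_spec(reg)
  sv <- survey_table(rep(reg$site_id, each = 5), rep(1994:1998, 5), FALSE)
  sv$detected[sv$site_id == "Vx"] <- TRUE
  sv$detected[sv$site_id == "S01" & sv$year >= 1995] <- TRUE
  sv <- survey_table(sv$site_id, sv$year, sv$detected)
  counts <- site_point_counts(tr, grid, reg)
  for (sc in c("ventoux_only", "all_sites", "all_sites_delay4")) {
    a <- build_exposure(tr, grid, reg, sv, sc, root = "Vx")
    b <- exposure_from_counts(counts, sv, sc, root = "Vx")
    expect_equal(a$x, b$x)
  }
})

test_that("sites outside the grid are rejected", {
  reg <- make_registry(4)
  grid <- grid_spec(reg, pad_km = 10)
  far <- reg
  far$lat[4] <- 50
  sv <- survey_table(rep(far$site_id, each = 2), rep(1994:1995, 4), FALSE)
  tr <- trajectory_set(data.frame(site_id = "Vx", year = 1994L, day = 1L,
                                  hour = 0:15, lat = reg$lat[1],
                                  lon = reg$lon[1], altitude = 50))
  expect_error(build_exposure(tr, grid, far, sv, "ventoux_only", root = "Vx"),
               "outside the grid")
})
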
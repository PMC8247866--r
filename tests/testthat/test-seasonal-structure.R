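# build a projected season with a stopover residence and a winter residence
# at known sites and dwell windows (12-h fixes)
build_two_site_season <- function(stop_days = 90, win_days = 150) {
  proj <- laea_projection(4, 52)
  t0 <- utc("2020-08-01 00:00:00")
  mk <- function(lon, lat, n, start_h) {
    set.seed(start_h)
    ll <- cbind(lon + rnorm(n, 0, 0.02), lat + rnorm(n, 0, 0.02))
    data.frame(individual_id = "t1", lon = ll[, 1], lat = ll[, 2],
               timestamp = t0 + 3600 * (start_h + 12 * (seq_len(n) - 1)),
               stringsAsFactors = FALSE)
  }
  n_stop <- stop_days * 2
  stopover <- mk(4, 47, n_stop, 0)
  winter_start <- n_stop * 12 + 48
  # 12-h travel fixes bridging the two residences (no transition data hole)
  travel <- data.frame(individual_id = "t1",
                       lon = 4, lat = c(45.8, 44.5, 43.2),
                       timestamp = t0 + 3600 * (n_stop * 12 - 12 + 12 * (1:3)),
                       stringsAsFactors = FALSE)
  winter <- mk(4, 42, win_days * 2, winter_start)
  fx <- rbind(stopover, travel, winter)
  fx <- project_tracks(fx, proj)
  season <- structure(list(individual_id = "t1", label = "2020-21",
                           colony = c(4, 52),
                           colony_departure = fx$timestamp[1],
                           colony_arrival = fx$timestamp[nrow(fx)],
                           fixes = fx), class = "season_window")
  list(season = season, proj = proj)
}

test_that("core-area extraction separates stopover and winter residences", {
  b <- build_two_site_season()
  fx <- b$season$fixes
  ud <- kde_ud(fx, cell = 10000, h = 100000, proj = b$proj)
  cores <- extract_core_areas(ud, fx)
  expect_equal(length(cores), 2L)
  dw <- vapply(cores, function(a) a$dwell_days, numeric(1))
  expect_equal(sum(dw), nrow(fx) * 0.5, tolerance = 2)  # nearly all fixes inside
  lats <- vapply(cores, function(a) a$centroid_lonlat["lat"], numeric(1))
  expect_equal(sort(round(lats)), c(42, 47), tolerance = 0.5)
})

test_that("winter assignment uses December-March dwell, not total dwell", {
  # stopover dwell (Aug-Dec, 150 days) exceeds winter dwell (80 days) but
  # the winter site holds almost all December-March time
  b <- build_two_site_season(stop_days = 150, win_days = 80)
  fx <- b$season$fixes
  ud <- kde_ud(fx, cell = 10000, h = 100000, proj = b$proj)
  cores <- extract_core_areas(ud, fx)
  cores <- assign_winter(cores, colony = c(4, 52))
  w <- cores[[attr(cores, "winter")]]
  expect_equal(unname(round(w$centroid_lonlat["lat"])), 42)
  expect_equal(w$role, "winter")
  others <- vapply(cores, function(a) a$role, character(1))
  expect_equal(sort(others), c("stopover", "winter"))
  # single core area: it is the winter area
  fx_w <- fx[fx$lat < 45, ]
  ud2 <- kde_ud(fx_w, cell = 10000, h = 100000, proj = b$proj)
  c2 <- extract_core_areas(ud2, fx_w)
  expect_equal(attr(assign_winter(c2, c(4, 52)), "winter"), 1L)
})

test_that("an exact December-March dwell tie goes to the farther core area", {
  near <- structure(list(member_idx = 1:2, centroid_xy = c(x = 0, y = 0),
                         centroid_lonlat = c(lon = 4, lat = 50),
                         dwell_days = 10, dwell_winter_days = 10,
                         role = NA_character_), class = "core_area")
  far <- structure(list(member_idx = 3:4, centroid_xy = c(x = 0, y = -1e6),
                        centroid_lonlat = c(lon = 4, lat = 40),
                        dwell_days = 10, dwell_winter_days = 10,
                        role = NA_character_), class = "core_area")
  out <- assign_winter(list(near, far), colony = c(4, 52))
  expect_equal(attr(out, "winter"), 2L)
  expect_error(assign_winter(list(), c(4, 52)))
  nowin <- near; nowin$dwell_winter_days <- 0
  expect_error(assign_winter(list(nowin), c(4, 52)), "no winter residence")
})

test_that("fragmented winter polygons are grouped across years, idempotently", {
  g <- grid_spec(0, 1e5, 0, 1e5, cell = 10000)  # 10 x 10
  z <- matrix(1 / 100, 10, 10)
  mk_year <- function(cores_cells, winter_k) {
    ud <- migvar:::new_grid_ud(g, z, "fixed-kernel")
    cores <- lapply(seq_along(cores_cells), function(k) {
      structure(list(member_idx = cores_cells[[k]],
                     centroid_xy = migvar:::cells_centroid(ud, cores_cells[[k]]),
                     centroid_lonlat = c(lon = NA, lat = NA),
                     dwell_days = 10, dwell_winter_days = 10,
                     role = if (k == winter_k) "winter" else "stopover"),
                class = "core_area")
    })
    list(ud = ud, cores = cores, winter = winter_k)
  }
  # year A: one wide winter strip (cells 11..14 = column 2, rows 1:4)
  yA <- mk_year(list(c(11L, 12L, 13L, 14L)), 1L)
  # year B: two fragments, each overlapping A's strip
  yB <- mk_year(list(c(11L), c(13L, 14L)), 1L)
  merged <- merge_fragmented_winters(list(A = yA, B = yB))
  expect_equal(length(merged$B$cores), 1L)
  expect_equal(sort(merged$B$cores[[1]]$member_idx), c(11L, 13L, 14L))
  expect_equal(merged$B$cores[[merged$B$winter]]$role, "winter")
  # idempotence
  again <- merge_fragmented_winters(merged)
  expect_equal(again$B$cores[[1]]$member_idx, merged$B$cores[[1]]$member_idx)
  # non-overlapping years are untouched
  yC <- mk_year(list(c(91L), c(99L, 100L)), 1L)
  un <- merge_fragmented_winters(list(A = yA, C = yC))
  expect_equal(length(un$C$cores), 2L)
})

test_that("phenology flags traits whose transition is spanned by a gap", {
  b <- build_two_site_season()
  fx <- b$season$fixes
  ud <- kde_ud(fx, cell = 10000, h = 100000, proj = b$proj)
  cores <- assign_winter(extract_core_areas(ud, fx), c(4, 52))
  wa <- cores[[attr(cores, "winter")]]
  rec <- phenology(b$season, wa, migvar:::ud_grid(ud))
  expect_s3_class(rec, "season_record")
  expect_equal(rec$n_flagged, 0L)
  expect_true(rec$colony_departure <= rec$winter_arrival)
  expect_true(rec$winter_arrival <= rec$winter_departure)

  # remove 3 days of fixes around the winter entry: winter_arrival flagged,
  # the other traits survive
  entry <- attr(rec, "timestamps")$winter_arrival
  cut <- b$season
  cut$fixes <- fx[fx$timestamp < entry - 86400 | fx$timestamp > entry + 2 * 86400, ]
  rec2 <- phenology(cut, wa, migvar:::ud_grid(ud))
  expect_true(is.na(rec2$winter_arrival))
  expect_false(is.na(rec2$winter_departure))
  expect_false(is.na(rec2$colony_arrival))
  # a season that never touches the polygon is an error
  off <- b$season
  off$fixes <- fx[fx$lat > 45, ]
  expect_error(phenology(off, wa, migvar:::ud_grid(ud)), "no fix inside")
})

test_that("migration distance is colony-to-centroid great-circle, zero at the colony", {
  at_colony <- structure(list(member_idx = 1L, centroid_xy = c(x = 0, y = 0),
                              centroid_lonlat = c(lon = 4, lat = 52),
                              dwell_days = 1, dwell_winter_days = 1,
                              role = "winter"), class = "core_area")
  expect_equal(unname(migration_distance(c(4, 52), at_colony)), 0)
  away <- at_colony
  away$centroid_lonlat <- c(lon = 4, lat = 42)
  expect_equal(unname(migration_distance(c(4, 52), away)),
               great_circle_km(4, 52, 4, 42))
})

test_that("strategy switches are any-pair winter-polygon disjointness", {
  expect_false(detect_strategy_switch(list(1:5, 3:8)))
  expect_true(detect_strategy_switch(list(1:5, 10:12)))
  # years 1 and 3 overlap but year 2 is disjoint: still a switch
  expect_true(detect_strategy_switch(list(1:5, 10:12, 4:6)))
  expect_false(detect_strategy_switch(list(1:5)))
})

test_that("season records keep the date ordering invariant on synthetic data", {
  pop <- small_population()
  cfg <- pop$config
  res <- run_pipeline(pop$fixes, cfg$colonies,
                      run_config(do_fidelity = FALSE, do_routes = FALSE,
                                 do_stats = FALSE))
  rec <- res$season_records
  expect_gt(nrow(rec), 0)
  expect_true(all(rec$colony_departure <= rec$winter_arrival, na.rm = TRUE))
  expect_true(all(rec$winter_arrival <= rec$winter_departure, na.rm = TRUE))
  expect_true(all(rec$winter_departure <= rec$colony_arrival, na.rm = TRUE))
  expect_true(all(rec$migration_distance_km >= 0))
})
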
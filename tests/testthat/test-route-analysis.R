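straight_leg <- function(y_off_m, n = 100, len_m = 5e5) {
  cbind(seq(0, len_m, length.out = n), rep(y_off_m, n))
}

test_that("identical legs give a zero-variation mean route on the leg", {
  leg <- straight_leg(0)
  mr <- mean_route(list(leg, leg), n_points = 100)
  expect_equal(mr$route_variation_km, 0, tolerance = 1e-9)
  expect_equal(mr$objective, 0, tolerance = 1e-12)
  expect_equal(max(abs(mr$points[, 2])), 0, tolerance = 1e-9)
  expect_error(mean_route(list(leg)), "at least 2 legs")
})

test_that("parallel legs offset +/- d give the midline and variation d", {
  d_km <- 40
  legs <- list(straight_leg(d_km * 1000), straight_leg(-d_km * 1000))
  mr <- mean_route(legs, n_points = 200)
  expect_equal(max(abs(mr$points[, 2])), 0, tolerance = d_km * 0.01)
  expect_equal(mr$route_variation_km, d_km, tolerance = d_km * 0.01)
  expect_equal(unname(mr$per_point_variance[100]), d_km^2, tolerance = 1)
  # standalone metric agrees
  rv <- route_variation(mr, legs)
  expect_equal(rv$variation_km, mr$route_variation_km)
  expect_equal(rv$variation_km2, mr$route_variation_km2)
})

test_that("the reported objective matches an independent brute-force evaluation", {
  set.seed(17)
  bend <- function(jit) {
    x <- seq(0, 6e5, length.out = 60)
    cbind(x, 8e4 * sin(x / 6e5 * pi) + jit * 1000 + rnorm(60, 0, 2000))
  }
  legs <- list(bend(15), bend(-15), bend(5))
  mr <- mean_route(legs, n_points = 120)
  oracle <- brute_force_route_objective(mr$points, lapply(legs, function(l) l / 1000))
  expect_equal(mr$objective, oracle, tolerance = 1e-9)
  expect_equal(mr$route_variation_km2, oracle, tolerance = 1e-9)
})

test_that("route metric is homogeneous of degree 1 and rigid-motion invariant", {
  set.seed(23)
  l1 <- straight_leg(2e4, n = 50) + rnorm(100, 0, 3000)
  l2 <- straight_leg(-2e4, n = 50) + rnorm(100, 0, 3000)
  base <- mean_route(list(l1, l2), n_points = 80)
  # scaling doubles the metric
  sc <- mean_route(list(l1 * 2, l2 * 2), n_points = 80)
  expect_equal(sc$route_variation_km, 2 * base$route_variation_km,
               tolerance = 1e-6)
  # rotation + translation leave it unchanged
  th <- 0.7
  Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  mv <- function(l) sweep(l %*% Rm, 2, c(3e5, -2e5), "+")
  rot <- mean_route(list(mv(l1), mv(l2)), n_points = 80)
  expect_equal(rot$route_variation_km, base$route_variation_km,
               tolerance = 1e-6)
})

test_that("between-individual route variation is symmetric and reflects corridor separation", {
  la <- straight_leg(5e4)
  lb <- straight_leg(-5e4)
  ab <- between_individual_route_variation(la, lb, n_points = 100)
  ba <- between_individual_route_variation(lb, la, n_points = 100)
  expect_equal(ab$route_variation_km, ba$route_variation_km, tolerance = 1e-9)
  # half the corridor separation on each side: metric = 50 km
  expect_equal(ab$route_variation_km, 50, tolerance = 0.5)
  same <- between_individual_route_variation(la, la, n_points = 100)
  expect_equal(same$route_variation_km, 0, tolerance = 1e-9)
})

test_that("leg extraction collapses stopovers to centroids and applies the 24-h gap rule", {
  pop <- small_population()
  cfg <- pop$config
  proj <- laea_projection(mean(cfg$colonies$lon), mean(cfg$colonies$lat))
  fixes <- project_tracks(pop$fixes, proj)
  it <- pop$truth$individuals
  # pick an individual with a stopover
  id <- it$individual_id[it$has_stopover][1]
  fx <- fixes[fixes$individual_id == id, ]
  attr(fx, "proj") <- proj
  colony <- c(it$colony_lon[it$individual_id == id],
              it$colony_lat[it$individual_id == id])
  seas <- apply_inclusion_filters(split_seasons(fx, colony))
  ana <- analyze_individual(seas, colony, proj = proj)
  yr <- ana$years[[1]]
  lg <- extract_legs(yr$season, yr$record, yr$cores, migvar:::ud_grid(yr$ud))
  expect_s3_class(lg$autumn, "migration_leg")
  expect_s3_class(lg$spring, "migration_leg")
  # exactly one inserted centroid on the autumn leg (the stopover), none of
  # the retained points inside a stopover polygon (the leg's last point may
  # sit on the wintering-area boundary by construction)
  expect_equal(sum(lg$autumn$centroid_point), 1L)
  pts <- lg$autumn$points[!lg$autumn$centroid_point, , drop = FALSE]
  cell_of <- migvar:::point_cell_index(pts[, 1], pts[, 2], migvar:::ud_grid(yr$ud))
  stop_core <- unlist(lapply(yr$cores[vapply(yr$cores, function(a)
    identical(a$role, "stopover"), logical(1))], function(a) a$member_idx))
  expect_false(any(cell_of %in% stop_core, na.rm = TRUE))
  # the stopover centroid sits between its temporal neighbours
  k <- which(lg$autumn$centroid_point)
  expect_gt(k, 1L); expect_lt(k, nrow(lg$autumn$points))

})

test_that("a 30-h hole during migratory flight drops that leg only", {
  # one long-distance direct migrant with a slow, many-hour outbound flight,
  # so the hole falls between fixes that are both outside any core area
  cfg <- population_config(n_individuals = 1, years_per_individual = c(2, 2),
                           migration_distance_range_km = c(3500, 3500),
                           speed_range_kmh = c(30, 35), p_stopover = 0,
                           seed = 3)
  gen <- generate_population(cfg)
  proj <- laea_projection(mean(cfg$colonies$lon), mean(cfg$colonies$lat))
  fx <- project_tracks(gen$fixes, proj)
  it <- gen$truth$individuals
  colony <- c(it$colony_lon[1], it$colony_lat[1])
  seas <- apply_inclusion_filters(split_seasons(fx, colony))
  ana <- analyze_individual(seas, colony, proj = proj)
  yr <- ana$years[[1]]
  lg_ok <- extract_legs(yr$season, yr$record, yr$cores, migvar:::ud_grid(yr$ud))
  expect_s3_class(lg_ok$autumn, "migration_leg")

  ts <- attr(yr$record, "timestamps")
  mid_flight <- ts$colony_departure + 2 * 3600
  cut <- yr$season
  cut$fixes <- cut$fixes[cut$fixes$timestamp <= mid_flight |
                           cut$fixes$timestamp > mid_flight + 30 * 3600, ]
  lg2 <- extract_legs(cut, yr$record, yr$cores, migvar:::ud_grid(yr$ud))
  expect_null(lg2$autumn)
  expect_true(any(grepl("gap outside core areas", attr(lg2, "dropped"))))
  expect_s3_class(lg2$spring, "migration_leg")
})

test_that("two stopovers insert two centroid points in temporal order", {
  # hand-built season: colony -> core A -> core B -> winter, on a simple grid
  g <- grid_spec(0, 4e5, 0, 1e5, cell = 10000)
  proj <- laea_projection(4, 52)
  xs <- c(seq(0, 9e4, by = 1e4),            # flight
          rep(1.05e5, 8),                   # core A visit
          seq(1.2e5, 1.9e5, by = 1e4),      # flight
          rep(2.05e5, 8),                   # core B visit
          seq(2.2e5, 3.9e5, by = 1e4))      # flight to winter
  fx <- planar_fixes(xs, rep(5e4, length(xs)))
  fx$individual_id <- "h1"
  season <- structure(list(individual_id = "h1", label = "2020-21",
                           colony = c(4, 52),
                           colony_departure = fx$timestamp[1],
                           colony_arrival = fx$timestamp[nrow(fx)],
                           fixes = fx), class = "season_window")
  core_at <- function(x0) {
    idx <- migvar:::point_cell_index(x0, 5e4, g)
    structure(list(member_idx = idx, centroid_xy = c(x = x0, y = 5e4),
                   centroid_lonlat = c(lon = NA, lat = NA),
                   dwell_days = 4, dwell_winter_days = 0,
                   role = "stopover"), class = "core_area")
  }
  cores <- list(core_at(1.05e5), core_at(2.05e5))
  rec <- data.frame(individual_id = "h1", season = "2020-21")
  attr(rec, "timestamps") <- list(colony_departure = fx$timestamp[1],
                                  winter_arrival = fx$timestamp[nrow(fx)],
                                  winter_departure = NULL,
                                  colony_arrival = NULL)
  lg <- extract_legs(season, rec, cores, g)
  cent <- which(lg$autumn$centroid_point)
  expect_equal(length(cent), 2L)
  expect_equal(lg$autumn$points[cent, 1], c(1.05e5, 2.05e5))
})
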
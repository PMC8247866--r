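test_that("configuration validation rejects inconsistent settings", {
  expect_error(population_config(sigma_among_days = -1), "non-negative")
  expect_error(population_config(fix_interval_h = 0), "positive")
  expect_error(population_config(
    timing_mu_days = c(colony_departure = 200, winter_arrival = 101,
                       winter_departure = 262, colony_arrival = 272)),
    "overlap inconsistently")
  expect_error(population_config(n_individuals = 0), "at least one individual")
  cfg <- population_config()
  expect_s3_class(cfg, "population_config")
  expect_equal(true_repeatability(population_config(sigma_among_days = 3,
                                                    sigma_within_days = 1)),
               0.9)
  expect_equal(true_repeatability(population_config(sigma_among_days = 3,
                                                    sigma_within_days = 3)),
               0.5)
})

test_that("identical seeds give byte-identical tracks; truth is ordered and bounded", {
  cfg <- population_config(n_individuals = 3, years_per_individual = c(2, 2),
                           fix_interval_h = 6, seed = 99)
  g1 <- generate_population(cfg)
  g2 <- generate_population(cfg)
  expect_identical(g1$fixes, g2$fixes)
  expect_identical(g1$truth$individuals, g2$truth$individuals)
  # timestamps strictly increasing, no duplicates, per individual
  for (id in unique(g1$fixes$individual_id))
    expect_true(all(diff(as.numeric(
      g1$fixes$timestamp[g1$fixes$individual_id == id])) > 0))
  # realized season dates respect the cycle ordering
  tr <- g1$truth$seasons
  expect_true(all(tr$colony_departure < tr$winter_arrival))
  expect_true(all(tr$winter_arrival < tr$winter_departure))
  expect_true(all(tr$winter_departure < tr$colony_arrival))
  # distances within the configured range
  it <- g1$truth$individuals
  expect_true(all(it$migration_distance_km >=
                    cfg$migration_distance_range_km[1] - 1))
  expect_true(all(it$migration_distance_km <=
                    cfg$migration_distance_range_km[2] + 1))
})

test_that("zero within-individual variance repeats dates exactly across years", {
  cfg <- population_config(n_individuals = 4, years_per_individual = c(3, 3),
                           migration_distance_range_km = c(1200, 2500),
                           p_stopover = 1, sigma_within_days = 0,
                           fix_interval_h = 6, seed = 5)
  gen <- generate_population(cfg)
  tr <- gen$truth$seasons
  for (id in unique(tr$individual_id)) {
    s <- tr[tr$individual_id == id, ]
    for (v in c("colony_departure", "winter_arrival", "winter_departure",
                "colony_arrival")) {
      doy <- as.numeric(s[[v]] - as.Date(sprintf("%d-07-01", s$cycle_year)))
      expect_equal(length(unique(doy)), 1L, info = paste(id, v))
    }
  }
})

test_that("individuals sharing colony and near-identical winters get near-equal distances", {
  cfg <- population_config(
    n_individuals = 2, years_per_individual = c(2, 2),
    colonies = data.frame(colony_id = "C", lon = 3.18, lat = 51.3),
    migration_distance_range_km = c(1500, 1510),
    bearing_range_deg = c(200, 200.3), fix_interval_h = 6, seed = 12)
  gen <- generate_population(cfg)
  it <- gen$truth$individuals
  # winter centroids within ~12 km of each other by construction
  sep <- great_circle_km(it$winter_lon[1], it$winter_lat[1],
                         it$winter_lon[2], it$winter_lat[2])
  expect_lte(sep, 15)
  expect_lte(abs(diff(it$migration_distance_km)), sep + 1)
})

test_that("migration fixes move at realistic flight speed", {
  cfg <- population_config(n_individuals = 4, years_per_individual = c(2, 2),
                           migration_distance_range_km = c(800, 3000),
                           seed = 31)
  gen <- generate_population(cfg)
  fx <- gen$fixes
  for (id in unique(fx$individual_id)) {
    f <- fx[fx$individual_id == id, ]
    v <- great_circle_km(f$lon[-nrow(f)], f$lat[-nrow(f)],
                         f$lon[-1], f$lat[-1]) /
      (diff(as.numeric(f$timestamp)) / 3600)
    moving <- v > 15  # migratory flight steps
    expect_gt(sum(moving), 10)
    expect_lte(max(v), 82)
    expect_gte(stats::quantile(v[moving], 0.05), 18)
  }
})

test_that("gap injection is deterministic, non-destructive, and respects windows", {
  pop <- small_population()
  fx <- pop$fixes
  expect_identical(inject_gaps(fx, list(), seed = 1), fx)
  gaps <- list(list(p = 1, days = c(5, 10)))
  a <- inject_gaps(fx, gaps, seed = 3)
  b <- inject_gaps(fx, gaps, seed = 3)
  expect_identical(a, b)
  expect_lt(nrow(a), nrow(fx))
  expect_identical(fx, pop$fixes)  # original untouched
  # a window pins the gap location
  id <- fx$individual_id[1]
  w <- c(utc("2014-12-01 00:00:00"), utc("2014-12-02 00:00:00"))
  g2 <- inject_gaps(fx, list(list(p = 1, days = c(3, 3), window = w)), seed = 1)
  gone <- fx$individual_id == id &
    fx$timestamp >= utc("2014-12-02 00:00:00") &
    fx$timestamp < utc("2014-12-04 00:00:00")
  expect_false(any(g2$individual_id == id &
                     g2$timestamp %in% fx$timestamp[gone][1]))
})

test_that("a forced 25-day gap kills its season downstream; a 20-day gap does not", {
  pop <- small_population()
  it <- pop$truth$individuals
  # use an individual with three seasons so one drop leaves it in the study
  id <- it$individual_id[it$n_years == 3][1]
  fx <- pop$fixes
  colony <- c(it$colony_lon[it$individual_id == id],
              it$colony_lat[it$individual_id == id])
  w <- c(utc("2014-12-10 00:00:00"), utc("2014-12-10 01:00:00"))
  n_base <- length(apply_inclusion_filters(
    split_seasons(fx[fx$individual_id == id, ], colony)))
  expect_equal(n_base, 3L)

  g25 <- inject_gaps(fx[fx$individual_id == id, ],
                     list(list(p = 1, days = c(25, 25), window = w)), seed = 2)
  s25 <- apply_inclusion_filters(split_seasons(g25, colony))
  expect_equal(length(s25), n_base - 1L)
  expect_true(any(grepl("gap of 25", attr(s25, "drops")$reason)))

  g20 <- inject_gaps(fx[fx$individual_id == id, ],
                     list(list(p = 1, days = c(20, 20), window = w)), seed = 2)
  s20 <- apply_inclusion_filters(split_seasons(g20, colony))
  expect_equal(length(s20), n_base)
})

test_that("generator recovery: timing repeatability and winter distances (5 seeds)", {
  # generator-level invariant: the variance-component estimate applied to the
  # realized season dates recovers R_true within 0.1 at 80 x 3
  for (seed in 1:5) {
    cfg <- population_config(
      n_individuals = 80, years_per_individual = c(3, 3),
      migration_distance_range_km = c(1000, 3000), p_stopover = 1,
      sigma_among_days = 3, sigma_within_days = 1,
      fix_interval_h = 24 * 365,  # truth tables only; no trajectory needed
      seed = seed)
    gen <- generate_population(cfg)
    tr <- gen$truth$seasons
    it <- gen$truth$individuals
    col_of <- stats::setNames(it$colony_id, it$individual_id)
    dist_of <- stats::setNames(it$migration_distance_km, it$individual_id)
    for (v in c("colony_departure", "colony_arrival")) {
      doy <- as.numeric(tr[[v]] - as.Date(sprintf("%d-07-01", tr$cycle_year)))
      df <- data.frame(value = doy, individual = tr$individual_id,
                       colony = col_of[tr$individual_id],
                       distance = dist_of[tr$individual_id])
      fit <- fit_variance_components(df, include_distance = FALSE)
      expect_lte(abs(fit$R - gen$truth$R_true), 0.1,
                 label = sprintf("seed %d, %s: |R - R_true| = %.3f", seed, v,
                                 abs(fit$R - gen$truth$R_true)))
    }
  }
})
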
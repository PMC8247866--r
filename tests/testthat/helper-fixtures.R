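# shared fixture builders (all data generated in code)

utc <- function(s) as.POSIXct(s, tz = "UTC")

# projected fixes at given planar coordinates and hourly times
planar_fixes <- function(x, y, t0 = utc("2020-01-01 00:00:00"), dt_h = 1) {
  data.frame(x = x, y = y,
             timestamp = t0 + 3600 * dt_h * (seq_along(x) - 1))
}

# track_fixes data frame from lon/lat vectors
lonlat_fixes <- function(id, lon, lat, t0 = utc("2020-01-01 00:00:00"), dt_h = 1) {
  structure(data.frame(individual_id = id, lon = lon, lat = lat,
                       timestamp = t0 + 3600 * dt_h * (seq_along(lon) - 1),
                       stringsAsFactors = FALSE),
            class = c("track_fixes", "data.frame"))
}

# a small synthetic population used by several files; memoised per session
small_population <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- population_config(
        n_individuals = 6, years_per_individual = c(2, 3),
        migration_distance_range_km = c(600, 2500), p_stopover = 1,
        stopover_min_distance_km = 1000, seed = 11)
      cache <<- c(generate_population(cfg), list(config = cfg))
    }
    cache
  }
})

# independent brute-force Gaussian-mixture UD oracle (plain exp, no dnorm)
brute_force_ud <- function(fixes, grid, h) {
  xs <- grid$x0 + (seq_len(grid$nx) - 0.5) * grid$cell
  ys <- grid$y0 + (seq_len(grid$ny) - 0.5) * grid$cell
  z <- matrix(0, grid$nx, grid$ny)
  for (i in seq_len(grid$nx)) for (j in seq_len(grid$ny)) {
    d2 <- (xs[i] - fixes$x)^2 + (ys[j] - fixes$y)^2
    z[i, j] <- sum(exp(-d2 / (2 * h^2)) / (2 * pi * h^2)) * grid$cell^2
  }
  z / sum(z)
}

# independent nearest-distance objective oracle for mean routes (slow loops)
brute_force_route_objective <- function(route_km, legs_km) {
  legs_km <- lapply(legs_km, unname)
  route_km <- unname(route_km)
  n <- nrow(route_km)
  total <- 0
  for (q in seq_len(n)) {
    px <- route_km[q, 1]; py <- route_km[q, 2]
    dsum <- 0
    for (leg in legs_km) {
      best <- Inf
      for (s in seq_len(nrow(leg) - 1)) {
        ax <- leg[s, 1]; ay <- leg[s, 2]
        bx <- leg[s + 1, 1]; by <- leg[s + 1, 2]
        vx <- bx - ax; vy <- by - ay
        L2 <- vx^2 + vy^2
        t <- if (L2 == 0) 0 else max(0, min(1, ((px - ax) * vx + (py - ay) * vy) / L2))
        d2 <- (ax + t * vx - px)^2 + (ay + t * vy - py)^2
        if (d2 < best) best <- d2
      }
      dsum <- dsum + best
    }
    total <- total + dsum / length(legs_km)
  }
  as.numeric(total / n)
}
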
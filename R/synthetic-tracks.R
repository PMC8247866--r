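# --- spherical helpers (radius 6,371 km) -----------------------------------

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

# destination point given start, initial bearing (deg) and distance (km)
dest_point <- function(lon, lat, bearing_deg, dist_km) {
  d <- dist_km / EARTH_RADIUS_KM
  b <- deg2rad(bearing_deg)
  p1 <- deg2rad(lat); l1 <- deg2rad(lon)
  p2 <- asin(sin(p1) * cos(d) + cos(p1) * sin(d) * cos(b))
  l2 <- l1 + atan2(sin(b) * sin(d) * cos(p1), cos(d) - sin(p1) * sin(p2))
  cbind(lon = ((rad2deg(l2) + 180) %% 360) - 180, lat = rad2deg(p2))
}

# initial bearing (deg) from point 1 to point 2
gc_bearing <- function(lon1, lat1, lon2, lat2) {
  p1 <- deg2rad(lat1); p2 <- deg2rad(lat2); dl <- deg2rad(lon2 - lon1)
  th <- atan2(sin(dl) * cos(p2),
              cos(p1) * sin(p2) - sin(p1) * cos(p2) * cos(dl))
  (rad2deg(th) + 360) %% 360
}

# spherical interpolation between two lon/lat points at fractions f in [0,1]
gc_interp <- function(lon1, lat1, lon2, lat2, f) {
  to_xyz <- function(lon, lat) {
    p <- deg2rad(lat); l <- deg2rad(lon)
    c(cos(p) * cos(l), cos(p) * sin(l), sin(p))
  }
  a <- to_xyz(lon1, lat1); b <- to_xyz(lon2, lat2)
  delta <- acos(max(-1, min(1, sum(a * b))))
  if (delta < 1e-12) return(cbind(lon = rep(lon1, length(f)),
                                  lat = rep(lat1, length(f))))
  sa <- sin((1 - f) * delta) / sin(delta)
  sb <- sin(f * delta) / sin(delta)
  x <- sa * a[1] + sb * b[1]
  y <- sa * a[2] + sb * b[2]
  z <- sa * a[3] + sb * b[3]
  cbind(lon = rad2deg(atan2(y, x)), lat = rad2deg(asin(z / sqrt(x^2 + y^2 + z^2))))
}

# stationary AR(1) positional jitter (km), sd = scale, one axis
ou_jitter <- function(n, scale_km, phi = 0.9) {
  if (n == 0L) return(numeric(0))
  eps <- stats::rnorm(n, 0, scale_km * sqrt(1 - phi^2))
  eps[1] <- stats::rnorm(1, 0, scale_km)
  as.numeric(stats::filter(eps, phi, method = "recursive"))
}

# displace lon/lat points by east/north km offsets (small-offset approximation)
offset_lonlat <- function(lon, lat, dx_km, dy_km) {
  lat2 <- lat + dy_km / 111.195
  lon2 <- lon + dx_km / (111.195 * cos(deg2rad(lat)))
  cbind(lon = lon2, lat = lat2)
}

# --- configuration ----------------------------------------------------------

#' Configuration for the synthetic gull population generator
#'
#' Defines the statistical structure of the simulated tracking data set:
#' colonies, migration distances, timing means with separate among- and
#' within-individual standard deviations, route offsets, residence jitter,
#' device gaps and the random seed. All timing is expressed in days since
#' 1 July of the cycle's starting year; the default means place colony
#' departure in late July, winter arrival in late October (leaving a
#' prolonged stopover window), winter departure in mid March and colony
#' arrival in late March, matching a Western European gull annual cycle.
#'
#' @param n_individuals number of individuals (default 20).
#' @param colonies data frame `colony_id`, `lon`, `lat`; default two North
#'   Sea colonies.
#' @param years_per_individual integer range `c(min, max)` of tracked annual
#'   cycles per individual (default `c(2, 4)`).
#' @param start_year first cycle starts 1 July of this year (default 2014).
#' @param fix_interval_h GPS fix interval in hours (default 1).
#' @param migration_distance_range_km range of colony-to-winter great-circle
#'   distances (default `c(50, 4600)`).
#' @param bearing_range_deg sector of departure bearings from the colony in
#'   degrees (default `c(190, 215)`, south-southwest), which concentrates
#'   winter sites along a shared corridor so that the 250-km pairing
#'   constraint is satisfiable; widen it to make pairing impossible.
#' @param p_stopover probability that an individual (with migration distance
#'   at least `stopover_min_distance_km`) maintains a stopover site
#'   (default 0.7).
#' @param stopover_min_distance_km minimum migration distance for stopovers
#'   (default 1000).
#' @param timing_mu_days named vector of population mean event days (since
#'   1 July): `colony_departure`, `winter_arrival`, `winter_departure`,
#'   `colony_arrival`.
#' @param sigma_among_days SD of individual mean dates around the population
#'   mean, days (default 6).
#' @param sigma_within_days SD of yearly dates around the individual mean,
#'   days (default 3).
#' @param route_offset_sigma_km SD of the individual lateral route offset
#'   (default 30).
#' @param route_jitter_sigma_km SD of the yearly lateral route jitter
#'   (default 10).
#' @param site_jitter_km stationary SD of daily movement around residence
#'   centroids (default 3).
#' @param speed_range_kmh range of migratory flight speeds (default
#'   `c(30, 70)`; with lateral jitter, realized speeds between fixes stay
#'   within 20-80 km/h).
#' @param gap_injection list of gap specifications for [inject_gaps()]
#'   applied at generation time (default none).
#' @param seed integer seed; identical seeds give byte-identical output.
#' @return a validated `population_config` list.
#' @export
population_config <- function(
    n_individuals = 20,
    colonies = data.frame(colony_id = c("NS1", "NS2"),
                          lon = c(3.18, 4.72), lat = c(51.3, 53.0),
                          stringsAsFactors = FALSE),
    years_per_individual = c(2L, 4L),
    start_year = 2014,
    fix_interval_h = 1,
    migration_distance_range_km = c(50, 4600),
    bearing_range_deg = c(190, 215),
    p_stopover = 0.7,
    stopover_min_distance_km = 1000,
    timing_mu_days = c(colony_departure = 20, winter_arrival = 115,
                       winter_departure = 255, colony_arrival = 272),
    sigma_among_days = 6,
    sigma_within_days = 3,
    route_offset_sigma_km = 30,
    route_jitter_sigma_km = 10,
    site_jitter_km = 3,
    speed_range_kmh = c(30, 70),
    gap_injection = list(),
    seed = 1) {
  cfg <- list(n_individuals = as.integer(n_individuals), colonies = colonies,
              years_per_individual = as.integer(years_per_individual),
              start_year = as.integer(start_year),
              fix_interval_h = fix_interval_h,
              migration_distance_range_km = migration_distance_range_km,
              bearing_range_deg = bearing_range_deg,
              p_stopover = p_stopover,
              stopover_min_distance_km = stopover_min_distance_km,
              timing_mu_days = timing_mu_days,
              sigma_among_days = sigma_among_days,
              sigma_within_days = sigma_within_days,
              route_offset_sigma_km = route_offset_sigma_km,
              route_jitter_sigma_km = route_jitter_sigma_km,
              site_jitter_km = site_jitter_km,
              speed_range_kmh = speed_range_kmh,
              gap_injection = gap_injection,
              seed = as.integer(seed))
  if (cfg$n_individuals < 1) stop("need at least one individual")
  if (nrow(colonies) < 1) stop("need at least one colony")
  if (fix_interval_h <= 0) stop("fix_interval_h must be positive")
  if (sigma_among_days < 0 || sigma_within_days < 0 || site_jitter_km < 0 ||
      route_offset_sigma_km < 0 || route_jitter_sigma_km < 0)
    stop("all standard deviations must be non-negative")
  tm <- timing_mu_days
  need <- c("colony_departure", "winter_arrival", "winter_departure",
            "colony_arrival")
  if (!all(need %in% names(tm))) stop("timing_mu_days must name all four events")
  if (!(tm["colony_departure"] < tm["winter_arrival"] &&
        tm["winter_arrival"] < tm["winter_departure"] &&
        tm["winter_departure"] < tm["colony_arrival"]))
    stop("timing windows overlap inconsistently: require colony departure < ",
         "winter arrival < winter departure < colony arrival")
  structure(cfg, class = "population_config")
}

#' @export
print.population_config <- function(x, ...) {
  cat(sprintf(paste0("synthetic population: %d individuals, %d colonies, ",
                     "%d-%d years each, distances %.0f-%.0f km, R_true = %.3f\n"),
              x$n_individuals, nrow(x$colonies), x$years_per_individual[1],
              x$years_per_individual[2], x$migration_distance_range_km[1],
              x$migration_distance_range_km[2], true_repeatability(x)))
  invisible(x)
}

#' Theoretical repeatability implied by a configuration
#'
#' `R_true = sigma_among^2 / (sigma_among^2 + sigma_within^2)`, the
#' among-individual share of timing-trait variance under the generative
#' two-level normal model.
#'
#' @param config a `population_config`.
#' @return numeric in \[0, 1\].
#' @export
true_repeatability <- function(config) {
  a2 <- config$sigma_among_days^2; w2 <- config$sigma_within_days^2
  if (a2 + w2 == 0) return(1)
  a2 / (a2 + w2)
}

# --- generation -------------------------------------------------------------

#' Generate a synthetic multi-individual, multi-year GPS tracking data set
#'
#' Simulates the full annual cycle for each individual: colony residence,
#' an outbound migration leg at realistic flight speed with optional
#' prolonged stopovers, a winter residence spanning December-March, and a
#' return leg -- with individual-specific mean timing, route and sites, and
#' separate among- and within-individual variance in timing (individual mean
#' dates ~ Normal(population mean, sigma_among); yearly dates ~
#' Normal(individual mean, sigma_within), with ordering preserved).
#' Residence periods are a bounded random walk around the site centroid;
#' migration legs are great-circle paths with a smooth lateral displacement
#' (individual offset through stopover placement plus yearly jitter).
#' All transitions are scheduled at midday UTC. Identical seeds give
#' identical output.
#'
#' @param config a [population_config()].
#' @return list with `fixes` (a `track_fixes` data frame for all
#'   individuals) and `truth` (a `ground_truth` list: `individuals` and
#'   `seasons` data frames, `R_true`, `config`).
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "population_config"))
  with_local_seed(config$seed, generate_population_impl(config))
}

generate_population_impl <- function(cfg) {
  tm <- cfg$timing_mu_days
  n <- cfg$n_individuals
  ids <- sprintf("bird%03d", seq_len(n))
  col_idx <- sample.int(nrow(cfg$colonies), n, replace = TRUE)
  dist_km <- stats::runif(n, cfg$migration_distance_range_km[1],
                          cfg$migration_distance_range_km[2])
  bearing <- stats::runif(n, cfg$bearing_range_deg[1], cfg$bearing_range_deg[2])
  yr_rng <- cfg$years_per_individual
  n_years <- if (yr_rng[1] == yr_rng[2]) rep(yr_rng[1], n) else
    sample(seq(yr_rng[1], yr_rng[2]), n, replace = TRUE)
  has_stop <- dist_km >= cfg$stopover_min_distance_km &
    stats::runif(n) < cfg$p_stopover
  stop_frac <- stats::runif(n, 0.35, 0.65)
  off_i <- stats::rnorm(n, 0, cfg$route_offset_sigma_km)
  # individual mean event days; enforce ordering with margins
  mu <- matrix(stats::rnorm(4 * n, mean = rep(tm, each = n),
                            sd = cfg$sigma_among_days), n, 4)
  colnames(mu) <- names(tm)

  col_lon <- cfg$colonies$lon[col_idx]; col_lat <- cfg$colonies$lat[col_idx]
  win <- dest_point(col_lon, col_lat, bearing, dist_km)
  # stopover site: on the great-circle at stop_frac, displaced laterally by
  # the individual route offset (clamped to 8% of the distance so that
  # realized flight speeds stay within bounds)
  off_eff <- pmax(pmin(off_i, 0.08 * dist_km), -0.08 * dist_km)
  stop_site <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    if (!has_stop[i]) next
    p <- gc_interp(col_lon[i], col_lat[i], win[i, 1], win[i, 2], stop_frac[i])
    brg <- gc_bearing(p[1, 1], p[1, 2], win[i, 1], win[i, 2])
    stop_site[i, ] <- dest_point(p[1, 1], p[1, 2], brg + 90,
                                 off_eff[i] * sin(pi * stop_frac[i]))
  }

  fixes_l <- list()
  seasons <- NULL
  iv_h <- cfg$fix_interval_h

  for (i in seq_len(n)) {
    waypts <- rbind(c(col_lon[i], col_lat[i]),
                    if (has_stop[i]) stop_site[i, , drop = FALSE],
                    win[i, , drop = FALSE])
    leg_len <- great_circle_km(waypts[-nrow(waypts), 1], waypts[-nrow(waypts), 2],
                               waypts[-1, 1], waypts[-1, 2])
    for (y in seq_len(n_years[i])) {
      yy <- cfg$start_year + y - 1L
      t0 <- as.numeric(as.POSIXct(sprintf("%d-07-01 00:00:00", yy), tz = "UTC"))
      v_out <- stats::runif(1, cfg$speed_range_kmh[1], cfg$speed_range_kmh[2])
      v_ret <- stats::runif(1, cfg$speed_range_kmh[1], cfg$speed_range_kmh[2])
      j_y <- stats::rnorm(1, 0, cfg$route_jitter_sigma_km)
      d4 <- mu[i, ] + stats::rnorm(4, 0, cfg$sigma_within_days)
      d4 <- round(d4)
      trav_out_d <- sum(leg_len) / v_out / 24
      trav_ret_d <- dist_km[i] / v_ret / 24
      # enforce a feasible, ordered cycle
      d4[1] <- max(d4[1], 2)
      if (has_stop[i]) {
        d4[2] <- max(d4[2], d4[1] + ceiling(trav_out_d) + 23)
      } else {
        # direct migrant: winter arrival follows departure by the travel time
        d4[2] <- d4[1] + ceiling(trav_out_d) + 2
      }
      d4[3] <- max(d4[3], d4[2] + 30)
      d4[4] <- max(d4[4], d4[3] + ceiling(trav_ret_d) + 1)
      d4[4] <- min(d4[4], 363)
      ts_of <- function(day) t0 + day * 86400 + 12 * 3600  # midday UTC
      dep_t <- ts_of(d4[1]); win_arr_t <- ts_of(d4[2])
      win_dep_t <- ts_of(d4[3]); col_arr_t <- ts_of(d4[4])
      t_end <- t0 + 365 * 86400

      tt <- seq(t0, t_end - 1, by = iv_h * 3600)
      pos <- matrix(NA_real_, length(tt), 2)

      fill_res <- function(sel, centre) {
        m <- sum(sel)
        if (m == 0L) return()
        jx <- ou_jitter(m, cfg$site_jitter_km)
        jy <- ou_jitter(m, cfg$site_jitter_km)
        pos[sel, ] <<- offset_lonlat(rep(centre[1], m), rep(centre[2], m), jx, jy)
      }
      fill_leg <- function(t_a, t_b, A, B, jit_km) {
        sel <- tt >= t_a & tt < t_b
        m <- sum(sel)
        if (m == 0L) return()
        f <- (tt[sel] - t_a) / (t_b - t_a)
        p <- gc_interp(A[1], A[2], B[1], B[2], f)
        if (abs(jit_km) > 1e-9) {
          brg <- gc_bearing(A[1], A[2], B[1], B[2])
          p <- dest_point(p[, 1], p[, 2], brg + 90, jit_km * sin(pi * f))
        }
        pos[sel, ] <<- p
      }

      # colony residence, outbound, winter, return, colony residence
      fill_res(tt < dep_t, c(col_lon[i], col_lat[i]))
      d_leg_km <- dist_km[i]
      jit_eff <- max(min(j_y, 0.08 * d_leg_km), -0.08 * d_leg_km)
      if (has_stop[i]) {
        trav1 <- leg_len[1] / v_out * 3600; trav2 <- leg_len[2] / v_out * 3600
        stop_arr <- dep_t + trav1
        stop_dep <- win_arr_t - trav2
        fill_leg(dep_t, stop_arr, waypts[1, ], waypts[2, ], jit_eff)
        fill_res(tt >= stop_arr & tt < stop_dep, waypts[2, ])
        fill_leg(stop_dep, win_arr_t, waypts[2, ], waypts[3, ], jit_eff)
      } else {
        # any slack between travel time and the winter-arrival date is spent
        # in a short en-route rest at 55% of the route (never a core area)
        trav_s <- dist_km[i] / v_out * 3600
        slack <- (win_arr_t - dep_t) - trav_s
        if (slack > 6 * 3600) {
          rp <- gc_interp(col_lon[i], col_lat[i], win[i, 1], win[i, 2], 0.55)
          t1 <- dep_t + 0.55 * trav_s
          t2 <- t1 + slack
          fill_leg(dep_t, t1, c(col_lon[i], col_lat[i]), rp[1, ], jit_eff)
          fill_res(tt >= t1 & tt < t2, rp[1, ])
          fill_leg(t2, win_arr_t, rp[1, ], win[i, ], jit_eff)
        } else {
          fill_leg(dep_t, win_arr_t, c(col_lon[i], col_lat[i]), win[i, ], jit_eff)
        }
      }
      fill_res(tt >= win_arr_t & tt < win_dep_t, win[i, ])
      # return leg with optional short rest absorbing spring slack
      trav_s <- dist_km[i] / v_ret * 3600
      slack <- (col_arr_t - win_dep_t) - trav_s
      if (slack > 6 * 3600) {
        rp <- gc_interp(win[i, 1], win[i, 2], col_lon[i], col_lat[i], 0.55)
        t1 <- win_dep_t + 0.55 * trav_s
        t2 <- t1 + slack
        fill_leg(win_dep_t, t1, win[i, ], rp[1, ], -jit_eff)
        fill_res(tt >= t1 & tt < t2, rp[1, ])
        fill_leg(t2, col_arr_t, rp[1, ], c(col_lon[i], col_lat[i]), -jit_eff)
      } else {
        fill_leg(win_dep_t, col_arr_t, win[i, ], c(col_lon[i], col_lat[i]),
                 -jit_eff)
      }
      fill_res(tt >= col_arr_t, c(col_lon[i], col_lat[i]))

      fixes_l[[length(fixes_l) + 1L]] <- data.frame(
        individual_id = ids[i], timestamp = tt,
        lon = pos[, 1], lat = pos[, 2], stringsAsFactors = FALSE)
      as_date_s <- function(s)
        as.Date(as.POSIXct(s, origin = "1970-01-01", tz = "UTC"), tz = "UTC")
      seasons <- rbind(seasons, data.frame(
        individual_id = ids[i], cycle_year = yy,
        colony_departure = as_date_s(dep_t),
        winter_arrival = as_date_s(win_arr_t),
        winter_departure = as_date_s(win_dep_t),
        colony_arrival = as_date_s(col_arr_t),
        n_stopovers = as.integer(has_stop[i]),
        stringsAsFactors = FALSE))
    }
  }
  rownames(seasons) <- NULL
  fixes <- do.call(rbind, fixes_l)
  fixes$timestamp <- as.POSIXct(fixes$timestamp, origin = "1970-01-01", tz = "UTC")
  fixes <- fixes[order(fixes$individual_id, fixes$timestamp), , drop = FALSE]
  rownames(fixes) <- NULL
  class(fixes) <- c("track_fixes", "data.frame")

  individuals <- data.frame(
    individual_id = ids,
    colony_id = cfg$colonies$colony_id[col_idx],
    colony_lon = col_lon, colony_lat = col_lat,
    winter_lon = win[, 1], winter_lat = win[, 2],
    stopover_lon = stop_site[, 1], stopover_lat = stop_site[, 2],
    has_stopover = has_stop,
    n_years = n_years,
    migration_distance_km = great_circle_km(col_lon, col_lat, win[, 1], win[, 2]),
    mu_colony_departure = mu[, 1], mu_winter_arrival = mu[, 2],
    mu_winter_departure = mu[, 3], mu_colony_arrival = mu[, 4],
    stringsAsFactors = FALSE)

  truth <- structure(list(individuals = individuals, seasons = seasons,
                          R_true = true_repeatability(cfg), config = cfg),
                     class = "ground_truth")
  if (length(cfg$gap_injection) > 0L)
    fixes <- inject_gaps(fixes, cfg$gap_injection, seed = cfg$seed + 1L)
  list(fixes = fixes, truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground truth for %d individuals, %d seasons; R_true = %.3f\n",
              nrow(x$individuals), nrow(x$seasons), x$R_true))
  invisible(x)
}

#' Inject device gaps into a trajectory
#'
#' Deletes runs of fixes to emulate low-battery or device-malfunction gaps.
#' Each element of `gaps` is applied per individual: with probability `p`, a
#' gap of duration drawn uniformly from `days` is placed at a start time
#' drawn uniformly over the track span (or over `window`, a POSIXct range),
#' and all fixes within it are removed. The input is not modified;
#' deterministic given the seed.
#'
#' @param fixes a `track_fixes` data frame (one or more individuals).
#' @param gaps list of `list(p =, days = c(lo, hi), window = NULL)` entries;
#'   an empty list returns the input unchanged.
#' @param seed integer seed.
#' @return the fixes with gap runs deleted.
#' @export
inject_gaps <- function(fixes, gaps, seed = 1) {
  if (length(gaps) == 0L) return(fixes)
  with_local_seed(seed, {
    drop <- rep(FALSE, nrow(fixes))
    for (id in unique(fixes$individual_id)) {
      sel <- which(fixes$individual_id == id)
      tt <- as.numeric(fixes$timestamp[sel])
      for (g in gaps) {
        if (stats::runif(1) >= g$p) next
        dur <- stats::runif(1, g$days[1], g$days[2]) * 86400
        if (!is.null(g$window)) {
          lo <- as.numeric(g$window[1]); hi <- as.numeric(g$window[2])
        } else {
          lo <- tt[1]; hi <- max(tt[1], tt[length(tt)] - dur)
        }
        start <- stats::runif(1, lo, hi)
        drop[sel[tt >= start & tt < start + dur]] <- TRUE
      }
    }
    out <- fixes[!drop, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Write ground truth tables to delimited text
#'
#' @param truth a `ground_truth` object.
#' @param path output path for the per-individual table; the per-season
#'   table is written next to it with suffix `_seasons`.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth$individuals, path, sep = ",", row.names = FALSE,
                     quote = FALSE)
  sp <- sub("(\\.[^.]+)?$", "_seasons\\1", path)
  utils::write.table(truth$seasons, sp, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(c(path, sp))
}
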
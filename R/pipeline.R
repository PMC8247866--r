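#' Pipeline run configuration
#'
#' All stage parameters in one place, defaulting to the analysis' standard
#' values: 12-h subsampling, 10-km seasonal grid with a fixed 100-km
#' bandwidth, 95\%/50\% isopleth levels, 21-day gap filter, 10-km colony
#' radius, 250-km pairing constraint, 24-h route gap filter, 500 route
#' points, 10,000 randomizations and 1,000 parametric bootstraps.
#'
#' @param subsample_h subsampling interval (hours).
#' @param cell seasonal grid resolution (metres).
#' @param h seasonal kernel bandwidth (metres).
#' @param overlap_level UD truncation level for overlap.
#' @param core_level isopleth level defining core areas.
#' @param max_gap_days season gap filter (days).
#' @param min_seasons minimum seasons per individual.
#' @param colony_radius_km colony detection radius (km).
#' @param anchor_window breeding anchor window, `c("mm-dd", "mm-dd")`.
#' @param absence_days,sustained_days season splitting thresholds (days).
#' @param pairing_km between-individual pairing constraint (km).
#' @param route_gap_h migration-leg gap filter (hours).
#' @param route_points mean-route points.
#' @param brb_cell winter UD grid resolution (metres).
#' @param brb winter UD parameters, a [brb_params()].
#' @param n_perm randomization-test permutations.
#' @param n_boot parametric bootstrap iterations (0 skips the CI).
#' @param winter_arrival_distance keep the migration-distance fixed effect
#'   in the winter-arrival model (default FALSE, for convergence).
#' @param do_overlap,do_fidelity,do_routes,do_stats stage switches.
#' @param seed master seed for season selection, randomizations, bootstraps.
#' @return a `run_config` list.
#' @export
run_config <- function(subsample_h = 12, cell = 10000, h = 100000,
                       overlap_level = 0.95, core_level = 0.5,
                       max_gap_days = 21, min_seasons = 2,
                       colony_radius_km = 10,
                       anchor_window = c("05-01", "07-15"),
                       absence_days = 7, sustained_days = 7,
                       pairing_km = 250, route_gap_h = 24, route_points = 500,
                       brb_cell = 500, brb = brb_params(),
                       n_perm = 10000, n_boot = 1000,
                       winter_arrival_distance = FALSE,
                       do_overlap = TRUE, do_fidelity = TRUE,
                       do_routes = TRUE, do_stats = TRUE, seed = 1) {
  structure(as.list(environment()), class = "run_config")
}

assign_colony <- function(fixes, colonies) {
  # nearest colony to the first fix (tracks start at the breeding colony)
  d <- great_circle_km(fixes$lon[1], fixes$lat[1], colonies$lon, colonies$lat)
  which.min(d)
}

day_of_cycle <- function(dates, season_labels) {
  # days since 1 July of the season's starting year (comparable across years)
  y0 <- as.integer(substr(season_labels, 1, 4))
  anchor <- as.Date(sprintf("%d-07-01", y0))
  as.numeric(dates - anchor)
}

#' Run the full analysis pipeline
#'
#' Executes ingest, season splitting and filtering, seasonal utilization
#' distributions, core areas and phenology, non-breeding distribution
#' overlap, winter site fidelity, mean routes and route variation, and the
#' population statistics (pairing, randomization tests, repeatability with
#' bootstrap CIs, individual repeatability, distance models with the
#' between-individual null-model correction). Re-running with the same
#' inputs, configuration and seed reproduces the outputs exactly.
#'
#' @param fixes a `track_fixes` data frame (e.g. from [read_tracks()] or
#'   [generate_population()]), or a path to a delimited track file.
#' @param colonies data frame `colony_id`, `lon`, `lat`.
#' @param config a [run_config()].
#' @param out_dir optional directory; when given, result tables, GeoJSON and
#'   a run manifest are written there.
#' @return a `pipeline_result` list: `season_records`, `individuals`,
#'   `overlap`, `fidelity`, `routes`, `stats`, `drops`, `config`.
#' @export
run_pipeline <- function(fixes, colonies, config = run_config(),
                         out_dir = NULL) {
  if (is.character(fixes)) fixes <- read_tracks(fixes)
  proj <- laea_projection(mean(colonies$lon), mean(colonies$lat))
  fixes <- project_tracks(fixes, proj)

  ids <- unique(fixes$individual_id)
  drops <- list()
  season_records <- NULL
  ind_rows <- NULL
  overlap_rows <- NULL
  fidelity_rows <- NULL
  route_rows <- NULL
  per_ind <- list()

  for (id in ids) {
    fx <- fixes[fixes$individual_id == id, , drop = FALSE]
    attr(fx, "proj") <- proj
    ci <- assign_colony(fx, colonies)
    colony <- c(colonies$lon[ci], colonies$lat[ci])
    seas <- split_seasons(fx, colony, radius_km = config$colony_radius_km,
                          anchor_window = config$anchor_window,
                          absence_days = config$absence_days,
                          sustained_days = config$sustained_days)
    if (isTRUE(attr(seas, "resident"))) {
      drops[[id]] <- "resident: never beyond the colony radius"
      next
    }
    seas <- apply_inclusion_filters(seas, max_gap_days = config$max_gap_days,
                                    min_seasons = config$min_seasons)
    dr <- attr(seas, "drops")
    if (nrow(dr) > 0L)
      drops[[id]] <- sprintf("%s: %s", dr$season, dr$reason)
    if (length(seas) < config$min_seasons) next

    ana <- analyze_individual(seas, colony, cell = config$cell, h = config$h,
                              subsample_h = config$subsample_h,
                              overlap_level = config$overlap_level,
                              core_level = config$core_level, proj = proj)
    if (length(ana$dropped) > 0L)
      drops[[id]] <- c(drops[[id]], ana$dropped)
    if (is.null(ana$records) || nrow(ana$records) < config$min_seasons) next

    season_records <- rbind(season_records, ana$records)
    ind_rows <- rbind(ind_rows, data.frame(
      individual_id = id, colony_id = colonies$colony_id[ci],
      colony_lon = colony[1], colony_lat = colony[2],
      winter_lon = stats::median(ana$records$winter_lon),
      winter_lat = stats::median(ana$records$winter_lat),
      median_distance_km = ana$median_distance_km,
      n_seasons = nrow(ana$records),
      switched = ana$switched, stringsAsFactors = FALSE))
    if (config$do_overlap && !is.null(ana$overlap))
      overlap_rows <- rbind(overlap_rows, data.frame(
        individual_id = id, mean_ba = ana$overlap$mean_ba,
        n_pairs = nrow(ana$overlap$pairs), stringsAsFactors = FALSE))

    # winter site fidelity from full-rate fixes between winter transitions
    if (config$do_fidelity) {
      wuds <- list()
      for (lab in names(ana$years)) {
        yr <- ana$years[[lab]]
        if (is.null(yr$record)) next
        ts <- attr(yr$record, "timestamps")
        wfx <- yr$season$fixes
        wfx <- wfx[wfx$timestamp >= ts$winter_arrival &
                     wfx$timestamp <= ts$winter_departure, , drop = FALSE]
        if (nrow(wfx) < 2L) next
        wuds[[lab]] <- tryCatch(
          brb_ud(wfx, cell = config$brb_cell, params = config$brb, proj = proj),
          error = function(e) NULL)
      }
      wuds <- Filter(Negate(is.null), wuds)
      if (length(wuds) >= 2L) {
        fid <- winter_site_fidelity(wuds, level = config$overlap_level)
        fidelity_rows <- rbind(fidelity_rows, data.frame(
          individual_id = id, mean_ba = fid$mean_ba,
          n_pairs = nrow(fid$pairs), stringsAsFactors = FALSE))
      }
    }

    # migration legs and mean routes
    legs_by_dir <- list(autumn = list(), spring = list())
    if (config$do_routes) {
      for (lab in names(ana$years)) {
        yr <- ana$years[[lab]]
        if (is.null(yr$record)) next
        lg <- extract_legs(yr$season, yr$record, yr$cores, ud_grid(yr$ud),
                           max_gap_h = config$route_gap_h)
        if (!is.null(lg$autumn))
          legs_by_dir$autumn[[lab]] <- lg$autumn
        if (!is.null(lg$spring))
          legs_by_dir$spring[[lab]] <- lg$spring
        if (length(attr(lg, "dropped")) > 0L)
          drops[[id]] <- c(drops[[id]], attr(lg, "dropped"))
      }
      for (dir in c("autumn", "spring")) {
        if (length(legs_by_dir[[dir]]) >= 2L) {
          mr <- mean_route(legs_by_dir[[dir]], n_points = config$route_points)
          route_rows <- rbind(route_rows, data.frame(
            individual_id = id, direction = dir,
            variation_km = mr$route_variation_km,
            variation_km2 = mr$route_variation_km2,
            n_legs = mr$n_legs, converged = mr$converged,
            stringsAsFactors = FALSE))
          per_ind[[id]]$routes[[dir]] <- mr
        }
      }
    }
    per_ind[[id]]$analysis <- if (config$do_overlap) ana[c("overlap", "switched")] else NULL
    per_ind[[id]]$years <- if (config$do_overlap) ana$years else NULL
    per_ind[[id]]$legs <- legs_by_dir
  }

  stats_out <- NULL
  if (config$do_stats && !is.null(ind_rows) && nrow(ind_rows) >= 2L)
    stats_out <- pipeline_stats(season_records, ind_rows, overlap_rows,
                                fidelity_rows, route_rows, per_ind, config)

  result <- structure(list(
    season_records = season_records, individuals = ind_rows,
    overlap = overlap_rows, fidelity = fidelity_rows, routes = route_rows,
    stats = stats_out, drops = drops, config = config), class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_outputs(result, per_ind, out_dir)
  result
}

pipeline_stats <- function(season_records, individuals, overlap_rows,
                           fidelity_rows, route_rows, per_ind, config) {
  out <- list()
  nonsw <- individuals$individual_id[!individuals$switched]

  # between-individual pairing (switchers excluded from all pairwise metrics)
  cand <- individuals[individuals$individual_id %in% nonsw, , drop = FALSE]
  seasons_by_ind <- split(season_records$season, season_records$individual_id)
  pairs <- build_pairs(cand, seasons_by_ind, constraint_km = config$pairing_km,
                       seed = config$seed)
  out$pairs <- pairs

  dist_of <- stats::setNames(individuals$median_distance_km,
                             individuals$individual_id)

  # between-individual non-breeding overlap on the selected seasons
  if (nrow(pairs) > 0L && config$do_overlap) {
    ba <- rep(NA_real_, nrow(pairs))
    for (k in seq_len(nrow(pairs))) {
      ya <- per_ind[[pairs$id_a[k]]]$years[[pairs$season_a[k]]]
      yb <- per_ind[[pairs$id_b[k]]]$years[[pairs$season_b[k]]]
      if (is.null(ya) || is.null(yb)) next
      ba[k] <- ba_lattice(truncate_ud(ya$ud, config$overlap_level),
                          truncate_ud(yb$ud, config$overlap_level))
    }
    pairs$ba <- ba
    pairs$mean_distance_km <- (dist_of[pairs$id_a] + dist_of[pairs$id_b]) / 2
    out$pairs <- pairs

    within_ov <- overlap_rows$mean_ba[overlap_rows$individual_id %in% nonsw]
    between_ov <- ba[!is.na(ba)]
    if (length(within_ov) > 0L && length(between_ov) > 0L) {
      out$overlap_test <- randomization_test(
        within = 1 - within_ov, between = 1 - between_ov,
        n_perm = config$n_perm, seed = config$seed)
      out$overlap_medians <- c(within = stats::median(within_ov),
                               between = stats::median(between_ov))
    }
    ok <- overlap_rows$individual_id %in% nonsw
    dd <- dist_of[overlap_rows$individual_id[ok]]
    if (sum(ok) >= 3L && stats::var(dd) > 0) {
      out$overlap_distance <- distance_model(overlap_rows$mean_ba[ok], dd)
      bm_ok <- !is.na(pairs$ba)
      if (sum(bm_ok) >= 3L && stats::var(pairs$mean_distance_km[bm_ok]) > 0) {
        out$overlap_between_distance <-
          distance_model(pairs$ba[bm_ok], pairs$mean_distance_km[bm_ok])
        out$overlap_residual <- residual_variation(
          overlap_rows$mean_ba[ok], dd, out$overlap_between_distance)
      }
    }
  }

  # winter site fidelity vs distance
  if (!is.null(fidelity_rows)) {
    ok <- fidelity_rows$individual_id %in% nonsw
    dd <- dist_of[fidelity_rows$individual_id[ok]]
    if (sum(ok) >= 3L && stats::var(dd) > 0)
      out$fidelity_distance <- distance_model(fidelity_rows$mean_ba[ok], dd)
  }

  # between-individual route variation on paired legs
  if (!is.null(route_rows) && nrow(pairs) > 0L) {
    for (dir in c("autumn", "spring")) {
      bet <- rep(NA_real_, nrow(pairs))
      for (k in seq_len(nrow(pairs))) {
        la <- per_ind[[pairs$id_a[k]]]$legs[[dir]][[pairs$season_a[k]]]
        lb <- per_ind[[pairs$id_b[k]]]$legs[[dir]][[pairs$season_b[k]]]
        if (is.null(la) || is.null(lb)) next
        bet[k] <- between_individual_route_variation(
          la, lb, n_points = config$route_points)$route_variation_km
      }
      wt <- route_rows[route_rows$direction == dir &
                         route_rows$individual_id %in% nonsw, , drop = FALSE]
      if (nrow(wt) > 0L && any(!is.na(bet))) {
        out[[paste0("route_test_", dir)]] <- randomization_test(
          within = wt$variation_km, between = bet[!is.na(bet)],
          n_perm = config$n_perm, seed = config$seed + 1L)
        out[[paste0("route_medians_", dir)]] <-
          c(within = stats::median(wt$variation_km),
            between = stats::median(bet, na.rm = TRUE))
      }
      dd <- dist_of[wt$individual_id]
      if (nrow(wt) >= 3L && stats::var(dd) > 0) {
        out[[paste0("route_distance_", dir)]] <-
          distance_model(wt$variation_km, dd)
        bm_ok <- !is.na(bet)
        if (sum(bm_ok) >= 3L && stats::var(pairs$mean_distance_km[bm_ok]) > 0) {
          bm <- distance_model(bet[bm_ok], pairs$mean_distance_km[bm_ok])
          out[[paste0("route_between_distance_", dir)]] <- bm
          out[[paste0("route_residual_", dir)]] <-
            residual_variation(wt$variation_km, dd, bm)
        }
      }
    }
  }

  # repeatability of the four timing traits (switchers retained)
  traits <- c("colony_departure", "winter_arrival", "winter_departure",
              "colony_arrival")
  col_of <- stats::setNames(individuals$colony_id, individuals$individual_id)
  out$repeatability <- list()
  out$individual_repeatability <- list()
  for (tr in traits) {
    vals <- day_of_cycle(season_records[[tr]], season_records$season)
    df <- data.frame(value = vals,
                     individual = season_records$individual_id,
                     colony = col_of[season_records$individual_id],
                     distance = dist_of[season_records$individual_id],
                     stringsAsFactors = FALSE)
    df <- df[!is.na(df$value), , drop = FALSE]
    if (length(unique(df$individual)) < 2L) next
    incl_d <- if (tr == "winter_arrival") config$winter_arrival_distance else TRUE
    fit <- tryCatch(fit_variance_components(df, include_distance = incl_d),
                    error = function(e) NULL)
    if (is.null(fit)) next
    if (config$n_boot > 0L)
      fit <- bootstrap_ci(fit, n_boot = config$n_boot, seed = config$seed + 2L)
    out$repeatability[[tr]] <- fit
    ri <- individual_repeatability(fit)
    ri <- ri[ri$individual %in% nonsw, , drop = FALSE]
    out$individual_repeatability[[tr]] <- ri
    dd <- dist_of[ri$individual]
    if (nrow(ri) >= 3L && stats::var(dd) > 0)
      out[[paste0("ri_distance_", tr)]] <- distance_model(ri$R_i, dd)
  }
  out
}

write_pipeline_outputs <- function(result, per_ind, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    if (is.null(df)) return()
    utils::write.table(df, file.path(out_dir, name), sep = ",",
                       row.names = FALSE, quote = FALSE)
  }
  wt(result$season_records, "season_records.csv")
  wt(result$individuals, "individuals.csv")
  wt(result$overlap, "overlap.csv")
  wt(result$fidelity, "fidelity.csv")
  wt(result$routes, "routes.csv")
  if (!is.null(result$stats)) {
    wt(result$stats$pairs, "pairs.csv")
    reps <- result$stats$repeatability
    if (length(reps) > 0L) {
      rdf <- do.call(rbind, lapply(names(reps), function(tr) {
        r <- reps[[tr]]
        data.frame(trait = tr, s_a2 = r$s_a2, s_col2 = r$s_col2,
                   s_eps2 = r$s_eps2, R = r$R,
                   ci_lo = if (is.null(r$ci)) NA else r$ci[1],
                   ci_hi = if (is.null(r$ci)) NA else r$ci[2],
                   singular = r$singular, stringsAsFactors = FALSE)
      }))
      wt(rdf, "repeatability.csv")
    }
    ri <- result$stats$individual_repeatability
    if (length(ri) > 0L) {
      ridf <- do.call(rbind, lapply(names(ri), function(tr)
        cbind(trait = tr, ri[[tr]])))
      wt(ridf, "individual_repeatability.csv")
    }
  }
  for (id in names(per_ind)) {
    for (dir in names(per_ind[[id]]$routes)) {
      write_route_geojson(per_ind[[id]]$routes[[dir]],
                          file.path(out_dir, sprintf("route_%s_%s.geojson", id, dir)))
    }
  }
  manifest <- list(
    package = "migvar",
    version = as.character(utils::packageVersion("migvar")),
    timestamp = "(run manifest; re-run with the same config and seed reproduces all outputs)",
    seed = result$config$seed,
    config = result$config[setdiff(names(result$config), "brb")],
    brb = unclass(result$config$brb),
    drops = result$drops,
    units = list(distance = "km", coordinates = "WGS84 lon/lat; planar metres, equal-area azimuthal projection"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null", force = TRUE)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline result: %d individuals, %d seasons\n",
              if (is.null(x$individuals)) 0L else nrow(x$individuals),
              if (is.null(x$season_records)) 0L else nrow(x$season_records)))
  if (!is.null(x$stats) && !is.null(x$stats$overlap_medians))
    cat(sprintf("  non-breeding overlap: median within %.3f, between %.3f (p = %.4g)\n",
                x$stats$overlap_medians["within"],
                x$stats$overlap_medians["between"], x$stats$overlap_test$p))
  for (tr in names(x$stats$repeatability))
    cat(sprintf("  R(%s) = %.3f\n", tr, x$stats$repeatability[[tr]]$R))
  invisible(x)
}

#' Generate synthetic tracks and write them to disk
#'
#' Wraps [generate_population()] and writes the track file plus ground-truth
#' tables.
#'
#' @param config a [population_config()].
#' @param out_dir output directory.
#' @return (invisibly) the generation result.
#' @export
simulate_tracks <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gen <- generate_population(config)
  write_tracks(gen$fixes, file.path(out_dir, "tracks.csv"))
  write_truth(gen$truth, file.path(out_dir, "truth.csv"))
  invisible(gen)
}
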
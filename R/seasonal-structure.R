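# cell index of each point on a grid; NA when outside the extent.
# Fixes exactly on a cell edge belong to the cell whose lower-left corner
# they touch (floor rule), making polygon membership boundary-inclusive on
# the lower/left edges and deterministic everywhere.
point_cell_index <- function(x, y, g) {
  i <- floor((x - g$x0) / g$cell) + 1
  j <- floor((y - g$y0) / g$cell) + 1
  ok <- i >= 1 & i <= g$nx & j >= 1 & j <= g$ny
  idx <- ifelse(ok, (j - 1) * g$nx + i, NA_real_)
  as.integer(idx)
}

ud_grid <- function(ud) list(x0 = ud$x0, y0 = ud$y0, cell = ud$cell,
                             nx = ud$nx, ny = ud$ny)

# mass-weighted centroid (planar metres) of a cell set of a UD
cells_centroid <- function(ud, member_idx) {
  ij <- arrayInd(member_idx, c(ud$nx, ud$ny))
  wts <- ud$z[member_idx]
  if (sum(wts) <= 0) wts <- rep(1, length(member_idx))
  cx <- ud$x0 + (ij[, 1] - 0.5) * ud$cell
  cy <- ud$y0 + (ij[, 2] - 0.5) * ud$cell
  c(x = sum(cx * wts) / sum(wts), y = sum(cy * wts) / sum(wts))
}

in_winter_months <- function(timestamps) {
  m <- as.integer(format(timestamps, "%m"))
  m == 12L | m <= 3L
}

#' Extract core areas from a seasonal utilization distribution
#'
#' Core areas are the connected components of the 50\% isopleth of the
#' seasonal UD: coarse-scale regions where the bird wintered or stopped over.
#' Dwell time is counted in 12-h subsampled fixes (0.5 day per fix inside the
#' component), matching the data basis of the UD; winter dwell is restricted
#' to December 1 to March 31 (UTC dates).
#'
#' @param ud the seasonal `grid_ud` (from 12-h fixes).
#' @param fixes_12h the subsampled fixes the UD was built from.
#' @param level isopleth level (default 0.5).
#' @return list of `core_area` objects: `member_idx` (cell indices),
#'   `centroid_xy` (metres), `centroid_lonlat` (if the UD carries a
#'   projection), `dwell_days`, `dwell_winter_days`, `role` (NA until
#'   assigned).
#' @export
extract_core_areas <- function(ud, fixes_12h, level = 0.5) {
  iso <- isopleth(ud, level)
  g <- ud_grid(ud)
  cell_of <- point_cell_index(fixes_12h$x, fixes_12h$y, g)
  winterish <- in_winter_months(fixes_12h$timestamp)
  lapply(seq_len(iso$n_components), function(k) {
    memb <- iso$member_idx[iso$component == k]
    inside <- !is.na(cell_of) & cell_of %in% memb
    cen <- cells_centroid(ud, memb)
    ll <- if (!is.null(ud$proj))
      drop(laea_inverse(cen["x"], cen["y"], ud$proj)) else c(lon = NA, lat = NA)
    structure(list(member_idx = memb, centroid_xy = cen,
                   centroid_lonlat = c(lon = unname(ll[1]), lat = unname(ll[2])),
                   dwell_days = 0.5 * sum(inside),
                   dwell_winter_days = 0.5 * sum(inside & winterish),
                   role = NA_character_),
              class = "core_area")
  })
}

#' Assign the wintering area among a season's core areas
#'
#' The wintering area is the core area with the most dwell time between
#' December 1 and March 31. Exact ties are broken in favour of the core area
#' farther from the colony. All other core areas are labelled stopovers.
#'
#' @param cores list of `core_area` objects from [extract_core_areas()].
#' @param colony `c(lon, lat)` of the breeding colony.
#' @return the input list with `role` filled; attribute `winter` holds the
#'   index of the wintering area.
#' @export
assign_winter <- function(cores, colony) {
  if (length(cores) == 0L) stop("no core areas")
  wdwell <- vapply(cores, function(a) a$dwell_winter_days, numeric(1))
  if (max(wdwell) <= 0) stop("no winter residence (no December-March dwell in any core area)")
  best <- which(abs(wdwell - max(wdwell)) < 1e-9)
  if (length(best) > 1L) {
    d <- vapply(cores[best], function(a)
      great_circle_km(a$centroid_lonlat["lon"], a$centroid_lonlat["lat"],
                      colony[1], colony[2]), numeric(1))
    best <- best[which.max(d)]
  } else best <- best[1L]
  for (k in seq_along(cores))
    cores[[k]]$role <- if (k == best) "winter" else "stopover"
  structure(cores, winter = best)
}

#' Group fragmented wintering areas across years
#'
#' When the wintering polygon of one year overlaps two or more 50\%-isopleth
#' polygons of another year, those fragments are unioned into a single
#' wintering area for that year. The grouping is applied symmetrically over
#' all ordered year pairs and iterated to a fixed point, so it is idempotent.
#' All years must be on a common grid (see [resample_common()]).
#'
#' @param years list, one element per year, each a list with elements `ud`
#'   (the seasonal `grid_ud`), `cores` (from [assign_winter()]) and `winter`
#'   (index of the wintering core area).
#' @return the input list with fragments merged and centroids/dwells updated.
#' @export
merge_fragmented_winters <- function(years) {
  if (length(years) < 2L) return(years)
  merge_into <- function(yr, ks) {
    # union core areas ks of year yr into one
    keep <- ks[1L]
    others <- ks[-1L]
    a <- yr$cores[[keep]]
    for (o in yr$cores[others]) {
      a$member_idx <- sort(unique(c(a$member_idx, o$member_idx)))
      a$dwell_days <- a$dwell_days + o$dwell_days
      a$dwell_winter_days <- a$dwell_winter_days + o$dwell_winter_days
    }
    a$centroid_xy <- cells_centroid(yr$ud, a$member_idx)
    if (!is.null(yr$ud$proj)) {
      ll <- drop(laea_inverse(a$centroid_xy["x"], a$centroid_xy["y"], yr$ud$proj))
      a$centroid_lonlat <- c(lon = unname(ll[1]), lat = unname(ll[2]))
    }
    a$role <- if (any(vapply(yr$cores[ks], function(cc)
      identical(cc$role, "winter"), logical(1)))) "winter" else a$role
    yr$cores[[keep]] <- a
    yr$cores <- yr$cores[-others]
    yr$winter <- which(vapply(yr$cores, function(cc)
      identical(cc$role, "winter"), logical(1)))[1L]
    yr
  }
  repeat {
    changed <- FALSE
    for (a_i in seq_along(years)) for (b_i in seq_along(years)) {
      if (a_i == b_i) next
      wa <- years[[a_i]]$cores[[years[[a_i]]$winter]]$member_idx
      hits <- which(vapply(years[[b_i]]$cores, function(cc)
        length(intersect(wa, cc$member_idx)) > 0L, logical(1)))
      if (length(hits) >= 2L) {
        years[[b_i]] <- merge_into(years[[b_i]], hits)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  years
}

#' Derive the phenology record for one season
#'
#' Colony departure and arrival come from the season window. Winter arrival
#' and departure are the dates of the first and last fix (full rate) inside
#' the wintering-area polygon. A trait whose transition is spanned by a data
#' gap longer than `transition_gap_days` is flagged missing rather than
#' reported.
#'
#' @param season a `season_window` (full-rate fixes, projected).
#' @param winter_area a `core_area` with role `"winter"`.
#' @param grid the grid geometry of the UD the winter area came from.
#' @param transition_gap_days gap length (days) beyond which a transition is
#'   considered unresolved (default 1).
#' @return a one-row `season_record` data frame: the four dates (class Date,
#'   NA when flagged), their timestamps, winter centroid, and flags.
#' @export
phenology <- function(season, winter_area, grid, transition_gap_days = 1) {
  fx <- season$fixes
  cell_of <- point_cell_index(fx$x, fx$y, grid)
  inside <- !is.na(cell_of) & cell_of %in% winter_area$member_idx
  if (!any(inside)) stop("no fix inside the wintering area polygon")
  i_arr <- which(inside)[1L]
  i_dep <- which(inside)[sum(inside)]
  tt <- as.numeric(fx$timestamp)
  gap_before <- function(i) if (i <= 1L) 0 else (tt[i] - tt[i - 1L]) / 86400
  gap_after <- function(i) if (i >= nrow(fx)) 0 else (tt[i + 1L] - tt[i]) / 86400
  flag_win_arr <- gap_before(i_arr) > transition_gap_days
  flag_win_dep <- gap_after(i_dep) > transition_gap_days
  flag_col_dep <- gap_after(1L) > transition_gap_days
  flag_col_arr <- gap_before(nrow(fx)) > transition_gap_days
  as_d <- function(ts, flag) if (flag) as.Date(NA) else as.Date(ts, tz = "UTC")
  rec <- data.frame(
    individual_id = season$individual_id,
    season = season$label,
    colony_departure = as_d(season$colony_departure, flag_col_dep),
    winter_arrival = as_d(fx$timestamp[i_arr], flag_win_arr),
    winter_departure = as_d(fx$timestamp[i_dep], flag_win_dep),
    colony_arrival = as_d(season$colony_arrival, flag_col_arr),
    winter_lon = unname(winter_area$centroid_lonlat["lon"]),
    winter_lat = unname(winter_area$centroid_lonlat["lat"]),
    n_flagged = sum(flag_col_dep, flag_win_arr, flag_win_dep, flag_col_arr),
    stringsAsFactors = FALSE)
  attr(rec, "timestamps") <- list(
    colony_departure = season$colony_departure,
    winter_arrival = fx$timestamp[i_arr],
    winter_departure = fx$timestamp[i_dep],
    colony_arrival = season$colony_arrival)
  class(rec) <- c("season_record", "data.frame")
  rec
}

#' Migration distance of a season
#'
#' Great-circle distance (km) between the breeding colony and the
#' mass-weighted centroid of the wintering area. The per-individual distance
#' covariate used in the regressions is the median of this across years.
#'
#' @param colony `c(lon, lat)`.
#' @param winter_area a `core_area`.
#' @return distance in km.
#' @export
migration_distance <- function(colony, winter_area) {
  great_circle_km(colony[1], colony[2],
                  winter_area$centroid_lonlat["lon"],
                  winter_area$centroid_lonlat["lat"])
}

#' Detect a wintering-area switch
#'
#' TRUE when any pair of the individual's yearly wintering areas has no
#' overlapping cells (on a common grid). Switchers are excluded from
#' distance regressions, individual repeatability and the variation metrics,
#' but retained in population repeatability of timing.
#'
#' @param winter_cell_sets list (one per year) of wintering-area cell index
#'   vectors on a common grid.
#' @return logical.
#' @export
detect_strategy_switch <- function(winter_cell_sets) {
  n <- length(winter_cell_sets)
  if (n < 2L) return(FALSE)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    if (length(intersect(winter_cell_sets[[i]], winter_cell_sets[[j]])) == 0L)
      return(TRUE)
  FALSE
}

#' Full seasonal analysis for one individual
#'
#' Runs the per-individual chain: 12-h subsampling, seasonal kernel UD,
#' 50\% core areas, winter assignment, cross-year fragment grouping,
#' phenology, migration distance, seasonal (95\% UD) overlap and switch
#' detection. Seasons that fail a stage (no December-March residence, no fix
#' in the wintering polygon) are dropped with a reason.
#'
#' @param seasons list of `season_window` objects for one individual
#'   (projected fixes), already filtered by [apply_inclusion_filters()].
#' @param colony `c(lon, lat)`.
#' @param cell seasonal grid resolution in metres (default 10,000).
#' @param h kernel bandwidth in metres (default 100,000).
#' @param subsample_h subsampling interval in hours (default 12).
#' @param overlap_level truncation level for the seasonal overlap
#'   (default 0.95).
#' @param core_level isopleth level defining core areas (default 0.5).
#' @param proj projection used for the fixes.
#' @return list with `records` (season_record rows bound together), `overlap`
#'   (from [seasonal_overlap()], NULL if < 2 usable seasons), `switched`,
#'   `median_distance_km`, `years` (per-season detail: ud, cores, winter),
#'   `dropped` (reasons).
#' @export
analyze_individual <- function(seasons, colony, cell = 10000, h = 100000,
                               subsample_h = 12, overlap_level = 0.95,
                               core_level = 0.5, proj = NULL) {
  if (length(seasons) == 0L) stop("no seasons supplied")
  if (is.null(proj)) proj <- attr(seasons[[1L]]$fixes, "proj")
  dropped <- character(0)

  # one shared grid so cores, overlap and switch detection are comparable
  allx <- unlist(lapply(seasons, function(s) range(s$fixes$x)))
  ally <- unlist(lapply(seasons, function(s) range(s$fixes$y)))
  g <- grid_spec(min(allx), max(allx), min(ally), max(ally),
                 cell = cell, pad = 3 * h)

  years <- list()
  for (s in seasons) {
    fx12 <- subsample_fixes(s$fixes, subsample_h)
    res <- tryCatch({
      ud <- kde_ud(fx12, grid = g, h = h, proj = proj)
      cores <- extract_core_areas(ud, fx12, level = core_level)
      cores <- assign_winter(cores, colony)
      list(season = s, fixes12 = fx12, ud = ud, cores = cores,
           winter = attr(cores, "winter"))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      dropped <- c(dropped, sprintf("%s: %s", s$label, conditionMessage(res)))
    } else years[[s$label]] <- res
  }
  if (length(years) == 0L)
    return(list(records = NULL, overlap = NULL, switched = NA,
                median_distance_km = NA_real_, years = list(),
                dropped = dropped))

  years <- merge_fragmented_winters(years)

  records <- NULL
  for (lab in names(years)) {
    yr <- years[[lab]]
    wa <- yr$cores[[yr$winter]]
    rec <- tryCatch(phenology(yr$season, wa, ud_grid(yr$ud)),
                    error = function(e) e)
    if (inherits(rec, "error")) {
      dropped <- c(dropped, sprintf("%s: %s", lab, conditionMessage(rec)))
      next
    }
    rec$migration_distance_km <- unname(migration_distance(colony, wa))
    years[[lab]]$record <- rec
    records <- rbind(records, rec)
  }

  usable <- names(years)[vapply(years, function(y) !is.null(y$record), logical(1))]
  overlap <- if (length(usable) >= 2L) {
    uds <- lapply(years[usable], function(y) y$ud)
    seasonal_overlap(uds, level = overlap_level)
  } else NULL
  switched <- detect_strategy_switch(lapply(years[usable], function(y)
    y$cores[[y$winter]]$member_idx))
  list(records = records, overlap = overlap, switched = switched,
       median_distance_km = if (is.null(records)) NA_real_ else
         stats::median(records$migration_distance_km),
       years = years, dropped = dropped)
}
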
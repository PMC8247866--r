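# Resample a polyline (n x 2 matrix) to m points uniformly spaced by arc
# length. Degenerate (zero-length) polylines repeat the single location.
resample_polyline <- function(pts, m) {
  if (nrow(pts) == 1L) return(pts[rep(1L, m), , drop = FALSE])
  seg <- sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  if (L <= 0) return(pts[rep(1L, m), , drop = FALSE])
  target <- seq(0, L, length.out = m)
  xi <- stats::approx(s, pts[, 1], xout = target, ties = "ordered")$y
  yi <- stats::approx(s, pts[, 2], xout = target, ties = "ordered")$y
  matrix(c(xi, yi), ncol = 2)
}

# For each query point (q x 2), the nearest point on the polyline (n x 2),
# continuous over segments. Returns list(points = q x 2, dist2 = q).
nearest_on_polyline <- function(query, pts) {
  if (nrow(pts) == 1L) {
    d2 <- (query[, 1] - pts[1, 1])^2 + (query[, 2] - pts[1, 2])^2
    return(list(points = pts[rep(1L, nrow(query)), , drop = FALSE], dist2 = d2))
  }
  p1x <- pts[-nrow(pts), 1]; p1y <- pts[-nrow(pts), 2]
  dx <- diff(pts[, 1]); dy <- diff(pts[, 2])
  len2 <- dx^2 + dy^2
  len2[len2 == 0] <- 1e-300
  # t = clamp(((q - p1) . d) / |d|^2): q x nseg matrices
  tx <- outer(query[, 1], p1x, "-")
  ty <- outer(query[, 2], p1y, "-")
  tmat <- sweep(sweep(tx, 2, dx, "*") + sweep(ty, 2, dy, "*"), 2, len2, "/")
  tmat[tmat < 0] <- 0; tmat[tmat > 1] <- 1
  fx <- sweep(tmat, 2, dx, "*"); fx <- sweep(fx, 2, p1x, "+")
  fy <- sweep(tmat, 2, dy, "*"); fy <- sweep(fy, 2, p1y, "+")
  d2 <- (fx - query[, 1])^2 + (fy - query[, 2])^2
  best <- max.col(-d2, ties.method = "first")
  ii <- cbind(seq_len(nrow(query)), best)
  list(points = cbind(fx[ii], fy[ii]), dist2 = d2[ii])
}

#' Extract the autumn and spring migration legs of a season
#'
#' The autumn leg runs from colony departure to winter arrival, the spring
#' leg from winter departure to colony arrival (full-rate fixes). Every
#' contiguous visit to a core area is replaced by a single point at the core
#' area's centroid, so legs consist only of migratory-flight fixes. A leg
#' with a gap longer than `max_gap_h` between consecutive fixes outside core
#' areas is dropped with a reason.
#'
#' @param season a `season_window` with projected full-rate fixes.
#' @param record the season's `season_record` (for the transition
#'   timestamps).
#' @param cores list of the season's `core_area` objects (winter and
#'   stopovers).
#' @param grid grid geometry of the UD the core areas came from.
#' @param max_gap_h maximum tolerated gap outside core areas, hours
#'   (default 24).
#' @return list with elements `autumn` and `spring`, each either a
#'   `migration_leg` (list: `points` n x 2 metres, `direction`,
#'   `individual_id`, `season`) or `NULL` with the drop reason recorded in
#'   attribute `dropped`.
#' @export
extract_legs <- function(season, record, cores, grid, max_gap_h = 24) {
  ts <- attr(record, "timestamps")
  fx <- season$fixes
  cell_of <- point_cell_index(fx$x, fx$y, grid)
  # only stopover visits are collapsed to centroids: the legs begin and end
  # at the wintering-area boundary, so the winter polygon is never entered
  # mid-leg
  cores <- cores[vapply(cores, function(a)
    !identical(a$role, "winter"), logical(1))]
  core_cells <- lapply(cores, function(a) a$member_idx)
  in_core <- rep(0L, nrow(fx))  # 0 = outside, k = inside core k
  for (k in seq_along(core_cells)) {
    hit <- !is.na(cell_of) & cell_of %in% core_cells[[k]] & in_core == 0L
    in_core[hit] <- k
  }
  dropped <- character(0)

  build_leg <- function(t_from, t_to, direction) {
    sel <- fx$timestamp >= t_from & fx$timestamp <= t_to
    if (sum(sel) < 2L) {
      dropped <<- c(dropped, sprintf("%s: too few fixes", direction))
      return(NULL)
    }
    sub <- which(sel)
    core_id <- in_core[sub]
    # collapse contiguous core visits to centroid points
    pts <- NULL; is_centroid <- NULL; tprev_out <- NULL; max_gap <- 0
    i <- 1L
    tt <- as.numeric(fx$timestamp[sub])
    while (i <= length(sub)) {
      if (core_id[i] == 0L) {
        pts <- rbind(pts, c(fx$x[sub[i]], fx$y[sub[i]]))
        is_centroid <- c(is_centroid, FALSE)
        # gap rule: consecutive outside-core fixes
        if (i > 1L && core_id[i - 1L] == 0L)
          max_gap <- max(max_gap, tt[i] - tt[i - 1L])
        i <- i + 1L
      } else {
        k <- core_id[i]
        while (i <= length(sub) && core_id[i] == k) i <- i + 1L
        cen <- cores[[k]]$centroid_xy
        pts <- rbind(pts, c(unname(cen["x"]), unname(cen["y"])))
        is_centroid <- c(is_centroid, TRUE)
      }
    }
    if (max_gap / 3600 > max_gap_h) {
      dropped <<- c(dropped, sprintf(
        "%s: %.1f-h gap outside core areas exceeds %g h",
        direction, max_gap / 3600, max_gap_h))
      return(NULL)
    }
    if (is.null(pts) || nrow(pts) < 2L) {
      dropped <<- c(dropped, sprintf("%s: too few route points", direction))
      return(NULL)
    }
    structure(list(points = unname(pts), direction = direction,
                   individual_id = season$individual_id,
                   season = season$label, centroid_point = is_centroid),
              class = "migration_leg")
  }

  autumn <- if (!is.null(ts$winter_arrival))
    build_leg(ts$colony_departure, ts$winter_arrival, "autumn") else NULL
  spring <- if (!is.null(ts$winter_departure))
    build_leg(ts$winter_departure, ts$colony_arrival, "spring") else NULL
  structure(list(autumn = autumn, spring = spring), dropped = dropped)
}

#' Mean migration route across years
#'
#' Estimates a 500-point mean route that minimizes the squared distance to
#' the nearest-neighbour locations on the yearly migration legs. The mean is
#' initialized as the arc-length-uniform resampling of the leg-wise
#' coordinate average, then refined by sweeps that (1) move every mean point
#' to the centroid of its nearest point on each leg's polyline (continuous
#' point-to-segment matching), and (2) re-space the points uniformly by arc
#' length. A sweep is accepted only if the objective (mean over mean points
#' of the mean squared nearest-neighbour distance) does not increase;
#' iteration stops when the maximum point displacement falls below `tol_km`
#' or after `max_iter` sweeps.
#'
#' @param legs list of at least two `migration_leg` objects of the same
#'   direction (or bare n x 2 coordinate matrices in metres).
#' @param n_points number of mean-route points (default 500).
#' @param tol_km convergence tolerance on point displacement, km (default 1).
#' @param max_iter maximum sweeps (default 200).
#' @return a `mean_route`: list with `points` (n_points x 2, km),
#'   `per_point_variance` (km^2), `route_variation_km`,
#'   `route_variation_km2` (mean variance), `objective` (km^2), `direction`,
#'   `converged`, `n_iter`.
#' @export
mean_route <- function(legs, n_points = 500, tol_km = 1, max_iter = 200) {
  if (length(legs) < 2L) stop("need at least 2 legs (multi-year data)")
  direction <- NA_character_
  mats <- lapply(legs, function(l) {
    if (inherits(l, "migration_leg")) {
      direction <<- l$direction
      l$points / 1000  # work in km
    } else as.matrix(l) / 1000
  })
  if (any(vapply(mats, nrow, integer(1)) < 2L))
    stop("each leg needs at least 2 points")

  init <- lapply(mats, resample_polyline, m = n_points)
  avg <- Reduce(`+`, init) / length(init)
  mr <- resample_polyline(avg, n_points)

  objective <- function(m) {
    d2 <- vapply(mats, function(p) nearest_on_polyline(m, p)$dist2,
                 numeric(nrow(m)))
    mean(rowMeans(d2))
  }
  obj <- objective(mr)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    nn <- lapply(mats, function(p) nearest_on_polyline(mr, p)$points)
    cand <- Reduce(`+`, nn) / length(nn)
    cand <- resample_polyline(cand, n_points)
    cand_obj <- objective(cand)
    if (cand_obj > obj + 1e-12) break  # re-spacing worsened the fit: stop
    disp <- max(sqrt((cand[, 1] - mr[, 1])^2 + (cand[, 2] - mr[, 2])^2))
    mr <- cand
    obj <- cand_obj
    if (disp < tol_km) { converged <- TRUE; break }
  }

  d2 <- vapply(mats, function(p) nearest_on_polyline(mr, p)$dist2,
               numeric(nrow(mr)))
  per_point_var <- rowMeans(d2)
  structure(list(points = mr, per_point_variance = per_point_var,
                 route_variation_km2 = mean(per_point_var),
                 route_variation_km = sqrt(mean(per_point_var)),
                 objective = obj, direction = direction,
                 converged = converged, n_iter = iter,
                 n_legs = length(mats)),
            class = "mean_route")
}

#' @export
print.mean_route <- function(x, ...) {
  cat(sprintf("mean %s route: %d points from %d legs, variation %.1f km (%s after %d sweeps)\n",
              ifelse(is.na(x$direction), "migration", x$direction),
              nrow(x$points), x$n_legs, x$route_variation_km,
              ifelse(x$converged, "converged", "not converged"), x$n_iter))
  invisible(x)
}

#' Route variation around a mean route
#'
#' Per mean-route point, the variance is the mean over legs of the squared
#' planar distance (km^2) from the point to that leg's nearest location. The
#' headline metric is the square root of the mean per-point variance, in km;
#' the mean variance itself (km^2) is also returned.
#'
#' @param route a `mean_route`.
#' @param legs the legs it was fitted to.
#' @return list with `per_point_variance` (km^2), `variation_km2`,
#'   `variation_km`.
#' @export
route_variation <- function(route, legs) {
  mats <- lapply(legs, function(l)
    if (inherits(l, "migration_leg")) l$points / 1000 else as.matrix(l) / 1000)
  d2 <- vapply(mats, function(p) nearest_on_polyline(route$points, p)$dist2,
               numeric(nrow(route$points)))
  v <- rowMeans(d2)
  list(per_point_variance = v, variation_km2 = mean(v),
       variation_km = sqrt(mean(v)))
}

#' Between-individual route variation for a pair
#'
#' Fits a mean route to one selected leg from each of two paired individuals
#' and returns the same variation metric as within individuals. Symmetric in
#' the pair order.
#'
#' @param leg_a,leg_b one `migration_leg` per individual, same direction.
#' @param ... passed to [mean_route()].
#' @return the fitted `mean_route` (carrying `route_variation_km`).
#' @export
between_individual_route_variation <- function(leg_a, leg_b, ...) {
  mean_route(list(leg_a, leg_b), ...)
}
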
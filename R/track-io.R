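#' Read GPS track fixes from delimited text
#'
#' Reads a comma- or tab-separated file with one GPS fix per row, parses
#' timestamps as UTC, drops malformed rows (unparseable timestamp,
#' latitude outside \[-90, 90\], longitude outside \[-180, 180\], missing id),
#' de-duplicates on (individual, timestamp) keeping the first occurrence, and
#' sorts by individual then time.
#'
#' @param path path to a delimited text file with a header row.
#' @param column_map named character vector mapping the canonical column names
#'   `individual_id`, `timestamp`, `lon`, `lat` to the names used in the file.
#'   Defaults to the identity mapping.
#' @param sep field separator; `NULL` (default) auto-detects comma vs tab from
#'   the header line.
#' @return a `track_fixes` data frame with columns `individual_id` (character),
#'   `timestamp` (POSIXct, UTC), `lon`, `lat`, carrying attributes
#'   `n_rejected` (count of dropped malformed rows) and `n_duplicates`.
#' @export
read_tracks <- function(path, column_map = NULL, sep = NULL) {
  if (!file.exists(path)) stop("track file not found: ", path)
  if (is.null(sep)) {
    hdr <- readLines(path, n = 1L)
    sep <- if (grepl("\t", hdr)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, comment.char = "",
                           colClasses = "character")
  canon <- c("individual_id", "timestamp", "lon", "lat")
  cmap <- stats::setNames(canon, canon)
  if (!is.null(column_map)) cmap[names(column_map)] <- column_map
  missing_cols <- cmap[!(cmap %in% names(raw))]
  if (length(missing_cols) > 0L)
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  parse_ts <- function(x) {
    out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
    for (fmt in c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                  "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M", "%Y-%m-%d")) {
      todo <- is.na(out)
      if (!any(todo)) break
      out[todo] <- as.POSIXct(strptime(x[todo], fmt, tz = "UTC"), tz = "UTC")
    }
    out
  }
  df <- data.frame(
    individual_id = raw[[cmap["individual_id"]]],
    timestamp = parse_ts(raw[[cmap["timestamp"]]]),
    lon = suppressWarnings(as.numeric(raw[[cmap["lon"]]])),
    lat = suppressWarnings(as.numeric(raw[[cmap["lat"]]])),
    stringsAsFactors = FALSE)
  ok <- !is.na(df$timestamp) & !is.na(df$lon) & !is.na(df$lat) &
    df$lat >= -90 & df$lat <= 90 & df$lon >= -180 & df$lon <= 180 &
    !is.na(df$individual_id) & nzchar(df$individual_id)
  n_rejected <- sum(!ok)
  df <- df[ok, , drop = FALSE]
  dup <- duplicated(df[, c("individual_id", "timestamp")])
  n_dup <- sum(dup)
  df <- df[!dup, , drop = FALSE]
  df <- df[order(df$individual_id, df$timestamp), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, n_rejected = n_rejected, n_duplicates = n_dup,
            class = c("track_fixes", "data.frame"))
}

#' Write track fixes to delimited text
#'
#' Inverse of [read_tracks()]; timestamps are written as ISO-8601 UTC.
#'
#' @param fixes a `track_fixes` data frame.
#' @param path output path.
#' @param sep field separator (default comma).
#' @export
write_tracks <- function(fixes, path, sep = ",") {
  out <- data.frame(
    individual_id = fixes$individual_id,
    timestamp = format(fixes$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    lon = sprintf("%.6f", fixes$lon),
    lat = sprintf("%.6f", fixes$lat),
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Earth radius (km) used for all spherical geometry in the package.
EARTH_RADIUS_KM <- 6371

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6,371 km. Symmetric,
#' non-negative, and zero only for identical points.
#'
#' @param lon1,lat1,lon2,lat2 coordinates in decimal degrees (vectorized).
#' @return distance(s) in km.
#' @export
great_circle_km <- function(lon1, lat1, lon2, lat2) {
  p1 <- lat1 * pi / 180; p2 <- lat2 * pi / 180
  dp <- (lat2 - lat1) * pi / 180
  dl <- (lon2 - lon1) * pi / 180
  a <- sin(dp / 2)^2 + cos(p1) * cos(p2) * sin(dl / 2)^2
  a <- pmin(pmax(a, 0), 1)
  2 * EARTH_RADIUS_KM * asin(sqrt(a))
}

#' Define an equal-area azimuthal projection
#'
#' Spherical Lambert azimuthal equal-area projection centred at
#' (`lon0`, `lat0`), on a sphere of radius 6,371 km, with planar coordinates
#' in metres. The projection centre maps to (0, 0).
#'
#' @param lon0,lat0 projection centre in decimal degrees.
#' @return a `laea_proj` object.
#' @export
laea_projection <- function(lon0, lat0) {
  structure(list(lon0 = lon0, lat0 = lat0, R = EARTH_RADIUS_KM * 1000),
            class = "laea_proj")
}

#' @export
print.laea_proj <- function(x, ...) {
  cat(sprintf("Lambert azimuthal equal-area projection, centre (%.4f, %.4f), R = %.0f m\n",
              x$lon0, x$lat0, x$R))
  invisible(x)
}

#' Forward projection: lon/lat to planar metres
#'
#' @param lon,lat coordinates in decimal degrees (vectorized).
#' @param proj a `laea_proj` object.
#' @return two-column matrix of x, y in metres.
#' @export
laea_forward <- function(lon, lat, proj) {
  l0 <- proj$lon0 * pi / 180; p0 <- proj$lat0 * pi / 180
  l <- lon * pi / 180; p <- lat * pi / 180
  denom <- 1 + sin(p0) * sin(p) + cos(p0) * cos(p) * cos(l - l0)
  bad <- which(denom < 1e-12)
  if (length(bad) > 0L)
    stop("projection undefined (antipodal to centre) at fix index ", bad[1L],
         " (lon = ", lon[bad[1L]], ", lat = ", lat[bad[1L]], ")")
  k <- sqrt(2 / denom)
  x <- proj$R * k * cos(p) * sin(l - l0)
  y <- proj$R * k * (cos(p0) * sin(p) - sin(p0) * cos(p) * cos(l - l0))
  cbind(x = x, y = y)
}

#' Inverse projection: planar metres to lon/lat
#'
#' @param x,y planar coordinates in metres (vectorized).
#' @param proj a `laea_proj` object.
#' @return two-column matrix of lon, lat in decimal degrees.
#' @export
laea_inverse <- function(x, y, proj) {
  l0 <- proj$lon0 * pi / 180; p0 <- proj$lat0 * pi / 180
  rho <- sqrt(x^2 + y^2)
  c_ang <- 2 * asin(pmin(1, rho / (2 * proj$R)))
  lat <- ifelse(rho < 1e-12, proj$lat0,
                asin(cos(c_ang) * sin(p0) + y * sin(c_ang) * cos(p0) / rho) * 180 / pi)
  lon <- ifelse(rho < 1e-12, proj$lon0,
                (l0 + atan2(x * sin(c_ang),
                            rho * cos(p0) * cos(c_ang) - y * sin(p0) * sin(c_ang))) * 180 / pi)
  lon <- ((lon + 180) %% 360) - 180
  cbind(lon = lon, lat = lat)
}

#' Project track fixes onto the working planar coordinate system
#'
#' Adds `x`, `y` columns (metres) to a fix table using an equal-area
#' azimuthal projection.
#'
#' @param fixes a `track_fixes` data frame with `lon`, `lat`.
#' @param proj a `laea_proj` object; if `NULL`, a projection centred at the
#'   mean fix location is used.
#' @return the fixes with `x`, `y` columns and a `proj` attribute.
#' @export
project_tracks <- function(fixes, proj = NULL) {
  if (is.null(proj))
    proj <- laea_projection(mean(fixes$lon), mean(fixes$lat))
  xy <- laea_forward(fixes$lon, fixes$lat, proj)
  fixes$x <- xy[, 1]
  fixes$y <- xy[, 2]
  attr(fixes, "proj") <- proj
  fixes
}

#' Subsample fixes to a regular interval
#'
#' Bins fixes into consecutive intervals anchored at the first fix and keeps,
#' in each non-empty bin, the fix nearest the bin centre (earlier fix on
#' ties). Empty bins stay empty: no interpolation across data holes.
#'
#' @param fixes time-ordered fixes for one individual (or one season).
#' @param interval_h bin width in hours (default 12).
#' @return the subsampled fixes, same columns.
#' @export
subsample_fixes <- function(fixes, interval_h = 12) {
  if (nrow(fixes) <= 1L) return(fixes)
  t0 <- as.numeric(fixes$timestamp[1L])
  rel <- (as.numeric(fixes$timestamp) - t0) / 3600
  bin <- floor(rel / interval_h)
  centre_off <- abs(rel - (bin + 0.5) * interval_h)
  ord <- order(bin, centre_off, rel)  # per bin: nearest centre, then earliest
  keep_first <- !duplicated(bin[ord])
  keep <- sort(ord[keep_first])
  fixes[keep, , drop = FALSE]
}

season_label <- function(dep_date) {
  y <- as.integer(format(dep_date, "%Y"))
  sprintf("%d-%02d", y, (y + 1) %% 100)
}

#' Split an individual's track into non-breeding season windows
#'
#' A non-breeding season runs from colony departure (last fix within
#' `radius_km` of the colony before a sustained absence following the breeding
#' anchor window) to colony arrival (first fix within the radius at the end of
#' that absence). Colony presence shorter than `sustained_days` does not
#' terminate a season (brief mid-season returns are ignored), and absences
#' shorter than `absence_days` do not start one (foraging excursions).
#'
#' @param fixes time-ordered fixes for one individual (lon/lat required).
#' @param colony length-2 numeric `c(lon, lat)` of the breeding colony.
#' @param radius_km colony radius in km, boundary inclusive (default 10).
#' @param anchor_window character `c(start, end)` as `"mm-dd"`; the breeding
#'   anchor window (default 1 May to 15 July). A season must follow a colony
#'   residence that overlaps an anchor window.
#' @param absence_days minimum absence span to open a season (default 7).
#' @param sustained_days minimum colony presence span to close a season
#'   (default 7).
#' @return list of `season_window` objects (possibly empty), with attribute
#'   `resident = TRUE` when the individual never left the colony radius.
#' @export
split_seasons <- function(fixes, colony, radius_km = 10,
                          anchor_window = c("05-01", "07-15"),
                          absence_days = 7, sustained_days = 7) {
  n <- nrow(fixes)
  if (n < 2L) return(structure(list(), resident = FALSE))
  d_col <- great_circle_km(fixes$lon, fixes$lat, colony[1], colony[2])
  inside <- d_col <= radius_km
  if (all(inside))
    return(structure(list(), resident = TRUE))
  tt <- as.numeric(fixes$timestamp)

  # maximal runs of consecutive inside/outside fixes
  r <- rle(inside)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts, end = ends, inside = r$values)
  runs$span_days <- (tt[runs$end] - tt[runs$start]) / 86400
  # bridge gap spans: an outside run's effective span includes the time from
  # the last inside fix before it to the first inside fix after it
  for (k in seq_len(nrow(runs))) {
    if (!runs$inside[k]) {
      t_a <- if (k > 1L) tt[runs$end[k - 1L]] else tt[runs$start[k]]
      t_b <- if (k < nrow(runs)) tt[runs$start[k + 1L]] else tt[runs$end[k]]
      runs$span_days[k] <- (t_b - t_a) / 86400
    }
  }

  # merge short absences into residence, short presences into absence
  state <- ifelse(runs$inside, "res", ifelse(runs$span_days >= absence_days,
                                             "abs", "res"))
  # a brief inside touch between two long absences does not close the season
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(runs))) {
      if (runs$inside[k] && state[k] == "res" && runs$span_days[k] < sustained_days &&
          k > 1L && k < nrow(runs) &&
          state[k - 1L] == "abs" && state[k + 1L] == "abs") {
        state[k] <- "abs"; changed <- TRUE
      }
    }
    if (!changed) break
  }

  # collapse to alternating blocks
  blk <- rle(state)
  bend <- cumsum(blk$lengths); bstart <- bend - blk$lengths + 1L
  blocks <- data.frame(state = blk$values,
                       fix_start = runs$start[bstart],
                       fix_end = runs$end[bend])

  anchor_contains <- function(t1, t2) {
    # does [t1, t2] overlap any yearly anchor window?
    y1 <- as.integer(format(as.POSIXct(t1, origin = "1970-01-01", tz = "UTC"), "%Y"))
    y2 <- as.integer(format(as.POSIXct(t2, origin = "1970-01-01", tz = "UTC"), "%Y"))
    for (y in (y1 - 1L):(y2 + 1L)) {
      a <- as.numeric(as.POSIXct(sprintf("%d-%s 00:00:00", y, anchor_window[1]), tz = "UTC"))
      b <- as.numeric(as.POSIXct(sprintf("%d-%s 23:59:59", y, anchor_window[2]), tz = "UTC"))
      if (t1 <= b && t2 >= a) return(TRUE)
    }
    FALSE
  }

  seasons <- list()
  res_idx <- which(blocks$state == "res")
  for (k in res_idx) {
    if (k + 1L > nrow(blocks) || blocks$state[k + 1L] != "abs") next
    if (k + 2L > nrow(blocks) || blocks$state[k + 2L] != "res") next
    # residence block must overlap a breeding anchor window
    if (!anchor_contains(tt[blocks$fix_start[k]], tt[blocks$fix_end[k]])) next
    # departure: last inside fix of residence block k
    in_blk <- blocks$fix_start[k]:blocks$fix_end[k]
    dep_i <- max(in_blk[inside[in_blk]])
    nxt <- blocks$fix_start[k + 2L]:blocks$fix_end[k + 2L]
    arr_i <- min(nxt[inside[nxt]])
    w <- fixes[dep_i:arr_i, , drop = FALSE]
    seasons[[length(seasons) + 1L]] <- structure(list(
      individual_id = fixes$individual_id[1L],
      label = season_label(as.Date(fixes$timestamp[dep_i])),
      colony = colony,
      colony_departure = fixes$timestamp[dep_i],
      colony_arrival = fixes$timestamp[arr_i],
      fixes = w), class = "season_window")
  }
  structure(seasons, resident = FALSE)
}

#' @export
print.season_window <- function(x, ...) {
  cat(sprintf("season %s of %s: %s to %s (%d fixes)\n", x$label,
              x$individual_id, format(x$colony_departure, "%Y-%m-%d"),
              format(x$colony_arrival, "%Y-%m-%d"), nrow(x$fixes)))
  invisible(x)
}

#' Apply the season and individual inclusion filters
#'
#' Drops any season containing a consecutive inter-fix gap longer than
#' `max_gap_days`, then drops individuals left with fewer than `min_seasons`
#' seasons. Both filters are idempotent. Every drop is recorded with its
#' reason in the `drops` attribute.
#'
#' @param seasons list of `season_window` objects (one or more individuals).
#' @param max_gap_days maximum tolerated inter-fix gap in days (default 21);
#'   gaps strictly longer are fatal to the season.
#' @param min_seasons minimum seasons an individual must retain (default 2).
#' @return filtered list with attribute `drops` (data frame:
#'   individual_id, season, reason).
#' @export
apply_inclusion_filters <- function(seasons, max_gap_days = 21, min_seasons = 2) {
  drops <- data.frame(individual_id = character(), season = character(),
                      reason = character(), stringsAsFactors = FALSE)
  keep <- logical(length(seasons))
  for (k in seq_along(seasons)) {
    s <- seasons[[k]]
    gaps <- diff(as.numeric(s$fixes$timestamp)) / 86400
    if (length(gaps) > 0L && max(gaps) > max_gap_days) {
      drops <- rbind(drops, data.frame(
        individual_id = s$individual_id, season = s$label,
        reason = sprintf("gap of %.1f days exceeds %g days", max(gaps), max_gap_days),
        stringsAsFactors = FALSE))
    } else keep[k] <- TRUE
  }
  seasons <- seasons[keep]
  ids <- vapply(seasons, function(s) s$individual_id, character(1))
  cnt <- table(ids)
  low <- names(cnt)[cnt < min_seasons]
  if (length(low) > 0L) {
    for (id in low) {
      labs <- vapply(seasons[ids == id], function(s) s$label, character(1))
      drops <- rbind(drops, data.frame(
        individual_id = id, season = labs,
        reason = sprintf("individual has fewer than %d seasons", min_seasons),
        stringsAsFactors = FALSE))
    }
    seasons <- seasons[!(ids %in% low)]
  }
  structure(seasons, drops = drops)
}
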
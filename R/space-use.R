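#' Construct a grid specification snapped to the shared lattice
#'
#' Grids are always aligned to a global lattice with origin (0, 0) in the
#' working projection, so that any two grids with the same cell size can be
#' embedded into a common grid without mass redistribution.
#'
#' @param xmin,xmax,ymin,ymax bounding box in metres.
#' @param cell cell size in metres.
#' @param pad padding added on every side in metres.
#' @return list with `x0`, `y0` (lower-left corner), `cell`, `nx`, `ny`.
#' @export
grid_spec <- function(xmin, xmax, ymin, ymax, cell, pad = 0) {
  x0 <- floor((xmin - pad) / cell) * cell
  y0 <- floor((ymin - pad) / cell) * cell
  nx <- max(1L, ceiling(((xmax + pad) - x0) / cell))
  ny <- max(1L, ceiling(((ymax + pad) - y0) / cell))
  list(x0 = x0, y0 = y0, cell = cell, nx = as.integer(nx), ny = as.integer(ny))
}

grid_centres_x <- function(g) g$x0 + (seq_len(g$nx) - 0.5) * g$cell
grid_centres_y <- function(g) g$y0 + (seq_len(g$ny) - 0.5) * g$cell

new_grid_ud <- function(g, z, method, h = NA_real_, D = NA_real_,
                        truncation = NULL, proj = NULL) {
  structure(list(x0 = g$x0, y0 = g$y0, cell = g$cell, nx = g$nx, ny = g$ny,
                 z = z, method = method, h = h, D = D,
                 truncation = truncation, proj = proj),
            class = "grid_ud")
}

#' @export
print.grid_ud <- function(x, ...) {
  cat(sprintf("%s utilization distribution: %d x %d grid, %.0f m cells, mass %.6f%s\n",
              x$method, x$nx, x$ny, x$cell, sum(x$z),
              if (is.null(x$truncation)) "" else
                sprintf(" (truncated at %.2f)", x$truncation)))
  invisible(x)
}

#' Fixed-kernel utilization distribution
#'
#' Estimates a gridded UD from projected fixes with an isotropic bivariate
#' normal kernel of standard deviation `h` on each fix. Cell mass is the
#' kernel density at the cell centre times the cell area (fast path) or the
#' exact Gaussian integral over the cell (`exact = TRUE`), averaged over
#' fixes and normalized to total mass 1.
#'
#' @param fixes data frame with projected `x`, `y` columns (metres); at least
#'   5 fixes are required.
#' @param cell grid resolution in metres (default 10,000).
#' @param h kernel bandwidth (standard deviation) in metres (default 100,000).
#' @param pad grid padding beyond the fix bounding box in metres
#'   (default `3 * h`).
#' @param grid optional pre-built grid (from [grid_spec()]) overriding
#'   `cell`/`pad`.
#' @param exact evaluate exact per-cell Gaussian integrals instead of the
#'   centre approximation (default FALSE).
#' @param proj optional projection metadata carried on the result.
#' @return a `grid_ud` with masses summing to 1.
#' @export
kde_ud <- function(fixes, cell = 10000, h = 100000, pad = 3 * h, grid = NULL,
                   exact = FALSE, proj = NULL) {
  if (nrow(fixes) < 5L) stop("insufficient fixes (need at least 5)")
  if (is.null(proj)) proj <- attr(fixes, "proj")
  if (is.null(grid))
    grid <- grid_spec(min(fixes$x), max(fixes$x), min(fixes$y), max(fixes$y),
                      cell = cell, pad = pad)
  xs <- grid_centres_x(grid); ys <- grid_centres_y(grid)
  if (exact) {
    # P(cell) along each axis via pnorm differences, per fix
    ex <- function(centres, mu) {
      lo <- outer(mu, centres - grid$cell / 2, function(m, c) stats::pnorm(c, m, h))
      hi <- outer(mu, centres + grid$cell / 2, function(m, c) stats::pnorm(c, m, h))
      hi - lo
    }
    A <- ex(xs, fixes$x); B <- ex(ys, fixes$y)
    z <- crossprod(A, B)
  } else {
    A <- outer(fixes$x, xs, function(m, c) stats::dnorm(c, m, h))
    B <- outer(fixes$y, ys, function(m, c) stats::dnorm(c, m, h))
    z <- crossprod(A, B) * grid$cell^2
  }
  z <- z / nrow(fixes)
  z <- z / sum(z)
  new_grid_ud(grid, z, method = "fixed-kernel", h = h, proj = proj)
}

#' Isopleth (contour) cell set of a utilization distribution
#'
#' Cells are sorted by mass in decreasing order (ties broken by cell index)
#' and accumulated until at least `level` of the total mass is enclosed. The
#' member cells are dissolved into connected components (edge adjacency).
#'
#' @param ud a `grid_ud`.
#' @param level fraction of mass to enclose, in (0, 1).
#' @return an `isopleth_set`: list with `level`, `cells` (two-column matrix of
#'   cell indices i, j), `component` (integer label per member cell),
#'   `mass` (enclosed mass), `n_components`.
#' @export
isopleth <- function(ud, level) {
  if (!is.numeric(level) || level <= 0 || level > 1)
    stop("level must be in (0, 1]")
  z <- ud$z
  ord <- order(z, decreasing = TRUE)  # stable: ties keep cell-index order
  cs <- cumsum(z[ord])
  total <- cs[length(cs)]
  n_keep <- which(cs >= level * total - 1e-12)[1L]
  member <- ord[seq_len(n_keep)]
  member <- member[z[member] > 0]
  mask <- matrix(FALSE, ud$nx, ud$ny)
  mask[member] <- TRUE
  lab <- label_components(mask)
  ij <- arrayInd(member, c(ud$nx, ud$ny))
  structure(list(level = level, cells = ij, member_idx = member,
                 component = lab[member], mass = sum(z[member]),
                 n_components = max(lab[member])),
            class = "isopleth_set")
}

# connected-component labelling on a logical matrix, rook adjacency
label_components <- function(mask) {
  nx <- nrow(mask); ny <- ncol(mask)
  lab <- matrix(0L, nx, ny)
  cur <- 0L
  idx_all <- which(mask)
  for (start in idx_all) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    lab[start] <- cur
    while (length(stack) > 0L) {
      p <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- (p - 1L) %% nx + 1L
      j <- (p - 1L) %/% nx + 1L
      nb <- integer(0)
      if (i > 1L) nb <- c(nb, p - 1L)
      if (i < nx) nb <- c(nb, p + 1L)
      if (j > 1L) nb <- c(nb, p - nx)
      if (j < ny) nb <- c(nb, p + nx)
      nb <- nb[mask[nb] & lab[nb] == 0L]
      lab[nb] <- cur
      stack <- c(stack, nb)
    }
  }
  lab
}

#' Truncate a utilization distribution at an isopleth level
#'
#' Zeroes all mass outside the `level` isopleth cell set without
#' renormalizing, so the truncated UD sums to approximately `level`. Under
#' this convention the maximum attainable Bhattacharyya affinity between two
#' UDs truncated at 0.95 is 0.95.
#'
#' @param ud a `grid_ud`.
#' @param level truncation level, default 0.95.
#' @return the truncated `grid_ud` (with `truncation` set).
#' @export
truncate_ud <- function(ud, level = 0.95) {
  iso <- isopleth(ud, level)
  z <- matrix(0, ud$nx, ud$ny)
  z[iso$member_idx] <- ud$z[iso$member_idx]
  ud$z <- z
  ud$truncation <- level
  ud
}

#' Bhattacharyya affinity of two gridded UDs
#'
#' BA = sum over cells of sqrt(m1 * m2). Requires both UDs on the identical
#' grid (same origin, cell size and extent); use [resample_common()] first
#' when extents differ. BA is symmetric; it is 1 for an untruncated UD with
#' itself and at most `level` for UDs truncated (un-renormalized) at `level`.
#'
#' @param ud1,ud2 `grid_ud` objects on the same grid.
#' @return affinity in \[0, 1\].
#' @export
bhattacharyya <- function(ud1, ud2) {
  if (ud1$cell != ud2$cell || ud1$x0 != ud2$x0 || ud1$y0 != ud2$y0 ||
      ud1$nx != ud2$nx || ud1$ny != ud2$ny)
    stop("UD grids differ (origin, cell size or extent); resample to a common grid first")
  sum(sqrt(ud1$z * ud2$z))
}

#' Embed several UDs on a common grid
#'
#' All UDs must share the cell size and lie on the shared lattice (as all
#' grids built by [grid_spec()] do). The union extent is used; mass is
#' preserved exactly because cells align.
#'
#' @param uds list of `grid_ud` objects.
#' @return list of `grid_ud` objects on the identical grid.
#' @export
resample_common <- function(uds) {
  cells <- vapply(uds, function(u) u$cell, numeric(1))
  if (length(unique(cells)) != 1L) stop("cell sizes differ")
  cell <- cells[1L]
  off <- vapply(uds, function(u) c(u$x0, u$y0) %% cell, numeric(2))
  if (any(abs(off - off[, 1]) > 1e-6 & abs(abs(off - off[, 1]) - cell) > 1e-6))
    stop("grids are not on a shared lattice")
  x0 <- min(vapply(uds, function(u) u$x0, numeric(1)))
  y0 <- min(vapply(uds, function(u) u$y0, numeric(1)))
  x1 <- max(vapply(uds, function(u) u$x0 + u$nx * u$cell, numeric(1)))
  y1 <- max(vapply(uds, function(u) u$y0 + u$ny * u$cell, numeric(1)))
  nx <- as.integer(round((x1 - x0) / cell))
  ny <- as.integer(round((y1 - y0) / cell))
  g <- list(x0 = x0, y0 = y0, cell = cell, nx = nx, ny = ny)
  lapply(uds, function(u) {
    z <- matrix(0, nx, ny)
    i0 <- as.integer(round((u$x0 - x0) / cell))
    j0 <- as.integer(round((u$y0 - y0) / cell))
    z[i0 + seq_len(u$nx), j0 + seq_len(u$ny)] <- u$z
    new_grid_ud(g, z, method = u$method, h = u$h, D = u$D,
                truncation = u$truncation, proj = u$proj)
  })
}

#' Biased-random-bridge parameters
#'
#' @param t_max_h maximum step duration in hours for bridge interpolation
#'   (default 3).
#' @param l_min_m minimum step length in metres for a step to be treated as
#'   directed movement (default 20).
#' @param h_min_m minimum smoothing parameter in metres (default 150).
#' @param D diffusion coefficient in m^2/s; `NULL` to estimate from the data
#'   with [estimate_diffusion()].
#' @param n_interp interpolated kernel positions per bridged step (default 10).
#' @return a `brb_params` list.
#' @export
brb_params <- function(t_max_h = 3, l_min_m = 20, h_min_m = 150, D = NULL,
                       n_interp = 10L) {
  stopifnot(t_max_h > 0, l_min_m > 0, h_min_m > 0, n_interp >= 1)
  structure(list(t_max_h = t_max_h, l_min_m = l_min_m, h_min_m = h_min_m,
                 D = D, n_interp = as.integer(n_interp)),
            class = "brb_params")
}

#' Estimate the movement diffusion coefficient
#'
#' Robust plug-in style estimator from step displacements: over eligible
#' steps (duration at most `t_max_h`, length at least `l_min_m`),
#' `D = median(L^2 / (4 T)) / ln 2`. For two-dimensional Brownian motion
#' `L^2/(4 D T)` is exponential with unit mean, whose median is ln 2; the
#' correction makes the median estimator consistent while retaining its
#' robustness to non-Brownian outlier steps.
#'
#' @param fixes time-ordered projected fixes (`x`, `y`, `timestamp`).
#' @param t_max_h maximum step duration in hours (default 3).
#' @param l_min_m minimum step length in metres (default 20).
#' @return diffusion coefficient D in m^2/s.
#' @export
estimate_diffusion <- function(fixes, t_max_h = 3, l_min_m = 20) {
  if (nrow(fixes) < 2L) stop("no eligible steps for diffusion estimation")
  dt <- diff(as.numeric(fixes$timestamp))
  L <- sqrt(diff(fixes$x)^2 + diff(fixes$y)^2)
  ok <- dt > 0 & dt <= t_max_h * 3600 & L >= l_min_m
  if (!any(ok)) stop("no eligible steps for diffusion estimation")
  stats::median(L[ok]^2 / (4 * dt[ok])) / log(2)
}

#' Biased-random-bridge utilization distribution
#'
#' Movement-based kernel UD for high-frequency winter fixes. Each step with
#' duration `T <= t_max_h` and length `>= l_min_m` is bridged: positions are
#' linearly interpolated at `n_interp` relative times p in (0, 1) and each
#' contributes a bivariate normal kernel with variance
#' `h_min^2 + 4 D T p (1 - p)` (weight 1/n_interp). Steps exceeding the
#' duration cap, or shorter than the length floor (residence), contribute
#' only their endpoint kernels at variance `h_min^2` (weight 1/2 each). The
#' result is normalized to total mass 1.
#'
#' @param fixes full-rate time-ordered projected fixes between winter arrival
#'   and departure (at least 2).
#' @param cell grid resolution in metres (default 500).
#' @param params a [brb_params()] object.
#' @param grid optional pre-built grid.
#' @param pad grid padding in metres; default covers 3 standard deviations of
#'   the widest kernel.
#' @param proj optional projection metadata.
#' @return a `grid_ud` with `method = "BRB"`.
#' @export
brb_ud <- function(fixes, cell = 500, params = brb_params(), grid = NULL,
                   pad = NULL, proj = NULL) {
  if (nrow(fixes) < 2L) stop("empty winter window (need at least 2 fixes)")
  if (is.null(proj)) proj <- attr(fixes, "proj")
  D <- params$D
  if (is.null(D))
    D <- tryCatch(estimate_diffusion(fixes, params$t_max_h, params$l_min_m),
                  error = function(e) 0)
  dt <- diff(as.numeric(fixes$timestamp))
  L <- sqrt(diff(fixes$x)^2 + diff(fixes$y)^2)
  bridged <- dt > 0 & dt <= params$t_max_h * 3600 & L >= params$l_min_m

  n1 <- nrow(fixes) - 1L
  cx <- list(); cy <- list(); sd_ <- list(); w <- list()
  if (any(bridged)) {
    p <- (seq_len(params$n_interp) - 0.5) / params$n_interp
    ib <- which(bridged)
    px <- outer(fixes$x[ib], rep(1, length(p))) +
      outer(fixes$x[ib + 1L] - fixes$x[ib], p)
    py <- outer(fixes$y[ib], rep(1, length(p))) +
      outer(fixes$y[ib + 1L] - fixes$y[ib], p)
    s2 <- params$h_min_m^2 + 4 * D * outer(dt[ib], p * (1 - p))
    cx[[1]] <- as.vector(px); cy[[1]] <- as.vector(py)
    sd_[[1]] <- sqrt(as.vector(s2))
    w[[1]] <- rep(1 / params$n_interp, length(px))
  }
  if (any(!bridged)) {
    ie <- which(!bridged)
    cx[[2]] <- c(fixes$x[ie], fixes$x[ie + 1L])
    cy[[2]] <- c(fixes$y[ie], fixes$y[ie + 1L])
    sd_[[2]] <- rep(params$h_min_m, 2L * length(ie))
    w[[2]] <- rep(0.5, 2L * length(ie))
  }
  cx <- unlist(cx); cy <- unlist(cy); sd_ <- unlist(sd_); w <- unlist(w)

  if (is.null(pad)) pad <- 3 * sqrt(params$h_min_m^2 + D * params$t_max_h * 3600) + cell
  if (is.null(grid))
    grid <- grid_spec(min(cx), max(cx), min(cy), max(cy), cell = cell, pad = pad)
  xs <- grid_centres_x(grid); ys <- grid_centres_y(grid)
  # separable kernels with per-contribution sd: z = t(A * w) %*% B * cell^2
  A <- stats::dnorm(matrix(xs, length(cx), grid$nx, byrow = TRUE),
                    mean = cx, sd = sd_)
  B <- stats::dnorm(matrix(ys, length(cy), grid$ny, byrow = TRUE),
                    mean = cy, sd = sd_)
  z <- crossprod(A * w, B) * grid$cell^2
  z <- z / sum(z)
  new_grid_ud(grid, z, method = "BRB", h = params$h_min_m, D = D, proj = proj)
}

# Bhattacharyya affinity of two lattice-aligned UDs without materializing a
# union grid: masses outside the extent intersection contribute nothing.
ba_lattice <- function(u1, u2) {
  if (u1$cell != u2$cell) stop("cell sizes differ")
  if (abs((u1$x0 - u2$x0) %% u1$cell) > 1e-6 &&
      abs((u1$x0 - u2$x0) %% u1$cell - u1$cell) > 1e-6)
    stop("grids are not on a shared lattice")
  cell <- u1$cell
  ix0 <- max(u1$x0, u2$x0); iy0 <- max(u1$y0, u2$y0)
  ix1 <- min(u1$x0 + u1$nx * cell, u2$x0 + u2$nx * cell)
  iy1 <- min(u1$y0 + u1$ny * cell, u2$y0 + u2$ny * cell)
  if (ix1 <= ix0 || iy1 <= iy0) return(0)
  sub <- function(u) {
    i0 <- as.integer(round((ix0 - u$x0) / cell))
    j0 <- as.integer(round((iy0 - u$y0) / cell))
    ni <- as.integer(round((ix1 - ix0) / cell))
    nj <- as.integer(round((iy1 - iy0) / cell))
    u$z[i0 + seq_len(ni), j0 + seq_len(nj), drop = FALSE]
  }
  sum(sqrt(sub(u1) * sub(u2)))
}

#' Mean pairwise overlap of an individual's seasonal UDs
#'
#' Truncates every seasonal UD at `level` (un-renormalized), embeds all on a
#' common grid, and returns the mean Bhattacharyya affinity over all
#' unordered season pairs, retaining the per-pair values.
#'
#' @param uds list of at least two seasonal `grid_ud` objects (same cell
#'   size, shared lattice).
#' @param level truncation level (default 0.95); `NULL` for no truncation.
#' @return list with `mean_ba`, `pairs` (data frame season_a, season_b, ba)
#'   and `ba_matrix`.
#' @export
seasonal_overlap <- function(uds, level = 0.95) {
  if (length(uds) < 2L) stop("need at least 2 seasons for overlap")
  if (!is.null(level)) uds <- lapply(uds, truncate_ud, level = level)
  n <- length(uds)
  nm <- names(uds)
  if (is.null(nm)) nm <- as.character(seq_len(n))
  m <- matrix(NA_real_, n, n, dimnames = list(nm, nm))
  pairs <- NULL
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ba <- ba_lattice(uds[[i]], uds[[j]])
    m[i, j] <- m[j, i] <- ba
    pairs <- rbind(pairs, data.frame(season_a = nm[i], season_b = nm[j],
                                     ba = ba, stringsAsFactors = FALSE))
  }
  list(mean_ba = mean(pairs$ba), pairs = pairs, ba_matrix = m)
}

#' Winter site fidelity from biased-random-bridge UDs
#'
#' Mean pairwise Bhattacharyya affinity of an individual's winter BRB UDs,
#' each truncated at the 95th percentile (un-renormalized), on a common
#' 500-m grid.
#'
#' @param uds list of at least two winter `grid_ud` objects from [brb_ud()].
#' @param level truncation level (default 0.95).
#' @return as [seasonal_overlap()].
#' @export
winter_site_fidelity <- function(uds, level = 0.95) {
  seasonal_overlap(uds, level = level)
}
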
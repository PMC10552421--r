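#' Turn angle correlation
#'
#' Sum of squared (wrapped) differences between successive turn angles; a
#' path whose consecutive turns are alike (strong directional memory) scores
#' low. Because the raw sum grows with track length, the per-pair mean is
#' also returned and is what cross-individual comparisons use.
#'
#' @param angles Turn angles in radians (NA allowed; pairs touching NA are
#'   skipped).
#' @return List with `sum` (radians^2), `mean` (per-pair), `n_pairs`.
#' @export
turn_angle_correlation <- function(angles) {
  a <- angles
  if (sum(!is.na(a)) < 3) {
    return(list(sum = NA_real_, mean = NA_real_, n_pairs = 0L))
  }
  d <- wrap_angle(diff(a))
  d <- d[!is.na(d)]
  list(sum = sum(d^2), mean = mean(d^2), n_pairs = length(d))
}

# Crossing-time event scan: for a circle of `radius` around fix `i`, return
# interpolated entry/exit times of the trajectory.
circle_events <- function(t, d, radius) {
  inside <- d <= radius
  switches <- which(diff(inside) != 0)
  if (length(switches) == 0) {
    return(list(inside = inside, cross_t = numeric(0), cross_dir = integer(0)))
  }
  k <- switches
  frac <- (radius - d[k]) / (d[k + 1] - d[k])
  list(inside = inside,
       cross_t = t[k] + frac * (t[k + 1] - t[k]),
       cross_dir = ifelse(inside[k], -1L, 1L))  # -1 exit, +1 entry
}

residence_one <- function(t, d, radius, cutoff) {
  n <- length(t)
  ev <- circle_events(t, d, radius)
  # build maximal inside intervals [start, end] in time
  starts <- numeric(0); ends <- numeric(0)
  cur_start <- if (ev$inside[1]) t[1] else NA_real_
  if (length(ev$cross_t) > 0) {
    for (j in seq_along(ev$cross_t)) {
      if (ev$cross_dir[j] == -1L) { # exit
        starts <- c(starts, cur_start); ends <- c(ends, ev$cross_t[j])
        cur_start <- NA_real_
      } else {
        cur_start <- ev$cross_t[j]
      }
    }
  }
  if (!is.na(cur_start)) { starts <- c(starts, cur_start); ends <- c(ends, t[n]) }
  list(starts = starts, ends = ends)
}

#' Residence time
#'
#' Hours the animal spends inside a circle of `radius` centered on each
#' location, where excursions outside shorter than `cutoff` do not end the
#' visit (the animal is deemed still resident) while longer excursions do.
#' The scan runs backward and forward from each fix with linearly
#' interpolated circle-crossing times.
#'
#' @param t Times (seconds or POSIXct).
#' @param x,y Coordinates (meters).
#' @param radius Circle radius in meters (convention: the individual's mean
#'   step length).
#' @param cutoff Excursion cutoff in seconds (default 12 h).
#' @param every Compute at every `every`-th fix (subsampling for long
#'   tracks); others get `NA`.
#' @return List with `hours` (per-fix residence, hours) and `mean`.
#' @export
residence_time <- function(t, x, y, radius, cutoff = 12 * 3600, every = 1) {
  assert_positive(radius, "radius")
  t <- as.numeric(t)
  n <- length(t)
  hours <- rep(NA_real_, n)
  for (i in seq(1, n, by = every)) {
    d <- sqrt((x - x[i])^2 + (y - y[i])^2)
    iv <- residence_one(t, d, radius, cutoff)
    k0 <- findInterval(t[i], iv$starts)  # interval containing the focal fix
    tot <- iv$ends[k0] - iv$starts[k0]
    # forward: absorb visits whose preceding gap <= cutoff
    j <- k0
    while (j < length(iv$starts) && iv$starts[j + 1] - iv$ends[j] <= cutoff) {
      j <- j + 1
      tot <- tot + iv$ends[j] - iv$starts[j]
    }
    # backward
    j <- k0
    while (j > 1 && iv$starts[j] - iv$ends[j - 1] <= cutoff) {
      j <- j - 1
      tot <- tot + iv$ends[j] - iv$starts[j]
    }
    hours[i] <- tot / 3600
  }
  list(hours = hours, mean = mean(hours, na.rm = TRUE))
}

#' Time to return
#'
#' For each fix, the duration of the first excursion outside the circle of
#' `radius` centered on it that both exceeds `cutoff` and ends with a
#' re-entry; fixes whose track never again qualifies are censored (`NA`) and
#' excluded from the mean (count reported). All returned values exceed the
#' cutoff by construction.
#'
#' @inheritParams residence_time
#' @return List with `hours` (per-fix, `NA` when censored), `mean`,
#'   `n_censored`.
#' @export
time_to_return <- function(t, x, y, radius, cutoff = 12 * 3600, every = 1) {
  assert_positive(radius, "radius")
  t <- as.numeric(t)
  n <- length(t)
  hours <- rep(NA_real_, n)
  computed <- rep(FALSE, n)
  for (i in seq(1, n, by = every)) {
    computed[i] <- TRUE
    d <- sqrt((x - x[i])^2 + (y - y[i])^2)
    iv <- residence_one(t, d, radius, cutoff)
    k0 <- findInterval(t[i], iv$starts)
    if (k0 < length(iv$starts)) {
      gaps <- iv$starts[(k0 + 1):length(iv$starts)] -
        iv$ends[k0:(length(iv$ends) - 1)]
      q <- which(gaps > cutoff)
      if (length(q) > 0) hours[i] <- gaps[q[1]] / 3600
    }
  }
  list(hours = hours, mean = mean(hours, na.rm = TRUE),
       n_censored = sum(computed & is.na(hours)))
}

#' Kernel utilization distribution
#'
#' Plain Gaussian kernel density estimate of the utilization distribution on
#' a regular grid, with the 95% isopleth area as the home range. Automatic
#' bandwidth is the reference-style rule `h = sigma * n^(-1/6)` with `sigma`
#' the mean of the coordinate standard deviations; the grid cell is at most
#' `bandwidth / 4` and the extent is padded by 3 bandwidths.
#'
#' @param x,y Fix coordinates (meters).
#' @param bandwidth Kernel standard deviation in meters, or `"auto"`.
#' @param lims Optional `c(xmin, xmax, ymin, ymax)` grid limits (for putting
#'   several UDs on a common grid).
#' @param max_cells Cap on grid points per axis.
#' @return Object of class `utilization_distribution`: grid vectors `gx`,
#'   `gy`, density matrix `z` (integrates to 1), `bandwidth`, `cell_area`
#'   (m^2), and the source points.
#' @export
kde_ud <- function(x, y, bandwidth = "auto", lims = NULL, max_cells = 400) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 30) abort("Utilization distribution needs >= 30 fixes.",
                    class = "msms_insufficient_data")
  if (identical(bandwidth, "auto")) {
    sigma <- mean(c(sd(x), sd(y)))
    if (sigma == 0) abort("All fixes identical; utilization distribution is degenerate.",
                          class = "msms_degenerate_data")
    bandwidth <- sigma * n^(-1 / 6)
  }
  assert_positive(bandwidth, "bandwidth")
  if (is.null(lims)) {
    lims <- c(range(x) + c(-3, 3) * bandwidth,
              range(y) + c(-3, 3) * bandwidth)
  }
  cell <- bandwidth / 4
  nx <- min(max_cells, max(20, ceiling((lims[2] - lims[1]) / cell) + 1))
  ny <- min(max_cells, max(20, ceiling((lims[4] - lims[3]) / cell) + 1))
  # MASS::kde2d uses h/4 as the Gaussian kernel sd
  k <- MASS::kde2d(x, y, h = 4 * bandwidth, n = c(nx, ny), lims = lims)
  cell_area <- diff(k$x[1:2]) * diff(k$y[1:2])
  z <- k$z / (sum(k$z) * cell_area)
  structure(list(gx = k$x, gy = k$y, z = z, bandwidth = bandwidth,
                 cell_area = cell_area, points = cbind(x = x, y = y)),
            class = "utilization_distribution")
}

#' @export
print.utilization_distribution <- function(x, ...) {
  cat(sprintf("Utilization distribution: %d x %d grid, bandwidth %.1f m, 95%% isopleth %.1f ha\n",
              length(x$gx), length(x$gy), x$bandwidth, isopleth_area(x, 0.95)))
  invisible(x)
}

#' Isopleth (home range) area of a utilization distribution
#'
#' Area of the smallest set of grid cells containing probability `p`; at
#' `p = 0.95` this is the kernel home range.
#'
#' @param ud A [kde_ud()] object.
#' @param p Probability level.
#' @return Area in hectares.
#' @export
isopleth_area <- function(ud, p = 0.95) {
  dens <- sort(as.vector(ud$z), decreasing = TRUE)
  cum <- cumsum(dens) * ud$cell_area
  ncells <- which(cum >= p)[1]
  if (is.na(ncells)) ncells <- length(dens)
  ncells * ud$cell_area / 1e4
}

#' Volume of intersection of two utilization distributions
#'
#' `VI = integral of min(UD1, UD2)`: 1 for identical distributions, 0 for
#' disjoint ones. When the two UDs are not on the same grid they are
#' recomputed from their source points on a common grid covering both
#' (each keeping its own bandwidth).
#'
#' @param ud1,ud2 [kde_ud()] objects.
#' @return Overlap in \[0, 1\].
#' @export
volume_of_intersection <- function(ud1, ud2) {
  same_grid <- length(ud1$gx) == length(ud2$gx) &&
    length(ud1$gy) == length(ud2$gy) &&
    isTRUE(all.equal(ud1$gx, ud2$gx)) && isTRUE(all.equal(ud1$gy, ud2$gy))
  if (!same_grid) {
    lims <- c(min(ud1$gx[1], ud2$gx[1]), max(max(ud1$gx), max(ud2$gx)),
              min(ud1$gy[1], ud2$gy[1]), max(max(ud1$gy), max(ud2$gy)))
    ud1 <- kde_ud(ud1$points[, 1], ud1$points[, 2],
                  bandwidth = ud1$bandwidth, lims = lims)
    ud2 <- kde_ud(ud2$points[, 1], ud2$points[, 2],
                  bandwidth = ud2$bandwidth, lims = lims)
  }
  min(1, sum(pmin(ud1$z, ud2$z)) * ud1$cell_area)
}

#' Monthly home-range overlap
#'
#' Mean volume of intersection between the utilization distributions of
#' successive qualifying calendar months (>= `min_fixes` fixes each); a
#' measure of home-range stability. Individuals with fewer than two
#' qualifying months get `NA`.
#'
#' @param t,x,y Fix times and coordinates for one individual.
#' @param min_fixes Minimum fixes for a month to qualify (default 200).
#' @param bandwidth Passed to [kde_ud()].
#' @return Mean VI (or `NA`).
#' @export
vi_monthly <- function(t, x, y, min_fixes = 200, bandwidth = "auto") {
  mo <- format(lubridate::as_datetime(as.numeric(t), tz = "UTC"), "%Y-%m")
  tab <- table(mo)
  months <- names(tab)[tab >= min_fixes]
  if (length(months) < 2) return(NA_real_)
  months <- sort(months)
  uds <- lapply(months, function(m) {
    kde_ud(x[mo == m], y[mo == m], bandwidth = bandwidth)
  })
  vis <- vapply(seq_len(length(uds) - 1),
                function(i) volume_of_intersection(uds[[i]], uds[[i + 1]]), 0)
  mean(vis)
}

#' Maximum net squared displacement
#'
#' Largest squared Euclidean displacement from the first relocation of the
#' trajectory; its species-scaled version (divided by the smallest value in
#' the species) is computed by [lifephase_metrics()].
#'
#' @param x,y Fix coordinates, time-ordered.
#' @return MNSD in m^2.
#' @export
max_net_squared_displacement <- function(x, y) {
  if (length(x) < 2) return(0)
  max((x - x[1])^2 + (y - y[1])^2)
}

#' Life-history-phase metric table
#'
#' Computes, per individual over the whole track: mean-per-pair turn angle
#' correlation, mean residence time and time-to-return (circle radius = the
#' individual's mean step length, 12 h cutoff), mean monthly home-range
#' overlap (VI), maximum net squared displacement (raw and scaled by the
#' species minimum, so each species' smallest ranger scores exactly 1), and
#' the 95% kernel home range in hectares.
#'
#' @param fixes Cleaned fix tibble (observed + interpolated).
#' @param cutoff Residence/return excursion cutoff in seconds.
#' @param every Subsampling stride for the per-fix residence/return scans.
#' @param vi_min_fixes Minimum fixes per month for the VI computation.
#' @return Tibble with one row per individual: `individual_id`, `species`,
#'   `n_fixes`, `tac_mean`, `tac_sum`, `residence_h`, `time_to_return_h`,
#'   `vi`, `mnsd_m2`, `mnsd_scaled`, `home_range_ha`.
#' @export
lifephase_metrics <- function(fixes, cutoff = 12 * 3600, every = 1,
                              vi_min_fixes = 200) {
  res <- fixes %>%
    dplyr::group_by(.data$individual_id, .data$species) %>%
    dplyr::group_modify(function(g, key) {
      g <- dplyr::arrange(g, .data$timestamp)
      n <- nrow(g)
      steps <- sqrt(diff(g$x)^2 + diff(g$y)^2)
      radius <- mean(steps)
      h <- atan2(diff(g$y), diff(g$x))
      h[steps == 0] <- NA
      turns <- wrap_angle(diff(h))
      tac <- turn_angle_correlation(turns)
      rt <- if (radius > 0)
        residence_time(g$timestamp, g$x, g$y, radius, cutoff, every)
      else list(mean = NA_real_)
      tr <- if (radius > 0)
        time_to_return(g$timestamp, g$x, g$y, radius, cutoff, every)
      else list(mean = NA_real_)
      hr <- tryCatch(isopleth_area(kde_ud(g$x, g$y), 0.95),
                     error = function(e) NA_real_)
      tibble::tibble(
        n_fixes = n,
        tac_mean = tac$mean, tac_sum = tac$sum,
        residence_h = rt$mean, time_to_return_h = tr$mean,
        vi = vi_monthly(g$timestamp, g$x, g$y, min_fixes = vi_min_fixes),
        mnsd_m2 = max_net_squared_displacement(g$x, g$y),
        home_range_ha = hr)
    }) %>%
    dplyr::ungroup() %>%
    dplyr::group_by(.data$species) %>%
    dplyr::mutate(mnsd_scaled = .data$mnsd_m2 /
                    min(.data$mnsd_m2[.data$mnsd_m2 > 0])) %>%
    dplyr::ungroup()
  res
}
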
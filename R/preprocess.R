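#' Outlier flag helpers
#'
#' Fix tables carry a semicolon-separated `outlier_flags` column; flags are
#' `duplicate`, `altitude`, `boundary`, `speed`. Flagging never alters
#' coordinates — [drop_outliers()] is the separate projection onto clean
#' fixes.
#'
#' @param flags Character vector of current flags.
#' @param flag Single flag name.
#' @return `add_flag()` the updated flag strings; `has_flag()` a logical
#'   vector; `drop_outliers()` the unflagged rows.
#' @export
add_flag <- function(flags, flag) {
  flags[is.na(flags)] <- ""
  ifelse(flags == "", flag,
         ifelse(has_flag(flags, flag), flags, paste(flags, flag, sep = ";")))
}

#' @rdname add_flag
#' @export
has_flag <- function(flags, flag) {
  vapply(strsplit(ifelse(is.na(flags), "", flags), ";", fixed = TRUE),
         function(f) flag %in% f, logical(1))
}

#' @rdname add_flag
#' @param fixes A fix tibble.
#' @export
drop_outliers <- function(fixes) {
  fixes[is.na(fixes$outlier_flags) | fixes$outlier_flags == "", , drop = FALSE]
}

#' Summarize outlier flags
#'
#' @param fixes A fix tibble.
#' @return Tibble of per-flag counts across the table.
#' @export
outlier_report <- function(fixes) {
  flags <- c("duplicate", "altitude", "boundary", "speed")
  tibble::tibble(
    flag = flags,
    n = vapply(flags, function(f) sum(has_flag(fixes$outlier_flags, f)),
               integer(1)))
}

#' Flag altitude (height-above-ellipsoid) outliers
#'
#' GPS altitude is a sensitive error indicator: fixes whose
#' height-above-ellipsoid falls at or below a floor or above a ceiling are
#' flagged as impossible positions. With `"auto"` thresholds the floor and
#' ceiling are computed per individual as Q1 - 2*IQR and Q3 + 2*IQR of that
#' animal's altitudes (type-7 quantiles), the quartile rule the fixed study
#' thresholds of 21 m and 244 m correspond to.
#'
#' @param fixes A fix tibble with `altitude_hae`.
#' @param low,high Numeric thresholds in meters, or `"auto"`.
#' @return The fix tibble with `altitude` flags added. Fixes with missing
#'   altitude are never flagged.
#' @export
flag_altitude_outliers <- function(fixes, low = 21, high = 244) {
  auto <- identical(low, "auto") || identical(high, "auto")
  out <- fixes %>% dplyr::group_by(.data$individual_id)
  flag_one <- function(alt, low, high) {
    if (identical(low, "auto") || identical(high, "auto")) {
      av <- alt[!is.na(alt)]
      if (length(av) < 4) {
        abort("Automatic altitude thresholds need >= 4 altitude values.",
              class = "msms_config_error")
      }
      q <- quantile(av, c(.25, .75), names = FALSE)
      iqr <- q[2] - q[1]
      if (identical(low, "auto")) low <- q[1] - 2 * iqr
      if (identical(high, "auto")) high <- q[2] + 2 * iqr
      # auto rule: at/below floor or at/above ceiling
      !is.na(alt) & (alt <= low | alt >= high)
    } else {
      !is.na(alt) & (alt <= low | alt > high)
    }
  }
  out <- out %>%
    dplyr::mutate(outlier_flags = ifelse(
      flag_one(.data$altitude_hae, low, high),
      add_flag(.data$outlier_flags, "altitude"), .data$outlier_flags)) %>%
    dplyr::ungroup()
  out
}

#' Parse a study-area boundary polygon
#'
#' Accepts a two-column matrix/data frame of vertices, a WKT `POLYGON`
#' string, or a GeoJSON string/file with a `Polygon` geometry (outer ring
#' used). Coordinates must be in the same planar CRS as the fixes (project
#' lon/lat rings with [project_utm()] first).
#'
#' @param boundary Polygon in any accepted form.
#' @return Closed two-column matrix of vertices.
#' @export
parse_boundary <- function(boundary) {
  if (is.character(boundary) && length(boundary) == 1) {
    if (file.exists(boundary)) boundary <- paste(readLines(boundary), collapse = "\n")
    if (grepl("^\\s*POLYGON", boundary, ignore.case = TRUE)) {
      ring <- sub(".*\\(\\(", "", boundary)
      ring <- sub("\\)\\).*", "", ring)
      pts <- strsplit(trimws(strsplit(ring, ",")[[1]]), "\\s+")
      m <- do.call(rbind, lapply(pts, function(p) as.numeric(p[1:2])))
    } else {
      gj <- jsonlite::fromJSON(boundary, simplifyMatrix = TRUE)
      coords <- gj$coordinates %||% gj$geometry$coordinates
      if (is.null(coords)) abort("No polygon coordinates found in GeoJSON.",
                                 class = "msms_geometry_error")
      m <- if (is.list(coords)) coords[[1]] else coords[1, , ]
      m <- matrix(as.numeric(m), ncol = 2)
    }
    boundary <- m
  }
  m <- as.matrix(boundary)[, 1:2, drop = FALSE]
  storage.mode(m) <- "double"
  if (nrow(m) < 3 || any(!is.finite(m))) {
    abort("Boundary polygon needs >= 3 finite vertices.",
          class = "msms_geometry_error")
  }
  if (any(m[1, ] != m[nrow(m), ])) m <- rbind(m, m[1, ])
  m
}

#' Point-in-polygon test (even-odd rule)
#'
#' Even-odd ray casting; points exactly on an edge count as inside, the
#' convention used for boundary screening (an animal on the shoreline is not
#' an outlier).
#'
#' @param px,py Point coordinates.
#' @param polygon Polygon acceptable to [parse_boundary()].
#' @return Logical vector, `TRUE` when inside or on the boundary.
#' @export
point_in_polygon <- function(px, py, polygon) {
  poly <- parse_boundary(polygon)
  n <- nrow(poly) - 1
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  eps <- 1e-9
  for (i in seq_len(n)) {
    x1 <- poly[i, 1]; y1 <- poly[i, 2]
    x2 <- poly[i + 1, 1]; y2 <- poly[i + 1, 2]
    # collinear and within segment bounding box -> on edge
    cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    seg2 <- (x2 - x1)^2 + (y2 - y1)^2
    on_seg <- abs(cross) <= eps * max(1, sqrt(seg2)) &
      px >= pmin(x1, x2) - eps & px <= pmax(x1, x2) + eps &
      py >= pmin(y1, y2) - eps & py <= pmax(y1, y2) + eps
    on_edge <- on_edge | on_seg
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < x1 + (py - y1) / (y2 - y1) * (x2 - x1))
    crosses[is.na(crosses)] <- FALSE
    inside <- xor(inside, crosses)
  }
  inside | on_edge
}

#' Flag fixes outside the study-area boundary
#'
#' Location estimates strictly outside the boundary polygon (e.g. in the
#' water around an island site) are flagged `boundary`; on-edge points count
#' as inside.
#'
#' @param fixes A fix tibble.
#' @param boundary Polygon acceptable to [parse_boundary()], in the fixes'
#'   planar CRS.
#' @return The fix tibble with `boundary` flags added.
#' @export
flag_boundary_outliers <- function(fixes, boundary) {
  poly <- parse_boundary(boundary)
  outside <- !point_in_polygon(fixes$x, fixes$y, poly)
  fixes$outlier_flags <- ifelse(outside,
                                add_flag(fixes$outlier_flags, "boundary"),
                                fixes$outlier_flags)
  fixes
}

#' Flag speed and displacement outliers
#'
#' A deterministic surrogate for interactive outlier screening: a fix is
#' flagged `speed` when both its incoming and outgoing straight-line speeds
#' exceed `vmax` (a teleporting spike; genuine fast travel raises only one of
#' the two), or when its distance from the individual's median location
#' exceeds `median_mult` times the 95th percentile of such distances.
#'
#' @param fixes A fix tibble.
#' @param vmax Speed cap in m/s (default 3, generous for a ~3 kg arboreal
#'   mammal at a 4-min interval).
#' @param median_mult Multiplier on the 95th percentile of
#'   distance-to-median-location (default 10).
#' @return The fix tibble with `speed` flags added.
#' @export
flag_speed_outliers <- function(fixes, vmax = 3, median_mult = 10) {
  assert_positive(vmax, "vmax")
  fixes %>%
    dplyr::group_by(.data$individual_id) %>%
    dplyr::arrange(.data$timestamp, .by_group = TRUE) %>%
    dplyr::mutate(outlier_flags = {
      n <- dplyr::n()
      if (n < 2) .data$outlier_flags else {
        dt <- diff(as.numeric(.data$timestamp))
        dd <- sqrt(diff(.data$x)^2 + diff(.data$y)^2)
        v <- dd / pmax(dt, 1e-9)
        vin <- c(NA, v)
        vout <- c(v, NA)
        spike <- !is.na(vin) & !is.na(vout) & vin > vmax & vout > vmax
        dmed <- sqrt((.data$x - median(.data$x))^2 +
                       (.data$y - median(.data$y))^2)
        far <- dmed > median_mult * quantile(dmed, 0.95, names = FALSE)
        ifelse(spike | far, add_flag(.data$outlier_flags, "speed"),
               .data$outlier_flags)
      }
    }) %>%
    dplyr::ungroup()
}

#' Interpolate fixes through inactivity gaps
#'
#' Activity-informed collars suppress GPS attempts while the animal is
#' still, leaving gaps in the 4-min fix grid. When a gap's bounding observed
#' fixes are within `stationarity_radius` of each other (the animal did not
#' move), the missing grid times are filled with fixes anchored at the last
#' observed position and displaced by a modeled GPS error: an integer radius
#' in meters drawn from a negative binomial with mean `mean_error` (default
#' 5.46 m) and dispersion (size) `dispersion` (default 2.4), at a uniform
#' random angle. Gaps whose endpoints are farther apart are left unfilled —
#' the animal moved, so the gap is not an inactive period. When activity
#' windows are supplied only in-window grid times are filled.
#'
#' @param fixes A fix tibble (outliers are ignored as anchors).
#' @param mean_error,dispersion Negative binomial error model (meters).
#' @param interval Nominal fix interval in seconds (default 240).
#' @param stationarity_radius Maximum distance between gap-bounding fixes for
#'   the gap to count as inactive (default 30 m, the cluster/ARS scale).
#' @param activity_windows Optional windows as in [assemble_daily_paths()].
#' @param tz_local Timezone for window evaluation.
#' @param seed Optional integer; when given the draw is made reproducible
#'   without disturbing the caller's RNG stream.
#' @return The fix tibble with `source = "interpolated"` rows inserted,
#'   time-ordered. Observed fixes are never altered.
#' @export
interpolate_inactive_gaps <- function(fixes, mean_error = 5.46,
                                      dispersion = 2.4, interval = 240,
                                      stationarity_radius = 30,
                                      activity_windows = NULL,
                                      tz_local = "Etc/GMT+5", seed = NULL) {
  if (mean_error < 0 || dispersion <= 0) {
    abort("Error model needs mean_error >= 0 and dispersion > 0.",
          class = "msms_config_error")
  }
  run <- function() {
    clean <- drop_outliers(fixes)
    new_rows <- clean %>%
      dplyr::group_by(.data$individual_id) %>%
      dplyr::group_map(function(g, key) {
        g <- dplyr::arrange(g, .data$timestamp)
        if (nrow(g) < 2) return(NULL)
        tt <- as.numeric(g$timestamp)
        gaps <- which(diff(tt) > 1.5 * interval)
        purrr::map_dfr(gaps, function(i) {
          d <- sqrt((g$x[i + 1] - g$x[i])^2 + (g$y[i + 1] - g$y[i])^2)
          if (d > stationarity_radius) return(NULL)
          times <- seq(tt[i] + interval, tt[i + 1] - interval / 2,
                       by = interval)
          if (length(times) == 0) return(NULL)
          ts <- lubridate::as_datetime(times, tz = "UTC")
          if (!is.null(activity_windows)) {
            aw <- normalize_windows(activity_windows, g$species[1])
            aw <- aw[aw$species == g$species[1], ]
            if (nrow(aw) == 1) {
              lt <- lubridate::with_tz(ts, tz_local)
              tod <- as.numeric(lt - lubridate::floor_date(lt, "day"),
                                units = "secs")
              ws <- parse_hm(aw$window_start); we <- parse_hm(aw$window_end)
              keep <- if (ws > we) tod >= ws | tod <= we else
                tod >= ws & tod <= we
              ts <- ts[keep]
            }
          }
          if (length(ts) == 0) return(NULL)
          m <- length(ts)
          r <- if (mean_error == 0) rep(0, m) else
            rnbinom(m, size = dispersion, mu = mean_error)
          a <- runif(m, -pi, pi)
          tibble::tibble(
            individual_id = key$individual_id[1], species = g$species[1],
            timestamp = ts,
            x = g$x[i] + r * cos(a), y = g$y[i] + r * sin(a),
            altitude_hae = NA_real_, burst_id = NA_character_,
            source = "interpolated", outlier_flags = "")
        })
      }) %>% dplyr::bind_rows()
    dplyr::bind_rows(fixes, new_rows) %>%
      dplyr::arrange(.data$individual_id, .data$timestamp)
  }
  if (is.null(seed)) run() else {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    run()
  }
}

#' Run the full preprocessing chain
#'
#' Dedup (at ingestion) -> burst selection -> altitude -> boundary -> speed
#' flagging -> inactivity-gap interpolation, in that fixed order.
#'
#' @param fixes A fix tibble from [read_tracking_csv()].
#' @param boundary Optional study-area polygon.
#' @param altitude_low,altitude_high Altitude thresholds or `"auto"`; `NULL`
#'   skips altitude screening.
#' @param vmax Speed cap in m/s; `NULL` skips speed screening.
#' @param interpolate Fill inactivity gaps after flagging?
#' @inheritParams interpolate_inactive_gaps
#' @return List with `fixes` (clean, interpolated table), `flagged` (the
#'   flagged-out rows) and `report` (per-flag counts).
#' @export
preprocess_tracks <- function(fixes, boundary = NULL, altitude_low = 21,
                              altitude_high = 244, vmax = 3,
                              interpolate = TRUE, mean_error = 5.46,
                              dispersion = 2.4, interval = 240,
                              stationarity_radius = 30,
                              activity_windows = NULL,
                              tz_local = "Etc/GMT+5", seed = NULL) {
  f <- select_burst_last_fix(fixes)
  if (!is.null(altitude_low) && !is.null(altitude_high) &&
      any(!is.na(f$altitude_hae))) {
    f <- flag_altitude_outliers(f, altitude_low, altitude_high)
  }
  if (!is.null(boundary)) f <- flag_boundary_outliers(f, boundary)
  if (!is.null(vmax)) f <- flag_speed_outliers(f, vmax)
  report <- outlier_report(f)
  flagged <- f[!(is.na(f$outlier_flags) | f$outlier_flags == ""), ]
  clean <- drop_outliers(f)
  if (interpolate) {
    clean <- interpolate_inactive_gaps(
      clean, mean_error = mean_error, dispersion = dispersion,
      interval = interval, stationarity_radius = stationarity_radius,
      activity_windows = activity_windows, tz_local = tz_local, seed = seed)
  }
  list(fixes = clean, flagged = flagged, report = report)
}
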
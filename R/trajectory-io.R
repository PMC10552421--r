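#' Column mappings for tracking tables
#'
#' `movebank_columns()` maps the default Movebank export headers onto the
#' canonical fix schema; `msms_columns()` is the identity mapping for tables
#' this package writes. Pass a modified copy to [read_tracking_csv()] for
#' other dialects.
#'
#' @return Named character vector: names are canonical fix columns, values
#'   are the column headers expected in the file. Coordinate entries may name
#'   either lon/lat (`lon`, `lat`) or planar (`x`, `y`) columns.
#' @export
movebank_columns <- function() {
  c(individual_id = "individual-local-identifier",
    species = "individual-taxon-canonical-name",
    timestamp = "timestamp",
    lon = "location-long",
    lat = "location-lat",
    altitude_hae = "height-above-ellipsoid",
    burst_id = "burst-id")
}

#' @rdname movebank_columns
#' @export
msms_columns <- function() {
  c(individual_id = "individual_id", species = "species",
    timestamp = "timestamp", x = "x", y = "y",
    altitude_hae = "altitude_hae", burst_id = "burst_id")
}

#' Read a tracking table into a canonical fix tibble
#'
#' Reads a Movebank-style CSV of GPS relocations and returns one row per fix
#' with the canonical columns `individual_id`, `species`, `timestamp`
#' (POSIXct, UTC), `x`, `y` (projected meters), `altitude_hae`, `burst_id`,
#' `source` (`"observed"`), and `outlier_flags`. Longitude/latitude input is
#' projected to UTM (zone of the data centroid unless given); planar input is
#' passed through. Within each individual, rows are sorted by time and any
#' row repeating an earlier timestamp is flagged `duplicate` (first
#' occurrence kept unflagged).
#'
#' @param path CSV file path.
#' @param columns Named mapping from canonical names to file headers; see
#'   [movebank_columns()]. Auto-detected between the Movebank and canonical
#'   dialects when `NULL`.
#' @param zone,hemisphere UTM zone passed to [project_utm()] when the file
#'   carries lon/lat.
#' @return A fix tibble; the projection used (if any) is attached as
#'   `attr(, "crs")`.
#' @export
read_tracking_csv <- function(path, columns = NULL, zone = NULL,
                              hemisphere = "north") {
  if (!file.exists(path)) {
    abort(sprintf("Tracking file not found: %s", path),
          class = "msms_io_error")
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (is.null(columns)) {
    columns <- if (all(c("individual-local-identifier", "location-long")
                       %in% names(raw))) movebank_columns() else msms_columns()
  }

  planar <- all(c("x", "y") %in% names(columns)) &&
    all(columns[c("x", "y")] %in% names(raw))
  lonlat <- all(c("lon", "lat") %in% names(columns)) &&
    all(columns[c("lon", "lat")] %in% names(raw))
  required <- c("individual_id", "timestamp",
                if (lonlat) c("lon", "lat") else c("x", "y"))
  missing_cols <- setdiff(columns[required][!is.na(columns[required])],
                          names(raw))
  if (!planar && !lonlat) {
    missing_cols <- unique(c(missing_cols,
                             columns[c("lon", "lat")], columns[c("x", "y")]))
  }
  if (length(missing_cols) > 0) {
    abort(sprintf("Required column(s) missing from %s: %s", path,
                  paste(missing_cols, collapse = ", ")),
          class = "msms_schema_error")
  }

  pick <- function(canon) {
    col <- columns[[canon]]
    if (!is.null(col) && !is.na(col) && col %in% names(raw)) raw[[col]]
    else rep(NA_character_, nrow(raw))
  }

  ts_raw <- pick("timestamp")
  ts <- NULL
  for (fmt in c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%dT%H:%M:%OS",
                "%Y/%m/%d %H:%M:%OS", "%Y-%m-%d %H:%M")) {
    cand <- as.POSIXct(ts_raw, format = fmt, tz = "UTC")
    if (!anyNA(cand[!is.na(ts_raw)])) { ts <- cand; break }
    if (is.null(ts) || sum(!is.na(cand)) > sum(!is.na(ts))) ts <- cand
  }
  if (anyNA(ts)) {
    bad <- which(is.na(ts))
    abort(sprintf("Unparseable timestamp at data row(s): %s",
                  paste(head(bad, 5), collapse = ", ")),
          class = "msms_parse_error")
  }

  crs <- NULL
  if (lonlat) {
    lon <- as.numeric(pick("lon"))
    lat <- as.numeric(pick("lat"))
    prj <- project_utm(lon, lat, zone = zone, hemisphere = hemisphere)
    xy <- tibble::tibble(x = prj$x, y = prj$y)
    crs <- attr(prj, "crs")
  } else {
    xy <- tibble::tibble(x = as.numeric(pick("x")), y = as.numeric(pick("y")))
  }
  if (any(!is.finite(xy$x) | !is.finite(xy$y))) {
    abort("Non-finite coordinates after parsing/projection.",
          class = "msms_parse_error")
  }

  fixes <- tibble::tibble(
    individual_id = pick("individual_id"),
    species = pick("species"),
    timestamp = ts,
    x = xy$x, y = xy$y,
    altitude_hae = suppressWarnings(as.numeric(pick("altitude_hae"))),
    burst_id = pick("burst_id"),
    source = "observed",
    outlier_flags = ""
  ) %>%
    dplyr::arrange(.data$individual_id, .data$timestamp) %>%
    dplyr::group_by(.data$individual_id) %>%
    dplyr::mutate(outlier_flags = ifelse(
      duplicated(.data$timestamp), add_flag(.data$outlier_flags, "duplicate"),
      .data$outlier_flags)) %>%
    dplyr::ungroup()
  attr(fixes, "crs") <- crs
  fixes
}

#' Write a fix tibble back to CSV
#'
#' Writes the canonical columns with timestamps formatted to the second in
#' UTC and coordinates at micro-meter precision, so a write/read round trip
#' reproduces the table exactly.
#'
#' @param fixes A fix tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracking_csv <- function(fixes, path) {
  out <- fixes
  out$timestamp <- format(out$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC")
  out$x <- sprintf("%.6f", out$x)
  out$y <- sprintf("%.6f", out$y)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Keep only the last fix of each GPS burst
#'
#' Burst-sampling collars record several rapid fixes per scheduled attempt;
#' the final fix has the best horizontal accuracy, so only the latest fix of
#' each burst enters analyses. Fixes without a burst id pass through
#' unchanged, and the operation is idempotent.
#'
#' @param fixes A fix tibble.
#' @return The fix tibble restricted to one (latest) fix per
#'   individual-burst, time-ordered.
#' @export
select_burst_last_fix <- function(fixes) {
  no_burst <- is.na(fixes$burst_id) | fixes$burst_id == ""
  kept <- dplyr::bind_rows(
    fixes[no_burst, ],
    fixes[!no_burst, ] %>%
      dplyr::group_by(.data$individual_id, .data$burst_id) %>%
      dplyr::slice_max(.data$timestamp, n = 1, with_ties = FALSE) %>%
      dplyr::ungroup()
  )
  dplyr::arrange(kept, .data$individual_id, .data$timestamp)
}

#' Species activity windows
#'
#' Activity windows delimit the daily period a species is tracked; fixes
#' outside the window are not part of any daily path. The default table
#' carries the four study species of the Barro Colorado Island frugivore
#' system: nocturnal kinkajous (23:00-06:30, spanning midnight) and diurnal
#' coatis (06:00-18:30), capuchins and spider monkeys (06:00-18:00).
#'
#' @return Tibble with columns `species`, `window_start`, `window_end`
#'   (local "HH:MM" strings).
#' @export
bci_activity_windows <- function() {
  tibble::tribble(
    ~species,        ~window_start, ~window_end,
    "kinkajou",      "23:00",       "06:30",
    "coati",         "06:00",       "18:30",
    "capuchin",      "06:00",       "18:00",
    "spider_monkey", "06:00",       "18:00"
  )
}

parse_hm <- function(s) {
  p <- strsplit(s, ":", fixed = TRUE)
  vapply(p, function(q) as.numeric(q[1]) * 3600 + as.numeric(q[2]) * 60, 0)
}

normalize_windows <- function(activity_windows, species) {
  if (is.character(activity_windows) && length(activity_windows) == 2) {
    return(tibble::tibble(species = unique(species),
                          window_start = activity_windows[1],
                          window_end = activity_windows[2]))
  }
  aw <- tibble::as_tibble(activity_windows)
  stopifnot(all(c("species", "window_start", "window_end") %in% names(aw)))
  aw
}

#' Assemble daily paths from a cleaned fix table
#'
#' Assigns every in-window fix to one behavioral day (the daily path). For
#' windows that span midnight the path is keyed to the date the window
#' starts, so one night of a nocturnal animal is one path. Flagged outliers
#' are excluded; a path is `complete` when no inter-fix gap inside it exceeds
#' `max_gap` (default one hour), the completeness rule used to admit a day
#' into distance summaries.
#'
#' @param fixes A fix tibble (outliers still present are dropped here).
#' @param activity_windows Either a `c(start, end)` "HH:MM" pair applied to
#'   all species, or a tibble like [bci_activity_windows()].
#' @param tz_local Timezone in which windows are evaluated (default UTC-5,
#'   fixed offset).
#' @param max_gap Completeness threshold in seconds.
#' @return The in-window fixes with added `period_date` (Date) and, joined
#'   per path, `complete` and `n_fixes`.
#' @export
assemble_daily_paths <- function(fixes, activity_windows = bci_activity_windows(),
                                 tz_local = "Etc/GMT+5", max_gap = 3600) {
  if (nrow(fixes) == 0) return(dplyr::mutate(fixes,
    period_date = as.Date(character()), complete = logical(),
    n_fixes = integer()))
  aw <- normalize_windows(activity_windows, fixes$species)
  f <- drop_outliers(fixes) %>%
    dplyr::inner_join(aw, by = "species")
  lt <- lubridate::with_tz(f$timestamp, tz_local)
  tod <- as.numeric(lt - lubridate::floor_date(lt, "day"), units = "secs")
  ws <- parse_hm(f$window_start)
  we <- parse_hm(f$window_end)
  spans <- ws > we
  in_win <- ifelse(spans, tod >= ws | tod <= we, tod >= ws & tod <= we)
  date0 <- as.Date(lubridate::floor_date(lt, "day"))
  period <- dplyr::if_else(spans & tod <= we, date0 - 1, date0)
  out <- f[in_win, setdiff(names(f), c("window_start", "window_end"))]
  out$period_date <- period[in_win]
  out <- dplyr::arrange(out, .data$individual_id, .data$timestamp)
  summ <- out %>%
    dplyr::group_by(.data$individual_id, .data$period_date) %>%
    dplyr::summarise(
      n_fixes = dplyr::n(),
      complete = dplyr::n() >= 2 &&
        max(diff(as.numeric(.data$timestamp))) <= max_gap,
      .groups = "drop")
  dplyr::left_join(out, summ, by = c("individual_id", "period_date"))
}

#' Summarize daily paths
#'
#' One row per individual-day with fix count, completeness, and the largest
#' inter-fix gap.
#'
#' @param daily_fixes Output of [assemble_daily_paths()].
#' @return Tibble keyed by `individual_id`, `species`, `period_date`.
#' @export
summarize_daily_paths <- function(daily_fixes) {
  daily_fixes %>%
    dplyr::group_by(.data$individual_id, .data$species, .data$period_date) %>%
    dplyr::summarise(
      n_fixes = dplyr::n(),
      max_gap_s = if (dplyr::n() >= 2)
        max(diff(as.numeric(.data$timestamp))) else NA_real_,
      complete = .data$complete[1],
      .groups = "drop")
}
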
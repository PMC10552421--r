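#' Total path distance
#'
#' Sum of straight-line distances between consecutive fixes; the daily
#' distance when applied to one daily path.
#'
#' @param x,y Coordinate vectors (meters), time-ordered.
#' @return Distance in meters (0 for fewer than 2 fixes).
#' @export
path_distance <- function(x, y) {
  if (length(x) < 2) return(0)
  sum(sqrt(diff(x)^2 + diff(y)^2))
}

#' Straightness index
#'
#' Ratio of the beeline distance (start to end) to the distance actually
#' travelled: 1 for a perfectly straight path, 0 for a closed loop. A
#' measure of orientation efficiency.
#'
#' @param x,y Coordinate vectors, time-ordered.
#' @return Value in \[0, 1\], or `NA` when the path has zero length.
#' @export
straightness_index <- function(x, y) {
  total <- path_distance(x, y)
  if (total == 0) return(NA_real_)
  sqrt((x[length(x)] - x[1])^2 + (y[length(y)] - y[1])^2) / total
}

#' Rediscretize a path to constant step length
#'
#' Resamples points spaced exactly `step` meters apart along the
#' piecewise-linear path, starting at the first fix; the trailing remainder
#' shorter than `step` is discarded. Used to put paths of different fix
#' rates on a common spatial scale before computing sinuosity.
#'
#' @param x,y Coordinate vectors, time-ordered.
#' @param step Resampling step in meters.
#' @return Tibble of resampled `x`, `y`.
#' @export
rediscretize_path <- function(x, y, step) {
  assert_positive(step, "step")
  seg <- sqrt(diff(x)^2 + diff(y)^2)
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  if (total < step) {
    abort("Path shorter than one rediscretization step.",
          class = "msms_too_short")
  }
  s <- seq(0, total, by = step)
  idx <- findInterval(s, cum, rightmost.closed = TRUE)
  idx <- pmin(idx, length(seg))
  frac <- ifelse(seg[idx] > 0, (s - cum[idx]) / seg[idx], 0)
  tibble::tibble(x = x[idx] + frac * diff(x)[idx],
                 y = y[idx] + frac * diff(y)[idx])
}

#' Corrected sinuosity index
#'
#' Tortuosity of a search path, computed on the rediscretized track:
#' `S = 2 * sqrt(1 / (p * (1 + c) / (1 - c)))` where `p` is the
#' rediscretization step (meters) and `c` the mean cosine of the
#' rediscretized turn angles. Units m^(-1/2); 0 for a straight path, larger
#' for more tortuous ones.
#'
#' @param x,y Coordinate vectors, time-ordered.
#' @param step Rediscretization step `p` in meters (use the species mean
#'   step length).
#' @param rediscretized Compute the mean cosine on the rediscretized path
#'   (default, the convention matching constant-step theory) or on the raw
#'   fix series.
#' @return Sinuosity (>= 0), or `NA` when fewer than 3 rediscretized points
#'   are available.
#' @export
sinuosity_index <- function(x, y, step, rediscretized = TRUE) {
  assert_positive(step, "step")
  if (rediscretized) {
    pts <- tryCatch(rediscretize_path(x, y, step),
                    msms_too_short = function(e) NULL)
    if (is.null(pts) || nrow(pts) < 3) return(NA_real_)
    xx <- pts$x; yy <- pts$y
  } else {
    if (length(x) < 3) return(NA_real_)
    xx <- x; yy <- y
  }
  h <- atan2(diff(yy), diff(xx))
  turns <- wrap_angle(diff(h))
  turns <- turns[!is.na(turns)]
  if (length(turns) < 1) return(NA_real_)
  cbar <- mean(cos(turns))
  cbar <- min(max(cbar, -1 + 1e-12), 1 - 1e-12)
  2 / sqrt(step * (1 + cbar) / (1 - cbar))
}

#' Species mean step length
#'
#' Mean observed step length pooled over all individuals of each species;
#' the rediscretization step used for that species' sinuosity.
#'
#' @param steps Output of [compute_steps()] carrying `species`.
#' @return Tibble `species`, `mean_step_m`.
#' @export
species_mean_step <- function(steps) {
  steps %>%
    dplyr::group_by(.data$species) %>%
    dplyr::summarise(mean_step_m = mean(.data$step_length, na.rm = TRUE),
                     .groups = "drop")
}

#' Daily-path metric table
#'
#' Computes the five path-scale metrics for every individual-day: total
#' distance, straightness, sinuosity (at the species mean step length), and
#' the proportions of fixes labeled cluster / ARS / travel (when a `label`
#' column from [segment_behavior()] is present). A day is `eligible` when it
#' has at least `min_fixes` locations and no gap over an hour; only eligible
#' days should enter cross-individual comparisons.
#'
#' @param daily_fixes Output of [assemble_daily_paths()], optionally with a
#'   `label` column.
#' @param species_step Optional tibble from [species_mean_step()]; computed
#'   from `daily_fixes` itself when `NULL`.
#' @param min_fixes Minimum locations per day (default 100).
#' @return Tibble with one row per individual-day: `individual_id`,
#'   `species`, `period_date`, `n_fixes`, `complete`, `eligible`,
#'   `distance_m`, `straightness`, `sinuosity`, `prop_cluster`, `prop_ars`,
#'   `prop_travel`.
#' @export
daily_path_metrics <- function(daily_fixes, species_step = NULL,
                               min_fixes = 100) {
  if (is.null(species_step)) {
    steps <- compute_steps(daily_fixes, by = c("individual_id", "period_date"))
    species_step <- species_mean_step(steps)
  }
  daily_fixes %>%
    dplyr::left_join(species_step, by = "species") %>%
    dplyr::group_by(.data$individual_id, .data$species, .data$period_date) %>%
    dplyr::group_modify(function(g, key) {
      g <- dplyr::arrange(g, .data$timestamp)
      n <- nrow(g)
      complete <- isTRUE(g$complete[1])
      eligible <- n >= min_fixes && complete
      dist <- path_distance(g$x, g$y)
      props <- rep(NA_real_, 3)
      if ("label" %in% names(g)) {
        lab <- g$label[!is.na(g$label)]
        if (length(lab) > 0) {
          props <- vapply(BEHAVIOR_LEVELS,
                          function(l) mean(lab == l), 0, USE.NAMES = FALSE)
        }
      }
      tibble::tibble(
        n_fixes = n, complete = complete, eligible = eligible,
        distance_m = if (complete) dist else NA_real_,
        straightness = if (n >= 2) straightness_index(g$x, g$y) else NA_real_,
        sinuosity = if (n >= 3 && is.finite(g$mean_step_m[1]))
          sinuosity_index(g$x, g$y, g$mean_step_m[1]) else NA_real_,
        prop_cluster = props[1], prop_ars = props[2], prop_travel = props[3])
    }) %>%
    dplyr::ungroup()
}
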
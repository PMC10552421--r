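#' Build a simulation configuration
#'
#' One simulated individual is a three-state (cluster / ARS / travel)
#' correlated random walk observed through a burst-structured GPS layer.
#' States switch each 4-min tick by a Markov chain; each tick the animal
#' moves a Gamma step length at a heading equal to the previous heading plus
#' a von Mises turn, blended with the unit vector toward a home-range center
#' with weight `attraction`. The observation layer emits a burst of
#' `burst_n` 1-Hz fixes per tick, adds negative-binomial radial GPS error to
#' each, and (emulating activity-informed collars) drops cluster-state
#' bursts with probability `acc_dropout`, creating the inactivity gaps the
#' preprocessing interpolates.
#'
#' @param species,individual_id Identifiers for the emitted fixes.
#' @param days Number of activity periods to simulate.
#' @param activity_window `c(start, end)` local "HH:MM" pair; windows where
#'   start > end span midnight.
#' @param states Named list `cluster`/`ars`/`travel`, each
#'   `list(k, theta, kappa)`: Gamma step parameters (meters per tick) and
#'   von Mises turn concentration.
#' @param transition 3x3 row-stochastic matrix in the order cluster, ars,
#'   travel.
#' @param attraction Home-range bias weight in \[0, 1) (0 = free walk).
#' @param center Attraction center `c(x, y)` in meters.
#' @param start Start `c(x, y)`.
#' @param start_date First (local) calendar date.
#' @param fix_interval Tick length in seconds (default 240).
#' @param burst_n Fixes per burst (default 6 at 1 Hz).
#' @param error_mean,error_dispersion Negative binomial GPS error model
#'   (meters).
#' @param acc_dropout Probability a cluster-state burst is suppressed.
#' @param tz_local Timezone of the activity window.
#' @param start_state Behavioral state of the first tick.
#' @return A `sim_config` list.
#' @export
sim_config <- function(species = "generic", individual_id = "sim_01",
                       days = 10, activity_window = c("06:00", "18:00"),
                       states = list(
                         cluster = list(k = 1, theta = 2, kappa = 0),
                         ars = list(k = 6, theta = 2.5, kappa = 2),
                         travel = list(k = 6, theta = 10, kappa = 3)),
                       transition = default_transition(),
                       attraction = 0.1, center = c(0, 0), start = c(0, 0),
                       start_date = as.Date("2016-01-01"),
                       fix_interval = 240, burst_n = 6,
                       error_mean = 5.46, error_dispersion = 2.4,
                       acc_dropout = 0, tz_local = "Etc/GMT+5",
                       start_state = "cluster") {
  cfg <- list(species = species, individual_id = individual_id, days = days,
              activity_window = activity_window, states = states,
              transition = transition, attraction = attraction,
              center = center, start = start, start_date = start_date,
              fix_interval = fix_interval, burst_n = burst_n,
              error_mean = error_mean, error_dispersion = error_dispersion,
              acc_dropout = acc_dropout, tz_local = tz_local,
              start_state = start_state)
  validate_sim_config(cfg)
  cfg
}

default_transition <- function() {
  matrix(c(0.85, 0.10, 0.05,
           0.10, 0.80, 0.10,
           0.05, 0.10, 0.85), 3, 3, byrow = TRUE,
         dimnames = list(BEHAVIOR_LEVELS, BEHAVIOR_LEVELS))
}

validate_sim_config <- function(cfg) {
  tm <- cfg$transition
  if (!is.matrix(tm) || any(dim(tm) != 3) || any(tm < 0) ||
      any(abs(rowSums(tm) - 1) > 1e-8)) {
    abort("Transition matrix must be 3x3 row-stochastic.",
          class = "msms_config_error")
  }
  for (s in BEHAVIOR_LEVELS) {
    st <- cfg$states[[s]]
    if (is.null(st) || st$k <= 0 || st$theta <= 0 || st$kappa < 0) {
      abort(sprintf("Invalid state parameters for '%s'.", s),
            class = "msms_config_error")
    }
  }
  if (cfg$attraction < 0 || cfg$attraction >= 1) {
    abort("attraction must be in [0, 1).", class = "msms_config_error")
  }
  invisible(cfg)
}

rvonmises <- function(n, mu, kappa) {
  # Best & Fisher (1979) rejection sampler
  if (kappa < 1e-8) return(runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1
  while (i <= n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    if (c_ * (2 - c_) - u[2] > 0 || log(c_ / u[2]) + 1 - c_ >= 0) {
      out[i] <- wrap_angle(mu + sign(u[3] - 0.5) * acos(f))
      i <- i + 1
    }
  }
  out
}

#' Simulate one tracked individual
#'
#' Runs the state-switching correlated random walk of a [sim_config()] and
#' its GPS observation layer. Fully reproducible: the same seed gives
#' bit-identical fix tables.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (set internally; `NULL` uses the current RNG
#'   state).
#' @return List with `fixes` (canonical fix tibble, burst-structured,
#'   last-of-burst flagged by `burst_id`) and `truth` (one row per tick:
#'   `timestamp`, `state`, `true_x`, `true_y`, `emitted`).
#' @export
simulate_individual <- function(config, seed = NULL) {
  validate_sim_config(config)
  if (!is.null(seed)) set.seed(seed)
  ws <- parse_hm(config$activity_window[1])
  we <- parse_hm(config$activity_window[2])
  span <- ws > we
  win_len <- if (span) (86400 - ws) + we else we - ws
  ticks_per_day <- floor(win_len / config$fix_interval) + 1

  day0 <- lubridate::force_tz(lubridate::as_datetime(config$start_date),
                              config$tz_local)
  # fixed-offset local timezone: plain seconds arithmetic is exact
  tick_times <- as.numeric(day0) +
    rep(86400 * (seq_len(config$days) - 1), each = ticks_per_day) +
    ws + config$fix_interval * (seq_len(ticks_per_day) - 1)

  n <- length(tick_times)
  states_i <- integer(n)
  x <- numeric(n); y <- numeric(n)
  states_i[1] <- match(config$start_state %||% "cluster", BEHAVIOR_LEVELS)
  x[1] <- config$start[1]; y[1] <- config$start[2]
  heading <- runif(1, -pi, pi)
  cum_tm <- t(apply(config$transition, 1, cumsum))
  u_state <- runif(n)
  for (i in 2:n) {
    states_i[i] <- findInterval(u_state[i], cum_tm[states_i[i - 1], ],
                                left.open = TRUE) + 1L
    st <- config$states[[states_i[i]]]
    turn <- rvonmises(1, 0, st$kappa)
    h_crw <- wrap_angle(heading + turn)
    if (config$attraction > 0) {
      to_c <- atan2(config$center[2] - y[i - 1],
                    config$center[1] - x[i - 1])
      vx <- (1 - config$attraction) * cos(h_crw) +
        config$attraction * cos(to_c)
      vy <- (1 - config$attraction) * sin(h_crw) +
        config$attraction * sin(to_c)
      heading <- atan2(vy, vx)
    } else {
      heading <- h_crw
    }
    len <- rgamma(1, shape = st$k, scale = st$theta)
    x[i] <- x[i - 1] + len * cos(heading)
    y[i] <- y[i - 1] + len * sin(heading)
  }
  state <- BEHAVIOR_LEVELS[states_i]

  drop <- state == "cluster" & runif(n) < config$acc_dropout
  emit <- which(!drop)
  bn <- config$burst_n
  m <- length(emit) * bn
  r <- rnbinom(m, size = config$error_dispersion, mu = config$error_mean)
  a <- runif(m, -pi, pi)
  fixes <- tibble::tibble(
    individual_id = config$individual_id,
    species = config$species,
    timestamp = lubridate::as_datetime(
      rep(tick_times[emit], each = bn) + rep(seq_len(bn) - 1, length(emit)),
      tz = "UTC"),
    x = rep(x[emit], each = bn) + r * cos(a),
    y = rep(y[emit], each = bn) + r * sin(a),
    altitude_hae = NA_real_,
    burst_id = rep(sprintf("%s_b%06d", config$individual_id, emit), each = bn),
    source = "observed",
    outlier_flags = "")
  truth <- tibble::tibble(
    individual_id = config$individual_id,
    species = config$species,
    timestamp = lubridate::as_datetime(tick_times, tz = "UTC"),
    state = state, true_x = x, true_y = y, emitted = !drop)
  list(fixes = fixes, truth = truth)
}

#' Species presets for a synthetic four-frugivore study
#'
#' Simulation configurations loosely parameterized from the four-species
#' Barro Colorado Island system: a nocturnal, cluster-heavy, small-range,
#' sinuous "kinkajou"; ARS/travel-heavy wide-ranging "coati" and "capuchin";
#' and a cluster-heavy but straight-traveling, very wide-ranging
#' "spider_monkey". Per-state step scales are solved so the expected true
#' daily path distance matches each species' target (3.3, 3.8, 3.7, 3.1 km)
#' given its window length and state mix; `target_daily_distance_m` is
#' recorded on each preset.
#'
#' @param days Days per individual.
#' @return Named list of `sim_config` templates (centers/start dates are
#'   filled by [simulate_study()]).
#' @export
species_presets <- function(days = 10) {
  mk_states <- function(mix, m_cluster, m_ars, m_travel, kappa_travel,
                        target) {
    list(states = list(
      cluster = list(k = 1, theta = m_cluster, kappa = 0),
      ars = list(k = 6, theta = m_ars / 6, kappa = 2),
      travel = list(k = 6, theta = m_travel / 6, kappa = kappa_travel)),
      mix = mix, target = target)
  }
  # reversible chain with exact stationary distribution `mix`: leave rate
  # c*(1 - mix_i) gives dwell times of ~7-10 ticks at c = 0.2
  mk_trans <- function(mix, c_rate = 0.2) {
    tm <- matrix(0, 3, 3, dimnames = list(BEHAVIOR_LEVELS, BEHAVIOR_LEVELS))
    for (i in 1:3) {
      tm[i, -i] <- c_rate * mix[-i]
      tm[i, i] <- 1 - c_rate * (1 - mix[i])
    }
    tm
  }
  solve_travel <- function(target, window_h, mix, m_cluster, m_ars) {
    ticks <- floor(window_h * 3600 / 240) + 1
    (target / ticks - mix[1] * m_cluster - mix[2] * m_ars) / mix[3]
  }
  presets <- list()
  spec <- list(
    kinkajou = list(window = c("23:00", "06:30"), window_h = 7.5,
                    mix = c(0.45, 0.15, 0.40), kappa_travel = 0.8,
                    target = 3300, attraction = 0.28),
    coati = list(window = c("06:00", "18:30"), window_h = 12.5,
                 mix = c(0.20, 0.45, 0.35), kappa_travel = 2,
                 target = 3800, attraction = 0.12),
    capuchin = list(window = c("06:00", "18:00"), window_h = 12,
                    mix = c(0.25, 0.40, 0.35), kappa_travel = 2,
                    target = 3700, attraction = 0.14),
    spider_monkey = list(window = c("06:00", "18:00"), window_h = 12,
                         mix = c(0.50, 0.15, 0.35), kappa_travel = 6,
                         target = 3100, attraction = 0.05))
  for (sp in names(spec)) {
    s <- spec[[sp]]
    m_travel <- solve_travel(s$target, s$window_h, s$mix, 2, 14)
    st <- mk_states(s$mix, 2, 14, m_travel, s$kappa_travel, s$target)
    cfg <- sim_config(
      species = sp, days = days, activity_window = s$window,
      states = st$states,
      transition = mk_trans(s$mix),
      attraction = s$attraction,
      acc_dropout = if (sp %in% c("kinkajou", "coati")) 0.3 else 0)
    cfg$target_daily_distance_m <- s$target
    presets[[sp]] <- cfg
  }
  presets
}

#' Simulate a multi-individual, multi-species study
#'
#' Draws `n_per_species` individuals from each preset, with home-range
#' centers spread on a grid so individuals do not share ranges, and returns
#' the pooled fix table plus the ground-truth sidecar.
#'
#' @param presets Named list of `sim_config`s (default [species_presets()]).
#' @param n_per_species Individuals per species.
#' @param seed Integer seed for the whole study.
#' @param spacing Center grid spacing in meters.
#' @return List with `fixes`, `truth`, and `presets`.
#' @export
simulate_study <- function(presets = species_presets(), n_per_species = 3,
                           seed = 1, spacing = 4000) {
  set.seed(seed)
  all_fixes <- list(); all_truth <- list()
  idx <- 0
  for (sp in names(presets)) {
    for (j in seq_len(n_per_species)) {
      idx <- idx + 1
      cfg <- presets[[sp]]
      cfg$individual_id <- sprintf("%s_%02d", sp, j)
      cfg$center <- c((idx %% 5) * spacing, (idx %/% 5) * spacing)
      cfg$start <- cfg$center
      sim <- simulate_individual(cfg, seed = NULL)
      all_fixes[[idx]] <- sim$fixes
      all_truth[[idx]] <- sim$truth
    }
  }
  list(fixes = dplyr::bind_rows(all_fixes),
       truth = dplyr::bind_rows(all_truth),
       presets = presets)
}
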
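# Fixture builders shared across the suite. Everything is generated in code;
# no stored data.

make_fixes <- function(x, y, t = seq_along(x) * 240, id = "a", species = "sp",
                       altitude = NA_real_, burst = NA_character_) {
  tibble::tibble(
    individual_id = id, species = species,
    timestamp = as.POSIXct("2016-01-01 12:00:00", tz = "UTC") + t,
    x = x, y = y,
    altitude_hae = altitude, burst_id = burst,
    source = "observed", outlier_flags = "")
}

# a daily-path-shaped table (adds period_date / complete columns)
make_daily <- function(x, y, t = seq_along(x) * 240 - 240, id = "a",
                       species = "sp", date = as.Date("2016-01-05")) {
  f <- make_fixes(x, y, t, id = id, species = species)
  f$period_date <- date
  f$complete <- TRUE
  f$n_fixes <- nrow(f)
  f
}

# constant-velocity track along the x axis
straight_track <- function(n, v = 1, dt = 60, id = "a") {
  make_fixes(x = v * dt * (seq_len(n) - 1), y = rep(0, n),
             t = dt * (seq_len(n) - 1), id = id)
}

unit_square <- function() {
  matrix(c(0, 0, 1, 0, 1, 1, 0, 1, 0, 0), ncol = 2, byrow = TRUE)
}

expect_flagged <- function(fixes, flag, idx) {
  expect_identical(which(msms::has_flag(fixes$outlier_flags, flag)),
                   as.integer(idx))
}
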
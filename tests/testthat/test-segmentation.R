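test_that("FPT on a stationary track is censored at the track duration", {
  n <- 11
  f <- make_fixes(x = rep(0, n), y = rep(0, n), t = 60 * (0:(n - 1)))
  r <- first_passage_time(f$timestamp, f$x, f$y, index = 6, radius = 15)
  expect_true(r$censored)
  expect_equal(r$fpt, 600)  # full duration, a lower bound
})

test_that("FPT on a constant-velocity track is 2r/v at interior fixes", {
  f <- straight_track(121, v = 1, dt = 10)
  r <- first_passage_time(f$timestamp, f$x, f$y, index = 61, radius = 15)
  expect_false(r$censored)
  expect_equal(r$fpt, 30, tolerance = 1e-9)
  r30 <- first_passage_time(f$timestamp, f$x, f$y, index = 61, radius = 30)
  expect_equal(r30$fpt, 60, tolerance = 1e-9)
})

test_that("FPT matches a fine-grid resampling oracle on a random walk", {
  set.seed(14)
  n <- 500
  dt <- 240
  x <- cumsum(rnorm(n, 0, 12)); y <- cumsum(rnorm(n, 0, 12))
  t <- dt * (seq_len(n) - 1)
  # dense 1-s linear resampling oracle
  tf <- seq(0, t[n], by = 1)
  xf <- approx(t, x, tf)$y; yf <- approx(t, y, tf)$y
  oracle_fpt <- function(i, radius) {
    d <- sqrt((xf - x[i])^2 + (yf - y[i])^2)
    i0 <- t[i] + 1
    fw <- which(d[(i0 + 1):length(d)] > radius)
    bw <- which(rev(d[1:(i0 - 1)]) > radius)
    fwt <- if (length(fw) == 0) t[n] - t[i] else fw[1]
    bwt <- if (length(bw) == 0) t[i] else bw[1]
    fwt + bwt
  }
  idx <- sample(20:(n - 20), 20)
  for (i in idx) {
    for (r in c(15, 30)) {
      mine <- first_passage_time(t, x, y, i, r)
      expect_equal(mine$fpt, oracle_fpt(i, r), tolerance = dt / mine$fpt)
    }
  }
})

test_that("FPT is non-decreasing in radius at every fix", {
  set.seed(15)
  x <- cumsum(rnorm(120, 0, 10)); y <- cumsum(rnorm(120, 0, 10))
  t <- 240 * (0:119)
  for (i in c(5, 40, 80, 115)) {
    fpts <- vapply(c(5, 10, 20, 40, 80),
                   function(r) first_passage_time(t, x, y, i, r)$fpt, 0)
    expect_true(all(diff(fpts) >= -1e-9))
  }
})

test_that("FPT classification implements the 15/30 m 12-min rules", {
  mk <- function(v) {
    n <- 60
    d <- make_daily(x = v * 240 * (0:(n - 1)), y = rep(0, n),
                    t = 240 * (0:(n - 1)))
    d
  }
  # slow wiggle: net < 15 m over any 12 min
  slow <- classify_fpt(mk(0.01))
  expect_true(all(slow$label[5:55] == "cluster"))
  # drift crossing 15 m within 12 min but not 30 m
  mid <- classify_fpt(mk(0.06))
  expect_true(all(mid$label[10:50] == "ars"))
  # fast travel exits 30 m in 60 s
  fast <- classify_fpt(mk(1))
  expect_true(all(fast$label[10:50] == "travel"))
})

test_that("day-edge fixes with short censored FPT stay unlabeled", {
  d <- make_daily(x = 0.06 * 240 * (0:59), y = rep(0, 60),
                  t = 240 * (0:59))
  seg <- classify_fpt(d)
  expect_true(is.na(seg$label[1]))
  expect_true(is.na(seg$label[60]))
  # censored at >= 720 s is still conclusive for cluster
  d2 <- make_daily(x = rep(0, 10), y = rep(0, 10), t = 240 * (0:9))
  seg2 <- classify_fpt(d2)
  expect_true(all(seg2$label == "cluster"))
})

test_that("any fix whose 12-min neighborhood fits in 7.5 m is a cluster", {
  set.seed(16)
  n <- 40
  # jittered stationary day: everything within a 5 m disc
  ang <- runif(n, -pi, pi); rad <- runif(n, 0, 5)
  d <- make_daily(x = rad * cos(ang), y = rad * sin(ang), t = 240 * (0:(n - 1)))
  seg <- classify_fpt(d)
  expect_true(all(seg$label == "cluster"))
})

test_that("CVM fit recovers eta and tau from simulated OU-velocity tracks", {
  set.seed(55)
  eta <- 0.5; tau <- 300
  sim_iou <- function(n_fix, dt_fix = 240) {
    # exact OU velocity on a 1-s grid, integrated to positions
    tt <- seq(0, (n_fix - 1) * dt_fix)
    rho <- exp(-1 / tau)
    sd_ax <- eta / sqrt(2)
    innov_sd <- sd_ax * sqrt(1 - rho^2)
    vx <- stats::filter(rnorm(length(tt), 0, innov_sd), rho, "recursive",
                        init = rnorm(1, 0, sd_ax))
    vy <- stats::filter(rnorm(length(tt), 0, innov_sd), rho, "recursive",
                        init = rnorm(1, 0, sd_ax))
    x <- cumsum(as.numeric(vx)); y <- cumsum(as.numeric(vy))
    keep <- 1 + dt_fix * (0:(n_fix - 1))
    list(t = tt[keep], x = x[keep], y = y[keep])
  }
  fits <- purrr::map_dfr(1:24, function(i) {
    s <- sim_iou(200)
    f <- fit_cvm(s$t, s$x, s$y)
    tibble::tibble(eta = f$eta, tau = f$tau)
  })
  expect_lt(abs(median(fits$eta) - eta) / eta, 0.10)
  expect_lt(abs(median(fits$tau) - tau) / tau, 0.25)
})

test_that("CVM: stationary jittered track has near-zero eta", {
  set.seed(56)
  t <- 240 * (0:30)
  f <- fit_cvm(t, rnorm(31, 0, 0.1), rnorm(31, 0, 0.1))
  expect_lt(f$eta, 0.01)
})

test_that("CVM: doubling coordinates doubles eta, leaves tau unchanged", {
  set.seed(57)
  t <- 240 * (0:99)
  x <- cumsum(rnorm(100, 0, 30)); y <- cumsum(rnorm(100, 0, 30))
  f1 <- fit_cvm(t, x, y)
  f2 <- fit_cvm(t, 2 * x, 2 * y)
  expect_equal(f2$eta, 2 * f1$eta, tolerance = 1e-4)
  expect_equal(f2$tau, f1$tau, tolerance = 1e-3)
})

test_that("three separated eta groups map to cluster/ars/travel by speed", {
  set.seed(58)
  seg <- tibble::tibble(
    individual_id = "a", period_date = as.Date("2016-01-01"),
    timestamp = as.POSIXct("2016-01-01", tz = "UTC") + 240 * (1:30),
    x = 0, y = 0,
    label = NA_character_, basis = NA_character_,
    eta = rep(c(0.01, 0.1, 1.0), each = 10) * exp(rnorm(30, 0, 0.05)),
    tau = rep(c(150, 300, 600), each = 10) * exp(rnorm(30, 0, 0.05)))
  out <- impute_edge_labels(seg)
  expect_equal(out$label, rep(c("cluster", "ars", "travel"), each = 10))
  expect_true(all(out$basis == "cvm_cluster"))
})

test_that("degenerate identical CVM records fall back with a warning", {
  seg <- tibble::tibble(
    individual_id = "a", period_date = as.Date("2016-01-01"),
    timestamp = as.POSIXct("2016-01-01", tz = "UTC") + 240 * (1:6),
    x = 0, y = 0,
    label = c("travel", "travel", "cluster", NA, NA, NA),
    basis = c("fpt", "fpt", "fpt", NA, NA, NA),
    eta = c(1, 1.1, 0.01, 0.5, 0.5, 0.5),
    tau = rep(300, 6))
  expect_warning(out <- impute_edge_labels(seg), "Degenerate|eta rank")
  expect_true(all(!is.na(out$label)))
})

test_that("Ward imputation matches a brute-force agglomerative oracle", {
  set.seed(59)
  n <- 90
  eta <- exp(rnorm(n, rep(c(-3, -1, 0.5), each = n / 3), 0.3))
  tau <- exp(rnorm(n, 5.5, 0.4))
  seg <- tibble::tibble(
    individual_id = "a", period_date = as.Date("2016-01-01"),
    timestamp = as.POSIXct("2016-01-01", tz = "UTC") + 240 * (1:n),
    x = 0, y = 0, label = NA_character_, basis = NA_character_,
    eta = eta, tau = tau)
  out <- impute_edge_labels(seg)

  # brute-force Ward (Lance-Williams) agglomeration on the same features
  Z <- scale(cbind(log(eta), log(tau)))
  d2 <- as.matrix(dist(Z))^2
  active <- as.list(seq_len(n))
  sizes <- rep(1, n)
  D <- d2
  diag(D) <- Inf
  while (length(active) > 3) {
    m <- length(active)
    ij <- which(D == min(D), arr.ind = TRUE)[1, ]
    i <- min(ij); j <- max(ij)
    ni <- sizes[i]; nj <- sizes[j]
    for (k in seq_len(m)) {
      if (k == i || k == j) next
      nk <- sizes[k]
      D[i, k] <- D[k, i] <- ((ni + nk) * D[i, k] + (nj + nk) * D[j, k] -
                               nk * D[i, j]) / (ni + nj + nk)
    }
    active[[i]] <- c(active[[i]], active[[j]])
    sizes[i] <- ni + nj
    active[[j]] <- NULL
    sizes <- sizes[-j]
    D <- D[-j, -j, drop = FALSE]
  }
  oracle <- integer(n)
  for (g in seq_along(active)) oracle[active[[g]]] <- g
  # same partition (labels may be permuted)
  got <- out$label
  expect_equal(length(unique(got)), 3)
  tab <- table(oracle, got)
  expect_equal(sum(apply(tab, 1, max)), n)  # one-to-one block structure
})

test_that("segment_behavior labels every fix of a simulated day", {
  set.seed(60)
  sim <- simulate_individual(sim_config(days = 2, error_mean = 2,
                                        error_dispersion = 2.4))
  f <- select_burst_last_fix(sim$fixes)
  d <- assemble_daily_paths(f, activity_windows = c("06:00", "18:00"))
  seg <- segment_behavior(d)
  expect_true(all(!is.na(seg$label)))
  expect_true(all(seg$label %in% c("cluster", "ars", "travel")))
  expect_true(all(seg$basis %in% c("fpt", "cvm_cluster", "nearest")))
})

test_that("noiseless separated-regime simulation is recovered above 0.8 balanced accuracy", {
  set.seed(61)
  cfg <- sim_config(days = 3, error_mean = 0, error_dispersion = 2.4,
                    acc_dropout = 0)
  sim <- simulate_individual(cfg)
  f <- select_burst_last_fix(sim$fixes)
  d <- assemble_daily_paths(f, activity_windows = c("06:00", "18:00"))
  seg <- segment_behavior(d)
  # last-of-burst fixes sit 5 s after the tick the truth is keyed to
  m <- dplyr::inner_join(
    dplyr::mutate(seg, tick = timestamp - (nrow(sim$fixes) / nrow(sim$truth) - 1)),
    dplyr::mutate(sim$truth, tick = timestamp),
    by = c("individual_id", "tick"))
  expect_gt(nrow(m), 100)
  bal_acc <- mean(vapply(split(m$label == m$state, m$state), mean, 0))
  expect_gt(bal_acc, 0.8)
})
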
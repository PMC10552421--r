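#' First passage time through a circle
#'
#' Time for the trajectory to first leave the circle of radius `radius`
#' centered on fix `index`, scanning both backward and forward from the fix
#' and summing the two passage durations. Crossing times are linearly
#' interpolated between the bracketing fixes. When the track starts or ends
#' inside the circle the corresponding side never exits and the value is a
#' lower bound (`censored = TRUE`).
#'
#' @param t Numeric times (seconds) or POSIXct.
#' @param x,y Coordinates (meters).
#' @param index Fix position the circle is centered on.
#' @param radius Circle radius in meters.
#' @return List with `fpt` (seconds) and `censored`.
#' @export
first_passage_time <- function(t, x, y, index, radius) {
  assert_positive(radius, "radius")
  t <- as.numeric(t)
  d <- sqrt((x - x[index])^2 + (y - y[index])^2)
  n <- length(t)

  cross_after <- function(i, j) {
    # first exit strictly between fixes i..j scanning forward
    out <- which(d[seq(i, j)] > radius)
    if (length(out) == 0) return(NA_real_)
    k <- out[1] + i - 1
    frac <- (radius - d[k - 1]) / (d[k] - d[k - 1])
    t[k - 1] + frac * (t[k] - t[k - 1])
  }
  fwd_cross <- if (index < n) cross_after(index + 1, n) else NA_real_
  bwd_cross <- if (index > 1) {
    out <- which(d[seq_len(index - 1)] > radius)
    if (length(out) == 0) NA_real_ else {
      k <- out[length(out)]
      frac <- (radius - d[k + 1]) / (d[k] - d[k + 1])
      t[k + 1] + frac * (t[k] - t[k + 1])
    }
  } else NA_real_

  fwd <- if (is.na(fwd_cross)) t[n] - t[index] else fwd_cross - t[index]
  bwd <- if (is.na(bwd_cross)) t[index] - t[1] else t[index] - bwd_cross
  list(fpt = fwd + bwd, censored = is.na(fwd_cross) || is.na(bwd_cross))
}

fpt_all <- function(t, x, y, radius) {
  n <- length(t)
  fpt <- numeric(n); cens <- logical(n)
  for (i in seq_len(n)) {
    r <- first_passage_time(t, x, y, i, radius)
    fpt[i] <- r$fpt; cens[i] <- r$censored
  }
  list(fpt = fpt, censored = cens)
}

#' Classify fixes by first passage time
#'
#' Behavioral classification over a 12-min window: a fix whose 15-m circle
#' is not exited within 720 s is a `cluster` (movement < 15 m, e.g. feeding
#' within one tree crown); failing that, a 30-m circle not exited within
#' 720 s is `ars` (area-restricted search, 15-30 m); otherwise `travel`
#' (> 30 m). A censored passage time below 720 s (the day's track ends
#' inside the circle before the verdict) leaves the fix unlabeled for
#' CVM-based imputation; a censored value at or above 720 s is still
#' conclusive, since the circle was provably not exited within the window.
#'
#' FPT is computed within each daily path, so labels never bridge days.
#'
#' @param daily_fixes Output of [assemble_daily_paths()].
#' @param radii Inner/outer radii in meters (default `c(15, 30)`).
#' @param window Decision window in seconds (default 720 = 12 min).
#' @return `daily_fixes` with columns `fpt15`, `fpt15_censored`, `fpt30`,
#'   `fpt30_censored`, `label` (`NA` where undecidable) and `basis`
#'   (`"fpt"`).
#' @export
classify_fpt <- function(daily_fixes, radii = c(15, 30), window = 720) {
  stopifnot(length(radii) == 2, radii[1] < radii[2])
  daily_fixes %>%
    dplyr::group_by(.data$individual_id, .data$period_date) %>%
    dplyr::group_modify(function(g, key) {
      g <- dplyr::arrange(g, .data$timestamp)
      t <- as.numeric(g$timestamp)
      f1 <- fpt_all(t, g$x, g$y, radii[1])
      f2 <- fpt_all(t, g$x, g$y, radii[2])
      lab <- rep(NA_character_, nrow(g))
      lab[f1$fpt >= window] <- "cluster"
      und <- is.na(lab)
      lab[und & !f1$censored & f2$fpt >= window] <- "ars"
      lab[und & !f1$censored & !f2$censored & f2$fpt < window] <- "travel"
      g$fpt15 <- f1$fpt; g$fpt15_censored <- f1$censored
      g$fpt30 <- f2$fpt; g$fpt30_censored <- f2$censored
      g$label <- lab
      g$basis <- ifelse(is.na(lab), NA_character_, "fpt")
      g
    }) %>%
    dplyr::ungroup()
}

# Covariance of position increments of an integrated Ornstein-Uhlenbeck
# velocity process (per axis variance sigma2, timescale tau) over intervals
# [t_i, t_{i+1}].
cvm_increment_cov <- function(t, sigma2, tau) {
  n <- length(t) - 1
  a <- t[-length(t)]; b <- t[-1]
  V <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d <- b[i] - a[i]
    V[i, i] <- 2 * sigma2 * tau * (d - tau * (1 - exp(-d / tau)))
    if (i < n) {
      j <- (i + 1):n
      V[i, j] <- V[j, i] <- sigma2 * tau^2 *
        (exp(-(a[j] - b[i]) / tau) - exp(-(b[j] - b[i]) / tau) -
           exp(-(a[j] - a[i]) / tau) + exp(-(b[j] - a[i]) / tau))
    }
  }
  V
}

#' Fit a correlated velocity model to a track window
#'
#' Maximum-likelihood fit of the continuous-time correlated velocity model
#' (Ornstein-Uhlenbeck velocity) to a window of positions, via the exact
#' Gaussian likelihood of the position increments (isotropic, independent
#' axes). Returns `eta`, the root-mean-squared (2-D) velocity, and `tau`,
#' the velocity autocorrelation timescale — the two statistics that mirror
#' first-passage behavior but are computable at every fix, including the
#' start and end of a day where FPT is censored.
#'
#' @param t Times (seconds or POSIXct).
#' @param x,y Coordinates (meters).
#' @return Object of class `cvm_fit`: `eta` (m/s), `tau` (s), `loglik`,
#'   `n`, `converged`.
#' @export
fit_cvm <- function(t, x, y) {
  t <- as.numeric(t)
  n <- length(t)
  if (n < 8) abort("CVM fit needs >= 8 fixes.",
                   class = "msms_insufficient_data")
  dx <- diff(x); dy <- diff(y); dt <- diff(t)
  if (any(dt <= 0)) abort("Times must be strictly increasing.",
                          class = "msms_validation_error")
  v2 <- mean((dx^2 + dy^2) / dt^2)
  eta0 <- sqrt(max(v2, 1e-12))
  tau0 <- median(dt)
  # timescales below a fraction of the sampling interval are not resolvable
  # (the white-noise ridge sigma^2 -> Inf, tau -> 0 fits GPS jitter with
  # arbitrarily large rms speed); bound tau to the identifiable range
  tau_lo <- log(min(dt) / 4)
  tau_hi <- log(10 * (t[n] - t[1]))
  nll <- function(par) {
    sigma2 <- exp(par[1]); tau <- exp(par[2])
    V <- cvm_increment_cov(t, sigma2, tau)
    ch <- tryCatch(chol(V + diag(1e-10 * max(diag(V)), nrow(V))),
                   error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    ld <- 2 * sum(log(diag(ch)))
    q <- function(z) sum(backsolve(ch, z, transpose = TRUE)^2)
    0.5 * (2 * ld + q(dx) + q(dy)) + (n - 1) * log(2 * pi)
  }
  fit <- tryCatch(
    optim(c(log(eta0^2 / 2), min(max(log(tau0), tau_lo), tau_hi)), nll,
          method = "L-BFGS-B",
          lower = c(-40, tau_lo), upper = c(40, tau_hi),
          control = list(maxit = 500, factr = 1e4)),
    error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$value) || fit$value >= 1e10) {
    return(structure(list(eta = NA_real_, tau = NA_real_, loglik = NA_real_,
                          n = n, converged = FALSE), class = "cvm_fit"))
  }
  sigma2 <- exp(fit$par[1]); tau <- exp(fit$par[2])
  structure(list(eta = sqrt(2 * sigma2), tau = tau, loglik = -fit$value,
                 n = n, converged = fit$convergence == 0),
            class = "cvm_fit")
}

#' @export
print.cvm_fit <- function(x, ...) {
  cat(sprintf("CVM fit: eta = %.4f m/s, tau = %.1f s (n = %d, %s)\n",
              x$eta, x$tau, x$n,
              if (isTRUE(x$converged)) "converged" else "not converged"))
  invisible(x)
}

#' @export
tidy.cvm_fit <- function(x, ...) {
  tibble::tibble(term = c("eta", "tau"), estimate = c(x$eta, x$tau))
}

#' Sliding-window CVM parameters
#'
#' Fits the correlated velocity model in a centered window of `window` fixes
#' around each requested fix of each daily path (edge windows shrink, down
#' to `min_fixes`).
#'
#' @param daily_fixes Output of [assemble_daily_paths()] (optionally already
#'   labeled).
#' @param at Logical vector (length `nrow(daily_fixes)`) selecting fixes to
#'   fit; default all.
#' @param window Window size in fixes (default 31, about two hours at 4-min
#'   sampling).
#' @param min_fixes Minimum usable window (default 8).
#' @return `daily_fixes` with `eta` and `tau` columns (NA where not fitted
#'   or non-convergent).
#' @export
cvm_params <- function(daily_fixes, at = NULL, window = 31, min_fixes = 8) {
  if (is.null(at)) at <- rep(TRUE, nrow(daily_fixes))
  daily_fixes$.at <- at
  half <- window %/% 2
  out <- daily_fixes %>%
    dplyr::group_by(.data$individual_id, .data$period_date) %>%
    dplyr::group_modify(function(g, key) {
      g <- dplyr::arrange(g, .data$timestamp)
      n <- nrow(g)
      g$eta <- NA_real_; g$tau <- NA_real_
      for (i in which(g$.at)) {
        lo <- max(1, i - half); hi <- min(n, i + half)
        if (hi - lo + 1 < min_fixes) next
        f <- fit_cvm(g$timestamp[lo:hi], g$x[lo:hi], g$y[lo:hi])
        if (isTRUE(f$converged)) { g$eta[i] <- f$eta; g$tau[i] <- f$tau }
      }
      g
    }) %>%
    dplyr::ungroup()
  out$.at <- NULL
  out
}

#' Impute behavior labels at path edges from CVM parameters
#'
#' Fixes left unlabeled by [classify_fpt()] (their 12-min window was
#' truncated by the start or end of the day) are grouped by Ward
#' agglomerative clustering on standardized (log eta, log tau) into three
#' clusters, mapped to behaviors by ascending mean eta: slowest cluster ->
#' `cluster`, middle -> `ars`, fastest -> `travel`. With fewer than 3
#' unlabeled records (or a degenerate clustering) each record falls back to
#' the label whose FPT-labeled group has the nearest mean log eta, with a
#' warning.
#'
#' @param seg Output of [classify_fpt()] piped through [cvm_params()];
#'   must carry `label`, `eta`, `tau`.
#' @return `seg` with imputed labels (`basis = "cvm_cluster"`). Unlabeled
#'   fixes without valid CVM parameters inherit the nearest-in-time label of
#'   their day (`basis = "nearest"`), so every fix ends up labeled.
#' @export
impute_edge_labels <- function(seg) {
  unl <- which(is.na(seg$label) & is.finite(seg$eta) & is.finite(seg$tau) &
                 seg$eta > 0 & seg$tau > 0)
  lab_means <- seg %>%
    dplyr::filter(!is.na(.data$label), is.finite(.data$eta), .data$eta > 0) %>%
    dplyr::group_by(.data$label) %>%
    dplyr::summarise(m = mean(log(.data$eta)), .groups = "drop")

  nearest_by_eta <- function(logeta) {
    if (nrow(lab_means) == 0) return(rep(NA_character_, length(logeta)))
    lab_means$label[max.col(-abs(outer(logeta, lab_means$m, "-")))]
  }

  if (length(unl) >= 3) {
    Z <- cbind(log(seg$eta[unl]), log(seg$tau[unl]))
    sds <- apply(Z, 2, sd)
    if (any(sds == 0) || nrow(unique(Z)) < 3) {
      warn("Degenerate CVM parameters among unlabeled fixes; assigning by eta rank against labeled groups.")
      seg$label[unl] <- nearest_by_eta(Z[, 1])
      seg$basis[unl] <- "cvm_cluster"
    } else {
      Zs <- scale(Z)
      hc <- hclust(dist(Zs), method = "ward.D2")
      cl <- cutree(hc, k = 3)
      ord <- order(tapply(seg$eta[unl], cl, mean))
      map <- character(3)
      map[ord] <- BEHAVIOR_LEVELS
      seg$label[unl] <- map[cl]
      seg$basis[unl] <- "cvm_cluster"
    }
  } else if (length(unl) > 0) {
    warn("Fewer than 3 unlabeled fixes with CVM parameters; using nearest labeled group in eta.")
    seg$label[unl] <- nearest_by_eta(log(seg$eta[unl]))
    seg$basis[unl] <- "cvm_cluster"
  }

  # any fix still unlabeled inherits the nearest labeled fix of its day
  still <- is.na(seg$label)
  if (any(still)) {
    seg <- seg %>%
      dplyr::group_by(.data$individual_id, .data$period_date) %>%
      dplyr::group_modify(function(g, key) {
        miss <- which(is.na(g$label))
        have <- which(!is.na(g$label))
        if (length(miss) > 0 && length(have) > 0) {
          tt <- as.numeric(g$timestamp)
          for (i in miss) {
            j <- have[which.min(abs(tt[have] - tt[i]))]
            g$label[i] <- g$label[j]
            g$basis[i] <- "nearest"
          }
        }
        g
      }) %>%
      dplyr::ungroup()
  }
  seg
}

#' Segment behavior for every fix of every daily path
#'
#' The full segmentation chain: FPT classification at 15/30 m over a 12-min
#' window, CVM parameter estimation for the undecidable (edge) fixes, and
#' Ward-cluster imputation of their labels.
#'
#' @inheritParams classify_fpt
#' @inheritParams cvm_params
#' @return `daily_fixes` with `fpt15`, `fpt30`, censoring flags, `eta`,
#'   `tau`, `label`, `basis`; every fix labeled.
#' @export
segment_behavior <- function(daily_fixes, radii = c(15, 30), window = 720,
                             cvm_window = 31, min_fixes = 8) {
  seg <- classify_fpt(daily_fixes, radii = radii, window = window)
  need <- is.na(seg$label)
  if (any(need)) {
    seg <- cvm_params(seg, at = need, window = cvm_window,
                      min_fixes = min_fixes)
    seg <- impute_edge_labels(seg)
  } else {
    seg$eta <- NA_real_; seg$tau <- NA_real_
  }
  seg
}
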
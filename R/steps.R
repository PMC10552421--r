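#' Compute step lengths, headings, and turn angles
#'
#' The step is the smallest trajectory unit: the displacement between two
#' consecutive analysis fixes (here the 4-min last-of-burst series, observed
#' plus interpolated). A turn angle needs three consecutive fixes and is the
#' wrapped difference between successive headings, attached to the later
#' step. Zero-length steps have no heading, so turn angles touching them are
#' left `NA` rather than fabricated; the count of such dropped angles is
#' reported via `attr(, "n_dropped_turns")`.
#'
#' @param fixes A fix tibble (or daily-path tibble).
#' @param by Grouping columns defining one track each; turn angles never
#'   bridge groups. Default per individual; add `"period_date"` for per-day
#'   series.
#' @return Tibble with one row per step: the grouping columns, `t0`, `t1`,
#'   `dt` (s), `step_length` (m), `heading` and `turn_angle` (radians in
#'   (-pi, pi]).
#' @examples
#' f <- tibble::tibble(individual_id = "a", species = "sp",
#'   timestamp = as.POSIXct("2020-01-01", tz = "UTC") + 240 * (0:2),
#'   x = c(0, 1, 1), y = c(0, 0, 1))
#' compute_steps(f)
#' @export
compute_steps <- function(fixes, by = "individual_id") {
  if (any(!is.finite(fixes$x) | !is.finite(fixes$y))) {
    abort("Fix coordinates must be finite.", class = "msms_validation_error")
  }
  keep_meta <- intersect(c("species"), names(fixes))
  out <- fixes %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) %>%
    dplyr::group_modify(function(g, key) {
      g <- dplyr::arrange(g, .data$timestamp)
      n <- nrow(g)
      if (n < 2) {
        return(tibble::tibble(t0 = g$timestamp[0], t1 = g$timestamp[0],
                              dt = numeric(0), step_length = numeric(0),
                              heading = numeric(0), turn_angle = numeric(0)))
      }
      dx <- diff(g$x); dy <- diff(g$y)
      len <- sqrt(dx^2 + dy^2)
      head_ <- ifelse(len > 0, atan2(dy, dx), NA_real_)
      turn <- c(NA_real_, wrap_angle(diff(head_)))
      res <- tibble::tibble(
        t0 = g$timestamp[-n], t1 = g$timestamp[-1],
        dt = diff(as.numeric(g$timestamp)),
        step_length = len, heading = head_, turn_angle = turn)
      for (m in keep_meta) res[[m]] <- g[[m]][-n]
      res
    }) %>%
    dplyr::ungroup()
  # turns undefined because a bounding step had zero length (not track edges)
  n_dropped <- sum(is.na(out$turn_angle) &
                     (out$step_length == 0 | c(FALSE, head(out$step_length, -1) == 0)))
  attr(out, "n_dropped_turns") <- n_dropped
  out
}

#' Fit a Gamma distribution to step lengths
#'
#' Maximum-likelihood Gamma fit (shape `k`, scale `theta`) to strictly
#' positive step lengths, the step-scale model for displacement magnitude.
#' Zeros are excluded (their count is kept on the fit). The MLE is computed
#' by Newton iteration on the profile likelihood equation
#' `log(k) - digamma(k) = log(mean(x)) - mean(log(x))` with `theta =
#' mean(x)/k`, converged to 1e-8 in the parameters.
#'
#' @param lengths Numeric vector of step lengths (meters).
#' @return Object of class `gamma_fit` with elements `k`, `theta`, `loglik`,
#'   `n`, `n_zero`.
#' @export
fit_gamma <- function(lengths) {
  x <- lengths[!is.na(lengths)]
  n_zero <- sum(x <= 0)
  x <- x[x > 0]
  if (length(x) < 10) {
    abort("Gamma fit needs >= 10 strictly positive step lengths.",
          class = "msms_insufficient_data")
  }
  if (diff(range(x)) == 0) {
    abort("All step lengths identical; Gamma fit is degenerate.",
          class = "msms_degenerate_data")
  }
  mx <- mean(x)
  s <- log(mx) - mean(log(x))
  k <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
  for (i in 1:100) {
    f <- log(k) - digamma(k) - s
    step <- f / (1 / k - trigamma(k))
    k_new <- k - step
    if (k_new <= 0) k_new <- k / 2
    if (abs(k_new - k) < 1e-8 * max(1, k)) { k <- k_new; break }
    k <- k_new
  }
  theta <- mx / k
  structure(
    list(k = k, theta = theta,
         loglik = sum(dgamma(x, shape = k, scale = theta, log = TRUE)),
         n = length(x), n_zero = n_zero),
    class = "gamma_fit")
}

#' Fit a von Mises distribution to turn angles
#'
#' Maximum-likelihood von Mises fit (mean direction `mu`, concentration
#' `kappa`) to turn angles, the step-scale model for directional
#' persistence. `mu` is the circular mean; `kappa` solves `A1(kappa) =
#' Rbar` (the mean resultant length) by standard series initialisation plus
#' Newton refinement on the Bessel ratio, capped at `kappa_max` for
#' near-degenerate (point-mass) data.
#'
#' @param angles Numeric vector of angles in radians.
#' @param kappa_max Concentration cap (default 500).
#' @return Object of class `vonmises_fit` with `mu`, `kappa`, `rbar`,
#'   `loglik`, `n`.
#' @export
fit_vonmises <- function(angles, kappa_max = 500) {
  x <- angles[!is.na(angles)]
  if (length(x) < 10) {
    abort("von Mises fit needs >= 10 angles.",
          class = "msms_insufficient_data")
  }
  C <- mean(cos(x)); S <- mean(sin(x))
  rbar <- sqrt(C^2 + S^2)
  mu <- atan2(S, C)
  a1 <- function(k) besselI(k, 1, expon.scaled = TRUE) /
    besselI(k, 0, expon.scaled = TRUE)
  if (rbar >= 1 - 1e-8) {
    kappa <- kappa_max
  } else if (rbar < 1e-8) {
    kappa <- 0
  } else {
    kappa <- if (rbar < 0.53) 2 * rbar + rbar^3 + 5 * rbar^5 / 6
    else if (rbar < 0.85) -0.4 + 1.39 * rbar + 0.43 / (1 - rbar)
    else 1 / (rbar^3 - 4 * rbar^2 + 3 * rbar)
    for (i in 1:50) {
      A <- a1(kappa)
      dA <- 1 - A / kappa - A^2
      stepn <- (A - rbar) / dA
      kappa_new <- kappa - stepn
      if (kappa_new <= 0) kappa_new <- kappa / 2
      if (kappa_new >= kappa_max) { kappa <- kappa_max; break }
      if (abs(kappa_new - kappa) < 1e-10 * max(1, kappa)) {
        kappa <- kappa_new; break
      }
      kappa <- kappa_new
    }
    kappa <- min(kappa, kappa_max)
  }
  ll <- sum(kappa * cos(x - mu)) - length(x) *
    (log(2 * pi) + log(besselI(kappa, 0, expon.scaled = TRUE)) + kappa)
  structure(list(mu = mu, kappa = kappa, rbar = rbar, loglik = ll,
                 n = length(x)),
            class = "vonmises_fit")
}

#' Per-individual step-scale distribution parameters
#'
#' Pools each individual's steps over the entire study and fits the Gamma
#' step-length and von Mises turn-angle distributions, producing the
#' step-scale metric table (one row per individual) consumed by the
#' variance-partition and syndrome analyses.
#'
#' @param steps Output of [compute_steps()] (must carry `species`).
#' @param min_steps Minimum usable steps/turns per individual; individuals
#'   below it are dropped with a warning.
#' @return Tibble with columns `individual_id`, `species`, `n_steps`,
#'   `n_turns`, `gamma_k`, `gamma_theta`, `vm_mu`, `vm_kappa`.
#' @export
fit_step_distributions <- function(steps, min_steps = 10) {
  res <- steps %>%
    dplyr::group_by(.data$individual_id, .data$species) %>%
    dplyr::group_modify(function(g, key) {
      len <- g$step_length[!is.na(g$step_length) & g$step_length > 0]
      ang <- g$turn_angle[!is.na(g$turn_angle)]
      if (length(len) < min_steps || length(ang) < min_steps) {
        return(tibble::tibble(n_steps = length(len), n_turns = length(ang),
                              gamma_k = NA_real_, gamma_theta = NA_real_,
                              vm_mu = NA_real_, vm_kappa = NA_real_))
      }
      gf <- fit_gamma(len)
      vf <- fit_vonmises(ang)
      tibble::tibble(n_steps = gf$n, n_turns = vf$n,
                     gamma_k = gf$k, gamma_theta = gf$theta,
                     vm_mu = vf$mu, vm_kappa = vf$kappa)
    }) %>%
    dplyr::ungroup()
  if (anyNA(res$gamma_k)) {
    warn(sprintf("%d individual(s) had too few steps for distribution fits.",
                 sum(is.na(res$gamma_k))))
  }
  res
}

#' @export
print.gamma_fit <- function(x, ...) {
  cat(sprintf("Gamma step-length fit: k = %.4f, theta = %.4f m (n = %d, logLik = %.2f)\n",
              x$k, x$theta, x$n, x$loglik))
  if (x$n_zero > 0) cat(sprintf("  (%d zero-length steps excluded)\n", x$n_zero))
  invisible(x)
}

#' @export
print.vonmises_fit <- function(x, ...) {
  cat(sprintf("von Mises turn-angle fit: mu = %.4f rad, kappa = %.4f (Rbar = %.4f, n = %d)\n",
              x$mu, x$kappa, x$rbar, x$n))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.gamma_fit <- function(x, ...) {
  tibble::tibble(term = c("k", "theta"), estimate = c(x$k, x$theta))
}

#' @export
glance.gamma_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, n = x$n, n_zero = x$n_zero)
}

#' @export
tidy.vonmises_fit <- function(x, ...) {
  tibble::tibble(term = c("mu", "kappa"), estimate = c(x$mu, x$kappa))
}

#' @export
glance.vonmises_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, rbar = x$rbar, n = x$n)
}
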
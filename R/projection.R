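#' Universal Transverse Mercator projection
#'
#' Forward and inverse UTM (WGS84) projection used to place longitude/latitude
#' tracking data on a planar metric grid at ingestion. The transverse Mercator
#' mapping uses the Krüger series in the third flattening carried to sixth
#' order, which is accurate well below a millimeter over a UTM zone — ample
#' for GPS relocations whose own error is meters.
#'
#' All trajectory geometry in this package (step lengths, path metrics, home
#' ranges) is Euclidean in meters, so lon/lat inputs are projected once and
#' analyses never touch spherical coordinates again.
#'
#' @param lon,lat Longitude and latitude in decimal degrees (WGS84).
#' @param zone UTM zone number (1-60). Defaults to the zone of the data
#'   centroid.
#' @param hemisphere `"north"` or `"south"`; controls the false northing.
#' @return `project_utm()` returns a tibble with columns `x`, `y` (meters,
#'   easting/northing), plus `zone` and `hemisphere` as attributes of the
#'   tibble (`attr(, "crs")`). `unproject_utm()` returns a tibble with `lon`,
#'   `lat`.
#' @examples
#' pts <- project_utm(c(-79.85, -79.84), c(9.15, 9.16))
#' unproject_utm(pts$x, pts$y, zone = attr(pts, "crs")$zone)
#' @export
project_utm <- function(lon, lat, zone = NULL, hemisphere = c("north", "south")) {
  hemisphere <- match.arg(hemisphere)
  if (length(lon) != length(lat)) abort("`lon` and `lat` lengths differ.")
  if (any(abs(lat) > 84, na.rm = TRUE)) {
    abort("UTM is undefined poleward of 84 degrees latitude.",
          class = "msms_config_error")
  }
  if (is.null(zone)) zone <- utm_zone(mean(lon, na.rm = TRUE))
  lam0 <- (6 * zone - 183) * pi / 180
  k0 <- 0.9996

  phi <- lat * pi / 180
  dl <- wrap_angle(lon * pi / 180 - lam0)

  e <- .tm$e
  # conformal latitude
  tau <- tan(phi)
  sigma <- sinh(e * atanh(e * sin(phi)))
  taup <- tau * sqrt(1 + sigma^2) - sigma * sqrt(1 + tau^2)

  xi0 <- atan2(taup, cos(dl))
  eta0 <- asinh(sin(dl) / sqrt(taup^2 + cos(dl)^2))

  xi <- xi0
  eta <- eta0
  for (j in seq_along(.tm$alpha)) {
    xi <- xi + .tm$alpha[j] * sin(2 * j * xi0) * cosh(2 * j * eta0)
    eta <- eta + .tm$alpha[j] * cos(2 * j * xi0) * sinh(2 * j * eta0)
  }

  x <- k0 * .tm$A * eta + 5e5
  y <- k0 * .tm$A * xi + if (hemisphere == "south") 1e7 else 0
  out <- tibble::tibble(x = x, y = y)
  attr(out, "crs") <- list(projection = "utm", zone = zone,
                           hemisphere = hemisphere, datum = "WGS84")
  out
}

#' @rdname project_utm
#' @param x,y Easting and northing in meters.
#' @export
unproject_utm <- function(x, y, zone, hemisphere = c("north", "south")) {
  hemisphere <- match.arg(hemisphere)
  k0 <- 0.9996
  lam0 <- (6 * zone - 183) * pi / 180
  xi <- (y - if (hemisphere == "south") 1e7 else 0) / (k0 * .tm$A)
  eta <- (x - 5e5) / (k0 * .tm$A)

  xi0 <- xi
  eta0 <- eta
  for (j in seq_along(.tm$beta)) {
    xi0 <- xi0 - .tm$beta[j] * sin(2 * j * xi) * cosh(2 * j * eta)
    eta0 <- eta0 - .tm$beta[j] * cos(2 * j * xi) * sinh(2 * j * eta)
  }

  taup <- sin(xi0) / sqrt(sinh(eta0)^2 + cos(xi0)^2)
  dl <- atan2(sinh(eta0), cos(xi0))

  # invert the conformal latitude by Newton iteration on tau
  e <- .tm$e
  tau <- taup
  for (i in 1:8) {
    sigma <- sinh(e * atanh(e * tau / sqrt(1 + tau^2)))
    taupi <- tau * sqrt(1 + sigma^2) - sigma * sqrt(1 + tau^2)
    dtau <- (taup - taupi) * (1 + (1 - e^2) * tau^2) /
      ((1 - e^2) * sqrt((1 + taupi^2) * (1 + tau^2)))
    tau <- tau + dtau
    if (all(abs(dtau) < 1e-14, na.rm = TRUE)) break
  }
  phi <- atan(tau)
  tibble::tibble(lon = (dl + lam0) * 180 / pi, lat = phi * 180 / pi)
}

#' @rdname project_utm
#' @export
utm_zone <- function(lon) {
  z <- floor((wrap_angle(lon * pi / 180) * 180 / pi + 180) / 6) + 1
  as.integer(pmin(pmax(z, 1), 60))
}

# WGS84 transverse Mercator series constants (third flattening n).
.tm <- local({
  a <- 6378137
  f <- 1 / 298.257223563
  n <- f / (2 - f)
  A <- a / (1 + n) * (1 + n^2 / 4 + n^4 / 64 + n^6 / 256)
  alpha <- c(
    n / 2 - 2 * n^2 / 3 + 5 * n^3 / 16 + 41 * n^4 / 180 - 127 * n^5 / 288 +
      7891 * n^6 / 37800,
    13 * n^2 / 48 - 3 * n^3 / 5 + 557 * n^4 / 1440 + 281 * n^5 / 630 -
      1983433 * n^6 / 1935360,
    61 * n^3 / 240 - 103 * n^4 / 140 + 15061 * n^5 / 26880 +
      167603 * n^6 / 181440,
    49561 * n^4 / 161280 - 179 * n^5 / 168 + 6601661 * n^6 / 7257600,
    34729 * n^5 / 80640 - 3418889 * n^6 / 1995840,
    212378941 * n^6 / 319334400
  )
  beta <- c(
    n / 2 - 2 * n^2 / 3 + 37 * n^3 / 96 - n^4 / 360 - 81 * n^5 / 512 +
      96199 * n^6 / 604800,
    n^2 / 48 + n^3 / 15 - 437 * n^4 / 1440 + 46 * n^5 / 105 -
      1118711 * n^6 / 3870720,
    17 * n^3 / 480 - 37 * n^4 / 840 - 209 * n^5 / 4480 + 5569 * n^6 / 90720,
    4397 * n^4 / 161280 - 11 * n^5 / 504 - 830251 * n^6 / 7257600,
    4583 * n^5 / 161280 - 108847 * n^6 / 3991680,
    20648693 * n^6 / 638668800
  )
  list(a = a, f = f, n = n, A = A, e = sqrt(f * (2 - f)),
       alpha = alpha, beta = beta)
})
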
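#' Potential density anomaly of seawater
#'
#' Computes the potential density anomaly referenced to the surface,
#' `sigma_theta = rho(S, theta, 0) - 1000` kg/m^3, using the UNESCO (EOS-80)
#' one-atmosphere equation of state (Millero & Poisson polynomial) and the
#' Fofonoff adiabatic-lapse-rate integration for potential temperature. At
#' surface pressure the potential and in-situ temperatures coincide, so for
#' the shallow CTD casts this pipeline targets the pressure correction is a
#' refinement, not a requirement.
#'
#' @param temperature In-situ temperature, degrees C (valid -2 to 40).
#' @param salinity Practical salinity (valid 0 to 42).
#' @param pressure Pressure, decibars (default 0; depth in meters is an
#'   adequate stand-in for shallow casts).
#' @return sigma-theta, kg/m^3 (vectorized).
#' @export
#' @examples
#' potential_density(10, 35) > potential_density(20, 35)  # colder is denser
potential_density <- function(temperature, salinity, pressure = 0) {
  if (any(temperature < -2 | temperature > 40)) {
    stop("potential_density: temperature outside [-2, 40] C", call. = FALSE)
  }
  if (any(salinity < 0 | salinity > 42)) {
    stop("potential_density: salinity outside [0, 42]", call. = FALSE)
  }
  if (any(pressure < 0)) {
    stop("potential_density: pressure must be >= 0 db", call. = FALSE)
  }
  theta <- potential_temperature(salinity, temperature, pressure, 0)
  density_surface(salinity, theta) - 1000
}

# EOS-80 density at one atmosphere (kg/m^3), Millero & Poisson polynomial.
density_surface <- function(S, T) {
  rho_w <- 999.842594 + 6.793952e-2 * T - 9.095290e-3 * T^2 +
    1.001685e-4 * T^3 - 1.120083e-6 * T^4 + 6.536332e-9 * T^5
  A <- 8.24493e-1 - 4.0899e-3 * T + 7.6438e-5 * T^2 -
    8.2467e-7 * T^3 + 5.3875e-9 * T^4
  B <- -5.72466e-3 + 1.0227e-4 * T - 1.6546e-6 * T^2
  C <- 4.8314e-4
  rho_w + A * S + B * S^1.5 + C * S^2
}

# Adiabatic temperature gradient (deg C / decibar), EOS-80.
adiabatic_gradient <- function(S, T, P) {
  ds <- S - 35
  3.5803e-5 + 8.5258e-6 * T - 6.836e-8 * T^2 + 6.6228e-10 * T^3 +
    (1.8932e-6 - 4.2393e-8 * T) * ds +
    (1.8741e-8 - 6.7795e-10 * T + 8.733e-12 * T^2 - 5.4481e-14 * T^3) * P +
    (-1.1351e-10 + 2.7759e-12 * T) * ds * P +
    (-4.6206e-13 + 1.8676e-14 * T - 2.1687e-16 * T^2) * P^2
}

# Potential temperature by the standard 4th-order Runge-Kutta (Gill) scheme.
potential_temperature <- function(S, T, P, P_ref = 0) {
  del_P <- P_ref - P
  del_th <- del_P * adiabatic_gradient(S, T, P)
  th <- T + 0.5 * del_th
  q <- del_th

  del_th <- del_P * adiabatic_gradient(S, th, P + 0.5 * del_P)
  th <- th + (1 - 1 / sqrt(2)) * (del_th - q)
  q <- (2 - sqrt(2)) * del_th + (-2 + 3 / sqrt(2)) * q

  del_th <- del_P * adiabatic_gradient(S, th, P + 0.5 * del_P)
  th <- th + (1 + 1 / sqrt(2)) * (del_th - q)
  q <- (2 + sqrt(2)) * del_th + (-2 - 3 / sqrt(2)) * q

  del_th <- del_P * adiabatic_gradient(S, th, P + del_P)
  th + (del_th - 2 * q) / 6
}

#' CTD profile container
#'
#' @param depth Depths, meters; strictly increasing, positive.
#' @param temperature Temperatures, degrees C.
#' @param salinity Practical salinities.
#' @param pressure Optional pressures, decibars; defaults to depth.
#' @param sigma_theta Optional precomputed potential density anomalies; when
#'   omitted they are derived with [potential_density()].
#' @return data.frame of class `ctd_profile`.
#' @export
ctd_profile <- function(depth, temperature, salinity, pressure = NULL,
                        sigma_theta = NULL) {
  if (length(depth) < 2) {
    stop("ctd_profile: at least two records required", call. = FALSE)
  }
  if (any(diff(depth) <= 0) || any(depth <= 0)) {
    stop("ctd_profile: depths must be positive and strictly increasing",
         call. = FALSE)
  }
  if (anyNA(temperature) || anyNA(salinity)) {
    stop("ctd_profile: missing temperature or salinity", call. = FALSE)
  }
  if (is.null(pressure)) pressure <- depth
  if (is.null(sigma_theta)) {
    sigma_theta <- potential_density(temperature, salinity, pressure)
  }
  structure(data.frame(depth = depth, temperature = temperature,
                       salinity = salinity, pressure = pressure,
                       sigma_theta = sigma_theta),
            class = c("ctd_profile", "data.frame"))
}

#' Mixed-layer depth from a CTD profile
#'
#' The shallowest depth at which the potential density anomaly exceeds the
#' surface value (shallowest record) by more than `threshold`. With
#' `mode = "interpolate"` (default) the crossing depth is linearly
#' interpolated between the bracketing records; `mode = "bin"` returns the
#' first record exceeding the threshold. If the threshold is never exceeded
#' the deepest depth is returned, flagged via the
#' `extends_beyond_profile` attribute.
#'
#' @param profile A [ctd_profile()].
#' @param threshold Density criterion, kg/m^3.
#' @param mode `"interpolate"` or `"bin"`.
#' @return Mixed-layer depth in meters, with logical attribute
#'   `extends_beyond_profile`.
#' @export
mixed_layer_depth <- function(profile, threshold = 0.35,
                              mode = c("interpolate", "bin")) {
  stopifnot(inherits(profile, "ctd_profile"))
  mode <- match.arg(mode)
  delta <- profile$sigma_theta - profile$sigma_theta[1]
  k <- which(delta > threshold)[1]
  if (is.na(k)) {
    mld <- profile$depth[nrow(profile)]
    attr(mld, "extends_beyond_profile") <- TRUE
    return(mld)
  }
  mld <- if (mode == "bin" || k == 1) {
    profile$depth[k]
  } else {
    profile$depth[k - 1] + (threshold - delta[k - 1]) *
      (profile$depth[k] - profile$depth[k - 1]) / (delta[k] - delta[k - 1])
  }
  attr(mld, "extends_beyond_profile") <- FALSE
  mld
}

#' Mixed-layer mean temperature and salinity
#'
#' Depth-weighted (trapezoidal) means of temperature and salinity between the
#' shallowest record and the mixed-layer depth; values at the mixed-layer
#' depth are linearly interpolated. Exact for profiles linear in depth, and
#' insensitive to adding interior points on such profiles.
#'
#' @param profile A [ctd_profile()].
#' @param mld Mixed-layer depth, meters (within the profile's depth range).
#' @return Named vector `c(temperature, salinity)`.
#' @export
mixed_layer_average <- function(profile, mld) {
  stopifnot(inherits(profile, "ctd_profile"))
  z <- profile$depth
  if (mld < z[1]) {
    stop("mixed_layer_average: mld is above the shallowest record",
         call. = FALSE)
  }
  if (mld > z[length(z)]) {
    stop("mixed_layer_average: mld is below the profile", call. = FALSE)
  }
  trap <- function(v) {
    zz <- z[z <= mld]
    vv <- v[z <= mld]
    if (max(zz) < mld) {
      vv <- c(vv, stats::approx(z, v, xout = mld)$y)
      zz <- c(zz, mld)
    }
    if (length(zz) == 1) return(vv[1])
    sum(diff(zz) * (head_(vv) + tail_(vv)) / 2) / (max(zz) - zz[1])
  }
  c(temperature = trap(profile$temperature),
    salinity = trap(profile$salinity))
}

head_ <- function(v) v[-length(v)]
tail_ <- function(v) v[-1]
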
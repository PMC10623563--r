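#' Noise model for synthetic data generation
#'
#' Describes the stochastic perturbation applied by the generators:
#' \code{"gaussian-relative"} adds \eqn{N(0, (scale \cdot |y|)^2)},
#' \code{"gaussian-absolute"} adds \eqn{N(0, scale^2)}, and
#' \code{"poisson-like"} adds \eqn{N(0, scale^2 |y|)} (variance
#' proportional to the signal). Identical seeds produce identical output;
#' \code{scale = 0} returns the model exactly.
#'
#' @param kind noise family.
#' @param scale nonnegative noise scale (relative, absolute, or per-count).
#' @param seed integer seed; required when \code{scale > 0}.
#' @return object of class \code{"noise_model"}.
#' @export
noise_model <- function(kind = c("gaussian-relative", "gaussian-absolute",
                                 "poisson-like"),
                        scale = 0, seed = NULL) {
  kind <- match.arg(kind)
  if (!is.finite(scale) || scale < 0) stop("'scale' must be >= 0")
  if (scale > 0 && is.null(seed))
    stop("a seed is required for nonzero noise (reproducibility)")
  structure(list(kind = kind, scale = scale, seed = seed),
            class = "noise_model")
}

# returns list(y = noisy values, sigma = per-point standard deviation or NULL)
apply_noise <- function(y, noise) {
  stopifnot(inherits(noise, "noise_model"))
  if (noise$scale == 0) return(list(y = y, sigma = NULL))
  sigma <- switch(noise$kind,
                  "gaussian-relative" = noise$scale * abs(y),
                  "gaussian-absolute" = rep(noise$scale, length(y)),
                  "poisson-like" = noise$scale * sqrt(abs(y)))
  sigma <- pmax(sigma, .Machine$double.eps)
  set.seed(noise$seed)
  list(y = y + stats::rnorm(length(y), 0, sigma), sigma = sigma)
}

#' Canonical vesicle fixtures
#'
#' Reference parameterizations used throughout the examples and tests:
#' an unloaded-vesicle-like profile (\code{lip0_profile}: R = 46 nm,
#' d = 3.9 nm) and a protein-loaded-vesicle-like profile
#' (\code{lipcas_profile}: R = 52 nm, d = 3.9 nm, with a heavier external
#' head layer), plus the matching hollow-sphere models at the radii obtained
#' from multi-angle light scattering (41.5 and 46.5 nm, shell thickness
#' 4 nm).
#'
#' @return a [gaussian_shell_profile()] or [hollow_sphere_model()].
#' @export
lip0_profile <- function() {
  gaussian_shell_profile(R = 46, rho = c(1, -0.9, -1.1),
                         eps = c(0, -1.95, 1.95),
                         sigma = c(0.9, 0.45, 0.55))
}

#' @rdname lip0_profile
#' @export
lipcas_profile <- function() {
  gaussian_shell_profile(R = 52, rho = c(1, -0.85, -1.25),
                         eps = c(0, -1.95, 1.95),
                         sigma = c(0.9, 0.45, 0.65))
}

#' @rdname lip0_profile
#' @export
lip0_mals_model <- function() hollow_sphere_model(R_mid = 41.5, t = 4)

#' @rdname lip0_profile
#' @export
lipcas_mals_model <- function() hollow_sphere_model(R_mid = 46.5, t = 4)

#' Generate a synthetic SAXS curve
#'
#' Evaluates the Gaussian-shell intensity on a q grid and applies the noise
#' model; the uncertainty column is populated from the noise model's
#' per-point standard deviation (absent at zero noise).
#'
#' @param profile a [gaussian_shell_profile()].
#' @param q q grid, nm^-1 (default 400 points over 0.1--5).
#' @param scale intensity scale.
#' @param noise a [noise_model()].
#' @return a SAXS [scattering_curve()].
#' @export
gen_saxs <- function(profile, q = seq(0.1, 5, length.out = 400), scale = 1,
                     noise = noise_model()) {
  I <- saxs_intensity(profile, q, scale = scale)
  ny <- apply_noise(I, noise)
  scattering_curve(q, ny$y, sigma = ny$sigma, technique = "SAXS")
}

#' Generate a synthetic MALS Rayleigh-ratio curve
#'
#' @param model a [hollow_sphere_model()].
#' @param q q grid, um^-1 (default 40 log-spaced points over 5--25).
#' @param amplitude Rayleigh-ratio amplitude, cm^-1.
#' @param noise a [noise_model()].
#' @return a [rayleigh_curve()].
#' @export
gen_mals <- function(model, q = exp(seq(log(5), log(25), length.out = 40)),
                     amplitude = 1e-4, noise = noise_model()) {
  y <- amplitude * hollow_sphere_pq(model, q * 1e-3)
  ny <- apply_noise(y, noise)
  rayleigh_curve(q, pmax(ny$y, 0), sigma = ny$sigma, q_unit = "um^-1")
}

#' Generate a synthetic DLS autocorrelation trace
#'
#' Builds the field correlation of a polydisperse vesicle population,
#' \eqn{g_1(\tau) = \sum_i w_i e^{-\Gamma(R_i)\tau}} with the decay rates
#' from Stokes--Einstein at the trace's instrument constants, and returns
#' \eqn{g_2 - 1 = \beta g_1^2} plus noise.
#'
#' @param dist an intensity-basis [size_distribution()].
#' @param beta coherence factor (default 0.7).
#' @param tau lag grid, s (default 120 log-spaced points, 1 us -- 1 s).
#' @param q,wavelength,temperature,eta instrument constants, as in
#'   [correlation_trace()].
#' @param noise a [noise_model()] (applied additively to \eqn{g_2-1}).
#' @return a [correlation_trace()].
#' @export
gen_dls <- function(dist, beta = 0.7,
                    tau = exp(seq(log(1e-6), log(1), length.out = 120)),
                    q = 22.3, wavelength = 532, temperature = 293.15,
                    eta = 1.002e-3, noise = noise_model()) {
  stopifnot(inherits(dist, "size_distribution"))
  if (!identical(dist$basis, "intensity"))
    stop("gen_dls() expects an intensity-basis distribution")
  gammas <- radius_to_gamma(dist$radii, q = q, temperature = temperature,
                            eta = eta)
  g1 <- as.numeric(exp(-outer(tau, gammas)) %*% dist$weights)
  g2m1 <- beta * g1^2
  ny <- apply_noise(g2m1, noise)
  correlation_trace(tau, ny$y, q = q, wavelength = wavelength,
                    temperature = temperature, eta = eta)
}

#' Generate a synthetic fluorophore calibration table
#'
#' @param slope,intercept line parameters (intensity per mol/L, a.u.).
#' @param concentrations mol/L grid.
#' @param noise a [noise_model()].
#' @return data frame with columns \code{concentration}, \code{intensity}.
#' @export
gen_calibration <- function(slope, intercept = 0,
                            concentrations = seq(1e-9, 1e-7,
                                                 length.out = 8),
                            noise = noise_model()) {
  y <- intercept + slope * concentrations
  data.frame(concentration = concentrations,
             intensity = apply_noise(y, noise)$y)
}

#' Generate a synthetic Laurdan emission spectrum with a target GP
#'
#' Builds a two-band spectrum (Gaussian emission bands centered at 435 and
#' 500 nm) whose intensities at exactly 435 and 500 nm reproduce the
#' requested generalized polarization; the band amplitudes are obtained by
#' solving the 2x2 linear system that accounts for the overlap of each band
#' at the other wavelength, so the round trip through [laurdan_gp()] is
#' exact at zero noise.
#'
#' @param gp target GP in (-1, 1).
#' @param wavelengths nm grid (must cover 435 and 500 nm).
#' @param width emission band width, nm (default 25).
#' @param noise a [noise_model()].
#' @return data frame with columns \code{wavelength}, \code{intensity}.
#' @export
gen_laurdan <- function(gp, wavelengths = seq(400, 550, by = 1), width = 25,
                        noise = noise_model()) {
  if (!is.finite(gp) || gp <= -1 || gp >= 1) stop("'gp' must be in (-1, 1)")
  I435 <- (1 + gp) / 2
  I500 <- (1 - gp) / 2
  k <- exp(-(500 - 435)^2 / (2 * width^2))  # cross-band leakage
  M <- matrix(c(1, k, k, 1), 2, 2)
  a <- solve(M, c(I435, I500))
  y <- a[1L] * exp(-(wavelengths - 435)^2 / (2 * width^2)) +
    a[2L] * exp(-(wavelengths - 500)^2 / (2 * width^2))
  y <- pmax(y, 0)
  data.frame(wavelength = wavelengths,
             intensity = pmax(apply_noise(y, noise)$y, 0))
}

#' Generate a synthetic CMC titration
#'
#' Continuous two-segment piecewise-linear probe-fluorescence curve with a
#' slope change at the critical micelle concentration.
#'
#' @param cmc breakpoint, mg/mL (default 0.215).
#' @param slope_below,slope_above segment slopes (a.u. per mg/mL).
#' @param intercept intensity at zero concentration.
#' @param concentrations mg/mL grid spanning the break.
#' @param noise a [noise_model()].
#' @return data frame with columns \code{concentration}, \code{intensity}.
#' @export
gen_cmc <- function(cmc = 0.215, slope_below = 0.6, slope_above = 9,
                    intercept = 1,
                    concentrations = seq(0.02, 0.42, length.out = 14),
                    noise = noise_model()) {
  if (cmc <= min(concentrations) || cmc >= max(concentrations))
    stop("'concentrations' must span the breakpoint")
  y <- intercept + slope_below * pmin(concentrations, cmc) +
    slope_above * pmax(concentrations - cmc, 0)
  data.frame(concentration = concentrations,
             intensity = apply_noise(y, noise)$y)
}

#' Log-normal vesicle size distribution
#'
#' Convenience generator of an intensity-basis size distribution with
#' log-normal weights, emulating an extruded vesicle population.
#'
#' @param median_R median radius, nm (default 45, near the 50 nm extrusion
#'   pore scale).
#' @param sigma_log log-scale width (default 0.15).
#' @param radii radius grid, nm.
#' @return an intensity-basis [size_distribution()].
#' @export
lognormal_sizes <- function(median_R = 45, sigma_log = 0.15,
                            radii = exp(seq(log(5), log(500),
                                            length.out = 100))) {
  w <- stats::dlnorm(radii, meanlog = log(median_R), sdlog = sigma_log)
  size_distribution(radii, w, basis = "intensity")
}
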
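#' DLS intensity-autocorrelation trace
#'
#' Container for a dynamic light-scattering measurement: lag times and the
#' baseline-subtracted intensity autocorrelation \eqn{g_2(\tau) - 1},
#' together with the instrument constants needed to convert decay rates to
#' hydrodynamic radii. Defaults match a 532 nm solid-state laser measured at
#' \eqn{q = 22.3} um^-1 in water at 20 degC.
#'
#' @param tau lag times, s, strictly increasing and positive.
#' @param g2m1 measured \eqn{g_2(\tau) - 1}, dimensionless.
#' @param q scattering vector, um^-1 (default 22.3).
#' @param wavelength laser wavelength, nm (default 532).
#' @param temperature solvent temperature, K (default 293.15).
#' @param eta solvent viscosity, Pa s (default 1.002e-3, water at 20 degC).
#' @return object of class \code{"correlation_trace"}.
#' @export
correlation_trace <- function(tau, g2m1, q = 22.3, wavelength = 532,
                              temperature = 293.15, eta = 1.002e-3) {
  tau <- as.numeric(tau); g2m1 <- as.numeric(g2m1)
  if (length(tau) != length(g2m1)) stop("'tau'/'g2m1' length mismatch")
  if (any(tau <= 0) || any(diff(tau) <= 0))
    stop("'tau' must be positive and strictly increasing")
  stopifnot(q > 0, wavelength > 0, temperature > 0, eta > 0)
  structure(list(tau = tau, g2m1 = g2m1, q = q, wavelength = wavelength,
                 temperature = temperature, eta = eta),
            class = "correlation_trace")
}

#' @export
print.correlation_trace <- function(x, ...) {
  cat(sprintf(paste0("DLS trace: %d lags in [%.3g, %.3g] s, q = %.3g um^-1, ",
                     "T = %.2f K\n"),
              length(x$tau), min(x$tau), max(x$tau), x$q, x$temperature))
  invisible(x)
}

#' Field autocorrelation from the Siegert relation
#'
#' Inverts \eqn{g_2(\tau) - 1 = \beta |g_1(\tau)|^2} to obtain the field
#' autocorrelation \eqn{g_1(\tau) = \sqrt{(g_2 - 1)/\beta}}. When
#' \code{beta} is not supplied, the coherence factor is estimated from the
#' short-lag plateau (mean of the first few points). Small negative values
#' of \eqn{(g_2-1)/\beta} from baseline noise are clipped to zero; values
#' more negative than the noise tolerance trigger a warning.
#'
#' @param trace a [correlation_trace()].
#' @param beta coherence (intercept) factor in (0, 1]; \code{NULL} to
#'   estimate from the plateau.
#' @param n_plateau number of leading lags used for the plateau estimate.
#' @param noise_tol negative excursions beyond \code{-noise_tol} warn
#'   (default 0.05 in \eqn{g_1^2} units).
#' @return list with \code{g1} (field correlation), \code{tau} and the
#'   \code{beta} used.
#' @export
siegert_to_g1 <- function(trace, beta = NULL, n_plateau = 3,
                          noise_tol = 0.05) {
  stopifnot(inherits(trace, "correlation_trace"))
  if (is.null(beta))
    beta <- mean(trace$g2m1[seq_len(min(n_plateau, length(trace$g2m1)))])
  if (!is.finite(beta) || beta <= 0 || beta > 1)
    stop("'beta' must lie in (0, 1]")
  ratio <- trace$g2m1 / beta
  if (any(ratio < -noise_tol))
    warning("g2-1 values negative beyond the noise tolerance; clipped")
  list(g1 = sqrt(pmax(ratio, 0)), tau = trace$tau, beta = beta)
}

#' Regularized inversion of a multi-exponential decay
#'
#' Recovers a decay-rate distribution from a field autocorrelation by
#' smoothing-constrained (CONTIN-style) regularization: solves
#' \deqn{\min_{w \ge 0} \; \|K w - g_1\|^2 + \lambda \|L_2 w\|^2,}
#' where \eqn{K_{ij} = \exp(-\Gamma_j \tau_i)} and \eqn{L_2} is the
#' second-difference operator penalizing curvature of the recovered
#' spectrum. The nonnegative solution is obtained by Lawson--Hanson NNLS on
#' the stacked system. The smoothing weight is chosen by the L-curve corner
#' (point of maximum Menger curvature of the log residual-norm versus log
#' seminorm curve) unless given explicitly.
#'
#' @param g1 field autocorrelation values.
#' @param tau lag times, s.
#' @param gamma_grid decay-rate grid, s^-1; default 100 log-spaced points
#'   spanning one decade beyond the reciprocal lag range on each side.
#' @param lambda_reg smoothing weight: a nonnegative number, or
#'   \code{"lcurve"} (default) for automatic corner selection.
#' @param n_lambda number of candidate weights for the L-curve search.
#' @return object of class \code{"decay_spectrum"}: list with \code{gamma},
#'   normalized \code{weights} (sum 1), \code{lambda}, \code{residual_norm}
#'   and \code{all_zero} flag.
#' @export
regularized_invert <- function(g1, tau, gamma_grid = NULL,
                               lambda_reg = "lcurve", n_lambda = 24) {
  stopifnot(length(g1) == length(tau), all(tau > 0))
  if (is.null(gamma_grid))
    gamma_grid <- exp(seq(log(0.1 / max(tau)), log(10 / min(tau)),
                          length.out = 100))
  if (min(gamma_grid) > 1 / max(tau) || max(gamma_grid) < 1 / min(tau))
    warning("'gamma_grid' does not span the full reciprocal lag range; ",
            "decays outside the grid cannot be represented")
  K <- exp(-outer(tau, gamma_grid))
  m <- length(gamma_grid)
  L2 <- diag(m)[-c(1L, 2L), , drop = FALSE] * 0
  for (i in seq_len(m - 2L)) {
    L2[i, i] <- 1; L2[i, i + 1L] <- -2; L2[i, i + 2L] <- 1
  }

  solve_one <- function(lambda) {
    A <- if (lambda > 0) rbind(K, sqrt(lambda) * L2) else K
    b <- c(g1, rep(0, if (lambda > 0) nrow(L2) else 0L))
    sol <- pracma::lsqnonneg(A, b)
    w <- sol$x
    list(w = w, rnorm = sqrt(sum((K %*% w - g1)^2)),
         snorm = sqrt(sum((L2 %*% w)^2)))
  }

  if (identical(lambda_reg, "lcurve")) {
    lambdas <- 10^seq(-8, 2, length.out = n_lambda)
    sols <- lapply(lambdas, solve_one)
    lr <- log10(pmax(vapply(sols, `[[`, 0, "rnorm"), 1e-15))
    ls <- log10(pmax(vapply(sols, `[[`, 0, "snorm"), 1e-15))
    # discrete Menger curvature along the (log rho, log eta) curve
    kappa <- rep(-Inf, n_lambda)
    for (i in 2:(n_lambda - 1L)) {
      a <- c(lr[i - 1L], ls[i - 1L]); b <- c(lr[i], ls[i])
      cc <- c(lr[i + 1L], ls[i + 1L])
      num <- 2 * abs((b[1] - a[1]) * (cc[2] - a[2]) -
                       (b[2] - a[2]) * (cc[1] - a[1]))
      den <- sqrt(sum((b - a)^2)) * sqrt(sum((cc - b)^2)) *
        sqrt(sum((cc - a)^2))
      kappa[i] <- if (den > 0) num / den else -Inf
    }
    best <- which.max(kappa)
    lambda <- lambdas[best]
    sol <- sols[[best]]
  } else {
    lambda <- as.numeric(lambda_reg)
    if (!is.finite(lambda) || lambda < 0)
      stop("'lambda_reg' must be nonnegative or \"lcurve\"")
    if (lambda == 0 && kappa_est(K) > 1e10)
      warning("kernel is severely ill-conditioned and lambda_reg = 0")
    sol <- solve_one(lambda)
  }
  w <- sol$w
  all_zero <- sum(w) <= 0
  if (all_zero) warning("inversion returned an all-zero spectrum")
  else w <- w / sum(w)
  structure(list(gamma = gamma_grid, weights = w, lambda = lambda,
                 residual_norm = sol$rnorm, all_zero = all_zero),
            class = "decay_spectrum")
}

kappa_est <- function(K) {
  s <- svd(K, nu = 0, nv = 0)$d
  s[1] / max(s[length(s)], .Machine$double.eps)
}

k_boltzmann <- 1.380649e-23  # J/K

#' Convert DLS decay rates to hydrodynamic radii (and back)
#'
#' Stokes--Einstein conversion: the decay rate of a diffusing species is
#' \eqn{\Gamma = D q^2} with \eqn{D = k_B T / (6 \pi \eta R_h)}, so
#' \deqn{R_h = \frac{k_B T q^2}{6 \pi \eta \Gamma}.}
#'
#' @param gamma decay rate(s), s^-1, positive.
#' @param trace a [correlation_trace()] (supplies q, T, eta), or \code{NULL}
#'   to use the explicit arguments.
#' @param q scattering vector, um^-1.
#' @param temperature K.
#' @param eta Pa s.
#' @return hydrodynamic radius, nm.
#' @export
gamma_to_radius <- function(gamma, trace = NULL, q = 22.3,
                            temperature = 293.15, eta = 1.002e-3) {
  if (!is.null(trace)) {
    stopifnot(inherits(trace, "correlation_trace"))
    q <- trace$q; temperature <- trace$temperature; eta <- trace$eta
  }
  if (any(gamma <= 0)) stop("'gamma' must be positive")
  q_m <- q * 1e6                       # um^-1 -> m^-1
  D <- gamma / q_m^2                   # m^2/s
  Rh_m <- k_boltzmann * temperature / (6 * pi * eta * D)
  Rh_m * 1e9
}

#' @rdname gamma_to_radius
#' @param radius hydrodynamic radius, nm, positive.
#' @export
radius_to_gamma <- function(radius, trace = NULL, q = 22.3,
                            temperature = 293.15, eta = 1.002e-3) {
  if (!is.null(trace)) {
    stopifnot(inherits(trace, "correlation_trace"))
    q <- trace$q; temperature <- trace$temperature; eta <- trace$eta
  }
  if (any(radius <= 0)) stop("'radius' must be positive")
  q_m <- q * 1e6
  D <- k_boltzmann * temperature / (6 * pi * eta * radius * 1e-9)
  D * q_m^2
}

#' Size-distribution container
#'
#' A hydrodynamic-size distribution on a radius grid, with an explicit
#' weighting basis. Weights are normalized to unit sum on construction.
#'
#' @param radii radius grid, nm, strictly increasing.
#' @param weights nonnegative weights.
#' @param basis \code{"intensity"}, \code{"number"} or \code{"mass"}.
#' @return object of class \code{"size_distribution"}.
#' @export
size_distribution <- function(radii, weights,
                              basis = c("intensity", "number", "mass")) {
  basis <- match.arg(basis)
  stopifnot(length(radii) == length(weights))
  if (any(radii <= 0) || any(diff(radii) <= 0))
    stop("'radii' must be positive and strictly increasing")
  if (any(weights < 0)) stop("'weights' must be nonnegative")
  s <- sum(weights)
  if (s <= 0) stop("'weights' must not be all zero")
  structure(list(radii = as.numeric(radii), weights = as.numeric(weights) / s,
                 basis = basis),
            class = "size_distribution")
}

#' @export
print.size_distribution <- function(x, ...) {
  med <- distribution_median(x)
  cat(sprintf("%s-weighted size distribution: %d bins, median R = %.2f nm\n",
              x$basis, length(x$radii), med))
  invisible(x)
}

#' Weighted median radius of a size distribution
#' @param dist a [size_distribution()].
#' @return median radius, nm.
#' @export
distribution_median <- function(dist) {
  stopifnot(inherits(dist, "size_distribution"))
  cw <- cumsum(dist$weights)
  dist$radii[which(cw >= 0.5)[1L]]
}

#' Reweight a size distribution between intensity, number and mass bases
#'
#' DLS inversions natively yield intensity weights: each bin contributes in
#' proportion to the light it scatters, \eqn{w_I(R) \propto n(R)\, m(R)^2\,
#' P(q, R)}, where \eqn{m(R) \propto R^2} is the mass of a thin-shell
#' vesicle of fixed bilayer thickness and \eqn{P} its form factor at the
#' measurement q. Mass weights follow as
#' \deqn{w_m(R) \propto \frac{w_I(R)}{m(R)\, P(q, R)},}
#' and number weights as \eqn{w_I/(m^2 P)}. In the \eqn{q \to 0} limit
#' (\eqn{P \to 1}) intensity-to-mass reduces to division by \eqn{R^2}.
#' Form factors are evaluated with the hollow-sphere model at shell
#' thickness \code{t}; bins where \eqn{P(q,R)} vanishes are excluded with a
#' warning.
#'
#' @param dist a [size_distribution()].
#' @param target_basis requested basis.
#' @param q measurement momentum transfer, nm^-1 (DLS at 22.3 um^-1 is
#'   0.0223 nm^-1).
#' @param t shell thickness for the form factor, nm (default 4).
#' @param mass_exponent exponent of the vesicle mass--radius scaling
#'   (default 2, thin shell; 3 would be a filled particle).
#' @return reweighted, renormalized [size_distribution()].
#' @export
reweight <- function(dist, target_basis = c("mass", "number", "intensity"),
                     q = 0.0223, t = 4, mass_exponent = 2) {
  stopifnot(inherits(dist, "size_distribution"))
  target_basis <- match.arg(target_basis)
  if (identical(dist$basis, target_basis)) return(dist)
  R <- dist$radii
  P <- vapply(R, function(r)
    hollow_sphere_pq(hollow_sphere_model(max(r, t / 2 + 1e-9), t), q),
    numeric(1))
  mass <- R^mass_exponent
  # w_I = n m^2 P ; w_m = n m ; w_N = n
  m_pow <- c(intensity = 2, mass = 1, number = 0)  # powers of m per basis
  p_pow <- c(intensity = 1, mass = 0, number = 0)  # powers of P per basis
  dm <- m_pow[[target_basis]] - m_pow[[dist$basis]]
  dp <- p_pow[[target_basis]] - p_pow[[dist$basis]]
  fac <- mass^dm * P^dp
  w <- dist$weights * fac
  drop <- dp < 0 & P < 1e-12 & dist$weights > 0
  if (any(drop)) {
    warning(sum(drop), " bins with vanishing form factor excluded")
    w[drop] <- 0
  }
  w[!is.finite(w)] <- 0
  size_distribution(R, w, basis = target_basis)
}

#' Full DLS size-distribution inversion
#'
#' Convenience chain: Siegert conversion, regularized inversion on a
#' decay-rate grid mapped from a radius grid via Stokes--Einstein, returning
#' an intensity-weighted size distribution (optionally reweighted).
#'
#' @param trace a [correlation_trace()].
#' @param beta coherence factor; \code{NULL} to estimate from the plateau.
#' @param radii radius grid, nm; default 100 log-spaced points over
#'   5--500 nm (an order of magnitude either side of the 50 nm extrusion
#'   scale).
#' @param lambda_reg passed to [regularized_invert()].
#' @param basis basis of the returned distribution (reweighting applied at
#'   the trace's measurement q when not \code{"intensity"}).
#' @param trim_tail drop lags after the correlation has decayed into the
#'   noise floor (default \code{TRUE}). The floor is 3 standard deviations
#'   of \eqn{g_2-1} over the last decade of lags; the square-root Siegert
#'   transform of pure baseline noise is biased upward and would otherwise
#'   be fitted as a spurious slow mode.
#' @return a [size_distribution()].
#' @export
invert_dls <- function(trace, beta = NULL,
                       radii = exp(seq(log(5), log(500), length.out = 100)),
                       lambda_reg = "lcurve", basis = "intensity",
                       trim_tail = TRUE) {
  if (trim_tail) {
    n <- length(trace$tau)
    tail_idx <- trace$tau > max(trace$tau) / 10
    floor_v <- if (sum(tail_idx) >= 5)
      3 * stats::sd(trace$g2m1[tail_idx]) else 0
    below <- which(trace$g2m1 < floor_v)
    cut <- if (length(below)) below[1L] else n
    if (cut > 5L && cut < n)
      trace <- correlation_trace(trace$tau[1:cut], trace$g2m1[1:cut],
                                 q = trace$q, wavelength = trace$wavelength,
                                 temperature = trace$temperature,
                                 eta = trace$eta)
  }
  sg <- siegert_to_g1(trace, beta)
  gammas <- radius_to_gamma(rev(radii), trace)  # large R = slow decay
  spec <- withCallingHandlers(
    regularized_invert(sg$g1, sg$tau, gamma_grid = gammas,
                       lambda_reg = lambda_reg),
    warning = function(w) {
      if (grepl("reciprocal lag range", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  dist <- size_distribution(radii, rev(spec$weights), basis = "intensity")
  if (!identical(basis, "intensity"))
    dist <- reweight(dist, basis, q = trace$q * 1e-3)
  dist
}
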
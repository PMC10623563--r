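#' Convert MALS counts to Rayleigh ratios
#'
#' Static light-scattering intensities are put on the absolute Rayleigh-ratio
#' scale by subtracting the solvent background and normalizing against the
#' scattering of toluene,
#' \deqn{R_\theta(q) = \frac{I_{sample}(q) - I_{solvent}(q)}{I_{toluene}}
#'   \, R_{tol},}
#' with the toluene reference \eqn{R_{tol} = 28 \times 10^{-6}} cm^-1.
#' Negative background-corrected intensities are clipped to zero with a
#' warning.
#'
#' @param q momentum transfer grid shared by all three intensity vectors.
#' @param I_sample,I_solvent detector counts on the common grid.
#' @param I_toluene toluene reference counts (scalar or per-q vector),
#'   strictly positive.
#' @param R_tol toluene Rayleigh ratio, cm^-1 (default \code{28e-6}).
#' @param q_unit unit of \code{q} (default \code{"um^-1"}, the MALS
#'   convention; converted to nm^-1 internally).
#' @return object of class \code{"rayleigh_curve"}: data frame with columns
#'   \code{q} (nm^-1) and \code{R_theta} (cm^-1).
#' @export
to_rayleigh <- function(q, I_sample, I_solvent, I_toluene, R_tol = 28e-6,
                        q_unit = c("um^-1", "nm^-1")) {
  q_unit <- match.arg(q_unit)
  if (any(!is.finite(I_toluene)) || any(I_toluene <= 0))
    stop("'I_toluene' must be positive")
  if (length(I_sample) != length(q) || length(I_solvent) != length(q))
    stop("intensity arrays must be aligned on the same q grid")
  excess <- I_sample - I_solvent
  if (any(excess < 0)) {
    warning("negative background-corrected intensities clipped to zero")
    excess <- pmax(excess, 0)
  }
  rayleigh_curve(q = q, R_theta = excess / I_toluene * R_tol, q_unit = q_unit)
}

#' Rayleigh-ratio curve container
#'
#' @param q momentum transfer, strictly increasing.
#' @param R_theta Rayleigh ratio, cm^-1, nonnegative.
#' @param sigma optional uncertainties.
#' @param q_unit unit of the supplied \code{q}.
#' @return object of class \code{"rayleigh_curve"} with \code{q} in nm^-1.
#' @export
rayleigh_curve <- function(q, R_theta, sigma = NULL,
                           q_unit = c("um^-1", "nm^-1")) {
  q_unit <- match.arg(q_unit)
  q <- as.numeric(q)
  if (q_unit == "um^-1") q <- q * 1e-3
  if (any(diff(q) <= 0)) stop("'q' must be strictly increasing")
  if (any(!is.finite(R_theta)) || any(R_theta < 0))
    stop("'R_theta' must be finite and nonnegative")
  df <- data.frame(q = q, R_theta = as.numeric(R_theta))
  if (!is.null(sigma)) {
    if (any(sigma <= 0)) stop("'sigma' must be positive")
    df$sigma <- as.numeric(sigma)
  }
  class(df) <- c("rayleigh_curve", "data.frame")
  df
}

#' Fit the hollow-sphere model to a MALS Rayleigh curve
#'
#' Weighted least squares of \eqn{A \cdot P(q; R_{mid}, t)} against a
#' Rayleigh-ratio curve, with the shell thickness \code{t} fixed (default
#' 4 nm, the SAXS-derived bilayer thickness) and a single multiplicative
#' amplitude as nuisance parameter. No background term is floated. Also
#' reports the radius of gyration of the fitted shell.
#'
#' @param curve a [rayleigh_curve()] (or MALS [scattering_curve()]).
#' @param t_fixed shell thickness, nm, held fixed during the fit.
#' @param init_R starting mid-shell radius, nm (default 30).
#' @param qmin,qmax fitting window in um^-1 (default 5--25, the instrument
#'   range).
#' @return object of class \code{"mals_fit"}: \code{params} (\code{R_mid},
#'   \code{amplitude}, \code{Rg}), \code{se}, \code{chi2_reduced},
#'   \code{converged}, \code{identifiable}, and the fitted model.
#' @export
#' @examples
#' crv <- gen_mals(hollow_sphere_model(41.5, 4), amplitude = 1e-4)
#' fit_mals(crv, init_R = 30)$params$R_mid
fit_mals <- function(curve, t_fixed = 4, init_R = 30, qmin = 5, qmax = 25) {
  if (inherits(curve, "scattering_curve")) {
    if (!identical(attr(curve, "technique"), "MALS"))
      stop("expected a MALS curve")
    curve <- rayleigh_curve(curve$q, pmax(curve$I, 0), curve$sigma,
                            q_unit = "nm^-1")
  }
  stopifnot(inherits(curve, "rayleigh_curve"))
  keep <- curve$q >= qmin * 1e-3 & curve$q <= qmax * 1e-3
  q <- curve$q[keep]; y <- curve$R_theta[keep]
  if (length(q) < 4L) stop("too few points in the MALS fitting window")
  w <- if (!is.null(curve$sigma)) 1 / curve$sigma[keep] else rep(1, length(q))

  rel_range <- diff(range(y)) / max(mean(y), .Machine$double.eps)
  identifiable <- rel_range > 1e-6
  if (!identifiable)
    warning("flat Rayleigh curve: radius not identifiable")

  resid_fn <- function(p) {
    m <- hollow_sphere_model(p[["R_mid"]], t = t_fixed)
    w * (exp(p[["logA"]]) * hollow_sphere_pq(m, q) - y)
  }
  A0 <- {
    P0 <- hollow_sphere_pq(hollow_sphere_model(init_R, t_fixed), q)
    a <- sum(w^2 * P0 * y) / sum(w^2 * P0^2)
    if (!is.finite(a) || a <= 0) a <- max(y)
    a
  }
  fit <- minpack.lm::nls.lm(
    par = c(R_mid = init_R, logA = log(A0)),
    lower = c(R_mid = t_fixed / 2 + 0.1, logA = -Inf),
    upper = c(R_mid = 1000, logA = Inf),
    fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                         ptol = 1e-14))
  pb <- fit$par
  se <- c(R_mid = NA_real_, logA = NA_real_)
  sm <- tryCatch(summary(fit), error = function(e) NULL)
  if (!is.null(sm)) se[rownames(sm$coefficients)] <-
      sm$coefficients[, "Std. Error"]
  model <- hollow_sphere_model(pb[["R_mid"]], t = t_fixed)
  out <- list(params = list(R_mid = pb[["R_mid"]],
                            amplitude = exp(pb[["logA"]]),
                            t = t_fixed,
                            Rg = shell_radius_of_gyration(model)),
              se = list(R_mid = se[["R_mid"]]),
              chi2_reduced = fit$deviance / max(length(q) - 2L, 1L),
              converged = fit$info %in% 1:4,
              identifiable = identifiable,
              model = model,
              q = q, R_theta = y,
              fit = exp(pb[["logA"]]) * hollow_sphere_pq(model, q))
  class(out) <- "mals_fit"
  out
}

#' @export
print.mals_fit <- function(x, ...) {
  cat("Hollow-sphere MALS fit\n")
  cat(sprintf("  R_mid = %.3f +/- %.3g nm (t fixed at %.2f nm)\n",
              x$params$R_mid, x$se$R_mid, x$params$t))
  cat(sprintf("  Rg = %.3f nm | chi2_reduced = %.4g | converged: %s%s\n",
              x$params$Rg, x$chi2_reduced, x$converged,
              if (!x$identifiable) " | NOT IDENTIFIABLE" else ""))
  invisible(x)
}
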
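#' Linear fluorophore calibration curve
#'
#' Ordinary least-squares line through a dilution series of a fluorescent
#' standard (intensity versus molar concentration), as used for the
#' Alexa Fluor 647 emission calibration at 650 nm.
#'
#' @param concentrations mol/L, at least 3 distinct values.
#' @param intensities arbitrary units, same length.
#' @param lambda_em emission wavelength recorded, nm (default 650).
#' @return object of class \code{"fluor_calibration"} with \code{slope},
#'   \code{intercept}, \code{r_squared} and the data.
#' @export
fit_calibration <- function(concentrations, intensities, lambda_em = 650) {
  if (length(concentrations) < 3L)
    stop("at least 3 calibration points are required")
  if (length(unique(concentrations)) < 2L)
    stop("calibration concentrations are singular (one unique value)")
  if (length(concentrations) != length(intensities))
    stop("length mismatch")
  fit <- stats::lm(intensities ~ concentrations)
  cf <- stats::coef(fit)
  tss <- sum((intensities - mean(intensities))^2)
  r2 <- if (tss > 0) 1 - sum(stats::resid(fit)^2) / tss else 1
  structure(list(slope = unname(cf[2L]), intercept = unname(cf[1L]),
                 r_squared = r2,
                 lambda_em = lambda_em,
                 concentrations = concentrations,
                 intensities = intensities),
            class = "fluor_calibration")
}

#' @export
print.fluor_calibration <- function(x, ...) {
  cat(sprintf(paste0("Fluorophore calibration (%g nm): I = %.4g c %+.4g, ",
                     "r^2 = %.5f (%d points)\n"),
              x$lambda_em, x$slope, x$intercept, x$r_squared,
              length(x$concentrations)))
  invisible(x)
}

#' Quantify loaded protein from labeled-conjugate emission
#'
#' Back-calculates the dye concentration from the calibration line and
#' divides by the degree of labeling (DOL, dyes per protein) to obtain the
#' molar concentration of the loaded protein:
#' \eqn{c = [(I - b)/a] / DOL}.
#'
#' @param intensity emission intensity at the calibration wavelength, a.u.
#' @param calib a [fit_calibration()] result.
#' @param dol degree of labeling, dyes per protein molecule, positive.
#' @return molar protein concentration, mol/L.
#' @export
quantify_loaded <- function(intensity, calib, dol) {
  stopifnot(inherits(calib, "fluor_calibration"))
  if (!is.finite(dol) || dol <= 0) stop("'dol' must be positive")
  rng <- range(calib$intensities)
  if (intensity < rng[1L] || intensity > rng[2L])
    warning("intensity outside the calibration range; extrapolating")
  c_dye <- (intensity - calib$intercept) / calib$slope
  tol <- 1e-9 * max(abs(calib$concentrations))
  if (c_dye < -tol)
    stop("negative back-calculated dye concentration")
  max(c_dye, 0) / dol
}

#' Preparation metadata for a loading mass balance
#'
#' Records the masses, volumes and concentrations of a proteo-liposome
#' preparation from which the loading percentages are computed. The default
#' arguments are the reference preparation: a 3 mg lipid film hydrated with
#' 0.5 mL of 0.2 mg/mL protein solution, diluted to 5 mL of suspension at
#' 0.2 mg/mL lipid and 0.09e-3 mg/mL encapsulated protein, protein molar
#' mass 23.6 kDa.
#'
#' @param lipid_film_mass mg.
#' @param hydration_volume mL.
#' @param hydration_drug_conc mg/mL of the hydration solution.
#' @param final_volume mL.
#' @param final_lipid_conc mg/mL.
#' @param final_drug_conc mg/mL of encapsulated drug in the final
#'   suspension.
#' @param drug_MW molar mass of the drug/protein, kDa.
#' @return object of class \code{"prep_spec"}.
#' @export
prep_spec <- function(lipid_film_mass = 3, hydration_volume = 0.5,
                      hydration_drug_conc = 0.2, final_volume = 5,
                      final_lipid_conc = 0.2, final_drug_conc = 0.09e-3,
                      drug_MW = 23.6) {
  vals <- c(lipid_film_mass, hydration_volume, hydration_drug_conc,
            final_volume, final_lipid_conc, final_drug_conc, drug_MW)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all preparation quantities must be positive")
  if (final_drug_conc > hydration_drug_conc * hydration_volume /
        final_volume + 1e-12)
    stop("final drug content exceeds the drug offered at hydration")
  structure(list(lipid_film_mass = lipid_film_mass,
                 hydration_volume = hydration_volume,
                 hydration_drug_conc = hydration_drug_conc,
                 final_volume = final_volume,
                 final_lipid_conc = final_lipid_conc,
                 final_drug_conc = final_drug_conc,
                 drug_MW = drug_MW),
            class = "prep_spec")
}

#' Drug loading and loading efficacy percentages
#'
#' Mass-balance loading figures of merit for an encapsulation preparation:
#' \deqn{DL\% = 100 \cdot \frac{c_{drug}}{c_{lipid}}, \qquad
#'   LE\% = 100 \cdot \frac{c_{drug} V_{final}}
#'   {c_{hydration} V_{hydration}},}
#' both on a mass basis (DL relative to the carrier lipid, LE relative to
#' the total drug offered), plus the molar loaded concentration
#' \eqn{c_{drug}/MW}. An alternative DL convention with drug + lipid in the
#' denominator is available via \code{dl_denominator}.
#'
#' @param prep a [prep_spec()].
#' @param dl_denominator \code{"lipid"} (default) or \code{"lipid+drug"}.
#' @return object of class \code{"loading_report"}: list with
#'   \code{loaded_conc_mg_per_mL}, \code{loaded_conc_molar} (mol/L),
#'   \code{loaded_conc_nM}, \code{DL_percent}, \code{LE_percent}.
#' @export
#' @examples
#' rep <- loading_percentages(prep_spec())
#' c(rep$DL_percent, rep$LE_percent, rep$loaded_conc_nM)
loading_percentages <- function(prep,
                                dl_denominator = c("lipid", "lipid+drug")) {
  stopifnot(inherits(prep, "prep_spec"))
  dl_denominator <- match.arg(dl_denominator)
  if (prep$final_lipid_conc <= 0) stop("zero lipid concentration")
  den <- switch(dl_denominator,
                "lipid" = prep$final_lipid_conc,
                "lipid+drug" = prep$final_lipid_conc + prep$final_drug_conc)
  DL <- 100 * prep$final_drug_conc / den
  LE <- 100 * (prep$final_drug_conc * prep$final_volume) /
    (prep$hydration_drug_conc * prep$hydration_volume)
  # mg/mL = g/L; kDa = kg/mol = 1000 g/mol
  molar <- prep$final_drug_conc / (prep$drug_MW * 1000)
  structure(list(loaded_conc_mg_per_mL = prep$final_drug_conc,
                 loaded_conc_molar = molar,
                 loaded_conc_nM = molar * 1e9,
                 DL_percent = DL,
                 LE_percent = LE),
            class = "loading_report")
}

#' @export
print.loading_report <- function(x, ...) {
  cat(sprintf("Loading report: DL%% = %.4g, LE%% = %.4g, loaded = %.3g nM\n",
              x$DL_percent, x$LE_percent, x$loaded_conc_nM))
  invisible(x)
}

#' Laurdan generalized polarization
#'
#' Membrane surface order/hydration index from the Laurdan emission
#' spectrum,
#' \deqn{GP = \frac{I_{435} - I_{500}}{I_{435} + I_{500}},}
#' bounded in \eqn{[-1, 1]}: higher values indicate a more ordered, less
#' hydrated bilayer surface. Intensities are taken at the grid points
#' nearest 435 and 500 nm (within 1 nm).
#'
#' @param wavelengths nm grid covering 435 and 500 nm.
#' @param intensities nonnegative emission intensities.
#' @return GP, dimensionless.
#' @export
laurdan_gp <- function(wavelengths, intensities) {
  stopifnot(length(wavelengths) == length(intensities))
  if (any(intensities < 0)) stop("intensities must be nonnegative")
  pick <- function(lambda) {
    i <- which.min(abs(wavelengths - lambda))
    if (abs(wavelengths[i] - lambda) > 1)
      stop("spectrum does not cover ", lambda, " nm (within 1 nm)")
    intensities[i]
  }
  I435 <- pick(435); I500 <- pick(500)
  if (I435 + I500 == 0) stop("zero intensity at both GP wavelengths")
  (I435 - I500) / (I435 + I500)
}

#' Critical micelle concentration from a fluorescence titration
#'
#' Locates the CMC as the breakpoint of a continuous two-segment
#' piecewise-linear fit to a probe-fluorescence titration (e.g. ANS versus
#' protein concentration): candidate breakpoints between interior data
#' points are screened exhaustively, the best is refined by golden-section
#' search on the residual sum of squares, and the two-segment model is
#' accepted only if it beats a single straight line in an F-test at
#' \code{alpha}.
#'
#' @param concentrations mg/mL, at least 6 points spanning the break.
#' @param fluorescence a.u.
#' @param MW molar mass, kDa, for the molar CMC (optional).
#' @param alpha significance level of the slope-change F-test (default
#'   0.05).
#' @return object of class \code{"cmc_fit"}: \code{cmc_mg_ml},
#'   \code{cmc_molar} (mol/L, \code{NA} without \code{MW}),
#'   \code{detected}, \code{p_value}, segment slopes/intercepts.
#'   When no slope change is detectable, \code{detected = FALSE} and the
#'   CMC fields are \code{NA}.
#' @export
#' @examples
#' x <- seq(0.05, 0.4, length.out = 12)
#' y <- ifelse(x < 0.215, 1 + 0.5 * x, 1 + 0.5 * 0.215 + 8 * (x - 0.215))
#' cmc_breakpoint(x, y, MW = 23.6)$cmc_mg_ml
cmc_breakpoint <- function(concentrations, fluorescence, MW = NULL,
                           alpha = 0.05) {
  x <- as.numeric(concentrations); y <- as.numeric(fluorescence)
  stopifnot(length(x) == length(y))
  if (length(x) < 6L) stop("at least 6 titration points are required")
  ord <- order(x); x <- x[ord]; y <- y[ord]
  n <- length(x)

  rss_at <- function(cp) {
    h <- pmax(x - cp, 0)
    fit <- stats::lm(y ~ x + h)
    sum(stats::resid(fit)^2)
  }
  # exhaustive screen over interior intervals, keeping >= 2 points per side
  cand <- (x[-1] + x[-n]) / 2
  cand <- cand[cand > x[2L] & cand < x[n - 1L]]
  if (length(cand) == 0L) stop("no admissible interior breakpoints")
  rss <- vapply(cand, rss_at, numeric(1))
  ibest <- which.min(rss)
  lo <- if (ibest > 1L) cand[ibest - 1L] else x[2L]
  hi <- if (ibest < length(cand)) cand[ibest + 1L] else x[n - 1L]
  opt <- stats::optimize(rss_at, c(lo, hi), tol = 1e-10)
  cp <- opt$minimum
  rss2 <- opt$objective

  fit1 <- stats::lm(y ~ x)
  rss1 <- sum(stats::resid(fit1)^2)
  df2 <- n - 4L  # two slopes, one intercept, one breakpoint
  Fstat <- ((rss1 - rss2) / 2) / max(rss2 / df2, .Machine$double.eps)
  p <- stats::pf(Fstat, 2, df2, lower.tail = FALSE)
  detected <- is.finite(Fstat) && p < alpha

  h <- pmax(x - cp, 0)
  cf <- stats::coef(stats::lm(y ~ x + h))
  out <- list(cmc_mg_ml = if (detected) cp else NA_real_,
              cmc_molar = if (detected && !is.null(MW))
                cp / (MW * 1000) else NA_real_,
              detected = detected,
              p_value = p,
              slope_below = unname(cf[2L]),
              slope_above = unname(cf[2L] + cf[3L]),
              intercept = unname(cf[1L]),
              rss = rss2)
  class(out) <- "cmc_fit"
  out
}

#' @export
print.cmc_fit <- function(x, ...) {
  if (!x$detected) cat("CMC fit: no breakpoint detected\n")
  else cat(sprintf("CMC = %.4g mg/mL%s (slope-change p = %.3g)\n",
                   x$cmc_mg_ml,
                   if (is.na(x$cmc_molar)) "" else
                     sprintf(" (%.3g uM)", x$cmc_molar * 1e6),
                   x$p_value))
  invisible(x)
}

#' Protein concentration from UV absorbance
#'
#' Beer--Lambert conversion \eqn{c = A_{280} / (\epsilon\, l)} with a
#' mass-based extinction coefficient (default 0.81 mL mg^-1 cm^-1, the
#' 280 nm coefficient of the casein used here).
#'
#' @param A280 absorbance at 280 nm, nonnegative.
#' @param path_cm optical path length, cm.
#' @param epsilon extinction coefficient, mg^-1 mL cm^-1.
#' @return concentration, mg/mL.
#' @export
absorbance_to_conc <- function(A280, path_cm = 1, epsilon = 0.81) {
  if (any(A280 < 0)) stop("'A280' must be nonnegative")
  if (path_cm <= 0 || epsilon <= 0) stop("path and epsilon must be positive")
  A280 / (epsilon * path_cm)
}
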
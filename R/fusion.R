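#' Sew MALS and SAXS branches into a whole-liposome form factor
#'
#' The MALS (5--25 um^-1) and SAXS (0.1--5 nm^-1) q ranges do not overlap,
#' so the two branches are joined through the fitted models rather than a
#' data overlap window. The normalized whole-liposome form factor predicted
#' by the fitted Gaussian-shell profile, \eqn{P(q) = |F(q)|^2/|F(0)|^2},
#' serves as the bridge: the SAXS branch, whose measured intensity carries
#' the thin-shell factor \eqn{I(q) \propto |F(q)|^2/q^2}, is first mapped to
#' form-factor space as \eqn{q^2 I(q)} and then scaled by
#' \deqn{\alpha = \arg\min_\alpha \sum_{q \in W}
#'   \left[ \alpha\, q^2 I_{SAXS}(q) - P(q) \right]^2}
#' over the low-q bridging window \eqn{W} (default 0.1--0.3 nm^-1). The
#' MALS branch is normalized by its fitted hollow-sphere amplitude, so
#' \eqn{P \to 1} as \eqn{q \to 0}. The output concatenates both branches
#' with per-point provenance.
#'
#' @param mals_fit a [fit_mals()] result (supplies the MALS data and its
#'   amplitude normalization), or a data frame with columns \code{q}
#'   (nm^-1) and \code{P} already normalized.
#' @param saxs_curve the SAXS [scattering_curve()].
#' @param shell_profile the fitted [gaussian_shell_profile()] bridging the
#'   two ranges.
#' @param window bridging window in nm^-1, default \code{c(0.1, 0.3)}.
#' @return object of class \code{"composite_form_factor"}: data frame with
#'   columns \code{q} (nm^-1), \code{P}, \code{source} (\code{"MALS"} /
#'   \code{"SAXS"}), with attribute \code{saxs_scale} = \eqn{\alpha}.
#' @export
#' @examples
#' prof <- lip0_profile()
#' mals <- fit_mals(gen_mals(hollow_sphere_model(41.5, 4), amplitude = 2e-5))
#' saxs <- gen_saxs(prof, scale = 3.5)
#' comp <- sew(mals, saxs, prof)
#' attr(comp, "saxs_scale")
sew <- function(mals_fit, saxs_curve, shell_profile,
                window = c(0.1, 0.3)) {
  stopifnot(inherits(shell_profile, "gaussian_shell"),
            inherits(saxs_curve, "scattering_curve"))
  if (inherits(mals_fit, "mals_fit")) {
    mals_df <- data.frame(q = mals_fit$q,
                          P = mals_fit$R_theta / mals_fit$params$amplitude)
  } else {
    mals_df <- as.data.frame(mals_fit)
    if (!all(c("q", "P") %in% names(mals_df)))
      stop("'mals_fit' must be a fit_mals() result or have columns q, P")
  }

  F0sq <- gaussian_shell_f0(shell_profile)^2
  if (F0sq <= 0) stop("degenerate shell profile: zero forward amplitude")
  in_win <- saxs_curve$q >= window[1L] & saxs_curve$q <= window[2L]
  if (sum(in_win) < 3L) stop("too few SAXS points in the bridging window")
  qw <- saxs_curve$q[in_win]
  y <- qw^2 * saxs_curve$I[in_win]
  P_model <- gaussian_shell_amplitude(shell_profile, qw)^2 / F0sq
  alpha <- sum(y * P_model) / sum(y^2)
  if (!is.finite(alpha) || alpha <= 0)
    stop("non-positive bridging scale: check the sign/scale of the inputs")

  saxs_df <- data.frame(q = saxs_curve$q,
                        P = alpha * saxs_curve$q^2 * saxs_curve$I)
  out <- rbind(cbind(mals_df[, c("q", "P")], source = "MALS"),
               cbind(saxs_df, source = "SAXS"))
  out <- out[order(out$q), ]
  if (any(diff(out$q) <= 0))
    stop("MALS and SAXS branches overlap in q; merged grid not increasing")
  rownames(out) <- NULL
  attr(out, "saxs_scale") <- alpha
  class(out) <- c("composite_form_factor", "data.frame")
  out
}

#' @export
print.composite_form_factor <- function(x, ...) {
  cat(sprintf(paste0("Composite form factor: %d points (%d MALS + %d SAXS), ",
                     "saxs_scale = %.4g\n"),
              nrow(x), sum(x$source == "MALS"), sum(x$source == "SAXS"),
              attr(x, "saxs_scale")))
  invisible(x)
}
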
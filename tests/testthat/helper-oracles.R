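# Independent numerical oracles used to pin down the closed-form models.

# radial Fourier transform of the Gaussian-shell density by adaptive
# quadrature: F(q) = 4*pi/q * Int_0^inf rho(r) r sin(qr) dr
quad_shell_amplitude <- function(profile, q) {
  vapply(q, function(qq) {
    f <- function(r) {
      rho <- 0
      for (k in seq_along(profile$rho))
        rho <- rho + profile$rho[k] *
          exp(-(r - profile$R - profile$eps[k])^2 /
                (2 * profile$sigma[k]^2))
      rho * r * sin(qq * r)
    }
    up <- profile$R + 40 * max(profile$sigma)
    4 * pi / qq *
      stats::integrate(f, 0, up, subdivisions = 2000L,
                       rel.tol = 1e-11)$value
  }, numeric(1))
}

# uniform-shell form factor by quadrature of the radial density
quad_hollow_sphere_pq <- function(model, q) {
  Ri <- model$R_mid - model$t / 2
  Ro <- model$R_mid + model$t / 2
  den <- (Ro^3 - Ri^3) / 3
  vapply(q, function(qq) {
    if (qq == 0) return(1)
    num <- stats::integrate(function(r) r * sin(qq * r), Ri, Ro,
                            rel.tol = 1e-10)$value / qq
    (num / den)^2
  }, numeric(1))
}

# multiplicative perturbation of a three-component profile, keeping the
# fixed core component and the head-position sign convention
perturb_profile <- function(profile, spread = 0.2, seed = 1) {
  set.seed(seed)
  fac <- stats::runif(8, 1 - spread, 1 + spread)
  gaussian_shell_profile(
    R = profile$R * fac[1],
    rho = c(1, profile$rho[2] * fac[2], profile$rho[3] * fac[3]),
    eps = c(0, profile$eps[2] * fac[4], profile$eps[3] * fac[5]),
    sigma = profile$sigma * fac[6:8])
}
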
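test_that("profile constructor enforces the bilayer invariants", {
  p <- lip0_profile()
  expect_s3_class(p, "gaussian_shell")
  expect_equal(p$d, 3.9)
  expect_error(gaussian_shell_profile(-1, c(1), c(0), c(1)), "positive")
  expect_error(gaussian_shell_profile(46, c(0.5, -1, -1), c(0, -2, 2),
                                      c(1, 1, 1)), "rho\\[1\\]")
  expect_error(gaussian_shell_profile(46, c(1, -1, -1), c(0.5, -2, 2),
                                      c(1, 1, 1)), "eps\\[1\\]")
  expect_error(gaussian_shell_profile(46, c(1, -1, -1), c(0, 2, -2),
                                      c(1, 1, 1)), "eps\\[2\\]")
  expect_error(gaussian_shell_profile(46, c(1, -1, -1), c(0, -2, 2),
                                      c(1, -1, 1)), "sigma")
})

test_that("shell amplitude matches adaptive quadrature across q", {
  q <- c(0.005, 0.05, 0.1, 0.5, 1, 2, 5)
  for (p in list(lip0_profile(), lipcas_profile())) {
    closed <- gaussian_shell_amplitude(p, q)
    oracle <- quad_shell_amplitude(p, q)
    expect_lt(max(abs(closed / oracle - 1)), 1e-3)
  }
})

test_that("shell amplitude is linear in the contrasts and zero without them", {
  p <- lip0_profile()
  q <- seq(0.1, 5, length.out = 50)
  # rho enters linearly: doubling every contrast doubles F (bypass the
  # rho[1] = 1 normalization via the raw structure)
  p2 <- p
  p2$rho <- 2 * p$rho
  expect_equal(gaussian_shell_amplitude(p2, q),
               2 * gaussian_shell_amplitude(p, q))
  p0 <- p
  p0$rho <- c(0, 0, 0)
  expect_equal(gaussian_shell_amplitude(p0, q), rep(0, length(q)))
})

test_that("amplitude rejects non-positive q and warns on wide Gaussians", {
  p <- lip0_profile()
  expect_error(gaussian_shell_amplitude(p, c(0, 1)), "positive")
  expect_error(gaussian_shell_amplitude(p, -0.1), "positive")
  wide <- p
  wide$sigma[1] <- p$R / 2
  expect_warning(gaussian_shell_amplitude(wide, 1), "closed form")
})

test_that("SAXS intensity is scale-linear, nonnegative, with nodes at F's sign changes", {
  p <- lip0_profile()
  q <- seq(0.1, 5, length.out = 2000)
  I1 <- saxs_intensity(p, q, scale = 1)
  I2 <- saxs_intensity(p, q, scale = 2)
  expect_equal(I2, 2 * I1)
  expect_true(all(I1 >= 0))
  expect_error(saxs_intensity(p, q, scale = -1), "positive")
  expect_error(saxs_intensity(p, 0.05), "0.1")
  expect_silent(saxs_intensity(p, 0.05, enforce_window = FALSE))
  # local minima of I coincide with sign changes of F to grid resolution
  F <- gaussian_shell_amplitude(p, q)
  sign_flip <- which(diff(sign(F)) != 0)
  mins <- which(diff(sign(diff(I1))) > 0) + 1L
  for (i in sign_flip)
    expect_true(min(abs(mins - i)) <= 1)
})

test_that("hollow-sphere form factor: P(0)=1, quadrature agreement, solid-sphere zero", {
  m <- hollow_sphere_model(41.5, 4)
  expect_equal(hollow_sphere_pq(m, 0), 1)
  q <- c(0.001, 0.01, 0.05, 0.1, 0.3)
  expect_lt(max(abs(hollow_sphere_pq(m, q) /
                      quad_hollow_sphere_pq(m, q) - 1)), 1e-6)
  # t -> 2 R_mid limit is a solid sphere with first zero at q R_o = 4.4934
  solid <- hollow_sphere_model(5, 9.9999)
  qs <- seq(0.40, 0.50, by = 1e-5)
  P <- hollow_sphere_pq(solid, qs)
  q_first_min <- qs[which(diff(sign(diff(P))) > 0)[1L] + 1L]
  expect_equal(q_first_min * (solid$R_mid + solid$t / 2), 4.4934,
               tolerance = 1e-3)
  expect_error(hollow_sphere_model(1, 4), "R_mid")
  expect_error(hollow_sphere_model(10, -1), "positive")
})

test_that("shell radius of gyration: closed form, thin-shell limit, monotonicity", {
  m <- hollow_sphere_model(41.5, 4)
  expect_equal(shell_radius_of_gyration(m), 41.5802, tolerance = 1e-4)
  # Monte-Carlo cross-check: random points uniform in the shell volume
  set.seed(42)
  n <- 2e5
  Ri <- 39.5; Ro <- 43.5
  r <- (Ri^3 + stats::runif(n) * (Ro^3 - Ri^3))^(1 / 3)
  expect_equal(shell_radius_of_gyration(m), sqrt(mean(r^2)),
               tolerance = 5e-3)
  # thin-shell limit and monotonicity in R_mid
  expect_equal(shell_radius_of_gyration(hollow_sphere_model(50, 1e-6)), 50,
               tolerance = 1e-9)
  rg <- vapply(seq(30, 60, by = 5),
               function(R) shell_radius_of_gyration(hollow_sphere_model(R, 4)),
               numeric(1))
  expect_true(all(diff(rg) > 0))
})

test_that("increasing bilayer thickness moves the first SAXS minimum to lower q", {
  q <- seq(0.5, 5, length.out = 3000)
  first_min <- vapply(c(3.0, 3.5, 3.9, 4.4, 5.0), function(d) {
    p <- gaussian_shell_profile(46, c(1, -0.9, -1.1),
                                c(0, -d / 2, d / 2),
                                c(0.9, 0.45, 0.55))
    I <- saxs_intensity(p, q)
    q[which(diff(sign(diff(I))) > 0)[1L] + 1L]
  }, numeric(1))
  expect_true(all(diff(first_min) < 0))
})

test_that("scattering_curve validates and converts units", {
  crv <- scattering_curve(c(5, 10, 25), c(3, 2, 1), technique = "MALS",
                          q_unit = "um^-1")
  expect_equal(crv$q, c(5, 10, 25) * 1e-3)
  expect_error(scattering_curve(c(1, 1, 2), 1:3), "increasing")
  expect_error(scattering_curve(1:3, c(1, NA, 3)), "finite")
  expect_error(scattering_curve(1:3, 1:3, sigma = c(1, 0, 1)), "sigma")
})
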
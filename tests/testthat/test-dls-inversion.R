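test_that("Siegert conversion: plateau, exact monoexponential identity, scale cancellation", {
  tau <- exp(seq(log(1e-6), log(0.1), length.out = 80))
  beta <- 0.7
  g2m1 <- beta * exp(-2 * 2000 * tau)
  tr <- correlation_trace(tau, g2m1)
  sg <- siegert_to_g1(tr, beta = beta)
  expect_equal(sg$g1, exp(-2000 * tau))
  # plateau estimate of beta from the short-lag limit
  sg_auto <- siegert_to_g1(tr)
  expect_equal(sg_auto$beta, beta, tolerance = 0.02)
  # halving beta with data halved leaves g1 unchanged
  tr_half <- correlation_trace(tau, g2m1 / 2)
  expect_equal(siegert_to_g1(tr_half, beta = beta / 2)$g1, sg$g1)
  # strongly negative values warn and are clipped
  tr_neg <- correlation_trace(tau, c(rep(beta, 40), rep(-0.2, 40)))
  expect_warning(out <- siegert_to_g1(tr_neg, beta = beta), "clipped")
  expect_true(all(out$g1 >= 0))
})

test_that("regularized inversion recovers a delta and a bimodal spectrum", {
  tau <- exp(seq(log(1e-6), log(1), length.out = 120))
  # monoexponential: mass concentrates within one grid spacing of 2000/s
  spec <- suppressWarnings(
    regularized_invert(exp(-2000 * tau), tau, lambda_reg = 0))
  expect_false(spec$all_zero)
  expect_true(all(spec$weights >= 0))
  expect_equal(sum(spec$weights), 1)
  step <- diff(log(spec$gamma))[1L]
  near <- abs(log(spec$gamma / 2000)) <= 1.5 * step
  expect_gt(sum(spec$weights[near]), 0.99)
  # two well-separated exponentials with equal weights
  g1b <- 0.5 * exp(-500 * tau) + 0.5 * exp(-5000 * tau)
  sp2 <- suppressWarnings(regularized_invert(g1b, tau, lambda_reg = 0))
  split <- sqrt(500 * 5000)
  w_lo <- sum(sp2$weights[sp2$gamma < split])
  w_hi <- sum(sp2$weights[sp2$gamma >= split])
  expect_lt(abs(w_lo / w_hi - 1), 0.1)
})

test_that("residual norm decreases monotonically as the smoothing relaxes", {
  tau <- exp(seq(log(1e-5), log(0.1), length.out = 60))
  g1 <- 0.6 * exp(-800 * tau) + 0.4 * exp(-4000 * tau)
  lambdas <- c(10^seq(2, -6, by = -1), 0)
  rn <- vapply(lambdas, function(l)
    suppressWarnings(regularized_invert(g1, tau, lambda_reg = l))$residual_norm,
    numeric(1))
  expect_true(all(diff(rn) <= 1e-10))
  expect_lt(rn[length(rn)], 1e-3)
})

test_that("Stokes-Einstein conversion matches the hand-computed rate and inverts", {
  # R_h = 50 nm, T = 293 K, eta = 1.002e-3 Pa s, q = 22.3 um^-1:
  # D = kT/(6 pi eta R) = 4.284e-12 m^2/s, Gamma = D q^2 = 2.13e3 / s
  gam <- radius_to_gamma(50, q = 22.3, temperature = 293, eta = 1.002e-3)
  expect_equal(gam, 2.13e3, tolerance = 2e-3)
  expect_equal(gamma_to_radius(gam, q = 22.3, temperature = 293,
                               eta = 1.002e-3), 50, tolerance = 1e-12)
  # q^2 scaling
  expect_equal(radius_to_gamma(50, q = 44.6) / radius_to_gamma(50, q = 22.3),
               4, tolerance = 1e-12)
  expect_error(gamma_to_radius(-1), "positive")
})

test_that("reweighting: monodisperse invariance, q->0 limit, exact round trip", {
  mono <- size_distribution(c(30, 45, 60), c(0, 1, 0), basis = "intensity")
  rw <- reweight(mono, "mass")
  expect_equal(rw$weights, mono$weights)
  # q -> 0: intensity -> mass is division by R^2
  radii <- seq(20, 80, by = 5)
  w <- stats::dnorm(radii, 45, 10)
  d <- size_distribution(radii, w, basis = "intensity")
  m0 <- reweight(d, "mass", q = 1e-8)
  expect_equal(m0$weights, (w / radii^2) / sum(w / radii^2),
               tolerance = 1e-6)
  # intensity -> mass -> intensity round trip at the measurement q
  m <- reweight(d, "mass", q = 0.0223)
  back <- reweight(m, "intensity", q = 0.0223)
  expect_equal(back$weights, d$weights, tolerance = 1e-12)
  # outputs always nonnegative and normalized
  expect_true(all(m$weights >= 0))
  expect_equal(sum(m$weights), 1)
})

test_that("log-normal population median is recovered within 10% at SNR 100", {
  dist <- lognormal_sizes(45, 0.15)
  true_med <- distribution_median(dist)
  for (s in 1:5) {
    tr <- gen_dls(dist, beta = 0.7,
                  noise = noise_model("gaussian-absolute", 0.007, seed = s))
    out <- suppressWarnings(invert_dls(tr))
    expect_lt(abs(distribution_median(out) / true_med - 1), 0.10)
    expect_true(all(out$weights >= 0))
    expect_equal(sum(out$weights), 1)
  }
})

test_that("size_distribution validates and normalizes", {
  expect_error(size_distribution(c(2, 1), c(1, 1)), "increasing")
  expect_error(size_distribution(c(1, 2), c(-1, 1)), "nonnegative")
  expect_error(size_distribution(c(1, 2), c(0, 0)), "zero")
  d <- size_distribution(c(1, 2), c(2, 2), basis = "mass")
  expect_equal(d$weights, c(0.5, 0.5))
  expect_identical(d$basis, "mass")
})
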
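test_that("self-fit of a model-generated curve has ~zero reduced chi-square", {
  truth <- lip0_profile()
  crv <- gen_saxs(truth, scale = 3.7)
  fit <- fit_saxs(crv, init = truth, n_restarts = 1)
  expect_true(fit$converged)
  expect_lt(fit$chi2_reduced / mean(crv$I^2), 1e-12)
  expect_equal(fit$params$R, 46, tolerance = 1e-6)
  expect_equal(fit$params$d, 3.9, tolerance = 1e-6)
})

test_that("noise-free self-consistent fits recover all free parameters below 1%", {
  for (truth in list(lip0_profile(), lipcas_profile())) {
    crv <- gen_saxs(truth, scale = 3.7)
    fit <- fit_saxs(crv, init = truth, n_restarts = 1)
    tv <- c(R = truth$R, rho_2 = truth$rho[2], rho_3 = truth$rho[3],
            eps_2 = truth$eps[2], eps_3 = truth$eps[3],
            sigma_1 = truth$sigma[1], sigma_2 = truth$sigma[2],
            sigma_3 = truth$sigma[3])
    rel <- abs(unlist(fit$params[names(tv)]) / tv - 1)
    expect_true(all(rel < 0.01))
  }
})

test_that("noise-free fits from perturbed starts recover the geometry", {
  for (truth in list(lip0_profile(), lipcas_profile())) {
    crv <- gen_saxs(truth, scale = 3.7)
    init <- perturb_profile(truth, 0.2, seed = 7)
    fit <- suppressWarnings(fit_saxs(crv, init, n_restarts = 8, seed = 1))
    expect_lt(abs(fit$params$R / truth$R - 1), 0.01)
    expect_lt(abs(fit$params$d / truth$d - 1), 0.01)
    expect_gt(fit$params$d, 0)
    expect_false(fit$multimodal)
  }
})

test_that("head-group canonicalization keeps eps_2 < 0 < eps_3", {
  crv <- gen_saxs(lip0_profile(), scale = 1)
  fit <- suppressWarnings(fit_saxs(crv, n_restarts = 2, seed = 3))
  expect_lt(fit$params$eps_2, 0)
  expect_gt(fit$params$eps_3, 0)
})

test_that("noisy-replicate uncertainties are calibrated (3-sigma coverage)", {
  truth <- lip0_profile()
  tv <- c(R = 46, rho_2 = -0.9, rho_3 = -1.1, eps_2 = -1.95, eps_3 = 1.95,
          sigma_1 = 0.9, sigma_2 = 0.45, sigma_3 = 0.55)
  hits <- logical(100)
  for (s in seq_len(100)) {
    crv <- gen_saxs(truth, scale = 3.7,
                    noise = noise_model("gaussian-relative", 0.02, seed = s))
    fit <- suppressWarnings(fit_saxs(crv, init = truth, n_restarts = 1))
    z <- abs(unlist(fit$params[names(tv)]) - tv) / unlist(fit$se[names(tv)])
    hits[s] <- all(is.finite(z)) && all(z <= 3)
  }
  expect_gte(mean(hits), 0.95)
})

test_that("electron density profile: symmetry, peak positions, baseline", {
  sym <- gaussian_shell_profile(46, c(1, -1, -1), c(0, -2, 2),
                                c(0.8, 0.4, 0.4))
  prof <- electron_density_profile(sym, seq(-5, 5, length.out = 401))
  expect_equal(prof$rho, rev(prof$rho))
  # well-separated heads peak at eps_2 and eps_3
  sep <- gaussian_shell_profile(46, c(1, -4, -4), c(0, -3.2, 3.2),
                                c(0.6, 0.5, 0.5))
  dense <- electron_density_profile(sep, seq(-6, 6, length.out = 12001))
  neg <- dense[dense$eps < 0, ]
  pos <- dense[dense$eps > 0, ]
  expect_equal(neg$eps[which.min(neg$rho)], -3.2, tolerance = 0.02)
  expect_equal(pos$eps[which.min(pos$rho)], 3.2, tolerance = 0.02)
  # baseline: contrast decays to the bulk level far from the bilayer
  far <- electron_density_profile(sym, c(-60, 60))
  expect_lt(max(abs(far$rho)), 1e-12)
})

test_that("fit_saxs rejects wrong technique and narrow windows", {
  mals <- scattering_curve(c(5, 10, 25), c(3, 2, 1), technique = "MALS",
                           q_unit = "um^-1")
  expect_error(fit_saxs(mals), "SAXS")
  crv <- gen_saxs(lip0_profile())
  expect_error(fit_saxs(crv, qmin = 4.9, qmax = 5), "few points")
})
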
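test_that("calibration fit: exact line, permutation invariance, degenerate design", {
  x <- c(1, 2, 3, 4) * 1e-8
  cal <- fit_calibration(x, 2 * x + 1)
  expect_equal(cal$slope, 2)
  expect_equal(cal$intercept, 1)
  expect_equal(cal$r_squared, 1)
  perm <- sample(seq_along(x))
  cal_p <- fit_calibration(x[perm], (2 * x + 1)[perm])
  expect_equal(cal_p$slope, cal$slope)
  expect_equal(cal_p$intercept, cal$intercept)
  expect_error(fit_calibration(rep(1e-8, 4), 1:4), "singular")
  expect_error(fit_calibration(x[1:2], 1:2), "3 calibration points")
  # symmetric +/- eps noise on duplicated points leaves the OLS slope exact
  xx <- rep(x, each = 2)
  yy <- rep(2 * x + 1, each = 2) + rep(c(1e-3, -1e-3), 4)
  expect_equal(fit_calibration(xx, yy)$slope, 2, tolerance = 1e-6)
})

test_that("loaded-protein quantification inverts the calibration exactly", {
  cal <- fit_calibration(c(1, 2, 4, 8) * 1e-9, 5e9 * c(1, 2, 4, 8) * 1e-9 + 0.2)
  # blank: intensity at the intercept gives zero (below the lowest
  # standard, so the extrapolation warning fires by design)
  expect_warning(blank <- quantify_loaded(0.2, cal, dol = 2), "extrapolat")
  expect_equal(blank, 0)
  # forward simulation round trip: c -> I -> c
  c_true <- 3e-9; dol <- 2.4
  I <- cal$intercept + cal$slope * (c_true * dol)
  expect_equal(quantify_loaded(I, cal, dol = dol), c_true)
  # DOL = 1 reduces to plain inverse calibration
  expect_equal(quantify_loaded(I, cal, dol = 1), c_true * dol)
  expect_warning(quantify_loaded(1e6, cal, dol = 1), "extrapolat")
  expect_error(suppressWarnings(quantify_loaded(0.1, cal, dol = 1)),
               "negative")
})

test_that("reference preparation reproduces the printed loading figures", {
  rep <- loading_percentages(prep_spec())
  expect_equal(rep$DL_percent, 0.045)
  expect_equal(rep$LE_percent, 0.45)
  expect_equal(rep$loaded_conc_nM, 3.8, tolerance = 0.005)
  # full retention gives LE = 100%
  full <- prep_spec(final_drug_conc = 0.2 * 0.5 / 5)
  expect_equal(loading_percentages(full)$LE_percent, 100)
  # unit rescaling invariance (mg -> ug on both drug and lipid)
  scaled <- prep_spec(final_lipid_conc = 0.2 * 1000,
                      final_drug_conc = 0.09e-3 * 1000,
                      hydration_drug_conc = 0.2 * 1000)
  expect_equal(loading_percentages(scaled)$DL_percent, 0.045)
  # alternative denominator differs only beyond the printed precision
  alt <- loading_percentages(prep_spec(), dl_denominator = "lipid+drug")
  expect_equal(alt$DL_percent, 0.045, tolerance = 1e-3)
  expect_error(prep_spec(final_drug_conc = 1), "exceeds")
})

test_that("generalized polarization: bounds and special values", {
  wl <- seq(400, 550, by = 1)
  flat <- rep(1, length(wl))
  expect_equal(laurdan_gp(wl, flat), 0)
  only_blue <- ifelse(wl == 435, 1, 0)
  expect_equal(laurdan_gp(wl, only_blue), 1)
  expect_equal(laurdan_gp(c(435, 500), c(0.634, 0.366)), 0.268)
  expect_error(laurdan_gp(c(435, 500), c(0, 0)), "zero intensity")
  expect_error(laurdan_gp(seq(450, 490, 1), rep(1, 41)), "cover")
  # GP stays in [-1, 1] for arbitrary nonnegative spectra
  set.seed(1)
  for (i in 1:50) {
    gp <- laurdan_gp(wl, stats::runif(length(wl)))
    expect_gte(gp, -1); expect_lte(gp, 1)
  }
})

test_that("CMC breakpoint: exact recovery, molar conversion, degenerate line", {
  dat <- gen_cmc(cmc = 0.215)
  fit <- cmc_breakpoint(dat$concentration, dat$intensity, MW = 23.6)
  expect_true(fit$detected)
  expect_equal(fit$cmc_mg_ml, 0.215, tolerance = 1e-6)
  expect_equal(fit$cmc_molar * 1e6, 9.1, tolerance = 0.02)
  # single straight line: no CMC detected
  x <- seq(0.05, 0.4, length.out = 10)
  line <- cmc_breakpoint(x, 1 + 2 * x)
  expect_false(line$detected)
  expect_true(is.na(line$cmc_mg_ml))
  expect_error(cmc_breakpoint(x[1:5], (1 + 2 * x)[1:5]), "6 titration")
})

test_that("absorbance conversion follows Beer-Lambert", {
  expect_equal(absorbance_to_conc(0.81), 1.0)
  expect_equal(absorbance_to_conc(0), 0)
  expect_equal(absorbance_to_conc(0.405), 0.5)
  expect_error(absorbance_to_conc(-0.1), "nonnegative")
})
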
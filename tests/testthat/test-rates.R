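# Intensity-series reduction: decay fits, tilted-frame R2, NOE, eta_xy
# build-up, RCZZ and the slow-exchange map.

sp15 <- spin_system("N15")
fc750 <- field_context(750, sp15)

test_that("monoexponential fit recovers exact and noisy rates", {
  t <- seq(0.04, 1.52, length.out = 8)
  clean <- tibble::tibble(time = t, intensity = 250 * exp(-1.5 * t))
  f <- fit_monoexponential(clean)
  expect_equal(f$rate, 1.5, tolerance = 1e-9)
  expect_equal(f$i0, 250, tolerance = 1e-9)
  expect_true(f$converged)

  # two points: exact log-ratio solution
  f2 <- fit_monoexponential(
    tibble::tibble(time = c(0, 1), intensity = c(100, 36.788))
  )
  expect_equal(f2$rate, 1.0, tolerance = 1e-4)

  # scale invariance of the rate
  f3 <- fit_monoexponential(
    dplyr::mutate(clean, intensity = intensity * 1e4)
  )
  expect_equal(f3$rate, f$rate, tolerance = 1e-9)

  expect_error(
    fit_monoexponential(tibble::tibble(time = c(1, 1, 1), intensity = 1:3)),
    "delays"
  )
})

test_that("noisy replicate series: rate within 3 sigma, error vs MC oracle", {
  t <- rep(seq(0.01, 0.4, length.out = 8), each = 2)
  r_true <- 12
  withr::with_seed(7, {
    y <- 100 * exp(-r_true * t) + stats::rnorm(length(t), 0, 2)
  })
  d <- tibble::tibble(time = t, intensity = y, replicate = rep(1:2, 8))
  # replicate pooling estimates the injected noise level
  fp <- fit_monoexponential(d)
  expect_lt(abs(fp$noise_sigma - 2) / 2, 0.5)
  # error comparison at the known noise level
  f <- fit_monoexponential(d, noise_sigma = 2)
  expect_lt(abs(f$rate - r_true), 3 * f$rate_err)
  # independent Monte-Carlo oracle for the rate standard error: resample
  # the data and refit with stats::nls (an optimizer the package does not
  # use), then compare the empirical spread with the covariance estimate
  mc <- withr::with_seed(11, {
    vapply(seq_len(1000), function(i) {
      yy <- 100 * exp(-r_true * t) + stats::rnorm(length(t), 0, 2)
      fit <- stats::nls(yy ~ a * exp(-b * t),
        start = list(a = 100, b = 10),
        control = stats::nls.control(warnOnly = TRUE)
      )
      stats::coef(fit)[["b"]]
    }, numeric(1))
  })
  expect_lt(abs(f$rate_err - stats::sd(mc)) / stats::sd(mc), 0.5)
  # monte-carlo error option is seeded and reproducible
  fm1 <- fit_monoexponential(d, error = "monte_carlo", n_mc = 50, seed = 3)
  fm2 <- fit_monoexponential(d, error = "monte_carlo", n_mc = 50, seed = 3)
  expect_identical(fm1$rate_err, fm2$rate_err)
})

test_that("error estimates shrink roughly as 1/sqrt(replicates)", {
  t8 <- seq(0.01, 0.4, length.out = 8)
  errs <- vapply(c(1, 4), function(nrep) {
    mean(vapply(1:40, function(s) {
      withr::with_seed(s, {
        tt <- rep(t8, each = nrep)
        y <- 100 * exp(-12 * tt) + stats::rnorm(length(tt), 0, 2)
      })
      fit_monoexponential(
        tibble::tibble(time = tt, intensity = y),
        noise_sigma = 2
      )$rate_err
    }, numeric(1)))
  }, numeric(1))
  expect_equal(errs[1] / errs[2], 2, tolerance = 0.2)
})

test_that("tilted-frame R2 follows the stated relation", {
  # on resonance: R2 = R1rho
  expect_equal(r2_from_r1rho(10, 1.5, 1000, 0), 10)
  # R1rho = R1 gives R2 = R1 at any tilt
  expect_equal(r2_from_r1rho(1.5, 1.5, 1000, 700), 1.5)
  # theta = 60 degrees worked example
  expect_equal(r2_from_r1rho(10, 1.5, sqrt(3) * 1000, 1000),
    (10 - 1.5 * 0.25) / 0.75,
    tolerance = 1e-12
  )
  # continuous at omega_off -> 0
  expect_equal(r2_from_r1rho(10, 1.5, 1000, 1e-8), 10, tolerance = 1e-9)
  expect_error(r2_from_r1rho(10, 1.5, 10, 2000), "off-resonance")
  expect_error(r2_from_r1rho(10, 1.5, -5, 0), "positive")
})

test_that("alignment filter keeps |omega_off|/omega_sl <= 0.4", {
  d <- tibble::tibble(omega_sl = 1000, omega_off = c(0, 300, 400, 401, -500))
  expect_equal(nrow(filter_alignment(d)), 3)
  expect_equal(nrow(filter_alignment(d, max_ratio = 0.45)), 4)
})

test_that("heteronuclear NOE ratio and its error propagation", {
  expect_equal(het_noe(100, 100)$noe, 1)
  expect_equal(het_noe(-20, 100)$noe, -0.2)
  expect_error(het_noe(5, 0), "non-zero")
  # propagation vs a large Monte-Carlo oracle
  sig <- 3
  mc <- withr::with_seed(5, {
    isat <- -20 + stats::rnorm(1e5, 0, sig)
    iref <- 100 + stats::rnorm(1e5, 0, sig)
    stats::sd(isat / iref)
  })
  expect_equal(het_noe(-20, 100, sig)$noe_err, mc, tolerance = 0.05)
  expect_true(het_noe(5, 8, noise_sigma = 3)$flagged)
})

test_that("eta_xy build-up fit: closed form, zero and noisy cases", {
  expect_equal(
    fit_eta_xy(tibble::tibble(time = 0.040, ratio = tanh(0.5)))$eta_xy,
    12.5,
    tolerance = 1e-9
  )
  expect_equal(
    fit_eta_xy(tibble::tibble(time = c(0.016, 0.04), ratio = c(0, 0)))$eta_xy,
    0
  )
  expect_error(fit_eta_xy(tibble::tibble(time = 0.04, ratio = 1.2)), "ratio")
  # noisy three-delay fit matches a dense grid search to 4 significant digits
  tt <- c(0.016, 0.032, 0.040)
  withr::with_seed(21, {
    rr <- tanh(8 * tt) * (1 + stats::rnorm(3, 0, 0.01))
  })
  f <- fit_eta_xy(tibble::tibble(time = tt, ratio = rr), ratio_sigma = 0.01)
  grid <- seq(5, 11, by = 1e-4)
  chi <- vapply(grid, function(e) sum((rr - tanh(e * tt))^2), numeric(1))
  expect_equal(f$eta_xy, grid[which.min(chi)], tolerance = 1e-4)
  expect_lt(abs(f$eta_xy - 8), 3 * f$eta_xy_err)
})

test_that("RCZZ rate and CPMG R2eff from intensity ratios", {
  expect_equal(rczz_r2(80, 80)$r2_rczz, 0)
  expect_equal(rczz_r2(exp(-1), 1)$r2_rczz, 1 / 0.1296, tolerance = 1e-12)
  expect_true(rczz_r2(-2, 100)$flagged)
  # round trip through the exponential form
  r2 <- 17.3
  expect_equal(
    rczz_r2(100 * exp(-r2 * 0.1296), 100)$r2_rczz, r2,
    tolerance = 1e-10
  )
  expect_equal(cpmg_r2eff(100, 100, 0.080)$r2eff, 0)
  expect_equal(cpmg_r2eff(exp(-1), 1, 0.080)$r2eff, 12.5)
  expect_warning(out <- cpmg_r2eff(c(-1, 50), c(100, 100), 0.064), "flagged")
  expect_true(out$flagged[1])
  expect_equal(out$r2eff[2], -log(0.5) / 0.064)
})

test_that("slow-exchange map: worked value and forward-model consistency", {
  expect_equal(
    rex_from_rczz(20, eta_xy = 15 / 1.2283, r1 = 2, kappa = 1.2283)$rex, 6
  )
  # quadrature error
  e <- rex_from_rczz(20, 10, 2, 1.2,
    r2_rczz_err = 0.3, eta_xy_err = 0.2, r1_err = 0.1
  )
  expect_equal(e$rex_err, sqrt(0.3^2 + (1.2 * 0.2)^2 + 0.05^2))

  # exchange-free residue built from the forward model: Rex = 0 exactly
  jf <- function(w) j_modelfree(w, 0.88, 6.5e-9, 20e-12)
  r <- rates_from_j(sp15, fc750, jf)
  eta <- eta_xy(sp15, fc750, jf(0), jf(fc750$omega_x))
  kap <- kappa_factor(sp15, fc750)
  r2_rczz <- kap * eta - r[["R1"]] / 2 # no exchange
  expect_lt(
    abs(rex_from_rczz(r2_rczz, eta, r[["R1"]], kap)$rex), 1e-6
  )
  # injected Rex = 4 recovered exactly from clean intensities
  rz <- rczz_r2(100 * exp(-(r2_rczz + 4) * 0.1296), 100)$r2_rczz
  expect_equal(
    rex_from_rczz(rz, eta, r[["R1"]], kap)$rex, 4,
    tolerance = 1e-9
  )
})
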
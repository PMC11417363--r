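# Two-site exchange forward models and dispersion fitting.

sp15 <- spin_system("N15")

test_that("Carver-Richards limits: no shift difference, vanishing minor state", {
  nu <- c(25, 50, 100, 250, 500, 750)
  # dw = 0: exactly flat at the intrinsic rate
  expect_equal(
    carver_richards_r2eff(nu, pa = 0.7, kex = 1000, dw = 0, ra = 15),
    rep(15, 6)
  )
  # pb -> 0: flat at Ra
  expect_equal(
    carver_richards_r2eff(nu,
      pa = 1 - 1e-12, kex = 1000,
      dw = ppm_to_rad(3, 750, sp15), ra = 12
    ),
    rep(12, 6),
    tolerance = 1e-6
  )
  # large nu_cp limit: pa Ra + pb Rb
  lim <- carver_richards_r2eff(1e5,
    pa = 0.95, kex = 800,
    dw = ppm_to_rad(3, 750, sp15), ra = 10, rb = 20
  )
  expect_equal(lim, 0.95 * 10 + 0.05 * 20, tolerance = 0.1)
})

test_that("Carver-Richards symmetry and monotonicity properties", {
  nu <- c(25, 75, 150, 300, 600)
  withr::with_seed(99, {
    for (i in 1:200) {
      pa <- stats::runif(1, 0.55, 0.999)
      kex <- 10^stats::runif(1, 2, 4.5)
      dw <- stats::runif(1, 100, 4000)
      ra <- stats::runif(1, 5, 25)
      rb <- stats::runif(1, 5, 25)
      # label-exchange invariance
      expect_equal(
        carver_richards_r2eff(nu, pa, kex, dw, ra, rb, quiet = TRUE),
        carver_richards_r2eff(nu, 1 - pa, kex, -dw, rb, ra, quiet = TRUE),
        tolerance = 1e-9
      )
      # monotone non-increasing in nu_cp for Ra = Rb
      v <- carver_richards_r2eff(nu, pa, kex, dw, ra, quiet = TRUE)
      expect_true(all(diff(v) <= 1e-9))
    }
  })
})

test_that("Carver-Richards matches the Bloch-McConnell propagator over regimes", {
  nu <- c(25, 50, 100, 200, 400, 750)
  for (kex in c(200, 2000, 20000)) {
    for (dwppm in c(0.5, 2, 4)) {
      dw <- ppm_to_rad(dwppm, 750, sp15)
      cr <- carver_richards_r2eff(nu, 0.97, kex, dw, ra = 10, quiet = TRUE)
      bm <- bm_cpmg_r2eff(nu, 0.97, kex, dw, 10, t_relax = 0.08)
      expect_lt(max(abs(cr - bm) / bm), 0.02)
    }
  }
})

test_that("fast-exchange limit agrees with Luz-Meiboom", {
  nu <- seq(25, 750, length.out = 20)
  dw <- ppm_to_rad(1, 750, sp15)
  kex <- 15 * dw # deep fast exchange
  pa <- 0.9
  cr <- carver_richards_r2eff(nu, pa, kex, dw, ra = 8, quiet = TRUE)
  lm <- fast_exchange_cpmg(nu, pa * (1 - pa) * dw^2, kex, 8)
  expect_lt(max(abs(cr - lm) / lm), 0.02)
})

test_that("fast-exchange R1rho model: limits and effective-field dependence", {
  expect_equal(fast_exchange_r1rho(1400, 0, 0, 7000, 14), 14)
  # monotone non-increasing in effective field, R2_0 asymptote
  sl <- c(200, 500, 1000, 3000, 10000, 1e6)
  v <- fast_exchange_r1rho(sl, 0, 5e4, 7000, 14)
  expect_true(all(diff(v) < 0))
  expect_equal(v[6], 14, tolerance = 1e-3)
  # depends on (omega_sl, omega_off) only through the squared sum
  expect_equal(
    fast_exchange_r1rho(300, 1200, 4e4, 6000, 10),
    fast_exchange_r1rho(1200, 300, 4e4, 6000, 10)
  )
  # zero-field intercept of the exchange term is phi_ex / kex
  expect_equal(
    fast_exchange_r1rho(1e-9, 0, 5e4, 7000, 0), 5e4 / 7000,
    tolerance = 1e-6
  )
})

test_that("fast-exchange R1rho matches the Bloch-McConnell oracle", {
  sl <- c(200, 500, 1000, 2000, 3000)
  for (kex in c(3000, 7000, 20000)) {
    for (dwppm in c(0.25, 0.5, 1)) {
      dw <- ppm_to_rad(dwppm, 750, sp15)
      phi <- 0.97 * 0.03 * dw^2
      fe <- fast_exchange_r1rho(sl, 0, phi, kex, 12)
      bm <- vapply(sl, function(s) bm_r1rho(s, 0, 0.97, kex, dw, 1.5, 12),
        numeric(1)
      )
      expect_lt(max(abs(fe - bm) / bm), 0.03)
    }
  }
})

test_that("per-residue CPMG fit recovers noiseless truth exactly", {
  prof <- make_profile("free_rrm1_like",
    seed = 3, kex_cterm = 850,
    pb_cterm = 0.003
  )
  prof$residues <- prof$residues[prof$residues$ex_group %in% "cterm", ][1:2, ]
  cur <- simulate_cpmg(prof, sp15, sigma = 0.4, seed = 11)
  cur$r2eff <- cur$r2eff_true
  one <- cur[cur$residue == cur$residue[1], ]
  dw_true <- attr(cur, "truth")$dw_ppm[1]
  f <- fit_cpmg(one, fixed_dw = dw_true)
  est <- function(term) f$params$estimate[f$params$term == term]
  expect_equal(est("kex"), 850, tolerance = 1e-3)
  expect_equal(est("pb"), 0.003, tolerance = 1e-3)
  # chi2 at the optimum is no worse than at the generating truth
  chi_truth <- sum(vapply(c(750, 900), function(fl) {
    rows <- one$field_mhz == fl
    pred <- carver_richards_r2eff(one$nu_cp[rows], 1 - 0.003, 850,
      ppm_to_rad(dw_true, fl, sp15),
      ra = one$r0[rows][1], quiet = TRUE
    )
    sum(((one$r2eff[rows] - pred) / one$sigma[rows])^2)
  }, numeric(1)))
  expect_lte(f$chi2, chi_truth + 1e-6)
})

test_that("flat synthetic curves favour the no-exchange description", {
  nu <- seq(25, 750, length.out = 10)
  withr::with_seed(17, {
    d <- tibble::tibble(
      field_mhz = 750, nu_cp = rep(nu, 2),
      r2eff = 12 + stats::rnorm(20, 0, 0.12), sigma = 0.12
    )
  })
  ff <- fit_cpmg(d, model = "fast")
  fg <- fit_cpmg(d, model = "general")
  cmp <- aic_compare(ff, fg, labels = c("fast", "general"))
  expect_equal(cmp$model[1], "fast")
  # fitted dispersion amplitude consistent with zero within 2 sigma
  phi <- ff$params$estimate[ff$params$term == "phi_ex_ppm2"]
  amp <- phi * ppm_to_rad(1, 750, sp15)^2 /
    ff$params$estimate[ff$params$term == "kex"]
  expect_lt(amp, 2 * 0.12)
})

test_that("global CPMG fit: single residue equals individual fit", {
  prof <- make_profile("free_rrm1_like", seed = 5)
  prof$residues <- prof$residues[prof$residues$ex_group %in% "beta4", ][1:2, ]
  cur <- simulate_cpmg(prof, sp15, sigma = 0.3, seed = 2)
  g <- fit_cpmg_global(cur, shared = "kex")
  # with per-residue pb free and one shared kex over identical-group
  # residues, each residue's global chi2 stays close to its individual one
  expect_true(all(g$per_residue$chi2_ratio < 1.6))
  expect_error(
    fit_cpmg_global(cur[cur$residue == cur$residue[1], ]),
    ">= 2 residues"
  )
})

test_that("global CPMG flags a residue generated with different kinetics", {
  prof <- make_profile("free_rrm1_like",
    seed = 8, kex_beta4 = 900,
    pb_beta4 = 0.01
  )
  keep <- prof$residues$ex_group %in% "beta4"
  prof$residues <- prof$residues[keep, ]
  cur <- simulate_cpmg(prof, sp15, sigma = 0.1, seed = 4)
  # regenerate one residue with very different kinetics
  out_prof <- prof
  out_prof$residues <- prof$residues[1, ]
  out_prof$groups$kex[out_prof$groups$group == "beta4"] <- 8000
  out_prof$residues$dw_ppm <- 4
  cur2 <- simulate_cpmg(out_prof, sp15, sigma = 0.1, seed = 9)
  mixed <- dplyr::bind_rows(
    cur[cur$residue != prof$residues$residue[1], ], cur2
  )
  g <- fit_cpmg_global(mixed, shared = c("kex", "pb"), ratio_cutoff = 2)
  expect_true(prof$residues$residue[1] %in% g$excluded)
})

test_that("r1rho fit: flat curve pins phi_ex at zero and is flagged", {
  withr::with_seed(31, {
    d <- tibble::tibble(
      site = "a",
      omega_sl = c(200, 500, 1000, 2000, 3500, 5000),
      omega_off = 0,
      r2eff = 15 + stats::rnorm(6, 0, 0.2), sigma = 0.2, r2_0 = 15
    )
  })
  f <- fit_r1rho(d, global_kex = FALSE)
  expect_lt(f$per_site$phi_ex[1] * f$individual$kex[1] /
    (f$individual$kex[1]^2), 2 * 0.2)
  expect_true(f$per_site$flagged[1])
})

test_that("r1rho global fit recovers a shared kex from multi-site data", {
  prof <- make_profile("bound_rrm1_like", seed = 2, kex_interface = 7000)
  cur <- simulate_r1rho(prof, sp15,
    omega_sl = c(800, 1100, rep(1400, 6)),
    omega_off = c(0, 0, 500, 1000, 1700, 2500, 3300, 4000),
    frac_sigma = 0.01, seed = 12
  )
  f <- fit_r1rho(cur, global_kex = TRUE)
  expect_equal(f$kex, 7000, tolerance = 0.15)
  expect_true(all(f$per_site$chi2_ratio < 2, na.rm = TRUE))
  # tidy/glance surface
  td <- tidy(f)
  expect_true(all(c("site", "phi_ex", "kex") %in% names(td)))
  expect_equal(glance(f)$kex, f$kex)
})

test_that("AIC comparison prefers parsimony and reports deltas", {
  fa <- list(chi2 = 30, n_params = 3, n_points = 20)
  fb <- list(chi2 = 30, n_params = 5, n_points = 20)
  cmp <- aic_compare(fa, fb, labels = c("A", "B"))
  expect_equal(cmp$model, c("A", "B"))
  expect_equal(cmp$delta_aic, c(0, 4))
  fc_ <- list(chi2 = 30, n_params = 3, n_points = 15)
  expect_error(aic_compare(fa, fc_), "different data")
})

test_that("Monte-Carlo parameter errors are seeded and scale with noise", {
  prof <- make_profile("free_rrm1_like", seed = 4)
  prof$residues <- prof$residues[prof$residues$ex_group %in% "beta4", ][1, ]
  cur <- simulate_cpmg(prof, sp15, sigma = 0.3, seed = 6)
  f <- fit_cpmg(cur, model = "general")
  e1 <- mc_parameter_errors(f, n_draws = 20, seed = 5)
  e2 <- mc_parameter_errors(f, n_draws = 20, seed = 5)
  expect_identical(e1$mc_error, e2$mc_error)
  # smaller point noise gives smaller parameter errors
  cur_small <- cur
  cur_small$sigma <- cur$sigma / 10
  cur_small$r2eff <- cur$r2eff_true +
    withr::with_seed(8, stats::rnorm(nrow(cur), 0, cur_small$sigma))
  fs <- fit_cpmg(cur_small, model = "general")
  es <- mc_parameter_errors(fs, n_draws = 20, seed = 5)
  kex_err <- function(e) e$mc_error[e$term == "kex"]
  expect_lt(kex_err(es), kex_err(e1))
})

test_that("MC errors match closed-form weighted LS on a linear sub-problem", {
  # fixed kex: r1rho model is linear in phi_ex; the weighted-LS sigma of
  # phi_ex has a closed form
  kex <- 7000
  sl <- c(200, 500, 1000, 2000, 3000, 4500)
  x <- kex / ((2 * pi * sl)^2 + kex^2)
  sig <- 0.25
  phi_true <- 4e4
  withr::with_seed(13, {
    d <- tibble::tibble(
      site = "s1", omega_sl = sl, omega_off = 0,
      r2eff = 12 + phi_true * x + stats::rnorm(6, 0, sig),
      sigma = sig, r2_0 = 12
    )
  })
  f <- fit_r1rho(d,
    global_kex = TRUE,
    kex_range = log10(kex) + c(-1e-4, 1e-4)
  )
  e <- mc_parameter_errors(f, n_draws = 400, seed = 2)
  closed <- sig / sqrt(sum(x^2))
  got <- e$mc_error[e$term == "phi_ex_s1"]
  expect_equal(got, closed, tolerance = 0.1)
})
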
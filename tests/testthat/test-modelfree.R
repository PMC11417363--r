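# Rotational diffusion estimation and model-free fitting.

sp15 <- spin_system("N15")
fc700 <- field_context(700, sp15)

test_that("isotropic tau_c is recovered from rigid synthetic rates", {
  # truly rigid residues: inversion is exact to 4 digits
  prof <- make_profile("uniform_rigid", seed = 1, tau_c = 6.54e-9, n_residues = 20)
  prof$residues$tau_i <- 0
  rates <- simulate_rates(prof, sp15, fc700, frac_sigma = 0, noe_sigma = 0,
    seed = 1)
  tc <- estimate_tc_isotropic(rates, sp15, fc700)
  expect_equal(tc$tau_c, 6.54e-9, tolerance = 1e-4)
  # single rigid residue: per-residue equals ensemble
  tc1 <- estimate_tc_isotropic(rates[1, ], sp15, fc700)
  expect_equal(tc1$per_residue$tau_c[1], tc1$tau_c)
  # field invariance for rigid synthetic residues
  fc900 <- field_context(900, sp15)
  rates900 <- simulate_rates(prof, sp15, fc900, frac_sigma = 0,
    noe_sigma = 0, seed = 1)
  tc900 <- estimate_tc_isotropic(rates900, sp15, fc900)
  expect_equal(tc900$tau_c, tc$tau_c, tolerance = 0.01)
})

test_that("exchange-broadened residues are excluded by the R2/R1 trimming", {
  prof <- make_profile("uniform_rigid", seed = 2, tau_c = 6.54e-9, n_residues = 20)
  prof$residues$tau_i <- 0
  rates <- simulate_rates(prof, sp15, fc700, frac_sigma = 0.002,
    noe_sigma = 0.002, seed = 2)
  tc0 <- estimate_tc_isotropic(rates, sp15, fc700)
  rates$R2[3] <- rates$R2[3] + 5 # inject Rex into one residue
  tc1 <- estimate_tc_isotropic(rates, sp15, fc700)
  expect_false(tc1$per_residue$used[3])
  expect_equal(tc1$tau_c, tc0$tau_c, tolerance = 0.01)
})

test_that("axial tensor fit recovers anisotropy and prefers the right model", {
  prof <- make_profile("bound_rrm1_like", seed = 3, n_residues = 50,
    tau_c = 11.8e-9, d_ratio = 1.26)
  prof$residues$ex_group <- NA_character_
  rates <- simulate_rates(prof, sp15, fc700, frac_sigma = 0.01,
    noe_sigma = 0.01, seed = 13)
  f <- fit_axial_tensor(rates, prof$vectors, sp15, fc700)
  expect_equal(f$tensor$d_ratio, 1.26, tolerance = 0.08 / 1.26)
  expect_equal(f$tensor$tau_c, 11.8e-9, tolerance = 0.02)
  expect_equal(f$preferred, "axial")
  # axis reported in the upper hemisphere
  expect_gte(f$tensor$axis[3], 0)

  # isotropic truth: ratio within noise of 1, isotropic preferred
  prof_i <- make_profile("uniform_rigid", seed = 4, tau_c = 6.5e-9,
    n_residues = 40)
  prof_i$residues$tau_i <- 0
  rates_i <- simulate_rates(prof_i, sp15, fc700, frac_sigma = 0.01,
    noe_sigma = 0.01, seed = 14)
  f_i <- fit_axial_tensor(rates_i, prof_i$vectors, sp15, fc700)
  expect_equal(f_i$preferred, "isotropic")
  expect_equal(f_i$tensor$d_ratio, 1, tolerance = 0.08)
})

test_that("tensor fit falls back to isotropic on degenerate input", {
  prof <- make_profile("uniform_rigid", seed = 5, n_residues = 6)
  prof$residues$tau_i <- 0
  rates <- simulate_rates(prof, sp15, fc700, frac_sigma = 0.005,
    noe_sigma = 0.005, seed = 15)
  expect_warning(
    f <- fit_axial_tensor(rates, prof$vectors, sp15, fc700),
    "isotropic"
  )
  expect_equal(f$preferred, "isotropic")
})

test_that("model-free fit: noiseless model-1 residue selects model 1", {
  tens <- diffusion_tensor(6.5e-9)
  r <- rates_from_j(sp15, fc700, function(w) j_modelfree(w, 0.88, 6.5e-9))
  d <- tibble::tibble(
    residue = 1, R1 = r[["R1"]], R2 = r[["R2"]], NOE = r[["NOE"]],
    R1_err = 0.02 * r[["R1"]], R2_err = 0.02 * r[["R2"]], NOE_err = 0.02
  )
  mf <- fit_modelfree(d, tens, sp15, fc700)
  expect_equal(mf$model, 1L)
  expect_true(mf$selected)
  expect_equal(mf$s2, 0.88, tolerance = 1e-4)
  expect_lt(mf$chi2, 1e-6)
})

test_that("model-free fit recovers rigid and extended residues with noise", {
  tens <- diffusion_tensor(6.54e-9)
  # rigid residue with fast internal motion: model 2, S2 within 0.02
  errs <- replicate(20, NA_real_)
  mods <- integer(20)
  for (s in 1:20) {
    r <- rates_from_j(sp15, fc700,
      function(w) j_modelfree(w, 0.90, 6.54e-9, 30e-12))
    withr::with_seed(s, {
      obs <- r * c(1 + stats::rnorm(2, 0, 0.005), 1)
      obs[3] <- r[["NOE"]] + stats::rnorm(1, 0, 0.005)
    })
    d <- tibble::tibble(
      residue = 1, R1 = obs[1], R2 = obs[2], NOE = obs[3],
      R1_err = 0.005 * r[["R1"]], R2_err = 0.005 * r[["R2"]], NOE_err = 0.005
    )
    mf <- fit_modelfree(d, tens, sp15, fc700)
    errs[s] <- mf$s2 - 0.90
    mods[s] <- mf$model
  }
  expect_lt(mean(abs(errs)), 0.02)
  # occasional spurious complexity is tolerated at the test size
  expect_gte(mean(mods %in% c(1L, 2L)), 0.9)

  # extended-dynamics terminus: model 5 selected, S2 within 0.05
  s2_true <- 0.8 * 0.5
  sel5 <- logical(10)
  errs5 <- numeric(10)
  for (s in 1:10) {
    r <- rates_from_j(sp15, fc700,
      function(w) j_extended(w, 0.8, 0.5, 6.54e-9, 1.2e-9))
    withr::with_seed(100 + s, {
      obs <- c(r[1:2] * (1 + stats::rnorm(2, 0, 0.005)),
        r[[3]] + stats::rnorm(1, 0, 0.005))
    })
    d <- tibble::tibble(
      residue = 1, R1 = obs[1], R2 = obs[2], NOE = obs[3],
      R1_err = 0.005 * r[["R1"]], R2_err = 0.005 * r[["R2"]], NOE_err = 0.005
    )
    mf <- fit_modelfree(d, tens, sp15, fc700)
    sel5[s] <- mf$model == 5L
    errs5[s] <- mf$s2 - s2_true
  }
  expect_gte(mean(sel5), 0.8)
  expect_lt(mean(abs(errs5)), 0.05)
})

test_that("selected models reproduce the input rates (round trip)", {
  tens <- diffusion_tensor(6.5e-9)
  prof <- make_profile("free_rrm1_like", seed = 6, n_residues = 40)
  rates <- simulate_rates(prof, sp15, fc700, seed = 16)
  mf <- fit_modelfree(rates, tens, sp15, fc700)
  for (i in seq_len(nrow(mf))) {
    row <- mf[i, ]
    ti <- if (is.na(row$tau_i)) 0 else row$tau_i
    j <- if (row$model == 5L) {
      function(w) j_extended(w, row$sf2, row$ss2, tens$tau_c, row$tau_s)
    } else {
      function(w) j_modelfree(w, row$s2, tens$tau_c, ti)
    }
    pred <- rates_from_j(sp15, fc700, j,
      rex = if (is.na(row$rex)) 0 else row$rex)
    obs <- rates[rates$residue == row$residue, ]
    # within ~4 combined-sigma of the generating noise for selected fits
    if (row$selected) {
      expect_lt(abs(pred[["R1"]] - obs$R1) / obs$R1_err, 4.5)
      expect_lt(abs(pred[["R2"]] - obs$R2) / obs$R2_err, 4.5)
      expect_lt(abs(pred[["NOE"]] - obs$NOE) / obs$NOE_err, 4.5)
    }
  }
})

test_that("false-positive exchange selection is rare", {
  # residues generated without exchange: models 3/4 chosen rarely
  tens <- diffusion_tensor(6.5e-9)
  n_fp <- 0
  n <- 0
  for (s in 1:4) {
    prof <- make_profile("uniform_rigid", seed = s, n_residues = 50)
    rates <- simulate_rates(prof, sp15, fc700, seed = 20 + s)
    mf <- fit_modelfree(rates, tens, sp15, fc700)
    n_fp <- n_fp + sum(mf$model %in% c(3L, 4L))
    n <- n + nrow(mf)
  }
  expect_lte(n_fp / n, 0.10)
})

test_that("viscosity rescaling of tau_c", {
  expect_equal(scale_tc_viscosity(5, eta_target = 1, eta_ref = 1), 5)
  expect_equal(scale_tc_viscosity(1.002), 0.653)
  expect_equal(scale_tc_viscosity(6.37), 4.1513074, tolerance = 1e-7)
})
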
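# Seeded ground-truth generators for every observable the pipeline
# consumes, so each fitting stage is tested by parameter recovery. The
# presets emulate the dynamic architecture of a two-state RRM domain:
# rigid core, flexible termini with ns internal motions, a beta4-like
# slow-exchange group and a C-terminal helix-coil exchange group in the
# free state; slower anisotropic tumbling plus a fast-exchanging
# interface group in the bound state.

#' Build a ground-truth dynamics profile
#'
#' Returns a per-residue table of model-free and exchange ground truth,
#' together with the diffusion tensor and exchange-group definitions, for
#' use by the `simulate_*` generators. Presets:
#'
#' * `free_rrm1_like` — 120 residues, isotropic tau_c = 6.5 ns; flexible
#'   N-terminus (residues 1-20) and C-terminus (106-120) with extended
#'   model-free dynamics (Sf2 = 0.75-0.9, Ss2 chosen so S2 spans 0.3-0.7,
#'   tau_s = 0.5-2 ns); rigid core (21-105, S2 = 0.85-0.95, tau_i =
#'   10-50 ps); a beta4-like exchange group (residues 95-100, kex drawn
#'   in 800-1000 1/s, pb = 1 percent) and a C-terminal group (residues
#'   106-112, kex in 750-950 1/s, pb = 0.3 percent), shift differences
#'   1.5-4 ppm.
#' * `bound_rrm1_like` — tau_c = 11.8 ns, axially symmetric tensor with
#'   D_par/D_perp = 1.26; quenched termini; a fast-exchanging interface
#'   group (residues 40-50, kex = 7000 1/s, pb = 3 percent, dw 0.5-2 ppm).
#' * `uniform_rigid` — all S2 = 0.9, tau_i = 20 ps, no exchange.
#'
#' Every random draw is governed by `seed`; the same seed yields an
#' identical profile. All preset numbers are configuration through `...`
#' overrides, not claims about any particular protein.
#'
#' @param preset one of `"free_rrm1_like"`, `"bound_rrm1_like"`,
#'   `"uniform_rigid"`.
#' @param seed integer seed.
#' @param n_residues number of pseudo-residues.
#' @param ... overrides: `tau_c`, `d_ratio`, `core_s2`, `term_s2`,
#'   `kex_beta4`, `kex_cterm`, `kex_interface`, `pb_beta4`, `pb_cterm`,
#'   `pb_interface`.
#' @return a `synth_profile`: list with `residues` (tibble: residue,
#'   region, model, s2, sf2, ss2, tau_i, tau_s, rex, ex_group), `groups`
#'   (tibble: group, kex, pb, dw range), `tensor`, `vectors` (unit N-H
#'   vectors), `seed`, `preset`.
#' @export
make_profile <- function(preset = c(
                           "free_rrm1_like", "bound_rrm1_like",
                           "uniform_rigid"
                         ),
                         seed = 1L, n_residues = 120, ...) {
  preset <- match.arg(preset)
  ov <- list(...)
  gv <- function(nm, default) ov[[nm]] %||% default
  withr::with_seed(seed, {
    resid <- seq_len(n_residues)
    vectors <- .random_unit_vectors(n_residues)
    if (preset == "uniform_rigid") {
      residues <- tibble::tibble(
        residue = resid, region = "core", model = 2L,
        s2 = gv("core_s2", 0.9), sf2 = NA_real_, ss2 = NA_real_,
        tau_i = 20e-12, tau_s = NA_real_, rex = 0, ex_group = NA_character_
      )
      groups <- tibble::tibble(
        group = character(), kex = numeric(), pb = numeric()
      )
      tensor <- diffusion_tensor(gv("tau_c", 6.5e-9))
    } else if (preset == "free_rrm1_like") {
      nterm <- resid <= 20
      cterm <- resid >= 106
      core <- !nterm & !cterm
      beta4 <- resid >= 95 & resid <= 100
      cterm_ex <- resid >= 106 & resid <= 112
      region <- dplyr::case_when(
        nterm ~ "nterm",
        beta4 ~ "beta4",
        cterm ~ "cterm",
        resid >= 72 & resid <= 80 ~ "alpha2",
        TRUE ~ "core"
      )
      s2 <- numeric(n_residues)
      sf2 <- rep(NA_real_, n_residues)
      ss2 <- rep(NA_real_, n_residues)
      tau_i <- rep(NA_real_, n_residues)
      tau_s <- rep(NA_real_, n_residues)
      model <- integer(n_residues)
      term <- nterm | cterm
      s2[!term] <- stats::runif(sum(!term), 0.85, 0.95)
      tau_i[!term] <- stats::runif(sum(!term), 10e-12, 50e-12)
      model[!term] <- 2L
      sf2[term] <- stats::runif(sum(term), 0.75, 0.9)
      s2[term] <- stats::runif(sum(term), 0.3, 0.7)
      ss2[term] <- s2[term] / sf2[term]
      tau_s[term] <- stats::runif(sum(term), 0.5e-9, 2e-9)
      model[term] <- 5L
      ex_group <- rep(NA_character_, n_residues)
      ex_group[beta4] <- "beta4"
      ex_group[cterm_ex] <- "cterm"
      groups <- tibble::tibble(
        group = c("beta4", "cterm"),
        kex = c(
          gv("kex_beta4", stats::runif(1, 800, 1000)),
          gv("kex_cterm", stats::runif(1, 750, 950))
        ),
        pb = c(gv("pb_beta4", 0.01), gv("pb_cterm", 0.003))
      )
      tensor <- diffusion_tensor(gv("tau_c", 6.5e-9))
      residues <- tibble::tibble(
        residue = resid, region = region, model = model, s2 = s2,
        sf2 = sf2, ss2 = ss2, tau_i = tau_i, tau_s = tau_s,
        rex = 0, ex_group = ex_group
      )
    } else { # bound_rrm1_like
      interface <- resid >= 40 & resid <= 50
      region <- ifelse(interface, "interface", "core")
      s2 <- stats::runif(n_residues, 0.85, 0.95)
      residues <- tibble::tibble(
        residue = resid, region = region, model = 2L, s2 = s2,
        sf2 = NA_real_, ss2 = NA_real_,
        tau_i = stats::runif(n_residues, 10e-12, 50e-12),
        tau_s = NA_real_, rex = 0,
        ex_group = ifelse(interface, "interface", NA_character_)
      )
      groups <- tibble::tibble(
        group = "interface",
        kex = gv("kex_interface", 7000),
        pb = gv("pb_interface", 0.03)
      )
      tensor <- diffusion_tensor(
        gv("tau_c", 11.8e-9), gv("d_ratio", 1.26),
        axis = c(0.3, 0.2, 0.93)
      )
    }
    # per-residue shift differences for exchange members
    dw_rng <- if (preset == "bound_rrm1_like") c(0.5, 2) else c(1.5, 4)
    residues$dw_ppm <- ifelse(
      is.na(residues$ex_group), NA_real_,
      stats::runif(nrow(residues), dw_rng[1], dw_rng[2])
    )
    structure(
      list(
        residues = residues, groups = groups, tensor = tensor,
        vectors = tibble::tibble(
          residue = resid,
          x = vectors[, 1], y = vectors[, 2], z = vectors[, 3]
        ),
        seed = seed, preset = preset
      ),
      class = "synth_profile"
    )
  })
}

#' @export
print.synth_profile <- function(x, ...) {
  cat(sprintf(
    "<synth_profile> %s  %d residues  tau_c = %.2f ns  %d exchange group(s)\n",
    x$preset, nrow(x$residues), x$tensor$tau_c * 1e9, nrow(x$groups)
  ))
  invisible(x)
}

#' @noRd
.random_unit_vectors <- function(n) {
  m <- matrix(stats::rnorm(3 * n), ncol = 3)
  m / sqrt(rowSums(m^2))
}

#' Spectral density callable for one profile residue
#' @noRd
.profile_j <- function(profile, i, nh_angle = NULL) {
  row <- profile$residues[i, ]
  tensor <- profile$tensor
  if (row$model == 5L) {
    function(w) j_extended(w, row$sf2, row$ss2, tensor$tau_c, row$tau_s)
  } else if (tensor$model == "axial") {
    ang <- nh_angle %||% {
      v <- unlist(profile$vectors[i, c("x", "y", "z")])
      acos(min(max(abs(sum(v * tensor$axis)), 0), 1)) * 180 / pi
    }
    function(w) j_axial(w, row$s2, row$tau_i %|NA|% 0, tensor, ang)
  } else {
    function(w) j_modelfree(w, row$s2, tensor$tau_c, row$tau_i %|NA|% 0)
  }
}

#' Fast-exchange Rex of an exchange-group member at a given field
#' @noRd
.profile_rex <- function(profile, i, spin, field) {
  row <- profile$residues[i, ]
  if (is.na(row$ex_group)) return(row$rex)
  g <- profile$groups[profile$groups$group == row$ex_group, ]
  dw <- ppm_to_rad(row$dw_ppm, field, spin)
  row$rex + (1 - g$pb) * g$pb * dw^2 / g$kex
}

#' Simulate a per-residue relaxation-rate table
#'
#' Exact closed-form (R1, R2, NOE) from the profile's spectral densities,
#' with each exchange-group member's fast-limit Rex added to R2, plus
#' seeded Gaussian noise (fractional for R1/R2, absolute for NOE).
#'
#' @param profile a [make_profile()] result.
#' @param spin,field spin system and field to simulate at.
#' @param frac_sigma fractional noise on R1 and R2 (default 2 percent).
#' @param noe_sigma absolute NOE noise (default 0.02).
#' @param seed integer seed; 0 noise draws are still reproducible.
#' @return tibble: `residue`, `region`, `R1`, `R2`, `NOE` and `_err`
#'   columns holding the known noise levels.
#' @export
simulate_rates <- function(profile, spin, field, frac_sigma = 0.02,
                           noe_sigma = 0.02, seed = 1L) {
  n <- nrow(profile$residues)
  clean <- t(vapply(seq_len(n), function(i) {
    rates_from_j(spin, field, .profile_j(profile, i),
      rex = .profile_rex(profile, i, spin, field)
    )
  }, numeric(3)))
  withr::with_seed(seed, {
    r1 <- clean[, 1] * (1 + stats::rnorm(n, 0, frac_sigma))
    r2 <- clean[, 2] * (1 + stats::rnorm(n, 0, frac_sigma))
    noe <- clean[, 3] + stats::rnorm(n, 0, noe_sigma)
    tibble::tibble(
      residue = profile$residues$residue,
      region = profile$residues$region,
      R1 = r1, R2 = r2, NOE = noe,
      R1_err = frac_sigma * clean[, 1],
      R2_err = frac_sigma * clean[, 2],
      NOE_err = rep(noe_sigma, n)
    )
  })
}

#' Simulate CPMG dispersion curves for the profile's exchange residues
#'
#' Carver-Richards forward model at each field's nu_cp grid plus Gaussian
#' noise of standard deviation `sigma`. The per-residue intrinsic rate is
#' the exchange-free R2 from the profile's spectral density (Ra = Rb).
#' With `as_intensity = TRUE` the curves are also emitted as constant-time
#' intensity pairs through the inverse of [cpmg_r2eff()].
#'
#' @param profile a [make_profile()] result.
#' @param spin the observed nucleus.
#' @param fields_mhz 1H frequencies, MHz.
#' @param nu_cp named list of nu_cp grids (Hz) per field; defaults to 16
#'   constant-time-compatible values spanning 25-750 Hz (31.25-750 Hz at
#'   900 MHz).
#' @param sigma R2eff noise, 1/s.
#' @param t_relax named constant-time values (s) per field, for the
#'   intensity emission (defaults 0.080 at 750, 0.064 at 900).
#' @param as_intensity also emit intensity pairs.
#' @param seed integer seed.
#' @return tibble: `residue`, `field_mhz`, `nu_cp`, `r2eff`, `sigma`,
#'   `r2eff_true`, plus `i_cpmg`, `i_ref` when requested; attribute
#'   `truth` holds the generating parameters.
#' @export
simulate_cpmg <- function(profile, spin = spin_system("N15"),
                          fields_mhz = c(750, 900), nu_cp = NULL,
                          sigma = 0.4, t_relax = NULL,
                          as_intensity = FALSE, seed = 1L) {
  # default grids mirror constant-time sampling: nu_cp is a multiple of
  # 1/t_relax (12.5 Hz at 750 MHz / 80 ms, 15.625 Hz at 900 MHz / 64 ms),
  # 16 values spanning 25-750 Hz
  nu_cp <- nu_cp %||% stats::setNames(lapply(fields_mhz, function(f) {
    step <- if (f >= 900) 15.625 else 12.5
    lo <- 2 * step
    unique(round(seq(lo, 750, length.out = 16) / step) * step)
  }), as.character(fields_mhz))
  t_relax <- t_relax %||% stats::setNames(
    ifelse(fields_mhz >= 900, 0.064, 0.080), as.character(fields_mhz)
  )
  ex <- which(!is.na(profile$residues$ex_group))
  if (!length(ex)) stop("profile has no exchange residues", call. = FALSE)
  grid <- purrr::map_dfr(ex, function(i) {
    row <- profile$residues[i, ]
    g <- profile$groups[profile$groups$group == row$ex_group, ]
    purrr::map_dfr(fields_mhz, function(f) {
      fc <- field_context(f, spin)
      r0 <- rates_from_j(spin, fc, .profile_j(profile, i))[["R2"]]
      nu_grid <- nu_cp[[as.character(f)]]
      tibble::tibble(
        residue = row$residue, field_mhz = f, nu_cp = nu_grid,
        r2eff_true = carver_richards_r2eff(
          nu_grid,
          pa = 1 - g$pb, kex = g$kex,
          dw = ppm_to_rad(row$dw_ppm, f, spin), ra = r0, quiet = TRUE
        ),
        r0 = r0
      )
    })
  })
  withr::with_seed(seed, {
    grid$r2eff <- grid$r2eff_true + stats::rnorm(nrow(grid), 0, sigma)
    grid$sigma <- sigma
  })
  if (as_intensity) {
    tt <- unname(t_relax[as.character(grid$field_mhz)])
    grid$i_ref <- 100
    grid$i_cpmg <- grid$i_ref * exp(-grid$r2eff * tt)
    grid$t_relax <- unname(tt)
  }
  truth <- dplyr::left_join(
    profile$residues[ex, c("residue", "ex_group", "dw_ppm")],
    profile$groups,
    by = c(ex_group = "group")
  )
  attr(grid, "truth") <- truth
  grid
}

#' Simulate spin-lock (R1rho) dispersion curves
#'
#' Fast-exchange forward model per exchange-group member. For 15N sites
#' the exchange-free baseline R2_0 is kappa * eta_xy computed from the
#' profile's spectral density (the RCZZ-calibrated protocol); for 13C
#' sites R2_0 is taken from the profile rates and reported as unknown
#' (`r2_0 = NA` in the output, with the true value kept in the truth
#' attribute) so fits must recover it.
#'
#' @param profile a [make_profile()] result.
#' @param spin observed nucleus.
#' @param field_mhz 1H frequency, MHz.
#' @param omega_sl spin-lock field strengths, Hz.
#' @param omega_off spin-lock offsets, Hz (recycled against `omega_sl`).
#' @param frac_sigma fractional R2eff noise (default 3 percent).
#' @param fix_r2_0 emit the known R2_0 (15N protocol) or NA (13C).
#' @param seed integer seed.
#' @return tibble: `site`, `omega_sl`, `omega_off`, `r2eff`, `sigma`,
#'   `r2_0`; attribute `truth` carries phi_ex, kex, r2_0 per site.
#' @export
simulate_r1rho <- function(profile, spin = spin_system("N15"),
                           field_mhz = 750,
                           omega_sl = c(
                             200, 400, 700, 1000, 1400, 2000, 2800, 4000
                           ),
                           omega_off = 0, frac_sigma = 0.03,
                           fix_r2_0 = TRUE, seed = 1L) {
  fc <- field_context(field_mhz, spin)
  ex <- which(!is.na(profile$residues$ex_group))
  if (!length(ex)) stop("profile has no exchange residues", call. = FALSE)
  pts <- tibble::tibble(omega_sl = omega_sl, omega_off = omega_off)
  curves <- purrr::map_dfr(ex, function(i) {
    row <- profile$residues[i, ]
    g <- profile$groups[profile$groups$group == row$ex_group, ]
    jfun <- .profile_j(profile, i)
    r2_0 <- kappa_factor(spin, fc) *
      eta_xy(spin, fc, jfun(0), jfun(fc$omega_x))
    dw <- ppm_to_rad(row$dw_ppm, fc, spin)
    phi <- (1 - g$pb) * g$pb * dw^2
    tibble::tibble(
      site = row$residue, omega_sl = pts$omega_sl, omega_off = pts$omega_off,
      r2eff_true = fast_exchange_r1rho(
        pts$omega_sl, pts$omega_off, phi, g$kex, r2_0
      ),
      r2_0 = if (fix_r2_0) r2_0 else NA_real_,
      r2_0_true = r2_0, phi_ex_true = phi, kex_true = g$kex
    )
  })
  withr::with_seed(seed, {
    curves$sigma <- frac_sigma * curves$r2eff_true
    curves$r2eff <- curves$r2eff_true + stats::rnorm(nrow(curves), 0,
      curves$sigma)
  })
  truth <- dplyr::distinct(
    curves[, c("site", "phi_ex_true", "kex_true", "r2_0_true")]
  )
  out <- curves[, c(
    "site", "omega_sl", "omega_off", "r2eff", "sigma", "r2_0", "r2eff_true"
  )]
  attr(out, "truth") <- truth
  out
}

#' Simulate RCZZ / eta_xy intensity tables
#'
#' Emits, per residue: the tanh build-up series for eta_xy, the Hahn-echo
#' intensity pair encoding R2_RCZZ = kappa eta_xy - R1/2 + Rex (the
#' inverse of the slow-exchange relation), and the R1 decay series needed
#' to complete the Rex map. Zero noise reproduces the generating rates
#' exactly through the extraction pipeline.
#'
#' @param profile a [make_profile()] result.
#' @param spin,field spin system and field.
#' @param eta_delays build-up delays T, s.
#' @param tau_total RCZZ total echo period, s.
#' @param frac_sigma fractional intensity noise.
#' @param seed integer seed.
#' @return list of tibbles `eta_series` (residue, time, ratio),
#'   `rczz` (residue, i, i_ref), `r1_series` (residue, time, intensity,
#'   replicate) and `truth` (residue, eta_xy, r1, rex, r2_rczz).
#' @export
simulate_rczz <- function(profile, spin, field,
                          eta_delays = c(0.016, 0.032, 0.040),
                          tau_total = 0.1296, frac_sigma = 0, seed = 1L) {
  kap <- kappa_factor(spin, field)
  n <- nrow(profile$residues)
  truth <- purrr::map_dfr(seq_len(n), function(i) {
    jfun <- .profile_j(profile, i)
    eta <- eta_xy(spin, field, jfun(0), jfun(field$omega_x))
    r1 <- rates_from_j(spin, field, jfun)[["R1"]]
    rex <- .profile_rex(profile, i, spin, field)
    tibble::tibble(
      residue = profile$residues$residue[i], eta_xy = eta, r1 = r1,
      rex = rex, r2_rczz = kap * eta - r1 / 2 + rex
    )
  })
  withr::with_seed(seed, {
    eta_series <- purrr::map_dfr(seq_len(n), function(i) {
      ratio <- tanh(truth$eta_xy[i] * eta_delays)
      tibble::tibble(
        residue = truth$residue[i], time = eta_delays,
        ratio = ratio * (1 + stats::rnorm(length(ratio), 0, frac_sigma))
      )
    })
    rczz <- tibble::tibble(
      residue = truth$residue,
      i = 100 * exp(-truth$r2_rczz * tau_total) *
        (1 + stats::rnorm(n, 0, frac_sigma)),
      i_ref = 100 * (1 + stats::rnorm(n, 0, frac_sigma))
    )
    r1_delays <- seq(0.08, 1.2, length.out = 8)
    r1_series <- purrr::map_dfr(seq_len(n), function(i) {
      purrr::map_dfr(1:2, function(rep) {
        tibble::tibble(
          residue = truth$residue[i], time = r1_delays,
          intensity = 100 * exp(-truth$r1[i] * r1_delays) *
            (1 + stats::rnorm(length(r1_delays), 0, frac_sigma)),
          replicate = rep
        )
      })
    })
    list(
      eta_series = eta_series, rczz = rczz, r1_series = r1_series,
      truth = truth
    )
  })
}
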
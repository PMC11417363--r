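# Two-site exchange forward models (Carver-Richards CPMG, fast-exchange
# R1rho) and dispersion fitting: per-residue, multi-field, global
# shared-kinetics and fixed-delta-omega fits, AIC comparison, Monte-Carlo
# parameter errors.

#' Convert a chemical-shift difference from ppm to rad/s
#'
#' @param dw_ppm shift difference, ppm.
#' @param field a [field_context()] built for the relevant nucleus, or a 1H
#'   frequency in MHz.
#' @param spin a [spin_system()]; needed when `field` is given in MHz.
#' @return angular frequency difference, rad/s.
#' @export
ppm_to_rad <- function(dw_ppm, field, spin = spin_system("N15")) {
  if (is.numeric(field)) field <- field_context(field, spin)
  dw_ppm * 1e-6 * field$omega_x
}

#' Carver-Richards effective CPMG relaxation rate
#'
#' General two-site exchange R2eff(nu_cp) valid in all exchange regimes:
#' R2eff = (1/2)(Ra + Rb + kex) - nu_cp * acosh\[D+ cosh(eta+) - D- cos(eta-)\]
#' with
#' D+- = (1/2)\[+-1 + (psi + 2 dw^2) / sqrt(psi^2 + xi^2)\],
#' eta+- = (1 / (sqrt(8) nu_cp)) \[+-psi + sqrt(psi^2 + xi^2)\]^(1/2),
#' psi = \[Ra - Rb + (pb - pa) kex\]^2 - dw^2 + 4 pa pb kex^2,
#' xi = 2 dw \[Ra - Rb + (pb - pa) kex\].
#' `nu_cp` is the 180-degree pulse repetition frequency (inter-pulse delay
#' 1 / (2 nu_cp)). Vectorised over `nu_cp`.
#'
#' @param nu_cp CPMG pulse repetition frequency, Hz.
#' @param pa major-state population (0 < pa < 1).
#' @param kex exchange rate ka + kb, 1/s.
#' @param dw chemical-shift difference between the sites, rad/s.
#' @param ra,rb intrinsic transverse rates of the two sites, 1/s
#'   (`rb` defaults to `ra`).
#' @param quiet suppress the warning emitted when the acosh argument must
#'   be clamped to 1.
#' @return R2eff, 1/s.
#' @examples
#' carver_richards_r2eff(c(25, 100, 750), pa = 0.99, kex = 1000,
#'   dw = ppm_to_rad(2, 750), ra = 10)
#' @export
carver_richards_r2eff <- function(nu_cp, pa, kex, dw, ra, rb = ra,
                                  quiet = FALSE) {
  stopifnot(pa > 0, pa < 1, kex > 0, all(nu_cp > 0), ra >= 0, rb >= 0)
  pb <- 1 - pa
  drk <- ra - rb + (pb - pa) * kex
  psi <- drk^2 - dw^2 + 4 * pa * pb * kex^2
  xi <- 2 * dw * drk
  root <- sqrt(psi^2 + xi^2)
  dplus <- 0.5 * (1 + (psi + 2 * dw^2) / root)
  dminus <- 0.5 * (-1 + (psi + 2 * dw^2) / root)
  etap <- sqrt(pmax(psi + root, 0) / 2) / (2 * nu_cp) # 1/(sqrt(8) nu) * sqrt(.)
  etam <- sqrt(pmax(-psi + root, 0) / 2) / (2 * nu_cp)
  # acosh argument; for large eta+ use the asymptotic log form to avoid
  # cosh overflow (the D- cos term is then negligible)
  big <- etap > 25
  lam <- numeric(length(nu_cp))
  if (any(!big)) {
    z <- dplus * cosh(etap[!big]) - dminus * cos(etam[!big])
    if (any(z < 1)) {
      if (!quiet) {
        warning("acosh argument < 1 clamped (deep slow-exchange limit)",
          call. = FALSE
        )
      }
      z <- pmax(z, 1)
    }
    lam[!big] <- acosh(z)
  }
  if (any(big)) lam[big] <- etap[big] + log(dplus) # acosh(D+ cosh x) ~ x + ln D+
  0.5 * (ra + rb + kex) - nu_cp * lam
}

#' Luz-Meiboom fast-exchange CPMG model
#'
#' R2eff = R0 + (phi_ex / kex) \[1 - (4 nu_cp / kex) tanh(kex / (4 nu_cp))\],
#' the fast-exchange limit of the general two-site model, with
#' phi_ex = pa pb dw^2 (rad^2/s^2).
#'
#' @inheritParams carver_richards_r2eff
#' @param phi_ex pa pb dw^2, rad^2/s^2.
#' @param r0 exchange-free transverse rate, 1/s.
#' @return R2eff, 1/s.
#' @export
fast_exchange_cpmg <- function(nu_cp, phi_ex, kex, r0) {
  stopifnot(kex > 0, all(nu_cp > 0))
  x <- kex / (4 * nu_cp)
  r0 + (phi_ex / kex) * (1 - tanh(x) / x)
}

#' Fast-exchange spin-lock (R1rho) dispersion model
#'
#' R2eff = R2_0 + phi_ex kex / (omega_SL^2 + omega_off^2 + kex^2) with
#' phi_ex = pa pb dw^2. Spin-lock field and offset are supplied in Hz and
#' converted to angular units internally (the denominator mixes them with
#' kex additively). Depends on the spin-lock geometry only through the
#' effective field omega_SL^2 + omega_off^2.
#'
#' @param omega_sl spin-lock field strength, Hz.
#' @param omega_off spin-lock offset, Hz.
#' @param phi_ex pa pb dw^2, rad^2/s^2.
#' @param kex exchange rate, 1/s.
#' @param r2_0 exchange-free transverse rate, 1/s.
#' @return R2eff, 1/s.
#' @examples
#' fast_exchange_r1rho(1400, 0, phi_ex = 5e4, kex = 7000, r2_0 = 14)
#' @export
fast_exchange_r1rho <- function(omega_sl, omega_off, phi_ex, kex, r2_0) {
  stopifnot(kex > 0)
  weff2 <- (2 * pi * omega_sl)^2 + (2 * pi * omega_off)^2
  r2_0 + phi_ex * kex / (weff2 + kex^2)
}

# ---------------------------------------------------------------------------
# CPMG fitting

#' Chi-square of a CPMG parameter set against one or more curves
#' @noRd
.cpmg_chi2 <- function(data, pa, kex, dw_ppm, r0_by_field, spin) {
  ch <- 0
  for (f in names(r0_by_field)) {
    rows <- data$field_mhz == as.numeric(f)
    dw <- ppm_to_rad(dw_ppm, as.numeric(f), spin)
    pred <- carver_richards_r2eff(data$nu_cp[rows], pa, kex, dw,
      ra = r0_by_field[[f]], quiet = TRUE
    )
    ch <- ch + sum(((data$r2eff[rows] - pred) / data$sigma[rows])^2)
  }
  ch
}

#' Parameter transforms: unconstrained <-> natural scale. kex is bounded
#' to [1e2, 1e5] 1/s, the window a constant-time CPMG experiment is
#' sensitive to; slower exchange drives the Carver-Richards expression
#' into its oscillatory slow-exchange regime where it chases point noise.
#' @noRd
.kex_from_q <- function(q) 10^(2 + 3 * stats::plogis(q))
.q_from_kex <- function(kex) {
  stats::qlogis(pmin(pmax((log10(kex) - 2) / 3, 1e-3), 1 - 1e-3))
}

.cpmg_untransform <- function(p, dw_max = 10) {
  list(
    kex = .kex_from_q(p[["qkex"]]),
    pb = 0.5 * stats::plogis(p[["qpb"]]),
    dw_ppm = dw_max * stats::plogis(p[["qdw"]])
  )
}

# shift differences are bounded to (0, dw_max] ppm: amide 15N (and ribose
# 13C) shift changes between conformers do not plausibly exceed ~10 ppm,
# and an unbounded dw lets slow-exchange solutions mimic fast-exchange
# curves with absurd shift differences
.q_from_dw <- function(dw, dw_max = 10) {
  stats::qlogis(pmin(pmax(dw / dw_max, 1e-3), 1 - 1e-3))
}

#' Fit one residue's CPMG dispersion (one or two fields)
#'
#' Weighted least-squares fit of either the general two-site
#' Carver-Richards model (`model = "general"`: parameters pb, kex, dw with
#' dw stored in ppm and scaled per field, plus one intrinsic rate per field
#' with Ra = Rb) or the Luz-Meiboom fast-exchange model (`model = "fast"`:
#' phi_ex in ppm^2, kex, per-field R0). A multi-start grid over kex, pb and
#' dw guards against the multimodal chi-square surface; `fixed_dw` clamps
#' the shift difference (used when weak dispersions cannot constrain dw).
#'
#' @param data tibble with columns `field_mhz`, `nu_cp` (Hz), `r2eff`
#'   (1/s), `sigma` (1/s); rows with `NA` r2eff are dropped.
#' @param model `"general"` or `"fast"`.
#' @param fixed_dw optional shift difference in ppm to clamp (general model).
#' @param spin the [spin_system()] of the observed nucleus.
#' @param starts optional list overriding the start grid
#'   (`kex`, `pb`, `dw`).
#' @param dw_max upper bound of the fitted shift difference, ppm.
#' @return a `cpmg_fit` object; see [tidy.cpmg_fit()] / [glance.cpmg_fit()].
#' @export
fit_cpmg <- function(data, model = c("general", "fast"), fixed_dw = NULL,
                     spin = spin_system("N15"), starts = NULL, dw_max = 10) {
  model <- match.arg(model)
  data <- dplyr::filter(tibble::as_tibble(data), !is.na(.data$r2eff))
  stopifnot(all(c("field_mhz", "nu_cp", "r2eff", "sigma") %in% names(data)))
  if (nrow(data) < 6) stop("need >= 6 dispersion points", call. = FALSE)
  fields <- sort(unique(data$field_mhz))
  r0_init <- vapply(fields, function(f) {
    rows <- data$field_mhz == f
    min(stats::quantile(data$r2eff[rows], 0.25), data$r2eff[rows][
      which.max(data$nu_cp[rows])
    ])
  }, numeric(1))
  names(r0_init) <- as.character(fields)

  if (model == "fast") {
    fit <- .fit_cpmg_fast(data, fields, r0_init, spin)
  } else {
    fit <- .fit_cpmg_general(data, fields, r0_init, spin, fixed_dw, starts,
      dw_max)
  }
  fit$data <- data
  fit$model <- model
  fit$spin <- spin
  fit$dw_max <- dw_max
  fit$aic <- fit$chi2 + 2 * fit$n_params
  class(fit) <- "cpmg_fit"
  fit
}

#' @noRd
.fit_cpmg_general <- function(data, fields, r0_init, spin, fixed_dw, starts,
                              dw_max = 10) {
  free_dw <- is.null(fixed_dw)
  grid <- starts %||% list(
    kex = 10^seq(2, 5, length.out = 4),
    pb = c(0.003, 0.03, 0.2),
    dw = if (free_dw) c(0.5, 1.5, 3) else fixed_dw
  )
  resid_fn <- function(p) {
    nat <- .cpmg_untransform(p, dw_max)
    dwp <- if (free_dw) nat$dw_ppm else fixed_dw
    unlist(lapply(fields, function(f) {
      rows <- data$field_mhz == f
      pred <- carver_richards_r2eff(
        data$nu_cp[rows],
        pa = 1 - nat$pb, kex = nat$kex,
        dw = ppm_to_rad(dwp, f, spin),
        ra = p[[paste0("r0_", f)]], quiet = TRUE
      )
      (data$r2eff[rows] - pred) / data$sigma[rows]
    }))
  }
  best <- NULL
  for (k0 in grid$kex) for (p0 in grid$pb) for (d0 in grid$dw) {
    par0 <- c(
      qkex = .q_from_kex(k0), qpb = stats::qlogis(min(p0 / 0.5, 0.999)),
      qdw = .q_from_dw(d0, dw_max)
    )
    for (f in fields) par0[[paste0("r0_", f)]] <- max(r0_init[[as.character(f)]], 0.5)
    res <- try(minpack.lm::nls.lm(
      par = as.list(par0), fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 150, ptol = 1e-10)
    ), silent = TRUE)
    if (inherits(res, "try-error")) next
    ch <- sum(res$fvec^2)
    if (is.null(best) || ch < best$chi2 - 1e-12) {
      best <- list(res = res, chi2 = ch)
    }
  }
  if (is.null(best)) {
    return(list(
      params = tibble::tibble(), chi2 = Inf, n_points = nrow(data),
      n_params = 0, converged = FALSE
    ))
  }
  p <- best$res$par
  nat <- .cpmg_untransform(unlist(p), dw_max)
  r0s <- vapply(fields, function(f) p[[paste0("r0_", f)]], numeric(1))
  params <- tibble::tibble(
    term = c("kex", "pb", "dw_ppm", paste0("r0_", fields)),
    estimate = c(nat$kex, nat$pb, if (free_dw) nat$dw_ppm else fixed_dw, r0s),
    fixed = c(FALSE, FALSE, !free_dw, rep(FALSE, length(fields)))
  )
  list(
    params = params, chi2 = best$chi2, n_points = nrow(data),
    n_params = 2 + free_dw + length(fields), converged = TRUE,
    fixed_dw = fixed_dw, fields = fields
  )
}

#' Fast (Luz-Meiboom) CPMG fit: phi_ex in ppm^2 shared across fields
#' @noRd
.fit_cpmg_fast <- function(data, fields, r0_init, spin) {
  resid_fn <- function(p) {
    kex <- .kex_from_q(p[["qkex"]])
    unlist(lapply(fields, function(f) {
      rows <- data$field_mhz == f
      phi <- exp(p[["lphi"]]) * ppm_to_rad(1, f, spin)^2 # ppm^2 -> rad^2/s^2
      pred <- fast_exchange_cpmg(
        data$nu_cp[rows], phi, kex,
        r0 = p[[paste0("r0_", f)]]
      )
      (data$r2eff[rows] - pred) / data$sigma[rows]
    }))
  }
  best <- NULL
  for (k0 in 10^seq(2.5, 4.5, length.out = 4)) for (ph0 in c(0.01, 0.1, 1)) {
    par0 <- list(qkex = .q_from_kex(k0), lphi = log(ph0))
    for (f in fields) par0[[paste0("r0_", f)]] <- max(r0_init[[as.character(f)]], 0.5)
    res <- try(minpack.lm::nls.lm(
      par = par0, fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 150)
    ), silent = TRUE)
    if (inherits(res, "try-error")) next
    ch <- sum(res$fvec^2)
    if (is.null(best) || ch < best$chi2 - 1e-12) best <- list(res = res, chi2 = ch)
  }
  if (is.null(best)) {
    return(list(
      params = tibble::tibble(), chi2 = Inf, n_points = nrow(data),
      n_params = 0, converged = FALSE
    ))
  }
  p <- best$res$par
  r0s <- vapply(fields, function(f) p[[paste0("r0_", f)]], numeric(1))
  params <- tibble::tibble(
    term = c("kex", "phi_ex_ppm2", paste0("r0_", fields)),
    estimate = c(.kex_from_q(p$qkex), exp(p$lphi), r0s),
    fixed = FALSE
  )
  list(
    params = params, chi2 = best$chi2, n_points = nrow(data),
    n_params = 2 + length(fields), converged = TRUE, fields = fields
  )
}

#' Predicted dispersion curve from a cpmg_fit
#' @noRd
.cpmg_predict <- function(fit, newdata) {
  est <- function(term) fit$params$estimate[fit$params$term == term]
  vapply(seq_len(nrow(newdata)), function(i) {
    f <- newdata$field_mhz[i]
    if (fit$model == "general") {
      carver_richards_r2eff(newdata$nu_cp[i],
        pa = 1 - est("pb"), kex = est("kex"),
        dw = ppm_to_rad(est("dw_ppm"), f, fit$spin),
        ra = est(paste0("r0_", f)), quiet = TRUE
      )
    } else {
      fast_exchange_cpmg(newdata$nu_cp[i],
        phi_ex = est("phi_ex_ppm2") * ppm_to_rad(1, f, fit$spin)^2,
        kex = est("kex"), r0 = est(paste0("r0_", f))
      )
    }
  }, numeric(1))
}

#' Global CPMG fit with shared kinetics across residues
#'
#' Fits all residues' dispersion curves simultaneously with shared
#' exchange parameters (`shared = c("kex", "pb")` or `"kex"` only), one
#' shift difference per residue (ppm; scaled per field) and one intrinsic
#' rate per residue per field (Ra = Rb). Individual per-residue fits are
#' run first (also providing the initial values), and the per-residue
#' ratio chi2_global/chi2_individual is reported; residues exceeding
#' `ratio_cutoff` (default 2.0) are flagged, excluded, and the global fit
#' rerun once.
#'
#' @param data tibble with columns `residue`, `field_mhz`, `nu_cp`,
#'   `r2eff`, `sigma`.
#' @param shared character vector of shared kinetic parameters.
#' @param fixed_dw optional named numeric vector (names = residues) of
#'   clamped shift differences, ppm.
#' @param ratio_cutoff chi2_g/chi2_i exclusion threshold.
#' @param spin the observed nucleus.
#' @param dw_max upper bound of fitted shift differences, ppm.
#' @return a `cpmg_global_fit` object with elements `params` (shared),
#'   `per_residue` (dw, r0s, chi2 ratios, flags), `chi2`, `aic`,
#'   `excluded`.
#' @export
fit_cpmg_global <- function(data, shared = c("kex", "pb"), fixed_dw = NULL,
                            ratio_cutoff = 2.0, spin = spin_system("N15"),
                            dw_max = 10) {
  data <- dplyr::filter(tibble::as_tibble(data), !is.na(.data$r2eff))
  stopifnot(all(c("residue", "field_mhz", "nu_cp", "r2eff", "sigma")
  %in% names(data)))
  residues <- unique(data$residue)
  if (length(residues) < 2) {
    stop("global fit needs >= 2 residues; use fit_cpmg() for one",
      call. = FALSE
    )
  }
  indiv <- lapply(residues, function(r) {
    fit_cpmg(data[data$residue == r, ],
      model = "general",
      fixed_dw = unname(fixed_dw[as.character(r)]), spin = spin,
      dw_max = dw_max
    )
  })
  names(indiv) <- as.character(residues)
  keep <- residues
  for (pass in 1:2) {
    g <- .fit_cpmg_global_once(
      data[data$residue %in% keep, ], indiv[as.character(keep)],
      shared, fixed_dw, spin, dw_max
    )
    ratios <- g$per_residue$chi2_ratio
    bad <- g$per_residue$residue[!is.na(ratios) & ratios > ratio_cutoff]
    if (length(bad) == 0 || length(keep) - length(bad) < 2) break
    keep <- setdiff(keep, bad)
  }
  g$excluded <- setdiff(residues, keep)
  g$individual <- indiv
  g$data <- data
  g$spin <- spin
  g$shared <- shared
  g$fixed_dw <- fixed_dw
  g$ratio_cutoff <- ratio_cutoff
  g$aic <- g$chi2 + 2 * g$n_params
  class(g) <- "cpmg_global_fit"
  g
}

#' @noRd
.fit_cpmg_global_once <- function(data, indiv, shared, fixed_dw, spin,
                                  dw_max = 10) {
  residues <- unique(data$residue)
  fields <- sort(unique(data$field_mhz))
  share_pb <- "pb" %in% shared
  est0 <- function(fit, term, default) {
    if (!fit$converged) return(default)
    v <- fit$params$estimate[fit$params$term == term]
    if (length(v)) v else default
  }
  kex0 <- stats::median(vapply(indiv, est0, numeric(1), term = "kex", default = 1000))
  pb0 <- stats::median(vapply(indiv, est0, numeric(1), term = "pb", default = 0.01))
  par0 <- list(qkex = .q_from_kex(kex0))
  if (share_pb) par0$qpb <- stats::qlogis(min(pb0 / 0.5, 0.999))
  for (r in residues) {
    rc <- as.character(r)
    fx <- unname(fixed_dw[rc])
    if (is.null(fx) || is.na(fx)) {
      par0[[paste0("qdw_", rc)]] <-
        .q_from_dw(max(est0(indiv[[rc]], "dw_ppm", 1.5), 0.05), dw_max)
    }
    if (!share_pb) {
      par0[[paste0("qpb_", rc)]] <-
        stats::qlogis(min(est0(indiv[[rc]], "pb", 0.01) / 0.5, 0.999))
    }
    for (f in fields) {
      par0[[paste0("r0_", rc, "_", f)]] <-
        est0(indiv[[rc]], paste0("r0_", f),
          default = stats::median(data$r2eff[data$residue == r &
            data$field_mhz == f]))
    }
  }
  resid_fn <- function(p) {
    kex <- .kex_from_q(p[["qkex"]])
    unlist(lapply(residues, function(r) {
      rc <- as.character(r)
      fx <- unname(fixed_dw[rc])
      dwp <- if (is.null(fx) || is.na(fx)) {
        dw_max * stats::plogis(p[[paste0("qdw_", rc)]])
      } else {
        fx
      }
      pb <- if (share_pb) {
        0.5 * stats::plogis(p[["qpb"]])
      } else {
        0.5 * stats::plogis(p[[paste0("qpb_", rc)]])
      }
      unlist(lapply(fields, function(f) {
        rows <- data$residue == r & data$field_mhz == f
        if (!any(rows)) return(numeric(0))
        pred <- carver_richards_r2eff(data$nu_cp[rows],
          pa = 1 - pb,
          kex = kex, dw = ppm_to_rad(dwp, f, spin),
          ra = p[[paste0("r0_", rc, "_", f)]], quiet = TRUE
        )
        (data$r2eff[rows] - pred) / data$sigma[rows]
      }))
    }))
  }
  # multi-start around the individual-fit consensus plus a coarse kex grid
  best <- NULL
  for (qk in unique(c(.q_from_kex(kex0), .q_from_kex(c(300, 1000, 5000, 2e4))))) {
    p0 <- par0
    p0$qkex <- qk
    res <- try(minpack.lm::nls.lm(
      par = p0, fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 200, ptol = 1e-10)
    ), silent = TRUE)
    if (inherits(res, "try-error")) next
    ch <- sum(res$fvec^2)
    if (is.null(best) || ch < best$chi2 - 1e-12) best <- list(res = res, chi2 = ch)
  }
  if (is.null(best)) stop("global CPMG fit failed to converge", call. = FALSE)
  p <- best$res$par
  kex <- .kex_from_q(p$qkex)
  pb_sh <- if (share_pb) 0.5 * stats::plogis(p$qpb) else NA_real_
  per_res <- purrr::map_dfr(residues, function(r) {
    rc <- as.character(r)
    fx <- unname(fixed_dw[rc])
    dwp <- if (is.null(fx) || is.na(fx)) {
      dw_max * stats::plogis(p[[paste0("qdw_", rc)]])
    } else {
      fx
    }
    pb <- if (share_pb) pb_sh else 0.5 * stats::plogis(p[[paste0("qpb_", rc)]])
    r0s <- vapply(fields, function(f) p[[paste0("r0_", rc, "_", f)]], numeric(1))
    rows <- data$residue == r
    chg <- sum(vapply(fields, function(f) {
      rr <- rows & data$field_mhz == f
      if (!any(rr)) return(0)
      pred <- carver_richards_r2eff(data$nu_cp[rr],
        pa = 1 - pb, kex = kex,
        dw = ppm_to_rad(dwp, f, spin), ra = p[[paste0("r0_", rc, "_", f)]],
        quiet = TRUE
      )
      sum(((data$r2eff[rr] - pred) / data$sigma[rr])^2)
    }, numeric(1)))
    chi <- indiv[[rc]]$chi2
    tibble::tibble(
      residue = r, dw_ppm = dwp, pb = pb,
      !!!stats::setNames(as.list(r0s), paste0("r0_", fields)),
      chi2_global = chg, chi2_indiv = chi,
      chi2_ratio = ifelse(chi > 0, chg / chi, NA_real_)
    )
  })
  params <- tibble::tibble(
    term = c("kex", if (share_pb) "pb"),
    estimate = c(kex, if (share_pb) pb_sh)
  )
  n_par <- 1 + share_pb +
    sum(vapply(residues, function(r) {
      fx <- unname(fixed_dw[as.character(r)])
      (is.null(fx) || is.na(fx)) + (!share_pb) + length(fields)
    }, numeric(1)))
  list(
    params = params, per_residue = per_res, chi2 = best$chi2,
    n_points = nrow(data), n_params = n_par, converged = TRUE,
    fields = fields
  )
}

# ---------------------------------------------------------------------------
# R1rho fitting

#' Fit fast-exchange R1rho dispersion (per-site and global)
#'
#' For a fixed exchange rate the model R2eff = R2_0 + phi_ex kex /
#' (omega_eff^2 + kex^2) is linear in phi_ex (and in R2_0 when fitted), so
#' each site's amplitude parameters are profiled out by weighted linear
#' least squares and kex is optimised on a log grid by 1-D minimisation.
#' Sites with a supplied `r2_0` column (15N protocol: R2_0 fixed to
#' kappa eta_xy) fit phi_ex only; sites with `r2_0 = NA` (13C protocol)
#' fit R2_0 too. With `global_kex = TRUE` a single kex is shared across
#' all sites (mixed nuclei allowed; the nucleus enters only through unit
#' conversions upstream). Per-site individual fits provide
#' chi2_global/chi2_individual.
#'
#' @param data tibble with columns `site`, `omega_sl` (Hz), `omega_off`
#'   (Hz), `r2eff`, `sigma`, and `r2_0` (fixed value, or NA to fit).
#' @param global_kex share one kex across sites?
#' @param kex_range log10 search interval for kex (1/s).
#' @return an `r1rho_fit` object.
#' @export
fit_r1rho <- function(data, global_kex = TRUE, kex_range = c(2, 5.5)) {
  data <- tibble::as_tibble(data)
  stopifnot(all(c("site", "omega_sl", "omega_off", "r2eff", "sigma")
  %in% names(data)))
  if (!"r2_0" %in% names(data)) data$r2_0 <- NA_real_
  data$weff2 <- (2 * pi * data$omega_sl)^2 + (2 * pi * data$omega_off)^2
  sites <- unique(data$site)

  site_fit <- function(rows, kex) {
    # profile linear params for fixed kex; returns chi2 + estimates
    x <- kex / (rows$weff2 + kex^2)
    w <- 1 / rows$sigma^2
    if (all(is.na(rows$r2_0))) {
      X <- cbind(1, x)
      cf <- tryCatch(
        solve(crossprod(X * sqrt(w)), crossprod(X * sqrt(w), rows$r2eff * sqrt(w))),
        error = function(e) NULL
      )
      if (is.null(cf)) return(list(chi2 = Inf))
      r2_0 <- cf[1]
      phi <- max(cf[2], 0)
      if (cf[2] < 0) { # refit with phi pinned at 0
        r2_0 <- sum(w * rows$r2eff) / sum(w)
      }
      pred <- r2_0 + phi * x
      list(chi2 = sum(w * (rows$r2eff - pred)^2), phi = phi, r2_0 = r2_0,
           fit_r2_0 = TRUE)
    } else {
      y <- rows$r2eff - rows$r2_0
      phi <- max(sum(w * x * y) / sum(w * x^2), 0)
      pred <- rows$r2_0 + phi * x
      list(chi2 = sum(w * (rows$r2eff - pred)^2), phi = phi,
           r2_0 = rows$r2_0[1], fit_r2_0 = FALSE)
    }
  }
  total_chi2 <- function(kex, dat, site_list) {
    ch <- sum(vapply(site_list, function(s) {
      site_fit(dat[dat$site == s, ], kex)$chi2
    }, numeric(1)))
    if (!is.finite(ch)) 1e30 else ch
  }
  optimise_kex <- function(dat, site_list) {
    opt <- stats::optimize(function(lk) total_chi2(10^lk, dat, site_list),
      interval = kex_range, tol = 1e-6
    )
    10^opt$minimum
  }

  indiv <- purrr::map_dfr(sites, function(s) {
    rows <- data[data$site == s, ]
    kex_i <- optimise_kex(rows, s)
    sf <- site_fit(rows, kex_i)
    # dispersion amplitude resolved across the measured effective-field
    # window; below the noise it means phi_ex/kex are unidentifiable
    amp <- sf$phi * kex_i *
      (1 / (min(rows$weff2) + kex_i^2) - 1 / (max(rows$weff2) + kex_i^2))
    tibble::tibble(
      site = s, kex = kex_i, phi_ex = sf$phi, r2_0 = sf$r2_0,
      chi2 = sf$chi2, n = nrow(rows),
      flagged = sf$phi == 0 || amp < 2 * stats::median(rows$sigma)
    )
  })

  if (global_kex) {
    kex_g <- optimise_kex(data, sites)
    per_site <- purrr::map_dfr(sites, function(s) {
      sf <- site_fit(data[data$site == s, ], kex_g)
      chi_i <- indiv$chi2[indiv$site == s]
      tibble::tibble(
        site = s, phi_ex = sf$phi, r2_0 = sf$r2_0, chi2_global = sf$chi2,
        chi2_indiv = chi_i,
        chi2_ratio = ifelse(chi_i > 0, sf$chi2 / chi_i, NA_real_),
        flagged = indiv$flagged[indiv$site == s]
      )
    })
    chi2 <- sum(per_site$chi2_global)
    n_par <- 1 + sum(ifelse(is.na(data$r2_0[!duplicated(data$site)]), 2, 1))
  } else {
    kex_g <- NA_real_
    per_site <- indiv
    chi2 <- sum(indiv$chi2)
    n_par <- sum(ifelse(is.na(data$r2_0[!duplicated(data$site)]), 3, 2))
  }
  structure(
    list(
      kex = kex_g, per_site = per_site, individual = indiv, chi2 = chi2,
      n_points = nrow(data), n_params = n_par, aic = chi2 + 2 * n_par,
      global = global_kex, data = data, kex_range = kex_range,
      converged = TRUE
    ),
    class = "r1rho_fit"
  )
}

# ---------------------------------------------------------------------------
# Model comparison and Monte-Carlo errors

#' Akaike comparison of dispersion fits
#'
#' AIC = chi^2 + 2 n_params (measurement errors treated as known). Fits
#' must be on the same data; lower AIC is preferred.
#'
#' @param ... fit objects (or a single list of them), each with `chi2`,
#'   `n_params` and `n_points`.
#' @param labels optional model labels.
#' @param corrected use the small-sample AICc variant.
#' @return tibble ranked by AIC with `delta_aic` relative to the best.
#' @export
aic_compare <- function(..., labels = NULL, corrected = FALSE) {
  fits <- list(...)
  if (length(fits) == 1 && is.list(fits[[1]]) && is.null(fits[[1]]$chi2)) {
    fits <- fits[[1]]
  }
  npts <- vapply(fits, function(f) f$n_points, numeric(1))
  if (length(unique(npts)) != 1) {
    stop("fits compare different data (n_points differ)", call. = FALSE)
  }
  aic <- vapply(fits, function(f) {
    a <- f$chi2 + 2 * f$n_params
    if (corrected) {
      a <- a + 2 * f$n_params * (f$n_params + 1) /
        max(f$n_points - f$n_params - 1, 1)
    }
    a
  }, numeric(1))
  out <- tibble::tibble(
    model = labels %||% vapply(fits, function(f) {
      paste0(class(f)[1], "/", f$model %||% "")
    }, character(1)),
    chi2 = vapply(fits, function(f) f$chi2, numeric(1)),
    n_params = vapply(fits, function(f) f$n_params, numeric(1)),
    aic = aic
  )
  out <- dplyr::arrange(out, .data$aic)
  out$delta_aic <- out$aic - out$aic[1]
  out
}

#' Monte-Carlo parameter uncertainties for a dispersion fit
#'
#' Refits `n_draws` synthetic datasets built by perturbing the fitted
#' curve with Gaussian noise at the per-point sigma; parameter
#' uncertainties are the standard deviations over draws. Seeded and
#' reproducible.
#'
#' @param fit a `cpmg_fit`, `cpmg_global_fit` or `r1rho_fit`.
#' @param n_draws number of synthetic datasets.
#' @param seed RNG seed.
#' @return tibble with `term`, `estimate`, `mc_error`; attribute
#'   `n_failed` counts non-convergent draws (flagged above 20%).
#' @export
mc_parameter_errors <- function(fit, n_draws = 100, seed = 1L) {
  UseMethod("mc_parameter_errors")
}

#' @export
mc_parameter_errors.cpmg_fit <- function(fit, n_draws = 100, seed = 1L) {
  pred <- .cpmg_predict(fit, fit$data)
  draws <- withr::with_seed(seed, lapply(seq_len(n_draws), function(i) {
    d <- fit$data
    d$r2eff <- pred + stats::rnorm(nrow(d), 0, d$sigma)
    f <- try(
      fit_cpmg(d,
        model = fit$model, fixed_dw = fit$fixed_dw, spin = fit$spin,
        starts = list(
          kex = fit$params$estimate[fit$params$term == "kex"],
          pb = max(fit$params$estimate[fit$params$term == "pb"], 1e-4),
          dw = if (is.null(fit$fixed_dw)) {
            fit$params$estimate[fit$params$term == "dw_ppm"]
          } else {
            fit$fixed_dw
          }
        )
      ),
      silent = TRUE
    )
    if (inherits(f, "try-error") || !f$converged) NULL else f$params$estimate
  }))
  .mc_summarise(fit$params, draws, n_draws)
}

#' @export
mc_parameter_errors.r1rho_fit <- function(fit, n_draws = 100, seed = 1L) {
  est <- fit$per_site
  pred <- vapply(seq_len(nrow(fit$data)), function(i) {
    row <- fit$data[i, ]
    e <- est[est$site == row$site, ]
    e$r2_0 + e$phi_ex * fit$kex / (row$weff2 + fit$kex^2)
  }, numeric(1))
  params <- tibble::tibble(
    term = c("kex", paste0("phi_ex_", est$site)),
    estimate = c(fit$kex, est$phi_ex)
  )
  draws <- withr::with_seed(seed, lapply(seq_len(n_draws), function(i) {
    d <- fit$data
    d$r2eff <- pred + stats::rnorm(nrow(d), 0, d$sigma)
    f <- try(fit_r1rho(d, global_kex = fit$global, kex_range = fit$kex_range),
      silent = TRUE
    )
    if (inherits(f, "try-error")) NULL else c(f$kex, f$per_site$phi_ex)
  }))
  .mc_summarise(params, draws, n_draws)
}

#' @noRd
.mc_summarise <- function(params, draws, n_draws) {
  ok <- !vapply(draws, is.null, logical(1))
  n_failed <- sum(!ok)
  if (n_failed > 0.2 * n_draws) {
    warning(sprintf(
      "%d/%d Monte-Carlo draws failed to converge", n_failed, n_draws
    ), call. = FALSE)
  }
  mat <- do.call(cbind, draws[ok])
  out <- params
  out$mc_error <- apply(mat, 1, stats::sd)
  attr(out, "n_failed") <- n_failed
  out
}
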
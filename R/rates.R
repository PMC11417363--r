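# Reduction of raw peak-intensity series to relaxation rates and exchange
# maps: monoexponential fits, tilted-frame R2, heteronuclear NOE, eta_xy
# tanh fits, RCZZ R2 and the slow-exchange map Rex.

#' Fit a monoexponential intensity decay
#'
#' Least-squares fit of I(t) = I0 exp(-R t) to one residue's decay series.
#' When at least two replicate measurements exist per delay, the intensity
#' noise is pooled from replicate differences (sd of paired differences /
#' sqrt(2)); otherwise a user-supplied `noise_sigma` (or the fit residual
#' sd) is used. Rate uncertainty comes from the linearised covariance by
#' default, or from seeded Monte-Carlo resampling.
#'
#' @param data a data frame with columns `time` (s) and `intensity`;
#'   an optional `replicate` column marks repeat measurements.
#' @param noise_sigma optional intensity noise (same units as `intensity`).
#' @param error one of `"covariance"` or `"monte_carlo"`.
#' @param n_mc Monte-Carlo draws when `error = "monte_carlo"`.
#' @param seed RNG seed for the Monte-Carlo error.
#' @return one-row tibble: `rate` (1/s), `rate_err`, `i0`, `i0_err`,
#'   `noise_sigma`, `converged`.
#' @examples
#' d <- tibble::tibble(time = c(0, 0.5, 1), intensity = 100 * exp(-1.5 * time))
#' fit_monoexponential(d)
#' @export
fit_monoexponential <- function(data, noise_sigma = NULL,
                                error = c("covariance", "monte_carlo"),
                                n_mc = 500, seed = 1L) {
  error <- match.arg(error)
  stopifnot(all(c("time", "intensity") %in% names(data)))
  t <- data$time
  y <- data$intensity
  if (length(unique(t)) < 2) stop("all delays identical", call. = FALSE)
  if (length(unique(t)) < 3 && length(t) > 2) {
    stop("need >= 3 distinct delays for a decay fit", call. = FALSE)
  }
  if (is.null(noise_sigma) && "replicate" %in% names(data)) {
    noise_sigma <- .pooled_replicate_sigma(t, y, data$replicate)
  }
  fit <- .monoexp_ls(t, y)
  if (!fit$converged) {
    return(tibble::tibble(
      rate = fit$rate, rate_err = NA_real_, i0 = fit$i0, i0_err = NA_real_,
      noise_sigma = noise_sigma %||% NA_real_, converged = FALSE
    ))
  }
  resid_sd <- sqrt(sum((y - fit$i0 * exp(-fit$rate * t))^2) /
    max(1, length(t) - 2))
  sig <- noise_sigma %||% resid_sd
  if (error == "covariance") {
    errs <- .monoexp_cov_errors(t, fit$rate, fit$i0, sig)
  } else {
    errs <- .monoexp_mc_errors(t, fit$rate, fit$i0, sig, n_mc, seed)
  }
  tibble::tibble(
    rate = fit$rate, rate_err = errs["rate"], i0 = fit$i0,
    i0_err = errs["i0"], noise_sigma = sig, converged = TRUE
  )
}

#' @noRd
.pooled_replicate_sigma <- function(t, y, rep) {
  diffs <- unlist(lapply(split(seq_along(y), t), function(idx) {
    if (length(idx) >= 2) diff(y[idx][order(rep[idx])])[1] else NULL
  }))
  if (length(diffs) >= 2) stats::sd(diffs) / sqrt(2) else NULL
}

#' Gauss-Newton monoexponential LS with log-linear start
#' @noRd
.monoexp_ls <- function(t, y) {
  pos <- y > 0
  if (sum(pos) >= 2) {
    cf <- stats::lm.fit(cbind(1, t[pos]), log(y[pos]))$coefficients
    start <- c(i0 = exp(cf[[1]]), rate = max(1e-6, -cf[[2]]))
  } else {
    start <- c(i0 = max(abs(y)), rate = 1)
  }
  res <- try(
    minpack.lm::nls.lm(
      par = list(li0 = log(start[["i0"]]), rate = start[["rate"]]),
      fn = function(p) y - exp(p$li0) * exp(-p$rate * t),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    silent = TRUE
  )
  if (inherits(res, "try-error") || res$info %in% c(0, 5)) {
    return(list(rate = unname(start[["rate"]]), i0 = unname(start[["i0"]]),
                converged = FALSE))
  }
  list(rate = res$par$rate, i0 = exp(res$par$li0), converged = TRUE)
}

#' @noRd
.monoexp_cov_errors <- function(t, rate, i0, sigma) {
  jac <- cbind(exp(-rate * t), -i0 * t * exp(-rate * t)) # d/d(i0), d/d(rate)
  cov <- try(sigma^2 * solve(crossprod(jac)), silent = TRUE)
  if (inherits(cov, "try-error")) {
    return(c(i0 = NA_real_, rate = NA_real_))
  }
  c(i0 = sqrt(cov[1, 1]), rate = sqrt(cov[2, 2]))
}

#' @noRd
.monoexp_mc_errors <- function(t, rate, i0, sigma, n_mc, seed) {
  yhat <- i0 * exp(-rate * t)
  draws <- withr::with_seed(seed, {
    vapply(seq_len(n_mc), function(i) {
      f <- .monoexp_ls(t, yhat + stats::rnorm(length(t), 0, sigma))
      c(f$i0, f$rate)
    }, numeric(2))
  })
  c(i0 = stats::sd(draws[1, ]), rate = stats::sd(draws[2, ]))
}

#' Fit decay rates for a whole intensity table
#'
#' Maps [fit_monoexponential()] over residues of a tidy intensity table.
#'
#' @param data a data frame with columns `residue`, `time`, `intensity`
#'   and optionally `replicate`.
#' @param ... passed to [fit_monoexponential()].
#' @return tibble with one row per residue.
#' @export
fit_decay_rates <- function(data, ...) {
  stopifnot(all(c("residue", "time", "intensity") %in% names(data)))
  data |>
    dplyr::group_by(.data$residue) |>
    dplyr::group_modify(~ fit_monoexponential(.x, ...)) |>
    dplyr::ungroup()
}

#' Transverse rate from a tilted-frame R1rho measurement
#'
#' R2 = (R1rho - R1 cos^2 theta) / sin^2 theta with tilt angle
#' theta = arctan(omega_SL / omega_off); on resonance (omega_off = 0)
#' theta = 90 degrees and R2 = R1rho. Vectorised.
#'
#' @param r1rho rotating-frame rate, 1/s.
#' @param r1 longitudinal rate, 1/s.
#' @param omega_sl spin-lock field strength, Hz.
#' @param omega_off spin-lock offset, Hz.
#' @param min_sin2 smallest tolerated sin^2(theta); smaller tilts (far
#'   off-resonance) are an error.
#' @return R2, 1/s.
#' @examples
#' r2_from_r1rho(10, 1.5, omega_sl = 1732, omega_off = 1000) # theta = 60 deg
#' @export
r2_from_r1rho <- function(r1rho, r1, omega_sl, omega_off = 0,
                          min_sin2 = 0.05) {
  if (any(omega_sl <= 0)) stop("omega_sl must be positive", call. = FALSE)
  theta <- atan2(omega_sl, omega_off)
  s2t <- sin(theta)^2
  if (any(s2t < min_sin2)) {
    stop("tilt angle too far off-resonance (sin^2 theta < min_sin2)",
      call. = FALSE
    )
  }
  (r1rho - r1 * cos(theta)^2) / s2t
}

#' Spin-lock alignment filter
#'
#' Keeps on-resonance R1rho points satisfying |omega_off| / omega_SL <=
#' `max_ratio` (default 0.4), the criterion used to limit magnetisation
#' alignment errors.
#'
#' @param data a data frame with columns `omega_sl` and `omega_off` (Hz).
#' @param max_ratio alignment threshold.
#' @return the filtered tibble.
#' @export
filter_alignment <- function(data, max_ratio = 0.4) {
  stopifnot(all(c("omega_sl", "omega_off") %in% names(data)))
  dplyr::filter(tibble::as_tibble(data),
                abs(.data$omega_off) / .data$omega_sl <= max_ratio)
}

#' Heteronuclear NOE from saturated/reference intensities
#'
#' NOE = I_sat / I_ref, with the uncertainty from first-order ratio error
#' propagation: sigma_NOE = |NOE| sqrt((s/I_sat)^2 + (s/I_ref)^2).
#'
#' @param i_sat peak intensity with 1H saturation.
#' @param i_ref reference intensity.
#' @param noise_sigma spectral noise (intensity units).
#' @return tibble with `noe`, `noe_err`, and `flagged` (TRUE when the
#'   reference intensity is within 3 sigma of zero).
#' @examples
#' het_noe(-20, 100, noise_sigma = 2)
#' @export
het_noe <- function(i_sat, i_ref, noise_sigma = 0) {
  if (any(i_ref == 0)) stop("i_ref must be non-zero", call. = FALSE)
  noe <- i_sat / i_ref
  err <- abs(noe) * sqrt((noise_sigma / i_sat)^2 + (noise_sigma / i_ref)^2)
  tibble::tibble(
    noe = noe, noe_err = err,
    flagged = abs(i_ref) < 3 * noise_sigma
  )
}

#' Fit the CSA/dipole cross-correlated rate eta_xy
#'
#' Fits the intensity-ratio build-up I_B/I_A = tanh(eta_xy T) by weighted
#' least squares. A single (T, ratio) pair is solved in closed form,
#' atanh(ratio)/T.
#'
#' @param data a data frame with columns `time` (s) and `ratio` (I_B/I_A,
#'   |ratio| < 1).
#' @param ratio_sigma optional per-point ratio uncertainty (scalar or
#'   vector); used for the fit weights and the error estimate.
#' @return one-row tibble: `eta_xy` (1/s), `eta_xy_err`.
#' @examples
#' fit_eta_xy(tibble::tibble(time = 0.040, ratio = tanh(0.5)))
#' @export
fit_eta_xy <- function(data, ratio_sigma = NULL) {
  stopifnot(all(c("time", "ratio") %in% names(data)))
  t <- data$time
  r <- data$ratio
  if (any(abs(r) >= 1)) stop("|ratio| must be < 1 for tanh model", call. = FALSE)
  if (length(t) == 1) {
    eta <- atanh(r) / t
    err <- if (!is.null(ratio_sigma)) ratio_sigma / ((1 - r^2) * t) else NA_real_
    return(tibble::tibble(eta_xy = eta, eta_xy_err = err))
  }
  w <- if (is.null(ratio_sigma)) rep(1, length(t)) else 1 / ratio_sigma^2
  if (all(r == 0)) {
    return(tibble::tibble(eta_xy = 0, eta_xy_err = NA_real_))
  }
  obj <- function(eta) sum(w * (r - tanh(eta * t))^2)
  hi <- 2 * max(abs(atanh(r)) / t)
  opt <- stats::optimize(obj, interval = c(-hi, hi), tol = 1e-12)
  eta <- opt$minimum
  err <- if (!is.null(ratio_sigma)) {
    jac <- t / cosh(eta * t)^2
    1 / sqrt(sum(w * jac^2))
  } else {
    NA_real_
  }
  tibble::tibble(eta_xy = eta, eta_xy_err = err)
}

#' RCZZ transverse relaxation rate from a Hahn-echo intensity pair
#'
#' R2_RCZZ = -(1 / (2 tau_he)) ln(I / I_ref), with `tau_total` = 2 tau_he
#' the total echo period (default 0.1296 s, n / J_NH).
#'
#' @param i,i_ref intensities with and without the echo period.
#' @param tau_total total echo delay 2 tau_he, s.
#' @return tibble with `r2_rczz` (1/s; NA when flagged) and `flagged`
#'   (TRUE for non-positive ratios: exchange-broadened beyond detection).
#' @examples
#' rczz_r2(exp(-1), 1) # 1/0.1296
#' @export
rczz_r2 <- function(i, i_ref, tau_total = 0.1296) {
  ratio <- i / i_ref
  bad <- ratio <= 0
  r2 <- ifelse(bad, NA_real_, -log(pmax(ratio, 1e-300)) / tau_total)
  tibble::tibble(r2_rczz = r2, flagged = bad)
}

#' Slow-exchange map from RCZZ, eta_xy and R1
#'
#' Rex = R2_RCZZ - kappa eta_xy + R1/2: the RCZZ rate minus the intrinsic
#' (CSA + dipolar) transverse rate estimated from cross-correlated
#' relaxation. Uncertainty by quadrature.
#'
#' @param r2_rczz RCZZ transverse rate, 1/s.
#' @param eta_xy cross-correlated rate, 1/s.
#' @param r1 longitudinal rate, 1/s.
#' @param kappa the CSA/dipole factor from [kappa_factor()].
#' @param r2_rczz_err,eta_xy_err,r1_err optional 1-sigma uncertainties.
#' @return tibble with `rex` (1/s) and `rex_err`.
#' @examples
#' rex_from_rczz(20, eta_xy = 15 / 1.2283, r1 = 2, kappa = 1.2283)
#' @export
rex_from_rczz <- function(r2_rczz, eta_xy, r1, kappa,
                          r2_rczz_err = 0, eta_xy_err = 0, r1_err = 0) {
  rex <- r2_rczz - kappa * eta_xy + r1 / 2
  err <- sqrt(r2_rczz_err^2 + (kappa * eta_xy_err)^2 + (r1_err / 2)^2)
  tibble::tibble(rex = rex, rex_err = err)
}

#' Effective R2 from constant-time CPMG intensities
#'
#' R2_eff = -(1/T) ln(I_CPMG / I_ref) with constant relaxation time T
#' (0.080 s at 750 MHz and 0.064 s at 900 MHz in the reference protocol).
#' Per-point uncertainty by first-order propagation of the intensity noise.
#'
#' @param i_cpmg,i_ref intensities with and without the CPMG period.
#' @param t_relax constant relaxation time, s.
#' @param noise_sigma intensity noise for the error estimate.
#' @return tibble with `r2eff` (1/s), `r2eff_err` and `flagged` (TRUE for
#'   non-positive ratios; such points are excluded from dispersion fits).
#' @examples
#' cpmg_r2eff(exp(-1), 1, t_relax = 0.080) # 12.5 1/s
#' @export
cpmg_r2eff <- function(i_cpmg, i_ref, t_relax = 0.080, noise_sigma = 0) {
  ratio <- i_cpmg / i_ref
  bad <- ratio <= 0
  if (any(bad)) {
    warning("non-positive intensity ratio: point(s) flagged and excluded",
      call. = FALSE
    )
  }
  r2 <- ifelse(bad, NA_real_, -log(pmax(ratio, 1e-300)) / t_relax)
  err <- (1 / t_relax) * sqrt((noise_sigma / i_cpmg)^2 +
    (noise_sigma / i_ref)^2)
  tibble::tibble(r2eff = r2, r2eff_err = abs(err), flagged = bad)
}
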
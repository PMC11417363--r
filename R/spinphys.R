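# Physical constants, spectral density functions and closed-form relaxation
# rates shared by every simulation and fitting stage.

# Gyromagnetic ratios in rad s^-1 T^-1. The 1H value is the shielded-proton
# (H2O) constant: spectrometer "1H frequency" designations reference the
# water resonance, and the printed kappa worked value is only reproduced with
# this convention. Magnitudes are stored; signs are carried separately.
.GAMMA_H <- 2.675153151e8
.GAMMA_X <- c(N15 = 2.71261804e7, C13 = 6.728284e7)
.GAMMA_SIGN <- c(N15 = -1, C13 = +1)
.MU0 <- 4 * pi * 1e-7
.PLANCK_H <- 6.62607015e-34

#' Nucleus-pair spin system
#'
#' Bundles the physical constants of an X-H spin pair: bond length, CSA
#' anisotropy, the angle between the CSA major axis and the bond vector, and
#' the gyromagnetic ratios. Defaults describe a backbone amide 15N-1H pair
#' (r = 1.02 A, CSA anisotropy -164 ppm, CSA/bond angle 18 degrees).
#'
#' @param nucleus `"N15"` or `"C13"`.
#' @param r_xh X-H bond length in Angstrom. Must be positive.
#' @param delta_sigma CSA anisotropy (sigma_par - sigma_perp) in ppm, signed.
#' @param beta angle between the CSA major axis and the X-H vector, degrees.
#' @return An object of class `spin_system`: a list with fields `nucleus`,
#'   `r_xh`, `delta_sigma`, `beta`, `gamma_x` (magnitude, rad/s/T),
#'   `gamma_h`, and `gamma_ratio` (signed gamma_H/gamma_X; negative for 15N).
#' @examples
#' spin_system("N15")
#' @export
spin_system <- function(nucleus = c("N15", "C13"), r_xh = NULL,
                        delta_sigma = NULL, beta = NULL) {
  nucleus <- match.arg(nucleus)
  defaults <- switch(nucleus,
    N15 = list(r_xh = 1.02, delta_sigma = -164, beta = 18),
    # nominal ribose/aromatic 13C-1H values; CSA only matters for forward
    # simulation since 13C R1rho fits treat R2_0 as a free parameter
    C13 = list(r_xh = 1.09, delta_sigma = 25, beta = 0)
  )
  r_xh <- r_xh %||% defaults$r_xh
  delta_sigma <- delta_sigma %||% defaults$delta_sigma
  beta <- beta %||% defaults$beta
  if (!is.numeric(r_xh) || r_xh <= 0) {
    stop("`r_xh` must be a positive bond length in Angstrom", call. = FALSE)
  }
  if (abs(beta) > 90) stop("`beta` must lie in [-90, 90] degrees", call. = FALSE)
  structure(
    list(
      nucleus = nucleus,
      r_xh = r_xh,
      delta_sigma = delta_sigma,
      beta = beta,
      gamma_x = unname(.GAMMA_X[nucleus]),
      gamma_h = .GAMMA_H,
      gamma_ratio = unname(.GAMMA_SIGN[nucleus] * .GAMMA_H / .GAMMA_X[nucleus])
    ),
    class = "spin_system"
  )
}

#' @export
print.spin_system <- function(x, ...) {
  cat(sprintf(
    "<spin_system> %s-1H  r = %.3f A  delta_sigma = %g ppm  beta = %g deg\n",
    x$nucleus, x$r_xh, x$delta_sigma, x$beta
  ))
  invisible(x)
}

#' Static field context
#'
#' A spectrometer field identified by its 1H Larmor frequency, with the
#' derived angular frequencies of 1H and of the X nucleus.
#'
#' @param proton_mhz 1H Larmor frequency in MHz (e.g. 750).
#' @param spin a [spin_system()] giving the X nucleus.
#' @param temperature sample temperature in K.
#' @return An object of class `field_context` with fields `proton_mhz`,
#'   `omega_h` and `omega_x` (angular frequency magnitudes, rad/s),
#'   `b0` (Tesla) and `temperature`.
#' @examples
#' field_context(750, spin_system("N15"))
#' @export
field_context <- function(proton_mhz, spin = spin_system("N15"),
                          temperature = 298) {
  stopifnot(is.numeric(proton_mhz), proton_mhz > 0)
  omega_h <- 2 * pi * proton_mhz * 1e6
  structure(
    list(
      proton_mhz = proton_mhz,
      omega_h = omega_h,
      omega_x = omega_h * spin$gamma_x / spin$gamma_h,
      b0 = omega_h / spin$gamma_h,
      temperature = temperature
    ),
    class = "field_context"
  )
}

#' @export
print.field_context <- function(x, ...) {
  cat(sprintf(
    "<field_context> 1H %.1f MHz  (X: %.2f MHz)  B0 = %.2f T  T = %g K\n",
    x$proton_mhz, x$omega_x / (2 * pi * 1e6), x$b0, x$temperature
  ))
  invisible(x)
}

#' Dipolar interaction constant
#'
#' d = mu0 h gamma_H gamma_X / (8 pi^2 r^3), returned as a positive
#' magnitude in rad/s. Field-independent.
#'
#' @param spin a [spin_system()].
#' @param field a [field_context()]; accepted for interface symmetry with
#'   [csa_constant()] but unused (d contains no frequency term).
#' @return dipolar constant, rad/s.
#' @examples
#' dipolar_constant(spin_system("N15"))
#' @export
dipolar_constant <- function(spin, field = NULL) {
  if (spin$r_xh <= 0) stop("non-physical bond length", call. = FALSE)
  r <- spin$r_xh * 1e-10
  .MU0 * .PLANCK_H * spin$gamma_h * spin$gamma_x / (8 * pi^2 * r^3)
}

#' CSA interaction constant
#'
#' c = omega_X (sigma_par - sigma_perp) / sqrt(3), signed with the CSA
#' anisotropy (negative for the amide 15N default) and proportional to the
#' static field.
#'
#' @inheritParams dipolar_constant
#' @param field a [field_context()].
#' @return CSA constant, rad/s (signed).
#' @export
csa_constant <- function(spin, field) {
  field$omega_x * spin$delta_sigma * 1e-6 / sqrt(3)
}

#' Second Legendre polynomial of cos(beta in degrees)
#' @noRd
.p2_cos_deg <- function(beta) (3 * cos(beta * pi / 180)^2 - 1) / 2

#' CSA/dipole cross-correlation factor kappa
#'
#' The dimensionless factor relating the transverse cross-correlated rate
#' eta_xy to the exchange-free intrinsic R2:
#' kappa = -6 \[(d^2/8) + (c^2/6)\] / \[sqrt(3) c d P2(cos beta)\].
#' For the amide 15N defaults at a 750 MHz field kappa = 1.2283.
#'
#' @inheritParams csa_constant
#' @return kappa, dimensionless; positive for the 15N defaults.
#' @examples
#' kappa_factor(spin_system("N15"), field_context(750))
#' @export
kappa_factor <- function(spin, field) {
  d <- dipolar_constant(spin, field)
  cc <- csa_constant(spin, field)
  p2 <- .p2_cos_deg(spin$beta)
  if (abs(p2) < 1e-8) {
    stop("beta is at the magic angle: P2(cos beta) = 0, kappa is singular",
      call. = FALSE
    )
  }
  if (cc == 0 || d == 0) stop("c and d must be non-zero", call. = FALSE)
  -6 * ((d^2 / 8) + (cc^2 / 6)) / (sqrt(3) * cc * d * p2)
}

#' Lipari-Szabo model-free spectral density
#'
#' J(omega) = (2/5)\[S^2 tau_c / (1 + (omega tau_c)^2) +
#' (1 - S^2) tau / (1 + (omega tau)^2)\] with 1/tau = 1/tau_c + 1/tau_i.
#' `tau_i = 0` collapses the internal-motion term.
#'
#' @param omega angular frequency, rad/s (vectorised).
#' @param s2 generalised order parameter in \[0, 1\].
#' @param tau_c overall rotational correlation time, s.
#' @param tau_i effective internal correlation time, s (>= 0).
#' @return spectral density, s/rad.
#' @examples
#' j_modelfree(0, s2 = 1, tau_c = 6.5e-9) # 0.4 * tau_c
#' @export
j_modelfree <- function(omega, s2, tau_c, tau_i = 0) {
  stopifnot(s2 >= 0, s2 <= 1, tau_c > 0, tau_i >= 0)
  tau <- if (tau_i > 0) 1 / (1 / tau_c + 1 / tau_i) else 0
  0.4 * (s2 * tau_c / (1 + (omega * tau_c)^2) +
    if (tau > 0) (1 - s2) * tau / (1 + (omega * tau)^2) else 0)
}

#' Extended (two-timescale) model-free spectral density
#'
#' J(omega) = (2/5)\[S^2 tau_c / (1 + (omega tau_c)^2) +
#' (Sf^2 - S^2) tau' / (1 + (omega tau')^2)\] with S^2 = Sf^2 Ss^2 and
#' 1/tau' = 1/tau_c + 1/tau_s. Reduces to [j_modelfree()] when Sf^2 = 1.
#'
#' @inheritParams j_modelfree
#' @param sf2 order parameter of the fast internal motion, \[0, 1\].
#' @param ss2 order parameter of the slow internal motion, \[0, 1\].
#' @param tau_s slow internal correlation time, s.
#' @return spectral density, s/rad.
#' @export
j_extended <- function(omega, sf2, ss2, tau_c, tau_s) {
  stopifnot(sf2 >= 0, sf2 <= 1, ss2 >= 0, ss2 <= 1, tau_c > 0, tau_s >= 0)
  s2 <- sf2 * ss2
  taup <- if (tau_s > 0) 1 / (1 / tau_c + 1 / tau_s) else 0
  0.4 * (s2 * tau_c / (1 + (omega * tau_c)^2) +
    if (taup > 0) (sf2 - s2) * taup / (1 + (omega * taup)^2) else 0)
}

#' Axially symmetric rotational diffusion tensor
#'
#' @param tau_c global correlation time, s (tau_c = 1/(6 D_iso)).
#' @param d_ratio anisotropy D_par / D_perp; 1 for isotropic tumbling.
#' @param axis unit vector of the unique axis in the molecular frame
#'   (axial tensors only).
#' @return An object of class `diffusion_tensor` with fields `model`
#'   (`"isotropic"` or `"axial"`), `tau_c`, `d_ratio`, `axis`.
#' @examples
#' diffusion_tensor(11.8e-9, d_ratio = 1.26, axis = c(0, 0, 1))
#' @export
diffusion_tensor <- function(tau_c, d_ratio = 1, axis = c(0, 0, 1)) {
  stopifnot(tau_c > 0, d_ratio > 0)
  axis <- axis / sqrt(sum(axis^2))
  if (axis[3] < 0) axis <- -axis # report upper hemisphere (v and -v equivalent)
  structure(
    list(
      model = if (isTRUE(all.equal(d_ratio, 1))) "isotropic" else "axial",
      tau_c = tau_c, d_ratio = d_ratio, axis = axis
    ),
    class = "diffusion_tensor"
  )
}

#' @export
print.diffusion_tensor <- function(x, ...) {
  cat(sprintf(
    "<diffusion_tensor> %s  tau_c = %.3f ns  D_par/D_perp = %.3f\n",
    x$model, x$tau_c * 1e9, x$d_ratio
  ))
  invisible(x)
}

#' Model-free spectral density under axially symmetric diffusion
#'
#' Three-Lorentzian form: J(omega) = (2/5) sum_k A_k \[S^2 tau_k /
#' (1 + (omega tau_k)^2) + (1 - S^2) tau_k' / (1 + (omega tau_k')^2)\],
#' with weights A1 = (3 cos^2 a - 1)^2 / 4, A2 = 3 sin^2 a cos^2 a,
#' A3 = (3/4) sin^4 a for NH/axis angle a, correlation times
#' tau_1 = 1/(6 D_perp), tau_2 = 1/(5 D_perp + D_par),
#' tau_3 = 1/(2 D_perp + 4 D_par), and 1/tau_k' = 1/tau_k + 1/tau_i.
#' Collapses to [j_modelfree()] with tau_c = 1/(6 D_iso) when
#' D_par/D_perp = 1.
#'
#' @inheritParams j_modelfree
#' @param tensor a [diffusion_tensor()].
#' @param nh_angle angle between the X-H vector and the unique axis, degrees.
#' @return spectral density, s/rad.
#' @export
j_axial <- function(omega, s2, tau_i, tensor, nh_angle) {
  stopifnot(inherits(tensor, "diffusion_tensor"))
  d_iso <- 1 / (6 * tensor$tau_c)
  # D_iso = (D_par + 2 D_perp)/3 with D_par = ratio * D_perp
  d_perp <- 3 * d_iso / (tensor$d_ratio + 2)
  d_par <- tensor$d_ratio * d_perp
  taus <- c(
    1 / (6 * d_perp),
    1 / (5 * d_perp + d_par),
    1 / (2 * d_perp + 4 * d_par)
  )
  ca2 <- cos(nh_angle * pi / 180)^2
  sa2 <- 1 - ca2
  wts <- c((3 * ca2 - 1)^2 / 4, 3 * sa2 * ca2, 0.75 * sa2^2)
  out <- 0
  for (k in 1:3) {
    tk <- taus[k]
    tkp <- if (tau_i > 0) 1 / (1 / tk + 1 / tau_i) else 0
    out <- out + wts[k] * (s2 * tk / (1 + (omega * tk)^2) +
      if (tkp > 0) (1 - s2) * tkp / (1 + (omega * tkp)^2) else 0)
  }
  0.4 * out
}

#' Relaxation rates from a spectral density function
#'
#' Standard dipolar + CSA expressions for an X-H pair:
#' R1 = (d^2/4)\[J(wH-wX) + 3 J(wX) + 6 J(wH+wX)\] + c^2 J(wX);
#' R2 = (d^2/8)\[4 J(0) + J(wH-wX) + 3 J(wX) + 6 J(wH) + 6 J(wH+wX)\] +
#' (c^2/6)\[4 J(0) + 3 J(wX)\] + Rex;
#' NOE = 1 + (d^2/4)(gammaH/gammaX)\[6 J(wH+wX) - J(wH-wX)\] / R1
#' with the signed gyromagnetic ratio (so NOE < 1 is possible for 15N).
#'
#' @inheritParams csa_constant
#' @param j a function of angular frequency (rad/s) returning J in s/rad.
#' @param rex exchange contribution to R2, 1/s.
#' @return named numeric vector `c(R1 =, R2 =, NOE =)`.
#' @examples
#' sp <- spin_system("N15"); fc <- field_context(700, sp)
#' rates_from_j(sp, fc, function(w) j_modelfree(w, 0.85, 6.5e-9, 50e-12))
#' @export
rates_from_j <- function(spin, field, j, rex = 0) {
  d <- dipolar_constant(spin, field)
  cc <- csa_constant(spin, field)
  wh <- field$omega_h
  wx <- field$omega_x
  j0 <- j(0); jx <- j(wx); jh <- j(wh)
  jhmx <- j(wh - wx); jhpx <- j(wh + wx)
  r1 <- (d^2 / 4) * (jhmx + 3 * jx + 6 * jhpx) + cc^2 * jx
  r2 <- (d^2 / 8) * (4 * j0 + jhmx + 3 * jx + 6 * jh + 6 * jhpx) +
    (cc^2 / 6) * (4 * j0 + 3 * jx) + rex
  if (r1 == 0) {
    if (r2 == rex && rex == 0) {
      return(c(R1 = 0, R2 = 0, NOE = NA_real_))
    }
    stop("R1 = 0: NOE undefined", call. = FALSE)
  }
  noe <- 1 + (d^2 / 4) * spin$gamma_ratio * (6 * jhpx - jhmx) / r1
  c(R1 = r1, R2 = r2, NOE = noe)
}

#' Transverse CSA/dipole cross-correlated relaxation rate
#'
#' eta_xy normalised so that the defining identity
#' kappa * eta_xy = \[(d^2/8) + (c^2/6)\] \[4 J(0) + 3 J(wX)\]
#' holds exactly: kappa * eta_xy is then the exchange-free part of R2
#' (high-frequency terms excluded), which is what the RCZZ exchange map
#' subtracts. Positive for the 15N defaults.
#'
#' @inheritParams csa_constant
#' @param j0 J(0), s/rad.
#' @param jwx J(omega_X), s/rad.
#' @return eta_xy, 1/s.
#' @export
eta_xy <- function(spin, field, j0, jwx) {
  d <- dipolar_constant(spin, field)
  cc <- csa_constant(spin, field)
  p2 <- .p2_cos_deg(spin$beta)
  # ((d^2/8)+(c^2/6)) (4 J0 + 3 JwX) / kappa, with kappa expanded
  -(sqrt(3) * cc * d * p2 / 6) * (4 * j0 + 3 * jwx)
}

#' Reduced spectral density mapping
#'
#' Inverts measured (R1, R2, NOE) to the spectral density values J(0),
#' J(omega_X) and J(0.87 omega_H) under the high-frequency flatness
#' approximation J(wH - wX) = J(wH) = J(wH + wX) = J(0.87 wH) and Rex = 0.
#' The coefficients are the exact algebraic inverse of [rates_from_j()]
#' under that approximation, so the round trip is an identity:
#' sigma = (NOE - 1) R1 (gammaX/gammaH);
#' J(0.87 wH) = 4 sigma / (5 d^2);
#' J(wX) = \[4 R1 - (28/5) sigma\] / (3 d^2 + 4 c^2);
#' J(0) = \[R2 - (13/8) d^2 Jh - (3 d^2/8 + c^2/2) J(wX)\] / (d^2/2 + 2 c^2/3).
#'
#' An exchange contribution or noise can drive the apparent J(0) negative;
#' such rows are kept and flagged.
#'
#' @param data a data frame with columns `R1`, `R2`, `NOE` (one row per
#'   residue; any other columns are carried through).
#' @inheritParams csa_constant
#' @return the input tibble with columns `j0`, `jwx`, `jwh` (s/rad) and
#'   logical `j0_negative` appended.
#' @examples
#' sp <- spin_system("N15"); fc <- field_context(700, sp)
#' r <- rates_from_j(sp, fc, function(w) j_modelfree(w, 0.9, 6.5e-9))
#' reduced_spectral_density_map(tibble::tibble(R1 = r["R1"], R2 = r["R2"],
#'   NOE = r["NOE"]), sp, fc)
#' @export
reduced_spectral_density_map <- function(data, spin, field) {
  stopifnot(all(c("R1", "R2", "NOE") %in% names(data)))
  if (any(data$R1 <= 0)) stop("R1 must be positive", call. = FALSE)
  d <- dipolar_constant(spin, field)
  cc <- csa_constant(spin, field)
  sigma <- (data$NOE - 1) * data$R1 / spin$gamma_ratio
  jh <- 4 * sigma / (5 * d^2)
  jx <- (4 * data$R1 - (28 / 5) * sigma) / (3 * d^2 + 4 * cc^2)
  j0 <- (data$R2 - (13 / 8) * d^2 * jh - (3 * d^2 / 8 + cc^2 / 2) * jx) /
    (d^2 / 2 + 2 * cc^2 / 3)
  out <- tibble::as_tibble(data)
  out$j0 <- j0
  out$jwx <- jx
  out$jwh <- jh
  out$j0_negative <- j0 < 0
  out
}
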
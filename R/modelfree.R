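# Rotational diffusion estimation from R2/R1 ratios and per-residue
# Lipari-Szabo model-free fitting with conservative model selection.

#' Internal: rates for a residue given model-free parameters
#' @noRd
.mf_rates <- function(spin, field, tensor, nh_angle, s2, tau_i, rex,
                      sf2 = NULL, tau_s = NULL) {
  j <- if (!is.null(sf2)) {
    # extended form: s2 here is the slow-motion parameter product Sf2*Ss2
    function(w) j_extended(w, sf2, s2 / sf2, tensor$tau_c, tau_s)
  } else if (tensor$model == "axial") {
    function(w) j_axial(w, s2, tau_i, tensor, nh_angle)
  } else {
    function(w) j_modelfree(w, s2, tensor$tau_c, tau_i)
  }
  rates_from_j(spin, field, j, rex = rex)
}

#' Rigid-body R2/R1 ratio as a function of tau_c (isotropic, S2 = 1)
#' @noRd
.rigid_ratio <- function(tau_c, spin, field) {
  r <- rates_from_j(spin, field, function(w) j_modelfree(w, 1, tau_c))
  r[["R2"]] / r[["R1"]]
}

#' Estimate the isotropic rotational correlation time from R2/R1 ratios
#'
#' Residues dominated by overall tumbling satisfy the rigid-body (S2 = 1,
#' tau_i = 0) relation between R2/R1 and tau_c; each qualifying residue's
#' ratio is inverted by root finding and the ensemble tau_c is the mean of
#' the surviving residues with its standard error. Residues with NOE below
#' `noe_min` (internal motion) are excluded, then residues whose R2/R1
#' deviates more than `sd_cut` standard deviations from the
#' `trim`-trimmed mean (exchange contributions inflate R2) are excluded.
#'
#' @param data tibble with columns `R1`, `R2`, `NOE` (and optionally
#'   `residue`).
#' @param spin,field the spin system and field of the measurements.
#' @param noe_min NOE threshold for the internal-motion filter.
#' @param trim trimming fraction for the reference mean of R2/R1.
#' @param sd_cut exclusion threshold in standard deviations.
#' @return list with `tau_c` (s), `tau_c_err` (SEM), `n_used`, and
#'   `per_residue` (tibble with each residue's tau_c and inclusion flag).
#' @export
estimate_tc_isotropic <- function(data, spin, field, noe_min = 0.65,
                                  trim = 0.1, sd_cut = 1.5) {
  stopifnot(all(c("R1", "R2", "NOE") %in% names(data)))
  data <- tibble::as_tibble(data)
  if (!"residue" %in% names(data)) data$residue <- seq_len(nrow(data))
  ratio <- data$R2 / data$R1
  keep <- data$NOE >= noe_min
  if (sum(keep) >= 5) {
    m <- mean(ratio[keep], trim = trim)
    s <- stats::sd(ratio[keep])
    keep <- keep & abs(ratio - m) <= sd_cut * s
  }
  if (sum(keep) < 1) stop("no residues qualify for tau_c estimation",
    call. = FALSE)
  tc <- vapply(seq_len(nrow(data)), function(i) {
    if (!keep[i]) return(NA_real_)
    f <- function(lt) .rigid_ratio(10^lt, spin, field) - ratio[i]
    out <- try(stats::uniroot(f, c(log10(2e-10), log10(6e-8)), tol = 1e-12),
      silent = TRUE
    )
    if (inherits(out, "try-error")) NA_real_ else 10^out$root
  }, numeric(1))
  used <- !is.na(tc)
  if (sum(used) < 1) stop("tau_c root finding failed for all residues",
    call. = FALSE)
  list(
    tau_c = mean(tc[used]),
    tau_c_err = stats::sd(tc[used]) / sqrt(sum(used)),
    n_used = sum(used),
    per_residue = tibble::tibble(
      residue = data$residue, r2_over_r1 = ratio,
      tau_c = tc, used = used
    )
  )
}

#' Fit an axially symmetric rotational diffusion tensor
#'
#' Nonlinear fit of (tau_c, D_par/D_perp, axis polar angles) to per-residue
#' R2/R1 ratios using the rigid axial spectral density; the angle each N-H
#' vector makes with the candidate unique axis sets its local effective
#' correlation time. The isotropic model is fitted alongside and compared
#' by AIC; with fewer than 8 residues (or a degenerate vector set) the
#' isotropic result is returned with a warning. The reported axis is in
#' the upper hemisphere (v and -v are equivalent).
#'
#' @param data tibble with `residue`, `R1`, `R2`, `NOE` and optionally
#'   `R1_err`, `R2_err` for weighting.
#' @param vectors tibble with `residue`, `x`, `y`, `z` unit N-H vectors.
#' @param spin,field the spin system and field.
#' @param noe_min filter threshold as in [estimate_tc_isotropic()].
#' @return list with `tensor` (a [diffusion_tensor()]), `chi2`, `aic`,
#'   `aic_iso`, `preferred` (`"axial"` or `"isotropic"`), `n_used`.
#' @export
fit_axial_tensor <- function(data, vectors, spin, field, noe_min = 0.65) {
  data <- dplyr::inner_join(
    tibble::as_tibble(data), tibble::as_tibble(vectors),
    by = "residue"
  )
  iso <- estimate_tc_isotropic(data, spin, field, noe_min = noe_min)
  used <- iso$per_residue$used
  dat <- data[used, ]
  v <- as.matrix(dat[, c("x", "y", "z")])
  v <- v / sqrt(rowSums(v^2))
  ratio <- dat$R2 / dat$R1
  sig <- if (all(c("R1_err", "R2_err") %in% names(dat))) {
    ratio * sqrt((dat$R2_err / dat$R2)^2 + (dat$R1_err / dat$R1)^2)
  } else {
    rep(0.02 * stats::median(ratio), nrow(dat))
  }
  spread <- nrow(dat) >= 8 &&
    min(svd(sweep(v, 2, colMeans(v)))$d) > 1e-3
  if (!spread) {
    warning("too few residues or degenerate N-H vector distribution; ",
      "falling back to the isotropic model",
      call. = FALSE
    )
    return(list(
      tensor = diffusion_tensor(iso$tau_c), chi2 = NA_real_,
      aic = NA_real_, aic_iso = NA_real_, preferred = "isotropic",
      n_used = iso$n_used
    ))
  }
  # vectorised rigid-body R2/R1 over residues for a candidate tensor:
  # shared correlation times, per-residue weights from the NH/axis angle
  d2 <- dipolar_constant(spin, field)^2
  c2 <- csa_constant(spin, field)^2
  wh <- field$omega_h
  wx <- field$omega_x
  omegas <- c(0, wx, wh - wx, wh, wh + wx)
  pred_ratio <- function(tau_c, d_ratio, axis) {
    ca2 <- pmin(pmax((v %*% axis)^2, 0), 1)[, 1]
    sa2 <- 1 - ca2
    wts <- cbind((3 * ca2 - 1)^2 / 4, 3 * sa2 * ca2, 0.75 * sa2^2)
    d_iso <- 1 / (6 * tau_c)
    d_perp <- 3 * d_iso / (d_ratio + 2)
    d_par <- d_ratio * d_perp
    taus <- c(1 / (6 * d_perp), 1 / (5 * d_perp + d_par),
      1 / (2 * d_perp + 4 * d_par))
    lor <- outer(taus, omegas, function(tk, w) 0.4 * tk / (1 + (w * tk)^2))
    j <- wts %*% lor # residues x 5 frequencies
    r1 <- (d2 / 4) * (j[, 3] + 3 * j[, 2] + 6 * j[, 5]) + c2 * j[, 2]
    r2 <- (d2 / 8) * (4 * j[, 1] + j[, 3] + 3 * j[, 2] + 6 * j[, 4] +
      6 * j[, 5]) + (c2 / 6) * (4 * j[, 1] + 3 * j[, 2])
    r2 / r1
  }
  obj <- function(p) {
    tau_c <- exp(p[1])
    d_ratio <- exp(p[2])
    axis <- c(
      sin(p[3]) * cos(p[4]), sin(p[3]) * sin(p[4]), cos(p[3])
    )
    sum(((ratio - pred_ratio(tau_c, d_ratio, axis)) / sig)^2)
  }
  starts <- expand.grid(
    theta = c(0.3, 1.0, 1.5), phi = c(0, pi / 2, pi), lr = log(c(0.8, 1.25))
  )
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    p0 <- c(log(iso$tau_c), starts$lr[i], starts$theta[i], starts$phi[i])
    res <- try(stats::optim(p0, obj, method = "Nelder-Mead",
      control = list(maxit = 400, reltol = 1e-10)), silent = TRUE)
    if (inherits(res, "try-error")) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  chi2_iso <- sum(((ratio - .rigid_ratio(iso$tau_c, spin, field)) / sig)^2)
  aic_iso <- chi2_iso + 2
  p <- best$par
  axis <- c(sin(p[3]) * cos(p[4]), sin(p[3]) * sin(p[4]), cos(p[3]))
  tensor <- diffusion_tensor(exp(p[1]), exp(p[2]), axis)
  aic_ax <- best$value + 2 * 4
  list(
    tensor = tensor, chi2 = best$value, aic = aic_ax, aic_iso = aic_iso,
    preferred = if (aic_ax < aic_iso) "axial" else "isotropic",
    n_used = nrow(dat)
  )
}

# ---------------------------------------------------------------------------
# Model-free fitting

.MF_MODELS <- list(
  `1` = c("s2"),
  `2` = c("s2", "tau_i"),
  `3` = c("s2", "rex"),
  `4` = c("s2", "tau_i", "rex"),
  `5` = c("sf2", "s2", "tau_s")
)

#' Chi-square of observed vs calculated rates
#' @noRd
.mf_chi2 <- function(obs, calc) {
  sum(((obs$vals - calc) / obs$errs)^2)
}

#' Precompute the constants of the rate expressions for one residue so the
#' per-model optimisers run on plain arithmetic (the fits call these
#' thousands of times).
#' @noRd
.mf_context <- function(spin, field, tensor, nh_angle) {
  d2 <- dipolar_constant(spin, field)^2
  c2 <- csa_constant(spin, field)^2
  wh <- field$omega_h
  wx <- field$omega_x
  omegas <- c(0, wx, wh - wx, wh, wh + wx)
  ctx <- list(
    d2 = d2, c2 = c2, gr = spin$gamma_ratio, omegas = omegas,
    tensor = tensor, nh_angle = nh_angle
  )
  if (tensor$model == "axial") {
    d_iso <- 1 / (6 * tensor$tau_c)
    d_perp <- 3 * d_iso / (tensor$d_ratio + 2)
    d_par <- tensor$d_ratio * d_perp
    ctx$taus <- c(
      1 / (6 * d_perp), 1 / (5 * d_perp + d_par), 1 / (2 * d_perp + 4 * d_par)
    )
    ca2 <- cos(nh_angle * pi / 180)^2
    sa2 <- 1 - ca2
    ctx$wts <- c((3 * ca2 - 1)^2 / 4, 3 * sa2 * ca2, 0.75 * sa2^2)
  }
  ctx
}

#' J at the five rate frequencies for the three parameterisations
#' @noRd
.mf_jvals <- function(ctx, s2, tau_i = 0, sf2 = NULL, tau_s = NULL) {
  w <- ctx$omegas
  if (!is.null(sf2)) {
    tc <- ctx$tensor$tau_c
    taup <- if (tau_s > 0) 1 / (1 / tc + 1 / tau_s) else 0
    0.4 * (s2 * tc / (1 + (w * tc)^2) +
      if (taup > 0) (sf2 - s2) * taup / (1 + (w * taup)^2) else 0)
  } else if (ctx$tensor$model == "axial") {
    out <- numeric(length(w))
    for (k in 1:3) {
      tk <- ctx$taus[k]
      tkp <- if (tau_i > 0) 1 / (1 / tk + 1 / tau_i) else 0
      out <- out + ctx$wts[k] * (s2 * tk / (1 + (w * tk)^2) +
        if (tkp > 0) (1 - s2) * tkp / (1 + (w * tkp)^2) else 0)
    }
    0.4 * out
  } else {
    tc <- ctx$tensor$tau_c
    tau <- if (tau_i > 0) 1 / (1 / tc + 1 / tau_i) else 0
    0.4 * (s2 * tc / (1 + (w * tc)^2) +
      if (tau > 0) (1 - s2) * tau / (1 + (w * tau)^2) else 0)
  }
}

#' (R1, R2, NOE) from the five J values
#' @noRd
.mf_rates_fast <- function(ctx, j, rex = 0) {
  r1 <- (ctx$d2 / 4) * (j[3] + 3 * j[2] + 6 * j[5]) + ctx$c2 * j[2]
  r2 <- (ctx$d2 / 8) * (4 * j[1] + j[3] + 3 * j[2] + 6 * j[4] + 6 * j[5]) +
    (ctx$c2 / 6) * (4 * j[1] + 3 * j[2]) + rex
  noe <- 1 + (ctx$d2 / 4) * ctx$gr * (6 * j[5] - j[3]) / r1
  c(r1, r2, noe)
}

#' Fit one model-free model to one residue
#' @noRd
.mf_fit_one <- function(model_id, obs, spin, field, tensor, nh_angle,
                        ctx = NULL) {
  ctx <- ctx %||% .mf_context(spin, field, tensor, nh_angle)
  calc <- function(s2, tau_i = 0, rex = 0, sf2 = NULL, tau_s = NULL) {
    .mf_rates_fast(ctx, .mf_jvals(ctx, s2, tau_i, sf2, tau_s), rex)
  }
  chi_of <- function(...) .mf_chi2(obs, calc(...))
  fit <- switch(as.character(model_id),
    "1" = {
      o <- stats::optimize(function(s2) chi_of(s2), c(0, 1), tol = 1e-10)
      list(par = c(s2 = o$minimum), chi2 = o$objective)
    },
    "2" = {
      inner <- function(lt) {
        stats::optimize(function(s2) chi_of(s2, tau_i = 10^lt), c(0, 1),
          tol = 1e-9
        )
      }
      o <- stats::optimize(function(lt) inner(lt)$objective,
        c(log10(1e-12), log10(tensor$tau_c * 0.9)),
        tol = 1e-7
      )
      s2 <- inner(o$minimum)$minimum
      list(
        par = c(s2 = s2, tau_i = 10^o$minimum),
        chi2 = o$objective
      )
    },
    "3" = {
      # rex enters R2 only and linearly: profile it (clamped at 0)
      o <- stats::optimize(function(s2) {
        base <- calc(s2)
        rex <- max(0, obs$vals[2] - base[2])
        .mf_chi2(obs, base + c(0, rex, 0))
      }, c(0, 1), tol = 1e-10)
      s2 <- o$minimum
      base <- calc(s2)
      rex <- max(0, obs$vals[2] - base[2])
      list(par = c(s2 = s2, rex = rex), chi2 = o$objective)
    },
    "4" = {
      inner <- function(lt) {
        ti <- 10^lt
        if (ti >= tensor$tau_c) return(list(objective = 1e10, minimum = NA))
        stats::optimize(function(s2) {
          base <- calc(s2, tau_i = ti)
          rex <- max(0, obs$vals[2] - base[2])
          .mf_chi2(obs, base + c(0, rex, 0))
        }, c(0, 1), tol = 1e-9)
      }
      o <- stats::optimize(function(lt) inner(lt)$objective,
        c(log10(1e-12), log10(tensor$tau_c * 0.9)),
        tol = 1e-6
      )
      ti <- 10^o$minimum
      s2 <- inner(o$minimum)$minimum
      base <- calc(s2, tau_i = ti)
      rex <- max(0, obs$vals[2] - base[2])
      list(
        par = c(s2 = s2, tau_i = ti, rex = rex),
        chi2 = .mf_chi2(obs, base + c(0, rex, 0))
      )
    },
    "5" = {
      inner <- function(lt) {
        ts <- 10^lt
        o2 <- stats::optim(c(0.8, 0.5), function(p) {
          sf2 <- p[1]; ss2 <- p[2]
          if (sf2 <= 0.01 || sf2 > 1 || ss2 < 0 || ss2 > 1) return(1e10)
          chi_of(sf2 * ss2, sf2 = sf2, tau_s = ts)
        }, method = "Nelder-Mead", control = list(reltol = 1e-10, maxit = 300))
        o2
      }
      o <- stats::optimize(function(lt) inner(lt)$value,
        c(log10(50e-12), log10(tensor$tau_c * 0.9)),
        tol = 1e-6
      )
      ts <- 10^o$minimum
      o2 <- inner(o$minimum)
      list(
        par = c(sf2 = o2$par[1], ss2 = o2$par[2], s2 = o2$par[1] * o2$par[2],
          tau_s = ts),
        chi2 = o2$value
      )
    }
  )
  fit
}

#' Lipari-Szabo model-free analysis of per-residue relaxation rates
#'
#' Fits the five standard model-free parameterisations to each residue's
#' (R1, R2, NOE): 1 S2; 2 S2, tau_i; 3 S2, Rex; 4 S2, tau_i, Rex;
#' 5 the extended two-timescale form Sf2, Ss2, tau_s. Selection follows a
#' conservative complexity ladder: the simplest model whose chi-square
#' falls below the alpha = 0.05 critical value for its residual degrees of
#' freedom is accepted; when several models of equal complexity pass, the
#' lower AIC wins; when none passes, the three-parameter models (4, 5) are
#' compared by AIC and flagged. With an axial `tensor`, per-residue N-H
#' vectors supply the angle to the unique axis.
#'
#' @param data tibble with columns `residue`, `R1`, `R2`, `NOE` and
#'   errors `R1_err`, `R2_err`, `NOE_err`.
#' @param tensor a [diffusion_tensor()].
#' @param spin,field the spin system and field of the measurements.
#' @param vectors optional tibble `residue`, `x`, `y`, `z` (axial tensors).
#' @param models subset of models to consider (default 1:5).
#' @return tibble with one row per residue: `model` (selected id), `s2`,
#'   `sf2`, `ss2`, `tau_i`, `tau_s`, `rex`, `chi2`, `selected` (FALSE when
#'   every model was rejected and the best chi-square is reported).
#' @export
fit_modelfree <- function(data, tensor, spin, field, vectors = NULL,
                          models = 1:5) {
  stopifnot(all(c("residue", "R1", "R2", "NOE") %in% names(data)))
  data <- tibble::as_tibble(data)
  for (col in c("R1_err", "R2_err", "NOE_err")) {
    if (!col %in% names(data)) {
      base <- sub("_err", "", col)
      data[[col]] <- if (base == "NOE") 0.02 else 0.02 * data[[base]]
    }
  }
  angles <- rep(NA_real_, nrow(data))
  if (tensor$model == "axial") {
    if (is.null(vectors)) {
      stop("axial tensor requires per-residue N-H `vectors`", call. = FALSE)
    }
    vmat <- tibble::as_tibble(vectors)
    idx <- match(data$residue, vmat$residue)
    vv <- as.matrix(vmat[idx, c("x", "y", "z")])
    vv <- vv / sqrt(rowSums(vv^2))
    angles <- acos(pmin(pmax(abs(vv %*% tensor$axis), 0), 1)) * 180 / pi
  }
  purrr::map_dfr(seq_len(nrow(data)), function(i) {
    row <- data[i, ]
    obs <- list(
      vals = c(row$R1, row$R2, row$NOE),
      errs = c(row$R1_err, row$R2_err, row$NOE_err)
    )
    ctx <- .mf_context(spin, field, tensor, angles[i])
    ks <- vapply(models, function(m) {
      length(.MF_MODELS[[as.character(m)]])
    }, numeric(1))
    fits <- list()
    sel <- NULL
    # lazy complexity ladder: only fit the next tier when the simpler
    # tier is rejected
    for (k in sort(unique(ks))) {
      tier <- models[ks == k]
      cand <- lapply(tier, function(m) {
        f <- .mf_fit_one(m, obs, spin, field, tensor, angles[i], ctx = ctx)
        f$model <- m
        f$k <- k
        f
      })
      fits <- c(fits, cand)
      df <- 3 - k
      crit <- if (df >= 1) stats::qchisq(0.95, df) else stats::qchisq(0.95, 1)
      pass <- Filter(function(f) f$chi2 <= crit, cand)
      if (length(pass)) {
        aics <- vapply(pass, function(f) f$chi2 + 2 * f$k, numeric(1))
        sel <- pass[[which.min(aics)]]
        sel$selected <- TRUE
        break
      }
    }
    if (is.null(sel)) {
      chis <- vapply(fits, function(f) f$chi2, numeric(1))
      sel <- fits[[which.min(chis)]]
      sel$selected <- FALSE
    }
    pget <- function(nm) unname(sel$par[nm])
    tibble::tibble(
      residue = row$residue, model = sel$model,
      s2 = pget("s2"), sf2 = pget("sf2"), ss2 = pget("ss2"),
      tau_i = pget("tau_i"), tau_s = pget("tau_s"),
      rex = pget("rex") %|NA|% 0,
      chi2 = sel$chi2, selected = isTRUE(sel$selected)
    )
  })
}

#' NA-coalescing helper
#' @noRd
`%|NA|%` <- function(a, b) ifelse(is.na(a), b, a)

#' Rescale a rotational correlation time for water viscosity
#'
#' Correlation times computed from hydrodynamic calculations at 293 K are
#' rescaled to another temperature by the ratio of water viscosities,
#' tau_c * eta(T_target) / eta(T_ref); defaults take 293 K (1.002 mPa s)
#' to 313 K (0.653 mPa s).
#'
#' @param tau_c correlation time (any unit; scaled in place).
#' @param eta_target water viscosity at the target temperature, mPa s.
#' @param eta_ref water viscosity at the reference temperature, mPa s.
#' @return scaled correlation time.
#' @examples
#' scale_tc_viscosity(6.37) # ns at 293 K -> ns at 313 K
#' @export
scale_tc_viscosity <- function(tau_c, eta_target = 0.653, eta_ref = 1.002) {
  stopifnot(all(tau_c > 0))
  tau_c * eta_target / eta_ref
}
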
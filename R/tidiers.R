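# broom-style tidiers and ggplot2 autoplot methods for fit objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a per-residue CPMG fit
#'
#' @param x a `cpmg_fit`.
#' @param ... unused.
#' @return tibble with `term`, `estimate`, `fixed`.
#' @export
tidy.cpmg_fit <- function(x, ...) x$params

#' @rdname tidy.cpmg_fit
#' @export
glance.cpmg_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model, chi2 = x$chi2, n_points = x$n_points,
    n_params = x$n_params, aic = x$aic, converged = x$converged
  )
}

#' Tidy a global CPMG fit
#'
#' @param x a `cpmg_global_fit`.
#' @param ... unused.
#' @return shared kinetic parameters; per-residue terms are in
#'   `x$per_residue`.
#' @export
tidy.cpmg_global_fit <- function(x, ...) x$params

#' @rdname tidy.cpmg_global_fit
#' @export
glance.cpmg_global_fit <- function(x, ...) {
  tibble::tibble(
    chi2 = x$chi2, n_points = x$n_points, n_params = x$n_params,
    aic = x$aic, n_excluded = length(x$excluded),
    max_chi2_ratio = max(x$per_residue$chi2_ratio, na.rm = TRUE)
  )
}

#' Tidy a spin-lock dispersion fit
#'
#' @param x an `r1rho_fit`.
#' @param ... unused.
#' @return per-site tibble with `site`, `phi_ex`, `r2_0`, chi-square
#'   diagnostics and the shared `kex` attached as a column.
#' @export
tidy.r1rho_fit <- function(x, ...) {
  out <- x$per_site
  out$kex <- if (x$global) x$kex else x$individual$kex
  out
}

#' @rdname tidy.r1rho_fit
#' @export
glance.r1rho_fit <- function(x, ...) {
  tibble::tibble(
    kex = x$kex, chi2 = x$chi2, n_points = x$n_points,
    n_params = x$n_params, aic = x$aic, global = x$global
  )
}

#' @export
print.cpmg_fit <- function(x, ...) {
  cat(sprintf(
    "<cpmg_fit> %s model  chi2 = %.2f  (%d points, %d params)\n",
    x$model, x$chi2, x$n_points, x$n_params
  ))
  print(x$params)
  invisible(x)
}

#' @export
print.cpmg_global_fit <- function(x, ...) {
  cat(sprintf(
    "<cpmg_global_fit> %d residues  chi2 = %.2f  aic = %.2f\n",
    nrow(x$per_residue), x$chi2, x$aic
  ))
  print(x$params)
  if (length(x$excluded)) {
    cat(
      "excluded (chi2 ratio >", x$ratio_cutoff, "):",
      paste(x$excluded, collapse = ", "), "\n"
    )
  }
  invisible(x)
}

#' @export
print.r1rho_fit <- function(x, ...) {
  cat(sprintf(
    "<r1rho_fit> %s  kex = %.0f 1/s  chi2 = %.2f\n",
    if (x$global) "global" else "individual", x$kex, x$chi2
  ))
  invisible(x)
}

#' Plot a CPMG dispersion fit
#'
#' Measured R2eff vs nu_cp with the fitted dispersion curve, one panel
#' per field.
#'
#' @param object a `cpmg_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.cpmg_fit <- function(object, ...) {
  dat <- object$data
  line <- purrr::map_dfr(unique(dat$field_mhz), function(f) {
    nu <- exp(seq(log(min(dat$nu_cp)), log(max(dat$nu_cp)), length.out = 80))
    tibble::tibble(
      field_mhz = f, nu_cp = nu,
      r2eff = .cpmg_predict(object, tibble::tibble(field_mhz = f, nu_cp = nu))
    )
  })
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$nu_cp, y = .data$r2eff)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$r2eff - .data$sigma, ymax = .data$r2eff + .data$sigma
    ), size = 0.3) +
    ggplot2::geom_line(data = line, colour = "steelblue") +
    ggplot2::facet_wrap(~field_mhz, labeller = ggplot2::label_both) +
    ggplot2::labs(
      x = expression(nu[CP] ~ "(Hz)"), y = expression(R[2]^eff ~ (s^-1))
    ) +
    ggplot2::theme_bw()
}

#' Plot a spin-lock dispersion fit
#'
#' R2eff vs effective-field strength squared with the shared-kex fit, one
#' panel per site.
#'
#' @param object an `r1rho_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.r1rho_fit <- function(object, ...) {
  dat <- object$data
  est <- object$per_site
  line <- purrr::map_dfr(est$site, function(s) {
    e <- est[est$site == s, ]
    w2 <- seq(min(dat$weff2), max(dat$weff2), length.out = 100)
    tibble::tibble(
      site = s, weff2 = w2,
      r2eff = e$r2_0 + e$phi_ex * object$kex / (w2 + object$kex^2)
    )
  })
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$weff2 / (4 * pi^2 * 1e6),
    y = .data$r2eff)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$r2eff - .data$sigma, ymax = .data$r2eff + .data$sigma
    ), size = 0.3) +
    ggplot2::geom_line(data = line, colour = "firebrick") +
    ggplot2::facet_wrap(~site) +
    ggplot2::labs(
      x = expression(omega[eff]^2 / (2 * pi)^2 ~ (kHz^2)),
      y = expression(R[2]^eff ~ (s^-1))
    ) +
    ggplot2::theme_bw()
}

#' Per-residue model-free parameter map
#'
#' Stacked panels of S2, internal correlation time and Rex against
#' residue number — the standard presentation of backbone dynamics.
#'
#' @param results tibble from [fit_modelfree()].
#' @return a ggplot.
#' @export
plot_modelfree <- function(results) {
  long <- results |>
    dplyr::transmute(
      residue = .data$residue, S2 = .data$s2,
      `tau (ns)` = dplyr::coalesce(.data$tau_s, .data$tau_i) * 1e9,
      `Rex (1/s)` = .data$rex
    ) |>
    tidyr::pivot_longer(-"residue", names_to = "parameter")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$residue, y = .data$value)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_grid(parameter ~ ., scales = "free_y", switch = "y") +
    ggplot2::labs(x = "residue", y = NULL) +
    ggplot2::theme_bw()
}
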
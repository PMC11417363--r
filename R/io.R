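# Readers and writers for the package's TSV dialects, the PDB coordinate
# reader for N-H bond vectors, and the pipeline configuration.

#' Read a peak-intensity table
#'
#' Tab-separated, header-driven (column order free): `residue`, `atom`,
#' `condition_type` (one of `delay`, `nu_cp`, `spinlock`),
#' `condition_value` (s or Hz; for `spinlock` rows an `omega_off` column
#' supplies the offset), `intensity`, `replicate`. Malformed rows are
#' reported with their line numbers.
#'
#' @param path file path.
#' @return tibble with the validated columns.
#' @export
read_intensity_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  required <- c(
    "residue", "atom", "condition_type", "condition_value",
    "intensity", "replicate"
  )
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in c("condition_value", "intensity")) {
    vals <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(vals) & !is.na(df[[col]]) & df[[col]] != "NA")
    if (length(bad)) {
      stop(sprintf(
        "non-numeric `%s` at line(s) %s", col,
        paste(bad + 1, collapse = ", ")
      ), call. = FALSE)
    }
    df[[col]] <- vals
  }
  key <- paste(df$residue, df$atom, df$condition_type, df$condition_value,
    df$replicate,
    sep = "\r"
  )
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop(sprintf(
      "duplicate (residue, condition, replicate) row(s) at line(s) %s",
      paste(dup + 1, collapse = ", ")
    ), call. = FALSE)
  }
  ok <- df$condition_type %in% c("delay", "nu_cp", "spinlock")
  if (any(!ok)) {
    stop(sprintf(
      "unknown condition_type at line(s) %s",
      paste(which(!ok) + 1, collapse = ", ")
    ), call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' Write a peak-intensity table
#' @param data tibble as returned by [read_intensity_table()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_intensity_table <- function(data, path) {
  utils::write.table(data, path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Read / write per-residue rate tables
#'
#' TSV with columns `residue`, `R1`, `R1_err`, `R2`, `R2_err`, `NOE`,
#' `NOE_err` and optional extras; `field_mhz` and `temperature_k` are
#' carried as columns so multi-condition tables stay tidy.
#'
#' @param path file path.
#' @return tibble.
#' @export
read_rate_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  required <- c("residue", "R1", "R2", "NOE")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' @rdname read_rate_table
#' @param data tibble to write.
#' @export
write_rate_table <- function(data, path) {
  utils::write.table(data, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write dispersion-point tables
#'
#' TSV with columns `residue` (or `site`), `field_mhz`, and either
#' `nu_cp` (CPMG) or `omega_sl` + `omega_off` (spin lock), plus `r2eff`
#' and `sigma`.
#'
#' @param path file path.
#' @return tibble.
#' @export
read_dispersion_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!any(c("nu_cp", "omega_sl") %in% names(df))) {
    stop("need a `nu_cp` or `omega_sl` column", call. = FALSE)
  }
  if (!all(c("r2eff", "sigma") %in% names(df))) {
    stop("need `r2eff` and `sigma` columns", call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' @rdname read_dispersion_table
#' @param data tibble to write.
#' @export
write_dispersion_table <- function(data, path) {
  utils::write.table(data, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract N-H bond unit vectors from a PDB file
#'
#' Reads backbone N and amide H (H or HN) atoms of one model/chain and
#' returns the normalised N-to-H vector per residue. Residues lacking
#' either atom (prolines, unprotonated structures) are skipped with a
#' warning.
#'
#' @param path PDB file.
#' @param chain chain identifier; `NULL` keeps all chains.
#' @param model_index model to use in multi-model files.
#' @return tibble: `residue`, `x`, `y`, `z` (unit vectors).
#' @export
read_nh_vectors <- function(path, chain = NULL, model_index = 1) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  if (!is.null(chain)) at <- at[at$chain %in% chain, ]
  if (!is.null(pdb$xyz) && nrow(pdb$xyz) >= model_index && model_index > 1) {
    xyz <- matrix(pdb$xyz[model_index, ], ncol = 3, byrow = TRUE)
    at$x <- xyz[at$eleno, 1][seq_len(nrow(at))]
  }
  ns <- at[at$elety == "N", ]
  hs <- at[at$elety %in% c("H", "HN"), ]
  res <- intersect(ns$resno, hs$resno)
  skipped <- setdiff(ns$resno, res)
  if (length(skipped)) {
    warning(
      "no amide H for residue(s): ", paste(skipped, collapse = ", "),
      call. = FALSE
    )
  }
  purrr::map_dfr(res, function(r) {
    n <- ns[ns$resno == r, ][1, ]
    h <- hs[hs$resno == r, ][1, ]
    v <- c(h$x - n$x, h$y - n$y, h$z - n$z)
    v <- v / sqrt(sum(v^2))
    tibble::tibble(residue = r, x = v[1], y = v[2], z = v[3])
  })
}

#' Pipeline configuration
#'
#' A single list holding every tunable of the pipeline: spin-system
#' defaults, fields, noise model, fit grids and cutoffs, and filter
#' thresholds. `pipeline_config()` returns the defaults merged with
#' overrides; [read_config()] / [write_config()] round-trip it through
#' YAML losslessly.
#'
#' @param ... overrides of the default entries (nested lists are merged
#'   shallowly).
#' @return a named list of class `spindyn_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    spin = list(r_nh = 1.02, delta_sigma = -164, beta = 18),
    fields_mhz = c(750, 900),
    noise = list(rate_frac_sigma = 0.02, noe_sigma = 0.02, cpmg_sigma = 0.4),
    fit = list(
      kex_grid = 10^seq(2, 5, length.out = 4),
      pb_grid = c(0.003, 0.03, 0.2),
      dw_grid = c(0.5, 1.5, 3),
      mc_draws = 100, seed = 1L
    ),
    filters = list(
      noe_min = 0.65, alignment_max = 0.4, chi2_ratio_cutoff = 2.0
    )
  )
  ov <- list(...)
  for (nm in names(ov)) {
    if (is.list(ov[[nm]]) && is.list(defaults[[nm]])) {
      defaults[[nm]][names(ov[[nm]])] <- ov[[nm]]
    } else {
      defaults[[nm]] <- ov[[nm]]
    }
  }
  structure(defaults, class = c("spindyn_config", "list"))
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

#' @rdname pipeline_config
#' @param config a `spindyn_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
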
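#' Write and read pipeline tables as CSV
#'
#' Delimited-text interchange for the pipeline's tabular objects. Metadata
#' (site, frame, spin-lock frequency, scaling factor, scan rate) travels in
#' extra constant columns so a round trip preserves the object. When
#' synthetic ground truth is attached, `write_spindyn_csv()` drops a JSON
#' sidecar `<path>.truth.json` beside the table.
#'
#' @param x a [decay_curve()], [rate_series()], [dipolar_pattern()] or
#'   [dsc_trace()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_spindyn_csv <- function(x, path) {
  df <- as.data.frame(x)
  if (inherits(x, "decay_curve")) {
    df <- data.frame(site = attr(x, "site"), delay_s = df$delay_s,
                     intensity = df$intensity, frame = attr(x, "frame"),
                     spin_lock_kHz = attr(x, "spin_lock_nu"))
  } else if (inherits(x, "rate_series")) {
    df <- data.frame(site = attr(x, "site"), T_K = df$T_K,
                     `rate_s-1` = df$rate_s1, frame = attr(x, "frame"),
                     spin_lock_kHz = attr(x, "spin_lock_nu"),
                     check.names = FALSE)
  } else if (inherits(x, "dipolar_pattern")) {
    df <- data.frame(site = attr(x, "site"), freq_kHz = df$freq_kHz,
                     intensity = df$intensity,
                     scale_applied = attr(x, "scale_applied"))
  } else if (inherits(x, "dsc_trace")) {
    df <- data.frame(T_K = df$T_K, signal = df$signal, mode = attr(x, "mode"),
                     scan_rate_K_min = attr(x, "scan_rate"))
  } else stop_invalid("unsupported object of class %s", class(x)[1])
  utils::write.csv(df, path, row.names = FALSE)
  truth <- attr(x, "truth")
  if (!is.null(truth)) {
    jsonlite::write_json(truth, paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' @rdname write_spindyn_csv
#' @param path CSV path written by [write_spindyn_csv()] (or following the
#'   same column layout).
#' @param type one of `"decay"`, `"rates"`, `"pattern"`, `"dsc"`.
#' @export
read_spindyn_csv <- function(path, type = c("decay", "rates", "pattern", "dsc")) {
  type <- match.arg(type)
  df <- utils::read.csv(path, check.names = FALSE)
  switch(type,
    decay = decay_curve(df$delay_s, df$intensity, site = df$site[1],
                        frame = df$frame[1], spin_lock_nu = df$spin_lock_kHz[1]),
    rates = rate_series(df$T_K, df[["rate_s-1"]], site = df$site[1],
                        frame = df$frame[1], spin_lock_nu = df$spin_lock_kHz[1]),
    pattern = dipolar_pattern(df$freq_kHz, df$intensity, site = df$site[1],
                              scale_applied = df$scale_applied[1]),
    dsc = dsc_trace(df$T_K, df$signal, mode = df$mode[1],
                    scan_rate = df$scan_rate_K_min[1])
  )
}

#' Write a unit cell as a minimal CIF
#'
#' Emits a single `data_` block in P1: cell parameters, symmetry, and an
#' `atom_site` loop with fractional coordinates. The dialect is the core
#' CIF subset that [read_structure()] parses back.
#'
#' @param cell a [unit_cell()].
#' @param path output path.
#' @param data_name block name after `data_`.
#' @return `path`, invisibly.
#' @export
write_cif <- function(cell, path, data_name = "spindyn") {
  s <- cell$sites
  lines <- c(
    sprintf("data_%s", data_name),
    sprintf("_cell_length_a %.6f", cell$a),
    sprintf("_cell_length_b %.6f", cell$b),
    sprintf("_cell_length_c %.6f", cell$c),
    sprintf("_cell_angle_alpha %.6f", cell$alpha),
    sprintf("_cell_angle_beta %.6f", cell$beta),
    sprintf("_cell_angle_gamma %.6f", cell$gamma),
    "_symmetry_space_group_name_H-M 'P 1'",
    "loop_",
    "_symmetry_equiv_pos_as_xyz",
    "'x, y, z'"
  )
  if (nrow(s)) {
    lines <- c(lines,
      "loop_",
      "_atom_site_label",
      "_atom_site_type_symbol",
      "_atom_site_fract_x",
      "_atom_site_fract_y",
      "_atom_site_fract_z",
      sprintf("%s %s %.6f %.6f %.6f", s$label, s$element, s$x, s$y, s$z))
  }
  writeLines(lines, path)
  invisible(path)
}
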
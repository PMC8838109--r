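#' Magnetization decay curve
#'
#' Container for a single-site relaxation decay: signal intensity versus
#' relaxation delay, in the laboratory frame (T1) or the rotating frame
#' (T1rho, with the spin-lock nutation frequency recorded).
#'
#' @param delays relaxation delays, seconds; strictly increasing.
#' @param intensities signal intensities, arbitrary units.
#' @param site site label (e.g. a carbon number).
#' @param frame `"lab"` or `"rotating"`.
#' @param spin_lock_nu spin-lock nutation frequency, kHz (rotating frame).
#' @param truth optional list of generating parameters (synthetic data).
#' @return an object of class `decay_curve`: a data.frame with columns
#'   `delay_s`, `intensity` and attributes `site`, `frame`, `spin_lock_nu`.
#' @export
decay_curve <- function(delays, intensities, site = "site1", frame = c("lab", "rotating"),
                        spin_lock_nu = NA_real_, truth = NULL) {
  frame <- match.arg(frame)
  if (length(delays) != length(intensities))
    stop_invalid("delays and intensities differ in length")
  if (any(!is.finite(delays)) || any(delays < 0))
    stop_invalid("delays must be finite and non-negative")
  if (is.unsorted(delays, strictly = TRUE))
    stop_invalid("delays must be strictly increasing")
  out <- data.frame(delay_s = as.numeric(delays), intensity = as.numeric(intensities))
  structure(out, class = c("decay_curve", "data.frame"),
            site = site, frame = frame, spin_lock_nu = spin_lock_nu, truth = truth)
}

#' @export
print.decay_curve <- function(x, ...) {
  cat(sprintf("<decay_curve> site %s, %s frame, %d delays [%g, %g] s\n",
              attr(x, "site"), attr(x, "frame"), nrow(x),
              min(x$delay_s), max(x$delay_s)))
  invisible(x)
}

#' Variable-temperature relaxation-rate series
#'
#' Per-site relaxation rates versus temperature, in the laboratory frame
#' (R1 = 1/T1) or rotating frame (R1rho = 1/T1rho).
#'
#' @param temperatures temperatures, Kelvin; all positive.
#' @param rates relaxation rates, s^-1; all positive.
#' @param site site label.
#' @param frame `"lab"` or `"rotating"`.
#' @param spin_lock_nu spin-lock frequency, kHz, or `NA` for lab frame.
#' @param truth optional generating parameters.
#' @return object of class `rate_series`, a data.frame with columns
#'   `T_K`, `rate_s1`.
#' @export
rate_series <- function(temperatures, rates, site = "site1",
                        frame = c("lab", "rotating"), spin_lock_nu = NA_real_,
                        truth = NULL) {
  frame <- match.arg(frame)
  if (length(temperatures) != length(rates))
    stop_invalid("temperatures and rates differ in length")
  if (length(temperatures) == 0L) stop_invalid("empty rate series")
  if (any(temperatures <= 0)) stop_invalid("temperatures must be positive (K)")
  if (any(rates <= 0)) stop_invalid("rates must be positive")
  out <- data.frame(T_K = as.numeric(temperatures), rate_s1 = as.numeric(rates))
  structure(out, class = c("rate_series", "data.frame"),
            site = site, frame = frame, spin_lock_nu = spin_lock_nu, truth = truth)
}

#' @export
print.rate_series <- function(x, ...) {
  cat(sprintf("<rate_series> site %s, %s frame, %d temperatures %g-%g K\n",
              attr(x, "site"), attr(x, "frame"), nrow(x), min(x$T_K), max(x$T_K)))
  invisible(x)
}

#' One-dimensional dipolar powder-pattern slice
#'
#' A frequency/intensity slice through a separated-local-field spectrum
#' (e.g. a vertical slice of a 2D PILGRIM experiment). `scale_applied`
#' records any dipolar scaling factor already present in the data, such as
#' the Lee-Goldburg factor 1/sqrt(3).
#'
#' @param freqs frequency axis, kHz; strictly increasing.
#' @param intensities intensities, arbitrary units, non-negative.
#' @param site site label.
#' @param scale_applied scaling factor already in the data (default 1).
#' @param truth optional generating parameters.
#' @return object of class `dipolar_pattern`.
#' @export
dipolar_pattern <- function(freqs, intensities, site = "site1",
                            scale_applied = 1, truth = NULL) {
  if (length(freqs) != length(intensities))
    stop_invalid("freqs and intensities differ in length")
  if (is.unsorted(freqs, strictly = TRUE))
    stop_invalid("frequency axis must be strictly increasing")
  if (any(intensities < 0)) stop_invalid("intensities must be non-negative")
  if (!(scale_applied > 0 && scale_applied <= 1))
    stop_invalid("scale_applied must be in (0, 1]")
  out <- data.frame(freq_kHz = as.numeric(freqs), intensity = as.numeric(intensities))
  structure(out, class = c("dipolar_pattern", "data.frame"),
            site = site, scale_applied = scale_applied, truth = truth)
}

#' @export
print.dipolar_pattern <- function(x, ...) {
  cat(sprintf("<dipolar_pattern> site %s, %d points, %g to %g kHz, scale_applied %.5g\n",
              attr(x, "site"), nrow(x), min(x$freq_kHz), max(x$freq_kHz),
              attr(x, "scale_applied")))
  invisible(x)
}

#' DSC trace
#'
#' A differential scanning calorimetry curve, either raw heat flow
#' (W g^-1, requiring a scan rate for enthalpy integration) or specific
#' heat capacity (J g^-1 K^-1).
#'
#' @param temperatures temperatures; Kelvin, or Celsius with
#'   `unit = "C"` (converted on construction).
#' @param signal heat flow (W g^-1) or cp (J g^-1 K^-1).
#' @param mode `"heatflow"` or `"cp"`.
#' @param scan_rate scan rate, K min^-1; required (non-zero) for
#'   heat-flow integration.
#' @param unit temperature unit of the input, `"K"` or `"C"`.
#' @param exo_up logical; `TRUE` if exothermic events point up.
#' @param truth optional generating parameters.
#' @return object of class `dsc_trace`, a data.frame with `T_K`, `signal`.
#' @export
dsc_trace <- function(temperatures, signal, mode = c("heatflow", "cp"),
                      scan_rate = 10, unit = c("K", "C"), exo_up = FALSE,
                      truth = NULL) {
  mode <- match.arg(mode)
  unit <- match.arg(unit)
  if (length(temperatures) != length(signal))
    stop_invalid("temperatures and signal differ in length")
  if (unit == "C") temperatures <- temperatures + 273.15
  if (is.unsorted(temperatures, strictly = TRUE))
    stop_invalid("temperatures must be strictly increasing")
  if (mode == "heatflow" && (!is.finite(scan_rate) || scan_rate == 0))
    stop_invalid("heat-flow traces need a non-zero scan_rate (K/min)")
  out <- data.frame(T_K = as.numeric(temperatures), signal = as.numeric(signal))
  structure(out, class = c("dsc_trace", "data.frame"),
            mode = mode, scan_rate = scan_rate, exo_up = exo_up, truth = truth)
}

#' @export
print.dsc_trace <- function(x, ...) {
  cat(sprintf("<dsc_trace> %s mode, %d points, %g-%g K, scan rate %g K/min\n",
              attr(x, "mode"), nrow(x), min(x$T_K), max(x$T_K), attr(x, "scan_rate")))
  invisible(x)
}

#' Crystallographic unit cell with atomic sites
#'
#' @param a,b,c cell lengths, Angstrom.
#' @param alpha,beta,gamma cell angles, degrees, each in (0, 180).
#' @param sites data.frame with columns `element`, `x`, `y`, `z`
#'   (fractional coordinates, wrapped into `[0, 1)`) and optionally `label`.
#' @return object of class `unit_cell`.
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90,
                      sites = NULL) {
  lens <- c(a, b, c)
  angs <- c(alpha, beta, gamma)
  if (any(lens <= 0)) stop_invalid("cell lengths must be positive")
  if (any(angs <= 0 | angs >= 180)) stop_invalid("cell angles must lie in (0, 180) degrees")
  if (is.null(sites)) {
    sites <- data.frame(element = character(), x = numeric(), y = numeric(),
                        z = numeric(), label = character())
  } else {
    sites <- as.data.frame(sites)
    need <- c("element", "x", "y", "z")
    if (!all(need %in% names(sites)))
      stop_invalid("sites needs columns element, x, y, z")
    if (!"label" %in% names(sites)) {
      sites$label <- if (nrow(sites)) paste0(sites$element, seq_len(nrow(sites))) else character()
    }
    unknown <- setdiff(unique(sites$element), names(.bondi_radii))
    if (length(unknown))
      stop_invalid("unknown element symbol(s): %s", paste(unknown, collapse = ", "))
    for (cc in c("x", "y", "z")) sites[[cc]] <- sites[[cc]] %% 1
  }
  structure(list(a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma,
                 sites = sites),
            class = "unit_cell")
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("<unit_cell> a=%g b=%g c=%g A, alpha=%g beta=%g gamma=%g deg, %d site(s)\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma, nrow(x$sites)))
  invisible(x)
}

#' Cell matrix (fractional -> Cartesian)
#'
#' Standard lower-triangular cell matrix: Cartesian coordinates are
#' `M %*% fractional` with `a` along x.
#'
#' @param cell a `unit_cell`.
#' @return 3x3 numeric matrix, Angstrom.
#' @export
cell_matrix <- function(cell) {
  al <- deg2rad(cell$alpha); be <- deg2rad(cell$beta); ga <- deg2rad(cell$gamma)
  v <- sqrt(1 - cos(al)^2 - cos(be)^2 - cos(ga)^2 + 2 * cos(al) * cos(be) * cos(ga))
  matrix(c(cell$a, cell$b * cos(ga), cell$c * cos(be),
           0,      cell$b * sin(ga), cell$c * (cos(al) - cos(be) * cos(ga)) / sin(ga),
           0,      0,                cell$c * v / sin(ga)),
         nrow = 3, byrow = TRUE)
}
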
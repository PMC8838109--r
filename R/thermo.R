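#' Integrate a DSC transition peak to a molar enthalpy
#'
#' Subtracts a baseline interpolated linearly between anchor regions just
#' outside the integration window (the mean signal over `anchor_frac` of
#' the window width on each side), integrates the excess signal over
#' temperature by the trapezoidal rule, divides by the scan rate for
#' heat-flow traces, and scales to molar units.
#'
#' @param trace a [dsc_trace()].
#' @param window temperature window `c(T_lo, T_hi)`, K, inside the trace.
#' @param molar_mass molar mass, g mol^-1 (default simvastatin, 418.57).
#' @param anchor_frac width of each baseline anchor region as a fraction
#'   of the window width.
#' @param baseline `"linear"` (default) or `"sigmoid"` (tanh step between
#'   the anchor levels, weighted by the integrated peak fraction).
#' @return transition enthalpy, kJ mol^-1 (positive for endotherms on an
#'   exo-down trace).
#' @export
integrate_peak <- function(trace, window, molar_mass = simvastatin_molar_mass(),
                           anchor_frac = 0.1, baseline = c("linear", "sigmoid")) {
  stopifnot(inherits(trace, "dsc_trace"))
  baseline <- match.arg(baseline)
  Tlo <- min(window); Thi <- max(window)
  if (Tlo < min(trace$T_K) || Thi > max(trace$T_K))
    stop_invalid("window [%g, %g] K extends outside the trace", Tlo, Thi)
  sel <- trace$T_K >= Tlo & trace$T_K <= Thi
  Tg <- trace$T_K[sel]; y <- trace$signal[sel]
  if (length(Tg) < 5) stop_invalid("window contains too few points")
  aw <- anchor_frac * (Thi - Tlo)
  lo_anchor <- Tg <= Tlo + aw
  hi_anchor <- Tg >= Thi - aw
  y_lo <- mean(y[lo_anchor]); y_hi <- mean(y[hi_anchor])
  T_lo_mid <- mean(Tg[lo_anchor]); T_hi_mid <- mean(Tg[hi_anchor])
  base <- y_lo + (y_hi - y_lo) * (Tg - T_lo_mid) / (T_hi_mid - T_lo_mid)
  excess <- y - base
  if (baseline == "sigmoid") {
    # step positioned at the running integral midpoint of the excess
    cum <- cumsum(c(0, diff(Tg) * (utils::head(excess, -1) + utils::tail(excess, -1)) / 2))
    frac <- if (max(abs(cum)) > 0) cum / cum[length(cum)] else rep(0, length(cum))
    base <- y_lo + (y_hi - y_lo) * pmin(pmax(frac, 0), 1)
    excess <- y - base
  }
  # truncation check: excess still substantial at the window edges
  edge <- max(abs(excess[c(1, length(excess))]))
  if (edge > 0.05 * max(abs(excess)))
    warning(sprintf("window may truncate the peak (edge excess %.3g of max %.3g)",
                    edge, max(abs(excess))))
  area <- pracma::trapz(Tg, excess)                      # (W/g)*K or (J/g/K)*K
  if (attr(trace, "mode") == "heatflow")
    area <- area / (attr(trace, "scan_rate") / 60)       # -> J/g
  if (isTRUE(attr(trace, "exo_up"))) area <- -area       # report endotherm-positive
  abs(area) * molar_mass / 1000                          # kJ/mol
}

#' Transition entropy from enthalpy and temperature
#'
#' For a reversible (equilibrium) solid-solid transition,
#' `dS = dH / T_trans`; inputs in kJ mol^-1 and K, output in
#' J mol^-1 K^-1.
#'
#' @param dH transition enthalpy, kJ mol^-1.
#' @param T_trans transition temperature, K, positive.
#' @return transition entropy, J mol^-1 K^-1.
#' @export
transition_entropy <- function(dH, T_trans) {
  if (any(T_trans <= 0)) stop_invalid("T_trans must be positive (K)")
  1000 * dH / T_trans
}

#' Heat-capacity step across a transition
#'
#' Fits linear baselines to the trace below and above `T_star` (excluding
#' a guard zone of `exclude` K around it), extrapolates both to `T_star`,
#' and returns the drop: below-extrapolation minus above-extrapolation
#' (positive when cp is reduced above the transition).
#'
#' @param trace a cp-mode [dsc_trace()] (J g^-1 K^-1).
#' @param T_star transition temperature, K.
#' @param exclude half-width of the excluded zone around `T_star`, K.
#' @param flank maximum width of each fitting flank, K.
#' @return cp step, J g^-1 K^-1.
#' @export
cp_step <- function(trace, T_star, exclude = 3, flank = 20) {
  stopifnot(inherits(trace, "dsc_trace"))
  if (attr(trace, "mode") != "cp")
    stop_invalid("cp_step needs a cp-mode trace (divide heat flow by the scan rate first)")
  lo <- trace$T_K < (T_star - exclude) & trace$T_K > (T_star - exclude - flank)
  hi <- trace$T_K > (T_star + exclude) & trace$T_K < (T_star + exclude + flank)
  if (sum(lo) < 5 || sum(hi) < 5)
    stop_invalid("need at least 5 points on each side of T_star outside the excluded zone")
  f_lo <- stats::lm(signal ~ T_K, data = trace[lo, ])
  f_hi <- stats::lm(signal ~ T_K, data = trace[hi, ])
  pred <- function(f) unname(stats::predict(f, newdata = data.frame(T_K = T_star)))
  pred(f_lo) - pred(f_hi)
}

#' Entropy integral of a molar heat-capacity curve
#'
#' `dS = int_{T_lo}^{T_hi} cp / T dT` by the trapezoidal rule; the trace
#' signal must be molar cp in J mol^-1 K^-1.
#'
#' @param cp_curve a cp-mode [dsc_trace()] whose signal is molar cp.
#' @param T_lo,T_hi integration limits, K, covered by the curve.
#' @return entropy change, J mol^-1 K^-1.
#' @export
entropy_integral <- function(cp_curve, T_lo, T_hi) {
  stopifnot(inherits(cp_curve, "dsc_trace"))
  if (T_lo < min(cp_curve$T_K) || T_hi > max(cp_curve$T_K))
    stop_invalid("curve does not cover [%g, %g] K", T_lo, T_hi)
  Tq <- sort(unique(c(T_lo, T_hi, cp_curve$T_K[cp_curve$T_K > T_lo & cp_curve$T_K < T_hi])))
  cp <- stats::approx(cp_curve$T_K, cp_curve$signal, xout = Tq)$y
  pracma::trapz(Tq, cp / Tq)
}

#' High-temperature heat-capacity limit of a free rotor
#'
#' The classical one-dimensional free-rotor heat capacity, `R / 2 = 4.157`
#' J mol^-1 K^-1: the asymptote that a hindered-rotor contribution
#' converges to from above. Used to annotate reports when a cp decrease
#' across a transition is detected (a segment rotating freely above the
#' transition no longer needs excitation on heating).
#'
#' @return R/2, J mol^-1 K^-1.
#' @export
hindered_rotor_limit <- function() spindyn_constants$R_gas / 2

#' Characterize a DSC transition
#'
#' Bundles [integrate_peak()] and [transition_entropy()] into a transition
#' record.
#'
#' @param trace a [dsc_trace()].
#' @param T_trans transition temperature, K.
#' @param window integration window, K; default `T_trans +/- 10` K.
#' @param molar_mass molar mass, g mol^-1.
#' @param order_hint `"first"`, `"second"` or `"lambda"`.
#' @return object of class `transition`: list with `T_trans`, `dH_kJmol`,
#'   `dS_JmolK`, `order_hint`.
#' @export
characterize_transition <- function(trace, T_trans, window = T_trans + c(-10, 10),
                                    molar_mass = simvastatin_molar_mass(),
                                    order_hint = "lambda") {
  dH <- integrate_peak(trace, window, molar_mass = molar_mass)
  structure(list(T_trans = T_trans, dH_kJmol = dH,
                 dS_JmolK = transition_entropy(dH, T_trans),
                 order_hint = order_hint),
            class = "transition")
}

#' @export
print.transition <- function(x, ...) {
  cat(sprintf("<transition> T = %g K, dH = %.3g kJ/mol, dS = %.3g J/mol/K (%s)\n",
              x$T_trans, x$dH_kJmol, x$dS_JmolK, x$order_hint))
  invisible(x)
}
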
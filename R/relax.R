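#' Fit a mono-exponential relaxation decay
#'
#' Nonlinear least squares of `I(t) = I0 * exp(-t / T1)` by
#' Levenberg-Marquardt, initialized from a log-linear regression of the
#' positive intensities. An optional stretched-exponential
#' `I0 * exp(-(t/T1)^beta)` is available for inhomogeneous decays; the
#' default is the plain single exponential (one relaxation time per site).
#'
#' @param curve a [decay_curve()] with at least 4 points.
#' @param stretched logical; fit a stretched exponential (default `FALSE`).
#' @return list with elements `T1` (s), `stderr` (s), `I0`, `beta`
#'   (1 unless `stretched`), `residual_sd`, and the `nls` fit object.
#' @export
fit_decay <- function(curve, stretched = FALSE) {
  stopifnot(inherits(curve, "decay_curve"))
  if (nrow(curve) < 4) stop_invalid("need at least 4 points to fit a decay")
  if (diff(range(curve$intensity)) == 0)
    stop_invalid("intensities are all equal; nothing to fit")
  t <- curve$delay_s; y <- curve$intensity
  pos <- y > 0
  if (sum(pos) >= 2) {
    ini <- unname(stats::coef(stats::lm(log(y[pos]) ~ t[pos])))
    T1_0 <- if (is.finite(ini[2]) && ini[2] < 0) -1 / ini[2] else diff(range(t)) / 2
    I0_0 <- exp(ini[1])
  } else {
    T1_0 <- diff(range(t)) / 2; I0_0 <- max(y)
  }
  fit <- tryCatch(
    if (stretched) {
      minpack.lm::nlsLM(y ~ I0 * exp(-(t / T1)^beta),
                        start = list(I0 = I0_0, T1 = T1_0, beta = 1),
                        lower = c(0, 1e-12, 0.2), upper = c(Inf, Inf, 2),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(y ~ I0 * exp(-t / T1),
                        start = list(I0 = I0_0, T1 = T1_0),
                        lower = c(0, 1e-12),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    },
    error = function(e) stop_invalid("decay fit failed to converge: %s (residual range %g..%g)",
                                     conditionMessage(e), min(y), max(y)))
  co <- summary(fit)$coefficients
  list(T1 = unname(co["T1", "Estimate"]),
       stderr = unname(co["T1", "Std. Error"]),
       I0 = unname(co["I0", "Estimate"]),
       beta = if (stretched) unname(co["beta", "Estimate"]) else 1,
       residual_sd = summary(fit)$sigma,
       fit = fit)
}

#' Arrhenius fit of a relaxation-rate series
#'
#' Ordinary least squares of `ln(rate)` on `1/T` (the slope of the linear
#' part of the temperature dependence). The activation energy is
#' `|slope| * R` in kJ mol^-1; the motional branch is `"slow"` for a
#' positive slope (rate rising as temperature falls) and `"fast"` for a
#' negative slope. Weighted regression is available via `weights`.
#'
#' A window containing a rate maximum (the cap-shaped regime where the
#' motional frequency crosses the probe frequency) is not Arrhenius-linear;
#' if an interior maximum is detected a warning advises splitting the
#' window into the two branches.
#'
#' @param series a [rate_series()].
#' @param window optional temperature range `c(T_lo, T_hi)` in K; points
#'   outside are dropped before fitting.
#' @param weights optional regression weights (same length as the
#'   windowed series).
#' @return object of class `arrhenius_result`: list with `E_star`
#'   (kJ mol^-1), `lnA`, `branch`, `stderr_E` (kJ mol^-1), `r_squared`,
#'   `n`, `flat` (TRUE when the series carries no resolvable slope).
#' @export
arrhenius_fit <- function(series, window = NULL, weights = NULL) {
  stopifnot(inherits(series, "rate_series"))
  df <- as.data.frame(series)
  if (!is.null(window)) {
    keep <- df$T_K >= min(window) & df$T_K <= max(window)
    df <- df[keep, , drop = FALSE]
    if (!is.null(weights)) weights <- weights[keep]
  }
  if (nrow(df) < 3) stop_invalid("need at least 3 points in the window")
  x <- 1 / df$T_K
  yl <- log(df$rate_s1)
  flat <- diff(range(yl)) < 1e-12
  if (flat) {
    return(structure(list(E_star = 0, lnA = mean(yl), branch = "fast",
                          stderr_E = 0, r_squared = 0, n = nrow(df), flat = TRUE),
                     class = "arrhenius_result"))
  }
  fit <- stats::lm(yl ~ x, weights = weights)
  sm <- suppressWarnings(summary(fit))  # noiseless series trip summary.lm's perfect-fit warning
  # interior maximum detection: significant concavity of ln-rate in 1/T
  # with the vertex inside the window marks the cap-shaped crossover
  # regime, which is not Arrhenius-linear
  if (length(yl) >= 4) {
    qf <- stats::lm(yl ~ x + I(x^2), weights = weights)
    qc <- suppressWarnings(summary(qf))$coefficients
    if (nrow(qc) == 3 && is.finite(qc[3, "t value"]) &&
        qc[3, "Estimate"] < 0 && qc[3, "t value"] < -3) {
      vertex <- -qc[2, "Estimate"] / (2 * qc[3, "Estimate"])
      if (vertex > min(x) && vertex < max(x)) {
        warning("rate series has an interior maximum; fit the fast and slow branches in split windows")
      }
    }
  }
  sl <- stats::coef(fit)[["x"]]
  se <- sm$coefficients["x", "Std. Error"]
  Rg <- spindyn_constants$R_gas
  structure(list(E_star = abs(sl) * Rg / 1000,
                 lnA = stats::coef(fit)[["(Intercept)"]],
                 branch = if (sl > 0) "slow" else "fast",
                 stderr_E = se * Rg / 1000,
                 r_squared = sm$r.squared,
                 n = nrow(df), flat = FALSE),
            class = "arrhenius_result")
}

#' @export
print.arrhenius_result <- function(x, ...) {
  cat(sprintf("<arrhenius_result> E* = %.3g +/- %.2g kJ/mol, branch %s, R^2 = %.4f, n = %d%s\n",
              x$E_star, x$stderr_E, x$branch, x$r_squared, x$n,
              if (x$flat) " (flat series)" else ""))
  invisible(x)
}

#' Spectral-density parameters for heteronuclear dipolar relaxation
#'
#' Parameter bundle for the BPP model of 13C relaxation by an attached
#' proton. `geometry_factor` multiplies the dipolar prefactor
#' `(3/20) (mu0/4pi)^2 hbar^2 gammaH^2 gammaC^2 / r^6` and carries
#' motional-model geometry (e.g. the jump-modulated fraction for methyl
#' three-site jumps); 1 means the full single-pair coupling is modulated.
#'
#' @param tau_c correlation time, seconds.
#' @param r_CH C-H distance, Angstrom.
#' @param nu_C,nu_H Larmor frequencies, MHz (defaults: 13C/1H at 11.7 T).
#' @param geometry_factor dimensionless multiplier on the dipolar
#'   prefactor.
#' @return object of class `sd_params`.
#' @export
sd_params <- function(tau_c = 1e-10, r_CH = 1.09, nu_C = 125.76, nu_H = 500.13,
                      geometry_factor = 1) {
  vals <- c(tau_c, r_CH, nu_C, nu_H, geometry_factor)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop_invalid("all spectral-density parameters must be positive")
  structure(list(tau_c = tau_c, r_CH = r_CH, nu_C = nu_C, nu_H = nu_H,
                 geometry_factor = geometry_factor),
            class = "sd_params")
}

#' Methyl three-site-jump parameter convention
#'
#' Convenience constructor of [sd_params()] for methyl 13C relaxation
#' driven by three-site jumps about the C3 axis: vibrationally averaged
#' methyl C-H distance `r_CH = 1.115` Angstrom and
#' `geometry_factor = 8/9`, the fraction of the dipolar autocorrelation
#' modulated by rotation of a C-H vector inclined at 70.53 degrees to the
#' jump axis (`1 - P2(cos 70.53)^2`). Both choices are conventions and can
#' be overridden; correlation times depend on them at the tens-of-percent
#' level.
#'
#' @param tau_c correlation time, s.
#' @param nu_C,nu_H Larmor frequencies, MHz.
#' @param ... overrides passed to [sd_params()].
#' @return an [sd_params()] object.
#' @export
methyl_jump_params <- function(tau_c = 1e-10, nu_C = 125.76, nu_H = 500.13, ...) {
  args <- utils::modifyList(
    list(tau_c = tau_c, r_CH = 1.115, nu_C = nu_C, nu_H = nu_H,
         geometry_factor = 8 / 9),
    list(...))
  do.call(sd_params, args)
}

# internal: dipolar prefactor (3/20) (mu0/4pi hbar gH gC / r^3)^2, s^-2
.dd_prefactor <- function(params) {
  cst <- spindyn_constants
  r_m <- params$r_CH * 1e-10
  d <- cst$mu0_over_4pi * cst$hbar * cst$gamma_H * cst$gamma_C / r_m^3  # rad/s
  params$geometry_factor * (3 / 20) * d^2
}

# internal: Lorentzian spectral density, J(w) = tau / (1 + w^2 tau^2), s/rad
.jw <- function(omega, tau) tau / (1 + (omega * tau)^2)

#' Heteronuclear dipolar BPP relaxation rate
#'
#' Lab frame: `R1 = K [ J(wH - wC) + 3 J(wC) + 6 J(wH + wC) ]` with
#' Lorentzian `J(w) = tau / (1 + w^2 tau^2)` and
#' `K = geometry_factor * (3/20) (mu0/4pi)^2 hbar^2 gH^2 gC^2 / r^6`.
#' Rotating frame: Jones-type `R1rho` adding the dominant spin-lock term
#' `1.5 * J(2 w1)` (with `w1 = 2 pi * spin_lock_nu`) to the lab-frame
#' terms. At fixed frequencies the rate is a positive, single-maximum
#' function of the correlation time.
#'
#' @param params an [sd_params()]; `tau_c` may be a vector.
#' @param frame `"lab"` or `"rotating"`.
#' @param spin_lock_nu spin-lock nutation frequency, kHz (rotating frame).
#' @return relaxation rate(s), s^-1.
#' @export
bpp_rate <- function(params, frame = c("lab", "rotating"), spin_lock_nu = 62.5) {
  frame <- match.arg(frame)
  stopifnot(inherits(params, "sd_params"))
  tau <- params$tau_c
  wC <- 2 * pi * params$nu_C * 1e6
  wH <- 2 * pi * params$nu_H * 1e6
  K <- .dd_prefactor(params)
  r <- K * (.jw(wH - wC, tau) + 3 * .jw(wC, tau) + 6 * .jw(wH + wC, tau))
  if (frame == "rotating") {
    w1 <- 2 * pi * spin_lock_nu * 1e3
    r <- r + K * 1.5 * .jw(2 * w1, tau)
  }
  r
}

# internal: correlation time at the rate maximum (fixed frequencies)
.bpp_tau_max <- function(params, frame = "lab", spin_lock_nu = 62.5) {
  f <- function(lt) {
    p <- params; p$tau_c <- exp(lt)
    bpp_rate(p, frame = frame, spin_lock_nu = spin_lock_nu)
  }
  hi <- if (frame == "rotating") log(1e-2) else log(1e-6)
  opt <- stats::optimize(f, c(log(1e-14), hi), maximum = TRUE, tol = 1e-12)
  exp(opt$maximum)
}

#' Invert a relaxation rate to a correlation time
#'
#' Solves `bpp_rate(tau) = rate` on the requested motional branch. The
#' BPP rate is unimodal in `tau`, so any achievable rate has two roots:
#' the fast branch (`tau` below the rate maximum) and the slow branch
#' (`tau` above it).
#'
#' @param rate relaxation rate, s^-1; must not exceed the model maximum.
#' @param params an [sd_params()] (its `tau_c` is ignored).
#' @param frame,spin_lock_nu as in [bpp_rate()].
#' @param branch `"fast"` or `"slow"`.
#' @return correlation time, seconds, satisfying
#'   `bpp_rate(tau) == rate` to 1e-6 relative.
#' @export
invert_rate_to_tau <- function(rate, params, frame = c("lab", "rotating"),
                               spin_lock_nu = 62.5, branch = c("fast", "slow")) {
  frame <- match.arg(frame); branch <- match.arg(branch)
  stopifnot(inherits(params, "sd_params"), is.finite(rate), rate > 0)
  tmax <- .bpp_tau_max(params, frame, spin_lock_nu)
  pmax_ <- params; pmax_$tau_c <- tmax
  rmax <- bpp_rate(pmax_, frame, spin_lock_nu)
  if (rate > rmax * (1 + 1e-12))
    stop_invalid("rate %.6g 1/s exceeds the model maximum %.6g 1/s", rate, rmax)
  if (rate >= rmax * (1 - 1e-10)) return(tmax)
  f <- function(lt) {
    p <- params; p$tau_c <- exp(lt)
    log(bpp_rate(p, frame, spin_lock_nu)) - log(rate)
  }
  iv <- if (branch == "fast") c(log(1e-16), log(tmax)) else c(log(tmax), log(1))
  root <- stats::uniroot(f, iv, tol = 1e-14)$root
  exp(root)
}

#' Correlation time at the R1rho maximum (matching condition)
#'
#' Operational rule for locating the motional correlation time from the
#' temperature of the rotating-frame rate maximum: the motion matches the
#' spin-lock field when its correlation time equals the reciprocal of the
#' spin-lock nutation frequency (e.g. 62.5 kHz -> 16 microseconds).
#'
#' @param spin_lock_nu spin-lock nutation frequency, kHz, positive.
#' @return correlation time, seconds.
#' @export
r1rho_max_tau <- function(spin_lock_nu) {
  if (any(!is.finite(spin_lock_nu)) || any(spin_lock_nu <= 0))
    stop_invalid("spin_lock_nu must be positive (kHz)")
  1 / (spin_lock_nu * 1e3)
}

#' Classify a correlation time as fast- or slow-branch
#'
#' A motion is on the slow branch of the T1 curve when its correlation
#' time exceeds the correlation time of the T1 minimum at the probe
#' frequency (about 8e-9 s near 125 MHz); rates then rise as temperature
#' falls.
#'
#' @param tau_c correlation time, s.
#' @param params an [sd_params()] defining the frequencies.
#' @return `"fast"` or `"slow"` per element of `tau_c`.
#' @export
classify_tau_branch <- function(tau_c, params = sd_params()) {
  tmax <- .bpp_tau_max(params, "lab")
  ifelse(tau_c > tmax, "slow", "fast")
}
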
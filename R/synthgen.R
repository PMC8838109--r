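#' Ground truth for a synthetic Arrhenius rate series
#'
#' Bundles the activation energy and prefactor of the thermally activated
#' process `R = A * exp(+/- E_star / (R T))` together with the noise level
#' and RNG seed used to synthesize data from it.
#'
#' @param E_star activation energy, kJ mol^-1, non-negative.
#' @param A Arrhenius prefactor, s^-1.
#' @param noise_sd relative Gaussian noise level (0 = noiseless).
#' @param seed integer RNG seed, or `NULL`.
#' @return object of class `ground_truth`.
#' @export
ground_truth <- function(E_star, A = 1, noise_sd = 0, seed = NULL) {
  if (!is.finite(E_star) || E_star < 0) stop_invalid("E_star must be >= 0 (kJ/mol)")
  if (!is.finite(A) || A <= 0) stop_invalid("A must be positive (1/s)")
  if (!is.finite(noise_sd) || noise_sd < 0) stop_invalid("noise_sd must be >= 0")
  structure(list(E_star = E_star, A = A, noise_sd = noise_sd, seed = seed),
            class = "ground_truth")
}

#' Synthesize a mono-exponential magnetization decay
#'
#' Emulates a T1 (or T1rho) relaxation measurement: intensities follow
#' `exp(-t / T1_true) * (1 + eps)` with `eps ~ N(0, noise_sd)`.
#'
#' @param T1_true true relaxation time, seconds, positive.
#' @param delays relaxation delays, seconds; non-empty, non-negative.
#' @param noise_sd relative Gaussian noise (0 = noiseless).
#' @param seed RNG seed; recorded in the curve's `truth` attribute.
#' @param site,frame,spin_lock_nu passed to [decay_curve()].
#' @return a [decay_curve()].
#' @export
gen_decay <- function(T1_true, delays, noise_sd = 0, seed = NULL,
                      site = "site1", frame = "lab", spin_lock_nu = NA_real_) {
  if (!is.finite(T1_true) || T1_true <= 0) stop_invalid("T1_true must be positive")
  if (length(delays) == 0L) stop_invalid("delays must be non-empty")
  delays <- sort(unique(as.numeric(delays)))
  ideal <- exp(-delays / T1_true)
  eps <- if (noise_sd > 0) {
    with_local_seed(seed, stats::rnorm(length(delays), sd = noise_sd))
  } else rep(0, length(delays))
  decay_curve(delays, ideal * (1 + eps), site = site, frame = frame,
              spin_lock_nu = spin_lock_nu,
              truth = list(T1_true = T1_true, noise_sd = noise_sd, seed = seed))
}

#' Synthesize a variable-temperature relaxation-rate series
#'
#' Rates follow the Arrhenius law on the requested motional branch:
#' slow branch `R = A * exp(+E_star/(R T))` (rate rising as temperature
#' falls, correlation times longer than the inverse probe frequency);
#' fast branch `R = A * exp(-E_star/(R T))`. `ln R` versus `1/T` is exactly
#' linear when `noise_sd = 0`; relative Gaussian noise is applied
#' multiplicatively otherwise.
#'
#' @param truth a [ground_truth()].
#' @param temperatures temperatures, Kelvin; non-empty, positive.
#' @param branch `"slow"` or `"fast"`.
#' @param site,frame,spin_lock_nu passed to [rate_series()].
#' @return a [rate_series()].
#' @export
gen_rate_series <- function(truth, temperatures, branch = c("slow", "fast"),
                            site = "site1", frame = "lab", spin_lock_nu = NA_real_) {
  branch <- match.arg(branch)
  stopifnot(inherits(truth, "ground_truth"))
  if (length(temperatures) == 0L) stop_invalid("temperatures must be non-empty")
  if (any(temperatures <= 0)) stop_invalid("temperatures must be positive (K)")
  sgn <- if (branch == "slow") 1 else -1
  Rg <- spindyn_constants$R_gas
  rates <- truth$A * exp(sgn * truth$E_star * 1000 / (Rg * temperatures))
  if (truth$noise_sd > 0) {
    eps <- with_local_seed(truth$seed,
                           stats::rnorm(length(temperatures), sd = truth$noise_sd))
    rates <- rates * (1 + eps)
  }
  rate_series(temperatures, rates, site = site, frame = frame,
              spin_lock_nu = spin_lock_nu,
              truth = c(unclass(truth), list(branch = branch)))
}

#' Synthesize an axially symmetric (eta = 0) Pake powder pattern
#'
#' Powder-averages a dipolar doublet over orientations: for each value of
#' `u = cos(theta)` (uniform powder weight) the two transition frequencies
#' are `+/- D_s * (3 u^2 - 1) / 2` with `D_s = scale * D`, so the
#' perpendicular-edge "horns" sit at `+/- D_s / 2` and the horn-to-horn
#' splitting of the noiseless pattern equals `scale * D` (the package's
#' splitting convention: the splitting *is* the effective coupling).
#' Parallel shoulders extend to `+/- D_s`.
#'
#' @param D dipolar coupling constant, kHz, positive.
#' @param scale scaling factor in (0, 1], e.g. [lg_scale()] for
#'   Lee-Goldburg acquisition.
#' @param lb Gaussian line broadening (standard deviation), kHz. A floor of
#'   a quarter of the grid bin is applied so the powder average stays smooth.
#' @param grid frequency axis, kHz; must cover `+/- scale * D`.
#' @param n_orient number of orientations in the powder average.
#' @param noise_sd relative intensity noise (fraction of max intensity).
#' @param seed RNG seed for the noise.
#' @param site site label.
#' @return a [dipolar_pattern()] with `scale_applied = scale`.
#' @export
gen_pake <- function(D, scale = 1, lb = 0.1, grid = seq(-30, 30, by = 0.05),
                     n_orient = 4000, noise_sd = 0, seed = NULL, site = "site1") {
  if (!is.finite(D) || D <= 0) stop_invalid("D must be positive (kHz)")
  if (!(scale > 0 && scale <= 1)) stop_invalid("scale must be in (0, 1]")
  grid <- as.numeric(grid)
  if (is.unsorted(grid, strictly = TRUE)) stop_invalid("grid must be strictly increasing")
  Ds <- scale * D
  if (min(grid) > -Ds || max(grid) < Ds)
    stop_invalid("grid [%g, %g] kHz does not cover +/-%g kHz", min(grid), max(grid), Ds)
  bin <- stats::median(diff(grid))
  sd_eff <- max(lb, bin / 4)
  u <- (seq_len(n_orient) - 0.5) / n_orient
  nu <- Ds * (3 * u^2 - 1) / 2
  lines <- c(nu, -nu)
  # Gaussian kernel accumulation over both transition branches
  intens <- rowSums(exp(-outer(grid, lines, "-")^2 / (2 * sd_eff^2)))
  intens <- intens / max(intens)
  if (noise_sd > 0) {
    eps <- with_local_seed(seed, stats::rnorm(length(grid), sd = noise_sd))
    intens <- pmax(intens + eps, 0)
  }
  dipolar_pattern(grid, intens, site = site, scale_applied = scale,
                  truth = list(D = D, scale = scale, lb = lb,
                               noise_sd = noise_sd, seed = seed))
}

#' Parameters of a two-site exchange pair
#'
#' @param nu_A,nu_B site resonance frequencies, Hz.
#' @param k site-to-site exchange rate constant, s^-1 (for equal
#'   populations, `k` is the A->B = B->A rate).
#' @param T2 transverse decay time, seconds, positive.
#' @param populations length-2 fractions summing to 1.
#' @return object of class `exchange_pair`.
#' @export
exchange_pair <- function(nu_A, nu_B, k, T2 = 0.05, populations = c(0.5, 0.5)) {
  if (!is.finite(k) || k < 0) stop_invalid("k must be >= 0")
  if (!is.finite(T2) || T2 <= 0) stop_invalid("T2 must be positive")
  if (length(populations) != 2L || any(populations < 0) ||
      abs(sum(populations) - 1) > 1e-8)
    stop_invalid("populations must be two non-negative fractions summing to 1")
  structure(list(nu_A = nu_A, nu_B = nu_B, k = k, T2 = T2,
                 populations = populations),
            class = "exchange_pair")
}

#' Two-site chemical-exchange lineshape
#'
#' Symmetric-exchange Bloch-McConnell closed form. The absorption
#' lineshape is `Re[ 1' (Lambda(nu))^-1 p ]` with
#' `Lambda = diag(1/T2 + 2 pi i (nu_j - nu)) + K`, where the kinetic
#' matrix `K` has site-to-site rates `k_AB = 2 k p_B`, `k_BA = 2 k p_A`
#' (so that equal populations give the textbook symmetric rate `k` each
#' way). In the `k -> 0` limit the spectrum is two Lorentzians at the site
#' frequencies; for `k -> Inf` a single Lorentzian at the
#' population-weighted mean. This lineshape is an emulation used for
#' fixtures: broadening/coalescence phenomenology, not a fitted model.
#'
#' @param pair an [exchange_pair()].
#' @param grid frequency axis, Hz, spanning both site frequencies.
#' @return data.frame with columns `freq_Hz`, `intensity` and class
#'   `exchange_spectrum`.
#' @export
gen_exchange_spectrum <- function(pair, grid = NULL) {
  stopifnot(inherits(pair, "exchange_pair"))
  if (is.null(grid)) {
    span <- abs(pair$nu_B - pair$nu_A) + 20 / pair$T2
    mid <- (pair$nu_A + pair$nu_B) / 2
    grid <- seq(mid - span, mid + span, length.out = 2048)
  }
  if (min(grid) > min(pair$nu_A, pair$nu_B) || max(grid) < max(pair$nu_A, pair$nu_B))
    stop_invalid("grid must span both site frequencies")
  p <- pair$populations
  kAB <- 2 * pair$k * p[2]
  kBA <- 2 * pair$k * p[1]
  r2 <- 1 / pair$T2
  # 2x2 complex solve, closed form, vectorized over the grid
  a11 <- r2 + kAB + 2i * pi * (pair$nu_A - grid)
  a22 <- r2 + kBA + 2i * pi * (pair$nu_B - grid)
  a12 <- -kBA
  a21 <- -kAB
  det <- a11 * a22 - a12 * a21
  x1 <- (a22 * p[1] - a12 * p[2]) / det
  x2 <- (a11 * p[2] - a21 * p[1]) / det
  intens <- Re(x1 + x2)
  out <- data.frame(freq_Hz = as.numeric(grid), intensity = intens)
  structure(out, class = c("exchange_spectrum", "data.frame"),
            truth = unclass(pair))
}

#' Synthesize a DSC trace with lambda-shaped transitions
#'
#' Builds a baseline (piecewise-linear cp, optionally with steps) and adds
#' one asymmetric lambda-shaped excess peak per transition: a power-law
#' rise over `5 * width` below the transition temperature and a sharp
#' Gaussian cut of width `width / 4` above it. The shape is a fixture
#' choice; only its integral (the transition enthalpy) and the baseline
#' step are contractually meaningful. Each peak is normalized numerically
#' on the output grid, so trapezoidal re-integration recovers the
#' requested enthalpy up to baseline-estimation error.
#'
#' @param baseline_cp baseline specification: a single number
#'   (constant cp, J g^-1 K^-1) or a data.frame with columns `T_K`, `cp`
#'   interpolated linearly (use two nearby points to encode a step).
#' @param transitions data.frame with columns `T_K` (transition
#'   temperature), `dH_kJmol` (enthalpy, kJ mol^-1) and `width_K`
#'   (peak width parameter, K); `NULL` or zero rows for no transitions.
#' @param T_range temperature range of the trace, K.
#' @param dT grid spacing, K.
#' @param mode `"heatflow"` (W g^-1, excess = cp * beta) or `"cp"`.
#' @param scan_rate scan rate, K min^-1 (heat-flow mode).
#' @param molar_mass molar mass used to convert molar enthalpies to
#'   per-gram signal, g mol^-1; default simvastatin C25H38O5.
#' @param noise_sd absolute Gaussian noise on the signal.
#' @param seed RNG seed.
#' @return a [dsc_trace()].
#' @export
gen_dsc <- function(baseline_cp = 1.2, transitions = NULL,
                    T_range = c(200, 320), dT = 0.05,
                    mode = c("heatflow", "cp"), scan_rate = 10,
                    molar_mass = simvastatin_molar_mass(),
                    noise_sd = 0, seed = NULL) {
  mode <- match.arg(mode)
  Tg <- seq(T_range[1], T_range[2], by = dT)
  cp_base <- if (is.data.frame(baseline_cp)) {
    stats::approx(baseline_cp$T_K, baseline_cp$cp, xout = Tg, rule = 2)$y
  } else rep(as.numeric(baseline_cp), length(Tg))
  excess <- rep(0, length(Tg))  # J g^-1 K^-1
  if (!is.null(transitions) && nrow(transitions) > 0) {
    tr <- as.data.frame(transitions)
    if (any(tr$width_K <= 0)) stop_invalid("transition widths must be positive")
    if (nrow(tr) > 1) {
      ord <- order(tr$T_K)
      gaps <- diff(tr$T_K[ord])
      minsep <- 3 * (utils::head(tr$width_K[ord], -1) + utils::tail(tr$width_K[ord], -1))
      if (any(gaps < minsep))
        warning("transitions closer than 3 widths overlap; integrals may mix")
    }
    for (i in seq_len(nrow(tr))) {
      Tc <- tr$T_K[i]; w <- tr$width_K[i]
      shape <- rep(0, length(Tg))
      rise <- Tg >= (Tc - 5 * w) & Tg <= Tc
      shape[rise] <- ((Tg[rise] - (Tc - 5 * w)) / (5 * w))^4
      fall <- Tg > Tc
      shape[fall] <- exp(-(Tg[fall] - Tc)^2 / (2 * (w / 4)^2))
      area <- pracma::trapz(Tg, shape)
      # dH in kJ/mol -> J/g under the trace
      shape <- shape / area * tr$dH_kJmol[i] * 1000 / molar_mass
      excess <- excess + shape
    }
  }
  cp_total <- cp_base + excess
  signal <- if (mode == "heatflow") cp_total * (scan_rate / 60) else cp_total
  if (noise_sd > 0) {
    eps <- with_local_seed(seed, stats::rnorm(length(Tg), sd = noise_sd))
    signal <- signal + eps
  }
  dsc_trace(Tg, signal, mode = mode, scan_rate = scan_rate,
            truth = list(baseline_cp = baseline_cp, transitions = transitions,
                         molar_mass = molar_mass, noise_sd = noise_sd, seed = seed))
}

#' Molar mass of simvastatin (C25H38O5)
#'
#' @return molar mass, g mol^-1 (418.57).
#' @export
simvastatin_molar_mass <- function() {
  # C 12.011, H 1.008, O 15.999
  25 * 12.011 + 38 * 1.008 + 5 * 15.999
}

#' Build a toy unit cell of hard spheres
#'
#' @param lattice numeric vector `c(a, b, c, alpha, beta, gamma)`
#'   (Angstrom / degrees); angles default to 90 if only lengths given.
#' @param sites data.frame with columns `element`, `x`, `y`, `z`
#'   (fractional), optional `label`; `NULL` for an empty cell.
#' @return a [unit_cell()].
#' @export
gen_toy_cell <- function(lattice, sites = NULL) {
  if (length(lattice) == 3) lattice <- c(lattice, 90, 90, 90)
  if (length(lattice) != 6) stop_invalid("lattice must be length 3 or 6")
  unit_cell(lattice[1], lattice[2], lattice[3],
            lattice[4], lattice[5], lattice[6], sites = sites)
}
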
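---
title: "Methods: solid-state NMR dynamics of polymorphic molecular crystals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: solid-state NMR dynamics of polymorphic molecular crystals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spindyn)
```

## The problem this package addresses

Many molecular crystals — drug substances prominently among them — are not
rigid. Rotatable side chains keep moving in the lattice, and that motion can
drive polymorphism: a compound such as simvastatin passes reversibly through
three crystal forms on cooling, with a dynamically disordered
high-temperature form, an intermediate form with strongly thermally
activated segmental motion, and an essentially rigid low-temperature form.
Establishing such a picture experimentally takes several independent
measurements that must be analyzed jointly:

* **DSC** locates the solid–solid transitions and quantifies their
  enthalpy and entropy;
* **variable-temperature relaxation** (laboratory-frame T1, rotating-frame
  T1rho) gives motional *frequencies* via activation energies and
  correlation times;
* **separated-local-field dipolar spectra** give motional *amplitudes* via
  order parameters;
* **motional models** translate order parameters into geometry (wobble
  angles, jump geometries, rotation axes);
* **NMR crystallography** (GIPAW shielding regression, crystal-geometry
  descriptors) ties the spectroscopy to the structures.

`spindyn` implements this chain as composable, individually tested stages,
together with a synthetic-data generator that emulates every input with
known ground truth. The generator is first-class code: it is what makes the
downstream estimators testable without a spectrometer, and it defines the
study conditions under which the package's self-checks run.

## Relaxation analysis

### Decay fitting

Magnetization decays are fitted as single exponentials
$I(t) = I_0\,e^{-t/T_1}$ by Levenberg–Marquardt least squares, initialized
from a log-linear regression. One relaxation time per site is the model
throughout; a stretched exponential $I_0\,e^{-(t/T_1)^\beta}$ is available
behind a flag for visibly inhomogeneous decays but is off by default. The
reported standard error comes from the nonlinear fit; a Monte-Carlo test
(100 seeded replicates at 5 % noise) checks that it matches the empirical
scatter.

### Arrhenius fits

Thermally activated motion obeys $R = A\,e^{\pm E^*/RT}$, so the
activation energy is taken from an ordinary least-squares fit of
$\ln R$ on $1/T$: $E^* = |{\rm slope}| \cdot R$ in kJ mol⁻¹, with
$R = 8.314462618$ J mol⁻¹ K⁻¹. The *branch* is part of the result: a
positive slope (rate rising as temperature falls) means the motion is
slower than the probe frequency (slow branch), a negative slope means
faster (fast branch). The generator exposes the same branch switch
explicitly rather than fixing one sign convention, because a rate series
alone does not identify the sign of the exponent — only the branch does.
OLS in log space (not a weighted nonlinear fit) matches how activation
energies are conventionally read off the linear parts of such plots;
weights are available as an argument.

A window that contains the rate *maximum* — where the motional frequency
crosses the probe frequency — is not Arrhenius-linear. `arrhenius_fit()`
detects this cap shape by testing for significant concavity of
$\ln R$ in $1/T$ (quadratic term negative with $|t| > 3$ and vertex inside
the window) and warns that the two branches should be fitted in split
windows.

### Spectral densities and correlation times

Rates are connected to correlation times through the heteronuclear dipolar
BPP model with Lorentzian spectral density
$J(\omega) = \tau/(1 + \omega^2\tau^2)$:

$$R_1 = K\,[\,J(\omega_H - \omega_C) + 3 J(\omega_C) + 6 J(\omega_H + \omega_C)\,],
\qquad K = g \cdot \tfrac{3}{20}\left(\tfrac{\mu_0}{4\pi}\right)^2
\frac{\hbar^2\gamma_H^2\gamma_C^2}{r_{CH}^6}.$$

The rotating-frame rate adds the dominant spin-lock term
$1.5\,J(2\omega_1)$ to the laboratory-frame terms, a Jones-type
convention; we document it as such because operationally the
rotating-frame analysis uses only the matching rule below. At fixed
frequencies the rate is positive and unimodal in $\tau$, so
`invert_rate_to_tau()` can return the root on either side of the maximum
(fast/slow branch), verified to reproduce the input rate to $10^{-6}$
relative.

The dimensionless geometry factor $g$ carries the motional-model
convention. For methyl groups treated as three-site jumps about the C3
axis, `methyl_jump_params()` uses $g = 8/9$ — the fraction
$1 - P_2(\cos 70.53^\circ)^2$ of the dipolar autocorrelation modulated by
rotation of a C–H vector inclined at the tetrahedral complement to the
jump axis — together with a vibrationally averaged methyl C–H distance of
1.115 Å. Both are conventions, stated and overridable; inferred
correlation times depend on them at the tens-of-percent level, which is
why the package's self-check on the methyl T1-to-τ mapping is banded at
25 % rather than exact. With these defaults, laboratory-frame T1 values of
0.4–1.1 s at 125 MHz map to correlation times of roughly 0.4–1.1 × 10⁻¹⁰ s,
the range characteristic of fast methyl rotation in molecular crystals.

The rotating-frame *matching rule* is deliberately simple: the correlation
time at the R1rho maximum is taken as the reciprocal of the spin-lock
nutation frequency in Hz (62.5 kHz → 16 μs). This is the operational rule
used when reading a rate maximum off a temperature series, and it is kept
separate from the full spectral-density model so the two cannot silently
disagree.

## Dipolar couplings and order parameters

The rigid-limit one-bond C–H coupling is
$D = (\mu_0/4\pi)\,\gamma_H\gamma_C\hbar/(2\pi r^3)$; 1.09 Å gives
23.3 kHz, consistent with the commonly quoted ca. 23.5 kHz. Under
Lee–Goldburg irradiation, splittings are scaled by the magic-angle cosine.
The package default is the exact value $1/\sqrt{3} = 0.57735$;
`lg_scale(paper_literal = TRUE)` returns $\cos(54.7^\circ) = 0.57786$ for
comparison with work that quotes the rounded angle. Note the two
published anchors are not mutually consistent: 23.5 kHz × 0.577 = 13.57 kHz,
whereas the scaled rigid limit is often quoted as ca. 13.2 kHz. The
package exposes both constants and reconciles nothing silently; per-site
rigid limits can be set via `r_CH` overrides (13.2 kHz corresponds to
r ≈ 1.10 Å after scaling).

An axially symmetric (η = 0) dipolar powder pattern is generated by
numerically averaging the doublet $\pm D_s(3u^2-1)/2$ over uniformly
distributed $u = \cos\theta$; the horns (perpendicular edges) then sit at
$\pm D_s/2$ and the package's splitting convention is **horn-to-horn
separation = effective coupling** $D_s = s\cdot D$, with the 2:1
shoulder-to-horn extent following automatically from the powder average.

Horn positions are one-sided inverse-square-root singularities, and any
line broadening shifts the apparent maxima *inward* by roughly the
broadening width — a bias of about two bins at typical digital
resolutions, larger than the ±1-bin uncertainty the data support.
`extract_splitting()` therefore fits each horn locally with the physical
edge shape (the singularity convolved with a Gaussian, with location,
width, amplitude and baseline free), which recovers the underlying edge
to a small fraction of a bin across couplings of 2–25 kHz and broadenings
up to several bins; plain parabolic interpolation of the maxima is kept
as a fallback method. The reported uncertainty remains one bin — the
digital resolution of the slice — rather than the formal fit error, which
would overstate what such data can support. Horns are accepted only with
prominence ≥ 5 × the robust noise level (MAD of first differences); a
single-horn or flat pattern raises an error pointing at the fast-motion
limit rather than returning a spurious splitting.

The order parameter is the ratio $S = D_{\rm eff}/D_{\rm rig}$ (the field
writes it $S_{CH_2}$, a label this package treats as-is, not as a square
to be rooted). Values marginally above 1, within the stated uncertainty,
are clipped to 1 with a flag; larger overshoots are errors.

## Motional models

Three standard geometries convert order parameters to motion:

* **Small-amplitude wobble**: $S = 1 - \tfrac{3}{2}\langle\theta^2\rangle$
  with θ in radians; `wobble_angle()` is the closed-form inverse
  (exact round trip to $10^{-10}$). The interface is in degrees, internal
  math in radians. The expansion loses meaning beyond
  ~30°, so larger angles are flagged. Note 9° gives S = 0.963, i.e. 0.96
  at two decimals; published pairings of angles and order parameters at
  this level (e.g. 7° with 0.97) are only approximately consistent with
  the formula itself, so comparisons against such pairings are banded, not
  exact.
* **N-site jumps**: $S = \sum_{ij} p_i p_j P_2(\cos\theta_{ij})$ over
  populations and inter-orientation angles. Two equally populated
  orientations at the tetrahedral angle give exactly 1/3 — inside the
  0.33–0.37 band observed for a freely jumping ester methylene. Because a
  Pake splitting is sign-blind, predicted couplings use $|S|$.
* **Uniaxial rotation**: fast rotation about an axis at angle β averages
  the coupling by $P_2(\cos\beta)$: zero at the magic angle, −1/3 at the
  methyl geometry (70.53°).

A motion averages one-bond dipolar couplings when its correlation time is
below 40 μs (configurable; strict inequality, so exactly 40 μs counts as
static).

## DSC analysis

Transition enthalpies are trapezoidal integrals of baseline-subtracted
excess signal over the integration window, divided by the scan rate for
heat-flow traces and scaled to molar units (simvastatin:
418.57 g mol⁻¹ from C₂₅H₃₈O₅). The default baseline is linear between
anchor regions just outside the window — the data themselves do not
identify a baseline model — with a sigmoid (integral-weighted step)
variant behind a flag. Windows that truncate a peak trigger a warning
with the estimated edge excess. Transition entropies are exact algebra,
$\Delta S = \Delta H/T_{\rm trans}$, valid for reversible transitions at
equilibrium. Heat-capacity steps are differences of linear extrapolations
fitted on flanks outside a guard zone around the transition; entropy
integrals are trapezoidal $\int c_p/T\,{\rm d}T$. The free-rotor
heat-capacity limit R/2 = 4.157 J mol⁻¹ K⁻¹ is provided as the documented
asymptote against which a cp *decrease* across a transition is
interpreted (a segment that already rotates freely needs no further
excitation on heating). Temperatures may be supplied in °C (converted on
construction); exo-up and exo-down conventions are declared in metadata.

The generator's λ-shaped peak — a quartic power-law rise over five widths
below the transition with a sharp Gaussian cut above — is a fixture shape:
only its integral and the baseline step are contractually meaningful, and
the peak is normalized numerically on the output grid so re-integration
recovers the requested enthalpy up to baseline error. Transitions closer
than three widths draw an overlap warning rather than an error.

## Shielding–shift regression

MAGRES `ms` blocks are parsed to isotropic shieldings (tensor trace / 3).
Experimental shifts are regressed on computed shieldings per element by
OLS with a free slope; the slope is *not* fixed to −1 by default because
systematic DFT scaling errors are real and a free slope absorbs them; a
fixed-slope(−1) referencing mode exists behind a flag. "Standard
deviation" of the model is the residual standard deviation with $n-2$
degrees of freedom, and adjusted R² uses the matching correction — the
definitions are stated because published agreement statistics rarely
define them. Self-checks calibrate the estimator on synthetic carbons
(500 seeds at 1.45 ppm noise recover a mean residual sd of 1.45 within
0.05). Reproducing a specific published regression exactly requires the
corresponding supplementary shielding and shift tables, which are data,
not code.

## Crystal-geometry descriptors

Structures are read from core-subset CIF (cell, symmetry-operator loop,
atom_site loop) or fixed-column PDB (CRYST1 + ATOM/HETATM), expanded to
P1 by applying every symmetry operator and merging duplicates within
0.3 Å. Coordinates live in fractional space; Cartesian conversion uses
the standard lower-triangular cell matrix. Volumes use the triclinic
closed form. Contacts are periodic minimum-image distances with image
enumeration sufficient for the cutoff (oblique cells included), each pair
reported once with its image shift; the default O…O report cutoff of
3.2 Å is a configurable hydrogen-bond screen, not a physical claim.

The probe-occupiable void fraction is the percentage of cell volume
farther than vdW(atom) + probe radius from every atom. It is estimated on
a regular fractional grid with one level of adaptive refinement: points
whose distance margin to the nearest exclusion surface is smaller than
half a grid-cell diagonal are re-sampled on a 2×2×2 subgrid, which makes
the boundary effectively twice as finely resolved and brings the
0.2 Å-grid estimate within ~0.01 percentage points of the 0.1 Å estimate
on test cells. Radii default to the Bondi set (H 1.20, C 1.70, O 1.52 Å)
and are swappable, because published void figures rarely state their
radii and the result is tolerance-sensitive to them. Reference polymorph
structures from crystallographic databases are licence-gated and must be
supplied by the user; all shipped geometry fixtures are synthetic and
labelled as such.

## Pipeline and regime classification

`run_pipeline()` joins the stages per site and labels motional regimes:
**fast** when $S \le 0.5$ on the fast branch, **rigid** when
$S \ge 0.95$ with a flat rate series (activation energy below
2 kJ mol⁻¹), **intermediate** otherwise. The thresholds live in the
configuration and are labels anchored to the observed bands (fast ester
0.33–0.37; restricted segments 0.91–1.00), not claims about physics.
Transition temperatures come from the DSC stage as inputs to
interpretation; the pipeline does not infer phase boundaries from NMR
alone, and it reports the metrics behind a modulated-phase interpretation
(void fractions, order-parameter trends) without automating that
inference. A missing stage input degrades only its evidence column;
reports are deterministic (no timestamps) so reruns are byte-identical.

## What the synthetic generator does and does not emulate

The generator produces mono-exponential decays with multiplicative
Gaussian noise, exactly Arrhenius rate series on a stated branch, η = 0
powder doublets with Gaussian broadening, symmetric two-site
Bloch–McConnell exchange lineshapes (the k→0 and k→∞ limits and the
classical coalescence at $k = \pi\Delta\nu/\sqrt{2}$ are verified
numerically), λ-shaped DSC transitions on piecewise-linear baselines, and
hard-sphere toy cells. Real spectra additionally contain CSA lineshapes,
spinning sidebands, rf inhomogeneity, t1 noise, temperature gradients
across the rotor, and baseline drifts that none of these fixtures model.
Passing the round-trip suites therefore demonstrates that the estimators
are correct and calibrated *under the stated noise model* — it does not
certify accuracy on instrument data with uncharacterized artifacts.
Noise defaults (2 % relative) are fixture choices, not instrument
calibrations.

## Numerical choices and problem sizes

Powder averages use 4000 orientations; pattern grids in the self-checks
span ±30 kHz at 0.05 kHz bins. Monte-Carlo calibrations use 100–500
seeded replicates; Arrhenius recovery checks use 8-point temperature
series and 200 replicates per activation energy. Void fractions use a
0.2 Å default grid (refined at boundaries) on cells of ≤ ~16 Å edge in
tests. Every stochastic fixture takes an explicit integer seed, each
generator call seeds its own stream and restores the caller's RNG state,
and identical seeds give bit-identical outputs. These sizes keep the full
suite under a minute per module while leaving estimator standard errors
well below the tolerances being asserted.

## Known limitations

* No CSA or quadrupolar relaxation mechanisms; no Lipari–Szabo
  model-free fitting (order parameters here come from dipolar couplings,
  not relaxation).
* No 2D processing: dipolar slices are assumed already extracted; no
  η ≠ 0 tensors; no sideband or pulse-sequence simulation.
* The exchange lineshape is an emulation for fixtures, not a fitted
  model.
* Real calorimetric cp curves are not shipped; entropy-integral checks
  run on constructed curves.
* Peak assignment is input, not output, of the shift regression.
* Void fractions depend on the radii set; comparisons across software
  require matching radii.
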
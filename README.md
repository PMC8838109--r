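# spindyn

Segmental dynamics and polymorph thermodynamics of molecular crystals from
variable-temperature solid-state NMR and DSC.

Molecular crystals with rotatable side chains — many drug substances
included — are rarely rigid. Internal motion can drive enantiotropic
polymorphism: on cooling, a dynamically disordered high-temperature form
may pass through an intermediate phase with strongly thermally activated
motion into an ordered low-temperature form. Establishing such motional
regimes experimentally combines calorimetry (where are the transitions,
what are ΔH and ΔS), relaxation (how *fast* do segments move), dipolar
couplings (how *large* are the motional amplitudes), and NMR
crystallography (how does it all sit in the structure). `spindyn` is for
spectroscopists and materials scientists who want that analysis chain as
composable, tested functions rather than spreadsheet fragments.

## What it computes

* **Relaxation** — mono-exponential T1/T1ρ decay fits; Arrhenius
  activation energies from `ln R` vs `1/T` (`E* = |slope|·R`), with the
  motional branch (slow: rate rises as T falls; fast: opposite) part of
  the result; BPP spectral densities
  `R1 = K [J(ωH−ωC) + 3J(ωC) + 6J(ωH+ωC)]`, `J(ω) = τ/(1+ω²τ²)`, inverted
  to correlation times on either branch; the rotating-frame matching rule
  τ = 1/ν₁ at the R1ρ maximum.
* **Dipolar couplings** — rigid-limit one-bond C–H coupling
  `D = (μ0/4π) γH γC ħ / (2π r³)` (23.3 kHz at 1.09 Å); Lee–Goldburg
  scaling `1/√3`; horn-to-horn splittings extracted from Pake patterns by
  a powder-edge model fit; order parameters `S = D_eff / D_rig`.
* **Motional models** — small-amplitude wobble `S = 1 − (3/2)⟨θ²⟩`;
  N-site jumps `S = Σ p_i p_j P2(cos θ_ij)`; uniaxial rotation
  `S = P2(cos β)`; a 40 μs dipolar-averaging classifier.
* **DSC** — baseline-subtracted peak integration to molar ΔH;
  `ΔS = ΔH/T`; heat-capacity steps; entropy integrals `∫ cp/T dT`; the
  free-rotor limit R/2.
* **NMR crystallography** — MAGRES shielding import; per-element OLS of
  experimental shifts on computed shieldings with residual sd and
  adjusted R²; CIF/PDB import with P1 expansion; cell volumes; periodic
  minimum-image contacts; probe-occupiable void fractions on an
  adaptively refined grid.
* **Pipeline** — per-site regime labels (fast / intermediate / rigid)
  from the joined evidence, with deterministic JSON/Markdown reports.

A synthetic-data generator (`gen_decay`, `gen_rate_series`, `gen_pake`,
`gen_exchange_spectrum`, `gen_dsc`, `gen_toy_cell`) emulates every input
with known ground truth, so the whole chain is testable without a
spectrometer.

## Worked example

Synthetic study of one flexible site through a polymorphic transition
sequence: two λ-transitions in the DSC, a slow-branch Arrhenius series,
and a motionally averaged dipolar pattern.

```r
library(spindyn)

## DSC: two lambda transitions
tr <- gen_dsc(transitions = data.frame(T_K = c(272, 232),
                                       dH_kJmol = c(1.13, 0.46),
                                       width_K = c(1.5, 1.5)))
characterize_transition(tr, 272, window = c(262, 282))
#> <transition> T = 272 K, dH = 1.13 kJ/mol, dS = 4.15 J/mol/K (lambda)
characterize_transition(tr, 232, window = c(222, 242))
#> <transition> T = 232 K, dH = 0.46 kJ/mol, dS = 1.98 J/mol/K (lambda)

## relaxation: activation energy of a slow-branch ester motion
rs <- gen_rate_series(ground_truth(E_star = 30, A = 1e-4, noise_sd = 0.02, seed = 1),
                      seq(240, 270, length.out = 8), branch = "slow", site = "C22")
arrhenius_fit(rs)
#> <arrhenius_result> E* = 29.7 +/- 0.33 kJ/mol, branch slow, R^2 = 0.9992, n = 8

## dipolar: order parameter of a Lee-Goldburg-scaled powder pattern
pat <- gen_pake(D = rigid_limit_D() * 0.35, scale = lg_scale(), lb = 0.1, site = "C22")
fit_pattern(pat)
#> <coupling_result> D_eff 8.16 kHz / D_rig 23.3 kHz -> S2 = 0.350

## motional geometry
wobble_angle(0.96)                            # 9.4 degrees rms wobble
jump_S2(jump_model(c(0.5, 0.5), 109.47))      # 0.333: tetrahedral two-site jump
r1rho_max_tau(62.5)                           # 1.6e-05 s at the R1rho maximum
classify_averaging(r1rho_max_tau(62.5))       # "averaged"
```

Reading the output: the two transitions carry entropies of 4.15 and
1.98 J mol⁻¹ K⁻¹ (ΔH/T), the 29.7 ± 0.33 kJ mol⁻¹ slow-branch activation
energy recovers the generating 30 kJ mol⁻¹ within one standard error, and
the dipolar pattern generated at 35 % of the rigid coupling returns
S² = 0.350 — a motional amplitude far beyond small-angle wobble,
consistent with large-amplitude two-site jumps (the tetrahedral jump
value is exactly 1/3).

`run_pipeline()` assembles the same calls over a YAML/list configuration
into a per-site regime report; see `?run_pipeline` and the methods
vignette (`vignettes/spindyn-methods.Rmd`) for the conventions behind
every stage. A thin command-line wrapper lives at
`inst/scripts/spindyn.R`.

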
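---
title: "Ion-based neuron models: bistability and ionic excitability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ion-based neuron models: bistability and ionic excitability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

Classical Hodgkin–Huxley (HH) theory treats ion concentrations as fixed
parameters.  `ionshift` implements the minimal *ion-based* extension: the
intra- and extracellular concentrations of Na⁺, K⁺ and (optionally) Cl⁻
become dynamical variables, every membrane current moves matter as well as
charge, and a Na⁺/K⁺-ATPase pump with 3:2 stoichiometry feeds free energy
into the gradients.  The state couples the millisecond membrane dynamics
(`V`, potassium activation `n`) to ion dynamics that are roughly five
orders of magnitude slower — the ratio of `1/C_m` to the current-to-
concentration conversion `10·γ/V_i` with `γ = A_m/F`.

The rate equations are, per unit membrane area (mV, ms, mMol/l, µA/cm²),

* `C_m dV/dt = −(I_Na + I_K + I_Cl + I_p) + I_app`
* `dn/dt = φ (α_n(V)(1−n) − β_n(V) n)`
* `dK_i/dt = −(10γ/V_i)(I_K − 2 I_p)`
* `dCl_i/dt = +(10γ/V_i) I_Cl`

with ionic currents `I_X = (g_X,leak + g_X,gated · gate)(V − E_X)` (Nernst
form) or their constant-field (GHK) counterparts, gating factors `m³h` and
`n⁴`, pump current `I_p` saturating at the maximal pump rate, and Nernst
potentials `E_X = (φ_T/z) ln(c_e/c_i)`.  Two exact reductions close the
system:

1. **Fast sodium activation** is eliminated adiabatically, `m = m_∞(V)`.
2. **Sodium inactivation** is replaced by a sigmoidal function of `n`,
   `h(n) = 1/(1 + exp((n − θ)/σ))`, fitted to membrane-model dynamics
   (`fit_h_of_n()`).  A linear fit `h ≈ 1 − n` would go negative at the
   large `n` of the depolarised state; the sigmoid keeps `h ∈ (0,1)`
   everywhere.  The packaged coefficients θ = 0.4837, σ = 0.1143 were
   fitted over constant-current drives from rest to strong depolarisation
   (0–150 µA/cm²), so the fit is constrained on the whole `n` range the
   ion-based model visits, not only around single spikes.

Because all transmembrane currents move ions, the unreduced system carries
an exact conservation law — the membrane potential minus the scaled
intracellular charge concentration is constant — which makes its Jacobian
singular everywhere.  The package therefore eliminates the sodium rate
through the charge constraint

`Na_i = Na_i⁰ − ΔK_i + ΔCl_i + (10γ C_m/V_i)(V − V_0)`,

whose voltage term is tiny (≈ 4.4·10⁻³ mMol/l per 100 mV).  An applied
current is always interpreted as a *sodium* current; the constraint then
carries its ionic bookkeeping automatically, which is exactly the
consistency rule that makes the reduced model structurally stable.
Extracellular concentrations follow from per-species mass conservation
with the volume lever `V_i/V_e = 3`.

## Parameters

All defaults are embedded in `ion_params()`.  The reference concentrations
(Na_i 27, Na_e 120, K_i 130.99, K_e 4, Cl_i 9.66, Cl_e 124 mMol/l)
reproduce the reference reversal potentials 39.74, −92.94 and −68 mV at a
thermal voltage of φ_T = 26.64 mV; the constructor validates this at load
time, which guards against swapped compartment labels.  φ_T itself is
fixed by requiring all three printed reversal potentials simultaneously
rather than assuming a nominal temperature.  Geometry: V_i = 2160 µm³,
V_e = 720 µm³ (extracellular volume fraction ω = 0.25), A_m = 922 µm²,
γ = A_m/F = 9.556·10⁻³.  In this unit system the conversion from µA/cm²
to mMol/l/ms is `10·γ/V` for volumes in µm³ — the factor 10 is the unit
patch made explicit.

Pump model A is a product of sigmoids in `Na_i` and `K_e` saturating at
ρ = 5.25 µA/cm²; their arguments are clamped at ±50 before
exponentiation so that extreme free-energy-starved states can never
produce non-finite currents.  Pump model B is a saturating Hill form
(cubic in sodium site occupancy with half-saturation 10 mMol/l, quadratic
in potassium with 3.5 mMol/l).  Its maximum `Imax_B` = 5.7232 µA/cm² is
calibrated by `calibrate_pump_B()` so that pump B carries exactly the
pump-A current at the default fixed point, which retains the equilibrium
at −68 mV; as expected it comes out slightly above 5.25.

**Variant switches** (`ion_config()`): Nernst vs GHK currents, pump A vs
B, chloride on/off, gated vs leak-only membrane (leak-only drops `n` from
the state entirely, avoiding a spurious neutral direction), and a closed
ECS vs diffusive coupling of `K_e` to a potassium bath
(λ = 2.7·10⁻⁵ /ms, bath level 4 mMol/l).

### GHK permeabilities

For the GHK variants, permeabilities are derived from the conductances by
requiring equal GHK and Nernst currents under the reference equilibrium
conditions; the conversion factor `P/g` is per ion species and shared by
leak and gated channels.  Chloride is degenerate at the matching point
(its reversal potential *is* the resting potential, so both currents
vanish); the package resolves this by the l'Hôpital limit of the same
condition — matching the GHK slope conductance at the reversal.  This
construction yields `P/g` = 0.0342, 0.1506 and 0.1033 (µm/s per mS/cm²)
for Na, K and Cl.  A published table of permeabilities for this model
family prints substantially different values (e.g. 0.0264 µm/s for the
sodium leak); those values are *not* reproducible from the stated
construction — the required sodium conversion exceeds the mathematical
upper bound `φ_T/(F·min(Na_i, Na_e))` of any constant-field chord
matching at any voltage, in any consistent unit system.  The package
keeps the physically derived values; with them the GHK and Nernst
variants have identical equilibrium currents by construction and fixed
points within 2·10⁻⁴ mV of each other.

## What the package computes

**Simulation** (`simulate_model()`): lsoda integration (default rtol 1e-8,
atol 1e-10), segmented exactly at protocol edges (pulse on/off, pump
off/on) so discontinuities are never stepped over.  `detect_events()`
finds spikes (upward 0 mV crossings), sustained depolarisation (V above
−40 mV, the midpoint between the resting and near-Donnan potentials, for
at least 5 s) and classifies the terminal regime.  The −40 mV threshold
and the 5 s minimum separate spikes from free-energy-starvation robustly;
classification `PHYSIOLOGICAL` requires the terminal V within 2 mV of
rest and `K_e` within 10 % of its reference, which for the buffered model
is only reached on the hours scale (full recovery is asymptotic).

**Fixed points** (`find_fixed_point()`): damped Newton iteration with
central finite-difference Jacobians (relative step 1e-6), residuals
scaled per variable (fast variables by 1, ion rates by 1e-4) so both
timescales count comparably, step halving on residual increase or domain
violation.  `donnan_state()` solves the pump-off limit: all reversal
potentials equal to the membrane potential under electroneutral
redistribution.  The Newton seed comes from the closed-form
electroneutral construction (a single scalar root for the common cation
ratio), after which the full system including the tiny voltage term is
refined.  Newton from arbitrary far-away states can stall on the domain
boundary — use the provided seeds (reference state, Donnan state, or a
trajectory endpoint).

**Continuation** (`trace_branch()`): pseudo-arclength with secant
predictor and bordered Newton corrector; variables scaled by 100 mV /
100 mMol/l / 1, pump rate by 5 µA/cm².  Steps grow ×1.3 after fast
convergence (≤4 iterations) and halve on failure; solutions that do not
advance along the tangent, or that land much farther than the trust
region (5 step lengths; 25 on the first step, whose tangent is crude),
are rejected — this prevents silent branch retracing and fold hopping.
Limit points are flagged by a determinant sign change together with a
parameter-direction reversal, Hopf points by a sign change of the largest
real part over complex eigenvalue pairs; both are refined by bisection in
arclength to a parameter bracket below 1e-4.  `bistable_range()` returns
the two edges of bistability: the fold that annihilates the physiological
state (minimal physiological pump rate) and the Hopf that destabilises
the depolarised state (minimal recovery pump rate).
`bistable_range_scan()` is a deliberately independent brute-force oracle
(grid scan plus Newton and bisection) used to cross-check the
continuation to better than 1 %.

**Two-parameter curves** (`two_parameter_curve()`): the LP/HB loci over
the membrane-surface scale ζ ∈ [0.1, 10] or the extracellular volume
fraction ω ∈ [0.02, 0.5], computed by the re-fetch strategy (a fresh
one-parameter detection per second-parameter value, warm-started) rather
than bordered codimension-1 continuation; the choice is declared in the
result metadata and trades speed for robustness across folds.

**Nullclines** (`nullcline_curve()`, `nullcline_intersections()`): the
slow-subsystem nullclines in the (K_i, Na_i) projection, with the fast
fixed-point conditions (and bath stationarity, when buffered) imposed
along the curves.  Because the curves are multivalued in this projection,
intersections are *counted* by enumerating fixed points from seeded
Newton solves (physiological state, Donnan state and interpolants,
deduplicated by scaled distance); every intersection of the curves is a
genuine fixed point since the remaining chloride rate vanishes by charge
conservation.  The unphysical regions of the projection are bounded by
the zero-level sets of the derived extracellular concentrations.

## Results the test-suite reproduces

With the default parameters the package finds the physiological fixed
point at V = −68.0 mV with all concentrations within 0.1 % of the
reference table, and a second, strongly depolarised stable fixed point
(V ≈ −24.4 mV, K_e ≈ 44 mMol/l, Na_e ≈ 25 mMol/l) with nearly collapsed
gradients — the free-energy-starved (FES) state.  A 1 s, 150 µA/cm²
sodium pulse and a 30 s pump interruption terminate in the *same* FES
point to 15 digits.  Continuation of the fixed point in the pump rate
yields a z-shaped branch with two limit points (ρ ≈ 0.98 and ≈ 205) and
three subcritical Hopf points (ρ ≈ 38.0, 66.9, 69.7); the system is
bistable for 0.98 < ρ < 38.0, comfortably bracketing the default 5.25.
One detail of the fine structure differs from the published analysis of
this model family: there the two non-recovery Hopf points lie on the
middle (saddle) section between the folds, here they sit on the upper
section between the second fold and the recovery Hopf, and at the default
pump rate the depolarised point is a stable node rather than a focus.
These features belong to the unstable limit cycles the published analysis
itself calls physiologically irrelevant; they are sensitive to the exact
`h(n)` reduction, whose published functional form was not available to
this implementation.

Across the eight gated variants the recovery-to-baseline ratio spans 5.1
(GHK, pump A, chloride) to 44.6 (Nernst, pump B, no chloride) — the
qualitative conclusion that Na⁺/K⁺ pumps alone cannot plausibly recover a
neuron from FES (the published span starts near threefold; our floor is
higher, again through the GHK/permeability route).  No leak-only variant
is bistable, all pump-A variants tolerate lower pump rates than pump-B
variants, and the chloride-including variants have the lower recovery
thresholds.  Scaling the membrane surface by ζ ∈ [0.1, 10] moves the
bifurcation pump rates by < 0.1 % (the fixed-point equations are
ζ-independent up to the tiny charge term, and the pumps are saturated at
the Hopf points), while shrinking ω lowers the recovery rate strongly and
monotonically and the physiological limit far less — cell swelling helps
recovery.  The computed Donnan potential is −24.6 mV with chloride and
−6.5 mV without: including the redistributing anion *lowers* (polarises)
the pump-free equilibrium, consistent with the mechanism that a falling
Cl_i forces the cation sum down and with it the cation Nernst potentials.

With potassium-bath coupling the FES fixed point disappears (one
nullcline intersection instead of three) and the same stimulus produces a
large transient excursion instead: ≈ 70 s above −40 mV, a
hyperpolarised undershoot below −80 mV, and an asymptotic return to rest
on the two-hour scale — ionic excitability.  In this implementation the
membrane potential lingers several mV below rest for tens of minutes
before the final approach, so "resting potential recovered to within
5 mV" is reached later than the published nine-to-ten-minute functional
recovery; spiking capability returns much earlier.

## Problem sizes and numerical choices

The test-suite and the acceptance script use the study conditions
directly (150 µA/cm² / 1 s pulses, 30 s pump interruptions, λ =
2.7·10⁻⁵/ms, default geometry).  Long-horizon integrations are run to
10⁴ s for the Donnan limit and 7.2·10³ s for the excitability
classification; continuation uses up to 6000 arclength steps for the
full z-branch and early-stopping traces for the per-variant ranges.
Halving the solver tolerances moves terminal potentials by < 0.1 mV; the
conserved charge combination drifts by < 10⁻⁶ relative over 1000 s.

What the synthetic scenarios do *not* emulate: osmotic volume dynamics
(volumes are static parameters), spatial propagation, temperature
dependence (φ_T is fixed by the reversal-potential table), and any
detailed multi-channel membrane; conclusions about real tissue transfer
only insofar as the minimal model does.
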
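# ionshift

Ion-based Hodgkin–Huxley neuron models with dynamic ion concentrations,
Na⁺/K⁺-ATPase pumps, and the numerical machinery — stiff simulation, fixed
points, pseudo-arclength continuation — to analyse when ion homeostasis is
bistable and when it is excitable.

## The problem

When a neuron fires, the charge it moves is negligible against the free
energy stored in its transmembrane ion gradients.  In migraine aura,
stroke and brain trauma, however, those gradients can nearly vanish: the
cell falls into a *free-energy-starved* (FES) state — strongly
depolarised, electrically silent, with almost flat Na⁺/K⁺/Cl⁻ gradients.
`ionshift` implements the minimal biophysical model family in which this
happens: the classical HH membrane (leak + gated Na⁺/K⁺ currents,
optional Cl⁻) extended so that every current moves ions between the
intra- and extracellular compartments, with a 3:2 Na⁺/K⁺ pump driven at
maximal rate ρ.  Mass conservation and an exact charge-potential
conservation law reduce the closed model to the state `(V, n, K_i, Cl_i)`:

```
C_m dV/dt   = −(I_Na + I_K + I_Cl + I_p) + I_app
   dn/dt    = φ (α_n(1−n) − β_n n)
   dK_i/dt  = −(10γ/V_i)(I_K − 2 I_p)
   dCl_i/dt = +(10γ/V_i) I_Cl,        γ = A_m / F
```

with `I_X = (g_leak + g_gated·gate)(V − E_X)` or the GHK constant-field
equivalent, and `Na_i` recovered from the charge constraint.  The package
asks, and answers, the bifurcation-theoretic question: for which pump
rates do the physiological and FES states coexist (bistability), and what
turns that bistability into transient, excitable dynamics (coupling
extracellular K⁺ to a glial/vascular bath)?

For whom: computational neuroscientists studying spreading
depolarization, anoxic depolarization and seizure-related ion dynamics,
and anyone needing a compact, fully-tested reference implementation of
ion-based HH modelling with continuation analysis in R.

## Worked example

```r
library(ionshift)

## the default model: Nernst currents, pump A at 5.25 uA/cm^2, chloride
fp <- find_fixed_point()
fp
#> <ion_fixed_point> V = -68.001 mV  [4,0] STABLE_NODE  (rho = 5.25, residual 2.9e-14)

## a 1 s, 150 uA/cm^2 sodium pulse drives the cell into the second
## stable state: spiking, then sustained depolarisation
tr <- simulate_model(protocol = protocol_na_pulse(amplitude = 150),
                     t_end = 500e3, n_out = 4000)
detect_events(tr)
#> <ion_events> 40 spikes; FES 10.2 s -> end of run ; terminal: FES

## where did it land?  refine the endpoint by Newton:
nm <- c("V", "n", "K_i", "Cl_i")
y  <- unlist(tr[nrow(tr), nm])
tidy(find_fixed_point(guess = y))
#> V = -24.4 mV, K_e = 44.0, Na_e = 25.4 mMol/l ... (gradients collapsed)

## bistable range of pump rates: fold below, Hopf above
br <- bistable_range()
c(br$rho_min_phys, br$rho_recovery)
#> [1]  0.9806048 37.9633999     # 5.25 sits comfortably inside

## potassium-bath coupling makes the system excitable instead
ex <- excitability_run(t_end = 7.2e6)
ex$events
#> <ion_events> 40 spikes; FES 10.2 s -> 79.4 s (duration 69.2 s) ; terminal: PHYSIOLOGICAL
```

The first call pins the resting state at −68 mV (the chloride reversal
potential, since chloride is not pumped).  The pulse run shows the
defining bistability: the trajectory never returns, ending in the
depolarised fixed point with extracellular potassium risen from 4 to
44 mMol/l.  `bistable_range()` quantifies it: the physiological state
exists for ρ > 0.98 µA/cm², but recovery from the FES state needs
ρ > 38 µA/cm² — over seven times the physiological pump rate, which is
why pumps alone cannot rescue the neuron and an extracellular potassium
bath (glia, vasculature) is needed; with it, the same stimulus produces
only a ~70 s transient.

Other entry points: `trace_branch()` (full z-shaped bifurcation diagram
with LP/HB detection), `variant_sweep()` (all eight
Nernst/GHK × pump A/B × chloride variants plus leak-only controls),
`two_parameter_curve()` / `geometry_sweep()` (membrane surface and
extracellular volume fraction), `nullcline_intersections()`,
`donnan_state()`, `autoplot()` on trajectories and branches, and a thin
CLI at `inst/cli/ionshift`.

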
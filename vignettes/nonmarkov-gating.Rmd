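---
title: "Semi-Markov gating of thermosensitive TRP channels: models, numerics and design choices"
author: "trpgating"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-Markov gating of thermosensitive TRP channels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trpgating)
```

## The model and its assumptions

A gating scheme in this package is an alternating-renewal (semi-Markov)
process on a linear chain of conformational states: C ⇌ O, or
C1 ⇌ C2 ⇌ O. The residence time in each state is drawn independently
from that state's dwell law; only when every law is exponential does
the process reduce to a memoryless Markov chain. Four dwell families
are supported, chosen so that each either has a closed-form Laplace
transform or one that is cheap to evaluate:

* **exponential** (rate λ) — the Markov limit; hazard constant;
* **gamma** (shape κ, scale θ_s) — multi-stage relaxation; hazard
  increasing for κ > 1;
* **stretched-exponential** (stretch b ∈ (0, 1], scale θ_s) — a broad,
  sub-exponential spectrum of rates;
* **Pareto** (tail exponent α, cut-off t_m) — scale-free heavy tails;
  the mean is infinite for α ≤ 1, and `dwell_mean()` reports `Inf`
  explicitly rather than overflowing.

The key assumptions are that successive dwells are independent
(renewal property), that the chain is linear (no loops other than the
alternation itself), and that conductance takes only two levels: every
closed state is electrically silent. The semi-Markov kernel at the
branching state C2 uses the standard competing-risks construction: the
dwell is drawn from C2's law and the destination (O or C1) from a
Bernoulli branch with probability `p_c2_open`, which corresponds to
k(C2→O)/(k(C2→O) + k(C2→C1)) in rate language.

Two re-entry conventions are provided for the three-state chain. The
strict linear chain returns from O to C2 (`o_reentry = "C2"`). The
renewal-cycle convention (`o_reentry = "C1"`) makes every closing
restart the closed-side relaxation from the first closed stage —
Closed1 → Closed2 → Open → Closed1 — which is the natural reading of an
energy-dissipating, "each closed state is new" gating cycle, and is the
convention under which the observed closed residence time is the full
two-stage first-passage time. The default is the strict chain; the
discrimination study (below) uses the cycle and says so.

## Temperature, voltage, and the gating asymmetry

Rates follow the Eyring form k = ν₀·exp(−ΔG/RT). Energies are molar
(J/mol, gas constant R); `gating_constants()` exposes R, k_B and
Avogadro's number for the per-molecule convention. Temperature is
kelvin everywhere internally; Celsius is accepted only at I/O
boundaries (`temperature_C` columns), which avoids offset bugs inside
exponentials. Voltage enters twice: a linearized driving
k(t) ≈ k(0)(1 − βV_s) for small signals around the holding potential
(clamped at zero with a warning when the first-order expansion would go
negative, since a negative rate is unphysical), and a multiplicative
Boltzmann factor on the conductance surface of the synthetic generator.

The open/closed asymmetry is

ε(T) = ΔH − T·ΔS + RT·ln(1 + k_c1·τ_r),

with the sign convention, fixed here and used consistently, that
ε > 0 favours the closed state (P_O < ½). P_O = 1/(1 + e^{ε/RT})
crosses ½ at T\* = ΔH/ΔS when the memory term vanishes; ΔH, ΔS > 0
gives heat activation, ΔH, ΔS < 0 cold activation. τ_r is treated as a
free non-negative relaxation-time parameter, and k_c1 is identified
with the reciprocal mean residence time of the first closed stage.

**An identifiability fact that shaped the design.** With a constant
memory product m = k_c1·τ_r, the correction RT·ln(1 + m) is *linear in
T* and therefore exactly collinear with the entropy term: equilibrium
conductance–temperature data alone cannot distinguish a non-Markov model
with (ΔS, m) from a Markov model with entropy ΔS − R·ln(1 + m). The
package handles this two ways. First, `epsilon_with_memory()` lets the
memory rate itself follow an Eyring law,
m(T) = m_ref·exp[−E_a/R (1/T − 1/T_ref)], which bends the correction
away from linearity; on noiseless data a Markov fit to such a surface
leaves a systematic residual trend that the reported Wald–Wolfowitz
runs test flags, although at realistic noise (sd ≈ 0.03) the curvature
is far below detectability. Second — and this is the package's primary
discrimination route — the memory term is tested where it actually
lives: in the dwell-time record. A hidden closed stage makes the
observed closed residence distribution non-exponential, and
`fit_dwell_model()` compares exponential (`markov_2`) against gamma
(`nonmarkov_2`) residence laws by AIC on the collapsed open/closed
record. With memory product 2 and a few hundred sojourns the
non-Markov model wins by ΔAIC > 2 in essentially all replicates.

## Occupancy solvers and their numerics

Three routes to P_O(t) cross-validate each other:

1. **Monte Carlo** (`mc_occupancy`): trajectories sampled by
   inverse-CDF draws from each dwell law. One root seed spawns a
   deterministic child seed per trajectory, so results are independent
   of batching. The final, truncated dwell of each trajectory is
   excluded from dwell statistics to avoid length-biased means.
2. **Closed-form master equation** (`master_equation_occupancy`) in the
   exponential (Markov) limit.
3. **Laplace-domain renewal equation** (`gme_occupancy_laplace`)
   inverted numerically. The inverter is a Bromwich-trapezoid with
   Euler (binomial) acceleration; the discretization level A = 18.4
   bounds the aliasing error near e^{−A} ≈ 1e−8. The inverter
   estimates its own error by re-summing with more terms and *fails
   loudly with diagnostics* rather than returning values outside the
   requested accuracy (default 1e−6 relative for smooth transforms;
   heavy-tailed targets should be requested at 1e−3). Complex-argument
   dwell transforms are available in closed form for the exponential
   and gamma families, which is where the Laplace route is supported;
   heavy-tailed laws are handled by simulation and by Tauberian
   analysis instead.

`tauberian_tail()` classifies the long-time approach to equilibrium
from the small-s structure of ψ̂: exponential/exponential gives
relaxation at rate k_o + k_c; a Pareto closed law with α ∈ (0, 1) gives
ψ̂_C(s) ~ 1 − c·s^α and a power-law tail of exponent α (for a Pareto
law the hazard is exactly α/t). Time grids are geometric
(`log_time_grid`) so both the fast relaxation and slow tails are
resolved. Occupancy normalization holds to 1e−9 for analytic curves
and exactly for Monte-Carlo fractions.

Temperature couples to non-exponential laws minimally: the law's mean
is rescaled to the reciprocal Eyring rate at each temperature, shape
parameters fixed. This is an assumption, not a derivation; it
preserves effective (reciprocal-mean) rates by construction while
letting hazard shapes differ. Effective rates are *reported as
reciprocal mean residence times*, the dimensionally consistent reading
of a rate defined from a mean dwell.

## The synthetic generator

`generator_profile()` freezes the study conditions:

* `trpv1_like` (heat): ΔH = 200 kJ/mol, ΔS = 635 J/(mol K), so
  T\* ≈ 315 K — activation just above 42 °C; temperatures 296–331 K in
  5 K steps.
* `trpm8_like` (cold): ΔH = −150 kJ/mol, ΔS = −520 J/(mol K),
  T\* ≈ 288 K; temperatures 273–308 K.
* both: voltage ladder −120..+160 mV in 20 mV steps; multiplicative
  Boltzmann voltage factor (V_half = 0 mV, slope 40 mV); barriers
  26–30 kJ/mol with ν₀ = 10⁶ s⁻¹ (dwell times of tens of
  milliseconds); truncated-Gaussian noise, sd 0.02 by default,
  clipped to [0, 1]; three replicates per condition.

These thermodynamic values are synthetic conventions chosen for the
correct activation polarity and steepness, and are marked as such in
the dataset metadata; they are not fitted experimental constants. The
generator emulates plateau-conductance surfaces with replicate noise;
it does **not** emulate raw current traces, instrument filtering,
capacitance/leak artefacts, rundown, or ligand modulation
(capsaicin/menthol), so passing tests demonstrate correctness of the
estimators under the stated statistical model, not robustness to those
experimental realities. Every dataset is a pure function of
(profile, seed).

## Fitting design

`fit_equilibrium_model()` minimizes (optionally sd-weighted) squared
conductance residuals with multi-start Nelder–Mead: one van't Hoff warm
start plus seeded random restarts (8 by default), a final polish at
tighter tolerance, and covariance from the numerical Hessian of the
chi-square surface (z intervals when the noise sd is known; t
intervals with the estimated residual variance otherwise). Records are
sorted before fitting, so fits are invariant to row order. The attempt
frequency ν₀ is never free — freeing it alongside barriers creates a
perfect prefactor/barrier ridge. Three-state equilibrium fits fix the
closed–closed ratio c21 by configuration, honouring the accounting
that only four of the six rate coefficients are identifiable
(`count_parameters("markov_3")` returns (6, 4)); requests with more
free parameters than the cap are refused with an explanatory message
rather than silently fitted. The two-state chain is counted fully
identifiable, (2, 2), from the two observable dwell distributions; the
view that the two-state system is likewise under-determined is noted
as a discrepancy with standard dwell-time identifiability and not
adopted. AICc replaces AIC whenever n/k < 40. p_open values are
clipped to [1e−6, 1 − 1e−6] before ln K, bounding |ln K| by
ln((1−c)/c) ≈ 13.8.

Dwell-law likelihoods use `fitdistrplus` for the exponential, gamma
and Weibull (stretched-exponential) families; the Pareto MLE is closed
form (t̂_m = min x, α̂ = n/Σln(x/t̂_m)). A fitted Weibull shape above 1
is clamped to the stretched regime with a warning. Fits with fewer
than 50 events per state warn about wide intervals instead of failing.

## Study conditions and what the checks compute

The packaged studies run at sizes chosen to be statistically decisive
for the properties they check: Markov-limit agreement at 10⁴
trajectories over a 12-point geometric grid (Monte Carlo within
3·stderr pointwise; Laplace inversion within 1e−6 relative of the
closed form); the renewal-reward limit for gamma dwells (means 0.5 s
closed, 0.2 s open; long-time P_O = 0.2/0.7) at 3000 trajectories and
t = 35 s; Tauberian survival slopes over two decades from 10⁵ events;
ΔH/ΔS recovery over 100 seeded 8-temperature datasets at noise sd
0.03 (median relative errors ≈ 5–6%, 95% CI coverage in the
mid-90s); and Markov/non-Markov discrimination over 100 seeded
records of ~200 observed sojourns each (memory product 2; non-Markov
ΔAIC wins in ≈ 97–100% of replicates). `scripts/acceptance.R` recomputes
all of these from a single seed.

## Known limitations

* The Laplace-domain solver covers the two-state scheme with
  exponential/gamma laws; other laws go through simulation.
* No inference from raw current traces (idealization, missed events,
  filtering); inputs are idealized dwell lists or conductance tables.
* The equilibrium memory parameter m_ref is weakly identified from
  conductance data by construction (the collinearity above); treat its
  equilibrium estimate as diagnostic and rely on dwell-time fits for
  memory inference.
* The linearized voltage driving is first-order only; large drivings
  clamp at zero rather than following the full exponential law.
* Three-state occupancy is simulation-only; its equilibrium fit uses a
  fixed closed–closed ratio rather than freeing all rate coefficients.
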
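# trpgating

Semi-Markov (alternating-renewal) gating models for thermosensitive TRP
ion channels.

## The problem

Thermosensitive TRP channels — TRPV1, activated by noxious heat, and
TRPM8, activated by cold — switch stochastically between conducting
(open) and non-conducting (closed) conformations. The standard Markov
state description assigns a constant rate to every transition, which
forces all residence (dwell) times to be exponential and makes the
process memoryless. Real gating dissipates energy and responds to
temperature: closed sojourns traverse hidden relaxation stages, dwell
distributions become non-exponential, and effective opening and closing
rates are asymmetric. `trpgating` implements the more general
alternating-renewal (semi-Markov) description, in which each state
carries an arbitrary residence-time law, together with the
thermodynamics that couples gating to temperature and voltage. It is
aimed at channel biophysicists who want to simulate such processes, fit
them to conductance–temperature–voltage data or idealized dwell lists,
and test Markov against non-Markov descriptions.

## The model

Each state of a two-state (C ⇌ O) or three-state (C1 ⇌ C2 ⇌ O) chain
carries a dwell law ψ(t) (exponential, gamma, stretched-exponential, or
Pareto). Transition rates follow the Eyring form

    k_{o,c}(0) = ν₀ exp[ −ΔG_{O,C}(V₀) / RT ],

with a linearized voltage driving k(t) ≈ k(0)(1 − β V_s(t)). The
open/closed free-energy asymmetry is

    ε(T) = ΔH − T·ΔS + RT·ln(1 + k_c1 τ_r),

whose last term is the memory correction contributed by a hidden closed
stage (rate k_c1, relaxation time τ_r); the equilibrium open probability
is the Boltzmann map P_O = 1/(1 + e^{ε/RT}), crossing ½ at the
half-activation temperature T* = ΔH/ΔS when the memory term vanishes.
State occupancies are computed three ways — Monte-Carlo simulation, the
closed-form Markov master equation, and numerical inversion of the
Laplace-domain renewal (generalized master) equation

    P̂_O(s) = ψ̂_C(s)(1 − ψ̂_O(s)) / [ s (1 − ψ̂_C(s) ψ̂_O(s)) ],

with Tauberian small-s analysis classifying the long-time tail
(exponential relaxation in the Markov limit; power-law of exponent α for
heavy-tailed closed dwells). Analysis-side, the package provides
Boltzmann G–V fits, van't Hoff extraction of ΔH/ΔS/T*, Q10, dwell-law
maximum likelihood, equilibrium model fits with identifiability
accounting (the three-state Markov chain has 6 rate coefficients but
only 4 identifiable parameters), and AIC model comparison.

## Worked example

```r
library(trpgating)

# a synthetic heat-activated dataset (voltage ladder -120..+160 mV,
# temperatures 296..331 K), fully reproducible from the seed
profile <- generator_profile("trpv1_like", noise_sd = 0.02, seed = 42)
dataset <- generate_gv_dataset(profile)

# conductance-temperature curve at +80 mV and van't Hoff analysis
curve <- g_vs_temperature(dataset, V_mV = 80)
round(curve, 4)
#>   temperature_K g_mean   g_sd n
#> 1           296 0.0212 0.0058 3
#> 2           301 0.0369 0.0031 3
#> 3           306 0.0661 0.0186 3
#> 4           311 0.2476 0.0244 3
#> 5           316 0.5017 0.0326 3
#> 6           321 0.7002 0.0112 3
#> 7           326 0.8244 0.0086 3
#> 8           331 0.8579 0.0291 3

vant_hoff_fit(curve$temperature_K,
              curve$g_mean / (1 / (1 + exp(-80 / 40))))
#> <vant_hoff_fit> dH = 180.3 kJ/mol, dS = 573.4 J/(mol K), T* = 314.41 K (41.3 C)
```

The steep sigmoidal G–T curve is the heat-activation signature; the
van't Hoff fit recovers the generating enthalpy/entropy (truth: 200
kJ/mol and 635 J/(mol K), T\* = 314.96 K) to within the noise of a
single 8-temperature dataset, with the half-activation temperature just
above 41 °C.

```r
# the memory term as a testable dwell-time signature: a hidden closed
# stage (k_c1 = 20/s, tau_r = 0.1 s, memory product 2) makes the
# observed closed residence non-exponential
scheme <- three_state_scheme(
  c1 = dwell_law("exponential", rate = 20),
  c2 = dwell_law("exponential", rate = 10),
  open = dwell_law("exponential", rate = 5),
  p_c2_open = 0.5, o_reentry = "C1")
events <- collapse_to_conductance_events(
  generate_dwell_events(scheme, 1000, seed = 42))
compare_models(list(fit_dwell_model(events, "markov_2"),
                    fit_dwell_model(events, "nonmarkov_2")))
#>     model_tag k_free   AICc delta_AIC akaike_weight
#> 2 nonmarkov_2      4 -390.4      0.00     1.000e+00
#> 1    markov_2      2 -368.6     21.86     1.788e-05
```

The non-Markov (gamma residence) description beats the memoryless model
by ΔAIC ≈ 22 on a single record of ~400 observed sojourns.

A command-line front end over the same functions is installed at
`inst/cli/trpgating.R` with subcommands
`simulate | fit | gv | recover | make-fixtures`.

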
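# phosphoshift

Quantifying the hydrolytic decay of pentose-1-phosphates from apparent
equilibrium shifts of a nucleoside phosphorolysis reaction.

## The problem and the idea

Pentose-1-phosphates (e.g. ribose-1-phosphate, Rib1P) are key
intermediates of nucleoside catabolism and of phosphorylase-catalyzed
transglycosylations, but they are UV-inactive, hard to detect from
buffered mixtures, and expensive to buy pure — so their hydrolysis
kinetics are awkward to measure directly. Nucleoside phosphorolysis

    nucleoside (N) + phosphate (P)  <=>  nucleobase (B) + pentose-1-phosphate (P1P)

is tightly thermodynamically controlled, with

    K = [P1P][B] / ([N][P])        (K ~ 0.01-0.8 for natural nucleosides)

and both N and B are UV-active. If the sugar phosphate is generated *in
situ*, incubated under hydrolyzing conditions, and the phosphorolysis is
then re-equilibrated with fresh enzyme, the hydrolytic loss shifts the
apparent equilibrium conversion from c1 to c2 > c1 (Le Chatelier). The
shifted mass balances give the hydrolyzed amount in closed form:

    h = [ c2^2 N0 - K (1 - c2)(P0 - c2 N0) ] / [ K (1 - c2) + c2 ]

where N0, P0 are the initial nucleoside and phosphate concentrations.
Fitting the residual pool `c1*N0 - h(t)` over incubation time as a
first-order decay `A exp(-k t)` yields the rate constant and half-life of
a compound that is itself invisible to the detector. The package provides
this algebra (including the full-hydrolysis ceiling `c2_max` and the
design map of the maximum shift over K and phosphate excess), the UV
spectral-unmixing conversion readout, the decay fitting with bootstrap
uncertainties and pH-rate profiling, and seeded synthetic-data generators
for the entire pipeline.

## Worked example

Uridine with 4 equivalents of phosphate (2 mM uridine, 8 mM phosphate,
K = 0.15):

```r
library(phosphoshift)

sys <- reaction_system(N0 = 2, P0 = 8, K = 0.15)
c1  <- solve_equilibrium_conversion(sys)   # 0.5078 -> ~51 % conversion
max_shift(c1, sys)
#> <shift_window>  c1 = 0.5078   c2_max = 0.7241   delta_c_max = 0.2163 (21.6 pp)
```

About half the nucleoside converts (1.02 mM each of nucleobase and sugar
phosphate), and even complete hydrolysis of that pool can push the
conversion only to ~72 % — the ceiling against which measurements are
checked. A simulated campaign (true half-life 3.9 h, 5 sampling times,
conversion noise 0.01) and its analysis:

```r
sim <- simulate_experiment(sys, true_k = log(2) / 3.9,
                           times = c(0, 1, 2, 3, 5), sigma_c = 0.01,
                           pH = 8, seed = 1)
obs <- quantify_hydrolysis(sim$time_h, sim$c2, sys,
                           tol = 8 * conversion_noise_to_h(0.01, sys),
                           clamp = FALSE)
obs
#>   time_h pH     c2    h_mM residual_mM
#> 1      0  8 0.5015 -0.0350      1.0505
#> 2      1  8 0.5403  0.1750      0.8406
#> 3      2  8 0.5571  0.2616      0.7540
#> 4      3  8 0.6049  0.4959      0.5197
#> 5      5  8 0.6302  0.6130      0.4026
fit_first_order(obs)
#> <decay_fit>  k = 0.1891 1/h   t_half = 3.665 h   A = 1.016 mM (fixed)   RMS = 0.04 mM   n = 5
```

Each measured conversion maps to a hydrolyzed amount `h_mM` and a residual
pool `residual_mM`; the exponential fit recovers the generating half-life
(3.67 h fitted vs 3.9 h true) within the noise of a single 5-point series.
Negative `h_mM` at t = 0 is expected with unclamped noise and is part of
keeping the fit unbiased. Experimental design questions — how much
phosphate excess makes the shift measurable — are answered by the window
tools:

```r
recommend_equivalents(K = 0.15, target_delta = 0.20)$interval
#> [1]  2.236 10.853   # equivalents giving >= 20 pp of potential shift
```

The same steps are scriptable from a shell via `exec/phosphoshift`
(subcommands `quantify`, `window`, `simulate`, `unmix`).

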
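# dnacyc

Sequence-dependent Monte Carlo estimation of DNA cyclization J factors
from a coarse-grained rigid base-pair-step model of the double helix.

## The problem

How readily a DNA fragment closes into a ring is quantified by the
Jacobson–Stockmayer **J factor**: the ratio of the equilibrium constants
for cyclization and for bimolecular association, with units of
concentration (mol/L). J depends strongly on fragment length — through
the bending cost for short fragments and the entropic cost for long
ones — and on sequence, because the equilibrium geometry of each
base-pair step (its intrinsic curvature) is sequence dependent. `dnacyc`
is for structural-bioinformatics and biophysics users who want to
compute J factors for arbitrary sequences under published tables of
equilibrium step parameters, and to compare parameter sets against
experimental cyclization measurements.

## The model

Each base-pair step is described by the six helicoidal parameters
(tilt θ₁, roll θ₂, twist θ₃ in degrees; shift θ₄, slide θ₅, rise θ₆ in
Å). A parameter set maps each context k-mer (di-, tri-, or
pentanucleotide window around the step) to equilibrium values Θ⁰; absent
entries fall back to defaults (twist 34.30°, rise 3.40 Å, all else 0).
Thermal fluctuations around Θ⁰ are harmonic,

G_k = ½ ΣᵢΣⱼ f_ij Δθ_i Δθ_j  (in kT, with βF the elastic matrix),

and configurations are drawn with probability ∝ exp(−G) as independent
normals along the principal axes of deformation. The default elastic
model uses isotropic bending fluctuations of 4.84° RMS in tilt and roll
(persistence length ≈ 147 bp) and 4.09° RMS in twist, with displacements
frozen.

Chains are built by composing the rigid transform of each step
(mid-step triad convention). The J factor is estimated as the product of
three conditional closure probabilities,

J = (4π/N_A) · W(r ≈ 0) · Γ(cos γ ≈ 1) · Φ(φ ≈ 0),

counted with the standard thresholds: end-to-end distance r < 30 Å,
terminal-normal alignment cos γ > 0.86, torsional register cos φ > 0.86.
Each factor is an empirical density over its acceptance window, and the
normalization is fixed in closed form (no tunable constant): on an
ensemble with uniform end density and isotropic end orientations the
formula returns exactly the molar concentration of one end in the
sampled volume. Sampling uses the half-chain enhancement — M half-chains
from each end give M² implied full chains — with an exact spatial-grid
prefilter, and runs until the between-batch relative error of J drops
below 5 % (or a configurable chain budget is exhausted; fragments with
no observed closure are reported at the floor of 10⁻¹⁵ M).

## Worked example

The built-in curved reference model (artificial X/Z alphabet; XX/XZ
steps twist 36.00°, ZZ/ZX steps twist 35.57° with roll 7.41°) bends a
150 bp fragment into a nearly closed circle, so its J factor is huge:

```r
library(dnacyc)
est <- j_factor(curved_repeat_sequence(150), builtin_curved(),
                cfg = sampler_config(half_chains = 20000), seed = 1)
est
#> <j_estimate> J = 0.00159 M (halfchain)  rel. error 1.3%
#> <closure_counts> n=4e+08  r-hits=5.95279e+06  gamma-hits=1.28499e+06  phi-hits=517836
tidy(est)
#> # A tibble: 3 x 7
#>   factor description                  hits    trials    window unit      density
#>   <chr>  <chr>                       <dbl>     <dbl>     <dbl> <chr>       <dbl>
#> 1 W      circularity (end capture) 5952794 400000000 113097.   A^3       1.32e-7
#> 2 Gamma  terminal normal alignment 1284986   5952794      0.14 cos(gamm~ 1.54e+0
#> 3 Phi    torsional register         517836   1284986      1.07 radian    3.76e-1
```

Of 4×10⁸ implied chains, ~6×10⁶ close within 30 Å, and about 9 % of
those also align bending and torsion, giving J ≈ 1.6×10⁻³ M. An
intrinsically straight fragment of torsionally matched length behaves
like a stiff elastic rod and is about five orders of magnitude harder to
cyclize:

```r
j_factor(strrep("A", 210), builtin_straight(),
         cfg = sampler_config(half_chains = 50000), seed = 1)
#> <j_estimate> J = 1.48e-08 M (halfchain)  rel. error 17.8%
#> <closure_counts> n=2.5e+09  r-hits=5099  gamma-hits=71  phi-hits=30
```

J(L) for the straight model oscillates with the ~10.5 bp helical repeat
(`j_length_scan()` + `oscillation_period()`), and the pipeline functions
(`evaluate_benchmark()`, `concordance_curve()`,
`straight_baseline_deviation()`, `length_stratified_summary()`) compare
computed J factors against experimental tables or the straight baseline
across whole sequence collections. `autoplot()` methods draw each result
type. A thin command-line front end lives at `inst/cli/dnacyc.R`.

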
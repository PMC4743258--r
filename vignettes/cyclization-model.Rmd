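---
title: "The ring-closure model behind dnacyc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The ring-closure model behind dnacyc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`dnacyc` estimates the Jacobson–Stockmayer J factor of a DNA fragment —
the effective molar concentration of one end in the correctly oriented
neighbourhood of the other — by Monte Carlo sampling of a coarse-grained
rigid base-pair model. This vignette records the model, the numerical
conventions, and the design decisions that were genuinely open, in the
order a reader needs them to trust (or challenge) the results.

## The coarse-grained model

A fragment of N base pairs is a chain of N rigid bodies. Consecutive
base pairs are related by six helicoidal step parameters: three angles
(tilt, roll, helix twist; degrees at every user-facing interface) and
three displacements (shift, slide, rise; Å). Sequence enters only
through the equilibrium values Θ⁰ of these parameters, looked up per
step in a context-keyed table (a `parameter_set`): dinucleotide tables
key on the two bases flanking the step, trinucleotide tables on bases
k−1..k+1 around step k, pentanucleotide tables on k−2..k+2.

Three conventions here were not fixed by any authority and are declared
choices:

* **Context centring.** For odd widths the window covers bases
  k−(w−1)/2 .. k+(w−1)/2 relative to step k (the step sits between the
  window's central base and its successor). Nothing in the published
  tables pins the alternative (centring on the step's midpoint); we fix
  one convention and expose it in `equilibrium_profile()`'s
  documentation rather than a switch, because mixing conventions
  silently is the real hazard.
* **End handling.** Windows that overrun a sequence end fall back to the
  set's defaults, because chains are generated as linear molecules; a
  `circular = TRUE` flag wraps the context instead for users modelling
  minicircles.
* **Reverse-complement symmetry.** Tables that list only unique steps
  are completed by the standard rigid-step symmetry: the missing context
  takes its reverse complement's parameters with tilt and shift negated
  (the two coordinates that are odd under strand exchange).

Absent columns and cells fall back to the defaults
tilt = roll = shift = slide = 0, twist = 34.30°, rise = 3.40 Å — the
conventional average B-DNA geometry used when a published table provides
only a subset of the six parameters (many provide only roll).

## Elasticity and sampling

Thermal fluctuations around Θ⁰ are harmonic: the step energy is
½ ΔΘᵀ (βF) ΔΘ in units of kT, with βF a symmetric positive-semidefinite
6×6 matrix over (radian, Å) deviations, and the total energy is the sum
over steps. Diagonalizing βF gives principal axes of deformation along
which deviations are independent normals with standard deviation
1/√D_ii; the sampler draws exactly these.

Two representational details matter. First, force constants are stored
already normalized to kT, so temperature never appears; it enters only
through the σ values a user supplies. Second, a frozen coordinate
(σ = 0) is represented by a zero row/column of βF. Physically its
stiffness is infinite; the zero acts as a sentinel meaning "never
displace this coordinate", and `step_energy()` assigns zero energy to
deviations along it. This keeps βF finite and makes the diagonal
shorthand and the matrix form interconvertible.

The default model — RMS fluctuations of 4.84° in tilt and roll
(isotropic bending) and 4.09° in twist, displacements frozen — is the
one used for every headline number. For a discrete chain with isotropic
bending σ (radians), the tangent correlation decays per step by 1 − σ²,
giving a persistence length of −1/ln(1 − σ²) ≈ 140 steps for σ = 4.84°,
conventionally quoted as ≈ 147 bp; the test suite checks the simulated
decay lands in 130–155 bp. The twist σ corresponds to a torsional
stiffness compatible with equilibrium topoisomer distributions. A
general symmetric βF path (coupled coordinates) exists and is tested,
but no sequence-dependent elasticity is provided: one elastic model
applies to all steps, which is the assumption under which the published
equilibrium tables were applied.

## Frame algebra

Step parameters map to a rigid transform by the mid-step triad
construction: tilt and roll combine into a single bend of magnitude
Γ = √(tilt² + roll²) about an in-plane axis at phase φ = atan2(tilt,
roll), twist is applied half before and half after the bend, and the
displacement vector is expressed in the mid-step triad:

    R    = Rz(twist/2 − φ) · Ry(Γ) · Rz(twist/2 + φ)
    Tmid = Rz(twist/2 − φ) · Ry(Γ/2) · Rz(φ)

This is the de facto standard rebuild algebra for these six coordinates.
It makes a pure twist rotate about the frame normal and translate by
(0, 0, rise) — so ten 36° steps compose to the identity and an
intrinsically straight 150 bp chain spans exactly 149 × 3.40 Å — and a
single nonzero angle produces a rotation by exactly that angle. Whether
the original ring-closure studies split the twist symmetrically is not
recoverable; the symmetric split is the declared choice, and the checks
above are insensitive to it.

## The closure estimator

J is decomposed into three conditional factors, each counted against a
threshold: end-to-end distance r < 30 Å (capture volume V = 4πr³_c/3),
terminal-normal alignment cos γ > 0.86, and torsional register
cos φ > 0.86. The residual twist φ is defined as the rotation about the
*mean* of the two terminal normals that carries the first short axis
onto the last — well defined whenever the normals are not antiparallel,
which the nested test guarantees (φ is only evaluated after the γ test
passes). The three empirical densities (per Å³, per unit cos γ, per
radian) multiply with the 4π/N_A prefactor and the Å³→L conversion:

    J [mol/L] = (4π/N_A) · 10²⁷ ·
                (n_r/n)/V_cap · (n_γ/n_r)/(1 − 0.86) ·
                (n_φ/n_γ)/(2 arccos 0.86)

The unit bookkeeping closes on its own: for an ensemble whose ends are
uniform in a box with isotropic orientations, cos γ is uniform on
[−1, 1] (density ½) and φ uniform on (−π, π] (density 1/2π), so the
formula returns exactly 10²⁷/(N_A·V_box) — the molar concentration of
one end in the box, which is the Jacobson–Stockmayer definition. The
calibration constant is therefore exactly 1, and the test suite pins it
with `make_known_density_ensemble()` rather than by matching a published
curve whose numerical data we do not ship. Fragments with no observed
torsionally aligned closure report the configured floor (10⁻¹⁵ M) with
a `floored` flag, and floored values participate in concordance curves
as-is.

Two estimators share this counting:

* **Naive**: independent full chains, in batches.
* **Half-chain**: M half-chains from each end; every ordered pair (i, j)
  implies a full chain by rigid composition, so M² configurations cost
  2M chain builds. The capture condition |a_i + R_i b_j| < r_c is
  rewritten as |b_j − u_i| < r_c with u_i = −R_iᵀ a_i, and an exact
  uniform grid (cell edge r_c) over the b_j prefilters candidate pairs;
  the grid changes nothing but time, which the suite verifies by running
  with the prefilter disabled. The estimator is unbiased for the same
  expectation as the naive one because the two halves of a full chain
  are independent.

**Error estimate and convergence.** The published protocol stops at an
"error below 5 %" without defining the estimator; we declare it as the
between-batch relative standard error of J over ≥ 20 batches (the three
factors are correlated ratios, but their product telescopes to
n_φ/n_total, so batch J values are simple to form). For the half-chain
estimator, batches partition the first-half draws, each paired against
all second halves; the induced correlation between batches through
shared second halves is negligible in the rare-event regime the
estimator exists for. The half-chain sample doubles geometrically until
the target error or the chain budget (`max_chains`, desk-scale default
10¹⁰ effective pairs, configurable up to the protocol's 5×10¹⁵) is
reached. All randomness flows through R's seeded generator, including
inside the compiled kernels, so identical configuration plus seed gives
bit-identical counts.

## Reference models and the validation suite

Two built-in sets validate the implementation end to end. The straight
model (twist 34.28°, rise 3.40 Å, everything else zero) is a featureless
elastic rod: its J(L) curve oscillates with the helical repeat
360/34.28 ≈ 10.5 bp because only torsionally matched lengths close
easily. The suite scans L = 190–230 bp and requires the fitted period
(profile least squares of log₁₀J on a quadratic trend plus a sinusoid)
to sit within 1 bp of the repeat. The curved model (X/Z alphabet, XX/XZ
twist 36.00°, ZZ/ZX twist 35.57° with roll 7.41°) bends the 5X+5Z repeat
into a near-circle at 150 bp; the minimum-energy 150 bp chain closes to
r ≈ 3.65 Å, under 1 % of its 506.6 Å contour, and that deterministic
value is regression-tested.

The estimator-equivalence check deserves a note on design. Under the
default elastic model a 100 bp straight fragment essentially never
closes at desk-scale sampling — both estimators would return the floor
and agree vacuously. The suite therefore compares them on a 100 bp
fragment under a *softer* bending model (σ_tilt = σ_roll = 15°), where
both register hundreds of events in seconds; since the two estimators
share their expectation for any elastic model, this loses no
generality.

Problem sizes used by the suite — 10⁵ energy samples for equipartition,
4000 chains for the tangent correlation, M = 5×10⁴ half-chains per
length for the oscillation scan, 240 records over three lengths for the
benchmark-recovery check — were chosen as the smallest sizes whose 3-SE
bands are decisively narrower than the effects being measured.

## What the synthetic generators do and do not emulate

`make_synthetic_parameter_set()` draws full-coverage tables with twist
uniform in 30–40° and roll/tilt in ±8°, spanning the range of published
step-parameter tables without copying any of them.
`make_synthetic_benchmark()` builds pseudo-experimental records as the
straight-model J at the sequence's length perturbed by lognormal noise
(default 0.5 log₁₀ units — a synthetic choice, not an estimate of
experimental scatter); with noise 1.0 the fraction recovered within one
order of magnitude estimates the standard normal mass in ±1σ (68.3 %),
which the suite verifies by counting. These fixtures exercise every
pipeline path, but they do not imitate real sequence composition, real
parameter covariances, or the length-dependence of experimental error —
so passing tests demonstrate correctness of the machinery, not accuracy
of any particular published table against nature.

## Limitations

* The harmonic rigid-step model undervalues J for fragments below
  ~100 bp, where kinking and local melting are believed to contribute;
  no kinkable or meltable extension is provided.
* One elastic model applies to all steps; sequence-dependent stiffness
  is out of scope.
* The estimator targets the fully constrained (torsionally aligned)
  J factor only; torsionally relaxed variants are not computed.
* Experimentally measured J factors enter only as input tables
  (ligation-kinetics constants are documented in the benchmark schema,
  never computed).
* At the desk-scale defaults, fragments whose true J is below roughly
  10⁻¹¹ M floor out; reproducing sub-100 bp measurements requires chain
  budgets far beyond interactive use.
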
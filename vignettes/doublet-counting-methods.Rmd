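---
title: "Methods: differential doublet counting and dye-dilution analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential doublet counting and dye-dilution analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plateletdiv)
```

# The measurement problem

Platelets divide in culture, but the division fraction is difficult to
measure: impedance counters confuse progeny with debris and clumps, and
a dividing platelet is indistinguishable from two touching ones in a
suspension. The semisolid-culture design solves this geometrically — in a
viscous medium nothing diffuses, so a platelet that divides leaves its
progeny *next to itself* as a doublet — and chromatically: mixing
red-labelled and green-labelled aliquots makes contact doublets (formed
while dispensing the mixture) carry a predictable colour signature,
while division doublets are always same-coloured.

This vignette documents the statistical model behind the package, the
design decisions that were genuinely open, the synthetic-data generator
used to validate everything, and the known limitations.

# The count model

## Observables and null model

One experiment yields five numbers (`field_counts()`): the total red
and green platelets across the surveyed fields (`n_red`, `n_green`) and
the doublet counts by colour combination (`d_rr`, `d_gg`, `d_rg`).
Totals count every platelet, inside doublets or not, so singlet counts
are implied (`s_r = n_red - 2 d_rr - d_rg`). Clusters of three or more
platelets are excluded from all counts before this stage; with a
six-hour culture (at most one division per platelet) they are rare.

If no platelet divides, every doublet is an incidental contact of two
independently coloured platelets, so its class follows the binomial
pattern `(p_rr, p_rg, p_gg) = (R², 2RG, G²)/(R+G)²`
(`expected_doublet_proportions()`). Division only adds same-colour
doublets, so the red–green class can only be *depleted* relative to this
null — hence a one-sided test.

## Tail test

Conditional on the doublet total `T = d_rr + d_gg + d_rg`, the red–green
count is `Binomial(T, p_rg)` under the null. `doublet_null_test()`
reports the lower-tail probability `P(RG <= observed)` using the normal
approximation *without* continuity correction,

$$p = \Phi\!\left(\frac{d_{rg} - T p_{rg}}
  {\sqrt{T p_{rg}(1-p_{rg})}}\right),$$

which is the convention under which the packaged experiment series was
originally evaluated; the exact binomial lower tail is available as
`method = "exact_binomial"`. At small doublet totals the two differ
appreciably (the first pre-culture experiment gives 0.39 by the normal
approximation and 0.50 exactly), which is why the method is an explicit
argument rather than a hidden choice.

## Division-fraction estimator

Write `R0`, `G0` for the unknown numbers of platelets originally seeded
into the surveyed fields and `F_r`, `F_g` for the division fractions.
The balances are: each division adds one platelet and one same-colour
doublet, and contact same-colour doublets stand to red–green doublets in
the binomial ratio (`RR : RG = R0 : 2 G0`):

$$n_r = R_0(1+F_r), \qquad
  d_{rr} = \frac{d_{rg} R_0}{2 G_0} + F_r R_0,$$

and symmetrically for green. Eliminating the fractions gives, with
`a = d_rg/2`, `A = n_r - d_rr`, `B = n_g - d_gg`,
`t = (A - a)/(B - a)`:

$$R_0 = A + a t, \qquad G_0 = B + a/t,$$

equivalently `G0 = (AB - a²)/(A - a)`. `estimate_division_fractions()`
evaluates this closed form and verifies the doublet balances to 1e-9
relative as a self-check; the test suite additionally confirms agreement
with an independent 1-D root-finding solution of the same system to
1e-6 relative on a thousand random count tables.

Numerical notes:

* Any internally consistent count table keeps the denominators positive
  (`B - a = s_g + d_gg + d_rg/2`), so the degenerate-input error can only
  be triggered by corrupted records — it is still checked.
* Sampling noise legitimately produces negative fractions (pre-culture
  counts hover around zero); estimates are never clamped.
* The estimator is exactly equivariant under colour swap, and exact
  binomial doublet patterns are fixed points with `F = 0`.

## Confidence intervals

The interval construction was an open design choice (no reference
procedure is attached to the published intervals, so they are treated as
qualitative context only, not as reproduction targets).
`bootstrap_division_ci()` uses a percentile bootstrap over resampled
counts. Two resampling schemes are implemented:

* **Independent Poisson** (default): each of the five independent field
  totals — the two singlet counts and three doublet classes — is redrawn
  as `Poisson(observed)`. Counts of objects accumulated over randomly
  chosen microscopic fields are Poisson-like, making this the natural
  nonparametric model, and it propagates the variance of the doublet
  *total* as well as of its split.
* **Multinomial**: the doublet class vector is redrawn from
  `Multinomial(T, observed proportions)` with Poisson singlets. Because
  it conditions on `T`, it suppresses part of the sampling variance:
  in the calibration study below its intervals cover only ~89% at
  nominal 95%, versus 95/93% for the Poisson scheme. It is retained as
  an explicit option for sensitivity analysis.

Coverage was calibrated on the stochastic simulator at the study scale
(5000 + 5000 platelets, 200 contact pairs, 12% division, 500 simulated
datasets, 1000 bootstrap replicates each); the acceptance test re-runs
that exact study.

# The synthetic-data generator

`simulation_truth()` + `simulate_counts()` generate experiments at three
fidelities. The defaults describe the emulated bench conditions: about
165 platelets of each colour spread over ten 100 × 100 µm fields
(matching the field totals of the packaged experiments), around 25
incidental-contact pairs, and 12% division per colour (the observed
six-hour fractions span roughly 9–17%). These defaults are fixed
descriptions of the emulated experiment, not tuning knobs.

* **Expectation mode** returns the exact expected counts; the estimator
  recovers the generating fractions to ~1e-9, making this the algebraic
  round-trip oracle.
* **Sampling mode** draws the contact classes multinomially, consumes
  those platelets, and lets every *remaining* platelet divide
  independently. Barring contacted platelets from division keeps the
  realised data inside the estimator's model (a contacted platelet that
  divided would form a triplet, which the counting protocol excludes).
  A consequence worth stating precisely: the generative model's true
  divided fraction is then `f (1 - 2Hr/r0)` per colour, slightly below
  the nominal division probability `f` — 0.1152 versus 0.12 under the
  calibration conditions. `true_division_fractions()` returns this
  estimand, and recovery/coverage tests target it (the estimator's mean
  over 200 replicates sits within 0.01 of either value).
* **Spatial mode** places platelets uniformly with a hard-core minimum
  separation of 2 µm — platelets are solid bodies a couple of µm across,
  so coincident centres are unphysical (and unresolvable) — lets each
  divide with its colour's probability placing progeny 2.2 µm away,
  groups everything by single-link clustering at the 3 µm contact
  distance, and drops clusters of three or more from the counts while
  reporting them. Here contacts arise from density rather than from a
  budget, divided platelets *may* touch others and be excluded, so this
  mode probes the estimator's robustness rather than its correctness.

`render_fields()` turns the spatial ground truth into two-channel
images: each platelet becomes an isotropic Gaussian (σ = 0.3 µm,
0.15 µm pixels, integrated intensity 5000 photons on a background of
100) integrated exactly over the pixel grid, with optional
Poisson-plus-read noise, clamped to 16 bits. There is no channel
bleed-through, depth structure, or platelet shape — deliberately, since
the imaging front-end's job is geometry, not photometry.

`simulate_dilution_events()` emulates the dye-dilution assay: log-normal
generation-0 intensities truncated to a narrow sort gate (0.1 log10
units wide), division replacing one event by two at half intensity with
a 5% CV multiplicative spread, and an optional below-gate leak fraction
reproducing the small "divided" percentages seen immediately after
sorting. One division per platelet is modelled, matching the single
reduced cluster resolvable in short platelet cultures.

## What passing simulations do and do not show

The generator reproduces the *count structure* of the experiments, not
their optics or biology: real fields have platelet shape, focal drift,
dye brightness variation and possibly motion; real division may be
spatially clustered. Exact round-trip results on synthetic data
therefore validate the algebra, the detection geometry and the
bookkeeping — they do not certify performance on real micrographs.

# The imaging front-end

`detect_spots()` band-pass filters with a difference of Gaussians
(σ and 2σ), takes strict 8-neighbour local maxima above
`median + 5 × MAD` of the filtered image, additionally requires the raw
pixel to clear the same robust threshold on the raw image (replicate
padding inflates filtered noise variance at the borders; the raw-image
criterion rejects those edge artefacts), merges maxima closer than the
minimum separation keeping the brighter, and refines centres by a
re-centred intensity-weighted centroid over a `(2 ceil(2σ)+1)²` window —
sub-0.1-pixel accuracy on clean, separated spots. Border spots are
counted but flagged in the QC output, since their clusters may be
truncated by the field edge; excluding them would bias totals in a way
manual counting could not have done either.

`cluster_particles()` mirrors the visual adjacency judgement: a
single-link grouping joining spots within the contact distance
(default 3 µm, ~1.5 platelet diameters — the adjacency criterion is a
declared convention, since "touching" has no unique quantitative
definition under a 63× objective). Colocalised red and green spots stay
two spots (channel assignment is by acquisition channel, not spectral
unmixing) and form an RG doublet. `count_fields()` aggregates fields
into a `field_counts()` record with per-field QC.

# Dye-dilution quantification

`estimate_divided_fraction()` works on log2 intensities: the
generation-0 mode is the highest-intensity peak of a kernel-smoothed
density (peaks below 5% of the maximum are ignored as ripples), and the
class boundary is the deepest density minimum within one log2 unit below
that mode ("valley"), requiring at least two modes and a dip below half
the generation-0 peak; otherwise the estimator falls back, with a
warning, to a boundary exactly half a log2 unit below the mode
("half-dilution"). The divided event fraction is converted to the
divided platelet fraction via `q = e/(2 - e)`. Which of the two scales a
given published percentage refers to is generally ambiguous; both are
always reported.

# Problem sizes used in validation

The test suite validates at sizes chosen to make each check sharp while
staying light: 1000 random count tables for the closed-form/root-finder
agreement, 200 stochastic replicates at 5000 + 5000 platelets for
estimator bias, 500 datasets × 1000 bootstrap replicates for interval
coverage, a 20-field spatial simulation (660 platelets) for the exact
imaging round trip, and 10⁵-event populations at divided fractions
0.1–0.8 for dilution recovery.

# Known limitations

* The contact-pair budget `H` is a per-experiment constant, not a
  spatial process; only the spatial mode generates density-dependent
  contacts.
* Single division generation throughout; prolonged cultures with
  second divisions (triplets/quadruplets) are out of scope, as is
  multi-generation dilution deconvolution.
* The imaging model omits optical realism (bleed-through, aberration,
  3-D structure) and platelet shape.
* Published interval bounds are not reproduction targets (construction
  unknown); two published table cells disagree with recomputation from
  their own counts (a pre-culture fraction pair printed as 0.8/0.8 where
  the equations give ≈0.3/1.3, and two cultured cells off by 0.1) — the
  package asserts the recomputed values and documents the deltas in its
  tests.
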
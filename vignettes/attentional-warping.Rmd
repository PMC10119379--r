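---
title: "Attentional warping of color space: models, defaults and their rationale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attentional warping of color space: models, defaults and their rationale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(attnwarp)
```

## The paradigm and what the package computes

An observer searches a brief array for an oddball color target among
distractors drawn D degrees away on a 360° hue circle, then judges which of
two probes — the exact target color or a foil Δ degrees from it — matches
the target they just selected. If attentional selection is tuned away from
the distractor ("optimal tuning" when targets and distractors are
confusable), the represented target color is repelled from the distractor
and the 2AFC choice becomes systematically biased: away-rotated foils are
preferred, toward-rotated foils rejected, most strongly at small D.

`attnwarp` implements the full computational chain around that logic:
deterministic trial-design generation (module `experiment-design`), a
generative observer that produces data with exactly the statistical
structure the analysis assumes (`observer`), the d′/maximum-likelihood
analysis that reads the bias back out (`sdt-model`), a neural-population
simulation connecting the behavioral bias to representational geometry
(`population-geometry`), and an orchestration layer with exclusion
filtering, CSV/JSON I/O and a CLI (`pipeline`, `cli`).

## The observer model

On a trial with foil distance Δ, the internal representation of the target
hue is modeled as x ~ N(b, σ²) on the hue axis, with the positive direction
pointing away from the distractor:

* **b (degrees)** — the attentional bias, a rigid shift of the represented
  target away from the distractor. b may be shared or condition-specific
  (`bias_by_D`), since the repulsion grows as target-distractor similarity
  increases.
* **σ (degrees)** — representation noise, the SD of x.
* **λ ∈ [0, 0.5]** — lapse rate, a stimulus-independent uniform guess.
  Default 0; it exists because real 2AFC data rarely saturate at P = 1 even
  for 180° foils. It is identifiable only with such near-ceiling cells in
  the design.

The observer reports whichever option is closer to x. For an away foil (at
+Δ) the decision boundary is Δ/2, giving
P(target) = (1−λ)·Φ((Δ/2 − b)/σ) + λ/2; for a toward foil (at −Δ),
P(target) = (1−λ)·Φ((Δ/2 + b)/σ) + λ/2. Two consequences carry all of the
scientific weight:

1. **Chance-point identity.** P = 0.5 for an away foil exactly when
   b = Δ/2, for *any* symmetric noise and λ = 0. A condition observed at
   chance therefore measures the bias directly (`infer_bias_from_chance`):
   10° foils at chance imply b = 5°, 20° foils imply b = 10°. No fitting,
   no distributional assumption beyond symmetry.
2. **Sign pattern.** For b > Δ/2 the away foil is preferred (d′ < 0) while
   toward foils give d′ > 0, with |d′| decreasing as the bias shrinks at
   larger D.

### Linearization and the circular variant

The default model works on the locally linearized hue axis, valid because
design offsets satisfy Δ ≤ 60 ≪ 360 and plausible σ ≤ 30. The `"circular"`
variant wraps the same Gaussian noise onto the circle and uses arc-distance
comparison; the two agree within 0.005 in P over that regime (tested), and
the chance point is preserved exactly. The wrapped normal was chosen over a
von Mises deliberately: a von Mises matched in circular SD differs from the
Gaussian by up to ~0.007 in P at σ = 30 purely through its shape, which
would confound the check of the *wrap-around geometry* with a check of the
noise family. The exact supplementary-model parameterization behind the
published fits is not reproduced verbatim here; the chance-point logic is
invariant across symmetric-noise members of the family, which is why the
simplest member is the default.

## Designs and the synthetic cohort

The four designs are generated with their exact cell structures (E1: 300
trials, 25 per D × foil-direction cell over D ∈ {15,…,180}; E2: 432, 36 per
D × Δ cell, away foils only; E3: 288, half search-report and half
similarity-report; E4: 240, distractors 30° on both sides with one side
salient). Distractor rotation direction is balanced within cells; with 25
repetitions exact balance is impossible, so cells carry 12/13 splits whose
extras alternate across cells, keeping whole designs exactly balanced. At
D = 180 the two rotation labels are physically identical; the label is
recorded and the condition serves as the zero-bias control. 2AFC left/right
placement is randomized uniformly (counterbalancing unstated in the source
procedure). Target hues are drawn uniformly from the 360 integer wheel
entries; uniformity is χ²-tested.

`simulate_cohort` draws per-subject parameters (bias truncated at 0 —
repulsion only — and noise truncated at 1°) and resamples each subject's
stimulus realization, as in the real task. Search accuracy is generated
independently of the 2AFC process from a per-D accuracy map; it exists so
the exclusion filter (subjects < 70% search accuracy, or < 40% in the
harder E4) has something real to act on. The generator deliberately omits
several features of real data: sequential dependencies, reaction times,
learning, and any coupling between search success and the similarity
judgment on the same trial. A green test therefore establishes that the
analysis recovers the generating process when its assumptions hold — not
that human data satisfy those assumptions.

For the qualitative sign/ordering check of the first experiment the
generator's stated world is a 30-subject cohort (the experiment's own n)
with a bias profile decreasing in D — b = 16, 13, 10.5, 8, 6.5, 0 degrees
for D = 15…180, σ = 10 — chosen a priori so that b > Δ/2 = 5 holds through
D = 90 (the regime where away-foil d′ is negative) and expected |d′| gaps
between neighboring D exceed ~2 binomial SEs at the pooled counts. The
endpoints bracket the two fitted biases the analysis is expected to
recover (11.5° at D = 30, 5.3° at D = 60).

## Fitting: numerical choices

`fit_bias_model` maximizes the binomial likelihood of per-cell
target-choice counts, by default pooled over subjects (mirroring
group-level dashed-line fits; per-subject summaries are available via
`condition_summary(by_subject = TRUE)`). Deterministic two-stage
optimization: a coarse grid (b ∈ [0, 30] step 1; σ ∈ [2, 40] step 2),
exploiting that per-D biases separate given σ, then Nelder-Mead on the
unconstrained scale (free-signed b, log σ, logit λ/2). The refinement is
allowed to leave the grid box — negative b̂ is meaningful for null data and
required for likelihood-ratio calibration (the b = 0 null is then interior,
and the free-vs-fixed LR statistic is verified χ²₁ by simulation).
Degenerate cells (predicted p saturated at 0/1 with discordant counts)
yield an infinite NLL that the optimizer treats as a large finite penalty;
reported per-cell predictions are clamped to [1e−12, 1−1e−12] so d′
predictions stay finite. D = 180 cells carry their own free bias (expected
≈ 0) by default rather than being pinned, because whether the published
fits pinned them is unknown; `b_fixed` provides the pinned alternative.
Convergence and boundary estimates are flagged, never silently accepted;
if the simplex ends worse than the grid seed the grid point is returned
and flagged.

d′ uses the standard unbiased-2AFC convention √2·Φ⁻¹(P̂) with P̂ clamped to
[1/(2n), 1−1/(2n)]; the source never prints its formula, and the convention
only scales the statistic without affecting any sign or ordering claim.

## Population geometry: what warps and why

A deterministic population of 180 units with preferred hues tiling the
circle responds to hue θ with gain(μᵢ)·f(θ; μᵢ, κ). Two tuning families sit
behind one interface (von Mises, default, and a wrapped Gaussian of matched
peak curvature); every geometric claim is required to hold for both.
Attention multiplies responses by 1 + A·exp(κ_g·(cos(μ−θ_a)−1)), peaked at
an attended hue θ_a placed *off* the true target, on the side away from
the distractor. Distances are Euclidean between stimulus-evoked population
patterns — the only reading under which a stimulus-space geometry exists —
and classical (Torgerson) MDS embeds them in 2-D, with the arbitrary
rotation/reflection canonicalized (hue 0 on +x, hue 90 given +y).

**Why the defaults are κ = 1.25 and κ_g = 0.4.** Neither tuning nor gain
width is specified by the source, but the qualitative claims constrain
them jointly, and naive choices fail them:

* If the gain is as narrow as the tuning, the geometry *compresses* at the
  attended hue. Local discriminability at hue θ is carried by flank-tuned
  units about one tuning width away (peak-tuned units have zero slope
  there), so a narrow gain at θ_a boosts units that are flanks for
  θ_a ± width and the expansion lands off-center, flipping the
  toward/away asymmetry. A gain profile broader than the tuning
  (κ_g ≪ κ) places the expansion maximum at θ_a itself.
* If the tuning is too narrow (κ ≈ 4), pattern distances saturate beyond
  ~90° of separation while 2-D chord distances keep growing, and the
  embedding-vs-input distance correlation drops to ~0.94, i.e. the
  unattended code no longer "is" a circle in the near-faithful sense.
  Broad tuning (κ ≈ 1.25, first-harmonic dominated) keeps the correlation
  above 0.99 while radii remain constant to machine precision.

With these defaults, for both families: A = 0 gives an exact circle
(radii CV ~ 1e−16) and asymmetry index exactly 1; gain at θ_a = 20° with
A = 1 expands the geometry maximally within one grid step of 20° and gives
asymmetry index > 1 (away foil farther), growing monotonically in A over
[0, 2], and the same inequality holds in the full response space before
any MDS — the embedding is an illustration, not the mechanism. Only these
sign/ordering facts are anchored to the source; the numeric index values
are properties of the chosen defaults.

## Degenerate inputs, tolerances, determinism

Circular arithmetic is exact modular arithmetic on real degrees; wheel
lookup rounds to the nearest of the 360 integer hues only when a Lab triple
is requested. MDS flags fewer than 2 meaningfully positive eigenvalues as
degenerate instead of returning a spurious plane. All randomness flows
through explicit integer seeds (`withr::with_seed`, restoring the caller's
RNG state); identical seeds reproduce designs, simulations and pipeline
artifacts bitwise, and fitting is seed-free by construction. Validation of
trial tables checks the hue geometry against the condition columns to 1e−8
degrees.

## Known limitations

* The observer has no memory, sequential or RT component; the package
  cannot adjudicate delay-based accounts, only mimic designs that do.
* The bias is a rigid shift; skew or width changes of the internal
  representation are not modeled, though the chance-point identity is
  robust to them as long as symmetry about the shifted mean holds.
* The population model is noiseless and its asymmetry-index magnitudes are
  not calibrated to behavior; mapping representational distance to choice
  probability would require a decoding model that is out of scope.
* Real-data reproduction of the published fitted biases requires the
  deposited dataset; the package ships the ingestion adapter
  (`read_trials_mapped`) and demonstrates recovery on synthetic data
  generated at those values instead.
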
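---
title: "Decoding maze-navigation routes from multivoxel patterns: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding maze-navigation routes from multivoxel patterns: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(navdecode)
```

## The problem

During virtual-maze navigation, fMRI activity in visual and motor cortex
carries abundant information that is only *indirectly* spatial: which wall
pictures are in view, the local contrast structure of the first-person
scene, the direction of turning, the moments at which a new goal is
revealed. `navdecode` reconstructs the route a navigator followed by
decoding each of these variables separately from region-of-interest voxel
patterns, converting classifier outputs into predicted probability traces,
scoring every candidate route by how well its actual traces match the
predictions, and combining the resulting rankings across information
sources and brain regions.

Because no public dataset exists for this paradigm, the package also
contains a complete synthetic world — maze, navigator, renderer, and an
encoding model of voxel signals — so that every stage of the analysis can
be validated end to end with known ground truth.

## The maze world

The environment is a 22 × 22 tile grid (walls and corridors, loadable from
a plain-text layout) with seven pairs of doors (exactly one door of each
pair open per trial), nine pictures at fixed wall positions, four fixed
rewards to be collected in a per-trial order, and a fifth reward at one of
four sites on the outer corridor, collectable at any time. Coordinates are
1-based `(row, col)` tile indices with tile centers at `(r − 0.5, c − 0.5)`;
headings are degrees, counter-clockwise positive, 0 = east.

The bundled layout (`inst/extdata/default_maze.txt`) is a synthetic
stand-in: a corridor lattice on which the seven door pairs block only
parallel interior segments, so *every* of the 2^7 door configurations
leaves all rewards reachable by construction.

The route planner stands in for the human navigator: breadth-first-search
shortest paths through the rewards in their prescribed order, with the
bonus reward inserted at the point of minimum added length, and an optional
per-junction detour probability (default 0.15 in the experiment driver)
that diversifies tracks so candidate pools are not degenerate. Kinematics
follow the button-press model: forward motion at 1 tile per 0.78 s sampled
at 20 frames/s, turning in place at `turn_rate` degrees per frame. The
turn rate is not constrained by any published value; the default of
6°/frame (0.75 s per 90° turn) was chosen once so that turning and
single-tile translation live on comparable timescales. Within a straight
segment the position advances a fixed step per frame and clamps at the
corner, so a segment of `L` tiles costs `ceiling(L / step)` frames and a
turn of angle `A` costs `ceiling(A / turn_rate)` frames — the closed form
the kinematics tests assert. Simulated trial durations are kept inside the
plausible range of 57–195 s by escalating the detour probability when a
route would be too short.

The renderer casts one ray per screen column through the tile grid (closed
doors are walls, open doors are gaps) with a 60° field of view at a default
200 × 150 resolution; the experiment driver uses 40 × 30, which preserves
the 28-region scene statistics while keeping rendering tractable. Walls
carry a procedural brick texture, the sky region is darker than the walls,
and pictures are drawn as oriented-grating quads on the central 70% × 70%
of their wall face, flagged in an integer mask so visible picture area is
an exact pixel count. These textures are stand-ins — the original wall
photographs are not available — and only their summary statistics matter
downstream.

## The 73 decoding variables

All variables are computed at 20 frames/s and averaged within TR bins
(TR = 3 s → 60 frames per bin; a final partial bin averages its available
frames, so a track of `F` frames yields `ceiling(F/60)` TRs):

* **quadrant (6)** — the TR-mean position is assigned to one of four 9 × 9
  tile rectangles; a 2-tile central cross is unassigned and masked from
  training. The exact rectangle bounds are only known graphically for the
  original environment, so the geometry is configurable
  (`quadrant_geometry()`). Each unordered pair of quadrants is one binary
  variable (value 1 / 0 / 0.5-masked).
* **visibility (9)** — per picture, the fraction of scene pixels showing
  it, measured from the renderer's picture mask. Pixel counting (rather
  than projected-quad geometry) is used deliberately: it is occlusion-aware
  by construction.
* **motion (1)** — signed frame-to-frame heading change, left positive.
* **reward (1)** — 1 at TRs where the navigator first learns the next
  goal: trial start plus each pickup that reveals a successor.
* **scene RMS (28)** — per region of the 5 × 5 grid (center square split
  into four), the *population* SD of pixel luminance. Population rather
  than sample SD is an arbitrary but fixed choice; nothing downstream is
  sensitive to the `n/(n−1)` factor.
* **scene Temp (28)** — per region, the sum over pixels of the positive
  part of the frame-to-frame luminance difference (onsets only); the first
  frame is 0.

## The synthetic scanner

`synthesize_run()` generates a voxel × TR matrix as

    data[v, t] = Σ_k tuning[v, k] · x_k(t − lag) + drift_v(t) + ε,
    ε ~ N(0, noise_sd²)

with the hemodynamic delay modeled as a pure 2-TR lag — exactly the
assumption the analysis side makes; no HRF convolution is applied, so the
generator and the analysis share their temporal model and any mismatch
robustness is out of scope. Variables are standardized per run before
mixing because the six sources have incommensurate units. Each tuned voxel
(70% of an ROI by default) loads on 1–3 of its ROI's variables with weight
`snr/sqrt(k)`, so the per-voxel signal SD is about `snr` noise units; the
first tuned voxels cover each variable once so that every encoded variable
is represented whenever the ROI has at least as many tuned voxels as
variables. Per-voxel linear and quadratic drifts (SD 1 noise unit over the
run) emulate what the normalization step removes. The default ROI roster
assigns scene content, visibility and motion to the visual regions (V1,
Ve, Pa), motion and reward to the motor regions (M1, PM), weak quadrant
signal to the hippocampus (gain 0.3), and nothing to the white-matter
control.

What the generator does *not* emulate: spatial noise correlations,
physiological confounds, HRF shape variability, eye movements, or any
nonlinearity of the BOLD response. Passing tests therefore demonstrate the
internal consistency and calibration of the pipeline — not that real
tissue yields these effect sizes. No quantitative effect sizes exist to
copy, so `snr` is a free dial; the suite probes a 0 / 1 / 4 grid.

## Signal preparation and decoding

Runs are normalized by subtracting the scalar grand mean over all voxels
and time points, then removing a per-voxel least-squares fit of
`[1, t, t²]` (the grand mean first matches the description order; both
operations are linear so the order is immaterial). Variables at TR `t` are
paired with signal at `t + 2` TRs strictly *within* trial, so each trial
loses its trailing 2 variable time points and no pairing bleeds across
trial boundaries.

Each variable × ROI is decoded by a linear SVM (`C = 1`, `e1071`/libsvm, no
rescaling) under leave-one-trial-out cross-validation. Binarization rules
per source: quadrant pairs use their built-in labels; motion keeps only the
lower and upper tertiles of training values (turn right vs. left); reward
and visibility label positive values "yes" and subsample the "no" class to
at most 3:1 (seeded, uniform); scene statistics split at the training
median. All thresholds (tertiles, medians, subsampling) are recomputed
inside each cross-validation fold from the training trials only and reused
verbatim for the held-out trial — a deliberately strict reading that
excludes any leakage; the no-leak property is asserted by a test that
permutes held-out values.

Decision values are calibrated into probabilities by sorting training
points by decision value, binning in consecutive groups of 20 (a final
partial bin is kept if it has ≥ 10 points, else dropped), and fitting
`y = c + (1 − c − d)/(1 + exp((x − a)/b))` by Levenberg–Marquardt least
squares (`minpack.lm`). Initialization: `a` at the median decision value,
`|b|` at a tenth of the decision-value range with the sign chosen from the
empirical slope, `c = d = 0.05`, with `c, d` bounded in `[0, 0.5]`;
predictions are clipped to `[0, 1]`. If the fit fails, a clipped linear map
through the two extreme bins is used — a graceful degradation that
preserves monotone orderings.

Accuracy is reported as the signal-detection corrected proportion correct
`P = Φ((z(H) − z(F))/2)`. Proportions of exactly 0 or 1 are clipped to
`[1/(2n), 1 − 1/(2n)]` with a single `n` (the number of test points behind
both proportions); under this convention an always-majority classifier at
any prevalence has `H = F` after clipping, `d′ = 0`, and lands exactly at
50%.

## Ranking and combination

For one trial and one source × ROI combination, the predicted trace of each
of the source's variables and the actual trace of every candidate track are
linearly resampled to the TR length of the longest track in the pool,
standardized *separately* to mean 0 and variance 1, concatenated across
variables, and compared by the sum of squared differences. Candidates are
ranked by this mismatch (midranks on ties, so the expected rank under
exchangeability is exactly `(n+1)/2`); the normalized rank divides by
`n + 1`, putting chance at 0.5 for any pool size. Zero-variance vectors
standardize to zeros rather than erroring, which keeps degenerate constant
variables neutral instead of aborting a trial.

Rankings are combined by a weighted average of per-candidate ranks,
re-ranked; the weight of a combination is
`max(0, (R_chance − mean_rank)/(R_chance − 1))` — 1 at a mean correct-track
rank of 1, 0 at chance, floored at 0 below chance. Weights come from
cross-validated correct-track ranks; by default they are taken from the
*other* sessions' trials when more than one session exists (falling back to
the same split for single-session experiments), and a same-split option
reproduces the bias comparison between the two choices. The combined score
re-ranks weighted mean ranks (not normalized ranks); the two orderings
coincide whenever all combinations rank the same pool, which holds
throughout.

Significance uses an empirical null from the white-matter control:
normalized correct-track ranks of non-informative decodings, thresholded at
2.4 SD below the null mean (≈ 0.01 one-sided under normality). At desk
scale the null is built from per-(trial × source) white-matter ranks so
that it holds over a hundred values; a resampled mean-of-k distribution
(`mean_of_k_null()`, 5000 draws without replacement) supports judging
averages across sessions. The foil-similarity analysis scores each foil's
similarity to the correct track as the SS-distance of their standardized
actual traces for a named source and compares the combined ranks of the
five most vs. five least similar foils with both a paired t-test and a
10,000-flip sign-permutation test — the permutation guards the small-n
synthetic runs where normality is doubtful.

## Problem sizes and determinism

The test suite's synthetic experiment uses one session of 20 trials
(a 20-track candidate pool), renderer 40 × 30 at 20 frames/s, a 2-TR lag,
V1 at 120 voxels (sized so its tuned voxels can span its 66 encoded
variables — with fewer voxels single-variable readout is crosstalk-limited
regardless of snr), M1 at 40 and the white-matter control at 40 voxels,
over an snr grid of 0 / 1 / 4. The default `experiment_config()` is the
larger 2-session × 12-trial, 7-ROI layout. Every random draw — trial
factors, detours, tuning matrices, noise, subsampling, permutations — flows
from explicit integer seeds, so identical configurations reproduce results
exactly; a dedicated test re-runs a config and compares.

## Known limitations

* The maze layout, textures, field of view and turning kinematics of the
  original paradigm are not publicly specified; the bundled versions are
  documented synthetic stand-ins, and all quadrant/band geometry is
  configurable.
* The encoding model is linear with i.i.d. Gaussian noise and a pure-lag
  hemodynamic; it validates the pipeline's calibration and integration
  properties, not physiological effect sizes.
* Headline real-data quantities (identification rates among hundreds of
  alternative tracks, per-ROI accuracies) depend on data that were never
  deposited and are therefore out of reach; the package asserts the
  analytically forced constants and the property-level behavior instead.
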
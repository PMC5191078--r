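---
title: "Boosted color-component classification for grape cluster detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Boosted color-component classification for grape cluster detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grapeboost)
```

## The problem and the model

Locating ripe grape clusters in vineyard photographs is the first task of a
grape-harvesting robot's vision system. Dark table grapes are chromatically
close to parts of their background — shaded foliage, branches, soil — and
outdoor illumination shifts the whole color distribution between shots. No
single color component separates fruit from background reliably, but
several components are *partially* informative, each failing on a different
part of the background. That structure is exactly what boosting exploits.

`grapeboost` models a pixel by the mean, over the 7×7 window centered on
it, of six normalized color components: HSI hue `H`, YCbCr chroma `Cb`,
CIELab `bstar`, and the raw `R`, `G`, `B` channels. Four families of linear
weak classifiers are defined on these features: thresholds on `H` and `Cb`
(grape side above), a threshold on `bstar` (grape side below — ripe dark
berries sit toward the blue end of the yellow–blue axis), and a dividing
line over a channel pair, by default `(B, R)`. Each is trained by the
lowest-classification-error (LCE) criterion and combined by discrete
AdaBoost into `H(x) = sign(sum_t alpha_t h_t(x))` with
`alpha_t = 0.5 * log((1 - eps_t) / eps_t)` (natural logarithm).

The assumptions are worth stating plainly: classification is purely
chromatic (no texture or shape cues), per-pixel (spatial context enters
only through the window mean and the later morphology), and
variety-specific — a classifier trained on dark purple berries transfers
only to similarly colored varieties, and unripe green berries inside a
cluster are genuinely invisible to it.

## Weak classifier training

The 1-D threshold search is exhaustive and exact: candidate thresholds are
the midpoints between consecutive sorted distinct feature values plus one
sentinel on each side (so a constant classifier is always attainable, which
guarantees a weighted error no worse than `min(w+, w-)`). For step-function
losses this candidate set provably contains an optimum. Ties among
equally-optimal candidates are broken toward the threshold with the largest
margin to the nearest sample, then toward the smaller value — determinism
plus a little robustness for free.

The two-channel family is searched direction-then-intercept: unit
directions over a half circle (default `n_directions = 180`, i.e. 1°
resolution), with the intercept optimized *exactly* per direction by the
1-D search, both orientations considered. This is exact in the intercept
and dense in angle, far cheaper and better-behaved than a 3-parameter grid.

Weights are first-class throughout: the plain LCE criterion is the uniform
special case. This is the only reading under which boosting's per-round
refit is defined at all.

## Boosting loop and numerical choices

Per round, every available family is refit under the current weights and
the lowest-error one is kept. Numerical edge cases are pinned down as
follows:

* A round whose best error reaches 0.5 is discarded and training stops
  (at round one this is an error — no learner beats chance). `eps = 0.5`
  exactly would give a useless zero-weight round and is also rejected.
* A perfect round (`eps = 0`) has its error floored at `1/(2N)` before the
  weight formula — standard smoothing that keeps `alpha` finite while
  letting the round dominate.
* The printed weight-update normalizer, read literally, sums the
  *pre-update* weights (always 1) and would not normalize anything; the
  implementation normalizes the post-update weights to sum to one, the only
  reading that makes the next round's weights a distribution.
* The strong vote uses strict `>`: an exact zero vote sum is background.
  With typical irrational `alpha` values the case is measure-zero, but the
  tie rule is fixed for determinism.
* By default each family is used at most once (`without_replacement =
  TRUE`), reproducing the published four-round structure; classical
  boosting with repeatable families is a flag away, and a `refit = FALSE`
  mode weights a fixed pool of pre-fit models without re-training them.
* Training stops early when the strong training error drops below
  `target_error` (default 0.05), the published stopping rule. On easy
  draws this can end training before the pool is exhausted.

Every training run asserts the classical AdaBoost bound — training error
at most `prod(2 * sqrt(eps_t * (1 - eps_t)))` — in the test suite.

## Color transforms and their normalization

The transforms follow the standard printed formulas: the angular HSI hue;
`Cb` on the 0–255 scale clipped and divided by 255 (its coefficients cancel
exactly on grays, so any achromatic pixel maps to 128/255); and `b* =
200 [f(Y) - f(Z/1.192)]` from the un-normalized CIE RGB matrix scaled by
1/0.17697, with the two-branch companding function `f`.

Two conventions are ours to fix, because no published scale exists for
them. Achromatic pixels make the hue formula 0/0; we define `H = 0` (any
constant works — such pixels carry no hue information, and the arccos
argument is clamped to [−1, 1] against floating-point drift). And `b*` has
no stated normalization; we map it affinely from the conventional raw range
[−128, 127] to [0, 1] and clip, exposing the limits as an argument.
*Internal consistency is the contract*: thresholds are learned on exactly
the scale the pipeline later computes, so the arbitrary choice cancels.
Published threshold values on other (unstated) scales are not comparable
number-for-number.

The two-channel family is generic over any component pair because the
source material itself names three different pairs in different places;
the default `(B, R)` follows its final printed classifier table.

## Segmentation and detection parameters

| parameter | default | meaning |
|---|---|---|
| `window` | 7 px | feature window side, training and inference alike |
| `mean_kernel` | 3 px | preprocessing box mean on the RGB image |
| `region_fraction` | 1/10 | components smaller than this fraction of the largest are erased |
| `connectivity` | 8 | diagonal berry contacts count as connected |
| `disc_radius` | 5 px | structuring element `{dx² + dy² ≤ r²}` for opening/closing |
| `split_ratio` | 1.4 | width/height above which a region is split at its barycenter |
| `resize` | NULL | optional bicubic resize, e.g. `c(600, 800)` for full-size photographs |

The region fraction is printed inconsistently in the source (1/10 in the
prose, 1/4 in the pseudo-code); we default to the prose value and expose
the parameter. Connectivity is unstated there; 8-connectivity is the
natural choice for touching berries. Border pixels use reflective padding
rather than a shrunken mask. The adjoining-two-clusters trigger is
genuinely unspecified in the source; the width/height ratio test with
threshold 1.4 is this package's own heuristic — a single hanging cluster is
taller than wide — and a region that is simply one very wide cluster will
be wrongly split. The split line itself is vertical through the region
barycenter, with pixels exactly on the barycenter column going to the right
part. Coordinates are 1-based `(row, col)` throughout, R's native indexing,
with boxes reported as inclusive `(top, left, height, width)`.

Pipeline order follows the published pseudo-code: classify → region filter
→ open/close → hole fill → rectangles. Note that opening with the radius-5
disc erases any structure thinner than the disc — which is why the region
filter alone cannot be relied on to remove noise attached near cluster
boundaries, and why closing may absorb noise lying within its bridging
distance of a cluster.

## What the synthetic generator emulates — and what it does not

`scene_spec()` renders 220×300 scenes: a sky band, a soil band, leaf
texture crossed by branch strips, and elliptical clusters of overlapping
berry discs (radius 7–10 px) with per-berry color jitter and occasional
specular highlights; three illumination regimes are affine gain/offset
transforms of the whole image. Cluster height is about a third of the image
height — the relative scale of working-distance vineyard photographs — and
berries are larger than the radius-5 cleanup disc, as real berries are at
that distance.

Class colors are Gaussians in RGB, and the background deliberately includes
two *confuser* layers so that no weak family is perfect: purple-brown dead
leaves overlap grape in hue, and bluish shaded foliage overlaps it in
`Cb`, `b*` and `B−R`. Under the defaults the four weak errors land in
roughly the 5–25% band and boosting uses the full pool — the same
qualitative structure as the published per-classifier accuracies. Training
tables default to 400 grape / 800 background samples drawn across all
three regimes; scenes for the recovery study are 20 per run.

What passing tests therefore show: the estimator recovers planted
thresholds, the pipeline is robust to the modeled noise, illumination
shifts and confuser layers, and end-to-end recovery reaches mean PRA ≥ 85%
with ≥ 90% cluster-count accuracy over 20 scenes. What they do *not* show:
performance on real photographs. The generator has no texture, no cast
shadows with hue shift, no specular foliage, no occlusion by wires or
leaves, no camera noise model, and its illumination changes are affine.
Field accuracy claims cannot be transferred from these fixtures.

## Known limitations

* Purely color-based: unripe (green) berries inside a cluster are missed,
  and strongly color-shifted varieties require retraining.
* The two-cluster split is a heuristic; three or more mutually adjoining
  clusters are out of scope and will be merged or mis-split.
* PRA measures truth coverage only; it does not penalize
  over-segmentation. The detection-count metrics cover that side.
* The 16-bit export of component planes uses TIFF; the PNG writer
  available to the package is 8-bit.

## Problem sizes in the shipped tests

Unit tests run on small constructed instances (n ≤ 50 for the brute-force
LCE oracles, 100 random instances; 1000 random pixels for the transform
oracles). The recovery study trains one classifier on the default 1200
sample table and detects over 20 scenes of 220×300 px; the whole suite
completes in well under a minute on one core.
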
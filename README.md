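# grapeboost

Detection of ripe grape clusters in RGB vineyard images, built for the
vision stage of grape-harvesting robots. Dark-purple table grapes are hard
to segment with any single color cue — foliage, branches, soil and sky each
overlap some component of the fruit's color, and illumination in a vineyard
ranges from direct sun to deep shade. `grapeboost` attacks this by boosting
several *weak* color-component classifiers into one *strong* pixel
classifier, then cleaning and vectorizing the resulting binary mask into
enclosing rectangles a robot arm can target.

## The method

Every pixel is described by color components averaged over the 7×7 window
centered on it: HSI hue *H*, YCbCr chroma *Cb*, CIELab *b\**, and the raw
*R*, *G*, *B* channels, all normalized to [0, 1]. Four linear weak
classifiers are defined over these components,

```
h1:  H(x)  − H_th          ≥ 0   (hue above a threshold)
h2:  Cb(x) − Cb_th         ≥ 0   (Cb above a threshold)
h3:  b_th  − b*(x)         ≥ 0   (b* below a threshold)
h4:  a·B(x) + b·R(x) + c   ≥ 0   (a dividing line in the B–R plane)
```

each voting +1 (grape) or −1 (background). Parameters are fit by the
lowest-classification-error (LCE) criterion: an exhaustive search over all
candidate thresholds (midpoints of consecutive sorted feature values) that
exactly minimizes the weighted misclassification rate. Discrete AdaBoost
then combines the weak classifiers: at round *t* the best family under the
current sample weights D_t is selected with error ε_t, weighted by

    α_t = ½ ln((1 − ε_t) / ε_t),

and the weights are renormalized after scaling mistakes by e^{+α_t} and
correct samples by e^{−α_t}. The strong classifier is
H(x) = sign(Σ_t α_t h_t(x)).

Detection sweeps H(x) over every pixel, then removes noise with the region
threshold method (connected components smaller than 1/10 of the largest are
erased), a morphological opening and closing with a radius-5 disc, and hole
filling. Each surviving region is reported as its tightest enclosing
rectangle; a region much wider than tall is split into two rectangles by a
vertical line through its barycenter, handling two adjoining clusters.

Since no photographic corpus ships with the package, a synthetic scene
generator renders vineyard-like images (elliptical berry clusters over
leaf/branch/sky/soil backgrounds under three illumination regimes) with
exact ground-truth masks, so the whole pipeline is trainable and testable
from code alone.

## Worked example

```r
library(grapeboost)

samples <- generate_samples(n_grape = 400, n_background = 800, seed = 1)
fit <- grape_boost(samples)
summary(fit)
#> Boosted grape classifier: per-round weak classifiers
#>
#>  round                                equation epsilon  alpha train_error
#>      1                       H(x) - 0.6943 = 0  0.0700 1.2933     0.07000
#>      2                   0.3534 - bstar(x) = 0  0.0786 1.2308     0.07000
#>      3                      Cb(x) - 0.5316 = 0  0.3398 0.3321     0.06583
#>      4 -0.4067*B(x) + 0.9135*R(x) - 0.2191 = 0  0.3559 0.2966     0.04167
#>
#> Final training error: 0.0417

scene <- generate_scene(scene_spec(seed = 42))
det <- detect_clusters(scene$image, fit)
det
#> Grape cluster detections: 2 rectangle(s)
#>  id top left height width split region
#>   1  68  166     90    73 FALSE      1
#>   2  75   66     90    69 FALSE      2
pra(scene$mask, det$mask)
#> [1] 88.6
```

Reading the output: boosting selected all four families, hue first (round
error ε = 0.070, weight α = 1.29), and drove the training error from 7% to
4.2%. On a fresh synthetic scene both clusters are found, and the final
mask covers 88.6% of the ground-truth grape pixels (PRA, pixel recognition
accuracy — 75% is the usability bar for a harvesting robot).

The same pipeline is scriptable from a shell via the thin CLI in
`inst/cli/grapeboost.R` (`synth`, `train`, `detect`, `evaluate`).

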
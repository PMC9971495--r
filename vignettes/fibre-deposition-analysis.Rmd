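---
title: "Simulating and quantifying asbestiform fibre depositions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and quantifying asbestiform fibre depositions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In vitro toxicology of asbestiform minerals needs substrates carrying a
known, spatially even population of *single* fibres: agglomerated or
entangled fibres interact with cells differently, and the biologically
relevant dose is better described by the number of individually countable
fibres per unit area than by deposited mass. The classical preparation —
evaporating a pipetted drop of suspension — suffers from the stain
(coffee-ring) effect: as the sessile drop evaporates at roughly constant
contact angle its contact area shrinks, dragging suspended fibres inwards
and packing them into bundles. Inkjet-style micro-dispensing of picolitre
droplets on a programmed X-Y grid avoids this, because each tiny droplet
dries in place and carries at most a few fibres.

`fibredep` provides the full quantitative tool chain for comparing the two
preparations: a synthetic-data generator that emulates both deposition
physics at the geometric level, a segmentation and morphometry pipeline for
the resulting micrographs, class-histogram and homogeneity statistics, and
an automated implementation of the NIOSH Method 7400 / AIA fibre-counting
rules driven by skeleton-graph topology.

## The deposition models

**Fibre population.** `sample_fibres()` draws lengths uniformly on
5–15 µm and widths uniformly on 0.3–1 µm by default, the dimensional
envelope of a needle-like synthetic amphibole powder. Only the range of
these dimensions is constrained by the application, so the uniform law is
the default; a truncated lognormal is available
(`distribution = "lognormal"`) for more realistic right-skewed powders.

**Micro-drop model.** `deposit_microdrop()` places droplets on an
`n_x × n_y` grid (`droplet_grid()`). Per droplet, the fibre count is
Poisson with mean `mean_fibres_per_droplet`; each fibre lands uniformly
within the droplet's wetted footprint disc plus Gaussian stage jitter
(default sd 1 µm, the positioning accuracy of a typical X-Y translation
stage); orientations are uniform on [0, π). The default droplet volume is
180 pL (a 70 µm dispensing nozzle); the default footprint radius of 30 µm
corresponds to such a droplet of a fast-wetting solvent (ethanol) spreading
to roughly its own diameter on silicon. The expected fibre load per droplet
is exposed directly rather than derived from suspension concentration,
which would require assuming a mineral density and capture efficiency.
`avoid_overlap = TRUE` additionally resamples positions within the droplet
until fibre outlines keep a minimum clearance; this produces the
non-overlapping preparations used for pipeline validation, where the true
object count must be recoverable exactly.

**Drop (stain-effect) model.** `deposit_drop()` is a minimal geometric
realisation of ring-free evaporative concentration on a hydrophobic
substrate: initial positions are uniform in the drop contact disc of radius
R, and the final radial coordinate is contracted as

r_final = R (r/R)^(1+γ),

with γ = `compression_exponent` (γ = 0 reduces to uniform deposition;
default 2 gives a strongly concentrated deposit). Bundling is modelled
sequentially: a fibre landing within `bundle_capture_radius` (default 5 µm,
about half a fibre length) of an earlier fibre joins that fibre's bundle
and takes its orientation plus Gaussian noise (default sd 0.2 rad). These
two defaults were chosen once as a plausible geometric proxy for the
qualitative contrast between the two preparations — large entangled
aggregates versus isolated fibres — and are not calibrated against any
measured bundle-size distribution, since none is available; only the
*ordering* of homogeneity metrics between the two models is treated as a
testable claim.

**Rendering.** `render_field()` rasterizes each fibre as a capsule (a
rectangle with semicircular end caps) whose total tip-to-tip extent equals
the fibre length, so the expected segmented area of an L × W fibre is
(L−W)·W + π(W/2)². A Gaussian point-spread blur and additive Gaussian
noise follow, then quantisation to 8 (default) or 16 bits. Fibres narrower
than one pixel are rendered one pixel wide and flagged. The ground-truth
table records every fibre (fibres crossing the substrate edge are clipped
in the image but kept, flagged `touches_border`) together with its overlap
cluster, so that merged objects can be accounted for.

## Segmentation

`preprocess()` smooths with a Gaussian of physical bandwidth (µm, divided
by the pixel size), `binarize()` thresholds — Otsu by default, or a fixed
intensity band mirroring a manually chosen threshold range — and
`label_objects()` extracts connected components. Defaults: 8-connectivity
(diagonally touching thin fibres remain one object), a 4-pixel minimum
object size (suppresses single-pixel noise while retaining the sub-2-µm
particle class), and border objects kept but flagged. All three defaults
are recorded in the pipeline run log because they are conventions, not
measurements.

## Morphometry

`measure_objects()` reports, per object, the area (pixel count × pixel
area) and the minimum-area enclosing rectangle of the object's pixel-corner
convex hull, computed by rotating calipers (the optimum is attained with a
side collinear to a hull edge, so the search over hull-edge directions is
exact; the test suite verifies agreement with a 0.1°-step brute-force
search to within 0.5%). Length and width are the rectangle's longer and
shorter sides and the elongation factor is EF = length/width, the
length/diameter ratio whose EF > 3 class demarcates fibrous particles. A
`length_definition = "diagonal"` switch reports the rectangle diagonal
instead, for workflows that define "maximum length" that way; for thin
rods the two nearly coincide. Objects shorter than 2 µm are flagged
`small_class` and pooled downstream, reflecting the practice of collapsing
particles that cannot be discriminated from background into one class.

Pixel-corner measurements quantise each rectangle side upwards by up to
about one pixel for oblique objects. EF is therefore only
rotation-invariant to within that discretisation: the invariance property
is tested on rods at least 20 px wide (10% tolerance), and measurements of
marginally resolved fibres (a few pixels wide) should be interpreted with
the corresponding ±1 px caveat.

## Class statistics and homogeneity

`histogram_by_class()` bins per-object values into half-open `[lo, hi)`
classes with open-ended extremes (built-in schemes: EF classes <1.8,
1.8–2.2, 2.2–2.6, 2.6–3, >3; area classes <2 … >20 µm²; length classes
0–2 … >5 µm), normalises counts to 1 mm² of inspected area and accumulates
running percentages.

`batch_summary()` aggregates per-image counts and coverages: mean,
relative standard deviation, totals and density. The RSD convention is the
population (divisor *n*) standard deviation over the mean. Summary tables
in this field conventionally round the mean to an integer before forming
the RSD; `rsd_count_report` follows that convention (SD over the rounded
mean) while `rsd_count` is the exact value — for the reference drop-method
counts the two give 48% and 47.2% respectively, and a sample-SD variant
would give 50%. Both are returned so nothing is hidden by rounding.

`tile_homogeneity()` grids the substrate into equal square tiles, counts
objects per tile by centroid and returns the population RSD of tile
counts: 0% for a perfectly regular deposition, √3·100 ≈ 173% when
everything sits in one tile of four. This is the metric behind the
package's central simulation property: at equal fibre load, micro-drop
fields tile more evenly than stain-effect drop fields (γ ≥ 1) in
essentially every seed pairing.

## NIOSH 7400 fibre counting

`count_fibres()` automates the counting rules: a countable fibre is
(i) longer than 5 µm along its elongation axis, (ii) narrower than 3 µm,
(iii) of aspect ratio above 3, and (iv) free of attached particles larger
than 3 µm; (v) crossed fibres count individually, (vi) branched fibres
count once, (vii) entangled fibres are not counted. Rule boundaries are
strict inequalities. The implementation works per segmented object:

1. **Skeletonization** (`skeletonize_object()`): Zhang–Suen thinning to a
   one-pixel medial skeleton, converted to a graph with endpoint nodes
   (degree 1) and junction nodes (adjacent degree-≥3 pixels clustered;
   junction pairs connected by a bridge shorter than
   max(3 px, 2.5 × local width) are merged, since thinning splits oblique
   crossings into two nearby junctions). Edge geodesic lengths are measured
   on a coarsened (≈1 µm spacing) polyline, because the raw pixel staircase
   overestimates oblique runs, and each free end is extended along its
   local direction to the object boundary to compensate the tip erosion of
   thinning; the net accuracy for straight rods is a few tenths of a
   micrometre at 0.25 µm/px. Local widths come from the Euclidean distance
   transform, width = (2d − 1) px — exact for odd pixel widths, biased one
   pixel low for even ones.
2. **Topology** (`classify_topology()`): no junctions and no loops → one
   simple candidate; a single 4-way junction whose branches pair into two
   collinear through-paths (within 30°, the tolerance separating an X from
   a Y/T) → two crossed candidates, conserving total skeleton length; a
   single 3-way junction → one branched candidate spanning the longest
   endpoint-to-endpoint geodesic; more than 3 junctions or more than 1
   independent loop → entangled, no candidates (a purely topological proxy
   for a visual judgement, exposed in `niosh_params()`); remaining cases
   are decomposed greedily by collinear pairing at each junction, absorbing
   unpaired stubs shorter than the minimum countable length. A closed ring
   with no junctions (one loop) is treated as a single curled fibre.
3. **Geometry** (`apply_geometric_rules()`): rules i–iv on each candidate's
   skeleton path length and mean local width; the attached-particle
   diameter is the largest local width at positions where the width profile
   exceeds twice its median (a distance-transform peak detector — the 3 µm
   limit is prescribed, the detector is this package's choice). Rejections
   are tallied by first failing rule.

Fibre length for counting is the skeleton geodesic (robust for bent
fibres), not the enclosing-rectangle side used in morphometry; the two
agree for straight rods, which is property-tested. `fibre_length_histogram()`
bins accepted lengths into 3-µm classes from 5 µm.

The rule engine is validated against a catalogue of 22 constructed masks
(`fixture_masks()`): straight rods on both sides of each rule boundary,
X/Y/T/H configurations, a ring, bent and curved fibres, blob-attached rods
and an entangled clump, each with a hand-assigned expected count; exact
agreement on all of them is part of the test suite.

## What the simulations do and do not establish

The generator reproduces the *geometry* of the two deposition methods:
Poisson droplet loading on a jittered grid versus radial contraction with
capture bundling, plus capsule optics with Gaussian blur and noise. It does
not model evaporation fluid dynamics, Marangoni flows, 3-D fibre stacking,
real background texture, or phase-contrast optics. Passing tests therefore
establish that the measurement chain is correct on images whose ground
truth is known and that the qualitative drop/micro-drop contrast follows
from the stated geometric assumptions — not that any particular absolute
count from a real micrograph would be reproduced. Statistics derived from
published per-image summary tables (means, RSDs, coverages, densities,
class fractions) are reproduced exactly from those printed inputs; absolute
image-derived contrasts require the original micrographs and are out of
scope.

## Numerical choices and problem sizes

* Determinism: every stochastic function takes a `seed`; fixed seeds give
  bit-identical fields and images, and `run_pipeline()` derives all
  per-image seeds from one master seed so reruns are byte-identical on
  disk.
* Pipeline validation uses 10 × 10 droplet grids at rate 3 (≈300 fibres)
  rendered at 0.5 µm/px, five seeds, clean and noisy (noise sd 5% of the
  dynamic range); the clean object count must equal the ground truth
  exactly, the noisy one within 2%.
* The homogeneity ordering is checked over 100 paired simulations of ≈400
  fibres each at equal load and comparable extent, tiled at the droplet
  pitch (60 µm).
* Rotation-invariance and oracle comparisons use rods rendered at
  0.05–0.25 µm/px as described above.
* Degenerate inputs: empty populations, empty masks, all-background
  images, zero rates and single-pixel objects are all defined and tested;
  RSDs of all-zero counts are `NA` rather than an error or 0.

## Known limitations

* Bundle-size distributions of the drop model are a qualitative proxy; no
  printed data exist to calibrate them.
* Skeleton local widths carry the ±1 px parity bias of the distance
  transform; rule (ii) decisions within one pixel of the 3 µm limit are
  resolution-dependent.
* Entanglement is operationalised topologically (junction/loop limits);
  a human counter's judgement of "entangled" may differ on marginal
  objects.
* Equivalence with any specific commercial image-processing tool's
  preprocessing cannot be exact, since convolution kernels in such tools
  are unspecified; Otsu plus a fixed-band override spans the reasonable
  choices.
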
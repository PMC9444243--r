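---
title: "traplife: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{traplife: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

traplife analyses time-lapse microscopy of budding yeast mother cells held
in microfluidic traps. Because each trap retains exactly one mother while
daughters are washed away, tracking reduces to classifying the state of
the trap at every frame — "hardware-based cell tracking". This vignette
explains the models behind each stage, the parameters that matter, what
the synthetic generator does and does not emulate, and the design choices
made where the method description left the design open. It states no
empirical result that the test suite does not itself compute.

## The per-frame state model

Every frame of a trap movie is in exactly one of six states, in a fixed
canonical order used by every probability matrix and confusion matrix in
the package:

| state | meaning |
|---|---|
| `unbud` | mother present, no bud visible, no daughter in contact |
| `small` | mother with a bud below the size threshold |
| `large` | mother with a large bud, or last daughter still in contact |
| `dead`  | abrupt, strong change in contrast and appearance of the mother |
| `clog`  | more than ~50% of the trap filled with cells |
| `empty` | no mother in the trap |

The size threshold between `small` and `large` is defined so that each
class covers roughly half of the frames of a cell cycle. A consequence
worth noting: a mother with no attached object is `unbud`, and a mother
whose last daughter is still in contact is `large` — the two classes are
distinguished by the presence of a companion body, which is why the
synthetic renderer draws that companion (see below).

## Division counting and lifespan reconstruction

A new generation starts when the state re-enters `small` from `large` or
`unbud`. `detect_budding_events()` scores an event at every such
transition; a direct `unbud -> large` transition (the short small-budded
phase fell between two acquisitions) optionally counts as one event and is
flagged (`skipped_small_events`). Whether that transition hides one event
or two cannot be decided from the data; we count one and flag it.

`reconstruct_lifespan()` ends the lifespan at the earliest of four stop
rules, with ties at the same frame resolved in this order: (1) a `dead`
frame; (2) division arrest — more than `arrest_hours` (default 10 h)
without a new budding event; (3) a `clog` frame; (4) an `empty` frame.
Clog/empty records are flagged `excluded` and never enter survival
statistics. Sequences that reach the last frame without a stop are
right-censored (`end_reason = "end_of_movie"`) rather than dropped, which
keeps the Kaplan–Meier estimator valid. Two timestamps are our own
constructions where the rules name none: an arrest death-frame is placed
at the last budding event plus the arrest window (the latest frame the
cell was known dividing plus the declared horizon), and an arrest only
triggers at a frame strictly beyond the window with no event at that
frame — an event landing exactly at `anchor + window + 1` cancels it (the
event-free time never strictly exceeded the window).

The replicative lifespan (RLS) of a record is its number of budding
events. All frame indices in public records are 0-based (frame 0 is the
first acquired image), matching the pixel-coordinate convention;
generation indices are 0-based for the same reason.

Per-frame classifiers sporadically mislabel a live cell as `dead`. The
"CNN+PP" post-processing rule requires two consecutive `dead` frames to
call a death: `postprocess_cnn_labels()` relabels every isolated `dead`
frame to the nearest preceding non-dead label (nearest following for the
first frame). The relabelling target is our choice — the rule as stated
only says such frames are ignored. The operation is idempotent. Under the
sequence classifier (CNN+LSTM) the first `dead` frame ends the lifespan
directly; the two-frame requirement applies only to `pp_mode = "cnn_pp"`.

## Classifiers

The frame classifier is a small convolutional network (default four
conv/relu/maxpool blocks, then a dense feature layer and a softmax head)
trained with Adam. The backbone is deliberately small: published
comparisons of large pretrained backbones found no accuracy gain on this
task, and a compact network trains on one CPU in minutes. The
classification head is zero-initialised, which makes training exactly
equivariant under class relabelling (a property the test suite asserts
bit-tight). Inputs are centred by subtracting 0.5; images are resized by
nearest neighbour when a movie does not match the model input (recorded
in an attribute).

The sequence classifier is a bidirectional LSTM (default 150 hidden
units; desk-scale tests use 96) over the CNN's penultimate-layer feature
sequence, emitting per-frame probabilities over the six classes. It sees
the whole movie at once and so suppresses isolated per-frame errors —
the property that makes automated division counting reliable; the
acceptance suite measures exactly this (frame error strictly below the
CNN's, ghost generations rare, cycle durations and survival curves
matching the truth).

The SEP (senescence entry point) classifier is a second bidirectional
LSTM that labels every frame of a lifespan `pre_sep`/`post_sep` from the
4-class probability sequence (unbud/small/large/dead; clog/empty frames
are masked from the loss). Its raw per-frame calls are reduced to one
changepoint per cell: the split minimising disagreement with the raw
predictions, ties resolved to the earliest frame (favouring sensitivity),
SEP absent when the best split is the sequence end. How per-frame calls
were reduced to the single published SEP per cell is unstated in the
method description; this reduction is our construction, and it is tested
against exhaustive search over all splits. A rule-based oracle
(`sep_rule_oracle()`: first generation exceeding 1.5x the median of prior
durations and staying elevated for at least 2 of the next 3 generations)
provides an independent check on synthetic data.

All trainers take explicit integer seeds and touch no global RNG state;
identical seeds give identical fits.

## Segmentation and quantification

`train_segmenter()` fits a three-scale fully convolutional
encoder/decoder (full, 1/2 and 1/4 resolution with skip connections —
a miniature of the atrous-pyramid encoder/decoder family used for this
task) emitting per-pixel class probabilities; being fully convolutional
it accepts any input size (odd sizes are padded and cropped back). Two
coordinate channels (normalised row/column offset from the trap centre)
are appended by default: the mother class is *defined* by its conserved
central position, which a small receptive field cannot otherwise see.

A pixel is assigned the target class (mother or nucleus) iff its
probability reaches a threshold; `select_threshold()` picks the threshold
maximising target-class F1 on a validation set (ties to the larger,
i.e. more conservative, threshold) and returns the full
precision/recall/F1 table. Among mother-predicted pixels, only the
8-connected component whose centroid lies nearest the trap centre is
kept; other components are relabelled `other`. That selection rule is our
construction on top of the stated reliance on the mother's conserved
central position. Buds are not separable from surrounding cells and are
not part of the mother mask.

`quantify()` reports, per frame: mother area (pixels and µm², since the
source material does not say which unit its areas use), nucleus area,
total nuclear fluorescence = sum over nucleus pixels of intensity minus
background, and mean cytoplasmic fluorescence over the mother mask. The
background is the per-frame median intensity over the background class of
the nucleus mask; the fluorescence normalisation of the original analysis
is undescribed, and the median over background pixels is robust to the
nuclear signal itself. Frames with an empty mother mask report area 0 and
absent (NA) fluorescence.

## Survival statistics

`km_estimate()` computes the Kaplan–Meier estimator on the replicative
age axis, S(g) = prod over death generations g_i <= g of (1 - d_i/n_i),
with Greenwood variance S^2 * sum d_i / (n_i (n_i - d_i)) and a plain
95% band clipped to [0,1] (a log(-log) band is available as an option;
the plain band is the simplest reading of "the Greenwood method").
Median RLS is the smallest g with S(g) <= 0.5, no interpolation. The
discrete hazard h(g) = d(g)/n(g) gets its SD from resampling records
with replacement (default 100 replicates, seeded). The two-group
log-rank test is the standard censoring-aware chi-square with 1 df; the
rank-sum test is the two-sided Wilcoxon–Mann–Whitney with midranks,
exact for small tie-free samples. Time axes: generation index for RLS
curves, frame time for death-fraction traces.

## The synthetic world

The generator (`simulate_cell_history()` + `render_trap_movie()`) states
a compressed desk-scale world, chosen once:

* movies of 150 frames at 5 min/frame (12.5 h);
* pre-SEP cycles lognormal, mean 90 min, CV 0.15;
* an SEP after 1 + Poisson(2.5) pre-SEP generations, which doubles the
  mean cycle duration and adds 20 min per further generation (CV 0.15) —
  the abrupt-slowdown structure of real senescence trajectories;
* a per-generation death probability of 0.35 after the SEP (and an
  optional constant hazard for geometric-lifespan checks: death is tested
  after every budding event, so RLS is geometric with mean 1/p);
* per-movie probabilities of 0.03 arrest, 0.05 clog, 0.05 empty (half
  empty from frame 0, half mother loss mid-movie).

Real wild-type lifespans run ~25 generations over days; compressing to
~5–7 generations keeps every property the pipeline relies on (label
oscillations, an SEP break, censoring, excluded trap fates) while letting
every model train on one CPU in minutes. Rendering is schematic —
anti-aliased it is not: disks with a dark rim on a flat background with
trap walls, a bud whose area grows affinely through the cycle from a
visible minimum (15% of the maximal bud area; the `small` class is
defined by a *visible* bud) and crosses the class threshold mid-cycle,
lingering daughters behind the mother, a contrast-inverted speckled
texture for death, near-full cell cover for clogs, and additive plus
signal-dependent Gaussian noise. Mother radius varies across cells (12%
CV) and grows 1.5% per generation, so area-recovery statistics have
variance to explain. The fluorescence channel holds a nuclear blob whose
total intensity rises 3% per frame after the SEP.

What a green test on this world does establish: the logic
(event/stop/censoring rules, statistics, pairing, changepoint) is exact,
and the learning components can recover the generating structure from
pixels at desk scale. What it does not establish: performance on real
brightfield yeast images, robustness to focus drift, debris,
mother/daughter confusion, or trap-geometry variation — none of which the
renderer emulates, and no appearance model for dead/clogged traps was
available to calibrate against.

## Numerical choices

Probability rows must sum to 1 within 1e-6; argmax ties break to the
first class in canonical order. Event pairing
(`pair_generation_events()`) maximises matched pairs, then minimises
total |frame offset|, within a tolerance of ±2 frames by default (a cycle
is ~18 frames at 5-min sampling, so ±2 is unambiguous; no tolerance was
stated). For sorted inputs with absolute-difference costs the optimum can
be taken non-crossing, which the dynamic program exploits; tests compare
it to exhaustive assignment. Undefined metrics (no predictions, empty
class) are reported absent, never 0. Cross-correlation for trap detection
is zero-mean/unit-variance (illumination invariant); zero-variance
windows score 0, flat templates are an error; the detection threshold
(0.5) and suppression radius (the template width) are our defaults — none
were stated. ROI positions are frozen at frame 0; traps are stationary.
Adam uses (0.9, 0.999, 1e-8); the segmenter halves its learning rate at
1/2 and 3/4 of the schedule. LSTM forget-gate biases start at 1.

## On-disk formats

Movies and masks travel as uncompressed little-endian multi-page TIFF
(float32 intensities, uint8 mask codes) written and parsed by the
package — the environment provides no TIFF bindings, and the baseline
subset round-trips exactly. Mask files use TIFF rather than indexed PNG
for the same reason (no PNG encoder available). Tables are CSV with a
header row, records JSON-lines, groundtruth and reports JSON, models a
binary blob with a JSON sidecar (class order, config, seed). Every
pipeline stage writes a `manifest.json` naming its inputs, configuration
hash, seed and package version.

## Known limitations

Mother replacement by a daughter after mother loss is not detected (a
stated limitation of the approach this package follows). Multi-phase
aging-trajectory typing is out of scope. The renderer's dead/clog
appearance is a surrogate, not calibrated to data. The CNN expects input
sides divisible by `2^n_blocks`; other sizes are resized, not padded.
Training at the default desk scale is CPU-minutes, not seconds.
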
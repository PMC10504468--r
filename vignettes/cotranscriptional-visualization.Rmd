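---
title: "Visualizing cotranscriptional RNA folding ensembles"
author: "cofoldviz authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Visualizing cotranscriptional RNA folding ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cofoldviz)
```

## The problem

An RNA molecule starts folding while it is still being transcribed, so the
folding substrate grows over time and the population of secondary structures
("the ensemble") shifts as new helices become possible and old ones are
displaced. Simulators of this process emit, for a series of time points, the
set of structures present and the fraction of the ensemble each one occupies
(its *occupancy*). Those tables are hard to read directly: important
refolding events hide in thousands of rows.

cofoldviz turns such a table into a composite figure per time point:

* a **treemap panel** in which every displayed structure gets a rectangle
  whose area is proportional to its occupancy, the most occupied structure
  leftmost, each rectangle holding a 2D drawing of the structure;
* an **overview strip** underneath in which, for every time point, the
  per-nucleotide colors of the *dominant* (most occupied) structure are
  stacked along the y axis, so a horizontal read of the strip shows where
  the dominant structure changes;
* a **composite time axis** that is linear during transcription and
  logarithmic afterwards, with the end of transcription always pinned at
  75% of the axis width.

A frame series over all time points serves as a batch animation.

## Input model

A trajectory is a whitespace-separated table whose header must contain the
column names `id time occupancy structure energy` (any order; extra columns
are ignored; `#` lines are comments). `id` is an integer lineage label that
groups a structure across transcript lengths, `time` is in seconds,
`occupancy` in `[0, 1]`, `structure` a dot-bracket string (bracket layers
`()`, `[]`, `{}`, `<>` allow pseudoknots), `energy` in kcal/mol. Parsing is
strict at the row level — every violation is reported with its line number —
but deliberately tolerant about ensemble bookkeeping: per-time-point
occupancy sums slightly above 1 or duplicated ids raise warnings, not
errors, because aggregated stochastic simulations routinely produce such
tables. What is enforced as an error is monotone transcript growth: the
maximum structure length per time point must never decrease.

The nucleotide sequence travels separately (raw text or FASTA, first record)
and may contain arbitrary annotation characters; it is only used to letter
the drawings.

## Coloring by imaginary center

Every base pair `(i, j)` has an *imaginary center* `c = (i + j) / 2`. All
pairs of a perfect helix share one center, so a helix is one color, and two
perfectly aligned helices (equal centers) share a color across panels and
time points — which is exactly what makes motifs recognizable. The hue is

    H(c) = (floor(c / 9) + 160 c) mod 360

in degrees. Since centers are half-integers, `160 c mod 360` steps through
the color circle in 80-degree jumps and visits nine base hues; the
`floor(c/9)` term slowly detunes successive traversals of that cycle so
that nearby repeats of the nine base colors drift apart over long
sequences. The formula is implemented exactly as stated, including the
floor term; note that distant centers can still collide in hue early on
(e.g. `H(1.0) = H(5.5) = 160`), which we accept as a property of the
scheme rather than "fixing" it. Unpaired nucleotides are drawn in a neutral
gray (`#B0B0B0`) and hues are realized at fixed saturation 0.75 and value
0.88; only the hue carries information.

## The composite time axis

With `t0` the first displayed time point, `t_end` the end of transcription
and `t_max` the last time point, the axis maps

* `t <= t_end`: `x = 0.75 (t - t0) / (t_end - t0)`
* `t >  t_end`: `x = 0.75 + 0.25 log(t / t_end) / log(t_max / t_end)`

which is continuous, strictly increasing, and pins `x(t_end) = 0.75`
regardless of how long the post-transcriptional simulation ran. The inverse
map is closed-form and round-trips to better than 1e-9 relative, which is
what cursor scrubbing needs. The input format has no transcript-length
column, so `t_end` is detected as the earliest time point at which the
maximum structure length reaches its overall maximum.

Degenerate inputs keep a well-defined axis rather than failing: if the
simulation stops at the end of transcription the axis is fully linear; if
no growth is observed at all it is fully logarithmic from the first
positive time point; a single time point maps everything to `x = 1`. The
split fraction 0.75 is deliberately not configurable.

## Treemap layout

Tiles are laid out with a strip variant of squarified treemapping: tiles
are grouped greedily into vertical strips (full panel height, placed left
to right in descending occupancy order), and a strip accepts the next tile
as long as that improves the worst aspect ratio in the strip. Tiling is
*relative*: tiles always fill the whole panel even when the displayed
structures cover only a small fraction of the ensemble; that fraction is
communicated by the "sum of occupancies" annotation instead of empty
space. Compared to the classical alternating-orientation squarify, the
vertical-strip variant gives up a little squareness to guarantee a useful
reading order — tile left edges never decrease as occupancy decreases, so
the dominant structure is always leftmost. Areas are exact: they conserve
the panel area and are proportional to occupancy to floating-point
accuracy, which the tests assert at 1e-6 relative.

## Structure drawing

Drawings come from a deterministic two-stage layout. First a radial
construction places every loop on a circle (one slot per unpaired base, two
per emerging helix; the circle radius is chosen so adjacent slots are about
one backbone length apart) and every helix as two parallel rails of stacked
pairs. Then a fixed 200 iterations of spring relaxation refine the picture:
backbone and base-pair edges are springs with rest length 1 (spring
constant 0.5), all node pairs repel with an inverse-square force (strength
0.05), and the step size cools linearly from 0.15 to 0.01. A seeded jitter
of ±0.01 breaks symmetric degeneracies; given the same structure and seed
the coordinates are bitwise identical, which makes rendered SVG documents
byte-reproducible. Pseudoknotted pairs (bracket layers beyond the first)
are excluded from the radial nesting — standard practice for knotted
drawings — but participate as springs, so they pull their partners
together without destroying the planar skeleton. The relaxation constants
were chosen so that pair and backbone distances settle within about 20% of
rest length for typical structures; visual equivalence with any particular
interactive drawing engine is a non-goal, legibility and determinism are
the contract.

## Overview strip conventions

Per time point the dominant structure is the occupancy maximum, ties going
to the smallest id (the same tie-break used when sorting a time slice).
Position 1 (the 5' end) is drawn at the bottom of the strip and the
transcript grows upward; positions beyond the current transcript length are
background-colored. Columns follow a step-function convention: the column
of time point `t_i` spans from `x(t_i)` to `x(t_{i+1})` (the last column to
`x = 1`), so the strip is piecewise constant between simulation outputs and
the columns tile `[x(t_first), 1]` without gaps or overlaps. A consequence
of pinning the last time point at `x = 1` is that its own column is empty;
the final ensemble state is still visible because the previous column
extends to the right edge.

## Filtering, animation, and the skip rule

The `min_occupancy` parameter (default 0.01) removes structures below the
threshold before rendering; a time point whose structures are all removed
disappears from the axis and the frame series entirely. The filter is
idempotent and monotone, and because per-time-point occupancies sum to at
most 1, a threshold of 0.01 caps the number of drawn structures at 100 per
time point. Animations emit one frame per remaining time point at
`1000 / speed` milliseconds per frame. For interactive scrubbing semantics
the package exposes the skip rule as a pure function: a time point selected
for less than `5 m` milliseconds produces no output, where `m` is the
maximal number of structures per time point in the file (`m = 0` yields 0:
empty time points are never skipped). The canonical output is an SVG frame
series; assembling frames into a GIF is left to external tools, SVG being
the format the figures are designed in.

## The synthetic generator

`generate_fixture()` produces the study conditions the package is tested
under: a transcript growing from 8 nt to `final_length` at 50 nt/s — a
typical bacterial polymerase speed — with 75% of the time points spread
linearly over transcription and 25% log-spaced over a 1000-fold
post-transcriptional time span. Occupancies at each time point sum to 1
over 1–3 structures. The `helix-competition` preset moves the ensemble
from a 5'-proximal hairpin to a competing 3'-reaching hairpin while
transcription is still running (the dominant id is guaranteed to switch
during transcription); `late-refold` keeps the cotranscriptional structure
at occupancy 0.92 throughout transcription and lets it decay as
`(t / t_end)^{-0.7}` afterwards, so the switch happens in the logarithmic
regime; `single-hairpin` is the minimal one-lineage control. A ±0.02
seeded perturbation (renormalized) keeps occupancies away from exact
round numbers without affecting which structure dominates.

The generator emulates the *shape* of simulator output, not its physics:
energies are a simple −1.5 kcal/mol per pair, competing helices are not
literally mutually exclusive, and the 1–3 structures per time point are far
fewer than an aggregated stochastic ensemble would carry. Tests passing on
these fixtures therefore demonstrate the correctness of parsing, geometry,
coloring and rendering — not that any particular biological system folds
this way.

## Numerical choices and problem sizes

Occupancy sums are checked against `1 + 1e-6`; trajectory writing prints
times and occupancies with the shortest decimal that round-trips the double
exactly and energies with two decimals; treemap invariants are asserted at
1e-6 relative, the axis inverse at 1e-9. The test suite runs its
property checks on randomized dot-bracket strings up to 30 nt (against a
recursive-descent oracle), structure layouts up to ~60 nt, and trajectories
of 8–12 time points and 16–30 nt final length; these sizes exercise every
code path (multiloops, bulges, pseudoknots, degenerate axes) while keeping
the full suite fast.

## Known limitations

* One trajectory per figure; merging or aggregating stochastic runs into
  occupancies is upstream preprocessing, not part of this package.
* The hue scheme guarantees distinctness of *nearby* centers, not global
  uniqueness.
* The force layout is tuned for structures up to a few hundred nucleotides;
  far larger structures will render but relaxation cost grows
  quadratically.
* Letters are only drawn when tiles are large enough for them to be
  legible.
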
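---
title: "wormsight: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{wormsight: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains what `wormsight` computes, the assumptions
behind it, the parameters that matter, what the synthetic fixtures do
and do not emulate, and the numerical choices in the geometry and
rendering code.

## The data model

Two kinds of input meet in this package, and they disagree about the
unit of observation.

**Expression tables** are gene × neuron-class matrices in CSV, after
the style of the CeNGEN consortium's thresholded single-cell RNA-seq
matrices. Columns are transcriptomic neuron classes (AVK, RIM, VA,
...), values are non-negative, and — crucially — detection has already
been decided upstream: a nonzero entry means "this class expresses
this gene at the chosen stringency". `wormsight` therefore treats
*expressed* as *strictly positive* by default. The `min_value` cutoff
(strict: value > `min_value`) exists for continuous tables; it is
applied uniformly to all query genes. Per-gene cutoffs were considered
and deferred: the primary data contract is a pre-thresholded matrix,
where a uniform 0 is the right default and per-gene knobs invite
silent inconsistency.

**Anatomy models** are 3D scenes with one named triangle mesh per
individual neuron, plus context meshes (body outline, pharynx). The
hermaphrodite has exactly 302 neurons; classes contain 1–13 cells
(AVKL/AVKR ↔ class AVK; VA1..VA12 ↔ class VA). The packaged roster
(`inst/extdata/neuron_roster.csv`, 302 rows, 118 classes) is frozen
data rather than runtime nomenclature rules, so it is auditable and
its invariants (unique cells, classes partition the roster) are tested
directly.

The bridge is `expand_class()`, a *total* function: an exact class
label returns its members; a state-suffixed label (`AWC_ON`,
`AWC_OFF`) returns the base class's two cells flagged
`state_ambiguous`, because anatomy cannot distinguish stochastically
lateralized functional states and a fabricated left/right assignment
would be worse than an honest ambiguity; a label that is itself a cell
name (`ASEL`, `ASER` — which some atlases use as column headers)
returns that single cell; anything else returns an empty set flagged
`unknown`. No label ever throws, so one odd column cannot abort a
session. Column headers that match nothing are kept in the table but
flagged, which is the hedge against atlas exports carrying
non-neuronal cell types.

## Signatures, partitions, colors

For a query gene list $(g_1, \dots, g_m)$, each cell's signature is
the bit vector of which query genes its class expresses. Cells are
grouped by exact signature; the all-false signature is the background
and never forms a block. This formalizes iterated single-gene
selection in a GUI as one joint computation — the only place the
package sharpens an interactive workflow into an algorithm — and makes
"any number of genes" well defined: blocks are pairwise disjoint,
their union is the set of cells expressing at least one query gene,
and adding a gene can only split blocks, never merge them (tested as a
property, and re-verified by the acceptance script against exhaustive
enumeration over all $2^m$ signatures).

Default colors are assigned by ordering blocks by (popcount, then the
signature read as a binary number with gene 1 as the most significant
bit) and walking a palette. The default palette is Okabe–Ito
(colorblind-safe, 8 colors) extended with evenly spaced HCL hues when
a partition has more blocks. The ordering means deeper co-expression
takes later palette colors — the familiar green → blue → orange
progression of monoamine co-expression figures arises from the
explicit three-color map in the examples, and from the ordering when
defaults are used. Assignment is a pure function of (partition,
palette, gene order); the `seed` argument is kept for interface
stability but consumes no randomness. Explicit maps always win and
must cover every block — a missing block is an error listing the
uncovered signatures, not a silently grey neuron.

The sender/receiver overlay is the two-gene case with signatures
renamed: ligand-only = sender (dark red), receptor-only = receiver
(light blue), both = its own purple rather than a blend, since blends
are ambiguous against light backgrounds. The equality between the
overlay and the two-gene partition is asserted in tests, not assumed.

## Geometry and rendering

No mesh or rendering library for R is part of this package's
dependency footprint; the geometry layer is self-contained and small:

- **Formats.** OBJ with named `o` groups plus an MTL library (one
  material per distinct color; alpha as `d`), glTF 2.0 with the
  vertex/index buffer embedded as a base64 data URI (float32
  positions, uint32 indices, `baseColorFactor` materials), and ASCII
  PLY with per-vertex RGBA, one file per object — matching the
  one-file-per-neuron PLY input mode. All colors are quantized to
  8 bits per channel *at scene-build time*, so every export → import
  round-trip reproduces cell → color bindings exactly, and the
  quantization is applied once (it is idempotent, which is tested).
- **Soma positions** are centroids of the largest connected component
  of a neuron's mesh (union-find over shared vertices), so a thin
  neurite attached to a soma, or a stray satellite blob, does not drag
  the soma point away.
- **Coordinate frames are never touched.** Whatever frame a model file
  uses is preserved; camera presets (`whole_worm`, `head`, `midbody`,
  `tail`) are defined from the bounding box: the long body axis is the
  axis of largest extent, "head" is its maximum end by convention, and
  the camera views from the axis of smallest extent. This is the
  honest choice when a model's anatomical axis conventions are not
  documented.
- **Rendering** is a deterministic software rasterizer: perspective
  projection, per-pixel z-buffer with perspective-correct depth from
  interpolated $1/z$, flat unlit per-object colors, no anti-aliasing.
  Determinism (same scene + camera ⇒ byte-identical PNG) is a tested
  contract. Context meshes are handled specially in flat mode: each
  context object's silhouette is rasterized to a coverage mask and its
  color alpha-blended exactly once over the background within that
  mask (default opacity 0.15), then neurons draw opaquely on top. A
  naive per-triangle blend would composite the front and back walls of
  a body tube twice and produce pixel colors outside the declared
  material set; the coverage approach keeps the flat-mode invariant
  that every pixel is either background, a context blend, neutral, or
  a block color. Lit shading is deliberately out of scope for
  pixel-exact guarantees.
- **Picking** is a 3D proximity query, not a mouse event: exact
  point-to-triangle distance (the standard closest-point-on-triangle
  construction, vectorized over triangles), with an even/odd
  ray-parity interior test so points inside a watertight mesh report
  distance 0. The parity ray carries a small fixed tilt so it does not
  run along mesh edges. Ties are broken lexicographically by cell
  name, which makes the AVKL-vs-AVKR midpoint case reproducible.
  Screen-pixel picking unprojects the pixel through the camera and
  takes the first ray–mesh intersection.

## The synthetic fixtures

`fixture_spec()` + `make_synthetic_model()` /
`make_synthetic_expression()` generate a toy worm: soma spheres at
deterministic positions along a body tube, left/right pair members
mirrored in the z coordinate, mesh names equal to cell names, and an
expression CSV that is either an explicit gene → class design (used
for the nested three-gene and ligand/receptor examples) or a
Bernoulli(sparsity) draw under the spec seed with positive values
where expressed. Class names are *real* class names (AVK, RIM, RIC,
...) so the nomenclature paths are exercised on the true vocabulary.
Every generator is byte-deterministic under its seed.

Chosen fixture conditions, and why: 2 cells per class (the modal class
size in the real roster, and it exercises L/R expansion); soma radius
2 model units on a body of length 100 (somas well separated, so
picking accuracy measures the query, not fixture crowding); the
ligand/receptor fixture uses 12 classes with the ligand confined to
the AVK-like pair and the receptor in 6 of the 12 classes, excluding
the ligand class — broad enough to count as "widely expressed", and
the exclusion makes sender/receiver counts a clean set-arithmetic
prediction (2 senders, 12 receivers, 0 both).

What the fixtures do **not** emulate: CeNGEN's count distributions or
thresholding procedure, real neuron morphology (somas are spheres;
neurites, when enabled, are straight stubs), the nerve ring's packed
neuropil, or anatomically meaningful soma placement. Passing tests
therefore demonstrate the correctness of nomenclature resolution,
signature algebra, coloring, geometry queries and format round-trips —
not biological fidelity of any rendering.

## Problem sizes and tolerances

The test suite and acceptance script run at deliberately chosen sizes:
50 random designs with up to 5 genes and up to 20 classes for the
partition-vs-enumeration and refinement checks (an exhaustive $2^5$
enumeration over 302 cells is still cheap); 1000 seeded interior
points for picking, drawn uniformly within 95% of the soma radius so
the expected answer is unambiguous; renders at 64×64 up to 320×240.
Geometric tolerances: sphere-distance checks allow 2% for mesh
discretization (a 24×32 UV sphere underestimates the true sphere);
soma centroids match construction centers to 1e-6; everything
discrete (partitions, counts, colors, bytes) is compared exactly.

## Known limitations

- Gene identity is the case-folded symbol string; WormBase ID
  cross-mapping is not attempted, so renamed genes must be queried by
  the symbol the table uses (the edit-distance suggestions soften
  this).
- Only the hermaphrodite roster ships; male and embryonic anatomies
  would need their own rosters and models.
- The glTF reader supports the dialect the writer emits (embedded
  buffer, one primitive per mesh), not arbitrary glTF from other
  tools; OBJ import is the general-purpose path.
- Translucency in flat mode is a single compositing step per context
  object, not depth-sorted transparency; overlapping context objects
  blend in draw order.
- Video output is a numbered PNG frame sequence (`render_turntable()`);
  encoding is left to external tools for codec reproducibility.
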
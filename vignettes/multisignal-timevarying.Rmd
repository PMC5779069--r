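---
title: "Multi-signal and time-varying neuronal reconstructions with swcx"
author: "swcx authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-signal and time-varying neuronal reconstructions with swcx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swcx)
```

## The model

A digital neuronal reconstruction in the classic SWC sense is a rooted tree
of nodes, each a line of seven values: node id, structure type (1 soma,
2 axon, 3 dendrite), x/y/z position in micrometres, local radius, and the
parent node id (-1 at a root). Every node together with its parent delimits
one *compartment*: a frustum (truncated cone) whose end radii are the parent
and node radii. The frustum tree is the unit of everything this package
computes. Two design choices close gaps the classic definition leaves open:
a root's compartment is the sphere of its own radius (so somatic voxels are
claimable during extraction), and a frustum whose two ends coincide in space
degenerates to a sphere of the larger radius (avoiding a zero-length axis in
membership tests).

`swcx` implements two orthogonal extensions of this representation and the
algorithms that populate them.

### Per-compartment channel statistics (ESWC)

Branch position and thickness are traced from the membrane label (the
*primary* channel); subcellular constituents (microtubules, F-actin,
calcium indicators, ...) arrive as additional *secondary* channels of the
same acquisition. Because their distribution within a branch is non-uniform,
each compartment is summarised, per secondary channel, by three numbers:

* **ratio** — the fraction of the compartment's candidate voxels whose
  secondary intensity passes that channel's threshold;
* **mean** — the mean secondary intensity of those passing voxels;
* **sd** — their population standard deviation.

A ratio near 1 with low sd indicates a homogeneously distributed substrate;
a ratio near 0 with high sd indicates punctate expression. An ESWC file
carries `7 + 3C` values per node for `C` channels (13 values for two).

The extraction pipeline (`extractMultichannel()`) works in two stages.
`assignVoxels()` selects candidate voxels — primary intensity at or above
the primary threshold, voxel centre inside at least one compartment — and
resolves overlaps near branch points by giving each voxel to the compartment
with the smallest *normalised radial distance* `d / r(t)` (radial distance
over local frustum radius at the projected axis position), ties to the lower
node id. This makes the assignment a deterministic partition: candidate
voxel counts are conserved, nothing is double-counted. `computeChannelStats()`
then thresholds the same voxels in each secondary stack. Empty candidate
sets or channels with no passing voxel report `(0, 0, 0)` so that column
counts stay fixed; a single passing voxel has sd 0 by the population
(divide-by-n) convention, which is used throughout because per-compartment
counts are small.

Numerical conventions: voxel indices are 0-based; the physical centre of
voxel `(i, j, k)` is `((i + 0.5) sx, (j + 0.5) sy, (k + 0.5) sz)` in the
same micrometre frame as the SWC coordinates, with no axis flips.
"Above threshold" means `intensity >= threshold` — a voxel exactly at the
default threshold of 15 (0–255 scale) is considered. The ratio denominator
is the compartment's *primary-passing* voxels, not all voxels of the
frustum; this follows directly from candidate selection preceding secondary
thresholding.

Two output dialects exist alongside ESWC. The back-compatible file
(`writeChannelSWC()`) repeats the original 7-column body verbatim and
appends, after a `#CHANNELSWC` tag, one comment line per node with the
ratio and mean of every channel (`# <id> <ratio> <mean> ...`); any SWC
reader that skips `#` lines recovers the morphology untouched. The render
export (`renderOBJ()`) writes the morphology as triangulated external
frustums plus, for each compartment with positive ratio, an internal
frustum whose radius is the external radius times `sqrt(ratio)`, so the
internal *cross-sectional area* fraction approximates the volumetric voxel
fraction (a square-root rather than linear or cube-root scaling is a
rendering choice, documented here because the quantity visualised is a
volume fraction on a per-slice basis). Mean intensity maps linearly onto an
indigo-to-dark-red ramp between user-supplied limits and clamps at the ends.

### Time-varying morphologies (SWCX)

A time-lapse series of reconstructions of the same neuron is consolidated
into one table with a row for every node present at *any* time point. The
first seven columns are the node's SWC fields at time 0; every later time
point contributes a seven-column block: a *link* field followed by updated
type, position, radius and parent. The link field holds either

* a positive integer — the *temporal parent*, i.e. the id of the
  corresponding node at the previous time point (for stable nodes);
* a dynamic event code: -1 branch extension (terminal or interstitial),
  -2 local scaling (stretch/contraction along the branch or radius change),
  -3 rotation/deformation, -5 re-emergence (extension following a
  retraction at the same location); or
* 0 when the node is absent at that time point (all other block fields are
  then zero as well).

Terminal retraction (-4) has no natural column of its own — the node's
block at the disappearance time is absent — so it is recorded in the
per-transition event report (`transitionEvents()`), which is the
authoritative record of retractions; the table stores the all-zero absent
block. Nodes that do not yet exist at time 0 keep their id in column 1 with
the remaining time-0 fields zeroed, which keeps ids file-unique and rows
fixed-width.

`classifyEvent()` uses a decision cascade per node and transition:
absent-to-present is an extension, or a re-emergence if the node was
present at any earlier time; present-to-absent is a retraction;
present-to-present within the positional and radius tolerances links to the
temporal parent; otherwise a displacement within an angular tolerance
(default 15 degrees) of the parent-axis direction, or a pure radius change,
is local scaling, and anything else is rotation/deformation. The angular
discriminant is this package's concrete rule for separating the scaling and
deformation categories, which are defined conceptually but not numerically
in the field. Defaults: positional tolerance 0.01 um, radius tolerance
0.01 um, matching radius 1.0 um for the optional nearest-neighbour
correspondence. The default correspondence is id-based, matching
id-preserving editing workflows; nearest-neighbour matching is greedy
within the matching radius and constrained to preserve parent–child order.

Row ordering follows the ordering rule of the per-time-point files: new
branches appear immediately after their parent node (terminal extension) or
after the entire subtree of their attachment node (interstitial extension).
Consolidation realises this with a stable merge: walking each time point's
node order, known ids advance a cursor and new ids are inserted right after
it. Timestamps are free-unit floats (minutes and days both occur in
practice) recorded verbatim in the header; extra header metadata (e.g.
global skeleton scaling) is carried as `# key = value` comment lines.

The combined layout extends *every* time block (including time 0) with
three statistics columns per imaging channel, giving `(7 + 3C) x T` columns
— e.g. 40 columns for one channel over four time points. Absent nodes carry
zero statistics.

The intermediate per-transition interchange file (`writeAnnotatedSWC()`)
keeps seven columns with the neurite-type column temporarily repurposed to
carry the link/event code, so a series can be edited in standard SWC
tooling. This dialect cannot carry the type of newly extended nodes; on
re-reading, stable nodes recover their type from the previous time point
and new nodes default to dendrite (type 3). The in-memory pipeline
(`annotateSeries()` then `consolidateSWCX()`) has no such loss. A further
consequence of pairwise files is that re-emergence detection needs presence
history older than the immediately preceding time point, which the
file-by-file CLI path cannot see; `annotateSeries()` threads it.

## The synthetic generator

Every fixture is generated in code, deterministically per seed.

* `generateMorphology()` grows a binary tree from a spherical soma:
  segments of about 3 nodes, lengths `N(8, 2)` um, sibling branch angle
  `N(50, 10)` degrees, radius taper 0.85 per segment, per-node direction
  jitter of 3 degrees. These scales give arbor proportions typical of the
  dendritic trees this representation is used for at light-microscopic
  resolution, while staying small enough to rasterize into test-sized
  volumes. Coordinates and radii are rounded to 6 decimals so written files
  round-trip byte for byte.
* `rasterizeMembrane()` reverse-generates an image stack from a tracing
  (voxel centres inside any compartment get the stated intensity), the same
  trick used to produce ground-truth stacks for tracing software.
* `paintChannel()` paints a secondary channel over a voxel assignment:
  per compartment, exactly `round(ratio * n)` voxels receive intensities
  from a normal distribution truncated below at the threshold (rejection
  sampling, integer-rounded, clamped to the bit depth); all other voxels
  get uniform sub-threshold noise in `[0, threshold - 1]`, so thresholding
  is unambiguous. Because rounding and truncation shift the realised
  moments away from the nominal targets, the generator records the realised
  (ratio, mean, sd) of the painted integers, and those recorded values —
  not the nominal spec — are the recovery oracle. The preset regimes are
  homogeneous (ratio 0.9, mean 120, sd 6) and punctate (ratio 0.15,
  mean 160, sd 45) on the 8-bit scale.
* `simulateDynamics()` applies a script of extension, scaling, deformation,
  retraction and re-emergence events, one transition per time step,
  preserving node ids of untouched structure, and emits the per-time-point
  trees together with the gold SWCX table and gold event reports the
  annotation pipeline must reproduce exactly. Random scripts keep the
  events of one step independent (a node is targeted at most once, and a
  moved node's parent and children are frozen for that step) and keep
  magnitudes clear of the classifier tolerances — displacements of at least
  0.5 um and radius factors outside `[0.7, 1.4]` — so every scripted event
  has exactly one correct label. Scale events encode their flavour in the
  magnitude sign: positive is an axial stretch in micrometres, negative a
  radius scale factor.

What the generator does *not* emulate: optics. There is no point-spread
blur, no photobleaching, no z-anisotropic smearing, no registration error
between channels or time points, and correspondence across time points is
id-preserving by construction. Passing tests therefore demonstrate the
correctness of the representation and of the extraction/annotation
algorithms on geometrically exact, aligned inputs — not robustness to
tracing error or imaging noise in real acquisitions, where thresholds and
tolerances would need tuning to the data.

## Problem sizes and performance

The test suite and the acceptance script use stacks of 24–48 voxels per
axis and arbors of roughly 10–30 nodes; at these sizes the exhaustive
all-pairs oracle stays cheap, 50 oracle comparisons plus 100 scripted
time-lapse round trips complete in well under a minute, and every numerical
property (exact ratio recovery, 1e-9 relative agreement of mean/sd) is
already decided at machine precision, so larger volumes would add runtime
without adding evidence. The voxel-assignment loop itself is vectorised per
compartment over a bounding box, and scales to realistic stacks
(hundreds of voxels per axis) in seconds.

## Known limitations

* Assignment is by voxel centre, not partial-volume overlap; voxels
  straddling the frustum surface are all-or-nothing.
* The ESWC/CHANNELSWC headers (`# channels`, `# thresholds`, `# spacing`,
  the `#CHANNELSWC` block layout) are this package's documented dialect;
  other tools record the same quantities but no header grammar is
  standardised.
* Fixed-decimal output (6 decimals, trailing zeros trimmed) round-trips
  exactly only for values representable at that precision; computed ratios
  such as 2/3 re-read to within 1e-6. In-memory pipelines are unaffected.
* No image registration, spectral unmixing or deconvolution: stacks are
  assumed aligned to the tracing and to each other.
* Retraction is modelled for terminal branches; interior deletions that
  split a tree are out of scope, as is any repair of structurally broken
  input beyond diagnostics.
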
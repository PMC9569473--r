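---
title: "Validating and assembling multi-domain protein models with cross-link restraints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating and assembling multi-domain protein models with cross-link restraints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xlinkr)
```

## The problem

Very large proteins — apolipoprotein B-100, with 4536 residues in its mature
form, is the motivating case — cannot be modeled in one piece by current
structure-prediction tools. A practical strategy is divide and conquer:
split the sequence into subunits and domains at predicted boundaries, model
each piece independently, then validate and assemble the pieces against
experimental distance restraints. Two restraint sources are used here:

* **MS-cleavable cross-links.** An amine-reactive linker such as DSSO
  covalently joins two lysines that were close in space; mass spectrometry
  identifies the linked residue pair. The linker geometry bounds the
  Cα–Cα distance of the pair.
* **Disulfide bonds.** Known cystine pairs require their sulfur atoms to be
  within bonding distance.

`xlinkr` implements the full downstream workflow: deriving the distance
threshold from linker geometry, measuring and classifying restraints on a
model, keeping the segmentation bookkeeping, rigid-body assembly of domain
models under restraints (including the mirror-image ambiguity), simplified
lipoprotein-particle geometry checks, and the protein-painting
surface-exposure logic. Spectral search, FDR control and model generation
are upstream and out of scope; the package consumes residue-pair lists and
PDB coordinates.

## The distance model

A cross-link between residues $i$ and $j$ implies

$$ d(C\alpha_i, C\alpha_j) \;\le\; L_{spacer} + a_i + a_j + f $$

where $L_{spacer}$ is the linker spacer length, $a$ the side-chain arm of
each linked residue and $f$ a flexibility allowance for backbone dynamics.
For DSSO linking two lysines this is $10.1 + 2 \times 6.29 + 3.0 =
25.68\,\mathrm{\AA}$, reported (rounded to the nearest integer) as the
working threshold of 26 Å:

```{r}
max_ca_distance(linker_dsso(), "K", "K")
```

Measured distances are classified into bands:

* **satisfied**: $d \le$ threshold (the bound is closed: exactly 26.0 Å
  counts as within the limit);
* **marginal**: threshold $< d \le$ grace (default 30 Å) — "slightly
  beyond the limit", compatible with local flexibility not captured by a
  static model;
* **violated**: $d >$ grace;
* **unmeasurable**: an endpoint falls in a region absent from the model.

The 30 Å grace bound is this package's own convention for separating
"slightly beyond" from clear violations; both bounds are arguments
everywhere they appear. Unmeasurable is deliberately not an error: with a
partial model, a cross-link can be identified by MS yet impossible to
measure, and reports carry `n_identified = n_measured + n_unmeasurable`.

Disulfides are evaluated on SG–SG distance against a 5.6 Å bound. On
Cα-only traces the package falls back to Cα–Cα with a wider default bound
(7.5 Å, roughly the Cα separation of bonded cystines) and flags the
evaluation, so a fallback can never masquerade as a true sulfur check.

## Segmentation bookkeeping

A segmentation scheme records named segments at three levels — subunit,
domain, coil — as inclusive 1-based ranges in full-sequence
(preproprotein) numbering, a convention chosen so residue labels match the
literature even though the signal peptide itself lies outside the modeled
span. Segments may own several ranges (a domain assembled from three
separate stretches is one segment with three ranges). A coverage mask,
separate from the scheme, marks residues actually present in the models.
The packaged apoB-100 scheme ships in `inst/extdata/apob_scheme.yaml` with
five subunits over residues 28–4563, eleven domains, the two long coils,
and a secondary-structure content table whose cells are percentages of the
*whole* sequence — so the cells of one class sum to that class's total
content (~24% helix, 41% strand, 35% coil). Both that convention and
per-segment percentages are available in `ss_content()`.

Cross-link topology follows the segmentation: a link is inter-subunit when
its endpoints fall in different subunits, intra-domain when both share a
domain-level segment, and intra-subunit otherwise.

Consensus domain boundaries from sliding-window predictions are clustered
by single linkage with a 10-residue tolerance; a cluster is kept when
supported by at least 2 distinct windows, capped by the number of windows
that actually cover the position (so a boundary near the span edge, seen
by a single window, is not penalized for lack of witnesses). The
representative is the rounded median. All three knobs are arguments; the
defaults are this package's choice, since window comparison rules are
rarely published in detail.

In-silico trypsin digestion cleaves after K/R except before P and defaults
to the settings typical of cross-linking searches (≤3 missed cleavages,
minimum peptide length 5).

## Rigid-body assembly

Domain models are placed as rigid bodies. The objective for placing a
mobile domain against a fixed, already-placed assembly is

$$ \mathcal{L} \;=\; \sum_{\text{links}} \max(0,\, d - d_{max})^2
   \;+\; \lambda \cdot \#\{\text{clashes}\} $$

with $\lambda = 100\,\mathrm{\AA^2}$ per clashing Cα–Cα pair closer than
4 Å between different bodies. Experimental links are upper bounds only. Synthetic fixtures additionally record each planted
link's true distance and can fit it two-sided ($(d - d_{target})^2$); this
matters because a single upper bound removes at most one degree of freedom,
so a handful of inequality restraints leaves a continuum of zero-loss
poses — fine for satisfaction checks, useless for accuracy claims. The
recovery guarantees quoted for this package therefore use two-sided
targets over at least six links with spread directions.

The optimizer is a seeded multi-start search: uniform random rotations
(quaternion sampling) with the mobile restraint-anchor centroid initialized
near the fixed anchors' centroid; each start is first flowed by an
alternating projection (project each anchor onto the sphere of its bound
around its fixed partner, re-superpose by least squares, repeat to
convergence), then the best candidates are polished by coordinate descent
over the six pose parameters with step halving (initial steps 0.4 rad /
8 Å, convergence at a loss change below 1e-6 or steps below 1e-4 rad /
1e-3 Å, at most 500 sweeps). The loss trace is recorded and is
non-increasing; the final loss never exceeds the best random start.
Anchors that are collinear (or fewer than three) cannot pin a rigid pose;
the fit warns and flags `degenerate` in its diagnostics.

**Mirror-image ambiguity.** Distance-only restraints cannot distinguish a
placement from its reflection: reflecting a zero-loss configuration
through any plane yields another zero-loss configuration (up to clashes).
When `allow_mirror = TRUE` the optimizer also fits the reflected mobile
copy and returns the improper solution only when its loss is strictly
lower — always flagged, never silently applied, because reflecting real
atomic coordinates inverts chirality and produces a non-physical
enantiomer. The flag tells the analyst the same thing it told the original
modelers: the domain model itself is likely the mirror image of the true
fold and should be rebuilt or repositioned, not literally reflected.

Greedy sequential assembly places segments in a given order (the first is
the anchor), each fitted against the union of everything already placed
using every bridging restraint; segments with no bridging restraint are
skipped with a warning. Links with an endpoint in a coil-level segment can
receive a configurable slack (default 10 Å) on top of their bound when a
scheme is supplied — coils are flexible, and a rigid-body engine should
not charge full stringency for them.

## Particle geometry

LDL and VLDL particles are idealized as a discoid (default 200 × 200 ×
110 Å) and a sphere (default 300 Å diameter). The discoid surface is the
set of points at constant distance $d_z/2$ from a flat central ellipse
with semi-axes $d_x/2 - d_z/2$ and $d_y/2 - d_z/2$ — an elliptical disc
with a rounded rim that reproduces the stated bounding dimensions. Signed
surface distance for the rim region is computed numerically by minimizing
over the rim angle (coarse 5° probe followed by local optimization).
`shell_containment()` reports the fraction of Cα atoms within a shell
(default ±20 Å) around the surface — a coarse sanity check that an
assembly actually wraps a particle, not a fit to density.

## Solvent accessibility and protein painting

Accessible surface area uses sphere-point sampling: each atom inflated by
the probe radius (1.4 Å), sampled with a deterministic golden-spiral of
960 points, fraction of points outside all neighboring inflated spheres
summed per residue. Cα-only traces get an enlarged 3.0 Å pseudo-atom
radius standing in for the missing residue body. Relative accessibility is
reported against published tripeptide reference maxima (shipped as data,
swappable), clipped to [0, 1.2] with over-reference values flagged.
Because the sample grid is fixed in the laboratory frame, areas are
rotation invariant only to sampling tolerance (≤2% at 960 points).

Protein painting: a peptide is paint-positive iff present in **all**
unpainted replicates and absent in **all** painted replicates (default
three of each); exposed regions are the merged ranges of paint-positive
peptides, so the output has peptide-level, not residue-level, resolution.
Hydrolyzed mono-link concordance is the fraction of dead-end linker sites
falling inside those ranges — reported as a number with no pass threshold,
since "almost entirely" is not a quantity.

## The synthetic generator

Every algorithm is testable without external structures. `make_segment()`
produces idealized Cα traces (helix: radius 2.3 Å, rise 1.5 Å/residue,
twist 100°/residue; strand: 3.8 Å steps with a 10° zigzag; coil:
self-avoiding walk, 3.8 Å steps, 3.5 Å minimum separation), all with
closed-form oracles. `plant_crosslinks()` samples residue pairs whose true
distances fall in requested category bands and records the ground truth.
`toy_apob()` builds a five-segment bundle at one tenth of the apoB subunit
lengths (99/106/48/151/51 residues) with 13 planted inter-segment links
distributed 4+3+3+3 along the default assembly order — enough bridging
restraints per step for a well-posed greedy assembly. `mirror_fixture()`
plants links against a *reflected* copy of the mobile coil, so only an
improper transform can satisfy them; coils are used on both sides because
an ideal helix is nearly mirror-symmetric at the Cα level and would blur
the two branches. Everything is deterministic under a seed.

What the fixtures do **not** emulate: real side chains and packing,
linker-accessibility of lysines (a planted pair ignores whether a real
linker could reach it), spectral noise and FDR, and flexible-backbone
behavior. Passing tests demonstrate the bookkeeping, geometry and
optimization are correct — not that any particular biological model is.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run the optimizer on segments
of 40–151 residues with 8–13 restraints, 20 random starts, and 20 seeded
recovery replicates — sizes chosen so the full suite exercises every code
path in a few minutes on one core while leaving the conclusions unchanged
at larger sizes. Clash counting uses a cell-list grid identical in result
to the all-pairs scan; inside the optimizer loop a direct vectorized count
is used below 250k pair candidates, the grid above. Ties in classification
land on the closed side of each band; violation lists are ordered by
distance descending, then residue index, so reports diff cleanly.

## Known limitations

* Rigid bodies only: the engine approximates coil flexibility with bound
  slack, never remodels torsions.
* Upper-bound-only restraint sets leave pose families; accuracy statements
  require two-sided (ground-truth or harmonic) restraints.
* The particle shells are bounding geometry, not density; containment is a
  sanity check.
* SASA on Cα traces is a coarse proxy; use full-atom models where side-chain
  accessibility matters.
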
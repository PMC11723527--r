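---
title: "Parsing predicted protein structures into domains: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parsing predicted protein structures into domains: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domainseg)
```

## Overview

`domainseg` parses a single predicted protein chain into structural domains
in two stages. First, a convolutional network maps stacked residue-pair
feature matrices to a per-pair "same-domain" probability map. Second, a
deterministic pipeline converts that map into discrete domain definitions:
disorder masking, helical-linker detection, segment clustering, and
contact-based boundary refinement. This vignette documents the model, the
parameters that matter, the numerical conventions, and the design decisions
taken where the procedure was genuinely open — together with what the
synthetic test suite does and does not demonstrate.

## Input features

For a chain of `L` residues the parser assembles 24 channels of shape
`L x L` (`featurize()`), later mapped into 500 x 500 crops:

| channel | content | units / range |
|---|---|---|
| 1 | minimal heavy-atom distance between residues i and j | Angstrom |
| 2 | predicted aligned error, symmetrized | Angstrom |
| 3, 4 | residue positions i and j, divided by 2000, clipped to 1 | [0, 1] |
| 5–14 | up to 10 sequence-evidence matrices (HHprob / 100) | [0, 1] |
| 15–24 | up to 10 structure-evidence matrices (Z / (Z + 10)) | [0, 1) |

Assumptions: one polypeptide chain, at least one heavy atom per residue,
per-residue model confidence (pLDDT) stored in the coordinate file's
B-factor field, and an AFDB-style PAE matrix of matching size.

**PAE symmetrization.** PAE is asymmetric by construction (the error of
residue j's position when aligned on residue i). All consumers here use the
elementwise minimum of the matrix and its transpose. The minimum preserves
the strongest "well-modeled" signal in either direction and gives a single
convention for both the network channel and disorder detection; it is
isolated in one place (`pae_matrix()$sym`) so a mean or raw variant is a
one-line change.

**Evidence channels.** Hits are filtered by `acceptability_config()`.
The exact numeric criteria for an "acceptable" hit are pipeline-dependent
and intentionally all exposed; the defaults (sequence: HHprob >= 20 and
>= 10 aligned residues; structure: Z >= 2 and >= 20 aligned residues) are
placeholders to be calibrated against whichever search stack produced the
hits. Accepted hits are ranked (score descending, ties by reference-domain
id ascending) and grouped greedily: a hit joins the first group where its
coverage overlap is below 20% of either the hit's or the group's coverage.
A group therefore collects *complementary* (low-overlap) hits that tile the
query, and alternative hypotheses for the same region land in different
groups. Group matrices merge member blocks by elementwise maximum; groups
are ranked by their best member's scaled score and capped at 10 per source.
HHprob (0–100) and Z (unbounded) live on different scales, so sequence
scores are divided by 100 and Z is squashed as `z / (z + 10)` — bounded,
monotone, and comparable across sources; both maps live in
`scale_hit_score()`.

**External searches are out of process.** The package parses `.hhr` files,
a Dali-derived block table, and a pre-digested hits TSV; it does not run
HHsuite, Foldseek or Dali. The iterative masked alignment loop
(`iterative_structural_alignment()`) — re-aligning the unaligned remainder
of the query against one reference domain until nothing is found, so tandem
copies are each recovered — takes the aligner as a pluggable function and
stops when fewer than 20 query residues remain (configurable).

## Cropping

The network consumes fixed 500 x 500 inputs.

* `L <= 500`: one padded crop. During training the left pad is uniform on
  `[0, 500 - L]` (re-drawn every epoch); at inference it is zero. Padded
  pixels are zero in every channel and excluded from loss and assembly.
  `L = 500` is handled by the padding path with a zero-width pad.
* `L > 500`: `crop_count(L)` crops per epoch (1 up to 750 residues, 2 up to
  1000, 3 up to 1500, 4 up to 2000, 5 beyond). Each training crop is,
  with equal probability, one 500-residue window at a uniform start, or two
  windows totalling exactly 500 residues. Two-segment lengths are split
  uniformly with each segment at least 50 residues — the bounds are random
  rather than fixed at 250/250, matching the spirit of fully randomized
  segment boundaries; the floor keeps degenerate slivers out.
* Inference uses a deterministic tiling: continuous 500-wide windows at
  stride 250 (the last clamped to end at `L`) plus two-segment crops pairing
  each 250-residue tile with every later non-adjacent tile. Any pair within
  500 residues falls inside a continuous window; any farther pair falls in
  the cross block of a two-segment crop, so every residue pair is covered —
  the tests verify this exhaustively for L in {501, 700, 1300, 2100}. The
  stride and pairing scheme are the smallest simple scheme with guaranteed
  pair coverage, O((L/250)^2) crops; only the coverage contract is load-
  bearing. Outputs for pairs in several crops are averaged (plain means; no
  blending weights) and the result symmetrized by averaging with its
  transpose.

Position channels store residue numbers scaled by 1/2000 and clipped to 1:
raw indices are unbounded and would dominate the input scale; 2000 sits
above the longest crop-addressable chains of interest.

## Network

`network_config("full")` describes the full-scale architecture: a 1x1
projection of the 24 channels to 64 filters, then 12 residual blocks of 4
dilated 3x3 convolutions — 48 convolutional layers — with filters stepping
64/48/32/16 and dilations 8/4/2/1 across block quartiles, 15 dropout layers
(ratio 0.15) after every 3rd trunk convolution (positions 3, 6, ..., 45),
and a 1x1 two-class softmax head whose class-1 map is the same-domain
probability. Early wide-dilation layers give every pixel broad context;
late narrow layers refine local boundaries. Layer counting is by
introspection (`count_layers()`): the 48 counts the trunk's dilated
convolutions; the input projection, skip projections (1x1, used when a
block changes the filter count) and the head are reported separately.

Everything the published description leaves open is configuration, not
constant: the exact filter/dilation schedule, the optimizer (Adam,
learning rate 1e-3 by default), batch size (1 crop per update), and the
epoch cap (30) with optional early-stopping patience (off by default, so
the cap governs). Distances and PAE are squashed inside the forward pass as
`d/(d+15)` and `p/(p+10)` to keep all channels on comparable bounded
scales; weights use He-normal initialization from the run seed.

**Masked semantics.** The network is defined so that activations are zero
at padding pixels at every layer. Because every crop's valid pixels form
one contiguous square block (segments are placed consecutively after the
left pad), the forward pass runs on the valid bounding box with zero
boundary conditions — exactly equivalent, and it means padded inputs
provably cannot influence the loss (a property the tests check by
perturbing padding and asserting an identical loss), while short proteins
train at `L x L` cost rather than 500 x 500.

**Training.** Examples carry whole-protein feature sets plus reference
domains; crops are re-drawn each epoch from a per-epoch seed derived from
the run seed, so successive epochs see slightly different inputs. The loss
is masked binary cross-entropy between the class-1 map and the 2D
representation of the reference domains (1 iff both residues are in the
same domain; residues in no domain are 0 against everything), probabilities
clipped to `[1e-7, 1 - 1e-7]`. Validation holds out whole homology
clusters (`split_by_cluster()`, default 5% of clusters) so close homologs
never straddle the split. A non-finite loss aborts with the epoch index.
Both the "tiny" preset (8 convolutions, 2 dropout layers, 8 filters) and
the per-epoch crop seeds are deterministic on CPU: two runs from one seed
produce bitwise-identical logs and parameters.

## From probabilities to domains

All thresholds below are fields of `disorder_config()`, `linker_config()`
and `cluster_config()`.

1. **Disorder.** A residue's PAE neighbors are residues at sequence
   separation >= 20 with symmetrized PAE < 6 Angstrom. The chain is tiled
   into non-overlapping 5-residue windows (the trailing remnant kept as a
   short window under the same rule); a window whose residues total <= 10
   neighbors is disordered. Tiled rather than sliding windows match the
   segment convention below and keep every residue's label unique; the
   choice is documented here because either reading is defensible.
2. **Helical linkers.** Same windowed test, with neighbor pairs inside one
   secondary-structure element not counted, windows required to have at
   most 40% candidate intra-domain residues (residues covered by acceptable
   hits), and — since the target is *helical* linkers — only windows
   intersecting a helix are eligible (`helix_only = FALSE` relaxes this).
   Secondary structure elements are maximal runs of DSSP codes: >= 3
   consecutive B/E residues form a strand, >= 6 consecutive G/H/I a helix.
   The thresholding consumes a DSSP-alphabet string (from `read_dssp()` or
   any assigner); bundling a DSSP reimplementation would couple the rule to
   one assigner for no gain, and the synthetic generator plants its codes
   directly.
3. **Segments.** Non-overlapping 5-residue tiles; a trailing remnant
   shorter than 5 is kept as a short segment (discarding termini would bias
   boundaries; its Psame values average over the actual block size).
   Tiles with >= 3 excluded residues are dropped.
4. **Clustering.** For segment pairs with mean same-domain probability
   Psame above `p_min = 0.89`, processed in descending order, three
   scenarios apply: both ungrouped — the pair founds a group; one grouped —
   the free segment joins if (group within-mean) / (segment-to-group
   cross-mean) `< ratio_max = 1.12`, else it founds a singleton group; both
   grouped — the groups merge if either within-mean is below `ratio_max`
   times the cross-mean. Ties in Psame are ordered by segment indices
   ascending, making the pass fully deterministic. A singleton group has no
   within pairs; its within-mean is defined as its own diagonal block mean
   — the natural degenerate value, and it only matters until the group
   gains a second member. The defaults 0.89 and 1.12 are the grid-search
   optimum of the correct-domain fraction (> 75% mutual overlap);
   `grid_search_xy()` reruns that optimization on any validation set, with
   ties resolved to the smallest `p_min` then smallest `ratio_max`.
5. **Refinement.** Contacts are residue pairs under 6 Angstrom (minimal
   heavy-atom distance) and more than 6 residues apart in sequence. Sweeps
   run N- to C-terminal with removals before additions — a fixed order
   chosen for determinism, capped at 20 sweeps (a fixed point is typically
   reached in a few): a terminus of a contiguous run with strictly more
   contacts outside its domain than inside is dropped; an unassigned
   residue sequence-adjacent to a run with strictly more contacts inside
   than outside is recruited. Segments left ungrouped by clustering stay
   unassigned rather than being force-merged; the recruitment rule may
   still claim their residues. Finally, domains under 20 residues are
   discarded. Outputs are 1-based inclusive ECOD-style range strings;
   internal coordinates are also 1-based inclusive throughout (the native R
   convention — a deliberate choice to avoid a permanent off-by-one hazard
   at the I/O boundary).

Degenerate inputs behave predictably: an all-disordered chain yields no
domains and a fully unassigned residue set; an empty segment list or empty
pair list yields no clusters; IoU of two empty sets is an error rather than
a silent 0.

## Evaluation conventions

Detection uses *at least* 50% of a reference domain's residues assigned to
predicted domains collectively; split counting uses *strictly more than*
50% per predicted domain — both inequalities carried exactly as printed in
the conventions this package follows. Correctness requires strictly more
than 75% mutual overlap. Summary quantiles (e.g. median IoU in the CLI
report) use linear interpolation (R's default type 7).

## The synthetic generator: what it does and does not show

`make_protein()` realizes each domain as a compact self-avoiding random
blob (step 3.8 Angstrom, minimum separation 3 Angstrom, confined to a ball
sized so intra-domain distances are mostly under ~15 Angstrom), translates
blobs at least 25 Angstrom apart, and joins them with extended jittered
linkers; PAE is drawn uniformly from 2–5 Angstrom within domains and 15–30
elsewhere; pLDDT is 85–95 in domains, 30–50 on linkers; DSSP codes tile
strand/helix elements inside domains. `make_hits()` plants 1–5 high-scoring
hits per domain covering 60–100% of it, plus optional low-scoring decoys
straddling boundaries. `make_probability()` substitutes for the network
with Beta-mode block noise and a controlled flip rate. One flag produces a
discontinuous layout (first domain wrapping the second). All randomness
derives from one seed; domain sizes below ~45 residues interact with the
20-residue neighbor separation and can legitimately be flagged disordered,
which is a property of the method, not a bug.

This emulates the *statistical block structure* the pipeline consumes —
distance and PAE contrast, evidence coverage, single- and multi-domain
architectures — not protein chemistry: no real fold topology, no
AlphaFold-specific error correlations, no ambiguous packing between tightly
interacting evolutionary units. Passing tests therefore demonstrate that
the implementation is faithful (each operation matches independent
brute-force oracles; a small network can recover planted structure
end-to-end), not that the parser attains any particular accuracy on real
AlphaFold models — that depends on training data and search pipelines
outside this package's scope.

## Problem sizes in the test suite

The shipped tests train the "tiny" preset on a 30-protein suite (15
two-protein homology clusters over five architectures, chains of roughly
130–260 residues) for 8 epochs at learning rate 3e-3 with 20% of clusters
held out — sizes chosen so the whole suite, including the 1000-instance
oracle-equivalence sweep, runs comfortably on a single CPU while still
exercising discontinuous domains, decoy hits and held-out generalization.
The full-scale preset is instantiated and introspected but not trained by
the tests; training it is a data-scale undertaking, not a desk-scale one.

## Known limitations

* Single chains only: no assemblies, no inter-chain domains; hydrogens are
  ignored and only the first-listed altloc is kept.
* The package defines the orchestration contract for homology searches but
  does not run them; evidence quality is inherited from whatever produced
  the hit files.
* Discontinuous domains are supported throughout (crops, targets, parsing,
  range strings), but segment clustering has no explicit prior favoring
  them; recovering a discontinuous domain relies on the probability map
  carrying its cross-segment block.
* The feature and probability containers are RDS files; the layouts are
  small documented lists, trivially re-exportable to other formats.
* No GPU path: the convolution kernels are single-threaded C++, which is
  what makes bitwise determinism straightforward.
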
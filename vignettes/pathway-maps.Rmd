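---
title: "Process-description signalling maps: model, scores and rendering choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Process-description signalling maps: model, scores and rendering choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathmapr)
```

## The problem and the model

Comprehensive signalling maps represent whole areas of cell biology (DNA
repair and its coupling to the cell cycle, EMT regulation, ...) as one
seamless process-description diagram: a bipartite reaction network whose
nodes are typed molecular species — proteins, genes, RNAs, antisense RNAs,
simple molecules, ions, drugs, phenotypes and complexes — and whose typed
hyperedges are biochemical reactions (state transitions, translation,
transcription, association/dissociation, transport, degradation) carrying
regulators of five classes (catalysis, inhibition, modulation, trigger,
physical stimulation). `pathmapr` models exactly this vocabulary
(`map_entity()`, `map_reaction()`, `signalling_map()`) and reads/writes the
CellDesigner SBML dialect in which such maps are curated in practice.

Identity conventions, applied consistently across merging, scoring and
overlay:

* proteins/genes/RNAs are identified by their **HUGO symbol**, never by the
  display name; drawn modification states (`A` vs phosphorylated `A`) stay
  distinct entities but collapse to one symbol for scoring and staining,
  because both scores and omics data live at the gene/protein level;
* small molecules are identified by a CHEBI-style identifier (falling back
  to the name), **class-free**, so that the same chemical drawn once as
  `SIMPLE_MOLECULE` and once as `ION` surfaces as a merge conflict rather
  than a silent duplicate;
* coordinates are pixels of the most detailed zoom level, origin top-left,
  y growing downwards, an entity's position being the top-left corner of
  its box — the raster/tile convention used downstream.

## Annotation dialect

Entity annotations have four sections — Identifiers, Maps_Modules,
References, Confidence — plus free-text notes. The on-disk grammar
(`NAMESPACE:id`, `MAP:<map>`, `MODULE:<map>:<module>`, `PMID:<id>
[review]`, `REF=<n>`/`FUNC=<n>`) is this package's own dialect: the
four-section structure and the tagging idea are established practice, but
no literal syntax is standardised, so we chose a colon grammar that is
unambiguous, greppable and round-trips exactly
(`parse_annotation(serialise_annotation(a)) == a` is property-tested).
Review-vs-original classification is an explicit `[review]` suffix
(defaulting to original): the curator knows the publication type, and the
toolkit stays offline and deterministic. Semantic flags needed by other
modules ("backbone", "canonical") are plain note lines, so they survive the
round trip without extending the format.

## Confidence scores

Two integer scores in 0..5 (0 = undefined, 5 = high confidence) are
computed for every reaction and every complex (`score_map()`).

**REF** weighs the references of the element's own annotation: 1 point per
original article, 3 per review, and the score is `min(5, sum)`; an empty
reference list is 0. The capped sum is the simplest rule consistent with
the published weights and the published endpoint (two reviews → 5); it is a
dialect choice and is documented as such.

**FUNC** measures functional proximity of the participant set `P` (all
protein participants as reactants, products or regulators, complexes
recursively flattened to protein members) in a user-supplied PPI network
(HPRD-like; supplied as a SIF edge list, never downloaded):

* `|P| < 2`, or any symbol absent from the network → 0 (undefined);
* any pair in different components → 0 (disconnected);
* otherwise `FUNC = clamp(6 − round_half_up(d̄), 1, 5)` with `d̄` the mean
  over all unordered pairwise shortest-path distances.

Published behaviour fixes the single-pair column (1→5, 2→4, 3→3, 4→2,
disconnected→0). Two points are extrapolations of ours: (i) distances are
**averaged before** discretisation (mean-then-round, round-half-up), since
whether the original implementation averaged distances or per-pair scores
is not stated — the alternative gives the same result on all published
single-pair cases; (ii) a connected but remote participant set (`d̄ ≥ 5`)
scores 1, reserving 0 strictly for undefined/disconnected, matching the
"0 = undefined confidence" semantics. The implementation is verified
against an independent vectorised Floyd–Warshall oracle on hundreds of
random graphs, plus monotonicity under network densification.

## Hierarchy: layers, modules, extraction, merging

Module membership comes from the machine-readable `MODULE:` tags, not from
geometry — background shapes are rendering artefacts. `modules_from_tags()`
creates one module per distinct tag; untagged entities land in a reserved
`_untagged` module; a reaction is listed in every module containing at
least one participant. Module tags carry no layer, so the operation accepts
an optional module→layer mapping (the fixture truth record provides one);
unmapped modules go to a `_default` layer.

Module extraction uses the **strict** boundary rule by default (keep a
reaction only if *all* participants are inside the module closure —
entities plus their complex members), with the loose (≥ 1 participant)
rule behind a flag: published practice only says module content is limited
to the module's processes, leaving the boundary rule open. Extracted maps
get a fresh layout: `relayout()` runs a seeded Fruchterman–Reingold layout
(no algorithm is prescribed anywhere, FR is the field's default), then
snaps boxes to a grid ordered by the FR coordinates — this guarantees zero
overlapping boxes (checked O(n²) in tests) while preserving the layout's
neighbourhood structure, and is exactly reproducible from the seed.

`merge_maps()` unifies entities by identity key, unions identifiers and
tags, de-duplicates references by identifier and reactions by
(class, reactant-set, product-set, regulator-set) over keys, and offsets
the second map to a free canvas region; it is commutative up to layout.

## Semantic zoom

The default policy has three levels, within the recommended three-to-four:

1. **backbone** — entities with participation degree ≥ `k` (default
   `k = 4`) or an explicit `backbone` note, plus module background shapes.
   "Backbone" has no formal published definition; participation degree is
   our operationalisation, and the explicit flag lets curators override it.
2. **canonical** — entities/reactions carrying the `canonical` note. The
   published description derives canonical membership by intersecting the
   map with external pathway databases; that intersection is delegated to
   the curator/tag to keep the tool offline.
3. **detail** — the full map.

`prune()` is a pure per-level rule and never reroutes: a reaction is kept
only with all its participants. Monotone detail across levels (everything
visible at level *i* stays visible at *i* + 1) is enforced in
`zoom_views()` by cumulative union, rather than inside `prune()`, keeping
the rule itself simple. (The published figure caption orders the views
differently from the running text; we follow the text's narrative: top
level = module backbone.)

Tiles are 256 px; **level 0 renders the native canvas and each deeper level
doubles the resolution**, so level `L` has
`ceil(W·2^L/256) · ceil(H·2^L/256)` tiles. This dialect is recorded in
`index.json` to avoid confusion with pyramids whose level 0 is a single
tile. Rendering uses the cairo PNG device with fixed fonts and colours and
is byte-identical across runs (asserted by direct byte comparison of two
renders, which is stronger than comparing digests).

## Omics overlay

Matching between data and map is by upper-cased HUGO symbol only. Every
overlay operation emits a reconciliation report with
`matched + ignored = total`. Aggregation over sample groups and protein
families is NA-skipping mean or median, with deterministic (sorted)
row/column order; empty cells yield NA plus a warning.

**Map staining** attaches each gene's value to every entity centre carrying
that symbol (complexes flattened) and computes a Nadaraya–Watson field:
isotropic Gaussian kernel, normalised weights, default bandwidth 5 % of
the canvas diagonal — the technique has a published name but no published
kernel, so the kernel-field choice is our dialect (a nearest-entity
colouring would be the natural alternative). Because normalised weights
make the field constant far from data, the **total kernel mass** is kept
alongside and used as rendering opacity, so the stain visually fades away
from any anchor. The field is invariant under entity enumeration order.

Glyphs (default: triangle) flag binary per-gene events at each matching
entity's box corner, stacking horizontally; charts draw one bar/cell per
data column with one shared axis and colour scale across the whole map so
entities are comparable.

## Synthetic fixtures: what a green test establishes

The fixture map emulates the *structure* of a comprehensive map — the
hierarchical 18-module composition (10 repair mechanisms + 4 cell-cycle
phases + 4 checkpoints in three layers), per-module reaction chains,
planted high-degree hubs, canonical tags, a sprinkling of complexes
(default: one per fourth module) — with exact truth records. The PPI
generator plants exact distances (paths, rings, complete and
Erdős–Rényi graphs, optional disconnected component). The omics generator
draws Gaussian values (sd 1) for two groups of 50 samples with a planted
mean shift of 2 on a quarter of the genes and 5 % missing values —
magnitudes a two-class expression contrast at that sample size would
plausibly show, chosen once and kept fixed.

The fixtures do **not** emulate real HPRD topology, real cohort scale, or
the curated aesthetics of a hand-drawn atlas. A green suite therefore
establishes that the machinery is correct on known ground truth, not that
any biological conclusion holds.

## Numerical and degenerate-input choices

* FUNC rounding is round-half-up (`floor(x + 0.5)`), so `d̄ = 2.5` → 4.
* Degradation reactions may have no products; SIF export then targets the
  reserved sink token `__degraded__` (SIF requires a target).
* The compartment id `default` is reserved for "no compartment" in the
  XML dialect.
* Unknown XML constructs are skipped, reported in the dialect report, and
  never fatal; a complex without resolvable members degrades to `UNKNOWN`.
* Canvas sizes grow to fit all boxes (minimum 256 px) when unspecified.
* All randomness (layout, fixtures) flows through explicit seeds and
  restores the caller's RNG state.

## Known limitations

* The interactive web application (search, selection panel, callout
  bubbles, curation blog) is out of scope; only the static pyramid and a
  minimal HTML shell are produced.
* BioPAX/SBGN-ML import-export and kinetic laws are not supported.
* Multi-parent nesting of a complex inside several complexes is not
  representable in the alias dialect (one alias per complex).
* Meta-modules are not modelled; only layers and modules are operational.
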
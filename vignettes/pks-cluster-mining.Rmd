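---
title: "Mining PKS macroclusters and 16S clustering: methods and design notes"
author: "pksminer maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining PKS macroclusters and 16S clustering: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pksminer)
```

## What the package models

Trans-AT polyketide synthase (PKS) biosynthetic gene clusters in *Bacillus*
are large, gene-dense operons: the bacillaene (*bae*/*pks*) macrocluster of
*B. subtilis* spans roughly 78 kb and encodes, in conserved order, two
hypothetical proteins, a TetR-family transcriptional regulator, the
malonyl-transfer and acyl-carrier machinery (PksB–PksE, AcpK), the
beta-branching cassette (PksF–PksI, PksG), the giant hybrid NRPS/PKS
megasynthases (PksJ, PksL, PksM, PksN, PksR) and a cytochrome P450 tailoring
enzyme (PksS). Macrolactin (*mln*) and difficidin (*dfn*) clusters are
organized similarly. `pksminer` treats a cluster as a *template*: an ordered
list of component slots, each described by annotation evidence (gene
synonyms, EC numbers, product keywords) and optionally by reference protein
sequences.

The mining model is deliberately annotation-first: the published evidence
for these clusters in type-strain genomes is a table of protein ids and
nucleotide loci extracted from GenBank feature tables, so the primary
matching signal is what the annotation already says. Homology mode exists as
an annotation-independent fallback, not as the default.

## Matching, chaining and classification

**Match precedence.** A CDS is assigned to at most one component, ranked by
evidence strength: `gene_name` (exact, case-insensitive synonym) beats `ec`
(Enzyme Commission number, `-` wildcards honoured on both sides) beats
`keyword` (all tokens of a pattern must occur in the product string,
lower-cased and punctuation-stripped) beats `homology`. Remaining ties break
by score, then — for keyword ties — by pattern specificity (the pattern
matching more tokens wins), then by catalogue order. The specificity level
is our own addition: the catalogue legitimately contains token-subset
description pairs (e.g. an "enoyl CoA hydratase/isomerase" slot and an
"enoyl CoA hydratase/isomerase family protein" slot), and without it the
catalogue-order tie-break would systematically shadow the more specific
slot. The shipped catalogue also contains annotation-identical slot pairs
(the two oxidoreductase megagenes, and the two hypothetical-protein slots
sharing one EC number); these are distinguishable only by gene name or
position, which is why the fixture generator always plants gene names and
why keyword-only scans of such pairs conservatively recover one slot of the
pair rather than guessing.

**Chaining.** Hits sorted by start coordinate are chained while the gap
between successive hit features (`start_next − end_prev`) stays at or below
the template's `max_gap_bp`. The default of 20 kb was chosen against the
anatomy of the known macrocluster: the *bae* operon is gene-dense with
intergenic gaps of tens to hundreds of bp, while paralogous PKS genes
elsewhere on the chromosome sit hundreds of kb away; 20 kb comfortably
bridges annotation hiccups (a missed or split gene) without fusing separate
loci. It is per-template and user-configurable.

**Completeness and status.** Completeness is the fraction of distinct
template components matched in one call. A call is *complete* when at most
`complete_max_missing = 3` components are missing. This operationalizes
"almost complete": the *B. amyloliquefaciens*-type presence/absence pattern
(regulator plus two enzymatic slots missing, 15/18 present) is still called
complete, while genuinely cluster-free genomes — which match nothing — are
*absent* and reported with the conventional footnote phrase "PKs Loci was
not found". Between the two sits *partial* (at least `partial_min_hits = 1`
hit). The thresholds operate on all 18 slots rather than only the 15 "core"
enzymatic ones; the core flag is retained as metadata. With both
conventions the published patterns classify identically (the non-core slots
are among the missing ones in every published complete genome), and
counting all slots keeps the completeness fraction interpretable against
the full template.

**Labelling.** A call is labelled with the template whose components form a
strict majority of its hits, `unknown` otherwise. Per-template calls are
trivially labelled; the operation matters for user-assembled mixed calls.

## Homology fallback

Local alignment is exact Smith–Waterman with affine gaps (Gotoh), BLOSUM62,
gap open −11 / extend −1 — the standard protein-search parameterization. A
gap of length L costs `open + L·extend`, matching the Biostrings
convention, which lets the test suite use `Biostrings::pairwiseAlignment`
as an independent oracle. Traceback ties prefer diagonal, then the gap in
the reference, then the gap in the query, and the best cell is the first
maximum in row-major order, so results are deterministic. A hit requires
identity ≥ 0.4 and reference coverage ≥ 0.7 (conventional ortholog-screen
values, configurable); its score is identity × coverage, which keeps
homology hits comparable to (and always ranked below) annotation hits.
No heuristic seeding is used: at desk scale (one genome, tens of reference
proteins) exhaustive per-CDS DP is affordable.

## Phylogenetics

**K2P distances.** `d = −½ ln((1−2P−Q)√(1−2Q))` with transition proportion
`P` and transversion proportion `Q` computed over gap-free columns of each
pair (pairwise deletion; complete deletion is available as an option since
the published procedure does not state which was used). Saturated pairs
(non-positive log arguments) raise a classed error rather than returning
`NaN`; bootstrap replicates hitting saturation are skipped, warned about,
and removed from the support denominator.

**Neighbor joining.** Classical Saitou–Nei NJ (Q-criterion, standard
branch-length formulas, three-point formulas at the final star). The
published tree caption names both NJ/BioNJ and a composite-likelihood
distance; we implement classical NJ on K2P distances because both are fully
specified self-contained procedures, and note that BioNJ variance weighting
and composite-likelihood distances are out of scope. Ties in the Q matrix
break at the lowest (row, column) pair, making the topology deterministic.
Negative branch-length estimates (a known NJ artifact on non-additive
matrices) are clamped to zero with the deficit moved to the sibling edge —
the MEGA-compatible convention — and the raw estimates are preserved in the
`raw_lengths` attribute for diagnostics.

**Bootstrap.** Column resampling with replacement, default 1000 replicates
(the published resampling depth; tests run 100 for time). Support is the
percentage of valid replicates containing each internal bipartition of the
full-data tree, written into `node.label` so Newick export carries integer
supports.

## The synthetic world

`generate_genome()` emulates an annotated type-strain replicon: the chosen
template's component genes at realistic per-slot lengths (megagenes are
megagenes: PksJ ≈ 15 kb, AcpK ≈ 250 bp), exponentially distributed
intergenic gaps (mean `gap_scale_bp = 200`, about the observed operon
density), optional deletions, order shuffling and strand flips, flanked by
decoy genes drawn from a vocabulary chosen token-disjoint from every
catalogue keyword pattern so that expected hits are unambiguous. An
adversarial mode adds near-miss products (tokens overlapping catalogue
patterns without covering any full pattern) for precision testing. Decoys
are placed on the cluster flanks, not inside it, which is what makes the
"adding background genes never changes the call" invariant exactly true
rather than probabilistic. The ground-truth status is derived from the
planted coordinates by an independent re-statement of the chain rule, and a
declared `expect_status` that contradicts the realized layout is an error.

What a green fixture suite does **not** establish: robustness to real-world
annotation drift (products phrased differently from the catalogue
keywords), frameshifted or pseudo-gene fragments, origin-spanning clusters
on circular replicons (treated as linear; a documented limitation), or
contamination between closely related paralogous clusters. The
network-dependent checks against the published accessions cannot run in an
offline build; the test suite instead plants the published AM1 cluster
coordinates and the published per-genome presence/absence patterns and
verifies the pipeline reproduces them cell-for-cell.

`simulate_k2p_alignment()` evolves sites independently under the K2P
process with the exact closed-form transition probabilities. `kappa` is the
transition/transversion *rate ratio* α/(2β): `kappa = 0.5` makes all three
substitution types equally likely, and the default `kappa = 2` is a typical
16S value. It simulates neither rate heterogeneity across sites nor indels,
so simulated alignments are gap-free.

## Numerical and engineering choices

* Coordinates are 1-based inclusive throughout (GenBank convention);
  compound locations collapse to their envelope with a `compound` flag so
  pseudo-gene fragments can be excluded by configuration.
* The GenBank writer emits deterministic output (fixed timestamp,
  word-boundary qualifier wrapping) so fixture generation is byte-identical
  per seed and `parse(write(x))` round-trips field-wise.
* All user-facing randomness is seeded through one RNG guard that restores
  the caller's RNG state.
* Classed conditions (`pks_parse_error`, `pks_coordinate_error`,
  `pks_saturation_error`, `pks_config_error`, ...) separate input errors
  (CLI exit 2) from configuration errors (exit 3).
* Branch lengths are serialized at 10 significant digits when trees are
  assembled via Newick fragments; exact-recovery tests therefore assert at
  1e-8, not machine precision.

## Known limitations

* No profile-HMM component models; keyword matching is sensitive to
  annotation wording (mitigated by EC/gene-name precedence and homology
  fallback).
* Multi-replicon files are mined and reported per replicon (one matrix
  column per LOCUS); cross-replicon aggregation to a single genome-level
  status is left to the caller.
* The two annotation-identical oxidoreductase slots cannot be told apart
  without gene names; on keyword-only evidence one of them will absorb both
  features' assignments.
* BioNJ weighting and composite-likelihood distances are not implemented.
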
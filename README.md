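# pksminer

Mining polyketide synthase (PKS) gene clusters in annotated bacterial
genomes, with a companion 16S phylogenetics workflow.

## The problem

Many *Bacillus* strains — including gut-microbiota isolates of
biotechnological interest — owe their antimicrobial activity to polyketides
synthesized by giant trans-AT PKS operons. Three such clusters are the
classic trio of the *B. subtilis* / *B. amyloliquefaciens* group:

* **bae** — bacillaene (the ~80 kb *pks* macrocluster, PksA–PksS plus the
  AcpK acyl carrier protein and a TetR-family regulator),
* **mln** — macrolactin (mlnA–I),
* **dfn** — difficidin (dfnA–M).

Given a genome annotation record (GenBank flat file), `pksminer` answers:
does this genome harbor a PKS macrocluster, is it complete, partial or
absent, which metabolite cluster is it, which loci encode each component,
and what sits immediately upstream and downstream of the cluster? For
strain typing it also implements the standard 16S pipeline: Kimura
2-parameter (K2P) distances on an aligned rRNA set, neighbor-joining (NJ),
and nonparametric bootstrap supports.

## Method at a glance

1. **Parse** GenBank flat files into an annotated-genome model (CDS features
   with coordinates, strand, product, EC numbers, protein ids,
   translations). Compound join/complement locations collapse to their
   envelope span.
2. **Match** each CDS against a curated component catalogue. Match modes in
   precedence order: gene name > EC number (with `-` wildcards) > product
   keywords (a pattern matches when all its tokens occur in the product) >
   optional Smith–Waterman homology against reference proteins
   (hit iff identity ≥ 0.4 and reference coverage ≥ 0.7 by default).
3. **Chain** hits into cluster calls: successive hits at most `max_gap_bp`
   (default 20 kb) apart form one candidate cluster.
4. **Score**: completeness = distinct matched components / template size;
   a call is *complete* when ≤ `complete_max_missing` (default 3) components
   are missing, *partial* when it still has ≥ `partial_min_hits` hits, and a
   genome without any hit is *absent* — reported with the phrase
   "PKs Loci was not found".
5. **Label** multi-template calls by strict majority of component hits.

For phylogenetics, `d = -1/2 ln((1-2P-Q) sqrt(1-2Q))` with transition
proportion `P` and transversion proportion `Q` over gap-free columns
(pairwise deletion by default), classical Saitou–Nei NJ with deterministic
tie-breaking, and bootstrap support = % of column-resampled replicates
containing each internal bipartition (default 1000 resamplings).

A synthetic-fixture generator plants a (possibly mutated, shuffled, gap
inflated, decoy-laden) cluster into a GenBank record together with a ground
truth table, so the whole pipeline is testable offline.

## Worked example

```r
library(pksminer)

# a synthetic genome emulating the B. amyloliquefaciens pattern
# (Regulator, PksF, PksN deleted from the bae macrocluster)
fx <- generate_genome(fixture_spec(seed = 101, n_background = 10,
                                   deleted_components = c("Regulator", "PksF", "PksN")))
gbk <- tempfile(fileext = ".gbk"); writeLines(fx$genbank, gbk)

rec <- read_genbank(gbk)[[1]]
rec
#> <genome_record> SYNB000101 (synthetic Bacillus fixture), 90608 bp linear, 25 CDS features

res <- classify_genome(rec, default_catalog())
res$bae
#> <cluster_call> bae: complete, 15 hits, span 8513..81363, completeness 0.83, missing: Regulator,PksF,PksN
res$mln
#> <cluster_call> mln: absent (PKs Loci was not found)
```

15 of the 18 bae components were found chained inside one 73 kb window;
three missing slots is still within the "almost complete" threshold, so the
genome is called *complete* for bacillaene and *absent* for macrolactin.
The gene neighborhood of the cluster:

```r
neighborhood(rec, res$bae$span, k = 2)
#> Neighborhood of 8513..81363
#> upstream (2):
#>   FIX_0005 6635..7798 (+) cell division septum formation initiator
#>   FIX_0004 5843..6454 (+) phosphate import ATPase
#> downstream (2):
#>   FIX_0021 83300..84118 (+) cell division septum formation initiator
#>   FIX_0022 84285..85064 (+) ribosome maturation GTPase
```

And the 16S workflow:

```r
aln <- simulate_k2p_alignment("((A:0.05,B:0.05):0.04,(C:0.05,D:0.05):0.04);",
                              1000, kappa = 2, seed = 7)
round(k2p_distance(aln[["A"]], aln[["B"]]), 4)
#> [1] 0.1017                          # true A-B patristic distance is 0.10
tree <- bootstrap_support(aln, n_replicates = 100, seed = 8)
ape::write.tree(tree)
#> (A:0.05287368927,B:0.04884509416,(C:0.03644306324,D:0.05438865653)100:0.1000799325);
```

The internal `(C,D)` bipartition is recovered with 100% bootstrap support.

## Command line

```sh
inst/scripts/pksmine scan genome1.gbk genome2.gbk --out-dir report/
inst/scripts/pksmine neighborhood --genome genome1.gbk --template bae --k 5
inst/scripts/pksmine phylo --fasta aligned_16S.fasta --boot 1000 --seed 1 --out-prefix tree
inst/scripts/pksmine fixtures --spec spec.json --out-prefix fixture
inst/scripts/pksmine catalog dump --out catalog.json
```

`scan` writes a components × genomes TSV matrix (cells
`"<protein_id> <start>..<end>"`, missing `-`, absent genomes footnoted) plus
per-genome JSON cluster calls. Exit codes: 0 success, 2 input error,
3 configuration error.

## Scope and limitations

* Annotation-record mining only — no HMM domain models, no NRPS hybrid
  prediction, no read assembly.
* Circular replicons are treated as linear for cluster assembly
  (the known bae/mln/dfn clusters are origin-distal).
* mln/dfn component inventories are synonym/keyword-driven and
  user-overridable; the bae template carries the full curated 18 slots.
* See `vignettes/pks-cluster-mining.Rmd` for the full methods discussion.
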
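---
title: "Screening ocean metagenomes for relatives of the mitochondrial lineage: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening ocean metagenomes for relatives of the mitochondrial lineage: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoscreen)
```

## The problem

The mitochondrial progenitor was an alphaproteobacterium, most closely
related among cultured organisms to the Rickettsiales. A free-living
relative, if one persists, should be sought in marine shotgun metagenomes —
but those pools are overwhelmingly dominated by the SAR11 clade, and any
mitochondria-affiliated lineage will be a fraction of a percent of the
data. `mitoscreen` implements the screening pipeline for this regime:
curate per-marker ortholog sets from hit tables, select phylogenetically
well-behaved markers, and repeatedly subsample the environmental pool to
find sequences that consistently place inside or next to the mitochondrial
clade.

This vignette records the models, the tunable parameters and the design
decisions, in the package's own terms.

## Homology filtering

Hit tables (tab-separated; query, subject, identity, alignment length,
E-value, bitscore, query-coverage fraction, subject OG, subject species)
are *inputs*: the package never runs a search program. Three thresholds do
all the work, and all three are **strict** inequalities, verified by
boundary fixtures that the synthetic generator plants deliberately
(E-value exactly 1e-10, coverage exactly 0.5 and 0.7 must all be
rejected):

* candidate retrieval: E-value < 1e-10 and HSP overlap > 0.5 of the query;
* reciprocal confirmation: the *top* back-hit (same E-value cut, overlap
  > 0.7) must be in the expected orthologous group;
* dataset gate: a marker qualifies with > 500 retrieved sequences.

"Best/top hit" is resolved by bitscore, with ties broken by smaller
E-value and then lexicographic subject id; an `best_hit_by = "evalue"`
ordering is available since the original protocols rarely state which
ordering their search tool used. HSP overlap is the single best HSP's
coverage of the query; HSP chaining is out of scope. In the orchestrated
synthetic workflow the size gate is *reported but not enforced*
(`pipeline_config(enforce_gate = ...)`): the gate's 500-sequence threshold
presumes survey-scale pools, while the synthetic pool spreads 1000
sequences over five markers.

Block filtering of alignments is a transparent gap-fraction column mask
(`mask_columns`, default maximum gap fraction 0.5) that reports the
kept-column map, so any external masking program can be substituted
without touching downstream code.

## Marker selection

A marker is **coherent** when, on its reference tree, (i) the
mitochondrial sequences are monophyletic and (ii) the alphaproteobacterial
clade — every leaf except the outgroup, since the mitochondrial lineage
arises *inside* the Alphaproteobacteria — is monophyletic. On unrooted
trees monophyly means bipartition presence. Coherence is assessed on a
single tree per marker from the pluggable inference backend; the built-in
default for these reference trees is neighbor joining over
Poisson-corrected distances.

Composition bias is measured at the protein level: the frequencies of
residues encoded by AT-rich codon families (F, Y, M, I, N, K) versus
GC-rich families (G, A, R, P). No amino acid is encoded *solely* by A/T or
G/C bases under the standard code, so the established FYMINK/GARP
convention is used and both sets are configurable. The per-dataset spread
(max − min across taxa) above 0.05 — "a few percent" — flags a marker as
bias-prone. Note that the flag is diagnostic only; selection is by
coherence.

## Diversity pruning

Faith's PD of a leaf subset is the total branch length of the minimal
spanning subtree, in the unrooted convention by default (the rooted
variant, which adds the path to the root, is a flag). Greedy selection —
start from the two leaves with the largest path length, repeatedly add the
leaf with the largest PD increment — attains the exact optimum on trees
(the Steel/Pardi result); the test suite asserts this by exhaustive
enumeration on 200 random trees. With a `must_keep` set (the reference
taxa, in the pipeline) the seeding is the must-keep set and optimality is
guaranteed only for the unconstrained increments; this is the standard
compromise and is recorded in the provenance log. Ties are broken by
lexicographically smallest label, and the default target size is k = 150.
The guide tree is the built-in NJ tree over the full candidate set unless
one is supplied.

## The jack-knife neighbour screen

Per replicate, `sample_size` (default 100) environmental sequences are
drawn uniformly *with replacement* (so m may exceed the pool), combined
with the full reference set, a tree is inferred, rooted on the outgroup
(the rooting bisects the separating branch, conserving total length), and
environmental leaves are extracted that lie

* inside the MRCA of the mitochondrial leaves, or
* (default mode `INSIDE_PLUS_SISTER`) in the sister clade of that MRCA —
  sister placements are what "close to or at the root of the
  Rickettsiales" means topologically. For a polytomous parent the sister
  is the union of all siblings.

Two behaviours deserve explanation:

* **Backbone-sister suppression.** In a small fraction of replicates the
  long outgroup branch pulls the compact mitochondrial clade toward the
  base of the ingroup, making its "sister" the entire backbone and
  flooding hundreds of spurious flags. A sister clade whose *reference*
  leaves span more than one order is therefore ignored; the rule is purely
  topological, names no particular order, and leaves genuine neighbour
  clades (pure environmental groups, or groups with references of a single
  order) untouched.
* **Backend choice.** The screen's default backend is NJ over a
  composition-aware corrected distance, `d = -b ln(1 - p/b)` with
  `b = 1 - sum(pi_hat^2)` estimated from the pooled residue frequencies
  (the protein analogue of the Tajima–Nei / equal-input correction). The
  plain Poisson correction systematically under-corrects deep divergences,
  which at some alignment realisations mis-resolves the deep quartet
  (Rickettsiales, (mitochondria, neighbour)) for a whole marker at once;
  the matched correction is exact for an equal-input substitution process
  and reduces to near-Poisson behaviour on homogeneous data. Any function
  mapping an alignment matrix to a `phylo` can replace it.

Failed replicates (inference or rooting errors) are skipped and logged;
more than 10% failures aborts the screen. Flag counts can never exceed
sampling counts, and a fixed seed reproduces the result bit-for-bit. A
sequence enters the flagged set at `min_flag_count` flags (default 1 —
the original extraction counted any association; raising it trades recall
for reproducibility). The closed form `(1 - 1/N)^(m*r)` reports the
probability that a pool member was never examined.

Flagged sequences on scaffolds carrying at least two marker genes are
concatenated in a fixed marker order (references likewise; absent markers
gap-filled), with 1-based inclusive partition boundaries reported. A
scaffold carrying the same marker twice is a paralogy flag and an error.

## Clade abundance

Each environmental leaf takes the order of the *strict* majority of
reference leaves in the smallest clade containing the leaf and at least
one reference leaf; ties and mixed majorities yield `UNCLASSIFIED`, which
is first-class so that percentages never silently renormalise. Collapsed
clades are summarised as (l, n) = (branch length within the clade
excluding its stem, number of environmental leaves). The rare-clade
fraction is plain percentage arithmetic, rounded to one decimal only at
the reporting layer, and the overall-abundance product multiplies the
clade percentage by the assumed alphaproteobacterial fraction of all cells
(default 0.325). The product treats sequence fractions as cell fractions —
an approximation, reported as computed; with a 2.1% clade fraction it
gives 0.68%.

## The synthetic metagenome generator

The generator is first-class, tested code. Its defaults *are* the study
conditions:

* 28 reference taxa in six order-like clades (SAR11 3, Rickettsiales 6,
  Rhodobacterales 6, Rhodospirillales 5, Rhizobiales 5, Caulobacterales
  3), 5 mitochondrial taxa sister to the Rickettsiales, 2 outgroup taxa;
* an environmental pool of 1000 gene sequences at the published-scale
  order profile (SAR11 0.825, Rhodobacterales 0.093, Rhodospirillales
  0.074, Rhizobiales 0.006, Rickettsiales 0.002);
* a planted clade of 2% of the pool attached at the *mitochondrial* stem
  (stem length 0.3 substitutions/site). Attachment at the
  Rickettsiales+mitochondria group stem is available
  (`planted_attach = "group_stem"`), but the default matches what the
  screen is defined to detect — sequences sister to, or inside, the
  mitochondrial clade;
* organisms carry 1–3 genes (probabilities 0.7/0.25/0.05) of five markers
  on one scaffold each, so multi-gene scaffolds exist for concatenation;
* sequences evolve site-independently toward a global stationary
  amino-acid frequency vector (equal-input/F81-style process calibrated so
  branch lengths are expected substitutions/site). Lineages designated
  AT-biased (SAR11, Rickettsiales, mitochondria, planted) substitute
  toward frequencies shifted by `bias_strength` (default 0.1) into the
  FYMINK set, reproducing the AT/GC heterogeneity that makes some markers
  treacherous. Alignments are gapless — indel realism is out of scope, and
  real data arrive pre-aligned;
* branch lengths are exponential draws (within-clade mean 0.05; backbone
  mean 0.07 plus a floor of 0.05, because the reference backbone is taken
  as resolved — with floorless exponentials an occasional
  \~0.004-substitutions/site backbone edge makes the planted clade
  unrecoverable by *any* method at these alignment lengths). Clade stems
  (orders 0.25, mitochondria 0.35, outgroup 0.6) keep the maximum
  p-distance near 0.85, inside the correctable range of the distance
  models;
* hit tables are emitted from truth — the filters, not the search engine,
  are the scientific content — with strong same-OG hits for true
  orthologs, cross-OG top hits for decoy paralogs (`hit_noise$decoy_rate`),
  optional jitter, and the strict-threshold boundary records always
  present.

Everything is deterministic under `rng_seed`, and every sequence carries a
truth label (order, organism, scaffold, planted flag).

What passing tests on this generator do **not** show: robustness to
alignment error, indels and fragmentary sequences; to model misspecification
beyond composition shifts (no rate heterogeneity across sites or lineages);
to chimeric scaffolds or contamination. The generator's clean signal is the
point — it isolates the pipeline's logic from inference noise.

## Numerical choices and degenerate inputs

* NJ clamps negative estimated branch lengths to zero and collapses
  zero-length internal branches to polytomies (an all-zero matrix yields a
  star); labels are sorted before agglomeration, so results are invariant
  to input row order.
* Distances use pairwise deletion of gap columns; a pair with no
  comparable columns is an error, as are saturated pairs (p = 1 under
  Poisson, p ≥ b under the corrected model).
* Majority-rule consensus keeps splits with frequency *strictly* above
  0.5 (two conflicting trees give a star); burn-in removes the first
  `floor(burnin_fraction * n)` trees, default 0.25. The max-diff
  convergence diagnostic compares split-frequency spectra with a 0.3
  verdict threshold.
* Polytomies are supported throughout; the screen's sister rule on a
  polytomous parent takes the union of siblings.
* Seeds: the generator uses one seed for everything; the pipeline derives
  per-stage, per-marker offsets so that `run_stage("all")` is exactly the
  composition of the individual stages.

## Problem sizes

The shipped analyses and acceptance script use the default pool of 1000
sequences with m = 100 and r = 20 jack-knife replicates per marker (the
screen default is r = 100; 20 replicates already sample each pool member
about ten times, and the acceptance run covers three seeds). Property
suites use trees of up to 12 leaves for exhaustive enumeration, 20 leaves
for additive-matrix recovery, and 10^5–10^6 Monte-Carlo trials for the
coverage closed form.

## Known limitations

* The screen's verdicts are only as good as the backend trees; with the
  built-in distance methods, very deep or compositionally extreme markers
  may need an external ML/Bayesian backend.
* Clade assignment is a nearest-reference heuristic, not a placement
  method; its `UNCLASSIFIED` rate grows with sparse reference sampling.
* The overall-abundance product inherits every caveat of equating sequence
  and cell fractions (copy number, sequencing depth, temporal variation).
* The dataset gate, dedup rule and shortlist size reflect one published
  protocol; other datasets may need different settings, which is why every
  threshold lives in a config object.
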
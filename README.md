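# mitoscreen

A phylometagenomic screen for rare, free-living relatives of the
mitochondrial lineage in ocean metagenome data.

Mitochondria descend from an alphaproteobacterium whose closest known
relatives are the Rickettsiales — obligate intracellular parasites. If
free-living relatives of that ancestor survive anywhere, the sun-lit ocean
surface is the place to look, but any such lineage will be a needle in a
haystack dominated by the SAR11 clade (*Ca.* Pelagibacter and relatives,
\~82.5% of alphaproteobacterial sequences in ocean shotgun data).
`mitoscreen` implements the full screening pipeline that finds that needle,
plus a fully labelled synthetic metagenome generator so every stage can be
validated end-to-end against known truth.

## The method

Given a set of mitochondrially encoded marker proteins (COX1, COX2, COB,
NAD7, RPS2, ...), BLAST-style hit tables against an environmental pool and
a reference orthologous-group (OG) database, and reference proteomes for
the alphaproteobacterial orders:

1. **Staged homology filtering** — a candidate environmental sequence needs
   a hit to the seed protein with E-value < 10⁻¹⁰ and HSP overlap > 50% of
   the query, and is retained only if its *top* reciprocal hit against the
   OG database (E-value < 10⁻¹⁰, overlap > 70%) falls in the seed's own
   orthologous group; one member per species; markers qualify with > 500
   retrieved sequences. All thresholds strict.
2. **Marker selection** — a marker is phylogenetically coherent when, on its
   reference tree, the mitochondrial sequences are monophyletic *and* the
   alphaproteobacterial clade is monophyletic. Composition bias is
   quantified per taxon as the frequencies of FYMINK (AT-rich codon
   families) versus GARP (GC-rich) residues; a max−min spread above a few
   percent (default 0.05) flags a marker as bias-prone.
3. **Diversity pruning** — Faith's phylogenetic diversity
   PD(S) = total branch length of the minimal subtree spanning S; a greedy
   algorithm (provably optimal on trees) selects k = 150 sequences of
   maximal PD, with the reference taxa as a must-keep set.
4. **Jack-knife neighbour screen** — r = 100 replicates (r = 20 in the
   scaled-down runs here) each draw m = 100 environmental sequences with
   replacement, build a tree with the full reference set, root on the
   outgroup, and flag environmental leaves *inside* the mitochondrial clade
   or in its *sister* clade. The closed form (1 − 1/N)^{mr} gives the
   probability a pool member is never examined (\~6.6·10⁻⁵ at N = 1040,
   m = r = 100).
5. **Scaffold concatenation** — flagged sequences sitting on assembly
   scaffolds with ≥ 2 marker genes are concatenated into a partitioned
   supermatrix for downstream phylogenetics.
6. **Clade abundance** — environmental leaves are assigned to reference
   orders by strict majority in the smallest reference-containing clade;
   the rare-clade arithmetic (e.g. 12 of 566 COX1 sequences = 2.1%) and the
   overall-abundance product (2.1% × 32.5% alphaproteobacterial cells)
   summarise how rare the detected clade is.

Tree machinery (Newick I/O, bipartitions, monophyly, outgroup rooting,
neighbor joining over p/Poisson/composition-corrected distances,
majority-rule consensus, split max-diff) is built in; tree inference is a
pluggable backend so external ML/Bayesian engines can be substituted.

## Worked example

The numbered drivers under `analysis/` run the whole pipeline on the
synthetic metagenome (seed and output directory via `MS_SEED` / `MS_OUT`):

```sh
Rscript analysis/01_simulate.R   # simulated 1020 environmental gene sequences (20 planted) on 746 scaffolds
Rscript analysis/02_filter.R    # retained 1020 of 1020 candidate sequences across 5 markers
Rscript analysis/03_select_markers.R  # 5 of 5 markers pass the coherence criterion
Rscript analysis/04_prune.R     # pruned selections retain 93.1% of total tree length on average
Rscript analysis/05_screen.R    # flagged 23 sequences; 20/20 planted recovered (precision 0.87)
Rscript analysis/06_abundance.R
```

The comments show the messages printed with the default seed. The screen
recovers every member of the planted rare clade (20 sequences, 2% of the
pool, sister to the mitochondria) at precision 0.87; the final abundance
report puts the dominant SAR11-like clade at 82.3% of assigned sequences —
the synthetic pool was drawn at 82.5% — and the flagged COX1 fraction at
1.6%, i.e. an overall abundance below 1% of cells under the 32.5%
assumption.

Equivalent programmatic use:

```r
library(mitoscreen)
sim <- simulate_dataset(sim_config(rng_seed = 1))
md  <- marker_datasets(sim, "COX1")
res <- run_screen(md$env, md$reference,
                  screen_config(sample_size = 100, replicates = 20,
                                rng_seed = 1))
res$flagged                      # environmental ids affiliated with the
                                 # mitochondrial clade
res$unsampled_fraction_estimate  # coverage of the jack-knife
```

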
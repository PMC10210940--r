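# stcminer

Genome mining and cyclization-clade classification of fungal sesquiterpene
cyclases (STC).

## What it is for

Fungal STC convert farnesyl diphosphate (FPP) into cyclic sesquiterpene
skeletons, and enzymes that share a phylogenetic clade tend to share their
first cyclization step: clade 1 performs 1,10-cyclization of (2E,6E)-FPP,
clade 2 the 1,10-cyclization of (3R)-NPP, clade 3 the 1,11-cyclization of
(2E,6E)-FPP, clade 4 the 1,6/1,7-cyclization of (3R)-NPP. Finding these
genes in predicted proteomes is hard: fungal STC are short and divergent,
and prenyltransferases share the aspartate-rich DDxxD metal-binding motif
without being cyclases. `stcminer` is for computational natural-product and
fungal-genomics researchers who want a deterministic, fully testable
pipeline that goes from protein FASTA to per-gene clade calls and a tandem
duplication report.

The pipeline:

1. **Similarity screen** - exact Smith-Waterman (BLOSUM62, gap open 11 /
   extend 1) of every protein against characterized seed enzymes, kept if
   identity > 30% and query coverage > 60% (strict).
2. **Metal-binding motif filter** - an N-terminal-half (D/N)DxxD/E or
   DDxxxE *and* a C-terminal-half NxxxSxxxE; the conjunction rejects
   prenyltransferase-like proteins.
3. **Length filter** - 250 < L < 500 aa (exclusive).
4. **Distance classification** - progressive alignment (guide tree +
   profile-profile DP, gap open 2.3 / extend 0.63 on a bit-scaled matrix),
   gap-threshold column trimming, physicochemical-category distances
   (d = -ln(1 - D) with category penalty 0.5), UPGMA, and a
   smallest-enclosing-reference-cluster purity rule.
5. **Discriminative motifs** - exact 3-6-mers present in >= 75% of one
   clade and absent from the others; unclassified sequences carrying
   motifs of exactly one clade are reassigned.
6. **Profile HMMs** - per-clade plan7-style models (Laplace +1
   pseudocounts, uniform background), glocal Viterbi scoring in bits,
   gathering threshold 25, best-scoring model wins; a second generation of
   models is rebuilt from the top 100 basidiomycete and top 100 ascomycete
   hits per clade.
7. **Tandem duplications** - two called STC genes within four gene
   positions on the same scaffold are a tandem pair; clusters are the
   connected components.

A seeded synthetic-data generator (`sim_spec()`, `make_genome()`) builds
planted clade families, decoy proteins and genome layouts with known
truth, so every stage is validated end to end without any downloads.

## Worked example

```r
library(stcminer)

fx  <- make_genome(sim_spec(seed = 1))   # 4 x 30 planted STC + 60 decoys
res <- run_pipeline(fx$proteome, fx$seeds, fx$seed_clades, fx$loci)

cat(report_table1(res))
#> genome      n_input  filter1  filter2  filter3
#> simgenome   180      140      140      120
#> Total       180      140      140      120
```

180 input proteins shrink to 140 after the similarity screen (the 20
unrelated and 20 prenyltransferase-like decoys drop out), stay 140 through
the metal-binding filter, and reach 120 after the length filter (the 20
wrong-length decoys drop out) - exactly the 120 planted STC.

```r
res$motifs[res$motifs$pattern %in% c("DTSGC", "LRRENS", "DLMN", "FYK"),
           c("pattern", "positive_freq", "clade")]
#>   pattern positive_freq clade
#> 1   DTSGC     0.9333333     1
#> 3  LRRENS     0.8000000     2
#> 4    DLMN     0.8666667     3
#> 5     FYK     0.9333333     4
```

Discovery recovers each planted clade signature at its realized penetrance
(the generator plants motifs in ~90% of family members), with zero
occurrences in the other clades.

```r
print(res$tandem)
#> tandem report: 140 STC, 70 in tandem (50.0%), 35 pairs, 100.0% same-clade pairs

head(res$calls_gen2, 3)
#>   protein_id clade       evidence    score
#> 1     stc1_1     1 hmm_best_score 659.0389
#> 2    stc1_10     1 hmm_best_score 727.9118
#> 3    stc1_11     1 hmm_best_score 687.9278
```

Final calls carry the clade, the evidence type and the bit score of the
best second-generation model. The HMM stage also recovers the 20
wrong-length decoys (they are genuine homologous fragments - the HMM
search has no length gate), which is why the tandem report counts 140
called genes.

A command-line front end with the same stages as subcommands ships in
`inst/exec/stcmine` (see `stcmine pipeline --help`).

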
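---
title: "Mining fungal genomes for sesquiterpene cyclases: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining fungal genomes for sesquiterpene cyclases: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(stcminer)
```

## The problem

Sesquiterpene cyclases (STC) convert the linear C15 precursor farnesyl
diphosphate (FPP) into cyclic sesquiterpene skeletons. The skeleton a fungal
STC produces is largely determined by the first cyclization step, and
phylogenetically related enzymes tend to share it. Four clades are
distinguished: clade 1 (1,10-cyclization of (2E,6E)-FPP), clade 2
(1,10-cyclization of (3R)-NPP), clade 3 (1,11-cyclization of (2E,6E)-FPP,
the trans-humulyl route), and clade 4 (1,6/1,7-cyclization of (3R)-NPP).
Because fungal STC are short, divergent, and poorly covered by
plant-derived domain models, naive similarity search both misses distant
family members and drags in prenyltransferases, which share the DDxxD
metal-binding signature without being cyclases.

`stcminer` implements a complete mining-and-classification pipeline for
predicted fungal proteomes:

1. **Similarity screen** of every protein against a small set of
   characterized seed enzymes (exact Smith-Waterman, BLOSUM62, affine gaps
   with open 11 / extend 1), gated *strictly* at >30% identity and >60%
   query coverage. Identity counts identical columns over all alignment
   columns including gaps; coverage is the aligned query span over the
   query length.
2. **Metal-binding motif filter**: a surviving sequence must carry
   (D/N)DxxD/E or DDxxxE in its N-terminal half *and* NxxxSxxxE in its
   C-terminal half. The conjunction is what rejects prenyltransferase-like
   proteins. "N-terminal region" is operationalized as the first
   floor(L/2) positions - the class-I terpene-synthase fold puts the
   aspartate-rich motif well before the NSE triad, so halving is a safe,
   testable cut.
3. **Length filter**: exclusive window 250 < L < 500 aa.
4. **Distance-based clade assignment**: survivors are pooled with the seed
   enzymes, aligned progressively, trimmed, and compared through a
   physicochemical-category distance; a UPGMA dendrogram is read
   automatically by a smallest-enclosing-cluster rule.
5. **Discriminative motifs**: exact k-mers (k = 3..6) present in at least
   75% of one clade's sequences and absent from every sequence of the
   other clades; sequences the dendrogram could not place are reassigned
   when they carry motifs of exactly one clade.
6. **Profile HMMs**: one model per clade, built from the trimmed
   alignments; proteomes are searched glocally at a gathering threshold of
   25 bits and each hit takes the clade of its best-scoring model.
   A second generation of models is rebuilt from the top 100
   basidiomycete-derived and top 100 ascomycete-derived hits per clade.
7. **Tandem duplication report**: two called STC genes are tandem if they
   lie within four gene positions on the same scaffold, strand ignored;
   clusters are connected components of the pair graph.

## The profile HMM

Models are plan7-style: nodes 1..L with match/insert/delete states, an
insert state before node 1, silent begin/end. Alignment columns with gap
fraction below 0.5 become match states. Emissions are observed counts with
a +1 Laplace pseudocount over the 20 residues; transitions are observed
state-path counts with +1 per legal outgoing edge; the background is
uniform 0.05. These are deliberate simplifications of hmmbuild's Dirichlet
mixtures and entropy weighting: every number in a built model is
hand-checkable, which the test suite exploits (a 4-row column with residues
{A,A,A,C} must give P(A) = 4/24 exactly). Row weighting of the training
alignment is a known extension point; training sets here are synthetic and
near-uniform, where weighting changes little.

Scoring is glocal in log2-odds: the model must be traversed begin to end
(deletions allowed), while sequence flanks outside the aligned core are
emitted at background frequencies and contribute exactly 0 bits. The
unknown residue X also emits background (0 bits) in every state. Viterbi
scores the best path; Forward log-sums all paths and therefore never falls
below Viterbi. Both kernels are exact dynamic programs (compiled), and both
are checked against brute-force enumeration of *all* state paths for small
models - agreement is required to 1e-9 bits.

The gathering threshold default is 25 bits, configurable
(`hmm_bit_threshold`). Tied best scores across clades leave a protein
unclassified rather than picking arbitrarily.

## Alignment machinery

The progressive aligner builds a guide tree by UPGMA on cosine distances
between 3-mer count vectors, then merges profiles along the tree with a
global affine-gap profile-profile DP. BLOSUM62 is rescaled to unit mean
diagonal (the same normalization idea MAFFT applies) so the gap penalties
open 2.3 / extend 0.63 sit on the matrix scale; opening a gap costs about
three average matches. Ties in every DP prefer diagonal, then the first
profile, then the second, so alignments are deterministic. On two
sequences the result provably equals the pairwise global DP under the same
scoring, which the tests assert against an independent implementation.
Column trimming keeps exactly the columns with gap fraction <= 0.5
(boundary kept), is idempotent, and errors rather than silently returning
an empty alignment.

The category distance follows the protdist "categories" idea: residues are
grouped as {C}, {M,V,L,I}, {G,A,S,T,P}, {F,Y,W}, {N,D,E,Q}, {H,K,R}; a
shared column scores 0 if identical, 0.5 if same category, 1 otherwise (X
always 1); the mean D is corrected as d = -ln(1 - D) and capped at 10.
The published tool has additional rate parameters that are not stated
anywhere usable; the 0/0.5/1 scheme preserves the property that matters
for clade separation - same-category substitutions cost less - while
remaining a two-line formula a reviewer can recompute.

"Clusters unambiguously" is made operational as: walk from the candidate
leaf toward the root and stop at the first (smallest) cluster containing a
reference; if all references inside share one clade, assign it, otherwise
leave the candidate unclassified. This is deterministic and matches what a
reader does with a dendrogram figure.

## The synthetic study system

All validation runs on seeded synthetic data; nothing is downloaded. The
generator plants one profile HMM per clade:

* match emissions are Dirichlet draws with concentration `divergence` on a
  random consensus residue. The default `divergence = 50` yields ~50-60%
  within-family identity and background-level (~20%) cross-family identity,
  which is the regime where the screen (>30%) passes family members and
  rejects decoys with margin on both sides.
* metal-binding residues are pinned (emission probability 1) at fixed
  positions in each half, and the clade signature motif (defaults DTSGC,
  LRRENS, DLMN, FYK) at a clade-specific interior position.
* transitions are indel-free by default (`indel_prob = 0`), so sampled
  sequences have the model's exact length, inside the exclusive (250, 500)
  window, and deletions can never remove a planted motif. An `indel_prob`
  knob exists for alignment stress tests.
* model lengths are drawn in [300, 340].

Families are sampled along the model (the same machinery that scores them -
sampler/scorer consistency is what makes the parameter-recovery test
meaningful). Each member carries the clade motif with probability
`motif_penetrance` (default 0.9); knocked-out members have those positions
resampled from background. Accidental occurrences of *any* planted clade
motif away from its designated site are scrubbed and resampled, so "absent
from all negatives" holds by construction - without scrubbing, a 3-mer
like FYK appears by chance in roughly 1 in 27 random 300-mers and would
poison discovery. `sample_family(exact_penetrance = TRUE)` knocks out
exactly round((1-p)n) members instead of Bernoulli sampling; the recovery
validation uses it because a 100%-recovery guarantee only exists when the
realized positive fraction cannot fluctuate below the discovery threshold.

Decoys come in three classes: prenyltransferase-like (random background
plus an N-half DDxxD, never the C-terminal triad), unrelated (pure
background), and wrong-length (clade-model samples either internally
shortened below 250 aa or minimally padded past 500 aa, keeping both metal
motifs, so the length rule is what rejects them). Genome layouts place STC
genes singly or as within-family tandem pairs at ordinal gaps 1-4, with
nine gene slots per placement group so different groups can never fall
within the tandem window of each other: the planted tandem truth coincides
exactly with what the detector must find.

What the fixture does *not* emulate: real amino-acid composition,
correlated indels, domain architecture variation, fragmented gene models,
or clades that are themselves homologous to each other (planted clades are
mutually random). Passing tests therefore demonstrate the machinery is
correct and well-calibrated on its stated model, not that the thresholds
are optimal for any particular real genome.

## Numerical and design choices

* Strict inequalities at the screen thresholds (>30, >60) and exclusive
  length bounds (250 < L < 500): the tabulated protocol is treated as the
  operational record over looser prose.
* X (unknown residue): scores 0 and counts as mismatch in identity, matches
  no motif literal (but is matched by the wildcard), emits background in
  HMMs, contributes a full mismatch in the category distance, and carries
  no mass in alignment profiles. Conservative and deterministic everywhere.
* The similarity screen applies no E-value gate; identity and coverage are
  the only decision variables, and the exact DP replaces heuristic seeding.
* UPGMA ties break on the lexicographically smallest pair of cluster
  labels (a cluster is labelled by its smallest member id), making trees
  invariant to input order.
* Motif discovery reports only maximal motifs: a k-mer is dropped when a
  one-residue extension within the length bounds is supported by exactly
  the same positives. Discovery with an empty negative set is an error,
  not an empty result.
* Model serialization stores plain probabilities with 17 significant
  digits, which round-trips IEEE doubles exactly; the read path re-validates
  every emission row and transition bundle and reports the offending line.
* The gathering threshold is read as a bit score (25), the interpretation
  consistent with gathering-threshold semantics; the alternative e-25
  reading that also appears in the source material is not used.
* Generation-1 training sets include motif-reassigned sequences and the
  seed enzymes by default (`train_with_motif_calls`, `include_seeds`).
  Distance classification pools all genomes by default; the stages accept
  per-genome inputs if a caller prefers per-genome dendrograms.
* Tandem statistics are reported both pair-wise (fraction of classified
  tandem pairs sharing a clade) and gene-wise (fraction of classified
  in-tandem genes sharing a clade with at least one partner), because the
  gene-phrased and pair-phrased readings differ and both are defensible.
  Pairs involving unclassified genes are excluded from the same-clade
  denominator and counted separately.

## Problem sizes used in validation

The shipped validation uses 30 sequences per clade (plus 2-3 references
per clade, mirroring the nine characterized seed enzymes), 60 decoys, and
model lengths around 300 - small enough that the full pipeline runs in
about half a minute while every stage still has statistical room to fail
if mis-implemented. The parameter-recovery check rebuilds a planted model
from 500 sampled sequences and requires >= 95% per-column consensus
recovery plus complete bit-score separation (no overlap) between held-out
true sequences and their residue-shuffled controls at the 25-bit
threshold. The scoring kernels are verified against exhaustive path
enumeration (200 model/sequence pairs), the aligners against brute-force
DP (100 pairs), and the motif finder against a brute-force enumerator
(50 cases on restricted alphabets).

## Known limitations

* Glocal (not local) HMM alignment: adequate for near-full-length
  candidates after the length filter, but fragments pay heavy delete
  penalties; genuinely fragmented gene models are better served by a local
  architecture.
* No E-value calibration for HMM scores; the bit threshold is absolute.
* Exact-residue motifs only; the discovery scheme does not generalize to
  physicochemical-class wildcards (documented extension point).
* UPGMA assumes rate constancy (ultrametricity); the clade assignment is
  robust to this on well-separated families but is not a phylogeny.
* The progressive aligner has no iterative refinement; pathological guide
  trees on twilight-zone families will propagate early errors.
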
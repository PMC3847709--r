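---
title: "venomscan: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{venomscan: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

venomscan is a desk-scale reimplementation of the classic EST-style
workflow used to annotate snake venom-gland transcriptomes: assemble cDNA
reads into contigs, predict ORFs, screen for secretion signals, annotate
toxins by similarity against a curated toxin panel with a
reciprocal-best-hit guard, group sequences into families with a
similarity network, rank transcripts by abundance, mine the abundant
orphans for novel secreted proteins, and run a light selection screen on
toxin isoform groups. This vignette records the models, the tunable
parameters, and the design decisions behind each stage, together with
what the bundled synthetic data can and cannot demonstrate.

## The synthetic transcriptome and what it emulates

`generateTranscriptome()` plants a fixed protein repertoire modelled on a
venom-gland transcriptome of a burrowing asp:

* **13 three-finger toxin (3FTx) isoforms**, each carrying the ten
  mature cysteines of the plesiotypic scaffold. The isoforms are
  engineered into four similarity clusters (4 + 4 + 2 + 2 members,
  within-cluster amino-acid identity around 80%) plus one unrelated
  outlier scaffold, so that the within-family similarity network at an
  E-value ceiling of 1e-20 resolves four groups and one singleton.
* **2 polycistronic sarafotoxin precursors**: tandem cassettes behind
  dibasic KR processing sites, each cassette a 21-residue
  endothelin-like core (cysteines at core positions 1 and 7). The first
  precursor carries three *long* cassettes ending in the acidic DEP
  extension (mature peptides of 24 residues); the second carries one
  long and one bare 21-residue cassette.
* **3 lipocalins and 1 CRISP** as further known toxin families.
* **10 novel secreted isoforms**: mature region of exactly 173 residues
  with two conserved cysteines, a valid signal peptide, and no
  counterpart in the reference panel — the planted "new toxin class".
* **Background**: 200 housekeeping transcripts, 5 transposon-like
  transcripts, and two orphan controls, one of which is highly abundant
  but signal-negative (the negative control for the novel screen).

The amino-acid repertoire is drawn from a fixed internal random stream,
independent of the user seed. This is deliberate: the packaged reference
panel (one diverged ortholog per planted toxin isoform plus decoy
families, the stand-in for a curated toxin database snapshot) must match
the generated proteins for *any* seed, and the engineered cluster and
reciprocal-best-hit structure must be stable enough to assert in tests.
The user seed controls everything library-specific: synonymous codon
choice, UTR sequence, the abundance ranks of background transcripts, and
read sampling. A fixed seed yields bit-identical output.

**Abundance model.** Transcript weights follow a discrete truncated power
law over abundance ranks, with the exponent fitted at generation time so
that the 57 highest-weight templates carry 55% of the total weight —
a majority share, reproducing the situation in which a small set of
transcripts dominates the gland's output. Planted transcripts occupy
fixed ranks (the most abundant transcript is a novel secreted isoform,
a signal-negative orphan sits at rank 2, lipocalins at ranks 3/18/27,
the 3FTx isoforms and remaining novel isoforms spread through the top
57, sarafotoxins near the bottom of the top set); background transcripts
fill the remaining ranks in seeded random order.

**Read model.** Reads are sampled from templates proportionally to
weight (`non_normalized`) or to `weight^0.25` renormalized
(`normalized`; the exponent 0.25 is a free stand-in for normalization
kinetics, chosen once to compress the dynamic range roughly as a
duplex-specific normalization would — the flattening direction, not its
chemistry, is what downstream comparisons use). Start positions are
uniform, strands random, lengths normal with mode-specific means
(315 nt non-normalized, 344 nt normalized; sd 60) truncated to
[50 nt, transcript length], and substitution errors are i.i.d. at
`errorRate`. The default error rate is 0.005/base: substitution error in
long-read pyrosequencing is well below 1%, and the dominant homopolymer
indel mode is deliberately out of scope. This default also keeps the
read-versus-read overlap identity (about `2 * errorRate` mismatches)
clearly above the assembler's 98% merge threshold, so that the planted
coverage, not the error model, determines assembly outcomes.

What the generator does **not** emulate: homopolymer indels and quality
decay, chimeric reads, alternative splicing, paralog gene trees within a
cluster, and real codon-usage bias (synonymous codons are uniform).
Passing the end-to-end tests therefore shows that the pipeline logic is
correct under a realistic abundance and divergence structure — not that
it is robust to every artefact of a real sequencing run.

## Assembly

`assembleReads()` is a greedy overlap-consensus assembler with the
classic cDNA contig-building thresholds: a merge requires a verified
overlap of at least 40 alignment columns at 98% identity. Each contig is
seeded with the longest unassigned read; at each step the unassigned
read with the best verified overlap against the growing consensus (most
matching columns, ties broken by longer overlap then lexicographic read
id) is merged. Reads are reverse-complemented when their best overlap is
on the reverse strand, since cDNA reads are unstranded. The consensus is
a per-column majority vote; ties fall back to the base contributed by
the earliest-joined read, then to alphabetical order. Reads that merge
with nothing are singletons, and reads shorter than 50 nt are dropped
with a logged count before assembly.

Overlap **candidates** are located by exact k-mer seeding (k = 16, every
4th read k-mer indexed, consensus scanned densely) with diagonal voting;
each candidate is then **verified** by a banded free-end-gap
dynamic-programming alignment (band 10) around the voted diagonal, and
the merge decision uses only the verified overlap length and identity.
Pure banded-DP scanning of all read pairs would be quadratic in the
number of reads and is not tractable at the default study size of 1e5
reads, so seeding is used strictly as a candidate filter; with 16-mers
against a 40-column minimum overlap, an overlap that passes the
thresholds essentially always shares a seeded k-mer. The assembler and
the read mapper are compiled (Rcpp), as is usual for alignment kernels
in this field.

`mapReadsToContigs()` reuses the same verification kernel to assign
reads to an arbitrary contig or transcript set (best verified alignment;
equal-best hits on different contigs are assigned to the
lexicographically smaller id and flagged ambiguous), conserving counts:
mapped plus unmapped equals the input reads.

## ORFs, signal peptides, cysteine profiles

`findOrfs()` reports maximal ORFs in all six frames (first ATG after the
previous in-frame stop, stop required, standard genetic code), with a
minimum length of 60 aa — the classic annotation floor below which BLAST
matching becomes unreliable. Partial ORFs clipped by contig ends can be
reported flagged (`no_stop` / `no_start`); they feed the truncation
stringency filter rather than being silently discarded.

`predictSignalPeptide()` is a deterministic rule-based stand-in for an
HMM signal-peptide predictor, encoding the three canonical features of
secretory signals: at least one K/R among the first five residues
(n-region charge), a window of at least 6 residues with mean
Kyte-Doolittle hydropathy >= 1.6 inside positions 3..c-3 (h-region), and
small residues (A/G/S/C/T) at the -3 and -1 positions of a cleavage site
c between 15 and 35. The generator's signal peptides are built to
satisfy exactly one cleavage position, so generator and detector are
co-designed and the detector's acceptance of every planted secreted
protein is a tested contract. On shuffled mature-region sequences the
acceptance rate is under 5%; on arbitrary non-secreted proteins it is
higher (roughly 15-20%), which matters only for the novel screen's
false-positive rate, not for known-toxin calls (those additionally
require a reciprocal best hit). Sequences shorter than 25 residues are
reported not-evaluable rather than rejected.

## Similarity, E-values, reciprocal best hits

`alignPair()`/`searchAllVsAll()` perform exact Smith-Waterman local
alignment (BLOSUM62, gap open 11 / extend 1, ambiguity codes scored 0)
in a compiled kernel, with no seeding heuristics or compositional
adjustment — exactness over speed at desk scale. Raw scores are
converted to E-values with the Karlin-Altschul formula
`E = K * m * n * exp(-lambda * S)` using the standard gapped
BLOSUM62-11-1 constants (lambda = 0.267, K = 0.041), against the panel's
total residue count to approximate database-mode searching (the
constants and the database size are configurable through
`scoringScheme()`). No claim of bit-exact agreement with a full BLAST
stack is made; the E-values order hits identically to the raw scores
within one search and give the familiar scale for thresholds (1e-5 for
annotation, 1e-10 and 1e-20 for networks).

`reciprocalBestHits()` reports pairs that are each other's unique top
hit in both directions (ranking by E-value, raw score, then id); ties
that cannot be resolved exclude the sequence, with a message — a
deliberate false-positive guard, since keyword matching of hit
descriptions alone is highly prone to false positives when toxins are
recruited from ordinary cellular gene families. `clusterNonredundant()`
provides greedy longest-first clustering (identity over the shorter
sequence, default 0.9) to de-redundant a panel before network analysis.

## Networks and family groups

`buildSimilarityGraph()` collapses directional hits into undirected
edges weighted by the minimum of the two directional E-values (local
alignment is score-symmetric, but database-mode E-values differ by
direction, so the more significant one defines the edge). Components of
the graph (`connectedComponentsPartition()`) approximate families;
degree-0 nodes are singletons and, as in the classic network view, do
not appear in any group. Group labels (`G1`, `G2`, ...) are assigned by
component size then smallest member id — the labels are arbitrary, so
determinism is the only requirement. Export is GraphML plus SIF with a
membership TSV for Cytoscape-style viewers.

## The annotation decision workflow

`annotateTranscriptome()` chains the stages: representative ORF per
transcript (longest complete, falling back to longest truncated), signal
and cysteine screening, panel search at E <= 1e-5, keyword matching of
the top hit's description, reciprocal-best-hit confirmation
(keyword + RBH = `known_toxin`), the three stringency filters of the
toxin-repertory analysis (truncated ORF, ambiguous X residues, missing
signal peptide → `excluded`, with a named relaxation set for weakly
expressed families whose full-length transcripts cannot be recovered),
abundance ranking (raw mapped-read counts, not length-normalized —
ranking follows reads), and finally the novel screen: no panel hit,
accepted signal peptide, at least 2 mature cysteines, and an abundance
rank within the top 57 (all four gates configurable via
`novelParams()`). Every transcript with a qualifying ORF receives
exactly one verdict.

`cumulativeCoverage()` inverts the cumulative abundance curve: the
smallest k such that the k most abundant transcripts reach a target read
fraction. Comparing normalized and non-normalized libraries built from
the same templates reproduces the expected direction: the flattened
library needs substantially more transcripts to reach 80% of reads.

`parseSarafotoxinPrecursor()` locates cassettes by motif — a dibasic KR
boundary followed by the endothelin-like cysteine spacing (C at mature
positions 1 and 7), a 21-residue core, and a greedy extension of up to 4
residues drawn from {D, E, P} — yielding mature peptides of 21-25
residues and 24 for the long-DEP form. Real precursor processing sites
are not fully characterised; the motif is a documented, configurable
stand-in.

## The selection screen

`ng86Pairwise()` implements Nei-Gojobori (1986) counting with
equal-weight averaging over minimal mutational pathways and a
Jukes-Cantor correction. Two conventions needed fixing where the
literature varies: mutations to stop codons count as nonsynonymous in
*site* counting, which preserves the conservation identity
`sSites + nSites = 3 * codons`; and pathways through stop codons are
excluded from *difference* counting with weights renormalised (all
pathways are used unweighted in the degenerate case where every pathway
is blocked). Saturated corrections (log argument <= 0) flag the pair and
exclude it from group summaries; `omega = dN/dS` is undefined when
`dS = 0` and is then reported as NA alongside a positive dN.
`groupOmegaScreen()` averages omega over the defined pairs of an
alignment and flags the group as diversifying when the mean exceeds 1 —
the inferential direction (omega > 1 ⇒ positive selection) of the
site-model machinery it stands in for, without any claim of equivalence
to ML codon models, which are out of scope.

`simulateCodonAlignment()` provides the matching generator: a star-tree
continuous-time simulation in which each nucleotide position mutates
uniformly and changes are accepted at relative rate 1 (synonymous),
omega (nonsynonymous) or 0 (stop). The default branch length is 0.03
expected neutral substitutions per site: counting estimators are
consistent only at low divergence, and within-family toxin isoform
comparisons live in that regime. At this setting the screen recovers
simulated omega of 0.2, 1 and 3 within about 8% on average (500-codon
pairs), and flags omega = 3 families in effectively every replicate.

## Numerical and degenerate-input choices

* Assembly tie-breaks (seed choice, merge order, consensus votes) and
  network orderings are all fully deterministic, so fixed seeds give
  bit-identical outputs across runs.
* `rankAbundance()` uses dense ranks (tied counts share a rank) with id
  order for display; all-zero count vectors are an error.
* `cumulativeCoverage()` guards the target to (0, 1]; boundary sums use
  a 1e-12 tolerance.
* Reads shorter than the 50-nt usable minimum are dropped with a logged
  count; empty libraries and empty panels warn and return empty results
  rather than erroring.
* The E-value ceiling of a graph must be positive; self-edges are never
  created.

## Problem sizes

The shipped tests and the acceptance script run the full chain at the
default study size: 236 templates, a non-normalized library of 100,000
reads (assembled in a few minutes on one CPU), a 33-entry reference
panel, oracle checks on 50-100 random instances per kernel, and 24
replicate 500-codon pairs per omega level for the selection screen.
These sizes were chosen so every stage is exercised at a scale where its
statistical behaviour (majority-vote consensus convergence, top-57
abundance share, estimator bias) is visible, while a complete run stays
in the minutes range.

## Known limitations

* The signal-peptide rule is a heuristic; its false-positive rate on
  arbitrary cytoplasmic proteins means novel-candidate lists from real
  data would need downstream curation (as they do in practice).
* E-values are Karlin-Altschul approximations with fixed constants, not
  BLAST-calibrated per-search estimates.
* The assembler has no scaffolding, no quality-aware consensus, and a
  substitution-only error model; it is not a replacement for a
  production assembler on real 454/Illumina data.
* NG86 is a counting estimator: it saturates at high divergence and
  mildly underestimates strong positive selection; site-specific and
  branch-site inference are explicitly out of scope.
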
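---
title: "Methods: EST pipeline models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EST pipeline models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

estkit re-implements, as a tested and reusable toolkit, the computational
stages of a classic Sanger-era expressed sequence tag (EST) project on a
non-model invertebrate: read cleaning, stringent assembly into unigenes,
coding-region determination, composition statistics (GC structure, codon
usage, amino-acid profiles), interaction sub-network analysis, and
taxonomic-specificity classification. Every stage can be exercised end to
end on data from the package's own seeded simulators, so each algorithm is
testable against planted ground truth without any external database or
download. This vignette records the models, the parameters that matter,
and the decisions taken where the procedure left genuine design freedom.

## Read cleaning

**Quality clipping.** A window of 20 bases is slid along the phred quality
vector from both ends; the clip interval runs from the start of the first
window (left to right) whose *mean* phred exceeds 13 to the end of the
first such window scanning right to left. "Window value above a
threshold" is read as the window mean: a per-base reading would make the
window length meaningless, and mean-above-threshold is the common trimming
convention. Reads shorter than one window are evaluated as a single
window. Coordinates are 0-based half-open internally and 1-based inclusive
in exported reports.

**Vector masking.** A seeded-alignment stand-in for cross_match: reads
sharing at least one exact 12-mer with a vector sequence (either strand)
are locally aligned to it (match +1, mismatch −2, gap open 4, extend 1);
every aligned segment of ≥ `min_match` (default 20) nt with a
mismatch+indel rate ≤ `max_mismatch_rate` (default 0.1) becomes a mask.
Masking is iterated on the unmasked remainder, so independent 5' and 3'
contaminations are both found. The cross_match scoring dialect is not
reproduced bit-exactly; on substitution-only data the masks are exact.

**Poly(A)/poly(T) boundary masking.** Tails are detected with a
20-of-25 rule — scanning inward from a read end (or from the inner edge of
a terminal vector mask), windows of 25 nt containing ≥ 20 A (or T) extend
a candidate tail region. The final mask is then trimmed to the maximal
contiguous terminal A (or T) run inside that region. The trimming step is
deliberate: a pure window-extension mask systematically overshoots a
planted tail by up to 5 nt (window minus hits), which would contradict
exact recovery on error-free reads. Under sequencing errors the trimmed
mask conservatively stops at the innermost error. Both base types are
searched at both ends, since clones are sequenced in either orientation.
A tail shorter than 20 nt cannot satisfy the window rule and is by
construction undetectable.

**Disposition.** After clipping and masking, the longest contiguous
unmasked stretch inside the clip is kept if it is ≥ 100 nt (`kept`),
otherwise the read is `too_short`; a read whose clip region is entirely
vector-masked is `empty_vector`. The kept fraction, the poly(A) fraction
and mean clean length are reported per run.

## Assembly

Unigenes (contigs + singletons) are built by a greedy
overlap-layout-consensus assembler under a stringent contract: two
sequences merge only when they share an overlap of ≥ `min_overlap`
(default 40 nt, the usual assembler default) at ≥ `overlap_identity`
(default 90%), with at most `clip_range` (default 30 nt) of a read end
clipped to reconcile the overlap. Reverse-complement overlaps are allowed.
The 90%/30 nt pair mirrors stringent EST assembly practice aimed at
keeping paralogs, divergent alleles and splice variants apart.

The merge order is incremental rather than all-pairs: reads are processed
in descending length (ties by id), each read is compared via shared
16-mers against the consensi of the unigenes built so far, candidate
overlaps are scored (overlap length × identity) and the read joins the
best qualifying unigene, extending its consensus where the read overhangs;
a final consolidation pass greedily merges unigene pairs whose consensi
themselves pass the same thresholds, highest score first. All-pairs greedy
merging is quadratic in cluster size and becomes infeasible for the deep
clusters (hundreds to thousands of reads) that highly expressed genes
produce; the incremental order preserves every stated threshold, is fully
deterministic, and is re-verified post hoc by realigning member reads to
their consensus. Overlaps are scored by a seed-diagonal ungapped check
first (exact for substitution-only divergence) with a fall-back to
ends-free pairwise alignment when the ungapped identity comes within 0.05
of the cutoff, suggesting indels.

The consensus is a per-column phred-weighted majority; ties resolve toward
the alphabetically first base. Read insertions relative to the consensus
are dropped from the profile (they cannot shift established coordinates);
with substitution-only errors this is exact. Member read counts per
unigene are the expression proxy, and ranking by count defines the highly
expressed gene lists.

## Coding-region determination

Two tracks, reconciled with homology precedence.

**Homology track.** The reading frame comes from the best protein hit
(lowest E-value ≤ 1e−5; ties by alignment length × identity, then subject
id). The matched interval is extended in frame: 3' to the first in-frame
stop codon (included) or the sequence end; 5' to the first in-frame stop,
after which the first ATG becomes the initiation codon — if no 5' stop
exists the CDS runs to the sequence start and is 5'-partial. A CDS is
*complete* when it starts with ATG, ends with a stop, and covers at least
80% of the best hit's subject; a structurally complete CDS under that
coverage is downgraded to the partial class of the uncovered subject
end(s). The 80% rule is applied as a completeness criterion, not an
acceptance filter, following the placement of the rule among the
completeness conditions. Frameshifts indicated by same-subject hit
segments in different frames (same orientation) are masked by one 'X' per
inter-segment residue; mixed-orientation segments are rejected.

**Ab initio track.** An order-5 Markov (hexamer) log-odds model stands in
for an ESTScan-style coding-potential scorer: in-frame dicodon frequencies
from coding training sequences versus position-free hexamer frequencies
from noncoding ones, pseudocount-smoothed, summed over hexamers stepped by
one codon; the best of the six frames is reported. The stand-in reproduces
the score-threshold workflow (a published operating point of
specificity 70% / sensitivity 66% at a cutoff of 200 is a property of the
original data and model, not of this scorer) while remaining fully
specifiable; it has no indel states. The acceptance cutoff is optimized
against homology labels by maximizing Youden's J, with the full ROC table
returned so any operating point can be read off.

## Composition statistics

**GC by region.** GC = (G+C)/(A+C+G+T) with N excluded from both
numerator and denominator; GC3 is computed over third codon positions with
the stop codon excluded; the 3'UTR GC is computed after removal of a
terminal poly(A) run. A cross-identity (GC3 from the codon-usage table
equals GC3 from raw third positions) is enforced by test.

**Codon usage.** RSCU is the standard observed/expected ratio under
uniform synonymous usage; per amino acid, RSCU averages to 1 when the
amino acid occurs, and codons of unexpressed amino acids are NA. Stop
codons are tallied separately.

**Correspondence analysis.** Standard CA: SVD of the standardized Pearson
residuals of the relative-frequency matrix. Axes are ordered by inertia;
the sign of each axis is fixed by making its largest-magnitude codon
loading positive, so results are deterministic. Total inertia equals the
table's chi-square divided by the grand total, checked against an
independent eigendecomposition to 1e−8. Optimal-codon candidates are the
codons in the extreme tail (default 10%) of axis 1 at each pole, oriented
by the Spearman correlation between gene axis-1 coordinates and
expression.

**Expression–GC regression.** The model menu is linear (a + bx), power
(a·x^b), exponential, logarithmic, and a saturating form
plateau − (plateau − base)·x^(−rate). The original description of the
best-fitting "power function (y = ax+b)" is internally inconsistent
(a power law written with a linear formula), so the fitter exposes the
whole menu and compares by residual sum of squares rather than guessing
the typo's intent; the saturating form is the generator's planted model
and reproduces a plateau at roughly 25–30 copies with asymptote ~0.55.
Nonlinear fits use Levenberg–Marquardt with analytic-free starts from
log-space linear fits; the F statistic compares each fit against the
intercept-only model.

**Amino-acid composition.** Charged residues are D, E, K, R and the
positive subset is K, R; histidine is excluded by default (the observed
excess is attributed to lysine and arginine) and can be included with a
flag. Hydrophobicity is the mean of the Sweet–Eisenberg optimal matching
hydrophobicity (OMH) scale, shipped as a package constant.
Cross-taxon homogeneity is tested with both the chi-square and G
(log-likelihood ratio) statistics on the taxon × amino-acid count table.

**Identity matrices.** For each ortholog family (one aligned sequence per
taxon) every column containing a gap in any sequence is discarded; percent
identities are computed on the concatenation of retained columns, so all
taxon pairs use the identical position set.

## Interaction sub-networks

Networks are built from scored edge lists at a combined-score cutoff of
0.9 (inclusive); duplicate undirected edges keep the maximum score,
self-loops are dropped, and isolated nodes are retained. A level-1
sub-network is a seed plus its direct neighbours with all induced edges,
scored by the ratio of consistency Rc = edges / (n(n−1)/2). Rc for n ≤ 1
is defined as 1 (vacuously consistent); the consequence — a singleton
contained in another sub-network always fuses into it — matches the
criterion's intent. Two sub-networks fuse when
1 − (1 − Nc)(1 − RcA)(1 − RcB) ≥ 0.7 **and** Nc ≥ 0.5, where Nc is the
shared-node fraction of the smaller sub-network. Fusion is greedy
highest-score-first with full recomputation after each merge (ties by
larger Nc, then lexicographically smallest member pair), iterated to
fixpoint; the order is not prescribed by the original description, so
determinism and input-order invariance are enforced by the tie-breaking
rules and checked against an exhaustive-search oracle on small pools.

Query-to-network mapping tries identifier types in a fixed priority order
(uniprot_id, uniprot_ensembl, refseq, genome_reviews, gene_name),
accepting the first unique textual match, falling back to the best
similarity hit at E ≤ 1e−5, else unmapped. Pathway coverage counts
distinct enzymes only and flags pathways covered above 50%.

## Taxonomic specificity

Hits above E = 1e−5 are discarded; hits in Annelida or Mollusca — the
query's own lineage and its sister group — are ignored as uninformative;
a query whose remaining hits reduce to a single taxon label is specific to
that taxon, an empty remainder is "no informative homolog" (the
lineage-specific pool), anything else is shared. The gene-loss sets are
exact set definitions over the effective taxon sets (Deuterostomia only;
exactly Deuterostomia+Cnidaria; Cnidaria plus ≥1 protostome and nothing
else; protostome-only; no homolog) and are pairwise disjoint by
construction. Family/superfamily grouping is out of scope; an optional
user-supplied family mapping aggregates per-protein calls by majority.

## The synthetic-data generators

The generators define the study conditions every test runs under.

**Transcriptomes.** mRNAs are 5'UTR + CDS + 3'UTR with UTR GC targets
0.457 / 0.397 (typical invertebrate values) and CDS lengths lognormal
around 540 nt. Copy numbers (the expression proxy) are log-uniform on
[1, 223], the observed range of cDNA cluster sizes, with the endpoints
forced present. GC3 follows the saturating model
plateau − (plateau − base)·c^(−rate) with defaults base 0.40,
plateau 0.55, rate 1 — reaching ~96% of the rise by 25 copies, matching
the observed plateau onset — plus Gaussian scatter (sd 0.008). GC-ending
synonymous codons are allocated by exact count (accounting for the fixed
G third positions of ATG and TGG), so realized GC3 matches its target to
a few thousandths. The last 5'UTR codon is always an in-frame stop: with
an upstream stop immediately adjacent to the start codon, the
homology-extension rule ("first ATG after the 5' stop") identifies the
planted initiation site exactly, which the planted-recovery contract
requires; real 5'UTRs only usually carry such stops, so start-codon
recovery on real data is correspondingly less certain. The scatter value is a calibration: it is the level at
which the planted parameters remain identifiable to 10% relative error at
the ribosomal-set sample size (n = 84) in ≥95% of replicates, which the
generator is contractually required to support. Real per-gene GC3 scatter
is larger (the observed spread is ±0.075 including the expression trend),
so parameter-recovery results on synthetic data do not imply the same
precision on real data.

**Reads.** Substrings of the mRNA with Gaussian lengths (mean 674 nt, the
observed mean clean length), substitution-only errors, per-base phreds
around a logistic profile decaying from ~45 mid-read to ~8 over the last
~30 bases of each end (Sanger-like traces), optional reverse
complementation, poly(A) tails appended to 3'-anchored reads at a
configurable rate (observed range 8–43% per library), 5'-anchored
"capped" reads emulating full-length-enriched library construction, and
vector contamination as a vector *suffix* at the 5' end and *prefix* at
the 3' end, as at real cloning junctions — which also makes planted masks
exactly identifiable. Reads per transcript are allocated proportionally
to copy number by largest-remainder rounding. The truth table records
every planted feature in exact read coordinates. No error model was
published for the original reads; substitution-only is an assumption of
the simulator, not an inference about the study's data, and chimeras,
indels and base-caller artefacts are not emulated — which is exactly why
mask/assembly recovery being exact here says nothing about exactness on
real traces.

**Interactomes.** Planted-partition graphs: intra-module edge probability
`p_in`, inter-module `p_out` (requiring p_in > p_out), with combined
scores drawn from [0.9, 1] inside modules and [0.5, 0.9) between them, so
the 0.9 score cutoff retains planted modules and discards most
cross-module contacts — the role an integrated-confidence score plays in
real interactomes. Under uniform scores the level-1 neighbourhoods would
necessarily carry cross-module contamination (Jaccard ~0.77 at
p_out = 0.01) no matter the fusion rule.

**Hit profiles.** A scenario maps each protein to its homolog-bearing
taxa; 1–3 hits per pair are emitted with E-values ≤ 1e−5 and none outside
the scenario.

All generators route randomness through one seeded RNG per call and are
byte-reproducible; truth tables account for every emitted read, edge and
hit exactly once.

## Numerical choices and degenerate inputs

* Coordinates: 0-based half-open everywhere internally; GFF3 export is
  1-based inclusive.
* Empty inputs: an empty read set assembles to an empty unigene set; an
  empty edge list builds a graph of isolated nodes; zero countable bases
  give NA GC values; a single-class label vector is an error for cutoff
  optimization, as is an empty proteome or a rank-0 count matrix.
* Ties: consensus ties toward the higher summed phred then alphabetical;
  best hits tie-break by bit proxy then subject id; fusion ties by Nc then
  lexicographic member ids; CA signs fixed by the dominant loading.
* Tolerances: CA is validated to 1e−8 against an independent
  eigendecomposition; noise-free power-fit recovery to 1e−6; the
  saturating fit runs Levenberg–Marquardt to 500 iterations.

## Problem sizes used by the test suite and acceptance script

The suite exercises: the clip oracle on 10^4 random quality vectors; mask
recovery on 5,000 planted reads; assembly recovery on 50 transcripts at
8× error-free tiling plus 85%-identity paralog separation; the CDS oracle
on 500 constructed unigenes; CA oracle agreement on 20 random 10×59
matrices; saturating-parameter recovery over 200 seeds at n = 84; the
fusion oracle on 100 random ≤10-node instances and planted-module
recovery over 50 seeds; the classification oracle on 10^4 random
profiles; and a byte-identity check of the full pipeline on 500
transcripts / 20,000 reads run twice. The acceptance script runs the same
pipeline once at the 500-transcript / 20,000-read scale and reports its
headline quantities. These sizes were chosen to give stable statistics
while keeping a full run comfortably interactive on a laptop.

## Known limitations

* The assembler is a stand-in honouring the stated parameters, not a
  CAP3 re-implementation; indel-rich or chimeric reads are outside its
  tested envelope.
* The coding-potential model has no indel states and is trained on
  synthetic composition, so its absolute scores are not comparable to
  ESTScan's; only the threshold workflow is reproduced.
* Per-protein taxonomic calls ignore family structure unless a family
  mapping is supplied; no lowest-common-ancestor placement is attempted.
* Rc for singleton sub-networks and the fusion processing order are
  package decisions where the original description is silent.
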
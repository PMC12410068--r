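---
title: "Detecting spliced-leader trans-splicing and predicting operons from long RNA reads"
author: "SLcallR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting spliced-leader trans-splicing and predicting operons from long RNA reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The biological problem

In nematodes and several other eukaryote lineages, most mRNAs are matured
by spliced-leader (SL) trans-splicing: a short conserved leader RNA
(~22 nt in *C. elegans*) replaces the 5' outron of the pre-mRNA. Two
leader classes exist in *C. elegans*: a single SL1 sequence, attached to
most trans-spliced genes, and a family of SL2 variants attached almost
exclusively to the *downstream* genes of operons — polycistronic gene
clusters resolved into monocistronic mRNAs by trans-splicing. Typing the
SL on each RNA molecule therefore does two things at once: it certifies
that the read captured a complete mRNA 5' end, and it reads out operon
structure directly from the transcriptome.

When a long RNA read is spliced-aligned to the genome, the SL has no
genomic origin near the gene, so it survives only as an *unaligned 5'
soft clip*. Three properties make calling SLs from these clips hard:

* direct RNA sequencing proceeds 3'→5', so the 5' end is sequenced last
  and is frequently truncated — usually only a 5–9 nt residue of the SL
  survives;
* the 5' ends of nanopore reads carry elevated error rates;
* SL1 and the SL2 variants are similar to one another, so a partial,
  noisy residue is easily mis-assigned.

`SLcallR` scores soft-clip residues against an SL reference set with a
local alignment score augmented for exactly this setting, calibrates a
dynamic score cutoff against random control sequences, and aggregates
per-read SL types into per-gene evidence for operon calling.

## The detection model

### Candidate extraction

Only primary alignments are considered. For a plus-strand alignment the
leading soft clip of SEQ is the read's 5' clip; for a minus-strand
alignment the trailing soft clip is reverse-complemented. Hard-clipped
bases are absent from SEQ and contribute nothing. Reads whose 5' clip is
shorter than `minClip` (default 5 nt, the shortest residue worth scoring)
are tallied as *other*; the rest are *candidate* reads.

### The SL score

Each clip is aligned to every SL reference with a Smith–Waterman local
alignment (match +1; mismatch, gap-open and gap-extend penalties all 1; a
k-base gap costs `gapOpen + k*gapExtend`). Equal-scoring optima are
resolved by the canonical row-major convention — the first optimum
scanning query, then reference positions. On the optimal region the score
is augmented and normalized:

* **continuity** — `C` counts sliding 5-column windows of the alignment
  with at most one non-match column (gap columns count as mismatches);
  each adds `w_c = 0.5` to the raw score `raw = sw + w_c*C`. Genuine SL
  residues align as one contiguous exact or near-exact block; scattered
  partial matches do not.
* **reference 3' proximity** — factor `f3 = ref_end / len(ref)`. The SL
  3' end is the trans-splice junction, so a real residue must reach the
  reference 3' end; matches buried in the middle of the reference are
  discounted.
* **query 5' proximity** — factor `f5 = 1 - query_start / len(clip)`.
  The residue must sit at the very start of the clip, adjacent to the
  aligned mRNA.
* **normalization** — the final score is
  `raw * f3 * f5 / M(n)` with `M(n) = n + w_c*max(0, n-4)` and `n` the
  full clip length, clamped to [0, 1]. A clip that aligns perfectly
  end-to-end to a reference 3' end scores exactly 1.

Two design points deserve justification, because both were settled by
measurement rather than taste. First, the normalizer uses the *clip*
length, not the aligned-region length. Normalizing by the aligned region
makes every exact k-mer coincidence score 1.0 — even a 2-base clip prefix
equal to a control's last two bases — and with 5–9 nt residues such
coincidences are so frequent that the background distribution develops a
large mass at 1.0 and no cutoff can separate signal from noise. Counting
unaligned clip bases against the score caps a k-mer coincidence near
`k/n` while leaving complete residues at 1. Second, alignment ties are
broken neutrally rather than toward the reference 3' end: the same
scoring must be applied to SL references and random controls alike, and a
tie-break that hands every ambiguous short match the maximal positional
weight inflates the null in exactly the region where the cutoff is
decided.

### Random controls and the dynamic cutoff

Ten i.i.d.-uniform control sequences are generated at the rounded mean
reference length (22 nt for the *C. elegans* set; rounding is half-up),
from a user-visible seed that is recorded in the run summary. Each
candidate read keeps its best SL score and its best control score; it is
a *potential SL* read only if the SL score strictly exceeds the control
score (ties fail).

For the cutoff, both best-score distributions are turned into cumulative
curves over the union of observed score values: `N_SL(s)` counts
candidate reads with best-SL score ≥ s, `N_random(s)` likewise for
controls. The dynamic cutoff is

```
s_c = min{ s : N_SL(s) / N_random(s) >= f }
```

with fold `f = 4` by default; `N_random(s) = 0` with `N_SL(s) > 0`
satisfies the condition. Potential SL reads with score ≥ `s_c` become
*high-confidence SL* reads. When no score satisfies the condition — the
expected outcome for a species without SLs, where the two curves
coincide in distribution — the run completes with zero high-confidence
reads and a warning. The trapezoidal area ratio between the two curves
(`aucSeparation`) summarizes how well the score separates signal from
background.

### SL typing

Per read, the reference with the unique highest score gives the label. A
tie spanning SL1 and an SL2 variant yields `SL_unknown` (class
unresolvable; such reads are excluded from operon evidence); a tie among
SL2 variants yields `SL2_unknown`, which still counts as class SL2. With
short residues many SL2 variants are legitimately indistinguishable —
they share 3' suffixes — so variant-level labels saturate long before
class-level labels do.

## Operon prediction

* **Gene assignment.** A gene is assigned to a read when the exonic
  intersection covers at least one-third of the read's exonic span *and*
  one-third of the gene's exonic span. The symmetric rule keeps short
  reads from claiming long genes and vice versa. Reads assigned ≥ 2 genes
  are *fusion reads* — molecules spanning adjacent genes, the signature
  of a partially processed polycistronic transcript.
* **Evidence aggregation.** High-confidence reads with a resolved class
  increment SL1 or SL2 counters on their gene. For fusion reads the SL
  belongs to the first gene in transcription order; downstream genes
  inherit it only if their transcription-direction start lies within half
  the first gene's length of the first gene's start (measured from the
  start, one of two defensible anchors; the choice is recorded here
  deliberately). Total assigned reads are counted per gene regardless of
  SL status.
* **Roles.** More SL1 than SL2 reads → *upstream* gene; otherwise
  *downstream*. Independently of the majority, a gene whose SL2 reads
  exceed one-fourth of its total assigned reads *and* number more than
  five (≥ 6) is *both* — it can close one operon segment and open
  another. Genes without SL-typed reads are *none*.
* **Grouping and calling.** Same-strand neighbours with an intergenic gap
  ≤ 5000 bp (the operon promoter span; gap measured end-to-start in
  transcription order) share a cluster. Within a cluster, maximal runs of
  an upstream/both gene followed by downstream/both genes are candidate
  operons, confirmed when *every* downstream gene has ≥ 3 SL2-type
  supporting reads. Separately, a multi-gene combination observed in more
  than three identical fusion reads that contains an SL2-classified gene
  is called with fusion evidence. A cluster may emit several disjoint
  runs. Calls are written as GFF3 `operon` features carrying the ordered
  gene list and support counts; output is byte-deterministic.
* **Evaluation.** Against a reference operon annotation, gene-level
  precision/recall treat each operon-member gene as a unit;
  structure-level metrics require the ordered gene list to match a
  reference operon exactly.

## The synthetic data generator

The simulator emulates the features of a direct RNA experiment on a
trans-splicing nematode that the pipeline actually exercises: operonic
gene blocks whose downstream genes receive SL2 variants and whose first
genes (and singletons) receive SL1; geometric-like 5' truncation
(a fixed 13 nt offset plus a geometric(0.3) tail of further loss, SL
bases lost first) leaving a modal SL residue of 9 nt and most residues in
the 5–9 nt band; substitution/insertion/deletion noise at nanopore-like
rates (3%/1%/1%); occasional fusion reads spanning a gene and its
predecessor (rate 0.1); reads without any SL, a fraction of which carry
short random "junk" clips as transcription-start scatter does in real
alignments; and units placed on both strands. Alignments are written
directly as SAM with soft clips exactly equal to the surviving,
noise-bearing SL residue, so tests are hermetic and the truth table is
exact; a FASTQ of the reads is also emitted for users who prefer to run a
real aligner.

The default configuration *is* the documented study condition used by the
acceptance checks: 20 operons of 3 genes (60 genes), 10 reads per gene
(a realistic per-gene depth for a moderate direct-RNA run that gives the
≥ 3-read downstream support rule adequate power), gene lengths 1–2 kb,
within-operon gaps 200–800 bp, 8 kb between units so distinct units never
co-cluster under the 5 kb span.

What the simulator does **not** model — and hence what green tests do not
certify about real data: homopolymer-biased and signal-level nanopore
errors, poly(A) tails, alternative TSSs and unannotated 5' exons beyond
the junk-clip placeholder, expression-level variation between genes,
multi-chromosome genomes, and soft-clip misplacement by a real aligner
(cDNA mode in particular shifts more of the burden to the aligner).

## Numerical and degenerate-input choices

* Mean reference length is rounded half-up; U is mapped to T on FASTA
  input; reference categories come from an `SL1` name-prefix rule (a
  digit may not follow, so `SL10` is SL2) overridable by an explicit map.
* "Strictly exceeds" for potential-SL status, `>= s_c` for promotion (the
  minimal satisfying score is itself selected).
* Score grid for the cutoff: union of best-SL and best-random scores, so
  the fold ratio is evaluated at every point where either curve steps.
* A zero SW score yields an SL score of 0 with an empty region; empty
  candidate sets are an error for curve building; an absent cutoff
  promotes nothing and warns.
* Problem sizes used by the test-suite: the alignment oracle is checked
  on 500 random pairs of length ≤ 15 against an independently written
  plain-R DP; score bounds on 10^4 random clip/reference pairs; the
  end-to-end check runs the default study condition once with a fixed
  seed.

## Known limitations

Scores are discrete for short clips, so ties (resolved conservatively)
are common at 5–6 nt residues; variant-level SL2 labels are frequently
`SL2_unknown` at realistic residue lengths; the promoter-span grouping is
a coordinate heuristic, not a promoter model; and fusion-read SL
propagation uses a half-gene-length window anchored at the first gene's
start, which is one of several defensible readings of how far a
polycistronic molecule's SL should reach.
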
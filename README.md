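# SLcallR

Spliced-leader detection and operon prediction from long RNA reads.

## The problem

In *C. elegans* and many other eukaryotes, mRNAs are matured by
**spliced-leader (SL) trans-splicing**: a short conserved leader
(~22 nt) replaces the pre-mRNA's 5' end. The SL1 leader marks most
trans-spliced genes; the SL2 variant family marks the *downstream* genes
of **operons**, so per-read SL typing reads operon structure straight
out of the transcriptome. After spliced alignment of a long RNA read,
the SL survives only as a short, error-prone **5' soft-clipped residue**
— typically 5–9 nt in direct RNA sequencing, where the 5' end is
sequenced last and often lost. `SLcallR` is for transcriptomics
researchers who have spliced long-read alignments (nanopore direct RNA
or cDNA) of a trans-splicing species and want per-read SL calls and an
operon annotation.

## The method

For each candidate read (primary alignment, 5' clip ≥ 5 nt, strand-aware
extraction) the clip is aligned to every SL reference by Smith–Waterman
(match +1, mismatch/gap-open/gap-extend penalties 1, a *k*-base gap
costing `1 + k`). The optimal region is rescored as

    SL score = (sw + 0.5 C) * f3 * f5 / M(n)

where `C` counts 5-column alignment windows with ≤ 1 non-match column,
`f3 = ref_end / |ref|` rewards regions reaching the reference 3' end
(the trans-splice junction), `f5 = 1 - query_start / n` rewards residues
at the clip's 5' start, and `M(n) = n + 0.5 max(0, n - 4)` is the best
score the whole clip of length `n` could achieve. A complete residue
scores exactly 1; a coincidental *k*-mer match tops out near `k/n`.

The same scoring against 10 seeded random control sequences (at the
rounded mean reference length, 22 nt for *C. elegans*) gives a per-read
background score. Reads whose best SL score strictly beats their best
control score are *potential SL* reads, and the **dynamic cutoff**

    s_c = min{ s : N_SL(s) / N_random(s) >= 4 }

over the cumulative score curves promotes them to *high-confidence SL*
reads; for data without SLs no cutoff exists and nothing is promoted.
Reads are typed SL1 / specific SL2 variant / `SL2_unknown` /
`SL_unknown`; per-gene SL1/SL2 tallies (with fusion-read propagation)
classify genes as upstream / downstream / both, and operons are called
from same-strand gene clusters (≤ 5000 bp gaps) showing the
upstream→downstream pattern with ≥ 3 SL2 reads per downstream gene, or
from > 3 identical fusion reads containing an SL2 gene. Calls are
written as GFF3 and can be benchmarked against a reference operon
annotation at gene and structure level.

## Worked example

Everything below is generated in-code — a synthetic genome, annotation,
trans-spliced reads and their SAM alignments — so it runs without any
external data:

```r
library(SLcallR)

refs <- loadSLReferences(system.file("extdata",
        "celegans_sl_synthetic.fasta", package = "SLcallR"))
refs
#> SLReferenceSet with 13 references ( 1 SL1, 12 SL2 )
#>   control length: 22 nt
#>   names: SL1, SL2, SL3, SL4, SL5, SL6 ...

sim <- simulateDataset(simulationConfig(seed = 9, nGenes = 9,
        nOperons = 3, genesPerOperon = 3, readsPerGene = 8),
        refs, "demo")
det <- runDetect(sim$alignments, refs, seed = 9)
det$tally
#>              other          candidate       potential_SL high_confidence_SL
#>                 12                  1                  3                 56
round(det$cutoff, 3)
#> [1] 0.525

op <- runOperon(det, sim$annotation, outdir = "demo/out")
#> genes: 3 upstream, 2 downstream, 4 both, 0 without SL; 3 operons
unlist(evaluateOperons(op$operons, sim$operons))
#>      gene_precision         gene_recall structure_precision    structure_recall
#>                   1                   1                   1                   1

residualLengthHistogram(det$calls)
#>  5  6  7  8  9 10
#>  5 12 13 11 13  2
```

Of 72 simulated reads, 60 carry a 5' clip ≥ 5 nt; 56 are promoted to
high-confidence SL reads at the dynamic cutoff of 0.525. All three
simulated operons are recovered exactly, and the surviving SL residues
concentrate at 5–9 nt, as expected for direct RNA reads. The SL FASTA
shipped under `inst/extdata/` is a synthetic stand-in assembled from the
community-known *C. elegans* SL1/SL2-family sequences; point
`loadSLReferences()` at your own reference FASTA for real analyses.

A thin command-line wrapper with `detect`, `operon`, `simulate` and
`evaluate` subcommands is installed at
`system.file("scripts", "sl_pipeline.R", package = "SLcallR")`.

## Vignette

`vignettes/sl-detection-methods.Rmd` documents the scoring model and its
rationale, all tunable parameters with defaults and units, what the
simulator does and does not emulate, and known limitations.
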
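# stacer

Tag-based discovery of novel genes and reconstruction of full-length cDNA
ends (STACE), for transcriptomics researchers who have SAGE-style expressed
tag libraries and an annotated genome, and want to turn unexplained tags
into testable primers and, after sequencing, into gene models.

## What it does

A (long)SAGE tag is a short transcript signature — `CATG` (the NlaIII
anchor) plus 17 bases taken at the 3'-most anchor site of a transcript —
counted across expression libraries. A tag that maps to the genome but to no
annotated transcript is expression evidence for a missing gene. STACE
(sequence tag-based amplification of cDNA ends) recovers that gene's cDNA
with two anchored PCRs: an upstream amplicon between the SL1 trans-spliced
leader (present at the 5' end of ~half of *C. elegans* mRNAs) and a primer
derived from the tag, and a downstream amplicon between the tag primer and a
universal 3' site attached during reverse transcription.

`stacer` implements the computational pipeline around the bench work:

1. **Screen** (`stace_screen()` / `run_cascade()`): filter a tag library
   through the published cascade — unique exact genomic mapping, exclusion
   of tags in any annotated exon or spliced transcript (the *virtual
   transcriptome*), normalized frequency ≥ 3 per 100,000 reads, no intron
   overlap and ≥ 500 bp from any annotated gene boundary, GC ∈ [35, 45]%,
   and successful primer derivation — emitting the per-stage survivor
   funnel.
2. **Design** (`derive_primer()`): the primer is the reverse complement of
   the (possibly end-trimmed) tag, screened on GC, nearest-neighbor melting
   temperature (55–65 °C at PCR-like salt), hairpins, and homo-/hetero-dimers
   against the fixed SL1 (`GGTTTAATTACCCAAGTTTGAG`) and universal
   (`CACTATGCTCATACGACGCAGT`) primers.
3. **Classify** (`stace_classify()`): strip SL1 leaders and polyA
   tails/adapters from sequenced amplicons, align them spliced to the
   genome (built-in exact aligner, or ingest BLAT-style BED12/PSL), call a
   result *true positive* when its genomic span overlaps the originating
   tag, validate GT–AG splice signals, categorise it as novel gene /
   annotation extension / non-protein-coding overlap, and assemble
   upstream+downstream pairs into cDNA models — *full-length* when SL1 and
   polyA evidence are both present.
4. **Simulate** (`stace_simulate()`): a seeded generator of toy genomes
   with hidden novel genes, tag libraries with error-derived noise tags,
   and STACE amplicon pairs, with complete ground truth — every stage of
   the pipeline is testable offline.

## Worked example

```r
library(stacer)
dir <- file.path(tempdir(), "demo")
sim <- stace_simulate(simulation_config(seed = 7), out_dir = dir)

cascade <- stace_screen(file.path(dir, "genome.fasta"),
                        file.path(dir, "annotations.gff3"),
                        file.path(dir, "tags.tsv"),
                        out_dir = file.path(dir, "screen"))
print(cascade)
#> stace_cascade funnel:
#>              stage count
#>              total    14
#>           mappable    11
#>  non_transcriptome     3
#>       frequency_ok     3
#>        position_ok     3
#>              gc_ok     3
#>         primerable     3
```

The simulated library holds 14 distinct tags: one per gene (6 coding genes,
a pseudogene, an ncRNA, 3 hidden novel genes) plus 3 low-count sequencing
error tags. The error tags die at mapping, the 8 annotated genes' tags at
the transcriptome stage, and exactly the 3 tags planted in hidden
intergenic genes survive, each with a usable primer:

```r
subset(cascade$records, final,
       select = c(tag, chrom, start0, strand, count, gc, primer))
#>                     tag chrom start0 strand count       gc              primer
#> 1 CATGTCATTCGGATCATTCAC  chr1   1607      +     7 42.85714 GTGAATGATCCGAATGACA
#> 3 CATGTGGTCGTCTTCTTTGTA  chr1   5015      +    17 42.85714 TACAAAGAAGACGACCACA
#> 4 CATGTACCTCAAAGAAGCCTA  chr1   6072      -    12 42.85714 TAGGCTTCTTTGAGGTACA

results <- stace_classify(file.path(dir, "genome.fasta"),
                          file.path(dir, "annotations.gff3"),
                          file.path(dir, "amplicons.fasta"),
                          out_dir = file.path(dir, "classify"))
results[, c("id", "sl1_found", "polya_found", "true_positive", "category")]
#>             id sl1_found polya_found true_positive   category
#> 1   novel02.up      TRUE       FALSE          TRUE novel_gene
#> 2 novel02.down     FALSE        TRUE          TRUE novel_gene
#> 3   novel01.up      TRUE       FALSE          TRUE novel_gene
#> 4 novel01.down     FALSE        TRUE          TRUE novel_gene
#> 5   novel03.up      TRUE       FALSE          TRUE novel_gene
#> 6 novel03.down     FALSE        TRUE          TRUE novel_gene

print(attr(results, "models")[[1]])
#> stace_model: chr1(+), 3 exon(s), full-length
```

Every amplicon is a true positive (its alignment span covers its tag), every
pair assembles into a model whose exon coordinates equal the planted gene's,
and all inferred introns carry canonical GT–AG signals.

The package also ships transcriptions of the original *C. elegans* screen's
published results (`stace_published_cdnas()`, `stace_published_outcomes()`,
`stace_published_funnels()`) as reference fixtures for the true-positive
containment rule, the SL1+polyA full-length rule, and the success-rate
arithmetic.

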
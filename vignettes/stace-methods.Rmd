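---
title: "Screening SAGE tags for novel genes and reconstructing cDNA ends with stacer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening SAGE tags for novel genes and reconstructing cDNA ends with stacer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stacer)
```

## The problem

Gene catalogues of even intensively curated genomes are incomplete: gene
predictors miss loci, and rare or stage-specific transcripts are
under-represented in cDNA sequencing. Serial analysis of gene expression
(SAGE) offers an orthogonal signal. Each (long)SAGE tag is a 21 bp sequence
anchored at the 3'-most NlaIII site (CATG) of a transcript, counted across
libraries. A tag that maps cleanly to the genome but matches no annotated
transcript is direct expression evidence for something missing from the
annotation.

STACE (sequence tag-based amplification of cDNA ends) turns such tags into
full-length cDNA models. Three primer sites are used: the SL1 trans-spliced
leader found at the extreme 5' end of roughly half of all *C. elegans*
mRNAs, a universal 3' site attached during reverse transcription with a
modified oligo d(T) primer, and a gene-specific primer derived from the tag
itself. Two PCRs recover an upstream amplicon (SL1 primer + tag primer) and
a downstream amplicon (tag primer + universal primer); their spliced genomic
alignments overlap at the tag and merge into a transcript model. `stacer`
implements the computational half of this workflow plus a fully synthetic
test-bed; the wet-lab half (RT, PCR, cloning, sequencing) is out of scope.

## The tag screen

`run_cascade()` filters a tag library in a fixed order, each stage evaluated
only for tags that passed all earlier ones, so the funnel of survivor counts
is non-increasing by construction:

1. **Mappability.** Exact, full-length, ungapped matching on both genome
   strands (`map_tag()`). Only uniquely mapping tags proceed: a multi-mapped
   tag cannot anchor a gene-specific primer, and an unmapped one is
   uninterpretable. There is no mismatch rescue; sequencing errors are
   handled by the frequency filter instead. `keep_multi = TRUE` retains
   multi-mapped tags for inspection only.
2. **Transcriptome exclusion.** A tag fails if its interval overlaps any
   annotated exon of any biotype, or if the tag (or its reverse complement)
   occurs in any spliced transcript of the virtual transcriptome
   (`build_virtual_transcriptome()`). The substring test documents the
   exon-exon junction case even though such tags already fail mappability.
   Treating *all* exons (including UTRs, pseudogenes, ncRNAs) as excluded
   is the stricter reading of "coding exon" and is the default.
3. **Frequency.** At least 3 tags per 100,000 reads, inclusive
   ("at least three"), computed as `count * 1e5 / library_size`. When
   several libraries are involved the filter is naturally applied per
   library before `merge_libraries()`; both routes are available.
4. **Position.** No overlap with any annotated intron (an intronic tag more
   likely flags a missing exon than a novel gene), and at least 500 bp from
   any annotated 5' or 3' gene boundary, measured edge-to-edge between the
   tag interval and the outermost gene span across the gene's transcripts
   (the conservative reading of "gene boundary"). Whether ncRNA/pseudogene
   loci count as boundaries is not specified anywhere we know of; the
   default includes all biotypes, restrictable via `boundary_biotypes`.
5. **GC content.** Between 35% and 45% on the full untrimmed tag. Bounds
   are inclusive; "between" is ambiguous, and inclusivity matches the "at
   least" phrasing style of the other thresholds.
6. **Primer derivation.** The tag must yield an acceptable primer
   (`derive_primer()`, below).

Stage order matters to the per-stage counts but never to the survivor set:
the filters are independent predicates of a tag, which `run_cascade()`
exposes via `stage_order` and the test suite asserts under permutation.

## Primer derivation

The gene-specific primer is the reverse complement of the tag, optionally
after trimming up to 4 bases total off the two tag ends (result length at
least 17 nt). All admissible `(left, right)` trims are enumerated; the
candidate with minimal total trim wins, ties broken by the smaller left
trim, so results are fully deterministic. Each candidate must pass:

* GC within [35, 45]%;
* melting temperature within [55, 65] degrees C, bracketing the protocol's
  60 degree annealing step;
* no hairpin with a stem of 4+ reverse-complementary bases around a loop of
  3+ bases (`hairpin_score()`);
* no homodimer, and no heterodimer against the fixed SL1 and universal
  primers: no antiparallel complementary run of 5+ bases, tightened to 3+
  when the run includes either 3' terminus, since 3'-anchored duplexes
  prime extension (`dimer_score()`).

These are explicit, documented heuristics, not a wrapper around an external
design program; every threshold is surfaced in `primer_constraints()`.

One consequence worth knowing: an untrimmed tag primer always ends in CATG
(the reverse complement of the tag's anchor), and CATG is its own reverse
complement, so two copies of such a primer pair over their last four bases
-- a 3'-anchored homodimer run of 4, which the tightened 3' threshold
flags. Under the default constraints the search therefore always trims at
least one base from the tag's anchor side, producing 19-20 nt primers that
do not end in the full CATG. The trimmed, non-CATG-terminal primers of the
original screen's final (fully filtered) set have exactly this shape, while
its earlier, more permissively screened sets retained 21 nt CATG-terminal
primers; loosen `dimer_min_run` to reproduce those.

`tm_estimate()` uses SantaLucia (1998) unified nearest-neighbor
thermodynamics with duplex-initiation terms, at PCR-like conditions: 50 mM
monovalent cation, 1.5 mM Mg2+ with 0.6 mM dNTP folded into an equivalent
monovalent concentration by the conventional `120 * sqrt([Mg] - [dNTP])`
term, and 250 nM oligo. The divalent term matters: at 50 mM monovalent
alone, 17-21-mers at 35-45% GC melt around 44-56 degrees and the [55, 65]
window would be nearly unreachable, whereas under PCR-like salt the window
is exactly where such primers sit (the three published 19-21 nt primers we
can evaluate land at 55.3-57.2 degrees). The classical Wallace rule
`2(A+T) + 4(G+C)` (`tm_wallace()`) tracks the estimate within a few degrees
at primer lengths and serves as a coarse cross-check in the tests; it
substantially overestimates very short AT-rich oligos (an all-A/T 8-mer
melts near 0 degrees by nearest-neighbor thermodynamics, not 16), so the
cross-check is asserted only at primer-realistic lengths.

## Amplicon interpretation

`detect_and_strip_sl1()` calls the SL1 leader when a suffix of the 22 nt
leader of 12+ bases prefixes the read exactly; `detect_and_strip_polya()`
strips the 3' adapter (the reverse complement of the universal primer,
full or a truncated prefix of 8+ bases) and then requires a terminal A-run
of 10+ bases. The minima are conservative defaults against chance matches
(a 12-base exact match arises by chance once per ~17 Mb) and are
configurable.

`align_amplicon()` is a purpose-built spliced aligner for toy-scale
genomes: greedy maximal exact seeding (18 bp seeds) and left-to-right
chaining, requiring full read coverage on one chromosome and strand, with
inter-block gaps of at least 30 bp treated as introns. Because an exact
chain can place a junction anywhere within a repeated context, junctions
are slid to the sequence-equivalent placement whose intron starts GT and
ends AG on the transcribed strand when one exists. By default alignment is
exact; `max_mismatch` tolerates isolated substitutions inside blocks.
Real screens use BLAT or similar; externally produced spliced alignments
enter through `read_alignments_bed12()` / `read_alignments_psl()` and flow
through the identical downstream logic.

A result is a **true positive** when the closed genomic span between the
amplicon's outermost mapping boundaries intersects the tag interval used to
design its primer. The span uses min/max of the two boundaries, making the
rule orientation-agnostic (minus-strand results report their 5' coordinate
numerically greater than the 3' one). True positives are categorised
against the annotation by 1 bp or more of exon-block overlap with gene
spans: overlap with a pseudogene or ncRNA is `non_coding_overlap`,
otherwise overlap with any gene is `annotation_extension` (the amplicon
necessarily adds structure, since its tag matched no annotated transcript),
otherwise `novel_gene`. Non-coding overlap takes precedence when both a
coding and a non-coding gene overlap; that tie-break is this package's
documented decision -- the original screen's precedence was never stated,
but its pseudogene-overlap call is consistent with it.

`assemble_full_length()` merges an upstream and a downstream alignment for
one tag when they lie on one chromosome and strand, their genomic overlap
contains the tag interval, and their exon chains agree exactly over that
overlap; disagreement rejects the merge with a diagnostic rather than
guessing. A model is **full-length** iff the upstream read carried SL1
evidence and the downstream read polyA evidence; an upstream-only model is
a partial (5'-complete) model.

GT-AG validation (`check_splice_signals()`) labels introns, it never
rejects them: non-canonical signals are reported for inspection.

## The synthetic test-bed

`stace_simulate()` builds a deterministic toy study from one seed: by
default 2 chromosomes of 30 kb, 6 annotated protein-coding genes plus one
pseudogene and one ncRNA, and 3 *hidden* novel genes present in the
sequence and the tag library but absent from the emitted GFF3. Genes have
1-4 exons (novel genes 2-3, so spliced alignment is always exercised),
exons of 90-250 bp, introns of 45-200 bp built GT..AG, and gene spans
separated by at least 700 bp so planted tags clear the 500 bp boundary rule
with margin. Every transcript carries an engineered tag -- CATG plus 17
bases at 35-45% GC, kept the 3'-most anchor by scrubbing CATG from the
downstream tail -- and hidden genes' tag regions are rejection-sampled
until `derive_primer()` accepts them, so the ground-truth qualifying set is
qualifying *by construction*. The generator asserts (rather than silently
repairs) that every planted tag occurs exactly once in the genome and in no
other transcript. Expression counts are exact (novel genes 5-20 counts
against a 100,000-read library, safely above the frequency threshold);
substitution-error reads appear as distinct low-count noise tags
constructed to stay below the threshold. Amplicon pairs follow the two-PCR
design: SL1 + transcript-through-tag upstream, tag-through-3'-end + polyA +
adapter downstream.

What passing tests show -- and what they do not: the generator emulates the
*logic* of the screen (anchoring, splicing, trans-splicing,
polyadenylation, error tags), not the statistics of real data. Real
genomes have repeats that multi-map tags, biased base composition,
alternative isoforms, incomplete annotations in the annotated fraction,
and alignment ambiguity that BLAT resolves heuristically. Recovery rates
of 1 on this test-bed validate the implementation, not the biology; the
published screen's own yield was 12 candidate cDNAs from 144 primers.

Because the primer screen participates in the generator's rejection
sampling, the planted-recovery test checks the mapping, transcriptome,
frequency and position logic end-to-end but shares the primer predicate
with the generator by construction; the primer screen itself is instead
validated against exhaustive oracles in its own tests.

## Numerical and interface conventions

* Coordinates are 0-based half-open internally, 1-based inclusive in every
  file and report (GFF3/browser convention).
* Funnel reports carry the seven computable stages (total through
  primer-ready); the published tables' final column (primers actually
  tested) reflects an experimental choice, not a computation, and is not a
  funnel stage.
* Reference success rates are reproduced with round-half-away-from-zero
  percentages, which matches every published per-set figure.
* One published cDNA record prints a 5' boundary inconsistent with its
  chromosome arm (a typographical artifact); the packaged fixture stores it
  as `NA` and containment tests substitute the tag-side coordinate, which
  is the conservative direction (it can only shrink the span).
* Absolute funnel counts of the original study are not reproducible here --
  they require the WS160 genome and the original SAGE libraries -- and are
  used only as a monotonicity reference.
* Problem sizes in the packaged tests (30 kb x 2 chromosomes, ~1,000-tag
  mapper batteries) were chosen as the smallest scales at which every
  code path (multi-exon splicing, both strands, multi-chromosome indexing,
  noise tags) is exercised.

## Limitations

No thermodynamic structure folding (hairpin/dimer screens are
longest-complementary-run heuristics); no mismatch-tolerant tag mapping; the
built-in aligner assumes near-exact reads on toy-scale genomes; operons and
trans-spliced variants beyond SL1, alternative references, and GTF/GFF2
dialects are unsupported; ORF or coding-potential assessment of recovered
models is out of scope.
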
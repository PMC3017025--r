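#' Published STACE results from the original *C. elegans* screen
#'
#' Accessors for the packaged transcriptions of the original *C. elegans*
#' (WS160) STACE screen's published result tables, used as reference
#' fixtures.
#'
#' `stace_published_cdnas()` returns the 14 SL1-trans-spliced cDNA
#' sequences the screen identified: for each, the tag primer, the tag's
#' genomic location, the amplicon's 5' and 3' genomic mapping boundaries
#' (1-based; on minus-strand results the 5' coordinate exceeds the 3' one),
#' the full-length/partial label, and SL1/polyA evidence flags. One record
#' (2.2) prints a 5' boundary incompatible with its chromosome-arm
#' neighbourhood -- a typographical artifact -- which is stored as `NA`;
#' containment tests substitute the tag-side coordinate for it.
#'
#' `stace_published_outcomes()` returns the per-set result classifications
#' (novel genes, annotation extensions, non-protein-coding overlaps) and the
#' number of tag primers tested per set.
#'
#' `stace_published_funnels()` returns the per-set screening funnel counts
#' of the original study; these absolute numbers depend on the WS160 genome
#' and the original SAGE libraries and are packaged only for
#' shape/monotonicity checks.
#'
#' @return A data frame.
#' @export
stace_published_cdnas <- function() {
  utils::read.delim(system.file("extdata", "celegans_stace_cdnas.tsv",
                                package = "stacer"),
                    stringsAsFactors = FALSE)
}

#' @rdname stace_published_cdnas
#' @export
stace_published_outcomes <- function() {
  utils::read.delim(system.file("extdata", "celegans_stace_outcomes.tsv",
                                package = "stacer"),
                    stringsAsFactors = FALSE)
}

#' @rdname stace_published_cdnas
#' @export
stace_published_funnels <- function() {
  utils::read.delim(system.file("extdata", "celegans_stace_funnels.tsv",
                                package = "stacer"),
                    stringsAsFactors = FALSE)
}

#' True-positive containment over a table of cDNA alignment records
#'
#' Applies the orientation-agnostic span/tag containment rule
#' ([span_overlaps_tag()]) to each record of a table shaped like
#' [stace_published_cdnas()]. A missing boundary (`NA`) is replaced by the
#' tag-side coordinate, so the span degrades gracefully to the interval
#' between the tag and the remaining boundary. The tag interval length is
#' the record's primer length.
#'
#' @param cdnas Data frame with columns `tag_chrom`, `tag_pos`, `primer`,
#'   `bound5_chrom`, `bound5_pos`, `bound3_chrom`, `bound3_pos`.
#' @return Logical vector, one element per record.
#' @export
containment_true_positives <- function(cdnas = stace_published_cdnas()) {
  vapply(seq_len(nrow(cdnas)), function(i) {
    r <- cdnas[i, ]
    b5 <- if (is.na(r$bound5_pos)) r$tag_pos else r$bound5_pos
    b3 <- if (is.na(r$bound3_pos)) r$tag_pos else r$bound3_pos
    c5 <- if (is.na(r$bound5_pos)) r$tag_chrom else r$bound5_chrom
    if (c5 != r$bound3_chrom) return(FALSE)
    span_overlaps_tag(c5, b5, b3, r$tag_chrom, r$tag_pos, nchar(r$primer))
  }, logical(1L))
}

#' Full-length calls from SL1/polyA evidence
#'
#' A reconstructed cDNA is full-length iff it carries the SL1 leader at the
#' 5' end AND polyadenylation at the 3' end.
#'
#' @param cdnas Data frame with logical columns `sl1_evidence`,
#'   `polya_evidence`.
#' @return Logical vector.
#' @export
full_length_calls <- function(cdnas = stace_published_cdnas()) {
  cdnas$sl1_evidence & cdnas$polya_evidence
}

#' Per-set and overall STACE success rates
#'
#' Candidate cDNAs per set are the sum of the three result categories;
#' the success rate is candidates over primers tested, in percent, rounded
#' half away from zero (matching how the published per-set percentages were
#' derived). A `total` row is appended.
#'
#' @param outcomes Data frame shaped like [stace_published_outcomes()].
#' @return Data frame: `set`, `candidates`, `primers_tested`, `percent`.
#' @export
stace_success_rates <- function(outcomes = stace_published_outcomes()) {
  cand <- outcomes$novel_genes + outcomes$annotation_extensions +
    outcomes$noncoding_overlaps
  df <- data.frame(set = outcomes$set, candidates = cand,
                   primers_tested = outcomes$primers_tested,
                   stringsAsFactors = FALSE)
  df <- rbind(df, data.frame(set = "total", candidates = sum(cand),
                             primers_tested = sum(outcomes$primers_tested),
                             stringsAsFactors = FALSE))
  df$percent <- round_half_away(100 * df$candidates / df$primers_tested)
  df
}
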
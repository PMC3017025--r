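#' Screening parameters for the candidate-tag cascade
#'
#' Collects every threshold of the tag screen with its published default:
#' minimum normalized frequency 3 per 100,000 reads (inclusive), minimum
#' distance 500 bp from any annotated 5'/3' gene boundary, GC content within
#' \[35, 45\]% (inclusive bounds), plus the primer-derivation constraints.
#'
#' @param min_freq Minimum tags per 100,000 reads (inclusive).
#' @param min_boundary_dist Minimum distance (bp) from annotated gene spans.
#' @param gc_min,gc_max GC bounds in percent, inclusive.
#' @param boundary_biotypes Gene biotypes whose boundaries count for the
#'   distance rule (`NULL` = all annotated genes, the conservative default).
#' @param keep_multi Keep multi-mapped tags for inspection instead of failing
#'   them at the mappability stage (default `FALSE`).
#' @param primer Primer constraints, see [primer_constraints()].
#' @return A `stace_params` list.
#' @export
stace_params <- function(min_freq = 3, min_boundary_dist = 500,
                         gc_min = 35, gc_max = 45,
                         boundary_biotypes = NULL, keep_multi = FALSE,
                         primer = primer_constraints()) {
  structure(list(min_freq = min_freq, min_boundary_dist = min_boundary_dist,
                 gc_min = gc_min, gc_max = gc_max,
                 boundary_biotypes = boundary_biotypes,
                 keep_multi = keep_multi, primer = primer),
            class = "stace_params")
}

verdict_pass <- "pass"
verdict_na <- "not_evaluated"
verdict_fail <- function(reason) paste0("fail:", reason)
is_pass <- function(v) v == verdict_pass

#' Transcriptome-exclusion filter
#'
#' Fails a uniquely mapped tag that (a) overlaps any annotated exon of any
#' biotype, or (b) occurs (directly or reverse-complemented) as a substring
#' of any virtual transcript -- the latter catches tags spanning exon-exon
#' junctions, which never map to the genome contiguously but still derive
#' from known transcripts.
#'
#' @param tag Tag sequence.
#' @param chrom,start0,end0 The tag's unique genomic mapping (internal
#'   coordinates).
#' @param vt Virtual transcriptome ([build_virtual_transcriptome()]).
#' @param annotation A `stace_annotation`.
#' @return `"pass"` or `"fail:<reason>"`.
#' @export
filter_non_transcriptome <- function(tag, chrom, start0, end0, vt,
                                     annotation) {
  if (overlaps_any(annotation$exons, chrom, start0, end0)) {
    return(verdict_fail("exon_overlap"))
  }
  if (length(vt) > 0L) {
    n <- sum(Biostrings::vcountPattern(tag, vt, fixed = TRUE)) +
      sum(Biostrings::vcountPattern(revcomp(tag), vt, fixed = TRUE))
    if (n > 0L) return(verdict_fail("transcriptome_hit"))
  }
  verdict_pass
}

#' Expression-frequency filter
#'
#' Tags below `min_freq` per 100,000 reads are likely sequencing errors and
#' are discarded; the comparison is inclusive ("at least three").
#'
#' @param count Raw count.
#' @param library_size Sequencing total.
#' @param min_freq Threshold (default 3 per 100,000).
#' @return `"pass"` or `"fail:low_frequency"`.
#' @export
filter_frequency <- function(count, library_size, min_freq = 3) {
  if (normalized_frequency(count, library_size) >= min_freq) verdict_pass
  else verdict_fail("low_frequency")
}

#' Positional filter
#'
#' Fails tags overlapping any annotated intron (they more likely flag a
#' missing exon than a novel gene) and tags closer than `min_dist` bp to any
#' annotated 5' or 3' gene boundary, measured from the tag interval's nearest
#' edge to the gene span's nearest edge.
#'
#' @inheritParams filter_non_transcriptome
#' @param min_dist Minimum boundary distance in bp (default 500).
#' @param biotypes Restrict boundary genes to these biotypes (`NULL` = all).
#' @return `"pass"` or `"fail:<intron|near_boundary>"`.
#' @export
filter_position <- function(chrom, start0, end0, annotation, min_dist = 500,
                            biotypes = NULL) {
  if (overlaps_any(annotation$introns, chrom, start0, end0)) {
    return(verdict_fail("intron"))
  }
  d <- distance_to_nearest_gene_boundary(annotation, chrom, start0, end0,
                                         biotypes = biotypes)
  if (d < min_dist) verdict_fail("near_boundary") else verdict_pass
}

#' GC-content filter
#'
#' Primers amplify reliably from moderately GC-balanced templates; the
#' screen keeps tags with GC between `gc_min` and `gc_max` percent, bounds
#' inclusive, evaluated on the full (untrimmed) tag.
#'
#' @param tag Tag sequence.
#' @param gc_min,gc_max Bounds in percent.
#' @return `"pass"` or `"fail:gc_content"`.
#' @export
filter_gc <- function(tag, gc_min = 35, gc_max = 45) {
  gc <- gc_content(tag)
  if (gc >= gc_min && gc <= gc_max) verdict_pass
  else verdict_fail("gc_content")
}

cascade_stages <- c("mappable", "non_transcriptome", "frequency_ok",
                    "position_ok", "gc_ok", "primerable")

#' Run the candidate-tag filter cascade
#'
#' Executes the screen in its fixed order -- mappability, transcriptome
#' exclusion, frequency, position, GC, primer derivation -- over a tag
#' library, and returns per-tag records plus the funnel of per-stage
#' survivor counts. A tag is counted at a stage only if it passed all
#' earlier stages; stages after a failure are marked `not_evaluated`.
#'
#' @param library A `stace_tag_library`.
#' @param genome A `stace_genome`.
#' @param annotation A `stace_annotation`.
#' @param params A [stace_params()] object.
#' @param vt Virtual transcriptome; built from the annotation when `NULL`.
#' @param stage_order Order in which the five post-mappability filters are
#'   applied (mappability is always first since later filters need the
#'   unique mapping). Permuting it changes per-stage counts but never the
#'   final survivor set.
#' @return A `stace_cascade`: list with `records` (data frame: tag, count,
#'   norm_freq, mapping, GC, per-stage verdicts, `final`, derived primer) and
#'   `funnel` (data frame `stage`, `count`, non-increasing).
#' @export
run_cascade <- function(library, genome, annotation,
                        params = stace_params(), vt = NULL,
                        stage_order = c("non_transcriptome", "frequency_ok",
                                        "position_ok", "gc_ok",
                                        "primerable")) {
  stopifnot(inherits(library, "stace_tag_library"),
            setequal(stage_order, cascade_stages[-1L]))
  if (is.null(vt)) vt <- build_virtual_transcriptome(genome, annotation)
  tags <- library$tags
  n <- nrow(tags)
  k <- library$tag_length

  rec <- data.frame(tag = tags$tag, count = tags$count,
                    norm_freq = if (n) normalized_frequency(
                      tags$count, library$library_size) else numeric(0),
                    chrom = rep(NA_character_, n),
                    start0 = rep(NA_integer_, n),
                    strand = rep(NA_character_, n),
                    gc = if (n) gc_content(tags$tag) else numeric(0),
                    stringsAsFactors = FALSE)
  for (s in cascade_stages) rec[[s]] <- rep(verdict_na, n)
  rec$primer <- rep(NA_character_, n)
  rec$primer_tm <- rep(NA_real_, n)
  rec$trim_left <- rep(NA_integer_, n)
  rec$trim_right <- rep(NA_integer_, n)

  if (n > 0L) {
    index <- build_tag_index(genome, k)
    mp <- classify_mappability(tags$tag, index)
    for (i in seq_len(n)) {
      st <- mp$status[[tags$tag[i]]]
      keep <- st == "unique" || (params$keep_multi && st == "multi")
      rec$mappable[i] <- if (keep) verdict_pass else
        verdict_fail(if (st == "unmapped") "unmapped" else "multi_mapped")
      if (!is_pass(rec$mappable[i])) next
      m <- mp$mappings[mp$mappings$tag == tags$tag[i], , drop = FALSE][1L, ]
      rec$chrom[i] <- m$chrom
      rec$start0[i] <- m$start0
      rec$strand[i] <- m$strand

      for (s in stage_order) {
        v <- switch(
          s,
          non_transcriptome = filter_non_transcriptome(
            tags$tag[i], m$chrom, m$start0, m$start0 + k, vt, annotation),
          frequency_ok = filter_frequency(tags$count[i], library$library_size,
                                          params$min_freq),
          position_ok = filter_position(m$chrom, m$start0, m$start0 + k,
                                        annotation, params$min_boundary_dist,
                                        params$boundary_biotypes),
          gc_ok = filter_gc(tags$tag[i], params$gc_min, params$gc_max),
          primerable = {
            pc <- derive_primer(tags$tag[i], params$primer)
            if (is.null(pc)) verdict_fail("no_primer") else {
              rec$primer[i] <- pc$primer
              rec$primer_tm[i] <- pc$tm
              rec$trim_left[i] <- pc$trim_left
              rec$trim_right[i] <- pc$trim_right
              verdict_pass
            }
          })
        rec[[s]][i] <- v
        if (!is_pass(v)) break
      }
    }
  }
  rec$final <- Reduce(`&`, lapply(cascade_stages, function(s) is_pass(rec[[s]])),
                      rep(TRUE, n))

  counts <- c(total = n)
  surviving <- rep(TRUE, n)
  for (s in c("mappable", stage_order)) {
    surviving <- surviving & is_pass(rec[[s]])
    counts[s] <- sum(surviving)
  }
  ## funnel reported in canonical cascade order regardless of stage_order
  funnel <- data.frame(stage = c("total", "mappable", stage_order),
                       count = as.integer(counts), stringsAsFactors = FALSE)
  structure(list(records = rec, funnel = funnel, params = params),
            class = "stace_cascade")
}

#' @export
print.stace_cascade <- function(x, ...) {
  cat("stace_cascade funnel:\n")
  print(x$funnel, row.names = FALSE)
  invisible(x)
}

#' Write cascade outputs
#'
#' Candidate TSV (tag, 1-based location, counts, GC, per-stage verdicts,
#' primer), BED6 of surviving tag intervals, and the funnel TSV.
#'
#' @param cascade A `stace_cascade`.
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix.
#' @return Named character vector of written paths, invisibly.
#' @export
write_cascade <- function(cascade, dir, prefix = "candidates") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rec <- cascade$records
  out <- rec
  out$start <- out$start0 + 1L
  out$start0 <- NULL
  cand_path <- file.path(dir, paste0(prefix, ".tsv"))
  utils::write.table(out, cand_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  surv <- rec[rec$final, , drop = FALSE]
  bed_path <- file.path(dir, paste0(prefix, ".bed"))
  bed <- data.frame(chrom = surv$chrom, start = surv$start0,
                    end = surv$start0 + nchar(surv$tag), name = surv$tag,
                    score = surv$count, strand = surv$strand)
  utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  funnel_path <- file.path(dir, "funnel.tsv")
  utils::write.table(cascade$funnel, funnel_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(candidates = cand_path, bed = bed_path, funnel = funnel_path))
}
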
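#' Detect and strip the SL1 trans-spliced leader
#'
#' In *C. elegans* the 22-nt SL1 leader is trans-spliced onto the extreme 5'
#' end of about half of all mRNAs; finding it at the start of an amplicon
#' read is 5'-completeness evidence. The leader is detected when a suffix of
#' the SL1 sequence of at least `min_sl1` bases is an exact prefix of the
#' read (amplicons primed inside the leader start mid-SL1).
#'
#' @param read Amplicon sequence in mRNA sense.
#' @param min_sl1 Minimum matching SL1 suffix length (default 12).
#' @return List: `read` (leader removed when found), `sl1_found`.
#' @export
detect_and_strip_sl1 <- function(read, min_sl1 = 12L) {
  read <- toupper(read)
  sl1 <- stace_fixed_primers()$sl1
  for (l in nchar(sl1):min_sl1) {
    suf <- substr(sl1, nchar(sl1) - l + 1L, nchar(sl1))
    if (startsWith(read, suf)) {
      return(list(read = substr(read, l + 1L, nchar(read)), sl1_found = TRUE))
    }
  }
  list(read = read, sl1_found = FALSE)
}

#' Detect and strip the polyA tail (and 3' adapter)
#'
#' Strips an optional 3' adapter -- the reverse complement of the universal
#' primer region introduced by the modified oligo d(T) RT primer -- then
#' requires a terminal A-run of at least `min_a` bases as polyadenylation
#' evidence. A truncated adapter (a prefix of at least `min_adapter` bases)
#' is also recognised.
#'
#' @param read Amplicon sequence in mRNA sense.
#' @param min_a Minimum terminal A-run (default 10).
#' @param min_adapter Minimum recognisable adapter prefix (default 8).
#' @return List: `read` (tail/adapter removed when found), `polya_found`.
#' @export
detect_and_strip_polya <- function(read, min_a = 10L, min_adapter = 8L) {
  read <- toupper(read)
  adapter <- revcomp(stace_fixed_primers()$universal)
  for (l in nchar(adapter):min_adapter) {
    pre <- substr(adapter, 1L, l)
    if (endsWith(read, pre)) {
      read <- substr(read, 1L, nchar(read) - l)
      break
    }
  }
  m <- regmatches(read, regexpr("A+$", read))
  run <- if (length(m)) nchar(m) else 0L
  if (run >= min_a) {
    list(read = substr(read, 1L, nchar(read) - run), polya_found = TRUE)
  } else {
    list(read = read, polya_found = FALSE)
  }
}

new_alignment <- function(id, chrom, strand, blocks, mismatches = 0L) {
  blocks <- blocks[order(blocks$start0), , drop = FALSE]
  rownames(blocks) <- NULL
  structure(list(id = id, chrom = chrom, strand = strand, blocks = blocks,
                 mismatches = mismatches),
            class = "stace_alignment")
}

#' @export
print.stace_alignment <- function(x, ...) {
  cat(sprintf("stace_alignment %s: %s(%s), %d block(s), span %d-%d\n",
              x$id, x$chrom, x$strand, nrow(x$blocks),
              min(x$blocks$start0) + 1L, max(x$blocks$end0)))
  invisible(x)
}

## genomic span of an alignment, 1-based closed
alignment_span <- function(aln) {
  c(start = min(aln$blocks$start0) + 1L, end = max(aln$blocks$end0))
}

## exact (or <= max_mismatch substitutions) chain of read blocks along one
## chromosome from one seed position; returns blocks df or NULL
chain_from <- function(rb, subj, g0, min_intron, max_intron, max_mismatch,
                       seed_len, subj_str) {
  n <- length(rb)
  blocks <- list()
  rpos <- 1L
  gpos <- g0
  block_g <- g0
  mm <- 0L
  glen <- length(subj)
  repeat {
    while (rpos <= n && gpos <= glen && subj[gpos] == rb[rpos]) {
      rpos <- rpos + 1L
      gpos <- gpos + 1L
    }
    if (rpos > n) {
      blocks[[length(blocks) + 1L]] <- c(block_g, gpos)
      break
    }
    ## substitution? require the next few bases to keep matching
    look <- min(5L, n - rpos, glen - gpos)
    if (mm < max_mismatch && gpos <= glen && look > 0L &&
        all(subj[(gpos + 1L):(gpos + look)] == rb[(rpos + 1L):(rpos + look)])) {
      mm <- mm + 1L
      rpos <- rpos + 1L
      gpos <- gpos + 1L
      next
    }
    ## close the block and look for the next exon downstream
    if (gpos == block_g) return(NULL)   # zero-length block: seed was wrong
    blocks[[length(blocks) + 1L]] <- c(block_g, gpos)
    remaining <- n - rpos + 1L
    if (remaining < 8L) return(NULL)
    s2len <- min(seed_len, remaining)
    seed2 <- paste(rb[rpos:(rpos + s2len - 1L)], collapse = "")
    from <- gpos - 1L + min_intron          # 0-based genomic lower bound
    to <- min(glen, gpos - 1L + max_intron + remaining)
    if (from + s2len > to) return(NULL)
    window <- substr(subj_str, from + 1L, to)
    hit <- str_find_all(seed2, window)
    if (length(hit) == 0L) return(NULL)
    block_g <- from + hit[1L]               # back to 1-based chromosome pos
    gpos <- block_g
  }
  df <- do.call(rbind, blocks)
  data.frame(start0 = df[, 1L] - 1L, end0 = df[, 2L] - 1L)
}

## slide each junction so the intron starts GT and ends AG on the
## transcribed strand, when an equivalent placement exists
adjust_junctions <- function(blocks, subj_str, strand, max_shift = 12L) {
  if (nrow(blocks) < 2L) return(blocks)
  canonical <- function(i_start0, i_end0) {
    don <- substr(subj_str, i_start0 + 1L, i_start0 + 2L)
    acc <- substr(subj_str, i_end0 - 1L, i_end0)
    if (strand == "+") don == "GT" && acc == "AG"
    else don == "CT" && acc == "AC"   # GT..AG on the minus strand
  }
  for (b in seq_len(nrow(blocks) - 1L)) {
    e1 <- blocks$end0[b]          # current intron [e1, s2)
    s2 <- blocks$start0[b + 1L]
    if (canonical(e1, s2)) next
    found <- NA_integer_
    for (d in order(abs(seq(-max_shift, max_shift)))) {
      delta <- seq(-max_shift, max_shift)[d]
      if (delta == 0L) next
      ## shifting the junction by delta is sequence-equivalent iff the
      ## delta bases entering one exon equal those leaving the other
      ok <- if (delta > 0L) {
        substr(subj_str, e1 + 1L, e1 + delta) ==
          substr(subj_str, s2 + 1L, s2 + delta)
      } else {
        substr(subj_str, e1 + delta + 1L, e1) ==
          substr(subj_str, s2 + delta + 1L, s2)
      }
      feasible <- blocks$end0[b] + delta > blocks$start0[b] &&
        blocks$start0[b + 1L] + delta < blocks$end0[b + 1L]
      if (ok && feasible && canonical(e1 + delta, s2 + delta)) {
        found <- delta
        break
      }
    }
    if (!is.na(found)) {
      blocks$end0[b] <- e1 + found
      blocks$start0[b + 1L] <- s2 + found
    }
  }
  blocks
}

#' Align an amplicon read to a toy-scale genome
#'
#' Exact spliced alignment by maximal-exact-match seeding and left-to-right
#' chaining: the read must be fully covered by ungapped blocks on one
#' chromosome and strand, separated by gaps of at least `min_intron` bp
#' (inferred introns). Junctions are preferentially placed so introns start
#' GT and end AG on the transcribed strand whenever an equivalent placement
#' exists. With `max_mismatch > 0`, up to that many isolated substitutions
#' are tolerated inside blocks; the default is exact.
#'
#' This is a purpose-built aligner for the package's toy genomes; externally
#' produced spliced alignments (BED12/PSL) can be ingested instead via
#' [read_alignments_bed12()] / [read_alignments_psl()].
#'
#' @param read Amplicon sequence (already SL1/polyA-stripped), mRNA sense.
#' @param genome A `stace_genome` (intended for genomes up to ~10 Mb).
#' @param id Alignment identifier.
#' @param min_intron Minimum inferred intron length (default 30).
#' @param max_intron Maximum inferred intron length (default 25000).
#' @param max_mismatch Substitution budget (default 0).
#' @param seed_len Seed length for block anchoring (default 18).
#' @return A `stace_alignment`, or `NULL` when no full-coverage chain exists.
#' @export
align_amplicon <- function(read, genome, id = "amplicon", min_intron = 30L,
                           max_intron = 25000L, max_mismatch = 0L,
                           seed_len = 18L) {
  read <- toupper(read)
  if (nchar(read) < seed_len) seed_len <- nchar(read)
  for (strand in c("+", "-")) {
    r <- if (strand == "+") read else revcomp(read)
    rb <- strsplit(r, "")[[1L]]
    seed <- substr(r, 1L, seed_len)
    for (chrom in names(genome$seqs)) {
      subj_str <- as.character(genome$seqs[[chrom]])
      starts <- str_find_all(seed, subj_str)
      if (length(starts) == 0L) next
      subj <- strsplit(subj_str, "")[[1L]]
      for (g0 in starts) {
        blocks <- chain_from(rb, subj, g0, min_intron, max_intron,
                             max_mismatch, seed_len, subj_str)
        if (!is.null(blocks)) {
          blocks <- adjust_junctions(blocks, subj_str, strand)
          return(new_alignment(id, chrom, strand, blocks))
        }
      }
    }
  }
  NULL
}

#' True-positive test for a STACE amplicon
#'
#' An amplicon alignment is a true positive when its genomic span -- the
#' closed interval between its outermost 5' and 3' mapping boundaries,
#' orientation-agnostic (min/max of the two, since minus-strand results list
#' 5' > 3') -- intersects the interval of the tag used to design its primer.
#' A different chromosome is simply `FALSE`, not an error.
#'
#' @param chrom,bound5,bound3 Alignment chromosome and its 5'/3' mapping
#'   boundaries (1-based, either order).
#' @param tag_chrom,tag_start Tag chromosome and 1-based start.
#' @param tag_length Tag interval length (the tag length used for that
#'   primer set).
#' @return Logical.
#' @export
span_overlaps_tag <- function(chrom, bound5, bound3, tag_chrom, tag_start,
                              tag_length) {
  if (is.na(chrom) || is.na(tag_chrom) || chrom != tag_chrom) return(FALSE)
  lo <- min(bound5, bound3)
  hi <- max(bound5, bound3)
  tag_end <- tag_start + tag_length - 1L
  lo <= tag_end && hi >= tag_start
}

#' @rdname span_overlaps_tag
#' @param alignment A `stace_alignment`.
#' @param tag_mapping One-row data frame (or list) with `chrom`, `start0`.
#' @export
is_true_positive <- function(alignment, tag_mapping, tag_length) {
  sp <- alignment_span(alignment)
  span_overlaps_tag(alignment$chrom, sp[["start"]], sp[["end"]],
                    tag_mapping$chrom, tag_mapping$start0 + 1L, tag_length)
}

#' Validate GT-AG splice signals
#'
#' Labels each inferred intron of an alignment canonical when, on the
#' transcribed strand, it begins with GT and ends with AG. Non-canonical
#' introns are flagged, not rejected.
#'
#' @param alignment A `stace_alignment`.
#' @param genome A `stace_genome`.
#' @return Data frame: `intron_start0`, `intron_end0`, `donor`, `acceptor`
#'   (transcribed-strand dinucleotides), `canonical`; zero rows for a
#'   single-block alignment.
#' @export
check_splice_signals <- function(alignment, genome) {
  b <- alignment$blocks
  out <- data.frame(intron_start0 = integer(), intron_end0 = integer(),
                    donor = character(), acceptor = character(),
                    canonical = logical(), stringsAsFactors = FALSE)
  if (nrow(b) < 2L) return(out)
  subj <- as.character(genome$seqs[[alignment$chrom]])
  for (i in seq_len(nrow(b) - 1L)) {
    s0 <- b$end0[i]
    e0 <- b$start0[i + 1L]
    first2 <- substr(subj, s0 + 1L, s0 + 2L)
    last2 <- substr(subj, e0 - 1L, e0)
    if (alignment$strand == "+") {
      don <- first2; acc <- last2
    } else {
      don <- revcomp(last2); acc <- revcomp(first2)
    }
    out <- rbind(out, data.frame(intron_start0 = s0, intron_end0 = e0,
                                 donor = don, acceptor = acc,
                                 canonical = don == "GT" && acc == "AG",
                                 stringsAsFactors = FALSE))
  }
  out
}

#' Categorise a true-positive STACE result against the annotation
#'
#' Categories: `non_coding_overlap` when any overlapped gene (>= 1 bp
#' exon-block intersection with a gene span) is a pseudogene or ncRNA --
#' taking precedence, so a pseudogene overlap is reported even when a coding
#' gene also overlaps; else `annotation_extension` when a protein-coding (or
#' other) gene overlaps -- the amplicon necessarily extends it, since
#' candidate tags were excluded from the annotated transcriptome; else
#' `novel_gene`.
#'
#' @param alignment A `stace_alignment`.
#' @param annotation A `stace_annotation`.
#' @return List: `category`, `overlapping_genes` (character vector of ids).
#' @export
classify_result <- function(alignment, annotation) {
  hits <- unique(do.call(rbind, lapply(seq_len(nrow(alignment$blocks)),
    function(i) overlapping_genes(annotation, alignment$chrom,
                                  alignment$blocks$start0[i],
                                  alignment$blocks$end0[i]))))
  if (is.null(hits) || nrow(hits) == 0L) {
    return(list(category = "novel_gene", overlapping_genes = character(0)))
  }
  category <- if (any(hits$biotype %in% c("pseudogene", "ncRNA"))) {
    "non_coding_overlap"
  } else {
    "annotation_extension"
  }
  list(category = category, overlapping_genes = hits$gene_id)
}

#' Assemble a full-length cDNA model from an amplicon pair
#'
#' Merges the exon chains of an upstream (SL1-anchored) and a downstream
#' (polyA-anchored) amplicon alignment for the same tag. The merge is valid
#' only when both alignments lie on one chromosome and strand, their genomic
#' overlap contains the tag interval, and the two exon chains agree exactly
#' over that overlap; otherwise the merge is rejected with a diagnostic.
#' `full_length` is `TRUE` iff the upstream read carried SL1 evidence and
#' the downstream read polyA evidence.
#'
#' @param upstream,downstream `stace_alignment` objects (both true-positive
#'   for the same tag). `downstream` may be `NULL` for a partial (5'-only)
#'   model.
#' @param tag_mapping List/row with `chrom`, `start0`.
#' @param tag_length Tag length.
#' @param sl1_found,polya_found Evidence flags from read trimming.
#' @return A `stace_model`: list with `ok`, `chrom`, `strand`, `blocks`,
#'   `full_length`, `partial`, `reason` (diagnostic when `ok` is `FALSE`).
#' @export
assemble_full_length <- function(upstream, downstream, tag_mapping,
                                 tag_length, sl1_found = FALSE,
                                 polya_found = FALSE) {
  reject <- function(reason) {
    structure(list(ok = FALSE, reason = reason), class = "stace_model")
  }
  if (is.null(downstream)) {
    return(structure(list(ok = TRUE, chrom = upstream$chrom,
                          strand = upstream$strand, blocks = upstream$blocks,
                          full_length = FALSE, partial = TRUE,
                          reason = "downstream amplicon missing"),
                     class = "stace_model"))
  }
  if (upstream$chrom != downstream$chrom ||
      upstream$strand != downstream$strand) {
    return(reject("alignments on different chromosome or strand"))
  }
  su <- alignment_span(upstream)
  sd <- alignment_span(downstream)
  ov_lo <- max(su[["start"]], sd[["start"]])
  ov_hi <- min(su[["end"]], sd[["end"]])
  if (ov_lo > ov_hi) return(reject("alignments do not overlap"))
  tag_lo <- tag_mapping$start0 + 1L
  tag_hi <- tag_mapping$start0 + tag_length
  if (tag_mapping$chrom != upstream$chrom || tag_lo < ov_lo ||
      tag_hi > ov_hi) {
    return(reject("overlap region does not contain the tag interval"))
  }
  clip <- function(blocks) {
    b <- blocks
    b$start0 <- pmax(b$start0, ov_lo - 1L)
    b$end0 <- pmin(b$end0, ov_hi)
    b <- b[b$start0 < b$end0, , drop = FALSE]
    rownames(b) <- NULL
    b
  }
  cu <- clip(upstream$blocks)
  cd <- clip(downstream$blocks)
  if (!isTRUE(all.equal(cu, cd, check.attributes = FALSE))) {
    return(reject("exon chains disagree over the overlap region"))
  }
  all_b <- rbind(upstream$blocks, downstream$blocks)
  ir <- IRanges::reduce(IRanges::IRanges(all_b$start0 + 1L, all_b$end0))
  merged <- data.frame(start0 = BiocGenerics::start(ir) - 1L,
                       end0 = BiocGenerics::end(ir))
  structure(list(ok = TRUE, chrom = upstream$chrom,
                 strand = upstream$strand, blocks = merged,
                 full_length = sl1_found && polya_found, partial = FALSE,
                 reason = NA_character_),
            class = "stace_model")
}

#' @export
print.stace_model <- function(x, ...) {
  if (!x$ok) {
    cat("stace_model: merge rejected --", x$reason, "\n")
  } else {
    cat(sprintf("stace_model: %s(%s), %d exon(s), %s\n", x$chrom, x$strand,
                nrow(x$blocks),
                if (x$full_length) "full-length" else "partial"))
  }
  invisible(x)
}

#' Ingest spliced alignments from BED12
#'
#' @param path BED12 file.
#' @return List of `stace_alignment` objects.
#' @export
read_alignments_bed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  lapply(seq_along(gr), function(i) {
    g <- gr[i]
    chrom_start0 <- BiocGenerics::start(g) - 1L
    bl <- S4Vectors::mcols(g)$blocks[[1L]]
    blocks <- data.frame(
      start0 = chrom_start0 + BiocGenerics::start(bl) - 1L,
      end0 = chrom_start0 + BiocGenerics::end(bl))
    new_alignment(id = S4Vectors::mcols(g)$name,
                  chrom = as.character(GenomicRanges::seqnames(g)),
                  strand = as.character(BiocGenerics::strand(g)),
                  blocks = blocks)
  })
}

#' Ingest spliced alignments from PSL
#'
#' Minimal PSL reader (21 tab-separated columns, optional header); target
#' block starts are taken as plus-strand 0-based coordinates, the strand
#' column gives the query orientation.
#'
#' @param path PSL file.
#' @return List of `stace_alignment` objects.
#' @export
read_alignments_psl <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  ## skip optional psLayout header block
  if (length(lines) && grepl("^psLayout", lines[1L])) {
    body_at <- grep("^-+$", lines)
    lines <- if (length(body_at)) lines[-seq_len(body_at[1L])] else lines
  }
  lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 21L) stop("malformed PSL line: ", ln)
    sizes <- as.integer(strsplit(f[19L], ",", fixed = TRUE)[[1L]])
    tstarts <- as.integer(strsplit(f[21L], ",", fixed = TRUE)[[1L]])
    new_alignment(id = f[10L], chrom = f[14L],
                  strand = substr(f[9L], 1L, 1L),
                  blocks = data.frame(start0 = tstarts,
                                      end0 = tstarts + sizes))
  })
}
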
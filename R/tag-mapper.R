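#' Build an exact-match tag index over a genome
#'
#' Answers exact full-length occurrence queries for fixed-length tags on both
#' strands. A tag "maps" only where the genome substring equals the tag (plus
#' strand) or its reverse complement (minus strand); ambiguity bases (N) in
#' the genome never match. No mismatches, no gaps: a tag that does not map as
#' one single uninterrupted alignment is discarded by the screen, and
#' sequencing errors are handled by the frequency filter instead of mismatch
#' rescue.
#'
#' @param genome A `stace_genome`.
#' @param k Tag length.
#' @return A `stace_tag_index`.
#' @export
build_tag_index <- function(genome, k) {
  stopifnot(inherits(genome, "stace_genome"), k >= 1L)
  if (length(genome$seqs) == 0L) stop("empty genome")
  if (k > min(Biostrings::width(genome$seqs))) {
    warning("k exceeds the shortest chromosome; those chromosomes cannot ",
            "carry any match")
  }
  structure(list(genome = genome, k = as.integer(k)),
            class = "stace_tag_index")
}

#' Map one tag to the genome
#'
#' All exact occurrences on both strands, sorted by (chrom, start, strand).
#' A minus-strand mapping is reported on plus-strand coordinates: the genomic
#' interval whose sequence equals the reverse complement of the tag.
#'
#' @param tag Tag sequence (length must equal the index `k`).
#' @param index A `stace_tag_index`.
#' @return Data frame with columns `tag`, `chrom`, `start0`, `strand`
#'   (0 rows when unmapped). Tags containing N return 0 rows with a message.
#' @export
map_tag <- function(tag, index) {
  stopifnot(inherits(index, "stace_tag_index"))
  tag <- toupper(tag)
  empty <- data.frame(tag = character(), chrom = character(),
                      start0 = integer(), strand = character(),
                      stringsAsFactors = FALSE)
  if (nchar(tag) != index$k) {
    stop("tag length ", nchar(tag), " != index k ", index$k)
  }
  if (grepl("[^ACGT]", tag)) {
    message("tag containing non-ACGT characters cannot map: ", tag)
    return(empty)
  }
  rc <- revcomp(tag)
  hits <- lapply(names(index$genome$seqs), function(chrom) {
    subj <- index$genome$seqs[[chrom]]
    plus <- Biostrings::start(Biostrings::matchPattern(tag, subj,
                                                       fixed = TRUE))
    minus <- Biostrings::start(Biostrings::matchPattern(rc, subj,
                                                        fixed = TRUE))
    if (tag == rc) minus <- integer(0)  # palindrome: one interval, one record
    n_hit <- length(plus) + length(minus)
    data.frame(tag = rep(tag, n_hit), chrom = rep(chrom, n_hit),
               start0 = c(plus, minus) - 1L,
               strand = c(rep("+", length(plus)), rep("-", length(minus))),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, hits)
  out <- out[order(out$chrom, out$start0, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify the mappability of a set of tags
#'
#' Each tag is `unmapped`, `unique` (exactly one genomic occurrence, the only
#' category counted as mappable by the filter cascade: a multi-mapped tag
#' cannot anchor a gene-specific primer), or `multi`.
#'
#' @param tags Character vector of tag sequences.
#' @param index A `stace_tag_index`.
#' @return A `stace_mappability`: list with `status` (named character vector:
#'   unmapped/unique/multi) and `mappings` (data frame of all mappings).
#' @export
classify_mappability <- function(tags, index) {
  tags <- toupper(unique(tags))
  maps <- lapply(tags, function(t) {
    if (grepl("[^ACGT]", t)) NULL else map_tag(t, index)
  })
  n_hit <- vapply(maps, function(m) if (is.null(m)) 0L else nrow(m),
                  integer(1L))
  status <- ifelse(n_hit == 0L, "unmapped",
                   ifelse(n_hit == 1L, "unique", "multi"))
  names(status) <- tags
  mappings <- do.call(rbind, maps[n_hit > 0L])
  if (is.null(mappings)) {
    mappings <- data.frame(tag = character(), chrom = character(),
                           start0 = integer(), strand = character(),
                           stringsAsFactors = FALSE)
  }
  rownames(mappings) <- NULL
  structure(list(status = status, mappings = mappings),
            class = "stace_mappability")
}

#' Write a tag mapping report
#'
#' TSV with one row per tag: status, and for uniquely mapped tags the
#' location (1-based start).
#'
#' @param report A `stace_mappability`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_mapping_report <- function(report, path) {
  uniq <- report$mappings[report$mappings$tag %in%
                            names(report$status)[report$status == "unique"], ,
                          drop = FALSE]
  df <- data.frame(tag = names(report$status),
                   status = unname(report$status),
                   chrom = uniq$chrom[match(names(report$status), uniq$tag)],
                   start = uniq$start0[match(names(report$status),
                                             uniq$tag)] + 1L,
                   strand = uniq$strand[match(names(report$status), uniq$tag)],
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
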
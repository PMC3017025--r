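#' Load a genome from FASTA
#'
#' Reads a multi-FASTA genome. Sequences are uppercased; soft-masked
#' (lowercase) stretches are recorded as per-chromosome ranges but ignored by
#' every downstream operation by default.
#'
#' @param fasta_path Path to an (uncompressed or gzipped) FASTA file.
#' @return A `stace_genome`: list with `seqs` (named [Biostrings::DNAStringSet],
#'   uppercase) and `mask` (named list of [IRanges::IRanges] of soft-masked
#'   positions, 1-based).
#' @export
load_genome <- function(fasta_path) {
  if (!file.exists(fasta_path)) stop("genome FASTA not found: ", fasta_path)
  raw <- Biostrings::readBStringSet(fasta_path)
  if (length(raw) == 0L) stop("FASTA contains no records: ", fasta_path)
  nms <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(nms)) {
    stop("duplicate chromosome name in FASTA: ",
         nms[duplicated(nms)][1L])
  }
  chars <- as.character(raw)
  if (any(nchar(chars) == 0L)) {
    stop("empty FASTA record: ", nms[nchar(chars) == 0L][1L])
  }
  mask <- lapply(chars, function(s) {
    pos <- which(strsplit(s, "")[[1L]] %in% c("a", "c", "g", "t", "n"))
    if (length(pos)) IRanges::reduce(IRanges::IRanges(pos, pos))
    else IRanges::IRanges()
  })
  up <- toupper(chars)
  if (any(grepl("[^ACGTN]", up))) {
    stop("genome contains characters outside ACGTN after normalization")
  }
  names(mask) <- nms
  seqs <- Biostrings::DNAStringSet(up)
  names(seqs) <- nms
  structure(list(seqs = seqs, mask = mask), class = "stace_genome")
}

#' @export
print.stace_genome <- function(x, ...) {
  cat("stace_genome:", length(x$seqs), "chromosome(s),",
      sum(Biostrings::width(x$seqs)), "bp total\n")
  invisible(x)
}

genome_chrom <- function(genome, chrom) {
  if (!chrom %in% names(genome$seqs)) {
    stop("unknown chromosome: ", chrom)
  }
  genome$seqs[[chrom]]
}

## extract genome subsequence, 0-based half-open coordinates
genome_subseq <- function(genome, chrom, start0, end0) {
  s <- genome_chrom(genome, chrom)
  if (start0 < 0L || end0 > length(s) || start0 >= end0) {
    stop(sprintf("interval [%d,%d) out of bounds on %s (length %d)",
                 start0, end0, chrom, length(s)))
  }
  as.character(Biostrings::subseq(s, start = start0 + 1L, end = end0))
}
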
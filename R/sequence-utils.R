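#' Reverse complement of a DNA sequence
#'
#' Watson-Crick reverse complement over the ACGTN alphabet. N complements to
#' N. Vectorised over its input.
#'
#' @param x Character vector of DNA sequences (ACGTN, case-insensitive).
#' @return Character vector of reverse complements, uppercase.
#' @examples
#' revcomp("CATG")                     # "CATG" (NlaIII site is palindromic)
#' revcomp("GTTAGGATCGTAGAGGACATG")    # "CATGTCCTCTACGATCCTAAC"
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  x <- toupper(x)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop("revcomp(): sequence contains characters outside ACGTN: ",
         x[bad][1L])
  }
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1L]]), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

#' GC content of a sequence, in percent
#'
#' @param x Character vector of DNA sequences.
#' @return Numeric vector: 100 * (G + C) / length.
#' @examples
#' gc_content("TAGCTCAGTCAAAACAACATG")  # 8/21 = 38.1
#' @export
gc_content <- function(x) {
  x <- toupper(x)
  n <- nchar(x)
  gc <- vapply(strsplit(x, ""), function(b) sum(b %in% c("G", "C")),
               numeric(1L))
  ifelse(n > 0L, 100 * gc / n, NA_real_)
}

## round half away from zero (base round() rounds half to even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

## locate all (1-based) start positions of a fixed pattern in a string
str_find_all <- function(pattern, subject) {
  m <- gregexpr(pattern, subject, fixed = TRUE)[[1L]]
  if (m[1L] == -1L) integer(0) else as.integer(m)
}
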
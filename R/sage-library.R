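#' Read a SAGE tag library from TSV
#'
#' Expects two columns (`tag`, `count`; a header row is optional) plus the
#' sequencing total as a comment line `#library_size=<int>` (or the
#' `library_size` argument). Tags must match the NlaIII-anchored pattern
#' `CATG[ACGT]{L-4}`; rows failing validation are collected in a rejects
#' table, never silently dropped. Duplicate tag rows have their counts
#' summed, with a warning.
#'
#' @param tsv_path Path to the tag TSV.
#' @param library_size Sequencing total (reads). Overrides / replaces the
#'   `#library_size=` header; required if the header is absent.
#' @param tag_length Expected tag length; default `NULL` infers it from the
#'   first valid row.
#' @param name Library name; defaults to the file name.
#' @return A `stace_tag_library`: list with `name`, `tags` (data frame
#'   `tag`, `count`), `library_size`, `tag_length`, and `rejects` (data frame
#'   `row`, `tag`, `count`, `reason`).
#' @export
read_tag_library <- function(tsv_path, library_size = NULL,
                             tag_length = NULL, name = NULL) {
  if (!file.exists(tsv_path)) stop("tag library not found: ", tsv_path)
  lines <- readLines(tsv_path)
  hdr <- grep("^#\\s*library_size\\s*=", lines, value = TRUE)
  if (is.null(library_size)) {
    if (length(hdr) == 0L) {
      stop("library_size missing: no '#library_size=' header and no argument")
    }
    library_size <- as.integer(sub("^#\\s*library_size\\s*=\\s*", "", hdr[1L]))
  }
  if (is.na(library_size) || library_size <= 0L) {
    stop("library_size must be a positive integer")
  }
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(body) && grepl("^tag\\b", body[1L], ignore.case = TRUE)) {
    body <- body[-1L]
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  tag <- toupper(vapply(parts, `[`, character(1L), 1L))
  count <- suppressWarnings(as.integer(vapply(parts, function(p)
    if (length(p) >= 2L) p[2L] else NA_character_, character(1L))))

  reason <- rep(NA_character_, length(tag))
  reason[is.na(count) | count < 0L] <- "bad_count"
  reason[grepl("[^ACGT]", tag)] <- "non_acgt"
  reason[is.na(reason) & !startsWith(tag, "CATG")] <- "no_catg_anchor"
  if (is.null(tag_length)) {
    ok1 <- which(is.na(reason))
    ## an empty (or fully rejected) library is legal: the funnel is all-zero
    tag_length <- if (length(ok1)) nchar(tag[ok1[1L]]) else 21L
  }
  reason[is.na(reason) & nchar(tag) != tag_length] <- "wrong_length"

  rejects <- data.frame(row = which(!is.na(reason)),
                        tag = tag[!is.na(reason)],
                        count = count[!is.na(reason)],
                        reason = reason[!is.na(reason)],
                        stringsAsFactors = FALSE)
  keep <- is.na(reason)
  tags <- data.frame(tag = tag[keep], count = count[keep],
                     stringsAsFactors = FALSE)
  if (anyDuplicated(tags$tag)) {
    warning("duplicate tag rows in ", tsv_path, "; counts summed")
    agg <- stats::aggregate(count ~ tag, data = tags, FUN = sum)
    tags <- agg[order(match(agg$tag, tags$tag)), , drop = FALSE]
    rownames(tags) <- NULL
  }
  structure(list(name = if (is.null(name)) basename(tsv_path) else name,
                 tags = tags, library_size = as.numeric(library_size),
                 tag_length = tag_length, rejects = rejects),
            class = "stace_tag_library")
}

#' Construct a tag library in memory
#'
#' @param tags Named integer vector (names are tag sequences) or data frame
#'   with columns `tag`, `count`.
#' @param library_size Sequencing total.
#' @param name Library name.
#' @return A `stace_tag_library`.
#' @export
tag_library <- function(tags, library_size, name = "library") {
  if (!is.data.frame(tags)) {
    tags <- data.frame(tag = names(tags), count = as.integer(tags),
                       stringsAsFactors = FALSE)
  }
  stopifnot(all(grepl("^CATG[ACGT]*$", tags$tag)) || nrow(tags) == 0L,
            library_size > 0)
  tl <- if (nrow(tags)) nchar(tags$tag[1L]) else 21L
  stopifnot(all(nchar(tags$tag) == tl))
  structure(list(name = name, tags = tags,
                 library_size = as.numeric(library_size), tag_length = tl,
                 rejects = data.frame(row = integer(), tag = character(),
                                      count = integer(), reason = character())),
            class = "stace_tag_library")
}

#' @export
print.stace_tag_library <- function(x, ...) {
  cat(sprintf("stace_tag_library '%s': %d unique tag(s), length %d, %s reads\n",
              x$name, nrow(x$tags), x$tag_length,
              format(x$library_size, big.mark = ",")))
  invisible(x)
}

#' Merge SAGE tag libraries into a meta-library
#'
#' Counts are summed per tag, library sizes are summed, and the name records
#' provenance. All input libraries must share one tag length.
#'
#' @param libraries List of `stace_tag_library` objects (at least one).
#' @return A merged `stace_tag_library`.
#' @export
merge_libraries <- function(libraries) {
  if (!is.list(libraries) || length(libraries) == 0L ||
      !all(vapply(libraries, inherits, logical(1L), "stace_tag_library"))) {
    stop("merge_libraries() needs a non-empty list of tag libraries")
  }
  tls <- vapply(libraries, `[[`, numeric(1L), "tag_length")
  if (length(unique(tls)) != 1L) {
    stop("cannot merge libraries with mixed tag lengths: ",
         paste(unique(tls), collapse = ", "))
  }
  all_tags <- do.call(rbind, lapply(libraries, `[[`, "tags"))
  if (nrow(all_tags)) {
    agg <- stats::aggregate(count ~ tag, data = all_tags, FUN = sum)
    agg <- agg[order(match(agg$tag, all_tags$tag)), , drop = FALSE]
    rownames(agg) <- NULL
  } else {
    agg <- all_tags
  }
  tag_library(agg,
              library_size = sum(vapply(libraries, `[[`, numeric(1L),
                                        "library_size")),
              name = paste(vapply(libraries, `[[`, character(1L), "name"),
                           collapse = "+"))
}

#' Normalized tag frequency per 100,000 reads
#'
#' The expression filter keeps tags seen at least three times per 100,000
#' reads; that comparison is inclusive.
#'
#' @param count Raw tag count(s).
#' @param library_size Sequencing total (> 0).
#' @return `count * 100000 / library_size`.
#' @examples
#' normalized_frequency(3, 100000)   # 3.0, exactly at the threshold
#' normalized_frequency(6, 300000)   # 2.0
#' @export
normalized_frequency <- function(count, library_size) {
  if (any(library_size <= 0)) stop("library_size must be > 0")
  count * 1e5 / library_size
}

#' Extract the expected SAGE tag from a spliced cDNA
#'
#' A (long)SAGE tag derives from the 3'-most NlaIII site (CATG) of the
#' transcript: the anchor plus the following `tag_length - 4` bases. Returns
#' `NA` when the transcript has no CATG, or when fewer than `tag_length - 4`
#' bases follow the 3'-most site (unless `fallback = TRUE`, which then tries
#' the next site upstream). A polyA tail present in the input counts as
#' sequence.
#'
#' @param spliced_cdna Transcript sequence in mRNA sense (character scalar).
#' @param tag_length Total tag length including the anchor (default 21).
#' @param fallback Fall back to upstream CATG sites when the 3'-most one has
#'   insufficient downstream sequence (default `FALSE`).
#' @return Tag sequence, or `NA_character_`.
#' @export
extract_expected_tag <- function(spliced_cdna, tag_length = 21L,
                                 fallback = FALSE) {
  stopifnot(tag_length >= 5L)
  s <- toupper(spliced_cdna)
  pos <- str_find_all("CATG", s)
  if (length(pos) == 0L) return(NA_character_)
  for (p in rev(pos)) {
    if (p + tag_length - 1L <= nchar(s)) {
      return(substr(s, p, p + tag_length - 1L))
    }
    if (!fallback) return(NA_character_)
  }
  NA_character_
}
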
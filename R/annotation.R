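#' Coordinate conversions between GFF and internal conventions
#'
#' Internally all intervals are 0-based half-open; GFF3 (and every
#' user-facing report) is 1-based inclusive.
#'
#' @param start,end GFF3 1-based inclusive coordinates.
#' @param start0,end0 internal 0-based half-open coordinates.
#' @return A list with the converted pair.
#' @export
to_internal_coords <- function(start, end) {
  list(start0 = start - 1L, end0 = end)
}

#' @rdname to_internal_coords
#' @export
to_gff_coords <- function(start0, end0) {
  list(start = start0 + 1L, end = end0)
}

## 1-based closed gap between [a1,b1] and [a2,b2]; 0 when overlapping/abutting
interval_gap1 <- function(a1, b1, a2, b2) {
  pmax(0, pmax(a2 - b1 - 1L, a1 - b2 - 1L))
}

#' Load gene annotations from GFF3
#'
#' Parses gene / transcript / exon rows of a GFF3 file into gene models with
#' a biotype, plus an interval index over exons, introns (gaps between
#' consecutive exons of a transcript) and gene spans. Coordinates are
#' converted to the internal 0-based half-open convention.
#'
#' Biotype is taken from the feature type column (`pseudogene`,
#' `ncRNA_gene`) or a `biotype` attribute, defaulting to `protein_coding`
#' when unannotated (conservative for the exon-overlap filter). Exons whose
#' parent feature is unknown are skipped with a warning; exons outside
#' chromosome bounds are an error.
#'
#' @param gff3_path Path to a GFF3 file.
#' @param genome A `stace_genome` from [load_genome()], used for bounds
#'   checks.
#' @return A `stace_annotation`: list with data frames `genes`,
#'   `transcripts`, `exons`, `introns` (internal coordinates) and `index`, a
#'   list of [GenomicRanges::GRanges] over gene spans, exons and introns.
#' @export
load_annotations <- function(gff3_path, genome) {
  if (!file.exists(gff3_path)) stop("GFF3 not found: ", gff3_path)
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)

  gene_types <- c("gene", "pseudogene", "ncRNA_gene")
  tx_types <- c("mRNA", "transcript", "ncRNA", "pseudogenic_transcript",
                "tRNA", "rRNA", "snoRNA", "snRNA", "miRNA")

  ids <- if ("ID" %in% names(md)) as.character(md$ID) else
    rep(NA_character_, length(gr))
  parents <- if ("Parent" %in% names(md)) {
    vapply(md$Parent, function(p) if (length(p)) as.character(p)[1L]
           else NA_character_, character(1L))
  } else rep(NA_character_, length(gr))

  is_gene <- type %in% gene_types
  is_tx <- type %in% tx_types
  is_exon <- type == "exon"

  biotype_of <- function(i) {
    if (type[i] == "pseudogene") return("pseudogene")
    if (type[i] == "ncRNA_gene") return("ncRNA")
    bt <- if ("biotype" %in% names(md)) as.character(md$biotype[i]) else NA
    if (is.na(bt) || !nzchar(bt)) return("protein_coding")
    if (bt %in% c("protein_coding", "pseudogene", "ncRNA")) bt else "other"
  }

  genes <- data.frame(
    gene_id = ids[is_gene],
    chrom = as.character(GenomicRanges::seqnames(gr))[is_gene],
    strand = as.character(BiocGenerics::strand(gr))[is_gene],
    biotype = vapply(which(is_gene), biotype_of, character(1L)),
    start0 = GenomicRanges::start(gr)[is_gene] - 1L,
    end0 = GenomicRanges::end(gr)[is_gene],
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene ID in GFF3")

  transcripts <- data.frame(
    transcript_id = ids[is_tx],
    gene_id = parents[is_tx],
    chrom = as.character(GenomicRanges::seqnames(gr))[is_tx],
    strand = as.character(BiocGenerics::strand(gr))[is_tx],
    stringsAsFactors = FALSE
  )

  ## exons: parent may be a transcript or (flat GFF3) a gene
  ex_idx <- which(is_exon)
  ex_parent <- parents[ex_idx]
  orphan <- is.na(ex_parent) |
    !(ex_parent %in% c(transcripts$transcript_id, genes$gene_id))
  if (any(orphan)) {
    warning(sum(orphan), " orphan exon(s) without a known parent skipped")
    ex_idx <- ex_idx[!orphan]
    ex_parent <- ex_parent[!orphan]
  }

  ## synthesise one transcript per gene for exons attached directly to genes
  direct <- ex_parent %in% genes$gene_id & !(ex_parent %in% transcripts$transcript_id)
  if (any(direct)) {
    gids <- unique(ex_parent[direct])
    synth <- data.frame(
      transcript_id = paste0(gids, ".t1"),
      gene_id = gids,
      chrom = genes$chrom[match(gids, genes$gene_id)],
      strand = genes$strand[match(gids, genes$gene_id)],
      stringsAsFactors = FALSE
    )
    transcripts <- rbind(transcripts, synth)
    ex_parent[direct] <- paste0(ex_parent[direct], ".t1")
  }

  exons <- data.frame(
    transcript_id = ex_parent,
    gene_id = transcripts$gene_id[match(ex_parent, transcripts$transcript_id)],
    chrom = as.character(GenomicRanges::seqnames(gr))[ex_idx],
    strand = as.character(BiocGenerics::strand(gr))[ex_idx],
    start0 = GenomicRanges::start(gr)[ex_idx] - 1L,
    end0 = GenomicRanges::end(gr)[ex_idx],
    stringsAsFactors = FALSE
  )

  ## bounds check against the genome
  chrom_len <- stats::setNames(Biostrings::width(genome$seqs),
                               names(genome$seqs))
  bad_chrom <- !(exons$chrom %in% names(chrom_len))
  if (any(bad_chrom)) {
    stop("exon of transcript ", exons$transcript_id[bad_chrom][1L],
         " on unknown chromosome ", exons$chrom[bad_chrom][1L])
  }
  oob <- exons$start0 < 0L | exons$end0 > chrom_len[exons$chrom]
  if (any(oob)) {
    stop("exon of transcript ", exons$transcript_id[oob][1L],
         " outside chromosome bounds on ", exons$chrom[oob][1L])
  }

  ## sort exons within transcripts, validate, derive introns
  exons <- exons[order(exons$transcript_id, exons$start0), , drop = FALSE]
  rownames(exons) <- NULL
  intron_list <- lapply(split(exons, exons$transcript_id), function(ex) {
    if (nrow(ex) > 1L) {
      if (any(ex$start0[-1L] < ex$end0[-nrow(ex)])) {
        stop("overlapping exons in transcript ", ex$transcript_id[1L])
      }
      data.frame(transcript_id = ex$transcript_id[1L],
                 gene_id = ex$gene_id[1L],
                 chrom = ex$chrom[1L], strand = ex$strand[1L],
                 start0 = ex$end0[-nrow(ex)], end0 = ex$start0[-1L],
                 stringsAsFactors = FALSE)
    } else NULL
  })
  introns <- do.call(rbind, c(intron_list, list(
    data.frame(transcript_id = character(), gene_id = character(),
               chrom = character(), strand = character(),
               start0 = integer(), end0 = integer(),
               stringsAsFactors = FALSE))))
  rownames(introns) <- NULL

  ## strand consistency across a gene's transcripts
  for (g in split(exons, exons$gene_id)) {
    if (length(unique(g$strand)) > 1L) {
      stop("inconsistent strand within gene ", g$gene_id[1L])
    }
  }

  ann <- structure(list(genes = genes, transcripts = transcripts,
                        exons = exons, introns = introns),
                   class = "stace_annotation")
  ann$index <- build_annotation_index(ann)
  ann
}

## GRanges interval index (1-based closed internally to IRanges)
build_annotation_index <- function(ann) {
  as_gr <- function(df, extra = NULL) {
    gr <- GenomicRanges::GRanges(
      seqnames = df$chrom,
      ranges = IRanges::IRanges(start = df$start0 + 1L, end = df$end0))
    for (nm in extra) S4Vectors::mcols(gr)[[nm]] <- df[[nm]]
    gr
  }
  list(genes = as_gr(ann$genes, c("gene_id", "biotype")),
       exons = as_gr(ann$exons, c("transcript_id", "gene_id")),
       introns = as_gr(ann$introns, c("transcript_id", "gene_id")))
}

#' @export
print.stace_annotation <- function(x, ...) {
  cat("stace_annotation:", nrow(x$genes), "gene(s),",
      nrow(x$transcripts), "transcript(s),", nrow(x$exons), "exon(s),",
      nrow(x$introns), "intron(s)\n")
  invisible(x)
}

## which gene spans does interval [start0,end0) on chrom overlap (>=1 bp)?
overlapping_genes <- function(ann, chrom, start0, end0) {
  g <- ann$genes
  hit <- g$chrom == chrom & g$start0 < end0 & g$end0 > start0
  g[hit, , drop = FALSE]
}

overlaps_any <- function(df, chrom, start0, end0) {
  any(df$chrom == chrom & df$start0 < end0 & df$end0 > start0)
}

#' Build the virtual transcriptome
#'
#' Materialises the spliced cDNA sequence of every annotated transcript:
#' exon genomic subsequences concatenated in coordinate order, reverse
#' complemented for minus-strand transcripts. Tags matching any of these
#' sequences derive from known genes and are excluded by the screen.
#'
#' @param genome A `stace_genome`.
#' @param annotation A `stace_annotation`.
#' @return A named [Biostrings::DNAStringSet], one spliced sequence per
#'   transcript.
#' @export
build_virtual_transcriptome <- function(genome, annotation) {
  tx_ids <- unique(annotation$exons$transcript_id)
  seqs <- vapply(tx_ids, function(tx) {
    ex <- annotation$exons[annotation$exons$transcript_id == tx, ,
                           drop = FALSE]
    ex <- ex[order(ex$start0), , drop = FALSE]
    s <- paste(mapply(genome_subseq, ex$start0, ex$end0,
                      MoreArgs = list(genome = genome, chrom = ex$chrom[1L])),
               collapse = "")
    if (ex$strand[1L] == "-") revcomp(s) else s
  }, character(1L))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- tx_ids
  out
}

#' Distance from an interval to the nearest annotated gene boundary
#'
#' Minimum over all gene spans (outermost extent of a gene across its
#' transcripts) of the gap between the query interval and the nearer gene
#' end; 0 when the interval overlaps or abuts a gene span. Used by the
#' positional filter, which requires candidate tags to sit at least 500 bp
#' away from any annotated 5' or 3' gene boundary.
#'
#' @param annotation A `stace_annotation`.
#' @param chrom Chromosome name.
#' @param start0,end0 Query interval, 0-based half-open.
#' @param biotypes Optional character vector restricting which gene biotypes
#'   count as boundaries (default: all).
#' @param genome Optional `stace_genome`; when supplied, an interval on a
#'   chromosome absent from the genome is an error rather than `Inf`.
#' @return Non-negative number of base pairs, or `Inf` when the chromosome
#'   carries no (matching) gene.
#' @export
distance_to_nearest_gene_boundary <- function(annotation, chrom, start0,
                                              end0, biotypes = NULL,
                                              genome = NULL) {
  if (!is.null(genome) && !chrom %in% names(genome$seqs)) {
    stop("unknown chromosome: ", chrom)
  }
  g <- annotation$genes
  g <- g[g$chrom == chrom, , drop = FALSE]
  if (!is.null(biotypes)) g <- g[g$biotype %in% biotypes, , drop = FALSE]
  if (nrow(g) == 0L) return(Inf)
  min(interval_gap1(start0 + 1L, end0, g$start0 + 1L, g$end0))
}
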
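#' Configuration for the synthetic STACE test-bed
#'
#' Describes a toy study: a small multi-chromosome genome carrying annotated
#' multi-exon genes (optionally a pseudogene and an ncRNA), plus "hidden"
#' novel genes that are present in the sequence and expressed in the tag
#' library but absent from the emitted annotation -- the ground truth the
#' screen is expected to recover. Defaults are chosen so that every hidden
#' gene's tag qualifies on all screen criteria by construction: intergenic
#' spacing of at least 700 bp clears the 500 bp boundary rule, novel
#' expression of 5-20 counts against a 100,000-read library clears the
#' 3-per-100k frequency rule, and tag regions are engineered to 35-45% GC
#' with a derivable primer.
#'
#' @param seed Mandatory RNG seed.
#' @param n_chromosomes,chrom_length Genome shape.
#' @param n_annotated_genes Annotated protein-coding genes.
#' @param n_novel_genes Hidden (planted) novel genes.
#' @param include_pseudogene,include_ncrna Add one annotated pseudogene /
#'   ncRNA gene.
#' @param exons_per_gene,novel_exons Exon-count ranges (novel genes default
#'   to >= 2 exons so spliced alignment is exercised).
#' @param exon_length,intron_length Length ranges in bp (introns begin GT
#'   and end AG).
#' @param min_intergenic Minimum spacing between gene spans, bp.
#' @param tag_length Tag length (CATG + 17 by default).
#' @param library_size Sequencing total of the simulated library.
#' @param expression,novel_expression Count ranges per annotated / novel
#'   gene.
#' @param tag_error_rate Per-tag substitution-error read fraction; error
#'   reads appear as low-count noise tags below the frequency threshold.
#' @param polya_length Simulated polyA tail length.
#' @param sl1_fraction Fraction of upstream amplicons carrying the SL1
#'   leader.
#' @return A `stace_sim_config` list.
#' @export
simulation_config <- function(seed, n_chromosomes = 2L, chrom_length = 30000L,
                              n_annotated_genes = 6L, n_novel_genes = 3L,
                              include_pseudogene = TRUE, include_ncrna = TRUE,
                              exons_per_gene = c(1L, 4L),
                              novel_exons = c(2L, 3L),
                              exon_length = c(90L, 250L),
                              intron_length = c(45L, 200L),
                              min_intergenic = 700L, tag_length = 21L,
                              library_size = 100000L,
                              expression = c(5L, 40L),
                              novel_expression = c(5L, 20L),
                              tag_error_rate = 0.02, polya_length = 16L,
                              sl1_fraction = 1) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  stopifnot(n_chromosomes >= 1L, chrom_length > 0L, tag_length >= 5L,
            all(exon_length > 0L), all(intron_length >= 30L),
            min_intergenic > 500L, library_size > 0L,
            sl1_fraction >= 0, sl1_fraction <= 1)
  structure(as.list(environment()), class = "stace_sim_config")
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## random DNA free of CATG anchors (so an engineered anchor stays 3'-most)
rand_dna_no_catg <- function(n) {
  s <- rand_dna(n)
  while (grepl("CATG", s, fixed = TRUE)) {
    s <- sub("CATG", paste0("C", sample(c("C", "G", "T"), 1L), "TG"), s,
             fixed = TRUE)
  }
  s
}

## engineered CATG tag: GC in [35,45]% and (optionally) a derivable primer
engineer_tag <- function(tag_length, require_primer,
                         constraints = primer_constraints()) {
  body_len <- tag_length - 4L
  for (attempt in 1:500) {
    n_gc <- sample(c(6L, 7L), 1L)         # + CATG's 2 -> 8 or 9 of 21
    body <- sample(c(sample(c("G", "C"), n_gc, replace = TRUE),
                     sample(c("A", "T"), body_len - n_gc, replace = TRUE)))
    tag <- paste0("CATG", paste(body, collapse = ""))
    if (grepl("CATG", substr(tag, 2L, tag_length), fixed = TRUE)) next
    gc <- gc_content(tag)
    if (gc < 35 || gc > 45) next
    if (require_primer && is.null(derive_primer(tag, constraints))) next
    return(tag)
  }
  stop("could not engineer a qualifying tag in 500 attempts")
}

## build one gene: returns genomic block sequence plus transcript-relative
## structure (exon/intron lengths in transcription order) and the tag
build_gene <- function(cfg, n_exons_range, require_primer) {
  strand <- sample(c("+", "-"), 1L)
  n_ex <- sample(seq(n_exons_range[1L], n_exons_range[2L]), 1L)
  ex_len <- sample(seq(cfg$exon_length[1L], cfg$exon_length[2L]), n_ex,
                   replace = TRUE)
  in_len <- if (n_ex > 1L) {
    sample(seq(cfg$intron_length[1L], cfg$intron_length[2L]), n_ex - 1L,
           replace = TRUE)
  } else integer(0)

  tag <- engineer_tag(cfg$tag_length, require_primer)
  ## last exon (transcription order): pad | tag | CATG-free tail ending non-A
  tail_len <- 30L
  pad_len <- max(ex_len[n_ex] - cfg$tag_length - tail_len, 10L)
  last_exon <- paste0(rand_dna(pad_len), tag,
                      substr(rand_dna_no_catg(tail_len), 1L, tail_len - 1L),
                      sample(c("C", "G", "T"), 1L))
  ex_len[n_ex] <- nchar(last_exon)
  exon_seqs <- c(if (n_ex > 1L) vapply(ex_len[-n_ex], rand_dna, character(1L)),
                 last_exon)
  intron_seqs <- vapply(in_len, function(l) {
    paste0("GT", rand_dna(l - 4L), "AG")
  }, character(1L))

  pre <- character(0)
  for (i in seq_len(n_ex)) {
    pre <- c(pre, exon_seqs[i],
             if (i < n_ex) intron_seqs[i])
  }
  pre_sense <- paste(pre, collapse = "")
  glen <- nchar(pre_sense)

  ## transcription-order exon offsets within the pre-mRNA (0-based)
  starts_tx <- cumsum(c(0L, if (n_ex > 1L) ex_len[-n_ex] + in_len))
  ends_tx <- starts_tx + ex_len
  if (strand == "+") {
    ex_g <- data.frame(start0 = starts_tx, end0 = ends_tx, rank = seq_len(n_ex))
    gseq <- pre_sense
  } else {
    ex_g <- data.frame(start0 = glen - ends_tx, end0 = glen - starts_tx,
                       rank = seq_len(n_ex))
    gseq <- revcomp(pre_sense)
  }
  ## tag offset within the last transcription-order exon
  tag_off_in_exon <- pad_len
  tag_tx_start <- starts_tx[n_ex] + tag_off_in_exon
  tag_g_start0 <- if (strand == "+") tag_tx_start
    else glen - (tag_tx_start + cfg$tag_length)

  list(strand = strand, gseq = gseq, glen = glen, exons = ex_g,
       transcript = paste(exon_seqs, collapse = ""), tag = tag,
       tag_g_start0 = tag_g_start0)
}

#' Generate a toy genome with planted novel genes
#'
#' Deterministic for a given seed (the seed is set once at entry; all other
#' generator operations continue the same stream). Annotated genes
#' (protein-coding plus optional pseudogene/ncRNA) are emitted to the
#' annotation; hidden novel genes exist only in the sequence and the ground
#' truth. Every gene's transcript carries an engineered NlaIII tag (CATG +
#' 17 bases, GC 35-45%); hidden genes' tags additionally pass primer
#' derivation and sit at least `min_intergenic` > 500 bp from every
#' annotated gene span. The generator asserts genome-wide tag uniqueness
#' rather than silently repairing collisions.
#'
#' @param config A [simulation_config()].
#' @return A `stace_sim`: list with `genome` (`stace_genome`), `gff3_lines`
#'   (annotated features only), `truth` (genes, exons, tags, transcripts),
#'   and `config`.
#' @export
generate_toy_genome <- function(config) {
  stopifnot(inherits(config, "stace_sim_config"))
  set.seed(config$seed)
  cfg <- config

  roster <- data.frame(
    gene_id = character(0), biotype = character(0), hidden = logical(0),
    stringsAsFactors = FALSE)
  add <- function(r, ids, biotype, hidden) {
    rbind(r, data.frame(gene_id = ids, biotype = biotype, hidden = hidden,
                        stringsAsFactors = FALSE))
  }
  roster <- add(roster, sprintf("gene%02d", seq_len(cfg$n_annotated_genes)),
                "protein_coding", FALSE)
  if (cfg$include_pseudogene) roster <- add(roster, "pseudo1", "pseudogene",
                                            FALSE)
  if (cfg$include_ncrna) roster <- add(roster, "ncrna1", "ncRNA", FALSE)
  roster <- add(roster, sprintf("novel%02d", seq_len(cfg$n_novel_genes)),
                "protein_coding", TRUE)
  ## shuffle placement so hidden genes interleave with annotated ones
  roster <- roster[sample(nrow(roster)), , drop = FALSE]
  roster$chrom <- sprintf("chr%s", rep(seq_len(cfg$n_chromosomes),
                                       length.out = nrow(roster)))

  genes <- list(); exons <- list(); tags <- list(); txseq <- list()
  chrom_seq <- stats::setNames(rep("", cfg$n_chromosomes),
                               sprintf("chr%d", seq_len(cfg$n_chromosomes)))
  for (chrom in names(chrom_seq)) {
    pos <- 0L
    parts <- character(0)
    for (i in which(roster$chrom == chrom)) {
      g <- build_gene(cfg,
                      if (roster$hidden[i]) cfg$novel_exons
                      else cfg$exons_per_gene,
                      require_primer = roster$hidden[i])
      spacer <- cfg$min_intergenic +
        sample.int(300L, 1L)              # > 500 bp rule with margin
      parts <- c(parts, rand_dna_no_catg(spacer), g$gseq)
      gstart <- pos + spacer
      pos <- gstart + g$glen
      gid <- roster$gene_id[i]
      genes[[gid]] <- data.frame(
        gene_id = gid, chrom = chrom, strand = g$strand,
        biotype = roster$biotype[i], hidden = roster$hidden[i],
        start0 = gstart, end0 = pos, stringsAsFactors = FALSE)
      exons[[gid]] <- data.frame(
        gene_id = gid, transcript_id = paste0(gid, ".1"), chrom = chrom,
        strand = g$strand, start0 = gstart + g$exons$start0,
        end0 = gstart + g$exons$end0, rank = g$exons$rank,
        stringsAsFactors = FALSE)
      tags[[gid]] <- data.frame(
        gene_id = gid, tag = g$tag, chrom = chrom,
        start0 = gstart + g$tag_g_start0,
        strand = g$strand, hidden = roster$hidden[i],
        stringsAsFactors = FALSE)
      txseq[[paste0(gid, ".1")]] <- g$transcript
    }
    tail_pad <- cfg$chrom_length - pos
    if (tail_pad < cfg$min_intergenic) {
      stop("infeasible packing: genes exceed chrom_length on ", chrom)
    }
    chrom_seq[chrom] <- paste(c(parts, rand_dna_no_catg(tail_pad)),
                              collapse = "")
  }

  seqs <- Biostrings::DNAStringSet(chrom_seq)
  genome <- structure(list(
    seqs = seqs,
    mask = stats::setNames(rep(list(IRanges::IRanges()), length(seqs)),
                           names(seqs))), class = "stace_genome")

  truth <- list(genes = do.call(rbind, genes),
                exons = do.call(rbind, exons),
                tags = do.call(rbind, tags),
                transcripts = txseq)
  rownames(truth$genes) <- rownames(truth$exons) <- rownames(truth$tags) <- NULL

  ## expression levels (counts)
  hid <- truth$tags$hidden
  truth$tags$count <- NA_integer_
  truth$tags$count[!hid] <- sample(seq(cfg$expression[1L],
                                       cfg$expression[2L]),
                                   sum(!hid), replace = TRUE)
  truth$tags$count[hid] <- sample(seq(cfg$novel_expression[1L],
                                      cfg$novel_expression[2L]),
                                  sum(hid), replace = TRUE)
  truth$expected_survivors <- sort(truth$tags$tag[hid])

  ## the planted tags must be unique in the genome and absent (fwd or rc)
  ## from every *other* transcript; assert rather than repair
  gseq_all <- as.character(seqs)
  for (j in seq_len(nrow(truth$tags))) {
    t <- truth$tags$tag[j]
    n_occ <- sum(vapply(gseq_all, function(s)
      length(str_find_all(t, s)) + length(str_find_all(revcomp(t), s)),
      integer(1L)))
    if (n_occ != 1L) {
      stop("planted tag ", t, " occurs ", n_occ, " times in the genome; ",
           "choose a different seed")
    }
    others <- truth$transcripts[names(truth$transcripts) !=
                                  paste0(truth$tags$gene_id[j], ".1")]
    hit <- any(vapply(others, function(s)
      grepl(t, s, fixed = TRUE) || grepl(revcomp(t), s, fixed = TRUE),
      logical(1L)))
    if (hit) stop("planted tag ", t, " is shared by another transcript; ",
                  "choose a different seed")
  }

  structure(list(genome = genome, gff3_lines = sim_gff3_lines(truth),
                 truth = truth, config = cfg), class = "stace_sim")
}

## GFF3 text for the annotated (non-hidden) genes
sim_gff3_lines <- function(truth) {
  lines <- "##gff-version 3"
  ann <- truth$genes[!truth$genes$hidden, , drop = FALSE]
  for (i in seq_len(nrow(ann))) {
    g <- ann[i, ]
    gene_type <- switch(g$biotype, pseudogene = "pseudogene",
                        ncRNA = "ncRNA_gene", "gene")
    tx_type <- switch(g$biotype, pseudogene = "pseudogenic_transcript",
                      ncRNA = "ncRNA", "mRNA")
    tx_id <- paste0(g$gene_id, ".1")
    lines <- c(lines, paste(
      g$chrom, "stacer_sim", gene_type, g$start0 + 1L, g$end0, ".",
      g$strand, ".", sprintf("ID=%s;biotype=%s", g$gene_id, g$biotype),
      sep = "\t"))
    lines <- c(lines, paste(
      g$chrom, "stacer_sim", tx_type, g$start0 + 1L, g$end0, ".",
      g$strand, ".", sprintf("ID=%s;Parent=%s", tx_id, g$gene_id),
      sep = "\t"))
    ex <- truth$exons[truth$exons$gene_id == g$gene_id, , drop = FALSE]
    ex <- ex[order(ex$start0), , drop = FALSE]
    for (k in seq_len(nrow(ex))) {
      lines <- c(lines, paste(
        g$chrom, "stacer_sim", "exon", ex$start0[k] + 1L, ex$end0[k], ".",
        g$strand, ".", sprintf("ID=%s.e%d;Parent=%s", tx_id, k, tx_id),
        sep = "\t"))
    }
  }
  lines
}

#' Simulate the SAGE tag library of a toy study
#'
#' Every gene (annotated and hidden) contributes its engineered tag at
#' exactly its expression count. With a positive error rate, each tag
#' additionally emits `round(count * rate)` error reads carrying one random
#' substitution outside the CATG anchor; these appear as distinct low-count
#' noise tags that fall below the frequency threshold by construction.
#' Continues the RNG stream of [generate_toy_genome()]; do not reseed in
#' between.
#'
#' @param sim A `stace_sim` from [generate_toy_genome()].
#' @return The `stace_sim` with `$library` (a `stace_tag_library`) and
#'   `truth$noise_tags` filled in.
#' @export
simulate_sage_library <- function(sim) {
  cfg <- sim$config
  tags <- sim$truth$tags
  counts <- stats::setNames(tags$count, tags$tag)
  noise <- character(0)
  noise_counts <- integer(0)
  if (cfg$tag_error_rate > 0) {
    ## noise must stay strictly below the 3-per-100k frequency threshold so
    ## the cascade's behavior on it is deterministic by design
    cap <- max(ceiling(3 * cfg$library_size / 1e5) - 1L, 1L)
    for (j in seq_len(nrow(tags))) {
      n_err <- round(tags$count[j] * cfg$tag_error_rate)
      for (e in seq_len(n_err)) {
        for (try in 1:20) {
          b <- strsplit(tags$tag[j], "")[[1L]]
          p <- sample(5:cfg$tag_length, 1L)
          b[p] <- sample(setdiff(c("A", "C", "G", "T"), b[p]), 1L)
          mut <- paste(b, collapse = "")
          cur <- if (mut %in% names(noise_counts)) noise_counts[[mut]] else 0L
          if (!(mut %in% tags$tag) && cur < cap) {
            noise_counts[mut] <- cur + 1L
            noise <- c(noise, mut)
            break
          }
        }
      }
    }
  }
  for (t in names(noise_counts)) counts[t] <- noise_counts[[t]]
  if (sum(counts) > cfg$library_size) {
    stop("library_size smaller than the simulated read total")
  }
  lib <- tag_library(counts, library_size = cfg$library_size,
                     name = sprintf("sim_seed%d", cfg$seed))
  sim$library <- lib
  sim$truth$noise_tags <- unique(noise)
  sim
}

#' Simulate a STACE amplicon pair for one transcript/tag
#'
#' The upstream amplicon (PCR product of the SL1 primer and the tag primer)
#' is the SL1 leader plus the spliced sequence from the transcript start
#' through the tag's end; the downstream amplicon (tag primer and universal
#' primer) runs from the tag's start through the 3' end, plus the polyA
#' tail and the 3' adapter. Both are in mRNA sense and overlap exactly over
#' the tag.
#'
#' @param transcript Spliced transcript sequence (mRNA sense).
#' @param tag Tag sequence; must occur in the transcript.
#' @param sl1 Attach the SL1 leader to the upstream read?
#' @param polya_length PolyA tail length on the downstream read.
#' @return List: `upstream`, `downstream`.
#' @export
simulate_amplicons <- function(transcript, tag, sl1 = TRUE,
                               polya_length = 16L) {
  pos <- str_find_all(tag, transcript)
  if (length(pos) == 0L) stop("tag not found in transcript")
  p <- pos[length(pos)]
  fixed <- stace_fixed_primers()
  upstream <- paste0(if (sl1) fixed$sl1 else "",
                     substr(transcript, 1L, p + nchar(tag) - 1L))
  downstream <- paste0(substr(transcript, p, nchar(transcript)),
                       strrep("A", polya_length), revcomp(fixed$universal))
  list(upstream = upstream, downstream = downstream)
}

#' Run the full simulator and write a fixture directory
#'
#' Generates genome, annotation, tag library and amplicon reads (one
#' upstream/downstream pair per hidden novel gene), all deterministic for
#' the configured seed, and -- when `out_dir` is given -- writes
#' `genome.fasta`, `annotations.gff3`, `tags.tsv`, `amplicons.fasta` and
#' `truth.json`.
#'
#' @param config A [simulation_config()].
#' @param out_dir Optional output directory.
#' @return A `stace_sim` with `genome`, `truth`, `library`, `amplicons`
#'   (data frame: id, gene_id, tag, role, sl1, read) and `paths` (when
#'   written).
#' @export
stace_simulate <- function(config, out_dir = NULL) {
  sim <- generate_toy_genome(config)
  sim <- simulate_sage_library(sim)

  hid <- sim$truth$tags[sim$truth$tags$hidden, , drop = FALSE]
  amp <- list()
  for (j in seq_len(nrow(hid))) {
    gid <- hid$gene_id[j]
    with_sl1 <- stats::runif(1L) < sim$config$sl1_fraction
    pair <- simulate_amplicons(sim$truth$transcripts[[paste0(gid, ".1")]],
                               hid$tag[j], sl1 = with_sl1,
                               polya_length = sim$config$polya_length)
    amp[[length(amp) + 1L]] <- data.frame(
      id = paste0(gid, ".up"), gene_id = gid, tag = hid$tag[j], role = "up",
      sl1 = with_sl1, read = pair$upstream, stringsAsFactors = FALSE)
    amp[[length(amp) + 1L]] <- data.frame(
      id = paste0(gid, ".down"), gene_id = gid, tag = hid$tag[j],
      role = "down", sl1 = FALSE, read = pair$downstream,
      stringsAsFactors = FALSE)
  }
  sim$amplicons <- do.call(rbind, amp)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- list(
      genome = file.path(out_dir, "genome.fasta"),
      gff3 = file.path(out_dir, "annotations.gff3"),
      tags = file.path(out_dir, "tags.tsv"),
      amplicons = file.path(out_dir, "amplicons.fasta"),
      truth = file.path(out_dir, "truth.json"))
    Biostrings::writeXStringSet(sim$genome$seqs, p$genome)
    writeLines(sim$gff3_lines, p$gff3)
    writeLines(c(sprintf("#library_size=%d", sim$config$library_size),
                 "tag\tcount",
                 sprintf("%s\t%d", sim$library$tags$tag,
                         sim$library$tags$count)), p$tags)
    reads <- Biostrings::DNAStringSet(sim$amplicons$read)
    names(reads) <- sprintf("%s tag=%s dir=%s gene=%s", sim$amplicons$id,
                            sim$amplicons$tag, sim$amplicons$role,
                            sim$amplicons$gene_id)
    Biostrings::writeXStringSet(reads, p$amplicons)
    truth_json <- sim$truth
    truth_json$transcripts <- as.list(truth_json$transcripts)
    jsonlite::write_json(truth_json, p$truth, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    sim$paths <- p
  }
  sim
}
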
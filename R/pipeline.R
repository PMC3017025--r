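## machine-readable run manifest: inputs (with checksums), parameters,
## versions -- enough to re-run a screen byte-identically
write_manifest <- function(dir, command, inputs, params) {
  manifest <- list(
    command = command,
    inputs = lapply(inputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    params = params,
    package_version = as.character(utils::packageVersion("stacer")),
    r_version = as.character(getRversion()))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

params_as_list <- function(params) {
  p <- unclass(params)
  p$primer <- unclass(p$primer)
  p
}

#' Screen a SAGE tag library for novel-gene candidate tags
#'
#' End-to-end screening command: loads genome, annotation and tag library,
#' runs the filter cascade, and writes the candidate table, a BED6 of
#' surviving tag intervals, the funnel report, the primer report for the
#' survivors, and a run manifest. Exits cleanly (funnel written) even with
#' zero survivors.
#'
#' @param genome_fasta,gff3,tags_tsv Input paths.
#' @param out_dir Output directory.
#' @param params A [stace_params()] object.
#' @param library_size Optional override for the tag library's read total.
#' @return The `stace_cascade`, invisibly.
#' @export
stace_screen <- function(genome_fasta, gff3, tags_tsv, out_dir,
                         params = stace_params(), library_size = NULL) {
  genome <- load_genome(genome_fasta)
  annotation <- load_annotations(gff3, genome)
  library <- read_tag_library(tags_tsv, library_size = library_size)
  cascade <- run_cascade(library, genome, annotation, params)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_cascade(cascade, out_dir)
  surv <- cascade$records$tag[cascade$records$final]
  write_primer_report(surv, file.path(out_dir, "primers.tsv"),
                      params$primer)
  if (nrow(library$rejects)) {
    utils::write.table(library$rejects, file.path(out_dir, "rejects.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_manifest(out_dir, "screen",
                 list(genome = genome_fasta, gff3 = gff3, tags = tags_tsv),
                 params_as_list(params))
  invisible(cascade)
}

## parse "key=value" fields from a FASTA header description
header_fields <- function(desc) {
  kv <- regmatches(desc, gregexpr("[A-Za-z0-9_]+=[^ ]+", desc))[[1L]]
  out <- sub("^[^=]+=", "", kv)
  stats::setNames(out, sub("=.*$", "", kv))
}

#' Classify sequenced STACE amplicons
#'
#' For each amplicon read: strip SL1 leader and polyA tail/adapter, align to
#' the genome (spliced, exact), test the true-positive rule against the tag
#' that designed its primer, validate GT-AG splice signals, and categorise
#' against the annotation. Upstream/downstream pairs sharing a tag are then
#' assembled into cDNA models; models are written as GFF3 plus spliced
#' FASTA, the per-amplicon table as TSV.
#'
#' Amplicon FASTA headers must carry `tag=<sequence>` and `dir=<up|down>`
#' fields (as written by [stace_simulate()]); tags are located on the genome
#' by exact mapping. Precomputed spliced alignments (BED12/PSL, as from
#' BLAT) can be supplied instead of the built-in aligner via `alignments`;
#' their ids must match the FASTA ids.
#'
#' @param genome_fasta,gff3,amplicons_fasta Input paths.
#' @param out_dir Output directory.
#' @param alignments Optional BED12 or PSL path replacing the built-in
#'   aligner.
#' @param params A [stace_params()] object.
#' @param max_mismatch Substitution budget for the built-in aligner.
#' @return Data frame with one row per amplicon: true-positive flag,
#'   category, SL1/polyA evidence, canonical-intron summary; plus an
#'   attribute `"models"` with the assembled `stace_model`s per tag.
#' @export
stace_classify <- function(genome_fasta, gff3, amplicons_fasta, out_dir,
                           alignments = NULL, params = stace_params(),
                           max_mismatch = 0L) {
  genome <- load_genome(genome_fasta)
  annotation <- load_annotations(gff3, genome)
  reads <- Biostrings::readBStringSet(amplicons_fasta)
  ids <- sub("\\s.*$", "", names(reads))
  fields <- lapply(names(reads), header_fields)
  ext <- if (!is.null(alignments)) {
    alns <- if (grepl("\\.psl$", alignments)) read_alignments_psl(alignments)
      else read_alignments_bed12(alignments)
    stats::setNames(alns, vapply(alns, `[[`, character(1L), "id"))
  }

  tag_cache <- new.env(parent = emptyenv())
  rows <- list()
  models <- list()
  for (i in seq_along(reads)) {
    id <- ids[i]
    f <- fields[[i]]
    tag <- unname(f["tag"])
    dir_role <- unname(f["dir"])
    raw <- toupper(as.character(reads[[i]]))
    sl1 <- detect_and_strip_sl1(raw)
    pa <- detect_and_strip_polya(sl1$read)
    row <- data.frame(id = id, tag = tag, role = dir_role,
                      sl1_found = sl1$sl1_found, polya_found = pa$polya_found,
                      aligned = FALSE, chrom = NA_character_,
                      strand = NA_character_, n_exons = NA_integer_,
                      bound5 = NA_integer_, bound3 = NA_integer_,
                      true_positive = NA, category = NA_character_,
                      introns_canonical = NA_character_,
                      note = NA_character_, stringsAsFactors = FALSE)

    ## tag mapping (cached per tag)
    tm <- if (!is.na(tag)) {
      if (!exists(tag, tag_cache)) {
        idx <- build_tag_index(genome, nchar(tag))
        assign(tag, map_tag(tag, idx), tag_cache)
      }
      get(tag, tag_cache)
    } else NULL
    if (is.null(tm) || nrow(tm) != 1L) {
      row$note <- "tag does not map uniquely to the genome"
      rows[[i]] <- row
      next
    }

    aln <- if (!is.null(ext)) ext[[id]] else {
      align_amplicon(pa$read, genome, id = id, max_mismatch = max_mismatch)
    }
    if (is.null(aln)) {
      row$note <- "unaligned"
      rows[[i]] <- row
      next
    }
    if (!aln$chrom %in% names(genome$seqs)) {
      row$note <- "alignment on a chromosome absent from the genome"
      rows[[i]] <- row
      next
    }
    sp <- alignment_span(aln)
    row$aligned <- TRUE
    row$chrom <- aln$chrom
    row$strand <- aln$strand
    row$n_exons <- nrow(aln$blocks)
    ## report 5'/3' mapping boundaries in transcription orientation
    if (aln$strand == "+") {
      row$bound5 <- sp[["start"]]; row$bound3 <- sp[["end"]]
    } else {
      row$bound5 <- sp[["end"]]; row$bound3 <- sp[["start"]]
    }
    row$true_positive <- is_true_positive(aln, tm, nchar(tag))
    if (isTRUE(row$true_positive)) {
      row$category <- classify_result(aln, annotation)$category
    }
    ss <- check_splice_signals(aln, genome)
    row$introns_canonical <- paste(ss$canonical, collapse = ",")
    rows[[i]] <- row
    models[[id]] <- list(aln = aln, tag = tag, tm = tm, role = dir_role,
                         sl1 = sl1$sl1_found, polya = pa$polya_found,
                         tp = row$true_positive)
  }
  results <- do.call(rbind, rows)

  ## assemble models per tag from true-positive up/down pairs
  assembled <- list()
  for (tag in unique(stats::na.omit(results$tag))) {
    parts <- Filter(function(m) m$tag == tag && isTRUE(m$tp), models)
    up <- Filter(function(m) m$role == "up", parts)
    down <- Filter(function(m) m$role == "down", parts)
    if (length(up) == 0L) next
    u <- up[[1L]]
    d <- if (length(down)) down[[1L]] else NULL
    assembled[[tag]] <- assemble_full_length(
      u$aln, if (is.null(d)) NULL else d$aln, u$tm, nchar(tag),
      sl1_found = u$sl1, polya_found = !is.null(d) && d$polya)
  }

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(results, file.path(out_dir, "results.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_models(assembled, genome, out_dir)
  write_manifest(out_dir, "classify",
                 list(genome = genome_fasta, gff3 = gff3,
                      amplicons = amplicons_fasta),
                 params_as_list(params))
  attr(results, "models") <- assembled
  invisible(results)
}

## assembled cDNA models as GFF3 + spliced FASTA
write_models <- function(models, genome, out_dir) {
  gff <- "##gff-version 3"
  seqs <- character(0)
  for (tag in names(models)) {
    m <- models[[tag]]
    if (!isTRUE(m$ok)) next
    mid <- paste0("stace_", tag)
    gff <- c(gff, paste(m$chrom, "stacer", "mRNA",
                        min(m$blocks$start0) + 1L, max(m$blocks$end0), ".",
                        m$strand, ".",
                        sprintf("ID=%s;full_length=%s", mid, m$full_length),
                        sep = "\t"))
    ord <- order(m$blocks$start0)
    for (k in seq_along(ord)) {
      b <- m$blocks[ord[k], ]
      gff <- c(gff, paste(m$chrom, "stacer", "exon", b$start0 + 1L, b$end0,
                          ".", m$strand, ".",
                          sprintf("ID=%s.e%d;Parent=%s", mid, k, mid),
                          sep = "\t"))
    }
    spliced <- paste(vapply(ord, function(k)
      genome_subseq(genome, m$chrom, m$blocks$start0[k], m$blocks$end0[k]),
      character(1L)), collapse = "")
    if (m$strand == "-") spliced <- revcomp(spliced)
    seqs[mid] <- spliced
  }
  writeLines(gff, file.path(out_dir, "models.gff3"))
  if (length(seqs)) {
    ss <- Biostrings::DNAStringSet(seqs)
    Biostrings::writeXStringSet(ss, file.path(out_dir, "models.fasta"))
  } else {
    file.create(file.path(out_dir, "models.fasta"))
  }
  invisible(NULL)
}

#' Read / write run configuration as YAML
#'
#' All screen thresholds (frequency, boundary distance, GC window, primer
#' constraints) round-trip losslessly through a YAML file; values absent
#' from the file keep their defaults.
#'
#' @param path YAML path.
#' @param params A [stace_params()] object (for writing).
#' @return [stace_params()] for `read_run_config()`; `path` invisibly for
#'   `write_run_config()`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  primer_args <- y$primer
  y$primer <- NULL
  base <- do.call(stace_params, y)
  if (!is.null(primer_args)) {
    base$primer <- do.call(primer_constraints, primer_args)
  }
  base
}

#' @rdname read_run_config
#' @export
write_run_config <- function(params, path) {
  p <- params_as_list(params)
  p$primer$fixed <- NULL   # constants, never configured
  yaml::write_yaml(p, path)
  invisible(path)
}
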
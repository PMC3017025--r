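sl1_seq <- stace_fixed_primers()$sl1
adapter <- revcomp(stace_fixed_primers()$universal)

test_that("SL1 leader detection accepts full and partial leaders", {
  body <- "ACGTACGTACGTACGTACGTACGT"
  full <- detect_and_strip_sl1(paste0(sl1_seq, body))
  expect_true(full$sl1_found)
  expect_equal(full$read, body)
  mid <- detect_and_strip_sl1(paste0(substr(sl1_seq, 9L, 22L), body))  # 14 nt
  expect_true(mid$sl1_found)
  expect_equal(mid$read, body)
  none <- detect_and_strip_sl1(body)
  expect_false(none$sl1_found)
  expect_equal(none$read, body)
  ## below the minimum suffix: not called
  short <- detect_and_strip_sl1(paste0(substr(sl1_seq, 13L, 22L), body))
  expect_false(short$sl1_found)
})

test_that("polyA detection strips tails and the 3' adapter", {
  body <- "ACGTACGTACGTCCGGTT"
  with_tail <- detect_and_strip_polya(paste0(body, strrep("A", 16L)))
  expect_true(with_tail$polya_found)
  expect_equal(with_tail$read, body)
  short_tail <- detect_and_strip_polya(paste0(body, strrep("A", 5L)))
  expect_false(short_tail$polya_found)
  expect_equal(short_tail$read, paste0(body, strrep("A", 5L)))
  with_adapter <- detect_and_strip_polya(paste0(body, strrep("A", 16L),
                                                adapter))
  expect_true(with_adapter$polya_found)
  expect_equal(with_adapter$read, body)
})

test_that("spliced alignment recovers planted exon structures exactly", {
  sim <- sim_fixture()
  for (i in seq_len(nrow(sim$amplicons))) {
    a <- sim$amplicons[i, ]
    read <- detect_and_strip_polya(detect_and_strip_sl1(a$read)$read)$read
    aln <- align_amplicon(read, sim$genome, id = a$id)
    expect_false(is.null(aln), info = a$id)
    truth_ex <- sim$truth$exons[sim$truth$exons$gene_id == a$gene_id, ]
    truth_ex <- truth_ex[order(truth_ex$start0), ]
    tag_row <- sim$truth$tags[sim$truth$tags$gene_id == a$gene_id, ]
    expect_equal(aln$chrom, truth_ex$chrom[1L], info = a$id)
    expect_equal(aln$strand, truth_ex$strand[1L], info = a$id)
    ## the aligned blocks are a clipped sub-chain of the gene's exon chain:
    ## every inferred intron equals an annotated-truth intron
    if (nrow(aln$blocks) > 1L) {
      got_introns <- data.frame(s = aln$blocks$end0[-nrow(aln$blocks)],
                                e = aln$blocks$start0[-1L])
      want_introns <- data.frame(s = truth_ex$end0[-nrow(truth_ex)],
                                 e = truth_ex$start0[-1L])
      expect_true(all(paste(got_introns$s, got_introns$e) %in%
                        paste(want_introns$s, want_introns$e)), info = a$id)
    }
    ## alignment span stays within the gene and covers the tag
    expect_gte(min(aln$blocks$start0), min(truth_ex$start0))
    expect_lte(max(aln$blocks$end0), max(truth_ex$end0))
    expect_true(is_true_positive(aln, tag_row, nchar(a$tag)), info = a$id)
  }
})

test_that("single-exon and mismatched reads behave as documented", {
  sim <- sim_fixture()
  chrom <- names(sim$genome$seqs)[1L]
  s <- as.character(sim$genome$seqs[[chrom]])
  read <- substr(s, 201L, 400L)
  aln <- align_amplicon(read, sim$genome)
  expect_equal(nrow(aln$blocks), 1L)
  expect_equal(aln$blocks$start0, 200L)
  expect_equal(aln$blocks$end0, 400L)
  expect_equal(nrow(check_splice_signals(aln, sim$genome)), 0L)

  ## one internal substitution: unaligned in exact mode, aligned with budget
  b <- strsplit(read, "")[[1L]]
  b[100L] <- setdiff(c("A", "C", "G", "T"), b[100L])[1L]
  mut <- paste(b, collapse = "")
  expect_null(align_amplicon(mut, sim$genome))
  aln1 <- align_amplicon(mut, sim$genome, max_mismatch = 1L)
  expect_false(is.null(aln1))
  expect_equal(aln1$blocks$start0, 200L)
  expect_equal(aln1$blocks$end0, 400L)
})

test_that("true-positive rule is orientation-agnostic containment", {
  ## plus-orientation published example: tag II:8786920, span 8786297..8787044
  expect_true(span_overlaps_tag("II", 8786297, 8787044, "II", 8786920, 21L))
  ## minus-orientation: boundaries listed 5' > 3' still bracket the tag
  expect_true(span_overlaps_tag("II", 9376228, 9375792, "II", 9375813, 21L))
  ## different chromosome is FALSE, not an error
  expect_false(span_overlaps_tag("X", 100, 200, "II", 999999, 21L))
  ## edge contact counts as overlap
  expect_true(span_overlaps_tag("I", 120, 100, "I", 120, 21L))
  expect_false(span_overlaps_tag("I", 100, 120, "I", 121, 21L))
})

test_that("GT-AG validation flags non-canonical introns without rejecting", {
  sim <- sim_fixture()
  ## all simulator introns are canonical by construction
  for (i in seq_len(nrow(sim$amplicons))) {
    a <- sim$amplicons[i, ]
    read <- detect_and_strip_polya(detect_and_strip_sl1(a$read)$read)$read
    aln <- align_amplicon(read, sim$genome, id = a$id)
    ss <- check_splice_signals(aln, sim$genome)
    expect_true(all(ss$canonical), info = a$id)
    if (nrow(ss)) expect_true(all(ss$donor == "GT" & ss$acceptor == "AG"))
  }
  ## constructed GC..AG mutant: flagged non-canonical
  dir <- withr::local_tempdir()
  set.seed(18)
  e1 <- rdna(60L); e2 <- rdna(60L)
  intron <- paste0("GC", rdna(40L), "AG")
  fa <- write_fasta(list(cM = paste0(rdna(20L), e1, intron, e2, rdna(20L))),
                    file.path(dir, "m.fa"))
  gm <- load_genome(fa)
  aln <- align_amplicon(paste0(e1, e2), gm)
  expect_equal(nrow(aln$blocks), 2L)
  ss <- check_splice_signals(aln, gm)
  expect_false(ss$canonical[1L])
  expect_equal(ss$donor[1L], "GC")
  expect_equal(ss$acceptor[1L], "AG")
})

test_that("categorisation follows the planted biotypes with precedence", {
  sim <- sim_fixture()
  genome <- sim$genome
  ann <- load_annotations(sim$paths$gff3, genome)
  align_gene <- function(gid) {
    tx <- sim$truth$transcripts[[paste0(gid, ".1")]]
    tag <- sim$truth$tags$tag[sim$truth$tags$gene_id == gid]
    pair <- simulate_amplicons(tx, tag)
    read <- detect_and_strip_sl1(pair$upstream)$read
    align_amplicon(read, genome, id = gid)
  }
  ## amplicon over a hidden novel gene overlaps nothing annotated
  expect_equal(classify_result(align_gene("novel01"), ann)$category,
               "novel_gene")
  ## over the annotated pseudogene / ncRNA: non-coding overlap
  expect_equal(classify_result(align_gene("pseudo1"), ann)$category,
               "non_coding_overlap")
  expect_equal(classify_result(align_gene("ncrna1"), ann)$category,
               "non_coding_overlap")
  ## over an annotated protein-coding gene: annotation extension
  expect_equal(classify_result(align_gene("gene01"), ann)$category,
               "annotation_extension")
})

test_that("model assembly merges agreeing chains and rejects conflicts", {
  sim <- sim_fixture()
  a <- sim$amplicons[sim$amplicons$gene_id == "novel01", ]
  up_raw <- a$read[a$role == "up"]
  down_raw <- a$read[a$role == "down"]
  tag <- a$tag[1L]
  sl1 <- detect_and_strip_sl1(up_raw)
  pa <- detect_and_strip_polya(down_raw)
  up <- align_amplicon(sl1$read, sim$genome, id = "up")
  down <- align_amplicon(pa$read, sim$genome, id = "down")
  tagm <- sim$truth$tags[sim$truth$tags$gene_id == "novel01", ]

  m <- assemble_full_length(up, down, tagm, nchar(tag),
                            sl1_found = sl1$sl1_found,
                            polya_found = pa$polya_found)
  expect_true(m$ok)
  expect_true(m$full_length)
  truth_ex <- sim$truth$exons[sim$truth$exons$gene_id == "novel01", ]
  truth_ex <- truth_ex[order(truth_ex$start0), ]
  expect_equal(m$blocks$start0, truth_ex$start0)
  expect_equal(m$blocks$end0, truth_ex$end0)

  ## upstream only: partial, never full-length
  p <- assemble_full_length(up, NULL, tagm, nchar(tag), sl1_found = TRUE,
                            polya_found = TRUE)
  expect_true(p$ok)
  expect_true(p$partial)
  expect_false(p$full_length)

  ## a conflicting downstream chain (spurious intron inside the overlap)
  ## is rejected with a diagnostic
  bad <- down
  b1 <- bad$blocks[1L, ]
  mid <- b1$start0 + (b1$end0 - b1$start0) %/% 2L
  bad$blocks <- rbind(data.frame(start0 = b1$start0, end0 = mid - 20L),
                      data.frame(start0 = mid + 20L, end0 = b1$end0),
                      bad$blocks[-1L, ])
  r <- assemble_full_length(up, bad, tagm, nchar(tag), TRUE, TRUE)
  expect_false(r$ok)
  expect_match(r$reason, "disagree")

  ## missing SL1 evidence blocks the full-length call
  nf <- assemble_full_length(up, down, tagm, nchar(tag), sl1_found = FALSE,
                             polya_found = TRUE)
  expect_false(nf$full_length)
})

test_that("external BED12 and PSL alignments are ingested equivalently", {
  sim <- sim_fixture()
  a <- sim$amplicons[1L, ]
  read <- detect_and_strip_polya(detect_and_strip_sl1(a$read)$read)$read
  aln <- align_amplicon(read, sim$genome, id = a$id)
  b <- aln$blocks
  dir <- withr::local_tempdir()

  bed <- file.path(dir, "a.bed")
  sizes <- paste0(paste(b$end0 - b$start0, collapse = ","), ",")
  rel <- paste0(paste(b$start0 - min(b$start0), collapse = ","), ",")
  writeLines(paste(aln$chrom, min(b$start0), max(b$end0), a$id, 0,
                   aln$strand, min(b$start0), max(b$end0), "0", nrow(b),
                   sizes, rel, sep = "\t"), bed)
  from_bed <- read_alignments_bed12(bed)[[1L]]
  expect_equal(from_bed$blocks, aln$blocks)
  expect_equal(from_bed$chrom, aln$chrom)

  psl <- file.path(dir, "a.psl")
  writeLines(paste(sum(b$end0 - b$start0), 0, 0, 0, 0, 0, nrow(b) - 1L,
                   sum(diff(b$start0)) - sum((b$end0 - b$start0)[-nrow(b)]),
                   aln$strand, a$id, nchar(read), 0, nchar(read), aln$chrom,
                   nchar(as.character(sim$genome$seqs[[aln$chrom]])),
                   min(b$start0), max(b$end0), nrow(b),
                   sizes, rel, paste0(paste(b$start0, collapse = ","), ","),
                   sep = "\t"), psl)
  from_psl <- read_alignments_psl(psl)[[1L]]
  expect_equal(from_psl$blocks, aln$blocks)
  expect_equal(from_psl$strand, aln$strand)
})
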
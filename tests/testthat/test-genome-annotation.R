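test_that("load_genome normalizes case, records soft-mask, rejects bad input", {
  dir <- withr::local_tempdir()
  fa <- write_fasta(list(chr1 = "ACGT"), file.path(dir, "a.fasta"))
  g <- load_genome(fa)
  expect_equal(names(g$seqs), "chr1")
  expect_equal(Biostrings::width(g$seqs), 4L)

  fa2 <- write_fasta(list(chr1 = "acgt"), file.path(dir, "b.fasta"))
  g2 <- load_genome(fa2)
  expect_equal(as.character(g2$seqs[[1L]]), "ACGT")
  expect_equal(sum(IRanges::width(g2$mask$chr1)), 4L)

  writeLines(c(">chr1", "ACGT", ">chr1", "GGCC"), file.path(dir, "dup.fasta"))
  expect_error(load_genome(file.path(dir, "dup.fasta")), "duplicate")
  writeLines(c(">chr1", "ACGT", ">chr2"), file.path(dir, "empty.fasta"))
  expect_error(load_genome(file.path(dir, "empty.fasta")), "empty")
})

test_that("GFF3 loading derives introns, biotypes, and flags bad exons", {
  toy <- toy_locus()
  ann <- toy$annotation
  expect_equal(nrow(ann$genes), 1L)
  expect_equal(nrow(ann$introns), 1L)
  ## exons [1,1800],[2101,3000] 1-based -> intron [1801,2100] = [1800,2100)
  expect_equal(ann$introns$start0, 1800L)
  expect_equal(ann$introns$end0, 2100L)

  dir <- withr::local_tempdir()
  fa <- write_fasta(list(c1 = strrep("ACGT", 200L)), file.path(dir, "g.fa"))
  genome <- load_genome(fa)

  ## single-exon gene: zero introns; pseudogene type maps to its biotype
  writeLines(c(
    "##gff-version 3",
    "c1\tt\tpseudogene\t11\t110\t.\t+\t.\tID=ps1",
    "c1\tt\tpseudogenic_transcript\t11\t110\t.\t+\t.\tID=ps1.1;Parent=ps1",
    "c1\tt\texon\t11\t110\t.\t+\t.\tID=e1;Parent=ps1.1"),
    file.path(dir, "ps.gff3"))
  ann2 <- load_annotations(file.path(dir, "ps.gff3"), genome)
  expect_equal(ann2$genes$biotype, "pseudogene")
  expect_equal(nrow(ann2$introns), 0L)

  ## orphan exon -> warning + skip; out-of-bounds exon -> error naming it
  writeLines(c(
    "##gff-version 3",
    "c1\tt\tgene\t11\t110\t.\t+\t.\tID=g1",
    "c1\tt\tmRNA\t11\t110\t.\t+\t.\tID=g1.1;Parent=g1",
    "c1\tt\texon\t11\t110\t.\t+\t.\tID=e1;Parent=g1.1",
    "c1\tt\texon\t11\t110\t.\t+\t.\tID=e2;Parent=ghost"),
    file.path(dir, "orphan.gff3"))
  expect_warning(load_annotations(file.path(dir, "orphan.gff3"), genome),
                 "orphan")
  writeLines(c(
    "##gff-version 3",
    "c1\tt\tgene\t11\t9000\t.\t+\t.\tID=g1",
    "c1\tt\tmRNA\t11\t9000\t.\t+\t.\tID=g1.1;Parent=g1",
    "c1\tt\texon\t11\t9000\t.\t+\t.\tID=e1;Parent=g1.1"),
    file.path(dir, "oob.gff3"))
  expect_error(load_annotations(file.path(dir, "oob.gff3"), genome), "g1.1")
})

test_that("coordinate conversion is an involution on loaded features", {
  toy <- toy_locus()
  ex <- toy$annotation$exons
  back <- to_gff_coords(ex$start0, ex$end0)
  expect_equal(back$start, c(1000L, 2101L))
  expect_equal(back$end, c(1800L, 3000L))
  ## random round trips
  set.seed(1)
  s <- sample.int(1e6, 50L)
  e <- s + sample.int(1000, 50L)
  int <- to_internal_coords(s, e)
  expect_identical(to_gff_coords(int$start0, int$end0), list(start = s, end = e))
})

test_that("virtual transcriptome splices and reverse-complements correctly", {
  dir <- withr::local_tempdir()
  ## plus gene exons AAA, CCC and minus gene with same genomic exons
  g <- paste0("TT", "AAA", "GTGGAG", "CCC", "TT")   # exons at 3-5, 12-14
  fa <- write_fasta(list(c1 = g), file.path(dir, "g.fa"))
  genome <- load_genome(fa)
  gff <- function(strand, id) c(
    sprintf("c1\tt\tgene\t3\t14\t.\t%s\t.\tID=%s", strand, id),
    sprintf("c1\tt\tmRNA\t3\t14\t.\t%s\t.\tID=%s.1;Parent=%s", strand, id, id),
    sprintf("c1\tt\texon\t3\t5\t.\t%s\t.\tID=%s.e1;Parent=%s.1", strand, id, id),
    sprintf("c1\tt\texon\t12\t14\t.\t%s\t.\tID=%s.e2;Parent=%s.1",
            strand, id, id))
  writeLines(c("##gff-version 3", gff("+", "gp"), gff("-", "gm")),
             file.path(dir, "a.gff3"))
  ann <- load_annotations(file.path(dir, "a.gff3"), genome)
  vt <- build_virtual_transcriptome(genome, ann)
  expect_equal(as.character(vt[["gp.1"]]), "AAACCC")
  expect_equal(as.character(vt[["gm.1"]]), "GGGTTT")
  expect_equal(sum(Biostrings::width(vt)), 12L)
})

test_that("simulated transcripts round-trip through the virtual transcriptome", {
  sim <- sim_fixture()
  genome <- load_genome(sim$paths$genome)
  ann <- load_annotations(sim$paths$gff3, genome)
  vt <- build_virtual_transcriptome(genome, ann)
  for (tx in names(vt)) {
    expect_identical(as.character(vt[[tx]]), sim$truth$transcripts[[tx]],
                     info = tx)
  }
  ## exon/intron tiling covers each transcript's genomic span exactly
  for (tx in unique(ann$exons$transcript_id)) {
    ex <- ann$exons[ann$exons$transcript_id == tx, ]
    ins <- ann$introns[ann$introns$transcript_id == tx, ]
    expect_equal(nrow(ins), nrow(ex) - 1L)
    pieces <- rbind(ex[, c("start0", "end0")], ins[, c("start0", "end0")])
    pieces <- pieces[order(pieces$start0), ]
    expect_true(all(pieces$start0[-1L] == pieces$end0[-nrow(pieces)]))
    expect_equal(sum(pieces$end0 - pieces$start0),
                 max(ex$end0) - min(ex$start0))
  }
})

test_that("distance to the nearest gene boundary follows the 1-based gap", {
  toy <- toy_locus()   # gene span [1000, 3000] 1-based
  ann <- toy$annotation
  d <- function(s1, e1) {  # 1-based closed query
    distance_to_nearest_gene_boundary(ann, "chr1", s1 - 1L, e1)
  }
  expect_equal(d(3401, 3421), 400)
  expect_equal(d(3601, 3621), 600)
  expect_equal(d(1500, 1520), 0)      # inside the span
  expect_equal(d(3001, 3021), 0)      # abutting
  expect_equal(distance_to_nearest_gene_boundary(ann, "chrX", 0L, 10L), Inf)
  expect_error(
    distance_to_nearest_gene_boundary(ann, "chrX", 0L, 10L,
                                      genome = toy$genome),
    "unknown chromosome")
})
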
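test_that("the generator is byte-deterministic per seed and seed-sensitive", {
  d1 <- file.path(withr::local_tempdir(), "s1")
  d2 <- file.path(withr::local_tempdir(), "s2")
  d3 <- file.path(withr::local_tempdir(), "s3")
  stace_simulate(simulation_config(seed = 303), out_dir = d1)
  stace_simulate(simulation_config(seed = 303), out_dir = d2)
  stace_simulate(simulation_config(seed = 304), out_dir = d3)
  for (f in c("genome.fasta", "annotations.gff3", "tags.tsv",
              "amplicons.fasta", "truth.json")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), info = f)
  }
  expect_false(identical(unname(tools::md5sum(file.path(d1, "genome.fasta"))),
                         unname(tools::md5sum(file.path(d3, "genome.fasta")))))
  expect_error(simulation_config(), "seed")
})

test_that("hidden genes are absent from the GFF3 but present in truth", {
  sim <- sim_fixture()
  gff <- readLines(sim$paths$gff3)
  hidden <- sim$truth$genes$gene_id[sim$truth$genes$hidden]
  expect_length(hidden, 3L)
  for (h in hidden) expect_false(any(grepl(h, gff, fixed = TRUE)), info = h)
  expect_true(any(grepl("pseudogene", gff)))
  expect_true(any(grepl("ncRNA_gene", gff)))
  ## annotated genes all present
  for (g in sim$truth$genes$gene_id[!sim$truth$genes$hidden]) {
    expect_true(any(grepl(paste0("ID=", g, ";"), gff, fixed = TRUE)), info = g)
  }
})

test_that("planted gene structure honours the configured constraints", {
  sim <- sim_fixture()
  cfg <- sim$config
  genes <- sim$truth$genes
  exons <- sim$truth$exons
  ## intergenic spacing: every pair of gene spans on a chromosome >= 500 bp
  ## apart (the generator leaves >= min_intergenic = 700)
  for (chrom in unique(genes$chrom)) {
    g <- genes[genes$chrom == chrom, ]
    g <- g[order(g$start0), ]
    if (nrow(g) > 1L) {
      expect_true(all(g$start0[-1L] - g$end0[-nrow(g)] >= cfg$min_intergenic))
    }
  }
  ## introns within configured lengths and GT..AG on the transcribed strand
  genome <- sim$genome
  for (tx in unique(exons$transcript_id)) {
    ex <- exons[exons$transcript_id == tx, ]
    ex <- ex[order(ex$start0), ]
    if (nrow(ex) < 2L) next
    for (i in seq_len(nrow(ex) - 1L)) {
      s0 <- ex$end0[i]; e0 <- ex$start0[i + 1L]
      expect_gte(e0 - s0, cfg$intron_length[1L])
      expect_lte(e0 - s0, cfg$intron_length[2L])
      chrom_s <- as.character(genome$seqs[[ex$chrom[1L]]])
      first2 <- substr(chrom_s, s0 + 1L, s0 + 2L)
      last2 <- substr(chrom_s, e0 - 1L, e0)
      if (ex$strand[1L] == "+") {
        expect_equal(first2, "GT"); expect_equal(last2, "AG")
      } else {
        expect_equal(first2, "CT"); expect_equal(last2, "AC")
      }
    }
  }
  ## every planted tag: CATG anchor, GC within [35,45]
  expect_true(all(startsWith(sim$truth$tags$tag, "CATG")))
  gc <- gc_content(sim$truth$tags$tag)
  expect_true(all(gc >= 35 & gc <= 45))
  ## tag genomic interval matches the recorded coordinates
  for (j in seq_len(nrow(sim$truth$tags))) {
    t <- sim$truth$tags[j, ]
    sub <- substr(as.character(genome$seqs[[t$chrom]]), t$start0 + 1L,
                  t$start0 + nchar(t$tag))
    expect_identical(sub, if (t$strand == "+") t$tag else ora_revcomp(t$tag),
                     info = t$gene_id)
  }
})

test_that("library counts are exact at error rate 0 and noisy below threshold", {
  clean <- stace_simulate(simulation_config(seed = 505, tag_error_rate = 0))
  tl <- clean$library$tags
  expect_setequal(tl$tag, clean$truth$tags$tag)
  for (j in seq_len(nrow(clean$truth$tags))) {
    expect_equal(tl$count[tl$tag == clean$truth$tags$tag[j]],
                 clean$truth$tags$count[j])
  }
  expect_length(clean$truth$noise_tags, 0L)

  noisy <- stace_simulate(simulation_config(seed = 505, tag_error_rate = 0.5))
  expect_gt(length(noisy$truth$noise_tags), 0L)
  nt <- noisy$library$tags[noisy$library$tags$tag %in%
                             noisy$truth$noise_tags, ]
  expect_true(all(normalized_frequency(nt$count,
                                       noisy$library$library_size) < 3))
  ## noise keeps the anchor (errors are injected outside CATG)
  expect_true(all(startsWith(nt$tag, "CATG")))
})

test_that("amplicon pairs overlap exactly over the tag, SL1 fraction respected", {
  sim <- sim_fixture()   # sl1_fraction = 1
  for (gid in unique(sim$amplicons$gene_id)) {
    a <- sim$amplicons[sim$amplicons$gene_id == gid, ]
    up <- a$read[a$role == "up"]
    down <- a$read[a$role == "down"]
    tag <- a$tag[1L]
    expect_true(startsWith(up, stace_fixed_primers()$sl1), info = gid)
    body <- sub(paste0("^", stace_fixed_primers()$sl1), "", up)
    expect_true(endsWith(body, tag), info = gid)     # up ends at tag end
    expect_true(startsWith(down, tag), info = gid)   # down starts at tag
    tx <- sim$truth$transcripts[[paste0(gid, ".1")]]
    expect_true(grepl(body, tx, fixed = TRUE) || body == tx)
  }
  ## without SL1 leadering, upstream reads have no leader
  bare <- stace_simulate(simulation_config(seed = 606, sl1_fraction = 0))
  ups <- bare$amplicons$read[bare$amplicons$role == "up"]
  expect_false(any(startsWith(ups, stace_fixed_primers()$sl1)))
  expect_error(simulate_amplicons("ACGTACGT", "CATGAAAA"), "not found")
})

test_that("infeasible packing is rejected", {
  cfg <- simulation_config(seed = 1, chrom_length = 3000L,
                           n_annotated_genes = 10L)
  expect_error(generate_toy_genome(cfg), "infeasible packing")
})
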
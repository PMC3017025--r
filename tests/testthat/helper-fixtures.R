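## Shared fixtures and independent brute-force oracles for the test suite.
## Oracles deliberately use naive base-R scans, independent of the package's
## Biostrings-backed implementation paths.

## deterministic random DNA
rdna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                          collapse = "")

write_fasta <- function(records, path) {
  writeLines(unlist(lapply(names(records), function(nm)
    c(paste0(">", nm), records[[nm]]))), path)
  path
}

## tiny hand-laid-out genome + single 2-exon gene for arithmetic tests:
## gene span 1-based [1000, 3000], exons [1000, 1800] and [2101, 3000]
## (1-based), i.e. one intron [1801, 2100] 1-based = [1800, 2100) internal
toy_locus <- function(dir = withr::local_tempdir()) {
  set.seed(42)
  g <- rdna(6000)
  fa <- write_fasta(list(chr1 = g), file.path(dir, "toy.fasta"))
  gff <- file.path(dir, "toy.gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\ttoy\tgene\t1000\t3000\t.\t+\t.\tID=g1;biotype=protein_coding",
    "chr1\ttoy\tmRNA\t1000\t3000\t.\t+\t.\tID=g1.1;Parent=g1",
    "chr1\ttoy\texon\t1000\t1800\t.\t+\t.\tID=g1.1.e1;Parent=g1.1",
    "chr1\ttoy\texon\t2101\t3000\t.\t+\t.\tID=g1.1.e2;Parent=g1.1"),
    gff)
  genome <- load_genome(fa)
  list(dir = dir, fasta = fa, gff3 = gff, genome = genome,
       annotation = load_annotations(gff, genome))
}

## one simulated study per suite run, shared across test files
sim_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "stacer-sim-fixture")
      cache <<- stace_simulate(simulation_config(seed = 101), out_dir = dir)
    }
    cache
  }
})

## ---- brute-force oracles -------------------------------------------------

## naive complement without revcomp()
ora_comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
ora_revcomp <- function(s) {
  paste(rev(ora_comp[strsplit(s, "")[[1L]]]), collapse = "")
}

## sliding-window exact mapping over genome and its reverse complement;
## the k-mer table can be precomputed once for large batches of queries
oracle_kmers <- function(chrom_seqs, k) {
  lapply(chrom_seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    pos <- seq_len(n - k + 1L)
    substring(s, pos, pos + k - 1L)
  })
}

oracle_map <- function(tag, chrom_seqs, kmer_tab = NULL) {
  k <- nchar(tag)
  rc <- ora_revcomp(tag)
  if (is.null(kmer_tab)) kmer_tab <- oracle_kmers(chrom_seqs, k)
  out <- list()
  for (chrom in names(chrom_seqs)) {
    kmers <- kmer_tab[[chrom]]
    plus <- which(kmers == tag)
    minus <- if (rc == tag) integer(0) else which(kmers == rc)
    nh <- length(plus) + length(minus)
    if (nh) {
      out[[chrom]] <- data.frame(
        tag = rep(tag, nh), chrom = rep(chrom, nh),
        start0 = c(plus, minus) - 1L,
        strand = c(rep("+", length(plus)), rep("-", length(minus))),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(tag = character(), chrom = character(),
                      start0 = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, out)
  df <- df[order(df$chrom, df$start0, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  df
}

## exhaustive substring-pair hairpin search
oracle_hairpin <- function(s, min_loop = 3L) {
  b <- strsplit(toupper(s), "")[[1L]]
  n <- length(b)
  best <- 0L
  for (len in seq_len(n %/% 2L)) {
    for (i in seq_len(n - len + 1L)) {
      arm1 <- substr(s, i, i + len - 1L)
      for (j in seq_len(n - len + 1L)) {
        if (j - (i + len - 1L) - 1L < min_loop) next
        if (substr(s, j, j + len - 1L) == ora_revcomp(arm1) && len > best) {
          best <- len
        }
      }
    }
  }
  best
}

## exhaustive antiparallel complementary-run search
oracle_dimer <- function(sa, sb) {
  a <- strsplit(toupper(sa), "")[[1L]]
  b <- strsplit(toupper(sb), "")[[1L]]
  na <- length(a); nb <- length(b)
  best <- 0L; best3 <- 0L
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      l <- 0L
      while (i + l <= na && j - l >= 1L && a[i + l] == ora_comp[[b[j - l]]]) {
        l <- l + 1L
      }
      if (l > best) best <- l
      ## run covers a positions i..i+l-1 and b positions j-l+1..j
      if (l > 0L && (i + l - 1L == na || j == nb) && l > best3) best3 <- l
    }
  }
  list(run = best, run_3prime = best3)
}

## brute-force trim enumeration mirroring derive_primer's search order
oracle_trims <- function(L, max_trim, min_length) {
  out <- list()
  for (total in 0:max_trim) {
    if (L - total < min_length) break
    for (left in 0:total) {
      out[[length(out) + 1L]] <- c(left = left, right = total - left)
    }
  }
  out
}
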
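test_that("reverse complement is correct and involutive", {
  expect_equal(revcomp("CATG"), "CATG")
  expect_equal(revcomp("GTTAGGATCGTAGAGGACATG"), "CATGTCCTCTACGATCCTAAC")
  expect_equal(revcomp("AN"), "NT")
  expect_error(revcomp("ACGU"), "outside ACGTN")
  set.seed(14)
  for (i in 1:20) {
    s <- rdna(sample(5:40, 1L))
    expect_identical(revcomp(revcomp(s)), s)
  }
})

test_that("hairpin screen matches the exhaustive substring-pair oracle", {
  expect_equal(hairpin_score("GGGGAAAACCCC"),
               list(stem = 4L, flagged = TRUE))
  expect_equal(hairpin_score("ACACACACACAC")$flagged, FALSE)
  ## below the evaluable length: clean by definition
  expect_equal(hairpin_score("GGGGCCCCGG", min_stem = 4L, min_loop = 3L),
               list(stem = 0L, flagged = FALSE))
  set.seed(15)
  for (i in 1:60) {
    s <- rdna(sample(11:30, 1L))
    got <- hairpin_score(s)
    expect_equal(got$stem, oracle_hairpin(s), info = s)
    expect_equal(got$flagged, got$stem >= 4L)
  }
})

test_that("dimer screen matches the exhaustive offset-scan oracle", {
  full <- dimer_score("AAAAAAAA", "TTTTTTTT")
  expect_equal(full$run, 8L)
  expect_true(full$flagged)
  self <- dimer_score("ACGTACGT", "ACGTACGT", min_run = 4L)
  expect_gte(self$run, 4L)
  expect_true(self$flagged)
  expect_error(dimer_score("ACGT", ""), "empty")
  set.seed(16)
  for (i in 1:50) {
    a <- rdna(sample(8:25, 1L))
    b <- rdna(sample(8:25, 1L))
    want <- oracle_dimer(a, b)
    got <- dimer_score(a, b)
    expect_equal(got$run, want$run, info = paste(a, b))
    expect_equal(got$run_3prime, want$run_3prime, info = paste(a, b))
    ## homodimer is the same screen against itself
    wself <- oracle_dimer(a, a)
    gself <- dimer_score(a, a)
    expect_equal(gself$run, wself$run, info = a)
  }
})

test_that("Tm estimate behaves thermodynamically and tracks Wallace at primer lengths", {
  expect_gt(tm_estimate("GCGCGCGCGC"), tm_estimate("ATATATATAT"))
  expect_error(tm_estimate("ACGTACG"), "length")
  ## deterministic
  expect_identical(tm_estimate("CATGTCCTCTACGATCCTAAC"),
                   tm_estimate("CATGTCCTCTACGATCCTAAC"))
  set.seed(17)
  mk <- function(n, gc) {
    ngc <- round(n * gc)
    paste(sample(c(sample(c("G", "C"), ngc, TRUE),
                   sample(c("A", "T"), n - ngc, TRUE))), collapse = "")
  }
  for (i in 1:60) {
    s <- mk(sample(17:21, 1L), runif(1, 0.35, 0.45))
    ## coarse sanity cross-check at primer-realistic lengths
    expect_lt(abs(tm_estimate(s) - tm_wallace(s)), 8, label = s)
    ## extending with a GC base never lowers Tm
    expect_gte(tm_estimate(paste0(s, "G")), tm_estimate(s))
    expect_gte(tm_estimate(paste0("C", s)), tm_estimate(s))
  }
})

test_that("primer derivation is an exhaustive trim search with revalidation", {
  cn <- primer_constraints()
  sim <- sim_fixture()
  tags <- sim$truth$tags$tag[sim$truth$tags$hidden]   # primerable by design
  for (tag in tags) {
    pc <- derive_primer(tag, cn)
    expect_false(is.null(pc), info = tag)
    L <- nchar(tag)
    core <- substr(tag, 1L + pc$trim_left, L - pc$trim_right)
    expect_identical(pc$primer, revcomp(core))
    expect_gte(nchar(pc$primer), cn$min_length)
    ## revalidate every claimed screen independently
    expect_true(pc$gc >= cn$gc_min && pc$gc <= cn$gc_max)
    expect_true(pc$tm >= cn$tm_min && pc$tm <= cn$tm_max)
    expect_false(hairpin_score(pc$primer, cn$hairpin_min_stem,
                               cn$hairpin_min_loop)$flagged)
    expect_false(dimer_score(pc$primer, pc$primer, cn$dimer_min_run)$flagged)
    for (f in c(cn$fixed$sl1, cn$fixed$universal)) {
      expect_false(dimer_score(pc$primer, f, cn$dimer_min_run)$flagged)
    }
    ## minimal-trim tie-break: no admissible smaller/earlier trim passes
    for (tr in oracle_trims(L, cn$max_trim, cn$min_length)) {
      if (tr[["left"]] + tr[["right"]] > pc$trim_left + pc$trim_right ||
          (tr[["left"]] + tr[["right"]] == pc$trim_left + pc$trim_right &&
           tr[["left"]] >= pc$trim_left)) next
      alt <- revcomp(substr(tag, 1L + tr[["left"]], L - tr[["right"]]))
      expect_null(stacer:::screen_primer(alt, cn),
                  info = sprintf("%s trim %d/%d", tag, tr[["left"]],
                                 tr[["right"]]))
    }
  }
  ## an all-A/T tag can never reach 35% GC
  expect_null(derive_primer(paste0("CATG", strrep("AT", 9))[1L], cn))
})

test_that("published primer lengths are admissible output shapes", {
  cn <- primer_constraints()
  cdnas <- stace_published_cdnas()
  expect_true(all(nchar(cdnas$primer) %in% 19:21))
  ## the untrimmed (21 nt) and 1-2 nt trimmed shapes both arise from
  ## tag lengths 21 with trims 0-4 at min_length 17
  trims <- oracle_trims(21L, cn$max_trim, cn$min_length)
  lens <- unique(vapply(trims, function(t) 21L - sum(t), integer(1L)))
  expect_true(all(nchar(cdnas$primer) %in% lens))
})
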
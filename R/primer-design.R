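#' Fixed STACE primers
#'
#' The three constant oligos of the STACE protocol in *C. elegans*: the SL1
#' trans-spliced leader primer (5' site, present at the extreme 5' end of
#' roughly half of all mRNAs), the universal primer (3' site, matching the
#' common sequence attached during reverse transcription), and the modified
#' oligo d(T) RT primer whose 5' segment equals the universal primer.
#'
#' @return Named list: `sl1`, `universal`, `rt`.
#' @export
stace_fixed_primers <- function() {
  sl1 <- "GGTTTAATTACCCAAGTTTGAG"
  universal <- "CACTATGCTCATACGACGCAGT"
  rt <- paste0("CCAGA", universal, strrep("T", 16L), "VN")
  list(sl1 = sl1, universal = universal, rt = rt)
}

#' Constraints for tag-derived primer design
#'
#' Gene-specific primers are the reverse complement of a (possibly
#' end-trimmed) qualifying tag. A trimmed candidate is accepted when its GC,
#' melting temperature and secondary-structure screens all pass. The Tm
#' window brackets the protocol's 60 degree annealing step; Tm is estimated
#' under PCR-like conditions (see [tm_estimate()]). All thresholds are
#' explicit here rather than delegated to an external design program.
#'
#' @param min_length Minimum primer length after trimming (default 17).
#' @param max_trim Maximum total bases trimmed off the two tag ends
#'   (default 4).
#' @param gc_min,gc_max GC window in percent, inclusive (default \[35, 45\]).
#' @param tm_min,tm_max Melting-temperature window in Celsius (default
#'   \[55, 65\]).
#' @param hairpin_min_stem Minimum self-complementary stem length flagged as
#'   a hairpin (default 4).
#' @param hairpin_min_loop Minimum loop between stem arms (default 3).
#' @param dimer_min_run Minimum inter-molecular complementary run flagged as
#'   a dimer; runs reaching a 3' terminus are flagged at `dimer_min_run - 2`
#'   (default 5).
#' @param fixed Fixed primers screened against for hetero-dimers.
#' @return A `stace_primer_constraints` list.
#' @export
primer_constraints <- function(min_length = 17L, max_trim = 4L,
                               gc_min = 35, gc_max = 45,
                               tm_min = 55, tm_max = 65,
                               hairpin_min_stem = 4L, hairpin_min_loop = 3L,
                               dimer_min_run = 5L,
                               fixed = stace_fixed_primers()) {
  structure(list(min_length = min_length, max_trim = max_trim,
                 gc_min = gc_min, gc_max = gc_max,
                 tm_min = tm_min, tm_max = tm_max,
                 hairpin_min_stem = hairpin_min_stem,
                 hairpin_min_loop = hairpin_min_loop,
                 dimer_min_run = dimer_min_run, fixed = fixed),
            class = "stace_primer_constraints")
}

#' Hairpin screen
#'
#' Finds the longest pair of reverse-complementary substrings within one
#' sequence separated by at least `min_loop` bases (the stem of a potential
#' hairpin). Sequences shorter than `2 * min_stem + min_loop` cannot form a
#' qualifying hairpin and are clean by definition.
#'
#' @param sequence Primer sequence.
#' @param min_stem Stem length at or above which the sequence is flagged.
#' @param min_loop Minimum unpaired bases between the stem arms.
#' @return List with `stem` (longest stem found, 0 if none) and `flagged`.
#' @examples
#' hairpin_score("GGGGAAAACCCC")  # stem 4 (GGGG/CCCC), flagged
#' @export
hairpin_score <- function(sequence, min_stem = 4L, min_loop = 3L) {
  s <- toupper(sequence)
  n <- nchar(s)
  if (n < 2L * min_stem + min_loop) {
    return(list(stem = 0L, flagged = FALSE))
  }
  b <- strsplit(s, "")[[1L]]
  comp <- chartr("ACGTN", "TGCAN", b)
  best <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      ## arm1 starts at i, arm2 ends at j; extend stem outward:
      ## pair (i + l - 1) with (j - l + 1)
      l <- 0L
      while (i + l <= n && j - l >= 1L &&
             (j - l) - (i + l) - 1L >= min_loop &&
             b[i + l] == comp[j - l]) {
        l <- l + 1L
      }
      if (l > best) best <- l
    }
  }
  list(stem = best, flagged = best >= min_stem)
}

#' Dimer screen
#'
#' Longest ungapped complementary run between two sequences in antiparallel
#' orientation, over all alignment offsets. A run of `min_run` or more is
#' flagged; a run that includes either sequence's 3' terminus is flagged
#' already at `min_run - 2`, since 3'-anchored duplexes prime extension.
#' `dimer_score(s, s)` is the homodimer screen.
#'
#' @param seq_a,seq_b Primer sequences (non-empty).
#' @param min_run Flagging threshold for internal runs.
#' @return List with `run` (longest complementary run), `run_3prime`
#'   (longest run touching a 3' terminus) and `flagged`.
#' @export
dimer_score <- function(seq_a, seq_b, min_run = 5L) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("dimer_score(): empty sequence")
  a <- strsplit(toupper(seq_a), "")[[1L]]
  ## antiparallel pairing: a[i] pairs with b[j] when a[i] == complement(b[j]);
  ## scanning a against revcomp(b) turns this into positional equality
  c_rb <- strsplit(revcomp(seq_b), "")[[1L]]
  na <- length(a); nb <- length(c_rb)
  best <- 0L; best3 <- 0L
  for (shift in (-(nb - 1L)):(na - 1L)) {
    lo <- max(1L, 1L + shift); hi <- min(na, nb + shift)
    if (lo > hi) next
    run <- 0L
    for (i in lo:hi) {
      if (a[i] == c_rb[i - shift]) {
        run <- run + 1L
      } else if (run > 0L) {
        ## a's 3' end = position na; b's 3' end = position 1 of revcomp(b)
        if (run > best) best <- run
        if ((i - 1L) - run + 1L - shift == 1L && run > best3) best3 <- run
        run <- 0L
      }
    }
    if (run > 0L) {
      if (run > best) best <- run
      covers_a3 <- hi == na
      covers_b3 <- hi - run + 1L - shift == 1L
      if ((covers_a3 || covers_b3) && run > best3) best3 <- run
    }
  }
  flagged <- best >= min_run || best3 >= max(min_run - 2L, 1L)
  list(run = best, run_3prime = best3, flagged = flagged)
}

## SantaLucia (1998) unified nearest-neighbor parameters
## dH kcal/mol, dS cal/(mol K)
.nn_params <- local({
  dH <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4, CT = -7.8,
          GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0)
  dS <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
          CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9)
  rc <- function(p) {   # reverse complement of a dinucleotide step
    m <- c(A = "T", C = "G", G = "C", T = "A")
    paste0(m[[substr(p, 2L, 2L)]], m[[substr(p, 1L, 1L)]])
  }
  for (p in c("TT", "TG", "AC", "AG", "TC", "CC")) {
    dH[p] <- dH[rc(p)]
    dS[p] <- dS[rc(p)]
  }
  list(dH = dH, dS = dS)
})

#' Nearest-neighbor melting temperature
#'
#' Unified nearest-neighbor thermodynamics with duplex-initiation terms,
#' evaluated at PCR-like default conditions: 50 mM monovalent cation, 1.5 mM
#' Mg2+ and 0.6 mM dNTP (divalents folded into an equivalent monovalent
#' concentration by the conventional `120 * sqrt([Mg] - [dNTP])` term), and
#' 250 nM oligo. Deterministic; no structure folding.
#'
#' @param sequence Primer sequence, length >= 8.
#' @param Na Monovalent cation concentration, mol/L.
#' @param Mg Divalent cation concentration, mol/L.
#' @param dNTP dNTP concentration, mol/L (binds Mg2+).
#' @param conc Oligo concentration, mol/L.
#' @return Melting temperature in Celsius.
#' @export
tm_estimate <- function(sequence, Na = 0.05, Mg = 0.0015, dNTP = 0.0006,
                        conc = 250e-9) {
  s <- toupper(sequence)
  n <- nchar(s)
  if (n < 8L) stop("tm_estimate() needs length >= 8")
  if (grepl("[^ACGT]", s)) stop("tm_estimate(): sequence must be ACGT only")
  b <- strsplit(s, "")[[1L]]
  steps <- paste0(b[-n], b[-1L])
  dH <- sum(.nn_params$dH[steps])
  dS <- sum(.nn_params$dS[steps])
  for (term in b[c(1L, n)]) {   # initiation with terminal G.C / A.T
    if (term %in% c("G", "C")) {
      dH <- dH + 0.1; dS <- dS - 2.8
    } else {
      dH <- dH + 2.3; dS <- dS + 4.1
    }
  }
  na_eq <- Na + 120 * sqrt(max(Mg - dNTP, 0) * 1000) / 1000
  dS <- dS + 0.368 * (n - 1L) * log(na_eq)
  dH * 1000 / (dS + 1.987 * log(conc / 4)) - 273.15
}

#' Wallace-rule melting temperature
#'
#' `2(A+T) + 4(G+C)`, the classical quick estimate. Exposed as a coarse
#' sanity cross-check for [tm_estimate()] at primer-realistic lengths; it
#' substantially overestimates very short AT-rich oligos.
#'
#' @param sequence Primer sequence.
#' @return Temperature in Celsius.
#' @export
tm_wallace <- function(sequence) {
  b <- strsplit(toupper(sequence), "")[[1L]]
  2 * sum(b %in% c("A", "T")) + 4 * sum(b %in% c("G", "C"))
}

## screens one explicit primer sequence against all constraints
screen_primer <- function(primer, cn) {
  gc <- gc_content(primer)
  if (gc < cn$gc_min || gc > cn$gc_max) return(NULL)
  tm <- tm_estimate(primer)
  if (tm < cn$tm_min || tm > cn$tm_max) return(NULL)
  hp <- hairpin_score(primer, cn$hairpin_min_stem, cn$hairpin_min_loop)
  if (hp$flagged) return(NULL)
  homo <- dimer_score(primer, primer, cn$dimer_min_run)
  if (homo$flagged) return(NULL)
  for (f in c(cn$fixed$sl1, cn$fixed$universal)) {
    if (dimer_score(primer, f, cn$dimer_min_run)$flagged) return(NULL)
  }
  list(gc = gc, tm = tm, hairpin_stem = hp$stem, homodimer_run = homo$run)
}

#' Derive a gene-specific primer from a candidate tag
#'
#' The primer is the reverse complement of the tag, possibly after trimming
#' bases from either tag end to rescue primer quality. All `(left, right)`
#' trims with `left + right <= max_trim` and a resulting length of at least
#' `min_length` are searched; each candidate is screened on GC, Tm, hairpin,
#' homodimer, and heterodimer against the fixed SL1 and universal primers.
#' The accepted candidate is the one with minimal total trim (ties broken by
#' the smaller left trim, deterministically). Returns `NULL` when no trim
#' passes -- such tags cannot guide proper primer design and leave the
#' screen.
#'
#' @param tag Candidate tag sequence (CATG-anchored).
#' @param constraints A [primer_constraints()] object.
#' @return List (`primer`, `tag`, `trim_left`, `trim_right`, `gc`, `tm`,
#'   `hairpin_stem`, `homodimer_run`) or `NULL`.
#' @export
derive_primer <- function(tag, constraints = primer_constraints()) {
  cn <- constraints
  tag <- toupper(tag)
  L <- nchar(tag)
  for (total in 0L:cn$max_trim) {
    if (L - total < cn$min_length) break
    for (left in 0L:total) {
      right <- total - left
      core <- substr(tag, 1L + left, L - right)
      primer <- revcomp(core)
      res <- screen_primer(primer, cn)
      if (!is.null(res)) {
        return(c(list(primer = primer, tag = tag, trim_left = left,
                      trim_right = right), res))
      }
    }
  }
  NULL
}

#' Write a primer report
#'
#' One TSV row per tag: derived primer (or empty), trims, GC, Tm, structure
#' diagnostics and the verdict.
#'
#' @param tags Character vector of tags.
#' @param path Output TSV path.
#' @param constraints A [primer_constraints()] object.
#' @return The report data frame, invisibly.
#' @export
write_primer_report <- function(tags, path,
                                constraints = primer_constraints()) {
  rows <- lapply(tags, function(t) {
    pc <- derive_primer(t, constraints)
    if (is.null(pc)) {
      data.frame(tag = t, primer = NA_character_, trim_left = NA_integer_,
                 trim_right = NA_integer_, gc = NA_real_, tm = NA_real_,
                 hairpin_stem = NA_integer_, homodimer_run = NA_integer_,
                 verdict = "fail", stringsAsFactors = FALSE)
    } else {
      data.frame(tag = t, primer = pc$primer, trim_left = pc$trim_left,
                 trim_right = pc$trim_right, gc = pc$gc, tm = pc$tm,
                 hairpin_stem = pc$hairpin_stem,
                 homodimer_run = pc$homodimer_run, verdict = "pass",
                 stringsAsFactors = FALSE)
    }
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(tag = character(), primer = character(),
               trim_left = integer(), trim_right = integer(), gc = numeric(),
               tm = numeric(), hairpin_stem = integer(),
               homodimer_run = integer(), verdict = character(),
               stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
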
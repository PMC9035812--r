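# SSR (microsatellite) scanning restricted to short perfect tandem repeats.
# MIG-seq's first PCR targets four motif classes (ACT, TTG, GTG, GT); a primer
# anneals to either strand, so a motif class is the equivalence class of a
# motif under rotation and reverse complement.

.BASES <- c("A", "C", "G", "T")

.rotations <- function(m) {
  n <- nchar(m)
  vapply(0:(n - 1L), function(k) {
    paste0(substr(m, k + 1L, n), substr(m, 1L, k))
  }, character(1))
}

.revcomp <- function(m) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(m, "", fixed = TRUE)[[1]]), collapse = ""))
}

#' Motif families and canonical motif classes
#'
#' `motif_family()` lists all motifs equivalent to `m` under rotation (and,
#' with `strand_collapse = TRUE`, reverse complement). `canonical_motif()`
#' returns the lexicographically smallest member, the internal class key.
#' `motif_class()` maps motifs to a display class name: members of the four
#' targeted families are named by their conventional representative
#' (`"ACT"`, `"TTG"`, `"GTG"`, `"GT"`); anything else is named by its
#' canonical motif.
#'
#' @param m character vector of motifs (`A/C/G/T` only).
#' @param strand_collapse collapse reverse complements into one class
#'   (default `TRUE`; a primer anneals to either strand).
#' @param targets representatives whose families get named classes.
#' @return `motif_family()`: character vector of equivalent motifs.
#'   `canonical_motif()`/`motif_class()`: character vector parallel to `m`.
#' @export
#' @examples
#' motif_family("GT")           # GT, TG, AC, CA
#' canonical_motif("CA")        # "AC"
#' motif_class(c("CA", "AAG"))  # "GT", "AAG"-family canonical
motif_family <- function(m, strand_collapse = TRUE) {
  stopifnot(length(m) == 1L)
  fam <- .rotations(m)
  if (strand_collapse) fam <- c(fam, .rotations(.revcomp(m)))
  unique(fam)
}

#' @rdname motif_family
#' @export
canonical_motif <- function(m, strand_collapse = TRUE) {
  vapply(m, function(x) min(motif_family(x, strand_collapse)), character(1),
         USE.NAMES = FALSE)
}

#' @rdname motif_family
#' @export
motif_class <- function(m, strand_collapse = TRUE,
                        targets = c("ACT", "TTG", "GTG", "GT")) {
  map <- setNames(targets, canonical_motif(targets, strand_collapse))
  cn <- canonical_motif(m, strand_collapse)
  out <- unname(map[cn])
  out[is.na(out)] <- cn[is.na(out)]
  out
}

#' Scan sequences for perfect di- and tri-nucleotide SSRs
#'
#' Detects maximal perfect tandem repeats of 2-bp and 3-bp motifs, reports
#' them leftmost-first as 0-based half-open intervals, and canonicalises the
#' motif into a strand/rotation-collapsed class. Overlapping candidate runs
#' are resolved greedily by start coordinate (the longer run wins ties), so a
#' position belongs to at most one reported locus. Non-`ACGT` characters break
#' runs; scanning is case-insensitive. Mononucleotide runs (degenerate motifs
#' such as `AA` or `AAA`) are not reported.
#'
#' @param sequences named character vector of sequences, or a
#'   `Biostrings::DNAStringSet`.
#' @param min_repeats named integer vector: minimum repeat count per motif
#'   length. Default: di-nucleotide >= 7 repeats, tri-nucleotide >= 5.
#' @param strand_collapse collapse reverse-complement motifs into one class.
#' @return data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `motif_class`, `motif` (the literal repeat unit at the locus
#'   start), `repeat_count`. `end - start == repeat_count * nchar(motif)`;
#'   trailing partial motif copies are trimmed. Rows are sorted by
#'   `(chrom, start)` and the result is invariant to input chromosome order
#'   and sequence case.
#' @export
#' @examples
#' scan_ssrs(c(chr1 = "AAACACACACACACACACTTT"))
scan_ssrs <- function(sequences,
                      min_repeats = c(`2` = 7L, `3` = 5L),
                      strand_collapse = TRUE) {
  if (methods::is(sequences, "DNAStringSet")) {
    sequences <- setNames(as.character(sequences), names(sequences))
  }
  if (length(sequences) == 0L || all(nchar(sequences) == 0L)) {
    stop("empty FASTA: no sequences to scan")
  }
  stopifnot(is.character(sequences), !is.null(names(sequences)))
  periods <- as.integer(names(min_repeats))
  stopifnot(all(periods %in% c(2L, 3L)), all(min_repeats >= 2L))

  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), motif_class = character(),
                      motif = character(), repeat_count = integer(),
                      stringsAsFactors = FALSE)
  out <- list()
  for (chrom in sort(names(sequences))) {
    s <- toupper(sequences[[chrom]])
    n <- nchar(s)
    if (n < 4L) next
    xr <- charToRaw(s)
    valid <- xr == charToRaw("A") | xr == charToRaw("C") |
      xr == charToRaw("G") | xr == charToRaw("T")

    # candidate maximal periodic regions: 0-based start plus total length of
    # the periodic stretch (including a trailing partial motif copy)
    cand <- list()
    for (p in periods) {
      if (n < 2L * p) next
      min_rep <- as.integer(min_repeats[[as.character(p)]])
      eq <- (xr[seq_len(n - p)] == xr[(p + 1L):n]) & valid[seq_len(n - p)]
      r <- rle(eq)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      sel <- which(r$values & (r$lengths + p) >= p * min_rep)
      for (k in sel) {
        i <- starts[k]
        motif <- substr(s, i, i + p - 1L)
        ch <- strsplit(motif, "", fixed = TRUE)[[1]]
        if (length(unique(ch)) == 1L) next            # mononucleotide run
        cand[[length(cand) + 1L]] <- data.frame(
          start = i - 1L, total = r$lengths[k] + p, p = p,
          stringsAsFactors = FALSE)
      }
    }
    if (length(cand) == 0L) next
    cd <- do.call(rbind, cand)
    cd <- cd[order(cd$start, -cd$total), , drop = FALSE]
    # greedy left-to-right: a region that only partially overlaps an already
    # reported locus is trimmed to the first free position (every in-region
    # position starts a rotation of the motif), then kept if enough full
    # copies remain
    rows <- list()
    last_end <- 0L
    for (q in seq_len(nrow(cd))) {
      p <- cd$p[q]
      s0 <- max(cd$start[q], last_end)
      reps <- (cd$start[q] + cd$total[q] - s0) %/% p
      if (reps < as.integer(min_repeats[[as.character(p)]])) next
      motif <- substr(s, s0 + 1L, s0 + p)
      rows[[length(rows) + 1L]] <- data.frame(
        start = s0, end = s0 + reps * p, motif = motif, repeat_count = reps,
        stringsAsFactors = FALSE)
      last_end <- s0 + reps * p
    }
    if (length(rows) == 0L) next
    cd <- do.call(rbind, rows)
    out[[chrom]] <- data.frame(
      chrom = chrom, start = cd$start, end = cd$end,
      motif_class = motif_class(cd$motif, strand_collapse),
      motif = cd$motif, repeat_count = cd$repeat_count,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "strand_collapse") <- strand_collapse
  res
}

#' Count SSR loci of the targeted motif classes
#'
#' @param loci data.frame from [scan_ssrs()] (or a truth table with a
#'   `motif_class` column).
#' @param targets character vector of class names to count.
#' @return list with `counts` (named integer vector, one entry per target)
#'   and `total` (their sum).
#' @export
#' @examples
#' loci <- scan_ssrs(c(chr1 = strrep("GT", 10)))
#' count_targeted_ssrs(loci)
count_targeted_ssrs <- function(loci, targets = c("ACT", "TTG", "GTG", "GT")) {
  counts <- vapply(targets, function(t) sum(loci$motif_class == t),
                   integer(1))
  list(counts = counts, total = sum(counts))
}

#' Pearson correlation between two genome-level metrics
#'
#' Product-moment correlation with the usual t-based two-sided p-value, used
#' to relate SSR counts and mapped base counts to genome size.
#'
#' @param x,y numeric vectors of equal length (>= 3, finite).
#' @return list with `r`, `p` and `n`.
#' @export
#' @examples
#' correlate_metrics(1:10, 2 * (1:10) + rnorm(10, sd = 0.1))
correlate_metrics <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L,
            all(is.finite(x)), all(is.finite(y)))
  if (sd(x) == 0 || sd(y) == 0) {
    stop("undefined correlation: zero variance in x or y")
  }
  ct <- cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
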
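# Shared fixtures and independent oracles, all built in code at test time.

# small genotype matrix with explicit cells
gm_fix <- function(gt, dp = NULL, ad_ref = NULL, ad_alt = NULL,
                   qual = NA_real_, chrom = "chr1") {
  gt <- as.matrix(gt)
  ns <- nrow(gt)
  genotype_matrix(
    sites = data.frame(chrom = rep(chrom, ns), pos = seq_len(ns) * 10L,
                       ref = rep("A", ns), alt = rep("T", ns),
                       qual = rep(qual, length.out = max(ns, 0))[seq_len(ns)]),
    samples = sprintf("s%02d", seq_len(ncol(gt))),
    gt = gt, dp = dp, ad_ref = ad_ref, ad_alt = ad_alt)
}

# independent brute-force SSR oracle: per concrete motif, a lookahead perl
# regex enumerates EVERY start position offering >= k tandem copies (with the
# greedy match length captured); the published tie-break (leftmost-first,
# longest run wins ties at equal start, later candidates trimmed out by kept
# loci) is then applied to the complete candidate list
oracle_scan <- function(sequences, min_repeats = c(`2` = 7L, `3` = 5L),
                        strand_collapse = TRUE) {
  all_motifs <- function(p) {
    g <- do.call(expand.grid,
                 c(rep(list(c("A", "C", "G", "T")), p),
                   stringsAsFactors = FALSE))
    ms <- apply(g, 1, paste, collapse = "")
    ms[vapply(strsplit(ms, ""), function(ch) length(unique(ch)) > 1,
              logical(1))]
  }
  out <- list()
  for (chrom in sort(names(sequences))) {
    s <- toupper(sequences[[chrom]])
    cand <- list()
    for (p in c(2L, 3L)) {
      k <- min_repeats[[as.character(p)]]
      for (m in all_motifs(p)) {
        g <- gregexpr(paste0("(?=((?:", m, "){", k, ",}))"), s,
                      perl = TRUE)[[1]]
        if (g[1] == -1) next
        len <- as.integer(attr(g, "capture.length")[, 1])
        cand[[length(cand) + 1L]] <- data.frame(
          start = as.integer(g) - 1L, len = len, motif = m,
          repeat_count = len %/% p, stringsAsFactors = FALSE)
      }
    }
    if (!length(cand)) next
    cd <- do.call(rbind, cand)
    cd <- cd[order(cd$start, -cd$len), , drop = FALSE]
    keep <- logical(nrow(cd))
    last_end <- 0L
    for (q in seq_len(nrow(cd))) {
      if (cd$start[q] >= last_end) {
        keep[q] <- TRUE
        last_end <- cd$start[q] + cd$len[q]
      }
    }
    cd <- cd[keep, , drop = FALSE]
    out[[chrom]] <- data.frame(
      chrom = chrom, start = cd$start, end = cd$start + cd$len,
      motif_class = motif_class(cd$motif, strand_collapse),
      repeat_count = cd$repeat_count, stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), motif_class = character(),
                      repeat_count = integer()))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# random sequence with embedded tandem repeats (targeted and untargeted
# motifs), for fuzzing the scanner against the oracle
fuzz_sequence <- function(n, n_repeats = 20L) {
  s <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  motifs <- c("GT", "AC", "TG", "AG", "CT", "AT",
              "ACT", "TTG", "GTG", "AAG", "CCG", "ATC", "TAG", "CAA")
  for (k in seq_len(n_repeats)) {
    m <- sample(motifs, 1)
    reps <- sample(3:15, 1)
    unit <- strsplit(m, "")[[1]]
    len <- reps * length(unit)
    at <- sample.int(n - len - 1L, 1)
    s[at:(at + len - 1L)] <- rep(unit, reps)
  }
  paste(s, collapse = "")
}

# RIL-coded genotypes (0/2) for linkage tests, hets masked
ril_geno <- function(cross) {
  g <- cross$genotypes
  g[g == 1L] <- NA_integer_
  g
}

# parents differing at a regular marker grid, for cross/QTL fixtures
grid_parents <- function(chrom_lengths, spacing_bp) {
  pos <- lapply(names(chrom_lengths), function(ch) {
    p <- seq(spacing_bp, chrom_lengths[[ch]] - 1L, by = spacing_bp)
    data.frame(chrom = ch, pos = as.integer(p), ref = "A", alt = "T",
               stringsAsFactors = FALSE)
  })
  list(a = data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      stringsAsFactors = FALSE),
       b = do.call(rbind, pos))
}
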
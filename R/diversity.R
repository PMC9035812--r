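# All-pairs nucleotide diversity from genotypes plus depth masks, and the
# linear marker-count extrapolation used to judge whether a cross between two
# accessions can yield a linkage map of a desired size. Pairwise nucleotide
# diversity between two inbred accessions is the number of SNP differences
# divided by the number of bases jointly sequenced at DP >= 5 in both.

#' All-pairs nucleotide diversity
#'
#' For every unordered sample pair: `common_bases` counts genome positions
#' with depth >= `min_dp` in both samples; `snp_count` counts sites where both
#' samples have a (depth-passing) homozygous call and the alleles differ;
#' `pi = snp_count / common_bases`. Heterozygous calls are excluded by default
#' (inbred-line semantics); `het_mode = "half"` instead counts a hom-het
#' difference as 1/2.
#'
#' @param m a [genotype_matrix()].
#' @param depths named list of [per_base_depth()], one per sample of `m`.
#' @param min_dp joint depth threshold (default 5).
#' @param snps_only exclude indel sites (ref or alt longer than 1 bp).
#' @param het_mode `"exclude"` or `"half"`.
#' @param labels optional named character vector sample -> group, filling the
#'   `relation` column (`same`/`different`).
#' @return data.frame with one row per pair: `sample_a`, `sample_b`,
#'   `snp_count`, `common_bases`, `pi`, `flagged` (TRUE when
#'   `common_bases == 0`, in which case `pi` is `NA` rather than 0), and
#'   `relation` when labels are given. Symmetric in the pair and invariant to
#'   sample and site order.
#' @export
pairwise_diversity <- function(m, depths, min_dp = 5L, snps_only = TRUE,
                               het_mode = c("exclude", "half"),
                               labels = NULL) {
  het_mode <- match.arg(het_mode)
  stopifnot(inherits(m, "genotype_matrix"),
            all(m$samples %in% names(depths)))
  masks <- lapply(m$samples, function(s) {
    lapply(depths[[s]]$depths, function(v) v >= min_dp)
  })
  names(masks) <- m$samples

  keep_site <- if (snps_only) {
    nchar(m$sites$ref) == 1L & nchar(m$sites$alt) == 1L &
      !grepl(",", m$sites$alt, fixed = TRUE)
  } else rep(TRUE, n_sites(m))
  gtm <- m$gt
  low <- !(m$dp >= min_dp)
  low[is.na(low)] <- TRUE
  gtm[low] <- NA_integer_
  gtm <- gtm[keep_site, , drop = FALSE]

  smp <- sort(m$samples)
  pairs <- if (length(smp) >= 2) t(utils::combn(smp, 2)) else
    matrix(character(0), 0, 2)
  out <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    cb <- sum(mapply(function(a, b) sum(a & b), masks[[i]], masks[[j]]))
    gi <- gtm[, i]; gj <- gtm[, j]
    if (het_mode == "exclude") {
      ok <- !is.na(gi) & !is.na(gj) & gi != 1L & gj != 1L
      snp <- sum(gi[ok] != gj[ok])
    } else {
      ok <- !is.na(gi) & !is.na(gj)
      snp <- sum(abs(gi[ok] - gj[ok])) / 2
    }
    flagged <- cb == 0L
    out[[k]] <- data.frame(
      sample_a = i, sample_b = j, snp_count = as.numeric(snp),
      common_bases = as.integer(cb),
      pi = if (flagged) NA_real_ else snp / cb, flagged = flagged,
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(sample_a = character(), sample_b = character(),
               snp_count = numeric(), common_bases = integer(),
               pi = numeric(), flagged = logical())
  if (!is.null(labels)) {
    stopifnot(all(m$samples %in% names(labels)))
    res$relation <- ifelse(labels[res$sample_a] == labels[res$sample_b],
                           "same", "different")
  }
  rownames(res) <- NULL
  res
}

#' Minimum nucleotide diversity needed for a target marker count
#'
#' Assuming the number of polymorphisms between two accessions scales linearly
#' with their nucleotide diversity, the diversity needed to reach
#' `target_markers` given a reference cross that yielded `ref_markers` at
#' diversity `ref_pi` is `target_markers / ref_markers * ref_pi`.
#'
#' @param target_markers desired marker count (> 0).
#' @param ref_markers marker count of the reference linkage map (> 0).
#' @param ref_pi nucleotide diversity of the reference cross (> 0).
#' @return Predicted minimum diversity.
#' @export
#' @examples
#' predict_min_diversity(1000, 3257, 0.002548)  # ~0.000782
predict_min_diversity <- function(target_markers, ref_markers, ref_pi) {
  stopifnot(target_markers > 0, ref_markers > 0, ref_pi > 0)
  target_markers / ref_markers * ref_pi
}

#' Marker count predicted from nucleotide diversity
#'
#' Inverse of [predict_min_diversity()]: `pi / ref_pi * ref_markers`.
#'
#' @param pi nucleotide diversity of the candidate pair (>= 0).
#' @param ref_markers,ref_pi reference map marker count and diversity.
#' @return Predicted marker count.
#' @export
predict_marker_count <- function(pi, ref_markers, ref_pi) {
  stopifnot(pi >= 0, ref_markers > 0, ref_pi > 0)
  pi / ref_pi * ref_markers
}

#' Fraction of pairs above a diversity threshold, by group relation
#'
#' @param pairs result of [pairwise_diversity()].
#' @param labels named character vector sample -> group.
#' @param threshold diversity threshold; a pair counts when `pi > threshold`.
#' @return data.frame with one row per relation (`same`, `different`):
#'   `n_pairs`, `n_above`, `fraction` (`NA` and `flagged = TRUE` for an empty
#'   stratum).
#' @export
summarize_by_group <- function(pairs, labels, threshold) {
  stopifnot(all(c(pairs$sample_a, pairs$sample_b) %in% names(labels)))
  rel <- ifelse(labels[pairs$sample_a] == labels[pairs$sample_b],
                "same", "different")
  out <- lapply(c("same", "different"), function(r) {
    sel <- rel == r & !is.na(pairs$pi)
    n <- sum(sel)
    na <- sum(pairs$pi[sel] > threshold)
    data.frame(relation = r, n_pairs = n, n_above = na,
               fraction = if (n == 0) NA_real_ else na / n,
               flagged = n == 0, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
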
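# Virtual-F1 heterozygous-call accuracy. Read data from two homozygous
# parents, subsampled to a chosen amount and merged, constitutes an artificial
# F1 that is heterozygous at every parental-difference marker by construction.
# Calling genotypes on the merged allele depths with a minimum-depth threshold
# then yields, per (read amount, min DP) grid point, the error rate (truth-het
# markers called homozygous, because all retained reads happened to come from
# one parent) and the missing rate (markers below the depth threshold).

#' Hypergeometric thinning of marker-level depth counts
#'
#' Emulates subsampling `n_reads` reads without replacement from a library of
#' `total_reads`, at the marker-depth level: the vector of per-marker depths is
#' jointly multivariate-hypergeometrically thinned, so each marker's expected
#' depth scales by `n_reads / total_reads`.
#'
#' @param depths non-negative integer vector of per-marker depths.
#' @param n_reads reads to keep (0 <= `n_reads` <= `total_reads`).
#' @param total_reads library size; must be at least `sum(depths)` (reads not
#'   hitting any marker make up the difference). Default `sum(depths)`.
#' @param seed integer seed.
#' @return Integer vector of thinned depths, same length as `depths`.
#' @export
subsample_counts <- function(depths, n_reads, total_reads = sum(depths),
                             seed = 1L) {
  depths <- as.integer(depths)
  stopifnot(all(depths >= 0L), n_reads >= 0, total_reads >= sum(depths))
  if (n_reads > total_reads) stop("n_reads exceeds total_reads")
  if (n_reads == total_reads) return(depths)
  with_seed_(seed, {
    out <- integer(length(depths))
    remaining <- n_reads
    pop <- total_reads
    for (i in seq_along(depths)) {
      if (remaining == 0L) break
      x <- rhyper(1L, m = depths[i], n = pop - depths[i], k = remaining)
      out[i] <- x
      remaining <- remaining - x
      pop <- pop - depths[i]
    }
    out
  })
}

#' Merge subsampled parental depths into a virtual F1
#'
#' @param depth_a,depth_b per-marker depth vectors of parent A and parent B
#'   over the same marker universe (if named, names must match as sets).
#' @param replicate replicate identifier.
#' @return An object of class `virtual_f1`: list with `ad_a`, `ad_b`,
#'   `markers`, `replicate`. Total depth at a marker is the sum of the two
#'   parental depths; the truth genotype is heterozygous at every marker.
#' @export
make_virtual_f1 <- function(depth_a, depth_b, replicate = 1L) {
  if (!is.null(names(depth_a)) && !is.null(names(depth_b))) {
    if (!setequal(names(depth_a), names(depth_b))) {
      stop("parental depth tables cover different marker universes")
    }
    depth_b <- depth_b[names(depth_a)]
  } else if (length(depth_a) != length(depth_b)) {
    stop("parental depth tables cover different marker universes")
  }
  structure(list(ad_a = as.integer(depth_a), ad_b = as.integer(depth_b),
                 markers = names(depth_a) %||% seq_along(depth_a),
                 replicate = replicate),
            class = "virtual_f1")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Minimal allele-depth genotype caller
#'
#' The deliberately simple stand-in caller that makes the error/missing curves
#' reproducible: missing if `a + b < min_dp`; heterozygous if both alleles are
#' seen; otherwise homozygous for the observed allele.
#'
#' @param ad_a,ad_b non-negative integer allele depths (vectorised).
#' @param min_dp minimum total depth (>= 1).
#' @return Character vector in `{"hom_a", "het", "hom_b"}` with `NA` for
#'   missing.
#' @export
#' @examples
#' call_genotype(c(3, 4, 6), c(2, 0, 0), min_dp = 5)  # het, NA, hom_a
call_genotype <- function(ad_a, ad_b, min_dp = 1L) {
  stopifnot(min_dp >= 1, all(ad_a >= 0), all(ad_b >= 0),
            length(ad_a) == length(ad_b))
  out <- rep(NA_character_, length(ad_a))
  called <- ad_a + ad_b >= min_dp
  out[called & ad_a > 0 & ad_b > 0] <- "het"
  out[called & ad_a > 0 & ad_b == 0] <- "hom_a"
  out[called & ad_a == 0 & ad_b > 0] <- "hom_b"
  out
}

#' Error and missing rates of heterozygous calls over a min-DP grid
#'
#' Every marker of a virtual F1 is truth-heterozygous, so at each threshold
#' `error_rate` = homozygous calls / non-missing calls and `missing_rate` =
#' missing calls / all markers. Rates are reported per replicate and averaged.
#'
#' @param replicates list of [make_virtual_f1()] objects.
#' @param min_dp integer vector of thresholds (default `1:20`).
#' @return list of class `error_curve` with `per_replicate` (data.frame:
#'   `min_dp`, `replicate`, `n_markers`, `n_called`, `error_rate`,
#'   `missing_rate`, `flagged`) and `mean` (averaged over replicates).
#'   `error_rate` is `NA` and flagged where a replicate has zero non-missing
#'   calls. `missing_rate` is non-decreasing in `min_dp`.
#' @export
error_missing_curves <- function(replicates, min_dp = 1:20) {
  stopifnot(length(replicates) >= 1,
            all(vapply(replicates, inherits, logical(1), "virtual_f1")))
  rows <- list()
  for (f1 in replicates) {
    tot <- f1$ad_a + f1$ad_b
    nm <- length(tot)
    for (t in min_dp) {
      called <- tot >= t
      hom <- called & (f1$ad_a == 0L | f1$ad_b == 0L) & tot > 0L
      n_called <- sum(called)
      rows[[length(rows) + 1L]] <- data.frame(
        min_dp = t, replicate = f1$replicate, n_markers = nm,
        n_called = n_called,
        error_rate = if (n_called == 0L) NA_real_ else sum(hom) / n_called,
        missing_rate = (nm - n_called) / nm,
        flagged = n_called == 0L)
    }
  }
  per <- do.call(rbind, rows)
  rownames(per) <- NULL
  per_dt <- data.table::as.data.table(per)
  mean_dt <- per_dt[, list(
    error_rate = mean(error_rate, na.rm = TRUE),
    missing_rate = mean(missing_rate),
    n_called = sum(n_called), n_markers = sum(n_markers)),
    by = "min_dp"]
  structure(list(per_replicate = per, mean = as.data.frame(mean_dt)),
            class = "error_curve")
}

#' Analytic oracle for heterozygous-call error and missing rates
#'
#' Under the minimal caller and a perfect 1:1 allele split, a truth-het marker
#' of total depth `d` is called homozygous with probability `2^(1-d)` (all `d`
#' reads from one parent). Given a depth distribution `p(d)`:
#' `missing = sum_(d < t) p(d)` and
#' `error = sum_(d >= t) p(d) 2^(1-d) / sum_(d >= t) p(d)`.
#'
#' @param dist named numeric vector: names are depths, values probabilities
#'   summing to 1.
#' @param min_dp threshold (>= 1).
#' @return list with `error` (`NA` and `flagged = TRUE` when the distribution
#'   has no support at or above `min_dp`) and `missing`.
#' @export
#' @examples
#' analytic_het_error(c(`3` = 1), min_dp = 1)  # error 0.25
analytic_het_error <- function(dist, min_dp = 1L) {
  stopifnot(min_dp >= 1, !is.null(names(dist)),
            abs(sum(dist) - 1) < 1e-8, all(dist >= 0))
  d <- as.numeric(names(dist))
  above <- d >= min_dp
  denom <- sum(dist[above])
  missing <- sum(dist[!above])
  if (denom == 0) {
    return(list(error = NA_real_, missing = missing, flagged = TRUE))
  }
  err <- sum(dist[above] * 2^(1 - d[above])) / denom
  list(error = err, missing = missing, flagged = FALSE)
}

#' Full virtual-F1 error/missing grid
#'
#' Runs the whole procedure: for each read amount and replicate, both parents'
#' marker depths are hypergeometrically thinned to `reads_per_parent`, merged
#' into a virtual F1, and the error/missing curves computed over the `min_dp`
#' grid.
#'
#' @param depth_a,depth_b full-library per-marker depth vectors of the two
#'   parents.
#' @param reads_per_parent integer vector of per-parent subsample sizes (the
#'   virtual F1 then holds twice that amount).
#' @param total_reads_a,total_reads_b library sizes (default `sum(depths)`).
#' @param n_replicates independent replicates per read amount (default 8).
#' @param min_dp threshold grid (default `1:20`).
#' @param seed integer seed.
#' @return data.frame in long format: `reads_per_parent`, `reads_per_f1`,
#'   `min_dp`, `replicate`, `error_rate`, `missing_rate`, `n_called`,
#'   `n_markers`, `flagged`.
#' @export
virtual_f1_grid <- function(depth_a, depth_b, reads_per_parent,
                            total_reads_a = sum(depth_a),
                            total_reads_b = sum(depth_b),
                            n_replicates = 8L, min_dp = 1:20, seed = 1L) {
  out <- list()
  for (li in seq_along(reads_per_parent)) {
    n <- reads_per_parent[li]
    reps <- lapply(seq_len(n_replicates), function(r) {
      sa <- subsample_counts(depth_a, n, total_reads_a,
                             seed = derive_seed(seed, li * 1000L + r * 2L))
      sb <- subsample_counts(depth_b, n, total_reads_b,
                             seed = derive_seed(seed, li * 1000L + r * 2L + 1L))
      make_virtual_f1(sa, sb, replicate = r)
    })
    curves <- error_missing_curves(reps, min_dp)$per_replicate
    curves$reads_per_parent <- n
    curves$reads_per_f1 <- 2 * n
    out[[li]] <- curves
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("reads_per_parent", "reads_per_f1", "min_dp", "replicate",
          "error_rate", "missing_rate", "n_called", "n_markers", "flagged")]
}
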
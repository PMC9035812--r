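#' Genotype matrix container
#'
#' Sites-by-samples genotype calls with per-cell total depth (DP) and
#' per-allele depths (AD), the in-memory equivalent of a biallelic multi-sample
#' VCF with `GT:AD:DP` genotype fields. Genotypes are coded as the count of
#' alternate alleles: `0` = homozygous reference, `1` = heterozygous, `2` =
#' homozygous alternate, `NA` = missing. Sites are kept sorted by
#' `(chrom, pos)`.
#'
#' @param sites data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`, and optionally `qual` (site quality; `NA` allowed).
#' @param samples character vector of sample names.
#' @param gt integer matrix `nrow(sites) x length(samples)` of genotype codes
#'   in `{0, 1, 2, NA}`.
#' @param dp,ad_ref,ad_alt optional integer matrices of the same shape: total
#'   depth and per-allele depths. `sum(AD) <= DP` is enforced cell-wise.
#' @return An object of class `genotype_matrix`: a list with elements `sites`,
#'   `samples`, `gt`, `dp`, `ad_ref`, `ad_alt`.
#' @export
#' @examples
#' m <- genotype_matrix(
#'   sites = data.frame(chrom = "chr1", pos = c(10L, 20L), ref = "A", alt = "T"),
#'   samples = c("s1", "s2"),
#'   gt = matrix(c(0L, 2L, 1L, NA), 2, 2)
#' )
#' n_sites(m)
genotype_matrix <- function(sites, samples, gt, dp = NULL, ad_ref = NULL,
                            ad_alt = NULL) {
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "ref", "alt") %in% names(sites)))
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  if (is.null(sites$qual)) sites$qual <- NA_real_
  sites <- sites[, c("chrom", "pos", "ref", "alt", "qual")]
  sites$chrom <- as.character(sites$chrom)
  sites$pos <- as.integer(sites$pos)
  sites$ref <- as.character(sites$ref)
  sites$alt <- as.character(sites$alt)
  sites$qual <- as.numeric(sites$qual)
  samples <- as.character(samples)
  ns <- nrow(sites)
  nn <- length(samples)

  shape <- function(x, what) {
    if (is.null(x)) x <- rep(NA_integer_, ns * nn)
    x <- matrix(as.integer(x), nrow = ns, ncol = nn)
    colnames(x) <- samples
    rownames(x) <- NULL
    x
  }
  gt <- shape(gt, "gt")
  if (!all(gt %in% c(0L, 1L, 2L, NA))) {
    stop("genotype codes must be 0, 1, 2 or NA")
  }
  dp <- shape(dp, "dp")
  ad_ref <- shape(ad_ref, "ad_ref")
  ad_alt <- shape(ad_alt, "ad_alt")
  if (any(dp < 0L, na.rm = TRUE)) stop("DP must be non-negative")
  adsum <- ad_ref + ad_alt
  if (any(adsum > dp, na.rm = TRUE)) stop("sum(AD) must not exceed DP")

  ord <- order(sites$chrom, sites$pos)
  m <- structure(list(
    sites = sites[ord, , drop = FALSE],
    samples = samples,
    gt = gt[ord, , drop = FALSE],
    dp = dp[ord, , drop = FALSE],
    ad_ref = ad_ref[ord, , drop = FALSE],
    ad_alt = ad_alt[ord, , drop = FALSE]
  ), class = "genotype_matrix")
  rownames(m$sites) <- NULL
  m
}

#' @rdname genotype_matrix
#' @param m a `genotype_matrix`.
#' @export
n_sites <- function(m) nrow(m$sites)

#' @rdname genotype_matrix
#' @export
n_samples <- function(m) length(m$samples)

#' @rdname genotype_matrix
#' @export
site_keys <- function(m) paste(m$sites$chrom, m$sites$pos, sep = ":")

#' Subset a genotype matrix by sites or samples
#'
#' @param m a [genotype_matrix()].
#' @param i logical/integer index over sites, or character site keys
#'   (`"chrom:pos"`).
#' @return A `genotype_matrix` restricted to the requested rows/columns.
#' @export
gm_subset_sites <- function(m, i) {
  if (is.character(i)) i <- site_keys(m) %in% i
  genotype_matrix(m$sites[i, , drop = FALSE], m$samples,
                  m$gt[i, , drop = FALSE], m$dp[i, , drop = FALSE],
                  m$ad_ref[i, , drop = FALSE], m$ad_alt[i, , drop = FALSE])
}

#' @rdname gm_subset_sites
#' @param j logical/integer index over samples, or sample names.
#' @export
gm_subset_samples <- function(m, j) {
  if (is.character(j)) j <- match(j, m$samples)
  genotype_matrix(m$sites, m$samples[j],
                  m$gt[, j, drop = FALSE], m$dp[, j, drop = FALSE],
                  m$ad_ref[, j, drop = FALSE], m$ad_alt[, j, drop = FALSE])
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d sites x %d samples\n", n_sites(x),
              n_samples(x)))
  cat(sprintf("  missing: %.1f%%\n", 100 * mean(is.na(x$gt))))
  invisible(x)
}

#' Per-base depth container
#'
#' Dense per-position coverage depths for one sample over a genome, the
#' in-memory form of a 3-column depth table (chrom, 1-based position, depth)
#' as produced by per-base depth export of alignment toolkits. Positions
#' absent from such a table are depth 0.
#'
#' @param depths named list (one element per chromosome) of non-negative
#'   integer vectors; element `i` is the depth at 1-based position `i`.
#' @param sample sample name.
#' @param raw_read_gb gigabases of raw read data behind this sample, used by
#'   [normalize_per_half_gb()]. `NA` if unknown.
#' @return An object of class `per_base_depth`.
#' @export
per_base_depth <- function(depths, sample = "sample", raw_read_gb = NA_real_) {
  stopifnot(is.list(depths), !is.null(names(depths)),
            !anyDuplicated(names(depths)))
  depths <- lapply(depths, function(d) {
    d <- as.integer(d)
    if (anyNA(d) || any(d < 0L)) stop("depths must be non-negative integers")
    d
  })
  structure(list(sample = as.character(sample), depths = depths,
                 raw_read_gb = as.numeric(raw_read_gb)),
            class = "per_base_depth")
}

#' @export
print.per_base_depth <- function(x, ...) {
  cat(sprintf("per_base_depth: sample '%s', %d chromosome(s), %d bp\n",
              x$sample, length(x$depths), sum(lengths(x$depths))))
  invisible(x)
}

#' Marker set (QC provenance)
#'
#' The set of sites accepted by a genotype-matrix filter, together with a
#' per-site verdict table recording which sub-filters passed and the filter
#' parameters used.
#'
#' @param keys character vector of accepted site keys (`"chrom:pos"`).
#' @param table data.frame with one row per candidate site and logical verdict
#'   columns (must contain a `key` and a `pass` column).
#' @param params list of the filter parameters (provenance).
#' @return An object of class `marker_set`.
#' @export
marker_set <- function(keys, table, params = list()) {
  stopifnot(all(c("key", "pass") %in% names(table)),
            all(keys %in% table$key))
  structure(list(keys = keys, table = table, params = params),
            class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("marker_set: %d / %d sites pass\n", length(x$keys),
              nrow(x$table)))
  invisible(x)
}

#' Restrict a genotype matrix to a marker set
#'
#' @param m a [genotype_matrix()].
#' @param ms a [marker_set()].
#' @return The genotype matrix restricted to the accepted sites.
#' @export
apply_marker_set <- function(m, ms) {
  stopifnot(inherits(ms, "marker_set"))
  gm_subset_sites(m, site_keys(m) %in% ms$keys)
}
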
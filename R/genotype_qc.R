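# Genotype-matrix quality control: depth masking, site and individual
# missingness filters, heterozygote handling, site quality, and
# parental-replicate consistency. Filters only drop or mask cells; a retained
# genotype value is never altered.

#' Mask low-depth genotype cells
#'
#' Converts genotype calls with insufficient depth to missing. The two
#' comparators mirror the two population presets: an F2 rule masking
#' `DP < 10` (`comparator = "lt"`, `min_dp = 10`) and a RIL rule masking
#' `DP <= 5` (`comparator = "le"`, `min_dp = 5`).
#'
#' @param m a [genotype_matrix()].
#' @param min_dp depth threshold (>= 1).
#' @param comparator `"lt"`: mask cells with `DP < min_dp`; `"le"`: mask cells
#'   with `DP <= min_dp`. Cells with unknown DP are masked.
#' @return The masked `genotype_matrix`; DP/AD are left untouched.
#' @export
mask_low_depth <- function(m, min_dp, comparator = c("lt", "le")) {
  stopifnot(inherits(m, "genotype_matrix"), min_dp >= 1)
  comparator <- match.arg(comparator)
  low <- if (comparator == "lt") m$dp < min_dp else m$dp <= min_dp
  low[is.na(low)] <- TRUE
  m$gt[low] <- NA_integer_
  m
}

#' Filter sites by genotype rate, heterozygote content and quality
#'
#' The genotype rate of a site is the fraction of individuals with a
#' non-missing call. A site is kept iff its rate clears `min_genotype_rate`
#' (strict `>` by default, matching "more than 97%"; `rate_comparator = "ge"`
#' with a threshold of 1 expresses a "no missing genotypes" filter), its
#' quality is at least `min_site_quality`, it carries no heterozygous call
#' when `remove_any_het`, and it is biallelic when `biallelic_only`.
#'
#' @param m a [genotype_matrix()].
#' @param min_genotype_rate fraction in `[0, 1]`.
#' @param remove_any_het drop sites with any heterozygous call.
#' @param min_site_quality minimum site quality (`-Inf` disables; sites with
#'   unknown quality fail any finite threshold).
#' @param biallelic_only drop sites with multiple alternate alleles.
#' @param rate_comparator `"gt"` (strict, default) or `"ge"`.
#' @return A [marker_set()] whose verdict table has one row per site.
#' @export
filter_sites <- function(m, min_genotype_rate = 0, remove_any_het = FALSE,
                         min_site_quality = -Inf, biallelic_only = FALSE,
                         rate_comparator = c("gt", "ge")) {
  stopifnot(inherits(m, "genotype_matrix"),
            min_genotype_rate >= 0, min_genotype_rate <= 1)
  rate_comparator <- match.arg(rate_comparator)
  rate <- rowMeans(!is.na(m$gt))
  pass_rate <- if (rate_comparator == "gt") rate > min_genotype_rate else
    rate >= min_genotype_rate
  n_het <- rowSums(m$gt == 1L, na.rm = TRUE)
  pass_het <- if (remove_any_het) n_het == 0L else rep(TRUE, n_sites(m))
  qual <- m$sites$qual
  pass_qual <- if (is.finite(min_site_quality)) {
    !is.na(qual) & qual >= min_site_quality
  } else rep(TRUE, n_sites(m))
  pass_biallelic <- if (biallelic_only) !grepl(",", m$sites$alt, fixed = TRUE)
    else rep(TRUE, n_sites(m))
  pass <- pass_rate & pass_het & pass_qual & pass_biallelic
  tab <- data.frame(key = site_keys(m), genotype_rate = rate, n_het = n_het,
                    qual = qual, pass_rate = pass_rate, pass_het = pass_het,
                    pass_qual = pass_qual, pass_biallelic = pass_biallelic,
                    pass = pass, stringsAsFactors = FALSE)
  marker_set(tab$key[pass], tab,
             params = list(min_genotype_rate = min_genotype_rate,
                           rate_comparator = rate_comparator,
                           remove_any_het = remove_any_het,
                           min_site_quality = min_site_quality,
                           biallelic_only = biallelic_only))
}

#' Remove individuals with excessive missingness
#'
#' Samples whose fraction of missing genotypes exceeds `max_missing_fraction`
#' are removed; survivors are untouched.
#'
#' @param m a [genotype_matrix()].
#' @param max_missing_fraction bound in `[0, 1]`.
#' @return The filtered `genotype_matrix`; removed sample names are attached
#'   as attribute `"removed"`.
#' @export
filter_individuals <- function(m, max_missing_fraction) {
  stopifnot(inherits(m, "genotype_matrix"),
            max_missing_fraction >= 0, max_missing_fraction <= 1)
  miss <- colMeans(is.na(m$gt))
  keep <- miss <= max_missing_fraction
  if (!any(keep)) stop("all samples exceed the missingness bound")
  out <- gm_subset_samples(m, which(keep))
  attr(out, "removed") <- m$samples[!keep]
  out
}

# per-site replicate consensus; NA where replicates conflict (or, in strict
# mode, where any replicate is missing)
.replicate_consensus <- function(gt, strict) {
  apply(gt, 1L, function(x) {
    if (strict) {
      if (anyNA(x) || length(unique(x)) != 1L) NA_integer_ else x[1]
    } else {
      x <- x[!is.na(x)]
      if (length(x) == 0L || length(unique(x)) != 1L) NA_integer_ else x[1]
    }
  })
}

#' Markers consistent across parental replicates and polymorphic between
#' parents
#'
#' Two modes: `"strict"` requires every replicate of a parent to be
#' non-missing and identical; `"lenient"` requires the non-missing replicates
#' (at least one) to be identical. In both modes the two parental consensus
#' genotypes must differ.
#'
#' @param replicates_a,replicates_b [genotype_matrix()] objects holding the
#'   replicate samples of parent A and parent B (>= 2 replicates each); their
#'   site lists are intersected.
#' @param mode `"strict"` or `"lenient"`.
#' @return A [marker_set()]; the verdict table carries the parental consensus
#'   genotypes (`consensus_a`, `consensus_b`).
#' @export
parental_marker_set <- function(replicates_a, replicates_b,
                                mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  stopifnot(inherits(replicates_a, "genotype_matrix"),
            inherits(replicates_b, "genotype_matrix"),
            n_samples(replicates_a) >= 2, n_samples(replicates_b) >= 2)
  keys <- intersect(site_keys(replicates_a), site_keys(replicates_b))
  if (length(keys) == 0L) stop("parental replicate matrices share no sites")
  a <- gm_subset_sites(replicates_a, keys)
  b <- gm_subset_sites(replicates_b, keys)
  stopifnot(identical(site_keys(a), site_keys(b)))
  strict <- mode == "strict"
  ca <- .replicate_consensus(a$gt, strict)
  cb <- .replicate_consensus(b$gt, strict)
  pass <- !is.na(ca) & !is.na(cb) & ca != cb
  tab <- data.frame(key = site_keys(a), consensus_a = ca, consensus_b = cb,
                    pass = pass, stringsAsFactors = FALSE)
  marker_set(tab$key[pass], tab, params = list(mode = mode))
}

#' Convert heterozygous calls to missing
#'
#' Applied to RIL data, where residual heterozygotes are treated as missing
#' before mapping. Idempotent; homozygous cells are untouched.
#'
#' @param m a [genotype_matrix()].
#' @return The converted `genotype_matrix`.
#' @export
het_to_missing <- function(m) {
  stopifnot(inherits(m, "genotype_matrix"))
  m$gt[m$gt == 1L] <- NA_integer_
  m
}

#' Population QC presets
#'
#' The three filter stacks used for a diversity panel, an F2 population and a
#' RIL population:
#' * `panel`: mask `DP < 5`, keep fully genotyped biallelic sites with site
#'   quality >= 30 and zero heterozygous calls.
#' * `f2`: mask `DP < 10`, drop individuals missing > 5% of sites, keep sites
#'   genotyped in more than 97% of individuals.
#' * `ril`: mask `DP <= 5`, drop individuals missing > 10%, convert residual
#'   heterozygotes to missing, keep sites genotyped in more than 95%.
#'
#' @param m a [genotype_matrix()].
#' @param population `"panel"`, `"f2"` or `"ril"`.
#' @return list with the filtered `matrix`, the site-level `marker_set`, and
#'   `removed_individuals`.
#' @export
run_qc <- function(m, population = c("panel", "f2", "ril")) {
  population <- match.arg(population)
  removed <- character(0)
  if (population == "panel") {
    m2 <- mask_low_depth(m, 5L, "lt")
    ms <- filter_sites(m2, min_genotype_rate = 1, rate_comparator = "ge",
                       remove_any_het = TRUE, min_site_quality = 30,
                       biallelic_only = TRUE)
  } else if (population == "f2") {
    m2 <- mask_low_depth(m, 10L, "lt")
    m2 <- filter_individuals(m2, 0.05)
    removed <- attr(m2, "removed")
    ms <- filter_sites(m2, min_genotype_rate = 0.97, rate_comparator = "gt")
  } else {
    m2 <- mask_low_depth(m, 5L, "le")
    m2 <- filter_individuals(m2, 0.10)
    removed <- attr(m2, "removed")
    m2 <- het_to_missing(m2)
    ms <- filter_sites(m2, min_genotype_rate = 0.95, rate_comparator = "gt")
  }
  list(matrix = apply_marker_set(m2, ms), marker_set = ms,
       removed_individuals = removed)
}
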
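# Two-point linkage statistics (recombination fraction, Kosambi distance, map
# summaries, segregation distortion) and a single-marker QTL scan with a
# permutation-derived LOD threshold. Marker grouping/ordering heuristics are
# deliberately out of scope: maps are summarised over a supplied order
# (physical order by default).

#' Two-point recombination fraction
#'
#' F2 (co-dominant): maximum-likelihood estimate by expectation-maximisation
#' over the 3 x 3 joint genotype table, treating the double heterozygote as a
#' mixture of 0 and 2 recombinant gametes. RIL (selfed to fixation):
#' the observed fraction `R` of recombinant lines among jointly homozygous
#' calls is mapped back by `r = R / (2 - 2R)`.
#'
#' @param g1,g2 integer genotype vectors at the two markers (codes 0/1/2,
#'   `NA` missing), one entry per individual.
#' @param population `"F2"` or `"RIL"`.
#' @param max_iter,tol EM controls (F2 only).
#' @return Estimated recombination fraction in `[0, 0.5]`; `NA` with attribute
#'   `flag` when a marker is monomorphic or fewer than 10 individuals are
#'   jointly genotyped.
#' @export
#' @examples
#' recombination_fraction(c(0, 0, 2, 2, 0, 2, 0, 2, 0, 2),
#'                        c(0, 0, 2, 2, 0, 2, 0, 2, 2, 0), "RIL")
recombination_fraction <- function(g1, g2, population = c("F2", "RIL"),
                                   max_iter = 100L, tol = 1e-10) {
  population <- match.arg(population)
  stopifnot(length(g1) == length(g2))
  ok <- !is.na(g1) & !is.na(g2)
  flagged <- function(flag) {
    r <- NA_real_; attr(r, "flag") <- flag; r
  }
  if (sum(ok) < 10L) return(flagged("fewer than 10 jointly genotyped"))
  a <- g1[ok]; b <- g2[ok]
  if (length(unique(a)) < 2L || length(unique(b)) < 2L) {
    return(flagged("monomorphic marker"))
  }
  if (population == "RIL") {
    hom <- a != 1L & b != 1L
    if (sum(hom) == 0L) return(flagged("no jointly homozygous calls"))
    R <- mean(a[hom] != b[hom])
    r <- R / (2 - 2 * R)
    return(max(0, min(r, 0.5)))
  }
  # F2 EM; recombinant-gamete count per joint genotype class
  n <- table(factor(a, 0:2), factor(b, 0:2))
  rec <- matrix(c(0, 1, 2,
                  1, NA, 1,
                  2, 1, 0), 3, 3, byrow = TRUE)
  N <- sum(n)
  r <- 0.25
  for (it in seq_len(max_iter)) {
    e11 <- 2 * r^2 / (r^2 + (1 - r)^2)   # E[rec gametes | double het]
    total <- sum(n * rec, na.rm = TRUE) + n[2, 2] * e11
    r_new <- min(max(total / (2 * N), 1e-9), 0.4999999)
    if (abs(r_new - r) < tol) {
      r <- r_new
      break
    }
    r <- r_new
  }
  max(0, min(r, 0.5))
}

#' Kosambi and Haldane mapping functions
#'
#' `kosambi_cM(r) = 25 * ln((1 + 2r) / (1 - 2r))`;
#' `haldane_cM(r) = -50 * ln(1 - 2r)`. Both are strictly increasing on
#' `[0, 0.5)` and `kosambi_cM(r) <= haldane_cM(r)`.
#'
#' @param r recombination fraction(s) in `[0, 0.5)`.
#' @return Genetic distance(s) in centimorgan.
#' @export
#' @examples
#' kosambi_cM(0.1)   # 25 * log(1.5)
#' kosambi_cM(0.25)  # 25 * log(3)
kosambi_cM <- function(r) {
  stopifnot(all(r >= 0))
  if (any(r >= 0.5)) stop("r >= 0.5: genetic distance is infinite")
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' @rdname kosambi_cM
#' @export
haldane_cM <- function(r) {
  stopifnot(all(r >= 0))
  if (any(r >= 0.5)) stop("r >= 0.5: genetic distance is infinite")
  -50 * log(1 - 2 * r)
}

# inverse Kosambi: cM -> r
.kosambi_r <- function(d) tanh(d / 50) / 2

#' Ordered linkage map container
#'
#' @param table data.frame with columns `group` (linkage group), `marker`,
#'   `pos_bp` (physical position) and `cM` (cumulative genetic position,
#'   non-decreasing within each group).
#' @return An object of class `ordered_map`.
#' @export
ordered_map <- function(table) {
  stopifnot(all(c("group", "marker", "cM") %in% names(table)))
  for (g in unique(table$group)) {
    cm <- table$cM[table$group == g]
    if (is.unsorted(cm)) stop(sprintf("cM not non-decreasing in group %s", g))
  }
  structure(list(table = table), class = "ordered_map")
}

#' Linkage map summary
#'
#' Total map length (summed last cM over linkage groups), marker count, and
#' average marker spacing. Spacing follows the `length / markers` convention
#' (not `length / (markers - groups)`), which is the convention under which
#' published totals and spacings are mutually consistent.
#'
#' @param map an [ordered_map()], or the total map length in cM (with
#'   `n_markers` supplied).
#' @param ... passed on.
#' @return list with `total_cM`, `n_markers`, `n_groups`, `avg_spacing_cM`.
#' @export
#' @examples
#' map_summary(5022.0, 3257)$avg_spacing_cM  # ~1.54
map_summary <- function(map, ...) UseMethod("map_summary")

#' @rdname map_summary
#' @export
map_summary.ordered_map <- function(map, ...) {
  tb <- map$table
  total <- sum(tapply(tb$cM, tb$group, max))
  list(total_cM = total, n_markers = nrow(tb),
       n_groups = length(unique(tb$group)),
       avg_spacing_cM = total / nrow(tb))
}

#' @rdname map_summary
#' @param n_markers marker count (numeric-map form).
#' @param n_groups number of linkage groups (numeric-map form; informational).
#' @export
map_summary.numeric <- function(map, n_markers, n_groups = NA_integer_, ...) {
  stopifnot(length(map) == 1, map >= 0, n_markers >= 1)
  list(total_cM = map, n_markers = n_markers, n_groups = n_groups,
       avg_spacing_cM = map / n_markers)
}

#' Build a two-point linkage map over a supplied marker order
#'
#' Estimates the recombination fraction between consecutive markers (physical
#' order within each chromosome/group), converts to Kosambi distances, and
#' accumulates genetic positions. Adjacent pairs whose estimate is undefined
#' or unlinked (`r = 0.5`) contribute a capped distance and are flagged.
#'
#' @param geno individuals x markers integer matrix (codes 0/1/2, `NA`).
#' @param markers data.frame with columns `chrom` and `pos` (one row per
#'   column of `geno`, same order).
#' @param population `"F2"` or `"RIL"`.
#' @param max_r cap on adjacent recombination fractions (default 0.4999).
#' @return list with `map` (an [ordered_map()]) and `two_point` (data.frame of
#'   adjacent-pair estimates: `group`, `marker1`, `marker2`, `r`, `cM`,
#'   `flagged`).
#' @export
build_linkage_map <- function(geno, markers, population = c("F2", "RIL"),
                              max_r = 0.4999) {
  population <- match.arg(population)
  stopifnot(ncol(geno) == nrow(markers))
  key <- paste(markers$chrom, markers$pos, sep = ":")
  ord <- order(markers$chrom, markers$pos)
  rows <- list(); tp <- list()
  for (g in unique(markers$chrom[ord])) {
    idx <- ord[markers$chrom[ord] == g]
    cm <- numeric(length(idx))
    if (length(idx) > 1) {
      for (k in 2:length(idx)) {
        r <- recombination_fraction(geno[, idx[k - 1]], geno[, idx[k]],
                                    population)
        fl <- !is.na(attr(r, "flag") %||% NA)
        rr <- if (is.na(r)) max_r else min(r, max_r)
        d <- kosambi_cM(rr)
        cm[k] <- cm[k - 1] + d
        tp[[length(tp) + 1L]] <- data.frame(
          group = g, marker1 = key[idx[k - 1]], marker2 = key[idx[k]],
          r = as.numeric(r), cM = d, flagged = fl || is.na(r),
          stringsAsFactors = FALSE)
      }
    }
    rows[[g]] <- data.frame(group = g, marker = key[idx],
                            pos_bp = markers$pos[idx], cM = cm,
                            stringsAsFactors = FALSE)
  }
  map_tb <- do.call(rbind, rows)
  rownames(map_tb) <- NULL
  two_point <- if (length(tp)) do.call(rbind, tp) else
    data.frame(group = character(), marker1 = character(),
               marker2 = character(), r = numeric(), cM = numeric(),
               flagged = logical())
  list(map = ordered_map(map_tb), two_point = two_point)
}

#' Segregation distortion test
#'
#' Pearson chi-squared test of observed genotype counts against a Mendelian
#' expectation (1:2:1 for F2 over codes 0/1/2; 1:1 for fixed RILs over codes
#' 0/2), per marker, among non-missing calls.
#'
#' @param geno individuals x markers integer matrix (codes 0/1/2, `NA`), or a
#'   vector for a single marker.
#' @param expected expected ratio: length 3 (classes 0, 1, 2) or length 2
#'   (classes 0, 2).
#' @return data.frame with one row per marker: `marker`, `n`, `chisq`, `df`,
#'   `p` (`NA` when no non-missing calls).
#' @export
#' @examples
#' segregation_distortion(matrix(rep(c(0, 1, 1, 2), 25)), expected = c(1, 2, 1))
segregation_distortion <- function(geno, expected = c(1, 2, 1)) {
  if (is.vector(geno)) geno <- matrix(geno, ncol = 1)
  stopifnot(length(expected) %in% c(2L, 3L), all(expected > 0))
  classes <- if (length(expected) == 3L) c(0L, 1L, 2L) else c(0L, 2L)
  p_exp <- expected / sum(expected)
  out <- lapply(seq_len(ncol(geno)), function(j) {
    x <- geno[, j]
    x <- x[!is.na(x)]
    n <- length(x)
    if (n == 0L) {
      return(data.frame(marker = j, n = 0L, chisq = NA_real_,
                        df = length(classes) - 1L, p = NA_real_))
    }
    obs <- vapply(classes, function(cl) sum(x == cl), integer(1))
    e <- n * p_exp
    chisq <- sum((obs - e)^2 / e)
    data.frame(marker = j, n = n, chisq = chisq, df = length(classes) - 1L,
               p = pchisq(chisq, df = length(classes) - 1L,
                          lower.tail = FALSE))
  })
  res <- do.call(rbind, out)
  if (!is.null(colnames(geno))) res$marker <- colnames(geno)
  rownames(res) <- NULL
  res
}

# vectorised per-marker simple-regression statistics.
# G: n x m additive codes (+1/0/-1, NA allowed); Y: n x P phenotype columns.
# returns list(lod (m x P), slope (m x P), r2 (m x P), n (m x P), mono (m))
.marker_stats <- function(G, Y) {
  W <- !is.na(G)
  G0 <- G
  G0[!W] <- 0
  storage.mode(W) <- "double"
  nj <- crossprod(W, Y^0)                 # m x P counts of usable pairs
  Sg <- crossprod(G0, Y^0)                # sum of codes where y observed
  Sgg <- crossprod(G0^2, Y^0)
  Sy <- crossprod(W, Y)
  Syy <- crossprod(W, Y^2)
  Sgy <- crossprod(G0, Y)
  den_g <- nj * Sgg - Sg^2
  den_y <- nj * Syy - Sy^2
  num <- nj * Sgy - Sg * Sy
  mono <- den_g <= 0
  r2 <- num^2 / (den_g * den_y)
  r2[mono | den_y <= 0] <- 0
  r2 <- pmin(pmax(r2, 0), 1)
  lod <- -(nj / 2) * log10(1 - pmin(r2, 1 - 1e-12))
  slope <- num / den_g
  slope[mono] <- NA_real_
  list(lod = lod, slope = slope, r2 = r2, n = nj, mono = mono[, 1])
}

#' Single-marker QTL scan
#'
#' Per marker, least-squares regression of the phenotype on the additive code
#' (+1 homozygous parent A, 0 heterozygous, -1 homozygous parent B):
#' `LOD = (n/2) log10(RSS0 / RSS1)`, additive effect = the regression slope
#' (half the difference between homozygous class means in a balanced design;
#' positive = parent-A allele raises the phenotype), `R^2 = 1 - RSS1/RSS0`.
#'
#' @param geno individuals x markers integer genotype matrix (codes 0/1/2,
#'   `NA` missing), column names = marker names.
#' @param phenotype numeric vector, one entry per individual (`NA` allowed).
#' @return data.frame of class `lod_profile`: `marker`, `n`, `lod`, `effect`,
#'   `r2`, `flagged` (monomorphic markers get LOD 0).
#' @export
lod_scan <- function(geno, phenotype) {
  stopifnot(nrow(geno) == length(phenotype))
  usable <- !is.na(phenotype)
  if (sum(usable & rowSums(!is.na(geno)) > 0) < 20) {
    stop("phenotype available for fewer than 20 genotyped individuals")
  }
  G <- 1 - geno[usable, , drop = FALSE]   # additive coding
  y <- matrix(phenotype[usable], ncol = 1)
  st <- .marker_stats(G, y)
  res <- data.frame(
    marker = colnames(geno) %||% seq_len(ncol(geno)),
    n = as.integer(st$n[, 1]), lod = st$lod[, 1], effect = st$slope[, 1],
    r2 = st$r2[, 1], flagged = st$mono, stringsAsFactors = FALSE)
  res$lod[res$flagged] <- 0
  class(res) <- c("lod_profile", "data.frame")
  res
}

#' Permutation-derived genome-wide LOD threshold
#'
#' Permutes the phenotype `n_perm` times, records the maximum LOD over all
#' markers per permutation, and returns the empirical `(1 - alpha)` quantile
#' of that null distribution (type-1 quantile; `alpha = 1` returns the
#' minimum).
#'
#' @param geno individuals x markers genotype matrix (codes 0/1/2, `NA`).
#' @param phenotype numeric vector.
#' @param n_perm number of permutations (>= 100; 1000 by convention).
#' @param alpha genome-wide type-I level.
#' @param seed integer seed.
#' @return The LOD threshold, with attributes `n_perm`, `alpha`, `seed` and
#'   `max_lods` (the null distribution).
#' @export
permutation_threshold <- function(geno, phenotype, n_perm = 1000L,
                                  alpha = 0.05, seed = 1L) {
  stopifnot(n_perm >= 100L, alpha > 0, alpha <= 1,
            nrow(geno) == length(phenotype))
  usable <- !is.na(phenotype)
  G <- 1 - geno[usable, , drop = FALSE]
  # permute the sorted multiset: the null distribution depends on the
  # phenotype values only, so the threshold is exactly invariant to any
  # relabeling of the phenotype across individuals
  y <- sort(phenotype[usable])
  Y <- with_seed_(derive_seed(seed, 0L), {
    vapply(seq_len(n_perm), function(k) sample(y), numeric(length(y)))
  })
  st <- .marker_stats(G, Y)
  lod <- st$lod
  lod[st$mono, ] <- 0
  max_lods <- apply(lod, 2, max)
  thr <- quantile(max_lods, probs = 1 - alpha, type = 1, names = FALSE)
  attr(thr, "n_perm") <- n_perm
  attr(thr, "alpha") <- alpha
  attr(thr, "seed") <- seed
  attr(thr, "max_lods") <- max_lods
  thr
}
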
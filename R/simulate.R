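# Synthetic-data generators with known truth tables. These emulate the data
# regime of a MIG-seq evaluation study: genomes carrying the four targeted SSR
# motif classes at a controllable density, inbred accession panels diverged at
# a requested pairwise nucleotide diversity, F2 / RIL crosses from
# interference-free meiosis, and locus coverage with strong per-locus
# overdispersion (lognormal amplification weights + Poisson sampling, i.e. a
# negative-binomial-like marginal depth).

#' Simulate a genome carrying targeted SSR loci
#'
#' Background sequence is i.i.d. uniform over A/C/G/T. SSR loci are placed
#' uniformly at random without overlap; each locus is a perfect tandem repeat
#' of a random member of one of the targeted motif families, and its flanking
#' bases are chosen so the repeat cannot extend beyond the recorded interval
#' (the truth table is therefore exact for a scanner of maximal runs).
#'
#' @param length_bp total genome length (>= 10,000), split evenly over
#'   chromosomes.
#' @param n_chromosomes number of chromosomes.
#' @param ssr_density expected SSR loci per Mb (Poisson per chromosome).
#' @param motif_weights named non-negative weights over the motif classes to
#'   place (names are family representatives, e.g. `ACT`, `TTG`, `GTG`, `GT`).
#' @param repeat_range integer `[min, max]` repeat count per locus.
#' @param seed integer seed.
#' @param max_tries placement retries per locus before giving up.
#' @return An object of class `genome_truth`: list with `sequences` (named
#'   character), `ssr_loci` (truth table: `chrom`, `start`, `end` 0-based
#'   half-open, `motif_class`, `motif`, `repeat_count`), `chrom_lengths`,
#'   `length_bp`.
#' @export
#' @examples
#' g <- simulate_genome(20000, n_chromosomes = 2, ssr_density = 100, seed = 1)
#' nrow(g$ssr_loci)
simulate_genome <- function(length_bp, n_chromosomes = 1L, ssr_density = 100,
                            motif_weights = c(ACT = 1, TTG = 1, GTG = 1,
                                              GT = 1),
                            repeat_range = c(8L, 14L), seed = 1L,
                            max_tries = 50L) {
  stopifnot(length_bp >= 10000, n_chromosomes >= 1, ssr_density >= 0,
            sum(motif_weights) > 0, all(motif_weights >= 0),
            repeat_range[1] >= 2, repeat_range[1] <= repeat_range[2])
  classes <- names(motif_weights)
  stopifnot(!is.null(classes))

  lens <- rep(as.integer(length_bp %/% n_chromosomes), n_chromosomes)
  lens[n_chromosomes] <- lens[n_chromosomes] +
    as.integer(length_bp %% n_chromosomes)
  names(lens) <- sprintf("chr%d", seq_len(n_chromosomes))

  with_seed_(seed, {
    seqs <- character(n_chromosomes)
    names(seqs) <- names(lens)
    loci <- list()
    for (ci in seq_len(n_chromosomes)) {
      L <- lens[ci]
      chars <- sample(.BASES, L, replace = TRUE)
      n_loci <- rpois(1L, ssr_density * L / 1e6)
      occ_start <- integer(0)  # occupied intervals incl. flanks, 1-based
      occ_end <- integer(0)
      if (n_loci > 0) {
        for (k in seq_len(n_loci)) {
          cls <- sample(classes, 1L, prob = motif_weights)
          variant <- sample(motif_family(cls), 1L)
          p <- nchar(variant)
          reps <- if (repeat_range[1] == repeat_range[2]) repeat_range[1] else
            sample(repeat_range[1]:repeat_range[2], 1L)
          len <- reps * p
          placed <- FALSE
          for (try in seq_len(max_tries)) {
            s <- sample.int(L - len - 2L, 1L) + 1L   # 1-based, flanks inside
            e <- s + len - 1L
            if (!any(s - 1L <= occ_end & e + 1L >= occ_start)) {
              vch <- strsplit(variant, "", fixed = TRUE)[[1]]
              chars[s:e] <- rep(vch, reps)
              # break run extension at both flanks
              chars[s - 1L] <- sample(setdiff(.BASES, vch[p]), 1L)
              chars[e + 1L] <- sample(setdiff(.BASES, vch[1L]), 1L)
              occ_start <- c(occ_start, s - 1L)
              occ_end <- c(occ_end, e + 1L)
              loci[[length(loci) + 1L]] <- data.frame(
                chrom = names(lens)[ci], start = s - 1L, end = s - 1L + len,
                motif_class = cls, motif = variant, repeat_count = reps,
                stringsAsFactors = FALSE)
              placed <- TRUE
              break
            }
          }
          if (!placed) {
            stop(sprintf(
              "cannot place SSR locus %d on %s after %d tries (density too high)",
              k, names(lens)[ci], max_tries))
          }
        }
      }
      seqs[ci] <- paste(chars, collapse = "")
    }
    ssr_loci <- if (length(loci)) do.call(rbind, loci) else
      data.frame(chrom = character(), start = integer(), end = integer(),
                 motif_class = character(), motif = character(),
                 repeat_count = integer(), stringsAsFactors = FALSE)
    ssr_loci <- ssr_loci[order(ssr_loci$chrom, ssr_loci$start), , drop = FALSE]
    rownames(ssr_loci) <- NULL
    structure(list(sequences = seqs, ssr_loci = ssr_loci,
                   chrom_lengths = lens, length_bp = sum(lens)),
              class = "genome_truth")
  })
}

#' @export
print.genome_truth <- function(x, ...) {
  cat(sprintf("genome_truth: %d chromosome(s), %d bp, %d SSR loci\n",
              length(x$sequences), x$length_bp, nrow(x$ssr_loci)))
  invisible(x)
}

# map global 1-based positions to (chrom index, within-chrom position)
.global_to_chrom <- function(g, lens) {
  offsets <- cumsum(c(0, as.double(lens)))
  ci <- findInterval(g, offsets, left.open = TRUE)
  list(chrom = names(lens)[ci], pos = as.integer(g - offsets[ci]))
}

#' Simulate an inbred accession panel at a target nucleotide diversity
#'
#' Infinite-sites model: each accession (lineage) independently accumulates
#' `Poisson(pi/2 * genome length)` homozygous substitutions at uniform
#' positions, so the expected pairwise difference density between any two
#' accessions is `pi`. No indels; all accessions are fully inbred.
#'
#' @param genome a [simulate_genome()] result.
#' @param n_accessions number of accessions (>= 2).
#' @param pi target pairwise nucleotide diversity in `[0, 0.05]`.
#' @param seed integer seed (per-accession streams derived from it).
#' @return An object of class `panel_truth`: list with `accessions` (named
#'   list of variant data.frames `chrom`, `pos`, `ref`, `alt`), `target_pi`,
#'   `genome_length`.
#' @export
simulate_panel <- function(genome, n_accessions, pi, seed = 1L) {
  stopifnot(inherits(genome, "genome_truth"), n_accessions >= 2)
  if (pi < 0 || pi > 0.05) stop("pi out of range [0, 0.05]")
  lens <- genome$chrom_lengths
  L <- genome$length_bp
  acc <- vector("list", n_accessions)
  names(acc) <- sprintf("acc%02d", seq_len(n_accessions))
  for (i in seq_len(n_accessions)) {
    acc[[i]] <- with_seed_(derive_seed(seed, i), {
      n_mut <- rpois(1L, pi / 2 * L)
      if (n_mut == 0L) {
        data.frame(chrom = character(), pos = integer(), ref = character(),
                   alt = character(), stringsAsFactors = FALSE)
      } else {
        g <- sample.int(L, n_mut)
        loc <- .global_to_chrom(g, lens)
        ref <- vapply(seq_len(n_mut), function(k) {
          substr(genome$sequences[[loc$chrom[k]]], loc$pos[k], loc$pos[k])
        }, character(1))
        alt <- vapply(ref, function(r) sample(setdiff(.BASES, r), 1L),
                      character(1), USE.NAMES = FALSE)
        d <- data.frame(chrom = loc$chrom, pos = loc$pos, ref = ref,
                        alt = alt, stringsAsFactors = FALSE)
        d <- d[order(d$chrom, d$pos), , drop = FALSE]
        rownames(d) <- NULL
        d
      }
    })
  }
  structure(list(accessions = acc, target_pi = pi, genome_length = L),
            class = "panel_truth")
}

#' @export
print.panel_truth <- function(x, ...) {
  cat(sprintf("panel_truth: %d accessions, target pi %.5g\n",
              length(x$accessions), x$target_pi))
  invisible(x)
}

# one gamete from a diploid (h1, h2): Poisson crossovers, no interference
.gamete <- function(h1, h2, marker_cM, marker_chrom, chrom_len_cM) {
  out <- integer(length(h1))
  for (ch in unique(marker_chrom)) {
    idx <- which(marker_chrom == ch)
    mc <- marker_cM[idx]
    len <- chrom_len_cM[[ch]]
    k <- rpois(1L, len / 100)
    strand <- sample(0:1, 1L)
    if (k > 0L) {
      x <- runif(k, 0, len)
      nbelow <- colSums(outer(x, mc, "<"))
      ph <- (strand + nbelow) %% 2L
    } else {
      ph <- rep(strand, length(idx))
    }
    out[idx] <- ifelse(ph == 0L, h1[idx], h2[idx])
  }
  out
}

#' Simulate an F2 or recombinant-inbred cross
#'
#' Markers are the positions at which the two (inbred) parents carry different
#' alleles. Meiosis is simulated with Poisson crossovers and no interference
#' (genetic position = physical position times `cM_per_Mb`). F2 progeny are
#' two independent F1 gametes; RILs are built by single-seed-descent selfing
#' to the requested generation, so residual per-marker heterozygosity is
#' `0.5^(generation - 1)` in expectation.
#'
#' @param parent_a,parent_b variant data.frames (`chrom`, `pos`, `ref`,
#'   `alt`), e.g. two accessions of a [simulate_panel()].
#' @param design `"F2"` or `"RIL"`.
#' @param n_progeny number of progeny/lines.
#' @param chrom_lengths named integer vector of chromosome lengths in bp.
#' @param generation RIL generation g (selfing to F_g; ignored for F2).
#' @param cM_per_Mb crossover rate.
#' @param seed integer seed (per-progeny streams derived from it).
#' @return An object of class `cross_truth`: list with `design`, `generation`,
#'   `genotypes` (progeny x markers matrix of B-allele counts 0/1/2),
#'   `markers` (`chrom`, `pos`, `ref`, `allele_a`, `allele_b`, `cM`),
#'   `cM_per_Mb`, `chrom_lengths`.
#' @export
simulate_cross <- function(parent_a, parent_b, design = c("F2", "RIL"),
                           n_progeny, chrom_lengths, generation = 6L,
                           cM_per_Mb = 2, seed = 1L) {
  design <- match.arg(design)
  stopifnot(n_progeny >= 1, cM_per_Mb > 0, !is.null(names(chrom_lengths)))
  if (design == "RIL") stopifnot(generation >= 2)

  ka <- paste(parent_a$chrom, parent_a$pos, sep = ":")
  kb <- paste(parent_b$chrom, parent_b$pos, sep = ":")
  keys <- union(ka, kb)
  ia <- match(keys, ka)
  ib <- match(keys, kb)
  chrom <- ifelse(is.na(ia), parent_b$chrom[ib], parent_a$chrom[ia])
  pos <- ifelse(is.na(ia), parent_b$pos[ib], parent_a$pos[ia])
  ref <- ifelse(is.na(ia), parent_b$ref[ib], parent_a$ref[ia])
  allele_a <- ifelse(is.na(ia), ref, parent_a$alt[ia])
  allele_b <- ifelse(is.na(ib), ref, parent_b$alt[ib])
  differ <- allele_a != allele_b
  if (!any(differ)) stop("no segregating markers: parents are identical")
  markers <- data.frame(chrom = chrom[differ], pos = as.integer(pos[differ]),
                        ref = ref[differ], allele_a = allele_a[differ],
                        allele_b = allele_b[differ], stringsAsFactors = FALSE)
  markers <- markers[order(markers$chrom, markers$pos), , drop = FALSE]
  rownames(markers) <- NULL
  markers$cM <- markers$pos / 1e6 * cM_per_Mb
  chrom_len_cM <- as.list(chrom_lengths / 1e6 * cM_per_Mb)

  m <- nrow(markers)
  hap_a <- integer(m)        # 0 = A allele
  hap_b <- rep(1L, m)        # 1 = B allele
  gen_rounds <- if (design == "F2") 1L else generation - 1L

  geno <- matrix(NA_integer_, n_progeny, m,
                 dimnames = list(sprintf("p%03d", seq_len(n_progeny)), NULL))
  for (j in seq_len(n_progeny)) {
    geno[j, ] <- with_seed_(derive_seed(seed, j), {
      if (design == "F2") {
        g1 <- .gamete(hap_a, hap_b, markers$cM, markers$chrom, chrom_len_cM)
        g2 <- .gamete(hap_a, hap_b, markers$cM, markers$chrom, chrom_len_cM)
        g1 + g2
      } else {
        h1 <- hap_a; h2 <- hap_b
        for (r in seq_len(gen_rounds)) {
          n1 <- .gamete(h1, h2, markers$cM, markers$chrom, chrom_len_cM)
          n2 <- .gamete(h1, h2, markers$cM, markers$chrom, chrom_len_cM)
          h1 <- n1; h2 <- n2
        }
        h1 + h2
      }
    })
  }
  structure(list(design = design,
                 generation = if (design == "F2") 2L else as.integer(generation),
                 genotypes = geno, markers = markers, cM_per_Mb = cM_per_Mb,
                 chrom_lengths = chrom_lengths),
            class = "cross_truth")
}

#' @export
print.cross_truth <- function(x, ...) {
  cat(sprintf("cross_truth: %s (generation %d), %d progeny x %d markers\n",
              x$design, x$generation, nrow(x$genotypes), ncol(x$genotypes)))
  invisible(x)
}

#' Coverage model for MIG-seq amplicon depth simulation
#'
#' Per-locus amplification weights are lognormal (`overdispersion` is the
#' log-scale standard deviation, 0 = equal efficiency at every locus) and
#' realised depths are Poisson around `n_read_pairs * weight`, giving the
#' heavy-tailed, negative-binomial-like per-locus depth distributions seen in
#' real MIG-seq libraries. Each amplicon extends downstream of its anchoring
#' SSR by an insert length drawn uniformly from `insert_range`; read pairs
#' cover `read_length` bases from each insert end.
#'
#' @param overdispersion lognormal sd of per-locus amplification weights.
#' @param insert_range integer `[min, max]` insert length in bp.
#' @param read_length read length in bp.
#' @param base_error_rate per-read probability that a read reports the wrong
#'   allele at a variant site.
#' @return An object of class `coverage_model`.
#' @export
coverage_model <- function(overdispersion = 1, insert_range = c(350L, 800L),
                           read_length = 150L, base_error_rate = 0) {
  stopifnot(overdispersion >= 0, length(insert_range) == 2,
            insert_range[1] > 0, insert_range[1] <= insert_range[2],
            read_length > 0, base_error_rate >= 0, base_error_rate <= 1)
  structure(list(overdispersion = overdispersion,
                 insert_range = as.integer(insert_range),
                 read_length = as.integer(read_length),
                 base_error_rate = base_error_rate),
            class = "coverage_model")
}

# truth genotype codes (B/alt allele count) for a panel or cross at the
# simulated site list; returns list(sites, gt, sample_names)
.truth_sites <- function(samples) {
  if (inherits(samples, "panel_truth")) {
    acc <- samples$accessions
    av <- do.call(rbind, lapply(names(acc), function(nm) {
      if (nrow(acc[[nm]]) == 0) return(NULL)
      cbind(acc[[nm]], sample = nm, stringsAsFactors = FALSE)
    }))
    if (is.null(av) || nrow(av) == 0) {
      sites <- data.frame(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          stringsAsFactors = FALSE)
      gt <- matrix(0L, 0, length(acc), dimnames = list(NULL, names(acc)))
      return(list(sites = sites, gt = gt, sample_names = names(acc)))
    }
    key <- paste(av$chrom, av$pos, sep = ":")
    first <- !duplicated(key)
    sites <- av[first, c("chrom", "pos", "ref", "alt")]
    ord <- order(sites$chrom, sites$pos)
    sites <- sites[ord, , drop = FALSE]
    rownames(sites) <- NULL
    skey <- paste(sites$chrom, sites$pos, sep = ":")
    # an accession is hom-alt (2) iff it carries exactly the site's alt;
    # rare multi-allelic collisions fall back to hom-ref
    gt <- matrix(0L, nrow(sites), length(acc),
                 dimnames = list(NULL, names(acc)))
    for (nm in names(acc)) {
      v <- acc[[nm]]
      if (nrow(v) == 0) next
      idx <- match(paste(v$chrom, v$pos, sep = ":"), skey)
      hit <- !is.na(idx) & v$alt == sites$alt[idx]
      gt[idx[hit], nm] <- 2L
    }
    list(sites = sites, gt = gt, sample_names = names(acc))
  } else if (inherits(samples, "cross_truth")) {
    mk <- samples$markers
    # synthetic biallelic convention: REF = parent-A allele, ALT = parent-B
    sites <- data.frame(chrom = mk$chrom, pos = mk$pos, ref = mk$allele_a,
                        alt = mk$allele_b, stringsAsFactors = FALSE)
    gt <- t(samples$genotypes)
    list(sites = sites, gt = gt, sample_names = rownames(samples$genotypes))
  } else {
    stop("samples must be a panel_truth or cross_truth")
  }
}

#' Simulate MIG-seq per-base depths and a genotype matrix
#'
#' Each SSR locus of the genome anchors one amplicon. Per-locus expected depth
#' is `n_read_pairs * weight` with lognormal weights shared across samples
#' (amplification efficiency is a locus property) and independent Poisson
#' draws per sample. Per-base depth equals the locus depth over the
#' read-covered parts of the amplicon and 0 elsewhere. At variant sites the
#' genotype matrix records the truth genotype (missing where depth is 0),
#' total depth, and allele depths: heterozygous sites split reads
#' `Binomial(DP, 1/2)`; base errors flip reads to the other allele at
#' `model$base_error_rate`.
#'
#' @param genome a [simulate_genome()] result.
#' @param samples a [simulate_panel()] or [simulate_cross()] result.
#' @param model a [coverage_model()].
#' @param n_read_pairs expected read pairs per sample.
#' @param seed integer seed.
#' @return list with `depths` (named list of [per_base_depth()]), `matrix`
#'   (a [genotype_matrix()]), `amplicons` (data.frame), `locus_weights`.
#' @export
simulate_migseq_depths <- function(genome, samples, model = coverage_model(),
                                   n_read_pairs, seed = 1L) {
  stopifnot(inherits(genome, "genome_truth"),
            inherits(model, "coverage_model"), n_read_pairs > 0)
  loci <- genome$ssr_loci
  if (nrow(loci) == 0L) stop("no amplifiable loci in genome")
  lens <- genome$chrom_lengths
  rl <- model$read_length

  truth <- .truth_sites(samples)
  sites <- truth$sites
  sample_names <- truth$sample_names

  with_seed_(derive_seed(seed, 0L), {
    nl <- nrow(loci)
    w <- exp(rnorm(nl, 0, model$overdispersion))
    w <- w / sum(w)
    ins <- sample(model$insert_range[1]:model$insert_range[2], nl,
                  replace = TRUE)
    astart <- loci$end + 1L                      # 1-based, just after the SSR
    aend <- pmin(astart + ins - 1L, lens[loci$chrom])
    amplicons <- data.frame(chrom = loci$chrom, start = astart - 1L,
                            end = aend, weight = w,
                            stringsAsFactors = FALSE)
  })

  ok <- amplicons$end >= amplicons$start + 1L   # amplicon has >= 1 base
  site_key <- paste(sites$chrom, sites$pos, sep = ":")
  ns <- nrow(sites)
  nn <- length(sample_names)
  gt <- matrix(NA_integer_, ns, nn)
  dp <- matrix(0L, ns, nn)
  adr <- matrix(0L, ns, nn)
  ada <- matrix(0L, ns, nn)
  depths <- vector("list", nn)
  names(depths) <- sample_names

  for (i in seq_len(nn)) {
    di <- with_seed_(derive_seed(seed, i), {
      d_loc <- rpois(nrow(amplicons), n_read_pairs * amplicons$weight)
      dv <- lapply(lens, function(L) integer(L))
      for (k in which(ok & d_loc > 0L)) {
        ch <- amplicons$chrom[k]
        a <- amplicons$start[k] + 1L
        b <- amplicons$end[k]
        if (b - a + 1L <= 2L * rl) {
          dv[[ch]][a:b] <- dv[[ch]][a:b] + d_loc[k]
        } else {
          dv[[ch]][a:(a + rl - 1L)] <- dv[[ch]][a:(a + rl - 1L)] + d_loc[k]
          dv[[ch]][(b - rl + 1L):b] <- dv[[ch]][(b - rl + 1L):b] + d_loc[k]
        }
      }
      site_dp <- if (ns > 0) {
        vapply(seq_len(ns), function(s) dv[[sites$chrom[s]]][sites$pos[s]],
               integer(1))
      } else integer(0)
      g <- truth$gt[, i]
      g[site_dp == 0L] <- NA_integer_
      alt_reads <- integer(ns)
      e <- model$base_error_rate
      is_het <- !is.na(g) & g == 1L
      is_hr <- !is.na(g) & g == 0L
      is_ha <- !is.na(g) & g == 2L
      alt_reads[is_het] <- rbinom(sum(is_het), site_dp[is_het], 0.5)
      alt_reads[is_hr] <- rbinom(sum(is_hr), site_dp[is_hr], e)
      alt_reads[is_ha] <- site_dp[is_ha] - rbinom(sum(is_ha),
                                                  site_dp[is_ha], e)
      list(dv = dv, dp = site_dp, gt = g, ada = alt_reads,
           adr = site_dp - alt_reads)
    })
    depths[[i]] <- per_base_depth(
      di$dv, sample = sample_names[i],
      raw_read_gb = n_read_pairs * 2 * rl / 1e9)
    dp[, i] <- di$dp
    gt[, i] <- di$gt
    ada[, i] <- di$ada
    adr[, i] <- di$adr
  }
  sites$qual <- 100
  m <- genotype_matrix(sites, sample_names, gt, dp, adr, ada)
  list(depths = depths, matrix = m, amplicons = amplicons,
       locus_weights = amplicons$weight)
}

#' Simulate an additive phenotype on a cross
#'
#' `phenotype = baseline + sum(a_k * code_k) + N(0, noise_sd^2)` with additive
#' coding `+1` for homozygous parent-A, `0` heterozygous, `-1` homozygous
#' parent-B, so a positive effect means the parent-A allele raises the
#' phenotype.
#'
#' @param cross a [simulate_cross()] result.
#' @param qtl_spec data.frame with columns `marker` (site key `"chrom:pos"` or
#'   integer marker index) and `effect` (additive effect `a`). `NULL` for no
#'   QTL.
#' @param noise_sd residual standard deviation.
#' @param seed integer seed.
#' @param baseline intercept.
#' @return data.frame with columns `sample` and `phenotype`.
#' @export
simulate_phenotype <- function(cross, qtl_spec = NULL, noise_sd = 1,
                               seed = 1L, baseline = 0) {
  stopifnot(inherits(cross, "cross_truth"), noise_sd >= 0)
  n <- nrow(cross$genotypes)
  y <- rep(baseline, n)
  if (!is.null(qtl_spec) && nrow(qtl_spec) > 0) {
    keys <- paste(cross$markers$chrom, cross$markers$pos, sep = ":")
    idx <- if (is.numeric(qtl_spec$marker)) as.integer(qtl_spec$marker) else
      match(as.character(qtl_spec$marker), keys)
    if (anyNA(idx) || any(idx < 1L) || any(idx > ncol(cross$genotypes))) {
      stop("unknown marker in qtl_spec")
    }
    code <- 1 - cross$genotypes[, idx, drop = FALSE]   # +1 AA, 0 AB, -1 BB
    y <- y + as.vector(code %*% qtl_spec$effect)
  }
  y <- y + with_seed_(derive_seed(seed, 0L), rnorm(n, 0, noise_sd))
  data.frame(sample = rownames(cross$genotypes), phenotype = y,
             stringsAsFactors = FALSE)
}
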
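# synthetic-data generators: truth-table invariants and closed-form checks

test_that("simulate_genome places loci at the requested density", {
  # empty case
  g0 <- simulate_genome(20000, ssr_density = 0, seed = 1)
  expect_identical(nrow(g0$ssr_loci), 0L)
  expect_identical(g0$length_bp, 20000L)

  # Poisson 99% bound at 1 Mb x 100 loci/Mb
  g <- simulate_genome(1e6, n_chromosomes = 2, ssr_density = 100, seed = 7)
  n <- nrow(g$ssr_loci)
  expect_gte(n, qpois(0.005, 100))
  expect_lte(n, qpois(0.995, 100))

  # proportionality: doubling the genome ~doubles the locus count
  g1 <- simulate_genome(5e5, ssr_density = 100, seed = 11)
  g2 <- simulate_genome(1e6, ssr_density = 100, seed = 12)
  ratio <- nrow(g2$ssr_loci) / nrow(g1$ssr_loci)
  expect_gt(ratio, 1.3)
  expect_lt(ratio, 3.0)
})

test_that("simulate_genome truth tables satisfy their invariants", {
  g <- simulate_genome(50000, n_chromosomes = 3, ssr_density = 300, seed = 2)
  loci <- g$ssr_loci
  expect_true(all(loci$end - loci$start ==
                    loci$repeat_count * nchar(loci$motif)))
  # intervals inside chromosomes, non-overlapping per chromosome
  expect_true(all(loci$start >= 0))
  expect_true(all(loci$end <= g$chrom_lengths[loci$chrom]))
  for (ch in unique(loci$chrom)) {
    l <- loci[loci$chrom == ch, ]
    l <- l[order(l$start), ]
    if (nrow(l) > 1) expect_true(all(l$start[-1] >= l$end[-nrow(l)]))
  }
  expect_true(all(strsplit(paste(g$sequences, collapse = ""), "")[[1]] %in%
                    c("A", "C", "G", "T")))
  # density too high for placement errors out explicitly
  expect_error(simulate_genome(10000, ssr_density = 30000, seed = 1),
               "cannot place")
})

test_that("simulate_panel hits the requested pairwise diversity", {
  g <- simulate_genome(1e6, ssr_density = 50, seed = 3)

  p0 <- simulate_panel(g, 3, 0, seed = 1)
  expect_true(all(vapply(p0$accessions, nrow, integer(1)) == 0L))

  expect_error(simulate_panel(g, 3, 0.2, seed = 1), "out of range")
  expect_error(simulate_panel(g, 1, 0.001, seed = 1))

  # per-pair realized difference count within the 99% interval around
  # pi * L = 2500 (per-lineage Poisson mutations on disjoint positions)
  p <- simulate_panel(g, 4, 0.0025, seed = 5)
  pair_diffs <- function(a, b) {
    ka <- paste(a$chrom, a$pos, a$alt)
    kb <- paste(b$chrom, b$pos, b$alt)
    length(setdiff(ka, kb)) + length(setdiff(kb, ka))
  }
  lo <- qpois(0.005, 2500); hi <- qpois(0.995, 2500)
  for (pr in list(c(1, 2), c(1, 3), c(2, 4), c(3, 4))) {
    d <- pair_diffs(p$accessions[[pr[1]]], p$accessions[[pr[2]]])
    expect_gte(d, lo)
    expect_lte(d, hi)
  }

  # derived per-accession streams: accession i identical across panel sizes
  p2 <- simulate_panel(g, 2, 0.0025, seed = 5)
  expect_identical(p2$accessions[[1]], p$accessions[[1]])
  expect_identical(p2$accessions[[2]], p$accessions[[2]])
})

test_that("simulate_cross matches Mendelian and RIL expectations", {
  lens <- c(chr1 = 2e6)
  pa <- data.frame(chrom = character(), pos = integer(), ref = character(),
                   alt = character())
  # single-marker F2: 1:2:1 within the chi-squared 99% acceptance region
  pb1 <- data.frame(chrom = "chr1", pos = 1e6L, ref = "A", alt = "T")
  f2 <- simulate_cross(pa, pb1, "F2", 400, lens, seed = 21)
  counts <- tabulate(f2$genotypes[, 1] + 1L, 3)
  chisq <- sum((counts - 400 * c(1, 2, 1) / 4)^2 / (400 * c(1, 2, 1) / 4))
  expect_lt(chisq, qchisq(0.99, 2))

  # RIL residual heterozygosity ~= 0.5^(g-1), 3 sigma with independent
  # chromosomes (within-chromosome marker correlation only tightens this)
  lens8 <- setNames(rep(2e6L, 8), sprintf("chr%d", 1:8))
  pb8 <- do.call(rbind, lapply(names(lens8), function(ch) {
    data.frame(chrom = ch, pos = c(5e5L, 1e6L, 15e5L), ref = "A", alt = "T")
  }))
  ril <- simulate_cross(pa, pb8, "RIL", 200, lens8, generation = 6, seed = 31)
  p_exp <- 0.5^5
  sigma <- sqrt(p_exp * (1 - p_exp) / (200 * 8))
  expect_lt(abs(mean(ril$genotypes == 1L) - p_exp), 3 * sigma)

  # adjacent markers: no recombination at (effectively) zero distance
  pb2 <- data.frame(chrom = "chr1", pos = c(1e6L, 1e6L + 1L), ref = "A",
                    alt = "T")
  f2b <- simulate_cross(pa, pb2, "F2", 300, lens, seed = 41)
  expect_true(all(f2b$genotypes[, 1] == f2b$genotypes[, 2]))

  expect_error(simulate_cross(pa, pa, "F2", 10, lens),
               "no segregating markers")
})

test_that("simulate_migseq_depths reproduces the coverage model", {
  g <- simulate_genome(2e5, ssr_density = 150, seed = 9)
  p <- simulate_panel(g, 2, 0.002, seed = 10)

  # overdispersion 0: per-locus depths are Poisson with a common mean.
  # Restrict to amplicons that overlap no other amplicon, so the depth at the
  # amplicon start is that locus's depth alone.
  isolated <- function(amp) {
    vapply(seq_len(nrow(amp)), function(k) {
      same <- amp$chrom == amp$chrom[k]
      same[k] <- FALSE
      !any(same & amp$start < amp$end[k] & amp$end > amp$start[k])
    }, logical(1))
  }
  locus_depths <- function(sim) {
    amp <- sim$amplicons[isolated(sim$amplicons), ]
    d1 <- sim$depths[[1]]
    vapply(seq_len(nrow(amp)), function(k) {
      d1$depths[[amp$chrom[k]]][amp$start[k] + 1L]
    }, integer(1))
  }
  sim0 <- simulate_migseq_depths(g, p, coverage_model(overdispersion = 0),
                                 5000, seed = 2)
  loc_dp <- locus_depths(sim0)
  expect_gt(length(loc_dp), 10)
  vm0 <- var(loc_dp) / mean(loc_dp)
  expect_lt(vm0, 3)

  simb <- simulate_migseq_depths(g, p, coverage_model(overdispersion = 1.5),
                                 5000, seed = 2)
  loc_dpb <- locus_depths(simb)
  expect_gt(var(loc_dpb) / mean(loc_dpb), vm0)

  # linearity: doubling read pairs ~doubles total mapped bases
  sim2 <- simulate_migseq_depths(g, p, coverage_model(overdispersion = 0),
                                 10000, seed = 2)
  tot1 <- sum(vapply(sim0$depths, function(x)
    sum(as.numeric(unlist(x$depths))), numeric(1)))
  tot2 <- sum(vapply(sim2$depths, function(x)
    sum(as.numeric(unlist(x$depths))), numeric(1)))
  expect_gt(tot2 / tot1, 1.8)
  expect_lt(tot2 / tot1, 2.2)

  # AD conservation at truth-het sites (error rate 0)
  lens <- g$chrom_lengths
  pb <- data.frame(chrom = "chr1", pos = c(2000L, 9000L), ref = "A",
                   alt = "T")
  pa <- pb[0, ]
  f2 <- simulate_cross(pa, pb, "F2", 20, lens, seed = 3)
  simx <- simulate_migseq_depths(g, f2, coverage_model(0), 5000, seed = 4)
  expect_true(all(simx$matrix$ad_ref + simx$matrix$ad_alt == simx$matrix$dp,
                  na.rm = TRUE))

  # no loci -> explicit error
  g0 <- simulate_genome(20000, ssr_density = 0, seed = 1)
  expect_error(simulate_migseq_depths(g0, p, coverage_model(), 100),
               "no amplifiable loci")
})

test_that("simulate_phenotype codes additive effects as documented", {
  lens <- c(chr1 = 2e6)
  pa <- data.frame(chrom = character(), pos = integer(), ref = character(),
                   alt = character())
  pb <- data.frame(chrom = "chr1", pos = c(5e5L, 1e6L, 15e5L), ref = "A",
                   alt = "T")
  f2 <- simulate_cross(pa, pb, "F2", 150, lens, seed = 8)

  ph0 <- simulate_phenotype(f2, NULL, noise_sd = 0, seed = 1, baseline = 3)
  expect_true(all(ph0$phenotype == 3))

  ph <- simulate_phenotype(f2, data.frame(marker = 2, effect = 2),
                           noise_sd = 0, seed = 1)
  g <- f2$genotypes[, 2]
  expect_equal(mean(ph$phenotype[g == 0]) - mean(ph$phenotype[g == 2]), 4)

  expect_error(simulate_phenotype(f2, data.frame(marker = 99, effect = 1)),
               "unknown marker")
})
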
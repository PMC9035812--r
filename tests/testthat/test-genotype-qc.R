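# genotype-matrix QC filters

test_that("genotype_matrix validates and sorts its inputs", {
  expect_error(gm_fix(matrix(3L, 1, 1)), "codes")
  expect_error(gm_fix(matrix(0L, 1, 1), dp = matrix(2L, 1, 1),
                      ad_ref = matrix(2L, 1, 1), ad_alt = matrix(1L, 1, 1)),
               "exceed DP")
  m <- genotype_matrix(
    data.frame(chrom = c("c2", "c1"), pos = c(5L, 9L), ref = "A", alt = "T"),
    "s1", matrix(c(0L, 2L), 2, 1))
  expect_identical(m$sites$chrom, c("c1", "c2"))
  expect_identical(m$gt[, 1], c(2L, 0L))
  expect_identical(site_keys(m), c("c1:9", "c2:5"))
})

test_that("mask_low_depth honours both comparators", {
  m <- gm_fix(gt = matrix(c(0L, 1L, 2L), 3, 1),
              dp = matrix(c(9L, 5L, 100L), 3, 1))
  f2 <- mask_low_depth(m, 10, "lt")       # DP < 10 -> missing
  expect_identical(f2$gt[, 1], c(NA, NA, 2L))
  ril <- mask_low_depth(m, 5, "le")       # DP <= 5 -> missing
  expect_identical(ril$gt[, 1], c(0L, NA, 2L))
  high <- gm_fix(gt = matrix(c(0L, 1L, 2L), 3, 1),
                 dp = matrix(100L, 3, 1))
  expect_identical(mask_low_depth(high, 10)$gt, high$gt)
  # unknown DP is masked
  m_na <- gm_fix(gt = matrix(0L, 1, 1))
  expect_true(is.na(mask_low_depth(m_na, 5)$gt[1, 1]))
})

test_that("filter_sites applies rate, het, quality and allele filters", {
  # 96/100 genotyped vs strict 0.97 -> dropped
  gt <- matrix(0L, 2, 100)
  gt[1, 1:4] <- NA
  m <- gm_fix(gt, qual = c(50, 50))
  ms <- filter_sites(m, min_genotype_rate = 0.97)
  expect_identical(ms$keys, site_keys(m)[2])
  expect_false(ms$table$pass_rate[1])

  # one het cell with remove_any_het -> dropped
  gt2 <- matrix(0L, 2, 4); gt2[1, 2] <- 1L
  ms2 <- filter_sites(gm_fix(gt2), remove_any_het = TRUE)
  expect_identical(length(ms2$keys), 1L)

  # rate 1 with >= semantics keeps exactly the fully genotyped sites
  gt3 <- matrix(0L, 3, 4); gt3[2, 3] <- NA
  ms3 <- filter_sites(gm_fix(gt3), min_genotype_rate = 1,
                      rate_comparator = "ge")
  expect_identical(ms3$keys, site_keys(gm_fix(gt3))[c(1, 3)])

  # quality threshold; unknown quality fails a finite threshold
  m4 <- gm_fix(matrix(0L, 3, 2), qual = c(29, 30, NA))
  ms4 <- filter_sites(m4, min_site_quality = 30)
  expect_identical(ms4$keys, site_keys(m4)[2])

  # multiallelic sites dropped when biallelic_only
  sites <- data.frame(chrom = "c1", pos = c(1L, 2L), ref = "A",
                      alt = c("T", "T,G"))
  m5 <- genotype_matrix(sites, c("s1"), matrix(0L, 2, 1))
  expect_identical(filter_sites(m5, biallelic_only = TRUE)$keys, "c1:1")
})

test_that("filter_individuals removes samples above the missingness bound", {
  gt <- matrix(0L, 50, 3)
  gt[1:6, 2] <- NA            # 12% missing
  m <- gm_fix(gt)
  out <- filter_individuals(m, 0.10)
  expect_identical(out$samples, c("s01", "s03"))
  expect_identical(attr(out, "removed"), "s02")
  expect_identical(filter_individuals(m, 0.2)$samples, m$samples)

  # brute-force recount over random matrices
  set.seed(5)
  for (k in 1:5) {
    gt <- matrix(sample(c(0L, 1L, 2L, NA), 200, TRUE), 20, 10)
    m <- gm_fix(gt)
    bound <- runif(1, 0.1, 0.9)
    expected_removed <- sum(colMeans(is.na(gt)) > bound)
    if (expected_removed == 10) {
      expect_error(filter_individuals(m, bound), "all samples")
    } else {
      expect_identical(length(attr(filter_individuals(m, bound), "removed")),
                       expected_removed)
    }
  }
})

test_that("parental_marker_set distinguishes strict and lenient modes", {
  # 3 sites x 8 replicates per parent
  ga <- matrix(0L, 3, 8)
  gb <- matrix(2L, 3, 8)
  ga[1, 1] <- NA              # site 1: one missing replicate in parent A
  gb[3, ] <- 0L               # site 3: parents identical
  a <- gm_fix(ga); b <- gm_fix(gb)

  strict <- parental_marker_set(a, b, "strict")
  expect_identical(strict$keys, site_keys(a)[2])
  lenient <- parental_marker_set(a, b, "lenient")
  expect_identical(lenient$keys, site_keys(a)[1:2])

  # conflicting replicates fail in both modes
  ga2 <- ga; ga2[2, 1] <- 2L
  both <- parental_marker_set(gm_fix(ga2), b, "lenient")
  expect_false("c1:20" %in% both$keys)
})

test_that("het_to_missing is exact and idempotent", {
  gt <- matrix(c(0L, 1L, 2L, 1L), 2, 2)
  m <- gm_fix(gt)
  h <- het_to_missing(m)
  expect_identical(sum(is.na(h$gt)), 2L)
  expect_identical(h$gt[h$gt %in% c(0L, 2L)], m$gt[m$gt %in% c(0L, 2L)])
  expect_identical(het_to_missing(h)$gt, h$gt)
  all_hom <- gm_fix(matrix(c(0L, 2L), 2, 2))
  expect_identical(het_to_missing(all_hom)$gt, all_hom$gt)
})

test_that("mask-then-filter equals the fused single pass", {
  set.seed(6)
  gt <- matrix(sample(c(0L, 1L, 2L, NA), 400, TRUE), 40, 10)
  dp <- matrix(rpois(400, 8), 40, 10)
  m <- gm_fix(gt, dp = dp)
  staged <- filter_sites(mask_low_depth(m, 10, "lt"),
                         min_genotype_rate = 0.5)$keys
  # fused: count a cell as genotyped iff called and DP >= 10
  rate <- rowMeans(!is.na(gt) & dp >= 10)
  expect_identical(staged, site_keys(m)[rate > 0.5])
})

test_that("run_qc presets behave on simulated data", {
  g <- simulate_genome(1e5, ssr_density = 300, seed = 23)
  p <- simulate_panel(g, 4, 0.003, seed = 4)
  sim <- simulate_migseq_depths(g, p, coverage_model(0.5), 8000, seed = 5)
  qc <- run_qc(sim$matrix, "panel")
  expect_lte(n_sites(qc$matrix), n_sites(sim$matrix))
  # panel preset: surviving sites fully genotyped at DP >= 5, no hets
  expect_true(all(!is.na(qc$matrix$gt)))
  expect_true(all(qc$matrix$gt != 1L))
  expect_true(all(qc$matrix$dp >= 5L))
  # truth-het cells never survive het_to_missing
  expect_identical(sum(het_to_missing(sim$matrix)$gt == 1L, na.rm = TRUE), 0L)
})
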
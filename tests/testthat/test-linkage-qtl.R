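# two-point linkage, mapping functions, distortion, LOD scan, permutations

test_that("recombination_fraction: closed forms and recovery", {
  # RIL: observed recombinant fraction R = 0.2 -> r = R/(2-2R) = 0.125
  g1 <- c(rep(0L, 10), rep(2L, 10))
  g2 <- g1
  g2[c(1, 2, 11, 12)] <- 2L - g2[c(1, 2, 11, 12)]
  expect_equal(recombination_fraction(g1, g2, "RIL"), 0.125)
  expect_equal(recombination_fraction(g1, g1, "RIL"), 0)

  # undefined cases are flagged
  r <- recombination_fraction(rep(0L, 20), g2, "RIL")
  expect_true(is.na(r))
  expect_match(attr(r, "flag"), "monomorphic")
  r2 <- recombination_fraction(g1[1:5], g2[1:5], "RIL")
  expect_match(attr(r2, "flag"), "fewer than 10")

  # F2 EM recovers the simulated r (Poisson crossovers are Haldane-world:
  # d = -50 log(1 - 2r) places markers at r = 0.1)
  lens <- c(chr1 = 3e7)
  d_cM <- -50 * log(1 - 0.2)
  pb <- data.frame(chrom = "chr1", pos = c(1e6L, as.integer(1e6 + d_cM * 1e6)),
                   ref = "A", alt = "T")
  pa <- pb[0, ]
  f2 <- simulate_cross(pa, pb, "F2", 500, lens, cM_per_Mb = 1, seed = 51)
  r_hat <- recombination_fraction(f2$genotypes[, 1], f2$genotypes[, 2], "F2")
  expect_lt(abs(r_hat - 0.1), 0.04)

  # RIL recovery through the selfing correction
  ril <- simulate_cross(pa, pb, "RIL", 500, lens, generation = 6,
                        cM_per_Mb = 1, seed = 52)
  r_ril <- recombination_fraction(ril_geno(ril)[, 1], ril_geno(ril)[, 2],
                                  "RIL")
  expect_lt(abs(r_ril - 0.1), 0.05)
})

test_that("kosambi and haldane mapping functions", {
  expect_equal(kosambi_cM(0), 0)
  expect_equal(kosambi_cM(0.1), 25 * log(1.5), tolerance = 1e-12)
  expect_equal(kosambi_cM(0.25), 25 * log(3), tolerance = 1e-12)
  expect_error(kosambi_cM(0.5), "infinite")
  expect_error(kosambi_cM(-0.1))

  r <- seq(0.01, 0.49, by = 0.01)
  k <- kosambi_cM(r)
  h <- haldane_cM(r)
  expect_true(all(k <= h))
  expect_true(all(diff(k) > 0))              # strictly increasing
  expect_true(all(diff(diff(k)) > 0))        # convex
})

test_that("map_summary uses the length/markers convention", {
  expect_equal(round(map_summary(5022.0, 3257)$avg_spacing_cM, 2), 1.54)
  expect_equal(round(map_summary(2521.6, 3148)$avg_spacing_cM, 2), 0.80)

  tb <- data.frame(group = "lg1", marker = sprintf("m%02d", 1:11),
                   pos_bp = 1:11, cM = seq(0, 10, by = 1))
  s <- map_summary(ordered_map(tb))
  expect_equal(s$total_cM, 10)
  expect_equal(s$avg_spacing_cM, 10 / 11, tolerance = 1e-12)
  expect_error(ordered_map(data.frame(group = "g", marker = c("a", "b"),
                                      pos_bp = 1:2, cM = c(2, 1))),
               "non-decreasing")
})

test_that("adjacent Kosambi distances recover a simulated map length", {
  # markers every 5 cM over 100 cM, F2 with n = 500
  lens <- c(chr1 = as.integer(105e6))
  pb <- data.frame(chrom = "chr1", pos = as.integer(seq(1e6, 101e6, 5e6)),
                   ref = "A", alt = "T")
  f2 <- simulate_cross(pb[0, ], pb, "F2", 500, lens, cM_per_Mb = 1,
                       seed = 61)
  lm <- build_linkage_map(f2$genotypes, f2$markers, "F2")
  total <- map_summary(lm$map)$total_cM
  true_len <- max(f2$markers$cM) - min(f2$markers$cM)
  expect_lt(abs(total - true_len) / true_len, 0.10)
  expect_false(any(lm$two_point$flagged))
})

test_that("segregation_distortion computes the Pearson chi-squared test", {
  m0 <- c(rep(0L, 30), rep(1L, 60), rep(2L, 30))
  s0 <- segregation_distortion(m0, c(1, 2, 1))
  expect_equal(s0$chisq, 0)
  expect_equal(s0$p, 1)

  m1 <- c(rep(0L, 50), rep(1L, 50), rep(2L, 20))
  s1 <- segregation_distortion(m1, c(1, 2, 1))
  expect_equal(s1$chisq, 55 / 3, tolerance = 1e-12)   # 18.33, df 2
  expect_identical(s1$df, 2L)

  # RIL 1:1 over homozygote classes
  s2 <- segregation_distortion(c(rep(0L, 40), rep(2L, 60)), c(1, 1))
  expect_equal(s2$chisq, 4)
  expect_identical(s2$df, 1L)
  # all-missing marker
  s3 <- segregation_distortion(rep(NA_integer_, 10), c(1, 2, 1))
  expect_true(is.na(s3$p))

  # type-I behaviour: ~5% of undistorted markers at p < 0.05
  set.seed(8)
  cnt <- rmultinom(1000, 200, c(0.25, 0.5, 0.25))
  geno <- apply(cnt, 2, function(x) rep(c(0L, 1L, 2L), x))
  pv <- segregation_distortion(geno, c(1, 2, 1))$p
  expect_lt(abs(mean(pv < 0.05) - 0.05), 0.025)
})

test_that("lod_scan recovers simulated QTL", {
  lens <- c(chr1 = 3e7, chr2 = 3e7)
  pb <- do.call(rbind, lapply(names(lens), function(ch) {
    data.frame(chrom = ch, pos = as.integer(seq(2e6, 28e6, 4e6)), ref = "A",
               alt = "T")
  }))
  ril <- simulate_cross(pb[0, ], pb, "RIL", 200, lens, generation = 6,
                        cM_per_Mb = 2, seed = 71)
  g <- ril_geno(ril)

  # constant phenotype: LOD 0 everywhere
  prof0 <- lod_scan(g, rep(1, 200))
  expect_true(all(prof0$lod == 0))

  # noise-free QTL: perfect fit at the causal marker, positive effect for
  # the parent-A allele
  causal <- 4L
  ph <- simulate_phenotype(ril, data.frame(marker = causal, effect = 2),
                           noise_sd = 0, seed = 1)
  prof <- lod_scan(g, ph$phenotype)
  expect_identical(which.max(prof$lod), as.integer(causal))
  expect_equal(prof$r2[causal], 1)
  expect_equal(prof$effect[causal], 2)

  # noisy F2 recovery: effect within 3 sigma of the truth
  f2 <- simulate_cross(pb[0, ], pb, "F2", 400, lens, cM_per_Mb = 2,
                       seed = 72)
  ph2 <- simulate_phenotype(f2, data.frame(marker = causal, effect = 2),
                            noise_sd = 2, seed = 2)
  prof2 <- lod_scan(f2$genotypes, ph2$phenotype)
  se <- 2 / sqrt(sum(f2$genotypes[, causal] != 1))
  expect_lt(abs(prof2$effect[causal] - 2), 3 * se)

  # monomorphic marker: flagged with LOD 0
  gm <- cbind(g, mono = 0L)
  prof3 <- lod_scan(gm, ph$phenotype)
  expect_true(prof3$flagged[ncol(gm)])
  expect_equal(prof3$lod[ncol(gm)], 0)

  expect_error(lod_scan(g[1:10, ], ph$phenotype[1:10]), "fewer than 20")
})

test_that("permutation_threshold quantiles and invariance", {
  set.seed(9)
  g <- matrix(sample(c(0L, 2L), 100 * 40, TRUE), 100, 40)
  y <- rnorm(100)
  thr <- permutation_threshold(g, y, n_perm = 200, alpha = 0.05, seed = 3)
  ml <- attr(thr, "max_lods")
  expect_identical(length(ml), 200L)
  expect_equal(as.numeric(thr), sort(ml)[190])

  # alpha = 1 gives the minimum of the null distribution
  thr1 <- permutation_threshold(g, y, n_perm = 200, alpha = 1, seed = 3)
  expect_equal(as.numeric(thr1), min(ml))

  # exactly invariant to relabeling the phenotype
  perm <- sample(100)
  thr_p <- permutation_threshold(g, y[perm], n_perm = 200, alpha = 0.05,
                                 seed = 3)
  expect_equal(as.numeric(thr_p), as.numeric(thr))

  expect_error(permutation_threshold(g, y, n_perm = 50), "n_perm")
})
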
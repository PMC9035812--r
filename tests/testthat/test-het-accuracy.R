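# virtual-F1 construction, the minimal caller and error/missing curves

test_that("subsample_counts thins hypergeometrically", {
  d <- c(5L, 0L, 12L, 3L)
  expect_identical(subsample_counts(d, sum(d)), d)
  expect_identical(subsample_counts(d, 0), c(0L, 0L, 0L, 0L))
  expect_error(subsample_counts(d, 100, total_reads = 50), "exceeds")

  # totals are exact when every read hits a marker
  set.seed(1)
  for (k in 1:5) {
    dd <- rpois(50, 20)
    th <- subsample_counts(dd, 300, seed = k)
    expect_identical(sum(th), 300L)
    expect_true(all(th <= dd))
  }

  # thinning fraction f scales each marker's mean depth by f
  dd <- rep(40L, 200)
  means <- rowMeans(vapply(1:40, function(s) {
    subsample_counts(dd, 4000, total_reads = 16000, seed = s)
  }, integer(200)))
  expect_lt(max(abs(means - 10)), 1.5)
})

test_that("make_virtual_f1 merges parental depths", {
  f1 <- make_virtual_f1(c(m1 = 3L, m2 = 0L), c(m2 = 2L, m1 = 1L))
  expect_identical(f1$ad_a + f1$ad_b, c(4L, 2L))   # conservation
  expect_identical(f1$markers, c("m1", "m2"))
  expect_error(make_virtual_f1(c(m1 = 1L), c(m2 = 1L)), "different marker")
  # parent B absent at a marker: only hom-A or missing is possible
  calls <- call_genotype(f1$ad_a, f1$ad_b, min_dp = 1)
  expect_identical(calls[2], "hom_b")
})

test_that("call_genotype implements the minimal AD caller", {
  expect_identical(call_genotype(3, 2, 5), "het")
  expect_identical(call_genotype(4, 0, 5), NA_character_)
  expect_identical(call_genotype(6, 0, 5), "hom_a")
  expect_identical(call_genotype(0, 6, 5), "hom_b")
  expect_identical(call_genotype(0, 0, 1), NA_character_)
})

test_that("error_missing_curves matches closed forms", {
  # complete, balanced depths: no error, no missing
  f1 <- make_virtual_f1(rep(5L, 100), rep(5L, 100))
  ec <- error_missing_curves(list(f1), min_dp = 1:10)
  expect_true(all(ec$mean$error_rate == 0))
  expect_true(all(ec$mean$missing_rate == 0))

  # threshold above the maximum depth: everything missing, error undefined
  ec2 <- error_missing_curves(list(f1), min_dp = 11L)
  expect_equal(ec2$mean$missing_rate, 1)
  expect_true(ec2$per_replicate$flagged)
  expect_true(is.na(ec2$per_replicate$error_rate))

  # missing_rate non-decreasing in min_dp
  set.seed(2)
  tot <- rpois(500, 6)
  a <- rbinom(500, tot, 0.5)
  f1r <- make_virtual_f1(a, tot - a)
  ecr <- error_missing_curves(list(f1r), 1:20)
  expect_true(all(diff(ecr$mean$missing_rate) >= 0))

  # fixed depth d, error-free reads: error rate -> 2^(1-d)
  set.seed(3)
  d <- 5L
  tot <- rep(d, 20000)
  aa <- rbinom(20000, d, 0.5)
  f1d <- make_virtual_f1(aa, tot - aa)
  ecd <- error_missing_curves(list(f1d), min_dp = 1L)
  expected <- 2^(1 - d)
  sigma <- sqrt(expected * (1 - expected) / 20000)
  expect_lt(abs(ecd$mean$error_rate - expected), 3 * sigma)
})

test_that("analytic_het_error matches brute-force enumeration", {
  # point mass at d = 1: a single read is always homozygous
  expect_equal(analytic_het_error(c(`1` = 1), 1)$error, 1)

  # point mass at d = 3: enumerate all 8 equiprobable allele assignments
  outcomes <- expand.grid(rep(list(c("A", "B")), 3))
  hom <- mean(apply(outcomes, 1, function(x) length(unique(x)) == 1))
  expect_equal(hom, 0.25)
  expect_equal(analytic_het_error(c(`3` = 1), 1)$error, hom)

  expect_equal(analytic_het_error(c(`10` = 1), 1)$error, 2^-9)

  # mixed distribution: missing mass below threshold, renormalised error
  dist <- c(`2` = 0.3, `5` = 0.5, `9` = 0.2)
  r <- analytic_het_error(dist, 4)
  expect_equal(r$missing, 0.3)
  expect_equal(r$error, (0.5 * 2^-4 + 0.2 * 2^-8) / 0.7)

  # no support above threshold
  r2 <- analytic_het_error(c(`2` = 1), 5)
  expect_true(is.na(r2$error))
  expect_equal(r2$missing, 1)
  expect_error(analytic_het_error(c(`2` = 0.5), 1), "sum")
})

test_that("analytic curves are monotone in threshold and read amount", {
  pois_dist <- function(lambda) {
    d <- 0:60
    setNames(dpois(d, lambda) / sum(dpois(d, lambda)), d)
  }
  dist <- pois_dist(8)
  err <- vapply(1:15, function(t) analytic_het_error(dist, t)$error,
                numeric(1))
  mis <- vapply(1:15, function(t) analytic_het_error(dist, t)$missing,
                numeric(1))
  expect_true(all(diff(err) <= 1e-15))
  expect_true(all(diff(mis) >= 0))

  # stochastically larger depths (more reads) lower the error at fixed t
  err_by_lambda <- vapply(c(2, 4, 8, 16), function(l) {
    analytic_het_error(pois_dist(l), 3)$error
  }, numeric(1))
  expect_true(all(diff(err_by_lambda) < 0))
})

test_that("virtual_f1_grid produces the long-format table", {
  set.seed(4)
  pa <- rpois(300, 20)
  pb <- rpois(300, 20)
  grid <- virtual_f1_grid(pa, pb, reads_per_parent = c(1000L, 3000L),
                          n_replicates = 3, min_dp = 1:5, seed = 9)
  expect_identical(nrow(grid), 2L * 3L * 5L)
  expect_true(all(grid$reads_per_f1 == 2 * grid$reads_per_parent))
  expect_true(all(grid$error_rate >= 0 & grid$error_rate <= 1, na.rm = TRUE))
  # more reads -> lower mean error at a fixed threshold
  m1 <- mean(grid$error_rate[grid$reads_per_parent == 1000 & grid$min_dp == 2])
  m3 <- mean(grid$error_rate[grid$reads_per_parent == 3000 & grid$min_dp == 2])
  expect_gt(m1, m3)
})
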
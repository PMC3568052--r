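test_that("relative error is |est - truth| / |truth| * 100", {
  expect_equal(relative_error(11, 10), 10)
  expect_equal(relative_error(9, 10), 10)
  expect_equal(relative_error(5, 5), 0)
  expect_error(relative_error(1, 0), "undefined")
})

test_that("Cohen's d matches the pooled-variance hand computation", {
  a <- c(2, 2, 4, 4); b <- c(1, 1, 3, 3)
  # means 3 and 2; both variances 4/3 -> pooled sd sqrt(4/3)
  expect_equal(cohens_d(a, b), 1 / sqrt(4 / 3), tolerance = 1e-12)
  expect_equal(cohens_d(b, a), -cohens_d(a, b))
  expect_equal(cohens_d(a, a), 0)
  expect_error(cohens_d(c(1, 1), c(1, 1)), "pooled")
  expect_error(cohens_d(1, c(1, 2)), ">= 2")
})

test_that("two-sample permutation test behaves at the extremes", {
  set.seed(1)
  same <- rnorm(12)
  p_same <- two_sample_permutation(same, same, n_perm = 499, seed = 3)$p_value
  expect_gt(p_same, 0.5)
  apart <- two_sample_permutation(rnorm(10) + 20, rnorm(10), n_perm = 999,
                                  seed = 3)
  expect_lt(apart$p_value, 0.005)
  # degenerate: all values equal -> p = 1
  expect_equal(two_sample_permutation(rep(2, 5), rep(2, 4), n_perm = 99,
                                      seed = 1)$p_value, 1)
})

test_that("permutation p-values live in (0, 1] and are seed-reproducible", {
  set.seed(10)
  for (rep in 1:10) {
    a <- rnorm(sample(3:10, 1)); b <- rnorm(sample(3:10, 1), mean = runif(1, 0, 2))
    p <- two_sample_permutation(a, b, n_perm = 199, seed = rep)$p_value
    expect_gt(p, 0); expect_lte(p, 1)
  }
  a <- rnorm(8); b <- rnorm(8)
  r1 <- two_sample_permutation(a, b, n_perm = 299, seed = 42)
  r2 <- two_sample_permutation(a, b, n_perm = 299, seed = 42)
  expect_identical(r1$p_value, r2$p_value)
})

test_that("Spearman rank agreement handles identity, reversal and masks", {
  m <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  m[upper.tri(m)] <- c(1, 2, 3, 4, 5, 6); m <- m + t(m)
  expect_equal(spearman_rank_pairs(m, m), 1)
  rev <- m; rev[upper.tri(rev)] <- 7 - m[upper.tri(m)]
  rev[lower.tri(rev)] <- t(rev)[lower.tri(rev)]
  expect_equal(spearman_rank_pairs(rev, m), -1)
  # toy 4-pair case against the classical rank formula (no ties):
  # ranks x: 1,2,3,4 vs y: 2,1,4,3 -> rho = 1 - 6*4/(4*15) = 0.6
  x <- m; y <- m
  x[upper.tri(x)] <- c(10, 20, 30, 40, NA, NA)
  y[upper.tri(y)] <- c(22, 11, 44, 33, NA, NA)
  x[lower.tri(x)] <- t(x)[lower.tri(x)]; y[lower.tri(y)] <- t(y)[lower.tri(y)]
  expect_equal(spearman_rank_pairs(x, y), 0.6)
  # fewer than 3 common defined pairs -> undefined
  z <- m; z[upper.tri(z)] <- c(1, 2, NA, NA, NA, NA)
  z[lower.tri(z)] <- t(z)[lower.tri(z)]
  expect_true(is.na(spearman_rank_pairs(z, m)))
})

random_dist <- function(S, seed) {
  set.seed(seed)
  co <- matrix(runif(2 * S), S)
  m <- as.matrix(dist(co))
  dimnames(m) <- list(paste0("s", 1:S), paste0("s", 1:S))
  dist_matrix(m, "geo")
}

test_that("Mantel statistic is exact under identity and affine maps", {
  d1 <- random_dist(6, 1)
  res <- mantel_test(d1, d1)
  expect_equal(res$statistic, 1)
  expect_true(res$exact)
  expect_lt(res$p_value, 0.05)
  d2 <- dist_matrix(unclass(d1) * 3 + 0.7 * (1 - diag(6)), "geo")
  expect_equal(mantel_test(d1, d2)$statistic, 1)
})

test_that("exact Mantel enumeration matches the brute-force oracle", {
  set.seed(2)
  for (seed in 1:3) {
    a <- unclass(random_dist(5, seed))
    b <- unclass(random_dist(5, seed + 50))
    res <- mantel_test(dist_matrix(a, "x"), dist_matrix(b, "y"))
    ora <- oracle_mantel_exact(a, b)
    expect_equal(res$statistic, ora$r, tolerance = 1e-12)
    expect_equal(res$p_value, ora$p, tolerance = 1e-12)
  }
})

test_that("Mantel handles masked pairs and zero variance correctly", {
  a <- unclass(random_dist(6, 3))
  a[1, 2] <- a[2, 1] <- NA
  b <- unclass(random_dist(6, 4))
  res <- mantel_test(dist_matrix(a, "x"), dist_matrix(b, "y"))
  ora <- oracle_mantel_exact(a, b)
  expect_equal(res$statistic, ora$r, tolerance = 1e-12)
  expect_equal(res$p_value, ora$p, tolerance = 1e-12)
  flat <- matrix(1, 5, 5, dimnames = dimnames(unclass(random_dist(5, 1))))
  diag(flat) <- 0
  expect_error(mantel_test(dist_matrix(flat, "x"), random_dist(5, 2)),
               "zero variance|undefined")
})

test_that("sampled Mantel p-values are seed-reproducible", {
  d1 <- random_dist(9, 5); d2 <- random_dist(9, 6)
  r1 <- mantel_test(d1, d2, n_perm = 499, seed = 7)
  r2 <- mantel_test(d1, d2, n_perm = 499, seed = 7)
  expect_false(r1$exact)
  expect_identical(r1$p_value, r2$p_value)
})

test_that("Mantel type-I error is near alpha on independent matrices", {
  hits <- 0; nrep <- 1000
  for (i in seq_len(nrep)) {
    d1 <- random_dist(8, 2 * i)
    d2 <- random_dist(8, 2 * i + 1)
    if (mantel_test(d1, d2, n_perm = 99, seed = i)$p_value < 0.05)
      hits <- hits + 1
  }
  expect_lt(abs(hits / nrep - 0.05), 0.02)
})

test_that("Mantel agrees with vegan on fully defined matrices", {
  skip_if_not_installed("vegan")
  d1 <- random_dist(10, 11); d2 <- random_dist(10, 12)
  ours <- mantel_test(d1, d2, n_perm = 999, seed = 1)
  ref <- vegan::mantel(as.dist(unclass(d1)), as.dist(unclass(d2)),
                       permutations = 999)
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
})

test_that("bootstrap interval collapses for identical matrices and narrows with S", {
  d1 <- random_dist(10, 21)
  ci <- mantel_bootstrap_ci(d1, d1, n_boot = 200, seed = 2)
  expect_equal(ci$lower, 1, tolerance = 1e-9)
  expect_equal(ci$upper, 1, tolerance = 1e-9)
  # on IBD data the interval contains the point estimate, and more sites
  # give a narrower interval
  widths <- sapply(c(8, 16), function(S) {
    ds <- small_ibd_ds(31, n_sites = S, n_loci = 8, n = 12)
    de <- pairwise_matrix(ds, "deucl")
    geo <- geographic_distance_matrix(ds, log_transform = TRUE)
    ci <- mantel_bootstrap_ci(de, geo, n_boot = 300, seed = 5)
    expect_gte(ci$point, ci$lower - 1e-9)
    expect_lte(ci$point, ci$upper + 1e-9)
    ci$upper - ci$lower
  })
  expect_lt(widths[2], widths[1])
})

test_that("larger effect sizes give smaller permutation p-values", {
  set.seed(55)
  med_p <- sapply(c(0.2, 1, 3), function(delta) {
    ps <- replicate(20, {
      a <- rnorm(8); b <- rnorm(8) + delta
      two_sample_permutation(a, b, n_perm = 199,
                             seed = sample.int(1e6, 1))$p_value
    })
    median(ps)
  })
  expect_true(all(diff(med_p) <= 0))
})

test_that("tidy rows carry statistic, p, permutations and seed", {
  res <- two_sample_permutation(1:5, 6:10, n_perm = 99, seed = 3)
  row <- as_tidy_row(res, "mean difference")
  expect_equal(names(row), c("statistic", "value", "n_perm", "p", "seed"))
  expect_equal(row$value, -5)
  expect_equal(row$seed, 3)
})
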
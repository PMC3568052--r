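fixed_pair_ds <- function(n = 4) {
  toy_ds(A = matrix(1L, n, 2), B = matrix(2L, n, 2))
}

test_that("theta is 1 for sites fixed for different alleles", {
  for (n in c(2, 5, 9))
    expect_equal(fst_weir_cockerham(fixed_pair_ds(n), "A", "B")$value, 1,
                 tolerance = 1e-12)
})

test_that("theta is non-positive when both sites are copies of the same individuals", {
  set.seed(7)
  g <- matrix(sample(1:4, 40, replace = TRUE), 10, 4)
  ds <- toy_ds(A = g, B = g)
  expect_lte(fst_weir_cockerham(ds, "A", "B")$value, 1e-12)
})

test_that("theta matches the brute-force variance-component oracle", {
  # hand-enumerable toy: 2 sites x 4 individuals x 2 loci
  set.seed(21)
  ds <- toy_ds(A = rbind(c(1L,1L, 2L,3L), c(1L,2L, 3L,3L),
                         c(2L,2L, 2L,2L), c(1L,1L, 2L,3L)),
               B = rbind(c(2L,2L, 3L,3L), c(2L,3L, 2L,3L),
                         c(3L,3L, 3L,3L), c(2L,2L, 2L,2L)))
  expect_equal(fst_weir_cockerham(ds, "A", "B")$value,
               oracle_wc_theta(ds, "A", "B"), tolerance = 1e-12)
  # randomized small instances, including missing data
  for (seed in 1:6) {
    set.seed(seed)
    g1 <- matrix(sample(0:5, 48, replace = TRUE, prob = c(.1, rep(.18, 5))), 8, 6)
    g2 <- matrix(sample(0:5, 36, replace = TRUE, prob = c(.1, rep(.18, 5))), 6, 6)
    ds <- toy_ds(A = g1, B = g2)
    expect_equal(fst_weir_cockerham(ds, "A", "B")$value,
                 oracle_wc_theta(ds, "A", "B"), tolerance = 1e-12)
  }
})

test_that("Jost's D is exactly 1 under complete differentiation", {
  # disjoint allele sets, equal within-site heterozygosity
  ds <- toy_ds(A = matrix(c(1L, 2L), 10, 2, byrow = TRUE),
               B = matrix(c(3L, 4L), 10, 2, byrow = TRUE))
  expect_equal(jost_dest(ds, "A", "B")$value, 1, tolerance = 1e-12)
  expect_equal(jost_dest(fixed_pair_ds(6), "A", "B")$value, 1,
               tolerance = 1e-12)
})

test_that("Jost's D tends to zero for identical allele frequencies", {
  set.seed(8)
  g <- hwe_block(replicate(4, rep(0.25, 4), simplify = FALSE), 200)
  g2 <- hwe_block(replicate(4, rep(0.25, 4), simplify = FALSE), 200)
  ds <- toy_ds(A = g, B = g2)
  expect_lt(abs(jost_dest(ds, "A", "B", combine = "arithmetic")$value), 0.02)
})

test_that("Jost's D matches the direct-formula oracle (both combinations)", {
  for (seed in 1:6) {
    set.seed(seed + 100)
    g1 <- matrix(sample(0:4, 60, replace = TRUE), 10, 6)
    g2 <- matrix(sample(0:4, 48, replace = TRUE), 8, 6)
    ds <- toy_ds(A = g1, B = g2)
    for (comb in c("harmonic", "arithmetic"))
      expect_equal(jost_dest(ds, "A", "B", combine = comb)$value,
                   oracle_jost_d(ds, "A", "B", combine = comb),
                   tolerance = 1e-12)
  }
})

test_that("d_eucl handles identities, fixed differences and monomorphic loci", {
  ds_same <- toy_ds(A = matrix(1L, 5, 2), B = matrix(1L, 5, 2))
  expect_equal(d_eucl(ds_same, "A", "B")$value, 0)
  expect_equal(d_eucl(fixed_pair_ds(), "A", "B")$value, sqrt(2),
               tolerance = 1e-12)
  # appending a monomorphic locus changes nothing
  ds1 <- toy_ds(A = rbind(c(1L,2L), c(2L,2L)), B = rbind(c(1L,1L), c(1L,2L)))
  ds2 <- toy_ds(A = cbind(rbind(c(1L,2L), c(2L,2L)), matrix(7L, 2, 2)),
                B = cbind(rbind(c(1L,1L), c(1L,2L)), matrix(7L, 2, 2)))
  expect_equal(d_eucl(ds1, "A", "B")$value, d_eucl(ds2, "A", "B")$value)
})

test_that("d_eucl matches the counting oracle and satisfies metric axioms", {
  set.seed(31)
  g <- lapply(1:4, function(i) matrix(sample(1:5, 40, replace = TRUE), 5, 8))
  ds <- toy_ds(A = g[[1]], B = g[[2]], C = g[[3]], D = g[[4]])
  labs <- c("A", "B", "C", "D")
  m <- unclass(pairwise_matrix(ds, "deucl"))
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(m[i, j], oracle_deucl(ds, labs[i], labs[j]),
                 tolerance = 1e-12)
  for (i in 1:4) for (j in 1:4) for (k in 1:4)
    expect_lte(m[i, j], m[i, k] + m[k, j] + 1e-12)
})

test_that("pairwise matrices agree with per-pair calls and permute consistently", {
  set.seed(5)
  ds <- small_ibd_ds(5, n_sites = 4, n_loci = 5, n = 8)
  labs <- site_labels <- ds$sites$site
  for (metric in c("fst", "dest", "deucl")) {
    m <- pairwise_matrix(ds, metric)
    expect_equal(sum(!is.na(m[upper.tri(m)])), 6)
    fun <- switch(metric, fst = fst_weir_cockerham, dest = jost_dest,
                  deucl = d_eucl)
    for (i in 1:3) for (j in (i + 1):4)
      expect_equal(m[i, j], fun(ds, labs[i], labs[j])$value)
  }
  # permuting site order permutes the matrix consistently
  perm <- c(3, 1, 4, 2)
  ds2 <- genotype_dataset(ds$genotypes, ds$loci, ds$site,
                          ds$sites[perm, ], ds$id)
  m1 <- unclass(pairwise_matrix(ds, "fst"))
  m2 <- unclass(pairwise_matrix(ds2, "fst"))
  expect_equal(m2, m1[labs[perm], labs[perm]], ignore_attr = TRUE)
})

test_that("pairwise estimates are local: deleting a third site never changes them", {
  # the mechanism behind zero relative error under unsampled sites
  for (seed in 1:4) {
    ds <- small_ibd_ds(seed + 40, n_sites = 6, n_loci = 6, n = 10)
    labs <- ds$sites$site
    drop <- sample(labs[-(1:2)], 1)
    sub <- subset_dataset(ds, sites = setdiff(labs, drop))
    for (metric in c("fst", "dest", "deucl")) {
      full <- pairwise_matrix(ds, metric)
      red <- pairwise_matrix(sub, metric)
      expect_identical(full[labs[1], labs[2]], red[labs[1], labs[2]])
    }
  }
})

test_that("estimators respond monotonically to allele-frequency divergence", {
  # k = 0 would leave every locus monomorphic (theta undefined); start at 1
  vals <- sapply(1:10, function(k) {
    gB <- rbind(matrix(2L, k, 2), matrix(1L, 10 - k, 2))
    ds <- toy_ds(A = matrix(1L, 10, 2), B = gB)
    c(fst = fst_weir_cockerham(ds, "A", "B")$value,
      dest = jost_dest(ds, "A", "B")$value,
      deucl = d_eucl(ds, "A", "B")$value)
  })
  for (metric in rownames(vals))
    expect_true(all(diff(vals[metric, ]) >= -1e-12), info = metric)
})

test_that("D_est stays in [0,1] and theta can be slightly negative, never > 1", {
  set.seed(77)
  for (rep in 1:8) {
    g1 <- matrix(sample(1:3, 32, replace = TRUE), 8, 4)
    g2 <- matrix(sample(1:3, 32, replace = TRUE), 8, 4)
    ds <- toy_ds(A = g1, B = g2)
    d <- jost_dest(ds, "A", "B")$value
    expect_gte(d, 0); expect_lte(d, 1 + 1e-9)
    expect_lte(fst_weir_cockerham(ds, "A", "B")$value, 1 + 1e-12)
  }
})

test_that("per-locus audit table lines up with the estimators", {
  ds <- fixed_pair_ds()
  aud <- per_locus_audit(ds, "A", "B")
  expect_equal(nrow(aud), 1)
  expect_equal(aud$fst, 1, tolerance = 1e-12)
})
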
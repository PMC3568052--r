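test_that("centrality ordering is deterministic, complete and tie-broken by label", {
  ds <- small_ibd_ds(61, n_sites = 8, n_loci = 8, n = 12)
  o1 <- order_sites_by_centrality(ds)
  o2 <- order_sites_by_centrality(ds)
  expect_identical(o1, o2)
  expect_setequal(o1, ds$sites$site)
  # consistency with the underlying graph scores
  g <- build_population_graph(ds)
  sc <- eigenvector_centrality(g)
  comps <- graph_components(g)
  size <- setNames(rep(0L, length(g$nodes)), g$nodes)
  for (cs in comps) size[cs] <- length(cs)
  expect_identical(o1, g$nodes[order(-size[g$nodes], -sc[g$nodes], g$nodes)])
})

test_that("unsampled experiment: pairwise metrics have zero RE, cGD does not", {
  ds <- small_ibd_ds(62, n_sites = 10, n_loci = 8, n = 12)
  tr <- unsampled_experiment(ds, "add_least_connected", n_perm = 99)
  for (m in c("fst", "dest", "deucl"))
    expect_true(all(tr$rel_error_pct[tr$metric == m] == 0), info = m)
  cg <- tr$rel_error_pct[tr$metric == "cgd"]
  expect_true(any(cg[!is.na(cg)] > 0))
})

test_that("unsampled experiment converges exactly at the final iteration", {
  ds <- small_ibd_ds(63, n_sites = 8, n_loci = 8, n = 12)
  geo <- geographic_distance_matrix(ds, log_transform = TRUE)
  for (dir in c("add_least_connected", "add_most_connected")) {
    tr <- unsampled_experiment(ds, dir, n_perm = 99)
    last <- tr[tr$iteration == max(tr$iteration), ]
    expect_true(all(last$rel_error_pct == 0))
    expect_equal(last$spearman_rho, rep(1, nrow(last)), tolerance = 1e-12)
    # iteration 0 has the minimal dataset
    expect_equal(unique(tr$n_active_sites[tr$iteration == 0]), 4)
    # the Mantel r series ends at the full-data value
    core <- attr(tr, "core")
    full_cgd <- conditional_genetic_distance(build_population_graph(ds))
    ref <- mantel_test(
      dist_matrix(unclass(full_cgd)[core, core], "cgd"),
      dist_matrix(unclass(geo)[core, core], "log_geo"), n_perm = 99, seed = 1)
    expect_equal(last$mantel_r[last$metric == "cgd"], ref$statistic)
  }
})

test_that("the two directions use opposite extremes of the same ordering", {
  ds <- small_ibd_ds(64, n_sites = 9, n_loci = 8, n = 12)
  ord <- order_sites_by_centrality(ds)
  t1 <- unsampled_experiment(ds, "add_least_connected", metrics = "deucl",
                             n_perm = 99)
  t2 <- unsampled_experiment(ds, "add_most_connected", metrics = "deucl",
                             n_perm = 99)
  expect_setequal(attr(t1, "core"), ord[1:5])
  expect_setequal(attr(t2, "core"), ord[5:9])
  expect_identical(attr(t1, "added_order"), ord[6:9])
  expect_identical(attr(t2, "added_order"), rev(ord[1:4]))
})

test_that("rarity scores flag private-allele carriers and ignore ordering", {
  g <- matrix(1L, 20, 8)
  g[7, 1:2] <- 5L  # individual 7 carries a private allele at loci 1
  ds <- genotype_dataset(g, paste0("L", 1:4), rep(c("A", "B"), each = 10),
                         data.frame(site = c("A", "B"), x = 1:2, y = 0))
  rs <- rarity_scores(ds)
  expect_equal(which.max(rs$rarity), 7)
  # duplicated individuals share |score|
  g2 <- rbind(g, g[7, ])
  ds2 <- genotype_dataset(g2, paste0("L", 1:4), c(rep(c("A", "B"), each = 10), "B"),
                          data.frame(site = c("A", "B"), x = 1:2, y = 0))
  rs2 <- rarity_scores(ds2)
  expect_equal(rs2$rarity[7], rs2$rarity[21], tolerance = 1e-9)
  # invariance to individual order (up to the same permutation)
  perm <- sample(nrow(g))
  ds3 <- genotype_dataset(g[perm, ], paste0("L", 1:4),
                          rep(c("A", "B"), each = 10)[perm],
                          data.frame(site = c("A", "B"), x = 1:2, y = 0))
  rs3 <- rarity_scores(ds3)
  expect_equal(rs3$score, rs$score[perm], tolerance = 1e-9)
  expect_error(rarity_scores(genotype_dataset(matrix(1L, 3, 2), "L1",
                                              rep("A", 3),
                                              data.frame(site = "A", x = 0, y = 0))),
               "zero-variance")
})

test_that("removal caps reproduce the published ad-hoc rules", {
  n <- setNames(c(47, 27, 27, 11, 20), paste0("s", 1:5))
  r <- popsens:::removal_counts(n, "second_largest")
  expect_equal(unname(r), c(13, 13, 13, 5, 10))   # 47 -> 13, not 23
  n2 <- setNames(c(48, 35, 30), paste0("s", 1:3))
  expect_equal(unname(popsens:::removal_counts(n2, "second_largest")),
               c(17, 17, 15))                      # 48 -> 17
  expect_equal(unname(popsens:::removal_counts(n, "none")),
               c(23, 13, 13, 5, 10))
  expect_equal(unname(popsens:::removal_counts(n, c(s1 = 4))),
               c(4, 13, 13, 5, 10))
})

test_that("under-sampled experiment: structure, convergence and exhaustion", {
  set.seed(65)
  sizes <- c(14, 8, 8, 6, 6, 6)
  ds <- generate_ibd(generator_spec(6, 8, 8, sizes = sizes, ibd_decay = 0.01),
                     seed = 65)
  tr <- undersampled_experiment(ds, "add_rare", n_perm = 99)
  # cap rule: largest site removals capped at second largest (8 -> 4)
  removed <- attr(tr, "removed")
  expect_equal(lengths(removed)[[1]], 4)
  expect_equal(max(tr$iteration), 4)
  # all metrics imperfect at iteration 0 on structured data
  it0 <- tr[tr$iteration == 0, ]
  expect_true(all(it0$rel_error_pct > 0))
  # exact convergence at the final iteration
  last <- tr[tr$iteration == max(tr$iteration), ]
  expect_true(all(last$rel_error_pct == 0))
  expect_equal(last$spearman_rho, rep(1, nrow(last)), tolerance = 1e-12)
})

test_that("re-addition order follows the rarity semantics of the two modes", {
  ds <- small_ibd_ds(66, n_sites = 5, n_loci = 6, n = 10)
  rs <- rarity_scores(ds)
  tr_rare <- undersampled_experiment(ds, "add_rare", metrics = "deucl",
                                     n_perm = 99)
  tr_common <- undersampled_experiment(ds, "add_common", metrics = "deucl",
                                       n_perm = 99)
  rar <- setNames(rs$rarity, rs$id)
  for (ids in attr(tr_rare, "removed")) {
    if (length(ids) < 2) next
    expect_true(all(diff(rar[ids]) >= 0))  # least rare first
    # the removed set holds the site's rarest individuals
    site <- ds$site[match(ids[1], ds$id)]
    others <- setdiff(ds$id[ds$site == site], ids)
    expect_true(min(rar[ids]) >= max(rar[others]) - 1e-12)
  }
  for (ids in attr(tr_common, "removed")) {
    if (length(ids) < 2) next
    expect_true(all(diff(rar[ids]) <= 0))  # least common first
  }
})

test_that("experiments are deterministic given the dataset", {
  ds <- small_ibd_ds(67, n_sites = 8, n_loci = 6, n = 10)
  t1 <- unsampled_experiment(ds, "add_least_connected", metrics = c("cgd", "fst"),
                             n_perm = 99)
  t2 <- unsampled_experiment(ds, "add_least_connected", metrics = c("cgd", "fst"),
                             n_perm = 99)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
})

test_that("summarize_experiment produces summary tables and contrasts", {
  ds <- small_ibd_ds(68, n_sites = 8, n_loci = 6, n = 10)
  tr <- unsampled_experiment(ds, "add_least_connected",
                             metrics = c("cgd", "deucl"), n_perm = 99)
  tab <- summarize_experiment(list(least = tr))
  expect_equal(names(tab), c("trace", "metric", "n", "mean", "sd"))
  expect_equal(tab$mean[tab$metric == "deucl"], 0)
  cmp <- summarize_experiment(
    list(least = tr),
    comparisons = list(list(label = "cgd vs deucl",
                            a = list(trace = "least", metric = "cgd"),
                            b = list(trace = "least", metric = "deucl"))),
    n_perm = 199)
  expect_equal(names(cmp), c("comparison", "mean_a", "mean_b", "cohens_d",
                             "p_value"))
  expect_gt(cmp$cohens_d, 0)
  # identical series: effect size 0 by definition
  same <- summarize_experiment(
    list(a = tr, b = tr),
    comparisons = list(list(label = "same",
                            a = list(trace = "a", metric = "deucl"),
                            b = list(trace = "b", metric = "deucl"))),
    n_perm = 99)
  expect_equal(same$cohens_d, 0)
})

test_that("trace TSV has the fixed column contract", {
  ds <- small_ibd_ds(69, n_sites = 8, n_loci = 6, n = 10)
  tr <- unsampled_experiment(ds, "add_least_connected", metrics = "fst",
                             n_perm = 99)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_trace_tsv(tr, f)
  tab <- read.delim(f)
  expect_equal(names(tab), c("iteration", "metric", "mean_estimate",
                             "rel_error_pct", "spearman_rho", "mantel_r",
                             "mantel_p", "n_components"))
})

test_that("single-site jackknife quantifies cGD sensitivity", {
  ds <- small_ibd_ds(70, n_sites = 7, n_loci = 6, n = 10)
  jk <- cgd_site_jackknife(ds)
  expect_equal(nrow(jk), 8)
  expect_equal(jk$dropped_site[1], "(none)")
  expect_gt(sd(jk$mean_cgd, na.rm = TRUE), 0)
})
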
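#' @name experiments
#' @title Unsampled-site and under-sampled-site subsampling experiments
#'
#' @description
#' The two subsampling protocols at the heart of the sensitivity analysis.
#' The *unsampled-site* experiment removes half of the sites (ranked by
#' eigenvector centrality), then restores them one per iteration while
#' recording pairwise measures only among a fixed core of sites. The
#' *under-sampled-site* experiment removes half of the individuals from every
#' site (ranked by PCA genotype rarity), then restores one individual per site
#' per iteration. Each iteration records, per metric, the mean pairwise
#' estimate, the absolute relative error against the full-data truth, the
#' Spearman rank agreement with the full-data matrix, the Mantel correlation
#' with log geographic distance, and the number of network components.
NULL

# Metric dispatch shared by the experiments: a distance matrix plus the
# component count of the population graph (cgd only).
metric_matrix <- function(ds, metric, alpha = 0.05) {
  if (metric == "cgd") {
    g <- build_population_graph(ds, alpha = alpha)
    list(mat = conditional_genetic_distance(g),
         n_components = length(graph_components(g)))
  } else {
    list(mat = pairwise_matrix(ds, metric), n_components = NA_integer_)
  }
}

mean_defined <- function(m, labels = rownames(m)) {
  v <- pair_values(unclass(m)[labels, labels, drop = FALSE])$value
  if (!length(v)) NA_real_ else mean(v)
}

#' Order sites by eigenvector centrality
#'
#' Total order from most to least connected, based on the eigenvector
#' centrality of the full-data population graph. If the graph is
#' disconnected, centrality is computed per component and components are
#' ordered by size (largest first). Ties are broken by site label.
#'
#' @param ds a [genotype_dataset()].
#' @param alpha pruning significance level for the underlying graph.
#' @return character vector of site labels, most connected first.
#' @export
order_sites_by_centrality <- function(ds, alpha = 0.05) {
  g <- build_population_graph(ds, alpha = alpha)
  sc <- eigenvector_centrality(g)
  comps <- graph_components(g)
  comp_size <- stats::setNames(rep(0L, length(g$nodes)), g$nodes)
  for (cset in comps) comp_size[cset] <- length(cset)
  labs <- g$nodes
  labs[order(-comp_size[labs], -sc[labs], labs)]
}

trace_row <- function(iteration, n_active, metric, mm, core, truth) {
  mean_est <- mean_defined(mm$mat, core)
  data.frame(iteration = iteration, n_active_sites = n_active, metric = metric,
             mean_estimate = mean_est,
             rel_error_pct = if (is.na(mean_est)) NA_real_
             else relative_error(mean_est, truth$mean[[metric]]),
             spearman_rho = spearman_rank_pairs(
               unclass(mm$mat)[core, core, drop = FALSE], truth$mat[[metric]]),
             mantel_r = NA_real_, mantel_p = NA_real_,
             n_components = mm$n_components, stringsAsFactors = FALSE)
}

add_mantel <- function(row, mm, core, geo, n_perm, seed) {
  res <- tryCatch(
    mantel_test(dist_matrix(unclass(mm$mat)[core, core, drop = FALSE],
                            attr(mm$mat, "metric")),
                dist_matrix(unclass(geo)[core, core, drop = FALSE], "log_geo"),
                n_perm = n_perm, seed = seed),
    error = function(e) NULL)
  if (!is.null(res)) { row$mantel_r <- res$statistic; row$mantel_p <- res$p_value }
  row
}

experiment_truth <- function(ds, metrics, core, alpha) {
  mats <- list(); means <- list()
  for (m in metrics) {
    mm <- metric_matrix(ds, m, alpha)
    mats[[m]] <- unclass(mm$mat)[core, core, drop = FALSE]
    means[[m]] <- mean_defined(mm$mat, core)
  }
  list(mat = mats, mean = means)
}

#' Unsampled-site experiment
#'
#' Removes the `floor(S/2)` sites at one extreme of the centrality ordering,
#' then restores them one per iteration, recomputing every metric on the
#' active dataset but summarizing only over pairs among the fixed retained
#' core (so sample size is held constant). `direction = "add_least_connected"`
#' retains the most connected half as the core and restores the least
#' connected sites in order of most to least connected;
#' `"add_most_connected"` retains the least connected half and restores the
#' most connected sites in order of least to most connected. The truth is the
#' full-data value over the same core pairs, so the final iteration has
#' relative error exactly 0 and Spearman rho exactly 1.
#'
#' @param ds a [genotype_dataset()] with at least 6 sites.
#' @param direction which sites are restored (see above).
#' @param metrics metrics to trace, subset of `c("cgd","fst","dest","deucl")`.
#' @param alpha population-graph pruning level.
#' @param n_perm permutations for the per-iteration Mantel test.
#' @param seed seed for the Mantel permutations (the protocol itself is
#'   deterministic: orderings are fully specified by the data).
#' @return data frame of class `experiment_trace` (one row per iteration and
#'   metric) with attributes `core`, `added_order`, `direction`,
#'   `truth_means`.
#' @export
unsampled_experiment <- function(ds,
                                 direction = c("add_least_connected",
                                               "add_most_connected"),
                                 metrics = c("cgd", "fst", "dest", "deucl"),
                                 alpha = 0.05, n_perm = 999, seed = 1) {
  direction <- match.arg(direction)
  metrics <- match.arg(metrics, several.ok = TRUE)
  labs <- site_labels(ds)
  S <- length(labs)
  if (S < 6) stop("unsampled experiment needs >= 6 sites")
  ord <- order_sites_by_centrality(ds, alpha = alpha)
  n_core <- ceiling(S / 2)
  if (direction == "add_least_connected") {
    core <- ord[seq_len(n_core)]
    pool <- ord[seq(n_core + 1, S)]              # most -> least connected
  } else {
    core <- ord[seq(S - n_core + 1, S)]
    pool <- rev(ord[seq_len(S - n_core)])        # least -> most connected
  }
  core <- labs[labs %in% core]
  truth <- experiment_truth(ds, metrics, core, alpha)
  geo <- geographic_distance_matrix(ds, log_transform = TRUE)
  rows <- list()
  for (k in 0:length(pool)) {
    active <- c(core, pool[seq_len(k)])
    sub <- subset_dataset(ds, sites = labs[labs %in% active])
    for (m in metrics) {
      mm <- metric_matrix(sub, m, alpha)
      row <- trace_row(k, length(active), m, mm, core, truth)
      rows[[length(rows) + 1L]] <- add_mantel(row, mm, core, geo, n_perm, seed)
    }
  }
  out <- do.call(rbind, rows)
  structure(out, class = c("experiment_trace", "data.frame"),
            core = core, added_order = pool, direction = direction,
            truth_means = truth$mean)
}

#' PCA rarity scores for individuals
#'
#' First-principal-component scores of the centered (unscaled) individual
#' allele-dosage matrix. Individuals with extreme positive or negative scores
#' carry rare genotypes relative to individuals with scores near zero, so the
#' rarity rank is by descending `|score|` and the commonness rank by ascending
#' `|score|`. The eigenvector sign is fixed by making the largest-magnitude
#' loading positive.
#'
#' @param ds a [genotype_dataset()] with >= 2 individuals.
#' @return data frame `(id, site, score, rarity)` in individual order, where
#'   `rarity = abs(score)`.
#' @export
rarity_scores <- function(ds) {
  if (n_individuals(ds) < 2) stop("rarity scores need >= 2 individuals")
  X <- dosage_matrix(ds)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  if (all(abs(Xc) < 1e-12)) stop("zero-variance genotype data")
  sv <- svd(Xc, nu = 1, nv = 1)
  v <- sv$v[, 1]
  if (v[which.max(abs(v))] < 0) v <- -v
  score <- as.vector(Xc %*% v)
  data.frame(id = ds$id, site = ds$site, score = score, rarity = abs(score),
             stringsAsFactors = FALSE)
}

# Per-site removal counts under the cap rule. The default caps the largest
# site's removals at the second-largest removal count, which reproduces the
# published ad-hoc caps (47 -> 13 when the next sites have 27; 48 -> 17) from
# a single rule.
removal_counts <- function(n_by_site, cap_rule) {
  r <- floor(n_by_site / 2)
  if (is.numeric(cap_rule)) {
    stopifnot(!is.null(names(cap_rule)))
    r[names(cap_rule)] <- pmin(r[names(cap_rule)], cap_rule)
  } else if (identical(cap_rule, "second_largest") && length(r) >= 2) {
    mx <- which.max(r)
    cap <- max(r[-mx])
    r <- pmin(r, cap)
  }
  r
}

#' Under-sampled-site experiment
#'
#' Removes roughly half of the individuals from every site -- those with the
#' most extreme (`mode = "add_rare"`) or the most central
#' (`mode = "add_common"`) PCA rarity scores -- then restores one individual
#' per site per iteration, in order of least to most rare (or least to most
#' common). Sites whose removed individuals run out simply stop receiving
#' additions. All metrics are recomputed on the active dataset over *all*
#' site pairs, with the full dataset as truth.
#'
#' @param ds a [genotype_dataset()]; every site needs >= 2 individuals.
#' @param mode which individuals were removed and are restored (see above).
#' @param metrics,alpha,n_perm,seed as in [unsampled_experiment()].
#' @param cap_rule `"second_largest"` (default: cap the largest site's
#'   removals at the second-largest removal count so the iteration count is
#'   not inflated by one heavily sampled site), `"none"`, or a named numeric
#'   vector of explicit per-site removal caps.
#' @return data frame of class `experiment_trace` with attributes `removed`
#'   (per-site removed ids, in re-addition order) and `mode`.
#' @export
undersampled_experiment <- function(ds, mode = c("add_rare", "add_common"),
                                    metrics = c("cgd", "fst", "dest", "deucl"),
                                    alpha = 0.05, cap_rule = "second_largest",
                                    n_perm = 999, seed = 1) {
  mode <- match.arg(mode)
  metrics <- match.arg(metrics, several.ok = TRUE)
  labs <- site_labels(ds)
  tab <- table(factor(ds$site, levels = labs))
  if (any(tab < 2)) stop("every site needs >= 2 individuals")
  rs <- rarity_scores(ds)
  r <- removal_counts(stats::setNames(as.numeric(tab), labs), cap_rule)
  removed <- list()   # per site: row indices in re-addition order
  for (s in labs) {
    idx <- which(ds$site == s)
    rr <- rs$rarity[idx]
    k <- r[[s]]
    if (k == 0) { removed[[s]] <- integer(0); next }
    sel <- if (mode == "add_rare") idx[order(-rr)][seq_len(k)]
    else idx[order(rr)][seq_len(k)]
    # re-add least extreme of the removal criterion first
    removed[[s]] <- if (mode == "add_rare") sel[order(rs$rarity[sel])]
    else sel[order(-rs$rarity[sel])]
  }
  truth <- experiment_truth(ds, metrics, labs, alpha)
  geo <- geographic_distance_matrix(ds, log_transform = TRUE)
  n_iter <- max(vapply(removed, length, 1L))
  all_removed <- unlist(removed, use.names = FALSE)
  rows <- list()
  for (k in 0:n_iter) {
    back <- unlist(lapply(removed, function(v) v[seq_len(min(k, length(v)))]),
                   use.names = FALSE)
    keep <- setdiff(seq_len(n_individuals(ds)), setdiff(all_removed, back))
    sub <- subset_dataset(ds, individuals = keep)
    for (m in metrics) {
      mm <- metric_matrix(sub, m, alpha)
      row <- trace_row(k, length(labs), m, mm, labs, truth)
      rows[[length(rows) + 1L]] <- add_mantel(row, mm, labs, geo, n_perm, seed)
    }
  }
  out <- do.call(rbind, rows)
  structure(out, class = c("experiment_trace", "data.frame"),
            removed = lapply(removed, function(v) ds$id[v]), mode = mode,
            truth_means = truth$mean)
}

#' Summarize experiment traces
#'
#' With `comparisons = NULL`, returns per-trace, per-metric means and standard
#' deviations of a trace column (default the relative-error series) -- the
#' layout of a summary table of mean RE by metric, dataset and experiment.
#' With a list of comparisons, each entry
#' `list(label=, a=list(trace=, metric=), b=list(trace=, metric=))` contrasts
#' two series via Cohen's d and a two-sample permutation test.
#'
#' @param traces a named list of `experiment_trace` objects (or a single one).
#' @param comparisons optional list of contrasts (see above).
#' @param value trace column to summarize (default `"rel_error_pct"`).
#' @param n_perm,seed permutation-test settings.
#' @return a tidy data frame: `(trace, metric, n, mean, sd)` or
#'   `(comparison, mean_a, mean_b, cohens_d, p_value)`.
#' @export
summarize_experiment <- function(traces, comparisons = NULL,
                                 value = "rel_error_pct",
                                 n_perm = 9999, seed = 1) {
  if (inherits(traces, "experiment_trace")) traces <- list(trace = traces)
  pull <- function(spec) {
    tr <- traces[[spec$trace]]
    if (is.null(tr)) stop("unknown trace: ", spec$trace)
    v <- tr[[value]][tr$metric == spec$metric]
    v[!is.na(v)]
  }
  if (is.null(comparisons)) {
    rows <- list()
    for (nm in names(traces)) {
      tr <- traces[[nm]]
      for (m in unique(tr$metric)) {
        v <- tr[[value]][tr$metric == m]
        v <- v[!is.na(v)]
        rows[[length(rows) + 1L]] <-
          data.frame(trace = nm, metric = m, n = length(v),
                     mean = mean(v), sd = stats::sd(v),
                     stringsAsFactors = FALSE)
      }
    }
    return(do.call(rbind, rows))
  }
  rows <- lapply(comparisons, function(cmp) {
    a <- pull(cmp$a); b <- pull(cmp$b)
    pt <- two_sample_permutation(a, b, n_perm = n_perm, seed = seed)
    # identical series have zero pooled SD; their effect size is 0 by definition
    d <- tryCatch(cohens_d(a, b),
                  error = function(e) if (isTRUE(all.equal(mean(a), mean(b)))) 0
                  else sign(mean(a) - mean(b)) * Inf)
    data.frame(comparison = cmp$label, mean_a = mean(a), mean_b = mean(b),
               cohens_d = d, p_value = pt$p_value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Jackknife cGD variability over site subsets
#'
#' Thin convenience wrapper: repeatedly drops one site and recomputes cGD over
#' the remaining pairs, reporting the spread of the mean pairwise cGD. A
#' practical probe of a network's sensitivity to any single unsampled site.
#'
#' @param ds a [genotype_dataset()].
#' @param alpha pruning level.
#' @return data frame `(dropped_site, mean_cgd)`, one row per site plus a
#'   `"(none)"` row for the full network.
#' @export
cgd_site_jackknife <- function(ds, alpha = 0.05) {
  labs <- site_labels(ds)
  full <- metric_matrix(ds, "cgd", alpha)
  rows <- data.frame(dropped_site = "(none)",
                     mean_cgd = mean_defined(full$mat),
                     stringsAsFactors = FALSE)
  for (s in labs) {
    sub <- subset_dataset(ds, sites = setdiff(labs, s))
    mm <- metric_matrix(sub, "cgd", alpha)
    rows <- rbind(rows, data.frame(dropped_site = s,
                                   mean_cgd = mean_defined(mm$mat),
                                   stringsAsFactors = FALSE))
  }
  rows
}

#' Write an experiment trace as TSV
#'
#' Fixed column layout: `iteration, metric, mean_estimate, rel_error_pct,
#' spearman_rho, mantel_r, mantel_p, n_components`.
#'
#' @param trace an `experiment_trace`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trace_tsv <- function(trace, path) {
  cols <- c("iteration", "metric", "mean_estimate", "rel_error_pct",
            "spearman_rho", "mantel_r", "mantel_p", "n_components")
  utils::write.table(as.data.frame(trace)[, cols], path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
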
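#' @name sensitivity-stats
#' @title Sensitivity statistics
#'
#' @description
#' The summary statistics used by the subsampling experiments: absolute
#' relative error, Cohen's d, two-sample permutation tests, Spearman rank
#' deviation between distance matrices, and Mantel machinery with
#' undefined-pair masking. All randomized procedures are bit-reproducible
#' given a seed.
NULL

# Evaluate code under a temporary RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

#' Absolute relative error (percent)
#'
#' `|estimate - truth| / |truth| * 100`; the iteration-level error measure of
#' the subsampling experiments.
#'
#' @param estimate summary value at an iteration.
#' @param truth full-data ("true") summary value; must be non-zero.
#' @return non-negative percent.
#' @export
relative_error <- function(estimate, truth) {
  if (any(truth == 0)) stop("relative error undefined for truth = 0")
  abs(estimate - truth) / abs(truth) * 100
}

#' Cohen's d effect size
#'
#' Difference between group means divided by the pooled standard deviation
#' (sample variances weighted by their degrees of freedom). Guideline values:
#' 0.2 small, 0.5 medium, 0.8 large.
#'
#' @param group_a,group_b numeric vectors (each of length >= 2).
#' @return signed effect size.
#' @export
cohens_d <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  if (na < 2 || nb < 2) stop("each group needs >= 2 values")
  sp2 <- ((na - 1) * stats::var(group_a) + (nb - 1) * stats::var(group_b)) /
    (na + nb - 2)
  if (sp2 <= 0) stop("pooled standard deviation is zero")
  (mean(group_a) - mean(group_b)) / sqrt(sp2)
}

new_permutation_result <- function(statistic, n_perm, p_value, seed,
                                   method, exact = FALSE) {
  structure(list(statistic = statistic, n_perm = n_perm, p_value = p_value,
                 seed = seed, method = method, exact = exact),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.6g, p = %.4g (%s%d permutations)\n",
              x$method, x$statistic, x$p_value,
              if (x$exact) "exact, " else "", x$n_perm))
  invisible(x)
}

#' Two-sample permutation test for a difference in means
#'
#' Label-permutation test of `mean(a) - mean(b)`; two-sided by default. The
#' p-value uses the add-one rule `p = (1 + #extreme) / (1 + n_perm)` so it is
#' always in (0, 1].
#'
#' @param group_a,group_b numeric vectors (non-empty).
#' @param n_perm number of random label permutations (default 9999).
#' @param seed RNG seed for reproducibility.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return a `permutation_result`.
#' @export
two_sample_permutation <- function(group_a, group_b, n_perm = 9999,
                                   seed = NULL,
                                   alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (!length(group_a) || !length(group_b)) stop("both groups must be non-empty")
  pool <- c(group_a, group_b)
  na <- length(group_a)
  obs <- mean(group_a) - mean(group_b)
  perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(length(pool), na)
    mean(pool[idx]) - mean(pool[-idx])
  }, numeric(1)))
  extreme <- switch(alternative,
                    two.sided = abs(perm) >= abs(obs) - 1e-12,
                    greater = perm >= obs - 1e-12,
                    less = perm <= obs + 1e-12)
  p <- (1 + sum(extreme)) / (1 + n_perm)
  new_permutation_result(obs, n_perm, p, seed, "two-sample permutation test")
}

#' Spearman rank agreement between two distance matrices
#'
#' Spearman's rho over the off-diagonal pairs defined in *both* matrices
#' (undefined/masked pairs are dropped), with average-rank ties. Used to track
#' how the rank order of pairwise cGD in a subsampled network deviates from
#' the full-data network.
#'
#' @param current,full [dist_matrix()] objects (or plain labelled matrices);
#'   compared over their common site labels.
#' @return Spearman's rho, or `NA` when fewer than 3 common defined pairs
#'   exist.
#' @export
spearman_rank_pairs <- function(current, full) {
  common <- intersect(rownames(current), rownames(full))
  a <- unclass(current)[common, common, drop = FALSE]
  b <- unclass(full)[common, common, drop = FALSE]
  ut <- upper.tri(a)
  ok <- ut & !is.na(a) & !is.na(b)
  if (sum(ok) < 3) return(NA_real_)
  stats::cor(a[ok], b[ok], method = "spearman")
}

# All permutations of 1..n (n small), one per row.
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  k <- 0L
  for (pos in seq_len(n)) {
    blk <- matrix(0L, nrow(sub), n)
    blk[, pos] <- n
    blk[, -pos] <- sub
    out[k + seq_len(nrow(sub)), ] <- blk
    k <- k + nrow(sub)
  }
  out
}

mantel_r_masked <- function(a, b) {
  ut <- upper.tri(a)
  ok <- ut & !is.na(a) & !is.na(b)
  if (sum(ok) < 3) return(NA_real_)
  x <- a[ok]; y <- b[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Mantel test between two distance matrices
#'
#' Mantel correlation `r` = Pearson correlation of the off-diagonal
#' upper-triangle entries, with significance from simultaneous row/column
#' permutation of the second matrix. Undefined pairs are excluded pairwise,
#' and each permutation statistic is computed under the same pairwise
#' exclusion rule. The test is one-sided for positive association by default
#' (every isolation-by-distance/resistance use here tests a positive
#' relationship). With `S <= exact_max` sites, all `S!` permutations are
#' enumerated and the p-value is exact.
#'
#' @param d1,d2 [dist_matrix()] objects over the same site set.
#' @param n_perm number of random permutations when enumeration is not used.
#' @param seed RNG seed.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @param exact_max enumerate all permutations when the number of sites is at
#'   most this (default 7).
#' @return a `permutation_result` with the observed `r` as statistic.
#' @export
mantel_test <- function(d1, d2, n_perm = 9999, seed = NULL,
                        alternative = c("greater", "two.sided"),
                        exact_max = 7) {
  alternative <- match.arg(alternative)
  if (!setequal(rownames(d1), rownames(d2)))
    stop("Mantel test needs the same site sets")
  labs <- rownames(d1)
  S <- length(labs)
  if (S < 4) stop("Mantel test needs >= 4 sites")
  a <- unclass(d1)[labs, labs]
  b <- unclass(d2)[labs, labs]
  obs <- mantel_r_masked(a, b)
  if (is.na(obs))
    stop("Mantel statistic undefined (zero variance or < 3 defined pairs)")
  score <- function(r) switch(alternative,
                              greater = r >= obs - 1e-12,
                              two.sided = abs(r) >= abs(obs) - 1e-12)
  if (S <= exact_max) {
    perms <- all_permutations(S)
    rs <- vapply(seq_len(nrow(perms)), function(k) {
      p <- perms[k, ]
      mantel_r_masked(a, b[p, p])
    }, numeric(1))
    ok <- !is.na(rs)
    p <- sum(score(rs[ok])) / sum(ok)
    return(new_permutation_result(obs, nrow(perms), p, seed,
                                  "Mantel test", exact = TRUE))
  }
  rs <- with_seed(seed, vapply(seq_len(n_perm), function(k) {
    p <- sample.int(S)
    mantel_r_masked(a, b[p, p])
  }, numeric(1)))
  rs <- rs[!is.na(rs)]
  p <- (1 + sum(score(rs))) / (1 + length(rs))
  new_permutation_result(obs, n_perm, p, seed, "Mantel test")
}

#' Site-subsampling bootstrap interval for the Mantel correlation
#'
#' Percentile interval of the Mantel `r` over repeated recomputation on a
#' random fraction of the sites, sampled without replacement (default 90% of
#' sites, 10,000 draws). Degenerate draws (zero variance or too few defined
#' pairs) are skipped and counted.
#'
#' @param d1,d2 [dist_matrix()] objects over the same site set (>= 5 sites).
#' @param n_boot number of subsample draws.
#' @param frac fraction of sites per draw.
#' @param level interval coverage (default 0.95).
#' @param seed RNG seed.
#' @return list with `point`, `lower`, `upper`, `level`, `n_boot`,
#'   `n_skipped`.
#' @export
mantel_bootstrap_ci <- function(d1, d2, n_boot = 10000, frac = 0.90,
                                level = 0.95, seed = NULL) {
  if (!setequal(rownames(d1), rownames(d2)))
    stop("Mantel bootstrap needs the same site sets")
  labs <- rownames(d1)
  S <- length(labs)
  if (S < 5) stop("Mantel bootstrap needs >= 5 sites")
  a <- unclass(d1)[labs, labs]
  b <- unclass(d2)[labs, labs]
  m <- max(4L, round(frac * S))
  rs <- with_seed(seed, vapply(seq_len(n_boot), function(k) {
    idx <- sample.int(S, m)
    mantel_r_masked(a[idx, idx], b[idx, idx])
  }, numeric(1)))
  skipped <- sum(is.na(rs))
  rs <- rs[!is.na(rs)]
  if (!length(rs)) stop("all bootstrap draws were degenerate")
  qs <- stats::quantile(rs, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  list(point = mantel_r_masked(a, b), lower = qs[1], upper = qs[2],
       level = level, n_boot = n_boot, n_skipped = skipped)
}

#' Tidy one-row summary of a permutation result
#'
#' @param x a `permutation_result`.
#' @param statistic label for the statistic column.
#' @return one-row data frame `(statistic, value, n_perm, p, seed)` matching
#'   the package's TSV output conventions.
#' @export
as_tidy_row <- function(x, statistic = x$method) {
  data.frame(statistic = statistic, value = x$statistic, n_perm = x$n_perm,
             p = x$p_value, seed = if (is.null(x$seed)) NA_integer_ else x$seed,
             stringsAsFactors = FALSE)
}
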
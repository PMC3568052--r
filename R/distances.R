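#' @name distances
#' @title Pairwise genetic differentiation estimators
#'
#' @description
#' Three site-pair differentiation measures used throughout the package:
#' Weir-Cockerham theta (`fst`), Jost's D with Nei-Chesser sample-size
#' corrections (`dest`), and the Euclidean distance between site
#' allele-frequency vectors (`deucl`). All three are strictly *pairwise*:
#' the estimate for a pair of sites depends only on the genotypes sampled at
#' those two sites, which is the mechanism behind their zero relative error
#' under unsampled-site experiments.
NULL

# Per-locus statistics needed by the estimators.
# For theta an individual counts at a locus only when both alleles are
# observed (genotypic heterozygosity is part of the estimator); frequency-based
# measures (dest, deucl) use gene-copy-wise exclusion instead.
locus_stats <- function(ds) {
  S <- length(site_labels(ds)); L <- n_loci(ds)
  sf <- factor(ds$site, levels = site_labels(ds))
  aft <- allele_frequencies(ds)
  out <- vector("list", L)
  for (l in seq_len(L)) {
    a1 <- ds$genotypes[, 2L * l - 1L]; a2 <- ds$genotypes[, 2L * l]
    comp <- a1 > 0L & a2 > 0L
    obs <- sort(unique(c(a1[comp], a2[comp])))
    A <- length(obs)
    n <- as.numeric(table(sf[comp]))
    cnt <- matrix(0, S, A, dimnames = list(site_labels(ds), as.character(obs)))
    het <- cnt
    if (A > 0 && any(comp)) {
      sc <- sf[comp]; g1 <- a1[comp]; g2 <- a2[comp]
      for (u in seq_len(A)) {
        dose <- (g1 == obs[u]) + (g2 == obs[u])
        cnt[, u] <- tapply(dose, sc, sum, default = 0)
        het[, u] <- tapply(dose == 1L, sc, sum, default = 0)
      }
    }
    p <- cnt / ifelse(2 * n > 0, 2 * n, 1)
    p[n == 0, ] <- NA_real_
    out[[l]] <- list(alleles = obs, n = n, p = p, het = het,
                     f = aft$freq[[l]], copies = aft$copies[, l])
  }
  names(out) <- ds$loci
  out
}

# Weir-Cockerham variance components for one locus, two populations.
# Returns the per-allele a, b, c components (NULL if the locus is unusable).
wc_components <- function(st, i, j) {
  n1 <- st$n[i]; n2 <- st$n[j]
  if (n1 < 1 || n2 < 1 || n1 + n2 < 3) return(NULL)
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
  p1 <- st$p[i, ]; p2 <- st$p[j, ]
  h1 <- st$het[i, ] / n1; h2 <- st$het[j, ] / n2
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (n1 + n2)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c <- hbar / 2
  list(a = a, b = b, c = c)
}

#' Pairwise Weir-Cockerham theta
#'
#' Multilocus theta for one pair of sites: the ratio of the summed
#' among-population variance components to the summed total variance
#' components over all loci and alleles (the multilocus combination used by
#' GENEPOP-style F-statistics, not a mean of per-locus ratios). Values may be
#' slightly negative by estimator construction and are reported as computed.
#'
#' @param ds a [genotype_dataset()].
#' @param site_a,site_b site labels.
#' @param stats optional precomputed result of the internal locus statistics
#'   (used by [pairwise_matrix()] to avoid recomputation).
#' @return list of class `pairwise_estimate` with elements `pair`, `value`,
#'   `per_locus` (per-locus ratios, for audit) and `metric`. `value` is `NA`
#'   when no locus is usable.
#' @export
fst_weir_cockerham <- function(ds, site_a, site_b, stats = NULL) {
  st <- if (is.null(stats)) locus_stats(ds) else stats
  i <- match(site_a, site_labels(ds)); j <- match(site_b, site_labels(ds))
  if (anyNA(c(i, j))) stop("unknown site label")
  num <- 0; den <- 0
  per_locus <- stats::setNames(rep(NA_real_, length(st)), names(st))
  for (l in seq_along(st)) {
    comp <- wc_components(st[[l]], i, j)
    if (is.null(comp)) next
    sa <- sum(comp$a); stot <- sum(comp$a + comp$b + comp$c)
    num <- num + sa; den <- den + stot
    if (stot > 0) per_locus[l] <- sa / stot
  }
  value <- if (den > 0) num / den else NA_real_
  structure(list(pair = c(site_a, site_b), value = value,
                 per_locus = per_locus, metric = "fst"),
            class = "pairwise_estimate")
}

# Per-locus Jost D for two demes with Nei-Chesser corrected heterozygosities.
jost_d_locus <- function(f1, f2, n1, n2) {
  if (anyNA(f1) || anyNA(f2) || n1 <= 0 || n2 <= 0) return(NA_real_)
  ntilde <- 2 / (1 / n1 + 1 / n2)
  if (2 * ntilde <= 1) return(NA_real_)
  hs <- 1 - (sum(f1^2) + sum(f2^2)) / 2
  ht <- 1 - sum(((f1 + f2) / 2)^2)
  hs_est <- 2 * ntilde / (2 * ntilde - 1) * hs
  ht_est <- ht + hs_est / (4 * ntilde)
  if (1 - hs_est <= 0) return(NA_real_)
  2 * (ht_est - hs_est) / (1 - hs_est)
}

#' Pairwise Jost's D
#'
#' Per-locus D for the two demes, `D = [(Ht - Hs)/(1 - Hs)] * n/(n-1)` with
#' `n = 2` demes and Nei-Chesser sample-size-corrected heterozygosities
#' (deme sizes counted in diploid individuals equivalent, i.e. gene copies/2,
#' combined by harmonic mean). Loci where the corrected within-deme
#' heterozygosity reaches 1 are skipped (the ratio is undefined).
#'
#' @inheritParams fst_weir_cockerham
#' @param combine multilocus combination: `"harmonic"` (harmonic mean of
#'   per-locus values truncated below at `eps`, as reported by SMOGD) or
#'   `"arithmetic"`.
#' @param eps truncation floor for non-positive per-locus values under the
#'   harmonic combination.
#' @return a `pairwise_estimate` (see [fst_weir_cockerham()]).
#' @export
jost_dest <- function(ds, site_a, site_b, combine = c("harmonic", "arithmetic"),
                      eps = 1e-6, stats = NULL) {
  combine <- match.arg(combine)
  st <- if (is.null(stats)) locus_stats(ds) else stats
  i <- match(site_a, site_labels(ds)); j <- match(site_b, site_labels(ds))
  if (anyNA(c(i, j))) stop("unknown site label")
  per_locus <- stats::setNames(rep(NA_real_, length(st)), names(st))
  for (l in seq_along(st)) {
    s <- st[[l]]
    per_locus[l] <- jost_d_locus(s$f[i, ], s$f[j, ],
                                 s$copies[i] / 2, s$copies[j] / 2)
  }
  usable <- per_locus[!is.na(per_locus)]
  value <- if (length(usable) == 0) NA_real_
  else if (combine == "harmonic") length(usable) / sum(1 / pmax(usable, eps))
  else mean(usable)
  structure(list(pair = c(site_a, site_b), value = value,
                 per_locus = per_locus, metric = "dest"),
            class = "pairwise_estimate")
}

#' Pairwise Euclidean allele-frequency distance
#'
#' The straight-line distance between the two sites in multivariate
#' allele-frequency space: the Euclidean norm of the difference between their
#' concatenated per-locus frequency vectors (alleles absent from a site count
#' as frequency 0; loci with no data at either site are skipped). The default
#' is the raw norm; `scaling = "rogers"` instead averages the per-locus
#' half-scaled norms (Rogers' distance).
#'
#' @inheritParams fst_weir_cockerham
#' @param scaling `"raw"` or `"rogers"`.
#' @return a `pairwise_estimate` (see [fst_weir_cockerham()]).
#' @export
d_eucl <- function(ds, site_a, site_b, scaling = c("raw", "rogers"),
                   stats = NULL) {
  scaling <- match.arg(scaling)
  st <- if (is.null(stats)) locus_stats(ds) else stats
  i <- match(site_a, site_labels(ds)); j <- match(site_b, site_labels(ds))
  if (anyNA(c(i, j))) stop("unknown site label")
  per_locus <- stats::setNames(rep(NA_real_, length(st)), names(st))
  for (l in seq_along(st)) {
    f1 <- st[[l]]$f[i, ]; f2 <- st[[l]]$f[j, ]
    if (anyNA(f1) || anyNA(f2)) next
    per_locus[l] <- sum((f1 - f2)^2)
  }
  ss <- per_locus[!is.na(per_locus)]
  value <- if (length(ss) == 0) NA_real_
  else if (scaling == "raw") sqrt(sum(ss))
  else mean(sqrt(ss / 2))
  structure(list(pair = c(site_a, site_b), value = value,
                 per_locus = per_locus, metric = "deucl"),
            class = "pairwise_estimate")
}

#' @export
print.pairwise_estimate <- function(x, ...) {
  cat(sprintf("%s(%s, %s) = %.6g\n", x$metric, x$pair[1], x$pair[2], x$value))
  invisible(x)
}

#' Pairwise distance matrix over all site pairs
#'
#' @param ds a [genotype_dataset()].
#' @param metric one of `"fst"`, `"dest"`, `"deucl"`.
#' @param ... passed to the per-pair estimator (`combine`, `eps`, `scaling`).
#' @return a [dist_matrix()] over all sites; undefined pairs are `NA`.
#' @export
pairwise_matrix <- function(ds, metric = c("fst", "dest", "deucl"), ...) {
  metric <- match.arg(metric)
  fun <- switch(metric, fst = fst_weir_cockerham, dest = jost_dest,
                deucl = d_eucl)
  st <- locus_stats(ds)
  labs <- site_labels(ds)
  m <- matrix(NA_real_, length(labs), length(labs), dimnames = list(labs, labs))
  diag(m) <- 0
  if (length(labs) >= 2) {
    for (i in seq_len(length(labs) - 1)) for (j in seq(i + 1, length(labs))) {
      v <- fun(ds, labs[i], labs[j], stats = st, ...)$value
      m[i, j] <- v; m[j, i] <- v
    }
  }
  dist_matrix(m, metric = metric)
}

#' Per-locus audit table for a site pair
#'
#' @param ds a [genotype_dataset()].
#' @param site_a,site_b site labels.
#' @param ... passed to the estimators.
#' @return data frame with one row per locus and one column per metric.
#' @export
per_locus_audit <- function(ds, site_a, site_b, ...) {
  st <- locus_stats(ds)
  data.frame(locus = ds$loci,
             fst = fst_weir_cockerham(ds, site_a, site_b, stats = st)$per_locus,
             dest = jost_dest(ds, site_a, site_b, stats = st, ...)$per_locus,
             deucl_sq = d_eucl(ds, site_a, site_b, stats = st)$per_locus,
             row.names = NULL)
}
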
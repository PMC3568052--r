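#' @name popgraph
#' @title Population graphs and conditional genetic distance
#'
#' @description
#' A population graph is a network whose nodes are sampling sites and whose
#' edges are retained only where the genetic covariance between two sites is
#' significant *conditional on all other sites*. Conditional genetic distance
#' (cGD) between two sites is the shortest path through the pruned network, so
#' unlike strictly pairwise estimators it depends on every site included in the
#' analysis.
NULL

# Individual allele-dosage encoding: one column per (locus, allele) observed in
# the whole dataset, entries = allele count / 2. A missing genotype at a locus
# contributes the site-mean dosage for those columns (mean imputation keeps the
# centroid algebra exact); sites with no data at a locus fall back to the
# dataset-wide mean.
dosage_matrix <- function(ds) {
  n <- n_individuals(ds)
  sf <- factor(ds$site, levels = site_labels(ds))
  blocks <- vector("list", n_loci(ds))
  for (l in seq_len(n_loci(ds))) {
    a1 <- ds$genotypes[, 2L * l - 1L]; a2 <- ds$genotypes[, 2L * l]
    comp <- a1 > 0L & a2 > 0L
    obs <- sort(unique(c(a1[comp], a2[comp])))
    if (length(obs) == 0L) next
    X <- matrix(NA_real_, n, length(obs),
                dimnames = list(NULL, paste(ds$loci[l], obs, sep = ".")))
    X[comp, ] <- (outer(a1[comp], obs, "==") + outer(a2[comp], obs, "==")) / 2
    if (any(!comp)) {
      for (u in seq_along(obs)) {
        sm <- tapply(X[comp, u], sf[comp], mean)
        fill <- sm[as.character(sf[!comp])]
        fill[is.na(fill)] <- mean(X[comp, u])
        X[!comp, u] <- fill
      }
    }
    blocks[[l]] <- X
  }
  do.call(cbind, blocks)
}

#' Partial correlations from a covariance or correlation matrix
#'
#' Standardizes `sigma` to a correlation matrix, takes its (pseudo-)inverse --
#' the precision matrix -- and returns the partial correlations
#' `rho_ij = -omega_ij / sqrt(omega_ii * omega_jj)`.
#'
#' With `lambda > 0` the positive eigenvalues `e` of the correlation matrix
#' are shrunk to `(1 - lambda) * e + lambda` before inversion (linear
#' shrinkage toward the identity, restricted to the range so that null
#' directions -- e.g. the compositional constraint of a double-centered
#' matrix -- stay excluded). `lambda = 0` is the plain Moore-Penrose path.
#'
#' Exported because it is the numerical core of population-graph pruning and
#' is useful for checking against explicit regression-residual computations.
#'
#' @param sigma symmetric covariance/correlation matrix.
#' @param lambda shrinkage intensity in `[0, 1]`.
#' @param tol eigenvalue tolerance for the rank decision.
#' @return symmetric matrix of partial correlations (unit diagonal).
#' @export
partial_correlations <- function(sigma, lambda = 0,
                                 tol = sqrt(.Machine$double.eps)) {
  sigma <- as.matrix(sigma)
  d <- diag(sigma)
  if (any(d <= 0)) stop("non-positive diagonal in covariance matrix")
  R <- sigma / sqrt(d %o% d)
  es <- eigen(R, symmetric = TRUE)
  keep <- es$values > max(es$values) * tol
  ev <- (1 - lambda) * es$values[keep] + lambda
  U <- es$vectors[, keep, drop = FALSE]
  omega <- U %*% (t(U) / ev)
  do <- diag(omega)
  do[do <= 0] <- NA_real_
  rho <- -omega / sqrt(do %o% do)
  diag(rho) <- 1
  dimnames(rho) <- dimnames(sigma)
  (rho + t(rho)) / 2
}

#' Shrinkage intensity for an among-site correlation matrix
#'
#' Ledoit-Wolf/Schafer-Strimmer optimal intensity for shrinking a correlation
#' matrix toward the identity, `lambda* = sum(Var(r_ij)) / sum(r_ij^2)`, with
#' the variances of the correlation estimates computed from the per-axis
#' products. `z` holds the observations in rows (here: allele axes) and the
#' variables in columns (sites).
#'
#' @param z observations-by-variables matrix.
#' @return shrinkage intensity in `[0, 1]`.
#' @export
shrinkage_intensity <- function(z) {
  n <- nrow(z)
  if (n < 3) return(1)
  zs <- scale(z) * sqrt(n / (n - 1))
  zs[is.nan(zs)] <- 0
  R <- crossprod(zs) / (n - 1)
  S <- ncol(z)
  num <- 0; den <- 0
  for (i in seq_len(S - 1)) for (j in seq(i + 1, S)) {
    w <- zs[, i] * zs[, j]
    num <- num + n / (n - 1)^3 * sum((w - mean(w))^2)
    den <- den + R[i, j]^2
  }
  if (den <= 0) return(1)
  max(0, min(1, num / den))
}

#' Build a population graph
#'
#' Constructs the conditional-independence genetic network of the sampled
#' sites: (i) site centroids are the means of the individual allele-dosage
#' vectors; (ii) the among-site covariance structure is obtained by
#' double-centering the squared centroid-distance matrix
#' (`C = -1/2 * H D^2 H`); (iii) `C` is standardized to a correlation matrix
#' whose precision (pseudo-inverse) yields partial correlations; (iv) each
#' candidate edge is tested with the edge-exclusion deviance
#' `-N * log(1 - rho^2)` against the upper-`alpha` quantile of chi-squared with
#' 1 df, and non-significant edges are removed in one shot; (v) retained edges
#' are weighted by the Euclidean distance between the two site centroids.
#'
#' The among-site covariance is estimated *across allele axes*, so the
#' deviance sample size `N` is, by default, the number of independent axes
#' (dosage columns minus one compositional constraint per locus). This keeps
#' the test calibrated: with `deviance_n = "individuals"` (the number of
#' genotyped individuals, an alternative reading of the edge-exclusion test)
#' the threshold falls below the sampling noise of the partial correlations
#' and graphs saturate, collapsing conditional genetic distance onto the
#' direct centroid distances.
#'
#' With `shrinkage = "auto"` (the default) the correlation matrix is shrunk
#' toward the identity with the Ledoit-Wolf/Schafer-Strimmer intensity
#' estimated from the axes (see [shrinkage_intensity()]) before inversion.
#' This stabilizes the precision matrix when the among-site correlations are
#' strong but noisily estimated; for cleanly structured data the estimated
#' intensity is near zero and the procedure reduces to the plain
#' pseudo-inverse (`shrinkage = "none"`).
#'
#' Double-centering always leaves the centered correlation matrix singular by
#' one dimension, so the pseudo-inverse is the normal path; a warning is
#' emitted only when the rank drops further (collinear centroids).
#'
#' @param ds a [genotype_dataset()] with at least 3 sites.
#' @param alpha edge-exclusion significance level in (0,1); default 0.05.
#' @param shrinkage `"auto"` (data-driven intensity, default) or `"none"`.
#' @param deviance_n sample size used in the edge-exclusion deviance:
#'   `"axes"` (default) or `"individuals"`.
#' @param weighting retained-edge weight rule; `"centroid_distance"` (the
#'   Euclidean distance between site centroids, i.e. the d_eucl of the mean
#'   dosage vectors) is the implemented rule.
#' @return An object of class `population_graph`: list with `nodes`, `coords`,
#'   `edges` (data frame over all node pairs: `a`, `b`, `rho`, `deviance`,
#'   `retained`, `weight`), `alpha`, `lambda` (shrinkage intensity used),
#'   `n_individuals`.
#' @export
build_population_graph <- function(ds, alpha = 0.05,
                                   shrinkage = c("auto", "none"),
                                   deviance_n = c("axes", "individuals"),
                                   weighting = c("centroid_distance")) {
  weighting <- match.arg(weighting)
  shrinkage <- match.arg(shrinkage)
  deviance_n <- match.arg(deviance_n)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0,1)")
  labs <- site_labels(ds)
  S <- length(labs)
  if (S < 3) stop("population graph needs at least 3 sites")
  X <- dosage_matrix(ds)
  if (is.null(X)) stop("no usable loci")
  cent <- rowsum(X, factor(ds$site, levels = labs)) /
    as.vector(table(factor(ds$site, levels = labs)))
  D <- as.matrix(stats::dist(cent))
  H <- diag(S) - matrix(1 / S, S, S)
  C <- -0.5 * H %*% (D^2) %*% H
  C <- (C + t(C)) / 2
  dimnames(C) <- list(labs, labs)
  if (any(diag(C) <= .Machine$double.eps * max(abs(C))))
    stop("degenerate configuration: a site centroid coincides with the grand centroid")
  ev <- eigen(C / sqrt(diag(C) %o% diag(C)), symmetric = TRUE, only.values = TRUE)$values
  rank <- sum(ev > max(ev) * sqrt(.Machine$double.eps))
  if (rank < S - 1)
    warning("among-site correlation matrix has rank ", rank,
            " < ", S - 1, "; pseudo-inverse used on a deficient structure")
  lambda <- if (shrinkage == "auto")
    shrinkage_intensity(t(sweep(cent, 2, colMeans(cent)))) else 0
  rho <- partial_correlations(C, lambda = lambda)
  N <- if (deviance_n == "axes") ncol(X) - n_loci(ds) else n_individuals(ds)
  crit <- stats::qchisq(1 - alpha, df = 1)
  ut <- which(upper.tri(rho), arr.ind = TRUE)
  r <- rho[ut]
  dev <- -N * log(pmax(1 - r^2, .Machine$double.xmin))
  retained <- dev > crit
  edges <- data.frame(a = labs[ut[, 1]], b = labs[ut[, 2]],
                      rho = r, deviance = dev, retained = retained,
                      weight = ifelse(retained, D[ut], NA_real_),
                      stringsAsFactors = FALSE)
  structure(list(nodes = labs,
                 coords = ds$sites[match(labs, ds$sites$site), c("x", "y")],
                 edges = edges, alpha = alpha, lambda = lambda,
                 n_individuals = n_individuals(ds), deviance_n = N),
            class = "population_graph")
}

#' @export
print.population_graph <- function(x, ...) {
  cat("population_graph:", length(x$nodes), "nodes,",
      sum(x$edges$retained), "of", nrow(x$edges),
      "edges retained (alpha =", x$alpha, ")\n")
  invisible(x)
}

# igraph view of the retained edge set (keeps isolated nodes).
pg_igraph <- function(graph) {
  e <- graph$edges[graph$edges$retained, c("a", "b", "weight"), drop = FALSE]
  igraph::graph_from_data_frame(e, directed = FALSE,
                                vertices = data.frame(name = graph$nodes))
}

#' Conditional genetic distance (cGD)
#'
#' All-pairs shortest-path sums over the retained edge weights of a population
#' graph. Pairs of sites in different connected components have no path and
#' are undefined (`NA`) -- data, not an error.
#'
#' @param graph a [build_population_graph()] result.
#' @return a [dist_matrix()] with metric `"cgd"`.
#' @export
conditional_genetic_distance <- function(graph) {
  g <- pg_igraph(graph)
  m <- igraph::distances(g, weights = igraph::E(g)$weight)
  m <- m[graph$nodes, graph$nodes]
  m[is.infinite(m)] <- NA_real_
  dist_matrix(m, metric = "cgd")
}

#' Eigenvector centrality of a population graph
#'
#' Principal-eigenvector scores of the adjacency structure of the pruned
#' graph, computed per connected component and normalized so the maximum score
#' in each component is 1; scores are non-negative. The default adjacency is
#' binary: edge weights here are distances (large weight = weak connection),
#' so weighting centrality by them would invert its meaning. `weighted = TRUE`
#' uses `1/weight` instead.
#'
#' @param graph a [build_population_graph()] result.
#' @param weighted use inverse-weight adjacency?
#' @return named numeric vector of scores (0 for isolated nodes).
#' @export
eigenvector_centrality <- function(graph, weighted = FALSE) {
  if (length(graph$nodes) == 0) stop("empty graph")
  A <- matrix(0, length(graph$nodes), length(graph$nodes),
              dimnames = list(graph$nodes, graph$nodes))
  e <- graph$edges[graph$edges$retained, , drop = FALSE]
  if (nrow(e)) {
    w <- if (weighted) 1 / e$weight else rep(1, nrow(e))
    A[cbind(e$a, e$b)] <- w
    A[cbind(e$b, e$a)] <- w
  }
  scores <- stats::setNames(rep(0, length(graph$nodes)), graph$nodes)
  for (comp in graph_components(graph)) {
    if (length(comp) == 1) next
    sub <- A[comp, comp, drop = FALSE]
    es <- eigen(sub, symmetric = TRUE)
    v <- abs(es$vectors[, 1])
    scores[comp] <- v / max(v)
  }
  scores
}

#' Connected components of a population graph
#'
#' @param graph a [build_population_graph()] result.
#' @return list of character vectors (node sets), largest component first.
#' @export
graph_components <- function(graph) {
  g <- pg_igraph(graph)
  cmp <- igraph::components(g)
  sets <- split(names(cmp$membership), cmp$membership)
  sets <- lapply(sets, function(s) graph$nodes[graph$nodes %in% s])
  unname(sets[order(-vapply(sets, length, 1L),
                    vapply(sets, function(s) s[1], ""))])
}

#' Export a population graph to GraphML
#'
#' Nodes carry coordinates and eigenvector centrality; edges carry weights.
#'
#' @param graph a [build_population_graph()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_popgraph_graphml <- function(graph, path) {
  g <- pg_igraph(graph)
  ord <- match(igraph::V(g)$name, graph$nodes)
  igraph::V(g)$x <- graph$coords$x[ord]
  igraph::V(g)$y <- graph$coords$y[ord]
  igraph::V(g)$centrality <- eigenvector_centrality(graph)[igraph::V(g)$name]
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
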
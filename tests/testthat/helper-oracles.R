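# Independent brute-force oracles. These deliberately share no code with the
# package implementations: explicit loops, textbook formulas, naive
# shortest-path and permutation enumeration.

# Weir-Cockerham two-population multilocus theta by direct enumeration.
oracle_wc_theta <- function(ds, site_a, site_b) {
  num <- 0; den <- 0
  for (l in seq_along(ds$loci)) {
    a1 <- ds$genotypes[, 2 * l - 1]; a2 <- ds$genotypes[, 2 * l]
    ok <- a1 > 0 & a2 > 0
    ga1 <- a1[ok & ds$site == site_a]; ga2 <- a2[ok & ds$site == site_a]
    gb1 <- a1[ok & ds$site == site_b]; gb2 <- a2[ok & ds$site == site_b]
    n1 <- length(ga1); n2 <- length(gb1)
    if (n1 < 1 || n2 < 1 || n1 + n2 < 3) next
    alleles <- sort(unique(c(ga1, ga2, gb1, gb2)))
    r <- 2; nbar <- (n1 + n2) / 2
    nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
    for (u in alleles) {
      p1 <- (sum(ga1 == u) + sum(ga2 == u)) / (2 * n1)
      p2 <- (sum(gb1 == u) + sum(gb2 == u)) / (2 * n2)
      h1 <- sum((ga1 == u) != (ga2 == u)) / n1
      h2 <- sum((gb1 == u) != (gb2 == u)) / n2
      pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
      s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
      hbar <- (n1 * h1 + n2 * h2) / (n1 + n2)
      a <- (nbar / nc) *
        (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
      b <- (nbar / (nbar - 1)) *
        (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
      cc <- hbar / 2
      num <- num + a; den <- den + a + b + cc
    }
  }
  if (den > 0) num / den else NA_real_
}

# Gene-copy-wise allele frequencies at one locus for one site, by counting.
oracle_freqs <- function(ds, site, locus) {
  a <- c(ds$genotypes[ds$site == site, 2 * locus - 1],
         ds$genotypes[ds$site == site, 2 * locus])
  a <- a[a > 0]
  if (!length(a)) return(NULL)
  table(a) / length(a)
}

# Jost's D (two demes, Nei-Chesser corrections) by direct evaluation.
oracle_jost_d <- function(ds, site_a, site_b, combine = "harmonic", eps = 1e-6) {
  vals <- c()
  for (l in seq_along(ds$loci)) {
    fa <- oracle_freqs(ds, site_a, l); fb <- oracle_freqs(ds, site_b, l)
    if (is.null(fa) || is.null(fb)) next
    ca <- sum(ds$genotypes[ds$site == site_a, c(2 * l - 1, 2 * l)] > 0) / 2
    cb <- sum(ds$genotypes[ds$site == site_b, c(2 * l - 1, 2 * l)] > 0) / 2
    ntilde <- 2 / (1 / ca + 1 / cb)
    if (2 * ntilde <= 1) next
    alleles <- union(names(fa), names(fb))
    p1 <- sapply(alleles, function(u) if (u %in% names(fa)) fa[[u]] else 0)
    p2 <- sapply(alleles, function(u) if (u %in% names(fb)) fb[[u]] else 0)
    hs <- 1 - (sum(p1^2) + sum(p2^2)) / 2
    ht <- 1 - sum(((p1 + p2) / 2)^2)
    hs_est <- 2 * ntilde / (2 * ntilde - 1) * hs
    ht_est <- ht + hs_est / (4 * ntilde)
    if (1 - hs_est <= 0) next
    vals <- c(vals, 2 * (ht_est - hs_est) / (1 - hs_est))
  }
  if (!length(vals)) return(NA_real_)
  if (combine == "harmonic") length(vals) / sum(1 / pmax(vals, eps))
  else mean(vals)
}

# Euclidean allele-frequency distance by direct counting.
oracle_deucl <- function(ds, site_a, site_b) {
  ss <- 0; used <- FALSE
  for (l in seq_along(ds$loci)) {
    fa <- oracle_freqs(ds, site_a, l); fb <- oracle_freqs(ds, site_b, l)
    if (is.null(fa) || is.null(fb)) next
    used <- TRUE
    for (u in union(names(fa), names(fb))) {
      pa <- if (u %in% names(fa)) fa[[u]] else 0
      pb <- if (u %in% names(fb)) fb[[u]] else 0
      ss <- ss + (pa - pb)^2
    }
  }
  if (used) sqrt(ss) else NA_real_
}

# Partial correlation of each pair given all remaining variables, via the
# Schur complement (conditional covariance after regressing on the rest).
oracle_partial_schur <- function(sigma) {
  S <- nrow(sigma)
  out <- diag(S)
  for (i in seq_len(S - 1)) for (j in seq(i + 1, S)) {
    rest <- setdiff(seq_len(S), c(i, j))
    cond <- sigma[c(i, j), c(i, j)] -
      sigma[c(i, j), rest] %*% solve(sigma[rest, rest]) %*% sigma[rest, c(i, j)]
    out[i, j] <- out[j, i] <- cond[1, 2] / sqrt(cond[1, 1] * cond[2, 2])
  }
  dimnames(out) <- dimnames(sigma)
  out
}

# Classic O(V^2) Dijkstra on a weighted adjacency matrix (NA = no edge).
oracle_dijkstra <- function(W) {
  V <- nrow(W)
  out <- matrix(Inf, V, V, dimnames = dimnames(W))
  for (s in seq_len(V)) {
    dist <- rep(Inf, V); dist[s] <- 0
    done <- rep(FALSE, V)
    for (k in seq_len(V)) {
      u <- which(!done)[which.min(dist[!done])]
      if (!length(u) || is.infinite(dist[u])) break
      done[u] <- TRUE
      for (v in seq_len(V)) {
        if (!is.na(W[u, v]) && dist[u] + W[u, v] < dist[v])
          dist[v] <- dist[u] + W[u, v]
      }
    }
    out[s, ] <- dist
  }
  out
}

# Exact Mantel test by full permutation enumeration (one-sided, positive).
oracle_mantel_exact <- function(a, b) {
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (k in seq_along(v)) for (p in perms(v[-k])) out <- c(out, list(c(v[k], p)))
    out
  }
  rfun <- function(x, y) {
    ut <- upper.tri(x)
    ok <- ut & !is.na(x) & !is.na(y)
    if (sum(ok) < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0) return(NA_real_)
    cor(x[ok], y[ok])
  }
  obs <- rfun(a, b)
  rs <- vapply(perms(seq_len(nrow(a))), function(p) rfun(a, b[p, p]), numeric(1))
  rs <- rs[!is.na(rs)]
  list(r = obs, p = mean(rs >= obs - 1e-12))
}
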
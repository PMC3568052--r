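# Shared dataset constructors for tests.

rdirich <- function(a) { x <- rgamma(length(a), a); x / sum(x) }

hwe_block <- function(freqs, n) {
  L <- length(freqs)
  g <- matrix(0L, n, 2 * L)
  for (l in seq_len(L)) {
    a <- sample.int(length(freqs[[l]]), 2 * n, replace = TRUE, prob = freqs[[l]])
    g[, 2 * l - 1] <- a[seq_len(n)]
    g[, 2 * l] <- a[n + seq_len(n)]
  }
  g
}

# Small dataset from explicit per-site genotype matrices.
toy_ds <- function(..., loci = NULL, coords = NULL) {
  blocks <- list(...)
  labs <- names(blocks)
  geno <- do.call(rbind, blocks)
  site <- rep(labs, vapply(blocks, nrow, 1L))
  L <- ncol(geno) / 2
  if (is.null(loci)) loci <- paste0("L", seq_len(L))
  if (is.null(coords))
    coords <- data.frame(site = labs, x = seq_along(labs), y = 0)
  genotype_dataset(geno, loci, site, coords)
}

# Stepping-stone drift chain: site i+1 drifts from site i (Dirichlet with
# concentration `conc`); strong conditional-independence structure.
drift_chain_ds <- function(S = 6, L = 80, n = 60, conc = 3, seed = 1,
                           n_alleles = 6) {
  set.seed(seed)
  labs <- LETTERS[seq_len(S)]
  fr <- vector("list", S)
  fr[[1]] <- replicate(L, rdirich(rep(1, n_alleles)), simplify = FALSE)
  for (i in seq(2, S))
    fr[[i]] <- lapply(fr[[i - 1]], function(p) rdirich(conc * p))
  g <- do.call(rbind, lapply(fr, hwe_block, n = n))
  genotype_dataset(g, paste0("L", seq_len(L)), rep(labs, each = n),
                   data.frame(site = labs, x = seq_len(S), y = 0))
}

# Small isolation-by-distance dataset from the package generator.
small_ibd_ds <- function(seed, n_sites = 12, n_loci = 10, n = 15,
                         decay = 0.01) {
  generate_ibd(generator_spec(n_sites, n_loci, 8, K = 1,
                              sizes = rep(n, n_sites), ibd_decay = decay),
               seed = seed)
}

# Hand-made population_graph object from an edge list (for unit tests of the
# graph-metric operations).
toy_graph <- function(nodes, edges) {
  all_pairs <- t(combn(nodes, 2))
  key <- paste(all_pairs[, 1], all_pairs[, 2])
  w <- setNames(rep(NA_real_, length(key)), key)
  for (i in seq_len(nrow(edges)))
    w[paste(edges$a[i], edges$b[i])] <- edges$w[i]
  structure(list(
    nodes = nodes,
    coords = data.frame(x = seq_along(nodes), y = 0),
    edges = data.frame(a = all_pairs[, 1], b = all_pairs[, 2],
                       rho = ifelse(is.na(w), 0, 0.9),
                       deviance = ifelse(is.na(w), 0, 100),
                       retained = !is.na(w), weight = unname(w),
                       stringsAsFactors = FALSE),
    alpha = 0.05, lambda = 0, n_individuals = 100, deviance_n = 100),
    class = "population_graph")
}
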
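#' @name simulator
#' @title Spatially explicit gene-flow simulation on a barrier cost surface
#'
#' @description
#' An individual-based, non-overlapping-site simulation of mating and
#' dispersal on a lattice cost surface, in the style of CDPOP: fixed
#' locations, random adult mortality, local mating, inverse-square dispersal
#' of offspring along least-cost distances, and k-allele mutation. Together
#' with [ibr_experiment()] it provides a ground-truth isolation-by-resistance
#' system for probing the sensitivity of conditional genetic distance to
#' unsampled sites.
NULL

#' Cost surface
#'
#' A grid of cells, each `cell_size` x `cell_size` movement units. Passable
#' cells carry a per-unit traversal cost (>= 1); `NA` cells are complete
#' barriers. Selected cells are populated sites.
#'
#' @param costs numeric matrix of per-unit cell costs; `NA` = barrier.
#' @param sites data frame `site,row,col` placing each populated site on a
#'   passable cell.
#' @param cell_size units per cell side (default 5).
#' @return object of class `cost_surface`.
#' @export
cost_surface <- function(costs, sites, cell_size = 5) {
  costs <- as.matrix(costs)
  if (any(costs < 1, na.rm = TRUE)) stop("passable cell costs must be >= 1")
  sites <- data.frame(site = as.character(sites$site),
                      row = as.integer(sites$row), col = as.integer(sites$col),
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(sites)))
    if (is.na(costs[sites$row[i], sites$col[i]]))
      stop("site ", sites$site[i], " lies on a barrier cell")
  structure(list(costs = costs, sites = sites,
                 cell_size = as.integer(cell_size)),
            class = "cost_surface")
}

#' @export
print.cost_surface <- function(x, ...) {
  cat("cost_surface:", nrow(x$costs), "x", ncol(x$costs), "cells (",
      x$cell_size, "x", x$cell_size, "units each ),",
      sum(is.na(x$costs)), "barrier cells,", nrow(x$sites), "sites\n")
  invisible(x)
}

#' Default isolation-by-resistance surface
#'
#' A 7 x 7 grid (49 cells of 5 x 5 units), nine of which are complete
#' barriers, with nine populated sites in a 3 x 3 arrangement numbered
#' row-major (so sites 4-6 form the middle row). Six barrier cells sit on the
#' direct segments between vertically adjacent sites (plus three corner
#' cells), so horizontal neighbours are 10 cost units apart, vertical
#' neighbours 16 (detoured), and the top and bottom site rows are more than 25
#' cost units apart everywhere. Under the default 25-unit dispersal cap the
#' middle-row sites are therefore the only conduit of top-bottom gene flow --
#' the resistance structure whose detection the unsampled-site experiment
#' probes -- and no dispersal can exceed two sites away.
#'
#' @return a [cost_surface()].
#' @export
default_ibr_surface <- function() {
  costs <- matrix(1, 7, 7)
  barriers <- rbind(c(3, 2), c(3, 4), c(3, 6), c(5, 2), c(5, 4), c(5, 6),
                    c(1, 1), c(1, 7), c(7, 1))
  costs[barriers] <- NA
  rc <- expand.grid(col = c(2, 4, 6), row = c(2, 4, 6))
  sites <- data.frame(site = as.character(1:9), row = rc$row, col = rc$col)
  cost_surface(costs, sites)
}

#' Read / write a cost surface as a CSV grid
#'
#' Cell costs, with `B` marking barrier cells. Site placement is written as a
#' sidecar CSV (`site,row,col`).
#'
#' @param surface a [cost_surface()].
#' @param path grid CSV path.
#' @param sites_path sidecar CSV path (defaults to `<path>` with a `_sites`
#'   suffix).
#' @param cell_size units per cell when reading.
#' @return `path` (write) or a `cost_surface` (read).
#' @export
write_cost_surface <- function(surface, path, sites_path = NULL) {
  if (is.null(sites_path)) sites_path <- sub("(\\.[^.]*)?$", "_sites.csv", path)
  m <- surface$costs
  ch <- matrix(as.character(m), nrow(m))
  ch[is.na(m)] <- "B"
  utils::write.table(ch, path, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  utils::write.csv(surface$sites, sites_path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cost_surface
#' @export
read_cost_surface <- function(path, sites_path = NULL, cell_size = 5) {
  if (is.null(sites_path)) sites_path <- sub("(\\.[^.]*)?$", "_sites.csv", path)
  ch <- as.matrix(utils::read.table(path, sep = ",", stringsAsFactors = FALSE))
  m <- suppressWarnings(matrix(as.numeric(ch), nrow(ch)))
  m[trimws(ch) == "B"] <- NA
  cost_surface(m, utils::read.csv(sites_path, stringsAsFactors = FALSE),
               cell_size = cell_size)
}

# Unit-resolution lattice of a cost surface: passable unit coordinates and a
# directed igraph whose edge weights are the destination unit's cell cost
# (4-neighbour moves).
unit_lattice <- function(surface) {
  cs <- surface$cell_size
  nr <- nrow(surface$costs) * cs
  nc <- ncol(surface$costs) * cs
  cell_of <- function(u) (u - 1L) %/% cs + 1L
  ur <- rep(seq_len(nr), times = nc)
  uc <- rep(seq_len(nc), each = nr)
  cost <- surface$costs[cbind(cell_of(ur), cell_of(uc))]
  passable <- !is.na(cost)
  vid <- rep(NA_integer_, nr * nc)
  vid[passable] <- seq_len(sum(passable))
  idx <- function(r, c) (c - 1L) * nr + r
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (d in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
    r2 <- ur + d[1]; c2 <- uc + d[2]
    ok <- passable & r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
    ok[ok] <- passable[idx(r2[ok], c2[ok])]
    from <- c(from, vid[idx(ur[ok], uc[ok])])
    to <- c(to, vid[idx(r2[ok], c2[ok])])
    w <- c(w, cost[idx(r2[ok], c2[ok])])
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = TRUE)
  npass <- sum(passable)
  if (igraph::vcount(g) < npass)
    g <- igraph::add_vertices(g, npass - igraph::vcount(g))
  igraph::E(g)$weight <- w
  list(graph = g, nr = nr, nc = nc,
       vid = function(r, c) vid[idx(r, c)],
       passable = function(r, c) passable[idx(r, c)])
}

#' Least-cost distances between unit locations
#'
#' Shortest-path costs over the unit-resolution lattice with 4-neighbour
#' moves, where each step pays the destination cell's per-unit cost. Barrier
#' cells are impassable; unreachable pairs are `Inf`.
#'
#' @param surface a [cost_surface()].
#' @param locations data frame or matrix with unit coordinates `row`, `col`.
#' @return matrix of least-cost distances (cost units).
#' @export
cost_distance_matrix <- function(surface, locations) {
  locations <- as.data.frame(locations)
  lat <- unit_lattice(surface)
  v <- lat$vid(locations$row, locations$col)
  if (anyNA(v)) stop("location on a barrier (or outside the grid)")
  uv <- unique(v)
  d <- igraph::distances(lat$graph, v = uv, to = uv, mode = "out",
                         weights = igraph::E(lat$graph)$weight)
  m <- d[match(v, uv), match(v, uv), drop = FALSE]
  dimnames(m) <- NULL
  m
}

#' Unit coordinates of site cell centres
#'
#' @param surface a [cost_surface()].
#' @return data frame `site,row,col` in unit coordinates.
#' @export
site_centers <- function(surface) {
  cs <- surface$cell_size
  mid <- ceiling(cs / 2)
  data.frame(site = surface$sites$site,
             row = (surface$sites$row - 1L) * cs + mid,
             col = (surface$sites$col - 1L) * cs + mid,
             stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Defaults follow the reference isolation-by-resistance design: 15 loci with
#' 10 possible alleles, k-allele mutation at 5e-4 per allele copy per
#' generation, 250 generations, 50% adult mortality per generation, 4
#' offspring per mated pair with equal sex ratio, mate search within 3 cost
#' units (males with replacement), and inverse-square dispersal capped at 25
#' cost units.
#'
#' @param n_loci,n_alleles genotype dimensions.
#' @param mutation_rate per-allele-copy k-allele mutation probability.
#' @param generations number of generations to simulate.
#' @param adult_mortality per-generation adult death probability.
#' @param offspring_per_pair offspring per mated female.
#' @param mate_radius maximum cost distance to a mate.
#' @param dispersal_max maximum dispersal cost distance for offspring.
#' @param natal_floor floor on the dispersal distance (the natal location and
#'   its co-located slot count at this distance, avoiding division by zero in
#'   the inverse-square kernel).
#' @param strict_nonoverlap if `TRUE`, all adults die each generation (strictly
#'   non-overlapping generations) instead of random 50% survival.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_loci = 15, n_alleles = 10, mutation_rate = 5e-4,
                       generations = 250, adult_mortality = 0.5,
                       offspring_per_pair = 4, mate_radius = 3,
                       dispersal_max = 25, natal_floor = 1,
                       strict_nonoverlap = FALSE) {
  stopifnot(mutation_rate >= 0, mutation_rate <= 1,
            adult_mortality >= 0, adult_mortality <= 1,
            n_alleles >= 1, n_loci >= 1, generations >= 1,
            offspring_per_pair >= 1, natal_floor > 0)
  if (n_alleles == 1 && mutation_rate > 0)
    stop("a single-allele model cannot mutate; set mutation_rate = 0")
  structure(list(n_loci = n_loci, n_alleles = n_alleles,
                 mutation_rate = mutation_rate, generations = generations,
                 adult_mortality = adult_mortality,
                 offspring_per_pair = offspring_per_pair,
                 mate_radius = mate_radius, dispersal_max = dispersal_max,
                 natal_floor = natal_floor,
                 strict_nonoverlap = strict_nonoverlap),
            class = "sim_config")
}

# Fixed location list: every unit of every site cell carries two location
# slots (initially one male and one female per unit).
sim_locations <- function(surface) {
  cs <- surface$cell_size
  locs <- list()
  for (i in seq_len(nrow(surface$sites))) {
    rr <- (surface$sites$row[i] - 1L) * cs + seq_len(cs)
    cc <- (surface$sites$col[i] - 1L) * cs + seq_len(cs)
    grid <- expand.grid(row = rr, col = cc)
    locs[[i]] <- data.frame(site = surface$sites$site[i],
                            row = rep(grid$row, each = 2),
                            col = rep(grid$col, each = 2),
                            slot = rep(1:2, nrow(grid)),
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, locs)
}

#' Simulate gene flow on a cost surface
#'
#' Initializes two individuals (one male, one female) at every unit of every
#' site cell with uniformly random genotypes, then iterates generations:
#' (1) each adult dies independently with probability `adult_mortality`,
#' vacating its location; (2) each surviving female mates with a male drawn
#' uniformly from the males within `mate_radius` cost units (males are reused
#' freely); (3) each pair produces `offspring_per_pair` offspring with
#' equiprobable sex; (4) offspring, in random order, settle on a vacant
#' location with probability proportional to `1/d^2` (least-cost `d` from the
#' natal location, floored at `natal_floor`) among vacant locations within
#' `dispersal_max`; offspring with no reachable vacancy die; (5) every allele
#' copy mutates with probability `mutation_rate` to one of the other
#' `n_alleles - 1` states uniformly.
#'
#' @param surface a [cost_surface()].
#' @param config a [sim_config()].
#' @param seed RNG seed (runs are bit-reproducible per seed and config).
#' @param snapshot_every if given, genotype datasets are also recorded every
#'   this many generations (attribute `snapshots`).
#' @return final occupants as a [genotype_dataset()] (site coordinates are the
#'   cell centres in unit coordinates; `x = col`, `y = row`). Attributes:
#'   `extinctions` (generations at which any site stood empty), `n_occupied`
#'   (per-generation population size).
#' @export
simulate_ibr <- function(surface, config = sim_config(), seed = NULL,
                         snapshot_every = NULL) {
  locs <- sim_locations(surface)
  nloc <- nrow(locs)
  D <- cost_distance_matrix(surface, locs[, c("row", "col")])
  mate_nbrs <- apply(D <= config$mate_radius, 1, which, simplify = FALSE)
  disp <- lapply(seq_len(nloc), function(i) {
    j <- which(D[i, ] <= config$dispersal_max)
    list(to = j, w = 1 / pmax(D[i, j], config$natal_floor)^2)
  })
  L <- config$n_loci; k <- config$n_alleles
  with_seed(seed, {
    occupied <- rep(TRUE, nloc)
    sex <- rep(c(1L, 2L), nloc / 2)             # 1 = male, 2 = female
    geno <- matrix(sample.int(k, nloc * 2L * L, replace = TRUE), nloc, 2L * L)
    extinct_gens <- integer(0)
    n_occ <- integer(config$generations)
    snapshots <- list()
    mk_dataset <- function() {
      keep <- which(occupied)
      ctr <- site_centers(surface)
      genotype_dataset(geno[keep, , drop = FALSE],
                       sprintf("loc%02d", seq_len(L)),
                       locs$site[keep],
                       data.frame(site = ctr$site, x = ctr$col, y = ctr$row),
                       id = sprintf("g_%04d", keep),
                       sex = c("M", "F")[sex[keep]])
    }
    for (gen in seq_len(config$generations)) {
      # 1. adult mortality
      if (config$strict_nonoverlap) {
        parents <- which(occupied)
        occupied[] <- FALSE
      } else {
        dies <- occupied & stats::runif(nloc) < config$adult_mortality
        occupied[dies] <- FALSE
        parents <- which(occupied)
      }
      # 2. mating
      males <- parents[sex[parents] == 1L]
      females <- parents[sex[parents] == 2L]
      male_at <- rep(FALSE, nloc); male_at[males] <- TRUE
      fathers <- vapply(females, function(f) {
        cand <- mate_nbrs[[f]]
        cand <- cand[male_at[cand]]
        if (!length(cand)) NA_integer_
        else if (length(cand) == 1L) cand
        else cand[sample.int(length(cand), 1L)]
      }, integer(1))
      mated <- !is.na(fathers)
      mothers <- females[mated]; fathers <- fathers[mated]
      if (length(mothers)) {
        # 3. offspring: Mendelian sampling, equal sex ratio
        noff <- length(mothers) * config$offspring_per_pair
        mom <- rep(mothers, each = config$offspring_per_pair)
        dad <- rep(fathers, each = config$offspring_per_pair)
        og <- matrix(0L, noff, 2L * L)
        pick_m <- matrix(sample.int(2L, noff * L, replace = TRUE), noff, L)
        pick_d <- matrix(sample.int(2L, noff * L, replace = TRUE), noff, L)
        for (l in seq_len(L)) {
          og[, 2L * l - 1L] <- geno[cbind(mom, 2L * l - 2L + pick_m[, l])]
          og[, 2L * l] <- geno[cbind(dad, 2L * l - 2L + pick_d[, l])]
        }
        # 5. k-allele mutation (applied to the cohort before settlement)
        mut <- if (k > 1L && config$mutation_rate > 0)
          which(stats::runif(length(og)) < config$mutation_rate) else integer(0)
        if (length(mut))
          og[mut] <- 1L + (og[mut] - 1L +
                             sample.int(k - 1L, length(mut), replace = TRUE)) %% k
        osex <- sample.int(2L, noff, replace = TRUE)
        # 4. settlement in random order, inverse-square of cost distance
        for (o in sample.int(noff)) {
          dd <- disp[[mom[o]]]
          vac <- !occupied[dd$to]
          if (!any(vac)) next
          to <- dd$to[vac]
          j <- if (length(to) == 1L) to
          else to[sample.int(length(to), 1L, prob = dd$w[vac])]
          occupied[j] <- TRUE
          sex[j] <- osex[o]
          geno[j, ] <- og[o, ]
        }
      }
      n_occ[gen] <- sum(occupied)
      site_occ <- tapply(occupied, locs$site, any)
      if (!all(site_occ)) extinct_gens <- c(extinct_gens, gen)
      if (!is.null(snapshot_every) && gen %% snapshot_every == 0)
        snapshots[[as.character(gen)]] <- mk_dataset()
    }
    out <- mk_dataset()
    attr(out, "extinctions") <- extinct_gens
    attr(out, "n_occupied") <- n_occ
    if (length(snapshots)) attr(out, "snapshots") <- snapshots
    out
  })
}

#' Isolation-by-resistance unsampled-site experiment
#'
#' For each replicate dataset and each inclusion condition, builds the
#' population graph on the core sites plus the included pool sites, computes
#' cGD among the core sites only, and correlates it (Mantel r) with the
#' log-transformed least-cost distance between the core site centres. The
#' default conditions nest the unsampled pool \{4, 5, 6\}: none included, then
#' \{6\}, then \{4, 6\}, then all three.
#'
#' Pairwise metrics (`fst`, `dest`, `deucl`) can be traced alongside; being
#' strictly pairwise they are constant across conditions.
#'
#' @param datasets list of replicate [genotype_dataset()]s (from
#'   [simulate_ibr()]).
#' @param surface the [cost_surface()] the replicates were simulated on.
#' @param core core (always-sampled) site labels.
#' @param pool_nesting named list: condition label (number of pool sites
#'   included) to character vector of included pool sites.
#' @param metrics metrics to evaluate (default `"cgd"`).
#' @param alpha pruning level for the population graph.
#' @return data frame `(replicate, n_included, metric, mantel_r, n_pairs,
#'   n_components)`.
#' @export
ibr_experiment <- function(datasets, surface,
                           core = as.character(c(1, 2, 3, 7, 8, 9)),
                           pool_nesting = list(`0` = character(0),
                                               `1` = "6",
                                               `2` = c("4", "6"),
                                               `3` = c("4", "5", "6")),
                           metrics = "cgd", alpha = 0.05) {
  ctr <- site_centers(surface)
  ci <- match(core, ctr$site)
  cd <- cost_distance_matrix(surface, ctr[ci, c("row", "col")])
  dimnames(cd) <- list(core, core)
  if (any(cd[upper.tri(cd)] <= 0) || any(is.infinite(cd)))
    stop("core sites must be mutually reachable at positive cost distance")
  logcd <- cd; logcd[] <- ifelse(row(cd) == col(cd), 0, log(cd))
  rows <- list()
  for (rep_i in seq_along(datasets)) {
    ds <- datasets[[rep_i]]
    for (cond in names(pool_nesting)) {
      active <- c(core, pool_nesting[[cond]])
      sub <- subset_dataset(ds, sites = intersect(site_labels(ds), active))
      for (m in metrics) {
        mm <- metric_matrix(sub, m, alpha)
        cg <- unclass(mm$mat)[core, core, drop = FALSE]
        rows[[length(rows) + 1L]] <- data.frame(
          replicate = rep_i, n_included = as.integer(cond), metric = m,
          mantel_r = mantel_r_masked(cg, logcd),
          n_pairs = sum(!is.na(cg[upper.tri(cg)])),
          n_components = mm$n_components, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Contrasts between IBR inclusion conditions
#'
#' Cohen's d and a two-sample permutation test on the per-replicate Mantel r
#' values of two inclusion conditions. `d > 0` means the condition with more
#' pool sites included has the larger mean Mantel r.
#'
#' @param tbl output of [ibr_experiment()].
#' @param metric metric to contrast (default `"cgd"`).
#' @param pairs list of `c(more_included, fewer_included)` condition pairs.
#' @param n_perm,seed permutation-test settings.
#' @return data frame `(comparison, mean_more, mean_fewer, cohens_d,
#'   p_value)`.
#' @export
ibr_contrasts <- function(tbl, metric = "cgd",
                          pairs = list(c(3, 0), c(1, 0), c(2, 1), c(3, 2)),
                          n_perm = 9999, seed = 1) {
  rows <- lapply(pairs, function(pr) {
    a <- tbl$mantel_r[tbl$n_included == pr[1] & tbl$metric == metric]
    b <- tbl$mantel_r[tbl$n_included == pr[2] & tbl$metric == metric]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    pt <- two_sample_permutation(a, b, n_perm = n_perm, seed = seed)
    data.frame(comparison = sprintf("included_%d_vs_%d", pr[1], pr[2]),
               mean_more = mean(a), mean_fewer = mean(b),
               cohens_d = cohens_d(a, b), p_value = pt$p_value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
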
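#' Multilocus diploid genotype dataset
#'
#' Container for codominant (microsatellite-style) diploid genotypes grouped
#' into sampling sites with planar coordinates. This is the universal input of
#' every estimator, experiment and simulation summary in the package.
#'
#' @param genotypes integer matrix, one row per individual and two columns per
#'   locus (columns `2j-1`, `2j` hold the two allele codes of locus `j`).
#'   Allele codes are positive integers; `0` marks a missing allele copy.
#' @param loci character vector of locus names (length `ncol(genotypes)/2`).
#' @param site character vector assigning each individual to a site label.
#' @param sites data frame with columns `site`, `x`, `y` giving the site labels
#'   (in their canonical order) and planar coordinates.
#' @param id optional character vector of individual identifiers.
#' @param sex optional character vector (`"M"`/`"F"`/`NA`) per individual.
#'
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(genotypes, loci, site, sites, id = NULL, sex = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  n <- nrow(genotypes)
  if (ncol(genotypes) != 2L * length(loci))
    stop("genotypes must have two columns per locus (got ", ncol(genotypes),
         " columns for ", length(loci), " loci)")
  if (length(site) != n) stop("length(site) != number of individuals")
  site <- as.character(site)
  if (!is.data.frame(sites) || !all(c("site", "x", "y") %in% names(sites)))
    stop("sites must be a data frame with columns site, x, y")
  sites <- data.frame(site = as.character(sites$site),
                      x = as.numeric(sites$x), y = as.numeric(sites$y),
                      stringsAsFactors = FALSE)
  if (anyDuplicated(sites$site)) stop("duplicated site labels in site table")
  if (!all(site %in% sites$site))
    stop("individual site labels missing from the site table: ",
         paste(unique(setdiff(site, sites$site)), collapse = ", "))
  if (any(genotypes < 0L, na.rm = TRUE)) stop("allele codes must be >= 0")
  if (is.null(id)) id <- sprintf("ind_%04d", seq_len(n))
  if (is.null(sex)) sex <- rep(NA_character_, n)
  structure(list(genotypes = genotypes, loci = as.character(loci),
                 site = site, sites = sites,
                 id = as.character(id), sex = as.character(sex)),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", nrow(x$genotypes), "individuals,",
      nrow(x$sites), "sites,", length(x$loci), "loci\n")
  tab <- table(factor(x$site, levels = x$sites$site))
  cat("individuals per site:", paste(range(tab), collapse = "-"),
      sprintf("(mean %.1f)\n", mean(tab)))
  invisible(x)
}

n_loci <- function(ds) length(ds$loci)
site_labels <- function(ds) ds$sites$site
n_individuals <- function(ds) nrow(ds$genotypes)

#' Subset a dataset by site and/or individuals
#'
#' @param ds a [genotype_dataset()].
#' @param sites character vector of site labels to retain (order taken from the
#'   dataset's site table), or `NULL` to keep all.
#' @param individuals logical or integer index over individuals, or `NULL`.
#' @return a `genotype_dataset` restricted to the selection.
#' @export
subset_dataset <- function(ds, sites = NULL, individuals = NULL) {
  keep <- rep(TRUE, n_individuals(ds))
  if (!is.null(individuals)) {
    keep2 <- rep(FALSE, n_individuals(ds))
    keep2[individuals] <- TRUE
    keep <- keep & keep2
  }
  site_tab <- ds$sites
  if (!is.null(sites)) {
    if (!all(sites %in% ds$sites$site)) stop("unknown site label in subset")
    site_tab <- ds$sites[ds$sites$site %in% sites, , drop = FALSE]
    keep <- keep & ds$site %in% sites
  }
  genotype_dataset(ds$genotypes[keep, , drop = FALSE], ds$loci,
                   ds$site[keep], site_tab, ds$id[keep], ds$sex[keep])
}

#' Read genotypes from a Genepop file
#'
#' Parses the classic Genepop text format: a title line, one locus name per
#' line (or a single comma-separated line), `Pop` separators (matched
#' case-insensitively) and `id , a1a2 a1a2 ...` genotype rows in the 2- or
#' 3-digit diploid encoding (`00`/`000` = missing allele).
#'
#' Genepop files carry no canonical site naming, so site labels and coordinates
#' come from a sidecar CSV (columns `site,x,y`, one row per `Pop` block in file
#' order). Without a sidecar, the label of the last individual in each block
#' names the site (the Genepop convention) and coordinates are set to `NA`.
#'
#' @param path path to the Genepop file.
#' @param coords optional path to a `site,x,y` CSV, or a data frame.
#' @return a [genotype_dataset()].
#' @export
read_genepop <- function(path, coords = NULL) {
  if (!file.exists(path)) stop("cannot open Genepop file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  if (length(lines) < 3L) stop("Genepop parse error: file too short")
  is_pop <- grepl("^\\s*pop\\s*$", lines, ignore.case = TRUE)
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("Genepop parse error: no Pop blocks found")
  header <- lines[2:(first_pop - 1)]
  loci <- unlist(strsplit(header, ","))
  loci <- trimws(loci)
  loci <- loci[nzchar(loci)]
  if (length(loci) == 0L) stop("Genepop parse error: no locus names")
  L <- length(loci)

  ids <- character(0); site_idx <- integer(0)
  geno_rows <- list()
  pop <- 0L
  last_id_per_pop <- character(0)
  for (i in seq(first_pop, length(lines))) {
    ln <- lines[i]
    if (grepl("^\\s*pop\\s*$", ln, ignore.case = TRUE)) { pop <- pop + 1L; next }
    if (!nzchar(trimws(ln))) next
    parts <- strsplit(ln, ",")[[1]]
    if (length(parts) < 2L)
      stop("Genepop parse error at line ", i, ": expected 'id , genotypes'")
    id <- trimws(parts[1])
    gstr <- trimws(paste(parts[-1], collapse = " "))
    toks <- strsplit(gstr, "\\s+")[[1]]
    toks <- toks[nzchar(toks)]
    if (length(toks) != L)
      stop("Genepop parse error at line ", i, ": ", length(toks),
           " genotypes for ", L, " loci")
    w <- nchar(toks)
    if (!all(w %in% c(4L, 6L)) || length(unique(w)) != 1L)
      stop("Genepop parse error at line ", i,
           ": genotype width must be uniformly 4 (2-digit) or 6 (3-digit)")
    half <- w[1] / 2L
    a1 <- as.integer(substr(toks, 1L, half))
    a2 <- as.integer(substr(toks, half + 1L, w[1]))
    if (anyNA(a1) || anyNA(a2))
      stop("Genepop parse error at line ", i, ": non-numeric allele code")
    ids <- c(ids, id)
    site_idx <- c(site_idx, pop)
    geno_rows[[length(geno_rows) + 1L]] <- as.vector(rbind(a1, a2))
    last_id_per_pop[pop] <- id
  }
  if (pop == 0L || length(ids) == 0L)
    stop("Genepop parse error: no genotype rows")
  geno <- do.call(rbind, geno_rows)

  if (!is.null(coords)) {
    ct <- if (is.data.frame(coords)) coords else
      utils::read.csv(coords, stringsAsFactors = FALSE)
    if (nrow(ct) != pop)
      stop("coordinates table has ", nrow(ct), " rows for ", pop, " Pop blocks")
    sites <- data.frame(site = as.character(ct$site), x = ct$x, y = ct$y,
                        stringsAsFactors = FALSE)
  } else {
    sites <- data.frame(site = make.unique(last_id_per_pop),
                        x = NA_real_, y = NA_real_, stringsAsFactors = FALSE)
  }
  genotype_dataset(geno, loci, sites$site[site_idx], sites, id = ids)
}

#' Write genotypes to a Genepop file
#'
#' Emits the 3-digit diploid dialect (`000` = missing). Site blocks follow the
#' dataset's site-table order.
#'
#' @param ds a [genotype_dataset()].
#' @param path output file path.
#' @param title title line (first line of the file).
#' @param coords_path optional path for a sidecar `site,x,y` CSV.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(ds, path, title = "popsens export", coords_path = NULL) {
  if (any(ds$genotypes > 999L))
    stop("allele code exceeds 999; cannot encode in 3-digit Genepop")
  con <- c(title, ds$loci)
  for (s in site_labels(ds)) {
    rows <- which(ds$site == s)
    if (length(rows) == 0L) stop("site ", s, " has no individuals")
    con <- c(con, "Pop")
    for (r in rows) {
      g <- ds$genotypes[r, ]
      toks <- sprintf("%03d%03d", g[seq(1, length(g), 2)], g[seq(2, length(g), 2)])
      con <- c(con, paste0(ds$id[r], " , ", paste(toks, collapse = " ")))
    }
  }
  writeLines(con, path)
  if (!is.null(coords_path))
    utils::write.csv(ds$sites, coords_path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-site allele frequencies
#'
#' Relative allele frequencies per site and locus, computed gene-copy-wise:
#' each `0` allele code removes one gene copy from the denominator, so a
#' half-missing genotype still contributes its observed copy.
#'
#' @param ds a [genotype_dataset()].
#' @param subset optional logical/integer index selecting individuals; every
#'   retained site must keep at least one individual.
#' @return An object of class `allele_freq_table`: a list with `sites`, `loci`,
#'   `alleles` (per-locus sorted allele codes), `freq` (per-locus site-by-allele
#'   frequency matrix), `copies` (site-by-locus non-missing gene-copy counts)
#'   and `empty` (site-by-locus flag for no data).
#' @export
allele_frequencies <- function(ds, subset = NULL) {
  if (!is.null(subset)) {
    keep <- rep(FALSE, n_individuals(ds)); keep[subset] <- TRUE
    dropped <- setdiff(site_labels(ds), unique(ds$site[keep]))
    if (length(dropped))
      stop("subset leaves no individuals at site(s): ", paste(dropped, collapse = ", "))
    ds <- subset_dataset(ds, individuals = keep)
  }
  S <- length(site_labels(ds)); L <- n_loci(ds)
  sf <- factor(ds$site, levels = site_labels(ds))
  alleles <- vector("list", L); freq <- vector("list", L)
  copies <- matrix(0, S, L, dimnames = list(site_labels(ds), ds$loci))
  for (l in seq_len(L)) {
    cols <- c(2L * l - 1L, 2L * l)
    a <- c(ds$genotypes[, cols[1]], ds$genotypes[, cols[2]])
    s <- factor(rep(sf, 2L), levels = levels(sf))
    ok <- a > 0L
    obs <- sort(unique(a[ok]))
    if (length(obs) == 0L) obs <- integer(0)
    cnt <- table(s[ok], factor(a[ok], levels = obs))
    cnt <- matrix(as.numeric(cnt), nrow = S,
                  dimnames = list(site_labels(ds), as.character(obs)))
    tot <- rowSums(cnt)
    fr <- cnt / ifelse(tot > 0, tot, 1)
    fr[tot == 0, ] <- NA_real_
    alleles[[l]] <- obs
    freq[[l]] <- fr
    copies[, l] <- tot
  }
  structure(list(sites = site_labels(ds), loci = ds$loci, alleles = alleles,
                 freq = freq, copies = copies, empty = copies == 0),
            class = "allele_freq_table")
}

#' Concatenated site allele-frequency vectors
#'
#' One row per site, columns spanning all observed alleles at all loci; the
#' multivariate space in which `d_eucl` and population-graph centroids live.
#' Loci with no data at a site yield `NA` entries.
#'
#' @param aft an [allele_frequencies()] table.
#' @return numeric matrix, sites x total alleles.
#' @export
site_frequency_matrix <- function(aft) {
  do.call(cbind, lapply(seq_along(aft$loci), function(l) {
    m <- aft$freq[[l]]
    if (ncol(m)) colnames(m) <- paste(aft$loci[l], colnames(m), sep = ".")
    m
  }))
}

#' Geographic distance matrix between sites
#'
#' Euclidean distances between site coordinates (planar units), optionally
#' natural-log transformed as used in isolation-by-distance Mantel tests.
#'
#' @param ds a [genotype_dataset()] with coordinates.
#' @param log_transform take `log()` of the pairwise distances?
#' @return a [dist_matrix()] with metric `"geo"` or `"log_geo"`.
#' @export
geographic_distance_matrix <- function(ds, log_transform = FALSE) {
  xy <- as.matrix(ds$sites[, c("x", "y")])
  if (anyNA(xy)) stop("site coordinates are missing")
  d <- as.matrix(stats::dist(xy))
  dimnames(d) <- list(ds$sites$site, ds$sites$site)
  if (log_transform) {
    off <- d[upper.tri(d)]
    if (any(off <= 0))
      stop("duplicate coordinates: log of a zero distance is undefined")
    d[] <- ifelse(row(d) == col(d), 0, log(d))
  }
  dist_matrix(d, metric = if (log_transform) "log_geo" else "geo")
}

#' Site-by-site distance matrix with undefined entries
#'
#' A symmetric matrix of non-negative pairwise values in which `NA` marks an
#' undefined pair (e.g. sites in different population-graph components). The
#' diagonal is zero.
#'
#' @param m symmetric numeric matrix with dimnames (site labels).
#' @param metric name tag (e.g. `"fst"`, `"dest"`, `"deucl"`, `"cgd"`).
#' @return object of class `dist_matrix` (a matrix with a `metric` attribute).
#' @export
dist_matrix <- function(m, metric = "dist") {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("distance matrix must be square")
  if (is.null(rownames(m))) stop("distance matrix needs site labels as dimnames")
  if (!isTRUE(all.equal(m, t(m), check.attributes = FALSE)))
    stop("distance matrix must be symmetric (NA pattern included)")
  diag(m) <- 0
  structure(m, metric = metric, class = c("dist_matrix", "matrix", "array"))
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat("dist_matrix (", attr(x, "metric"), "): ", nrow(x), " sites, ",
      sum(is.na(x[upper.tri(x)])), " undefined pairs\n", sep = "")
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x)))])
  invisible(x)
}

#' Upper-triangle pair values of a distance matrix
#'
#' @param m a [dist_matrix()] or plain matrix.
#' @param drop_na drop undefined pairs?
#' @return data frame with columns `a`, `b`, `value`.
#' @export
pair_values <- function(m, drop_na = TRUE) {
  ut <- which(upper.tri(m), arr.ind = TRUE)
  out <- data.frame(a = rownames(m)[ut[, 1]], b = colnames(m)[ut[, 2]],
                    value = m[ut], stringsAsFactors = FALSE)
  if (drop_na) out <- out[!is.na(out$value), , drop = FALSE]
  out
}

#' Write / read a distance matrix as square CSV
#'
#' Square layout with a header row and a leading label column; undefined pairs
#' are written as `NA`.
#'
#' @param m a [dist_matrix()].
#' @param path file path.
#' @return `path` (write) or a `dist_matrix` (read).
#' @export
write_dist_csv <- function(m, path) {
  df <- data.frame(site = rownames(m), as.data.frame(unclass(m)),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_dist_csv
#' @param metric metric tag for the re-read matrix.
#' @export
read_dist_csv <- function(path, metric = "dist") {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  dist_matrix(m, metric = metric)
}
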
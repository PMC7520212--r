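# Pairwise multilocus allele differences, the clonal network, multilocus
# genotype collapsing and clonality statistics.
#
# The genetic distance between two diploid samples is the summed per-locus
# count of non-shared alleles under multiset comparison (0, 1 or 2 per
# locus), so a homozygote (a,a) against a heterozygote (a,b) counts 1.
# Identical genotypes (distance 0) are read as clonal; small differences
# (1..somatic_threshold, default 3) as clonal with somatic mutations
# accumulated during lateral growth.

# multiset overlap of two sorted allele pairs: 2, 1 or 0 shared alleles
pair_shared <- function(x1, x2, y1, y2) {
  ifelse(x1 == y1 & x2 == y2, 2L,
         ifelse(x1 == y1 | x2 == y2 | x1 == y2 | x2 == y1, 1L, 0L))
}

#' Pairwise multilocus allele differences
#'
#' For every unordered pair of samples, sums over loci the number of
#' alleles not shared between the two diploid genotypes (per-locus values
#' 0, 1 or 2 under multiset comparison).  Loci missing in either sample are
#' skipped and `loci_compared` decremented; a pair sharing fewer than
#' `min_shared_loci` typed loci is flagged not comparable
#' (`comparable = FALSE`) and is excluded from clonal calls downstream but
#' retained in the output for auditability.
#'
#' @param table genotype_table with at least 2 samples.
#' @param min_shared_loci minimum number of loci typed in both samples for
#'   the pair to be usable in clone calling (default 12).
#' @return data.frame of class `pairwise_distance` with columns `sample_a`,
#'   `sample_b`, `allele_diff`, `loci_compared`, `comparable`.
#' @export
pairwise_allele_distance <- function(table, min_shared_loci = 12L) {
  n <- n_samples(table)
  if (n < 2L) {
    warning("fewer than 2 samples; no pairs to compare")
    out <- data.frame(sample_a = character(0), sample_b = character(0),
                      allele_diff = integer(0), loci_compared = integer(0),
                      comparable = logical(0))
    class(out) <- c("pairwise_distance", "data.frame")
    return(out)
  }
  ia <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  ib <- unlist(lapply(seq_len(n - 1L), function(i) (i + 1L):n))
  diff_sum <- integer(length(ia))
  ncomp <- integer(length(ia))
  for (loc in loci_names(table)) {
    a1 <- table$alleles[, paste0(loc, ".a1")]
    a2 <- table$alleles[, paste0(loc, ".a2")]
    present <- !is.na(a1)
    both <- present[ia] & present[ib]
    sh <- pair_shared(a1[ia], a2[ia], a1[ib], a2[ib])
    d <- 2L - sh
    d[!both] <- 0L
    diff_sum <- diff_sum + d
    ncomp <- ncomp + as.integer(both)
  }
  out <- data.frame(
    sample_a = table$samples$sample_id[ia],
    sample_b = table$samples$sample_id[ib],
    allele_diff = diff_sum,
    loci_compared = ncomp,
    comparable = ncomp >= min_shared_loci,
    stringsAsFactors = FALSE
  )
  attr(out, "min_shared_loci") <- as.integer(min_shared_loci)
  class(out) <- c("pairwise_distance", "data.frame")
  out
}

#' Attach geographic distances to sample pairs
#'
#' Adds a `geo_dist_m` column (great-circle metres, see
#' [geographic_distance()]) to a pairwise-distance table.
#' @param dists pairwise_distance data.frame
#' @param table the genotype_table the pairs came from
#' @return the input with a `geo_dist_m` column
#' @export
attach_geo_distances <- function(dists, table) {
  idx_a <- match(dists$sample_a, table$samples$sample_id)
  idx_b <- match(dists$sample_b, table$samples$sample_id)
  if (anyNA(idx_a) || anyNA(idx_b)) stop("pair references a sample absent from the table")
  dists$geo_dist_m <- geographic_distance_vec(
    table$samples$lon[idx_a], table$samples$lat[idx_a],
    table$samples$lon[idx_b], table$samples$lat[idx_b])
  dists
}

#' Build the clonal network
#'
#' Keeps edges between individuals whose allele difference is at most
#' `somatic_threshold`; connected components of that edge set (single-linkage
#' transitive closure) are the clonal groups.  Edges with 0 differences are
#' classed `IDENTICAL`, those with 1..threshold `SOMATIC`.  Replicate
#' samples of one individual are merged to a single node beforehand — the
#' between-individual distance is the minimum over their sample pairs — and
#' replicate pairs within an individual that differ by 1..threshold alleles
#' are reported separately as within-individual somatic mutations.
#'
#' @param dists pairwise_distance data.frame (sample level); pairs flagged
#'   not comparable are ignored.
#' @param table the genotype_table the distances came from (maps samples to
#'   individuals and supplies coordinates).
#' @param somatic_threshold maximum allele difference still read as clonal
#'   with somatic mutations (default 3).
#' @return An object of class `clonal_network`: list with `nodes`
#'   (individual ids), `edges` (node_a, node_b, allele_diff, edge_class,
#'   geo_dist_m), `membership` (named component id per node), `components`
#'   (list of node-id vectors, groups of >= 2 first), and
#'   `within_individual` (replicate sample pairs with 1..threshold diffs).
#' @export
build_clonal_network <- function(dists, table, somatic_threshold = 3L) {
  ind_of <- table$samples$individual_id[match(dists$sample_a, table$samples$sample_id)]
  ind_b  <- table$samples$individual_id[match(dists$sample_b, table$samples$sample_id)]
  if (anyNA(ind_of) || anyNA(ind_b)) stop("distance pair references a sample absent from the table")

  within <- dists[ind_of == ind_b & dists$comparable &
                    dists$allele_diff >= 1L & dists$allele_diff <= somatic_threshold, , drop = FALSE]
  within$individual_id <- table$samples$individual_id[match(within$sample_a, table$samples$sample_id)]

  between <- dists[ind_of != ind_b & dists$comparable, , drop = FALSE]
  a <- pmin(ind_of[ind_of != ind_b & dists$comparable], ind_b[ind_of != ind_b & dists$comparable])
  b <- pmax(ind_of[ind_of != ind_b & dists$comparable], ind_b[ind_of != ind_b & dists$comparable])
  key <- paste(a, b, sep = "\r")
  # individual-level distance: minimum over replicate sample pairs
  if (nrow(between) > 0L) {
    min_diff <- tapply(between$allele_diff, key, min)
    edges_all <- data.frame(
      node_a = sub("\r.*", "", names(min_diff)),
      node_b = sub(".*\r", "", names(min_diff)),
      allele_diff = as.integer(min_diff),
      stringsAsFactors = FALSE
    )
  } else {
    edges_all <- data.frame(node_a = character(0), node_b = character(0),
                            allele_diff = integer(0), stringsAsFactors = FALSE)
  }
  edges <- edges_all[edges_all$allele_diff <= somatic_threshold, , drop = FALSE]
  edges$edge_class <- ifelse(edges$allele_diff == 0L, "IDENTICAL", "SOMATIC")

  ind_tab <- first_sample_per_individual(table)
  nodes <- sort(unique(ind_tab$samples$individual_id))
  ii_a <- match(edges$node_a, ind_tab$samples$individual_id)
  ii_b <- match(edges$node_b, ind_tab$samples$individual_id)
  edges$geo_dist_m <- if (nrow(edges) > 0L) {
    geographic_distance_vec(ind_tab$samples$lon[ii_a], ind_tab$samples$lat[ii_a],
                            ind_tab$samples$lon[ii_b], ind_tab$samples$lat[ii_b])
  } else numeric(0)
  rownames(edges) <- NULL

  g <- igraph::graph_from_data_frame(edges[, c("node_a", "node_b")],
                                     directed = FALSE,
                                     vertices = data.frame(name = nodes))
  comp <- igraph::components(g)
  membership <- comp$membership[nodes]
  comp_list <- split(nodes, membership)
  sizes <- vapply(comp_list, length, integer(1))
  comp_list <- comp_list[order(-sizes, vapply(comp_list, function(v) v[1L], character(1)))]
  names(comp_list) <- paste0("G", seq_along(comp_list))
  # renumber membership to match ordered components
  memb <- integer(length(nodes)); names(memb) <- nodes
  for (i in seq_along(comp_list)) memb[comp_list[[i]]] <- i

  structure(
    list(nodes = nodes, edges = edges, membership = memb,
         components = comp_list,
         within_individual = within,
         somatic_threshold = as.integer(somatic_threshold)),
    class = "clonal_network"
  )
}

#' @export
print.clonal_network <- function(x, ...) {
  sizes <- vapply(x$components, length, integer(1))
  cat("clonal_network:", length(x$nodes), "individuals,",
      nrow(x$edges), "clonal edges (threshold", x$somatic_threshold, ")\n")
  cat("  groups of >=2:", sum(sizes >= 2L), " singletons:", sum(sizes == 1L), "\n")
  if (nrow(x$within_individual) > 0L) {
    cat("  within-individual somatic-mutation sample pairs:",
        nrow(x$within_individual), "\n")
  }
  invisible(x)
}

#' Collapse samples into multilocus genotypes
#'
#' Counts distinct multilocus genotypes (MLGs) among individuals.  Under
#' `policy = "identical"` an MLG is a connected component of 0-difference
#' pairs; under `policy = "tolerant"` somatic mutants are merged too
#' (components of pairs with difference <= `somatic_threshold`), so the
#' tolerant count can never exceed the identical-only count.
#'
#' @param dists pairwise_distance data.frame (sample level)
#' @param table genotype_table
#' @param policy `"identical"` or `"tolerant"`
#' @param somatic_threshold threshold used when `policy = "tolerant"`
#' @return list with `n_mlg` and `assignment` (named integer MLG id per
#'   individual)
#' @export
collapse_mlg <- function(dists, table, policy = c("identical", "tolerant"),
                         somatic_threshold = 3L) {
  policy <- match.arg(policy)
  thr <- if (policy == "identical") 0L else as.integer(somatic_threshold)
  net <- build_clonal_network(dists, table, somatic_threshold = thr)
  list(n_mlg = length(net$components), assignment = net$membership)
}

#' Clonality summary of a network
#'
#' Summarises clone structure at the individual level: the number of
#' distinct genotypes, singleton genotypes (found once), clonal groups of
#' two or more individuals, the clonal fraction
#' `(N - n_singletons) / N` (share of individuals sitting in clonal
#' groups), and the clonal growth excess
#' `(N - n_singletons - n_groups) / N` — the share of individuals
#' attributable to clonal duplication beyond one founder per group.
#'
#' @param network clonal_network
#' @return object of class `clonality_summary`
#' @export
clonality_summary <- function(network) {
  sizes <- vapply(network$components, length, integer(1))
  clonality_from_counts(
    n_individuals = length(network$nodes),
    n_singletons = sum(sizes == 1L),
    n_groups = sum(sizes >= 2L)
  )
}

#' Clonality arithmetic from counts
#'
#' The same arithmetic as [clonality_summary()] but starting from already
#' tallied counts, e.g. when reproducing published tallies.
#' @param n_individuals total individuals N
#' @param n_singletons genotypes observed exactly once
#' @param n_groups clonal groups of two or more individuals
#' @return object of class `clonality_summary`: the counts plus `n_mlg`,
#'   `clonal_fraction` and `clonal_excess` (proportions in \[0, 1\])
#' @export
clonality_from_counts <- function(n_individuals, n_singletons, n_groups) {
  if (n_individuals <= 0L) stop("n_individuals must be positive")
  if (n_singletons + n_groups > n_individuals) {
    stop("n_singletons + n_groups exceeds n_individuals")
  }
  structure(list(
    n_individuals = as.integer(n_individuals),
    n_mlg = as.integer(n_singletons + n_groups),
    n_singletons = as.integer(n_singletons),
    n_groups = as.integer(n_groups),
    clonal_fraction = (n_individuals - n_singletons) / n_individuals,
    clonal_excess = (n_individuals - n_singletons - n_groups) / n_individuals
  ), class = "clonality_summary")
}

#' @export
print.clonality_summary <- function(x, ...) {
  cat("clonality summary\n")
  cat(sprintf("  individuals          %d\n", x$n_individuals))
  cat(sprintf("  multilocus genotypes %d\n", x$n_mlg))
  cat(sprintf("  singleton genotypes  %d\n", x$n_singletons))
  cat(sprintf("  clonal groups (>=2)  %d\n", x$n_groups))
  cat(sprintf("  clonal fraction      %.2f%%\n", 100 * x$clonal_fraction))
  cat(sprintf("  clonal growth excess %.2f%%\n", 100 * x$clonal_excess))
  invisible(x)
}

mlg_strings <- function(table, loci_subset = NULL) {
  cols <- colnames(table$alleles)
  if (!is.null(loci_subset)) {
    keep <- sub("\\.a[12]$", "", cols) %in% loci_subset
    cols <- cols[keep]
  }
  apply(table$alleles[, cols, drop = FALSE], 1L, paste, collapse = "/")
}

#' Genotype accumulation curve
#'
#' How many loci are needed to discriminate the multilocus genotypes?  For
#' each subset size k = 1..L-1, draws `n_perm` random subsets of k loci and
#' counts the distinct MLGs observable from those loci alone (string
#' identity; missing data treated as an own state).  Reports min, mean and
#' max per k, and the smallest k whose maximum reaches the full-panel MLG
#' count.
#'
#' @param table genotype_table (already censored/subset as desired)
#' @param n_perm random locus subsets per k (default 100)
#' @param seed RNG seed
#' @return list with `curve` (data.frame k, min, mean, max), `full_mlg`,
#'   and `k_sufficient` (NA if no k < L attains the full count)
#' @export
genotype_accumulation_curve <- function(table, n_perm = 100L, seed = 1L) {
  L <- length(loci_names(table))
  if (L < 2L) stop("need at least 2 loci for an accumulation curve")
  full_mlg <- length(unique(mlg_strings(table)))
  set.seed(seed)
  locs <- loci_names(table)
  rows <- lapply(seq_len(L - 1L), function(k) {
    counts <- vapply(seq_len(n_perm), function(i) {
      sub <- sample(locs, k)
      length(unique(mlg_strings(table, sub)))
    }, integer(1))
    data.frame(k = k, min = min(counts), mean = mean(counts), max = max(counts))
  })
  curve <- do.call(rbind, rows)
  ks <- curve$k[curve$max >= full_mlg]
  list(curve = curve, full_mlg = full_mlg,
       k_sufficient = if (length(ks) > 0L) min(ks) else NA_integer_)
}

#' Clone-censor a genotype table
#'
#' Returns one row per retained genotype at the requested tolerance:
#' `"none"` keeps every individual (replicate samples still reduced to one
#' row per individual); `"clones"` keeps one representative per group of
#' identical genotypes; `"clones_and_mutations"` merges somatic mutants
#' into their group as well (threshold from the network).  The
#' representative of a group is the individual whose chosen sample has the
#' fewest missing loci, ties broken lexicographically by sample id.
#'
#' @param table genotype_table
#' @param dists sample-level pairwise_distance (from
#'   [pairwise_allele_distance()])
#' @param level `"none"`, `"clones"` or `"clones_and_mutations"`
#' @param somatic_threshold threshold for `"clones_and_mutations"`
#' @return genotype_table with one sample per retained genotype
#' @export
censor <- function(table, dists,
                   level = c("none", "clones", "clones_and_mutations"),
                   somatic_threshold = 3L) {
  level <- match.arg(level)
  ind_tab <- first_sample_per_individual(table)
  if (level == "none") return(ind_tab)
  thr <- if (level == "clones") 0L else as.integer(somatic_threshold)
  net <- build_clonal_network(dists, table, somatic_threshold = thr)
  nmiss <- rowSums(is.na(ind_tab$alleles)) / 2
  names(nmiss) <- ind_tab$samples$individual_id
  reps <- vapply(net$components, function(members) {
    ord <- order(nmiss[members], members)
    members[ord][1L]
  }, character(1))
  subset_samples(ind_tab, ind_tab$samples$individual_id %in% reps)
}
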
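# Fixture builders and independent oracles used across the suite.
# Oracles deliberately use a different code path from the package
# (multiset tables, explicit union-find, transliterated textbook
# formulas) so that agreement is evidence, not tautology.

# Build a genotype table from a list of per-sample allele vectors.
# genos: list of integer vectors of length 2*L (a1,a2 per locus), NA ok.
make_table <- function(genos, lat = NULL, lon = NULL, site = "REGION",
                       individual_id = NULL, loci = NULL) {
  n <- length(genos)
  L <- length(genos[[1L]]) / 2L
  if (is.null(loci)) loci <- sprintf("loc%02d", seq_len(L))
  amat <- do.call(rbind, genos)
  colnames(amat) <- as.vector(rbind(paste0(loci, ".a1"), paste0(loci, ".a2")))
  if (is.null(lat)) lat <- 72.5 + seq_len(n) * 1e-4
  if (is.null(lon)) lon <- 105.7 + seq_len(n) * 1e-4
  ids <- sprintf("S%03d", seq_len(n))
  if (is.null(individual_id)) individual_id <- ids
  genets::genotype_table(
    data.frame(sample_id = ids, individual_id = individual_id,
               site = rep_len(site, n), lat = lat, lon = lon,
               stringsAsFactors = FALSE),
    amat)
}

# Random small genotype table (possibly with missing loci).
random_table <- function(n = 5L, L = 4L, n_alleles = 4L, missing_rate = 0,
                         seed = 1L) {
  set.seed(seed)
  genos <- lapply(seq_len(n), function(i) {
    g <- unlist(lapply(seq_len(L), function(j) {
      sort(sample(100L + 2L * seq_len(n_alleles), 2L, replace = TRUE))
    }))
    if (missing_rate > 0) {
      for (j in seq_len(L)) {
        if (runif(1) < missing_rate) g[(2L * j - 1L):(2L * j)] <- NA_integer_
      }
    }
    g
  })
  make_table(genos)
}

# Oracle: multiset allele difference between two samples via table().
oracle_pair_distance <- function(tab, i, j) {
  L <- length(genets::loci_names(tab))
  total <- 0L; compared <- 0L
  for (l in seq_len(L)) {
    cols <- (2L * l - 1L):(2L * l)
    x <- tab$alleles[i, cols]; y <- tab$alleles[j, cols]
    if (anyNA(x) || anyNA(y)) next
    compared <- compared + 1L
    tx <- table(x); ty <- table(y)
    shared <- sum(vapply(union(names(tx), names(ty)), function(a) {
      min(ifelse(a %in% names(tx), tx[[a]], 0L),
          ifelse(a %in% names(ty), ty[[a]], 0L))
    }, numeric(1)))
    total <- total + (2L - shared)
  }
  list(allele_diff = as.integer(total), loci_compared = compared)
}

# Oracle: connected components by explicit union-find.
oracle_components <- function(nodes, edges_a, edges_b) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (k in seq_along(edges_a)) {
    ra <- find(edges_a[k]); rb <- find(edges_b[k])
    if (ra != rb) parent[[ra]] <- rb
  }
  roots <- vapply(nodes, find, character(1))
  split(nodes, roots)
}

# Oracle: Weir & Cockerham (1984) variance components, transliterated for
# one allele of one locus from population counts.
# n_i: individuals per pop, p_i: allele freq per pop, h_i: het freq per pop
wc_oracle_components <- function(n_i, p_i, h_i) {
  r <- length(n_i)
  nbar <- mean(n_i)
  nsum <- sum(n_i)
  nc <- (nsum - sum(n_i^2) / nsum) / (r - 1)
  pbar <- sum(n_i * p_i) / nsum
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / nsum
  a <- (nbar / nc) * (s2 - 1 / (nbar - 1) *
                        (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              (2 * nbar - 1) / (4 * nbar) * hbar)
  c <- hbar / 2
  c(a = a, b = b, c = c)
}

# Oracle: index of association from first principles (explicit pair loop).
ia_oracle <- function(tab) {
  n <- genets::n_samples(tab)
  L <- length(genets::loci_names(tab))
  pairs <- utils::combn(n, 2L)
  dj <- matrix(0, ncol(pairs), L)
  for (k in seq_len(ncol(pairs))) {
    for (l in seq_len(L)) {
      cols <- (2L * l - 1L):(2L * l)
      x <- tab$alleles[pairs[1L, k], cols]; y <- tab$alleles[pairs[2L, k], cols]
      shared <- sum(vapply(unique(c(x, y)), function(a) {
        min(sum(x == a), sum(y == a))
      }, numeric(1)))
      dj[k, l] <- 2 - shared
    }
  }
  D <- rowSums(dj)
  V_O <- stats::var(D)
  vars <- apply(dj, 2L, stats::var)
  V_E <- sum(vars)
  sds <- sqrt(vars)
  cross <- (sum(sds)^2 - sum(vars)) / 2
  list(I_A = V_O / V_E - 1, rbarD = (V_O - V_E) / (2 * cross),
       V_O = V_O, V_E = V_E)
}

# Write a genotype table in the on-disk format by hand (column order and
# tokens controlled by the test, not by write_genotype_table()).
write_raw_genotype_file <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(lines, path)
  path
}

# A table of n HW genotypes at one locus with given allele frequencies.
hw_locus_table <- function(n, freqs, seed = 1L, sizes = NULL) {
  set.seed(seed)
  k <- length(freqs)
  if (is.null(sizes)) sizes <- 100L + 2L * seq_len(k)
  genos <- lapply(seq_len(n), function(i) {
    # two loci: the locus under test plus a constant filler locus
    c(sort(sample(sizes, 2L, replace = TRUE, prob = freqs)), 100L, 100L)
  })
  make_table(genos)
}
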
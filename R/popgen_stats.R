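# Per-locus diversity summaries, Hardy-Weinberg Monte-Carlo exact tests,
# Weir-Cockerham F-statistics and the index of association.
#
# All statistics drop missing genotypes per locus (complete-case per
# locus).  Permutation p-values use the add-one convention
# p = (1 + #{perm >= obs}) / (n_perm + 1), which cannot return zero.

locus_genotypes <- function(table, locus) {
  a1 <- table$alleles[, paste0(locus, ".a1")]
  a2 <- table$alleles[, paste0(locus, ".a2")]
  ok <- !is.na(a1)
  cbind(a1 = a1[ok], a2 = a2[ok])
}

allele_freqs <- function(geno) {
  al <- c(geno[, 1L], geno[, 2L])
  tab <- table(al)
  as.numeric(tab) / sum(tab)
}

#' Per-locus diversity summaries
#'
#' For each locus: number of alleles, observed size range (bp), observed
#' heterozygosity H_O (fraction of typed genotypes that are heterozygous),
#' Nei's unbiased expected heterozygosity
#' H_E = (1 - sum p_i^2) * 2n / (2n - 1), the E5 evenness of the allele
#' frequency distribution, the fraction of individuals with missing
#' alleles, and a Monte-Carlo Hardy-Weinberg p-value (see
#' [hwe_test_mc()]).  For Table-style stand reporting these summaries are
#' conventionally computed on the clone-and-mutation-censored subset to
#' avoid pseudo-replicating clonal genotypes; the function itself takes
#' whatever table it is given.
#'
#' @param table genotype_table (typically censored first, see [censor()])
#' @param n_perm Monte-Carlo permutations for the HWE test (default 1000)
#' @param seed RNG seed for the HWE permutations
#' @param unbiased use Nei's small-sample correction for H_E (default
#'   TRUE); FALSE gives the plain gene diversity 1 - sum p_i^2
#' @return data.frame, one row per locus: `locus`, `n_typed`, `N_A`,
#'   `size_min`, `size_max`, `H_O`, `H_E`, `hwe_p`, `evenness`,
#'   `missing_fraction`
#' @export
locus_summaries <- function(table, n_perm = 1000L, seed = 1L, unbiased = TRUE) {
  n_tot <- n_samples(table)
  rows <- lapply(seq_along(loci_names(table)), function(li) {
    loc <- loci_names(table)[li]
    g <- locus_genotypes(table, loc)
    n <- nrow(g)
    if (n == 0L) {
      return(data.frame(locus = loc, n_typed = 0L, N_A = NA_integer_,
                        size_min = NA_integer_, size_max = NA_integer_,
                        H_O = NA_real_, H_E = NA_real_, hwe_p = NA_real_,
                        evenness = NA_real_, missing_fraction = 1))
    }
    p <- allele_freqs(g)
    Ho <- mean(g[, 1L] != g[, 2L])
    He <- 1 - sum(p^2)
    if (unbiased && n > 0L) He <- He * (2 * n) / (2 * n - 1)
    data.frame(
      locus = loc, n_typed = n, N_A = length(p),
      size_min = min(g), size_max = max(g),
      H_O = Ho, H_E = He,
      hwe_p = hwe_test_mc(table, loc, n_perm = n_perm, seed = seed + li),
      evenness = evenness_e5(p),
      missing_fraction = 1 - n / n_tot,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' E5 evenness of a frequency vector
#'
#' E5 = (1/lambda - 1) / (exp(H') - 1) with lambda the Simpson index
#' (sum p_i^2) and H' the Shannon entropy; equals 1 for a uniform
#' distribution and, by convention here, for a monomorphic locus.
#' @param p vector of frequencies summing to 1
#' @return evenness in (0, 1]
#' @export
evenness_e5 <- function(p) {
  p <- p[p > 0]
  if (length(p) <= 1L) return(1)
  lambda <- sum(p^2)
  H <- -sum(p * log(p))
  (1 / lambda - 1) / (exp(H) - 1)
}

hwe_chisq_stat <- function(g) {
  # Pearson chi-squared of observed genotype counts vs HWE expectations
  n <- nrow(g)
  al <- sort(unique(c(g[, 1L], g[, 2L])))
  k <- length(al)
  i1 <- match(g[, 1L], al); i2 <- match(g[, 2L], al)
  lo <- pmin(i1, i2); hi <- pmax(i1, i2)
  # unordered genotype class (lo, hi) stored row-major at (lo-1)*k + hi
  obs <- tabulate((lo - 1L) * k + hi, nbins = k * k)
  cnt <- tabulate(c(i1, i2), nbins = k)
  p <- cnt / (2 * n)
  E <- 2 * n * outer(p, p)   # 2 n p_i p_j heterozygotes (counted once, i < j)
  diag(E) <- n * p^2         # n p_i^2 homozygotes
  Ev <- as.numeric(t(E))     # row-major, matching the obs layout
  mask <- as.vector(t(upper.tri(E, diag = TRUE))) & Ev > 0
  sum((obs[mask] - Ev[mask])^2 / Ev[mask])
}

#' Monte-Carlo exact test of Hardy-Weinberg equilibrium
#'
#' The statistic is the Pearson chi-squared distance between observed
#' genotype counts and their Hardy-Weinberg expectations from the sample
#' allele frequencies.  The null distribution is obtained by pooling the
#' 2n observed alleles and re-pairing them at random `n_perm` times
#' (permutation of alleles); the one-sided p-value is
#' (1 + #\{perm stat >= observed\}) / (n_perm + 1).
#'
#' @param table genotype_table
#' @param locus locus name
#' @param n_perm Monte-Carlo permutations (default 1000)
#' @param seed RNG seed
#' @return p-value in (0, 1]; a monomorphic locus returns 1.
#' @export
hwe_test_mc <- function(table, locus, n_perm = 1000L, seed = 1L) {
  g <- locus_genotypes(table, locus)
  n <- nrow(g)
  if (n == 0L) return(NA_real_)
  al_pool <- c(g[, 1L], g[, 2L])
  if (length(unique(al_pool)) < 2L) return(1)
  obs <- hwe_chisq_stat(g)
  set.seed(seed)
  ge <- 0L
  for (b in seq_len(n_perm)) {
    perm <- sample(al_pool)
    gp <- cbind(perm[seq_len(n)], perm[n + seq_len(n)])
    if (hwe_chisq_stat(gp) >= obs - 1e-12) ge <- ge + 1L
  }
  (1 + ge) / (n_perm + 1)
}

#' Weir-Cockerham F-statistics
#'
#' Estimates F_ST and F_IS (and F_IT) from the Weir & Cockerham (1984)
#' variance components: for every allele at every locus the among-
#' population (a), among-individual-within-population (b) and
#' within-individual (c) components are computed from population sample
#' sizes, allele frequencies and heterozygote frequencies; the estimators
#' are ratios of summed components, F_ST = sum(a) / sum(a + b + c) and
#' F_IS = 1 - sum(c) / sum(b + c), per locus and overall.  Slightly
#' negative estimates are legitimate (sampling noise around zero).
#'
#' @param table genotype_table
#' @param grouping population label per sample: either a column name of
#'   the sample metadata (e.g. `"site"`) or a vector of labels of length
#'   `n_samples(table)`
#' @return list of class `fstats`: `per_locus` data.frame (locus, F_ST,
#'   F_IS, F_IT), `overall` named vector, `groups` the labels used
#' @export
weir_cockerham <- function(table, grouping = "site") {
  if (is.character(grouping) && length(grouping) == 1L) {
    if (!grouping %in% names(table$samples)) stop("no metadata column '", grouping, "'")
    pops <- table$samples[[grouping]]
  } else {
    if (length(grouping) != n_samples(table)) stop("grouping length must equal sample count")
    pops <- as.character(grouping)
  }
  if (length(unique(pops)) < 2L) stop("need at least 2 populations for F-statistics")

  per_locus <- lapply(loci_names(table), function(loc) {
    comp <- wc_components(table, loc, pops)
    if (is.null(comp)) return(NULL)
    data.frame(locus = loc,
               a = sum(comp$a), b = sum(comp$b), c = sum(comp$c),
               stringsAsFactors = FALSE)
  })
  per_locus <- do.call(rbind, per_locus)
  if (is.null(per_locus) || nrow(per_locus) == 0L) stop("no locus usable for F-statistics")

  fst <- function(a, b, c) ifelse(a + b + c == 0, NA_real_, a / (a + b + c))
  fis <- function(b, c) ifelse(b + c == 0, NA_real_, 1 - c / (b + c))
  fit <- function(a, b, c) ifelse(a + b + c == 0, NA_real_, 1 - c / (a + b + c))
  out_locus <- data.frame(
    locus = per_locus$locus,
    F_ST = fst(per_locus$a, per_locus$b, per_locus$c),
    F_IS = fis(per_locus$b, per_locus$c),
    F_IT = fit(per_locus$a, per_locus$b, per_locus$c),
    stringsAsFactors = FALSE
  )
  A <- sum(per_locus$a); B <- sum(per_locus$b); C <- sum(per_locus$c)
  overall <- c(F_ST = fst(A, B, C), F_IS = fis(B, C), F_IT = fit(A, B, C))
  structure(list(per_locus = out_locus, overall = overall,
                 groups = sort(unique(pops))),
            class = "fstats")
}

#' @export
print.fstats <- function(x, ...) {
  cat("Weir-Cockerham F-statistics over", length(x$groups), "groups\n")
  cat(sprintf("  overall: F_ST = %.4f  F_IS = %.4f  F_IT = %.4f\n",
              x$overall["F_ST"], x$overall["F_IS"], x$overall["F_IT"]))
  invisible(x)
}

# Variance components a, b, c per allele for one locus.
# Populations with no typed genotype at the locus are dropped; returns
# NULL when fewer than 2 populations remain or the locus is monomorphic.
wc_components <- function(table, locus, pops) {
  a1 <- table$alleles[, paste0(locus, ".a1")]
  a2 <- table$alleles[, paste0(locus, ".a2")]
  ok <- !is.na(a1)
  if (!any(ok)) return(NULL)
  a1 <- a1[ok]; a2 <- a2[ok]; pop <- pops[ok]
  pop_levels <- unique(pop)
  r <- length(pop_levels)
  if (r < 2L) {
    warning("locus ", locus, " typed in fewer than 2 populations; skipped")
    return(NULL)
  }
  alleles <- sort(unique(c(a1, a2)))
  if (length(alleles) < 2L) return(NULL)

  n_i <- as.numeric(table(factor(pop, levels = pop_levels)))
  nbar <- mean(n_i)
  n_sum <- sum(n_i)
  nc <- (n_sum - sum(n_i^2) / n_sum) / (r - 1)

  a_v <- b_v <- c_v <- numeric(length(alleles))
  for (ai in seq_along(alleles)) {
    A <- alleles[ai]
    cnt <- (a1 == A) + (a2 == A)
    het <- (a1 == A) != (a2 == A)   # exactly one copy of A
    p_i <- as.numeric(tapply(cnt, factor(pop, levels = pop_levels), sum)) / (2 * n_i)
    h_i <- as.numeric(tapply(het, factor(pop, levels = pop_levels), mean))
    pbar <- sum(n_i * p_i) / n_sum
    s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n_i * h_i) / n_sum
    a_v[ai] <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
    b_v[ai] <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
    c_v[ai] <- hbar / 2
  }
  list(a = a_v, b = b_v, c = c_v, alleles = alleles)
}

# per-locus pairwise distance matrices (0/1/2 multiset metric), missing
# entries imputed with the locus mean pairwise distance
per_locus_distance_matrices <- function(table) {
  n <- n_samples(table)
  lapply(loci_names(table), function(loc) {
    a1 <- table$alleles[, paste0(loc, ".a1")]
    a2 <- table$alleles[, paste0(loc, ".a2")]
    d <- matrix(NA_real_, n, n)
    ia <- rep(seq_len(n), times = n)
    ib <- rep(seq_len(n), each = n)
    sh <- pair_shared(a1[ia], a2[ia], a1[ib], a2[ib])
    d[] <- 2 - sh
    d[is.na(a1)[ia] | is.na(a1)[ib]] <- NA_real_
    diag(d) <- 0
    off <- d[lower.tri(d)]
    if (anyNA(off)) {
      fill <- mean(off, na.rm = TRUE)
      if (is.nan(fill)) fill <- 0
      d[is.na(d)] <- fill
    }
    d
  })
}

ia_from_matrices <- function(dmats, perm = NULL) {
  n <- nrow(dmats[[1L]])
  lt <- lower.tri(dmats[[1L]])
  per_locus <- vapply(seq_along(dmats), function(j) {
    d <- dmats[[j]]
    if (!is.null(perm)) d <- d[perm[[j]], perm[[j]]]
    d[lt]
  }, numeric(sum(lt)))
  D <- rowSums(per_locus)
  V_O <- stats::var(D)
  vars <- apply(per_locus, 2L, stats::var)
  V_E <- sum(vars)
  if (V_E == 0) stop("no variance: all loci have identical genotypes across samples")
  sds <- sqrt(vars)
  cross <- (sum(sds)^2 - sum(vars)) / 2   # sum_{j<k} sd_j sd_k
  list(I_A = V_O / V_E - 1,
       rbarD = if (cross > 0) (V_O - V_E) / (2 * cross) else NA_real_,
       V_O = V_O, V_E = V_E)
}

#' Index of association with permutation test
#'
#' Multilocus linkage disequilibrium: with per-locus pairwise genetic
#' distances d_j over sample pairs and their sum D, the index is
#' I_A = V_O / V_E - 1 where V_O = Var(D) and V_E = sum_j Var(d_j); the
#' standardized form is rbarD = (V_O - V_E) / (2 sum_\{j<k\}
#' sqrt(Var d_j Var d_k)).  Under sexual recombination loci are
#' independent and I_A is near 0; clonal reproduction couples loci and
#' inflates it.  The null distribution permutes each locus's genotype
#' column independently across samples; p = (1 + #\{perm I_A >= obs\}) /
#' (n_perm + 1).  Missing per-locus distances are imputed with the locus
#' mean before the variance computation.
#'
#' @param table genotype_table (>= 3 samples, >= 2 loci)
#' @param n_perm permutations (default 1000)
#' @param seed RNG seed
#' @param dataset_level free-text label carried into the result (e.g.
#'   `"all"`, `"clone-censored"`)
#' @return list of class `ia_result`: `I_A`, `rbarD`, `V_O`, `V_E`,
#'   `p_value`, `n_perm`, `dataset_level`
#' @export
index_of_association <- function(table, n_perm = 1000L, seed = 1L,
                                 dataset_level = "all") {
  if (n_samples(table) < 3L) stop("need at least 3 samples")
  if (length(loci_names(table)) < 2L) stop("need at least 2 loci")
  dmats <- per_locus_distance_matrices(table)
  obs <- ia_from_matrices(dmats)
  set.seed(seed)
  n <- n_samples(table)
  ge <- 0L
  for (b in seq_len(n_perm)) {
    perm <- lapply(seq_along(dmats), function(j) sample.int(n))
    ia_b <- ia_from_matrices(dmats, perm)$I_A
    if (ia_b >= obs$I_A - 1e-12) ge <- ge + 1L
  }
  structure(list(I_A = obs$I_A, rbarD = obs$rbarD, V_O = obs$V_O, V_E = obs$V_E,
                 p_value = (1 + ge) / (n_perm + 1), n_perm = as.integer(n_perm),
                 dataset_level = dataset_level),
            class = "ia_result")
}

#' @export
print.ia_result <- function(x, ...) {
  cat(sprintf("index of association (%s): I_A = %.4f, rbarD = %.4f, p = %.4g (%d permutations)\n",
              x$dataset_level, x$I_A, x$rbarD, x$p_value, x$n_perm))
  invisible(x)
}
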
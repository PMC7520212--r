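test_that("per-locus multiset differences match hand cases", {
  base <- rep(c(154L, 172L), 16L)  # heterozygous at 16 loci
  # identical at all loci
  tab <- make_table(list(base, base))
  d <- pairwise_allele_distance(tab)
  expect_equal(d$allele_diff, 0L)
  expect_equal(d$loci_compared, 16L)
  expect_true(d$comparable)

  # (154,172) vs (154,154) at locus 1, rest identical -> 1
  g2 <- base; g2[1:2] <- c(154L, 154L)
  expect_equal(pairwise_allele_distance(make_table(list(base, g2)))$allele_diff, 1L)

  # (154,172) vs (160,166) at locus 1 -> that locus contributes 2
  g3 <- base; g3[1:2] <- c(160L, 166L)
  expect_equal(pairwise_allele_distance(make_table(list(base, g3)))$allele_diff, 2L)

  # homozygote vs homozygote, different alleles -> 2
  g4 <- base; g4[1:2] <- c(154L, 154L); g5 <- base; g5[1:2] <- c(160L, 160L)
  expect_equal(pairwise_allele_distance(make_table(list(g4, g5)))$allele_diff, 2L)
})

test_that("distances agree with the brute-force multiset oracle on random tables", {
  for (seed in 1:12) {
    tab <- random_table(n = 6L, L = 4L, n_alleles = 3L,
                        missing_rate = 0.25, seed = seed)
    d <- pairwise_allele_distance(tab, min_shared_loci = 2L)
    for (k in seq_len(nrow(d))) {
      i <- match(d$sample_a[k], tab$samples$sample_id)
      j <- match(d$sample_b[k], tab$samples$sample_id)
      oracle <- oracle_pair_distance(tab, i, j)
      expect_identical(d$allele_diff[k], oracle$allele_diff)
      expect_identical(d$loci_compared[k], oracle$loci_compared)
    }
  }
})

test_that("distance is symmetric, non-negative, bounded and identity-respecting", {
  tab <- random_table(n = 6L, L = 5L, missing_rate = 0.2, seed = 42L)
  d <- pairwise_allele_distance(tab, min_shared_loci = 1L)
  expect_true(all(d$allele_diff >= 0L))
  expect_true(all(d$allele_diff <= 2L * d$loci_compared))
  # self-distance via a duplicated genotype row
  genos <- c(list(tab$alleles[1L, ]), lapply(1:6, function(i) tab$alleles[i, ]))
  dup <- make_table(genos)   # sample S001 duplicates S002's genotype
  dd <- pairwise_allele_distance(dup, min_shared_loci = 1L)
  self <- dd[dd$sample_a == "S001" & dd$sample_b == "S002", ]
  expect_equal(self$allele_diff, 0L)
})

test_that("pairs sharing too few loci are flagged not comparable but retained", {
  g1 <- c(154L, 156L, NA, NA, NA, NA)
  g2 <- c(154L, 156L, 160L, 162L, 170L, 170L)
  tab <- make_table(list(g1, g2))
  d <- pairwise_allele_distance(tab, min_shared_loci = 2L)
  expect_equal(nrow(d), 1L)
  expect_false(d$comparable)
  expect_equal(d$loci_compared, 1L)
  # not comparable pairs yield no network edge
  net <- build_clonal_network(d, tab)
  expect_length(net$components, 2L)
})

test_that("clonal network components equal brute-force union-find closure", {
  # chain A-B (0 diff), B-C (2 diff) -> one component
  base <- rep(c(154L, 172L), 16L)
  gC <- base; gC[1:4] <- c(154L, 154L, 172L, 172L)  # 2 diffs from base
  tab <- make_table(list(base, base, gC))
  d <- pairwise_allele_distance(tab)
  net <- build_clonal_network(d, tab)
  expect_length(net$components, 1L)
  expect_setequal(net$components[[1L]], tab$samples$individual_id)

  # mixed edge classes coexist in one component
  g1 <- base
  g2 <- base; g2[1:2] <- c(154L, 154L)                      # 1 diff from g1
  g3 <- base; g3[1:2] <- c(154L, 154L); g3[3:4] <- c(154L, 154L)  # 2 from g1
  tab2 <- make_table(list(g1, g1, g2, g3))
  d2 <- pairwise_allele_distance(tab2)
  net2 <- build_clonal_network(d2, tab2)
  expect_length(net2$components, 1L)
  expect_setequal(unique(net2$edges$edge_class), c("IDENTICAL", "SOMATIC"))

  # random tables: components match an independent union-find
  for (seed in 1:8) {
    tab3 <- random_table(n = 7L, L = 4L, n_alleles = 3L, seed = seed)
    d3 <- pairwise_allele_distance(tab3, min_shared_loci = 1L)
    net3 <- build_clonal_network(d3, tab3, somatic_threshold = 2L)
    keep <- d3$allele_diff <= 2L
    oc <- oracle_components(tab3$samples$individual_id,
                            d3$sample_a[keep], d3$sample_b[keep])
    sig <- function(comps) sort(vapply(comps, function(v)
      paste(sort(v), collapse = ","), character(1)))
    expect_equal(unname(sig(net3$components)), unname(sig(oc)))
  }
})

test_that("all pairwise differences above threshold leave every node a singleton", {
  tab <- make_table(list(
    rep(c(100L, 102L), 16L),
    rep(c(120L, 122L), 16L),
    rep(c(140L, 142L), 16L)))
  net <- build_clonal_network(pairwise_allele_distance(tab), tab)
  expect_length(net$components, 3L)
  expect_equal(nrow(net$edges), 0L)
})

test_that("component structure is invariant under sample order permutation", {
  tab <- random_table(n = 8L, L = 4L, n_alleles = 3L, seed = 99L)
  d <- pairwise_allele_distance(tab, min_shared_loci = 1L)
  net <- build_clonal_network(d, tab, somatic_threshold = 2L)
  perm <- c(5L, 2L, 8L, 1L, 7L, 3L, 6L, 4L)
  tabp <- subset_samples(tab, perm)
  dp <- pairwise_allele_distance(tabp, min_shared_loci = 1L)
  netp <- build_clonal_network(dp, tabp, somatic_threshold = 2L)
  sig <- function(comps) sort(vapply(comps, function(v)
    paste(sort(v), collapse = ","), character(1)))
  expect_equal(unname(sig(net$components)), unname(sig(netp$components)))
})

test_that("replicate samples merge to one node and somatic replicates are reported", {
  base <- rep(c(154L, 172L), 16L)
  mut <- base; mut[1:2] <- c(154L, 154L)  # 1 somatic difference
  tab <- make_table(list(base, mut, base),
                    individual_id = c("T1", "T1", "T2"))
  d <- pairwise_allele_distance(tab)
  net <- build_clonal_network(d, tab)
  expect_setequal(net$nodes, c("T1", "T2"))
  expect_equal(nrow(net$within_individual), 1L)
  expect_equal(net$within_individual$individual_id, "T1")
  expect_equal(net$within_individual$allele_diff, 1L)
  # T1-T2 distance is the minimum over replicate pairs (0, via the base sample)
  expect_equal(net$edges$allele_diff, 0L)
  expect_length(net$components, 1L)
})

test_that("MLG collapsing: identical vs tolerant policies", {
  base <- rep(c(154L, 172L), 16L)
  mut <- base; mut[1:2] <- c(154L, 154L)
  far <- rep(c(200L, 202L), 16L)
  tab <- make_table(list(base, base, mut, far))
  d <- pairwise_allele_distance(tab)
  expect_equal(collapse_mlg(d, tab, "identical")$n_mlg, 3L)
  expect_equal(collapse_mlg(d, tab, "tolerant")$n_mlg, 2L)

  # all distinct -> n_mlg = n; tolerant never exceeds identical (property)
  for (seed in 1:6) {
    tabr <- random_table(n = 6L, L = 4L, n_alleles = 4L, seed = seed)
    dr <- pairwise_allele_distance(tabr, min_shared_loci = 1L)
    ni <- collapse_mlg(dr, tabr, "identical")$n_mlg
    nt <- collapse_mlg(dr, tabr, "tolerant")$n_mlg
    expect_lte(nt, ni)
  }
})

test_that("clonality summary arithmetic and its exact invariant", {
  s <- clonality_from_counts(10L, 4L, 2L)
  expect_equal(s$clonal_fraction, 0.6)
  expect_equal(s$clonal_excess, 0.4)
  expect_equal(s$n_mlg, 6L)
  # clonal_excess = clonal_fraction - n_groups/N exactly
  expect_equal(s$clonal_excess, s$clonal_fraction - s$n_groups / s$n_individuals)

  # all singletons -> both zero
  s0 <- clonality_from_counts(5L, 5L, 0L)
  expect_equal(s0$clonal_fraction, 0)
  expect_equal(s0$clonal_excess, 0)
  expect_error(clonality_from_counts(0L, 0L, 0L), "positive")

  # network-derived summary agrees with counts
  tab <- make_table(list(rep(c(1L, 2L), 4L), rep(c(1L, 2L), 4L),
                         rep(c(9L, 9L), 4L)))
  net <- build_clonal_network(pairwise_allele_distance(tab, 2L), tab)
  cs <- clonality_summary(net)
  expect_equal(cs$n_singletons + cs$n_groups, length(net$components))
  expect_equal(cs$clonal_fraction, 2 / 3)
  expect_equal(cs$clonal_excess, 1 / 3)
})

test_that("genotype accumulation curve is monotone and plateaus correctly", {
  # samples all differ at locus 1 -> subsets containing it discriminate fully
  genos <- lapply(1:5, function(i) c(100L + 2L * i, 100L + 2L * i,
                                     150L, 152L, 200L, 200L))
  tab <- make_table(genos)
  acc <- genotype_accumulation_curve(tab, n_perm = 50L, seed = 1L)
  expect_equal(acc$full_mlg, 5L)
  expect_equal(acc$curve$max[1L], 5L)  # some 1-locus subset (locus 1) suffices
  expect_equal(acc$k_sufficient, 1L)

  # mean is non-decreasing in k (property over random tables)
  for (seed in 1:4) {
    tabr <- random_table(n = 8L, L = 5L, n_alleles = 3L, seed = seed)
    accr <- genotype_accumulation_curve(tabr, n_perm = 30L, seed = seed)
    expect_true(all(diff(accr$curve$mean) >= -1e-9))
  }

  # duplicate genotypes: curve plateaus below the sample count
  dup <- make_table(list(rep(c(1L, 2L), 4L), rep(c(1L, 2L), 4L),
                         rep(c(3L, 4L), 4L)))
  accd <- genotype_accumulation_curve(dup, n_perm = 20L, seed = 2L)
  expect_equal(accd$full_mlg, 2L)
  expect_true(all(accd$curve$max <= 2L))
  expect_error(genotype_accumulation_curve(make_table(list(c(1L, 2L))), 10L, 1L),
               "2 loci")
})

test_that("censoring keeps one representative per group and respects the keep rule", {
  base <- rep(c(154L, 172L), 16L)
  mut <- base; mut[1:2] <- c(154L, 154L)
  far <- rep(c(200L, 202L), 16L)
  tab <- make_table(list(base, mut, far, base))
  d <- pairwise_allele_distance(tab)

  none <- censor(tab, d, "none")
  expect_equal(n_samples(none), 4L)   # identity when every sample is its own individual

  cl <- censor(tab, d, "clones")
  expect_equal(n_samples(cl), 3L)     # the two identical samples collapse

  cm <- censor(tab, d, "clones_and_mutations")
  expect_equal(n_samples(cm), 2L)     # the mutant joins its group

  # censored table: minimum pairwise difference exceeds the threshold
  dcm <- pairwise_allele_distance(cm)
  expect_true(all(dcm$allele_diff[dcm$comparable] > 3L))

  # representative = fewest missing loci, tie -> lexicographic sample id
  tab2 <- make_table(list(base, base, base))
  tab2$alleles[1L, 1:4] <- NA_integer_   # S001 has 2 missing loci
  tab2 <- genotype_table(tab2$samples, tab2$alleles)
  d2 <- pairwise_allele_distance(tab2, min_shared_loci = 10L)
  c2 <- censor(tab2, d2, "clones")
  expect_equal(c2$samples$sample_id, "S002")
})
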
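test_that("locus summaries match hand-computed frequencies on a small fixture", {
  # 10 samples, locus 1: alleles 100/102 with frequencies 0.6/0.4,
  # 4 heterozygotes; locus 2 monomorphic; locus 3 with 2 missing
  genos <- list(
    c(100L, 100L, 50L, 50L, 10L, 12L),
    c(100L, 100L, 50L, 50L, 10L, 12L),
    c(100L, 100L, 50L, 50L, NA, NA),
    c(100L, 100L, 50L, 50L, 10L, 10L),
    c(100L, 102L, 50L, 50L, 12L, 12L),
    c(100L, 102L, 50L, 50L, 10L, 12L),
    c(100L, 102L, 50L, 50L, 10L, 12L),
    c(100L, 102L, 50L, 50L, NA, NA),
    c(102L, 102L, 50L, 50L, 10L, 12L),
    c(102L, 102L, 50L, 50L, 10L, 10L))
  tab <- make_table(genos)
  s <- locus_summaries(tab, n_perm = 200L, seed = 7L)

  # locus 1 oracle: p(100) = 12/20, p(102) = 8/20, n = 10
  p <- c(12, 8) / 20
  expect_equal(s$N_A[1L], 2L)
  expect_equal(s$H_O[1L], 4 / 10)
  expect_equal(s$H_E[1L], (1 - sum(p^2)) * 20 / 19)
  expect_equal(s$size_min[1L], 100L)
  expect_equal(s$size_max[1L], 102L)
  expect_equal(s$missing_fraction[1L], 0)
  lam <- sum(p^2); H <- -sum(p * log(p))
  expect_equal(s$evenness[1L], (1 / lam - 1) / (exp(H) - 1))

  # monomorphic locus: H_E = 0, evenness 1, HWE p = 1
  expect_equal(s$H_E[2L], 0)
  expect_equal(s$evenness[2L], 1)
  expect_equal(s$hwe_p[2L], 1)
  expect_equal(s$H_O[2L], 0)

  # missing accounting on locus 3
  expect_equal(s$missing_fraction[3L], 0.2)
  expect_equal(s$n_typed[3L], 8L)

  # uncorrected H_E switch
  s2 <- locus_summaries(tab, n_perm = 10L, seed = 1L, unbiased = FALSE)
  expect_equal(s2$H_E[1L], 1 - sum(p^2))
})

test_that("H_E approaches the closed form and H_O is exact on constructed data", {
  # equal-frequency biallelic locus, all heterozygous -> H_O = 1
  genos <- replicate(50, c(100L, 102L, 10L, 12L), simplify = FALSE)
  s <- locus_summaries(make_table(genos), n_perm = 10L, seed = 1L)
  expect_equal(s$H_O[1L], 1)
  expect_equal(s$H_E[1L], 0.5 * 100 / 99)  # (1 - 2*0.25) * 2n/(2n-1)
})

test_that("HWE Monte-Carlo test calls a gross heterozygote excess and respects bounds", {
  # all 50 genotypes heterozygous ab, p = 0.5: far off HW proportions
  genos <- replicate(50, c(100L, 102L, 10L, 12L), simplify = FALSE)
  tab <- make_table(genos)
  p <- hwe_test_mc(tab, "loc01", n_perm = 500L, seed = 11L)
  expect_lte(p, 0.05)

  # n_perm = 1 can only give 0.5 or 1
  p1 <- hwe_test_mc(tab, "loc01", n_perm = 1L, seed = 3L)
  expect_true(p1 %in% c(0.5, 1))

  # p is never 0 and never above 1
  for (seed in 1:5) {
    tabr <- random_table(n = 12L, L = 2L, n_alleles = 3L, seed = seed)
    pr <- hwe_test_mc(tabr, "loc01", n_perm = 99L, seed = seed)
    expect_gt(pr, 0)
    expect_lte(pr, 1)
  }
})

test_that("HWE p-values are roughly uniform under a small simulated null", {
  # quick sanity version of the full calibration (which runs in acceptance)
  set.seed(21)
  ps <- vapply(1:60, function(r) {
    freqs <- rep(0.2, 5)
    sizes <- 100L + 2L * (1:5)
    genos <- replicate(60, {
      g <- sample(sizes, 2L, replace = TRUE, prob = freqs)
      c(sort(g), 10L, 12L)
    }, simplify = FALSE)
    hwe_test_mc(make_table(genos), "loc01", n_perm = 99L, seed = 1000L + r)
  }, numeric(1))
  expect_gt(mean(ps > 0.05), 0.75)  # not systematically anticonservative
  expect_gt(min(ps), 0)
})

test_that("Weir-Cockerham estimates hit the limit cases", {
  # two populations fixed for different alleles -> F_ST = 1
  genos <- c(replicate(10, c(100L, 100L, 50L, 50L), simplify = FALSE),
             replicate(10, c(120L, 120L, 60L, 60L), simplify = FALSE))
  tab <- make_table(genos, site = rep(c("P1", "P2"), each = 10))
  fs <- weir_cockerham(tab, "site")
  expect_equal(unname(fs$overall["F_ST"]), 1)

  # a single panmictic population split arbitrarily -> F_ST near 0
  set.seed(5)
  genos2 <- replicate(120, {
    g1 <- sort(sample(c(100L, 102L, 104L, 106L), 2L, replace = TRUE))
    g2 <- sort(sample(c(50L, 52L, 54L), 2L, replace = TRUE))
    c(g1, g2)
  }, simplify = FALSE)
  tab2 <- make_table(genos2, site = rep(c("A", "B", "C"), length.out = 120))
  fs2 <- weir_cockerham(tab2, "site")
  expect_lt(abs(fs2$overall["F_ST"]), 0.02)

  expect_error(weir_cockerham(make_table(list(c(1L, 2L)), site = "X"), "site"),
               "2 populations")
})

test_that("Weir-Cockerham variance components match the transliterated oracle", {
  # biallelic toy small enough to hand-derive: 2 pops, counts fixed
  # P1: 4x AA, 4x AB, 2x BB ; P2: 1x AA, 3x AB, 6x BB
  gP1 <- c(replicate(4, c(100L, 100L), simplify = FALSE),
           replicate(4, c(100L, 102L), simplify = FALSE),
           replicate(2, c(102L, 102L), simplify = FALSE))
  gP2 <- c(replicate(1, c(100L, 100L), simplify = FALSE),
           replicate(3, c(100L, 102L), simplify = FALSE),
           replicate(6, c(102L, 102L), simplify = FALSE))
  genos <- lapply(c(gP1, gP2), function(g) c(g, 10L, 12L))
  tab <- make_table(genos, site = rep(c("P1", "P2"), each = 10))

  # oracle per allele from the population summaries
  n_i <- c(10, 10)
  pA_i <- c((2 * 4 + 4) / 20, (2 * 1 + 3) / 20)
  hA_i <- c(4 / 10, 3 / 10)
  oA <- wc_oracle_components(n_i, pA_i, hA_i)
  oB <- wc_oracle_components(n_i, 1 - pA_i, hA_i)
  fst_oracle <- (oA["a"] + oB["a"]) / sum(oA + oB)
  fis_oracle <- 1 - (oA["c"] + oB["c"]) / (oA["b"] + oB["b"] + oA["c"] + oB["c"])

  fs <- weir_cockerham(tab, "site")
  row <- fs$per_locus[fs$per_locus$locus == "loc01", ]
  expect_equal(row$F_ST, unname(fst_oracle), tolerance = 1e-12)
  expect_equal(row$F_IS, unname(fis_oracle), tolerance = 1e-12)
})

test_that("index of association equals first-principles enumeration on toys", {
  # 3 samples, 2 loci
  genos <- list(c(100L, 102L, 50L, 52L),
                c(100L, 100L, 50L, 50L),
                c(102L, 104L, 54L, 56L))
  tab <- make_table(genos)
  oracle <- ia_oracle(tab)
  res <- index_of_association(tab, n_perm = 10L, seed = 1L)
  expect_equal(res$I_A, oracle$I_A, tolerance = 1e-12)
  expect_equal(res$rbarD, oracle$rbarD, tolerance = 1e-12)
  expect_equal(res$V_O, oracle$V_O, tolerance = 1e-12)
  expect_equal(res$V_E, oracle$V_E, tolerance = 1e-12)

  # and on random complete tables
  for (seed in 1:5) {
    tabr <- random_table(n = 7L, L = 3L, n_alleles = 3L, seed = seed)
    o <- ia_oracle(tabr)
    r <- index_of_association(tabr, n_perm = 5L, seed = seed)
    expect_equal(r$I_A, o$I_A, tolerance = 1e-10)
  }
})

test_that("index of association is invariant to sample order and allele relabeling", {
  tab <- random_table(n = 8L, L = 4L, n_alleles = 3L, seed = 17L)
  r1 <- index_of_association(tab, n_perm = 5L, seed = 1L)
  perm <- c(3L, 1L, 8L, 5L, 2L, 7L, 4L, 6L)
  r2 <- index_of_association(subset_samples(tab, perm), n_perm = 5L, seed = 1L)
  expect_equal(r1$I_A, r2$I_A, tolerance = 1e-12)

  # relabel alleles within each locus (order-preserving shift)
  tab3 <- tab
  tab3$alleles <- tab3$alleles + 1000L
  tab3 <- genotype_table(tab3$samples, tab3$alleles)
  r3 <- index_of_association(tab3, n_perm = 5L, seed = 1L)
  expect_equal(r1$I_A, r3$I_A, tolerance = 1e-12)
})

test_that("clonal duplication inflates the index of association", {
  # exact clones force inter-locus correlation -> large I_A, small p
  set.seed(30)
  founders <- replicate(12, unlist(lapply(1:6, function(j)
    sort(sample(100L + 2L * (1:6), 2L, replace = TRUE)))), simplify = FALSE)
  clones <- rep(founders, times = c(4, 4, 3, 3, 2, 2, rep(1, 6)))
  tab <- make_table(clones)
  res <- index_of_association(tab, n_perm = 99L, seed = 2L)
  expect_gt(res$I_A, 0.5)
  expect_lte(res$p_value, 0.01)

  expect_error(index_of_association(make_table(list(c(1L, 1L, 2L, 2L),
                                                    c(1L, 1L, 2L, 2L),
                                                    c(1L, 1L, 2L, 2L))),
                                    n_perm = 5L, seed = 1L),
               "no variance")
})
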
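# Synthetic krummholz stand generator.  Emulates the processes the
# analysis assumes: Hardy-Weinberg founder genotypes at multiallelic
# microsatellite loci, clonal ramets spread by lateral growth (distance =
# separation age x growth rate), stepwise somatic mutations accumulating
# per metre of spread, rare long-distance transport of a ramet, missing
# data, and within-individual replicate samples.  A truth record stores
# every individual's genet lineage, separation age and mutation count so
# recovery can be scored exactly.

#' Simulation configuration
#'
#' Defaults emulate a sparse treeline larch stand: ~124 founder genets on
#' ~1.8 km^2, 16 microsatellite loci with 8-36 alleles each, a Poisson
#' number of clonal ramets per founder placed at distance
#' separation-age x 1.74 cm/yr with separation ages uniform on 0-2500 yr,
#' stepwise (+/- 1 repeat = 2 bp) somatic mutations per allele copy per
#' metre of lateral spread, ~1 % of ramets displaced ~1 km by transport,
#' and ~3.6 % missing genotypes per locus.
#'
#' @param n_founders founder genets (default 124)
#' @param n_loci loci (default 16)
#' @param alleles_per_locus range of allele counts per locus (default
#'   c(8, 36))
#' @param allele_freq_concentration Dirichlet concentration of allele
#'   frequencies; larger = more even (default 1)
#' @param clonal_rate Poisson mean of ramets per founder (default 0.57)
#' @param spread_rate_cm_yr lateral growth rate (default 1.74)
#' @param separation_age_range_yr uniform range of clonal separation ages
#'   (default c(0, 2500), the regional cooling horizon)
#' @param somatic_mutation_per_meter probability an allele copy mutates
#'   per metre of clonal spread (default 3e-4, at which roughly a fifth of
#'   clonal separations carry at least one mutation, matching the rarity
#'   of observed somatic variants)
#' @param mutation_step_bp size of one stepwise mutation (default 2,
#'   dinucleotide repeat)
#' @param missing_rate per-locus probability a genotype is missing
#'   (default 0.036)
#' @param transport_prob probability a ramet is displaced by transport
#'   instead of lateral growth (default 0.01)
#' @param transport_dist_m displacement distance of transported ramets
#'   (default 1000)
#' @param area_extent_m side of the square landscape (default 1350,
#'   ~1.8 km^2)
#' @param n_replicate_individuals individuals receiving a second
#'   within-plant sample (default 20)
#' @param replicate_spread_m within-plant distance of the second sample
#'   (default 3)
#' @param ibd_strength 0..1; >0 blends two regional allele pools along
#'   the east-west axis, creating isolation by distance among founders
#'   (default 0)
#' @param n_offspring sexually produced (Mendelian) extra individuals
#'   from random founder pairs (default 0; founders are already a
#'   random-mating draw)
#' @param branch_rate_cv lognormal coefficient of variation of per-branch
#'   growth rates around `spread_rate_cm_yr` (default 0.9, matching the
#'   wide observed spread)
#' @param seed RNG seed
#' @return list of class `simulation_config`
#' @export
simulation_config <- function(n_founders = 124L,
                              n_loci = 16L,
                              alleles_per_locus = c(8L, 36L),
                              allele_freq_concentration = 1,
                              clonal_rate = 0.57,
                              spread_rate_cm_yr = 1.74,
                              separation_age_range_yr = c(0, 2500),
                              somatic_mutation_per_meter = 3e-4,
                              mutation_step_bp = 2L,
                              missing_rate = 0.036,
                              transport_prob = 0.01,
                              transport_dist_m = 1000,
                              area_extent_m = 1350,
                              n_replicate_individuals = 20L,
                              replicate_spread_m = 3,
                              ibd_strength = 0,
                              n_offspring = 0L,
                              branch_rate_cv = 0.9,
                              seed = 1L) {
  cfg <- list(n_founders = as.integer(n_founders), n_loci = as.integer(n_loci),
              alleles_per_locus = as.integer(alleles_per_locus),
              allele_freq_concentration = allele_freq_concentration,
              clonal_rate = clonal_rate, spread_rate_cm_yr = spread_rate_cm_yr,
              separation_age_range_yr = separation_age_range_yr,
              somatic_mutation_per_meter = somatic_mutation_per_meter,
              mutation_step_bp = as.integer(mutation_step_bp),
              missing_rate = missing_rate,
              transport_prob = transport_prob,
              transport_dist_m = transport_dist_m,
              area_extent_m = area_extent_m,
              n_replicate_individuals = as.integer(n_replicate_individuals),
              replicate_spread_m = replicate_spread_m,
              ibd_strength = ibd_strength,
              n_offspring = as.integer(n_offspring),
              branch_rate_cv = branch_rate_cv,
              seed = as.integer(seed))
  probs <- c("somatic_mutation_per_meter", "missing_rate", "transport_prob",
             "ibd_strength")
  for (p in probs) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must lie in [0, 1]")
  }
  if (cfg$n_founders < 1L) stop("need at least 1 founder")
  if (cfg$n_loci < 2L) stop("need at least 2 loci")
  if (cfg$spread_rate_cm_yr <= 0) stop("spread rate must be positive")
  class(cfg) <- "simulation_config"
  cfg
}

ORIGIN_LAT <- 72.549
ORIGIN_LON <- 105.745
M_PER_DEG_LAT <- pi * EARTH_RADIUS_M / 180

xy_to_lonlat <- function(x_m, y_m) {
  lat <- ORIGIN_LAT + y_m / M_PER_DEG_LAT
  lon <- ORIGIN_LON + x_m / (M_PER_DEG_LAT * cos(ORIGIN_LAT * pi / 180))
  cbind(lon = lon, lat = lat)
}

rdirichlet1 <- function(k, conc) {
  g <- stats::rgamma(k, shape = conc, rate = 1)
  if (sum(g) == 0) g <- rep(1, k)
  g / sum(g)
}

# stepwise mutations on one diploid genotype row (2L alleles); n metres of
# spread, per-copy per-metre probability mu, step +/- step_bp
mutate_genotype <- function(geno, dist_m, mu, step_bp) {
  if (dist_m <= 0 || mu <= 0) return(list(geno = geno, n_mut = 0L))
  n_events <- stats::rpois(length(geno), lambda = mu * dist_m)
  tot <- 0L
  for (i in seq_along(geno)) {
    if (n_events[i] > 0L && !is.na(geno[i])) {
      steps <- sum(sample(c(-1L, 1L), n_events[i], replace = TRUE))
      geno[i] <- geno[i] + step_bp * steps
      tot <- tot + n_events[i]
    }
  }
  list(geno = geno, n_mut = tot)
}

site_label <- function(x_m, y_m, extent) {
  # two dense subsites (discs) inside the wider region
  cA <- c(0.30, 0.30) * extent; cB <- c(0.70, 0.60) * extent
  rad <- 0.12 * extent
  inA <- sqrt((x_m - cA[1L])^2 + (y_m - cA[2L])^2) <= rad
  inB <- sqrt((x_m - cB[1L])^2 + (y_m - cB[2L])^2) <= rad
  ifelse(inA, "SITE-A", ifelse(inB, "SITE-B", "REGION"))
}

#' Simulate a clonally structured stand
#'
#' Draws founder genotypes in Hardy-Weinberg proportions from per-locus
#' Dirichlet allele frequencies, spawns Poisson-many clonal ramets per
#' founder at distance separation-age x growth-rate in a uniform random
#' direction, accumulates stepwise somatic mutations per metre of spread,
#' occasionally displaces a ramet ~1 km (transport; the genotype travels
#' unchanged), injects missing data, and adds within-individual replicate
#' samples.  The truth record stores each individual's genet, parent,
#' separation age, spread distance, mutation count and transport flag.
#'
#' @param cfg [simulation_config()]
#' @return list with `table` (genotype_table), `truth` (data.frame, one
#'   row per individual), `replicate_truth` (per replicate sample),
#'   `allele_freqs` (per-locus frequency vectors), `config`
#' @export
simulate_population <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  L <- cfg$n_loci
  extent <- cfg$area_extent_m

  k_per_locus <- sample(seq(cfg$alleles_per_locus[1L], cfg$alleles_per_locus[2L]),
                        L, replace = TRUE)
  locus_names <- sprintf("loc%02d", seq_len(L))
  base_size <- sample(seq(100L, 260L, by = 2L), L, replace = TRUE)
  allele_sizes <- lapply(seq_len(L), function(j) {
    base_size[j] + cfg$mutation_step_bp * (0:(k_per_locus[j] - 1L))
  })
  freqA <- lapply(seq_len(L), function(j)
    rdirichlet1(k_per_locus[j], cfg$allele_freq_concentration))
  freqB <- if (cfg$ibd_strength > 0) {
    lapply(seq_len(L), function(j)
      rdirichlet1(k_per_locus[j], cfg$allele_freq_concentration))
  } else freqA

  draw_genotype <- function(x_m) {
    w <- cfg$ibd_strength * x_m / extent
    unlist(lapply(seq_len(L), function(j) {
      p <- (1 - w) * freqA[[j]] + w * freqB[[j]]
      sort(sample(allele_sizes[[j]], 2L, replace = TRUE, prob = p))
    }))
  }

  nF <- cfg$n_founders
  fx <- stats::runif(nF, 0, extent); fy <- stats::runif(nF, 0, extent)
  genos <- t(vapply(seq_len(nF), function(i) draw_genotype(fx[i]),
                    numeric(2L * L)))

  truth <- data.frame(
    individual_id = sprintf("L%03d", seq_len(nF)),
    genet_id = sprintf("g%03d", seq_len(nF)),
    parent_id = NA_character_, founder = TRUE,
    separation_age_yr = 0, spread_dist_m = 0,
    n_mutations = 0L, transported = FALSE,
    x_m = fx, y_m = fy, stringsAsFactors = FALSE
  )

  # sexual offspring by Mendelian sampling from two random parents
  if (cfg$n_offspring > 0L) {
    for (o in seq_len(cfg$n_offspring)) {
      pid <- sample.int(nF, 2L)
      child <- unlist(lapply(seq_len(L), function(j) {
        cols <- (2L * j - 1L):(2L * j)
        sort(c(sample(genos[pid[1L], cols], 1L),
               sample(genos[pid[2L], cols], 1L)))
      }))
      ox <- min(max((fx[pid[1L]] + fx[pid[2L]]) / 2 + stats::rnorm(1, 0, extent / 20), 0), extent)
      oy <- min(max((fy[pid[1L]] + fy[pid[2L]]) / 2 + stats::rnorm(1, 0, extent / 20), 0), extent)
      genos <- rbind(genos, child)
      truth <- rbind(truth, data.frame(
        individual_id = sprintf("L%03d", nrow(truth) + 1L),
        genet_id = sprintf("g%03d", nrow(truth) + 1L),
        parent_id = truth$individual_id[pid[1L]], founder = TRUE,
        separation_age_yr = 0, spread_dist_m = 0,
        n_mutations = 0L, transported = FALSE,
        x_m = ox, y_m = oy, stringsAsFactors = FALSE))
    }
  }

  # clonal ramets
  n_parents <- nrow(truth)
  for (i in seq_len(n_parents)) {
    n_ram <- stats::rpois(1L, cfg$clonal_rate)
    if (n_ram == 0L) next
    for (rme in seq_len(n_ram)) {
      age <- stats::runif(1L, cfg$separation_age_range_yr[1L],
                          cfg$separation_age_range_yr[2L])
      transported <- stats::runif(1L) < cfg$transport_prob
      growth_dist <- age * cfg$spread_rate_cm_yr / 100
      dist_m <- if (transported) cfg$transport_dist_m else growth_dist
      theta <- stats::runif(1L, 0, 2 * pi)
      rx <- truth$x_m[i] + dist_m * cos(theta)
      ry <- truth$y_m[i] + dist_m * sin(theta)
      mut_dist <- if (transported) 0 else growth_dist  # transport moves the genotype unchanged
      mut <- mutate_genotype(genos[i, ], mut_dist,
                             cfg$somatic_mutation_per_meter, cfg$mutation_step_bp)
      genos <- rbind(genos, mut$geno)
      truth <- rbind(truth, data.frame(
        individual_id = sprintf("L%03d", nrow(truth) + 1L),
        genet_id = truth$genet_id[i],
        parent_id = truth$individual_id[i], founder = FALSE,
        separation_age_yr = age, spread_dist_m = dist_m,
        n_mutations = mut$n_mut, transported = transported,
        x_m = rx, y_m = ry, stringsAsFactors = FALSE))
    }
  }
  rownames(genos) <- truth$individual_id

  n_ind <- nrow(truth)
  samples <- data.frame(
    sample_id = paste0(truth$individual_id, "-a"),
    individual_id = truth$individual_id,
    site = site_label(truth$x_m, truth$y_m, extent),
    stringsAsFactors = FALSE
  )
  ll <- xy_to_lonlat(truth$x_m, truth$y_m)
  samples$lat <- ll[, "lat"]; samples$lon <- ll[, "lon"]
  amat <- genos

  # within-individual replicate samples with their own short spread
  n_rep <- min(cfg$n_replicate_individuals, n_ind)
  rep_truth <- NULL
  if (n_rep > 0L) {
    rep_ids <- sample(truth$individual_id, n_rep)
    for (id in rep_ids) {
      i <- match(id, truth$individual_id)
      d <- stats::runif(1L, 0, cfg$replicate_spread_m)
      theta <- stats::runif(1L, 0, 2 * pi)
      ll2 <- xy_to_lonlat(truth$x_m[i] + d * cos(theta),
                          truth$y_m[i] + d * sin(theta))
      mut <- mutate_genotype(genos[i, ], d, cfg$somatic_mutation_per_meter,
                             cfg$mutation_step_bp)
      samples <- rbind(samples, data.frame(
        sample_id = paste0(id, "-b"), individual_id = id,
        site = samples$site[i], lat = ll2[, "lat"], lon = ll2[, "lon"],
        stringsAsFactors = FALSE))
      amat <- rbind(amat, mut$geno)
      rep_truth <- rbind(rep_truth, data.frame(
        individual_id = id, sample_id = paste0(id, "-b"),
        within_dist_m = d, n_mutations = mut$n_mut, stringsAsFactors = FALSE))
    }
  }

  # per-locus missing data (both alleles of a locus at once)
  if (cfg$missing_rate > 0) {
    for (j in seq_len(L)) {
      drop <- stats::runif(nrow(amat)) < cfg$missing_rate
      amat[drop, (2L * j - 1L):(2L * j)] <- NA_integer_
    }
  }
  colnames(amat) <- as.vector(rbind(paste0(locus_names, ".a1"),
                                    paste0(locus_names, ".a2")))

  table <- genotype_table(samples, amat,
                          provenance = sprintf("simulated stand (seed %d)", cfg$seed))
  genet_sizes <- table(truth$genet_id)
  list(table = table, truth = truth, replicate_truth = rep_truth,
       allele_freqs = freqA,
       true_clonal_fraction = mean(genet_sizes[truth$genet_id] >= 2L),
       config = cfg)
}

#' Simulate branch-section ring counts
#'
#' Grows branches at the configured lateral rate perturbed by lognormal
#' per-branch noise (mean preserved), cuts them into 10-cm sections and
#' ages a subset per branch: the base (oldest) section, the middle one,
#' and for larger `sections_per_branch` additional quarter points — the
#' field sampling scheme.  Ring counts are the rounded true section ages.
#'
#' @param cfg [simulation_config()] (uses `spread_rate_cm_yr`,
#'   `branch_rate_cv`, `seed`)
#' @param n_branches number of branches (default 16)
#' @param sections_per_branch aged sections per branch, 2-4 (default 3);
#'   1 produces series unusable for rates (precondition testing)
#' @param branch_age_range_yr branch ages drawn uniformly (default
#'   c(15, 45))
#' @return list with `sections` (branch_sections) and `truth` (per-branch
#'   true rate, age and length)
#' @export
simulate_branch_sections <- function(cfg = simulation_config(), n_branches = 16L,
                                     sections_per_branch = 3L,
                                     branch_age_range_yr = c(15, 45)) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed + 1000L)
  sdlog <- sqrt(log(1 + cfg$branch_rate_cv^2))
  rows <- NULL; tr <- NULL
  inds <- sprintf("B%02d", rep(seq_len(max(1L, ceiling(n_branches / 4L))),
                               each = 4L, length.out = n_branches))
  for (b in seq_len(n_branches)) {
    rate_b <- cfg$spread_rate_cm_yr * stats::rlnorm(1L, meanlog = -sdlog^2 / 2,
                                                    sdlog = sdlog)
    age_b <- stats::runif(1L, branch_age_range_yr[1L], branch_age_range_yr[2L])
    len <- rate_b * age_b
    cuts <- seq(0, len, by = 10)
    picks <- unique(switch(min(sections_per_branch, 4L),
                           cuts[1L],
                           c(cuts[1L], cuts[ceiling(length(cuts) / 2)]),
                           c(cuts[1L], cuts[ceiling(length(cuts) / 2)],
                             cuts[length(cuts)]),
                           cuts[unique(ceiling(c(1, length(cuts) / 3,
                                                 2 * length(cuts) / 3,
                                                 length(cuts))))]))
    rings <- as.integer(round((len - picks) / rate_b))
    keep <- !duplicated(picks)
    branch_id <- sprintf("H%d", ((b - 1L) %% 4L) + 1L)
    rows <- rbind(rows, data.frame(
      individual_id = inds[b], branch_id = branch_id,
      position_cm = picks[keep], ring_count_yr = rings[keep],
      stringsAsFactors = FALSE))
    tr <- rbind(tr, data.frame(
      individual_id = inds[b], branch_id = branch_id,
      rate_cm_yr = rate_b, age_yr = age_b, length_cm = len,
      stringsAsFactors = FALSE))
  }
  list(sections = branch_sections(rows), truth = tr)
}
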
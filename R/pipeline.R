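# End-to-end orchestration: simulate or load data, detect clones, compute
# population-genetic statistics, estimate the lateral growth rate, date
# clonal separations and fit the distance-decay regressions, collecting
# everything into one structured, reproducible report.

#' Pipeline configuration
#'
#' All knobs of the analysis in one list.  Either supply input paths
#' (`genotypes`, `sections`) or leave them NULL to run on data simulated
#' from `sim`.  Every stochastic stage derives its seed from `seed`, so a
#' rerun with an identical configuration reproduces the report byte for
#' byte.
#'
#' @param genotypes path to a genotype table, or NULL to simulate
#' @param sections path to a branch-section table, or NULL to simulate
#' @param sim [simulation_config()] used when inputs are NULL
#' @param somatic_threshold max allele differences still clonal (default 3)
#' @param min_shared_loci min loci typed in both samples of a pair
#'   (default 12)
#' @param n_perm permutations for HWE and index-of-association tests
#'   (default 1000)
#' @param accumulation_perm locus subsets per k in the genotype
#'   accumulation curve (default 100)
#' @param outlier_dist_m clone-pair distance flagged as transport
#'   (default 100)
#' @param bin_width_yr age histogram bin width (default 200)
#' @param weighting growth-rate pooling, `"per_segment"` or
#'   `"per_branch"`
#' @param grouping metadata column naming populations for F-statistics
#'   (default `"site"`)
#' @param seed master seed
#' @param out output directory for written artifacts, or NULL
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(genotypes = NULL, sections = NULL,
                            sim = simulation_config(),
                            somatic_threshold = 3L, min_shared_loci = 12L,
                            n_perm = 1000L, accumulation_perm = 100L,
                            outlier_dist_m = 100, bin_width_yr = 200,
                            weighting = "per_segment", grouping = "site",
                            seed = 1L, out = NULL) {
  structure(list(genotypes = genotypes, sections = sections, sim = sim,
                 somatic_threshold = as.integer(somatic_threshold),
                 min_shared_loci = as.integer(min_shared_loci),
                 n_perm = as.integer(n_perm),
                 accumulation_perm = as.integer(accumulation_perm),
                 outlier_dist_m = outlier_dist_m,
                 bin_width_yr = bin_width_yr,
                 weighting = weighting, grouping = grouping,
                 seed = as.integer(seed), out = out),
            class = "pipeline_config")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full clonal-structure pipeline
#'
#' simulate/load -> pairwise distances -> clonal network -> clonality
#' summary -> censoring -> locus summaries (clone-and-mutation-censored)
#' -> F-statistics -> index of association at three censoring levels ->
#' genotype accumulation curve -> growth rate -> clone ages ->
#' distance-decay regressions.  Any stage failure aborts with the stage
#' name; stages whose preconditions the data cannot meet (e.g. too few
#' mutated groups for the somatic decay) are recorded as NULL with a
#' note instead.
#'
#' @param cfg [pipeline_config()]
#' @return list of class `genets_report` with elements `data`, `network`,
#'   `clonality`, `mlg`, `locus_summary`, `fstats`, `ia`, `accumulation`,
#'   `growth`, `ages`, `decay`, `notes`, `config`
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  notes <- character(0)

  if (is.null(cfg$genotypes)) {
    sim_cfg <- cfg$sim; sim_cfg$seed <- cfg$seed
    sim <- run_stage("simulate", simulate_population(sim_cfg))
    table <- sim$table
  } else {
    sim <- NULL
    table <- run_stage("read_genotypes", read_genotype_table(cfg$genotypes))
  }
  if (is.null(cfg$sections)) {
    sim_cfg2 <- cfg$sim; sim_cfg2$seed <- cfg$seed
    bs <- run_stage("simulate_sections", simulate_branch_sections(sim_cfg2))
    sections <- bs$sections
  } else {
    bs <- NULL
    sections <- run_stage("read_sections", read_branch_sections(cfg$sections))
  }

  dists <- run_stage("distances", {
    d <- pairwise_allele_distance(table, min_shared_loci = cfg$min_shared_loci)
    attach_geo_distances(d, table)
  })
  network <- run_stage("network",
                       build_clonal_network(dists, table,
                                            somatic_threshold = cfg$somatic_threshold))
  clonality <- run_stage("clonality", clonality_summary(network))
  mlg <- run_stage("mlg", list(
    identical = collapse_mlg(dists, table, "identical")$n_mlg,
    tolerant = collapse_mlg(dists, table, "tolerant",
                            somatic_threshold = cfg$somatic_threshold)$n_mlg))

  censored <- run_stage("censor", list(
    none = censor(table, dists, "none"),
    clones = censor(table, dists, "clones"),
    clones_and_mutations = censor(table, dists, "clones_and_mutations",
                                  somatic_threshold = cfg$somatic_threshold)))

  locus_summary <- run_stage("locus_summaries",
                             locus_summaries(censored$clones_and_mutations,
                                             n_perm = cfg$n_perm,
                                             seed = cfg$seed + 100L))

  fstats <- NULL
  pops <- censored$clones_and_mutations$samples[[cfg$grouping]]
  if (length(unique(pops)) >= 2L) {
    fstats <- run_stage("fstats",
                        weir_cockerham(censored$clones_and_mutations,
                                       grouping = cfg$grouping))
  } else {
    notes <- c(notes, "fstats skipped: fewer than 2 populations")
  }

  ia <- run_stage("index_of_association", list(
    all = index_of_association(censored$none, n_perm = cfg$n_perm,
                               seed = cfg$seed + 200L, dataset_level = "all"),
    clone_censored = index_of_association(censored$clones, n_perm = cfg$n_perm,
                                          seed = cfg$seed + 201L,
                                          dataset_level = "clone-censored"),
    clone_mutation_censored = index_of_association(
      censored$clones_and_mutations, n_perm = cfg$n_perm,
      seed = cfg$seed + 202L, dataset_level = "clone+mutation-censored")))

  accumulation <- run_stage("accumulation",
                            genotype_accumulation_curve(
                              censored$clones_and_mutations,
                              n_perm = cfg$accumulation_perm,
                              seed = cfg$seed + 300L))

  growth <- run_stage("growth", pooled_growth_rate(sections, cfg$weighting))
  ages <- run_stage("ages", clone_pair_ages(network, table, growth,
                                            outlier_dist_m = cfg$outlier_dist_m,
                                            bin_width_yr = cfg$bin_width_yr))

  sexual <- tryCatch({
    cen_tab <- censored$clones_and_mutations
    d <- pairwise_allele_distance(cen_tab, min_shared_loci = cfg$min_shared_loci)
    sexual_distance_decay(attach_geo_distances(d, cen_tab),
                          somatic_threshold = cfg$somatic_threshold)
  }, error = function(e) {
    notes <<- c(notes, paste("sexual decay skipped:", conditionMessage(e)))
    NULL
  })
  somatic <- tryCatch(somatic_mutation_decay(network), error = function(e) {
    notes <<- c(notes, paste("somatic decay skipped:", conditionMessage(e)))
    NULL
  })

  report <- structure(list(
    data = list(table = table, sections = sections, sim = sim, sim_sections = bs),
    network = network, clonality = clonality, mlg = mlg,
    locus_summary = locus_summary, fstats = fstats, ia = ia,
    accumulation = accumulation, growth = growth, ages = ages,
    decay = list(sexual = sexual, somatic = somatic),
    notes = notes, config = cfg), class = "genets_report")

  if (!is.null(cfg$out)) {
    write_report(report, cfg$out)
  }
  report
}

#' Flatten a report into named scalar quantities
#'
#' The headline numbers of a run (counts, proportions in percent, rates,
#' distances, test statistics) as a flat named list — the structured
#' summary written to `report.json`.
#' @param report genets_report
#' @return named list of scalars
#' @export
report_summary <- function(report) {
  cl <- report$clonality
  ds <- report$ages$distance_summary
  out <- list(
    n_samples = n_samples(report$data$table),
    n_individuals = cl$n_individuals,
    n_mlg_identical = report$mlg$identical,
    n_mlg_tolerant = report$mlg$tolerant,
    n_singletons = cl$n_singletons,
    n_groups = cl$n_groups,
    clonal_fraction_pct = 100 * cl$clonal_fraction,
    clonal_excess_pct = 100 * cl$clonal_excess,
    mean_H_O = mean(report$locus_summary$H_O, na.rm = TRUE),
    mean_H_E = mean(report$locus_summary$H_E, na.rm = TRUE),
    mean_evenness = mean(report$locus_summary$evenness, na.rm = TRUE),
    F_ST = if (!is.null(report$fstats)) unname(report$fstats$overall["F_ST"]) else NA_real_,
    F_IS = if (!is.null(report$fstats)) unname(report$fstats$overall["F_IS"]) else NA_real_,
    ia_p_all = report$ia$all$p_value,
    ia_p_clone_censored = report$ia$clone_censored$p_value,
    ia_p_clone_mutation_censored = report$ia$clone_mutation_censored$p_value,
    k_loci_sufficient = report$accumulation$k_sufficient,
    growth_rate_cm_yr = report$growth$mean_rate,
    growth_rate_sd = report$growth$sd_rate,
    n_clone_pairs = ds$n_pairs,
    median_pair_dist_m = ds$median_m,
    mean_pair_dist_m = ds$mean_m,
    max_pair_dist_m = ds$max_m,
    n_distance_outliers = nrow(ds$outliers),
    age_95pct_yr = unname(report$ages$age_quantiles["95%"]),
    sexual_decay_slope = if (!is.null(report$decay$sexual)) report$decay$sexual$slope else NA_real_,
    sexual_decay_p = if (!is.null(report$decay$sexual)) report$decay$sexual$p_value else NA_real_,
    somatic_decay_slope = if (!is.null(report$decay$somatic)) report$decay$somatic$slope else NA_real_,
    somatic_decay_p = if (!is.null(report$decay$somatic)) report$decay$somatic$p_value else NA_real_
  )
  out
}

#' Serialize the report summary to a JSON string
#' @param report genets_report
#' @return JSON character scalar
#' @export
report_json <- function(report) {
  as.character(jsonlite::toJSON(report_summary(report), auto_unbox = TRUE,
                                digits = NA, na = "null", pretty = TRUE))
}

#' Write all pipeline artifacts to a directory
#'
#' `report.json` (the [report_summary()]), the clonal network edge list,
#' the locus summary, per-locus F-statistics, clone-pair ages, the age
#' histogram, the accumulation curve, and run metadata (config, seed,
#' package version).
#' @param report genets_report
#' @param dir output directory
#' @return written paths, invisibly
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p_json <- file.path(dir, "report.json")
  writeLines(report_json(report), p_json)
  cfg <- report$config
  meta <- list(
    package = "genets",
    version = as.character(utils::packageVersion("genets")),
    seed = cfg$seed,
    somatic_threshold = cfg$somatic_threshold,
    min_shared_loci = cfg$min_shared_loci,
    n_perm = cfg$n_perm,
    outlier_dist_m = cfg$outlier_dist_m,
    weighting = cfg$weighting
  )
  written <- write_outputs(list(
    network = report$network,
    locus_summary = report$locus_summary,
    fstats_per_locus = if (!is.null(report$fstats)) report$fstats$per_locus else NULL,
    clone_pairs = report$ages$pairs,
    age_histogram = report$ages$age_histogram,
    accumulation_curve = report$accumulation$curve,
    metadata = meta
  ), dir)
  invisible(c(p_json, written))
}

#' @export
print.genets_report <- function(x, ...) {
  cat("== clonal-structure pipeline report ==\n")
  print(x$clonality)
  cat(sprintf("MLGs: %d identical-only, %d mutation-tolerant\n",
              x$mlg$identical, x$mlg$tolerant))
  print(x$growth)
  print(x$ages)
  for (lvl in names(x$ia)) print(x$ia[[lvl]])
  if (!is.null(x$fstats)) print(x$fstats)
  if (length(x$notes) > 0L) cat("notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}
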
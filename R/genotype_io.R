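# Reading, validating and writing the tabular genotype and branch-section
# formats.  A genotype table holds one row per needle sample: identifiers,
# site label, WGS84 coordinates, and two integer allele lengths (bp) per
# locus.  Missing data are accepted as empty cells, "NA" or 0 on input and
# written back as "NA".

MISSING_TOKENS <- c("", "NA", "0")

#' Construct a genotype table
#'
#' The central container of the package: per-sample metadata plus a diploid
#' allele-length matrix.  Within each locus the two alleles are stored in
#' nondecreasing order so that genotype comparison is order-insensitive,
#' and a locus is either fully typed (both alleles) or fully missing.
#'
#' @param samples data.frame with columns `sample_id`, `individual_id`,
#'   `site`, `lat`, `lon` and optionally `height_m`.  Several samples may
#'   share one `individual_id` (within-individual replicates).
#' @param alleles integer matrix, one row per sample, columns
#'   `<locus>.a1`, `<locus>.a2` for each locus; `NA` marks missing.
#' @param loci optional character vector of locus names (defaults to the
#'   names implied by `colnames(alleles)`), or a data.frame panel with a
#'   `name` column and optional `repeat_motif`, `size_min`, `size_max`.
#' @param provenance free-text origin note carried through outputs.
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(samples, alleles, loci = NULL, provenance = "") {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  req <- c("sample_id", "individual_id", "site", "lat", "lon")
  miss <- setdiff(req, names(samples))
  if (length(miss) > 0L) {
    stop("genotype table metadata lacks column(s): ", paste(miss, collapse = ", "))
  }
  samples$sample_id <- as.character(samples$sample_id)
  samples$individual_id <- as.character(samples$individual_id)
  samples$site <- as.character(samples$site)
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicate sample_id: ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]), collapse = ", "))
  }
  ok_lat <- is.na(samples$lat) | (samples$lat >= -90 & samples$lat <= 90)
  ok_lon <- is.na(samples$lon) | (samples$lon >= -180 & samples$lon <= 180)
  if (!all(ok_lat)) stop("latitude out of [-90, 90] for sample ", samples$sample_id[!ok_lat][1L])
  if (!all(ok_lon)) stop("longitude out of [-180, 180] for sample ", samples$sample_id[!ok_lon][1L])

  alleles <- as.matrix(alleles)
  if (nrow(alleles) != nrow(samples)) stop("allele matrix and sample metadata differ in row count")
  if (ncol(alleles) %% 2L != 0L || ncol(alleles) == 0L) {
    stop("allele matrix needs two columns per locus")
  }
  locus_names <- unique(sub("\\.a[12]$", "", colnames(alleles)))
  if (length(locus_names) * 2L != ncol(alleles)) {
    stop("allele columns must come in <locus>.a1/<locus>.a2 pairs")
  }
  storage.mode(alleles) <- "integer"
  rownames(alleles) <- samples$sample_id

  panel <- normalize_panel(loci, locus_names)

  x <- structure(
    list(samples = samples, alleles = alleles, loci = panel,
         provenance = as.character(provenance)[1L]),
    class = "genotype_table"
  )
  x <- normalize_allele_order(x)
  check_half_missing(x)
  x
}

normalize_panel <- function(loci, locus_names) {
  if (is.null(loci)) {
    return(data.frame(name = locus_names, stringsAsFactors = FALSE))
  }
  if (is.character(loci)) loci <- data.frame(name = loci, stringsAsFactors = FALSE)
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  if (!"name" %in% names(loci)) stop("locus panel needs a 'name' column")
  if (anyDuplicated(loci$name)) stop("locus panel has duplicated names")
  if (all(c("size_min", "size_max") %in% names(loci))) {
    bad <- !is.na(loci$size_min) & !is.na(loci$size_max) & loci$size_min >= loci$size_max
    if (any(bad)) stop("locus panel size range min >= max for ", loci$name[bad][1L])
  }
  extra <- setdiff(locus_names, loci$name)
  if (length(extra) > 0L) {
    warning("loci in data but not in declared panel: ", paste(extra, collapse = ", "))
    loci <- rbind(loci[, "name", drop = FALSE],
                  data.frame(name = extra, stringsAsFactors = FALSE))
  }
  absent <- setdiff(loci$name, locus_names)
  if (length(absent) > 0L) {
    loci <- loci[!loci$name %in% absent, , drop = FALSE]
  }
  # keep data column order
  loci[match(locus_names, loci$name), , drop = FALSE]
}

normalize_allele_order <- function(x) {
  L <- loci_names(x)
  for (loc in L) {
    i1 <- paste0(loc, ".a1"); i2 <- paste0(loc, ".a2")
    a1 <- x$alleles[, i1]; a2 <- x$alleles[, i2]
    swap <- !is.na(a1) & !is.na(a2) & a1 > a2
    if (any(swap)) {
      tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
      x$alleles[, i1] <- a1; x$alleles[, i2] <- a2
    }
  }
  x
}

check_half_missing <- function(x) {
  for (loc in loci_names(x)) {
    a1 <- x$alleles[, paste0(loc, ".a1")]
    a2 <- x$alleles[, paste0(loc, ".a2")]
    half <- xor(is.na(a1), is.na(a2))
    if (any(half)) {
      stop("half-missing genotype at locus ", loc, " for sample ",
           x$samples$sample_id[half][1L],
           " (one allele present, one missing)")
    }
  }
  invisible(x)
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", nrow(x$samples), "samples,",
      length(unique(x$samples$individual_id)), "individuals,",
      length(loci_names(x)), "loci\n")
  mf <- mean(is.na(x$alleles))
  cat(sprintf("  missing allele cells: %.2f%%\n", 100 * mf))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Locus names of a genotype table
#' @param x genotype_table
#' @return character vector
#' @export
loci_names <- function(x) x$loci$name

#' Number of samples in a genotype table
#' @param x genotype_table
#' @return integer
#' @export
n_samples <- function(x) nrow(x$samples)

#' Subset a genotype table by sample
#' @param x genotype_table
#' @param keep logical or index vector over samples
#' @return genotype_table
#' @export
subset_samples <- function(x, keep) {
  genotype_table(x$samples[keep, , drop = FALSE],
                 x$alleles[keep, , drop = FALSE],
                 loci = x$loci, provenance = x$provenance)
}

#' One row per individual
#'
#' Reduces within-individual replicate samples to a single representative:
#' the sample with the fewest missing loci, ties broken lexicographically
#' by `sample_id`.
#' @param x genotype_table
#' @return genotype_table with unique `individual_id`
#' @export
first_sample_per_individual <- function(x) {
  nmiss <- rowSums(is.na(x$alleles)) / 2
  ord <- order(x$samples$individual_id, nmiss, x$samples$sample_id)
  keep_ids <- x$samples$sample_id[ord][!duplicated(x$samples$individual_id[ord])]
  subset_samples(x, x$samples$sample_id %in% keep_ids)
}

autodetect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Read a genotype table from delimited text
#'
#' Expects a UTF-8 comma- or tab-delimited file (autodetected) with a header
#' row naming `sample_id`, `individual_id`, `site`, `lat`, `lon`, optionally
#' `height_m`, followed by `<locus>.a1`/`<locus>.a2` integer allele-length
#' columns.  Missing alleles may be encoded as an empty cell, `"NA"` or `0`;
#' all three are accepted.  Within each locus allele order is normalized to
#' (min, max).  A locus half-missing in a sample (one allele typed, one
#' missing) is rejected with an error naming the sample and locus.
#'
#' @param path file path.
#' @param panel optional declared locus panel (character vector or
#'   data.frame with `name`); loci present in the file but absent from the
#'   panel raise a warning, not an error.
#' @param col_map optional named character vector remapping file column
#'   names to the expected metadata names, e.g.
#'   `c(sample_id = "Sample", lat = "Latitude")`.
#' @return A [genotype_table()].
#' @export
read_genotype_table <- function(path, panel = NULL, col_map = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- autodetect_sep(path)
  raw <- utils::read.table(path, header = TRUE, sep = sep, colClasses = "character",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = NULL, quote = "\"", comment.char = "")
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      j <- match(col_map[[std]], names(raw))
      if (!is.na(j)) names(raw)[j] <- std
    }
  }
  req <- c("sample_id", "individual_id", "site", "lat", "lon")
  miss <- setdiff(req, names(raw))
  if (length(miss) > 0L) {
    stop("genotype file header lacks column(s): ", paste(miss, collapse = ", "))
  }
  allele_cols <- grep("\\.a[12]$", names(raw), value = TRUE)
  if (length(allele_cols) == 0L) stop("genotype file has no <locus>.a1/<locus>.a2 allele columns")
  loc_of <- sub("\\.a[12]$", "", allele_cols)
  for (loc in unique(loc_of)) {
    have <- allele_cols[loc_of == loc]
    if (length(have) != 2L) {
      stop("locus ", loc, " must have exactly columns ", loc, ".a1 and ", loc,
           ".a2; found: ", paste(have, collapse = ", "))
    }
  }

  meta <- raw[, intersect(c(req, "height_m"), names(raw)), drop = FALSE]
  meta$lat <- parse_number_col(meta$lat, "lat")
  meta$lon <- parse_number_col(meta$lon, "lon")
  if ("height_m" %in% names(meta)) meta$height_m <- parse_number_col(meta$height_m, "height_m")

  amat <- matrix(NA_integer_, nrow = nrow(raw), ncol = length(allele_cols),
                 dimnames = list(NULL, allele_cols))
  for (j in allele_cols) {
    v <- trimws(raw[[j]])
    v[v %in% MISSING_TOKENS] <- NA_character_
    bad <- !is.na(v) & !grepl("^-?[0-9]+$", v)
    if (any(bad)) {
      stop("non-integer allele value '", v[bad][1L], "' in column ", j,
           " for sample ", raw$sample_id[bad][1L])
    }
    amat[, j] <- as.integer(v)
  }
  # order columns locus-wise: a1, a2 adjacent
  ord <- order(match(loc_of, unique(loc_of)), allele_cols)
  amat <- amat[, ord, drop = FALSE]

  genotype_table(meta, amat, loci = panel,
                 provenance = paste0("read from ", path))
}

parse_number_col <- function(v, name) {
  v <- trimws(v)
  v[v %in% c("", "NA")] <- NA_character_
  out <- suppressWarnings(as.numeric(v))
  bad <- !is.na(v) & is.na(out)
  if (any(bad)) stop("non-numeric value '", v[bad][1L], "' in column ", name)
  out
}

#' Write a genotype table to delimited text
#'
#' Inverse of [read_genotype_table()]: emits comma-separated text with the
#' canonical header and `"NA"` for missing alleles.
#' @param x genotype_table
#' @param path output file path
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(x, path) {
  out <- cbind(x$samples, as.data.frame(x$alleles, check.names = FALSE))
  utils::write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read branch-section tree-ring series
#'
#' Expects delimited text with columns `individual_id`, `branch_id`,
#' `position_cm` (distance along the branch from its base) and
#' `ring_count_yr`.  Rows are grouped by (individual, branch) and sorted by
#' position; ring counts must be non-increasing toward the branch tip
#' (sections nearer the base are older).  A branch with a single section is
#' accepted but yields no growth-rate segment.
#'
#' @param path file path
#' @param col_map optional named character vector remapping column names.
#' @return A data.frame of class `branch_sections`, sorted by individual,
#'   branch and position.
#' @export
read_branch_sections <- function(path, col_map = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- autodetect_sep(path)
  raw <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "\"", comment.char = "")
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      j <- match(col_map[[std]], names(raw))
      if (!is.na(j)) names(raw)[j] <- std
    }
  }
  branch_sections(raw)
}

#' Construct/validate a branch-section table
#' @param df data.frame with `individual_id`, `branch_id`, `position_cm`,
#'   `ring_count_yr`
#' @return data.frame of class `branch_sections`
#' @export
branch_sections <- function(df) {
  req <- c("individual_id", "branch_id", "position_cm", "ring_count_yr")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0L) stop("branch-section table lacks column(s): ", paste(miss, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$individual_id <- as.character(df$individual_id)
  df$branch_id <- as.character(df$branch_id)
  df$position_cm <- as.numeric(df$position_cm)
  df$ring_count_yr <- as.integer(df$ring_count_yr)
  if (any(is.na(df$position_cm)) || any(df$position_cm < 0)) {
    stop("position_cm must be numeric and >= 0")
  }
  if (any(is.na(df$ring_count_yr)) || any(df$ring_count_yr < 0L)) {
    stop("ring_count_yr must be a non-negative integer (0 only at the growing tip)")
  }
  df <- df[order(df$individual_id, df$branch_id, df$position_cm), , drop = FALSE]
  rownames(df) <- NULL
  key <- paste(df$individual_id, df$branch_id, sep = ":")
  for (k in unique(key)) {
    s <- df[key == k, , drop = FALSE]
    if (anyDuplicated(s$position_cm)) {
      stop("duplicate section position on branch ", k)
    }
    if (is.unsorted(rev(s$ring_count_yr))) {
      stop("ring counts increase toward the tip on branch ", k,
           " (sections nearer the base must be older)")
    }
  }
  class(df) <- c("branch_sections", "data.frame")
  df
}

#' Write branch sections to delimited text
#' @param x branch_sections
#' @param path output file path
#' @return `path`, invisibly.
#' @export
write_branch_sections <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = ",", row.names = FALSE,
                     quote = FALSE, na = "NA")
  invisible(path)
}

#' Split branch sections into per-branch series
#' @param x branch_sections
#' @return named list of data.frames, one per (individual, branch)
#' @export
split_branches <- function(x) {
  split(as.data.frame(x), paste(x$individual_id, x$branch_id, sep = ":"))
}

#' Write pipeline outputs to a directory
#'
#' Writes the clonal network as an edge list (`network_edges.csv`:
#' `sample_a`, `sample_b`, `allele_diff`, `geo_dist_m`; header always
#' present, so an empty network yields a header-only file), summary tables
#' as CSV, and run metadata (config, seed, package version) as JSON.
#'
#' @param results named list; recognised elements are `network`
#'   (a `clonal_network`), data.frames (written as `<name>.csv`), and
#'   `metadata` (a list, written as `run_metadata.json`).
#' @param dir output directory, created if absent.
#' @return character vector of written paths, invisibly.
#' @export
write_outputs <- function(results, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(dir)) stop("cannot create output directory: ", dir)
  }
  written <- character(0)
  for (nm in names(results)) {
    obj <- results[[nm]]
    if (inherits(obj, "clonal_network")) {
      p <- file.path(dir, paste0(nm, "_edges.csv"))
      write_network_edges(obj, p)
      written <- c(written, p)
    } else if (is.data.frame(obj)) {
      p <- file.path(dir, paste0(nm, ".csv"))
      utils::write.table(obj, p, sep = ",", row.names = FALSE, quote = FALSE, na = "NA")
      written <- c(written, p)
    } else if (identical(nm, "metadata")) {
      p <- file.path(dir, "run_metadata.json")
      jsonlite::write_json(obj, p, auto_unbox = TRUE, pretty = TRUE, digits = NA)
      written <- c(written, p)
    }
  }
  invisible(written)
}

write_network_edges <- function(net, path) {
  e <- net$edges
  cols <- c("node_a", "node_b", "allele_diff", "geo_dist_m")
  if (nrow(e) == 0L) {
    e <- data.frame(node_a = character(0), node_b = character(0),
                    allele_diff = integer(0), geo_dist_m = numeric(0))
  }
  if (!"geo_dist_m" %in% names(e)) e$geo_dist_m <- NA_real_
  utils::write.table(e[, cols], path, sep = ",", row.names = FALSE,
                     quote = FALSE, na = "NA")
  invisible(path)
}

#' Read a network edge list written by [write_outputs()]
#' @param path edge-list CSV
#' @return data.frame with `node_a`, `node_b`, `allele_diff`, `geo_dist_m`
#' @export
read_network_edges <- function(path) {
  utils::read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE,
                    colClasses = c(node_a = "character", node_b = "character",
                                   allele_diff = "integer", geo_dist_m = "numeric"))
}
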
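# Dating clonal spread: geographic distance between ramets divided by the
# lateral growth rate gives the years since their separation.

EARTH_RADIUS_M <- 6371008.8  # WGS84 mean radius

geographic_distance_vec <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = EARTH_RADIUS_M)
}

#' Great-circle distance between two samples
#'
#' Haversine distance on a sphere of the WGS84 mean radius (6371008.8 m).
#' At stand scale (< 2 km) this is exchangeable with a local planar
#' projection to well under 0.01 %.
#'
#' @param a,b sample records: lists or one-row data.frames with `lat` and
#'   `lon` in decimal degrees
#' @return distance in metres
#' @export
geographic_distance <- function(a, b) {
  if (is.null(a$lat) || is.null(a$lon) || is.null(b$lat) || is.null(b$lon) ||
      is.na(a$lat) || is.na(a$lon) || is.na(b$lat) || is.na(b$lon)) {
    stop("both records need lat and lon coordinates")
  }
  as.numeric(geographic_distance_vec(a$lon, a$lat, b$lon, b$lat))
}

#' Ages of clonal separations from distances and growth rate
#'
#' Converts each within-group ramet pair's geographic distance into the
#' time lateral growth would need to cover it:
#' `age_yr = geo_dist_m * 100 / rate_cm_yr`.  Pairs farther apart than
#' `outlier_dist_m` are flagged as putative transport events (e.g.
#' zoochory) and excluded from the distance summary, the age histogram and
#' the quantile curve, but still reported.  The age of a clonal group with
#' more than two members is the maximum unflagged pair age within it.
#' Pair distances are computed between the representative samples of the
#' individuals (first sample per individual).
#'
#' @param network clonal_network (carries within-group edges with
#'   geographic distances; all within-component pairs are used, not only
#'   network edges)
#' @param table the genotype_table behind the network (coordinates)
#' @param rate a `growth_rate` object or a positive number (cm/yr)
#' @param outlier_dist_m distance above which a pair is flagged
#'   (default 100)
#' @param bin_width_yr width of the age histogram bins (default 200)
#' @param quantile_probs probabilities for the age quantile curve
#' @return list of class `age_estimates`: `pairs` (per-pair data.frame
#'   with `group`, ids, `geo_dist_m`, `age_yr`, `outlier`), `groups`
#'   (per-group max age), `distance_summary` (n_pairs, median_m, mean_m,
#'   max_m over unflagged pairs; `outliers` listed), `age_histogram`
#'   (bin_start, bin_end, count), `age_quantiles`, `rate_cm_yr`
#' @export
clone_pair_ages <- function(network, table, rate, outlier_dist_m = 100,
                            bin_width_yr = 200,
                            quantile_probs = c(0.5, 0.75, 0.9, 0.95, 0.99)) {
  rate_cm_yr <- if (inherits(rate, "growth_rate")) rate$mean_rate else as.numeric(rate)
  if (!is.finite(rate_cm_yr) || rate_cm_yr <= 0) stop("growth rate must be positive")

  ind_tab <- first_sample_per_individual(table)
  coord <- ind_tab$samples[match(network$nodes, ind_tab$samples$individual_id), c("lon", "lat")]
  rownames(coord) <- network$nodes

  pair_rows <- list()
  for (gi in seq_along(network$components)) {
    members <- network$components[[gi]]
    m <- length(members)
    if (m < 2L) next
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        d <- geographic_distance_vec(coord[members[i], "lon"], coord[members[i], "lat"],
                                     coord[members[j], "lon"], coord[members[j], "lat"])
        pair_rows[[length(pair_rows) + 1L]] <- data.frame(
          group = names(network$components)[gi],
          individual_a = members[i], individual_b = members[j],
          geo_dist_m = as.numeric(d), stringsAsFactors = FALSE)
      }
    }
  }
  pairs <- if (length(pair_rows) > 0L) do.call(rbind, pair_rows) else
    data.frame(group = character(0), individual_a = character(0),
               individual_b = character(0), geo_dist_m = numeric(0))
  pairs$age_yr <- pairs$geo_dist_m * 100 / rate_cm_yr
  pairs$outlier <- pairs$geo_dist_m > outlier_dist_m

  keep <- pairs[!pairs$outlier, , drop = FALSE]
  distance_summary <- list(
    n_pairs = nrow(keep),
    median_m = if (nrow(keep) > 0L) stats::median(keep$geo_dist_m) else NA_real_,
    mean_m = if (nrow(keep) > 0L) mean(keep$geo_dist_m) else NA_real_,
    max_m = if (nrow(keep) > 0L) max(keep$geo_dist_m) else NA_real_,
    outliers = pairs[pairs$outlier, c("individual_a", "individual_b", "geo_dist_m"),
                     drop = FALSE]
  )

  groups <- if (nrow(keep) > 0L) {
    ga <- tapply(keep$age_yr, keep$group, max)
    data.frame(group = names(ga), age_yr = as.numeric(ga),
               stringsAsFactors = FALSE)
  } else data.frame(group = character(0), age_yr = numeric(0))

  if (nrow(keep) > 0L) {
    top <- max(keep$age_yr)
    breaks <- seq(0, (floor(top / bin_width_yr) + 1) * bin_width_yr,
                  by = bin_width_yr)
    cnt <- tabulate(findInterval(keep$age_yr, breaks),
                    nbins = length(breaks) - 1L)  # right-open bins
    age_histogram <- data.frame(bin_start = breaks[-length(breaks)],
                                bin_end = breaks[-1L], count = cnt)
    age_quantiles <- stats::quantile(keep$age_yr, probs = quantile_probs,
                                     names = TRUE)
  } else {
    age_histogram <- data.frame(bin_start = numeric(0), bin_end = numeric(0),
                                count = integer(0))
    age_quantiles <- stats::setNames(rep(NA_real_, length(quantile_probs)),
                                     paste0(100 * quantile_probs, "%"))
  }

  structure(list(pairs = pairs, groups = groups,
                 distance_summary = distance_summary,
                 age_histogram = age_histogram,
                 age_quantiles = age_quantiles,
                 rate_cm_yr = rate_cm_yr,
                 outlier_dist_m = outlier_dist_m),
            class = "age_estimates")
}

#' @export
print.age_estimates <- function(x, ...) {
  ds <- x$distance_summary
  cat(sprintf("clone pair ages at %.2f cm/yr: %d pairs (%d outliers > %g m)\n",
              x$rate_cm_yr, nrow(x$pairs), nrow(ds$outliers), x$outlier_dist_m))
  if (ds$n_pairs > 0L) {
    cat(sprintf("  distances: median %.2f m, mean %.2f m, max %.2f m\n",
                ds$median_m, ds$mean_m, ds$max_m))
    cat(sprintf("  95%% of pair ages below %.0f yr\n", x$age_quantiles["95%"]))
  }
  invisible(x)
}
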
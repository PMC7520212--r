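# Lateral growth rates from tree-ring counts along branch sections.
# The ring count of a section equals its age, so between two aged sections
# the branch grew (pos2 - pos1) cm in (rings1 - rings2) years.

#' Per-segment lateral growth rates of one branch
#'
#' For each consecutive pair of aged sections along a branch the rate is
#' the length grown divided by the age difference,
#' `(pos2 - pos1) / (rings1 - rings2)` cm/yr.  A pair with equal ring
#' counts spans no measurable time and is skipped with a warning; a ring
#' count increasing toward the tip violates the sampling logic and errors.
#'
#' @param series data.frame with `position_cm` and `ring_count_yr`
#'   (one branch, sorted or not), e.g. one element of [split_branches()].
#' @return data.frame with `from_cm`, `to_cm`, `rate_cm_yr` (possibly
#'   0 rows for single-section or age-flat branches); carries over
#'   `individual_id`/`branch_id` when present.
#' @export
segment_growth_rates <- function(series) {
  s <- as.data.frame(series)
  s <- s[order(s$position_cm), , drop = FALSE]
  n <- nrow(s)
  empty <- data.frame(from_cm = numeric(0), to_cm = numeric(0),
                      rate_cm_yr = numeric(0))
  if (n < 2L) return(empty)
  d_age <- s$ring_count_yr[-n] - s$ring_count_yr[-1L]   # older minus younger
  if (any(d_age < 0L)) {
    stop("ring count increases toward the branch tip between ",
         s$position_cm[which(d_age < 0L)[1L]], " and ",
         s$position_cm[which(d_age < 0L)[1L] + 1L], " cm")
  }
  keep <- d_age > 0L
  if (any(!keep)) {
    warning(sum(!keep), " segment(s) with zero age difference skipped")
  }
  if (!any(keep)) return(empty)
  out <- data.frame(
    from_cm = s$position_cm[-n][keep],
    to_cm = s$position_cm[-1L][keep],
    rate_cm_yr = (s$position_cm[-1L] - s$position_cm[-n])[keep] / d_age[keep]
  )
  if (!is.null(s$individual_id)) out$individual_id <- s$individual_id[1L]
  if (!is.null(s$branch_id)) out$branch_id <- s$branch_id[1L]
  out
}

#' Pooled lateral growth rate over many branches
#'
#' Combines segment rates from all branches into a single regional
#' estimate.  `weighting = "per_segment"` (default) averages all segment
#' rates directly; `"per_branch"` first averages within each branch and
#' then across branches, giving every branch equal weight.  The spread is
#' the sample standard deviation (n - 1) over the same units.
#'
#' @param sections branch_sections table (or list of per-branch
#'   data.frames)
#' @param weighting `"per_segment"` or `"per_branch"`
#' @return list of class `growth_rate`: `mean_rate`, `sd_rate`,
#'   `n_segments`, `n_branches`, `weighting`, `segments` (all per-segment
#'   rates)
#' @export
pooled_growth_rate <- function(sections, weighting = c("per_segment", "per_branch")) {
  weighting <- match.arg(weighting)
  branches <- if (is.data.frame(sections)) split_branches(sections) else sections
  segs <- do.call(rbind, lapply(branches, segment_growth_rates))
  if (is.null(segs) || nrow(segs) == 0L) {
    stop("no usable segments: every branch has fewer than 2 aged sections or no age difference")
  }
  if (weighting == "per_segment") {
    m <- mean(segs$rate_cm_yr)
    s <- if (nrow(segs) > 1L) stats::sd(segs$rate_cm_yr) else 0
  } else {
    key <- paste(segs$individual_id, segs$branch_id, sep = ":")
    bm <- tapply(segs$rate_cm_yr, key, mean)
    m <- mean(bm)
    s <- if (length(bm) > 1L) stats::sd(bm) else 0
  }
  structure(list(mean_rate = as.numeric(m), sd_rate = as.numeric(s),
                 n_segments = nrow(segs),
                 n_branches = length(branches),
                 weighting = weighting, segments = segs),
            class = "growth_rate")
}

#' @export
print.growth_rate <- function(x, ...) {
  cat(sprintf("lateral growth rate: %.2f +/- %.2f cm/yr (%d segments, %d branches, %s)\n",
              x$mean_rate, x$sd_rate, x$n_segments, x$n_branches, x$weighting))
  invisible(x)
}
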
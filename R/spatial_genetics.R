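# Distance-decay regressions: genetic distance against geographic distance
# for sexually distinct pairs (isolation by distance) and for somatic
# mutations within clonal groups (mutation accumulation during spread).

regression_result <- function(fit, n, permutation_p = NA_real_) {
  # a perfect fit (tiny engineered point sets) is legitimate here; keep the
  # exact-fit warning from summary.lm out of the caller's way
  sm <- withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
  fs <- sm$fstatistic
  structure(list(
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    F_stat = unname(fs["value"]),
    df_num = unname(fs["numdf"]),
    df_den = unname(fs["dendf"]),
    p_value = unname(stats::pf(fs["value"], fs["numdf"], fs["dendf"],
                               lower.tail = FALSE)),
    R2 = sm$r.squared,
    n = n,
    permutation_p = permutation_p
  ), class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("OLS: slope = %.4g, F(%d, %d) = %.4g, p = %.4g, R2 = %.4g, n = %d\n",
              x$slope, x$df_num, x$df_den, x$F_stat, x$p_value, x$R2, x$n))
  if (!is.na(x$permutation_p)) {
    cat(sprintf("  permutation p = %.4g\n", x$permutation_p))
  }
  invisible(x)
}

#' Allele differences vs. distance for sexually distinct pairs
#'
#' Ordinary least squares of pairwise allele difference on geographic
#' distance, restricted to comparable pairs beyond the somatic threshold
#' (i.e. pairs not read as clonal).  A positive slope indicates isolation
#' by distance.  Pairwise points are not independent; the parametric
#' F-test is reported as-is and an optional Mantel-style permutation p
#' (shuffling distances against differences) can be requested.
#'
#' @param dists pairwise_distance data.frame with a `geo_dist_m` column
#'   (see [attach_geo_distances()])
#' @param somatic_threshold pairs with `allele_diff` above this enter the
#'   regression (default 3)
#' @param n_perm permutations for the optional Mantel-style p (0 = skip)
#' @param seed RNG seed for the permutations
#' @return [regression_result] (class `regression_result`)
#' @export
sexual_distance_decay <- function(dists, somatic_threshold = 3L,
                                  n_perm = 0L, seed = 1L) {
  if (!"geo_dist_m" %in% names(dists)) {
    stop("distances lack geo_dist_m; run attach_geo_distances() first")
  }
  d <- dists[dists$comparable & dists$allele_diff > somatic_threshold, , drop = FALSE]
  if (nrow(d) < 3L) stop("need at least 3 non-clonal pairs, have ", nrow(d))
  fit <- stats::lm(allele_diff ~ geo_dist_m, data = d)
  perm_p <- NA_real_
  if (n_perm > 0L) {
    obs <- abs(stats::coef(fit)[2L])
    set.seed(seed)
    ge <- 0L
    for (b in seq_len(n_perm)) {
      sl <- stats::coef(stats::lm(d$allele_diff ~ sample(d$geo_dist_m)))[2L]
      if (abs(sl) >= obs - 1e-12) ge <- ge + 1L
    }
    perm_p <- (1 + ge) / (n_perm + 1)
  }
  regression_result(fit, nrow(d), perm_p)
}

#' Somatic-mutation accumulation with distance inside clonal groups
#'
#' One point per clonal group that contains at least one somatic-mutation
#' pair (allele difference >= 1 within the group): the within-group pair
#' with the maximum allele difference (under `max_rule = "diff"`, ties
#' broken by the larger geographic distance) or the maximum geographic
#' distance (`max_rule = "dist"`).  OLS of allele difference on distance
#' over these group maxima.
#'
#' @param network clonal_network built with geographic distances
#' @param max_rule `"diff"` (default) or `"dist"` — which within-group
#'   pair represents the group
#' @return [regression_result] with one point per qualifying group
#' @export
somatic_mutation_decay <- function(network, max_rule = c("diff", "dist")) {
  max_rule <- match.arg(max_rule)
  e <- network$edges
  e <- e[e$allele_diff >= 1L, , drop = FALSE]
  if (nrow(e) == 0L) stop("0 clonal groups contain a somatic-mutation pair; need >= 3")
  grp <- network$membership[e$node_a]
  pts <- do.call(rbind, lapply(split(e, grp), function(s) {
    ord <- if (max_rule == "diff") {
      order(-s$allele_diff, -s$geo_dist_m)
    } else {
      order(-s$geo_dist_m, -s$allele_diff)
    }
    s[ord[1L], c("allele_diff", "geo_dist_m")]
  }))
  if (nrow(pts) < 3L) {
    stop("only ", nrow(pts), " clonal group(s) contain a somatic-mutation pair; need >= 3")
  }
  fit <- stats::lm(allele_diff ~ geo_dist_m, data = pts)
  regression_result(fit, nrow(pts))
}
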
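#' Bootstrap settings for pairwise significance testing
#'
#' Settings for the bias-corrected (BC) percentile bootstrap used to compare
#' mean spot volumes between group pairs: B resamples of size n (the number
#' of replicates actually observed in each group), a nominal confidence
#' level, and a Bonferroni family size m that widens the intervals to level
#' `1 - (1 - confidence)/m`.
#'
#' Two decision rules are available. In `"difference_ci"` mode (default) a
#' spot is significant for a pair when the adjusted BC interval for the
#' difference of group means DV = mean_y - mean_x excludes 0. In
#' `"group_ci_overlap"` mode each group's mean gets its own adjusted BC
#' interval and the spot is significant when the two intervals are disjoint;
#' this reading of "per-spot mean CIs, then compared" is considerably more
#' conservative.
#'
#' @param B Number of bootstrap resamples (default 2000).
#' @param confidence Nominal confidence level (default 0.95).
#' @param bonferroni_family Family size m; `NULL` (default) means the number
#'   of group pairs (3 for three groups). Use `"spots_pairs"` in
#'   [pairwise_significance()] contexts via an integer equal to
#'   spots x pairs for the stricter global family.
#' @param mode `"difference_ci"` or `"group_ci_overlap"`.
#' @param seed Integer seed governing all resampling.
#' @return A `bootstrap_settings` list.
#' @export
bootstrap_settings <- function(B = 2000, confidence = 0.95,
                               bonferroni_family = NULL,
                               mode = c("difference_ci", "group_ci_overlap"),
                               seed = 1L) {
  mode <- match.arg(mode)
  if (B < 1) abort("`B` must be >= 1.", class = "gelquant_config_error")
  if (confidence <= 0 || confidence >= 1) {
    abort("`confidence` must lie in (0, 1).", class = "gelquant_config_error")
  }
  if (!is.null(bonferroni_family) &&
      (!is.numeric(bonferroni_family) || bonferroni_family < 1)) {
    abort("`bonferroni_family` must be NULL or an integer >= 1.",
          class = "gelquant_config_error")
  }
  structure(list(B = as.integer(B), confidence = confidence,
                 bonferroni_family = bonferroni_family, mode = mode,
                 seed = as.integer(seed)),
            class = "bootstrap_settings")
}

#' Bootstrap resampling distribution of a mean or mean difference
#'
#' Draws B resamples with replacement, independently within each group and
#' of the same size as the observed group, and returns the resampled
#' statistic: `mean_y - mean_x` when both value sets are given, or the
#' single group's mean when `values_y` is `NULL`. An empty group (spot
#' absent from that group) contributes a mean of 0, so for unshared spots
#' the statistic reduces to (plus or minus) the present group's resampled
#' mean.
#'
#' @param values_x,values_y Numeric vectors of observed volumes; `values_y
#'   = NULL` requests the one-group mean statistic; a zero-length vector is
#'   an absent group.
#' @param B Number of resamples.
#' @param seed Optional integer; when supplied the RNG is seeded so the
#'   result is reproducible in isolation. Leave `NULL` inside larger
#'   seeded procedures.
#' @return Numeric vector of B resampled statistics.
#' @export
bootstrap_statistic <- function(values_x, values_y = NULL, B = 2000, seed = NULL) {
  one_group <- is.null(values_y)
  if (length(values_x) == 0 && (one_group || length(values_y) == 0)) {
    abort("At least one group must have observed values.",
          class = "gelquant_input_error")
  }
  if (!is.null(seed)) set.seed(seed)
  if (one_group) return(resample_means(values_x, B))
  resample_means(values_y, B) - resample_means(values_x, B)
}

resample_means <- function(v, B) {
  n <- length(v)
  if (n == 0) return(rep(0, B))
  if (n == 1) return(rep(v, B))
  rowMeans(matrix(sample(v, n * B, replace = TRUE), B, n))
}

#' Bias-corrected percentile confidence interval
#'
#' The BC percentile interval shifts the quantile levels of the plain
#' percentile interval by a bias-correction constant
#' `z0 = qnorm(p)` with `p` the proportion of resampled statistics strictly
#' below the observed statistic: the endpoints are the empirical quantiles
#' (linear interpolation between order statistics, `type = 7`) at levels
#' `pnorm(2*z0 + qnorm(alpha/2))` and `pnorm(2*z0 + qnorm(1 - alpha/2))`.
#' When the resampling distribution is symmetric about the observed value
#' (`p = 0.5`, `z0 = 0`) it reduces exactly to the percentile interval.
#' Proportions of 0 or 1 are clamped to `1/(2B)` and `1 - 1/(2B)` before
#' the probit transform; a degenerate distribution (all resamples equal)
#' yields the zero-width interval at that value.
#'
#' @param resamples Numeric vector of resampled statistics.
#' @param observed Observed value of the statistic.
#' @param confidence Confidence level of the interval (already
#'   Bonferroni-adjusted where applicable).
#' @return A `bootstrap_ci` list: `lower`, `upper`, `point_estimate`, `z0`,
#'   `confidence`.
#' @export
bc_percentile_ci <- function(resamples, observed, confidence = 0.95) {
  if (length(resamples) == 0) {
    abort("`resamples` must be non-empty.", class = "gelquant_input_error")
  }
  if (confidence <= 0 || confidence >= 1) {
    abort("`confidence` must lie in (0, 1).", class = "gelquant_config_error")
  }
  if (max(resamples) == min(resamples)) {
    return(structure(list(lower = resamples[1], upper = resamples[1],
                          point_estimate = observed, z0 = 0,
                          confidence = confidence),
                     class = "bootstrap_ci"))
  }
  B <- length(resamples)
  p <- mean(resamples < observed)
  p <- min(max(p, 1 / (2 * B)), 1 - 1 / (2 * B))
  z0 <- qnorm(p)
  a <- (1 - confidence) / 2
  lv <- pnorm(2 * z0 + qnorm(c(a, 1 - a)))
  q <- quantile(resamples, probs = lv, type = 7, names = FALSE)
  structure(list(lower = q[1], upper = q[2], point_estimate = observed,
                 z0 = z0, confidence = confidence),
            class = "bootstrap_ci")
}

#' Bonferroni-adjusted confidence level
#'
#' Widens a nominal confidence level to control the family-wise error over
#' m simultaneous intervals: `1 - (1 - confidence)/m`.
#'
#' @param confidence Nominal level.
#' @param m Family size (>= 1).
#' @return The adjusted level.
#' @examples
#' bonferroni_level(0.95, 3) # 0.98333...
#' @export
bonferroni_level <- function(confidence, m) {
  if (m < 1) abort("`m` must be >= 1.", class = "gelquant_config_error")
  1 - (1 - confidence) / m
}

#' Pairwise bootstrap significance calls for every spot
#'
#' For every validated spot and every ordered group pair, computes the group
#' means of normalized volumes (x first group, y second), the difference
#' DV = y - x, a Bonferroni-adjusted BC bootstrap interval, and a
#' significance flag according to the configured mode (see
#' [bootstrap_settings()]). A group whose presence flag is `FALSE` is
#' treated as absent: its mean is 0, any stray detections are excluded from
#' resampling, and for unshared spots the statistic resamples only the
#' present group. Spots absent from both groups of a pair get status
#' `"absent_both"` and an `NA` significance flag.
#'
#' All resampling flows from `settings$seed`; identical inputs and seed give
#' identical calls.
#'
#' @param table Normalized, filtered [as_spot_table()] tibble.
#' @param design The matching [as_experiment_design()].
#' @param presence [call_presence()] output for the same table.
#' @param settings A [bootstrap_settings()].
#' @return A tibble with one row per (spot, pair): `spot_id`, `group_x`,
#'   `group_y`, `pair`, `n_x`, `n_y`, `mean_x`, `mean_y`, `DV`, `ci_lower`,
#'   `ci_upper`, `z0`, `significant`, `shared`, `status`; in
#'   `group_ci_overlap` mode the per-group intervals are reported in
#'   `ci_x_lower`, `ci_x_upper`, `ci_y_lower`, `ci_y_upper` instead of the
#'   DV interval. Attributes: `mode`, `conf_adjusted`, `bonferroni_m`,
#'   `settings`.
#' @export
pairwise_significance <- function(table, design, presence,
                                  settings = bootstrap_settings()) {
  check_paired(table, design)
  pairs <- group_pairs(design)
  m <- settings$bonferroni_family %||% nrow(pairs)
  conf <- bonferroni_level(settings$confidence, m)
  B <- settings$B
  diff_mode <- settings$mode == "difference_ci"

  vol <- volume_matrix(table)
  groups <- levels(design$group)
  gel_idx <- lapply(groups, function(g) match(gels_of_group(design, g), colnames(vol)))
  names(gel_idx) <- groups
  if (!all(rownames(vol) %in% presence$spot_id)) {
    abort("`presence` does not cover every spot in `table`.",
          class = "gelquant_consistency_error")
  }
  pres <- matrix(FALSE, nrow(vol), length(groups),
                 dimnames = list(rownames(vol), groups))
  pr <- presence[presence$spot_id %in% rownames(vol), ]
  pres[cbind(pr$spot_id, as.character(pr$group))] <- pr$present

  n_row <- nrow(vol) * nrow(pairs)
  res <- vector("list", n_row)
  k <- 0L
  set.seed(settings$seed)
  for (s in seq_len(nrow(vol))) {
    for (pidx in seq_len(nrow(pairs))) {
      gx <- pairs$group_x[pidx]; gy <- pairs$group_y[pidx]
      px <- pres[s, gx]; py <- pres[s, gy]
      vx <- if (px) vol[s, gel_idx[[gx]]] else numeric(0)
      vy <- if (py) vol[s, gel_idx[[gy]]] else numeric(0)
      vx <- vx[!is.na(vx)]; vy <- vy[!is.na(vy)]
      mean_x <- if (px) mean(vx) else 0
      mean_y <- if (py) mean(vy) else 0
      DV <- mean_y - mean_x
      row <- list(spot_id = rownames(vol)[s], group_x = gx, group_y = gy,
                  pair = pairs$pair[pidx],
                  n_x = length(vx), n_y = length(vy),
                  mean_x = mean_x, mean_y = mean_y, DV = DV,
                  ci_lower = NA_real_, ci_upper = NA_real_, z0 = NA_real_,
                  ci_x_lower = NA_real_, ci_x_upper = NA_real_,
                  ci_y_lower = NA_real_, ci_y_upper = NA_real_,
                  significant = NA, shared = px && py,
                  status = "ok")
      if (!px && !py) {
        row$status <- "absent_both"
      } else if (diff_mode) {
        stat <- resample_means(vy, B) - resample_means(vx, B)
        ci <- bc_percentile_ci(stat, DV, conf)
        row$ci_lower <- ci$lower; row$ci_upper <- ci$upper; row$z0 <- ci$z0
        row$significant <- ci$lower > 0 || ci$upper < 0
      } else {
        ci_x <- if (px) bc_percentile_ci(resample_means(vx, B), mean_x, conf)
                else list(lower = 0, upper = 0)
        ci_y <- if (py) bc_percentile_ci(resample_means(vy, B), mean_y, conf)
                else list(lower = 0, upper = 0)
        row$ci_x_lower <- ci_x$lower; row$ci_x_upper <- ci_x$upper
        row$ci_y_lower <- ci_y$lower; row$ci_y_upper <- ci_y$upper
        row$significant <- ci_x$upper < ci_y$lower || ci_y$upper < ci_x$lower
      }
      k <- k + 1L
      res[[k]] <- row
    }
  }
  out <- dplyr::bind_rows(res)
  if (diff_mode) {
    out <- dplyr::select(out, -dplyr::starts_with("ci_x"), -dplyr::starts_with("ci_y"))
  } else {
    out <- dplyr::select(out, -"ci_lower", -"ci_upper", -"z0")
  }
  attr(out, "mode") <- settings$mode
  attr(out, "conf_adjusted") <- conf
  attr(out, "bonferroni_m") <- m
  attr(out, "settings") <- settings
  out
}
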
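#' Fold change of group mean volumes
#'
#' `FC = y / x` for group means x and y; ratios below one are replaced by
#' their negative reciprocal `-x / y`, so a halving is reported as -2 rather
#' than 0.5 and equal means give +1. For unshared spots the convention is
#' `x = 0 -> +Inf` and `y = 0 -> -Inf`: the fold change of a spot present in
#' only one group is infinite whatever its volume.
#'
#' @param mean_x,mean_y Non-negative group means (vectorized).
#' @return Numeric vector of fold changes in (-Inf, -1] U \{+1\} U [+1, Inf).
#' @examples
#' fold_change(1, 1.49)  # +1.49
#' fold_change(2, 1)     # -2
#' fold_change(0.37, 0)  # -Inf
#' @export
fold_change <- function(mean_x, mean_y) {
  if (any(mean_x < 0 | mean_y < 0, na.rm = TRUE)) {
    abort("Group means must be non-negative.", class = "gelquant_input_error")
  }
  if (any(mean_x == 0 & mean_y == 0, na.rm = TRUE)) {
    abort("Fold change undefined when both group means are 0.",
          class = "gelquant_input_error")
  }
  fc <- mean_y / mean_x                       # x = 0 gives +Inf
  fc[mean_y == 0] <- -Inf
  flip <- is.finite(fc) & fc < 1
  fc[flip] <- -mean_x[flip] / mean_y[flip]
  fc
}

#' Relative change of a mean-volume difference
#'
#' `RC = DV / |DVR_max|`, where DV = mean_y - mean_x and DVR_max is the
#' maximum-magnitude DV across all significant spot-pair results. RC is
#' bounded in \[-1, +1\] for shared and unshared spots alike, and the entry
#' attaining the maximum has |RC| = 1 exactly.
#'
#' @param DV Difference(s) of group means.
#' @param DVR_max_abs Positive scalar, `max(abs(DV))` over the significant
#'   set.
#' @return Numeric vector of relative changes in \[-1, 1\].
#' @export
relative_change <- function(DV, DVR_max_abs) {
  if (!is.numeric(DVR_max_abs) || length(DVR_max_abs) != 1 || DVR_max_abs <= 0) {
    abort("`DVR_max_abs` must be a positive scalar.",
          class = "gelquant_input_error")
  }
  DV / DVR_max_abs
}

#' FC and RC effect sizes over pairwise significance results
#'
#' Computes fold change (FC) and relative change (RC) for every significant
#' (spot, pair) entry. The RC denominator DVR_max is determined jointly over
#' all significant entries of all pairs, so exactly the maximum-|DV| entry
#' gets |RC| = 1. Non-significant entries are labeled `ns`; entries where a
#' spot is absent from both groups of a pair are labeled `N/A`.
#'
#' @param results A [pairwise_significance()] tibble.
#' @return A tibble of class `effect_sizes` with the columns of `results`
#'   plus `FC`, `RC` (both `NA` for non-significant entries) and `status`
#'   (`"significant"`, `"ns"` or `"N/A"`). Attributes: `DVR_max` (signed DV
#'   attaining the maximum magnitude; `NA` when nothing is significant),
#'   `DVR_max_abs`, `n_significant`.
#' @export
compute_effects <- function(results) {
  sig <- results$significant %in% TRUE & results$status == "ok"
  out <- results
  out$FC <- NA_real_
  out$RC <- NA_real_
  out$status <- dplyr::case_when(
    results$status == "absent_both" ~ "N/A",
    sig ~ "significant",
    .default = "ns"
  )
  if (any(sig)) {
    dvr_i <- which(sig)[which.max(abs(results$DV[sig]))]
    dvr_max <- results$DV[dvr_i]
    dvr_abs <- abs(dvr_max)
    out$FC[sig] <- fold_change(results$mean_x[sig], results$mean_y[sig])
    out$RC[sig] <- relative_change(results$DV[sig], dvr_abs)
  } else {
    dvr_max <- NA_real_
    dvr_abs <- NA_real_
  }
  attr(out, "DVR_max") <- dvr_max
  attr(out, "DVR_max_abs") <- dvr_abs
  attr(out, "n_significant") <- sum(sig)
  class(out) <- c("effect_sizes", class(tibble::tibble()))
  out
}

#' Render an effect-size table in the reporting layout
#'
#' One row per spot, one FC and one RC column per group pair, with the
#' report sentinels: signed fixed-decimal numbers (FC to `fc_digits`, RC to
#' `rc_digits`), `+inf`/`-inf` for unshared spots, `ns` for non-significant
#' entries and `N/A` where the comparison is not applicable.
#'
#' @param effects A [compute_effects()] tibble.
#' @param fc_digits,rc_digits Decimals for FC (default 2) and RC (default 3).
#' @return A tibble with character columns `<pair>_FC`, `<pair>_RC`.
#' @export
format_effect_table <- function(effects, fc_digits = 2, rc_digits = 3) {
  fmt <- function(v, digits) {
    dplyr::case_when(
      is.infinite(v) & v > 0 ~ "+inf",
      is.infinite(v) ~ "-inf",
      !is.na(v) ~ sprintf(paste0("%+.", digits, "f"), v),
      .default = NA_character_
    )
  }
  long <- effects |>
    dplyr::mutate(
      FC_chr = dplyr::case_when(
        .data$status == "significant" ~ fmt(.data$FC, fc_digits),
        .data$status == "N/A" ~ "N/A",
        .default = "ns"
      ),
      RC_chr = dplyr::case_when(
        .data$status == "significant" ~ fmt(.data$RC, rc_digits),
        .data$status == "N/A" ~ "N/A",
        .default = "ns"
      )
    ) |>
    dplyr::select("spot_id", "pair", "FC_chr", "RC_chr")
  long |>
    tidyr::pivot_wider(names_from = "pair",
                       values_from = c("FC_chr", "RC_chr"),
                       names_glue = "{pair}_{sub('_chr', '', .value)}") |>
    dplyr::select("spot_id", dplyr::all_of(
      as.vector(t(outer(unique(long$pair), c("_FC", "_RC"), paste0)))
    ))
}

#' Relative-change overview plot
#'
#' Bar chart of RC for every significant spot-pair entry, one facet per
#' group pair, spots ordered by RC. Entries at the bounds (-1 or +1) carry
#' the largest mean-volume difference in the whole analysis.
#'
#' @param object A [compute_effects()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.effect_sizes <- function(object, ...) {
  df <- dplyr::filter(object, .data$status == "significant")
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$spot_id, .data$RC),
    y = .data$RC, fill = .data$RC > 0
  )) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~pair, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "relative change (RC)") +
    ggplot2::theme_minimal()
}
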
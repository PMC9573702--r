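#' Presence calling per spot and group
#'
#' Counts, for every spot and group, on how many replicate gels the spot was
#' detected (non-missing volume; an explicit 0 counts as detected), and
#' flags the spot "present" in a group when it was detected in at least
#' `min_present_replicates` biological replicates — the reproducibility rule
#' used to validate spots (at least 3 of 4 replicates in the emulated
#' study).
#'
#' @param table A [as_spot_table()] tibble.
#' @param design The matching [as_experiment_design()].
#' @param min_present_replicates Minimum detected replicates for presence
#'   (default 3).
#' @return A tibble with columns `spot_id`, `group`, `n_detected`,
#'   `n_replicates`, `present`; attribute `min_present_replicates`.
#' @export
call_presence <- function(table, design, min_present_replicates = 3) {
  check_paired(table, design)
  grp_sizes <- dplyr::count(design, .data$group, name = "n_replicates")
  if (min_present_replicates < 1 || min_present_replicates > max(grp_sizes$n_replicates)) {
    abort("`min_present_replicates` must lie between 1 and the replicate count.",
          class = "gelquant_config_error")
  }
  out <- table |>
    tidyr::pivot_longer(dplyr::all_of(gel_ids(table)),
                        names_to = "gel_id", values_to = "volume") |>
    dplyr::left_join(design, by = "gel_id") |>
    dplyr::group_by(.data$spot_id, .data$group) |>
    dplyr::summarise(n_detected = sum(!is.na(.data$volume)), .groups = "drop") |>
    dplyr::left_join(grp_sizes, by = "group") |>
    dplyr::mutate(present = .data$n_detected >= min_present_replicates) |>
    dplyr::arrange(match(.data$spot_id, table$spot_id), .data$group)
  attr(out, "min_present_replicates") <- min_present_replicates
  out
}

check_paired <- function(table, design) {
  gels <- gel_ids(table)
  missing <- setdiff(gels, design$gel_id)
  if (length(missing) > 0) {
    abort(paste0("Gel(s) in table but not in design: ",
                 paste(missing, collapse = ", ")),
          class = "gelquant_consistency_error")
  }
  extra <- setdiff(design$gel_id, gels)
  if (length(extra) > 0) {
    abort(paste0("Gel(s) in design but not in table: ",
                 paste(extra, collapse = ", ")),
          class = "gelquant_consistency_error")
  }
  invisible(TRUE)
}

#' Filter spots to the reproducibly detected ("validated") set
#'
#' Retains the spots whose presence flag is `TRUE` in at least one group
#' (`scope = "any"`, the default) or in every group (`scope = "all"`). The
#' `"any"` rule keeps spots reproducibly present in one group and absent in
#' another — the "unique" spots whose fold change is infinite — which an
#' all-groups rule would discard. The operation is idempotent.
#'
#' @param table A [as_spot_table()] tibble.
#' @param presence Output of [call_presence()] on the same table.
#' @param scope `"any"` (default) or `"all"`.
#' @return The filtered `spot_table`, spot order preserved.
#' @export
filter_reproducible <- function(table, presence, scope = c("any", "all")) {
  scope <- match.arg(scope)
  keep <- presence |>
    dplyr::group_by(.data$spot_id) |>
    dplyr::summarise(keep = if (scope == "any") any(.data$present)
                     else all(.data$present),
                     .groups = "drop")
  ids <- keep$spot_id[keep$keep]
  out <- table[table$spot_id %in% ids, , drop = FALSE]
  validate_spot_table(out)
}

#' Total-spot-density normalization
#'
#' Replaces every volume by `raw / total_g * C`, where `total_g` is the sum
#' of validated-spot volumes on gel g and `C` is a common constant: either a
#' positive number (e.g. `1e6` for ppm-style output) or `"mean-total"` (the
#' mean per-gel total, which keeps volumes on the raw scale). After
#' normalization all per-gel totals over validated spots are equal, so
#' multiplicative gel-to-gel intensity differences cancel. Missing entries
#' stay missing. The table should already be filtered to validated spots,
#' since the totals are computed over the spots given.
#'
#' @param table A filtered [as_spot_table()] tibble.
#' @param constant Positive number, or `"mean-total"` (default).
#' @return The normalized `spot_table`.
#' @export
normalize_total_density <- function(table, constant = "mean-total") {
  gels <- gel_ids(table)
  m <- volume_matrix(table)
  totals <- colSums(m, na.rm = TRUE)
  zero <- names(totals)[totals <= 0]
  if (length(zero) > 0) {
    abort(paste0("Gel(s) with zero total validated-spot volume: ",
                 paste(zero, collapse = ", ")),
          class = "gelquant_normalization_error")
  }
  C <- if (identical(constant, "mean-total")) mean(totals) else {
    if (!is.numeric(constant) || length(constant) != 1 || constant <= 0) {
      abort("`constant` must be a positive number or \"mean-total\".",
            class = "gelquant_config_error")
    }
    constant
  }
  out <- table
  for (g in gels) out[[g]] <- table[[g]] / totals[[g]] * C
  validate_spot_table(out)
}
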
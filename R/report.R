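#' Percentage with explicit half-up rounding
#'
#' `100 * count / total`, rounded half away from zero to `digits` decimals —
#' the convention used for the headline percentages of the analysis report
#' (e.g. 78 of 345 spots = 22.6%; 52 of 78 = 67% at 0 decimals).
#'
#' @param count,total Non-negative counts, `total > 0`.
#' @param digits Decimals to keep (default 1).
#' @return The rounded percentage.
#' @examples
#' percent_of(78, 345)      # 22.6
#' percent_of(52, 78, 0)    # 67
#' @export
percent_of <- function(count, total, digits = 1) {
  if (any(total <= 0)) {
    abort("`total` must be positive.", class = "gelquant_input_error")
  }
  round_half_up(100 * count / total, digits)
}

round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Aggregate stage outputs into an analysis report
#'
#' Collects the headline numbers of a full run: how many spots passed the
#' reproducibility filter, how many are significant in at least one group
#' pair (and what percentage that is), per-pair significant counts, the
#' formatted effect table, the PCA variance summary, and an echo of the
#' configuration (seed, B, mode, ...) so the run can be reproduced.
#'
#' @param presence [call_presence()] output (computed on the unfiltered
#'   table; validated spots are those present in >= 1 group).
#' @param results [pairwise_significance()] output.
#' @param effects [compute_effects()] output.
#' @param pca Optional [run_pca()] result.
#' @param config Optional named list echoed verbatim into the report.
#' @return An `analysis_report` list.
#' @export
summarize_analysis <- function(presence, results, effects, pca = NULL,
                               config = list()) {
  validated <- presence |>
    dplyr::group_by(.data$spot_id) |>
    dplyr::summarise(v = any(.data$present), .groups = "drop")
  validated_ids <- validated$spot_id[validated$v]
  if (!all(unique(results$spot_id) %in% validated_ids)) {
    abort("Results contain spots that did not pass the presence filter.",
          class = "gelquant_consistency_error")
  }
  if (!identical(sort(unique(results$spot_id)),
                 sort(unique(effects$spot_id)))) {
    abort("`results` and `effects` cover different spot sets.",
          class = "gelquant_consistency_error")
  }
  n_validated <- length(validated_ids)
  sig_spots <- unique(results$spot_id[results$significant %in% TRUE])
  pair_counts <- results |>
    dplyr::group_by(.data$pair) |>
    dplyr::summarise(n_significant = sum(.data$significant %in% TRUE),
                     .groups = "drop")
  report <- list(
    n_validated_spots = n_validated,
    n_significant_spots = length(sig_spots),
    pct_significant = percent_of(length(sig_spots), n_validated, 1),
    pair_counts = pair_counts,
    DVR_max = attr(effects, "DVR_max"),
    DVR_max_abs = attr(effects, "DVR_max_abs"),
    effect_table = format_effect_table(
      dplyr::filter(effects, .data$spot_id %in% sig_spots)),
    pca_variance = if (!is.null(pca)) pca$variance else NULL,
    pct_variance_first_two = if (!is.null(pca)) {
      round_half_up(100 * sum(pca$variance$variance_fraction[
        seq_len(min(2, nrow(pca$variance)))]), 1)
    } else NULL,
    config = config
  )
  class(report) <- "analysis_report"
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Validated spots:      ", x$n_validated_spots, "\n")
  cat("Significant spots:    ", x$n_significant_spots,
      sprintf(" (%.1f%%)", x$pct_significant), "\n", sep = "")
  for (i in seq_len(nrow(x$pair_counts))) {
    cat("  ", x$pair_counts$pair[i], ": ", x$pair_counts$n_significant[i],
        " significant\n", sep = "")
  }
  if (!is.null(x$pct_variance_first_two)) {
    cat("PCA, first two components: ", x$pct_variance_first_two,
        "% of total variance\n", sep = "")
  }
  invisible(x)
}

#' @rdname summarize_analysis
#' @param x An `analysis_report`.
#' @param ... Unused.
#' @export
glance.analysis_report <- function(x, ...) {
  tibble::tibble(
    n_validated_spots = x$n_validated_spots,
    n_significant_spots = x$n_significant_spots,
    pct_significant = x$pct_significant,
    DVR_max = x$DVR_max %||% NA_real_,
    pct_variance_first_two = x$pct_variance_first_two %||% NA_real_
  )
}

#' Write an analysis report to disk
#'
#' Writes `report.json` (canonical, machine-readable; tibbles as arrays of
#' records) and `report.md` (a human-readable digest with the effect table
#' in the reporting layout) into `dir`.
#'
#' @param report An [summarize_analysis()] report.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
render_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  json_path <- file.path(dir, "report.json")
  md_path <- file.path(dir, "report.md")
  payload <- report
  class(payload) <- NULL
  payload$pair_counts <- as.data.frame(payload$pair_counts)
  payload$effect_table <- as.data.frame(payload$effect_table)
  if (!is.null(payload$pca_variance)) {
    payload$pca_variance <- as.data.frame(payload$pca_variance)
  }
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)

  lines <- c("# Differential spot-volume analysis report", "",
             paste0("- Validated spots: ", report$n_validated_spots),
             paste0("- Significant spots: ", report$n_significant_spots,
                    " (", report$pct_significant, "%)"))
  for (i in seq_len(nrow(report$pair_counts))) {
    lines <- c(lines, paste0("- ", report$pair_counts$pair[i], ": ",
                             report$pair_counts$n_significant[i],
                             " significant"))
  }
  if (!is.null(report$pct_variance_first_two)) {
    lines <- c(lines, paste0("- PCA, first two components: ",
                             report$pct_variance_first_two, "% of variance"))
  }
  lines <- c(lines, "", "## Effect sizes (FC / RC)", "")
  et <- report$effect_table
  if (nrow(et) == 0) {
    lines <- c(lines, "No significant spots.")
  } else {
    lines <- c(lines,
               paste0("| ", paste(names(et), collapse = " | "), " |"),
               paste0("|", paste(rep("---", ncol(et)), collapse = "|"), "|"),
               vapply(seq_len(nrow(et)), function(i) {
                 paste0("| ", paste(unlist(et[i, ]), collapse = " | "), " |")
               }, character(1)))
  }
  writeLines(lines, md_path)
  invisible(c(json = json_path, md = md_path))
}
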
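#' Run the full differential spot-volume pipeline
#'
#' Chains every stage: (optionally) simulate a dataset, call presence,
#' filter to reproducible spots, normalize to equal total spot density,
#' compute pairwise bootstrap significance, derive FC/RC effect sizes, run
#' PCA on the significant spots, and aggregate the report. Identical inputs
#' and seeds give identical outputs; when `out_dir` is given every
#' intermediate table plus `report.json` / `report.md` are written there.
#'
#' @param table,design A spot table and design, or `NULL` when `generator`
#'   is supplied.
#' @param generator A [generator_config()]; when given, `table`/`design`
#'   are simulated from it.
#' @param min_present_replicates Reproducibility threshold (default 3).
#' @param presence_scope `"any"` (default) or `"all"`; see
#'   [filter_reproducible()].
#' @param normalization_constant See [normalize_total_density()].
#' @param settings A [bootstrap_settings()].
#' @param pca_scale Correlation (`TRUE`) vs covariance (`FALSE`, default)
#'   PCA.
#' @param out_dir Optional output directory.
#' @return A `gelquant_pipeline` list: `table_raw`, `design`, `truth`
#'   (generator runs only), `presence`, `table_filtered`,
#'   `table_normalized`, `results`, `effects`, `pca` (`NULL` when nothing
#'   is significant), `report`.
#' @examples
#' \donttest{
#' fit <- run_pipeline(generator = generator_config(n_spots = 60, seed = 7),
#'                     settings = bootstrap_settings(B = 200, seed = 7))
#' fit$report
#' }
#' @export
run_pipeline <- function(table = NULL, design = NULL, generator = NULL,
                         min_present_replicates = 3,
                         presence_scope = c("any", "all"),
                         normalization_constant = "mean-total",
                         settings = bootstrap_settings(),
                         pca_scale = FALSE, out_dir = NULL) {
  presence_scope <- match.arg(presence_scope)
  truth <- NULL
  if (!is.null(generator)) {
    sim <- generate_dataset(generator)
    table <- sim$table
    design <- sim$design
    truth <- sim$truth
  }
  if (is.null(table) || is.null(design)) {
    abort("Provide `table` and `design`, or a `generator` config.",
          class = "gelquant_config_error")
  }
  table <- as_spot_table(table)
  design <- as_experiment_design(design)

  presence <- call_presence(table, design, min_present_replicates)
  filtered <- filter_reproducible(table, presence, scope = presence_scope)
  normalized <- normalize_total_density(filtered, normalization_constant)
  results <- pairwise_significance(normalized, design, presence, settings)
  effects <- compute_effects(results)

  sig_spots <- unique(results$spot_id[results$significant %in% TRUE])
  pca <- if (length(sig_spots) >= 1) {
    run_pca(normalized, design, scale = pca_scale, spots = sig_spots)
  } else NULL

  config_echo <- list(
    min_present_replicates = min_present_replicates,
    presence_scope = presence_scope,
    normalization_constant = normalization_constant,
    bootstrap = unclass(settings),
    pca_scale = pca_scale,
    generator = if (!is.null(generator)) unclass(generator) else NULL
  )
  report <- summarize_analysis(presence, results, effects, pca, config_echo)

  out <- structure(list(table_raw = table, design = design, truth = truth,
                        presence = presence, table_filtered = filtered,
                        table_normalized = normalized, results = results,
                        effects = effects, pca = pca, report = report),
                   class = "gelquant_pipeline")
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_spot_table(table, file.path(out_dir, "spot_table_raw.csv"))
    write_design(design, file.path(out_dir, "design.csv"))
    write_spot_table(normalized, file.path(out_dir, "spot_table_normalized.csv"))
    readr::write_csv(presence, file.path(out_dir, "presence.csv"), na = "")
    readr::write_csv(results, file.path(out_dir, "pairwise_results.csv"), na = "")
    readr::write_csv(effects, file.path(out_dir, "effects.csv"), na = "")
    if (!is.null(truth)) {
      readr::write_csv(truth$spots, file.path(out_dir, "truth_spots.csv"), na = "")
      readr::write_csv(truth$groups, file.path(out_dir, "truth_groups.csv"), na = "")
    }
    render_report(report, out_dir)
  }
  out
}

#' @export
print.gelquant_pipeline <- function(x, ...) {
  cat("gelquant pipeline run\n")
  print(x$report)
  invisible(x)
}

#' @rdname run_pipeline
#' @param x A `gelquant_pipeline`.
#' @param ... Unused.
#' @export
glance.gelquant_pipeline <- function(x, ...) {
  glance(x$report)
}
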
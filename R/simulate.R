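#' Configuration of the synthetic spot-table generator
#'
#' The generator emulates the structure of a comparative 2-DE study: a few
#' hundred reproducible spots quantified on replicate gels of several
#' cultivars, a minority of spots with a true abundance difference in one
#' group, occasional spots entirely absent from one group (which downstream
#' become "unique" spots with infinite fold change), random per-gel
#' detection dropout, and multiplicative gel-to-gel variation in total
#' stain intensity (what total-density normalization removes).
#'
#' Volumes are log-normal: the expected volume of spot s on gel g is
#' `baseline_s * multiplier_{s,group(g)} * scale_g`, with replicate
#' coefficient of variation `cv_replicate` on top. Differential spots have
#' their multiplier shifted by `2^e` in one randomly chosen group, with `e`
#' drawn uniformly from `effect_log2` and an up/down direction chosen with
#' probability one half.
#'
#' @param n_spots Number of spots (default 345, the scale of the emulated
#'   study).
#' @param groups Character vector of group (cultivar) names; default three
#'   groups.
#' @param replicates Biological replicate gels per group (default 4).
#' @param frac_differential Fraction of spots with a true group effect
#'   (default 0.22).
#' @param effect_log2 Length-2 range of the absolute log2 effect size for
#'   differential spots (default `c(0.5, 2)`; drawn uniformly).
#' @param cv_replicate Within-group coefficient of variation of volumes
#'   (default 0.25).
#' @param dropout_prob Probability that a truly present spot goes undetected
#'   on a given gel (default 0.05).
#' @param frac_unique Fraction of spots truly absent from one group
#'   (default 0.03).
#' @param gel_scale_sd Standard deviation, on the log scale, of the per-gel
#'   log-normal total-intensity scaling (default 0.2).
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of the
#'   per-spot baseline volumes (arbitrary densitometric units).
#' @param with_coordinates Attach synthetic per-spot gel coordinates
#'   (`pI_obs` uniform on pH 4-7, `Mr_obs_kDa` uniform on 15-200 kDa)?
#' @param seed Integer master seed; all stages derive their randomness from
#'   it deterministically.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_spots = 345,
                             groups = c("A", "B", "C"),
                             replicates = 4,
                             frac_differential = 0.22,
                             effect_log2 = c(0.5, 2),
                             cv_replicate = 0.25,
                             dropout_prob = 0.05,
                             frac_unique = 0.03,
                             gel_scale_sd = 0.2,
                             baseline_meanlog = log(5000),
                             baseline_sdlog = 1,
                             with_coordinates = TRUE,
                             seed = 1L) {
  cfg <- list(n_spots = as.integer(n_spots), groups = as.character(groups),
              replicates = as.integer(replicates),
              frac_differential = frac_differential, effect_log2 = effect_log2,
              cv_replicate = cv_replicate, dropout_prob = dropout_prob,
              frac_unique = frac_unique, gel_scale_sd = gel_scale_sd,
              baseline_meanlog = baseline_meanlog,
              baseline_sdlog = baseline_sdlog,
              with_coordinates = isTRUE(with_coordinates),
              seed = as.integer(seed))
  validate_generator_config(cfg)
}

validate_generator_config <- function(cfg) {
  stopifnot(cfg$n_spots >= 1, length(cfg$groups) >= 2, cfg$replicates >= 2,
            cfg$cv_replicate > 0, length(cfg$effect_log2) == 2)
  for (f in c("frac_differential", "dropout_prob", "frac_unique")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) {
      abort(paste0("`", f, "` must lie in [0, 1]."),
            class = "gelquant_config_error")
    }
  }
  if (cfg$frac_differential + cfg$frac_unique > 1) {
    abort("`frac_differential` + `frac_unique` must not exceed 1.",
          class = "gelquant_config_error")
  }
  if (cfg$gel_scale_sd < 0) {
    abort("`gel_scale_sd` must be non-negative.", class = "gelquant_config_error")
  }
  structure(cfg, class = "generator_config")
}

#' Generate a synthetic spot-volume dataset with ground truth
#'
#' Draws a full spots-by-gels volume table, the matching experiment design,
#' and a ground-truth record of which spots carry a true effect, suitable
#' for validating the reproducibility filter, normalization, bootstrap
#' significance calls and effect statistics. Identical configurations
#' (including the seed) produce identical datasets.
#'
#' @param config A [generator_config()].
#' @return A list of class `synthetic_dataset` with elements `table` (a
#'   [as_spot_table()] tibble), `design` (an [as_experiment_design()]),
#'   and `truth` (see Details).
#' @details `truth` is a list with `spots` (one row per spot: `spot_id`,
#'   `label` in `null`/`differential`/`unique`, `baseline`, signed
#'   `effect_log2`, `affected_group`, `excluded_group`) and `groups` (one
#'   row per spot-group: `multiplier`, `present` — the true presence flag;
#'   unique spots are never detected in their excluded group).
#' @export
generate_dataset <- function(config = generator_config()) {
  cfg <- validate_generator_config(unclass(config))
  set.seed(cfg$seed)
  stage_seed <- sample.int(.Machine$integer.max - 1L, 5L)

  n <- cfg$n_spots
  G <- length(cfg$groups)
  spot_id <- sprintf("spot_%04d", seq_len(n))
  gel_tbl <- tidyr::expand_grid(group = cfg$groups, replicate = seq_len(cfg$replicates))
  gel_tbl$gel_id <- paste0(gel_tbl$group, "_r", gel_tbl$replicate)
  design <- as_experiment_design(gel_tbl[c("gel_id", "group", "replicate")])

  # stage 1: baselines and truth labels
  set.seed(stage_seed[1])
  baseline <- rlnorm(n, cfg$baseline_meanlog, cfg$baseline_sdlog)
  n_unique <- round(cfg$frac_unique * n)
  n_diff <- round(cfg$frac_differential * n)
  shuffled <- sample.int(n)
  idx_unique <- sort(shuffled[seq_len(n_unique)])
  idx_diff <- sort(shuffled[n_unique + seq_len(n_diff)])
  label <- rep("null", n)
  label[idx_unique] <- "unique"
  label[idx_diff] <- "differential"

  set.seed(stage_seed[2])
  affected <- rep(NA_character_, n)
  excluded <- rep(NA_character_, n)
  eff <- rep(NA_real_, n)
  if (n_diff > 0) {
    affected[idx_diff] <- sample(cfg$groups, n_diff, replace = TRUE)
    mag <- runif(n_diff, cfg$effect_log2[1], cfg$effect_log2[2])
    dir <- sample(c(-1, 1), n_diff, replace = TRUE)
    eff[idx_diff] <- mag * dir
  }
  if (n_unique > 0) {
    excluded[idx_unique] <- sample(cfg$groups, n_unique, replace = TRUE)
  }

  multiplier <- matrix(1, n, G, dimnames = list(spot_id, cfg$groups))
  present <- matrix(TRUE, n, G, dimnames = list(spot_id, cfg$groups))
  for (i in idx_diff) multiplier[i, affected[i]] <- 2^eff[i]
  for (i in idx_unique) present[i, excluded[i]] <- FALSE

  # stage 2: per-gel total-intensity scaling
  set.seed(stage_seed[3])
  gel_scale <- rlnorm(nrow(design), 0, cfg$gel_scale_sd)
  names(gel_scale) <- design$gel_id

  # stage 3: replicate noise around expected volume (mean parameterization)
  set.seed(stage_seed[4])
  sdlog_rep <- sqrt(log(1 + cfg$cv_replicate^2))
  vol <- matrix(NA_real_, n, nrow(design),
                dimnames = list(spot_id, design$gel_id))
  for (j in seq_len(nrow(design))) {
    g <- as.character(design$group[j])
    mu <- baseline * multiplier[, g] * gel_scale[j]
    vol[, j] <- rlnorm(n, log(mu) - sdlog_rep^2 / 2, sdlog_rep)
    vol[!present[, g], j] <- NA_real_
  }

  # stage 4: detection dropout, independent per (spot, gel)
  set.seed(stage_seed[5])
  if (cfg$dropout_prob > 0) {
    drop <- matrix(runif(length(vol)) < cfg$dropout_prob, nrow(vol))
    vol[drop] <- NA_real_
  }

  tbl <- tibble::tibble(spot_id = spot_id)
  for (j in seq_len(ncol(vol))) tbl[[colnames(vol)[j]]] <- vol[, j]
  if (cfg$with_coordinates) {
    tbl$pI_obs <- round(runif(n, 4, 7), 2)
    tbl$Mr_obs_kDa <- round(runif(n, 15, 200), 1)
  }

  truth <- list(
    spots = tibble::tibble(spot_id = spot_id, label = label,
                           baseline = baseline, effect_log2 = eff,
                           affected_group = affected,
                           excluded_group = excluded),
    groups = tidyr::expand_grid(spot_id = spot_id, group = cfg$groups) |>
      dplyr::mutate(multiplier = multiplier[cbind(.data$spot_id, .data$group)],
                    present = present[cbind(.data$spot_id, .data$group)])
  )
  class(truth) <- "synthetic_truth"

  structure(list(table = as_spot_table(tbl), design = design, truth = truth,
                 config = cfg),
            class = "synthetic_dataset")
}

#' Confusion counts of significance calls against synthetic ground truth
#'
#' For each group pair, a spot is truly changed when its two true group
#' multipliers differ or its true presence flags differ (unique spots).
#' Each spot in `results` is counted exactly once per pair; `NA`
#' significance (spot absent from both groups of the pair) counts as a
#' negative call.
#'
#' @param truth The `truth` element of a [generate_dataset()] result.
#' @param results A [pairwise_significance()] tibble computed on the same
#'   dataset.
#' @return A tibble with one row per pair: `TP`, `FP`, `TN`, `FN`.
#' @export
truth_confusion <- function(truth, results) {
  missing_spots <- setdiff(unique(results$spot_id), truth$spots$spot_id)
  if (length(missing_spots) > 0) {
    abort(paste0("Spot(s) in results but not in truth: ",
                 paste(utils::head(missing_spots, 5), collapse = ", ")),
          class = "gelquant_consistency_error")
  }
  tg <- truth$groups
  joined <- results |>
    dplyr::left_join(dplyr::rename(tg, group_x = "group", mult_x = "multiplier",
                                   pres_x = "present"),
                     by = c("spot_id", "group_x")) |>
    dplyr::left_join(dplyr::rename(tg, group_y = "group", mult_y = "multiplier",
                                   pres_y = "present"),
                     by = c("spot_id", "group_y")) |>
    dplyr::mutate(
      truly_changed = .data$mult_x != .data$mult_y | .data$pres_x != .data$pres_y,
      called = .data$significant %in% TRUE
    )
  joined |>
    dplyr::group_by(.data$pair) |>
    dplyr::summarise(
      TP = sum(.data$called & .data$truly_changed),
      FP = sum(.data$called & !.data$truly_changed),
      TN = sum(!.data$called & !.data$truly_changed),
      FN = sum(!.data$called & .data$truly_changed),
      .groups = "drop"
    )
}
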
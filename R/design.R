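#' Experiment designs
#'
#' An experiment design maps each gel to the biological group (here,
#' cultivar) it belongs to and a replicate index within that group. Groups
#' define the pairwise comparisons; the study design this package emulates
#' is 3 cultivars with 4 biological replicate gels each.
#'
#' @param x A data frame with columns `gel_id`, `group` and optionally
#'   `replicate`. Replicate indices are auto-assigned in row order within
#'   each group when absent.
#' @return An `experiment_design` tibble with columns `gel_id`, `group`
#'   (factor, levels in order of first appearance) and `replicate` (integer).
#' @examples
#' des <- as_experiment_design(data.frame(
#'   gel_id = c("g1", "g2", "g3", "g4"),
#'   group = c("A", "A", "B", "B")
#' ))
#' group_pairs(des)
#' @export
as_experiment_design <- function(x) {
  x <- tibble::as_tibble(x)
  need <- c("gel_id", "group")
  if (!all(need %in% names(x))) {
    if (ncol(x) >= 2) {
      names(x)[1:2] <- need
    } else {
      abort("A design needs `gel_id` and `group` columns.",
            class = "gelquant_format_error")
    }
  }
  x$gel_id <- as.character(x$gel_id)
  dup <- x$gel_id[duplicated(x$gel_id)]
  if (length(dup) > 0) {
    abort(paste0("Gel(s) assigned more than once: ",
                 paste(unique(dup), collapse = ", ")),
          class = "gelquant_format_error")
  }
  x$group <- factor(as.character(x$group), levels = unique(as.character(x$group)))
  sizes <- table(x$group)
  if (length(sizes) < 2) {
    abort("A design needs at least two groups.", class = "gelquant_validation_error")
  }
  if (any(sizes < 2)) {
    abort(paste0("Group(s) with fewer than 2 gels: ",
                 paste(names(sizes)[sizes < 2], collapse = ", ")),
          class = "gelquant_validation_error")
  }
  if (!"replicate" %in% names(x)) {
    x <- x |>
      dplyr::group_by(.data$group) |>
      dplyr::mutate(replicate = dplyr::row_number()) |>
      dplyr::ungroup()
  }
  x$replicate <- as.integer(x$replicate)
  x <- x[c("gel_id", "group", "replicate")]
  structure(x, class = c("experiment_design", class(tibble::tibble())))
}

#' @rdname as_experiment_design
#' @param path Path to a CSV/TSV file with header `gel_id, group[, replicate]`.
#' @param dialect `"csv"` or `"tsv"` (default guessed from the extension).
#' @export
read_design <- function(path, dialect = NULL) {
  dialect <- dialect %||% guess_dialect(path)
  x <- readr::read_delim(path, delim = delim_for(dialect),
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  as_experiment_design(x)
}

#' @rdname as_experiment_design
#' @param design An `experiment_design`.
#' @export
write_design <- function(design, path, dialect = NULL) {
  dialect <- dialect %||% guess_dialect(path)
  readr::write_delim(design, path, delim = delim_for(dialect), na = "")
  invisible(path)
}

#' All ordered group pairs of a design
#'
#' Pairs follow the group order of the design: for groups (A, B, C) the
#' pairs are A-B, A-C, B-C. In each pair the first group plays the role of
#' x and the second of y in the difference of means DV = mean_y - mean_x.
#'
#' @param design An `experiment_design`.
#' @return A tibble with columns `group_x`, `group_y`, `pair`.
#' @export
group_pairs <- function(design) {
  g <- levels(design$group)
  cmb <- combn(g, 2)
  tibble::tibble(group_x = cmb[1, ], group_y = cmb[2, ],
                 pair = paste(cmb[1, ], cmb[2, ], sep = "-"))
}

gels_of_group <- function(design, group) {
  design$gel_id[design$group == group]
}
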
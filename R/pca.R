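#' Principal component analysis of spot volumes across gels
#'
#' PCA with gels as observations and spots as variables, typically run on
#' the differentially abundant spot subset to visualize how replicate gels
#' cluster by group. Missing entries are imputed as 0 before decomposition:
#' absence is informative (a spot unique to one group separates that group).
#' The matrix is column-centered; unit-variance scaling is off by default
#' (covariance PCA) and available via `scale = TRUE` (correlation PCA).
#' Component signs are fixed by forcing the largest-magnitude loading of
#' each component positive, so results are reproducible across platforms.
#'
#' @param table A [as_spot_table()] tibble (restrict to the spots of
#'   interest first, or pass `spots`).
#' @param design The matching [as_experiment_design()].
#' @param scale Unit-variance scale the spot columns? Default `FALSE`.
#' @param spots Optional character vector of spot ids to restrict to.
#' @return A `spot_pca` object: `scores` (tibble gel_id, group, PC1..),
#'   `loadings` (tibble spot_id, PC1..), `variance` (tibble component,
#'   variance_fraction, cumulative), plus `center`, `scale_values`, `sdev`.
#' @export
run_pca <- function(table, design, scale = FALSE, spots = NULL) {
  check_paired(table, design)
  if (!is.null(spots)) table <- table[table$spot_id %in% spots, , drop = FALSE]
  m <- volume_matrix(table)
  if (ncol(m) < 2) {
    abort("PCA needs at least 2 observations (gels).",
          class = "gelquant_input_error")
  }
  if (nrow(m) < 1) {
    abort("PCA needs at least 1 spot.", class = "gelquant_input_error")
  }
  X <- t(m)                       # gels x spots
  X[is.na(X)] <- 0
  if (scale) {
    sds <- apply(X, 2, sd)
    if (any(sds == 0)) {
      warn(paste0("Dropping ", sum(sds == 0),
                  " zero-variance spot(s) before correlation PCA."))
      X <- X[, sds > 0, drop = FALSE]
    }
  }
  pr <- prcomp(X, center = TRUE, scale. = scale)
  # sign convention: largest-|loading| entry of each component is positive
  for (k in seq_len(ncol(pr$rotation))) {
    i <- which.max(abs(pr$rotation[, k]))
    if (pr$rotation[i, k] < 0) {
      pr$rotation[, k] <- -pr$rotation[, k]
      pr$x[, k] <- -pr$x[, k]
    }
  }
  vf <- pr$sdev^2 / sum(pr$sdev^2)
  scores <- tibble::as_tibble(pr$x, rownames = "gel_id") |>
    dplyr::left_join(design[c("gel_id", "group")], by = "gel_id") |>
    dplyr::relocate("group", .after = "gel_id")
  loadings <- tibble::as_tibble(pr$rotation, rownames = "spot_id")
  structure(list(
    scores = scores, loadings = loadings,
    variance = tibble::tibble(component = paste0("PC", seq_along(vf)),
                              variance_fraction = vf,
                              cumulative = cumsum(vf)),
    center = pr$center, scale_values = if (scale) pr$scale else NULL,
    sdev = pr$sdev
  ), class = "spot_pca")
}

#' @export
print.spot_pca <- function(x, ...) {
  v <- x$variance$variance_fraction
  cat("PCA of spot volumes:", nrow(x$loadings), "spots x",
      nrow(x$scores), "gels\n")
  cat(sprintf("PC1 %.1f%%, PC2 %.1f%% (first two: %.1f%% of total variance)\n",
              100 * v[1], 100 * v[2], 100 * sum(v[1:2])))
  invisible(x)
}

#' Tidy a spot PCA
#'
#' @param x A [run_pca()] result.
#' @param matrix Which table to return: `"variance"` (default), `"scores"`
#'   or `"loadings"`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.spot_pca <- function(x, matrix = c("variance", "scores", "loadings"), ...) {
  matrix <- match.arg(matrix)
  x[[matrix]]
}

#' @rdname tidy.spot_pca
#' @export
glance.spot_pca <- function(x, ...) {
  v <- x$variance$variance_fraction
  tibble::tibble(
    n_spots = nrow(x$loadings), n_gels = nrow(x$scores),
    n_components = length(v),
    var_pc1 = v[1], var_pc2 = if (length(v) > 1) v[2] else NA_real_,
    var_first_two = sum(v[seq_len(min(2, length(v)))])
  )
}

#' Score plot of a spot PCA
#'
#' PC1-PC2 scatter of gel scores colored by group, axis labels annotated
#' with the variance fraction each component explains.
#'
#' @param object A [run_pca()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spot_pca <- function(object, ...) {
  v <- object$variance$variance_fraction
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(.data$PC1, .data$PC2, colour = .data$group)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", 100 * v[1]),
                  y = sprintf("PC2 (%.1f%%)", 100 * v[2]),
                  colour = "group") +
    ggplot2::theme_minimal()
}
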
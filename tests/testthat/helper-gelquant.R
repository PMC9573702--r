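# Shared fixtures, built in code.

# A small fully-crossed table: 2 groups x 4 replicate gels.
make_table <- function(values = NULL, n_spots = 3, gels = paste0(rep(c("A", "B"), each = 4), "_r", 1:4)) {
  if (is.null(values)) {
    set.seed(99)
    values <- matrix(rlnorm(n_spots * length(gels), log(100), 0.3),
                     n_spots, length(gels))
  }
  df <- data.frame(spot_id = sprintf("s%02d", seq_len(nrow(values))))
  for (j in seq_along(gels)) df[[gels[j]]] <- values[, j]
  as_spot_table(df)
}

make_design <- function(groups = c("A", "B"), replicates = 4) {
  as_experiment_design(data.frame(
    gel_id = paste0(rep(groups, each = replicates), "_r", seq_len(replicates)),
    group = rep(groups, each = replicates)
  ))
}

# Exhaustive resampling distribution of the mean: all n^n with-replacement
# resamples of v (the brute-force oracle for small n).
exhaustive_means <- function(v) {
  n <- length(v)
  idx <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  rowMeans(matrix(v[idx], nrow(idx), n))
}

# Plain mean silhouette on a score matrix with given labels (euclidean);
# independent of any clustering package.
mean_silhouette <- function(X, labels) {
  X <- as.matrix(X)
  D <- as.matrix(dist(X))
  sil <- vapply(seq_len(nrow(X)), function(i) {
    own <- labels == labels[i]
    a <- mean(D[i, own & seq_len(nrow(X)) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(g) mean(D[i, labels == g]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(sil)
}
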
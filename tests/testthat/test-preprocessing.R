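test_that("presence calling applies the at-least-min-replicates rule", {
  vals <- matrix(1, 3, 8)
  tbl <- make_table(values = vals)
  tbl$A_r4[2] <- NA                 # 3 of 4 in group A
  tbl$A_r3[3] <- NA; tbl$A_r4[3] <- NA   # 2 of 4 in group A
  tbl <- as_spot_table(tbl)
  des <- make_design()
  pres <- call_presence(tbl, des, min_present_replicates = 3)
  pa <- dplyr::filter(pres, group == "A")
  expect_identical(pa$n_detected, c(4L, 3L, 2L))
  expect_identical(pa$present, c(TRUE, TRUE, FALSE))
  expect_true(all(dplyr::filter(pres, group == "B")$present))
})

test_that("an explicit zero volume counts as detected", {
  vals <- matrix(1, 1, 8)
  tbl <- make_table(values = vals)
  tbl$A_r1[1] <- 0
  pres <- call_presence(as_spot_table(tbl), make_design(), 3)
  expect_identical(dplyr::filter(pres, group == "A")$n_detected, 4L)
})

test_that("reproducibility filter keeps any-group spots, marks unique ones, drops the rest", {
  vals <- matrix(10, 3, 8)
  tbl <- make_table(values = vals)
  # spot 2: 3/4 in A, 0/4 in B -> retained, unique to A
  tbl$A_r4[2] <- NA
  for (g in paste0("B_r", 1:4)) tbl[[g]][2] <- NA
  # spot 3: 2/4 everywhere -> removed
  for (g in c("A_r1", "A_r2", "B_r1", "B_r2")) tbl[[g]][3] <- NA
  tbl <- as_spot_table(tbl)
  des <- make_design()
  pres <- call_presence(tbl, des, 3)
  kept <- filter_reproducible(tbl, pres)
  expect_identical(kept$spot_id, c("s01", "s02"))
  flags <- dplyr::filter(pres, spot_id == "s02")
  expect_identical(flags$present[flags$group == "A"], TRUE)
  expect_identical(flags$present[flags$group == "B"], FALSE)

  # all-groups scope would drop the unique spot
  kept_all <- filter_reproducible(tbl, pres, scope = "all")
  expect_identical(kept_all$spot_id, "s01")

  # idempotence
  pres2 <- call_presence(kept, des, 3)
  expect_identical(filter_reproducible(kept, pres2), kept)
})

test_that("total-density normalization forces the configured arithmetic", {
  tbl <- as_spot_table(data.frame(spot_id = c("s1", "s2"),
                                  g1 = c(10, 90), g2 = c(10, 190)))
  norm <- normalize_total_density(tbl, constant = 1e6)
  expect_equal(norm$g1[1], 1.0e5)
  expect_equal(norm$g2[1], 5.0e4)
  # already equal totals: relative abundances unchanged, common factor only
  eq <- as_spot_table(data.frame(spot_id = c("s1", "s2"),
                                 g1 = c(30, 70), g2 = c(50, 50)))
  norm_eq <- normalize_total_density(eq, constant = "mean-total")
  expect_equal(volume_matrix(norm_eq), volume_matrix(eq))
})

test_that("per-gel totals are equal after normalization of scaled synthetic data", {
  sim <- generate_dataset(generator_config(n_spots = 80, gel_scale_sd = 0.3,
                                           seed = 21))
  pres <- call_presence(sim$table, sim$design, 3)
  filt <- filter_reproducible(sim$table, pres)
  norm <- normalize_total_density(filt)
  totals <- colSums(volume_matrix(norm), na.rm = TRUE)
  expect_lt(diff(range(totals)) / mean(totals), 1e-9)
})

test_that("normalization is invariant to per-gel rescaling and keeps missingness and presence", {
  sim <- generate_dataset(generator_config(n_spots = 40, seed = 22))
  pres <- call_presence(sim$table, sim$design, 3)
  filt <- filter_reproducible(sim$table, pres)
  norm <- normalize_total_density(filt, constant = 1e6)

  rescaled <- filt
  set.seed(1)
  for (g in gel_ids(filt)) rescaled[[g]] <- filt[[g]] * runif(1, 0.2, 5)
  norm2 <- normalize_total_density(as_spot_table(rescaled), constant = 1e6)
  expect_equal(volume_matrix(norm2), volume_matrix(norm), tolerance = 1e-9)

  # with the mean-total constant the table is invariant up to a common factor
  nm1 <- volume_matrix(normalize_total_density(filt))
  nm2 <- volume_matrix(normalize_total_density(as_spot_table(rescaled)))
  ratio <- nm2 / nm1
  expect_lt(diff(range(ratio, na.rm = TRUE)) / mean(ratio, na.rm = TRUE), 1e-9)

  expect_identical(is.na(volume_matrix(norm)), is.na(volume_matrix(filt)))
  pres_norm <- call_presence(norm, sim$design, 3)
  pres_kept <- dplyr::filter(pres, spot_id %in% norm$spot_id)
  expect_equal(as.data.frame(pres_norm), as.data.frame(pres_kept))
})

test_that("a gel with zero validated total raises an error naming the gel", {
  tbl <- as_spot_table(data.frame(spot_id = c("s1", "s2"),
                                  g1 = c(1, 2), g2 = c(0, NA)))
  expect_error(normalize_total_density(tbl), regexp = "g2",
               class = "gelquant_normalization_error")
})
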
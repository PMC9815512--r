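test_that("fold change reproduces the reported arithmetic", {
  # 35 vs 20 positive cells at equal area is log2(1.75), i.e. +75%
  expect_equal(fold_change(35, 1, 20, 1), log2(1.75))
  expect_equal(percent_change(fold_change(35, 1, 20, 1)), 75)
  expect_equal(fold_change(10, 2, 10, 2), 0)
  # pseudocount path: (0+1) vs (8+1) at equal areas
  expect_equal(fold_change(0, 1, 8, 1, pseudocount = 1), log2(1 / 9))
  # area normalization: same counts, half the area, doubles the density
  expect_equal(fold_change(20, 0.5, 20, 1), 1)
  expect_error(fold_change(0, 1, 0, 1), class = "imdspatial_undefined_value")
  expect_error(fold_change(1, 0, 1, 1), class = "imdspatial_validation_error")
})

test_that("percent change converts log2 fold changes as reported", {
  expect_equal(percent_change(-1), -50)
  expect_equal(percent_change(0), 0)
  expect_equal(percent_change(log2(1.6)), 60)
  expect_error(percent_change(Inf), class = "imdspatial_validation_error")
})

make_counts <- function(fc_tab, null_tab = NULL) {
  # build a condition_counts object from explicit per-tumor counts
  out <- fc_tab
  attr(out, "control_null") <- null_tab
  class(out) <- c("condition_counts", class(out))
  out
}

test_that("effect table aggregates per-tumor fold changes with a t-test vs nulls", {
  fc <- data.frame(tumor_id = paste0("T", 1:3), condition = "drug", marker = "CD8",
                   count_roi = c(44, 52, 38), count_control = c(20, 24, 22),
                   area_roi = 1, area_control = 1)
  nul <- data.frame(tumor_id = paste0("T", 1:3), marker = "CD8",
                    count_a = c(21, 19, 23), area_a = 1,
                    count_b = c(20, 22, 21), area_b = 1)
  et <- effect_table(make_counts(fc, nul))
  x <- log2(c(44 / 20, 52 / 24, 38 / 22))
  y <- log2(c(21 / 20, 19 / 22, 23 / 21))
  expect_equal(et$mean_log2fc, mean(x))
  expect_equal(et$sem, sd(x) / sqrt(3))
  expect_equal(et$percent_change, (2^mean(x) - 1) * 100)
  expect_equal(et$p_value, oracle_t2(x, y))
  w <- effect_table(make_counts(fc, nul), var_equal = FALSE)
  expect_equal(w$p_value, oracle_t2(x, y, var_equal = FALSE))
})

test_that("identical groups give p = 1 and a single tumor gives no p", {
  fc <- data.frame(tumor_id = paste0("T", 1:3), condition = "drug", marker = "CD3",
                   count_roi = c(11, 23, 32), count_control = c(11, 23, 32),
                   area_roi = 1, area_control = 1)
  nul <- data.frame(tumor_id = paste0("T", 1:3), marker = "CD3",
                    count_a = c(11, 23, 32), area_a = 1,
                    count_b = c(11, 23, 32), area_b = 1)
  et <- effect_table(make_counts(fc, nul))
  expect_equal(et$mean_log2fc, 0)
  expect_equal(et$p_value, 1)
  one <- effect_table(make_counts(fc[1, ], nul[1, ]))
  expect_true(is.na(one$p_value))
  expect_equal(one$percent_change, 0)
})

test_that("control-vs-control inputs centre on zero with p near 1 at large n", {
  set.seed(14)
  n <- 60
  a <- rpois(n, 400); b <- rpois(n, 400) # same-rate pseudo condition vs control
  fc <- data.frame(tumor_id = paste0("T", 1:n), condition = "sham", marker = "CD8",
                   count_roi = a, count_control = b, area_roi = 1, area_control = 1)
  nul <- data.frame(tumor_id = paste0("T", 1:n), marker = "CD8",
                    count_a = rpois(n, 400), area_a = 1,
                    count_b = rpois(n, 400), area_b = 1)
  et <- effect_table(make_counts(fc, nul))
  expect_lt(abs(et$mean_log2fc), 0.05)
  expect_gt(et$p_value, 0.1)
})

test_that("per-ring QC flags mark rings deviating 3-fold from neighbours", {
  tum <- gen_device_tumor(perturbation_preset("NULL", seed = 3, n_tumors = 1,
                                              tumor_cell_density = 200))$tumors[[1]]
  # implant a dense artifact in ring 2 of reservoir 1 (distance 600-900 um)
  art <- data.frame(cell_id = -(1:4000),
                    x = runif(4000, 600, 850), y = runif(4000, -50, 50),
                    tumor_id = tum$tumor_id, CD3 = TRUE, CD8 = TRUE,
                    FOXP3 = FALSE, nucleus = TRUE)
  art <- art[sqrt(art$x^2 + art$y^2) >= 600 & sqrt(art$x^2 + art$y^2) < 900, ]
  tum$cells <- rbind(tum$cells, art)
  per <- attr(condition_counts(list(tum)), "per_ring")
  r1 <- per[per$reservoir_id == 1 & per$marker == "CD8", ]
  expect_true(r1$qc_flag[r1$ring_index == 2])
  expect_false(r1$qc_flag[r1$ring_index == 0]) # its only neighbour is normal
})
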
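light_scenario <- function(name, seed, n_tumors = 1) {
  # low tumor-cell density: the background is irrelevant to marker laws
  perturbation_preset(name, seed = seed, n_tumors = n_tumors,
                      tumor_cell_density = 200)
}

test_that("generators are deterministic under a fixed seed", {
  e1 <- gen_device_tumor(light_scenario("ARG_CD8", seed = 5))
  e2 <- gen_device_tumor(light_scenario("ARG_CD8", seed = 5))
  expect_identical(e1$tumors[[1]]$cells, e2$tumors[[1]]$cells)
  s <- metabolomics_scenario(grid_extent = c(6000, 6000), n_hotspots = 2, seed = 9)
  i1 <- gen_ion_image(s); i2 <- gen_ion_image(s)
  expect_identical(i1$image$counts, i2$image$counts)
  expect_identical(i1$cells, i2$cells)
  t1 <- gen_st_rois(st_scenario(seed = 3)); t2 <- gen_st_rois(st_scenario(seed = 3))
  expect_identical(t1$rois, t2$rois)
  expect_identical(t1$expression, t2$expression)
})

test_that("scenario validation rejects impossible conditions", {
  expect_error(perturbation_scenario(marker_effects = c(CD8 = -1)),
               class = "imdspatial_validation_error")
  expect_error(perturbation_scenario(baseline_density = c(CD3 = 50, CD8 = 40, FOXP3 = 30)),
               class = "imdspatial_validation_error") # CD3-only would be negative
  bad_layout <- data.frame(reservoir_id = 1:2, x = c(0, 1000), y = 0,
                           condition = c("drug", "empty"), is_control = c(FALSE, TRUE))
  expect_error(gen_device_tumor(perturbation_preset("ARG_CD8"), layout = bad_layout),
               class = "imdspatial_layout_error")
  expect_error(gen_ion_image(metabolomics_scenario(grid_extent = c(2000, 2000),
                                                   n_hotspots = 4)),
               class = "imdspatial_layout_error")
  expect_error(st_scenario(genes = character(0)), class = "imdspatial_validation_error")
})

test_that("marker flags are nested and tumor cells marker-free", {
  cells <- gen_device_tumor(light_scenario("BSO", seed = 2))$tumors[[1]]$cells
  expect_true(all(cells$CD3[cells$CD8]))
  expect_true(all(cells$CD3[cells$FOXP3]))
  expect_false(any(cells$CD8 & cells$FOXP3))
  expect_true(all(cells$nucleus))
})

test_that("empirical marker density follows the planted intensity law", {
  # 100 replicate tumors; ARG_CD8 plants +75% on CD8 inside the ROI only
  n_rep <- 100
  lam_in <- 60 * 1.75; lam_out <- 60
  dens_cond <- dens_ring0 <- dens_ring3 <- dens_ctrl <- dens_cd3 <- numeric(n_rep)
  spec <- ring_spec()
  for (i in seq_len(n_rep)) {
    tum <- gen_device_tumor(light_scenario("ARG_CD8", seed = 1000 + i))$tumors[[1]]
    cc <- condition_counts(list(tum), spec)
    per <- attr(cc, "per_ring")
    cd8 <- cc[cc$marker == "CD8", ]
    dens_cond[i] <- cd8$count_roi / cd8$area_roi
    dens_ctrl[i] <- cd8$count_control / cd8$area_control
    pr <- per[per$marker == "CD8" & !per$is_control, ]
    dens_ring0[i] <- pr$density[pr$ring_index == 0]
    dens_ring3[i] <- pr$density[pr$ring_index == 3]
    cd3 <- cc[cc$marker == "CD3", ]
    dens_cd3[i] <- cd3$count_roi / cd3$area_roi
  }
  within3se <- function(x, target) abs(mean(x) - target) < 3 * sd(x) / sqrt(length(x))
  expect_true(within3se(dens_cond, lam_in))   # pooled ROI at lambda(0..1200)
  expect_true(within3se(dens_ring0, lam_in))  # flat kernel: every ring at lam_in
  expect_true(within3se(dens_ring3, lam_in))
  expect_true(within3se(dens_ctrl, lam_out))  # controls at baseline
  # the CD3 law has effect 0 in ARG_CD8, so total CD3 density stays at
  # baseline even though its CD8+ subset is enriched
  expect_true(within3se(dens_cd3, 150))
})

test_that("null scenario leaves ROI and control densities equal", {
  et <- run_perturbation(gen_device_tumor(perturbation_preset("NULL", seed = 21)))
  ratio <- 2^et$mean_log2fc
  expect_true(all(abs(ratio - 1) < 0.1))
})

test_that("ARG_CD8 raises CD8 density near the reservoir above control", {
  cc <- condition_counts(gen_device_tumor(light_scenario("ARG_CD8", seed = 31, n_tumors = 2)))
  cd8 <- cc[cc$marker == "CD8", ]
  expect_true(all(cd8$count_roi / cd8$area_roi > cd8$count_control / cd8$area_control))
})

test_that("ion counts match the stated overdispersion on a null grid", {
  # 100 x 100 null grid, no field, no effects: variance = mu + phi * mu^2
  phi <- 0.1
  sim <- gen_ion_image(metabolomics_scenario(
    metabolites = "glutathione", n_hotspots = 1, metabolite_effects = c(glutathione = 0),
    grid_extent = c(12500, 12500), count_noise = phi, field_sd = 0, seed = 17))
  x <- as.vector(sim$image$counts[, , "glutathione"])
  expect_length(x, 10000L)
  mu <- mean(x)
  expect_equal(var(x), mu + phi * mu^2, tolerance = 0.1)
})

test_that("hotspot centres respect the pairwise-separation guarantee", {
  for (seed in 1:3) {
    sim <- gen_ion_image(metabolomics_scenario(n_hotspots = 6, seed = seed,
                                               metabolites = "citrate"))
    d <- as.matrix(dist(sim$hotspots))
    expect_true(all(d[upper.tri(d)] >= 4 * 400))
  }
})

test_that("ST ROI generation honours the class composition bands", {
  st <- gen_st_rois(st_scenario(class_counts = c(high = 9, intermediate = 12, low = 9),
                                seed = 4))
  expect_equal(nrow(st$rois), 30L)
  expect_equal(sum(st$rois$positive_index > 0.20), 9L)
  expect_equal(sum(st$rois$positive_index > 0.05 & st$rois$positive_index <= 0.20), 12L)
  expect_equal(sum(st$rois$positive_index < 0.05), 9L)
  expect_equal(as.integer(table(st$rois$cd8_class)[c("high", "intermediate", "low")]),
               c(9L, 12L, 9L))
  one <- gen_st_rois(st_scenario(class_counts = c(high = 0, intermediate = 0, low = 1)))
  expect_equal(one$rois$cd8_class, "low")
})

test_that("null ST scenario has no class-wise expression shift", {
  st <- gen_st_rois(st_preset("NULL", seed = 8))
  hi <- st$rois$cd8_class == "high"; lo <- st$rois$cd8_class == "low"
  diff <- rowMeans(log2(st$expression[, hi])) - rowMeans(log2(st$expression[, lo]))
  expect_lt(max(abs(mean(diff))), 0.05)
  expect_lt(max(abs(diff)), 0.6) # 0.25 log2 noise, n = 9 per class
})
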
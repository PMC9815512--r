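grid25 <- list(pixel_size = 200, origin = c(0, 0), nx = 25, ny = 25)

test_that("density maps conserve mass and match the per-pixel oracle", {
  one <- data.frame(x = 2500, y = 2500, CD8 = TRUE)
  m <- density_map(one, "CD8", grid25, bandwidth = 300)
  px_area <- 200^2 / 1e6
  expect_equal(sum(m$values) * px_area, 1, tolerance = 1e-6)
  # edge cell still integrates to one (edge correction)
  edge <- density_map(data.frame(x = 50, y = 4950, CD8 = TRUE), "CD8", grid25, 300)
  expect_equal(sum(edge$values) * px_area, 1, tolerance = 1e-6)
  # two far-apart cells give two symmetric modes
  two <- density_map(data.frame(x = c(1000, 4000), y = c(1000, 4000), CD8 = TRUE),
                     "CD8", grid25, 300)
  # symmetric modes at the two cells (pixel (5,5) covers 800-1000 um, etc.)
  expect_equal(two$values[5, 5], max(two$values))
  expect_equal(two$values[20, 20], max(two$values))
  # 200 random cells: full grid equals the brute-force kernel evaluation
  set.seed(23)
  cells <- data.frame(x = runif(200, 0, 5000), y = runif(200, 0, 5000), CD8 = TRUE)
  got <- density_map(cells, "CD8", grid25, bandwidth = 250)
  want <- oracle_density_map(cells, grid25, 250)
  expect_equal(got$values, want, tolerance = 1e-10)
  expect_equal(sum(got$values) * px_area, 200, tolerance = 1e-6)
  expect_warning(z <- density_map(cells[0, ], "CD8", grid25), "all zero")
  expect_true(all(z$values == 0))
})

test_that("hotspot detection recovers planted clusters and ignores flat maps", {
  sim <- gen_ion_image(metabolomics_scenario(n_hotspots = 1, seed = 41,
                                             grid_extent = c(6000, 6000),
                                             metabolites = "citrate"))
  map <- density_map(sim$cells, "CD8", sim$image)
  hs <- detect_hotspots(map, sim$cells)
  expect_equal(nrow(hs), 1L)
  expect_lt(sqrt((hs$x - sim$hotspots$x)^2 + (hs$y - sim$hotspots$y)^2),
            sim$image$pixel_size)
  # uniform map: strict super-quantile set is empty
  flat <- map; flat$values <- matrix(1, map$ny, map$nx)
  expect_equal(nrow(detect_hotspots(flat)), 0L)
  expect_error(detect_hotspots(map, quantile = 1.2),
               class = "imdspatial_validation_error")
  # the six planted hotspots of the CD8 preset are all recovered
  sim6 <- gen_ion_image(metabolomics_preset("CD8_HOTSPOT", seed = 42))
  hs6 <- detect_hotspots(density_map(sim6$cells, "CD8", sim6$image), sim6$cells)
  expect_equal(nrow(hs6), 6L)
  d <- sqrt(outer(hs6$x, sim6$hotspots$x, "-")^2 + outer(hs6$y, sim6$hotspots$y, "-")^2)
  expect_true(all(apply(d, 2, min) < sim6$image$pixel_size))
})

test_that("pairing applies the fold, overlap and separation rules", {
  grid <- list(pixel_size = 100, origin = c(0, 0), nx = 100, ny = 100)
  hs <- data.frame(roi_id = 1L, x = 3000, y = 3000, radius = 400,
                   area_mm2 = pi * 0.16, n_pixels = 50, marker = "CD8",
                   marker_count = NA_real_)
  mk_cells <- function(n_hot, n_low, low_x) {
    rbind(data.frame(x = rnorm(n_hot, 3000, 150), y = rnorm(n_hot, 3000, 150), CD8 = TRUE),
          data.frame(x = rnorm(n_low, low_x, 150), y = rnorm(n_low, 3000, 150), CD8 = TRUE))
  }
  set.seed(5)
  # 40 vs ~20 cells: log2 ratio ~ 1 >= 0.5 -> accepted
  p1 <- pair_rois(hs, mk_cells(40, 20, 6000), grid)
  expect_equal(nrow(p1), 1L)
  expect_gte(p1$count_log2fc, 0.5)
  expect_gte(p1$separation, 2 * p1$radius) # no overlap with the hotspot
  expect_equal(p1$area_ratio, 1)
  # uniform lattice of marker cells: every candidate matches the hotspot
  # count almost exactly, so the fold rule can never be met
  lat <- expand.grid(x = seq(25, 9975, by = 50), y = seq(25, 9975, by = 50))
  lat$CD8 <- TRUE
  expect_message(p2 <- pair_rois(hs, lat, grid), "no valid low-region candidate")
  expect_equal(nrow(p2), 0L)
  expect_equal(nrow(pair_rois(hs[0, ], dense, grid)), 0L)
})

test_that("every emitted pair satisfies the pairing constraints on re-check", {
  sim <- gen_ion_image(metabolomics_preset("CD8_HOTSPOT", seed = 7))
  hs <- detect_hotspots(density_map(sim$cells, "CD8", sim$image), sim$cells)
  pr <- pair_rois(hs, sim$cells, sim$image, min_fold = 0.5, max_separation = 3000)
  expect_gt(nrow(pr), 1L)
  for (i in seq_len(nrow(pr))) {
    nh <- sum(sim$cells$CD8 &
                (sim$cells$x - pr$high_x[i])^2 + (sim$cells$y - pr$high_y[i])^2
              <= pr$radius[i]^2)
    nl <- sum(sim$cells$CD8 &
                (sim$cells$x - pr$low_x[i])^2 + (sim$cells$y - pr$low_y[i])^2
              <= pr$radius[i]^2)
    expect_gte(log2((nh + 0.5) / (nl + 0.5)), 0.5)
    expect_lte(pr$separation[i], 3000)
    # disjoint from every hotspot disc and every other accepted low disc
    d_hot <- sqrt((hs$x - pr$low_x[i])^2 + (hs$y - pr$low_y[i])^2)
    expect_true(all(d_hot >= hs$radius + pr$radius[i]))
    d_low <- sqrt((pr$low_x[-i] - pr$low_x[i])^2 + (pr$low_y[-i] - pr$low_y[i])^2)
    if (length(d_low)) expect_true(all(d_low >= 2 * pr$radius[i]))
  }
})

test_that("ion-count extraction equals the exhaustive pixel-centre oracle", {
  img <- make_test_image(2, 2, 100, list(glc = matrix(1:4, 2, 2)))
  roi_all <- list(x = 100, y = 100, radius = 120)
  got <- extract_ion_counts(img, roi_all)
  expect_equal(got$total, 10)
  expect_equal(got$mean, 2.5)
  expect_equal(got$n_pixels, 4L)
  one <- extract_ion_counts(img, list(x = 50, y = 50, radius = 10))
  expect_equal(one$total, 1) # bottom-left pixel only
  expect_error(extract_ion_counts(img, list(x = 1e5, y = 1e5, radius = 50)),
               class = "imdspatial_validation_error")
  # random ROI on a random grid vs brute-force pixel-centre test
  set.seed(31)
  img2 <- make_test_image(30, 20, 50, list(a = matrix(rpois(600, 40), 20, 30),
                                           b = matrix(rpois(600, 9), 20, 30)))
  roi <- list(x = 700, y = 480, radius = 260)
  got2 <- extract_ion_counts(img2, roi)
  for (ch in c("a", "b")) {
    tot <- 0; npx <- 0
    for (i in 1:20) for (j in 1:30) {
      cx <- (j - 0.5) * 50; cy <- (i - 0.5) * 50
      if ((cx - roi$x)^2 + (cy - roi$y)^2 <= roi$radius^2) {
        tot <- tot + as.numeric(img2$counts[i, j, ch]); npx <- npx + 1
      }
    }
    expect_equal(got2$total[got2$metabolite == ch], tot)
    expect_equal(got2$n_pixels[got2$metabolite == ch], npx)
  }
})

test_that("paired statistics match the one-sample t oracle and flag planted effects", {
  sim <- gen_ion_image(metabolomics_preset("CD8_HOTSPOT", seed = 3))
  hs <- detect_hotspots(density_map(sim$cells, "CD8", sim$image), sim$cells)
  pr <- pair_rois(hs, sim$cells, sim$image)
  st <- paired_stats(pr, sim$image)
  # planted channels recovered significant-positive
  for (m in c("glutathione", "N-acetyl-cysteine")) {
    row <- st[st$metabolite == m, ]
    expect_true(row$significant)
    expect_gt(row$mean_log2fc, 0.5)
  }
  # BH adjustment: monotone in rank order and >= raw p
  expect_true(all(st$adjusted_p >= st$p_value))
  o <- order(st$p_value)
  expect_true(all(diff(st$adjusted_p[o]) >= -1e-12))
  # t p-value equals the closed form on the recomputed pair differences
  d <- vapply(seq_len(nrow(pr)), function(i) {
    hi <- extract_ion_counts(sim$image, list(x = pr$high_x[i], y = pr$high_y[i],
                                             radius = pr$radius[i]))
    lo <- extract_ion_counts(sim$image, list(x = pr$low_x[i], y = pr$low_y[i],
                                             radius = pr$radius[i]))
    log2((hi$mean[hi$metabolite == "citrate"] + 0.5) /
           (lo$mean[lo$metabolite == "citrate"] + 0.5))
  }, numeric(1))
  expect_equal(st$p_value[st$metabolite == "citrate"], oracle_t1(d))
  # identical high/low counts in every pair -> log2FC 0, p = 1
  flat_img <- sim$image
  flat_img$counts[] <- 100
  st0 <- paired_stats(pr, flat_img)
  expect_true(all(st0$mean_log2fc == 0))
  expect_true(all(st0$p_value == 1))
  expect_error(paired_stats(pr[1, ], sim$image), class = "imdspatial_validation_error")
})

test_that("hypergeometric ORA equals exhaustive enumeration", {
  universe <- sprintf("m%02d", 1:20)
  sets <- list(path_a = universe[1:5])
  sig <- universe[c(1, 2, 3, 10)] # overlap 3 with a 5-member set
  res <- pathway_ora(sig, universe, sets)
  expect_equal(res$p_value, 155 / 4845, tolerance = 1e-12)
  expect_equal(res$p_value, oracle_hyper_tail(20, 5, 4, 3))
  # zero overlap with a tiny set: P(X >= 0) = 1
  res0 <- pathway_ora(universe[10:12], universe, list(s = universe[1:2]))
  expect_equal(res0$p_value, 1)
  # a set identical to the significant list beats any other set
  sets2 <- list(exact = sig, other = universe[5:16])
  res2 <- pathway_ora(sig, universe, sets2)
  expect_equal(res2$set[1], "exact")
  expect_lt(res2$p_value[1], res2$p_value[2])
  expect_error(pathway_ora(sig, character(0), sets),
               class = "imdspatial_validation_error")
  expect_error(pathway_ora("not_in_universe", universe, sets),
               class = "imdspatial_validation_error")
})

test_that("ORA matches enumeration across random small instances", {
  set.seed(91)
  for (rep in 1:20) {
    N <- sample(8:25, 1)
    universe <- sprintf("u%02d", seq_len(N))
    m <- sample(2:(N - 2), 1)
    n_sig <- sample(2:(N - 2), 1)
    sets <- list(s = universe[seq_len(m)])
    sig <- sample(universe, n_sig)
    k <- length(intersect(sig, sets$s))
    got <- pathway_ora(sig, universe, sets)$p_value
    expect_equal(got, oracle_hyper_tail(N, m, n_sig, k), tolerance = 1e-10)
  }
})

test_that("signature matrices behave like Pearson correlation with tertile bands", {
  set.seed(55)
  ab <- matrix(rexp(8 * 6, 0.01), 8, 6,
               dimnames = list(NULL, paste0("met", 1:6)))
  ab[, 2] <- ab[, 1] # duplicated channel
  ab[, 3] <- 1e4 / (ab[, 1] + 1) # inverse pattern
  sm <- signature_matrix(ab)
  expect_equal(sm$correlation[1, 2], 1)
  expect_lt(sm$correlation[1, 3], -0.9)
  expect_true(isSymmetric(sm$correlation))
  expect_true(all(diag(sm$correlation) == 1))
  expect_true(all(abs(sm$correlation) <= 1 + 1e-12))
  # entries match the textbook formula on the log2 abundances
  lx <- log2(ab + 0.5)
  manual <- sum((lx[, 1] - mean(lx[, 1])) * (lx[, 4] - mean(lx[, 4]))) /
    sqrt(sum((lx[, 1] - mean(lx[, 1]))^2) * sum((lx[, 4] - mean(lx[, 4]))^2))
  expect_equal(sm$correlation[1, 4], manual)
  expect_equal(length(levels(sm$categories)), 3L)
  # constant metabolite reported as missing
  ab2 <- ab; ab2[, 5] <- 3
  expect_warning(sm2 <- signature_matrix(ab2), "constant")
  expect_true(all(is.na(sm2$correlation[5, ])))
  expect_error(signature_matrix(ab[1:2, ]), class = "imdspatial_validation_error")
})

test_that("opposite-trend calls need significance in both and strict sign reversal", {
  a <- data.frame(metabolite = c("m1", "m2", "m3", "m4"),
                  mean_log2fc = c(1, 1, -1, 1),
                  significant = c(TRUE, TRUE, TRUE, FALSE))
  b <- data.frame(metabolite = c("m1", "m2", "m3", "m4"),
                  mean_log2fc = c(-1, 1, 1, -1),
                  significant = c(TRUE, TRUE, TRUE, TRUE))
  expect_equal(opposite_trend(a, b), c("m1", "m3"))
  expect_warning(res <- opposite_trend(a, data.frame(metabolite = "zz",
                                                     mean_log2fc = 1,
                                                     significant = TRUE)),
                 "share no metabolites")
  expect_equal(res, character(0))
})
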
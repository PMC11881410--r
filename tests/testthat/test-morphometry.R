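test_that("GLCM closed-form cases match hand enumeration", {
  cfg2 <- glcm_config(levels = 2L)

  # constant window: single-cell matrix
  const <- glcm_features(matrix(100, 8, 8), matrix(1, 8, 8), cfg2)
  expect_equal(unname(const),
               c(0, 1, 0, 1), tolerance = 1e-15)

  # 2x2 window, rows [0,0] and [1,1] (levels at G=2), offset (0,1):
  # P(0,0) = P(1,1) = 0.5
  g <- matrix(c(0, 200, 0, 200), 2, 2)  # row 1 = (0,0), row 2 = (200,200)
  f_row <- glcm_features(g, matrix(1, 2, 2), cfg2, offsets = list(c(0, 1)))
  expect_equal(unname(f_row), c(0, 0.5, 1, 1), tolerance = 1e-15)

  # offset (1,0): P(0,1) = P(1,0) = 0.5 -> contrast 1 -> 100% at G=2
  f_col <- glcm_features(g, matrix(1, 2, 2), cfg2, offsets = list(c(1, 0)))
  expect_equal(f_col[["contrast_pct"]], 100, tolerance = 1e-15)
  expect_equal(f_col[["energy"]], 0.5, tolerance = 1e-15)
  expect_equal(f_col[["entropy_bits"]], 1, tolerance = 1e-15)
  expect_equal(f_col[["homogeneity"]], 0.5, tolerance = 1e-15)
})

test_that("GLCM features equal the brute-force pair-enumeration oracle", {
  set.seed(4242)
  for (rep in 1:25) {
    G <- sample(c(2L, 8L, 16L), 1)
    gray <- matrix(sample(0:255, 256, replace = TRUE), 16, 16)
    win <- matrix(runif(256) < 0.7, 16, 16)
    if (rep %% 5 == 0) win[5:9, 5:9] <- FALSE  # window with a hole
    if (sum(win) < 8) win[1:4, 1:4] <- TRUE
    got <- glcm_features(gray, win, glcm_config(levels = G))
    want <- glcm_oracle(gray, win, G)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("undefined texture is flagged, not fabricated", {
  # one isolated pixel: no pair for any offset
  w <- matrix(FALSE, 8, 8); w[4, 4] <- TRUE
  f <- glcm_features(matrix(0, 8, 8), w)
  expect_true(all(is.na(f)))
})

test_that("a bright halo raises contrast and lowers homogeneity", {
  n <- 41
  nucleus <- disc_mask(n, 21, 21, 8)
  ring <- disc_mask(n, 21, 21, 12) & !nucleus
  base <- matrix(185, n, n)   # eosin-pink luminance
  base[nucleus] <- 70
  haloed <- base
  haloed[ring] <- 237
  win <- disc_mask(n, 21, 21, 13)
  f_plain <- glcm_features(base, win)
  f_halo <- glcm_features(haloed, win)
  expect_gt(f_halo[["contrast_pct"]], f_plain[["contrast_pct"]])
  expect_lt(f_halo[["homogeneity"]], f_plain[["homogeneity"]])
})

test_that("shape descriptors hit their geometric anchors", {
  ps <- 1
  d <- disc_mask(64, 32, 32, 20.5)
  sh <- shape_features(d, ps)
  expect_gte(sh[["roundness"]], 0.95)
  expect_lt(abs(sh[["aspect_ratio"]] - 1), 0.05)
  expect_lt(abs(sh[["area_um2"]] - pi * 20.5^2) / (pi * 20.5^2), 0.05)
  expect_lt(abs(sh[["perimeter_um"]] - 2 * pi * 20.5) / (2 * pi * 20.5),
            0.05)

  sq <- matrix(FALSE, 64, 64); sq[11:50, 11:50] <- TRUE
  shq <- shape_features(sq, ps)
  expect_lt(abs(shq[["roundness"]] - pi / 4), 0.05)

  expect_error(shape_features(matrix(c(TRUE, rep(FALSE, 24)), 5, 5), ps),
               "at least 4 pixels")
})

test_that("area and perimeter are stable across scan resolution", {
  # same physical disc rasterized at 0.46 and 0.23 um/px
  r_um <- 4
  m1 <- disc_mask(64, 32, 32, r_um / 0.46)
  m2 <- disc_mask(128, 64, 64, r_um / 0.23)
  s1 <- shape_features(m1, 0.46)
  s2 <- shape_features(m2, 0.23)
  expect_lt(abs(s1[["area_um2"]] - s2[["area_um2"]]) / s2[["area_um2"]],
            0.05)
  expect_lt(abs(s1[["perimeter_um"]] - s2[["perimeter_um"]]) /
              s2[["perimeter_um"]], 0.05)
})

test_that("intensity statistics use population variance over the mask", {
  g <- matrix(50, 6, 6)
  f <- intensity_features(g, matrix(1, 6, 6))
  expect_equal(unname(f), c(50, 50, 50, 0))

  g2 <- matrix(c(10, 20, 0, 0), 2, 2)
  m2 <- matrix(c(1, 1, 0, 0), 2, 2)
  f2 <- intensity_features(g2, m2)
  expect_equal(unname(f2), c(10, 20, 15, 25))
  expect_error(intensity_features(g2, matrix(0, 2, 2)), "empty")
})

test_that("density features equal the brute-force neighbourhood oracle", {
  d <- density_features(data.frame(x = c(0, 3), y = c(0, 4)), 30)
  expect_equal(d$nn_distance_um, c(5, 5))
  expect_equal(d$n_neighbors, c(1L, 1L))

  far <- density_features(data.frame(x = c(0, 40, 80), y = c(0, 0, 0)), 30)
  expect_equal(far$n_neighbors, c(0L, 0L, 0L))
  expect_equal(far$nn_distance_um, c(40, 40, 40))

  one <- density_features(data.frame(x = 1, y = 1), 30)
  expect_equal(one$n_neighbors, 0L)
  expect_true(is.na(one$nn_distance_um))

  set.seed(77)
  pts <- data.frame(x = runif(200, 0, 300), y = runif(200, 0, 300))
  got <- density_features(pts, 30)
  # oracle: explicit distance matrix
  dm <- as.matrix(stats::dist(pts))
  diag(dm) <- Inf
  expect_identical(got$n_neighbors,
                   as.integer(rowSums(dm <= 30)))
  expect_equal(got$nn_distance_um, unname(apply(dm, 1, min)))
})

test_that("epidermal depth is 0 at the surface and monotone with row", {
  h <- 120; w <- 80
  tis <- label_mask(rbind(matrix(0L, 20, w), matrix(1L, 100, w)),
                    "tissue-binary", 1)
  epi <- label_mask(rbind(matrix(0L, 20, w), matrix(1L, 40, w),
                          matrix(0L, 60, w)),
                    "epidermis-binary", 1)
  maps <- histonox:::epidermal_depth_maps(epi, tis)
  # outer surface at row 20 (0-based), dermal boundary at row 59
  expect_equal(epidermal_depth(c(40, 20), epi, tis, maps), 0)
  mid <- epidermal_depth(c(40, 39.6), epi, tis, maps)  # equidistant-ish
  expect_lt(abs(mid - 0.5), 0.03)
  depths <- vapply(21:58, function(r)
    epidermal_depth(c(40, r), epi, tis, maps), 0)
  expect_true(all(diff(depths) > 0))
  expect_true(is.na(epidermal_depth(c(40, 90), epi, tis, maps)))
})

test_that("build_records yields one complete record per instance", {
  s <- generate_slide(small_spec(n_epidermal_nuclei = 50,
                                 n_dermal_nuclei = 0, halo_fraction = 0.2))
  cfg <- default_config()
  res <- build_records(s$image, s$truth$nucleus_labels,
                       s$truth$epidermis_mask, cfg, "s1", "ctrl",
                       tissue = s$truth$tissue_mask)
  expect_s3_class(res, "SampleResult")
  expect_equal(res$n_nuclei, 50)
  expect_equal(nrow(res$records), 50)
  expect_identical(res$records$nucleus_id, 1:50)
  shape_cols <- c("area_um2", "perimeter_um", "roundness", "aspect_ratio")
  expect_false(any(is.na(as.matrix(res$records[, shape_cols]))))
  expect_false(any(is.na(res$records$glcm_contrast_pct)))

  # determinism
  res2 <- build_records(s$image, s$truth$nucleus_labels,
                        s$truth$epidermis_mask, cfg, "s1", "ctrl",
                        tissue = s$truth$tissue_mask)
  expect_identical(res$records, res2$records)
})

test_that("a single-nucleus sample flags nn distance undefined", {
  img <- array(rep(c(244, 144, 240), each = 128 * 128), c(128, 128, 3))
  nuc <- round(255 * 10^(-0.9 * c(0.650, 0.704, 0.286)))
  d <- disc_mask(128, 64, 64, 7)
  for (k in 1:3) { pl <- img[, , k]; pl[d] <- nuc[k]; img[, , k] <- pl }
  lab <- label_mask(matrix(as.integer(d), 128, 128),
                    "nuclei-instances", 0.46)
  res <- build_records(slide_image(img, 0.46), lab, NULL, default_config())
  expect_equal(res$n_nuclei, 1L)
  expect_true(is.na(res$records$nn_distance_um))
  expect_equal(res$records$n_neighbors, 0L)
  expect_false(is.na(res$records$area_um2))
})

test_that("pyknotic nuclei read darker than plain ones in luminance", {
  s <- generate_slide(small_spec(pyknotic_fraction = 0.4, noise_sd = 0,
                                 rng_seed = 5))
  res <- build_records(s$image, s$truth$nucleus_labels, NULL,
                       default_config())
  tt <- s$truth$truth_table
  expect_gt(mean(res$records$intensity_mean[!tt$is_pyknotic]),
            mean(res$records$intensity_mean[tt$is_pyknotic]))
})
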
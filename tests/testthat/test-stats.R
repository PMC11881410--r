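test_that("HCM summaries follow their definitions including the tie rule", {
  rec <- data.frame(glcm_contrast_pct = c(10, 20, 30))
  s <- hcm_summary(rec, halo_threshold_pct = 20)
  expect_equal(s[["hcm_mean_pct"]], 20)
  expect_equal(s[["haloed_fraction_pct"]], 100 / 3)  # strict >

  s2 <- hcm_summary(data.frame(glcm_contrast_pct = c(NA, 6, NA)),
                    halo_threshold_pct = 4)
  expect_equal(s2[["hcm_mean_pct"]], 6)
  expect_equal(s2[["haloed_fraction_pct"]], 100)
  expect_true(all(is.na(
    hcm_summary(data.frame(glcm_contrast_pct = NA_real_)))))
})

test_that("t statistics and p-values match closed forms and references", {
  # identical groups
  same <- compare_groups("x", c(1, 2, 3), c(1, 2, 3), mode = "student")
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)
  expect_equal(same$ssmd, 0)

  # closed-form SSMD: mean difference 3, variances 4 and 5
  a <- 3 + c(-sqrt(2), sqrt(2))          # mean 3, sample var 4
  b <- c(-sqrt(2.5), sqrt(2.5))          # mean 0, sample var 5
  expect_equal(compare_groups("x", a, b)$ssmd, 1.0, tolerance = 1e-12)

  # closed-form Welch case
  w <- compare_groups("x", c(1, 2, 3, 4), c(2, 3, 4, 5), mode = "welch")
  expect_equal(w$t_statistic, -1 / sqrt(5 / 6), tolerance = 1e-12)
  expect_equal(w$degrees_of_freedom, 6, tolerance = 1e-12)
  expect_equal(w$mean_difference, -1)

  # frozen external reference values (high-precision scipy computations)
  cases <- list(
    list(a = c(10.165, 9.071, 10.101, 11.372, 6.486, 13.369),
         b = c(9.626, 9.211, 7.859, 13.795, 13.025, 14.733, 13.679),
         welch = c(-1.15570404593029, 0.272287961936456),
         student = c(-1.13955501111073, 0.278678607056037),
         paired = c(-1.03455261365012, 0.348297664902498)),
    list(a = c(10.526, 10.657, 11.87, 8.245, 9.908, 10.764),
         b = c(9.642, 13.165, 9.944, 13.018, 11.422, 12.388, 6.447),
         welch = c(-0.5171132729937, 0.61740572487997),
         student = c(-0.491914268265639, 0.632449224099905),
         paired = c(-1.29336061203489, 0.252413170355083)),
    list(a = c(8.279, 12.689, 10.356, 9.837, 11.927, 11.502),
         b = c(10.86, 9.071, 16.883, 13.072, 6.284, 13.518, 13.305),
         welch = c(-0.74817401674377, 0.474026604507625),
         student = c(-0.708839303432573, 0.493173568721297),
         paired = c(-0.455481045335287, 0.667860373110736)),
    list(a = c(11.628, 9.192, 12.943, 8.504, 12.422, 10.585),
         b = c(16.092, 9.834, 13.089, 13.534, 10.029, 11.034, 9.756),
         welch = c(-0.885875606176842, 0.394965050224179),
         student = c(-0.86425493353456, 0.405899862192216),
         paired = c(-1.2034462411249, 0.282668905062512)),
    list(a = c(10.956, 11.377, 9.417, 10.692, 8.836, 8.958),
         b = c(5.232, 7.478, 8.978, 11.325, 15.561, 11.807, 11.274),
         welch = c(-0.146711748493972, 0.887243453036849),
         student = c(-0.137166271803405, 0.893377792012327),
         paired = c(-0.013112727578415, 0.990044984116776)))
  for (cs in cases) {
    for (mode in c("welch", "student")) {
      g <- compare_groups("x", cs$a, cs$b, mode = mode)
      expect_equal(g$t_statistic, cs[[mode]][1], tolerance = 1e-10)
      expect_equal(g$p_value, cs[[mode]][2], tolerance = 1e-10)
    }
    gp <- compare_groups("x", cs$a, cs$b[1:6], mode = "paired")
    expect_equal(gp$t_statistic, cs$paired[1], tolerance = 1e-10)
    expect_equal(gp$p_value, cs$paired[2], tolerance = 1e-10)
  }
})

test_that("degenerate and invalid comparison inputs are handled", {
  z <- compare_groups("x", c(2, 2, 2), c(5, 5, 5))
  expect_true(is.infinite(z$t_statistic) && z$t_statistic < 0)
  expect_equal(z$p_value, 1e-300)
  expect_true(is.infinite(z$ssmd))

  expect_error(compare_groups("x", 1:3, 1:4, mode = "paired"),
               "equal group lengths")
  expect_error(compare_groups("x", 1, 1:5), "at least 2")
})

test_that("swapping groups flips only the signs", {
  set.seed(11)
  a <- rnorm(20); b <- rnorm(25, 0.4)
  for (mode in c("welch", "student")) {
    ab <- compare_groups("x", a, b, mode = mode)
    ba <- compare_groups("x", b, a, mode = mode)
    expect_equal(ab$t_statistic, -ba$t_statistic)
    expect_equal(ab$mean_difference, -ba$mean_difference)
    expect_equal(ab$ssmd, -ba$ssmd)
    expect_equal(ab$p_value, ba$p_value)
    expect_equal(ab$degrees_of_freedom, ba$degrees_of_freedom)
  }
})

test_that("SSMD recovers its population value from samples", {
  set.seed(31)
  vals <- replicate(20, {
    compare_groups("x", rnorm(200, 1, 1), rnorm(200, 0, 1))$ssmd
  })
  expect_true(all(abs(vals - 1 / sqrt(2)) < 0.25))
})

test_that("Benjamini-Hochberg adjustment matches hand computation", {
  expect_equal(adjust_pvalues(0.5), 0.5)
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_pvalues(c(1, 1, 1)), c(1, 1, 1))
  p <- c(0.005, 0.04, 0.2)
  expect_equal(adjust_pvalues(p), c(0.015, 0.06, 0.2))
  expect_error(adjust_pvalues(c(0.5, 1.2)), "must lie in")
})

test_that("PCA explains variance correctly and reconstructs the input", {
  x <- cbind(a = 1:10, b = 2 * (1:10) + 3)
  p <- pca_scores(x)
  expect_equal(p$explained[1], 1, tolerance = 1e-12)

  set.seed(5)
  y <- cbind(a = c(scale(rnorm(40))), b = c(scale(rnorm(40))))
  y[, 2] <- c(scale(residuals(lm(y[, 2] ~ y[, 1]))))  # exactly orthogonal
  p2 <- pca_scores(y)
  expect_equal(p2$explained, c(0.5, 0.5), tolerance = 1e-10)

  set.seed(6)
  z <- matrix(rnorm(300), 50, 6)
  p3 <- pca_scores(z)
  recon <- p3$scores %*% t(p3$loadings)
  expect_equal(recon, unname(scale(z)), tolerance = 1e-8,
               ignore_attr = TRUE)
  # sign convention: largest-magnitude loading entry positive
  for (j in 1:6)
    expect_gt(p3$loadings[which.max(abs(p3$loadings[, j])), j], 0)

  zv <- cbind(z, k = rep(1, 50))
  expect_warning(pca_scores(zv), "zero-variance")
  expect_error(suppressWarnings(pca_scores(cbind(1:5, rep(1, 5)))),
               "2 usable columns")
})

test_that("the LDA axis finds the separating direction and is antisymmetric", {
  set.seed(12)
  n <- 60
  x <- rbind(cbind(rnorm(n, 0, 0.3), rnorm(n, 0, 1)),
             cbind(rnorm(n, 5, 0.3), rnorm(n, 0, 1)))
  lab <- rep(c("hi", "lo"), each = n)  # class "hi" at mean 0? no: first level
  # first factor level "hi" has mean 0; orientation puts class 1 higher,
  # so w1 must be negative with |w1| ~ 1
  ax <- lda_axis(x, lab)
  expect_gte(abs(ax$w[1]), 0.99)
  expect_gt(ax$means[["class1"]], ax$means[["class2"]])

  flip <- lda_axis(x, rep(c("lo", "hi"), each = n))
  expect_equal(unname(flip$w), -unname(ax$w), tolerance = 1e-12)

  same <- lda_axis(rbind(cbind(rnorm(n), rnorm(n)),
                         cbind(rnorm(n), rnorm(n))),
                   rep(c("a", "b"), each = n))
  expect_lt(abs(same$means[["class1"]] - same$means[["class2"]]), 0.5)
})

test_that("descriptor-table comparison adjusts across descriptors", {
  set.seed(21)
  ra <- data.frame(area_um2 = rnorm(50, 25), roundness = runif(50, 0.8, 1),
                   glcm_contrast_pct = rnorm(50, 5, 1))
  rb <- data.frame(area_um2 = rnorm(50, 25), roundness = runif(50, 0.8, 1),
                   glcm_contrast_pct = rnorm(50, 2, 1))
  cmp <- compare_descriptors(ra, rb)
  expect_setequal(cmp$descriptor,
                  c("area_um2", "roundness", "glcm_contrast_pct"))
  expect_true(all(cmp$p_adjusted >= cmp$p_value - 1e-15))
  expect_lt(cmp$p_adjusted[cmp$descriptor == "glcm_contrast_pct"], 0.05)
})
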
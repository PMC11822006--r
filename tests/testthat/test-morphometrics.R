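test_that("histogram-tail binarization keeps at most the requested tail", {
  set.seed(1)
  img <- matrix(runif(1000), 40, 25)
  m <- binarize_channel(img, 0.005)
  expect_lte(sum(m), 5)
  # monotone ramp: exactly the top 1%
  ramp <- matrix(seq_len(1000), 40, 25)
  m1 <- binarize_channel(ramp, 0.01)
  expect_equal(sum(m1), 10)
  expect_true(all(ramp[m1] > 990))
  expect_warning(mc <- binarize_channel(matrix(5, 10, 10), 0.005), "constant")
  expect_equal(sum(mc), 0)
  expect_error(binarize_channel(ramp, 0.05), "tail_fraction")
  # brute-force oracle: smallest threshold with frac(above) <= tail
  for (rep in 1:5) {
    x <- matrix(sample(0:50, 400, replace = TRUE), 20, 20)
    m <- binarize_channel(x, 0.01)
    thr <- attr(m, "threshold")
    expect_lte(mean(x > thr), 0.01)
    expect_true(thr == min(x) || mean(x > (thr - 1)) > 0.01)
  }
})

test_that("nuclear segmentation labels disjoint nuclei", {
  img <- matrix(0, 100, 100)
  xg <- row(img); yg <- col(img)
  img[(xg - 25)^2 + (yg - 25)^2 < 64] <- 4000
  img[(xg - 70)^2 + (yg - 70)^2 < 64] <- 4000
  lab <- segment_nuclei(img, blur_sigma_px = 1)
  expect_equal(max(lab), 2)
  expect_warning(z <- segment_nuclei(matrix(0, 20, 20)), "empty")
  expect_equal(max(z), 0)
})

test_that("ROI dilation is isotropic and resolves contested pixels", {
  img <- matrix(0L, 80, 80)
  xg <- row(img); yg <- col(img)
  disc <- (xg - 40)^2 + (yg - 40)^2 <= (5 / 0.5)^2  # 5 um at 0.5 um/px
  img[disc] <- 1L
  roi <- dilate_rois(img, pixel_size_um = 0.5, radius_um = 3)
  # 5 um disc + 3 um -> 8 um disc; compare areas within discretization
  expect_equal(sum(roi > 0) * 0.5^2, pi * 8^2, tolerance = 0.1)
  expect_identical(dilate_rois(img, pixel_size_um = 0.5, radius_um = 0), img)
  expect_error(dilate_rois(img, radius_um = 3), "pixel_size_um")

  # two seeds 4 um apart split contested pixels by nearest seed
  two <- matrix(0L, 60, 60)
  two[30, 26] <- 1L
  two[30, 34] <- 2L  # 8 px = 4 um apart
  roi2 <- dilate_rois(two, pixel_size_um = 0.5, radius_um = 3)
  lab_left <- roi2[30, 27:29]
  lab_right <- roi2[30, 31:33]
  expect_true(all(lab_left == 1L))
  expect_true(all(lab_right == 2L))
})

test_that("percent area covered is an exact pixel fraction", {
  roi <- matrix(FALSE, 10, 10); roi[1:10, 1:10] <- TRUE
  mask <- matrix(FALSE, 10, 10); mask[1:5, 1:5] <- TRUE
  expect_equal(percent_area_covered(mask, roi), 25)
  expect_equal(percent_area_covered(matrix(FALSE, 10, 10), roi), 0)
  expect_equal(percent_area_covered(matrix(TRUE, 10, 10), roi), 100)
  expect_error(percent_area_covered(mask, matrix(FALSE, 10, 10)), "empty ROI")
})

test_that("excitatory filter applies the Slc17a7/Gad1 thresholds", {
  cells <- data.frame(pac_slc17a7 = c(0.3, 0.2, 1.0, 5),
                      pac_gad1 = c(0, 0, 0.1, 0))
  kept <- filter_excitatory(cells)
  expect_equal(kept$pac_slc17a7, c(0.3, 5))
  expect_error(filter_excitatory(data.frame(pac_slc17a7 = 1)), "pac_gad1")
})

test_that("phenotype index partitions marker expression", {
  ph <- phenotype_index(c(2, 1, 0), c(0, 1, 3))
  expect_equal(ph$index, c(1, 0, -1))
  expect_equal(ph$label, c("Ly6g6e", "unassigned", "Cck"))
  expect_warning(z <- phenotype_index(0, 0), "zero PAC")
  expect_true(is.na(z$index))
  expect_error(phenotype_index(-1, 2), ">= 0")
})

test_that("shape features match exact polygon formulas", {
  sq <- shape_features(unit_square)
  expect_identical(sq$circularity, 4 * pi * 1 / 16)  # pi/4, exact arithmetic
  expect_equal(sq$feret_max_um, sqrt(2))
  expect_equal(sq$feret_ratio, 1 / sqrt(2))
  expect_equal(sq$area_um2, 1)
  expect_equal(sq$perimeter_um, 4)

  circ <- shape_features(ellipse_polygon(c(0, 0), 5, 5, n = 256))
  expect_gte(circ$circularity, 0.99)
  expect_gte(circ$feret_ratio, 0.99)

  ell <- shape_features(ellipse_polygon(c(2, 3), 6, 3, angle = 0, n = 256))
  expect_equal(ell$width_um, 12, tolerance = 1e-3)
  expect_equal(ell$height_um, 6, tolerance = 1e-3)
  expect_equal(ell$alveus_aspect_ratio, 0.5, tolerance = 1e-3)

  expect_error(shape_features(rbind(c(0, 0), c(1, 1), c(2, 2))), "degenerate")
})

test_that("ratio features are rotation-invariant and scale-equivariant", {
  set.seed(3)
  poly <- ellipse_polygon(c(1, -2), 7, 3, angle = 0.4, n = 90)
  base <- shape_features(poly, alveus_angle = 0.1)
  for (th in c(0.3, 1.2, 2.5)) {
    rot <- cbind(cos(th) * poly[, 1] - sin(th) * poly[, 2],
                 sin(th) * poly[, 1] + cos(th) * poly[, 2])
    f <- shape_features(rot, alveus_angle = 0.1 + th)
    for (col in c("alveus_aspect_ratio", "circularity", "feret_ratio")) {
      expect_equal(f[[col]], base[[col]], tolerance = 1e-6)
    }
    expect_equal(f$height_um, base$height_um, tolerance = 1e-6)
  }
  scaled <- shape_features(3 * poly, alveus_angle = 0.1)
  expect_equal(scaled$area_um2, 9 * base$area_um2, tolerance = 1e-9)
  expect_equal(scaled$perimeter_um, 3 * base$perimeter_um, tolerance = 1e-9)
  expect_equal(scaled$circularity, base$circularity, tolerance = 1e-9)
})

test_that("circularity never exceeds 1 on simple polygons", {
  set.seed(4)
  for (rep in 1:20) {
    # star-shaped simple polygon around the origin
    nv <- sample(5:30, 1)
    th <- sort(runif(nv, 0, 2 * pi))
    r <- runif(nv, 0.5, 2)
    poly <- cbind(r * cos(th), r * sin(th))
    expect_lte(shape_features(poly)$circularity, 1 + 1e-12)
  }
})

test_that("PCA embedding is centred, scaled, and fails on constant features", {
  set.seed(5)
  X <- data.frame(a = rnorm(30), b = rnorm(30, 5, 3), c = runif(30))
  p <- pca_embedding(X)
  expect_true(all(abs(colMeans(p$scores)) < 1e-10))
  expect_equal(sum(p$explained_variance), 3)
  X$d <- 1
  expect_error(pca_embedding(X), "d")
})
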
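make_rois <- function(dims, cell_center, cell_r, bg_centers, bg_r = 3) {
  disk <- function(c0) {
    y <- row(matrix(0, dims[1], dims[2])); x <- col(matrix(0, dims[1], dims[2]))
    sqrt((y - c0[1])^2 + (x - c0[2])^2) <= c0[3]
  }
  roi_set(cell_rois = list(cell = disk(c(cell_center, cell_r))),
          background_rois = lapply(bg_centers, function(c0) disk(c(c0, bg_r))))
}

test_that("sum projection conserves intensity and widens integers", {
  vol <- array(2L, c(8, 5, 6))
  img <- sum_project(vol)
  expect_true(all(img == 16))
  single <- array(runif(30), c(1, 5, 6))
  expect_equal(sum_project(single), single[1, , ])
  set.seed(2)
  rv <- array(rnorm(8 * 5 * 6), c(8, 5, 6))
  expect_equal(sum(sum_project(rv)), sum(rv))
  big <- array(.Machine$integer.max, c(4, 2, 2))
  expect_equal(sum_project(big)[1, 1], 4 * as.numeric(.Machine$integer.max))
  expect_error(sum_project(matrix(1, 2, 2)), "3D")
})

test_that("corrected intensity is the ROI mean minus the background mean", {
  img <- matrix(0, 40, 40)
  rois <- make_rois(c(40, 40), c(20, 20), 4,
                    list(c(6, 6), c(6, 34), c(34, 6)))
  img[rois$cell_rois$cell] <- 50
  img[rois$background_rois[[1]]] <- 10
  img[rois$background_rois[[2]]] <- 12
  img[rois$background_rois[[3]]] <- 14
  expect_equal(as.numeric(corrected_intensity(img, rois, "cell")), 50 - 12)
  # uniform image corrects to zero for any geometry
  expect_equal(as.numeric(corrected_intensity(matrix(7, 40, 40), rois, "cell")), 0)
  # invariance to adding a constant to the whole image
  v1 <- as.numeric(corrected_intensity(img, rois, "cell"))
  v2 <- as.numeric(corrected_intensity(img + 123, rois, "cell"))
  expect_equal(v1, v2)
  # negative values flagged, not clipped
  dark <- matrix(20, 40, 40)
  dark[rois$cell_rois$cell] <- 5
  cv <- corrected_intensity(dark, rois, "cell")
  expect_lt(as.numeric(cv), 0)
  expect_true(attr(cv, "negative"))
  expect_error(corrected_intensity(img, rois, "nope"), "no ROI")
})

test_that("ROI sets enforce the three-background rule and disjointness", {
  m <- matrix(FALSE, 10, 10)
  a <- m; a[2:4, 2:4] <- TRUE
  b <- m; b[6:8, 2:4] <- TRUE
  c1 <- m; c1[2:4, 6:8] <- TRUE
  d <- m; d[6:8, 6:8] <- TRUE
  expect_error(roi_set(list(cell = a), list(b, c1)), "exactly 3")
  expect_error(roi_set(list(cell = a), list(a, c1, d)), "overlaps")
  expect_s3_class(roi_set(list(cell = a), list(b, c1, d)), "roi_set")
})

test_that("corrected ROI intensity recovers synthetic ground truth within 5%", {
  cells <- data.frame(cell_id = "a", z = 10, y = 16, x = 16, radius = 4,
                      peak = 80)
  tr <- data.frame(cell_id = "a", time_hr = 0, intensity = 100)
  ss <- render_stack_series(stack_spec(c(20, 32, 32), cells,
                                       background_level = 10), tr)
  img <- sum_project(ss$volumes[[1]])
  rois <- make_rois(c(32, 32), c(16, 16), 9,
                    list(c(5, 5), c(5, 27), c(27, 5)))
  corr <- as.numeric(corrected_intensity(img, rois, "cell"))
  integrated <- corr * sum(rois$cell_rois$cell)
  expect_equal(integrated, ss$ground_truth$integrated_intensity,
               tolerance = 0.05)
})

test_that("3D mask sums recover ground truth and split components", {
  # uniform volume at background level: empty mask
  flat <- array(10, c(8, 8, 8))
  ms0 <- mask_intensity_sum(flat, threshold = 5, background = 10)
  expect_true(ms0$empty)
  expect_equal(ms0$total, 0)
  # one blob at 10%-of-peak threshold: within 5% of the true integral
  cells <- data.frame(cell_id = "a", z = 10, y = 16, x = 16, radius = 4,
                      peak = 100)
  tr <- data.frame(cell_id = "a", time_hr = 0, intensity = 100)
  ss <- render_stack_series(stack_spec(c(20, 32, 32), cells,
                                       background_level = 10), tr)
  ms <- mask_intensity_sum(ss$volumes[[1]], threshold = 10, background = 10)
  expect_length(ms$component_sums, 1)
  expect_equal(ms$total, ss$ground_truth$integrated_intensity,
               tolerance = 0.05)
  # two disjoint blobs: two components, each scored against its truth
  two <- data.frame(cell_id = c("a", "b"), z = c(10, 10), y = c(9, 24),
                    x = c(9, 24), radius = c(4, 3), peak = c(100, 60))
  tr2 <- data.frame(cell_id = c("a", "b"), time_hr = 0,
                    intensity = c(100, 100))
  ss2 <- render_stack_series(stack_spec(c(20, 32, 32), two,
                                        background_level = 10), tr2)
  ms2 <- mask_intensity_sum(ss2$volumes[[1]], threshold = 6, background = 10)
  expect_length(ms2$component_sums, 2)
  gt2 <- ss2$ground_truth
  expect_equal(sort(as.numeric(ms2$component_sums)),
               sort(gt2$integrated_intensity), tolerance = 0.05)
})

test_that("mask sum is monotone non-decreasing as the threshold decreases", {
  cells <- data.frame(cell_id = "a", z = 8, y = 12, x = 12, radius = 3,
                      peak = 100)
  tr <- data.frame(cell_id = "a", time_hr = 0, intensity = 100)
  ss <- render_stack_series(stack_spec(c(16, 24, 24), cells,
                                       background_level = 10), tr)
  sums <- vapply(c(50, 25, 10, 5, 1), function(th) {
    mask_intensity_sum(ss$volumes[[1]], th, background = 10)$total
  }, numeric(1))
  expect_true(all(diff(sums) >= 0))
  expect_error(mask_intensity_sum(ss$volumes[[1]], 0), "positive")
})

test_that("26-connectivity joins corner-touching voxels", {
  m <- array(FALSE, c(3, 3, 3))
  m[1, 1, 1] <- TRUE
  m[2, 2, 2] <- TRUE  # corner neighbour of (1,1,1)
  m[3, 3, 3] <- TRUE
  lab <- label_components_3d(m)
  expect_equal(max(lab), 1L)
  m[3, 3, 3] <- FALSE
  m[1, 3, 3] <- TRUE  # isolated from the (1,1,1)-(2,2,2) pair? corner of (2,2,2)
  lab2 <- label_components_3d(m)
  expect_equal(max(lab2), 1L)
  # genuinely separate voxels
  m2 <- array(FALSE, c(5, 5, 5))
  m2[1, 1, 1] <- TRUE
  m2[5, 5, 5] <- TRUE
  expect_equal(max(label_components_3d(m2)), 2L)
})

test_that("nuclear/cytoplasmic ratio follows its definition", {
  img <- matrix(0, 20, 20)
  nuc <- img == 1; nuc[5:8, 5:8] <- TRUE
  cyt <- img == 1; cyt[12:15, 12:15] <- TRUE
  img[nuc] <- 40; img[cyt] <- 20
  expect_equal(nuclear_cytoplasmic_ratio(img, nuc, cyt), 2)
  # equal compartments give 1 regardless of background
  img[cyt] <- 40
  expect_equal(nuclear_cytoplasmic_ratio(img, nuc, cyt, background_mean = 7), 1)
  img[cyt] <- 5
  expect_error(nuclear_cytoplasmic_ratio(img, nuc, cyt, background_mean = 10),
               "not positive")
  expect_error(nuclear_cytoplasmic_ratio(img, nuc, nuc), "disjoint")
})

test_that("synthetic nuclear:cytoplasmic contrast is recovered within 10%", {
  set.seed(31)
  img <- matrix(rnorm(40 * 40, mean = 10, sd = 1), 40, 40)
  nuc <- matrix(FALSE, 40, 40); nuc[18:22, 18:22] <- TRUE
  cyt <- matrix(FALSE, 40, 40)
  cyt[14:26, 14:26] <- TRUE; cyt[nuc] <- FALSE
  img[cyt] <- img[cyt] + 30   # corrected cytoplasmic level 30
  img[nuc] <- img[nuc] + 90   # corrected nuclear level 90: ratio 3
  r <- nuclear_cytoplasmic_ratio(img, nuc, cyt, background_mean = 10)
  expect_equal(r, 3, tolerance = 0.1)
})
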
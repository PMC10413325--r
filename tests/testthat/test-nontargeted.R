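# a small in-memory dataset with controllable per-scan peak content:
# one line, uniform 1 s scans, so scan k maps to pixel (0, k-1)
peaks_dataset <- function(spec_peaks) {
  spectra <- lapply(seq_along(spec_peaks), function(k) {
    p <- spec_peaks[[k]]
    make_spectrum(p$mz, p$intensity, k - 1)
  })
  make_dataset(list(structure(
    list(source_id = "mem", line_index = 0L, spectra = spectra),
    class = "LineScan")))
}

full_roi <- function(shape) {
  mask_from_polygon(cbind(c(-1, -1, shape[2] + 1, shape[2] + 1),
                          c(-1, shape[1] + 1, shape[1] + 1, -1)),
                    shape, name = "all")
}

test_that("peak pooling collects every centroid of every ROI pixel", {
  ds <- peaks_dataset(list(
    list(mz = c(100, 200, 300, 400, 500), intensity = rep(10, 5)),
    list(mz = c(150, 250), intensity = c(1, 2)),
    list(mz = 600, intensity = 7)))
  grid <- build_time_grid(ds, "FT")
  shape <- c(1, grid$n_ticks)

  # 1-pixel ROI over the first scan: its 5 peaks
  roi1 <- mask_from_polygon(cbind(c(0, 0, 1, 1), c(0, 1, 1, 0)), shape)
  p1 <- collect_peaks(ds, "FT", roi1)
  expect_equal(nrow(p1), 5L)
  expect_equal(p1$mz, c(100, 200, 300, 400, 500))

  # whole-image ROI: the total centroid count
  pall <- collect_peaks(ds, "FT", full_roi(shape))
  expect_equal(nrow(pall), 8L)
  expect_true(all(pall$intensity > 0))
})

test_that("an ROI over only fill pixels pools nothing", {
  # line 2 stops at t=2 on a grid reaching t=5
  ds <- make_dataset(list(make_line(0:5), make_line(0:2, line_index = 1)))
  grid <- build_time_grid(ds, "FT")
  roi <- mask_from_polygon(cbind(c(4.2, 4.2, 6, 6), c(1, 2, 2, 1)),
                           c(2, grid$n_ticks))
  expect_true(all(which(roi$mask, arr.ind = TRUE)[, 1] == 2))
  expect_equal(nrow(collect_peaks(ds, "FT", roi)), 0L)
})

test_that("ppm gap grouping splits and merges as the gap arithmetic dictates", {
  pk <- data.frame(mz = c(500.0000, 500.0010, 500.0050),
                   intensity = c(1, 1, 1),
                   line_index = 0L, tick_index = 0:2, pixel_id = 0:2)
  fg <- group_features(pk, 5)
  expect_equal(nrow(fg$groups), 2L)
  expect_equal(fg$groups$n_members, c(2L, 1L))
  expect_equal(fg$peaks$group, c(1L, 1L, 2L))

  # identical m/z values -> one group with zero spread
  fg2 <- group_features(data.frame(mz = rep(700.7, 4), intensity = 1:4,
                                   line_index = 0L, tick_index = 0:3,
                                   pixel_id = 0:3), 5)
  expect_equal(nrow(fg2$groups), 1L)
  expect_equal(fg2$groups$spread_ppm, 0)
  expect_equal(fg2$groups$centroid_mz, 700.7)

  # intensity-weighted vs plain centroid
  pk3 <- data.frame(mz = c(500.0000, 500.0010), intensity = c(3, 1),
                    line_index = 0L, tick_index = 0:1, pixel_id = 0:1)
  expect_equal(group_features(pk3, 5)$groups$centroid_mz,
               (3 * 500.0000 + 1 * 500.0010) / 4)
  expect_equal(group_features(pk3, 5, weighted = FALSE)$groups$centroid_mz,
               500.0005)
})

test_that("grouping equals the brute-force transitive closure and is monotone", {
  skip_if_not_installed("igraph")
  set.seed(31)
  for (case in 1:50) {
    n <- sample(10:200, 1)
    # clustered m/z values so groups of several sizes arise
    centers <- runif(sample(3:12, 1), 100, 1000)
    mz <- sample(centers, n, replace = TRUE)
    mz <- mz * (1 + rnorm(n, 0, 2) / 1e6)
    pk <- data.frame(mz = mz, intensity = runif(n, 1, 100),
                     line_index = 0L, tick_index = seq_len(n) - 1L,
                     pixel_id = seq_len(n) - 1L)
    prev_n <- Inf
    for (tol in c(0.5, 1, 2, 5, 10)) {
      fg <- group_features(pk, tol)
      # partition property: every peak in exactly one group, counts conserved
      expect_equal(sum(fg$groups$n_members), n)
      expect_false(any(is.na(fg$peaks$group)))
      # oracle equivalence
      expect_identical(canonical_partition(fg$peaks$group),
                       canonical_partition(oracle_partition(pk$mz, tol)))
      # tolerance monotonicity
      expect_lte(nrow(fg$groups), prev_n)
      prev_n <- nrow(fg$groups)
    }
  }
})

test_that("per-ROI group statistics tally pixels like the naive count", {
  # 10-pixel line; feature A in 3 pixels, twice in one of them
  ds <- peaks_dataset(list(
    list(mz = c(400.0, 400.000001), intensity = c(10, 30)),  # same pixel x2
    list(mz = 500.0, intensity = 5),
    list(mz = 400.0, intensity = 20),
    list(mz = 500.0, intensity = 5),
    list(mz = 400.0, intensity = 40),
    list(mz = 500.0, intensity = 5),
    list(mz = 500.0, intensity = 5),
    list(mz = 500.0, intensity = 5),
    list(mz = 500.0, intensity = 5),
    list(mz = 500.0, intensity = 5)))
  grid <- build_time_grid(ds, "FT")
  roi <- full_roi(c(1, grid$n_ticks))
  pk <- collect_peaks(ds, "FT", roi)
  fg <- group_features(pk, 5)
  st <- group_stats(fg, roi)
  a <- which.min(abs(st$centroid_mz - 400))
  expect_equal(st$det_freq[a], 0.3)
  # mean over detected pixels; the double-member pixel sums to 40
  expect_equal(st$mean_intensity[a], (40 + 20 + 40) / 3)

  # single member, single-pixel ROI
  roi1 <- mask_from_polygon(cbind(c(0, 0, 1, 1), c(0, 1, 1, 0)),
                            c(1, grid$n_ticks))
  pk1 <- collect_peaks(ds, "FT", roi1)
  fg1 <- group_features(pk1, 5)
  st1 <- group_stats(fg1, roi1)
  expect_equal(st1$det_freq, 1.0)
  expect_equal(st1$mean_intensity, 40)
})

test_that("two-ROI screening recovers the planted feature and only it", {
  sim <- get_sim("two_region")
  shape <- c(length(sim$dataset$lines), sim$grid$n_ticks)
  roi_a <- mask_from_polygon(sim$phantom$roi_a_vertices, shape, "A")
  roi_b <- mask_from_polygon(sim$phantom$roi_b_vertices, shape, "B")
  tab <- compare_rois(sim$dataset, sim$scan_filter, roi_a, roi_b, 10,
                      criteria = filter_criteria(c(1, Inf), c(0.1, 1), 2),
                      grid = sim$grid)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$centroid_mz, 400.25, tolerance = 1e-5)
  expect_gt(tab$fold_change, 100)
  expect_equal(tab$det_freq_b, 0)

  # identical ROIs -> every fold change exactly 1
  same <- compare_rois(sim$dataset, sim$scan_filter, roi_a, roi_a, 10,
                       grid = sim$grid)
  expect_true(all(same$fold_change == 1))

  # unfiltered table is sorted by descending fold change
  all_tab <- compare_rois(sim$dataset, sim$scan_filter, roi_a, roi_b, 10,
                          grid = sim$grid)
  expect_true(!is.unsorted(rev(all_tab$fold_change)))
  expect_gt(nrow(all_tab), 20)
})

test_that("a frequency window excludes sparsely detected groups", {
  ds <- peaks_dataset(lapply(1:10, function(k) {
    if (k <= 3) list(mz = c(400, 500), intensity = c(10, 5))
    else list(mz = 500, intensity = 5)
  }))
  grid <- build_time_grid(ds, "FT")
  roi <- full_roi(c(1, grid$n_ticks))
  # feature 400 detected in 30% of pixels: excluded by [0.5, 1]
  tab <- compare_rois(ds, "FT", roi, roi, 5,
                      criteria = filter_criteria(c(0, Inf), c(0.5, 1), 0.5))
  expect_false(any(abs(tab$centroid_mz - 400) < 0.1))
  # but included by [0.1, 1]
  tab2 <- compare_rois(ds, "FT", roi, roi, 5,
                       criteria = filter_criteria(c(0, Inf), c(0.1, 1), 0.5))
  expect_true(any(abs(tab2$centroid_mz - 400) < 0.1))
})

test_that("a group's ion image equals the targeted image of its centroid", {
  sim <- get_sim("two_region")
  img <- group_image(sim$dataset, sim$scan_filter, 400.25, 10,
                     grid = sim$grid)
  ref <- build_target_images(sim$dataset, sim$scan_filter, 400.25, 10,
                             grid = sim$grid)[[1]]
  expect_identical(img$values, ref$values)
  # the planted feature's image is zero outside its painted region
  shape <- dim(img)
  roi_b <- mask_from_polygon(sim$phantom$roi_b_vertices, shape, "B")
  expect_true(all(img$values[roi_b$mask] == 0))
})
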
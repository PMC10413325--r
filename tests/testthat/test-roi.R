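test_that("polygon rasterization includes exactly the pixel centers inside", {
  m <- mask_from_polygon(cbind(c(0, 0, 2, 2), c(0, 2, 2, 0)), c(4, 4))
  want <- matrix(FALSE, 4, 4)
  want[1:2, 1:2] <- TRUE                     # pixels (0,0),(0,1),(1,0),(1,1)
  expect_identical(m$mask, want)

  # polygon covering the whole grid -> all pixels
  all_m <- mask_from_polygon(cbind(c(-1, -1, 5, 5), c(-1, 5, 5, -1)), c(4, 4))
  expect_true(all(all_m$mask))

  # degenerate: zero area
  expect_error(mask_from_polygon(cbind(c(0, 1, 2), c(0, 1, 2)), c(4, 4)),
               "degenerate")
  # sliver between pixel centers -> empty -> error
  expect_error(mask_from_polygon(cbind(c(0.9, 1.1, 1.1, 0.9),
                                       c(0.6, 0.6, 0.9, 0.9)), c(4, 4)),
               "no pixel center")
})

test_that("rasterization is deterministic and respects containment", {
  set.seed(21)
  shape <- c(20, 30)
  for (i in 1:20) {
    v <- random_polygon(6, shape)
    m1 <- tryCatch(mask_from_polygon(v, shape), error = function(e) NULL)
    if (is.null(m1)) next
    m2 <- mask_from_polygon(v, shape)
    expect_identical(m1$mask, m2$mask)
  }
  # containment: concentric regular polygons give nested masks
  ang <- seq(0, 2 * pi, length.out = 13)[-13]
  for (i in 1:10) {
    ctr <- c(runif(1, 8, 22), runif(1, 6, 14))
    r_out <- runif(1, 4, 6)
    outer_v <- cbind(ctr[1] + r_out * cos(ang), ctr[2] + r_out * sin(ang))
    inner_v <- cbind(ctr[1] + r_out / 2 * cos(ang),
                     ctr[2] + r_out / 2 * sin(ang))
    mo <- mask_from_polygon(outer_v, shape)
    mi <- mask_from_polygon(inner_v, shape)
    expect_true(all(mo$mask[mi$mask]))
  }
})

test_that("ROI statistics match naive recomputation", {
  img <- new_ion_image(matrix(c(1, 2, 3, 4), 2))
  roi <- mask_from_polygon(cbind(c(0, 0, 2, 2), c(0, 2, 2, 0)), c(2, 2))
  st <- roi_stats(img, roi)
  expect_equal(st$mean, 2.5)
  expect_equal(st$median, 2.5)
  expect_equal(st$min, 1)
  expect_equal(st$max, 4)
  expect_equal(st$sum, 10)
  expect_equal(st$n_pixels, 4L)

  # all-equal values -> zero spread
  st2 <- roi_stats(new_ion_image(matrix(7, 2, 2)), roi)
  expect_equal(st2$sd, 0)
  expect_equal(st2$rsd_pct, 0)

  # random masks vs first-principles statistics
  set.seed(22)
  big <- new_ion_image(matrix(rlnorm(600, 5, 2), 20, 30))
  for (i in 1:30) {
    v <- random_polygon(7, c(20, 30))
    roi_i <- tryCatch(mask_from_polygon(v, c(20, 30)),
                      error = function(e) NULL)
    if (is.null(roi_i)) next
    st_i <- roi_stats(big, roi_i)
    want <- oracle_stats(big$values[roi_i$mask])
    expect_identical(st_i$n_pixels, want$n_pixels)
    expect_equal(st_i$mean, want$mean)
    expect_identical(st_i$median, want$median)
    expect_equal(st_i$sd, want$sd)
    expect_identical(st_i$min, want$min)
    expect_identical(st_i$max, want$max)
    expect_equal(st_i$sum, want$sum)
  }

  expect_error(roi_stats(new_ion_image(matrix(1, 3, 3)), roi), "match")
})

test_that("one ROI applies across channels in order", {
  imgs <- list(new_ion_image(matrix(1:4, 2), channel = "a"),
               new_ion_image(matrix(5, 2, 2), channel = "b"),
               new_ion_image(matrix(8:5, 2), channel = "c"))
  roi <- mask_from_polygon(cbind(c(0, 0, 2, 2), c(0, 2, 2, 0)), c(2, 2))
  tab <- apply_roi_multi(imgs, roi)
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$channel, c("a", "b", "c"))
  expect_equal(tab$mean[2], 5)                 # constant channel
  expect_equal(tab$mean, vapply(imgs, function(im) roi_stats(im, roi)$mean,
                                numeric(1)))
})

test_that("ROI masks survive save/load, and grids are never silently rescaled", {
  roi <- mask_from_polygon(cbind(c(1, 1, 6.5, 7, 4), c(1, 5, 6, 1.5, 0.5)),
                           c(10, 12), name = "hippocampus")
  f <- withr::local_tempfile(fileext = ".json")
  save_roi(roi, f)
  got <- load_roi(f, grid_shape = c(10, 12))
  expect_identical(got$mask, roi$mask)
  expect_equal(got$vertices, unname(roi$vertices))
  expect_identical(got$name, roi$name)

  expect_error(load_roi(f, grid_shape = c(10, 13)), "not rescaled")

  # vertices-only file re-rasterizes to the identical mask
  obj <- jsonlite::read_json(f, simplifyVector = TRUE)
  obj$mask_rle <- NULL
  f2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(obj, f2, auto_unbox = TRUE, digits = NA)
  expect_identical(load_roi(f2)$mask, roi$mask)

  # save -> load -> save is byte-stable
  f3 <- withr::local_tempfile(fileext = ".json")
  save_roi(got, f3)
  expect_identical(readLines(f), readLines(f3))

  # CSV raster export
  f4 <- withr::local_tempfile(fileext = ".csv")
  save_roi(roi, withr::local_tempfile(fileext = ".json"), csv_path = f4)
  m <- as.matrix(utils::read.table(f4, sep = ","))
  expect_equal(unname(m == 1), roi$mask)
})
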
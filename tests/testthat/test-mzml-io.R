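test_that("written mzML round-trips content, times, filters and TIC fallback", {
  line <- structure(list(
    source_id = "rt.mzML", line_index = 0L,
    spectra = list(
      make_spectrum(c(100.1, 200.2, 300.3), c(10, 20, 30), 0,
                    "FTMS + p ESI Full ms [100.00-1000.00]", tic = 60),
      make_spectrum(c(150.05, 250.5), c(10, 30), 0.5,
                    "FTMS + p ESI Full ms [100.00-1000.00]", tic = NA),
      make_spectrum(760.5851, 999, 1.0,
                    "FTMS + p ESI SIM ms [760.00-761.00]", tic = 999))),
    class = "LineScan")
  path <- withr::local_tempfile(fileext = ".mzML")
  write_mzml(line, path)

  got <- suppressMessages(read_line_scan(path, line_index = 3L))
  expect_equal(got$line_index, 3L)
  expect_length(got$spectra, 3L)
  expect_equal(vapply(got$spectra, `[[`, numeric(1), "time_s"),
               c(0, 0.5, 1.0), tolerance = 1e-6)
  expect_equal(got$spectra[[1]]$mz, c(100.1, 200.2, 300.3))
  expect_equal(got$spectra[[1]]$intensity, c(10, 20, 30))
  # verbatim filter strings
  expect_equal(got$spectra[[3]]$scan_filter,
               "FTMS + p ESI SIM ms [760.00-761.00]")
  # spectrum without TIC attribute falls back to the intensity sum
  expect_equal(got$spectra[[2]]$tic, 40)
  expect_equal(got$spectra[[1]]$tic, 60)
})

test_that("scan start time declared in minutes is converted to seconds", {
  # write_mzml declares times in minutes; 36 s is stored as 0.6 min
  line <- make_line(c(0, 36), values = c(1, 2))
  path <- withr::local_tempfile(fileext = ".mzML")
  write_mzml(line, path)
  txt <- readLines(path)
  expect_true(any(grepl('scan start time" value="0.59999', txt) |
                  grepl('scan start time" value="0.6"', txt)))
  got <- read_line_scan(path)
  expect_equal(got$spectra[[2]]$time_s, 36, tolerance = 1e-6)
})

test_that("invalid mzML input fails naming the file; profile data only warns", {
  bad <- withr::local_tempfile(fileext = ".mzML")
  writeLines("this is not xml", bad)
  expect_error(read_line_scan(bad), basename(bad))
  expect_error(read_line_scan(file.path(tempdir(), "nope.mzML")), "not found")

  # flip the centroid CV param to profile and expect a warning
  line <- make_line(c(0, 1), values = c(5, 6))
  path <- withr::local_tempfile(fileext = ".mzML")
  write_mzml(line, path)
  txt <- readLines(path)
  txt <- gsub('accession="MS:1000127" name="centroid spectrum"',
              'accession="MS:1000128" name="profile spectrum"', txt)
  writeLines(txt, path)
  expect_warning(read_line_scan(path), "profile")
})

test_that("load_dataset preserves input order and collects filters", {
  dir <- withr::local_tempdir()
  paths <- file.path(dir, sprintf("L%d.mzML", 1:4))
  for (i in 1:4) {
    write_mzml(make_line(c(0, 1, 2), values = c(i, i, i)), paths[i])
  }
  ds <- load_dataset(paths)
  expect_length(ds$lines, 4L)
  expect_equal(vapply(ds$lines, `[[`, integer(1), "line_index"), 0:3)
  expect_equal(vapply(ds$lines, `[[`, character(1), "source_id"),
               basename(paths))
  expect_error(load_dataset(character(0)), "no mzML files")
})

test_that("interlaced scan filters are all discovered and counted", {
  dir <- withr::local_tempdir()
  mk <- function(i) {
    spectra <- lapply(0:5, function(k) {
      make_spectrum(400 + k, 10, k * 1.0,
                    filter = if (k %% 3 == 2) "SIM" else "FULL")
    })
    line <- structure(list(source_id = sprintf("i%d.mzML", i),
                           line_index = i, spectra = spectra),
                      class = "LineScan")
    p <- file.path(dir, sprintf("i%d.mzML", i))
    write_mzml(line, p)
    p
  }
  ds <- load_dataset(c(mk(0), mk(1)))
  expect_setequal(ds$filters, c("FULL", "SIM"))
  ft <- list_scan_filters(ds)
  expect_equal(nrow(ft), 2L)
  expect_equal(sum(ft$n_scans), 12L)
  expect_equal(ft$n_scans[ft$scan_filter == "SIM"], 4L)
})

test_that("filter counts sum to the total scan count on simulated data", {
  sim <- get_sim("alignment")
  ft <- list_scan_filters(sim$dataset)
  total <- sum(vapply(sim$dataset$lines,
                      function(ln) length(ln$spectra), integer(1)))
  expect_equal(sum(ft$n_scans), total)
})

test_that("sort_line_paths orders embedded numbers numerically", {
  p <- c("run/line_10.mzML", "run/line_2.mzML", "run/line_1.mzML")
  expect_equal(sort_line_paths(p),
               c("run/line_1.mzML", "run/line_2.mzML", "run/line_10.mzML"))
  p2 <- c("b2a10.mzML", "b2a9.mzML", "b10a1.mzML")
  expect_equal(sort_line_paths(p2),
               c("b2a9.mzML", "b2a10.mzML", "b10a1.mzML"))
})
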
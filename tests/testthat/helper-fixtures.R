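# In-memory spectrum / line / dataset builders (no files involved)

make_spectrum <- function(mz, intensity, time_s, filter = "FT", tic = NULL) {
  list(mz = mz, intensity = intensity, time_s = time_s,
       scan_filter = filter, tic = if (is.null(tic)) sum(intensity) else tic)
}

# one single-peak spectrum per time; per-scan TIC from `values`
make_line <- function(times, values = NULL, filter = "FT", line_index = 0L) {
  spectra <- lapply(seq_along(times), function(i) {
    v <- if (is.null(values)) 100 else values[i]
    make_spectrum(500.0, v, times[i], filter, tic = v)
  })
  structure(list(source_id = paste0("mem_", line_index),
                 line_index = as.integer(line_index), spectra = spectra),
            class = "LineScan")
}

make_dataset <- function(lines, speed = 20, step = 75) {
  filters <- unique(unlist(lapply(lines, function(ln) {
    vapply(ln$spectra, `[[`, character(1), "scan_filter")
  })))
  structure(list(lines = lines,
                 geometry = acquisition_geometry(speed, step),
                 filters = filters),
            class = "ImagingDataset")
}

# random LineScan for writer/reader round trips
random_line <- function(line_index, n_scans = 30, n_peaks = 50) {
  times <- cumsum(runif(n_scans, 0.7, 1.3))
  spectra <- lapply(seq_len(n_scans), function(i) {
    mz <- sort(runif(n_peaks, 100, 1000))
    make_spectrum(mz, 10^runif(n_peaks, 2, 7), times[i],
                  filter = "FTMS + p ESI Full ms [100.00-1000.00]")
  })
  structure(list(source_id = sprintf("rt_%02d.mzML", line_index),
                 line_index = as.integer(line_index), spectra = spectra),
            class = "LineScan")
}

# Shared simulated datasets, generated once per test run
.sim_cache <- new.env(parent = emptyenv())

get_sim <- function(name, seed = 1L) {
  key <- paste0(name, "_", seed)
  if (!is.null(.sim_cache[[key]])) return(.sim_cache[[key]])
  ph <- switch(name,
    alignment = phantom_alignment(),
    two_region = phantom_two_region(),
    gradient = phantom_gradient(),
    stop("unknown sim preset ", name))
  dir <- file.path(tempdir(), paste0("msiline_sim_", key))
  unlink(dir, recursive = TRUE)
  res <- generate_dataset(ph, agc_model(jitter = 0.3),
                          acquisition_geometry(), dir, seed = seed,
                          write_truth = FALSE)
  ds <- suppressMessages(load_dataset(res$paths, res$geometry))
  flt <- ds$filters[[1L]]
  grid <- build_time_grid(ds, flt)
  out <- list(phantom = ph, dataset = ds, scan_filter = flt, grid = grid,
              paths = res$paths, agc = res$agc)
  .sim_cache[[key]] <- out
  out
}
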
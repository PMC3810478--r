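# Configuration files, signature/report export, TIFF image I/O.

#' Load a run configuration from YAML or JSON
#'
#' A configuration holds `fluorophores` blocks (`tau_ns`, `r0`, `theta_ns`,
#' `peak_nm`, `fwhm_nm`, optional `brightness`), an optional `grid` block
#' (`T_ns`, `n_time_gates` or `time_edges_ns`, `wavelength_edges_nm` or
#' `wavelength_range_nm` + `n_spectral_bins`, `polarizations`), and optional
#' `optimization` (`epsilon`, `max_channels`, `x_range`) and `simulation`
#' (`N`, `rows`, `cols`, `seed`, `reps`) blocks. Missing grid fields default
#' to the reference instrument (12.5 ns period, 64 time gates, 16 spectral
#' bins over 440-630 nm, both polarizations). Validation errors name the
#' offending field.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list of class `run_config` with elements `fluorophores` (named
#'   list of [fluorophore()]), `grid` ([detection_grid()]), `optimization`,
#'   `simulation`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Config file not found: %s", path), class = "hdim_error_io")
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw$fluorophores) || length(raw$fluorophores) == 0L) {
    abort("Config error at `fluorophores`: at least one block is required.",
          class = "hdim_error_config")
  }
  fluors <- imap(raw$fluorophores, function(fb, nm) {
    for (field in c("tau_ns", "peak_nm", "fwhm_nm")) {
      if (is.null(fb[[field]])) {
        abort(sprintf("Config error at `fluorophores$%s$%s`: field is required.",
                      nm, field),
              class = "hdim_error_config")
      }
    }
    tryCatch(
      fluorophore(tau_ns = fb$tau_ns, r0 = fb$r0 %||% 0,
                  theta_ns = fb$theta_ns %||% 1,
                  peak_nm = fb$peak_nm, fwhm_nm = fb$fwhm_nm,
                  brightness = fb$brightness %||% 1,
                  name = if (is.character(nm) && nzchar(nm)) nm else fb$name),
      hdim_error_domain = function(e) {
        abort(sprintf("Config error at `fluorophores$%s`: %s", nm,
                      conditionMessage(e)),
              class = "hdim_error_config")
      }
    )
  })
  gb <- raw$grid %||% list()
  T_ns <- gb$T_ns %||% 12.5
  time_edges <- if (!is.null(gb$time_edges_ns)) {
    as.numeric(gb$time_edges_ns)
  } else {
    seq(0, T_ns, length.out = (gb$n_time_gates %||% 64) + 1)
  }
  wavelength_edges <- if (!is.null(gb$wavelength_edges_nm)) {
    as.numeric(gb$wavelength_edges_nm)
  } else {
    rng <- gb$wavelength_range_nm %||% c(440, 630)
    seq(rng[1], rng[2], length.out = (gb$n_spectral_bins %||% 16) + 1)
  }
  grid <- tryCatch(
    detection_grid(time_edges, T_ns, wavelength_edges,
                   gb$polarizations %||% c("parallel", "perpendicular")),
    error = function(e) {
      abort(sprintf("Config error at `grid`: %s", conditionMessage(e)),
            class = "hdim_error_config")
    }
  )
  sim <- raw$simulation %||% list()
  # unquoted `N:` is a YAML 1.1 boolean; recover the intended key name
  names(sim)[names(sim) %in% c("FALSE", "no")] <- "N"
  structure(list(fluorophores = fluors, grid = grid,
                 optimization = raw$optimization %||% list(),
                 simulation = sim),
            class = "run_config")
}

#' Save a run configuration back to YAML
#'
#' Inverse of [load_config()]: [load_config()] of the written file rebuilds
#' an identical configuration.
#'
#' @param config A `run_config`.
#' @param path Output path (`.yaml`).
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  fl <- lapply(config$fluorophores, function(f) {
    list(tau_ns = f$tau_ns, r0 = f$r0, theta_ns = f$theta_ns,
         peak_nm = f$peak_nm, fwhm_nm = f$fwhm_nm, brightness = f$brightness)
  })
  names(fl) <- vapply(config$fluorophores, `[[`, character(1), "name")
  out <- list(
    fluorophores = fl,
    grid = list(T_ns = config$grid$laser_period_ns,
                time_edges_ns = config$grid$time_edges,
                wavelength_edges_nm = config$grid$wavelength_edges,
                polarizations = config$grid$polarizations),
    optimization = config$optimization,
    simulation = config$simulation
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Export a signature as a per-channel CSV table
#'
#' One row per channel in flattened order, with channel boundaries
#' (wavelengths in nm, times in ns) and the expected photon fraction.
#'
#' @param hdss An `hdss` signature.
#' @param path Output CSV path.
#' @return The written tibble, invisibly.
#' @export
write_signature_csv <- function(hdss, path) {
  tab <- channel_table(hdss$grid)
  tab$fraction <- as_channel_vector(hdss)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(as_tibble(tab))
}

#' Write / read a multi-channel image as multi-page TIFF plus JSON sidecar
#'
#' Each detection channel becomes one float TIFF page (flattened
#' polarization-major channel order); counts are scaled into `[0, 1]` for
#' storage and the scale factor, grid definition, photon level and seed are
#' recorded in a JSON sidecar (`<path>.json`) so the image round-trips
#' exactly.
#'
#' @param image An `hdim_image`.
#' @param path Output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(image, path) {
  stopifnot(inherits(image, "hdim_image"))
  cm <- counts_matrix(image)
  scale <- max(1, max(cm$mat))
  pages <- lapply(seq_len(nrow(cm$mat)), function(ch) {
    matrix(cm$mat[ch, ] / scale, cm$rows, cm$cols)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  sidecar <- list(
    count_scale = scale,
    expected_N = image$expected_N,
    seed = image$seed,
    fluorophores = image$fluorophores,
    grid = list(time_edges_ns = image$grid$time_edges,
                T_ns = image$grid$laser_period_ns,
                wavelength_edges_nm = image$grid$wavelength_edges,
                polarizations = image$grid$polarizations)
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path) {
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  grid <- detection_grid(sidecar$grid$time_edges_ns, sidecar$grid$T_ns,
                         sidecar$grid$wavelength_edges_nm,
                         sidecar$grid$polarizations)
  d <- grid_dims(grid)
  rows <- nrow(pages[[1L]])
  cols <- ncol(pages[[1L]])
  flat <- vapply(pages, function(p) as.vector(t(p)), numeric(rows * cols))
  # flat: pixels x channels with pixel index row-major; rebuild (rows, cols, ch)
  counts <- round(array(flat, dim = c(cols, rows, length(pages))) *
                    sidecar$count_scale)
  counts <- aperm(counts, c(2L, 1L, 3L))
  # unflatten channels (time fastest) back to (pol, wl, time)
  arr <- array(aperm(counts, c(3L, 1L, 2L)),
               dim = c(unname(d[c("time", "wavelength", "pol")]), rows, cols))
  arr <- aperm(arr, c(4L, 5L, 3L, 2L, 1L))
  structure(
    list(counts = arr, grid = grid, true_abundances = NULL,
         expected_N = sidecar$expected_N, seed = sidecar$seed,
         fluorophores = sidecar$fluorophores),
    class = "hdim_image"
  )
}

#' Write an analysis report: CSV tables plus a reproducibility manifest
#'
#' Writes every data frame in `results` as `<name>.csv` inside `dir`, plus a
#' `manifest.json` recording the package version, seed, and the
#' configuration (with a content hash) needed to reproduce the run
#' bit-for-bit.
#'
#' @param results Named list of data frames.
#' @param dir Output directory (created if needed).
#' @param config Optional `run_config` to embed.
#' @param seed Optional seed to record.
#' @return Path to the manifest, invisibly.
#' @export
write_report <- function(results, dir, config = NULL, seed = NULL) {
  stopifnot(is.list(results), length(names(results)) == length(results))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) {
    abort(sprintf("Cannot create report directory: %s", dir),
          class = "hdim_error_io")
  }
  for (nm in names(results)) {
    utils::write.csv(results[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  cfg <- if (!is.null(config)) {
    tmp <- tempfile(fileext = ".yaml")
    save_config(config, tmp)
    list(yaml = paste(readLines(tmp), collapse = "\n"),
         hash = rlang::hash(readLines(tmp)))
  }
  manifest <- list(
    package = "hdimtools",
    version = as.character(utils::packageVersion("hdimtools")),
    seed = seed,
    tables = names(results),
    config = cfg,
    created = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, null = "null")
  invisible(mpath)
}
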
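#' Write sinograms to a multi-page 32-bit TIFF with an angle sidecar
#'
#' The interchange format with beamline tooling: one TIFF page per
#' sinogram plus a JSON sidecar (`<path>.json`) holding the projection
#' angles and provenance.
#'
#' Projection values are affinely mapped to the 32-bit integer sample
#' range; the map's offset/scale live in the sidecar, so arbitrary
#' intensity units round-trip to about 1e-9 relative precision.
#'
#' @param sinos A [sinogram()] or list of sinograms sharing one angle
#'   grid.
#' @param path Output `.tif` path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_sinogram_tiff <- function(sinos, path) {
  if (is_sinogram(sinos)) sinos <- list(sinos)
  stopifnot(length(sinos) > 0L, all(vapply(sinos, is_sinogram, logical(1))))
  ang <- angles(sinos[[1]])
  enc <- encode_pages(lapply(sinos, sino_data), path)
  jsonlite::write_json(list(angles_deg = ang, n_pages = length(sinos),
                            offset = enc$offset, scale = enc$scale,
                            format = "destriper-sinogram-stack", version = 1L),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# TIFF samples are unsigned integers scaled from [0, 1]; intensities are
# therefore stored as (x - offset) / scale at 32 bits and undone on read.
encode_pages <- function(pages, path) {
  rng <- range(vapply(pages, range, numeric(2)))
  offset <- rng[1]
  scale <- diff(rng)
  norm <- if (scale > 0) {
    lapply(pages, function(m) (m - offset) / scale)
  } else {
    lapply(pages, function(m) m * 0)
  }
  tiff::writeTIFF(norm, path, bits.per.sample = 32L, reduce = FALSE)
  list(offset = offset, scale = scale)
}

decode_page <- function(m, offset, scale) {
  if (is.null(offset) || is.null(scale)) return(m)
  m * scale + offset
}

# Write a stack of plain images (e.g. reconstructed slices) with the
# same normalized 32-bit encoding + sidecar as sinogram stacks.
write_image_stack <- function(images, path) {
  enc <- encode_pages(images, path)
  jsonlite::write_json(list(n_pages = length(images), offset = enc$offset,
                            scale = enc$scale,
                            format = "destriper-image-stack", version = 1L),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load sinograms from TIFF stacks, TIFF directories, or dataset folders
#'
#' Accepts: a multi-page TIFF written by [write_sinogram_tiff()] (angles
#' from its JSON sidecar), a directory of single-page 2-D TIFFs of one
#' common size, or a dataset directory from [write_dataset()] (loads the
#' corrupted stack). Integer inputs are promoted to float.
#'
#' @param path File or directory.
#' @param angles_deg Optional angle vector overriding/replacing sidecar
#'   metadata; required for bare TIFFs without a sidecar.
#' @return List of [sinogram()]s.
#' @export
load_sinograms <- function(path, angles_deg = NULL) {
  if (dir.exists(path)) {
    if (file.exists(file.path(path, "meta.json"))) {
      ds <- read_dataset(path)
      return(lapply(c(ds$train, ds$test), function(r) r$corrupted))
    }
    files <- sort(list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                             full.names = TRUE))
    if (length(files) == 0L) {
      stop("no TIFF files found under ", path,
           "; expected *.tif sinograms or a dataset with meta.json",
           call. = FALSE)
    }
    mats <- lapply(files, read_tiff_matrix)
    dims <- vapply(mats, dim, integer(2))
    bad <- which(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])
    if (length(bad) > 0L) {
      stop("mixed image sizes in ", path, ": ", basename(files[bad[1]]),
           " is ", paste(dims[, bad[1]], collapse = "x"),
           " but ", basename(files[1]), " is ",
           paste(dims[, 1], collapse = "x"), call. = FALSE)
    }
  } else {
    if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
    pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
    if (!is.list(pages)) pages <- list(pages)
    mats <- lapply(pages, page_to_matrix)
    sidecar <- paste0(path, ".json")
    if (file.exists(sidecar)) {
      js <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
      if (is.null(angles_deg)) angles_deg <- js$angles_deg
      mats <- lapply(mats, decode_page, offset = js$offset, scale = js$scale)
    }
  }
  if (is.null(angles_deg)) {
    stop("no angle metadata: supply angles_deg or provide a '",
         basename(path), ".json' sidecar with an angles_deg field",
         call. = FALSE)
  }
  lapply(mats, sinogram, angles_deg = angles_deg)
}

read_tiff_matrix <- function(f) {
  img <- tiff::readTIFF(f, as.is = FALSE)
  page_to_matrix(img)
}

page_to_matrix <- function(img) {
  if (length(dim(img)) == 3L) img <- img[, , 1]
  m <- as.matrix(img)
  storage.mode(m) <- "double"
  m
}

#' Persist / load a paired dataset
#'
#' Canonical on-disk layout for paired clean/corrupted data: a directory
#' holding multi-page 32-bit TIFF stacks `train_clean.tif`,
#' `train_corrupted.tif`, `test_clean.tif`, `test_corrupted.tif` plus
#' `meta.json` (angles, stripe specification, seeds, split indices).
#' Wavelet coefficients and artifact fields are recomputed on load, so
#' a round trip reproduces [build_dataset()]'s records to near machine
#' precision.
#'
#' @param dataset A `sino_dataset` from [build_dataset()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "sino_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stack_scales <- list()
  for (split in c("train", "test")) {
    recs <- dataset[[split]]
    for (kind in c("clean", "corrupted")) {
      field <- if (kind == "clean") function(r) sino_data(r$clean)
               else function(r) sino_data(r$corrupted)
      enc <- encode_pages(lapply(recs, field),
                          file.path(dir, paste0(split, "_", kind, ".tif")))
      stack_scales[[paste0(split, "_", kind)]] <- enc
    }
  }
  meta <- dataset$meta
  jsonlite::write_json(
    list(format = "destriper-dataset", version = 1L,
         angles_deg = meta$angles,
         stripe_spec = unclass(meta$spec),
         n_total = meta$n_total, train_fraction = meta$train_fraction,
         size_px = meta$size_px, n_shapes = meta$n_shapes,
         seed = meta$seed, train_idx = meta$train_idx,
         test_idx = meta$test_idx, stack_scales = stack_scales),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  meta_path <- file.path(dir, "meta.json")
  if (!file.exists(meta_path)) {
    stop(dir, " is not a dataset directory (missing meta.json)", call. = FALSE)
  }
  js <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  ang <- js$angles_deg
  spec <- do.call(stripe_spec, js$stripe_spec[c("n_stripes_range",
                                                "width_range_px",
                                                "amplitude_range",
                                                "partial_fraction",
                                                "mode", "seed")])
  load_split <- function(split) {
    clean <- tiff::readTIFF(file.path(dir, paste0(split, "_clean.tif")), all = TRUE)
    corr <- tiff::readTIFF(file.path(dir, paste0(split, "_corrupted.tif")), all = TRUE)
    if (!is.list(clean)) clean <- list(clean)
    if (!is.list(corr)) corr <- list(corr)
    sc_cl <- js$stack_scales[[paste0(split, "_clean")]]
    sc_co <- js$stack_scales[[paste0(split, "_corrupted")]]
    purrr::map2(clean, corr, function(cl, co) {
      cl <- decode_page(page_to_matrix(cl), sc_cl$offset, sc_cl$scale)
      co <- decode_page(page_to_matrix(co), sc_co$offset, sc_co$scale)
      pc <- pad_to_even(cl); pco <- pad_to_even(co)
      clean_coeffs <- hdwt(pc$image)
      corrupted_coeffs <- hdwt(pco$image)
      structure(list(
        clean = sinogram(cl, ang), corrupted = sinogram(co, ang),
        artifact_field = co - cl,
        clean_coeffs = clean_coeffs, corrupted_coeffs = corrupted_coeffs,
        artifact_coeffs = coeffs_map2(corrupted_coeffs, clean_coeffs, `-`),
        pad = pc$pad,
        meta = list(seed = NA_integer_, spec = spec,
                    n_stripes = NA_integer_, stripes = NULL)
      ), class = "sample_record")
    })
  }
  structure(list(train = load_split("train"), test = load_split("test"),
                 meta = list(n_total = js$n_total,
                             train_fraction = js$train_fraction,
                             size_px = js$size_px, n_shapes = js$n_shapes,
                             angles = ang, spec = spec, seed = js$seed,
                             train_idx = js$train_idx,
                             test_idx = js$test_idx)),
            class = "sino_dataset")
}

#' Write a machine-readable run manifest
#'
#' Records everything needed to re-execute a pipeline run bit-identically
#' in deterministic mode: the resolved configuration, master seed, package
#' version, and MD5 fingerprints of the input files.
#'
#' @param path Output JSON path.
#' @param command Pipeline stage name.
#' @param config Named list of resolved configuration values.
#' @param inputs Character vector of input file paths to fingerprint.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, command, config, inputs = character()) {
  # fingerprint files only; for dataset directories take their meta.json
  inputs <- unlist(lapply(inputs, function(p) {
    if (dir.exists(p)) {
      mj <- file.path(p, "meta.json")
      if (file.exists(mj)) mj else character()
    } else if (file.exists(p)) p else character()
  }))
  inputs <- as.character(inputs)
  hashes <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  jsonlite::write_json(
    list(format = "destriper-manifest", version = 1L, command = command,
         package_version = as.character(utils::packageVersion("destriper")),
         r_version = R.version.string,
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         config = config, input_md5 = hashes),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
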
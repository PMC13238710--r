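#' Write / read a binary mask with pixel-size sidecar
#'
#' Masks are stored as single-channel images (PNG or TIFF by extension;
#' 0 = background) with a YAML sidecar (`<path>.yaml`) holding
#' `pixel_size_um` and an optional class label.
#'
#' @param mask A [raster_mask].
#' @param path Output path ending in `.png`, `.tif` or `.tiff`.
#' @param label Optional class label stored in the sidecar.
#' @return `read_mask` returns a [raster_mask].
#' @export
write_mask <- function(mask, path, label = NULL) {
  stopifnot(is_raster_mask(mask))
  img <- mask$grid * 1.0
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(img, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(img, path, bits.per.sample = 8L)
  } else {
    stop("mask path must end in .png, .tif or .tiff", call. = FALSE)
  }
  yaml::write_yaml(
    list(pixel_size_um = mask$pixel_size_um, label = label),
    paste0(path, ".yaml")
  )
  invisible(path)
}

#' @rdname write_mask
#' @param pixel_size_um Pixel size override; by default read from the
#'   sidecar.
#' @export
read_mask <- function(path, pixel_size_um = NULL) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    png::readPNG(path)
  } else {
    tiff::readTIFF(path)
  }
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  if (is.null(pixel_size_um)) {
    sidecar <- paste0(path, ".yaml")
    if (!file.exists(sidecar)) {
      stop("no pixel_size_um given and no sidecar found at ", sidecar, call. = FALSE)
    }
    pixel_size_um <- yaml::read_yaml(sidecar)$pixel_size_um
  }
  raster_mask(img > 0.5, pixel_size_um)
}

#' Write / read a 16-bit channel image (TIFF) with sidecar
#'
#' @param channel A [channel_image].
#' @param path Output path ending in `.tif`/`.tiff`.
#' @return `read_channel` returns a [channel_image].
#' @export
write_channel <- function(channel, path) {
  stopifnot(inherits(channel, "channel_image"))
  tiff::writeTIFF(pmin(channel$grid, 65535) / 65535, path, bits.per.sample = 16L)
  yaml::write_yaml(
    list(marker = channel$marker, pixel_size_um = channel$pixel_size_um,
         bit_depth = channel$bit_depth),
    paste0(path, ".yaml")
  )
  invisible(path)
}

#' @rdname write_channel
#' @export
read_channel <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  channel_image(round(img * 65535), meta$marker, meta$pixel_size_um,
                bit_depth = meta$bit_depth %||% 16)
}

#' Write an annotated section to a directory
#'
#' Channels become 16-bit TIFFs, masks PNG label images, and metadata
#' (pixel size, planted ground truth when present) a YAML file; the
#' basement-membrane polyline can be recovered downstream with
#' [basement_membrane] and exported with [write_polyline_csv].
#'
#' @param section An `annotated_section`.
#' @param dir Output directory (created if needed).
#' @param id Section identifier used as filename prefix.
#' @return `read_section` returns an `annotated_section`.
#' @export
write_section <- function(section, dir, id = "section") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (marker in names(section$channels)) {
    safe <- gsub("[^A-Za-z0-9]", "", marker)
    write_channel(section$channels[[marker]],
                  file.path(dir, sprintf("%s_chan_%s.tif", id, safe)))
  }
  for (mn in names(section$masks)) {
    write_mask(section$masks[[mn]],
               file.path(dir, sprintf("%s_mask_%s.png", id, mn)), label = mn)
  }
  meta <- list(
    id = id,
    pixel_size_um = section$pixel_size_um,
    channels = names(section$channels),
    masks = names(section$masks),
    truth = section$truth
  )
  yaml::write_yaml(meta, file.path(dir, sprintf("%s_meta.yaml", id)))
  invisible(dir)
}

#' @rdname write_section
#' @export
read_section <- function(dir, id = "section") {
  meta <- yaml::read_yaml(file.path(dir, sprintf("%s_meta.yaml", id)))
  channels <- list()
  for (marker in meta$channels) {
    safe <- gsub("[^A-Za-z0-9]", "", marker)
    channels[[marker]] <- read_channel(
      file.path(dir, sprintf("%s_chan_%s.tif", id, safe))
    )
  }
  masks <- list()
  for (mn in meta$masks) {
    masks[[mn]] <- read_mask(file.path(dir, sprintf("%s_mask_%s.png", id, mn)))
  }
  truth <- meta$truth
  if (!is.null(truth$fiber_mean)) truth$fiber_mean <- unlist(truth$fiber_mean)
  structure(list(
    channels = channels, masks = masks,
    pixel_size_um = meta$pixel_size_um,
    truth = truth
  ), class = "annotated_section")
}

#' Export a basement-membrane polyline as CSV
#'
#' Ordered 0-based `(row, col)` pixel coordinates, one row per vertex, with
#' a `polyline` index for multi-segment membranes.
#'
#' @param membrane A `basement_membrane` (see [basement_membrane]).
#' @param path Output CSV path.
#' @export
write_polyline_csv <- function(membrane, path) {
  stopifnot(inherits(membrane, "basement_membrane"))
  rows <- lapply(seq_along(membrane$polylines), function(i) {
    m <- membrane$polylines[[i]]
    data.frame(polyline = i, row = m[, 1L], col = m[, 2L])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Materialize a synthetic cohort as a file tree
#'
#' Writes every image (channels + masks + metadata), the clinical CSVs
#' (QST raw values, nerve conduction, pain ratings), the qPCR Ct table, and
#' a JSON truth manifest recording every planted parameter.
#'
#' @param cohort A `skin_cohort` from [generate_cohort].
#' @param dir Output directory.
#' @param images Write the image files (set `FALSE` for tables only).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir, images = TRUE) {
  stopifnot(inherits(cohort, "skin_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$subjects, file.path(dir, "subjects.csv"), row.names = FALSE)
  utils::write.csv(cohort$clinical$qst, file.path(dir, "qst_raw.csv"), row.names = FALSE)
  utils::write.csv(cohort$clinical$ncs, file.path(dir, "ncs.csv"), row.names = FALSE)
  utils::write.csv(cohort$clinical$nrs, file.path(dir, "nrs.csv"), row.names = FALSE)
  utils::write.csv(cohort$ct, file.path(dir, "ct_values.csv"), row.names = FALSE)
  truth <- cohort$truth
  truth$subject_factors <- NULL
  jsonlite::write_json(
    list(planted = truth,
         subject_factors = cohort$truth$subject_factors),
    file.path(dir, "truth_manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  if (images) {
    img_dir <- file.path(dir, "images")
    for (entry in cohort$image_specs) {
      section <- generate_section(entry$spec)
      write_section(section, img_dir,
                    id = sprintf("%s_img%d", entry$subject, entry$image))
    }
  }
  invisible(dir)
}
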
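#' Single-channel fluorescence image
#'
#' A 2D non-negative intensity raster for one marker channel, sharing the
#' grid and pixel size of its companion masks. Intensities are kept as
#' acquired (12- or 16-bit range); no background subtraction or flat-field
#' correction is applied -- ratio normalization to the pan-neuronal reference
#' marker is the analysis-level control for staining and imaging variability.
#'
#' @param grid Numeric matrix of non-negative intensities.
#' @param marker Marker label (e.g. `"PGP9.5"`, `"TrkA"`).
#' @param pixel_size_um Micrometers per pixel edge.
#' @param bit_depth Acquisition bit depth, 12 or 16 (metadata only).
#' @return An object of class `channel_image`.
#' @export
channel_image <- function(grid, marker, pixel_size_um, bit_depth = 16) {
  if (is.null(dim(grid)) || length(dim(grid)) != 2L) {
    stop("`grid` must be a 2D matrix", call. = FALSE)
  }
  if (anyNA(grid) || any(grid < 0)) {
    stop("intensities must be non-negative and non-missing", call. = FALSE)
  }
  if (!is_scalar_number(pixel_size_um) || pixel_size_um <= 0) {
    stop("`pixel_size_um` must be a single positive number", call. = FALSE)
  }
  if (!bit_depth %in% c(8, 12, 16)) {
    stop("`bit_depth` must be 8, 12 or 16", call. = FALSE)
  }
  structure(
    list(grid = grid, marker = marker,
         pixel_size_um = as.numeric(pixel_size_um), bit_depth = bit_depth),
    class = "channel_image"
  )
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("<channel_image> %s: %d x %d px @ %.4g um/px (%d-bit)\n",
              x$marker, nrow(x$grid), ncol(x$grid), x$pixel_size_um, x$bit_depth))
  invisible(x)
}

check_channel_mask <- function(channel, mask) {
  stopifnot(inherits(channel, "channel_image"), is_raster_mask(mask))
  if (!identical(dim(channel$grid), dim(mask$grid))) {
    stop("channel image and mask have different grid shapes", call. = FALSE)
  }
  invisible(TRUE)
}

#' Mean fluorescence intensity within nerve fibers inside an ROI
#'
#' Arithmetic mean of channel intensities over the pixels of
#' `nerve & roi`. Marker quantification is restricted to nerve fiber
#' segmentations: intensity outside fibers never contributes. When the
#' intersection is empty the MFI is *missing*, never zero -- absence of
#' fibers is not zero intensity.
#'
#' @param channel A [channel_image].
#' @param nerve [raster_mask] of nerve fibers (conventionally the
#'   pan-neuronal PGP9.5-based mask, shared by all markers of an image).
#' @param roi [raster_mask] of the region (epidermis, sub-epidermis, dermis).
#' @param roi_name Label of the region, stored in the record.
#' @return An object of class `mfi_record`: `marker`, `roi_name`, `mfi`
#'   (`NA` if no pixels), `pixel_count`, `normalized_to`, `normalized_mfi`.
#' @export
mfi <- function(channel, nerve, roi, roi_name = "roi") {
  check_channel_mask(channel, nerve)
  check_compatible(nerve, roi, "nerve mask and roi")
  sel <- nerve$grid & roi$grid
  n <- sum(sel)
  structure(
    list(
      marker = channel$marker,
      roi_name = roi_name,
      mfi = if (n > 0L) mean(channel$grid[sel]) else NA_real_,
      pixel_count = n,
      normalized_to = NA_character_,
      normalized_mfi = NA_real_
    ),
    class = "mfi_record"
  )
}

#' @export
print.mfi_record <- function(x, ...) {
  cat(sprintf("<mfi_record> %s in %s: mfi=%s over %d px%s\n",
              x$marker, x$roi_name,
              if (is.na(x$mfi)) "missing" else sprintf("%.2f", x$mfi),
              x$pixel_count,
              if (!is.na(x$normalized_mfi)) {
                sprintf(", normalized to %s = %.3f", x$normalized_to, x$normalized_mfi)
              } else ""))
  invisible(x)
}

#' Normalize a marker MFI to a reference marker
#'
#' Ratio of a target marker's MFI to a reference marker's MFI in the same
#' region (e.g. TrkA / PGP9.5). The ratio is invariant to any common
#' intensity scaling, which is why it is the preferred comparison metric.
#'
#' @param target,reference `mfi_record`s from [mfi] with the same `roi_name`.
#' @return A copy of `target` with `normalized_to` and `normalized_mfi`
#'   filled; the ratio is `NA` (flagged via `attr(, "flag")`) when the
#'   reference MFI is missing or non-positive, and missing target MFI
#'   propagates.
#' @export
normalized_mfi <- function(target, reference) {
  stopifnot(inherits(target, "mfi_record"), inherits(reference, "mfi_record"))
  if (!identical(target$roi_name, reference$roi_name)) {
    stop("target and reference MFI must come from the same ROI", call. = FALSE)
  }
  out <- target
  out$normalized_to <- reference$marker
  if (is.na(reference$mfi) || reference$mfi <= 0) {
    out$normalized_mfi <- NA_real_
    attr(out, "flag") <- "reference_mfi_missing_or_zero"
  } else if (is.na(target$mfi)) {
    out$normalized_mfi <- NA_real_
  } else {
    out$normalized_mfi <- target$mfi / reference$mfi
  }
  out
}

#' Marker-positive area fraction within an ROI
#'
#' Fraction of the total nerve fiber area occupied by a marker-positive
#' subset (e.g. CGRP+ area / PGP9.5+ area), within a region of interest.
#'
#' @param marker_mask [raster_mask] of marker-positive fibers.
#' @param total_mask [raster_mask] of all fibers.
#' @param roi Optional [raster_mask] restricting both areas.
#' @return The ratio in `[0, 1]` when `marker_mask` is contained in
#'   `total_mask`; `NA` when the total area in the ROI is zero. A ratio > 1
#'   (marker pixels outside the total mask: segmentation inconsistency)
#'   triggers a warning.
#' @export
area_ratio <- function(marker_mask, total_mask, roi = NULL) {
  check_compatible(marker_mask, total_mask, "marker and total masks")
  denom <- mask_area(total_mask, roi)
  if (denom == 0) return(NA_real_)
  ratio <- mask_area(marker_mask, roi) / denom
  if (ratio > 1) {
    warning("area ratio > 1: marker mask extends outside the total mask",
            call. = FALSE)
  }
  ratio
}
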
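#' Binary raster mask with physical pixel size
#'
#' The unit of all morphometry in skinquant: a 2D logical grid together with
#' an isotropic pixel edge length in micrometers. Segmentation classes
#' (epidermis, dermis, nerve fibers, blood vessels) are each represented as
#' one `raster_mask` on a shared grid.
#'
#' Coordinate convention: matrices are indexed `[row, col]`; pixel `(r, c)`
#' (1-based in R, 0-based in exported CSVs) has its center at
#' `(r - 0.5, c - 0.5)` pixel units from the image origin. All distances are
#' Euclidean distances between pixel centers.
#'
#' @param grid A logical (or 0/1 numeric) matrix; `TRUE` marks foreground.
#' @param pixel_size_um Micrometers per pixel edge; a single positive number.
#' @return An object of class `raster_mask` with fields `grid` and
#'   `pixel_size_um`.
#' @examples
#' m <- raster_mask(matrix(c(TRUE, FALSE, TRUE, TRUE), 2, 2), pixel_size_um = 0.61)
#' mask_area(m)  # 3 * 0.61^2
#' @export
raster_mask <- function(grid, pixel_size_um) {
  if (is.null(dim(grid)) || length(dim(grid)) != 2L) {
    stop("`grid` must be a 2D matrix", call. = FALSE)
  }
  if (nrow(grid) < 1L || ncol(grid) < 1L) {
    stop("`grid` must have at least 1x1 pixels", call. = FALSE)
  }
  if (!is.logical(grid)) {
    grid <- matrix(as.vector(grid) != 0, nrow(grid), ncol(grid))
  }
  if (anyNA(grid)) stop("`grid` must not contain NA", call. = FALSE)
  if (!is_scalar_number(pixel_size_um) || pixel_size_um <= 0) {
    stop("`pixel_size_um` must be a single positive number", call. = FALSE)
  }
  structure(
    list(grid = grid, pixel_size_um = as.numeric(pixel_size_um)),
    class = "raster_mask"
  )
}

#' @export
print.raster_mask <- function(x, ...) {
  cat(sprintf(
    "<raster_mask> %d x %d px @ %.4g um/px, %d foreground px (%.4g um^2)\n",
    nrow(x$grid), ncol(x$grid), x$pixel_size_um, sum(x$grid), mask_area(x)
  ))
  invisible(x)
}

is_raster_mask <- function(x) inherits(x, "raster_mask")

# Error unless two masks share grid shape and pixel size.
check_compatible <- function(a, b, what = "masks") {
  stopifnot(is_raster_mask(a), is_raster_mask(b))
  if (!identical(dim(a$grid), dim(b$grid))) {
    stop(sprintf("%s have different grid shapes (%s vs %s)", what,
                 paste(dim(a$grid), collapse = "x"),
                 paste(dim(b$grid), collapse = "x")), call. = FALSE)
  }
  if (!isTRUE(all.equal(a$pixel_size_um, b$pixel_size_um))) {
    stop(sprintf("%s have different pixel sizes (%g vs %g um)", what,
                 a$pixel_size_um, b$pixel_size_um), call. = FALSE)
  }
  invisible(TRUE)
}

#' Mask area in square micrometers
#'
#' Area of the foreground of `mask`, optionally restricted to a region of
#' interest, as foreground pixel count times `pixel_size_um^2`.
#'
#' @param mask A [raster_mask].
#' @param roi Optional [raster_mask] on the same grid; if given, the area of
#'   `mask & roi` is returned.
#' @return Area in um^2 (zero for an empty intersection).
#' @export
mask_area <- function(mask, roi = NULL) {
  stopifnot(is_raster_mask(mask))
  g <- mask$grid
  if (!is.null(roi)) {
    check_compatible(mask, roi, "mask and roi")
    g <- g & roi$grid
  }
  sum(g) * mask$pixel_size_um^2
}

#' Expand a mask by a physical distance
#'
#' Morphological expansion with a Euclidean closed ball: the result contains
#' exactly the pixels whose center lies within `distance_um` of the center of
#' some foreground pixel (foreground pixels themselves included, distance 0).
#' Used for the 50 um sub-epidermal band and the 5 um nerve proximity region.
#' Expansion is clipped at the image border.
#'
#' @param mask A [raster_mask].
#' @param distance_um Non-negative expansion distance in micrometers.
#' @return A [raster_mask] on the same grid.
#' @details Distances are computed with an exact Euclidean distance transform
#'   ([EBImage::distmap]); inclusion is `distance <= distance_um` with a
#'   1e-9 px tolerance so that lattice-exact radii (e.g. 5 px) include their
#'   boundary pixels.
#' @export
expand_mask <- function(mask, distance_um) {
  stopifnot(is_raster_mask(mask))
  if (!is_scalar_number(distance_um)) {
    stop("`distance_um` must be a single finite number", call. = FALSE)
  }
  if (distance_um < 0) {
    stop("`distance_um` must be >= 0", call. = FALSE)
  }
  g <- mask$grid
  if (distance_um == 0 || !any(g)) {
    return(mask)
  }
  r_px <- distance_um / mask$pixel_size_um
  d <- EBImage::imageData(EBImage::distmap(1 - g))
  raster_mask(g | (d <= r_px + 1e-9), mask$pixel_size_um)
}

#' Resolve overlapping epidermis/dermis masks
#'
#' Segmentation tools may emit overlapping class masks. [derive_subepidermis]
#' and [basement_membrane] require disjoint inputs, so this documented
#' pre-step reassigns every overlap pixel to one class (epidermis by default).
#'
#' @param epidermis,dermis [raster_mask]s on the same grid.
#' @param prefer `"epidermis"` or `"dermis"`: the class that keeps overlap
#'   pixels.
#' @return A list with the two disjoint masks and `n_overlap`, the number of
#'   reassigned pixels.
#' @export
resolve_mask_overlap <- function(epidermis, dermis, prefer = c("epidermis", "dermis")) {
  prefer <- match.arg(prefer)
  check_compatible(epidermis, dermis, "epidermis and dermis")
  ov <- epidermis$grid & dermis$grid
  if (prefer == "epidermis") {
    dermis <- raster_mask(dermis$grid & !ov, dermis$pixel_size_um)
  } else {
    epidermis <- raster_mask(epidermis$grid & !ov, epidermis$pixel_size_um)
  }
  list(epidermis = epidermis, dermis = dermis, n_overlap = sum(ov))
}
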
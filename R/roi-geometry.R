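#' Derive the sub-epidermal band
#'
#' The sub-epidermis is the dermal band within a fixed physical distance of
#' the epidermis, obtained by expanding the epidermis mask by `distance_um`
#' (default 50 um) and intersecting with the dermis mask.
#'
#' @param epidermis,dermis Disjoint [raster_mask]s on the same grid.
#' @param distance_um Expansion distance in micrometers (default 50).
#' @return A [raster_mask]: `expand_mask(epidermis, distance_um) & dermis`.
#' @seealso [resolve_mask_overlap] when segmentation masks overlap.
#' @export
derive_subepidermis <- function(epidermis, dermis, distance_um = 50) {
  check_compatible(epidermis, dermis, "epidermis and dermis")
  n_overlap <- sum(epidermis$grid & dermis$grid)
  if (n_overlap > 0L) {
    stop(sprintf(
      "epidermis and dermis masks overlap in %d pixel(s); resolve with resolve_mask_overlap()",
      n_overlap
    ), call. = FALSE)
  }
  expanded <- expand_mask(epidermis, distance_um)
  raster_mask(expanded$grid & dermis$grid, epidermis$pixel_size_um)
}

#' Extract the basement membrane (epidermis-dermis interface)
#'
#' Identifies the shared interface between epidermis and dermis -- the
#' counting line for intraepidermal nerve fiber density -- as ordered
#' polylines of epidermal boundary pixels that have an 8-adjacent dermal
#' neighbour, and measures its physical length. The free epidermal surface
#' (skin-air side) never contributes.
#'
#' @param epidermis,dermis Disjoint [raster_mask]s on the same grid.
#' @return An object of class `basement_membrane`:
#'   \describe{
#'     \item{polylines}{list of ordered coordinate matrices (columns `row`,
#'       `col`, 0-based pixel indices).}
#'     \item{length_mm}{total interface length in millimeters.}
#'     \item{band}{[raster_mask] of interface pixels (1 px wide,
#'       epidermis side), used for crossing detection.}
#'   }
#' @details Each epidermis component's closed boundary is traced in order
#'   ([EBImage::ocontour]); maximal runs of interface pixels along the
#'   boundary become polylines. The arc length of an open polyline is the sum
#'   of consecutive center-to-center distances plus one pixel of end extent,
#'   so a straight interface of `w` pixels has length exactly
#'   `w * pixel_size_um`. Length is invariant under translation and 90-degree
#'   rotation and scales linearly with `pixel_size_um`.
#' @export
basement_membrane <- function(epidermis, dermis) {
  check_compatible(epidermis, dermis, "epidermis and dermis")
  if (any(epidermis$grid & dermis$grid)) {
    stop("epidermis and dermis masks overlap; resolve with resolve_mask_overlap()",
         call. = FALSE)
  }
  px <- epidermis$pixel_size_um
  membrane <- epidermis$grid & dilate8(dermis$grid)
  if (!any(membrane)) {
    stop("no basement membrane found: epidermis and dermis are nowhere adjacent",
         call. = FALSE)
  }

  lab <- EBImage::bwlabel(epidermis$grid)
  contours <- EBImage::ocontour(lab)

  polylines <- list()
  total_px <- 0
  for (ct in contours) {
    # ocontour returns 0-based (row, col) vertices of the closed boundary walk
    r1 <- ct[, 1L] + 1L
    c1 <- ct[, 2L] + 1L
    on_membrane <- membrane[cbind(r1, c1)]
    # thin regions are traversed twice; count each pixel at first visit only
    first_visit <- !duplicated(cbind(r1, c1))
    keep <- as.vector(on_membrane & first_visit)
    n <- length(keep)
    if (!any(keep)) next

    if (all(keep)) {
      # whole boundary is interface: closed loop, arc includes the wrap step
      pts <- cbind(row = r1, col = c1)
      seg <- sqrt(diff(c(r1, r1[1L]))^2 + diff(c(c1, c1[1L]))^2)
      total_px <- total_px + sum(seg)
      polylines[[length(polylines) + 1L]] <- pts - 1L
      next
    }

    # rotate the cyclic sequence so it starts off-membrane, then take runs
    start <- which(!keep)[1L]
    ord <- c(start:n, if (start > 1L) 1:(start - 1L))
    kr <- keep[ord]
    runs <- rle(kr)
    pos <- cumsum(c(1L, runs$lengths))
    for (i in seq_along(runs$values)) {
      if (!runs$values[i]) next
      vid <- ord[pos[i]:(pos[i + 1L] - 1L)]
      pts <- cbind(row = r1[vid], col = c1[vid])
      if (nrow(pts) == 1L) {
        total_px <- total_px + 1
      } else {
        seg <- sqrt(diff(pts[, 1L])^2 + diff(pts[, 2L])^2)
        total_px <- total_px + sum(seg) + 1
      }
      polylines[[length(polylines) + 1L]] <- pts - 1L
    }
  }

  structure(
    list(
      polylines = polylines,
      length_mm = total_px * px / 1000,
      band = raster_mask(membrane, px),
      pixel_size_um = px
    ),
    class = "basement_membrane"
  )
}

#' @export
print.basement_membrane <- function(x, ...) {
  cat(sprintf("<basement_membrane> %d polyline(s), length %.4f mm, %d band px\n",
              length(x$polylines), x$length_mm, sum(x$band$grid)))
  invisible(x)
}

#' Build the full region-of-interest set for one section
#'
#' Bundles the epidermis and dermis masks with the derived sub-epidermal band
#' and the basement membrane into the `roi_set` consumed by the IENFD,
#' fluorescence and vessel quantification steps.
#'
#' @param epidermis,dermis Disjoint [raster_mask]s on the same grid.
#' @param distance_um Sub-epidermal band depth in micrometers (default 50).
#' @return An object of class `roi_set` with fields `epidermis`, `dermis`,
#'   `subepidermis`, `membrane` (a `basement_membrane`) and `distance_um`.
#' @export
roi_set <- function(epidermis, dermis, distance_um = 50) {
  membrane <- basement_membrane(epidermis, dermis)
  structure(
    list(
      epidermis = epidermis,
      dermis = dermis,
      subepidermis = derive_subepidermis(epidermis, dermis, distance_um),
      membrane = membrane,
      distance_um = distance_um
    ),
    class = "roi_set"
  )
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf(
    "<roi_set> epidermis %.4g um^2, subepidermis (%g um) %.4g um^2, membrane %.4f mm\n",
    mask_area(x$epidermis), x$distance_um, mask_area(x$subepidermis),
    x$membrane$length_mm
  ))
  invisible(x)
}
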
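#' Nerve fiber proximity region
#'
#' The area within `radius_um` (default 5 um) of the nerve fiber mask,
#' including the fibers themselves. Blood vessels intersecting this region
#' are considered in close spatial proximity to nerve fibers.
#'
#' @param nerve [raster_mask] of nerve fibers.
#' @param radius_um Positive proximity radius in micrometers (default 5).
#' @return A [raster_mask]; see [expand_mask] for the distance convention.
#' @export
nerve_proximity_region <- function(nerve, radius_um = 5) {
  if (!is_scalar_number(radius_um) || radius_um <= 0) {
    stop("`radius_um` must be a single positive number", call. = FALSE)
  }
  expand_mask(nerve, radius_um)
}

#' Dermal vessel area and vessel-nerve interaction area
#'
#' Quantifies dermal blood vessels and their spatial interaction with nerve
#' fibers: the vessel area restricted to the dermis, and the part of that
#' area lying inside the nerve proximity region (the "broadened" fibers).
#' Vessel pixels outside the dermis (segmentation spillover into the
#' epidermis) are excluded from both quantities.
#'
#' @param vessels [raster_mask] of blood vessels.
#' @param nerve [raster_mask] of nerve fibers.
#' @param dermis Non-empty [raster_mask] of the dermis.
#' @param radius_um Proximity radius in micrometers (default 5).
#' @return An object of class `vessel_metrics`: `vessel_area_um2`,
#'   `interaction_area_um2`, `proximity_radius_um`. Always
#'   `0 <= interaction_area_um2 <= vessel_area_um2`.
#' @export
interaction_area <- function(vessels, nerve, dermis, radius_um = 5) {
  check_compatible(vessels, nerve, "vessel and nerve masks")
  check_compatible(vessels, dermis, "vessel and dermis masks")
  if (!any(dermis$grid)) {
    stop("dermis mask is empty", call. = FALSE)
  }
  dermal_vessels <- raster_mask(vessels$grid & dermis$grid, vessels$pixel_size_um)
  prox <- nerve_proximity_region(nerve, radius_um)
  structure(
    list(
      vessel_area_um2 = mask_area(dermal_vessels),
      interaction_area_um2 = mask_area(dermal_vessels, prox),
      proximity_radius_um = radius_um
    ),
    class = "vessel_metrics"
  )
}

#' @export
print.vessel_metrics <- function(x, ...) {
  cat(sprintf(
    "<vessel_metrics> dermal vessel area %.4g um^2, interaction area %.4g um^2 (radius %g um)\n",
    x$vessel_area_um2, x$interaction_area_um2, x$proximity_radius_um
  ))
  invisible(x)
}
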
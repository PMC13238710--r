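#' Default per-channel intensity model for synthetic sections
#'
#' Fiber pixels receive `fiber_mean` plus zero-mean Gaussian noise
#' (`noise_sd`), background pixels `background_mean` plus noise, both
#' truncated at zero and quantized to the 16-bit range. DAPI is modelled as
#' an elevated epidermal background (nuclear staining) with no fiber signal.
#'
#' @return Named list of channel parameter lists for DAPI, PGP9.5, CGRP,
#'   TrkA and GAP43.
#' @export
default_channel_spec <- function() {
  list(
    "DAPI" = list(background_mean = 250, background_sd = 60,
                  epidermis_mean = 1100, epidermis_sd = 200),
    "PGP9.5" = list(fiber_mean = 2000, background_mean = 200, noise_sd = 50),
    "CGRP" = list(fiber_mean = 1800, background_mean = 150, noise_sd = 50,
                  subset = "cgrp"),
    "TrkA" = list(fiber_mean = 400, background_mean = 120, noise_sd = 50),
    "GAP43" = list(fiber_mean = 800, background_mean = 150, noise_sd = 50,
                   subset = "gap43")
  )
}

#' Specification of one synthetic skin section
#'
#' Describes a synthetic 2D section: an undulating epidermal band over
#' dermis, curvilinear nerve fibers crossing the basement membrane at a
#' programmable rate (plus dermal-only fibers), elliptical dermal vessels
#' planted at programmable distances from the fibers, and per-channel
#' fluorescence intensities. The seed fixes the whole section
#' deterministically.
#'
#' @param width_px,height_px Image size in pixels.
#' @param pixel_size_um Micrometers per pixel (default 0.61).
#' @param epi_top_um Depth of the free epidermal surface below the image top.
#' @param epi_depth_um Mean epidermal thickness.
#' @param undulation_amp_um,undulation_wavelength_um Amplitude and wavelength
#'   of the sinusoidal basement-membrane undulation (amplitude 0 gives a
#'   straight interface with analytically known length).
#' @param n_crossing_fibers Number of nerve fibers crossing the basement
#'   membrane (each is guaranteed a single interface contact).
#' @param n_dermal_fibers Number of fibers confined to the dermis.
#' @param fiber_width_px Rasterized fiber width (odd integer).
#' @param min_crossing_spacing_px Minimum horizontal spacing between planted
#'   crossing sites; an infeasible request (fibers denser than the interface
#'   permits) is an error.
#' @param vessels Data.frame with columns `radius_um` and `target_dist_um`
#'   (planted center-to-nearest-fiber distance), one row per vessel.
#' @param channels Channel model, see [default_channel_spec].
#' @param cgrp_fraction,gap43_fraction Per-fiber probability of belonging to
#'   the CGRP+ (peptidergic) / GAP43+ subset.
#' @param seed Integer seed.
#' @return An object of class `section_spec`.
#' @export
section_spec <- function(width_px = 1024, height_px = 1024, pixel_size_um = 0.61,
                         epi_top_um = 15, epi_depth_um = 50,
                         undulation_amp_um = 12, undulation_wavelength_um = 180,
                         n_crossing_fibers = 8, n_dermal_fibers = 4,
                         fiber_width_px = 3, min_crossing_spacing_px = 6,
                         vessels = data.frame(
                           radius_um = c(3, 3, 4),
                           target_dist_um = c(4, 12, 25)
                         ),
                         channels = default_channel_spec(),
                         cgrp_fraction = 0.35, gap43_fraction = 0.5,
                         seed = 1L) {
  spec <- list(
    width_px = as.integer(width_px), height_px = as.integer(height_px),
    pixel_size_um = pixel_size_um,
    epi_top_um = epi_top_um, epi_depth_um = epi_depth_um,
    undulation_amp_um = undulation_amp_um,
    undulation_wavelength_um = undulation_wavelength_um,
    n_crossing_fibers = as.integer(n_crossing_fibers),
    n_dermal_fibers = as.integer(n_dermal_fibers),
    fiber_width_px = as.integer(fiber_width_px),
    min_crossing_spacing_px = as.integer(min_crossing_spacing_px),
    vessels = vessels,
    channels = channels,
    cgrp_fraction = cgrp_fraction, gap43_fraction = gap43_fraction,
    seed = as.integer(seed)
  )
  if (spec$width_px < 32L || spec$height_px < 32L) {
    stop("section must be at least 32x32 px", call. = FALSE)
  }
  if (spec$pixel_size_um <= 0) stop("pixel_size_um must be > 0", call. = FALSE)
  if (spec$n_crossing_fibers < 0L || spec$n_dermal_fibers < 0L) {
    stop("fiber counts must be >= 0", call. = FALSE)
  }
  if (spec$fiber_width_px < 1L || spec$fiber_width_px %% 2L == 0L) {
    stop("fiber_width_px must be a positive odd integer", call. = FALSE)
  }
  if (!is.null(spec$vessels) && nrow(spec$vessels) &&
      !all(c("radius_um", "target_dist_um") %in% names(spec$vessels))) {
    stop("vessels needs columns radius_um and target_dist_um", call. = FALSE)
  }
  class(spec) <- "section_spec"
  spec
}

# number of 8-connected components among a sparse pixel coordinate set
count_components_sparse <- function(coords) {
  if (is.null(coords) || nrow(coords) == 0L) return(0L)
  r0 <- min(coords[, 1L]); c0 <- min(coords[, 2L])
  g <- matrix(FALSE, max(coords[, 1L]) - r0 + 1L, max(coords[, 2L]) - c0 + 1L)
  g[cbind(coords[, 1L] - r0 + 1L, coords[, 2L] - c0 + 1L)] <- TRUE
  length(label_components8(g))
}

# rasterize a pixel path with a square brush of the given odd width,
# clipping to the image; returns linear indices
rasterize_path <- function(rows, cols, width_px, H, W) {
  hw <- (width_px - 1L) %/% 2L
  off <- expand.grid(dr = -hw:hw, dc = -hw:hw)
  r <- rep(rows, each = nrow(off)) + off$dr
  c <- rep(cols, each = nrow(off)) + off$dc
  ok <- r >= 1L & r <= H & c >= 1L & c <= W
  unique((c[ok] - 1L) * H + r[ok])
}

#' Generate a synthetic annotated skin section
#'
#' Emits multi-channel images, structure masks (epidermis, dermis, nerve,
#' CGRP+/GAP43+ fiber subsets, vessels) and the planted ground truth for one
#' section. Exactly `n_crossing_fibers` nerve components intersect the
#' basement membrane (each planted fiber is re-drawn until it has a single
#' interface contact, separated from its neighbours); planted vessels
#' respect their center-to-fiber distance targets within one pixel.
#'
#' @param spec A [section_spec].
#' @return An object of class `annotated_section`: `channels` (named list of
#'   [channel_image]), `masks` (named list of [raster_mask]:
#'   `epidermis`, `dermis`, `nerve`, `nerve_cgrp`, `nerve_gap43`, `vessels`),
#'   `pixel_size_um`, and `truth` with fields `crossing_count`,
#'   `membrane_length_mm` (analytic arc length of the generating boundary
#'   curve), `fiber_mean` (per channel), `vessel_area_um2`,
#'   `interaction_area_um2` (at 5 um, by brute-force pixel distances),
#'   `vessel_target_dist_um`, `vessel_actual_dist_um`.
#' @export
generate_section <- function(spec) {
  stopifnot(inherits(spec, "section_spec"))
  with_seed(spec$seed, generate_section_impl(spec))
}

generate_section_impl <- function(spec) {
  H <- spec$height_px; W <- spec$width_px; px <- spec$pixel_size_um

  epi_top <- max(2L, round(spec$epi_top_um / px))
  depth_px <- spec$epi_depth_um / px
  amp_px <- spec$undulation_amp_um / px
  wl_px <- max(4, spec$undulation_wavelength_um / px)
  dermis_min_px <- 30L

  if (epi_top + depth_px + amp_px + dermis_min_px >= H) {
    stop("infeasible section: epidermis plus undulation leaves no dermis", call. = FALSE)
  }
  if (depth_px - amp_px < 3) {
    stop("infeasible section: undulation amplitude exceeds epidermal depth", call. = FALSE)
  }

  phase <- stats::runif(1, 0, 2 * pi)
  cols <- seq_len(W)
  b <- epi_top + depth_px + amp_px * sin(2 * pi * cols / wl_px + phase)
  bfloor <- as.integer(pmax(epi_top + 2, pmin(H - dermis_min_px, floor(b))))

  R <- matrix(seq_len(H), H, W)
  BF <- matrix(rep(bfloor, each = H), H, W)
  epi_g <- R >= epi_top & R <= BF
  derm_g <- R > BF
  band_g <- epi_g & dilate8(derm_g)

  # analytic arc length of the generating boundary curve
  tt <- seq(0, W, length.out = 8L * W + 1L)
  fprime <- amp_px * (2 * pi / wl_px) * cos(2 * pi * tt / wl_px + phase)
  integrand <- sqrt(1 + fprime^2)
  L_px <- sum((integrand[-1] + integrand[-length(integrand)]) / 2) * (W / (length(tt) - 1L))
  membrane_length_mm <- L_px * px / 1000

  # ---- crossing fibers ----------------------------------------------------
  n_cross <- spec$n_crossing_fibers
  s <- spec$min_crossing_spacing_px
  margin_c <- spec$fiber_width_px + 4L
  lo <- margin_c; hi <- W - margin_c
  fiber_idx <- list()
  contact_coords <- NULL

  if (n_cross > 0L) {
    if (hi - lo < (n_cross - 1L) * s) {
      stop("infeasible section: interface too short for requested crossing fibers at minimum spacing",
           call. = FALSE)
    }
    base_pos <- if (n_cross == 1L) {
      round((lo + hi) / 2)
    } else {
      round(seq(lo, hi, length.out = n_cross))
    }
    gap <- if (n_cross > 1L) min(diff(base_pos)) else hi - lo
    jit <- max(0, floor((gap - s) / 2))
    positions <- as.integer(pmax(lo, pmin(hi, base_pos +
      round(stats::runif(n_cross, -jit, jit)))))

    dev <- max(1L, min(4L, floor((s - 1L) / 2)))
    band_idx <- which(band_g)

    for (k in seq_len(n_cross)) {
      x0 <- positions[k]
      placed <- FALSE
      for (try in 1:30) {
        rb <- bfloor[x0]
        up_max <- max(2L, min(14L, rb - epi_top - 1L))
        up <- sample(seq(2L, up_max), 1L)
        down <- sample(22:38, 1L)
        r1 <- min(H - 2L, rb + down)
        r0 <- max(epi_top + 1L, rb - up)
        rows_path <- seq(r1, r0, by = -1L)
        n_steps <- length(rows_path)
        cc <- integer(n_steps)
        cc[1L] <- x0
        for (i in 2:n_steps) {
          near_boundary <- abs(rows_path[i] - rb) <= 3L
          step <- if (near_boundary) 0L else sample(c(-1L, 0L, 0L, 1L), 1L)
          cc[i] <- min(max(cc[i - 1L] + step, x0 - dev), x0 + dev)
        }
        idx <- rasterize_path(rows_path, cc, spec$fiber_width_px, H, W)
        f_band <- intersect(idx, band_idx)
        if (!length(f_band)) next
        fc <- cbind((f_band - 1L) %% H + 1L, (f_band - 1L) %/% H + 1L)
        if (count_components_sparse(fc) != 1L) next
        if (!is.null(contact_coords)) {
          cheb <- outer(fc[, 2L], contact_coords[, 2L],
                        function(a, b) abs(a - b))
          cheb_r <- outer(fc[, 1L], contact_coords[, 1L],
                          function(a, b) abs(a - b))
          if (min(pmax(cheb, cheb_r)) < 2L) next
        }
        fiber_idx[[length(fiber_idx) + 1L]] <- idx
        contact_coords <- rbind(contact_coords, fc)
        placed <- TRUE
        break
      }
      if (!placed) {
        stop("could not place a crossing fiber with a single interface contact; spec too dense",
             call. = FALSE)
      }
    }
  }
  n_cross_fibers <- length(fiber_idx)

  # ---- dermal-only fibers -------------------------------------------------
  max_bf <- max(bfloor)
  band_idx_all <- which(band_g)
  if (spec$n_dermal_fibers > 0L && H - max_bf > 20L) {
    for (k in seq_len(spec$n_dermal_fibers)) {
      for (try in 1:20) {
        len <- sample(30:70, 1L)
        c0 <- sample(seq(margin_c, max(margin_c + 1L, W - margin_c - len)), 1L)
        r0 <- sample(seq(max_bf + 8L, H - 6L), 1L)
        cols_path <- c0 + seq_len(len) - 1L
        rows_path <- integer(len)
        rows_path[1L] <- r0
        for (i in 2:len) {
          rows_path[i] <- rows_path[i - 1L] + sample(c(-1L, 0L, 1L), 1L)
        }
        cols_path <- pmin(pmax(cols_path, 1L), W)
        rows_path <- pmin(pmax(rows_path, bfloor[cols_path] + 5L), H - 1L)
        idx <- rasterize_path(rows_path, cols_path, spec$fiber_width_px, H, W)
        if (length(intersect(idx, band_idx_all))) next
        fiber_idx[[length(fiber_idx) + 1L]] <- idx
        break
      }
    }
  }

  nerve_g <- matrix(FALSE, H, W)
  for (idx in fiber_idx) nerve_g[idx] <- TRUE

  # ---- marker-positive fiber subsets -------------------------------------
  n_fibers <- length(fiber_idx)
  is_cgrp <- if (n_fibers) stats::runif(n_fibers) < spec$cgrp_fraction else logical(0)
  is_gap43 <- if (n_fibers) stats::runif(n_fibers) < spec$gap43_fraction else logical(0)
  cgrp_g <- matrix(FALSE, H, W)
  for (i in which(is_cgrp)) cgrp_g[fiber_idx[[i]]] <- TRUE
  gap43_g <- matrix(FALSE, H, W)
  for (i in which(is_gap43)) gap43_g[fiber_idx[[i]]] <- TRUE

  # ---- vessels ------------------------------------------------------------
  vessel_g <- matrix(FALSE, H, W)
  vspec <- spec$vessels
  target_d <- numeric(0)
  actual_d <- numeric(0)
  nerve_idx <- which(nerve_g)
  Fr <- (nerve_idx - 1L) %% H + 1L
  Fc <- (nerve_idx - 1L) %/% H + 1L
  dermal_fiber <- which(Fr > bfloor[Fc] + 2L)

  if (!is.null(vspec) && nrow(vspec)) {
    if (!length(dermal_fiber)) {
      stop("cannot place vessels: no dermal nerve fiber pixels", call. = FALSE)
    }
    for (vi in seq_len(nrow(vspec))) {
      d_px <- vspec$target_dist_um[vi] / px
      r1_px <- vspec$radius_um[vi] / px
      r2_px <- r1_px * stats::runif(1, 0.65, 1)
      theta <- stats::runif(1, 0, pi)
      placed <- FALSE
      for (try in 1:80) {
        p <- sample(dermal_fiber, 1L)
        pr <- Fr[p]; pc <- Fc[p]
        phi <- stats::runif(1, 0, 2 * pi)
        u <- c(cos(phi), sin(phi))
        ctr <- c(pr, pc) + d_px * u
        for (it in 1:5) {
          dmin <- sqrt(min((Fr - ctr[1L])^2 + (Fc - ctr[2L])^2))
          if (abs(dmin - d_px) <= 0.5) break
          ctr <- ctr + (d_px - dmin) * u
        }
        dmin <- sqrt(min((Fr - ctr[1L])^2 + (Fc - ctr[2L])^2))
        if (abs(dmin - d_px) > 1) next
        ext <- ceiling(max(r1_px, r2_px)) + 1L
        rr <- max(1L, floor(ctr[1L] - ext)):min(H, ceiling(ctr[1L] + ext))
        cb <- max(1L, floor(ctr[2L] - ext)):min(W, ceiling(ctr[2L] + ext))
        gr <- expand.grid(r = rr, c = cb)
        xr <- (gr$r - ctr[1L]) * cos(theta) + (gr$c - ctr[2L]) * sin(theta)
        yr <- -(gr$r - ctr[1L]) * sin(theta) + (gr$c - ctr[2L]) * cos(theta)
        inside <- (xr / r1_px)^2 + (yr / r2_px)^2 <= 1
        if (!any(inside)) next
        vr <- gr$r[inside]; vc <- gr$c[inside]
        if (min(vr) < 1L || max(vr) > H || min(vc) < 1L || max(vc) > W) next
        if (!all(derm_g[cbind(vr, vc)])) next
        vidx <- (vc - 1L) * H + vr
        if (d_px > r1_px && any(nerve_g[vidx])) next
        if (any(vessel_g[vidx])) next
        vessel_g[vidx] <- TRUE
        target_d <- c(target_d, vspec$target_dist_um[vi])
        actual_d <- c(actual_d, dmin * px)
        placed <- TRUE
        break
      }
      if (!placed) {
        stop(sprintf("could not place vessel %d (radius %g um at %g um from fibers)",
                     vi, vspec$radius_um[vi], vspec$target_dist_um[vi]), call. = FALSE)
      }
    }
  }

  # ---- true interaction area at 5 um by brute-force pixel distances -------
  interaction_px <- 0L
  vessel_idx <- which(vessel_g)
  if (length(vessel_idx) && length(nerve_idx)) {
    Vr <- (vessel_idx - 1L) %% H + 1L
    Vc <- (vessel_idx - 1L) %/% H + 1L
    r5 <- 5 / px + 1e-9
    step <- 2000L
    for (start in seq(1L, length(vessel_idx), by = step)) {
      ii <- start:min(start + step - 1L, length(vessel_idx))
      dd <- outer(Vr[ii], Fr, `-`)^2 + outer(Vc[ii], Fc, `-`)^2
      interaction_px <- interaction_px + sum(sqrt(.rowMins(dd)) <= r5)
    }
  }

  # ---- channels -----------------------------------------------------------
  channels <- list()
  fiber_mean <- numeric(0)
  for (marker in names(spec$channels)) {
    ch <- spec$channels[[marker]]
    bg_sd <- ch$background_sd %||% ch$noise_sd %||% 50
    img <- matrix(stats::rnorm(H * W, ch$background_mean %||% 200, bg_sd), H, W)
    if (!is.null(ch$epidermis_mean)) {
      n_epi <- sum(epi_g)
      img[epi_g] <- stats::rnorm(n_epi, ch$epidermis_mean, ch$epidermis_sd %||% bg_sd)
    }
    if (!is.null(ch$fiber_mean)) {
      subset <- ch$subset %||% "all"
      tgt <- switch(subset, cgrp = cgrp_g, gap43 = gap43_g, nerve_g)
      idx <- which(tgt)
      if (length(idx)) {
        img[idx] <- stats::rnorm(length(idx), ch$fiber_mean, ch$noise_sd %||% 50)
      }
      fiber_mean[marker] <- ch$fiber_mean
    }
    img <- round(pmin(pmax(img, 0), 65535))
    channels[[marker]] <- channel_image(img, marker, px, bit_depth = 16)
  }

  structure(list(
    channels = channels,
    masks = list(
      epidermis = raster_mask(epi_g, px),
      dermis = raster_mask(derm_g, px),
      nerve = raster_mask(nerve_g, px),
      nerve_cgrp = raster_mask(cgrp_g, px),
      nerve_gap43 = raster_mask(gap43_g, px),
      vessels = raster_mask(vessel_g, px)
    ),
    pixel_size_um = px,
    spec = spec,
    truth = list(
      crossing_count = n_cross_fibers,
      membrane_length_mm = membrane_length_mm,
      fiber_mean = fiber_mean,
      vessel_area_um2 = sum(vessel_g) * px^2,
      interaction_area_um2 = interaction_px * px^2,
      interaction_radius_um = 5,
      vessel_target_dist_um = target_d,
      vessel_actual_dist_um = actual_d
    )
  ), class = "annotated_section")
}

.rowMins <- function(m) {
  do.call(pmin, as.data.frame(m))
}

#' @export
print.annotated_section <- function(x, ...) {
  cat(sprintf(
    "<annotated_section> %d x %d px @ %.3g um/px; %d planted crossing(s); channels: %s\n",
    nrow(x$masks$epidermis$grid), ncol(x$masks$epidermis$grid), x$pixel_size_um,
    x$truth$crossing_count, paste(names(x$channels), collapse = ", ")
  ))
  invisible(x)
}

#' Threshold a channel image into a mask
#'
#' Simple intensity-threshold segmentation (pixels `>= threshold`), an
#' end-to-end demonstration stand-in for an external segmentation step on
#' high-contrast synthetic data.
#'
#' @param channel A [channel_image].
#' @param threshold Intensity threshold within the channel's bit-depth range.
#' @return A [raster_mask].
#' @export
threshold_segment <- function(channel, threshold) {
  stopifnot(inherits(channel, "channel_image"))
  if (!is_scalar_number(threshold) || threshold < 0 || threshold > 2^channel$bit_depth - 1) {
    stop("threshold must lie within the bit-depth range", call. = FALSE)
  }
  raster_mask(channel$grid >= threshold, channel$pixel_size_um)
}
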
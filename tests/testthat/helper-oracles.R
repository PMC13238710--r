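# Independent oracles and fixture builders used across tests.

# Brute-force all-pairs Euclidean expansion oracle: a pixel is in the result
# iff its center lies within r_px of some foreground pixel center.
oracle_expand <- function(grid, r_px) {
  fg <- which(grid, arr.ind = TRUE)
  out <- matrix(FALSE, nrow(grid), ncol(grid))
  if (nrow(fg) == 0L) return(out)
  all_r <- as.vector(row(grid))
  all_c <- as.vector(col(grid))
  # all-pairs squared distances between every pixel and every foreground pixel
  d2 <- outer(all_r, fg[, 1L], `-`)^2 + outer(all_c, fg[, 2L], `-`)^2
  dmin <- sqrt(do.call(pmin, as.data.frame(d2)))
  matrix(dmin <= r_px + 1e-9, nrow(grid), ncol(grid))
}

# Horizontal epidermis band over dermis, both full width.
band_masks <- function(epi_rows = 10L, total_rows = 100L, width = 100L,
                       px = 1) {
  epi <- matrix(FALSE, total_rows, width)
  epi[seq_len(epi_rows), ] <- TRUE
  derm <- matrix(FALSE, total_rows, width)
  derm[(epi_rows + 1L):total_rows, ] <- TRUE
  list(
    epidermis = raster_mask(epi, px),
    dermis = raster_mask(derm, px)
  )
}

# Vertical 1-px fibers spanning the given rows at the given columns.
vertical_fibers <- function(cols, rows, total_rows, width, px = 1) {
  g <- matrix(FALSE, total_rows, width)
  for (cc in cols) g[rows, cc] <- TRUE
  raster_mask(g, px)
}

# Exact two-tailed Mann-Whitney p by full enumeration of rank assignments
# (no ties): fraction of group assignments with |U - n1 n2 / 2| at least as
# extreme as observed.
mw_exact_enum <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  pooled <- c(x, y)
  rk <- rank(pooled)
  u_of <- function(sel) {
    sum(rk[sel]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_of(seq_len(n1))
  center <- n1 * n2 / 2
  combs <- utils::combn(n1 + n2, n1)
  us <- apply(combs, 2L, u_of)
  mean(abs(us - center) >= abs(u_obs - center) - 1e-12)
}

small_section_spec <- function(seed, ...) {
  section_spec(width_px = 320, height_px = 256, seed = seed, ...)
}
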
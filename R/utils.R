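# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Deterministic sub-seed derivation; stays within 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + as.double(k) * 16807) %% 2147483629) + 1L
}

`%||%` <- function(x, y) if (is.null(x)) y else x

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# Shift a logical matrix by (dr, dc), padding with FALSE.
shift_mask <- function(g, dr, dc) {
  nr <- nrow(g)
  nc <- ncol(g)
  out <- matrix(FALSE, nr, nc)
  r_dst <- seq_len(nr)
  c_dst <- seq_len(nc)
  r_src <- r_dst - dr
  c_src <- c_dst - dc
  ok_r <- r_src >= 1L & r_src <= nr
  ok_c <- c_src >= 1L & c_src <= nc
  if (any(ok_r) && any(ok_c)) {
    out[r_dst[ok_r], c_dst[ok_c]] <- g[r_src[ok_r], c_src[ok_c]]
  }
  out
}

# One-pixel 8-neighbourhood dilation (Chebyshev ball of radius 1).
dilate8 <- function(g) {
  out <- g
  for (dr in -1:1) {
    for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      out <- out | shift_mask(g, dr, dc)
    }
  }
  out
}

# 8-connected components of the TRUE pixels of a logical matrix.
# Returns a list of coordinate matrices (columns row, col; 1-based).
# Union-find on the sparse pixel set: intersections fed to this are small
# (nerve-mask / membrane-band overlaps), so O(n log n) lookups suffice.
label_components8 <- function(g) {
  idx <- which(g)
  n <- length(idx)
  if (n == 0L) return(list())
  nr <- nrow(g)
  nc <- ncol(g)
  r <- (idx - 1L) %% nr + 1L
  c <- (idx - 1L) %/% nr + 1L

  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }

  # forward half of the 8-neighbourhood is enough for union-find
  offsets <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))
  for (off in offsets) {
    nbr_key <- idx + off[1L] + off[2L] * nr
    valid <- r + off[1L] >= 1L & r + off[1L] <= nr & c + off[2L] <= nc
    j <- match(nbr_key, idx)
    hit <- which(valid & !is.na(j))
    for (i in hit) {
      ri <- find(i)
      rj <- find(j[i])
      if (ri != rj) parent[ri] <- rj
    }
  }

  root <- vapply(seq_len(n), find, integer(1))
  split_idx <- split(seq_len(n), root)
  lapply(unname(split_idx), function(is) {
    cbind(row = r[is], col = c[is])
  })
}
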
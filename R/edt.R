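#' Exact Euclidean distance transform of a binary mask
#'
#' Computes, for every voxel, the exact Euclidean distance (mm) to the
#' nearest voxel centre belonging to `mask`, honouring anisotropic voxel
#' spacing. Uses the separable lower-envelope (parabola) algorithm applied
#' along each axis in turn, which is exact for the squared distance.
#'
#' Voxels inside the mask have distance 0. Used for dose fall-off shells
#' (e.g. the 20 mm ring behind D2cm) and spatial importance weighting.
#'
#' @param mask a binary `voxel_grid` (or 3D array, with `spacing` given).
#' @param spacing voxel pitch in mm when `mask` is a bare array.
#' @return A 3D array of distances in mm.
#' @export
distance_transform <- function(mask, spacing = NULL) {
  if (is_voxel_grid(mask)) {
    spacing <- mask$spacing
    m <- mask$data != 0
  } else {
    if (is.null(spacing)) stop("`spacing` required for bare arrays")
    m <- mask != 0
  }
  d <- dim(m)
  INF <- 1e20
  f <- array(ifelse(m, 0, INF), d)
  for (ax in 1:3) {
    f <- edt_pass(f, ax, spacing[ax])
  }
  sqrt(f)
}

# One separable pass: replace f by the 1D squared-distance transform along
# axis `ax` with sample pitch `h`. Vectorised over all lines at once:
# permute the axis to the front, run the envelope scan over rows.
edt_pass <- function(f, ax, h) {
  d <- dim(f)
  perm <- switch(ax, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  g <- aperm(f, perm)
  pd <- dim(g)
  n <- pd[1]
  m <- prod(pd[2:3])
  dim(g) <- c(n, m)
  out <- matrix(0, n, m)
  for (col in seq_len(m)) {
    out[, col] <- edt_1d(g[, col], h)
  }
  dim(out) <- pd
  aperm(out, order(perm))
}

# Felzenszwalb & Huttenlocher 1D squared-distance transform under a
# lower envelope of parabolas; positions are i*h for grid pitch h.
edt_1d <- function(f, h) {
  n <- length(f)
  if (n == 1L || all(f == 0)) return(f)
  v <- integer(n)      # parabola apex indices
  z <- numeric(n + 1)  # envelope breakpoints
  k <- 1L
  v[1] <- 1L
  z[1] <- -Inf
  z[2] <- Inf
  x <- (seq_len(n) - 1) * h
  for (q in 2:n) {
    p <- v[k]
    s <- ((f[q] + x[q]^2) - (f[p] + x[p]^2)) / (2 * (x[q] - x[p]))
    while (s <= z[k]) {  # cannot underflow: z[1] = -Inf and s is finite-ish
      k <- k - 1L
      p <- v[k]
      s <- ((f[q] + x[q]^2) - (f[p] + x[p]^2)) / (2 * (x[q] - x[p]))
    }
    k <- k + 1L
    v[k] <- q
    z[k] <- s
    z[k + 1] <- Inf
  }
  out <- numeric(n)
  k <- 1L
  for (q in seq_len(n)) {
    while (z[k + 1] < x[q]) k <- k + 1L
    p <- v[k]
    out[q] <- (x[q] - x[p])^2 + f[p]
  }
  out
}
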
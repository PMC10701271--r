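#' Dose-kernel parameters
#'
#' Parameters of the simplified analytic per-beamlet dose kernel used to
#' build deposition matrices. The kernel models primary attenuation with an
#' effective linear coefficient, a Gaussian lateral penumbra, and
#' inverse-square fall-off; the medium is treated as homogeneous
#' water-equivalent inside the external (head) contour.
#'
#' @param mu_eff effective linear attenuation coefficient (1/mm).
#' @param penumbra_sigma lateral Gaussian penumbra sigma (mm).
#' @param inverse_square apply inverse-square fall-off with depth.
#' @param sparsity_floor drop matrix entries below this fraction of their
#'   column maximum.
#' @param step ray-marching step (mm) for water-equivalent depth; defaults
#'   to the smallest voxel pitch.
#' @return A `kernel_params` list.
#' @export
kernel_params <- function(mu_eff = 0.004, penumbra_sigma = 3.0,
                          inverse_square = TRUE, sparsity_floor = 1e-4,
                          step = NULL) {
  stopifnot(mu_eff > 0, penumbra_sigma > 0, sparsity_floor >= 0)
  structure(list(mu_eff = mu_eff, penumbra_sigma = penumbra_sigma,
                 inverse_square = inverse_square,
                 sparsity_floor = sparsity_floor, step = step),
            class = "kernel_params")
}

# Unit vectors of a coplanar beam at gantry angle g (degrees), IEC 61217
# with LPS world axes: gantry 0 has the source anterior (-y), rotation is
# clockwise viewed from the patient's feet.
#   u: isocentre -> source;  d: beam travel direction (= -u)
#   e1: lateral beam's-eye-view axis in the axial plane;  e2: +z
gantry_vectors <- function(gantry_deg) {
  g <- gantry_deg * pi / 180
  u <- c(sin(g), -cos(g), 0)
  list(u = u, d = -u, e1 = c(cos(g), sin(g), 0), e2 = c(0, 0, 1))
}

#' Automatic coplanar beam configuration
#'
#' Places the primary beam along the direction linking the brain (head
#' contour) centre to the target centre, projected to the axial plane, then
#' adds beams clockwise and counter-clockwise at fixed gantry increments,
#' giving `n_beams` uniformly spaced coplanar beams with the isocentre at
#' the target centroid.
#'
#' @param case a `plan_case`.
#' @param n_beams number of beams (odd; default 9).
#' @param spacing_deg gantry increment between adjacent beams (degrees).
#' @param beamlet_size beamlet pitch of the fluence lattice (mm).
#' @param margin_mm lattice margin beyond the target projection (mm).
#' @param sad source-axis distance (mm).
#' @return A list of `beam_geometry` objects (fields: `gantry_deg`,
#'   `isocenter`, `sad`, `beamlet_size`, `p_centers`, `q_centers`).
#' @export
auto_configure_beams <- function(case, n_beams = 9, spacing_deg = 20,
                                 beamlet_size = 5, margin_mm = 10,
                                 sad = 1000) {
  stopifnot(n_beams >= 1)
  pgtv <- case$structures[["PGTV"]]
  head <- case$structures[["Head"]]
  if (is.null(pgtv) || sum(pgtv$data) == 0) stop("PGTV mask is empty")
  if (is.null(head) || sum(head$data) == 0) stop("Head mask is empty")
  iso <- mask_centroid(pgtv)
  brain_c <- mask_centroid(head)
  v <- (iso - brain_c)[1:2]
  if (sqrt(sum(v^2)) < 1e-6) {
    dl_log("target centroid coincides with brain centre; primary gantry 0")
    g0 <- 0
  } else {
    d_xy <- v / sqrt(sum(v^2))        # beam travel direction, axial plane
    u <- -d_xy                        # isocentre -> source
    g0 <- atan2(u[1], -u[2]) * 180 / pi
  }
  half <- (n_beams - 1) / 2
  angles <- (g0 + spacing_deg * seq(-half, half)) %% 360
  # lattice extent from the PGTV projection (shared by all beams: the
  # in-plane half-extent is rotation-dependent, so take the worst case --
  # the maximal radial extent -- giving one lattice size for all beams)
  idx <- which(pgtv$data != 0, arr.ind = TRUE)
  w <- sweep(sweep(idx - 1, 2, pgtv$spacing, "*"), 2, pgtv$origin, "+")
  rel <- sweep(w, 2, iso, "-")
  r_xy <- max(sqrt(rel[, 1]^2 + rel[, 2]^2))
  r_z <- max(abs(rel[, 3]))
  lat_centers <- function(half_extent) {
    n <- max(1L, ceiling(2 * half_extent / beamlet_size))
    (seq_len(n) - (n + 1) / 2) * beamlet_size
  }
  p_centers <- lat_centers(r_xy + margin_mm)
  q_centers <- lat_centers(r_z + margin_mm)
  lapply(angles, function(g) {
    structure(list(gantry_deg = g, isocenter = iso, sad = sad,
                   beamlet_size = beamlet_size,
                   p_centers = p_centers, q_centers = q_centers),
              class = "beam_geometry")
  })
}

# Water-equivalent depth of each listed point along -d (towards the source),
# by fixed-step ray marching through the head mask (nearest-neighbour
# lookup). Exact up to the step size for convex external contours.
ray_depths <- function(coords, d, head, step, max_len) {
  n <- nrow(coords)
  hd <- dim(head$data)
  depth <- numeric(n)
  n_steps <- ceiling(max_len / step)
  hx <- head$data != 0
  for (k in seq_len(n_steps)) {
    s <- (k - 0.5) * step
    sx <- coords[, 1] - s * d[1]
    sy <- coords[, 2] - s * d[2]
    sz <- coords[, 3] - s * d[3]
    ix <- round((sx - head$origin[1]) / head$spacing[1])
    iy <- round((sy - head$origin[2]) / head$spacing[2])
    iz <- round((sz - head$origin[3]) / head$spacing[3])
    ok <- ix >= 0 & ix < hd[1] & iy >= 0 & iy < hd[2] & iz >= 0 & iz < hd[3]
    if (!any(ok)) break
    lin <- 1 + ix[ok] + hd[1] * (iy[ok] + hd[2] * iz[ok])
    depth[ok] <- depth[ok] + step * hx[lin]
  }
  depth
}

#' Build the sparse deposition matrix
#'
#' Assembles the linear operator mapping per-beamlet fluence weights to
#' voxel dose. For voxel `v` and beamlet `b` the entry is
#' `exp(-mu_eff * depth(v)) * exp(-lat^2/(2 sigma^2)) * (SAD/(SAD+depth))^2`
#' where `depth` is the water-equivalent depth of `v` from the patient
#' surface along the beam and `lat` the lateral distance of `v` from the
#' beamlet ray. Dose is only deposited inside the head contour; entries
#' below `sparsity_floor` of their column maximum are dropped.
#'
#' @param case a `plan_case` (provides geometry and the Head mask).
#' @param beams beam list from [auto_configure_beams()].
#' @param kernel a [kernel_params()] object.
#' @return A `deposition_matrix`: list with sparse `M` (voxels x beamlets),
#'   `beams` (with per-beam column offsets), `kernel` and grid geometry.
#' @export
build_deposition_matrix <- function(case, beams, kernel = kernel_params()) {
  ct <- case$ct
  head <- case$structures[["Head"]]
  if (is.null(head)) stop("case has no Head mask")
  gd <- dim(ct$data)
  n_vox <- prod(gd)
  step <- kernel$step %||% min(ct$spacing)
  sigma <- kernel$penumbra_sigma
  trunc2 <- (3 * sigma)^2
  head_idx <- which(head$data != 0)
  coords <- voxel_coords(ct)[head_idx, , drop = FALSE]
  max_len <- sqrt(sum((gd * ct$spacing)^2))
  iso <- beams[[1]]$isocenter
  rel <- sweep(coords, 2, iso, "-")
  col_offset <- 0L
  trip_i <- list(); trip_j <- list(); trip_x <- list()
  for (bi in seq_along(beams)) {
    bm <- beams[[bi]]
    gv <- gantry_vectors(bm$gantry_deg)
    depth <- ray_depths(coords, gv$d, head, step, max_len)
    p <- rel %*% gv$e1
    q <- rel[, 3]
    amp <- exp(-kernel$mu_eff * depth)
    if (kernel$inverse_square)
      amp <- amp * (bm$sad / (bm$sad + depth))^2
    bs <- bm$beamlet_size
    np <- length(bm$p_centers); nq <- length(bm$q_centers)
    ip0 <- round((p - bm$p_centers[1]) / bs)       # 0-based nearest bin
    iq0 <- round((q - bm$q_centers[1]) / bs)
    rad <- ceiling(3 * sigma / bs)
    for (di in -rad:rad) {
      for (dj in -rad:rad) {
        ip <- ip0 + di; iq <- iq0 + dj
        ok <- ip >= 0 & ip < np & iq >= 0 & iq < nq
        if (!any(ok)) next
        lat2 <- (p[ok] - bm$p_centers[ip[ok] + 1])^2 +
          (q[ok] - bm$q_centers[iq[ok] + 1])^2
        keep <- lat2 <= trunc2
        if (!any(keep)) next
        okk <- which(ok)[keep]
        val <- amp[okk] * exp(-lat2[keep] / (2 * sigma^2))
        trip_i[[length(trip_i) + 1L]] <- head_idx[okk]
        trip_j[[length(trip_j) + 1L]] <-
          col_offset + ip[okk] + np * iq[okk] + 1L
        trip_x[[length(trip_x) + 1L]] <- val
      }
    }
    beams[[bi]]$col_offset <- col_offset
    beams[[bi]]$n_beamlets <- np * nq
    col_offset <- col_offset + np * nq
  }
  M <- Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
                            x = unlist(trip_x),
                            dims = c(n_vox, col_offset))
  if (kernel$sparsity_floor > 0) {
    cm <- colmax_dgc(M)
    nper <- diff(M@p)
    thr <- rep(cm * kernel$sparsity_floor, nper)
    keep <- M@x >= thr
    M@x[!keep] <- 0
    M <- Matrix::drop0(M)
  }
  empty <- which(diff(M@p) == 0L)
  if (length(empty) > 0)
    dl_log("%d beamlet(s) deposit no dose (miss the head)", length(empty))
  structure(list(M = M, beams = beams, kernel = kernel,
                 grid_dim = gd, spacing = ct$spacing, origin = ct$origin),
            class = "deposition_matrix")
}

colmax_dgc <- function(M) {
  p <- M@p
  n <- ncol(M)
  out <- numeric(n)
  nper <- diff(p)
  nz <- nper > 0
  if (any(nz)) {
    grp <- rep.int(seq_len(n)[nz], nper[nz])
    out[nz] <- vapply(split(M@x, grp), max, numeric(1))
  }
  out
}

#' @export
print.deposition_matrix <- function(x, ...) {
  cat(sprintf(
    "<deposition_matrix> %d voxels x %d beamlets (%d beams), %d nonzeros\n",
    nrow(x$M), ncol(x$M), length(x$beams), length(x$M@x)))
  invisible(x)
}

#' Per-beam fluence map container
#'
#' @param beams beam list (from a `deposition_matrix` or
#'   [auto_configure_beams()]).
#' @param maps list of matrices, one per beam, dim
#'   `(length(p_centers), length(q_centers))`; defaults to zeros.
#' @return A `fluence_map` object.
#' @export
fluence_map <- function(beams, maps = NULL) {
  if (is.null(maps))
    maps <- lapply(beams, function(b)
      matrix(0, length(b$p_centers), length(b$q_centers)))
  stopifnot(length(maps) == length(beams))
  for (i in seq_along(beams)) {
    stopifnot(identical(dim(maps[[i]]),
                        c(length(beams[[i]]$p_centers),
                          length(beams[[i]]$q_centers))))
    if (any(maps[[i]] < 0)) stop("fluence must be non-negative")
  }
  structure(list(beams = beams, maps = maps), class = "fluence_map")
}

# Flatten a fluence_map to the beamlet vector ordering of the matrix.
fluence_vector <- function(fl) {
  unlist(lapply(fl$maps, as.numeric), use.names = FALSE)
}

# Rebuild a fluence_map from a flat beamlet vector.
fluence_from_vector <- function(f, beams) {
  maps <- lapply(beams, function(b) {
    np <- length(b$p_centers); nq <- length(b$q_centers)
    matrix(f[b$col_offset + seq_len(np * nq)], np, nq)
  })
  fluence_map(beams, maps)
}

#' Compute dose from a deposition matrix and fluence
#'
#' `dose = D %*% f`, reshaped onto the voxel grid. Linear in the fluence.
#'
#' @param D a `deposition_matrix`.
#' @param fluence a `fluence_map` or flat non-negative beamlet vector.
#' @return A `voxel_grid` of dose (engine units; scale via fluence).
#' @export
compute_dose <- function(D, fluence) {
  f <- if (inherits(fluence, "fluence_map")) fluence_vector(fluence)
  else as.numeric(fluence)
  if (length(f) != ncol(D$M)) stop("fluence length does not match matrix")
  if (any(f < 0)) stop("fluence must be non-negative")
  dose <- as.numeric(D$M %*% f)
  voxel_grid(array(dose, D$grid_dim), D$spacing, D$origin)
}

#' Recompute all fields at gantry 0 onto a measurement plane
#'
#' Emulates array-based delivery verification: every field is delivered at
#' gantry 0 onto a detector plane at fixed water-equivalent depth, and the
#' per-field dose maps are composited by summation. The same analytic
#' kernel as the deposition matrix is used, so planned and delivered
#' fluence differ only through sequencing.
#'
#' @param fluence a `fluence_map`.
#' @param kernel a [kernel_params()] object.
#' @param depth_mm water-equivalent depth of the plane (mm).
#' @param pitch_mm detector pitch (mm).
#' @param sad source-axis distance (mm).
#' @return List with `dose` (matrix), `pitch_mm`, `u`, `v` (detector
#'   coordinates, mm).
#' @export
plane_dose <- function(fluence, kernel = kernel_params(), depth_mm = 50,
                       pitch_mm = 2.5, sad = 1000) {
  sigma <- kernel$penumbra_sigma
  pad <- 3 * sigma + 2 * pitch_mm
  pr <- range(unlist(lapply(fluence$beams, function(b) range(b$p_centers))))
  qr <- range(unlist(lapply(fluence$beams, function(b) range(b$q_centers))))
  u <- seq(pr[1] - pad, pr[2] + pad, by = pitch_mm)
  v <- seq(qr[1] - pad, qr[2] + pad, by = pitch_mm)
  amp <- exp(-kernel$mu_eff * depth_mm)
  if (kernel$inverse_square) amp <- amp * (sad / (sad + depth_mm))^2
  dose <- matrix(0, length(u), length(v))
  for (bi in seq_along(fluence$beams)) {
    b <- fluence$beams[[bi]]
    f <- fluence$maps[[bi]]
    nzb <- which(f != 0, arr.ind = TRUE)
    if (nrow(nzb) == 0) next
    for (r in seq_len(nrow(nzb))) {
      pb <- b$p_centers[nzb[r, 1]]
      qb <- b$q_centers[nzb[r, 2]]
      w <- f[nzb[r, 1], nzb[r, 2]]
      gu <- exp(-(u - pb)^2 / (2 * sigma^2))
      gv <- exp(-(v - qb)^2 / (2 * sigma^2))
      dose <- dose + (amp * w) * outer(gu, gv)
    }
  }
  list(dose = dose, pitch_mm = pitch_mm, u = u, v = v)
}
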
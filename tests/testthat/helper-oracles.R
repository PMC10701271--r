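# Brute-force reference implementations, kept deliberately naive and
# independent of the package's optimized code paths.

# exhaustive gamma: for every reference point search ALL evaluated points
gamma_brute <- function(ref_vals, ref_pts, ev_vals, ev_pts, dd, dta,
                        dnorm) {
  vapply(seq_along(ref_vals), function(i) {
    dr2 <- rowSums((ev_pts - matrix(ref_pts[i, ], nrow(ev_pts), 3,
                                    byrow = TRUE))^2)
    keep <- dr2 <= (3 * dta)^2
    if (!any(keep)) return(Inf)
    sqrt(min(dr2[keep] / dta^2 +
               ((ref_vals[i] - ev_vals[keep]) / (dd * dnorm))^2))
  }, numeric(1))
}

# all-pairs Euclidean distance to the nearest mask voxel centre
edt_brute <- function(mask, spacing) {
  idx <- which(mask != 0, arr.ind = TRUE)
  pts <- sweep(idx - 1, 2, spacing, "*")
  all_idx <- which(array(TRUE, dim(mask)), arr.ind = TRUE)
  all_pts <- sweep(all_idx - 1, 2, spacing, "*")
  out <- vapply(seq_len(nrow(all_pts)), function(i) {
    sqrt(min(rowSums((pts - matrix(all_pts[i, ], nrow(pts), 3,
                                   byrow = TRUE))^2)))
  }, numeric(1))
  array(out, dim(mask))
}

# dose-at-volume by explicit sort-and-interpolate over mask voxels
dose_at_volume_brute <- function(dose_vals, q) {
  v <- sort(dose_vals)
  n <- length(v)
  h <- (1 - q / 100) * (n - 1)
  lo <- floor(h)
  v[lo + 1] + (h - lo) * (v[min(lo + 2, n)] - v[lo + 1])
}

# naive per-voxel kernel evaluation for one beamlet (independent of the
# sparse assembly): fine ray marching for depth, explicit lateral distance
deposition_entry_brute <- function(coord, iso, gantry_deg, pb, qb, head,
                                   mu, sigma, sad, step = 0.25) {
  g <- gantry_deg * pi / 180
  d <- c(-sin(g), cos(g), 0)
  e1 <- c(cos(g), sin(g), 0)
  depth <- 0
  s <- step / 2
  repeat {
    p <- coord - s * d
    ijk <- round((p - head$origin) / head$spacing)
    if (any(ijk < 0) || any(ijk >= dim(head$data))) break
    if (head$data[matrix(ijk + 1, 1)] != 0) depth <- depth + step
    s <- s + step
    if (s > 500) break
  }
  rel <- coord - iso
  lat2 <- (sum(rel * e1) - pb)^2 + (rel[3] - qb)^2
  if (lat2 > (3 * sigma)^2) return(0)
  exp(-mu * depth) * exp(-lat2 / (2 * sigma^2)) * (sad / (sad + depth))^2
}
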
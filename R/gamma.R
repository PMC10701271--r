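#' Gamma analysis of two dose distributions
#'
#' For every reference point above the lower dose threshold, the gamma
#' index is the minimum over evaluated points of
#' `sqrt((dr/dta)^2 + (dd_gy/(dd * Dnorm))^2)`, with the search restricted
#' to a radius of `search_factor * dta`. A point passes when `gamma <= 1`;
#' the pass rate is the percentage of evaluated reference points passing.
#' Normalization is global (reference maximum) by default, or local
#' (per-point reference dose). The evaluated distribution can be resampled
#' onto a finer lattice (`resample_factor`) for sub-voxel distance
#' resolution.
#'
#' @param ref,eval `voxel_grid`s on a common orientation (spacings may
#'   differ), or 2D dose planes as lists with `dose` (matrix) and
#'   `pitch_mm`.
#' @param dd dose-difference criterion as a fraction (default 0.03).
#' @param dta distance-to-agreement criterion in mm (default 3).
#' @param threshold lower dose cutoff as a fraction of the normalization
#'   dose; reference points below it are excluded from the denominator.
#' @param normalization `"global"` or `"local"`.
#' @param resample_factor integer lattice refinement of the evaluated
#'   distribution (1 = no refinement).
#' @param search_factor search radius in units of `dta`.
#' @return A `gamma_result`: list with `pass_rate` (%), `gamma` (array over
#'   the reference grid, `NA` below threshold), `n_evaluated`, and the
#'   criteria used.
#' @export
gamma_analysis <- function(ref, eval, dd = 0.03, dta = 3,
                           threshold = 0.1,
                           normalization = c("global", "local"),
                           resample_factor = 1L, search_factor = 3) {
  normalization <- match.arg(normalization)
  r <- as_gamma_grid(ref)
  e <- as_gamma_grid(eval)
  k <- as.integer(resample_factor)
  stopifnot(k >= 1L)
  dmax <- max(r$data)
  if (dmax <= 0) stop("reference distribution has no positive dose")
  radius <- search_factor * dta

  # fine lattice: each reference axis refined k-fold and extended by the
  # search radius; the evaluated dose is interpolated onto it once
  fine_sp <- r$spacing / k
  marg <- ceiling(radius / fine_sp)
  if (r$is_2d && e$is_2d) marg[3] <- 0L  # planar comparison: in-plane search
  axes <- lapply(1:3, function(ax) {
    n <- r$dim[ax]
    idx <- seq(-marg[ax], (n - 1) * k + marg[ax])
    list(pos = r$origin[ax] + idx * fine_sp[ax],
         ref_at = marg[ax] + 1 + (seq_len(n) - 1) * k)
  })
  ev_src <- voxel_grid(e$data, e$spacing, e$origin)
  ef <- interp_grid_at(ev_src, axes[[1]]$pos, axes[[2]]$pos, axes[[3]]$pos,
                       method = "linear", fill = NA_real_)
  dim(ef) <- vapply(axes, function(a) length(a$pos), integer(1))

  # offsets of the fine lattice within the search radius
  off <- expand.grid(dx = -marg[1]:marg[1], dy = -marg[2]:marg[2],
                     dz = -marg[3]:marg[3])
  dist2 <- (off$dx * fine_sp[1])^2 + (off$dy * fine_sp[2])^2 +
    (off$dz * fine_sp[3])^2
  keep <- dist2 <= radius^2
  off <- off[keep, ]
  dist2 <- dist2[keep]
  ord <- order(dist2)  # near offsets first: tight gamma found early
  off <- off[ord, ]; dist2 <- dist2[ord]

  dnorm_term <- if (normalization == "global") dd * dmax else dd * r$data
  gam2 <- array(Inf, r$dim)
  base_i <- axes[[1]]$ref_at; base_j <- axes[[2]]$ref_at
  base_l <- axes[[3]]$ref_at
  for (oi in seq_len(nrow(off))) {
    ev <- ef[base_i + off$dx[oi], base_j + off$dy[oi],
             base_l + off$dz[oi], drop = FALSE]
    dim(ev) <- r$dim
    cand <- dist2[oi] / dta^2 + ((r$data - ev) / dnorm_term)^2
    gam2 <- pmin(gam2, cand, na.rm = TRUE)
  }
  gamma <- sqrt(gam2)
  thr_dose <- threshold * (if (normalization == "global") dmax
                           else max(r$data))
  evaluated <- r$data >= thr_dose & is.finite(gamma)
  n_eval <- sum(evaluated)
  if (n_eval == 0L) stop("no reference points above the dose threshold")
  pass_rate <- 100 * sum(gamma[evaluated] <= 1) / n_eval
  gamma[!evaluated] <- NA_real_
  structure(list(pass_rate = pass_rate, gamma = gamma,
                 n_evaluated = n_eval, dd = dd, dta = dta,
                 threshold = threshold, normalization = normalization,
                 resample_factor = k, search_factor = search_factor,
                 is_2d = r$is_2d),
            class = "gamma_result")
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf(
    "<gamma_result> %s gamma %g%%/%g mm: pass rate %.2f%% (%d points)\n",
    if (x$is_2d) "2D" else "3D", 100 * x$dd, x$dta, x$pass_rate,
    x$n_evaluated))
  invisible(x)
}

# Coerce a voxel_grid or 2D plane (list with dose + pitch_mm, as returned
# by plane_dose()) into a common internal form.
as_gamma_grid <- function(x) {
  if (is_voxel_grid(x)) {
    d <- dim(x$data)
    return(list(data = x$data, spacing = x$spacing, origin = x$origin,
                dim = d, is_2d = d[3] == 1L))
  }
  if (is.list(x) && !is.null(x$dose) && !is.null(x$pitch_mm)) {
    d2 <- dim(x$dose)
    org <- c(if (!is.null(x$u)) x$u[1] else 0,
             if (!is.null(x$v)) x$v[1] else 0, 0)
    return(list(data = array(x$dose, c(d2, 1L)),
                spacing = c(x$pitch_mm, x$pitch_mm, 1),
                origin = org, dim = c(d2, 1L), is_2d = TRUE))
  }
  stop("cannot interpret input as a dose distribution")
}
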
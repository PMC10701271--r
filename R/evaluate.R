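mask_doses <- function(dose, mask) {
  if (!same_geometry(dose, mask)) stop("dose and mask grids are misaligned")
  v <- dose$data[mask$data != 0]
  if (length(v) == 0L) stop("mask is empty")
  v
}

#' Cumulative dose-volume histogram
#'
#' Fraction of the structure volume receiving at least each dose level, by
#' exhaustive voxel counting.
#'
#' @param dose,mask aligned `voxel_grid`s.
#' @param bin_width histogram bin width in Gy.
#' @return A `dvh_curve` data.frame with `dose_gy` and `volume_fraction`.
#' @export
dvh <- function(dose, mask, bin_width = 0.1) {
  v <- sort(mask_doses(dose, mask))
  n <- length(v)
  edges <- seq(0, max(v) + bin_width, by = bin_width)
  n_below <- findInterval(edges, v, left.open = TRUE)  # #{v < edge}
  out <- data.frame(dose_gy = edges,
                    volume_fraction = (n - n_below) / n)
  class(out) <- c("dvh_curve", class(out))
  out
}

#' Dose received by the hottest q% of a structure
#'
#' The largest dose `d` such that at least `q`% of the structure volume
#' receives `>= d` (inverse cumulative DVH), linearly interpolated between
#' order statistics with ties broken toward the lower dose.
#'
#' @param dose,mask aligned `voxel_grid`s.
#' @param q_percent coverage percentage in (0, 100].
#' @return Dose in Gy.
#' @export
dose_at_volume <- function(dose, mask, q_percent) {
  stopifnot(q_percent > 0, q_percent <= 100)
  v <- sort(mask_doses(dose, mask))
  n <- length(v)
  if (n == 1L) return(v)
  h <- (1 - q_percent / 100) * (n - 1)
  lo <- floor(h)
  frac <- h - lo
  v[lo + 1] + frac * (v[pmin(lo + 2, n)] - v[lo + 1])
}

#' Paddick-style conformity index
#'
#' `CI = (V_PGTV,Rx)^2 / (V_PGTV * V_Rx)` where `V_Rx` is the prescription
#' isodose volume and `V_PGTV,Rx` the target volume covered by it; all
#' volumes by voxel count. 1 means perfect conformity; Cauchy-Schwarz
#' bounds it in [0, 1].
#'
#' @param dose `voxel_grid` of dose.
#' @param pgtv_mask target mask.
#' @param rx prescription dose in Gy.
#' @return Unitless CI in `[0, 1]`.
#' @export
conformity_index <- function(dose, pgtv_mask, rx) {
  stopifnot(rx > 0)
  if (!same_geometry(dose, pgtv_mask)) stop("grids are misaligned")
  pgtv <- pgtv_mask$data != 0
  if (!any(pgtv)) stop("PGTV mask is empty")
  vrx <- dose$data >= rx
  n_rx <- sum(vrx)
  if (n_rx == 0L) {
    dl_log("prescription isodose volume is empty; CI = 0")
    return(0)
  }
  sum(pgtv & vrx)^2 / (sum(pgtv) * n_rx)
}

#' Homogeneity index
#'
#' `HI = (D2% - D98%) / Dmean` over the target; 0 for a perfectly uniform
#' target dose, larger values mean poorer homogeneity. Scale invariant.
#'
#' @param dose,pgtv_mask aligned `voxel_grid`s.
#' @return Unitless HI.
#' @export
homogeneity_index <- function(dose, pgtv_mask) {
  v <- mask_doses(dose, pgtv_mask)
  dmean <- mean(v)
  if (dmean <= 0) stop("mean target dose is zero; HI undefined")
  (dose_at_volume(dose, pgtv_mask, 2) -
      dose_at_volume(dose, pgtv_mask, 98)) / dmean
}

#' Intermediate-dose spillage R50%
#'
#' Ratio of the half-prescription isodose volume (anywhere in the grid) to
#' the target volume.
#'
#' @param dose,pgtv_mask aligned `voxel_grid`s.
#' @param rx prescription dose in Gy.
#' @return Unitless R50%.
#' @export
r50 <- function(dose, pgtv_mask, rx) {
  if (!same_geometry(dose, pgtv_mask)) stop("grids are misaligned")
  n_pgtv <- sum(pgtv_mask$data != 0)
  if (n_pgtv == 0L) stop("PGTV mask is empty")
  sum(dose$data >= 0.5 * rx) / n_pgtv
}

#' Maximum dose 2 cm outside the target
#'
#' Maximum dose over the 20 mm distance shell outside the PGTV (voxels
#' whose exact Euclidean distance to the target lies in
#' `[20, 20 + voxel pitch)` mm), measuring the dose fall-off. With
#' `mode = "exterior"` the maximum is instead taken over all voxels at
#' least 20 mm away.
#'
#' @param dose,pgtv_mask aligned `voxel_grid`s.
#' @param distance_mm shell distance (default 20).
#' @param mode `"shell"` (default) or `"exterior"`.
#' @return Dose in Gy.
#' @export
d2cm <- function(dose, pgtv_mask, distance_mm = 20,
                 mode = c("shell", "exterior")) {
  mode <- match.arg(mode)
  if (!same_geometry(dose, pgtv_mask)) stop("grids are misaligned")
  if (sum(pgtv_mask$data) == 0) stop("PGTV mask is empty")
  dist <- distance_transform(pgtv_mask)
  sel <- if (mode == "shell") {
    dist >= distance_mm & dist < distance_mm + max(pgtv_mask$spacing)
  } else {
    dist >= distance_mm
  }
  if (!any(sel))
    stop("the ", distance_mm,
         " mm shell is empty; the target sits too close to the volume ",
         "border -- pad the dose grid")
  max(dose$data[sel])
}

#' Percent of a structure receiving at least a dose level
#'
#' @param dose,mask aligned `voxel_grid`s.
#' @param level_gy dose level in Gy.
#' @return Percentage in `[0, 100]` (e.g. brainstem V23).
#' @export
volume_at_dose <- function(dose, mask, level_gy) {
  v <- mask_doses(dose, mask)
  100 * mean(v >= level_gy)
}

#' Point-wise dose-difference statistics
#'
#' Mean, standard deviation and mean absolute error of
#' `delta = reference - comparison` over a region, plus the same statistics
#' normalized to the prescription dose (in %).
#'
#' @param d_ref,d_cmp aligned `voxel_grid`s (reference first, e.g. the
#'   clinical dose).
#' @param region_mask optional `voxel_grid`; defaults to the whole grid.
#' @param rx prescription dose in Gy for normalization (default 30).
#' @return A list with `mean`, `sd`, `mae` (Gy) and `*_pct` (% of `rx`).
#' @export
pointwise_stats <- function(d_ref, d_cmp, region_mask = NULL, rx = 30) {
  if (!same_geometry(d_ref, d_cmp)) stop("dose grids are misaligned")
  delta <- d_ref$data - d_cmp$data
  if (!is.null(region_mask)) {
    if (!same_geometry(d_ref, region_mask)) stop("mask is misaligned")
    delta <- delta[region_mask$data != 0]
  }
  m <- mean(delta); s <- stats::sd(as.numeric(delta)); a <- mean(abs(delta))
  list(mean = m, sd = s, mae = a,
       mean_pct = 100 * m / rx, sd_pct = 100 * s / rx,
       mae_pct = 100 * a / rx)
}

#' Dice coefficient of two isodose volumes
#'
#' `DSC = 2|a n b| / (|a| + |b|)` for the regions receiving at least
#' `level_fraction * rx` in each distribution. If both regions are empty
#' the DSC is defined as 1 (logged convention).
#'
#' @param d_a,d_b aligned `voxel_grid`s.
#' @param level_fraction isodose level as a fraction of `rx`.
#' @param rx prescription dose in Gy.
#' @return Unitless DSC in `[0, 1]`.
#' @export
isodose_dsc <- function(d_a, d_b, level_fraction, rx = 30) {
  if (!same_geometry(d_a, d_b)) stop("dose grids are misaligned")
  lev <- level_fraction * rx
  a <- d_a$data >= lev
  b <- d_b$data >= lev
  denom <- sum(a) + sum(b)
  if (denom == 0L) {
    dl_log("both isodose volumes empty at %.3g Gy; DSC defined as 1", lev)
    return(1)
  }
  2 * sum(a & b) / denom
}

#' Full dosimetric panel for one case
#'
#' Computes the target metrics (D2%/D98%/D95%/D50%, Dmean, Dmax, HI, CI,
#' R50%, D2cm), brainstem V23, and per-OAR Dmax/Dmean.
#'
#' @param dose `voxel_grid` of the plan dose.
#' @param case the `plan_case` providing masks and prescription.
#' @return A one-row data.frame.
#' @export
dose_metrics <- function(dose, case) {
  rx <- case$prescription_dose
  pgtv <- case$structures$PGTV
  out <- data.frame(
    d2 = dose_at_volume(dose, pgtv, 2),
    d98 = dose_at_volume(dose, pgtv, 98),
    d95 = dose_at_volume(dose, pgtv, 95),
    d50 = dose_at_volume(dose, pgtv, 50),
    dmean = mean(mask_doses(dose, pgtv)),
    dmax = max(mask_doses(dose, pgtv)),
    hi = homogeneity_index(dose, pgtv),
    ci = conformity_index(dose, pgtv, rx),
    r50 = r50(dose, pgtv, rx),
    d2cm = d2cm(dose, pgtv))
  oars <- setdiff(names(case$structures), c("PGTV", "Head"))
  for (nm in oars) {
    msk <- case$structures[[nm]]
    if (sum(msk$data) == 0) next
    v <- mask_doses(dose, msk)
    out[[paste0(tolower(nm), "_dmax")]] <- max(v)
    out[[paste0(tolower(nm), "_dmean")]] <- mean(v)
  }
  if (!is.null(case$structures$Brainstem) &&
      sum(case$structures$Brainstem$data) > 0)
    out$v23_brainstem <- volume_at_dose(dose, case$structures$Brainstem, 23)
  out
}

#' Check the SRS clinical planning criteria
#'
#' Hard checks: D95%(PGTV) at least the prescription; normal-tissue volume
#' receiving more than 105% of the prescription under 15% of the target
#' volume (high-dose spillage confined to the target). D2cm and R50% are
#' reported for review (they are minimized, not thresholded).
#'
#' @param dose `voxel_grid` of the plan dose.
#' @param case the `plan_case`.
#' @return A list with per-criterion values and pass flags.
#' @export
clinical_criteria <- function(dose, case) {
  rx <- case$prescription_dose
  pgtv <- case$structures$PGTV
  d95_val <- dose_at_volume(dose, pgtv, 95)
  hot <- dose$data > 1.05 * rx
  n_hot_outside <- sum(hot & pgtv$data == 0)
  spill_frac <- n_hot_outside / sum(pgtv$data != 0)
  list(d95 = d95_val, d95_pass = d95_val >= rx - 1e-9,
       hotspot_outside_frac = spill_frac,
       hotspot_pass = spill_frac < 0.15,
       d2cm = d2cm(dose, pgtv), r50 = r50(dose, pgtv, rx),
       pass = (d95_val >= rx - 1e-9) && (spill_frac < 0.15))
}

#' Paired comparison of two metric panels
#'
#' Paired-sample t-test per shared metric column, flagging P < 0.05 as a
#' significant deviation. No multiple-testing correction is applied.
#'
#' @param panel_a,panel_b data.frames with one row per case (same cases,
#'   same order).
#' @return A data.frame with means, mean absolute difference and P-value
#'   per metric.
#' @export
compare_panels <- function(panel_a, panel_b) {
  cols <- intersect(names(panel_a), names(panel_b))
  cols <- cols[vapply(panel_a[cols], is.numeric, logical(1))]
  rows <- lapply(cols, function(cl) {
    a <- panel_a[[cl]]; b <- panel_b[[cl]]
    p <- if (length(a) > 1 && stats::sd(a - b) > 0)
      tryCatch(stats::t.test(a, b, paired = TRUE)$p.value,
               error = function(e) NA_real_)  # essentially constant diff
    else NA_real_
    data.frame(metric = cl, mean_a = mean(a), mean_b = mean(b),
               mean_abs_diff = mean(abs(a - b)), p_value = p,
               significant = !is.na(p) & p < 0.05)
  })
  do.call(rbind, rows)
}

#' Format a panel as mean +/- SD strings
#'
#' @param panel data.frame with one row per case.
#' @param digits number of digits after the decimal point.
#' @return A named character vector, one `"m ± s"` entry per column.
#' @export
format_panel_summary <- function(panel, digits = 1) {
  cols <- names(panel)[vapply(panel, is.numeric, logical(1))]
  out <- vapply(cols, function(cl)
    sprintf(paste0("%.", digits, "f ± %.", digits, "f"),
            mean(panel[[cl]]),
            if (nrow(panel) > 1) stats::sd(panel[[cl]]) else 0),
    character(1))
  stats::setNames(out, cols)
}
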
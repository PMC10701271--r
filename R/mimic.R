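#' Configuration of the dose-mimicking stage
#'
#' @param n_beams,spacing_deg,beamlet_size beam protocol settings (see
#'   [auto_configure_beams()]).
#' @param kernel dose kernel, see [kernel_params()].
#' @param n_levels fluence quantization levels for MLC sequencing.
#' @param max_iter,tol fluence optimizer iteration cap and relative
#'   objective tolerance.
#' @param renormalize scale the final plan so delivered D95%(PGTV) equals
#'   the prescription (clinical plan normalization).
#' @param plane_depth_mm,plane_pitch_mm verification plane geometry.
#' @return A `mimic_config` list.
#' @export
mimic_config <- function(n_beams = 9, spacing_deg = 20, beamlet_size = 5,
                         kernel = kernel_params(), n_levels = 10,
                         max_iter = 500, tol = 1e-6, renormalize = TRUE,
                         plane_depth_mm = 50, plane_pitch_mm = 2.5) {
  structure(list(n_beams = n_beams, spacing_deg = spacing_deg,
                 beamlet_size = beamlet_size, kernel = kernel,
                 n_levels = n_levels, max_iter = max_iter, tol = tol,
                 renormalize = renormalize,
                 plane_depth_mm = plane_depth_mm,
                 plane_pitch_mm = plane_pitch_mm),
            class = "mimic_config")
}

#' Optimize beamlet fluence against a target dose
#'
#' Minimizes the importance-weighted voxel-wise squared disparity
#' `sum_v w_v (sum_b D_vb f_b - t_v)^2` subject to `f >= 0`, by projected
#' gradient descent with Barzilai-Borwein steps and a monotone
#' backtracking safeguard, so the recorded objective history is
#' non-increasing.
#'
#' @param D a `deposition_matrix`.
#' @param target `voxel_grid` of the desired dose (aligned to `D`).
#' @param weights per-voxel importance (array order); default 1.
#' @param max_iter iteration cap.
#' @param tol relative objective-decrease tolerance for convergence.
#' @return A `fluence_fit`: list with `fluence` (a `fluence_map`),
#'   `objective` (non-increasing history), `iterations`, `converged`.
#' @export
optimize_fluence <- function(D, target, weights = NULL, max_iter = 500,
                             tol = 1e-6) {
  M <- D$M
  t_vec <- as.numeric(target$data)
  if (length(t_vec) != nrow(M))
    stop("target is not aligned to the deposition matrix grid")
  if (is.null(weights)) weights <- rep(1, nrow(M))
  w <- as.numeric(weights)
  if (any(w < 0)) stop("weights must be non-negative")
  nb <- ncol(M)
  if (all(t_vec == 0)) {
    return(structure(list(fluence = fluence_from_vector(numeric(nb),
                                                        D$beams),
                          objective = 0, iterations = 0L,
                          converged = TRUE),
                     class = "fluence_fit"))
  }
  f <- numeric(nb)
  r <- -t_vec
  obj <- sum(w * r^2)
  hist <- obj
  g <- as.numeric(2 * Matrix::crossprod(M, w * r))
  f_prev <- NULL; g_prev <- NULL
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    if (is.null(f_prev)) {
      Mg <- as.numeric(M %*% g)
      denom <- 2 * sum(w * Mg^2)
      if (denom <= 0) break
      alpha <- sum(g^2) / denom       # exact Cauchy step
    } else {
      s <- f - f_prev
      y <- g - g_prev
      sy <- sum(s * y)
      alpha <- if (sy > 0) sum(s * s) / sy else 1
    }
    ok <- FALSE
    for (bt in 1:30) {
      f_new <- pmax(f - alpha * g, 0)
      r_new <- as.numeric(M %*% f_new) - t_vec
      obj_new <- sum(w * r_new^2)
      if (obj_new <= obj) { ok <- TRUE; break }
      alpha <- alpha / 2
    }
    if (!ok) break
    f_prev <- f; g_prev <- g
    rel_drop <- (obj - obj_new) / max(obj, .Machine$double.eps)
    f <- f_new; r <- r_new; obj <- obj_new
    hist <- c(hist, obj)
    g <- as.numeric(2 * Matrix::crossprod(M, w * r))
    if (rel_drop < tol) { converged <- TRUE; break }
  }
  structure(list(fluence = fluence_from_vector(f, D$beams),
                 objective = hist, iterations = length(hist) - 1L,
                 converged = converged),
            class = "fluence_fit")
}

# Aperture of one dual-layer segment from its leaf intervals: layer 1
# opens a column interval per row, layer 2 a row interval per column; the
# open region is their intersection.
build_aperture <- function(row_int, col_int) {
  np <- nrow(row_int); nq <- nrow(col_int)
  open1 <- matrix(FALSE, np, nq)
  for (i in seq_len(np)) {
    if (!is.na(row_int[i, 1]))
      open1[i, row_int[i, 1]:row_int[i, 2]] <- TRUE
  }
  open2 <- matrix(FALSE, np, nq)
  for (j in seq_len(nq)) {
    if (!is.na(col_int[j, 1]))
      open2[col_int[j, 1]:col_int[j, 2], j] <- TRUE
  }
  open1 & open2
}

interval_hull <- function(mask_rows) {
  # per row of a logical matrix: [first, last] TRUE column, NA when closed
  t(apply(mask_rows, 1, function(rw) {
    wh <- which(rw)
    if (length(wh) == 0) c(NA_integer_, NA_integer_)
    else c(wh[1], wh[length(wh)])
  }))
}

#' Sequence fluence maps into dual-layer orthogonal MLC segments
#'
#' Each beam's fluence is quantized to `n_levels` uniform levels; the
#' super-level sets are delivered as stacked segments whose open region is
#' the intersection of per-row column intervals (layer 1) and per-column
#' row intervals (layer 2). Consecutive levels with identical apertures
#' are merged into one weighted segment. For row- and column-convex level
#' sets the quantized map is reconstructed exactly, so the per-beamlet
#' reconstruction error is bounded by half a quantization step.
#'
#' @param fluence a `fluence_map`.
#' @param n_levels number of quantization levels (>= 1).
#' @return An `aperture_sequence`: per-beam list of segments
#'   (`weight`, `row_intervals`, `col_intervals`) plus the beam
#'   geometries and quantization steps.
#' @export
sequence_mlc <- function(fluence, n_levels = 10) {
  if (n_levels < 1) stop("n_levels must be at least 1")
  beams_segments <- vector("list", length(fluence$maps))
  steps <- numeric(length(fluence$maps))
  for (bi in seq_along(fluence$maps)) {
    f <- fluence$maps[[bi]]
    fmax <- max(f)
    if (fmax <= 0) {
      beams_segments[[bi]] <- list()
      steps[bi] <- 0
      next
    }
    step <- fmax / n_levels
    steps[bi] <- step
    q <- round(f / step)
    segs <- list()
    prev <- NULL
    for (k in seq_len(max(q))) {
      R <- q >= k
      row_int <- interval_hull(R)
      col_int <- interval_hull(t(R))
      if (!is.null(prev) && identical(prev$row_intervals, row_int) &&
          identical(prev$col_intervals, col_int)) {
        prev$weight <- prev$weight + step
        segs[[length(segs)]] <- prev
      } else {
        prev <- list(weight = step, row_intervals = row_int,
                     col_intervals = col_int)
        segs[[length(segs) + 1L]] <- prev
      }
    }
    beams_segments[[bi]] <- segs
  }
  structure(list(beams = fluence$beams, segments = beams_segments,
                 quant_step = steps, n_levels = n_levels),
            class = "aperture_sequence")
}

#' Reconstruct the deliverable fluence of an aperture sequence
#'
#' `sum_k weight_k x aperture-indicator_k` per beam.
#'
#' @param sequence an `aperture_sequence`.
#' @return A `fluence_map`.
#' @export
reconstruct_fluence <- function(sequence) {
  maps <- lapply(seq_along(sequence$beams), function(bi) {
    b <- sequence$beams[[bi]]
    np <- length(b$p_centers); nq <- length(b$q_centers)
    f <- matrix(0, np, nq)
    for (seg in sequence$segments[[bi]]) {
      f <- f + seg$weight * build_aperture(seg$row_intervals,
                                           seg$col_intervals)
    }
    f
  })
  fluence_map(sequence$beams, maps)
}

#' Compute the delivered dose of an aperture sequence
#'
#' Reconstructs the deliverable fluence and pushes it through the
#' deposition matrix.
#'
#' @param sequence an `aperture_sequence`.
#' @param D the `deposition_matrix` used for planning.
#' @return A `voxel_grid` of delivered dose.
#' @export
deliver <- function(sequence, D) {
  if (length(sequence$beams) != length(D$beams))
    stop("sequence and deposition matrix have different beam counts")
  for (i in seq_along(D$beams)) {
    sb <- sequence$beams[[i]]
    nb <- length(sb$p_centers) * length(sb$q_centers)
    if (abs(sb$gantry_deg - D$beams[[i]]$gantry_deg) > 1e-9 ||
        nb != D$beams[[i]]$n_beamlets)
      stop("sequence beam geometry does not match the deposition matrix")
  }
  compute_dose(D, reconstruct_fluence(sequence))
}

#' Verify a plan by gamma analysis
#'
#' With `plane_mode = FALSE`, compares two 3D dose grids directly. With
#' `plane_mode = TRUE`, emulates detector-array delivery verification:
#' both arguments must be `fluence_map`s (planned and deliverable); every
#' field is recomputed at gantry 0 onto a measurement plane at fixed
#' water-equivalent depth, the per-field maps are composited, and 2D gamma
#' is run on the composite.
#'
#' @param planned,delivered `voxel_grid`s (3D mode) or `fluence_map`s
#'   (plane mode).
#' @param plane_mode switch between the two comparisons.
#' @param dd,dta,threshold gamma criteria (fraction, mm, fraction).
#' @param kernel,plane_depth_mm,plane_pitch_mm plane recomputation
#'   settings (plane mode only).
#' @param ... further arguments for [gamma_analysis()].
#' @return A `gamma_result`.
#' @export
verify_plan <- function(planned, delivered, plane_mode = FALSE, dd = 0.03,
                        dta = 3, threshold = 0.1,
                        kernel = kernel_params(), plane_depth_mm = 50,
                        plane_pitch_mm = 2.5, ...) {
  if (plane_mode) {
    if (!inherits(planned, "fluence_map") ||
        !inherits(delivered, "fluence_map"))
      stop("plane-mode verification needs the planned and deliverable ",
           "fluence maps")
    p_plane <- plane_dose(planned, kernel, plane_depth_mm, plane_pitch_mm)
    d_plane <- plane_dose(delivered, kernel, plane_depth_mm,
                          plane_pitch_mm)
    if (max(p_plane$dose) <= 0) stop("empty plane intersection")
    return(gamma_analysis(p_plane, d_plane, dd = dd, dta = dta,
                          threshold = threshold, resample_factor = 3L,
                          ...))
  }
  gamma_analysis(planned, delivered, dd = dd, dta = dta,
                 threshold = threshold, ...)
}

#' Full dose-mimicking pipeline
#'
#' Converts a (predicted) dose distribution into a deliverable plan:
#' auto-configured coplanar beams, deposition matrix, voxel-wise fluence
#' optimization against the prediction, dual-layer MLC sequencing,
#' delivered-dose recomputation, plan renormalization (delivered
#' D95%(PGTV) = prescription), and delivery verification (2D plane gamma
#' and 3D gamma), plus the clinical criteria report.
#'
#' @param case a `plan_case`.
#' @param predicted `voxel_grid` of the dose to mimic; defaults to the
#'   case's reference dose.
#' @param config a [mimic_config()].
#' @param D optional precomputed `deposition_matrix` (reused when the
#'   caller already built one for this case).
#' @return A `mimic_result`: fluence, sequence, planned and delivered
#'   doses, objective history, gamma verification, clinical criteria.
#' @export
mimic_pipeline <- function(case, predicted = NULL, config = mimic_config(),
                           D = NULL) {
  predicted <- predicted %||% case$reference_dose
  if (is.null(predicted)) stop("mimic: no predicted dose given")
  if (!same_geometry(case$ct, predicted))
    stop("mimic: predicted dose is not aligned to the case")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  if (is.null(D)) {
    beams <- stage("beams", auto_configure_beams(
      case, n_beams = config$n_beams, spacing_deg = config$spacing_deg,
      beamlet_size = config$beamlet_size))
    D <- stage("deposition", build_deposition_matrix(case, beams,
                                                     config$kernel))
  }
  w <- stage("weights", importance_weights(case))
  fit <- stage("optimize", optimize_fluence(D, predicted, w,
                                            max_iter = config$max_iter,
                                            tol = config$tol))
  fl <- fit$fluence
  sequence <- stage("sequence", sequence_mlc(fl, config$n_levels))
  delivered <- stage("deliver", deliver(sequence, D))
  if (config$renormalize) {
    d95 <- dose_at_volume(delivered, case$structures$PGTV, 95)
    if (d95 <= 0) stop("[stage renormalize] delivered dose misses the target")
    s <- case$prescription_dose / d95
    dl_log("plan renormalization x%.4f (delivered D95 %.2f -> %.2f Gy)",
           s, d95, case$prescription_dose)
    fl$maps <- lapply(fl$maps, function(m) m * s)
    for (bi in seq_along(sequence$segments)) {
      sequence$segments[[bi]] <- lapply(sequence$segments[[bi]],
                                        function(seg) {
                                          seg$weight <- seg$weight * s
                                          seg
                                        })
    }
    sequence$quant_step <- sequence$quant_step * s
    delivered <- grid_like(delivered, delivered$data * s)
  }
  planned_dose <- stage("plan-dose", compute_dose(D, fl))
  gamma_2d <- stage("verify-2d", verify_plan(
    fl, reconstruct_fluence(sequence), plane_mode = TRUE,
    kernel = config$kernel, plane_depth_mm = config$plane_depth_mm,
    plane_pitch_mm = config$plane_pitch_mm))
  gamma_3d <- stage("verify-3d", verify_plan(planned_dose, delivered))
  criteria <- stage("criteria", clinical_criteria(delivered, case))
  structure(list(fluence = fl, sequence = sequence,
                 planned_dose = planned_dose, delivered_dose = delivered,
                 objective = fit$objective, iterations = fit$iterations,
                 gamma_2d = gamma_2d, gamma_3d = gamma_3d,
                 criteria = criteria),
            class = "mimic_result")
}

#' @export
print.mimic_result <- function(x, ...) {
  cat(sprintf(paste0(
    "<mimic_result> %d beams, %d optimizer iterations\n",
    "  2D gamma pass %.1f%%, 3D gamma pass %.1f%%\n",
    "  delivered D95 %.2f Gy (criteria %s)\n"),
    length(x$fluence$beams), x$iterations, x$gamma_2d$pass_rate,
    x$gamma_3d$pass_rate, x$criteria$d95,
    if (x$criteria$pass) "pass" else "FAIL"))
  invisible(x)
}

#' Export a plan as a JSON description
#'
#' Beams, segments and weights in a portable text form.
#'
#' @param result a `mimic_result`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_plan_json <- function(result, path) {
  plan <- list(
    beams = lapply(result$sequence$beams, function(b)
      list(gantry_deg = b$gantry_deg, isocenter = b$isocenter,
           sad = b$sad, beamlet_size = b$beamlet_size)),
    segments = lapply(result$sequence$segments, function(segs)
      lapply(segs, function(s)
        list(weight = s$weight,
             row_intervals = apply(s$row_intervals, 1, as.list),
             col_intervals = apply(s$col_intervals, 1, as.list)))),
    verification = list(gamma_2d_pass = result$gamma_2d$pass_rate,
                        gamma_3d_pass = result$gamma_3d$pass_rate),
    criteria = result$criteria)
  jsonlite::write_json(plan, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
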
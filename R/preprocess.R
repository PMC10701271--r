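#' Normalization specification
#'
#' Intensity normalization used before model training: CT values are
#' clipped to `[ct_clip_low, ct_clip_high]` HU and mapped affinely to
#' `[-1, 1]`; dose is mapped affinely from `[0, dose_ref_max]` to
#' `[-1, 1]`. The dose ceiling defaults to 1.4x the 30 Gy prescription
#' (42 Gy), comfortably above clinically observed near-maximum doses.
#'
#' @param ct_clip_low,ct_clip_high HU clipping window (default -200, 300).
#' @param dose_ref_max dose normalization ceiling in Gy (default 42).
#' @return A `normalization_spec` list.
#' @export
normalization_spec <- function(ct_clip_low = -200, ct_clip_high = 300,
                               dose_ref_max = 42) {
  stopifnot(ct_clip_low < ct_clip_high, dose_ref_max > 0)
  structure(list(ct_clip_low = ct_clip_low, ct_clip_high = ct_clip_high,
                 dose_ref_max = dose_ref_max),
            class = "normalization_spec")
}

#' Clip and normalize CT intensities to [-1, 1]
#'
#' `y = (clip(x, low, high) - mid) / halfwidth`, so with the default
#' window, -200 HU maps to -1 and +300 HU to +1.
#'
#' @param ct `voxel_grid` or array of HU values.
#' @param spec a [normalization_spec()].
#' @return Array of normalized values in `[-1, 1]`.
#' @export
normalize_ct <- function(ct, spec = normalization_spec()) {
  x <- if (is_voxel_grid(ct)) ct$data else ct
  if (any(!is.finite(x))) stop("CT contains non-finite values")
  mid <- (spec$ct_clip_low + spec$ct_clip_high) / 2
  half <- (spec$ct_clip_high - spec$ct_clip_low) / 2
  (clamp(x, spec$ct_clip_low, spec$ct_clip_high) - mid) / half
}

#' Normalize dose to [-1, 1]
#'
#' Affine map of `[0, dose_ref_max]` Gy onto `[-1, 1]`. Doses above the
#' ceiling are clipped with a warning.
#'
#' @param dose `voxel_grid` or array of dose in Gy (non-negative).
#' @param spec a [normalization_spec()].
#' @return Array of normalized values.
#' @export
normalize_dose <- function(dose, spec = normalization_spec()) {
  x <- if (is_voxel_grid(dose)) dose$data else dose
  if (any(x < 0)) stop("dose must be non-negative")
  if (any(x > spec$dose_ref_max)) {
    dl_log("dose exceeds the %g Gy normalization ceiling at %d voxel(s); clipping",
           spec$dose_ref_max, sum(x > spec$dose_ref_max))
    x <- pmin(x, spec$dose_ref_max)
  }
  2 * x / spec$dose_ref_max - 1
}

#' Invert [normalize_dose()]
#'
#' @param y normalized array in `[-1, 1]`.
#' @param spec a [normalization_spec()].
#' @return Dose array in Gy.
#' @export
denormalize_dose <- function(y, spec = normalization_spec()) {
  (y + 1) / 2 * spec$dose_ref_max
}

#' Align structures and dose onto the CT grid
#'
#' Resamples every structure mask (nearest neighbour) and the reference
#' dose (trilinear) onto the CT geometry. A case already on a common grid
#' is returned unchanged.
#'
#' @param case a `plan_case` whose members may live on different grids.
#' @return The aligned `plan_case`.
#' @export
align_case <- function(case) {
  ct <- case$ct
  aligned <- TRUE
  for (nm in names(case$structures))
    if (!same_geometry(ct, case$structures[[nm]])) aligned <- FALSE
  if (!is.null(case$reference_dose) &&
      !same_geometry(ct, case$reference_dose)) aligned <- FALSE
  if (aligned) return(case)
  check_overlap <- function(g, what) {
    lo_a <- g$origin; hi_a <- g$origin + (dim(g$data) - 1) * g$spacing
    lo_b <- ct$origin; hi_b <- ct$origin + (dim(ct$data) - 1) * ct$spacing
    if (any(hi_a < lo_b) || any(lo_a > hi_b))
      stop(sprintf("%s grid has no spatial overlap with the CT grid", what))
  }
  structures <- lapply(names(case$structures), function(nm) {
    g <- case$structures[[nm]]
    if (same_geometry(ct, g)) return(g)
    check_overlap(g, nm)
    resample_grid(g, ct, method = "nearest", fill = 0)
  })
  names(structures) <- names(case$structures)
  ref <- case$reference_dose
  if (!is.null(ref) && !same_geometry(ct, ref)) {
    check_overlap(ref, "dose")
    ref <- resample_grid(ref, ct, method = "linear", fill = 0)
  }
  plan_case(ct, structures, case$prescription_dose, case$fractions,
            reference_dose = ref, meta = case$meta)
}

#' Encode structures into one integer-label channel
#'
#' Structures are painted in a fixed priority order with the PGTV highest,
#' so the target always wins voxel overlaps. The code map (name -> integer,
#' background 0) is returned for exact decoding.
#'
#' @param structures named list of binary `voxel_grid`s.
#' @return List with `labels` (integer array) and `code_map`.
#' @export
encode_structures <- function(structures) {
  nms <- names(structures)
  oars <- sort(setdiff(nms, c("Head", "PGTV")))
  order_low_to_high <- c(intersect("Head", nms), oars,
                         intersect("PGTV", nms))
  code_map <- stats::setNames(seq_along(order_low_to_high),
                              order_low_to_high)
  labels <- array(0L, dim(structures[[1]]$data))
  for (nm in order_low_to_high)
    labels[structures[[nm]]$data != 0] <- code_map[[nm]]
  list(labels = labels, code_map = code_map)
}

#' Decode an integer-label channel back to binary masks
#'
#' Inverts the painting semantics of [encode_structures()]: each voxel
#' carries its highest-priority structure, so a decoded mask is the
#' original minus any higher-priority overlap (the one-hot encoding keeps
#' overlapping structures lossless instead). `Head` decodes as everything
#' non-background.
#'
#' @param labels integer array from [encode_structures()].
#' @param code_map the accompanying code map.
#' @return Named list of logical arrays.
#' @export
decode_structures <- function(labels, code_map) {
  out <- lapply(names(code_map), function(nm) {
    if (nm == "Head") labels >= code_map[[nm]] else labels == code_map[[nm]]
  })
  stats::setNames(out, names(code_map))
}

#' Crop and resample a case into a model-ready tensor
#'
#' Resamples the case to the target spacing and extracts a window of the
#' target shape centred on the PGTV centroid (snapped to the resampling
#' lattice so an identity-spacing crop is an exact sub-array). Windows
#' reaching past the volume are padded (air HU / zero dose). Channels:
#' structure labels rescaled to `[-1, 1]`, then normalized CT. The `meta`
#' element carries everything needed to restore Gy and CT coordinates.
#'
#' @param case a `plan_case`.
#' @param shape voxel window shape (default the 224 x 224 x 32 preset).
#' @param spacing target voxel pitch in mm (default 2.5 isotropic).
#' @param norm a [normalization_spec()].
#' @param one_hot emit one binary channel per structure instead of the
#'   integer-label channel.
#' @return A `tensor_case`: list with `inputs` (array `X,Y,Z,C`), `target`
#'   (normalized dose array or `NULL`), and `meta`.
#' @export
crop_to_shape <- function(case, shape = c(224, 224, 32),
                          spacing = c(2.5, 2.5, 2.5),
                          norm = normalization_spec(),
                          one_hot = FALSE) {
  case <- align_case(case)
  pgtv <- case$structures$PGTV
  if (sum(pgtv$data) == 0) stop("PGTV mask is empty")
  centroid <- mask_centroid(pgtv)
  # snap the window to the lattice {ct_origin + k * spacing}
  i0 <- round((centroid - case$ct$origin) / spacing)
  start <- i0 - floor(shape / 2)
  worigin <- case$ct$origin + start * spacing
  wgeom <- list(dim = as.integer(shape), spacing = spacing,
                origin = worigin)
  air_hu <- -1000
  ct_w <- resample_grid(case$ct, wgeom, "linear", fill = air_hu)
  masks_w <- lapply(case$structures, resample_grid, target = wgeom,
                    method = "nearest", fill = 0)
  enc <- encode_structures(masks_w)
  n_codes <- max(1L, length(enc$code_map))
  if (one_hot) {
    # independent binary channels straight from the masks, so overlapping
    # structures (e.g. lens inside eye) are preserved exactly
    chans <- lapply(names(enc$code_map), function(nm)
      (masks_w[[nm]]$data != 0) * 1)
    label_block <- array(unlist(chans), c(shape, length(chans)))
    chan_names <- c(names(enc$code_map), "CT")
  } else {
    label_block <- array(2 * enc$labels / n_codes - 1, c(shape, 1))
    chan_names <- c("labels", "CT")
  }
  ct_chan <- array(normalize_ct(ct_w, norm), c(shape, 1))
  inputs <- array(c(label_block, ct_chan),
                  c(shape, dim(label_block)[4] + 1))
  target <- NULL
  if (!is.null(case$reference_dose)) {
    dose_w <- resample_grid(case$reference_dose, wgeom, "linear", fill = 0)
    target <- normalize_dose(clamp(dose_w$data, 0, Inf), norm)
  }
  meta <- list(window = wgeom, ct_geometry = list(
                 dim = dim(case$ct$data), spacing = case$ct$spacing,
                 origin = case$ct$origin),
               norm = norm, code_map = enc$code_map, n_codes = n_codes,
               one_hot = one_hot, channels = chan_names,
               prescription_dose = case$prescription_dose)
  structure(list(inputs = inputs, target = target, meta = meta),
            class = "tensor_case")
}

#' Restore a window-cropped dose array to CT coordinates
#'
#' Inverse of the cropping step: places a (physical-unit) dose array
#' defined on a tensor case's window back onto the original CT geometry,
#' zero outside the window.
#'
#' @param dose_array array on the tensor window (Gy).
#' @param meta the `meta` element of a `tensor_case`.
#' @return A `voxel_grid` on the original CT geometry.
#' @export
uncrop_to_ct <- function(dose_array, meta) {
  w <- meta$window
  src <- voxel_grid(dose_array, w$spacing, w$origin)
  resample_grid(src, list(dim = meta$ct_geometry$dim,
                          spacing = meta$ct_geometry$spacing,
                          origin = meta$ct_geometry$origin),
                method = "linear", fill = 0)
}

#' Assign the PGTV size group
#'
#' `small` iff the rasterized target volume is at most 20 cc (inclusive),
#' `large` otherwise.
#'
#' @param case a `plan_case`.
#' @return `"small"` or `"large"`.
#' @export
assign_group <- function(case) {
  pgtv <- case$structures$PGTV
  if (sum(pgtv$data) == 0) stop("PGTV mask is empty")
  if (mask_volume_cc(pgtv) <= 20) "small" else "large"
}
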
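#' One patient-equivalent planning case
#'
#' Bundles everything one case carries through the pipeline: the CT (HU),
#' the structure set (binary masks, including the external `Head` contour
#' and the `PGTV` target), the prescription, and optionally a reference
#' dose. The size group is assigned from the rasterized target volume
#' (`small` iff PGTV volume <= 20 cc).
#'
#' @param ct `voxel_grid` of Hounsfield units.
#' @param structures named list of binary `voxel_grid`s; must contain
#'   `PGTV` and `Head`.
#' @param prescription_dose prescription in Gy (default 30).
#' @param fractions number of fractions (default 5).
#' @param reference_dose optional `voxel_grid` of dose in Gy.
#' @param meta optional named list of provenance (seed, spec, ...).
#' @return A `plan_case` object.
#' @export
plan_case <- function(ct, structures, prescription_dose = 30, fractions = 5,
                      reference_dose = NULL, meta = list()) {
  stopifnot(is_voxel_grid(ct), is.list(structures))
  if (is.null(structures[["PGTV"]])) stop("structures must contain 'PGTV'")
  for (nm in names(structures)) {
    if (!same_geometry(ct, structures[[nm]]))
      stop(sprintf("structure '%s' does not share the CT geometry", nm))
  }
  if (!is.null(reference_dose) && !same_geometry(ct, reference_dose))
    stop("reference dose does not share the CT geometry")
  obj <- structure(list(ct = ct, structures = structures,
                        prescription_dose = prescription_dose,
                        fractions = fractions,
                        reference_dose = reference_dose,
                        size_group = NA_character_, meta = meta),
                   class = "plan_case")
  obj$size_group <- assign_group(obj)
  obj
}

#' @export
print.plan_case <- function(x, ...) {
  cat(sprintf(
    "<plan_case> %s, %d structures, PGTV %.2f cc (%s), Rx %g Gy / %d fx%s\n",
    paste(dim(x$ct$data), collapse = "x"), length(x$structures),
    mask_volume_cc(x$structures$PGTV), x$size_group,
    x$prescription_dose, x$fractions,
    if (is.null(x$reference_dose)) "" else ", reference dose present"))
  invisible(x)
}

default_oar_layout <- function() {
  # geometric primitives at anatomically plausible offsets (mm, LPS with
  # the head centre at the world origin; anterior = -y, inferior = -z)
  list(
    Brainstem   = list(type = "capsule", a = c(0, 25, -40), b = c(0, 25, 5),
                       r = 10),
    OpticChiasm = list(type = "sphere", c = c(0, 8, -12), r = 5),
    OpticNerve_L = list(type = "capsule", a = c(4, 4, -12),
                        b = c(24, -50, -8), r = 2.5),
    OpticNerve_R = list(type = "capsule", a = c(-4, 4, -12),
                        b = c(-24, -50, -8), r = 2.5),
    Eye_L  = list(type = "sphere", c = c(28, -60, -8), r = 12),
    Eye_R  = list(type = "sphere", c = c(-28, -60, -8), r = 12),
    Lens_L = list(type = "sphere", c = c(28, -70, -8), r = 4),
    Lens_R = list(type = "sphere", c = c(-28, -70, -8), r = 4),
    Hypophysis = list(type = "sphere", c = c(0, 10, -18), r = 4))
}

#' Synthetic head phantom specification
#'
#' Defines the geometry and intensity model of one synthetic case: a
#' head-like ellipsoid (brain surrounded by a skull shell), a spherical
#' target (PGTV), and nine organs at risk placed as geometric primitives at
#' plausible relative positions, deliberately separated from typical target
#' locations. Identical spec + seed produces a bit-identical case.
#'
#' @param grid_dim voxel grid shape (default `c(96, 96, 32)`).
#' @param spacing voxel pitch in mm (default 2.5 isotropic).
#' @param head_semi_axes ellipsoid semi-axes of the head (mm).
#' @param skull_thickness skull shell thickness (mm).
#' @param pgtv_center `"random"` or LPS world mm triple.
#' @param pgtv_radius target sphere radius (mm).
#' @param oar_layout named list of primitives (`sphere` or `capsule`).
#' @param hu_values HU per tissue class (air, skull, brain, tumor).
#' @param noise_sd additive Gaussian CT noise (HU).
#' @param seed RNG seed for noise and random placement.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid_dim = c(96, 96, 32),
                         spacing = c(2.5, 2.5, 2.5),
                         head_semi_axes = c(70, 85, 75),
                         skull_thickness = 6,
                         pgtv_center = "random",
                         pgtv_radius = 10,
                         oar_layout = default_oar_layout(),
                         hu_values = c(air = -1000, skull = 700,
                                       brain = 40, tumor = 60),
                         noise_sd = 20,
                         seed = 1L) {
  stopifnot(pgtv_radius > 0, skull_thickness > 0,
            all(head_semi_axes > 0), noise_sd >= 0)
  structure(list(grid_dim = as.integer(grid_dim), spacing = spacing,
                 head_semi_axes = head_semi_axes,
                 skull_thickness = skull_thickness,
                 pgtv_center = pgtv_center, pgtv_radius = pgtv_radius,
                 oar_layout = oar_layout, hu_values = hu_values,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Rasterize primitives: a voxel belongs to the mask iff its centre is
# inside the primitive (half-open rasterization).
raster_sphere <- function(coords, center, r) {
  colSums((t(coords) - center)^2) <= r^2
}

raster_capsule <- function(coords, a, b, r) {
  ab <- b - a
  len2 <- sum(ab^2)
  rel <- sweep(coords, 2, a, "-")
  t <- clamp((rel %*% ab) / len2, 0, 1)
  dx <- rel - outer(as.numeric(t), ab)
  rowSums(dx^2) <= r^2
}

raster_primitive <- function(coords, prim) {
  switch(prim$type,
         sphere = raster_sphere(coords, prim$c, prim$r),
         capsule = raster_capsule(coords, prim$a, prim$b, prim$r),
         stop("unknown primitive type: ", prim$type))
}

ellipsoid_inside <- function(coords, semi_axes) {
  (coords[, 1] / semi_axes[1])^2 + (coords[, 2] / semi_axes[2])^2 +
    (coords[, 3] / semi_axes[3])^2 <= 1
}

# Shortest distance from a point to a primitive surface (negative inside).
primitive_distance <- function(p, prim) {
  if (prim$type == "sphere") return(sqrt(sum((p - prim$c)^2)) - prim$r)
  ab <- prim$b - prim$a
  t <- clamp(sum((p - prim$a) * ab) / sum(ab^2), 0, 1)
  sqrt(sum((p - (prim$a + t * ab))^2)) - prim$r
}

#' Generate one synthetic planning case
#'
#' Builds the CT, structure masks and (optionally) a physically consistent
#' reference dose for a phantom spec. The reference dose is produced by the
#' package's own dose engine: beams are auto-configured, a deposition
#' matrix is built, the fluence is optimized against an idealized target
#' (prescription inside the PGTV with exponential fall-off outside), and
#' the resulting dose is renormalized so that D95%(PGTV) equals the
#' prescription.
#'
#' @param spec a [phantom_spec()].
#' @param prescription_dose Gy (default 30).
#' @param fractions count (default 5).
#' @param compute_reference compute the reference dose (default `TRUE`;
#'   geometry-only tests may switch it off).
#' @param mimic_config optimizer settings for the reference dose, see
#'   [mimic_config()].
#' @return A `plan_case`.
#' @export
generate_case <- function(spec, prescription_dose = 30, fractions = 5,
                          compute_reference = TRUE,
                          mimic_config = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  d <- spec$grid_dim
  sp <- spec$spacing
  origin <- -(d - 1) / 2 * sp  # head centre at the world origin
  geom <- voxel_grid(array(0, d), sp, origin)
  coords <- voxel_coords(geom)
  hu <- spec$hu_values

  head_in <- ellipsoid_inside(coords, spec$head_semi_axes)
  brain_in <- ellipsoid_inside(coords,
                               spec$head_semi_axes - spec$skull_thickness)
  ct_vals <- rep(hu[["air"]], nrow(coords))
  ct_vals[head_in] <- hu[["skull"]]
  ct_vals[brain_in] <- hu[["brain"]]

  oar_masks <- lapply(spec$oar_layout, function(prim) {
    raster_primitive(coords, prim) & brain_in
  })

  pgtv_r <- spec$pgtv_radius
  if (identical(spec$pgtv_center, "random")) {
    center <- sample_pgtv_center(spec)
  } else {
    center <- as.numeric(spec$pgtv_center)
    if (!pgtv_center_valid(center, spec))
      stop("geometry error: PGTV does not fit inside the head at this centre")
  }
  pgtv_in <- raster_sphere(coords, center, pgtv_r)
  if (!all(head_in[pgtv_in]))
    stop("geometry error: PGTV extends outside the head")
  for (nm in names(oar_masks)) {
    if (any(pgtv_in & oar_masks[[nm]]))
      stop(sprintf("geometry error: PGTV overlaps OAR '%s'", nm))
  }
  ct_vals[pgtv_in] <- hu[["tumor"]]
  if (spec$noise_sd > 0)
    ct_vals <- ct_vals + stats::rnorm(length(ct_vals), sd = spec$noise_sd)

  as_mask <- function(v) voxel_grid(array(as.numeric(v), d), sp, origin)
  structures <- c(list(Head = as_mask(head_in), PGTV = as_mask(pgtv_in)),
                  lapply(oar_masks, as_mask))
  case <- plan_case(voxel_grid(array(ct_vals, d), sp, origin), structures,
                    prescription_dose, fractions,
                    meta = list(seed = spec$seed, pgtv_center = center,
                                pgtv_radius = pgtv_r))
  if (compute_reference)
    case$reference_dose <- reference_dose(case, mimic_config = mimic_config)
  case
}

pgtv_center_valid <- function(center, spec, margin = 2) {
  shrink <- spec$head_semi_axes - spec$skull_thickness -
    spec$pgtv_radius - margin
  if (any(shrink <= 0)) return(FALSE)
  z_half <- (spec$grid_dim[3] - 1) / 2 * spec$spacing[3]
  if (abs(center[3]) + spec$pgtv_radius > z_half - spec$spacing[3])
    return(FALSE)
  if (!ellipsoid_inside(matrix(center, 1), shrink)) return(FALSE)
  for (prim in spec$oar_layout) {
    if (primitive_distance(center, prim) < spec$pgtv_radius + margin)
      return(FALSE)
  }
  TRUE
}

sample_pgtv_center <- function(spec, max_tries = 500) {
  box <- 0.8 * (spec$head_semi_axes - spec$skull_thickness)
  z_half <- (spec$grid_dim[3] - 1) / 2 * spec$spacing[3]
  for (i in seq_len(max_tries)) {
    c_try <- c(stats::runif(1, -box[1], box[1]),
               stats::runif(1, -box[2], box[2]),
               stats::runif(1, -min(box[3], z_half * 0.6),
                            min(box[3], z_half * 0.6)))
    if (pgtv_center_valid(c_try, spec)) return(c_try)
  }
  stop("could not place the PGTV after ", max_tries, " draws; ",
       "reduce pgtv_radius or enlarge the grid")
}

#' Idealized reference dose for a phantom case
#'
#' Optimizes beam fluence against an idealized dose objective (105% of the
#' prescription inside the PGTV, exponential fall-off with distance
#' outside, 5 mm half-dose distance emulating SRS-grade gradients) and
#' renormalizes the delivered dose
#' so D95%(PGTV) equals the prescription — emulating a clinically
#' acceptable SRS plan.
#'
#' @param case a `plan_case`.
#' @param halfdose_mm fall-off half-dose distance (mm).
#' @param hotspot_frac objective level inside the PGTV as a fraction of the
#'   prescription.
#' @param mimic_config optimizer settings, see [mimic_config()].
#' @param D optional precomputed `deposition_matrix` for this case.
#' @return A `voxel_grid` of dose in Gy.
#' @export
reference_dose <- function(case, halfdose_mm = 5, hotspot_frac = 1.05,
                           mimic_config = NULL, D = NULL) {
  cfg <- mimic_config %||% doseloop::mimic_config()
  if (is.null(D)) {
    beams <- auto_configure_beams(case, n_beams = cfg$n_beams,
                                  spacing_deg = cfg$spacing_deg,
                                  beamlet_size = cfg$beamlet_size)
    D <- build_deposition_matrix(case, beams, cfg$kernel)
  }
  rx <- case$prescription_dose
  dist <- distance_transform(case$structures$PGTV)
  target <- hotspot_frac * rx * 0.5^(dist / halfdose_mm)
  target[case$structures$Head$data == 0] <- 0
  tgrid <- grid_like(case$ct, array(target, dim(case$ct$data)))
  w <- importance_weights(case)
  fl <- optimize_fluence(D, tgrid, w, max_iter = cfg$max_iter,
                         tol = cfg$tol)
  dose <- compute_dose(D, fl$fluence)
  d95 <- dose_at_volume(dose, case$structures$PGTV, 95)
  if (d95 <= 0) stop("reference optimization produced no target dose")
  grid_like(dose, dose$data * (rx / d95))
}

#' Spatial importance weights for fluence optimization
#'
#' Default weighting: PGTV x10, a 20 mm shell around it x3, everywhere
#' else x1.
#'
#' @param case a `plan_case`.
#' @param w_pgtv,w_shell,w_else weights.
#' @param shell_mm shell width around the PGTV (mm).
#' @return A numeric vector over voxels (array order).
#' @export
importance_weights <- function(case, w_pgtv = 10, w_shell = 3, w_else = 1,
                               shell_mm = 20) {
  dist <- distance_transform(case$structures$PGTV)
  w <- rep(w_else, length(dist))
  w[dist <= shell_mm] <- w_shell
  w[case$structures$PGTV$data != 0] <- w_pgtv
  w
}

#' Generate a dataset of phantom cases
#'
#' Draws `n_small` cases with target volumes below the 20 cc grouping
#' threshold and `n_large` above it, with independent geometry per case.
#'
#' @param n_small,n_large case counts per size group.
#' @param seed master seed; per-case seeds are derived from it.
#' @param spec template [phantom_spec()] (centre and radius are redrawn).
#' @param small_volume_cc,large_volume_cc uniform sampling ranges (cc) for
#'   the target volume in each group.
#' @param ... passed to [generate_case()] (e.g. `compute_reference`).
#' @return A list of `plan_case` objects (small group first).
#' @export
make_dataset <- function(n_small, n_large, seed = 1L,
                         spec = phantom_spec(),
                         small_volume_cc = c(2, 18),
                         large_volume_cc = c(23, 58), ...) {
  stopifnot(n_small >= 0, n_large >= 0)
  n <- n_small + n_large
  if (n == 0L) return(list())
  set.seed(seed)
  case_seeds <- sample.int(.Machine$integer.max, n)
  vols <- c(stats::runif(n_small, small_volume_cc[1], small_volume_cc[2]),
            stats::runif(n_large, large_volume_cc[1], large_volume_cc[2]))
  lapply(seq_len(n), function(i) {
    s <- spec
    s$seed <- case_seeds[i]
    s$pgtv_center <- "random"
    s$pgtv_radius <- (3 * vols[i] * 1000 / (4 * pi))^(1 / 3)
    generate_case(s, ...)
  })
}

#' Export a case to NIfTI volumes plus a JSON sidecar
#'
#' Writes `ct.nii.gz`, one `mask_<name>.nii.gz` per structure, optionally
#' `dose.nii.gz`, and `case.json` (prescription, group, provenance).
#'
#' @param case a `plan_case`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_case <- function(case, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_grid_nifti(case$ct, file.path(dir, "ct.nii.gz"))
  for (nm in names(case$structures))
    write_grid_nifti(case$structures[[nm]],
                     file.path(dir, paste0("mask_", nm, ".nii.gz")))
  if (!is.null(case$reference_dose))
    write_grid_nifti(case$reference_dose, file.path(dir, "dose.nii.gz"))
  side <- list(prescription_dose = case$prescription_dose,
               fractions = case$fractions, size_group = case$size_group,
               pgtv_volume_cc = mask_volume_cc(case$structures$PGTV),
               structures = names(case$structures), meta = case$meta)
  jsonlite::write_json(side, file.path(dir, "case.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a case previously written by [write_case()]
#'
#' @param dir case directory.
#' @return A `plan_case`.
#' @export
read_case <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "case.json"),
                              simplifyVector = TRUE)
  ct <- read_grid_nifti(file.path(dir, "ct.nii.gz"))
  structures <- lapply(side$structures, function(nm)
    read_grid_nifti(file.path(dir, paste0("mask_", nm, ".nii.gz"))))
  names(structures) <- side$structures
  dose_path <- file.path(dir, "dose.nii.gz")
  ref <- if (file.exists(dose_path)) read_grid_nifti(dose_path) else NULL
  plan_case(ct, structures, side$prescription_dose, side$fractions,
            reference_dose = ref, meta = as.list(side$meta))
}
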
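# Shared fixtures, memoised so expensive phantoms build once per run.
options(doseloop.verbose = FALSE)

.fixture_env <- new.env()

memo <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

# small phantom spec: coarse 5 mm grid keeps engine work light
tiny_spec <- function(seed = 11, pgtv_center = c(25, -15, 0),
                      pgtv_radius = 10, ...) {
  phantom_spec(grid_dim = c(48, 48, 16), spacing = c(5, 5, 5),
               pgtv_center = pgtv_center, pgtv_radius = pgtv_radius,
               noise_sd = 0, seed = seed, ...)
}

tiny_case <- function() {
  memo("tiny_case", generate_case(tiny_spec(), compute_reference = FALSE))
}

tiny_case_ref <- function() {
  memo("tiny_case_ref", generate_case(tiny_spec()))
}

tiny_matrix <- function() {
  memo("tiny_matrix", {
    case <- tiny_case_ref()
    beams <- auto_configure_beams(case)
    build_deposition_matrix(case, beams)
  })
}

# uniform spherical dose distribution on a small grid
sphere_dose_case <- function(value = 30, radius = 12, n = 24,
                             spacing = 2.5) {
  g <- voxel_grid(array(0, c(n, n, n)), rep(spacing, 3),
                  rep(-(n - 1) / 2 * spacing, 3))
  cc <- voxel_coords(g)
  inside <- colSums((t(cc))^2) <= radius^2
  mask <- grid_like(g, array(as.numeric(inside), dim(g$data)))
  dose <- grid_like(g, array(value * inside, dim(g$data)))
  list(grid = g, mask = mask, dose = dose)
}
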
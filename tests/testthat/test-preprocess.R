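test_that("CT normalization maps the clip window onto [-1, 1]", {
  x <- c(-500, -200, 50, 300, 1000)
  y <- normalize_ct(array(x, c(5, 1, 1)))
  expect_equal(as.numeric(y), c(-1, -1, 0, 1, 1))
  # monotone on a random sample
  set.seed(1)
  xs <- sort(runif(100, -1200, 1500))
  expect_true(all(diff(normalize_ct(array(xs, c(100, 1, 1)))) >= 0))
})

test_that("dose normalization is an exact affine round trip", {
  spec <- normalization_spec()
  expect_equal(as.numeric(normalize_dose(array(0, c(1, 1, 1)), spec)), -1)
  expect_equal(as.numeric(normalize_dose(array(spec$dose_ref_max,
                                               c(1, 1, 1)), spec)), 1)
  set.seed(2)
  d <- array(runif(4^3, 0, spec$dose_ref_max), c(4, 4, 4))
  back <- denormalize_dose(normalize_dose(d, spec), spec)
  expect_lt(max(abs(back - d)), 1e-6 * spec$dose_ref_max)
  expect_error(normalize_dose(array(-1, c(1, 1, 1))), "non-negative")
})

test_that("doses above the normalization ceiling are clipped, with log", {
  spec <- normalization_spec(dose_ref_max = 10)
  withr::local_options(doseloop.verbose = TRUE)
  expect_message(y <- normalize_dose(array(c(5, 20), c(2, 1, 1)), spec),
                 "ceiling")
  expect_equal(as.numeric(y), c(0, 1))
})

test_that("align_case is the identity on already-aligned cases", {
  case <- tiny_case()
  expect_identical(align_case(case)$structures$PGTV$data,
                   case$structures$PGTV$data)
})

test_that("align_case resamples a pitch-shifted dose back onto the CT", {
  case <- tiny_case()
  set.seed(4)
  d <- dim(case$ct$data)
  vals <- array(runif(prod(d)), d)
  # dose grid shifted by exactly one voxel pitch along x
  case$reference_dose <- voxel_grid(vals, case$ct$spacing,
                                    case$ct$origin + c(case$ct$spacing[1],
                                                       0, 0))
  aligned <- align_case(case)
  expect_equal(aligned$reference_dose$data[2:d[1], , ],
               vals[1:(d[1] - 1), , ], tolerance = 1e-10)
  # no overlap at all is an error
  case$reference_dose <- voxel_grid(vals, case$ct$spacing,
                                    case$ct$origin + c(1e5, 0, 0))
  expect_error(align_case(case), "no spatial overlap")
})

test_that("label encoding gives PGTV priority and decodes exactly", {
  case <- tiny_case()
  enc <- encode_structures(case$structures)
  expect_identical(unname(enc$code_map[["Head"]]), 1L)
  expect_identical(unname(enc$code_map[["PGTV"]]),
                   length(enc$code_map))
  dec <- decode_structures(enc$labels, enc$code_map)
  expect_identical(dec$PGTV, case$structures$PGTV$data != 0)
  expect_identical(dec$Head, case$structures$Head$data != 0)
  # painting semantics: each voxel carries its highest-priority structure
  # (the lens sits inside the eye, so nested voxels belong to the lens)
  nms <- names(enc$code_map)
  for (i in setdiff(seq_along(nms), c(1, length(nms)))) {
    want <- case$structures[[nms[i]]]$data != 0
    for (j in seq(i + 1, length(nms)))
      want <- want & !(case$structures[[nms[j]]]$data != 0)
    expect_identical(dec[[nms[i]]], want, info = nms[i])
  }
  # the one-hot encoding keeps overlapping structures independent
  tc1 <- crop_to_shape(case, shape = c(32, 32, 16), spacing = c(5, 5, 5),
                       one_hot = TRUE)
  ch <- match("PGTV", tc1$meta$channels)
  expect_equal(sum(tc1$inputs[, , , ch] != 0),
               sum(case$structures$PGTV$data != 0))
})

test_that("cropping centres the PGTV, pads, and restores exactly", {
  case <- tiny_case_ref()
  tc <- crop_to_shape(case, shape = c(16, 16, 16), spacing = c(5, 5, 5))
  expect_identical(dim(tc$inputs), c(16L, 16L, 16L, 2L))
  expect_true(all(tc$inputs >= -1 - 1e-12 & tc$inputs <= 1 + 1e-12))
  expect_true(all(tc$target >= -1 - 1e-12 & tc$target <= 1 + 1e-12))
  # PGTV centroid lands mid-window
  lab <- tc$inputs[, , , 1]
  pgtv_code <- tc$meta$code_map[["PGTV"]]
  pgtv_lab <- 2 * pgtv_code / tc$meta$n_codes - 1
  idx <- which(abs(lab - pgtv_lab) < 1e-9, arr.ind = TRUE)
  expect_gt(nrow(idx), 0)
  expect_true(all(abs(colMeans(idx) - 8.5) < 2))
  # identity-spacing crop restores reference dose exactly in the window
  dose_win <- denormalize_dose(tc$target, tc$meta$norm)
  restored <- uncrop_to_ct(dose_win, tc$meta)
  w <- tc$meta$window
  i0 <- round((w$origin - case$ct$origin) / case$ct$spacing)
  sel_x <- pmax(1, i0[1] + 1):min(dim(case$ct$data)[1], i0[1] + 16)
  expect_equal(restored$data[sel_x, i0[2] + 8, i0[3] + 8],
               case$reference_dose$data[sel_x, i0[2] + 8, i0[3] + 8],
               tolerance = 1e-8)
})

test_that("a corner target is padded rather than erroring", {
  spec <- tiny_spec(pgtv_center = c(-40, 28, 12), pgtv_radius = 8)
  case <- generate_case(spec, compute_reference = FALSE)
  tc <- crop_to_shape(case, shape = c(32, 32, 16), spacing = c(5, 5, 5))
  expect_identical(dim(tc$inputs)[1:3], c(32L, 32L, 16L))
  pgtv_code <- tc$meta$code_map[["PGTV"]]
  pgtv_lab <- 2 * pgtv_code / tc$meta$n_codes - 1
  n_in_window <- sum(abs(tc$inputs[, , , 1] - pgtv_lab) < 1e-9)
  expect_equal(n_in_window, sum(case$structures$PGTV$data != 0))
})

test_that("group assignment is inclusive at exactly 20 cc", {
  g <- voxel_grid(array(0, c(20, 20, 10)), c(2.5, 2.5, 2.5), c(0, 0, 0))
  # voxel volume 15.625 mm^3; 1280 voxels = exactly 20 cc
  mk <- function(n_vox) {
    m <- grid_like(g)
    m$data[seq_len(n_vox)] <- 1
    plan_case(g, list(PGTV = m, Head = grid_like(g, array(1, dim(g$data)))))
  }
  expect_identical(assign_group(mk(1280)), "small")
  expect_identical(assign_group(mk(1281)), "large")
})
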
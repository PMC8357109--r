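test_that("configuration validation enforces plane order, fixed top and sign constraints", {
  expect_error(
    deformation_config(top = pivotal_plane(10), middle = pivotal_plane(37),
                       lower = pivotal_plane(16)),
    "lower\\$z < middle\\$z < top\\$z"
  )
  expect_error(
    deformation_config(top = pivotal_plane(60, dy = 1),
                       middle = pivotal_plane(37), lower = pivotal_plane(16)),
    "exactly 0"
  )
  expect_error(pivotal_plane(10, dy = -1), ">= 0")
  expect_error(pivotal_plane(10, ys = -20, yc = -10), "smaller")
})

test_that("zero parameters give a bit-exact identity deformation", {
  mesh <- generate_airway(default_tube_spec())
  out <- deform_mesh(mesh, default_config())
  expect_identical(out$vertices, mesh$vertices)
  expect_identical(out$faces, mesh$faces)
})

test_that("the displacement field is identically zero when all parameters vanish", {
  mesh <- generate_airway(default_tube_spec())
  field <- build_displacement_field(default_config(), mesh = mesh)
  set.seed(5)
  pts <- cbind(runif(1000, -12, 12), runif(1000, -8, 8), runif(1000, -5, 105))
  expect_identical(max(abs(field(pts))), 0)
})

test_that("the fixed regions are exactly fixed: above the top plane and on the spine side", {
  mesh <- generate_airway(default_tube_spec())
  cfg <- default_config(dy_m = 4, dx_m = 1, dy_l = 6, dx_l = 2)
  field <- build_displacement_field(cfg, mesh = mesh)

  set.seed(6)
  above <- cbind(runif(500, -12, 12), runif(500, -8, 8), runif(500, 60, 110))
  expect_identical(max(abs(field(above))), 0)

  spine <- cbind(runif(500, -12, 12), runif(500, 6, 12), runif(500, 0, 60))
  expect_identical(max(abs(field(spine))), 0)

  deformed <- deform_mesh(mesh, cfg)
  fixed <- mesh$vertices[, 3] >= 60 | mesh$vertices[, 2] >= 6
  expect_identical(deformed$vertices[fixed, ], mesh$vertices[fixed, ])
})

test_that("the prescribed dY is achieved exactly at the anterior control point", {
  mesh <- generate_airway(default_tube_spec())
  cfg <- default_config(dy_m = 4, dx_m = 1)
  field <- build_displacement_field(cfg, mesh = mesh)
  # anterior extreme on the mid-sagittal line of the middle plane
  d <- field(cbind(0, -6, 37))
  expect_equal(d[1, 2], -4, tolerance = 1e-12)
  expect_equal(d[1, 1], 0, tolerance = 1e-12)
  expect_identical(d[1, 3], 0)
})

test_that("deformation enlarges sections by the prescribed widths at the controlled planes", {
  mesh <- generate_airway(default_tube_spec())
  cfg <- default_config(dy_m = 4, dx_m = 1, dy_l = 6, dx_l = 2)
  deformed <- deform_mesh(mesh, cfg)

  cmp_m <- compare_sections(slice_mesh(mesh, 37), slice_mesh(deformed, 37))
  expect_equal(cmp_m$achieved_dY, 4, tolerance = 0.05)
  expect_equal(cmp_m$achieved_dX_total, 2, tolerance = 0.05)

  cmp_l <- compare_sections(slice_mesh(mesh, 16), slice_mesh(deformed, 16))
  expect_equal(cmp_l$achieved_dY, 6, tolerance = 0.05)
  expect_equal(cmp_l$achieved_dX_total, 4, tolerance = 0.05)
})

test_that("first derivatives of the field are continuous across planes and the spine boundary", {
  mesh <- generate_airway(default_tube_spec())
  cfg <- default_config(dy_m = 4, dx_m = 1, dy_l = 6, dx_l = 2)
  field <- build_displacement_field(cfg, mesh = mesh)

  # across the pivotal planes and the interior spline knots, in z
  max_jump <- 0
  for (z0 in c(16, 26.5, 37, 48.5, 60)) {
    for (xy in list(c(0, -6), c(5, -3), c(-8, 2), c(9, 0))) {
      for (comp in 1:2) {
        f <- function(z) field(cbind(xy[1], xy[2], z))[, comp]
        jump <- abs(one_sided_deriv(f, z0, -1) - one_sided_deriv(f, z0, +1))
        max_jump <- max(max_jump, jump)
      }
    }
  }
  expect_lt(max_jump, 1e-3)

  # across the spine-side boundary, in y
  max_jump_y <- 0
  for (z0 in c(20, 37, 50)) {
    for (x0 in c(-7, 0, 7)) {
      for (comp in 1:2) {
        f <- function(y) field(cbind(x0, y, z0))[, comp]
        jump <- abs(one_sided_deriv(f, 6, -1) - one_sided_deriv(f, 6, +1))
        max_jump_y <- max(max_jump_y, jump)
      }
    }
  }
  expect_lt(max_jump_y, 1e-3)

  # across the mid-sagittal line, in x (lateral term changes sign there)
  f <- function(x) field(cbind(x, -3, 37))[, 1]
  expect_lt(abs(one_sided_deriv(f, 0, -1) - one_sided_deriv(f, 0, +1)), 1e-3)
})

test_that("non-negative parameters never shrink any cross-section", {
  mesh <- generate_airway(default_tube_spec())
  cfg <- default_config(dy_m = 3, dx_m = 1.5, dy_l = 5, dx_l = 0.5)
  deformed <- deform_mesh(mesh, cfg)
  for (z in seq(16, 60, by = 4)) {
    expect_gte(slice_mesh(deformed, z)$area, slice_mesh(mesh, z)$area - 1e-9)
  }
})

test_that("displacement scales linearly with the deformation parameters", {
  mesh <- generate_airway(default_tube_spec())
  full <- build_displacement_field(
    default_config(dy_m = 4, dx_m = 2, dy_l = 6, dx_l = 3), mesh = mesh)
  half <- build_displacement_field(
    default_config(dy_m = 2, dx_m = 1, dy_l = 3, dx_l = 1.5), mesh = mesh)
  set.seed(8)
  pts <- cbind(runif(400, -10, 10), runif(400, -6, 6), runif(400, 0, 70))
  expect_equal(full(pts), 2 * half(pts), tolerance = 1e-12)
})

test_that("plane anatomy estimation matches the analytic tube", {
  mesh <- generate_airway(default_tube_spec(angular_resolution = 128L))
  an <- estimate_plane_anatomy(mesh, 40)
  expect_equal(an$ys, 6, tolerance = 1e-6)
  expect_equal(an$yc, -6, tolerance = 1e-6)
  expect_equal(an$x_c, 0, tolerance = 1e-9)
  expect_equal(an$w_half, 10, tolerance = 1e-6)
  expect_equal(an$y_widest, 0, tolerance = 1e-9)

  # circle: depth equals width
  circ <- generate_airway(airway_spec(a = 6, b = 6, angular_resolution = 64L))
  an2 <- estimate_plane_anatomy(circ, 40)
  expect_equal(an2$ys - an2$yc, 2 * an2$w_half, tolerance = 1e-9)
})

test_that("multi-contour slices take anatomy from the largest contour", {
  spec <- default_tube_spec(nasal_radii = c(2, 4), nasal_x_offset = 7)
  mesh <- generate_airway(spec)
  an <- estimate_plane_anatomy(mesh, 90) # two nasal tubes, radii 2 and 4
  expect_equal(an$w_half, 4, tolerance = 0.05)
  expect_equal(an$x_c, 7, tolerance = 1e-6)
  expect_equal(an$ys, 4, tolerance = 0.05)
  expect_error(estimate_plane_anatomy(mesh, 500), "no airway contour")
})

test_that("a mesh entirely above the top plane is returned unchanged with a warning", {
  mesh <- generate_airway(default_tube_spec())
  cfg <- deformation_config(
    top = pivotal_plane(-10), middle = pivotal_plane(-20, dy = 2),
    lower = pivotal_plane(-30, dy = 1)
  )
  expect_warning(out <- deform_mesh(mesh, cfg), "unchanged")
  expect_identical(out$vertices, mesh$vertices)
})

test_that("deformation configs round-trip through JSON", {
  cfg <- deformation_config(
    top = pivotal_plane(-566, label = "fixed"),
    middle = pivotal_plane(-587, dy = 4, dx_half = 1, ys = -11.76, yc = -20,
                           label = "soft palate tip"),
    lower = pivotal_plane(-610, dy = 6, dx_half = 2, ys = -7.78,
                          label = "nasal confluence")
  )
  f <- withr::local_tempfile(fileext = ".json")
  write_deformation_config(cfg, f)
  back <- read_deformation_config(f)
  expect_equal(back, cfg)
})

test_that("the surgeon's total widening maps to the half-to-peak parameter", {
  expect_identical(lateral_half_enlargement(2), 1)
  expect_identical(lateral_half_enlargement(4), 2)
  expect_error(lateral_half_enlargement(-1), "non-negative")
})
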
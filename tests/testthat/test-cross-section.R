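test_that("slicing the elliptical tube reproduces the analytic area within 1%", {
  spec <- default_tube_spec()
  mesh <- generate_airway(spec)
  sec <- slice_mesh(mesh, 40)
  expect_equal(sec$area, 188.4956, tolerance = 0.01 * 188.4956)
  expect_equal(sec$depth_y, 12, tolerance = 0.01)
  expect_equal(sec$ys, 6, tolerance = 1e-9)
  expect_equal(sec$yc, -6, tolerance = 1e-9)
})

test_that("a plane missing the mesh gives an empty section with area 0", {
  mesh <- generate_airway(default_tube_spec())
  sec <- slice_mesh(mesh, 500)
  expect_length(sec$contours, 0L)
  expect_identical(sec$area, 0)
})

test_that("slice metrics are invariant to facet order", {
  mesh <- generate_airway(default_tube_spec(angular_resolution = 32L))
  set.seed(11)
  perm <- triangle_mesh(mesh$vertices,
                        mesh$faces[sample(nrow(mesh$faces)), ])
  for (z in c(25, 55)) {
    a <- slice_mesh(mesh, z)
    b <- slice_mesh(perm, z)
    expect_lt(abs(a$area - b$area), 1e-9)
    expect_lt(abs(a$ys - b$ys), 1e-9)
    expect_lt(abs(a$yc - b$yc), 1e-9)
    expect_lt(abs(a$width_x - b$width_x), 1e-9)
  }
})

test_that("slice area matches a Monte-Carlo estimate on a convex section", {
  spec <- default_tube_spec()
  mesh <- generate_airway(spec)
  sec <- slice_mesh(mesh, 40)
  poly <- sec$contours[[1L]]
  set.seed(101)
  n <- 1e6
  px <- stats::runif(n, min(poly[, 1]), max(poly[, 1]))
  py <- stats::runif(n, min(poly[, 2]), max(poly[, 2]))
  # ray-crossing point-in-polygon, vectorized over test points
  inside <- rep(FALSE, n)
  np <- nrow(poly) - 1L
  for (i in seq_len(np)) {
    x1 <- poly[i, 1]; y1 <- poly[i, 2]
    x2 <- poly[i + 1L, 1]; y2 <- poly[i + 1L, 2]
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
  }
  box <- diff(range(poly[, 1])) * diff(range(poly[, 2]))
  mc_area <- mean(inside) * box
  expect_lt(abs(mc_area - sec$area) / sec$area, 0.005)
})

test_that("depth equals twice the anteroposterior semi-axis along the tube", {
  spec <- airway_spec(a = 9, b = function(z) 6 - 0.02 * z,
                      angular_resolution = 128L)
  mesh <- generate_airway(spec)
  for (z in c(15, 45, 75)) {
    expect_equal(slice_mesh(mesh, z)$depth_y, 2 * spec$b(z), tolerance = 0.01)
  }
})

test_that("comparing identical sections gives zero change and unit area ratio", {
  sec <- slice_mesh(generate_airway(default_tube_spec()), 40)
  cmp <- compare_sections(sec, sec)
  expect_identical(cmp$achieved_dY, 0)
  expect_identical(cmp$achieved_dX_total, 0)
  expect_identical(cmp$area_ratio, 1)
})

test_that("section comparison reproduces analytic ellipse arithmetic", {
  pre <- analytic_cross_section(airway_spec(a = 10, b = 6), 10)
  post <- analytic_cross_section(airway_spec(a = 11, b = 8), 10)
  cmp <- compare_sections(pre, post)
  expect_equal(cmp$achieved_dX_total, 2)
  expect_equal(cmp$achieved_dY, 4)
  expect_equal(cmp$area_ratio, 88 / 60)
})

test_that("sections on different planes refuse comparison", {
  spec <- default_tube_spec()
  expect_error(
    compare_sections(analytic_cross_section(spec, 10),
                     analytic_cross_section(spec, 20)),
    "different planes"
  )
})

test_that("export writes blank-line-separated x y blocks that re-parse exactly", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0, 0))
  sec1 <- cross_section(5, list(sq))
  f <- withr::local_tempfile(fileext = ".dat")
  export_section(sec1, f)
  lines <- readLines(f)
  expect_length(lines, 5L) # closure point repeated

  two <- cross_section(5, list(sq, sq + 3))
  f2 <- withr::local_tempfile(fileext = ".dat")
  export_section(two, f2)
  lines2 <- readLines(f2)
  expect_identical(sum(lines2 == ""), 1L)

  blocks <- split(lines2[lines2 != ""], cumsum(lines2 == "")[lines2 != ""])
  parsed <- lapply(blocks, function(b) {
    matrix(scan(text = b, quiet = TRUE), ncol = 2, byrow = TRUE)
  })
  expect_equal(unname(parsed[[1L]]), unname(sq))
  expect_equal(unname(parsed[[2L]]), unname(sq + 3))

  expect_error(export_section(cross_section(1, list()), tempfile()), "empty")
})

test_that("multi-contour sections report summed area and global extrema", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0, 0))
  sec <- cross_section(0, list(sq, sq + 5))
  expect_equal(sec$area, 2)
  expect_equal(sec$width_x, 6)
  expect_equal(sec$ys, 6)
  expect_identical(nrow(sec$per_contour), 2L)
})

test_that("slicing a non-watertight mesh reports the open chains", {
  mesh <- generate_airway(default_tube_spec(angular_resolution = 16L))
  holed <- triangle_mesh(mesh$vertices, mesh$faces[-10L, , drop = FALSE])
  zs <- mesh$vertices[mesh$faces[10L, ], 3]
  zmid <- mean(range(zs))
  expect_error(slice_mesh(holed, zmid), "open chains")
})
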
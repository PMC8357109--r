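test_that("ASCII STL of a tetrahedron reads back with 4 facets and 4 shared vertices", {
  tet <- make_tetra()
  f <- withr::local_tempfile(fileext = ".stl")
  write_stl(tet, f, "ascii")
  lines <- readLines(f)
  expect_length(grep("facet normal", lines), 4L)
  expect_length(grep("endfacet", lines), 4L)

  back <- read_stl(f)
  expect_identical(nrow(back$faces), 4L)
  expect_identical(nrow(back$vertices), 4L)
  expect_identical(attr(back, "source_dialect"), "ascii")
  key <- function(v) sort(apply(round(v, 9), 1, paste, collapse = ","))
  expect_identical(key(back$vertices), key(tet$vertices))
})

test_that("both STL dialects round-trip facet count exactly and coordinates to 1e-6 mm", {
  tet <- make_tetra()
  for (dialect in c("ascii", "binary")) {
    f <- withr::local_tempfile(fileext = ".stl")
    write_stl(tet, f, dialect)
    back <- read_stl(f)
    expect_identical(nrow(back$faces), nrow(tet$faces))
    key <- function(v) do.call(order, as.data.frame(v))
    a <- back$vertices[key(back$vertices), ]
    b <- tet$vertices[key(tet$vertices), ]
    expect_lt(max(abs(a - b)), 1e-6)
  }
})

test_that("a generated airway survives write/read in both dialects with topology intact", {
  mesh <- generate_airway(default_tube_spec(angular_resolution = 32L,
                                            axial_resolution = 0.25))
  for (dialect in c("ascii", "binary")) {
    f <- withr::local_tempfile(fileext = ".stl")
    write_stl(mesh, f, dialect)
    back <- read_stl(f)
    expect_identical(nrow(back$faces), nrow(mesh$faces))
    expect_true(is_closed_mesh(back))
    expect_equal(slice_mesh(back, 40)$area, slice_mesh(mesh, 40)$area,
                 tolerance = 1e-4)
  }
})

test_that("malformed STL inputs raise format errors naming the problem location", {
  mesh <- generate_airway(default_tube_spec(angular_resolution = 16L))
  f <- withr::local_tempfile(fileext = ".stl")
  write_stl(mesh, f, "binary")
  raw <- readBin(f, "raw", file.size(f))

  # declared facet count exceeds remaining bytes
  trunc <- withr::local_tempfile(fileext = ".stl")
  writeBin(raw[seq_len(500)], trunc)
  expect_error(read_stl(trunc), "bytes")

  # missing file
  expect_error(read_stl(file.path(tempdir(), "no-such.stl")), "not found")

  # ascii with a broken vertex line
  fa <- withr::local_tempfile(fileext = ".stl")
  writeLines(c("solid x", " facet normal 0 0 1", "  outer loop",
               "   vertex 0 0 0", "   vertex 1 0 oops", "   vertex 0 1 0",
               "  endloop", " endfacet", "endsolid x"), fa)
  expect_error(read_stl(fa), "format error")
})

test_that("writing an empty mesh is refused", {
  tet <- make_tetra()
  tet$faces <- tet$faces[0, , drop = FALSE]
  expect_error(write_stl(tet, tempfile(), "ascii"), "empty mesh")
})

test_that("validate_mesh reports degenerate facets and the bounding box without mutating its input", {
  tet <- make_tetra()
  rep0 <- validate_mesh(tet)
  expect_identical(rep0$facet_count, 4L)
  expect_identical(rep0$degenerate_facets, 0L)
  expect_equal(unname(rep0$bounding_box["min", ]), c(0, 0, 0))
  expect_equal(unname(rep0$bounding_box["max", ]), c(1, 1, 1))

  # add one zero-area facet (repeated geometric point via distinct indices)
  bad <- triangle_mesh(
    rbind(tet$vertices, c(0.5, 0.5, 0.5), c(0.5, 0.5, 0.5)),
    rbind(tet$faces, c(5L, 6L, 1L))
  )
  expect_identical(validate_mesh(bad)$degenerate_facets, 1L)

  before <- serialize(tet, NULL)
  invisible(validate_mesh(tet))
  expect_identical(serialize(tet, NULL), before)
})

test_that("mesh report serializes to JSON with bounding box fields", {
  rep0 <- validate_mesh(make_tetra())
  j <- jsonlite::fromJSON(mesh_report_json(rep0))
  expect_identical(j$facet_count, 4L)
  expect_equal(j$bounding_box$max$z, 1)
})

test_that("smoothing keeps topology, is the identity at 0 iterations, and contracts radial noise", {
  noisy <- make_uv_sphere(r = 10, noise_amp = 0.2, seed = 3L)
  expect_identical(smooth_mesh(noisy, 0L)$vertices, noisy$vertices)

  sm <- smooth_mesh(noisy, 10L, strength = 0.6)
  expect_identical(dim(sm$vertices), dim(noisy$vertices))
  expect_identical(sm$faces, noisy$faces)

  dev <- function(m) mean(abs(sqrt(rowSums(m$vertices^2)) - 10))
  expect_lt(dev(sm), dev(noisy))
})

test_that("smoothing a clean elliptical tube changes cross-section areas by under 1%", {
  tube <- generate_airway(default_tube_spec())
  sm <- smooth_mesh(tube, 10L, strength = 0.6)
  for (z in c(20, 40, 60)) {
    a0 <- slice_mesh(tube, z)$area
    a1 <- slice_mesh(sm, z)$area
    expect_lt(abs(a1 - a0) / a0, 0.01)
  }
})

test_that("smoothing rejects out-of-range strength", {
  expect_error(smooth_mesh(make_tetra(), 1L, strength = 1.5), "\\[0, 1\\]")
  expect_error(smooth_mesh(make_tetra(), -1L), "non-negative")
})
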
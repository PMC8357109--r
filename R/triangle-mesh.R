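#' Triangle surface mesh in the patient frame
#'
#' Light container for a triangulated airway surface. Coordinates are in
#' millimetres in the CT-derived patient frame: x runs right to left, y from
#' the face to the back (so the spine side is +y), and z from the foot to the
#' head. Vertices are shared between facets; per-facet normals are optional
#' and are recomputed from vertex winding whenever the mesh is written out.
#'
#' @param vertices numeric matrix, one row per vertex, columns x, y, z (mm).
#' @param faces integer matrix, one row per facet, three vertex indices
#'   (1-based).
#' @param normals optional numeric matrix of per-facet unit normals.
#' @return An object of class `triangle_mesh` with elements `vertices`,
#'   `faces` and (optionally) `normals`.
#' @examples
#' tet <- triangle_mesh(
#'   vertices = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
#'   faces = rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3))
#' )
#' tet
#' @export
triangle_mesh <- function(vertices, faces, normals = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) {
    stop("`vertices` must have three columns (x, y, z in mm)", call. = FALSE)
  }
  if (ncol(faces) != 3L) {
    stop("`faces` must have three columns of vertex indices", call. = FALSE)
  }
  if (nrow(faces) < 1L) {
    stop("empty mesh: at least one facet is required", call. = FALSE)
  }
  if (!all(is.finite(vertices))) {
    stop("all vertex coordinates must be finite", call. = FALSE)
  }
  if (min(faces) < 1L || max(faces) > nrow(vertices)) {
    stop("facet indices out of range", call. = FALSE)
  }
  if (any(faces[, 1L] == faces[, 2L] | faces[, 2L] == faces[, 3L] |
            faces[, 1L] == faces[, 3L])) {
    stop("a facet repeats a vertex index", call. = FALSE)
  }
  dimnames(vertices) <- list(NULL, c("x", "y", "z"))
  dimnames(faces) <- NULL
  out <- list(vertices = vertices, faces = faces)
  if (!is.null(normals)) {
    normals <- as.matrix(normals)
    storage.mode(normals) <- "double"
    stopifnot(nrow(normals) == nrow(faces), ncol(normals) == 3L)
    out$normals <- normals
  }
  structure(out, class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  bb <- mesh_bounding_box(x)
  cat(sprintf(
    "<triangle_mesh> %d vertices, %d facets\n", nrow(x$vertices), nrow(x$faces)
  ))
  cat(sprintf(
    "  bounding box (mm): x [%.3f, %.3f]  y [%.3f, %.3f]  z [%.3f, %.3f]\n",
    bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]
  ))
  invisible(x)
}

#' Axis-aligned bounding box of a mesh
#'
#' @param mesh a [triangle_mesh()].
#' @return 2 x 3 matrix with rows `min`, `max` and columns x, y, z (mm).
#' @export
mesh_bounding_box <- function(mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  rbind(
    min = apply(mesh$vertices, 2L, min),
    max = apply(mesh$vertices, 2L, max)
  )
}

# Per-facet normals from vertex winding (right-hand rule); zero-area facets
# get a zero vector.
.facet_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  e2 <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  n <- cbind(
    e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
    e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
    e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L]
  )
  len <- sqrt(rowSums(n^2))
  ok <- len > 0
  n[ok, ] <- n[ok, , drop = FALSE] / len[ok]
  n[!ok, ] <- 0
  n
}

# Facet areas in mm^2.
.facet_areas <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  e2 <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  n <- cbind(
    e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
    e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
    e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L]
  )
  0.5 * sqrt(rowSums(n^2))
}

# Undirected edge list as a 2-column integer matrix (one row per facet edge,
# smaller index first; duplicates retained so incidence can be counted).
.mesh_edge_instances <- function(mesh) {
  f <- mesh$faces
  e <- rbind(
    f[, c(1L, 2L), drop = FALSE],
    f[, c(2L, 3L), drop = FALSE],
    f[, c(3L, 1L), drop = FALSE]
  )
  cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
}

#' Check that every edge of a mesh is shared by exactly two facets
#'
#' A closed (watertight) triangulated surface has every undirected edge
#' incident to exactly two facets. Multiple disjoint closed components
#' satisfy the test too.
#'
#' @param mesh a [triangle_mesh()].
#' @return `TRUE` if closed, `FALSE` otherwise.
#' @export
is_closed_mesh <- function(mesh) {
  e <- .mesh_edge_instances(mesh)
  key <- paste(e[, 1L], e[, 2L])
  all(tabulate(factor(key)) == 2L)
}

# Merge vertices closer than `tol` (grid snap) and reindex facets. Facets
# that collapse to a repeated index are dropped.
.merge_vertices <- function(vertices, faces, tol = 1e-6) {
  key <- paste(
    round(vertices[, 1L] / tol),
    round(vertices[, 2L] / tol),
    round(vertices[, 3L] / tol)
  )
  first <- !duplicated(key)
  map <- match(key, key[first])
  verts <- vertices[first, , drop = FALSE]
  f <- matrix(map[faces], ncol = 3L)
  bad <- f[, 1L] == f[, 2L] | f[, 2L] == f[, 3L] | f[, 1L] == f[, 3L]
  if (any(bad)) {
    warning(sprintf(
      "dropped %d facet(s) degenerate after vertex merging", sum(bad)
    ), call. = FALSE)
    f <- f[!bad, , drop = FALSE]
  }
  list(vertices = verts, faces = f)
}
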
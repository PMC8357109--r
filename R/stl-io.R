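#' Read an STL surface mesh
#'
#' Reads ASCII or binary stereolithography files, auto-detecting the dialect.
#' STL stores each facet's three corners independently; corners closer than
#' the merge tolerance (1e-6 mm, grid snap) are merged into shared vertex
#' indices so that connectivity-based operations (smoothing, slicing) work.
#'
#' @param path path to an STL file.
#' @return A [triangle_mesh()]. The attribute `source_dialect` records whether
#'   the file was `"ascii"` or `"binary"`.
#' @seealso [write_stl()]
#' @export
read_stl <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("STL file not found: %s", path), call. = FALSE)
  }
  size <- file.info(path)$size
  if (size < 15) {
    stop(sprintf(
      "STL format error in %s: file has only %d bytes", path, size
    ), call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  raw <- readBin(con, "raw", n = size)

  # Binary detection: 80-byte header + uint32 facet count whose implied size
  # matches the file. ASCII files begin with the keyword "solid".
  is_binary <- FALSE
  if (size >= 84) {
    count <- readBin(raw[81:84], "integer", size = 4L, endian = "little")
    if (count >= 0 && size == 84 + 50 * as.numeric(count)) is_binary <- TRUE
  }
  lead <- rawToChar(raw[seq_len(min(80L, size))][raw[seq_len(min(80L, size))] != as.raw(0L)])
  starts_solid <- grepl("^\\s*solid", lead)
  if (!is_binary && !starts_solid) {
    # Truncated or over-long binary: report the byte mismatch.
    if (size >= 84) {
      count <- readBin(raw[81:84], "integer", size = 4L, endian = "little")
      stop(sprintf(
        paste0(
          "STL format error in %s: declared %d binary facets need %d bytes ",
          "but file has %d bytes"
        ),
        path, count, 84 + 50 * as.numeric(count), size
      ), call. = FALSE)
    }
    stop(sprintf("STL format error in %s: unrecognized dialect", path),
         call. = FALSE)
  }

  if (is_binary) {
    count <- readBin(raw[81:84], "integer", size = 4L, endian = "little")
    if (count == 0L) {
      stop(sprintf("empty mesh: %s declares 0 facets", path), call. = FALSE)
    }
    body <- matrix(raw[85:size], nrow = 50L)
    floats <- readBin(
      as.vector(body[1:48, , drop = FALSE]), "numeric",
      size = 4L, n = 12L * count, endian = "little"
    )
    rec <- matrix(floats, nrow = 12L)
    # rows 4:12 are v1x v1y v1z v2x ... v3z; one column per facet
    verts <- t(matrix(rec[4:12, , drop = FALSE], nrow = 3L))
    dialect <- "binary"
  } else {
    lines <- readLines(path, warn = FALSE)
    vidx <- grep("^\\s*vertex\\b", lines)
    if (length(vidx) == 0L) {
      stop(sprintf("empty mesh: %s contains no vertex lines", path),
           call. = FALSE)
    }
    if (length(vidx) %% 3L != 0L) {
      stop(sprintf(
        "STL format error in %s: %d vertex lines (not a multiple of 3); last at line %d",
        path, length(vidx), vidx[length(vidx)]
      ), call. = FALSE)
    }
    txt <- sub("^\\s*vertex\\s+", "", lines[vidx])
    nums <- tryCatch(
      suppressWarnings(scan(text = txt, what = double(), quiet = TRUE)),
      error = function(e) NULL
    )
    if (is.null(nums) || length(nums) != 3L * length(vidx) || anyNA(nums)) {
      bad <- which(is.na(
        suppressWarnings(sapply(strsplit(trimws(txt), "\\s+"), function(p) {
          if (length(p) != 3L) NA_real_ else sum(as.numeric(p))
        }))
      ))
      at <- if (length(bad)) vidx[bad[1L]] else vidx[1L]
      stop(sprintf(
        "STL format error in %s: malformed vertex line %d", path, at
      ), call. = FALSE)
    }
    verts <- matrix(nums, ncol = 3L, byrow = TRUE)
    dialect <- "ascii"
  }

  nfac <- nrow(verts) / 3L
  faces <- matrix(seq_len(3L * nfac), ncol = 3L, byrow = TRUE)
  merged <- .merge_vertices(verts, faces, tol = 1e-6)
  if (nrow(merged$faces) == 0L) {
    stop(sprintf("empty mesh: %s has no non-degenerate facets", path),
         call. = FALSE)
  }
  mesh <- triangle_mesh(merged$vertices, merged$faces)
  attr(mesh, "source_dialect") <- dialect
  mesh
}

#' Write a mesh as an STL file
#'
#' Facet normals are always recomputed from vertex winding; normals stored on
#' the mesh are not trusted (a common inconsistency between STL writers).
#' The binary dialect uses the standard 80-byte header, uint32 facet count
#' and 50-byte facet records.
#'
#' @param mesh a [triangle_mesh()].
#' @param path output path.
#' @param dialect `"ascii"` or `"binary"`.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, dialect = c("binary", "ascii")) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  dialect <- match.arg(dialect)
  if (nrow(mesh$faces) == 0L) {
    stop("empty mesh: refusing to write an STL with 0 facets", call. = FALSE)
  }
  n <- nrow(mesh$faces)
  nrm <- .facet_normals(mesh)
  v1 <- mesh$vertices[mesh$faces[, 1L], , drop = FALSE]
  v2 <- mesh$vertices[mesh$faces[, 2L], , drop = FALSE]
  v3 <- mesh$vertices[mesh$faces[, 3L], , drop = FALSE]

  if (dialect == "ascii") {
    con <- file(path, "w")
    on.exit(close(con))
    fmt <- paste0(
      " facet normal %.9e %.9e %.9e\n  outer loop\n",
      "   vertex %.9e %.9e %.9e\n   vertex %.9e %.9e %.9e\n",
      "   vertex %.9e %.9e %.9e\n  endloop\n endfacet"
    )
    body <- sprintf(
      fmt,
      nrm[, 1L], nrm[, 2L], nrm[, 3L],
      v1[, 1L], v1[, 2L], v1[, 3L],
      v2[, 1L], v2[, 2L], v2[, 3L],
      v3[, 1L], v3[, 2L], v3[, 3L]
    )
    writeLines(c("solid airwaydeform", body, "endsolid airwaydeform"), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    header <- charToRaw(sprintf("%-80s", "airwaydeform binary STL"))[1:80]
    writeBin(header, con)
    writeBin(as.integer(n), con, size = 4L, endian = "little")
    # 12 float32 per facet (normal + 3 vertices) + uint16 attribute count.
    dat <- rbind(t(nrm), t(v1), t(v2), t(v3)) # 12 x n
    fbytes <- writeBin(as.vector(dat), raw(), size = 4L, endian = "little")
    fmat <- matrix(fbytes, nrow = 48L)
    recs <- rbind(fmat, matrix(as.raw(0L), nrow = 2L, ncol = n))
    writeBin(as.vector(recs), con)
  }
  invisible(path)
}

#' Validate a mesh and report basic quality metrics
#'
#' Pure function: the input mesh is never modified. Degenerate facets are
#' those with zero area (collinear or coincident corners).
#'
#' @param mesh a [triangle_mesh()].
#' @return An object of class `mesh_report`: a list with `facet_count`,
#'   `degenerate_facets`, `bounding_box` (2 x 3 matrix, mm) and
#'   `is_binary_source` (`NA` if the mesh was not read from a file).
#' @export
validate_mesh <- function(mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  areas <- .facet_areas(mesh)
  dialect <- attr(mesh, "source_dialect")
  structure(
    list(
      facet_count = nrow(mesh$faces),
      degenerate_facets = sum(areas <= 1e-12),
      bounding_box = mesh_bounding_box(mesh),
      is_binary_source = if (is.null(dialect)) NA else identical(dialect, "binary")
    ),
    class = "mesh_report"
  )
}

#' @export
print.mesh_report <- function(x, ...) {
  cat(sprintf(
    "<mesh_report> %d facets, %d degenerate\n", x$facet_count,
    x$degenerate_facets
  ))
  bb <- x$bounding_box
  cat(sprintf(
    "  bounding box (mm): x [%.3f, %.3f]  y [%.3f, %.3f]  z [%.3f, %.3f]\n",
    bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]
  ))
  invisible(x)
}

#' Serialize a mesh report to JSON
#'
#' @param report a `mesh_report` from [validate_mesh()].
#' @param path optional output path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
mesh_report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "mesh_report"))
  obj <- list(
    facet_count = report$facet_count,
    degenerate_facets = report$degenerate_facets,
    bounding_box = list(
      min = as.list(stats::setNames(report$bounding_box[1L, ], c("x", "y", "z"))),
      max = as.list(stats::setNames(report$bounding_box[2L, ], c("x", "y", "z")))
    ),
    is_binary_source = report$is_binary_source
  )
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Smooth a mesh by volume-preserving two-step neighbor averaging
#'
#' Each iteration performs a positive neighbor-averaging step followed by a
#' slightly larger negative back-step (Taubin's lambda/mu scheme), which
#' removes digitization corrugation without the lumen shrinkage of plain
#' Laplacian smoothing -- shrinkage would bias downstream cross-section
#' areas. Topology (vertex and facet counts, connectivity) is unchanged.
#'
#' @param mesh a [triangle_mesh()].
#' @param iterations number of smoothing passes; `0` returns an identical
#'   copy.
#' @param strength in `[0, 1]`; scales the per-step displacement.
#' @return The smoothed [triangle_mesh()].
#' @export
smooth_mesh <- function(mesh, iterations = 10L, strength = 0.6) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (!is.numeric(iterations) || length(iterations) != 1L || iterations < 0) {
    stop("`iterations` must be a single non-negative count", call. = FALSE)
  }
  if (!is.numeric(strength) || length(strength) != 1L ||
        strength < 0 || strength > 1) {
    stop("`strength` must lie in [0, 1]", call. = FALSE)
  }
  iterations <- as.integer(iterations)
  if (iterations == 0L) return(mesh)

  e <- unique(.mesh_edge_instances(mesh))
  nv <- nrow(mesh$vertices)
  adj <- Matrix::sparseMatrix(
    i = c(e[, 1L], e[, 2L]), j = c(e[, 2L], e[, 1L]),
    x = 1, dims = c(nv, nv)
  )
  deg <- Matrix::rowSums(adj)
  deg[deg == 0] <- 1
  lam <- 0.33 * strength
  mu <- -0.34 * strength
  v <- mesh$vertices
  for (i in seq_len(iterations)) {
    lap <- as.matrix(adj %*% v) / deg - v
    v <- v + lam * lap
    lap <- as.matrix(adj %*% v) / deg - v
    v <- v + mu * lap
  }
  out <- triangle_mesh(v, mesh$faces)
  attr(out, "source_dialect") <- attr(mesh, "source_dialect")
  out
}
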
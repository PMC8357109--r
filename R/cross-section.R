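#' Cross-section of an airway at a horizontal plane
#'
#' Container for the closed contours produced by slicing a mesh with a plane
#' of constant z, together with the dimensioning quantities used in surgical
#' planning: the summed enclosed area, the spine-side extreme Ys (maximum y),
#' the anterior mid-sagittal extreme Yc (minimum y within a band around the
#' mid-sagittal x), the lateral width and the anteroposterior depth.
#'
#' Yc is taken over contour points with `|x - x_c| <= 0.5` mm, where `x_c` is
#' the mid-range x of the largest contour; the band makes the "minimum y on a
#' sagittal plane" robust to contour discretization. If no point falls in the
#' band the point nearest the mid-sagittal line is used.
#'
#' @param z plane height (mm).
#' @param contours list of closed polylines: 2-column (x, y) matrices whose
#'   first and last rows coincide.
#' @param area optional known area (mm^2); computed by the shoelace formula
#'   when omitted.
#' @return An object of class `cross_section` with elements `z`, `contours`,
#'   `area`, `ys`, `yc`, `width_x`, `depth_y`, `x_c` and `per_contour`
#'   (a data frame of per-contour areas and extents).
#' @export
cross_section <- function(z, contours, area = NULL) {
  stopifnot(is.list(contours))
  if (length(contours) == 0L) {
    return(structure(
      list(
        z = z, contours = list(), area = 0, ys = NA_real_, yc = NA_real_,
        width_x = NA_real_, depth_y = NA_real_, x_c = NA_real_,
        per_contour = data.frame(
          area = numeric(0), min_x = numeric(0), max_x = numeric(0),
          min_y = numeric(0), max_y = numeric(0)
        )
      ),
      class = "cross_section"
    ))
  }
  contours <- lapply(contours, function(p) {
    p <- as.matrix(p)
    if (ncol(p) != 2L || nrow(p) < 4L) {
      stop("each contour needs >= 3 distinct (x, y) points plus closure",
           call. = FALSE)
    }
    if (max(abs(p[1L, ] - p[nrow(p), ])) > 1e-6) {
      stop("contour is not closed (first and last points differ)",
           call. = FALSE)
    }
    dimnames(p) <- list(NULL, c("x", "y"))
    p
  })
  areas <- vapply(contours, .shoelace_area, numeric(1L))
  per <- data.frame(
    area = areas,
    min_x = vapply(contours, function(p) min(p[, 1L]), numeric(1L)),
    max_x = vapply(contours, function(p) max(p[, 1L]), numeric(1L)),
    min_y = vapply(contours, function(p) min(p[, 2L]), numeric(1L)),
    max_y = vapply(contours, function(p) max(p[, 2L]), numeric(1L))
  )
  big <- which.max(areas)
  x_c <- (per$min_x[big] + per$max_x[big]) / 2
  all_pts <- do.call(rbind, contours)
  ys <- max(all_pts[, 2L])
  in_band <- abs(all_pts[, 1L] - x_c) <= 0.5
  yc <- if (any(in_band)) {
    min(all_pts[in_band, 2L])
  } else {
    all_pts[which.min(abs(all_pts[, 1L] - x_c)), 2L]
  }
  structure(
    list(
      z = z,
      contours = contours,
      area = if (is.null(area)) sum(areas) else area,
      ys = ys,
      yc = yc,
      width_x = max(per$max_x) - min(per$min_x),
      depth_y = ys - yc,
      x_c = x_c,
      per_contour = per
    ),
    class = "cross_section"
  )
}

#' @export
print.cross_section <- function(x, ...) {
  cat(sprintf("<cross_section> z = %.3f mm, %d contour(s)\n",
              x$z, length(x$contours)))
  if (length(x$contours)) {
    cat(sprintf(
      "  area %.4f mm^2 | width_x %.3f | depth_y %.3f | Ys %.3f | Yc %.3f\n",
      x$area, x$width_x, x$depth_y, x$ys, x$yc
    ))
  } else {
    cat("  empty section\n")
  }
  invisible(x)
}

# Signed shoelace area, returned as magnitude.
.shoelace_area <- function(p) {
  n <- nrow(p)
  x <- p[-n, 1L]; y <- p[-n, 2L]
  x2 <- p[-1L, 1L]; y2 <- p[-1L, 2L]
  abs(sum(x * y2 - x2 * y)) / 2
}

#' Slice a mesh with a horizontal plane
#'
#' Intersects every facet with the plane `z = const`, chains the resulting
#' segments into closed loops, and returns the section with its dimensioning
#' metrics. Chaining is exact: the intersection point on each crossing mesh
#' edge is computed once, so adjacent facets share endpoints bit-for-bit and
#' no floating-point tolerance enters loop assembly. Vertices lying exactly
#' on the plane are treated as lying 1e-9 mm above it, the usual symbolic
#' perturbation for coplanar facets.
#'
#' @param mesh a [triangle_mesh()].
#' @param z plane height (mm).
#' @return A [cross_section()]; empty (area 0) when the plane misses the mesh.
#' @export
slice_mesh <- function(mesh, z) {
  stopifnot(inherits(mesh, "triangle_mesh"), is.numeric(z), length(z) == 1L)
  zv <- mesh$vertices[, 3L]
  zv[zv == z] <- z + 1e-9
  above <- zv > z
  f <- mesh$faces
  nab <- above[f[, 1L]] + above[f[, 2L]] + above[f[, 3L]]
  hit <- which(nab == 1L | nab == 2L)
  if (length(hit) == 0L) return(cross_section(z, list()))

  # Crossing edges per facet (exactly two per crossing facet).
  fh <- f[hit, , drop = FALSE]
  seg_edges <- matrix(NA_integer_, nrow = length(hit), ncol = 4L)
  pair <- function(i, j) {
    cbind(pmin(fh[, i], fh[, j]), pmax(fh[, i], fh[, j]))
  }
  e12 <- pair(1L, 2L); e23 <- pair(2L, 3L); e31 <- pair(3L, 1L)
  x12 <- above[fh[, 1L]] != above[fh[, 2L]]
  x23 <- above[fh[, 2L]] != above[fh[, 3L]]
  x31 <- above[fh[, 3L]] != above[fh[, 1L]]
  for (k in seq_along(hit)) {
    ee <- rbind(
      if (x12[k]) e12[k, ],
      if (x23[k]) e23[k, ],
      if (x31[k]) e31[k, ]
    )
    seg_edges[k, ] <- as.integer(t(ee))
  }
  # Unique crossing edges -> one intersection point each.
  all_e <- rbind(seg_edges[, 1:2, drop = FALSE], seg_edges[, 3:4, drop = FALSE])
  ekey <- paste(all_e[, 1L], all_e[, 2L])
  ufirst <- !duplicated(ekey)
  uedges <- all_e[ufirst, , drop = FALSE]
  node_of <- match(ekey, ekey[ufirst])
  seg_a <- node_of[seq_along(hit)]
  seg_b <- node_of[seq_along(hit) + length(hit)]

  va <- mesh$vertices[uedges[, 1L], , drop = FALSE]
  vb <- mesh$vertices[uedges[, 2L], , drop = FALSE]
  za <- zv[uedges[, 1L]]; zb <- zv[uedges[, 2L]]
  t <- (z - za) / (zb - za)
  pts <- cbind(
    va[, 1L] + t * (vb[, 1L] - va[, 1L]),
    va[, 2L] + t * (vb[, 2L] - va[, 2L])
  )

  loops <- .assemble_loops(seg_a, seg_b, pts)
  cross_section(z, loops)
}

# Chain segments (pairs of node ids) into closed loops; error on open chains.
.assemble_loops <- function(seg_a, seg_b, pts) {
  m <- length(seg_a)
  node_segs <- split(rep(seq_len(m), 2L), c(seg_a, seg_b))
  deg <- lengths(node_segs)
  if (any(deg != 2L)) {
    open_nodes <- as.integer(names(node_segs)[deg != 2L])
    gap <- if (length(open_nodes) >= 2L) {
      d <- as.matrix(stats::dist(pts[open_nodes, , drop = FALSE]))
      diag(d) <- Inf
      min(d)
    } else {
      NA_real_
    }
    stop(sprintf(
      paste0("slicing produced open chains (mesh not watertight at this z): ",
             "%d loose endpoint(s), smallest gap %.6g mm"),
      length(open_nodes), gap
    ), call. = FALSE)
  }
  seg_nodes <- cbind(seg_a, seg_b)
  used <- logical(m)
  loops <- list()
  for (s0 in seq_len(m)) {
    if (used[s0]) next
    start_node <- seg_a[s0]
    node <- start_node
    seg <- s0
    path <- integer(0)
    repeat {
      used[seg] <- TRUE
      path <- c(path, node)
      node <- if (seg_nodes[seg, 1L] == node) seg_nodes[seg, 2L] else seg_nodes[seg, 1L]
      if (node == start_node) break
      cand <- node_segs[[as.character(node)]]
      seg <- cand[cand != seg][1L]
    }
    loop <- pts[c(path, path[1L]), , drop = FALSE]
    loops[[length(loops) + 1L]] <- loop
  }
  loops
}

#' Compare two cross-sections at the same plane
#'
#' Quantifies the achieved enlargement between a preoperative and a
#' predicted/postoperative section.
#'
#' @param pre,post [cross_section()]s at the same z (within 1e-3 mm).
#' @return An object of class `section_comparison`: list with `achieved_dY`
#'   (post depth minus pre depth, mm), `achieved_dX_total` (post width minus
#'   pre width, mm) and `area_ratio` (post / pre).
#' @export
compare_sections <- function(pre, post) {
  stopifnot(inherits(pre, "cross_section"), inherits(post, "cross_section"))
  if (abs(pre$z - post$z) > 1e-3) {
    stop(sprintf(
      "sections are on different planes (z = %.4f vs %.4f mm)", pre$z, post$z
    ), call. = FALSE)
  }
  if (length(pre$contours) == 0L || length(post$contours) == 0L) {
    stop("cannot compare empty sections", call. = FALSE)
  }
  structure(
    list(
      z = pre$z,
      achieved_dY = post$depth_y - pre$depth_y,
      achieved_dX_total = post$width_x - pre$width_x,
      area_ratio = post$area / pre$area
    ),
    class = "section_comparison"
  )
}

#' @export
print.section_comparison <- function(x, ...) {
  cat(sprintf(
    "<section_comparison> z = %.3f mm: dY %.3f mm, dX total %.3f mm, area ratio %.4f\n",
    x$z, x$achieved_dY, x$achieved_dX_total, x$area_ratio
  ))
  invisible(x)
}

#' Export a cross-section as plot-ready columns
#'
#' Writes contour coordinates as whitespace-delimited `x y` lines, one block
#' per contour separated by a blank line -- the layout consumed directly by
#' common graphing utilities.
#'
#' @param section a non-empty [cross_section()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_section <- function(section, path) {
  stopifnot(inherits(section, "cross_section"))
  if (length(section$contours) == 0L) {
    stop("cannot export an empty section", call. = FALSE)
  }
  blocks <- lapply(section$contours, function(p) {
    sprintf("%.9e %.9e", p[, 1L], p[, 2L])
  })
  out <- unlist(mapply(
    function(b, i) if (i == 1L) b else c("", b),
    blocks, seq_along(blocks), SIMPLIFY = FALSE
  ))
  writeLines(out, path)
  invisible(path)
}

#' Serialize cross-section metrics to JSON
#'
#' @param section a [cross_section()].
#' @param path optional output path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
section_metrics_json <- function(section, path = NULL) {
  stopifnot(inherits(section, "cross_section"))
  obj <- list(
    z = section$z,
    n_contours = length(section$contours),
    area = section$area,
    ys = section$ys,
    yc = section$yc,
    width_x = section$width_x,
    depth_y = section$depth_y
  )
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
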
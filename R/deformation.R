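#' Pivotal control plane of the deformation model
#'
#' A pivotal plane is a horizontal (constant-z) plane on which the airway
#' enlargement is prescribed. `dy` is the increase of the anteroposterior
#' airway diameter (sagittal direction) and `dx_half` the half-to-peak
#' lateral enlargement (coronal direction) at that plane. `ys` is the
#' maximum y coordinate of the pharynx wall (the spine-side extreme) and
#' `yc` the minimum y on the mid-sagittal line (the anterior extreme); both
#' can be left `NULL` and estimated from the mesh at deformation time.
#'
#' @param z plane height (mm).
#' @param dy anteroposterior enlargement (mm, >= 0).
#' @param dx_half half-to-peak lateral enlargement (mm, >= 0).
#' @param ys,yc optional wall extremes at this plane (mm).
#' @param label cosmetic free-text label; never interpreted.
#' @return An object of class `pivotal_plane`.
#' @export
pivotal_plane <- function(z, dy = 0, dx_half = 0, ys = NULL, yc = NULL,
                          label = "") {
  stopifnot(is.numeric(z), length(z) == 1L, is.finite(z))
  if (dy < 0 || dx_half < 0) {
    stop("`dy` and `dx_half` must be >= 0 (enlargement only)", call. = FALSE)
  }
  if (!is.null(ys) && !is.null(yc) && yc >= ys) {
    stop("`yc` must be smaller than `ys`", call. = FALSE)
  }
  structure(
    list(
      z = as.numeric(z), dy = as.numeric(dy), dx_half = as.numeric(dx_half),
      ys = if (is.null(ys)) NA_real_ else as.numeric(ys),
      yc = if (is.null(yc)) NA_real_ else as.numeric(yc),
      label = as.character(label)
    ),
    class = "pivotal_plane"
  )
}

#' Three-plane deformation configuration
#'
#' The deformation is controlled by three pivotal planes orthogonal to the
#' z-axis (z runs foot to head). The geometry is fixed at and above the top
#' plane, whose parameters must be exactly zero; the middle and lower planes
#' each carry a `(dy, dx_half)` pair. Everything with y at or beyond the
#' (z-interpolated) spine-side wall Ys is also fixed.
#'
#' @param top,middle,lower [pivotal_plane()]s with
#'   `lower$z < middle$z < top$z`.
#' @param spine_fix_margin mm (>= 0); shrinks the mobile region so that
#'   displacement already vanishes `spine_fix_margin` mm in front of Ys.
#' @return An object of class `deformation_config`.
#' @export
deformation_config <- function(top, middle, lower, spine_fix_margin = 0) {
  for (p in list(top, middle, lower)) {
    if (!inherits(p, "pivotal_plane")) {
      stop("planes must be `pivotal_plane` objects", call. = FALSE)
    }
  }
  if (!(lower$z < middle$z && middle$z < top$z)) {
    stop("plane order must satisfy lower$z < middle$z < top$z (z runs foot to head)",
         call. = FALSE)
  }
  if (top$dy != 0 || top$dx_half != 0) {
    stop("the top plane is a fixed boundary: its dy and dx_half must be exactly 0",
         call. = FALSE)
  }
  if (spine_fix_margin < 0) {
    stop("`spine_fix_margin` must be >= 0", call. = FALSE)
  }
  structure(
    list(top = top, middle = middle, lower = lower,
         spine_fix_margin = as.numeric(spine_fix_margin)),
    class = "deformation_config"
  )
}

#' @export
print.deformation_config <- function(x, ...) {
  cat("<deformation_config> (z foot to head; mm)\n")
  row <- function(p, role) {
    cat(sprintf(
      "  %-6s z %9.3f  Ys %8s  Yc %8s  dY %5.2f  dX_half %5.2f  %s\n",
      role, p$z,
      ifelse(is.na(p$ys), "--", sprintf("%.2f", p$ys)),
      ifelse(is.na(p$yc), "--", sprintf("%.2f", p$yc)),
      p$dy, p$dx_half, p$label
    ))
  }
  row(x$top, "top"); row(x$middle, "middle"); row(x$lower, "lower")
  if (x$spine_fix_margin > 0) {
    cat(sprintf("  spine fix margin %.2f mm\n", x$spine_fix_margin))
  }
  invisible(x)
}

#' Read / write a deformation configuration as JSON
#'
#' The JSON layout mirrors the tabular parameter block surgeons fill in:
#' one object per plane with `z`, optional `ys`/`yc`, `dy`, `dx_half` and a
#' cosmetic `label`.
#'
#' @param path JSON file path.
#' @return `read_deformation_config()` returns a [deformation_config()];
#'   `write_deformation_config()` returns `path` invisibly.
#' @export
read_deformation_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  }
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  mk <- function(p) {
    pivotal_plane(
      z = p$z,
      dy = if (is.null(p$dy)) 0 else p$dy,
      dx_half = if (is.null(p$dx_half)) 0 else p$dx_half,
      ys = p$ys, yc = p$yc,
      label = if (is.null(p$label)) "" else p$label
    )
  }
  deformation_config(
    top = mk(j$planes$top), middle = mk(j$planes$middle),
    lower = mk(j$planes$lower),
    spine_fix_margin = if (is.null(j$spine_fix_margin)) 0 else j$spine_fix_margin
  )
}

#' @rdname read_deformation_config
#' @param config a [deformation_config()].
#' @export
write_deformation_config <- function(config, path) {
  stopifnot(inherits(config, "deformation_config"))
  pl <- function(p) {
    out <- list(z = p$z, dy = p$dy, dx_half = p$dx_half, label = p$label)
    if (!is.na(p$ys)) out$ys <- p$ys
    if (!is.na(p$yc)) out$yc <- p$yc
    out
  }
  jsonlite::write_json(
    list(
      planes = list(top = pl(config$top), middle = pl(config$middle),
                    lower = pl(config$lower)),
      spine_fix_margin = config$spine_fix_margin
    ),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' Half-to-peak lateral parameter from a total widening estimate
#'
#' Surgeons estimate the total lateral (coronal) widening of an airway
#' cross-section; the deformation model is parameterized by the half-to-peak
#' value applied symmetrically about the mid-sagittal plane.
#'
#' @param total_dx total lateral widening (mm, >= 0).
#' @return Half-to-peak `dx_half` in mm.
#' @examples
#' lateral_half_enlargement(2) # 1
#' @export
lateral_half_enlargement <- function(total_dx) {
  if (!is.numeric(total_dx) || any(total_dx < 0)) {
    stop("`total_dx` must be a non-negative widening in mm", call. = FALSE)
  }
  total_dx / 2
}

#' Estimate per-plane wall anatomy from a mesh
#'
#' Slices the mesh at z and reports, from the largest-area contour: the
#' spine-side extreme `ys`, the anterior mid-sagittal extreme `yc`, the
#' mid-sagittal x `x_c`, the half-width `w_half`, and `y_widest` (the y
#' level of the lateral extremes, where the lateral enlargement acts at
#' full strength).
#'
#' @param mesh a [triangle_mesh()].
#' @param z plane height (mm).
#' @return Named list `ys`, `yc`, `x_c`, `w_half`, `y_widest` (mm).
#' @export
estimate_plane_anatomy <- function(mesh, z) {
  sec <- slice_mesh(mesh, z)
  if (length(sec$contours) == 0L) {
    stop(sprintf("no airway contour at z = %.3f mm", z), call. = FALSE)
  }
  big <- sec$contours[[which.max(sec$per_contour$area)]]
  pts <- big[-nrow(big), , drop = FALSE]
  x_c <- (min(pts[, 1L]) + max(pts[, 1L])) / 2
  in_band <- abs(pts[, 1L] - x_c) <= 0.5
  yc <- if (any(in_band)) {
    min(pts[in_band, 2L])
  } else {
    pts[which.min(abs(pts[, 1L] - x_c)), 2L]
  }
  i_min <- which.min(pts[, 1L]); i_max <- which.max(pts[, 1L])
  list(
    ys = max(pts[, 2L]),
    yc = unname(yc),
    x_c = unname(x_c),
    w_half = unname((pts[i_max, 1L] - pts[i_min, 1L]) / 2),
    y_widest = unname((pts[i_min, 2L] + pts[i_max, 2L]) / 2)
  )
}

# Complete the per-plane anatomy table: user-supplied ys/yc win, mesh
# estimates fill the gaps. Rows ordered lower, middle, top.
.config_anatomy <- function(config, mesh = NULL, anatomy = NULL) {
  planes <- list(lower = config$lower, middle = config$middle,
                 top = config$top)
  fill <- function(role) {
    p <- planes[[role]]
    est <- if (!is.null(anatomy) && !is.null(anatomy[[role]])) {
      anatomy[[role]]
    } else if (!is.null(mesh)) {
      estimate_plane_anatomy(mesh, p$z)
    } else {
      stop("anatomy (ys/yc/x_c/w_half) unavailable: supply a mesh or an `anatomy` list",
           call. = FALSE)
    }
    list(
      z = p$z,
      ys = if (!is.na(p$ys)) p$ys else est$ys,
      yc = if (!is.na(p$yc)) p$yc else est$yc,
      x_c = est$x_c,
      w_half = est$w_half,
      y_widest = if (is.null(est$y_widest)) est$yc else est$y_widest
    )
  }
  out <- lapply(stats::setNames(nm = names(planes)), fill)
  for (role in names(out)) {
    if (out[[role]]$yc >= out[[role]]$ys) {
      stop(sprintf("plane %s: Yc must be smaller than Ys", role),
           call. = FALSE)
    }
    if (out[[role]]$w_half <= 0) {
      stop(sprintf("plane %s: half-width must be positive", role),
           call. = FALSE)
    }
  }
  out
}

#' Build the smooth displacement field of a deformation configuration
#'
#' Returns a callable field `f(points)` mapping an n x 3 matrix of (x, y, z)
#' points (mm) to an n x 3 matrix of displacements (mm). The field is built
#' from combined quadratic equations with continuous first derivatives in
#' all three directions:
#'
#' * Axial: each controlled plane carries a cardinal piecewise-quadratic
#'   basis that is 1 at its own plane, 0 with zero slope at the top plane,
#'   C1 between planes, and constant below the lower plane.
#' * Anterior: `dy(p) = -dY(z) * Wy(y)` with `Wy` quadratic in y, equal to 1
#'   at the interpolated anterior extreme Yc(z) and reaching 0 with zero
#'   slope at the spine-side wall Ys(z).
#' * Lateral: `dx(p) = dX(z) * S(x) * F(y)` where
#'   `S = sign(x - x_c) * min(1, ((x - x_c) / w_half)^2)` (C1 at the
#'   mid-sagittal line) and `F` is a C1 falloff in y that is 1 at the
#'   section's widest level and 0 at Ys(z), so the spine side stays fixed.
#' * `dz = 0` everywhere; displacement is exactly zero for `z >= top$z` and
#'   for `y >= Ys(z)`.
#'
#' At each controlled plane the achieved enlargement at the control points
#' equals the prescribed `dy` / `dx_half` exactly.
#'
#' @param config a [deformation_config()].
#' @param mesh optional [triangle_mesh()] used to estimate per-plane
#'   `x_c`, `w_half`, widest-level y and any missing `ys`/`yc`.
#' @param anatomy optional list with elements `lower`, `middle`, `top`, each
#'   a list like the return of [estimate_plane_anatomy()]; overrides mesh
#'   estimation.
#' @return An object of classes `displacement_field` and `function`.
#' @export
build_displacement_field <- function(config, mesh = NULL, anatomy = NULL) {
  stopifnot(inherits(config, "deformation_config"))
  an <- .config_anatomy(config, mesh = mesh, anatomy = anatomy)
  zl <- config$lower$z; zm <- config$middle$z; zt <- config$top$z
  dy_l <- config$lower$dy; dy_m <- config$middle$dy
  dx_l <- config$lower$dx_half; dx_m <- config$middle$dx_half
  margin <- config$spine_fix_margin

  interp <- function(z, what) {
    .anat_interp(z, zl, zm, zt,
                 an$lower[[what]], an$middle[[what]], an$top[[what]])
  }

  field <- function(points) {
    points <- as.matrix(points)
    if (ncol(points) != 3L) stop("`points` must be n x 3", call. = FALSE)
    x <- points[, 1L]; y <- points[, 2L]; z <- points[, 3L]
    dyz <- .axial_profile(z, zl, zm, zt, dy_l, dy_m)
    dxz <- .axial_profile(z, zl, zm, zt, dx_l, dx_m)
    ys <- interp(z, "ys") - margin
    yc <- interp(z, "yc")
    xc <- interp(z, "x_c")
    wh <- interp(z, "w_half")
    yw <- interp(z, "y_widest")

    wy <- numeric(length(y))
    mob <- y < ys
    wy[mob] <- ((ys[mob] - y[mob]) / (ys[mob] - yc[mob]))^2

    u <- x - xc
    s <- sign(u) * pmin(1, (u / wh)^2)
    fy <- .smooth_falloff(y, pmin(yw, ys - 1e-9), ys)

    cbind(dxz * s * fy, -dyz * wy, 0)
  }
  structure(field, class = c("displacement_field", "function"),
            config = config, anatomy = an)
}

#' @export
print.displacement_field <- function(x, ...) {
  cfg <- attr(x, "config")
  cat("<displacement_field> pivotal-plane airway deformation\n")
  print(cfg)
  invisible(x)
}

#' Apply a pivotal-plane deformation to a mesh
#'
#' Vertex-wise application of the displacement field of `config`; topology
#' is unchanged and the result is deterministic. With all parameters zero
#' the output vertices are bit-identical to the input.
#'
#' @param mesh a [triangle_mesh()].
#' @param config a [deformation_config()].
#' @param anatomy optional anatomy override, see
#'   [build_displacement_field()].
#' @return The deformed [triangle_mesh()].
#' @export
deform_mesh <- function(mesh, config, anatomy = NULL) {
  stopifnot(inherits(mesh, "triangle_mesh"),
            inherits(config, "deformation_config"))
  bb <- mesh_bounding_box(mesh)
  if (bb[1L, 3L] >= config$top$z) {
    warning("mesh lies entirely at or above the top pivotal plane; returning it unchanged",
            call. = FALSE)
    return(mesh)
  }
  if (config$middle$dy == 0 && config$middle$dx_half == 0 &&
        config$lower$dy == 0 && config$lower$dx_half == 0) {
    return(mesh) # exact identity, no field evaluation round-off
  }
  field <- build_displacement_field(config, mesh = mesh, anatomy = anatomy)
  out <- triangle_mesh(mesh$vertices + field(mesh$vertices), mesh$faces)
  attr(out, "source_dialect") <- attr(mesh, "source_dialect")
  out
}
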
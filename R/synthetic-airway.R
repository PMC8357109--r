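#' Specification of a parametric synthetic airway
#'
#' Defines a surrogate upper airway with analytically known cross-sections:
#' a single pharyngeal tube with elliptical sections of lateral semi-axis
#' `a(z)` and anteroposterior semi-axis `b(z)` centered at `(0, c(z))`,
#' surmounted by two circular nasal tubes that stand in for the left and
#' right nasal passages above the confluence plane. Each component is an
#' individually watertight closed surface; slicing above the confluence
#' yields two contours, below it one.
#'
#' @param pharynx_z_range length-2 numeric, `(z_low, z_high)` in mm; `z_high`
#'   is the nasal confluence plane.
#' @param a,b lateral / anteroposterior semi-axes of the pharyngeal ellipse:
#'   either positive constants or functions of z returning mm.
#' @param c_offset anteroposterior centerline offset: constant or function of
#'   z (mm).
#' @param nasal_radii length-2 positive numeric, radii of the right and left
#'   nasal tubes (mm).
#' @param nasal_length axial length of the nasal tubes above the confluence
#'   (mm).
#' @param nasal_x_offset lateral distance of each nasal tube center from the
#'   mid-sagittal plane (mm); tubes sit at -offset and +offset.
#' @param angular_resolution vertices per ring (>= 8); multiples of 4 place
#'   vertices exactly at the lateral and anteroposterior extremes.
#' @param axial_resolution rings per mm (>= 0.2).
#' @param noise_amp amplitude of optional uniform radial surface noise (mm);
#'   `0` (default) for an exact surface.
#' @param seed integer seed driving only the optional noise.
#' @return An object of class `airway_spec`.
#' @export
airway_spec <- function(pharynx_z_range = c(0, 80),
                        a = 10, b = 6, c_offset = 0,
                        nasal_radii = c(3.5, 3.5),
                        nasal_length = 20,
                        nasal_x_offset = 7,
                        angular_resolution = 64L,
                        axial_resolution = 0.5,
                        noise_amp = 0,
                        seed = 1L) {
  as_fn <- function(v, name) {
    if (is.function(v)) return(v)
    if (is.numeric(v) && length(v) == 1L) return(function(z) rep(v, length(z)))
    stop(sprintf("`%s` must be a constant or a function of z", name),
         call. = FALSE)
  }
  if (length(pharynx_z_range) != 2L ||
        pharynx_z_range[2L] <= pharynx_z_range[1L]) {
    stop("`pharynx_z_range` must be (z_low, z_high) with z_low < z_high",
         call. = FALSE)
  }
  if (angular_resolution < 8L) {
    stop("`angular_resolution` must be >= 8 vertices per ring", call. = FALSE)
  }
  if (axial_resolution < 0.2) {
    stop("`axial_resolution` must be >= 0.2 rings per mm", call. = FALSE)
  }
  if (any(nasal_radii <= 0) || length(nasal_radii) != 2L) {
    stop("`nasal_radii` must be two positive radii (mm)", call. = FALSE)
  }
  if (noise_amp < 0) stop("`noise_amp` must be >= 0", call. = FALSE)
  spec <- structure(
    list(
      pharynx_z_range = as.numeric(pharynx_z_range),
      a = as_fn(a, "a"), b = as_fn(b, "b"),
      c_offset = as_fn(c_offset, "c_offset"),
      nasal_radii = as.numeric(nasal_radii),
      nasal_length = as.numeric(nasal_length),
      nasal_x_offset = as.numeric(nasal_x_offset),
      angular_resolution = as.integer(angular_resolution),
      axial_resolution = as.numeric(axial_resolution),
      noise_amp = as.numeric(noise_amp),
      seed = as.integer(seed)
    ),
    class = "airway_spec"
  )
  zs <- seq(pharynx_z_range[1L], pharynx_z_range[2L], length.out = 33L)
  if (any(spec$a(zs) <= 0) || any(spec$b(zs) <= 0)) {
    stop("semi-axes a(z) and b(z) must be positive over the pharynx range",
         call. = FALSE)
  }
  spec
}

#' @export
print.airway_spec <- function(x, ...) {
  zr <- x$pharynx_z_range
  cat(sprintf(
    "<airway_spec> pharynx z [%.1f, %.1f] mm, confluence at %.1f mm\n",
    zr[1L], zr[2L], zr[2L]
  ))
  cat(sprintf(
    "  %d vertices/ring, %.2f rings/mm, nasal radii %.2f/%.2f mm, noise %.2f mm\n",
    x$angular_resolution, x$axial_resolution,
    x$nasal_radii[1L], x$nasal_radii[2L], x$noise_amp
  ))
  invisible(x)
}

# Closed tube: rings of `n` vertices at heights `zs`, ring k centered at
# (cx[k], cy[k]) with semi-axes ax[k], ay[k]; flat caps at both ends.
.closed_tube <- function(zs, cx, cy, ax, ay, n, radial_noise = NULL) {
  nz <- length(zs)
  th <- 2 * pi * (seq_len(n) - 1L) / n
  ct <- cos(th); st <- sin(th)
  verts <- matrix(0, nrow = nz * n + 2L, ncol = 3L)
  for (k in seq_len(nz)) {
    rows <- (k - 1L) * n + seq_len(n)
    rx <- ax[k]; ry <- ay[k]
    px <- rx * ct; py <- ry * st
    if (!is.null(radial_noise)) {
      len <- sqrt(px^2 + py^2)
      s <- 1 + radial_noise[rows] / len
      px <- px * s; py <- py * s
    }
    verts[rows, ] <- cbind(cx[k] + px, cy[k] + py, zs[k])
  }
  bot_c <- nz * n + 1L
  top_c <- nz * n + 2L
  verts[bot_c, ] <- c(cx[1L], cy[1L], zs[1L])
  verts[top_c, ] <- c(cx[nz], cy[nz], zs[nz])

  faces <- vector("list", nz + 1L)
  idx <- function(k, j) (k - 1L) * n + ((j - 1L) %% n) + 1L
  j <- seq_len(n)
  for (k in seq_len(nz - 1L)) {
    a1 <- idx(k, j); a2 <- idx(k, j + 1L)
    b1 <- idx(k + 1L, j); b2 <- idx(k + 1L, j + 1L)
    faces[[k]] <- rbind(cbind(a1, a2, b2), cbind(a1, b2, b1))
  }
  faces[[nz]] <- cbind(idx(1L, j + 1L), idx(1L, j), bot_c)        # bottom cap
  faces[[nz + 1L]] <- cbind(idx(nz, j), idx(nz, j + 1L), top_c)   # top cap
  list(vertices = verts, faces = do.call(rbind, faces))
}

#' Generate the synthetic airway surface
#'
#' Deterministic for a fixed spec and seed: the geometry is exact and the
#' seed only drives the optional radial surface noise (used to exercise
#' smoothing).
#'
#' @param spec an [airway_spec()].
#' @return A watertight [triangle_mesh()].
#' @export
generate_airway <- function(spec) {
  stopifnot(inherits(spec, "airway_spec"))
  zr <- spec$pharynx_z_range
  n <- spec$angular_resolution
  nz <- max(2L, ceiling(diff(zr) * spec$axial_resolution) + 1L)
  zs <- seq(zr[1L], zr[2L], length.out = nz)

  noise <- NULL
  if (spec$noise_amp > 0) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(spec$seed)
  }

  ph <- .closed_tube(
    zs,
    cx = rep(0, nz), cy = spec$c_offset(zs),
    ax = spec$a(zs), ay = spec$b(zs), n = n,
    radial_noise = if (spec$noise_amp > 0) {
      stats::runif(nz * n + 2L, -spec$noise_amp, spec$noise_amp)
    }
  )

  nb <- max(8L, n %/% 2L)
  zn <- seq(zr[2L], zr[2L] + spec$nasal_length,
            length.out = max(2L, ceiling(spec$nasal_length *
                                           spec$axial_resolution) + 1L))
  cyn <- rep(spec$c_offset(zr[2L]), length(zn))
  right <- .closed_tube(
    zn, cx = rep(-spec$nasal_x_offset, length(zn)), cy = cyn,
    ax = rep(spec$nasal_radii[1L], length(zn)),
    ay = rep(spec$nasal_radii[1L], length(zn)), n = nb
  )
  left <- .closed_tube(
    zn, cx = rep(spec$nasal_x_offset, length(zn)), cy = cyn,
    ax = rep(spec$nasal_radii[2L], length(zn)),
    ay = rep(spec$nasal_radii[2L], length(zn)), n = nb
  )

  off1 <- nrow(ph$vertices)
  off2 <- off1 + nrow(right$vertices)
  triangle_mesh(
    rbind(ph$vertices, right$vertices, left$vertices),
    rbind(ph$faces, right$faces + off1, left$faces + off2)
  )
}

#' Exact cross-section of the synthetic pharynx
#'
#' Analytic oracle for [slice_mesh()]: within the pharyngeal range the
#' section at height z is the ellipse with semi-axes `a(z)`, `b(z)` centered
#' at `(0, c(z))`, so the area is `pi * a(z) * b(z)`, `Ys = c(z) + b(z)` and
#' `Yc = c(z) - b(z)`.
#'
#' @param spec an [airway_spec()].
#' @param z plane height (mm), inside `pharynx_z_range`.
#' @param n_points number of polygon points used to represent the exact
#'   contour.
#' @return A [cross_section()] whose `area` is the exact ellipse area.
#' @export
analytic_cross_section <- function(spec, z, n_points = 256L) {
  stopifnot(inherits(spec, "airway_spec"))
  zr <- spec$pharynx_z_range
  if (z < zr[1L] || z > zr[2L]) {
    stop(sprintf(
      "z = %.3f mm outside the pharynx range [%.3f, %.3f]", z, zr[1L], zr[2L]
    ), call. = FALSE)
  }
  a <- spec$a(z); b <- spec$b(z); cc <- spec$c_offset(z)
  th <- 2 * pi * (seq_len(n_points) - 1L) / n_points
  poly <- cbind(a * cos(th), cc + b * sin(th))
  poly <- rbind(poly, poly[1L, ])
  sec <- cross_section(z, list(poly), area = pi * a * b)
  sec$ys <- cc + b
  sec$yc <- cc - b
  sec$width_x <- 2 * a
  sec$depth_y <- 2 * b
  sec$x_c <- 0
  sec
}

#' Read an airway spec from JSON
#'
#' JSON carries constant semi-axes and offsets (functions are not
#' serializable); see [airway_spec()] for field meanings.
#'
#' @param path path to a JSON file.
#' @return An [airway_spec()].
#' @export
read_airway_spec <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("spec file not found: %s", path), call. = FALSE)
  }
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(airway_spec, j)
}
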
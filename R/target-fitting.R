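#' Target section dimensions for follow-up prediction
#'
#' A fit target prescribes, at one controlled pivotal plane, either the
#' postoperative widths (lateral `width_x` and anteroposterior `depth_y`) or
#' the postoperative area that the deformed geometry should reach.
#'
#' @param z plane height (mm); must coincide with the middle or lower
#'   pivotal plane of the configuration being fitted (within 1e-3 mm).
#' @param mode `"widths"` or `"area"`.
#' @param width_x,depth_y target widths (mm), required for `mode = "widths"`.
#' @param area target area (mm^2), required for `mode = "area"`.
#' @param tolerance convergence tolerance: mm on each width residual
#'   (default 0.05), or relative area error (default 0.005).
#' @return An object of class `fit_target`.
#' @export
fit_target <- function(z, mode = c("widths", "area"), width_x = NULL,
                       depth_y = NULL, area = NULL, tolerance = NULL) {
  mode <- match.arg(mode)
  if (mode == "widths") {
    if (is.null(width_x) || is.null(depth_y)) {
      stop("widths mode needs both `width_x` and `depth_y`", call. = FALSE)
    }
    if (!is.null(area)) {
      stop("widths mode must not carry an `area` target", call. = FALSE)
    }
    if (width_x <= 0 || depth_y <= 0) {
      stop("target widths must be positive", call. = FALSE)
    }
    if (is.null(tolerance)) tolerance <- 0.05
  } else {
    if (is.null(area)) stop("area mode needs `area`", call. = FALSE)
    if (!is.null(width_x) || !is.null(depth_y)) {
      stop("area mode must not carry width targets", call. = FALSE)
    }
    if (area <= 0) stop("target area must be positive", call. = FALSE)
    if (is.null(tolerance)) tolerance <- 0.005
  }
  if (tolerance <= 0) stop("`tolerance` must be positive", call. = FALSE)
  structure(
    list(z = as.numeric(z), mode = mode,
         width_x = if (is.null(width_x)) NA_real_ else as.numeric(width_x),
         depth_y = if (is.null(depth_y)) NA_real_ else as.numeric(depth_y),
         area = if (is.null(area)) NA_real_ else as.numeric(area),
         tolerance = as.numeric(tolerance)),
    class = "fit_target"
  )
}

#' Fit deformation parameters to target cross-section dimensions
#'
#' Fixed-point iteration of the follow-up prediction: the current
#' configuration is applied to the preoperative mesh, the deformed geometry
#' is sliced at every target plane, and each plane's parameters are updated
#' from the measured shortfall. Width targets use an undamped difference
#' step -- `dy <- dy + (target depth - achieved depth)` and
#' `dx_half <- dx_half + (target width - achieved width) / 2` -- which is
#' exact in one step where the field responds linearly at the control
#' points. Area targets scale the plane's `(dy, dx_half)` jointly by a
#' 0.5-damped factor built from `sqrt(target area / achieved area)` (the
#' area responds nonlinearly). All target planes are fitted simultaneously.
#' Parameters are clamped at zero: the model only enlarges.
#'
#' @param mesh the preoperative [triangle_mesh()].
#' @param config base [deformation_config()] supplying the plane heights
#'   and any known `ys`/`yc`; its `dy`/`dx_half` values seed the iteration.
#' @param targets a [fit_target()] or a list of them, one per controlled
#'   plane at most.
#' @param max_iterations iteration cap (default 50).
#' @return An object of class `airway_fit`; non-convergence is reported in
#'   its `converged` flag, not as an error.
#' @seealso [coef.airway_fit()], [predict.airway_fit()], [plot.airway_fit()]
#' @export
fit_deformation <- function(mesh, config, targets, max_iterations = 50L) {
  stopifnot(inherits(mesh, "triangle_mesh"),
            inherits(config, "deformation_config"))
  if (inherits(targets, "fit_target")) targets <- list(targets)
  if (length(targets) < 1L) stop("at least one target is required", call. = FALSE)
  bb <- mesh_bounding_box(mesh)
  roles <- vapply(targets, function(tg) {
    if (!inherits(tg, "fit_target")) {
      stop("`targets` must be fit_target objects", call. = FALSE)
    }
    if (tg$z < bb[1L, 3L] || tg$z > bb[2L, 3L]) {
      stop(sprintf("target plane z = %.3f mm lies outside the mesh", tg$z),
           call. = FALSE)
    }
    if (abs(tg$z - config$middle$z) <= 1e-3) return("middle")
    if (abs(tg$z - config$lower$z) <= 1e-3) return("lower")
    stop(sprintf(
      "target z = %.3f mm matches no controlled pivotal plane", tg$z
    ), call. = FALSE)
  }, character(1L))
  if (anyDuplicated(roles)) {
    stop("at most one target per controlled plane", call. = FALSE)
  }

  # Anatomy is estimated once from the preoperative mesh and reused in every
  # iteration so the field the fit searches over is the field that will be
  # applied.
  anatomy <- .config_anatomy(config, mesh = mesh)
  pre_secs <- lapply(targets, function(tg) slice_mesh(mesh, tg$z))
  params <- list(
    middle = c(dy = config$middle$dy, dx = config$middle$dx_half),
    lower = c(dy = config$lower$dy, dx = config$lower$dx_half)
  )
  cfg_with <- function(params) {
    deformation_config(
      top = config$top,
      middle = pivotal_plane(config$middle$z, params$middle[["dy"]],
                             params$middle[["dx"]],
                             ys = .na_null(config$middle$ys),
                             yc = .na_null(config$middle$yc),
                             label = config$middle$label),
      lower = pivotal_plane(config$lower$z, params$lower[["dy"]],
                            params$lower[["dx"]],
                            ys = .na_null(config$lower$ys),
                            yc = .na_null(config$lower$yc),
                            label = config$lower$label),
      spine_fix_margin = config$spine_fix_margin
    )
  }

  history <- numeric(0)
  residuals <- NULL
  converged <- FALSE
  iterations <- 0L
  for (it in seq_len(max_iterations)) {
    iterations <- it
    cur_cfg <- cfg_with(params)
    deformed <- deform_mesh(mesh, cur_cfg, anatomy = anatomy)
    resid <- list()
    all_ok <- TRUE
    for (k in seq_along(targets)) {
      tg <- targets[[k]]
      role <- roles[k]
      sec <- slice_mesh(deformed, tg$z)
      if (tg$mode == "widths") {
        r_depth <- tg$depth_y - sec$depth_y
        r_width <- tg$width_x - sec$width_x
        resid[[role]] <- c(depth = abs(r_depth), width = abs(r_width))
        ok <- abs(r_depth) <= tg$tolerance && abs(r_width) <= tg$tolerance
        if (!ok) {
          params[[role]][["dy"]] <- max(0, params[[role]][["dy"]] + r_depth)
          params[[role]][["dx"]] <- max(0, params[[role]][["dx"]] + r_width / 2)
        }
      } else {
        rel <- abs(sec$area - tg$area) / tg$area
        resid[[role]] <- c(area_rel = rel)
        ok <- rel <= tg$tolerance
        if (!ok) {
          if (params[[role]][["dy"]] == 0 && params[[role]][["dx"]] == 0) {
            # Seed from the preoperative section assuming proportional growth.
            pre <- pre_secs[[k]]
            s <- sqrt(tg$area / pre$area) - 1
            if (s > 0) {
              params[[role]][["dy"]] <- s * pre$depth_y
              params[[role]][["dx"]] <- s * pre$width_x / 2
            }
          } else {
            f <- 1 + 0.5 * (sqrt(tg$area / sec$area) - 1)
            params[[role]][["dy"]] <- max(0, params[[role]][["dy"]] * f)
            params[[role]][["dx"]] <- max(0, params[[role]][["dx"]] * f)
          }
        }
      }
      all_ok <- all_ok && ok
    }
    residuals <- unlist(resid)
    history <- c(history, max(residuals))
    if (all_ok) {
      converged <- TRUE
      break
    }
  }

  structure(
    list(
      config = cfg_with(params),
      iterations = iterations,
      residuals = residuals,
      converged = converged,
      history = history,
      targets = targets,
      target_roles = roles,
      anatomy = anatomy,
      mesh_info = list(vertices = nrow(mesh$vertices),
                       facets = nrow(mesh$faces))
    ),
    class = "airway_fit"
  )
}

.na_null <- function(x) if (is.na(x)) NULL else x

#' @export
print.airway_fit <- function(x, ...) {
  cat(sprintf(
    "<airway_fit> %s after %d iteration(s); max residual %.4g\n",
    if (x$converged) "converged" else "NOT converged",
    x$iterations, max(x$residuals)
  ))
  print(x$config)
  invisible(x)
}

#' @export
summary.airway_fit <- function(object, ...) {
  cat(sprintf(
    "Pivotal-plane deformation fit (%d targets, %d facets)\n",
    length(object$targets), object$mesh_info$facets
  ))
  cat(sprintf(
    "  %s in %d iteration(s)\n",
    if (object$converged) "converged" else "stopped without converging",
    object$iterations
  ))
  cat("  residuals:\n")
  for (nm in names(object$residuals)) {
    cat(sprintf("    %-14s %.5f\n", nm, object$residuals[[nm]]))
  }
  cat("  fitted parameters (mm):\n")
  co <- coef(object)
  for (nm in names(co)) cat(sprintf("    %-16s %.4f\n", nm, co[[nm]]))
  invisible(object)
}

#' Fitted deformation parameters
#'
#' @param object an `airway_fit`.
#' @param ... unused.
#' @return Named numeric vector `dy_middle`, `dx_half_middle`, `dy_lower`,
#'   `dx_half_lower` (mm).
#' @export
coef.airway_fit <- function(object, ...) {
  c(
    dy_middle = object$config$middle$dy,
    dx_half_middle = object$config$middle$dx_half,
    dy_lower = object$config$lower$dy,
    dx_half_lower = object$config$lower$dx_half
  )
}

#' Apply a fitted deformation to a mesh
#'
#' @param object an `airway_fit`.
#' @param mesh the mesh to deform; defaults to reusing the anatomy captured
#'   at fit time, so the mesh should be the one the fit was computed on (or
#'   pass `anatomy = NULL` behavior by deforming manually with
#'   [deform_mesh()]).
#' @param ... unused.
#' @return The deformed [triangle_mesh()].
#' @export
predict.airway_fit <- function(object, mesh, ...) {
  deform_mesh(mesh, object$config, anatomy = object$anatomy)
}

#' Residuals of a deformation fit
#'
#' @param object an `airway_fit`.
#' @param ... unused.
#' @return Named numeric vector of final absolute residuals (mm, or
#'   relative area error).
#' @export
residuals.airway_fit <- function(object, ...) object$residuals

#' Plot pre- and post-fit contours at the target planes
#'
#' @param x an `airway_fit`.
#' @param mesh the preoperative mesh used in the fit.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.airway_fit <- function(x, mesh, ...) {
  deformed <- predict(x, mesh)
  n <- length(x$targets)
  old <- graphics::par(mfrow = c(1, n))
  on.exit(graphics::par(old))
  for (k in seq_len(n)) {
    z <- x$targets[[k]]$z
    pre <- slice_mesh(mesh, z)
    post <- slice_mesh(deformed, z)
    xl <- range(unlist(lapply(c(pre$contours, post$contours), function(p) p[, 1])))
    yl <- range(unlist(lapply(c(pre$contours, post$contours), function(p) p[, 2])))
    graphics::plot(NA, xlim = xl, ylim = yl, asp = 1,
                   xlab = "x (mm)", ylab = "y (mm)",
                   main = sprintf("z = %.1f mm", z), ...)
    for (p in pre$contours) graphics::lines(p, col = "grey40")
    for (p in post$contours) graphics::lines(p, col = "red3")
    graphics::legend("topright", legend = c("preoperative", "fitted"),
                     col = c("grey40", "red3"), lty = 1, bty = "n", cex = 0.8)
  }
  invisible(x)
}
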
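#' CFD case metadata for the airway flow analysis
#'
#' Records the boundary conditions and convergence criteria of the
#' steady-state respiratory airflow analysis so an external solver run can
#' be reproduced: breathing at rest at ambient pressure 1.013e5 Pa and
#' 25 degrees C, air viscosity 1.822e-5 Pa.s, mass flow fixed at the inlet,
#' static pressure fixed at the outlet, iteration residual below 1e-6 or
#' inlet/outlet mass-flow imbalance below 0.5%, and a near-wall y+ kept
#' between 2 and 5. This package only writes and reads the metadata; it
#' never solves a flow field.
#'
#' @param ambient_pressure Pa.
#' @param temperature degrees C.
#' @param viscosity Pa.s.
#' @param inlet_condition,outlet_condition boundary condition identifiers.
#' @param residual_criterion average iteration residual threshold.
#' @param mass_flow_imbalance_criterion fraction.
#' @param y_plus_range length-2 increasing numeric.
#' @return An object of class `cfd_case_spec`.
#' @export
cfd_case_spec <- function(ambient_pressure = 1.013e5,
                          temperature = 25,
                          viscosity = 1.822e-5,
                          inlet_condition = "mass-flow-fixed",
                          outlet_condition = "static-pressure-fixed",
                          residual_criterion = 1e-6,
                          mass_flow_imbalance_criterion = 0.005,
                          y_plus_range = c(2, 5)) {
  if (ambient_pressure <= 0 || viscosity <= 0) {
    stop("physical constants must be positive", call. = FALSE)
  }
  if (length(y_plus_range) != 2L || y_plus_range[1L] >= y_plus_range[2L]) {
    stop("`y_plus_range` must be an increasing pair", call. = FALSE)
  }
  structure(
    list(
      ambient_pressure = ambient_pressure,
      temperature = temperature,
      viscosity = viscosity,
      inlet_condition = inlet_condition,
      outlet_condition = outlet_condition,
      residual_criterion = residual_criterion,
      mass_flow_imbalance_criterion = mass_flow_imbalance_criterion,
      y_plus_range = as.numeric(y_plus_range)
    ),
    class = "cfd_case_spec"
  )
}

#' @export
print.cfd_case_spec <- function(x, ...) {
  cat("<cfd_case_spec>\n")
  cat(sprintf("  ambient %.4g Pa at %.1f C, viscosity %.4g Pa.s\n",
              x$ambient_pressure, x$temperature, x$viscosity))
  cat(sprintf("  inlet %s, outlet %s\n", x$inlet_condition, x$outlet_condition))
  cat(sprintf("  residual < %.0e or mass-flow imbalance < %.2g%%; y+ in [%g, %g]\n",
              x$residual_criterion, 100 * x$mass_flow_imbalance_criterion,
              x$y_plus_range[1L], x$y_plus_range[2L]))
  invisible(x)
}

#' Write a CFD case file
#'
#' Serializes the case constants plus the requested inlet mass flow to JSON
#' for consumption by external meshing/solver tooling. The file round-trips
#' losslessly through [read_cfd_case()].
#'
#' @param spec a [cfd_case_spec()].
#' @param flow_rate requested volume flow at the inlet (cm^3/s, > 0).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cfd_case <- function(spec, flow_rate, path) {
  stopifnot(inherits(spec, "cfd_case_spec"))
  if (!is.numeric(flow_rate) || length(flow_rate) != 1L || flow_rate <= 0) {
    stop("`flow_rate` must be a single positive value in cm^3/s",
         call. = FALSE)
  }
  jsonlite::write_json(
    c(unclass(spec), list(flow_rate_cm3_s = flow_rate)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_cfd_case
#' @return `read_cfd_case()` returns a list with elements `spec` (a
#'   [cfd_case_spec()]) and `flow_rate_cm3_s`.
#' @export
read_cfd_case <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("case file not found: %s", path), call. = FALSE)
  }
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  flow <- j$flow_rate_cm3_s
  j$flow_rate_cm3_s <- NULL
  list(spec = do.call(cfd_case_spec, j), flow_rate_cm3_s = flow)
}
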
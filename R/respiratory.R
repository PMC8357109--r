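#' Single-naris rhinomanometric resistance
#'
#' Anterior-mask rhinomanometry measures, for one naris, the nasal airflow
#' F, the anterior pressure P1 and the posterior pressure P2 (tapped through
#' the plugged contralateral naris); the resistance is their quotient
#' `(P1 - P2) / F`.
#'
#' @param p1 anterior pressure (Pa).
#' @param p2 posterior pressure (Pa).
#' @param flow nasal airflow (cm^3/s); must be non-zero.
#' @return Resistance in Pa.s/cm^3. A zero pressure difference yields 0 with
#'   a non-physical-measurement warning.
#' @export
naris_resistance <- function(p1, p2, flow) {
  stopifnot(is.numeric(p1), is.numeric(p2), is.numeric(flow))
  if (any(flow == 0)) {
    stop("zero flow: resistance is undefined; check the flow channel or use a non-zero reading",
         call. = FALSE)
  }
  r <- (p1 - p2) / flow
  if (any(r == 0)) {
    warning("zero pressure difference gives zero resistance, which is non-physical",
            call. = FALSE)
  }
  r
}

#' Total nasal resistance of both nares in parallel
#'
#' The two nasal passages carry flow side by side between shared anterior
#' and posterior pressures, so the total resistance follows Ohm's law for
#' parallel resistances: `R_total = R_left * R_right / (R_left + R_right)`.
#'
#' @param r_left,r_right per-naris resistances (Pa.s/cm^3, > 0). An infinite
#'   value models a fully blocked naris and returns the other resistance.
#' @return Total resistance (Pa.s/cm^3).
#' @export
total_resistance <- function(r_left, r_right) {
  if (!is.numeric(r_left) || !is.numeric(r_right) ||
        any(r_left <= 0) || any(r_right <= 0)) {
    stop("per-naris resistances must be positive", call. = FALSE)
  }
  out <- r_left * r_right / (r_left + r_right)
  rl <- rep_len(r_left, length(out))
  rr <- rep_len(r_right, length(out))
  out[rl == rr] <- rl[rl == rr] / 2 # exact halving of equal branches
  li <- is.infinite(rl)
  ri <- is.infinite(rr)
  out[li & !ri] <- rr[li & !ri] # fully blocked naris: the other carries all flow
  out[ri & !li] <- rl[ri & !li]
  out
}

#' Rhinomanometric pressure-flow curve
#'
#' Readings of pressure difference versus volume flow for one naris (or the
#' whole nose), one breathing phase and one timepoint. Inhalation and
#' exhalation are both stored with positive `delta_p` and `flow`; the
#' `phase` field carries the direction.
#'
#' @param delta_p pressure differences (Pa).
#' @param flow volume flows (cm^3/s).
#' @param naris `"left"`, `"right"` or `"total"`.
#' @param phase `"inhale"` or `"exhale"`.
#' @param timepoint `"pre"` or `"post"`.
#' @return An object of class `pf_curve` sorted by `|delta_p|`.
#' @export
pressure_flow_curve <- function(delta_p, flow, naris = "total",
                                phase = "inhale", timepoint = "pre") {
  stopifnot(is.numeric(delta_p), is.numeric(flow),
            length(delta_p) == length(flow))
  if (length(delta_p) < 1L) {
    stop("a pressure-flow curve needs at least one point", call. = FALSE)
  }
  naris <- match.arg(naris, c("left", "right", "total"))
  phase <- match.arg(phase, c("inhale", "exhale"))
  timepoint <- match.arg(timepoint, c("pre", "post"))
  if (any(sign(delta_p) * sign(flow) < 0)) {
    stop("`delta_p` and `flow` must share sign conventions within a phase",
         call. = FALSE)
  }
  o <- order(abs(delta_p))
  structure(
    list(naris = naris, phase = phase, timepoint = timepoint,
         delta_p = delta_p[o], flow = flow[o]),
    class = "pf_curve"
  )
}

#' @export
print.pf_curve <- function(x, ...) {
  cat(sprintf("<pf_curve> %s naris, %s, %s-op: %d points, |dP| %.4g..%.4g Pa\n",
              x$naris, x$phase, x$timepoint, length(x$delta_p),
              min(abs(x$delta_p)), max(abs(x$delta_p))))
  invisible(x)
}

#' Resistance read off a pressure-flow curve at a reference pressure
#'
#' Interpolates the flow linearly at the reference pressure difference and
#' returns `reference_delta_p / flow`. The default reference of 100 Pa is
#' the international anterior-rhinomanometry convention.
#'
#' @param curve a [pressure_flow_curve()].
#' @param reference_delta_p reference pressure difference (Pa); must be
#'   bracketed by the curve (no extrapolation). A single-point curve is
#'   usable only at its own `delta_p`.
#' @return Resistance (Pa.s/cm^3).
#' @export
resistance_from_curve <- function(curve, reference_delta_p = 100) {
  stopifnot(inherits(curve, "pf_curve"))
  dp <- abs(curve$delta_p)
  fl <- abs(curve$flow)
  ref <- abs(reference_delta_p)
  if (length(dp) == 1L) {
    if (abs(dp - ref) > 1e-9) {
      stop("single-point curve: reference must equal its own delta_p",
           call. = FALSE)
    }
    return(ref / fl)
  }
  if (ref < min(dp) || ref > max(dp)) {
    stop(sprintf(
      "reference %.4g Pa outside the measured range [%.4g, %.4g] Pa; extrapolation refused",
      ref, min(dp), max(dp)
    ), call. = FALSE)
  }
  flow_ref <- stats::approx(dp, fl, xout = ref, ties = mean)$y
  ref / flow_ref
}

#' Read pressure-flow curves from CSV
#'
#' Expected columns: `naris`, `phase`, `timepoint`, `delta_p_pa`,
#' `flow_cm3_s`. One curve is built per (naris, phase, timepoint) group.
#'
#' @param path CSV path.
#' @return Named list of [pressure_flow_curve()]s.
#' @export
read_pressure_flow_csv <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("CSV file not found: %s", path), call. = FALSE)
  }
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("naris", "phase", "timepoint", "delta_p_pa", "flow_cm3_s")
  if (!all(need %in% names(d))) {
    stop(sprintf("CSV must have columns: %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  groups <- split(d, interaction(d$naris, d$phase, d$timepoint, drop = TRUE))
  out <- lapply(groups, function(g) {
    pressure_flow_curve(g$delta_p_pa, g$flow_cm3_s, naris = g$naris[1L],
                        phase = g$phase[1L], timepoint = g$timepoint[1L])
  })
  names(out) <- names(groups)
  out
}

#' Grid-refinement series of a CFD mesh-independence study
#'
#' Pairs of total cell count and resulting inlet-outlet pressure difference
#' (optionally with the near-wall y+ of each mesh).
#'
#' @param cells total cell counts, strictly increasing.
#' @param delta_p pressure differences (Pa, > 0).
#' @param y_plus optional non-dimensional wall distances.
#' @return An object of class `refinement_series`.
#' @export
refinement_series <- function(cells, delta_p, y_plus = NULL) {
  stopifnot(is.numeric(cells), is.numeric(delta_p),
            length(cells) == length(delta_p))
  if (length(cells) >= 2L && any(diff(cells) <= 0)) {
    stop("`cells` must be strictly increasing", call. = FALSE)
  }
  if (any(delta_p <= 0)) stop("`delta_p` must be positive", call. = FALSE)
  if (!is.null(y_plus) && length(y_plus) != length(cells)) {
    stop("`y_plus` must match `cells` in length", call. = FALSE)
  }
  structure(
    list(cells = as.numeric(cells), delta_p = as.numeric(delta_p),
         y_plus = if (is.null(y_plus)) rep(NA_real_, length(cells)) else as.numeric(y_plus)),
    class = "refinement_series"
  )
}

#' Read a refinement series from CSV
#'
#' Expected columns: `cells`, `delta_p_pa`, optional `y_plus`.
#'
#' @param path CSV path.
#' @return A [refinement_series()].
#' @export
read_refinement_csv <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("CSV file not found: %s", path), call. = FALSE)
  }
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("cells", "delta_p_pa") %in% names(d))) {
    stop("CSV must have columns `cells` and `delta_p_pa`", call. = FALSE)
  }
  refinement_series(d$cells, d$delta_p_pa,
                    y_plus = if ("y_plus" %in% names(d)) d$y_plus)
}

#' Recommend a minimum mesh size from a refinement series
#'
#' Takes the finest mesh's pressure difference as the reference and returns
#' the smallest cell count whose pressure difference lies within
#' `relative_tolerance` of it. The default tolerance of 10% encodes the
#' usual engineering judgement for pressure-drop mesh independence.
#'
#' @param series a [refinement_series()] with >= 2 points.
#' @param relative_tolerance acceptable relative deviation from the finest
#'   mesh (fraction, default 0.10).
#' @return An object of class `refinement_assessment`: list with
#'   `recommended_cells`, `relative_tolerance`, `reference_delta_p` and a
#'   data frame `deviations` of per-point relative deviations.
#' @export
assess_refinement <- function(series, relative_tolerance = 0.10) {
  stopifnot(inherits(series, "refinement_series"))
  if (length(series$cells) < 2L) {
    stop("refinement assessment needs at least 2 points", call. = FALSE)
  }
  if (relative_tolerance <= 0) {
    stop("`relative_tolerance` must be positive", call. = FALSE)
  }
  ref <- series$delta_p[length(series$delta_p)]
  dev <- abs(series$delta_p - ref) / ref
  ok <- dev <= relative_tolerance
  structure(
    list(
      recommended_cells = min(series$cells[ok]),
      relative_tolerance = relative_tolerance,
      reference_delta_p = ref,
      deviations = data.frame(
        cells = series$cells, delta_p = series$delta_p,
        y_plus = series$y_plus, relative_deviation = dev
      )
    ),
    class = "refinement_assessment"
  )
}

#' @export
print.refinement_assessment <- function(x, ...) {
  cat(sprintf(
    "<refinement_assessment> recommended minimum: %.1f million cells (tolerance %.0f%% of %.4g Pa)\n",
    x$recommended_cells / 1e6, 100 * x$relative_tolerance, x$reference_delta_p
  ))
  print(x$deviations, row.names = FALSE)
  invisible(x)
}
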
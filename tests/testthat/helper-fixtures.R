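# Fixtures built in code: smallest closed solid, a UV sphere for smoothing
# tests, and standard synthetic-airway configurations.

make_tetra <- function() {
  triangle_mesh(
    vertices = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
    faces = rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3))
  )
}

# Closed UV sphere of radius r with optional uniform radial noise.
make_uv_sphere <- function(r = 10, n_th = 48L, n_ph = 24L, noise_amp = 0,
                           seed = 3L) {
  th <- seq(0, 2 * pi, length.out = n_th + 1L)[-1L]
  ph <- seq(0, pi, length.out = n_ph + 1L)[c(-1L, -(n_ph + 1L))]
  g <- expand.grid(th = th, ph = ph)
  np <- nrow(g)
  rad <- rep(r, np + 2L)
  if (noise_amp > 0) {
    set.seed(seed)
    rad <- r + stats::runif(np + 2L, -noise_amp, noise_amp)
  }
  v <- cbind(
    rad[seq_len(np)] * sin(g$ph) * cos(g$th),
    rad[seq_len(np)] * sin(g$ph) * sin(g$th),
    rad[seq_len(np)] * cos(g$ph)
  )
  v <- rbind(v, c(0, 0, rad[np + 1L]), c(0, 0, -rad[np + 2L]))
  top <- np + 1L
  bot <- np + 2L
  idx <- function(i, j) (j - 1L) * n_th + ((i - 1L) %% n_th) + 1L
  i <- seq_len(n_th)
  fl <- list()
  for (j in seq_len(length(ph) - 1L)) {
    fl[[j]] <- rbind(
      cbind(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L)),
      cbind(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L))
    )
  }
  fl[[length(ph)]] <- cbind(idx(i + 1L, 1L), idx(i, 1L), top)
  fl[[length(ph) + 1L]] <- cbind(idx(i, length(ph)), idx(i + 1L, length(ph)), bot)
  triangle_mesh(v, do.call(rbind, fl))
}

# Constant elliptical tube with a two-tube nasal region, vertex at every
# quadrant extreme (angular resolution divisible by 4).
default_tube_spec <- function(...) {
  airway_spec(pharynx_z_range = c(0, 80), a = 10, b = 6, c_offset = 0, ...)
}

# Pivotal planes spaced like the worked surgical example (21 and 23 mm
# inter-plane gaps), all strictly inside the pharyngeal range.
default_config <- function(dy_m = 0, dx_m = 0, dy_l = 0, dx_l = 0, ...) {
  deformation_config(
    top = pivotal_plane(60, label = "fixed"),
    middle = pivotal_plane(37, dy = dy_m, dx_half = dx_m,
                           label = "soft-palate level"),
    lower = pivotal_plane(16, dy = dy_l, dx_half = dx_l,
                          label = "epiglottis level"),
    ...
  )
}

# Exact one-sided derivative at x0 for piecewise-quadratic functions
# (second-order 3-point formula); dir = -1 from below, +1 from above.
one_sided_deriv <- function(f, x0, dir, h = 0.1) {
  (3 * f(x0) - 4 * f(x0 - dir * h) + f(x0 - dir * 2 * h)) / (2 * dir * h)
}

bundled_refinement_csv <- function() {
  system.file("extdata", "grid-refinement-series.csv",
              package = "airwaydeform", mustWork = TRUE)
}
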
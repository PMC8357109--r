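# C1 piecewise-quadratic building blocks for the displacement field.
#
# .qh_eval evaluates the unique two-piece quadratic spline on [x0, x1] (knot
# at the midpoint) matching prescribed endpoint values and slopes. Quadratic
# Hermite data need two pieces: a single quadratic has three degrees of
# freedom, four endpoint conditions are imposed.
.qh_eval <- function(x, x0, v0, s0, x1, v1, s1) {
  h <- (x1 - x0) / 2
  xk <- x0 + h
  a <- ((s1 - s0) / (2 * h) + (v1 - v0 - (s0 + s1) * h) / h^2) / 2
  b <- (s1 - s0) / (2 * h) - a
  out <- numeric(length(x))
  lo <- x <= xk
  d0 <- x[lo] - x0
  d1 <- x[!lo] - x1
  out[lo] <- v0 + s0 * d0 + a * d0^2
  out[!lo] <- v1 + s1 * d1 + b * d1^2
  out
}

# Axial profile of one deformation parameter. Cardinal in the plane values:
# profile(z_l) = p_l, profile(z_m) = p_m, with zero value and slope at the
# top plane z_t, C1 everywhere, and a constant (C1, zero-slope) extension
# below the lower plane. Linear in (p_l, p_m).
.axial_profile <- function(z, zl, zm, zt, pl, pm) {
  g <- zt - zm
  out <- numeric(length(z))
  up <- z >= zm & z < zt
  out[up] <- pm * ((zt - z[up]) / g)^2
  mid <- z >= zl & z < zm
  if (any(mid)) {
    out[mid] <- .qh_eval(z[mid], zl, pl, 0, zm, pm, -2 * pm / g)
  }
  out[z < zl] <- pl
  out # zero for z >= zt
}

# C1 interpolation of a per-plane anatomical quantity (Ys, Yc, x_c, w_half,
# y at the widest point) across [z_l, z_t], clamped outside. Zero slope is
# imposed at both outer planes so the clamped extensions are C1; the slope
# at the middle plane is the centered finite difference.
.anat_interp <- function(z, zl, zm, zt, vl, vm, vt) {
  sm <- (vt - vl) / (zt - zl)
  out <- numeric(length(z))
  out[z >= zt] <- vt
  up <- z >= zm & z < zt
  if (any(up)) out[up] <- .qh_eval(z[up], zm, vm, sm, zt, vt, 0)
  mid <- z > zl & z < zm
  if (any(mid)) out[mid] <- .qh_eval(z[mid], zl, vl, 0, zm, vm, sm)
  out[z <= zl] <- vl
  out
}

# C1 falloff in y for the lateral displacement: 1 at and below y1 (the
# section's widest-point height), 0 at and above y2 (the spine-side wall),
# two quadratic pieces in between with zero slope at both ends. Vectorized
# over per-point bounds.
.smooth_falloff <- function(y, y1, y2) {
  t <- (y - y1) / (y2 - y1)
  out <- numeric(length(y))
  out[t <= 0] <- 1
  a <- t > 0 & t <= 0.5
  b <- t > 0.5 & t < 1
  out[a] <- 1 - 2 * t[a]^2
  out[b] <- 2 * (1 - t[b])^2
  out # zero for t >= 1
}
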
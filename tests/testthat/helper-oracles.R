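# Independent numerical oracles and tiny fixture builders.

# Surface of revolution of the ellipse (x = a sin u, z = c cos u) about the
# z axis, by adaptive quadrature; independent of the closed-form ellipsoid
# area formulas it checks.
oblate_area_quadrature <- function(a, c) {
  f <- function(u) 2 * pi * a * sin(u) * sqrt(a^2 * cos(u)^2 + c^2 * sin(u)^2)
  stats::integrate(f, 0, pi, rel.tol = 1e-12)$value
}

# Prolate case: rotate (x = b sin u, z = a cos u) about the long (z) axis.
prolate_area_quadrature <- function(a, b) {
  f <- function(u) 2 * pi * b * sin(u) * sqrt(b^2 * cos(u)^2 + a^2 * sin(u)^2)
  stats::integrate(f, 0, pi, rel.tol = 1e-12)$value
}

# Deterministic miniature visit table for exact-arithmetic checks.
tiny_visits <- function(T_a = c(15, 25, 35),
                        T_hd = T_a + 6,
                        T_th = T_a + 10,
                        T_ab = T_a + 2,
                        G = c(10, 500, 300),
                        M_mW = NULL) {
  v <- data.frame(
    T_a_C = T_a, T_hd_C = T_hd, T_th_C = T_th, T_ab_C = T_ab, G_Wm2 = G
  )
  if (!is.null(M_mW)) v$M_mW <- M_mW
  v
}

# Relative difference with a magnitude floor, so coefficients fitted at
# essentially zero do not blow up a relative comparison.
rel_diff <- function(x, ref) {
  floor_scale <- 1e-3 * max(abs(ref))
  max(abs(x - ref) / pmax(abs(ref), floor_scale))
}
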
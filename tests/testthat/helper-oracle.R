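# Independent oracles. These deliberately re-derive the physics and geometry
# with their own code paths (quadrature instead of closed forms, fine-grid
# energy balance instead of lumped coefficients) so package results can be
# checked against something that shares no implementation with them.

# Poiseuille resistance of a uniform tube, closed form (SI inputs)
oracle_tube_resistance <- function(diameter_m, length_m, mu = 0.0035) {
  128 * mu * length_m / (pi * diameter_m^4)
}

# area of a circle of diameter D truncated by a chord leaving lumen height h,
# by adaptive quadrature over horizontal strips (independent of the
# closed-form circular-segment formula)
oracle_truncated_circle_area <- function(height_mm, diameter_mm) {
  r <- diameter_mm / 2
  stats::integrate(function(z) 2 * sqrt(pmax(r^2 - z^2, 0)),
                   -r, height_mm - r,               # lumen occupies z <= h - r
                   rel.tol = 1e-10)$value
}

# local diameter-stenosis severity, re-implemented from the shape definitions
oracle_severity <- function(x, ds, len, center, profile, taper, shoulder = 1) {
  xi <- x - (center - len / 2)
  s <- numeric(length(x))
  inside <- xi >= 0 & xi <= len
  if (profile == "rectangular") {
    s[inside] <- ds
  } else if (taper == "focal") {
    s[inside] <- ds * (1 - cos(2 * pi * xi[inside] / len)) / 2
  } else {
    z <- xi[inside]
    v <- rep(ds, length(z))
    v[z < shoulder] <- ds * (1 - cos(pi * z[z < shoulder] / shoulder)) / 2
    dn <- z > len - shoulder
    v[dn] <- ds * (1 - cos(pi * (len - z[dn]) / shoulder)) / 2
    s[inside] <- v
  }
  s
}

# fine-grid 1-D energy-balance pressure drop for a lesioned straight vessel:
# viscous term integrated on its own grid (step_mm), plus a Borda-Carnot
# expansion per lesion from the grid-minimum area through the vena contracta.
# `lesions` is a list of plain lists with fields ds, len, center, cs
# ("concentric"/"eccentric"), profile, taper.
oracle_pressure_drop <- function(diameter_mm, length_mm, lesions, q_m3_s,
                                 kt = 1.04, cc_throat = 0.70,
                                 mu = 0.0035, rho = 1056, step_mm = 0.0125) {
  x <- seq(0, length_mm, by = step_mm)
  r <- diameter_mm / 2
  area <- rep(pi * r^2, length(x))                       # mm^2
  for (l in lesions) {
    s <- oracle_severity(x, l$ds, l$len, l$center, l$profile, l$taper)
    a <- if (l$cs == "concentric") {
      pi * ((1 - s) * r)^2
    } else {
      vapply((1 - s) * diameter_mm, oracle_truncated_circle_area,
             numeric(1), diameter_mm = diameter_mm)
    }
    area <- pmin(area, a)
  }
  a_m2 <- area * 1e-6
  integrand <- 8 * pi * mu / (a_m2^2) * q_m3_s           # dP/dx, Poiseuille
  dx <- step_mm * 1e-3
  visc <- sum((integrand[-1] + integrand[-length(integrand)]) / 2) * dx
  expn <- 0
  a_ref <- pi * r^2 * 1e-6
  for (l in lesions) {
    sel <- abs(x - l$center) <= l$len / 2
    a_min <- min(a_m2[sel])
    cc <- if (l$profile == "rectangular" || l$taper == "uniform") cc_throat else 1
    expn <- expn + kt * rho / 2 * (1 / (cc * a_min) - 1 / a_ref)^2 *
      q_m3_s * abs(q_m3_s)
  }
  visc + expn
}

# default placed lesion list for the oracle, mirroring the auto-placement
oracle_place <- function(n, len, length_mm, gap = 10) {
  total <- n * len + (n - 1) * gap
  start <- (length_mm - total) / 2
  centers <- start + len / 2 + (seq_len(n) - 1) * (len + gap)
  centers
}
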
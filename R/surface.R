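# Surface export: triangulated lumen surfaces for visual QC and
# interoperability with external CFD tooling. ASCII STL or legacy-ASCII VTK.

# combined local severity over all lesions (non-overlapping, so max works)
segment_severity <- function(segment, x_mm) {
  s <- numeric(length(x_mm))
  cs <- rep("concentric", length(x_mm))
  for (l in segment$lesions) {
    sl <- lesion_shape_function(l, x_mm)
    take <- sl > s
    s[take] <- sl[take]
    cs[take] <- l$cross_section
  }
  list(severity = s, cross_section = cs)
}

#' Cross-section boundary polygon at one axial station
#'
#' Concentric sections are circles narrowed in both planes; eccentric
#' sections are the reference circle truncated by a flat plaque face
#' (chord), leaving a residual lumen height `(1 - s) * D`.
#'
#' @param diameter_mm Reference diameter, mm.
#' @param severity Local diameter-stenosis fraction.
#' @param cross_section `"concentric"` or `"eccentric"`.
#' @param n Number of boundary points.
#' @return An `n x 2` matrix of (y, z) coordinates in mm.
#' @keywords internal
cross_section_polygon <- function(diameter_mm, severity,
                                  cross_section = "concentric", n = 64) {
  r <- diameter_mm / 2
  if (cross_section == "concentric" || severity <= 0) {
    rr <- (1 - severity) * r
    th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
    return(cbind(rr * cos(th), rr * sin(th)))
  }
  # eccentric: lumen is {z <= c} of the reference circle, chord at z = c
  h <- (1 - severity) * diameter_mm
  cz <- h - r
  th0 <- asin(pmin(pmax(cz / r, -1), 1))        # chord meets circle
  th <- seq(pi - th0, 2 * pi + th0, length.out = n)  # lower arc, ccw
  arc <- cbind(r * cos(th), r * sin(th))
  arc  # the chord is closed implicitly between the first and last points
}

polygon_area <- function(p) {
  y <- p[, 1]; z <- p[, 2]
  abs(sum(y * c(z[-1], z[1]) - c(y[-1], y[1]) * z)) / 2
}

#' Export a triangulated lumen surface
#'
#' Sweeps the cross-section polygons along the axis (a surface of revolution
#' for concentric sections, extruded truncated-circle sections for eccentric
#' ones), closes both ends with fans, and writes ASCII STL or legacy ASCII
#' VTK. Intended for visual QC; at each axial station the section area
#' matches the area profile to within about 1% for the default resolution.
#'
#' @param profile An [build_area_profile()] result.
#' @param path Output file.
#' @param format `"stl"` or `"vtk"`.
#' @param n_theta Boundary points per station.
#' @param max_stations Axial stations are thinned to at most this many.
#' @return Invisibly, `path`.
#' @export
export_surface <- function(profile, path, format = c("stl", "vtk"),
                           n_theta = 64, max_stations = 200) {
  stopifnot(inherits(profile, "area_profile"))
  format <- match.arg(format)
  x <- profile$x_mm
  if (length(x) > max_stations) {
    x <- x[unique(round(seq(1, length(x), length.out = max_stations)))]
  }
  sev <- segment_severity(profile$segment, x)
  verts <- lapply(seq_along(x), function(i) {
    p <- cross_section_polygon(profile$segment$diameter_mm,
                               sev$severity[i], sev$cross_section[i], n_theta)
    cbind(x[i], p)
  })
  tri <- list()
  n <- n_theta
  for (i in seq_len(length(x) - 1)) {
    a <- verts[[i]]; b <- verts[[i + 1]]
    for (j in seq_len(n)) {
      k <- if (j == n) 1L else j + 1L
      tri[[length(tri) + 1L]] <- rbind(a[j, ], b[j, ], b[k, ])
      tri[[length(tri) + 1L]] <- rbind(a[j, ], b[k, ], a[k, ])
    }
  }
  cap <- function(v, flip) {
    ctr <- colMeans(v)
    for (j in seq_len(n)) {
      k <- if (j == n) 1L else j + 1L
      t <- if (flip) rbind(ctr, v[k, ], v[j, ]) else rbind(ctr, v[j, ], v[k, ])
      tri[[length(tri) + 1L]] <<- t
    }
  }
  cap(verts[[1]], flip = TRUE)
  cap(verts[[length(verts)]], flip = FALSE)

  if (format == "stl") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid lumen", con)
    for (t in tri) {
      nrm <- normal_of(t)
      writeLines(sprintf("  facet normal %g %g %g", nrm[1], nrm[2], nrm[3]),
                 con)
      writeLines("    outer loop", con)
      for (r in 1:3) {
        writeLines(sprintf("      vertex %g %g %g", t[r, 1], t[r, 2], t[r, 3]),
                   con)
      }
      writeLines(c("    endloop", "  endfacet"), con)
    }
    writeLines("endsolid lumen", con)
  } else {
    pts <- do.call(rbind, verts)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("# vtk DataFile Version 3.0", "stenoflow lumen surface",
                 "ASCII", "DATASET POLYDATA",
                 sprintf("POINTS %d float", nrow(pts))), con)
    utils::write.table(pts, con, row.names = FALSE, col.names = FALSE)
    m <- length(x)
    polys <- list()
    idx <- function(i, j) (i - 1L) * n + (j - 1L)  # 0-based
    for (i in seq_len(m - 1)) for (j in seq_len(n)) {
      k <- if (j == n) 1L else j + 1L
      polys[[length(polys) + 1L]] <-
        c(4, idx(i, j), idx(i + 1, j), idx(i + 1, k), idx(i, k))
    }
    writeLines(sprintf("POLYGONS %d %d", length(polys), 5 * length(polys)),
               con)
    utils::write.table(do.call(rbind, polys), con, row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}

normal_of <- function(t) {
  u <- t[2, ] - t[1, ]
  v <- t[3, ] - t[1, ]
  n <- c(u[2] * v[3] - u[3] * v[2],
         u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  l <- sqrt(sum(n^2))
  if (l == 0) c(0, 0, 0) else n / l
}
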
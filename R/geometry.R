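#' Cross-sectional area of a concentric stenosis
#'
#' A concentric lesion narrows the lumen in both orthogonal planes, so the
#' stenosed cross-section is a circle whose diameter is `(1 - ds) * D`.
#' The corresponding area stenosis is `1 - (1 - ds)^2` (e.g. a 50% diameter
#' stenosis is a 75% area stenosis).
#'
#' @param ds_fraction Diameter stenosis as a fraction in `[0, 1)`.
#' @param diameter_mm Reference (healthy) lumen diameter in mm.
#' @return Lumen cross-sectional area in mm^2.
#' @seealso [csa_eccentric()]
#' @examples
#' csa_concentric(0.5, 3.5)   # 75% area stenosis
#' @export
csa_concentric <- function(ds_fraction, diameter_mm) {
  check_ds(ds_fraction)
  stopifnot(diameter_mm > 0)
  pi * ((1 - ds_fraction) * diameter_mm / 2)^2
}

#' Cross-sectional area of an eccentric (flat-plaque) stenosis
#'
#' An eccentric lesion narrows the lumen in one plane only. It is modelled as
#' a circular segment: the reference circle truncated by a flat plaque face
#' (a chord), leaving a residual lumen height `h = (1 - ds) * D`. At 50% DS
#' the chord passes through the centre and the area is exactly half the
#' reference area. Eccentric lesions are always milder in area terms than
#' concentric lesions of the same diameter stenosis.
#'
#' @inheritParams csa_concentric
#' @return Lumen cross-sectional area in mm^2.
#' @seealso [csa_concentric()]
#' @examples
#' csa_eccentric(0.5, 3.5) / csa_concentric(0, 3.5)  # exactly 0.5
#' @export
csa_eccentric <- function(ds_fraction, diameter_mm) {
  check_ds(ds_fraction)
  stopifnot(diameter_mm > 0)
  r <- diameter_mm / 2
  h <- (1 - ds_fraction) * diameter_mm
  # circular-segment area for height h measured from the intact wall
  r^2 * acos((r - h) / r) - (r - h) * sqrt(pmax(2 * r * h - h^2, 0))
}

check_ds <- function(ds) {
  if (any(!is.finite(ds)) || any(ds < 0) || any(ds >= 1)) {
    stop("invalid lesion: ds_fraction must lie in [0, 1); ",
         "a fully occluded vessel (ds >= 1) is not modelled", call. = FALSE)
  }
  invisible(ds)
}

#' Specify a single stenosis
#'
#' @param ds_fraction Peak diameter stenosis, fraction in `[0, 1)`.
#' @param length_mm Lesion length in mm (> 0).
#' @param cross_section `"concentric"` (narrowed in both orthogonal planes)
#'   or `"eccentric"` (narrowed in one plane; flat-plaque model).
#' @param profile Longitudinal profile: `"rounded"` (smooth) or
#'   `"rectangular"` (step edges over the whole lesion length).
#' @param taper For rounded lesions: `"focal"` (raised-cosine reaching peak
#'   DS only at mid-lesion) or `"uniform"` (constant peak DS plateau with
#'   short raised-cosine shoulders). Ignored for rectangular lesions.
#' @param center_mm Axial position of the lesion midpoint within its parent
#'   segment, in mm. `NA` (default) lets [build_area_profile()] and the study
#'   pipeline place the lesion (mid-vessel, or a centred serial set).
#' @param shoulder_mm Shoulder ramp length per end for uniform lesions, mm.
#' @return An object of class `lesion_spec`.
#' @examples
#' lesion_spec(0.7, 5)  # the study's basic stenosis
#' @export
lesion_spec <- function(ds_fraction, length_mm,
                        cross_section = c("concentric", "eccentric"),
                        profile = c("rounded", "rectangular"),
                        taper = c("focal", "uniform"),
                        center_mm = NA_real_,
                        shoulder_mm = 1) {
  check_ds(ds_fraction)
  cross_section <- match.arg(cross_section)
  profile <- match.arg(profile)
  taper <- match.arg(taper)
  if (!is.numeric(length_mm) || length_mm <= 0) {
    stop("invalid lesion: length_mm must be > 0", call. = FALSE)
  }
  if (shoulder_mm <= 0 || 2 * shoulder_mm > length_mm) {
    stop("invalid lesion: need 0 < shoulder_mm <= length_mm / 2", call. = FALSE)
  }
  structure(
    list(ds_fraction = ds_fraction, length_mm = length_mm,
         cross_section = cross_section, profile = profile, taper = taper,
         center_mm = center_mm, shoulder_mm = shoulder_mm),
    class = "lesion_spec")
}

#' @export
print.lesion_spec <- function(x, ...) {
  cat(sprintf("<lesion> %.0f%% DS, %g mm, %s, %s%s%s\n",
              100 * x$ds_fraction, x$length_mm, x$cross_section, x$profile,
              if (x$profile == "rounded") paste0(" ", x$taper) else "",
              if (is.finite(x$center_mm))
                sprintf(", centred at %g mm", x$center_mm) else ""))
  invisible(x)
}

#' Specify a vessel segment
#'
#' A rigid straight tube of constant reference diameter carrying zero or more
#' non-overlapping stenoses. The study's template is a 3.5 mm vessel, 50 mm
#' (single short lesions) or 100 mm (long and serial lesions) long.
#'
#' @param diameter_mm Reference healthy lumen diameter in mm.
#' @param length_mm Segment length in mm.
#' @param lesions A `lesion_spec` or list of them. Lesions without a
#'   `center_mm` are placed automatically: a single lesion mid-vessel, a
#'   serial set centred with edge-to-edge gaps of `gap_mm`.
#' @param gap_mm Edge-to-edge spacing used when auto-placing serial lesions
#'   (the study uses 10 mm).
#' @return An object of class `segment_spec` with lesions placed, sorted and
#'   validated (inside the segment, pairwise non-overlapping).
#' @examples
#' segment_spec(3.5, 100, rep(list(lesion_spec(0.7, 5)), 2))
#' @export
segment_spec <- function(diameter_mm = 3.5, length_mm = 50, lesions = list(),
                         gap_mm = 10) {
  stopifnot(diameter_mm > 0, length_mm > 0)
  if (inherits(lesions, "lesion_spec")) lesions <- list(lesions)
  stopifnot(all(vapply(lesions, inherits, logical(1), "lesion_spec")))
  lesions <- place_lesions(lesions, length_mm, gap_mm)
  seg <- structure(
    list(diameter_mm = diameter_mm, length_mm = length_mm,
         lesions = lesions, gap_mm = gap_mm),
    class = "segment_spec")
  validate_segment(seg)
  seg
}

# auto-placement: unplaced lesions form a centred train with fixed gaps
place_lesions <- function(lesions, length_mm, gap_mm) {
  if (length(lesions) == 0L) return(lesions)
  unplaced <- vapply(lesions, function(l) !is.finite(l$center_mm), logical(1))
  if (any(unplaced) && !all(unplaced)) {
    stop("either give center_mm for every lesion or for none", call. = FALSE)
  }
  if (all(unplaced)) {
    len <- vapply(lesions, `[[`, numeric(1), "length_mm")
    total <- sum(len) + gap_mm * (length(lesions) - 1L)
    if (total > length_mm) {
      stop("lesion train (", total, " mm) exceeds segment length", call. = FALSE)
    }
    start <- (length_mm - total) / 2
    for (i in seq_along(lesions)) {
      lesions[[i]]$center_mm <- start + len[i] / 2
      start <- start + len[i] + gap_mm
    }
  }
  lesions[order(vapply(lesions, `[[`, numeric(1), "center_mm"))]
}

validate_segment <- function(seg) {
  les <- seg$lesions
  if (length(les) == 0L) return(invisible(seg))
  a <- vapply(les, function(l) l$center_mm - l$length_mm / 2, numeric(1))
  b <- vapply(les, function(l) l$center_mm + l$length_mm / 2, numeric(1))
  bad <- which(a < 0 | b > seg$length_mm)
  if (length(bad)) {
    stop("lesion ", bad[1], " extends outside the segment [0, ",
         seg$length_mm, "] mm", call. = FALSE)
  }
  if (length(les) > 1L) {
    for (i in seq_len(length(les) - 1L)) {
      if (b[i] > a[i + 1L]) {
        stop(sprintf("lesions %d and %d overlap (%.3g mm > %.3g mm)",
                     i, i + 1L, b[i], a[i + 1L]), call. = FALSE)
      }
    }
  }
  invisible(seg)
}

#' @export
print.segment_spec <- function(x, ...) {
  cat(sprintf("<segment> D = %g mm, L = %g mm, %d lesion(s)\n",
              x$diameter_mm, x$length_mm, length(x$lesions)))
  for (l in x$lesions) print(l)
  invisible(x)
}

#' Local severity of a lesion along the axis
#'
#' Maps axial position to the local diameter-stenosis fraction in the
#' narrowed plane(s), in `[0, ds_fraction]`; zero outside the lesion extent.
#'
#' * rounded + focal: raised cosine peaking at `ds_fraction` at mid-lesion,
#'   zero at both ends (C1 at the ends);
#' * rounded + uniform: raised-cosine ramps over `shoulder_mm` at each end
#'   with a constant-severity plateau between;
#' * rectangular: a step to the full `ds_fraction` across the whole length.
#'
#' @param lesion A [lesion_spec()].
#' @param x_mm Axial positions (mm) in segment coordinates (vectorised).
#' @return Numeric vector of local severities.
#' @export
lesion_shape_function <- function(lesion, x_mm) {
  stopifnot(inherits(lesion, "lesion_spec"), is.finite(lesion$center_mm))
  len <- lesion$length_mm
  ds <- lesion$ds_fraction
  xi <- x_mm - (lesion$center_mm - len / 2)   # 0 at proximal edge
  s <- numeric(length(x_mm))
  inside <- xi >= 0 & xi <= len
  if (lesion$profile == "rectangular") {
    s[inside] <- ds
  } else if (lesion$taper == "focal") {
    s[inside] <- ds * 0.5 * (1 - cos(2 * pi * xi[inside] / len))
  } else {
    sh <- lesion$shoulder_mm
    z <- xi[inside]
    v <- rep(ds, length(z))
    up <- z < sh
    dn <- z > len - sh
    v[up] <- ds * 0.5 * (1 - cos(pi * z[up] / sh))
    v[dn] <- ds * 0.5 * (1 - cos(pi * (len - z[dn]) / sh))
    s[inside] <- v
  }
  s
}

#' Discretize a segment into an axial lumen area profile
#'
#' Composes the lesion shape functions onto the reference lumen and returns
#' the discretized `A(x)` description that the haemodynamic solver consumes.
#' The grid is uniform at `grid_step_mm` with breakpoints inserted at lesion
#' edges, shoulder ends and (bracketed) rectangular discontinuities, so the
#' composite-trapezoid viscous integral converges to well under 0.5% on
#' refinement for every study geometry.
#'
#' @param segment A [segment_spec()].
#' @param grid_step_mm Nominal axial grid step in mm (default 0.1).
#' @return An object of class `area_profile`: list with `x_mm`, `area_mm2`,
#'   `d_eff_mm` (effective circular diameter `sqrt(4A/pi)`), `min_area_mm2`,
#'   `min_area_x_mm`, `reference_area_mm2`, and the originating `segment`.
#' @examples
#' seg <- segment_spec(3.5, 50, lesion_spec(0.7, 5))
#' prof <- build_area_profile(seg)
#' prof$min_area_mm2   # ~0.866 mm^2
#' @export
build_area_profile <- function(segment, grid_step_mm = 0.1) {
  stopifnot(inherits(segment, "segment_spec"), grid_step_mm > 0)
  validate_segment(segment)
  L <- segment$length_mm
  x <- seq(0, L, by = grid_step_mm)
  if (x[length(x)] < L) x <- c(x, L)
  eps <- 1e-9  # bracket discontinuities so the trapezoid rule sees the jump
  for (l in segment$lesions) {
    a <- l$center_mm - l$length_mm / 2
    b <- l$center_mm + l$length_mm / 2
    x <- c(x, a, b)
    if (l$profile == "rectangular") {
      x <- c(x, a - eps, a + eps, b - eps, b + eps)
    } else if (l$taper == "uniform") {
      x <- c(x, a + l$shoulder_mm, b - l$shoulder_mm)
    }
  }
  x <- sort(unique(pmin(pmax(x, 0), L)))
  ref_area <- csa_concentric(0, segment$diameter_mm)
  area <- rep(ref_area, length(x))
  for (l in segment$lesions) {
    s <- lesion_shape_function(l, x)
    al <- if (l$cross_section == "concentric") {
      csa_concentric(s, segment$diameter_mm)
    } else {
      csa_eccentric(s, segment$diameter_mm)
    }
    area <- pmin(area, al)
  }
  i <- which.min(area)
  structure(
    list(x_mm = x, area_mm2 = area, d_eff_mm = sqrt(4 * area / pi),
         min_area_mm2 = area[i], min_area_x_mm = x[i],
         reference_area_mm2 = ref_area, grid_step_mm = grid_step_mm,
         segment = segment),
    class = "area_profile")
}

#' @export
print.area_profile <- function(x, ...) {
  cat(sprintf(
    "<area profile> %d nodes over %g mm; reference %.3f mm^2, min %.3f mm^2 at %.1f mm\n",
    length(x$x_mm), max(x$x_mm), x$reference_area_mm2, x$min_area_mm2,
    x$min_area_x_mm))
  invisible(x)
}

# exact minimal lumen area of a lesion (closed form, no grid)
lesion_min_area_mm2 <- function(lesion, diameter_mm) {
  if (lesion$cross_section == "concentric") {
    csa_concentric(lesion$ds_fraction, diameter_mm)
  } else {
    csa_eccentric(lesion$ds_fraction, diameter_mm)
  }
}
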
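#' Daughter diameter from a bifurcation law
#'
#' Given the parent and one daughter diameter, returns the diameter of the
#' other daughter under the selected law:
#' * `murray`: \eqn{d_p^3 = d_1^3 + d_2^3}
#' * `finet`: \eqn{d_p = 0.678 (d_1 + d_2)}
#' * `huo_kassab`: \eqn{d_p^{7/3} = d_1^{7/3} + d_2^{7/3}}
#'
#' @param law `"murray"`, `"finet"` or `"huo_kassab"`.
#' @param d_parent_mm Parent (proximal main branch) diameter, mm.
#' @param d_other_mm The known daughter (distal main branch) diameter, mm.
#' @return Side-branch diameter in mm.
#' @examples
#' daughter_diameter("murray", 3.5, 2.8)
#' @export
daughter_diameter <- function(law = c("murray", "finet", "huo_kassab"),
                              d_parent_mm, d_other_mm) {
  law <- match.arg(law)
  stopifnot(d_parent_mm > 0, d_other_mm > 0)
  d <- switch(law,
    murray = (d_parent_mm^3 - d_other_mm^3)^(1 / 3),
    finet = d_parent_mm / 0.678 - d_other_mm,
    huo_kassab = (d_parent_mm^(7 / 3) - d_other_mm^(7 / 3))^(3 / 7))
  if (!is.finite(d) || d <= 0) {
    stop(sprintf(
      "non-physical bifurcation: %s law gives no positive side-branch for parent %.3g mm, daughter %.3g mm",
      law, d_parent_mm, d_other_mm), call. = FALSE)
  }
  d
}

#' Distribute microvascular resistance across outlets by diameter
#'
#' Each outlet receives \eqn{R_i = R_{ref} (d_{ref} / d_i)^{exponent}}. The
#' default exponent 3 follows Murray-type flow scaling (flow, and hence the
#' subtended myocardial mass, proportional to \eqn{d^3}); with it a healthy
#' Murray-law tree conserves the reference total resistance exactly. The
#' same exponent is used whichever law sized the side branch, because the
#' downstream myocardium does not depend on the sizing rule.
#'
#' @param reference_mvr Reference single-vessel MVR, Pa.s/m^3.
#' @param reference_diameter_mm Diameter the reference MVR belongs to, mm.
#' @param outlet_diameters_mm Vector of outlet diameters, mm.
#' @param exponent Diameter-scaling exponent (default 3).
#' @return Named-preserving numeric vector of per-outlet MVRs.
#' @export
distribute_mvr <- function(reference_mvr, reference_diameter_mm,
                           outlet_diameters_mm, exponent = 3) {
  stopifnot(reference_mvr > 0, reference_diameter_mm > 0,
            all(outlet_diameters_mm > 0))
  reference_mvr * (reference_diameter_mm / outlet_diameters_mm)^exponent
}

#' Specify a one-junction coronary bifurcation
#'
#' The proximal main branch (PMB) splits into the distal main branch (DMB)
#' and a side branch (SB). The SB diameter may be given as `NA` to be derived
#' from the selected diameter law. The branch angle is recorded for the
#' geometry but deliberately plays no part in the physics (static pressure is
#' taken continuous across the junction).
#'
#' @param pmb,dmb,sb [segment_spec()]s; give `sb` a diameter of `NA` to have
#'   it computed by `law`.
#' @param law Diameter law used to size the side branch.
#' @param angle_deg Branch angle in degrees (recorded only).
#' @return Object of class `bifurcation_spec`.
#' @examples
#' bifurcation_spec(dmb = segment_spec(2.8, 25))
#' @export
bifurcation_spec <- function(pmb = segment_spec(3.5, 25),
                             dmb = segment_spec(2.8, 25),
                             sb = sb_placeholder(),
                             law = c("murray", "finet", "huo_kassab"),
                             angle_deg = 45) {
  law <- match.arg(law)
  stopifnot(inherits(pmb, "segment_spec"), inherits(dmb, "segment_spec"))
  if (!inherits(sb, "segment_spec")) stop("sb must be a segment_spec")
  if (!is.finite(sb$diameter_mm)) {
    sb$diameter_mm <- daughter_diameter(law, pmb$diameter_mm, dmb$diameter_mm)
  }
  if (dmb$diameter_mm >= pmb$diameter_mm) {
    stop("distal main branch must be narrower than the proximal main branch",
         call. = FALSE)
  }
  structure(list(pmb = pmb, dmb = dmb, sb = sb, law = law,
                 angle_deg = angle_deg),
            class = "bifurcation_spec")
}

#' @export
print.bifurcation_spec <- function(x, ...) {
  cat(sprintf("<bifurcation> %s law, %g deg; PMB %g mm / DMB %g mm / SB %.3f mm\n",
              x$law, x$angle_deg, x$pmb$diameter_mm, x$dmb$diameter_mm,
              x$sb$diameter_mm))
  invisible(x)
}

# helper: a segment_spec with NA diameter is only a placeholder; segment_spec()
# validates diameter > 0, so allow NA through a thin wrapper used by callers.
#' @rdname bifurcation_spec
#' @param diameter_mm,length_mm,lesions,gap_mm As in [segment_spec()], but
#'   `diameter_mm = NA` is allowed (side branch sized later by the law).
#' @export
sb_placeholder <- function(diameter_mm = NA, length_mm = 25, lesions = list(),
                           gap_mm = 10) {
  if (is.na(diameter_mm)) {
    seg <- segment_spec(1, length_mm, lesions, gap_mm)
    seg$diameter_mm <- NA_real_
    seg
  } else {
    segment_spec(diameter_mm, length_mm, lesions, gap_mm)
  }
}

#' Solve the two-outlet bifurcation network
#'
#' The PMB loss is common to both outlets; the DMB and SB (each with its own
#' lesions and distributed MVR) hang in parallel off the junction, where
#' static pressure is continuous and mass is conserved. The solver iterates
#' on the junction pressure with nested monotone flow solves per branch, and
#' reports the vFFR at each outlet against the common inlet pressure.
#'
#' @param spec A [bifurcation_spec()].
#' @param params [loss_model_params()].
#' @param fluid [fluid_properties()].
#' @param bc [boundary_conditions()]; `outlet_mvr_Pa_s_m3` is the reference
#'   single-vessel MVR, apportioned by [distribute_mvr()].
#' @param mvr_exponent Exponent passed to [distribute_mvr()].
#' @param grid_step_mm Axial grid step for the segment profiles.
#' @return Object of class `branch_flow_solution`: per-outlet vFFR and flow,
#'   junction pressure, inlet flow, and the junction mass residual.
#' @examples
#' spec <- bifurcation_spec(pmb = segment_spec(3.5, 25, lesion_spec(0.7, 5)))
#' solve_branch_flow(spec)$vffr
#' @export
solve_branch_flow <- function(spec, params = loss_model_params(),
                              fluid = fluid_properties(),
                              bc = boundary_conditions(),
                              mvr_exponent = 3, grid_step_mm = 0.1) {
  stopifnot(inherits(spec, "bifurcation_spec"))
  pa <- bc$inlet_pressure_Pa
  pv <- bc$venous_pressure_Pa
  segs <- list(pmb = spec$pmb, dmb = spec$dmb, sb = spec$sb)
  lumped <- lapply(segs, function(s) {
    prof <- build_area_profile(s, grid_step_mm)
    list(rv = viscous_resistance(prof, fluid),
         ce = expansion_coef_total(prof, s$lesions, params, fluid))
  })
  rmv <- distribute_mvr(bc$outlet_mvr_Pa_s_m3, spec$pmb$diameter_mm,
                        c(dmb = spec$dmb$diameter_mm,
                          sb = spec$sb$diameter_mm), mvr_exponent)

  branch_flow <- function(nm, pj) {
    if (pj <= pv) return(0)
    b <- list(inlet_pressure_Pa = pj, venous_pressure_Pa = pv)
    solve_operating_point(lumped[[nm]]$rv, lumped[[nm]]$ce, b,
                          rmv = rmv[[nm]], inlet_Pa = pj)$flow_m3_s
  }
  inlet_flow <- function(pj) {
    # Pa - dP_pmb(Q) = pj; dP strictly increasing, so invert by bisection
    drop <- pa - pj
    if (drop <= 0) return(0)
    rv <- lumped$pmb$rv
    ce <- lumped$pmb$ce
    if (ce == 0) return(drop / rv)
    (-rv + sqrt(rv^2 + 4 * ce * drop)) / (2 * ce)
  }
  imbalance <- function(pj) {
    inlet_flow(pj) - branch_flow("dmb", pj) - branch_flow("sb", pj)
  }
  pj <- stats::uniroot(imbalance, c(pv, pa), tol = 1e-12,
                       f.lower = imbalance(pv), f.upper = imbalance(pa),
                       maxiter = 1000L)$root
  q <- c(dmb = branch_flow("dmb", pj), sb = branch_flow("sb", pj))
  q_in <- inlet_flow(pj)
  pd <- pv + rmv * q
  structure(list(
    vffr = pd / pa,
    outlet_pressure_Pa = pd,
    flow_m3_s = q,
    inlet_flow_m3_s = q_in,
    junction_pressure_Pa = pj,
    outlet_mvr_Pa_s_m3 = rmv,
    sb_diameter_mm = spec$sb$diameter_mm,
    law = spec$law,
    mass_residual = (q_in - sum(q)) / q_in,
    converged = TRUE),
    class = "branch_flow_solution")
}

#' @export
print.branch_flow_solution <- function(x, ...) {
  cat(sprintf(
    "<branch solution> %s law, SB %.3f mm: vFFR DMB %.3f, SB %.3f (Q %.3f / %.3f mL/s)\n",
    x$law, x$sb_diameter_mm, x$vffr[["dmb"]], x$vffr[["sb"]],
    x$flow_m3_s[["dmb"]] * 1e6, x$flow_m3_s[["sb"]] * 1e6))
  invisible(x)
}
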
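#' Blood fluid properties
#'
#' Defaults are standard values for blood treated as a Newtonian fluid at
#' hyperaemic shear rates: dynamic viscosity 3.5 mPa.s, density 1056 kg/m^3.
#'
#' @param viscosity_Pa_s Dynamic viscosity in Pa.s.
#' @param density_kg_m3 Density in kg/m^3.
#' @return Object of class `fluid_properties`.
#' @export
fluid_properties <- function(viscosity_Pa_s = 0.0035, density_kg_m3 = 1056) {
  stopifnot(viscosity_Pa_s > 0, density_kg_m3 > 0)
  structure(list(viscosity_Pa_s = viscosity_Pa_s,
                 density_kg_m3 = density_kg_m3),
            class = "fluid_properties")
}

#' Boundary conditions for the steady solve
#'
#' The inlet is held at aortic pressure (default 100 mmHg = 13332.2 Pa),
#' each outlet drains through a lumped microvascular resistance (MVR) to the
#' venous pressure. The standard MVR is the population-average
#' 8.721e9 Pa.s.m^-3.
#'
#' @param inlet_pressure_Pa Proximal (aortic) pressure, Pa.
#' @param venous_pressure_Pa Venous pressure, Pa (>= 0, below inlet).
#' @param outlet_mvr_Pa_s_m3 Microvascular resistance per outlet, Pa.s/m^3.
#' @return Object of class `boundary_conditions`.
#' @export
boundary_conditions <- function(inlet_pressure_Pa = 13332.2,
                                venous_pressure_Pa = 0,
                                outlet_mvr_Pa_s_m3 = 8.721e9) {
  stopifnot(venous_pressure_Pa >= 0,
            inlet_pressure_Pa > venous_pressure_Pa,
            outlet_mvr_Pa_s_m3 > 0)
  structure(list(inlet_pressure_Pa = inlet_pressure_Pa,
                 venous_pressure_Pa = venous_pressure_Pa,
                 outlet_mvr_Pa_s_m3 = outlet_mvr_Pa_s_m3),
            class = "boundary_conditions")
}

#' Trans-lesion loss-model coefficients
#'
#' The trans-lesion pressure drop is split into a Poiseuille (viscous) part
#' integrated over the discretized lumen and a Borda-Carnot expansion part
#' per lesion,
#' \deqn{\Delta P_t = \frac{K_t \rho}{2}\left(\frac{1}{C_c A_{min}} -
#'   \frac{1}{A_{ref}}\right)^2 Q |Q|,}
#' where the contraction coefficient \eqn{C_c} shrinks the effective minimal
#' area to the vena contracta. \eqn{C_c} is selected by throat type: lesions
#' with a constant-area throat (rectangular profile, or rounded lesions of
#' uniform taper) separate at entry and take
#' `contraction_coefficient_rectangular`; gently tapered (rounded focal)
#' lesions keep attached flow and take `contraction_coefficient_rounded`
#' (default 1, no contraction).
#'
#' Defaults were calibrated once against the reference CFD values for the
#' single short-lesion block (severity x shape) and then frozen for every
#' analysis in the package; see the methods vignette.
#'
#' @param expansion_coefficient Kt, weight of the expansion loss (>= 0;
#'   zero recovers the purely viscous, linear resistance model).
#' @param contraction_coefficient_rounded Cc for tapered (focal) lesions.
#' @param contraction_coefficient_rectangular Cc for constant-area throats
#'   (rectangular or uniform); must not exceed the rounded value.
#' @return Object of class `loss_model_params`.
#' @export
loss_model_params <- function(expansion_coefficient = 1.04,
                              contraction_coefficient_rounded = 1.0,
                              contraction_coefficient_rectangular = 0.70) {
  stopifnot(expansion_coefficient >= 0,
            contraction_coefficient_rounded > 0,
            contraction_coefficient_rounded <= 1,
            contraction_coefficient_rectangular > 0,
            contraction_coefficient_rectangular <=
              contraction_coefficient_rounded)
  structure(list(
    expansion_coefficient = expansion_coefficient,
    contraction_coefficient_rounded = contraction_coefficient_rounded,
    contraction_coefficient_rectangular = contraction_coefficient_rectangular),
    class = "loss_model_params")
}

contraction_coefficient <- function(lesion, params) {
  if (lesion$profile == "rectangular" || lesion$taper == "uniform") {
    params$contraction_coefficient_rectangular
  } else {
    params$contraction_coefficient_rounded
  }
}

#' Poiseuille (viscous) resistance of an area profile
#'
#' Computes \eqn{R_v = (128 \mu / \pi) \int dx / d_{eff}(x)^4} by the
#' composite trapezoid rule on the profile grid. The associated loss is
#' linear in flow, \eqn{\Delta P_v = R_v Q}.
#'
#' @param profile An [build_area_profile()] result.
#' @param fluid A [fluid_properties()].
#' @return Viscous resistance in Pa.s/m^3.
#' @examples
#' prof <- build_area_profile(segment_spec(3.5, 100))
#' viscous_resistance(prof, fluid_properties())  # ~9.50e7, closed-form tube
#' @export
viscous_resistance <- function(profile, fluid = fluid_properties()) {
  stopifnot(inherits(profile, "area_profile"))
  d_m <- profile$d_eff_mm * 1e-3
  x_m <- profile$x_mm * 1e-3
  f <- 1 / d_m^4
  if (any(!is.finite(f))) {
    stop("invalid profile: non-finite viscous integrand (zero lumen area?)",
         call. = FALSE)
  }
  integral <- sum(diff(x_m) * (f[-length(f)] + f[-1]) / 2)
  128 * fluid$viscosity_Pa_s / pi * integral
}

#' Post-stenotic expansion (vena contracta) pressure loss of one lesion
#'
#' @param profile The parent [build_area_profile()] (supplies the reference
#'   area).
#' @param lesion The [lesion_spec()] incurring the loss.
#' @param params [loss_model_params()].
#' @param fluid [fluid_properties()].
#' @param flow_m3_s Flow rate Q in m^3/s (signed; loss follows the flow
#'   direction through the Q|Q| law).
#' @return Pressure drop in Pa.
#' @export
expansion_loss <- function(profile, lesion, params = loss_model_params(),
                           fluid = fluid_properties(), flow_m3_s) {
  stopifnot(inherits(profile, "area_profile"), is.finite(flow_m3_s))
  a_min <- lesion_min_area_mm2(lesion, profile$segment$diameter_mm) * 1e-6
  if (a_min <= 0) stop("invalid lesion: minimal area <= 0", call. = FALSE)
  a_ref <- profile$reference_area_mm2 * 1e-6
  cc <- contraction_coefficient(lesion, params)
  k <- params$expansion_coefficient * fluid$density_kg_m3 / 2 *
    (1 / (cc * a_min) - 1 / a_ref)^2
  k * flow_m3_s * abs(flow_m3_s)
}

# quadratic coefficient of the summed expansion losses (SI)
expansion_coef_total <- function(profile, lesions, params, fluid) {
  if (length(lesions) == 0L) return(0)
  a_ref <- profile$reference_area_mm2 * 1e-6
  sum(vapply(lesions, function(l) {
    a_min <- lesion_min_area_mm2(l, profile$segment$diameter_mm) * 1e-6
    cc <- contraction_coefficient(l, params)
    params$expansion_coefficient * fluid$density_kg_m3 / 2 *
      (1 / (cc * a_min) - 1 / a_ref)^2
  }, numeric(1)))
}

#' Total trans-segment pressure drop at a given flow
#'
#' \eqn{\Delta P(Q) = R_v Q + \sum_{lesions} \Delta P_t(Q)}: strictly
#' increasing and continuous in Q, which guarantees a unique operating point
#' against any positive outlet resistance.
#'
#' @inheritParams expansion_loss
#' @param lesions List of lesions (defaults to those of the profile's
#'   segment).
#' @return Pressure drop in Pa (vectorised over `flow_m3_s`).
#' @export
total_pressure_drop <- function(profile, lesions = NULL,
                                params = loss_model_params(),
                                fluid = fluid_properties(), flow_m3_s) {
  stopifnot(inherits(profile, "area_profile"))
  if (is.null(lesions)) lesions <- profile$segment$lesions
  rv <- viscous_resistance(profile, fluid)
  ce <- expansion_coef_total(profile, lesions, params, fluid)
  rv * flow_m3_s + ce * flow_m3_s * abs(flow_m3_s)
}

# Newton with bisection fallback for Pa - dP(Q) - Rmv*Q - Pv = 0 on [0, Qmax].
# dp_fun(Q) and its derivative are the quadratic lumped forms.
solve_operating_point <- function(rv, ce, bc, rmv = bc$outlet_mvr_Pa_s_m3,
                                  inlet_Pa = bc$inlet_pressure_Pa,
                                  tol = 1e-10, max_iter = 200L) {
  pa <- inlet_Pa
  pv <- bc$venous_pressure_Pa
  f <- function(q) pa - rv * q - ce * q * abs(q) - rmv * q - pv
  lo <- 0
  hi <- (pa - pv) / rmv          # dP >= 0 puts the root at or below this
  if (f(hi) > 0) hi <- hi * (1 + 1e-9) + 1e-300
  q <- hi / 2
  iter <- 0L
  repeat {
    iter <- iter + 1L
    fq <- f(q)
    if (fq > 0) lo <- q else hi <- q
    dq <- fq / (rv + 2 * ce * abs(q) + rmv)   # Newton step (f' < 0)
    qn <- q + dq
    if (!is.finite(qn) || qn <= lo || qn >= hi) qn <- (lo + hi) / 2
    done <- abs(qn - q) <= tol * max(qn, 1e-300)
    q <- qn
    if (done || iter >= max_iter) break
  }
  residual <- f(q)
  if (abs(residual) / pa > 1e-8) {
    stop(sprintf(
      "flow solve did not converge: relative residual %.3e after %d iterations",
      abs(residual) / pa, iter), call. = FALSE)
  }
  list(flow_m3_s = q, residual = residual, iterations = iter)
}

#' Solve the steady flow and virtual FFR of a single vessel
#'
#' Finds the unique flow Q >= 0 satisfying the pressure balance
#' `Pa - dP(Q) = Pv + Rmv * Q`, i.e. the trans-lesion drop in series with the
#' microvascular outlet resistance, then reports the outlet pressure and
#' `vFFR = Pd / Pa`. In the linear limit (no expansion losses) this reduces
#' to the resistance-ratio identity `vFFR = Rmv / (Rmv + Rv)`.
#'
#' @inheritParams total_pressure_drop
#' @param bc [boundary_conditions()].
#' @return An object of class `flow_solution`: converged flow (m^3/s), axial
#'   pressure curve (data frame `x_mm`, `pressure_Pa`; expansion losses are
#'   booked at each lesion's minimal-area station), outlet pressure, `vffr`,
#'   lesion-free reference flow `q_normal_m3_s`, secant stenosis resistance
#'   `dP(Q)/Q`, significance vs the 0.80 threshold, and convergence info.
#' @examples
#' prof <- build_area_profile(segment_spec(3.5, 50, lesion_spec(0.7, 5)))
#' solve_flow(prof)$vffr
#' @export
solve_flow <- function(profile, lesions = NULL,
                       params = loss_model_params(),
                       fluid = fluid_properties(),
                       bc = boundary_conditions()) {
  stopifnot(inherits(profile, "area_profile"),
            inherits(params, "loss_model_params"),
            inherits(fluid, "fluid_properties"),
            inherits(bc, "boundary_conditions"))
  if (is.null(lesions)) lesions <- profile$segment$lesions
  rv <- viscous_resistance(profile, fluid)
  ce <- expansion_coef_total(profile, lesions, params, fluid)
  op <- solve_operating_point(rv, ce, bc)
  q <- op$flow_m3_s
  pa <- bc$inlet_pressure_Pa
  pd <- bc$venous_pressure_Pa + bc$outlet_mvr_Pa_s_m3 * q
  structure(list(
    flow_m3_s = q,
    pressure_curve = pressure_curve(profile, lesions, params, fluid, q, pa),
    outlet_pressure_Pa = pd,
    vffr = pd / pa,
    q_normal_m3_s = (pa - bc$venous_pressure_Pa) /
      (bc$outlet_mvr_Pa_s_m3 + viscous_resistance(
        build_area_profile(segment_spec(profile$segment$diameter_mm,
                                        profile$segment$length_mm),
                           profile$grid_step_mm), fluid)),
    stenosis_resistance_Pa_s_m3 = if (q > 0) (rv * q + ce * q^2) / q else rv,
    converged = TRUE, residual = op$residual, iterations = op$iterations),
    class = "flow_solution")
}

# axial pressure: cumulative viscous drop plus expansion steps at the
# minimal-area station of each lesion; non-increasing along the flow
pressure_curve <- function(profile, lesions, params, fluid, q, inlet_Pa) {
  d_m <- profile$d_eff_mm * 1e-3
  x_m <- profile$x_mm * 1e-3
  f <- 128 * fluid$viscosity_Pa_s / pi / d_m^4
  visc <- c(0, cumsum(diff(x_m) * (f[-length(f)] + f[-1]) / 2)) * q
  p <- inlet_Pa - visc
  for (l in lesions) {
    dp <- expansion_loss(profile, l, params, fluid, q)
    p <- p - dp * (profile$x_mm >= l$center_mm)
  }
  data.frame(x_mm = profile$x_mm, pressure_Pa = p)
}

#' @export
print.flow_solution <- function(x, ...) {
  cat(sprintf(
    "<flow solution> Q = %.3f mL/s, Pd = %.0f Pa, vFFR = %.3f (%s), %d iter\n",
    x$flow_m3_s * 1e6, x$outlet_pressure_Pa, x$vffr,
    if (x$vffr <= 0.80) "significant" else "non-significant", x$iterations))
  invisible(x)
}

#' Sensitivity of vFFR to the microvascular resistance
#'
#' Re-solves at `Rmv - delta`, `Rmv` and `Rmv + delta` (the study varies the
#' standard MVR by +-2e9 Pa.s.m^-3, about a quartile spread of the source
#' patient cohort). A lower MVR draws more flow and lowers vFFR.
#'
#' @inheritParams solve_flow
#' @param delta_mvr Pa.s/m^3 perturbation (default 2e9).
#' @return Named numeric triple `c(low, standard, high)` of vFFRs, ordered
#'   `low <= standard <= high`.
#' @export
vffr_sensitivity_mvr <- function(profile, lesions = NULL,
                                 params = loss_model_params(),
                                 fluid = fluid_properties(),
                                 bc = boundary_conditions(),
                                 delta_mvr = 2e9) {
  stopifnot(bc$outlet_mvr_Pa_s_m3 - delta_mvr > 0)
  at <- function(rmv) {
    b <- bc
    b$outlet_mvr_Pa_s_m3 <- rmv
    solve_flow(profile, lesions, params, fluid, b)$vffr
  }
  r <- bc$outlet_mvr_Pa_s_m3
  c(low = at(r - delta_mvr), standard = at(r), high = at(r + delta_mvr))
}
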
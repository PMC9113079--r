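#' Run configuration
#'
#' Bundles every tunable of the analysis. The defaults are the frozen
#' configuration used for the whole study sweep (no per-row tuning):
#' aortic inlet 13332.2 Pa (100 mmHg), venous 0 Pa, standard MVR
#' 8.721e9 Pa.s.m^-3 varied by +-2e9, blood at 3.5 mPa.s / 1056 kg/m^3,
#' expansion coefficient 1.04 with vena-contracta coefficient 0.70 for
#' constant-area throats, 0.1 mm axial grid, 10 mm serial spacing, 0.80
#' ischaemic threshold, cube-law MVR distribution, 25 mm branch segments.
#'
#' @param fluid [fluid_properties()].
#' @param bc [boundary_conditions()].
#' @param loss [loss_model_params()].
#' @param grid_step_mm Axial discretization step, mm.
#' @param mvr_delta_Pa_s_m3 MVR perturbation for the sensitivity study.
#' @param significance_threshold vFFR at or below this is "positive".
#' @param mvr_exponent Exponent for [distribute_mvr()].
#' @param serial_gap_mm Edge-to-edge spacing of serial lesions, mm.
#' @param branch_segment_length_mm Length of PMB, DMB and SB segments, mm.
#' @param verbose Emit per-solve log lines from the pipeline and CLI.
#' @return Object of class `run_config`.
#' @export
run_config <- function(fluid = fluid_properties(),
                       bc = boundary_conditions(),
                       loss = loss_model_params(),
                       grid_step_mm = 0.1,
                       mvr_delta_Pa_s_m3 = 2e9,
                       significance_threshold = 0.80,
                       mvr_exponent = 3,
                       serial_gap_mm = 10,
                       branch_segment_length_mm = 25,
                       verbose = FALSE) {
  stopifnot(inherits(fluid, "fluid_properties"),
            inherits(bc, "boundary_conditions"),
            inherits(loss, "loss_model_params"),
            grid_step_mm > 0, mvr_delta_Pa_s_m3 >= 0,
            significance_threshold > 0, significance_threshold < 1,
            serial_gap_mm > 0, branch_segment_length_mm > 0)
  if (bc$outlet_mvr_Pa_s_m3 - mvr_delta_Pa_s_m3 <= 0) {
    stop("mvr_delta_Pa_s_m3 must leave the low-MVR setting positive",
         call. = FALSE)
  }
  structure(list(fluid = fluid, bc = bc, loss = loss,
                 grid_step_mm = grid_step_mm,
                 mvr_delta_Pa_s_m3 = mvr_delta_Pa_s_m3,
                 significance_threshold = significance_threshold,
                 mvr_exponent = mvr_exponent,
                 serial_gap_mm = serial_gap_mm,
                 branch_segment_length_mm = branch_segment_length_mm,
                 verbose = isTRUE(verbose)),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run config>", config_hash(x), "\n")
  cat(sprintf("  inlet %.1f Pa, venous %.1f Pa, MVR %.4g +- %.2g Pa.s/m^3\n",
              x$bc$inlet_pressure_Pa, x$bc$venous_pressure_Pa,
              x$bc$outlet_mvr_Pa_s_m3, x$mvr_delta_Pa_s_m3))
  cat(sprintf("  mu %.4g Pa.s, rho %.4g kg/m^3, Kt %.3g, Cc %.3g/%.3g\n",
              x$fluid$viscosity_Pa_s, x$fluid$density_kg_m3,
              x$loss$expansion_coefficient,
              x$loss$contraction_coefficient_rounded,
              x$loss$contraction_coefficient_rectangular))
  cat(sprintf("  grid %.3g mm, threshold %.2f, MVR exponent %.3g\n",
              x$grid_step_mm, x$significance_threshold, x$mvr_exponent))
  invisible(x)
}

config_to_list <- function(config) {
  list(fluid = unclass(config$fluid), bc = unclass(config$bc),
       loss = unclass(config$loss),
       grid_step_mm = config$grid_step_mm,
       mvr_delta_Pa_s_m3 = config$mvr_delta_Pa_s_m3,
       significance_threshold = config$significance_threshold,
       mvr_exponent = config$mvr_exponent,
       serial_gap_mm = config$serial_gap_mm,
       branch_segment_length_mm = config$branch_segment_length_mm,
       verbose = config$verbose)
}

#' Write / read a run configuration as JSON
#'
#' The round trip `read_config(write_config(x))` is lossless.
#'
#' @param config A [run_config()].
#' @param path File path.
#' @return `write_config` returns `path` invisibly; `read_config` a
#'   validated [run_config()].
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(config_to_list(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  needed <- c("fluid", "bc", "loss", "grid_step_mm")
  missing <- setdiff(needed, names(raw))
  if (length(missing)) {
    stop("config file ", path, " lacks field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  run_config(
    fluid = do.call(fluid_properties, as.list(raw$fluid)),
    bc = do.call(boundary_conditions, as.list(raw$bc)),
    loss = do.call(loss_model_params, as.list(raw$loss)),
    grid_step_mm = raw$grid_step_mm,
    mvr_delta_Pa_s_m3 = raw$mvr_delta_Pa_s_m3 %||% 2e9,
    significance_threshold = raw$significance_threshold %||% 0.80,
    mvr_exponent = raw$mvr_exponent %||% 3,
    serial_gap_mm = raw$serial_gap_mm %||% 10,
    branch_segment_length_mm = raw$branch_segment_length_mm %||% 25,
    verbose = raw$verbose %||% FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Short hash identifying a configuration
#'
#' MD5 of the canonical JSON dump, truncated to 12 hex digits; stamped into
#' every results table so outputs are traceable to their configuration.
#'
#' @param config A [run_config()].
#' @return A 12-character string.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config_to_list(config), tmp, auto_unbox = TRUE,
                       digits = NA)
  substr(unname(tools::md5sum(tmp)), 1, 12)
}
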
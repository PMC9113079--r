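# JSON (de)serialization of geometry specifications. Field names mirror the
# constructor arguments, so files are self-describing.

spec_to_list <- function(spec) {
  if (inherits(spec, "lesion_spec")) {
    c(list(type = "lesion"), unclass(spec))
  } else if (inherits(spec, "segment_spec")) {
    list(type = "segment", diameter_mm = spec$diameter_mm,
         length_mm = spec$length_mm, gap_mm = spec$gap_mm,
         lesions = lapply(spec$lesions, spec_to_list))
  } else if (inherits(spec, "bifurcation_spec")) {
    list(type = "bifurcation", law = spec$law, angle_deg = spec$angle_deg,
         pmb = spec_to_list(spec$pmb), dmb = spec_to_list(spec$dmb),
         sb = spec_to_list(spec$sb))
  } else {
    stop("not a serializable spec: ", paste(class(spec), collapse = "/"),
         call. = FALSE)
  }
}

list_to_spec <- function(x) {
  switch(x$type,
    lesion = lesion_spec(
      ds_fraction = x$ds_fraction, length_mm = x$length_mm,
      cross_section = x$cross_section, profile = x$profile, taper = x$taper,
      center_mm = x$center_mm %||% NA_real_,
      shoulder_mm = x$shoulder_mm %||% 1),
    segment = segment_spec(
      diameter_mm = x$diameter_mm, length_mm = x$length_mm,
      lesions = lapply(x$lesions, list_to_spec), gap_mm = x$gap_mm %||% 10),
    bifurcation = bifurcation_spec(
      pmb = list_to_spec(x$pmb), dmb = list_to_spec(x$dmb),
      sb = list_to_spec(x$sb), law = x$law, angle_deg = x$angle_deg %||% 45),
    stop("unknown spec type: ", x$type, call. = FALSE))
}

#' Write or read a geometry specification as JSON
#'
#' Serializes [lesion_spec()], [segment_spec()] and [bifurcation_spec()]
#' objects to a documented JSON schema (field names are the constructor
#' arguments). The round trip is lossless.
#'
#' @param spec A lesion, segment or bifurcation spec.
#' @param path File path.
#' @return `write_spec` returns `path` invisibly; `read_spec` the
#'   reconstructed, validated spec object.
#' @examples
#' p <- tempfile(fileext = ".json")
#' write_spec(segment_spec(3.5, 50, lesion_spec(0.7, 5)), p)
#' read_spec(p)
#' @export
write_spec <- function(spec, path) {
  jsonlite::write_json(spec_to_list(spec), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_spec
#' @export
read_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  list_to_spec(x)
}
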
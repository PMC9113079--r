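#' Clinical colour scale for vFFR
#'
#' Piecewise-linear RGB map used to portray vFFR on reconstructed vessels:
#' green at 1.00 (no flow limitation), yellow/orange at 0.80 (borderline,
#' the ischaemic threshold) and red at 0.60 (severe flow limitation);
#' values below 0.60 are clamped to red.
#'
#' @param vffr Numeric vector of vFFR values in (0, 1].
#' @param anchors Optional 3-row matrix of RGB anchors (rows: green, orange,
#'   red; cosmetic, configurable).
#' @return Character vector of hex colours.
#' @examples
#' vffr_to_colour(c(1, 0.8, 0.6))
#' @export
vffr_to_colour <- function(vffr,
                           anchors = rbind(green = c(0, 153, 0),
                                           orange = c(255, 165, 0),
                                           red = c(204, 0, 0))) {
  if (any(!is.finite(vffr)) || any(vffr <= 0) || any(vffr > 1)) {
    stop("vffr must lie in (0, 1]", call. = FALSE)
  }
  stopifnot(is.matrix(anchors), nrow(anchors) == 3, ncol(anchors) == 3)
  interp <- function(v, lo, hi, c_lo, c_hi) {
    w <- (v - lo) / (hi - lo)
    c_lo + w * (c_hi - c_lo)
  }
  out <- vapply(vffr, function(v) {
    rgbv <- if (v >= 0.80) {
      interp(v, 0.80, 1.00, anchors[2, ], anchors[1, ])
    } else if (v >= 0.60) {
      interp(v, 0.60, 0.80, anchors[3, ], anchors[2, ])
    } else {
      anchors[3, ]
    }
    grDevices::rgb(rgbv[1], rgbv[2], rgbv[3], maxColorValue = 255)
  }, character(1))
  out
}
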
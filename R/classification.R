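#' Mean gray value of one cell (G)
#'
#' Arithmetic mean of the gray intensities over all pixels enclosed by the
#' cell's outer contour — the filled component, so hole pixels (central
#' pallor) are included. This is the per-cell gray value G of the RBC /
#' nucleated-cell discrimination rule.
#'
#' @param gray gray matrix from [rgb_to_gray()].
#' @param contour a `cell_contour` whose `pixel_idx` indexes into `gray`.
#' @return Scalar mean gray value in `[0, 255]`.
#' @export
mean_gray_of_cell <- function(gray, contour) {
  if (max(contour$points[, 1]) > nrow(gray) ||
      max(contour$points[, 2]) > ncol(gray) || min(contour$points) < 1)
    stop("contour lies outside the image bounds")
  mean(gray[contour$pixel_idx])
}

#' Mean gray value over all located single cells (Mg)
#'
#' Mg is the per-image mean of the per-cell gray values G, taken over the
#' effective single cells only (pending and merged contours excluded). It
#' is the denominator of the classification ratio G/Mg.
#'
#' @param g_values numeric vector of per-cell G values.
#' @return Scalar Mg.
#' @export
cohort_mean_gray <- function(g_values) {
  if (!length(g_values))
    stop("no located single cells: Mg is undefined")
  mean(g_values)
}

#' Classify a single cell as RBC or nucleated
#'
#' An anucleate RBC stains pale (high gray value); a nucleated cell
#' carries a dark purple nucleus that pulls its mean gray down. A cell
#' with `G / Mg` above the threshold is an RBC, below it a nucleated
#' cell. A ratio exactly at the threshold goes to RBC (documented
#' tie-break; the rule itself defines only the strict inequalities).
#'
#' @param g per-cell mean gray value.
#' @param mg image-wide mean gray value over located single cells (> 0).
#' @param ratio_threshold decision boundary on G/Mg (default 0.8).
#' @return `"rbc"` or `"nucleated"`.
#' @export
classify_cell <- function(g, mg, ratio_threshold = 0.8) {
  if (!is.finite(mg) || mg <= 0) stop("Mg must be finite and positive")
  if (g / mg >= ratio_threshold) "rbc" else "nucleated"
}
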
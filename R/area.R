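# --- minimum enclosing circle (Welzl) -------------------------------------

# Circle through two points (diameter) or three points (circumcircle).
# Three collinear points fall back to the widest two-point circle.
circle_from <- function(support) {
  n <- nrow(support)
  if (n == 0L) return(list(center = c(0, 0), radius = 0))
  if (n == 1L) return(list(center = support[1, ], radius = 0))
  if (n == 2L) {
    ctr <- (support[1, ] + support[2, ]) / 2
    return(list(center = ctr, radius = sqrt(sum((support[1, ] - ctr)^2))))
  }
  p <- support[1, ]; q <- support[2, ]; r <- support[3, ]
  d <- 2 * (p[1] * (q[2] - r[2]) + q[1] * (r[2] - p[2]) + r[1] * (p[2] - q[2]))
  if (abs(d) < 1e-12) {
    # collinear: minimal circle over the three pairwise diameters
    best <- NULL
    for (ij in list(c(1, 2), c(1, 3), c(2, 3))) {
      cc <- circle_from(support[ij, , drop = FALSE])
      if (all(sqrt(colSums((t(support) - cc$center)^2)) <=
              cc$radius + 1e-9) &&
          (is.null(best) || cc$radius < best$radius)) best <- cc
    }
    return(best)
  }
  p2 <- sum(p^2); q2 <- sum(q^2); r2 <- sum(r^2)
  ux <- (p2 * (q[2] - r[2]) + q2 * (r[2] - p[2]) + r2 * (p[2] - q[2])) / d
  uy <- (p2 * (r[1] - q[1]) + q2 * (p[1] - r[1]) + r2 * (q[1] - p[1])) / d
  ctr <- c(ux, uy)
  list(center = ctr, radius = sqrt(sum((p - ctr)^2)))
}

# Exact MEC of a small point set by exhaustion over all 2- and 3-point
# support circles.
mec_brute_small <- function(P) {
  k <- nrow(P)
  if (k == 1L) return(list(center = P[1, ], radius = 0))
  best <- NULL
  consider <- function(cc) {
    if (is.null(cc)) return(invisible())
    d2 <- (P[, 1] - cc$center[1])^2 + (P[, 2] - cc$center[2])^2
    if (max(d2) <= (cc$radius + 1e-9)^2 &&
        (is.null(best) || cc$radius < best$radius)) best <<- cc
    invisible()
  }
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k))
    consider(circle_from(P[c(i, j), , drop = FALSE]))
  if (k >= 3L)
    for (i in seq_len(k - 2)) for (j in seq(i + 1, k - 1))
      for (l in seq(j + 1, k))
        consider(circle_from(P[c(i, j, l), , drop = FALSE]))
  best
}

#' Minimum enclosing circle of a contour
#'
#' The smallest circle containing every contour point (supported by at
#' most three of them), computed exactly by farthest-violator iteration:
#' the enclosing circle of a small support set is solved exhaustively and
#' the farthest outside point is added until every point is covered. The
#' radius grows strictly at each step, so the iteration terminates; in
#' practice the support set stays below ~15 points. The radius r defines
#' the upper-bound cell area Si = pi * r^2.
#'
#' @param points an n x 2 matrix of (row, col) coordinates (n >= 3), or a
#'   `cell_contour` whose `points` are used.
#' @return List with `center` (length-2 numeric) and `radius` (pixels,
#'   exact to ~1e-9).
#' @export
min_enclosing_circle <- function(points) {
  if (inherits(points, "cell_contour")) points <- points$points
  pts <- unique(matrix(as.numeric(points), ncol = 2, dimnames = NULL))
  if (nrow(pts) < 3L)
    stop("degenerate contour: need at least 3 distinct points, got ",
         nrow(pts))
  # seed the support with a far-apart pair
  d0 <- (pts[, 1] - pts[1, 1])^2 + (pts[, 2] - pts[1, 2])^2
  a <- which.max(d0)
  d1 <- (pts[, 1] - pts[a, 1])^2 + (pts[, 2] - pts[a, 2])^2
  S <- pts[unique(c(a, which.max(d1))), , drop = FALSE]
  repeat {
    cc <- mec_brute_small(S)
    d2 <- (pts[, 1] - cc$center[1])^2 + (pts[, 2] - cc$center[2])^2
    worst <- which.max(d2)
    if (d2[worst] <= (cc$radius + 1e-9)^2) return(cc)
    S <- rbind(S, pts[worst, ])
  }
}

#' Radial roundness profile of a contour (Pmean)
#'
#' For each contour point, the ratio of its distance r_i from the
#' enclosing-circle center to the circle radius r. A perfect circle gives
#' every ratio 1; dents and elongation pull ratios down. Pmean, the
#' per-cell mean of the ratios, converts the enclosing-circle area to the
#' measured cell area Sr = Si * Pmean^2.
#'
#' @param points n x 2 coordinate matrix or a `cell_contour`.
#' @param center length-2 circle center.
#' @param radius_px circle radius in pixels (> 0).
#' @return List with `ratios` (each in `[0, 1]`) and `pmean`.
#' @export
roundness_profile <- function(points, center, radius_px) {
  if (inherits(points, "cell_contour")) points <- points$points
  if (!is.finite(radius_px) || radius_px <= 0)
    stop("circle radius must be positive")
  d <- sqrt((points[, 1] - center[1])^2 + (points[, 2] - center[2])^2)
  ratios <- pmin(d / radius_px, 1)
  list(ratios = ratios, pmean = mean(ratios))
}

#' Recall decision for a measured RBC
#'
#' A located cell is a "recall RBC" — the only kind whose area enters the
#' smear average — when every contour point lies close to the enclosing
#' circle (all ratios above `roundness_min`) and the enclosing-circle area
#' falls strictly inside the relative band `(a * S_mean, b * S_mean)`.
#'
#' @param ratios roundness ratios from [roundness_profile()].
#' @param area_circle_um2 enclosing-circle area Si in um^2.
#' @param s_mean per-image reference mean area in um^2.
#' @param a,b relative band bounds (defaults 0.3 and 5).
#' @param roundness_min per-point roundness floor (default 0.85).
#' @return Logical.
#' @export
is_recall_rbc <- function(ratios, area_circle_um2, s_mean, a = 0.3, b = 5,
                          roundness_min = 0.85) {
  if (!is.finite(s_mean) || s_mean <= 0) stop("`s_mean` must be positive")
  all(ratios > roundness_min) &&
    area_circle_um2 > a * s_mean && area_circle_um2 < b * s_mean
}

#' Enclosing-circle area Si
#'
#' `Si = pi * r^2` with r converted to micrometers by the calibration.
#'
#' @param radius_px enclosing-circle radius in pixels (> 0).
#' @param microns_per_pixel calibration, um/px.
#' @return Si in um^2.
#' @export
area_si <- function(radius_px, microns_per_pixel) {
  if (any(radius_px <= 0)) stop("radius must be positive")
  pi * (radius_px * microns_per_pixel)^2
}

#' Roundness-corrected RBC area Sr
#'
#' `Sr = Si * Pmean^2`: shrinking the enclosing-circle radius by the mean
#' radial ratio recovers the cell's own area in the manner of a polar
#' integral, so Sr approximates the true disk area for near-circular
#' cells.
#'
#' @param si_um2 enclosing-circle area (> 0).
#' @param pmean per-cell mean radial ratio, in (0, 1].
#' @return Sr in um^2 (always <= Si).
#' @export
area_sr <- function(si_um2, pmean) {
  if (any(si_um2 <= 0)) stop("Si must be positive")
  if (any(pmean <= 0 | pmean > 1)) stop("Pmean must lie in (0, 1]")
  si_um2 * pmean^2
}

#' Coefficient of variation in percent
#'
#' `100 * SD / mean` — the dispersion measure reported alongside every
#' group's area distribution.
#'
#' @param mean_value distribution mean (nonzero).
#' @param sd_value distribution standard deviation.
#' @return CV in percent.
#' @export
cv_percent <- function(mean_value, sd_value) {
  if (any(mean_value == 0)) stop("CV undefined for zero mean")
  100 * sd_value / mean_value
}

#' Summarize the measured RBC areas of one subject's smear
#'
#' Averages the roundness-corrected areas Sr over the cells classified as
#' RBC that passed the recall check. SD uses the n-1 denominator; with a
#' single cell the SD (and CV) are undefined and reported as `NA`.
#'
#' @param cells data frame of per-cell records with columns `cell_class`,
#'   `recall` and `sr_um2` (as produced by [measure_smear()]).
#' @param subject_id subject label.
#' @param include_non_recall if `TRUE`, non-recall RBCs enter the average
#'   too (default `FALSE`: deformed or clipped cells are excluded).
#' @return One-row data frame of class `smear_summary`: `subject_id`,
#'   `n_rbc_measured`, `mean_area_um2`, `sd_area_um2`, `cv_percent`.
#' @export
summarize_smear <- function(cells, subject_id, include_non_recall = FALSE) {
  keep <- if (nrow(cells))
    cells$cell_class == "rbc" & (cells$recall | include_non_recall)
  else logical(0)
  sr <- cells$sr_um2[keep]
  sr <- sr[is.finite(sr)]
  n <- length(sr)
  m <- if (n > 0) mean(sr) else NA_real_
  s <- if (n > 1) stats::sd(sr) else NA_real_
  structure(
    data.frame(subject_id = as.character(subject_id), n_rbc_measured = n,
               mean_area_um2 = m, sd_area_um2 = s,
               cv_percent = if (n > 1) cv_percent(m, s) else NA_real_,
               stringsAsFactors = FALSE),
    class = c("smear_summary", "data.frame")
  )
}
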
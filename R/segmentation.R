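#' Segment cell regions from the smear background
#'
#' Computes Otsu's between-class-variance-maximizing threshold on one HSV
#' channel (the saturation channel by default) and marks pixels above it as
#' foreground. On a Wright-Giemsa smear the stained cells are the saturated
#' objects; the background is pale and nearly achromatic.
#'
#' @param hsv an `hsv_image` from [rgb_to_hsv()].
#' @param channel channel to threshold: `"s"` (default), `"v"` or `"h"`.
#' @return A logical matrix (`TRUE` = foreground) with the image
#'   dimensions; the threshold is attached as attribute `"threshold"`.
#' @export
otsu_segment <- function(hsv, channel = "s") {
  stopifnot(inherits(hsv, "hsv_image"))
  channel <- match.arg(channel, c("s", "v", "h"))
  x <- hsv[[channel]]
  if (channel == "h") x <- x / 360
  rng <- range(x)
  if (diff(rng) < 1e-6)
    stop("degenerate threshold: the '", channel,
         "' channel is constant (", signif(rng[1], 4), ")")
  thr <- EBImage::otsu(x, range = c(0, 1), levels = 256L)
  structure(x > thr, threshold = thr, dim = dim(x))
}

#' Refine a segmentation mask toward gray-level edges
#'
#' Applies a morphological closing (sealing small boundary gaps), then a
#' boundary adjustment: pixels within a 2-px band around the mask boundary
#' are reassigned to foreground or background according to whichever mean
#' gray level (inside vs outside the mask) they are closer to. The
#' adjustment is capped so the foreground pixel count changes by at most
#' 20% of its input value; when the cap binds, the pixels with the largest
#' gray-level margin are reassigned first.
#'
#' @param mask logical matrix from [otsu_segment()].
#' @param gray gray matrix from [rgb_to_gray()], same dimensions.
#' @param max_change_frac cap on the reassigned fraction of the input
#'   foreground (default 0.2).
#' @return A refined logical mask.
#' @export
edge_refine <- function(mask, gray, max_change_frac = 0.2) {
  if (!identical(dim(mask), dim(gray)))
    stop("mask and gray image dimensions differ")
  if (!any(mask) || all(mask)) return(mask)

  m <- EBImage::closing(mask + 0L, EBImage::makeBrush(3L, "diamond")) > 0
  if (!any(m) || all(m)) return(m)

  fg_mean <- mean(gray[m])
  bg_mean <- mean(gray[!m])
  if (abs(fg_mean - bg_mean) < 1e-9) return(m)

  brush <- EBImage::makeBrush(5L, "disc")
  band <- (EBImage::dilate(m + 0L, brush) > 0) & !(EBImage::erode(m + 0L, brush) > 0)
  idx <- which(band)
  to_fg <- abs(gray[idx] - fg_mean) < abs(gray[idx] - bg_mean)
  changed <- idx[to_fg != m[idx]]
  cap <- floor(max_change_frac * sum(mask))
  if (length(changed) > cap) {
    margin <- abs(abs(gray[changed] - fg_mean) - abs(gray[changed] - bg_mean))
    changed <- changed[order(margin, decreasing = TRUE)][seq_len(cap)]
  }
  m[changed] <- !m[changed]
  m
}

# Signed shoelace area of a closed polygon given as an n x 2 matrix of
# vertices (absolute value returned).
shoelace_area <- function(pts) {
  n <- nrow(pts)
  if (n < 3L) return(0)
  x <- pts[, 1]; y <- pts[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

# Merge labels of diagonally adjacent components so that labelling is
# 8-connected (EBImage::bwlabel is 4-connected). Returns a relabelled
# integer matrix with consecutive labels 1..k.
label_8connected <- function(mask) {
  lab <- EBImage::bwlabel(mask + 0L)
  nr <- nrow(lab); nc <- ncol(lab)
  a <- lab[-nr, -nc]; b <- lab[-1, -1]    # "\" diagonal neighbours
  c_ <- lab[-nr, -1]; d <- lab[-1, -nc]   # "/" diagonal neighbours
  sel1 <- a > 0 & b > 0 & a != b
  sel2 <- c_ > 0 & d > 0 & c_ != d
  pairs <- rbind(cbind(a[sel1], b[sel1]), cbind(c_[sel2], d[sel2]))
  nlab <- max(lab)
  parent <- seq_len(max(nlab, 1L))
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(nlab), find, integer(1))
  remap <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- remap[lab[lab > 0]]
  storage.mode(out) <- "integer"
  out
}

#' Extract outer cell contours from a binary mask
#'
#' Holes inside cells (the central pallor of an RBC) are filled before
#' labelling, so only the OUTER boundary of each 8-connected foreground
#' component is traced. The contour area in pixels is the lattice-point
#' count of the boundary polygon (shoelace area plus the Pick boundary
#' correction `B/2 + 1`), which matches the pixel fill of the component;
#' the raw shoelace polygon area is used for the convexity ratio.
#'
#' @param mask logical matrix, `TRUE` = foreground.
#' @param microns_per_pixel calibration used to report `area_um2`.
#' @return A list of `cell_contour` objects, each a list with `points`
#'   (n x 2 matrix of 1-based (row, col) boundary pixel centers),
#'   `area_px`, `area_um2`, `convexity_ratio`, `n_pixels`, `pixel_idx`
#'   (linear indices of the filled component, for gray-level statistics),
#'   `stage` and `status` (both `"unassigned"` until filtering).
#' @export
extract_outer_contours <- function(mask, microns_per_pixel) {
  if (!any(mask)) return(list())
  filled <- EBImage::fillHull(mask + 0L) > 0
  lab <- label_8connected(filled)
  ids <- seq_len(max(lab))
  oc <- EBImage::ocontour(lab)
  lapply(ids, function(i) {
    pts <- oc[[i]] + 1  # 0-based (row-1, col-1) -> 1-based (row, col)
    pix <- which(lab == i)
    if (nrow(pts) >= 4L) {
      poly <- shoelace_area(pts)
      area_px <- poly + nrow(pts) / 2 + 1
      hull <- grDevices::chull(pts)
      hull_area <- shoelace_area(pts[hull, , drop = FALSE])
      convexity <- if (hull_area > 0) min(poly / hull_area, 1) else 1
    } else {
      area_px <- length(pix)
      convexity <- 1
    }
    structure(
      list(points = pts, area_px = area_px,
           area_um2 = px_area_to_um2(area_px, microns_per_pixel),
           convexity_ratio = convexity, n_pixels = length(pix),
           pixel_idx = pix, stage = "unassigned", status = "unassigned"),
      class = "cell_contour"
    )
  })
}

#' Partition contours into noise, pending and candidate sets
#'
#' Contours below the noise floor are rejected outright; contours in
#' `[noise_floor, pending_ceiling)` um^2 are "pending" — debris and
#' fragments too small to be cells, excluded both from the reference mean
#' S_mean and from single-cell selection; contours at or above the ceiling
#' are candidates.
#'
#' @param contours list of `cell_contour` from [extract_outer_contours()].
#' @param noise_floor_um2 lower bound of the pending band (default 0.5).
#' @param pending_ceiling_um2 upper bound, exclusive (default 10).
#' @return The contour list with `stage` set to `"noise"`, `"pending"` or
#'   `"candidate"`; noise contours also get `status = "rejected"` and
#'   pending contours `status = "pending"`.
#' @export
flag_pending <- function(contours, noise_floor_um2 = 0.5,
                         pending_ceiling_um2 = 10) {
  if (pending_ceiling_um2 <= noise_floor_um2)
    stop("pending ceiling (", pending_ceiling_um2,
         ") must exceed the noise floor (", noise_floor_um2, ")")
  lapply(contours, function(ct) {
    if (ct$area_um2 < noise_floor_um2) {
      ct$stage <- "noise"; ct$status <- "rejected"
    } else if (ct$area_um2 < pending_ceiling_um2) {
      ct$stage <- "pending"; ct$status <- "pending"
    } else {
      ct$stage <- "candidate"
    }
    ct
  })
}

#' Mean area of non-pending contours (S_mean)
#'
#' S_mean is the per-image average area of all outer contours except the
#' pending (and noise) ones; it sets the scale for the relative selection
#' band `(a * S_mean, b * S_mean)`.
#'
#' @param contours list of contours after [flag_pending()].
#' @return An object of class `contour_set_summary`: list with
#'   `s_mean_um2` and the counts `n_total`, `n_noise`, `n_pending`,
#'   `n_candidate`.
#' @export
compute_s_mean <- function(contours) {
  stage <- vapply(contours, `[[`, character(1), "stage")
  cand <- contours[stage == "candidate"]
  if (!length(cand))
    stop("no candidate contours: S_mean is undefined for this field")
  structure(
    list(s_mean_um2 = mean(vapply(cand, `[[`, numeric(1), "area_um2")),
         n_total = length(contours), n_noise = sum(stage == "noise"),
         n_pending = sum(stage == "pending"),
         n_candidate = length(cand)),
    class = "contour_set_summary"
  )
}

#' Select effective single-cell contours
#'
#' A candidate whose area lies strictly inside `(a * S_mean, b * S_mean)`
#' and whose shape is convex (contour area / convex-hull area at or above
#' `convexity_min`) is an effective single cell. A candidate at or above
#' `b * S_mean` is a multi-cell merge and is excluded from measurement;
#' everything else is rejected. The interval is open at both ends.
#'
#' @param contours contour list after [flag_pending()].
#' @param s_mean reference mean area in um^2 (see [compute_s_mean()]).
#' @param a lower relative bound, in (0, 1); default 0.3.
#' @param b upper relative bound, > 1; default 5.
#' @param convexity_min minimum convexity ratio for a single cell
#'   (default 0.9; fused-cell dumbbells fall below it, rasterized disks
#'   above).
#' @return The contour list with `status` finalized for every candidate
#'   (`"effective"`, `"merged"` or `"rejected"`).
#' @export
select_effective_contours <- function(contours, s_mean, a = 0.3, b = 5,
                                      convexity_min = 0.9) {
  if (a <= 0 || a >= 1) stop("`a` must lie in (0, 1), got ", a)
  if (b <= 1) stop("`b` must exceed 1, got ", b)
  if (s_mean <= 0) stop("`s_mean` must be positive")
  lapply(contours, function(ct) {
    if (ct$stage != "candidate") return(ct)
    ct$status <-
      if (ct$area_um2 >= b * s_mean) "merged"
      else if (ct$area_um2 > a * s_mean &&
               ct$convexity_ratio >= convexity_min) "effective"
      else "rejected"
    ct
  })
}
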
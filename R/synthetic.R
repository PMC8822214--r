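# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic smear field
#'
#' Describes one 1000x-magnification field of view for the renderer:
#' image geometry, cell counts and sizes, Wright-Giemsa-like colors, and
#' noise. Defaults emulate a normal adult smear: round pale-red RBCs with
#' mean radius 3.75 um (area ~44.2 um^2, the normal-cohort mean), a
#' lighter central pallor, and occasional darker nucleated cells.
#'
#' @param width,height image size in pixels.
#' @param microns_per_pixel calibration (default 0.1 um/px).
#' @param n_rbc,n_nucleated cell counts.
#' @param rbc_radius_mean_um,rbc_radius_sd_um RBC equivalent-radius
#'   distribution (um).
#' @param nucleated_radius_mean_um nucleated-cell radius (um).
#' @param ellipticity_max cells are ellipses with axis ratio drawn from
#'   `[1, ellipticity_max]`; 1.05 keeps RBCs within the roundness gate.
#' @param fraction_touching fraction of RBCs placed as touching pairs
#'   (center distance below the sum of radii).
#' @param background,rbc_color,nucleus_color,nucleated_cytoplasm_color
#'   RGB triples in `[0, 255]`.
#' @param central_pallor_depth lightening of the RBC center, in `[0, 1]`.
#' @param nucleus_fraction fraction of a nucleated cell's area occupied
#'   by the nucleus (>= 0.5).
#' @param noise_sd additive Gaussian pixel noise SD (gray levels).
#' @param seed integer; fixes the entire scene.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(width = 512L, height = 512L, microns_per_pixel = 0.1,
                       n_rbc = 12L, n_nucleated = 2L,
                       rbc_radius_mean_um = 3.75, rbc_radius_sd_um = 0.2,
                       nucleated_radius_mean_um = 4.5,
                       ellipticity_max = 1.05, fraction_touching = 0,
                       background = c(245, 240, 240),
                       rbc_color = c(230, 160, 150),
                       nucleus_color = c(90, 60, 130),
                       nucleated_cytoplasm_color = c(150, 130, 180),
                       central_pallor_depth = 0.35,
                       nucleus_fraction = 0.6,
                       noise_sd = 4, seed = 1L) {
  spec <- list(width = as.integer(width), height = as.integer(height),
               microns_per_pixel = microns_per_pixel, n_rbc = as.integer(n_rbc),
               n_nucleated = as.integer(n_nucleated),
               rbc_radius_mean_um = rbc_radius_mean_um,
               rbc_radius_sd_um = rbc_radius_sd_um,
               nucleated_radius_mean_um = nucleated_radius_mean_um,
               ellipticity_max = ellipticity_max,
               fraction_touching = fraction_touching,
               background = background, rbc_color = rbc_color,
               nucleus_color = nucleus_color,
               nucleated_cytoplasm_color = nucleated_cytoplasm_color,
               central_pallor_depth = central_pallor_depth,
               nucleus_fraction = nucleus_fraction,
               noise_sd = noise_sd, seed = as.integer(seed))
  stopifnot(spec$n_rbc >= 0, spec$n_nucleated >= 0,
            spec$microns_per_pixel > 0, spec$ellipticity_max >= 1,
            spec$fraction_touching >= 0, spec$fraction_touching <= 1,
            spec$central_pallor_depth >= 0, spec$central_pallor_depth <= 1,
            all(vapply(list(spec$background, spec$rbc_color,
                            spec$nucleus_color,
                            spec$nucleated_cytoplasm_color),
                       function(col) length(col) == 3 && all(col >= 0) &&
                         all(col <= 255), logical(1))))
  class(spec) <- "scene_spec"
  spec
}

# Alpha-composite one anti-aliased rotated ellipse onto `img` (h x w x 3).
# `pallor` > 0 lightens the center toward `pallor_color`.
draw_ellipse <- function(img, center, a_px, b_px, angle, color,
                         pallor = 0, pallor_color = c(255, 255, 255)) {
  h <- dim(img)[1]; w <- dim(img)[2]
  half <- max(a_px, b_px) + 2
  r0 <- max(1L, floor(center[1] - half)); r1 <- min(h, ceiling(center[1] + half))
  c0 <- max(1L, floor(center[2] - half)); c1 <- min(w, ceiling(center[2] + half))
  rows <- r0:r1; cols <- c0:c1
  dy <- outer(rows - center[1], rep(1, length(cols)))
  dx <- outer(rep(1, length(rows)), cols - center[2])
  u <- (dy * cos(angle) + dx * sin(angle)) / a_px
  v <- (-dy * sin(angle) + dx * cos(angle)) / b_px
  d <- sqrt(u^2 + v^2)
  alpha <- pmin(1, pmax(0, (1 - d) * min(a_px, b_px) + 0.5))
  pw <- if (pallor > 0) pallor * pmax(0, pmin(1, (0.5 - d) / 0.15)) else 0
  for (ch in 1:3) {
    col_ch <- color[ch] * (1 - pw) + pallor_color[ch] * pw
    img[rows, cols, ch] <- img[rows, cols, ch] * (1 - alpha) + col_ch * alpha
  }
  img
}

#' Render a synthetic smear field with ground truth
#'
#' Places non-overlapping (or deliberately touching) elliptical cells on
#' a pale background, renders them with anti-aliasing — RBCs in pale red
#' with a central pallor, nucleated cells with a dark nucleus covering
#' most of the cell — and adds clipped Gaussian pixel noise. The output
#' is bit-reproducible for a given spec (the scene seed governs all
#' randomness and the caller's RNG state is untouched).
#'
#' @param spec a [scene_spec()].
#' @param max_tries placement retry budget per cell.
#' @return A `synthetic_scene` list: `image` (a [smear_image]), `truth`
#'   (data frame: `cell_id`, `label`, `center_row`, `center_col`,
#'   `semi_a_um`, `semi_b_um`, `true_area_um2`, `touching`), `spec`.
#' @export
generate_scene <- function(spec, max_tries = 2000L) {
  stopifnot(inherits(spec, "scene_spec"))
  mpp <- spec$microns_per_pixel
  with_seed(spec$seed, {
    n_pairs <- floor(spec$fraction_touching * spec$n_rbc / 2)
    labels <- c(rep("rbc", spec$n_rbc), rep("nucleated", spec$n_nucleated))
    n_cells <- length(labels)
    radius_um <- ifelse(
      labels == "rbc",
      pmax(1, stats::rnorm(n_cells, spec$rbc_radius_mean_um,
                           spec$rbc_radius_sd_um)),
      pmax(1.5, stats::rnorm(n_cells, spec$nucleated_radius_mean_um, 0.3)))
    ell <- stats::runif(n_cells, 1, spec$ellipticity_max)
    a_um <- radius_um * sqrt(ell); b_um <- radius_um / sqrt(ell)
    angle <- stats::runif(n_cells, 0, 2 * pi)

    gap_px <- 4
    # indices 2k-1, 2k of the first 2*n_pairs RBCs form touching pairs
    partner_of <- rep(NA_integer_, n_cells)
    if (n_pairs > 0)
      partner_of[seq_len(n_pairs) * 2] <- seq_len(n_pairs) * 2 - 1

    # sequential random packing; a failed sequence is restarted from
    # scratch (deterministic: the RNG stream simply continues)
    try_place <- function() {
      centers <- matrix(NA_real_, n_cells, 2)
      touching <- logical(n_cells)
      for (i in seq_len(n_cells)) {
        half_px <- max(a_um[i], b_um[i]) / mpp + 2
        placed <- FALSE
        for (t in seq_len(max_tries)) {
          if (!is.na(partner_of[i])) {
            j <- partner_of[i]
            th <- stats::runif(1, 0, 2 * pi)
            dist_px <- 0.85 * (radius_um[i] + radius_um[j]) / mpp
            cand <- centers[j, ] + dist_px * c(cos(th), sin(th))
            others <- setdiff(which(!is.na(centers[, 1])), j)
          } else {
            cand <- c(stats::runif(1, half_px, spec$height - half_px),
                      stats::runif(1, half_px, spec$width - half_px))
            others <- which(!is.na(centers[, 1]))
          }
          if (cand[1] < half_px || cand[1] > spec$height - half_px ||
              cand[2] < half_px || cand[2] > spec$width - half_px) next
          ok <- TRUE
          for (j2 in others) {
            min_d <- (max(a_um[i], b_um[i]) + max(a_um[j2], b_um[j2])) / mpp +
              gap_px
            if (sqrt(sum((cand - centers[j2, ])^2)) < min_d) { ok <- FALSE; break }
          }
          if (ok) {
            centers[i, ] <- cand
            if (!is.na(partner_of[i])) touching[c(i, partner_of[i])] <- TRUE
            placed <- TRUE
            break
          }
        }
        if (!placed) return(NULL)
      }
      list(centers = centers, touching = touching)
    }
    placement <- NULL
    for (attempt in 1:20) {
      placement <- try_place()
      if (!is.null(placement)) break
    }
    if (is.null(placement))
      stop("could not place ", n_cells, " cells within the retry budget; ",
           "reduce cell count or size")
    centers <- placement$centers
    touching <- placement$touching

    img <- array(rep(spec$background, each = spec$height * spec$width),
                 dim = c(spec$height, spec$width, 3))
    for (i in seq_len(n_cells)) {
      if (labels[i] == "rbc") {
        img <- draw_ellipse(img, centers[i, ], a_um[i] / mpp, b_um[i] / mpp,
                            angle[i], spec$rbc_color,
                            pallor = spec$central_pallor_depth,
                            pallor_color = spec$background)
      } else {
        img <- draw_ellipse(img, centers[i, ], a_um[i] / mpp, b_um[i] / mpp,
                            angle[i], spec$nucleated_cytoplasm_color)
        k <- sqrt(spec$nucleus_fraction)
        img <- draw_ellipse(img, centers[i, ], k * a_um[i] / mpp,
                            k * b_um[i] / mpp, angle[i], spec$nucleus_color)
      }
    }
    if (spec$noise_sd > 0)
      img <- img + stats::rnorm(length(img), 0, spec$noise_sd)
    img[] <- pmin(255, pmax(0, img))

    truth <- data.frame(
      cell_id = seq_len(n_cells), label = labels,
      center_row = centers[, 1], center_col = centers[, 2],
      semi_a_um = a_um, semi_b_um = b_um,
      true_area_um2 = pi * a_um * b_um, touching = touching,
      stringsAsFactors = FALSE)
    structure(
      list(image = smear_image(img, mpp,
                               source_id = paste0("synthetic-seed", spec$seed)),
           truth = truth, spec = spec),
      class = "synthetic_scene")
  })
}

#' Cohort moments emulated by the synthetic generator
#'
#' The published cohort that the generator reproduces by default: for each
#' group (normal subjects and patients with aplastic anemia, MDS and
#' megaloblastic anemia) the subject count, the mean and SD of per-subject
#' RBC area, whether the group's area distribution is skewed, and the
#' mean/SD of the four CBC indices. These moments double as the reference
#' values for coefficient-of-variation identities.
#'
#' @return Named list with one entry per group (`normal`, `AA`, `MDS`,
#'   `MA`), each a list `n`, `area_mean`, `area_sd`, `skewed`, `cbc`
#'   (4 x 2 matrix of mean/sd for mcv_fl, mch_pg, mchc_g_per_l,
#'   rdw_percent).
#' @export
reference_cohort_moments <- function() {
  cbc <- function(mcv, mch, mchc, rdw)
    matrix(c(mcv, mch, mchc, rdw), 4, 2, byrow = TRUE,
           dimnames = list(c("mcv_fl", "mch_pg", "mchc_g_per_l",
                             "rdw_percent"), c("mean", "sd")))
  list(
    normal = list(n = 25L, area_mean = 44.19, area_sd = 3.88, skewed = FALSE,
                  cbc = cbc(c(89.94, 5.87), c(29.60, 2.33),
                            c(328.44, 9.93), c(13.76, 1.66))),
    AA = list(n = 25L, area_mean = 43.47, area_sd = 4.37, skewed = TRUE,
              cbc = cbc(c(95.82, 14.25), c(33.22, 5.12),
                        c(347.05, 15.01), c(15.20, 3.91))),
    MDS = list(n = 68L, area_mean = 45.86, area_sd = 6.42, skewed = TRUE,
               cbc = cbc(c(100.80, 13.33), c(33.21, 4.92),
                         c(328.90, 14.59), c(18.90, 5.45))),
    MA = list(n = 64L, area_mean = 52.87, area_sd = 7.68, skewed = FALSE,
              cbc = cbc(c(123.26, 13.28), c(41.91, 4.93),
                        c(340.84, 11.47), c(19.16, 4.84)))
  )
}

#' Simulate a per-subject cohort table
#'
#' Draws per-subject mean RBC areas — normal for the normal and MA
#' groups, lognormal (matching the requested mean/SD) for the skewed AA
#' and MDS groups — together with CBC indices. By default the CBC indices
#' are drawn independently of area, encoding the null-correlation regime;
#' `area_cbc_correlation` injects a common latent factor for power
#' studies.
#'
#' @param moments group moments as returned by
#'   [reference_cohort_moments()] (any subset of groups).
#' @param area_cbc_correlation correlation between area and each CBC
#'   index within group (default 0).
#' @param seed integer seed; the draw is deterministic given it.
#' @return A data frame of class `rbc_cohort` with columns `subject_id`,
#'   `group` (factor), `mean_area_um2`, `mcv_fl`, `mch_pg`,
#'   `mchc_g_per_l`, `rdw_percent`.
#' @export
generate_cohort <- function(moments = reference_cohort_moments(),
                            area_cbc_correlation = 0, seed = 1L) {
  known <- c("normal", "AA", "MDS", "MA")
  if (!all(names(moments) %in% known))
    stop("unknown group name(s): ",
         paste(setdiff(names(moments), known), collapse = ", "))
  rho <- area_cbc_correlation
  stopifnot(abs(rho) <= 1)
  with_seed(seed, {
    rows <- lapply(names(moments), function(g) {
      m <- moments[[g]]
      stopifnot(m$n >= 2L, m$area_sd >= 0)
      if (m$skewed && m$area_sd > 0) {
        s2 <- log(1 + (m$area_sd / m$area_mean)^2)
        area <- stats::rlnorm(m$n, log(m$area_mean) - s2 / 2, sqrt(s2))
      } else {
        area <- stats::rnorm(m$n, m$area_mean, m$area_sd)
      }
      z_area <- if (stats::sd(area) > 0) scale(area)[, 1] else rep(0, m$n)
      cbc_draw <- function(mu, sd) {
        z <- stats::rnorm(m$n)
        mu + sd * (rho * z_area + sqrt(1 - rho^2) * z)
      }
      data.frame(
        subject_id = sprintf("%s_%02d", g, seq_len(m$n)), group = g,
        mean_area_um2 = area,
        mcv_fl = cbc_draw(m$cbc["mcv_fl", "mean"], m$cbc["mcv_fl", "sd"]),
        mch_pg = cbc_draw(m$cbc["mch_pg", "mean"], m$cbc["mch_pg", "sd"]),
        mchc_g_per_l = cbc_draw(m$cbc["mchc_g_per_l", "mean"],
                                m$cbc["mchc_g_per_l", "sd"]),
        rdw_percent = cbc_draw(m$cbc["rdw_percent", "mean"],
                               m$cbc["rdw_percent", "sd"]),
        stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$group <- factor(out$group, levels = intersect(known, names(moments)))
    rownames(out) <- NULL
    class(out) <- c("rbc_cohort", "data.frame")
    out
  })
}
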
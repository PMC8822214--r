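# Shared fixtures and independent oracles, built in code at test time.

# Binary disk mask: pixel centers within `radius` of `center` (row, col).
disk_mask <- function(nr, nc, center, radius) {
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  (rr - center[1])^2 + (cc - center[2])^2 <= radius^2
}

# Uniform-color smear image.
solid_image <- function(nr, nc, rgb, mpp = 0.1) {
  smear_image(array(rep(rgb, each = nr * nc), dim = c(nr, nc, 3)), mpp)
}

# Paint a disk of color `rgb` onto a smear image (hard edge, no AA).
paint_disk <- function(img, center, radius, rgb) {
  m <- disk_mask(dim(img$pixels)[1], dim(img$pixels)[2], center, radius)
  for (ch in 1:3) {
    plane <- img$pixels[, , ch]
    plane[m] <- rgb[ch]
    img$pixels[, , ch] <- plane
  }
  img
}

# Exhaustive O(n^4) minimum-enclosing-circle oracle: minimum over every
# valid 2- and 3-point support circle.
brute_mec <- function(P) {
  n <- nrow(P)
  best <- list(radius = Inf)
  check <- function(center, radius) {
    d <- sqrt((P[, 1] - center[1])^2 + (P[, 2] - center[2])^2)
    if (all(d <= radius + 1e-7) && radius < best$radius)
      best <<- list(center = center, radius = radius)
  }
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    ctr <- (P[i, ] + P[j, ]) / 2
    check(ctr, sqrt(sum((P[i, ] - ctr)^2)))
  }
  if (n >= 3) for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    p <- P[i, ]; q <- P[j, ]; r <- P[k, ]
    d <- 2 * (p[1] * (q[2] - r[2]) + q[1] * (r[2] - p[2]) + r[1] * (p[2] - q[2]))
    if (abs(d) < 1e-12) next
    ux <- (sum(p^2) * (q[2] - r[2]) + sum(q^2) * (r[2] - p[2]) +
             sum(r^2) * (p[2] - q[2])) / d
    uy <- (sum(p^2) * (r[1] - q[1]) + sum(q^2) * (p[1] - r[1]) +
             sum(r^2) * (q[1] - p[1])) / d
    check(c(ux, uy), sqrt(sum((p - c(ux, uy))^2)))
  }
  best
}

# Brute-force Otsu: scan all 256-bin thresholds for the maximum
# between-class variance.
brute_otsu <- function(x, levels = 256) {
  bins <- floor(pmin(x, 1 - 1e-12) * levels)
  h <- tabulate(bins + 1L, nbins = levels)
  p <- h / sum(h)
  mids <- (seq_len(levels) - 0.5) / levels
  best_t <- NA_real_; best_v <- -Inf
  for (t in 1:(levels - 1)) {
    w0 <- sum(p[1:t]); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(p[1:t] * mids[1:t]) / w0
    mu1 <- sum(p[(t + 1):levels] * mids[(t + 1):levels]) / w1
    v <- w0 * w1 * (mu0 - mu1)^2
    if (v > best_v) { best_v <- v; best_t <- t / levels }
  }
  best_t
}

# AUC oracle: concordant-pair fraction with half credit for ties.
brute_auc <- function(scores, is_case) {
  s1 <- scores[is_case]; s0 <- scores[!is_case]
  tot <- 0
  for (a in s1) for (b in s0)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(s1) * length(s0))
}

# Fabricate a minimal candidate contour with prescribed area/convexity
# for the selection-rule tests.
fake_contour <- function(area_um2, convexity = 0.95, stage = "candidate") {
  structure(
    list(points = rbind(c(1, 1), c(1, 2), c(2, 2), c(2, 1)),
         area_px = area_um2 / 0.01, area_um2 = area_um2,
         convexity_ratio = convexity, n_pixels = round(area_um2 / 0.01),
         pixel_idx = integer(), stage = stage,
         status = if (stage == "pending") "pending" else "unassigned"),
    class = "cell_contour")
}

# Match measured cells to ground-truth cells by nearest center.
match_truth <- function(cells, truth) {
  idx <- vapply(seq_len(nrow(cells)), function(i) {
    which.min((truth$center_row - cells$circle_row[i])^2 +
                (truth$center_col - cells$circle_col[i])^2)
  }, integer(1))
  truth[idx, ]
}
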
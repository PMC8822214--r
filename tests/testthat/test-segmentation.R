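test_that("Otsu segmentation recovers stained disks on a pale background", {
  img <- solid_image(128, 128, c(245, 240, 240))
  img <- paint_disk(img, c(40, 40), 12, c(230, 160, 150))
  img <- paint_disk(img, c(90, 85), 12, c(230, 160, 150))
  mask <- otsu_segment(rgb_to_hsv(img))
  truth <- disk_mask(128, 128, c(40, 40), 12) | disk_mask(128, 128, c(90, 85), 12)
  expect_equal(mask, truth, ignore_attr = TRUE)
})

test_that("Otsu on a constant channel raises a degenerate-threshold error", {
  img <- solid_image(128, 128, c(245, 240, 240))
  expect_error(otsu_segment(rgb_to_hsv(img)), "degenerate.*'s' channel")
})

test_that("Otsu threshold maximizes the brute-force between-class variance", {
  # the objective can plateau between well-separated modes, so compare the
  # achieved between-class variance, not the arg max
  objective <- function(x, thr) {
    lo <- x[x <= thr]; hi <- x[x > thr]
    length(lo) / length(x) * length(hi) / length(x) *
      (mean(lo) - mean(hi))^2
  }
  s <- matrix(c(rep(0.1, 2048), rep(0.9, 2048)), 64, 64)
  hsv <- structure(list(h = s * 0, s = s, v = s * 0 + 0.9),
                   class = "hsv_image")
  thr <- attr(otsu_segment(hsv), "threshold")
  expect_gt(thr, 0.1)
  expect_lt(thr, 0.9)
  expect_equal(objective(s, thr), objective(s, brute_otsu(s)),
               tolerance = 1e-6)

  set.seed(9)
  s2 <- matrix(c(runif(2000, 0, 0.3), runif(2096, 0.5, 1)), 64, 64)
  hsv2 <- structure(list(h = s2 * 0, s = s2, v = s2), class = "hsv_image")
  thr2 <- attr(otsu_segment(hsv2), "threshold")
  expect_equal(objective(s2, thr2), objective(s2, brute_otsu(s2)),
               tolerance = 1e-3)
})

test_that("edge refinement is a fixed point on an aligned sharp disk", {
  truth <- disk_mask(128, 128, c(64, 64), 20)
  gray <- matrix(240, 128, 128)
  gray[truth] <- 100
  expect_identical(edge_refine(truth, gray), truth)
})

test_that("edge refinement pulls a dilated mask back to the true boundary", {
  truth <- disk_mask(128, 128, c(64, 64), 20)
  gray <- matrix(240, 128, 128)
  gray[truth] <- 100
  dilated <- disk_mask(128, 128, c(64, 64), 22)
  refined <- edge_refine(dilated, gray)
  # every refined-foreground pixel within 1 px of the true disk, and the
  # true disk fully retained
  expect_true(all(refined[truth]))
  outer1 <- disk_mask(128, 128, c(64, 64), 21)
  expect_true(all(!refined[!outer1]))
  expect_lte(abs(sum(refined) - sum(truth)) / sum(truth), 0.2)
})

test_that("edge refinement handles empty masks and rejects mismatched dims", {
  empty <- matrix(FALSE, 80, 80)
  expect_identical(edge_refine(empty, matrix(0, 80, 80)), empty)
  expect_error(edge_refine(empty, matrix(0, 80, 81)), "dimensions differ")
})

test_that("outer contours: one per 8-connected component, holes ignored", {
  # single 21-px-diameter disk
  m <- disk_mask(100, 100, c(50, 50), 10.5)
  ct <- extract_outer_contours(m, 0.1)
  expect_length(ct, 1)
  expect_lt(abs(ct[[1]]$area_px - pi * 10.5^2) / (pi * 10.5^2), 0.05)

  # two disjoint disks
  m2 <- disk_mask(100, 100, c(30, 30), 9) | disk_mask(100, 100, c(70, 70), 9)
  expect_length(extract_outer_contours(m2, 0.1), 2)

  # annulus: outer contour only, full outer-disk area
  ann <- disk_mask(100, 100, c(50, 50), 15) & !disk_mask(100, 100, c(50, 50), 7)
  ct3 <- extract_outer_contours(ann, 0.1)
  expect_length(ct3, 1)
  expect_lt(abs(ct3[[1]]$area_px - pi * 15^2) / (pi * 15^2), 0.05)

  # diagonal-touching pixels belong to one component (8-connectivity)
  m4 <- matrix(FALSE, 70, 70)
  m4[cbind(c(10, 11), c(10, 11))] <- TRUE
  expect_length(extract_outer_contours(m4, 0.1), 1)

  expect_identical(extract_outer_contours(matrix(FALSE, 70, 70), 0.1), list())
})

test_that("shoelace contour area tracks the pixel fill within 5% for r >= 8", {
  for (r in c(8, 12, 20, 33)) {
    m <- disk_mask(90, 90, c(45, 45), r)
    ct <- extract_outer_contours(m, 0.1)[[1]]
    expect_lt(abs(ct$area_px - ct$n_pixels) / ct$n_pixels, 0.05)
  }
})

test_that("pending partition follows the 0.5-10 um2 band", {
  cts <- flag_pending(lapply(c(0.2, 5, 40), fake_contour, stage = "unassigned"))
  expect_identical(vapply(cts, `[[`, character(1), "stage"),
                   c("noise", "pending", "candidate"))
  expect_identical(vapply(cts, `[[`, character(1), "status")[1:2],
                   c("rejected", "pending"))

  expect_identical(flag_pending(list()), list())

  # ceiling excluded from the pending band
  at10 <- flag_pending(lapply(c(10, 10), fake_contour, stage = "unassigned"))
  expect_true(all(vapply(at10, `[[`, character(1), "stage") == "candidate"))

  expect_error(flag_pending(list(), 10, 0.5), "exceed")
})

test_that("S_mean is the mean candidate area", {
  cts <- flag_pending(lapply(c(40, 50, 60), fake_contour, stage = "unassigned"))
  expect_equal(compute_s_mean(cts)$s_mean_um2, 50)
  one <- flag_pending(list(fake_contour(44, stage = "unassigned")))
  expect_equal(compute_s_mean(one)$s_mean_um2, 44)

  set.seed(21)
  areas <- runif(100, 11, 90)
  many <- flag_pending(lapply(areas, fake_contour, stage = "unassigned"))
  expect_equal(compute_s_mean(many)$s_mean_um2, sum(areas) / 100,
               tolerance = 1e-9)

  only_small <- flag_pending(list(fake_contour(3, stage = "unassigned")))
  expect_error(compute_s_mean(only_small), "no candidate")
})

test_that("effective-contour selection applies the (a*S, b*S) band and convexity", {
  cts <- lapply(c(20, 60, 300), fake_contour)
  out <- select_effective_contours(cts, s_mean = 50)
  expect_identical(vapply(out, `[[`, character(1), "status"),
                   c("effective", "effective", "merged"))

  # boundary: area exactly a * S_mean is outside the open interval
  at_edge <- select_effective_contours(list(fake_contour(15)), s_mean = 50)
  expect_identical(at_edge[[1]]$status, "rejected")

  # low convexity (fused-cell dumbbell) is rejected even in range
  dumb <- select_effective_contours(list(fake_contour(60, convexity = 0.75)),
                                    s_mean = 50)
  expect_identical(dumb[[1]]$status, "rejected")

  expect_error(select_effective_contours(cts, 50, a = 1.2), "a")
  expect_error(select_effective_contours(cts, 50, b = 0.9), "b")
})

test_that("a fused-disk dumbbell polygon fails the convexity criterion", {
  # two circles of radius 20 px with centers 38 px apart: union outline
  th <- seq(0, 2 * pi, length.out = 400)
  c1 <- cbind(20 * cos(th), 20 * sin(th))
  c2 <- cbind(20 * cos(th), 38 + 20 * sin(th))
  keep1 <- c1[, 2]^2 + (c1[, 1])^2 >= 0 & (c1[, 2] - 38)^2 + c1[, 1]^2 > 400
  keep2 <- (c2[, 2])^2 + c2[, 1]^2 > 400
  poly <- rbind(c1[keep1, ], c2[keep2, ])
  ang <- atan2(poly[, 1], poly[, 2] - 19)
  poly <- poly[order(ang), ]
  # convex-hull-area oracle
  hull <- grDevices::chull(poly)
  sho <- function(p) { n <- nrow(p); x <- p[, 1]; y <- p[, 2]
    abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2 }
  ratio <- sho(poly) / sho(poly[hull, ])
  expect_lt(ratio, 0.9)
})

test_that("every contour of a scene receives exactly one final status", {
  sc <- generate_scene(scene_spec(seed = 13, n_rbc = 8, n_nucleated = 2,
                                  width = 448L, height = 448L))
  m <- measure_smear(sc$image)
  status <- vapply(m$contours, `[[`, character(1), "status")
  expect_true(all(status %in% c("pending", "effective", "merged", "rejected")))
  counts <- table(factor(status, c("pending", "effective", "merged", "rejected")))
  expect_equal(sum(counts), length(m$contours))
  # non-touching scene: effective contours = generated cells
  expect_equal(sum(status == "effective"), nrow(sc$truth))
})

test_that("selection decisions are invariant under calibration rescaling", {
  m <- disk_mask(128, 128, c(40, 40), 20) | disk_mask(128, 128, c(90, 85), 26)
  k <- 2.5
  run <- function(mpp, floor_um2, ceil_um2) {
    ct <- flag_pending(extract_outer_contours(m, mpp), floor_um2, ceil_um2)
    sm <- compute_s_mean(ct)$s_mean_um2
    list(ct = select_effective_contours(ct, sm), sm = sm)
  }
  r1 <- run(0.1, 0.5, 10)
  r2 <- run(0.1 * k, 0.5 * k^2, 10 * k^2)
  a1 <- vapply(r1$ct, `[[`, numeric(1), "area_um2")
  a2 <- vapply(r2$ct, `[[`, numeric(1), "area_um2")
  expect_equal(a2, k^2 * a1, tolerance = 1e-12)
  expect_equal(r2$sm, k^2 * r1$sm, tolerance = 1e-12)
  expect_identical(vapply(r1$ct, `[[`, character(1), "status"),
                   vapply(r2$ct, `[[`, character(1), "status"))
})
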
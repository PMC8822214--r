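test_that("minimum enclosing circle solves closed-form cases", {
  sq <- min_enclosing_circle(rbind(c(0, 0), c(0, 10), c(10, 0), c(10, 10)))
  expect_equal(sq$center, c(5, 5), tolerance = 1e-9)
  expect_equal(sq$radius, 5 * sqrt(2), tolerance = 1e-9)

  th <- seq(0, 2 * pi, length.out = 61)[-61]
  circ <- min_enclosing_circle(cbind(3 + 12 * cos(th), -5 + 12 * sin(th)))
  expect_equal(circ$radius, 12, tolerance = 1e-6)
  expect_equal(circ$center, c(3, -5), tolerance = 1e-6)

  # three collinear points: diameter circle of the extremes
  col3 <- min_enclosing_circle(rbind(c(0, 0), c(4, 4), c(10, 10)))
  expect_equal(col3$radius, 5 * sqrt(2), tolerance = 1e-9)

  expect_error(min_enclosing_circle(rbind(c(1, 1), c(2, 2))), "degenerate")
  expect_error(min_enclosing_circle(rbind(c(1, 1), c(1, 1), c(1, 1))),
               "degenerate")
})

test_that("minimum enclosing circle matches the exhaustive oracle", {
  set.seed(101)
  for (rep in 1:25) {
    n <- sample(5:40, 1)
    P <- matrix(stats::runif(2 * n, 0, 100), n, 2)
    got <- min_enclosing_circle(P)
    want <- brute_mec(P)
    expect_equal(got$radius, want$radius, tolerance = 1e-6)
    # every point enclosed
    d <- sqrt((P[, 1] - got$center[1])^2 + (P[, 2] - got$center[2])^2)
    expect_lte(max(d), got$radius + 1e-6)
  }
})

test_that("roundness profile and Pmean behave on canonical shapes", {
  th <- seq(0, 2 * pi, length.out = 200)[-200]
  circ <- cbind(10 * cos(th), 10 * sin(th))
  rp <- roundness_profile(circ, c(0, 0), 10)
  expect_true(all(abs(rp$ratios - 1) < 1e-9))
  expect_equal(rp$pmean, 1, tolerance = 1e-9)

  # grid containing the exact vertices/co-vertices so the enclosing circle
  # is the closed-form one (radius 10 about the origin)
  the <- seq(0, 2 * pi, length.out = 201)[-201]
  ell <- cbind(10 * cos(the), 8 * sin(the))
  mec <- min_enclosing_circle(ell)
  expect_equal(mec$radius, 10, tolerance = 1e-9)
  rpe <- roundness_profile(ell, mec$center, mec$radius)
  expect_equal(min(rpe$ratios), 0.8, tolerance = 1e-9)
  expect_gt(rpe$pmean, 0.8)
  expect_lt(rpe$pmean, 1)
  # dense-sampling oracle for the mean radial ratio of the ellipse
  oracle <- mean(sqrt((10 * cos(the))^2 + (8 * sin(the))^2) / 10)
  expect_equal(rpe$pmean, oracle, tolerance = 1e-6)

  tri <- rbind(c(2, 0), c(0, 2), c(1, 0))
  rp3 <- roundness_profile(tri, c(0, 0), 2)
  expect_equal(rp3$pmean, 5 / 6, tolerance = 1e-12)

  expect_error(roundness_profile(tri, c(0, 0), 0), "positive")
})

test_that("recall requires all-point roundness and the relative area band", {
  ones <- rep(1, 50)
  expect_true(is_recall_rbc(ones, 44, 44))           # 13.2 < 44 < 220
  expect_false(is_recall_rbc(c(ones, 0.7), 44, 44))  # one dented point
  expect_false(is_recall_rbc(ones, 300, 50))         # 300 >= 5 * 50
  expect_false(is_recall_rbc(ones, 15, 50))          # 15 <= 0.3 * 50
  expect_error(is_recall_rbc(ones, 44, 0), "positive")
})

test_that("Si and Sr follow the circle-area formulas", {
  expect_equal(area_si(37.5, 0.1), pi * 3.75^2, tolerance = 1e-12)
  expect_equal(area_si(10, 0.1), pi, tolerance = 1e-12)
  expect_equal(area_si(20, 0.1), 4 * area_si(10, 0.1), tolerance = 1e-12)
  expect_error(area_si(0, 0.1), "positive")

  expect_equal(area_sr(50, 1), 50)
  expect_equal(area_sr(50, 0.9), 40.5)
  expect_error(area_sr(50, 0), "Pmean")
  expect_error(area_sr(50, 1.2), "Pmean")
  expect_error(area_sr(-3, 0.9), "Si")

  set.seed(17)
  si <- runif(50, 10, 90); pm <- runif(50, 0.6, 1)
  expect_true(all(mapply(area_sr, si, pm) <= si))
})

test_that("Sr of a rasterized disk approximates its pixel-count area", {
  m <- disk_mask(120, 120, c(60, 60), 40)
  ct <- extract_outer_contours(m, 0.1)[[1]]
  mec <- min_enclosing_circle(ct)
  rp <- roundness_profile(ct, mec$center, mec$radius)
  sr <- area_sr(area_si(mec$radius, 0.1), rp$pmean)
  pixel_area <- px_area_to_um2(sum(m), 0.1)
  expect_lt(abs(sr - pixel_area) / pixel_area, 0.03)
})

test_that("smear summary averages recall RBCs with sample SD", {
  cells <- data.frame(cell_class = "rbc", recall = TRUE,
                      sr_um2 = c(40, 44, 48))
  s <- summarize_smear(cells, "subj1")
  expect_equal(s$n_rbc_measured, 3)
  expect_equal(s$mean_area_um2, 44)
  expect_equal(s$sd_area_um2, 4)
  expect_equal(s$cv_percent, 100 * 4 / 44, tolerance = 1e-9)

  one <- summarize_smear(data.frame(cell_class = "rbc", recall = TRUE,
                                    sr_um2 = 44), "s")
  expect_equal(one$mean_area_um2, 44)
  expect_true(is.na(one$sd_area_um2))

  none <- summarize_smear(data.frame(cell_class = "nucleated", recall = TRUE,
                                     sr_um2 = 60), "s")
  expect_equal(none$n_rbc_measured, 0)
  expect_true(is.na(none$mean_area_um2))

  # non-recall cells excluded unless explicitly included
  mix <- data.frame(cell_class = "rbc", recall = c(TRUE, TRUE, FALSE),
                    sr_um2 = c(40, 44, 90))
  expect_equal(summarize_smear(mix, "s")$mean_area_um2, 42)
  expect_equal(summarize_smear(mix, "s", include_non_recall = TRUE)$mean_area_um2,
               58)
})

test_that("summary moments agree with an independent two-pass oracle", {
  set.seed(41)
  sr <- rnorm(200, 44, 4)
  cells <- data.frame(cell_class = "rbc", recall = TRUE, sr_um2 = sr)
  s <- summarize_smear(cells, "x")
  m1 <- sum(sr) / length(sr)
  v <- sum((sr - m1)^2) / (length(sr) - 1)
  expect_equal(s$mean_area_um2, m1, tolerance = 1e-9)
  expect_equal(s$sd_area_um2, sqrt(v), tolerance = 1e-9)
  expect_equal(s$cv_percent, 100 * sqrt(v) / m1, tolerance = 1e-9)
})

test_that("mean Sr of generated circular cells tracks the true disk area", {
  for (r_um in c(3, 4, 5)) {
    sc <- generate_scene(scene_spec(seed = 300 + r_um, n_rbc = 6,
                                    n_nucleated = 0, width = 384L,
                                    height = 384L, rbc_radius_mean_um = r_um,
                                    rbc_radius_sd_um = 0,
                                    ellipticity_max = 1))
    m <- measure_smear(sc$image)
    truth_area <- pi * r_um^2
    expect_lte(abs(m$summary$mean_area_um2 - truth_area) / truth_area, 0.05)
  }
})
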
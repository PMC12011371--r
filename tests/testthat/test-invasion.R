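sim_field <- gen_invasion_field(100, 0.4, seed = 11)

test_that("degradation segmentation finds the dark patches, not noise", {
  mask <- segment_degradation(sim_field$gelatin)
  truth_area <- attr(sim_field$truth, "patch_area_px")
  expect_lt(abs(sum(mask) - truth_area) / truth_area, 0.1)
  # uniform and noise-only fields give empty masks
  expect_warning(m0 <- segment_degradation(fluorescence_image(matrix(1, 64, 64))),
                 "constant")
  expect_false(any(m0))
  noise <- gen_invasion_field(50, 0, seed = 3)$gelatin
  expect_false(any(segment_degradation(noise)))
})

test_that("segmentation is invariant to affine intensity rescaling", {
  g <- sim_field$gelatin
  g2 <- fluorescence_image(g$pixels * 3 + 10, g$pixel_size_um, g$channel)
  m1 <- segment_degradation(g)
  m2 <- segment_degradation(g2)
  expect_identical(unclass(m1)[, ], unclass(m2)[, ])
})

test_that("nucleus detection is unbiased with an exclusion radius", {
  expect_equal(nrow(detect_nuclei(fluorescence_image(matrix(0, 64, 64)))), 0)
  pts <- detect_nuclei(sim_field$dapi)
  expect_lte(abs(nrow(pts) - 100), 2)
  # positions land near the true nuclei (sub-pixel refinement)
  d2min <- vapply(seq_len(nrow(pts)), function(i) {
    min((sim_field$truth$row - pts$row[i])^2 +
          (sim_field$truth$col - pts$col[i])^2)
  }, numeric(1))
  expect_lt(sqrt(max(d2min)), 2)
  # two blobs closer than the exclusion radius collapse to one point
  two <- matrix(0, 40, 40)
  two <- crowdquant:::add_gaussian_blob(two, 20, 18, 2, 1)
  two <- crowdquant:::add_gaussian_blob(two, 20, 22, 2, 1)
  expect_equal(nrow(detect_nuclei(fluorescence_image(two),
                                  min_separation_px = 5)), 1)
})

test_that("invasive fraction obeys its boundary and monotonicity laws", {
  pts <- detect_nuclei(sim_field$dapi)
  full <- structure(matrix(TRUE, 384, 384), threshold = 0.5,
                    method = "manual", class = "degradation_mask")
  none <- structure(matrix(FALSE, 384, 384), threshold = 0.5,
                    method = "manual", class = "degradation_mask")
  expect_equal(invasive_fraction(full, pts)$invasive_fraction, 1)
  expect_equal(invasive_fraction(none, pts)$invasive_fraction, 0)
  expect_error(invasive_fraction(none, pts[0, ]), "undefined|no cells")
  mask <- segment_degradation(sim_field$gelatin)
  f0 <- invasive_fraction(mask, pts)$invasive_fraction
  dil <- EBImage::dilate(EBImage::Image(unclass(mask)[, ]),
                         EBImage::makeBrush(9, "disc"))
  grown <- structure(matrix(as.logical(dil), 384, 384), threshold = 0.5,
                     method = "dilated", class = "degradation_mask")
  expect_gte(invasive_fraction(grown, pts)$invasive_fraction, f0)
})

test_that("the whole invasion pipeline is scale invariant", {
  g2 <- fluorescence_image(sim_field$gelatin$pixels * 7)
  d2 <- fluorescence_image(sim_field$dapi$pixels * 7)
  a <- invasive_fraction(segment_degradation(sim_field$gelatin),
                         detect_nuclei(sim_field$dapi))
  b <- invasive_fraction(segment_degradation(g2), detect_nuclei(d2))
  expect_equal(a$invasive_fraction, b$invasive_fraction)
})

test_that("invasive fraction recovers generator truth across the range", {
  for (f in c(0, 0.5, 1)) {
    s <- gen_invasion_field(100, f, seed = 21)
    est <- invasive_fraction(segment_degradation(s$gelatin),
                             detect_nuclei(s$dapi))$invasive_fraction
    expect_lt(abs(est - f), 0.05)
  }
})

test_that("viability fraction counts greedy one-to-one matches", {
  all_pts <- structure(data.frame(row = runif(1000, 10, 500),
                                  col = runif(1000, 10, 500),
                                  score = 1),
                       class = c("point_set", "data.frame"))
  none <- all_pts[0, ]
  expect_equal(viability_fraction(none, all_pts), 0)
  expect_equal(viability_fraction(all_pts, all_pts), 1)
  dead <- all_pts[1:20, ]
  dead$row <- dead$row + 0.5  # slight registration offset
  expect_equal(viability_fraction(dead, all_pts, match_radius_px = 4), 0.02)
  expect_error(viability_fraction(dead, none), "empty")
})
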
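test_that("Canny finds no edges in flat images and rings around squares", {
  expect_equal(sum(detect_edges(uniform_image(100, 16, 16))), 0)
  m <- matrix(40, 24, 24)
  m[8:17, 8:17] <- 220
  img <- gray_image(m)
  edges <- detect_edges(img, contour_params(5, 15))
  expect_gt(sum(edges), 0)
  # the ring encloses the square's interior
  enc <- enclosed_components(close_gaps(edges, 1))
  expect_equal(nrow(enc), 1)
  inner <- matrix(FALSE, 24, 24); inner[enc$pixels[[1]]] <- TRUE
  expect_true(all(which(inner) %in% which(m == 220)))
  expect_true(inner[12, 12])
  # a single sub-threshold impulse produces nothing
  m2 <- matrix(100, 16, 16); m2[8, 8] <- 102
  expect_equal(sum(detect_edges(gray_image(m2), contour_params(3, 6))), 0)
  expect_error(contour_params(6, 6), "canny_low < canny_high")
})

test_that("closing is extensive and bridges a 1-pixel gap at radius 1", {
  ring <- square_ring(15, 15, 4, 11, 4, 11)
  closed <- close_gaps(ring, 1)
  expect_true(all(closed[ring])) # extensive
  expect_equal(nrow(enclosed_components(closed)), 1)

  gapped <- ring
  gapped[4, 8] <- FALSE
  expect_equal(nrow(enclosed_components(gapped)), 0) # leak through the gap
  bridged <- close_gaps(gapped, 1)
  expect_true(bridged[4, 8])
  expect_equal(nrow(enclosed_components(bridged)), 1)

  # oracle: explicit dilate-then-erode with the same 3x3 structuring element
  off <- as.matrix(expand.grid(dr = -1:1, dc = -1:1))
  want <- erode_with(dilate_with(gapped, off), off) | gapped
  expect_identical(close_gaps(gapped, 1), want)

  expect_equal(sum(close_gaps(matrix(FALSE, 8, 8), 1)), 0)
})

test_that("enclosed components come from border-seeded flood fill", {
  h <- 30; w <- 30
  ring <- square_ring(h, w, 5, 25, 5, 25)
  enc <- enclosed_components(ring)
  expect_equal(nrow(enc), 1)
  expect_equal(enc$size, (25 - 5 - 1)^2)
  # flood-fill oracle: interior = not edge, not reachable from the border
  want <- !ring & !oracle_flood_outside(ring)
  got <- matrix(FALSE, h, w); got[enc$pixels[[1]]] <- TRUE
  expect_identical(got, want)

  open_ring <- ring; open_ring[5, 10:14] <- FALSE
  expect_equal(nrow(enclosed_components(open_ring)), 0)

  nested <- ring | square_ring(h, w, 10, 20, 10, 20)
  enc2 <- enclosed_components(nested)
  expect_equal(nrow(enc2), 2) # annulus and inner disk
  expect_setequal(enc2$size, c((25 - 5 - 1)^2 - (20 - 10 + 1)^2,
                               (20 - 10 - 1)^2))

  # a region touching the border is never enclosed
  tube <- matrix(FALSE, 10, 10)
  tube[, 4] <- TRUE; tube[, 7] <- TRUE # open-ended corridor
  expect_equal(nrow(enclosed_components(tube)), 0)
})

test_that("perimeter rings sit one pixel beyond the contour", {
  edges <- matrix(FALSE, 9, 9)
  ring <- component_perimeter_ring(cbind(5, 5), edges)
  expect_equal(nrow(ring), 8)
  expect_true(all(abs(ring[, 1] - 5) <= 1 & abs(ring[, 2] - 5) <= 1))

  comp <- as.matrix(expand.grid(row = 2:4, col = 2:4))
  ring2 <- component_perimeter_ring(comp, matrix(FALSE, 5, 5))
  expect_equal(nrow(ring2), 16) # full one-pixel frame around a 3x3 block

  # with an edge ring between component and surround, the ring skips the
  # edge pixels and lands on the far side
  edges3 <- square_ring(9, 9, 3, 7, 3, 7)
  ring3 <- component_perimeter_ring(as.matrix(expand.grid(row = 4:6,
                                                          col = 4:6)),
                                    edges3)
  vals <- matrix(FALSE, 9, 9); vals[ring3] <- TRUE
  expect_true(all(!edges3[ring3]))          # never on the contour itself
  expect_true(all(abs(ring3[, 1] - 5) == 3 | abs(ring3[, 2] - 5) == 3))

  # clipped at the image border: corner component keeps in-bounds ring only
  ring4 <- component_perimeter_ring(cbind(1, 1), matrix(FALSE, 4, 4))
  expect_equal(nrow(ring4), 3)
})

test_that("the Type 3 filter applies all four strict constraints", {
  # build 20 components with known interior value, surround value and size
  h <- 60; w <- 120
  gray <- matrix(50, h, w)
  mask <- matrix(FALSE, h, w)
  specs <- list()
  set.seed(42)
  sizes <- rep(c(1, 2, 3, 4, 5), 4)    # square side lengths
  means <- rep(c(80, 120, 160, 200), each = 5)
  surrounds <- rep(c(40, 70, 90, 140), each = 5)
  pos <- expand.grid(r = c(8, 22, 36, 50), c = seq(8, 110, by = 12))
  for (i in 1:20) {
    side <- sizes[i]
    r0 <- pos$r[i]; c0 <- pos$c[i]
    rs <- r0:(r0 + side - 1); cs <- c0:(c0 + side - 1)
    gray[(r0 - 2):(r0 + side + 1), (c0 - 2):(c0 + side + 1)] <- surrounds[i]
    gray[rs, cs] <- means[i]
    mask[rs, cs] <- TRUE
    specs[[i]] <- list(mean = means[i], ring = surrounds[i], size = side^2)
  }
  cand <- connected_components(mask, gray)
  expect_equal(nrow(cand), 20)
  # map components back to their construction by interior value + size
  key <- purrr::map_chr(specs, ~ paste(.x$mean, .x$size))
  edges <- matrix(FALSE, h, w)
  settings <- list(
    type3_constraints(t_av = 100, t_diff = 30, t_cc_min = 1, t_cc_max = 30),
    type3_constraints(t_av = 160, t_diff = 10, t_cc_min = 2, t_cc_max = 26),
    # boundary strictness: t_av equal to an interior mean excludes it
    type3_constraints(t_av = 120, t_diff = 5, t_cc_min = 1, t_cc_max = 1000),
    # t_diff equal to an exact drop (160 - 90 = 70) excludes it
    type3_constraints(t_av = 50, t_diff = 70, t_cc_min = 1, t_cc_max = 1000),
    # size bounds equal to an exact size (9) exclude it
    type3_constraints(t_av = 50, t_diff = 1, t_cc_min = 9, t_cc_max = 16)
  )
  for (cs in settings) {
    kept <- classify_type3(cand, gray, edges, cs)
    got <- sort(paste(round(kept$mean_intensity), kept$size))
    want <- sort(purrr::map_chr(
      Filter(function(s) s$mean > cs$t_av &&
               (s$mean - s$ring) > cs$t_diff &&
               s$size > cs$t_cc_min && s$size < cs$t_cc_max, specs),
      ~ paste(.x$mean, .x$size)))
    expect_equal(got, want)
  }
})

test_that("components with an empty surround ring are excluded with a warning", {
  # component filling everything except a 1-pixel edge frame: ring would be
  # out of bounds
  h <- 6; w <- 6
  gray <- matrix(200, h, w)
  mask <- matrix(TRUE, h, w)
  cand <- connected_components(mask, gray)
  expect_warning(
    kept <- classify_type3(cand, gray, matrix(FALSE, h, w),
                           type3_constraints(t_av = 10, t_diff = 1,
                                             t_cc_min = 1, t_cc_max = 100)),
    "empty surround"
  )
  expect_equal(nrow(kept), 0)
})

test_that("hybrid segmentation classifies a clean bright square as Type 2", {
  m <- matrix(40, 32, 32)
  m[12:19, 12:19] <- 230
  img <- gray_image(m)
  res <- hybrid_segment(img, cone = cone_params(100, 0.4),
                        contour = contour_params(5, 15),
                        constraints = type3_constraints(t_av = 60,
                                                        t_diff = 10))
  expect_gt(sum(res$type2), 0)
  expect_equal(sum(res$type1), 0)
  expect_equal(sum(res$type3), 0)
  # the Type 2 mask covers the square interior and stays near the square
  expect_true(all(res$type2[14:17, 14:17]))
  expect_equal(sum(res$type2 & m == 40), 0)
  expect_identical(res$union, res$type1 | res$type2 | res$type3)
})

test_that("hybrid output is empty on uniform tissue and degenerates without edges", {
  flat <- uniform_image(c(120, 60, 50), 24, 24)
  res <- hybrid_segment(flat)
  expect_equal(sum(res$union), 0)
  # edge-free bright image: hybrid equals cone thresholding + lobe growing
  bright <- uniform_image(200, 24, 24)
  res2 <- hybrid_segment(bright, cone = cone_params(180, 0.3),
                         lobe = lobe_params(0.7))
  ref <- segment_with_lobes(bright, cone_segment(bright,
                                                 cone_params(180, 0.3)),
                            lobe_params(0.7))
  expect_identical(res2$union, ref)
})

test_that("hybrid invariants hold on synthetic scenes", {
  for (seed in c(4, 17)) {
    sc <- generate_scene(scene_spec(seed = seed, width = 64, height = 64,
                                    n_type1 = 1, n_type2 = 1, n_type3 = 2))
    cn <- cone_params(140, 0.5)
    res <- hybrid_segment(sc$image, cone = cn,
                          contour = contour_params(2.5, 5,
                                                   closing_radius = 2),
                          constraints = type3_constraints(t_av = 60,
                                                          t_diff = 8,
                                                          t_cc_min = 3))
    core <- cone_segment(sc$image, cn)
    # Type 3 components never intersect the thresholded set
    t3 <- res$components_by_type[res$components_by_type$type == 3, ]
    for (px in t3$pixels) expect_equal(sum(core[px]), 0)
    # every Type 2/3 component is an enclosed component of the edge map,
    # verified with the independent flood-fill oracle
    interior <- !res$edges & !oracle_flood_outside(res$edges)
    t23 <- res$components_by_type[res$components_by_type$type != 1, ]
    for (px in t23$pixels) expect_true(all(interior[px]))
    # union is monotone under relaxed Type 3 constraints
    res_relaxed <- hybrid_segment(sc$image, cone = cn,
                                  contour = contour_params(2.5, 5,
                                                           closing_radius = 2),
                                  constraints = type3_constraints(
                                    t_av = 30, t_diff = 4, t_cc_min = 2,
                                    t_cc_max = 5000))
    expect_true(all(res$union <= res_relaxed$union))
    expect_identical(res$union, res$type1 | res$type2 | res$type3)
  }
})
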
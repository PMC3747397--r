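test_that("saturation channel matches the HSV formula", {
  expect_equal(saturation_channel(uniform_image(c(128, 128, 128), 1, 1))[1, 1], 0)
  expect_equal(saturation_channel(uniform_image(c(255, 0, 0), 1, 1))[1, 1], 1)
  expect_equal(saturation_channel(uniform_image(c(200, 100, 100), 1, 1))[1, 1], 0.5)
  expect_equal(saturation_channel(uniform_image(c(0, 0, 0), 1, 1))[1, 1], 0)
  # cross-check against base R's rgb2hsv on random pixels
  img <- random_image(21, 6, 6)
  s <- saturation_channel(img)
  ref <- grDevices::rgb2hsv(rbind(as.vector(img[, , 1]),
                                  as.vector(img[, , 2]),
                                  as.vector(img[, , 3])),
                            maxColorValue = 255)["s", ]
  expect_equal(as.vector(s), unname(ref))
})

test_that("saturation suppression dims colored pixels, keeps gray fixed", {
  expect_equal(suppress_saturation(uniform_image(c(128, 128, 128), 1, 1))[1, 1, ],
               c(128, 128, 128))
  expect_equal(suppress_saturation(uniform_image(c(255, 0, 0), 1, 1))[1, 1, ],
               c(0, 0, 0))
  expect_equal(suppress_saturation(uniform_image(c(200, 100, 100), 1, 1))[1, 1, ],
               c(100, 50, 50))
  # never brightens any channel
  for (seed in 1:5) {
    img <- random_image(seed, 8, 8)
    expect_true(all(suppress_saturation(img) <= img))
  }
})

test_that("luminance is the BT.601 weighted sum", {
  expect_equal(luminance(uniform_image(c(255, 255, 255), 1, 1))[1, 1], 255)
  expect_equal(luminance(uniform_image(0, 1, 1))[1, 1], 0)
  expect_equal(luminance(uniform_image(c(100, 200, 50), 1, 1))[1, 1], 153.0)
})

test_that("histograms count rounded intensities and conserve mass", {
  h <- compute_histogram(matrix(0, 3, 3))
  expect_equal(h[1], 9)
  expect_equal(sum(h), 9)
  h2 <- compute_histogram(matrix(c(10, 10, 20), 1, 3))
  expect_equal(h2[11], 2)
  expect_equal(h2[21], 1)
  set.seed(9)
  g <- matrix(runif(100, 0, 255), 10, 10)
  expect_equal(sum(compute_histogram(g)), 100)
})

test_that("histogram smoothing preserves mass and matches a kernel-sum oracle", {
  u <- rep(4, 256)
  expect_equal(smooth_histogram(u, 2), u, tolerance = 1e-12)
  spike <- numeric(256); spike[101] <- 1 # t = 100
  sm <- smooth_histogram(spike, 2)
  expect_equal(sum(sm), 1, tolerance = 1e-9)
  expect_equal(which.max(sm), 101)
  expect_equal(sm[99], sm[103]) # symmetric about the spike
  # explicit kernel-sum loop oracle
  r <- ceiling(3 * 2)
  k <- exp(-((-r):r)^2 / 8); k <- k / sum(k)
  expected <- sapply(97:105, function(t) k[(t - 100) + r + 1])
  expect_equal(sm[98:106], expected, tolerance = 1e-12)
})

test_that("specular-peak threshold selects the valley before the brightest peak", {
  h <- numeric(256)
  h[100:105 + 1] <- c(50, 30, 10, 5, 20, 40)
  # valley at t = 102; the final descent at t = 105 has no mass above it
  expect_equal(select_specular_peak_threshold(h, peak_params(t_min = 50)), 102L)
  expect_true(is.na(select_specular_peak_threshold(h, peak_params(t_min = 150))))
  mono <- as.numeric(0:255) # strictly non-decreasing: no descent anywhere
  expect_true(is.na(select_specular_peak_threshold(mono, peak_params(t_min = 0))))
  # exhaustive-scan oracle agreement on random smoothed histograms
  for (seed in 1:20) {
    set.seed(seed)
    hh <- smooth_histogram(tabulate(sample(1:256, 500, replace = TRUE), 256), 2)
    got <- select_specular_peak_threshold(hh, peak_params(t_min = 30))
    h1 <- function(t) if (hh[t + 1] - hh[t + 2] > 0) 1 else 0
    cand <- Filter(function(t) h1(t) == 1 && h1(t + 1) == 0 &&
                     sum(hh[(t + 2):256]) > 0, 0:253)
    cand <- cand[cand > 30]
    want <- if (length(cand) == 0) NA_integer_ else max(cand)
    expect_equal(got, want)
  }
})

test_that("specular-peak segmentation isolates a bright gray blob", {
  m <- matrix(80, 24, 24)
  m[8:12, 8:12] <- 250
  img <- gray_image(m)
  mask <- specular_peak_segment(img, peak_params(t_min = 50, sigma = 1))
  expect_equal(mask, m > 200, ignore_attr = TRUE)
  expect_true(attr(mask, "t_spec") > 50 && attr(mask, "t_spec") < 250)
  # a t_min above the only valley vetoes the segmentation entirely: the
  # robustness filter treats the image as reflection-free
  veto <- specular_peak_segment(img, peak_params(t_min = 100, sigma = 1))
  expect_equal(sum(veto), 0)
  # uniform image: single spike, no valley, empty segmentation
  expect_equal(sum(specular_peak_segment(uniform_image(128, 16, 16))), 0)
  # a fully saturated blob is annihilated by the transform
  img2 <- uniform_image(c(30, 30, 30), 16, 16)
  img2[6:8, 6:8, 1] <- 255; img2[6:8, 6:8, 2] <- 0; img2[6:8, 6:8, 3] <- 0
  mask2 <- specular_peak_segment(img2, peak_params(t_min = 100, sigma = 1))
  expect_equal(sum(mask2), 0)
})

test_that("cone membership follows the projection inequality", {
  expect_true(cone_segment(uniform_image(255, 1, 1), cone_params(200, 0.3))[1, 1])
  expect_false(cone_segment(uniform_image(c(255, 0, 0), 1, 1),
                            cone_params(100, 0.3))[1, 1])
  expect_false(cone_segment(uniform_image(0, 1, 1), cone_params(0, 0.5))[1, 1])
  expect_error(cone_params(100, 0), "must be > 0")
  expect_error(cone_params(100, -1), "must be > 0")
})

test_that("gray-level thresholding is a strict luminance cut", {
  img <- uniform_image(200, 4, 4)
  expect_equal(sum(gray_level_segment(img, gray_params(255))), 0)
  expect_equal(sum(gray_level_segment(img, gray_params(199))), 16)
  img2 <- uniform_image(0, 4, 4); img2[2, 2, ] <- c(9, 9, 9)
  expect_equal(which(gray_level_segment(img2, gray_params(0))), 2 + 4)
})

test_that("thresholding detectors obey their monotonicity and symmetry laws", {
  img <- blob_image(31)
  m1 <- gray_level_segment(img, gray_params(120))
  m2 <- gray_level_segment(img, gray_params(180))
  expect_true(all(m2 <= m1)) # higher threshold, smaller mask
  c1 <- cone_segment(img, cone_params(120, 0.4))
  expect_true(all(cone_segment(img, cone_params(170, 0.4)) <= c1))
  expect_true(all(cone_segment(img, cone_params(120, 0.2)) <= c1))
  # gray-axis symmetry: permuting channels leaves cone membership unchanged
  perm <- img[, , c(3, 1, 2)]
  expect_identical(cone_segment(perm, cone_params(140, 0.5)),
                   cone_segment(img, cone_params(140, 0.5)))
})

test_that("peak and cone segmentations match brute-force oracles (spot check)", {
  for (seed in 1:5) {
    img <- if (seed %% 2) blob_image(seed) else random_image(seed)
    expect_identical(cone_segment(img, cone_params(150, 0.4)),
                     oracle_cone(img, 150, 0.4))
    got <- specular_peak_segment(img, peak_params(100, 2))
    expect_equal(unclass(got), oracle_peak_segment(img, 100, 2),
                 ignore_attr = TRUE)
  }
})
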
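test_that("max projection reduces stacks by per-pixel maximum", {
  # single-plane identity
  p <- matrix(1:6, 2, 3)
  st <- channel_stack(list(DAPI = p), pixel_size_um = 0.5)
  expect_equal(unclass(max_project(st, "DAPI")), p + 0, ignore_attr = TRUE)
  expect_equal(pixel_size(max_project(st, "DAPI")), 0.5)

  # elementwise max of two planes
  st2 <- channel_stack(list(DAPI = list(matrix(c(1, 3, 2, 4), 2, 2),
                                        matrix(c(4, 2, 3, 1), 2, 2))))
  expect_equal(unclass(max_project(st2, "DAPI")),
               matrix(c(4, 3, 3, 4), 2, 2), ignore_attr = TRUE)

  # 5-plane random stack against a brute-force per-pixel loop
  set.seed(11)
  planes <- lapply(1:5, function(z) matrix(runif(12 * 10), 12, 10))
  st5 <- channel_stack(list(GFP = planes))
  want <- matrix(0, 12, 10)
  for (i in 1:12) for (j in 1:10)
    want[i, j] <- max(vapply(planes, function(p) p[i, j], 0))
  expect_equal(unclass(max_project(st5, "GFP")), want, ignore_attr = TRUE)

  expect_error(max_project(st5, "RFP"), "not in stack")
})

test_that("max projection is idempotent on its own output", {
  set.seed(3)
  st <- channel_stack(list(DAPI = lapply(1:4, function(z) matrix(runif(64), 8, 8))))
  pr <- max_project(st, "DAPI")
  again <- max_project(channel_stack(list(DAPI = unclass(pr))), "DAPI")
  expect_equal(unclass(again), unclass(pr))
})

test_that("levels adjustment rescales between the chosen percentiles", {
  img <- image_plane(matrix(0:99, 10, 10))
  out <- adjust_levels(img, 0, 100)
  expect_equal(unclass(out), unclass(img) / 99, ignore_attr = TRUE)

  expect_warning(z <- adjust_levels(image_plane(matrix(5, 4, 4))),
                 "constant")
  expect_true(all(unclass(z) == 0))

  # ten known values, window (10, 90): closed-form clip/rescale
  v <- seq(10, 100, by = 10)
  img10 <- image_plane(matrix(v, 2, 5))
  q <- quantile(v, c(0.10, 0.90), names = FALSE)
  want <- pmin(1, pmax(0, (v - q[1]) / (q[2] - q[1])))
  expect_equal(as.vector(unclass(adjust_levels(img10, 10, 90))), want)

  expect_error(adjust_levels(img, 50, 50), "low_pct")
})

test_that("median denoising matches a brute-force sliding-window median", {
  img <- image_plane(matrix(runif(30), 5, 6))
  expect_equal(denoise(img, 0), img)

  # lone impulse in a flat field is removed at radius 1
  flat <- matrix(1, 9, 9); flat[5, 5] <- 100
  out <- denoise(image_plane(flat), 1)
  expect_equal(unclass(out)[5, 5], 1)

  # brute-force oracle: explicit double loop with truncated windows
  set.seed(21)
  x <- matrix(rpois(16 * 16, 10) + runif(256), 16, 16)
  for (r in 1:2) {
    want <- matrix(0, 16, 16)
    for (i in 1:16) for (j in 1:16) {
      rows <- max(1, i - r):min(16, i + r)
      cols <- max(1, j - r):min(16, j + r)
      want[i, j] <- median(x[rows, cols])
    }
    expect_equal(unclass(denoise(image_plane(x), r)), want, ignore_attr = TRUE)
  }
})

test_that("denoising never widens the intensity range", {
  set.seed(8)
  for (k in 1:5) {
    x <- matrix(runif(400, min = 2, max = 9), 20, 20)
    y <- unclass(denoise(image_plane(x), sample(1:3, 1)))
    expect_gte(min(y), min(x))
    expect_lte(max(y), max(x))
  }
})

test_that("roi masks follow the even-odd rule with boundary inclusion", {
  sq <- roi_polygon(rbind(c(0, 0), c(0, 9), c(9, 9), c(9, 0)))
  expect_equal(sum(roi_mask(sq, c(10, 10))), 100)

  # triangle area approximates the shoelace area
  tri <- roi_polygon(rbind(c(5, 5), c(5, 90), c(80, 20)))
  a_true <- 0.5 * abs((90 - 5) * (80 - 5) - (20 - 5) * (5 - 5))
  expect_lt(abs(sum(roi_mask(tri, c(100, 100))) - a_true) / a_true, 0.02)

  # polygon fully outside the frame
  far <- roi_polygon(rbind(c(500, 500), c(500, 520), c(520, 510)))
  expect_false(any(roi_mask(far, c(50, 50))))

  expect_error(roi_mask(rbind(c(0, 0), c(5, 5), c(10, 10)), c(20, 20)), "degenerate")
  expect_error(roi_polygon(rbind(c(0, 0), c(10, 10), c(0, 10), c(10, 0))), "simple")
})

test_that("roi mask area converges to the shoelace area with resolution", {
  v <- rbind(c(2, 3), c(3, 17), c(15, 19), c(18, 6))
  a_true <- 0.5 * abs(sum(v[, 1] * v[c(2:4, 1), 2] - v[c(2:4, 1), 1] * v[, 2]))
  err <- vapply(c(1, 4), function(s) {
    m <- roi_mask(roi_polygon(v * s), c(25 * s, 25 * s))
    abs(sum(m) / s^2 - a_true) / a_true
  }, 0)
  expect_lt(err[2], err[1] + 1e-9)
  expect_lt(err[2], 0.02)
})

test_that("intensity ranking orders reporter images by mean ROI signal", {
  roi <- roi_polygon(rbind(c(0, 0), c(0, 19), c(19, 19), c(19, 0)))
  mk <- function(m) image_plane(matrix(m, 20, 20), channel = "GFP")
  rk <- rank_by_intensity(list(mk(5), mk(50), mk(20)), list(roi, roi, roi))
  expect_equal(rk$index, c(1, 3, 2))
  expect_false(any(rk$tied))

  tied <- rank_by_intensity(list(mk(7), mk(7), mk(7)), list(roi, roi, roi))
  expect_true(all(tied$tied))
  expect_equal(tied$rank, rep(2, 3))

  # programmed means with noise recover the programmed order
  set.seed(4)
  means <- sample(seq(10, 100, by = 10))
  planes <- lapply(means, function(m)
    image_plane(matrix(pmax(0, m + rnorm(400)), 20, 20), channel = "GFP"))
  rk10 <- rank_by_intensity(planes, rep(list(roi), 10))
  expect_equal(rk10$index, order(means))
  expect_setequal(rk10$index, 1:10)  # permutation property

  out <- roi_polygon(rbind(c(100, 100), c(100, 110), c(110, 105)))
  expect_error(rank_by_intensity(list(mk(1), mk(2)), list(roi, out)), "empty ROI")
})

test_that("stacks round-trip through multi-page TIFF with sidecar", {
  set.seed(5)
  st <- channel_stack(list(DAPI = lapply(1:2, function(z) matrix(runif(48), 6, 8)),
                           RFP = lapply(1:2, function(z) matrix(runif(48), 6, 8))),
                      pixel_size_um = 0.62, metadata = list(origin = "test"))
  path <- file.path(tempdir(), "stack.tif")
  write_stack_tiff(st, path)
  back <- read_stack_tiff(path)
  expect_equal(names(back$channels), c("DAPI", "RFP"))
  expect_equal(back$pixel_size_um, 0.62)
  expect_equal(unclass(back$channels$DAPI[[2]]), unclass(st$channels$DAPI[[2]]),
               tolerance = 1e-6, ignore_attr = TRUE)
})
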
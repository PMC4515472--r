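# Helpers: paint disks directly (independent of the scene generator) so the
# segmentation oracle does not share code with the path under test.
paint <- function(mat, r0, c0, rad) {
  for (i in seq_len(nrow(mat))) for (j in seq_len(ncol(mat)))
    if ((i - 1 - r0)^2 + (j - 1 - c0)^2 <= rad^2) mat[i, j] <- 1
  mat
}

test_that("tissue detection recovers the gut band", {
  sc <- generate_scene(scene_params(), "virgin", seed = 31)
  m <- detect_gut_area(sc$stack)
  tm <- sc$truth$gut_mask
  expect_gte(sum(m & tm) / sum(m | tm), 0.95)
  # single connected component
  expect_equal(max(EBImage::bwlabel(m)), 1)
})

test_that("tissue detection handles saturating and empty frames", {
  full <- channel_stack(list(DAPI = matrix(0.7, 64, 64)))
  expect_true(all(detect_gut_area(full)))
  empty <- channel_stack(list(DAPI = matrix(0, 64, 64)))
  expect_error(detect_gut_area(empty), "no tissue")
})

test_that("nucleus segmentation finds disjoint disks with analytic areas", {
  x <- matrix(0, 220, 220)
  centers <- expand.grid(r = c(30, 85, 140, 195) - 10, c = c(40, 110, 180))
  for (k in 1:12) x <- paint(x, centers$r[k], centers$c[k], 8)
  rec <- segment_nuclei(image_plane(x, pixel_size_um = 1),
                        params = segmentation_params(min_nucleus_area_um2 = 20))
  expect_equal(nrow(rec), 12)
  expect_true(all(abs(rec$area_um2 - pi * 64) / (pi * 64) < 0.10))
  # centroids match the painted centres
  ord <- order(rec$centroid_row, rec$centroid_col)
  ord_t <- order(centers$r, centers$c)
  expect_lt(max(abs(rec$centroid_row[ord] - centers$r[ord_t])), 1)
})

test_that("segmentation of a blank plane returns no nuclei with a warning", {
  expect_warning(rec <- segment_nuclei(image_plane(matrix(0, 40, 40))),
                 "zero foreground")
  expect_equal(nrow(rec), 0)
})

test_that("watershed splitting separates touching nuclei", {
  x <- matrix(0, 60, 60)
  x <- paint(x, 29, 22, 8); x <- paint(x, 29, 38, 8)  # centres 16 px apart
  img <- image_plane(x, pixel_size_um = 1)
  on <- segment_nuclei(img, params = segmentation_params(split_touching = TRUE,
                                                         min_nucleus_area_um2 = 20))
  off <- segment_nuclei(img, params = segmentation_params(split_touching = FALSE,
                                                          min_nucleus_area_um2 = 20))
  expect_equal(nrow(on), 2)
  expect_equal(nrow(off), 1)
})

test_that("ploidy is called by area threshold, fixed or automatic", {
  rec <- data.frame(label = 1:3, centroid_row = 0, centroid_col = 0,
                    area_um2 = c(20, 25, 400), mean_DAPI = 1,
                    ploidy = NA_character_, cell_class = NA_character_)
  class(rec) <- c("nucleus_records", "data.frame")
  out <- classify_ploidy(rec, segmentation_params(ploidy_area_threshold_um2 = 100))
  expect_equal(out$ploidy, c("diploid", "diploid", "polyploid"))

  below <- classify_ploidy(transform(rec, area_um2 = c(20, 25, 30)),
                           segmentation_params(ploidy_area_threshold_um2 = 100))
  expect_true(all(below$ploidy == "diploid"))

  # auto mode on a bimodal mixture built from the study's nucleus geometry
  set.seed(17)
  r_dip <- pmin(pmax(rnorm(120, 2.5, 0.3), 1.9), 3.1)
  r_pol <- pmin(pmax(rnorm(80, 6, 0.8), 4.4), 7.6)
  mix <- rec[rep(1, 200), ]
  mix$area_um2 <- pi * c(r_dip, r_pol)^2
  mix$label <- 1:200
  truth <- rep(c("diploid", "polyploid"), c(120, 80))
  auto <- classify_ploidy(mix, segmentation_params(ploidy_area_threshold_um2 = "auto"))
  expect_gte(mean(auto$ploidy == truth), 0.98)

  expect_error(classify_ploidy(rec[1:3, ],
                               segmentation_params(ploidy_area_threshold_um2 = "auto")),
               ">= 4 nuclei")
})

test_that("a fixed-composition noiseless scene yields the forced report", {
  p <- scene_params(counts = c(preexisting_ec = 10, preexisting_diploid = 0,
                               progenitor = 5, new_ec = 3, new_eec = 0),
                    noise_sd_fraction = 0, overlap_tolerance_um = -2,
                    deterministic_counts = TRUE)
  sc <- generate_scene(p, "virgin", seed = 7)
  r <- reddm_quantify(sc$stack)
  expect_equal(r$report$n_total_nuclei, 18)
  expect_equal(r$report$n_ec, 13)
  expect_equal(r$report$n_rfp, 8)
  expect_equal(r$report$n_gfp, 5)
  expect_equal(r$report$n_new_progeny, 3)
  expect_equal(r$report$n_anomalous, 0)
})

test_that("blank reporter channels leave every nucleus pre-existing", {
  p <- scene_params(noise_sd_fraction = 0, deterministic_counts = TRUE)
  sc <- generate_scene(p, "virgin", seed = 12)
  dapi_planes <- sc$stack$channels$DAPI
  zero <- matrix(0, nrow(dapi_planes[[1]]), ncol(dapi_planes[[1]]))
  st <- channel_stack(list(DAPI = lapply(dapi_planes, unclass), RFP = zero, GFP = zero),
                      pixel_size_um = sc$stack$pixel_size_um)
  r <- reddm_quantify(st)
  expect_equal(r$report$n_rfp, 0)
  expect_equal(r$report$n_gfp, 0)
  expect_true(all(r$records$cell_class == "preexisting"))
})

test_that("every nucleus gets exactly one class and counts are conserved", {
  for (seed in c(2, 9)) {
    sc <- generate_scene(scene_params(), if (seed %% 2) "virgin" else "mated", seed = seed)
    r <- reddm_quantify(sc$stack)
    expect_true(all(r$records$cell_class %in% c("preexisting", "progenitor", "new_progeny")))
    tab <- table(factor(r$records$cell_class,
                        levels = c("preexisting", "progenitor", "new_progeny")))
    expect_equal(sum(tab), r$report$n_total_nuclei)
    if (r$report$n_anomalous == 0)
      expect_equal(r$report$n_new_progeny, r$report$n_rfp - r$report$n_gfp)
    expect_gte(r$report$n_new_progeny, 0)
    expect_equal(r$report$density_per_mm2,
                 r$report$n_total_nuclei / (r$report$gut_area_um2 * 1e-6))
  }
})

test_that("density is stable when pixel size doubles at matched physical size", {
  p_fine <- scene_params(field_size_px = c(560, 560), pixel_size_um = 0.5,
                         noise_sd_fraction = 0)
  p_coarse <- scene_params(field_size_px = c(280, 280), pixel_size_um = 1.0,
                           noise_sd_fraction = 0)
  d <- vapply(list(p_fine, p_coarse), function(p) {
    sc <- generate_scene(p, "virgin", seed = 19)
    reddm_quantify(sc$stack)$report$density_per_mm2
  }, 0)
  expect_lt(abs(d[1] - d[2]) / d[1], 0.05)
})

test_that("diameter is measured along the centre line in physical units", {
  band <- matrix(FALSE, 100, 100); band[31:70, ] <- TRUE
  expect_equal(measure_diameter(band, 2), 80)

  disc <- matrix(FALSE, 101, 101)
  for (i in 1:101) for (j in 1:101)
    if ((i - 51)^2 + (j - 51)^2 <= 50^2) disc[i, j] <- TRUE
  d <- measure_diameter(disc, 1)
  expect_gte(d, 99); expect_lte(d, 101)

  corner <- matrix(FALSE, 100, 100); corner[1:20, 1:20] <- TRUE
  expect_error(measure_diameter(corner, 1), "centre")
})

test_that("spot counting matches the constructed and generated truth", {
  x <- matrix(0, 120, 120)
  pos <- cbind(c(15, 15, 60, 60, 60, 100, 100), c(20, 80, 20, 60, 100, 40, 90))
  for (k in 1:7) x <- paint(x, pos[k, 1], pos[k, 2], 4)
  expect_equal(count_spots(image_plane(x, channel = "PH3")), 7)
  expect_equal(count_spots(image_plane(matrix(0, 50, 50))), 0)

  # seeded random scene at SNR >= 5 (amplitude 1, noise sd 0.2)
  for (seed in c(1, 5, 23)) {
    g <- generate_spots(11, radius_px = 4, amplitude = 1, noise_sd = 0.2, seed = seed)
    expect_equal(count_spots(g$plane), g$n_spots)
  }
})
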
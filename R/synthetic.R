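# Ground-truthed synthetic inputs for every pipeline stage. Each generator
# is a pure function of (params, seed): identical inputs give identical
# outputs, and the truth object always carries enough information for the
# matching analysis stage to be checked against it exactly at zero noise.

#' Synthetic midgut scene parameters
#'
#' Defines the rendered field and the cellular composition of a tracing
#' scene. Per-class counts are condition-specific Poisson means: mating
#' multiplies the new-progeny means by `mated_new_factor` and the progenitor
#' mean by `mated_progenitor_factor`. Per-field counts are declared knobs of
#' the generator, not measured biological magnitudes.
#'
#' @param field_size_px `c(rows, cols)` of the rendered field.
#' @param pixel_size_um micrometres per pixel.
#' @param counts named per-class mean counts (virgin condition):
#'   `preexisting_ec`, `preexisting_diploid`, `progenitor`, `new_ec`,
#'   `new_eec`.
#' @param mated_new_factor,mated_progenitor_factor mated-condition
#'   multipliers on the new-progeny and progenitor means.
#' @param diploid_radius_um,polyploid_radius_um `c(mean, sd)` nucleus radii
#'   in um, drawn truncated-normal at +-2 sd so the two size classes stay
#'   disjoint; the polyploid mean must exceed the diploid mean.
#' @param psf_sigma_px Gaussian point-spread blur sigma (px).
#' @param noise_sd_fraction additive Gaussian noise SD as a fraction of the
#'   signal amplitude.
#' @param background_gradient amplitude of a linear left-to-right background
#'   ramp, as a fraction of the signal amplitude (0 = off).
#' @param gut_band_height_um height of the horizontal tissue band (um).
#' @param tissue_background diffuse background-staining level of the tissue
#'   band in the DAPI channel, as a fraction of the nucleus amplitude — the
#'   signal by which the gut area is identified.
#' @param gfp_ring_width_um width of the rendered membrane-GFP ring (um).
#' @param overlap_tolerance_um allowed nucleus overlap depth; 0 = hard-core
#'   contact; negative values enforce a minimum clearance between nuclei.
#' @param deterministic_counts use the (rounded) class means as exact counts
#'   instead of Poisson draws — for fixed-composition validation scenes.
#' @param scale joint scale factor: multiplies class counts by `scale` and
#'   field area (and band height) by `scale`, preserving density — used to
#'   run many-scene simulations at reduced size.
#' @param seed default RNG seed for [generate_scene()].
#' @return An object of class `scene_params`.
#' @export
scene_params <- function(field_size_px = c(400L, 400L),
                         pixel_size_um = 0.75,
                         counts = c(preexisting_ec = 60, preexisting_diploid = 25,
                                    progenitor = 12, new_ec = 4, new_eec = 2),
                         mated_new_factor = 3,
                         mated_progenitor_factor = 1.5,
                         diploid_radius_um = c(mean = 2.5, sd = 0.3),
                         polyploid_radius_um = c(mean = 6, sd = 0.8),
                         psf_sigma_px = 1,
                         noise_sd_fraction = 0.1,
                         background_gradient = 0,
                         gut_band_height_um = 220,
                         tissue_background = 0.15,
                         gfp_ring_width_um = 1.5,
                         overlap_tolerance_um = 0,
                         deterministic_counts = FALSE,
                         scale = 1,
                         seed = 1L) {
  if (scale != 1) {
    counts <- counts * scale
    field_size_px <- pmax(32L, as.integer(round(field_size_px * sqrt(scale))))
    gut_band_height_um <- gut_band_height_um * sqrt(scale)
  }
  p <- list(field_size_px = as.integer(field_size_px), pixel_size_um = pixel_size_um,
            counts = counts, mated_new_factor = mated_new_factor,
            mated_progenitor_factor = mated_progenitor_factor,
            diploid_radius_um = diploid_radius_um,
            polyploid_radius_um = polyploid_radius_um,
            psf_sigma_px = psf_sigma_px, noise_sd_fraction = noise_sd_fraction,
            background_gradient = background_gradient,
            gut_band_height_um = gut_band_height_um,
            tissue_background = tissue_background,
            gfp_ring_width_um = gfp_ring_width_um,
            overlap_tolerance_um = overlap_tolerance_um,
            deterministic_counts = isTRUE(deterministic_counts), seed = seed)
  need <- c("preexisting_ec", "preexisting_diploid", "progenitor", "new_ec", "new_eec")
  if (!all(need %in% names(p$counts))) stopf("counts needs: %s", paste(need, collapse = ", "))
  if (any(p$counts < 0)) stopf("class counts must be >= 0")
  if (p$diploid_radius_um[["mean"]] <= 0 || p$polyploid_radius_um[["mean"]] <= 0)
    stopf("radii must be > 0")
  if (p$polyploid_radius_um[["mean"]] <= p$diploid_radius_um[["mean"]])
    stopf("polyploid mean radius must exceed diploid mean radius")
  if (p$noise_sd_fraction < 0) stopf("noise fraction must be >= 0")
  structure(p, class = "scene_params")
}

# Class ground-truth table: ploidy and ReDDM channel flags per lineage class.
CLASS_TRUTH <- data.frame(
  class = c("preexisting_ec", "preexisting_diploid", "progenitor", "new_ec", "new_eec"),
  ploidy = c("polyploid", "diploid", "diploid", "polyploid", "diploid"),
  rfp = c(FALSE, FALSE, TRUE, TRUE, TRUE),
  gfp = c(FALSE, FALSE, TRUE, FALSE, FALSE),
  lineage = c("preexisting", "preexisting", "progenitor", "new_progeny", "new_progeny"))

# Additively paint a disk (or ring) of unit intensity, clipped to the frame.
paint_disk <- function(mat, row0, col0, r_px, value = 1, inner_px = NULL) {
  nr <- nrow(mat); nc <- ncol(mat)
  rr <- max(1L, floor(row0 - r_px) + 1L):min(nr, ceiling(row0 + r_px) + 1L)
  cc <- max(1L, floor(col0 - r_px) + 1L):min(nc, ceiling(col0 + r_px) + 1L)
  d2 <- outer((rr - 1L - row0)^2, (cc - 1L - col0)^2, `+`)
  sel <- d2 <= r_px^2
  if (!is.null(inner_px)) sel <- sel & d2 > inner_px^2
  sub <- mat[rr, cc]
  sub[sel] <- pmax(sub[sel], value)
  mat[rr, cc] <- sub
  mat
}

#' Generate a ground-truthed ReDDM midgut scene
#'
#' Draws per-class cell counts (Poisson around condition means), places
#' nuclei by hard-core rejection sampling inside a horizontal tissue band,
#' and renders DAPI (all nuclei as disks), RFP (disks for RFP+ nuclei) and
#' GFP (membrane rings around GFP+ nuclei), followed by Gaussian PSF blur,
#' a linear background gradient and additive Gaussian noise (clipped at 0).
#' The scene and its truth share the seed and are reproducible bit for bit.
#'
#' @param params a [scene_params].
#' @param condition `"virgin"` or `"mated"`.
#' @param seed RNG seed (default `params$seed`).
#' @return A list with `truth` (class `gut_scene`: `cells` data.frame with
#'   0-based centres, radii, ploidy, lineage class and channel flags;
#'   `gut_mask`; `params`; `condition`; `seed`) and `stack` (the rendered
#'   [channel_stack]).
#' @export
generate_scene <- function(params = scene_params(), condition = c("virgin", "mated"),
                           seed = NULL) {
  condition <- match.arg(condition)
  seed <- seed %||% params$seed
  with_seed(seed, {
    nr <- params$field_size_px[1]; nc <- params$field_size_px[2]
    ps <- params$pixel_size_um
    mu <- params$counts
    if (condition == "mated") {
      mu[c("new_ec", "new_eec")] <- mu[c("new_ec", "new_eec")] * params$mated_new_factor
      mu["progenitor"] <- mu["progenitor"] * params$mated_progenitor_factor
    }
    n_cls <- if (params$deterministic_counts) setNames(as.integer(round(mu)), names(mu))
             else setNames(rpois(length(mu), mu), names(mu))

    band_px <- min(nr, round(params$gut_band_height_um / ps))
    r0 <- floor((nr - band_px) / 2); r1 <- r0 + band_px - 1L  # 0-based rows
    gut_mask <- matrix(FALSE, nr, nc)
    gut_mask[(r0 + 1):(r1 + 1), ] <- TRUE

    cls <- rep(CLASS_TRUTH$class, times = n_cls[CLASS_TRUTH$class])
    info <- CLASS_TRUTH[match(cls, CLASS_TRUTH$class), ]
    n <- length(cls)
    rad <- numeric(n)
    for (i in seq_len(n)) {
      pr <- if (info$ploidy[i] == "polyploid") params$polyploid_radius_um
            else params$diploid_radius_um
      # truncated at +-2 sd: keeps the diploid and polyploid size classes
      # disjoint, so ploidy is decidable from area alone
      r <- rnorm(1, pr[["mean"]], pr[["sd"]])
      rad[i] <- max(0.8, min(max(r, pr[["mean"]] - 2 * pr[["sd"]]),
                             pr[["mean"]] + 2 * pr[["sd"]]))
    }
    ord <- order(-rad)  # place large nuclei first: helps dense packing
    rows <- cols <- numeric(n)
    tol_px <- params$overlap_tolerance_um / ps
    for (k in seq_len(n)) {
      i <- ord[k]
      rpx <- rad[i] / ps
      ok <- FALSE
      for (attempt in seq_len(2000L)) {
        ry <- runif(1, r0 + rpx, r1 - rpx)
        rx <- runif(1, rpx, nc - 1 - rpx)
        prev <- ord[seq_len(k - 1L)]
        if (!length(prev) ||
            all(sqrt((rows[prev] - ry)^2 + (cols[prev] - rx)^2) >=
                (rad[prev] + rad[i]) / ps - tol_px)) { ok <- TRUE; break }
      }
      if (!ok)
        stopf("placement failure: could not place nucleus %d of %d (class %s) without overlap; reduce counts or enlarge the field",
              k, n, cls[i])
      rows[i] <- ry; cols[i] <- rx
    }

    dapi <- params$tissue_background * gut_mask
    rfp <- matrix(0, nr, nc); gfp <- matrix(0, nr, nc)
    ring_px <- params$gfp_ring_width_um / ps
    for (i in seq_len(n)) {
      rpx <- rad[i] / ps
      dapi <- paint_disk(dapi, rows[i], cols[i], rpx)
      if (info$rfp[i]) rfp <- paint_disk(rfp, rows[i], cols[i], rpx)
      if (info$gfp[i]) gfp <- paint_disk(gfp, rows[i], cols[i], rpx + ring_px,
                                         inner_px = rpx)
    }
    degrade <- function(x) {
      if (params$psf_sigma_px > 0) x <- gauss_smooth(x, params$psf_sigma_px)
      if (params$background_gradient > 0)
        x <- x + params$background_gradient *
          matrix(rep(seq(0, 1, length.out = nc), each = nr), nr, nc)
      if (params$noise_sd_fraction > 0)
        x <- x + rnorm(length(x), 0, params$noise_sd_fraction)
      x[x < 0] <- 0
      x
    }
    stack <- channel_stack(list(DAPI = degrade(dapi), RFP = degrade(rfp),
                                GFP = degrade(gfp)),
                           pixel_size_um = ps,
                           metadata = list(generator = "gutquant synthetic scene",
                                           condition = condition, seed = seed))
    truth <- structure(list(
      cells = data.frame(row = rows, col = cols, radius_um = rad, class = cls,
                         ploidy = info$ploidy, rfp = info$rfp, gfp = info$gfp,
                         lineage = info$lineage),
      gut_mask = gut_mask, params = params, condition = condition, seed = seed),
      class = "gut_scene")
    validate_scene(truth)
    list(truth = truth, stack = stack)
  })
}

#' @export
print.gut_scene <- function(x, ...) {
  cat(sprintf("<gut_scene> %s, seed %s: %d cells (%s)\n", x$condition,
              format(x$seed), nrow(x$cells),
              paste(sprintf("%s=%d", names(table(x$cells$class)),
                            as.integer(table(x$cells$class))), collapse = ", ")))
  invisible(x)
}

#' Validate the internal consistency of a synthetic scene
#'
#' Re-checks the construction invariants: class flags consistent with the
#' lineage logic (progenitor = GFP+ RFP+; new progeny = RFP+ GFP-;
#' pre-existing = RFP- GFP-), all nuclei inside the tissue mask, and no two
#' nuclei overlapping beyond the configured tolerance.
#'
#' @param truth a `gut_scene`.
#' @return `TRUE` invisibly; errors on violation.
#' @export
validate_scene <- function(truth) {
  ref <- CLASS_TRUTH[match(truth$cells$class, CLASS_TRUTH$class), ]
  if (!all(truth$cells$rfp == ref$rfp & truth$cells$gfp == ref$gfp &
           truth$cells$ploidy == ref$ploidy & truth$cells$lineage == ref$lineage))
    stopf("scene truth violates the class-flag consistency invariant")
  m <- truth$gut_mask
  ri <- round(truth$cells$row) + 1L; ci <- round(truth$cells$col) + 1L
  if (nrow(truth$cells) && !all(m[cbind(ri, ci)]))
    stopf("scene truth places a nucleus outside the tissue mask")
  ps <- truth$params$pixel_size_um
  n <- nrow(truth$cells)
  if (n > 1L) {
    d <- as.matrix(stats::dist(cbind(truth$cells$row, truth$cells$col))) * ps
    lim <- outer(truth$cells$radius_um, truth$cells$radius_um, `+`) -
      truth$params$overlap_tolerance_um
    diag(d) <- Inf
    if (any(d < lim - 1e-9)) stopf("scene truth violates the hard-core placement invariant")
  }
  invisible(TRUE)
}

#' Ground-truth per-gut report of a scene
#'
#' The [cell_class_report] implied by the generator's class definitions,
#' against which the image-analysis report is checked.
#'
#' @param truth a `gut_scene`.
#' @return A [cell_class_report].
#' @export
truth_report <- function(truth) {
  ps <- truth$params$pixel_size_um
  cells <- truth$cells
  cell_class_report(
    n_total_nuclei = nrow(cells),
    n_ec = sum(cells$ploidy == "polyploid"),
    n_rfp = sum(cells$rfp),
    n_gfp = sum(cells$gfp),
    n_new_progeny = sum(cells$lineage == "new_progeny"),
    gut_area_um2 = sum(truth$gut_mask) * ps^2,
    diameter_um = sum(truth$gut_mask[, round((ncol(truth$gut_mask) + 1) / 2)]) * ps)
}

#' Score detected nuclei against scene ground truth
#'
#' Matches detected nuclei to truth cells one-to-one by greedy
#' nearest-centroid assignment (a pair matches when closer than the truth
#' radius plus `slack_px`), then scores the lineage classes: matched pairs
#' contribute true/false positives by class, unmatched truth cells are false
#' negatives, unmatched detections false positives.
#'
#' @param truth a `gut_scene`.
#' @param records `nucleus_records` with `cell_class` set.
#' @param slack_px extra matching distance beyond the truth radius.
#' @return A list with `confusion` (data.frame per class: tp, fp, fn,
#'   precision, recall, f1) and `matched` (index pairs).
#' @export
score_scene <- function(truth, records, slack_px = 3) {
  ps <- truth$params$pixel_size_um
  tc <- truth$cells
  nT <- nrow(tc); nD <- nrow(records)
  pairs <- NULL
  if (nT && nD) {
    d <- sqrt(outer(tc$row, records$centroid_row, `-`)^2 +
              outer(tc$col, records$centroid_col, `-`)^2)
    lim <- tc$radius_um / ps + slack_px
    cand <- which(d <= matrix(lim, nT, nD), arr.ind = TRUE)
    cand <- cand[order(d[cand]), , drop = FALSE]
    usedT <- logical(nT); usedD <- logical(nD)
    keep <- logical(nrow(cand))
    for (k in seq_len(nrow(cand))) {
      i <- cand[k, 1]; j <- cand[k, 2]
      if (!usedT[i] && !usedD[j]) { usedT[i] <- usedD[j] <- TRUE; keep[k] <- TRUE }
    }
    pairs <- cand[keep, , drop = FALSE]
  }
  classes <- c("preexisting", "progenitor", "new_progeny")
  tcls <- tc$lineage
  dcls <- records$cell_class
  conf <- do.call(rbind, lapply(classes, function(cl) {
    tp <- if (length(pairs)) sum(tcls[pairs[, 1]] == cl & dcls[pairs[, 2]] == cl) else 0L
    fn <- sum(tcls == cl) - (if (length(pairs)) sum(tcls[pairs[, 1]] == cl) else 0L) +
      (if (length(pairs)) sum(tcls[pairs[, 1]] == cl & dcls[pairs[, 2]] != cl) else 0L)
    fp <- sum(dcls == cl) - tp
    data.frame(class = cl, tp = tp, fp = fp, fn = fn,
               precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               f1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_)
  }))
  list(confusion = conf, matched = pairs)
}

#' Generate a bright-spot plane (synthetic mitosis marker field)
#'
#' Disjoint bright disks on a dark noisy background, with the true spot
#' count as ground truth, for validating [count_spots()].
#'
#' @param n_spots number of disks.
#' @param field_size_px `c(rows, cols)`.
#' @param radius_px disk radius.
#' @param amplitude disk intensity.
#' @param noise_sd background Gaussian noise SD.
#' @param seed RNG seed.
#' @return A list with `plane` ([image_plane]) and `n_spots`.
#' @export
generate_spots <- function(n_spots, field_size_px = c(256L, 256L), radius_px = 4,
                           amplitude = 1, noise_sd = 0, seed = 1L) {
  with_seed(seed, {
    nr <- field_size_px[1]; nc <- field_size_px[2]
    x <- matrix(0, nr, nc)
    rows <- cols <- numeric(n_spots)
    for (i in seq_len(n_spots)) {
      for (attempt in seq_len(5000L)) {
        ry <- runif(1, radius_px, nr - 1 - radius_px)
        rx <- runif(1, radius_px, nc - 1 - radius_px)
        prev <- seq_len(i - 1L)
        if (!length(prev) || all(sqrt((rows[prev] - ry)^2 + (cols[prev] - rx)^2) >
                                 2 * radius_px + 10)) break
        if (attempt == 5000L) stopf("placement failure for spot %d", i)
      }
      rows[i] <- ry; cols[i] <- rx
      x <- paint_disk(x, ry, rx, radius_px, amplitude)
    }
    if (noise_sd > 0) { x <- x + rnorm(length(x), 0, noise_sd); x[x < 0] <- 0 }
    list(plane = image_plane(x, channel = "PH3"), n_spots = n_spots)
  })
}

#' Generate an Oil Red O stained-gut image
#'
#' Grey background with red circular droplets covering approximately
#' `droplet_fraction` of the frame; droplet pixels have `R - G =
#' droplet_rg_delta`. The truth records the exact realised coverage.
#'
#' @param droplet_fraction target droplet coverage in `[0, 1]`.
#' @param droplet_rg_delta R minus G intensity on droplets.
#' @param field_size_px `c(rows, cols)`.
#' @param droplet_radius_px droplet radius.
#' @param grey background grey level (all three channels).
#' @param seed RNG seed.
#' @return A list with `image` ([rgb_image]) and `truth` (list with
#'   `coverage_fraction`, `rg_delta`, `droplet_mask`).
#' @export
generate_oro_image <- function(droplet_fraction, droplet_rg_delta,
                               field_size_px = c(256L, 256L), droplet_radius_px = 6,
                               grey = 120, seed = 1L) {
  if (droplet_fraction < 0 || droplet_fraction > 1)
    stopf("droplet_fraction must be in [0, 1]")
  with_seed(seed, {
    nr <- field_size_px[1]; nc <- field_size_px[2]
    mask <- matrix(FALSE, nr, nc)
    target <- droplet_fraction * nr * nc
    if (droplet_fraction >= 0.999) mask[] <- TRUE
    else if (droplet_fraction > 0) {
      for (attempt in seq_len(100000L)) {
        if (sum(mask) >= target) break
        ry <- runif(1, 0, nr - 1); rx <- runif(1, 0, nc - 1)
        mask <- paint_disk(mask * 1, ry, rx, droplet_radius_px) > 0
      }
    }
    r <- matrix(grey, nr, nc); r[mask] <- grey + droplet_rg_delta
    g <- b <- matrix(grey, nr, nc)
    list(image = rgb_image(r, g, b),
         truth = list(coverage_fraction = sum(mask) / (nr * nc),
                      rg_delta = droplet_rg_delta, droplet_mask = mask))
  })
}

#' Generate a DART-style mass spectrum
#'
#' Sum of Gaussian peaks on a uniform m/z grid plus non-negative-clipped
#' Gaussian noise.
#'
#' @param peaks data.frame/matrix with columns `mz` and `amplitude` (or a
#'   list of `c(mz, amplitude)` pairs); may be empty.
#' @param fwhm_th peak full width at half maximum (Th); default 0.04,
#'   resolving power ~6000 at m/z 250.
#' @param noise_sd Gaussian noise SD.
#' @param mz_range acquisition window (default 60-1000 Th).
#' @param step grid spacing (Th).
#' @param seed RNG seed.
#' @return A [mass_spectrum].
#' @export
generate_spectrum <- function(peaks, fwhm_th = 0.04, noise_sd = 0,
                              mz_range = c(60, 1000), step = 0.01, seed = 1L) {
  if (step <= 0) stopf("step must be > 0")
  if (is.list(peaks) && !is.data.frame(peaks))
    peaks <- do.call(rbind, lapply(peaks, function(p) data.frame(mz = p[1], amplitude = p[2])))
  peaks <- as.data.frame(peaks)
  if (nrow(peaks) && (!all(c("mz", "amplitude") %in% names(peaks))))
    names(peaks)[1:2] <- c("mz", "amplitude")
  if (nrow(peaks) && any(peaks$mz < mz_range[1] | peaks$mz > mz_range[2]))
    stopf("peaks must lie within mz_range")
  with_seed(seed, {
    grid <- seq(mz_range[1], mz_range[2], by = step)
    y <- numeric(length(grid))
    sg <- fwhm_th / (2 * sqrt(2 * log(2)))
    for (i in seq_len(nrow(peaks)))
      y <- y + peaks$amplitude[i] * exp(-(grid - peaks$mz[i])^2 / (2 * sg^2))
    if (noise_sd > 0) { y <- y + rnorm(length(y), 0, noise_sd); y[y < 0] <- 0 }
    mass_spectrum(grid, y)
  })
}

#' Generate a Ct table under a multiplicative fold-change model
#'
#' Virgin target Cts sit at `ct_base`; mated Cts are shifted by
#' `-log2(fold)` (higher expression = fewer cycles). The housekeeping gene
#' is constant across conditions. A per-sample additive shift (applied to
#' every gene of the sample, housekeeping included) models loading/batch
#' offsets and must cancel in the comparative-Ct analysis; per-replicate
#' Gaussian technical noise has SD `sd`.
#'
#' @param genes character vector of target gene names.
#' @param fold_changes mated/virgin fold change per gene (recycled).
#' @param ct_base virgin target-gene Ct (recycled per gene).
#' @param sd technical replicate noise SD (cycles).
#' @param n_batches paired batches; each holds one virgin and one mated sample.
#' @param n_replicates technical replicates per (sample, gene).
#' @param housekeeping_gene,housekeeping_ct reference gene and its Ct.
#' @param sample_shift_sd SD of the per-sample additive Ct shift.
#' @param seed RNG seed.
#' @return A [ct_table].
#' @export
generate_ct_table <- function(genes, fold_changes, ct_base = 25, sd = 0.2,
                              n_batches = 4L, n_replicates = 3L,
                              housekeeping_gene = "rp49", housekeeping_ct = 20,
                              sample_shift_sd = 0, seed = 1L) {
  if (any(fold_changes <= 0)) stopf("fold changes must be > 0")
  if (sd < 0) stopf("sd must be >= 0")
  fold_changes <- rep(fold_changes, length.out = length(genes))
  ct_base <- rep(ct_base, length.out = length(genes))
  with_seed(seed, {
    rows <- list()
    for (b in seq_len(n_batches)) for (cond in c("virgin", "mated")) {
      sid <- sprintf("b%d_%s", b, cond)
      shift <- if (sample_shift_sd > 0) rnorm(1, 0, sample_shift_sd) else 0
      for (gi in seq_along(genes)) {
        mu <- ct_base[gi] - if (cond == "mated") log2(fold_changes[gi]) else 0
        rows[[length(rows) + 1L]] <- data.frame(
          gene = genes[gi], sample_id = sid, condition = cond, batch_id = b,
          ct = mu + shift + (if (sd > 0) rnorm(n_replicates, 0, sd) else numeric(n_replicates)))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        gene = housekeeping_gene, sample_id = sid, condition = cond, batch_id = b,
        ct = housekeeping_ct + shift +
          (if (sd > 0) rnorm(n_replicates, 0, sd) else numeric(n_replicates)))
    }
    ct_table(do.call(rbind, rows), housekeeping_gene = housekeeping_gene)
  })
}

#' Generate negative-binomial count data
#'
#' Per-unit counts drawn NB(mu = group mean, size = dispersion), the
#' conventional variance mu + mu^2/theta parameterisation.
#'
#' @param group_means named numeric vector of group means (`> 0`).
#' @param dispersion NB theta (`> 0`); large theta approaches Poisson.
#' @param n_per_group units per group.
#' @param seed RNG seed.
#' @return A [count_data].
#' @export
generate_counts <- function(group_means, dispersion, n_per_group, seed = 1L) {
  if (any(group_means <= 0) || dispersion <= 0)
    stopf("group means and dispersion must be > 0")
  if (is.null(names(group_means)))
    names(group_means) <- paste0("g", seq_along(group_means))
  with_seed(seed, {
    rows <- do.call(rbind, lapply(names(group_means), function(g) {
      data.frame(unit_id = sprintf("%s_%d", g, seq_len(n_per_group)), group = g,
                 count = rnbinom(n_per_group, mu = group_means[[g]], size = dispersion))
    }))
    count_data(rows)
  })
}
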
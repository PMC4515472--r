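# ReDDM lineage-tracing quantification. The dual-marker system labels
# intestinal progenitors (ISCs + EBs) with membrane GFP and persistent
# nuclear H2B::RFP; progeny born during the tracing window inherit only the
# RFP. Quantification therefore reduces to: segment DAPI nuclei, call ploidy
# from nucleus size (polyploid = enterocyte), call RFP/GFP positivity per
# nucleus, and report per-gut class counts plus morphometry.

#' Segmentation and classification parameters
#'
#' Bundles every tunable of the ReDDM quantification. Defaults are chosen for
#' confocal-style midgut fields at sub-micron pixel sizes.
#'
#' @param dapi_threshold_method `"otsu"` (default) or `"fixed"`.
#' @param fixed_threshold intensity threshold used when method is `"fixed"`.
#' @param min_nucleus_area_um2 objects smaller than this are discarded (um^2).
#' @param smoothing_sigma_px Gaussian pre-smoothing sigma in pixels.
#' @param split_touching split touching nuclei by distance-map watershed.
#' @param watershed_tolerance_px minimum distance-map depth (px) between
#'   watershed maxima for objects to be split; smaller values split more
#'   aggressively.
#' @param ploidy_area_threshold_um2 area cut separating diploid from polyploid
#'   nuclei, or `"auto"` to place it by a two-class minimum-within-variance
#'   split of log-areas.
#' @param ploidy_fallback_area_um2 fixed cut used by the pipeline when auto
#'   mode lacks nuclei (< 4); 50 um^2 sits between typical diploid midgut
#'   nuclei (< ~38 um^2) and polyploid enterocytes (> ~60 um^2).
#' @param channel_positive_rule RFP positivity rule: `"mask_overlap"`
#'   (fraction of the nucleus inside the segmented RFP mask) or `"intensity"`
#'   (mean nuclear intensity above the channel threshold).
#' @param overlap_fraction fraction in (0, 1] required by `mask_overlap`.
#' @param gfp_annulus_px width in pixels of the perinuclear annulus used to
#'   score the membrane GFP signal.
#' @param gut_blur_sigma_um Gaussian sigma (um) for the tissue-detection
#'   pre-smoothing; physical units keep the mask boundary consistent across
#'   magnifications.
#' @param gut_close_radius_um disc radius (um) closing the tissue mask.
#' @param min_spot_area_px minimum object size (pixels) for [count_spots()].
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(dapi_threshold_method = c("otsu", "fixed"),
                                fixed_threshold = NA_real_,
                                min_nucleus_area_um2 = 6,
                                smoothing_sigma_px = 1,
                                split_touching = TRUE,
                                watershed_tolerance_px = 0.5,
                                ploidy_area_threshold_um2 = "auto",
                                ploidy_fallback_area_um2 = 50,
                                channel_positive_rule = c("mask_overlap", "intensity"),
                                overlap_fraction = 0.5,
                                gfp_annulus_px = 3L,
                                gut_blur_sigma_um = 6,
                                gut_close_radius_um = 8,
                                min_spot_area_px = 4L) {
  p <- list(dapi_threshold_method = match.arg(dapi_threshold_method),
            fixed_threshold = fixed_threshold,
            min_nucleus_area_um2 = min_nucleus_area_um2,
            smoothing_sigma_px = smoothing_sigma_px,
            split_touching = isTRUE(split_touching),
            watershed_tolerance_px = watershed_tolerance_px,
            ploidy_area_threshold_um2 = ploidy_area_threshold_um2,
            ploidy_fallback_area_um2 = ploidy_fallback_area_um2,
            channel_positive_rule = match.arg(channel_positive_rule),
            overlap_fraction = overlap_fraction,
            gfp_annulus_px = as.integer(gfp_annulus_px),
            gut_blur_sigma_um = gut_blur_sigma_um,
            gut_close_radius_um = gut_close_radius_um,
            min_spot_area_px = as.integer(min_spot_area_px))
  if (!(p$overlap_fraction > 0 && p$overlap_fraction <= 1))
    stopf("overlap_fraction must be in (0, 1]")
  if (p$min_nucleus_area_um2 < 0) stopf("min_nucleus_area_um2 must be >= 0")
  if (p$dapi_threshold_method == "fixed" &&
      (!is.finite(p$fixed_threshold) || p$fixed_threshold < 0))
    stopf("fixed threshold method needs a finite fixed_threshold >= 0")
  if (is.numeric(p$ploidy_area_threshold_um2) &&
      p$ploidy_area_threshold_um2 <= p$min_nucleus_area_um2)
    stopf("ploidy_area_threshold_um2 must exceed min_nucleus_area_um2")
  structure(p, class = "segmentation_params")
}

# Separable Gaussian smoothing, truncated at 3 sigma with border
# renormalisation (normalised convolution — behaves like edge replication
# without FFT wrap-around). Small kernels run as shift-and-add passes; wide
# kernels as banded-matrix products (BLAS).
gauss_smooth <- function(x, sigma) {
  x <- unclass(as.matrix(x))
  if (sigma <= 0) return(x)
  r <- ceiling(3 * sigma)
  if (r <= 9L) {
    k <- exp(-(-r:r)^2 / (2 * sigma^2))
    pass <- function(m, along_rows) {
      n <- if (along_rows) nrow(m) else ncol(m)
      acc <- matrix(0, nrow(m), ncol(m))
      for (i in seq_along(k)) {
        sh <- pmin(n, pmax(1L, seq_len(n) + (i - r - 1L)))
        acc <- acc + if (along_rows) k[i] * m[sh, , drop = FALSE]
                     else k[i] * m[, sh, drop = FALSE]
      }
      acc / sum(k)
    }
    # clamped-index shifts replicate the edge rows/columns
    return(pass(pass(x, TRUE), FALSE))
  }
  band <- function(n) {
    d <- outer(seq_len(n), seq_len(n), `-`)
    K <- exp(-d^2 / (2 * sigma^2))
    K[abs(d) > r] <- 0
    K / rowSums(K)
  }
  band(nrow(x)) %*% x %*% t(band(ncol(x)))
}

# Otsu with a signal-presence guard: returns Inf (nothing positive) when the
# plane is constant or when the foreground/background separation is within
# noise (< 4 background SDs), as for an unstained channel.
channel_threshold <- function(x, mask = NULL) {
  x <- unclass(as.matrix(x))
  v <- if (is.null(mask)) as.vector(x) else x[mask]
  if (length(v) == 0 || diff(range(v)) == 0) return(Inf)
  thr <- otsu_threshold(v)
  bg <- v[v < thr]; fg <- v[v >= thr]
  if (!length(bg) || !length(fg)) return(Inf)
  if ((mean(fg) - mean(bg)) < 4 * max(sd(bg), 1e-12)) return(Inf)
  thr
}

# Nucleus threshold: midpoint between the tissue floor (median of the
# within-mask intensities — nuclei occupy a minority of the tissue) and the
# robust peak level (99.9th percentile), i.e. the half-maximum above
# background. Unlike a histogram split this stays put when nuclei cover an
# arbitrarily small fraction of the field. Returns Inf when the bright tail
# does not rise above the background spread (no nuclei).
nucleus_threshold <- function(x, mask = NULL) {
  x <- unclass(as.matrix(x))
  v <- if (is.null(mask)) as.vector(x) else x[mask]
  if (!length(v) || diff(range(v)) == 0) return(Inf)
  med <- median(v)
  rmax <- quantile(v, 0.999, names = FALSE)
  if (rmax - med <= 5 * max(stats::mad(v), 1e-12)) return(Inf)
  (med + rmax) / 2
}

largest_component <- function(bw) {
  lab <- EBImage::bwlabel(bw)
  a <- tabulate(as.integer(lab))
  if (!length(a)) return(bw & FALSE)
  as.matrix(lab) == which.max(a)
}

# Replicate-pad a matrix by `r` pixels on every side (nearest-edge values),
# so that morphology treats tissue touching the frame edge as continuing
# beyond it rather than being eroded away.
pad_replicate <- function(m, r) {
  nr <- nrow(m); nc <- ncol(m)
  m[c(rep(1L, r), seq_len(nr), rep(nr, r)), c(rep(1L, r), seq_len(nc), rep(nc, r))]
}

closing_padded <- function(bw, r) {
  if (r <= 0) return(bw)
  brush <- EBImage::makeBrush(2L * r + 1L, "disc")
  p <- pad_replicate(bw, r)
  p <- as.matrix(EBImage::erode(EBImage::dilate(p, brush), brush)) > 0
  p[r + seq_len(nrow(bw)), r + seq_len(ncol(bw))]
}

#' Detect the gut tissue area
#'
#' Finds the tissue footprint from the background staining: the lightly
#' blurred summed channels are thresholded to a nucleus-presence mask, whose
#' union is closed with a large disc (bridging the inter-nucleus spacing),
#' hole-filled, and reduced to its largest connected component. Replicate
#' padding keeps tissue that touches the frame edge from being eroded.
#'
#' @param stack a [channel_stack] with a DAPI channel.
#' @param params a [segmentation_params]; `gut_blur_sigma_um` smooths the
#'   summed signal and `gut_close_radius_um` sets the closing radius, which
#'   should exceed half the largest inter-nucleus gap.
#' @return Logical tissue mask.
#' @export
detect_gut_area <- function(stack, params = segmentation_params()) {
  if (!"DAPI" %in% names(stack$channels)) stopf("DAPI channel required for tissue detection")
  x <- Reduce(`+`, lapply(names(stack$channels),
                          function(ch) unclass(max_project(stack, ch))))
  if (max(x) <= 0) stopf("no tissue: image is empty (all-zero intensities)")
  ps <- stack$pixel_size_um
  b <- gauss_smooth(x, params$gut_blur_sigma_um / ps)
  if (diff(range(b)) == 0) return(matrix(TRUE, nrow(x), ncol(x)))
  # threshold between the empty-background level (low quantile) and the
  # typical tissue level (median); otsu would split the within-tissue
  # variation instead when the tissue dominates the frame
  q <- quantile(b, 0.01, names = FALSE)
  thr <- q + 0.45 * (median(b) - q)
  bw <- b >= thr
  bw <- closing_padded(bw, max(1L, round(params$gut_close_radius_um / ps)))
  bw <- as.matrix(EBImage::fillHull(bw)) > 0
  m <- largest_component(bw)
  if (!any(m)) stopf("no tissue: threshold selected an empty mask")
  m
}

#' Segment nuclei in a DAPI plane
#'
#' Gaussian smoothing, global threshold (Otsu on the within-mask intensities
#' or a fixed value), optional distance-map watershed splitting of touching
#' objects, then removal of objects below `min_nucleus_area_um2` or outside
#' the tissue mask.
#'
#' @param dapi DAPI [image_plane].
#' @param mask logical tissue mask of the same shape (default: everything).
#' @param params a [segmentation_params].
#' @param channels optional named list of extra planes (e.g. GFP, RFP) whose
#'   per-nucleus mean intensities are recorded.
#' @return A data.frame of class `nucleus_records` with one row per nucleus
#'   (`label`, `centroid_row`, `centroid_col` in 0-based pixels, `area_um2`,
#'   `mean_DAPI`, further `mean_*` columns, `ploidy`, `cell_class`), carrying
#'   the integer label image as attribute `label_image`.
#' @export
segment_nuclei <- function(dapi, mask = NULL, params = segmentation_params(),
                           channels = list()) {
  x <- unclass(as.matrix(dapi))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(x), ncol(x))
  if (!all(dim(mask) == dim(x))) stopf("dapi and mask must have the same shape")
  ps <- pixel_size(dapi)
  sm <- gauss_smooth(x, params$smoothing_sigma_px)
  thr <- if (params$dapi_threshold_method == "fixed") params$fixed_threshold
         else nucleus_threshold(sm, mask)
  # threshold the full frame; membership in the tissue is decided per object
  # by its centroid, so nuclei straddling the (approximate) mask boundary are
  # not truncated
  bw <- sm >= thr
  empty <- empty_records(x, ps, names(channels))
  if (!any(bw)) {
    warnf("nucleus threshold selected zero foreground; returning no nuclei")
    return(empty)
  }
  lab <- if (params$split_touching)
    as.matrix(EBImage::watershed(EBImage::distmap(bw),
                                 tolerance = params$watershed_tolerance_px, ext = 1))
  else as.matrix(EBImage::bwlabel(bw))
  storage.mode(lab) <- "integer"
  n <- max(lab)
  px_area <- tabulate(lab, n)
  cen <- object_centroids(lab, n)
  # tolerate the tissue boundary's localisation uncertainty (~ half the
  # detection blur sigma) when deciding membership
  margin <- ceiling(params$gut_blur_sigma_um / ps / 2)
  mdil <- if (margin > 0 && !all(mask)) {
    p <- pad_replicate(mask, margin)
    as.matrix(EBImage::dilate(p, EBImage::makeBrush(2L * margin + 1L, "disc")))[
      margin + seq_len(nrow(mask)), margin + seq_len(ncol(mask))] > 0
  } else mask
  in_mask <- mdil[cbind(pmin(nrow(x), pmax(1L, round(cen$row) + 1L)),
                        pmin(ncol(x), pmax(1L, round(cen$col) + 1L)))]
  keep <- which(px_area * ps^2 >= params$min_nucleus_area_um2 & in_mask)
  if (!length(keep)) {
    warnf("no segmented object passes the size filter inside the mask; returning no nuclei")
    return(empty)
  }
  # relabel contiguously
  map <- integer(n); map[keep] <- seq_along(keep)
  lab[lab > 0L] <- map[lab[lab > 0L]]
  n <- length(keep)
  idx <- which(lab > 0L)
  l <- lab[idx]
  rows0 <- (idx - 1L) %% nrow(x)        # 0-based row of each foreground pixel
  cols0 <- (idx - 1L) %/% nrow(x)
  cnt <- tabulate(l, n)
  rec <- data.frame(
    label = seq_len(n),
    centroid_row = as.vector(rowsum(as.numeric(rows0), l)) / cnt,
    centroid_col = as.vector(rowsum(as.numeric(cols0), l)) / cnt,
    area_um2 = cnt * ps^2,
    mean_DAPI = as.vector(rowsum(x[idx], l)) / cnt)
  for (nm in names(channels)) {
    chx <- unclass(as.matrix(channels[[nm]]))
    rec[[paste0("mean_", nm)]] <- as.vector(rowsum(chx[idx], l)) / cnt
  }
  rec$ploidy <- NA_character_
  rec$cell_class <- NA_character_
  structure(rec, label_image = lab, pixel_size_um = ps,
            class = c("nucleus_records", "data.frame"))
}

# 0-based centroids of all labels in an integer label image.
object_centroids <- function(lab, n) {
  idx <- which(lab > 0L); l <- lab[idx]
  cnt <- tabulate(l, n)
  rows0 <- (idx - 1L) %% nrow(lab)
  cols0 <- (idx - 1L) %/% nrow(lab)
  list(row = as.vector(rowsum(as.numeric(rows0), l)) / cnt,
       col = as.vector(rowsum(as.numeric(cols0), l)) / cnt)
}

empty_records <- function(x, ps = 1, channel_names = character()) {
  rec <- data.frame(label = integer(), centroid_row = numeric(),
                    centroid_col = numeric(), area_um2 = numeric(),
                    mean_DAPI = numeric())
  for (nm in channel_names) rec[[paste0("mean_", nm)]] <- numeric()
  rec$ploidy <- character(); rec$cell_class <- character()
  structure(rec, label_image = matrix(0L, nrow(x), ncol(x)),
            pixel_size_um = ps,
            class = c("nucleus_records", "data.frame"))
}

# Two-class 1-D split of `v` minimising total within-class variance,
# exhaustive over all cut positions of the sorted values. Returns the
# midpoint between the two classes' adjacent values.
two_class_split <- function(v) {
  s <- sort(v)
  n <- length(s)
  css <- function(x) if (length(x) < 2) 0 else sum((x - mean(x))^2)
  wss <- vapply(seq_len(n - 1L), function(k) css(s[1:k]) + css(s[(k + 1):n]), 0)
  k <- which.min(wss)
  (s[k] + s[k + 1]) / 2
}

#' Classify nucleus ploidy from size
#'
#' Nucleus area discriminates the diploid cells of the midgut epithelium
#' (ISCs, EBs, EECs) from the large polyploid enterocytes: a nucleus is
#' called polyploid iff `area_um2 >= threshold`. In `"auto"` mode the
#' threshold is placed at the midpoint between the two classes of a
#' minimum-within-variance split of the log-areas, exploiting their
#' bimodality.
#'
#' @param nuclei a `nucleus_records` data.frame from [segment_nuclei()].
#' @param params a [segmentation_params]; `ploidy_area_threshold_um2` is
#'   either numeric (um^2) or `"auto"`.
#' @return The records with `ploidy` set, carrying the threshold used as
#'   attribute `ploidy_threshold_um2`.
#' @export
classify_ploidy <- function(nuclei, params = segmentation_params()) {
  thr <- params$ploidy_area_threshold_um2
  if (identical(thr, "auto")) {
    if (nrow(nuclei) < 4L)
      stopf("auto ploidy threshold needs >= 4 nuclei; supply a fixed ploidy_area_threshold_um2")
    thr <- exp(two_class_split(log(nuclei$area_um2)))
  }
  nuclei$ploidy <- ifelse(nuclei$area_um2 >= thr, "polyploid", "diploid")
  attr(nuclei, "ploidy_threshold_um2") <- thr
  nuclei
}

# Per-nucleus mean intensity in a perinuclear annulus of width `width_px`,
# excluding the pixels of every nucleus. Used for membrane markers.
annulus_means <- function(lab, plane, width_px) {
  x <- unclass(as.matrix(plane))
  n <- max(lab)
  any_nuc <- lab > 0L
  brush <- EBImage::makeBrush(2L * width_px + 1L, "disc")
  out <- numeric(n)
  nr <- nrow(lab); nc <- ncol(lab)
  for (i in seq_len(n)) {
    idx <- which(lab == i)
    r <- (idx - 1L) %% nr + 1L; c <- (idx - 1L) %/% nr + 1L
    r0 <- max(1L, min(r) - width_px); r1 <- min(nr, max(r) + width_px)
    c0 <- max(1L, min(c) - width_px); c1 <- min(nc, max(c) + width_px)
    sub <- lab[r0:r1, c0:c1] == i
    dil <- as.matrix(EBImage::dilate(sub, brush)) > 0
    ann <- dil & !any_nuc[r0:r1, c0:c1]
    out[i] <- if (any(ann)) mean(x[r0:r1, c0:c1][ann]) else 0
  }
  out
}

#' Assign ReDDM lineage classes and build the per-gut report
#'
#' RFP positivity follows `params$channel_positive_rule`: under
#' `"mask_overlap"` a nucleus is RFP+ when at least `overlap_fraction` of its
#' area lies inside the thresholded RFP mask (H2B::RFP is nuclear, so the
#' overlap is direct); under `"intensity"` when its mean nuclear RFP exceeds
#' the channel threshold. GFP (mCD8::GFP) marks membranes, so a nucleus is
#' GFP+ when the mean GFP in a perinuclear annulus of width `gfp_annulus_px`
#' exceeds the channel threshold. Classes: GFP+ & RFP+ = progenitor (ISC/EB);
#' GFP- & RFP+ = new postmitotic progeny; RFP- = pre-existing cell. GFP+ &
#' RFP- nuclei are counted as anomalies (they diagnose segmentation failure)
#' and reported, never reassigned.
#'
#' @param nuclei `nucleus_records` with ploidy set (see [classify_ploidy()]).
#' @param rfp,gfp RFP and GFP [image_plane]s matching the segmented frame.
#' @param params a [segmentation_params].
#' @param gut_mask optional tissue mask used for the report's area and
#'   density; defaults to the full frame.
#' @param diameter_um optional gut diameter to carry into the report.
#' @return A list with `records` (classes set, plus `rfp_positive` /
#'   `gfp_positive` columns) and `report` (a `cell_class_report`).
#' @export
assign_cell_classes <- function(nuclei, rfp, gfp, params = segmentation_params(),
                                gut_mask = NULL, diameter_um = NA_real_) {
  lab <- attr(nuclei, "label_image")
  if (is.null(lab)) stopf("nuclei must carry a label_image attribute (from segment_nuclei)")
  if (!all(dim(lab) == dim(as.matrix(rfp))) || !all(dim(lab) == dim(as.matrix(gfp))))
    stopf("rfp/gfp shape must match the segmented frame")
  if (nrow(nuclei) && any(is.na(nuclei$ploidy)))
    stopf("run classify_ploidy() before assign_cell_classes()")
  ps <- attr(nuclei, "pixel_size_um") %||% pixel_size(rfp)
  n <- nrow(nuclei)
  rfp_x <- unclass(as.matrix(rfp)); gfp_x <- unclass(as.matrix(gfp))
  tissue <- if (is.null(gut_mask)) matrix(TRUE, nrow(lab), ncol(lab)) else gut_mask

  if (n) {
    idx <- which(lab > 0L); l <- lab[idx]; cnt <- tabulate(l, n)
    rfp_thr <- channel_threshold(rfp_x, tissue)
    if (params$channel_positive_rule == "mask_overlap") {
      rmask <- rfp_x >= rfp_thr
      frac <- as.vector(rowsum(as.numeric(rmask[idx]), l)) / cnt
      rfp_pos <- frac >= params$overlap_fraction
    } else {
      mean_rfp <- as.vector(rowsum(rfp_x[idx], l)) / cnt
      rfp_pos <- mean_rfp >= rfp_thr
    }
    gfp_thr <- channel_threshold(gfp_x, tissue)
    gfp_pos <- if (is.finite(gfp_thr))
      annulus_means(lab, gfp_x, params$gfp_annulus_px) > gfp_thr
    else rep(FALSE, n)
    cls <- ifelse(!rfp_pos, "preexisting",
                  ifelse(gfp_pos, "progenitor", "new_progeny"))
    anomalous <- gfp_pos & !rfp_pos
  } else {
    rfp_pos <- gfp_pos <- logical(0); cls <- character(0); anomalous <- logical(0)
  }
  nuclei$rfp_positive <- rfp_pos
  nuclei$gfp_positive <- gfp_pos
  nuclei$cell_class <- cls

  gut_area_um2 <- sum(tissue) * ps^2
  report <- cell_class_report(
    n_total_nuclei = n,
    n_ec = sum(nuclei$ploidy == "polyploid"),
    n_rfp = sum(rfp_pos),
    n_gfp = sum(gfp_pos),
    n_new_progeny = sum(cls == "new_progeny"),
    n_anomalous = sum(anomalous),
    gut_area_um2 = gut_area_um2,
    diameter_um = diameter_um)
  list(records = nuclei, report = report)
}

#' Per-gut cell-class report
#'
#' The summary the tracing workflow emits per gut: total nuclei, total ECs
#' (large-DAPI polyploid nuclei), total RFP+ (progenitors + progeny), total
#' GFP+ (ISCs + EBs), newly generated progeny (RFP+ GFP-), tissue area,
#' density, and optionally the gut diameter.
#'
#' @param n_total_nuclei,n_ec,n_rfp,n_gfp,n_new_progeny,n_anomalous counts.
#' @param gut_area_um2 tissue area in um^2.
#' @param diameter_um optional diameter in um.
#' @return An object of class `cell_class_report`.
#' @export
cell_class_report <- function(n_total_nuclei, n_ec, n_rfp, n_gfp, n_new_progeny,
                              n_anomalous = 0L, gut_area_um2, diameter_um = NA_real_) {
  if (n_rfp > n_total_nuclei || n_ec > n_total_nuclei)
    stopf("class counts cannot exceed the total nucleus count")
  if (n_anomalous == 0L && n_new_progeny != n_rfp - n_gfp)
    stopf("inconsistent report: n_new_progeny must equal n_rfp - n_gfp when no anomalies")
  if (gut_area_um2 <= 0) stopf("gut_area_um2 must be > 0")
  structure(list(n_total_nuclei = as.integer(n_total_nuclei),
                 n_ec = as.integer(n_ec),
                 n_rfp = as.integer(n_rfp),
                 n_gfp = as.integer(n_gfp),
                 n_new_progeny = as.integer(n_new_progeny),
                 n_anomalous = as.integer(n_anomalous),
                 gut_area_um2 = gut_area_um2,
                 density_per_mm2 = n_total_nuclei / (gut_area_um2 * 1e-6),
                 diameter_um = diameter_um),
            class = "cell_class_report")
}

#' @export
print.cell_class_report <- function(x, ...) {
  cat("Per-gut cell-class report\n")
  cat(sprintf("  nuclei: %d total | %d EC (polyploid) | %d RFP+ | %d GFP+ | %d new progeny",
              x$n_total_nuclei, x$n_ec, x$n_rfp, x$n_gfp, x$n_new_progeny))
  if (x$n_anomalous > 0) cat(sprintf(" | %d anomalous (GFP+ RFP-)", x$n_anomalous))
  cat(sprintf("\n  area: %.0f um^2 | density: %.1f nuclei/mm^2", x$gut_area_um2,
              x$density_per_mm2))
  if (is.finite(x$diameter_um)) cat(sprintf(" | diameter: %.1f um", x$diameter_um))
  cat("\n")
  invisible(x)
}

#' Measure gut diameter along the image-centre line
#'
#' Reproducible stand-in for the manual line tool: the diameter is the extent
#' of the tissue mask along the vertical line through the image-centre column
#' (or the horizontal line through the centre row), i.e. the count of mask
#' pixels on that line times the pixel size.
#'
#' @param mask logical tissue mask (or an [image_plane] treated as `> 0`).
#' @param pixel_size_um physical pixel size; taken from the plane if present.
#' @param orientation `"vertical"` (default) or `"horizontal"` measuring line.
#' @return Diameter in um.
#' @export
measure_diameter <- function(mask, pixel_size_um = NULL,
                             orientation = c("vertical", "horizontal")) {
  orientation <- match.arg(orientation)
  pixel_size_um <- pixel_size_um %||% pixel_size(mask)
  m <- if (is.logical(mask)) mask else unclass(as.matrix(mask)) > 0
  if (!any(m)) stopf("empty mask")
  line <- if (orientation == "vertical") m[, round((ncol(m) + 1) / 2)]
          else m[round((nrow(m) + 1) / 2), ]
  if (!any(line))
    stopf("the centre %s line does not cross the mask; re-centre the ROI", orientation)
  sum(line) * pixel_size_um
}

#' Count bright spots (e.g. pH3+ mitotic nuclei)
#'
#' Counts connected supra-threshold objects within the mask after a minimum
#' size filter — an automated replacement for manual counting of mitotic
#' nuclei.
#'
#' Spots are sparse, so the threshold is set robustly from the background
#' (median plus 5 robust SDs of the lightly smoothed plane) rather than by a
#' histogram split, and objects smaller than `min_spot_area_px` are dropped.
#'
#' @param plane an [image_plane] (e.g. the pH3 channel).
#' @param mask logical mask restricting the count (default: full frame).
#' @param params a [segmentation_params] (`min_spot_area_px` is used).
#' @return Integer spot count.
#' @export
count_spots <- function(plane, mask = NULL, params = segmentation_params()) {
  x <- unclass(as.matrix(plane))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(x), ncol(x))
  if (!all(dim(mask) == dim(x))) stopf("plane and mask must share shape")
  sm <- gauss_smooth(x, 1)
  v <- sm[mask]
  thr <- median(v) + 5 * stats::mad(v)
  bw <- sm > thr & mask
  if (!any(bw)) return(0L)
  lab <- EBImage::bwlabel(bw)
  a <- tabulate(as.integer(lab))
  sum(a >= params$min_spot_area_px)
}

#' Quantify a ReDDM gut image end to end
#'
#' Runs the full pipeline on a stack: maximum projections, tissue detection,
#' DAPI nucleus segmentation, ploidy classification, RFP/GFP lineage-class
#' assignment, diameter measurement, and report assembly.
#'
#' @param stack a [channel_stack] with DAPI (required) and optionally GFP,
#'   RFP and PH3 channels.
#' @param params a [segmentation_params].
#' @return An object of class `reddm_report`: list with `records` (per-nucleus
#'   table), `report` (the [cell_class_report]), `gut_mask`, `n_ph3` (spot
#'   count if a PH3 channel is present) and `params`.
#' @export
reddm_quantify <- function(stack, params = segmentation_params()) {
  dapi <- max_project(stack, "DAPI")
  mask <- detect_gut_area(stack, params)
  zero <- plane_like(unclass(dapi) * 0, dapi)
  rfp <- if ("RFP" %in% names(stack$channels)) max_project(stack, "RFP") else zero
  gfp <- if ("GFP" %in% names(stack$channels)) max_project(stack, "GFP") else zero
  nuc <- segment_nuclei(dapi, mask, params, channels = list(RFP = rfp, GFP = gfp))
  if (nrow(nuc) < 4L && identical(params$ploidy_area_threshold_um2, "auto"))
    params$ploidy_area_threshold_um2 <- params$ploidy_fallback_area_um2
  nuc <- classify_ploidy(nuc, params)
  diam <- tryCatch(measure_diameter(mask, pixel_size(dapi)), error = function(e) NA_real_)
  cc <- assign_cell_classes(nuc, rfp, gfp, params, gut_mask = mask, diameter_um = diam)
  n_ph3 <- if ("PH3" %in% names(stack$channels))
    count_spots(max_project(stack, "PH3"), mask, params) else NA_integer_
  structure(list(records = cc$records, report = cc$report, gut_mask = mask,
                 n_ph3 = n_ph3, params = params),
            class = "reddm_report")
}

#' @export
print.reddm_report <- function(x, ...) {
  cat("ReDDM gut quantification\n")
  print(x$report)
  if (!is.na(x$n_ph3)) cat(sprintf("  pH3+ spots: %d\n", x$n_ph3))
  invisible(x)
}

#' @export
summary.reddm_report <- function(object, ...) {
  r <- object$report
  data.frame(n_total_nuclei = r$n_total_nuclei, n_ec = r$n_ec, n_rfp = r$n_rfp,
             n_gfp = r$n_gfp, n_new_progeny = r$n_new_progeny,
             n_anomalous = r$n_anomalous, gut_area_um2 = r$gut_area_um2,
             density_per_mm2 = r$density_per_mm2, diameter_um = r$diameter_um,
             n_ph3 = object$n_ph3)
}

#' Write per-nucleus records and the gut report to CSV
#'
#' @param result a `reddm_report` from [reddm_quantify()].
#' @param records_csv,report_csv output paths (either may be `NULL` to skip).
#' @return `result`, invisibly.
#' @export
write_reddm_csv <- function(result, records_csv = NULL, report_csv = NULL) {
  if (!is.null(records_csv))
    write.csv(as.data.frame(result$records), records_csv, row.names = FALSE)
  if (!is.null(report_csv))
    write.csv(summary(result), report_csv, row.names = FALSE)
  invisible(result)
}
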
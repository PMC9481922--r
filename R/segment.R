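# Classical instance segmentation of bright-field well images.
#
# A deterministic watershed pipeline stands behind a pluggable label-map
# contract: any segmenter producing a label image (0 = background, labels
# a contiguous 1..K) can replace it and the downstream analytics are
# unchanged.

#' Segmentation parameters
#'
#' @param smoothing_sigma Gaussian pre-smoothing sigma in px (0 = none).
#' @param threshold_method `"otsu"` (global Otsu on the
#'   background-subtracted image, floored at `min_contrast`) or
#'   `"offset"` (fixed contrast offset from the background median).
#' @param threshold_offset Contrast threshold used by `"offset"`.
#' @param min_contrast Lower bound on the Otsu threshold; prevents an
#'   all-background image from being split on noise.
#' @param min_area Minimum object area in um^2; smaller components are
#'   discarded as debris.
#' @param max_area Maximum object area in um^2.
#' @param min_circularity Minimum circularity used by
#'   [classify_objects()] for the tumorsphere call.
#' @param watershed_min_distance Minimum distance-map depth (px) between
#'   watershed seeds; touching objects closer than this are not split.
#' @param clear_border Drop objects touching the image border (their area
#'   is not measurable); documented as a count bias.
#' @return An object of class `mos_segmentation_params`.
#' @export
segmentation_params <- function(smoothing_sigma = 1,
                                threshold_method = c("otsu", "offset"),
                                threshold_offset = 0.1,
                                min_contrast = 0.05,
                                min_area = 500, max_area = Inf,
                                min_circularity = 0.6,
                                watershed_min_distance = 2,
                                clear_border = TRUE) {
  threshold_method <- match.arg(threshold_method)
  assert_number(smoothing_sigma, "smoothing_sigma", lower = 0)
  assert_number(threshold_offset, "threshold_offset", lower = 0, upper = 1)
  assert_number(min_contrast, "min_contrast", lower = 0, upper = 1)
  assert_number(min_area, "min_area", lower = 0)
  if (!(max_area > min_area))
    stop("`max_area` must exceed `min_area`", call. = FALSE)
  assert_number(min_circularity, "min_circularity", lower = 0, upper = 1)
  assert_number(watershed_min_distance, "watershed_min_distance", lower = 0)
  structure(list(smoothing_sigma = smoothing_sigma,
                 threshold_method = threshold_method,
                 threshold_offset = threshold_offset,
                 min_contrast = min_contrast,
                 min_area = min_area, max_area = max_area,
                 min_circularity = min_circularity,
                 watershed_min_distance = watershed_min_distance,
                 clear_border = clear_border),
            class = "mos_segmentation_params")
}

# relabel a label image to the contiguous set 1..K (stable order)
relabel_contiguous <- function(labels) {
  u <- sort(unique(labels[labels > 0]))
  if (!length(u)) return(matrix(0L, nrow(labels), ncol(labels)))
  lut <- integer(max(u))
  lut[u] <- seq_along(u)
  out <- labels
  out[labels > 0] <- lut[labels[labels > 0]]
  matrix(as.integer(out), nrow(labels), ncol(labels))
}

#' Segment organospheres from a bright-field well image
#'
#' Deterministic classical pipeline: Gaussian smoothing, background-
#' relative thresholding (objects are darker than the background),
#' hole filling, distance-transform watershed splitting of touching
#' objects, then removal of too-small/too-large components and of
#' objects touching the image border. Identical image and parameters
#' always give an identical label map.
#'
#' @param image Single-channel bright-field matrix with values in
#'   `[0, 1]`.
#' @param params A [segmentation_params()].
#' @param pixel_size Pixel calibration, um/px (converts the area limits).
#' @return An object of class `mos_labelmap`: list with integer matrix
#'   `labels` (0 = background, contiguous labels 1..K), `pixel_size`,
#'   and `provenance`.
#' @export
segment_brightfield <- function(image, params = segmentation_params(),
                                pixel_size = 10) {
  stopifnot(is.matrix(image))
  assert_number(pixel_size, "pixel_size", lower = 1e-9)
  bg <- median(image)
  inv <- pmax(bg - image, 0)
  if (params$smoothing_sigma > 0)
    inv <- EBImage::gblur(inv, params$smoothing_sigma)
  thr <- switch(params$threshold_method,
    otsu = max(EBImage::otsu(inv, range = c(0, 1)), params$min_contrast),
    offset = params$threshold_offset)
  mask <- inv > thr
  if (!any(mask)) {
    lab <- matrix(0L, nrow(image), ncol(image))
  } else {
    mask <- EBImage::fillHull(mask)
    dm <- EBImage::distmap(mask)
    lab <- EBImage::watershed(dm, tolerance = params$watershed_min_distance,
                              ext = 1)
    lab <- matrix(as.integer(lab), nrow(image), ncol(image))
    # size and border filters
    px_area <- pixel_size^2
    tab <- tabulate(lab[lab > 0])
    drop <- which(tab * px_area < params$min_area |
                  tab * px_area > params$max_area)
    border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    if (params$clear_border) drop <- union(drop, border[border > 0])
    if (length(drop)) lab[lab %in% drop] <- 0L
    lab <- relabel_contiguous(lab)
  }
  structure(list(labels = lab, pixel_size = pixel_size,
                 provenance = paste0("segment_brightfield/",
                   paste(unlist(params[1:8]), collapse = ","))),
            class = "mos_labelmap")
}

#' @export
print.mos_labelmap <- function(x, ...) {
  cat(sprintf("Label map: %d objects, %dx%d px, %g um/px\n",
              max(x$labels), nrow(x$labels), ncol(x$labels), x$pixel_size))
  invisible(x)
}

#' Wrap an externally produced label image
#'
#' Plug-in point for alternative segmenters (e.g. a learned model whose
#' masks were exported): validates and relabels the image to the
#' contiguous-label contract so the downstream pipeline is unchanged.
#'
#' @param labels Integer label matrix (0 = background).
#' @param pixel_size Pixel calibration, um/px.
#' @return An object of class `mos_labelmap`.
#' @export
as_labelmap <- function(labels, pixel_size = 10) {
  stopifnot(is.matrix(labels), all(labels >= 0))
  structure(list(labels = relabel_contiguous(labels),
                 pixel_size = pixel_size, provenance = "external"),
            class = "mos_labelmap")
}

#' Morphometrics and tumorsphere/stroma classification
#'
#' Computes per-object area, perimeter, centroid and circularity
#' (`4 * pi * area / perimeter^2`) and classifies each object: `stroma`
#' if its area is below `min_area_tumorsphere` or its circularity below
#' `min_circularity`, else `tumorsphere`. Stromal cells are small and
#' irregular; tumorspheres are large and round.
#'
#' @param labelmap A `mos_labelmap`.
#' @param min_area_tumorsphere Area cutoff in um^2 below which an object
#'   is called stroma.
#' @param min_circularity Circularity cutoff below which an object is
#'   called stroma.
#' @return A data.frame with one row per object: `label`,
#'   `centroid_row`, `centroid_col` (1-based px), `area_um2`,
#'   `perimeter_px`, `circularity`, `class`.
#' @export
classify_objects <- function(labelmap, min_area_tumorsphere = 2000,
                             min_circularity = 0.6) {
  stopifnot(inherits(labelmap, "mos_labelmap"))
  lab <- labelmap$labels
  k <- max(lab)
  if (k == 0L)
    return(data.frame(label = integer(0), centroid_row = numeric(0),
                      centroid_col = numeric(0), area_um2 = numeric(0),
                      perimeter_px = numeric(0), circularity = numeric(0),
                      class = character(0), stringsAsFactors = FALSE))
  sh <- EBImage::computeFeatures.shape(lab)
  mo <- EBImage::computeFeatures.moment(lab)
  area_um2 <- sh[, "s.area"] * labelmap$pixel_size^2
  circ <- 4 * pi * sh[, "s.area"] / pmax(sh[, "s.perimeter"], 1)^2
  cls <- ifelse(area_um2 < min_area_tumorsphere | circ < min_circularity,
                "stroma", "tumorsphere")
  data.frame(label = seq_len(k),
             centroid_row = as.numeric(mo[, "m.cx"]),
             centroid_col = as.numeric(mo[, "m.cy"]),
             area_um2 = as.numeric(area_um2),
             perimeter_px = as.numeric(sh[, "s.perimeter"]),
             circularity = as.numeric(circ),
             class = cls, row.names = NULL, stringsAsFactors = FALSE)
}

#' Match segmented objects to ground-truth masks
#'
#' Pairs segmentation labels with ground-truth labels greedily by
#' decreasing intersection-over-union (IoU); a pair is a match when its
#' IoU reaches `iou_threshold`. Used to score recall, precision, and
#' per-object area recovery against the simulator's masks.
#'
#' @param labelmap A `mos_labelmap` (or plain integer matrix).
#' @param gt_mask Ground-truth integer label matrix.
#' @param iou_threshold Minimum IoU for a match.
#' @param gt_ids Optional subset of ground-truth ids to score (e.g.
#'   tumorspheres only).
#' @param seg_ids Optional subset of segmentation labels to score against
#'   (e.g. objects classified as tumorspheres).
#' @return List with `recall`, `precision`, `n_gt`, `n_seg`, and a
#'   `matches` data.frame (`gt_id`, `seg_id`, `iou`, `area_gt_px`,
#'   `area_seg_px`, `rel_area_error`).
#' @export
evaluate_segmentation <- function(labelmap, gt_mask, iou_threshold = 0.5,
                                  gt_ids = NULL, seg_ids = NULL) {
  seg <- if (inherits(labelmap, "mos_labelmap")) labelmap$labels else labelmap
  stopifnot(all(dim(seg) == dim(gt_mask)))
  gt_all <- sort(unique(gt_mask[gt_mask > 0]))
  seg_all <- sort(unique(seg[seg > 0]))
  gt_ids <- if (is.null(gt_ids)) gt_all else intersect(gt_ids, gt_all)
  seg_ids <- if (is.null(seg_ids)) seg_all else intersect(seg_ids, seg_all)
  area_gt <- tabulate(gt_mask[gt_mask > 0], nbins = max(gt_all, 1))
  area_seg <- tabulate(seg[seg > 0], nbins = max(seg_all, 0, 1))
  both <- gt_mask > 0 & seg > 0
  matches <- data.frame(gt_id = integer(0), seg_id = integer(0),
                        iou = numeric(0), area_gt_px = numeric(0),
                        area_seg_px = numeric(0), rel_area_error = numeric(0))
  if (any(both)) {
    ov <- as.data.frame(table(gt = gt_mask[both], seg = seg[both]),
                        stringsAsFactors = FALSE)
    ov <- ov[ov$Freq > 0, ]
    ov$gt <- as.integer(ov$gt); ov$seg <- as.integer(ov$seg)
    ov$iou <- ov$Freq / (area_gt[ov$gt] + area_seg[ov$seg] - ov$Freq)
    ov <- ov[order(-ov$iou), ]
    used_gt <- used_seg <- integer(0)
    for (i in seq_len(nrow(ov))) {
      if (ov$iou[i] < iou_threshold) break
      if (ov$gt[i] %in% used_gt || ov$seg[i] %in% used_seg) next
      used_gt <- c(used_gt, ov$gt[i]); used_seg <- c(used_seg, ov$seg[i])
      matches <- rbind(matches, data.frame(
        gt_id = ov$gt[i], seg_id = ov$seg[i], iou = ov$iou[i],
        area_gt_px = area_gt[ov$gt[i]], area_seg_px = area_seg[ov$seg[i]],
        rel_area_error = (area_seg[ov$seg[i]] - area_gt[ov$gt[i]]) /
          area_gt[ov$gt[i]]))
    }
  }
  hit_gt <- sum(matches$gt_id %in% gt_ids)
  hit_seg <- sum(matches$seg_id %in% seg_ids)
  list(recall = if (length(gt_ids)) hit_gt / length(gt_ids) else NA_real_,
       precision = if (length(seg_ids)) hit_seg / length(seg_ids) else NA_real_,
       n_gt = length(gt_ids), n_seg = length(seg_ids), matches = matches)
}
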
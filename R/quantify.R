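# Per-object readouts and per-well aggregates.

#' Measure per-object size and integrated live/dead fluorescence
#'
#' For every segmented object: area in um^2 (pixel count times
#' `pixel_size^2`), background-subtracted integrated CAM (live) and EtH
#' (dead) intensity over the object mask (negatives clamped to 0), and
#' the live/dead ratio `(cam + epsilon) / (eth + epsilon)` with one
#' global pseudocount `epsilon` guarding fully dead objects. The
#' background of each channel is the median over pixels outside all
#' masks, so each image is self-normalizing.
#'
#' @param labelmap A `mos_labelmap` from [segment_brightfield()] (or
#'   [as_labelmap()]).
#' @param cam_image,eth_image Fluorescence matrices co-registered with
#'   the segmented bright-field image (same dimensions).
#' @param epsilon Ratio pseudocount in intensity units (> 0).
#' @param classification Optional precomputed [classify_objects()]
#'   output; computed with defaults when missing.
#' @param well_id Optional well id carried into the output.
#' @return A data.frame of object records: `well_id`, `label`, `class`,
#'   `area_um2`, `circularity`, `centroid_row`, `centroid_col`,
#'   `cam_integrated`, `eth_integrated`, `live_dead_ratio`.
#' @export
measure_objects <- function(labelmap, cam_image, eth_image, epsilon = 0.01,
                            classification = NULL, well_id = NA_character_) {
  stopifnot(inherits(labelmap, "mos_labelmap"))
  lab <- labelmap$labels
  if (!all(dim(lab) == dim(cam_image)) || !all(dim(lab) == dim(eth_image)))
    stop("images must be co-registered with the label map (same shape)",
         call. = FALSE)
  assert_number(epsilon, "epsilon", lower = 1e-12)
  if (is.null(classification)) classification <- classify_objects(labelmap)
  k <- max(lab)
  if (k == 0L)
    return(data.frame(well_id = character(0), label = integer(0),
                      class = character(0), area_um2 = numeric(0),
                      circularity = numeric(0), centroid_row = numeric(0),
                      centroid_col = numeric(0), cam_integrated = numeric(0),
                      eth_integrated = numeric(0),
                      live_dead_ratio = numeric(0), stringsAsFactors = FALSE))
  inside <- lab > 0
  bg_cam <- median(cam_image[!inside])
  bg_eth <- median(eth_image[!inside])
  n_px <- tabulate(lab[inside], nbins = k)
  sum_cam <- as.numeric(rowsum(cam_image[inside], lab[inside]))
  sum_eth <- as.numeric(rowsum(eth_image[inside], lab[inside]))
  cam_int <- pmax(sum_cam - bg_cam * n_px, 0)
  eth_int <- pmax(sum_eth - bg_eth * n_px, 0)
  data.frame(well_id = well_id, label = classification$label,
             class = classification$class,
             area_um2 = classification$area_um2,
             circularity = classification$circularity,
             centroid_row = classification$centroid_row,
             centroid_col = classification$centroid_col,
             cam_integrated = cam_int, eth_integrated = eth_int,
             live_dead_ratio = (cam_int + epsilon) / (eth_int + epsilon),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Aggregate object records into a per-well summary
#'
#' Stroma-classified objects are excluded from both the total surface
#' area (tSA) and the median live/dead ratio: tSA is the sum of
#' tumorsphere areas and `median_ratio` the median over tumorsphere
#' ratios. A well with zero tumorspheres gets `median_ratio = NA` and
#' `flagged = TRUE` so downstream stages can exclude it (an undefined
#' median is flagged, never coerced to zero).
#'
#' @param objects Object-record data.frame for one well
#'   ([measure_objects()] output).
#' @param rlu Raw luminescence for the well (optional).
#' @param well_id Well id (defaults to the one in `objects`).
#' @return One-row data.frame: `well_id`, `n_tumorspheres`, `n_stroma`,
#'   `tsa`, `median_ratio`, `raw_rlu`, `flagged`.
#' @export
summarize_well <- function(objects, rlu = NA_real_, well_id = NULL) {
  if (is.null(well_id))
    well_id <- if (nrow(objects)) objects$well_id[1] else NA_character_
  if (nrow(objects) && length(unique(objects$well_id)) > 1)
    stop("objects must belong to a single well", call. = FALSE)
  tum <- objects[objects$class == "tumorsphere", , drop = FALSE]
  data.frame(well_id = well_id,
             n_tumorspheres = nrow(tum),
             n_stroma = sum(objects$class == "stroma"),
             tsa = sum(tum$area_um2),
             median_ratio = if (nrow(tum)) median(tum$live_dead_ratio)
                            else NA_real_,
             raw_rlu = rlu,
             flagged = nrow(tum) == 0,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @rdname summarize_well
#' @param ctg Optional data.frame with columns `well_id`, `rlu` to join.
#' @param objects_all Object records spanning several wells.
#' @export
summarize_wells <- function(objects_all, ctg = NULL) {
  wells <- unique(objects_all$well_id)
  out <- do.call(rbind, lapply(wells, function(w) {
    rlu <- NA_real_
    if (!is.null(ctg)) {
      i <- match(w, ctg$well_id)
      if (!is.na(i)) rlu <- ctg$rlu[i]
    }
    summarize_well(objects_all[objects_all$well_id == w, , drop = FALSE],
                   rlu = rlu, well_id = w)
  }))
  rownames(out) <- NULL
  out
}
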
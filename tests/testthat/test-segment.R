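test_that("a blank well yields zero objects, not an error", {
  img <- matrix(0.75, 128, 128)
  lm <- segment_brightfield(img, pixel_size = 10)
  expect_identical(max(lm$labels), 0L)
  set.seed(1)
  noisy <- img + rnorm(length(img), 0, 0.01)
  expect_identical(max(segment_brightfield(noisy, pixel_size = 10)$labels), 0L)
})

test_that("noiseless wells are segmented exactly (count, overlap, area)", {
  ws <- rendered_wells(41, n_wells = 2, mos_per_well = 10,
                       stroma = stroma_spec(mean_per_well = 0),
                       noise = FALSE)
  params <- segmentation_params(smoothing_sigma = 0)
  for (x in ws) {
    lm <- segment_brightfield(x$rendered$bf, params, x$imaging$pixel_size)
    expect_identical(max(lm$labels), nrow(x$well$objects))
    ev <- evaluate_segmentation(lm, x$rendered$mask)
    expect_identical(ev$recall, 1)
    expect_true(all(ev$matches$iou >= 0.9))
    expect_true(all(abs(ev$matches$rel_area_error) <= 0.05))
  }
})

test_that("segmentation is deterministic and labels are contiguous", {
  ws <- rendered_wells(43, n_wells = 1)
  bf <- ws[[1]]$rendered$bf
  l1 <- segment_brightfield(bf, pixel_size = 10)
  l2 <- segment_brightfield(bf, pixel_size = 10)
  expect_identical(l1$labels, l2$labels)
  u <- sort(unique(as.vector(l1$labels)))
  expect_identical(u, 0:max(l1$labels))
})

test_that("raising min_area never increases the object count", {
  ws <- rendered_wells(47, n_wells = 1)
  bf <- ws[[1]]$rendered$bf
  counts <- vapply(c(200, 2000, 8000, 30000), function(a)
    max(segment_brightfield(bf, segmentation_params(min_area = a),
                            10)$labels), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("external label maps plug in through the same contract", {
  lab <- matrix(0L, 64, 64)
  lab[10:20, 10:20] <- 7L  # non-contiguous labels get renumbered
  lab[40:50, 40:50] <- 3L
  lm <- as_labelmap(lab, pixel_size = 5)
  expect_identical(sort(unique(as.vector(lm$labels))), 0:2)
  cls <- classify_objects(lm)
  expect_identical(nrow(cls), 2L)
})

test_that("round objects above the size cutoff are called tumorspheres", {
  lab <- matrix(0L, 128, 128)
  idx <- which((row(lab) - 60)^2 + (col(lab) - 60)^2 <= 12^2)
  lab[idx] <- 1L
  cls <- classify_objects(as_labelmap(lab, pixel_size = 10))
  expect_identical(cls$class, "tumorsphere")
  expect_gt(cls$circularity, 0.8)
})

test_that("tumorspheres and stroma are classified correctly on noisy wells", {
  n_tum_called <- n_tum <- n_str_called <- n_str <- 0
  for (s in 1:4) {
    ws <- rendered_wells(100 + s, n_wells = 2, mos_per_well = 10,
                         stroma = stroma_spec(mean_per_well = 10))
    for (x in ws) {
      lm <- segment_brightfield(x$rendered$bf, pixel_size =
                                  x$imaging$pixel_size)
      cls <- classify_objects(lm)
      gt_tum <- x$well$objects$id[x$well$objects$type == "tumorsphere"]
      gt_str <- x$well$objects$id[x$well$objects$type == "stroma"]
      ev_t <- evaluate_segmentation(lm, x$rendered$mask, gt_ids = gt_tum)
      mt <- ev_t$matches[ev_t$matches$gt_id %in% gt_tum, ]
      n_tum <- n_tum + nrow(mt)
      n_tum_called <- n_tum_called +
        sum(cls$class[match(mt$seg_id, cls$label)] == "tumorsphere")
      ev_s <- evaluate_segmentation(lm, x$rendered$mask, gt_ids = gt_str,
                                    iou_threshold = 0.3)
      ms <- ev_s$matches[ev_s$matches$gt_id %in% gt_str, ]
      n_str <- n_str + nrow(ms)
      n_str_called <- n_str_called +
        sum(cls$class[match(ms$seg_id, cls$label)] == "stroma")
    }
  }
  expect_gte(n_tum_called / n_tum, 0.95)
  expect_gte(n_str_called / max(n_str, 1), 0.9)
  expect_gt(n_str, 10) # enough detected stroma for the rate to mean much
})
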
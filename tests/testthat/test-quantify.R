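make_measured_well <- function(viable, dead, seed = 1, noise = FALSE) {
  im <- small_imaging(noise_sd = if (noise) 0.01 else 0,
                      psf_sigma = if (noise) 1 else 0)
  n <- length(viable)
  w <- list(well_id = "W01", objects = data.frame(
    id = seq_len(n), type = "tumorsphere",
    cx_px = seq(60, 200, length.out = n), cy_px = rep(128, n),
    r0_um = 80, r1_um = 80, viable0 = viable, dead0 = dead,
    viable1 = viable, dead1 = dead, resistant = FALSE, growth_rate = 0,
    stringsAsFactors = FALSE))
  r <- render_well(w, im, "endpoint", seed = seed)
  list(well = w, rendered = r, imaging = im,
       labelmap = as_labelmap(r$mask, im$pixel_size))
}

test_that("noiseless quantification recovers generator intensities exactly", {
  x <- make_measured_well(viable = c(600, 1500), dead = c(30, 75))
  ob <- measure_objects(x$labelmap, x$rendered$cam, x$rendered$eth,
                        well_id = "W01")
  expect_equal(ob$cam_integrated,
               x$imaging$kappa_live * x$well$objects$viable1,
               tolerance = 1e-9)
  expect_equal(ob$eth_integrated,
               x$imaging$kappa_dead * x$well$objects$dead1,
               tolerance = 1e-9)
})

test_that("equal live and dead signal gives a live/dead ratio of 1", {
  x <- make_measured_well(viable = c(800, 800), dead = c(800, 800))
  ob <- measure_objects(x$labelmap, x$rendered$cam, x$rendered$eth)
  expect_equal(ob$live_dead_ratio, rep(1, 2), tolerance = 1e-8)
})

test_that("shape mismatch between channels is a validation error", {
  x <- make_measured_well(viable = 500, dead = 25)
  expect_error(measure_objects(x$labelmap, x$rendered$cam[-1, ],
                               x$rendered$eth), "co-registered")
})

test_that("ratios are invariant to rescaling both fluorescence channels", {
  x <- make_measured_well(viable = c(600, 1500), dead = c(30, 75),
                          noise = TRUE)
  ob1 <- measure_objects(x$labelmap, x$rendered$cam, x$rendered$eth)
  ob2 <- measure_objects(x$labelmap, 0.5 * x$rendered$cam,
                         0.5 * x$rendered$eth)
  expect_equal(ob2$live_dead_ratio, ob1$live_dead_ratio, tolerance = 0.01)
})

test_that("well summaries exclude stroma and flag empty wells", {
  ob <- data.frame(well_id = "A01", label = 1:4,
                   class = c("tumorsphere", "tumorsphere", "stroma", "stroma"),
                   area_um2 = c(5000, 7000, 900, 1200),
                   live_dead_ratio = c(10, 20, 99, 99),
                   stringsAsFactors = FALSE)
  s <- summarize_well(ob, rlu = 1e5)
  expect_identical(s$tsa, 12000)
  expect_identical(s$median_ratio, 15)
  expect_identical(s$n_stroma, 2L)
  expect_false(s$flagged)
  # adding arbitrary stroma changes neither tSA nor the median ratio
  extra <- ob[3, ]; extra$label <- 9L; extra$area_um2 <- 1e6
  s2 <- summarize_well(rbind(ob, extra), rlu = 1e5)
  expect_identical(s2$tsa, s$tsa)
  expect_identical(s2$median_ratio, s$median_ratio)
  # tSA is additive over any partition of the tumorsphere objects
  s_a <- summarize_well(ob[1, , drop = FALSE])
  s_b <- summarize_well(ob[2, , drop = FALSE])
  expect_identical(s_a$tsa + s_b$tsa, s$tsa)

  all_str <- ob[ob$class == "stroma", ]
  s3 <- summarize_well(all_str, rlu = 5)
  expect_identical(s3$tsa, 0)
  expect_true(is.na(s3$median_ratio))
  expect_true(s3$flagged)
})

test_that("cytostatic treatment leaves the ratio distribution unchanged", {
  # two-sample check over seeds: treated vs vehicle ratios indistinguishable
  n_sig <- 0
  for (s in 1:5) {
    st <- fast_study(seed = 300 + s, n_replicates = 3)
    ob <- st$objects[st$objects$drug == "statB" &
                     st$objects$type == "tumorsphere", ]
    top <- max(ob$dose)
    p <- ks.test(ob$live_dead_ratio[ob$dose == top],
                 ob$live_dead_ratio[ob$dose == 0])$p.value
    n_sig <- n_sig + (p < 0.01)
  }
  expect_lte(n_sig, 1)
})
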
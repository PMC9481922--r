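p4 <- function(d, lower, upper, ec50, hill)
  lower + (upper - lower) / (1 + (d / ec50)^hill)

test_that("an exact 4PL is recovered to four significant figures", {
  d <- rep(10^seq(-3, 1, length.out = 9), each = 2)
  truth <- list(lower = 0.08, upper = 1.02, ec50 = 0.05, hill = 1.7)
  y <- p4(d, truth$lower, truth$upper, truth$ec50, truth$hill)
  f <- fit_curve(d, y)
  expect_false(f$flagged)
  for (nm in names(truth))
    expect_equal(f[[nm]], truth[[nm]], tolerance = 1e-4)
  expect_gt(f$r_squared, 0.99999)
})

test_that("refitting a fit's own predictions is idempotent", {
  d <- rep(10^seq(-2, 2, length.out = 7), each = 3)
  set.seed(6)
  f1 <- fit_curve(d, p4(d, 0.1, 1, 1.3, 1.1) + rnorm(length(d), 0, 0.04))
  f2 <- fit_curve(d, predict(f1, d))
  expect_equal(f2$ec50, f1$ec50, tolerance = 1e-4)
  expect_equal(f2$hill, f1$hill, tolerance = 1e-4)
})

test_that("monotone-increasing responses fall back to a flagged flat fit", {
  d <- rep(10^seq(-2, 2, length.out = 5), each = 2)
  y <- 0.5 + 0.4 * (log10(d) + 2) / 4
  f <- fit_curve(d, y)
  expect_true(f$flagged)
  expect_equal(predict(f, d), rep(mean(y), length(d)))
})

test_that("fit preconditions are enforced", {
  expect_error(fit_curve(c(1, 2, 3), c(1, 1, 1)), "4 distinct")
  expect_error(fit_curve(c(0, 1, 2, 3, 4), rep(1, 5)), "positive")
})

test_that("AUC convention: flat curves hit the bounds, step is ~0.5", {
  d <- 10^seq(-2, 2, length.out = 9)
  expect_equal(compute_auc(d, rep(1, 9)), 1)
  expect_equal(compute_auc(d, rep(0, 9)), 0)
  expect_equal(compute_auc(d, rep(2, 9)), 1) # clipped to [0, 1]
  # step curve: hand-computed trapezoid (one transition panel)
  y <- c(rep(1, 4), rep(0, 5))
  expect_equal(compute_auc(d, y), (3 + 0.5) / 8)
  expect_error(compute_auc(1, 1), "single dose")
})

test_that("AUC equals a fine-grid Riemann sum of the interpolant", {
  set.seed(7)
  d <- 10^seq(-3, 1, length.out = 7)
  y <- pmin(pmax(runif(7), 0), 1)
  x <- log10(d)
  grid <- seq(min(x), max(x), length.out = 2e5 + 1)
  riemann <- mean(approx(x, y, xout = grid)$y[-1] +
                  approx(x, y, xout = grid)$y[-length(grid)]) / 2
  expect_equal(compute_auc(d, y), riemann, tolerance = 1e-9)
})

test_that("AUC is pointwise monotone in the per-dose means", {
  d <- 10^seq(-2, 2, length.out = 6)
  y <- c(1, 0.9, 0.7, 0.5, 0.3, 0.2)
  a1 <- compute_auc(d, y)
  y2 <- y; y2[3] <- 0.5
  expect_lt(compute_auc(d, y2), a1)
})

test_that("curve builders produce the two parallel readouts", {
  st <- fast_study(seed = 51, n_replicates = 3)
  norm <- adjust_ctg(st$wells, st$wells0, st$layout)
  cc <- ctg_curve(norm, "toxA")
  rc <- ratio_curve(st$wells, st$layout, "toxA")
  expect_s3_class(cc, "mos_drc")
  expect_true(cc$auc >= 0 && cc$auc <= 1)
  expect_true(rc$auc >= 0 && rc$auc <= 1)
  # cytotoxic arm: both readouts decline and agree
  expect_lt(cc$auc, 0.75)
  expect_lt(abs(rc$auc - cc$auc), 0.2)
  # cytostatic arm: ratio readout stays flat while CTG declines
  cc2 <- ctg_curve(norm, "statB")
  rc2 <- ratio_curve(st$wells, st$layout, "statB")
  expect_gt(rc2$auc - cc2$auc, 0.2)
})

test_that("vehicle-only input yields a flat no-effect curve", {
  wells <- data.frame(well_id = c("A01", "A02"), n_tumorspheres = c(5L, 6L),
                      n_stroma = 0L, tsa = c(1e5, 1.2e5),
                      median_ratio = c(18, 21), raw_rlu = NA_real_,
                      flagged = FALSE, stringsAsFactors = FALSE)
  lay <- data.frame(well_id = c("A01", "A02"), drug = "d", dose = 0,
                    stringsAsFactors = FALSE)
  rc <- ratio_curve(wells, lay, "d")
  expect_equal(rc$auc, 1)
  expect_null(rc$fit)
})

test_that("ratio_curve drops flagged wells and empty doses with a message", {
  wells <- data.frame(well_id = sprintf("A%02d", 1:6),
                      n_tumorspheres = c(3L, 3L, 0L, 0L, 3L, 3L),
                      n_stroma = 0L, tsa = 1e5,
                      median_ratio = c(20, 19, NA, NA, 10, 2),
                      raw_rlu = NA_real_,
                      flagged = c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE),
                      stringsAsFactors = FALSE)
  lay <- data.frame(well_id = wells$well_id, drug = "d",
                    dose = c(0, 0, 0.1, 0.1, 1, 10), stringsAsFactors = FALSE)
  expect_message(rc <- ratio_curve(wells, lay, "d"), "dropping dose")
  expect_identical(nrow(rc$per_dose), 2L)
})
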
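mini_layout <- function(n_rep = 3) {
  plate_layout("d", doses = c(0.1, 1, 10), n_replicates = n_rep,
               n_vehicle = n_rep)
}

mini_wells <- function(layout, rlu, tsa) {
  list(endpoint = data.frame(well_id = layout$well_id, raw_rlu = rlu,
                             stringsAsFactors = FALSE),
       day0 = data.frame(well_id = layout$well_id, tsa = tsa,
                         flagged = FALSE, stringsAsFactors = FALSE))
}

test_that("a constant day-0 tSA cancels: adjusted equals raw scaling", {
  lay <- mini_layout()
  set.seed(2)
  w <- mini_wells(lay, rlu = rlnorm(nrow(lay), 10, 0.3),
                  tsa = rep(5e5, nrow(lay)))
  norm <- adjust_ctg(w$endpoint, w$day0, lay)
  expect_equal(norm$rel_viability, norm$rel_raw)
  # vehicle mean is exactly 1 by construction
  expect_equal(mean(norm$rel_viability[norm$dose == 0]), 1)
})

test_that("a double-seeded replicate is corrected by its day-0 tSA", {
  lay <- mini_layout()
  base_rlu <- rep(1e5, nrow(lay)); base_tsa <- rep(4e5, nrow(lay))
  i <- which(lay$dose == 0.1)[1] # one replicate got 2x the MOSs
  base_rlu[i] <- 2e5; base_tsa[i] <- 8e5
  w <- mini_wells(lay, base_rlu, base_tsa)
  norm <- adjust_ctg(w$endpoint, w$day0, lay)
  at_dose <- norm[norm$dose == 0.1, ]
  expect_gt(max(at_dose$rel_raw) / min(at_dose$rel_raw), 1.9)
  expect_equal(max(at_dose$rel_viability), min(at_dose$rel_viability))
})

test_that("adjusted viability is invariant to luminometer gain", {
  lay <- mini_layout()
  set.seed(3)
  rlu <- rlnorm(nrow(lay), 10, 0.2); tsa <- rlnorm(nrow(lay), 13, 0.2)
  w1 <- mini_wells(lay, rlu, tsa)
  w2 <- mini_wells(lay, 7.3 * rlu, tsa)
  expect_equal(adjust_ctg(w1$endpoint, w1$day0, lay)$rel_viability,
               adjust_ctg(w2$endpoint, w2$day0, lay)$rel_viability)
})

test_that("wells without usable day-0 records are excluded with reasons", {
  lay <- mini_layout()
  set.seed(4)
  w <- mini_wells(lay, rlnorm(nrow(lay), 10, 0.2), rep(4e5, nrow(lay)))
  w$day0$tsa[3] <- 0
  w$day0 <- w$day0[-5, ] # missing imaging record
  norm <- adjust_ctg(w$endpoint, w$day0, lay)
  excl <- attr(norm, "excluded")
  expect_identical(nrow(excl), 2L)
  expect_setequal(excl$well_id, lay$well_id[c(3, 5)])
  expect_false(any(excl$well_id %in% norm$well_id))
})

test_that("identical before/after values give zero deltas and p = 1", {
  lay <- mini_layout()
  set.seed(5)
  w <- mini_wells(lay, rlnorm(nrow(lay), 10, 0.3), rep(1, nrow(lay)))
  norm <- adjust_ctg(w$endpoint, w$day0, lay)
  vr <- variance_report(norm)
  expect_equal(vr$ss_before, vr$ss_after)
  expect_identical(vr$t_test_p, 1)
})

test_that("tSA normalization shrinks replicate scatter under plating noise", {
  dec <- logical(3)
  for (s in seq_along(dec)) {
    st <- fast_study(seed = 400 + s, n_replicates = 3)
    vr <- variance_report(adjust_ctg(st$wells, st$wells0, st$layout))
    dec[s] <- vr$ss_after < vr$ss_before
  }
  expect_true(all(dec))
})

test_that("with no plating variation normalization is neutral", {
  lay <- plate_layout("toxA", doses = 10^seq(-3, 0, length.out = 7),
                      n_replicates = 3, n_vehicle = 3)
  ratios <- vapply(1:3, function(s) {
    pl <- simulate_plate(lay, study_models(),
                         growth = growth_spec(radius_sdlog = 0, rate_cv = 0),
                         mos_per_well = 20, plating_cv = 0, seed = 500 + s)
    ws1 <- summarize_wells(simulate_object_records(pl), simulate_ctg(pl))
    ws0 <- summarize_wells(simulate_object_records(pl, "day0"))
    vr <- variance_report(adjust_ctg(ws1, ws0, lay))
    vr$ss_after / vr$ss_before
  }, 0)
  expect_gt(mean(ratios), 0.5)
  expect_lt(mean(ratios), 2)
})
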
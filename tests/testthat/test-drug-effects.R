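make_spheres <- function(n = 10, viable = 1000, seed = 1) {
  set.seed(seed)
  data.frame(id = seq_len(n), type = "tumorsphere",
             radius_um = rep(80, n), viable_cells = rep(viable, n),
             dead_cells = rep(0.05 * viable, n),
             resistant = rep(FALSE, n), growth_rate = rep(0.4, n),
             stringsAsFactors = FALSE)
}

test_that("Hill fraction is zero at dose 0 and monotone nondecreasing", {
  set.seed(4)
  for (i in 1:20) {
    m <- drug_effect_model("cytotoxic", ec50 = 10^runif(1, -2, 2),
                           hill = runif(1, 0.3, 4),
                           max_effect = runif(1, 0.2, 1))
    d <- sort(c(0, 10^runif(9, -3, 3)))
    f <- hill_fraction(m, d)
    expect_identical(f[1], 0)
    expect_true(all(diff(f) >= 0))
    expect_true(all(f <= m$max_effect + 1e-12))
  }
})

test_that("dose 0 leaves objects unchanged under every mechanism", {
  sp <- make_spheres()
  for (mech in c("cytotoxic", "cytostatic", "inactive")) {
    m <- drug_effect_model(mech, ec50 = 1)
    expect_identical(apply_drug_effect(m, 0, sp, duration_days = 0), sp)
  }
})

test_that("cytotoxic Hill midpoint converts half the viable cells", {
  sp <- make_spheres(viable = 1000)
  m <- drug_effect_model("cytotoxic", ec50 = 2, hill = 1, max_effect = 1)
  out <- apply_drug_effect(m, 2, sp, duration_days = 0)
  expect_equal(out$dead_cells - sp$dead_cells, rep(500, nrow(sp)))
  expect_equal(out$viable_cells, rep(500, nrow(sp)))
  # constant-density body: radius shrinks with cube root of viable fraction
  expect_equal(out$radius_um, sp$radius_um * 0.5^(1 / 3))
})

test_that("cytostatic saturating dose preserves composition, reduces size", {
  sp <- make_spheres()
  m <- drug_effect_model("cytostatic", ec50 = 0.01, hill = 2,
                         max_effect = 0.9)
  veh <- apply_drug_effect(m, 0, sp, duration_days = 3)
  trt <- apply_drug_effect(m, 1000, sp, duration_days = 3)
  expect_equal(trt$viable_cells / trt$dead_cells,
               veh$viable_cells / veh$dead_cells)
  expect_true(all(trt$radius_um < veh$radius_um))
  expect_true(all(trt$radius_um > sp$radius_um)) # residual growth
})

test_that("cytotoxic at saturating dose drives live/dead ratio toward 0", {
  sp <- make_spheres()
  m <- drug_effect_model("cytotoxic", ec50 = 0.01, hill = 2, max_effect = 1)
  trt <- apply_drug_effect(m, 1000, sp, duration_days = 3)
  expect_true(all(trt$viable_cells / trt$dead_cells < 0.01))
  expect_true(all(trt$dead_cells > 0)) # still EtH-stainable
})

test_that("dead clearance removes most killed cells from the stainable pool", {
  sp <- make_spheres(viable = 1000)
  m <- drug_effect_model("cytotoxic", ec50 = 2, hill = 1, max_effect = 1)
  out <- apply_drug_effect(m, 2, sp, duration_days = 0, dead_clearance = 0.95)
  expect_equal(out$dead_cells - sp$dead_cells, rep(0.05 * 500, nrow(sp)))
})

test_that("resistant spheres follow the vehicle trajectory exactly", {
  sp <- make_spheres()
  sp$resistant[c(2, 5)] <- TRUE
  for (mech in c("cytotoxic", "cytostatic")) {
    m <- drug_effect_model(mech, ec50 = 0.1, resistant_fraction = 0.2)
    veh <- apply_drug_effect(m, 0, sp, duration_days = 3)
    trt <- apply_drug_effect(m, 100, sp, duration_days = 3)
    expect_identical(trt[c(2, 5), ], veh[c(2, 5), ])
    expect_false(isTRUE(all.equal(trt$viable_cells[1], veh$viable_cells[1])))
  }
})

test_that("stroma objects are untouched by drug effects", {
  sp <- make_spheres()
  sp$type[1:3] <- "stroma"
  m <- drug_effect_model("cytotoxic", ec50 = 0.1, max_effect = 1)
  out <- apply_drug_effect(m, 100, sp, duration_days = 3)
  expect_identical(out[1:3, ], sp[1:3, ])
})
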
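# Whole-plate simulation: per-well ground truth at day 0 and endpoint.

# Exact pixel count of the digital disk {(x-cx)^2 + (y-cy)^2 <= r^2}.
disk_pixel_count <- function(cx, cy, r) {
  xs <- seq(floor(cx - r), ceiling(cx + r))
  n <- 0L
  for (x in xs) {
    dy2 <- r^2 - (x - cx)^2
    if (dy2 >= 0) {
      s <- sqrt(dy2)
      n <- n + (floor(cy + s) - ceiling(cy - s) + 1)
    }
  }
  as.integer(n)
}

# Rejection-sample non-overlapping object centers. Objects are placed
# largest-first with at least one object-radius clearance between rims;
# fails (error) after `max_tries` rejections for any single object.
place_objects <- function(radii_px, height, width, margin = 4,
                          max_tries = 2000) {
  k <- length(radii_px)
  ord <- order(radii_px, decreasing = TRUE)
  cx <- cy <- numeric(k)
  for (j in seq_len(k)) {
    i <- ord[j]
    r <- radii_px[i]
    lo_x <- r + margin; hi_x <- width - r - margin
    lo_y <- r + margin; hi_y <- height - r - margin
    if (hi_x <= lo_x || hi_y <= lo_y)
      stop("object too large for the image", call. = FALSE)
    placed <- ord[seq_len(j - 1L)]
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      x <- runif(1, lo_x, hi_x)
      y <- runif(1, lo_y, hi_y)
      if (j == 1L) { ok <- TRUE } else {
        dmin <- radii_px[placed] + r + pmax(radii_px[placed], r)
        ok <- all((cx[placed] - x)^2 + (cy[placed] - y)^2 >= dmin^2)
      }
      if (ok) { cx[i] <- x; cy[i] <- y; break }
    }
    if (!ok) stop(sprintf(
      "could not place object %d of %d after %d tries; reduce object count or size",
      j, k, max_tries), call. = FALSE)
  }
  data.frame(cx_px = cx, cy_px = cy)
}

# Ground truth for one well: day-0 and endpoint object states plus
# placement. Internal; use simulate_plate().
simulate_well <- function(well_id, drug_model, dose, n_mos,
                          growth = growth_spec(), imaging = imaging_spec(),
                          stroma = stroma_spec(), seed = NULL) {
  with_seed(seed, {
    r0 <- pmax(growth$radius_min,
               rlnorm(n_mos, growth$radius_meanlog, growth$radius_sdlog))
    viable0 <- growth$cells_per_um3 * (4 / 3) * pi * r0^3
    dead0 <- growth$baseline_dead_frac * viable0
    rate <- growth$rate_per_day * rlnorm_cv(n_mos, growth$rate_cv)
    resistant <- runif(n_mos) < drug_model$resistant_fraction

    n_s <- rpois(1, stroma$mean_per_well)
    rs <- runif(n_s, stroma$radius_range[1], stroma$radius_range[2])
    cs <- sample(seq(stroma$cells_range[1], stroma$cells_range[2]),
                 n_s, replace = TRUE)

    day0 <- data.frame(
      id = seq_len(n_mos + n_s),
      type = rep(c("tumorsphere", "stroma"), c(n_mos, n_s)),
      radius_um = c(r0, rs),
      viable_cells = c(viable0, as.numeric(cs)),
      dead_cells = c(dead0, rep(0, n_s)),
      resistant = c(resistant, rep(FALSE, n_s)),
      growth_rate = c(rate, rep(0, n_s)),
      stringsAsFactors = FALSE)

    endpoint <- apply_drug_effect(drug_model, dose, day0,
                                  duration_days = growth$duration_days,
                                  dead_clearance = growth$dead_clearance)

    r_place <- pmax(day0$radius_um, endpoint$radius_um) / imaging$pixel_size
    pos <- place_objects(r_place, imaging$image_size[1], imaging$image_size[2])

    objects <- data.frame(
      id = day0$id, type = day0$type,
      cx_px = pos$cx_px, cy_px = pos$cy_px,
      r0_um = day0$radius_um, r1_um = endpoint$radius_um,
      viable0 = day0$viable_cells, dead0 = day0$dead_cells,
      viable1 = endpoint$viable_cells, dead1 = endpoint$dead_cells,
      resistant = day0$resistant, growth_rate = day0$growth_rate,
      stringsAsFactors = FALSE)

    tum <- objects$type == "tumorsphere"
    px_area <- imaging$pixel_size^2
    tsa0 <- sum(vapply(which(tum), function(i) disk_pixel_count(
      objects$cx_px[i], objects$cy_px[i],
      objects$r0_um[i] / imaging$pixel_size), 0L)) * px_area
    tsa1 <- sum(vapply(which(tum), function(i) disk_pixel_count(
      objects$cx_px[i], objects$cy_px[i],
      objects$r1_um[i] / imaging$pixel_size), 0L)) * px_area

    list(well_id = well_id, drug = drug_model$mechanism, dose = dose,
         n_mos = n_mos, objects = objects,
         true_tsa0 = tsa0, true_tsa1 = tsa1,
         true_viable0 = sum(objects$viable0),
         true_viable1 = sum(objects$viable1))
  })
}

#' Simulate a full MOS plate with ground truth
#'
#' Generates every well of `layout`: the number of dispensed MOSs per well
#' varies around `mos_per_well` with lognormal CV `plating_cv` (plating
#' variation), day-0 sphere sizes are heterogeneous, stroma single cells
#' are added, and each well's spheres are advanced to the assay endpoint
#' under the drug model named in the layout. Per-well RNG substreams are
#' derived from `(seed, well_id)`, so results do not depend on well order.
#'
#' @param layout A [plate_layout()] data.frame.
#' @param models Named list of [drug_effect_model()]s, one per drug name
#'   appearing in `layout`.
#' @param growth A [growth_spec()].
#' @param imaging An [imaging_spec()].
#' @param stroma A [stroma_spec()].
#' @param mos_per_well Target MOSs dispensed per well.
#' @param plating_cv Between-well CV of the dispensed MOS count.
#' @param seed Integer base seed.
#' @return An object of class `mos_plate`: list with `layout`, `wells`
#'   (named list of per-well ground truth), and the parameter blocks.
#' @export
#' @examples
#' lay <- plate_layout("drugA", doses = c(0.01, 0.1, 1), n_replicates = 2,
#'                     n_vehicle = 2)
#' pl <- simulate_plate(lay, list(drugA = drug_effect_model("cytotoxic",
#'                      ec50 = 0.1)), mos_per_well = 5, seed = 1)
#' names(pl$wells)
simulate_plate <- function(layout, models, growth = growth_spec(),
                           imaging = imaging_spec(), stroma = stroma_spec(),
                           mos_per_well = 20, plating_cv = 0.3, seed = 1) {
  stopifnot(is.data.frame(layout),
            all(c("well_id", "drug", "dose") %in% names(layout)))
  missing <- setdiff(unique(layout$drug), names(models))
  if (length(missing))
    stop("no drug model for: ", paste(missing, collapse = ", "), call. = FALSE)
  wells <- vector("list", nrow(layout))
  names(wells) <- layout$well_id
  for (i in seq_len(nrow(layout))) {
    wid <- layout$well_id[i]
    ws <- derive_seed(seed, layout$plate_id[i] %||% "P1", wid)
    n_mos <- with_seed(derive_seed(ws, "plating"),
                       max(3L, as.integer(round(mos_per_well *
                                                rlnorm_cv(1, plating_cv)))))
    wells[[wid]] <- simulate_well(wid, models[[layout$drug[i]]],
                                  layout$dose[i], n_mos, growth = growth,
                                  imaging = imaging, stroma = stroma,
                                  seed = derive_seed(ws, "well"))
  }
  structure(list(layout = layout, wells = wells, models = models,
                 growth = growth, imaging = imaging, stroma = stroma,
                 mos_per_well = mos_per_well, plating_cv = plating_cv,
                 seed = seed),
            class = "mos_plate")
}

#' @export
print.mos_plate <- function(x, ...) {
  cat(sprintf("Synthetic MOS plate: %d wells, %d drug(s), seed %d\n",
              nrow(x$layout), length(unique(x$layout$drug)), x$seed))
  invisible(x)
}

#' Simulate CellTiter-Glo luminescence for a plate
#'
#' Bulk viability readout: `RLU = gain * sum(viable cells in well)` times
#' multiplicative lognormal noise with CV `noise_cv` (mean 1). Stroma
#' cells contribute to the sum, which is exactly why the bulk readout can
#' be confounded in stroma-rich wells.
#'
#' @param plate A `mos_plate` from [simulate_plate()].
#' @param timepoint `"endpoint"` or `"day0"`.
#' @param gain RLU per viable cell (> 0).
#' @param noise_cv CV of multiplicative lognormal noise (>= 0).
#' @param seed Optional integer seed; defaults to a substream of the
#'   plate's own seed.
#' @return A data.frame with columns `well_id`, `timepoint`, `rlu`.
#' @export
simulate_ctg <- function(plate, timepoint = c("endpoint", "day0"),
                         gain = 50, noise_cv = 0.1, seed = NULL) {
  stopifnot(inherits(plate, "mos_plate"))
  timepoint <- match.arg(timepoint)
  assert_number(gain, "gain", lower = 1e-12)
  assert_number(noise_cv, "noise_cv", lower = 0)
  seed <- seed %||% derive_seed(plate$seed, "ctg", timepoint)
  mass <- vapply(plate$wells, function(w)
    if (timepoint == "endpoint") w$true_viable1 else w$true_viable0, 0)
  with_seed(seed, {
    rlu <- gain * mass * rlnorm_cv(length(mass), noise_cv)
    data.frame(well_id = names(plate$wells), timepoint = timepoint,
               rlu = as.numeric(rlu), row.names = NULL,
               stringsAsFactors = FALSE)
  })
}

#' Measurement-level object records straight from ground truth
#'
#' Produces the same per-object records that [measure_objects()] extracts
#' from rendered images, but directly from the simulator's ground truth
#' with a simple multiplicative measurement-noise model. This bypasses
#' rendering and segmentation, and is intended for statistical studies
#' (mechanism-recovery, resistant-clone and normalization calibrations)
#' where imaging fidelity is tested elsewhere.
#'
#' @param plate A `mos_plate`.
#' @param timepoint `"endpoint"` or `"day0"`.
#' @param meas_cv CV of the multiplicative noise on integrated channel
#'   intensities.
#' @param area_cv CV of the multiplicative noise on measured areas.
#' @param epsilon Pseudocount added to both channels in the live/dead
#'   ratio (same convention as [measure_objects()]).
#' @param seed Optional integer seed; defaults to a substream of the
#'   plate's seed.
#' @return A data.frame of object records with truth columns (`type`,
#'   `resistant`) retained for evaluation, plus `drug` and `dose` joined
#'   from the layout.
#' @export
simulate_object_records <- function(plate, timepoint = c("endpoint", "day0"),
                                    meas_cv = 0.05, area_cv = 0.03,
                                    epsilon = 0.01, seed = NULL) {
  stopifnot(inherits(plate, "mos_plate"))
  timepoint <- match.arg(timepoint)
  seed <- seed %||% derive_seed(plate$seed, "records", timepoint)
  im <- plate$imaging
  recs <- with_seed(seed, lapply(plate$wells, function(w) {
    ob <- w$objects
    n <- nrow(ob)
    viable <- if (timepoint == "endpoint") ob$viable1 else ob$viable0
    dead <- if (timepoint == "endpoint") ob$dead1 else ob$dead0
    r_um <- if (timepoint == "endpoint") ob$r1_um else ob$r0_um
    cam <- im$kappa_live * viable * rlnorm_cv(n, meas_cv)
    eth <- im$kappa_dead * dead * rlnorm_cv(n, meas_cv)
    data.frame(well_id = w$well_id, label = ob$id, class = ob$type,
               area_um2 = pi * r_um^2 * rlnorm_cv(n, area_cv),
               cam_integrated = cam, eth_integrated = eth,
               live_dead_ratio = (cam + epsilon) / (eth + epsilon),
               type = ob$type, resistant = ob$resistant,
               stringsAsFactors = FALSE)
  }))
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  idx <- match(out$well_id, plate$layout$well_id)
  out$drug <- plate$layout$drug[idx]
  out$dose <- plate$layout$dose[idx]
  out
}
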
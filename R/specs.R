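# Constructors for the simulator's parameter blocks. Each returns a
# validated classed list so downstream code can trust the invariants.

#' Droplet encapsulation parameters
#'
#' Describes one generator run: the volume of the gel-cell mixture, the
#' droplet diameter, the mean Poisson cell occupancy per droplet, and the
#' probability that a seeded cell establishes a tumorsphere. Droplet
#' diameters are restricted to the 200-500 um operating range of the
#' droplet generator.
#'
#' @param gel_volume Gel-cell mixture volume in uL (> 0).
#' @param droplet_diameter Droplet diameter in um, in `[200, 500]`.
#' @param cells_per_droplet Mean cells per droplet (Poisson lambda, >= 0).
#' @param establishment_prob Probability a seeded cell forms a tumorsphere.
#' @return An object of class `mos_encapsulation_spec`.
#' @export
#' @examples
#' encapsulation_spec(gel_volume = 500, droplet_diameter = 300)
encapsulation_spec <- function(gel_volume = 500, droplet_diameter = 300,
                               cells_per_droplet = 5,
                               establishment_prob = 0.3) {
  assert_number(gel_volume, "gel_volume", lower = 1e-12)
  assert_number(droplet_diameter, "droplet_diameter", lower = 200, upper = 500)
  assert_number(cells_per_droplet, "cells_per_droplet", lower = 0)
  assert_number(establishment_prob, "establishment_prob", lower = 0, upper = 1)
  structure(list(gel_volume = gel_volume,
                 droplet_diameter = droplet_diameter,
                 cells_per_droplet = cells_per_droplet,
                 establishment_prob = establishment_prob),
            class = "mos_encapsulation_spec")
}

#' @export
print.mos_encapsulation_spec <- function(x, ...) {
  cat(sprintf(
    "MOS encapsulation: %g uL gel, %g um droplets, lambda = %g cells/droplet, P(establish) = %g\n",
    x$gel_volume, x$droplet_diameter, x$cells_per_droplet,
    x$establishment_prob))
  invisible(x)
}

#' Drug-effect model for the simulator
#'
#' The generative ground truth for a drug arm. The effect fraction at dose
#' d is the Hill curve `f(d) = max_effect * d^hill / (d^hill + ec50^hill)`.
#' A `cytotoxic` drug converts a fraction `f` of each sensitive sphere's
#' viable cells to dead cells (the sphere radius shrinking with the
#' cube root of the surviving viable fraction, i.e. treating spheres as
#' constant-density 3D bodies); a `cytostatic` drug multiplies the growth
#' rate by `1 - f` leaving the viable/dead composition unchanged;
#' `inactive` leaves spheres untouched. A fraction `resistant_fraction`
#' of spheres is insensitive and receives zero effect at every dose.
#'
#' @param mechanism One of `"cytotoxic"`, `"cytostatic"`, `"inactive"`.
#' @param ec50 Dose of half-maximal effect (> 0), in plate dose units.
#' @param hill Hill slope (> 0).
#' @param max_effect Maximal effect fraction in `[0, 1]`.
#' @param resistant_fraction Fraction of insensitive spheres in `[0, 1]`.
#' @return An object of class `mos_drug_model`.
#' @export
#' @examples
#' drug_effect_model("cytotoxic", ec50 = 0.03, hill = 1.5, max_effect = 0.95)
drug_effect_model <- function(mechanism = c("cytotoxic", "cytostatic",
                                            "inactive"),
                              ec50 = 1, hill = 1, max_effect = 1,
                              resistant_fraction = 0) {
  mechanism <- match.arg(mechanism)
  assert_number(ec50, "ec50", lower = 1e-300, allow_zero = FALSE)
  assert_number(hill, "hill", lower = 1e-12)
  assert_number(max_effect, "max_effect", lower = 0, upper = 1)
  assert_number(resistant_fraction, "resistant_fraction", lower = 0, upper = 1)
  structure(list(mechanism = mechanism, ec50 = ec50, hill = hill,
                 max_effect = max_effect,
                 resistant_fraction = resistant_fraction),
            class = "mos_drug_model")
}

#' @export
print.mos_drug_model <- function(x, ...) {
  cat(sprintf(
    "Drug-effect model: %s, EC50 = %g, hill = %g, max effect = %g, resistant fraction = %g\n",
    x$mechanism, x$ec50, x$hill, x$max_effect, x$resistant_fraction))
  invisible(x)
}

#' Imaging parameters for synthetic well rendering
#'
#' Wells are rendered as single-plane images (MOSs settle at the well
#' bottom and do not overlap, so no z-stacks are needed): one bright-field
#' channel and two fluorescence channels (CAM = calcein-AM, live, and
#' EtH = ethidium homodimer, dead). Intensities are stored on a `[0, 1]`
#' scale and written as 16-bit grayscale TIFF.
#'
#' @param image_size Integer `(height, width)` in pixels.
#' @param pixel_size Physical pixel size, um/px (> 0).
#' @param bf_background Bright-field background level.
#' @param fluor_background Fluorescence background level (both channels).
#' @param noise_sd Additive Gaussian noise SD per channel (>= 0).
#' @param psf_sigma Gaussian point-spread blur sigma in px (>= 0).
#' @param kappa_live Integrated CAM intensity contributed per viable cell.
#' @param kappa_dead Integrated EtH intensity contributed per dead cell.
#' @return An object of class `mos_imaging_spec`.
#' @export
imaging_spec <- function(image_size = c(512L, 512L), pixel_size = 10,
                         bf_background = 0.75, fluor_background = 0.04,
                         noise_sd = 0.01, psf_sigma = 1,
                         kappa_live = 0.08, kappa_dead = 0.08) {
  stopifnot(length(image_size) == 2L, all(image_size >= 32))
  assert_number(pixel_size, "pixel_size", lower = 1e-9)
  assert_number(noise_sd, "noise_sd", lower = 0)
  assert_number(psf_sigma, "psf_sigma", lower = 0)
  assert_number(kappa_live, "kappa_live", lower = 0)
  assert_number(kappa_dead, "kappa_dead", lower = 0)
  structure(list(image_size = as.integer(image_size),
                 pixel_size = pixel_size, bf_background = bf_background,
                 fluor_background = fluor_background, noise_sd = noise_sd,
                 psf_sigma = psf_sigma, kappa_live = kappa_live,
                 kappa_dead = kappa_dead),
            class = "mos_imaging_spec")
}

#' Spheroid growth and staining parameters
#'
#' Defines the untreated trajectory of a tumorsphere between plating
#' (day 0) and the assay endpoint, plus the composition of the
#' EtH-stainable dead-cell pool.
#'
#' Viable cell number grows exponentially at a per-sphere rate drawn
#' around `rate_per_day`; sphere radius follows the cube root of cell
#' number (constant-density 3D body). At any time a baseline fraction
#' `baseline_dead_frac` of the viable pool is dead from ordinary turnover.
#' Cells killed by a cytotoxic drug lyse and disappear over the assay
#' window: only `1 - dead_clearance` of them remain in the sphere to
#' stain with EtH at the endpoint.
#'
#' @param rate_per_day Mean exponential growth rate of viable cell number
#'   per day.
#' @param rate_cv Between-sphere CV of the growth rate.
#' @param duration_days Days between day-0 imaging and the endpoint.
#' @param radius_meanlog,radius_sdlog Lognormal parameters of the day-0
#'   sphere radius in um (heterogeneous sizes).
#' @param radius_min Lower truncation of the day-0 radius, um.
#' @param cells_per_um3 Cell-number density of a sphere (cells per um^3 of
#'   sphere volume).
#' @param baseline_dead_frac Baseline dead fraction of the viable pool.
#' @param dead_clearance Fraction of drug-killed cells cleared (lysed)
#'   before endpoint staining.
#' @return An object of class `mos_growth_spec`.
#' @export
growth_spec <- function(rate_per_day = 0.4, rate_cv = 0.15,
                        duration_days = 3,
                        radius_meanlog = log(75), radius_sdlog = 0.2,
                        radius_min = 50, cells_per_um3 = 3e-4,
                        baseline_dead_frac = 0.05, dead_clearance = 0.95) {
  assert_number(rate_per_day, "rate_per_day", lower = 0)
  assert_number(rate_cv, "rate_cv", lower = 0)
  assert_number(duration_days, "duration_days", lower = 0)
  assert_number(radius_sdlog, "radius_sdlog", lower = 0)
  assert_number(radius_min, "radius_min", lower = 1)
  assert_number(cells_per_um3, "cells_per_um3", lower = 1e-12)
  assert_number(baseline_dead_frac, "baseline_dead_frac", lower = 0, upper = 0.5)
  assert_number(dead_clearance, "dead_clearance", lower = 0, upper = 1)
  structure(list(rate_per_day = rate_per_day, rate_cv = rate_cv,
                 duration_days = duration_days,
                 radius_meanlog = radius_meanlog,
                 radius_sdlog = radius_sdlog, radius_min = radius_min,
                 cells_per_um3 = cells_per_um3,
                 baseline_dead_frac = baseline_dead_frac,
                 dead_clearance = dead_clearance),
            class = "mos_growth_spec")
}

#' Stromal single-cell parameters
#'
#' Resident stromal cells appear in wells as small irregular blobs well
#' below tumorsphere size; they contribute (weakly) to bulk luminescence
#' but must be excluded from sphere-level metrics. Stroma is unaffected by
#' the drug models.
#'
#' @param mean_per_well Mean stroma objects per well (Poisson).
#' @param radius_range Radius range in um (uniform).
#' @param cells_range Viable cells per stroma object (integer range).
#' @return An object of class `mos_stroma_spec`.
#' @export
stroma_spec <- function(mean_per_well = 12, radius_range = c(15, 28),
                        cells_range = c(1L, 3L)) {
  assert_number(mean_per_well, "mean_per_well", lower = 0)
  stopifnot(length(radius_range) == 2L, radius_range[1] > 0,
            diff(radius_range) >= 0, length(cells_range) == 2L)
  structure(list(mean_per_well = mean_per_well,
                 radius_range = radius_range,
                 cells_range = as.integer(cells_range)),
            class = "mos_stroma_spec")
}

#' Build a plate layout
#'
#' Maps wells to experimental condition: each drug gets `n_replicates`
#' wells at each nonzero dose plus `n_vehicle` vehicle (dose 0) wells.
#' Wells are assigned row-major on a standard lettered grid.
#'
#' @param drugs Character vector of drug names.
#' @param doses A numeric vector of nonzero doses shared by all drugs, or
#'   a named list of per-drug dose vectors.
#' @param n_replicates Replicate wells per (drug, dose).
#' @param n_vehicle Vehicle wells per drug.
#' @param plate_id Plate identifier.
#' @param n_cols Number of well columns on the plate grid.
#' @return A data.frame with columns `plate_id`, `well_id`, `drug`,
#'   `dose`, `replicate` (class `mos_layout`). Vehicle wells carry the
#'   drug name with `dose = 0`.
#' @export
#' @examples
#' plate_layout("SN38", doses = 10^seq(-3, 0, length.out = 7))
plate_layout <- function(drugs, doses, n_replicates = 3, n_vehicle = 3,
                         plate_id = "P1", n_cols = 12) {
  assert_count(n_replicates, "n_replicates", lower = 1)
  assert_count(n_vehicle, "n_vehicle", lower = 0)
  if (!is.list(doses)) doses <- setNames(rep(list(doses), length(drugs)), drugs)
  if (!all(drugs %in% names(doses)))
    stop("`doses` must be named for every drug", call. = FALSE)
  rows <- list()
  for (drug in drugs) {
    d <- sort(unique(as.numeric(doses[[drug]])))
    if (any(d <= 0)) stop("doses must be positive; vehicle wells are added separately",
                          call. = FALSE)
    dd <- c(rep(0, n_vehicle), rep(d, each = n_replicates))
    rr <- c(seq_len(n_vehicle), rep(seq_len(n_replicates), times = length(d)))
    rows[[drug]] <- data.frame(drug = drug, dose = dd, replicate = rr,
                               stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  n <- nrow(df)
  idx <- seq_len(n) - 1L
  df <- data.frame(plate_id = plate_id,
                   well_id = sprintf("%s%02d", LETTERS[idx %/% n_cols + 1L],
                                     idx %% n_cols + 1L),
                   df, row.names = NULL, stringsAsFactors = FALSE)
  class(df) <- c("mos_layout", "data.frame")
  df
}

#' Write / read a plate layout as structured text (YAML)
#'
#' @param layout A layout data.frame from [plate_layout()].
#' @param path File path.
#' @param extra Optional named list of extra metadata to persist (e.g.
#'   `pixel_size`, timepoints, dose units).
#' @return `write_plate_layout()` returns `path` invisibly;
#'   `read_plate_layout()` returns a list with elements `layout` and
#'   `meta`.
#' @export
write_plate_layout <- function(layout, path, extra = list()) {
  obj <- c(list(wells = lapply(seq_len(nrow(layout)), function(i)
    as.list(layout[i, c("plate_id", "well_id", "drug", "dose", "replicate")]))),
    extra)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_plate_layout
#' @export
read_plate_layout <- function(path) {
  obj <- yaml::read_yaml(path)
  layout <- do.call(rbind, lapply(obj$wells, function(w)
    data.frame(plate_id = w$plate_id, well_id = w$well_id, drug = w$drug,
               dose = as.numeric(w$dose), replicate = as.integer(w$replicate),
               stringsAsFactors = FALSE)))
  class(layout) <- c("mos_layout", "data.frame")
  list(layout = layout, meta = obj[setdiff(names(obj), "wells")])
}
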
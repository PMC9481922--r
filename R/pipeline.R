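# End-to-end orchestration: simulate -> segment -> quantify -> normalize
# -> fit -> classify, as a reproducible, configured, file-backed run.
#
# Every stage reads its inputs from and writes its outputs to the run
# directory, so stages can be re-run individually and a run can resume
# from the last completed stage. All randomness derives from the one
# config seed; per-well processing is order-independent and outputs are
# merged sorted by well id, so a re-run from the same persisted config
# is bit-identical.

PIPELINE_STAGES <- c("simulate", "segment", "quantify", "normalize",
                     "fit", "classify")

#' Build a validated pipeline run configuration
#'
#' @param seed Integer seed driving all randomness of the run.
#' @param out_dir Output directory for all artifacts.
#' @param simulation List: `drugs` (named list of [drug_effect_model()]
#'   argument lists), `doses` (named list of per-drug dose vectors),
#'   `n_replicates`, `n_vehicle`, `mos_per_well`, `plating_cv`,
#'   optional `growth`, `stroma`, and `ctg` (`gain`, `noise_cv`)
#'   argument lists.
#' @param imaging [imaging_spec()] argument list.
#' @param segmentation [segmentation_params()] argument list.
#' @param quantify List: `epsilon`, `min_area_tumorsphere`,
#'   `min_circularity`.
#' @param classify List: `alpha`, `min_rho`, `n_perm`, `k_sigma`,
#'   `resistant_min_area`, `n_high_doses`.
#' @return A validated list of class `mos_run_config`.
#' @export
run_config <- function(seed, out_dir, simulation, imaging = list(),
                       segmentation = list(), quantify = list(),
                       classify = list()) {
  seed <- assert_count(seed, "seed", lower = 0)
  stopifnot(is.character(out_dir), length(out_dir) == 1L)
  if (!is.list(simulation) || is.null(simulation$drugs) ||
      is.null(simulation$doses))
    stop("`simulation` must list `drugs` and `doses`", call. = FALSE)
  if (!all(names(simulation$drugs) %in% names(simulation$doses)) ||
      !length(simulation$drugs))
    stop("every drug needs a dose vector", call. = FALSE)
  # construct the parameter objects now: constructors enforce invariants,
  # so an invalid config fails here, before any stage runs
  for (d in names(simulation$drugs))
    do.call(drug_effect_model, simulation$drugs[[d]])
  do.call(growth_spec, simulation$growth %||% list())
  do.call(stroma_spec, simulation$stroma %||% list())
  do.call(imaging_spec, imaging)
  do.call(segmentation_params, segmentation)
  structure(list(seed = seed, out_dir = out_dir, simulation = simulation,
                 imaging = imaging, segmentation = segmentation,
                 quantify = quantify, classify = classify),
            class = "mos_run_config")
}

#' @export
print.mos_run_config <- function(x, ...) {
  cat(sprintf("MOS pipeline config: seed %d, %d drug(s), out_dir %s\n",
              x$seed, length(x$simulation$drugs), x$out_dir))
  invisible(x)
}

#' Persist / load a run configuration (YAML)
#'
#' @param config A `mos_run_config`.
#' @param path File path.
#' @return `write_run_config()` returns `path` invisibly;
#'   `read_run_config()` the validated config.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "mos_run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  obj <- yaml::read_yaml(path)
  obj$simulation$doses <- lapply(obj$simulation$doses, as.numeric)
  do.call(run_config, obj)
}

#' The documented demo configuration
#'
#' Two drug arms on one plate, 7 doses times 3 replicate wells each plus
#' vehicle wells, 20 MOSs per well with 30% plating CV: an SN38-like
#' cytotoxic model (5% resistant clones) and an erlotinib-like
#' cytostatic model. Running it end to end reproduces the assay's
#' signature contrasts: both readouts fall for the cytotoxic arm, the
#' ratio readout stays flat while CTG falls for the cytostatic arm, and
#' resistant clones appear above the high-dose band.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed.
#' @return A `mos_run_config`.
#' @export
make_demo_config <- function(out_dir = file.path(tempdir(), "mos_demo"),
                             seed = 101) {
  run_config(
    seed = seed, out_dir = out_dir,
    simulation = list(
      drugs = list(
        SN38like = list(mechanism = "cytotoxic", ec50 = 0.03, hill = 1.5,
                        max_effect = 0.95, resistant_fraction = 0.05),
        erlotiniblike = list(mechanism = "cytostatic", ec50 = 0.3,
                             hill = 1.5, max_effect = 0.9,
                             resistant_fraction = 0)),
      doses = list(SN38like = c(0.001, 0.003, 0.01, 0.03, 0.1, 0.3, 1),
                   erlotiniblike = c(0.01, 0.03, 0.1, 0.3, 1, 3, 10)),
      n_replicates = 3, n_vehicle = 3,
      mos_per_well = 20, plating_cv = 0.3,
      ctg = list(gain = 50, noise_cv = 0.1)),
    classify = list(alpha = 0.05, min_rho = 0.1, n_perm = 1000,
                    k_sigma = 2, resistant_min_area = 2000,
                    n_high_doses = 2))
}

# ---- stage implementations (file-backed) ------------------------------

resolve_params <- function(config) {
  sim <- config$simulation
  list(
    models = lapply(sim$drugs, function(a) do.call(drug_effect_model, a)),
    doses = lapply(sim$doses, as.numeric),
    n_replicates = sim$n_replicates %||% 3,
    n_vehicle = sim$n_vehicle %||% 3,
    mos_per_well = sim$mos_per_well %||% 20,
    plating_cv = sim$plating_cv %||% 0.3,
    growth = do.call(growth_spec, sim$growth %||% list()),
    stroma = do.call(stroma_spec, sim$stroma %||% list()),
    ctg = sim$ctg %||% list(gain = 50, noise_cv = 0.1),
    imaging = do.call(imaging_spec, config$imaging),
    seg = do.call(segmentation_params, config$segmentation),
    epsilon = config$quantify$epsilon %||% 0.01,
    min_area_tumorsphere = config$quantify$min_area_tumorsphere %||% 2000,
    min_circularity = config$quantify$min_circularity %||% 0.6,
    cls = config$classify)
}

stage_simulate <- function(config, out) {
  p <- resolve_params(config)
  layout <- plate_layout(names(p$models), doses = p$doses,
                         n_replicates = p$n_replicates,
                         n_vehicle = p$n_vehicle)
  plate <- simulate_plate(layout, p$models, growth = p$growth,
                          imaging = p$imaging, stroma = p$stroma,
                          mos_per_well = p$mos_per_well,
                          plating_cv = p$plating_cv, seed = config$seed)
  write_plate_layout(layout, file.path(out, "layout.yaml"),
                     extra = list(pixel_size = p$imaging$pixel_size,
                                  timepoints = c("day0", "endpoint"),
                                  seed = config$seed))
  ctg <- rbind(simulate_ctg(plate, "day0", gain = p$ctg$gain,
                            noise_cv = p$ctg$noise_cv),
               simulate_ctg(plate, "endpoint", gain = p$ctg$gain,
                            noise_cv = p$ctg$noise_cv))
  write.csv(ctg, file.path(out, "ctg.csv"), row.names = FALSE)
  truth <- do.call(rbind, lapply(plate$wells, function(w)
    data.frame(well_id = w$well_id, w$objects, stringsAsFactors = FALSE)))
  rownames(truth) <- NULL
  write.csv(truth, file.path(out, "truth_objects.csv"), row.names = FALSE)
  tw <- do.call(rbind, lapply(plate$wells, function(w)
    data.frame(well_id = w$well_id, n_mos = w$n_mos,
               true_tsa0 = w$true_tsa0, true_tsa1 = w$true_tsa1,
               true_viable0 = w$true_viable0, true_viable1 = w$true_viable1,
               stringsAsFactors = FALSE)))
  rownames(tw) <- NULL
  write.csv(tw, file.path(out, "truth_wells.csv"), row.names = FALSE)
  img_dir <- file.path(out, "images")
  for (wid in sort(names(plate$wells))) {
    ws <- derive_seed(config$seed, "render", wid)
    write_well_images(render_well(plate$wells[[wid]], p$imaging, "day0",
                                  seed = ws), img_dir,
                      channels = c("bf", "mask"))
    write_well_images(render_well(plate$wells[[wid]], p$imaging, "endpoint",
                                  seed = ws), img_dir)
  }
  invisible(NULL)
}

pipeline_layout <- function(out) read_plate_layout(file.path(out, "layout.yaml"))

stage_segment <- function(config, out) {
  p <- resolve_params(config)
  ll <- pipeline_layout(out)
  img_dir <- file.path(out, "images")
  for (tp in c("day0", "endpoint")) {
    rows <- list()
    for (wid in sort(ll$layout$well_id)) {
      im <- read_well_images(img_dir, wid, tp, channels = "bf",
                             pixel_size = p$imaging$pixel_size)
      lm <- segment_brightfield(im$bf, p$seg, p$imaging$pixel_size)
      tiff::writeTIFF(lm$labels / 65535,
                      file.path(img_dir, sprintf("%s_%s_labels.tif", wid, tp)),
                      bits.per.sample = 16)
      cls <- classify_objects(lm, p$min_area_tumorsphere, p$min_circularity)
      if (nrow(cls)) rows[[wid]] <- data.frame(well_id = wid, cls,
                                               stringsAsFactors = FALSE)
    }
    seg <- if (length(rows)) do.call(rbind, rows) else
      data.frame(well_id = character(0))
    rownames(seg) <- NULL
    write.csv(seg, file.path(out, sprintf("segmented_%s.csv", tp)),
              row.names = FALSE)
  }
  invisible(NULL)
}

read_labels <- function(img_dir, wid, tp) {
  m <- tiff::readTIFF(file.path(img_dir, sprintf("%s_%s_labels.tif", wid, tp)))
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}

stage_quantify <- function(config, out) {
  p <- resolve_params(config)
  ll <- pipeline_layout(out)
  img_dir <- file.path(out, "images")
  ctg <- read.csv(file.path(out, "ctg.csv"), stringsAsFactors = FALSE)
  # endpoint: full object records from the stained images
  rows <- list()
  for (wid in sort(ll$layout$well_id)) {
    lm <- as_labelmap(read_labels(img_dir, wid, "endpoint"),
                      p$imaging$pixel_size)
    im <- read_well_images(img_dir, wid, "endpoint",
                           channels = c("cam", "eth"))
    cls <- classify_objects(lm, p$min_area_tumorsphere, p$min_circularity)
    rows[[wid]] <- measure_objects(lm, im$cam, im$eth, epsilon = p$epsilon,
                                   classification = cls, well_id = wid)
  }
  objects <- do.call(rbind, rows)
  rownames(objects) <- NULL
  idx <- match(objects$well_id, ll$layout$well_id)
  objects$drug <- ll$layout$drug[idx]
  objects$dose <- ll$layout$dose[idx]
  write.csv(objects, file.path(out, "objects.csv"), row.names = FALSE)
  wells <- summarize_wells(objects,
                           ctg[ctg$timepoint == "endpoint", ])
  write.csv(wells, file.path(out, "wells.csv"), row.names = FALSE)
  # day 0: areas only (tSA); staining happens at the endpoint
  d0 <- read.csv(file.path(out, "segmented_day0.csv"),
                 stringsAsFactors = FALSE)
  d0$live_dead_ratio <- NA_real_
  wells0 <- if (nrow(d0)) summarize_wells(d0) else
    data.frame(well_id = character(0))
  write.csv(wells0, file.path(out, "wells_day0.csv"), row.names = FALSE)
  invisible(NULL)
}

stage_normalize <- function(config, out) {
  ll <- pipeline_layout(out)
  wells <- read.csv(file.path(out, "wells.csv"), stringsAsFactors = FALSE)
  wells0 <- read.csv(file.path(out, "wells_day0.csv"),
                     stringsAsFactors = FALSE)
  norm <- adjust_ctg(wells, wells0, ll$layout)
  write.csv(norm, file.path(out, "normalized.csv"), row.names = FALSE)
  write.csv(attr(norm, "excluded"), file.path(out, "excluded_wells.csv"),
            row.names = FALSE)
  r2b <- r2a <- c()
  for (dr in unique(norm$drug)) {
    fb <- tryCatch(ctg_curve(norm, dr, "rel_raw")$r_squared,
                   error = function(e) NA_real_)
    fa <- tryCatch(ctg_curve(norm, dr, "rel_viability")$r_squared,
                   error = function(e) NA_real_)
    r2b[dr] <- fb; r2a[dr] <- fa
  }
  vr <- variance_report(norm, r_squared_before = r2b, r_squared_after = r2a)
  jsonlite::write_json(list(
    ss_before = vr$ss_before, ss_after = vr$ss_after,
    t_test_p = vr$t_test_p,
    r_squared_before = as.list(r2b), r_squared_after = as.list(r2a),
    per_condition = vr$per_condition),
    file.path(out, "diagnostics.json"), auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

stage_fit <- function(config, out) {
  ll <- pipeline_layout(out)
  norm <- read.csv(file.path(out, "normalized.csv"), stringsAsFactors = FALSE)
  wells <- read.csv(file.path(out, "wells.csv"), stringsAsFactors = FALSE)
  res <- list(); per_dose <- list()
  for (dr in sort(unique(ll$layout$drug))) {
    cc <- ctg_curve(norm, dr)
    rc <- ratio_curve(wells, ll$layout, dr)
    res[[dr]] <- list(
      ctg = list(auc = cc$auc, r_squared = cc$r_squared,
                 fit = cc$fit[c("lower", "upper", "ec50", "hill",
                                "flagged", "ec50_extrapolated")]),
      ratio = list(auc = rc$auc, r_squared = rc$r_squared,
                   fit = rc$fit[c("lower", "upper", "ec50", "hill",
                                  "flagged", "ec50_extrapolated")]))
    per_dose[[dr]] <- rbind(
      data.frame(drug = dr, readout = "ctg", cc$per_dose),
      data.frame(drug = dr, readout = "ratio", rc$per_dose))
  }
  jsonlite::write_json(res, file.path(out, "dose_response.json"),
                       auto_unbox = TRUE, digits = NA)
  pd <- do.call(rbind, per_dose)
  rownames(pd) <- NULL
  write.csv(pd, file.path(out, "dose_response.csv"), row.names = FALSE)
  invisible(NULL)
}

stage_classify <- function(config, out) {
  cls <- config$classify
  objects <- read.csv(file.path(out, "objects.csv"), stringsAsFactors = FALSE)
  calls <- list(); bands <- list(); outliers <- list()
  for (dr in sort(unique(objects$drug))) {
    ob <- objects[objects$drug == dr, , drop = FALSE]
    ec <- call_mechanism(ob, alpha = cls$alpha %||% 0.05,
                         min_rho = cls$min_rho %||% 0.1,
                         n_perm = cls$n_perm %||% 1000,
                         seed = derive_seed(config$seed, "mechanism", dr))
    calls[[dr]] <- list(mechanism = ec$mechanism,
                        size_trend = ec$size_trend,
                        ratio_trend = ec$ratio_trend,
                        size_rho = ec$size_test$rho %||% NA,
                        size_p = ec$size_test$p_value %||% NA,
                        ratio_rho = ec$ratio_test$rho %||% NA,
                        ratio_p = ec$ratio_test$p_value %||% NA,
                        reason = ec$reason)
    rs <- detect_resistant(ob, k_sigma = cls$k_sigma %||% 2,
                           min_area = cls$resistant_min_area %||% 2000,
                           n_high_doses = cls$n_high_doses %||% 2)
    if (nrow(rs$bands)) bands[[dr]] <- data.frame(drug = dr, rs$bands)
    if (nrow(rs$outliers)) outliers[[dr]] <- data.frame(drug = dr,
                                                        rs$outliers)
  }
  jsonlite::write_json(calls, file.path(out, "effect_calls.json"),
                       auto_unbox = TRUE, digits = NA)
  bd <- if (length(bands)) do.call(rbind, bands) else
    data.frame(drug = character(0))
  rownames(bd) <- NULL
  write.csv(bd, file.path(out, "resistant_bands.csv"), row.names = FALSE)
  ol <- if (length(outliers)) do.call(rbind, outliers) else
    data.frame(drug = character(0))
  rownames(ol) <- NULL
  write.csv(ol, file.path(out, "resistant_clones.csv"), row.names = FALSE)
  invisible(NULL)
}

# ---- orchestration ----------------------------------------------------

#' Run the MOS assay pipeline end to end
#'
#' Executes the stages `simulate`, `segment`, `quantify`, `normalize`,
#' `fit`, `classify` in order, persisting every intermediate artifact
#' (images as 16-bit TIFF, tables as CSV, reports as JSON) under the
#' config's output directory, and finally writes `manifest.json` with an
#' MD5 hash of every output file and per-stage timings. Re-running the
#' same persisted config and seed reproduces every output bit for bit.
#' With `resume = TRUE`, stages whose completion is recorded in
#' `stages.yaml` are skipped, so a run resumes after the last valid
#' stage.
#'
#' @param config A `mos_run_config` (see [run_config()],
#'   [make_demo_config()], [read_run_config()]).
#' @param stages Stages to run (default: all, in order).
#' @param resume Skip stages already recorded as completed.
#' @param quiet Suppress progress messages.
#' @return The manifest (list with `files`, `stages`, `seed`),
#'   invisibly.
#' @export
run_pipeline <- function(config, stages = PIPELINE_STAGES, resume = FALSE,
                         quiet = FALSE) {
  stopifnot(inherits(config, "mos_run_config"))
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  # normalize the config through its persisted form so that a run and a
  # re-run from config.yaml always see bit-identical parameters
  write_run_config(config, file.path(out, "config.yaml"))
  config <- read_run_config(file.path(out, "config.yaml"))
  status_path <- file.path(out, "stages.yaml")
  done <- if (resume && file.exists(status_path))
    yaml::read_yaml(status_path) else list()
  fns <- list(simulate = stage_simulate, segment = stage_segment,
              quantify = stage_quantify, normalize = stage_normalize,
              fit = stage_fit, classify = stage_classify)
  timings <- list()
  for (st in PIPELINE_STAGES[PIPELINE_STAGES %in% stages]) {
    if (isTRUE(done[[st]])) {
      if (!quiet) message(sprintf("[%s] skipped (resume)", st))
      next
    }
    if (!quiet) message(sprintf("[%s] running ...", st))
    t0 <- Sys.time()
    tryCatch(fns[[st]](config, out), error = function(e) {
      done[[st]] <- FALSE
      yaml::write_yaml(done, status_path)
      stop(sprintf("stage '%s' failed: %s", st, conditionMessage(e)),
           call. = FALSE)
    })
    timings[[st]] <- as.numeric(Sys.time() - t0, units = "secs")
    done[[st]] <- TRUE
    yaml::write_yaml(done, status_path)
  }
  files <- setdiff(list.files(out, recursive = TRUE),
                   c("manifest.json", "stages.yaml"))
  hashes <- unname(tools::md5sum(file.path(out, files)))
  manifest <- list(seed = config$seed,
                   files = as.list(setNames(hashes, files)),
                   stages = timings)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
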
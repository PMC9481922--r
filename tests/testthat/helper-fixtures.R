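# Shared fixture builders. Everything is generated in code at test time;
# images are kept small so the suite stays fast.

small_imaging <- function(...) {
  args <- list(...)
  do.call(imaging_spec, c(list(image_size = c(256L, 256L)), args))
}

# the standard two-arm study models used across statistical tests
study_models <- function(resistant_fraction = 0.05) {
  list(
    toxA = drug_effect_model("cytotoxic", ec50 = 0.03, hill = 1.5,
                             max_effect = 0.95,
                             resistant_fraction = resistant_fraction),
    statB = drug_effect_model("cytostatic", ec50 = 0.3, hill = 1.5,
                              max_effect = 0.9))
}

study_doses <- function() list(toxA = 10^seq(-3, 0, length.out = 7),
                               statB = 10^seq(-2, 1, length.out = 7))

# fast (render-free) study: plate + measurement-level records + CTG
fast_study <- function(seed, n_replicates = 6,
                       models = study_models(), doses = study_doses()) {
  lay <- plate_layout(names(models), doses = doses,
                      n_replicates = n_replicates,
                      n_vehicle = n_replicates, n_cols = 18)
  plate <- simulate_plate(lay, models, seed = seed)
  objects <- simulate_object_records(plate)
  list(plate = plate, layout = lay, objects = objects,
       ctg = simulate_ctg(plate),
       wells = summarize_wells(objects, simulate_ctg(plate)),
       wells0 = summarize_wells(simulate_object_records(plate, "day0")))
}

# a small drug-free plate rendered through the imaging path
rendered_wells <- function(seed, n_wells = 3, mos_per_well = 12,
                           imaging = imaging_spec(), stroma = stroma_spec(),
                           noise = TRUE) {
  if (!noise) { imaging$noise_sd <- 0; imaging$psf_sigma <- 0 }
  lay <- plate_layout("veh", doses = c(0.001, 0.01),
                      n_replicates = max(1, n_wells - 2), n_vehicle = 2)
  lay <- lay[seq_len(n_wells), , drop = FALSE]
  plate <- simulate_plate(lay, list(veh = drug_effect_model("inactive")),
                          imaging = imaging, stroma = stroma,
                          mos_per_well = mos_per_well, seed = seed)
  lapply(names(plate$wells), function(wid) {
    w <- plate$wells[[wid]]
    list(well = w,
         rendered = render_well(w, imaging, "endpoint",
                                seed = derive_seed(seed, wid)),
         imaging = imaging)
  })
}
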
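# Droplet-yield arithmetic and Poisson seeding statistics.

#' Number of droplets obtainable from a gel volume
#'
#' Partitions the gel-cell mixture volume into spherical droplets:
#' `floor(gel_volume / ((pi/6) * d^3))` with 1 uL = 1e9 um^3. A 500 uL run
#' at 300 um diameter yields 35,367 droplets (~35,000).
#'
#' @param spec An [encapsulation_spec()], or a gel volume in uL if
#'   `droplet_diameter` is given.
#' @param droplet_diameter Droplet diameter in um (only when `spec` is a
#'   bare volume).
#' @return Integer droplet count.
#' @export
#' @examples
#' droplet_yield(encapsulation_spec(500, 300))
#' droplet_yield(500, 300)
droplet_yield <- function(spec, droplet_diameter = NULL) {
  if (!inherits(spec, "mos_encapsulation_spec")) {
    spec <- encapsulation_spec(gel_volume = spec,
                               droplet_diameter = droplet_diameter)
  }
  sphere_um3 <- pi / 6 * spec$droplet_diameter^3
  as.integer(floor(spec$gel_volume * 1e9 / sphere_um3))
}

#' Number of wells fillable at a fixed MOS density
#'
#' @param n_droplets Total droplet count (>= 0).
#' @param per_well MOSs dispensed per well (>= 1).
#' @return Integer well count, `floor(n_droplets / per_well)`.
#' @export
#' @examples
#' wells_at_density(35000, 20) # 1750
wells_at_density <- function(n_droplets, per_well) {
  assert_count(n_droplets, "n_droplets", lower = 0)
  assert_count(per_well, "per_well", lower = 1)
  as.integer(floor(n_droplets / per_well))
}

#' Simulate Poisson cell seeding into droplets
#'
#' Cells land in droplets i.i.d. Poisson with mean `cells_per_droplet`;
#' each seeded cell independently establishes a tumorsphere with
#' probability `establishment_prob`, so established counts are
#' Binomial(cells, p) per droplet (marginally Poisson(lambda * p)).
#'
#' @param spec An [encapsulation_spec()].
#' @param n_droplets Number of droplets to seed.
#' @param seed Optional integer seed (caller's RNG state is preserved).
#' @return A data.frame with columns `cells` and `tumorspheres`, one row
#'   per droplet.
#' @export
#' @examples
#' d <- seed_droplets(encapsulation_spec(cells_per_droplet = 5), 1000, seed = 1)
#' mean(d$cells)
seed_droplets <- function(spec, n_droplets, seed = NULL) {
  stopifnot(inherits(spec, "mos_encapsulation_spec"))
  n_droplets <- assert_count(n_droplets, "n_droplets", lower = 0)
  with_seed(seed, {
    cells <- rpois(n_droplets, spec$cells_per_droplet)
    spheres <- rbinom(n_droplets, cells, spec$establishment_prob)
    data.frame(cells = cells, tumorspheres = spheres)
  })
}
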
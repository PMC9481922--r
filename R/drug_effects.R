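# Hill-type drug effects applied to ground-truth spheres.

#' Hill effect fraction at a dose
#'
#' `f(d) = max_effect * d^hill / (d^hill + ec50^hill)`; `f(0) = 0`,
#' monotone nondecreasing in dose.
#'
#' @param model A [drug_effect_model()].
#' @param dose Numeric dose vector (>= 0).
#' @return Effect fractions in `[0, max_effect]`.
#' @export
hill_fraction <- function(model, dose) {
  stopifnot(inherits(model, "mos_drug_model"), all(dose >= 0))
  dh <- dose^model$hill
  ifelse(dose == 0, 0, model$max_effect * dh / (dh + model$ec50^model$hill))
}

#' Grow spheres and apply a drug effect
#'
#' Advances ground-truth objects from day 0 to `duration_days` later under
#' a drug-effect model. Tumorspheres grow exponentially at their own rate;
#' stroma objects are static and unaffected by drug. Mechanisms:
#'
#' * `cytotoxic`: spheres grow, then a fraction `f(dose)` of each
#'   sensitive sphere's viable cells converts to dead cells; the radius
#'   shrinks with the cube root of the surviving viable fraction
#'   (constant-density 3D body). A fraction `dead_clearance` of the
#'   killed cells lyses and is removed from the EtH-stainable dead pool.
#' * `cytostatic`: the growth rate is multiplied by `1 - f(dose)`; the
#'   viable/dead composition is unchanged.
#' * `inactive`: growth only.
#'
#' Resistant spheres (`resistant = TRUE`) receive zero effect under every
#' mechanism, so given identical growth draws their trajectories are
#' identical to vehicle. Cell bookkeeping is a deterministic mean-field
#' update (fractional cells allowed); stochasticity enters through the
#' per-sphere size and growth-rate draws and the measurement layer.
#'
#' @param model A [drug_effect_model()].
#' @param dose Scalar dose (>= 0).
#' @param spheres Ground-truth object data.frame with columns `type`,
#'   `radius_um`, `viable_cells`, `dead_cells`, `resistant`,
#'   `growth_rate`.
#' @param duration_days Exposure/growth time in days.
#' @param dead_clearance Fraction of drug-killed cells cleared before
#'   endpoint staining (default 0: every killed cell stays stainable).
#' @return The updated object data.frame.
#' @export
apply_drug_effect <- function(model, dose, spheres, duration_days = 3,
                              dead_clearance = 0) {
  stopifnot(inherits(model, "mos_drug_model"))
  assert_number(dose, "dose", lower = 0)
  assert_number(dead_clearance, "dead_clearance", lower = 0, upper = 1)
  out <- spheres
  tum <- out$type == "tumorsphere"
  if (!any(tum)) return(out)
  f <- hill_fraction(model, dose)
  f_i <- ifelse(out$resistant[tum], 0, f)

  g <- out$growth_rate[tum] * duration_days
  if (model$mechanism == "cytostatic") g <- g * (1 - f_i)
  m <- exp(g)
  viable <- out$viable_cells[tum] * m
  dead <- out$dead_cells[tum] * m # baseline turnover pool scales with growth
  radius <- out$radius_um[tum] * m^(1 / 3)

  if (model$mechanism == "cytotoxic") {
    killed <- f_i * viable
    viable <- viable - killed
    dead <- dead + (1 - dead_clearance) * killed
    radius <- radius * (1 - f_i)^(1 / 3)
  }
  out$viable_cells[tum] <- viable
  out$dead_cells[tum] <- dead
  out$radius_um[tum] <- radius
  out
}
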
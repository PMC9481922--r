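# Day-0 tSA normalization of bulk viability and its diagnostics.

#' Normalize endpoint luminescence by day-0 total surface area
#'
#' The number and size of spheres plated into a well varies; the imaged
#' day-0 tSA is a per-well proxy for the plated viable mass, so dividing
#' the endpoint luminescence by it removes plating variation:
#' `adjusted_rlu = raw_rlu / tsa_day0`. Both the raw and the adjusted
#' values are then rescaled so that the vehicle-well mean is exactly 1
#' within each (plate, drug) block, keeping the two readouts on a common
#' relative-viability scale. Wells without a usable day-0 record
#' (`tsa_day0 <= 0`, missing, or flagged) are excluded, never imputed;
#' exclusions and reasons are kept in the `"excluded"` attribute.
#'
#' @param endpoint Per-well summaries at the assay endpoint
#'   ([summarize_wells()] output with `raw_rlu`).
#' @param day0 Per-well summaries from day-0 imaging (uses `tsa`).
#' @param layout Plate layout mapping `well_id` to `drug` and `dose`.
#' @return A data.frame with columns `plate_id`, `well_id`, `drug`,
#'   `dose`, `replicate`, `raw_rlu`, `tsa_day0`, `adjusted_rlu`,
#'   `rel_raw` (vehicle-scaled raw), `rel_viability` (vehicle-scaled
#'   adjusted). Attribute `"excluded"` lists dropped wells with reasons.
#' @export
adjust_ctg <- function(endpoint, day0, layout) {
  stopifnot(all(c("well_id", "raw_rlu") %in% names(endpoint)),
            all(c("well_id", "tsa") %in% names(day0)),
            all(c("well_id", "drug", "dose") %in% names(layout)))
  df <- layout[, intersect(c("plate_id", "well_id", "drug", "dose",
                             "replicate"), names(layout)), drop = FALSE]
  df$raw_rlu <- endpoint$raw_rlu[match(df$well_id, endpoint$well_id)]
  i0 <- match(df$well_id, day0$well_id)
  df$tsa_day0 <- day0$tsa[i0]
  flag0 <- if ("flagged" %in% names(day0)) day0$flagged[i0] else FALSE

  reason <- rep(NA_character_, nrow(df))
  reason[is.na(df$raw_rlu)] <- "missing endpoint RLU"
  reason[is.na(df$tsa_day0)] <- "missing day-0 imaging record"
  reason[!is.na(df$tsa_day0) & df$tsa_day0 <= 0] <- "day-0 tSA is zero"
  reason[!is.na(flag0) & flag0 & is.na(reason)] <- "day-0 well flagged (no tumorspheres)"
  excluded <- data.frame(well_id = df$well_id[!is.na(reason)],
                         reason = reason[!is.na(reason)],
                         stringsAsFactors = FALSE)
  df <- df[is.na(reason), , drop = FALSE]

  df$adjusted_rlu <- df$raw_rlu / df$tsa_day0
  df$rel_raw <- NA_real_
  df$rel_viability <- NA_real_
  for (drug in unique(df$drug)) {
    sel <- df$drug == drug
    veh <- sel & df$dose == 0
    if (!any(veh))
      stop(sprintf("no vehicle wells for drug '%s'", drug), call. = FALSE)
    df$rel_raw[sel] <- df$raw_rlu[sel] / mean(df$raw_rlu[veh])
    df$rel_viability[sel] <- df$adjusted_rlu[sel] / mean(df$adjusted_rlu[veh])
  }
  rownames(df) <- NULL
  attr(df, "excluded") <- excluded
  df
}

# sum over doses and replicates of squared deviation from the dose mean
replicate_ss <- function(dose, value) {
  sum(unlist(lapply(split(value, dose), function(v) (v - mean(v))^2)))
}

#' Before/after variance diagnostics for tSA normalization
#'
#' Quantifies how much the day-0 tSA normalization tightens replicates,
#' on identically scaled (vehicle-normalized) values: per-condition
#' replicate range and sum of squares around the dose mean, before
#' (`rel_raw`) and after (`rel_viability`), plus a paired two-tailed
#' t test on the per-condition sum-of-squares pairs (reported, not
#' gated; p = 1 by convention when the paired differences have zero
#' variance). Dose-response fit R-squared values can be attached for the
#' before/after comparison.
#'
#' @param normalized Output of [adjust_ctg()].
#' @param r_squared_before,r_squared_after Optional named numeric
#'   vectors of per-drug fit R-squared values.
#' @return An object of class `mos_variance_diagnostics`: list with
#'   `per_condition` (drug, dose, n, range/ss before and after), totals
#'   `ss_before`, `ss_after`, `t_test_p`, and the R-squared slots.
#' @export
variance_report <- function(normalized, r_squared_before = NULL,
                            r_squared_after = NULL) {
  df <- normalized[normalized$dose > 0, , drop = FALSE]
  conds <- unique(df[, c("drug", "dose")])
  rows <- lapply(seq_len(nrow(conds)), function(i) {
    sel <- df$drug == conds$drug[i] & df$dose == conds$dose[i]
    b <- df$rel_raw[sel]; a <- df$rel_viability[sel]
    data.frame(drug = conds$drug[i], dose = conds$dose[i], n = sum(sel),
               range_before = diff(range(b)), range_after = diff(range(a)),
               ss_before = sum((b - mean(b))^2),
               ss_after = sum((a - mean(a))^2),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  if (any(per$n < 2))
    warning("conditions with < 2 replicates: replicate diagnostics undefined there")
  per <- per[per$n >= 2, , drop = FALSE]
  d <- per$ss_after - per$ss_before
  p <- if (nrow(per) < 2 || sd(d) == 0) 1 else t.test(d)$p.value
  structure(list(per_condition = per,
                 ss_before = sum(per$ss_before),
                 ss_after = sum(per$ss_after),
                 t_test_p = p,
                 r_squared_before = r_squared_before,
                 r_squared_after = r_squared_after),
            class = "mos_variance_diagnostics")
}

#' @export
print.mos_variance_diagnostics <- function(x, ...) {
  cat(sprintf(
    "tSA-normalization diagnostics over %d conditions:\n  sum of squares %.4g -> %.4g (paired t p = %.3g)\n",
    nrow(x$per_condition), x$ss_before, x$ss_after, x$t_test_p))
  if (!is.null(x$r_squared_before))
    cat(sprintf("  mean fit R^2 %.3f -> %.3f\n",
                mean(x$r_squared_before), mean(x$r_squared_after)))
  invisible(x)
}
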
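# Four-parameter log-logistic dose-response fits and normalized AUC.

#' Fit a four-parameter log-logistic dose-response curve
#'
#' Least-squares fit of `y = lower + (upper - lower) / (1 + (d /
#' ec50)^hill)` (4PL on log10 dose) with deterministic multi-start
#' initialization (a grid of ec50 over the tested doses crossed with
#' hill in \{0.5, 1, 2\}) and box bounds `lower` in `[0, 1]`, `upper` in
#' `[0.5, 1.5]`, `hill` in `(0, 10]`. An increasing fit (`upper <=
#' lower`) is disallowed; it and any all-start non-convergence fall back
#' to a flagged flat fit at the mean response. An ec50 outside the
#' tested dose range is flagged as extrapolated.
#'
#' @param doses Nonzero doses, one per response (>= 4 distinct values).
#' @param responses Vehicle-normalized responses.
#' @return An object of class `mos_4pl`: list with `lower`, `upper`,
#'   `ec50`, `hill`, `r_squared`, `flagged`, `flag_reason`,
#'   `ec50_extrapolated`, and the data.
#' @export
#' @examples
#' d <- rep(10^seq(-2, 2, length.out = 5), each = 3)
#' y <- 0.1 + 0.9 / (1 + (d / 1)^1.2)
#' fit_curve(d, y)
fit_curve <- function(doses, responses) {
  stopifnot(length(doses) == length(responses))
  ok <- is.finite(doses) & is.finite(responses)
  doses <- doses[ok]; responses <- responses[ok]
  if (any(doses <= 0))
    stop("doses must be positive; vehicle (dose 0) is used only for scaling",
         call. = FALSE)
  if (length(unique(doses)) < 4)
    stop("need >= 4 distinct nonzero doses for a 4PL fit", call. = FALSE)

  sst <- sum((responses - mean(responses))^2)
  flat <- function(reason) structure(list(
    lower = mean(responses), upper = mean(responses), ec50 = NA_real_,
    hill = NA_real_, r_squared = 0, flagged = TRUE, flag_reason = reason,
    ec50_extrapolated = NA, doses = doses, responses = responses),
    class = "mos_4pl")

  lo_b <- c(lower = 0, upper = 0.5, lec50 = log10(min(doses)) - 2,
            hill = 0.01)
  hi_b <- c(lower = 1, upper = 1.5, lec50 = log10(max(doses)) + 2,
            hill = 10)
  best <- NULL; best_sse <- Inf
  start_l <- min(max(min(responses), 0), 1)
  start_u <- min(max(max(responses), 0.5), 1.5)
  for (e0 in sort(unique(doses))) {
    for (h0 in c(0.5, 1, 2)) {
      fit <- tryCatch(minpack.lm::nlsLM(
        responses ~ lower + (upper - lower) / (1 + 10^(hill * (log10(doses) - lec50))),
        start = list(lower = start_l, upper = start_u,
                     lec50 = log10(e0), hill = h0),
        lower = lo_b, upper = hi_b,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (is.null(fit)) next
      sse <- sum(residuals(fit)^2)
      if (sse < best_sse) { best <- fit; best_sse <- sse }
    }
  }
  if (is.null(best)) return(flat("no start converged"))
  cf <- coef(best)
  if (cf[["upper"]] <= cf[["lower"]])
    return(flat("increasing response (upper <= lower) disallowed"))
  ec50 <- 10^cf[["lec50"]]
  structure(list(lower = unname(cf[["lower"]]), upper = unname(cf[["upper"]]),
                 ec50 = ec50, hill = unname(cf[["hill"]]),
                 r_squared = if (sst > 0) 1 - best_sse / sst else 1,
                 flagged = FALSE, flag_reason = NA_character_,
                 ec50_extrapolated = ec50 < min(doses) || ec50 > max(doses),
                 doses = doses, responses = responses),
            class = "mos_4pl")
}

#' Predicted response from a 4PL fit
#'
#' @param object A `mos_4pl` fit.
#' @param newdata Doses at which to predict (defaults to fitted doses).
#' @param ... Unused.
#' @return Predicted responses.
#' @export
predict.mos_4pl <- function(object, newdata = NULL, ...) {
  d <- newdata %||% object$doses
  if (object$flagged || is.na(object$ec50))
    return(rep(object$lower, length(d)))
  object$lower + (object$upper - object$lower) /
    (1 + (d / object$ec50)^object$hill)
}

#' @export
print.mos_4pl <- function(x, ...) {
  if (x$flagged) {
    cat(sprintf("4PL fit: FLAGGED (%s); flat fallback at %.3f\n",
                x$flag_reason, x$lower))
  } else {
    cat(sprintf(
      "4PL fit: lower %.3f, upper %.3f, EC50 %.4g%s, hill %.2f, R^2 %.3f\n",
      x$lower, x$upper, x$ec50,
      if (x$ec50_extrapolated) " (extrapolated)" else "", x$hill,
      x$r_squared))
  }
  invisible(x)
}

#' Normalized area under the dose-response curve
#'
#' Trapezoidal integral of the per-dose mean response over log10 dose,
#' divided by the log-dose span, with responses clipped to `[0, 1]`
#' first: a no-effect curve (response 1 everywhere) has AUC 1 and a
#' complete-kill curve has AUC 0; lower AUC = greater sensitivity.
#' Vehicle (dose 0) must not be included (log scale); use it for
#' response scaling only.
#'
#' @param doses Nonzero doses (>= 2 distinct values).
#' @param responses Responses, same length (replicates allowed; averaged
#'   per dose).
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' compute_auc(c(0.01, 0.1, 1, 10), c(1, 1, 0, 0))
compute_auc <- function(doses, responses) {
  stopifnot(length(doses) == length(responses))
  if (any(doses <= 0)) stop("doses must be positive", call. = FALSE)
  mu <- vapply(split(pmin(pmax(responses, 0), 1), doses), mean, 0)
  d <- sort(unique(doses))
  if (length(d) < 2)
    stop("AUC undefined for a single dose", call. = FALSE)
  x <- log10(d)
  y <- mu[order(as.numeric(names(mu)))]
  sum(diff(x) * (head(y, -1) + y[-1]) / 2) / (max(x) - min(x))
}

# shared builder for the two parallel readouts
build_curve <- function(df, drug, readout) {
  veh <- df$dose == 0
  trt <- !veh
  if (!any(trt)) {
    # vehicle-only input: nothing to fit; a flat no-effect curve at 1
    return(structure(list(drug = drug, readout = readout, data = df,
                          per_dose = data.frame(dose = numeric(0),
                                                n = integer(0),
                                                center = numeric(0)),
                          fit = NULL, auc = 1, r_squared = NA_real_),
                     class = "mos_drc"))
  }
  fit <- tryCatch(fit_curve(df$dose[trt], df$response[trt]),
                  error = function(e) NULL)
  per_dose <- do.call(rbind, lapply(split(df[trt, ], df$dose[trt]),
    function(g) data.frame(dose = g$dose[1], n = nrow(g),
      center = if (readout == "ctg") mean(g$response) else median(g$response))))
  rownames(per_dose) <- NULL
  structure(list(drug = drug, readout = readout,
                 data = df, per_dose = per_dose, fit = fit,
                 auc = compute_auc(per_dose$dose, per_dose$center),
                 r_squared = if (!is.null(fit)) fit$r_squared else NA_real_),
            class = "mos_drc")
}

#' Dose-response curve on the bulk (CTG) readout
#'
#' Builds the luminescence-based response curve for one drug from
#' normalized viability values: per-dose center = mean of replicate
#' wells, 4PL fit on the replicate values, AUC on the per-dose means.
#'
#' @param normalized Output of [adjust_ctg()] (or any data.frame with
#'   `drug`, `dose`, and the response column).
#' @param drug Drug to extract.
#' @param response Response column: `"rel_viability"` (adjusted) or
#'   `"rel_raw"`.
#' @return An object of class `mos_drc` with elements `per_dose`, `fit`
#'   (`mos_4pl`), `auc`, `r_squared`.
#' @export
ctg_curve <- function(normalized, drug, response = "rel_viability") {
  sel <- normalized$drug == drug
  if (!any(sel)) stop("unknown drug: ", drug, call. = FALSE)
  df <- data.frame(well_id = normalized$well_id[sel],
                   dose = normalized$dose[sel],
                   response = normalized[[response]][sel],
                   stringsAsFactors = FALSE)
  build_curve(df, drug, "ctg")
}

#' Dose-response curve on the median live/dead-ratio readout
#'
#' The orthogonal image-based response: each well contributes the median
#' CAM/EtH ratio of its tumorspheres, rescaled by the median over
#' vehicle wells; the per-dose center is the median over replicate wells
#' (median-of-medians, robust to resistant-clone outliers). Flagged
#' wells (no tumorspheres) are dropped; a dose whose wells are all
#' flagged is dropped with a message.
#'
#' @param wells Per-well summaries ([summarize_wells()] output).
#' @param layout Plate layout (`well_id`, `drug`, `dose`).
#' @param drug Drug to extract.
#' @return An object of class `mos_drc`.
#' @export
ratio_curve <- function(wells, layout, drug) {
  df <- merge(wells, layout[, c("well_id", "drug", "dose")], by = "well_id")
  df <- df[df$drug == drug, , drop = FALSE]
  if (!nrow(df)) stop("unknown drug: ", drug, call. = FALSE)
  bad <- df$flagged | is.na(df$median_ratio)
  dropped <- unique(df$dose[!df$dose %in% df$dose[!bad]])
  if (length(dropped))
    message("ratio_curve: dropping dose(s) with no usable wells: ",
            paste(signif(dropped, 3), collapse = ", "))
  df <- df[!bad, , drop = FALSE]
  veh <- df$dose == 0
  if (!any(veh)) stop("no usable vehicle wells", call. = FALSE)
  scale <- median(df$median_ratio[veh])
  out <- data.frame(well_id = df$well_id, dose = df$dose,
                    response = df$median_ratio / scale,
                    stringsAsFactors = FALSE)
  build_curve(out, drug, "ratio")
}

#' @export
print.mos_drc <- function(x, ...) {
  cat(sprintf("Dose-response [%s, %s readout]: AUC = %.3f, R^2 = %.3f\n",
              x$drug, x$readout, x$auc, x$r_squared))
  if (!is.null(x$fit)) print(x$fit)
  invisible(x)
}

#' Plot a dose-response curve
#'
#' @param x A `mos_drc`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.mos_drc <- function(x, ...) {
  trt <- x$data$dose > 0
  graphics::plot(log10(x$data$dose[trt]), x$data$response[trt],
                 xlab = "log10 dose", ylab = paste0("relative ", x$readout),
                 main = sprintf("%s (AUC %.2f)", x$drug, x$auc), ...)
  if (!is.null(x$fit) && !x$fit$flagged) {
    dd <- 10^seq(log10(min(x$data$dose[trt])),
                 log10(max(x$data$dose[trt])), length.out = 100)
    graphics::lines(log10(dd), predict(x$fit, dd))
  }
  invisible(x)
}
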
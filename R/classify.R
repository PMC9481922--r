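# Mechanism calling and resistant-clone detection from per-object
# readouts.

#' Permutation test for a dose trend (Spearman)
#'
#' Trend statistic: Spearman correlation between dose and a per-object
#' value, pooled across wells. Significance by permutation of the dose
#' labels across objects; the p-value uses the add-one convention
#' `(1 + #{|rho*| >= |rho|}) / (n_perm + 1)` and is therefore a valid
#' (slightly conservative) p-value under exchangeability.
#'
#' @param dose Per-object dose (vehicle = 0 allowed).
#' @param value Per-object readout.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Optional integer seed (caller's RNG state preserved).
#' @return List with `rho` and `p_value`.
#' @export
trend_test <- function(dose, value, n_perm = 1000, seed = NULL) {
  stopifnot(length(dose) == length(value))
  n_perm <- assert_count(n_perm, "n_perm", lower = 100)
  ok <- is.finite(dose) & is.finite(value)
  dose <- dose[ok]; value <- value[ok]
  n <- length(dose)
  if (n < 3 || length(unique(dose)) < 2 || length(unique(value)) < 2)
    return(list(rho = NA_real_, p_value = NA_real_))
  rx <- rank(dose); ry <- rank(value)
  zx <- (rx - mean(rx)); zy <- (ry - mean(ry))
  denom <- sqrt(sum(zx^2) * sum(zy^2))
  rho <- sum(zx * zy) / denom
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm),
           function(i) sum(zx[sample.int(n)] * zy) / denom, 0)
  })
  list(rho = rho, p_value = (1 + sum(abs(perm) >= abs(rho))) / (n_perm + 1))
}

trend_call <- function(tt, alpha, min_rho) {
  if (is.na(tt$rho)) return("flat")
  # "flat" unless both the permutation test and the effect-size guard
  # agree there is a trend (whichever is more conservative wins)
  if (tt$p_value < alpha && tt$rho <= -min_rho) "down"
  else if (tt$p_value < alpha && tt$rho >= min_rho) "up"
  else "flat"
}

#' Call drug mechanism from joint size and live/dead-ratio trends
#'
#' Operationalizes the visual criterion for separating drug effects:
#' a cytotoxic drug drives both per-object size and CAM/EtH ratio down
#' with dose; a cytostatic drug drives size down while the ratio stays
#' flat; an inactive drug moves neither. Trends are Spearman
#' correlations of dose vs per-object value pooled across wells, tested
#' by label permutation ([trend_test()]); a trend is "flat" unless it is
#' both significant at `alpha` and at least `min_rho` in magnitude.
#' Rule table (size, ratio) -> mechanism: (down, down) -> cytotoxic;
#' (down, flat) -> cytostatic; (flat, flat) -> inactive; any other
#' combination -> ambiguous. Only tumorsphere-classified objects enter.
#'
#' @param objects Object records with columns `dose`, `area_um2`,
#'   `live_dead_ratio`, `class` (several doses incl. vehicle pooled).
#' @param alpha Significance level for the permutation test.
#' @param min_rho Minimum |Spearman rho| to call a trend.
#' @param n_perm Permutations per trend test.
#' @param min_objects_per_dose QC floor; below it the call is
#'   `ambiguous` with a reason.
#' @param seed Optional integer seed.
#' @return An object of class `mos_effect_call`: list with `mechanism`,
#'   `size_trend`, `ratio_trend`, the two test results, and `reason`.
#' @export
call_mechanism <- function(objects, alpha = 0.05, min_rho = 0.1,
                           n_perm = 1000, min_objects_per_dose = 10,
                           seed = NULL) {
  ob <- objects[objects$class == "tumorsphere", , drop = FALSE]
  out <- function(mechanism, size_tr = NA, ratio_tr = NA, ts = NULL,
                  tr = NULL, reason = NA_character_)
    structure(list(mechanism = mechanism, size_trend = size_tr,
                   ratio_trend = ratio_tr, size_test = ts, ratio_test = tr,
                   alpha = alpha, min_rho = min_rho, reason = reason),
              class = "mos_effect_call")
  doses <- sort(unique(ob$dose))
  if (!(0 %in% doses) || length(doses) < 4)
    return(out("ambiguous",
               reason = "need vehicle plus >= 3 dose levels"))
  counts <- table(ob$dose)
  if (any(counts < min_objects_per_dose))
    return(out("ambiguous", reason = sprintf(
      "fewer than %d objects at dose(s) %s", min_objects_per_dose,
      paste(signif(as.numeric(names(counts)[counts < min_objects_per_dose]),
                   3), collapse = ", "))))
  ts <- trend_test(ob$dose, ob$area_um2, n_perm = n_perm,
                   seed = if (is.null(seed)) NULL else derive_seed(seed, "size"))
  tr <- trend_test(ob$dose, ob$live_dead_ratio, n_perm = n_perm,
                   seed = if (is.null(seed)) NULL else derive_seed(seed, "ratio"))
  s <- trend_call(ts, alpha, min_rho)
  r <- trend_call(tr, alpha, min_rho)
  mech <- if (s == "down" && r == "down") "cytotoxic"
          else if (s == "down" && r == "flat") "cytostatic"
          else if (s == "flat" && r == "flat") "inactive"
          else "ambiguous"
  out(mech, s, r, ts, tr)
}

#' @export
print.mos_effect_call <- function(x, ...) {
  cat(sprintf("Effect call: %s (size trend %s, ratio trend %s)\n",
              x$mechanism, x$size_trend, x$ratio_trend))
  if (!is.na(x$reason)) cat("  reason:", x$reason, "\n")
  invisible(x)
}

#' Detect resistant clones as high-dose live/dead-ratio outliers
#'
#' At each qualifying (high) dose, the cohort band is the object-weighted
#' mean of the live/dead ratios plus/minus one SD — every object counts
#' equally, regardless of its size. Objects whose ratio exceeds
#' `mean + k_sigma * sd` and whose area is at least `min_area` are
#' flagged as resistant-clone candidates, with coordinates retained so
#' review crops can be made. A degenerate band (`sd = 0`) yields no
#' outliers.
#'
#' @param objects Object records (`dose`, `live_dead_ratio`, `area_um2`,
#'   `class`, `well_id`, `label`; centroids carried through if present).
#' @param doses Doses to scan; default the top `n_high_doses` levels.
#' @param n_high_doses Number of highest dose levels scanned when
#'   `doses` is missing.
#' @param k_sigma Outlier threshold in band SD units.
#' @param min_area Minimum outlier area in um^2 (debris guard).
#' @param min_objects Minimum objects a dose needs to form a band.
#' @return An object of class `mos_resistant_set`: list with `bands`
#'   (per-dose center, sigma, n, threshold) and `outliers` (one row per
#'   flagged object).
#' @export
detect_resistant <- function(objects, doses = NULL, n_high_doses = 2,
                             k_sigma = 2, min_area = 2000,
                             min_objects = 10) {
  ob <- objects[objects$class == "tumorsphere" & objects$dose > 0, ,
                drop = FALSE]
  if (is.null(doses)) {
    lv <- sort(unique(ob$dose), decreasing = TRUE)
    doses <- head(lv, n_high_doses)
  }
  bands <- list(); outs <- list()
  keep_cols <- intersect(c("well_id", "label", "dose", "area_um2",
                           "live_dead_ratio", "centroid_row",
                           "centroid_col", "resistant"), names(ob))
  for (d in sort(doses)) {
    g <- ob[ob$dose == d, , drop = FALSE]
    if (nrow(g) < min_objects) {
      bands[[as.character(d)]] <- data.frame(dose = d, n = nrow(g),
        center = NA_real_, sigma = NA_real_, threshold = NA_real_,
        note = "too few objects", stringsAsFactors = FALSE)
      next
    }
    ctr <- mean(g$live_dead_ratio)
    sg <- sd(g$live_dead_ratio)
    thr <- ctr + k_sigma * sg
    bands[[as.character(d)]] <- data.frame(dose = d, n = nrow(g),
      center = ctr, sigma = sg, threshold = thr, note = NA_character_,
      stringsAsFactors = FALSE)
    if (sg > 0) {
      hit <- g$live_dead_ratio > thr & g$area_um2 >= min_area
      if (any(hit)) outs[[as.character(d)]] <- g[hit, keep_cols, drop = FALSE]
    }
  }
  outliers <- if (length(outs)) do.call(rbind, outs) else
    ob[0, keep_cols, drop = FALSE]
  rownames(outliers) <- NULL
  structure(list(bands = do.call(rbind, bands) %||%
                   data.frame(), outliers = outliers,
                 k_sigma = k_sigma, min_area = min_area),
            class = "mos_resistant_set")
}

#' @export
print.mos_resistant_set <- function(x, ...) {
  cat(sprintf(
    "Resistant-clone scan (k = %g sigma): %d outlier(s) over %d dose band(s)\n",
    x$k_sigma, nrow(x$outliers), nrow(x$bands)))
  invisible(x)
}
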
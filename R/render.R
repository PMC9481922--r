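# Rendering of synthetic whole-well images.
#
# Image matrices are indexed [row, col], 1-based; intensities live on a
# [0, 1] scale in memory and are written as 16-bit grayscale TIFF.
# Object centers (cx_px, cy_px) are (row, col) coordinates.

# linear indices of the digital disk around (row0, col0)
disk_indices <- function(row0, col0, r, height, width) {
  rows <- max(1L, floor(row0 - r)):min(height, ceiling(row0 + r))
  cols <- max(1L, floor(col0 - r)):min(width, ceiling(col0 + r))
  rr <- rep(rows, times = length(cols))
  cc <- rep(cols, each = length(rows))
  keep <- (rr - row0)^2 + (cc - col0)^2 <= r^2
  list(rows = rr[keep], cols = cc[keep],
       idx = rr[keep] + (cc[keep] - 1L) * height)
}

# Irregular stroma footprint: union of a few jittered sub-disks inside
# radius r. Shape is a deterministic function of the supplied RNG state.
blob_indices <- function(row0, col0, r, height, width) {
  k <- sample(2:3, 1)
  idx <- integer(0)
  for (i in seq_len(k)) {
    ang <- runif(1, 0, 2 * pi)
    d <- runif(1, 0, 0.4 * r)
    sub <- disk_indices(row0 + d * cos(ang), col0 + d * sin(ang),
                        runif(1, 0.55, 0.8) * r, height, width)
    idx <- union(idx, sub$idx)
  }
  idx
}

#' Render one well as bright-field, CAM and EtH images plus truth mask
#'
#' Draws every ground-truth object into a single-plane three-channel
#' image set. Tumorspheres are rendered as disks with a darker rim and a
#' brighter lumen in bright field; stroma as small irregular blobs. Each
#' object's fluorescence is spread uniformly over its footprint so that
#' the background-subtracted integral over the true mask equals
#' `kappa_live * viable_cells` (CAM) and `kappa_dead * dead_cells` (EtH)
#' exactly in the absence of blur and noise. Channels are then blurred
#' with a Gaussian PSF (`psf_sigma`) and corrupted with additive Gaussian
#' noise (`noise_sd`), both of which may be zero. The ground-truth label
#' mask (0 = background, k = object k) is returned alongside.
#'
#' @param well One element of `mos_plate$wells`.
#' @param imaging An [imaging_spec()] (use the plate's own).
#' @param timepoint `"day0"` or `"endpoint"` object states.
#' @param seed Integer seed for stroma shapes and noise. Pass the same
#'   seed for both timepoints: shapes are drawn from a
#'   timepoint-independent substream so static objects keep their shape,
#'   while noise differs per timepoint.
#' @return List with matrices `bf`, `cam`, `eth`, integer matrix `mask`,
#'   and `pixel_size`.
#' @export
render_well <- function(well, imaging = imaging_spec(),
                        timepoint = c("endpoint", "day0"), seed = 1) {
  timepoint <- match.arg(timepoint)
  h <- imaging$image_size[1]; w <- imaging$image_size[2]
  ob <- well$objects
  radius_px <- (if (timepoint == "endpoint") ob$r1_um else ob$r0_um) /
    imaging$pixel_size
  viable <- if (timepoint == "endpoint") ob$viable1 else ob$viable0
  dead <- if (timepoint == "endpoint") ob$dead1 else ob$dead0

  bf <- matrix(imaging$bf_background, h, w)
  cam <- matrix(imaging$fluor_background, h, w)
  eth <- matrix(imaging$fluor_background, h, w)
  mask <- matrix(0L, h, w)

  footprints <- with_seed(derive_seed(seed, "shape"), {
    lapply(seq_len(nrow(ob)), function(i) {
      if (ob$type[i] == "tumorsphere") {
        disk_indices(ob$cx_px[i], ob$cy_px[i], radius_px[i], h, w)$idx
      } else {
        blob_indices(ob$cx_px[i], ob$cy_px[i], radius_px[i], h, w)
      }
    })
  })

  for (i in seq_len(nrow(ob))) {
    idx <- footprints[[i]]
    if (!length(idx)) next
    if (any(mask[idx] != 0L))
      stop("object masks overlap; invalid placement", call. = FALSE)
    mask[idx] <- ob$id[i]
    if (ob$type[i] == "tumorsphere") {
      rr <- (idx - 1L) %% h + 1L
      cc <- (idx - 1L) %/% h + 1L
      d <- sqrt((rr - ob$cx_px[i])^2 + (cc - ob$cy_px[i])^2) /
        max(radius_px[i], 1e-9)
      shade <- ifelse(d > 0.82, 0.30, ifelse(d < 0.45, 0.62, 0.45))
      bf[idx] <- shade
    } else {
      bf[idx] <- 0.40
    }
    cam[idx] <- cam[idx] + imaging$kappa_live * viable[i] / length(idx)
    eth[idx] <- eth[idx] + imaging$kappa_dead * dead[i] / length(idx)
  }

  if (imaging$psf_sigma > 0) {
    bf <- EBImage::gblur(bf, imaging$psf_sigma)
    cam <- EBImage::gblur(cam, imaging$psf_sigma)
    eth <- EBImage::gblur(eth, imaging$psf_sigma)
  }
  if (imaging$noise_sd > 0) {
    with_seed(derive_seed(seed, "noise", timepoint), {
      bf <- bf + rnorm(h * w, 0, imaging$noise_sd)
      cam <- cam + rnorm(h * w, 0, imaging$noise_sd)
      eth <- eth + rnorm(h * w, 0, imaging$noise_sd)
    })
  }
  clip <- function(m) {m[m < 0] <- 0; m[m > 1] <- 1; m}
  list(bf = clip(bf), cam = clip(cam), eth = clip(eth), mask = mask,
       pixel_size = imaging$pixel_size, well_id = well$well_id,
       timepoint = timepoint)
}

#' Write / read a rendered well as 16-bit TIFF files
#'
#' Writes `<well>_<timepoint>_{bf,cam,eth,mask}.tif`. Intensity channels
#' are quantized to 16 bits; the label mask stores `label / 65535` so
#' that up to 65,535 objects round-trip exactly.
#'
#' @param rendered Output of [render_well()].
#' @param dir Output directory (created if needed).
#' @param channels Channels to write.
#' @return `write_well_images()` returns the file paths invisibly;
#'   `read_well_images()` returns the same structure as [render_well()].
#' @export
write_well_images <- function(rendered, dir,
                              channels = c("bf", "cam", "eth", "mask")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (ch in channels) {
    p <- file.path(dir, sprintf("%s_%s_%s.tif", rendered$well_id,
                                rendered$timepoint, ch))
    m <- rendered[[ch]]
    if (ch == "mask") {
      if (max(m) > 65535L) stop("more than 65535 objects", call. = FALSE)
      m <- m / 65535
    } else {
      m <- round(m * 65535) / 65535
    }
    tiff::writeTIFF(m, p, bits.per.sample = 16)
    paths[ch] <- p
  }
  invisible(paths)
}

#' @rdname write_well_images
#' @param well_id,timepoint Identify the files to read.
#' @param pixel_size Pixel calibration to attach, um/px.
#' @export
read_well_images <- function(dir, well_id, timepoint,
                             channels = c("bf", "cam", "eth", "mask"),
                             pixel_size = NULL) {
  out <- list(well_id = well_id, timepoint = timepoint,
              pixel_size = pixel_size)
  for (ch in channels) {
    p <- file.path(dir, sprintf("%s_%s_%s.tif", well_id, timepoint, ch))
    if (!file.exists(p)) { out[ch] <- list(NULL); next }
    m <- tiff::readTIFF(p)
    if (ch == "mask") m <- matrix(as.integer(round(m * 65535)),
                                  nrow(m), ncol(m))
    out[[ch]] <- m
  }
  out
}
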
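---
title: "Models and methods behind mosassay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mosassay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mosassay)
```

# The assay being modeled

A micro-organosphere (MOS) assay starts from a gel-cell mixture partitioned
into droplets of 200-500 um diameter. Dispensed into microplate wells, the
MOSs settle at the well bottom in a single focal plane without overlapping,
so a whole well can be imaged in one bright-field plane plus two
fluorescence channels — calcein-AM (CAM, stains live cells, green) and
ethidium homodimer (EtH, stains dead cells, red) — and every sphere can be
measured individually. In parallel, each well yields one bulk
CellTiter-Glo (CTG) luminescence value (RLU), proportional to viable cell
mass. `mosassay` implements both the per-object image analytics and the
bulk-readout normalization, and ships a simulator that generates complete
plates with ground truth so that every claim the analytics make can be
tested quantitatively.

# The synthetic-data generator

## Encapsulation and plate arithmetic

Droplet yield is pure geometry: a gel volume $V$ (uL) partitioned into
spheres of diameter $d$ (um) yields $\lfloor 10^9 V / (\tfrac{\pi}{6} d^3)
\rfloor$ droplets; dispensing $n$ droplets at $k$ per well fills
$\lfloor n/k \rfloor$ wells. Cell seeding is i.i.d. Poisson per droplet
with mean `cells_per_droplet`; each seeded cell independently establishes a
tumorsphere with probability `establishment_prob` (default 0.3 — the
establishment probability per seeded cell is not an experimentally
determined quantity here; it is a free parameter of the generator, and only
the monotone relationship between seeding density and established spheres
per droplet matters for the analytics).

## Spheres, growth, and drug effects

Each simulated well receives `mos_per_well` tumorspheres (default 20), with
the realized count varying between wells with lognormal CV `plating_cv`
(default 0.30) — this *plating variation* is the disturbance the day-0 tSA
normalization exists to remove. Day-0 sphere radii are lognormal (median
75 um, log-SD 0.2, truncated below at 50 um), matching the wide size
heterogeneity of early-passage cultures; cell number is proportional to
sphere volume (`cells_per_um3 = 3e-4`, i.e. a 150 um-diameter sphere holds
roughly 500 cells), and a baseline fraction `baseline_dead_frac = 0.05` of
cells is dead from ordinary turnover at any time. Viable cell number grows
exponentially at `rate_per_day = 0.4` (per-sphere rates vary with CV 0.15),
about one doubling every 1.7 days over the default 3-day assay; the radius
follows the cube root of cell number (constant-density 3D body imaged in
2D projection).

Drug effects are Hill curves $f(d) = E_{\max} d^h / (d^h +
\mathrm{EC}_{50}^h)$ applied per sphere:

* **cytotoxic** — spheres grow, then a fraction $f$ of viable cells
  converts to dead cells and the radius shrinks with the cube root of the
  surviving viable fraction;
* **cytostatic** — the growth rate is multiplied by $1 - f$; the
  viable/dead composition is untouched;
* **inactive** — growth only.

A fraction `resistant_fraction` of spheres is flagged insensitive at
creation and receives zero effect at every dose, so its trajectories are
identical to vehicle given the same growth draws. Stromal single cells
(Poisson count per well, radii 15-28 um, 1-3 cells) are static,
drug-insensitive, contribute weakly to CTG, and exist so the
tumorsphere/stroma classifier has a real decision to make.

**Dead-cell clearance.** Cells killed by drug do not all remain stainable:
over a multi-day exposure most dead cells lose integrity and lyse. The
simulator models this with `dead_clearance = 0.95` — only 5% of killed
cells remain in the sphere's EtH-stainable pool at the endpoint, while the
baseline turnover pool scales with the viable mass. Two observed properties
of the real assay pin this choice: integrated EtH still *increases* with
dose under a cytotoxic drug (clearance below 1), yet the CTG curve and the
median CAM/EtH-ratio curve of a cytotoxic drug remain *comparable* (strong
retention would make the ratio readout collapse at doses where bulk
viability has barely moved). With retention near the baseline dead
fraction, the per-sphere live/dead ratio approximately tracks the surviving
viable fraction, which is what makes the two readouts agree for cytotoxic
drugs and diverge only for cytostatic ones. `apply_drug_effect()` itself
defaults to `dead_clearance = 0` (every killed cell counted), so the Hill
bookkeeping is exact at the function level; the clearance is applied by the
plate simulator. Cell bookkeeping is a deterministic mean-field update —
stochasticity enters through per-sphere size/rate draws and measurement
noise, which keeps resistant-vs-vehicle trajectory identity exact.

## Rendering and the measurement model

Wells are rendered at 512x512 px, 10 um/px (a downsampled whole-well
scan; the field is ~5 mm). Bright field: background 0.75, tumorspheres as
disks with a darker rim and a brighter lumen, stroma as small irregular
blobs. Objects are placed by rejection sampling with at least one
object-radius clearance between rims (using each object's largest radius
across timepoints, so day-0 and endpoint renders share placements);
placement failure after a bounded number of tries is a generation error.
Fluorescence is spread uniformly over each object's footprint so that the
background-subtracted integral over the true mask equals `kappa_live *
viable_cells` and `kappa_dead * dead_cells` *exactly* when blur and noise
are off — the rendering round-trip that anchors the quantification tests.
Channels are blurred with a Gaussian PSF (`psf_sigma = 1` px) and corrupted
with additive Gaussian noise (`noise_sd = 0.01`); intensities live on a
[0, 1] scale and are written as 16-bit TIFF. `kappa = 0.08` per cell keeps
the largest spheres below pixel saturation; integrals are only meaningful
for unsaturated objects. CTG is `gain * (viable cells in well)` times
lognormal noise with CV 0.1 (the noise structure of the luminometer is not
derived from data; multiplicative noise with a ~10% CV is typical of
plate-reader luminescence).

All randomness flows from one integer seed; per-well substreams are derived
with a deterministic string hash of `(seed, plate, well)`, so wells can be
simulated in any order, or alone, with identical results.

For statistical studies (mechanism recovery, resistant-clone calibration,
normalization power), `simulate_object_records()` produces
measurement-level object records straight from ground truth with a simple
multiplicative noise model (5% CV on integrals, 3% on areas — the scale of
residual error the imaging path leaves after background subtraction),
bypassing rendering. Imaging fidelity itself is tested separately through
the full render-segment-quantify path.

## What the generator does not emulate

No microfluidics or droplet physics; no z-structure or out-of-focus light;
no illumination gradients, vignetting, or spectral bleed-through; no
sphere-sphere contact or merging; no debris other than stroma; no
well-edge effects. Tests passing on these images show the *analytics* are
correct (segmentation contract, normalization algebra, trend calibration,
detection rules); they do not certify the classical segmenter on real
microscopy, which is exactly why the segmenter sits behind a pluggable
label-map contract (`as_labelmap()`) that a trained model can fill.

# The analytics

## Segmentation and classification

`segment_brightfield()` is deterministic: Gaussian smoothing (sigma 1 px),
background-relative thresholding (objects are darker than background;
global Otsu on the background-subtracted image, floored at a minimum
contrast of 0.05 so a blank well yields zero objects rather than
noise-splitting), hole filling (the bright lumen must not punch holes in
a sphere), distance-transform watershed (minimum seed depth 2 px —
shallower splits of one round object are merged), then removal of
components below `min_area` (500 um^2, debris) or above `max_area`, and of
border-touching objects (unmeasurable area; a documented count bias).
Labels are relabeled to a contiguous 1..K. Coordinates are 1-based
(row, col), areas reported in um^2 via `pixel_size^2`.

Classification: `stroma` if area < 2,000 um^2 *or* circularity
$4\pi A/P^2$ < 0.6, else `tumorsphere`. The defaults separate the
generator's two object classes with margin: the smallest fully killed
tumorsphere (50 um day-0 radius, grown then shrunk by the cube root of the
5% surviving fraction) still covers ~2,400 um^2, while stroma blobs stay
below ~1,500 um^2. On real data both cutoffs are configuration, not
constants of nature. Digital perimeters make circularity of small pixelated
disks noisy — area does the work for small objects; circularity exists to
catch large irregular segments.

## Quantification

Per object: area = pixel count x `pixel_size^2`; channel integral =
sum of (channel - background) over the mask with negatives clamped to 0,
background being the per-image median outside all masks (self-contained
per image — no blank-well dependency); live/dead ratio =
`(cam + eps) / (eth + eps)`. The pseudocount `eps` exists solely to guard
fully dead objects (CAM integral 0); it defaults to 0.01, about 0.1% of a
typical integral on this intensity scale. A larger pseudocount is not
harmless: because it damps the ratio of *small* objects more than large
ones, it couples the ratio to object size and can fabricate a dose trend in
the ratio of a shrinking-but-healthy (cytostatic) population. Integrated
(not mean) intensities are used throughout. Per well: tSA and the median
ratio are computed over tumorsphere-classified objects only — stroma is
excluded, since bulk confounding by stromal cells is one of the failure
modes the per-object readout exists to avoid; a well with zero
tumorspheres carries `median_ratio = NA` and a `flagged` marker (an
undefined median is flagged, never coerced to zero).

## Day-0 tSA normalization

`adjusted_rlu = raw_rlu / tsa_day0`, per well, followed by rescaling so the
vehicle-well mean is exactly 1 within each (plate, drug) block — vehicle
scaling (rather than top-plateau scaling) is the declared convention so
that dose-response curves remain in relative-viability units. Both raw and
adjusted values are vehicle-scaled so the before/after variance comparison
is on identical scales. Wells lacking a usable day-0 record are excluded
listwise with a logged reason, never imputed. Diagnostics: per-condition
replicate range and sum of squares before/after, a paired two-tailed t test
on the per-condition sum-of-squares pairs (p = 1 by convention when the
paired differences are all zero), and fit R^2 before/after. The null
control matters as much as the benefit: with plating and size variation
switched off, tSA carries no information and normalization must be neutral
(sum-of-squares ratio near 1) — dividing by a noisy constant should not
manufacture improvement.

## Dose-response and AUC

4PL fits run on replicate-level vehicle-scaled responses at nonzero doses
(at least 4 distinct doses), with deterministic multi-start initialization
(EC50 grid over the tested doses crossed with hill in {0.5, 1, 2}), box
bounds lower in [0, 1], upper in [0.5, 1.5], hill in (0, 10], EC50 within
two decades of the tested range; the best converged start by SSE wins.
Degenerate outcomes are flagged, not silently returned: no convergence or a
fitted increasing curve (upper <= lower) falls back to a flat fit at the
mean response; an EC50 outside the tested range is marked extrapolated.

AUC is the trapezoidal integral of the per-dose center over log10 dose,
divided by the log-dose span, after clipping responses to [0, 1]: 1 =
no effect, 0 = complete kill, comparable across drugs only under this one
convention (dose 0 is excluded from the integral — it has no logarithm —
and used only for scaling). The per-dose center is the replicate mean for
the CTG readout and the median of per-well medians for the ratio readout;
the double median is deliberate, keeping resistant-clone outliers from
dragging the high-dose summary.

## Mechanism calling and resistant clones

The published contrast — a cytotoxic drug moves size *and* live/dead ratio
down, a cytostatic drug moves only size — is operationalized as two
permutation-tested Spearman trends over pooled per-object values (vehicle
included at dose 0), with the rule table (size, ratio): (down, down) ->
cytotoxic, (down, flat) -> cytostatic, (flat, flat) -> inactive, anything
else -> ambiguous, and QC floors (>= 3 dose levels plus vehicle, >= 10
objects per dose) that degrade to `ambiguous` with a reason. A trend is
flat unless it is both permutation-significant at `alpha = 0.05` *and* at
least 0.1 in |rho| — the effect-size guard keeps statistically significant
but negligible drifts (large n makes everything significant) from flipping
a call. The permutation p-value uses the add-one convention, making it
valid, slightly conservative, under exchangeability. Objects are pooled
across replicate wells within a dose; well-level clustering is ignored — a
noted limitation that inflates the permutation null's effective n when
wells differ systematically.

Resistant clones: at each scanned (by default the two highest) dose, the
band is the plain mean +/- SD over objects — every object weighted equally,
ignoring size — and outliers are objects above mean + `k_sigma` x SD
(default k = 2) with area at least 2,000 um^2 (debris guard). A degenerate
band (SD = 0) yields no outliers. The choice k = 2 and the flat-trend alpha
are operational defaults for the visual criteria they replace, exposed as
configuration. No biological claim attaches to a flag: it marks a
statistical outlier worth reviewing, with coordinates retained for cropping
review images.

# Pipeline determinism and problem sizes

`run_pipeline()` persists its config, then *re-reads it* and runs from the
parsed form, so a run and a later re-run from `config.yaml` see
bit-identical parameters regardless of serialization precision; with all
randomness derived from the config seed, re-runs are hash-identical
(verified over every output file's MD5 in the manifest). Stages are
file-backed and individually re-runnable; `resume = TRUE` skips stages
recorded as completed.

The shipped studies use sizes chosen to give the statistical checks real
power while staying desk-sized: the demo plate is 2 drugs x (7 doses x 3
replicates + 3 vehicle wells) at 20 MOSs/well; calibration studies
(mechanism recovery, resistant detection) use 6 replicate wells per dose —
roughly a thousand objects per arm, at which point the |rho| >= 0.1 guard,
not the permutation p, is the binding constraint on a false trend call;
segmentation is scored on ten simulated plates against generator masks;
type-I error uses 200 label-shuffled datasets. Empirical outcomes for all
of these are computed by the test suite and `scripts/acceptance.R`, not
quoted here.

# Known limitations

* The classical segmenter is matched to the generator's clean images; real
  bright-field microscopy (debris, halos, focus drift) will need tuned
  parameters or an external segmenter via `as_labelmap()`.
* Objects are not tracked across timepoints by identity; wells are matched,
  objects are not.
* No flat-field, unmixing, or illumination correction hooks are applied to
  the synthetic images (they do not need them; real data would).
* Per-object trend tests ignore well-level clustering.
* Saturated pixels bias integrated intensities downward; the generator's
  defaults avoid saturation, but real acquisitions must.
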
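#' Background-tissue uptake model
#'
#' Per-tissue log-normal distributions for background SUVmean, plus the
#' acquisition surrogates: additive truncated-Gaussian noise and Gaussian
#' point-spread blur. Defaults reproduce reference-tissue uptake typical of
#' PSMA-ligand PET: parotid gland median 20.1 (range 5.8-36.3), liver 11.3
#' (4.2-25.5), spleen 9.9 (4.7-28.7), with 2 mm FWHM post-reconstruction
#' smoothing. Tissues are sampled independently (their uptakes are
#' uncorrelated across patients).
#'
#' Each tissue is parameterized by its median and a range; the log-normal
#' has meanlog = log(median) (median exact) and sdlog chosen so the
#' 2.5-97.5 percentile span has the same width on the log scale as the
#' range. A degenerate range (lo == hi) yields a constant draw.
#'
#' @param parotis,liver,spleen,soft_tissue lists `list(median=, range=c(lo, hi))`.
#' @param noise_sd additive Gaussian noise SD in SUV units (truncated at 0).
#' @param psf_fwhm_mm Gaussian blur FWHM in mm.
#' @return An object of class `background_model`.
#' @export
background_model <- function(parotis = list(median = 20.1, range = c(5.8, 36.3)),
                             liver = list(median = 11.3, range = c(4.2, 25.5)),
                             spleen = list(median = 9.9, range = c(4.7, 28.7)),
                             soft_tissue = list(median = 1.5, range = c(0.8, 2.8)),
                             noise_sd = 0.3,
                             psf_fwhm_mm = 2) {
  tissues <- list(parotis = parotis, liver = liver, spleen = spleen,
                  soft_tissue = soft_tissue)
  for (nm in names(tissues)) {
    t <- tissues[[nm]]
    if (!is.list(t) || is.null(t$median) || is.null(t$range) ||
        length(t$range) != 2L)
      stop("tissue '", nm, "' needs median and range = c(lo, hi)", call. = FALSE)
    if (t$median <= 0 || any(t$range <= 0) || t$range[1] > t$range[2])
      stop("tissue '", nm, "': median and range must be positive, lo <= hi",
           call. = FALSE)
  }
  if (!is.finite(noise_sd) || noise_sd < 0) stop("noise_sd must be >= 0")
  if (!is.finite(psf_fwhm_mm) || psf_fwhm_mm < 0) stop("psf_fwhm_mm must be >= 0")
  structure(list(tissues = tissues, noise_sd = noise_sd,
                 psf_fwhm_mm = psf_fwhm_mm),
            class = "background_model")
}

# sdlog matching the log-width of the printed range to the central 95% span
lognorm_sdlog <- function(range) log(range[2] / range[1]) / (2 * stats::qnorm(0.975))

#' Sample background SUVmean values, one per tissue
#'
#' Independent log-normal draws per tissue; reproducible for a fixed seed.
#'
#' @param model a [background_model()].
#' @param seed optional integer seed; if `NULL` the current RNG stream is used.
#' @return Named numeric vector (parotis, liver, spleen, soft_tissue), all > 0.
#' @export
sample_background_suvs <- function(model, seed = NULL) {
  stopifnot(inherits(model, "background_model"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  vapply(model$tissues, function(t) {
    s <- lognorm_sdlog(t$range)
    if (s == 0) t$median else stats::rlnorm(1, meanlog = log(t$median), sdlog = s)
  }, numeric(1))
}

#' Specify one synthetic lymph-node lesion
#'
#' @param center world-coordinate centre in mm.
#' @param semi_axes per-axis semi-axis lengths in mm; the short axis must be
#'   at least 5 mm (short-axis diameter >= 1.0 cm, the inclusion criterion
#'   for a measurable node).
#' @param peak_suv homogeneous lesion uptake before blurring (SUV).
#' @return An object of class `lesion_spec`.
#' @export
lesion_spec <- function(center, semi_axes, peak_suv) {
  center <- as.numeric(center); semi_axes <- as.numeric(semi_axes)
  stopifnot(length(center) == 3L, length(semi_axes) == 3L,
            length(peak_suv) == 1L)
  if (any(semi_axes < 5))
    stop("short-axis diameter must be >= 10 mm (all semi_axes >= 5 mm)",
         call. = FALSE)
  if (!is.finite(peak_suv) || peak_suv <= 0)
    stop("peak_suv must be positive", call. = FALSE)
  structure(list(center = center, semi_axes = semi_axes,
                 peak_suv = as.numeric(peak_suv)),
            class = "lesion_spec")
}

# Fixed body layout (world mm) for the default phantom: the lesion sits in
# the left half of a 192 x 192 x 128 mm field of view; liver, parotid and
# spleen blocks occupy the right half, separated by soft-tissue gaps wide
# enough that blur does not mix tissues into each other's reference ROIs.
phantom_layout <- function() {
  list(
    field_mm = c(192, 192, 128),
    lesion_center = c(60, 95, 63),
    blocks = list(
      liver   = list(center = c(158, 40, 63),  edge = c(56, 64, 86)),
      parotis = list(center = c(158, 95, 63),  edge = c(56, 34, 86)),
      spleen  = list(center = c(158, 150, 63), edge = c(56, 64, 86))),
    rois = list(
      liver   = list(kind = "disc", center = c(158, 40, 63), diameter = 30),
      parotis = list(kind = "box",  center = c(158, 95, 63), edge = 10),
      spleen  = list(kind = "box",  center = c(158, 150, 63), edge = 30)))
}

layout_rois <- function(layout = phantom_layout()) {
  lapply(layout$rois, function(r) {
    if (r$kind == "disc") disc_roi(r$center, r$diameter)
    else box_roi(r$center, r$edge)
  })
}

#' Generate one phantom case
#'
#' Paints the tissue SUV fields (soft tissue everywhere, liver/parotid/spleen
#' blocks, homogeneous lesion ellipsoid at `peak_suv`), applies Gaussian
#' point-spread blur, then adds Gaussian noise truncated at 0. The analytic
#' ellipsoid volume of the lesion is recorded as the ground-truth
#' (CT-reference surrogate) volume. The lesion VOI is the lesion ellipsoid
#' dilated by `voi_margin_mm` per semi-axis.
#'
#' @param lesion a [lesion_spec()]; its centre must keep the lesion at least
#'   3 x `psf_fwhm_mm` from the image border and clear of the background ROIs.
#' @param model a [background_model()].
#' @param spacing isotropic voxel spacing in mm (default 2).
#' @param seed integer seed; the case is byte-reproducible for a fixed seed.
#' @param case_id identifier stored in the result.
#' @param voi_margin_mm VOI dilation per semi-axis in mm (default 6).
#' @return An object of class `phantom_case`: fields `case_id`, `pet`
#'   ([scalar_volume()]), `voi` ([ellipsoid_voi()]), `ct_reference_volume_ml`,
#'   `background_suvs` (named truth vector), `rois` (liver disc, parotid box,
#'   spleen box), `lesion`, and `post_blur_max` (recorded max SUV in the
#'   blurred, pre-noise lesion field).
#' @export
generate_case <- function(lesion, model = background_model(), spacing = 2,
                          seed = 1, case_id = "case_001", voi_margin_mm = 6) {
  stopifnot(inherits(lesion, "lesion_spec"), inherits(model, "background_model"))
  layout <- phantom_layout()
  dims <- pmax(2L, as.integer(round(layout$field_mm / spacing)))
  margin <- 3 * model$psf_fwhm_mm
  lo <- lesion$center - lesion$semi_axes
  hi <- lesion$center + lesion$semi_axes
  extent <- (dims - 1) * spacing
  if (any(lo < margin) || any(hi > extent - margin))
    stop("lesion too close to the image border (needs >= 3 x FWHM margin)",
         call. = FALSE)

  set.seed(as.integer(seed))
  bg <- sample_background_suvs(model)
  vol0 <- scalar_volume(array(bg[["soft_tissue"]], dims), spacing = rep(spacing, 3))
  vals <- vol0$values
  for (nm in c("liver", "parotis", "spleen")) {
    blk <- layout$blocks[[nm]]
    vals[rasterize(vol0, box_roi(blk$center, blk$edge))] <- bg[[nm]]
  }
  lesion_mask <- rasterize(vol0, ellipsoid_voi(lesion$center, lesion$semi_axes))
  if (lesion$peak_suv <= bg[["soft_tissue"]])
    stop("lesion peak_suv must exceed the soft-tissue background", call. = FALSE)
  vals[lesion_mask] <- lesion$peak_suv

  painted <- scalar_volume(vals, spacing = vol0$spacing, origin = vol0$origin)
  blurred <- gaussian_blur(painted, model$psf_fwhm_mm)
  post_blur_max <- max(blurred$values)
  out <- blurred$values
  if (model$noise_sd > 0)
    out <- pmax(0, out + stats::rnorm(length(out), sd = model$noise_sd))
  dim(out) <- dims
  pet <- scalar_volume(out, spacing = vol0$spacing, origin = vol0$origin)

  voi <- ellipsoid_voi(lesion$center, lesion$semi_axes + voi_margin_mm)
  rois <- layout_rois(layout)
  voi_mask <- rasterize(pet, voi)
  for (nm in names(rois))
    if (any(voi_mask & rasterize(pet, rois[[nm]])))
      stop("lesion VOI overlaps the ", nm, " reference ROI", call. = FALSE)

  structure(list(
    case_id = case_id,
    pet = pet,
    voi = voi,
    ct_reference_volume_ml = ellipsoid_volume_ml(lesion$semi_axes),
    background_suvs = bg,
    rois = rois,
    lesion = lesion,
    post_blur_max = post_blur_max),
    class = "phantom_case")
}

#' Cohort-level phantom configuration
#'
#' Defaults emulate the study cohort structure: 50 lymph-node lesions with
#' ground-truth volumes log-normal with median 3.2 ml, truncated to the
#' observed range 1.0-23.8 ml; elongation (long/short semi-axis ratio)
#' uniform on [1, 1.8] with a 5 mm short-axis floor; homogeneous lesion
#' uptake uniform on [8, 40] SUV; backgrounds and acquisition per
#' [background_model()].
#'
#' @param n_cases number of lesions (>= 2).
#' @param volume_median_ml,volume_range_ml ground-truth volume distribution
#'   (log-normal median; truncation range in ml).
#' @param elongation_range long-axis / short-axis semi-axis ratio range.
#' @param peak_suv_range uniform range for lesion uptake (SUV).
#' @param model a [background_model()].
#' @param spacing isotropic voxel spacing in mm.
#' @param voi_margin_mm VOI dilation per semi-axis in mm.
#' @param seed integer master seed; each case uses a derived sub-seed so
#'   cohorts are reproducible case-by-case.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_cases = 50,
                          volume_median_ml = 3.2,
                          volume_range_ml = c(1.0, 23.8),
                          elongation_range = c(1, 1.8),
                          peak_suv_range = c(8, 40),
                          model = background_model(),
                          spacing = 2,
                          voi_margin_mm = 6,
                          seed = 1) {
  stopifnot(n_cases >= 2, volume_range_ml[1] > 0,
            volume_range_ml[1] <= volume_median_ml,
            volume_median_ml <= volume_range_ml[2],
            elongation_range[1] >= 1, elongation_range[1] <= elongation_range[2],
            peak_suv_range[1] > 0, peak_suv_range[1] <= peak_suv_range[2],
            inherits(model, "background_model"))
  structure(list(n_cases = as.integer(n_cases),
                 volume_median_ml = volume_median_ml,
                 volume_range_ml = volume_range_ml,
                 elongation_range = elongation_range,
                 peak_suv_range = peak_suv_range,
                 model = model, spacing = spacing,
                 voi_margin_mm = voi_margin_mm,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Deterministic 32-bit sub-seed for case i of a cohort.
case_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + i * 104729) %% 2147483647)
}

# Draw one lesion spec from the cohort distributions (uses current RNG).
draw_lesion <- function(config) {
  rng <- config$volume_range_ml
  sdlog <- log(rng[2] / rng[1]) / (2 * stats::qnorm(0.975))
  repeat {
    v <- stats::rlnorm(1, meanlog = log(config$volume_median_ml), sdlog = sdlog)
    if (v >= rng[1] && v <= rng[2]) break
  }
  e <- stats::runif(1, config$elongation_range[1], config$elongation_range[2])
  # prolate ellipsoid a = e * b, b = c; enforce the 5 mm short-axis floor
  v_mm3 <- v * 1000
  b <- (3 * v_mm3 / (4 * pi * e))^(1 / 3)
  if (b < 5) {
    b <- 5
    e <- 3 * v_mm3 / (4 * pi * b^3)
  }
  a <- e * b
  peak <- stats::runif(1, config$peak_suv_range[1], config$peak_suv_range[2])
  lesion_spec(phantom_layout()$lesion_center, c(a, b, b), peak)
}

#' Generate a phantom cohort
#'
#' @param config a [cohort_config()].
#' @return List with `cases` (list of [generate_case()] results) and
#'   `ground_truth` (data.frame: case_id, ct_reference_volume_ml, peak_suv,
#'   per-tissue background SUV truths). All ground-truth volumes lie within
#'   the configured range.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  cases <- vector("list", config$n_cases)
  rows <- vector("list", config$n_cases)
  for (i in seq_len(config$n_cases)) {
    si <- case_seed(config$seed, i)
    set.seed(si)
    lesion <- draw_lesion(config)
    id <- sprintf("case_%03d", i)
    cs <- generate_case(lesion, model = config$model, spacing = config$spacing,
                        seed = case_seed(config$seed, i + config$n_cases),
                        case_id = id, voi_margin_mm = config$voi_margin_mm)
    cases[[i]] <- cs
    rows[[i]] <- data.frame(
      case_id = id,
      ct_reference_volume_ml = cs$ct_reference_volume_ml,
      peak_suv = lesion$peak_suv,
      suv_parotis = cs$background_suvs[["parotis"]],
      suv_liver = cs$background_suvs[["liver"]],
      suv_spleen = cs$background_suvs[["spleen"]],
      suv_soft_tissue = cs$background_suvs[["soft_tissue"]],
      stringsAsFactors = FALSE)
  }
  list(cases = cases, ground_truth = do.call(rbind, rows))
}
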
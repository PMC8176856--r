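#' Maximum SUV within a lesion VOI
#'
#' @param pet a [scalar_volume()].
#' @param voi an [ellipsoid_voi()] (or a precomputed logical mask).
#' @return The maximum voxel SUV among VOI voxels.
#' @export
suv_max_in_voi <- function(pet, voi) {
  mask <- as_mask(pet, voi)
  max(pet$values[mask])
}

#' Mean SUV within a background reference ROI
#'
#' @param pet a [scalar_volume()].
#' @param roi a [box_roi()] or [disc_roi()] (or a logical mask).
#' @return Arithmetic mean of voxel SUVs inside the ROI.
#' @export
roi_mean <- function(pet, roi) {
  mask <- as_mask(pet, roi)
  mean(pet$values[mask])
}

as_mask <- function(pet, geom) {
  stopifnot(inherits(pet, "scalar_volume"))
  if (is.logical(geom)) {
    if (!identical(dim(geom), dim(pet$values)))
      stop("mask grid does not match the volume", call. = FALSE)
    if (!any(geom)) stop("empty mask", call. = FALSE)
    geom
  } else {
    rasterize(pet, geom)
  }
}

new_delineation_result <- function(case_id, method, level, threshold_suv,
                                   n_voxels, vv_ml) {
  data.frame(case_id = case_id, method = method, level = level,
             threshold_suv = threshold_suv, n_voxels = n_voxels,
             volume_ml = n_voxels * vv_ml, stringsAsFactors = FALSE)
}

#' Fixed-SUV threshold segmentation within a VOI
#'
#' Counts VOI voxels with SUV at or above the absolute threshold
#' (inclusive rule, SUV >= t). An empty segmentation is a valid result with
#' volume 0. By default all suprathreshold VOI voxels count, with no
#' connectivity requirement (the VOI itself excludes off-target avid
#' structures); `connected = TRUE` restricts to the 26-connected component
#' containing the VOI maximum.
#'
#' @param pet a [scalar_volume()].
#' @param voi an [ellipsoid_voi()] or logical mask.
#' @param t absolute SUV threshold (>= 0).
#' @param case_id identifier carried into the result row.
#' @param connected if `TRUE`, keep only the 26-connected suprathreshold
#'   component containing the VOI SUVmax voxel.
#' @return One-row data.frame: case_id, method, level, threshold_suv,
#'   n_voxels, volume_ml.
#' @export
segment_fixed <- function(pet, voi, t, case_id = NA_character_,
                          connected = FALSE) {
  if (!is.finite(t) || t < 0) stop("threshold must be >= 0", call. = FALSE)
  mask <- as_mask(pet, voi)
  seg <- mask & (pet$values >= t)
  if (connected && any(seg)) seg <- main_component(pet, mask, seg)
  new_delineation_result(case_id, "fixed", t, t, sum(seg), voxel_volume_ml(pet))
}

#' Isocontour segmentation relative to the VOI SUVmax
#'
#' Threshold = `fraction` x SUVmax within the VOI, then as [segment_fixed()].
#'
#' @inheritParams segment_fixed
#' @param fraction isocontour level in (0, 1].
#' @return One-row data.frame; `level` is the fraction, `threshold_suv` the
#'   absolute SUV applied.
#' @export
segment_isocontour <- function(pet, voi, fraction, case_id = NA_character_,
                               connected = FALSE) {
  if (!is.finite(fraction) || fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1]", call. = FALSE)
  mask <- as_mask(pet, voi)
  t <- fraction * max(pet$values[mask])
  res <- segment_fixed(pet, mask, t, case_id, connected)
  res$method <- "isocontour"
  res$level <- fraction
  res
}

#' Segmentation at a fraction of a background tissue's SUVmean
#'
#' Threshold = `fraction` x `background_suv`, then as [segment_fixed()].
#'
#' @inheritParams segment_fixed
#' @param background_suv reference-tissue SUVmean (> 0), e.g. from
#'   [roi_mean()].
#' @param fraction threshold fraction (> 0).
#' @param method label stored in the result (e.g. "liver_rel").
#' @return One-row data.frame; `level` is the fraction.
#' @export
segment_background_relative <- function(pet, voi, background_suv, fraction,
                                        case_id = NA_character_,
                                        method = "background_rel",
                                        connected = FALSE) {
  if (!is.finite(background_suv) || background_suv <= 0)
    stop("background_suv must be positive", call. = FALSE)
  if (!is.finite(fraction) || fraction <= 0)
    stop("fraction must be positive", call. = FALSE)
  res <- segment_fixed(pet, voi, fraction * background_suv, case_id, connected)
  res$method <- method
  res$level <- fraction
  res
}

# 26-connected suprathreshold component containing the VOI max voxel.
main_component <- function(pet, voi_mask, seg) {
  d <- dim(seg)
  vals <- pet$values
  vals[!voi_mask] <- -Inf
  start <- arrayInd(which.max(vals), d)
  if (!seg[start]) return(array(FALSE, d))
  lab <- array(FALSE, d)
  queue <- matrix(start, ncol = 3)
  lab[start] <- TRUE
  shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  shifts <- shifts[rowSums(abs(shifts)) > 0, , drop = FALSE]
  while (nrow(queue) > 0) {
    cur <- queue[1, , drop = FALSE]
    queue <- queue[-1, , drop = FALSE]
    nb <- sweep(shifts, 2, cur, `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    nb <- nb[ok, , drop = FALSE]
    for (r in seq_len(nrow(nb))) {
      idx <- nb[r, , drop = FALSE]
      if (seg[idx] && !lab[idx]) {
        lab[idx] <- TRUE
        queue <- rbind(queue, idx)
      }
    }
  }
  lab
}

#' Per-lesion inverse ("backwards") threshold solve
#'
#' Finds the SUV threshold whose segmented VOI volume best matches a target
#' volume (the CT-derived reference). Candidate thresholds are the unique
#' voxel SUVs inside the VOI, over which volume(t) is a non-increasing step
#' function; the candidate minimizing |volume(t) - target| is returned, ties
#' broken toward the larger threshold (the smaller volume). Re-applying the
#' returned threshold with [segment_fixed()] reproduces
#' `achieved_volume_ml` exactly.
#'
#' @param pet a [scalar_volume()].
#' @param voi an [ellipsoid_voi()] or logical mask.
#' @param target_volume_ml target volume in ml; must lie in
#'   (0, full VOI volume].
#' @param case_id identifier carried into the result.
#' @return One-row data.frame: case_id, threshold_suv, achieved_volume_ml,
#'   target_volume_ml.
#' @export
backwards_threshold <- function(pet, voi, target_volume_ml,
                                case_id = NA_character_) {
  mask <- as_mask(pet, voi)
  vv <- voxel_volume_ml(pet)
  suvs <- pet$values[mask]
  full <- length(suvs) * vv
  if (!is.finite(target_volume_ml) || target_volume_ml <= 0 ||
      target_volume_ml > full)
    stop(sprintf("target volume must be in (0, %.4f] ml", full), call. = FALSE)
  cand <- sort(unique(suvs), decreasing = TRUE)
  # volume at threshold cand[k] is k-th cumulative count of the sorted
  # multiset (count of suvs >= cand[k]) times the voxel volume
  counts <- cumsum(tabulate(match(sort(suvs, decreasing = TRUE), cand),
                            nbins = length(cand)))
  vols <- counts * vv
  err <- abs(vols - target_volume_ml)
  best <- which(err == min(err))[1]  # candidates sorted decreasing: first = larger t
  data.frame(case_id = case_id,
             threshold_suv = cand[best],
             achieved_volume_ml = vols[best],
             target_volume_ml = target_volume_ml,
             stringsAsFactors = FALSE)
}

#' Whole-image fixed-threshold tumor volume
#'
#' Total volume of all voxels at or above an absolute SUV threshold outside a
#' set of exclusion masks (physiological-uptake regions). This is the
#' whole-body tumor-volume reading of a fixed cut-off such as SUV 4.0.
#'
#' @param pet a [scalar_volume()].
#' @param t absolute SUV threshold (>= 0).
#' @param exclusion_masks list of logical arrays on the same grid (may be
#'   empty).
#' @return Volume in ml.
#' @export
whole_image_fixed <- function(pet, t, exclusion_masks = list()) {
  stopifnot(inherits(pet, "scalar_volume"))
  if (!is.finite(t) || t < 0) stop("threshold must be >= 0", call. = FALSE)
  excl <- array(FALSE, dim(pet$values))
  for (m in exclusion_masks) {
    if (!is.logical(m) || !identical(dim(m), dim(pet$values)))
      stop("exclusion mask grid mismatch", call. = FALSE)
    excl <- excl | m
  }
  sum(pet$values >= t & !excl) * voxel_volume_ml(pet)
}
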
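#' Default threshold grids for the five delineation families
#'
#' Fixed SUV thresholds 2.5-15.0; isocontour levels 10-75% of SUVmax;
#' background-relative levels 45-75% of liver, 60-90% of parotid and
#' 40-70% of spleen SUVmean. Relative levels are stored as percent.
#'
#' @return Named list of [method_grid()] objects
#'   (fixed, isocontour, liver_rel, parotis_rel, spleen_rel).
#' @export
default_method_grids <- function() {
  list(
    fixed = method_grid("fixed", c(2.5, 3.0, 3.5, 4.0, 4.5, 5.0, 7.5, 10.0, 15.0)),
    isocontour = method_grid("isocontour",
      c(10, 15, 20, 25, 30, 35, 40, 42, 44, 45, 50, 55, 60, 65, 70, 75)),
    liver_rel = method_grid("liver_rel", c(45, 50, 55, 60, 70, 75)),
    parotis_rel = method_grid("parotis_rel", c(60, 70, 75, 80, 85, 90)),
    spleen_rel = method_grid("spleen_rel", c(40, 50, 55, 60, 65, 70)))
}

#' Threshold grid for one delineation family
#'
#' @param family one of "fixed", "isocontour", "liver_rel", "parotis_rel",
#'   "spleen_rel".
#' @param levels strictly increasing grid values: absolute SUV for "fixed",
#'   percent of SUVmax or of background SUVmean otherwise.
#' @return An object of class `method_grid`.
#' @export
method_grid <- function(family, levels) {
  family <- match.arg(family, c("fixed", "isocontour", "liver_rel",
                                "parotis_rel", "spleen_rel"))
  levels <- as.numeric(levels)
  if (length(levels) < 1L || any(diff(levels) <= 0))
    stop("levels must be strictly increasing", call. = FALSE)
  if (any(levels <= 0)) stop("levels must be positive", call. = FALSE)
  structure(list(family = family, levels = levels), class = "method_grid")
}

#' Choose Pearson or Spearman after a Shapiro-Wilk normality gate
#'
#' Pearson is used iff both variables pass the Shapiro-Wilk test at `alpha`;
#' otherwise Spearman.
#'
#' @param x,y numeric vectors, equal length, n >= 4, no missing values.
#' @param alpha gate significance level (default 0.05).
#' @return "pearson" or "spearman".
#' @export
choose_correlation_type <- function(x, y, alpha = 0.05) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(x) < 4) stop("need n >= 4", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("normality test undefined for a constant variable", call. = FALSE)
  px <- stats::shapiro.test(x)$p.value
  py <- stats::shapiro.test(y)$p.value
  if (px > alpha && py > alpha) "pearson" else "spearman"
}

#' Correlate PET-derived volumes with the reference volumes
#'
#' Correlation type is gated by [choose_correlation_type()] unless forced.
#'
#' @param volumes_pet,volumes_ref numeric vectors (ml), equal length, n >= 4.
#' @param alpha normality-gate level.
#' @param type NULL for the gate, or "pearson"/"spearman" to force.
#' @return List: correlation_type, r, r_squared (= r^2), p_value (two-sided),
#'   n.
#' @export
correlate <- function(volumes_pet, volumes_ref, alpha = 0.05, type = NULL) {
  if (length(volumes_pet) != length(volumes_ref))
    stop("length mismatch", call. = FALSE)
  if (length(volumes_pet) < 4) stop("need n >= 4", call. = FALSE)
  if (stats::sd(volumes_pet) == 0 || stats::sd(volumes_ref) == 0)
    stop("correlation undefined: zero variance", call. = FALSE)
  if (is.null(type))
    type <- choose_correlation_type(volumes_pet, volumes_ref, alpha)
  ct <- suppressWarnings(
    stats::cor.test(volumes_pet, volumes_ref, method = type, exact = FALSE))
  r <- unname(ct$estimate)
  list(correlation_type = type, r = r, r_squared = r^2,
       p_value = ct$p.value, n = length(volumes_pet))
}

#' Coefficient of variation in percent
#'
#' 100 x sample standard deviation (n - 1 denominator) / mean.
#'
#' @param values numeric vector, n >= 2, positive mean.
#' @return CoV in percent.
#' @examples
#' coefficient_of_variation(c(1, 2, 3))  # 50
#' @export
coefficient_of_variation <- function(values) {
  if (length(values) < 2) stop("need n >= 2", call. = FALSE)
  m <- mean(values)
  if (!is.finite(m) || m <= 0) stop("mean must be positive", call. = FALSE)
  100 * stats::sd(values) / m
}

#' Bland-Altman agreement between two paired measurements
#'
#' @param a,b numeric vectors (ml), equal length, n >= 2.
#' @return List: mean_diff (mean of a - b), sd_diff, loa (length-2, mean
#'   difference -/+ 1.96 x sd of the differences).
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch", call. = FALSE)
  if (length(a) < 2) stop("need n >= 2", call. = FALSE)
  d <- a - b
  md <- mean(d)
  s <- stats::sd(d)
  list(mean_diff = md, sd_diff = s, loa = c(md - 1.96 * s, md + 1.96 * s))
}

#' Kruskal-Wallis rank-sum comparison of groups
#'
#' Thin wrapper around [stats::kruskal.test()] (tie-corrected H, chi-square
#' p-value). Fully tied data (every observation equal) yields H = 0, p = 1.
#'
#' @param groups list of >= 2 numeric vectors.
#' @return List: H (statistic), df, p_value.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need at least 2 groups", call. = FALSE)
  pooled <- unlist(groups)
  if (length(unique(pooled)) == 1L)  # fully tied data: rank variance is zero
    return(list(H = 0, df = length(groups) - 1L, p_value = 1))
  kt <- stats::kruskal.test(groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value)
}

#' Apply every threshold family and level to every case
#'
#' For each case the VOI SUVmax and the per-case background ROI means are
#' measured once; each grid level is then segmented. Isocontour and
#' background-relative levels (percent) are converted to absolute SUV
#' thresholds per case.
#'
#' @param cases list of [generate_case()] results (class `phantom_case`).
#' @param grids named list of [method_grid()]s (default
#'   [default_method_grids()]).
#' @return Long-form data.frame with one row per case x family x level:
#'   case_id, method, level, threshold_suv, n_voxels, volume_ml.
#' @export
sweep_delineations <- function(cases, grids = default_method_grids()) {
  stopifnot(length(cases) >= 1)
  out <- vector("list", length(cases))
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    stopifnot(inherits(cs, "phantom_case"))
    mask <- rasterize(cs$pet, cs$voi)
    bg <- c(liver_rel = roi_mean(cs$pet, cs$rois$liver),
            parotis_rel = roi_mean(cs$pet, cs$rois$parotis),
            spleen_rel = roi_mean(cs$pet, cs$rois$spleen))
    rows <- lapply(grids, function(g) {
      do.call(rbind, lapply(g$levels, function(lv) {
        switch(g$family,
          fixed = segment_fixed(cs$pet, mask, lv, cs$case_id),
          isocontour = segment_isocontour(cs$pet, mask, lv / 100, cs$case_id),
          segment_background_relative(cs$pet, mask, bg[[g$family]], lv / 100,
                                      cs$case_id, method = g$family))
      }))
    })
    out[[i]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  # keep grid-scale levels (percent) for relative families in the output
  for (g in grids)
    if (g$family != "fixed")
      res$level[res$method == g$family] <- res$level[res$method == g$family] * 100
  res
}

#' Agreement summaries per family and level
#'
#' Correlates each family x level's PET volumes with the reference volumes
#' (Shapiro-Wilk gated Pearson/Spearman) and computes Bland-Altman
#' statistics of PET minus reference.
#'
#' @param results long-form output of [sweep_delineations()].
#' @param ground_truth data.frame with case_id and ct_reference_volume_ml.
#' @return data.frame: method, level, correlation_type, r, r_squared,
#'   p_value, n, ba_mean_diff, ba_loa_low, ba_loa_high.
#' @export
summarize_agreement <- function(results, ground_truth) {
  stopifnot(all(c("case_id", "method", "level", "volume_ml") %in% names(results)),
            all(c("case_id", "ct_reference_volume_ml") %in% names(ground_truth)))
  if (!all(results$case_id %in% ground_truth$case_id))
    stop("case ids in results not found in ground truth", call. = FALSE)
  ref <- stats::setNames(ground_truth$ct_reference_volume_ml,
                         ground_truth$case_id)
  keys <- unique(results[, c("method", "level")])
  rows <- lapply(seq_len(nrow(keys)), function(k) {
    sub <- results[results$method == keys$method[k] &
                     results$level == keys$level[k], ]
    v_pet <- sub$volume_ml
    v_ref <- unname(ref[sub$case_id])
    cr <- tryCatch(correlate(v_pet, v_ref),
                   error = function(e) list(correlation_type = NA_character_,
                                            r = NA_real_, r_squared = NA_real_,
                                            p_value = NA_real_, n = length(v_pet)))
    ba <- bland_altman(v_pet, v_ref)
    data.frame(method = keys$method[k], level = keys$level[k],
               correlation_type = cr$correlation_type, r = cr$r,
               r_squared = cr$r_squared, p_value = cr$p_value, n = cr$n,
               ba_mean_diff = ba$mean_diff, ba_loa_low = ba$loa[1],
               ba_loa_high = ba$loa[2], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Full sweep: delineate every case, then summarize agreement
#'
#' @inheritParams sweep_delineations
#' @param ground_truth data.frame with case_id and ct_reference_volume_ml.
#' @return List with `results` (per case x family x level) and `agreement`
#'   (per family x level).
#' @export
sweep_cohort <- function(cases, ground_truth, grids = default_method_grids()) {
  results <- sweep_delineations(cases, grids)
  list(results = results,
       agreement = summarize_agreement(results, ground_truth))
}

#' Best level per family and overall best method
#'
#' Argmax of r within each family; ties broken toward the lower level.
#'
#' @param summaries output of [summarize_agreement()].
#' @return List with `per_family` (one row per family, at its best level)
#'   and `overall` (single best row).
#' @export
rank_methods <- function(summaries) {
  if (is.null(summaries) || nrow(summaries) == 0)
    stop("no summaries to rank", call. = FALSE)
  pick <- function(df) {
    df <- df[order(df$level), ]
    df[which.max(df$r), , drop = FALSE]  # which.max: first max = lowest level
  }
  per_family <- do.call(rbind, lapply(split(summaries, summaries$method), pick))
  rownames(per_family) <- NULL
  list(per_family = per_family, overall = pick(per_family))
}

#' Summarize per-lesion backwards thresholds and re-apply their mean
#'
#' Computes mean, SD and coefficient of variation of the per-case inverse
#' thresholds, then segments every case at the single mean threshold and
#' correlates the resulting volumes with the reference volumes.
#'
#' @param cases list of `phantom_case`s.
#' @param backwards data.frame from [backwards_threshold()] rows, one per
#'   case (case_id, threshold_suv, ...).
#' @param ground_truth data.frame with case_id and ct_reference_volume_ml.
#' @return List: mean_threshold, sd_threshold, cov_percent,
#'   reapplied_volumes (data.frame case_id, volume_ml), reapplied_agreement
#'   ([correlate()] output, or a list with an `error` message when the
#'   correlation is undefined, e.g. zero variance).
#' @export
backwards_summary <- function(cases, backwards, ground_truth) {
  stopifnot(nrow(backwards) >= 1, length(cases) == nrow(backwards))
  thr <- backwards$threshold_suv
  m <- mean(thr)
  s <- stats::sd(thr)
  cov <- if (length(thr) >= 2) coefficient_of_variation(thr) else NA_real_
  reapplied <- do.call(rbind, lapply(cases, function(cs) {
    r <- segment_fixed(cs$pet, cs$voi, m, cs$case_id)
    data.frame(case_id = cs$case_id, volume_ml = r$volume_ml,
               stringsAsFactors = FALSE)
  }))
  ref <- stats::setNames(ground_truth$ct_reference_volume_ml,
                         ground_truth$case_id)
  agree <- tryCatch(
    correlate(reapplied$volume_ml, unname(ref[reapplied$case_id])),
    error = function(e) list(error = conditionMessage(e)))
  list(mean_threshold = m, sd_threshold = s, cov_percent = cov,
       reapplied_volumes = reapplied, reapplied_agreement = agree)
}
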
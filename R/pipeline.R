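#' Run configuration for the simulate / delineate / evaluate pipeline
#'
#' @param cohort a [cohort_config()].
#' @param grids named list of [method_grid()]s.
#' @param seed master seed; recorded (with a config hash) in the header of
#'   every CSV the pipeline writes.
#' @param rounding list of reporting precisions: `r` (decimals for r and
#'   r^2), `volume` (decimals for ml).
#' @return An object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(), grids = default_method_grids(),
                       seed = cohort$seed, rounding = list(r = 3, volume = 1)) {
  stopifnot(inherits(cohort, "cohort_config"))
  structure(list(cohort = cohort, grids = grids, seed = as.integer(seed),
                 rounding = rounding),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Recognized keys (all optional, defaults as in [cohort_config()] /
#' [background_model()]): `seed`, `n_cases`, `spacing`, `voi_margin_mm`,
#' `volume_median_ml`, `volume_range_ml`, `elongation_range`,
#' `peak_suv_range`, `noise_sd`, `psf_fwhm_mm`, `tissues` (per-tissue
#' `median` + `range`), and `grids` (family -> levels).
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  tis <- function(nm, default) {
    t <- y$tissues[[nm]]
    if (is.null(t)) default
    else list(median = t$median, range = as.numeric(t$range))
  }
  dm <- background_model()
  model <- background_model(
    parotis = tis("parotis", dm$tissues$parotis),
    liver = tis("liver", dm$tissues$liver),
    spleen = tis("spleen", dm$tissues$spleen),
    soft_tissue = tis("soft_tissue", dm$tissues$soft_tissue),
    noise_sd = y$noise_sd %||% dm$noise_sd,
    psf_fwhm_mm = y$psf_fwhm_mm %||% dm$psf_fwhm_mm)
  dc <- cohort_config()
  cohort <- cohort_config(
    n_cases = y$n_cases %||% dc$n_cases,
    volume_median_ml = y$volume_median_ml %||% dc$volume_median_ml,
    volume_range_ml = as.numeric(y$volume_range_ml %||% dc$volume_range_ml),
    elongation_range = as.numeric(y$elongation_range %||% dc$elongation_range),
    peak_suv_range = as.numeric(y$peak_suv_range %||% dc$peak_suv_range),
    model = model,
    spacing = y$spacing %||% dc$spacing,
    voi_margin_mm = y$voi_margin_mm %||% dc$voi_margin_mm,
    seed = y$seed %||% dc$seed)
  grids <- default_method_grids()
  if (!is.null(y$grids))
    for (nm in names(y$grids))
      grids[[nm]] <- method_grid(nm, as.numeric(y$grids[[nm]]))
  run_config(cohort = cohort, grids = grids, seed = cohort$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# 32-bit FNV-1a hash of a config, for run identification in CSV headers.
config_hash <- function(config) {
  s <- paste(utils::capture.output(utils::str(config)), collapse = "\n")
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    # xor on the low byte only (b < 256); h itself can exceed .Machine$integer.max
    h <- h - (h %% 256) + bitwXor(as.integer(h %% 256), as.integer(b %% 256))
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483648) + 0)
}

# CSV writers/readers with a '# suvseg seed=... config=...' header comment.
write_csv_stamped <- function(df, path, seed, hash) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# suvseg seed=%d config=%s", seed, hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline CSV (skipping the seed/config header comment)
#'
#' @param path CSV written by the pipeline.
#' @return data.frame.
#' @export
read_csv_stamped <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Simulate a phantom cohort to disk
#'
#' Writes one NIfTI volume per case, `ground_truth.csv` (case_id,
#' ct_reference_volume_ml, peak_suv, background truths), `geometry.csv`
#' (case_id, cx, cy, cz, ax, ay, az for the lesion VOI, world mm) and a
#' resolved copy of the configuration (`config.yaml`).
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if missing).
#' @return Invisibly, the in-memory cohort (list `cases`, `ground_truth`).
#' @export
run_simulate <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- generate_cohort(config$cohort)
  hash <- config_hash(config)
  for (cs in cohort$cases)
    write_volume(cs$pet, file.path(out_dir, paste0(cs$case_id, ".nii.gz")))
  geom <- do.call(rbind, lapply(cohort$cases, function(cs) {
    data.frame(case_id = cs$case_id,
               cx = cs$voi$center[1], cy = cs$voi$center[2],
               cz = cs$voi$center[3],
               ax = cs$voi$semi_axes[1], ay = cs$voi$semi_axes[2],
               az = cs$voi$semi_axes[3], stringsAsFactors = FALSE)
  }))
  write_csv_stamped(cohort$ground_truth, file.path(out_dir, "ground_truth.csv"),
                    config$seed, hash)
  write_csv_stamped(geom, file.path(out_dir, "geometry.csv"),
                    config$seed, hash)
  cc <- config$cohort
  yaml::write_yaml(list(
    seed = cc$seed, n_cases = cc$n_cases, spacing = cc$spacing,
    voi_margin_mm = cc$voi_margin_mm,
    volume_median_ml = cc$volume_median_ml,
    volume_range_ml = cc$volume_range_ml,
    elongation_range = cc$elongation_range,
    peak_suv_range = cc$peak_suv_range,
    noise_sd = cc$model$noise_sd, psf_fwhm_mm = cc$model$psf_fwhm_mm,
    tissues = lapply(cc$model$tissues, function(t)
      list(median = t$median, range = t$range)),
    grids = lapply(config$grids, function(g) g$levels),
    config_hash = hash),
    file.path(out_dir, "config.yaml"))
  invisible(cohort)
}

#' Load a simulated cohort from disk
#'
#' Reconstructs `phantom_case` objects from the NIfTI volumes, the geometry
#' and ground-truth CSVs and the resolved config written by [run_simulate()].
#'
#' @param cohort_dir directory written by [run_simulate()].
#' @return List with `cases` and `ground_truth`, as [generate_cohort()].
#' @export
load_cohort <- function(cohort_dir) {
  gt_path <- file.path(cohort_dir, "ground_truth.csv")
  if (!file.exists(gt_path))
    stop("no simulated cohort in ", cohort_dir, call. = FALSE)
  gt <- read_csv_stamped(gt_path)
  geom <- read_csv_stamped(file.path(cohort_dir, "geometry.csv"))
  rois <- layout_rois()
  cases <- lapply(seq_len(nrow(gt)), function(i) {
    id <- gt$case_id[i]
    g <- geom[geom$case_id == id, ]
    if (nrow(g) != 1) stop("geometry missing for ", id, call. = FALSE)
    structure(list(
      case_id = id,
      pet = read_volume(file.path(cohort_dir, paste0(id, ".nii.gz"))),
      voi = ellipsoid_voi(c(g$cx, g$cy, g$cz), c(g$ax, g$ay, g$az)),
      ct_reference_volume_ml = gt$ct_reference_volume_ml[i],
      background_suvs = c(parotis = gt$suv_parotis[i], liver = gt$suv_liver[i],
                          spleen = gt$suv_spleen[i],
                          soft_tissue = gt$suv_soft_tissue[i]),
      rois = rois,
      lesion = NULL, post_blur_max = NA_real_),
      class = "phantom_case")
  })
  list(cases = cases, ground_truth = gt)
}

#' Delineate a simulated cohort
#'
#' Runs [sweep_delineations()] over all grids, solves the per-case backwards
#' threshold against the ground-truth volume, and re-applies the cohort mean
#' backwards threshold to every case. Writes `results.csv`, `backwards.csv`
#' and `reapplied.csv` so that [run_evaluate()] needs no image access.
#'
#' @param cohort_dir directory written by [run_simulate()] (or an in-memory
#'   cohort list from [generate_cohort()]).
#' @param out_dir output directory (default: `cohort_dir`).
#' @param grids named list of [method_grid()]s.
#' @param families optional character subset of grid families to run.
#' @param seed seed recorded in output headers (default: from config.yaml
#'   when present, else 0).
#' @return Invisibly, list of the three data.frames.
#' @export
run_delineate <- function(cohort_dir, out_dir = NULL,
                          grids = default_method_grids(), families = NULL,
                          seed = NULL) {
  if (is.character(cohort_dir)) {
    cohort <- load_cohort(cohort_dir)
    if (is.null(out_dir)) out_dir <- cohort_dir
    if (is.null(seed)) {
      cfg <- file.path(cohort_dir, "config.yaml")
      seed <- if (file.exists(cfg)) yaml::read_yaml(cfg)$seed %||% 0L else 0L
    }
  } else {
    cohort <- cohort_dir
    if (is.null(out_dir)) stop("out_dir required for in-memory cohorts",
                               call. = FALSE)
    if (is.null(seed)) seed <- 0L
  }
  if (!is.null(families)) {
    if (!length(families) || !all(families %in% names(grids)))
      stop("unknown or empty family selection", call. = FALSE)
    grids <- grids[families]
  }
  if (!length(grids)) stop("empty grid list", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(grids)

  results <- sweep_delineations(cohort$cases, grids)
  gt <- cohort$ground_truth
  backwards <- do.call(rbind, lapply(cohort$cases, function(cs) {
    target <- gt$ct_reference_volume_ml[gt$case_id == cs$case_id]
    backwards_threshold(cs$pet, cs$voi, target, cs$case_id)
  }))
  mean_thr <- mean(backwards$threshold_suv)
  reapplied <- do.call(rbind, lapply(cohort$cases, function(cs) {
    r <- segment_fixed(cs$pet, cs$voi, mean_thr, cs$case_id)
    data.frame(case_id = cs$case_id, threshold_suv = mean_thr,
               volume_ml = r$volume_ml, stringsAsFactors = FALSE)
  }))
  write_csv_stamped(results, file.path(out_dir, "results.csv"), seed, hash)
  write_csv_stamped(backwards, file.path(out_dir, "backwards.csv"), seed, hash)
  write_csv_stamped(reapplied, file.path(out_dir, "reapplied.csv"), seed, hash)
  invisible(list(results = results, backwards = backwards,
                 reapplied = reapplied))
}

#' Evaluate delineation results against the ground truth
#'
#' Pure CSV -> CSV stage: computes agreement summaries per family and level,
#' the method ranking, and the backwards-thresholding summary, and writes
#' `agreement.csv`, `ranking.csv`, `backwards_summary.csv` and a markdown
#' `report.md` laid out like the method tables (method, r, r^2, p).
#'
#' @param results_csv path to `results.csv` from [run_delineate()].
#' @param truth_csv path to `ground_truth.csv` from [run_simulate()].
#' @param out_dir output directory.
#' @param backwards_csv,reapplied_csv optional paths (default: siblings of
#'   `results_csv`); when present the backwards summary is included.
#' @param rounding list(r =, volume =) decimals for the report.
#' @param seed seed recorded in output headers; by default inherited from
#'   the header comment of `results_csv`.
#' @return Invisibly, list(agreement, ranking, backwards).
#' @export
run_evaluate <- function(results_csv, truth_csv, out_dir,
                         backwards_csv = file.path(dirname(results_csv), "backwards.csv"),
                         reapplied_csv = file.path(dirname(results_csv), "reapplied.csv"),
                         rounding = list(r = 3, volume = 1), seed = NULL) {
  if (is.null(seed)) {  # inherit the seed stamped by the delineation stage
    first <- readLines(results_csv, n = 1)
    m <- regmatches(first, regexec("seed=([0-9]+)", first))[[1]]
    seed <- if (length(m) == 2) as.integer(m[2]) else 0L
  }
  results <- read_csv_stamped(results_csv)
  gt <- read_csv_stamped(truth_csv)
  if (!all(results$case_id %in% gt$case_id) ||
      !all(gt$case_id %in% results$case_id))
    stop("case-id mismatch between results and ground truth", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(list(results, gt))  # content, not paths: stable across runs

  agreement <- summarize_agreement(results, gt)
  ranking <- rank_methods(agreement)
  write_csv_stamped(agreement, file.path(out_dir, "agreement.csv"), seed, hash)
  write_csv_stamped(cbind(scope = c(rep("family", nrow(ranking$per_family)),
                                    "overall"),
                          rbind(ranking$per_family, ranking$overall)),
                    file.path(out_dir, "ranking.csv"), seed, hash)

  bw <- NULL
  if (file.exists(backwards_csv) && file.exists(reapplied_csv)) {
    backwards <- read_csv_stamped(backwards_csv)
    reapplied <- read_csv_stamped(reapplied_csv)
    thr <- backwards$threshold_suv
    ref <- stats::setNames(gt$ct_reference_volume_ml, gt$case_id)
    agree <- tryCatch(
      correlate(reapplied$volume_ml, unname(ref[reapplied$case_id])),
      error = function(e) list(correlation_type = NA_character_, r = NA_real_,
                               r_squared = NA_real_, p_value = NA_real_,
                               n = nrow(reapplied), error = conditionMessage(e)))
    bw <- data.frame(
      mean_threshold = mean(thr), sd_threshold = stats::sd(thr),
      cov_percent = coefficient_of_variation(thr),
      reapplied_r = agree$r, reapplied_r_squared = agree$r_squared,
      reapplied_p = agree$p_value,
      reapplied_type = agree$correlation_type %||% NA_character_,
      stringsAsFactors = FALSE)
    write_csv_stamped(bw, file.path(out_dir, "backwards_summary.csv"),
                      seed, hash)
  }
  writeLines(render_report(agreement, ranking, bw, rounding, seed, hash),
             file.path(out_dir, "report.md"))
  invisible(list(agreement = agreement, ranking = ranking, backwards = bw))
}

format_p <- function(p) ifelse(p < 0.001, "p<0.001", sprintf("p=%.3f", p))

render_report <- function(agreement, ranking, bw, rounding, seed, hash) {
  rd <- rounding$r %||% 3
  fam_titles <- c(fixed = "Fixed SUV thresholds",
                  isocontour = "Isocontour relative to SUVmax",
                  liver_rel = "Thresholds relative to liver SUVmean",
                  parotis_rel = "Thresholds relative to parotid SUVmean",
                  spleen_rel = "Thresholds relative to spleen SUVmean")
  lab <- function(m, lv) switch(m,
    fixed = sprintf("SUV %.1f", lv),
    isocontour = sprintf("Iso %g%%", lv),
    liver_rel = sprintf("%g%% SUV_liver", lv),
    parotis_rel = sprintf("%g%% SUV_parotis", lv),
    spleen_rel = sprintf("%g%% SUV_spleen", lv))
  out <- c("# Volumetric delineation report", "",
           sprintf("seed: %d, config: %s", seed, hash), "")
  for (m in intersect(names(fam_titles), unique(agreement$method))) {
    sub <- agreement[agreement$method == m, ]
    sub <- sub[order(sub$level), ]
    out <- c(out, sprintf("## %s", fam_titles[[m]]), "",
             "| Parameter | r | r^2 | Significance |",
             "|---|---|---|---|",
             sprintf("| %s | %s | %s | %s |",
                     mapply(lab, sub$method, sub$level),
                     formatC(round(sub$r, rd), format = "f", digits = rd),
                     formatC(round(sub$r_squared, rd), format = "f", digits = rd),
                     format_p(sub$p_value)),
             "")
  }
  best <- ranking$overall
  out <- c(out, "## Ranking", "",
           sprintf("Best per family: %s.",
                   paste(sprintf("%s (r=%s)", mapply(lab,
                         ranking$per_family$method, ranking$per_family$level),
                         formatC(round(ranking$per_family$r, rd),
                                 format = "f", digits = rd)),
                         collapse = "; ")),
           sprintf("Best overall: %s (r=%s).", lab(best$method, best$level),
                   formatC(round(best$r, rd), format = "f", digits = rd)), "")
  if (!is.null(bw)) {
    out <- c(out, "## Individual backwards thresholding", "",
             "| Quantity | Value |", "|---|---|",
             sprintf("| Mean +/- SD threshold (SUV) | %.1f +/- %.1f |",
                     bw$mean_threshold, bw$sd_threshold),
             sprintf("| Coefficient of variation | %.1f%% |", bw$cov_percent),
             if (is.na(bw$reapplied_r))
               "| Reapplied mean threshold | correlation undefined |"
             else sprintf("| Reapplied mean threshold | r=%s, r^2=%s, %s |",
                          formatC(round(bw$reapplied_r, rd), format = "f",
                                  digits = rd),
                          formatC(round(bw$reapplied_r_squared, rd),
                                  format = "f", digits = rd),
                          format_p(bw$reapplied_p)),
             "")
  }
  out
}
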
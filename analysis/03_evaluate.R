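#!/usr/bin/env Rscript
# Stage 3: volumetric agreement against the ground truth.
#
# Computes the per-level agreement summaries (Shapiro-Wilk gated
# Pearson/Spearman r, r^2, p; Bland-Altman mean difference and limits of
# agreement), ranks the families, summarizes the backwards thresholds, and
# renders report.md. Pass --plots to also write per-family scatter and
# Bland-Altman figures (requires ggplot2).
#
# Usage: Rscript analysis/03_evaluate.R [out_root] [--plots]

suppressPackageStartupMessages(library(suvseg))

args <- commandArgs(trailingOnly = TRUE)
plots <- "--plots" %in% args
args <- setdiff(args, "--plots")
out_root <- if (length(args) >= 1) args[1] else "results"
cohort_dir <- file.path(out_root, "cohort")
eval_dir <- file.path(out_root, "evaluation")

ev <- run_evaluate(file.path(cohort_dir, "results.csv"),
                   file.path(cohort_dir, "ground_truth.csv"), eval_dir)

rk <- ev$ranking
lab <- function(row) sprintf("%s @ %g (r=%.3f)", row$method, row$level, row$r)
message("Best level per family:")
for (i in seq_len(nrow(rk$per_family))) message("  ", lab(rk$per_family[i, ]))
message("Best overall: ", lab(rk$overall))
if (!is.null(ev$backwards))
  message(sprintf(
    "Backwards thresholds: mean %.2f SUV, CoV %.1f%%, reapplied r=%.3f",
    ev$backwards$mean_threshold, ev$backwards$cov_percent,
    ev$backwards$reapplied_r))

if (plots && requireNamespace("ggplot2", quietly = TRUE)) {
  fig_dir <- file.path(out_root, "figures")
  dir.create(fig_dir, recursive = TRUE, showWarnings = FALSE)
  results <- read_csv_stamped(file.path(cohort_dir, "results.csv"))
  gt <- read_csv_stamped(file.path(cohort_dir, "ground_truth.csv"))
  for (i in seq_len(nrow(rk$per_family))) {
    m <- rk$per_family$method[i]; lv <- rk$per_family$level[i]
    ggplot2::ggsave(file.path(fig_dir, sprintf("scatter_%s.png", m)),
                    plot_agreement(results, gt, m, lv), width = 4, height = 4)
    ggplot2::ggsave(file.path(fig_dir, sprintf("bland_altman_%s.png", m)),
                    plot_bland_altman(results, gt, m, lv),
                    width = 4, height = 4)
  }
  message("Figures written to ", fig_dir)
}
message("Evaluation written to ", eval_dir)
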
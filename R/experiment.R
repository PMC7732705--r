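#' Configuration for the two-factor factorial experiment
#'
#' Defines the 2 x 2 design: capture model (profilometer vs intraoral) x
#' alignment strategy (best-fit vs feature-trimmed), run on a synthetic
#' cohort with known ground truth. The Bonferroni family defaults to 6
#' comparisons: the scanner contrast within each of the two strategies, for
#' each of the three outcome metrics (2 x 3 = 6, giving the corrected level
#' 0.05/6, printed as .008). The family is declared explicitly here and `m`
#' is simply its length, so a different family can be configured.
#'
#' @param n_surfaces cohort size (30 mirrors the patient count of a typical
#'   monitoring cohort; use 76 for a surface-count-matched run).
#' @param seed master seed.
#' @param capture_models,strategies factor levels of the design.
#' @param family_alpha family-wise significance level.
#' @param comparisons data.frame with columns `metric`
#'   (`volume_change_mm3`, `max_point_loss_um`, `mean_profile_loss_um`),
#'   `contrast` (`"scanner"` or `"strategy"`), and `within` (the level of
#'   the other factor the contrast is nested in); NULL for the default 6.
#' @param alignment_seed seed offset for alignment sampling.
#' @param cohort_args extra arguments passed to [generate_cohort()].
#' @return object of class `factorial_config`.
#' @export
factorial_config <- function(n_surfaces = 30, seed = 1L,
                             capture_models = c("profilometer", "intraoral"),
                             strategies = c("bestfit", "feature_trimmed"),
                             family_alpha = 0.05,
                             comparisons = NULL,
                             alignment_seed = 7L,
                             cohort_args = list()) {
  if (is.null(comparisons)) {
    comparisons <- expand.grid(
      metric = c("volume_change_mm3", "max_point_loss_um",
                 "mean_profile_loss_um"),
      contrast = "scanner",
      within = strategies,
      stringsAsFactors = FALSE
    )
  }
  stopifnot(nrow(comparisons) >= 1, length(capture_models) >= 1,
            length(strategies) >= 1)
  structure(list(n_surfaces = n_surfaces, seed = as.integer(seed),
                 capture_models = capture_models, strategies = strategies,
                 family_alpha = family_alpha, comparisons = comparisons,
                 alignment_seed = as.integer(alignment_seed),
                 cohort_args = cohort_args),
            class = "factorial_config")
}

#' Run the full factorial study on a synthetic cohort
#'
#' Simulates the cohort, aligns each follow-up to its baseline in every
#' capture-model x strategy cell, measures the wear outcomes, and computes
#' the statistical layer: per-cell median (IQR) summaries, the truncated
#' (positives-to-zero) volume summary, paired Wilcoxon signed-rank tests at
#' the Bonferroni-corrected level, single-measures ICCs between scanners
#' within each strategy and between strategies within each scanner, and a
#' ground-truth audit (per-cell volume bias, RMSE, fraction of
#' physiologically impossible positive volumes). Surfaces failing alignment
#' (degenerate-alignment error) are excluded and counted, never imputed.
#' Fully deterministic given the seed.
#'
#' @param cfg a [factorial_config()].
#' @param progress print per-surface progress.
#' @return object of class `factorial_result` with elements `long`
#'   (surface x cell table), `summary`, `truncated_summary`, `tests`,
#'   `icc`, `audit`, `failures`, `ground_truth`, `config`.
#' @export
run_factorial <- function(cfg = factorial_config(), progress = FALSE) {
  cohort <- do.call(generate_cohort, c(
    list(n_surfaces = cfg$n_surfaces, seed = cfg$seed,
         capture_models = cfg$capture_models),
    cfg$cohort_args
  ))
  rows <- list()
  failures <- data.frame(surface_id = character(), scanner = character(),
                         strategy = character(), error = character(),
                         stringsAsFactors = FALSE)
  for (b in cohort$bundles) {
    if (progress) message("surface ", b$surface_id)
    for (cm in cfg$capture_models) {
      pair <- b$scans[[cm]]
      for (st in cfg$strategies) {
        acfg <- alignment_config(st, seed = derive_seed(cfg$alignment_seed,
                                                        length(rows) + 1))
        res <- tryCatch({
          al <- align_pair(pair$baseline, pair$followup, st, acfg)
          wr <- measure_wear(pair$baseline, al$aligned,
                             surface_id = b$surface_id, scanner = cm,
                             software_strategy = st)
          df <- as.data.frame(wr)
          df$rms_um <- al$report$rms_um
          df$iterations <- al$report$iterations
          df
        }, error = function(e) e)
        if (inherits(res, "error")) {
          failures <- rbind(failures, data.frame(
            surface_id = b$surface_id, scanner = cm, strategy = st,
            error = conditionMessage(res), stringsAsFactors = FALSE))
        } else {
          rows[[length(rows) + 1]] <- res
        }
      }
    }
  }
  long <- do.call(rbind, rows)
  result <- structure(list(long = long, failures = failures,
                           ground_truth = cohort$ground_truth, config = cfg),
                      class = "factorial_result")
  result$summary <- summarize_cells(long)
  result$truncated_summary <- summarize_cells(long, truncated = TRUE)
  result$tests <- run_family_tests(long, cfg)
  result$icc <- run_iccs(long, cfg)
  result$audit <- audit_against_truth(result, cohort$ground_truth)
  result
}

summarize_cells <- function(long, truncated = FALSE) {
  metrics <- if (truncated) "truncated_volume_mm3" else
    c("volume_change_mm3", "max_point_loss_um", "mean_profile_loss_um")
  out <- list()
  for (cm in unique(long$scanner)) {
    for (st in unique(long$strategy)) {
      sel <- long$scanner == cm & long$strategy == st
      if (!any(sel)) next
      for (m in metrics) {
        q <- median_iqr(long[[m]][sel])
        out[[length(out) + 1]] <- data.frame(
          scanner = cm, strategy = st, metric = m, n = sum(sel),
          median = q["median"], q1 = q["q1"], q3 = q["q3"],
          row.names = NULL, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

run_family_tests <- function(long, cfg) {
  m <- nrow(cfg$comparisons)
  corrected <- bonferroni_alpha(cfg$family_alpha, m)
  out <- list()
  for (i in seq_len(m)) {
    cmp <- cfg$comparisons[i, ]
    if (cmp$contrast == "scanner") {
      lv <- cfg$capture_models[1:2]
      a <- long[long$strategy == cmp$within & long$scanner == lv[1], ]
      b <- long[long$strategy == cmp$within & long$scanner == lv[2], ]
    } else {
      lv <- cfg$strategies[1:2]
      a <- long[long$scanner == cmp$within & long$strategy == lv[1], ]
      b <- long[long$scanner == cmp$within & long$strategy == lv[2], ]
    }
    ids <- intersect(a$surface_id, b$surface_id)
    x <- a[[cmp$metric]][match(ids, a$surface_id)]
    y <- b[[cmp$metric]][match(ids, b$surface_id)]
    tst <- if (length(ids) >= 5) {
      wilcoxon_signed_rank(x, y, alpha = corrected)
    } else {
      structure(list(statistic = NA, p_value = NA, n_effective = length(ids),
                     method = "insufficient_n", significant_at = corrected,
                     degenerate = TRUE), class = "signed_rank_test")
    }
    out[[i]] <- data.frame(
      metric = cmp$metric, contrast = cmp$contrast, within = cmp$within,
      level_a = lv[1], level_b = lv[2], n = length(ids),
      W = tst$statistic, p_value = tst$p_value,
      corrected_alpha = corrected,
      significant = !is.na(tst$p_value) && tst$p_value < corrected,
      method = tst$method, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

run_iccs <- function(long, cfg) {
  out <- list()
  add <- function(label, a, b) {
    ids <- intersect(a$surface_id, b$surface_id)
    if (length(ids) < 5) return()
    x <- a$volume_change_mm3[match(ids, a$surface_id)]
    y <- b$volume_change_mm3[match(ids, b$surface_id)]
    r <- icc_single(x, y)
    out[[length(out) + 1]] <<- data.frame(
      comparison = label, icc = r$estimate,
      ci_lower = r$ci[1], ci_upper = r$ci[2], n = r$n,
      row.names = NULL, stringsAsFactors = FALSE)
  }
  if (length(cfg$capture_models) >= 2) {
    for (st in cfg$strategies) {
      add(paste0("scanners within ", st),
          long[long$strategy == st & long$scanner == cfg$capture_models[1], ],
          long[long$strategy == st & long$scanner == cfg$capture_models[2], ])
    }
  }
  if (length(cfg$strategies) >= 2) {
    for (cm in cfg$capture_models) {
      add(paste0("strategies within ", cm),
          long[long$scanner == cm & long$strategy == cfg$strategies[1], ],
          long[long$scanner == cm & long$strategy == cfg$strategies[2], ])
    }
  }
  if (length(out) == 0) return(NULL)
  do.call(rbind, out)
}

#' Audit measured volumes against simulation ground truth
#'
#' Per design cell: signed bias `mean(measured - (-true_volume))`, RMSE,
#' and the fraction of surfaces reporting a positive (physiologically
#' impossible) volume change.
#'
#' @param result a `factorial_result` (or its `long` table).
#' @param ground_truth the cohort ground-truth data.frame
#'   (`surface_id`, `true_volume_mm3`).
#' @return data.frame with one row per cell.
#' @export
audit_against_truth <- function(result, ground_truth) {
  long <- if (inherits(result, "factorial_result")) result$long else result
  if (!all(long$surface_id %in% ground_truth$surface_id)) {
    stop("audit_against_truth: surfaces missing from ground truth")
  }
  truth <- -ground_truth$true_volume_mm3[match(long$surface_id,
                                               ground_truth$surface_id)]
  err <- long$volume_change_mm3 - truth
  out <- list()
  for (cm in unique(long$scanner)) {
    for (st in unique(long$strategy)) {
      sel <- long$scanner == cm & long$strategy == st
      if (!any(sel)) next
      out[[length(out) + 1]] <- data.frame(
        scanner = cm, strategy = st, n = sum(sel),
        bias_mm3 = mean(err[sel]),
        rmse_mm3 = sqrt(mean(err[sel]^2)),
        frac_positive_volume = mean(long$volume_change_mm3[sel] > 0),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Render a human-readable study report
#'
#' Emits a markdown summary: the per-cell median (IQR) table for each raw
#' metric, the truncated-volume table (the positives-to-zero secondary
#' analysis), the paired comparisons with their Bonferroni-corrected
#' level, ICCs, and the ground-truth audit.
#'
#' @param result a `factorial_result`.
#' @param path optional file to write; the lines are returned invisibly.
#' @return character vector of markdown lines, invisibly.
#' @export
render_report <- function(result, path = NULL) {
  stopifnot(inherits(result, "factorial_result"))
  if (is.null(result$long) || nrow(result$long) == 0) {
    stop("render_report: empty result")
  }
  fmt_mi <- function(r) sprintf("%.2f (%.2f to %.2f)", r$median, r$q1, r$q3)
  lines <- c("# Synthetic factorial wear study", "")
  lines <- c(lines, sprintf("Surfaces: %d; failed alignments: %d",
                            length(unique(result$long$surface_id)),
                            nrow(result$failures)), "")
  for (m in unique(result$summary$metric)) {
    lines <- c(lines, paste0("## ", m), "",
               "| scanner | strategy | median (IQR) |",
               "|---|---|---|")
    s <- result$summary[result$summary$metric == m, ]
    for (i in seq_len(nrow(s))) {
      lines <- c(lines, sprintf("| %s | %s | %s |", s$scanner[i],
                                s$strategy[i], fmt_mi(s[i, ])))
    }
    lines <- c(lines, "")
  }
  lines <- c(lines, "## Truncated volumes (positives set to zero)", "",
             "| scanner | strategy | median (IQR) |", "|---|---|---|")
  s <- result$truncated_summary
  for (i in seq_len(nrow(s))) {
    lines <- c(lines, sprintf("| %s | %s | %s |", s$scanner[i],
                              s$strategy[i], fmt_mi(s[i, ])))
  }
  tst <- result$tests
  lines <- c(lines, "", sprintf("## Paired comparisons (corrected alpha %.3f)",
                                tst$corrected_alpha[1]), "",
             "| metric | contrast | within | W | p | significant |",
             "|---|---|---|---|---|---|")
  for (i in seq_len(nrow(tst))) {
    lines <- c(lines, sprintf("| %s | %s | %s | %g | %.4g | %s |",
                              tst$metric[i], tst$contrast[i], tst$within[i],
                              tst$W[i], tst$p_value[i],
                              ifelse(tst$significant[i], "yes", "no")))
  }
  if (!is.null(result$icc)) {
    lines <- c(lines, "", "## Intraclass correlation (volume change)", "",
               "| comparison | ICC | 95% CI |", "|---|---|---|")
    for (i in seq_len(nrow(result$icc))) {
      lines <- c(lines, sprintf("| %s | %.3f | %.3f-%.3f |",
                                result$icc$comparison[i], result$icc$icc[i],
                                result$icc$ci_lower[i], result$icc$ci_upper[i]))
    }
  }
  lines <- c(lines, "", "## Ground-truth audit (volume)", "",
             "| scanner | strategy | bias (mm^3) | RMSE (mm^3) | % positive |",
             "|---|---|---|---|---|")
  a <- result$audit
  for (i in seq_len(nrow(a))) {
    lines <- c(lines, sprintf("| %s | %s | %+.3f | %.3f | %.0f%% |",
                              a$scanner[i], a$strategy[i], a$bias_mm3[i],
                              a$rmse_mm3[i], 100 * a$frac_positive_volume[i]))
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' @export
print.factorial_result <- function(x, ...) {
  cat(render_report(x), sep = "\n")
  invisible(x)
}
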
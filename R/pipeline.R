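fmt1 <- function(x) formatC(round_half_up(x, 1), format = "f", digits = 1)

count_pct <- function(k, n) sprintf("%d (%s)", k, fmt1(100 * k / n))

mean_sd <- function(x) {
  if (length(x) < 2) return(sprintf("%s (SD undefined)", fmt1(mean(x))))
  sprintf("%s ± %s", fmt1(mean(x)), fmt1(stats::sd(x)))
}

med_iqr <- function(x) {
  # linear-interpolation quantiles (type 7), stated in the report footer
  q <- stats::quantile(x, c(0.5, 0.25, 0.75), type = 7, names = FALSE)
  sprintf("%s (%s; %s)", fmt1(q[1]), fmt1(q[2]), fmt1(q[3]))
}

#' Cohort characteristics table stratified by a covariate
#'
#' Produces a baseline-characteristics table: continuous fields as
#' mean +/- SD (median with quartiles for the skewed CAC scores), counts
#' with percentages computed within column, and the progression-class
#' counts, for the whole cohort and within each level of `by`.
#'
#' @param pheno phenotype table.
#' @param classes progression classification (`id`, `class`), or `NULL`.
#' @param by stratifying phenotype column (default `"hmgri"`).
#' @return data.frame of formatted cells, one row per characteristic; the
#'   quantile convention is recorded in attribute `"footer"`.
#' @export
summarize_cohort <- function(pheno, classes = NULL, by = "hmgri") {
  if (!by %in% names(pheno)) stop_invalid("unknown `by` column '%s'", by)
  cl <- if (!is.null(classes)) classes$class[match(pheno$id, classes$id)]
  groups <- c(list(All = rep(TRUE, nrow(pheno))),
              lapply(stats::setNames(nm = sort(unique(pheno[[by]]))),
                     function(lv) pheno[[by]] == lv))
  names(groups)[-1] <- paste0(by, "=", names(groups)[-1])
  one_col <- function(sel) {
    p <- pheno[sel, , drop = FALSE]
    n <- nrow(p)
    rows <- c(N = as.character(n),
              `Age (years)` = mean_sd(p$age),
              Women = count_pct(sum(p$sex == "F"), n),
              `Use of HMGRIs` = count_pct(sum(p$hmgri), n),
              `CAC score at baseline` = med_iqr(p$cac_b),
              `CAC score at first follow-up` = med_iqr(p$cac_5y),
              `Follow-up (years)` = mean_sd(p$dt_years))
    if ("dm" %in% names(p)) rows <- c(rows, Diabetes = count_pct(sum(p$dm), n))
    if (!is.null(cl)) {
      cc <- cl[sel]
      rows <- c(rows,
                `Slow progression of CAC` = count_pct(sum(cc == "slow"), n),
                `Expected progression of CAC` = count_pct(sum(cc == "expected"), n),
                `Rapid progression of CAC` = count_pct(sum(cc == "rapid"), n))
    }
    rows
  }
  cols <- lapply(groups, one_col)
  out <- data.frame(characteristic = names(cols[[1]]), cols,
                    check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "footer") <-
    "count (percentage, half-up to 1 decimal); mean +/- SD; median (Q1; Q3), linear-interpolation quantiles"
  out
}

fit_to_df <- function(fit) {
  data.frame(term = names(fit$coefficients), estimate = fit$coefficients,
             robust_se = fit$se, rr = fit$rr, ci_low = fit$ci_low,
             ci_high = fit$ci_high, p = fit$p_value,
             row.names = NULL, stringsAsFactors = FALSE)
}

try_fit <- function(expr) {
  res <- try(expr, silent = TRUE)
  if (inherits(res, "try-error")) {
    list(failed = TRUE, message = attr(res, "condition")$message)
  } else res
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Simulate genotypes and phenotypes, apply genotype QC, score the genetic
#' risk, construct the rapid-progression outcome, fit the three
#' relative-risk models, the statin-stratified analysis and (optionally)
#' the full SNP interaction scan, and assemble a report.
#'
#' Two outcome modes: `"mechanistic"` classifies progression from the
#' simulated CAC trajectories via the percentile model; `"reduced_form"`
#' draws the binary outcome directly from the log-linear risk model with
#' the configured true relative risks (exactly known truth, used for
#' calibration), with the baseline risk solved so the marginal prevalence
#' equals `config$rapid_prevalence`.
#'
#' @param config a [cohort_config()].
#' @param panel scoring panel (default: bundled diabetes panel).
#' @param mode `"reduced_form"` or `"mechanistic"`.
#' @param band_frac classification band fraction (mechanistic mode).
#' @param alpha family-wise error rate for the scan.
#' @param scan fit the per-SNP interaction scan (slower).
#' @param out_dir if non-NULL, persist all intermediates under this
#'   directory (dosage TSV, VCF, phenotype CSV, truth JSON, QC, scores,
#'   progression, association tables, report JSON).
#' @return list of class `cohort_report`.
#' @export
run_cohort_analysis <- function(config = cohort_config(),
                                panel = dm_snp_panel(),
                                mode = c("reduced_form", "mechanistic"),
                                band_frac = 0.2, alpha = 0.05,
                                scan = FALSE, out_dir = NULL) {
  mode <- match.arg(mode)
  cohort <- simulate_cohort(config, panel)
  pheno <- cohort$phenotypes

  qc <- apply_qc(cohort$genotypes)
  keep_ids <- rownames(qc$genotypes)
  pheno <- pheno[match(keep_ids, pheno$id), , drop = FALSE]
  panel_kept <- panel[panel$snp_id %in% colnames(qc$genotypes), , drop = FALSE]

  scores <- grs_score(qc$genotypes, panel_kept)
  grs_z <- scores$std_grs

  lrr <- config$true_log_rr
  prog <- NULL
  if (mode == "mechanistic") {
    prog <- try_fit(cac_progression(pheno, band_frac = band_frac))
    if (isTRUE(prog$failed)) stop_invalid("progression stage failed: %s",
                                          prog$message)
    classes <- prog[, c("id", "class")]
  } else {
    eta <- lrr[["hmgri"]] * pheno$hmgri + lrr[["grs_per_sd"]] * grs_z +
      lrr[["interaction"]] * pheno$hmgri * grs_z
    base <- config$rapid_prevalence / mean(exp(eta))
    y <- simulate_binary_outcome(cbind(hmgri = pheno$hmgri, grs = grs_z,
                                       int = pheno$hmgri * grs_z),
                                 unname(lrr), base,
                                 seed = substream_seed(config$seed, "outcome"))
    classes <- data.frame(id = pheno$id,
                          class = ifelse(y == 1, "rapid", "expected"),
                          stringsAsFactors = FALSE)
  }

  fits <- list(
    model1 = try_fit(fit_rr_model(build_design(1, pheno, grs_z, classes))),
    model2 = try_fit(fit_rr_model(build_design(2, pheno, classes = classes))),
    model3 = try_fit(fit_rr_model(build_design(3, pheno, grs_z, classes))))
  strat <- stratified_analysis(pheno, grs_z, classes, "hmgri")
  scan_res <- if (scan) {
    interaction_scan(pheno, qc$genotypes, panel_kept, grs_z, classes, alpha)
  }

  report <- list(
    config = config, mode = mode,
    provenance = list(seed = config$seed,
                      package_version = as.character(utils::packageVersion("cacgrs"))),
    qc = qc$report,
    n_analyzed = nrow(pheno),
    rapid_prevalence = mean(classes$class == "rapid"),
    class_counts = table(factor(classes$class,
                                levels = c("slow", "expected", "rapid"))),
    grs_summary = c(mean_raw = mean(scores$raw_grs),
                    sd_raw = stats::sd(scores$raw_grs)),
    models = fits, stratified = strat, scan = scan_res,
    summary_table = summarize_cohort(pheno, classes, by = "hmgri"),
    truth = cohort$truth)
  class(report) <- "cohort_report"

  if (!is.null(out_dir)) {
    persist_report(report, cohort, qc, scores, prog, classes, out_dir)
  }
  report
}

persist_report <- function(report, cohort, qc, scores, prog, classes,
                           out_dir) {
  dirs <- file.path(out_dir, c("cohort", "qc", "assoc"))
  for (d in dirs) dir.create(d, recursive = TRUE, showWarnings = FALSE)
  write_dosage_tsv(cohort$genotypes, file.path(out_dir, "cohort", "dosages.tsv"))
  utils::write.csv(cohort$phenotypes,
                   file.path(out_dir, "cohort", "phenotypes.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(report$truth,
                       file.path(out_dir, "cohort", "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.table(qc$report$snps, file.path(out_dir, "qc", "snps.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(qc$report$samples, file.path(out_dir, "qc", "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(scores, file.path(out_dir, "scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(prog) && !isTRUE(prog$failed)) {
    utils::write.table(prog, file.path(out_dir, "progression.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (nm in names(report$models)) {
    f <- report$models[[nm]]
    if (!isTRUE(f$failed)) {
      utils::write.table(fit_to_df(f),
                         file.path(out_dir, "assoc", paste0(nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  if (!is.null(report$scan)) {
    utils::write.table(report$scan, file.path(out_dir, "assoc", "scan.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  rep_json <- list(
    mode = report$mode, provenance = report$provenance,
    n_analyzed = report$n_analyzed,
    rapid_prevalence = report$rapid_prevalence,
    class_counts = as.list(report$class_counts),
    models = lapply(report$models, function(f) {
      if (isTRUE(f$failed)) list(failed = TRUE, message = f$message)
      else fit_to_df(f)
    }))
  jsonlite::write_json(rep_json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("Cohort analysis (%s mode): %d participants analyzed\n",
              x$mode, x$n_analyzed))
  cat(sprintf("Rapid progression prevalence: %.1f%%\n",
              100 * x$rapid_prevalence))
  for (nm in names(x$models)) {
    f <- x$models[[nm]]
    if (isTRUE(f$failed)) {
      cat(sprintf("%s: FAILED (%s)\n", nm, f$message))
    } else {
      key <- intersect(c("exposure", "hmgri", "exposure_x_hmgri"),
                       names(f$rr))
      cat(sprintf("%s: %s\n", nm,
                  paste(sprintf("%s RR %.2f [%.2f; %.2f]", key, f$rr[key],
                                f$ci_low[key], f$ci_high[key]),
                        collapse = ", ")))
    }
  }
  invisible(x)
}
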
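#' Build the design for the study's models 1-3
#'
#' Model 1 regresses rapid progression on the genetic exposure adjusted for
#' age, sex and `log(CAC_b+1)`; model 2 replaces the exposure with statin
#' (HMGRI) intake; model 3 contains both plus their product term. The
#' outcome is 1 for rapid progression and 0 for expected/slow. Rows with any
#' missing required field are dropped (complete-case) and counted.
#'
#' @param model_id 1, 2 or 3.
#' @param pheno phenotype table (`id`, `age`, `sex`, `cac_b`, `hmgri`).
#' @param exposure named-or-plain numeric vector aligned with `pheno` rows
#'   (standardized GRS or per-SNP dosage); unused by model 2.
#' @param classes progression results (`id`, `class`) as from
#'   [cac_progression()], or any vector-bearing data.frame aligned by id.
#' @return list with `y`, `X` (model matrix including intercept; sex coded
#'   F = 1), `model_id` and `n_dropped`.
#' @export
build_design <- function(model_id, pheno, exposure = NULL, classes) {
  if (!model_id %in% 1:3) stop_invalid("model_id must be 1, 2 or 3")
  cl <- classes$class[match(pheno$id, classes$id)]
  y <- as.numeric(cl == "rapid")
  base <- data.frame(age = pheno$age,
                     sexF = as.numeric(pheno$sex == "F"),
                     log_cac_b = log_cac(pheno$cac_b))
  if (model_id != 2 && is.null(exposure)) {
    stop_invalid("models 1 and 3 need an exposure vector")
  }
  cols <- switch(as.character(model_id),
    "1" = cbind(exposure = exposure, base),
    "2" = cbind(hmgri = pheno$hmgri, base),
    "3" = cbind(exposure = exposure, base, hmgri = pheno$hmgri,
                exposure_x_hmgri = exposure * pheno$hmgri))
  M <- as.matrix(cols)
  keep <- stats::complete.cases(M) & !is.na(y)
  X <- cbind(intercept = 1, M[keep, , drop = FALSE])
  list(y = y[keep], X = X, model_id = model_id, n_dropped = sum(!keep))
}

#' Bonferroni threshold for a test family
#'
#' @param alpha family-wise error rate (default 0.05).
#' @param m number of tests.
#' @return `alpha / m` (report displays round this to one significant
#'   figure; the comparison always uses the exact value).
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  if (!is_scalar_number(m) || m < 1) stop_invalid("m must be >= 1")
  check_fraction(alpha, "alpha", open_left = TRUE, open_right = TRUE)
  alpha / m
}

#' Scan the GRS and every panel SNP for main and interaction effects
#'
#' Fits model 1 (main effect) and model 3 (statin-interaction effect) for
#' the standardized GRS and for each SNP (entered as expected imputed
#' dosage), reporting relative risks, 95% CIs and Wald p-values per term,
#' Table-3 style. The interaction family size is the number of SNPs plus
#' one (the GRS); Bonferroni flags compare against `alpha` divided by that
#' family size. Failing per-SNP fits are recorded and skipped.
#'
#' @param pheno phenotype table.
#' @param genotypes dosage matrix (post-QC).
#' @param panel matching [snp_panel][read_snp_panel].
#' @param grs_z standardized GRS vector aligned with `pheno`.
#' @param classes progression classification ([cac_progression()] output).
#' @param alpha family-wise error rate for the Bonferroni flags.
#' @return data.frame of class `scan_result`: one row per exposure with
#'   main- and interaction-term RR, CI, p, and Bonferroni flags; attributes
#'   `"m_tests"` and `"bonferroni_alpha"`.
#' @export
interaction_scan <- function(pheno, genotypes, panel, grs_z, classes,
                             alpha = 0.05) {
  panel <- as_snp_panel(panel)
  dos <- impute_missing(genotypes)
  exposures <- c(list(GRS = grs_z),
                 stats::setNames(lapply(seq_len(ncol(dos)),
                                        function(j) dos[, j]),
                                 colnames(dos)))
  m_tests <- length(exposures)
  thr <- bonferroni_threshold(alpha, m_tests)
  one <- function(name, ex) {
    res <- try({
      f1 <- fit_rr_model(build_design(1, pheno, ex, classes))
      f3 <- fit_rr_model(build_design(3, pheno, ex, classes))
      data.frame(term = name,
                 rr_main = f1$rr[["exposure"]],
                 ci_low_main = f1$ci_low[["exposure"]],
                 ci_high_main = f1$ci_high[["exposure"]],
                 p_main = f1$p_value[["exposure"]],
                 rr_int = f3$rr[["exposure_x_hmgri"]],
                 ci_low_int = f3$ci_low[["exposure_x_hmgri"]],
                 ci_high_int = f3$ci_high[["exposure_x_hmgri"]],
                 p_int = f3$p_value[["exposure_x_hmgri"]],
                 failed = FALSE, stringsAsFactors = FALSE)
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      data.frame(term = name, rr_main = NA, ci_low_main = NA,
                 ci_high_main = NA, p_main = NA, rr_int = NA,
                 ci_low_int = NA, ci_high_int = NA, p_int = NA,
                 failed = TRUE, stringsAsFactors = FALSE)
    } else res
  }
  out <- do.call(rbind, Map(one, names(exposures), exposures))
  rownames(out) <- NULL
  out$bonferroni_sig_main <- !is.na(out$p_main) & out$p_main < thr
  out$bonferroni_sig_int <- !is.na(out$p_int) & out$p_int < thr
  attr(out, "m_tests") <- m_tests
  attr(out, "bonferroni_alpha") <- thr
  class(out) <- c("scan_result", "data.frame")
  out
}

#' Stratified GRS analysis
#'
#' Fits model 1 (exposure + age + sex + log(CAC_b+1)) separately within each
#' level of a stratifying covariate (statin use in the published analysis).
#' A stratum whose fit fails (e.g. no events) is reported as a failure
#' record without stopping the others. A constant stratum column yields the
#' single unstratified fit.
#'
#' @param pheno phenotype table.
#' @param grs_z standardized GRS aligned with `pheno`.
#' @param classes progression classification.
#' @param stratum name of the phenotype column to stratify on.
#' @return named list (one element per stratum level) of `rr_glm` fits or
#'   failure records (`list(failed = TRUE, message = ...)`).
#' @export
stratified_analysis <- function(pheno, grs_z, classes, stratum = "hmgri") {
  if (!stratum %in% names(pheno)) {
    stop_invalid("unknown stratum column '%s'", stratum)
  }
  levs <- sort(unique(pheno[[stratum]]))
  out <- lapply(levs, function(lv) {
    sel <- pheno[[stratum]] == lv
    res <- try(fit_rr_model(build_design(1, pheno[sel, , drop = FALSE],
                                         grs_z[sel], classes)),
               silent = TRUE)
    if (inherits(res, "try-error")) {
      list(failed = TRUE, message = attr(res, "condition")$message)
    } else res
  })
  stats::setNames(out, paste0(stratum, "=", levs))
}
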
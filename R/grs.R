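#' Impute missing dosages to their expected value
#'
#' Missing risk-allele dosages are replaced by `2 * freq`, the expected
#' dosage under the sample risk-allele frequency of that SNP (or supplied
#' frequencies, e.g. frozen from a scoring population).
#'
#' @param matrix dosage matrix with `NA` for missing entries.
#' @param freqs optional per-SNP risk-allele frequencies; defaults to the
#'   sample frequencies of `matrix`.
#' @return real-valued dosage matrix with no missing entries. Attribute
#'   `"n_imputed"` holds the per-participant count of imputed entries.
#' @export
impute_missing <- function(matrix, freqs = NULL) {
  stopifnot(is.matrix(matrix))
  if (is.null(freqs)) {
    freqs <- colMeans(matrix, na.rm = TRUE) / 2
    if (anyNA(freqs)) {
      stop_invalid("SNP(s) entirely missing with no supplied frequency: %s",
                   paste(colnames(matrix)[is.na(freqs)], collapse = ", "))
    }
  }
  if (length(freqs) != ncol(matrix)) {
    stop_invalid("freqs length (%d) != number of SNPs (%d)",
                 length(freqs), ncol(matrix))
  }
  if (any(freqs < 0 | freqs > 1)) stop_invalid("freqs must lie in [0,1]")
  out <- matrix * 1.0
  na <- is.na(out)
  if (any(na)) {
    fill <- base::matrix(2 * unname(freqs), nrow(out), ncol(out), byrow = TRUE)
    out[na] <- fill[na]
  }
  attr(out, "n_imputed") <- rowSums(na)
  out
}

#' Compute the average weighted genetic risk score
#'
#' `raw_i = sum_k weight_k * dosage_ik / n` where `n` is the number of panel
#' SNPs (the fixed panel size, not the number observed per participant —
#' consistent with expected-value imputation of missing genotypes).
#'
#' @param dosages real-valued dosage matrix, columns in panel order.
#' @param panel [snp_panel][read_snp_panel] supplying the weights.
#' @return numeric vector of raw scores, named by participant.
#' @export
compute_grs <- function(dosages, panel) {
  panel <- as_snp_panel(panel)
  dosages <- as.matrix(dosages)
  if (ncol(dosages) != nrow(panel)) {
    stop_invalid("dosage columns (%d) != panel SNPs (%d)",
                 ncol(dosages), nrow(panel))
  }
  if (!is.null(colnames(dosages)) &&
      !identical(colnames(dosages), panel$snp_id)) {
    stop_invalid("dosage column order does not match the panel")
  }
  if (any(!is.finite(dosages))) stop_invalid("dosages must be finite")
  as.vector(dosages %*% panel$weight) / nrow(panel)
}

#' Standardize scores to mean 0 and unit variance
#'
#' Uses the scoring population's own mean and SD (n-1 denominator) unless a
#' frozen `(center, scale)` pair is supplied, so standardization parameters
#' can be estimated once and re-applied (e.g. in stratified analyses).
#'
#' @param raw numeric score vector (length >= 2 unless frozen parameters are
#'   given).
#' @param center,scale optional frozen standardization parameters.
#' @return list with `z` (standardized scores), `center`, `scale`.
#' @export
standardize_scores <- function(raw, center = NULL, scale = NULL) {
  if (is.null(center) || is.null(scale)) {
    if (length(raw) < 2) stop_invalid("need >= 2 scores to standardize")
    center <- mean(raw)
    scale <- stats::sd(raw)
    if (scale == 0) stop_invalid("scores are constant; variance degenerate")
  }
  if (scale <= 0) stop_invalid("scale must be positive")
  list(z = (raw - center) / scale, center = center, scale = scale)
}

#' Score a genotyped cohort
#'
#' Convenience wrapper: imputes missing dosages to their expected value,
#' computes the average weighted score and standardizes it in-sample.
#'
#' @param genotypes integer dosage matrix (`NA` missing).
#' @param panel scoring [snp_panel][read_snp_panel].
#' @param divisor `"panel"` (default: fixed panel size, as in the printed
#'   scoring equation) or `"observed"` (average over non-missing SNPs, the
#'   PLINK default).
#' @return data.frame `id, raw_grs, std_grs, n_imputed` with attributes
#'   `"center"`/`"scale"` (the standardization parameters used).
#' @export
grs_score <- function(genotypes, panel, divisor = c("panel", "observed")) {
  divisor <- match.arg(divisor)
  panel <- as_snp_panel(panel)
  dos <- impute_missing(genotypes)
  raw <- compute_grs(dos, panel)
  if (divisor == "observed") {
    n_obs <- rowSums(!is.na(genotypes))
    n_obs[n_obs == 0] <- nrow(panel)  # fully-imputed participant
    raw <- raw * nrow(panel) / n_obs
  }
  std <- standardize_scores(raw)
  out <- data.frame(id = rownames(genotypes) %||% seq_along(raw),
                    raw_grs = raw, std_grs = std$z,
                    n_imputed = attr(dos, "n_imputed"),
                    stringsAsFactors = FALSE)
  attr(out, "center") <- std$center
  attr(out, "scale") <- std$scale
  out
}
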
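#' Hard-call a genotype from posterior probabilities
#'
#' Converts a genotype-probability triplet `(p_AA, p_Aa, p_aa)` into the
#' dosage (0/1/2) of the second allele when the most probable genotype
#' reaches `threshold`, else `NA`. This is the conversion applied to imputed
#' array data before scoring.
#'
#' @param probs numeric length-3 vector or an n x 3 matrix of triplets.
#' @param threshold minimum posterior of the best genotype (default 0.8).
#' @return integer dosage(s), `NA` where below threshold.
#' @export
hard_call <- function(probs, threshold = 0.8) {
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1)
  probs <- as.matrix(probs)
  if (ncol(probs) != 3) stop_invalid("probs must have 3 columns")
  if (any(probs < 0, na.rm = TRUE)) {
    stop_invalid("genotype probabilities must be non-negative")
  }
  if (any(rowSums(probs) > 1 + 1e-6, na.rm = TRUE)) {
    stop_invalid("genotype probabilities sum to more than 1")
  }
  best <- max.col(probs, ties.method = "first")
  pbest <- probs[cbind(seq_len(nrow(probs)), best)]
  out <- ifelse(pbest >= threshold, best - 1L, NA_integer_)
  as.integer(out)
}

#' Exact test for Hardy-Weinberg equilibrium
#'
#' Two-sided conditional exact test: with the allele counts fixed, the
#' heterozygote count follows a multivariate-hypergeometric null; the
#' p-value sums the probabilities of all heterozygote counts (of matching
#' parity) whose probability does not exceed that of the observed
#' configuration. Probabilities are built by the numerically stable
#' recurrence from the modal configuration.
#'
#' @param n_hom_risk,n_het,n_hom_other genotype counts.
#' @return exact p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_hom_risk, n_het, n_hom_other) {
  cnt <- c(n_hom_risk, n_het, n_hom_other)
  if (any(cnt < 0) || any(cnt != round(cnt))) {
    stop_invalid("genotype counts must be non-negative integers")
  }
  n <- sum(cnt)
  if (n < 1) stop_invalid("all genotype counts are zero; test undefined")
  rare <- 2 * min(n_hom_risk, n_hom_other) + n_het
  if (rare == 0 || rare == 2 * n) return(1)  # monomorphic

  # heterozygote counts share the parity of the rare-allele count
  hets <- seq(rare %% 2, min(rare, 2 * n - rare), by = 2)
  # start at (or next to) the mode and fill by recurrence:
  # P(h+2)/P(h) = hr(h)*ho(h) * 4 / ((h+2)*(h+1))  with
  # hr = (rare-h)/2, ho = n - (h + hr)
  mid <- floor(rare * (2 * n - rare) / (2 * n))
  if (mid %% 2 != rare %% 2) mid <- mid + 1
  mid <- min(max(mid, hets[1]), hets[length(hets)])
  probs <- stats::setNames(numeric(length(hets)), hets)
  probs[as.character(mid)] <- 1
  h <- mid
  while (h - 2 >= hets[1]) {
    hr <- (rare - h) / 2; ho <- n - h - hr
    probs[as.character(h - 2)] <- probs[as.character(h)] *
      h * (h - 1) / (4 * (hr + 1) * (ho + 1))
    h <- h - 2
  }
  h <- mid
  while (h + 2 <= hets[length(hets)]) {
    hr <- (rare - h) / 2; ho <- n - h - hr
    probs[as.character(h + 2)] <- probs[as.character(h)] *
      4 * hr * ho / ((h + 2) * (h + 1))
    h <- h + 2
  }
  probs <- probs / sum(probs)
  p_obs <- probs[as.character(n_het)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}

#' Apply the genotype quality-control filters
#'
#' Samples are filtered first (genotype missingness above
#' `sample_missing_max`), then SNPs on the retained samples: minor allele
#' frequency below `maf_min`, missingness above `snp_missing_max`, or exact
#' Hardy-Weinberg p-value below `hwe_alpha`. Each exclusion carries one
#' primary reason, assessed in the order missingness, MAF, HWE.
#'
#' @param matrix dosage matrix (participants x SNPs, `NA` missing).
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param snp_missing_max maximum per-SNP missing fraction (default 0.05).
#' @param sample_missing_max maximum per-sample missing fraction (default 0.05).
#' @param hwe_alpha HWE exclusion threshold (default 1e-5).
#' @return list with `genotypes` (filtered matrix) and `report`
#'   (class `qc_report`: per-SNP and per-sample statistics, exclusions with
#'   reasons, thresholds).
#' @export
apply_qc <- function(matrix, maf_min = 0.01, snp_missing_max = 0.05,
                     sample_missing_max = 0.05, hwe_alpha = 1e-5) {
  if (!is.matrix(matrix) || nrow(matrix) == 0 || ncol(matrix) == 0) {
    stop_invalid("genotype matrix is empty")
  }
  for (th in c(maf_min, snp_missing_max, sample_missing_max, hwe_alpha)) {
    if (!is_scalar_number(th) || th < 0 || th > 1) {
      stop_invalid("QC thresholds must lie in [0,1]")
    }
  }
  sample_miss <- rowMeans(is.na(matrix))
  keep_s <- sample_miss <= sample_missing_max
  m2 <- matrix[keep_s, , drop = FALSE]

  snp_miss <- colMeans(is.na(m2))
  raf <- colMeans(m2, na.rm = TRUE) / 2          # risk-allele frequency
  maf <- pmin(raf, 1 - raf)                       # minor allele, either one
  hwe_p <- vapply(seq_len(ncol(m2)), function(j) {
    d <- m2[, j][!is.na(m2[, j])]
    if (!length(d)) return(NA_real_)
    hwe_exact_test(sum(d == 2), sum(d == 1), sum(d == 0))
  }, numeric(1))

  reason <- rep(NA_character_, ncol(m2))
  reason[is.na(reason) & snp_miss > snp_missing_max] <- "missing"
  reason[is.na(reason) & (is.na(maf) | maf < maf_min)] <- "maf"
  reason[is.na(reason) & !is.na(hwe_p) & hwe_p < hwe_alpha] <- "hwe"
  keep_v <- is.na(reason)

  report <- list(
    snps = data.frame(snp_id = colnames(matrix) %||%
                        paste0("snp", seq_len(ncol(matrix))),
                      maf = maf, missing_rate = snp_miss, hwe_p = hwe_p,
                      excluded = !keep_v, reason = reason,
                      stringsAsFactors = FALSE),
    samples = data.frame(id = rownames(matrix) %||%
                           paste0("s", seq_len(nrow(matrix))),
                         missing_rate = sample_miss, excluded = !keep_s,
                         reason = ifelse(keep_s, NA, "missing"),
                         stringsAsFactors = FALSE),
    thresholds = list(maf_min = maf_min, snp_missing_max = snp_missing_max,
                      sample_missing_max = sample_missing_max,
                      hwe_alpha = hwe_alpha))
  class(report) <- "qc_report"
  list(genotypes = m2[, keep_v, drop = FALSE], report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("Genotype QC: excluded %d/%d samples, %d/%d SNPs\n",
              sum(x$samples$excluded), nrow(x$samples),
              sum(x$snps$excluded), nrow(x$snps)))
  if (any(x$snps$excluded)) {
    print(table(reason = x$snps$reason[x$snps$excluded]))
  }
  invisible(x)
}
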
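#' Read a SNP weight panel
#'
#' A panel is a tab-separated table with one row per scoring SNP and columns
#' `snp_id`, `chrom`, `pos`, `risk_allele`, `other_allele`, `weight`
#' (the published log relative-risk estimate \eqn{b_n}) and `raf`
#' (risk-allele frequency). An optional `gene` column is carried through.
#'
#' @param path path to the TSV file.
#' @return a `data.frame` of class `snp_panel`, one row per SNP.
#' @seealso [dm_snp_panel()] for the bundled 100-SNP diabetes panel.
#' @export
read_snp_panel <- function(path) {
  if (!file.exists(path)) stop_invalid("panel file not found: %s", path)
  p <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("snp_id", "chrom", "pos", "risk_allele", "other_allele",
            "weight", "raf")
  miss <- setdiff(need, names(p))
  if (length(miss)) {
    stop_invalid("panel is missing column(s): %s", paste(miss, collapse = ", "))
  }
  as_snp_panel(p)
}

#' Construct and validate a SNP panel
#'
#' @param x data.frame with the panel columns (see [read_snp_panel()]).
#' @return validated `snp_panel`.
#' @export
as_snp_panel <- function(x) {
  stopifnot(is.data.frame(x))
  if (anyDuplicated(x$snp_id)) stop_invalid("panel SNP ids are not unique")
  if (any(x$risk_allele == x$other_allele)) {
    stop_invalid("risk and other allele identical for: %s",
                 paste(x$snp_id[x$risk_allele == x$other_allele], collapse = ", "))
  }
  if (!all(is.finite(x$weight))) stop_invalid("panel weights must be finite")
  if (any(x$raf <= 0 | x$raf >= 1)) {
    stop_invalid("risk-allele frequency outside (0,1) for: %s",
                 paste(x$snp_id[x$raf <= 0 | x$raf >= 1], collapse = ", "))
  }
  class(x) <- c("snp_panel", "data.frame")
  x
}

#' The bundled diabetes-mellitus SNP panel
#'
#' 100 diabetes-associated SNPs (identifier, locus, risk/other allele and
#' risk-allele frequency as reported for the source cohort). The `weight`
#' column is synthetic: the source study does not publish the per-SNP
#' log-risk estimates, so plausible diabetes-GWAS-scale weights were drawn
#' once and rescaled so that the panel-implied population mean score
#' (\eqn{\sum_k 2 p_k b_k / 100}) equals the reported 0.0498. Use it for
#' simulation and pipeline exercises, not for scoring real cohorts.
#'
#' @return a `snp_panel` with 100 rows.
#' @export
dm_snp_panel <- function() {
  read_snp_panel(system.file("extdata", "dm_snp_panel_synthetic_weights.tsv",
                             package = "cacgrs", mustWork = TRUE))
}
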
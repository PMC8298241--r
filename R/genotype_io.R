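DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

is_ambiguous_pair <- function(a, b) DNA_COMPLEMENT[a] == b

# decide how file alleles (ref, alt) map onto panel (risk, other).
# returns list(mode, flip_strand) where mode is one of
# "alt_is_risk", "ref_is_risk", "ambiguous", "mismatch"
orient_alleles <- function(ref, alt, risk, other, allow_ambiguous = FALSE) {
  ambiguous <- is_ambiguous_pair(risk, other)
  same <- function(a, b, x, y) a == x && b == y
  if (ambiguous) {
    # strand cannot be verified for A/T and C/G pairs; only face-value
    # matches are usable and only when explicitly allowed
    if (same(ref, alt, other, risk)) {
      return(list(mode = if (allow_ambiguous) "alt_is_risk" else "ambiguous"))
    }
    if (same(ref, alt, risk, other)) {
      return(list(mode = if (allow_ambiguous) "ref_is_risk" else "ambiguous"))
    }
    return(list(mode = "mismatch"))
  }
  if (same(ref, alt, other, risk)) return(list(mode = "alt_is_risk"))
  if (same(ref, alt, risk, other)) return(list(mode = "ref_is_risk"))
  cref <- unname(DNA_COMPLEMENT[ref]); calt <- unname(DNA_COMPLEMENT[alt])
  if (!is.na(cref) && !is.na(calt)) {
    if (same(cref, calt, other, risk)) {
      return(list(mode = "alt_is_risk", flipped = TRUE))
    }
    if (same(cref, calt, risk, other)) {
      return(list(mode = "ref_is_risk", flipped = TRUE))
    }
  }
  list(mode = "mismatch")
}

#' Read genotypes as risk-allele dosages
#'
#' Reads one of three dialects and orients every variant so the returned
#' dosage counts the panel's risk allele. Unambiguous strand flips (e.g. file
#' G/A vs panel C/T) are applied automatically and logged; A/T and C/G SNPs
#' whose strand cannot be verified are flagged and returned all-missing
#' unless `allow_ambiguous = TRUE`. File variants not in the panel are
#' ignored (counted in the log); panel SNPs absent from the file become
#' all-missing columns.
#'
#' @param path input file. For `dialect = "ped_map"` give the `.ped` file;
#'   the matching `.map` is looked up next to it.
#' @param dialect one of `"vcf"`, `"ped_map"`, `"dosage_tsv"`.
#' @param panel [snp_panel][read_snp_panel] defining SNPs and risk alleles.
#' @param allow_ambiguous accept face-value matches for strand-ambiguous
#'   (A/T, C/G) SNPs.
#' @return integer dosage matrix (participants x panel SNPs, `NA` missing)
#'   with attribute `"io_log"`: a data.frame of per-SNP status codes
#'   (`ok`, `flipped`, `ambiguous`, `mismatch`, `absent`) and attribute
#'   `"n_ignored"` (file variants outside the panel).
#' @export
read_genotypes <- function(path, dialect = c("vcf", "ped_map", "dosage_tsv"),
                           panel, allow_ambiguous = FALSE) {
  dialect <- match.arg(dialect)
  panel <- as_snp_panel(panel)
  if (!file.exists(path)) stop_invalid("file not found: %s", path)
  switch(dialect,
         vcf = read_genotypes_vcf(path, panel, allow_ambiguous),
         ped_map = read_genotypes_ped(path, panel, allow_ambiguous),
         dosage_tsv = read_genotypes_dosage(path, panel))
}

finish_matrix <- function(dos, log, n_ignored, panel) {
  colnames(dos) <- panel$snp_id
  attr(dos, "io_log") <- log
  attr(dos, "n_ignored") <- n_ignored
  dos
}

read_genotypes_vcf <- function(path, panel, allow_ambiguous) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix),
                                     dimnames = list(NULL, names(gt)))
  ids <- colnames(gt)
  n <- length(ids)
  key_id <- fix[, "ID"]
  key_pos <- paste0(fix[, "CHROM"], ":", fix[, "POS"])
  alt_counts <- function(g) {
    # count ALT alleles in a GT string; "." or NA -> missing
    vapply(strsplit(as.character(g), "[/|]"), function(a) {
      if (length(a) == 0 || anyNA(a) || any(a == ".")) NA_integer_
      else sum(a != "0")
    }, integer(1))
  }
  dos <- matrix(NA_integer_, n, nrow(panel), dimnames = list(ids, NULL))
  status <- rep("absent", nrow(panel))
  hit <- match(panel$snp_id, key_id)
  miss <- is.na(hit)
  hit[miss] <- match(paste0(panel$chrom, ":", panel$pos)[miss], key_pos)
  for (k in seq_len(nrow(panel))) {
    r <- hit[k]
    if (is.na(r)) next
    o <- orient_alleles(fix[r, "REF"], fix[r, "ALT"],
                        panel$risk_allele[k], panel$other_allele[k],
                        allow_ambiguous)
    status[k] <- o$mode
    if (o$mode %in% c("ambiguous", "mismatch")) next
    cnt <- alt_counts(gt[r, ])
    dos[, k] <- if (o$mode == "alt_is_risk") cnt else 2L - cnt
    if (isTRUE(o$flipped)) status[k] <- "flipped"
    else status[k] <- "ok"
  }
  log <- data.frame(snp_id = panel$snp_id, status = status,
                    stringsAsFactors = FALSE)
  finish_matrix(dos, log, sum(!seq_along(key_id) %in% hit), panel)
}

read_genotypes_ped <- function(path, panel, allow_ambiguous) {
  map_path <- sub("\\.ped$", ".map", path)
  if (map_path == path || !file.exists(map_path)) {
    stop_invalid("matching .map file not found for %s", path)
  }
  map <- utils::read.table(map_path, stringsAsFactors = FALSE,
                           col.names = c("chrom", "snp_id", "cm", "pos"))
  ped <- utils::read.table(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(ped) != 6 + 2 * nrow(map)) {
    stop_invalid(".ped has %d columns; expected %d for %d map SNPs",
                 ncol(ped), 6 + 2 * nrow(map), nrow(map))
  }
  ids <- ped[[2]]
  n <- nrow(ped)
  dos <- matrix(NA_integer_, n, nrow(panel), dimnames = list(ids, NULL))
  status <- rep("absent", nrow(panel))
  hit <- match(panel$snp_id, map$snp_id)
  miss <- is.na(hit)
  hit[miss] <- match(paste0(panel$chrom, ":", panel$pos)[miss],
                     paste0(map$chrom, ":", map$pos))
  for (k in seq_len(nrow(panel))) {
    r <- hit[k]
    if (is.na(r)) next
    a1 <- ped[[6 + 2 * r - 1]]; a2 <- ped[[6 + 2 * r]]
    obs <- setdiff(unique(c(a1, a2)), "0")
    risk <- panel$risk_allele[k]; other <- panel$other_allele[k]
    # infer file orientation from the observed allele set
    if (length(obs) == 0) { status[k] <- "ok"; next }  # fully missing column
    count_as <- NULL
    if (all(obs %in% c(risk, other))) {
      if (is_ambiguous_pair(risk, other) && !allow_ambiguous) {
        status[k] <- "ambiguous"; next
      }
      count_as <- risk
      status[k] <- "ok"
    } else if (all(DNA_COMPLEMENT[obs] %in% c(risk, other)) &&
               !is_ambiguous_pair(risk, other)) {
      count_as <- names(DNA_COMPLEMENT)[DNA_COMPLEMENT == risk]
      status[k] <- "flipped"
    } else {
      status[k] <- "mismatch"; next
    }
    ok <- a1 != "0" & a2 != "0"
    d <- (a1 == count_as) + (a2 == count_as)
    d[!ok] <- NA_integer_
    dos[, k] <- as.integer(d)
  }
  log <- data.frame(snp_id = panel$snp_id, status = status,
                    stringsAsFactors = FALSE)
  finish_matrix(dos, log, sum(!seq_len(nrow(map)) %in% hit), panel)
}

read_genotypes_dosage <- function(path, panel) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"id" %in% names(d)) stop_invalid("dosage TSV needs an `id` column")
  ids <- as.character(d$id)
  d$id <- NULL
  dos <- matrix(NA_integer_, length(ids), nrow(panel),
                dimnames = list(ids, NULL))
  hit <- match(panel$snp_id, names(d))
  for (k in seq_len(nrow(panel))) {
    if (!is.na(hit[k])) {
      v <- d[[hit[k]]]
      if (any(!is.na(v) & !v %in% 0:2)) {
        stop_invalid("dosage column %s has values outside {0,1,2,NA}",
                     panel$snp_id[k])
      }
      dos[, k] <- as.integer(v)
    }
  }
  log <- data.frame(snp_id = panel$snp_id,
                    status = ifelse(is.na(hit), "absent", "ok"),
                    stringsAsFactors = FALSE)
  finish_matrix(dos, log, sum(!seq_along(names(d)) %in% hit), panel)
}

#' Write a dosage matrix as TSV
#'
#' Rows are participants (column `id`), columns SNP ids, cells 0/1/2 or NA.
#' @param dosage matrix from [simulate_genotypes()] or [read_genotypes()].
#' @param path output path.
#' @export
write_dosage_tsv <- function(dosage, path) {
  df <- data.frame(id = rownames(dosage), dosage, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write genotypes as a minimal VCF (GT only)
#'
#' The panel's risk allele is written as ALT so that the ALT-allele count of
#' each genotype equals the stored dosage.
#' @param dosage integer dosage matrix (risk-allele counts).
#' @param panel matching [snp_panel][read_snp_panel].
#' @param path output path.
#' @export
write_genotype_vcf <- function(dosage, panel, path) {
  panel <- as_snp_panel(panel)
  stopifnot(ncol(dosage) == nrow(panel))
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(dosage)), collapse = "\t")),
             con)
  for (k in seq_len(nrow(panel))) {
    g <- dosage[, k]
    calls <- ifelse(is.na(g), "./.", gt_code[as.character(g)])
    writeLines(paste(c(panel$chrom[k], panel$pos[k], panel$snp_id[k],
                       panel$other_allele[k], panel$risk_allele[k], ".",
                       "PASS", ".", "GT", calls), collapse = "\t"), con)
  }
  invisible(path)
}
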
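# small fixtures built in code

# panel of m unambiguous-allele SNPs with assorted weights and frequencies
make_test_panel <- function(m = 6, seed = 42) {
  set.seed(seed)
  pairs <- list(c("A", "G"), c("C", "T"), c("G", "A"), c("T", "C"))
  pick <- pairs[1 + (seq_len(m) - 1) %% length(pairs)]
  as_snp_panel(data.frame(
    snp_id = sprintf("snp%02d", seq_len(m)),
    chrom = rep_len(1:4, m),
    pos = 1000 * seq_len(m),
    risk_allele = vapply(pick, `[`, "", 1),
    other_allele = vapply(pick, `[`, "", 2),
    weight = round(runif(m, 0.02, 0.2), 4),
    raf = round(runif(m, 0.1, 0.9), 2),
    stringsAsFactors = FALSE))
}

# phenotype cohort lying exactly on log-linear percentile lines:
# log(CAC+1) = intercept + slope*age + offset(percentile), the same offset
# multiset at every age, ages spaced so each fitting window holds one age
make_on_model_cohort <- function(slope = 0.1, intercept = 0, dt = 2.5,
                                 ages = c(45, 55, 65, 75), m = 9) {
  offs <- seq(0.3, by = 0.3, length.out = m)
  grid <- expand.grid(age = ages, off = offs, sex = c("F", "M"))
  y_b <- intercept + slope * grid$age + grid$off
  y_5 <- intercept + slope * (grid$age + dt) + grid$off
  data.frame(id = sprintf("C%03d", seq_len(nrow(grid))),
             age = grid$age, sex = as.character(grid$sex),
             cac_b = expm1(y_b), cac_5y = expm1(y_5),
             dt_years = dt, hmgri = 0L, stringsAsFactors = FALSE)
}

# brute-force HWE enumeration oracle: direct log-gamma pmf of the
# conditional multivariate-hypergeometric null (independent of the
# package's recurrence implementation)
hwe_enum_oracle <- function(n_hom_risk, n_het, n_hom_other) {
  n <- n_hom_risk + n_het + n_hom_other
  n_r <- 2 * n_hom_risk + n_het   # risk-allele count
  logp <- function(het) {
    hr <- (n_r - het) / 2
    ho <- n - het - hr
    lgamma(n + 1) - lgamma(hr + 1) - lgamma(het + 1) - lgamma(ho + 1) +
      het * log(2) + lgamma(n_r + 1) + lgamma(2 * n - n_r + 1) -
      lgamma(2 * n + 1)
  }
  hets <- seq(n_r %% 2, min(n_r, 2 * n - n_r), by = 2)
  p <- exp(vapply(hets, logp, numeric(1)))
  obs <- p[match(n_het, hets)]
  min(1, sum(p[p <= obs * (1 + 1e-12)]))
}

# reduced-form simulation helpers for association calibration
sim_assoc_cohort <- function(n, seed, lrr = c(hmgri = 0, grs = 0, int = 0),
                             base_risk = 0.196, prop_hmgri = 0.073) {
  set.seed(seed)
  pheno <- data.frame(id = seq_len(n),
                      age = rnorm(n, 59, 7.5),
                      sex = ifelse(rbinom(n, 1, 0.531) == 1, "F", "M"),
                      cac_b = round(exp(rnorm(n, 2, 1.6)), 1),
                      hmgri = rbinom(n, 1, prop_hmgri),
                      stringsAsFactors = FALSE)
  grs_z <- rnorm(n)
  design <- cbind(hmgri = pheno$hmgri, grs = grs_z,
                  int = pheno$hmgri * grs_z)
  y <- simulate_binary_outcome(design, unname(lrr), base_risk,
                               seed = seed + 1)
  classes <- data.frame(id = pheno$id,
                        class = ifelse(y == 1, "rapid", "expected"),
                        stringsAsFactors = FALSE)
  list(pheno = pheno, grs_z = grs_z, classes = classes, y = y)
}
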
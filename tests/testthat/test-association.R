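test_that("design construction follows the three model specifications", {
  sim <- sim_assoc_cohort(300, seed = 81)
  d3 <- build_design(3, sim$pheno, sim$grs_z, sim$classes)
  expect_identical(colnames(d3$X),
                   c("intercept", "exposure", "age", "sexF", "log_cac_b",
                     "hmgri", "exposure_x_hmgri"))
  expect_identical(ncol(d3$X), 7L)
  d1 <- build_design(1, sim$pheno, sim$grs_z, sim$classes)
  expect_identical(colnames(d1$X),
                   c("intercept", "exposure", "age", "sexF", "log_cac_b"))
  d2 <- build_design(2, sim$pheno, classes = sim$classes)
  expect_true("hmgri" %in% colnames(d2$X))
  expect_error(build_design(4, sim$pheno, sim$grs_z, sim$classes), "model_id")
  expect_error(build_design(1, sim$pheno, classes = sim$classes), "exposure")
})

test_that("the outcome codes rapid versus expected or slow", {
  pheno <- data.frame(id = 1:3, age = c(50, 60, 70), sex = c("F", "M", "F"),
                      cac_b = c(0, 10, 100), hmgri = c(0L, 1L, 0L))
  classes <- data.frame(id = 1:3, class = c("slow", "expected", "rapid"))
  d <- build_design(2, pheno, classes = classes)
  expect_identical(d$y, c(0, 0, 1))
})

test_that("rows with missing covariates are dropped and counted", {
  sim <- sim_assoc_cohort(200, seed = 82)
  sim$pheno$hmgri[c(5, 9)] <- NA
  d <- build_design(3, sim$pheno, sim$grs_z, sim$classes)
  expect_identical(d$n_dropped, 2L)
  expect_false(anyNA(d$X))
})

test_that("bonferroni threshold divides alpha by the family size", {
  expect_equal(bonferroni_threshold(0.05, 101), 0.05 / 101)
  expect_equal(signif(bonferroni_threshold(0.05, 101), 1), 5e-4)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 5), 0.01)
  expect_error(bonferroni_threshold(0.05, 0), "m must be")
})

test_that("the scan reports one row per exposure and a GRS-sized family", {
  panel <- make_test_panel(6)
  sim <- sim_assoc_cohort(500, seed = 83)
  g <- simulate_genotypes(panel, 500, 0.02, seed = 83)
  rownames(g) <- sim$pheno$id
  scan <- interaction_scan(sim$pheno, g, panel, sim$grs_z, sim$classes)
  expect_identical(nrow(scan), 7L)           # 6 SNPs + the GRS
  expect_identical(attr(scan, "m_tests"), 7L)
  expect_equal(attr(scan, "bonferroni_alpha"), 0.05 / 7)
  expect_identical(scan$term[1], "GRS")
  expect_false(any(scan$failed))
})

test_that("an exposure column equal to the GRS reproduces the GRS row", {
  panel <- make_test_panel(1)
  sim <- sim_assoc_cohort(400, seed = 84)
  g <- simulate_genotypes(panel, 400, 0, seed = 84)
  rownames(g) <- sim$pheno$id
  # same regressor in both roles: rows must coincide
  scan <- interaction_scan(sim$pheno, g, panel, as.numeric(g[, 1]),
                           sim$classes)
  expect_equal(scan$rr_main[2], scan$rr_main[1], tolerance = 1e-9)
  expect_equal(scan$p_int[2], scan$p_int[1], tolerance = 1e-9)
})

test_that("permuted outcomes reject at close to the nominal rate", {
  panel <- make_test_panel(12)
  n <- 1500
  sim <- sim_assoc_cohort(n, seed = 85, base_risk = 0.196,
                          prop_hmgri = 0.3)
  g <- simulate_genotypes(panel, n, 0, seed = 85)
  rownames(g) <- sim$pheno$id
  set.seed(86)
  pvals <- c()
  for (b in 1:25) {
    perm <- sim$classes
    perm$class <- sample(perm$class)
    sc <- interaction_scan(sim$pheno, g, panel, sim$grs_z, perm)
    pvals <- c(pvals, sc$p_int[!sc$failed])
  }
  frac <- mean(pvals < 0.05)
  se <- sqrt(0.05 * 0.95 / length(pvals))
  expect_lt(abs(frac - 0.05), 3 * se)
})

test_that("stratified fits key by level and handle degenerate strata", {
  sim <- sim_assoc_cohort(1200, seed = 87, lrr = c(0.2, 0.1, 0),
                          prop_hmgri = 0.25)
  out <- stratified_analysis(sim$pheno, sim$grs_z, sim$classes, "hmgri")
  expect_identical(names(out), c("hmgri=0", "hmgri=1"))
  expect_s3_class(out[["hmgri=0"]], "rr_glm")
  expect_s3_class(out[["hmgri=1"]], "rr_glm")

  # constant stratum: the single fit equals unstratified model 1
  sim$pheno$const <- 1L
  out1 <- stratified_analysis(sim$pheno, sim$grs_z, sim$classes, "const")
  ref <- fit_rr_model(build_design(1, sim$pheno, sim$grs_z, sim$classes))
  expect_equal(coef(out1[[1]]), coef(ref), tolerance = 1e-12)

  # a stratum without events is reported as a failure record
  sim2 <- sim_assoc_cohort(300, seed = 88, prop_hmgri = 0.1)
  rapid0 <- sim2$classes$class == "rapid" & sim2$pheno$hmgri == 1
  sim2$classes$class[rapid0] <- "expected"
  out2 <- stratified_analysis(sim2$pheno, sim2$grs_z, sim2$classes, "hmgri")
  expect_true(isTRUE(out2[["hmgri=1"]]$failed))
  expect_s3_class(out2[["hmgri=0"]], "rr_glm")
  expect_error(stratified_analysis(sim2$pheno, sim2$grs_z, sim2$classes,
                                   "nope"), "unknown stratum")
})

test_that("identical GRS effects in both strata rarely look different", {
  # planted common GRS effect; stratum estimates should agree within
  # 3 combined SEs in nearly all replicates
  hits <- 0
  reps <- 60
  for (r in seq_len(reps)) {
    sim <- sim_assoc_cohort(1500, seed = 8000 + r,
                            lrr = c(hmgri = 0.3, grs = log(1.2), int = 0),
                            prop_hmgri = 0.3)
    out <- stratified_analysis(sim$pheno, sim$grs_z, sim$classes, "hmgri")
    if (isTRUE(out[[1]]$failed) || isTRUE(out[[2]]$failed)) next
    b <- vapply(out, function(f) coef(f)[["exposure"]], numeric(1))
    s <- vapply(out, function(f) f$se[["exposure"]], numeric(1))
    if (abs(b[1] - b[2]) < 3 * sqrt(sum(s^2))) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.95)
})

test_that("a planted interaction is detected more often than a null one", {
  reps <- 150
  rej_alt <- rej_null <- logical(reps)
  for (r in seq_len(reps)) {
    alt <- sim_assoc_cohort(3157, seed = 9000 + r,
                            lrr = c(hmgri = 0, grs = 0, int = log(1.5)),
                            base_risk = 0.10)
    f_a <- fit_rr_model(build_design(3, alt$pheno, alt$grs_z, alt$classes))
    rej_alt[r] <- f_a$p_value[["exposure_x_hmgri"]] < 0.05
    nul <- sim_assoc_cohort(3157, seed = 19000 + r)
    f_n <- fit_rr_model(build_design(3, nul$pheno, nul$grs_z, nul$classes))
    rej_null[r] <- f_n$p_value[["exposure_x_hmgri"]] < 0.05
  }
  expect_gt(mean(rej_alt), mean(rej_null))
})
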
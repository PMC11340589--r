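test_that("Feng bolus input starts at zero, peaks early, scales linearly", {
  inp <- feng_input()
  expect_equal(inp$cp(0), 0)
  expect_true(all(inp$cp(seq(0, 25, by = 0.01)) >= -1e-12))

  # peak location matches a numeric root of dCp/dt (independent oracle)
  t_pk <- stats::optimize(inp$cp, c(0, 2), maximum = TRUE)$maximum
  dcp <- function(t) {
    e <- 1e-6
    (inp$cp(t + e) - inp$cp(t - e)) / (2 * e)
  }
  root <- stats::uniroot(dcp, c(0.05, 2))$root
  expect_equal(t_pk, root, tolerance = 1e-3)
  expect_lt(t_pk, 1)                       # peak within the first minute

  # doubling all amplitudes doubles Cp pointwise
  inp2 <- feng_input(A1 = 2 * 851.1, A2 = 2 * 21.9, A3 = 2 * 20.8)
  tt <- seq(0, 25, by = 0.1)
  expect_equal(inp2$cp(tt), 2 * inp$cp(tt), tolerance = 1e-12)

  expect_error(feng_input(lambda1 = -0.05, lambda2 = -0.12),
               "lambda")
})

test_that("plasma-to-blood ratio rescales the whole-blood curve", {
  inp <- feng_input(plasma_to_blood_ratio = 1.25)
  tt <- c(0.5, 2, 10)
  expect_equal(inp$cb(tt), inp$cp(tt) / 1.25)
})

test_that("simulate_tac honors its noise contract", {
  truth <- kinetic_params(0.04, 0.35, 0.15, vb = 0.05)
  clean <- simulate_tac(truth, default_input, canonical, noise_level = 0)
  direct <- frame_average(solve_2tc(truth, default_input,
                                    seq(0, 25 + 0.5 / 60, by = 0.5 / 60)),
                          canonical)
  expect_equal(clean$values, direct$values, tolerance = 1e-9)

  # determinism
  a <- simulate_tac(truth, default_input, canonical, 0.05, seed = 3L)
  b <- simulate_tac(truth, default_input, canonical, 0.05, seed = 3L)
  expect_identical(a$values, b$values)
  expect_false(identical(
    a$values,
    simulate_tac(truth, default_input, canonical, 0.05, seed = 4L)$values))

  # Monte-Carlo check of the per-frame SD (clip-free frames)
  nl <- 0.05
  dur <- (canonical$end_s - canonical$start_s) / 60
  sd_spec <- nl * sqrt(clean$values / dur)
  reps <- vapply(1:1000, function(s)
    simulate_tac(truth, default_input, canonical, nl, seed = s)$values,
    numeric(32))
  frames <- which(clean$values / sd_spec > 4)   # clipping negligible
  sd_emp <- apply(reps[frames, ], 1, stats::sd)
  expect_lt(max(abs(sd_emp / sd_spec[frames] - 1)), 0.10)
  expect_true(all(reps >= 0))
})

test_that("cohort generator encodes the designed covariate effects", {
  pri <- depot_priors()
  expect_identical(pri$depot, c("SCV", "UCH", "ABD", "muscle"))
  med_ki <- pri$K1_med * pri$k3_med / (pri$k2_med + pri$k3_med)
  names(med_ki) <- pri$depot
  expect_gt(med_ki[["muscle"]], med_ki[["SCV"]])
  expect_gt(med_ki[["SCV"]], med_ki[["UCH"]])
  expect_gt(med_ki[["UCH"]], med_ki[["ABD"]])
  expect_equal(med_ki[["SCV"]], 0.012, tolerance = 0.01)
  expect_equal(med_ki[["muscle"]] / med_ki[["SCV"]], 3, tolerance = 0.01)

  # null BMI effect: designed correlation vanishes
  co0 <- simulate_cohort(cohort_spec(n = 100, bmi_effect = 0,
                                     t2d_fraction = 0, noise_level = 0.05,
                                     seed = 2L))
  scv0 <- co0$truth[co0$truth$depot == "SCV", ]
  rho0 <- spearman_corr(co0$covariates$bmi, scv0$ki)$rho
  expect_lt(abs(rho0), 0.2)

  # default negative BMI effect: clearly negative designed correlation
  co1 <- simulate_cohort(cohort_spec(n = 100, seed = 2L))
  scv1 <- co1$truth[co1$truth$depot == "SCV", ]
  rho1 <- spearman_corr(co1$covariates$bmi, scv1$ki)$rho
  expect_lt(rho1, -0.3)

  # T2D effect separates the subgroup medians (one-sided rank test)
  co2 <- simulate_cohort(cohort_spec(n = 200, t2d_fraction = 0.3,
                                     t2d_effect = 0.6, seed = 3L))
  scv2 <- co2$truth[co2$truth$depot == "SCV", ]
  wt <- stats::wilcox.test(scv2$ki[co2$covariates$t2d],
                           scv2$ki[!co2$covariates$t2d],
                           alternative = "less")
  expect_lt(wt$p.value, 0.05)
})

test_that("cohort generation is deterministic and retains ground truth", {
  a <- simulate_cohort(cohort_spec(n = 5, seed = 10L))
  b <- simulate_cohort(cohort_spec(n = 5, seed = 10L))
  expect_identical(a$truth, b$truth)
  expect_identical(a$covariates, b$covariates)
  expect_identical(lapply(a$tacs, `[[`, "values"),
                   lapply(b$tacs, `[[`, "values"))
  expect_equal(nrow(a$truth), 5L * 4L)
  expect_setequal(names(a$tacs),
                  paste(rep(a$covariates$subject_id, each = 4),
                        rep(depot_priors()$depot, 5), sep = "::"))
  # every TAC carries the parameters that generated it
  tr <- attr(a$tacs[["S001::SCV"]], "truth")
  row <- a$truth[a$truth$subject_id == "S001" & a$truth$depot == "SCV", ]
  expect_equal(tr$params$K1, row$K1)
})

test_that("phantom regions carry the constructed HU, activity and counts", {
  ph <- make_phantom(seed = 8L)
  expect_s3_class(ph$ct, "image_volume")
  expect_equal(ph$ct$spacing, rep(2.344, 3))

  # adipose block: >= 99% of voxels inside the HU window
  scv <- ph$labels$scv
  hu <- ph$ct$values[scv$mask]
  expect_gte(mean(hu >= -190 & hu <= -30), 0.99)

  # muscle block contributes nothing to the adipose mask
  adi <- adipose_hu_mask(ph$ct, ph$labels$muscle)
  expect_equal(sum(adi$mask), 0L)

  # constructed counts and volume arithmetic
  expect_equal(sum(scv$mask), 1000L)           # 10x10x10 block
  expect_equal(mask_volume_ml(scv), 1000 * 2.344^3 / 1000)
  expect_gt(mask_volume_ml(scv), 5.0)

  # uniform PET activity inside each region
  expect_equal(unique(as.vector(ph$pet$values[scv$mask])), 2.0)

  # overlapping regions are rejected
  bad <- list(a = list(from = c(1, 1, 1), to = c(5, 5, 5),
                       hu_mean = -100, hu_sd = 5, pet = 1),
              b = list(from = c(4, 4, 4), to = c(8, 8, 8),
                       hu_mean = -100, hu_sd = 5, pet = 1))
  expect_error(make_phantom(layout = bad), "overlap")
})

test_that("qPCR generator reproduces designed fold-changes", {
  genes <- c("UCP1", "SLC25A44")
  # null: equal group medians of relative expression
  tab0 <- simulate_qpcr(genes = genes,
                        fold_changes = c(UCP1 = 1, SLC25A44 = 1),
                        n_per_group = c(40L, 40L), seed = 1L)
  re0 <- relative_expression(tab0$ct_target, tab0$ct_ref)
  m <- tapply(re0[tab0$gene == "UCP1"], tab0$group[tab0$gene == "UCP1"],
              stats::median)
  expect_equal(log2(m[["HBAT"]] / m[["LBAT"]]), 0, tolerance = 0.5)

  # noiseless limit: delta-Ct decreases by exactly log2(fold-change)
  tabx <- simulate_qpcr(genes = "UCP1", fold_changes = c(UCP1 = 4),
                        n_per_group = c(5L, 5L), sigma = 0, seed = 2L)
  dct <- tabx$ct_target - tabx$ct_ref
  expect_equal(mean(dct[tabx$group == "LBAT"]) -
                 mean(dct[tabx$group == "HBAT"]), 2)

  # power: UCP1 4-fold higher in HBAT detected by Mann-Whitney >= 80%
  hits <- vapply(1:200, function(s) {
    tab <- simulate_qpcr(genes = "UCP1", fold_changes = c(UCP1 = 4),
                         n_per_group = c(7L, 16L), seed = s)
    re <- relative_expression(tab$ct_target, tab$ct_ref)
    mann_whitney(re[tab$group == "HBAT"], re[tab$group == "LBAT"])$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
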
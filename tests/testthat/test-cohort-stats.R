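test_that("Friedman statistic equals the rank-formula oracle on a toy table", {
  # 4 subjects x 3 depots; ranks computed by hand give
  # R = (6, 9, 9), stat = 12/(4*3*4)*(36+81+81) - 3*4*4 = 1.5
  v <- rbind(c(1, 2, 3), c(2, 3, 1), c(1, 3, 2), c(2, 1, 3))
  colnames(v) <- c("SCV", "UCH", "ABD")
  res <- compare_depots_paired(v)
  expect_match(res$test, "Friedman")
  expect_equal(res$statistic, 1.5)

  # independent enumeration oracle: rank formula on within-row ranks
  rk <- t(apply(v, 1, rank))
  n <- nrow(v); k <- ncol(v)
  stat_oracle <- 12 / (n * k * (k + 1)) * sum(colSums(rk)^2) -
    3 * n * (k + 1)
  expect_equal(res$statistic, stat_oracle)
})

test_that("identical depot columns give a null comparison", {
  set.seed(61)
  skewed <- exp(rnorm(12))
  v <- cbind(SCV = skewed, UCH = skewed, ABD = skewed)
  res <- compare_depots_paired(v)
  expect_match(res$test, "Friedman")
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
  expect_true(all(res$pairwise$p_adj == 1))

  normal <- rnorm(12, 10, 1)
  vn <- cbind(SCV = normal, UCH = normal, ABD = normal)
  resn <- compare_depots_paired(vn)
  expect_match(resn$test, "ANOVA")
  expect_equal(resn$statistic, 0, tolerance = 1e-10)
})

test_that("a depot with a constant offset is flagged by pairwise tests", {
  set.seed(62)
  n <- 20
  base <- rnorm(n, 10, 1)
  v <- cbind(SCV = base + 5, UCH = base + rnorm(n, 0, 0.5),
             ABD = base + rnorm(n, 0, 0.5))
  res <- compare_depots_paired(v)
  expect_lt(res$p, 0.05)
  scv_rows <- res$pairwise$group1 == "SCV" | res$pairwise$group2 == "SCV"
  expect_true(all(res$pairwise$p_adj[scv_rows] < 0.05))

  # same design through the rank route (heavily skewed data)
  b <- exp(rnorm(n, 0, 1.5))
  vs <- cbind(SCV = b * 8, UCH = b * exp(rnorm(n, 0, 0.3)),
              ABD = b * exp(rnorm(n, 0, 0.3)))
  ress <- compare_depots_paired(vs)
  expect_match(ress$test, "Friedman")
  scv_rows <- ress$pairwise$group1 == "SCV" | ress$pairwise$group2 == "SCV"
  expect_true(all(ress$pairwise$p_adj[scv_rows] < 0.05))
})

test_that("incomplete subjects are dropped with a warning", {
  v <- cbind(SCV = c(1, 2, 3, NA, 5), UCH = 1:5, ABD = 5:1)
  expect_warning(res <- compare_depots_paired(v), "incomplete")
  expect_equal(res$n, 4L)
})

test_that("adjusted p values never fall below raw p values", {
  set.seed(63)
  v <- matrix(exp(rnorm(30)), 10, 3,
              dimnames = list(NULL, c("A", "B", "C")))
  res <- compare_depots_paired(v)
  expect_true(all(res$pairwise$p_adj >= res$pairwise$p_raw - 1e-12))
  g <- compare_groups(exp(rnorm(30)), rep(c("x", "y", "z"), 10))
  expect_true(all(g$pairwise$p_adj >= g$pairwise$p_raw - 1e-12))
})

test_that("Mann-Whitney U matches exact enumeration for small samples", {
  # canonical fully separated case
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$statistic, 0)
  expect_equal(mw$p, 0.1)

  # enumeration oracle over all group assignments, several draws
  set.seed(64)
  for (rep in 1:5) {
    nx <- sample(3:4, 1); ny <- sample(3:4, 1)
    pool <- sample(100, nx + ny)        # distinct values, no ties
    x <- pool[1:nx]; y <- pool[-(1:nx)]
    mw <- mann_whitney(x, y)
    combs <- utils::combn(nx + ny, nx)
    r_all <- rank(pool)
    u_obs <- sum(r_all[1:nx]) - nx * (nx + 1) / 2
    u_perm <- apply(combs, 2, function(ix)
      sum(rank(pool)[ix]) - nx * (nx + 1) / 2)
    p_lo <- mean(u_perm <= u_obs)
    p_hi <- mean(u_perm >= u_obs)
    p_exact <- min(1, 2 * min(p_lo, p_hi))
    expect_equal(mw$p, p_exact)
    expect_equal(mw$statistic, u_obs)
  }
})

test_that("Spearman rho and exact p match enumeration for n = 5", {
  expect_equal(spearman_corr(1:5, 1:5)$rho, 1)
  expect_equal(spearman_corr(1:5, 5:1)$rho, -1)

  # hand rank computation: d = (1,1,1,1,0), rho = 1 - 6*4/(5*24) = 0.8
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 5)
  sc <- spearman_corr(x, y)
  expect_equal(sc$rho, 0.8)

  # enumeration oracle over all 120 permutations
  perms <- as.matrix(expand.grid(rep(list(1:5), 5)))
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 5), ]
  rho_all <- apply(perms, 1, function(p) stats::cor(x, y[p],
                                                    method = "spearman"))
  p_enum <- mean(abs(rho_all) >= abs(sc$rho) - 1e-12)
  expect_equal(sc$p, p_enum)

  expect_error(spearman_corr(rep(1, 5), 1:5), "constant")
  expect_error(spearman_corr(1:2, 1:2), "pairs")
})

test_that("group comparisons route by normality and group count", {
  set.seed(65)
  # three normal groups, one shifted: ANOVA + Tukey finds the shift
  g <- rep(c("NW", "OW", "OB"), each = 12)
  v <- c(rnorm(12, 10), rnorm(12, 10), rnorm(12, 13))
  res <- compare_groups(v, g)
  expect_match(res$test, "ANOVA")
  ob_rows <- res$pairwise$group1 == "OB" | res$pairwise$group2 == "OB"
  expect_true(all(res$pairwise$p_adj[ob_rows] < 0.05))

  # skewed three-group data takes the rank route
  res_k <- compare_groups(exp(v), g)
  expect_match(res_k$test, "Kruskal")

  # two skewed groups: Mann-Whitney
  res_2 <- compare_groups(exp(c(rnorm(15), rnorm(15, 2))),
                          rep(c("a", "b"), each = 15))
  expect_match(res_2$test, "Mann-Whitney")
  expect_lt(res_2$p, 0.05)

  expect_error(compare_groups(1:5, c("a", "a", "a", "a", "b")),
               "insufficient-group")
})

test_that("designed monotone Ki decrease across BMI categories is detected", {
  set.seed(66)
  hits <- vapply(1:100, function(r) {
    ki <- c(rlnorm(9, log(0.014), 0.25),    # NW
            rlnorm(16, log(0.011), 0.25),   # OW
            rlnorm(10, log(0.008), 0.25))   # OB
    g <- rep(c("NW", "OW", "OB"), c(9, 16, 10))
    res <- compare_groups(ki, g)
    pr <- res$pairwise
    row <- (pr$group1 == "NW" & pr$group2 == "OB") |
      (pr$group1 == "OB" & pr$group2 == "NW")
    pr$p_adj[row] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("relative expression follows the 2^(-dCt) rule", {
  expect_equal(relative_expression(20, 20), 1)
  expect_equal(relative_expression(21, 20), 0.5)
  expect_equal(relative_expression(24.5, 18), 2^(-6.5))
  expect_equal(relative_expression(24.5, 18), 0.01104854, tolerance = 1e-6)
  expect_error(relative_expression(Inf, 20))
})

test_that("clearance estimate is volume times uptake rate", {
  expect_identical(clearance_estimate(100, 0.012), 1.2)
  expect_identical(clearance_estimate(0, 0.012), 0)
  expect_identical(clearance_estimate(30000, 0.036), 1080)
})

test_that("BMI categories use the WHO cutoffs", {
  expect_equal(as.character(bmi_category(c(24.9, 25, 29.9, 30, 18))),
               c("NW", "OW", "OW", "OB", "NW"))
  counts <- table(bmi_category(c(21, 22, 26, 27, 28, 31)))
  expect_equal(unname(counts[c("NW", "OW", "OB")]), c(2L, 3L, 1L),
               ignore_attr = TRUE)
  expect_error(bmi_category(-1))
})

test_that("BAT grouping splits at 20 mL", {
  expect_equal(as.character(bat_group(c(20, 19.99, 0, 45))),
               c("HBAT", "LBAT", "LBAT", "HBAT"))
})

test_that("the depot comparison pipeline is deterministic", {
  co <- simulate_cohort(cohort_spec(n = 12, seed = 4L))
  ki <- matrix(co$truth$ki, nrow = 12, byrow = TRUE,
               dimnames = list(NULL, depot_priors()$depot))
  r1 <- compare_depots_paired(ki)
  r2 <- compare_depots_paired(ki)
  expect_identical(r1, r2)
})
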
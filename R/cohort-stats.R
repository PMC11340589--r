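#' Shapiro-Wilk normality routing
#'
#' The comparison functions choose between parametric and rank-based routes
#' by testing each variable (or each group/depot column) with Shapiro-Wilk
#' at alpha = 0.05: every column normal -> parametric, otherwise ranks.
#'
#' @param columns List or data frame of numeric vectors.
#' @param alpha Significance level for rejecting normality.
#' @return TRUE when no column rejects normality.
#' @keywords internal
all_normal <- function(columns, alpha = 0.05) {
  all(vapply(columns, function(v) {
    v <- v[is.finite(v)]
    if (length(unique(v)) < 3L || length(v) < 3L) return(FALSE)
    if (length(v) > 5000) v <- v[seq_len(5000)]
    stats::shapiro.test(v)$p.value >= alpha
  }, logical(1)))
}

# Dunn's post hoc for a Friedman design: pairwise z on within-subject rank
# sums, SE = sqrt(k(k+1)/(6n)); Bonferroni-style correction over all pairs.
dunn_friedman <- function(rank_matrix, adjust = "bonferroni") {
  n <- nrow(rank_matrix); k <- ncol(rank_matrix)
  rbar <- colMeans(rank_matrix)
  se <- sqrt(k * (k + 1) / (6 * n))
  pairs <- utils::combn(k, 2)
  z <- abs(rbar[pairs[1, ]] - rbar[pairs[2, ]]) / se
  praw <- 2 * stats::pnorm(-z)
  data.frame(group1 = colnames(rank_matrix)[pairs[1, ]],
             group2 = colnames(rank_matrix)[pairs[2, ]],
             z = z, p_raw = praw,
             p_adj = pmin(stats::p.adjust(praw, adjust), 1),
             stringsAsFactors = FALSE)
}

# Dunn's post hoc for independent groups (Kruskal-Wallis design): z on mean
# ranks of the pooled sample with tie correction.
dunn_independent <- function(values, groups, adjust = "bonferroni") {
  groups <- factor(groups)
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  ng <- tapply(r, groups, length)
  ties <- table(values)
  tiecor <- sum(ties^3 - ties) / (12 * (N - 1))
  lev <- levels(groups)
  pairs <- utils::combn(length(lev), 2)
  se <- sqrt((N * (N + 1) / 12 - tiecor) *
               (1 / ng[pairs[1, ]] + 1 / ng[pairs[2, ]]))
  z <- abs(rbar[pairs[1, ]] - rbar[pairs[2, ]]) / se
  praw <- 2 * stats::pnorm(-z)
  data.frame(group1 = lev[pairs[1, ]], group2 = lev[pairs[2, ]],
             z = as.numeric(z), p_raw = as.numeric(praw),
             p_adj = pmin(stats::p.adjust(praw, adjust), 1),
             stringsAsFactors = FALSE)
}

group_summaries <- function(columns, normal) {
  do.call(rbind, lapply(names(columns), function(nm) {
    v <- columns[[nm]]
    if (normal)
      data.frame(group = nm, n = length(v), center = mean(v),
                 spread_lo = mean(v) - stats::sd(v),
                 spread_hi = mean(v) + stats::sd(v),
                 summary = "mean +/- SD", stringsAsFactors = FALSE)
    else
      data.frame(group = nm, n = length(v), center = stats::median(v),
                 spread_lo = unname(stats::quantile(v, 0.25)),
                 spread_hi = unname(stats::quantile(v, 0.75)),
                 summary = "median (IQR)", stringsAsFactors = FALSE)
  }))
}

#' Paired comparison of measurements across depots
#'
#' Each subject contributes one measurement per depot (complete cases
#' only). Normally distributed data (Shapiro-Wilk on every depot column at
#' alpha 0.05) are compared by repeated-measures ANOVA with Tukey-corrected
#' pairwise contrasts; skewed data by the Friedman rank test with Dunn's
#' correction for multiple comparisons.
#'
#' @param values Matrix or data frame, one row per subject, one column per
#'   depot (>= 3 columns, >= 3 complete rows).
#' @return A list of class `comparison_result`: `test`, `statistic`, `p`,
#'   `pairwise` (data frame with raw and adjusted p values) and
#'   `summaries`.
#' @export
compare_depots_paired <- function(values) {
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    colnames(values) <- paste0("depot", seq_len(ncol(values)))
  if (ncol(values) < 3L) stop("need >= 3 depots")
  cc <- stats::complete.cases(values)
  if (!all(cc)) {
    warning("dropping ", sum(!cc), " incomplete subject(s)")
    values <- values[cc, , drop = FALSE]
  }
  n <- nrow(values)
  if (n < 3L) stop("need >= 3 complete subjects")
  cols <- lapply(seq_len(ncol(values)), function(j) values[, j])
  names(cols) <- colnames(values)
  normal <- all_normal(cols)
  if (normal) {
    df <- data.frame(y = as.vector(values),
                     depot = factor(rep(colnames(values), each = n)),
                     subject = factor(rep(seq_len(n), ncol(values))))
    fit <- stats::aov(y ~ depot + subject, data = df)   # randomized block
    an <- summary(fit)[[1]]
    ss_depot <- an["depot", "Sum Sq"]
    ss_total <- sum((df$y - mean(df$y))^2)
    if (ss_depot < 1e-10 * max(ss_total, 1e-300)) {
      # no between-depot variation: perfect block fit makes the F ratio
      # numerically meaningless; report the null result directly
      pairs <- utils::combn(colnames(values), 2)
      pairwise <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                             diff = 0, p_raw = 1, p_adj = 1,
                             stringsAsFactors = FALSE)
      res <- list(test = "repeated-measures ANOVA + Tukey",
                  statistic = 0, p = 1, pairwise = pairwise)
    } else {
      tk <- stats::TukeyHSD(fit, which = "depot")$depot
      nm <- strsplit(rownames(tk), "-", fixed = TRUE)
      pairwise <- data.frame(
        group1 = vapply(nm, `[`, "", 2L),
        group2 = vapply(nm, `[`, "", 1L),
        diff = tk[, "diff"], p_raw = tk[, "p adj"], p_adj = tk[, "p adj"],
        stringsAsFactors = FALSE)
      res <- list(test = "repeated-measures ANOVA + Tukey",
                  statistic = an["depot", "F value"],
                  p = an["depot", "Pr(>F)"], pairwise = pairwise)
    }
  } else {
    fr <- stats::friedman.test(values)
    stat <- unname(fr$statistic)
    pval <- fr$p.value
    if (!is.finite(stat)) {
      # every row fully tied: the tie-corrected statistic is 0/0; the
      # depots are indistinguishable, so report the null result
      stat <- 0
      pval <- 1
    }
    rk <- t(apply(values, 1, rank))
    colnames(rk) <- colnames(values)
    res <- list(test = "Friedman + Dunn",
                statistic = stat, p = pval,
                pairwise = dunn_friedman(rk))
  }
  res$summaries <- group_summaries(cols, normal)
  res$n <- n
  class(res) <- "comparison_result"
  res
}

#' Compare independent groups
#'
#' Two groups: Student's t when both pass Shapiro-Wilk, Mann-Whitney U
#' otherwise (exact p for combined n <= 20 without ties, normal
#' approximation with tie correction beyond). Three or more groups:
#' one-way ANOVA with Tukey correction when all groups are normal,
#' Kruskal-Wallis with Dunn's correction otherwise.
#'
#' @param values Numeric vector of measurements.
#' @param groups Group labels, same length; every group needs n >= 2.
#' @return A `comparison_result` (see [compare_depots_paired()]).
#' @export
compare_groups <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]; groups <- factor(groups[ok])
  ng <- table(groups)
  if (length(ng) < 2L) stop("need >= 2 groups")
  if (any(ng < 2L)) stop("insufficient-group error: every group needs n >= 2")
  cols <- split(values, groups)
  normal <- all_normal(cols)
  if (length(ng) == 2L) {
    if (normal) {
      tt <- stats::t.test(cols[[1]], cols[[2]])
      res <- list(test = "Welch t", statistic = unname(tt$statistic),
                  p = tt$p.value,
                  pairwise = data.frame(group1 = names(cols)[1],
                                        group2 = names(cols)[2],
                                        p_raw = tt$p.value,
                                        p_adj = tt$p.value))
    } else {
      res <- c(mann_whitney(cols[[1]], cols[[2]]), list())
      res$pairwise <- data.frame(group1 = names(cols)[1],
                                 group2 = names(cols)[2],
                                 p_raw = res$p, p_adj = res$p)
    }
  } else if (normal) {
    df <- data.frame(y = values, g = groups)
    fit <- stats::aov(y ~ g, data = df)
    an <- summary(fit)[[1]]
    tk <- stats::TukeyHSD(fit)$g
    nm <- strsplit(rownames(tk), "-", fixed = TRUE)
    res <- list(test = "one-way ANOVA + Tukey",
                statistic = an["g", "F value"], p = an["g", "Pr(>F)"],
                pairwise = data.frame(
                  group1 = vapply(nm, `[`, "", 2L),
                  group2 = vapply(nm, `[`, "", 1L),
                  diff = tk[, "diff"], p_raw = tk[, "p adj"],
                  p_adj = tk[, "p adj"], stringsAsFactors = FALSE))
  } else {
    kw <- stats::kruskal.test(values, groups)
    res <- list(test = "Kruskal-Wallis + Dunn",
                statistic = unname(kw$statistic), p = kw$p.value,
                pairwise = dunn_independent(values, groups))
  }
  res$summaries <- group_summaries(cols, normal)
  res$n <- length(values)
  class(res) <- "comparison_result"
  res
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test reporting the U statistic. The p value is exact
#' when the combined sample size is at most 20 and there are no ties, and
#' uses the normal approximation with tie correction otherwise.
#'
#' @param x,y Numeric samples.
#' @return List with `test`, `statistic` (U of the first sample), `p`.
#' @export
mann_whitney <- function(x, y) {
  exact <- (length(x) + length(y)) <= 20 &&
    !any(duplicated(c(x, y)))
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = !exact))
  list(test = if (exact) "Mann-Whitney U (exact)"
       else "Mann-Whitney U (normal approx.)",
       statistic = unname(wt$statistic), p = wt$p.value)
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n = %d)\n",
              x$test, x$statistic, x$p, x$n))
  if (!is.null(x$pairwise)) {
    cat("pairwise (adjusted):\n")
    for (i in seq_len(nrow(x$pairwise)))
      cat(sprintf("  %s vs %s: p = %.4g\n", x$pairwise$group1[i],
                  x$pairwise$group2[i], x$pairwise$p_adj[i]))
  }
  invisible(x)
}

#' Spearman rank correlation
#'
#' Spearman's rho with midrank tie handling; the p value comes from the
#' t approximation (AS 89 exact routine for small untied samples, as in
#' [stats::cor.test()]).
#'
#' @param x,y Paired numeric vectors, n >= 3 complete pairs.
#' @return List with `rho` and `p`.
#' @export
spearman_corr <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need >= 3 complete pairs")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stop("undefined correlation: constant vector")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Relative gene expression, 2^(-dCt)
#'
#' Expression of a target gene relative to the housekeeping reference
#' (RPLP0): `2^(ct_reference - ct_target)`. One PCR cycle difference is a
#' 2-fold expression change.
#'
#' @param ct_target Target-gene threshold cycles (finite, > 0).
#' @param ct_reference Reference-gene threshold cycles (finite, > 0).
#' @return Relative expression, dimensionless, > 0.
#' @export
relative_expression <- function(ct_target, ct_reference) {
  stopifnot(all(is.finite(ct_target)), all(is.finite(ct_reference)),
            all(ct_target > 0), all(ct_reference > 0))
  2^(ct_reference - ct_target)
}

#' Whole-tissue plasma clearance
#'
#' Scales a per-volume net uptake rate to a whole-depot plasma clearance:
#' `volume (cm^3) x Ki (mL/min/cm^3) = mL plasma cleared per minute`. With
#' a typical 100 cm^3 brown-adipose depot at Ki = 0.012 this gives
#' 1.2 mL/min; 30 kg of muscle at ~3-fold the rate gives about 1 L/min.
#'
#' @param tissue_volume_cm3 Tissue volume, cm^3 (>= 0).
#' @param ki_mL_per_min_per_cm3 Net uptake rate, mL/min/cm^3 (>= 0).
#' @return Plasma clearance, mL/min.
#' @export
clearance_estimate <- function(tissue_volume_cm3, ki_mL_per_min_per_cm3) {
  stopifnot(tissue_volume_cm3 >= 0, ki_mL_per_min_per_cm3 >= 0)
  tissue_volume_cm3 * ki_mL_per_min_per_cm3
}

#' BMI category (WHO cutoffs)
#'
#' Normal weight below 25, overweight 25 to below 30, obese 30 and above.
#'
#' @param bmi Body-mass index, kg/m^2 (> 0); vectorized.
#' @return Factor with levels NW, OW, OB.
#' @export
bmi_category <- function(bmi) {
  stopifnot(all(bmi > 0))
  cut(bmi, breaks = c(0, 25, 30, Inf), labels = c("NW", "OW", "OB"),
      right = FALSE)
}

#' High/low BAT-volume grouping
#'
#' Subjects with FDG-PET-detectable BAT volume of at least 20 mL are HBAT,
#' below 20 mL LBAT.
#'
#' @param bat_volume_ml BAT volume, mL (>= 0); vectorized.
#' @return Factor with levels LBAT, HBAT.
#' @export
bat_group <- function(bat_volume_ml) {
  stopifnot(all(bat_volume_ml >= 0))
  factor(ifelse(bat_volume_ml >= 20, "HBAT", "LBAT"),
         levels = c("LBAT", "HBAT"))
}
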
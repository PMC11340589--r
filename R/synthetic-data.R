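#' Feng-type bolus plasma input function
#'
#' The classic tri-exponential bolus model
#' \deqn{C_p(t) = (A_1 t - A_2 - A_3) e^{\lambda_1 t} + A_2 e^{\lambda_2 t}
#'   + A_3 e^{\lambda_3 t}}
#' with \eqn{\lambda_1 < \lambda_2 \le \lambda_3 < 0}, which is exactly 0 at
#' t = 0 and peaks within the first minute — a parametric stand-in for an
#' image-derived ascending-aorta curve sampled on an early-frame-rich
#' schedule.
#'
#' @param A1 Linear-rise coefficient, kBq/mL/min.
#' @param A2,A3 Exponential amplitudes, kBq/mL.
#' @param lambda1,lambda2,lambda3 Decay rates, 1/min, all negative with
#'   `lambda1 < lambda2 <= lambda3`.
#' @param plasma_to_blood_ratio Scalar cp/cb ratio; default 1 (cb == cp).
#' @param t_check_max Upper end (min) of the nonnegativity check window.
#' @return A [plasma_input].
#' @examples
#' inp <- feng_input()
#' inp$cp(c(0, 0.5, 1, 5, 25))
#' @export
feng_input <- function(A1 = 851.1, A2 = 21.9, A3 = 20.8,
                       lambda1 = -4.13, lambda2 = -0.12, lambda3 = -0.01,
                       plasma_to_blood_ratio = 1, t_check_max = 25) {
  stopifnot(is.numeric(c(A1, A2, A3, lambda1, lambda2, lambda3)))
  if (!(lambda1 < lambda2 && lambda2 <= lambda3 && lambda3 < 0))
    stop("invalid params: need lambda1 < lambda2 <= lambda3 < 0")
  cp <- function(t) {
    (A1 * t - A2 - A3) * exp(lambda1 * t) + A2 * exp(lambda2 * t) +
      A3 * exp(lambda3 * t)
  }
  probe <- cp(seq(0, t_check_max, length.out = 2001))
  if (any(probe < -1e-9))
    stop("invalid params: Cp goes negative on the check window")
  plasma_input(cp, plasma_to_blood_ratio, model = "feng")
}

#' Simulate a noisy time-activity curve
#'
#' Runs the forward model ([solve_2tc()] on a fine grid, then
#' [frame_average()]) and adds zero-mean Gaussian noise with standard
#' deviation `noise_level * sqrt(value_i / duration_i_min)` — variance
#' inversely proportional to frame duration, a count-statistics proxy for
#' frame-averaged PET concentrations. Values are clipped at zero.
#'
#' @param params True [kinetic_params].
#' @param input_fn A [plasma_input].
#' @param schedule A [frame_schedule].
#' @param noise_level Noise scale (>= 0); 0 gives the exact frame means.
#'   Default 0.05 gives a moderate, depot-realistic noise level.
#' @param seed Integer seed; the same seed reproduces the curve exactly.
#' @param dt_s Fine-grid step, seconds.
#' @return A [tac] with attribute `truth` carrying the generating
#'   parameters and noiseless frame means.
#' @export
simulate_tac <- function(params, input_fn, schedule, noise_level = 0.05,
                         seed = 1L, dt_s = 0.5) {
  stopifnot(noise_level >= 0)
  t_end <- max(schedule$end_s) / 60
  h <- dt_s / 60
  grid <- seq(0, t_end + h, by = h)
  clean <- frame_average(solve_2tc(params, input_fn, grid), schedule)
  vals <- clean$values
  if (noise_level > 0) {
    dur <- (schedule$end_s - schedule$start_s) / 60
    sd <- noise_level * sqrt(pmax(vals, 0) / dur)
    noise <- with_preserved_rng(seed, stats::rnorm(length(vals), 0, sd))
    vals <- pmax(vals + noise, 0)
  }
  out <- tac(schedule, vals)
  attr(out, "truth") <- list(params = params, noiseless = clean$values,
                             noise_level = noise_level, seed = seed)
  out
}

#' Default per-depot kinetic parameter priors
#'
#' Independent log-normal priors for `K1`, `k2`, `k3` and `vb` in the three
#' adipose depots (supraclavicular SCV, upper chest UCH, subcutaneous
#' abdominal ABD) and skeletal muscle. Medians are anchored so that the
#' median net uptake rate Ki is about 0.012 (SCV), 0.008 (UCH), 0.005
#' (ABD) and 0.036 mL/min/cm^3 (muscle, ~3-fold the supraclavicular
#' rate), with spreads that let the depot distributions overlap while
#' preserving the ordering muscle > SCV > UCH > ABD in cohort medians.
#'
#' @return A data frame of class `depot_priors`, one row per depot, with
#'   log-median (`*_med`) and log-SD (`*_sdlog`) columns per parameter.
#' @export
depot_priors <- function() {
  pri <- data.frame(
    depot = c("SCV", "UCH", "ABD", "muscle"),
    K1_med = c(0.040, 0.032, 0.025, 0.090),
    k2_med = c(0.35, 0.36, 0.40, 0.30),
    k3_med = c(0.15, 0.12, 0.10, 0.20),
    vb_med = c(0.05, 0.03, 0.02, 0.04),
    K1_sdlog = 0.25, k2_sdlog = 0.25, k3_sdlog = 0.25, vb_sdlog = 0.30,
    stringsAsFactors = FALSE)
  class(pri) <- c("depot_priors", "data.frame")
  pri
}

#' Cohort simulation specification
#'
#' @param n Number of subjects (>= 3).
#' @param bmi_effect Log-linear slope of supraclavicular Ki on BMI, per BMI
#'   unit (negative: Ki falls with adiposity). Default -0.03.
#' @param t2d_fraction Fraction of subjects with type 2 diabetes.
#' @param t2d_effect Multiplicative reduction of supraclavicular Ki in T2D
#'   subjects (< 1 lowers Ki). Default 0.7.
#' @param bmi_range BMI sampling range, default 20-38 (normal to obese).
#' @param noise_level TAC noise scale passed to [simulate_tac()].
#' @param seed Integer seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 36L, bmi_effect = -0.03, t2d_fraction = 0.14,
                        t2d_effect = 0.7, bmi_range = c(20, 38),
                        noise_level = 0.05, seed = 1L) {
  if (n < 3L) stop("n must be >= 3")
  if (t2d_fraction < 0 || t2d_fraction > 1)
    stop("t2d_fraction must be in [0, 1]")
  structure(list(n = as.integer(n), bmi_effect = bmi_effect,
                 t2d_fraction = t2d_fraction, t2d_effect = t2d_effect,
                 bmi_range = bmi_range, noise_level = noise_level,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

draw_lognormal <- function(median, sdlog) {
  stats::rlnorm(1, meanlog = log(median), sdlog = sdlog)
}

#' Simulate a cohort with known ground truth
#'
#' For each subject: BMI drawn uniformly over `bmi_range`, a T2D flag with
#' probability `t2d_fraction`, injected dose and weight, and per-depot
#' kinetic parameters drawn from [depot_priors()]. The supraclavicular Ki
#' is modulated by BMI (`exp(bmi_effect * (BMI - mid))`, applied through
#' K1 so the rate constants stay consistent) and by the multiplicative T2D
#' effect. Per-depot noisy TACs are simulated on the canonical 32-frame
#' schedule. Ground truth is retained alongside every output.
#'
#' @param spec A [cohort_spec].
#' @param priors A [depot_priors()] table.
#' @param input_fn The shared [plasma_input]; default [feng_input()].
#' @param schedule Frame schedule; default [canonical_frame_schedule()].
#' @return A list of class `cohort`: `covariates` (data frame: subject_id,
#'   bmi, t2d, weight_kg, dose_MBq), `truth` (data frame: subject_id,
#'   depot, K1, k2, k3, vb, ki), `tacs` (list of [tac] keyed
#'   `subject::depot`), plus the spec, priors and input.
#' @export
simulate_cohort <- function(spec = cohort_spec(), priors = depot_priors(),
                            input_fn = feng_input(),
                            schedule = canonical_frame_schedule()) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(priors, "depot_priors"))
  bmi_mid <- mean(spec$bmi_range)
  res <- with_preserved_rng(spec$seed, {
    cov <- data.frame(
      subject_id = sprintf("S%03d", seq_len(spec$n)),
      bmi = stats::runif(spec$n, spec$bmi_range[1], spec$bmi_range[2]),
      t2d = stats::runif(spec$n) < spec$t2d_fraction,
      weight_kg = stats::runif(spec$n, 60, 110),
      dose_MBq = stats::rnorm(spec$n, 312, 10),
      stringsAsFactors = FALSE)
    truth <- list(); tacs <- list()
    for (i in seq_len(spec$n)) {
      for (d in seq_len(nrow(priors))) {
        pr <- priors[d, ]
        K1 <- draw_lognormal(pr$K1_med, pr$K1_sdlog)
        k2 <- draw_lognormal(pr$k2_med, pr$k2_sdlog)
        k3 <- draw_lognormal(pr$k3_med, pr$k3_sdlog)
        vb <- min(draw_lognormal(pr$vb_med, pr$vb_sdlog), 0.29)
        if (pr$depot == "SCV") {
          scale <- exp(spec$bmi_effect * (cov$bmi[i] - bmi_mid))
          if (cov$t2d[i]) scale <- scale * spec$t2d_effect
          K1 <- K1 * scale   # scales Ki by the same factor
        }
        par <- kinetic_params(K1, k2, k3, vb = vb)
        key <- paste(cov$subject_id[i], pr$depot, sep = "::")
        truth[[key]] <- data.frame(
          subject_id = cov$subject_id[i], depot = pr$depot,
          K1 = K1, k2 = k2, k3 = k3, vb = vb, ki = macro_ki(par),
          stringsAsFactors = FALSE)
        tacs[[key]] <- simulate_tac(
          par, input_fn, schedule, noise_level = spec$noise_level,
          seed = spec$seed + 1000L * i + d)
      }
    }
    list(covariates = cov,
         truth = do.call(rbind, c(truth, list(make.row.names = FALSE))),
         tacs = tacs)
  })
  structure(c(res, list(spec = spec, priors = priors, input_fn = input_fn,
                        schedule = schedule)),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d subjects x %d depots, noise %.3g, seed %d\n",
              x$spec$n, nrow(x$priors), x$spec$noise_level, x$spec$seed))
  invisible(x)
}

#' Fit every TAC of a simulated cohort
#'
#' Runs [fit_tac()] on each subject-by-depot TAC and returns the fitted
#' parameters merged with the ground truth.
#'
#' @param cohort A `cohort` from [simulate_cohort()].
#' @param opts [fit_options()] used for every fit.
#' @return A data frame: subject_id, depot, truth (`ki_true`, ...) and
#'   fitted (`ki_fit`, `K1_fit`, ...) columns, plus `converged`.
#' @export
fit_cohort <- function(cohort, opts = fit_options()) {
  stopifnot(inherits(cohort, "cohort"))
  rows <- lapply(names(cohort$tacs), function(key) {
    fit <- fit_tac(cohort$tacs[[key]], cohort$input_fn, opts)
    tr <- cohort$truth[paste(cohort$truth$subject_id, cohort$truth$depot,
                             sep = "::") == key, ]
    data.frame(tr[, c("subject_id", "depot")],
               ki_true = tr$ki, K1_true = tr$K1,
               ki_fit = fit$ki, K1_fit = fit$params$K1,
               k2_fit = fit$params$k2, k3_fit = fit$params$k3,
               vb_fit = fit$params$vb, wrss = fit$wrss,
               converged = fit$converged, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Construct a block phantom with paired CT and PET volumes
#'
#' Builds a voxel grid containing rectangular tissue regions with Gaussian
#' HU jitter and uniform PET activity — adipose blocks inside the -190 to
#' -30 HU window, muscle near +45 HU, blood-pool regions, each with a
#' ground-truth label mask. Used to validate masking, spill-over exclusion
#' and SUV quantification against known voxel counts.
#'
#' @param layout Named list of regions; each region is a list with `from`,
#'   `to` (inclusive voxel index triplets), `hu_mean`, `hu_sd`, `pet`
#'   (kBq/mL). Regions must not overlap. Default: SCV/UCH/ABD adipose
#'   blocks, a muscle block and a blood block in a 40^3 grid.
#' @param dims Grid dimensions.
#' @param spacing Voxel spacing, mm (default 2.344 isotropic).
#' @param background_hu HU of unlabelled voxels (air, -1000).
#' @param seed Integer seed for the HU jitter.
#' @return List with `ct`, `pet` ([image_volume]s), `labels` (named list of
#'   [voi_mask]s) and `layout`.
#' @export
make_phantom <- function(layout = default_phantom_layout(),
                         dims = c(40L, 40L, 40L), spacing = 2.344,
                         background_hu = -1000, seed = 1L) {
  ct <- array(background_hu, dims)
  pet <- array(0, dims)
  taken <- array(FALSE, dims)
  labels <- list()
  with_preserved_rng(seed, {
    for (nm in names(layout)) {
      rg <- layout[[nm]]
      idx <- as.matrix(expand.grid(rg$from[1]:rg$to[1],
                                   rg$from[2]:rg$to[2],
                                   rg$from[3]:rg$to[3]))
      if (max(idx) > max(dims) || any(idx < 1) ||
          any(idx > rep(dims, each = nrow(idx))))
        stop("layout error: region outside the grid")
      if (any(taken[idx])) stop("layout error: overlapping regions")
      taken[idx] <- TRUE
      ct[idx] <- stats::rnorm(nrow(idx), rg$hu_mean, rg$hu_sd)
      pet[idx] <- rg$pet
      m <- array(FALSE, dims); m[idx] <- TRUE
      labels[[nm]] <- voi_mask(m, spacing)
    }
  })
  list(ct = image_volume(ct, spacing, "ct"),
       pet = image_volume(pet, spacing, "pet"),
       labels = labels, layout = layout)
}

#' @rdname make_phantom
#' @export
default_phantom_layout <- function() {
  list(
    scv = list(from = c(3, 3, 3), to = c(12, 12, 12),
               hu_mean = -100, hu_sd = 10, pet = 2.0),
    uch = list(from = c(16, 3, 3), to = c(25, 12, 12),
               hu_mean = -95, hu_sd = 10, pet = 1.4),
    abd = list(from = c(29, 3, 3), to = c(38, 12, 12),
               hu_mean = -105, hu_sd = 10, pet = 0.9),
    muscle = list(from = c(3, 16, 3), to = c(12, 30, 12),
                  hu_mean = 45, hu_sd = 8, pet = 5.5),
    blood = list(from = c(16, 16, 3), to = c(25, 25, 12),
                 hu_mean = 40, hu_sd = 5, pet = 12.0))
}

#' Simulate a qPCR Ct table
#'
#' Reference-gene (RPLP0) Ct values are Normal(`mu_ref`, `sigma`); each
#' target gene's Ct is the reference plus a gene-specific offset, minus
#' `log2(fold_change)` in the second group (one PCR cycle per 2-fold
#' expression change), plus noise. Relative expression 2^(-dCt) then
#' carries the designed fold-changes.
#'
#' @param genes Character vector of target genes.
#' @param fold_changes Named fold-changes (> 0) of group `group_levels[2]`
#'   relative to `group_levels[1]`, one per gene.
#' @param n_per_group Integer vector, subjects per group (length 2).
#' @param group_levels Group labels; default LBAT (reference) and HBAT.
#' @param gene_offsets Baseline Ct offsets from the reference gene.
#' @param mu_ref,sigma Reference-gene Ct mean and the per-measurement SD.
#' @param seed Integer seed.
#' @return Data frame: subject_id, group, gene, ct_target, ct_ref — the
#'   qPCR input format of the statistics stage.
#' @export
simulate_qpcr <- function(genes = c("UCP1", "SLC25A44", "BCKDHB", "BCAT1",
                                    "BCAT2"),
                          fold_changes = stats::setNames(rep(1, length(genes)),
                                                         genes),
                          n_per_group = c(7L, 16L),
                          group_levels = c("LBAT", "HBAT"),
                          gene_offsets = NULL, mu_ref = 18, sigma = 0.6,
                          seed = 1L) {
  stopifnot(length(n_per_group) == 2L, all(fold_changes > 0),
            all(genes %in% names(fold_changes)))
  if (is.null(gene_offsets))
    gene_offsets <- stats::setNames(rep(6, length(genes)), genes)
  with_preserved_rng(seed, {
    rows <- list()
    sid <- 0L
    for (g in 1:2) {
      for (s in seq_len(n_per_group[g])) {
        sid <- sid + 1L
        ct_ref <- stats::rnorm(1, mu_ref, sigma)
        for (gene in genes) {
          shift <- if (g == 2L) log2(fold_changes[[gene]]) else 0
          ct_t <- ct_ref + gene_offsets[[gene]] - shift +
            stats::rnorm(1, 0, sigma)
          rows[[length(rows) + 1L]] <- data.frame(
            subject_id = sprintf("Q%03d", sid),
            group = group_levels[g], gene = gene,
            ct_target = ct_t, ct_ref = ct_ref,
            stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  })
}
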
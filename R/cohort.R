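#' Default dose-metric calibration table
#'
#' Cohort means and standard deviations of the V5-V25 dose metrics (percent)
#' and absolute structure volume (cm^3) for pelvic bone marrow and its three
#' substructures, separately for the two-phase conformal (CRT) and the
#' single-phase intensity-modulated (IMRT) delivery techniques. These are the
#' generator's default calibration targets.
#'
#' @return Data frame with columns `group`, `structure`, `metric`, `mean`,
#'   `sd`.
#' @export
dose_metric_calibration <- function() {
  build <- function(group, structure, volume, v) {
    data.frame(group = group, structure = structure,
               metric = c("volume", paste0("v", c(5, 10, 15, 20, 25))),
               mean = c(volume[1], v[, 1]), sd = c(volume[2], v[, 2]),
               stringsAsFactors = FALSE)
  }
  rbind(
    build("CRT", "whole_pelvis", c(1399.6, 253.1),
          cbind(c(60.4, 57.3, 53.9, 48.7, 46.7), c(12.9, 12.5, 12.0, 11.7, 11.7))),
    build("IMRT", "whole_pelvis", c(1335.6, 245.8),
          cbind(c(89.8, 82.6, 78.7, 73.8, 64.4), c(4.3, 4.7, 4.8, 5.2, 7.3))),
    build("CRT", "iliac", c(481.7, 82.2),
          cbind(c(40.1, 35.7, 33.2, 30.8, 28.4), c(19.5, 17.9, 16.6, 14.7, 14.7))),
    build("IMRT", "iliac", c(453.3, 73.5),
          cbind(c(83.0, 68.7, 61.5, 56.2, 47.5), c(7.4, 7.4, 6.8, 5.6, 6.6))),
    build("CRT", "lumbosacral", c(317.6, 65.1),
          cbind(c(24.0, 19.8, 17.6, 16.3, 15.1), c(24.0, 23.0, 22.6, 22.1, 21.7))),
    build("IMRT", "lumbosacral", c(312.7, 62.2),
          cbind(c(81.1, 71.4, 67.0, 63.1, 59.8), c(9.9, 11.5, 11.7, 11.9, 12.1))),
    build("CRT", "lower_pelvis", c(599.6, 119.5),
          cbind(c(95.9, 94.4, 89.5, 80.0, 77.9), c(7.5, 9.1, 9.4, 8.9, 9.0))),
    build("IMRT", "lower_pelvis", c(569.6, 128.0),
          cbind(c(100.0, 100.0, 99.0, 93.9, 80.7), c(0.0, 0.2, 1.6, 6.6, 11.2))))
}

#' Generator configuration
#'
#' Bundles every tunable of the synthetic cohort generator. Defaults encode
#' the study conditions the analysis is calibrated to: 25 conformal (CRT) and
#' 21 intensity-modulated (IMRT) patients; dose-metric means/SDs from
#' [dose_metric_calibration()]; cohort baseline blood counts (means with
#' SD taken as range/4 of the printed baseline ranges, truncated to those
#' ranges); covariate rates (female 27/46, T3-4 23/46, node-positive 19/46,
#' age 66 years on 44-88); the week-1..5 suppression template peaking at
#' week 3 with recovery from week 4; per-analyte susceptibility slopes tied
#' to the V10 dose metrics; and the default LKB parameter set used to draw
#' ground-truth HT3+ outcomes.
#'
#' @param n_crt,n_imrt Group sizes (>= 2).
#' @param metric_calibration Calibration table as from
#'   [dose_metric_calibration()].
#' @param level_correlation Correlation of the patient-level random effect
#'   shared across V5-V25 draws (default 0.7).
#' @param baseline_mean,baseline_sd,baseline_range Baseline blood
#'   distributions per analyte (hgb g/dL; wcc/anc/plats 10^9/L).
#' @param female_offset Additive shift of baseline means for female patients.
#' @param week_template Relative suppression weight per week 1..5.
#' @param slopes Susceptibility per percent V10: `wcc` (iliac), `anc`
#'   (mean of iliac and lumbosacral), `hgb` (iliac), `plats` (lower pelvis).
#' @param noise_sd_log,frailty_sd_log Log-scale SDs of the weekly
#'   multiplicative noise and the per-patient frailty factor.
#' @param ratio_clip Bounds applied to simulated weekly count ratios.
#' @param lkb [lkb_params()] used to simulate HT3+ ground truth.
#' @param plan Prescription structure: total dose, per-phase doses and
#'   fraction numbers, and the maximum plan dose closing the DVH tail.
#' @return An object of class `"generator_config"`.
#' @export
generator_config <- function(
    n_crt = 25, n_imrt = 21,
    metric_calibration = dose_metric_calibration(),
    level_correlation = 0.7,
    baseline_mean = c(hgb = 12.9, wcc = 8.0, anc = 5.1, plats = 274.5),
    baseline_sd = c(hgb = (16.0 - 8.8) / 4, wcc = (17.9 - 3.4) / 4,
                    anc = (14.9 - 1.2) / 4, plats = (611 - 144) / 4),
    baseline_range = list(hgb = c(8.8, 16.0), wcc = c(3.4, 17.9),
                          anc = c(1.2, 14.9), plats = c(144, 611)),
    female_offset = c(hgb = -1.0, wcc = -0.89, anc = -0.70, plats = -20),
    week_template = c(0.35, 0.70, 1.00, 0.95, 0.60),
    slopes = c(wcc = 0.010, anc = 0.015, hgb = 0.002, plats = 0.0055),
    noise_sd_log = 0.10, frailty_sd_log = 0.15,
    ratio_clip = c(0.05, 1.10),
    lkb = lkb_params(),
    plan = list(
      CRT = list(phase_dose = c(30.6, 19.8), phase_fractions = c(17, 11),
                 max_dose = 50.4),
      IMRT = list(phase_dose = 53.2, phase_fractions = 28,
                  max_dose = 53.2 * 1.05)),
    covariates = list(age_mean = 66, age_range = c(44, 88), age_sd = 11,
                      p_female = 27 / 46, p_t34 = 23 / 46,
                      p_node_positive = 19 / 46)) {
  if (n_crt < 2 || n_imrt < 2) stop("group sizes must be >= 2")
  if (any(metric_calibration$sd < 0)) stop("calibration SDs must be >= 0")
  if (level_correlation < 0 || level_correlation > 1)
    stop("level_correlation must lie in [0, 1]")
  structure(list(n_crt = n_crt, n_imrt = n_imrt,
                 metric_calibration = metric_calibration,
                 level_correlation = level_correlation,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 baseline_range = baseline_range,
                 female_offset = female_offset,
                 week_template = week_template, slopes = slopes,
                 noise_sd_log = noise_sd_log, frailty_sd_log = frailty_sd_log,
                 ratio_clip = ratio_clip, lkb = lkb, plan = plan,
                 covariates = covariates),
            class = "generator_config")
}

# one truncated-normal draw (rejection with cap, then clamp)
rtrunc1 <- function(mean, sd, lo, hi, tries = 100) {
  if (sd == 0) return(min(max(mean, lo), hi))
  for (i in seq_len(tries)) {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
  min(max(mean, lo), hi)
}

# pool-adjacent-violators projection onto non-increasing sequences
pava_decreasing <- function(v) {
  if (length(v) < 2L) return(v)
  rev(stats::isoreg(seq_along(v), rev(v))$yf)
}

#' Draw V5-V25 dose metrics and structure volume for one patient
#'
#' Levels share a patient-level random effect (correlation
#' `level_correlation` between levels) so a "hot" patient is hot at every
#' level; each level's marginal is a truncated normal on `[0, 100]` with the
#' calibrated mean/SD, degenerate SDs treated as point masses. The monotone
#' constraint V5 >= V10 >= ... >= V25 is enforced by isotonic (decreasing)
#' projection.
#'
#' @param group `"CRT"` or `"IMRT"`.
#' @param structure Structure label.
#' @param config A [generator_config()].
#' @return Named numeric: `volume`, `v5`, `v10`, `v15`, `v20`, `v25`.
#' @export
draw_dose_metrics <- function(group, structure, config = generator_config()) {
  cal <- config$metric_calibration
  cal <- cal[cal$group == group & cal$structure == structure, ]
  if (!nrow(cal)) stop("no calibration for ", group, "/", structure)
  rho <- config$level_correlation
  z0 <- stats::rnorm(1)
  lv <- paste0("v", c(5, 10, 15, 20, 25))
  vals <- vapply(lv, function(metric) {
    row <- cal[cal$metric == metric, ]
    if (row$sd == 0) return(row$mean)
    z <- sqrt(rho) * z0 + sqrt(1 - rho) * stats::rnorm(1)
    x <- row$mean + row$sd * z
    if (x < 0 || x > 100) x <- rtrunc1(row$mean, row$sd, 0, 100)
    x
  }, numeric(1))
  vals <- pava_decreasing(vals)
  vals <- pmin(pmax(vals, 0), 100)
  vrow <- cal[cal$metric == "volume", ]
  vol <- rtrunc1(vrow$mean, vrow$sd, 1e-3, Inf)
  c(volume = vol, stats::setNames(vals, lv))
}

#' Generate one synthetic DVH
#'
#' Draws V5-V25 via [draw_dose_metrics()] and builds a cumulative DVH that
#' passes exactly through the knots (0 Gy, 100%), (5, V5) ... (25, V25) with
#' linear interpolation, then decays linearly from V25 to zero volume at the
#' plan maximum dose (50.4 Gy for the summed two-phase CRT plan, 53.2 x 1.05
#' for IMRT). The curve is converted to a differential DVH on the 0.1 Gy
#' grid, so recomputing V10 from the generated DVH returns the drawn value.
#'
#' @inheritParams draw_dose_metrics
#' @param metrics Optional pre-drawn metrics (as returned by
#'   [draw_dose_metrics()]); drawn internally when `NULL`.
#' @return A [dvh()].
#' @export
generate_dvh <- function(group, structure, config = generator_config(),
                         metrics = NULL) {
  if (is.null(metrics)) metrics <- draw_dose_metrics(group, structure, config)
  dmax <- config$plan[[group]]$max_dose
  knots_x <- c(0, 5, 10, 15, 20, 25, dmax)
  knots_y <- c(100, metrics[paste0("v", c(5, 10, 15, 20, 25))], 0) / 100
  # resample the piecewise-linear curve onto the uniform grid edges before
  # differencing so each 0.1 Gy bin carries the mass dropped across it
  grid <- seq(0, ceiling(dmax * 10) / 10 + 0.1, by = 0.1)
  frac <- stats::approx(knots_x, knots_y, xout = pmin(grid, dmax),
                        method = "linear")$y
  frac[grid >= dmax] <- 0
  differential_from_cumulative(
    cumulative_dvh(grid, frac, total_volume_ccm = metrics[["volume"]],
                   structure = structure))
}

#' Draw patient covariates
#'
#' Age is a truncated normal (mean 66, range 44-88); female sex, T3-4 stage
#' and node positivity are independent Bernoulli draws at the configured
#' cohort rates.
#'
#' @param n Number of patients.
#' @param config A [generator_config()].
#' @return Data frame with columns `age`, `female`, `t34`, `node_positive`.
#' @export
generate_covariates <- function(n, config = generator_config()) {
  cv <- config$covariates
  age <- vapply(seq_len(n), function(i)
    rtrunc1(cv$age_mean, cv$age_sd, cv$age_range[1], cv$age_range[2]),
    numeric(1))
  data.frame(age = age,
             female = stats::runif(n) < cv$p_female,
             t34 = stats::runif(n) < cv$p_t34,
             node_positive = stats::runif(n) < cv$p_node_positive)
}

#' Simulate a weekly blood series for one patient
#'
#' Baseline counts are truncated normals (female patients shifted down by
#' the configured offsets). Weekly counts follow
#' `count = baseline * clip(1 - S_a * g_w * eps, 0.05, 1.10)` where `g` is
#' the week-1..5 template peaking at week 3 (nadir at weeks 2-3, recovery
#' from week 4), `eps` is lognormal weekly noise, and the susceptibility
#' `S_a` couples each analyte to the relevant V10 dose metric scaled by a
#' per-patient lognormal frailty: WCC to iliac V10, ANC to the mean of iliac
#' and lumbosacral V10, haemoglobin (weakly) to iliac V10 and platelets to
#' lower-pelvis V10. A zero-dose patient therefore keeps ratios at 1 up to
#' clipping.
#'
#' @param metrics_by_structure Named list (by structure) of metric vectors as
#'   returned by [draw_dose_metrics()]; needs `iliac`, `lumbosacral` and
#'   `lower_pelvis`.
#' @param female Logical; applies the baseline offset.
#' @param config A [generator_config()].
#' @return A [blood_series()].
#' @export
simulate_bloods <- function(metrics_by_structure, female = FALSE,
                            config = generator_config()) {
  cm <- config$baseline_mean
  if (female) cm <- cm + config$female_offset
  analytes <- c("hgb", "wcc", "anc", "plats")
  baseline <- vapply(analytes, function(a)
    rtrunc1(cm[[a]], config$baseline_sd[[a]],
            config$baseline_range[[a]][1], config$baseline_range[[a]][2]),
    numeric(1))
  iliac <- metrics_by_structure$iliac[["v10"]]
  ls <- metrics_by_structure$lumbosacral[["v10"]]
  lp <- metrics_by_structure$lower_pelvis[["v10"]]
  u <- stats::rlnorm(1, 0, config$frailty_sd_log)
  S <- c(hgb = config$slopes[["hgb"]] * iliac,
         wcc = config$slopes[["wcc"]] * iliac,
         anc = config$slopes[["anc"]] * (0.5 * iliac + 0.5 * ls),
         plats = config$slopes[["plats"]] * lp) * u
  g <- config$week_template
  weekly <- data.frame(week = seq_along(g))
  for (a in analytes) {
    eps <- stats::rlnorm(length(g), 0, config$noise_sd_log)
    r <- pmin(pmax(1 - S[[a]] * g * eps, config$ratio_clip[1]),
              config$ratio_clip[2])
    weekly[[a]] <- baseline[[a]] * r
  }
  blood_series(baseline, weekly, sex = if (female) "female" else "male")
}

#' Simulate the ground-truth HT3+ outcome
#'
#' A Bernoulli draw with success probability equal to the LKB complication
#' probability of the whole-pelvis effective dose of the patient's plan.
#'
#' @param phases List of [plan_phase()] objects.
#' @param config A [generator_config()] (supplies the LKB parameters).
#' @return Logical, with attribute `ntcp` (the generating probability).
#' @export
simulate_ht3_outcome <- function(phases, config = generator_config()) {
  d <- deff_plan(phases, "whole_pelvis", config$lkb)
  p <- stats::pnorm((d - config$lkb$td50) / (config$lkb$m * config$lkb$td50))
  out <- stats::runif(1) < p
  attr(out, "ntcp") <- p
  attr(out, "deff") <- d
  out
}

# split a summed-plan DVH into sequential phases by scaling bin doses in
# proportion to each phase's prescription (same spatial distribution per
# phase), then rebinning to the 0.1 Gy grid
split_phases <- function(dvhs, plan_spec) {
  total <- sum(plan_spec$phase_dose)
  lapply(seq_along(plan_spec$phase_dose), function(k) {
    scale <- plan_spec$phase_dose[k] / total
    phase_dvhs <- lapply(dvhs, function(d)
      rebin_dvh(d$dose_gy * scale, d$volume_fraction,
                total_volume_ccm = d$total_volume_ccm,
                structure = d$structure))
    plan_phase(phase_dvhs, plan_spec$phase_fractions[k])
  })
}

#' Generate a complete synthetic cohort
#'
#' Produces the default study layout: `n_crt` two-phase conformal patients
#' (30.6 Gy / 17 fractions then 19.8 Gy / 11 fractions) and `n_imrt`
#' single-phase intensity-modulated patients (28 fractions). A single RNG
#' stream seeded once is consumed in fixed per-patient order — covariates,
#' then the four structure DVHs, then bloods, then the HT3+ outcome — so a
#' fixed seed yields a bit-identical cohort.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed.
#' @return An object of class `"synthetic_cohort"`: list with `patients`
#'   (list of per-patient records), `config` and `seed`. Each patient record
#'   holds `patient_id`, `group`, covariates, `metrics` (per structure),
#'   `phases`, `bloods`, `ht3_true`, `ntcp_true`, `deff_true`.
#' @export
generate_cohort <- function(config = generator_config(), seed = 1) {
  set.seed(seed)
  structures <- c("whole_pelvis", "iliac", "lumbosacral", "lower_pelvis")
  groups <- c(rep("CRT", config$n_crt), rep("IMRT", config$n_imrt))
  patients <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    grp <- groups[i]
    cov <- generate_covariates(1, config)
    metrics <- lapply(stats::setNames(structures, structures), function(s)
      draw_dose_metrics(grp, s, config))
    dvhs <- lapply(stats::setNames(structures, structures), function(s)
      generate_dvh(grp, s, config, metrics = metrics[[s]]))
    phases <- if (grp == "CRT") split_phases(dvhs, config$plan$CRT)
              else list(plan_phase(dvhs, config$plan$IMRT$phase_fractions))
    bloods <- simulate_bloods(metrics, female = cov$female, config = config)
    outcome <- simulate_ht3_outcome(phases, config)
    patients[[i]] <- list(
      patient_id = sprintf("P%03d", i), group = grp,
      age = cov$age, female = cov$female, t34 = cov$t34,
      node_positive = cov$node_positive,
      metrics = metrics, dvhs = dvhs, phases = phases, bloods = bloods,
      ht3_true = as.logical(outcome),
      ntcp_true = attr(outcome, "ntcp"),
      deff_true = attr(outcome, "deff"))
  }
  structure(list(patients = patients, config = config, seed = seed),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  grp <- vapply(x$patients, `[[`, character(1), "group")
  cat("Synthetic cohort:", length(x$patients), "patients (",
      sum(grp == "CRT"), "CRT /", sum(grp == "IMRT"), "IMRT ), seed",
      x$seed, "\n")
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Emits `dvh.csv` (per-patient summed-plan DVHs, readable by
#' [read_dvh_csv()]), `bloods.csv` ([read_bloods_csv()] format),
#' `covariates.csv` (including group, phase layout and the simulated HT3+
#' ground truth) and `truth.json` (generating parameters, for recovery
#' tests).
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if absent).
#' @return Named character vector of the file paths written, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(dvh = file.path(dir, "dvh.csv"),
             bloods = file.path(dir, "bloods.csv"),
             covariates = file.path(dir, "covariates.csv"),
             truth = file.path(dir, "truth.json"))
  dvhs <- lapply(cohort$patients, `[[`, "dvhs")
  names(dvhs) <- vapply(cohort$patients, `[[`, character(1), "patient_id")
  write_dvh_csv(dvhs, paths[["dvh"]])
  bloods <- lapply(cohort$patients, `[[`, "bloods")
  names(bloods) <- names(dvhs)
  write_bloods_csv(bloods, paths[["bloods"]])
  cov <- do.call(rbind, lapply(cohort$patients, function(p)
    data.frame(patient_id = p$patient_id, group = p$group, age = p$age,
               female = p$female, t34 = p$t34,
               node_positive = p$node_positive, ht3_true = p$ht3_true,
               deff_true = p$deff_true, ntcp_true = p$ntcp_true,
               stringsAsFactors = FALSE)))
  utils::write.csv(cov, paths[["covariates"]], row.names = FALSE, quote = FALSE)
  cfg <- cohort$config
  truth <- list(seed = cohort$seed,
                lkb = list(n = cfg$lkb$n, m = cfg$lkb$m, td50 = cfg$lkb$td50,
                           alpha_beta = cfg$lkb$alpha_beta),
                slopes = as.list(cfg$slopes),
                week_template = cfg$week_template,
                n_crt = cfg$n_crt, n_imrt = cfg$n_imrt)
  writeLines(jsonlite::toJSON(truth, auto_unbox = TRUE, digits = NA),
             paths[["truth"]])
  invisible(paths)
}
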
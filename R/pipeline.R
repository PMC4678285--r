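#' Run the full group-comparison analysis on a cohort
#'
#' Executes the whole analysis battery on a synthetic (or file-loaded)
#' cohort and returns a bundle of result tables:
#'
#' * `dose_comparison` — per structure and dose level, group means and SDs
#'   with a two-sided Mann-Whitney U comparison;
#' * `blood_summary` — per group and analyte, mean baseline, absolute nadir
#'   and ratio nadir (with observed ranges) plus a Welch comparison of
#'   absolute nadirs between groups;
#' * `toxicity` — per-lineage maximum CTCAE grades, observed HT3+ rates by
#'   group;
#' * `regression` — univariate regressions of nadir ratios and absolute
#'   nadirs on each dose metric within each group, Holm-corrected within
#'   (group, structure, analyte) families, and multivariable models adding
#'   the clinical covariates to one dose metric at a time;
#' * `covariate_regression` — univariate regressions of absolute nadirs on
#'   the clinical covariates (female, age, T3-4, node-positive);
#' * `logistic` — univariate logistic regressions of simulated HT3+ truth on
#'   each whole-pelvis dose metric per group (skipped with a note where
#'   separation or a single outcome class makes them inestimable);
#' * `ntcp_panel` — per-patient effective dose, NTCP and parameter-CI band,
#'   group means and a Welch comparison of the NTCP distributions;
#' * `manifest` — seed, group sizes, parameter set and package version.
#'
#' @param cohort A [generate_cohort()] result (or a list with the same
#'   shape).
#' @param params [lkb_params()] for the NTCP panel.
#' @param correction `"holm"` (default) or `"BH"`.
#' @param alpha Family-wise level for corrected decisions.
#' @return An object of class `"analysis_bundle"` (named list of data
#'   frames plus `manifest`).
#' @export
run_comparison <- function(cohort, params = lkb_params(),
                           correction = c("holm", "BH"), alpha = 0.05) {
  correction <- match.arg(correction)
  pts <- cohort$patients
  grp <- vapply(pts, `[[`, character(1), "group")
  structures <- names(pts[[1]]$metrics)
  levels <- paste0("v", c(5, 10, 15, 20, 25))

  # recompute metrics from the DVHs (not the generator draws)
  met <- do.call(rbind, lapply(pts, function(p) {
    rows <- lapply(structures, function(s) {
      dm <- dose_metrics(p$dvhs[[s]])
      cbind(patient_id = p$patient_id, group = p$group, dm)
    })
    do.call(rbind, rows)
  }))

  dose_comparison <- do.call(rbind, lapply(structures, function(s) {
    do.call(rbind, lapply(levels, function(lv) {
      xs <- met[met$structure == s, ]
      a <- xs[[lv]][xs$group == "CRT"]; b <- xs[[lv]][xs$group == "IMRT"]
      tst <- mann_whitney_u(a, b)
      data.frame(structure = s, metric = lv,
                 crt_mean = mean(a), crt_sd = stats::sd(a),
                 imrt_mean = mean(b), imrt_sd = stats::sd(b),
                 u = tst$statistic, p = tst$p, stringsAsFactors = FALSE)
    }))
  }))

  nad <- do.call(rbind, lapply(pts, function(p)
    cbind(patient_id = p$patient_id, group = p$group, nadir(p$bloods))))
  blood_summary <- do.call(rbind, lapply(unique(nad$analyte), function(a) {
    do.call(rbind, lapply(c("CRT", "IMRT"), function(g) {
      b <- nad[nad$analyte == a & nad$group == g, ]
      data.frame(group = g, analyte = a,
                 baseline_mean = mean(b$baseline),
                 nadir_absolute_mean = mean(b$nadir_absolute),
                 nadir_absolute_min = min(b$nadir_absolute),
                 nadir_absolute_max = max(b$nadir_absolute),
                 nadir_ratio_mean = mean(b$nadir_ratio),
                 modal_nadir_week = as.integer(names(which.max(table(b$nadir_week)))),
                 stringsAsFactors = FALSE)
    }))
  }))
  nadir_tests <- do.call(rbind, lapply(unique(nad$analyte), function(a) {
    b <- nad[nad$analyte == a, ]
    tst <- welch_t(b$nadir_absolute[b$group == "CRT"],
                   b$nadir_absolute[b$group == "IMRT"])
    data.frame(analyte = a, t = tst$statistic, p = tst$p,
               stringsAsFactors = FALSE)
  }))

  tox <- lapply(pts, function(p) ht3_flag(p$bloods))
  toxicity <- data.frame(
    patient_id = vapply(pts, `[[`, character(1), "patient_id"),
    group = grp,
    anemia = vapply(tox, function(t) t$max_grade[["anemia"]], integer(1)),
    leukopenia = vapply(tox, function(t) t$max_grade[["leukopenia"]], integer(1)),
    neutropenia = vapply(tox, function(t) t$max_grade[["neutropenia"]], integer(1)),
    thrombocytopenia = vapply(tox, function(t) t$max_grade[["thrombocytopenia"]], integer(1)),
    ht3_observed = vapply(tox, `[[`, logical(1), "ht3_plus"),
    ht3_true = vapply(pts, `[[`, logical(1), "ht3_true"),
    stringsAsFactors = FALSE)

  # regression battery: nadir ratio and absolute nadir on each dose metric,
  # per group, Holm families = (group, structure, analyte)
  reg_rows <- list()
  for (g in c("CRT", "IMRT")) {
    sel <- grp == g
    for (s in structures) {
      ms <- met[met$structure == s & met$group == g, ]
      ms <- ms[match(vapply(pts[sel], `[[`, character(1), "patient_id"),
                     ms$patient_id), ]
      for (a in unique(nad$analyte)) {
        na_g <- nad[nad$analyte == a & nad$group == g, ]
        for (outcome_kind in c("nadir_ratio", "nadir_absolute")) {
          y <- na_g[[outcome_kind]]
          for (lv in levels) {
            x <- ms[[lv]]
            if (stats::var(x) == 0) next  # degenerate level (e.g. 100 +/- 0)
            r <- ols_fit(y, stats::setNames(data.frame(x), lv))
            reg_rows[[length(reg_rows) + 1L]] <- data.frame(
              group = g, structure = s, analyte = a,
              outcome = outcome_kind, metric = lv,
              beta = r$beta, se = r$se, p = r$p, n_obs = r$n_obs,
              family = paste(g, s, a, outcome_kind, sep = ":"),
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  regression <- family_correction(do.call(rbind, reg_rows),
                                  alpha = alpha, method = correction)

  # covariate regressions on absolute nadirs (pooled groups)
  cov_df <- data.frame(
    female = as.numeric(vapply(pts, `[[`, logical(1), "female")),
    age = vapply(pts, `[[`, numeric(1), "age"),
    t34 = as.numeric(vapply(pts, `[[`, logical(1), "t34")),
    node_positive = as.numeric(vapply(pts, `[[`, logical(1), "node_positive")))
  covariate_regression <- do.call(rbind, lapply(unique(nad$analyte), function(a) {
    y <- nad$nadir_absolute[nad$analyte == a]
    r <- ols_fit(y, cov_df)
    cbind(analyte = a, r)
  }))

  # multivariable: covariates + one whole-pelvis metric at a time
  multivariate <- do.call(rbind, lapply(levels, function(lv) {
    ms <- met[met$structure == "whole_pelvis", ]
    x <- ms[[lv]][match(vapply(pts, `[[`, character(1), "patient_id"),
                        ms$patient_id)]
    if (stats::var(x) == 0) return(NULL)
    y <- nad$nadir_ratio[nad$analyte == "wcc"]
    df <- cbind(cov_df, stats::setNames(data.frame(x), lv))
    r <- ols_fit(y, df, univariate = FALSE)
    cbind(metric = lv, r)
  }))

  # logistic: HT3+ truth on whole-pelvis metrics per group
  log_rows <- list()
  for (g in c("CRT", "IMRT")) {
    sel <- grp == g
    y <- vapply(pts[sel], `[[`, logical(1), "ht3_true")
    ms <- met[met$structure == "whole_pelvis" & met$group == g, ]
    ms <- ms[match(vapply(pts[sel], `[[`, character(1), "patient_id"),
                   ms$patient_id), ]
    for (lv in levels) {
      if (stats::var(ms[[lv]]) == 0) next
      r <- tryCatch(logistic_fit(y, stats::setNames(data.frame(ms[[lv]]), lv)),
                    error = function(e) NULL)
      note <- if (is.null(r)) "not estimable" else ""
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        group = g, metric = lv,
        beta = if (is.null(r)) NA_real_ else r$beta,
        se = if (is.null(r)) NA_real_ else r$se,
        p = if (is.null(r)) NA_real_ else r$p,
        note = note, stringsAsFactors = FALSE)
    }
  }
  logistic <- do.call(rbind, log_rows)

  # NTCP panel
  ntcp_panel <- do.call(rbind, lapply(pts, function(p) {
    d <- deff_plan(p$phases, "whole_pelvis", params)
    res <- ntcp(d, params)
    data.frame(patient_id = p$patient_id, group = p$group,
               deff_gy = d, ntcp = res$ntcp,
               ntcp_low = if (is.null(res$ci)) NA_real_ else res$ci[1],
               ntcp_high = if (is.null(res$ci)) NA_real_ else res$ci[2],
               stringsAsFactors = FALSE)
  }))
  ntcp_test <- welch_t(ntcp_panel$ntcp[ntcp_panel$group == "CRT"],
                       ntcp_panel$ntcp[ntcp_panel$group == "IMRT"])
  ntcp_summary <- do.call(rbind, lapply(c("CRT", "IMRT"), function(g) {
    b <- ntcp_panel[ntcp_panel$group == g, ]
    data.frame(group = g, mean_deff = mean(b$deff_gy),
               mean_ntcp = mean(b$ntcp),
               mean_ntcp_low = mean(b$ntcp_low),
               mean_ntcp_high = mean(b$ntcp_high),
               ht3_observed_rate = mean(toxicity$ht3_observed[toxicity$group == g]),
               ht3_true_rate = mean(toxicity$ht3_true[toxicity$group == g]),
               stringsAsFactors = FALSE)
  }))

  manifest <- list(
    seed = cohort$seed,
    n_crt = sum(grp == "CRT"), n_imrt = sum(grp == "IMRT"),
    lkb = list(n = params$n, m = params$m, td50 = params$td50,
               alpha_beta = params$alpha_beta),
    correction = correction, alpha = alpha,
    package_version = as.character(utils::packageVersion("pbmtox")))

  structure(list(dose_comparison = dose_comparison,
                 blood_summary = blood_summary,
                 nadir_tests = nadir_tests,
                 toxicity = toxicity,
                 regression = regression,
                 covariate_regression = covariate_regression,
                 multivariate = multivariate,
                 logistic = logistic,
                 ntcp_panel = ntcp_panel,
                 ntcp_summary = ntcp_summary,
                 ntcp_test = ntcp_test,
                 manifest = manifest),
            class = "analysis_bundle")
}

#' @export
print.analysis_bundle <- function(x, ...) {
  cat("Analysis bundle:", x$manifest$n_crt, "CRT /", x$manifest$n_imrt,
      "IMRT patients; tables:",
      paste(setdiff(names(x), "manifest"), collapse = ", "), "\n")
  invisible(x)
}

#' Write an analysis bundle to disk
#'
#' Emits one TSV per result table (`dose_comparison.tsv`,
#' `blood_summary.tsv`, `regression.tsv`, `ntcp_panel.tsv`,
#' `toxicity.tsv`, ...) plus `bundle.json` holding every table and the run
#' manifest; re-parsing the JSON reproduces the bundle's numeric content.
#' Percent metrics are written at 1 decimal and regression coefficients at
#' 3 decimals in the TSVs; the JSON keeps full precision.
#'
#' @param bundle An [run_comparison()] result.
#' @param dir Output directory (created if absent).
#' @return Named character vector of written paths, invisibly.
#' @export
emit_tables <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fmt <- function(df, percent_cols = NULL, coef_cols = NULL) {
    for (cc in intersect(percent_cols, names(df))) df[[cc]] <- round(df[[cc]], 1)
    for (cc in intersect(coef_cols, names(df))) df[[cc]] <- round(df[[cc]], 3)
    df
  }
  tables <- setdiff(names(bundle), "manifest")
  paths <- character(0)
  for (tb in tables) {
    df <- bundle[[tb]]
    if (!is.data.frame(df)) next
    df <- fmt(df,
              percent_cols = c("crt_mean", "crt_sd", "imrt_mean", "imrt_sd"),
              coef_cols = c("beta", "se"))
    p <- file.path(dir, paste0(tb, ".tsv"))
    utils::write.table(df, p, sep = "\t", row.names = FALSE, quote = FALSE)
    paths[tb] <- p
  }
  jp <- file.path(dir, "bundle.json")
  writeLines(jsonlite::toJSON(unclass(bundle), auto_unbox = TRUE,
                              digits = NA, dataframe = "columns"),
             jp)
  paths["bundle"] <- jp
  invisible(paths)
}
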
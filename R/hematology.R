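#' Weekly blood-count series for one patient
#'
#' Holds a baseline measurement set and weekly on-treatment values for
#' haemoglobin (`hgb`, g/dL), white cell count (`wcc`), absolute neutrophil
#' count (`anc`) and platelets (`plats`), the latter three in 10^9 cells per
#' litre. Weeks may be missing (gaps are allowed); baseline values must all
#' be present and positive.
#'
#' @param baseline Named numeric with elements `hgb`, `wcc`, `anc`, `plats`,
#'   all > 0.
#' @param weekly Data frame with integer column `week` (>= 1, unique) and
#'   numeric columns `hgb`, `wcc`, `anc`, `plats` (`NA` = missing sample).
#' @param sex `"female"` or `"male"`; sets the haemoglobin lower limit of
#'   normal used in grading.
#' @return An object of class `"blood_series"`.
#' @export
blood_series <- function(baseline, weekly, sex = c("female", "male")) {
  sex <- match.arg(sex)
  analytes <- c("hgb", "wcc", "anc", "plats")
  if (!all(analytes %in% names(baseline)))
    stop("baseline must contain hgb, wcc, anc, plats")
  baseline <- vapply(analytes, function(a) as.numeric(baseline[[a]]), numeric(1))
  if (anyNA(baseline) || any(baseline <= 0))
    stop("all baseline values must be present and positive")
  if (!is.data.frame(weekly) || !all(c("week", analytes) %in% names(weekly)))
    stop("weekly must be a data frame with columns week, hgb, wcc, anc, plats")
  if (anyDuplicated(weekly$week)) stop("week indices must be unique")
  if (any(weekly$week < 1)) stop("weekly observations start at week 1")
  vals <- as.matrix(weekly[analytes])
  if (any(vals < 0, na.rm = TRUE)) stop("weekly counts must be non-negative")
  weekly <- weekly[order(weekly$week), c("week", analytes)]
  rownames(weekly) <- NULL
  structure(list(baseline = baseline, weekly = weekly, sex = sex),
            class = "blood_series")
}

#' Weekly counts as ratios of baseline
#'
#' Divides each week's counts by the patient's baseline count, analyte by
#' analyte.
#'
#' @param s A [blood_series()].
#' @return Data frame with columns `week`, `hgb`, `wcc`, `anc`, `plats`
#'   holding ratios (NA where the weekly sample is missing).
#' @export
ratio_series <- function(s) {
  if (!inherits(s, "blood_series")) stop("s must be a blood_series")
  out <- s$weekly
  for (a in c("hgb", "wcc", "anc", "plats")) out[[a]] <- out[[a]] / s$baseline[[a]]
  out
}

#' Blood-count nadirs
#'
#' For each analyte, the minimum over observed on-treatment weeks (missing
#' weeks skipped), both absolute and as a ratio of baseline, together with
#' the earliest week attaining the minimum. The identity
#' `ratio_nadir * baseline == absolute_nadir` holds exactly.
#'
#' @param s A [blood_series()].
#' @return Data frame with one row per analyte and columns `analyte`,
#'   `baseline`, `nadir_absolute`, `nadir_ratio`, `nadir_week`.
#' @export
nadir <- function(s) {
  if (!inherits(s, "blood_series")) stop("s must be a blood_series")
  if (!nrow(s$weekly)) stop("at least one weekly observation is required")
  rows <- lapply(c("hgb", "wcc", "anc", "plats"), function(a) {
    v <- s$weekly[[a]]
    ok <- !is.na(v)
    if (!any(ok))
      return(data.frame(analyte = a, baseline = s$baseline[[a]],
                        nadir_absolute = NA_real_, nadir_ratio = NA_real_,
                        nadir_week = NA_integer_, stringsAsFactors = FALSE))
    mn <- min(v[ok])
    wk <- min(s$weekly$week[ok & v == mn])
    data.frame(analyte = a, baseline = s$baseline[[a]],
               nadir_absolute = mn, nadir_ratio = mn / s$baseline[[a]],
               nadir_week = as.integer(wk), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# CTCAE v4.0 cytopenia boundaries; strict "<" at each boundary, so a count
# exactly on a boundary takes the milder grade. HgB grade 4 needs clinical
# criteria not derivable from counts, hence the cap at 3.
ctcae_lln_defaults <- function(sex = "female") {
  c(hgb = if (sex == "male") 13.5 else 12.0, wcc = 4.0, anc = 1.5, plats = 150)
}

#' CTCAE v4.0 cytopenia grade for a single count
#'
#' Grades anemia (haemoglobin), leukopenia (WCC), neutropenia (ANC) and
#' thrombocytopenia (platelets) per the CTCAE v4.0 ranges: a value at or
#' above the lower limit of normal (LLN) is grade 0; below-LLN bands are
#' WCC <3/<2/<1, ANC <1.5/<1.0/<0.5, platelets <75/<50/<25, HgB <10/<8
#' (anemia grade 4 requires clinical criteria absent from count data, so the
#' maximum grade assignable here is 3). Boundaries are strict: e.g. an ANC of
#' exactly 1.0 is grade 2.
#'
#' @param analyte One of `"hgb"`, `"wcc"`, `"anc"`, `"plats"`.
#' @param value Count (vectorised, >= 0); units g/dL for `hgb`, 10^9/L
#'   otherwise.
#' @param lln Lower limit of normal; defaults per analyte
#'   (HgB 12.0 female / 13.5 male, WCC 4.0, ANC 1.5, platelets 150).
#' @param sex Used only for the default haemoglobin LLN.
#' @return Integer grade(s) 0-4.
#' @export
ctcae_grade <- function(analyte, value, lln = NULL, sex = "female") {
  analytes <- c("hgb", "wcc", "anc", "plats")
  if (!analyte %in% analytes)
    stop("unknown analyte '", analyte, "'; expected one of ",
         paste(analytes, collapse = ", "))
  if (any(value < 0, na.rm = TRUE)) stop("counts must be non-negative")
  if (is.null(lln)) lln <- ctcae_lln_defaults(sex)[[analyte]]
  cuts <- switch(analyte,
    hgb   = c(lln, 10.0, 8.0, -Inf),   # grade 4 not assignable from counts
    wcc   = c(lln, 3.0, 2.0, 1.0),
    anc   = c(lln, 1.5, 1.0, 0.5),
    plats = c(lln, 75, 50, 25))
  g <- integer(length(value))
  for (k in seq_along(cuts)) g[!is.na(value) & value < cuts[k]] <- k
  g[is.na(value)] <- NA_integer_
  g
}

#' Grade a blood series and flag grade 3+ haematologic toxicity
#'
#' Grades every observed on-treatment week in each lineage (baseline is not
#' graded), takes the per-lineage maximum, and flags HT3+ when any lineage
#' reaches grade 3 or higher at any week. Nadir summaries from [nadir()] are
#' attached.
#'
#' @param s A [blood_series()].
#' @param lln Optional named vector overriding the lower limits of normal.
#' @return An object of class `"toxicity_assessment"`: list with
#'   `max_grade` (named integer per lineage: anemia, leukopenia, neutropenia,
#'   thrombocytopenia), `ht3_plus` (logical), and `nadir` (data frame).
#' @export
ht3_flag <- function(s, lln = NULL) {
  if (!inherits(s, "blood_series")) stop("s must be a blood_series")
  lineages <- c(anemia = "hgb", leukopenia = "wcc",
                neutropenia = "anc", thrombocytopenia = "plats")
  if (is.null(lln)) lln <- ctcae_lln_defaults(s$sex)
  max_grade <- vapply(lineages, function(a) {
    g <- ctcae_grade(a, s$weekly[[a]], lln = lln[[a]])
    if (all(is.na(g))) 0L else max(g, na.rm = TRUE)
  }, integer(1))
  names(max_grade) <- names(lineages)
  structure(list(max_grade = max_grade,
                 ht3_plus = any(max_grade >= 3L),
                 nadir = nadir(s)),
            class = "toxicity_assessment")
}

#' @export
print.toxicity_assessment <- function(x, ...) {
  cat("Max CTCAE grade:",
      paste(names(x$max_grade), x$max_grade, sep = "=", collapse = " "),
      "\nHT3+:", x$ht3_plus, "\n")
  invisible(x)
}

#' Read weekly blood counts from CSV
#'
#' Expected columns: `patient_id`, `week` (0 = baseline, 1.. = on-treatment),
#' `hgb`, `wcc`, `anc`, `plats`; empty cells are missing samples. An optional
#' `sex` column (`female`/`male`) sets the haemoglobin grading limit.
#'
#' @param path CSV file path.
#' @return Named list of [blood_series()] keyed by patient id.
#' @export
read_bloods_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "week", "hgb", "wcc", "anc", "plats")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("bloods file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  out <- lapply(split(raw, raw$patient_id), function(block) {
    base <- block[block$week == 0, ]
    if (nrow(base) != 1L)
      stop("patient ", block$patient_id[1], " must have exactly one baseline (week 0) row in ", path)
    sex <- if ("sex" %in% names(block)) block$sex[1] else "female"
    blood_series(baseline = unlist(base[c("hgb", "wcc", "anc", "plats")]),
                 weekly = block[block$week > 0,
                                c("week", "hgb", "wcc", "anc", "plats")],
                 sex = sex)
  })
  out
}

#' Write blood series to CSV (inverse of [read_bloods_csv()])
#'
#' @param series Named list of [blood_series()] keyed by patient id.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_bloods_csv <- function(series, path) {
  rows <- lapply(names(series), function(pid) {
    s <- series[[pid]]
    base <- data.frame(patient_id = pid, week = 0L,
                       hgb = s$baseline[["hgb"]], wcc = s$baseline[["wcc"]],
                       anc = s$baseline[["anc"]], plats = s$baseline[["plats"]],
                       sex = s$sex, stringsAsFactors = FALSE)
    wk <- cbind(patient_id = pid, s$weekly, sex = s$sex)
    rbind(base, wk)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
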
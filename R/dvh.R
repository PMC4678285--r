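#' Dose-volume histograms for bone-marrow structures
#'
#' A differential DVH stores, for one delineated structure, the fraction of
#' structure volume whose absorbed dose falls in each 0.1 Gy bin. Bins are
#' half-open intervals `[dose_gy, dose_gy + 0.1)` labelled by their lower
#' edge, so a point dose of exactly 30 Gy sits in the bin labelled 30. Bins
#' with zero volume may be omitted (sparse representation); the stored bins
#' must be strictly ascending and lie on the 0.1 Gy grid.
#'
#' @param dose_gy Numeric vector of bin dose labels in Gy (ascending,
#'   multiples of the bin width).
#' @param volume_fraction Numeric vector of per-bin volume fractions in
#'   `[0, 1]`; for a completely covered structure these sum to 1 within
#'   `1e-6`.
#' @param total_volume_ccm Total structure volume in cm^3 (positive).
#' @param structure Structure label, one of `"whole_pelvis"`, `"iliac"`,
#'   `"lumbosacral"`, `"lower_pelvis"` or `"other"`.
#' @param bin_width Bin width in Gy; the canonical grid is 0.1 Gy.
#' @param complete If `TRUE` (default) the fractions must sum to 1 within
#'   `1e-6`.
#'
#' @return An object of class `"dvh"`.
#' @seealso [dose_metrics()], [v_at()], [cumulative_from_differential()]
#' @export
dvh <- function(dose_gy, volume_fraction, total_volume_ccm = 1,
                structure = "other", bin_width = 0.1, complete = TRUE) {
  dose_gy <- as.numeric(dose_gy)
  volume_fraction <- as.numeric(volume_fraction)
  if (length(dose_gy) != length(volume_fraction) || length(dose_gy) == 0L)
    stop("dose_gy and volume_fraction must be non-empty and equal length")
  if (anyNA(dose_gy) || anyNA(volume_fraction))
    stop("DVH values must be non-missing")
  if (is.unsorted(dose_gy, strictly = TRUE))
    stop("dose_gy must be strictly ascending")
  if (any(dose_gy < 0)) stop("doses must be non-negative")
  # bins must sit on the uniform grid
  off <- abs(dose_gy / bin_width - round(dose_gy / bin_width))
  if (any(off > 1e-6))
    stop("dose_gy values must be multiples of the bin width (", bin_width, " Gy)")
  if (any(volume_fraction < -1e-12))
    stop("volume fractions must be non-negative")
  volume_fraction <- pmax(volume_fraction, 0)
  if (complete && abs(sum(volume_fraction) - 1) > 1e-6)
    stop("volume fractions must sum to 1 within 1e-6 for a complete structure (got ",
         format(sum(volume_fraction)), ")")
  if (!is.numeric(total_volume_ccm) || length(total_volume_ccm) != 1L ||
      is.na(total_volume_ccm) || total_volume_ccm <= 0)
    stop("total_volume_ccm must be a positive scalar")
  structure <- match.arg(structure,
                         c("whole_pelvis", "iliac", "lumbosacral", "lower_pelvis", "other"))
  structure(list(dose_gy = dose_gy,
                 volume_fraction = volume_fraction,
                 total_volume_ccm = total_volume_ccm,
                 structure = structure,
                 bin_width = bin_width),
            class = "dvh")
}

#' @export
print.dvh <- function(x, ...) {
  cat("Differential DVH [", x$structure, "]: ", length(x$dose_gy),
      " bins, dose ", min(x$dose_gy), "-", max(x$dose_gy), " Gy, volume ",
      format(x$total_volume_ccm), " cm^3\n", sep = "")
  invisible(x)
}

#' Cumulative dose-volume histogram
#'
#' Stores the fraction of structure volume receiving at least each grid dose.
#' The curve is non-increasing, starts at 1 for a completely covered
#' structure, and is interpreted as piecewise linear between grid points.
#'
#' @param dose_gy Ascending dose grid in Gy.
#' @param fraction_at_or_above Non-increasing fractions in `[0, 1]`.
#' @param total_volume_ccm,structure Carried metadata, as in [dvh()].
#' @return An object of class `"cumulative_dvh"`.
#' @export
cumulative_dvh <- function(dose_gy, fraction_at_or_above,
                           total_volume_ccm = 1, structure = "other") {
  dose_gy <- as.numeric(dose_gy)
  fraction_at_or_above <- as.numeric(fraction_at_or_above)
  if (length(dose_gy) != length(fraction_at_or_above) || length(dose_gy) == 0L)
    stop("dose_gy and fraction_at_or_above must be non-empty and equal length")
  if (is.unsorted(dose_gy, strictly = TRUE))
    stop("dose_gy must be strictly ascending")
  if (any(diff(fraction_at_or_above) > 1e-9))
    stop("fraction_at_or_above must be non-increasing")
  if (fraction_at_or_above[1] > 1 + 1e-9 || fraction_at_or_above[length(fraction_at_or_above)] < -1e-9)
    stop("fractions must lie in [0, 1]")
  structure(list(dose_gy = dose_gy,
                 fraction_at_or_above = pmin(pmax(fraction_at_or_above, 0), 1),
                 total_volume_ccm = total_volume_ccm,
                 structure = structure),
            class = "cumulative_dvh")
}

#' Convert a cumulative DVH to differential form
#'
#' The drop in the cumulative curve between consecutive grid doses `d_j` and
#' `d_{j+1}` is the volume fraction receiving a dose in `[d_j, d_{j+1})`; that
#' mass is assigned to the 0.1 Gy bin containing `d_j`. Any volume still at or
#' above the last grid dose is assigned to that dose's bin, so total mass is
#' conserved (it equals the first cumulative value).
#'
#' @param c A [cumulative_dvh()].
#' @param bin_width Target uniform bin width in Gy (default 0.1).
#' @return A [dvh()] on the uniform grid.
#' @export
differential_from_cumulative <- function(c, bin_width = 0.1) {
  if (!inherits(c, "cumulative_dvh")) stop("c must be a cumulative_dvh")
  f <- c$fraction_at_or_above
  d <- c$dose_gy
  mass <- c(-diff(f), f[length(f)])
  keep <- mass > 1e-15
  if (!any(keep)) { # all-zero dose structure: everything in the 0 Gy bin
    return(dvh(0, f[1], c$total_volume_ccm, c$structure,
               bin_width = bin_width, complete = FALSE))
  }
  bins <- floor(d[keep] / bin_width + 1e-9) * bin_width
  agg <- tapply(mass[keep], bins, sum)
  dvh(as.numeric(names(agg)), as.numeric(agg),
      c$total_volume_ccm, c$structure, bin_width = bin_width,
      complete = FALSE)
}

#' Convert a differential DVH to cumulative form
#'
#' The returned grid has a point at 0 Gy, at each bin's lower edge (where the
#' bin's volume is still counted as "at or above") and at each bin's upper
#' edge (where it is not), so that [differential_from_cumulative()] inverts
#' the conversion exactly.
#'
#' @param d A [dvh()].
#' @return A [cumulative_dvh()].
#' @export
cumulative_from_differential <- function(d) {
  if (!inherits(d, "dvh")) stop("d must be a dvh")
  w <- d$bin_width
  grid <- sort(unique(round(c(0, d$dose_gy, d$dose_gy + w), 9)))
  total <- sum(d$volume_fraction)
  # fraction at or above g = sum of bins whose label >= g (within grid jitter)
  frac <- vapply(grid, function(g)
    sum(d$volume_fraction[d$dose_gy >= g - 1e-9]), numeric(1))
  cumulative_dvh(grid, frac, d$total_volume_ccm, d$structure)
}

#' Percent volume receiving at least a threshold dose
#'
#' `v_at(d, x)` is the classic Vx metric: 100 times the fraction of structure
#' volume with dose `>= x` Gy. A bin whose label equals the threshold counts
#' in full; thresholds interior to a bin are resolved by linear interpolation
#' of the cumulative curve across the bin (dose treated as uniform within a
#' bin).
#'
#' @param d A [dvh()].
#' @param threshold_gy Dose threshold in Gy (non-negative scalar or vector).
#' @return Percent volume in `[0, 100]`, same length as `threshold_gy`.
#' @export
v_at <- function(d, threshold_gy) {
  if (!inherits(d, "dvh")) stop("d must be a dvh")
  if (any(threshold_gy < 0)) stop("threshold must be non-negative")
  w <- d$bin_width
  # knots: (label, C including bin) and (label + width, C excluding bin)
  cum_above <- rev(cumsum(rev(d$volume_fraction)))
  x <- c(d$dose_gy, d$dose_gy + w)
  y <- c(cum_above, cum_above - d$volume_fraction)
  o <- order(x, -y)
  x <- round(x[o], 9); y <- y[o]
  dup <- duplicated(x)
  x <- x[dup == FALSE]; y <- y[dup == FALSE]
  total <- sum(d$volume_fraction)
  res <- vapply(threshold_gy, function(t) {
    if (t <= x[1]) return(total)
    if (t >= x[length(x)]) return(y[length(y)])
    stats::approx(x, y, xout = t, method = "linear")$y
  }, numeric(1))
  100 * pmin(pmax(res, 0), 1)
}

#' Standard V5-V25 dose metrics
#'
#' Evaluates [v_at()] at 5, 10, 15, 20 and 25 Gy, the levels routinely
#' reported for pelvic bone marrow, and carries the absolute structure volume.
#' The result is monotone non-increasing in threshold by construction.
#'
#' @param d A [dvh()].
#' @param levels_gy Dose levels in Gy (default `c(5, 10, 15, 20, 25)`).
#' @return An object of class `"dose_metrics"`: a one-row data frame with
#'   columns `structure`, `volume_ccm`, and `v5` ... `v25` (percent).
#' @export
dose_metrics <- function(d, levels_gy = c(5, 10, 15, 20, 25)) {
  v <- v_at(d, levels_gy)
  out <- data.frame(structure = d$structure,
                    volume_ccm = d$total_volume_ccm,
                    stringsAsFactors = FALSE)
  out[paste0("v", levels_gy)] <- as.list(v)
  class(out) <- c("dose_metrics", "data.frame")
  out
}

#' Rebin a DVH defined on an arbitrary dose grid
#'
#' Mass-preserving reassignment of per-bin volume onto the uniform 0.1 Gy
#' grid: each input bin's volume is moved to the uniform bin containing its
#' dose label. Conserved mass is checked to `1e-6`.
#'
#' @param dose_gy,volume_fraction Arbitrary-grid differential DVH data.
#' @param total_volume_ccm,structure Metadata, as in [dvh()].
#' @param bin_width Target bin width (default 0.1 Gy).
#' @return A [dvh()] on the uniform grid.
#' @export
rebin_dvh <- function(dose_gy, volume_fraction, total_volume_ccm = 1,
                      structure = "other", bin_width = 0.1) {
  if (length(dose_gy) != length(volume_fraction))
    stop("dose and volume vectors must have equal length")
  bins <- floor(dose_gy / bin_width + 1e-9) * bin_width
  agg <- tapply(volume_fraction, bins, sum)
  out <- dvh(as.numeric(names(agg)), as.numeric(agg), total_volume_ccm,
             structure, bin_width = bin_width, complete = FALSE)
  if (abs(sum(out$volume_fraction) - sum(volume_fraction)) > 1e-6)
    stop("rebinning failed to conserve volume mass")
  out
}

# ---- CSV I/O ---------------------------------------------------------------

#' Read per-structure DVHs from CSV
#'
#' The file must have a header with columns `structure`, `dose_gy`, `kind`
#' (`"differential"` or `"cumulative"`) and either `volume_fraction` or
#' `volume_ccm`; an optional `patient_id` column allows one file to hold many
#' patients, and an optional `total_volume_ccm` column carries absolute
#' structure volume. Cumulative input is converted to differential form;
#' `volume_ccm` input is normalised by the per-structure total.
#'
#' @param path CSV file path.
#' @return If `patient_id` is present, a named list (by patient) of named
#'   lists (by structure) of [dvh()] objects; otherwise a named list by
#'   structure.
#' @export
read_dvh_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("structure", "dose_gy", "kind")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("DVH file ", path, " is missing required column(s): ",
         paste(miss, collapse = ", "))
  vol_col <- intersect(c("volume_fraction", "volume_ccm"), names(raw))
  if (!length(vol_col))
    stop("DVH file ", path, " needs a volume_fraction or volume_ccm column")
  vol_col <- vol_col[1]
  if (!is.numeric(raw$dose_gy) || !is.numeric(raw[[vol_col]])) {
    bad <- which(is.na(suppressWarnings(as.numeric(raw$dose_gy))) |
                   is.na(suppressWarnings(as.numeric(raw[[vol_col]]))))
    stop("non-numeric dose or volume in ", path, " at data line(s): ",
         paste(utils::head(bad + 1L, 5), collapse = ", "))
  }
  has_pid <- "patient_id" %in% names(raw)
  key <- if (has_pid) interaction(raw$patient_id, raw$structure, drop = TRUE)
         else factor(raw$structure)

  parse_one <- function(block) {
    kind <- unique(block$kind)
    if (length(kind) != 1L || !kind %in% c("differential", "cumulative"))
      stop("kind must be uniformly 'differential' or 'cumulative' per structure in ", path)
    o <- order(block$dose_gy)
    block <- block[o, ]
    total <- if ("total_volume_ccm" %in% names(block) &&
                 !anyNA(block$total_volume_ccm)) block$total_volume_ccm[1] else NA_real_
    vols <- block[[vol_col]]
    if (kind == "cumulative") {
      if (any(diff(vols) > 1e-9)) {
        ln <- which(diff(vols) > 1e-9)[1]
        stop("non-monotone cumulative DVH for structure '", block$structure[1],
             "' in ", path, " near data line ", which(o == ln)[1] + 1L)
      }
      if (vol_col == "volume_ccm") {
        if (is.na(total)) total <- max(vols)
        vols <- vols / max(vols)
      }
      cd <- cumulative_dvh(block$dose_gy, vols,
                           total_volume_ccm = if (is.na(total)) 1 else total,
                           structure = block$structure[1])
      differential_from_cumulative(cd)
    } else {
      if (vol_col == "volume_ccm") {
        if (is.na(total)) total <- sum(vols)
        vols <- vols / sum(vols)
      }
      dvh(block$dose_gy, vols,
          total_volume_ccm = if (is.na(total)) 1 else total,
          structure = block$structure[1], complete = FALSE)
    }
  }

  blocks <- split(raw, key)
  dvhs <- lapply(blocks, parse_one)
  if (!has_pid) {
    names(dvhs) <- vapply(dvhs, `[[`, character(1), "structure")
    return(dvhs)
  }
  pids <- vapply(blocks, function(b) as.character(b$patient_id[1]), character(1))
  out <- split(dvhs, pids)
  lapply(out, function(l) {
    names(l) <- vapply(l, `[[`, character(1), "structure")
    l
  })
}

#' Write DVHs to CSV
#'
#' Inverse of [read_dvh_csv()]: writes differential DVHs with columns
#' `patient_id` (optional), `structure`, `dose_gy`, `volume_fraction`,
#' `total_volume_ccm`, `kind`. `write_dvh_csv` followed by `read_dvh_csv`
#' reproduces the input within `1e-9`.
#'
#' @param dvhs A named list of [dvh()] (by structure) or a named list of such
#'   lists (by patient).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dvh_csv <- function(dvhs, path) {
  nested <- length(dvhs) > 0 && !inherits(dvhs[[1]], "dvh")
  rows <- list()
  emit <- function(d, pid) {
    df <- data.frame(structure = d$structure,
                     dose_gy = d$dose_gy,
                     volume_fraction = d$volume_fraction,
                     total_volume_ccm = d$total_volume_ccm,
                     kind = "differential",
                     stringsAsFactors = FALSE)
    if (!is.null(pid)) df <- cbind(patient_id = pid, df)
    df
  }
  if (nested) {
    for (pid in names(dvhs))
      for (d in dvhs[[pid]]) rows[[length(rows) + 1L]] <- emit(d, pid)
  } else {
    for (d in dvhs) rows[[length(rows) + 1L]] <- emit(d, NULL)
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
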
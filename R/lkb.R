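#' Lyman-Kutcher-Burman model parameters
#'
#' Container for the LKB parameter set: the volume-effect exponent `n`, the
#' slope `m`, the position `td50` (uniform effective dose at 50% complication
#' probability) and the linear-quadratic `alpha_beta` ratio used for
#' fraction-size correction. Defaults are the published maximum-likelihood
#' fit for grade 3+ haematologic toxicity of pelvic bone marrow in anal
#' cancer chemoradiation (Bazan et al.): n fixed at 1 (fully parallel
#' marrow), m = 0.09, TD50 = 30 Gy, alpha/beta = 10 Gy, with the published
#' 95% confidence bounds TD50 28-32 Gy. The source prints the m interval as
#' "0.4-0.3", which cannot bracket 0.09 in either order; it is carried here
#' verbatim after sorting (0.3, 0.4) and should be replaced by the user if a
#' corrected interval is known — it is not silently repaired.
#'
#' @param n Volume-effect exponent (> 0).
#' @param m Slope parameter (> 0).
#' @param td50 Dose at 50% complication probability, Gy (> 0).
#' @param alpha_beta Linear-quadratic ratio in Gy (> 0).
#' @param m_ci,td50_ci Optional length-2 confidence bounds; sorted so
#'   low <= high.
#' @return An object of class `"lkb_params"`.
#' @export
lkb_params <- function(n = 1, m = 0.09, td50 = 30, alpha_beta = 10,
                       m_ci = c(0.3, 0.4), td50_ci = c(28, 32)) {
  for (v in list(n = n, m = m, td50 = td50, alpha_beta = alpha_beta)) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0)
      stop("n, m, td50 and alpha_beta must be positive scalars")
  }
  ci_check <- function(ci, label) {
    if (is.null(ci)) return(NULL)
    if (length(ci) != 2L || anyNA(ci) || any(ci <= 0))
      stop(label, " must be two positive values")
    sort(as.numeric(ci))
  }
  structure(list(n = n, m = m, td50 = td50, alpha_beta = alpha_beta,
                 m_ci = ci_check(m_ci, "m_ci"),
                 td50_ci = ci_check(td50_ci, "td50_ci")),
            class = "lkb_params")
}

#' @export
print.lkb_params <- function(x, ...) {
  cat("LKB parameters: n =", x$n, " m =", x$m, " TD50 =", x$td50,
      "Gy  alpha/beta =", x$alpha_beta, "Gy\n")
  if (!is.null(x$m_ci)) cat("  m 95% CI: ", x$m_ci[1], "-", x$m_ci[2], "\n")
  if (!is.null(x$td50_ci)) cat("  TD50 95% CI: ", x$td50_ci[1], "-", x$td50_ci[2], " Gy\n")
  invisible(x)
}

#' A single delivery phase of a radiotherapy plan
#'
#' @param dvh_per_structure Named list of [dvh()] objects keyed by structure.
#' @param n_fractions Number of fractions in this phase (>= 1).
#' @return An object of class `"plan_phase"`.
#' @export
plan_phase <- function(dvh_per_structure, n_fractions) {
  if (!is.list(dvh_per_structure) || !length(dvh_per_structure) ||
      !all(vapply(dvh_per_structure, inherits, logical(1), "dvh")))
    stop("dvh_per_structure must be a non-empty named list of dvh objects")
  if (!is.numeric(n_fractions) || length(n_fractions) != 1L ||
      is.na(n_fractions) || n_fractions < 1)
    stop("n_fractions must be >= 1")
  if (is.null(names(dvh_per_structure)))
    names(dvh_per_structure) <- vapply(dvh_per_structure, `[[`, character(1), "structure")
  structure(list(dvh_per_structure = dvh_per_structure,
                 n_fractions = n_fractions),
            class = "plan_phase")
}

#' Fraction-size corrected dose (EQD2 / LQED2)
#'
#' Converts a total bin dose delivered in `e` fractions to the biologically
#' equivalent dose delivered at 2 Gy per fraction under the linear-quadratic
#' model:
#' \deqn{LQED2 = D \frac{1 + (D/e)/(\alpha/\beta)}{1 + 2/(\alpha/\beta)}}
#' When the dose per fraction `D/e` is exactly 2 Gy the correction is the
#' identity.
#'
#' @param di Total dose in Gy (vectorised, >= 0).
#' @param e Number of fractions (>= 1).
#' @param alpha_beta Linear-quadratic ratio in Gy (> 0).
#' @return Corrected dose in Gy, same length as `di`.
#' @export
lqed2 <- function(di, e, alpha_beta = 10) {
  if (!is.numeric(e) || length(e) != 1L || is.na(e) || e < 1)
    stop("e (number of fractions) must be >= 1")
  if (alpha_beta <= 0) stop("alpha_beta must be positive")
  if (any(di < 0)) stop("doses must be non-negative")
  di * (1 + (di / e) / alpha_beta) / (1 + 2 / alpha_beta)
}

#' Effective dose of one plan phase for one structure
#'
#' The generalized-EUD reduction of the structure's DVH after fraction-size
#' correction of each bin dose:
#' \deqn{D_{eff} = \left(\sum_i v_i \, LQED2_i^{1/n}\right)^{n}}
#' With `n = 1` (parallel organ) this is the volume-weighted mean corrected
#' dose.
#'
#' @param phase A [plan_phase()].
#' @param structure Structure label present in the phase.
#' @param params An [lkb_params()].
#' @return Effective dose in Gy.
#' @export
deff <- function(phase, structure, params = lkb_params()) {
  if (!inherits(phase, "plan_phase")) stop("phase must be a plan_phase")
  if (!inherits(params, "lkb_params")) stop("params must be lkb_params")
  d <- phase$dvh_per_structure[[structure]]
  if (is.null(d))
    stop("structure '", structure, "' not present in this phase")
  lq <- lqed2(d$dose_gy, phase$n_fractions, params$alpha_beta)
  v <- d$volume_fraction / sum(d$volume_fraction)
  sum(v * lq^(1 / params$n))^params$n
}

#' Effective dose of a multi-phase plan
#'
#' Sequential phases (e.g. the two-phase conformal technique) are combined by
#' summing the per-phase effective doses; a single-phase plan reduces to
#' [deff()]. Note this summation operates on DVH-level effective doses, not
#' voxel-registered dose: it is the appropriate reduction when only
#' per-phase DVHs are available.
#'
#' @param phases A list of [plan_phase()] objects (>= 1).
#' @inheritParams deff
#' @return Effective dose in Gy.
#' @export
deff_plan <- function(phases, structure, params = lkb_params()) {
  if (inherits(phases, "plan_phase")) phases <- list(phases)
  if (!length(phases)) stop("at least one phase is required")
  sum(vapply(phases, deff, numeric(1), structure = structure, params = params))
}

#' LKB normal-tissue complication probability
#'
#' The probit dose-response: `x = (Deff - TD50) / (m * TD50)` and
#' `NTCP = Phi(x)`, the standard normal distribution function (evaluated in
#' closed form, absolute accuracy better than 1e-12). If both parameter
#' confidence intervals are present the NTCP confidence band from
#' [ntcp_interval()] is attached.
#'
#' @param deff_gy Effective dose in Gy (vectorised).
#' @param params An [lkb_params()].
#' @param with_ci Attach the parameter-CI probability band when bounds are
#'   available (default `TRUE`).
#' @return For scalar input, an object of class `"ntcp_result"` (fields
#'   `deff`, `x`, `ntcp`, optional `ci`); for vector input, a numeric vector
#'   of probabilities.
#' @export
ntcp <- function(deff_gy, params = lkb_params(), with_ci = TRUE) {
  if (!inherits(params, "lkb_params")) stop("params must be lkb_params")
  x <- (deff_gy - params$td50) / (params$m * params$td50)
  p <- stats::pnorm(x)
  if (length(deff_gy) > 1L) return(p)
  ci <- NULL
  if (with_ci && !is.null(params$m_ci) && !is.null(params$td50_ci))
    ci <- ntcp_interval(deff_gy, params)
  structure(list(deff = deff_gy, x = x, ntcp = p, ci = ci),
            class = "ntcp_result")
}

#' @export
print.ntcp_result <- function(x, ...) {
  cat(sprintf("Deff = %.3f Gy  x = %.4f  NTCP = %.4f", x$deff, x$x, x$ntcp))
  if (!is.null(x$ci)) cat(sprintf("  [CI %.4f-%.4f]", x$ci[1], x$ci[2]))
  cat("\n")
  invisible(x)
}

#' NTCP band from parameter confidence intervals
#'
#' Evaluates the model at the four (m, TD50) confidence-bound combinations
#' and returns the envelope `(min, max)`. Because NTCP is monotone in each
#' parameter for fixed effective dose, the extremes over the rectangular
#' parameter region occur at its corners; the point estimate is included in
#' the envelope.
#'
#' @inheritParams ntcp
#' @return Length-2 numeric `(low, high)`.
#' @export
ntcp_interval <- function(deff_gy, params = lkb_params()) {
  if (is.null(params$m_ci) || is.null(params$td50_ci))
    stop("both m_ci and td50_ci are required for an NTCP interval")
  corners <- expand.grid(m = params$m_ci, td50 = params$td50_ci)
  vals <- mapply(function(m, td50)
    stats::pnorm((deff_gy - td50) / (m * td50)),
    corners$m, corners$td50)
  point <- stats::pnorm((deff_gy - params$td50) / (params$m * params$td50))
  c(min(vals, point), max(vals, point))
}

# Bernoulli log-likelihood of (m, td50) given effective doses and outcomes;
# probabilities clipped to avoid log(0).
lkb_loglik <- function(m, td50, deffs, outcomes) {
  p <- stats::pnorm((deffs - td50) / (m * td50))
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  sum(outcomes * log(p) + (1 - outcomes) * log(1 - p))
}

#' Maximum-likelihood fit of the LKB slope and position parameters
#'
#' Fits `(m, TD50)` to binary toxicity outcomes by maximizing the Bernoulli
#' likelihood of the probit dose-response, with the volume exponent `n` held
#' fixed (the effective doses are taken as given, so `n` only matters
#' upstream). Optimization is a derivative-free Nelder-Mead simplex search
#' started from a 3 x 3 grid over the box m in \[0.01, 1\], TD50 in
#' \[5, 100\] Gy; the best converged start wins and ties go to the smallest
#' m. 95% confidence intervals are profile-likelihood bounds at a drop of
#' 1.92 log-likelihood units.
#'
#' @param deffs Positive effective doses in Gy, one per subject.
#' @param outcomes Binary outcomes (0/1 or logical), same length.
#' @param n_fixed Value at which the volume exponent is held (recorded in the
#'   result; default 1).
#' @param alpha_beta Recorded alongside the fit (default 10 Gy).
#' @param compute_ci Compute profile-likelihood CIs (default `TRUE`; disable
#'   for large simulation studies).
#' @param box Named list with elements `m` and `td50`, each `c(low, high)`.
#' @return An [lkb_params()] with attributes `loglik` (maximized value) and
#'   `converged`.
#' @export
fit_lkb_ml <- function(deffs, outcomes, n_fixed = 1, alpha_beta = 10,
                       compute_ci = TRUE,
                       box = list(m = c(0.01, 1), td50 = c(5, 100))) {
  outcomes <- as.numeric(outcomes)
  if (length(deffs) != length(outcomes) || length(deffs) < 2L)
    stop("deffs and outcomes must be equal length (>= 2)")
  if (any(deffs <= 0)) stop("all effective doses must be positive")
  if (!all(outcomes %in% c(0, 1))) stop("outcomes must be binary")
  if (length(unique(outcomes)) < 2L)
    stop("outcomes are all ", outcomes[1],
         ": LKB parameters are not identifiable from a single outcome class")

  negll <- function(par) {
    if (par[1] < box$m[1] || par[1] > box$m[2] ||
        par[2] < box$td50[1] || par[2] > box$td50[2]) return(1e10)
    -lkb_loglik(par[1], par[2], deffs, outcomes)
  }
  starts <- expand.grid(
    m = box$m[1] + c(0.15, 0.5, 0.85) * diff(box$m),
    td50 = box$td50[1] + c(0.15, 0.5, 0.85) * diff(box$td50))
  fits <- lapply(seq_len(nrow(starts)), function(i)
    stats::optim(as.numeric(starts[i, ]), negll, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-10)))
  vals <- vapply(fits, `[[`, numeric(1), "value")
  best <- which(abs(vals - min(vals)) < 1e-8)
  best <- best[which.min(vapply(fits[best], function(f) f$par[1], numeric(1)))]
  fit <- fits[[best]]
  if (fit$convergence != 0)
    stop("LKB likelihood maximization did not converge")
  m_hat <- fit$par[1]; td50_hat <- fit$par[2]
  llmax <- -fit$value

  m_ci <- td50_ci <- NULL
  if (compute_ci) {
    # profile log-likelihood in one parameter, maximizing over the other
    prof <- function(fix, which) {
      obj <- if (which == "m")
        function(t) -lkb_loglik(fix, t, deffs, outcomes)
      else
        function(t) -lkb_loglik(t, fix, deffs, outcomes)
      rng <- if (which == "m") box$td50 else box$m
      -stats::optimize(obj, rng, tol = 1e-8)$objective
    }
    bound <- function(which, hat, lo, hi) {
      target <- llmax - 1.92
      f <- function(v) prof(v, which) - target
      low <- if (f(lo) < 0)
        stats::uniroot(f, c(lo, hat), tol = 1e-7)$root else lo
      high <- if (f(hi) < 0)
        stats::uniroot(f, c(hat, hi), tol = 1e-7)$root else hi
      c(low, high)
    }
    m_ci <- bound("m", m_hat, box$m[1], box$m[2])
    td50_ci <- bound("td50", td50_hat, box$td50[1], box$td50[2])
  }

  out <- lkb_params(n = n_fixed, m = m_hat, td50 = td50_hat,
                    alpha_beta = alpha_beta, m_ci = m_ci, td50_ci = td50_ci)
  attr(out, "loglik") <- llmax
  attr(out, "converged") <- TRUE
  out
}
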
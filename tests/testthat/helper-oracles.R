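# Independent oracles used across the suite. These deliberately take the
# slow, literal route (enumeration, direct summation) so they share no code
# with the implementations they check.

# exact two-sided Mann-Whitney p by full enumeration of group assignments
mw_enumeration_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  splits <- utils::combn(n1 + n2, n1)
  u_all <- apply(splits, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  lo <- mean(u_all <= u_obs + 1e-9)
  hi <- mean(u_all >= u_obs - 1e-9)
  list(u = u_obs, p = min(1, 2 * min(lo, hi)))
}

# literal Holm step-down: sorted p(i) vs alpha / (k - i + 1), stop at first
# failure
holm_stepdown_oracle <- function(p, alpha = 0.05) {
  k <- length(p)
  o <- order(p)
  reject <- logical(k)
  for (i in seq_len(k)) {
    if (p[o[i]] <= alpha / (k - i + 1)) reject[o[i]] <- TRUE else break
  }
  reject
}

# plain Bonferroni rejections
bonferroni_oracle <- function(p, alpha = 0.05) p <= alpha / length(p)

# brute-force Vx: sum bin fractions at or above the threshold (valid when
# the threshold sits on a bin label or in a gap)
v_at_counting_oracle <- function(d, threshold) {
  100 * sum(d$volume_fraction[d$dose_gy >= threshold - 1e-9])
}

# random sparse DVH on the 0.1 Gy grid
random_dvh <- function(n_bins = sample(2:12, 1), max_dose = 60) {
  doses <- sort(sample(seq(0, max_dose, by = 0.1), n_bins))
  v <- stats::runif(n_bins)
  dvh(doses, v / sum(v), total_volume_ccm = stats::runif(1, 100, 2000))
}

# a tiny complete blood series
make_series <- function(baseline = c(hgb = 13, wcc = 8, anc = 5.1, plats = 274),
                        weekly_wcc = c(6, 4, 3.1, 5),
                        sex = "female") {
  n <- length(weekly_wcc)
  blood_series(baseline,
               data.frame(week = seq_len(n),
                          hgb = rep(baseline[["hgb"]], n),
                          wcc = weekly_wcc,
                          anc = rep(baseline[["anc"]], n),
                          plats = rep(baseline[["plats"]], n)),
               sex = sex)
}
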
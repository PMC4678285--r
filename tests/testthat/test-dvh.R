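test_that("cumulative-to-differential conversion places mass in the right bins", {
  # a point dose of exactly 30 Gy falls in the [30, 30.1) bin
  cd <- cumulative_dvh(c(0, 30, 30.1), c(1, 1, 0))
  d <- differential_from_cumulative(cd)
  expect_equal(d$dose_gy, 30)
  expect_equal(d$volume_fraction, 1)

  # two-level plateau: half the volume at 10 Gy, half at 30 Gy
  cd2 <- cumulative_dvh(c(0, 10, 10.1, 30, 30.1), c(1, 1, 0.5, 0.5, 0))
  d2 <- differential_from_cumulative(cd2)
  expect_equal(d2$dose_gy, c(10, 30))
  expect_equal(d2$volume_fraction, c(0.5, 0.5))

  # unirradiated structure collapses to the 0 Gy bin
  d3 <- differential_from_cumulative(cumulative_dvh(0, 1))
  expect_equal(d3$dose_gy, 0)
  expect_equal(d3$volume_fraction, 1)

  expect_error(cumulative_dvh(c(0, 10, 20), c(0.5, 1, 0)), "non-increasing")
})

test_that("differential-to-cumulative conversion and round trip are exact", {
  d <- dvh(30, 1)
  cd <- cumulative_from_differential(d)
  expect_true(all(cd$fraction_at_or_above[cd$dose_gy <= 30] == 1))

  d2 <- dvh(c(10, 30), c(0.5, 0.5))
  cd2 <- cumulative_from_differential(d2)
  expect_equal(cd2$fraction_at_or_above[cd2$dose_gy == 0], 1)
  expect_equal(cd2$fraction_at_or_above[cd2$dose_gy == 10.1], 0.5)
  expect_equal(cd2$fraction_at_or_above[cd2$dose_gy == 30.1], 0)

  set.seed(42)
  for (i in 1:25) {
    d <- random_dvh()
    back <- differential_from_cumulative(cumulative_from_differential(d))
    expect_equal(back$dose_gy, d$dose_gy, tolerance = 1e-9)
    expect_equal(back$volume_fraction, d$volume_fraction, tolerance = 1e-9)
  }
})

test_that("v_at implements the inclusive >= convention with interpolation", {
  uniform50 <- dvh(50, 1)
  expect_equal(v_at(uniform50, 25), 100)
  two <- dvh(c(10, 30), c(0.5, 0.5))
  expect_equal(v_at(two, 25), 50)
  expect_equal(v_at(two, 10), 100)  # bin exactly at threshold counts
  expect_error(v_at(two, -1), "non-negative")
})

test_that("v_at is non-increasing and agrees with the bin-counting oracle", {
  set.seed(7)
  for (i in 1:40) {
    d <- random_dvh(n_bins = sample(2:10, 1))
    thresholds <- sort(stats::runif(20, 0, 65))
    v <- v_at(d, thresholds)
    expect_true(all(diff(v) <= 1e-9))
    # at bin labels and in inter-bin gaps the counting oracle is exact
    for (t in d$dose_gy)
      expect_equal(v_at(d, t), v_at_counting_oracle(d, t), tolerance = 1e-9)
  }
})

test_that("dose_metrics reports monotone V5-V25", {
  expect_equal(unlist(dose_metrics(dvh(50, 1))[paste0("v", c(5, 10, 15, 20, 25))]),
               c(v5 = 100, v10 = 100, v15 = 100, v20 = 100, v25 = 100))
  expect_equal(unlist(dose_metrics(dvh(12, 1))[paste0("v", c(5, 10, 15, 20, 25))]),
               c(v5 = 100, v10 = 100, v15 = 0, v20 = 0, v25 = 0))
  expect_equal(unlist(dose_metrics(dvh(c(10, 30), c(0.5, 0.5)))[paste0("v", c(5, 10, 15, 20, 25))]),
               c(v5 = 100, v10 = 100, v15 = 50, v20 = 50, v25 = 50))
  set.seed(11)
  for (i in 1:25) {
    dm <- dose_metrics(random_dvh())
    v <- unlist(dm[paste0("v", c(5, 10, 15, 20, 25))])
    expect_true(all(diff(v) <= 1e-9))
  }
})

test_that("rebinning conserves mass on arbitrary grids", {
  set.seed(3)
  doses <- sort(stats::runif(40, 0, 55))
  v <- stats::runif(40); v <- v / sum(v)
  d <- rebin_dvh(doses, v)
  expect_equal(sum(d$volume_fraction), 1, tolerance = 1e-9)
  expect_true(all(abs(d$dose_gy * 10 - round(d$dose_gy * 10)) < 1e-6))
})

test_that("DVH CSV round-trips and rejects malformed input", {
  set.seed(5)
  dvhs <- list(A = list(), B = list())
  for (p in names(dvhs))
    for (s in c("whole_pelvis", "iliac")) {
      d <- random_dvh()
      d$structure <- s
      dvhs[[p]][[s]] <- d
    }
  path <- withr::local_tempfile(fileext = ".csv")
  write_dvh_csv(dvhs, path)
  back <- read_dvh_csv(path)
  expect_setequal(names(back), c("A", "B"))
  for (p in names(dvhs))
    for (s in names(dvhs[[p]])) {
      expect_equal(back[[p]][[s]]$dose_gy, dvhs[[p]][[s]]$dose_gy, tolerance = 1e-9)
      expect_equal(back[[p]][[s]]$volume_fraction,
                   dvhs[[p]][[s]]$volume_fraction, tolerance = 1e-9)
      expect_equal(back[[p]][[s]]$total_volume_ccm,
                   dvhs[[p]][[s]]$total_volume_ccm, tolerance = 1e-9)
    }

  # cumulative input converts to a differential summing to 1
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("structure,dose_gy,volume_fraction,kind",
               "iliac,0,1,cumulative",
               "iliac,10,1,cumulative",
               "iliac,10.1,0.4,cumulative",
               "iliac,30.1,0,cumulative"), p2)
  d <- read_dvh_csv(p2)$iliac
  expect_equal(sum(d$volume_fraction), 1, tolerance = 1e-9)

  # absolute cm^3 volumes are normalised by the structure total
  p3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("structure,dose_gy,volume_ccm,kind",
               "iliac,10,300,differential",
               "iliac,30,100,differential"), p3)
  d3 <- read_dvh_csv(p3)$iliac
  expect_equal(d3$volume_fraction, c(0.75, 0.25))
  expect_equal(d3$total_volume_ccm, 400)

  p4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("structure,dose_gy", "iliac,10"), p4)
  expect_error(read_dvh_csv(p4), "missing required column")

  p5 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("structure,dose_gy,volume_fraction,kind",
               "iliac,0,0.5,cumulative",
               "iliac,10,0.9,cumulative"), p5)
  expect_error(read_dvh_csv(p5), "non-monotone")
})

test_that("dvh constructor enforces its invariants", {
  expect_error(dvh(c(10, 5), c(0.5, 0.5)), "ascending")
  expect_error(dvh(c(10, 30), c(0.7, 0.7)), "sum to 1")
  expect_error(dvh(10.05, 1), "multiples of the bin width")
  expect_error(dvh(10, 1, total_volume_ccm = -5), "positive")
  expect_silent(dvh(c(10, 30), c(0.7, 0.2), complete = FALSE))
})
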
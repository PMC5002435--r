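make_series <- function(times, od, glyc = NA_real_, strain = "WT",
                        replicate = "r1") {
  tibble::tibble(strain = strain, condition = "GG", replicate = replicate,
                 time_days = times, od730 = od, glycerol_mM = glyc)
}

test_that("growth rate is the log-ratio of endpoint ODs", {
  d <- make_series(c(0, 2), c(0.1, 0.4))
  expect_equal(growth_rate(d, c(0, 2))$mu_per_day, log(4) / 2)
  # constant OD -> zero
  expect_equal(growth_rate(make_series(c(0, 2), c(0.3, 0.3)),
                           c(0, 2))$mu_per_day, 0)
  # declining OD -> negative, reported as-is
  expect_lt(growth_rate(make_series(c(0, 2), c(0.4, 0.3)),
                        c(0, 2))$mu_per_day, 0)
  # invariant under uniform OD rescaling
  expect_equal(growth_rate(make_series(c(0, 2), c(1, 4)), c(0, 2))$mu_per_day,
               log(4) / 2)
  # zero/negative OD is an error
  expect_error(growth_rate(make_series(c(0, 2), c(0, 0.4)), c(0, 2)),
               "non-positive OD")
  # times must be strictly increasing
  expect_error(growth_rate(make_series(c(0, 0), c(0.1, 0.4)), c(0, 2)),
               "strictly increasing")
  # interval outside the sampled range
  expect_error(growth_rate(make_series(c(0, 2), c(0.1, 0.4)), c(0, 4)),
               "outside")
})

test_that("growth ratio against the reference propagates replicate pairings", {
  exp_series <- function(mu, strain, rep) {
    t <- seq(0, 4, by = 1)
    make_series(t, 0.1 * exp(mu * t), strain = strain, replicate = rep)
  }
  d <- dplyr::bind_rows(
    exp_series(0.5, "WT", "r1"),
    exp_series(0.4, "dslr1670", "r1")
  )
  r <- growth_ratio(d, "dslr1670", c(0, 4))
  expect_equal(r$ratio_percent, 125)
  expect_equal(r$sd, 0)
  # series versus itself is exactly 100 +/- 0
  dd <- dplyr::bind_rows(exp_series(0.5, "WT", "r1"),
                         exp_series(0.5, "dslr1670", "r1"))
  rr <- growth_ratio(dd, "dslr1670", c(0, 4))
  expect_equal(rr$ratio_percent, 100)
  expect_equal(rr$sd, 0)
  # all strain x reference replicate pairings contribute
  d4 <- dplyr::bind_rows(
    exp_series(0.5, "WT", "r1"), exp_series(0.55, "WT", "r2"),
    exp_series(0.4, "dslr1670", "r1"), exp_series(0.45, "dslr1670", "r2")
  )
  r4 <- growth_ratio(d4, "dslr1670", c(0, 4))
  expect_equal(r4$n_pairs, 4)
  pairs <- 100 * as.vector(outer(c(0.5, 0.55), c(0.4, 0.45), "/"))
  expect_equal(r4$ratio_percent, mean(pairs))
  expect_equal(r4$sd, stats::sd(pairs))
  expect_false(r4$nonphysical)
  expect_error(growth_ratio(d, "nope", c(0, 4)), "reference strain")
})

test_that("declining cultures yield negative ratios flagged non-physical", {
  t <- seq(0, 4, by = 1)
  d <- dplyr::bind_rows(
    make_series(t, 0.4 * exp(-0.2 * t), strain = "WT"),
    make_series(t, 0.1 * exp(0.4 * t), strain = "dslr1670")
  )
  r <- growth_ratio(d, "dslr1670", c(0, 4))
  expect_lt(r$ratio_percent, 0)
  expect_true(r$nonphysical)
})

test_that("qGG estimation follows the glycerol balance arithmetic", {
  # 0.1 mmol/L over 48 h at constant OD 1.0 -> 0.1 / (0.2 * 48)
  d <- make_series(c(0, 2), c(1, 1), c(0, 0.1))
  expect_equal(estimate_qGG(d, c(0, 2))$qGG, 0.1 / (0.2 * 48))
  # no glycerol change -> zero
  d0 <- make_series(c(0, 2), c(1, 1), c(0.2, 0.2))
  est0 <- estimate_qGG(d0, c(0, 2))
  expect_equal(est0$qGG, 0)
  expect_equal(est0$flag, "ok")
  # decreasing glycerol -> 0 with a warning flag, not a negative rate
  dn <- make_series(c(0, 2), c(1, 1), c(0.2, 0.1))
  expect_warning(est <- estimate_qGG(dn, c(0, 2)), "re-uptake")
  expect_equal(est$qGG, 0)
  expect_equal(est$flag, "decreasing_glycerol")
  # endpoint vs trapezoid averaging agree at constant OD
  expect_equal(estimate_qGG(d, c(0, 2), method = "endpoint")$qGG,
               estimate_qGG(d, c(0, 2), method = "trapezoid")$qGG)
  expect_error(estimate_qGG(make_series(c(0, 2), c(1, 1)), c(0, 2)),
               "glycerol")
})

test_that("qGG estimation is invariant under time-unit-consistent inputs", {
  # same culture sampled twice as densely gives (nearly) the same estimate
  t1 <- seq(0, 4, by = 1)
  t2 <- seq(0, 4, by = 0.25)
  curve <- function(t) 0.1 * exp(0.5 * t)
  gly <- function(t) 0.01 * 24 * 0.2 * (curve(t) - curve(0)) / 0.5
  e1 <- estimate_qGG(make_series(t1, curve(t1), gly(t1)), c(0, 4))$qGG
  e2 <- estimate_qGG(make_series(t2, curve(t2), gly(t2)), c(0, 4))$qGG
  expect_equal(e1, e2, tolerance = 0.01)
  expect_equal(e2, 0.01, tolerance = 0.005)
})

test_that("intracellular concentration conversion matches the worked example", {
  # 0.12 umol from 1 mL at OD 6: 1.2 mg DW -> 1.2 uL -> 100 mmol/L
  expect_equal(intracellular_concentration(0.12, 1e-3, 6), 100)
  # linear in amount, inverse in OD
  expect_equal(intracellular_concentration(0.24, 1e-3, 6), 200)
  expect_equal(intracellular_concentration(0.12, 1e-3, 12), 50)
  expect_error(intracellular_concentration(0.12, 1e-3, 0), "positive")
})

test_that("culture CSV/TSV reading validates and sorts", {
  d <- make_series(c(0, 1, 2), c(0.1, 0.2, 0.4), c(0, 0.05, 0.1))
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(d[c(3, 1, 2), ], path, row.names = FALSE)
  back <- read_culture_csv(path)
  expect_equal(back$time_days, c(0, 1, 2))
  expect_equal(back$od730, d$od730)
  bad <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(x = 1), bad, row.names = FALSE)
  expect_error(read_culture_csv(bad), "lacks column")
})
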
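test_that("fitness ratio is exactly 100% without GG and matches the closed form with it", {
  tm <- toy_model(photon_bound = 100)
  expect_identical(fitness_ratio(tm, qGG = 0), 100)
  # salvage yield on the toy stoichiometry: 9 CH2O (2 ATP each) - 1 ATP
  # glycerol kinase = 17 ATP-equivalents per GG; mu0 = P/3
  # => ratio = (1 + 17 q / P) * 100
  for (q in c(0.005, 0.01, 0.05)) {
    expect_equal(fitness_ratio(tm, qGG = q), 100 * (1 + 17 * q / 100),
                 tolerance = 1e-9)
  }
})

test_that("fitness ratio is monotone non-decreasing and always >= 100", {
  tm <- toy_model()
  grid <- c(0, 1e-4, 1e-3, 0.01, 0.1, 0.5, 1.5)
  r <- vapply(grid, function(q) fitness_ratio(tm, qGG = q), numeric(1))
  expect_true(all(r >= 100))
  expect_true(all(diff(r) >= -1e-9))
})

test_that("a zero reference optimum raises an undefined-ratio error", {
  dark <- toy_model(photon_bound = 0)
  expect_error(fitness_ratio(dark, qGG = 0), "undefined")
})

test_that("endogenous supply route charges the synthesis cost to both sides", {
  tm <- toy_model(photon_bound = 100)
  # forced synthesis at q: reference stores GG, mu_ref = (P - 19q)/3;
  # salvage recovers the 9 CH2O at 1 ATP kinase cost, mu = (P - 2q)/3
  q <- 0.05
  r <- fitness_ratio(tm, qGG = q, supply = "synthesis")
  expect_equal(r, 100 * (100 - 2 * q) / (100 - 19 * q), tolerance = 1e-9)
  expect_identical(fitness_ratio(tm, qGG = 0, supply = "synthesis"), 100)
})

test_that("cleavage-mode sweep favours phosphorolysis and tends to 100%", {
  tm <- toy_model(photon_bound = 100)
  grid <- c(1e-4, 1e-3, 1e-2, 0.1, 0.5, 1.5)
  sw <- sweep_cleavage_modes(tm, grid)
  expect_s3_class(sw, "gg_sweep")
  expect_equal(sw$qGG, grid)
  # phosphorolysis spares the glucokinase ATP: (P + 17q)/(P + 16q)
  expect_equal(sw$ratio_percent, 100 * (100 + 17 * grid) / (100 + 16 * grid),
               tolerance = 1e-9)
  expect_true(all(sw$ratio_percent >= 100))
  # -> 100 as qGG -> 0, and exactly 100 at qGG = 0
  expect_lt(sw$ratio_percent[1] - 100, 1e-3)
  sw0 <- sweep_cleavage_modes(tm, c(0, 0.01))
  expect_identical(sw0$ratio_percent[1], 100)
})

test_that("glycerol utilization benefit is exactly 100 at zero and grows with qGG", {
  tm <- toy_model(photon_bound = 100)
  grid <- c(0, 1e-3, 0.01, 0.1, 1)
  gb <- glycerol_utilization_benefit(tm, grid)
  expect_identical(gb$ratio_percent[1], 100)
  # with phosphorolysis open: (P + 17q)/(P + 12q)
  expect_equal(gb$ratio_percent[-1],
               100 * (100 + 17 * grid[-1]) / (100 + 12 * grid[-1]),
               tolerance = 1e-9)
  expect_true(all(diff(gb$ratio_percent) > 0))
})

test_that("sweep input validation rejects unsorted or negative grids", {
  tm <- toy_model()
  expect_error(sweep_cleavage_modes(tm, c(0.1, 0.01)))
  expect_error(sweep_cleavage_modes(tm, c(-0.1, 0.01)))
})

test_that("strain ratio table reproduces self-ratio, strain equalities and monotonicity", {
  tm <- toy_model()
  tab <- simulate_table5(tm, strains = c("WT", "dggpS", "dglpK", "dslr1670"))
  expect_equal(nrow(tab), 4 * 5)
  # self-ratio of the reference strain is exactly 100 in every interval
  expect_identical(unique(tab$sim_ratio_percent[tab$strain == "dslr1670"]),
                   100)
  # strains with functional slr1670 and glpK are indistinguishable
  wt <- tab$sim_ratio_percent[tab$strain == "WT"]
  ggps <- tab$sim_ratio_percent[tab$strain == "dggpS"]
  expect_equal(wt, ggps, tolerance = 1e-9)
  # losing glycerol kinase loses part of the benefit
  glpk <- tab$sim_ratio_percent[tab$strain == "dglpK"]
  expect_true(all(glpk <= wt + 1e-9))
  expect_true(all(glpk >= 100 - 1e-9))
  # ratios ordered like the qGG values of the intervals
  expect_equal(order(wt), order(table5_intervals()$qGG))
})

test_that("the measured interval table carries the five published uptake rates", {
  iv <- table5_intervals()
  expect_equal(iv$qGG, c(0.008, 0.015, 0.014, 0.009, 0.003))
  expect_true(all(iv$t0 < iv$t1))
  tm <- toy_model()
  tab <- simulate_table5(tm, strains = "WT")
  # closed form at exchange supply: (P + 17q)/P per interval
  expect_equal(tab$sim_ratio_percent, 100 * (100 + 17 * iv$qGG) / 100,
               tolerance = 1e-9)
})

test_that("cleavage mode restriction changes the strain table accordingly", {
  tm <- toy_model()
  hyd <- simulate_table5(tm, strains = "WT", cleavage = "hydrolysis")
  phos <- simulate_table5(tm, strains = "WT", cleavage = "phosphorolysis")
  both <- simulate_table5(tm, strains = "WT", cleavage = "both")
  expect_true(all(phos$sim_ratio_percent >= hyd$sim_ratio_percent - 1e-9))
  expect_equal(both$sim_ratio_percent, phos$sim_ratio_percent,
               tolerance = 1e-9)
})

test_that("sweep results plot without error", {
  tm <- toy_model()
  sw <- sweep_cleavage_modes(tm, c(0.001, 0.01))
  p <- ggplot2::autoplot(sw)
  expect_s3_class(p, "ggplot")
})
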
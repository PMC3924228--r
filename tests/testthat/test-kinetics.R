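test_that("growth rate of an exact exponential is constant and equals its rate", {
  tt <- seq(0, 5, by = 0.5)
  for (r in c(0.2, log(2), 1.3)) {
    gr <- growth_rate(tt, 0.05 * exp(r * tt))
    expect_equal(gr$gr, rep(r, length(tt) - 1), tolerance = 1e-10)
  }
  # doubling every hour at unit intervals: GR = ln 2
  gr2 <- growth_rate(0:6, 2^(0:6))
  expect_equal(unique(round(gr2$gr, 12)), round(log(2), 12))
  # constant OD: GR identically zero
  expect_true(all(growth_rate(0:5, rep(0.3, 6))$gr == 0))
})

test_that("growth rate rejects non-positive OD naming the index", {
  expect_error(growth_rate(0:3, c(0.1, 0.2, 0, 0.4)),
               class = "crowdfba_nonpositive_od")
  expect_error(growth_rate(0:3, c(0.1, 0.2, 0, 0.4)), "index 3")
})

test_that("a logistic culture peaks early-exponential then slows", {
  tt <- seq(0, 10, by = 0.25)
  od <- 0.035 + 2 / (1 + exp(-1.2 * (tt - 4)))
  gr <- growth_rate(tt, od)
  peak <- gr$time[which.max(gr$gr)]
  expect_lt(peak, 6)                  # peaks before saturation
  expect_gt(peak, 1)
  expect_lt(tail(gr$gr, 1), max(gr$gr) / 10)
})

test_that("biomass normalization divides pointwise and rescales to 1", {
  tt <- 0:5
  flat <- normalize_to_biomass(tt, rep(2, 6), od600 = rep(0.5, 6))
  expect_equal(flat$value, rep(1, 6))
  halves <- normalize_to_biomass(tt, c(2, 2, 2, 1, 1, 1),
                                 od600 = rep(0.5, 6))
  expect_equal(tail(halves$value, 1), 0.5)
  expect_error(normalize_to_biomass(tt, rep(1, 6), od600 = rep(0, 6)),
               class = "crowdfba_nonpositive_od")
  # misaligned grids are linearly interpolated, never extrapolated
  odt <- seq(0, 5, by = 0.5)
  ali <- normalize_to_biomass(tt, rep(3, 6), od_times = odt,
                              od600 = 0.2 + 0.1 * odt)
  expect_equal(ali$value[1], 1)
  expect_error(normalize_to_biomass(0:6, rep(1, 7), od_times = 0:5,
                                    od600 = rep(1, 6)),
               class = "crowdfba_no_extrapolation")
})

test_that("one-phase decay recovers noiseless parameters exactly", {
  tt <- seq(0, 6, length.out = 20)
  y <- 1 * exp(-0.5 * tt)
  fit <- fit_one_phase_decay(tt, y)
  expect_true(fit$converged)
  expect_equal(fit$K, 0.5, tolerance = 1e-8)
  expect_equal(fit$y0, 1, tolerance = 1e-8)
  expect_equal(fit$plateau, 0, tolerance = 1e-6)
  expect_equal(fit$half_life, log(2) / 0.5, tolerance = 1e-7)
  # with a plateau
  y2 <- 0.2 + 0.8 * exp(-1.1 * tt)
  fit2 <- fit_one_phase_decay(tt, y2)
  expect_equal(fit2$K, 1.1, tolerance = 1e-7)
  expect_equal(fit2$plateau, 0.2, tolerance = 1e-7)
})

test_that("decay fit is scale-equivariant", {
  tt <- seq(0, 6, length.out = 24)
  y <- 0.1 + 0.9 * exp(-0.7 * tt)
  f1 <- fit_one_phase_decay(tt, y)
  f2 <- fit_one_phase_decay(tt, 100 * y)
  expect_equal(f2$K, f1$K, tolerance = 1e-8)
  expect_equal(f2$half_life, f1$half_life, tolerance = 1e-8)
  expect_equal(f2$y0, 100 * f1$y0, tolerance = 1e-6)
  expect_equal(f2$plateau, 100 * f1$plateau, tolerance = 1e-5)
})

test_that("degenerate decay inputs error informatively", {
  expect_error(fit_one_phase_decay(0:5, rep(1, 6)), class = "crowdfba_no_decay")
  expect_error(fit_one_phase_decay(0:2, c(1, 2, 3)),
               class = "crowdfba_validation")
})

test_that("promoter activity is GFP/OD and fold-ratio divides conditions", {
  tt <- 0:5
  od <- c(0.1, 0.2, 0.4, 0.8, 1.0, 1.2)
  same <- promoter_activity(tt, od, od)
  expect_equal(same$activity, rep(1, 6))
  ind <- promoter_activity(tt, 2 * od, od)
  fr <- promoter_fold_ratio(ind, same)
  expect_equal(fr$fold, rep(2, 6))
  expect_error(promoter_activity(tt, od, rep(0, 6)),
               class = "crowdfba_nonpositive_od")
})

test_that("CDD normalizes to 1 and summarizes delta and uniform profiles", {
  # all OD in the 1.14 g/ml layer
  od <- c(0, 0, 0, 1, 0, 0, 0, 0)
  prof <- cell_density_distribution(od)
  expect_equal(prof$cdd, od)
  expect_equal(prof$modal_density, 1.14)
  expect_equal(prof$mean_density, 1.14)
  # uniform loading
  u <- cell_density_distribution(rep(0.2, 8))
  expect_equal(u$cdd, rep(0.125, 8))
  expect_error(cell_density_distribution(rep(0, 8)),
               class = "crowdfba_empty_gradient")
  expect_warning(cell_density_distribution(c(-0.01, rep(0.1, 7))),
                 "clipped")
})

test_that("CDD sums to one over random non-negative profiles", {
  withr::with_seed(42, {
    for (i in 1:50) {
      od <- stats::runif(8, 0, 2)
      expect_equal(sum(cell_density_distribution(od)$cdd), 1,
                   tolerance = 1e-12)
    }
  })
})
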
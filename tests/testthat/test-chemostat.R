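test_that("consumption ratios are carbon-weighted fractions", {
  expect_equal(unname(consumption_ratio(c(glc = 3, gly = 0),
                                        c(glc = 6, gly = 3))),
               c(1, 0))
  # 1 mmol glucose (6 C) vs 2 mmol glycerol (3 C) -> 0.5 / 0.5
  expect_equal(unname(consumption_ratio(c(glc = 1, gly = 2),
                                        c(glc = 6, gly = 3))),
               c(0.5, 0.5))
  expect_equal(unname(consumption_ratio(c(glc = 0, gly = 0),
                                        c(glc = 6, gly = 3))),
               c(0, 0))
  expect_error(consumption_ratio(c(glc = -1), c(glc = 6)),
               class = "crowdfba_validation")
})

test_that("D = 0 gives an all-zero point and mu = D holds elsewhere", {
  net <- fixture_net()
  p0 <- simulate_chemostat_point(net, 0)
  expect_equal(p0$growth_rate, 0)
  expect_true(all(p0$consumption_ratios == 0))
  for (D in c(0.1, 0.4, 0.7)) {
    pt <- simulate_chemostat_point(net, D)
    expect_lt(abs(pt$growth_rate - D), 1e-6)
    expect_lte(pt$crowding_lhs, pt$crowding_budget + 1e-8)
    expect_equal(sum(pt$consumption_ratios), 1, tolerance = 1e-9)
  }
})

test_that("slow growth co-utilizes all substrates with no acetate", {
  pt <- simulate_chemostat_point(fixture_net(), 0.1)
  expect_true(all(pt$uptake_fluxes > 0))
  expect_equal(pt$acetate_secretion, 0, tolerance = 1e-9)
  expect_lt(pt$crowding_lhs, pt$crowding_budget)
})

test_that("the scan shows a CCR onset with glucose dominance above it", {
  net <- fixture_net()
  scan <- dilution_scan(net)
  df <- as.data.frame(scan)
  on <- ccr_onset(scan)
  expect_false(is.na(on$D_star))
  expect_gt(on$D_star, 0)
  expect_lte(on$D_star, 0.7)
  # co-utilization below onset: >= 2 substrates consumed at every sub-D*
  below <- df[df$D < on$D_star, ]
  for (D in unique(below$D))
    expect_gte(sum(below$uptake[below$D == D] > 1e-9), 2)
  # saturation at and above onset
  above <- unique(df[df$D >= on$D_star, c("D", "crowding_lhs")])
  expect_true(all(abs(above$crowding_lhs - 1) <= 1e-6))
  # glucose ratio non-decreasing above onset, and the maximum at the top
  glc <- df$ratio[df$substrate == "glc"]
  D <- unique(df$D)
  expect_true(all(diff(glc[D >= on$D_star]) >= -1e-9))
  top <- df[df$D == 0.7, ]
  expect_equal(top$substrate[which.max(top$ratio)], "glc")
})

test_that("acetate secretion is zero at the lowest D and grows above onset", {
  scan <- dilution_scan(fixture_net())
  df <- unique(as.data.frame(scan)[, c("D", "acetate")])
  on <- ccr_onset(scan)
  expect_equal(df$acetate[1], 0, tolerance = 1e-9)
  expect_false(is.na(on$acetate_onset_D))
  above <- df$acetate[df$D >= on$acetate_onset_D]
  expect_true(all(above > 0))
  expect_gt(tail(above, 1), above[1] - 1e-12)   # largest at the top
  expect_gt(tail(df$acetate, 1), 0)
})

test_that("with budget = Inf ratios are constant in D and acetate never appears", {
  df <- as.data.frame(dilution_scan(fixture_net(), crowding_budget = Inf))
  for (s in unique(df$substrate))
    expect_lt(diff(range(df$ratio[df$substrate == s])), 1e-9)
  expect_true(all(df$acetate <= 1e-9))
})

test_that("dilution rates beyond mu_max wash out", {
  net <- fixture_net()
  expect_error(simulate_chemostat_point(net, 2), class = "crowdfba_washout")
  scan <- dilution_scan(net, D_list = c(0.5, 2))
  df <- as.data.frame(scan)
  expect_false(df$washout[df$D == 0.5][1])
  expect_true(df$washout[df$D == 2][1])
  expect_length(dilution_scan(net, numeric(0)), 0)
})
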
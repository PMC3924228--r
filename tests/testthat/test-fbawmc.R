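test_that("two-substrate toy reaches the enumerated vertex optimum", {
  pr <- flux_problem(split_reversible(toy_two_substrate()),
                     uptake_capacity = c(EX1 = 5, EX2 = 5))
  sol <- solve_fbawmc(pr)
  expect_identical(sol$status, "optimal")
  expect_equal(sol$growth_rate, 7.5, tolerance = 1e-9)
  expect_equal(unname(sol$fluxes[c("EX1", "EX2")]), c(5, 2.5),
               tolerance = 1e-9)
  expect_equal(sol$crowding_lhs, 1, tolerance = 1e-9)
  oracle <- brute_force_oracle(pr)
  expect_equal(oracle$growth_rate, 7.5, tolerance = 1e-6)
})

test_that("starvation gives zero growth and zero flux", {
  pr <- flux_problem(split_reversible(toy_two_substrate()),
                     uptake_capacity = c(EX1 = 0, EX2 = 0))
  sol <- solve_fbawmc(pr)
  expect_identical(sol$status, "optimal")
  expect_equal(sol$growth_rate, 0)
  expect_true(all(abs(sol$fluxes) < 1e-9))
})

test_that("uncrowded linear chain has the closed-form optimum mu = U * y", {
  for (y in c(0.5, 1, 2)) {
    net <- linear_chain(U = 8, yield = y, budget = Inf)
    sol <- solve_fbawmc(flux_problem(split_reversible(net)))
    expect_equal(sol$growth_rate, 8 * y, tolerance = 1e-9)
  }
})

test_that("infeasible and unbounded problems are reported as status", {
  # force infeasibility: biomass lower bound above what uptake supports
  net <- linear_chain(U = 1, yield = 1)
  net$reactions$lower_bound[net$reactions$id == "BIOMASS"] <- 50
  sol <- solve_fbawmc(flux_problem(split_reversible(net)))
  expect_identical(sol$status, "infeasible")
  expect_true(is.na(sol$growth_rate))

  # unbounded: no budget, no finite bounds anywhere on the chain
  net2 <- linear_chain(U = Inf, yield = 1, budget = Inf)
  net2$reactions$upper_bound <- Inf
  sol2 <- solve_fbawmc(flux_problem(split_reversible(net2)))
  expect_identical(sol2$status, "unbounded")
})

test_that("crowding_lhs sums a_i v_i and rejects mismatched ids", {
  expect_equal(crowding_lhs(c(r1 = 0, r2 = 0), c(r1 = 0.1, r2 = 0.5)), 0)
  expect_equal(crowding_lhs(c(r1 = 5), c(r1 = 0.2)), 1.0)
  expect_error(crowding_lhs(c(r1 = 1), c(other = 0.2)),
               class = "crowdfba_validation")
})

test_that("LP agrees with the brute-force oracle on seeded random networks", {
  for (seed in 0:29) {
    pr <- flux_problem(split_reversible(random_small_network(seed)))
    lp <- solve_fbawmc(pr)
    oracle <- brute_force_oracle(pr)
    expect_identical(lp$status, oracle$status)
    if (lp$status == "optimal")
      expect_lt(abs(lp$growth_rate - oracle$growth_rate), 1e-6)
  }
})

test_that("budget = Inf reduces to plain FBA on random instances", {
  for (seed in 0:9) {
    sp <- split_reversible(random_small_network(seed))
    with_budget <- solve_fbawmc(flux_problem(sp, crowding_budget = Inf))
    # plain FBA computed on the same instance with the crowding row absent
    S <- stoich_matrix(sp)
    r <- sp$reactions
    raw <- crowdfba:::solve_lp(as.numeric(r$id == sp$biomass_id),
                               A_eq = S, b_eq = rep(0, nrow(S)),
                               lb = r$lower_bound, ub = r$upper_bound)
    expect_equal(with_budget$growth_rate, raw$value, tolerance = 1e-9)
  }
})

test_that("optimal growth is monotone in budget and in capacities on the fixture", {
  sp <- split_reversible(fixture_net())
  caps <- stats::setNames(fixture_params()$substrates$uptake_capacity,
                          sp$substrate_exchange_ids)
  mus_b <- vapply(c(0.25, 0.5, 1, 2, Inf), function(b)
    solve_fbawmc(flux_problem(sp, uptake_capacity = caps,
                              crowding_budget = b))$growth_rate, numeric(1))
  expect_true(all(diff(mus_b) >= -1e-9))
  mus_u <- vapply(c(0.1, 0.3, 0.6, 1), function(s)
    solve_fbawmc(flux_problem(sp, uptake_capacity = s * caps))$growth_rate,
    numeric(1))
  expect_true(all(diff(mus_u) >= -1e-9))
})

test_that("oracle refuses problems with too many free dimensions", {
  sp <- split_reversible(fixture_net())
  # make bounds finite so only dimensionality can be the refusal reason
  sp$reactions$upper_bound[!is.finite(sp$reactions$upper_bound)] <- 100
  expect_error(brute_force_oracle(flux_problem(sp), max_dim = 4),
               class = "crowdfba_dimensionality")
})
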
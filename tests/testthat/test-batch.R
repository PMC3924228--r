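test_that("single-substrate dFBA matches the analytic closed form", {
  # uncrowded culture growing at mu = U * k (capacity-limited): biomass
  # is exponential until exhaustion and the final biomass equals
  # X0 + yield_mass * C0
  net <- fixture_net()
  U <- 2                                  # mmol glc /gDW/hr
  cfg <- batch_config(initial_concentrations = single_medium("glc", 2),
                      vmax = c(glc = U), dt = 0.01, t_end = 18)
  sp <- split_reversible(net)
  p <- fixture_params()
  traj <- local({
    n2 <- net; n2$crowding_budget <- Inf
    simulate_batch(n2, cfg)
  })
  k <- 6 / 3                              # pyruvate per glucose
  mu_expect <- U * k * 3 / p$biomass_carbon
  early <- traj$growth_rate[traj$time < 1]
  expect_equal(unique(round(early, 9)), round(mu_expect, 9))
  # analytic exhaustion and final biomass
  X0 <- cfg$initial_od * cfg$od_to_gdw
  yield_mass <- (k * 3 / p$biomass_carbon) * 1000 / 180.16  # gDW per g glc
  X_final_expect <- X0 + yield_mass * 2
  expect_lt(abs(tail(traj$biomass, 1) - X_final_expect) / X_final_expect,
            0.01)
  # biomass trace matches X0 * exp(mu t) during growth
  i <- which.min(abs(traj$time - 2))
  expect_equal(traj$biomass[i], X0 * exp(mu_expect * traj$time[i]),
               tolerance = 1e-3)
})

test_that("carbon is conserved and the error vanishes as dt shrinks", {
  net <- fixture_net()
  errs <- vapply(c(0.1, 0.03, 0.01), function(dt) {
    traj <- simulate_batch(net, batch_config(
      initial_concentrations = mixed_medium(), dt = dt, t_end = 10))
    abs(carbon_balance(traj)$rel_error)
  }, numeric(1))
  expect_lt(errs[3], 0.01)
  expect_true(all(diff(errs) < 0))        # strictly improving with dt
})

test_that("mixed culture exhausts glucose first and glycerol last", {
  net <- fixture_net()
  traj <- simulate_batch(net, batch_config(
    initial_concentrations = mixed_medium(), dt = 0.02, t_end = 10))
  ord <- exhaustion_order(traj)
  expect_true(all(ord$exhausted))
  expect_identical(ord$substrate[1], "glc")
  expect_identical(ord$substrate[nrow(ord)], "gly")
  # acetate is secreted during the fast phase and re-assimilated later:
  # reuptake emerges from the LP, it is not scripted
  expect_gt(max(traj$acetate), 0)
  expect_lt(tail(traj$acetate, 1), 1e-6)
})

test_that("mixed-culture peak growth rate is at least every single-substrate peak", {
  net <- fixture_net()
  mixed <- simulate_batch(net, batch_config(
    initial_concentrations = mixed_medium(), dt = 0.05, t_end = 8))
  peak_mixed <- max(mixed$growth_rate)
  for (s in c("glc", "gal", "mal", "lac", "gly")) {
    single <- simulate_batch(net, batch_config(
      initial_concentrations = single_medium(s), dt = 0.05, t_end = 8))
    expect_gte(peak_mixed + 1e-9, max(single$growth_rate))
  }
})

test_that("without the crowding budget all substrates are consumed at once", {
  net <- fixture_net()
  net$crowding_budget <- Inf
  traj <- simulate_batch(net, batch_config(
    initial_concentrations = mixed_medium(), dt = 0.05, t_end = 1))
  # every substrate declines from the very first step: no hierarchy
  drop1 <- unlist(traj[1, c("glc", "gal", "mal", "lac", "gly")]) -
    unlist(traj[2, c("glc", "gal", "mal", "lac", "gly")])
  expect_true(all(drop1 > 0))
})

test_that("zero initial biomass keeps all state constant", {
  net <- fixture_net()
  traj <- simulate_batch(net, batch_config(
    initial_od = 0, initial_concentrations = mixed_medium(),
    dt = 0.1, t_end = 1))
  expect_true(all(traj$biomass == 0))
  expect_equal(unique(traj$glc), 0.4)
  expect_true(all(traj$growth_rate == 0))
})

test_that("exhaustion_order handles trivial inputs", {
  net <- fixture_net()
  single <- simulate_batch(net, batch_config(
    initial_concentrations = single_medium("glc"), dt = 0.1, t_end = 8))
  ord <- exhaustion_order(single)
  expect_identical(nrow(ord), 1L)
  empty <- simulate_batch(net, batch_config(
    initial_concentrations = stats::setNames(numeric(0), character(0)),
    dt = 0.1, t_end = 0.3))
  expect_identical(nrow(exhaustion_order(empty)), 0L)
  expect_error(batch_config(dt = -1), class = "crowdfba_config")
})
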
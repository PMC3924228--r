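test_that("fixture network ships five substrate exchanges and an acetate exchange", {
  net <- fixture_net()
  expect_length(net$substrate_exchange_ids, 5)
  expect_identical(net$substrate_exchange_ids,
                   paste0("EX_", c("glc", "gal", "mal", "lac", "gly")))
  expect_true(net$acetate_exchange_id %in% net$reactions$id)
  expect_identical(net$biomass_id, "BIOMASS")
})

test_that("the packaged fixture file loads and matches the built network", {
  f <- system.file("extdata", "fixture_network.json", package = "crowdfba")
  expect_true(nzchar(f))
  net <- load_network(f)
  expect_length(net$substrate_exchange_ids, 5)
  built <- fixture_net()
  expect_equal(stoich_matrix(net), stoich_matrix(built))
  expect_equal(net$reactions$crowding_coefficient,
               built$reactions$crowding_coefficient)
})

test_that("JSON round-trip is byte-identical on canonical output", {
  net <- fixture_net()
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  write_network(net, f1)
  net2 <- load_network(f1)
  write_network(net2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(stoich_matrix(net2), stoich_matrix(net))
  expect_equal(net2$crowding_budget, net$crowding_budget)
})

test_that("TSV round-trip preserves the network", {
  net <- fixture_net()
  d <- tempfile()
  write_network(net, d, format = "tsv")
  net2 <- load_network(d, format = "tsv")
  expect_equal(stoich_matrix(net2), stoich_matrix(net))
  expect_equal(net2$reactions$upper_bound, net$reactions$upper_bound)
  expect_identical(net2$substrate_exchange_ids, net$substrate_exchange_ids)
})

test_that("validation rejects missing biomass, duplicate ids, bad coefficients", {
  net <- fixture_net()
  broken <- net
  broken$biomass_id <- "NOT_THERE"
  expect_error(validate_network(broken), class = "crowdfba_no_biomass")

  dup <- net
  dup$reactions <- rbind(dup$reactions, dup$reactions[1, ])
  expect_error(validate_network(dup), class = "crowdfba_duplicate_id")

  neg <- net
  neg$reactions$crowding_coefficient[3] <- -0.1
  expect_error(validate_network(neg), class = "crowdfba_validation")
})

test_that("split_reversible makes a forward/backward pair with inherited crowding", {
  net <- fixture_net()
  sp <- split_reversible(net)
  expect_true(all(sp$reactions$lower_bound >= 0))
  i_f <- which(sp$reactions$id == "EX_ac")
  i_b <- which(sp$reactions$id == "EX_ac__r")
  expect_length(i_b, 1)
  expect_equal(sp$reactions$upper_bound[i_b],
               -net$reactions$lower_bound[net$reactions$id == "EX_ac"])
  expect_equal(sp$reactions$crowding_coefficient[i_b],
               net$reactions$crowding_coefficient[net$reactions$id == "EX_ac"])
  # already-irreversible network returned unchanged
  toy <- toy_two_substrate()
  sp_toy <- split_reversible(toy)
  expect_identical(sp_toy$reactions$id, toy$reactions$id)
})

test_that("splitting preserves the optimal biomass on random networks", {
  for (seed in 0:9) {
    net <- random_small_network(seed)
    mu_split <- solve_fbawmc(flux_problem(split_reversible(net)))$growth_rate
    # independent route: solve the unsplit LP directly (finite negative
    # lower bounds are handled by the variable shift)
    S <- stoich_matrix(net)
    r <- net$reactions
    a <- ifelse(r$kind == "exchange", 0, r$crowding_coefficient)
    raw <- crowdfba:::solve_lp(
      as.numeric(r$id == net$biomass_id),
      A_eq = S, b_eq = rep(0, nrow(S)),
      A_ub = matrix(abs(a), 1), b_ub = net$crowding_budget,
      lb = r$lower_bound, ub = r$upper_bound)
    expect_equal(mu_split, raw$value, tolerance = 1e-9,
                 label = paste("seed", seed))
  }
})

test_that("fixture calibration fails loudly when fermentation out-yields OxPhos", {
  p <- fixture_params()
  # make OxPhos yield (3 biomass C per pyruvate) worse than fermentation
  # by inflating its crowding so far that plain FBA prefers fermentation
  expect_error({
    net <- build_fixture_network(p)
    sto <- net$stoichiometry
    sto$coefficient[sto$reaction_id == "OXPHOS" &
                      sto$metabolite_id == "bmC"] <- 0.5
    net$stoichiometry <- sto
    crowdfba:::calibrate_fixture(net, p)
  }, class = "crowdfba_fixture_calibration")
})

test_that("fixture at infinite budget uses OxPhos only and secretes no acetate", {
  net <- fixture_net()
  sp <- crowdfba:::clamp_acetate_reuptake(split_reversible(net))
  sol <- solve_fbawmc(flux_problem(sp, crowding_budget = Inf))
  expect_identical(sol$status, "optimal")
  expect_lt(sol$fluxes[["FERM"]], 1e-8)
  expect_lt(max(crowdfba:::acetate_net_flux(sp, sol$fluxes), 0), 1e-8)
})
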
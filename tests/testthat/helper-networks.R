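# shared fixtures, built in code

# two-substrate toy: one unit of biomass per unit uptake, crowding
# coefficients 0.1 / 0.2 on the conversion steps, capacities 5/5,
# budget 1 -> optimum v = (5, 2.5), mu = 7.5 (vertex enumeration)
toy_two_substrate <- function(u = c(5, 5), a = c(0.1, 0.2), budget = 1) {
  mets <- data.frame(
    id = c("s1_e", "s2_e", "m1", "m2", "bm"),
    name = c("substrate 1", "substrate 2", "m1", "m2", "biomass unit"),
    carbon_atoms = c(6, 6, 6, 6, 1),
    is_external = c(TRUE, TRUE, FALSE, FALSE, FALSE))
  rxns <- data.frame(
    id = c("EX1", "EX2", "C1", "C2", "BIOMASS"),
    kind = c("exchange", "exchange", "internal", "internal", "biomass"),
    lower_bound = 0, upper_bound = c(u, 100, 100, 100),
    crowding_coefficient = c(0, 0, a, 0))
  sto <- data.frame(
    reaction_id = c("EX1", "EX1", "EX2", "EX2", "C1", "C1", "C2", "C2",
                    "BIOMASS"),
    metabolite_id = c("s1_e", "m1", "s2_e", "m2", "m1", "bm", "m2", "bm",
                      "bm"),
    coefficient = c(-1, 1, -1, 1, -1, 1, -1, 1, -1))
  mc_network(mets, rxns, sto, biomass_id = "BIOMASS",
             substrate_exchange_ids = c("EX1", "EX2"),
             crowding_budget = budget)
}

# single linear chain: uptake (cap U) -> internal -> biomass with yield y
linear_chain <- function(U = 8, yield = 1, budget = Inf) {
  mets <- data.frame(id = c("g_e", "g_c", "bm"),
                     name = c("glucose (medium)", "glucose", "biomass unit"),
                     carbon_atoms = c(6, 6, 1),
                     is_external = c(TRUE, FALSE, FALSE))
  rxns <- data.frame(
    id = c("EX_g", "CONV", "BIOMASS"),
    kind = c("exchange", "internal", "biomass"),
    lower_bound = 0, upper_bound = c(U, 1000, 1000),
    crowding_coefficient = c(0, 0.01, 0))
  sto <- data.frame(
    reaction_id = c("EX_g", "EX_g", "CONV", "CONV", "BIOMASS"),
    metabolite_id = c("g_e", "g_c", "g_c", "bm", "bm"),
    coefficient = c(-1, 1, -1, yield, -1))
  mc_network(mets, rxns, sto, biomass_id = "BIOMASS",
             substrate_exchange_ids = "EX_g", crowding_budget = budget)
}

# the calibrated fixture is expensive enough to build once per run
fixture_net <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_fixture_network()
    cache
  }
})
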
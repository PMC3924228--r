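#' Default parameters for the reduced five-substrate fixture network
#'
#' The fixture is a deliberately small, synthetic stand-in for a
#' genome-scale reconstruction: five carbon substrates (glucose,
#' galactose, maltose, lactate, glycerol), a shared pyruvate-level
#' carbon pool, and two ATP-equivalent routes to biomass carbon —
#' high-yield oxidative phosphorylation with a high crowding cost, and a
#' low-yield acetate-secreting fermentation branch with a low crowding
#' cost. All crowding coefficients are package constants chosen so the
#' calibration checks of [build_fixture_network()] hold; the network is
#' carbon-closed (no CO2 sink), so substrate carbon ends up in biomass,
#' acetate, or the medium.
#'
#' Per-substrate catabolism converts one substrate molecule into
#' `carbon_atoms/3` pyruvate units. OxPhos turns 1 pyruvate into 3
#' biomass-carbon units; fermentation turns 1 pyruvate into 1
#' biomass-carbon plus 1 acetate (2 C); acetate reuptake feeds 1 acetate
#' back into 2 biomass-carbon. The biomass reaction drains 40 mmol of
#' biomass carbon per gDW (realistic for E. coli), so biomass flux is the
#' specific growth rate in 1/hr.
#'
#' @return a list with elements `substrates` (data.frame: id,
#'   carbon_atoms, crowding_catabolism, uptake_capacity, molar_mass),
#'   `a_oxphos`, `a_ferm`, `a_acetate_use`, `a_biomass`,
#'   `biomass_carbon` (mmol C per gDW) and `crowding_budget`.
#' @export
fixture_params <- function() {
  list(
    substrates = data.frame(
      id = c("glc", "gal", "mal", "lac", "gly"),
      name = c("glucose", "galactose", "maltose", "lactate", "glycerol"),
      carbon_atoms = c(6, 6, 12, 3, 3),
      # crowding cost per unit catabolic flux (hr gDW/mmol substrate);
      # per-pyruvate costs order glc < mal < gal < lac < gly
      crowding_catabolism = c(0.015, 0.045, 0.060, 0.0375, 0.060),
      # base capacities reflect transporter physiology: the glucose PTS
      # is the fastest system, the maltose ABC transporter the slowest
      # in molar terms; three-carbon substrates move faster per mole
      uptake_capacity = c(10, 8, 4, 15, 15),
      molar_mass = c(180.16, 180.16, 342.30, 90.08, 92.09),
      stringsAsFactors = FALSE),
    a_oxphos = 0.12,
    a_ferm = 0.0225,
    # costly enough that fermenting + re-assimilating acetate never
    # undercuts direct OxPhos (a_ferm + a_acetate_use > a_oxphos)
    a_acetate_use = 0.15,
    a_biomass = 0.015,
    biomass_carbon = 40,
    acetate_molar_mass = 60.05,
    acetate_reuptake_capacity = 10,
    crowding_budget = 1
  )
}

#' Build and calibrate the reduced fixture network
#'
#' Constructs the five-substrate crowding-annotated network described in
#' [fixture_params()] and verifies two calibration properties by solving
#' the corresponding LPs: (a) with the crowding budget removed
#' (plain FBA) the optimum routes all carbon through the high-yield
#' OxPhos branch and secretes no acetate; (b) ranked by attainable
#' growth per unit crowding (each substrate alone, unlimited uptake,
#' budget 1), the substrate hierarchy is glucose > maltose > galactose >
#' lactate > glycerol, i.e. glucose first.
#'
#' @param params parameter list as returned by [fixture_params()].
#' @return a calibrated `mc_network` (unsplit). The substrate exchange ids
#'   are `EX_<substrate>`, acetate exchange `EX_ac` (reversible: positive =
#'   secretion, negative = reuptake), biomass reaction `BIOMASS`.
#' @export
build_fixture_network <- function(params = fixture_params()) {
  su <- params$substrates
  mets <- rbind(
    data.frame(id = paste0(su$id, "_e"), name = paste(su$name, "(medium)"),
               carbon_atoms = su$carbon_atoms, is_external = TRUE,
               stringsAsFactors = FALSE),
    data.frame(id = paste0(su$id, "_c"), name = su$name,
               carbon_atoms = su$carbon_atoms, is_external = FALSE,
               stringsAsFactors = FALSE),
    data.frame(id = c("pyr", "ac_c", "ac_e", "bmC"),
               name = c("pyruvate pool", "acetate", "acetate (medium)",
                        "biomass carbon"),
               carbon_atoms = c(3, 2, 2, 1),
               is_external = c(FALSE, FALSE, TRUE, FALSE),
               stringsAsFactors = FALSE))
  k_pyr <- su$carbon_atoms / 3
  rxns <- rbind(
    data.frame(id = paste0("EX_", su$id), kind = "exchange",
               lower_bound = 0, upper_bound = su$uptake_capacity,
               crowding_coefficient = 0, stringsAsFactors = FALSE),
    data.frame(id = paste0("CAT_", su$id), kind = "internal",
               lower_bound = 0, upper_bound = Inf,
               crowding_coefficient = su$crowding_catabolism,
               stringsAsFactors = FALSE),
    # acetate exchange is reversible; its reuptake capacity is finite
    # (availability-capped again during simulations)
    data.frame(id = c("OXPHOS", "FERM", "ACUSE", "EX_ac", "BIOMASS"),
               kind = c("internal", "internal", "internal", "exchange",
                        "biomass"),
               lower_bound = c(0, 0, 0, -params$acetate_reuptake_capacity, 0),
               upper_bound = c(Inf, Inf, Inf, Inf, Inf),
               crowding_coefficient = c(params$a_oxphos, params$a_ferm,
                                        params$a_acetate_use, 0,
                                        params$a_biomass),
               stringsAsFactors = FALSE))
  sto <- rbind(
    data.frame(reaction_id = paste0("EX_", su$id),
               metabolite_id = paste0(su$id, "_e"), coefficient = -1),
    data.frame(reaction_id = paste0("EX_", su$id),
               metabolite_id = paste0(su$id, "_c"), coefficient = 1),
    data.frame(reaction_id = paste0("CAT_", su$id),
               metabolite_id = paste0(su$id, "_c"), coefficient = -1),
    data.frame(reaction_id = paste0("CAT_", su$id),
               metabolite_id = "pyr", coefficient = k_pyr),
    data.frame(reaction_id = c("OXPHOS", "OXPHOS",
                               "FERM", "FERM", "FERM",
                               "ACUSE", "ACUSE",
                               "EX_ac", "EX_ac",
                               "BIOMASS"),
               metabolite_id = c("pyr", "bmC",
                                 "pyr", "bmC", "ac_c",
                                 "ac_c", "bmC",
                                 "ac_c", "ac_e",
                                 "bmC"),
               coefficient = c(-1, 3,
                               -1, 1, 1,
                               -1, 2,
                               -1, 1,
                               -params$biomass_carbon)))
  net <- mc_network(mets, rxns, sto, biomass_id = "BIOMASS",
                    substrate_exchange_ids = paste0("EX_", su$id),
                    acetate_exchange_id = "EX_ac",
                    crowding_budget = params$crowding_budget)
  attr(net, "params") <- params
  calibrate_fixture(net, params)
  net
}

# the two calibration LP checks; errors with a report of what failed
calibrate_fixture <- function(net, params) {
  split <- split_reversible(net)
  # both checks concern the five substrates alone: clamp acetate reuptake
  split <- clamp_acetate_reuptake(split)
  caps <- stats::setNames(params$substrates$uptake_capacity,
                          net$substrate_exchange_ids)
  # (a) no crowding budget -> pure OxPhos, zero acetate secretion
  sol <- solve_fbawmc(flux_problem(split, uptake_capacity = caps,
                                   crowding_budget = Inf))
  if (sol$status != "optimal")
    mc_stop("fixture-calibration", "plain-FBA check did not solve")
  ac_sec <- max(acetate_net_flux(split, sol$fluxes), 0)
  if (ac_sec > 1e-8 || sol$fluxes[["FERM"]] > 1e-8)
    mc_stop("fixture-calibration", sprintf(
      "check (a) failed: without the crowding budget the optimum ferments (FERM=%.3g) or secretes acetate (%.3g); raise the OxPhos yield above the fermentation yield",
      sol$fluxes[["FERM"]], ac_sec))
  # (b) substrate hierarchy by growth per unit crowding
  mu_solo <- vapply(net$substrate_exchange_ids, function(ex) {
    cap <- stats::setNames(rep(0, length(caps)), names(caps))
    cap[ex] <- Inf
    solve_fbawmc(flux_problem(split, uptake_capacity = cap))$growth_rate
  }, numeric(1))
  want <- paste0("EX_", c("glc", "mal", "gal", "lac", "gly"))
  got <- names(sort(mu_solo, decreasing = TRUE))
  if (!identical(got, want))
    mc_stop("fixture-calibration", sprintf(
      "check (b) failed: substrate hierarchy is %s (growth per unit crowding), expected %s",
      paste(sub("EX_", "", got), collapse = " > "),
      paste(sub("EX_", "", want), collapse = " > ")))
  invisible(TRUE)
}

#' Random small networks for solver validation
#'
#' Generates a seeded, bounded random network with at most `n_reactions`
#' reactions (uptake exchanges, random small-integer internal
#' conversions, and a biomass drain), suitable for comparing the LP
#' solver against the brute-force vertex-enumeration oracle.
#'
#' @param seed integer seed.
#' @param n_internal_mets number of internal metabolites (2--3 typical).
#' @param n_reactions total reaction budget (<= 8).
#' @return an unsplit `mc_network` with finite bounds and a random
#'   crowding budget in \[0.5, 2\].
#' @export
random_small_network <- function(seed, n_internal_mets = 3, n_reactions = 6) {
  with_stream(seed, "random_small_network", {
    nm <- n_internal_mets
    mets <- data.frame(id = c(paste0("m", seq_len(nm)), "x_e"),
                       name = c(paste0("m", seq_len(nm)), "source"),
                       carbon_atoms = c(sample(1:6, nm, TRUE), 6),
                       is_external = c(rep(FALSE, nm), TRUE),
                       stringsAsFactors = FALSE)
    # one or two uptakes, a biomass drain, the rest random conversions
    n_up <- sample(1:2, 1)
    rxns <- NULL; sto <- NULL
    for (i in seq_len(n_up)) {
      rid <- paste0("EX", i)
      tgt <- paste0("m", i)
      rxns <- rbind(rxns, data.frame(
        id = rid, kind = "exchange", lower_bound = 0,
        upper_bound = round(stats::runif(1, 1, 10), 2),
        crowding_coefficient = 0, stringsAsFactors = FALSE))
      sto <- rbind(sto,
        data.frame(reaction_id = rid, metabolite_id = c("x_e", tgt),
                   coefficient = c(-1, 1)))
    }
    n_conv <- max(1, n_reactions - n_up - 1)
    for (i in seq_len(n_conv)) {
      rid <- paste0("R", i)
      from <- sample(nm, 1)
      to <- sample(setdiff(seq_len(nm), from), 1)
      rxns <- rbind(rxns, data.frame(
        id = rid, kind = "internal",
        lower_bound = if (stats::runif(1) < 0.3) -round(stats::runif(1, 1, 5), 2) else 0,
        upper_bound = round(stats::runif(1, 2, 10), 2),
        crowding_coefficient = round(stats::runif(1, 0, 0.3), 3),
        stringsAsFactors = FALSE))
      sto <- rbind(sto, data.frame(
        reaction_id = rid,
        metabolite_id = paste0("m", c(from, to)),
        coefficient = c(-1, sample(1:2, 1))))
    }
    bm_src <- paste0("m", sample(nm, 1))
    rxns <- rbind(rxns, data.frame(
      id = "BIOMASS", kind = "biomass", lower_bound = 0,
      upper_bound = round(stats::runif(1, 5, 20), 2),
      crowding_coefficient = round(stats::runif(1, 0, 0.1), 3),
      stringsAsFactors = FALSE))
    sto <- rbind(sto, data.frame(reaction_id = "BIOMASS",
                                 metabolite_id = bm_src, coefficient = -1))
    mc_network(mets, rxns, sto, biomass_id = "BIOMASS",
               substrate_exchange_ids = paste0("EX", seq_len(n_up)),
               crowding_budget = round(stats::runif(1, 0.5, 2), 2))
  })
}
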
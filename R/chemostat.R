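#' Carbon-weighted substrate consumption ratios
#'
#' The contribution of each substrate to total carbon uptake:
#' \eqn{ratio_j = v_j c_j / \sum_k v_k c_k} with \eqn{c} the carbon atoms
#' per molecule, the normalization used to compare substrate uptake
#' across growth rates.
#'
#' @param uptake_fluxes named non-negative uptake fluxes (mmol/gDW/hr).
#' @param carbon_atoms named carbon counts per molecule, matching names.
#' @return named fractions summing to 1 (all zero if no uptake).
#' @export
consumption_ratio <- function(uptake_fluxes, carbon_atoms) {
  if (any(uptake_fluxes < -1e-9))
    mc_stop("validation", "negative uptake flux")
  uptake_fluxes <- pmax(uptake_fluxes, 0)
  w <- uptake_fluxes * carbon_atoms[names(uptake_fluxes)]
  tot <- sum(w)
  if (tot <= 0) return(stats::setNames(rep(0, length(w)), names(w)))
  w / tot
}

#' Steady state of a crowding-constrained chemostat at one dilution rate
#'
#' At steady state the specific growth rate equals the dilution rate D.
#' Substrate availability is coupled to D by scaling all maximum uptake
#' capacities by a common factor lambda and bisecting on lambda until the
#' FBAwMC optimum satisfies mu(lambda * U) = D — the substrate-limited
#' chemostat closure. The returned flux state is the parsimoniously
#' tie-broken optimum at that capacity scale.
#'
#' @param net an `mc_network` (split internally).
#' @param D dilution rate, 1/hr; must not exceed the network's maximal
#'   growth rate (washout).
#' @param base_capacities named vector of base capacities U per substrate
#'   exchange id; defaults to the network's exchange upper bounds.
#' @param crowding_budget optional override of the network budget.
#' @param per_substrate if `TRUE`, capacities are scaled per substrate so
#'   each substrate alone would support growth D... the default (joint
#'   scaling, `FALSE`) scales all capacities by one lambda.
#' @param allow_acetate_reuptake the feed contains no acetate, so reuptake
#'   is off by default in the chemostat.
#' @param mu_tol bisection tolerance on mu.
#' @return a `chemostat_point`: list with `dilution_rate`, `capacity_scale`
#'   (lambda), `uptake_fluxes`, `consumption_ratios`, `acetate_secretion`
#'   (mmol/gDW/hr), `growth_rate`, `crowding_lhs`, `crowding_budget`,
#'   `washout` (logical).
#' @export
simulate_chemostat_point <- function(net, D, base_capacities = NULL,
                                     crowding_budget = net$crowding_budget,
                                     per_substrate = FALSE,
                                     allow_acetate_reuptake = FALSE,
                                     mu_tol = 1e-8) {
  if (D < 0) mc_stop("config", "dilution rate must be >= 0")
  sp <- if (is_split(net)) net else split_reversible(net)
  if (!allow_acetate_reuptake) sp <- clamp_acetate_reuptake(sp)
  ex_ids <- net$substrate_exchange_ids
  if (is.null(base_capacities)) {
    i <- match(ex_ids, sp$reactions$id)
    base_capacities <- stats::setNames(sp$reactions$upper_bound[i], ex_ids)
  }
  carbon <- substrate_carbon_atoms(net)

  solve_at <- function(lambda) {
    solve_fbawmc(flux_problem(sp, uptake_capacity = lambda * base_capacities,
                              crowding_budget = crowding_budget))
  }
  empty_point <- function(washout = FALSE) {
    structure(list(dilution_rate = D, capacity_scale = if (washout) NA_real_ else 0,
                   uptake_fluxes = stats::setNames(rep(0, length(ex_ids)), ex_ids),
                   consumption_ratios = stats::setNames(rep(0, length(ex_ids)), ex_ids),
                   acetate_secretion = 0,
                   growth_rate = if (washout) NA_real_ else 0,
                   crowding_lhs = if (washout) NA_real_ else 0,
                   crowding_budget = crowding_budget, washout = washout),
              class = "chemostat_point")
  }
  if (D == 0) return(empty_point())

  # bracket: double lambda until mu >= D (or declare washout)
  lo <- 0; hi <- 1
  mu_hi <- solve_at(hi)$growth_rate
  it <- 0
  while (mu_hi < D && it < 60) {
    lo <- hi; hi <- hi * 2
    mu_hi <- solve_at(hi)$growth_rate
    it <- it + 1
  }
  if (mu_hi < D) {
    mc_stop("washout", sprintf(
      "D = %.3g/hr exceeds the attainable growth rate (mu_max ~ %.4g/hr)",
      D, mu_hi))
  }
  repeat {
    mid <- (lo + hi) / 2
    st <- solve_at(mid)
    if (st$growth_rate >= D) hi <- mid else lo <- mid
    if (abs(st$growth_rate - D) <= mu_tol || (hi - lo) < 1e-14) break
  }
  st <- solve_at(hi)   # smallest bracketed scale meeting D
  upt <- vapply(ex_ids, function(id) st$fluxes[[id]], numeric(1))
  structure(list(
    dilution_rate = D, capacity_scale = hi,
    uptake_fluxes = upt,
    consumption_ratios = consumption_ratio(upt, carbon),
    acetate_secretion = max(acetate_net_flux(sp, st$fluxes), 0),
    growth_rate = st$growth_rate,
    crowding_lhs = st$crowding_lhs,
    crowding_budget = crowding_budget, washout = FALSE),
    class = "chemostat_point")
}

# carbon atoms of the species behind each substrate exchange
substrate_carbon_atoms <- function(net) {
  ext <- net$metabolites$id[net$metabolites$is_external]
  vapply(net$substrate_exchange_ids, function(rid) {
    touched <- net$stoichiometry$metabolite_id[
      net$stoichiometry$reaction_id == rid]
    m <- setdiff(touched, ext)[1]
    net$metabolites$carbon_atoms[net$metabolites$id == m]
  }, numeric(1))
}

#' Scan a chemostat across dilution rates
#'
#' One steady-state point per dilution rate; washout at a given D is
#' recorded as a flagged row rather than aborting the scan.
#'
#' @inheritParams simulate_chemostat_point
#' @param D_list increasing positive dilution rates (1/hr); the study
#'   design this mirrors used 0.1--0.7/hr in steps of 0.1.
#' @return a `chemostat_scan`: list of `chemostat_point`s with a tidy
#'   `as.data.frame` method (columns `D`, `substrate`, `uptake`, `ratio`,
#'   `acetate`, `crowding_lhs`, `capacity_scale`, `washout`).
#' @export
dilution_scan <- function(net, D_list = seq(0.1, 0.7, by = 0.1),
                          base_capacities = NULL,
                          crowding_budget = net$crowding_budget, ...) {
  if (length(D_list) && any(diff(D_list) <= 0))
    mc_stop("config", "D_list must be strictly increasing")
  sp <- split_reversible(net)
  pts <- lapply(D_list, function(D) {
    tryCatch(
      simulate_chemostat_point(sp, D, base_capacities = base_capacities,
                               crowding_budget = crowding_budget, ...),
      crowdfba_washout = function(e) {
        p <- structure(list(dilution_rate = D, capacity_scale = NA_real_,
                            uptake_fluxes = NULL, consumption_ratios = NULL,
                            acetate_secretion = NA_real_,
                            growth_rate = NA_real_, crowding_lhs = NA_real_,
                            crowding_budget = crowding_budget,
                            washout = TRUE),
                       class = "chemostat_point")
        p
      })
  })
  structure(pts, class = "chemostat_scan")
}

#' @export
as.data.frame.chemostat_scan <- function(x, ...) {
  do.call(rbind, lapply(x, function(p) {
    if (p$washout)
      return(data.frame(D = p$dilution_rate, substrate = NA_character_,
                        uptake = NA_real_, ratio = NA_real_,
                        acetate = NA_real_, crowding_lhs = NA_real_,
                        capacity_scale = NA_real_, washout = TRUE))
    data.frame(D = p$dilution_rate,
               substrate = sub("^EX_", "", names(p$uptake_fluxes)),
               uptake = unname(p$uptake_fluxes),
               ratio = unname(p$consumption_ratios),
               acetate = p$acetate_secretion,
               crowding_lhs = p$crowding_lhs,
               capacity_scale = p$capacity_scale,
               washout = FALSE)
  }))
}

#' Onset of carbon catabolite repression in a dilution scan
#'
#' The lowest scanned dilution rate at which the crowding constraint is
#' saturated (its left-hand side reaches the budget within `tol`); below
#' this rate substrates are co-utilized, above it uptake turns
#' increasingly selective.
#'
#' @param scan a `chemostat_scan`.
#' @param tol saturation tolerance on `budget - lhs`.
#' @return list with `D_star` (NA if never saturated), `acetate_onset_D`
#'   (lowest D with positive acetate secretion, NA if none).
#' @export
ccr_onset <- function(scan, tol = 1e-6) {
  D <- vapply(scan, `[[`, numeric(1), "dilution_rate")
  lhs <- vapply(scan, function(p) p$crowding_lhs %||% NA_real_, numeric(1))
  bud <- vapply(scan, `[[`, numeric(1), "crowding_budget")
  ac <- vapply(scan, function(p) p$acetate_secretion %||% NA_real_, numeric(1))
  sat <- !is.na(lhs) & is.finite(bud) & (bud - lhs) <= tol
  list(D_star = if (any(sat)) min(D[sat]) else NA_real_,
       acetate_onset_D = if (any(ac > 1e-9, na.rm = TRUE))
         min(D[which(ac > 1e-9)]) else NA_real_)
}

#' @export
print.chemostat_point <- function(x, ...) {
  if (x$washout) {
    cat("chemostat_point: D =", x$dilution_rate, "/hr — WASHOUT\n")
    return(invisible(x))
  }
  cat("chemostat_point: D =", x$dilution_rate, "/hr, lambda =",
      format(x$capacity_scale, digits = 4), "\n  ratios:",
      paste(sprintf("%s %.3f", sub("^EX_", "", names(x$consumption_ratios)),
                    x$consumption_ratios), collapse = ", "),
      "\n  acetate:", format(x$acetate_secretion, digits = 4),
      "crowding lhs:", format(x$crowding_lhs, digits = 6), "\n")
  invisible(x)
}
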
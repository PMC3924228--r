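#' Configuration for a dynamic-FBA batch culture
#'
#' Defaults follow the study conditions this package emulates: cultures
#' started at OD600 0.035, single-substrate media at 2 g/L (0.2% w/vol),
#' mixed media at 0.4 g/L (0.04% w/vol) of each of the five substrates,
#' sampled over a working day. The OD600 <-> biomass conversion
#' (0.4 gDW/L per OD unit) is used only for display; all dynamics run in
#' gDW/L.
#'
#' @param initial_od starting OD600 of the culture.
#' @param od_to_gdw conversion constant, gDW/L per OD600 unit.
#' @param initial_concentrations named vector, substrate id (e.g. `"glc"`)
#'   -> g/L. Substrate ids must match the network's exchange ids minus the
#'   `EX_` prefix.
#' @param initial_acetate starting acetate concentration, g/L.
#' @param dt time step, hr.
#' @param t_end simulation horizon, hr.
#' @param uptake_kinetics `"hard_cap"` (capacity = Vmax while substrate
#'   remains, the form used for fixed-U simulations) or
#'   `"michaelis_menten"` (capacity = Vmax * C/(C+Km)).
#' @param vmax named per-substrate maximum uptake capacity U
#'   (mmol/gDW/hr); defaults to the network fixture's base capacities.
#' @param km named per-substrate Michaelis constant, g/L (only used by
#'   `"michaelis_menten"`).
#' @param molar_mass named vector g/mol per substrate (fixture defaults).
#' @param acetate_vmax maximum acetate reuptake capacity, mmol/gDW/hr.
#' @param exhaustion_threshold concentration (g/L) below which a substrate
#'   counts as exhausted.
#' @return a `batch_config` list.
#' @export
batch_config <- function(initial_od = 0.035, od_to_gdw = 0.4,
                         initial_concentrations = NULL,
                         initial_acetate = 0,
                         dt = 0.01, t_end = 12,
                         uptake_kinetics = c("hard_cap", "michaelis_menten"),
                         vmax = NULL, km = NULL, molar_mass = NULL,
                         acetate_vmax = 10,
                         exhaustion_threshold = 1e-4) {
  if (dt <= 0) mc_stop("config", "dt must be > 0")
  if (!is.null(initial_concentrations) && any(initial_concentrations < 0))
    mc_stop("config", "initial concentrations must be >= 0")
  structure(list(initial_od = initial_od, od_to_gdw = od_to_gdw,
                 initial_concentrations = initial_concentrations,
                 initial_acetate = initial_acetate, dt = dt, t_end = t_end,
                 uptake_kinetics = match.arg(uptake_kinetics),
                 vmax = vmax, km = km, molar_mass = molar_mass,
                 acetate_vmax = acetate_vmax,
                 exhaustion_threshold = exhaustion_threshold),
            class = "batch_config")
}

#' Mixed-culture initial concentrations (0.04% w/vol of each substrate)
#' @param substrates substrate ids.
#' @param g_per_l concentration of each substrate, g/L.
#' @return named vector of concentrations.
#' @export
mixed_medium <- function(substrates = c("glc", "gal", "mal", "lac", "gly"),
                         g_per_l = 0.4) {
  stats::setNames(rep(g_per_l, length(substrates)), substrates)
}

#' Single-substrate medium (0.2% w/vol)
#' @rdname mixed_medium
#' @param substrate single substrate id.
#' @export
single_medium <- function(substrate, g_per_l = 2.0) {
  stats::setNames(g_per_l, substrate)
}

#' Simulate a batch culture by dynamic FBA
#'
#' Explicit time stepping: at each step the crowding-constrained flux
#' balance problem is solved with uptake capacities derived from the
#' configured kinetics and current concentrations; biomass then grows
#' exponentially within the step at the optimal growth rate and
#' extracellular concentrations are updated from the uptake/secretion
#' fluxes. When a substrate would be overdrawn within a step, the step is
#' re-solved once with that substrate's capacity set to the
#' availability-limited rate, keeping concentrations non-negative without
#' a stiff integrator. Acetate exchange stays reversible throughout:
#' reuptake is never scripted and happens only when the LP finds it
#' optimal.
#'
#' @param net an `mc_network` (unsplit is fine; it is split internally).
#' @param cfg a [batch_config()].
#' @return a `batch_trajectory`: data.frame with columns `time`, `biomass`
#'   (gDW/L), `od600`, one column per substrate (g/L), `acetate` (g/L) and
#'   `growth_rate` (1/hr), with attributes `exhaustion_times` (named hr,
#'   `NA` if never exhausted) and `config`.
#' @export
simulate_batch <- function(net, cfg = batch_config()) {
  params <- attr(net, "params") %||% fixture_params()
  sub_ids <- sub("^EX_", "", net$substrate_exchange_ids)
  conc <- stats::setNames(rep(0, length(sub_ids)), sub_ids)
  ic <- cfg$initial_concentrations %||% mixed_medium(sub_ids)
  bad <- setdiff(names(ic), sub_ids)
  if (length(bad)) mc_stop("config", paste("unknown substrate:", bad[1]))
  conc[names(ic)] <- ic
  mm <- stats::setNames(params$substrates$molar_mass, params$substrates$id)
  if (!is.null(cfg$molar_mass)) mm[names(cfg$molar_mass)] <- cfg$molar_mass
  mm <- mm[sub_ids]
  mm_ac <- params$acetate_molar_mass %||% 60.05
  vmax <- stats::setNames(params$substrates$uptake_capacity,
                          params$substrates$id)[sub_ids]
  if (!is.null(cfg$vmax)) vmax[names(cfg$vmax)] <- cfg$vmax
  km <- stats::setNames(rep(0.05, length(sub_ids)), sub_ids)
  if (!is.null(cfg$km)) km[names(cfg$km)] <- cfg$km

  sp <- if (is_split(net)) net else split_reversible(net)
  ex_ids <- net$substrate_exchange_ids
  ac_ex <- net$acetate_exchange_id
  ac_back <- paste0(ac_ex, "__r")
  has_ac <- !is.na(ac_ex) && ac_back %in% sp$reactions$id
  ac_row <- if (has_ac) which(sp$reactions$id == ac_back) else NA_integer_

  X <- cfg$initial_od * cfg$od_to_gdw
  acetate <- cfg$initial_acetate
  times <- seq(0, cfg$t_end, by = cfg$dt)
  n_t <- length(times)
  out_bio <- numeric(n_t); out_ac <- numeric(n_t); out_mu <- numeric(n_t)
  out_conc <- matrix(0, n_t, length(sub_ids),
                     dimnames = list(NULL, sub_ids))
  exhaustion <- stats::setNames(rep(NA_real_, length(sub_ids)), sub_ids)

  cap_fun <- function(conc) {
    u <- vmax
    if (cfg$uptake_kinetics == "michaelis_menten")
      u <- vmax * conc / (conc + km)
    u[conc <= 0] <- 0
    u
  }
  # availability-limited uptake over one step: all of C consumed by X
  # growing at most at rate 0 (conservative: use current X)
  avail_rate <- function(C, M, X, dt) (C / M * 1000) / (X * dt)

  step_solve <- function(caps, ac_cap) {
    spl <- sp
    if (has_ac) spl$reactions$upper_bound[ac_row] <- ac_cap
    solve_fbawmc(flux_problem(spl,
                              uptake_capacity = stats::setNames(caps, ex_ids)))
  }

  for (k in seq_len(n_t)) {
    out_bio[k] <- X; out_ac[k] <- acetate; out_conc[k, ] <- conc
    just_ex <- is.na(exhaustion) & conc < cfg$exhaustion_threshold
    exhaustion[just_ex] <- times[k]
    if (k == n_t) { out_mu[k] <- out_mu[max(k - 1, 1)]; break }
    dt <- times[k + 1] - times[k]
    if (X <= 0) { out_mu[k] <- 0; next }
    caps <- cap_fun(conc)
    ac_cap <- if (acetate > 0) min(cfg$acetate_vmax,
                                   avail_rate(acetate, mm_ac, X, dt)) else 0
    st <- step_solve(caps, ac_cap)
    if (st$status != "optimal")
      mc_stop("lp-failure", sprintf("LP %s at step %d (t=%.3f hr)",
                                    st$status, k, times[k]))
    resolve <- function(st) {
      mu <- st$growth_rate
      Xint <- if (mu > 1e-12) X * (exp(mu * dt) - 1) / mu else X * dt
      upt <- st$fluxes[ex_ids]
      dC <- -upt * Xint * mm / 1000
      list(mu = mu, Xint = Xint, upt = upt, dC = dC)
    }
    rs <- resolve(st)
    over <- conc + rs$dC < -1e-12
    if (any(over)) {
      # bisected re-solve: cap overdrawn substrates at availability
      caps[over] <- pmin(caps[over],
                         avail_rate(conc[over], mm[over], rs$Xint, 1))
      st <- step_solve(caps, ac_cap)
      if (st$status != "optimal")
        mc_stop("lp-failure", sprintf("LP %s at step %d (t=%.3f hr)",
                                      st$status, k, times[k]))
      rs <- resolve(st)
    }
    mu <- rs$mu
    conc <- pmax(conc + rs$dC, 0)
    # snap the availability-limited tail to zero so exhaustion is a
    # clean crossing (residual < threshold, negligible carbon)
    conc[conc < cfg$exhaustion_threshold] <- 0
    ac_flux <- if (has_ac) acetate_net_flux(sp, st$fluxes) else 0
    acetate <- max(acetate + ac_flux * rs$Xint * mm_ac / 1000, 0)
    X <- X * exp(mu * dt)
    out_mu[k] <- mu
  }

  traj <- data.frame(time = times, biomass = out_bio,
                     od600 = out_bio / cfg$od_to_gdw,
                     out_conc, acetate = out_ac, growth_rate = out_mu)
  structure(traj, exhaustion_times = exhaustion, config = cfg,
            substrates = sub_ids,
            class = c("batch_trajectory", "data.frame"))
}

#' Order of substrate exhaustion in a batch trajectory
#'
#' @param traj a `batch_trajectory`.
#' @param threshold g/L below which a substrate counts as exhausted;
#'   defaults to the trajectory's configured threshold.
#' @return data.frame `substrate`, `time` (hr of first crossing, `NA` if
#'   never), `exhausted` (logical), ordered by exhaustion time with
#'   never-exhausted substrates last. Substrates that start at zero are
#'   not listed.
#' @export
exhaustion_order <- function(traj, threshold = NULL) {
  cfg <- attr(traj, "config")
  threshold <- threshold %||% cfg$exhaustion_threshold
  subs <- attr(traj, "substrates")
  present <- subs[traj[1, subs] > 0]
  if (!length(present))
    return(data.frame(substrate = character(), time = numeric(),
                      exhausted = logical()))
  tt <- vapply(present, function(s) {
    i <- which(traj[[s]] < threshold)
    if (length(i)) traj$time[i[1]] else NA_real_
  }, numeric(1))
  out <- data.frame(substrate = present, time = tt,
                    exhausted = !is.na(tt), row.names = NULL)
  out[order(!out$exhausted, out$time), , drop = FALSE]
}

#' Carbon balance of a batch trajectory
#'
#' The fixture network is carbon-closed, so at every time point
#' initial substrate carbon must equal residual substrate carbon plus
#' acetate carbon plus carbon fixed into new biomass. Returns the signed
#' relative error at the final time point (fraction of initial substrate
#' carbon).
#'
#' @param traj a `batch_trajectory` produced from a fixture-style network.
#' @param params the network's parameter list ([fixture_params()]).
#' @return list with `initial_carbon`, `final_carbon` (mmol C/L) and
#'   `rel_error`.
#' @export
carbon_balance <- function(traj, params = fixture_params()) {
  su <- params$substrates
  subs <- attr(traj, "substrates")
  first <- traj[1, ]; last <- traj[nrow(traj), ]
  cvec <- stats::setNames(su$carbon_atoms, su$id)[subs]
  mvec <- stats::setNames(su$molar_mass, su$id)[subs]
  mmolC <- function(row) sum(as.numeric(row[subs]) / mvec * 1000 * cvec)
  c0 <- mmolC(first) + first$acetate / params$acetate_molar_mass * 1000 * 2 +
    params$biomass_carbon * first$biomass
  c1 <- mmolC(last) + last$acetate / params$acetate_molar_mass * 1000 * 2 +
    params$biomass_carbon * last$biomass
  list(initial_carbon = c0, final_carbon = c1,
       rel_error = (c1 - c0) / c0)
}
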
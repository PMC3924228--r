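#' Define a crowding-constrained flux balance problem
#'
#' @param network an `mc_network` in split form (see [split_reversible()]).
#' @param uptake_capacity named vector, substrate exchange id -> maximum
#'   uptake capacity U (mmol/gDW/hr, >= 0). Exchanges not named keep their
#'   network bounds. `Inf` leaves a capacity unconstrained.
#' @param objective_id reaction to maximize; defaults to the biomass
#'   reaction.
#' @param crowding_budget overrides the network's budget; `Inf` disables
#'   the crowding constraint (plain FBA).
#' @param include_exchanges if `TRUE` exchange pseudo-reactions also pay
#'   their crowding coefficient (transporter cost); by default the crowding
#'   sum runs over internal and biomass reactions only.
#' @return a `flux_problem` object.
#' @export
flux_problem <- function(network, uptake_capacity = NULL,
                         objective_id = network$biomass_id,
                         crowding_budget = network$crowding_budget,
                         include_exchanges = FALSE) {
  if (!is_split(network))
    mc_stop("validation", "network must be in split form; call split_reversible()")
  if (!is.null(uptake_capacity)) {
    bad <- setdiff(names(uptake_capacity), network$substrate_exchange_ids)
    if (length(bad))
      mc_stop("validation", paste("uptake capacity for unknown substrate exchange:", bad[1]))
    if (any(uptake_capacity < 0))
      mc_stop("validation", "uptake capacities must be >= 0")
  }
  structure(list(network = network, uptake_capacity = uptake_capacity,
                 objective_id = objective_id,
                 crowding_budget = crowding_budget,
                 include_exchanges = include_exchanges),
            class = "flux_problem")
}

# assemble the LP ingredients shared by solver and oracle
problem_matrices <- function(problem, extra_ub = NULL) {
  net <- problem$network
  r <- net$reactions
  n <- nrow(r)
  S <- stoich_matrix(net)
  lb <- r$lower_bound
  ub <- r$upper_bound
  if (!is.null(problem$uptake_capacity)) {
    i <- match(names(problem$uptake_capacity), r$id)
    ub[i] <- pmin(ub[i], problem$uptake_capacity)
    lb[i] <- pmin(lb[i], ub[i])
  }
  a <- r$crowding_coefficient
  if (!problem$include_exchanges) a[r$kind == "exchange"] <- 0
  A_ub <- NULL; b_ub <- NULL
  if (is.finite(problem$crowding_budget)) {
    A_ub <- matrix(a, 1)
    b_ub <- problem$crowding_budget
  }
  list(S = S, lb = lb, ub = ub, a = a, A_ub = A_ub, b_ub = b_ub,
       obj = as.numeric(r$id == problem$objective_id), ids = r$id, n = n)
}

#' Solve a crowding-constrained flux balance problem
#'
#' Maximizes the objective flux subject to steady state (`S v = 0`), flux
#' bounds, uptake capacities, and the molecular crowding constraint
#' \eqn{\sum_i a_i v_i \le budget} over non-negative split fluxes. Among
#' alternate optima a lexicographic second stage minimizes total flux
#' (parsimonious tie-break) so reported uptake hierarchies are
#' deterministic, single-valued functions of the inputs.
#'
#' @param problem a [flux_problem()].
#' @return a `flux_state`: list with `fluxes` (named, split reactions),
#'   `growth_rate` (biomass flux, 1/hr), `objective_value`, `crowding_lhs`
#'   (\eqn{\sum a_i v_i}), `status` (`"optimal"`, `"infeasible"` or
#'   `"unbounded"`), and the numerical tolerances used (`feas_tol` 1e-8,
#'   `opt_tol` 1e-9). Infeasibility and unboundedness are reported as
#'   status, not errors.
#' @export
solve_fbawmc <- function(problem) {
  pm <- problem_matrices(problem)
  first <- solve_lp(pm$obj, A_eq = pm$S, b_eq = rep(0, nrow(pm$S)),
                    A_ub = pm$A_ub, b_ub = pm$b_ub,
                    lb = pm$lb, ub = pm$ub, maximize = TRUE)
  if (first$status != "optimal") {
    return(structure(list(
      fluxes = stats::setNames(rep(NA_real_, pm$n), pm$ids),
      growth_rate = if (first$status == "unbounded") Inf else NA_real_,
      objective_value = first$value, crowding_lhs = NA_real_,
      status = first$status, feas_tol = 1e-8, opt_tol = 1e-9),
      class = "flux_state"))
  }
  # parsimonious second stage: pin the objective, minimize total flux
  second <- solve_lp(rep(1, pm$n),
                     A_eq = rbind(pm$S, pm$obj),
                     b_eq = c(rep(0, nrow(pm$S)), first$value),
                     A_ub = pm$A_ub, b_ub = pm$b_ub,
                     lb = pm$lb, ub = pm$ub, maximize = FALSE)
  x <- if (second$status == "optimal") second$x else first$x
  fluxes <- stats::setNames(x, pm$ids)
  structure(list(
    fluxes = fluxes,
    growth_rate = unname(fluxes[problem$network$biomass_id]),
    objective_value = unname(sum(pm$obj * x)),
    crowding_lhs = unname(sum(pm$a * x)),
    status = "optimal", feas_tol = 1e-8, opt_tol = 1e-9),
    class = "flux_state")
}

#' @export
print.flux_state <- function(x, ...) {
  cat("flux_state:", x$status, "| growth rate:",
      format(x$growth_rate, digits = 6),
      "| crowding lhs:", format(x$crowding_lhs, digits = 6), "\n")
  invisible(x)
}

#' Left-hand side of the molecular crowding constraint
#'
#' Computes \eqn{\sum_i a_i v_i} over the supplied fluxes; by default
#' exchange pseudo-reactions carry zero cost (they are not enzymes), which
#' is already encoded when `coefficients` comes from `problem_matrices`.
#'
#' @param fluxes named non-negative flux vector (split form).
#' @param coefficients named crowding coefficients; names must match
#'   `fluxes` as sets.
#' @return dimensionless scalar.
#' @export
crowding_lhs <- function(fluxes, coefficients) {
  if (!setequal(names(fluxes), names(coefficients)))
    mc_stop("validation", "flux and coefficient id sets differ")
  sum(coefficients[names(fluxes)] * fluxes)
}

#' Brute-force oracle for small flux problems
#'
#' Enumerates the vertices of the feasible polytope (all ways of making
#' `n - rank(S)` inequality constraints tight), checks feasibility, and
#' returns the best vertex. Completely independent of the simplex code
#' path, so it serves as a ground-truth check on small instances.
#'
#' @param problem a [flux_problem()]; all bounds must be finite.
#' @param max_dim refuse problems with more free dimensions than this
#'   (default 8): vertex enumeration is exponential.
#' @return list with `objective_value`, `growth_rate`, `fluxes`, `status`.
#' @export
brute_force_oracle <- function(problem, max_dim = 8) {
  pm <- problem_matrices(problem)
  if (any(!is.finite(pm$ub)))
    mc_stop("validation", "oracle requires finite upper bounds")
  n <- pm$n
  qrS <- qr(t(pm$S))
  free_dim <- n - qrS$rank
  if (free_dim > max_dim)
    mc_stop("dimensionality", sprintf(
      "oracle refuses %d free dimensions (max %d)", free_dim, max_dim))
  # inequality rows as G v <= h: upper bounds, negated lower bounds, crowding
  G <- rbind(diag(n), -diag(n), pm$A_ub)
  h <- c(pm$ub, -pm$lb, pm$b_ub)
  m_eq <- nrow(pm$S)
  best <- NULL
  combos <- utils::combn(nrow(G), free_dim)
  for (j in seq_len(ncol(combos))) {
    idx <- combos[, j]
    A <- rbind(pm$S, G[idx, , drop = FALSE])
    b <- c(rep(0, m_eq), h[idx])
    sol <- tryCatch(qr.solve(A, b, tol = 1e-10), error = function(e) NULL)
    if (is.null(sol)) next
    if (max(abs(A %*% sol - b)) > 1e-7) next     # rank-deficient pick
    if (any(G %*% sol > h + 1e-7)) next          # infeasible vertex
    val <- sum(pm$obj * sol)
    if (is.null(best) || val > best$objective_value + 1e-12) {
      best <- list(objective_value = val,
                   fluxes = stats::setNames(as.numeric(sol), pm$ids))
    }
  }
  if (is.null(best))
    return(list(objective_value = NA_real_, growth_rate = NA_real_,
                fluxes = NULL, status = "infeasible"))
  best$growth_rate <- unname(best$fluxes[problem$network$biomass_id])
  best$status <- "optimal"
  best
}
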
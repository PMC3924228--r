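#' Construct a crowding-annotated metabolic network
#'
#' A `mc_network` holds metabolites, reactions with bounds and per-reaction
#' crowding coefficients, and the bookkeeping needed by the simulators:
#' which reaction is biomass, which exchanges feed the five carbon
#' substrates, which exchange carries acetate, and the crowding budget
#' (the right-hand side of the molecular crowding constraint
#' \eqn{\sum_i a_i v_i \le budget}).
#'
#' @param metabolites data.frame with columns `id`, `name`, `carbon_atoms`
#'   (atoms per molecule, >= 0) and `is_external` (logical; boundary species
#'   excluded from the steady-state mass balance).
#' @param reactions data.frame with columns `id`, `kind` (one of
#'   `"internal"`, `"exchange"`, `"biomass"`), `lower_bound`, `upper_bound`
#'   (mmol/gDW/hr; may be infinite), `crowding_coefficient`
#'   (hr gDW/mmol, >= 0).
#' @param stoichiometry data.frame with columns `reaction_id`,
#'   `metabolite_id`, `coefficient` (signed; negative = consumed).
#' @param biomass_id id of the biomass (objective) reaction.
#' @param substrate_exchange_ids ordered character vector of carbon-substrate
#'   exchange reaction ids.
#' @param acetate_exchange_id id of the acetate exchange reaction (positive
#'   flux = secretion, negative = reuptake), or `NA` if absent.
#' @param crowding_budget positive scalar, dimensionless; `Inf` disables the
#'   crowding constraint and recovers plain FBA.
#' @return an object of class `mc_network`.
#' @export
mc_network <- function(metabolites, reactions, stoichiometry,
                       biomass_id, substrate_exchange_ids = character(),
                       acetate_exchange_id = NA_character_,
                       crowding_budget = 1) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  stoichiometry <- as.data.frame(stoichiometry, stringsAsFactors = FALSE)
  net <- structure(
    list(metabolites = metabolites, reactions = reactions,
         stoichiometry = stoichiometry, biomass_id = biomass_id,
         substrate_exchange_ids = substrate_exchange_ids,
         acetate_exchange_id = acetate_exchange_id,
         crowding_budget = crowding_budget,
         schema_version = 1L),
    class = "mc_network")
  validate_network(net)
}

#' Validate a metabolic network
#'
#' Checks id uniqueness, bound ordering, non-negative crowding
#' coefficients and carbon counts, that every stoichiometry entry
#' references declared ids, that the biomass and all tagged exchange
#' reactions exist, and that each exchange reaction touches exactly one
#' non-external metabolite.
#'
#' @param net an `mc_network`.
#' @return `net`, invisibly unchanged, if valid; otherwise a classed error
#'   (e.g. condition class `crowdfba_no_biomass`, `crowdfba_duplicate_id`).
#' @export
validate_network <- function(net) {
  m <- net$metabolites; r <- net$reactions; s <- net$stoichiometry
  if (anyDuplicated(m$id))
    mc_stop("duplicate-id", paste("duplicate metabolite id:",
                                  m$id[duplicated(m$id)][1]))
  if (anyDuplicated(r$id))
    mc_stop("duplicate-id", paste("duplicate reaction id:",
                                  r$id[duplicated(r$id)][1]))
  if (any(m$carbon_atoms < 0))
    mc_stop("validation", "carbon_atoms must be >= 0")
  if (any(r$lower_bound > r$upper_bound))
    mc_stop("validation", "lower_bound > upper_bound")
  if (any(r$crowding_coefficient < 0))
    mc_stop("validation", "negative crowding coefficient")
  if (!all(r$kind %in% c("internal", "exchange", "biomass")))
    mc_stop("validation", "reaction kind must be internal/exchange/biomass")
  if (!all(s$metabolite_id %in% m$id))
    mc_stop("validation", paste("stoichiometry references undeclared metabolite:",
                                setdiff(s$metabolite_id, m$id)[1]))
  if (!all(s$reaction_id %in% r$id))
    mc_stop("validation", "stoichiometry references undeclared reaction")
  if (!(net$biomass_id %in% r$id))
    mc_stop("no-biomass", paste("biomass reaction", net$biomass_id,
                                "not present in the network"))
  missing_ex <- setdiff(net$substrate_exchange_ids, r$id)
  if (length(missing_ex))
    mc_stop("validation", paste("substrate exchange not present:", missing_ex[1]))
  if (!is.na(net$acetate_exchange_id) &&
      !(net$acetate_exchange_id %in% r$id))
    mc_stop("validation", "acetate exchange not present")
  if (!is.numeric(net$crowding_budget) || net$crowding_budget <= 0)
    mc_stop("validation", "crowding_budget must be > 0")
  ext <- m$id[m$is_external]
  for (rid in r$id[r$kind == "exchange"]) {
    touched <- s$metabolite_id[s$reaction_id == rid]
    if (sum(!(touched %in% ext)) != 1)
      mc_stop("validation", paste("exchange", rid,
                                  "must touch exactly one non-external metabolite"))
  }
  invisible(net)
}

#' Stoichiometric matrix of a network
#'
#' @param net an `mc_network`.
#' @param internal_only if `TRUE` (default) rows cover only non-external
#'   metabolites — the matrix `S` whose steady-state condition is `S v = 0`.
#' @return a dense numeric matrix, rows named by metabolite id, columns by
#'   reaction id.
#' @export
stoich_matrix <- function(net, internal_only = TRUE) {
  mets <- net$metabolites
  if (internal_only) mets <- mets[!mets$is_external, , drop = FALSE]
  S <- matrix(0, nrow(mets), nrow(net$reactions),
              dimnames = list(mets$id, net$reactions$id))
  s <- net$stoichiometry[net$stoichiometry$metabolite_id %in% mets$id, ]
  S[cbind(match(s$metabolite_id, mets$id),
          match(s$reaction_id, net$reactions$id))] <- s$coefficient
  S
}

#' Split reversible reactions into irreversible pairs
#'
#' Every reaction with a negative lower bound becomes a forward/backward
#' pair (backward id suffixed `__r`, stoichiometry negated), each
#' inheriting the original crowding coefficient, so that all fluxes are
#' non-negative and the crowding sum \eqn{\sum a_i v_i} is taken over
#' non-negative fluxes. Any feasible flux of the original network maps to
#' a feasible flux of the split network with the same biomass value.
#'
#' @param net an `mc_network`.
#' @return the split `mc_network`; attribute `"split_map"` records, for each
#'   original reversible reaction, its forward/backward column ids, and
#'   `is_split(net)` returns `TRUE`.
#' @seealso [collapse_fluxes()] to map split fluxes back to signed fluxes.
#' @export
split_reversible <- function(net) {
  r <- net$reactions; s <- net$stoichiometry
  rev_ids <- r$id[r$lower_bound < 0]
  if (!length(rev_ids)) {
    attr(net, "split_map") <- list()
    attr(net, "split") <- TRUE
    return(net)
  }
  map <- list()
  for (rid in rev_ids) {
    i <- which(r$id == rid)
    lb <- r$lower_bound[i]; ub <- r$upper_bound[i]
    back <- r[i, ]
    back$id <- paste0(rid, "__r")
    back$lower_bound <- max(0, -ub)
    back$upper_bound <- -lb
    r$lower_bound[i] <- max(0, lb)
    r$upper_bound[i] <- max(0, ub)
    r <- rbind(r, back)
    sb <- s[s$reaction_id == rid, ]
    sb$reaction_id <- back$id
    sb$coefficient <- -sb$coefficient
    s <- rbind(s, sb)
    map[[rid]] <- c(forward = rid, backward = back$id)
  }
  out <- net
  out$reactions <- r
  out$stoichiometry <- s
  out <- validate_network(out)
  attr(out, "split_map") <- map
  attr(out, "split") <- TRUE
  out
}

#' @rdname split_reversible
#' @export
is_split <- function(net) isTRUE(attr(net, "split"))

#' Collapse split fluxes back onto the original reaction set
#'
#' @param net a network produced by [split_reversible()].
#' @param fluxes named flux vector over the split reactions.
#' @return named vector over the original reaction ids
#'   (forward minus backward).
#' @export
collapse_fluxes <- function(net, fluxes) {
  map <- attr(net, "split_map")
  if (is.null(map)) mc_stop("validation", "network is not in split form")
  out <- fluxes[!grepl("__r$", names(fluxes))]
  for (rid in names(map))
    out[rid] <- fluxes[[map[[rid]]["forward"]]] - fluxes[[map[[rid]]["backward"]]]
  out
}

# net flux through the (possibly split) acetate exchange: positive =
# secretion into the medium, negative = reuptake
acetate_net_flux <- function(net, fluxes) {
  ex <- net$acetate_exchange_id
  if (is.na(ex)) return(0)
  back <- paste0(ex, "__r")
  f <- fluxes[[ex]] %||% 0
  b <- if (back %in% names(fluxes)) fluxes[[back]] else 0
  f - b
}

# forbid acetate reuptake on a split network (zero the backward column,
# or raise a negative lower bound on an unsplit exchange)
clamp_acetate_reuptake <- function(net) {
  ex <- net$acetate_exchange_id
  if (is.na(ex)) return(net)
  back <- paste0(ex, "__r")
  i <- which(net$reactions$id == back)
  if (length(i)) {
    net$reactions$lower_bound[i] <- 0
    net$reactions$upper_bound[i] <- 0
  } else {
    j <- which(net$reactions$id == ex)
    net$reactions$lower_bound[j] <- max(0, net$reactions$lower_bound[j])
  }
  net
}

# ---- file I/O -------------------------------------------------------------

# JSON schema (schema_version 1): top-level keys schema_version,
# crowding_budget, biomass_id, substrate_exchange_ids, acetate_exchange_id,
# metabolites [{id,name,carbon_atoms,is_external}], reactions
# [{id,kind,lower_bound,upper_bound,crowding_coefficient,
#   stoichiometry:{met:coef}}]. Infinite bounds are encoded as null.

#' Read a metabolic network from disk
#'
#' @param path for `format = "json"` a file; for `format = "tsv"` a directory
#'   containing `metabolites.tsv`, `reactions.tsv`, `stoichiometry.tsv`
#'   (columns `reaction_id`, `metabolite_id`, `coefficient`) and
#'   `network.json` with the scalar fields.
#' @param format `"json"` (default) or `"tsv"`.
#' @return a validated `mc_network`. Canonical JSON written by
#'   [write_network()] round-trips byte-identically.
#' @export
load_network <- function(path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "json") {
    j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    mets <- do.call(rbind, lapply(j$metabolites, function(m)
      data.frame(id = m$id, name = m$name %||% m$id,
                 carbon_atoms = as.numeric(m$carbon_atoms %||% 0),
                 is_external = isTRUE(m$is_external),
                 stringsAsFactors = FALSE)))
    rxns <- do.call(rbind, lapply(j$reactions, function(r)
      data.frame(id = r$id, kind = r$kind %||% "internal",
                 lower_bound = if (is.null(r$lower_bound)) -Inf else as.numeric(r$lower_bound),
                 upper_bound = if (is.null(r$upper_bound)) Inf else as.numeric(r$upper_bound),
                 crowding_coefficient = as.numeric(r$crowding_coefficient %||% 0),
                 stringsAsFactors = FALSE)))
    sto <- do.call(rbind, lapply(j$reactions, function(r) {
      if (!length(r$stoichiometry)) return(NULL)
      data.frame(reaction_id = r$id,
                 metabolite_id = names(r$stoichiometry),
                 coefficient = as.numeric(unlist(r$stoichiometry)),
                 stringsAsFactors = FALSE)
    }))
    mc_network(mets, rxns, sto,
               biomass_id = j$biomass_id %||% NA_character_,
               substrate_exchange_ids = as.character(unlist(j$substrate_exchange_ids)),
               acetate_exchange_id = j$acetate_exchange_id %||% NA_character_,
               crowding_budget = if (is.null(j$crowding_budget)) 1
                                 else as.numeric(j$crowding_budget))
  } else {
    rd <- function(f) utils::read.delim(file.path(path, f), sep = "\t",
                                        stringsAsFactors = FALSE)
    mets <- rd("metabolites.tsv")
    mets$is_external <- as.logical(mets$is_external)
    rxns <- rd("reactions.tsv")
    sto <- rd("stoichiometry.tsv")
    meta <- jsonlite::fromJSON(file.path(path, "network.json"),
                               simplifyVector = TRUE)
    rxns$lower_bound[is.na(rxns$lower_bound)] <- -Inf
    rxns$upper_bound[is.na(rxns$upper_bound)] <- Inf
    mc_network(mets, rxns, sto, biomass_id = meta$biomass_id,
               substrate_exchange_ids = meta$substrate_exchange_ids,
               acetate_exchange_id = meta$acetate_exchange_id %||% NA_character_,
               crowding_budget = meta$crowding_budget %||% 1)
  }
}

#' Write a metabolic network to disk
#'
#' @inheritParams load_network
#' @param net an `mc_network`.
#' @return `path`, invisibly. JSON output is canonical: fixed key order,
#'   metabolites and reactions in declaration order, infinite bounds as
#'   null, so `write(load(f))` is a byte-stable fixed point.
#' @export
write_network <- function(net, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  validate_network(net)
  if (format == "json") {
    num <- function(x) if (is.finite(x)) jsonlite::unbox(x) else NULL
    j <- list(
      schema_version = jsonlite::unbox(net$schema_version),
      crowding_budget = num(net$crowding_budget),
      biomass_id = jsonlite::unbox(net$biomass_id),
      substrate_exchange_ids = as.list(net$substrate_exchange_ids),
      acetate_exchange_id = if (is.na(net$acetate_exchange_id)) NULL
                            else jsonlite::unbox(net$acetate_exchange_id),
      metabolites = lapply(seq_len(nrow(net$metabolites)), function(i) {
        m <- net$metabolites[i, ]
        list(id = jsonlite::unbox(m$id), name = jsonlite::unbox(m$name),
             carbon_atoms = jsonlite::unbox(m$carbon_atoms),
             is_external = jsonlite::unbox(m$is_external))
      }),
      reactions = lapply(seq_len(nrow(net$reactions)), function(i) {
        r <- net$reactions[i, ]
        s <- net$stoichiometry[net$stoichiometry$reaction_id == r$id, ]
        s <- s[order(s$metabolite_id), ]
        coef <- as.list(s$coefficient)
        names(coef) <- s$metabolite_id
        list(id = jsonlite::unbox(r$id), kind = jsonlite::unbox(r$kind),
             lower_bound = num(r$lower_bound),
             upper_bound = num(r$upper_bound),
             crowding_coefficient = jsonlite::unbox(r$crowding_coefficient),
             stoichiometry = lapply(coef, jsonlite::unbox))
      })
    )
    txt <- jsonlite::toJSON(j, pretty = 2, digits = NA, null = "null")
    writeLines(txt, path)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    wr <- function(d, f) utils::write.table(
      d, file.path(path, f), sep = "\t", quote = FALSE, row.names = FALSE)
    wr(net$metabolites, "metabolites.tsv")
    r <- net$reactions
    r$lower_bound[!is.finite(r$lower_bound)] <- NA
    r$upper_bound[!is.finite(r$upper_bound)] <- NA
    wr(r, "reactions.tsv")
    wr(net$stoichiometry, "stoichiometry.tsv")
    meta <- list(schema_version = net$schema_version,
                 crowding_budget = net$crowding_budget,
                 biomass_id = net$biomass_id,
                 substrate_exchange_ids = net$substrate_exchange_ids,
                 acetate_exchange_id = net$acetate_exchange_id)
    writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                                pretty = 2),
               file.path(path, "network.json"))
  }
  invisible(path)
}

#' @export
print.mc_network <- function(x, ...) {
  cat("mc_network:", nrow(x$metabolites), "metabolites,",
      nrow(x$reactions), "reactions\n")
  cat("  biomass:", x$biomass_id,
      "| substrate exchanges:", paste(x$substrate_exchange_ids, collapse = ", "),
      "\n  crowding budget:", x$crowding_budget, "\n")
  invisible(x)
}
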
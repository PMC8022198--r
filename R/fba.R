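# Plain flux balance analysis on a (split, irreversible) stoichiometric
# model. Used for pathway parameter estimation and as the metabolic-layer
# workhorse underneath the proteome-coupled simulation.

#' Flux balance analysis
#'
#' Solves `max/min sum(objective * v)` subject to `S v = 0`, `lb <= v <= ub`
#' over the reactions of a split model, with optional fixed fluxes, blocked
#' reactions and relaxed (boundary) species.
#'
#' @param model a split `sm_model` (all `lb >= 0`; see [split_reversible()]).
#' @param objective named numeric vector of objective coefficients, or a
#'   single reaction id (coefficient 1).
#' @param maximize direction.
#' @param fixed named numeric vector of fluxes to pin (`lb = ub = value`).
#' @param lb,ub named numeric vectors overriding bounds of individual
#'   reactions.
#' @param blocked character vector of reaction ids forced to zero; ids
#'   matching `source_id` block every split/isozyme copy.
#' @param drop_balance metabolite ids whose mass balance is relaxed (the
#'   species becomes an unconstrained boundary pool).
#' @param minimize_total after optimizing, re-solve minimizing total flux at
#'   the achieved objective value (suppresses futile cycles and simultaneous
#'   forward/reverse flux).
#' @return list with `status`, `objective`, `fluxes` (over split reaction
#'   ids), `net` (over source ids), and `duals` (named by metabolite for the
#'   balance rows).
#' @export
fba <- function(model, objective, maximize = TRUE, fixed = NULL,
                lb = NULL, ub = NULL, blocked = NULL, drop_balance = NULL,
                minimize_total = FALSE) {
  stopifnot(inherits(model, "sm_model"), all(model$rxns$lb >= 0))
  rx <- model$rxns
  n <- nrow(rx)
  ids <- rx$id

  if (is.character(objective)) objective <- setNames(1, objective)
  obj <- setNames(numeric(n), ids)
  if (!all(names(objective) %in% ids)) {
    stop("unknown objective reactions: ",
         paste(setdiff(names(objective), ids), collapse = ", "))
  }
  obj[names(objective)] <- objective

  lo <- setNames(rx$lb, ids); hi <- setNames(rx$ub, ids)
  if (!is.null(lb)) lo[names(lb)] <- lb
  if (!is.null(ub)) hi[names(ub)] <- ub
  if (!is.null(fixed)) { lo[names(fixed)] <- fixed; hi[names(fixed)] <- fixed }
  if (!is.null(blocked)) {
    hit <- ids %in% blocked | rx$source_id %in% blocked
    lo[hit] <- 0; hi[hit] <- 0
  }
  if (any(lo > hi)) stop("inconsistent bounds after overrides")

  keep <- setdiff(rownames(model$S), drop_balance)
  Abal <- model$S[keep, , drop = FALSE]
  rows_b <- rep(0, length(keep)); dir_b <- rep("=", length(keep))

  # bound rows (upper bounds finite; positive lower bounds)
  iu <- which(is.finite(hi) & hi < 1000)
  il <- which(lo > 0)
  nb <- length(iu) + length(il)
  Abnd <- matrix(0, nb, n, dimnames = list(NULL, ids))
  bb <- numeric(nb); db <- character(nb)
  k <- 0
  for (i in iu) { k <- k + 1; Abnd[k, i] <- 1; bb[k] <- hi[i]; db[k] <- "<=" }
  for (i in il) { k <- k + 1; Abnd[k, i] <- 1; bb[k] <- lo[i]; db[k] <- ">=" }
  # reactions with ub >= 1000 are treated as unbounded above (capped rows
  # would only bloat the tableau); infeasibility from true caps is preserved
  A <- rbind(Abal, Abnd)
  b <- c(rows_b, bb)
  dirs <- c(dir_b, db)
  rownames(A) <- c(keep, rep("", nb))

  sol <- solve_lp(obj, A, b, dirs, maximize = maximize)
  if (sol$status == "optimal" && minimize_total) {
    A2 <- rbind(A, obj)
    b2 <- c(b, sol$objective)
    d2 <- c(dirs, "=")
    sol2 <- solve_lp(rep(1, n), A2, b2, d2, maximize = FALSE)
    if (sol2$status == "optimal") {
      sol$x <- sol2$x
      names(sol$x) <- ids
    }
  }
  v <- setNames(sol$x, ids)
  list(status = sol$status, objective = sol$objective, fluxes = v,
       net = if (sol$status == "optimal") net_fluxes(model, v) else NULL,
       duals = setNames(sol$duals[seq_along(keep)], keep))
}

#' Uptake reaction id for an extracellular compound
#'
#' After exchange splitting, uptake is the reverse copy of the exchange
#' reaction (`EX_<met>_rev`); this helper resolves it and errors when the
#' model has no exchange for the compound.
#'
#' @param model split `sm_model`.
#' @param met extracellular metabolite id (e.g. `"glc__D_e"`).
#' @export
uptake_rxn <- function(model, met) {
  id <- paste0("EX_", met, "_rev")
  if (!id %in% model$rxns$id) stop("no uptake reaction for ", met)
  id
}

# Close all uptake (reverse-exchange) reactions except the freely available
# inorganic species, returning an upper-bound override vector.
closed_uptakes <- function(model, except = c("h_e", "h2o_e")) {
  rx <- model$rxns
  rev_ex <- rx$id[rx$kind == "exchange" & rx$dir == "rev"]
  mets <- sub("_rev$", "", sub("^EX_", "", rev_ex))
  setNames(ifelse(mets %in% except, 1000, 0), rev_ex)
}
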
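# Growth-rate-parameterized linear program over the proteome-coupled model
# and the chemostat binary-search workflow. At fixed growth rate mu every
# catalyst concentration is eliminated through its dilution flux
# ([X] = v_dil / mu), which keeps the program linear in the fluxes.

sigma_from_S <- function(S, KM) if (is.infinite(S)) 1 else S / (KM + S)

#' Assemble the proteome-coupled linear program
#'
#' Builds the flux LP at fixed growth rate and glucose-transporter
#' saturation: mass balance for every species, `v <= k_cat [E]` coupling
#' for catalysed reactions (the glucose transporter's effective turnover is
#' scaled by the saturation), machinery capacity constraints, steady-state
#' degradation fluxes, the fixed total-modeled-proteome budget, the pinned
#' biomass-dilution and unmodeled-protein fluxes, growth-rate-dependent
#' amino-acid uptake bounds, the transporter concentration cap, and the
#' condition's blocked reactions. The objective maximizes dummy-protein
#' production.
#'
#' @param pc a `pc_model` from [make_toy_pc()] / [build_expression_layer()].
#' @param mu growth rate, 1/h (> 0).
#' @param sigma glucose-transporter saturation in `[0, 1]`.
#' @param block reaction ids (or source ids) forced to zero; defaults to
#'   the model's condition block list.
#' @param cap transporter concentration cap override, mmol/gCDW.
#' @return list with the LP pieces (`obj`, `A`, `b`, `dir`, `vars`).
#' @export
assemble_pc_lp <- function(pc, mu, sigma = 1, block = pc$block,
                           cap = pc$budget$transporter_cap) {
  stopifnot(inherits(pc, "pc_model"))
  if (mu <= 0) stop("mu must be positive (coupling coefficients are undefined at mu = 0)")
  stopifnot(sigma >= 0, sigma <= 1)
  model <- pc$model
  sc <- pc$config$macro_unit %||% 1e-6
  rx <- model$rxns
  ids <- rx$id
  n <- length(ids)
  vidx <- setNames(seq_len(n), ids)

  lo <- setNames(rx$lb, ids); hi <- setNames(rx$ub, ids)
  # glucose uptake through Michaelis-Menten transporter kinetics
  if (!is.null(pc$glucose) && is.finite(cap)) {
    hi[pc$glucose$uptake_rxn] <- pc$glucose$kcat * cap * sigma
  }
  # growth-rate-dependent amino-acid uptake bounds
  if (!is.null(pc$aa_uptake)) {
    for (i in seq_len(nrow(pc$aa_uptake))) {
      hi[pc$aa_uptake$rxn[i]] <- max(0, pc$aa_uptake$slope[i] * mu +
                                          pc$aa_uptake$intercept[i])
    }
  }
  if (!is.null(block)) {
    hitb <- ids %in% block | rx$source_id %in% block
    lo[hitb] <- 0; hi[hitb] <- 0
  }

  dil_of <- function(sp) {
    d <- pc$dil[[sp]]
    if (is.null(d) || is.na(d)) stop("no dilution reaction for species ", sp)
    d
  }

  cp <- pc$coupling
  if (is.null(cp) || nrow(cp) == 0) cp <- NULL
  if (!is.null(cp)) cp$rate <- vapply(seq_len(nrow(cp)), function(i) {
    r <- if (cp$type[i] == "enzyme") {
      e <- pc$enzymes[[cp$ref[i]]]
      kc <- enzyme_kcat(e, cp$rxn[i], rx$source_id[vidx[[cp$rxn[i]]]])
      if (is.na(kc)) stop("no k_cat for ", cp$rxn[i])
      kc * sc
    } else {
      pc$machineries[[cp$ref[i]]]$rate
    }
    if (!is.null(pc$glucose) && cp$rxn[i] %in% pc$glucose$pts_rxns) r * sigma else r
  }, numeric(1))
  # machinery capacities are single rows per machinery species
  groups <- if (is.null(cp)) list() else {
    key <- ifelse(cp$type == "machinery" & cp$species %in% c("ribosome", "rnap"),
                  paste0("cap:", cp$species), paste0("row:", seq_len(nrow(cp))))
    split(seq_len(nrow(cp)), key)
  }

  rows <- list(); bvec <- c(); dvec <- c(); rnames <- c()
  emit <- function(coefs, b, d, label = "") {
    row <- numeric(n)
    row[vidx[names(coefs)]] <- unname(coefs)
    rows[[length(rows) + 1]] <<- row
    bvec[length(bvec) + 1] <<- b
    dvec[length(dvec) + 1] <<- d
    rnames[length(rnames) + 1] <<- label
  }

  # coupling rows: sum(w * mu * v) - rate * v_dil <= 0
  for (g in groups) {
    co <- setNames(cp$weight[g] * mu, cp$rxn[g])
    if (cp$rate[g][1] <= 0 || length(unique(cp$species[g])) != 1) {
      stop("bad coupling group")
    }
    dr <- dil_of(cp$species[g][1])
    co <- c(co, setNames(-cp$rate[g][1], dr))
    co <- tapply(co, names(co), sum)
    emit(co, 0, "<=", paste0("coupling:", cp$species[g][1], ":", cp$rxn[g][1]))
  }
  # degradation steady state: mu * v_deg - kdeg * v_dil = 0
  if (!is.null(pc$deg)) {
    for (i in seq_len(nrow(pc$deg))) {
      emit(setNames(c(mu, -pc$deg$kdeg[i]),
                    c(pc$deg$rxn[i], dil_of(pc$deg$species[i]))),
           0, "=", paste0("deg:", pc$deg$species[i]))
    }
  }
  # proteome budget: sum(mass * unit * v_dil) = mu * F (masses are g/mmol;
  # dilution fluxes carry each species' own unit)
  if (length(pc$protein_mass) > 0) {
    units <- vapply(names(pc$protein_mass),
                    function(sp) pc$species_unit[[sp]] %||% sc, numeric(1))
    bud <- setNames(unname(pc$protein_mass) * units,
                    vapply(names(pc$protein_mass), dil_of, character(1)))
    emit(tapply(bud, names(bud), sum), mu * pc$budget$total_modeled_fraction,
         "=", "budget")
  }
  # unmodeled protein pinned: v_dil = mu * mass / MW
  if (!is.null(pc$unmodeled)) {
    emit(setNames(1, pc$unmodeled$dil),
         mu * pc$unmodeled$mass_target / (pc$unmodeled$mw * sc), "=",
         "pin:unmodeled")
  }
  # biomass dilution pinned to growth rate
  emit(setNames(1, pc$biomass), mu, "=", "pin:biomass")
  # transporter concentration cap: v_dil(transporter) <= mu * cap
  if (!is.null(pc$glucose) && is.finite(cap) &&
      !is.null(pc$glucose$transporter_species)) {
    emit(setNames(1, dil_of(pc$glucose$transporter_species)), mu * cap / sc,
         "<=", "transporter_cap")
  }

  # flux bounds as rows
  for (j in which(is.finite(hi) & hi < 1000)) {
    emit(setNames(1, ids[j]), hi[j], "<=", paste0("ub:", ids[j]))
  }
  for (j in which(lo > 0)) emit(setNames(1, ids[j]), lo[j], ">=", paste0("lb:", ids[j]))

  A <- rbind(model$S, do.call(rbind, rows))
  b <- c(rep(0, nrow(model$S)), bvec)
  dirs <- c(rep("=", nrow(model$S)), dvec)
  rownames(A) <- c(paste0("bal:", rownames(model$S)), rnames)
  colnames(A) <- ids
  obj <- setNames(numeric(n), ids)
  obj[pc$dummy$translation] <- 1
  list(obj = obj, A = A, b = b, dir = dirs, vars = ids,
       n_balance = nrow(model$S), mu = mu, sigma = sigma)
}

#' Solve the proteome-coupled model at fixed growth rate
#'
#' @inheritParams assemble_pc_lp
#' @param S extracellular glucose concentration, mM (`Inf` = saturating);
#'   used to set the transporter saturation.
#' @param minimize_total after optimizing, minimize total flux at the fixed
#'   objective to obtain a parsimonious, reproducible flux distribution.
#' @return an object of class `pc_result`: `status`, `feasible`, `mu`, `S`,
#'   `sigma`, `fluxes`, `net` (source-reaction net fluxes),
#'   `concentrations` (catalyst and pool concentrations, mmol/gCDW),
#'   `inactive` (inactive-enzyme mass, g/gCDW), `exchange` (net exchange
#'   fluxes by compound), `trna_charging`, and `proteome` (mass
#'   accounting).
#' @export
solve_pc <- function(pc, mu, S = Inf, block = pc$block,
                     cap = pc$budget$transporter_cap, minimize_total = FALSE,
                     obj_tol = 1e-6) {
  sigma <- sigma_from_S(S, pc$glucose$KM)
  lp <- assemble_pc_lp(pc, mu, sigma, block = block, cap = cap)
  # direct optimization first; when the optimizer cannot finish (these
  # programs are heavily degenerate), fall back to maximizing the objective
  # by bisection over its level set with pure feasibility probes
  sol <- try(solve_lp(lp$obj, lp$A, lp$b, lp$dir, method = "simplex"),
             silent = TRUE)
  direct_ok <- !inherits(sol, "try-error") &&
    sol$status %in% c("optimal", "infeasible")
  if (direct_ok && sol$status == "infeasible") {
    return(structure(list(status = "infeasible", feasible = FALSE,
                          mu = mu, S = S, sigma = sigma), class = "pc_result"))
  }
  if (!direct_ok) {
    probe <- function(z) {
      A2 <- rbind(lp$A, obj = lp$obj)
      solve_lp(lp$obj, A2, c(lp$b, z), c(lp$dir, ">="), feasible_only = TRUE)
    }
    base <- solve_lp(lp$obj, lp$A, lp$b, lp$dir, feasible_only = TRUE)
    if (base$status == "iteration_limit") stop("LP solver failed on feasibility probe")
    if (base$status != "optimal") {
      return(structure(list(status = base$status, feasible = FALSE,
                            mu = mu, S = S, sigma = sigma), class = "pc_result"))
    }
    z_base <- sum(lp$obj * base$x)
    lo <- z_base; hi <- max(1, 2 * abs(z_base))
    while (probe(hi)$status == "optimal") {
      lo <- hi; hi <- hi * 4
      if (hi > 1e12) break
    }
    sol <- base
    while ((hi - lo) > obj_tol * max(1, abs(lo))) {
      mid <- (lo + hi) / 2
      pz <- probe(mid)
      if (pz$status == "optimal") { lo <- mid; sol <- pz } else hi <- mid
    }
  }
  sol$objective <- sum(lp$obj * sol$x)
  if (minimize_total) {
    # parsimonious polish: bisect the total flux downward at fixed objective
    A3 <- rbind(lp$A, obj = lp$obj, tot = rep(1, length(lp$obj)))
    tot0 <- sum(sol$x)
    lo2 <- 0; hi2 <- tot0; best <- sol
    probe2 <- function(w) {
      solve_lp(lp$obj, A3, c(lp$b, sol$objective * (1 - 1e-9), w),
               c(lp$dir, ">=", "<="), feasible_only = TRUE)
    }
    for (k in 1:30) {
      mid <- (lo2 + hi2) / 2
      pz <- probe2(mid)
      if (pz$status == "optimal") { hi2 <- mid; best <- pz } else lo2 <- mid
      if ((hi2 - lo2) < 1e-4 * max(1, tot0)) break
    }
    best$objective <- sum(lp$obj * best$x)
    sol <- best
  }
  sol$status <- "optimal"
  v <- setNames(sol$x, lp$vars)
  sc <- pc$config$macro_unit %||% 1e-6
  conc <- if (length(pc$dil) == 0) numeric() else
    vapply(names(pc$dil), function(sp) {
      un <- pc$species_unit[[sp]] %||% sc
      un * v[[pc$dil[[sp]]]] / mu
    }, numeric(1))
  rxn_tab <- pc$model$rxns
  ex_ids <- rxn_tab$source_id[rxn_tab$kind == "exchange"]
  net <- net_fluxes(pc$model, v)
  exch <- net[unique(ex_ids)]
  names(exch) <- sub("^EX_", "", names(exch))
  charge_ids <- grep("^CHARGE_", lp$vars, value = TRUE)
  charging <- v[charge_ids]  # mmol amino acid charged per gCDW per h
  res <- structure(list(
    status = sol$status, feasible = TRUE, mu = mu, S = S, sigma = sigma,
    objective = sol$objective, fluxes = v, net = net,
    concentrations = conc, exchange = exch,
    trna_charging = setNames(charging, sub("^CHARGE_", "", charge_ids))
  ), class = "pc_result")
  res$inactive <- inactive_enzyme(res, pc)
  res$proteome <- proteome_accounting(res, pc)
  res
}

#' @export
print.pc_result <- function(x, ...) {
  if (!x$feasible) {
    cat(sprintf("pc_result: infeasible at mu = %.4g (status %s)\n",
                x$mu, x$status))
    return(invisible(x))
  }
  cat(sprintf("pc_result: mu = %.4g/h, S = %.4g mM, sigma = %.3f\n",
              x$mu, x$S, x$sigma))
  cat(sprintf("  glucose uptake %.4g, inactive enzyme %.4g g/gCDW\n",
              -x$exchange[["glc__D_e"]], x$inactive))
  invisible(x)
}

#' Feasibility of a growth rate at a glucose concentration
#'
#' @inheritParams solve_pc
#' @param probe test feasibility only (phase-1 solve; fast and numerically
#'   robust) and return `result = NULL`; with `probe = FALSE` the LP is
#'   optimized and the full simulation result returned.
#' @return list with `feasible` (logical) and the solved `result`.
#' @export
pc_feasible <- function(pc, mu, S = Inf, block = pc$block,
                        cap = pc$budget$transporter_cap, probe = FALSE) {
  if (probe) {
    # numerical failures on these LPs are pointwise: a minute shift of the
    # growth rate almost always yields a clean verdict, and feasibility is
    # monotone on a far coarser scale than the shift
    for (eps in c(0, 1e-3, -1e-3, 3e-3, -3e-3)) {
      mu_try <- mu * (1 + eps)
      sigma <- sigma_from_S(S, pc$glucose$KM)
      lp <- assemble_pc_lp(pc, mu_try, sigma, block = block, cap = cap)
      sol <- try(solve_lp(lp$obj, lp$A, lp$b, lp$dir, feasible_only = TRUE),
                 silent = TRUE)
      if (!inherits(sol, "try-error") &&
          sol$status %in% c("optimal", "infeasible")) {
        return(list(feasible = sol$status == "optimal", result = NULL))
      }
    }
    stop("solver failure (not infeasibility) at mu = ", mu)
  }
  res <- solve_pc(pc, mu, S, block = block, cap = cap)
  if (!res$feasible && !res$status %in% c("infeasible")) {
    stop("solver failure (not infeasibility): status ", res$status)
  }
  list(feasible = res$feasible, result = res)
}

#' Minimal glucose concentration sustaining a growth rate
#'
#' Binary search over the extracellular glucose concentration (equivalently
#' over transporter saturation) for the lowest concentration at which the
#' proteome-coupled LP remains feasible at growth rate `mu` — the
#' chemostat's residual-substrate relation.
#'
#' @inheritParams solve_pc
#' @param tol relative tolerance on the concentration bracket.
#' @param S_max upper end of the search bracket, mM.
#' @return list with `S_min` (mM), `sigma`, and the `result` at `S_min`.
#' @export
min_glucose_concentration <- function(pc, mu, tol = 1e-6, S_max = 1000,
                                      block = pc$block,
                                      cap = pc$budget$transporter_cap) {
  stopifnot(tol > 0)
  hi_ok <- pc_feasible(pc, mu, S_max, block = block, cap = cap, probe = TRUE)
  if (!hi_ok$feasible) {
    stop(sprintf("growth rate unreachable: infeasible even at S = %g mM", S_max))
  }
  lo <- 0; hi <- S_max
  while ((hi - lo) > tol * max(hi, 1e-12)) {
    mid <- (lo + hi) / 2
    if (pc_feasible(pc, mu, mid, block = block, cap = cap, probe = TRUE)$feasible) {
      hi <- mid
    } else {
      lo <- mid
    }
  }
  # solve for the reported fluxes a whisker inside the feasible region
  final <- NULL
  for (fac in c(1, 1 + 10 * tol, 1 + 100 * tol, 1.01, 1.05)) {
    final <- try(solve_pc(pc, mu, hi * fac, block = block, cap = cap,
                          minimize_total = TRUE), silent = TRUE)
    if (!inherits(final, "try-error") && final$feasible) break
  }
  if (inherits(final, "try-error") || !final$feasible) {
    final <- NULL
    warning("flux solve failed at S_min; returning the concentration only")
  }
  list(S_min = hi, sigma = sigma_from_S(hi, pc$glucose$KM), result = final)
}

#' Maximal growth rate at a glucose concentration
#'
#' Doubles an initial growth-rate guess until infeasible, then bisects to
#' relative tolerance.
#'
#' @inheritParams solve_pc
#' @param tol relative tolerance on the growth-rate bracket.
#' @param mu_init starting guess, 1/h.
#' @param growth_factor bracket expansion factor; use a value close to 1
#'   when `mu_init` is already known to be near the answer.
#' @return list with `mu_max` and the `result` at `mu_max`.
#' @export
max_growth_rate <- function(pc, S = Inf, tol = 1e-4, mu_init = 0.1,
                            block = pc$block,
                            cap = pc$budget$transporter_cap,
                            growth_factor = 2) {
  stopifnot(tol > 0, mu_init > 0, growth_factor > 1)
  lo <- 0; hi <- mu_init
  while (pc_feasible(pc, hi, S, block = block, cap = cap, probe = TRUE)$feasible) {
    lo <- hi; hi <- hi * growth_factor
    if (hi > 32) stop("growth rate appears unbounded")
  }
  if (lo == 0) {
    # mu_init already infeasible: shrink to find a feasible floor
    while (!pc_feasible(pc, hi, S, block = block, cap = cap, probe = TRUE)$feasible) {
      hi <- hi / 2
      if (hi < 1e-4) stop("model infeasible at any growth rate down to 1e-4/h")
    }
    lo <- hi; hi <- hi * 2
  }
  while ((hi - lo) > tol * max(lo, 1e-12)) {
    mid <- (lo + hi) / 2
    if (pc_feasible(pc, mid, S, block = block, cap = cap, probe = TRUE)$feasible) {
      lo <- mid
    } else {
      hi <- mid
    }
  }
  final <- NULL
  for (fac in c(1, 1 - 10 * tol, 1 - 100 * tol, 0.99, 0.95)) {
    final <- try(solve_pc(pc, lo * fac, S, block = block, cap = cap,
                          minimize_total = TRUE), silent = TRUE)
    if (!inherits(final, "try-error") && final$feasible) break
  }
  if (inherits(final, "try-error") || !final$feasible) {
    final <- NULL
    warning("flux solve failed at mu_max; returning the rate only")
  }
  list(mu_max = lo, result = final)
}

#' Inactive enzyme mass of a solution
#'
#' The inactive enzyme is the summed inactive fraction of all undersaturated
#' catalysts: for every catalyst, its mass times the difference between its
#' concentration and the concentration its fluxes actually require, plus
#' the mass of free (uncomplexed) protein pools. Zero exactly when the
#' total-modeled-proteome constraint is limiting.
#'
#' @param result a `pc_result`.
#' @param pc the `pc_model` it was solved on.
#' @return g/gCDW.
#' @export
inactive_enzyme <- function(result, pc) {
  stopifnot(result$feasible)
  if (is.null(pc$coupling) || nrow(pc$coupling) == 0 ||
      length(pc$protein_mass) == 0) return(0)
  v <- result$fluxes
  conc <- result$concentrations
  sc <- pc$config$macro_unit %||% 1e-6
  cp <- pc$coupling
  if (is.null(cp) || nrow(cp) == 0) cp <- NULL
  if (!is.null(cp)) cp$rate <- vapply(seq_len(nrow(cp)), function(i) {
    if (cp$type[i] == "enzyme") {
      e <- pc$enzymes[[cp$ref[i]]]
      kc <- enzyme_kcat(e, cp$rxn[i],
                        pc$model$rxns$source_id[match(cp$rxn[i], pc$model$rxns$id)])
      if (cp$rxn[i] %in% pc$glucose$pts_rxns) kc * result$sigma else kc
    } else {
      pc$machineries[[cp$ref[i]]]$rate
    }
  }, numeric(1))
  required <- setNames(numeric(length(pc$protein_mass)), names(pc$protein_mass))
  for (i in seq_len(nrow(cp))) {
    sp <- cp$species[i]
    if (!sp %in% names(required)) next
    # concentrations are reported in mmol/gCDW; machinery-coupled fluxes
    # carry the unit of their species, enzyme-coupled fluxes are mmol/h
    un <- pc$species_unit[[sp]] %||% sc
    need <- if (cp$type[i] == "machinery") {
      un * cp$weight[i] * v[[cp$rxn[i]]] / cp$rate[i]
    } else {
      cp$weight[i] * v[[cp$rxn[i]]] / cp$rate[i]
    }
    if (cp$type[i] == "machinery") {
      required[sp] <- required[sp] + need          # capacity is shared
    } else {
      required[sp] <- max(required[sp], need)      # per-reaction coupling
    }
  }
  surplus <- pmax(conc[names(pc$protein_mass)] - required, 0)
  sum(pc$protein_mass * surplus)
}

# Mass accounting of the proteome at a solution.
proteome_accounting <- function(result, pc) {
  if (length(pc$protein_mass) == 0 || is.null(pc$unmodeled)) {
    return(list(modeled = 0, unmodeled = 0,
                budget = pc$budget$total_modeled_fraction %||% NA_real_,
                inactive = result$inactive, closure = NA_real_))
  }
  conc <- result$concentrations
  modeled <- sum(pc$protein_mass * conc[names(pc$protein_mass)])
  unmod <- pc$unmodeled$mw * conc[[pc$unmodeled$species]]
  list(modeled = modeled, unmodeled = unmod,
       budget = pc$budget$total_modeled_fraction,
       inactive = result$inactive,
       closure = modeled - pc$budget$total_modeled_fraction)
}

#' Calibrate the glucose-transporter concentration cap
#'
#' Reproduces the documented calibration: with the cap released, find the
#' maximal growth rate at saturating glucose, then minimize the transporter
#' concentration that still supports it; that minimum becomes the cap.
#'
#' @param pc a `pc_model`.
#' @param tol growth-rate bisection tolerance.
#' @return the model with `budget$transporter_cap` set; the value is also
#'   attached as attribute `"calibration"` together with `mu_max`.
#' @export
calibrate_transporter_cap <- function(pc, tol = 1e-4) {
  mm <- max_growth_rate(pc, S = Inf, tol = tol, cap = Inf)
  lp <- assemble_pc_lp(pc, mm$mu_max, sigma = 1, cap = Inf)
  obj <- setNames(numeric(length(lp$vars)), lp$vars)
  obj[pc$dil[[pc$glucose$transporter_species]]] <- 1
  sol <- solve_lp(obj, lp$A, lp$b, lp$dir, maximize = FALSE)
  if (sol$status != "optimal") stop("cap calibration LP failed: ", sol$status)
  sc <- pc$config$macro_unit %||% 1e-6
  cap <- sc * sol$objective / mm$mu_max
  pc$budget$transporter_cap <- cap
  attr(pc, "calibration") <- list(mu_max = mm$mu_max, cap = cap)
  pc
}

#' Minimal glucose uptake sustaining a growth rate
#'
#' At fixed growth rate, minimizes the glucose uptake flux subject to all
#' stoichiometric and coupling constraints (the transporter bound itself is
#' released). The optimum is the glucose requirement of the growth rate;
#' the row duals quantify how that requirement responds to the amino-acid
#' uptake bounds, which is the LP-duality route to the scaled reduced
#' costs.
#'
#' @inheritParams solve_pc
#' @return list with `q_glc` (mmol/gCDW/h), `duals` (named by constraint
#'   label; amino-acid bound rows are `ub:EX_<met>_rev`), and `status`.
#' @export
min_glucose_uptake <- function(pc, mu, S = Inf, block = pc$block) {
  sigma <- sigma_from_S(S, pc$glucose$KM)
  lp <- assemble_pc_lp(pc, mu, sigma, block = block, cap = Inf)
  obj <- setNames(numeric(length(lp$vars)), lp$vars)
  obj[pc$glucose$uptake_rxn] <- 1
  sol <- solve_lp(obj, lp$A, lp$b, lp$dir, maximize = FALSE, method = "simplex")
  if (sol$status != "optimal") {
    sol2 <- solve_lp(obj, lp$A, lp$b, lp$dir, maximize = FALSE, method = "ipm")
    if (sol2$status == "optimal") sol <- sol2
  }
  if (sol$status != "optimal") stop("glucose-requirement LP failed: ", sol$status)
  list(q_glc = sol$objective, duals = sol$duals, status = sol$status)
}
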
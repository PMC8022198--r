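# The three-pathway ATP allocation model: parameter estimation from the
# metabolic layer (ATP yield, protein cost and protein efficiency of
# glycolysis + mixed-acid fermentation, glycolysis + lactate, and arginine
# catabolism), the proteome-capped ATP-maximization LP, its analytic
# solution, phase scanning and sensitivities.

#' Prepare the metabolic layer for flux analysis
#'
#' Splits reversible reactions and isozymes, assigns the dummy protein to
#' catalyst-less reactions, and builds the dummy enzyme (average
#' amino-acid composition, turnover equal to the median enzyme turnover).
#'
#' @param toy a toy-network bundle from [make_toy_network()].
#' @return list with the prepared `model`, `enzymes` (including `dummy`),
#'   `proteins` (including `dummy_protein`) and the originating bundle.
#' @export
metabolic_layer <- function(toy) {
  model <- assign_dummy(split_isozymes(split_reversible(toy$model)))
  all_kcat <- unlist(lapply(toy$enzymes, `[[`, "kcat"))
  dummy_kcat <- median(all_kcat)
  dummy_rxns <- unique(model$rxns$source_id[
    !is.na(model$rxns$catalyst_id) & model$rxns$catalyst_id == "dummy"])
  enzymes <- c(toy$enzymes, list(
    dummy = enzyme_spec("dummy", c(dummy_protein = 1),
                        setNames(rep(dummy_kcat, length(dummy_rxns)), dummy_rxns))))
  list(model = model, enzymes = enzymes, proteins = toy$proteins, toy = toy)
}

# Protein cost (g h / mmol) of every catalysed reaction in a prepared layer.
reaction_costs <- function(layer) {
  rx <- layer$model$rxns
  vapply(seq_len(nrow(rx)), function(i) {
    cid <- rx$catalyst_id[i]
    if (is.na(cid)) return(0)
    e <- layer$enzymes[[cid]]
    kc <- enzyme_kcat(e, rx$id[i], rx$source_id[i])
    if (is.na(kc)) stop("no k_cat for ", rx$id[i], " (catalyst ", cid, ")")
    enzyme_mass(e, layer$proteins) / kc
  }, numeric(1))
}

#' ATP yield and protein cost of the three fermentation pathways
#'
#' Solves three flux-balance LPs on the metabolic layer: (1) maximize the
#' ATP maintenance flux at a fixed glucose uptake of 1 mmol/gCDW/h
#' (mixed-acid fermentation); (2) maximize lactate production at glucose
#' uptake 1 and maintenance fixed at 2 (lactate fermentation); (3) maximize
#' maintenance at a fixed arginine uptake of 1 (arginine catabolism). From
#' each flux distribution the ATP yield `Y` (maintenance flux per unit
#' substrate), protein cost `p` (sum over reactions of protein cost times
#' flux) and protein efficiency `e = Y/p` are computed.
#'
#' @param toy toy bundle from [make_toy_network()], or a prepared layer
#'   from [metabolic_layer()].
#' @param proteome_cap proteome mass allocated to the small model, g/gCDW.
#' @param alpha,beta arginine-uptake coupling: `J3 <= alpha * Jglc + beta`.
#' @return a `small_model_params` list: vectors `Y`, `p`, `e` (pathways
#'   1 = mixed acid, 2 = lactate, 3 = arginine), `P`, `alpha`, `beta`, and
#'   the three flux distributions in `fluxes`.
#' @export
estimate_pathway_params <- function(toy, proteome_cap = 0.08,
                                    alpha = 0.15, beta = 0) {
  layer <- if (!is.null(toy$model) && inherits(toy$model, "sm_model") &&
               !is.null(toy$enzymes) && "dummy" %in% names(toy$enzymes)) {
    toy
  } else {
    metabolic_layer(toy)
  }
  model <- layer$model
  blocked <- layer$toy$block
  closed <- closed_uptakes(model)
  glc_up <- uptake_rxn(model, "glc__D_e")
  arg_up <- uptake_rxn(model, "arg__L_e")
  atpm_free <- setNames(0, "ATPM")  # maintenance lower bound released

  run <- function(objective, fixed, label, maximize = TRUE) {
    sol <- fba(model, objective, maximize = maximize, fixed = fixed,
               ub = closed, lb = atpm_free, blocked = blocked,
               minimize_total = TRUE)
    if (sol$status != "optimal") {
      stop("pathway LP infeasible: ", label, " (status ", sol$status, ")")
    }
    sol
  }

  sol1 <- run("ATPM", setNames(c(1, 0), c(glc_up, arg_up)), "mixed acid")
  sol2 <- run("EX_lac__L_e",
              setNames(c(1, 0, 2), c(glc_up, arg_up, "ATPM")), "lactate")
  sol3 <- run("ATPM", setNames(c(0, 1), c(glc_up, arg_up)), "arginine")

  costs <- reaction_costs(layer)
  pcost <- function(sol) sum(costs * sol$fluxes)
  Y <- c(sol1$fluxes[["ATPM"]], sol2$fluxes[["ATPM"]], sol3$fluxes[["ATPM"]])
  p <- c(pcost(sol1), pcost(sol2), pcost(sol3))
  structure(list(Y = Y, p = p, e = Y / p, P = proteome_cap,
                 alpha = alpha, beta = beta,
                 fluxes = list(mixed_acid = sol1$net, lactate = sol2$net,
                               arginine = sol3$net)),
            class = "small_model_params")
}

#' @export
print.small_model_params <- function(x, ...) {
  cat("Three-pathway parameters (1 mixed acid, 2 lactate, 3 arginine):\n")
  print(data.frame(pathway = 1:3, Y_ATP = x$Y, protein_cost = x$p,
                   efficiency = x$e))
  cat(sprintf("proteome cap P = %g g/gCDW; J3 <= %g*Jglc + %g\n",
              x$P, x$alpha, x$beta))
  invisible(x)
}

#' Construct small-model parameters directly
#'
#' @param Y ATP yields per substrate for pathways 1 (glycolysis + mixed
#'   acid), 2 (glycolysis + lactate), 3 (arginine catabolism).
#' @param p protein costs, g h/mmol (per unit substrate flux).
#' @param P proteome allocation, g/gCDW.
#' @param alpha,beta arginine-bound coupling `J3 <= alpha*Jglc + beta`.
#' @export
small_model_params <- function(Y, p, P, alpha = 0.15, beta = 0) {
  stopifnot(length(Y) == 3, length(p) == 3, all(Y > 0), all(p > 0), P > 0,
            alpha >= 0, beta >= 0)
  structure(list(Y = Y, p = p, e = Y / p, P = P, alpha = alpha, beta = beta),
            class = "small_model_params")
}

#' Solve the three-pathway ATP allocation LP
#'
#' Maximizes total ATP production `J_ATP = sum(Y_i J_i)` subject to
#' `J1 + J2 = Jglc` (all glucose is routed), the proteome allocation
#' `p1 J1 + p2 J2 + p3 J3 <= P`, and the arginine bound
#' `0 <= J3 <= alpha*Jglc + beta`.
#'
#' @param params a `small_model_params`.
#' @param Jglc total glucose uptake flux, mmol/gCDW/h.
#' @return list with `J` (fluxes J1, J2, J3), `J_ATP`, `inactive`
#'   (unused proteome mass, g/gCDW), and the LP `duals` for the three
#'   constraints.
#' @export
solve_small_model <- function(params, Jglc) {
  stopifnot(inherits(params, "small_model_params"), Jglc >= 0)
  U3 <- params$alpha * Jglc + params$beta
  A <- rbind(glucose = c(1, 1, 0), proteome = params$p, arginine = c(0, 0, 1))
  sol <- solve_lp(params$Y, A, c(Jglc, params$P, U3), c("=", "<=", "<="),
                  method = "simplex")
  if (sol$status != "optimal") {
    stop(sprintf(paste0("small model infeasible at Jglc = %g ",
                        "(maximum sustainable Jglc = %g)"),
                 Jglc, params$P / min(params$p[1:2])))
  }
  J <- setNames(sol$x, c("J1", "J2", "J3"))
  list(J = J, J_ATP = sol$objective,
       inactive = params$P - sum(params$p * J), duals = sol$duals)
}

#' Analytic solution of the three-pathway LP
#'
#' Independent closed-form route: with `J2 = Jglc - J1` eliminated, the
#' feasible set is a polygon in `(J1, J3)`; the optimum lies on a vertex,
#' and all pairwise intersections of the five bounding lines are
#' enumerated and compared exactly. Ties are broken toward higher `J3`,
#' then toward lactate (lower `J1`), so that scans are reproducible when
#' pathway efficiencies coincide.
#'
#' @inheritParams solve_small_model
#' @return as [solve_small_model()] (without duals).
#' @export
solve_small_model_analytic <- function(params, Jglc) {
  stopifnot(inherits(params, "small_model_params"), Jglc >= 0)
  Y <- params$Y; p <- params$p; P <- params$P
  U3 <- params$alpha * Jglc + params$beta
  if (min(p[1], p[2]) * Jglc > P + 1e-12) {
    stop(sprintf(paste0("small model infeasible at Jglc = %g ",
                        "(maximum sustainable Jglc = %g)"),
                 Jglc, P / min(p[1], p[2])))
  }
  # bounding lines in (x = J1, y = J3):
  #  1: x = 0; 2: x = Jglc; 3: y = 0; 4: y = U3; 5: (p1-p2) x + p3 y = P - p2*Jglc
  cands <- list()
  add <- function(x, y) cands[[length(cands) + 1]] <<- c(x, y)
  r <- P - p[2] * Jglc
  dpx <- p[1] - p[2]
  for (x in c(0, Jglc)) {
    for (y in c(0, U3)) add(x, y)
    if (p[3] > 0) add(x, (r - dpx * x) / p[3])        # lines 1/2 with 5
  }
  if (abs(dpx) > 0) {
    add((r - p[3] * 0) / dpx, 0)                       # line 3 with 5
    add((r - p[3] * U3) / dpx, U3)                     # line 4 with 5
  }
  feas <- function(v) {
    v[1] >= -1e-12 && v[1] <= Jglc + 1e-12 && v[2] >= -1e-12 &&
      v[2] <= U3 + 1e-12 && dpx * v[1] + p[3] * v[2] <= r + 1e-9 * max(1, P)
  }
  best <- NULL; best_key <- c(-Inf, -Inf, Inf)
  for (v in cands) {
    if (!feas(v)) next
    f <- Y[1] * v[1] + Y[2] * (Jglc - v[1]) + Y[3] * v[2]
    key <- c(f, v[2], -v[1])
    if (is.null(best) || key[1] > best_key[1] + 1e-12 ||
        (abs(key[1] - best_key[1]) <= 1e-12 &&
         (key[2] > best_key[2] + 1e-12 ||
          (abs(key[2] - best_key[2]) <= 1e-12 && key[3] > best_key[3] + 1e-12)))) {
      best <- v; best_key <- key
    }
  }
  J <- c(J1 = max(best[1], 0), J2 = max(Jglc - best[1], 0), J3 = max(best[2], 0))
  list(J = J, J_ATP = sum(params$Y * J), inactive = params$P - sum(params$p * J))
}

#' Scan glucose uptake and label the metabolic phases
#'
#' Solves the small model over an increasing grid of glucose uptake fluxes
#' and labels each point A, B or C from the finite-difference slopes of the
#' pathway fluxes: A while pathways 1 and 3 both rise (proteome not yet
#' limiting), B once arginine catabolism (J3) declines, and C once
#' mixed-acid fermentation (J1) declines in favour of lactate (J2).
#'
#' @param params a `small_model_params`.
#' @param Jglc_grid increasing numeric grid of glucose uptake fluxes.
#' @param slope_tol slopes below `slope_tol * max(|J|)` are treated as flat.
#' @return data.frame with Jglc, J1, J2, J3, J_ATP, inactive and `phase`;
#'   the phase sequence is checked to be contiguous blocks in order.
#' @export
phase_scan <- function(params, Jglc_grid, slope_tol = 1e-9) {
  if (is.unsorted(Jglc_grid, strictly = TRUE)) {
    stop("Jglc_grid must be strictly increasing")
  }
  sols <- lapply(Jglc_grid, function(g) solve_small_model(params, g))
  J <- t(vapply(sols, function(s) s$J, numeric(3)))
  out <- data.frame(
    Jglc = Jglc_grid, J1 = J[, 1], J2 = J[, 2], J3 = J[, 3],
    J_ATP = vapply(sols, `[[`, numeric(1), "J_ATP"),
    inactive = vapply(sols, `[[`, numeric(1), "inactive"))
  n <- nrow(out)
  tol <- slope_tol * max(abs(J), 1)
  # backward differences: a point is labeled by the change that produced it,
  # so the first point of phase B is the first point at which the proteome
  # is exhausted
  d1 <- diff(out$J1); d3 <- diff(out$J3)
  lab <- ifelse(d1 < -tol, "C", ifelse(d3 < -tol, "B", "A"))
  out$phase <- c(lab[1], lab)
  runs <- rle(out$phase)
  if (is.unsorted(match(runs$values, c("A", "B", "C"))) ||
      anyDuplicated(runs$values)) {
    warning("phase labels are not contiguous A->B->C blocks: ",
            paste(runs$values, collapse = ","))
  }
  out
}

#' Sensitivity of ATP production to the small-model constraints
#'
#' Scaled finite-difference sensitivity `S = (dJ_ATP/dc) * (c / J_ATP)` for
#' the glucose uptake, the proteome allocation, or the arginine-uptake
#' bound. The perturbation is relative by default (`c -> c (1 + dc)`);
#' absolute perturbations (`c -> c + dc`) are available for comparison.
#'
#' @param params a `small_model_params`.
#' @param Jglc glucose uptake flux of the reference point.
#' @param constraint `"glucose"`, `"proteome"` or `"arginine"`.
#' @param dc perturbation size (default 0.01).
#' @param relative interpret `dc` relative to the constraint value.
#' @return scaled sensitivity score (dimensionless).
#' @export
small_model_sensitivity <- function(params, Jglc,
                                    constraint = c("glucose", "proteome", "arginine"),
                                    dc = 0.01, relative = TRUE) {
  constraint <- match.arg(constraint)
  # the three constraint values are perturbed independently: the arginine
  # bound is frozen at its base value so a glucose perturbation does not
  # drag it along through the linear coupling
  U3 <- params$alpha * Jglc + params$beta
  fixed <- params
  fixed$alpha <- 0
  fixed$beta <- U3
  base <- solve_small_model(fixed, Jglc)
  c0 <- switch(constraint, glucose = Jglc, proteome = params$P, arginine = U3)
  delta <- if (relative) dc * c0 else dc
  if (delta == 0) return(0)
  pert <- fixed
  q1 <- switch(constraint,
    glucose = solve_small_model(fixed, Jglc + delta)$J_ATP,
    proteome = { pert$P <- fixed$P + delta; solve_small_model(pert, Jglc)$J_ATP },
    arginine = { pert$beta <- fixed$beta + delta; solve_small_model(pert, Jglc)$J_ATP })
  ((q1 - base$J_ATP) / delta) * (c0 / base$J_ATP)
}

#' Twofold robustness scan of the small model
#'
#' Varies each parameter (p1, p2, p3, P, alpha, and beta when nonzero) by a
#' factor up and down and re-runs the phase scan, checking that the decline
#' of arginine catabolism still begins only once the proteome allocation is
#' exhausted (inactive proteome zero).
#'
#' @param params a `small_model_params`.
#' @param Jglc_grid glucose-uptake grid for the scans.
#' @param factor fold change applied to each parameter (default 2).
#' @return data.frame: parameter, direction, arg_declines,
#'   decline_in_limited_regime (logical; `NA` when J3 never declines on the
#'   grid).
#' @export
small_model_robustness <- function(params, Jglc_grid = seq(0.5, 30, length.out = 120),
                                   factor = 2) {
  pars <- c("p1", "p2", "p3", "P", "alpha", if (params$beta > 0) "beta")
  out <- list()
  for (par in pars) {
    for (f in c(factor, 1 / factor)) {
      pp <- params
      if (par %in% c("p1", "p2", "p3")) {
        i <- as.integer(substring(par, 2))
        pp$p[i] <- pp$p[i] * f
        pp$e <- pp$Y / pp$p
      } else {
        pp[[par]] <- pp[[par]] * f
      }
      sc <- tryCatch(
        suppressWarnings(phase_scan(pp, Jglc_grid)),
        error = function(e) NULL)
      if (is.null(sc)) {
        out[[length(out) + 1]] <- data.frame(
          parameter = par, direction = ifelse(f > 1, "x2", "x0.5"),
          arg_declines = NA, decline_in_limited_regime = NA)
        next
      }
      d3 <- diff(sc$J3)
      tol <- 1e-9 * max(abs(sc$J3), 1)
      first_decline <- which(d3 < -tol)[1]
      declines <- !is.na(first_decline)
      in_limited <- if (declines) {
        # the decline happens between grid points i and i+1; the proteome
        # must be exhausted at its endpoint
        sc$inactive[first_decline + 1] <= 1e-6 * max(params$P, 1)
      } else NA
      out[[length(out) + 1]] <- data.frame(
        parameter = par, direction = ifelse(f > 1, "x2", "x0.5"),
        arg_declines = declines, decline_in_limited_regime = in_limited)
    }
  }
  do.call(rbind, out)
}

#' ATP yield of the arginine catabolism pathway
#'
#' Maximizes the ATP maintenance flux at a fixed arginine uptake of
#' 1 mmol/gCDW/h (glucose closed). With the default ATP synthase
#' stoichiometry of 3 protons per ATP, the yield is 1.67: 1 ATP from
#' carbamate kinase plus 2/3 ATP from the two cytosolic protons the pathway
#' consumes net, which the cell would otherwise have to export.
#'
#' @param toy toy bundle or prepared [metabolic_layer()].
#' @param decouple_protons relax the cytosolic proton balance (and close
#'   the ATP synthase, whose only role is proton translocation); the yield
#'   then collapses to the substrate-level phosphorylation of carbamate
#'   kinase alone (1.0).
#' @return mol ATP per mol arginine.
#' @export
arginine_atp_yield <- function(toy, decouple_protons = FALSE) {
  layer <- if (!is.null(toy$enzymes) && "dummy" %in% names(toy$enzymes)) toy
           else metabolic_layer(toy)
  model <- layer$model
  blocked <- layer$toy$block
  if (decouple_protons) blocked <- c(blocked, "ATPS")
  sol <- fba(model, "ATPM",
             fixed = setNames(c(0, 1), c(uptake_rxn(model, "glc__D_e"),
                                         uptake_rxn(model, "arg__L_e"))),
             ub = closed_uptakes(model), lb = setNames(0, "ATPM"),
             blocked = blocked,
             drop_balance = if (decouple_protons) "h_c",
             minimize_total = TRUE)
  if (sol$status != "optimal") stop("arginine pathway LP not optimal: ", sol$status)
  sol$objective
}
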
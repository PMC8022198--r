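# Sensitivity machinery on the proteome-coupled model: scaled reduced costs
# of amino-acid uptake bounds, sensitivity scores of the two structural
# constraints, and the twofold one-at-a-time parameter robustness scan.

# Resolve a condition: rich medium (saturating glucose) or glucose-limited
# at a fixed residual concentration.
condition_S <- function(condition) {
  if (!is.null(condition$S)) condition$S else Inf
}

#' Scaled reduced cost of an amino-acid uptake bound
#'
#' Raises the uptake bound of one amino acid by a small amount and measures
#' the growth-rate response at the condition's glucose setting:
#' `R = (dmu/dq) * (q/mu)`. A positive value flags the bound as an active
#' growth constraint; zero means the bound has slack.
#'
#' @param pc a `pc_model`.
#' @param condition list with `mu` (base growth rate) and optionally `S`
#'   (residual glucose, mM; default saturating). The base growth rate is
#'   re-derived as the maximal rate at that glucose setting so that the
#'   finite difference is taken on the feasibility frontier.
#' @param aa amino-acid name (row of `pc$aa_uptake`).
#' @param dq absolute bound increase, mmol/gCDW/h (default 0.01).
#' @param tol growth-rate bisection tolerance.
#' @return list with `R`, `mu_base`, `mu_pert`, `q` (bound value) and `aa`.
#' @export
scaled_reduced_cost <- function(pc, condition, aa, dq = 0.01, tol = 1e-4) {
  i <- match(aa, pc$aa_uptake$aa)
  if (is.na(i)) stop("unknown amino acid: ", aa)
  S <- condition_S(condition)
  # the condition's growth rate sits on (or near) the feasibility frontier,
  # so the brackets can expand gently
  base <- max_growth_rate(pc, S = S, tol = tol, mu_init = condition$mu,
                          growth_factor = 1.15)
  q <- max(0, pc$aa_uptake$slope[i] * base$mu_max + pc$aa_uptake$intercept[i])
  pc2 <- pc
  pc2$aa_uptake$intercept[i] <- pc2$aa_uptake$intercept[i] + dq
  pert <- max_growth_rate(pc2, S = S, tol = tol, mu_init = base$mu_max,
                          growth_factor = 1.15)
  dmu <- pert$mu_max - base$mu_max
  R <- if (q > 0) (dmu / dq) * (q / base$mu_max) else dmu / dq
  list(aa = aa, R = max(R, 0), mu_base = base$mu_max, mu_pert = pert$mu_max,
       q = q, unscaled = q <= 0)
}

#' Sensitivity score of a structural constraint
#'
#' Relaxes the glucose-transporter concentration cap or the total modeled
#' proteome by a small relative amount and measures the growth response:
#' `S = (dmu/dc) * (c/mu)`. Zero whenever the constraint has slack
#' (for the proteome: whenever inactive enzyme is positive).
#'
#' @inheritParams scaled_reduced_cost
#' @param constraint `"transporter_cap"` or `"proteome"`.
#' @param dc relative constraint increase (default 0.01 = 1%).
#' @return list with `score`, `mu_base`, `mu_pert`, `constraint`.
#' @export
sensitivity_score <- function(pc, condition,
                              constraint = c("transporter_cap", "proteome"),
                              dc = 0.01, tol = 1e-4) {
  constraint <- match.arg(constraint)
  S <- condition_S(condition)
  base <- max_growth_rate(pc, S = S, tol = tol, mu_init = condition$mu,
                          growth_factor = 1.15)
  pc2 <- pc
  if (constraint == "transporter_cap") {
    pc2$budget$transporter_cap <- pc$budget$transporter_cap * (1 + dc)
  } else {
    pc2$budget$total_modeled_fraction <-
      pc$budget$total_modeled_fraction * (1 + dc)
  }
  pert <- max_growth_rate(pc2, S = S, tol = tol, mu_init = base$mu_max)
  dmu <- pert$mu_max - base$mu_max
  # (dmu / (dc*c)) * (c/mu) = dmu / (dc * mu)
  list(constraint = constraint, score = max(dmu / (dc * base$mu_max), 0),
       mu_base = base$mu_max, mu_pert = pert$mu_max)
}

# Enumerate the scannable parameters of a pc model.
pc_parameters <- function(pc) {
  out <- list()
  for (e in names(pc$enzymes)) {
    for (rid in names(pc$enzymes[[e]]$kcat)) {
      out[[length(out) + 1]] <- data.frame(type = "kcat", id = e, key = rid,
                                           stringsAsFactors = FALSE)
    }
  }
  for (p in names(pc$proteins)) {
    if (pc$proteins[[p]]$k_deg > 0) {
      out[[length(out) + 1]] <- data.frame(type = "kdeg", id = p, key = "",
                                           stringsAsFactors = FALSE)
    }
  }
  for (m in names(pc$machineries)) {
    out[[length(out) + 1]] <- data.frame(type = "machinery_rate", id = m,
                                         key = "", stringsAsFactors = FALSE)
  }
  out[[length(out) + 1]] <- data.frame(type = "budget",
                                       id = "total_modeled_fraction", key = "",
                                       stringsAsFactors = FALSE)
  out[[length(out) + 1]] <- data.frame(type = "budget", id = "transporter_cap",
                                       key = "", stringsAsFactors = FALSE)
  do.call(rbind, out)
}

#' Set a single model parameter
#'
#' @param pc a `pc_model`.
#' @param type `"kcat"`, `"kdeg"`, `"machinery_rate"` or `"budget"`.
#' @param id enzyme / protein / machinery id, or the budget field name.
#' @param value new value.
#' @param key for `kcat`: the reaction id within the enzyme's map.
#' @export
pc_set_param <- function(pc, type, id, value, key = "") {
  switch(type,
    kcat = {
      pc$enzymes[[id]]$kcat[[key]] <- value
      if (!is.null(pc$glucose) && id == sub("^enzyme_", "", pc$glucose$transporter_species) &&
          key %in% c(pc$glucose$pts_rxns, "GLCpts")) {
        pc$glucose$kcat <- value
      }
    },
    kdeg = {
      pc$proteins[[id]]$k_deg <- value
      hit <- !is.null(pc$deg) & pc$deg$species == paste0("protein_", id)
      pc$deg$kdeg[hit] <- value
    },
    machinery_rate = {
      pc$machineries[[id]]$rate <- value
    },
    budget = {
      pc$budget[[id]] <- value
    },
    stop("unknown parameter type ", type))
  pc
}

# read a parameter's current value
pc_get_param <- function(pc, type, id, key = "") {
  switch(type,
    kcat = pc$enzymes[[id]]$kcat[[key]],
    kdeg = pc$proteins[[id]]$k_deg,
    machinery_rate = pc$machineries[[id]]$rate,
    budget = pc$budget[[id]])
}

#' Twofold parameter robustness scan
#'
#' Varies each parameter by a factor up and down and recomputes the maximal
#' growth rate at each reference condition, reporting the relative change
#' and flagging parameters whose variation shifts growth by more than the
#' threshold. Solver failures are recorded and the scan continues.
#'
#' @param pc a `pc_model`.
#' @param conditions named list of conditions as in
#'   [scaled_reduced_cost()] (default: rich medium, and glucose-limited at
#'   the residual concentration sustaining mu = 0.4).
#' @param factor fold change (default 2).
#' @param threshold relative growth change that flags a parameter
#'   (default 0.01 = 1%).
#' @param parameters optional subset (data.frame as from the internal
#'   enumeration: columns type, id, key); default scans everything.
#' @param tol growth-rate bisection tolerance.
#' @return data.frame: condition, type, id, key, direction, mu, rel_change,
#'   flagged; sorted by |rel_change| within condition.
#' @export
robustness_scan <- function(pc, conditions = NULL, factor = 2,
                            threshold = 0.01, parameters = NULL,
                            tol = 1e-3) {
  if (is.null(conditions)) {
    sm <- min_glucose_concentration(pc, 0.4, tol = 1e-3)
    conditions <- list(rich = list(mu = 0.5, S = Inf),
                       glucose_limited = list(mu = 0.4, S = sm$S_min))
  }
  if (is.null(parameters)) parameters <- pc_parameters(pc)
  rows <- list()
  for (cn in names(conditions)) {
    cond <- conditions[[cn]]
    S <- condition_S(cond)
    base <- max_growth_rate(pc, S = S, tol = tol, mu_init = cond$mu)
    for (i in seq_len(nrow(parameters))) {
      p <- parameters[i, ]
      v0 <- pc_get_param(pc, p$type, p$id, p$key)
      for (f in c(factor, 1 / factor)) {
        mu_new <- tryCatch({
          pc2 <- pc_set_param(pc, p$type, p$id, v0 * f, p$key)
          max_growth_rate(pc2, S = S, tol = tol,
                          mu_init = base$mu_max / 2)$mu_max
        }, error = function(e) NA_real_)
        rel <- (mu_new - base$mu_max) / base$mu_max
        rows[[length(rows) + 1]] <- data.frame(
          condition = cn, type = p$type, id = p$id, key = p$key,
          direction = ifelse(f > 1, "x2", "x0.5"),
          mu = mu_new, rel_change = rel,
          flagged = !is.na(rel) & abs(rel) > threshold,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$condition, -abs(ifelse(is.na(out$rel_change), 0,
                                       out$rel_change))), ]
}
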
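# Stoichiometric model container and the reformulation steps that turn a
# conventional metabolic reconstruction into the irreversible, per-isozyme,
# fully catalysed form required by proteome coupling.

#' Construct a stoichiometric model
#'
#' @param metabolites list of entries created by [metabolite()].
#' @param reactions list of entries created by [reaction()].
#' @return an object of class `sm_model`, holding the metabolite table
#'   (`mets`), the elemental composition matrix (`comp`), the stoichiometric
#'   matrix (`S`, metabolites x reactions), the reaction table (`rxns`) and
#'   the gene-protein-reaction map (`gpr`, reaction id -> isozyme ids).
#' @export
sm_model <- function(metabolites, reactions) {
  met_ids <- vapply(metabolites, `[[`, character(1), "id")
  if (anyDuplicated(met_ids)) {
    stop("duplicate metabolite ids: ",
         paste(unique(met_ids[duplicated(met_ids)]), collapse = ", "))
  }
  rxn_ids <- vapply(reactions, `[[`, character(1), "id")
  if (anyDuplicated(rxn_ids)) {
    stop("duplicate reaction ids: ",
         paste(unique(rxn_ids[duplicated(rxn_ids)]), collapse = ", "))
  }
  mets <- data.frame(
    id = met_ids,
    name = vapply(metabolites, function(m) m$name %||% m$id, character(1)),
    compartment = vapply(metabolites, `[[`, character(1), "compartment"),
    charge = vapply(metabolites, function(m) as.numeric(m$charge %||% 0), numeric(1)),
    stringsAsFactors = FALSE
  )
  comp <- t(vapply(metabolites, function(m) {
    cc <- m$composition %||% comp_zero()
    if (any(cc < 0)) stop("negative element count in metabolite ", m$id)
    cc[PC_ELEMENTS]
  }, numeric(length(PC_ELEMENTS))))
  rownames(comp) <- met_ids

  S <- matrix(0, nrow = length(met_ids), ncol = length(rxn_ids),
              dimnames = list(met_ids, rxn_ids))
  for (r in reactions) {
    st <- r$stoichiometry
    bad <- setdiff(names(st), met_ids)
    if (length(bad)) stop("reaction ", r$id, " references unknown metabolites: ",
                          paste(bad, collapse = ", "))
    S[names(st), r$id] <- unname(st)
  }
  rxns <- data.frame(
    id = rxn_ids,
    kind = vapply(reactions, `[[`, character(1), "kind"),
    lb = vapply(reactions, function(r) as.numeric(r$lb), numeric(1)),
    ub = vapply(reactions, function(r) as.numeric(r$ub), numeric(1)),
    catalyst_id = vapply(reactions, function(r) r$catalyst_id %||% NA_character_, character(1)),
    spontaneous = vapply(reactions, function(r) isTRUE(r$spontaneous), logical(1)),
    source_id = vapply(seq_along(reactions), function(i) {
      reactions[[i]]$source_id %||% rxn_ids[i]
    }, character(1)),
    dir = vapply(reactions, function(r) r$dir %||% "fwd", character(1)),
    stringsAsFactors = FALSE
  )
  if (any(rxns$lb > rxns$ub)) {
    stop("lower bound exceeds upper bound for: ",
         paste(rxns$id[rxns$lb > rxns$ub], collapse = ", "))
  }
  gpr <- lapply(reactions, function(r) r$gpr %||% character())
  names(gpr) <- rxn_ids
  structure(list(mets = mets, comp = comp, S = S, rxns = rxns, gpr = gpr),
            class = "sm_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.sm_model <- function(x, ...) {
  cat("Stoichiometric model:", nrow(x$mets), "metabolites,",
      nrow(x$rxns), "reactions\n")
  cat("  kinds:", paste(sprintf("%s=%d", names(table(x$rxns$kind)),
                                table(x$rxns$kind)), collapse = " "), "\n")
  invisible(x)
}

#' Metabolite entry
#'
#' @param id metabolite identifier (compartment as suffix tag: `_c`, `_m`, `_e`).
#' @param compartment one of `"cytosol"`, `"membrane"`, `"extracellular"`.
#' @param composition elemental composition from [comp()].
#' @param charge formal charge.
#' @param name display name.
#' @export
metabolite <- function(id, compartment = c("cytosol", "membrane", "extracellular"),
                       composition = comp(), charge = 0, name = id) {
  compartment <- match.arg(compartment)
  list(id = id, name = name, compartment = compartment,
       composition = composition, charge = charge)
}

REACTION_KINDS <- c("metabolic", "exchange", "transport", "expression",
                    "dilution", "degradation", "maintenance", "biomass")

#' Reaction entry
#'
#' @param id reaction identifier.
#' @param stoichiometry named numeric vector, metabolite id -> signed
#'   coefficient (negative = consumed).
#' @param lb,ub flux bounds, mmol/gCDW/h.
#' @param kind reaction class (see details).
#' @param gpr character vector of isozyme (enzyme spec) ids able to catalyse
#'   the reaction; empty for reactions without gene association.
#' @param spontaneous if `TRUE` the reaction needs no catalyst and is never
#'   assigned the dummy protein.
#' @param catalyst_id catalyst species already resolved (normally left `NA`
#'   and filled in by [split_isozymes()] / [assign_dummy()]).
#' @export
reaction <- function(id, stoichiometry, lb = 0, ub = 1000,
                     kind = REACTION_KINDS, gpr = character(),
                     spontaneous = FALSE, catalyst_id = NULL) {
  kind <- match.arg(kind)
  list(id = id, stoichiometry = stoichiometry, lb = lb, ub = ub, kind = kind,
       gpr = gpr, spontaneous = spontaneous, catalyst_id = catalyst_id)
}

#' Protein specification
#'
#' @param id protein identifier.
#' @param aa_composition named integer vector of residue counts per amino
#'   acid (names from [aa_table()]).
#' @param k_deg first-order degradation rate constant, 1/h.
#' @param molecular_weight optional override, g/mmol; defaults to the
#'   condensation-polymer mass of `aa_composition` and must agree with it
#'   within 5% when supplied.
#' @export
protein_spec <- function(id, aa_composition, k_deg = 0,
                         molecular_weight = NULL) {
  stopifnot(k_deg >= 0)
  chain <- peptide_chain(aa_composition)
  mw <- molecular_weight %||% chain$mw
  if (mw <= 0) stop("molecular weight must be positive for ", id)
  if (abs(mw - chain$mw) > 0.05 * chain$mw) {
    stop("molecular weight of ", id, " (", signif(mw, 4),
         ") inconsistent with residue-mass sum (", signif(chain$mw, 4), ")")
  }
  list(id = id, aa_composition = aa_composition, k_deg = k_deg,
       molecular_weight = mw, length = chain$length, chain = chain)
}

#' Enzyme specification
#'
#' @param id enzyme identifier.
#' @param subunits named integer vector, protein id -> copies per complex.
#' @param kcat named numeric vector, reaction id -> turnover rate (1/h, for
#'   the forward direction of the split reaction). Keys may name either the
#'   original reaction or a split/per-isozyme copy; lookups fall back to the
#'   source id, so a single entry covers both directions unless overridden.
#' @export
enzyme_spec <- function(id, subunits, kcat) {
  stopifnot(all(subunits > 0), all(subunits == round(subunits)),
            all(kcat > 0))
  list(id = id, subunits = subunits, kcat = kcat)
}

#' Machinery specification
#'
#' Expression-machinery catalysts: the ribosome (rate in amino acids
#' polymerized per machine per hour), the RNA polymerase (nucleotides/h),
#' per-gene mRNAs (translation initiations supported per mRNA per hour) and
#' per-amino-acid tRNAs (charging events per tRNA per hour).
#'
#' @param id one of `"ribosome"`, `"rna_polymerase"`, `"mrna:<gene>"`,
#'   `"trna:<aa>"`.
#' @param rate catalytic rate, events/h (> 0).
#' @param k_deg degradation rate constant, 1/h.
#' @param composition free-form description of the machine's makeup used by
#'   the expression-layer builder (e.g. protein subunits, RNA lengths).
#' @export
machinery_spec <- function(id, rate, k_deg = 0, composition = list()) {
  stopifnot(rate > 0, k_deg >= 0)
  list(id = id, rate = rate, k_deg = k_deg, composition = composition)
}

#' Proteome budget
#'
#' @param total_modeled_fraction fixed mass of modeled protein, g/gCDW.
#' @param unmodeled_fraction share of the *total* proteome that is outside
#'   the model's scope (synthesized with average amino-acid composition).
#' @param transporter_cap upper bound on glucose-transporter concentration,
#'   mmol/gCDW.
#' @export
proteome_budget <- function(total_modeled_fraction, unmodeled_fraction = 0.4,
                            transporter_cap = Inf) {
  stopifnot(total_modeled_fraction > 0,
            unmodeled_fraction >= 0, unmodeled_fraction < 1,
            transporter_cap > 0)
  list(total_modeled_fraction = total_modeled_fraction,
       unmodeled_fraction = unmodeled_fraction,
       transporter_cap = transporter_cap)
}

#' Split reversible reactions into forward and reverse copies
#'
#' Every reaction with `lb < 0` (exchanges included) is replaced by an
#' irreversible forward copy `[0, ub]` and a reverse copy `<id>_rev` with
#' negated stoichiometry and bounds `[0, -lb]`. The `source_id` and `dir`
#' columns of the reaction table retain the mapping, so net fluxes can be
#' reported with [net_fluxes()].
#'
#' @param model an `sm_model`.
#' @return an `sm_model` in which every reaction satisfies `lb >= 0`.
#' @export
split_reversible <- function(model) {
  stopifnot(inherits(model, "sm_model"))
  rx <- model$rxns
  out_S <- list(); out_rx <- list(); out_gpr <- list()
  for (i in seq_len(nrow(rx))) {
    id <- rx$id[i]
    col <- model$S[, id]
    if (rx$lb[i] >= 0) {
      out_S[[id]] <- col
      out_rx[[id]] <- rx[i, ]
      out_gpr[[id]] <- model$gpr[[id]]
    } else {
      fwd <- rx[i, ]; fwd$lb <- 0; fwd$ub <- max(rx$ub[i], 0); fwd$dir <- "fwd"
      rev <- rx[i, ]; rev$id <- paste0(id, "_rev"); rev$lb <- 0
      rev$ub <- -rx$lb[i]; rev$dir <- "rev"
      out_S[[id]] <- col; out_rx[[id]] <- fwd; out_gpr[[id]] <- model$gpr[[id]]
      out_S[[rev$id]] <- -col; out_rx[[rev$id]] <- rev
      out_gpr[[rev$id]] <- model$gpr[[id]]
    }
  }
  model$S <- do.call(cbind, out_S)
  colnames(model$S) <- names(out_S)
  model$rxns <- do.call(rbind, out_rx)
  rownames(model$rxns) <- NULL
  model$gpr <- out_gpr
  model
}

#' Expand reactions with isozymes into one copy per isozyme
#'
#' Reactions whose GPR lists several alternative enzymes are replaced by one
#' copy per isozyme, `<id>__<enzyme>`, each catalysed by a single enzyme;
#' reactions with a single isozyme simply get their `catalyst_id` resolved.
#' The flux of the original reaction is the sum over copies (see
#' [net_fluxes()]).
#'
#' @param model an `sm_model`.
#' @return an `sm_model` in which no reaction has more than one isozyme.
#' @export
split_isozymes <- function(model) {
  stopifnot(inherits(model, "sm_model"))
  rx <- model$rxns
  out_S <- list(); out_rx <- list(); out_gpr <- list()
  for (i in seq_len(nrow(rx))) {
    id <- rx$id[i]
    g <- model$gpr[[id]]
    if (length(g) <= 1) {
      row <- rx[i, ]
      if (length(g) == 1 && is.na(row$catalyst_id)) row$catalyst_id <- g
      out_S[[id]] <- model$S[, id]; out_rx[[id]] <- row; out_gpr[[id]] <- g
    } else {
      for (e in g) {
        cid <- paste0(id, "__", e)
        row <- rx[i, ]; row$id <- cid; row$catalyst_id <- e
        out_S[[cid]] <- model$S[, id]; out_rx[[cid]] <- row; out_gpr[[cid]] <- e
      }
    }
  }
  model$S <- do.call(cbind, out_S)
  colnames(model$S) <- names(out_S)
  model$rxns <- do.call(rbind, out_rx)
  rownames(model$rxns) <- NULL
  model$gpr <- out_gpr
  model
}

#' Assign the dummy protein to catalyst-less reactions
#'
#' Non-spontaneous metabolic and transport reactions without a gene
#' association would otherwise carry flux at zero protein cost, biasing
#' simulations toward them; they are assigned a shared placeholder enzyme.
#'
#' @param model an `sm_model`.
#' @param dummy_id catalyst id to assign (the expression-layer builder
#'   creates the corresponding average-composition enzyme).
#' @return the model with `catalyst_id` filled in.
#' @export
assign_dummy <- function(model, dummy_id = "dummy") {
  stopifnot(inherits(model, "sm_model"))
  need <- model$rxns$kind %in% c("metabolic", "transport") &
    is.na(model$rxns$catalyst_id) & !model$rxns$spontaneous
  model$rxns$catalyst_id[need] <- dummy_id
  model
}

#' Net fluxes on the original reaction ids
#'
#' Aggregates a flux vector of a split model back onto the source reaction
#' ids: reverse copies count negatively, isozyme copies sum.
#'
#' @param model split `sm_model`.
#' @param v named flux vector over the split reaction ids.
#' @return named vector over source reaction ids.
#' @export
net_fluxes <- function(model, v) {
  sgn <- ifelse(model$rxns$dir == "rev", -1, 1)
  contrib <- sgn * v[model$rxns$id]
  tapply(contrib, model$rxns$source_id, sum)[unique(model$rxns$source_id)]
}

#' Protein cost of a catalysed reaction
#'
#' The proteome price of carrying unit flux: enzyme mass over turnover rate.
#'
#' @param enzyme an [enzyme_spec()].
#' @param reaction_id reaction id (split or source id).
#' @param proteins named list of [protein_spec()]s covering the subunits.
#' @return cost in g protein per (mmol/gCDW/h) of flux, i.e. g h/mmol.
#' @export
protein_cost <- function(enzyme, reaction_id, proteins) {
  kc <- enzyme_kcat(enzyme, reaction_id)
  if (is.na(kc)) stop("enzyme ", enzyme$id, " does not catalyse ", reaction_id)
  if (kc <= 0) stop("k_cat must be positive")
  enzyme_mass(enzyme, proteins) / kc
}

#' Mass of an enzyme complex
#'
#' @param enzyme an [enzyme_spec()].
#' @param proteins named list of [protein_spec()]s.
#' @return g/mmol.
#' @export
enzyme_mass <- function(enzyme, proteins) {
  sum(vapply(names(enzyme$subunits), function(p) {
    enzyme$subunits[[p]] * proteins[[p]]$molecular_weight
  }, numeric(1)))
}

# kcat lookup with fallback from a split id to its source id: "PFL__E_pfl"
# or "ACKr_rev" resolve to "PFL"/"ACKr" entries unless overridden.
enzyme_kcat <- function(enzyme, reaction_id, source_id = NULL) {
  k <- enzyme$kcat
  for (key in unique(c(reaction_id, source_id,
                       sub("__.*$", "", sub("_rev$", "", reaction_id))))) {
    if (!is.null(key) && !is.na(key) && key %in% names(k)) return(unname(k[key]))
  }
  NA_real_
}

#' Validate model invariants
#'
#' Checks id uniqueness, bound ordering, elemental/charge balance of
#' internal reactions, and (for split models) that metabolic and transport
#' reactions carry a catalyst.
#'
#' @param model an `sm_model`.
#' @param require_catalysts require every non-spontaneous metabolic or
#'   transport reaction to have a `catalyst_id` (after [assign_dummy()]).
#' @return invisibly `TRUE`; stops with a message otherwise.
#' @export
validate_sm_model <- function(model, require_catalysts = FALSE) {
  stopifnot(inherits(model, "sm_model"))
  if (anyDuplicated(model$mets$id)) stop("duplicate metabolite ids")
  if (anyDuplicated(model$rxns$id)) stop("duplicate reaction ids")
  if (any(model$rxns$lb > model$rxns$ub)) stop("lb > ub")
  bal <- check_balance(model)
  if (nrow(bal) > 0) {
    stop("unbalanced reactions:\n",
         paste(utils::capture.output(print(bal)), collapse = "\n"))
  }
  if (require_catalysts) {
    miss <- model$rxns$kind %in% c("metabolic", "transport") &
      !model$rxns$spontaneous & is.na(model$rxns$catalyst_id)
    if (any(miss)) stop("uncatalysed reactions: ",
                        paste(model$rxns$id[miss], collapse = ", "))
  }
  invisible(TRUE)
}
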
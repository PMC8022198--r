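# Model interchange: a documented JSON schema for the stoichiometric layer
# plus parameter tables, and TSV writers for simulation results.

#' Write a stoichiometric model to JSON
#'
#' Schema: `metabolites` (id, name, compartment, charge, composition as an
#' element->count map), `reactions` (id, stoichiometry as metabolite->
#' coefficient map, lb, ub, kind, gpr, spontaneous).
#'
#' @param model an `sm_model`.
#' @param path output file.
#' @export
write_model_json <- function(model, path) {
  mets <- lapply(seq_len(nrow(model$mets)), function(i) {
    m <- model$mets[i, ]
    cc <- model$comp[m$id, ]
    list(id = m$id, name = m$name, compartment = m$compartment,
         charge = m$charge, composition = as.list(cc[cc != 0]))
  })
  rxns <- lapply(seq_len(nrow(model$rxns)), function(j) {
    r <- model$rxns[j, ]
    st <- model$S[, r$id]
    st <- st[st != 0]
    list(id = r$id, stoichiometry = as.list(st), lb = r$lb, ub = r$ub,
         kind = r$kind, gpr = model$gpr[[r$id]],
         spontaneous = r$spontaneous)
  })
  jsonlite::write_json(list(metabolites = mets, reactions = rxns), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a stoichiometric model from JSON
#'
#' @param path file written by [write_model_json()].
#' @return an `sm_model`.
#' @export
read_model_json <- function(path) {
  d <- jsonlite::read_json(path)
  mets <- lapply(d$metabolites, function(m) {
    cc <- comp_zero()
    for (el in names(m$composition)) cc[el] <- as.numeric(m$composition[[el]])
    metabolite(m$id, m$compartment, cc, as.numeric(m$charge %||% 0),
               m$name %||% m$id)
  })
  rxns <- lapply(d$reactions, function(r) {
    st <- vapply(r$stoichiometry, as.numeric, numeric(1))
    reaction(r$id, st, as.numeric(r$lb %||% 0), as.numeric(r$ub %||% 1000),
             r$kind %||% "metabolic",
             gpr = unlist(r$gpr) %||% character(),
             spontaneous = isTRUE(r$spontaneous))
  })
  sm_model(mets, rxns)
}

#' Write enzyme parameters to TSV
#'
#' One row per (enzyme, reaction): reaction id, k_cat (1/h), enzyme
#' molecular weight (g/mmol), mass-weighted subunit degradation constant.
#'
#' @param enzymes named list of [enzyme_spec()]s.
#' @param proteins named list of [protein_spec()]s.
#' @param path output file.
#' @export
write_enzyme_tsv <- function(enzymes, proteins, path) {
  rows <- list()
  for (e in names(enzymes)) {
    es <- enzymes[[e]]
    mw <- enzyme_mass(es, proteins)
    kd <- sum(vapply(names(es$subunits), function(p) {
      proteins[[p]]$molecular_weight * es$subunits[[p]] * proteins[[p]]$k_deg
    }, numeric(1))) / mw
    for (rid in names(es$kcat)) {
      rows[[length(rows) + 1]] <- data.frame(
        enzyme = e, reaction = rid, kcat = es$kcat[[rid]], mw = mw,
        kdeg = kd, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a simulation result to TSV
#'
#' Long format: one row per reaction with its flux, plus one row per
#' catalyst species with its concentration.
#'
#' @param result a `pc_result`.
#' @param path output file.
#' @export
write_result_tsv <- function(result, path) {
  stopifnot(result$feasible)
  tab <- rbind(
    data.frame(quantity = "flux", id = names(result$fluxes),
               value = unname(result$fluxes), stringsAsFactors = FALSE),
    data.frame(quantity = "concentration", id = names(result$concentrations),
               value = unname(result$concentrations), stringsAsFactors = FALSE))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
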
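# Gene-expression layer: per-gene transcription, mRNA degradation and
# dilution; per-amino-acid tRNA synthesis and charging; per-protein
# translation, degradation and dilution; per-enzyme formation and dilution;
# ribosome and RNA polymerase assembly. Together with the coupling table
# this turns a stoichiometric model into a proteome-coupled model.

#' Expression-layer stoichiometry configuration
#'
#' Energy and length parameters of the expression reactions. The bundled
#' network uses ATP as its generic NTP, so transcription consumes ATP and
#' releases pyrophosphate, and the GTP cost of translation is booked in
#' ATP equivalents.
#'
#' @param gtp_per_residue ATP-equivalents hydrolysed per residue translated
#'   (two GTP per elongation cycle).
#' @param atp_per_residue_degradation ATP per residue for proteolysis.
#' @param nt_per_codon transcript nucleotides per codon.
#' @param trna_length,rrna_length stable-RNA lengths, nucleotides.
#' @param macro_unit amount of macromolecule represented by one unit of an
#'   expression-layer species, in mmol (default 1e-6, i.e. macromolecules
#'   are carried in nmol/gCDW). Metabolic fluxes are mmol/gCDW/h while
#'   macromolecular synthesis fluxes are ~1e6-fold smaller; without this
#'   unit choice the coupled LP spans ten orders of magnitude and floating
#'   point solvers cannot separate feasibility from roundoff.
#' @param mets metabolite ids of the energy/monomer species.
#' @export
expression_config <- function(gtp_per_residue = 2,
                              atp_per_residue_degradation = 1,
                              nt_per_codon = 3,
                              trna_length = 25, rrna_length = 1500,
                              macro_unit = 1e-6,
                              mets = list(atp = "atp_c", adp = "adp_c",
                                          amp = "amp_c", pi = "pi_c",
                                          ppi = "ppi_c", h = "h_c",
                                          h2o = "h2o_c")) {
  list(gtp_per_residue = gtp_per_residue,
       atp_per_residue_degradation = atp_per_residue_degradation,
       nt_per_codon = nt_per_codon, trna_length = trna_length,
       rrna_length = rrna_length, macro_unit = macro_unit, mets = mets)
}

# Reconstruct the constructor lists from an sm_model so new species and
# reactions can be appended and the model rebuilt.
model_to_lists <- function(model) {
  mets <- lapply(seq_len(nrow(model$mets)), function(i) {
    m <- model$mets[i, ]
    metabolite(m$id, m$compartment, model$comp[m$id, ], m$charge, m$name)
  })
  rxns <- lapply(seq_len(nrow(model$rxns)), function(j) {
    r <- model$rxns[j, ]
    st <- model$S[, r$id]
    st <- st[st != 0]
    rr <- reaction(r$id, st, r$lb, r$ub, r$kind, model$gpr[[r$id]],
                   r$spontaneous, if (!is.na(r$catalyst_id)) r$catalyst_id)
    rr$source_id <- r$source_id
    rr$dir <- r$dir
    rr
  })
  list(mets = mets, rxns = rxns)
}

#' Build the proteome-coupled model
#'
#' Adds the gene-expression layer to an irreversible, catalyst-resolved
#' stoichiometric model and assembles the coupling metadata used by the
#' simulation module: for every catalysed reaction a `v <= k_cat [E]`
#' coupling, for every machinery a capacity constraint, for every degraded
#' catalyst a steady-state degradation flux, and the fixed total-modeled-
#' proteome budget that the dummy-protein pool fills when catalytic demand
#' is low.
#'
#' @param model split, isozyme-expanded, dummy-assigned `sm_model`
#'   (see [split_reversible()], [split_isozymes()], [assign_dummy()]).
#' @param proteins named list of [protein_spec()]s; must include every
#'   enzyme subunit, the machinery proteins, `dummy_protein` and
#'   `unmodeled_protein`.
#' @param enzymes named list of [enzyme_spec()]s covering every
#'   `catalyst_id` in the model (including `dummy`).
#' @param machineries named list of [machinery_spec()]s: `ribosome`,
#'   `rna_polymerase`, one `mrna:<protein>` per protein and one
#'   `trna:<aa>` per amino acid.
#' @param budget a [proteome_budget()].
#' @param config an [expression_config()].
#' @return an object of class `pc_model`.
#' @export
build_expression_layer <- function(model, proteins, enzymes, machineries,
                                   budget, config = expression_config()) {
  stopifnot(inherits(model, "sm_model"), all(model$rxns$lb >= 0))
  cm <- config$mets
  sc <- config$macro_unit %||% 1e-6
  aaT <- aa_table()

  # composition lookup extended as species are added
  comp_env <- new.env()
  for (id in model$mets$id) {
    assign(id, list(comp = model$comp[id, ], charge = model$mets$charge[model$mets$id == id]),
           envir = comp_env)
  }
  getc <- function(id) get(id, envir = comp_env)

  lists <- model_to_lists(model)
  new_mets <- list(); new_rxns <- list()
  coupling <- list(); deg <- list(); dil <- character()
  protein_mass <- numeric()

  add_species <- function(id, composition, charge) {
    new_mets[[length(new_mets) + 1]] <<- metabolite(id, "cytosol", composition, charge)
    assign(id, list(comp = composition, charge = charge), envir = comp_env)
  }
  add_rxn <- function(id, stoich, kind, balance = TRUE) {
    if (balance) stoich <- balance_water_protons(stoich, getc, cm, id)
    rr <- reaction(id, stoich, 0, 1000, kind, spontaneous = TRUE)
    rr$source_id <- id; rr$dir <- "fwd"
    new_rxns[[length(new_rxns) + 1]] <<- rr
    id
  }
  add_coupling <- function(rxn, species, weight, type, ref) {
    coupling[[length(coupling) + 1]] <<- data.frame(
      rxn = rxn, species = species, weight = weight, type = type, ref = ref,
      stringsAsFactors = FALSE)
  }
  add_deg <- function(rxn, species, kdeg) {
    deg[[length(deg) + 1]] <<- data.frame(rxn = rxn, species = species,
                                          kdeg = kdeg, stringsAsFactors = FALSE)
  }
  add_dil <- function(species) {
    id <- paste0("DIL_", species)
    add_rxn(id, setNames(-1, species), "dilution", balance = FALSE)
    dil[[species]] <<- id
    id
  }

  rna_res <- list(comp = getc(cm$atp)$comp - getc(cm$ppi)$comp,
                  charge = getc(cm$atp)$charge - getc(cm$ppi)$charge)

  # --- stable RNAs and machinery species -------------------------------
  rib <- machineries[["ribosome"]]
  rnp <- machineries[["rna_polymerase"]]
  if (is.null(rib) || is.null(rnp)) stop("ribosome and rna_polymerase machineries are required")
  rib_prot <- rib$composition$proteins
  rnp_prot <- rnp$composition$proteins
  rrna_len <- rib$composition$rrna_length %||% config$rrna_length

  add_species("rrna", comp_scale(rna_res$comp, rrna_len * sc),
              rna_res$charge * rrna_len * sc)
  # tRNAs stay in mmol: their charging flux carries the amino-acid flux
  # (mmol-scale), unlike the nmol-scale synthesis fluxes of the other
  # macromolecules
  for (a in aaT$aa) {
    tl <- config$trna_length
    add_species(paste0("trna_", a), comp_scale(rna_res$comp, tl),
                rna_res$charge * tl)
    aam <- getc(paste0(aa_met_stem(a), "_c"))
    add_species(paste0("trnac_", a),
                comp_scale(rna_res$comp, tl) + aam$comp - .WATER,
                rna_res$charge * tl + aam$charge)
  }

  # --- per-protein gene expression -------------------------------------
  need <- vapply(proteins, function(p) is.null(p$aa_composition), logical(1))
  if (any(need)) stop("missing amino-acid composition for protein(s): ",
                      paste(names(proteins)[need], collapse = ", "))
  for (p in names(proteins)) {
    ps <- proteins[[p]]
    L <- ps$length
    nt <- config$nt_per_codon * L
    mrna <- paste0("mrna_", p)
    prot <- paste0("protein_", p)
    mach_id <- paste0("mrna:", p)
    if (is.null(machineries[[mach_id]])) {
      stop("missing machinery spec ", mach_id)
    }
    add_species(mrna, comp_scale(rna_res$comp, nt * sc), rna_res$charge * nt * sc)
    add_species(prot, comp_scale(ps$chain$composition, sc), ps$chain$charge * sc)

    tcr <- add_rxn(paste0("TCR_", p),
                   setNames(c(-nt * sc, 1, nt * sc), c(cm$atp, mrna, cm$ppi)),
                   "expression")
    add_coupling(tcr, "rnap", nt, "machinery", "rna_polymerase")

    mdeg <- add_rxn(paste0("MDEG_", p),
                    setNames(c(-1, nt * sc), c(mrna, cm$amp)), "degradation")
    if (machineries[[mach_id]]$k_deg > 0) add_deg(mdeg, mrna, machineries[[mach_id]]$k_deg)
    add_dil(mrna)

    counts <- ps$aa_composition[ps$aa_composition > 0]
    st <- c(setNames(-counts * sc, paste0("trnac_", names(counts))),
            setNames(counts * sc, paste0("trna_", names(counts))),
            setNames(-config$gtp_per_residue * L * sc, cm$atp),
            setNames(config$gtp_per_residue * L * sc, cm$adp),
            setNames(config$gtp_per_residue * L * sc, cm$pi))
    st[prot] <- 1
    trl <- add_rxn(paste0("TRL_", p), st, "expression")
    add_coupling(trl, "ribosome", L, "machinery", "ribosome")
    add_coupling(trl, mrna, 1, "machinery", mach_id)

    dst <- c(setNames(-1, prot),
             setNames(counts * sc, paste0(vapply(names(counts), aa_met_stem, ""), "_c")),
             setNames(-config$atp_per_residue_degradation * L * sc, cm$atp),
             setNames(config$atp_per_residue_degradation * L * sc, cm$adp),
             setNames(config$atp_per_residue_degradation * L * sc, cm$pi))
    pdeg <- add_rxn(paste0("PDEG_", p), dst, "degradation")
    if (ps$k_deg > 0) add_deg(pdeg, prot, ps$k_deg)
    add_dil(prot)
    protein_mass[prot] <- ps$molecular_weight
  }

  # --- tRNA expression and charging ------------------------------------
  for (a in aaT$aa) {
    tl <- config$trna_length
    trna <- paste0("trna_", a); trnac <- paste0("trnac_", a)
    ts <- add_rxn(paste0("TRNAS_", a),
                  setNames(c(-tl, 1, tl), c(cm$atp, trna, cm$ppi)),
                  "expression")
    add_coupling(ts, "rnap", tl / sc, "machinery", "rna_polymerase")
    chg <- add_rxn(paste0("CHARGE_", a),
                   setNames(c(-1, -1, -1, 1, 1, 1),
                            c(paste0(aa_met_stem(a), "_c"), trna, cm$atp,
                              trnac, cm$amp, cm$ppi)),
                   "expression")
    add_coupling(chg, trna, 1, "machinery", paste0("trna:", a))
    add_dil(trna)
  }

  # --- enzyme complexes -------------------------------------------------
  for (e in names(enzymes)) {
    es <- enzymes[[e]]
    spc <- paste0("enzyme_", e)
    cc <- comp_zero(); ch <- 0; kd_num <- 0; kd_den <- 0
    for (su in names(es$subunits)) {
      k <- es$subunits[[su]]
      pc_ <- getc(paste0("protein_", su))
      cc <- cc + comp_scale(pc_$comp, k); ch <- ch + pc_$charge * k
      w <- proteins[[su]]$molecular_weight * k
      kd_num <- kd_num + w * proteins[[su]]$k_deg; kd_den <- kd_den + w
    }
    add_species(spc, cc, ch)
    add_rxn(paste0("ENZF_", e),
            c(setNames(-es$subunits, paste0("protein_", names(es$subunits))),
              setNames(1, spc)),
            "expression", balance = FALSE)
    add_dil(spc)
    kd <- kd_num / kd_den
    if (kd > 0) {
      counts <- Reduce(`+`, lapply(names(es$subunits), function(su) {
        proteins[[su]]$aa_composition * es$subunits[[su]]
      }))
      Ltot <- sum(counts)
      dst <- c(setNames(-1, spc),
               setNames(counts * sc, paste0(vapply(names(counts), aa_met_stem, ""), "_c")),
               setNames(-config$atp_per_residue_degradation * Ltot * sc, cm$atp),
               setNames(config$atp_per_residue_degradation * Ltot * sc, cm$adp),
               setNames(config$atp_per_residue_degradation * Ltot * sc, cm$pi))
      dge <- add_rxn(paste0("DEGENZ_", e), dst, "degradation")
      add_deg(dge, spc, kd)
    }
    protein_mass[spc] <- enzyme_mass(es, proteins)
  }

  # --- ribosome and RNA polymerase assembly ----------------------------
  rib_cc <- getc("rrna")$comp; rib_ch <- getc("rrna")$charge; rib_mass <- 0
  for (su in names(rib_prot)) {
    pc_ <- getc(paste0("protein_", su))
    rib_cc <- rib_cc + comp_scale(pc_$comp, rib_prot[[su]])
    rib_ch <- rib_ch + pc_$charge * rib_prot[[su]]
    rib_mass <- rib_mass + proteins[[su]]$molecular_weight * rib_prot[[su]]
  }
  add_species("ribosome", rib_cc, rib_ch)
  add_rxn("RRNAS", setNames(c(-rrna_len * sc, 1, rrna_len * sc),
                            c(cm$atp, "rrna", cm$ppi)),
          "expression")
  add_coupling("RRNAS", "rnap", rrna_len, "machinery", "rna_polymerase")
  add_rxn("RIBASM",
          c(setNames(-1, "rrna"),
            setNames(-rib_prot, paste0("protein_", names(rib_prot))),
            setNames(1, "ribosome")),
          "expression", balance = FALSE)
  add_dil("ribosome")
  protein_mass["ribosome"] <- rib_mass

  rnp_cc <- comp_zero(); rnp_ch <- 0; rnp_mass <- 0
  for (su in names(rnp_prot)) {
    pc_ <- getc(paste0("protein_", su))
    rnp_cc <- rnp_cc + comp_scale(pc_$comp, rnp_prot[[su]])
    rnp_ch <- rnp_ch + pc_$charge * rnp_prot[[su]]
    rnp_mass <- rnp_mass + proteins[[su]]$molecular_weight * rnp_prot[[su]]
  }
  add_species("rnap", rnp_cc, rnp_ch)
  add_rxn("RNAPASM",
          c(setNames(-rnp_prot, paste0("protein_", names(rnp_prot))),
            setNames(1, "rnap")),
          "expression", balance = FALSE)
  add_dil("rnap")
  protein_mass["rnap"] <- rnp_mass

  # the dummy pool and the unmodeled-protein species exist via their
  # protein_<id> species above; unmodeled protein is pinned, not budgeted
  unmod <- "protein_unmodeled_protein"
  if (!unmod %in% names(protein_mass)) stop("unmodeled_protein spec is required")
  unmod_mw <- protein_mass[[unmod]]
  protein_mass <- protein_mass[setdiff(names(protein_mass), unmod)]

  model2 <- sm_model(c(lists$mets, new_mets), c(lists$rxns, new_rxns))
  coupling_tab <- do.call(rbind, coupling)
  # enzyme coupling rows for the metabolic layer
  rx <- model2$rxns
  cat_rows <- which(!is.na(rx$catalyst_id))
  enz_coupling <- data.frame(
    rxn = rx$id[cat_rows],
    species = paste0("enzyme_", rx$catalyst_id[cat_rows]),
    weight = 1, type = "enzyme", ref = rx$catalyst_id[cat_rows],
    stringsAsFactors = FALSE)
  coupling_tab <- rbind(coupling_tab, enz_coupling)

  unmod_target <- budget$total_modeled_fraction * budget$unmodeled_fraction /
    (1 - budget$unmodeled_fraction)

  unit <- setNames(rep(sc, length(dil)), names(dil))
  unit[grep("^trna", names(unit))] <- 1
  pc <- structure(list(
    model = model2,
    proteins = proteins,
    enzymes = enzymes,
    machineries = machineries,
    budget = budget,
    config = config,
    coupling = coupling_tab,
    deg = if (length(deg)) do.call(rbind, deg) else NULL,
    dil = dil,
    species_unit = unit,
    protein_mass = protein_mass,
    unmodeled = list(species = unmod, dil = dil[[unmod]],
                     mass_target = unmod_target, mw = unmod_mw),
    dummy = list(protein = "protein_dummy_protein",
                 translation = "TRL_dummy_protein", enzyme = "dummy"),
    biomass = "BIOMASS", atpm = "ATPM"
  ), class = "pc_model")
  pc
}

# Append water/proton coefficients so a reaction balances every tracked
# element and charge; stops if anything but H/O/charge is off.
balance_water_protons <- function(stoich, getc, cm, id) {
  res <- comp_zero(); ch <- 0
  for (m in names(stoich)) {
    x <- getc(m)
    res <- res + comp_scale(x$comp, stoich[[m]])
    ch <- ch + x$charge * stoich[[m]]
  }
  if (any(abs(res[c("C", "N", "P")]) > 1e-6)) {
    stop("reaction ", id, " cannot be balanced with water/protons: ",
         paste(sprintf("%s=%g", names(res), res), collapse = " "))
  }
  n_h2o <- -res[["O"]]
  n_h <- -(res[["H"]] + 2 * n_h2o)
  # snap float-arithmetic residue to zero: a 1e-16 water coefficient is
  # noise, and noise columns wreck LP pivoting
  if (abs(n_h2o) < 1e-9) n_h2o <- 0
  if (abs(n_h) < 1e-9) n_h <- 0
  if (abs(ch + n_h) > 1e-6) {
    stop("reaction ", id, " has inconsistent charge after balancing")
  }
  for (sp in c(cm$h2o, cm$h)) if (!sp %in% names(stoich)) stoich[sp] <- 0
  stoich[cm$h2o] <- stoich[cm$h2o] + n_h2o
  stoich[cm$h] <- stoich[cm$h] + n_h
  stoich <- stoich[abs(stoich) > 1e-12]
  stoich
}

#' Build the proteome-coupled toy model
#'
#' Runs the full construction pipeline on the bundled network: reversible
#' splitting, isozyme expansion, dummy-protein assignment, and the
#' expression layer.
#'
#' @param toy bundle from [make_toy_network()] (built if omitted).
#' @return a `pc_model` carrying, in addition, the glucose-transporter
#'   kinetics (`$glucose`), the per-amino-acid uptake-bound coefficients
#'   (`$aa_uptake`) and the default blocked-reaction list (`$block`).
#' @export
make_toy_pc <- function(toy = make_toy_network()) {
  layer <- metabolic_layer(toy)
  pc <- build_expression_layer(layer$model, toy$proteins, layer$enzymes,
                               toy$machineries, toy$budget, toy$config)
  up <- toy$aa_uptake
  up$met <- paste0(vapply(up$aa, aa_met_stem, ""), "_e")
  up$rxn <- vapply(up$met, function(m) uptake_rxn(pc$model, m), character(1))
  pc$aa_uptake <- up
  rxn_ids <- pc$model$rxns
  pts_rxns <- rxn_ids$id[!is.na(rxn_ids$catalyst_id) &
                           rxn_ids$catalyst_id == toy$kinetics$transporter]
  pc$glucose <- list(kcat = toy$kinetics$kcat, KM = toy$kinetics$KM,
                     pts_rxns = pts_rxns,
                     transporter_species = paste0("enzyme_", toy$kinetics$transporter),
                     uptake_rxn = uptake_rxn(pc$model, "glc__D_e"))
  pc$block <- toy$block
  pc$toy <- toy
  pc
}

#' @export
print.pc_model <- function(x, ...) {
  cat("Proteome-coupled model:", nrow(x$model$mets), "species,",
      nrow(x$model$rxns), "reactions,",
      length(x$enzymes), "enzymes,", length(x$proteins), "proteins\n")
  cat(sprintf("  modeled proteome budget %.3g g/gCDW (unmodeled share %.0f%%)\n",
              x$budget$total_modeled_fraction, 100 * x$budget$unmodeled_fraction))
  invisible(x)
}
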
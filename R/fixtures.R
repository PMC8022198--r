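# Synthetic fixtures: a small fermentative network in the style of a lactic
# acid bacterium (glycolysis feeding mixed-acid and lactate branches, an
# arginine deiminase pathway with carbamate kinase ATP production, a PTS
# glucose uptake system and an explicit proton economy), plus a simulated
# glucose-limited chemostat dataset. Everything is a pure function of its
# arguments, so tests and simulations need no external data.

#' Toy network specification
#'
#' @param include_expression_layer build the gene-expression layer when the
#'   network is converted to a proteome-coupled model (see [make_toy_pc()]).
#' @param atpase_h_per_atp protons translocated per ATP by the membrane ATP
#'   synthase. The default of 3 makes two cytosolic protons worth 2/3 ATP,
#'   the equivalence underlying the arginine-pathway yield of 1.67.
#' @param pts_glucose import glucose by the phosphotransferase system
#'   (phosphorylation at the expense of phosphoenolpyruvate).
#' @param seed optional integer; when given, enzyme turnover numbers are
#'   jittered reproducibly (+/-20%) to create randomized variants.
#' @export
toy_network_spec <- function(include_expression_layer = TRUE,
                             atpase_h_per_atp = 3, pts_glucose = TRUE,
                             seed = NULL) {
  stopifnot(atpase_h_per_atp > 0)
  list(include_expression_layer = include_expression_layer,
       atpase_h_per_atp = atpase_h_per_atp,
       pts_glucose = pts_glucose, seed = seed)
}

# Metabolite id stem for an amino acid (arginine carries the L-isomer tag
# used throughout the network).
aa_met_stem <- function(a) ifelse(a == "arg", "arg__L", a)

# Deterministic residue composition for toy proteins: fixed proportions over
# the reduced alphabet, rounded so the counts sum to the requested length.
toy_aa_counts <- function(length, shares = c(gly = 0.18, ala = 0.22, ser = 0.16,
                                             asp = 0.14, glu = 0.18, arg = 0.12)) {
  counts <- floor(shares * length)
  rem <- length - sum(counts)
  if (rem > 0) {
    ord <- order(shares * length - counts, decreasing = TRUE)
    counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1
  }
  counts
}

#' Generate the toy fermentative network
#'
#' Builds the three-pathway network: PTS glucose uptake, lumped glycolysis
#' (glucose to 2 pyruvate, net +2 ATP and +2 NADH), a pyruvate
#' formate-lyase/acetate kinase/alcohol dehydrogenase mixed-acid branch, a
#' lactate dehydrogenase branch, and the arginine deiminase pathway
#' (arginine deiminase, ornithine transcarbamylase, carbamate kinase,
#' arginine/ornithine antiport) that consumes cytosolic protons. Weak acids
#' leave by proton symport; a reversible membrane ATP synthase translocates
#' `atpase_h_per_atp` protons per ATP. Every internal reaction balances C, H,
#' N, O, P and charge exactly.
#'
#' @param spec a [toy_network_spec()].
#' @return list with the unsplit `model` (an [sm_model()]), `proteins`,
#'   `enzymes`, `machineries`, `budget`, `kinetics` (glucose transporter
#'   kinetics), `aa_uptake` (per-amino-acid uptake-bound coefficients versus
#'   growth rate), `config` (expression-layer stoichiometry defaults) and
#'   `block` (reaction ids disabled under the default anaerobic condition).
#' @export
make_toy_network <- function(spec = toy_network_spec()) {
  aa <- aa_table()
  A <- function(a, el) aa[aa$aa == a, el]
  n_h <- spec$atpase_h_per_atp

  mets <- list(
    metabolite("glc__D_e", "extracellular", comp(6, 12, 0, 6), 0),
    metabolite("glc__D_c", "cytosol", comp(6, 12, 0, 6), 0),
    metabolite("g6p_c", "cytosol", comp(6, 11, 0, 9, 1), -2),
    metabolite("pep_c", "cytosol", comp(3, 2, 0, 6, 1), -3),
    metabolite("pyr_c", "cytosol", comp(3, 3, 0, 3), -1),
    metabolite("lac__L_c", "cytosol", comp(3, 5, 0, 3), -1),
    metabolite("lac__L_e", "extracellular", comp(3, 5, 0, 3), -1),
    metabolite("for_c", "cytosol", comp(1, 1, 0, 2), -1),
    metabolite("for_e", "extracellular", comp(1, 1, 0, 2), -1),
    metabolite("ac_c", "cytosol", comp(2, 3, 0, 2), -1),
    metabolite("ac_e", "extracellular", comp(2, 3, 0, 2), -1),
    metabolite("actp_c", "cytosol", comp(2, 3, 0, 5, 1), -2),
    metabolite("etoh_c", "cytosol", comp(2, 6, 0, 1), 0),
    metabolite("etoh_e", "extracellular", comp(2, 6, 0, 1), 0),
    metabolite("citr__L_c", "cytosol", comp(6, 13, 3, 3), 0),
    metabolite("orn_c", "cytosol", comp(5, 13, 2, 2), 1),
    metabolite("orn_e", "extracellular", comp(5, 13, 2, 2), 1),
    metabolite("cbp_c", "cytosol", comp(1, 2, 1, 5, 1), -2),
    metabolite("atp_c", "cytosol", comp(10, 12, 5, 13, 3), -4),
    metabolite("adp_c", "cytosol", comp(10, 12, 5, 10, 2), -3),
    metabolite("amp_c", "cytosol", comp(10, 12, 5, 7, 1), -2),
    metabolite("adn_c", "cytosol", comp(10, 13, 5, 4), 0),
    metabolite("adn_e", "extracellular", comp(10, 13, 5, 4), 0),
    metabolite("pi_c", "cytosol", comp(0, 1, 0, 4, 1), -2),
    metabolite("pi_e", "extracellular", comp(0, 1, 0, 4, 1), -2),
    metabolite("ppi_c", "cytosol", comp(0, 1, 0, 7, 2), -3),
    metabolite("nad_c", "cytosol", comp(21, 26, 7, 14, 2), -1),
    metabolite("nadh_c", "cytosol", comp(21, 27, 7, 14, 2), -2),
    metabolite("h_c", "cytosol", comp(0, 1, 0, 0), 1),
    metabolite("h_e", "extracellular", comp(0, 1, 0, 0), 1),
    metabolite("h2o_c", "cytosol", comp(0, 2, 0, 1), 0),
    metabolite("h2o_e", "extracellular", comp(0, 2, 0, 1), 0),
    metabolite("co2_c", "cytosol", comp(1, 0, 0, 2), 0),
    metabolite("co2_e", "extracellular", comp(1, 0, 0, 2), 0),
    metabolite("nh4_c", "cytosol", comp(0, 4, 1, 0), 1),
    metabolite("nh4_e", "extracellular", comp(0, 4, 1, 0), 1),
    metabolite("nh3_c", "cytosol", comp(0, 3, 1, 0), 0),
    metabolite("nh3_e", "extracellular", comp(0, 3, 1, 0), 0),
    metabolite("o2_c", "cytosol", comp(0, 0, 0, 2), 0),
    metabolite("o2_e", "extracellular", comp(0, 0, 0, 2), 0),
    metabolite("h2o2_c", "cytosol", comp(0, 2, 0, 2), 0),
    metabolite("h2o2_e", "extracellular", comp(0, 2, 0, 2), 0)
  )
  for (a in aa$aa) {
    cc <- comp(A(a, "C"), A(a, "H"), A(a, "N"), A(a, "O"), A(a, "P"))
    stem <- aa_met_stem(a)
    mets <- c(mets, list(
      metabolite(paste0(stem, "_c"), "cytosol", cc, A(a, "charge")),
      metabolite(paste0(stem, "_e"), "extracellular", cc, A(a, "charge"))
    ))
  }

  rxns <- list(
    # glucose uptake: PTS (primary) plus two low-expression routes that the
    # default condition blocks
    reaction("GLCpts", c(glc__D_e = -1, pep_c = -1, g6p_c = 1, pyr_c = 1),
             kind = "transport", gpr = "E_pts"),
    reaction("GLCt2", c(glc__D_e = -1, h_e = -1, glc__D_c = 1, h_c = 1),
             kind = "transport"),
    reaction("GLCabc", c(glc__D_e = -1, atp_c = -1, h2o_c = -1, glc__D_c = 1,
                         adp_c = 1, pi_c = 1, h_c = 1),
             kind = "transport"),
    reaction("HEX1", c(glc__D_c = -1, atp_c = -1, g6p_c = 1, adp_c = 1, h_c = 1),
             kind = "metabolic", gpr = "E_glk"),
    # lumped glycolysis g6p -> 2 pep (net +1 ATP, +2 NADH), pyruvate kinase
    reaction("GLYC", c(g6p_c = -1, nad_c = -2, pi_c = -2, adp_c = -1,
                       pep_c = 2, nadh_c = 2, atp_c = 1, h2o_c = 2, h_c = 3),
             kind = "metabolic", gpr = "E_glyc"),
    reaction("PYK", c(pep_c = -1, adp_c = -1, h_c = -1, pyr_c = 1, atp_c = 1),
             kind = "metabolic", gpr = "E_pyk"),
    # mixed-acid branch
    reaction("PFL", c(pyr_c = -1, pi_c = -1, actp_c = 1, for_c = 1),
             kind = "metabolic", gpr = "E_pfl"),
    reaction("ACKr", c(actp_c = -1, adp_c = -1, ac_c = 1, atp_c = 1),
             lb = -1000, kind = "metabolic", gpr = "E_ack"),
    reaction("ADHE", c(actp_c = -1, nadh_c = -2, h_c = -2,
                       etoh_c = 1, pi_c = 1, nad_c = 2),
             kind = "metabolic", gpr = c("E_adhE", "E_adhA")),
    # lactate branch
    reaction("LDH_L", c(pyr_c = -1, nadh_c = -1, h_c = -1, lac__L_c = 1, nad_c = 1),
             kind = "metabolic", gpr = "E_ldh"),
    # pyruvate oxidase (aerobic; blocked under the default condition)
    reaction("POX", c(pyr_c = -1, pi_c = -1, o2_c = -1, h_c = -1,
                      actp_c = 1, co2_c = 1, h2o2_c = 1),
             kind = "metabolic"),
    # arginine deiminase pathway; net proton consumer
    reaction("ARGORNt7", c(arg__L_e = -1, orn_c = -1, arg__L_c = 1, orn_e = 1),
             kind = "transport", gpr = "E_anti"),
    # ATP-driven arginine import: the antiport alone permits no net
    # assimilation (each arginine in trades an ornithine out), so anabolic
    # arginine enters through an ABC system at ATP cost
    reaction("ARGabc", c(arg__L_e = -1, atp_c = -1, h2o_c = -1,
                         arg__L_c = 1, adp_c = 1, pi_c = 1, h_c = 1),
             kind = "transport"),
    reaction("ADI", c(arg__L_c = -1, h2o_c = -1, citr__L_c = 1, nh4_c = 1),
             kind = "metabolic", gpr = "E_adi"),
    reaction("OTC", c(citr__L_c = -1, pi_c = -1, h_c = -1, orn_c = 1, cbp_c = 1),
             kind = "metabolic", gpr = "E_otc"),
    reaction("CK", c(cbp_c = -1, adp_c = -1, h_c = -1, atp_c = 1, co2_c = 1,
                     nh3_c = 1),
             kind = "metabolic", gpr = "E_ck"),
    reaction("NH3pr", c(nh3_c = -1, h_c = -1, nh4_c = 1),
             kind = "metabolic", spontaneous = TRUE),
    # membrane ATP synthase, n_h protons translocated per ATP (reversible)
    reaction("ATPS", c(adp_c = -1, pi_c = -1, atp_c = 1, h2o_c = 1,
                       h_e = -n_h, h_c = n_h - 1),
             lb = -1000, kind = "metabolic", gpr = "E_atps"),
    # weak-acid proton symport (undissociated acid efflux); no gene
    # association in the toy reconstruction, so the dummy protein pays
    reaction("ACt", c(ac_c = -1, h_c = -1, ac_e = 1, h_e = 1), kind = "transport"),
    reaction("FORt", c(for_c = -1, h_c = -1, for_e = 1, h_e = 1), kind = "transport"),
    reaction("L_LACt", c(lac__L_c = -1, h_c = -1, lac__L_e = 1, h_e = 1),
             kind = "transport"),
    reaction("ETOHt", c(etoh_c = -1, etoh_e = 1), kind = "transport",
             spontaneous = TRUE),
    reaction("NH4t", c(nh4_c = -1, nh4_e = 1), kind = "transport",
             spontaneous = TRUE),
    reaction("NH3t", c(nh3_c = -1, nh3_e = 1), kind = "transport",
             spontaneous = TRUE),
    reaction("CO2t", c(co2_c = -1, co2_e = 1), kind = "transport",
             spontaneous = TRUE),
    reaction("O2t", c(o2_e = -1, o2_c = 1), kind = "transport",
             spontaneous = TRUE),
    reaction("PIt", c(pi_e = -1, pi_c = 1), kind = "transport"),
    reaction("H2O2t", c(h2o2_c = -1, h2o2_e = 1), kind = "transport",
             spontaneous = TRUE),
    reaction("H2Ot", c(h2o_e = -1, h2o_c = 1), lb = -1000, kind = "transport",
             spontaneous = TRUE),
    # nucleotide housekeeping
    reaction("ADK1", c(amp_c = -1, atp_c = -1, adp_c = 2), lb = -1000,
             kind = "metabolic", gpr = "E_adk"),
    # nucleotide supply: RNA dilution permanently drains the adenylate
    # moiety, which salvage of medium adenosine replenishes
    reaction("ADNt", c(adn_e = -1, adn_c = 1), kind = "transport",
             spontaneous = TRUE),
    reaction("ADNK", c(adn_c = -1, atp_c = -1, amp_c = 1, adp_c = 1, h_c = 1),
             kind = "metabolic"),
    reaction("PPA", c(ppi_c = -1, h2o_c = -1, pi_c = 2, h_c = 1),
             kind = "metabolic"),
    # non-growth-associated maintenance
    reaction("ATPM", c(atp_c = -1, h2o_c = -1, adp_c = 1, pi_c = 1, h_c = 1),
             lb = 1, kind = "maintenance", spontaneous = TRUE),
    # dilution of non-protein, non-RNA biomass; flux pinned to the growth rate
    reaction("BIOMASS", c(g6p_c = -0.35, atp_c = -2.5, h2o_c = -2.5,
                          adp_c = 2.5, pi_c = 2.5, h_c = 2.5),
             kind = "biomass", spontaneous = TRUE)
  )
  # amino-acid import (dummy-catalysed permeases) and exchanges
  for (a in setdiff(aa$aa, "arg")) {
    rxns <- c(rxns, list(
      reaction(paste0("AAt_", a),
               setNames(c(-1, 1), paste0(a, c("_e", "_c"))),
               kind = "transport")
    ))
  }
  ex <- function(met, lb = 0, ub = 1000) {
    reaction(paste0("EX_", met), setNames(-1, met), lb = lb, ub = ub,
             kind = "exchange", spontaneous = TRUE)
  }
  rxns <- c(rxns, list(
    ex("glc__D_e", lb = -1000), ex("lac__L_e"), ex("ac_e"), ex("for_e"),
    ex("etoh_e"), ex("co2_e"), ex("nh4_e"), ex("nh3_e"), ex("orn_e"),
    ex("h_e", lb = -1000), ex("h2o_e", lb = -1000), ex("o2_e", lb = -1000),
    ex("h2o2_e"), ex("arg__L_e", lb = -1000), ex("pi_e", lb = -1000),
    ex("adn_e", lb = -1000)
  ))
  for (a in setdiff(aa$aa, "arg")) rxns <- c(rxns, list(ex(paste0(a, "_e"), lb = -1000)))

  model <- sm_model(mets, rxns)

  # protein lengths (residues) and enzyme turnover numbers (1/s before the
  # x3600 conversion); the arginine pathway is deliberately the least
  # protein-efficient ATP route and lactate the most efficient, mirroring
  # the pathway ordering observed in lactococci
  plen <- c(P_pts = 450, P_glk = 320, P_glyc = 800, P_pyk = 470, P_pfl = 760,
            P_ack = 400, P_adhE = 870, P_adhA = 870, P_ldh = 320,
            P_anti = 470, P_adi = 410, P_otc = 340, P_ck = 310,
            atpA = 500, atpB = 460, P_adk = 220,
            dummy_protein = 300, unmodeled_protein = 300,
            rpl = 1750, rpoB = 1800)
  kcat_s <- c(GLCpts = 90, HEX1 = 150, GLYC = 60, PYK = 200, PFL = 25,
              ACKr = 700, ADHE = 50, LDH_L = 250, ARGORNt7 = 5, ADI = 4,
              OTC = 6, CK = 8, ATPS = 150, ADK1 = 300)
  if (!is.null(spec$seed)) {
    rs <- .seeded_rng(spec$seed)
    kcat_s <- kcat_s * (0.8 + 0.4 * rs$runif(length(kcat_s)))
  }
  kcat <- kcat_s * 3600

  kdeg <- 0.02
  proteins <- lapply(names(plen), function(p) {
    protein_spec(p, toy_aa_counts(plen[[p]]), k_deg = kdeg)
  })
  names(proteins) <- names(plen)

  enz <- function(id, subunits, rxn_ids) {
    enzyme_spec(id, subunits, setNames(kcat[rxn_ids], rxn_ids))
  }
  enzymes <- list(
    enz("E_pts", c(P_pts = 1), "GLCpts"),
    enz("E_glk", c(P_glk = 1), "HEX1"),
    enz("E_glyc", c(P_glyc = 1), "GLYC"),
    enz("E_pyk", c(P_pyk = 1), "PYK"),
    enz("E_pfl", c(P_pfl = 1), "PFL"),
    enz("E_ack", c(P_ack = 1), "ACKr"),
    enz("E_adhE", c(P_adhE = 1), "ADHE"),
    enz("E_adhA", c(P_adhA = 1), "ADHE"),
    enz("E_ldh", c(P_ldh = 1), "LDH_L"),
    enz("E_anti", c(P_anti = 1), "ARGORNt7"),
    enz("E_adi", c(P_adi = 1), "ADI"),
    enz("E_otc", c(P_otc = 1), "OTC"),
    enz("E_ck", c(P_ck = 1), "CK"),
    enz("E_atps", c(atpA = 3, atpB = 3), "ATPS"),
    enz("E_adk", c(P_adk = 1), "ADK1")
  )
  names(enzymes) <- vapply(enzymes, `[[`, character(1), "id")

  machineries <- c(
    # effective machinery rates fold initiation, maturation and idling
    # overhead into a single constant, so they sit well below peptide-bond
    # elongation speed; together with the budget they put the proteome
    # switch in the chemostat's upper growth-rate range
    list(machinery_spec("ribosome", rate = 2 * 3600,
                        composition = list(proteins = c(rpl = 4), rrna_length = 1500)),
         machinery_spec("rna_polymerase", rate = 5 * 3600,
                        composition = list(proteins = c(rpoB = 2)))),
    lapply(names(plen), function(p) {
      machinery_spec(paste0("mrna:", p), rate = 80, k_deg = 10)
    }),
    lapply(aa$aa, function(a) machinery_spec(paste0("trna:", a), rate = 6000))
  )
  names(machineries) <- vapply(machineries, `[[`, character(1), "id")

  budget <- proteome_budget(total_modeled_fraction = 0.13,
                            unmodeled_fraction = 0.4,
                            transporter_cap = 2.5e-5)

  # growth-rate-dependent upper bounds on amino-acid uptake,
  # uptake <= slope * mu + intercept (mmol/gCDW/h); the chemostat generator
  # emulates the same trends
  aa_uptake <- data.frame(
    aa = c("gly", "ala", "ser", "asp", "glu", "arg"),
    slope = c(1.0, 1.2, 1.5, 0.8, 1.0, 2.5),
    intercept = c(0.05, 0.05, 0.05, 0.03, 0.04, 0.10),
    stringsAsFactors = FALSE
  )

  list(
    model = model,
    proteins = proteins,
    enzymes = enzymes,
    machineries = machineries,
    budget = budget,
    kinetics = list(kcat = unname(kcat["GLCpts"]), KM = 0.25,
                    pts_rxn = "GLCpts", transporter = "E_pts"),
    aa_uptake = aa_uptake,
    config = expression_config(),
    block = c("EX_o2_e", "POX", "ADHE__E_adhA", "GLCt2", "GLCabc"),
    spec = spec
  )
}

# Lightweight reproducible RNG stream that does not disturb .Random.seed.
.seeded_rng <- function(seed) {
  env <- new.env()
  env$state <- as.double(seed %% 2147483647)
  nextu <- function() {
    # Lehmer / Park-Miller
    env$state <- (16807 * env$state) %% 2147483647
    env$state / 2147483647
  }
  list(runif = function(n) vapply(seq_len(n), function(i) nextu(), numeric(1)),
       rnorm = function(n) {
         u1 <- vapply(seq_len(n), function(i) nextu(), numeric(1))
         u2 <- vapply(seq_len(n), function(i) nextu(), numeric(1))
         sqrt(-2 * log(pmax(u1, 1e-12))) * cos(2 * pi * u2)
       })
}

#' Chemostat dilution rate
#'
#' @param feed_ml_per_min medium feed, ml/min.
#' @param volume_ml working volume, ml.
#' @return dilution rate D, 1/h.
#' @examples
#' chemostat_dilution_rate(2.25, 270)  # 0.5/h
#' @export
chemostat_dilution_rate <- function(feed_ml_per_min, volume_ml) {
  stopifnot(feed_ml_per_min > 0, volume_ml > 0)
  feed_ml_per_min * 60 / volume_ml
}

#' Simulate a glucose-limited chemostat amino-acid dataset
#'
#' True uptake of each amino acid is linear in growth rate (`a * mu + b`),
#' except aspartate and glutamate which follow saturating profiles as
#' non-linear negative controls. Supernatant concentrations are
#' back-computed through the steady-state flux relation
#' `q = D (C_supernatant - C_medium) / X` and perturbed with Gaussian noise
#' proportional to the concentration.
#'
#' @param seed integer seed; output is a pure function of the arguments.
#' @param n_rates number of dilution rates (evenly spaced in
#'   `range_D`), at least 2.
#' @param noise_sd relative measurement noise on concentrations (default 5%).
#' @param n_replicates replicate chemostats per dilution rate.
#' @param range_D dilution-rate range, 1/h.
#' @return list with `records` (data.frame: replicate, D, compound,
#'   C_medium, C_supernatant, X_biomass) and `truth` (data.frame of the
#'   generating parameters: compound, model, slope, intercept).
#' @export
make_chemostat_dataset <- function(seed = 1, n_rates = 6, noise_sd = 0.05,
                                   n_replicates = 1, range_D = c(0.1, 0.6)) {
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  stopifnot(n_rates >= 2, n_replicates >= 1)
  rng <- .seeded_rng(seed)
  aa <- aa_table()$aa
  D <- seq(range_D[1], range_D[2], length.out = n_rates)
  X <- 1.0  # gCDW/l

  slope <- setNames(0.3 + 2.2 * rng$runif(length(aa)), aa)
  intercept <- setNames(0.15 * rng$runif(length(aa)), aa)
  model_kind <- setNames(rep("linear", length(aa)), aa)
  model_kind[c("asp", "glu")] <- "saturating"
  qmax <- setNames(rep(NA_real_, length(aa)), aa)
  qmax[c("asp", "glu")] <- 0.3 + 0.4 * rng$runif(2)

  truth <- data.frame(compound = aa, model = model_kind[aa],
                      slope = unname(slope[aa]), intercept = unname(intercept[aa]),
                      qmax = unname(qmax[aa]), stringsAsFactors = FALSE)

  rows <- list()
  for (rep_i in seq_len(n_replicates)) {
    for (d in D) {
      for (a in aa) {
        q_up <- if (model_kind[[a]] == "linear") {
          slope[[a]] * d + intercept[[a]]
        } else {
          qmax[[a]] * d / (0.15 + d)  # saturating negative control
        }
        c_med <- 12
        c_sup <- max(c_med - q_up * X / d, 0)
        if (noise_sd > 0) {
          c_med <- max(c_med * (1 + noise_sd * rng$rnorm(1)), 0)
          c_sup <- max(c_sup * (1 + noise_sd * rng$rnorm(1)), 0)
        }
        rows[[length(rows) + 1]] <- data.frame(
          replicate = rep_i, D = d, compound = a,
          C_medium = c_med, C_supernatant = c_sup, X_biomass = X,
          stringsAsFactors = FALSE)
      }
    }
  }
  list(records = do.call(rbind, rows), truth = truth)
}

#' Exchange flux from chemostat measurements
#'
#' `q = D (C_supernatant - C_medium) / X_biomass`; negative values are
#' uptake (the compound is depleted relative to the fresh medium).
#'
#' @param D dilution rate, 1/h.
#' @param C_supernatant,C_medium concentrations, mM.
#' @param X_biomass biomass density, gCDW/l.
#' @return flux in mmol/gCDW/h, consumption negative.
#' @export
flux_from_chemostat <- function(D, C_supernatant, C_medium, X_biomass) {
  if (any(X_biomass <= 0)) stop("X_biomass must be positive")
  D * (C_supernatant - C_medium) / X_biomass
}

#' Fit growth-rate-dependent uptake bounds
#'
#' Ordinary least squares of uptake magnitude on dilution rate, per
#' compound, for compounds that are consumed (mean flux negative); secreted
#' compounds are excluded, mirroring how measured trendlines are used as
#' uptake bounds. Negative intercepts are clipped to 0 in the reported
#' bound (uptake bounds cannot be negative at mu = 0); the raw fit is kept.
#'
#' @param records chemostat record data.frame (see
#'   [make_chemostat_dataset()]).
#' @return data.frame: compound, slope, intercept (clipped), slope_se,
#'   intercept_raw, n.
#' @export
fit_uptake_bounds <- function(records) {
  if (length(unique(records$D)) < 2) {
    stop("at least two distinct dilution rates are required")
  }
  out <- list()
  for (a in unique(records$compound)) {
    rec <- records[records$compound == a, ]
    q <- flux_from_chemostat(rec$D, rec$C_supernatant, rec$C_medium, rec$X_biomass)
    if (mean(q) >= 0) next  # secreted (or inert): no uptake bound
    fit <- lm(I(-q) ~ D, data = data.frame(D = rec$D, q = q))
    cf <- coef(fit)
    # a noise-free dataset fits exactly; the standard errors are then zero
    se <- suppressWarnings(sqrt(diag(vcov(fit))))
    out[[a]] <- data.frame(
      compound = a, slope = unname(cf[2]),
      intercept = max(unname(cf[1]), 0),
      slope_se = unname(se[2]), intercept_raw = unname(cf[1]),
      n = nrow(rec), stringsAsFactors = FALSE)
  }
  if (length(out) == 0) return(NULL)
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Minimal transporter/catabolism/maintenance model
#'
#' A three-reaction micro-model used to validate the chemostat binary
#' search against its closed form: a Michaelis-Menten glucose transporter
#' with a fixed concentration cap, one catabolic reaction converting the
#' imported sugar into `yield` energy units, a maintenance demand, and a
#' biomass drain proportional to the growth rate. The minimal glucose
#' concentration has the closed form
#' `S_min = KM * q / (kcat * cap - q)` with
#' `q = (maintenance + growth_coef * mu) / yield`.
#'
#' @param kcat transporter turnover, 1/h.
#' @param KM Michaelis constant, mM.
#' @param cap transporter concentration bound, mmol/gCDW.
#' @param yield energy units per imported glucose.
#' @param maintenance maintenance demand, mmol/gCDW/h.
#' @param growth_coef energy units drained per unit growth rate.
#' @return a degenerate `pc_model` (no expression layer) accepted by
#'   [min_glucose_concentration()] and [max_growth_rate()].
#' @export
make_micro_pc <- function(kcat = 180000, KM = 0.25, cap = 5e-5,
                          yield = 2, maintenance = 1, growth_coef = 10) {
  mets <- list(
    metabolite("glc__D_e", "extracellular", comp(6, 12, 0, 6), 0),
    metabolite("x_c", "cytosol", comp(6, 12, 0, 6), 0),
    metabolite("y_c", "cytosol", comp(), 0)
  )
  rxns <- list(
    reaction("EX_glc__D_e", c(glc__D_e = -1), lb = -1000, kind = "exchange",
             spontaneous = TRUE),
    reaction("GLCT", c(glc__D_e = -1, x_c = 1), kind = "transport",
             spontaneous = TRUE),
    reaction("CATAB", setNames(c(-1, yield), c("x_c", "y_c")),
             kind = "metabolic", spontaneous = TRUE),
    reaction("MAINT", c(y_c = -1), lb = maintenance, kind = "maintenance",
             spontaneous = TRUE),
    reaction("BIO", setNames(-growth_coef, "y_c"), kind = "biomass",
             spontaneous = TRUE)
  )
  model <- split_reversible(sm_model(mets, rxns))
  structure(list(
    model = model,
    proteins = list(), enzymes = list(), machineries = list(),
    budget = list(total_modeled_fraction = NA_real_,
                  unmodeled_fraction = NA_real_, transporter_cap = cap),
    config = expression_config(),
    coupling = NULL, deg = NULL, dil = character(),
    species_unit = numeric(), protein_mass = numeric(),
    unmodeled = NULL,
    dummy = list(translation = "MAINT"),
    biomass = "BIO", atpm = "MAINT",
    glucose = list(kcat = kcat, KM = KM, pts_rxns = character(),
                   transporter_species = NULL,
                   uptake_rxn = "EX_glc__D_e_rev"),
    aa_uptake = NULL, block = NULL,
    micro = list(yield = yield, maintenance = maintenance,
                 growth_coef = growth_coef)
  ), class = "pc_model")
}

#' Closed-form minimal glucose concentration of the micro-model
#'
#' @param micro a [make_micro_pc()] model.
#' @param mu growth rate, 1/h.
#' @return S_min in mM (the Michaelis-Menten inversion).
#' @export
micro_S_min_closed_form <- function(micro, mu) {
  q <- (micro$micro$maintenance + micro$micro$growth_coef * mu) /
    micro$micro$yield
  qmax <- micro$glucose$kcat * micro$budget$transporter_cap
  if (q >= qmax) return(Inf)
  micro$glucose$KM * q / (qmax - q)
}
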
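# Reformulation operations and domain-type invariants.

test_that("elemental bookkeeping and peptide masses are consistent", {
  expect_equal(comp_mw(comp(C = 6, H = 12, O = 6)), 0.1801558, tolerance = 1e-4)
  ch <- peptide_chain(c(gly = 2, ala = 1))
  # 2 gly + 1 ala - 2 H2O
  expect_equal(unname(ch$composition[["C"]]), 7)
  expect_equal(unname(ch$composition[["N"]]), 3)
  expect_equal(ch$length, 3)
  expect_equal(ch$mw, 2 * 75.0666 / 1000 + 89.0932 / 1000 - 2 * 18.015 / 1000,
               tolerance = 1e-3)
  # molecular weight override must stay within 5% of the residue-mass sum
  expect_error(protein_spec("p", c(gly = 10), molecular_weight = 2),
               "inconsistent")
})

test_that("reversible splitting produces irreversible pairs and a net-flux map", {
  m <- sm_model(
    list(metabolite("a_c", "cytosol"), metabolite("b_c", "cytosol")),
    list(reaction("R", c(a_c = -1, b_c = 1), lb = -10, ub = 10,
                  kind = "metabolic", spontaneous = TRUE),
         reaction("F", c(a_c = -1, b_c = 1), lb = 0, ub = 10,
                  kind = "metabolic", spontaneous = TRUE)))
  sp <- split_reversible(m)
  expect_true(all(sp$rxns$lb >= 0))
  expect_setequal(sp$rxns$id, c("R", "R_rev", "F"))
  expect_equal(sp$rxns$ub[sp$rxns$id == "R_rev"], 10)
  expect_equal(unname(sp$S[, "R_rev"]), -unname(sp$S[, "R"]))
  # irreversible reaction untouched
  expect_false("F_rev" %in% sp$rxns$id)
  # net flux report: fwd 3, rev 0 -> net 3; fwd 1, rev 4 -> net -3
  v <- c(R = 3, R_rev = 0, F = 1)
  expect_equal(unname(net_fluxes(sp, v)[["R"]]), 3)
  v2 <- c(R = 1, R_rev = 4, F = 0)
  expect_equal(unname(net_fluxes(sp, v2)[["R"]]), -3)
  # splitting round-trip: net stoichiometry is preserved
  agg <- sapply(unique(sp$rxns$source_id), function(s) {
    cols <- sp$rxns$id[sp$rxns$source_id == s & sp$rxns$dir == "fwd"]
    rowSums(sp$S[, cols, drop = FALSE])
  })
  expect_equal(agg[, "R"], m$S[, "R"])
})

test_that("isozyme expansion copies reactions and dummy assignment fills gaps", {
  m <- sm_model(
    list(metabolite("a_c", "cytosol"), metabolite("b_c", "cytosol")),
    list(reaction("R", c(a_c = -1, b_c = 1), kind = "metabolic",
                  gpr = c("E1", "E2")),
         reaction("S1", c(a_c = -1, b_c = 1), kind = "metabolic", gpr = "E3"),
         reaction("NOG", c(a_c = -1, b_c = 1), kind = "metabolic"),
         reaction("SPONT", c(a_c = -1, b_c = 1), kind = "metabolic",
                  spontaneous = TRUE),
         reaction("EX_b_c", c(b_c = -1), kind = "exchange", spontaneous = TRUE)))
  si <- assign_dummy(split_isozymes(m))
  expect_setequal(si$rxns$id,
                  c("R__E1", "R__E2", "S1", "NOG", "SPONT", "EX_b_c"))
  expect_equal(si$rxns$catalyst_id[si$rxns$id == "R__E1"], "E1")
  expect_equal(si$rxns$catalyst_id[si$rxns$id == "S1"], "E3")
  expect_equal(si$rxns$catalyst_id[si$rxns$id == "NOG"], "dummy")
  expect_true(is.na(si$rxns$catalyst_id[si$rxns$id == "SPONT"]))
  expect_true(is.na(si$rxns$catalyst_id[si$rxns$id == "EX_b_c"]))
  # per-isozyme fluxes sum in reports
  v <- c(R__E1 = 1, R__E2 = 2, S1 = 0, NOG = 0, SPONT = 0, EX_b_c = 0)
  expect_equal(unname(net_fluxes(si, v)[["R"]]), 3)
})

test_that("protein cost is enzyme mass over turnover", {
  prot <- list(P = protein_spec("P", c(ala = 100)))
  e1 <- enzyme_spec("E", c(P = 1), c(R = 100))
  mw <- prot$P$molecular_weight
  expect_equal(protein_cost(e1, "R", prot), mw / 100)
  # doubling k_cat halves the cost
  e2 <- enzyme_spec("E", c(P = 1), c(R = 200))
  expect_equal(protein_cost(e2, "R", prot), protein_cost(e1, "R", prot) / 2)
  # realistic magnitudes: fast enzyme at 90000/h
  e3 <- enzyme_spec("E", c(P = 1), c(R = 90000))
  expect_equal(protein_cost(e3, "R", prot), mw / 90000)
  # enzyme mass is additive over subunits
  prot2 <- list(A = protein_spec("A", c(gly = 50)), B = protein_spec("B", c(glu = 70)))
  eAB <- enzyme_spec("C", c(A = 2, B = 1), c(R = 1))
  expect_equal(enzyme_mass(eAB, prot2),
               2 * prot2$A$molecular_weight + prot2$B$molecular_weight)
})

test_that("kcat lookup falls back from split and isozyme copies to the source id", {
  e <- enzyme_spec("E", c(P = 1), c(ACKr = 10, ACKr_rev = 4))
  expect_equal(pcfba:::enzyme_kcat(e, "ACKr"), 10)
  expect_equal(pcfba:::enzyme_kcat(e, "ACKr_rev"), 4)      # explicit override
  expect_equal(pcfba:::enzyme_kcat(e, "ACKr__E"), 10)      # isozyme copy
  e2 <- enzyme_spec("E", c(P = 1), c(R = 7))
  expect_equal(pcfba:::enzyme_kcat(e2, "R_rev"), 7)        # shared both ways
  expect_true(is.na(pcfba:::enzyme_kcat(e2, "OTHER")))
})

test_that("model validation enforces ids, bounds, balance and catalysts", {
  expect_error(sm_model(list(metabolite("a_c", "cytosol"),
                             metabolite("a_c", "cytosol")), list()),
               "duplicate")
  m <- sm_model(list(metabolite("a_c", "cytosol", comp(C = 1)),
                     metabolite("b_c", "cytosol", comp(C = 2))),
                list(reaction("R", c(a_c = -1, b_c = 1), kind = "metabolic",
                              spontaneous = TRUE)))
  expect_error(validate_sm_model(m), "unbalanced")
  m2 <- sm_model(list(metabolite("a_c", "cytosol", comp(C = 1)),
                      metabolite("b_c", "cytosol", comp(C = 1))),
                 list(reaction("R", c(a_c = -1, b_c = 1), kind = "metabolic")))
  expect_silent(validate_sm_model(m2))
  expect_error(validate_sm_model(m2, require_catalysts = TRUE), "uncatalysed")
})
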
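# The gene-expression layer: reaction stoichiometry, coupling metadata and
# mass bookkeeping of the proteome-coupled build.

test_that("translation consumes charged tRNAs and energy per residue", {
  pc <- pc_fixture()
  S <- pc$model$S
  sc <- pc$config$macro_unit
  p <- pc$proteins$P_ldh
  col <- S[, "TRL_P_ldh"]
  # one protein out, counts charged tRNAs in / uncharged out (scaled to the
  # protein's nmol unit)
  expect_equal(unname(col[["protein_P_ldh"]]), 1)
  for (a in names(p$aa_composition)) {
    cnt <- p$aa_composition[[a]]
    if (cnt == 0) next
    expect_equal(unname(col[[paste0("trnac_", a)]]), -cnt * sc)
    expect_equal(unname(col[[paste0("trna_", a)]]), cnt * sc)
  }
  # two ATP-equivalents per residue
  expect_equal(unname(col[["atp_c"]]),
               -pc$config$gtp_per_residue * p$length * sc)
})

test_that("enzyme formation consumes its subunits stoichiometrically", {
  pc <- pc_fixture()
  col <- pc$model$S[, "ENZF_E_atps"]
  expect_equal(unname(col[["protein_atpA"]]), -3)
  expect_equal(unname(col[["protein_atpB"]]), -3)
  expect_equal(unname(col[["enzyme_E_atps"]]), 1)
  # complex mass equals the subunit sum
  expect_equal(pc$protein_mass[["enzyme_E_atps"]],
               3 * pc$proteins$atpA$molecular_weight +
                 3 * pc$proteins$atpB$molecular_weight)
})

test_that("every catalysed reaction has a coupling row and a dilution route", {
  pc <- pc_fixture()
  rx <- pc$model$rxns
  catalysed <- rx$id[!is.na(rx$catalyst_id)]
  expect_true(all(catalysed %in% pc$coupling$rxn[pc$coupling$type == "enzyme"]))
  # every coupled species has a dilution reaction defining its concentration
  expect_true(all(pc$coupling$species %in% names(pc$dil)))
  # machinery couplings cover translation (ribosome + per-gene mRNA)
  trl <- grep("^TRL_", rx$id, value = TRUE)
  rib_rows <- pc$coupling[pc$coupling$ref == "ribosome", ]
  expect_true(all(trl %in% rib_rows$rxn))
})

test_that("a build without a required machinery or composition fails loudly", {
  toy <- toy_fixture()
  layer <- layer_fixture()
  mach <- toy$machineries
  mach[["mrna:P_ldh"]] <- NULL
  expect_error(
    build_expression_layer(layer$model, toy$proteins, layer$enzymes,
                           mach, toy$budget, toy$config),
    "mrna:P_ldh")
  prots <- toy$proteins
  prots$P_ldh$aa_composition <- NULL
  expect_error(
    build_expression_layer(layer$model, prots, layer$enzymes,
                           toy$machineries, toy$budget, toy$config),
    "P_ldh")
})

test_that("degradation coupling entries carry the protein constants", {
  pc <- pc_fixture()
  row <- pc$deg[pc$deg$species == "protein_P_pts", ]
  expect_equal(nrow(row), 1)
  expect_equal(row$kdeg, pc$proteins$P_pts$k_deg)
  # mRNA degradation coupled at the machinery constant
  mrow <- pc$deg[pc$deg$species == "mrna_P_pts", ]
  expect_equal(mrow$kdeg, pc$machineries[["mrna:P_pts"]]$k_deg)
})
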
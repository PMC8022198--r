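# Chemostat simulation: feasibility structure, coupling soundness,
# proteome accounting and the binary searches.

test_that("growth far beyond the achievable rate is infeasible", {
  pc <- pc_fixture()
  f <- pc_feasible(pc, 5, S = Inf, probe = TRUE)
  expect_false(f$feasible)
  # coupling coefficients are undefined at zero growth
  expect_error(assemble_pc_lp(pc, 0, 1), "mu must be positive")
})

test_that("a solved state satisfies coupling and closes the proteome budget", {
  pc <- pc_fixture()
  r <- solve_pc(pc, 0.3, S = Inf)
  expect_true(r$feasible)
  v <- r$fluxes
  conc <- r$concentrations
  rx <- pc$model$rxns
  # post-solve audit: v <= kcat [E] for every catalysed reaction
  for (i in which(!is.na(rx$catalyst_id))) {
    e <- pc$enzymes[[rx$catalyst_id[i]]]
    kc <- pcfba:::enzyme_kcat(e, rx$id[i], rx$source_id[i])
    if (rx$id[i] %in% pc$glucose$pts_rxns) kc <- kc * r$sigma
    cap <- kc * conc[[paste0("enzyme_", rx$catalyst_id[i])]]
    expect_lte(v[[rx$id[i]]], cap + 1e-6 * max(1, cap))
  }
  # steady-state degradation: v_deg = kdeg [species]
  for (i in seq_len(nrow(pc$deg))) {
    expect_equal(v[[pc$deg$rxn[i]]] * pc$species_unit[[pc$deg$species[i]]],
                 pc$deg$kdeg[i] * conc[[pc$deg$species[i]]],
                 tolerance = 1e-6)
  }
  # modeled proteome mass equals the budget exactly
  expect_equal(r$proteome$modeled, pc$budget$total_modeled_fraction,
               tolerance = 1e-6)
  # inactive enzyme is nonnegative and here (low growth) strictly positive
  expect_gt(r$inactive, 0)
  # unmodeled protein pinned to its share
  expect_equal(r$concentrations[[pc$unmodeled$species]] * pc$unmodeled$mw,
               pc$unmodeled$mass_target, tolerance = 1e-6)
})

test_that("the chemostat search matches the micro-model closed form", {
  mic <- make_micro_pc()
  for (mu in c(0.1, 0.45)) {
    sm <- min_glucose_concentration(mic, mu, tol = 1e-7)
    expect_equal(sm$S_min, micro_S_min_closed_form(mic, mu),
                 tolerance = 1e-6)
  }
  # a growth rate beyond the transporter's saturated capacity is unreachable
  expect_error(min_glucose_concentration(mic, 3), "unreachable")
})

test_that("residual glucose and transporter saturation rise with growth rate", {
  pc <- pc_fixture()
  mus <- c(0.2, 0.35, 0.5)
  out <- lapply(mus, function(m) min_glucose_concentration(pc, m, tol = 1e-4))
  S <- vapply(out, `[[`, numeric(1), "S_min")
  sig <- vapply(out, `[[`, numeric(1), "sigma")
  expect_false(is.unsorted(S))
  expect_false(is.unsorted(sig))
  expect_true(all(sig >= 0 & sig < 1))
  # at S_min the uptake equals the Michaelis-Menten bound at the cap
  r <- out[[2]]$result
  if (!is.null(r)) {
    bound <- pc$glucose$kcat * pc$budget$transporter_cap * r$sigma
    expect_equal(-r$exchange[["glc__D_e"]], bound, tolerance = 0.05)
  }
})

test_that("maximal growth rate brackets are consistent and proteome-limited", {
  pc <- pc_fixture()
  mm <- cached("mumax_rich", function() max_growth_rate(pc_fixture(), S = Inf,
                                                        tol = 1e-3))
  expect_gt(mm$mu_max, 0.4)
  expect_lt(mm$mu_max, 0.7)
  expect_false(pc_feasible(pc, mm$mu_max * 1.05, S = Inf, probe = TRUE)$feasible)
  expect_true(pc_feasible(pc, mm$mu_max * 0.9, S = Inf, probe = TRUE)$feasible)
  # at the top of the chemostat curve the inactive enzyme is exhausted
  if (!is.null(mm$result)) {
    expect_lt(mm$result$inactive, 0.05 * pc$budget$total_modeled_fraction)
  }
})

test_that("transporter-cap calibration reproduces the documented procedure", {
  mic <- make_micro_pc()
  # with the cap released the micro model's growth is capped by nothing,
  # so calibration is exercised on the full toy model at coarse tolerance
  pc <- pc_fixture()
  pc2 <- calibrate_transporter_cap(pc, tol = 0.02)
  cal <- attr(pc2, "calibration")
  expect_true(is.finite(pc2$budget$transporter_cap))
  expect_gt(pc2$budget$transporter_cap, 0)
  expect_gt(cal$mu_max, 0)
  # the calibrated model still grows: the cap admits its own mu_max
  expect_true(pc_feasible(pc2, cal$mu_max * 0.8, S = Inf,
                          probe = TRUE)$feasible)
})
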
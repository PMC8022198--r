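# Synthetic-data generators: the fermentative toy network and the
# simulated chemostat dataset.

test_that("the toy network balances every internal reaction exactly", {
  toy <- toy_fixture()
  expect_equal(nrow(check_balance(toy$model)), 0)
  # the proteome-coupled build stays balanced (dilutions cross the boundary)
  pc <- pc_fixture()
  bal <- check_balance(pc$model, tol = 1e-6)
  bal <- bal[!grepl("^DIL_", bal$reaction), ]
  expect_equal(nrow(bal), 0)
})

test_that("pathway yields of the toy network match their hand derivations", {
  params <- params_fixture()
  # mixed acid: 2 glycolytic ATP + 1 acetate kinase, ethanol branch
  # reoxidizes the 2 NADH -> 3 ATP per glucose
  expect_equal(params$Y[1], 3, tolerance = 1e-6)
  # homolactic: the 2 substrate-level ATP only
  expect_equal(params$Y[2], 2, tolerance = 1e-6)
  # arginine deiminase: 1 carbamate kinase ATP + 2 protons at 3 H+/ATP
  expect_equal(params$Y[3], 5 / 3, tolerance = 1e-6)
  # protein-efficiency ordering that drives the phase structure
  expect_true(params$e[2] > params$e[1] && params$e[1] > params$e[3])
})

test_that("ATP synthase stoichiometry controls the proton credit", {
  toy4 <- make_toy_network(toy_network_spec(atpase_h_per_atp = 4))
  y4 <- arginine_atp_yield(toy4)
  # 1 + 2/4 when four protons are translocated per ATP
  expect_equal(y4, 1.5, tolerance = 1e-6)
})

test_that("chemostat dataset is a pure function of its arguments", {
  d1 <- make_chemostat_dataset(seed = 7, n_rates = 4, noise_sd = 0.05)
  d2 <- make_chemostat_dataset(seed = 7, n_rates = 4, noise_sd = 0.05)
  expect_identical(d1, d2)
  d3 <- make_chemostat_dataset(seed = 8, n_rates = 4, noise_sd = 0.05)
  expect_false(identical(d1$records$C_supernatant, d3$records$C_supernatant))
  expect_error(make_chemostat_dataset(noise_sd = -1), "nonnegative")
})

test_that("exchange-flux arithmetic and the dilution rate follow their formulas", {
  # q = D (C_sup - C_med) / X: depletion means uptake (negative)
  expect_equal(flux_from_chemostat(0.5, 2, 10, 1), -4)
  expect_equal(flux_from_chemostat(0.5, 10, 10, 1), 0)
  expect_error(flux_from_chemostat(0.5, 2, 10, 0), "positive")
  # 2.25 ml/min into a 270 ml working volume
  expect_equal(chemostat_dilution_rate(2.25, 270), 0.5)
})

test_that("uptake-bound fitting recovers noise-free trends and skips secretion", {
  d <- make_chemostat_dataset(seed = 3, n_rates = 5, noise_sd = 0)
  fit <- fit_uptake_bounds(d$records)
  lin <- d$truth[d$truth$model == "linear", ]
  for (i in seq_len(nrow(lin))) {
    row <- fit[fit$compound == lin$compound[i], ]
    expect_equal(row$slope, lin$slope[i], tolerance = 1e-6)
    expect_equal(row$intercept, lin$intercept[i], tolerance = 1e-6)
  }
  # a secreted compound yields no uptake bound
  rec <- data.frame(replicate = 1, D = c(0.2, 0.4),
                    compound = "waste", C_medium = c(0, 0),
                    C_supernatant = c(5, 5), X_biomass = 1)
  expect_null(fit_uptake_bounds(rec)$compound)
  # single dilution rate is rejected
  expect_error(fit_uptake_bounds(rec[1, ]), "two distinct")
  # a negative intercept is clipped in the reported bound
  rec2 <- data.frame(replicate = 1, D = c(0.2, 0.4, 0.6), compound = "aa",
                     C_medium = 10,
                     C_supernatant = 10 - pmax(0.5 * c(0.2, 0.4, 0.6) - 0.05, 0) /
                       c(0.2, 0.4, 0.6),
                     X_biomass = 1)
  f2 <- fit_uptake_bounds(rec2)
  expect_gte(f2$intercept, 0)
})

test_that("seeded turnover variants perturb within the stated band", {
  toy_a <- make_toy_network(toy_network_spec(seed = 5))
  toy_b <- make_toy_network(toy_network_spec(seed = 5))
  toy_c <- make_toy_network(toy_network_spec(seed = 6))
  ka <- toy_a$enzymes$E_pts$kcat[["GLCpts"]]
  expect_identical(ka, toy_b$enzymes$E_pts$kcat[["GLCpts"]])
  expect_false(identical(ka, toy_c$enzymes$E_pts$kcat[["GLCpts"]]))
  k0 <- toy_fixture()$enzymes$E_pts$kcat[["GLCpts"]]
  expect_true(ka >= 0.8 * k0 && ka <= 1.2 * k0)
})
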
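# Reduced-cost and sensitivity machinery on the coupled model.

test_that("arginine uptake is the active bound at low growth; others have slack", {
  pc <- pc_fixture()
  sm <- chemostat_point_fixture()
  cond <- list(mu = 0.3, S = sm$S_min)
  rc_arg <- scaled_reduced_cost(pc, cond, "arg", tol = 1e-3)
  expect_gt(rc_arg$R, 0)
  # an amino acid only used for protein synthesis sits below its bound
  rc_gly <- scaled_reduced_cost(pc, cond, "gly", tol = 1e-3)
  expect_equal(rc_gly$R, 0, tolerance = 1e-6)
  expect_error(scaled_reduced_cost(pc, cond, "nosuch"), "unknown")
})

test_that("structural sensitivities flip between the two regimes", {
  pc <- pc_fixture()
  sm <- chemostat_point_fixture()
  lim <- list(mu = 0.3, S = sm$S_min)
  # glucose-limited: the transporter is the active constraint, the proteome
  # has slack (inactive enzyme is positive)
  expect_gt(sensitivity_score(pc, lim, "transporter_cap", tol = 1e-3)$score, 0)
  expect_equal(sensitivity_score(pc, lim, "proteome", tol = 1e-3)$score, 0,
               tolerance = 1e-6)
  # saturating glucose at mu_max: the proteome becomes limiting
  rich <- list(mu = 0.5, S = Inf)
  expect_gt(sensitivity_score(pc, rich, "proteome", tol = 1e-3)$score, 0)
})

test_that("relaxing a bound never lowers the achievable growth rate", {
  pc <- pc_fixture()
  sm <- chemostat_point_fixture()
  base <- max_growth_rate(pc, S = sm$S_min, tol = 1e-3)
  for (dq in c(0.05, 0.2)) {
    pc2 <- pc
    pc2$aa_uptake$intercept <- pc2$aa_uptake$intercept + dq
    up <- max_growth_rate(pc2, S = sm$S_min, tol = 1e-3)
    expect_gte(up$mu_max, base$mu_max - 2e-3)
  }
})

test_that("the robustness scan covers each parameter twice and spares idle ones", {
  pc <- pc_fixture()
  sm <- chemostat_point_fixture()
  pars <- data.frame(
    type = c("kcat", "kcat", "budget"),
    id = c("E_pts", "E_adhA", "transporter_cap"),
    key = c("GLCpts", "ADHE", ""),
    stringsAsFactors = FALSE)
  scan <- robustness_scan(pc,
                          conditions = list(limited = list(mu = 0.3,
                                                           S = sm$S_min)),
                          parameters = pars, tol = 1e-3)
  expect_equal(nrow(scan), 2 * nrow(pars))
  # the blocked isozyme carries no flux: varying its turnover changes nothing
  idle <- scan[scan$id == "E_adhA", ]
  expect_true(all(abs(idle$rel_change) < 1e-3))
  # halving the glucose transporter turnover slows glucose-limited growth
  pts <- scan[scan$id == "E_pts" & scan$direction == "x0.5", ]
  expect_lt(pts$rel_change, -0.01)
  expect_true(pts$flagged)
})

test_that("parameter accessors round-trip every scannable entry", {
  pc <- pc_fixture()
  pars <- pcfba:::pc_parameters(pc)
  expect_true(all(c("kcat", "kdeg", "machinery_rate", "budget") %in% pars$type))
  for (i in sample(nrow(pars), 10)) {
    p <- pars[i, ]
    v0 <- pcfba:::pc_get_param(pc, p$type, p$id, p$key)
    pc2 <- pc_set_param(pc, p$type, p$id, v0 * 2, p$key)
    expect_equal(pcfba:::pc_get_param(pc2, p$type, p$id, p$key), v0 * 2)
  }
})
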
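# The three-pathway ATP allocation model.

test_that("the allocation LP matches the analytic vertex solution", {
  cases <- random_small_params(100)
  for (cs in cases) {
    lp <- solve_small_model(cs$params, cs$Jglc)
    an <- solve_small_model_analytic(cs$params, cs$Jglc)
    expect_equal(lp$J_ATP, an$J_ATP, tolerance = 1e-8)
    expect_lt(max(abs(lp$J - an$J)), 1e-7 * max(1, max(abs(an$J))))
    # glucose routing closes and the cap is respected
    expect_equal(unname(lp$J[["J1"]] + lp$J[["J2"]]), cs$Jglc, tolerance = 1e-8)
    expect_gte(lp$inactive, -1e-9)
  }
})

test_that("limiting regimes of the allocation LP behave as expected", {
  p <- small_model_params(Y = c(3, 2, 5 / 3), p = c(3e-3, 1e-3, 9e-3),
                          P = 1e6, alpha = 0.15, beta = 0)
  # unconstrained proteome: highest-yield pathway takes all glucose and the
  # arginine bound is filled
  s <- solve_small_model(p, 10)
  expect_equal(unname(s$J[["J1"]]), 10, tolerance = 1e-6)
  expect_equal(unname(s$J[["J2"]]), 0, tolerance = 1e-6)
  expect_equal(unname(s$J[["J3"]]), 1.5, tolerance = 1e-6)
  # no substrate at zero intercept: everything is zero
  s0 <- solve_small_model(p, 0)
  expect_equal(unname(s0$J_ATP), 0, tolerance = 1e-9)
  # over-capacity glucose is reported with the sustainable maximum
  p2 <- small_model_params(Y = c(3, 2, 5 / 3), p = c(3e-3, 1e-3, 9e-3),
                           P = 0.05, alpha = 0.15, beta = 0)
  expect_error(solve_small_model(p2, 100), "maximum sustainable")
})

test_that("phase scan yields contiguous A/B/C with the documented onsets", {
  params <- params_fixture()
  scan <- phase_scan(params, seq(0.5, 30, length.out = 150))
  runs <- rle(scan$phase)
  expect_equal(runs$values, c("A", "B", "C"))
  # the arginine decline starts where the inactive proteome vanishes (a
  # grid point may land exactly on the kink, hence the one-step latitude)
  bstart <- which(scan$phase == "B")[1]
  first_zero <- which(scan$inactive <= 1e-6)[1]
  expect_lt(scan$inactive[bstart], 1e-6)
  expect_lte(abs(bstart - first_zero), 1)
  # the arginine decline strictly precedes the mixed-acid decline
  first_d3 <- which(diff(scan$J3) < -1e-9)[1]
  first_d1 <- which(diff(scan$J1) < -1e-9)[1]
  expect_lt(first_d3, first_d1)
  # ATP production never decreases along the grid
  expect_true(all(diff(scan$J_ATP) > -1e-8))
})

test_that("raising the arginine efficiency above mixed acid inverts the order", {
  params <- params_fixture()
  p2 <- small_model_params(Y = params$Y,
                           p = c(params$p[1], params$p[2], params$p[3] / 60),
                           P = params$P, alpha = params$alpha, beta = params$beta)
  expect_gt(p2$e[3], p2$e[1])
  scan <- suppressWarnings(phase_scan(p2, seq(0.5, 30, length.out = 120)))
  first_d3 <- which(diff(scan$J3) < -1e-9)[1]
  first_d1 <- which(diff(scan$J1) < -1e-9)[1]
  # now pathway 1 is sacrificed before arginine
  expect_true(is.na(first_d3) || first_d1 < first_d3)
})

test_that("sensitivities switch with the phases and satisfy the scaling identity", {
  params <- params_fixture()
  scan <- phase_scan(params, seq(0.5, 30, length.out = 60))
  gA <- scan$Jglc[which(scan$phase == "A")[2]]
  gC <- utils::tail(scan$Jglc[scan$phase == "C"], 2)[1]
  # phase A: glucose and arginine matter, proteome does not
  expect_gt(small_model_sensitivity(params, gA, "glucose"), 0)
  expect_gt(small_model_sensitivity(params, gA, "arginine"), 0)
  expect_equal(small_model_sensitivity(params, gA, "proteome"), 0,
               tolerance = 1e-9)
  # phase C: the proteome is the active constraint
  expect_gt(small_model_sensitivity(params, gC, "proteome"), 0)
  # degree-1 homogeneity in (Jglc, P, U3): relative sensitivities sum to 1
  for (g in c(gA, gC)) {
    ssum <- sum(vapply(c("glucose", "proteome", "arginine"), function(cn) {
      small_model_sensitivity(params, g, cn, dc = 1e-4)
    }, numeric(1)))
    expect_equal(ssum, 1, tolerance = 0.02)
  }
  # local linearity: halving / doubling the perturbation moves scores < 20%
  s1 <- small_model_sensitivity(params, gC, "proteome", dc = 0.005)
  s2 <- small_model_sensitivity(params, gC, "proteome", dc = 0.01)
  s3 <- small_model_sensitivity(params, gC, "proteome", dc = 0.02)
  expect_lt(abs(s1 - s2) / s2, 0.2)
  expect_lt(abs(s3 - s2) / s2, 0.2)
})

test_that("twofold parameter variation preserves the arginine-shift mechanism", {
  params <- params_fixture()
  rob <- small_model_robustness(params)
  expect_equal(nrow(rob), 2 * 5)      # p1, p2, p3, P, alpha; beta = 0 skipped
  ok <- rob$arg_declines & !is.na(rob$arg_declines)
  expect_true(all(rob$decline_in_limited_regime[ok]))
  # the decline itself occurs in nearly all variants
  expect_gte(sum(ok), nrow(rob) - 2)
})

test_that("equal-efficiency ties resolve toward lactate deterministically", {
  # e1 == e2 exactly: analytic tie-break must prefer the lactate pathway
  p <- small_model_params(Y = c(3, 2, 1), p = c(3e-3, 2e-3, 5e-3), P = 1e-2,
                          alpha = 0, beta = 0)
  expect_equal(p$e[1], p$e[2])
  g <- 0.9 * p$P / min(p$p[1:2])
  an <- solve_small_model_analytic(p, g)
  expect_gt(an$J[["J2"]], an$J[["J1"]])
})
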
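# The LP engine: hand-derived optima, optimality certificates (primal
# feasibility + dual feasibility + zero gap, checked by plain arithmetic),
# finite-difference duals, and a lower-bound cross-check against
# boot::simplex restricted to points verified feasible.

test_that("hand-derived optima are reproduced by both engines", {
  # max x1 + 2 x2 s.t. x1 + x2 <= 4, x2 <= 3  ->  x = (1, 3), obj = 7
  A <- rbind(c(1, 1), c(0, 1))
  for (method in c("simplex", "ipm")) {
    r <- solve_lp(c(1, 2), A, c(4, 3), c("<=", "<="), method = method)
    expect_equal(r$status, "optimal")
    expect_equal(r$objective, 7, tolerance = 1e-6)
    expect_equal(unname(r$x), c(1, 3), tolerance = 1e-5)
  }
  # min x1 + x2 s.t. x1 + 2 x2 >= 4, 3 x1 + x2 >= 3 -> x = (2/5, 9/5), obj 11/5
  A2 <- rbind(c(1, 2), c(3, 1))
  r2 <- solve_lp(c(1, 1), A2, c(4, 3), c(">=", ">="), maximize = FALSE)
  expect_equal(r2$objective, 11 / 5, tolerance = 1e-6)
  # infeasible: x1 <= 1 and x1 >= 2
  r3 <- solve_lp(1, rbind(1, 1), c(1, 2), c("<=", ">="))
  expect_equal(r3$status, "infeasible")
  # unbounded: max x1, no constraint binds
  r4 <- solve_lp(1, matrix(-1, 1, 1), 0, "<=")
  expect_equal(r4$status, "unbounded")
})

test_that("random LPs terminate with a verifiable optimality certificate", {
  set.seed(7)
  n_checked <- 0
  for (k in 1:120) {
    m <- sample(2:10, 1); n <- sample(2:10, 1)
    A <- matrix(round(rnorm(m * n), 2), m, n)
    x0 <- runif(n)
    b <- as.numeric(A %*% x0) + round(runif(m, 0.05, 2), 2)
    cc <- round(rnorm(n), 2)
    r <- solve_lp(cc, A, b, rep("<=", m))
    if (r$status != "optimal") next
    n_checked <- n_checked + 1
    scale <- 1 + abs(r$objective)
    # primal feasibility
    expect_true(all(A %*% r$x - b <= 1e-6 * scale))
    expect_true(all(r$x >= -1e-7))
    # dual feasibility for max c'x, Ax <= b, x >= 0: y >= 0, A'y >= c
    # (interior-point duals carry the termination tolerance)
    y <- r$duals
    expect_true(all(y >= -1e-5 * scale))
    expect_true(all(t(A) %*% y - cc >= -1e-5 * scale))
    # duality gap closes to the solver tolerance
    expect_equal(sum(b * y), r$objective, tolerance = 1e-4 * scale)
  }
  expect_gt(n_checked, 50)
})

test_that("duals match finite differences of the optimum", {
  # at degenerate optima the dual is set-valued and a one-sided finite
  # difference picks one subgradient, so agreement is asserted in bulk
  set.seed(11)
  n_match <- 0; n_tot <- 0
  for (k in 1:20) {
    m <- 5; n <- 5
    A <- matrix(rnorm(m * n), m, n)
    b <- as.numeric(A %*% runif(n)) + runif(m, 0.1, 1)
    cc <- rnorm(n)
    r <- solve_lp(cc, A, b, rep("<=", m))
    if (r$status != "optimal") next
    for (i in 1:m) {
      b2 <- b; b2[i] <- b[i] + 1e-5
      r2 <- solve_lp(cc, A, b2, rep("<=", m))
      if (r2$status != "optimal") next
      fd <- (r2$objective - r$objective) / 1e-5
      n_tot <- n_tot + 1
      if (abs(fd - unname(r$duals[i])) <= 1e-3 * max(1, abs(fd))) {
        n_match <- n_match + 1
      }
    }
  }
  expect_gt(n_tot, 50)
  expect_gte(n_match / n_tot, 0.95)
})

test_that("independent simplex route never exceeds our optimum", {
  # boot::simplex sometimes returns points violating its own constraints;
  # whenever its point *is* feasible it lower-bounds the true maximum
  set.seed(3)
  n_used <- 0
  for (k in 1:60) {
    m <- sample(2:8, 1); n <- sample(2:8, 1)
    A <- matrix(round(rnorm(m * n), 2), m, n)
    b <- as.numeric(A %*% runif(n)) + round(runif(m, 0.1, 2), 2)
    cc <- round(rnorm(n), 2)
    r <- solve_lp(cc, A, b, rep("<=", m))
    if (r$status != "optimal") next
    s <- tryCatch(boot::simplex(a = cc, A1 = A, b1 = b, maxi = TRUE),
                  error = function(e) NULL)
    if (is.null(s) || s$solved != 1) next
    feas <- all(A %*% s$soln - b <= 1e-7) && all(s$soln >= -1e-9)
    if (!feas) next
    n_used <- n_used + 1
    expect_gte(r$objective + 1e-5 * max(1, abs(r$objective)), s$value)
  }
  expect_gt(n_used, 10)
})

test_that("interior point and simplex agree on equality-constrained programs", {
  set.seed(19)
  for (k in 1:25) {
    m <- sample(2:6, 1); n <- m + sample(1:4, 1)
    A <- matrix(rnorm(m * n), m, n)
    b <- as.numeric(A %*% runif(n))
    cc <- rnorm(n)
    r1 <- solve_lp(cc, A, b, rep("=", m), method = "simplex")
    r2 <- solve_lp(cc, A, b, rep("=", m), method = "ipm")
    if (r1$status == "optimal" && r2$status == "optimal") {
      expect_equal(r1$objective, r2$objective,
                   tolerance = 1e-5 * max(1, abs(r1$objective)))
    }
  }
})
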
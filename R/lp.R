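#' Solve a linear program
#'
#' Dense two-phase simplex over nonnegative variables. This is the LP engine
#' used by every simulation and analysis in the package; it is exposed because
#' proteome-coupled models are easy to inspect as explicit constraint systems.
#'
#' The problem solved is `max/min obj'x` subject to `A x (<=|=|>=) b`, `x >= 0`.
#' Rows and columns are equilibrated (max-magnitude scaling) before the solve,
#' which matters for coupling constraints whose coefficients mix turnover
#' numbers (~1e5/h) with fluxes (~1 mmol/gCDW/h).
#'
#' @param obj numeric objective coefficients (length n).
#' @param A dense constraint matrix (m x n).
#' @param b right-hand sides (length m).
#' @param dir character vector of `"<="`, `"="`, `">="` (length m).
#' @param maximize maximize (default) or minimize.
#' @param scale equilibrate rows and columns before solving.
#' @param max_iter simplex iteration cap.
#' @param feasible_only report only feasibility (`status` is `"optimal"`
#'   when a feasible point exists); the objective is ignored.
#' @param method `"auto"` (interior point, simplex fallback), `"ipm"`
#'   (homogeneous self-dual Mehrotra interior point; indifferent to the
#'   massive degeneracy of flux-balance programs), or `"simplex"` (revised
#'   simplex with refactorization; exact vertex solutions, used as the
#'   independent cross-check route).
#' @return A list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`,
#'   `"iteration_limit"`), `objective`, the primal solution `x` (named if `A`
#'   has column names), and the row `duals` (sign convention: d objective /
#'   d b, for the problem as posed).
#' @examples
#' # max x1 + 2 x2 s.t. x1 + x2 <= 4, x2 <= 3
#' solve_lp(c(1, 2), rbind(c(1, 1), c(0, 1)), c(4, 3), c("<=", "<="))
#' @export
solve_lp <- function(obj, A, b, dir, maximize = TRUE, scale = TRUE,
                     max_iter = NULL, feasible_only = FALSE,
                     method = c("auto", "ipm", "simplex")) {
  method <- match.arg(method)
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(obj) == n, length(b) == m, length(dir) == m)
  if (!all(dir %in% c("<=", "=", ">="))) {
    stop("dir must be one of '<=', '=', '>='")
  }
  dcode <- ifelse(dir == "<=", -1L, ifelse(dir == "=", 0L, 1L))
  if (is.null(max_iter)) max_iter <- max(2000L, 60L * (m + n))

  rs <- rep(1, m); cs <- rep(1, n)
  As <- A; bs <- b; cs_obj <- obj
  if (scale && m > 0 && n > 0) {
    # iterated geometric-mean equilibration, then a max-norm polish
    geo <- function(M, margin) {
      apply(M, margin, function(z) {
        nz <- abs(z[z != 0])
        if (!length(nz)) 1 else sqrt(max(nz) * min(nz))
      })
    }
    for (pass in 1:2) {
      r1 <- geo(As, 1); r1[!is.finite(r1) | r1 == 0] <- 1
      As <- As / r1; rs <- rs * r1
      c1 <- geo(As, 2); c1[!is.finite(c1) | c1 == 0] <- 1
      As <- sweep(As, 2, c1, "/"); cs <- cs * c1
    }
    r1 <- apply(abs(As), 1, max); r1[!is.finite(r1) | r1 == 0] <- 1
    As <- As / r1; rs <- rs * r1
    bs <- b / rs
    cs_obj <- obj / cs
  }

  if (feasible_only) cs_obj <- numeric(length(cs_obj))
  res <- NULL
  # small programs: the simplex is exact and fast; the interior point's
  # tolerance-limited feasibility verdict is only worth it at scale
  if (method == "auto" && feasible_only && m < 100) method <- "simplex"
  if (method %in% c("auto", "ipm")) {
    res <- .ipm_core(As, bs, cs_obj, dcode, maximize,
                     if (feasible_only) 100L else 80L, 1e-9)
    if (method == "auto" && res$status == 3L) res <- NULL
  }
  if (is.null(res)) {
    res <- .simplex_core(As, bs, cs_obj, dcode, maximize, as.integer(max_iter),
                         isTRUE(feasible_only))
  }
  status <- c("optimal", "infeasible", "unbounded", "iteration_limit")[res$status + 1L]
  x <- res$x / cs
  names(x) <- colnames(A)
  duals <- res$duals / rs
  names(duals) <- rownames(A)
  objective <- if (status == "optimal" && !feasible_only) sum(obj * x) else NA_real_
  list(status = status, objective = objective, x = x, duals = duals,
       iterations = res$iterations, phase1 = res$phase1)
}
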
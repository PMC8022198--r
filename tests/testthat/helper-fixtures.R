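# Shared fixtures, built lazily and cached for the whole test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

toy_fixture <- function() cached("toy", function() make_toy_network())

layer_fixture <- function() cached("layer", function() metabolic_layer(toy_fixture()))

pc_fixture <- function() cached("pc", function() make_toy_pc(toy_fixture()))

params_fixture <- function() cached("params", function() {
  estimate_pathway_params(layer_fixture())
})

# a solved glucose-limited chemostat point at mu = 0.3 (reused widely)
chemostat_point_fixture <- function() cached("chemo03", function() {
  min_glucose_concentration(pc_fixture(), 0.3, tol = 1e-4)
})

# random small-model parameter sets drawn reproducibly
random_small_params <- function(n, seed = 421) {
  rng <- pcfba:::.seeded_rng(seed)
  lapply(seq_len(n), function(i) {
    Y <- sort(0.5 + 3.5 * rng$runif(3), decreasing = TRUE)    # Y1 > Y2 > Y3
    p <- 10^(-3.5 + 1.5 * rng$runif(3))
    P <- 0.02 + 0.1 * rng$runif(1)
    alpha <- 0.3 * rng$runif(1)
    beta <- if (rng$runif(1) < 0.5) 0 else 0.5 * rng$runif(1)
    list(params = small_model_params(Y, p, P, alpha, beta),
         Jglc = 0.95 * P / min(p[1], p[2]) * rng$runif(1))
  })
}
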
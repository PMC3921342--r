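# shared fixtures, all built in code

# n1 x n2 grid of unit squares, row-major
grid_map <- function(n1, n2) {
  polys <- list()
  for (r in seq_len(n1)) for (c in seq_len(n2))
    polys[[length(polys) + 1L]] <-
      cbind(c(c - 1, c, c, c - 1), c(r - 1, r - 1, r, r))
  area_map(sprintf("G%02d", seq_len(n1 * n2)), polys)
}

# independent rook-adjacency oracle for a grid: enumerate cell pairs sharing
# a full edge from (row, col) arithmetic
grid_rook_oracle <- function(n1, n2) {
  nb <- vector("list", n1 * n2)
  idx <- function(r, c) (r - 1) * n2 + c
  for (r in seq_len(n1)) for (c in seq_len(n2)) {
    i <- idx(r, c)
    cand <- list(c(r - 1, c), c(r + 1, c), c(r, c - 1), c(r, c + 1))
    nb[[i]] <- sort(vapply(Filter(function(x)
      x[1] >= 1 && x[1] <= n1 && x[2] >= 1 && x[2] <= n2, cand),
      function(x) idx(x[1], x[2]), numeric(1)))
  }
  nb
}

# small synthetic BYM fit reused by several tests (cheap chains)
small_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- simulation_spec(n_areas = 30, beta = c(0.5),
                              survey_size_range = c(80L, 120L), seed = 5)
      ds <- simulate_dataset(spec)
      fit <- fit_bym(ds$outcomes, ds$X, ds$adjacency,
                     bym_config(burn_in = 500, samples = 500, seed = 5))
      cache <<- list(ds = ds, fit = fit)
    }
    cache
  }
})

# naive, term-by-term log-likelihood oracle (independent of the package path)
naive_poisson_loglik <- function(O, E, eta) {
  tot <- 0
  for (i in seq_along(O)) {
    mu <- E[i] * exp(eta[i])
    tot <- tot + O[i] * log(mu) - mu - lgamma(O[i] + 1)
  }
  tot
}
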
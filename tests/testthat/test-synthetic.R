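test_that("grid lattice has the stated shape and connectivity", {
  spec4 <- simulation_spec(n_areas = 4, seed = 1)
  m4 <- make_lattice(spec4)
  adj4 <- build_adjacency(m4, "rook")
  expect_equal(adj4$num, rep(2L, 4))            # 2x2: every cell 2 rook nbrs

  spec101 <- simulation_spec(n_areas = 101, seed = 1)
  m101 <- make_lattice(spec101)
  expect_length(m101$area_id, 101)
  expect_s3_class(build_adjacency(m101, "rook"), "adjacency_matrix")
})

test_that("voronoi lattice is deterministic under a fixed seed", {
  spec <- simulation_spec(n_areas = 101, lattice_kind = "voronoi", seed = 7)
  m1 <- make_lattice(spec)
  m2 <- make_lattice(spec)
  expect_identical(m1$polygons, m2$polygons)
  expect_s3_class(build_adjacency(m1, "rook"), "adjacency_matrix")
})

test_that("covariate generator reproduces the factor-model correlations", {
  # no common factors: off-diagonal correlations vanish with n
  spec0 <- simulation_spec(n_areas = 2000, loading_matrix = matrix(0, 5, 5),
                           factor_correlations = diag(5), seed = 2)
  X0 <- as.matrix(simulate_covariates(spec0)[, -1])
  r0 <- cor(X0); diag(r0) <- 0
  expect_lt(mean(abs(r0)), 0.03)

  # one factor, loadings 0.8: population inter-variable correlation 0.64
  L1 <- matrix(0.8, 6, 1)
  spec1 <- simulation_spec(n_areas = 5000, loading_matrix = L1,
                           factor_correlations = matrix(1, 1, 1), seed = 3)
  X1 <- as.matrix(simulate_covariates(spec1)[, -1])
  r1 <- cor(X1)
  off <- r1[upper.tri(r1)]
  expect_true(all(abs(off - 0.64) < 0.03))

  # determinism
  expect_identical(simulate_covariates(spec1), simulate_covariates(spec1))

  # impossible communality
  expect_error(
    simulate_covariates(simulation_spec(
      loading_matrix = matrix(1.2, 3, 1),
      factor_correlations = matrix(1, 1, 1), seed = 1)),
    "unique variance")
})

test_that("ICAR draws honour the sum-to-zero constraint and scale", {
  adj <- build_adjacency(grid_map(3, 3), "rook")
  u <- sample_icar(adj, sigma_u = 0.5, seed = 11)
  expect_lt(abs(sum(u)), 1e-10)
  expect_error(sample_icar(adj, sigma_u = 0), "sigma_u")
})

test_that("ICAR empirical covariance matches the precision pseudo-inverse", {
  adj <- build_adjacency(grid_map(2, 2), "rook")
  sigma_u <- 0.7
  # analytic oracle: pseudo-inverse of Q = (D - W)/sigma_u^2 on the
  # sum-zero subspace, computed directly from the 4-node eigensystem
  Q <- diag(adj$num)
  for (i in 1:4) Q[i, adj$neighbours[[i]]] <- -1
  e <- eigen(Q / sigma_u^2, symmetric = TRUE)
  keep <- e$values > 1e-8
  Sigma <- e$vectors[, keep] %*% diag(1 / e$values[keep]) %*% t(e$vectors[, keep])
  set.seed(99)
  draws <- t(replicate(10000, sample_icar(adj, sigma_u)))
  emp <- cov(draws)
  expect_lt(max(abs(emp - Sigma)), 4 * max(diag(Sigma)) / sqrt(10000) * 3)
})

test_that("outcome generator matches its null model and packages truth", {
  spec <- simulation_spec(n_areas = 101, beta0 = 0, beta = numeric(0),
                          sigma_u = 0, sigma_v = 0, baseline_rate = 0.12,
                          seed = 21)
  map <- make_lattice(spec)
  adj <- build_adjacency(map, "queen")
  cv <- simulate_covariates(spec)
  ds <- simulate_outcomes(spec, cv, adj)
  pooled <- sum(ds$outcomes$observed) / sum(ds$outcomes$surveyed)
  expect_lt(abs(pooled - 0.12), 0.01)          # ~15k Bernoulli trials
  expect_equal(ds$truth$beta0, 0)

  spec2 <- simulation_spec(beta = c(0.5, -0.3), seed = 22)
  ds2 <- simulate_dataset(spec2)
  expect_lt(abs(sum(ds2$truth$u)), 1e-10)
  expect_equal(nrow(ds2$outcomes), 101)
  expect_true(all(ds2$outcomes$observed <= ds2$outcomes$surveyed))

  # full-dataset determinism
  ds2b <- simulate_dataset(spec2)
  expect_identical(ds2$outcomes, ds2b$outcomes)
  expect_identical(ds2$truth, ds2b$truth)

  # implausible spec (rates above 1 nearly everywhere) is rejected
  bad <- simulation_spec(beta0 = 3, baseline_rate = 0.5, seed = 1)
  expect_error(simulate_outcomes(bad, cv, adj), "implausible")
})
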
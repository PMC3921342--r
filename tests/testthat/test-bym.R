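fake_draws <- function(beta_chains, likelihood = "poisson",
                       u = NULL, v = NULL, X = NULL, outcomes = NULL) {
  # assemble a minimal bym_draws object for diagnostic-function tests
  n <- if (is.null(u)) 1 else ncol(u[[1]])
  chains <- lapply(seq_along(beta_chains), function(i) {
    b <- beta_chains[[i]]
    ns <- nrow(b)
    list(beta = b,
         u = if (is.null(u)) matrix(0, ns, n) else u[[i]],
         v = if (is.null(v)) matrix(0, ns, n) else v[[i]],
         tau_u = rep(1, ns), tau_v = rep(1, ns), sigma2_e = rep(1, ns),
         deviance = rep(0, ns))
  })
  structure(list(chains = chains,
                 config = bym_config(likelihood = likelihood),
                 n_areas = n, covariate_names = colnames(beta_chains[[1]]),
                 X = X, area_id = as.character(seq_len(n))),
            class = "bym_draws")
}

test_that("log-likelihood matches closed forms and a naive oracle", {
  ot1 <- expected_counts(1, 10)
  expect_equal(ot1$expected, 1)
  p0 <- list(beta0 = 0, beta = numeric(0), u = 0, v = 0)
  expect_equal(log_likelihood_bym(p0, ot1, matrix(0, 1, 0)), -1)

  # saturated thetas maximize the poisson likelihood
  set.seed(41)
  O <- rpois(8, 6) + 1
  ot <- expected_counts(O, rep(50, 8))
  eta_sat <- log(ot$observed / ot$expected)
  ll_sat <- log_likelihood_bym(list(beta0 = 0, beta = numeric(0), u = eta_sat,
                                    v = rep(0, 8)), ot, matrix(0, 8, 0))
  for (i in 1:10) {
    eta <- eta_sat + rnorm(8, 0, 0.3)
    ll <- log_likelihood_bym(list(beta0 = 0, beta = numeric(0), u = eta,
                                  v = rep(0, 8)), ot, matrix(0, 8, 0))
    expect_lt(ll, ll_sat)
  }

  # naive term-by-term oracle
  X <- matrix(rnorm(16), 8, 2)
  pars <- list(beta0 = 0.1, beta = c(0.3, -0.2), u = rnorm(8, 0, 0.1),
               v = rnorm(8, 0, 0.1))
  eta <- pars$beta0 + drop(X %*% pars$beta) + pars$u + pars$v
  expect_equal(log_likelihood_bym(pars, ot, X),
               naive_poisson_loglik(ot$observed, ot$expected, eta),
               tolerance = 1e-10)
})

test_that("intercept-only model on null data concentrates near zero", {
  set.seed(43)
  n <- 60
  surveyed <- rep(150, n)
  O <- rpois(n, 0.1 * surveyed)
  ot <- expected_counts(O, surveyed)
  adj <- build_adjacency(grid_map(6, 10), "rook")
  fit <- fit_bym(ot, NULL, adj, bym_config(burn_in = 1000, samples = 1000,
                                           seed = 2))
  s <- summarize_posterior(fit)$coefficients
  expect_lt(abs(s$mean[1]), 2 * s$sd[1])
})

test_that("lognormal MCMC matches the conjugate closed-form posterior", {
  set.seed(47)
  n <- 101
  x <- as.numeric(scale(rnorm(n)))
  O <- rpois(n, 12 * exp(0.1 + 0.3 * x))
  O[O == 0] <- 1
  ot <- expected_counts(O, rep(400, n))
  s2 <- 0.05
  cfg <- bym_config(likelihood = "lognormal", include_structured = FALSE,
                    include_unstructured = FALSE, fix_sigma2_e = s2, seed = 3)
  fit <- fit_bym(ot, cbind(x = x), NULL, cfg)
  s <- summarize_posterior(fit)$coefficients
  y <- log(ot$observed / ot$expected)
  Xd <- cbind(1, x)
  V <- solve(crossprod(Xd) / s2 + diag(2) / 10000)
  m <- drop(V %*% (crossprod(Xd, y) / s2))
  for (j in 1:2) {
    expect_lt(abs(s$mean[j] - m[j]), 3 * s$mc_error[j])
    expect_lt(abs(s$sd[j] - sqrt(V[j, j])), 3 * s$mc_error[j])
  }
})

test_that("stored ICAR draws satisfy the sum-to-zero constraint", {
  sf <- small_fit()
  for (ch in sf$fit$chains)
    expect_lt(max(abs(rowSums(ch$u))), 1e-8)
})

test_that("DIC identities and oracle equivalence", {
  sf <- small_fit()
  d <- dic(sf$fit, sf$ds$outcomes)
  expect_equal(d$dic, d$dbar + d$pD, tolerance = 1e-12)
  expect_gt(d$pD, 0)

  # oracle: recompute dbar per draw with the naive likelihood summation
  devs <- c()
  for (ch in sf$fit$chains) {
    for (it in seq(1, nrow(ch$beta), by = 25)) {
      eta <- ch$beta[it, 1] +
        drop(sf$ds$X %*% ch$beta[it, -1]) + ch$u[it, ] + ch$v[it, ]
      devs <- c(devs, -2 * naive_poisson_loglik(sf$ds$outcomes$observed,
                                                sf$ds$outcomes$expected, eta))
    }
  }
  stored <- unlist(lapply(sf$fit$chains, function(ch)
    ch$deviance[seq(1, length(ch$deviance), by = 25)]))
  expect_equal(devs, stored, tolerance = 1e-8)

  # degenerate draws: point-mass posterior has pD = 0
  ot <- expected_counts(c(3, 4), c(30, 40))
  b <- matrix(0.2, 50, 1, dimnames = list(NULL, "beta0"))
  dd <- fake_draws(list(b, b), X = matrix(0, 2, 0), outcomes = ot)
  for (i in 1:2)
    dd$chains[[i]]$deviance <- rep(-2 * log_likelihood_bym(
      list(beta0 = 0.2, beta = numeric(0), u = c(0, 0), v = c(0, 0)),
      ot, matrix(0, 2, 0)), 50)
  d0 <- dic(dd, ot, matrix(0, 2, 0))
  expect_equal(d0$pD, 0, tolerance = 1e-10)
  expect_equal(d0$dic, d0$dbar, tolerance = 1e-10)
})

test_that("Gelman-Rubin behaves on identical, iid and divergent chains", {
  n <- 3000
  x <- matrix(rnorm(n), ncol = 1, dimnames = list(NULL, "beta0"))
  ident <- fake_draws(list(x, x))
  expect_lt(gelman_rubin(ident, "beta0"), 1.001)

  set.seed(53)
  iid <- fake_draws(list(
    matrix(rnorm(n), ncol = 1, dimnames = list(NULL, "beta0")),
    matrix(rnorm(n), ncol = 1, dimnames = list(NULL, "beta0"))))
  expect_lt(gelman_rubin(iid, "beta0"), 1.02)

  apart <- fake_draws(list(
    matrix(rnorm(n, 0), ncol = 1, dimnames = list(NULL, "beta0")),
    matrix(rnorm(n, 10), ncol = 1, dimnames = list(NULL, "beta0"))))
  expect_gt(gelman_rubin(apart, "beta0"), 3)

  expect_error(gelman_rubin(fake_draws(list(x)), "beta0"), "2 chains")
})

test_that("batch-means MC error tracks iid and autocorrelated chains", {
  set.seed(59)
  z <- rnorm(5000)
  expect_lt(abs(mc_error(z) - 1 / sqrt(5000)), 0.3 / sqrt(5000))
  expect_equal(mc_error(rep(2.5, 5000)), 0)
  # AR(1), rho = 0.9: batch means capture the autocorrelation
  ar <- as.numeric(arima.sim(list(ar = 0.9), 5000, sd = sqrt(1 - 0.81)))
  expect_gt(mc_error(ar), 2 / sqrt(5000))
  expect_error(mc_error(rnorm(30)), "too short")
})

test_that("posterior summaries keep the exp-transform identity", {
  sf <- small_fit()
  s <- summarize_posterior(sf$fit)
  expect_equal(s$odds_ratios$q2.5, exp(s$coefficients$q2.5), tolerance = 1e-15)
  expect_equal(s$odds_ratios$median, exp(s$coefficients$median),
               tolerance = 1e-15)
  expect_equal(s$odds_ratios$q97.5, exp(s$coefficients$q97.5),
               tolerance = 1e-15)
  expect_true(all(s$coefficients$q2.5 <= s$coefficients$median))
  expect_true(all(s$coefficients$median <= s$coefficients$q97.5))

  # constant draws: OR median = exp(coefficient)
  b <- matrix(0.074, 200, 1, dimnames = list(NULL, "beta0"))
  s2 <- summarize_posterior(fake_draws(list(b, b)))
  expect_equal(round(s2$odds_ratios$median, 2), 1.08)

  # symmetric draws around zero are not significant
  set.seed(61)
  z <- rnorm(2000, 0, 1)
  b3 <- matrix(c(z, -z), ncol = 1, dimnames = list(NULL, "beta0"))
  s3 <- summarize_posterior(fake_draws(list(b3, b3)))
  expect_false(s3$coefficients$significant[1])
})

test_that("draws persist as CSV with a JSON manifest", {
  sf <- small_fit()
  dir <- withr::local_tempdir()
  write_draws(sf$fit, dir)
  d <- read.csv(file.path(dir, "draws.csv"), check.names = FALSE)
  expect_equal(nrow(d), 2 * 500)
  expect_true(all(c("chain", "iteration", "beta0", "deviance") %in% names(d)))
  man <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  expect_equal(length(man$chain_seeds), 2)
  expect_true("gelman_rubin" %in% names(man))
})
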
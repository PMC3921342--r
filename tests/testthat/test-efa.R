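make_table <- function(m) {
  df <- data.frame(area_id = as.character(seq_len(nrow(m))))
  df[colnames(m)] <- as.data.frame(m)
  df
}

test_that("screening removes mutually exclusive and near-duplicate columns", {
  set.seed(31)
  x <- rnorm(60)
  tab <- make_table(cbind(same_address = x, diff_address = -x,
                          other = rnorm(60)))
  out <- screen_variables(tab, max_abs_corr = 0.90)
  kept <- setdiff(names(out), "area_id")
  expect_length(kept, 2)
  expect_true("other" %in% kept)
  expect_true(sum(c("same_address", "diff_address") %in% kept) == 1)
  expect_equal(nrow(attr(out, "screening_log")), 1)

  # all below threshold: unchanged
  tab2 <- make_table(matrix(rnorm(300), 100, 3,
                            dimnames = list(NULL, c("a", "b", "c"))))
  out2 <- screen_variables(tab2, max_abs_corr = 0.90)
  expect_equal(names(out2), names(tab2))

  # r(A,B) = 0.95: exactly one of A, B dropped, C kept
  z <- rnorm(500)
  A <- z; B <- 0.95 * z + sqrt(1 - 0.95^2) * rnorm(500)
  # force the empirical correlation above threshold
  tab3 <- make_table(cbind(A = A, B = A + 0.1 * rnorm(500), C = rnorm(500)))
  out3 <- screen_variables(tab3, max_abs_corr = 0.90)
  kept3 <- setdiff(names(out3), "area_id")
  expect_true("C" %in% kept3)
  expect_length(kept3, 2)
  expect_equal(kept3[1], "A")          # alphabetically first kept
})

test_that("Bartlett sphericity matches its closed form", {
  expect_equal(bartlett_sphericity(diag(4), 100)$chi2, 0)
  expect_equal(bartlett_sphericity(diag(4), 100)$p_value, 1)

  R2 <- matrix(c(1, 0.5, 0.5, 1), 2)
  b <- bartlett_sphericity(R2, 101)
  expect_equal(b$df, 1)
  expect_equal(b$chi2, -(100 - 9 / 6) * log(0.75), tolerance = 1e-12)
  expect_equal(b$chi2, 28.337, tolerance = 1e-3)

  # chi2 strictly increases with |r| at fixed p, n
  chis <- sapply(c(0.1, 0.3, 0.5, 0.7),
                 function(r) bartlett_sphericity(matrix(c(1, r, r, 1), 2),
                                                 101)$chi2)
  expect_true(all(diff(chis) > 0))
  expect_error(bartlett_sphericity(diag(5), 4), "exceed")
})

test_that("KMO matches a hand-built anti-image oracle", {
  # p = 2: partial correlation magnitude equals |r|, so KMO = 1/2 exactly
  R2 <- matrix(c(1, 0.37, 0.37, 1), 2)
  expect_equal(kmo(R2)$overall, 0.5)

  # 3-variable equicorrelated matrix: assemble the sums from the explicit
  # inverse, independently of the package implementation
  r <- 0.5
  R3 <- matrix(r, 3, 3); diag(R3) <- 1
  inv <- solve(R3)
  q <- -inv / sqrt(outer(diag(inv), diag(inv)))
  off <- upper.tri(R3)
  oracle <- sum(R3[off]^2) / (sum(R3[off]^2) + sum(q[off]^2))
  k <- kmo(R3)
  expect_equal(k$overall, oracle, tolerance = 1e-12)
  expect_equal(unname(k$msa), rep(oracle, 3))   # symmetry of the design

  # permutation invariance
  set.seed(5)
  X <- matrix(rnorm(600), 100, 6)
  X[, 2] <- X[, 1] + rnorm(100)
  R <- cor(X)
  perm <- c(3, 1, 6, 2, 5, 4)
  expect_equal(kmo(R[perm, perm])$overall, kmo(R)$overall)
})

test_that("principal-axis factoring recovers rank-1 structure", {
  R <- matrix(0.64, 5, 5); diag(R) <- 1
  paf <- principal_axis_factoring(R, 1)
  expect_true(paf$converged)
  expect_equal(unname(paf$loadings[, 1]), rep(0.8, 5), tolerance = 1e-4)
  expect_equal(unname(paf$communalities), rep(0.64, 5), tolerance = 1e-4)
  expect_true(all(diff(paf$eigenvalues) <= 1e-12))

  paf0 <- principal_axis_factoring(diag(6), 2)
  expect_lt(max(abs(paf0$loadings)), 1e-3)
  expect_lt(max(paf0$communalities), 1e-3)
})

test_that("oblimin leaves perfect simple structure alone", {
  L <- rbind(c(0.8, 0), c(0.7, 0), c(0.6, 0),
             c(0, 0.8), c(0, 0.7), c(0, 0.6))
  rot <- oblimin_rotate(L, kaiser = FALSE)
  # same columns up to permutation/sign
  M <- abs(t(rot$pattern) %*% L)
  perm <- apply(M, 2, which.max)
  expect_equal(sort(perm), 1:2)
  for (k in 1:2) {
    pk <- rot$pattern[, perm[k]]
    if (sum(pk * L[, k]) < 0) pk <- -pk
    expect_equal(pk, L[, k], tolerance = 1e-5, ignore_attr = TRUE)
  }
  expect_equal(unname(rot$phi), diag(2), tolerance = 1e-4)
})

test_that("rotation preserves the common-factor space", {
  set.seed(17)
  A <- matrix(rnorm(26 * 3, sd = 0.5), 26, 3)
  rot <- oblimin_rotate(A, kaiser = TRUE)
  # reconstruction invariance: P Phi P' = A A'
  expect_lt(max(abs(rot$pattern %*% rot$phi %*% t(rot$pattern) -
                    A %*% t(A))), 1e-8)
  # structure = pattern . phi by construction, checked anyway
  expect_lt(max(abs(rot$structure - rot$pattern %*% rot$phi)), 1e-12)
})

test_that("oblimin matches a coarse grid-search oracle for k = 2", {
  set.seed(23)
  A <- matrix(rnorm(12), 6, 2)
  rot <- oblimin_rotate(A, kaiser = FALSE)
  # oracle: parameterize oblique T by two column angles, enumerate
  crit <- function(L) {
    L2 <- L^2
    sum(L2[, 1] * L2[, 2]) / 2 / 2 * 2   # quartimin for k = 2: sum L1^2 L2^2 / 2
  }
  best <- Inf
  for (a1 in seq(0, pi, length.out = 181)) {
    for (a2 in seq(0, pi, length.out = 181)) {
      Tm <- cbind(c(cos(a1), sin(a1)), c(cos(a2), sin(a2)))
      if (abs(det(Tm)) < 1e-3) next
      L <- A %*% t(solve(Tm))
      f <- crit(L)
      if (f < best) best <- f
    }
  }
  expect_lt(rot$criterion, best + 1e-3)
})

test_that("run_efa reports diagnostics, masking and a sensible k", {
  spec <- simulation_spec(n_areas = 1500, seed = 13)
  cv <- simulate_covariates(spec)
  efa <- run_efa(cv, n_factors_range = 5:8)
  expect_equal(efa$suggested_k, 6)
  expect_equal(efa$selected, 6)
  dg <- efa$diagnostics
  expect_true(all(c("chi2", "df", "p_value") %in% names(dg$bartlett)))
  expect_true(dg$kmo_overall > 0 && dg$kmo_overall < 1)
  expect_length(dg$msa, 26)
  expect_equal(dim(dg$anti_image), c(26, 26))
  fit <- efa$fits[["6"]]
  # masking: below-threshold loadings hidden in the report, kept internally
  expect_true(all(is.na(fit$pattern_masked[abs(fit$pattern) < 0.30])))
  expect_true(all(!is.na(fit$pattern_masked[abs(fit$pattern) >= 0.30])))
  expect_false(anyNA(fit$pattern))
  # structure identity
  expect_lt(max(abs(fit$structure - fit$pattern %*% fit$phi)), 1e-10)
  # report files
  dir <- withr::local_tempdir()
  write_efa_report(efa, dir)
  expect_true(file.exists(file.path(dir, "pattern_masked.csv")))
  expect_true(file.exists(file.path(dir, "diagnostics.txt")))
})

test_that("model reconstruction holds on data simulated from the model", {
  spec <- simulation_spec(n_areas = 5000, seed = 29)
  cv <- simulate_covariates(spec)
  R <- cor(as.matrix(cv[, -1]))
  paf <- principal_axis_factoring(R, 6)
  rot <- oblimin_rotate(paf$loadings, kaiser = TRUE)
  Rhat <- rot$pattern %*% rot$phi %*% t(rot$pattern)
  diag(Rhat) <- 1
  expect_lt(max(abs(Rhat - R)), 0.05)
})
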
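## BYM spatial regression: configuration, MCMC front end, DIC, convergence
## diagnostics and posterior summaries.

#' Configure a BYM model fit
#'
#' Defaults follow the standard small-area disease-mapping setup: vague
#' N(0, 10000) priors on the intercept and coefficients, Gamma(0.5, 0.0005)
#' hyper-priors on random-effect precisions, two chains of 3000 burn-in plus
#' 3000 sampling iterations.
#'
#' @param likelihood `"poisson"` (counts, the default BYM likelihood) or
#'   `"lognormal"` (Gaussian model for log SMR).
#' @param include_structured include the ICAR spatially structured effect u.
#' @param include_unstructured include the iid heterogeneity effect v.
#' @param coef_prior_variance prior variance of intercept and coefficients.
#' @param precision_prior_shape,precision_prior_rate Gamma hyper-prior on
#'   random-effect precisions (equivalently an inverse-Gamma prior on the
#'   variances — the same distribution stated on the other scale).
#' @param n_chains,burn_in,samples,thin MCMC run lengths.
#' @param seed master seed; chain c uses `seed + c * 10007`.
#' @param lognormal_zero_correction constant c added to observed counts when
#'   forming `y = log((O + c)/E)` if any count is zero.
#' @param fix_tau_u,fix_tau_v,fix_sigma2_e optional fixed values (NULL =
#'   sampled); used for conjugate-oracle checks and sensitivity analyses.
#' @return Object of class `bym_config`.
#' @export
bym_config <- function(likelihood = c("poisson", "lognormal"),
                       include_structured = TRUE,
                       include_unstructured = TRUE,
                       coef_prior_variance = 10000,
                       precision_prior_shape = 0.5,
                       precision_prior_rate = 0.0005,
                       n_chains = 2L, burn_in = 3000L, samples = 3000L,
                       thin = 1L, seed = 1L,
                       lognormal_zero_correction = 0.5,
                       fix_tau_u = NULL, fix_tau_v = NULL, fix_sigma2_e = NULL) {
  likelihood <- match.arg(likelihood)
  stopifnot(burn_in > 0, samples > 0, thin >= 1, n_chains >= 1,
            coef_prior_variance > 0)
  structure(list(likelihood = likelihood,
                 include_structured = include_structured,
                 include_unstructured = include_unstructured,
                 coef_prior_variance = coef_prior_variance,
                 precision_prior_shape = precision_prior_shape,
                 precision_prior_rate = precision_prior_rate,
                 n_chains = as.integer(n_chains), burn_in = as.integer(burn_in),
                 samples = as.integer(samples), thin = as.integer(thin),
                 seed = as.integer(seed),
                 lognormal_zero_correction = lognormal_zero_correction,
                 fix_tau_u = fix_tau_u, fix_tau_v = fix_tau_v,
                 fix_sigma2_e = fix_sigma2_e),
            class = "bym_config")
}

lognormal_response <- function(outcomes, config) {
  cc <- if (any(outcomes$observed == 0)) config$lognormal_zero_correction else 0
  log((outcomes$observed + cc) / outcomes$expected)
}

#' Log-likelihood of a BYM state
#'
#' @param params list with `beta0`, `beta`, `u`, `v` and (lognormal)
#'   `sigma2_e`.
#' @param outcomes an `outcome_table` ([expected_counts()]).
#' @param X covariate matrix (n x p; p may be 0).
#' @param kind `"poisson"` or `"lognormal"`.
#' @param zero_correction used when forming the lognormal response.
#' @return scalar log-likelihood.
#' @export
log_likelihood_bym <- function(params, outcomes, X,
                               kind = c("poisson", "lognormal"),
                               zero_correction = 0.5) {
  kind <- match.arg(kind)
  n <- nrow(outcomes)
  X <- as.matrix(X)
  p <- ncol(X)
  eta <- params$beta0 +
    (if (p > 0) drop(X %*% params$beta) else 0) +
    (if (is.null(params$u)) 0 else params$u) +
    (if (is.null(params$v)) 0 else params$v)
  if (any(!is.finite(eta))) stop("non-finite linear predictor")
  if (kind == "poisson") {
    mu <- outcomes$expected * exp(eta)
    sum(dpois(outcomes$observed, mu, log = TRUE))
  } else {
    cc <- if (any(outcomes$observed == 0)) zero_correction else 0
    y <- log((outcomes$observed + cc) / outcomes$expected)
    sum(dnorm(y, eta, sqrt(params$sigma2_e), log = TRUE))
  }
}

#' Fit the BYM model by MCMC
#'
#' Runs `config$n_chains` independent chains (seeds derived from
#' `config$seed`).  Under the Poisson likelihood the sampler is single-site
#' adaptive random-walk Metropolis with conjugate Gamma draws for precisions
#' (adaptation frozen after burn-in); under the lognormal likelihood every
#' update is a conjugate Gibbs draw.  The structured effect is recentred to
#' sum to zero every sweep, with the mean absorbed into the intercept.
#'
#' @param outcomes an `outcome_table` with positive expected counts.
#' @param X covariate matrix or data.frame (n x p; may have 0 columns).
#'   Standardized covariates are recommended; a warning is issued if any
#'   column sd is far from 1.
#' @param adj an [adjacency_matrix] (required if `include_structured`).
#' @param config a [bym_config].
#' @return Object of class `bym_draws`: per-chain matrices of kept draws of
#'   beta (intercept first), u, v, precisions, `sigma2_e`, deviance, plus
#'   acceptance rates and a config echo.
#' @export
fit_bym <- function(outcomes, X, adj, config = bym_config()) {
  stopifnot(inherits(config, "bym_config"))
  n <- nrow(outcomes)
  if (all(outcomes$observed == 0)) stop("all observed counts are zero")
  if (any(outcomes$expected <= 0)) stop("expected counts must be positive")
  X <- if (is.null(X)) matrix(0, n, 0) else as.matrix(X)
  if (nrow(X) != n) stop("X rows must match outcomes")
  p <- ncol(X)
  if (p > 0) {
    sds <- apply(X, 2, sd)
    if (any(sds > 10 | sds < 0.1))
      warning("covariate columns have sd far from 1; standardization ",
              "recommended so the N(0, 10000) prior is genuinely vague")
  }
  if (config$include_structured) {
    stopifnot(inherits(adj, "adjacency_matrix"))
    if (adj$n != n) stop("adjacency size does not match outcomes")
    num <- adj$num
    adjvec <- adj$adj - 1L            # 0-based for the C++ core
  } else {
    num <- integer(n)
    adjvec <- integer(0)
  }
  y <- if (config$likelihood == "lognormal")
    lognormal_response(outcomes, config) else numeric(0)
  fx <- function(z) if (is.null(z)) -1 else z
  chains <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    chain_seed <- config$seed + ch * 10007L
    set.seed(chain_seed)
    init <- c(rnorm(1, 0, 0.1), rnorm(p, 0, 0.1),
              exp(rnorm(1, log(10), 0.2)), exp(rnorm(1, log(10), 0.2)),
              exp(rnorm(1, log(0.1), 0.2)))
    res <- bym_chain_cpp(as.numeric(outcomes$observed),
                         as.numeric(outcomes$expected), X,
                         as.integer(num), as.integer(adjvec),
                         if (config$likelihood == "poisson") 0L else 1L,
                         config$include_structured, config$include_unstructured,
                         config$coef_prior_variance,
                         config$precision_prior_shape,
                         config$precision_prior_rate,
                         config$burn_in, config$samples, config$thin,
                         fx(config$fix_tau_u), fx(config$fix_tau_v),
                         fx(config$fix_sigma2_e), y, init)
    colnames(res$beta) <- c("beta0",
                            if (p > 0) colnames(X) else character(0))
    res$seed <- chain_seed
    chains[[ch]] <- res
  }
  structure(list(chains = chains, config = config, n_areas = n,
                 covariate_names = colnames(X), X = X,
                 area_id = outcomes$area_id),
            class = "bym_draws")
}

#' @export
print.bym_draws <- function(x, ...) {
  cat("bym_draws:", length(x$chains), "chains x", x$config$samples,
      "kept iterations,", x$n_areas, "areas,",
      length(x$covariate_names) - 1, "covariates,",
      x$config$likelihood, "likelihood\n")
  invisible(x)
}

# pooled draws of a scalar parameter as an (iterations x chains) matrix
param_matrix <- function(draws, parameter) {
  get1 <- function(ch) {
    if (parameter %in% colnames(ch$beta)) return(ch$beta[, parameter])
    if (parameter %in% c("tau_u", "tau_v", "sigma2_e", "deviance"))
      return(ch[[parameter]])
    m <- regmatches(parameter, regexec("^(u|v)\\[(\\d+)\\]$", parameter))[[1]]
    if (length(m) == 3) return(ch[[m[2]]][, as.integer(m[3])])
    stop("unknown parameter '", parameter, "'")
  }
  sapply(draws$chains, get1)
}

#' DIC and effective number of parameters
#'
#' `Dbar` is the posterior mean deviance pooled over chains; `Dhat` the
#' deviance at the posterior means of all parameters (random effects
#' included); `pD = Dbar - Dhat`; `DIC = Dbar + pD`.  A negative `pD`
#' (poorly identified model) is reported as-is.
#'
#' @param draws a `bym_draws`.
#' @param outcomes,X the data the model was fitted to (defaults to the
#'   matrix stored in `draws`).
#' @return list of class `bym_dic`: `dbar`, `d_hat`, `pD`, `dic`.
#' @export
dic <- function(draws, outcomes, X = draws$X) {
  dev <- unlist(lapply(draws$chains, `[[`, "deviance"))
  if (length(dev) < 100) stop("need at least 100 kept iterations for DIC")
  dbar <- mean(dev)
  bmat <- do.call(rbind, lapply(draws$chains, `[[`, "beta"))
  pm <- list(beta0 = mean(bmat[, 1]),
             beta = if (ncol(bmat) > 1) colMeans(bmat[, -1, drop = FALSE])
                    else numeric(0),
             u = colMeans(do.call(rbind, lapply(draws$chains, `[[`, "u"))),
             v = colMeans(do.call(rbind, lapply(draws$chains, `[[`, "v"))),
             sigma2_e = mean(unlist(lapply(draws$chains, `[[`, "sigma2_e"))))
  d_hat <- -2 * log_likelihood_bym(pm, outcomes, X, draws$config$likelihood,
                                   draws$config$lognormal_zero_correction)
  if (!is.finite(d_hat)) stop("non-finite deviance at posterior means")
  pD <- dbar - d_hat
  structure(list(dbar = dbar, d_hat = d_hat, pD = pD, dic = dbar + pD),
            class = "bym_dic")
}

#' @export
print.bym_dic <- function(x, ...) {
  cat(sprintf("Dbar = %.3f  Dhat = %.3f  pD = %.3f  DIC = %.3f\n",
              x$dbar, x$d_hat, x$pD, x$dic))
  invisible(x)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' `sqrt(((n-1)/n * W + B/n) / W)` from the between- and within-chain
#' variances of a scalar parameter.
#'
#' @param draws a `bym_draws` with at least two chains.
#' @param parameter parameter name (`"beta0"`, a covariate name, `"tau_u"`,
#'   `"tau_v"`, `"sigma2_e"`, `"deviance"`, or `"u[i]"` / `"v[i]"`).
#' @return scalar PSRF.
#' @export
gelman_rubin <- function(draws, parameter) {
  m <- param_matrix(draws, parameter)
  if (ncol(m) < 2) stop("Gelman-Rubin needs at least 2 chains")
  n <- nrow(m)
  W <- mean(apply(m, 2, var))
  B_over_n <- var(colMeans(m))
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B_over_n) / W)
}

#' Batch-means Monte Carlo standard error
#'
#' WinBUGS convention: the chain is split into `n_batches` equal batches
#' (default 50) and the MC error is the standard deviation of batch means
#' divided by `sqrt(n_batches)`.
#'
#' @param x numeric chain.
#' @param n_batches number of batches.
#' @return scalar MC error.
#' @export
mc_error <- function(x, n_batches = 50) {
  n <- length(x)
  if (n < 20 * max(1, n_batches / 50) || n < n_batches)
    stop("chain too short for ", n_batches, " batches")
  b <- n %/% n_batches
  means <- colMeans(matrix(x[seq_len(b * n_batches)], nrow = b))
  sd(means) / sqrt(n_batches)
}

#' Posterior summary table (coefficient and odds-ratio scales)
#'
#' Per parameter: pooled posterior mean, sd, batch-means MC error and the
#' 2.5% / 50% / 97.5% quantiles.  For the intercept and coefficients an
#' odds-ratio-scale block is added: mean/sd/MC error are computed on the
#' exponentiated draws, while the OR quantile columns are exactly
#' `exp(coefficient quantiles)` (the quantile of a monotone transform).
#' `significant` flags coefficients whose 95% credible interval excludes 0.
#'
#' @param draws a `bym_draws`.
#' @param probs quantiles reported.
#' @return list of class `bym_summary` with data.frames `coefficients`,
#'   `odds_ratios`, `hyper`.
#' @export
summarize_posterior <- function(draws, probs = c(0.025, 0.5, 0.975)) {
  bmat <- do.call(rbind, lapply(draws$chains, `[[`, "beta"))
  summ1 <- function(x) {
    q <- unname(quantile(x, probs))
    c(mean = mean(x), sd = sd(x), mc_error = mc_error(x),
      q2.5 = q[1], median = q[2], q97.5 = q[3])
  }
  co <- t(apply(bmat, 2, summ1))
  coef_df <- data.frame(node = rownames(co), co, row.names = NULL,
                        check.names = FALSE)
  coef_df$significant <- sign(coef_df$q2.5) == sign(coef_df$q97.5) &
    coef_df$q2.5 != 0
  or <- t(apply(bmat, 2, function(x) {
    q <- unname(quantile(x, probs))
    c(mean = mean(exp(x)), sd = sd(exp(x)), mc_error = mc_error(exp(x)),
      q2.5 = exp(q[1]), median = exp(q[2]), q97.5 = exp(q[3]))
  }))
  or_df <- data.frame(node = paste0("OR.", rownames(or)), or,
                      row.names = NULL, check.names = FALSE)
  hyper_names <- c(if (draws$config$include_structured) "tau_u",
                   if (draws$config$include_unstructured) "tau_v",
                   if (draws$config$likelihood == "lognormal") "sigma2_e")
  hyper <- NULL
  if (length(hyper_names)) {
    hv <- t(vapply(hyper_names, function(nm)
      summ1(unlist(lapply(draws$chains, `[[`, nm))), numeric(6)))
    hyper <- data.frame(node = hyper_names, hv, row.names = NULL,
                        check.names = FALSE)
  }
  structure(list(coefficients = coef_df, odds_ratios = or_df, hyper = hyper),
            class = "bym_summary")
}

#' @export
print.bym_summary <- function(x, digits = 3, ...) {
  cat("Coefficients:\n")
  print(cbind(x$coefficients[1], round(x$coefficients[2:7], digits),
              x$coefficients[8]), row.names = FALSE)
  cat("\nOdds ratios:\n")
  print(cbind(x$odds_ratios[1], round(x$odds_ratios[2:7], 2)),
        row.names = FALSE)
  if (!is.null(x$hyper)) {
    cat("\nHyperparameters:\n")
    print(cbind(x$hyper[1], round(x$hyper[2:7], digits)), row.names = FALSE)
  }
  invisible(x)
}

#' Persist posterior draws as a long-format CSV plus a JSON run manifest
#'
#' @param draws a `bym_draws`.
#' @param dir output directory.
#' @param include_effects also write the (large) u and v draws.
#' @return `dir`, invisibly.
#' @export
write_draws <- function(draws, dir, include_effects = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (ch in seq_along(draws$chains)) {
    cc <- draws$chains[[ch]]
    base <- cbind(as.data.frame(cc$beta), tau_u = cc$tau_u, tau_v = cc$tau_v,
                  sigma2_e = cc$sigma2_e, deviance = cc$deviance)
    if (include_effects) {
      colnames(cc$u) <- paste0("u[", seq_len(ncol(cc$u)), "]")
      colnames(cc$v) <- paste0("v[", seq_len(ncol(cc$v)), "]")
      base <- cbind(base, as.data.frame(cc$u), as.data.frame(cc$v))
    }
    long <- data.frame(chain = ch, iteration = seq_len(nrow(base)),
                       base, check.names = FALSE)
    rows[[ch]] <- long
  }
  write.csv(do.call(rbind, rows), file.path(dir, "draws.csv"),
            row.names = FALSE)
  gr <- sapply(colnames(draws$chains[[1]]$beta),
               function(p) tryCatch(gelman_rubin(draws, p),
                                    error = function(e) NA_real_))
  manifest <- list(config = unclass(draws$config),
                   n_areas = draws$n_areas,
                   chain_seeds = vapply(draws$chains, `[[`, numeric(1), "seed"),
                   acceptance = lapply(draws$chains, `[[`, "accept"),
                   gelman_rubin = as.list(gr))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(dir)
}
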
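## Forward covariate selection by DIC.
##
## Decision rules: candidate DIC is averaged over several seeded reruns (DIC
## from MCMC is itself noisy); a candidate is accepted only if it gives the
## largest DIC decrease, the decrease exceeds `dic_tolerance` ("models whose
## DIC differs by more than one"), its own 95% credible interval excludes
## zero, and every previously accepted coefficient stays significant.  If
## the best candidate fails the significance rules the next-best is tried.

fit_with_seeds <- function(outcomes, X, adj, config, seeds) {
  fits <- lapply(seeds, function(s) {
    cfg <- config
    cfg$seed <- as.integer(s)
    fit_bym(outcomes, X, adj, cfg)
  })
  dics <- vapply(fits, function(f) {
    d <- dic(f, outcomes)
    c(d$pD, d$dic)
  }, numeric(2))
  # a coefficient counts as significant only if its 95% credible interval
  # excludes zero in every seeded rerun (a conclusion that flips with the
  # random-number seed is not robust — the point of the repeated runs)
  pnames <- colnames(fits[[1]]$chains[[1]]$beta)
  sig_run <- vapply(fits, function(f) {
    bmat <- do.call(rbind, lapply(f$chains, `[[`, "beta"))
    apply(bmat, 2, function(x) {
      q <- quantile(x, c(0.025, 0.975))
      sign(q[1]) == sign(q[2]) && q[1] != 0
    })
  }, logical(length(pnames)))
  sig <- apply(matrix(sig_run, nrow = length(pnames)), 1, all)
  names(sig) <- pnames
  list(pD = mean(dics[1, ]), dic = mean(dics[2, ]), dic_per_seed = dics[2, ],
       significant = sig, last_fit = fits[[length(fits)]])
}

#' Forward covariate selection by DIC over seeded reruns
#'
#' Starts from a base spatial model (CAR residual only by default; full BYM
#' via `config$include_unstructured = TRUE`) and adds candidates one at a
#' time per the rules above, stopping when no candidate both lowers the mean
#' DIC by more than `dic_tolerance` and keeps all coefficients significant.
#'
#' @param outcomes an `outcome_table`.
#' @param candidates data.frame of candidate covariates (`area_id` optional).
#' @param adj an [adjacency_matrix].
#' @param config a [bym_config]; `config$seed` deterministically generates
#'   the per-run seed list.
#' @param dic_tolerance minimal DIC decrease that counts (default 1.0).
#' @param n_seeds number of seeded reruns averaged per candidate model.
#' @return list of class `selection_trace`: `steps` data.frame (one row per
#'   step x candidate), `final_model` (accepted covariate names),
#'   `base_dic`, and `final_fit` (a `bym_draws` for the selected model).
#' @export
forward_select <- function(outcomes, candidates, adj, config = bym_config(),
                           dic_tolerance = 1.0, n_seeds = 3L) {
  cand_names <- setdiff(names(candidates), "area_id")
  if (length(cand_names) < 1) stop("need at least one candidate covariate")
  Xall <- as.matrix(candidates[, cand_names, drop = FALSE])
  seeds <- config$seed + 997L * seq_len(n_seeds)
  base <- fit_with_seeds(outcomes, NULL, adj, config, seeds)
  current <- character(0)
  current_dic <- base$dic
  trace <- list()
  step <- 0L
  final_fit <- base$last_fit
  repeat {
    step <- step + 1L
    remaining <- setdiff(cand_names, current)
    if (length(remaining) == 0) break
    evals <- list()
    for (cand in remaining) {
      X <- Xall[, c(current, cand), drop = FALSE]
      res <- tryCatch(fit_with_seeds(outcomes, X, adj, config, seeds),
                      error = function(e) e)
      if (inherits(res, "error")) {
        trace[[length(trace) + 1L]] <- data.frame(
          step = step, candidate = cand, pD = NA_real_, dic = NA_real_,
          decrease = NA_real_, candidate_significant = NA,
          previous_significant = NA, accepted = FALSE,
          note = paste("fit failed:", conditionMessage(res)))
        next
      }
      decrease <- current_dic - res$dic
      sig <- res$significant[-1]            # drop intercept
      cand_sig <- unname(sig[cand])
      prev_sig <- if (length(current)) all(sig[current]) else TRUE
      evals[[cand]] <- list(res = res, decrease = decrease,
                            cand_sig = cand_sig, prev_sig = prev_sig)
      trace[[length(trace) + 1L]] <- data.frame(
        step = step, candidate = cand, pD = res$pD, dic = res$dic,
        decrease = decrease, candidate_significant = cand_sig,
        previous_significant = prev_sig, accepted = FALSE, note = "")
    }
    if (length(evals) == 0) break
    ord <- names(evals)[order(vapply(evals, `[[`, numeric(1), "decrease"),
                              decreasing = TRUE)]
    accepted <- NULL
    for (cand in ord) {
      e <- evals[[cand]]
      if (e$decrease <= dic_tolerance) break   # sorted: nothing further passes
      if (!e$cand_sig) break      # best remaining candidate not significant: stop
      if (e$prev_sig) { accepted <- cand; break }
      # addition de-significs an earlier coefficient: reject, try next-best
    }
    if (is.null(accepted)) break
    for (i in seq_along(trace))
      if (trace[[i]]$step == step && trace[[i]]$candidate == accepted)
        trace[[i]]$accepted <- TRUE
    current <- c(current, accepted)
    current_dic <- evals[[accepted]]$res$dic
    final_fit <- evals[[accepted]]$res$last_fit
  }
  structure(list(steps = do.call(rbind, trace), final_model = current,
                 base_dic = base$dic, base_pD = base$pD,
                 final_dic = current_dic, final_fit = final_fit,
                 dic_tolerance = dic_tolerance, seeds = seeds),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat("Forward DIC selection: base DIC =", round(x$base_dic, 3), "\n")
  cat("Final model:", if (length(x$final_model))
    paste(x$final_model, collapse = " + ") else "(empty)",
    "| DIC =", round(x$final_dic, 3), "\n")
  invisible(x)
}

#' Export a selection trace as CSV (and optionally JSON)
#'
#' @param trace a `selection_trace`.
#' @param path CSV output path.
#' @param json_path optional JSON output path.
#' @export
write_selection_trace <- function(trace, path, json_path = NULL) {
  write.csv(trace$steps, path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(
      list(final_model = trace$final_model, base_dic = trace$base_dic,
           final_dic = trace$final_dic, dic_tolerance = trace$dic_tolerance,
           seeds = trace$seeds, steps = trace$steps),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
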
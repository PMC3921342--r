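## Exploratory factor analysis pipeline: correlation screening, suitability
## diagnostics (Bartlett, KMO/MSA, anti-image), principal-axis factoring and
## direct-oblimin rotation with Kaiser normalization.
##
## The rotation uses the gradient-projection algorithm for oblique rotations
## (Jennrich 2002); gamma = 0 gives direct quartimin, the SPSS oblimin
## default.

numeric_covariate_matrix <- function(table) {
  cols <- setdiff(names(table), "area_id")
  m <- as.matrix(table[, cols, drop = FALSE])
  if (!is.numeric(m)) stop("covariate columns must be numeric")
  if (anyNA(m)) stop("missing values in covariate table; screen them out first")
  m
}

#' Screen covariates for extreme collinearity
#'
#' Iteratively removes one variable of each pair with `|r| > max_abs_corr`:
#' the variable with the lower average absolute correlation with `outcome`
#' is dropped when an outcome is supplied, otherwise the alphabetically
#' later one.  Variables in `drop_list` are removed first.  Every removal is
#' recorded in the `"screening_log"` attribute.
#'
#' @param table data.frame with `area_id` plus numeric covariate columns.
#' @param max_abs_corr threshold in (0, 1]; default 0.90, the conventional
#'   multicollinearity cut-off.
#' @param drop_list character vector of columns to remove unconditionally.
#' @param outcome optional numeric vector (one per row) used to break ties.
#' @return The screened table, with attribute `screening_log` (data.frame of
#'   `variable`, `reason`).
#' @export
screen_variables <- function(table, max_abs_corr = 0.90,
                             drop_list = character(0), outcome = NULL) {
  stopifnot(max_abs_corr > 0, max_abs_corr <= 1)
  log <- data.frame(variable = character(0), reason = character(0))
  for (v in intersect(drop_list, names(table))) {
    table[[v]] <- NULL
    log <- rbind(log, data.frame(variable = v, reason = "explicit drop_list"))
  }
  repeat {
    m <- numeric_covariate_matrix(table)
    if (ncol(m) < 2) break
    r <- cor(m)
    diag(r) <- 0
    mx <- max(abs(r))
    if (mx <= max_abs_corr) break
    idx <- which(abs(r) == mx, arr.ind = TRUE)[1, ]
    pair <- sort(colnames(r)[idx])
    drop <- if (!is.null(outcome)) {
      ra <- abs(cor(m[, pair[1]], outcome))
      rb <- abs(cor(m[, pair[2]], outcome))
      if (ra >= rb) pair[2] else pair[1]
    } else pair[2]              # keep the alphabetically first
    table[[drop]] <- NULL
    log <- rbind(log, data.frame(
      variable = drop,
      reason = sprintf("|r| = %.3f with %s exceeds %.2f", mx,
                       setdiff(pair, drop), max_abs_corr)))
  }
  if (length(setdiff(names(table), "area_id")) == 0)
    stop("screening removed every covariate")
  attr(table, "screening_log") <- log
  table
}

#' Bartlett's test of sphericity
#'
#' Tests the null that the correlation matrix is the identity:
#' `chi2 = -((n - 1) - (2p + 5)/6) * log(det(R))` on `p(p-1)/2` degrees of
#' freedom.
#'
#' @param R correlation matrix.
#' @param n sample size (must exceed the number of variables).
#' @return list `(chi2, df, p_value)`.
#' @export
bartlett_sphericity <- function(R, n) {
  R <- as.matrix(R)
  p <- ncol(R)
  if (n <= p) stop("n must exceed the number of variables")
  d <- det(R)
  if (d <= 0)
    stop("correlation matrix is singular (det <= 0); screen variables further")
  chi2 <- -((n - 1) - (2 * p + 5) / 6) * log(d)
  df <- p * (p - 1) / 2
  list(chi2 = chi2, df = df, p_value = pchisq(chi2, df, lower.tail = FALSE))
}

#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' Anti-image (negative partial) correlations are formed from the inverse of
#' R; the KMO statistic is the ratio of summed squared correlations to
#' summed squared correlations plus summed squared partial correlations.
#' Per-variable MSA uses the same ratio restricted to each row.
#'
#' @param R invertible correlation matrix.
#' @return list `(overall, msa, anti_image)`; `anti_image` is the matrix of
#'   partial correlations with unit diagonal.
#' @export
kmo <- function(R) {
  R <- as.matrix(R)
  inv <- tryCatch(solve(R),
                  error = function(e) stop("correlation matrix is singular: ",
                                           conditionMessage(e)))
  s <- 1 / sqrt(diag(inv))
  Q <- -inv * outer(s, s)
  diag(Q) <- 1
  r2 <- R^2; diag(r2) <- 0
  q2 <- Q^2; diag(q2) <- 0
  overall <- sum(r2) / (sum(r2) + sum(q2))
  msa <- rowSums(r2) / (rowSums(r2) + rowSums(q2))
  names(msa) <- colnames(R)
  list(overall = overall, msa = msa, anti_image = Q)
}

#' Principal-axis factoring
#'
#' Iterated communalities on the reduced correlation matrix: starting from
#' squared multiple correlations, the diagonal of R is replaced by the
#' current communalities, the top `n_factors` eigenpairs give the loadings
#' (negative eigenvalues truncated at zero), and new communalities are the
#' row sums of squared loadings, until the largest communality change falls
#' below `tol`.  Heywood communalities are clipped to `1 - 1e-6` with a
#' warning.
#'
#' @param R correlation matrix.
#' @param n_factors number of factors, `1 <= n_factors < ncol(R)`.
#' @param tol convergence tolerance on communalities.
#' @param max_iter iteration cap; non-convergence is reported via
#'   `converged = FALSE`, not an error.
#' @return list `(loadings, communalities, eigenvalues, converged,
#'   n_iterations)`; `eigenvalues` are those of the final reduced matrix,
#'   in non-increasing order.
#' @export
principal_axis_factoring <- function(R, n_factors, tol = 1e-6, max_iter = 200) {
  R <- as.matrix(R)
  p <- ncol(R)
  stopifnot(n_factors >= 1, n_factors < p)
  inv <- solve(R)
  h2 <- 1 - 1 / diag(inv)             # squared multiple correlations
  converged <- FALSE
  iter <- 0L
  ev <- NULL; L <- NULL
  heywood <- FALSE
  for (iter in seq_len(max_iter)) {
    Rr <- R
    diag(Rr) <- h2
    e <- eigen(Rr, symmetric = TRUE)
    ev <- e$values
    lam <- sqrt(pmax(e$values[seq_len(n_factors)], 0))
    L <- e$vectors[, seq_len(n_factors), drop = FALSE] %*% diag(lam, n_factors)
    h2_new <- rowSums(L^2)
    if (any(h2_new > 1)) {
      heywood <- TRUE
      h2_new <- pmin(h2_new, 1 - 1e-6)
    }
    if (max(abs(h2_new - h2)) < tol) { h2 <- h2_new; converged <- TRUE; break }
    h2 <- h2_new
  }
  if (heywood) warning("Heywood case: communality > 1 clipped to 1 - 1e-6")
  # orient each factor so its largest-magnitude loading is positive
  for (k in seq_len(n_factors)) {
    j <- which.max(abs(L[, k]))
    if (L[j, k] < 0) L[, k] <- -L[, k]
  }
  dimnames(L) <- list(colnames(R), paste0("F", seq_len(n_factors)))
  names(h2) <- colnames(R)
  list(loadings = L, communalities = h2, eigenvalues = ev,
       converged = converged, n_iterations = iter)
}

# oblimin criterion value and gradient at pattern matrix L
oblimin_criterion <- function(L, gamma = 0) {
  k <- ncol(L); p <- nrow(L)
  N <- matrix(1, k, k) - diag(k)
  X <- L^2 %*% N
  if (gamma != 0) X <- (diag(p) - matrix(gamma / p, p, p)) %*% X
  list(f = sum(L^2 * X) / 4, Gq = L * X)
}

gpa_oblique <- function(A, gamma, Tmat, eps = 1e-6, max_iter = 1000) {
  k <- ncol(A)
  al <- 1
  L <- A %*% t(solve(Tmat))
  cr <- oblimin_criterion(L, gamma)
  f <- cr$f
  G <- -t(t(L) %*% cr$Gq %*% solve(Tmat))
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    Gp <- G - Tmat %*% diag(colSums(Tmat * G), k)
    s <- sqrt(sum(Gp^2))
    if (s < eps) { converged <- TRUE; break }
    al <- 2 * al
    repeat {
      X <- Tmat - al * Gp
      Tt <- X %*% diag(1 / sqrt(colSums(X^2)), k)
      Lt <- A %*% t(solve(Tt))
      crt <- oblimin_criterion(Lt, gamma)
      if (crt$f < f - 0.5 * s^2 * al || al < 1e-12) break
      al <- al / 2
    }
    Tmat <- Tt
    L <- Lt
    f <- crt$f
    G <- -t(t(L) %*% crt$Gq %*% solve(Tmat))
  }
  list(pattern = L, Tmat = Tmat, f = f, converged = converged, iterations = iter)
}

#' Direct-oblimin rotation
#'
#' Minimizes the direct-oblimin criterion (default `gamma = 0`, direct
#' quartimin — the SPSS default delta) over oblique rotations by gradient
#' projection, optionally with Kaiser row normalization.  Several
#' deterministic random starts guard against local minima; the best
#' criterion value wins.
#'
#' @param loadings unrotated p x k loading matrix, `k >= 2`.
#' @param gamma oblimin gamma parameter.
#' @param kaiser apply Kaiser normalization (rows scaled to unit communality
#'   before rotation, rescaled after).
#' @param n_starts number of random starting rotations besides the identity.
#' @param max_iter,eps gradient-projection controls.
#' @return list `(pattern, structure, phi, criterion, converged)`; columns
#'   are ordered by explained sum of squares and signed so each factor's
#'   largest loading is positive.
#' @export
oblimin_rotate <- function(loadings, gamma = 0, kaiser = TRUE, n_starts = 10,
                           max_iter = 1000, eps = 1e-6) {
  A <- as.matrix(loadings)
  k <- ncol(A)
  if (k < 2) stop("rotation needs at least 2 factors")
  h <- sqrt(rowSums(A^2))
  if (kaiser) {
    if (any(h < 1e-12)) stop("zero-communality row; cannot Kaiser-normalize")
    A_rot <- A / h
  } else A_rot <- A
  # deterministic random starts, isolated from the caller's RNG stream
  starts <- list(diag(k))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(760417L)
  for (s in seq_len(n_starts)) {
    M <- matrix(rnorm(k * k), k, k)
    Tm <- qr.Q(qr(M))
    starts[[s + 1L]] <- Tm %*% diag(1 / sqrt(colSums(Tm^2)), k)
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  best <- NULL
  for (Tmat in starts) {
    res <- gpa_oblique(A_rot, gamma, Tmat, eps = eps, max_iter = max_iter)
    if (is.null(best) || res$f < best$f) best <- res
  }
  if (!best$converged)
    stop("oblimin rotation did not converge; last criterion value ",
         format(best$f))
  P <- best$pattern
  if (kaiser) P <- P * h
  phi <- t(best$Tmat) %*% best$Tmat
  # order factors by explained SS, sign them to positive primary loadings
  ord <- order(colSums(P^2), decreasing = TRUE)
  P <- P[, ord, drop = FALSE]
  phi <- phi[ord, ord, drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(P[, j]))
    if (P[i, j] < 0) {
      P[, j] <- -P[, j]
      phi[j, ] <- -phi[j, ]
      phi[, j] <- -phi[, j]
    }
  }
  dimnames(P) <- list(rownames(A), paste0("F", seq_len(k)))
  dimnames(phi) <- list(colnames(P), colnames(P))
  list(pattern = P, structure = P %*% phi, phi = phi,
       criterion = best$f, converged = best$converged)
}

#' Run the full EFA pipeline over a range of factor counts
#'
#' For each k in `n_factors_range`: principal-axis factoring, direct-oblimin
#' rotation with Kaiser normalization, communality flags (`< 0.50`), and a
#' reporting pattern matrix with `|loading| < loading_threshold` masked
#' (values are retained unmasked in `pattern`).  Diagnostics (Bartlett, KMO,
#' per-variable MSA, anti-image matrix) and the scree eigenvalues of R are
#' computed once.  The suggested k is the Kaiser eigenvalue-greater-than-one
#' count, clipped into the requested range — a suggestion only; final choice
#' is the analyst's (interpretability).
#'
#' @param table screened covariate table (`area_id` + numeric columns).
#' @param n_factors_range integer vector of candidate factor counts.
#' @param loading_threshold mask threshold for the reported pattern matrix.
#' @param communality_flag flag variables with communality below this.
#' @param gamma oblimin gamma.
#' @return list of class `efa_result` with `diagnostics`, `scree_eigenvalues`,
#'   `fits` (one per k), `suggested_k`, `selected`.
#' @export
run_efa <- function(table, n_factors_range = 5:8, loading_threshold = 0.30,
                    communality_flag = 0.50, gamma = 0) {
  m <- numeric_covariate_matrix(table)
  n <- nrow(m)
  R <- cor(m)
  bart <- bartlett_sphericity(R, n)
  km <- kmo(R)
  scree <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  suggested <- sum(scree > 1)
  fits <- list()
  for (k in n_factors_range) {
    paf <- principal_axis_factoring(R, k)
    rot <- oblimin_rotate(paf$loadings, gamma = gamma, kaiser = TRUE)
    masked <- rot$pattern
    masked[abs(masked) < loading_threshold] <- NA
    fits[[as.character(k)]] <- list(
      n_factors = k,
      correlation_matrix = R,
      eigenvalues = paf$eigenvalues,
      communalities = paf$communalities,
      low_communality = names(paf$communalities)[
        paf$communalities < communality_flag],
      unrotated = paf$loadings,
      pattern = rot$pattern,
      pattern_masked = masked,
      structure = rot$structure,
      phi = rot$phi,
      converged = paf$converged && rot$converged,
      n_iterations = paf$n_iterations)
  }
  structure(list(
    n = n,
    diagnostics = list(bartlett = bart, kmo_overall = km$overall,
                       msa = km$msa, anti_image = km$anti_image),
    scree_eigenvalues = scree,
    fits = fits,
    suggested_k = suggested,
    selected = min(max(suggested, min(n_factors_range)), max(n_factors_range))),
    class = "efa_result")
}

#' @export
print.efa_result <- function(x, ...) {
  cat("EFA over k =", paste(names(x$fits), collapse = ", "),
      "| n =", x$n, "\n")
  cat(sprintf("Bartlett chi2 = %.2f (df %d, p = %.3g); KMO = %.3f\n",
              x$diagnostics$bartlett$chi2, x$diagnostics$bartlett$df,
              x$diagnostics$bartlett$p_value, x$diagnostics$kmo_overall))
  cat("Kaiser suggestion:", x$suggested_k, "factors; selected:", x$selected, "\n")
  invisible(x)
}

#' Write an EFA report (pattern/structure/phi/communalities + diagnostics)
#'
#' @param efa an `efa_result`.
#' @param dir output directory (created if needed).
#' @param k factor count to report (default the selected one).
#' @return The directory, invisibly.
#' @export
write_efa_report <- function(efa, dir, k = efa$selected) {
  fit <- efa$fits[[as.character(k)]]
  if (is.null(fit)) stop("no fit stored for k = ", k)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, f) write.csv(as.data.frame(x), file.path(dir, f))
  wr(fit$pattern_masked, "pattern_masked.csv")
  wr(fit$pattern, "pattern.csv")
  wr(fit$structure, "structure.csv")
  wr(fit$phi, "phi.csv")
  wr(data.frame(communality = fit$communalities), "communalities.csv")
  wr(data.frame(eigenvalue = efa$scree_eigenvalues), "scree.csv")
  dg <- efa$diagnostics
  writeLines(c(
    sprintf("n = %d", efa$n),
    sprintf("Bartlett chi2 = %.4f df = %d p = %.4g", dg$bartlett$chi2,
            dg$bartlett$df, dg$bartlett$p_value),
    sprintf("KMO overall = %.4f", dg$kmo_overall),
    "MSA per variable:",
    sprintf("  %s = %.4f", names(dg$msa), dg$msa),
    sprintf("low-communality (< 0.50) variables: %s",
            paste(fit$low_communality, collapse = ", "))),
    file.path(dir, "diagnostics.txt"))
  invisible(dir)
}
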
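## Law-Haining map decomposition: the posterior relative risk of each area
## factorizes, draw by draw, into multiplicative components
##   RR_i = exp(beta0) * prod_k exp(x_ik beta_k) * exp(u_i) * exp(v_i),
## so the contribution of each covariate, of spatial clustering and of
## unstructured heterogeneity can be mapped separately.

summarize_surface <- function(M) {
  # M: draws x areas matrix of one multiplicative component
  data.frame(mean = colMeans(M),
             median = apply(M, 2, median),
             q2.5 = apply(M, 2, quantile, 0.025),
             q97.5 = apply(M, 2, quantile, 0.975))
}

#' Decompose posterior relative risk into component surfaces
#'
#' Per kept draw and area, computes the intercept, per-covariate, spatially
#' structured and unstructured multiplicative components and the total
#' relative risk (the product, i.e. `exp(eta)` — always computed on
#' products per draw, never as a product of summaries).  Each component is
#' then summarized per area (posterior mean, median, 2.5%, 97.5%).
#'
#' @param draws a `bym_draws`.
#' @param X covariate matrix used in the fit (defaults to the stored one).
#' @param keep_draws also return the per-draw component matrices (draws x
#'   areas) under `$draws` — useful for checking the multiplicative identity.
#' @return list of class `component_surfaces`: `area_id`, `total_rr`,
#'   `intercept`, `covariates` (named list), `spatial`, `unstructured`,
#'   each a per-area summary data.frame.
#' @export
decompose_rr <- function(draws, X = draws$X, keep_draws = FALSE) {
  X <- as.matrix(X)
  p <- ncol(X)
  n <- draws$n_areas
  if (nrow(X) != n) stop("X rows must match the fitted areas")
  bmat <- do.call(rbind, lapply(draws$chains, `[[`, "beta"))
  if (p != ncol(bmat) - 1)
    stop("X columns (", p, ") do not match fitted coefficients (",
         ncol(bmat) - 1, ")")
  U <- do.call(rbind, lapply(draws$chains, `[[`, "u"))
  V <- do.call(rbind, lapply(draws$chains, `[[`, "v"))
  ndraw <- nrow(bmat)
  intercept <- matrix(exp(bmat[, 1]), ndraw, n)
  covariates <- list()
  cov_draws <- list()
  total_log <- matrix(bmat[, 1], ndraw, n) + U + V
  if (p > 0) {
    for (k in seq_len(p)) {
      lk <- outer(bmat[, k + 1], X[, k])      # draws x areas of x_ik beta_k
      covariates[[colnames(X)[k]]] <- summarize_surface(exp(lk))
      if (keep_draws) cov_draws[[colnames(X)[k]]] <- exp(lk)
      total_log <- total_log + lk
    }
  }
  kept <- if (keep_draws)
    list(intercept = intercept, covariates = cov_draws,
         spatial = exp(U), unstructured = exp(V),
         total_rr = exp(total_log)) else NULL
  structure(list(draws = kept,
                 area_id = draws$area_id,
                 total_rr = summarize_surface(exp(total_log)),
                 intercept = summarize_surface(intercept),
                 covariates = covariates,
                 spatial = summarize_surface(exp(U)),
                 unstructured = summarize_surface(exp(V))),
            class = "component_surfaces")
}

#' @export
print.component_surfaces <- function(x, ...) {
  cat("component_surfaces:", length(x$area_id), "areas;",
      length(x$covariates), "covariate component(s)\n")
  invisible(x)
}

surfaces_to_frame <- function(surfaces) {
  out <- data.frame(area_id = surfaces$area_id)
  add <- function(df, prefix) {
    for (col in names(df)) out[[paste0(prefix, "_", col)]] <<- df[[col]]
  }
  add(surfaces$total_rr, "total_rr")
  add(surfaces$intercept, "intercept")
  for (nm in names(surfaces$covariates)) add(surfaces$covariates[[nm]], nm)
  add(surfaces$spatial, "spatial")
  add(surfaces$unstructured, "unstructured")
  out
}

#' Export component surfaces as CSV and GeoJSON
#'
#' Writes a per-area CSV of all component summaries and, when an area map is
#' supplied, a GeoJSON FeatureCollection with the same summaries as feature
#' properties (one feature per area) for any choropleth tool.
#'
#' @param surfaces a `component_surfaces`.
#' @param area_map an [area_map] whose ids match the surfaces, or NULL to
#'   skip the GeoJSON.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
export_surfaces <- function(surfaces, area_map, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  df <- surfaces_to_frame(surfaces)
  write.csv(df, file.path(dir, "surfaces.csv"), row.names = FALSE)
  if (!is.null(area_map)) {
    stopifnot(inherits(area_map, "area_map"))
    missing_in_map <- setdiff(surfaces$area_id, area_map$area_id)
    missing_in_surf <- setdiff(area_map$area_id, surfaces$area_id)
    if (length(missing_in_map) || length(missing_in_surf))
      stop("area id mismatch; missing from map: ",
           paste(missing_in_map, collapse = ", "),
           "; missing from surfaces: ",
           paste(missing_in_surf, collapse = ", "))
    df_ord <- df[match(area_map$area_id, df$area_id), , drop = FALSE]
    write_geojson_areas(area_map, file.path(dir, "surfaces.geojson"),
                        properties = df_ord)
  }
  invisible(dir)
}
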
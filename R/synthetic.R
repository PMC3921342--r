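## Synthetic areal data with known ground truth.
##
## The generator emulates the study frame the package targets: ~101 suburbs,
## per-suburb survey sizes averaging ~150 mothers (n ~ 15,000 overall), a
## 6-factor covariate structure, and counts generated from a BYM
## (ICAR + iid heterogeneity) relative-risk model.

#' Default 26-variable, 6-factor loading pattern
#'
#' A simple-structure oblique pattern mirroring a published suburb-level
#' factor solution (disadvantage, social cohesion, health behaviours,
#' housing quality, service access, social capital).  Each variable loads on
#' one factor with the published primary loading and sign.
#'
#' @return 26 x 6 numeric matrix with variable row names.
#' @export
default_loading_pattern <- function() {
  rows <- list(
    # factor 1: disadvantaged community
    OneParentFamilies = c(1, 0.912), RentedDwellings = c(1, 0.818),
    PublicHousing = c(1, 0.777), UnplannedPregnancy = c(1, 0.709),
    OccupationalClass3 = c(1, 0.584), PoorFamilies = c(1, 0.567),
    ViolentCrimeRate = c(1, 0.546),
    # factor 2: social cohesion
    Volunteerism = c(2, 0.927), EntropyIndex = c(2, -0.784),
    NoVolunteerism = c(2, -0.651), LowSchooling = c(2, -0.567),
    IRSDDecile = c(2, -0.468),
    # factor 3: health behaviours
    Breastfeeding = c(3, 0.907), Smoking = c(3, 0.899),
    NoRegretLeaving = c(3, 0.795),
    # factor 4: housing quality
    Apartments = c(4, -0.825), SingleHouses = c(4, 0.728),
    VacancyRate = c(4, -0.637),
    # factor 5: access to services
    NurseVisitRate = c(5, 0.767), HomeVisitRate = c(5, 0.535),
    PoorHealth = c(5, 0.363),
    # factor 6: social capital / support networks
    NoSocialSupport = c(6, -0.679), NoPracticalSupport = c(6, -0.589),
    Density = c(6, -0.493), DifferentAddress5y = c(6, 0.395),
    MalyIndex = c(6, 0.308))
  L <- matrix(0, length(rows), 6,
              dimnames = list(names(rows), paste0("F", 1:6)))
  for (i in seq_along(rows)) L[i, rows[[i]][1]] <- rows[[i]][2]
  L
}

#' Default factor intercorrelation matrix
#'
#' Mild oblique structure: 0.15 baseline, 0.40 between disadvantage and
#' health behaviours, 0.26 between social cohesion and social capital
#' (the two correlations the source analysis reports).
#'
#' @return 6 x 6 positive-definite correlation matrix.
#' @export
default_factor_correlations <- function() {
  phi <- matrix(0.15, 6, 6)
  diag(phi) <- 1
  phi[1, 3] <- phi[3, 1] <- 0.40
  phi[2, 6] <- phi[6, 2] <- 0.26
  phi
}

#' Specify a synthetic areal study
#'
#' Bundles every knob of the generator.  Defaults state the emulated world:
#' 101 areas, 6 factors with the published loading pattern, survey sizes of
#' 60-245 mothers per area (mean ~152, i.e. ~15,400 overall), and a baseline
#' outcome prevalence of 9% (a realistic regional EDS > 12 rate).
#'
#' @param n_areas number of areas (default 101).
#' @param lattice_kind `"grid"` or `"voronoi"`.
#' @param loading_matrix variables x factors pattern matrix.
#' @param factor_correlations factor correlation matrix.
#' @param noise_sd unique-error standard deviation; `NULL` (default) completes
#'   each variable to unit total variance.
#' @param beta0 log baseline relative risk.
#' @param beta covariate effects on the log relative-risk scale.
#' @param sigma_u,sigma_v scales of the structured (ICAR) and unstructured
#'   random effects.
#' @param survey_size_range integer (min, max) mothers surveyed per area.
#' @param baseline_rate regional outcome prevalence in (0, 1).
#' @param family outcome likelihood used generatively: `"poisson"` (default,
#'   the standard disease-mapping approximation) or `"binomial"`.
#' @param seed integer seed; all generator randomness derives from it.
#' @return Object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_areas = 101L,
                            lattice_kind = c("grid", "voronoi"),
                            loading_matrix = default_loading_pattern(),
                            factor_correlations = default_factor_correlations(),
                            noise_sd = NULL,
                            beta0 = 0,
                            beta = numeric(0),
                            sigma_u = 0.3,
                            sigma_v = 0.1,
                            survey_size_range = c(60L, 245L),
                            baseline_rate = 0.09,
                            family = c("poisson", "binomial"),
                            seed = 1L) {
  lattice_kind <- match.arg(lattice_kind)
  family <- match.arg(family)
  stopifnot(n_areas >= 2, baseline_rate > 0, baseline_rate < 1,
            sigma_u >= 0, sigma_v >= 0,
            length(survey_size_range) == 2, survey_size_range[1] >= 1,
            survey_size_range[1] <= survey_size_range[2])
  phi <- as.matrix(factor_correlations)
  if (!isTRUE(all.equal(phi, t(phi))) || any(abs(diag(phi) - 1) > 1e-12))
    stop("factor_correlations must be symmetric with unit diagonal")
  if (min(eigen(phi, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("factor_correlations must be positive definite")
  L <- as.matrix(loading_matrix)
  if (ncol(L) != ncol(phi)) stop("loading_matrix / factor_correlations mismatch")
  if (!is.null(noise_sd) && noise_sd <= 0) stop("noise_sd must be positive")
  structure(list(n_areas = as.integer(n_areas), lattice_kind = lattice_kind,
                 loading_matrix = L, factor_correlations = phi,
                 noise_sd = noise_sd, beta0 = beta0, beta = beta,
                 sigma_u = sigma_u, sigma_v = sigma_v,
                 survey_size_range = as.integer(survey_size_range),
                 baseline_rate = baseline_rate, family = family,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

## ---- lattices -------------------------------------------------------------

grid_lattice <- function(n_areas) {
  nc <- ceiling(sqrt(n_areas))
  polys <- vector("list", n_areas)
  for (i in seq_len(n_areas)) {
    r <- (i - 1) %/% nc
    c <- (i - 1) %% nc
    polys[[i]] <- cbind(c(c, c + 1, c + 1, c), c(r, r, r + 1, r + 1))
  }
  area_map(sprintf("A%03d", seq_len(n_areas)), polys)
}

# clip a convex polygon by the half-plane {x : a.x <= b} (Sutherland-Hodgman)
clip_halfplane <- function(poly, a, b) {
  n <- nrow(poly)
  out <- matrix(0, 0, 2)
  d <- poly %*% a - b
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (d[i] <= 0) out <- rbind(out, poly[i, ])
    if ((d[i] <= 0) != (d[j] <= 0)) {
      t <- d[i] / (d[i] - d[j])
      out <- rbind(out, poly[i, ] + t * (poly[j, ] - poly[i, ]))
    }
  }
  out
}

voronoi_lattice <- function(n_areas) {
  pts <- cbind(runif(n_areas), runif(n_areas))
  square <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  polys <- vector("list", n_areas)
  for (i in seq_len(n_areas)) {
    cell <- square
    for (j in seq_len(n_areas)) {
      if (j == i) next
      a <- pts[j, ] - pts[i, ]
      b <- sum(a * (pts[i, ] + pts[j, ]) / 2)
      cell <- clip_halfplane(cell, a, b)
      if (nrow(cell) < 3) break
    }
    if (nrow(cell) < 3) return(NULL)   # degenerate tessellation; retry
    polys[[i]] <- cell
  }
  area_map(sprintf("A%03d", seq_len(n_areas)), polys)
}

#' Generate a planar areal map for simulation
#'
#' `grid` packs `n_areas` unit cells row-major into a near-square rectangle
#' (e.g. 101 areas = ten full rows of 11 plus a partial row), which is
#' rook-connected by construction.  `voronoi` tessellates `n_areas` uniform
#' seed points in the unit square; the tessellation is regenerated (bounded
#' retries) if its rook graph is disconnected or degenerate.
#'
#' @param spec a [simulation_spec].
#' @return An [area_map] whose rook-contiguity graph is connected.
#' @export
make_lattice <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (spec$lattice_kind == "grid") return(grid_lattice(spec$n_areas))
  set.seed(spec$seed)
  for (attempt in 1:5) {
    map <- voronoi_lattice(spec$n_areas)
    if (is.null(map)) next
    ok <- tryCatch({ build_adjacency(map, "rook", snap = 1e-9); TRUE },
                   error = function(e) FALSE)
    if (ok) return(map)
  }
  stop("could not generate a connected voronoi lattice in 5 attempts")
}

## ---- covariates -----------------------------------------------------------

#' Simulate factor-structured covariates
#'
#' Draws factor scores F (covariance = the given factor correlations) and
#' unique errors E, and returns X = F L' + E.  Unique standard deviations
#' default to completing each variable to unit total variance; columns are
#' standardized to zero mean / unit sample variance on output.
#'
#' @param spec a [simulation_spec].
#' @param n_areas number of rows to generate (defaults to `spec$n_areas`).
#' @param standardize standardize columns on output (default TRUE).
#' @return data.frame with `area_id` and one column per variable.
#' @export
simulate_covariates <- function(spec, n_areas = spec$n_areas, standardize = TRUE) {
  stopifnot(inherits(spec, "simulation_spec"))
  L <- spec$loading_matrix
  phi <- spec$factor_correlations
  p <- nrow(L); k <- ncol(L)
  h2 <- rowSums((L %*% phi) * L)      # communalities under the oblique model
  if (is.null(spec$noise_sd)) {
    uniq <- 1 - h2
    if (any(uniq <= 0))
      stop("implied unique variance <= 0 for variable(s): ",
           paste(rownames(L)[uniq <= 0], collapse = ", "))
    esd <- sqrt(uniq)
  } else esd <- rep(spec$noise_sd, p)
  set.seed(spec$seed + 1000L)
  Fs <- matrix(rnorm(n_areas * k), n_areas, k) %*% chol(phi)
  E <- matrix(rnorm(n_areas * p), n_areas, p) %*% diag(esd, p)
  X <- Fs %*% t(L) + E
  if (standardize) X <- scale(X)
  df <- data.frame(area_id = sprintf("A%03d", seq_len(n_areas)))
  vn <- rownames(L)
  if (is.null(vn)) vn <- paste0("V", seq_len(p))
  df[vn] <- as.data.frame(unclass(X))
  df
}

## ---- random effects and outcomes ------------------------------------------

#' Draw from the intrinsic CAR (ICAR) distribution
#'
#' Returns one draw of the spatially structured effect u with scale
#' `sigma_u`, i.e. a zero-mean Gaussian with covariance
#' `sigma_u^2 * pinv(D - W)` restricted to the sum-to-zero subspace (the
#' ICAR precision `(D - W)/sigma_u^2` is singular; its null space, the
#' constant vector on a connected graph, is pinned by the constraint).
#'
#' @param adjacency an [adjacency_matrix] (must be connected).
#' @param sigma_u positive scale.
#' @param seed optional integer seed.
#' @return Numeric vector of length `adjacency$n` summing to zero.
#' @export
sample_icar <- function(adjacency, sigma_u, seed = NULL) {
  stopifnot(inherits(adjacency, "adjacency_matrix"))
  if (sigma_u <= 0) stop("sigma_u must be > 0")
  if (!is.null(seed)) set.seed(seed)
  n <- adjacency$n
  Q <- diag(adjacency$num)
  for (i in seq_len(n)) Q[i, adjacency$neighbours[[i]]] <- -1
  e <- eigen(Q, symmetric = TRUE)
  pos <- e$values > max(e$values) * 1e-10
  if (sum(!pos) != 1L)
    stop("ICAR precision has ", sum(!pos), " null eigenvalues; graph must be connected")
  z <- rnorm(sum(pos))
  u <- sigma_u * (e$vectors[, pos, drop = FALSE] %*% (z / sqrt(e$values[pos])))
  u <- drop(u)
  u - mean(u)   # exact sum-to-zero (removes numerical residue)
}

#' Simulate outcome counts from a BYM model
#'
#' Draws per-area survey sizes, structured (ICAR) and unstructured random
#' effects, forms relative risks `theta = exp(beta0 + X beta + u + v)`, and
#' draws counts `O ~ Poisson(baseline_rate * n * theta)` truncated at the
#' survey size (or `Binomial(n, baseline_rate * theta)` when
#' `spec$family == "binomial"`).  Expected counts and SMRs in the returned
#' outcome table are internally standardized from the realized data, as an
#' analyst without the truth would compute them.
#'
#' @param spec a [simulation_spec]; `length(spec$beta)` covariate columns are
#'   used from `covariates`.
#' @param covariates data.frame from [simulate_covariates()] (or compatible);
#'   the first `length(spec$beta)` non-id columns are used.
#' @param adjacency an [adjacency_matrix] for the ICAR draw.
#' @return List of class `synthetic_dataset` with `outcomes` (see
#'   [expected_counts()]), `covariates`, `X` (the design matrix used) and
#'   `truth` (beta0, beta, u, v, sigma_u, sigma_v).
#' @export
simulate_outcomes <- function(spec, covariates, adjacency) {
  stopifnot(inherits(spec, "simulation_spec"),
            inherits(adjacency, "adjacency_matrix"))
  n <- adjacency$n
  num_cols <- setdiff(names(covariates), "area_id")
  if (nrow(covariates) != n) stop("covariates rows must equal n_areas")
  p <- length(spec$beta)
  if (p > length(num_cols)) stop("not enough covariate columns for beta")
  X <- if (p > 0) as.matrix(covariates[, num_cols[seq_len(p)], drop = FALSE])
       else matrix(0, n, 0)
  set.seed(spec$seed + 2000L)
  surveyed <- sample(spec$survey_size_range[1]:spec$survey_size_range[2], n,
                     replace = TRUE)
  u <- if (spec$sigma_u > 0) sample_icar(adjacency, spec$sigma_u) else rep(0, n)
  v <- if (spec$sigma_v > 0) rnorm(n, 0, spec$sigma_v) else rep(0, n)
  eta <- spec$beta0 + (if (p > 0) drop(X %*% spec$beta) else 0) + u + v
  theta <- exp(eta)
  if (any(!is.finite(theta))) stop("non-finite relative risk generated")
  prate <- spec$baseline_rate * theta
  if (mean(prate > 1) > 0.05)
    stop("baseline_rate * theta exceeds 1 in more than 5% of areas; ",
         "the simulation spec is implausible")
  observed <- switch(spec$family,
    poisson  = pmin(rpois(n, prate * surveyed), surveyed),
    binomial = rbinom(n, surveyed, pmin(prate, 1)))
  outcomes <- expected_counts(observed, surveyed,
                              area_id = covariates$area_id, cutoff = "EDS>12")
  structure(list(outcomes = outcomes, covariates = covariates, X = X,
                 truth = list(beta0 = spec$beta0, beta = spec$beta, u = u, v = v,
                              sigma_u = spec$sigma_u, sigma_v = spec$sigma_v)),
            class = "synthetic_dataset")
}

#' One-call synthetic study: map, adjacency, covariates and outcomes
#'
#' @param spec a [simulation_spec].
#' @param rule contiguity rule for the adjacency graph.
#' @return `synthetic_dataset` with `area_map` and `adjacency` attached.
#' @export
simulate_dataset <- function(spec, rule = "queen") {
  map <- make_lattice(spec)
  adj <- build_adjacency(map, rule)
  cov <- simulate_covariates(spec)
  ds <- simulate_outcomes(spec, cov, adj)
  ds$area_map <- map
  ds$adjacency <- adj
  ds
}
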
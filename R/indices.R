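## Derived ecological covariates: expected counts / SMRs, ethnic diversity
## indices, and the index of concentration at the extremes (ICE).

#' Internally standardized expected counts and SMRs
#'
#' The regional rate is `sum(observed) / sum(surveyed)`; each area's expected
#' count is that rate times the number surveyed there, so expected counts
#' conserve the observed total exactly.  `smr = observed / expected`.
#'
#' @param observed non-negative integer counts above the outcome cut-off.
#' @param surveyed positive integer numbers surveyed per area.
#' @param area_id optional identifiers (defaults to row numbers).
#' @param cutoff label for the outcome cut-off (e.g. `"EDS>9"`, `"EDS>12"`).
#' @param reference_denominator optional alternative denominator (e.g. women
#'   of child-bearing age) used in place of `surveyed` to form the rate and
#'   expected counts; a sensitivity-analysis hook, not a separate code path.
#' @return data.frame of class `outcome_table` with columns `area_id`,
#'   `observed`, `surveyed`, `expected`, `smr` and attribute `cutoff`.
#' @export
expected_counts <- function(observed, surveyed, area_id = NULL,
                            cutoff = "EDS>12", reference_denominator = NULL) {
  observed <- as.numeric(observed)
  surveyed <- as.numeric(surveyed)
  if (length(observed) != length(surveyed)) stop("length mismatch")
  if (any(surveyed <= 0))
    stop("all surveyed counts must be positive; drop empty areas upstream")
  if (any(observed < 0)) stop("observed counts must be non-negative")
  if (any(observed > surveyed)) stop("observed cannot exceed surveyed")
  denom <- if (is.null(reference_denominator)) surveyed
           else as.numeric(reference_denominator)
  if (any(denom <= 0)) stop("denominator must be positive")
  rate <- sum(observed) / sum(denom)
  expected <- rate * denom
  if (rate == 0) {
    warning("all observed counts are zero; SMRs set to 0")
    smr <- rep(0, length(observed))
  } else smr <- observed / expected
  if (is.null(area_id)) area_id <- as.character(seq_along(observed))
  out <- data.frame(area_id = as.character(area_id), observed = observed,
                    surveyed = surveyed, expected = expected, smr = smr)
  attr(out, "cutoff") <- cutoff
  class(out) <- c("outcome_table", "data.frame")
  out
}

check_proportions <- function(p, what = "p") {
  p <- as.numeric(p)
  if (length(p) < 2) stop(what, " needs at least 2 categories")
  if (any(p < 0)) stop(what, " has negative entries")
  if (abs(sum(p) - 1) > 1e-9) stop(what, " must sum to 1")
  p
}

#' Normalized entropy (Shannon) diversity index
#'
#' `E = -sum(p * log(p)) / log(R)` with `0 * log(0) := 0`; 0 for a completely
#' homogeneous composition, 1 for a uniform one.
#'
#' @param p proportions over R >= 2 categories, summing to 1.
#' @param normalize divide by `log(R)` (default TRUE, giving range [0, 1]).
#' @return scalar in [0, 1].
#' @export
entropy_index <- function(p, normalize = TRUE) {
  p <- check_proportions(p)
  terms <- ifelse(p > 0, p * log(p), 0)
  e <- -sum(terms)
  if (normalize) e <- e / log(length(p))
  e
}

#' Simpson diversity index
#'
#' `S = 1 - sum(p^2)`: the probability two randomly chosen residents belong
#' to different groups.  0 for a homogeneous composition; the maximum is
#' `1 - 1/R` (unnormalized by convention).
#'
#' @inheritParams entropy_index
#' @return scalar in [0, 1).
#' @export
simpson_index <- function(p) {
  p <- check_proportions(p)
  1 - sum(p^2)
}

#' Maly neighbourhood diversity index
#'
#' One minus half the L1 divergence between the area's composition and the
#' metropolitan reference composition: 1 when the area exactly matches the
#' metropolitan distribution, approaching 0 as the area concentrates in
#' groups absent from the reference.
#'
#' @param p_area area composition over R categories, summing to 1.
#' @param p_metro metropolitan reference over the same categories.
#' @return scalar in [0, 1].
#' @export
maly_index <- function(p_area, p_metro) {
  p_area <- check_proportions(p_area, "p_area")
  p_metro <- check_proportions(p_metro, "p_metro")
  if (length(p_area) != length(p_metro))
    stop("p_area and p_metro must share the same categories")
  1 - sum(abs(p_area - p_metro)) / 2
}

#' Index of concentration at the extremes (ICE)
#'
#' `(affluent - poor) / total` families: -1 when all families are poor,
#' +1 when all are affluent, 0 when balanced.
#'
#' @param affluent,poor,total family counts (vectorized).
#' @return values in [-1, 1].
#' @export
ice <- function(affluent, poor, total) {
  if (any(total <= 0)) stop("total must be positive")
  if (any(affluent + poor > total))
    stop("affluent + poor cannot exceed total")
  if (any(affluent < 0) || any(poor < 0)) stop("counts must be non-negative")
  (affluent - poor) / total
}

#' Per-area diversity indices from an ethnic composition table
#'
#' @param composition matrix/data.frame of per-area proportions over R
#'   categories (rows sum to 1).
#' @param metro_reference reference composition for the Maly index.
#' @return data.frame with columns `entropy`, `simpson`, `maly`.
#' @export
diversity_indices <- function(composition, metro_reference) {
  m <- as.matrix(composition)
  data.frame(
    entropy = apply(m, 1, entropy_index),
    simpson = apply(m, 1, simpson_index),
    maly = apply(m, 1, function(p) maly_index(p, metro_reference)))
}
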
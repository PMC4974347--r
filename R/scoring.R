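#' Forward model: probability of observing a cross-link at distance d
#'
#' Logistic in the bead-bead distance: `1 / (1 + exp((d - d0) / lambda))`.
#' Monotone non-increasing in d, value 1/2 at `d = d0`, approaching 1 as
#' d -> 0 and 0 as d -> infinity.
#'
#' @param d Distance(s) in Angstrom (>= 0).
#' @param params An [scoring_params()] (or anything with `d0`, `lambda`).
#' @return Probabilities in (0, 1).
#' @export
forward_model_probability <- function(d, params = scoring_params()) {
  stopifnot(all(d >= 0))
  1 / (1 + exp((d - params$d0) / params$lambda))
}

#' Cross-link log likelihood
#'
#' Sum over restrained pairs of `log(psi_c + (1 - 2 psi_c) * f(d))`, where
#' `f` is the logistic forward model, `d` the center-center distance of the
#' beads holding the two linked residues, and `psi_c` the uncertainty of the
#' link's class (`consistent` or `single`). At `d = d0` each term is
#' log(1/2) regardless of psi; as all distances shrink and psi -> 0 the log
#' likelihood approaches 0.
#'
#' @param coords N x 3 coordinate matrix (bead centers).
#' @param system An [bind_system()] result.
#' @param psi Numeric vector `c(consistent, single)` in (0, 0.5).
#' @return The log likelihood (scalar).
#' @export
crosslink_log_likelihood <- function(coords, system, psi) {
  d <- pair_dist(coords, system$xl_i, system$xl_j)
  f <- forward_model_probability(d, system$params)
  p <- psi[system$xl_class]
  sum(log(p + (1 - 2 * p) * f))
}

#' Prior score: excluded volume, connectivity, disulfides
#'
#' Sum of (a) soft-sphere excluded volume, `k_ev * overlap^2` for every
#' bead pair in different rigid bodies / strings (sequence-adjacent pairs
#' exempt), where overlap is the interpenetration of the two bead spheres;
#' (b) sequence connectivity, an upper-bounded harmonic
#' `k_conn * (d - rest)^2` for consecutive beads stretched beyond their
#' rest length (rest = 4 Angstrom per residue of sequence separation);
#' (c) a two-sided harmonic `k_ss * (d - rest)^2` on each disulfide pair.
#' Zero for a relaxed, non-overlapping configuration with disulfides at
#' rest length.
#'
#' @inheritParams crosslink_log_likelihood
#' @return The prior score (scalar, >= 0).
#' @export
prior_score <- function(coords, system) {
  rep <- system$rep
  par <- system$params
  s <- 0
  if (length(rep$ev$i) > 0) {
    d <- pair_dist(coords, rep$ev$i, rep$ev$j)
    overlap <- pmax(0, rep$ev$rsum - d)
    s <- s + par$k_ev * sum(overlap^2)
  }
  if (length(rep$conn$i) > 0) {
    d <- pair_dist(coords, rep$conn$i, rep$conn$j)
    stretch <- pmax(0, d - rep$conn$rest)
    s <- s + par$k_conn * sum(stretch^2)
  }
  if (length(system$ss_i) > 0) {
    d <- pair_dist(coords, system$ss_i, system$ss_j)
    s <- s + par$k_ss * sum((d - par$disulfide_rest)^2)
  }
  s
}

#' Total score (negative log posterior)
#'
#' `-log p(M | D, I)` up to a constant: minus the cross-link log likelihood
#' plus the prior score. The psi prior is uniform on
#' `[psi_min, psi_max]`, so it contributes a constant inside its bounds
#' (proposals are reflected at the bounds and never leave them). Lower is
#' better.
#'
#' @inheritParams crosslink_log_likelihood
#' @return The score (scalar).
#' @export
total_score <- function(coords, psi, system) {
  -crosslink_log_likelihood(coords, system, psi) +
    prior_score(coords, system)
}

pair_dist <- function(coords, i, j) {
  dx <- coords[i, 1] - coords[j, 1]
  dy <- coords[i, 2] - coords[j, 2]
  dz <- coords[i, 3] - coords[j, 3]
  sqrt(dx * dx + dy * dy + dz * dz)
}
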
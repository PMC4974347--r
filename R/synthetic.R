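#' Build a ground-truthed toy multi-domain protein
#'
#' Generates a deterministic (seeded) multi-domain protein in one or more
#' conformational states. Each domain is a compact cluster of beads at
#' C-alpha-like spacing (3.8 Angstrom snake path on a cubic grid), domains
#' are joined by flexible linker residues, and each state places the same
#' rigid domains at different positions/orientations — mimicking, e.g., a
#' terminal domain migrating along the length of a molecule between
#' conformers. Residue types are drawn with an enriched fraction of the
#' amine-reactive types (K, and some S/T/Y) so plenty of residue pairs are
#' cross-linkable.
#'
#' @param n_domains Number of domains (>= 2).
#' @param residues_per_domain Residues per domain.
#' @param linker_length Flexible residues between consecutive domains.
#' @param placements Named list of states; each state is a data frame with
#'   one row per domain: `domain` (1..n_domains), `x`, `y`, `z` (domain
#'   center) and optionally `angle`, `ax`, `ay`, `az` (rotation). `NULL`
#'   gives two default states where the last domain relocates from one end
#'   of the molecule to the other.
#' @param seed Integer seed (full determinism).
#' @return An `xl_toy_protein`: list with `coords` (tibble: `state`,
#'   `resno`, `domain`, `residue_type`, `x`, `y`, `z`), `domains` (tibble
#'   with `domain`, `start`, `end`), `placements` and `seed`.
#' @export
make_toy_protein <- function(n_domains = 3, residues_per_domain = 12,
                             linker_length = 6, placements = NULL,
                             seed = 1) {
  stopifnot(n_domains >= 2, residues_per_domain >= 3)
  if (is.null(placements)) {
    # compact assembly: consecutive domains in contact, as in a real
    # multi-domain protein; state B relocates the last domain to the far
    # side of the first one
    spacing <- 12.5
    base <- tibble::tibble(
      domain = seq_len(n_domains),
      x = (seq_len(n_domains) - 1) * spacing, y = 0, z = 0
    )
    moved <- base
    moved$x[n_domains] <- base$x[1] + 3
    moved$y[n_domains] <- 12.5
    moved$z[n_domains] <- 1.5
    placements <- list(A = base, B = moved)
  }
  with_seed(seed, {
    template <- domain_template(residues_per_domain)
    n_res <- n_domains * residues_per_domain +
      (n_domains - 1) * linker_length
    types <- sample(c("K", "S", "T", "Y", "A", "L", "E", "G", "V", "D"),
                    n_res, replace = TRUE,
                    prob = c(0.25, 0.08, 0.08, 0.08, 0.1, 0.1, 0.09,
                             0.08, 0.07, 0.07))
    dom_start <- (seq_len(n_domains) - 1) *
      (residues_per_domain + linker_length) + 1
    domains <- tibble::tibble(
      domain = seq_len(n_domains), start = dom_start,
      end = dom_start + residues_per_domain - 1
    )
    coords <- dplyr::bind_rows(lapply(names(placements), function(st) {
      pl <- tibble::as_tibble(placements[[st]])
      dom_xyz <- vector("list", n_domains)
      for (d in seq_len(n_domains)) {
        xyz <- template
        row <- pl[pl$domain == d, ]
        if (all(c("angle", "ax", "ay", "az") %in% names(row)) &&
            nrow(row) == 1 && !is.na(row$angle)) {
          ax <- c(row$ax, row$ay, row$az)
          ax <- ax / sqrt(sum(ax^2))
          xyz <- xyz %*% t(rotation_matrix(ax, row$angle))
        }
        dom_xyz[[d]] <- sweep(xyz, 2, c(row$x, row$y, row$z), "+")
      }
      res_rows <- vector("list", 2 * n_domains - 1)
      for (d in seq_len(n_domains)) {
        res_rows[[2 * d - 1]] <- tibble::tibble(
          resno = seq(domains$start[d], domains$end[d]),
          domain = paste0("D", d),
          x = dom_xyz[[d]][, 1], y = dom_xyz[[d]][, 2],
          z = dom_xyz[[d]][, 3]
        )
        if (d < n_domains && linker_length > 0) {
          from <- dom_xyz[[d]][residues_per_domain, ]
          to <- dom_xyz[[d + 1]][1, ]
          center <- colMeans(do.call(rbind, lapply(dom_xyz, colMeans)))
          pts <- arc_linker(from, to, linker_length, away_from = center)
          res_rows[[2 * d]] <- tibble::tibble(
            resno = seq(domains$end[d] + 1, domains$end[d] + linker_length),
            domain = "linker",
            x = pts[, 1], y = pts[, 2], z = pts[, 3]
          )
        }
      }
      out <- dplyr::bind_rows(res_rows)
      xyz <- relax_linker_beads(as.matrix(out[, c("x", "y", "z")]),
                                out$domain == "linker", out$resno)
      out$x <- xyz[, 1]
      out$y <- xyz[, 2]
      out$z <- xyz[, 3]
      out$state <- st
      out
    }))
    coords$residue_type <- types[coords$resno]
    structure(list(
      coords = coords[, c("state", "resno", "domain", "residue_type",
                          "x", "y", "z")],
      domains = domains, placements = placements, seed = seed
    ), class = "xl_toy_protein")
  })
}

# deterministic steric relaxation of linker beads: repeatedly push each
# flexible bead out of overlaps (same radii and 1-2/1-3 exemptions the
# modeling representation uses) and re-project onto the chain so bonded
# neighbors stay within the connectivity rest length; rigid beads never move
relax_linker_beads <- function(xyz, is_flex, resno, r_flex = 3.0,
                               r_rigid = 2.4, rest = 4.0, iters = 400,
                               step = 0.2) {
  n <- nrow(xyz)
  rad <- ifelse(is_flex, r_flex, r_rigid)
  flex <- which(is_flex)
  if (length(flex) == 0) return(xyz)
  for (it in seq_len(iters)) {
    force <- matrix(0, length(flex), 3)
    for (k in seq_along(flex)) {
      i <- flex[k]
      dv <- sweep(xyz, 2, xyz[i, ], "-")   # vectors i -> others
      dist <- sqrt(rowSums(dv^2))
      rsum <- rad + rad[i]
      clash <- which(dist < rsum & abs(resno - resno[i]) > 2)
      f <- c(0, 0, 0)
      if (length(clash) > 0) {
        # repulsion proportional to the overlap, away from each clash
        f <- f - colSums(dv[clash, , drop = FALSE] *
                           ((rsum[clash] - dist[clash]) /
                              pmax(dist[clash], 0.2)))
      }
      for (j in c(i - 1, i + 1)) {
        if (j >= 1 && j <= n && abs(resno[j] - resno[i]) == 1 &&
            dist[j] > rest) {
          # spring pulling an over-stretched bond back to rest length
          f <- f + dv[j, ] * (dist[j] - rest) / dist[j]
        }
      }
      force[k, ] <- f
    }
    norms <- sqrt(rowSums(force^2))
    if (max(norms) < 1e-3) break
    # damped, capped simultaneous update (per-bead step <= `step` Angstrom)
    scale <- pmin(1, 1 / pmax(norms, 1e-9))
    xyz[flex, ] <- xyz[flex, ] + step * force * scale
  }
  xyz
}

# place n linker beads between two anchor points at ~3.8 A spacing along a
# circular arc bulging away from the molecule center, so planted linkers are
# neither compressed (no self-overlap) nor stretched (no connectivity
# penalty) and avoid the domain surfaces
arc_linker <- function(from, to, n, away_from,
                       target_spacing = 3.8) {
  chord <- sqrt(sum((to - from)^2))
  want <- target_spacing * (n + 1)
  if (chord >= want) {
    # anchors too far apart for a relaxed chain: straight, equally spaced
    frac <- seq_len(n) / (n + 1)
    return(outer(frac, to - from) + matrix(from, n, 3, byrow = TRUE))
  }
  mid <- (from + to) / 2
  u <- mid - away_from
  # bulge direction perpendicular to the chord
  ch <- (to - from) / chord
  u <- u - sum(u * ch) * ch
  if (sqrt(sum(u^2)) < 1e-8) u <- perpendicular_of(ch)
  u <- u / sqrt(sum(u^2))
  # solve the arc angle: arclength = R * theta with R = chord/(2 sin(theta/2))
  theta <- stats::uniroot(function(th) {
    chord * th / (2 * sin(th / 2)) - want
  }, c(1e-6, 2 * pi - 1e-3))$root
  r <- chord / (2 * sin(theta / 2))
  ctr <- mid - r * cos(theta / 2) * u
  phi <- -theta / 2 + seq_len(n) / (n + 1) * theta
  t(vapply(phi, function(a) {
    ctr + r * (sin(a) * ch + cos(a) * u)
  }, numeric(3)))
}

perpendicular_of <- function(v) {
  w <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  p <- w - sum(w * v) * v
  p / sqrt(sum(p^2))
}

# compact snake path on a near-cubic grid, 3.8 A spacing, centered on the
# origin; grid dimensions are chosen as balanced as possible so domains are
# genuinely three-dimensional (link anchors far from coplanar)
domain_template <- function(n) {
  nz <- max(2, floor(n^(1 / 3)))
  ny <- max(2, floor(sqrt(n / nz)))
  nx <- ceiling(n / (ny * nz))
  # 2D boustrophedon over one layer; each successive layer retraces the
  # previous one in reverse, so consecutive beads are always grid neighbors
  layer <- do.call(rbind, lapply(seq_len(ny), function(iy) {
    xs <- if (iy %% 2 == 1) seq_len(nx) else rev(seq_len(nx))
    cbind(xs, iy)
  }))
  pts <- do.call(rbind, lapply(seq_len(nz), function(iz) {
    l <- if (iz %% 2 == 1) layer else layer[rev(seq_len(nrow(layer))), ]
    cbind(l, iz)
  }))[seq_len(n), ]
  pts <- pts * 3.8
  sweep(pts, 2, colMeans(pts))
}

#' Representation of a toy protein's domains as rigid bodies
#'
#' Convenience builder: every domain of the toy protein becomes one rigid
#' body (named `D1`, `D2`, ...), linkers become flexible strings, and the
#' chosen state's coordinates initialize the beads.
#'
#' @param toy An `xl_toy_protein`.
#' @param state State whose coordinates to use.
#' @param core Name of the core (fixed, superposition-target) body.
#' @return An `xl_representation`.
#' @export
toy_representation <- function(toy, state, core = "D1") {
  s <- toy_state_structure(toy, state)
  bodies <- lapply(seq_len(nrow(toy$domains)), function(d) {
    list(c(toy$domains$start[d], toy$domains$end[d]))
  })
  names(bodies) <- paste0("D", toy$domains$domain)
  if (!is.null(toy$domain_names)) names(bodies) <- toy$domain_names
  build_representation(s, bodies, core = core)
}

#' Coordinates of one state as an `xl_structure`
#'
#' @param toy An `xl_toy_protein`.
#' @param state State name.
#' @return An `xl_structure` for that state.
#' @export
toy_state_structure <- function(toy, state) {
  st <- toy$coords[toy$coords$state == state, ]
  if (nrow(st) == 0) stop("Unknown state: ", state, call. = FALSE)
  as_structure(st, structure_id = paste0("toy_", state))
}

#' Simulate distance-limited cross-link detection
#'
#' Samples cross-links among reactive-residue pairs of one conformational
#' state: true links come from pairs whose C-alpha distance is at most the
#' detection cutoff, noise links from pairs beyond it. Each emitted link is
#' a noise link with probability `noise_rate`. Deterministic given the seed.
#'
#' @param structure An `xl_structure` (one state's coordinates with residue
#'   types).
#' @param linker A [linker_spec()]; its reactive residue types define the
#'   candidate positions.
#' @param detection_cutoff Distance cutoff in Angstrom for a true link
#'   (default 27.4, the lysine-lysine reach of BS3).
#' @param n_links Number of links to emit.
#' @param noise_rate Probability in `[0, 1)` that an emitted link is a
#'   noise link.
#' @param min_seq_sep Minimum residue separation of a pair (default 5;
#'   nearer pairs are trivially linkable and uninformative).
#' @param seed Integer seed.
#' @return A link tibble: `res_a`, `res_b`, `type_a`, `type_b`, `distance`
#'   (in this state), `truth` (`"true"` or `"noise"`), `link_id`.
#' @export
simulate_crosslinks <- function(structure, linker = default_bs3_linker(),
                                detection_cutoff = 27.4, n_links = 15,
                                noise_rate = 0.05, min_seq_sep = 5,
                                seed = 1) {
  stopifnot(noise_rate >= 0, noise_rate < 1)
  cand <- crosslink_candidates(structure, linker, min_seq_sep)
  true_pool <- cand[cand$distance <= detection_cutoff, ]
  noise_pool <- cand[cand$distance > detection_cutoff, ]
  with_seed(seed, {
    is_noise <- stats::runif(n_links) < noise_rate
    n_noise <- sum(is_noise)
    n_true <- n_links - n_noise
    if (n_true > nrow(true_pool)) {
      stop("Not enough linkable pairs under the cutoff (", nrow(true_pool),
           " available, ", n_true, " requested).", call. = FALSE)
    }
    if (n_noise > nrow(noise_pool)) {
      stop("Not enough pairs beyond the cutoff for noise links.",
           call. = FALSE)
    }
    picked <- dplyr::bind_rows(
      true_pool[sample.int(nrow(true_pool), n_true), ],
      noise_pool[sample.int(nrow(noise_pool), n_noise), ]
    )
    picked$truth <- rep(c("true", "noise"), c(n_true, n_noise))
    normalize_links(picked[sample.int(nrow(picked)), ])
  })
}

# all reactive-residue pairs with distances
crosslink_candidates <- function(structure, linker, min_seq_sep) {
  reactive <- setdiff(names(linker$reactive_residues), "Nterm")
  s <- structure[structure$residue_type %in% reactive, ]
  n <- nrow(s)
  if (n < 2) stop("Too few reactive residues.", call. = FALSE)
  pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- abs(s$resno[pr[, 1]] - s$resno[pr[, 2]]) >= min_seq_sep
  i <- pr[keep, 1]
  j <- pr[keep, 2]
  tibble::tibble(
    res_a = s$resno[i], res_b = s$resno[j],
    type_a = s$residue_type[i], type_b = s$residue_type[j],
    distance = sqrt((s$x[i] - s$x[j])^2 + (s$y[i] - s$y[j])^2 +
                      (s$z[i] - s$z[j])^2)
  )
}

#' Cross-link detection across two states of a toy protein
#'
#' Samples link identities once from the union of candidate pairs, then
#' derives each link's presence per state from the geometry (present where
#' its distance is within the detection cutoff), so the planted two-state
#' category of every link is exact: links within reach in both states are
#' shared, links within reach in one state are unique to it. Noise links
#' (beyond the cutoff in both states) are included at `noise_rate` and are
#' assigned a random single state, mimicking spurious detections.
#'
#' @param toy An `xl_toy_protein` with states `state1` and `state2`.
#' @param state1,state2 State names (default the first two).
#' @inheritParams simulate_crosslinks
#' @return A link tibble with `res_a`, `res_b`, `type_a`, `type_b`,
#'   `dist_1`, `dist_2`, `present_1`, `present_2`, `truth`, `link_id`.
#' @export
simulate_two_state_links <- function(toy, state1 = NULL, state2 = NULL,
                                     linker = default_bs3_linker(),
                                     detection_cutoff = 27.4, n_links = 40,
                                     noise_rate = 0.05, min_seq_sep = 5,
                                     seed = 1) {
  states <- unique(toy$coords$state)
  state1 <- state1 %||% states[1]
  state2 <- state2 %||% states[2]
  s1 <- toy_state_structure(toy, state1)
  s2 <- toy_state_structure(toy, state2)
  c1 <- crosslink_candidates(s1, linker, min_seq_sep)
  c2 <- crosslink_candidates(s2, linker, min_seq_sep)
  stopifnot(identical(c1[, 1:4], c2[, 1:4]))
  cand <- c1
  cand$dist_1 <- c1$distance
  cand$dist_2 <- c2$distance
  cand$distance <- NULL
  cand$present_1 <- cand$dist_1 <= detection_cutoff
  cand$present_2 <- cand$dist_2 <= detection_cutoff
  detectable <- cand[cand$present_1 | cand$present_2, ]
  noise_pool <- cand[!(cand$present_1 | cand$present_2), ]
  with_seed(seed, {
    is_noise <- stats::runif(n_links) < noise_rate
    n_noise <- sum(is_noise)
    n_true <- n_links - n_noise
    stopifnot(n_true <= nrow(detectable), n_noise <= nrow(noise_pool))
    true_part <- detectable[sample.int(nrow(detectable), n_true), ]
    true_part$truth <- "true"
    noise_part <- noise_pool[sample.int(nrow(noise_pool), n_noise), ]
    noise_part$truth <- "noise"
    if (n_noise > 0) {
      which_state <- stats::runif(n_noise) < 0.5
      noise_part$present_1 <- which_state
      noise_part$present_2 <- !which_state
    }
    normalize_links(dplyr::bind_rows(true_part, noise_part))
  })
}

#' Simulate a heavy/light quantitation table with label swap
#'
#' Emits per-peptide peak areas for a two-condition comparison with the
#' full experimental design: `n_experiments` experiments, each with a pair
#' of label-swapped samples; links present in both conditions give doublet
#' signals whose log2 ratio is the planted effect plus peptide-level noise
#' plus a per-sample mixing bias (removed later by median normalization);
#' links present in one condition give singlet signals with the correct
#' label orientation in every sample. Each residue pair is supported by
#' 1-3 peptide pairs.
#'
#' @param links Link tibble with `link_id`, `present_1`, `present_2`
#'   (e.g. from [simulate_two_state_links()]).
#' @param conditions Two condition names, `c(condition1, condition2)`.
#' @param effects Named numeric of planted log2(condition1/condition2)
#'   effects per `link_id` (default 0 for every shared link). Links with
#'   `|effect| >= 1` are planted as enriched.
#' @param n_experiments Number of label-swap experiment pairs (default 2).
#' @param peptides_range Integer vector to draw the per-link number of
#'   supporting peptide pairs from (default `1:3`).
#' @param noise_sd Peptide-level s.d. of the log2 ratio (default 0.05).
#' @param mixing_bias Named numeric per sample id, or a single number used
#'   to generate per-sample biases uniformly in `[-b, b]`; default 0.3.
#' @param base_area Median peak area scale (default 1e6).
#' @param area_sd Log-normal s.d. of peak areas (default 0.5).
#' @param seed Integer seed.
#' @return List with `quant` (the peptide-level table), `design` (sample,
#'   experiment, heavy condition), and `truth` (per-link planted category
#'   and effect).
#' @export
simulate_quant <- function(links, conditions = c("A", "B"), effects = NULL,
                           n_experiments = 2, peptides_range = 1:3,
                           noise_sd = 0.05, mixing_bias = 0.3,
                           base_area = 1e6, area_sd = 0.5, seed = 1) {
  links <- tibble::as_tibble(links)
  stopifnot(all(c("link_id", "present_1", "present_2") %in% names(links)))
  exps <- as.character(utils::as.roman(seq_len(n_experiments)))
  design <- tibble::tibble(
    sample_id = paste0(rep(exps, each = 2), "-", 1:2),
    experiment_id = rep(exps, each = 2),
    heavy_condition = rep(c(conditions[2], conditions[1]), n_experiments)
  )
  eff <- stats::setNames(rep(0, nrow(links)), links$link_id)
  if (!is.null(effects)) eff[names(effects)] <- effects
  with_seed(seed, {
    if (length(mixing_bias) == 1 && is.null(names(mixing_bias))) {
      mixing_bias <- stats::setNames(
        stats::runif(nrow(design), -abs(mixing_bias), abs(mixing_bias)),
        design$sample_id
      )
    }
    n_pep <- sample(peptides_range, nrow(links), replace = TRUE)
    rows <- vector("list", nrow(links) * nrow(design))
    r <- 0
    for (li in seq_len(nrow(links))) {
      lk <- links[li, ]
      if (!lk$present_1 && !lk$present_2) next
      for (si in seq_len(nrow(design))) {
        smp <- design[si, ]
        pep_ids <- paste0(lk$link_id, "_p", seq_len(n_pep[li]))
        a2 <- base_area * exp(stats::rnorm(n_pep[li], 0, area_sd))
        if (lk$present_1 && lk$present_2) {
          ratio <- eff[[lk$link_id]] +
            stats::rnorm(n_pep[li], 0, noise_sd) +
            mixing_bias[[smp$sample_id]]
          a1 <- a2 * 2^ratio
        } else if (lk$present_1) {
          a1 <- a2
          a2 <- rep(0, n_pep[li])
        } else {
          a1 <- rep(0, n_pep[li])
        }
        light <- ifelse(rep(smp$heavy_condition == conditions[1],
                            n_pep[li]), a2, a1)
        heavy <- ifelse(rep(smp$heavy_condition == conditions[1],
                            n_pep[li]), a1, a2)
        r <- r + 1
        rows[[r]] <- tibble::tibble(
          sample_id = smp$sample_id, peptide_pair_id = pep_ids,
          res_a = lk$res_a, res_b = lk$res_b,
          type_a = if ("type_a" %in% names(lk)) lk$type_a else NA_character_,
          type_b = if ("type_b" %in% names(lk)) lk$type_b else NA_character_,
          area_light = light, area_heavy = heavy
        )
      }
    }
    quant <- dplyr::bind_rows(rows[seq_len(r)])
    truth <- tibble::tibble(
      link_id = links$link_id, res_a = links$res_a, res_b = links$res_b,
      present_1 = links$present_1, present_2 = links$present_2,
      effect = unname(eff[links$link_id]),
      category = dplyr::case_when(
        links$present_1 & !links$present_2 ~ "unique_1",
        !links$present_1 & links$present_2 ~ "unique_2",
        abs(eff[links$link_id]) >= 1 & eff[links$link_id] > 0 ~ "enriched_1",
        abs(eff[links$link_id]) >= 1 ~ "enriched_2",
        TRUE ~ "mutual"
      )
    )
    list(quant = quant, design = design, truth = truth,
         conditions = conditions, mixing_bias = mixing_bias)
  })
}

#' The two-state synthetic preset
#'
#' The package's standard end-to-end exercise: a three-domain toy protein
#' in two states (the third domain relocates), simulated cross-link
#' detection in both states (40 links, 5% noise), planted enrichment
#' effects on a few shared links, and a simulated label-swap quantitation
#' table. Planted null effects for shared links are evenly spaced in
#' [-0.8, 0.8] so the null spread is realistic but contains no accidental
#' outliers, and enrichment effects are +/-3 log2 units.
#'
#' @param seed Integer seed.
#' @param n_links Number of simulated links (default 40).
#' @return List with `toy`, `links`, `sim` (quant + design + truth) and
#'   `conditions`.
#' @export
simulate_two_state_preset <- function(seed = 1, n_links = 40) {
  toy <- make_toy_protein(n_domains = 3, residues_per_domain = 12,
                          linker_length = 6, seed = seed)
  links <- simulate_two_state_links(toy, n_links = n_links,
                                    detection_cutoff = 13,
                                    noise_rate = 0.05, seed = seed + 1)
  shared <- links$link_id[links$present_1 & links$present_2]
  effects <- numeric(0)
  if (length(shared) >= 8) {
    with_seed(seed + 2, {
      enr <- sample(shared, 4)
      effects <- stats::setNames(c(3, 3, -3, -3), enr)
      nulls <- setdiff(shared, enr)
      null_eff <- seq(-0.8, 0.8, length.out = length(nulls))
      effects <- c(effects,
                   stats::setNames(sample(null_eff), nulls))
    })
  }
  sim <- simulate_quant(links, conditions = c("stateA", "stateB"),
                        effects = effects, seed = seed + 3)
  list(toy = toy, links = links, sim = sim,
       conditions = c("stateA", "stateB"))
}
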
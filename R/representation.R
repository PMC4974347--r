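#' Coarse-grained bead representation with rigid bodies and flexible strings
#'
#' Builds the modeling representation from a structure: every residue in the
#' modeled range becomes one bead. Residues belonging to a configured rigid
#' body take their C-alpha coordinates from the structure and move as a
#' unit; all remaining residues (linkers and segments without structure)
#' become per-residue beads of a flexible string, initialized by linear
#' interpolation between the flanking structured residues. One rigid body is
#' designated the core: it is held fixed during sampling and used as the
#' superposition target in all ensemble analyses.
#'
#' @param structure An `xl_structure` providing C-alpha coordinates.
#' @param bodies Named list of rigid-body definitions; each element is an
#'   integer matrix/list of segments `c(start, end)` (mature numbering), or
#'   a plain integer vector of residue numbers. Every listed residue must be
#'   resolved in `structure`.
#' @param core Name of the core body (default: the first).
#' @param chains Optional data frame (`first_residue`, `last_residue`)
#'   defining the full modeled residue range; defaults to the contiguous
#'   range(s) spanned by `structure`.
#' @param radius_rigid,radius_flexible Bead radii in Angstrom (defaults 2.4
#'   and 3.0).
#' @param connectivity_rest Rest length in Angstrom per unit of sequence
#'   separation for the upper-bounded connectivity restraint (default 4.0).
#'
#' @return An `xl_representation`: list with `beads` (tibble: `bead`,
#'   `resno`, `domain`, `body`, `type`, `radius`), `coords` (N x 3 matrix),
#'   `bodies` (list of bead-index vectors), `core_body`, `movable_bodies`,
#'   `flexible_beads`, and precomputed restraint pair indices.
#' @export
build_representation <- function(structure, bodies, core = names(bodies)[1],
                                 chains = NULL,
                                 radius_rigid = 2.4, radius_flexible = 3.0,
                                 connectivity_rest = 4.0) {
  stopifnot(length(bodies) >= 1, !is.null(names(bodies)),
            core %in% names(bodies))
  body_residues <- lapply(bodies, function(b) {
    if (is.list(b)) {
      sort(unique(unlist(lapply(b, function(seg) seq(seg[1], seg[2])))))
    } else if (is.matrix(b)) {
      sort(unique(unlist(apply(b, 1, function(seg) seq(seg[1], seg[2])))))
    } else {
      sort(unique(as.integer(b)))
    }
  })
  all_body <- unlist(body_residues)
  if (anyDuplicated(all_body)) {
    stop("Rigid bodies overlap at residue ",
         all_body[duplicated(all_body)][1], ".", call. = FALSE)
  }
  missing <- setdiff(all_body, structure$resno)
  if (length(missing) > 0) {
    stop("Rigid-body residue(s) not resolved in the structure: ",
         paste(utils::head(missing, 10), collapse = ", "), call. = FALSE)
  }
  if (is.null(chains)) {
    chains <- residue_runs(sort(unique(c(structure$resno, all_body))))
  }
  chains <- tibble::as_tibble(chains)
  resno <- unlist(Map(seq, chains$first_residue, chains$last_residue))
  chain_id <- rep(seq_len(nrow(chains)),
                  chains$last_residue - chains$first_residue + 1)

  n <- length(resno)
  body_of <- rep(NA_integer_, n)
  for (k in seq_along(body_residues)) {
    body_of[resno %in% body_residues[[k]]] <- k
  }
  type <- ifelse(is.na(body_of), "flexible", "rigid")

  # coordinates: structure where available, interpolation elsewhere
  coords <- matrix(NA_real_, n, 3)
  hit <- match(resno, structure$resno)
  have <- !is.na(hit) & !is.na(body_of)  # rigid beads from structure
  coords[have, ] <- as.matrix(structure[hit[have], c("x", "y", "z")])
  # flexible beads: take structure coords if resolved, else interpolate
  flex_have <- !is.na(hit) & is.na(body_of)
  coords[flex_have, ] <- as.matrix(structure[hit[flex_have], c("x", "y", "z")])
  coords <- fill_gaps_linear(coords, chain_id)

  beads <- tibble::tibble(
    bead = seq_len(n), resno = as.integer(resno), chain = chain_id,
    domain = ifelse(is.na(body_of), "flexible", names(bodies)[body_of]),
    body = body_of, type = type,
    radius = ifelse(type == "rigid", radius_rigid, radius_flexible)
  )

  body_idx <- lapply(seq_along(bodies), function(k) which(body_of == k))
  names(body_idx) <- names(bodies)
  core_id <- match(core, names(bodies))

  # connectivity: consecutive beads within a chain
  conn_i <- which(diff(chain_id) == 0)
  conn_j <- conn_i + 1
  conn_rest <- connectivity_rest * (resno[conn_j] - resno[conn_i])

  # excluded volume: pairs in different units (unit = body, or the bead
  # itself when flexible), with the usual 1-2/1-3 bonded exemption
  unit <- ifelse(is.na(body_of), -seq_len(n), body_of)
  pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- unit[pr[, 1]] != unit[pr[, 2]] &
    !(chain_id[pr[, 1]] == chain_id[pr[, 2]] &
        abs(resno[pr[, 1]] - resno[pr[, 2]]) <= 2)
  ev_i <- pr[keep, 1]
  ev_j <- pr[keep, 2]
  ev_rsum <- beads$radius[ev_i] + beads$radius[ev_j]

  rep_obj <- list(
    beads = beads, coords = coords, bodies = body_idx, core_body = core_id,
    movable_bodies = setdiff(seq_along(body_idx), core_id),
    flexible_beads = which(is.na(body_of)),
    conn = list(i = conn_i, j = conn_j, rest = conn_rest),
    ev = list(i = ev_i, j = ev_j, rsum = ev_rsum)
  )
  class(rep_obj) <- "xl_representation"
  rep_obj
}

#' @export
print.xl_representation <- function(x, ...) {
  cat("<xl_representation> ", nrow(x$beads), " beads, ",
      length(x$bodies), " rigid bodies (core: ",
      names(x$bodies)[x$core_body], "), ",
      length(x$flexible_beads), " flexible beads\n", sep = "")
  invisible(x)
}

# contiguous runs of residue numbers -> chains table
residue_runs <- function(resno) {
  breaks <- c(0, which(diff(resno) > 1), length(resno))
  tibble::tibble(
    first_residue = resno[breaks[-length(breaks)] + 1],
    last_residue = resno[breaks[-1]]
  )
}

# linear interpolation of NA coordinate stretches within each chain;
# stretches at chain ends are extended from the nearest known bead with a
# small deterministic stagger so beads do not coincide
fill_gaps_linear <- function(coords, chain_id) {
  for (ch in unique(chain_id)) {
    rows <- which(chain_id == ch)
    for (dim in 1:3) {
      v <- coords[rows, dim]
      known <- which(!is.na(v))
      if (length(known) == 0) {
        v <- seq_along(v) * 3.8 * (dim == 1)
      } else if (length(known) < length(v)) {
        v <- stats::approx(known, v[known], xout = seq_along(v),
                           rule = 2)$y
        # stagger extrapolated ends so consecutive beads differ
        before <- seq_len(min(known) - 1)
        if (length(before) > 0 && dim == 1) {
          v[before] <- v[before] - 3.8 * rev(seq_along(before))
        }
        after <- seq(max(known) + 1, length.out = length(v) - max(known))
        if (length(after) > 0 && dim == 1) {
          v[after] <- v[after] + 3.8 * seq_along(after)
        }
      }
      coords[rows, dim] <- v
    }
  }
  coords
}

#' Restraint set for integrative modeling
#'
#' @param crosslinks Link data frame with `res_a`, `res_b` and a `class`
#'   column (`"consistent"` for links identified in all experiments,
#'   `"single"` for links identified once); a missing class column defaults
#'   to `"consistent"`.
#' @param disulfides Data frame of disulfide residue pairs (`res_a`,
#'   `res_b`), e.g. the C3 851-1491 bond; default none.
#' @param satisfaction_threshold C-alpha distance (Angstrom) below which a
#'   cross-link counts as satisfied in a model (default 35).
#' @return An `xl_restraints` list.
#' @export
restraint_set <- function(crosslinks,
                          disulfides = NULL,
                          satisfaction_threshold = 35) {
  stopifnot(satisfaction_threshold > 0)
  crosslinks <- normalize_links(crosslinks)
  if (!"class" %in% names(crosslinks)) crosslinks$class <- "consistent"
  if (!all(crosslinks$class %in% c("consistent", "single"))) {
    stop("Cross-link class must be 'consistent' or 'single'.", call. = FALSE)
  }
  if (!is.null(disulfides)) disulfides <- normalize_links(disulfides)
  structure(
    list(crosslinks = crosslinks, disulfides = disulfides,
         satisfaction_threshold = satisfaction_threshold),
    class = "xl_restraints"
  )
}

#' Scoring parameters for the Bayesian score
#'
#' @param d0 Forward-model inflection distance in Angstrom: the bead-bead
#'   distance at which the probability of observing a cross-link is 1/2
#'   (default 35, matching the satisfaction criterion).
#' @param lambda Forward-model steepness in Angstrom (default 2).
#' @param k_ev Excluded-volume strength per Angstrom^2 (default 1).
#' @param k_conn Connectivity strength per Angstrom^2 (default 1).
#' @param disulfide_rest Disulfide harmonic rest length in Angstrom
#'   (default 6).
#' @param k_ss Disulfide strength per Angstrom^2 (default 10).
#' @param psi_min,psi_max Bounds of the uniform prior on the cross-link
#'   uncertainties (default 0.01 and 0.49: noise fraction below coin-flip).
#' @return An `xl_scoring_params` list.
#' @export
scoring_params <- function(d0 = 35, lambda = 2, k_ev = 1, k_conn = 1,
                           disulfide_rest = 6, k_ss = 10,
                           psi_min = 0.01, psi_max = 0.49) {
  stopifnot(lambda > 0, d0 > 0, psi_min > 0, psi_max < 0.5,
            psi_min < psi_max)
  structure(list(d0 = d0, lambda = lambda, k_ev = k_ev, k_conn = k_conn,
                 disulfide_rest = disulfide_rest, k_ss = k_ss,
                 psi_min = psi_min, psi_max = psi_max),
            class = "xl_scoring_params")
}

#' Bind representation, restraints and parameters into a scoring system
#'
#' Precomputes bead indices for every restraint so the score can be
#' evaluated repeatedly during sampling. Restrained residues must map to
#' beads of the representation.
#'
#' @param rep An `xl_representation`.
#' @param restraints An `xl_restraints`.
#' @param params An `xl_scoring_params`.
#' @return An `xl_system` list.
#' @export
bind_system <- function(rep, restraints, params = scoring_params()) {
  stopifnot(inherits(rep, "xl_representation"),
            inherits(restraints, "xl_restraints"))
  bead_of <- function(pos, what) {
    i <- match(pos, rep$beads$resno)
    if (any(is.na(i))) {
      stop(what, " residue(s) not mapped to any bead: ",
           paste(pos[is.na(i)], collapse = ", "), call. = FALSE)
    }
    i
  }
  xl <- restraints$crosslinks
  ss <- restraints$disulfides
  sys <- list(
    rep = rep, restraints = restraints, params = params,
    xl_i = bead_of(xl$res_a, "Cross-linked"),
    xl_j = bead_of(xl$res_b, "Cross-linked"),
    xl_class = match(xl$class, c("consistent", "single")),
    ss_i = if (!is.null(ss)) bead_of(ss$res_a, "Disulfide") else integer(0),
    ss_j = if (!is.null(ss)) bead_of(ss$res_b, "Disulfide") else integer(0)
  )
  class(sys) <- "xl_system"
  sys
}
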
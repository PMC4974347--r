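#' Sampler configuration
#'
#' Replica-exchange Metropolis Monte Carlo settings. The published protocol
#' used 32 replicas at temperatures 1.0-2.5 and 200,000 recorded models over
#' two independent runs; the default here is the desk-scale profile (8
#' replicas, 20,000 models, one run) for a single CPU.
#'
#' @param n_replicas Number of replicas (>= 1; default 8).
#' @param temp_min,temp_max Dimensionless temperature range (default 1.0 and
#'   2.5); the ladder is geometric. The temperature multiplies the score
#'   scale in the acceptance ratio.
#' @param max_rigid_trans Maximum rigid-body translation per move, Angstrom
#'   (default 4).
#' @param max_rigid_rot Maximum rigid-body rotation per move, radians about
#'   the body centroid (default 0.03).
#' @param max_bead_trans Maximum flexible-bead translation per move,
#'   Angstrom (default 5).
#' @param psi_step Standard deviation of the Gaussian psi perturbation
#'   (default 0.01), reflected into the psi bounds.
#' @param n_models Number of recorded models (one per sweep from the
#'   cold replica; default 20000).
#' @param n_runs Independent sampling runs (default 1).
#' @param swap_every Attempt neighbor swaps every this many sweeps
#'   (default 10).
#' @param n_best Number of best-scoring models treated as solutions
#'   (default 200).
#' @param init_radius Radius in Angstrom of the bounding sphere (around the
#'   core centroid) for random initial placement of movable bodies
#'   (default 150).
#' @param seed Integer seed; every stochastic operation is seeded.
#' @return An `xl_sampler_config` list.
#' @export
sampler_config <- function(n_replicas = 8, temp_min = 1.0, temp_max = 2.5,
                           max_rigid_trans = 4, max_rigid_rot = 0.03,
                           max_bead_trans = 5, psi_step = 0.01,
                           n_models = 20000, n_runs = 1, swap_every = 10,
                           n_best = 200, init_radius = 150, seed = 1) {
  stopifnot(n_replicas >= 1, temp_min > 0, temp_max >= temp_min,
            max_rigid_trans > 0, max_rigid_rot > 0, max_bead_trans > 0,
            psi_step > 0, n_models >= 1, n_runs >= 1)
  structure(list(
    n_replicas = n_replicas, temp_min = temp_min, temp_max = temp_max,
    max_rigid_trans = max_rigid_trans, max_rigid_rot = max_rigid_rot,
    max_bead_trans = max_bead_trans, psi_step = psi_step,
    n_models = n_models, n_runs = n_runs, swap_every = swap_every,
    n_best = n_best, init_radius = init_radius, seed = seed
  ), class = "xl_sampler_config")
}

#' Geometric temperature ladder
#'
#' @param config An [sampler_config()].
#' @return Numeric vector of `n_replicas` temperatures, geometrically spaced
#'   from `temp_min` to `temp_max`.
#' @export
temperature_ladder <- function(config) {
  if (config$n_replicas == 1) return(config$temp_min)
  exp(seq(log(config$temp_min), log(config$temp_max),
          length.out = config$n_replicas))
}

#' Metropolis acceptance rule
#'
#' Accepts a proposal with probability `min(1, exp(-delta / temperature))`.
#'
#' @param delta Score difference (proposed minus current; lower scores are
#'   better).
#' @param temperature Dimensionless temperature (> 0).
#' @param u Uniform(0,1) draw (defaults to `runif(1)`; pass explicitly for
#'   deterministic use).
#' @return Logical: accept?
#' @export
metropolis_accept <- function(delta, temperature = 1,
                              u = stats::runif(1)) {
  delta <= 0 || u < exp(-delta / temperature)
}

#' One Metropolis Monte Carlo step
#'
#' Chooses one move uniformly among the four move types: rigid-body
#' translation (uniform in a ball of radius `max_rigid_trans`), rigid-body
#' rotation (random axis, angle uniform up to `max_rigid_rot`, about the
#' body centroid), flexible-bead translation (uniform ball of radius
#' `max_bead_trans`), and a Gaussian perturbation of one psi parameter
#' (reflected into `[psi_min, psi_max]`). The core body is never moved.
#' The proposal is accepted by the Metropolis rule at the given
#' temperature. Uses the R random number generator: a fixed seed gives a
#' bit-identical trajectory.
#'
#' @param state List with elements `coords` (N x 3), `psi`
#'   (`c(consistent, single)`) and `score`.
#' @param system An [bind_system()] result.
#' @param config An [sampler_config()].
#' @param temperature Temperature for the acceptance rule.
#' @return The (possibly updated) state, with logical element `accepted`
#'   and `move_type`.
#' @export
mc_step <- function(state, system, config, temperature = 1) {
  rep <- system$rep
  par <- system$params
  move_types <- c("rigid_translate", "rigid_rotate", "bead_translate",
                  "psi")
  # degenerate representations: drop unavailable move types
  if (length(rep$movable_bodies) == 0) {
    move_types <- setdiff(move_types, c("rigid_translate", "rigid_rotate"))
  }
  if (length(rep$flexible_beads) == 0) {
    move_types <- setdiff(move_types, "bead_translate")
  }
  mt <- move_types[sample.int(length(move_types), 1)]
  coords <- state$coords
  psi <- state$psi
  if (mt == "rigid_translate") {
    b <- rep$movable_bodies[sample.int(length(rep$movable_bodies), 1)]
    idx <- rep$bodies[[b]]
    shift <- runif_ball(config$max_rigid_trans)
    coords[idx, ] <- sweep(coords[idx, , drop = FALSE], 2, shift, "+")
  } else if (mt == "rigid_rotate") {
    b <- rep$movable_bodies[sample.int(length(rep$movable_bodies), 1)]
    idx <- rep$bodies[[b]]
    axis <- random_unit_vector()
    angle <- stats::runif(1, -config$max_rigid_rot, config$max_rigid_rot)
    ctr <- colMeans(coords[idx, , drop = FALSE])
    rot <- rotation_matrix(axis, angle)
    coords[idx, ] <- sweep(
      sweep(coords[idx, , drop = FALSE], 2, ctr, "-") %*% t(rot),
      2, ctr, "+"
    )
  } else if (mt == "bead_translate") {
    i <- rep$flexible_beads[sample.int(length(rep$flexible_beads), 1)]
    coords[i, ] <- coords[i, ] + runif_ball(config$max_bead_trans)
  } else {
    k <- sample.int(length(psi), 1)
    psi[k] <- reflect_into(psi[k] + stats::rnorm(1, 0, config$psi_step),
                           par$psi_min, par$psi_max)
  }
  new_score <- total_score(coords, psi, system)
  if (metropolis_accept(new_score - state$score, temperature)) {
    state$coords <- coords
    state$psi <- psi
    state$score <- new_score
    state$accepted <- TRUE
  } else {
    state$accepted <- FALSE
  }
  state$move_type <- mt
  state
}

#' Replica-exchange sampling of the posterior
#'
#' Runs replica-exchange Metropolis Monte Carlo on the bound system: each
#' sweep performs one MC move in every replica, neighbor swaps are attempted
#' every `swap_every` sweeps with acceptance
#' `min(1, exp((1/T_i - 1/T_j) (S_i - S_j)))`, and the configuration of the
#' coldest replica is recorded as one model per sweep. With a single replica
#' this reduces to plain Metropolis sampling. Independent runs (fresh random
#' initial configurations) are concatenated and tagged.
#'
#' Initialization places each movable rigid body at a uniformly random
#' rotation and a random position inside a sphere of radius `init_radius`
#' around the (fixed) core centroid; flexible beads start from the
#' representation coordinates with a small jitter.
#'
#' @param rep An `xl_representation`.
#' @param restraints An `xl_restraints`.
#' @param params An [scoring_params()].
#' @param config An [sampler_config()].
#' @return An `xl_ensemble`: list with `coords` (array
#'   `n_models_total x N x 3`), `scores`, `psis` (matrix), `run` (run id per
#'   model), plus the `system` and `config`.
#' @export
replica_exchange_sample <- function(rep, restraints,
                                    params = scoring_params(),
                                    config = sampler_config()) {
  system <- bind_system(rep, restraints, params)
  temps <- temperature_ladder(config)
  n_rep <- length(temps)
  n <- nrow(rep$coords)
  n_tot <- config$n_models * config$n_runs
  coords_out <- array(NA_real_, c(n_tot, n, 3))
  scores_out <- numeric(n_tot)
  psi_out <- matrix(NA_real_, n_tot, 2,
                    dimnames = list(NULL, c("consistent", "single")))
  run_out <- integer(n_tot)
  swap_attempt <- 0L
  swap_accept <- 0L
  accept_moves <- 0L

  old_rng <- rng_state_get()
  on.exit(rng_state_set(old_rng))
  set.seed(config$seed)
  {
    out_row <- 0L
    for (run in seq_len(config$n_runs)) {
      states <- lapply(seq_len(n_rep), function(r) {
        coords <- random_initial_coords(rep, config)
        psi <- c(consistent = 0.05, single = 0.05)
        list(coords = coords, psi = psi,
             score = total_score(coords, psi, system))
      })
      for (sweep in seq_len(config$n_models)) {
        for (r in seq_len(n_rep)) {
          states[[r]] <- mc_step(states[[r]], system, config, temps[r])
          accept_moves <- accept_moves + states[[r]]$accepted
        }
        if (n_rep > 1 && sweep %% config$swap_every == 0) {
          # alternate even/odd neighbor pairs
          start <- if ((sweep %/% config$swap_every) %% 2 == 0) 1L else 2L
          for (r in if (start <= n_rep - 1) {
            seq(start, n_rep - 1, by = 2)
          } else {
            integer(0)
          }) {
            swap_attempt <- swap_attempt + 1L
            d_beta <- 1 / temps[r] - 1 / temps[r + 1]
            d_s <- states[[r]]$score - states[[r + 1]]$score
            if (stats::runif(1) < min(1, exp(d_beta * d_s))) {
              tmp <- states[[r]]
              states[[r]] <- states[[r + 1]]
              states[[r + 1]] <- tmp
              swap_accept <- swap_accept + 1L
            }
          }
        }
        out_row <- out_row + 1L
        coords_out[out_row, , ] <- states[[1]]$coords
        scores_out[out_row] <- states[[1]]$score
        psi_out[out_row, ] <- states[[1]]$psi
        run_out[out_row] <- run
      }
    }
  }

  structure(list(
    coords = coords_out, scores = scores_out, psis = psi_out,
    run = run_out, system = system, config = config,
    acceptance_rate = accept_moves / (n_tot * n_rep),
    swap_rate = if (swap_attempt > 0) swap_accept / swap_attempt else NA
  ), class = "xl_ensemble")
}

#' @export
print.xl_ensemble <- function(x, ...) {
  cat("<xl_ensemble> ", length(x$scores), " models, ",
      dim(x$coords)[2], " beads; score range [",
      round(min(x$scores), 2), ", ", round(max(x$scores), 2),
      "]; move acceptance ", round(100 * x$acceptance_rate, 1), "%\n",
      sep = "")
  invisible(x)
}

random_initial_coords <- function(rep, config) {
  coords <- rep$coords
  core_ctr <- colMeans(coords[rep$bodies[[rep$core_body]], , drop = FALSE])
  for (b in rep$movable_bodies) {
    idx <- rep$bodies[[b]]
    ctr <- colMeans(coords[idx, , drop = FALSE])
    rot <- rotation_matrix(random_unit_vector(),
                           stats::runif(1, 0, 2 * pi))
    target <- core_ctr + runif_ball(config$init_radius)
    coords[idx, ] <- sweep(
      sweep(coords[idx, , drop = FALSE], 2, ctr, "-") %*% t(rot),
      2, target, "+"
    )
  }
  flex <- rep$flexible_beads
  if (length(flex) > 0) {
    coords[flex, ] <- coords[flex, ] +
      matrix(stats::rnorm(3 * length(flex), 0, 1), ncol = 3)
  }
  coords
}

# uniform draw in a ball of given radius
runif_ball <- function(radius) {
  repeat {
    v <- stats::runif(3, -1, 1)
    if (sum(v^2) <= 1) return(v * radius)
  }
}

random_unit_vector <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-12) return(v / n)
  }
}

# Rodrigues rotation matrix about a unit axis
rotation_matrix <- function(axis, angle) {
  c_ <- cos(angle)
  s_ <- sin(angle)
  x <- axis[1]; y <- axis[2]; z <- axis[3]
  matrix(c(
    c_ + x^2 * (1 - c_), x * y * (1 - c_) - z * s_,
    x * z * (1 - c_) + y * s_,
    y * x * (1 - c_) + z * s_, c_ + y^2 * (1 - c_),
    y * z * (1 - c_) - x * s_,
    z * x * (1 - c_) - y * s_, z * y * (1 - c_) + x * s_,
    c_ + z^2 * (1 - c_)
  ), 3, 3, byrow = TRUE)
}

reflect_into <- function(x, lo, hi) {
  width <- hi - lo
  # reflect repeatedly into [lo, hi]
  y <- (x - lo) %% (2 * width)
  y <- ifelse(y > width, 2 * width - y, y)
  lo + y
}

rng_state_get <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

rng_state_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# evaluate expr with a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- rng_state_get()
  on.exit(rng_state_set(old))
  set.seed(seed)
  expr
}
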
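test_that("representations partition residues into rigid bodies and
           flexible strings", {
  fix <- toy_two_body_rep()
  rep <- fix$rep
  expect_equal(nrow(rep$beads), 20)  # 2 x 8 rigid + 4 linker
  expect_equal(length(rep$bodies), 2)
  expect_equal(length(rep$flexible_beads), 4)
  # every residue in exactly one bead; bodies and strings partition them
  expect_equal(sort(unname(c(unlist(rep$bodies), rep$flexible_beads))),
               seq_len(nrow(rep$beads)))
  expect_equal(rep$beads$radius[rep$beads$type == "rigid"][1], 2.4)
  expect_equal(rep$beads$radius[rep$beads$type == "flexible"][1], 3.0)
  # a config covering every residue with structure has no flexible beads
  toy0 <- make_toy_protein(n_domains = 2, residues_per_domain = 6,
                           linker_length = 0, seed = 2)
  s0 <- toy_state_structure(toy0, "A")
  rep0 <- build_representation(
    s0, list(D1 = list(c(1, 6)), D2 = list(c(7, 12))), core = "D1")
  expect_equal(length(rep0$flexible_beads), 0)
  # unknown residues in a body definition are rejected
  expect_error(
    build_representation(fix$s, list(D1 = list(c(1, 999))), core = "D1"),
    "not resolved")
})

test_that("the forward model is a calibrated decreasing logistic", {
  par <- scoring_params(d0 = 35, lambda = 2)
  expect_equal(forward_model_probability(35, par), 0.5)
  expect_gt(forward_model_probability(0, par), 0.99)
  d <- seq(0, 100, by = 0.5)
  f <- forward_model_probability(d, par)
  expect_true(all(diff(f) < 0))
  expect_true(all(f > 0 & f < 1))
  expect_lt(forward_model_probability(1000, par), 1e-10)
})

test_that("the cross-link likelihood has its psi-free point at d0", {
  fix <- toy_two_body_rep()
  rep <- fix$rep
  par <- scoring_params(d0 = 20, lambda = 2)
  links <- data.frame(res_a = 1, res_b = rep$beads$resno[nrow(rep$beads)])
  sys <- bind_system(rep, restraint_set(links), par)
  coords <- rep$coords
  # place the two linked beads exactly d0 apart
  i <- sys$xl_i
  j <- sys$xl_j
  shift <- coords[j, ] - coords[i, ]
  coords[j, ] <- coords[i, ] + shift / sqrt(sum(shift^2)) * 20
  for (psi in c(0.01, 0.1, 0.3)) {
    expect_equal(crosslink_log_likelihood(coords, sys, c(psi, psi)),
                 log(0.5))
  }
  # all links at d -> 0 with psi -> 0: log likelihood -> 0
  coords[j, ] <- coords[i, ] + 1e-9
  expect_lt(abs(crosslink_log_likelihood(coords, sys, c(1e-12, 1e-12))),
            1e-4)
})

test_that("prior score is zero for relaxed configurations and quadratic in
           overlap", {
  # two single-bead bodies far apart, no flexible beads
  s <- as_structure(tibble::tibble(resno = c(1, 10), x = c(0, 50),
                                   y = 0, z = 0))
  rep <- build_representation(s, list(A = list(c(1, 1)),
                                      B = list(c(10, 10))), core = "A")
  sys <- bind_system(rep, restraint_set(data.frame(res_a = 1, res_b = 10)))
  expect_equal(prior_score(rep$coords, sys), 0)
  # fully overlapping beads: k * (r1 + r2)^2
  coords <- rep$coords
  coords[2, ] <- coords[1, ]
  expect_equal(prior_score(coords, sys), (2.4 + 2.4)^2)
  # disulfide at rest length contributes zero, displaced contributes
  # k_ss * (d - rest)^2
  sys2 <- bind_system(rep, restraint_set(
    data.frame(res_a = 1, res_b = 10),
    disulfides = data.frame(res_a = 1, res_b = 10)))
  coords2 <- rep$coords
  coords2[2, ] <- c(6, 0, 0)
  expect_equal(prior_score(coords2, sys2), 0)
  coords2[2, ] <- c(9, 0, 0)
  expect_equal(prior_score(coords2, sys2), 10 * 9)
})

test_that("total score equals a brute-force recomputation on random
           states", {
  fix <- toy_two_body_rep()
  rep <- fix$rep
  links <- data.frame(res_a = c(1, 3, 5), res_b = c(14, 16, 20),
                      class = c("consistent", "single", "consistent"))
  restraints <- restraint_set(links,
                              disulfides = data.frame(res_a = 2,
                                                      res_b = 15))
  par <- scoring_params(d0 = 18, lambda = 1.5)
  sys <- bind_system(rep, restraints, par)
  set.seed(31)
  for (i in 1:5) {
    coords <- rep$coords + matrix(rnorm(3 * nrow(rep$coords), sd = 3),
                                  ncol = 3)
    psi <- runif(2, 0.02, 0.4)
    expect_equal(total_score(coords, psi, sys),
                 brute_force_score(coords, rep, restraints, psi, par),
                 tolerance = 1e-10)
    # decomposition: total = -loglik + prior
    expect_equal(total_score(coords, psi, sys),
                 -crosslink_log_likelihood(coords, sys, psi) +
                   prior_score(coords, sys))
  }
})

test_that("shortening a violated link strictly improves the score", {
  s <- as_structure(tibble::tibble(resno = c(1, 10), x = c(0, 60),
                                   y = 0, z = 0))
  rep <- build_representation(s, list(A = list(c(1, 1)),
                                      B = list(c(10, 10))), core = "A")
  sys <- bind_system(rep, restraint_set(data.frame(res_a = 1, res_b = 10)),
                     scoring_params(d0 = 35, lambda = 2))
  psi <- c(0.05, 0.05)
  s_far <- total_score(rep$coords, psi, sys)
  coords <- rep$coords
  coords[2, 1] <- 25
  expect_lt(total_score(coords, psi, sys), s_far)
})

test_that("Metropolis accepts all downhill moves and obeys the Boltzmann
           ratio on a 2-state toy", {
  expect_true(metropolis_accept(-5, 1, u = 0.999999))
  expect_true(metropolis_accept(0, 1, u = 0.999999))
  # two-state chain with score gap dS: occupancy ratio converges to
  # exp(-dS/T) within Monte-Carlo error
  for (temp in c(1, 2)) {
    d_s <- 1.2
    set.seed(17)
    state <- 0L
    n <- 40000
    occ <- integer(n)
    for (i in seq_len(n)) {
      proposal <- 1L - state
      delta <- if (proposal == 1L) d_s else -d_s
      if (metropolis_accept(delta, temp)) state <- proposal
      occ[i] <- state
    }
    occ <- occ[-(1:1000)]
    expected <- exp(-d_s / temp) / (1 + exp(-d_s / temp))
    expect_equal(mean(occ), expected, tolerance = 0.05)
  }
})

test_that("mc_step respects move bounds, preserves rigid geometry, and is
           seed-deterministic", {
  fix <- toy_two_body_rep()
  rep <- fix$rep
  links <- data.frame(res_a = 1, res_b = 16)
  sys <- bind_system(rep, restraint_set(links), scoring_params())
  cfg <- sampler_config(max_rigid_trans = 4, max_rigid_rot = 0.03,
                        max_bead_trans = 5, seed = 1)
  state <- list(coords = rep$coords, psi = c(consistent = 0.05,
                                             single = 0.05),
                score = total_score(rep$coords, c(0.05, 0.05), sys))
  body2 <- rep$bodies[[2]]
  intra0 <- dist(rep$coords[body2, ])
  set.seed(99)
  max_bead_move <- 0
  for (i in 1:400) {
    old <- state
    state <- mc_step(state, sys, cfg, temperature = 5)
    moved <- sqrt(rowSums((state$coords - old$coords)^2))
    if (state$move_type == "rigid_translate" && state$accepted) {
      expect_lte(max(moved), 4 + 1e-9)
    }
    if (state$move_type == "bead_translate" && state$accepted) {
      max_bead_move <- max(max_bead_move, max(moved))
    }
    # psi stays inside its prior bounds
    expect_true(all(state$psi > 0.0099 & state$psi < 0.4901))
  }
  expect_lte(max_bead_move, 5 + 1e-9)
  # rigid-body moves preserve intra-body distances to 1e-9
  expect_equal(max(abs(dist(state$coords[body2, ]) - intra0)), 0,
               tolerance = 1e-9)
  # the core body never moves
  expect_identical(state$coords[rep$bodies[[1]], ],
                   rep$coords[rep$bodies[[1]], ])
  # fixed seed gives a bit-identical trajectory
  run <- function() {
    set.seed(7)
    s <- list(coords = rep$coords, psi = c(consistent = 0.05,
                                           single = 0.05),
              score = total_score(rep$coords, c(0.05, 0.05), sys))
    for (i in 1:50) s <- mc_step(s, sys, cfg, 1)
    s
  }
  expect_identical(run(), run())
})

test_that("replica exchange with identical temperatures accepts all swaps
           and a single replica reduces to plain Metropolis", {
  fix <- toy_two_body_rep()
  links <- data.frame(res_a = c(1, 5), res_b = c(14, 18))
  cfg_eq <- sampler_config(n_replicas = 4, temp_min = 1, temp_max = 1,
                           n_models = 300, swap_every = 5, n_best = 10,
                           init_radius = 30, seed = 2)
  ens <- replica_exchange_sample(fix$rep, restraint_set(links),
                                 scoring_params(d0 = 20), cfg_eq)
  expect_equal(ens$swap_rate, 1)
  cfg_one <- sampler_config(n_replicas = 1, temp_min = 1, temp_max = 1,
                            n_models = 300, n_best = 10, init_radius = 30,
                            seed = 2)
  ens1 <- replica_exchange_sample(fix$rep, restraint_set(links),
                                  scoring_params(d0 = 20), cfg_one)
  expect_true(is.na(ens1$swap_rate))
  expect_equal(length(ens1$scores), 300)
})

test_that("select_best returns the lowest scores with stable tie-break", {
  ens <- list(scores = c(5, 1, 3, 1, 2),
              coords = array(seq_len(5 * 2 * 3), c(5, 2, 3)),
              psis = matrix(0, 5, 2,
                            dimnames = list(NULL,
                                            c("consistent", "single"))),
              config = list(n_best = 3), system = NULL)
  class(ens) <- "xl_ensemble"
  sol <- select_best(ens, 3)
  expect_equal(sol$model_index, c(2, 4, 5))  # tie at 1 broken by index
  expect_equal(sol$scores, c(1, 1, 2))
  solall <- select_best(ens, 5)
  expect_equal(sort(solall$model_index), 1:5)
  sol1 <- select_best(ens, 1)
  expect_equal(sol1$model_index, 2)
})

test_that("superposition matches the quaternion oracle and undoes rigid
           motions", {
  set.seed(5)
  a <- matrix(rnorm(30 * 3, sd = 10), ncol = 3)
  # identity: rmsd 0
  s <- superpose_core(a, a)
  expect_equal(s$rmsd_core, 0, tolerance = 1e-9)
  # known rotation + translation: recovered exactly
  rot <- qclms:::rotation_matrix(c(0, 0, 1), 0.7)
  b <- a %*% t(rot) + matrix(c(5, -3, 2), nrow(a), 3, byrow = TRUE)
  s2 <- superpose_core(b, a)
  expect_equal(s2$rmsd_core, 0, tolerance = 1e-9)
  expect_equal(s2$coords, a, tolerance = 1e-9)
  # random pairs: RMSD equals the independent quaternion (Horn) oracle
  for (i in 1:6) {
    x <- matrix(rnorm(20 * 3, sd = 8), ncol = 3)
    y <- matrix(rnorm(20 * 3, sd = 8), ncol = 3)
    expect_equal(superpose_core(x, y)$rmsd_core, horn_superpose_rmsd(x, y),
                 tolerance = 1e-9)
  }
})

test_that("clustering separates planted configurations and handles
           degenerate cases", {
  fix <- toy_two_body_rep()
  rep <- fix$rep
  n_beads <- nrow(rep$beads)
  # two well-separated configurations, 10 noisy copies each
  base1 <- rep$coords
  base2 <- rep$coords
  base2[rep$bodies[[2]], 2] <- base2[rep$bodies[[2]], 2] + 40
  set.seed(3)
  coords <- array(NA_real_, c(20, n_beads, 3))
  for (i in 1:10) {
    coords[i, , ] <- base1 + rnorm(n_beads * 3, sd = 0.3)
  }
  for (i in 11:20) {
    coords[i, , ] <- base2 + rnorm(n_beads * 3, sd = 0.3)
  }
  sys <- bind_system(rep, restraint_set(data.frame(res_a = 1, res_b = 16)),
                     scoring_params())
  sol <- structure(list(coords = coords, scores = rep(1, 20),
                        psis = matrix(0.05, 20, 2),
                        model_index = 1:20, system = sys),
                   class = "xl_solutions")
  cl <- cluster_solutions(sol, k = 2, seed = 4)
  expect_equal(length(unique(cl$assignment[1:10])), 1)
  expect_equal(length(unique(cl$assignment[11:20])), 1)
  expect_false(cl$assignment[1] == cl$assignment[11])
  # k = 1: everything in one cluster
  cl1 <- cluster_solutions(sol, k = 1)
  expect_equal(unique(cl1$assignment), 1L)
  # duplicate solutions: zero within-cluster spread
  dup <- sol
  for (i in 1:20) dup$coords[i, , ] <- base1
  cld <- cluster_solutions(dup, k = 1)
  expect_equal(precision_accuracy(cld, 1)$precision, 0, tolerance = 1e-9)
})

test_that("precision and accuracy measure displacement exactly on
           constructed clusters", {
  fix <- toy_two_body_rep()
  rep <- fix$rep
  n_beads <- nrow(rep$beads)
  sys <- bind_system(rep, restraint_set(data.frame(res_a = 1, res_b = 16)),
                     scoring_params())
  # cluster: the reference and a copy whose second body is shifted by t
  t_shift <- 6
  shifted <- rep$coords
  shifted[rep$bodies[[2]], 1] <- shifted[rep$bodies[[2]], 1] + t_shift
  coords <- array(NA_real_, c(2, n_beads, 3))
  coords[1, , ] <- rep$coords
  coords[2, , ] <- shifted
  sol <- structure(list(coords = coords, scores = c(1, 2),
                        psis = matrix(0.05, 2, 2), model_index = 1:2,
                        system = sys),
                   class = "xl_solutions")
  cl <- cluster_solutions(sol, k = 1)
  pa <- precision_accuracy(cl, cluster = 1, reference = rep$coords)
  # center is one of the two members; the other differs on body-2 beads
  n2 <- length(rep$bodies[[2]])
  expected_rmsd <- sqrt(n2 * t_shift^2 / n_beads)
  expect_equal(pa$precision, expected_rmsd / 2, tolerance = 0.15)
  # per-domain breakdown: displacement lives in the moved body
  expect_lt(pa$per_domain$precision[pa$per_domain$domain == "D1"],
            pa$per_domain$precision[pa$per_domain$domain == "D2"])
})

test_that("localization densities are occupancy probabilities invariant to
           member order", {
  fix <- toy_two_body_rep()
  rep <- fix$rep
  n_beads <- nrow(rep$beads)
  sys <- bind_system(rep, restraint_set(data.frame(res_a = 1, res_b = 16)),
                     scoring_params())
  mk_sol <- function(order) {
    coords <- array(NA_real_, c(2, n_beads, 3))
    shifted <- rep$coords
    shifted[rep$bodies[[2]], 1] <- shifted[rep$bodies[[2]], 1] + 30
    pair <- list(rep$coords, shifted)[order]
    coords[1, , ] <- pair[[1]]
    coords[2, , ] <- pair[[2]]
    structure(list(coords = coords, scores = c(1, 1),
                   psis = matrix(0.05, 2, 2), model_index = 1:2,
                   system = sys), class = "xl_solutions")
  }
  cl_a <- cluster_solutions(mk_sol(1:2), k = 1)
  d_a <- localization_density(cl_a, "D2", cluster = 1, voxel = 4)
  expect_true(all(d_a$grid >= 0 & d_a$grid <= 1))
  # two disjoint half-clusters: occupancy at most 0.5 outside overlap
  expect_equal(max(d_a$grid), 0.5)
  # single-model cluster: binary grid
  one <- mk_sol(1:2)
  one$coords <- one$coords[1, , , drop = FALSE]
  one$scores <- 1
  one$psis <- one$psis[1, , drop = FALSE]
  one$model_index <- 1L
  cl_one <- cluster_solutions(one, k = 1)
  d_one <- localization_density(cl_one, "D2", cluster = 1, voxel = 4)
  expect_true(all(d_one$grid %in% c(0, 1)))
  # MRC output round-trips through a minimal header check
  tmp <- tempfile(fileext = ".mrc")
  write_density_mrc(d_one, tmp)
  con <- file(tmp, "rb")
  dims <- readBin(con, integer(), 3, size = 4, endian = "little")
  close(con)
  expect_equal(dims, dim(d_one$grid))
  expect_equal(file.size(tmp), 1024 + 4 * prod(dim(d_one$grid)))
})

test_that("satisfaction reports count links against the 35 A criterion", {
  fix <- toy_two_body_rep()
  rep <- fix$rep
  n_beads <- nrow(rep$beads)
  links <- data.frame(res_a = c(1, 2), res_b = c(16, 20))
  mk_cluster <- function(threshold) {
    sys <- bind_system(rep, restraint_set(links,
                                          satisfaction_threshold = threshold),
                       scoring_params())
    coords <- array(NA_real_, c(2, n_beads, 3))
    coords[1, , ] <- rep$coords
    coords[2, , ] <- rep$coords
    sol <- structure(list(coords = coords, scores = c(1, 2),
                          psis = matrix(0.05, 2, 2), model_index = 1:2,
                          system = sys), class = "xl_solutions")
    cluster_solutions(sol, k = 1)
  }
  rp <- satisfaction_report(mk_cluster(35))
  expect_equal(rp$fraction_satisfied, 1)
  expect_true(all(rp$links$satisfied == (rp$links$min_distance < 35)))
  expect_true(all(rp$contact >= 0 & rp$contact <= 1))
  # a zero threshold satisfies nothing at nonzero distances
  rp0 <- satisfaction_report(mk_cluster(1e-9))
  expect_equal(rp0$fraction_satisfied, 0)
})

test_that("tidiers expose models, clusters and comparisons as tibbles", {
  fix <- toy_two_body_rep()
  links <- data.frame(res_a = c(1, 5), res_b = c(14, 18))
  cfg <- sampler_config(n_replicas = 2, n_models = 200, n_best = 20,
                        init_radius = 30, seed = 6)
  ens <- replica_exchange_sample(fix$rep, restraint_set(links),
                                 scoring_params(d0 = 20), cfg)
  td <- tidy(ens)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 200)
  gl <- glance(ens)
  expect_equal(gl$n_models, 200)
  expect_true(gl$acceptance_rate > 0 && gl$acceptance_rate < 1)
  sol <- select_best(ens, 20)
  cl <- cluster_solutions(sol, k = 2, seed = 1)
  tdc <- tidy(cl)
  expect_equal(nrow(tdc), 20)
  expect_equal(sum(tdc$is_center), 2)
  expect_equal(glance(cl)$k, 2)
})
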
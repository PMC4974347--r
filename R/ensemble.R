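#' Select the best-scoring models (solutions)
#'
#' @param ensemble An `xl_ensemble`.
#' @param n Number of solutions (default `config$n_best`); ties at the
#'   cutoff are broken by model index (stable).
#' @return An `xl_solutions`: the subset ensemble (`coords`, `scores`,
#'   `psis`, `model_index`) plus the system.
#' @export
select_best <- function(ensemble, n = ensemble$config$n_best) {
  stopifnot(n >= 1, n <= length(ensemble$scores))
  ord <- order(ensemble$scores, seq_along(ensemble$scores))[seq_len(n)]
  structure(list(
    coords = ensemble$coords[ord, , , drop = FALSE],
    scores = ensemble$scores[ord],
    psis = ensemble$psis[ord, , drop = FALSE],
    model_index = ord,
    system = ensemble$system
  ), class = "xl_solutions")
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Superposes `coords` onto `reference` by the rotation and translation
#' minimizing the RMSD over the core bead selection, then applies the
#' transform to all beads.
#'
#' @param coords,reference N x 3 matrices.
#' @param core_idx Indices of the beads to superpose on (default: all).
#' @return List with `coords` (transformed), `rmsd_core` and the `rotation`
#'   and `translation` applied.
#' @export
superpose_core <- function(coords, reference, core_idx = seq_len(nrow(coords))) {
  a <- coords[core_idx, , drop = FALSE]
  b <- reference[core_idx, , drop = FALSE]
  ca <- colMeans(a)
  cb <- colMeans(b)
  a0 <- sweep(a, 2, ca)
  b0 <- sweep(b, 2, cb)
  h <- t(a0) %*% b0
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  out <- sweep(coords, 2, ca) %*% t(rot)
  out <- sweep(out, 2, cb, "+")
  list(
    coords = out,
    rmsd_core = rmsd(out[core_idx, , drop = FALSE], b),
    rotation = rot,
    translation = cb - as.vector(rot %*% ca)
  )
}

#' Root-mean-square deviation between two coordinate sets
#'
#' @param a,b N x 3 matrices (no superposition applied).
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(a, b) {
  sqrt(mean(rowSums((a - b)^2)))
}

#' Cluster solutions by post-superposition coordinates
#'
#' Superposes every solution on the first solution's core beads, then runs
#' k-means on the flattened coordinates (Euclidean distance in this feature
#' space is proportional to all-bead RMSD). Each cluster's center is the
#' member (medoid) minimizing the mean RMSD to its co-members; the cluster
#' best satisfying the cross-link restraints (largest fraction of links
#' under the satisfaction threshold in at least one member) is flagged.
#'
#' @param solutions An `xl_solutions`.
#' @param k Number of clusters (>= 1).
#' @param seed Seed for the k-means initialization (default 1).
#' @return An `xl_clusters`: list with `assignment`, `k`, `centers` (member
#'   index per cluster), `sizes`, `satisfaction` (fraction per cluster),
#'   `best_cluster`, `superposed` (array of superposed coords) and the
#'   solutions.
#' @export
cluster_solutions <- function(solutions, k, seed = 1) {
  stopifnot(k >= 1)
  n <- length(solutions$scores)
  rep <- solutions$system$rep
  core <- rep$bodies[[rep$core_body]]
  nb <- dim(solutions$coords)[2]
  sup <- array(NA_real_, dim(solutions$coords))
  ref <- solutions$coords[1, , ]
  for (i in seq_len(n)) {
    sup[i, , ] <- superpose_core(solutions$coords[i, , ], ref, core)$coords
  }
  feat <- matrix(sup, nrow = n)
  if (k == 1) {
    assignment <- rep_len(1L, n)
  } else {
    km <- with_seed(seed, stats::kmeans(feat, centers = k, nstart = 10,
                                        iter.max = 100))
    assignment <- km$cluster
  }
  centers <- integer(k)
  for (cl in seq_len(k)) {
    members <- which(assignment == cl)
    if (length(members) == 1) {
      centers[cl] <- members
      next
    }
    mean_rmsd <- vapply(members, function(i) {
      mean(vapply(setdiff(members, i), function(j) {
        rmsd(sup[i, , ], sup[j, , ])
      }, numeric(1)))
    }, numeric(1))
    centers[cl] <- members[which.min(mean_rmsd)]
  }
  sat <- vapply(seq_len(k), function(cl) {
    rep_sat <- satisfaction_fraction(
      solutions$coords[assignment == cl, , , drop = FALSE],
      solutions$system
    )
    rep_sat
  }, numeric(1))
  structure(list(
    assignment = assignment, k = k, centers = centers,
    sizes = as.integer(table(factor(assignment, levels = seq_len(k)))),
    satisfaction = sat, best_cluster = which.max(sat),
    superposed = sup, solutions = solutions
  ), class = "xl_clusters")
}

#' @export
print.xl_clusters <- function(x, ...) {
  cat("<xl_clusters> k = ", x$k, "; sizes: ",
      paste(x$sizes, collapse = ", "), "; restraint satisfaction: ",
      paste(round(100 * x$satisfaction, 1), "%", collapse = ", "),
      " (best: cluster ", x$best_cluster, ")\n", sep = "")
  invisible(x)
}

# fraction of cross-links satisfied (< threshold in at least one member)
satisfaction_fraction <- function(coords_arr, system) {
  thr <- system$restraints$satisfaction_threshold
  n <- dim(coords_arr)[1]
  if (n == 0) return(NA_real_)
  sat <- rep(FALSE, length(system$xl_i))
  for (i in seq_len(n)) {
    d <- pair_dist(coords_arr[i, , ], system$xl_i, system$xl_j)
    sat <- sat | (d < thr)
  }
  mean(sat)
}

#' Precision and accuracy of a cluster
#'
#' Precision: mean all-bead RMSD of the members to the cluster center after
#' superposition on the core beads. Accuracy: mean RMSD of the members to a
#' reference coordinate set (e.g. the crystal structure mapped onto the
#' beads), also after core superposition; `NA` when no reference is given.
#' Both are also broken down per domain (RMSD over each domain's beads,
#' superposition still on the core).
#'
#' @param clusters An `xl_clusters`.
#' @param cluster Which cluster (default: the best-satisfying one).
#' @param reference Optional N x 3 reference coordinates.
#' @return List with `precision`, `accuracy`, and `per_domain` (tibble:
#'   `domain`, `precision`, `accuracy`).
#' @export
precision_accuracy <- function(clusters, cluster = clusters$best_cluster,
                               reference = NULL) {
  rep <- clusters$solutions$system$rep
  core <- rep$bodies[[rep$core_body]]
  members <- which(clusters$assignment == cluster)
  stopifnot(length(members) > 0)
  center <- clusters$superposed[clusters$centers[cluster], , ]

  prec_all <- numeric(length(members))
  prec_dom <- NULL
  acc_all <- rep(NA_real_, length(members))
  acc_dom <- NULL
  domains <- unique(rep$beads$domain)
  dom_idx <- lapply(domains, function(d) which(rep$beads$domain == d))
  ref_sup <- NULL
  prec_dom <- matrix(NA_real_, length(members), length(domains))
  acc_dom <- matrix(NA_real_, length(members), length(domains))
  for (m in seq_along(members)) {
    sup_c <- superpose_core(clusters$superposed[members[m], , ], center,
                            core)$coords
    prec_all[m] <- rmsd(sup_c, center)
    for (d in seq_along(domains)) {
      idx <- dom_idx[[d]]
      prec_dom[m, d] <- rmsd(sup_c[idx, , drop = FALSE],
                             center[idx, , drop = FALSE])
    }
    if (!is.null(reference)) {
      sup_r <- superpose_core(clusters$superposed[members[m], , ],
                              reference, core)$coords
      acc_all[m] <- rmsd(sup_r, reference)
      for (d in seq_along(domains)) {
        idx <- dom_idx[[d]]
        acc_dom[m, d] <- rmsd(sup_r[idx, , drop = FALSE],
                              reference[idx, , drop = FALSE])
      }
    }
  }
  list(
    precision = mean(prec_all),
    accuracy = if (is.null(reference)) NA_real_ else mean(acc_all),
    per_domain = tibble::tibble(
      domain = domains,
      precision = colMeans(prec_dom),
      accuracy = if (is.null(reference)) NA_real_ else colMeans(acc_dom)
    )
  )
}

#' Localization density of a domain over a cluster
#'
#' Converts the superposed members of a cluster into the probability that a
#' volume element is occupied by the given domain: for each voxel, the
#' fraction of members in which any bead of the domain (a sphere of the
#' bead's radius) overlaps the voxel cube.
#'
#' @param clusters An `xl_clusters`.
#' @param domain Domain name (a value of the representation's bead
#'   `domain` column).
#' @param cluster Which cluster (default: best).
#' @param voxel Voxel edge length in Angstrom (default 5).
#' @param padding Extra margin around the domain bounding box (default 5).
#' @return An `xl_density`: list with `grid` (3d array of occupancy
#'   probabilities in `[0, 1]`), `origin` (corner of the first voxel) and
#'   `voxel`.
#' @export
localization_density <- function(clusters, domain,
                                 cluster = clusters$best_cluster,
                                 voxel = 5, padding = 5) {
  rep <- clusters$solutions$system$rep
  idx <- which(rep$beads$domain == domain)
  if (length(idx) == 0) stop("Unknown domain: ", domain, call. = FALSE)
  members <- which(clusters$assignment == cluster)
  stopifnot(length(members) > 0)
  radius <- rep$beads$radius[idx]
  pts <- do.call(rbind, lapply(members, function(m) {
    clusters$superposed[m, idx, , drop = FALSE][1, , ]
  }))
  pts <- matrix(pts, ncol = 3)
  lo <- apply(pts, 2, min) - max(radius) - padding
  hi <- apply(pts, 2, max) + max(radius) + padding
  dims <- pmax(1L, as.integer(ceiling((hi - lo) / voxel)))
  centers <- lapply(1:3, function(d) lo[d] + (seq_len(dims[d]) - 0.5) * voxel)
  grid <- array(0, dims)
  gx <- rep(centers[[1]], times = dims[2] * dims[3])
  gy <- rep(rep(centers[[2]], each = dims[1]), times = dims[3])
  gz <- rep(centers[[3]], each = dims[1] * dims[2])
  half <- voxel / 2
  for (m in seq_along(members)) {
    occ <- rep(FALSE, length(gx))
    p <- clusters$superposed[members[m], idx, , drop = FALSE][1, , ]
    p <- matrix(p, ncol = 3)
    for (b in seq_len(nrow(p))) {
      # distance from bead center to nearest point of each voxel cube
      dx <- pmax(0, abs(gx - p[b, 1]) - half)
      dy <- pmax(0, abs(gy - p[b, 2]) - half)
      dz <- pmax(0, abs(gz - p[b, 3]) - half)
      occ <- occ | (dx * dx + dy * dy + dz * dz <= radius[b]^2)
    }
    grid <- grid + array(occ, dims)
  }
  structure(list(grid = grid / length(members), origin = lo, voxel = voxel,
                 domain = domain),
            class = "xl_density")
}

#' Write a localization density as a CCP4/MRC map
#'
#' Minimal single-volume MRC2014 writer (mode 2, 32-bit float, orthogonal
#' axes): voxel occupancies on a cubic grid. Written for this package
#' because no installed R package emits MRC/CCP4 volumes.
#'
#' @param density An `xl_density` from [localization_density()].
#' @param path Output file path (conventionally `.mrc`).
#' @export
write_density_mrc <- function(density, path) {
  g <- density$grid
  dims <- dim(g)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(dims)                      # NX NY NZ
  wi(2)                         # MODE 2: float32
  wi(c(0, 0, 0))                # NXSTART NYSTART NZSTART
  wi(dims)                      # MX MY MZ
  wf(dims * density$voxel)      # CELLA
  wf(c(90, 90, 90))             # CELLB
  wi(c(1, 2, 3))                # MAPC MAPR MAPS
  wf(c(min(g), max(g), mean(g)))  # DMIN DMAX DMEAN
  wi(1)                         # ISPG
  wi(0)                         # NSYMBT
  writeBin(raw(100), con)       # EXTRA (25 words incl. EXTTYP/NVERSION)
  wf(density$origin)            # ORIGIN
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(as.vector(g)))   # RMS
  wi(0)                         # NLABL
  writeBin(raw(800), con)       # labels
  wf(as.vector(g))              # data, x fastest
  invisible(path)
}

#' Per-link satisfaction report and contact map
#'
#' A cross-link is satisfied when its bead-bead distance is below the
#' satisfaction threshold in at least one member of the cluster (the
#' ensemble is read as alternative conformations); the report also gives
#' the per-center-model call and each link's minimum distance across
#' members, plus a bead-bead contact frequency map at the same threshold.
#'
#' @param clusters An `xl_clusters`.
#' @param cluster Which cluster (default: best).
#' @return List with `links` (tibble: `res_a`, `res_b`, `class`,
#'   `min_distance`, `center_distance`, `satisfied`,
#'   `satisfied_in_center`), `fraction_satisfied`, and `contact`
#'   (bead x bead frequency matrix).
#' @export
satisfaction_report <- function(clusters, cluster = clusters$best_cluster) {
  sys <- clusters$solutions$system
  thr <- sys$restraints$satisfaction_threshold
  members <- which(clusters$assignment == cluster)
  nl <- length(sys$xl_i)
  min_d <- rep(Inf, nl)
  for (m in members) {
    d <- pair_dist(clusters$superposed[m, , ], sys$xl_i, sys$xl_j)
    min_d <- pmin(min_d, d)
  }
  center_coords <- clusters$superposed[clusters$centers[cluster], , ]
  center_d <- pair_dist(center_coords, sys$xl_i, sys$xl_j)
  nb <- dim(clusters$superposed)[2]
  contact <- matrix(0, nb, nb)
  for (m in members) {
    cm <- as.matrix(stats::dist(clusters$superposed[m, , ])) < thr
    contact <- contact + cm
  }
  contact <- contact / length(members)
  diag(contact) <- 1
  links <- tibble::tibble(
    res_a = sys$restraints$crosslinks$res_a,
    res_b = sys$restraints$crosslinks$res_b,
    class = sys$restraints$crosslinks$class,
    min_distance = min_d,
    center_distance = center_d,
    satisfied = min_d < thr,
    satisfied_in_center = center_d < thr
  )
  list(links = links, fraction_satisfied = mean(links$satisfied),
       contact = contact)
}

#' Write solutions as a multi-model bead PDB
#'
#' One pseudo-atom (CA) per bead, one MODEL block per solution.
#'
#' @param solutions An `xl_solutions` (or `xl_clusters`, whose superposed
#'   members are written).
#' @param path Output path.
#' @param max_models Cap on the number of models written (default all).
#' @export
write_ensemble_pdb <- function(solutions, path, max_models = Inf) {
  if (inherits(solutions, "xl_clusters")) {
    coords <- solutions$superposed
    rep <- solutions$solutions$system$rep
  } else {
    coords <- solutions$coords
    rep <- solutions$system$rep
  }
  n <- min(dim(coords)[1], max_models)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_len(n)) {
    writeLines(sprintf("MODEL     %4d", m), con)
    for (b in seq_len(nrow(rep$beads))) {
      writeLines(sprintf(
        "ATOM  %5d  CA  GLY A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        b %% 100000, rep$beads$resno[b] %% 10000,
        coords[m, b, 1], coords[m, b, 2], coords[m, b, 3]
      ), con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
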
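# shared fixtures and independent oracles

# minimal PDB text with given CA records
# rows: data.frame(chain, resno, resid3, x, y, z, occ = 1, alt = "")
write_toy_pdb <- function(rows, path) {
  lines <- vapply(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    alt <- if (!is.null(r$alt) && nzchar(r$alt)) r$alt else " "
    occ <- if (!is.null(r$occ)) r$occ else 1
    sprintf("ATOM  %5d  CA %s%-3s %s%4d    %8.3f%8.3f%8.3f%6.2f  0.00           C",
            i, alt, r$resid3, r$chain, r$resno, r$x, r$y, r$z, occ)
  }, character(1))
  writeLines(c(lines, "END"), path)
  path
}

# independent Significance A oracle via the normal CDF (the implementation
# uses the complementary error function)
sigA_oracle <- function(values, query) {
  m <- stats::median(values)
  qs <- stats::quantile(values, c(0.1587, 0.8413), names = FALSE)
  z <- ifelse(query >= m, (query - m) / (qs[2] - m), (m - query) / (m - qs[1]))
  stats::pnorm(z, lower.tail = FALSE)
}

# independent quaternion-method (Horn) superposition oracle
horn_superpose_rmsd <- function(a, b) {
  ca <- colMeans(a)
  cb <- colMeans(b)
  a0 <- sweep(a, 2, ca)
  b0 <- sweep(b, 2, cb)
  s <- t(a0) %*% b0
  sxx <- s[1, 1]; sxy <- s[1, 2]; sxz <- s[1, 3]
  syx <- s[2, 1]; syy <- s[2, 2]; syz <- s[2, 3]
  szx <- s[3, 1]; szy <- s[3, 2]; szz <- s[3, 3]
  n4 <- matrix(c(
    sxx + syy + szz, syz - szy, szx - sxz, sxy - syx,
    syz - szy, sxx - syy - szz, sxy + syx, szx + sxz,
    szx - sxz, sxy + syx, -sxx + syy - szz, syz + szy,
    sxy - syx, szx + sxz, syz + szy, -sxx - syy + szz
  ), 4, 4, byrow = TRUE)
  ev <- eigen(n4, symmetric = TRUE)
  q <- ev$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rot <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
  a_rot <- a0 %*% t(rot)
  sqrt(mean(rowSums((a_rot - b0)^2)))
}

# small representation used across modeling tests: 2 rigid bodies + linker
toy_two_body_rep <- function() {
  toy <- make_toy_protein(n_domains = 2, residues_per_domain = 8,
                          linker_length = 4, seed = 42)
  s <- toy_state_structure(toy, "A")
  bodies <- list(
    D1 = list(c(toy$domains$start[1], toy$domains$end[1])),
    D2 = list(c(toy$domains$start[2], toy$domains$end[2]))
  )
  rep <- build_representation(s, bodies, core = "D1")
  list(toy = toy, s = s, rep = rep)
}

# brute-force total score recomputation, independent of the packaged
# scoring path: explicit loops over all pairs and restraints
brute_force_score <- function(coords, rep, restraints, psi, params) {
  n <- nrow(coords)
  dmat <- as.matrix(stats::dist(coords))
  ll <- 0
  for (k in seq_len(nrow(restraints$crosslinks))) {
    i <- match(restraints$crosslinks$res_a[k], rep$beads$resno)
    j <- match(restraints$crosslinks$res_b[k], rep$beads$resno)
    d <- dmat[i, j]
    f <- 1 / (1 + exp((d - params$d0) / params$lambda))
    p <- psi[[match(restraints$crosslinks$class[k],
                    c("consistent", "single"))]]
    ll <- ll + log(p + (1 - 2 * p) * f)
  }
  ev <- 0
  unit <- ifelse(is.na(rep$beads$body), -seq_len(n), rep$beads$body)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (unit[i] == unit[j]) next
      if (rep$beads$chain[i] == rep$beads$chain[j] &&
          abs(rep$beads$resno[i] - rep$beads$resno[j]) <= 2) next
      ov <- rep$beads$radius[i] + rep$beads$radius[j] - dmat[i, j]
      if (ov > 0) ev <- ev + params$k_ev * ov^2
    }
  }
  conn <- 0
  for (i in seq_len(n - 1)) {
    if (rep$beads$chain[i] != rep$beads$chain[i + 1]) next
    rest <- 4 * (rep$beads$resno[i + 1] - rep$beads$resno[i])
    st <- dmat[i, i + 1] - rest
    if (st > 0) conn <- conn + params$k_conn * st^2
  }
  ss <- 0
  if (!is.null(restraints$disulfides)) {
    for (k in seq_len(nrow(restraints$disulfides))) {
      i <- match(restraints$disulfides$res_a[k], rep$beads$resno)
      j <- match(restraints$disulfides$res_b[k], rep$beads$resno)
      ss <- ss + params$k_ss * (dmat[i, j] - params$disulfide_rest)^2
    }
  }
  -ll + ev + conn + ss
}
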
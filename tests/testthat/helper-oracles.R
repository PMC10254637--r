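# Shared fixtures and independent oracles. The oracles are deliberately
# naive (explicit loops, no vectorisation, numeric optimisation instead of
# closed-form superposition) so they share no code path with the package.

KCAL_COULOMB <- 332.0637

# naive double-loop Coulomb sum
coulomb_naive <- function(xyz_a, q_a, xyz_b, q_b) {
  v <- 0
  for (i in seq_len(nrow(xyz_a))) {
    for (j in seq_len(nrow(xyz_b))) {
      r <- sqrt(sum((xyz_a[i, ] - xyz_b[j, ])^2))
      v <- v + q_a[i] * q_b[j] / r
    }
  }
  KCAL_COULOMB * v
}

# naive per-residue barrier shifts: loops over residues and states
deletion_scan_naive <- function(pair, eligible) {
  xr <- as.matrix(pair$reactant[, c("x", "y", "z")])
  xt <- as.matrix(pair$transition_state[, c("x", "y", "z")])
  qm_idx <- pair$qm$atom_indices
  row_key <- paste(pair$reactant$chain, pair$reactant$resid,
                   pair$reactant$resname, sep = ":")
  vapply(eligible, function(k) {
    idx <- which(row_key == k)
    v_r <- coulomb_naive(xr[idx, , drop = FALSE],
                         pair$reactant$charge[idx],
                         xr[qm_idx, , drop = FALSE], pair$qm$charges_R)
    v_ts <- coulomb_naive(xt[idx, , drop = FALSE],
                          pair$reactant$charge[idx],
                          xt[qm_idx, , drop = FALSE], pair$qm$charges_TS)
    -(v_ts - v_r)
  }, numeric(1))
}

# minimal hand-built structure: one row per atom
tiny_structure <- function(xyz, charge, resid = seq_len(nrow(xyz)),
                           resname = "ALA", chain = "A",
                           atom_name = NULL) {
  n <- nrow(xyz)
  resname <- rep_len(resname, n)
  resid <- rep_len(resid, n)
  if (is.null(atom_name)) {
    atom_name <- paste0("X", stats::ave(seq_len(n), resid, FUN = seq_along))
  }
  new_structure(data.frame(
    serial = seq_len(n), atom_name = atom_name, resname = resname,
    chain = chain, resid = as.integer(resid),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    charge = charge, stringsAsFactors = FALSE))
}

# random reactant/TS fixture: small QM core plus a handful of environment
# residues; TS jitters the QM geometry and redistributes QM charge with a
# zero-sum increment
random_fixture <- function(seed, n_res = 8, atoms_per_res = 3,
                           n_qm = 5) {
  set.seed(seed)
  qm_xyz <- matrix(stats::rnorm(3 * n_qm, 0, 1.5), ncol = 3)
  charges_R <- round(stats::rnorm(n_qm, 0, 0.5), 3)
  dq <- stats::rnorm(n_qm); dq <- round(dq - mean(dq), 3)
  dq[n_qm] <- -sum(dq[-n_qm])  # exact zero-sum in decimal
  charges_TS <- charges_R + dq
  env_xyz <- NULL; env_q <- NULL; env_resid <- NULL
  for (r in seq_len(n_res)) {
    center <- (6 + 9 * stats::runif(1)) * {
      u <- stats::rnorm(3); u / sqrt(sum(u^2))
    }
    pts <- sweep(matrix(stats::rnorm(3 * atoms_per_res, 0, 0.8), ncol = 3),
                 2, center, `+`)
    env_xyz <- rbind(env_xyz, pts)
    env_q <- c(env_q, round(stats::rnorm(atoms_per_res, 0, 0.4), 3))
    env_resid <- c(env_resid, rep(r, atoms_per_res))
  }
  xyz_R <- rbind(qm_xyz, env_xyz)
  charge <- c(charges_R, env_q)
  resid <- c(rep(500L, n_qm), env_resid)
  resname <- c(rep("QIN", n_qm), rep("ENV", length(env_resid)))
  s_R <- tiny_structure(xyz_R, charge, resid = resid, resname = resname)
  s_TS <- s_R
  qm_jit <- matrix(stats::rnorm(3 * n_qm, 0, 0.05), ncol = 3)
  s_TS$x[1:n_qm] <- s_TS$x[1:n_qm] + qm_jit[, 1]
  s_TS$y[1:n_qm] <- s_TS$y[1:n_qm] + qm_jit[, 2]
  s_TS$z[1:n_qm] <- s_TS$z[1:n_qm] + qm_jit[, 3]
  s_TS$charge[1:n_qm] <- charges_TS
  reaction_state_pair(s_R, s_TS,
                      qm_region(1:n_qm, charges_R, charges_TS))
}

# two-QM-atom pair with a single probe residue: the minimal macrodipole
# geometry (unit charge transferred donor -> acceptor)
probe_pair <- function(separation, probe_pos, probe_q, lambda = 1) {
  half <- separation / 2
  xyz <- rbind(c(-half, 0, 0), c(half, 0, 0), probe_pos)
  s_R <- tiny_structure(xyz, c(0, -1, probe_q),
                        resid = c(500L, 500L, 1L),
                        resname = c("QIN", "QIN", "PRB"))
  s_TS <- s_R
  charges_R <- c(0, -1)
  charges_TS <- c(-lambda, -1 + lambda)
  s_TS$charge[1:2] <- charges_TS
  reaction_state_pair(s_R, s_TS, qm_region(1:2, charges_R, charges_TS))
}

# brute-force superposition RMSD: centre both sets, then numerically
# minimise over Euler angles from a grid of starts (no Kabsch algebra)
rmsd_oracle <- function(mobile, target) {
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(target, 2, colMeans(target))
  rot <- function(ang) {
    ca <- cos(ang[1]); sa <- sin(ang[1])
    cb <- cos(ang[2]); sb <- sin(ang[2])
    cc <- cos(ang[3]); sc <- sin(ang[3])
    Rz <- matrix(c(ca, -sa, 0, sa, ca, 0, 0, 0, 1), 3, byrow = TRUE)
    Ry <- matrix(c(cb, 0, sb, 0, 1, 0, -sb, 0, cb), 3, byrow = TRUE)
    Rx <- matrix(c(1, 0, 0, 0, cc, -sc, 0, sc, cc), 3, byrow = TRUE)
    Rz %*% Ry %*% Rx
  }
  f <- function(ang) sqrt(sum((A %*% t(rot(ang)) - B)^2) / nrow(A))
  best <- Inf
  grid <- seq(0, 2 * pi, length.out = 5)[-5]
  for (a in grid) for (b in grid) for (cc in grid) {
    o <- stats::optim(c(a, b, cc), f, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000))
    if (o$value < best) best <- o$value
  }
  best
}
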
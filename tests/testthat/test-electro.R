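test_that("coulomb reproduces forced values and rejects overlaps", {
  # +1e and -1e at k/100 Angstrom: exactly -100 kcal/mol
  a <- matrix(c(0, 0, 0), ncol = 3)
  b <- matrix(c(3.320637, 0, 0), ncol = 3)
  expect_equal(coulomb(a, 1, b, -1), -100, tolerance = 1e-12)
  expect_identical(coulomb(a, 1, b, 0), 0)
  expect_identical(coulomb(a, 0, b, -1), 0)
  # symmetric in arguments
  set.seed(3)
  xa <- matrix(rnorm(30), ncol = 3); qa <- rnorm(10)
  xb <- matrix(rnorm(30, 8), ncol = 3); qb <- rnorm(10)
  expect_equal(coulomb(xa, qa, xb, qb), coulomb(xb, qb, xa, qa),
               tolerance = 1e-12)
  # matches the naive double loop
  expect_equal(coulomb(xa, qa, xb, qb), coulomb_naive(xa, qa, xb, qb),
               tolerance = 1e-9)
  expect_error(coulomb(a, 1, a, -1), "overlapping")
  # uniform dielectric simply scales
  expect_equal(coulomb(xa, qa, xb, qb, eps = 4),
               coulomb(xa, qa, xb, qb) / 4, tolerance = 1e-12)
})

test_that("state_interaction handles zero charge, symmetry, and QM overlap", {
  # probe equidistant from donor and acceptor that merely exchange -1e
  pair <- probe_pair(separation = 4, probe_pos = c(0, 6, 0), probe_q = 1)
  v <- state_interaction(pair, "A:1:PRB")
  expect_equal(v$V_R, v$V_TS, tolerance = 1e-12)

  zpair <- probe_pair(separation = 4, probe_pos = c(3, 5, 0), probe_q = 0)
  vz <- state_interaction(zpair, "A:1:PRB")
  expect_identical(c(vz$V_R, vz$V_TS), c(0, 0))

  expect_error(state_interaction(pair, "A:500:QIN"), "QM")
  expect_error(state_interaction(pair, "A:9:XXX"), "not found")
})

test_that("scan matches generator ground truth on the toy preset", {
  fx <- make_toy_enzyme(toy_ncs_spec(seed = 42L))
  scan <- deletion_scan(fx$pair, eligible = fx$truth$key)
  m <- merge(as.data.frame(scan), fx$truth, by = "resid",
             suffixes = c("_scan", "_truth"))
  expect_equal(nrow(m), nrow(fx$truth))
  expect_lt(max(abs(m$ddE_scan - m$ddE_truth)), 1e-9)
})

test_that("hand-evaluated four-term example: positive residue near the acceptor", {
  # acceptor -1e (R) -> -0.5e (TS) at 4 A from the probe; donor 0 -> -0.5e
  # at 10 A; probe +1e.  Four pairwise Coulomb terms evaluated by hand:
  k <- 332.0637
  # donor at (-10,0,0), acceptor at (-4,0,0), probe at the origin
  xyz <- rbind(c(-10, 0, 0), c(-4, 0, 0), c(0, 0, 0))
  s_R <- tiny_structure(xyz, c(0, -1, 1), resid = c(500L, 500L, 1L),
                        resname = c("QIN", "QIN", "PRB"))
  s_TS <- s_R
  s_TS$charge[1:2] <- c(-0.5, -0.5)
  pair <- reaction_state_pair(s_R, s_TS,
                              qm_region(1:2, c(0, -1), c(-0.5, -0.5)))
  scan <- deletion_scan(pair, dE_wt = 10.6, eligible = "A:1:PRB")
  V_R <- k * (1 * 0 / 10 + 1 * (-1) / 4)
  V_TS <- k * (1 * (-0.5) / 10 + 1 * (-0.5) / 4)
  expect_equal(scan$ddE, -(V_TS - V_R), tolerance = 1e-9)
  expect_lt(scan$ddE, 0)
  expect_identical(scan$effect_class, "anticatalytic")
  expect_equal(scan$dE_m, 10.6 + scan$ddE, tolerance = 1e-12)
})

test_that("neutral residues scan to exactly zero and classify neutral", {
  pair <- probe_pair(separation = 4, probe_pos = c(1, 7, -2), probe_q = 0)
  scan <- deletion_scan(pair, eligible = "A:1:PRB")
  expect_identical(scan$ddE, 0)
  expect_identical(scan$effect_class, "neutral")
})

test_that("scan agrees with the naive oracle on random fixtures", {
  for (seed in 1:50) {
    pair <- random_fixture(seed)
    eligible <- setdiff(residue_keys(pair$reactant), "A:500:QIN")
    scan <- deletion_scan(pair, eligible = eligible)
    got <- scan$ddE[match(eligible,
                          paste(scan$chain, scan$resid, scan$resname,
                                sep = ":"))]
    want <- deletion_scan_naive(pair, eligible)
    expect_lt(max(abs(got - unname(want))), 1e-9)
  }
})

test_that("per-residue shifts sum to the negated environment differential", {
  fx <- make_toy_enzyme(toy_ncs_spec(seed = 13L))
  scan <- deletion_scan(fx$pair, eligible = fx$truth$key)
  env <- setdiff(seq_len(nrow(fx$pair$reactant)),
                 fx$pair$qm$atom_indices)
  xr <- coords(fx$pair$reactant); xt <- coords(fx$pair$transition_state)
  qm_idx <- fx$pair$qm$atom_indices
  V_env_R <- coulomb(xr[env, ], fx$pair$reactant$charge[env],
                     xr[qm_idx, ], fx$pair$qm$charges_R)
  V_env_TS <- coulomb(xt[env, ], fx$pair$reactant$charge[env],
                      xt[qm_idx, ], fx$pair$qm$charges_TS)
  expect_equal(sum(scan$ddE), -(V_env_TS - V_env_R), tolerance = 1e-9)
})

test_that("energies scale as 1/s under uniform coordinate scaling", {
  pair <- random_fixture(99)
  eligible <- setdiff(residue_keys(pair$reactant), "A:500:QIN")
  scan1 <- deletion_scan(pair, eligible = eligible)
  s <- 1.75
  scale_struct <- function(st) {
    st$x <- st$x * s; st$y <- st$y * s; st$z <- st$z * s; st
  }
  scaled <- reaction_state_pair(scale_struct(pair$reactant),
                                scale_struct(pair$transition_state),
                                pair$qm)
  scan2 <- deletion_scan(scaled, eligible = eligible)
  expect_equal(scan2$ddE, scan1$ddE / s, tolerance = 1e-9)
})

test_that("barrier shifts are linear in the transfer fraction", {
  base <- function(lam) {
    spec <- toy_enzyme_spec(n_env_residues = 12, transfer_fraction = lam,
                            seed = 5L)
    fx <- make_toy_enzyme(spec)
    fx$truth$ddE[order(fx$truth$resid)]
  }
  full <- base(1)
  expect_equal(base(0.5), 0.5 * full, tolerance = 1e-12)
  expect_equal(base(0.25), 0.25 * full, tolerance = 1e-12)
  expect_true(all(base(0) == 0))
  # and the scan engine sees the same linearity
  spec <- toy_enzyme_spec(n_env_residues = 12, transfer_fraction = 0.5,
                          seed = 5L)
  fx <- make_toy_enzyme(spec)
  scan <- deletion_scan(fx$pair, eligible = fx$truth$key)
  m <- match(paste0("A:", scan$resid, ":", scan$resname), fx$truth$key)
  expect_lt(max(abs(scan$ddE - fx$truth$ddE[m])), 1e-9)
})

test_that("scan output is sorted ascending by ddE and carries metadata", {
  fx <- make_toy_enzyme(toy_ncs_spec(seed = 42L))
  scan <- deletion_scan(fx$pair, dE_wt = 10.6, eligible = fx$truth$key,
                        threshold = 1)
  expect_true(!is.unsorted(scan$ddE))
  expect_identical(attr(scan, "dE_wt"), 10.6)
  expect_error(deletion_scan(fx$pair, eligible = character(0)), "non-empty")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_scan_tsv(scan, f)
  back <- read_scan_tsv(f)
  expect_equal(back$ddE, scan$ddE, tolerance = 1e-15)
  expect_identical(back$effect_class, scan$effect_class)
})
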
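test_that("read_pqr transcribes records verbatim and errors on bad input", {
  f <- withr::local_tempfile(fileext = ".pqr")
  writeLines(c(
    "REMARK two-atom fixture",
    "ATOM      1 OD1  ASP  A    64     -10.0000      0.5000      0.0000   -1.0000  1.5000",
    "ATOM      2 CB   ASP  A    64      -8.5000      0.5000      0.0000    0.0000  1.7000"
  ), f)
  s <- read_pqr(f)
  expect_s3_class(s, "Structure")
  expect_equal(nrow(s), 2L)
  expect_equal(s$charge, c(-1, 0))
  expect_equal(s$radius, c(1.5, 1.7))
  expect_equal(s$chain, c("A", "A"))
  expect_equal(s$resid, c(64L, 64L))

  bad <- withr::local_tempfile(fileext = ".pqr")
  writeLines(c("ATOM 1 X ALA A 1 0 0 0", "ATOM x"), bad)
  expect_error(read_pqr(bad), "line")
  empty <- withr::local_tempfile(fileext = ".pqr")
  writeLines("REMARK nothing", empty)
  expect_error(read_pqr(empty), "no ATOM")
})

test_that("PQR write/read round trip is the identity, chain present or not", {
  set.seed(5)
  for (chain in c("A", "")) {
    s <- tiny_structure(matrix(round(rnorm(18), 4), ncol = 3),
                        charge = round(rnorm(6, 0, 0.5), 4),
                        resid = rep(1:2, each = 3), chain = chain)
    s$radius <- round(runif(6, 1, 2), 4)
    f <- withr::local_tempfile(fileext = ".pqr")
    write_pqr(s, f)
    back <- read_pqr(f)
    for (col in c("serial", "atom_name", "resname", "chain", "resid",
                  "x", "y", "z", "charge", "radius")) {
      expect_equal(back[[col]], s[[col]], info = paste(col, chain))
    }
    write_pqr(back, paste0(f, "2"))
    expect_identical(readLines(paste0(f, "2")), readLines(f))
  }
})

test_that("toy fixture files round trip with the recorded total charge", {
  dir <- withr::local_tempdir()
  fx <- make_toy_enzyme(toy_ncs_spec(seed = 42L), out_dir = dir)
  s <- read_pqr(file.path(dir, "R.pqr"))
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_equal(sum(s$charge), gt$total_charge, tolerance = 1e-12)
  expect_equal(nrow(s), nrow(fx$pair$reactant))
})

test_that("read_multimodel splits frames and enforces atom alignment", {
  dir <- withr::local_tempdir()
  fx <- make_toy_enzyme(toy_ncs_spec(seed = 7L))
  traj_file <- file.path(dir, "traj.pdb")
  make_trajectory(fx$pair$reactant, n_frames = 50, jitter_sigma = 0.1,
                  seed = 7L, path = traj_file)
  frames <- read_multimodel(traj_file)
  expect_length(frames, 50L)
  # frame 1 is the untouched reference at printed precision
  expect_lt(max(abs(coords(frames[[1]]) - coords(fx$pair$reactant))),
            5.1e-5)

  single <- file.path(dir, "single.pqr")
  write_pqr(fx$pair$reactant, single)
  expect_length(read_multimodel(single), 1L)

  # mismatched second model is rejected
  s2 <- fx$pair$reactant
  s2$atom_name[1] <- "ZZ"
  bad <- file.path(dir, "bad.pdb")
  write_multimodel(list(fx$pair$reactant, s2), bad)
  expect_error(read_multimodel(bad), "differs")
})

test_that("structure invariants are enforced", {
  xyz <- matrix(0:8, ncol = 3)
  expect_error(
    tiny_structure(xyz, c(0, 0, Inf)), "charge")
  df <- data.frame(serial = 1:2, atom_name = c("CA", "CA"),
                   resname = "ALA", chain = "A", resid = 1L,
                   x = c(0, 1), y = 0, z = 0, charge = 0)
  expect_error(new_structure(df), "duplicate")
})

test_that("eligibility respects the radius boundary and exclusions", {
  # QM core at origin; probes at controlled minimum distances
  qm_xyz <- rbind(c(0, 0, 0), c(1, 0, 0))
  probes <- rbind(c(9.9, 0, 0),    # resid 1: inside
                  c(11.1, 0, 0),   # resid 2: min distance 10.1, outside
                  c(0, 5, 0),      # resid 3: GLY, close but excluded
                  c(0, -6, 0))     # resid 4: excluded by id
  s <- tiny_structure(rbind(qm_xyz, probes), c(0.5, -0.5, 1, 1, 1, 1),
                      resid = c(500L, 500L, 1L, 2L, 3L, 4L),
                      resname = c("QIN", "QIN", "LYS", "LYS", "GLY", "ASP"))
  pair <- reaction_state_pair(s, s, qm_region(1:2, c(0.5, -0.5),
                                              c(-0.5, 0.5)))
  got <- select_eligible_residues(pair, radius = 10,
                                  excluded_ids = "A:4:ASP")
  expect_identical(got, "A:1:LYS")
  expect_error(select_eligible_residues(pair, radius = -1), "radius")
})

test_that("eligibility is monotone in radius and rigid-motion invariant", {
  fx <- make_toy_enzyme(toy_ncs_spec(seed = 3L))
  radii <- c(6, 8, 10, 14, 20, 40)
  sets <- lapply(radii, function(r) select_eligible_residues(fx$pair, r))
  for (i in seq_along(radii)[-1]) {
    expect_true(all(sets[[i - 1]] %in% sets[[i]]),
                info = paste("radius", radii[i]))
  }
  # all environment residues eventually eligible (minus Gly/Pro: none here)
  expect_setequal(sets[[length(sets)]], fx$truth$key)

  # rigid rotation + translation leaves the eligible set unchanged
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3,
              byrow = TRUE)
  move <- function(s) {
    xyz <- coords(s) %*% t(R)
    s$x <- xyz[, 1] + 3; s$y <- xyz[, 2] - 2; s$z <- xyz[, 3] + 11
    s
  }
  moved <- reaction_state_pair(move(fx$pair$reactant),
                               move(fx$pair$transition_state), fx$pair$qm)
  expect_identical(select_eligible_residues(moved, 10),
                   select_eligible_residues(fx$pair, 10))
})

test_that("sidecar charge tables attach by atom identity", {
  s <- tiny_structure(matrix(rnorm(9), ncol = 3), c(0, 0, 0),
                      resid = c(1L, 1L, 2L), resname = "ALA")
  csv <- withr::local_tempfile(fileext = ".csv")
  tab <- data.frame(chain = "A", resid = s$resid, atom_name = s$atom_name,
                    charge = c(0.1, -0.2, 0.3))
  write.csv(tab[c(3, 1, 2), ], csv, row.names = FALSE)  # order-independent
  s2 <- attach_charges(s, csv)
  expect_equal(s2$charge, c(0.1, -0.2, 0.3))
  write.csv(tab[-1, ], csv, row.names = FALSE)
  expect_error(attach_charges(s, csv), "missing atom")
})
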
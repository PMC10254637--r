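# ---------------------------------------------------------------------------
# Synthetic toy-enzyme generator.
#
# The fixture emulates the physics the deletion analysis assumes: a small QM
# core in which a proton transfer moves charge lambda from a donor site (the
# substrate oxygen that develops negative charge at the TS) to an acceptor
# site (a catalytic carboxylate partially neutralised at the TS), surrounded
# by charged/polar/neutral environment residues at controlled distances. The
# environment is rigid between R and TS and only the QM charges differ, so
# every residue's barrier shift has a two-centre closed form that serves as
# ground truth.

#' Describe one planted environment residue
#'
#' @param resid author-numbering residue id.
#' @param resname 3-letter residue name.
#' @param class one of `"acidic"`, `"basic"`, `"polar"`, `"apolar"`.
#' @param position placement policy: `"near_donor"`, `"near_acceptor"`,
#'   `"equidistant"` (on the plane bisecting the two sites), or `"far"`.
#' @param formal_charge side-chain formal charge (e); defaults to -1 for
#'   acidic, +1 for basic, 0 otherwise.
#' @param dipole for neutral residues, magnitude (e) of a two-atom dipole
#'   (+/- dipole separated 2 Angstrom radially); 0 gives small default
#'   partial charges for polar residues and none for apolar.
#' @param distance placement distance (Angstrom): from the named site for
#'   near_* policies, from the midpoint for `"equidistant"`.
#' @param buried if TRUE, the generator cages the residue's charged group
#'   with neutral dummy residues so exposure analyses classify it as buried.
#' @return a list describing the planted residue.
#' @export
planted_residue <- function(resid, resname,
                            class = c("acidic", "basic", "polar", "apolar"),
                            position = c("near_donor", "near_acceptor",
                                         "equidistant", "far"),
                            formal_charge = NULL, dipole = 0,
                            distance = 9.0, buried = FALSE) {
  class <- match.arg(class)
  position <- match.arg(position)
  if (is.null(formal_charge)) {
    formal_charge <- switch(class, acidic = -1, basic = +1, 0)
  }
  list(resid = as.integer(resid), resname = resname, class = class,
       position = position, formal_charge = formal_charge,
       dipole = dipole, distance = distance, buried = buried)
}

#' Toy-enzyme specification
#'
#' @param n_env_residues total environment residues (planted ones included;
#'   cage residues for buried controls are extra).
#' @param shell_radius_range radial band (Angstrom, from the site midpoint)
#'   on which non-planted environment residues are placed.
#' @param planted list of [planted_residue()] entries.
#' @param transfer_fraction lambda in `[0, 1]`: fraction of a unit charge
#'   moved from the donor site to the acceptor site between R and TS. The
#'   default 0.5 models a transition state in which the transferring proton
#'   is halfway along the donor-acceptor coordinate.
#' @param jitter_sigma Gaussian positional jitter (Angstrom, per coordinate)
#'   applied to environment atoms after placement.
#' @param site_separation donor-acceptor distance (Angstrom).
#' @param seed RNG seed; all generator randomness derives from it.
#' @return an object of class `toy_enzyme_spec`.
#' @export
toy_enzyme_spec <- function(n_env_residues = 30,
                            shell_radius_range = c(12, 18),
                            planted = list(),
                            transfer_fraction = 0.5,
                            jitter_sigma = 0.15,
                            site_separation = 4.0,
                            seed = 42L) {
  if (transfer_fraction < 0 || transfer_fraction > 1) {
    stop("transfer_fraction must be in [0, 1]")
  }
  if (any(shell_radius_range <= 0) || diff(shell_radius_range) < 0) {
    stop("shell radii must be positive and ordered")
  }
  if (jitter_sigma < 0) stop("jitter_sigma must be >= 0")
  resids <- vapply(planted, `[[`, 1L, "resid")
  if (anyDuplicated(resids)) stop("duplicate planted resid")
  structure(list(n_env_residues = n_env_residues,
                 shell_radius_range = shell_radius_range,
                 planted = planted,
                 transfer_fraction = transfer_fraction,
                 jitter_sigma = jitter_sigma,
                 site_separation = site_separation,
                 seed = as.integer(seed)),
            class = "toy_enzyme_spec")
}

#' The default toy preset
#'
#' Thirty environment residues on a 12-18 Angstrom shell around a QM core
#' whose donor and acceptor sites sit 4 Angstrom apart, lambda = 0.5. Six
#' planted charged residues reproduce the qualitative candidate pattern of a
#' macrodipole scan (acidic residues on the donor side, basic residues on
#' the acceptor side, all strongly anticatalytic), one neutral tyrosine-like
#' dipolar residue has a large negative barrier shift but no formal charge,
#' and one charged-but-buried control sits on the bisecting plane with a
#' near-zero shift, caged by neutral dummy residues.
#'
#' @param seed RNG seed (default 42).
#' @return a [toy_enzyme_spec()].
#' @export
toy_ncs_spec <- function(seed = 42L) {
  toy_enzyme_spec(
    n_env_residues = 30,
    shell_radius_range = c(12, 18),
    planted = list(
      planted_residue(64, "ASP", "acidic", "near_donor", distance = 8.0),
      planted_residue(71, "ASP", "acidic", "near_donor", distance = 9.0),
      planted_residue(105, "ARG", "basic", "near_acceptor", distance = 8.5),
      planted_residue(110, "LYS", "basic", "near_acceptor", distance = 9.5),
      planted_residue(117, "GLU", "acidic", "near_donor", distance = 8.8),
      planted_residue(163, "LYS", "basic", "near_acceptor", distance = 9.2),
      planted_residue(60, "TYR", "polar", "near_donor", dipole = 0.8,
                      distance = 8.0),
      planted_residue(200, "LYS", "basic", "equidistant", distance = 12.0,
                      buried = TRUE)
    ),
    transfer_fraction = 0.5,
    jitter_sigma = 0.15,
    site_separation = 4.0,
    seed = seed
  )
}

# unit vector
unitv <- function(v) v / sqrt(sum(v^2))

# random unit vector
runifv <- function() unitv(stats::rnorm(3))

#' Generate a toy reactant/transition-state fixture
#'
#' Builds the QM core and environment described by `spec`, with per-residue
#' closed-form ground-truth barrier shifts. The environment is identical in
#' R and TS (coordinates and charges); only the QM charges differ: charge
#' `lambda` is moved from the donor-site atom to the acceptor-site atom.
#' Ground truth is evaluated by an explicit two-centre double loop over the
#' charge increments, independent of the scan engine's state-energy path.
#'
#' @param spec a [toy_enzyme_spec()].
#' @param out_dir if non-NULL, write `R.pqr`, `TS.pqr`, `qm.json`, and
#'   `ground_truth.json` there (created if needed).
#' @return list with `pair` (a [reaction_state_pair()]), `truth` (data frame
#'   of per-residue ground truth), `total_env_differential`
#'   (\eqn{V_{env}(TS) - V_{env}(R)}, kcal/mol), and `files` (paths or NULL).
#' @export
make_toy_enzyme <- function(spec = toy_ncs_spec(), out_dir = NULL) {
  stopifnot(inherits(spec, "toy_enzyme_spec"))
  set.seed(spec$seed)
  lambda <- spec$transfer_fraction
  half <- spec$site_separation / 2
  donor_pos <- c(-half, 0, 0)
  acceptor_pos <- c(half, 0, 0)

  # --- QM core: 5 atoms over two residues; only OX and OE1 change charge
  qm_atoms <- data.frame(
    atom_name = c("OX", "C5", "C4A", "OE1", "CD"),
    resname   = c("QIN", "QIN", "QIN", "GLU", "GLU"),
    resid     = c(500L, 500L, 500L, 109L, 109L),
    x = c(donor_pos[1], -1.0, 0.0, acceptor_pos[1], half + 0.8),
    y = c(0, 0.8, -0.8, 0, 0.9),
    z = c(0, 0, 0, 0, 0),
    charge = c(-0.2, 0.3, 0.1, -0.9, -0.3),
    stringsAsFactors = FALSE
  )
  charges_R <- qm_atoms$charge
  charges_TS <- charges_R
  charges_TS[1] <- charges_TS[1] - lambda   # donor gains negative charge
  charges_TS[4] <- charges_TS[4] + lambda   # acceptor partially neutralised
  site_labels <- c("donor_site", "other", "other", "acceptor_site", "other")

  # --- environment residues
  placed_centers <- matrix(numeric(0), ncol = 3)
  place_center <- function(proposal_fun) {
    for (attempt in 1:100) {
      p <- proposal_fun()
      if (nrow(placed_centers) == 0L ||
          min(sqrt(rowSums(sweep(placed_centers, 2, p)^2))) >= 1.5) {
        placed_centers <<- rbind(placed_centers, p)
        return(p)
      }
    }
    stop("could not place residue without collision after 100 attempts")
  }

  center_for <- function(pl) {
    switch(pl$position,
      near_donor = {
        dir <- unitv(c(-1, stats::rnorm(2, 0, 0.3)))
        donor_pos + pl$distance * dir
      },
      near_acceptor = {
        dir <- unitv(c(1, stats::rnorm(2, 0, 0.3)))
        acceptor_pos + pl$distance * dir
      },
      equidistant = {
        dir <- unitv(c(0, stats::rnorm(2)))
        pl$distance * dir
      },
      far = {
        (2.5 * spec$shell_radius_range[2]) * runifv()
      })
  }

  env_rows <- list()
  add_atom <- function(name, resname, resid, pos, charge) {
    env_rows[[length(env_rows) + 1L]] <<- data.frame(
      atom_name = name, resname = resname, resid = as.integer(resid),
      x = pos[1], y = pos[2], z = pos[3], charge = charge,
      stringsAsFactors = FALSE)
  }

  charged_atom_name <- function(resname) {
    switch(resname, ASP = "OD1", GLU = "OE1", LYS = "NZ", ARG = "NH1",
           HIS = "NE2", "QC")
  }

  build_residue <- function(resname, resid, center, formal_charge, dipole,
                            class) {
    outward <- unitv(center)        # radial direction away from the QM core
    jit <- function(p) p + stats::rnorm(3, 0, spec$jitter_sigma)
    if (formal_charge != 0) {
      add_atom(charged_atom_name(resname), resname, resid, jit(center),
               formal_charge)
      add_atom("CB", resname, resid, jit(center + 1.5 * outward), 0)
      add_atom("CA", resname, resid, jit(center + 3.0 * outward), 0)
    } else if (dipole != 0) {
      add_atom("OH", resname, resid, jit(center), -dipole)
      add_atom("CZ", resname, resid, jit(center + 2.0 * outward), +dipole)
      add_atom("CB", resname, resid, jit(center + 3.5 * outward), 0)
    } else if (class == "polar") {
      add_atom("OG", resname, resid, jit(center), -0.15)
      add_atom("CB", resname, resid, jit(center + 1.2 * outward), +0.15)
      add_atom("CA", resname, resid, jit(center + 2.6 * outward), 0)
    } else {
      add_atom("CB", resname, resid, jit(center), 0)
      add_atom("CA", resname, resid, jit(center + 1.5 * outward), 0)
    }
  }

  used_ids <- vapply(spec$planted, `[[`, 1L, "resid")
  truth_meta <- list()
  for (pl in spec$planted) {
    center <- place_center(function() center_for(pl))
    build_residue(pl$resname, pl$resid, center, pl$formal_charge, pl$dipole,
                  pl$class)
    truth_meta[[length(truth_meta) + 1L]] <-
      data.frame(resid = pl$resid, class = pl$class, policy = pl$position,
                 planted = TRUE, buried = pl$buried,
                 stringsAsFactors = FALSE)
    if (pl$buried) {
      # cage of neutral dummy residues around the charged group
      n_cage <- 5L
      for (ci in seq_len(n_cage)) {
        cage_id <- 900L + length(used_ids) + ci
        for (ai in 1:6) {
          add_atom(paste0("C", ai), "ALA", cage_id,
                   center + 4.0 * runifv(), 0)
        }
      }
    }
  }

  n_random <- spec$n_env_residues - length(spec$planted)
  if (n_random < 0) stop("n_env_residues smaller than the planted list")
  next_id <- 1L
  for (i in seq_len(n_random)) {
    while (next_id %in% c(used_ids, 109L, 500L)) next_id <- next_id + 1L
    resid <- next_id
    next_id <- next_id + 1L
    center <- place_center(function() {
      r <- stats::runif(1, spec$shell_radius_range[1],
                        spec$shell_radius_range[2])
      r * runifv()
    })
    class <- sample(c("polar", "apolar"), 1L)
    resname <- if (class == "polar") "SER" else "ALA"
    build_residue(resname, resid, center, 0, 0, class)
    truth_meta[[length(truth_meta) + 1L]] <-
      data.frame(resid = resid, class = class, policy = "shell",
                 planted = FALSE, buried = FALSE, stringsAsFactors = FALSE)
  }

  env <- do.call(rbind, env_rows)
  atoms <- rbind(qm_atoms, env)
  atoms$serial <- seq_len(nrow(atoms))
  atoms$chain <- "A"
  atoms$radius <- 1.5
  atoms$element <- substr(atoms$atom_name, 1, 1)
  reactant <- new_structure(atoms)
  ts <- reactant  # rigid geometry; only QM charges differ
  ts$charge[seq_len(nrow(qm_atoms))] <- charges_TS
  reactant$charge[seq_len(nrow(qm_atoms))] <- charges_R
  qm <- qm_region(seq_len(nrow(qm_atoms)), charges_R, charges_TS,
                  site_labels)
  pair <- reaction_state_pair(reactant, ts, qm)

  # --- closed-form ground truth: explicit double loop over charge deltas
  dq <- charges_TS - charges_R
  qm_xyz <- coords(reactant)[qm$atom_indices, , drop = FALSE]
  env_keys <- setdiff(residue_keys(reactant), qm_residue_keys(pair))
  row_key <- residue_key_of_rows(reactant)
  xyz <- coords(reactant)
  truth_ddE <- vapply(env_keys, function(k) {
    idx <- which(row_key == k)
    acc <- 0
    for (j in idx) {
      for (i in seq_along(dq)) {
        if (dq[i] != 0) {
          r <- sqrt(sum((xyz[j, ] - qm_xyz[i, ])^2))
          acc <- acc + reactant$charge[j] * dq[i] / r
        }
      }
    }
    -COULOMB_K * acc
  }, numeric(1))

  meta <- do.call(rbind, truth_meta)
  info <- split_residue_key(env_keys)
  truth <- data.frame(key = env_keys, chain = info$chain, resid = info$resid,
                      resname = info$resname, ddE = unname(truth_ddE),
                      stringsAsFactors = FALSE)
  truth <- merge(truth, meta, by = "resid", all.x = TRUE, sort = FALSE)
  truth$class[is.na(truth$class)] <- "apolar"   # cage residues
  truth$policy[is.na(truth$policy)] <- "cage"
  truth$planted[is.na(truth$planted)] <- FALSE
  truth$buried[is.na(truth$buried)] <- FALSE
  truth <- truth[order(truth$chain, truth$resid), ]
  rownames(truth) <- NULL

  total_env_differential <- -sum(truth$ddE)

  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    hdr <- sprintf("toy enzyme fixture seed=%d lambda=%g", spec$seed, lambda)
    files <- list(
      reactant = file.path(out_dir, "R.pqr"),
      transition_state = file.path(out_dir, "TS.pqr"),
      qm = file.path(out_dir, "qm.json"),
      ground_truth = file.path(out_dir, "ground_truth.json")
    )
    write_pqr(reactant, files$reactant, header = hdr)
    write_pqr(ts, files$transition_state, header = hdr)
    write_qm_region(qm, files$qm)
    jsonlite::write_json(
      list(seed = spec$seed, lambda = lambda,
           total_charge = sum(reactant$charge),
           total_env_differential = total_env_differential,
           residues = truth),
      files$ground_truth, auto_unbox = TRUE, digits = NA)
  }

  list(pair = pair, truth = truth,
       total_env_differential = total_env_differential, files = files)
}

#' Generate a jittered multi-model trajectory
#'
#' Frame 1 is the reference geometry unchanged; every later frame adds
#' i.i.d. Gaussian displacement (sd `jitter_sigma`, per coordinate) to the
#' reference. A cheap stand-in for an equilibrated production run when
#' validating trajectory analyses.
#'
#' @param reference a `Structure`.
#' @param n_frames number of frames (>= 1).
#' @param jitter_sigma displacement sd in Angstrom (>= 0).
#' @param seed RNG seed.
#' @param path if non-NULL, also write the frames with [write_multimodel()].
#' @return list of `Structure` frames, invisibly when written to `path`.
#' @export
make_trajectory <- function(reference, n_frames, jitter_sigma, seed,
                            path = NULL) {
  stopifnot(is_structure(reference), n_frames >= 1, jitter_sigma >= 0)
  set.seed(seed)
  n <- nrow(reference)
  frames <- vector("list", n_frames)
  frames[[1]] <- reference
  for (f in seq_len(n_frames)[-1]) {
    fr <- reference
    disp <- matrix(stats::rnorm(3 * n, 0, jitter_sigma), ncol = 3)
    fr$x <- fr$x + disp[, 1]
    fr$y <- fr$y + disp[, 2]
    fr$z <- fr$z + disp[, 3]
    frames[[f]] <- fr
  }
  if (!is.null(path)) {
    write_multimodel(frames, path,
                     header = sprintf("jitter trajectory seed=%d sigma=%g",
                                      seed, jitter_sigma))
    return(invisible(frames))
  }
  frames
}

#' Generate a synthetic deletion energy table
#'
#' Emits wild-type and per-deletion state energies such that the noiseless
#' ledger recovers exactly the planted barrier shifts: each deletion row has
#' a random baseline reactant energy and a transition-state energy offset by
#' `wt_barrier + ddE`. With `noise_sigma > 0`, independent Gaussian noise is
#' added to every state energy (wild type included), emulating numerical
#' scatter in the single points.
#'
#' @param n_residues number of deletion rows; resids are 1..n unless named
#'   in `planted_effects`.
#' @param wt_barrier wild-type barrier (kcal/mol, default 10.6).
#' @param planted_effects named numeric vector: names are resids, values the
#'   planted ddE (kcal/mol); unnamed residues get ddE = 0.
#' @param noise_sigma sd of the per-energy Gaussian noise (kcal/mol).
#' @param seed RNG seed.
#' @param path if non-NULL, also write the table with [write_energy_csv()].
#' @return an [energy_table()] (kcal/mol).
#' @export
make_energy_table <- function(n_residues, wt_barrier = 10.6,
                              planted_effects = numeric(0),
                              noise_sigma = 0, seed = 1L, path = NULL) {
  stopifnot(n_residues >= 1, noise_sigma >= 0)
  set.seed(seed)
  planted_ids <- as.integer(names(planted_effects))
  if (anyDuplicated(planted_ids)) stop("duplicate resid in planted_effects")
  n_fill <- max(0L, n_residues - length(planted_ids))
  filler <- utils::head(setdiff(seq_len(n_residues + length(planted_ids)),
                                planted_ids), n_fill)
  resids <- sort(c(planted_ids, filler))
  ddE <- stats::setNames(rep(0, length(resids)), resids)
  ddE[as.character(planted_ids)] <- planted_effects
  base <- stats::runif(length(resids), -5, 5)
  E_R <- base
  E_TS <- base + wt_barrier + unname(ddE)
  wt <- c(E_R = 0, E_TS = wt_barrier)
  if (noise_sigma > 0) {
    wt <- wt + stats::rnorm(2, 0, noise_sigma)
    E_R <- E_R + stats::rnorm(length(E_R), 0, noise_sigma)
    E_TS <- E_TS + stats::rnorm(length(E_TS), 0, noise_sigma)
  }
  tab <- energy_table(
    wt = wt,
    rows = data.frame(chain = "A", resid = resids, resname = "ENV",
                      E_R = E_R, E_TS = E_TS, stringsAsFactors = FALSE),
    unit = "kcal/mol"
  )
  if (!is.null(path)) {
    write_energy_csv(tab, path,
                     header = sprintf("synthetic energy table seed=%d", seed))
  }
  tab
}
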
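#' @keywords internal
"_PACKAGE"

## NULL coalescing used throughout
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a structure from an atom table
#'
#' A structure is a data frame of atom records with one row per atom, in file
#' order. Atom order is the canonical identity used to match a reactant
#' against its transition state, so it is never reordered by the package.
#'
#' @param atoms data frame with columns `serial`, `atom_name`, `resname`,
#'   `chain`, `resid`, `x`, `y`, `z`, `charge`, and optionally `radius` and
#'   `element`.
#' @param model_index integer model number (1-based) for multi-model sources.
#' @return an object of class `Structure` (a data frame).
#' @export
new_structure <- function(atoms, model_index = 1L) {
  required <- c("serial", "atom_name", "resname", "chain", "resid",
                "x", "y", "z", "charge")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0L) {
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(atoms) == 0L) stop("structure must contain at least one atom")
  if (!all(is.finite(atoms$x)) || !all(is.finite(atoms$y)) ||
      !all(is.finite(atoms$z))) {
    stop("non-finite coordinates in atom table")
  }
  if (!all(is.finite(atoms$charge))) stop("non-finite charges in atom table")
  key <- paste(atoms$chain, atoms$resid, atoms$atom_name, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    stop("duplicate (chain, resid, atom_name) record: ",
         gsub("\r", "/", dup, fixed = TRUE))
  }
  if (is.null(atoms$radius)) atoms$radius <- NA_real_
  if (is.null(atoms$element)) atoms$element <- NA_character_
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  rownames(atoms) <- NULL
  attr(atoms, "model_index") <- as.integer(model_index)
  class(atoms) <- c("Structure", "data.frame")
  atoms
}

is_structure <- function(x) inherits(x, "Structure")

#' @export
print.Structure <- function(x, ...) {
  cat(sprintf("Structure: %d atoms, %d residues, total charge %+.4f e\n",
              nrow(x), length(unique(paste(x$chain, x$resid))),
              sum(x$charge)))
  invisible(x)
}

#' Coordinates of a structure as an n x 3 matrix
#' @param structure a `Structure`.
#' @return numeric matrix with columns x, y, z.
#' @export
coords <- function(structure) {
  as.matrix(structure[, c("x", "y", "z")])
}

#' Residue keys of a structure
#'
#' Residues are identified by `(chain, resid, resname)` in author numbering,
#' rendered as `"chain:resid:resname"` (empty chain allowed). Order follows
#' ascending chain then resid.
#'
#' @param structure a `Structure`.
#' @return character vector of unique residue keys.
#' @export
residue_keys <- function(structure) {
  u <- unique(structure[, c("chain", "resid", "resname")])
  u <- u[order(u$chain, u$resid), , drop = FALSE]
  paste(u$chain, u$resid, u$resname, sep = ":")
}

residue_key_of_rows <- function(structure) {
  paste(structure$chain, structure$resid, structure$resname, sep = ":")
}

split_residue_key <- function(key) {
  parts <- strsplit(key, ":", fixed = TRUE)
  data.frame(
    chain   = vapply(parts, `[`, "", 1L),
    resid   = as.integer(vapply(parts, `[`, "", 2L)),
    resname = vapply(parts, `[`, "", 3L),
    stringsAsFactors = FALSE
  )
}

#' Row indices of a residue's atoms
#' @param structure a `Structure`.
#' @param key residue key `"chain:resid:resname"`.
#' @return integer vector of row indices; error if the residue is absent.
#' @export
residue_atoms <- function(structure, key) {
  idx <- which(residue_key_of_rows(structure) == key)
  if (length(idx) == 0L) stop("residue not found: ", key)
  idx
}

# ---------------------------------------------------------------------------
# PQR / multi-model parsing.  Whitespace-delimited PQR dialect:
#   ATOM serial name resname [chain] resid x y z charge radius
# The chain column is optional (both common dialects); detection is by field
# count and by whether field 5 parses as an integer.

parse_atom_line <- function(line, lineno) {
  fields <- strsplit(trimws(line), "[[:space:]]+")[[1]]
  n <- length(fields)
  if (n < 10L) {
    stop(sprintf("malformed ATOM/HETATM record at line %d: expected >= 10 fields, got %d",
                 lineno, n))
  }
  # fields: 1 rec, 2 serial, 3 name, 4 resname, [5 chain], resid, x, y, z, q, r
  has_chain <- n >= 11L && is.na(suppressWarnings(as.numeric(fields[5])))
  off <- if (has_chain) 1L else 0L
  num <- suppressWarnings(as.numeric(fields[(5L + off):(10L + off)]))
  if (anyNA(num)) {
    stop(sprintf("malformed numeric field in ATOM/HETATM record at line %d", lineno))
  }
  list(
    serial    = as.integer(suppressWarnings(as.numeric(fields[2]))),
    atom_name = fields[3],
    resname   = fields[4],
    chain     = if (has_chain) fields[5] else "",
    resid     = as.integer(num[1]),
    x = num[2], y = num[3], z = num[4],
    charge = num[5], radius = num[6]
  )
}

parse_atom_block <- function(lines, linenos, model_index = 1L) {
  recs <- mapply(parse_atom_line, lines, linenos, SIMPLIFY = FALSE)
  atoms <- do.call(rbind, lapply(recs, as.data.frame,
                                 stringsAsFactors = FALSE))
  new_structure(atoms, model_index = model_index)
}

#' Read a PQR file
#'
#' Reads all ATOM/HETATM records of a whitespace-delimited PQR file in file
#' order, with per-atom partial charge (e) and radius (Angstrom). The chain
#' column is optional; when absent the chain is `""`.
#'
#' @param path path to the PQR file.
#' @return a [new_structure()] `Structure`.
#' @export
read_pqr <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  sel <- grepl("^(ATOM|HETATM)", lines)
  if (!any(sel)) stop("no ATOM/HETATM records in ", path)
  parse_atom_block(lines[sel], which(sel))
}

format_atom_line <- function(a) {
  if (nzchar(a$chain)) {
    sprintf("ATOM  %6d %-4s %-4s %-2s %5d %11.4f %11.4f %11.4f %9.4f %7.4f",
            a$serial, a$atom_name, a$resname, a$chain,
            a$resid, a$x, a$y, a$z, a$charge,
            ifelse(is.na(a$radius), 0, a$radius))
  } else {
    sprintf("ATOM  %6d %-4s %-4s %5d %11.4f %11.4f %11.4f %9.4f %7.4f",
            a$serial, a$atom_name, a$resname,
            a$resid, a$x, a$y, a$z, a$charge,
            ifelse(is.na(a$radius), 0, a$radius))
  }
}

#' Write a structure as PQR
#'
#' Writes whitespace-delimited PQR; atoms with an empty chain are written in
#' the chain-less dialect, so read/write round trips preserve the chain field
#' in both dialects.
#'
#' @param structure a `Structure`.
#' @param path output path.
#' @param header optional character vector of REMARK lines (without prefix).
#' @return `path`, invisibly.
#' @export
write_pqr <- function(structure, path, header = NULL) {
  out <- character(0)
  if (!is.null(header)) out <- paste("REMARK", header)
  out <- c(out, vapply(seq_len(nrow(structure)), function(i) {
    format_atom_line(structure[i, ])
  }, ""), "END")
  writeLines(out, path)
  invisible(path)
}

#' Read a multi-model PDB/PQR trajectory
#'
#' Accepts files with MODEL/ENDMDL blocks or a single-model file. All models
#' must carry identical `(chain, resid, atom_name)` sequences.
#'
#' @param path path to the file.
#' @return list of `Structure`, one per model, in file order.
#' @export
read_multimodel <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^MODEL", lines)
  if (length(starts) == 0L) return(list(read_pqr(path)))
  ends <- grep("^ENDMDL", lines)
  if (length(ends) != length(starts)) {
    stop("unbalanced MODEL/ENDMDL blocks in ", path)
  }
  models <- vector("list", length(starts))
  for (m in seq_along(starts)) {
    block <- seq(starts[m] + 1L, ends[m] - 1L)
    sel <- block[grepl("^(ATOM|HETATM)", lines[block])]
    if (length(sel) == 0L) stop("MODEL block ", m, " has no atoms in ", path)
    models[[m]] <- parse_atom_block(lines[sel], sel, model_index = m)
  }
  ref <- paste(models[[1]]$chain, models[[1]]$resid, models[[1]]$atom_name)
  for (m in seq_along(models)[-1]) {
    cur <- paste(models[[m]]$chain, models[[m]]$resid, models[[m]]$atom_name)
    if (length(cur) != length(ref) || any(cur != ref)) {
      stop("model ", m, " atom sequence differs from model 1 in ", path)
    }
  }
  models
}

#' Write structures as a multi-model PDB-like trajectory
#'
#' Each frame is written as a MODEL/ENDMDL block of whitespace-delimited
#' ATOM records (same dialect as [write_pqr()]).
#'
#' @param structures list of `Structure` with identical atom sequences.
#' @param path output path.
#' @param header optional REMARK lines.
#' @return `path`, invisibly.
#' @export
write_multimodel <- function(structures, path, header = NULL) {
  out <- character(0)
  if (!is.null(header)) out <- paste("REMARK", header)
  for (m in seq_along(structures)) {
    s <- structures[[m]]
    out <- c(out, sprintf("MODEL %8d", m),
             vapply(seq_len(nrow(s)), function(i) format_atom_line(s[i, ]), ""),
             "ENDMDL")
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}

#' Attach charges from a sidecar table to a charge-less structure
#'
#' Multi-model PDB files carry no charges; a CSV with columns
#' `chain,resid,atom_name,charge` supplies them.
#'
#' @param structure a `Structure`.
#' @param charge_csv path to the sidecar CSV.
#' @return the structure with its `charge` column replaced.
#' @export
attach_charges <- function(structure, charge_csv) {
  tab <- utils::read.csv(charge_csv, stringsAsFactors = FALSE)
  need <- c("chain", "resid", "atom_name", "charge")
  if (!all(need %in% names(tab))) {
    stop("charge table must have columns: ", paste(need, collapse = ", "))
  }
  key_s <- paste(structure$chain, structure$resid, structure$atom_name,
                 sep = "\r")
  key_t <- paste(tab$chain, tab$resid, tab$atom_name, sep = "\r")
  idx <- match(key_s, key_t)
  if (anyNA(idx)) {
    stop("charge table missing atom: ",
         gsub("\r", "/", key_s[which(is.na(idx))[1]], fixed = TRUE))
  }
  structure$charge <- tab$charge[idx]
  structure
}

# ---------------------------------------------------------------------------
# QM region and reactant/transition-state pairing

#' Define the QM region of a reaction-state pair
#'
#' The QM region is the set of atoms whose charges differ between the
#' reactant and the transition state (the quantum core in the embedding
#' picture). Total charge must be conserved between states: the modelled
#' event is an internal proton transfer.
#'
#' @param atom_indices integer row indices into the structures' atom tables.
#' @param charges_R,charges_TS per-state partial charges (e), aligned with
#'   `atom_indices`.
#' @param site_labels optional character vector aligned with `atom_indices`
#'   with values `"donor_site"`, `"acceptor_site"`, or `"other"`.
#' @return an object of class `qm_region`.
#' @export
qm_region <- function(atom_indices, charges_R, charges_TS,
                      site_labels = NULL) {
  atom_indices <- as.integer(atom_indices)
  if (length(atom_indices) == 0L) stop("QM region must contain atoms")
  if (anyDuplicated(atom_indices)) stop("duplicate QM atom indices")
  if (length(charges_R) != length(atom_indices) ||
      length(charges_TS) != length(atom_indices)) {
    stop("charges_R/charges_TS must align with atom_indices")
  }
  if (abs(sum(charges_R) - sum(charges_TS)) > 1e-10) {
    stop("QM total charge not conserved between R and TS (|drift| > 1e-10 e)")
  }
  if (is.null(site_labels)) site_labels <- rep("other", length(atom_indices))
  structure(
    list(atom_indices = atom_indices,
         charges_R = as.numeric(charges_R),
         charges_TS = as.numeric(charges_TS),
         site_labels = site_labels),
    class = "qm_region"
  )
}

#' Pair a reactant with its transition state
#'
#' Both structures must have identical atom counts and identical
#' `(chain, resid, atom_name)` sequences; atom order is the identity used to
#' match them.
#'
#' @param reactant,transition_state `Structure` objects.
#' @param qm a [qm_region()].
#' @return an object of class `reaction_state_pair`.
#' @export
reaction_state_pair <- function(reactant, transition_state, qm) {
  stopifnot(is_structure(reactant), is_structure(transition_state),
            inherits(qm, "qm_region"))
  if (nrow(reactant) != nrow(transition_state)) {
    stop("reactant and transition state differ in atom count")
  }
  kr <- paste(reactant$chain, reactant$resid, reactant$atom_name)
  kt <- paste(transition_state$chain, transition_state$resid,
              transition_state$atom_name)
  if (any(kr != kt)) {
    stop("reactant and transition state atom sequences differ (first at atom ",
         which(kr != kt)[1], ")")
  }
  if (any(qm$atom_indices < 1L) || any(qm$atom_indices > nrow(reactant))) {
    stop("QM atom index out of range")
  }
  structure(list(reactant = reactant, transition_state = transition_state,
                 qm = qm),
            class = "reaction_state_pair")
}

#' Read a QM-region definition from JSON
#'
#' @param path JSON with fields `atom_indices` (1-based), `charges_R`,
#'   `charges_TS`, optional `site_labels`.
#' @return a [qm_region()].
#' @export
read_qm_region <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  qm_region(j$atom_indices, j$charges_R, j$charges_TS,
            site_labels = j$site_labels %||% NULL)
}

#' Write a QM-region definition to JSON
#' @param qm a [qm_region()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_qm_region <- function(qm, path) {
  jsonlite::write_json(unclass(qm), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

# residue keys (chain:resid:resname) spanned by QM atom indices
qm_residue_keys <- function(pair) {
  unique(residue_key_of_rows(pair$reactant)[pair$qm$atom_indices])
}

#' Select deletion-eligible environment residues
#'
#' A residue is eligible for the deletion scan when the minimum distance from
#' any of its atoms (hydrogens included) to any QM-region atom, measured on
#' the reactant structure, is at most `radius`; Gly and Pro are excluded (no
#' charged or freely mutable side chain), as are residues overlapping the QM
#' region and any explicitly excluded keys.
#'
#' @param pair a [reaction_state_pair()].
#' @param radius eligibility radius in Angstrom (default 10).
#' @param excluded_resnames residue names never scanned (default GLY, PRO).
#' @param excluded_ids character vector of residue keys to drop.
#' @return character vector of residue keys, ascending by chain then resid.
#' @export
select_eligible_residues <- function(pair, radius = 10.0,
                                     excluded_resnames = c("GLY", "PRO"),
                                     excluded_ids = character(0)) {
  stopifnot(inherits(pair, "reaction_state_pair"))
  if (!is.numeric(radius) || radius <= 0) stop("radius must be > 0")
  if (length(pair$qm$atom_indices) == 0L) stop("empty QM region")
  s <- pair$reactant
  qm_xyz <- coords(s)[pair$qm$atom_indices, , drop = FALSE]
  keys <- residue_keys(s)
  keys <- setdiff(keys, qm_residue_keys(pair))
  info <- split_residue_key(keys)
  keep <- !(info$resname %in% excluded_resnames) & !(keys %in% excluded_ids)
  keys <- keys[keep]
  row_key <- residue_key_of_rows(s)
  xyz <- coords(s)
  eligible <- vapply(keys, function(k) {
    res_xyz <- xyz[row_key == k, , drop = FALSE]
    min_pair_distance(res_xyz, qm_xyz) <= radius
  }, logical(1))
  keys[eligible]
}

# minimum Euclidean distance between two coordinate sets
min_pair_distance <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
  sqrt(max(0, min(d2)))
}
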
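# ---------------------------------------------------------------------------
# Mutation advisor: turn a deletion scan into ranked, filtered candidates
# with charge-cancelling substitution suggestions.

STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL")

# side-chain charged-group heavy atoms for the standard charged types
CHARGED_GROUP_ATOMS <- list(
  ASP = c("CG", "OD1", "OD2"),
  GLU = c("CD", "OE1", "OE2"),
  LYS = c("NZ"),
  ARG = c("CZ", "NE", "NH1", "NH2"),
  HIS = c("ND1", "NE2")
)

#' Advisor configuration
#'
#' @param threshold candidacy threshold (kcal/mol, strict): a candidate must
#'   have ddE < -threshold. Default 1.0.
#' @param excluded_residues residue keys never proposed (catalytic or
#'   otherwise mechanistically required residues). Keys as
#'   `"chain:resid:resname"`.
#' @param mutation_map named character vector mapping charged residue types
#'   to neutral polar substitutions. Defaults: Glu->Gln, Asp->Asn, Lys->Gln,
#'   and the fallback Arg->Gln, His->Gln for charged types without a
#'   conventional charge-cancelling partner.
#' @param neighbor_radius exposure probe radius (Angstrom, default 8).
#' @param max_heavy_neighbors a charged group with at most this many heavy
#'   atoms of other residues within `neighbor_radius` of its centroid counts
#'   as solvent-exposed (default 16).
#' @param hbond_cutoff donor-acceptor distance cutoff (Angstrom, default
#'   3.5): any polar heavy atom of another residue within this distance of a
#'   charged-group atom marks the group as hydrogen-bonded.
#' @return a list of class `advisor_config`.
#' @export
advisor_config <- function(threshold = 1.0,
                           excluded_residues = character(0),
                           mutation_map = c(GLU = "GLN", ASP = "ASN",
                                            LYS = "GLN", ARG = "GLN",
                                            HIS = "GLN"),
                           neighbor_radius = 8.0,
                           max_heavy_neighbors = 16L,
                           hbond_cutoff = 3.5) {
  if (threshold <= 0) stop("threshold must be > 0")
  structure(list(threshold = threshold,
                 excluded_residues = excluded_residues,
                 mutation_map = mutation_map,
                 neighbor_radius = neighbor_radius,
                 max_heavy_neighbors = as.integer(max_heavy_neighbors),
                 hbond_cutoff = hbond_cutoff),
            class = "advisor_config")
}

#' Read an advisor configuration from JSON
#' @param path JSON object with any subset of the [advisor_config()] fields.
#' @return an `advisor_config`.
#' @export
read_advisor_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  defaults <- advisor_config()
  for (f in names(j)) {
    if (!f %in% names(defaults)) stop("unknown advisor config field: ", f)
    defaults[[f]] <- if (f == "mutation_map") unlist(j[[f]]) else j[[f]]
  }
  do.call(advisor_config, unclass(defaults))
}

# formal side-chain charge class of a residue: by name for the standard
# charged types; His counts as charged only when its recorded charges sum to
# a nonzero integer (protonated form)
is_charged_type <- function(resname, charge_sum = 0) {
  if (resname %in% c("ASP", "GLU", "LYS", "ARG")) return(TRUE)
  if (resname == "HIS") return(round(charge_sum) != 0)
  FALSE
}

#' Suggest a charge-cancelling substitution
#'
#' Maps a charged residue type to a neutral polar type that preserves side-
#' chain size and hydrogen-bonding character as far as possible (Glu->Gln,
#' Asp->Asn, Lys->Gln); charged types without a conventional partner fall
#' back to the configured default (Arg->Gln). Neutral input types need no
#' change.
#'
#' @param residue_type standard 3-letter code.
#' @param config an [advisor_config()].
#' @return the suggested 3-letter type, or `"none"` for neutral input.
#' @export
suggest_mutation <- function(residue_type, config = advisor_config()) {
  if (!residue_type %in% STANDARD_AA) {
    stop("unknown residue type: ", residue_type)
  }
  if (residue_type %in% names(config$mutation_map)) {
    return(unname(config$mutation_map[[residue_type]]))
  }
  "none"
}

# heavy-atom mask (no element column needed: PDB/PQR convention, hydrogens
# start with H after any leading digit)
is_heavy <- function(atom_name) {
  !grepl("^[0-9]*H", atom_name)
}

is_polar_heavy <- function(atom_name) {
  is_heavy(atom_name) & grepl("^[0-9]*[NO]", atom_name)
}

# atoms forming the residue's charged group: the named side-chain set when
# present, else the residue's non-zero-charge heavy atoms, else all its
# heavy atoms
charged_group_idx <- function(structure, key) {
  idx <- residue_atoms(structure, key)
  resname <- structure$resname[idx[1]]
  named <- CHARGED_GROUP_ATOMS[[resname]]
  if (!is.null(named)) {
    hit <- idx[structure$atom_name[idx] %in% named]
    if (length(hit) > 0L) return(hit)
  }
  hv <- idx[is_heavy(structure$atom_name[idx])]
  qh <- hv[abs(structure$charge[hv]) >= 0.25]
  if (length(qh) > 0L) return(qh)
  if (length(hv) > 0L) return(hv)
  stop("residue has no heavy atoms to define a charged group: ", key)
}

#' Solvent-exposure proxy for a residue's charged group
#'
#' Counts heavy atoms of other residues within `neighbor_radius` of the
#' charged-group centroid; the group is exposed when the count does not
#' exceed `max_heavy_neighbors`. A geometric stand-in for solvent
#' accessibility: surface charged groups see few protein neighbors.
#'
#' @param structure a `Structure`.
#' @param key residue key.
#' @param config an [advisor_config()].
#' @return list with `exposed` (logical) and `n_neighbors`.
#' @export
is_exposed <- function(structure, key, config = advisor_config()) {
  grp <- charged_group_idx(structure, key)
  if (structure$resname[grp[1]] == "GLY") {
    stop("residue lacks a side chain: ", key)
  }
  centroid <- colMeans(coords(structure)[grp, , drop = FALSE])
  others <- setdiff(which(is_heavy(structure$atom_name)),
                    residue_atoms(structure, key))
  if (length(others) == 0L) {
    return(list(exposed = TRUE, n_neighbors = 0L))
  }
  d <- sqrt(colSums((t(coords(structure)[others, , drop = FALSE]) -
                       centroid)^2))
  n <- sum(d <= config$neighbor_radius)
  list(exposed = n <= config$max_heavy_neighbors, n_neighbors = as.integer(n))
}

#' Hydrogen-bond freedom of a residue's charged group
#'
#' The group is hydrogen-bond free when no polar heavy atom (N/O) of another
#' residue lies within `hbond_cutoff` of any charged-group atom.
#'
#' @inheritParams is_exposed
#' @return list with `hbond_free` (logical) and `n_contacts`.
#' @export
is_hbond_free <- function(structure, key, config = advisor_config()) {
  grp <- charged_group_idx(structure, key)
  others <- setdiff(which(is_polar_heavy(structure$atom_name)),
                    residue_atoms(structure, key))
  if (length(others) == 0L) {
    return(list(hbond_free = TRUE, n_contacts = 0L))
  }
  grp_xyz <- coords(structure)[grp, , drop = FALSE]
  oth_xyz <- coords(structure)[others, , drop = FALSE]
  d2 <- outer(rowSums(grp_xyz^2), rowSums(oth_xyz^2), `+`) -
    2 * tcrossprod(grp_xyz, oth_xyz)
  n <- sum(apply(d2, 2, min) <= config$hbond_cutoff^2)
  list(hbond_free = n == 0L, n_contacts = as.integer(n))
}

#' Build a mutation-candidate report from a deletion scan
#'
#' A residue becomes a candidate when (i) its barrier shift satisfies
#' ddE < -threshold strictly, (ii) it is a charged type, and (iii) it is not
#' on the exclusion list. Large-effect residues failing (ii) or (iii) are
#' reported separately with the reason, so mechanistically required or
#' neutral residues with strong anticatalytic signals remain visible without
#' being proposed. Exposure and hydrogen-bond freedom are annotations, not
#' filters: raw neighbor/contact counts are always reported.
#'
#' @param scan a [deletion_scan()] or [compute_barriers()] result.
#' @param structure the reactant `Structure` (for geometry annotations).
#' @param config an [advisor_config()].
#' @return object of class `candidate_report`: list with `candidates`,
#'   `ineligible` (both data frames, ascending ddE), and `provenance`.
#' @export
build_report <- function(scan, structure, config = advisor_config()) {
  if (nrow(scan) == 0L) stop("scan is empty")
  keys <- paste(scan$chain, scan$resid, scan$resname, sep = ":")
  present <- keys %in% residue_keys(structure)
  if (!all(present)) {
    stop("scan residue absent from structure: ", keys[!present][1])
  }
  rows <- lapply(seq_len(nrow(scan)), function(i) {
    key <- keys[i]
    idx <- residue_atoms(structure, key)
    charge_sum <- sum(structure$charge[idx])
    charged <- is_charged_type(scan$resname[i], charge_sum)
    reason <- NULL
    if (!(scan$ddE[i] < -config$threshold)) {
      reason <- "below threshold"
    } else if (!charged) {
      reason <- "not a charged residue type"
    } else if (key %in% config$excluded_residues) {
      reason <- "on exclusion list (mechanistically required)"
    }
    exp <- tryCatch(is_exposed(structure, key, config),
                    error = function(e) list(exposed = NA, n_neighbors = NA))
    hb <- is_hbond_free(structure, key, config)
    data.frame(
      chain = scan$chain[i], resid = scan$resid[i],
      resname = scan$resname[i], ddE = scan$ddE[i],
      effect_class = scan$effect_class[i],
      suggested_mutation = if (charged) {
        suggest_mutation(scan$resname[i], config)
      } else "none",
      exposed = exp$exposed, n_neighbors = exp$n_neighbors,
      hbond_free = hb$hbond_free, n_polar_contacts = hb$n_contacts,
      excluded_reason = if (is.null(reason)) NA_character_ else reason,
      stringsAsFactors = FALSE)
  })
  all_rows <- do.call(rbind, rows)
  all_rows <- all_rows[order(all_rows$ddE,
                             paste(all_rows$chain, all_rows$resid)), ]
  rownames(all_rows) <- NULL
  candidates <- all_rows[is.na(all_rows$excluded_reason), , drop = FALSE]
  ineligible <- all_rows[!is.na(all_rows$excluded_reason) &
                           all_rows$ddE < -config$threshold, , drop = FALSE]
  rownames(candidates) <- rownames(ineligible) <- NULL
  structure(
    list(candidates = candidates, ineligible = ineligible,
         provenance = list(
           n_scanned = nrow(scan),
           threshold = config$threshold,
           config_hash = rlang::hash(unclass(config)),
           version = as.character(utils::packageVersion("dipolescan")))),
    class = "candidate_report")
}

#' @export
print.candidate_report <- function(x, ...) {
  cat(sprintf("Mutation-candidate report (%d scanned, threshold %.1f kcal/mol, config %s)\n",
              x$provenance$n_scanned, x$provenance$threshold,
              x$provenance$config_hash))
  if (nrow(x$candidates) == 0L) {
    cat("No candidates.\n")
  } else {
    cat("Candidates (ascending ddE):\n")
    for (i in seq_len(nrow(x$candidates))) {
      r <- x$candidates[i, ]
      cat(sprintf("  %s%d (%s) ddE %.1f kcal/mol -> %s%s%s\n",
                  r$resname, r$resid, r$chain, r$ddE, r$suggested_mutation,
                  if (isTRUE(r$exposed)) ", exposed" else ", buried",
                  if (isTRUE(r$hbond_free)) ", H-bond free" else ""))
    }
  }
  if (nrow(x$ineligible) > 0L) {
    cat("Large-effect residues not proposed:\n")
    for (i in seq_len(nrow(x$ineligible))) {
      r <- x$ineligible[i, ]
      cat(sprintf("  %s%d (%s) ddE %.1f kcal/mol: %s\n",
                  r$resname, r$resid, r$chain, r$ddE, r$excluded_reason))
    }
  }
  invisible(x)
}

#' Write a candidate report as TSV
#'
#' Two sections concatenated with a `section` column (`candidate` /
#' `ineligible`); full precision.
#'
#' @param report a [build_report()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(report, path) {
  stopifnot(inherits(report, "candidate_report"))
  out <- rbind(
    if (nrow(report$candidates) > 0L) {
      cbind(section = "candidate", report$candidates)
    },
    if (nrow(report$ineligible) > 0L) {
      cbind(section = "ineligible", report$ineligible)
    })
  if (is.null(out)) {
    out <- data.frame(section = character(0))
  }
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) sprintf("%.17g", v))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
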
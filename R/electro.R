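# Coulomb constant in kcal * Angstrom / (mol * e^2)
COULOMB_K <- 332.0637

# hartree -> kcal/mol
HARTREE_KCAL <- 627.509474

#' Coulomb interaction energy between two charge groups
#'
#' Vacuum point-charge Coulomb energy
#' \deqn{V = \frac{k}{\varepsilon} \sum_{i \in A}\sum_{j \in B} q_i q_j / r_{ij}}
#' with k = 332.0637 kcal A mol^-1 e^-2. No distance cutoff and no
#' periodicity: the surrogate mirrors the embedding-field character of
#' electrostatic embedding, where every MM point charge polarises the QM
#' region regardless of distance.
#'
#' @param xyz_a,xyz_b n x 3 coordinate matrices (Angstrom).
#' @param q_a,q_b charge vectors (e), aligned with the rows.
#' @param eps uniform relative dielectric constant (default 1, vacuum).
#' @return energy in kcal/mol; exactly 0 when either group is all-zero charge.
#' @export
coulomb <- function(xyz_a, q_a, xyz_b, q_b, eps = 1) {
  xyz_a <- as.matrix(xyz_a); xyz_b <- as.matrix(xyz_b)
  stopifnot(ncol(xyz_a) == 3L, ncol(xyz_b) == 3L,
            nrow(xyz_a) == length(q_a), nrow(xyz_b) == length(q_b))
  if (eps <= 0) stop("dielectric constant must be > 0")
  d2 <- outer(rowSums(xyz_a^2), rowSums(xyz_b^2), `+`) -
    2 * tcrossprod(xyz_a, xyz_b)
  d2[d2 < 0] <- 0
  if (any(d2 < 1e-12)) {  # (1e-6 A)^2
    bad <- which(d2 < 1e-12, arr.ind = TRUE)[1, ]
    stop(sprintf("overlapping atoms: group A atom %d and group B atom %d at distance %.2e A",
                 bad[1], bad[2], sqrt(d2[bad[1], bad[2]])))
  }
  if (all(q_a == 0) || all(q_b == 0)) return(0)
  (COULOMB_K / eps) * sum(tcrossprod(q_a, q_b) / sqrt(d2))
}

#' Residue-QM interaction energy in both states
#'
#' Computes the Coulomb interaction between one environment residue's point
#' charges and the QM charge distribution: `V_R` uses reactant coordinates
#' with the reactant QM charges, `V_TS` uses transition-state coordinates
#' with the transition-state QM charges. Environment charges are taken from
#' the structure records and are identical in both states under the rigid
#' environment assumption.
#'
#' @param pair a [reaction_state_pair()].
#' @param key residue key `"chain:resid:resname"`; must be disjoint from the
#'   QM region.
#' @param eps uniform dielectric constant (default 1).
#' @return list with `key`, `V_R`, `V_TS` (kcal/mol).
#' @export
state_interaction <- function(pair, key, eps = 1) {
  stopifnot(inherits(pair, "reaction_state_pair"))
  if (key %in% qm_residue_keys(pair)) {
    stop("residue overlaps the QM region: ", key)
  }
  idx <- residue_atoms(pair$reactant, key)
  qm_idx <- pair$qm$atom_indices
  if (length(intersect(idx, qm_idx)) > 0L) {
    stop("residue atoms overlap QM atom indices: ", key)
  }
  xr <- coords(pair$reactant)
  xt <- coords(pair$transition_state)
  q_res <- pair$reactant$charge[idx]
  list(
    key = key,
    V_R = coulomb(xr[idx, , drop = FALSE], q_res,
                  xr[qm_idx, , drop = FALSE], pair$qm$charges_R, eps = eps),
    V_TS = coulomb(xt[idx, , drop = FALSE], q_res,
                   xt[qm_idx, , drop = FALSE], pair$qm$charges_TS, eps = eps)
  )
}

classify_effect <- function(ddE, threshold) {
  ifelse(ddE < -threshold, "anticatalytic",
         ifelse(ddE > threshold, "procatalytic", "neutral"))
}

#' Per-residue deletion scan
#'
#' The computational mutagenesis ledger: for each eligible environment
#' residue m, deleting it from the embedding removes its interaction with the
#' QM charge distribution in both states, so the barrier shift is
#' \deqn{\Delta\Delta E_m = -(V_{TS}(m) - V_R(m))}
#' and the deleted-residue barrier is
#' \deqn{\Delta E_m = \Delta E_{wt} + \Delta\Delta E_m.}
#' A residue with \eqn{\Delta\Delta E_m < -threshold} is anticatalytic (it
#' stabilises the reactant more than the transition state; its charge-
#' cancelling mutation is predicted rate-enhancing), one with
#' \eqn{\Delta\Delta E_m > +threshold} procatalytic, otherwise neutral.
#' Comparisons are strict.
#'
#' @param pair a [reaction_state_pair()].
#' @param dE_wt wild-type barrier in kcal/mol. The surrogate carries no QM
#'   core energy, so the wild-type barrier is an input; the default 10.6 is
#'   the reference wild-type activation energy of the modelled system.
#' @param eligible residue keys to scan; see [select_eligible_residues()].
#' @param threshold classification threshold in kcal/mol (default 1.0).
#' @param eps uniform dielectric constant (default 1).
#' @return data frame with columns `chain`, `resid`, `resname`, `V_R`,
#'   `V_TS`, `dE_m`, `ddE`, `effect_class`, sorted ascending by `ddE` (ties
#'   by residue key).
#' @export
deletion_scan <- function(pair, dE_wt = 10.6, eligible, threshold = 1.0,
                          eps = 1) {
  if (missing(eligible) || length(eligible) == 0L) {
    stop("eligible residue list must be non-empty")
  }
  if (threshold <= 0) stop("threshold must be > 0")
  rows <- lapply(eligible, function(k) {
    v <- state_interaction(pair, k, eps = eps)
    data.frame(key = k, V_R = v$V_R, V_TS = v$V_TS,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  # dE_m first, then ddE = dE_m - dE_wt: the same floating-point path the
  # ledger takes, so exporting the scan as an energy table round-trips
  # bitwise through compute_barriers()
  res$dE_m <- dE_wt + (res$V_R - res$V_TS)
  res$ddE <- res$dE_m - dE_wt
  res$effect_class <- classify_effect(res$ddE, threshold)
  info <- split_residue_key(res$key)
  out <- data.frame(chain = info$chain, resid = info$resid,
                    resname = info$resname,
                    V_R = res$V_R, V_TS = res$V_TS,
                    dE_m = res$dE_m, ddE = res$ddE,
                    effect_class = res$effect_class,
                    stringsAsFactors = FALSE)
  out <- out[order(out$ddE, res$key), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dE_wt") <- dE_wt
  attr(out, "threshold") <- threshold
  class(out) <- c("deletion_scan", "data.frame")
  out
}

#' Write a deletion scan (or ledger result) as TSV
#'
#' Full machine precision; human-readable reports round to 0.1 kcal/mol but
#' the machine output never does.
#'
#' @param scan data frame from [deletion_scan()] or [compute_barriers()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scan_tsv <- function(scan, path) {
  df <- as.data.frame(scan)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a deletion scan TSV
#' @param path TSV written by [write_scan_tsv()].
#' @return data frame with the scan columns.
#' @export
read_scan_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE,
                    colClasses = c(chain = "character"))
}

#' Export a surrogate scan as an energy table
#'
#' Rewrites the scan as wild-type and per-deletion state energies so the
#' ledger ([compute_barriers()]) can reproduce the scan exactly: the
#' wild-type row is (0, dE_wt) and each deletion row is (0, dE_m).
#'
#' @param scan a [deletion_scan()] result.
#' @return an `energy_table` (see [energy_table()]).
#' @export
scan_as_energy_table <- function(scan) {
  stopifnot(inherits(scan, "deletion_scan"))
  dE_wt <- attr(scan, "dE_wt")
  energy_table(
    wt = c(E_R = 0, E_TS = dE_wt),
    rows = data.frame(chain = scan$chain, resid = scan$resid,
                      resname = scan$resname,
                      E_R = 0, E_TS = scan$dE_m,
                      stringsAsFactors = FALSE),
    unit = "kcal/mol"
  )
}
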
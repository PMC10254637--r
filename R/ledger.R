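#' Construct an energy table
#'
#' Wild-type and per-deletion state energies feeding the barrier ledger.
#' Energies may come from real QM/MM deletion single points (exported to CSV)
#' or from the surrogate scan / synthetic generator.
#'
#' @param wt named numeric `c(E_R=, E_TS=)`, the wild-type state energies.
#' @param rows data frame with columns `chain`, `resid`, `resname`, `E_R`,
#'   `E_TS`: one row per residue deletion.
#' @param unit `"kcal/mol"` or `"hartree"`; hartree values are converted with
#'   627.509474 kcal/mol per hartree. Any other unit requires `scale`.
#' @param scale optional explicit factor to kcal/mol (overrides `unit`).
#' @return an object of class `energy_table`.
#' @export
energy_table <- function(wt, rows, unit = "kcal/mol", scale = NULL) {
  if (is.null(scale)) {
    scale <- switch(unit,
                    "kcal/mol" = 1,
                    "kcal" = 1,
                    "hartree" = HARTREE_KCAL,
                    stop("unknown unit '", unit, "'; give scale= explicitly"))
  }
  if (!is.numeric(scale) || scale <= 0) stop("unit scale must be > 0")
  if (!all(c("E_R", "E_TS") %in% names(wt))) {
    stop("wt must have named elements E_R and E_TS")
  }
  need <- c("chain", "resid", "resname", "E_R", "E_TS")
  if (!all(need %in% names(rows))) {
    stop("rows must have columns: ", paste(need, collapse = ", "))
  }
  key <- paste(rows$chain, rows$resid, rows$resname, sep = ":")
  if (anyDuplicated(key)) {
    stop("duplicate residue key in energy table: ", key[duplicated(key)][1])
  }
  if (!all(is.finite(c(wt[["E_R"]], wt[["E_TS"]], rows$E_R, rows$E_TS)))) {
    stop("non-finite energies in table")
  }
  structure(list(wt = c(E_R = unname(wt[["E_R"]]), E_TS = unname(wt[["E_TS"]])),
                 rows = as.data.frame(rows, stringsAsFactors = FALSE),
                 scale = scale, unit = unit),
            class = "energy_table")
}

#' Read an energy table from CSV
#'
#' Expected dialect: comma-separated with header
#' `kind,chain,resid,resname,E_R,E_TS`, exactly one `kind=wildtype` row
#' (chain/resid/resname ignored there) and one `kind=deletion` row per
#' residue.
#'
#' @param path CSV path.
#' @param unit,scale see [energy_table()].
#' @return an `energy_table`.
#' @export
read_energy_csv <- function(path, unit = "kcal/mol", scale = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(chain = "character"),
                         comment.char = "#")
  need <- c("kind", "chain", "resid", "resname", "E_R", "E_TS")
  if (!all(need %in% names(tab))) {
    stop("energy CSV must have columns: ", paste(need, collapse = ", "))
  }
  wt_rows <- tab$kind == "wildtype"
  if (sum(wt_rows) != 1L) {
    stop("energy CSV must contain exactly one kind=wildtype row, found ",
         sum(wt_rows))
  }
  energy_table(
    wt = c(E_R = tab$E_R[wt_rows], E_TS = tab$E_TS[wt_rows]),
    rows = tab[tab$kind == "deletion",
               c("chain", "resid", "resname", "E_R", "E_TS")],
    unit = unit, scale = scale
  )
}

#' Write an energy table to CSV
#' @param table an [energy_table()].
#' @param path output path.
#' @param header optional comment lines (written with a leading `#`).
#' @return `path`, invisibly.
#' @export
write_energy_csv <- function(table, path, header = NULL) {
  stopifnot(inherits(table, "energy_table"))
  wt <- data.frame(kind = "wildtype", chain = "", resid = 0, resname = "WT",
                   E_R = table$wt[["E_R"]], E_TS = table$wt[["E_TS"]],
                   stringsAsFactors = FALSE)
  del <- cbind(kind = "deletion", table$rows)
  out <- rbind(wt, del[, names(wt)])
  num <- c("E_R", "E_TS")
  out[num] <- lapply(out[num], function(x) sprintf("%.17g", x))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste("#", header), con)
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Barriers and per-residue barrier shifts from an energy table
#'
#' The ledger arithmetic: the wild-type barrier is
#' \eqn{\Delta E_{wt} = (E_{TS} - E_R)_{wt}}, each deletion barrier
#' \eqn{\Delta E_m = (E_{TS} - E_R)_m}, and the residue's contribution
#' \eqn{\Delta\Delta E_{m-wt} = \Delta E_m - \Delta E_{wt}}, all in kcal/mol
#' after unit scaling. No zero-point, thermal, or entropic corrections are
#' applied: the ledger compares raw single-point state energies.
#'
#' @param table an [energy_table()].
#' @param threshold classification threshold in kcal/mol (default 1.0,
#'   strict comparison).
#' @return data frame with the same columns as [deletion_scan()] minus
#'   `V_R`/`V_TS` (plus `E_R`/`E_TS` in kcal/mol), sorted ascending by `ddE`.
#' @export
compute_barriers <- function(table, threshold = 1.0) {
  stopifnot(inherits(table, "energy_table"))
  if (threshold <= 0) stop("threshold must be > 0")
  s <- table$scale
  dE_wt <- (table$wt[["E_TS"]] - table$wt[["E_R"]]) * s
  rows <- table$rows
  dE_m <- (rows$E_TS - rows$E_R) * s
  ddE <- dE_m - dE_wt
  key <- paste(rows$chain, rows$resid, rows$resname, sep = ":")
  out <- data.frame(chain = rows$chain, resid = rows$resid,
                    resname = rows$resname,
                    E_R = rows$E_R * s, E_TS = rows$E_TS * s,
                    dE_m = dE_m, ddE = ddE,
                    effect_class = classify_effect(ddE, threshold),
                    stringsAsFactors = FALSE)
  out <- out[order(out$ddE, key), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dE_wt") <- dE_wt
  attr(out, "threshold") <- threshold
  class(out) <- c("barrier_ledger", "data.frame")
  out
}
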
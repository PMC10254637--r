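# ---------------------------------------------------------------------------
# Geometry-stability analyses: optimal-superposition RMSD and catalytic
# interaction-distance monitoring over multi-model trajectories.

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares superposition of `mobile` onto `target` using the SVD
#' construction, restricted to proper rotations (det = +1). No mass
#' weighting: plain per-atom RMSD, the common convention for backbone RMSD.
#'
#' @param mobile,target n x 3 coordinate matrices.
#' @return list with `R` (3 x 3 rotation), `t` (translation), and `apply`,
#'   a function mapping coordinates through the fitted transform.
#' @keywords internal
kabsch_fit <- function(mobile, target) {
  if (nrow(mobile) < 3L) stop("need >= 3 atoms to fit a superposition")
  cm <- colMeans(mobile); ct <- colMeans(target)
  A <- sweep(mobile, 2, cm); B <- sweep(target, 2, ct)
  if (qr(A)$rank < 2L) stop("degenerate (collinear) fit selection")
  H <- crossprod(A, B)
  s <- svd(H)
  d <- sign(det(tcrossprod(s$v, s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  list(R = R, t = ct - as.numeric(R %*% cm),
       apply = function(x) sweep(x %*% t(R), 2, ct - as.numeric(R %*% cm),
                                 `+`))
}

#' Superposition RMSD between two coordinate sets
#'
#' Fits a proper rigid-body transform of `mobile` onto `target` on
#' `fit_selection`, then evaluates the RMSD on `measure_selection` (defaults
#' to the fit selection). Selections index rows of the coordinate matrices.
#'
#' @param mobile,target n x 3 coordinate matrices (or `Structure`s).
#' @param fit_selection integer row indices used for the fit (>= 3 atoms,
#'   non-collinear); default all rows.
#' @param measure_selection integer row indices on which the RMSD is
#'   evaluated; default `fit_selection`.
#' @return RMSD in Angstrom.
#' @export
kabsch_rmsd <- function(mobile, target, fit_selection = NULL,
                        measure_selection = NULL) {
  if (is_structure(mobile)) mobile <- coords(mobile)
  if (is_structure(target)) target <- coords(target)
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (!all(dim(mobile) == dim(target))) {
    stop("mobile and target must have identical dimensions")
  }
  fit_selection <- fit_selection %||% seq_len(nrow(mobile))
  measure_selection <- measure_selection %||% fit_selection
  if (length(fit_selection) == 0L || length(measure_selection) == 0L) {
    stop("selections must be non-empty")
  }
  fit <- kabsch_fit(mobile[fit_selection, , drop = FALSE],
                    target[fit_selection, , drop = FALSE])
  moved <- fit$apply(mobile[measure_selection, , drop = FALSE])
  diffs <- moved - target[measure_selection, , drop = FALSE]
  sqrt(sum(diffs^2) / nrow(diffs))
}

#' Per-frame superposition RMSD series over a trajectory
#'
#' @param traj list of `Structure` frames (see [read_multimodel()]).
#' @param reference reference `Structure`; default the first frame.
#' @param fit_selection,measure_selection row indices as in [kabsch_rmsd()].
#' @param label selection label carried into the output.
#' @return data frame with columns `frame`, `rmsd`; attributes `mean`,
#'   `label`.
#' @export
rmsd_series <- function(traj, reference = NULL, fit_selection = NULL,
                        measure_selection = NULL, label = "selection") {
  stopifnot(length(traj) >= 1L)
  reference <- reference %||% traj[[1]]
  ref_xyz <- coords(reference)
  r <- vapply(traj, function(fr) {
    kabsch_rmsd(coords(fr), ref_xyz, fit_selection, measure_selection)
  }, numeric(1))
  out <- data.frame(frame = seq_along(traj), rmsd = r)
  attr(out, "mean") <- mean(r)
  attr(out, "label") <- label
  out
}

# resolve an atom selector "chain:resid:atom_name" to a row index
resolve_atom <- function(structure, selector, frame = NA) {
  parts <- strsplit(selector, ":", fixed = TRUE)[[1]]
  if (length(parts) != 3L) {
    stop("atom selector must be 'chain:resid:atom_name', got: ", selector)
  }
  idx <- which(structure$chain == parts[1] &
                 structure$resid == as.integer(parts[2]) &
                 structure$atom_name == parts[3])
  if (length(idx) != 1L) {
    stop("atom not found", if (!is.na(frame)) paste0(" in frame ", frame),
         ": ", selector)
  }
  idx
}

#' Define a distance monitor
#'
#' A monitor tracks the distance from one atom to another, or the minimum
#' over a set of partner atoms (e.g. the two carboxylate oxygens of a
#' catalytic glutamate, or the three ammonium protons of a lysine). For set
#' monitors the per-member series are retained so each member's mean can be
#' reported separately, mirroring the per-oxygen / per-proton comparison.
#'
#' @param label monitor name.
#' @param from atom selector `"chain:resid:atom_name"`.
#' @param to character vector of one or more partner selectors.
#' @return a list of class `distance_monitor_spec`.
#' @export
monitor_spec <- function(label, from, to) {
  stopifnot(is.character(from), length(from) == 1L,
            is.character(to), length(to) >= 1L)
  structure(list(label = label, from = from, to = to),
            class = "distance_monitor_spec")
}

#' Read monitor definitions from JSON
#' @param path JSON array of objects `{label, from, to}` (`to` may be a
#'   string or an array of strings).
#' @return list of [monitor_spec()].
#' @export
read_monitor_specs <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(seq_len(nrow(j)), function(i) {
    monitor_spec(j$label[i], j$from[i], unlist(j$to[i]))
  })
}

#' Monitor interaction distances over a trajectory
#'
#' @param traj list of `Structure` frames with identical atom sequences.
#' @param monitors list of [monitor_spec()].
#' @return list of `distance_monitor` objects, each with `label`, `series`
#'   (per-frame minimum distance), `mean`, `sd`, `members` (per-member
#'   selector), `member_series` (frames x members matrix), and
#'   `member_means`.
#' @export
monitor <- function(traj, monitors) {
  stopifnot(length(traj) >= 1L, length(monitors) >= 1L)
  lapply(monitors, function(m) {
    from_idx <- resolve_atom(traj[[1]], m$from, frame = 1)
    to_idx <- vapply(m$to, function(s) resolve_atom(traj[[1]], s, frame = 1),
                     integer(1))
    member_series <- vapply(seq_along(traj), function(f) {
      fr <- traj[[f]]
      # indices resolved on frame 1 are valid everywhere: read_multimodel
      # guarantees identical atom sequences, but verify presence defensively
      p <- coords(fr)
      from <- p[from_idx, ]
      vapply(to_idx, function(ti) sqrt(sum((p[ti, ] - from)^2)), numeric(1))
    }, numeric(length(to_idx)))
    member_series <- matrix(member_series, nrow = length(traj),
                            ncol = length(to_idx), byrow = TRUE)
    series <- apply(member_series, 1, min)
    structure(
      list(label = m$label, series = series,
           mean = mean(series),
           sd = if (length(series) > 1L) stats::sd(series) else 0,
           members = m$to,
           member_series = member_series,
           member_means = stats::setNames(colMeans(member_series), m$to)),
      class = "distance_monitor")
  })
}

#' @export
print.distance_monitor <- function(x, ...) {
  cat(sprintf("%s: mean %.2f A, sd %.2f A over %d frames\n",
              x$label, x$mean, x$sd, length(x$series)))
  if (length(x$members) > 1L) {
    for (m in seq_along(x$members)) {
      cat(sprintf("  %-20s mean %.2f A\n", x$members[m],
                  x$member_means[m]))
    }
  }
  invisible(x)
}

#' Write monitor summaries and time series as TSV
#'
#' @param mons list from [monitor()].
#' @param dir output directory (created if needed): one
#'   `<label>_series.tsv` per monitor plus `summary.tsv`.
#' @return `dir`, invisibly.
#' @export
write_monitor_tsv <- function(mons, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  summ <- do.call(rbind, lapply(mons, function(x) {
    data.frame(label = x$label, mean = x$mean, sd = x$sd,
               n_frames = length(x$series),
               members = paste(x$members, collapse = ";"),
               member_means = paste(sprintf("%.4f", x$member_means),
                                    collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(summ, file.path(dir, "summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (x in mons) {
    df <- data.frame(frame = seq_along(x$series), min_dist = x$series)
    colnames_extra <- make.names(x$members)
    mem <- as.data.frame(x$member_series)
    names(mem) <- colnames_extra
    utils::write.table(cbind(df, mem),
                       file.path(dir, paste0(gsub("[^A-Za-z0-9_.-]", "_",
                                                  x$label), "_series.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
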
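## Three-state discretization of the CE-NZ torsion and Boltzmann inversion
## of populations and transition frequencies into relative free energies
## and barrier estimates.

#' Three-state torsion binning
#'
#' Partitions the circle (-180, 180] into three 120-degree arcs:
#' (0, 120] -> g+, (-120, 0] -> g-, and the trans arc
#' (120, 180] u (-180, -120] -> t. Boundary values belong to the arc whose
#' half-open upper edge they hit (so exactly 120 is g+, exactly 0 is g-).
#'
#' @param edges Numeric `c(low, split, high)` bin edges in degrees;
#'   defaults `c(-120, 0, 120)`.
#' @return Object of class `state_binning`.
#' @export
state_binning <- function(edges = c(-120, 0, 120)) {
  stopifnot(length(edges) == 3, !is.unsorted(edges))
  structure(list(edges = edges, labels = .rot_states),
            class = "state_binning")
}

#' Assign torsion values to rotamer states
#'
#' @param series A [dihedral_series()] or a numeric vector of degrees in
#'   (-180, 180].
#' @param binning A [state_binning()].
#' @return Object of class `state_series`: character labels (`g+`, `g-`,
#'   `t`), one per frame, with the source series attached.
#' @export
assign_states <- function(series, binning = state_binning()) {
  vals <- if (inherits(series, "dihedral_series")) series$values else series
  e <- binning$edges
  labels <- ifelse(vals > e[2] & vals <= e[3], "g+",
                   ifelse(vals > e[1] & vals <= e[2], "g-", "t"))
  structure(list(labels = labels, source = series, binning = binning),
            class = "state_series")
}

#' @export
print.state_series <- function(x, ...) {
  tb <- table(factor(x$labels, levels = .rot_states))
  cat("state_series: ", length(x$labels), " frames; ",
      paste(sprintf("%s=%.3f", names(tb), tb / length(x$labels)),
            collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Populations, transitions, relative energies and barrier estimates
#'
#' Populations are occupancy fractions; relative state energies come from
#' Boltzmann inversion, `dG_i = -kT log(p_i / p_max)` (minimum zero).
#' Transitions are counted on consecutive-frame label changes at native
#' frame resolution, and each ordered barrier is estimated from the
#' per-opportunity transition probability,
#' `dE(i->j) = -kT log(n(i->j) / n_i)`: `+Inf` when the transition never
#' occurs, `NA` when state `i` is never visited. Absolute barrier values
#' carry the unknown attempt-frequency offset `-kT log(kappa)`; differences
#' between barriers are the supported output.
#'
#' @param series A `state_series` from [assign_states()], or a character
#'   vector of labels.
#' @param temperature Kelvin (default 310).
#' @param window Optional `c(start, end)` frame window (1-based, inclusive),
#'   e.g. to drop an equilibration span.
#' @return Object of class `state_stats`: list with `populations`,
#'   `residence_counts`, `transition_counts` (3x3, rows = from),
#'   `relative_energies`, `barrier_estimates`, `temperature`, `n_frames`.
#' @export
state_statistics <- function(series, temperature = 310, window = NULL) {
  labels <- if (inherits(series, "state_series")) series$labels else series
  if (!is.null(window)) {
    stopifnot(length(window) == 2, window[1] >= 1,
              window[2] <= length(labels), window[1] <= window[2])
    labels <- labels[window[1]:window[2]]
  }
  n <- length(labels)
  if (n < 2) stop("state_statistics needs at least 2 frames")
  f <- factor(labels, levels = .rot_states)
  if (anyNA(f)) stop("labels outside {g+, g-, t}")
  n_i <- table(f)
  p <- as.numeric(n_i) / n
  names(p) <- .rot_states
  kT <- .kB * temperature
  dG <- -kT * log(p / max(p))
  trans <- table(from = f[-n], to = f[-1])
  diag(trans) <- 0
  trans <- unclass(trans)
  ## opportunities to leave state i: frames in i that have a successor
  n_from <- table(f[-n])
  barrier <- matrix(NA_real_, 3, 3, dimnames = list(.rot_states, .rot_states))
  for (i in .rot_states) for (j in .rot_states) if (i != j) {
    if (n_from[[i]] == 0) next
    barrier[i, j] <- if (trans[i, j] > 0)
      -kT * log(trans[i, j] / n_from[[i]]) else Inf
  }
  structure(list(populations = p, residence_counts = as.numeric(n_i),
                 transition_counts = trans, relative_energies = dG,
                 barrier_estimates = barrier, temperature = temperature,
                 n_frames = n),
            class = "state_stats")
}

#' @export
print.state_stats <- function(x, ...) {
  cat("state_stats over", x$n_frames, "frames at", x$temperature, "K\n")
  cat("  populations:    ",
      paste(sprintf("%s=%.4f", .rot_states, x$populations), collapse = "  "),
      "\n  energies (kcal/mol):",
      paste(sprintf("%s=%.3f", .rot_states, x$relative_energies),
            collapse = "  "), "\n  transition counts:\n")
  print(x$transition_counts)
  cat("  barrier estimates (kcal/mol, attempt-frequency offset included):\n")
  print(round(x$barrier_estimates, 3))
  invisible(x)
}

#' @export
summary.state_stats <- function(object, ...) {
  df <- data.frame(state = .rot_states,
                   population = as.numeric(object$populations),
                   energy_kcal = as.numeric(object$relative_energies))
  df
}

#' Combine the equivalent methyl torsion series of one head
#'
#' For a di-/trimethylated head the three methyl torsions are offset by 120
#' degrees, so at most one methyl occupies each state per frame; whichever
#' methyl is in trans provides the Fe-aligned ("effectual") pose. Returns
#' the per-frame indicator that at least one methyl is in trans, its
#' trajectory fraction, the per-methyl state populations, and, as a
#' consistency check, the fraction of frames whose labels are pairwise
#' distinct (1 for an ideal tetrahedral head).
#'
#' @param series_list List of 1-3 `state_series` (or label vectors) over
#'   identical frames.
#' @return List with `any_t` (logical per frame), `any_t_fraction`,
#'   `per_methyl_populations` (matrix), `distinct_fraction`.
#' @export
combine_equivalent_methyls <- function(series_list) {
  labs <- lapply(series_list, function(s)
    if (inherits(s, "state_series")) s$labels else s)
  stopifnot(length(labs) >= 1, length(labs) <= 3)
  n <- unique(lengths(labs))
  if (length(n) != 1) stop("methyl series have differing lengths")
  m <- do.call(cbind, labs)
  any_t <- rowSums(m == "t") > 0
  pops <- sapply(labs, function(l)
    as.numeric(table(factor(l, levels = .rot_states))) / n)
  rownames(pops) <- .rot_states
  colnames(pops) <- paste0("CZ", seq_along(labs))
  distinct <- if (length(labs) == 1) rep(TRUE, n) else
    apply(m, 1, function(r) !any(duplicated(r)))
  list(any_t = any_t, any_t_fraction = mean(any_t),
       per_methyl_populations = pops / 1,
       distinct_fraction = mean(distinct))
}

#' Write state-analysis tables as CSV
#'
#' @param stats A `state_stats`.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return Paths written, invisibly.
#' @export
write_state_csv <- function(stats, dir, prefix = "states") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, paste0(prefix, "_populations.csv"))
  utils::write.csv(data.frame(
    state = .rot_states,
    population = as.numeric(stats$populations),
    residence_count = stats$residence_counts,
    energy_kcal = as.numeric(stats$relative_energies)), p1, row.names = FALSE)
  p2 <- file.path(dir, paste0(prefix, "_transitions.csv"))
  tc <- as.data.frame(as.table(stats$transition_counts))
  names(tc) <- c("from", "to", "count")
  tc$barrier_kcal <- mapply(function(i, j) stats$barrier_estimates[i, j],
                            as.character(tc$from), as.character(tc$to))
  utils::write.csv(tc[tc$from != tc$to, ], p2, row.names = FALSE)
  invisible(c(p1, p2))
}
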
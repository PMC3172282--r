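## Sphere-occupancy and distance statistics around reference atoms
## (methyl carbons about Fe(II); NZ to pocket oxygens; Fe to waters).

#' Sphere-occupancy frequency around a reference atom
#'
#' For each target atom, the fraction of frames it lies strictly within
#' `radius` of the reference atom, plus the union fraction (frames with at
#' least one target inside) and the arithmetic sum of the per-atom
#' fractions. Under single occupancy (never more than one target inside at
#' once) union and sum coincide; both are reported because a summed total
#' over targets is only interpretable as a frequency in that regime.
#'
#' @param traj A [trajectory()].
#' @param reference Atom index of the sphere centre (e.g. Fe).
#' @param targets Atom indices (e.g. the methyl carbons CZ1..CZ3).
#' @param radius Sphere radius, Angstrom (default 4.7).
#' @param window Optional `c(start, end)` frame window.
#' @return Object of class `occupancy_result`: list with `radius`,
#'   `per_atom_fraction` (named by atom label), `union_fraction`,
#'   `sum_fraction`, `n_frames`.
#' @export
occupancy_frequency <- function(traj, reference, targets, radius = 4.7,
                                window = NULL) {
  if (!length(targets)) stop("empty target selection")
  if (radius <= 0) stop("radius must be positive")
  fr <- .window_frames(traj, window)
  ref <- matrix(traj$coords[fr, reference, ], ncol = 3)
  inside <- matrix(FALSE, length(fr), length(targets))
  for (k in seq_along(targets)) {
    d2 <- rowSums((matrix(traj$coords[fr, targets[k], ], ncol = 3) - ref)^2)
    inside[, k] <- d2 < radius^2
  }
  per_atom <- colMeans(inside)
  names(per_atom) <- atom_labels(traj$structure, targets)
  structure(list(radius = radius, per_atom_fraction = per_atom,
                 union_fraction = mean(rowSums(inside) > 0),
                 sum_fraction = sum(per_atom), n_frames = length(fr)),
            class = "occupancy_result")
}

#' @export
print.occupancy_result <- function(x, ...) {
  cat(sprintf("occupancy within %.2f A over %d frames\n", x$radius,
              x$n_frames))
  for (nm in names(x$per_atom_fraction))
    cat(sprintf("  %-16s %6.1f%%\n", nm, 100 * x$per_atom_fraction[[nm]]))
  cat(sprintf("  union %.1f%%  sum %.1f%%\n", 100 * x$union_fraction,
              100 * x$sum_fraction))
  invisible(x)
}

#' Occupancy across a radius sweep
#'
#' @inheritParams occupancy_frequency
#' @param radii Sorted positive radii; default `c(4.6, 4.7, 4.8)`, the
#'   band over which the occupancy trend should be stable.
#' @return List of `occupancy_result`, one per radius, class
#'   `occupancy_sweep`.
#' @export
radius_sweep <- function(traj, reference, targets,
                         radii = c(4.6, 4.7, 4.8), window = NULL) {
  if (is.unsorted(radii) || any(radii <= 0))
    stop("radii must be positive and sorted")
  out <- lapply(radii, function(r)
    occupancy_frequency(traj, reference, targets, radius = r,
                        window = window))
  structure(out, class = "occupancy_sweep")
}

#' @export
print.occupancy_sweep <- function(x, ...) {
  for (res in x)
    cat(sprintf("r=%.2f A: union %.1f%%  sum %.1f%%\n", res$radius,
                100 * res$union_fraction, 100 * res$sum_fraction))
  invisible(x)
}

#' As-data.frame view of a sweep
#' @param x An `occupancy_sweep`.
#' @param ... Unused.
#' @return data.frame with radius, atom, per-atom, union and sum columns.
#' @export
as.data.frame.occupancy_sweep <- function(x, ...) {
  do.call(rbind, lapply(x, function(res)
    data.frame(radius = res$radius, atom = names(res$per_atom_fraction),
               fraction = as.numeric(res$per_atom_fraction),
               union_fraction = res$union_fraction,
               sum_fraction = res$sum_fraction, row.names = NULL)))
}

#' Pairwise distance statistics along a trajectory
#'
#' @param traj A [trajectory()].
#' @param a,b Distinct atom indices.
#' @param window Optional `c(start, end)` frame window.
#' @return Object of class `distance_stats`: `mean` and population `std`
#'   (Angstrom) plus the per-frame `series`.
#' @export
distance_stats <- function(traj, a, b, window = NULL) {
  if (a == b) stop("atoms must be distinct")
  fr <- .window_frames(traj, window)
  d <- sqrt(rowSums((matrix(traj$coords[fr, a, ], ncol = 3) -
                     matrix(traj$coords[fr, b, ], ncol = 3))^2))
  structure(list(mean = mean(d), std = sqrt(mean((d - mean(d))^2)),
                 series = d, times = traj$times[fr],
                 pair = atom_labels(traj$structure, c(a, b))),
            class = "distance_stats")
}

#' @export
print.distance_stats <- function(x, ...) {
  cat(sprintf("distance %s -- %s: %.2f (+/- %.2f) A over %d frames\n",
              x$pair[1], x$pair[2], x$mean, x$std, length(x$series)))
  invisible(x)
}
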
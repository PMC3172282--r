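## Rigid rotation of the methylammonium head about the CE-NZ axis and
## van der Waals overlap detection against the pocket.

#' Rigidly rotate a group of atoms about a bond axis
#'
#' Rotates `head` atoms about the CE -> NZ axis; the sign convention matches
#' [dihedral()]: rotating by `angle` changes the CD-CE-NZ-CZx torsion by
#' exactly `angle` (mod 360).
#'
#' @param coords `n_atoms x 3` coordinate matrix.
#' @param head Atom indices to rotate (must exclude the axis atoms' upstream
#'   chain; the axis atoms themselves are left untouched).
#' @param axis_from,axis_to Atom indices defining the axis (CE, NZ).
#' @param angle Degrees.
#' @return The coordinate matrix with the head atoms rotated.
#' @export
rotate_group <- function(coords, head, axis_from, axis_to, angle) {
  o <- coords[axis_from, ]
  ax <- coords[axis_to, ] - o
  if (sum(ax^2) < 1e-12) stop("coincident axis atoms")
  head <- setdiff(head, c(axis_from, axis_to))
  coords[head, ] <- rotate_about_axis(coords[head, , drop = FALSE],
                                      o, ax, angle)
  coords
}

#' Detect steric clashes between a head group and its environment
#'
#' A pair clashes when `d(i, j) < r_i + r_j - tolerance`. Radii come from
#' per-atom `vdw_radius` where assigned, else the packaged element table.
#' 1-2 and 1-3 neighbours of the head's attachment (the CD/CE/NZ stem and
#' the methyls bonded to NZ) are excluded by name.
#'
#' @param coords `n_atoms x 3` coordinate matrix.
#' @param structure The owning [structure_model()].
#' @param head,environment Atom index vectors (disjoint).
#' @param tolerance Overlap tolerance, Angstrom (default 0.4).
#' @param rotation_angle Annotation carried into the report.
#' @return Object of class `clash_report`: `rotation_angle`, `clash_count`,
#'   and a data.frame `pairs` (head atom, environment atom, distance,
#'   overlap).
#' @export
detect_clashes <- function(coords, structure, head, environment,
                           tolerance = 0.4, rotation_angle = 0) {
  a <- structure$atoms
  radius_of <- function(idx) {
    r <- a$vdw_radius[idx]
    el <- toupper(a$element[idx])
    miss <- is.na(r)
    r[miss] <- .default_vdw[el[miss]]
    if (anyNA(r))
      stop("no van der Waals radius for atom(s): ",
           paste(atom_labels(structure, idx[is.na(r)]), collapse = ", "))
    r
  }
  environment <- setdiff(environment, head)
  stem <- which(a$name %in% c("CD", "CE", "NZ") &
                a$chain_id %in% a$chain_id[head])
  environment <- setdiff(environment, stem)
  rh <- radius_of(head)
  re <- radius_of(environment)
  pairs <- NULL
  for (k in seq_along(head)) {
    d <- sqrt(rowSums(sweep(coords[environment, , drop = FALSE], 2,
                            coords[head[k], ])^2))
    thr <- rh[k] + re - tolerance
    hit <- which(d < thr)
    if (length(hit))
      pairs <- rbind(pairs, data.frame(
        head_atom = atom_labels(structure, rep(head[k], length(hit))),
        env_atom = atom_labels(structure, environment[hit]),
        distance = d[hit], overlap = thr[hit] - d[hit],
        row.names = NULL))
  }
  if (is.null(pairs))
    pairs <- data.frame(head_atom = character(0), env_atom = character(0),
                        distance = numeric(0), overlap = numeric(0))
  structure(list(rotation_angle = rotation_angle,
                 clash_count = nrow(pairs), pairs = pairs,
                 tolerance = tolerance),
            class = "clash_report")
}

#' @export
print.clash_report <- function(x, ...) {
  cat(sprintf("clash_report at %g deg: %d clashing pair(s)\n",
              x$rotation_angle, x$clash_count))
  if (x$clash_count)
    print(transform(x$pairs, distance = round(distance, 2),
                    overlap = round(overlap, 2)), row.names = FALSE)
  invisible(x)
}

#' Rotation clash scan of the methylammonium head
#'
#' Rotates the head rigidly about CE -> NZ through `angles` (default the
#' -120 degree scan: 0, -120, -240) with the pocket held fixed, reporting
#' the clashing pairs at each pose. For a symmetric trimethyl head the
#' three poses are equivalent and yield identical clash counts; restricted
#' pockets produce clashes only in rotated poses.
#'
#' @param coords `n_atoms x 3` coordinate matrix of the pose to scan from.
#' @param structure The owning [structure_model()].
#' @param head Atom indices rotated (the methyl carbons and any head
#'   hydrogens; NZ itself lies on the axis).
#' @param axis_from,axis_to Atom indices (CE, NZ).
#' @param environment Atom indices clashes are scored against.
#' @param angles Degrees; default `c(0, -120, -240)`.
#' @param tolerance Overlap tolerance, Angstrom.
#' @return Object of class `clash_scan`: list of [detect_clashes()] reports.
#' @export
rotation_scan <- function(coords, structure, head, axis_from, axis_to,
                          environment, angles = c(0, -120, -240),
                          tolerance = 0.4) {
  out <- lapply(angles, function(ang) {
    rot <- rotate_group(coords, head, axis_from, axis_to, ang)
    detect_clashes(rot, structure, head, environment,
                   tolerance = tolerance, rotation_angle = ang)
  })
  structure(out, class = "clash_scan")
}

#' @export
print.clash_scan <- function(x, ...) {
  for (rep in x)
    cat(sprintf("  %6g deg: %d clash(es)%s\n", rep$rotation_angle,
                rep$clash_count,
                if (rep$clash_count) paste0(" [",
                  paste(unique(rep$pairs$env_atom), collapse = ", "), "]")
                else ""))
  invisible(x)
}

#' As-data.frame view of a clash scan
#' @param x A `clash_scan`.
#' @param ... Unused.
#' @return data.frame of all clashing pairs across poses.
#' @export
as.data.frame.clash_scan <- function(x, ...) {
  do.call(rbind, lapply(x, function(rep) {
    if (!nrow(rep$pairs))
      return(data.frame(angle = numeric(0), head_atom = character(0),
                        env_atom = character(0), distance = numeric(0),
                        overlap = numeric(0)))
    cbind(angle = rep$rotation_angle, rep$pairs)
  }))
}
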
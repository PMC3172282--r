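## Gas-phase nonbonded interface energetics: Lennard-Jones + Coulomb pair
## terms and the per-residue decomposition of the enzyme-substrate
## interaction, trajectory-averaged. Continuum-solvation and entropy terms
## are deliberately outside this module's scope, so the per-residue
## rankings are gas-phase MM rankings.

#' Nonbonded parameters
#'
#' @param dielectric Uniform internal dielectric (default 4, the value
#'   appropriate for a buried protein interface).
#' @param cutoff Pair-distance cutoff in Angstrom, or `Inf` for none
#'   (default; desk-scale systems do not need one).
#' @return Object of class `nonbonded_params`. Combining rule is
#'   Lorentz-Berthelot (arithmetic sigma, geometric epsilon); the Coulomb
#'   constant is 332.0636 kcal Angstrom / (mol e^2).
#' @export
nonbonded_params <- function(dielectric = 4, cutoff = Inf) {
  stopifnot(dielectric > 0, cutoff > 0)
  structure(list(dielectric = dielectric, coulomb_constant = .coulomb_k,
                 cutoff = cutoff), class = "nonbonded_params")
}

#' Nonbonded pair energy
#'
#' `coulomb = k q_i q_j / (eps r)`;
#' `vdw = 4 eps_ij ((sigma_ij / r)^12 - (sigma_ij / r)^6)` with
#' `sigma_ij = (sigma_i + sigma_j) / 2`, `eps_ij = sqrt(eps_i eps_j)`.
#'
#' @param qi,qj Partial charges, e.
#' @param si,sj Lennard-Jones sigma, Angstrom.
#' @param ei,ej Lennard-Jones epsilon, kcal/mol.
#' @param r Distance, Angstrom (> 0).
#' @param params A [nonbonded_params()].
#' @return Named numeric `c(vdw = , coulomb = )`, kcal/mol.
#' @export
pair_energy <- function(qi, qj, si, sj, ei, ej, r,
                        params = nonbonded_params()) {
  if (any(is.na(c(qi, qj, si, sj, ei, ej))))
    stop("missing charge or Lennard-Jones parameters")
  stopifnot(r > 0)
  sij <- (si + sj) / 2
  eij <- sqrt(ei * ej)
  sr6 <- (sij / r)^6
  c(vdw = 4 * eij * (sr6^2 - sr6),
    coulomb = params$coulomb_constant * qi * qj / (params$dielectric * r))
}

#' Per-residue decomposition of the interface interaction energy
#'
#' For every residue on either side of the interface, sums the Lennard-Jones
#' and Coulomb energies between its atoms and all atoms of the opposite
#' selection, averaged over the analysis window. Only inter-selection pairs
#' enter, so intramolecular exclusions never arise.
#'
#' @param traj A [trajectory()] whose structure carries `charge`,
#'   `lj_sigma`, `lj_epsilon` on every selected atom.
#' @param enzyme,substrate Disjoint atom index vectors.
#' @param params A [nonbonded_params()].
#' @param window Optional `c(start, end)` frame window.
#' @return Object of class `residue_energy`: data.frame with one row per
#'   residue (both sides), columns `side`, `chain`, `residue_number`,
#'   `residue_name`, `vdw`, `coulomb`, `total` (kcal/mol) and
#'   `frames_averaged`, sorted most favourable first.
#' @export
interface_decomposition <- function(traj, enzyme, substrate,
                                    params = nonbonded_params(),
                                    window = NULL) {
  if (!length(enzyme) || !length(substrate))
    stop("empty enzyme or substrate selection")
  if (length(intersect(enzyme, substrate)))
    stop("enzyme and substrate selections overlap")
  a <- traj$structure$atoms
  sel <- c(enzyme, substrate)
  bad <- sel[is.na(a$charge[sel]) | is.na(a$lj_sigma[sel]) |
             is.na(a$lj_epsilon[sel])]
  if (length(bad))
    stop("missing nonbonded parameters for atom(s): ",
         paste(atom_labels(traj$structure, bad), collapse = ", "))
  fr <- .window_frames(traj, window)
  ne <- length(enzyme); ns <- length(substrate)
  qq <- params$coulomb_constant *
    outer(a$charge[enzyme], a$charge[substrate]) / params$dielectric
  sij <- outer(a$lj_sigma[enzyme], a$lj_sigma[substrate], "+") / 2
  eij <- sqrt(outer(a$lj_epsilon[enzyme], a$lj_epsilon[substrate]))
  vdw_acc <- matrix(0, ne, ns)
  cou_acc <- matrix(0, ne, ns)
  for (f in fr) {
    xyz <- frame_coords(traj, f)
    dx <- outer(xyz[enzyme, 1], xyz[substrate, 1], "-")
    dy <- outer(xyz[enzyme, 2], xyz[substrate, 2], "-")
    dz <- outer(xyz[enzyme, 3], xyz[substrate, 3], "-")
    r <- sqrt(dx^2 + dy^2 + dz^2)
    sr6 <- (sij / r)^6
    vdw <- 4 * eij * (sr6^2 - sr6)
    cou <- qq / r
    if (is.finite(params$cutoff)) {
      out <- r >= params$cutoff
      vdw[out] <- 0; cou[out] <- 0
    }
    vdw_acc <- vdw_acc + vdw
    cou_acc <- cou_acc + cou
  }
  vdw_acc <- vdw_acc / length(fr)
  cou_acc <- cou_acc / length(fr)
  rows_for <- function(idx, other_margin, vdw_m, cou_m, side) {
    key <- paste(a$chain_id[idx], a$residue_number[idx])
    uk <- unique(key)
    do.call(rbind, lapply(uk, function(k) {
      rows <- which(key == k)
      i1 <- idx[rows[1]]
      vd <- if (other_margin == 1) sum(vdw_m[rows, ]) else sum(vdw_m[, rows])
      co <- if (other_margin == 1) sum(cou_m[rows, ]) else sum(cou_m[, rows])
      data.frame(side = side, chain = a$chain_id[i1],
                 residue_number = a$residue_number[i1],
                 residue_name = a$residue_name[i1],
                 vdw = vd, coulomb = co, total = vd + co,
                 frames_averaged = length(fr))
    }))
  }
  out <- rbind(rows_for(enzyme, 1, vdw_acc, cou_acc, "enzyme"),
               rows_for(substrate, 2, vdw_acc, cou_acc, "substrate"))
  out <- out[order(out$total), ]
  rownames(out) <- NULL
  structure(out, class = c("residue_energy", "data.frame"))
}

#' Interface totals per side
#'
#' Sums the per-residue rows of each side; the two side totals are equal by
#' the pairwise symmetry of the decomposition.
#'
#' @param rows A `residue_energy` from [interface_decomposition()].
#' @return data.frame with one row per side: `vdw`, `coulomb`, `total`.
#' @export
interface_totals <- function(rows) {
  agg <- lapply(split(rows, rows$side), function(d)
    data.frame(side = d$side[1], vdw = sum(d$vdw), coulomb = sum(d$coulomb),
               total = sum(d$total)))
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}

#' @export
print.residue_energy <- function(x, ...) {
  cat("residue_energy:", nrow(x), "residue rows,",
      x$frames_averaged[1], "frame(s) averaged (kcal/mol)\n")
  df <- data.frame(side = x$side,
                   residue = paste0(x$residue_name, x$residue_number),
                   vdw = round(x$vdw, 3), coulomb = round(x$coulomb, 3),
                   total = round(x$total, 3))
  print(utils::head(df, 12), row.names = FALSE)
  if (nrow(df) > 12) cat("  ...", nrow(df) - 12, "more rows\n")
  invisible(x)
}
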
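## Geometric kernels: torsions, superposition RMSD, positional fluctuation.

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Signed dihedral angle of four points
#'
#' IUPAC sign convention: looking down the p2->p3 axis, a positive angle is a
#' clockwise rotation of p4 relative to p1. Result in degrees on (-180, 180],
#' with +180 canonical for the anti (trans) arrangement.
#'
#' @param p1,p2,p3,p4 Numeric length-3 coordinates in Angstrom.
#' @return Angle in degrees.
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  if (sum(b1^2) == 0 || sum(b2^2) == 0 || sum(b3^2) == 0)
    stop("degenerate dihedral: coincident consecutive points")
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  if (sum(n1^2) < 1e-20 || sum(n2^2) < 1e-20)
    stop("degenerate dihedral: collinear points")
  m1 <- .cross3(n1, b2 / sqrt(sum(b2^2)))
  ang <- -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  .wrap180(ang)
}

#' Per-frame dihedral series for one atom quadruple
#'
#' For the methyllysine head torsion the quadruple is CD, CE, NZ, CZx: the
#' rotation about the CE-NZ bond.
#'
#' @param traj A [trajectory()].
#' @param quad Four atom indices.
#' @param label Optional label (e.g. `"CZ1"`).
#' @return Object of class `dihedral_series`: list with `values` (degrees,
#'   one per frame), `times` (ps), `quad`, `label`.
#' @export
dihedral_series <- function(traj, quad, label = "") {
  stopifnot(length(quad) == 4)
  if (any(quad < 1 | quad > .n_atoms(traj$structure)))
    stop("dihedral quad indices out of range")
  p <- lapply(1:4, function(k) traj$coords[, quad[k], , drop = FALSE])
  p <- lapply(p, function(m) matrix(m, ncol = 3))
  vals <- .dihedral_vec(p[[1]], p[[2]], p[[3]], p[[4]])
  bad <- which(!is.finite(vals))
  if (length(bad))
    stop("degenerate dihedral geometry at frame ", bad[1])
  structure(list(values = vals, times = traj$times, quad = quad,
                 label = label), class = "dihedral_series")
}

## Vectorized dihedral over rows of four n x 3 matrices.
.dihedral_vec <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cr <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                             a[, 3] * b[, 1] - a[, 1] * b[, 3],
                             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  b2n <- b2 / sqrt(rowSums(b2^2))
  m1 <- cr(n1, b2n)
  ang <- -atan2(rowSums(m1 * n2), rowSums(n1 * n2)) * 180 / pi
  ang[rowSums(n1^2) < 1e-20 | rowSums(n2^2) < 1e-20] <- NaN
  .wrap180(ang)
}

#' @export
print.dihedral_series <- function(x, ...) {
  cat("dihedral_series", if (nzchar(x$label)) paste0(" [", x$label, "]"),
      ": ", length(x$values), " frames, circular mean ",
      sprintf("%.1f", .circ_mean(x$values)), " deg\n", sep = "")
  invisible(x)
}

.circ_mean <- function(deg) {
  r <- deg * pi / 180
  .wrap180(atan2(mean(sin(r)), mean(cos(r))) * 180 / pi)
}

#' Rotate points about an axis (Rodrigues rotation)
#'
#' @param pts `n x 3` matrix of points.
#' @param origin Point on the axis.
#' @param axis Direction vector (need not be unit).
#' @param angle Rotation angle in degrees; the sign follows the [dihedral()]
#'   convention: rotating p4 about the p2->p3 axis by `angle` changes the
#'   dihedral by `angle`.
#' @return Rotated `n x 3` matrix.
#' @export
rotate_about_axis <- function(pts, origin, axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  sweep(sweep(pts, 2, origin) %*% t(R), 2, origin, "+")
}

#' Optimal rigid superposition and RMSD (Kabsch)
#'
#' Least-squares rotation + translation, reflections excluded.
#'
#' @param reference,mobile `n x 3` coordinate matrices (same `n >= 3`).
#' @param subset Optional indices restricting the fit.
#' @return List with `rmsd` (Angstrom over the subset), `rotation` (3 x 3),
#'   `translation` (applied as `mobile %*% t(R) + t`), and `fitted`
#'   (all mobile coordinates transformed).
#' @export
superpose_rmsd <- function(reference, mobile, subset = NULL) {
  if (is.null(subset)) {
    if (nrow(reference) != nrow(mobile))
      stop("size mismatch between reference and mobile coordinates")
    subset <- seq_len(nrow(reference))
  }
  if (max(subset) > nrow(reference) || max(subset) > nrow(mobile))
    stop("subset size mismatch between reference and mobile")
  A <- reference[subset, , drop = FALSE]
  B <- mobile[subset, , drop = FALSE]
  if (nrow(A) < 3) stop("superposition needs at least 3 points")
  ca <- colMeans(A); cb <- colMeans(B)
  H <- t(sweep(B, 2, cb)) %*% sweep(A, 2, ca)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- ca - as.numeric(R %*% cb)
  fitted_sub <- sweep(B %*% t(R), 2, tr, "+")
  rmsd <- sqrt(mean(rowSums((fitted_sub - A)^2)))
  fitted <- sweep(mobile %*% t(R), 2, tr, "+")
  list(rmsd = rmsd, rotation = R, translation = tr, fitted = fitted)
}

#' Per-frame RMSD series against a reference frame
#'
#' Each frame is independently superposed on the reference over `subset`
#' before the RMSD is taken (the standard backbone-RMSD stability trace).
#'
#' @param traj A [trajectory()].
#' @param reference `n_atoms x 3` reference coordinates (default frame 1).
#' @param subset Atom indices to fit and measure over (e.g. a backbone
#'   selection); default all atoms.
#' @return Numeric vector, one Angstrom value per frame.
#' @export
rmsd_series <- function(traj, reference = NULL, subset = NULL) {
  if (is.null(reference)) reference <- frame_coords(traj, 1)
  vapply(seq_len(n_frames(traj)), function(f)
    superpose_rmsd(reference, frame_coords(traj, f), subset = subset)$rmsd,
    numeric(1))
}

#' Positional fluctuation of one atom
#'
#' Root-mean-square deviation of an atom's position from its trajectory-mean
#' position, without superposition. For isotropic Gaussian jitter of width
#' sigma per coordinate the expectation is `sqrt(3) * sigma`.
#'
#' @param traj A [trajectory()].
#' @param atom Atom index.
#' @param window Optional `c(start, end)` frame window.
#' @return Fluctuation in Angstrom.
#' @export
mean_fluctuation <- function(traj, atom, window = NULL) {
  fr <- .window_frames(traj, window)
  if (length(fr) < 2) stop("mean_fluctuation needs at least 2 frames")
  xyz <- matrix(traj$coords[fr, atom, ], ncol = 3)
  mu <- colMeans(xyz)
  sqrt(mean(rowSums(sweep(xyz, 2, mu)^2)))
}

#' Write a per-frame series as CSV
#' @param values Numeric vector, one per frame.
#' @param times Frame times in ps.
#' @param path Output path.
#' @param value_name Column name for the values.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(values, times, path, value_name = "value") {
  df <- data.frame(frame = seq_along(values), time_ps = times, value = values)
  names(df)[3] <- value_name
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
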
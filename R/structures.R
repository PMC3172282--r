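## Structure and trajectory containers plus readers/writers for the
## plain-text formats the pipeline touches (fixed-column PDB, XYZ,
## CSV parameter sidecars).

#' Construct a structure model
#'
#' A `structure_model` holds one atom table that every trajectory frame
#' references. Atom order is stable; selections resolve to indices into it.
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `residue_name`, `residue_number`, `chain_id` and optionally `charge`,
#'   `lj_sigma`, `lj_epsilon`, `vdw_radius`.
#' @param title Free-text title.
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(atoms, title = "") {
  required <- c("serial", "name", "element", "residue_name",
                "residue_number", "chain_id")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols))
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(atoms$serial))
    stop("duplicate atom serial(s): ",
         paste(unique(atoms$serial[duplicated(atoms$serial)]), collapse = ", "))
  for (col in c("charge", "lj_sigma", "lj_epsilon", "vdw_radius"))
    if (is.null(atoms[[col]])) atoms[[col]] <- NA_real_
  atoms$backbone <- atoms$name %in% .backbone_names &
    !(atoms$residue_name %in% c("HOH", "WAT"))
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, title = title), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  a <- x$atoms
  cat("structure_model: ", nrow(a), " atoms, ",
      length(unique(paste(a$chain_id, a$residue_number))), " residues, chains ",
      paste(sort(unique(a$chain_id)), collapse = ","), "\n", sep = "")
  if (nzchar(x$title)) cat("  title: ", x$title, "\n", sep = "")
  invisible(x)
}

.n_atoms <- function(structure) nrow(structure$atoms)

#' Construct a trajectory
#'
#' @param structure A [structure_model()].
#' @param coords Numeric array of dimension `(n_frames, n_atoms, 3)`,
#'   Angstrom, or a list of `n_atoms x 3` matrices.
#' @param dt Frame interval in ps.
#' @return An object of class `trajectory` with frame times `0, dt, 2 dt, ...`.
#' @export
trajectory <- function(structure, coords, dt = 1) {
  if (is.list(coords)) {
    n <- length(coords)
    arr <- array(NA_real_, c(n, .n_atoms(structure), 3))
    for (i in seq_len(n)) arr[i, , ] <- coords[[i]]
    coords <- arr
  }
  stopifnot(length(dim(coords)) == 3, dim(coords)[3] == 3)
  if (dim(coords)[2] != .n_atoms(structure))
    stop("coordinate atom count (", dim(coords)[2],
         ") does not match structure atom count (", .n_atoms(structure), ")")
  if (dt <= 0) stop("dt must be positive")
  structure(list(structure = structure, coords = coords, dt = dt,
                 times = (seq_len(dim(coords)[1]) - 1) * dt),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory: ", n_frames(x), " frames x ", .n_atoms(x$structure),
      " atoms, dt = ", x$dt, " ps (",
      format((n_frames(x) - 1) * x$dt), " ps total)\n", sep = "")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A [trajectory()].
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' Extract one frame as an `n_atoms x 3` matrix
#' @param traj A [trajectory()].
#' @param i Frame index (1-based).
#' @return Numeric matrix of coordinates in Angstrom.
#' @export
frame_coords <- function(traj, i) {
  if (i < 1 || i > n_frames(traj)) stop("frame index out of range: ", i)
  matrix(traj$coords[i, , ], ncol = 3)
}

## Resolve an analysis window to a frame-index vector.
.window_frames <- function(traj, window = NULL) {
  n <- n_frames(traj)
  if (is.null(window)) return(seq_len(n))
  stopifnot(length(window) == 2)
  if (window[1] < 1 || window[2] > n || window[1] > window[2])
    stop("window [", window[1], ", ", window[2],
         "] invalid for trajectory of ", n, " frames")
  seq(window[1], window[2])
}

## ---------------------------------------------------------------------------
## PDB reading. bio3d does the fixed-column parse; a validation pass on the
## raw lines supplies line-numbered errors bio3d does not report.

.validate_pdb_lines <- function(lines) {
  rec <- substr(lines, 1, 6)
  idx <- which(rec %in% c("ATOM  ", "HETATM"))
  for (i in idx) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop("malformed ATOM/HETATM line ", i, ": shorter than coordinate field")
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38), substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (anyNA(xyz))
      stop("malformed ATOM/HETATM line ", i, ": non-numeric coordinates")
  }
  idx
}

.guess_element <- function(name, residue_name) {
  nm <- gsub("[0-9']", "", toupper(trimws(name)))
  two <- c("FE", "ZN", "MG", "MN", "NA", "CL", "CA", "BR", "SE")
  # metal residues first so calcium "CA" beats alpha-carbon "CA"
  if (nm %in% two && toupper(trimws(residue_name)) %in% c(two, "FE2", "ZN2"))
    return(substr(paste0(substr(nm, 1, 1), tolower(substr(nm, 2, 2))), 1, 2))
  if (grepl("^[0-9]", trimws(name))) nm <- sub("^H.*", "H", nm)  # 1HB style
  first <- substr(nm, 1, 1)
  if (first %in% c("H", "C", "N", "O", "S", "P")) first else substr(nm, 1, 2)
}

.atoms_from_bio3d <- function(at, title = "") {
  elem <- trimws(at$elesy)
  need <- which(is.na(elem) | elem == "")
  if (length(need))
    elem[need] <- vapply(need, function(i)
      .guess_element(at$elety[i], at$resid[i]), character(1))
  atoms <- data.frame(
    serial = as.integer(at$eleno),
    name = trimws(at$elety),
    element = elem,
    residue_name = trimws(at$resid),
    residue_number = as.integer(at$resno),
    chain_id = ifelse(is.na(at$chain) | at$chain == "", " ", at$chain),
    stringsAsFactors = FALSE)
  structure_model(atoms, title = title)
}

#' Read a structure from a PDB file
#'
#' Parses ATOM/HETATM records under the fixed-column PDB convention (first
#' model only). Alternate locations other than blank or `A` are dropped.
#'
#' @param path Path to a PDB file.
#' @return A [structure_model()] with one atom per retained record and
#'   coordinates of the first model attached as attribute `"coords"`.
#' @export
read_structure <- function(path) {
  lines <- readLines(path, warn = FALSE)
  .validate_pdb_lines(lines)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE,
                                          verbose = FALSE))
  keep <- which(pdb$atom$alt %in% c("", "A") | is.na(pdb$atom$alt))
  at <- pdb$atom[keep, , drop = FALSE]
  if (anyDuplicated(at$eleno))
    stop("duplicate atom serial(s): ",
         paste(unique(at$eleno[duplicated(at$eleno)]), collapse = ", "))
  sm <- .atoms_from_bio3d(at, title = basename(path))
  attr(sm, "coords") <- cbind(at$x, at$y, at$z)
  sm
}

#' Read a trajectory from multi-model PDB or XYZ
#'
#' @param path Path to the trajectory file.
#' @param structure The [structure_model()] the frames reference.
#' @param dialect `"pdb"` (models delimited by MODEL/ENDMDL) or `"xyz"`.
#' @param dt Frame interval in ps.
#' @return A [trajectory()]; frame times are `0, dt, 2 dt, ...`.
#' @export
read_trajectory <- function(path, structure, dialect = c("pdb", "xyz"),
                            dt = 1) {
  dialect <- match.arg(dialect)
  n_atoms <- .n_atoms(structure)
  if (dialect == "xyz") {
    frames <- .read_xyz_frames(path)
  } else {
    lines <- readLines(path, warn = FALSE)
    .validate_pdb_lines(lines)
    rec <- substr(lines, 1, 6)
    model_start <- which(rec == "MODEL ")
    if (length(model_start) == 0) model_start <- 1
    breaks <- c(model_start, length(lines) + 1)
    frames <- vector("list", length(model_start))
    for (k in seq_along(model_start)) {
      blk <- lines[breaks[k]:(breaks[k + 1] - 1)]
      isat <- substr(blk, 1, 6) %in% c("ATOM  ", "HETATM")
      at <- blk[isat]
      frames[[k]] <- cbind(as.numeric(substr(at, 31, 38)),
                           as.numeric(substr(at, 39, 46)),
                           as.numeric(substr(at, 47, 54)))
    }
  }
  for (k in seq_along(frames))
    if (nrow(frames[[k]]) != n_atoms)
      stop("frame ", k, ": atom count ", nrow(frames[[k]]),
           " does not match structure atom count ", n_atoms)
  trajectory(structure, frames, dt = dt)
}

.read_xyz_frames <- function(path) {
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  i <- 1L
  k <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("XYZ parse error at line ", i, ": expected atom count")
    if (i + 1L + n > length(lines))
      stop("XYZ frame ", k + 1L, " truncated: expected ", n, " atom lines")
    body <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(body), "[[:space:]]+")
    bad <- which(lengths(parts) < 4)
    if (length(bad))
      stop("XYZ parse error at line ", i + 1L + bad[1], ": expected 'el x y z'")
    m <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    k <- k + 1L
    frames[[k]] <- m
    i <- i + 2L + n
  }
  if (k == 0L) stop("no frames found in XYZ file")
  frames
}

## ---------------------------------------------------------------------------
## Writers.

.pdb_atom_line <- function(serial, name, resname, chain, resno, xyz, element) {
  nm <- if (nchar(name) < 4 && nchar(element) == 1)
    sprintf(" %-3s", name) else sprintf("%-4s", name)
  sprintf("ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial %% 100000, nm, resname, chain, resno %% 10000,
          xyz[1], xyz[2], xyz[3], 1, 0, toupper(element))
}

#' Write a structure or trajectory in PDB format
#'
#' Trajectories are written as multi-model PDB (MODEL/ENDMDL); coordinates
#' carry the format's three-decimal precision.
#'
#' @param x A [structure_model()] (with a `"coords"` attribute or `coords`
#'   supplied) or a [trajectory()].
#' @param path Output path.
#' @param coords Optional `n_atoms x 3` matrix when `x` is a structure.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path, coords = NULL) {
  if (inherits(x, "trajectory")) {
    sm <- x$structure
    out <- character(0)
    for (f in seq_len(n_frames(x))) {
      out <- c(out, sprintf("MODEL %8d", f),
               .pdb_block(sm, frame_coords(x, f)), "ENDMDL")
    }
    writeLines(c(sprintf("TITLE     %s", sm$title), out, "END"), path)
  } else {
    if (is.null(coords)) coords <- attr(x, "coords")
    if (is.null(coords)) stop("no coordinates supplied for structure")
    writeLines(c(sprintf("TITLE     %s", x$title),
                 .pdb_block(x, coords), "END"), path)
  }
  invisible(path)
}

.pdb_block <- function(sm, coords) {
  a <- sm$atoms
  vapply(seq_len(nrow(a)), function(i)
    .pdb_atom_line(a$serial[i], a$name[i], a$residue_name[i], a$chain_id[i],
                   a$residue_number[i], coords[i, ], a$element[i]),
    character(1))
}

#' Write a trajectory in XYZ format
#'
#' @param traj A [trajectory()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(traj, path) {
  sm <- traj$structure
  el <- sm$atoms$element
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    xyz <- frame_coords(traj, f)
    writeLines(c(sprintf("%d", .n_atoms(sm)),
                 sprintf("frame %d t= %g ps %s", f, traj$times[f], sm$title),
                 sprintf("%-2s %12.6f %12.6f %12.6f", el,
                         xyz[, 1], xyz[, 2], xyz[, 3])), con)
  }
  invisible(path)
}

## ---------------------------------------------------------------------------
## Parameter sidecar.

#' Annotate atoms with charges and Lennard-Jones parameters
#'
#' Reads a CSV keyed by `(residue_name, atom_name)` with columns `charge`,
#' `lj_sigma`, `lj_epsilon`, `vdw_radius` and copies matching rows onto the
#' structure's atoms. Units: elementary charges, Angstrom, kcal/mol.
#'
#' @param structure A [structure_model()].
#' @param path Path to the parameter CSV.
#' @return The updated structure; attributes `"unmatched_atoms"` (atom indices
#'   no table row covered) and `"unmatched_keys"` (table keys matching no
#'   atom) report the join coverage.
#' @export
read_parameters <- function(structure, path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("residue_name", "atom_name")
  if (!all(need %in% names(tab)))
    stop("parameter table needs columns residue_name, atom_name")
  key <- paste(tab$residue_name, tab$atom_name)
  if (anyDuplicated(key))
    stop("duplicate parameter key(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  a <- structure$atoms
  akey <- paste(a$residue_name, a$name)
  hit <- match(akey, key)
  for (col in intersect(c("charge", "lj_sigma", "lj_epsilon", "vdw_radius"),
                        names(tab)))
    a[[col]][!is.na(hit)] <- tab[[col]][hit[!is.na(hit)]]
  structure$atoms <- a
  attr(structure, "unmatched_atoms") <- which(is.na(hit))
  attr(structure, "unmatched_keys") <- setdiff(key, akey)
  if (length(attr(structure, "unmatched_keys")))
    warning("parameter keys matching no atom: ",
            paste(attr(structure, "unmatched_keys"), collapse = "; "))
  structure
}

## ---------------------------------------------------------------------------
## Selections.

#' Resolve an atom selection
#'
#' Selections are (chain, residue, atom-name) predicates. Each argument
#' left `NULL` matches everything; `backbone`/`sidechain` restrict by the
#' main-chain atom-name convention. Clause order never affects the result:
#' indices come back sorted.
#'
#' @param structure A [structure_model()].
#' @param chain Chain id(s) or `NULL`.
#' @param residues Residue number(s) or `NULL`.
#' @param names Atom name(s) or `NULL`.
#' @param residue_names Residue name(s) or `NULL`.
#' @param backbone `NA` (either), `TRUE` (main chain only) or `FALSE`
#'   (side chain only; waters count as side chain).
#' @return Sorted integer vector of atom indices, class `atom_selection`.
#'   An empty result is an error, never a silent empty vector.
#' @export
resolve_selection <- function(structure, chain = NULL, residues = NULL,
                              names = NULL, residue_names = NULL,
                              backbone = NA) {
  a <- structure$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain)) keep <- keep & a$chain_id %in% chain
  if (!is.null(residues)) keep <- keep & a$residue_number %in% residues
  if (!is.null(names)) keep <- keep & a$name %in% names
  if (!is.null(residue_names)) keep <- keep & a$residue_name %in% residue_names
  if (!is.na(backbone)) keep <- keep & (a$backbone == backbone)
  idx <- which(keep)
  if (!length(idx))
    stop("empty selection: chain=", paste(chain, collapse = ","),
         " residues=", paste(residues, collapse = ","),
         " names=", paste(names, collapse = ","))
  structure(sort(unique(idx)), class = "atom_selection")
}

#' Human-readable atom labels
#' @param structure A [structure_model()].
#' @param idx Atom indices.
#' @return Character vector like `"B/M3L9/CZ1"`.
#' @export
atom_labels <- function(structure, idx) {
  if (!length(idx)) return(character(0))
  a <- structure$atoms
  paste0(a$chain_id[idx], "/", a$residue_name[idx], a$residue_number[idx],
         "/", a$name[idx])
}
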
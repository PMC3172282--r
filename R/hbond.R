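## Geometric hydrogen-bond detection: strict N/O-donor criteria
## (R < 3.00 Angstrom, 120 < theta <= 180) and loose C-H...O screening
## (R < 3.4 Angstrom), occupancy over a trajectory window, and
## main-chain/side-chain and interface/intra-chain classification.

#' Hydrogen-bond geometric criteria
#'
#' `R` is the donor-acceptor heavy-atom distance; `theta` is the
#' donor-hydrogen-acceptor angle. Strict defaults R < 3.00 Angstrom,
#' 120 < theta <= 180; the loose C-H...O screen uses R < 3.4 Angstrom with
#' the same angle window. `distance_definition = "hydrogen-acceptor"` is
#' exposed as the alternative reading of R.
#'
#' @param r_max Distance cutoff, Angstrom.
#' @param theta_min,theta_max Angle window, degrees.
#' @param mode `"strict"` (N/O donors) or `"cho"` (additionally C-H donors).
#' @param distance_definition `"donor-acceptor"` (default) or
#'   `"hydrogen-acceptor"`.
#' @return Object of class `hbond_criteria`.
#' @export
hbond_criteria <- function(r_max = if (mode == "cho") 3.4 else 3.0,
                           theta_min = 120, theta_max = 180,
                           mode = c("strict", "cho"),
                           distance_definition = c("donor-acceptor",
                                                   "hydrogen-acceptor")) {
  mode <- match.arg(mode)
  stopifnot(r_max > 0, theta_min >= 0, theta_min < theta_max,
            theta_max <= 180)
  structure(list(r_max = r_max, theta_min = theta_min, theta_max = theta_max,
                 mode = mode,
                 distance_definition = match.arg(distance_definition)),
            class = "hbond_criteria")
}

## Pair each hydrogen with its heavy donor atom by name within the residue:
## H -> N (backbone), HZ1 -> NZ, HH11 -> NH1, HG -> OG/SG/CG, water H1/H2
## -> O. No bond graph is read; the name map is the pairing rule.
.donor_of_hydrogen <- function(atoms, h_idx, allow_carbon = FALSE) {
  res_atoms <- which(atoms$residue_number == atoms$residue_number[h_idx] &
                     atoms$chain_id == atoms$chain_id[h_idx] &
                     atoms$element != "H")
  if (!length(res_atoms)) return(NA_integer_)
  hname <- atoms$name[h_idx]
  if (atoms$residue_name[h_idx] %in% c("HOH", "WAT")) {
    o <- res_atoms[atoms$element[res_atoms] == "O"]
    return(if (length(o)) o[1] else NA_integer_)
  }
  stem <- sub("^[0-9]*H", "", hname)          # HZ1 -> Z1, 1HB -> B, H -> ""
  stems <- unique(c(stem, sub("[0-9]$", "", stem),   # H11 -> H1
                    sub("[0-9]+$", "", stem)))       # Z1  -> Z
  elements <- if (allow_carbon) c("N", "O", "S", "C") else c("N", "O", "S")
  for (s in stems) {
    cand <- res_atoms[sub("^[A-Z]", "", atoms$name[res_atoms]) == s &
                      atoms$element[res_atoms] %in% elements]
    if (length(cand) > 1)  # amide H prefers N over the carbonyl O
      cand <- cand[order(match(atoms$element[cand], elements))]
    if (length(cand)) return(cand[1])
  }
  NA_integer_
}

#' Enumerate donor/hydrogen/acceptor candidate triples
#'
#' Strict mode: donors are N/O (and S) heavy atoms carrying a name-paired
#' hydrogen; acceptors are all N/O atoms. `cho` mode additionally admits
#' C-H donor pairs. The acceptor must differ from the donor heavy atom.
#'
#' @param structure A [structure_model()] containing hydrogens.
#' @param mode `"strict"` or `"cho"`.
#' @return data.frame with columns `donor`, `hydrogen`, `acceptor`
#'   (atom indices).
#' @export
enumerate_dha_triples <- function(structure, mode = c("strict", "cho")) {
  mode <- match.arg(mode)
  a <- structure$atoms
  h_idx <- which(a$element == "H")
  if (!length(h_idx))
    stop("structure contains no hydrogens; ",
         "geometric donor-H-acceptor criteria cannot apply")
  donors <- vapply(h_idx, function(i)
    .donor_of_hydrogen(a, i, allow_carbon = mode == "cho"), integer(1))
  keep <- !is.na(donors) &
    (a$element[donors] %in% c("N", "O", "S") |
       (mode == "cho" & a$element[donors] == "C"))
  h_idx <- h_idx[keep]; donors <- donors[keep]
  acceptors <- which(a$element %in% c("N", "O"))
  if (!length(h_idx) || !length(acceptors))
    return(data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0)))
  out <- expand.grid(k = seq_along(h_idx), acceptor = acceptors)
  out <- data.frame(donor = donors[out$k], hydrogen = h_idx[out$k],
                    acceptor = out$acceptor)
  out <- out[out$acceptor != out$donor & out$acceptor != out$hydrogen, ]
  rownames(out) <- NULL
  out
}

## Angle D-H-A in degrees for coordinate matrices (one row per triple).
.dha_angle <- function(d, h, a) {
  v1 <- d - h; v2 <- a - h
  cosang <- rowSums(v1 * v2) /
    sqrt(rowSums(v1^2) * rowSums(v2^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Detect satisfied hydrogen bonds in one frame
#'
#' A triple is satisfied iff `R < r_max` and
#' `theta_min < theta <= theta_max`.
#'
#' @param coords `n_atoms x 3` coordinate matrix.
#' @param triples data.frame from [enumerate_dha_triples()].
#' @param criteria A [hbond_criteria()].
#' @return Logical vector, one per triple.
#' @export
detect_frame <- function(coords, triples, criteria = hbond_criteria()) {
  if (!nrow(triples)) return(logical(0))
  d <- coords[triples$donor, , drop = FALSE]
  h <- coords[triples$hydrogen, , drop = FALSE]
  a <- coords[triples$acceptor, , drop = FALSE]
  r <- if (criteria$distance_definition == "donor-acceptor")
    sqrt(rowSums((d - a)^2)) else sqrt(rowSums((h - a)^2))
  th <- .dha_angle(d, h, a)
  r < criteria$r_max & th > criteria$theta_min & th <= criteria$theta_max
}

#' Hydrogen-bond occupancy over a trajectory
#'
#' Occupancy is the satisfied-frame count divided by the window length.
#' Mean distance and mean deviation from linearity (180 - theta) are taken
#' over satisfied frames only. Triples never satisfied are dropped.
#'
#' @param traj A [trajectory()].
#' @param triples data.frame from [enumerate_dha_triples()] (default:
#'   enumerate on the trajectory's structure with the criteria's mode).
#' @param criteria A [hbond_criteria()].
#' @param window Optional `c(start, end)` frame window.
#' @return Object of class `hbond_records`: data.frame with donor/hydrogen/
#'   acceptor labels and indices, `occupancy`, `mean_distance`,
#'   `mean_linearity_deviation`.
#' @export
hbond_occupancy <- function(traj, triples = NULL,
                            criteria = hbond_criteria(), window = NULL) {
  fr <- .window_frames(traj, window)
  if (!length(fr)) stop("empty analysis window")
  if (is.null(triples))
    triples <- enumerate_dha_triples(traj$structure, mode = criteria$mode)
  nt <- nrow(triples)
  if (!nt)
    return(structure(data.frame(), class = c("hbond_records", "data.frame")))
  sat <- matrix(FALSE, length(fr), nt)
  rmat <- matrix(NA_real_, length(fr), nt)
  thmat <- matrix(NA_real_, length(fr), nt)
  for (w in seq_along(fr)) {
    xyz <- frame_coords(traj, fr[w])
    d <- xyz[triples$donor, , drop = FALSE]
    h <- xyz[triples$hydrogen, , drop = FALSE]
    a <- xyz[triples$acceptor, , drop = FALSE]
    rmat[w, ] <- if (criteria$distance_definition == "donor-acceptor")
      sqrt(rowSums((d - a)^2)) else sqrt(rowSums((h - a)^2))
    thmat[w, ] <- .dha_angle(d, h, a)
    sat[w, ] <- rmat[w, ] < criteria$r_max & thmat[w, ] > criteria$theta_min &
      thmat[w, ] <= criteria$theta_max
  }
  occ <- colMeans(sat)
  keep <- which(occ > 0)
  sm <- traj$structure
  rec <- data.frame(
    donor = atom_labels(sm, triples$donor[keep]),
    hydrogen = atom_labels(sm, triples$hydrogen[keep]),
    acceptor = atom_labels(sm, triples$acceptor[keep]),
    donor_idx = triples$donor[keep], hydrogen_idx = triples$hydrogen[keep],
    acceptor_idx = triples$acceptor[keep],
    occupancy = occ[keep],
    mean_distance = vapply(keep, function(k) mean(rmat[sat[, k], k]),
                           numeric(1)),
    mean_linearity_deviation = vapply(keep, function(k)
      mean(180 - thmat[sat[, k], k]), numeric(1)),
    row.names = NULL)
  structure(rec, class = c("hbond_records", "data.frame"))
}

#' Classify hydrogen bonds by chain span and backbone character
#'
#' Donor/acceptor classes come from the main-chain atom-name convention
#' (waters always count as side chain). The span is `interface` when donor
#' and acceptor sit on different chains, `intra-substrate` when both are on
#' the substrate chain, `intra-enzyme` when both are on the enzyme chain.
#'
#' @param records An `hbond_records` from [hbond_occupancy()].
#' @param structure The [structure_model()] the records reference.
#' @param substrate_chain,enzyme_chain Chain ids. Water chains are treated
#'   as belonging to neither; a bond touching them is classed by its other
#'   partner's chain, or `water-mediated` when both ends are water.
#' @return The records with `donor_class`, `acceptor_class`, `span_class`
#'   columns added.
#' @export
classify_bond <- function(records, structure, substrate_chain = "B",
                          enzyme_chain = "A") {
  a <- structure$atoms
  water <- a$residue_name %in% c("HOH", "WAT")
  side <- function(idx) {
    ch <- a$chain_id[idx]
    out <- ifelse(water[idx], "water",
                  ifelse(ch == substrate_chain, "substrate",
                         ifelse(ch == enzyme_chain, "enzyme", NA)))
    if (anyNA(out))
      stop("atom(s) on neither declared chain: ",
           paste(atom_labels(structure, idx[is.na(out)]), collapse = ", "))
    out
  }
  bbclass <- function(idx) ifelse(a$backbone[idx], "main chain", "side chain")
  ds <- side(records$donor_idx)
  as_ <- side(records$acceptor_idx)
  span <- ifelse(ds == "water" & as_ == "water", "water-mediated",
          ifelse(ds == "water" | as_ == "water", paste0("water-",
                 ifelse(ds == "water", as_, ds)),
          ifelse(ds != as_, "interface",
          ifelse(ds == "substrate", "intra-substrate", "intra-enzyme"))))
  records$donor_class <- bbclass(records$donor_idx)
  records$acceptor_class <- bbclass(records$acceptor_idx)
  records$span_class <- span
  records
}

#' @export
print.hbond_records <- function(x, ...) {
  if (!nrow(x)) {
    cat("hbond_records: no satisfied hydrogen bonds\n")
    return(invisible(x))
  }
  cat("hbond_records:", nrow(x), "bond(s)\n")
  df <- data.frame(donor = x$donor, acceptor = x$acceptor,
                   occupancy = round(x$occupancy, 3),
                   R = round(x$mean_distance, 2),
                   dev = round(x$mean_linearity_deviation, 1))
  if (!is.null(x$span_class)) df$span <- x$span_class
  print(df, row.names = FALSE)
  invisible(x)
}
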
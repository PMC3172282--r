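## Configuration-driven runner: orchestrates the analyses in the order the
## study applies them (RMSD -> dihedrals -> states/barriers -> sphere
## occupancy -> distances -> H-bonds -> clash scan -> interface energy)
## and writes a reproducible report bundle.

.pipeline_stages <- c("rmsd", "dihedrals", "states", "occupancy",
                      "distances", "hbonds", "clashes", "energy")

#' Build a run configuration
#'
#' Either `synthetic` (a list with `case` in me1/me2/me3, `n_frames`, `dt`)
#' or `structure`/`trajectory` input paths must be given. All analysis
#' thresholds default to the study's values: sphere radii 4.6-4.8 Angstrom,
#' strict H-bond criteria, clash tolerance 0.4 Angstrom, dielectric 4,
#' temperature 310 K.
#'
#' @param synthetic `NULL` or list(case, n_frames, dt, hydrogens).
#' @param structure,trajectory,parameters Input paths (`NULL` when
#'   synthetic).
#' @param dialect Trajectory dialect for file input, `"pdb"` or `"xyz"`.
#' @param dt Frame interval in ps for file input.
#' @param substrate_chain,enzyme_chain Chain ids.
#' @param window `NULL` or `c(start, end)` frames.
#' @param radii Occupancy sweep radii, Angstrom.
#' @param hbond_mode `"strict"` or `"cho"`.
#' @param clash_tolerance Angstrom.
#' @param dielectric Unitless.
#' @param temperature Kelvin.
#' @param stages Character vector of stages to run (default all).
#' @param seed Integer seed.
#' @param out_dir Output directory.
#' @return Object of class `run_config` (a validated list).
#' @export
run_config <- function(synthetic = list(case = "me3", n_frames = 10000,
                                        dt = 1, hydrogens = FALSE),
                       structure = NULL, trajectory = NULL,
                       parameters = NULL, dialect = "xyz", dt = 1,
                       substrate_chain = "B", enzyme_chain = "A",
                       window = NULL, radii = c(4.6, 4.7, 4.8),
                       hbond_mode = "strict", clash_tolerance = 0.4,
                       dielectric = 4, temperature = 310,
                       stages = .pipeline_stages, seed = 1,
                       out_dir = "pocketdyn_run") {
  cfg <- list(synthetic = synthetic, structure = structure,
              trajectory = trajectory, parameters = parameters,
              dialect = dialect, dt = dt,
              substrate_chain = substrate_chain,
              enzyme_chain = enzyme_chain, window = window, radii = radii,
              hbond_mode = hbond_mode, clash_tolerance = clash_tolerance,
              dielectric = dielectric, temperature = temperature,
              stages = stages, seed = as.integer(seed), out_dir = out_dir)
  problems <- character(0)
  if (is.null(cfg$synthetic)) {
    if (is.null(cfg$structure) || !file.exists(cfg$structure))
      problems <- c(problems, paste("missing structure file:",
                                    cfg$structure))
    if (is.null(cfg$trajectory) || !file.exists(cfg$trajectory))
      problems <- c(problems, paste("missing trajectory file:",
                                    cfg$trajectory))
  } else if (!isTRUE(cfg$synthetic$case %in% c("me1", "me2", "me3")))
    problems <- c(problems, "synthetic$case must be me1, me2 or me3")
  bad <- setdiff(cfg$stages, .pipeline_stages)
  if (length(bad))
    problems <- c(problems, paste("unknown stage(s):",
                                  paste(bad, collapse = ", ")))
  if (!is.null(cfg$window) &&
      (length(cfg$window) != 2 || cfg$window[1] > cfg$window[2]))
    problems <- c(problems, "window must be c(start, end), start <= end")
  if (length(problems))
    stop("invalid configuration:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a YAML file
#' @param path YAML file with the [run_config()] keys.
#' @return A validated `run_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("missing config file: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (k in c("window", "radii")) if (!is.null(raw[[k]]))
    raw[[k]] <- as.numeric(unlist(raw[[k]]))
  do.call(run_config, raw)
}

.config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                              null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Deterministic given the configuration (including its seed): repeated
#' runs write byte-identical tables. Each stage's table lands in
#' `out_dir`; a `manifest.json` records the config hash, seed, package
#' version and per-stage status, and `report.json` the headline numbers.
#' Failure of one stage is recorded and the remaining stages still run.
#'
#' @param config A [run_config()] (or a path to a YAML config).
#' @return Invisibly, a list with the stage results, statuses and paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  log_msg <- function(...) message("[pocketdyn ", sprintf(
    "%7.2fs", proc.time()[["elapsed"]] - t0), "] ", ...)

  ## --- inputs -------------------------------------------------------------
  sim <- NULL
  if (!is.null(config$synthetic)) {
    s <- config$synthetic
    me <- as.integer(substr(s$case, 3, 3))
    log_msg("generating synthetic ", s$case, " trajectory: ",
            s$n_frames, " frames, seed ", config$seed)
    sim <- simulate_rotamer_trajectory(
      kinetics_preset(s$case, temperature = config$temperature),
      pocket_spec(me, hydrogens = isTRUE(s$hydrogens)),
      n_frames = s$n_frames, dt = if (is.null(s$dt)) 1 else s$dt,
      seed = config$seed)
    traj <- sim$trajectory
  } else {
    log_msg("reading structure ", config$structure)
    sm <- read_structure(config$structure)
    if (!is.null(config$parameters))
      sm <- read_parameters(sm, config$parameters)
    log_msg("reading trajectory ", config$trajectory)
    traj <- read_trajectory(config$trajectory, sm,
                            dialect = config$dialect, dt = config$dt)
  }
  sm <- traj$structure
  window <- config$window
  report <- list()
  status <- list()
  results <- list()

  ## selections shared by several stages; resolved up front so a broken
  ## selection fails the run before any stage output is written
  sub_sel <- resolve_selection(sm, chain = config$substrate_chain)
  methyls <- which(grepl("^CZ[0-9]$", sm$atoms$name) &
                   sm$atoms$chain_id == config$substrate_chain)
  quad <- c(which(sm$atoms$name == "CD" &
                  sm$atoms$chain_id == config$substrate_chain),
            which(sm$atoms$name == "CE" &
                  sm$atoms$chain_id == config$substrate_chain),
            which(sm$atoms$name == "NZ" &
                  sm$atoms$chain_id == config$substrate_chain))
  fe <- which(sm$atoms$name == "FE")

  run_stage <- function(name, fun) {
    if (!name %in% config$stages) {
      status[[name]] <<- "skipped"
      return(invisible(NULL))
    }
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      status[[name]] <<- paste("failed:", conditionMessage(res))
      log_msg("stage ", name, " failed: ", conditionMessage(res))
    } else {
      status[[name]] <<- "ok"
      results[[name]] <<- res
      log_msg("stage ", name, " done")
    }
  }

  run_stage("rmsd", function() {
    vals <- rmsd_series(traj, subset = sub_sel)
    write_series_csv(vals, traj$times, file.path(out, "rmsd.csv"),
                     "rmsd_A")
    report$rmsd_mean_A <<- mean(vals)
    vals
  })

  dihedrals <- NULL
  run_stage("dihedrals", function() {
    if (length(quad) < 3 || !length(methyls))
      stop("no CD/CE/NZ/CZx quad on the substrate chain")
    ser <- lapply(methyls, function(cz)
      dihedral_series(traj, c(quad, cz), label = sm$atoms$name[cz]))
    df <- data.frame(frame = seq_len(n_frames(traj)), time_ps = traj$times)
    for (s in ser) df[[paste0("torsion_", s$label)]] <- s$values
    utils::write.csv(df, file.path(out, "dihedrals.csv"), row.names = FALSE)
    dihedrals <<- ser
    ser
  })

  run_stage("states", function() {
    if (is.null(dihedrals)) stop("dihedrals stage did not run")
    states <- lapply(dihedrals, assign_states)
    stats <- state_statistics(states[[1]], temperature = config$temperature,
                              window = window)
    write_state_csv(stats, out)
    comb <- combine_equivalent_methyls(states)
    report$populations <<- as.list(stats$populations)
    report$any_methyl_trans_fraction <<- comb$any_t_fraction
    report$relative_energies_kcal <<- as.list(stats$relative_energies)
    list(stats = stats, combined = comb)
  })

  run_stage("occupancy", function() {
    if (!length(fe) || !length(methyls)) stop("no Fe or methyl carbons")
    sw <- radius_sweep(traj, fe[1], methyls, radii = config$radii,
                       window = window)
    utils::write.csv(as.data.frame(sw), file.path(out, "occupancy.csv"),
                     row.names = FALSE)
    mid <- which.min(abs(config$radii - 4.7))
    report$occupancy_union_4p7 <<- sw[[mid]]$union_fraction
    report$occupancy_sum_4p7 <<- sw[[mid]]$sum_fraction
    sw
  })

  run_stage("distances", function() {
    nz <- which(sm$atoms$name == "NZ" &
                sm$atoms$chain_id == config$substrate_chain)
    pocket_ox <- which(sm$atoms$element == "O" &
                       sm$atoms$chain_id == config$enzyme_chain)
    waters <- which(sm$atoms$residue_name %in% c("HOH", "WAT") &
                    sm$atoms$name == "O")
    rows <- NULL
    add_pair <- function(a, b) {
      ds <- distance_stats(traj, a, b, window = window)
      rows <<- rbind(rows, data.frame(
        atom_a = ds$pair[1], atom_b = ds$pair[2],
        mean_A = ds$mean, std_A = ds$std))
    }
    for (o in pocket_ox) add_pair(nz[1], o)
    if (length(fe)) for (w in waters) add_pair(fe[1], w)
    if (length(fe)) {
      fluct <- mean_fluctuation(traj, fe[1], window = window)
      report$fe_fluctuation_A <<- fluct
      rows <- rbind(rows, data.frame(atom_a = "FE", atom_b = "(mean pos)",
                                     mean_A = fluct, std_A = NA))
    }
    if (length(fe) && length(waters))
      report$fe_water_mean_A <<- mean(vapply(waters, function(w)
        distance_stats(traj, fe[1], w, window = window)$mean, numeric(1)))
    utils::write.csv(rows, file.path(out, "distances.csv"),
                     row.names = FALSE)
    rows
  })

  run_stage("hbonds", function() {
    crit <- hbond_criteria(mode = config$hbond_mode)
    if (!any(sm$atoms$element == "H")) {
      utils::write.csv(data.frame(), file.path(out, "hbonds.csv"),
                       row.names = FALSE)
      report$n_hbonds <<- 0
      return("no hydrogens in structure; empty census")
    }
    rec <- hbond_occupancy(traj, criteria = crit, window = window)
    if (nrow(rec))
      rec <- classify_bond(rec, sm, config$substrate_chain,
                           config$enzyme_chain)
    utils::write.csv(as.data.frame(rec), file.path(out, "hbonds.csv"),
                     row.names = FALSE)
    report$n_hbonds <<- nrow(rec)
    rec
  })

  run_stage("clashes", function() {
    if (length(quad) < 3 || !length(methyls))
      stop("no head to rotate")
    head <- which(sm$atoms$chain_id == config$substrate_chain &
                  !sm$atoms$name %in% c("CD", "CE", "NZ"))
    env <- setdiff(seq_len(.n_atoms(sm)), c(head, quad))
    scan <- rotation_scan(frame_coords(traj, 1), sm, head,
                          quad[2], quad[3], env,
                          tolerance = config$clash_tolerance)
    utils::write.csv(as.data.frame(scan), file.path(out, "clashes.csv"),
                     row.names = FALSE)
    report$clash_counts <<- stats::setNames(
      lapply(scan, function(r) r$clash_count),
      paste0("deg_", vapply(scan, function(r) r$rotation_angle, numeric(1))))
    scan
  })

  run_stage("energy", function() {
    enz <- resolve_selection(sm, chain = config$enzyme_chain)
    dec <- interface_decomposition(
      traj, enz, sub_sel,
      params = nonbonded_params(dielectric = config$dielectric),
      window = window)
    utils::write.csv(as.data.frame(dec), file.path(out, "energy.csv"),
                     row.names = FALSE)
    tot <- interface_totals(dec)
    report$interface_total_kcal <<- tot$total[1]
    report$interface_vdw_kcal <<- tot$vdw[1]
    report$interface_coulomb_kcal <<- tot$coulomb[1]
    dec
  })

  manifest <- list(
    package = "pocketdyn",
    version = as.character(utils::packageVersion("pocketdyn")),
    config_hash = .config_hash(config),
    seed = config$seed,
    stages = status)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_msg("bundle written to ", out)
  invisible(list(results = results, status = status, report = report,
                 manifest = manifest, out_dir = out, sim = sim))
}
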
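#' Evaluate geometry metrics along a trajectory
#'
#' Metric specifications are strings:
#' \describe{
#'   \item{\code{"distance:A3,B1"}}{COM distance between two domains (A).}
#'   \item{\code{"angle:A1,A2,A3"}}{COM angle at the middle domain (deg).}
#'   \item{\code{"torsion:B1,B2,B3,A1"}}{signed COM dihedral (deg).}
#'   \item{\code{"handedness"}}{sum of the topology's three interface
#'     torsions (deg).}
#'   \item{\code{"rotation:A1,A2"}}{signed inter-domain rotation relative to
#'     the first frame (deg).}
#'   \item{\code{"rmsd100"}}{C-alpha RMSD to the first frame after Kabsch
#'     superposition, normalised by 1 + ln(N/100) (A).}
#' }
#'
#' @param x a \code{clamp_structure} or \code{clamp_trajectory}.
#' @param topo a \code{clamp_topology}.
#' @param metrics character vector of metric specifications (non-empty).
#' @param discard_ps pre-equilibration window for downstream summaries.
#' @return named list of \code{\link{geometry_series}}.
#' @export
analyze_trajectory <- function(x, topo, metrics, discard_ps = 10000) {
  if (length(metrics) == 0L)
    .stopf("no metrics requested; supply at least one metric specification")
  if (inherits(x, "clamp_structure"))
    x <- clamp_trajectory(x, list(x$xyz))
  stopifnot(inherits(x, "clamp_trajectory"))
  asg <- assign_domains(x$template, topo)
  atoms <- x$template$atoms
  coms_per_frame <- lapply(x$frames, function(f)
    domain_coms(f, asg, atoms = atoms))

  one_metric <- function(spec) {
    parts <- strsplit(spec, ":", fixed = TRUE)[[1L]]
    kind <- parts[1L]
    doms <- if (length(parts) > 1L) strsplit(parts[2L], ",")[[1L]] else character()
    bad <- setdiff(doms, topo$ring_order)
    if (length(bad))
      .stopf("metric '%s' names unknown domain(s): %s", spec,
             paste(bad, collapse = ","))
    switch(kind,
      distance = {
        if (length(doms) != 2L) .stopf("distance metric needs 2 domains")
        vals <- vapply(coms_per_frame, function(cm)
          com_distance(cm[doms[1L], ], cm[doms[2L], ]), numeric(1L))
        geometry_series(gsub("[:,]", "_", spec), "angstrom", vals,
                        time_ps = x$time_ps, discard_ps = discard_ps)
      },
      angle = {
        if (length(doms) != 3L) .stopf("angle metric needs 3 domains")
        vals <- vapply(coms_per_frame, function(cm)
          com_angle(cm[doms[1L], ], cm[doms[2L], ], cm[doms[3L], ]),
          numeric(1L))
        geometry_series(gsub("[:,]", "_", spec), "degrees", vals,
                        time_ps = x$time_ps, discard_ps = discard_ps)
      },
      torsion = {
        if (length(doms) != 4L) .stopf("torsion metric needs 4 domains")
        vals <- vapply(coms_per_frame, function(cm)
          com_dihedral(cm[doms[1L], ], cm[doms[2L], ], cm[doms[3L], ],
                       cm[doms[4L], ]), numeric(1L))
        geometry_series(gsub("[:,]", "_", spec), "degrees", vals,
                        time_ps = x$time_ps, discard_ps = discard_ps)
      },
      handedness = {
        vals <- vapply(x$frames, function(f)
          handedness_sum(f, asg, topo, atoms = atoms), numeric(1L))
        geometry_series("handedness_sum", "degrees", vals,
                        time_ps = x$time_ps, discard_ps = discard_ps)
      },
      rotation = {
        if (length(doms) != 2L) .stopf("rotation metric needs 2 domains")
        s <- rotation_series(x, asg, doms)
        s$discard_ps <- discard_ps
        s
      },
      rmsd100 = {
        idx <- sort(unique(unlist(asg)))
        ca <- idx[trimws(atoms$elety[idx]) == "CA"]
        if (length(ca) < 3L) ca <- idx
        nres <- nrow(unique(atoms[idx, c("chain", "resno", "insert")]))
        ref <- x$frames[[1L]][ca, , drop = FALSE]
        vals <- vapply(x$frames, function(f)
          rmsd100(kabsch_superpose(ref, f[ca, , drop = FALSE])$rmsd, nres),
          numeric(1L))
        geometry_series("rmsd100", "angstrom", vals, time_ps = x$time_ps,
                        discard_ps = discard_ps)
      },
      .stopf("unknown metric kind '%s'", kind))
  }
  out <- lapply(metrics, one_metric)
  names(out) <- vapply(out, `[[`, character(1L), "metric")
  out
}

.summary_table <- function(series_list, discard_ps = NULL,
                           discard_frames = NULL) {
  do.call(rbind, lapply(series_list, function(s) {
    sm <- series_summary(s, discard_ps = discard_ps,
                         discard_frames = discard_frames)
    data.frame(metric = s$metric, unit = s$unit, mean = sm$mean, sd = sm$sd,
               n_frames = sm$n,
               discard_ps = if (is.null(discard_ps)) s$discard_ps else discard_ps,
               stringsAsFactors = FALSE)
  }))
}

#' Analyse a structure/trajectory and write metric CSVs
#'
#' End-to-end analysis command: parse the input PDB, apply the topology,
#' evaluate the requested metrics, and write a per-frame metric table
#' (\code{metrics.csv}) plus, for multi-frame input, a post-discard summary
#' (\code{summary.csv}, mean and SD after dropping the pre-equilibration
#' window).
#'
#' @param input path to a (multi-model) PDB file, or a
#'   \code{clamp_structure}/\code{clamp_trajectory}.
#' @param topology path to a topology YAML, or a \code{clamp_topology}.
#' @param metrics character vector of metric specifications
#'   (see \code{\link{analyze_trajectory}}).
#' @param output_dir directory for the CSV outputs (created if needed).
#' @param discard_ps pre-equilibration discard (default 10000 ps).
#' @param frame_dt_ps frame spacing used when the input has no times.
#' @return invisibly, list with \code{series}, \code{summary} (or NULL for
#'   single-frame input) and output \code{paths}.
#' @export
cmd_analyze <- function(input, topology, metrics, output_dir = ".",
                        discard_ps = 10000, frame_dt_ps = NULL) {
  topo <- if (inherits(topology, "clamp_topology")) topology
          else read_topology(topology)
  x <- if (is.character(input)) parse_structure(input) else input
  if (inherits(x, "clamp_trajectory") && is.null(x$time_ps) &&
      !is.null(frame_dt_ps))
    x$time_ps <- frame_dt_ps * (seq_along(x$frames) - 1L)
  series <- analyze_trajectory(x, topo, metrics, discard_ps = discard_ps)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  metrics_path <- file.path(output_dir, "metrics.csv")
  utils::write.csv(series_table(series), metrics_path, row.names = FALSE)
  paths <- metrics_path
  summary_df <- NULL
  n <- length(series[[1L]]$values)
  if (n > 2L) {
    summary_df <- .summary_table(series)
    summary_path <- file.path(output_dir, "summary.csv")
    utils::write.csv(summary_df, summary_path, row.names = FALSE)
    paths <- c(paths, summary_path)
  }
  invisible(list(series = series, summary = summary_df, paths = paths))
}

#' Build a CG clamp and run a steered ring-opening protocol
#'
#' Builds the coarse-grained system from a structure + topology (by default a
#' synthetic ideal ring), runs the requested protocol type, and writes a
#' multi-model PDB of bead pseudo-atoms plus the colvar traces CSV.
#'
#' @param model_type steering protocol type (1, 2 or 3).
#' @param output_dir output directory.
#' @param structure,topology source conformation; defaults to
#'   \code{\link{build_ideal_ring}} output.
#' @param params \code{\link{langevin_params}}.
#' @param steering_ps,post_steering_ps protocol phase durations (ps).
#' @param save_every save interval in steps.
#' @return invisibly, list with \code{trajectory} (a \code{cg_trajectory}),
#'   \code{colvars} (data.frame) and output \code{paths}.
#' @export
cmd_simulate <- function(model_type, output_dir = ".", structure = NULL,
                         topology = NULL, params = langevin_params(),
                         steering_ps = 10000, post_steering_ps = 10000,
                         save_every = 1000L) {
  if (is.null(structure) || is.null(topology)) {
    ring <- build_ideal_ring()
    structure <- ring$structure
    topology <- ring$topology
  } else if (is.character(structure)) {
    structure <- parse_structure(structure)
  }
  if (is.character(topology)) topology <- read_topology(topology)
  asg <- assign_domains(structure, topology)
  sys <- build_cg(structure, asg, topology)
  proto <- make_protocol(model_type, topology, steering_ps = steering_ps,
                         post_steering_ps = post_steering_ps)
  traj <- run_steered(sys, proto, params = params, save_every = save_every)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  cg <- cg_as_trajectory(traj)
  pdb_path <- file.path(output_dir, sprintf("cg_type%d.pdb", model_type))
  write_structure_pdb(cg$trajectory, pdb_path)
  cv <- colvar_table(traj)
  cv_path <- file.path(output_dir, sprintf("colvars_type%d.csv", model_type))
  utils::write.csv(cv, cv_path, row.names = FALSE)
  final <- cv[cv$time_ps == max(cv$time_ps), ]
  message(sprintf(
    "cmd_simulate: type %d, seed %d, %d steps; final colvar value(s): %s",
    model_type, params$seed, round((steering_ps + post_steering_ps) /
                                     params$timestep),
    paste(sprintf("%.2f", final$value), collapse = ", ")))
  invisible(list(trajectory = traj, colvars = cv,
                 paths = c(pdb_path, cv_path)))
}

#' Generate a synthetic clamp data set on disk
#'
#' Builds an ideal ring, optionally deforms it and/or generates a
#' Gaussian-rotation trajectory, and writes a multi-model PDB, the matching
#' topology YAML and the ground-truth CSV.
#'
#' @param output_dir output directory.
#' @param n_domains,ring_radius,atoms_per_domain,seed ring parameters
#'   (see \code{\link{build_ideal_ring}}).
#' @param mode optional deformation mode (see \code{\link{apply_deformation}});
#'   \code{NULL} keeps the planar ring.
#' @param twist,gap,increment deformation magnitudes.
#' @param n_frames frames to generate; 1 writes the static structure.
#' @param rotation_mean,rotation_sd,noise_sd trajectory parameters
#'   (see \code{\link{generate_trajectory}}).
#' @return invisibly, list with the objects and output \code{paths}.
#' @export
cmd_synth <- function(output_dir = ".", n_domains = 6L, ring_radius = 35,
                      atoms_per_domain = 20L, seed = 1L, mode = NULL,
                      twist = 20, gap = 20, increment = 7, n_frames = 1L,
                      rotation_mean = 13.9, rotation_sd = 4.4,
                      noise_sd = 0) {
  ring <- build_ideal_ring(n_domains = n_domains, ring_radius = ring_radius,
                           atoms_per_domain = atoms_per_domain, seed = seed)
  s <- ring$structure
  gt <- NULL
  if (!is.null(mode)) {
    s <- apply_deformation(s, ring$topology, mode = mode, twist = twist,
                           gap = gap, increment = increment)
    gt <- data.frame(what = "deformation", mode = mode,
                     magnitude = switch(mode, planar_open = gap,
                                        in_plane_angle = increment, twist))
  }
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  topo_path <- file.path(output_dir, "topology.yaml")
  write_topology(ring$topology, topo_path)
  pdb_path <- file.path(output_dir, "synthetic.pdb")
  out <- s
  if (n_frames > 1L) {
    out <- generate_trajectory(s, ring$topology, rotation_mean = rotation_mean,
                               rotation_sd = rotation_sd, noise_sd = noise_sd,
                               n_frames = n_frames, seed = seed)
    gt <- attr(out, "ground_truth")
  }
  write_structure_pdb(out, pdb_path)
  paths <- c(pdb_path, topo_path)
  if (!is.null(gt)) {
    gt_path <- file.path(output_dir, "ground_truth.csv")
    utils::write.csv(gt, gt_path, row.names = FALSE)
    paths <- c(paths, gt_path)
  }
  invisible(list(structure = s, output = out, topology = ring$topology,
                 ground_truth = gt, paths = paths))
}

#' Compute and write sphere-and-arrow output for a trajectory
#'
#' @param input path to a multi-model PDB, or a \code{clamp_trajectory}.
#' @param topology path to a topology YAML, or a \code{clamp_topology}.
#' @param output_dir output directory.
#' @param format \code{"csv"}, \code{"script"}, or both.
#' @return invisibly, list with \code{arrows} (per-frame list) and
#'   \code{paths}.
#' @export
cmd_arrows <- function(input, topology, output_dir = ".",
                       format = c("csv", "script")) {
  format <- match.arg(format, c("csv", "script"), several.ok = TRUE)
  topo <- if (inherits(topology, "clamp_topology")) topology
          else read_topology(topology)
  x <- if (is.character(input)) parse_structure(input) else input
  if (inherits(x, "clamp_structure")) x <- clamp_trajectory(x, list(x$xyz))
  asg <- assign_domains(x$template, topo)
  arrows <- arrow_series(x, asg)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  if ("csv" %in% format) {
    p <- file.path(output_dir, "arrows.csv")
    write_arrows(arrows, p, format = "csv")
    paths <- c(paths, p)
  }
  if ("script" %in% format) {
    p <- file.path(output_dir, "arrows.txt")
    write_arrows(arrows, p, format = "script")
    paths <- c(paths, p)
  }
  invisible(list(arrows = arrows, paths = paths))
}
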
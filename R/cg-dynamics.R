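#' Langevin thermostat parameters
#'
#' @param temperature temperature in K (default 310).
#' @param damping friction coefficient in ps^-1 (default 5).
#' @param timestep integration step in ps (default 0.01 = 10 fs, adequate for
#'   beads of ~10^4 amu under the default stiffness profile).
#' @param seed RNG seed; every run is bitwise reproducible given the seed.
#' @return named list of parameters.
#' @export
langevin_params <- function(temperature = 310, damping = 5, timestep = 0.01,
                            seed = 1L) {
  stopifnot(temperature >= 0, damping >= 0, timestep > 0)
  list(temperature = temperature, damping = damping, timestep = timestep,
       seed = as.integer(seed))
}

.cg_traj <- function(sys, res, protocol = NULL, params = NULL) {
  n <- length(sys$labels)
  frames <- lapply(seq_len(nrow(res$frames)), function(i) {
    m <- matrix(res$frames[i, ], ncol = 3L, byrow = TRUE)
    rownames(m) <- sys$labels
    m
  })
  structure(list(system = sys, times = as.numeric(res$times), frames = frames,
                 e_pot = as.numeric(res$e_pot), e_tot = as.numeric(res$e_tot),
                 cv_value = res$cv_value, cv_target = res$cv_target,
                 cv_energy = res$cv_energy,
                 x_final = res$x_final, v_final = res$v_final,
                 protocol = protocol, params = params),
            class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat(sprintf("<cg_trajectory> %d beads, %d saved frames, t = %g..%g ps\n",
              length(x$system$labels), length(x$frames),
              if (length(x$times)) min(x$times) else NA,
              if (length(x$times)) max(x$times) else NA))
  invisible(x)
}

#' Run Langevin dynamics on a CG clamp
#'
#' BAOAB-splitting Langevin integration (reduces to velocity Verlet at
#' temperature 0 / damping 0).  The integrator, forces and thermal noise run
#' in compiled code; the R-level seed makes trajectories bitwise reproducible.
#'
#' @param sys a \code{cg_system}.
#' @param params a \code{\link{langevin_params}} list.
#' @param n_steps number of integration steps.
#' @param restraints optional restraint list (see \code{\link{make_protocol}}).
#' @param save_every save positions/colvars every this many steps.
#' @param x0,v0 optional initial positions/velocities (default: reference
#'   positions, zero velocities).
#' @param t0 initial simulation time in ps.
#' @return A \code{cg_trajectory}: saved frames, times, potential/total
#'   energies and per-restraint colvar traces.
#' @export
run_langevin <- function(sys, params = langevin_params(), n_steps,
                         restraints = NULL, save_every = 100L,
                         x0 = NULL, v0 = NULL, t0 = 0) {
  if (is.null(x0)) x0 <- sys$x0
  if (is.null(v0)) v0 <- matrix(0, nrow(x0), 3L)
  cpp_sys <- .sys_for_cpp(sys, restraints, x = x0)
  set.seed(params$seed)
  res <- .cg_run_cpp(cpp_sys, as.matrix(x0), as.matrix(v0),
                     params$temperature, params$damping, params$timestep,
                     as.integer(n_steps), as.integer(save_every), t0)
  if (params$temperature == 0 && params$damping == 0 && length(res$e_tot) > 1L) {
    drift <- abs(diff(range(res$e_tot)))
    if (!is.finite(drift) || drift > 1e3)
      .stopf(paste0("integration unstable (energy drift %.3g kcal/mol); ",
                    "reduce the timestep"), drift)
  }
  .cg_traj(sys, res, params = params)
}

#' Run a steered ring-opening protocol with free relaxation
#'
#' Applies the protocol's moving harmonic restraints for the steering phase
#' (targets move linearly from the system's current colvar values), then
#' releases them and continues with unrestrained dynamics for the
#' post-steering phase.  Each restraint's collective-variable value, target
#' and applied energy are recorded at every saved frame.
#'
#' @param sys a \code{cg_system}.
#' @param protocol a \code{\link{make_protocol}} schedule.
#' @param params a \code{\link{langevin_params}} list.
#' @param save_every save interval in steps (default 1000 = every 10 ps at
#'   the default timestep).
#' @return A \code{cg_trajectory}; use \code{\link{colvar_table}} for the
#'   restraint traces.
#' @export
run_steered <- function(sys, protocol, params = langevin_params(),
                        save_every = 1000L) {
  stopifnot(inherits(protocol, "steering_protocol"))
  total_ps <- protocol$steering_ps + protocol$post_steering_ps
  n_steps <- round(total_ps / params$timestep)
  cpp_sys <- .sys_for_cpp(sys, protocol$restraints,
                          steering_ps = protocol$steering_ps)
  x0 <- sys$x0
  v0 <- matrix(0, nrow(x0), 3L)
  set.seed(params$seed)
  res <- .cg_run_cpp(cpp_sys, as.matrix(x0), v0,
                     params$temperature, params$damping, params$timestep,
                     as.integer(n_steps), as.integer(save_every), 0)
  .cg_traj(sys, res, protocol = protocol, params = params)
}

#' Colvar traces of a CG trajectory
#'
#' @param traj a \code{cg_trajectory} from \code{\link{run_steered}} or
#'   \code{\link{run_langevin}} with restraints.
#' @return tidy data.frame: time_ps, restraint_id, kind, value, target,
#'   energy.  Torsion values/targets are reported in degrees, distances in
#'   Angstrom.
#' @export
colvar_table <- function(traj) {
  stopifnot(inherits(traj, "cg_trajectory"))
  cv <- traj$cv_value
  if (is.null(cv) || ncol(cv) == 0L)
    return(data.frame(time_ps = numeric(), restraint_id = integer(),
                      kind = character(), value = numeric(),
                      target = numeric(), energy = numeric()))
  rs <- traj$protocol$restraints
  do.call(rbind, lapply(seq_len(ncol(cv)), function(r) {
    kind <- if (!is.null(rs)) rs[[r]]$kind else "colvar"
    ang <- identical(kind, "torsion")
    conv <- if (ang) 180 / pi else 1
    data.frame(time_ps = traj$times, restraint_id = r, kind = kind,
               value = cv[, r] * conv, target = traj$cv_target[, r] * conv,
               energy = traj$cv_energy[, r], stringsAsFactors = FALSE)
  }))
}

#' View a CG trajectory as a pseudo-atom clamp trajectory
#'
#' Each bead becomes one CA-like pseudo-atom carrying the domain mass, so the
#' geometry metrics (\code{\link{handedness_sum}},
#' \code{\link{com_dihedral}}, ...) and the PDB writer apply directly to CG
#' output.
#'
#' @param traj a \code{cg_trajectory}.
#' @return list with \code{trajectory} (a \code{clamp_trajectory}),
#'   \code{assignment} (one bead per domain) and \code{topology}.
#' @export
cg_as_trajectory <- function(traj) {
  stopifnot(inherits(traj, "cg_trajectory"))
  sys <- traj$system
  n <- length(sys$labels)
  atoms <- data.frame(chain = "A", resno = seq_len(n), insert = "",
                      resid = "DOM", elety = "CA", elesy = "C",
                      mass = as.numeric(sys$mass), stringsAsFactors = FALSE)
  template <- clamp_structure(atoms, sys$x0)
  asg <- as.list(setNames(seq_len(n), sys$labels))
  class(asg) <- "domain_assignment"
  list(trajectory = clamp_trajectory(template, traj$frames,
                                     time_ps = traj$times),
       assignment = asg, topology = sys$topology)
}

#' Handedness-sum trace of a CG trajectory
#'
#' @param traj a \code{cg_trajectory}.
#' @return a \code{\link{geometry_series}} (degrees) of the interface torsion
#'   sum per saved frame.
#' @export
cg_handedness_series <- function(traj) {
  v <- cg_as_trajectory(traj)
  vals <- vapply(v$trajectory$frames, function(f)
    handedness_sum(f, v$assignment, v$topology,
                   atoms = v$trajectory$template$atoms), numeric(1L))
  geometry_series("handedness_sum", "degrees", vals, time_ps = traj$times)
}
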
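#' Stiffness profile for the coarse-grained clamp
#'
#' Harmonic force constants for the bonded terms of the one-bead-per-domain
#' model.  Defaults are chosen so that thermal fluctuations at 310 K are a few
#' degrees in the angular coordinates, comparable to the spread of
#' inter-domain angles seen in equilibrated clamp simulations.
#'
#' @param bond bond force constant, kcal mol^-1 A^-2 (default 10).
#' @param angle angle force constant, kcal mol^-1 rad^-2 (default 30).
#' @param torsion torsion force constant, kcal mol^-1 rad^-2 (default 30).
#' @return named list of force constants.
#' @export
cg_stiffness <- function(bond = 10, angle = 30, torsion = 30) {
  stopifnot(bond > 0, angle > 0, torsion > 0)
  list(bond = bond, angle = angle, torsion = torsion)
}

#' Build a coarse-grained clamp system from a structure
#'
#' Reduces each clamp domain to a single bead at its centre of mass, carrying
#' the domain's aggregate mass, and connects consecutive beads with harmonic
#' bond, angle and torsion terms whose equilibrium values are the built
#' conformation's geometry (the built state therefore has exactly zero
#' potential energy and zero forces).  The bonded set spanning the designated
#' open interface is excluded (\code{break_interface = TRUE}, the default),
#' representing the opened ring as a chain.
#'
#' @param s a \code{clamp_structure}.
#' @param assignment a \code{domain_assignment}.
#' @param topology a \code{clamp_topology}.
#' @param stiffness a \code{\link{cg_stiffness}} profile.
#' @param break_interface exclude the open-interface bonded terms?
#' @return An object of class \code{cg_system}.
#' @export
build_cg <- function(s, assignment, topology, stiffness = cg_stiffness(),
                     break_interface = TRUE) {
  coms <- domain_coms(s, assignment)
  labs <- topology$ring_order
  mass <- vapply(labs, function(d) {
    idx <- assignment[[d]]
    heavy <- idx[s$atoms$elesy[idx] != "H"]
    if (length(heavy) == 0L) heavy <- idx
    sum(s$atoms$mass[heavy])
  }, numeric(1L))
  chain <- .chain_order(topology)
  x0 <- coms[chain, , drop = FALSE]
  n <- length(chain)
  pos <- function(lab) match(lab, chain)

  # consecutive windows along the open chain (closing terms excluded when the
  # interface is broken)
  windows <- function(w) {
    top <- if (break_interface) n - w + 1L else n
    if (top < 1L) return(NULL)
    t(vapply(seq_len(top), function(i) ((i - 1L + 0:(w - 1L)) %% n) + 1L,
             integer(w)))
  }
  bw <- windows(2L); aw <- windows(3L); tw <- windows(4L)

  bonds_par <- cbind(k = rep(stiffness$bond, nrow(bw)),
                     r0 = vapply(seq_len(nrow(bw)), function(i)
                       com_distance(x0[bw[i, 1L], ], x0[bw[i, 2L], ]),
                       numeric(1L)))
  angles_par <- cbind(k = rep(stiffness$angle, nrow(aw)),
                      theta0 = vapply(seq_len(nrow(aw)), function(i)
                        .rad(com_angle(x0[aw[i, 1L], ], x0[aw[i, 2L], ],
                                       x0[aw[i, 3L], ])), numeric(1L)))
  torsions_par <- cbind(k = rep(stiffness$torsion, nrow(tw)),
                        phi0 = vapply(seq_len(nrow(tw)), function(i)
                          .rad(com_dihedral(x0[tw[i, 1L], ], x0[tw[i, 2L], ],
                                            x0[tw[i, 3L], ], x0[tw[i, 4L], ])),
                          numeric(1L)))
  structure(list(labels = chain, mass = setNames(mass[chain], chain),
                 x0 = x0,
                 bonds_idx = bw, bonds_par = bonds_par,
                 angles_idx = aw, angles_par = angles_par,
                 torsions_idx = tw, torsions_par = torsions_par,
                 broken_interface = if (break_interface)
                   topology$open_interface else NULL,
                 topology = topology),
            class = "cg_system")
}

#' @export
print.cg_system <- function(x, ...) {
  cat(sprintf(
    "<cg_system> %d beads [%s], %d bonds / %d angles / %d torsions%s\n",
    length(x$labels), paste(x$labels, collapse = ","),
    nrow(x$bonds_idx), nrow(x$angles_idx), nrow(x$torsions_idx),
    if (is.null(x$broken_interface)) "" else
      sprintf(", broken interface %s/%s", x$broken_interface[1L],
              x$broken_interface[2L])))
  invisible(x)
}

# convert user-level restraints (degree-based torsion constants, per-ns
# velocities) to the internal radian/ps representation consumed by the C++
# engine, resolving target_start = NA from the current bead geometry
.internal_restraints <- function(sys, restraints, x = NULL,
                                 steering_ps = NULL) {
  if (is.null(restraints)) return(list())
  if (is.null(x)) x <- sys$x0
  lapply(seq_along(restraints), function(i) {
    r <- restraints[[i]]
    idx <- match(r$participants, sys$labels)
    if (any(is.na(idx)))
      .stopf("restraint %d names unknown beads (%s)", i,
             paste(r$participants, collapse = ","))
    dur <- if (!is.null(r$duration_ps)) r$duration_ps else steering_ps
    off <- if (!is.null(r$active_until_ps)) r$active_until_ps else dur
    if (r$kind == "com_distance") {
      start <- if (is.null(r$target_start) || is.na(r$target_start))
        com_distance(x[idx[1L], ], x[idx[2L], ]) else r$target_start
      list(kind = 0L, idx = idx, k = r$k, target0 = start,
           rate = r$target_velocity / 1000, duration = dur,
           active_until = off)
    } else if (r$kind == "torsion") {
      start <- if (is.null(r$target_start) || is.na(r$target_start))
        com_dihedral(x[idx[1L], ], x[idx[2L], ], x[idx[3L], ], x[idx[4L], ])
        else r$target_start
      list(kind = 1L, idx = idx, k = r$k * (180 / pi)^2,
           target0 = .rad(start), rate = .rad(r$target_velocity) / 1000,
           duration = dur, active_until = off)
    } else .stopf("unknown restraint kind '%s'", r$kind)
  })
}

.sys_for_cpp <- function(sys, restraints = NULL, x = NULL,
                         steering_ps = NULL) {
  list(mass = as.numeric(sys$mass),
       bonds_idx = sys$bonds_idx, bonds_par = sys$bonds_par,
       angles_idx = sys$angles_idx, angles_par = sys$angles_par,
       torsions_idx = sys$torsions_idx, torsions_par = sys$torsions_par,
       restraints = .internal_restraints(sys, restraints, x, steering_ps))
}

#' Potential energy and forces of a CG system
#'
#' Evaluates the bonded terms plus any time-dependent restraints at
#' configuration \code{x} and time \code{t}; forces are the analytic negative
#' gradient (kcal mol^-1 A^-1).  Restraint energies use the convention
#' U = (k/2)(xi - xi0(t))^2 with a linearly moving target
#' xi0(t) = xi0(0) + v min(t, duration).
#'
#' @param sys a \code{cg_system}.
#' @param x bead coordinates (default: the reference \code{sys$x0}).
#' @param t simulation time in ps (default 0).
#' @param restraints optional list of restraints (see
#'   \code{\link{make_protocol}} for the format).
#' @return \code{cg_energy}: total potential energy (kcal/mol);
#'   \code{cg_forces}: n x 3 force matrix.
#' @export
cg_energy <- function(sys, x = NULL, t = 0, restraints = NULL) {
  if (is.null(x)) x <- sys$x0
  .cg_eval_cpp(.sys_for_cpp(sys, restraints), as.matrix(x), t)$energy
}

#' @rdname cg_energy
#' @export
cg_forces <- function(sys, x = NULL, t = 0, restraints = NULL) {
  if (is.null(x)) x <- sys$x0
  .cg_eval_cpp(.sys_for_cpp(sys, restraints), as.matrix(x), t)$forces
}

#' Construct one of the three steered ring-opening protocols
#'
#' \describe{
#'   \item{type 1}{the open-interface COM distance is steered apart at
#'     constant velocity v = 2.0 A/ns under a tight harmonic restraint
#'     (k = 500 kcal mol^-1 A^-2), increasing the distance by 20 A over the
#'     10 ns steering phase.}
#'   \item{type 2}{the three interface COM torsions are each steered down by
#'     20 degrees (k = 50 kcal mol^-1 deg^-2), driving a left-handed spiral.}
#'   \item{type 3}{as type 2 with the torsions increased by 20 degrees
#'     (right-handed spiral).}
#' }
#' After the steering phase the restraints are released and the system
#' relaxes freely for \code{post_steering_ps}.
#'
#' @param model_type 1, 2 or 3.
#' @param topology a \code{clamp_topology} (supplies the open interface and
#'   torsion quadruples).
#' @param steering_ps steering-phase duration (default 10000 ps = 10 ns).
#' @param post_steering_ps free-relaxation duration (default 10000 ps; the
#'   full production schedule used 140 ns).
#' @param k_distance distance restraint constant, kcal mol^-1 A^-2.
#' @param k_torsion torsion restraint constant, kcal mol^-1 deg^-2.
#' @param delta_distance net distance change, A (default +20).
#' @param delta_torsion net per-torsion change magnitude, degrees (default 20).
#' @return An object of class \code{steering_protocol}.
#' @export
make_protocol <- function(model_type, topology, steering_ps = 10000,
                          post_steering_ps = 10000, k_distance = 500,
                          k_torsion = 50, delta_distance = 20,
                          delta_torsion = 20) {
  if (!model_type %in% 1:3) .stopf("unknown model_type %s (must be 1, 2 or 3)",
                                   as.character(model_type))
  if (is.null(topology$open_interface) ||
      is.null(topology$torsion_quadruples))
    .stopf("topology '%s' lacks an open interface / torsion quadruples",
           topology$clamp_name)
  if (model_type == 1) {
    restraints <- list(list(kind = "com_distance",
                            participants = topology$open_interface,
                            k = k_distance, target_start = NA,
                            target_velocity = delta_distance / (steering_ps / 1000),
                            duration_ps = steering_ps))
  } else {
    sgn <- if (model_type == 2) -1 else 1
    restraints <- lapply(topology$torsion_quadruples, function(q)
      list(kind = "torsion", participants = q, k = k_torsion,
           target_start = NA,
           target_velocity = sgn * delta_torsion / (steering_ps / 1000),
           duration_ps = steering_ps))
  }
  structure(list(model_type = model_type, restraints = restraints,
                 steering_ps = steering_ps,
                 post_steering_ps = post_steering_ps),
            class = "steering_protocol")
}

#' @export
print.steering_protocol <- function(x, ...) {
  cat(sprintf("<steering_protocol> type %d: %d restraint(s), steer %g ps + relax %g ps\n",
              x$model_type, length(x$restraints), x$steering_ps,
              x$post_steering_ps))
  invisible(x)
}
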
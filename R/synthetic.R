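#' Build an idealised pseudo-six-fold clamp ring
#'
#' Generates a planar closed ring of rigid pseudo-domains mimicking the
#' architecture of a sliding clamp: domain centres of mass equally spaced on
#' a circle in the z = 0 plane, each domain a reproducible rigid cloud of
#' pseudo-atoms (deliberately anisotropic so rigid-body orientation fits are
#' unique).  The companion topology labels the domains A1..A3, B1..B3 around
#' the ring (beta-clamp convention for n = 6), designates the A3/B1 interface
#' as the one that opens, and lists its three torsion quadruples.
#'
#' @param n_domains number of domains (>= 4; default 6).
#' @param ring_radius circle radius in Angstrom (default 35, clamp-sized).
#' @param atoms_per_domain pseudo-atoms per domain (default 20).
#' @param domain_spread cloud size in Angstrom (default 6; must be < radius).
#' @param domain_mass total mass per domain in amu (default 13000, the
#'   aggregate mass of a ~120-residue clamp domain).
#' @param seed RNG seed for the cloud shape.
#' @return list with \code{structure} (a \code{clamp_structure}) and
#'   \code{topology} (a \code{clamp_topology}).
#' @export
build_ideal_ring <- function(n_domains = 6L, ring_radius = 35,
                             atoms_per_domain = 20L, domain_spread = 6,
                             domain_mass = 13000, seed = 1L) {
  if (n_domains < 4L) .stopf("n_domains must be >= 4")
  if (!(ring_radius > domain_spread && domain_spread > 0))
    .stopf("require ring_radius > domain_spread > 0")
  set.seed(seed)
  # anisotropic rigid template cloud, centred at its COM
  cloud <- matrix(rnorm(atoms_per_domain * 3L), ncol = 3L)
  cloud <- sweep(cloud, 2L, c(1, 0.7, 0.45) * domain_spread / 2, `*`)
  cloud <- sweep(cloud, 2L, colMeans(cloud))

  labels <- if (n_domains == 6L) c("A1", "A2", "A3", "B1", "B2", "B3")
            else sprintf("A%d", seq_len(n_domains))
  xyz <- NULL
  for (k in seq_len(n_domains)) {
    ang <- 360 * (k - 1) / n_domains
    Rz <- rotation_matrix(c(0, 0, 1), ang)
    centre <- ring_radius * c(cos(.rad(ang)), sin(.rad(ang)), 0)
    xyz <- rbind(xyz, sweep(cloud %*% t(Rz), 2L, centre, `+`))
  }
  atoms <- data.frame(
    chain = "A",
    resno = seq_len(n_domains * atoms_per_domain),
    insert = "",
    resid = "GLY",
    elety = "CA",
    elesy = "C",
    mass = domain_mass / atoms_per_domain,
    stringsAsFactors = FALSE)
  s <- clamp_structure(atoms, xyz)

  dom <- data.frame(label = labels, chain = "A",
                    start = (seq_len(n_domains) - 1L) * atoms_per_domain + 1L,
                    end = seq_len(n_domains) * atoms_per_domain,
                    stringsAsFactors = FALSE)
  # open the interface between the last and first label; the three torsion
  # quadruples are the consecutive 4-windows of the chain that remains
  open_if <- c(labels[n_domains], labels[1L])
  chain_order <- labels  # chain runs from labels[1] to labels[n]
  quads <- lapply(1:3, function(k) chain_order[k:(k + 3L)])
  topo <- clamp_topology("synthetic_ring", dom, labels, open_if, quads)
  list(structure = s, topology = topo)
}

# ring order rearranged as an open chain starting just after the open interface
.chain_order <- function(topo) {
  n <- length(topo$ring_order)
  if (is.null(topo$open_interface)) return(topo$ring_order)
  i <- match(topo$open_interface[2L], topo$ring_order)
  j <- match(topo$open_interface[1L], topo$ring_order)
  if ((j - i) %% n != n - 1L) {  # ensure open_interface = (chain end, chain start)
    i <- match(topo$open_interface[1L], topo$ring_order)
  }
  topo$ring_order[((i - 1L + 0:(n - 1L)) %% n) + 1L]
}

#' Deform a clamp into an open, spiral, or hinged conformation
#'
#' Applies exact rigid per-domain transforms implementing one of four
#' conformational classes observed for open clamps:
#' \describe{
#'   \item{\code{rh_spiral} / \code{lh_spiral}}{rotates successive domains
#'     about the local interface axes so each of the three designated
#'     interface torsions changes by exactly \code{+twist} (right-handed) or
#'     \code{-twist} (left-handed) degrees.}
#'   \item{\code{planar_open}}{translates the half-ring on one side of the
#'     open interface in-plane along the interface COM axis, widening the
#'     open-interface COM distance by exactly \code{gap} Angstrom.}
#'   \item{\code{in_plane_angle}}{rotates the terminal domain(s) in the ring
#'     plane about the middle domain of \code{angle_triple}, increasing that
#'     COM angle by exactly \code{increment} degrees (a hinging motion).}
#' }
#' The applied transforms are recorded in the \code{"ground_truth"} attribute
#' of the result, and every deformation is exactly invertible by negating its
#' magnitude.
#'
#' @param s a \code{clamp_structure}.
#' @param topo its \code{clamp_topology}.
#' @param mode one of \code{"rh_spiral"}, \code{"lh_spiral"},
#'   \code{"planar_open"}, \code{"in_plane_angle"}.
#' @param twist per-interface torsion change magnitude in degrees (spirals).
#' @param gap interface widening in Angstrom (\code{planar_open}).
#' @param increment angle change in degrees (\code{in_plane_angle}).
#' @param angle_triple character(3) domain labels for \code{in_plane_angle};
#'   default: the last three domains of the open chain.
#' @return deformed \code{clamp_structure} with attribute
#'   \code{"ground_truth"}.
#' @export
apply_deformation <- function(s, topo,
                              mode = c("rh_spiral", "lh_spiral",
                                       "planar_open", "in_plane_angle"),
                              twist = 20, gap = 20, increment = 7,
                              angle_triple = NULL) {
  mode <- match.arg(mode)
  asg <- assign_domains(s, topo)
  chain <- .chain_order(topo)
  n <- length(chain)
  xyz <- s$xyz

  if (mode %in% c("rh_spiral", "lh_spiral")) {
    if (twist <= 0) .stopf("twist must be positive; handedness is set by mode")
    signed <- if (mode == "rh_spiral") twist else -twist
    gt <- data.frame(window = integer(), rotation_deg = numeric())
    # initial torsions of the three interface windows
    coms <- domain_coms(xyz, asg, atoms = s$atoms)
    target <- vapply(1:3, function(k) {
      q <- chain[k:(k + 3L)]
      com_dihedral(coms[q[1L], ], coms[q[2L], ], coms[q[3L], ], coms[q[4L], ])
    }, numeric(1L)) + signed
    for (k in 1:3) {
      coms <- domain_coms(xyz, asg, atoms = s$atoms)
      q <- chain[k:(k + 3L)]
      cur <- com_dihedral(coms[q[1L], ], coms[q[2L], ], coms[q[3L], ],
                          coms[q[4L], ])
      delta <- wrap_angle(target[k] - cur)
      axis <- coms[q[3L], ] - coms[q[2L], ]
      move <- unlist(asg[chain[(k + 3L):n]])
      xyz[move, ] <- .rotate_about(xyz[move, , drop = FALSE],
                                   coms[q[2L], ], axis, delta)
      gt <- rbind(gt, data.frame(window = k, rotation_deg = delta))
    }
    out <- clamp_structure(s$atoms, xyz)
    attr(out, "ground_truth") <- list(mode = mode, twist = signed, steps = gt)
    return(out)
  }

  if (mode == "planar_open") {
    coms <- domain_coms(xyz, asg, atoms = s$atoms)
    u <- .unit3(coms[chain[1L], ] - coms[chain[n], ])
    half <- chain[seq_len(floor(n / 2))]
    move <- unlist(asg[half])
    xyz[move, ] <- sweep(xyz[move, , drop = FALSE], 2L, gap * u, `+`)
    out <- clamp_structure(s$atoms, xyz)
    attr(out, "ground_truth") <- list(mode = mode, gap = gap, direction = u,
                                      moved = half)
    return(out)
  }

  # in_plane_angle
  if (is.null(angle_triple)) angle_triple <- chain[(n - 2L):n]
  pos <- match(angle_triple, chain)
  if (any(is.na(pos)) || any(diff(pos) != 1L))
    .stopf("angle_triple must be three consecutive domains of the open chain")
  coms <- domain_coms(xyz, asg, atoms = s$atoms)
  u <- coms[angle_triple[1L], ] - coms[angle_triple[2L], ]
  v <- coms[angle_triple[3L], ] - coms[angle_triple[2L], ]
  nrm <- .cross3(u, v)  # +increment about u x v opens the angle
  move <- unlist(asg[chain[pos[3L]:n]])
  xyz[move, ] <- .rotate_about(xyz[move, , drop = FALSE],
                               coms[angle_triple[2L], ], nrm, increment)
  out <- clamp_structure(s$atoms, xyz)
  attr(out, "ground_truth") <- list(mode = mode, increment = increment,
                                    angle_triple = angle_triple)
  out
}

#' Generate a synthetic trajectory with Gaussian inter-domain rotations
#'
#' Emulates the statistical structure of an equilibrated clamp (sub)assembly:
#' at each designated interface (i, j), every frame rotates domain j rigidly
#' about the reference inter-domain COM axis by an angle drawn i.i.d. from
#' Normal(\code{rotation_mean}, \code{rotation_sd}^2) degrees (e.g. the
#' 13.9 +/- 4.4 degrees reported for relative domain rotation in a gp45
#' monomer), then adds isotropic Gaussian coordinate noise.  The exact draws
#' are recorded in the \code{"ground_truth"} attribute.
#'
#' @param base reference \code{clamp_structure}.
#' @param topo its \code{clamp_topology}.
#' @param interfaces list of character(2) adjacent domain pairs to perturb
#'   (default: the first adjacent pair of the open chain).
#' @param rotation_mean,rotation_sd Gaussian parameters in degrees
#'   (\code{rotation_sd >= 0}).
#' @param noise_sd isotropic coordinate noise sd in Angstrom (>= 0).
#' @param n_frames number of frames (>= 2).
#' @param frame_dt_ps time spacing between frames (default 100 ps).
#' @param seed RNG seed.
#' @return a \code{clamp_trajectory} with attribute \code{"ground_truth"}
#'   (data.frame: frame, interface, applied_rotation_deg).
#' @export
generate_trajectory <- function(base, topo, interfaces = NULL,
                                rotation_mean = 13.9, rotation_sd = 4.4,
                                noise_sd = 0, n_frames = 1000L,
                                frame_dt_ps = 100, seed = 1L) {
  if (rotation_sd < 0 || noise_sd < 0) .stopf("sds must be non-negative")
  if (n_frames < 2L) .stopf("n_frames must be >= 2")
  asg <- assign_domains(base, topo)
  chain <- .chain_order(topo)
  if (is.null(interfaces)) interfaces <- list(chain[1:2])
  set.seed(seed)
  coms <- domain_coms(base, asg)
  gt <- NULL
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    xyz <- base$xyz
    for (iface in interfaces) {
      i <- iface[1L]; j <- iface[2L]
      theta <- rnorm(1L, rotation_mean, rotation_sd)
      axis <- coms[j, ] - coms[i, ]
      idx <- asg[[j]]
      xyz[idx, ] <- .rotate_about(xyz[idx, , drop = FALSE], coms[j, ],
                                  axis, theta)
      gt <- rbind(gt, data.frame(frame = f,
                                 interface = paste(i, j, sep = "-"),
                                 applied_rotation_deg = theta,
                                 stringsAsFactors = FALSE))
    }
    if (noise_sd > 0)
      xyz <- xyz + matrix(rnorm(length(xyz), 0, noise_sd), ncol = 3L)
    frames[[f]] <- xyz
  }
  traj <- clamp_trajectory(base, frames,
                           time_ps = frame_dt_ps * (seq_len(n_frames) - 1L))
  attr(traj, "ground_truth") <- gt
  traj
}
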
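#' Distance between two centres of mass
#'
#' @param p,q numeric(3) points in Angstrom.
#' @return Euclidean distance in Angstrom.
#' @export
com_distance <- function(p, q) {
  .check_finite(c(p, q), "points")
  .norm3(p - q)
}

#' Angle at a vertex defined by three centres of mass
#'
#' @param p1,p2,p3 numeric(3) points; the angle is measured at \code{p2}.
#' @return angle in degrees, in [0, 180].
#' @export
com_angle <- function(p1, p2, p3) {
  .check_finite(c(p1, p2, p3), "points")
  u <- p1 - p2
  v <- p3 - p2
  nu <- .norm3(u); nv <- .norm3(v)
  if (nu < 1e-9 || nv < 1e-9)
    .stopf("degenerate angle: a point coincides with the vertex")
  ct <- sum(u * v) / (nu * nv)
  .deg(acos(max(-1, min(1, ct))))
}

#' Signed dihedral angle of four centres of mass
#'
#' IUPAC right-handed convention: looking down the p2 -> p3 axis, a positive
#' angle is a clockwise rotation of p4 relative to p1; cis = 0, trans = 180.
#' Values lie in (-180, 180].
#'
#' @param p1,p2,p3,p4 numeric(3) points.
#' @return signed dihedral in degrees.
#' @export
com_dihedral <- function(p1, p2, p3, p4) {
  .check_finite(c(p1, p2, p3, p4), "points")
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  if (.norm3(n1) < 1e-9 * .norm3(b1) * .norm3(b2) ||
      .norm3(n2) < 1e-9 * .norm3(b2) * .norm3(b3))
    .stopf("degenerate dihedral: three consecutive points are collinear")
  phi <- .deg(atan2(sum(.cross3(n1, n2) * .unit3(b2)), sum(n1 * n2)))
  if (phi <= -180) phi + 360 else phi
}

#' Spiral handedness: sum of the three interface torsions
#'
#' The sum of the three signed centre-of-mass torsion angles spanning the
#' opened interface of a clamp.  A planar ring gives 0; a right-handed spiral
#' of domain COMs gives a positive sum, a left-handed spiral a negative one.
#'
#' @param s a \code{clamp_structure} or bare coordinate matrix.
#' @param assignment a \code{domain_assignment}.
#' @param topo a \code{clamp_topology} supplying \code{torsion_quadruples}.
#' @param atoms atom table when \code{s} is a bare matrix.
#' @return signed sum in degrees.
#' @export
handedness_sum <- function(s, assignment, topo, atoms = NULL) {
  if (is.null(topo$torsion_quadruples))
    .stopf("topology '%s' defines no torsion quadruples", topo$clamp_name)
  coms <- domain_coms(s, assignment, atoms = atoms)
  sum(vapply(topo$torsion_quadruples, function(q)
    com_dihedral(coms[q[1L], ], coms[q[2L], ], coms[q[3L], ], coms[q[4L], ]),
    numeric(1L)))
}

#' Least-squares (Kabsch) superposition
#'
#' Finds the proper rotation \code{R} (det = +1) and translation minimising
#' the weighted RMSD between \code{X} rotated onto \code{Y}.  The fitted
#' coordinates are \code{sweep(X, 2, cx) \%*\% t(R)} recentred on \code{Y}'s
#' weighted centroid; equivalently column vectors transform as
#' \code{v' = R v}.
#'
#' @param X,Y n x 3 coordinate matrices (n >= 3, non-degenerate spread).
#' @param weights optional non-negative weights (e.g. masses).
#' @return list with \code{R} (3 x 3 rotation), \code{t} (translation such
#'   that \code{Y ~ Xc \%*\% t(R) + t} with \code{Xc} centred X), \code{rmsd}
#'   (Angstrom), and centroids \code{cx}, \code{cy}.
#' @export
kabsch_superpose <- function(X, Y, weights = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y) || ncol(X) != 3L || ncol(Y) != 3L)
    .stopf("X and Y must be congruent n x 3 matrices")
  if (nrow(X) < 3L) .stopf("superposition needs at least 3 points")
  w <- if (is.null(weights)) rep(1, nrow(X)) else as.numeric(weights)
  if (length(w) != nrow(X) || any(w < 0) || sum(w) <= 0)
    .stopf("invalid weights")
  w <- w / sum(w)
  cx <- colSums(X * w); cy <- colSums(Y * w)
  Xc <- sweep(X, 2L, cx); Yc <- sweep(Y, 2L, cy)
  H <- t(Xc * w) %*% Yc
  sv <- svd(H)
  if (sv$d[2L] < 1e-12 * max(sv$d[1L], 1e-300))
    .stopf("degenerate point spread: superposition is not unique")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- Xc %*% t(R)
  rmsd <- sqrt(sum(w * rowSums((fitted - Yc)^2)))
  list(R = R, t = cy, rmsd = rmsd, cx = cx, cy = cy)
}

#' Size-normalised RMSD (RMSD100)
#'
#' Normalises an RMSD to a 100-residue equivalent,
#' \code{RMSD100 = RMSD / (1 + ln(N / 100))}, so that fluctuation amplitudes
#' of assemblies of different sizes can be compared.  Undefined for
#' \code{N <= exp(-1) * 100} (about 36 residues), where the denominator is
#' non-positive.
#'
#' @param rmsd RMSD in Angstrom (>= 0).
#' @param n_residues number of residues N (>= 37).
#' @return normalised RMSD in Angstrom.
#' @export
rmsd100 <- function(rmsd, n_residues) {
  if (any(n_residues <= 0)) .stopf("n_residues must be positive")
  if (any(rmsd < 0)) .stopf("rmsd must be non-negative")
  denom <- 1 + log(n_residues / 100)
  if (any(denom <= 0))
    .stopf("RMSD100 undefined for n_residues <= %d", floor(100 * exp(-1)))
  rmsd / denom
}

.rotation_angle_axis <- function(R) {
  tr <- sum(diag(R))
  ang <- acos(max(-1, min(1, (tr - 1) / 2)))
  ax <- c(R[3L, 2L] - R[2L, 3L], R[1L, 3L] - R[3L, 1L], R[2L, 1L] - R[1L, 2L])
  if (.norm3(ax) < 1e-12) ax <- c(0, 0, 0) else ax <- ax / .norm3(ax)
  list(angle = .deg(ang), axis = ax)
}

#' Signed rotation of one clamp domain relative to another
#'
#' Each domain's rigid-body rotation from its reference conformation to the
#' current frame is obtained by Kabsch superposition; the relative transform
#' \code{R_rel = R_j R_i^T} is reduced to its rotation angle
#' \code{acos((tr(R_rel) - 1) / 2)}.  The sign is the sign of the projection
#' of the rotation axis onto the reference inter-domain COM axis (i -> j), so
#' a rotation of domain j about that axis by +theta (right-hand rule) is
#' reported as +theta.
#'
#' @param ref_i,cur_i reference and current coordinates of domain i (n x 3).
#' @param ref_j,cur_j reference and current coordinates of domain j (m x 3).
#' @param weights_i,weights_j optional per-atom weights for the fits.
#' @param axis optional reference inter-domain axis; defaults to the vector
#'   between the unweighted centroids of \code{ref_i} and \code{ref_j}.
#' @return signed rotation angle in degrees, magnitude in [0, 180].
#' @export
inter_domain_rotation <- function(ref_i, cur_i, ref_j, cur_j,
                                  weights_i = NULL, weights_j = NULL,
                                  axis = NULL) {
  fi <- kabsch_superpose(ref_i, cur_i, weights_i)
  fj <- kabsch_superpose(ref_j, cur_j, weights_j)
  Rrel <- fj$R %*% t(fi$R)
  aa <- .rotation_angle_axis(Rrel)
  if (is.null(axis)) axis <- colMeans(as.matrix(ref_j)) - colMeans(as.matrix(ref_i))
  s <- sum(aa$axis * axis)
  if (aa$angle < 1e-10 || abs(s) < 1e-12) aa$angle else sign(s) * aa$angle
}

#' Per-frame inter-domain rotations over a trajectory
#'
#' Applies \code{\link{inter_domain_rotation}} between a designated pair of
#' adjacent domains for every frame of a trajectory, against the reference
#' frame (by default the first).
#'
#' @param traj a \code{clamp_trajectory}.
#' @param assignment a \code{domain_assignment} on the template.
#' @param pair character(2) domain labels (i, j).
#' @param ref_frame index of the reference frame; \code{NULL} (default) uses
#'   the trajectory template (for multi-model PDB input the template is the
#'   first model, so the default then coincides with \code{ref_frame = 1}).
#' @return A \code{\link{geometry_series}} (degrees).
#' @export
rotation_series <- function(traj, assignment, pair, ref_frame = NULL) {
  stopifnot(inherits(traj, "clamp_trajectory"), length(pair) == 2L)
  ii <- assignment[[pair[1L]]]
  jj <- assignment[[pair[2L]]]
  ref <- if (is.null(ref_frame)) traj$template$xyz else traj$frames[[ref_frame]]
  axis <- colMeans(ref[jj, , drop = FALSE]) - colMeans(ref[ii, , drop = FALSE])
  vals <- vapply(traj$frames, function(f)
    inter_domain_rotation(ref[ii, , drop = FALSE], f[ii, , drop = FALSE],
                          ref[jj, , drop = FALSE], f[jj, , drop = FALSE],
                          axis = axis),
    numeric(1L))
  geometry_series(paste0("rotation_", pair[1L], "_", pair[2L]), "degrees",
                  vals, time_ps = traj$time_ps)
}
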
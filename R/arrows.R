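#' Initialise the sphere-and-arrow representation
#'
#' Each clamp domain is drawn as a sphere at its centre of mass plus an arrow
#' that starts as the vector from the sphere to the system centre of mass at
#' the reference frame.  Over a trajectory the arrow's length and direction
#' are kept fixed with respect to the domain's own body frame: at each frame
#' the reference vector is rotated by the domain's fitted rigid-body rotation
#' (\code{\link{update_arrows}}), so changes in arrow direction visualise
#' changes in domain orientation.
#'
#' @param s reference \code{clamp_structure}.
#' @param assignment a \code{domain_assignment}.
#' @param fit_atoms \code{"calpha"} (default) to fit orientations on C-alpha
#'   atoms, or \code{"all"} for all assigned atoms.
#' @return An object of class \code{arrow_set}: data.frame (domain, cx, cy,
#'   cz, vx, vy, vz) with the reference data in attributes.
#' @export
init_arrows <- function(s, assignment, fit_atoms = c("calpha", "all")) {
  fit_atoms <- match.arg(fit_atoms)
  if (length(assignment) < 2L)
    .stopf("arrow representation needs at least 2 domains")
  coms <- domain_coms(s, assignment)
  sys <- system_com(s, assignment)
  df <- data.frame(domain = rownames(coms),
                   cx = coms[, 1L], cy = coms[, 2L], cz = coms[, 3L],
                   vx = sys[1L] - coms[, 1L],
                   vy = sys[2L] - coms[, 2L],
                   vz = sys[3L] - coms[, 3L],
                   row.names = NULL, stringsAsFactors = FALSE)
  fit_idx <- lapply(assignment, function(idx) {
    if (fit_atoms == "calpha") {
      ca <- idx[trimws(s$atoms$elety[idx]) == "CA"]
      if (length(ca) >= 3L) ca else idx
    } else idx
  })
  structure(df, class = c("arrow_set", "data.frame"),
            reference = s, assignment = assignment, fit_idx = fit_idx,
            ref_vectors = as.matrix(df[, c("vx", "vy", "vz")]))
}

#' Update arrows for a new frame
#'
#' Re-centres each sphere at the domain's current COM and rotates the
#' reference vector by the Kabsch-fitted rotation of the domain from the
#' reference frame to the current one, conserving arrow length exactly.
#'
#' @param a an \code{arrow_set}.
#' @param frame a \code{clamp_structure} or coordinate matrix congruent with
#'   the reference.
#' @return An updated \code{arrow_set} (same reference attributes).
#' @export
update_arrows <- function(a, frame) {
  stopifnot(inherits(a, "arrow_set"))
  ref <- attr(a, "reference")
  asg <- attr(a, "assignment")
  fit_idx <- attr(a, "fit_idx")
  refv <- attr(a, "ref_vectors")
  xyz <- if (inherits(frame, "clamp_structure")) frame$xyz else as.matrix(frame)
  if (nrow(xyz) != nrow(ref$xyz))
    .stopf("frame (%d atoms) does not match the reference (%d atoms)",
           nrow(xyz), nrow(ref$xyz))
  out <- a
  for (i in seq_len(nrow(a))) {
    d <- a$domain[i]
    com <- domain_com(xyz, asg, d, atoms = ref$atoms)
    fit <- kabsch_superpose(ref$xyz[fit_idx[[d]], , drop = FALSE],
                            xyz[fit_idx[[d]], , drop = FALSE])
    v <- as.numeric(fit$R %*% refv[i, ])
    out$cx[i] <- com[1L]; out$cy[i] <- com[2L]; out$cz[i] <- com[3L]
    out$vx[i] <- v[1L]; out$vy[i] <- v[2L]; out$vz[i] <- v[3L]
  }
  out
}

#' Arrow sets for every frame of a trajectory
#'
#' @param traj a \code{clamp_trajectory}.
#' @param assignment a \code{domain_assignment} on the template.
#' @param ref_frame reference frame index (default 1).
#' @param fit_atoms see \code{\link{init_arrows}}.
#' @return list of \code{arrow_set}, one per frame.
#' @export
arrow_series <- function(traj, assignment, ref_frame = 1L,
                         fit_atoms = c("calpha", "all")) {
  stopifnot(inherits(traj, "clamp_trajectory"))
  ref <- clamp_structure(traj$template$atoms, traj$frames[[ref_frame]])
  a0 <- init_arrows(ref, assignment, fit_atoms = fit_atoms)
  lapply(traj$frames, function(f) update_arrows(a0, f))
}

#' Write arrow sets to CSV or a graphics script
#'
#' \code{format = "csv"}: columns frame, domain, cx, cy, cz, vx, vy, vz.
#' \code{format = "script"}: one \code{sphere cx cy cz radius} and one
#' \code{arrow cx cy cz tx ty tz} primitive per domain per frame (tip
#' t = centre + vector), a minimal dialect that molecular-graphics front ends
#' can translate.
#'
#' @param arrows an \code{arrow_set} or list of them (frames).
#' @param path output file.
#' @param format \code{"csv"} or \code{"script"}.
#' @param radius sphere radius for the script output (Angstrom).
#' @return \code{path}, invisibly.
#' @export
write_arrows <- function(arrows, path, format = c("csv", "script"),
                         radius = 5) {
  format <- match.arg(format)
  if (inherits(arrows, "arrow_set")) arrows <- list(arrows)
  if (length(arrows) == 0L) .stopf("no arrow sets to write")
  if (format == "csv") {
    df <- do.call(rbind, lapply(seq_along(arrows), function(f)
      cbind(frame = f, as.data.frame(arrows[[f]])[,
        c("domain", "cx", "cy", "cz", "vx", "vy", "vz")])))
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (f in seq_along(arrows)) {
      a <- arrows[[f]]
      writeLines(sprintf("# frame %d", f), con)
      for (i in seq_len(nrow(a))) {
        writeLines(sprintf("sphere %.3f %.3f %.3f %.3f",
                           a$cx[i], a$cy[i], a$cz[i], radius), con)
        writeLines(sprintf("arrow %.3f %.3f %.3f %.3f %.3f %.3f",
                           a$cx[i], a$cy[i], a$cz[i],
                           a$cx[i] + a$vx[i], a$cy[i] + a$vy[i],
                           a$cz[i] + a$vz[i]), con)
      }
    }
  }
  invisible(path)
}

#' Read an arrows CSV back
#'
#' @param path CSV written by \code{\link{write_arrows}}.
#' @return data.frame with columns frame, domain, cx..vz.
#' @export
read_arrows_csv <- function(path) utils::read.csv(path, stringsAsFactors = FALSE)
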
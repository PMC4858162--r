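#' Construct a clamp structure object
#'
#' A \code{clamp_structure} is the in-memory carrier for PDB content: a table
#' of atom records plus an \code{n x 3} coordinate matrix in Angstrom.
#'
#' @param atoms data.frame with columns \code{chain}, \code{resno} (author
#'   numbering, integer), \code{insert} (insertion code, \code{""} if none),
#'   \code{resid} (residue name), \code{elety} (atom name), \code{elesy}
#'   (element symbol) and \code{mass} (amu, > 0).
#' @param xyz numeric matrix, one row per atom, columns x, y, z (Angstrom).
#' @return An object of class \code{clamp_structure}.
#' @export
clamp_structure <- function(atoms, xyz) {
  xyz <- as.matrix(xyz)
  if (nrow(atoms) != nrow(xyz) || ncol(xyz) != 3L)
    .stopf("atoms (%d rows) and xyz (%d x %d) are not congruent",
           nrow(atoms), nrow(xyz), ncol(xyz))
  .check_finite(xyz, "coordinates")
  if (any(!is.finite(atoms$mass)) || any(atoms$mass <= 0))
    .stopf("all atom masses must be positive and finite")
  dimnames(xyz) <- list(NULL, c("x", "y", "z"))
  structure(list(atoms = atoms, xyz = xyz), class = "clamp_structure")
}

#' Construct a trajectory of clamp structures
#'
#' @param template a \code{clamp_structure} providing the atom table.
#' @param frames list of coordinate matrices, each congruent with the template.
#' @param time_ps optional numeric vector of frame times in ps (strictly
#'   increasing).
#' @return An object of class \code{clamp_trajectory}.
#' @export
clamp_trajectory <- function(template, frames, time_ps = NULL) {
  stopifnot(inherits(template, "clamp_structure"))
  n <- nrow(template$xyz)
  frames <- lapply(frames, function(f) {
    f <- as.matrix(f)
    if (nrow(f) != n || ncol(f) != 3L)
      .stopf("frame with %d x %d coordinates does not match template (%d atoms)",
             nrow(f), ncol(f), n)
    .check_finite(f, "frame coordinates")
    dimnames(f) <- list(NULL, c("x", "y", "z"))
    f
  })
  if (!is.null(time_ps)) {
    if (length(time_ps) != length(frames))
      .stopf("time_ps length (%d) != number of frames (%d)",
             length(time_ps), length(frames))
    if (any(diff(time_ps) <= 0))
      .stopf("frame times must be strictly increasing")
  }
  structure(list(template = template, frames = frames, time_ps = time_ps),
            class = "clamp_trajectory")
}

#' @export
print.clamp_structure <- function(x, ...) {
  cat(sprintf("<clamp_structure> %d atoms, %d chain(s), %d residues\n",
              nrow(x$atoms), length(unique(x$atoms$chain)),
              nrow(unique(x$atoms[, c("chain", "resno", "insert")]))))
  invisible(x)
}

#' @export
print.clamp_trajectory <- function(x, ...) {
  cat(sprintf("<clamp_trajectory> %d frames x %d atoms%s\n",
              length(x$frames), nrow(x$template$xyz),
              if (is.null(x$time_ps)) "" else
                sprintf(", t = %g..%g ps", min(x$time_ps), max(x$time_ps))))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param x a \code{clamp_trajectory}
#' @return integer frame count
#' @export
n_frames <- function(x) length(x$frames)

.element_from_name <- function(elety) {
  # fall back to first letter of the atom name when the element column is blank
  e <- sub("^[0-9]*", "", trimws(elety))
  substr(e, 1L, 1L)
}

# standard atomic masses from bio3d's periodic-table dataset
.element_masses <- local({
  e <- new.env()
  utils::data("elements", package = "bio3d", envir = e)
  stats::setNames(e$elements$mass, e$elements$symb)
})

.atom_masses <- function(elesy) {
  # PDB element columns are upper case; the periodic table is mixed case
  sym <- paste0(toupper(substr(elesy, 1L, 1L)),
                tolower(substr(elesy, 2L, 2L)))
  m <- .element_masses[sym]
  miss <- is.na(m)
  if (any(miss)) {
    # rescue by first letter (e.g. odd two-letter names); else carbon-like
    m[miss] <- .element_masses[substr(sym[miss], 1L, 1L)]
    m[is.na(m)] <- .element_masses[["C"]]
  }
  unname(m)
}

#' Parse a (multi-model) PDB file
#'
#' Reads fixed-column PDB via \pkg{bio3d}.  Waters and heteroatoms are
#' excluded by default; alternate locations are resolved to the
#' highest-occupancy conformer; masses are standard atomic masses from the
#' element symbol.  A single-model file yields a \code{clamp_structure};
#' a multi-model file (MODEL/ENDMDL) yields a \code{clamp_trajectory} whose
#' \code{template} holds the atom table.
#'
#' @param path path to a PDB file.
#' @param keep_het logical; keep non-water HETATM records (default FALSE).
#' @param time_ps optional frame times for multi-model input.
#' @return A \code{clamp_structure} or \code{clamp_trajectory}.
#' @export
parse_structure <- function(path, keep_het = FALSE, time_ps = NULL) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = TRUE, rm.alt = TRUE, verbose = FALSE),
    error = function(e) .stopf("failed to parse PDB '%s': %s",
                               path, conditionMessage(e)))
  at <- pdb$atom
  keep <- at$type == "ATOM"
  if (keep_het) keep <- keep | (at$type == "HETATM" & !(at$resid %in% c("HOH", "WAT", "DOD")))
  if (!any(keep)) .stopf("no ATOM records in '%s'", path)
  at <- at[keep, , drop = FALSE]
  elesy <- trimws(ifelse(is.na(at$elesy) | at$elesy == "",
                         .element_from_name(at$elety), at$elesy))
  mass <- .atom_masses(elesy)
  atoms <- data.frame(chain = at$chain,
                      resno = at$resno,
                      insert = ifelse(is.na(at$insert), "", at$insert),
                      resid = at$resid,
                      elety = at$elety,
                      elesy = elesy,
                      mass = mass,
                      stringsAsFactors = FALSE)
  xyz <- pdb$xyz
  idx <- which(keep)
  cols <- as.vector(rbind(3L * idx - 2L, 3L * idx - 1L, 3L * idx))
  if (is.matrix(xyz) && nrow(xyz) > 1L) {
    frames <- lapply(seq_len(nrow(xyz)), function(i)
      matrix(xyz[i, cols], ncol = 3L, byrow = TRUE))
    template <- clamp_structure(atoms, frames[[1L]])
    clamp_trajectory(template, frames, time_ps = time_ps)
  } else {
    v <- if (is.matrix(xyz)) xyz[1L, ] else as.numeric(xyz)
    clamp_structure(atoms, matrix(v[cols], ncol = 3L, byrow = TRUE))
  }
}

.format_pdb_atom <- function(serial, elety, resid, chain, resno, insert, x, y, z, elesy) {
  name4 <- if (nchar(elety) < 4L) sprintf(" %-3s", elety) else substr(elety, 1L, 4L)
  sprintf("ATOM  %5d %4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial %% 100000L, name4, substr(resid, 1L, 3L), substr(chain, 1L, 1L),
          resno %% 10000L, ifelse(insert == "", " ", insert), x, y, z, 1, 0,
          substr(elesy, 1L, 2L))
}

#' Write a structure or trajectory as (multi-model) PDB
#'
#' Fixed-column ATOM records; multi-frame input is written as MODEL/ENDMDL
#' blocks.  Coordinates are rounded to the PDB precision of 0.001 Angstrom.
#' Atom masses are not representable in PDB and are re-derived from the
#' element on read-back.
#'
#' @param x a \code{clamp_structure} or \code{clamp_trajectory}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_structure_pdb <- function(x, path) {
  if (inherits(x, "clamp_structure")) {
    template <- x
    frames <- list(x$xyz)
    multi <- FALSE
  } else if (inherits(x, "clamp_trajectory")) {
    template <- x$template
    frames <- x$frames
    multi <- TRUE
  } else .stopf("x must be a clamp_structure or clamp_trajectory")
  at <- template$atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_along(frames)) {
    if (multi) writeLines(sprintf("MODEL %8d", f), con)
    xyz <- frames[[f]]
    lines <- vapply(seq_len(nrow(at)), function(i)
      .format_pdb_atom(i, at$elety[i], at$resid[i], at$chain[i], at$resno[i],
                       at$insert[i], xyz[i, 1L], xyz[i, 2L], xyz[i, 3L],
                       at$elesy[i]), character(1L))
    writeLines(lines, con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Fetch a PDB entry from the RCSB archive
#'
#' Convenience downloader for the crystal structures the clamp topologies in
#' \code{inst/extdata/topologies} were written for (1OK7, 1PLQ, 1B77, 1JQL).
#' Requires network access; files already present in \code{dir} are reused.
#'
#' @param id 4-character PDB accession.
#' @param dir download directory (created if needed).
#' @return Path to the downloaded PDB file.
#' @export
fetch_pdb <- function(id, dir = tempdir()) {
  stopifnot(nchar(id) == 4L)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dest <- file.path(dir, paste0(tolower(id), ".pdb"))
  if (!file.exists(dest)) {
    url <- sprintf("https://files.rcsb.org/download/%s.pdb", toupper(id))
    status <- tryCatch(utils::download.file(url, dest, quiet = TRUE, mode = "wb"),
                       error = function(e) -1L, warning = function(w) -1L)
    if (!identical(status, 0L) || !file.exists(dest) || file.size(dest) == 0) {
      unlink(dest)
      .stopf("could not download PDB entry %s (network unavailable?)", id)
    }
  }
  dest
}
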
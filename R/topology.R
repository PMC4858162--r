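#' Define a clamp domain topology
#'
#' A clamp topology names the DNA-clamp domains of a sliding clamp (three per
#' bacterial beta protomer, two per gp45/PCNA protomer), maps each to a chain
#' and an inclusive author-numbered residue range, fixes their cyclic order
#' around the ring, and designates the interface that opens together with the
#' three centre-of-mass torsion quadruples spanning it (for the beta clamp,
#' opening A3/B1: B1-B2-B3-A1, B2-B3-A1-A2, B3-A1-A2-A3).
#'
#' @param clamp_name label for the clamp.
#' @param domains data.frame with columns \code{label}, \code{chain},
#'   \code{start}, \code{end} (1-based inclusive author numbering).
#' @param ring_order character vector: cyclic ordering of all domain labels.
#' @param open_interface character(2): adjacent domain pair that opens.  May
#'   be \code{NULL} for sub-assemblies (monomers) that have no opening
#'   interface.
#' @param torsion_quadruples list of exactly three character(4) vectors, each
#'   of distinct labels, forming consecutive 4-windows around the open
#'   interface; \code{NULL} for sub-assemblies.
#' @return An object of class \code{clamp_topology}.
#' @export
clamp_topology <- function(clamp_name, domains, ring_order,
                           open_interface = NULL, torsion_quadruples = NULL) {
  domains <- as.data.frame(domains, stringsAsFactors = FALSE)
  need <- c("label", "chain", "start", "end")
  if (!all(need %in% names(domains)))
    .stopf("domains must have columns %s", paste(need, collapse = ", "))
  if (anyDuplicated(domains$label))
    .stopf("duplicate domain labels in topology")
  if (!setequal(ring_order, domains$label) ||
      length(ring_order) != nrow(domains))
    .stopf("ring_order must list every domain label exactly once")
  if (any(domains$end < domains$start))
    .stopf("residue ranges must satisfy start <= end")
  n <- length(ring_order)
  if (!is.null(open_interface)) {
    if (length(open_interface) != 2L)
      .stopf("open_interface must name two domains")
    i <- match(open_interface[1L], ring_order)
    j <- match(open_interface[2L], ring_order)
    if (is.na(i) || is.na(j) || !((j - i) %% n == 1L || (i - j) %% n == 1L))
      .stopf("open_interface domains '%s'/'%s' are not adjacent in ring_order",
             open_interface[1L], open_interface[2L])
    open_interface <- as.character(open_interface)
  }
  if (!is.null(torsion_quadruples)) {
    if (length(torsion_quadruples) != 3L)
      .stopf("exactly three torsion quadruples are required")
    for (q in torsion_quadruples) {
      if (length(q) != 4L || anyDuplicated(q) || !all(q %in% ring_order))
        .stopf("each torsion quadruple must be 4 distinct ring domains")
    }
    torsion_quadruples <- lapply(torsion_quadruples, as.character)
  }
  structure(list(clamp_name = clamp_name, domains = domains,
                 ring_order = ring_order,
                 open_interface = open_interface,
                 torsion_quadruples = torsion_quadruples),
            class = "clamp_topology")
}

#' @export
print.clamp_topology <- function(x, ...) {
  cat(sprintf("<clamp_topology> %s: %d domains [%s]%s\n",
              x$clamp_name, nrow(x$domains),
              paste(x$ring_order, collapse = ","),
              if (is.null(x$open_interface)) "" else
                sprintf(", open interface %s/%s", x$open_interface[1L],
                        x$open_interface[2L])))
  invisible(x)
}

#' Read / write a clamp topology in YAML
#'
#' YAML keys: \code{clamp_name}, \code{domains} (list of label/chain/start/end
#' maps), \code{ring_order}, \code{open_interface}, \code{torsion_quadruples}.
#'
#' @param path YAML file path.
#' @return \code{read_topology}: a \code{clamp_topology};
#'   \code{write_topology}: \code{path}, invisibly.
#' @export
read_topology <- function(path) {
  y <- yaml::read_yaml(path)
  dom <- do.call(rbind, lapply(y$domains, function(d)
    data.frame(label = d$label, chain = d$chain,
               start = as.integer(d$start), end = as.integer(d$end),
               stringsAsFactors = FALSE)))
  clamp_topology(y$clamp_name, dom, unlist(y$ring_order),
                 if (is.null(y$open_interface)) NULL else
                   unlist(y$open_interface),
                 if (is.null(y$torsion_quadruples)) NULL else
                   lapply(y$torsion_quadruples, unlist))
}

#' @rdname read_topology
#' @param topo a \code{clamp_topology}.
#' @export
write_topology <- function(topo, path) {
  y <- list(clamp_name = topo$clamp_name,
            domains = lapply(seq_len(nrow(topo$domains)), function(i)
              as.list(topo$domains[i, c("label", "chain", "start", "end")])),
            ring_order = as.list(topo$ring_order),
            open_interface = as.list(topo$open_interface),
            torsion_quadruples = lapply(topo$torsion_quadruples, as.list))
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Load one of the clamp topologies shipped with the package
#'
#' Topologies for the crystal structures 1OK7 (E. coli beta dimer), 1JQL
#' (beta monomer, chain A of the beta/delta complex), 1PLQ (yeast PCNA) and
#' 1B77 (phage gp45 homolog) are installed under
#' \code{extdata/topologies}.  The papers reporting these structures do not
#' tabulate domain boundaries; the shipped residue ranges are reconstructions
#' from the standard domain decomposition of each fold and can be edited in
#' the YAML.
#'
#' @param name one of \code{"1ok7"}, \code{"1jql"}, \code{"1plq"},
#'   \code{"1b77"}.
#' @return A \code{clamp_topology}.
#' @export
default_topology <- function(name = c("1ok7", "1jql", "1plq", "1b77")) {
  name <- match.arg(tolower(name), c("1ok7", "1jql", "1plq", "1b77"))
  path <- system.file("extdata", "topologies", paste0(name, ".yaml"),
                      package = "clampring", mustWork = TRUE)
  read_topology(path)
}

#' Assign structure atoms to clamp domains
#'
#' Maps every topology domain (chain + inclusive residue range) to the index
#' set of matching atoms.  The sets are disjoint by construction when ranges
#' do not overlap; atoms outside all ranges remain unassigned.
#'
#' @param s a \code{clamp_structure}.
#' @param topo a \code{clamp_topology}.
#' @return A named list of integer atom-index vectors (class
#'   \code{domain_assignment}), in \code{ring_order}.
#' @export
assign_domains <- function(s, topo) {
  stopifnot(inherits(s, "clamp_structure"), inherits(topo, "clamp_topology"))
  at <- s$atoms
  out <- lapply(topo$ring_order, function(lab) {
    d <- topo$domains[topo$domains$label == lab, ]
    idx <- which(at$chain == d$chain & at$resno >= d$start & at$resno <= d$end)
    if (length(idx) == 0L)
      .stopf("topology mismatch: no atoms for domain '%s' (chain %s, residues %d-%d)",
             lab, d$chain, d$start, d$end)
    idx
  })
  names(out) <- topo$ring_order
  all_idx <- unlist(out)
  if (anyDuplicated(all_idx))
    .stopf("domain residue ranges overlap: assignment is not a partition")
  class(out) <- "domain_assignment"
  out
}

#' Mass-weighted centre of mass of one clamp domain
#'
#' By default all non-hydrogen atoms contribute with their standard atomic
#' masses (crystal structures carry no hydrogens).  \code{method = "calpha"}
#' instead takes the unweighted mean of C-alpha positions, for robustness
#' comparisons.
#'
#' @param s a \code{clamp_structure}, or a bare coordinate matrix congruent
#'   with the assignment's source structure (then \code{atoms} must be given).
#' @param assignment a \code{domain_assignment}.
#' @param domain domain label.
#' @param method \code{"mass"} (default) or \code{"calpha"}.
#' @param atoms atom table when \code{s} is a bare matrix.
#' @return numeric(3) position in Angstrom.
#' @export
domain_com <- function(s, assignment, domain, method = c("mass", "calpha"),
                       atoms = NULL) {
  method <- match.arg(method)
  if (inherits(s, "clamp_structure")) {
    xyz <- s$xyz; atoms <- s$atoms
  } else {
    xyz <- as.matrix(s)
    if (is.null(atoms)) .stopf("atoms table required with bare coordinates")
  }
  idx <- assignment[[domain]]
  if (is.null(idx) || length(idx) == 0L)
    .stopf("domain '%s' is not assigned", domain)
  if (method == "calpha") {
    ca <- idx[trimws(atoms$elety[idx]) == "CA"]
    if (length(ca) == 0L) ca <- idx  # pseudo-atom systems without CA names
    return(unname(colMeans(xyz[ca, , drop = FALSE])))
  }
  heavy <- idx[atoms$elesy[idx] != "H"]
  if (length(heavy) == 0L) heavy <- idx
  m <- atoms$mass[heavy]
  if (sum(m) <= 0) .stopf("zero total mass for domain '%s'", domain)
  unname(colSums(xyz[heavy, , drop = FALSE] * m) / sum(m))
}

#' Centres of mass of all domains
#'
#' @inheritParams domain_com
#' @return matrix with one row per domain in \code{ring_order} (rownames are
#'   domain labels).
#' @export
domain_coms <- function(s, assignment, method = c("mass", "calpha"),
                        atoms = NULL) {
  method <- match.arg(method)
  labs <- names(assignment)
  out <- t(vapply(labs, function(d)
    domain_com(s, assignment, d, method = method, atoms = atoms),
    numeric(3L)))
  rownames(out) <- labs
  out
}

#' Mass-weighted centre of mass of all assigned atoms
#'
#' @inheritParams domain_com
#' @return numeric(3) position in Angstrom.
#' @export
system_com <- function(s, assignment, atoms = NULL) {
  if (inherits(s, "clamp_structure")) {
    xyz <- s$xyz; atoms <- s$atoms
  } else {
    xyz <- as.matrix(s)
    if (is.null(atoms)) .stopf("atoms table required with bare coordinates")
  }
  idx <- sort(unique(unlist(assignment)))
  heavy <- idx[atoms$elesy[idx] != "H"]
  if (length(heavy) == 0L) heavy <- idx
  m <- atoms$mass[heavy]
  unname(colSums(xyz[heavy, , drop = FALSE] * m) / sum(m))
}
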
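# Ligand chemistry annotations: which ligand atoms are aromatic ring
# members, hydrogen-bond donors/acceptors, charged, or nonpolar. Supplied
# explicitly (as the force field encodes them), never perceived.

#' Describe the chemistry of a ligand residue
#'
#' @param resname 3-letter residue name of the ligand.
#' @param chain optional chain id; `NULL` means every copy (one per
#'   subunit) is analyzed.
#' @param resno optional residue number.
#' @param ring_groups list of ordered atom-name vectors, >= 5 members each.
#' @param hbond_donors heavy-atom names bearing polar hydrogens.
#' @param hbond_acceptors heavy-atom acceptor names.
#' @param positive_groups list of atom-name vectors carrying + charge.
#' @param negative_groups list of atom-name vectors carrying - charge.
#' @param nonpolar_atoms carbon atom names counted for apolar contacts.
#' @return object of class `ligand_spec`.
#' @export
ligand_spec <- function(resname, chain = NULL, resno = NULL,
                        ring_groups = list(), hbond_donors = character(0),
                        hbond_acceptors = character(0),
                        positive_groups = list(), negative_groups = list(),
                        nonpolar_atoms = character(0)) {
  ring_groups <- lapply(ring_groups, as.character)
  if (any(vapply(ring_groups, length, integer(1)) < 5L)) {
    stop("every ring group needs at least 5 members")
  }
  structure(
    list(
      resname = resname, chain = chain, resno = resno,
      ring_groups = ring_groups,
      hbond_donors = as.character(hbond_donors),
      hbond_acceptors = as.character(hbond_acceptors),
      positive_groups = lapply(positive_groups, as.character),
      negative_groups = lapply(negative_groups, as.character),
      nonpolar_atoms = as.character(nonpolar_atoms)
    ),
    class = "ligand_spec"
  )
}

#' Read / write a ligand spec as JSON
#'
#' @param path file path.
#' @return for `read_ligand_spec`, a `ligand_spec`.
#' @export
read_ligand_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  groups <- function(g) {
    if (is.null(g)) list() else if (is.list(g)) g else list(g)
  }
  ligand_spec(
    resname = x$resname, chain = x$chain, resno = x$resno,
    ring_groups = groups(x$ring_groups),
    hbond_donors = x$hbond_donors %||% character(0),
    hbond_acceptors = x$hbond_acceptors %||% character(0),
    positive_groups = groups(x$positive_groups),
    negative_groups = groups(x$negative_groups),
    nonpolar_atoms = x$nonpolar_atoms %||% character(0)
  )
}

#' @rdname read_ligand_spec
#' @param spec a `ligand_spec`.
#' @export
write_ligand_spec <- function(spec, path) {
  jsonlite::write_json(
    unclass(spec), path,
    auto_unbox = TRUE, null = "null", pretty = TRUE
  )
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Resolve a ligand copy in a structure: returns indices of the ligand
# residue's atoms plus name lookup; errors on unknown annotated atoms.
.resolve_ligand <- function(structure, spec, chain = NULL) {
  a <- structure$atoms
  sel <- toupper(a$resname) == toupper(spec$resname)
  if (!is.null(chain)) sel <- sel & a$chain == chain
  if (!is.null(spec$chain) && is.null(chain)) sel <- sel & a$chain == spec$chain
  if (!is.null(spec$resno)) sel <- sel & a$resno == spec$resno
  idx <- which(sel)
  if (!length(idx)) {
    stop(
      "ligand residue ", spec$resname,
      if (!is.null(chain)) paste0(" in chain ", chain), " not found"
    )
  }
  names_here <- a$name[idx]
  lookup <- function(atom_names) {
    pos <- match(atom_names, names_here)
    if (anyNA(pos)) {
      stop(
        "ligand annotation references missing atom(s): ",
        paste(atom_names[is.na(pos)], collapse = ", ")
      )
    }
    idx[pos]
  }
  donors_accept <- c(spec$hbond_donors, spec$hbond_acceptors)
  bad <- donors_accept[!a$element[lookup(donors_accept)] %in% c("N", "O", "S")]
  if (length(bad)) {
    stop(
      "donor/acceptor atoms must be N/O/S: ",
      paste(unique(bad), collapse = ", ")
    )
  }
  list(
    atoms = idx,
    heavy = idx[a$element[idx] != "H"],
    rings = lapply(spec$ring_groups, lookup),
    donors = lookup(spec$hbond_donors),
    acceptors = lookup(spec$hbond_acceptors),
    positive = lapply(spec$positive_groups, lookup),
    negative = lapply(spec$negative_groups, lookup),
    nonpolar = lookup(spec$nonpolar_atoms),
    chain = unique(a$chain[idx])[1L]
  )
}

# Chains holding a copy of the ligand residue.
.ligand_chains <- function(structure, spec) {
  a <- structure$atoms
  sel <- toupper(a$resname) == toupper(spec$resname)
  if (!is.null(spec$chain)) sel <- sel & a$chain == spec$chain
  if (!is.null(spec$resno)) sel <- sel & a$resno == spec$resno
  sort(unique(a$chain[sel]))
}
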
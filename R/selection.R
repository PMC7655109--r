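# Declarative atom selections.

.backbone_names <- c("N", "CA", "C", "O", "OXT")

#' Build a declarative atom selection
#'
#' Each supplied field adds a constraint; constraints intersect. An empty
#' spec (no constraints at all) selects nothing.
#'
#' @param chains character vector of chain ids.
#' @param residue_ranges list of `c(start, end)` residue-number ranges
#'   (inclusive, insertion codes ordered after the plain number).
#' @param residue_names character vector of 3-letter residue names.
#' @param atom_names character vector of atom names.
#' @param element_classes any of `"backbone"`, `"calpha"`, `"heavy"`,
#'   `"water_oxygen"`, `"sidechain"`.
#' @param hetero logical; keep only HETATM (`TRUE`) or only ATOM (`FALSE`).
#' @return an object of class `selection_spec`.
#' @export
selection_spec <- function(chains = NULL, residue_ranges = NULL,
                           residue_names = NULL, atom_names = NULL,
                           element_classes = NULL, hetero = NULL) {
  if (!is.null(residue_ranges)) {
    if (!is.list(residue_ranges)) residue_ranges <- list(residue_ranges)
    ok <- vapply(
      residue_ranges,
      function(r) length(r) == 2L && r[1] <= r[2], logical(1)
    )
    if (!all(ok)) stop("residue_ranges must be c(start, end) with start <= end")
  }
  if (!is.null(element_classes)) {
    known <- c("backbone", "calpha", "heavy", "water_oxygen", "sidechain")
    bad <- setdiff(element_classes, known)
    if (length(bad)) stop("unknown element class: ", paste(bad, collapse = ", "))
  }
  structure(
    list(
      chains = chains, residue_ranges = residue_ranges,
      residue_names = residue_names, atom_names = atom_names,
      element_classes = element_classes, hetero = hetero
    ),
    class = "selection_spec"
  )
}

#' Resolve a selection to atom indices
#'
#' Deterministic and order-preserving: indices come back in topology order.
#' A constraint naming an unknown chain yields an empty selection with a
#' warning rather than an error.
#'
#' @param structure a `Structure`.
#' @param spec a [selection_spec()].
#' @return integer vector of atom indices.
#' @export
select_atoms <- function(structure, spec) {
  stopifnot(inherits(structure, "Structure"), inherits(spec, "selection_spec"))
  a <- structure$atoms
  if (all(vapply(spec, is.null, logical(1)))) {
    return(integer(0))
  }
  keep <- rep(TRUE, nrow(a))
  if (!is.null(spec$chains)) {
    if (!any(spec$chains %in% a$chain)) {
      warning(
        "selection references unknown chain(s): ",
        paste(setdiff(spec$chains, a$chain), collapse = ", "),
        call. = FALSE
      )
    }
    keep <- keep & a$chain %in% spec$chains
  }
  if (!is.null(spec$residue_ranges)) {
    in_any <- rep(FALSE, nrow(a))
    for (r in spec$residue_ranges) {
      in_any <- in_any | (a$resno >= r[1] & a$resno <= r[2])
    }
    keep <- keep & in_any
  }
  if (!is.null(spec$residue_names)) {
    keep <- keep & toupper(a$resname) %in% toupper(spec$residue_names)
  }
  if (!is.null(spec$atom_names)) {
    keep <- keep & a$name %in% spec$atom_names
  }
  if (!is.null(spec$element_classes)) {
    cls <- rep(FALSE, nrow(a))
    for (ec in spec$element_classes) {
      cls <- cls | switch(ec,
        backbone = a$name %in% .backbone_names & !.is_water(a$resname),
        calpha = a$name == "CA" & a$element == "C",
        heavy = a$element != "H",
        water_oxygen = .is_water(a$resname) & a$element == "O",
        sidechain = !(a$name %in% .backbone_names) & !.is_water(a$resname)
      )
    }
    keep <- keep & cls
  }
  if (!is.null(spec$hetero)) keep <- keep & (a$het == spec$hetero)
  which(keep)
}
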
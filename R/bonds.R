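# Covalent bond inference from inter-atomic distances.

# Cordero-style single-bond covalent radii (angstrom).
.covalent_radii <- c(
  H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05, P = 1.07,
  F = 0.57, Cl = 1.02, Br = 1.20, I = 1.39, Se = 1.20,
  Na = 1.66, K = 2.03, Mg = 1.41, Ca = 1.76, Zn = 1.22, Fe = 1.32,
  Mn = 1.39, Cu = 1.32, Ni = 1.24, Co = 1.26, Cd = 1.44, X = 0.77
)

.covalent_radius <- function(element) {
  r <- .covalent_radii[element]
  r[is.na(r)] <- .covalent_radii[["X"]]
  unname(r)
}

#' Infer covalent bonds from geometry
#'
#' Atoms i and j are bonded iff their distance does not exceed the sum of
#' their covalent radii plus `tolerance`. Bonds involving a water atom are
#' only kept within the same water residue, and hydrogen-heavy bonds are
#' only accepted up to 1.25 angstrom.
#'
#' @param structure a `Structure`.
#' @param tolerance slack added to the covalent-radius sum (default 0.45).
#' @return two-column integer matrix of bonded atom index pairs (i < j).
#' @export
infer_bonds <- function(structure, tolerance = 0.45) {
  a <- structure$atoms
  xyz <- coords(structure)
  n <- nrow(xyz)
  if (n < 2L) {
    return(matrix(integer(0), ncol = 2L))
  }
  rad <- .covalent_radius(a$element)
  d <- .cross_dist(xyz, xyz)
  diag(d) <- Inf

  # physicality check: non-altloc heavy-atom clashes
  clash <- which(d < 0.5, arr.ind = TRUE)
  clash <- clash[clash[, 1] < clash[, 2], , drop = FALSE]
  if (nrow(clash)) {
    same_alt <- a$altloc[clash[, 1]] == a$altloc[clash[, 2]] |
      !nzchar(a$altloc[clash[, 1]]) | !nzchar(a$altloc[clash[, 2]])
    clash <- clash[same_alt, , drop = FALSE]
    if (nrow(clash)) {
      pairs <- apply(clash, 1L, function(p) paste(p[1], p[2], sep = "-"))
      stop(
        "atoms closer than 0.5 angstrom: ",
        paste(utils::head(pairs, 10L), collapse = ", ")
      )
    }
  }

  cutoff <- outer(rad, rad, "+") + tolerance
  hyd <- a$element == "H"
  h_pair <- outer(hyd, hyd, "|")
  cutoff[h_pair] <- pmin(cutoff[h_pair], 1.25)

  hit <- which(d <= cutoff, arr.ind = TRUE)
  hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
  if (!nrow(hit)) {
    return(matrix(integer(0), ncol = 2L))
  }
  # no bonds to/through water unless both atoms are in the same residue
  wat <- .is_water(a$resname)
  res_key <- paste(a$chain, a$resno, a$icode, a$resname, sep = "\r")
  keep <- !(wat[hit[, 1]] | wat[hit[, 2]]) |
    res_key[hit[, 1]] == res_key[hit[, 2]]
  # never bond two hydrogens
  keep <- keep & !(hyd[hit[, 1]] & hyd[hit[, 2]])
  hit <- hit[keep, , drop = FALSE]
  hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
  storage.mode(hit) <- "integer"
  dimnames(hit) <- NULL
  hit
}
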
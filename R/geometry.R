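# Primitive geometry: dihedrals, ring planes, Kabsch superposition, RMSD,
# minimum distances. All inputs/outputs in angstrom and degrees.

#' Signed dihedral angle
#'
#' IUPAC sign convention: looking down the p2 -> p3 bond, a clockwise
#' rotation of the distal bond is positive. Result in (-180, 180].
#'
#' @param p1,p2,p3,p4 3-vectors (angstrom).
#' @return signed angle in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  if (.vnorm(n1) < 1e-9 || .vnorm(n2) < 1e-9) {
    stop("undefined dihedral: three consecutive points are collinear")
  }
  b2u <- b2 / .vnorm(b2)
  ang <- atan2(sum(.cross3(n1, n2) * b2u), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Best-fit ring plane
#'
#' Least-squares plane through an ordered ring of atoms (>= 5 members). The
#' unit normal's sign follows the right-hand rule over the member order.
#'
#' @param xyz full coordinate matrix, or the ring coordinates themselves.
#' @param idx optional atom indices of the ring members, in ring order.
#' @return list with `member_indices`, `centroid`, `unit_normal`.
#' @export
ring_geometry <- function(xyz, idx = NULL) {
  pts <- if (is.null(idx)) matrix(xyz, ncol = 3L) else xyz[idx, , drop = FALSE]
  if (nrow(pts) < 5L) stop("a ring needs at least 5 members")
  ctr <- colMeans(pts)
  centered <- sweep(pts, 2L, ctr)
  sv <- svd(centered)
  normal <- sv$v[, 3L]
  if (sv$d[2L] < 1e-8) stop("degenerate ring: members are collinear")
  # orient by the polygon's winding
  winding <- c(0, 0, 0)
  n <- nrow(centered)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    winding <- winding + .cross3(centered[i, ], centered[j, ])
  }
  if (sum(winding * normal) < 0) normal <- -normal
  list(
    member_indices = idx, centroid = ctr,
    unit_normal = normal / .vnorm(normal)
  )
}

#' Kabsch least-squares superposition
#'
#' Finds the proper rotation and translation minimizing the RMSD of
#' `mobile` onto `reference` (equal weights). The reflection branch of the
#' SVD is corrected so `det(rotation) == +1`.
#'
#' @param mobile,reference n x 3 coordinate matrices, n >= 3.
#' @return list with `rotation` (3 x 3), `translation` (length 3), `rmsd`.
#'   Transformed coordinates are `mobile %*% rotation + translation`.
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- matrix(mobile, ncol = 3L)
  reference <- matrix(reference, ncol = 3L)
  if (nrow(mobile) != nrow(reference)) stop("point counts differ")
  if (nrow(mobile) < 3L) stop("need at least 3 points")
  mc <- colMeans(mobile)
  rc <- colMeans(reference)
  m0 <- sweep(mobile, 2L, mc)
  r0 <- sweep(reference, 2L, rc)
  if (svd(m0)$d[2L] < 1e-9) stop("degenerate (collinear) configuration")
  h <- crossprod(m0, r0)
  sv <- svd(h)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  rot <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  fitted <- m0 %*% rot
  rmsd <- sqrt(mean(rowSums((fitted - r0)^2)))
  list(
    rotation = rot,
    translation = as.numeric(rc - mc %*% rot),
    rmsd = rmsd
  )
}

#' Apply a superposition transform
#'
#' @param xyz n x 3 coordinates.
#' @param sp result of [kabsch_superpose()].
#' @return transformed n x 3 coordinates.
#' @export
apply_superposition <- function(xyz, sp) {
  sweep(matrix(xyz, ncol = 3L) %*% sp$rotation, 2L, sp$translation, "+")
}

#' RMSD after alignment on a separate selection
#'
#' The transform is fitted on `align_idx` only and the RMSD is reported on
#' `measure_idx` only, without re-fitting on the measured set.
#'
#' @param frame,reference full coordinate matrices of matching atom order.
#' @param align_idx indices used to fit the superposition.
#' @param measure_idx indices over which the RMSD is evaluated.
#' @return RMSD in angstrom.
#' @export
rmsd_after_alignment <- function(frame, reference, align_idx, measure_idx) {
  if (!length(measure_idx)) stop("empty measure selection")
  if (max(c(align_idx, measure_idx)) > nrow(frame) ||
      max(c(align_idx, measure_idx)) > nrow(reference)) {
    stop("selection index out of range")
  }
  sp <- kabsch_superpose(
    frame[align_idx, , drop = FALSE],
    reference[align_idx, , drop = FALSE]
  )
  moved <- apply_superposition(frame[measure_idx, , drop = FALSE], sp)
  sqrt(mean(rowSums((moved - reference[measure_idx, , drop = FALSE])^2)))
}

#' Minimum inter-set distance
#'
#' Exact minimum over the Cartesian product of the two coordinate sets;
#' ties break to the lowest index pair (first set varying slowest).
#'
#' @param setA,setB coordinate matrices (n x 3), non-empty.
#' @return list with `distance` (angstrom) and `pair` (1-based indices
#'   `c(iA, iB)`).
#' @export
min_distance <- function(setA, setB) {
  setA <- matrix(setA, ncol = 3L)
  setB <- matrix(setB, ncol = 3L)
  if (!nrow(setA) || !nrow(setB)) stop("empty coordinate set")
  d <- .cross_dist(setA, setB)
  best <- min(d)
  hits <- which(d <= best + 1e-12, arr.ind = TRUE)
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  list(distance = best, pair = as.integer(hits[1L, ]))
}

# Rigid-transform helper used by tests and generators: random proper
# rotation + translation.
#' Random rigid transform
#'
#' Draws a uniformly random proper rotation and a translation, returned as
#' a function mapping n x 3 coordinates (used in invariance testing).
#'
#' @param translation_scale standard deviation of the translation (angstrom).
#' @return list with `rotation`, `translation`, and `apply(xyz)`.
#' @export
random_rigid_transform <- function(translation_scale = 20) {
  m <- matrix(stats::rnorm(9), 3L)
  qr_ <- qr(m)
  q <- qr.Q(qr_)
  q <- q %*% diag(sign(diag(qr.R(qr_))))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  tr <- stats::rnorm(3, sd = translation_scale)
  list(
    rotation = q, translation = tr,
    apply = function(xyz) {
      sweep(matrix(xyz, ncol = 3L) %*% q, 2L, tr, "+")
    }
  )
}
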
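# Maximal-sphere pore radius profile along the channel axis.
#
# At each axial position z the profiler finds the largest sphere whose
# center lies in the plane perpendicular to the axis and whose radius is
# min over atoms of (center-atom distance - vdw radius). Unlike HOLE's
# Monte Carlo annealing, the in-plane optimization is a deterministic
# multi-start pattern search with geometric step shrinking, which converges
# to the same optimum on convex pore cross-sections and makes repeated runs
# bit-identical.

# Bondi van der Waals radii (angstrom); swappable via pore_config.
.bondi_radii <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47, P = 1.80, S = 1.80,
  Cl = 1.75, Br = 1.85, I = 1.98, Na = 2.27, K = 2.75, X = 1.70
)

#' Pore-profiler configuration
#'
#' @param vdw_radii named vector of van der Waals radii by element (Bondi
#'   set by default; unknown elements fall back to `X`).
#' @param max_radius radius cap in angstrom (default 10); planes with no
#'   atom within reach are flagged unbounded.
#' @param step axial sampling step in angstrom (default 0.5).
#' @param search_tol in-plane convergence tolerance (default 1e-8).
#' @param max_center_shift largest allowed in-plane distance between a
#'   plane's center and its warm start (default 5).
#' @return object of class `pore_config`.
#' @export
pore_config <- function(vdw_radii = .bondi_radii, max_radius = 10,
                        step = 0.5, search_tol = 1e-8,
                        max_center_shift = 5) {
  if (step <= 0) stop("step must be positive")
  structure(
    list(
      vdw_radii = vdw_radii, max_radius = max_radius, step = step,
      search_tol = search_tol, max_center_shift = max_center_shift
    ),
    class = "pore_config"
  )
}

.vdw_of <- function(elements, table) {
  r <- table[elements]
  r[is.na(r)] <- table[["X"]]
  unname(r)
}

#' Principal axis of a structure
#'
#' The dominant principal component of the CA coordinates (all heavy atoms
#' if no CA present): for an elongated pentameric channel this is the C5
#' symmetry / pore axis. The sign is fixed by the third moment of the axial
#' coordinate so the result is rotation-covariant.
#'
#' @param structure a `Structure`.
#' @return list with unit `axis` and `anchor` (the centroid).
#' @export
principal_axis <- function(structure) {
  a <- structure$atoms
  idx <- which(a$name == "CA" & a$element == "C")
  if (length(idx) < 3L) idx <- which(a$element != "H")
  xyz <- coords(structure)[idx, , drop = FALSE]
  ctr <- colMeans(xyz)
  cen <- sweep(xyz, 2L, ctr)
  ev <- eigen(crossprod(cen) / nrow(cen), symmetric = TRUE)
  ax <- ev$vectors[, 1L]
  proj <- cen %*% ax
  if (sum(proj^3) < 0) ax <- -ax
  list(axis = as.numeric(ax), anchor = as.numeric(ctr))
}

# Deterministic in-plane maximization of
#   f(c) = min_i (|c - atom_i| - vdw_i)
# with c constrained to the plane anchor + z*axis + span{u, v}.
.plane_objective <- function(xyz, vdw, origin3, u, v) {
  force(xyz)
  # vectorized: `c2` is an m x 2 matrix of in-plane candidates
  function(c2) {
    c2 <- matrix(c2, ncol = 2L)
    p <- cbind(
      origin3[1] + u[1] * c2[, 1] + v[1] * c2[, 2],
      origin3[2] + u[2] * c2[, 1] + v[2] * c2[, 2],
      origin3[3] + u[3] * c2[, 1] + v[3] * c2[, 2]
    )
    d2 <- outer(rowSums(p^2), rowSums(xyz^2), "+") - 2 * tcrossprod(p, xyz)
    d2[d2 < 0] <- 0
    apply(sweep(sqrt(d2), 2L, vdw), 1L, min)
  }
}

# polar pattern search: 16 directions, shrinking steps; robust for the
# conical objective near a maximal-sphere optimum and fully deterministic.
.pattern_search <- function(fn, start, step0, tol, max_shift, cap) {
  ang <- (0:15) * (pi / 8)
  dirs <- cbind(cos(ang), sin(ang))
  best <- start
  fbest <- fn(rbind(best))
  step <- step0
  while (step > tol) {
    improved <- TRUE
    while (improved && fbest < cap) {
      improved <- FALSE
      cand <- sweep(dirs * step, 2L, best, "+")
      ok <- sqrt(rowSums(cand^2)) <= max_shift
      if (any(ok)) {
        vals <- fn(cand[ok, , drop = FALSE])
        i <- which.max(vals)
        if (vals[i] > fbest + 1e-15) {
          fbest <- vals[i]
          best <- cand[ok, , drop = FALSE][i, ]
          improved <- TRUE
        }
      }
    }
    step <- step * 0.4
  }
  list(center = best, value = fbest)
}

#' Largest sphere in one axial plane
#'
#' @param structure a single-frame `Structure`, already stripped of waters,
#'   ligands and ions (see [strip_for_pore()]).
#' @param z axial coordinate of the plane, relative to `anchor` (angstrom).
#' @param axis unit 3-vector of the pore axis.
#' @param anchor 3-vector; the plane is `anchor + z * axis + ` span of the
#'   in-plane directions.
#' @param prev_center in-plane 2-vector warm start (default origin).
#' @param config a [pore_config()].
#' @return list with `radius`, `center` (in-plane 2-vector), `center3d`,
#'   and `unbounded` flag.
#' @export
pore_radius_at <- function(structure, z, axis, anchor,
                           prev_center = c(0, 0),
                           config = pore_config()) {
  axis <- .unit(axis)
  a <- structure$atoms
  xyz <- coords(structure)
  vdw <- .vdw_of(a$element, config$vdw_radii)

  # in-plane basis from the world vector least aligned with the axis; the
  # optimum itself is basis-independent once converged.
  e <- diag(3L)[, which.min(abs(axis))]
  u <- .unit(e - sum(e * axis) * axis)
  v <- .cross3(axis, u)
  origin3 <- anchor + z * axis

  # atoms that could possibly bound a sphere of radius <= max_radius whose
  # center stays within max_center_shift of the warm start
  h <- as.numeric(sweep(xyz, 2L, origin3) %*% axis)
  keep <- abs(h) <= config$max_radius + vdw
  if (any(keep)) {
    start3 <- origin3 + u * prev_center[1L] + v * prev_center[2L]
    dd <- sqrt(colSums((t(xyz) - start3)^2))
    keep <- keep & (dd - vdw) <= config$max_radius + config$max_center_shift
  }
  if (!any(keep)) {
    return(list(
      radius = config$max_radius, center = prev_center,
      center3d = origin3 + u * prev_center[1L] + v * prev_center[2L],
      unbounded = TRUE
    ))
  }
  fn <- .plane_objective(
    xyz[keep, , drop = FALSE], vdw[keep], origin3, u, v
  )
  starts <- rbind(
    prev_center,
    c(0, 0),
    prev_center + c(0.75, 0.75)
  )
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    r <- .pattern_search(
      fn, starts[s, ], step0 = 1.0, tol = config$search_tol,
      max_shift = config$max_center_shift, cap = config$max_radius
    )
    if (is.null(best) || r$value > best$value) best <- r
  }
  unbounded <- best$value >= config$max_radius
  list(
    radius = min(best$value, config$max_radius),
    center = best$center,
    center3d = origin3 + u * best$center[1L] + v * best$center[2L],
    unbounded = unbounded
  )
}

#' Strip solvent, ligands and ions before pore profiling
#'
#' @param structure a `Structure`.
#' @param ligand_resnames residue names to remove besides waters and
#'   monatomic ions.
#' @return the stripped `Structure`.
#' @export
strip_for_pore <- function(structure, ligand_resnames = character(0)) {
  a <- structure$atoms
  drop <- .is_water(a$resname) |
    toupper(a$resname) %in% .ion_resnames |
    toupper(a$resname) %in% toupper(ligand_resnames)
  new_structure(
    a[!drop, , drop = FALSE],
    identifier = structure$identifier
  )
}

#' Pore radius profile along the axis
#'
#' Sweeps [pore_radius_at()] over an axial grid, warm-starting each plane's
#' center from its neighbor, outward in both directions from the midpoint.
#'
#' @param structure a single-frame `Structure` (pre-stripped; see
#'   [strip_for_pore()]).
#' @param axis unit axis; `NULL` uses [principal_axis()].
#' @param anchor axis anchor point; `NULL` uses the centroid.
#' @param z_range `c(min, max)` axial window relative to the anchor.
#' @param config a [pore_config()].
#' @param roles optional [residue_role_map()]; when given, the minimum
#'   sample is annotated with the nearest pore-marker residue label.
#' @return object of class `pore_profile`: data.frame `samples` with
#'   (z, center_x, center_y, radius, unbounded) plus `axis`, `anchor`,
#'   and `minimum` (list with z, radius, and optionally `marker`).
#' @export
pore_profile <- function(structure, axis = NULL, anchor = NULL,
                         z_range = NULL, config = pore_config(),
                         roles = NULL) {
  if (is.null(axis) || is.null(anchor)) {
    pa <- principal_axis(structure)
    if (is.null(axis)) axis <- pa$axis
    if (is.null(anchor)) anchor <- pa$anchor
  }
  axis <- .unit(axis)
  if (is.null(z_range)) {
    h <- as.numeric(sweep(coords(structure), 2L, anchor) %*% axis)
    z_range <- range(h)
  }
  zs <- seq(z_range[1L], z_range[2L], by = config$step)
  mid <- which.min(abs(zs - mean(z_range)))
  order_sweep <- c(mid:length(zs), if (mid > 1L) (mid - 1L):1L)
  res <- vector("list", length(zs))
  ctr_up <- c(0, 0)
  ctr_dn <- c(0, 0)
  for (i in order_sweep) {
    warm <- if (i >= mid) ctr_up else ctr_dn
    r <- pore_radius_at(structure, zs[i], axis, anchor, warm, config)
    res[[i]] <- r
    if (i >= mid) ctr_up <- r$center else ctr_dn <- r$center
    if (i == mid) ctr_dn <- r$center
  }
  samples <- data.frame(
    z = zs,
    center_x = vapply(res, function(r) r$center[1L], numeric(1)),
    center_y = vapply(res, function(r) r$center[2L], numeric(1)),
    radius = vapply(res, function(r) r$radius, numeric(1)),
    unbounded = vapply(res, function(r) r$unbounded, logical(1))
  )
  bounded <- which(!samples$unbounded)
  min_i <- if (length(bounded)) {
    bounded[which.min(samples$radius[bounded])]
  } else {
    which.min(samples$radius)
  }
  minimum <- list(z = samples$z[min_i], radius = samples$radius[min_i])
  if (!is.null(roles) && length(roles$pore_marker_residues)) {
    ctr3 <- res[[min_i]]$center3d
    a <- structure$atoms
    marks <- roles$pore_marker_residues
    dmin <- vapply(marks, function(rn) {
      idx <- which(a$resno == rn)
      if (!length(idx)) {
        return(Inf)
      }
      min(sqrt(rowSums(sweep(coords(structure)[idx, , drop = FALSE],
                             2L, ctr3)^2)))
    }, numeric(1))
    if (any(is.finite(dmin))) {
      minimum$marker <- names(marks)[which.min(dmin)]
      minimum$marker_resno <- unname(marks[which.min(dmin)])
    }
  }
  structure(
    list(
      samples = samples, axis = axis, anchor = anchor, minimum = minimum,
      vdw_set_name = "bondi"
    ),
    class = "pore_profile"
  )
}

#' @export
print.pore_profile <- function(x, ...) {
  cat(sprintf(
    "<pore_profile> %d samples, z in [%.1f, %.1f]; minimum radius %.2f A at z = %.1f%s\n",
    nrow(x$samples), min(x$samples$z), max(x$samples$z),
    x$minimum$radius, x$minimum$z,
    if (!is.null(x$minimum$marker)) paste0(" (", x$minimum$marker, ")") else ""
  ))
  invisible(x)
}

#' Cross-frame pore statistics
#'
#' Per-z mean and sample standard deviation over a list of profiles sharing
#' one z grid (e.g. equidistant simulation frames).
#'
#' @param profiles list of `pore_profile` objects.
#' @return data.frame with `z`, `mean_radius`, `sd_radius`, `n_frames`.
#' @export
profile_statistics <- function(profiles) {
  if (length(profiles) < 2L) stop("need at least 2 profiles")
  zs <- profiles[[1L]]$samples$z
  for (p in profiles[-1L]) {
    if (length(p$samples$z) != length(zs) ||
        max(abs(p$samples$z - zs)) > 1e-9) {
      stop("profiles are not on a common z grid")
    }
  }
  m <- vapply(profiles, function(p) p$samples$radius, numeric(length(zs)))
  data.frame(
    z = zs,
    mean_radius = rowMeans(m),
    sd_radius = apply(m, 1L, stats::sd),
    n_frames = length(profiles)
  )
}
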
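# Independent brute-force oracles. These re-derive every criterion from
# raw coordinates with plain O(N^2) loops and their own chemistry tables,
# deliberately sharing no code with the package implementation.

odist <- function(p, q) sqrt(sum((p - q)^2))

oracle_min_distance <- function(A, B) {
  best <- Inf
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(nrow(B))) {
      d <- odist(A[i, ], B[j, ])
      if (d < best) best <- d
    }
  }
  best
}

# signed dihedral via an independent construction: project the outer bonds
# onto the plane perpendicular to the central bond and take the signed
# angle between the projections.
oracle_dihedral <- function(p1, p2, p3, p4) {
  b <- p3 - p2
  b <- b / sqrt(sum(b^2))
  u <- (p1 - p2) - sum((p1 - p2) * b) * b
  w <- (p4 - p3) - sum((p4 - p3) * b) * b
  x <- sum(u * w)
  det3 <- sum(b * c(
    u[2] * w[3] - u[3] * w[2],
    u[3] * w[1] - u[1] * w[3],
    u[1] * w[2] - u[2] * w[1]
  ))
  ang <- atan2(det3, x) * 180 / pi
  if (ang <= -180) ang + 360 else ang
}

# least-squares superposition RMSD by direct numerical optimization over
# Euler angles + translation (no SVD).
oracle_kabsch_rmsd <- function(mobile, reference) {
  rotmat <- function(a) {
    cx <- cos(a[1]); sx <- sin(a[1])
    cy <- cos(a[2]); sy <- sin(a[2])
    cz <- cos(a[3]); sz <- sin(a[3])
    rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
    ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
    rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
    rx %*% ry %*% rz
  }
  m0 <- sweep(mobile, 2, colMeans(mobile))
  r0 <- sweep(reference, 2, colMeans(reference))
  f <- function(a) {
    sqrt(mean(rowSums((m0 %*% t(rotmat(a)) - r0)^2)))
  }
  best <- Inf
  for (s in 1:8) {
    a0 <- c(s %% 2, (s %/% 2) %% 2, (s %/% 4) %% 2) * pi
    o <- stats::optim(a0, f, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
    o <- stats::optim(o$par, f, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
    if (o$value < best) best <- o$value
  }
  best
}

# ---- fingerprint oracle -------------------------------------------------

o_ring_tables <- list(
  PHE = list(c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")),
  TYR = list(c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")),
  HIS = list(c("CG", "ND1", "CE1", "NE2", "CD2")),
  TRP = list(
    c("CG", "CD1", "NE1", "CE2", "CD2"),
    c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3")
  )
)
o_donor_tables <- list(
  ARG = c("NE", "NH1", "NH2"), LYS = "NZ", HIS = c("ND1", "NE2"),
  HIP = c("ND1", "NE2"), TRP = "NE1", ASN = "ND2", GLN = "NE2",
  SER = "OG", THR = "OG1", TYR = "OH", CYS = "SG"
)
o_acceptor_tables <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  SER = "OG", THR = "OG1", TYR = "OH", HIS = c("ND1", "NE2"), MET = "SD"
)
o_pos_tables <- list(
  ARG = c("NE", "NH1", "NH2"), LYS = "NZ",
  HIP = c("ND1", "NE2"), HSP = c("ND1", "NE2")
)
o_neg_tables <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

o_is_water <- function(rn) toupper(rn) %in% c("HOH", "WAT", "TIP3", "SOL")

# hydrogens attached to atom i (same residue, H, within 1.25 A)
o_hydrogens <- function(a, xyz, i) {
  out <- list()
  for (j in seq_len(nrow(a))) {
    if (a$element[j] == "H" && a$chain[j] == a$chain[i] &&
        a$resno[j] == a$resno[i] && a$resname[j] == a$resname[i] &&
        odist(xyz[i, ], xyz[j, ]) <= 1.25) {
      out[[length(out) + 1L]] <- xyz[j, ]
    }
  }
  out
}

o_hbond <- function(a, xyz, don, acc, cfg) {
  if (odist(xyz[don, ], xyz[acc, ]) > cfg$hbond_heavy_cutoff) {
    return(FALSE)
  }
  hs <- o_hydrogens(a, xyz, don)
  if (!length(hs)) {
    return(TRUE)
  }
  for (h in hs) {
    v1 <- xyz[don, ] - h
    v2 <- xyz[acc, ] - h
    ang <- acos(max(-1, min(1, sum(v1 * v2) /
                              sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
    if (ang >= cfg$hbond_angle_min) {
      return(TRUE)
    }
  }
  FALSE
}

# ring normal by averaging consecutive edge cross products (not SVD)
o_ring_normal <- function(pts) {
  ctr <- colMeans(pts)
  n <- c(0, 0, 0)
  m <- nrow(pts)
  for (i in seq_len(m)) {
    u <- pts[i, ] - ctr
    w <- pts[if (i == m) 1L else i + 1L, ] - ctr
    n <- n + c(
      u[2] * w[3] - u[3] * w[2],
      u[3] * w[1] - u[1] * w[3],
      u[1] * w[2] - u[2] * w[1]
    )
  }
  n / sqrt(sum(n^2))
}

# full 9-bit oracle for one residue of one single-frame structure
oracle_bits <- function(st, ligspec, chain, resno,
                        cfg = fingerprint_config()) {
  a <- st$atoms
  xyz <- coords(st)
  bits <- stats::setNames(rep(FALSE, 9L), fingerprint_bits)

  L <- which(toupper(a$resname) == toupper(ligspec$resname))
  lat <- function(nms) L[match(nms, a$name[L])]
  R <- which(a$chain == chain & a$resno == resno &
               !o_is_water(a$resname) & !seq_len(nrow(a)) %in% L)
  rn <- toupper(a$resname[R][1])
  if (rn %in% c("HSD", "HSE", "HID", "HIE")) rn <- "HIS"

  # APOLAR
  for (i in lat(ligspec$nonpolar_atoms)) {
    for (j in R[a$element[R] == "C"]) {
      if (odist(xyz[i, ], xyz[j, ]) <= cfg$apolar_cutoff) {
        bits["APOLAR"] <- TRUE
      }
    }
  }

  # aromatic
  rdefs <- o_ring_tables[[if (rn %in% c("HIP", "HSP")) "HIS" else rn]]
  if (!is.null(rdefs)) {
    for (rd in rdefs) {
      ridx <- R[match(rd, a$name[R])]
      if (anyNA(ridx)) next
      for (lg in ligspec$ring_groups) {
        lidx <- lat(lg)
        mind <- oracle_min_distance(
          xyz[lidx, , drop = FALSE], xyz[ridx, , drop = FALSE]
        )
        if (mind > cfg$aromatic_cutoff) next
        n1 <- o_ring_normal(xyz[lidx, , drop = FALSE])
        n2 <- o_ring_normal(xyz[ridx, , drop = FALSE])
        ang <- acos(min(1, abs(sum(n1 * n2)))) * 180 / pi
        if (ang <= cfg$ftf_normal_angle_max) {
          bits["AROM_FTF"] <- TRUE
        } else {
          bits["AROM_ETF"] <- TRUE
        }
      }
    }
  }

  # residue polar atoms
  r_don <- R[a$name[R] %in% c(if (rn != "PRO") "N", o_donor_tables[[rn]])]
  r_acc <- R[a$name[R] %in% c("O", "OXT", o_acceptor_tables[[rn]])]

  for (d in r_don) {
    for (acc in lat(ligspec$hbond_acceptors)) {
      if (o_hbond(a, xyz, d, acc, cfg)) bits["HB_PROT_DONOR"] <- TRUE
    }
  }
  for (acc in r_acc) {
    for (d in lat(ligspec$hbond_donors)) {
      if (o_hbond(a, xyz, d, acc, cfg)) bits["HB_PROT_ACCEPTOR"] <- TRUE
    }
  }

  # electrostatics
  pos <- R[a$name[R] %in% o_pos_tables[[rn]]]
  neg <- R[a$name[R] %in% o_neg_tables[[rn]]]
  if (length(pos)) {
    for (grp in ligspec$negative_groups) {
      if (oracle_min_distance(
        xyz[pos, , drop = FALSE], xyz[lat(grp), , drop = FALSE]
      ) <= cfg$electrostatic_cutoff) {
        bits["ELEC_PROT_POS"] <- TRUE
      }
    }
  }
  if (length(neg)) {
    for (grp in ligspec$positive_groups) {
      if (oracle_min_distance(
        xyz[neg, , drop = FALSE], xyz[lat(grp), , drop = FALSE]
      ) <= cfg$electrostatic_cutoff) {
        bits["ELEC_PROT_NEG"] <- TRUE
      }
    }
  }

  # water bridges by exhaustive path enumeration
  lp <- lat(unique(c(ligspec$hbond_donors, ligspec$hbond_acceptors)))
  lp_don <- lp %in% lat(ligspec$hbond_donors)
  lp_acc <- lp %in% lat(ligspec$hbond_acceptors)
  rp <- unique(c(r_don, r_acc))
  waters <- which(o_is_water(a$resname) & a$element == "O")
  hb_any <- function(i, j, i_don, i_acc, j_don, j_acc) {
    (i_don && j_acc && o_hbond(a, xyz, i, j, cfg)) ||
      (j_don && i_acc && o_hbond(a, xyz, j, i, cfg))
  }
  for (li in seq_along(lp)) {
    for (w in waters) {
      if (!hb_any(lp[li], w, lp_don[li], lp_acc[li], TRUE, TRUE)) next
      for (r in rp) {
        if (hb_any(w, r, TRUE, TRUE, r %in% r_don, r %in% r_acc)) {
          bits["WATER1"] <- TRUE
        }
      }
      for (w2 in waters) {
        if (w2 == w) next
        if (!hb_any(w, w2, TRUE, TRUE, TRUE, TRUE)) next
        for (r in rp) {
          if (hb_any(w2, r, TRUE, TRUE, r %in% r_don, r %in% r_acc)) {
            bits["WATER2"] <- TRUE
          }
        }
      }
    }
  }
  bits
}

# exhaustive bridge path list (order, ligand atom, waters..., residue atom)
oracle_bridge_paths <- function(st, lp, rp, waters,
                                cfg = fingerprint_config()) {
  a <- st$atoms
  xyz <- coords(st)
  paths <- list()
  hb <- function(i, j) {
    o_hbond(a, xyz, i, j, cfg) || o_hbond(a, xyz, j, i, cfg)
  }
  for (li in lp) {
    for (w in waters) {
      if (!hb(li, w)) next
      for (r in rp) {
        if (hb(w, r)) paths[[length(paths) + 1L]] <- c(1L, li, w, NA, r)
      }
      for (w2 in waters) {
        if (w2 == w || !hb(w, w2)) next
        for (r in rp) {
          if (hb(w2, r)) paths[[length(paths) + 1L]] <- c(2L, li, w, w2, r)
        }
      }
    }
  }
  if (!length(paths)) {
    return(NULL)
  }
  m <- unique(do.call(rbind, paths))
  m[order(m[, 1], m[, 2], m[, 3], m[, 5]), , drop = FALSE]
}

# dense-grid in-plane maximal-sphere search
oracle_pore_grid <- function(st, z, axis, anchor, extent = 4,
                             resolution = 0.05, vdw_table = NULL) {
  if (is.null(vdw_table)) {
    vdw_table <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                   X = 1.70)
  }
  axis <- axis / sqrt(sum(axis^2))
  e <- diag(3)[, which.min(abs(axis))]
  u <- e - sum(e * axis) * axis
  u <- u / sqrt(sum(u^2))
  v <- c(
    axis[2] * u[3] - axis[3] * u[2],
    axis[3] * u[1] - axis[1] * u[3],
    axis[1] * u[2] - axis[2] * u[1]
  )
  xyz <- coords(st)
  vdw <- vdw_table[st$atoms$element]
  vdw[is.na(vdw)] <- vdw_table[["X"]]
  g <- seq(-extent, extent, by = resolution)
  best <- -Inf
  o3 <- anchor + z * axis
  for (gu in g) {
    p0 <- o3 + gu * u
    for (gv in g) {
      p <- p0 + gv * v
      r <- min(sqrt((xyz[, 1] - p[1])^2 + (xyz[, 2] - p[2])^2 +
                      (xyz[, 3] - p[3])^2) - vdw)
      if (r > best) best <- r
    }
  }
  best
}
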
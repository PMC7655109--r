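# Nine-class structural interaction fingerprint (SIFt).
#
# Per residue and per frame, nine independent bits in fixed order:
#   1 APOLAR            ligand carbon -- residue carbon, <= apolar_cutoff
#   2 AROM_FTF          face-to-face aromatic stacking
#   3 AROM_ETF          edge-to-face aromatic stacking
#   4 HB_PROT_DONOR     hydrogen bond, protein donates
#   5 HB_PROT_ACCEPTOR  hydrogen bond, protein accepts
#   6 ELEC_PROT_POS     electrostatic, protein side positive
#   7 ELEC_PROT_NEG     electrostatic, protein side negative
#   8 WATER1            one-water-mediated hydrogen-bond bridge
#   9 WATER2            two-water-mediated hydrogen-bond bridge
#
# Distance gates: 4.5 A for apolar carbon pairs, 4.0 A for aromatic and
# electrostatic contacts (heavy atoms only, hydrogens never enter distance
# tests). All cutoffs are inclusive (<=).

#' Fingerprint bit names, in serialization order
#' @export
fingerprint_bits <- c(
  "APOLAR", "AROM_FTF", "AROM_ETF", "HB_PROT_DONOR", "HB_PROT_ACCEPTOR",
  "ELEC_PROT_POS", "ELEC_PROT_NEG", "WATER1", "WATER2"
)

#' Geometric thresholds of the fingerprint
#'
#' @param apolar_cutoff carbon-carbon apolar cutoff (angstrom, default 4.5).
#' @param aromatic_cutoff minimum inter-ring atom distance gate (4.0).
#' @param electrostatic_cutoff charged-group atom distance gate (4.0).
#' @param hbond_heavy_cutoff donor-acceptor heavy-atom cutoff (3.5).
#' @param hbond_angle_min donor-H-acceptor angle minimum in degrees (120),
#'   applied only when a polar hydrogen is present in the topology.
#' @param ftf_normal_angle_max inter-normal angle (folded to 0-90 degrees)
#'   below which an aromatic contact counts as face-to-face (45).
#' @param water_bridge_max_order maximal bridge order (2).
#' @return object of class `fingerprint_config`.
#' @export
fingerprint_config <- function(apolar_cutoff = 4.5, aromatic_cutoff = 4.0,
                               electrostatic_cutoff = 4.0,
                               hbond_heavy_cutoff = 3.5,
                               hbond_angle_min = 120,
                               ftf_normal_angle_max = 45,
                               water_bridge_max_order = 2L) {
  cuts <- c(
    apolar_cutoff, aromatic_cutoff, electrostatic_cutoff, hbond_heavy_cutoff
  )
  if (any(cuts <= 0)) stop("all cutoffs must be positive")
  if (ftf_normal_angle_max <= 0 || ftf_normal_angle_max >= 90) {
    stop("ftf_normal_angle_max must lie in (0, 90)")
  }
  structure(
    list(
      apolar_cutoff = apolar_cutoff, aromatic_cutoff = aromatic_cutoff,
      electrostatic_cutoff = electrostatic_cutoff,
      hbond_heavy_cutoff = hbond_heavy_cutoff,
      hbond_angle_min = hbond_angle_min,
      ftf_normal_angle_max = ftf_normal_angle_max,
      water_bridge_max_order = as.integer(water_bridge_max_order)
    ),
    class = "fingerprint_config"
  )
}

# ---- protein chemistry tables -------------------------------------------

.protein_rings <- list(
  PHE = list(c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")),
  TYR = list(c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")),
  HIS = list(c("CG", "ND1", "CE1", "NE2", "CD2")),
  # Trp contributes both rings of the indole, evaluated independently.
  TRP = list(
    c("CG", "CD1", "NE1", "CE2", "CD2"),
    c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3")
  )
)
.his_aliases <- c("HIS", "HSD", "HSE", "HSP", "HID", "HIE", "HIP")

.sidechain_donors <- list(
  ARG = c("NE", "NH1", "NH2"), LYS = c("NZ"), HIS = c("ND1", "NE2"),
  TRP = c("NE1"), ASN = c("ND2"), GLN = c("NE2"), SER = c("OG"),
  THR = c("OG1"), TYR = c("OH"), CYS = c("SG")
)
.sidechain_acceptors <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = c("OD1"),
  GLN = c("OE1"), SER = c("OG"), THR = c("OG1"), TYR = c("OH"),
  HIS = c("ND1", "NE2"), MET = c("SD")
)
# Charged groups at force-field pH 7: His positive only when explicitly
# protonated (HIP/HSP); chain termini excluded.
.positive_groups <- list(
  ARG = c("NE", "NH1", "NH2"), LYS = c("NZ"),
  HIP = c("ND1", "NE2"), HSP = c("ND1", "NE2")
)
.negative_groups <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2")
)

.canon_resname <- function(rn) {
  rn <- toupper(rn)
  ifelse(rn %in% .his_aliases & !rn %in% c("HIP", "HSP"), "HIS", rn)
}

# ---- elementary criteria ------------------------------------------------

#' Hydrogen-bond test
#'
#' True iff the donor-acceptor heavy-atom distance is within
#' `hbond_heavy_cutoff` and, when at least one hydrogen is attached to the
#' donor, the best donor-H-acceptor angle reaches `hbond_angle_min`. With no
#' hydrogen available (heavy-atom-only structures) the distance criterion
#' alone decides.
#'
#' @param donor_heavy,acceptor_heavy 3-vectors.
#' @param attached_h optional matrix of hydrogen coordinates on the donor.
#' @param config a [fingerprint_config()].
#' @return logical flag.
#' @export
hydrogen_bond <- function(donor_heavy, acceptor_heavy, attached_h = NULL,
                          config = fingerprint_config()) {
  d <- .vnorm(acceptor_heavy - donor_heavy)
  if (d > config$hbond_heavy_cutoff) {
    return(FALSE)
  }
  if (is.null(attached_h) || !NROW(attached_h)) {
    return(TRUE)
  }
  attached_h <- matrix(attached_h, ncol = 3L)
  angles <- apply(attached_h, 1L, function(h) {
    v1 <- donor_heavy - h
    v2 <- acceptor_heavy - h
    cosang <- sum(v1 * v2) / (.vnorm(v1) * .vnorm(v2))
    acos(max(-1, min(1, cosang))) * 180 / pi
  })
  max(angles) >= config$hbond_angle_min
}

#' Classify an aromatic ring-ring contact
#'
#' A contact exists iff the minimum inter-ring heavy-atom distance is within
#' `aromatic_cutoff`; it is face-to-face when the inter-normal angle (folded
#' to 0-90 degrees) is at most `ftf_normal_angle_max`, else edge-to-face.
#'
#' @param ring1,ring2 results of [ring_geometry()], each additionally
#'   carrying `$coords` (member coordinates) or passed via `coords1/coords2`.
#' @param coords1,coords2 member coordinate matrices.
#' @param config a [fingerprint_config()].
#' @return one of `"none"`, `"face_to_face"`, `"edge_to_face"`.
#' @export
aromatic_contact <- function(ring1, ring2, coords1, coords2,
                             config = fingerprint_config()) {
  mind <- min_distance(coords1, coords2)$distance
  if (mind > config$aromatic_cutoff) {
    return("none")
  }
  cosang <- abs(sum(ring1$unit_normal * ring2$unit_normal))
  ang <- acos(max(-1, min(1, cosang))) * 180 / pi
  if (ang <= config$ftf_normal_angle_max) "face_to_face" else "edge_to_face"
}

# hydrogens attached to a donor heavy atom: same residue, element H,
# within 1.25 A.
.attached_h <- function(xyz, atoms, donor_idx, res_key) {
  same_res <- which(res_key == res_key[donor_idx] & atoms$element == "H")
  if (!length(same_res)) {
    return(NULL)
  }
  d <- .cross_dist(xyz[donor_idx, , drop = FALSE], xyz[same_res, , drop = FALSE])
  h <- same_res[d[1L, ] <= 1.25]
  if (!length(h)) NULL else xyz[h, , drop = FALSE]
}

# pairwise hydrogen-bond adjacency between polar atom sets A and B, where
# each atom may act per its role flags (donor/acceptor).
.hb_pair <- function(xyz, atoms, res_key, i, j, i_donor, i_accept,
                     j_donor, j_accept, config) {
  di <- .vnorm(xyz[i, ] - xyz[j, ])
  if (di > config$hbond_heavy_cutoff) {
    return(FALSE)
  }
  if (i_donor && j_accept &&
      hydrogen_bond(
        xyz[i, ], xyz[j, ],
        .attached_h(xyz, atoms, i, res_key), config
      )) {
    return(TRUE)
  }
  if (j_donor && i_accept &&
      hydrogen_bond(
        xyz[j, ], xyz[i, ],
        .attached_h(xyz, atoms, j, res_key), config
      )) {
    return(TRUE)
  }
  FALSE
}

#' Enumerate water-mediated hydrogen-bond bridges
#'
#' Order-1 bridges are ligand-polar -HB- water -HB- residue-polar chains;
#' order-2 bridges pass through two distinct waters. Each link is evaluated
#' with [hydrogen_bond()], waters acting as both donor and acceptor. Paths
#' never revisit a water and identical paths are deduplicated; chains longer
#' than `water_bridge_max_order` are never reported.
#'
#' @param structure a `Structure` (one frame).
#' @param ligand_polar atom indices of ligand donors/acceptors; may carry
#'   attributes `donor`/`acceptor` (logical vectors); defaults to both roles.
#' @param residue_polar atom indices of residue polar atoms (same attributes).
#' @param water_oxygens atom indices of water oxygens.
#' @param config a [fingerprint_config()].
#' @return data.frame with columns `order`, `ligand_atom`, `water1`,
#'   `water2` (NA for order 1), `residue_atom`.
#' @export
water_bridges <- function(structure, ligand_polar, residue_polar,
                          water_oxygens, config = fingerprint_config()) {
  atoms <- structure$atoms
  xyz <- coords(structure)
  res_key <- paste(atoms$chain, atoms$resno, atoms$icode, sep = "\r")
  empty <- data.frame(
    order = integer(0), ligand_atom = integer(0), water1 = integer(0),
    water2 = integer(0), residue_atom = integer(0)
  )
  if (!length(ligand_polar) || !length(residue_polar) ||
      !length(water_oxygens)) {
    return(empty)
  }
  role <- function(idx, which) {
    a <- attr(idx, which)
    if (is.null(a)) rep(TRUE, length(idx)) else a
  }
  l_don <- role(ligand_polar, "donor")
  l_acc <- role(ligand_polar, "acceptor")
  r_don <- role(residue_polar, "donor")
  r_acc <- role(residue_polar, "acceptor")

  hb_lw <- matrix(FALSE, length(ligand_polar), length(water_oxygens))
  for (i in seq_along(ligand_polar)) {
    for (w in seq_along(water_oxygens)) {
      hb_lw[i, w] <- .hb_pair(
        xyz, atoms, res_key, ligand_polar[i], water_oxygens[w],
        l_don[i], l_acc[i], TRUE, TRUE, config
      )
    }
  }
  hb_wr <- matrix(FALSE, length(water_oxygens), length(residue_polar))
  for (w in seq_along(water_oxygens)) {
    for (j in seq_along(residue_polar)) {
      hb_wr[w, j] <- .hb_pair(
        xyz, atoms, res_key, water_oxygens[w], residue_polar[j],
        TRUE, TRUE, r_don[j], r_acc[j], config
      )
    }
  }
  out <- list()
  k <- 0L
  for (i in seq_along(ligand_polar)) {
    for (w in which(hb_lw[i, ])) {
      for (j in which(hb_wr[w, ])) {
        k <- k + 1L
        out[[k]] <- c(1L, ligand_polar[i], water_oxygens[w], NA_integer_,
                      residue_polar[j])
      }
    }
  }
  if (config$water_bridge_max_order >= 2L && length(water_oxygens) >= 2L) {
    hb_ww <- matrix(FALSE, length(water_oxygens), length(water_oxygens))
    for (w1 in seq_along(water_oxygens)) {
      for (w2 in seq_along(water_oxygens)) {
        if (w1 < w2) {
          hb_ww[w1, w2] <- hb_ww[w2, w1] <- .hb_pair(
            xyz, atoms, res_key, water_oxygens[w1], water_oxygens[w2],
            TRUE, TRUE, TRUE, TRUE, config
          )
        }
      }
    }
    for (i in seq_along(ligand_polar)) {
      for (w1 in which(hb_lw[i, ])) {
        for (w2 in which(hb_ww[w1, ])) {
          for (j in which(hb_wr[w2, ])) {
            k <- k + 1L
            out[[k]] <- c(2L, ligand_polar[i], water_oxygens[w1],
                          water_oxygens[w2], residue_polar[j])
          }
        }
      }
    }
  }
  if (!k) {
    return(empty)
  }
  df <- as.data.frame(do.call(rbind, out))
  names(df) <- c("order", "ligand_atom", "water1", "water2", "residue_atom")
  unique(df[order(df$order, df$ligand_atom, df$water1, df$residue_atom), ,
            drop = FALSE])
}

# ---- per-residue classification -----------------------------------------

# Precompute the per-structure context shared across residues and frames.
.fp_context <- function(structure, spec, config, chain = NULL) {
  atoms <- structure$atoms
  lig <- .resolve_ligand(structure, spec, chain = chain)
  res_key <- paste(atoms$chain, atoms$resno, atoms$icode, sep = "\r")
  is_lig <- seq_len(nrow(atoms)) %in% lig$atoms
  water_o <- which(.is_water(atoms$resname) & atoms$element == "O")
  list(
    atoms = atoms, lig = lig, res_key = res_key, is_lig = is_lig,
    water_o = water_o, config = config
  )
}

# Polar atoms of one protein residue (indices + donor/acceptor roles).
.residue_polar <- function(atoms, idx) {
  rn <- .canon_resname(atoms$resname[idx][1L])
  nm <- atoms$name[idx]
  donors <- nm %in% c(
    if (rn != "PRO") "N",
    .sidechain_donors[[rn]] %||%
      if (rn %in% c("HIP", "HSP")) c("ND1", "NE2") else NULL
  )
  acceptors <- nm %in% c(
    "O", "OXT",
    .sidechain_acceptors[[rn]] %||%
      if (rn %in% c("HIP", "HSP")) c("ND1", "NE2") else NULL
  )
  polar <- donors | acceptors
  out <- idx[polar]
  attr(out, "donor") <- donors[polar]
  attr(out, "acceptor") <- acceptors[polar]
  out
}

.classify_one <- function(structure, ctx, res_idx) {
  atoms <- ctx$atoms
  xyz <- coords(structure)
  cfg <- ctx$config
  lig <- ctx$lig
  bits <- stats::setNames(rep(FALSE, 9L), fingerprint_bits)
  rn <- .canon_resname(atoms$resname[res_idx][1L])
  res_heavy <- res_idx[atoms$element[res_idx] != "H"]

  # APOLAR: any ligand nonpolar carbon within cutoff of any residue carbon
  res_c <- res_idx[atoms$element[res_idx] == "C"]
  if (length(res_c) && length(lig$nonpolar)) {
    d <- .cross_dist(
      xyz[lig$nonpolar, , drop = FALSE],
      xyz[res_c, , drop = FALSE]
    )
    bits["APOLAR"] <- any(d <= cfg$apolar_cutoff)
  }

  # aromatic
  ring_defs <- .protein_rings[[if (rn %in% c("HIP", "HSP")) "HIS" else rn]]
  if (!is.null(ring_defs) && length(lig$rings)) {
    for (rdef in ring_defs) {
      ridx <- res_idx[match(rdef, atoms$name[res_idx])]
      if (anyNA(ridx)) next
      rg <- ring_geometry(xyz, ridx)
      for (lg_idx in lig$rings) {
        lg <- ring_geometry(xyz, lg_idx)
        cls <- aromatic_contact(
          lg, rg, xyz[lg_idx, , drop = FALSE], xyz[ridx, , drop = FALSE], cfg
        )
        if (cls == "face_to_face") bits["AROM_FTF"] <- TRUE
        if (cls == "edge_to_face") bits["AROM_ETF"] <- TRUE
      }
    }
  }

  # hydrogen bonds (sidechain and backbone heavy atoms both considered)
  rp <- .residue_polar(atoms, res_idx)
  r_don <- rp[attr(rp, "donor")]
  r_acc <- rp[attr(rp, "acceptor")]
  for (d in r_don) {
    for (a in lig$acceptors) {
      if (hydrogen_bond(
        xyz[d, ], xyz[a, ],
        .attached_h(xyz, atoms, d, ctx$res_key), cfg
      )) {
        bits["HB_PROT_DONOR"] <- TRUE
        break
      }
    }
    if (bits["HB_PROT_DONOR"]) break
  }
  for (a in r_acc) {
    for (d in lig$donors) {
      if (hydrogen_bond(
        xyz[d, ], xyz[a, ],
        .attached_h(xyz, atoms, d, ctx$res_key), cfg
      )) {
        bits["HB_PROT_ACCEPTOR"] <- TRUE
        break
      }
    }
    if (bits["HB_PROT_ACCEPTOR"]) break
  }

  # electrostatics: any atom of a charged protein group within cutoff of
  # any atom of an oppositely signed ligand group
  rn_raw <- toupper(atoms$resname[res_idx][1L])
  pos_names <- .positive_groups[[rn_raw]] %||% .positive_groups[[rn]]
  neg_names <- .negative_groups[[rn_raw]] %||% .negative_groups[[rn]]
  elec_hit <- function(group_names, lig_groups) {
    gidx <- res_idx[atoms$name[res_idx] %in% group_names]
    if (!length(gidx)) {
      return(FALSE)
    }
    for (lg in lig_groups) {
      if (length(lg) &&
          min_distance(
            xyz[gidx, , drop = FALSE],
            xyz[lg, , drop = FALSE]
          )$distance <= cfg$electrostatic_cutoff) {
        return(TRUE)
      }
    }
    FALSE
  }
  if (!is.null(pos_names)) {
    bits["ELEC_PROT_POS"] <- elec_hit(pos_names, lig$negative)
  }
  if (!is.null(neg_names)) {
    bits["ELEC_PROT_NEG"] <- elec_hit(neg_names, lig$positive)
  }

  # water bridges
  lig_polar <- union(lig$donors, lig$acceptors)
  if (length(lig_polar)) {
    attr(lig_polar, "donor") <- lig_polar %in% lig$donors
    attr(lig_polar, "acceptor") <- lig_polar %in% lig$acceptors
  }
  if (length(lig_polar) && length(rp) && length(ctx$water_o)) {
    # only waters anywhere near both endpoints can participate
    reach <- cfg$hbond_heavy_cutoff * cfg$water_bridge_max_order +
      cfg$hbond_heavy_cutoff
    dl <- .cross_dist(
      xyz[ctx$water_o, , drop = FALSE],
      xyz[lig_polar, , drop = FALSE]
    )
    dr <- .cross_dist(
      xyz[ctx$water_o, , drop = FALSE],
      xyz[rp, , drop = FALSE]
    )
    near <- ctx$water_o[
      apply(dl, 1L, min) <= reach & apply(dr, 1L, min) <= reach
    ]
    if (length(near)) {
      br <- water_bridges(structure, lig_polar, rp, near, cfg)
      bits["WATER1"] <- any(br$order == 1L)
      bits["WATER2"] <- any(br$order == 2L)
    }
  }
  bits
}

#' Classify the interactions of one residue in one frame
#'
#' @param structure a single-frame `Structure` (use [frame_structure()] for
#'   trajectory frames).
#' @param ligand a [ligand_spec()].
#' @param chain,resno identify the residue.
#' @param icode insertion code, default empty.
#' @param config a [fingerprint_config()].
#' @param subunit_chain chain holding the ligand copy; defaults to the
#'   spec's chain or the only copy present.
#' @return named logical vector over [fingerprint_bits].
#' @export
classify_residue_frame <- function(structure, ligand, chain, resno,
                                   icode = "", config = fingerprint_config(),
                                   subunit_chain = NULL) {
  ctx <- .fp_context(structure, ligand, config, chain = subunit_chain)
  atoms <- structure$atoms
  res_idx <- which(
    atoms$chain == chain & atoms$resno == resno & atoms$icode == icode &
      !ctx$is_lig & !.is_water(atoms$resname)
  )
  if (!length(res_idx)) {
    stop("residue ", .res_label(chain, resno, icode), " not found")
  }
  .classify_one(structure, ctx, res_idx)
}

#' Serialize a bitset to its 9-character 0/1 string
#' @param bits named logical vector over [fingerprint_bits].
#' @return character scalar like `"100000000"`.
#' @export
as_bitstring <- function(bits) {
  paste(as.integer(bits[fingerprint_bits]), collapse = "")
}

# ---- trajectory sweep ---------------------------------------------------

# frames whose time is an integer multiple of stride_ps
.stride_frames <- function(times, stride_ps) {
  if (is.null(stride_ps)) {
    return(seq_along(times))
  }
  which(abs(times / stride_ps - round(times / stride_ps)) < 1e-9)
}

#' Fingerprint a whole trajectory
#'
#' One bitset per (residue, subunit, sampled frame). Subunits are the chains
#' carrying a ligand copy; the residue list defaults, per subunit, to every
#' protein residue with a heavy atom within the largest cutoff plus 2
#' angstrom of any ligand atom in any sampled frame.
#'
#' @param traj a `Trajectory`.
#' @param ligand a [ligand_spec()].
#' @param config a [fingerprint_config()].
#' @param stride_ps sample frames whose time is a multiple of this stride
#'   (ps); `NULL` keeps every frame.
#' @param residues optional data.frame (`chain`, `resno`) fixing the residue
#'   list for every subunit.
#' @param subunits optional chain ids of the ligand copies to analyze.
#' @return object of class `fingerprint_matrix`: a logical array
#'   `[residue, bit, frame, subunit]` plus `$residues`, `$times`,
#'   `$subunits`.
#' @export
fingerprint_trajectory <- function(traj, ligand,
                                   config = fingerprint_config(),
                                   stride_ps = NULL, residues = NULL,
                                   subunits = NULL) {
  stopifnot(inherits(traj, "Trajectory"))
  topo <- traj$topology
  atoms <- topo$atoms
  if (is.null(subunits)) subunits <- .ligand_chains(topo, ligand)
  if (!length(subunits)) stop("no ligand copy found in any chain")
  fidx <- .stride_frames(traj$times, stride_ps)
  if (!length(fidx)) stop("stride leaves no frames")
  times <- traj$times[fidx]

  reach <- max(
    config$apolar_cutoff, config$aromatic_cutoff,
    config$electrostatic_cutoff, config$hbond_heavy_cutoff
  ) + 2

  lig_per_sub <- lapply(subunits, function(ch) {
    .resolve_ligand(topo, ligand, chain = ch)
  })
  names(lig_per_sub) <- subunits

  res_key <- paste(atoms$chain, atoms$resno, atoms$icode, sep = "\r")
  protein_mask <- !.is_water(atoms$resname) &
    !(toupper(atoms$resname) == toupper(ligand$resname))
  heavy <- atoms$element != "H"

  residue_sets <- lapply(subunits, function(ch) {
    lig_idx <- lig_per_sub[[ch]]$atoms
    if (!is.null(residues)) {
      keys <- unique(paste(residues$chain, residues$resno, "", sep = "\r"))
    } else {
      hits <- rep(FALSE, nrow(atoms))
      cand <- which(protein_mask & heavy)
      for (f in fidx) {
        xyz <- traj$frames[[f]]
        d <- .cross_dist(
          xyz[cand, , drop = FALSE],
          xyz[lig_idx, , drop = FALSE]
        )
        hits[cand] <- hits[cand] | apply(d, 1L, min) <= reach
      }
      keys <- unique(res_key[hits])
    }
    keys
  })
  names(residue_sets) <- subunits

  all_keys <- unique(unlist(residue_sets))
  if (!length(all_keys)) stop("no residues within reach of the ligand")
  key_parts <- do.call(rbind, strsplit(all_keys, "\r"))
  key_tab <- data.frame(
    key = all_keys,
    chain = key_parts[, 1],
    resno = as.integer(key_parts[, 2]),
    icode = if (ncol(key_parts) >= 3L) key_parts[, 3] else "",
    stringsAsFactors = FALSE
  )
  key_tab$resname <- atoms$resname[match(all_keys, res_key)]
  # residues are pooled by label across subunits: TRP156 of chain A in the
  # A-pocket and TRP156 of chain B in the B-pocket are one row, as the
  # per-residue probabilities average over all binding sites
  key_tab$label <- paste0(key_tab$resname, key_tab$resno)
  key_tab <- key_tab[order(key_tab$label, key_tab$chain), , drop = FALSE]
  res_tab <- key_tab[!duplicated(key_tab$label), c("chain", "resno", "icode",
                                                   "resname", "label")]
  res_tab <- res_tab[order(res_tab$resno, res_tab$label), , drop = FALSE]
  rownames(res_tab) <- NULL

  # per subunit, resolve each label to its residue instance in that
  # pocket; with several instances (one per subunit chain) the one nearest
  # the subunit's ligand copy wins
  xyz1 <- traj$frames[[fidx[1L]]]
  key_for <- vapply(seq_along(subunits), function(s) {
    ch <- subunits[s]
    lig_xyz <- xyz1[lig_per_sub[[ch]]$atoms, , drop = FALSE]
    vapply(res_tab$label, function(lb) {
      cand <- key_tab$key[key_tab$label == lb]
      inset <- cand[cand %in% residue_sets[[ch]]]
      if (!length(inset)) inset <- cand
      if (!length(inset)) {
        return("")
      }
      if (length(inset) == 1L) {
        return(inset)
      }
      d <- vapply(inset, function(k) {
        idx <- which(res_key == k)
        min(.cross_dist(xyz1[idx, , drop = FALSE], lig_xyz))
      }, numeric(1))
      inset[which.min(d)]
    }, character(1))
  }, character(nrow(res_tab)))
  key_for <- matrix(key_for, nrow = nrow(res_tab))

  bits <- array(
    FALSE,
    dim = c(nrow(res_tab), 9L, length(fidx), length(subunits)),
    dimnames = list(res_tab$label, fingerprint_bits, NULL, subunits)
  )
  for (s in seq_along(subunits)) {
    ch <- subunits[s]
    for (fi in seq_along(fidx)) {
      fs <- frame_structure(traj, fidx[fi])
      ctx <- .fp_context(fs, ligand, config, chain = ch)
      for (r in seq_len(nrow(res_tab))) {
        k <- key_for[r, s]
        if (!nzchar(k)) next
        if (is.null(residues) && !k %in% residue_sets[[ch]]) next
        res_idx <- which(res_key == k & !ctx$is_lig)
        if (!length(res_idx)) next
        bits[r, , fi, s] <- .classify_one(fs, ctx, res_idx)
      }
    }
  }
  structure(
    list(
      bits = bits, residues = res_tab, times = times, subunits = subunits,
      config = config
    ),
    class = "fingerprint_matrix"
  )
}

#' @export
print.fingerprint_matrix <- function(x, ...) {
  cat(
    "<fingerprint_matrix>", nrow(x$residues), "residues x 9 bits x",
    length(x$times), "frames x", length(x$subunits), "subunit(s)\n"
  )
  invisible(x)
}

#' Export a fingerprint matrix as a tidy table
#'
#' @param fp a `fingerprint_matrix`.
#' @param path optional CSV path.
#' @return data.frame with residue, chain, subunit, time_ps, the nine 0/1
#'   bit columns, and the 9-character bitstring.
#' @export
fingerprint_table <- function(fp, path = NULL) {
  dims <- dim(fp$bits)
  rows <- expand.grid(
    residue = seq_len(dims[1L]), frame = seq_len(dims[3L]),
    subunit = seq_len(dims[4L]), KEEP.OUT.ATTRS = FALSE
  )
  bitcols <- t(vapply(
    seq_len(nrow(rows)),
    function(i) {
      as.integer(fp$bits[rows$residue[i], , rows$frame[i], rows$subunit[i]])
    },
    integer(9L)
  ))
  colnames(bitcols) <- fingerprint_bits
  out <- data.frame(
    residue = fp$residues$label[rows$residue],
    chain = fp$residues$chain[rows$residue],
    subunit = fp$subunits[rows$subunit],
    time_ps = fp$times[rows$frame],
    bitcols,
    bitstring = apply(bitcols, 1L, paste, collapse = ""),
    stringsAsFactors = FALSE
  )
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
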
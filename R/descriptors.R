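# Channel-specific per-frame descriptors: ligand-pose RMSD, binding-loop
# (Loop C) RMSD and orientation dihedral, Arg65-Asp202 gate distance,
# pocket hydration, and per-residue displacement maps.
#
# All RMSD-type descriptors first superpose each frame onto the reference
# using the role map's alignment selection (extracellular-domain CA atoms
# in receptor work), then measure without re-fitting.

#' Residue roles used by the descriptor suite
#'
#' Defaults follow the 5-HT3A receptor conventions: Loop C RMSD over
#' residues 200-205 (Ser200-Asn205), the loop-orientation dihedral over the
#' CA atoms of residues 208, 199, 198, 203 (Ala208, Phe199, Glu198, Ile203),
#' and the gate salt bridge Arg65 (NE/NH1/NH2) - Asp202 (OD1/OD2).
#'
#' @param loopC_rmsd_range `c(start, end)` residue numbers (default 200-205).
#' @param loopC_dihedral_residues four residue numbers, dihedral order.
#' @param gate_pair list with `res1`/`res2`, each
#'   `list(resno =, atoms = c(...))`.
#' @param alignment_selection a [selection_spec()] picking the alignment
#'   atoms (no universal default exists; the residue set is a configuration
#'   input).
#' @param pore_marker_residues named integer vector labelling pore-lining
#'   positions (e.g. `c("9'" = 260)`).
#' @return object of class `residue_role_map`.
#' @export
residue_role_map <- function(loopC_rmsd_range = c(200L, 205L),
                             loopC_dihedral_residues = c(208L, 199L, 198L, 203L),
                             gate_pair = list(
                               res1 = list(resno = 65L, atoms = c("NE", "NH1", "NH2")),
                               res2 = list(resno = 202L, atoms = c("OD1", "OD2"))
                             ),
                             alignment_selection = NULL,
                             pore_marker_residues = c("9'" = 260L)) {
  if (length(loopC_dihedral_residues) != 4L) {
    stop("the loop dihedral needs exactly 4 residues")
  }
  structure(
    list(
      loopC_rmsd_range = as.integer(loopC_rmsd_range),
      loopC_dihedral_residues = as.integer(loopC_dihedral_residues),
      gate_pair = gate_pair,
      alignment_selection = alignment_selection,
      pore_marker_residues = pore_marker_residues
    ),
    class = "residue_role_map"
  )
}

#' Read a residue role map from JSON
#' @param path file path.
#' @return a `residue_role_map`.
#' @export
read_role_map <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sel <- NULL
  if (!is.null(x$alignment_selection)) {
    s <- x$alignment_selection
    rr <- s$residue_ranges
    if (!is.null(rr) && !is.list(rr)) {
      rr <- if (is.matrix(rr)) {
        lapply(seq_len(nrow(rr)), function(i) rr[i, ])
      } else {
        list(rr)
      }
    }
    sel <- selection_spec(
      chains = s$chains, residue_ranges = rr,
      residue_names = s$residue_names, atom_names = s$atom_names,
      element_classes = s$element_classes, hetero = s$hetero
    )
  }
  gp <- x$gate_pair %||% NULL
  residue_role_map(
    loopC_rmsd_range = x$loopC_rmsd_range %||% c(200L, 205L),
    loopC_dihedral_residues = x$loopC_dihedral_residues %||%
      c(208L, 199L, 198L, 203L),
    gate_pair = if (is.null(gp)) {
      list(
        res1 = list(resno = 65L, atoms = c("NE", "NH1", "NH2")),
        res2 = list(resno = 202L, atoms = c("OD1", "OD2"))
      )
    } else {
      gp
    },
    alignment_selection = sel,
    pore_marker_residues = x$pore_marker_residues %||% c("9'" = 260L)
  )
}

.alignment_indices <- function(structure, roles) {
  if (is.null(roles$alignment_selection)) {
    # fall back to every protein CA
    spec <- selection_spec(element_classes = "calpha")
  } else {
    spec <- roles$alignment_selection
  }
  idx <- select_atoms(structure, spec)
  if (length(idx) < 3L) stop("alignment selection resolves to < 3 atoms")
  idx
}

.descriptor_df <- function(name, subunit, times, values, units) {
  data.frame(
    descriptor = name, subunit = subunit, time_ps = times,
    value = values, units = units, stringsAsFactors = FALSE
  )
}

#' Ligand-pose RMSD per subunit
#'
#' Per frame and ligand copy: superpose the frame onto the reference on the
#' alignment selection, then report the RMSD of the ligand heavy atoms (or a
#' named substructure, e.g. a bicyclic ring) without re-fitting. The
#' attribute `grand_mean` averages over all subunits and frames (the five
#' subunits treated as replicates).
#'
#' @param traj a `Trajectory`.
#' @param reference a `Structure` with matching atom order.
#' @param ligand a [ligand_spec()].
#' @param roles a [residue_role_map()].
#' @param substructure optional atom-name vector restricting the measured
#'   set.
#' @param stride_ps optional sampling stride (ps).
#' @return tidy data.frame (descriptor, subunit, time_ps, value, units) with
#'   attribute `grand_mean`.
#' @export
ligand_pose_rmsd <- function(traj, reference, ligand, roles,
                             substructure = NULL, stride_ps = NULL) {
  align_idx <- .alignment_indices(reference, roles)
  ref_xyz <- coords(reference)
  chains <- .ligand_chains(traj$topology, ligand)
  if (!length(chains)) stop("no ligand copy found")
  fidx <- .stride_frames(traj$times, stride_ps)
  out <- list()
  for (ch in chains) {
    lig <- .resolve_ligand(traj$topology, ligand, chain = ch)
    midx <- lig$heavy
    if (!is.null(substructure)) {
      atoms <- traj$topology$atoms
      midx <- lig$atoms[match(substructure, atoms$name[lig$atoms])]
      if (anyNA(midx)) {
        stop(
          "substructure atom(s) missing: ",
          paste(substructure[is.na(midx)], collapse = ", ")
        )
      }
    }
    vals <- vapply(fidx, function(f) {
      rmsd_after_alignment(traj$frames[[f]], ref_xyz, align_idx, midx)
    }, numeric(1))
    out[[ch]] <- .descriptor_df(
      if (is.null(substructure)) "ligand_rmsd" else "substructure_rmsd",
      ch, traj$times[fidx], vals, "angstrom"
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "grand_mean") <- mean(res$value)
  res
}

# backbone atoms (CA, carbonyl C, backbone N) of a residue range in a chain
.loop_backbone_idx <- function(atoms, chain, range) {
  idx <- which(
    atoms$chain == chain & atoms$resno >= range[1] & atoms$resno <= range[2] &
      atoms$name %in% c("CA", "C", "N") & !.is_water(atoms$resname)
  )
  resnos <- range[1]:range[2]
  for (rn in resnos) {
    here <- atoms$name[idx][atoms$resno[idx] == rn]
    miss <- setdiff(c("CA", "C", "N"), here)
    if (length(miss)) {
      stop(
        "residue ", chain, ":", rn, " lacks backbone atom(s): ",
        paste(miss, collapse = ", ")
      )
    }
  }
  idx
}

#' Binding-loop RMSD and orientation dihedral per subunit
#'
#' RMSD over exactly the CA + carbonyl C + backbone N atoms of the loop
#' range (18 atoms for a 6-residue loop) after alignment on the role map's
#' selection; the dihedral is drawn between the four role CA atoms. Large
#' dihedral values denote a loop oriented away from the binding site.
#'
#' @inheritParams ligand_pose_rmsd
#' @param chains protein chains to analyze; defaults to all chains
#'   containing the loop range.
#' @return tidy data.frame with descriptors `loopC_rmsd` (angstrom) and
#'   `loopC_dihedral` (degrees).
#' @export
loopc_descriptors <- function(traj, reference, roles, chains = NULL,
                              stride_ps = NULL) {
  atoms <- traj$topology$atoms
  rng <- roles$loopC_rmsd_range
  if (is.null(chains)) {
    chains <- sort(unique(atoms$chain[
      atoms$resno >= rng[1] & atoms$resno <= rng[2] & atoms$name == "CA" &
        !.is_water(atoms$resname)
    ]))
  }
  if (!length(chains)) stop("no chain contains the loop residue range")
  align_idx <- .alignment_indices(reference, roles)
  ref_xyz <- coords(reference)
  fidx <- .stride_frames(traj$times, stride_ps)
  out <- list()
  for (ch in chains) {
    loop_idx <- .loop_backbone_idx(atoms, ch, rng)
    dihe_idx <- vapply(roles$loopC_dihedral_residues, function(rn) {
      i <- which(atoms$chain == ch & atoms$resno == rn & atoms$name == "CA")
      if (!length(i)) stop("missing CA of residue ", ch, ":", rn)
      i[1L]
    }, integer(1))
    rmsd_vals <- vapply(fidx, function(f) {
      rmsd_after_alignment(traj$frames[[f]], ref_xyz, align_idx, loop_idx)
    }, numeric(1))
    dihe_vals <- vapply(fidx, function(f) {
      xyz <- traj$frames[[f]]
      dihedral_angle(
        xyz[dihe_idx[1], ], xyz[dihe_idx[2], ],
        xyz[dihe_idx[3], ], xyz[dihe_idx[4], ]
      )
    }, numeric(1))
    out[[ch]] <- rbind(
      .descriptor_df("loopC_rmsd", ch, traj$times[fidx], rmsd_vals, "angstrom"),
      .descriptor_df("loopC_dihedral", ch, traj$times[fidx], dihe_vals, "degrees")
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Gate salt-bridge distance
#'
#' Minimum distance over the listed polar side-chain atom pairs of the two
#' gate residues; the contact is "engaged" when the distance is at or below
#' the threshold (inclusive; 4 angstrom is the conventional generous
#' hydrogen-bond cutoff for this pair).
#'
#' @param structure a single-frame `Structure`.
#' @param roles a [residue_role_map()].
#' @param threshold engagement threshold in angstrom (default 4.0).
#' @param chains chains to analyze; defaults to all chains containing both
#'   gate residues.
#' @return data.frame with `subunit`, `distance`, `engaged`.
#' @export
gate_distance <- function(structure, roles, threshold = 4.0, chains = NULL) {
  atoms <- structure$atoms
  xyz <- coords(structure)
  gp <- roles$gate_pair
  find <- function(ch, res) {
    which(
      atoms$chain == ch & atoms$resno == res$resno & atoms$name %in% res$atoms
    )
  }
  if (is.null(chains)) {
    chains <- sort(unique(atoms$chain))
    chains <- chains[vapply(chains, function(ch) {
      length(find(ch, gp$res1)) > 0 && length(find(ch, gp$res2)) > 0
    }, logical(1))]
  }
  if (!length(chains)) stop("no chain holds both gate residues' listed atoms")
  out <- lapply(chains, function(ch) {
    i1 <- find(ch, gp$res1)
    i2 <- find(ch, gp$res2)
    if (!length(i1) || !length(i2)) {
      stop("gate residue atoms missing in chain ", ch)
    }
    d <- min_distance(xyz[i1, , drop = FALSE], xyz[i2, , drop = FALSE])$distance
    data.frame(
      subunit = ch, distance = d, engaged = d <= threshold,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Count pocket waters
#'
#' Number of distinct water oxygens within `cutoff` of any ligand atom,
#' per ligand copy. A water within reach of several ligand atoms counts
#' once.
#'
#' @param structure a single-frame `Structure`.
#' @param ligand a [ligand_spec()].
#' @param cutoff distance cutoff in angstrom (default 3.0, inclusive).
#' @return data.frame with `subunit`, `n_waters`.
#' @export
pocket_water_count <- function(structure, ligand, cutoff = 3.0) {
  atoms <- structure$atoms
  xyz <- coords(structure)
  water_o <- which(.is_water(atoms$resname) & atoms$element == "O")
  chains <- .ligand_chains(structure, ligand)
  if (!length(chains)) stop("no ligand copy found")
  out <- lapply(chains, function(ch) {
    lig <- .resolve_ligand(structure, ligand, chain = ch)
    n <- if (length(water_o)) {
      d <- .cross_dist(
        xyz[water_o, , drop = FALSE],
        xyz[lig$atoms, , drop = FALSE]
      )
      sum(apply(d, 1L, min) <= cutoff)
    } else {
      0L
    }
    data.frame(subunit = ch, n_waters = n, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Per-residue CA displacement between two structures
#'
#' After superposing `structB` onto `structA` on the role map's alignment
#' selection (matched atom-by-atom), reports the displacement of each
#' matched residue's CA. Residues present in only one structure are absent
#' from the result, never reported as zero. Optional smoothing interpolates
#' a natural cubic spline over sequential residue index within each chain.
#'
#' @param structA,structB `Structure` objects.
#' @param roles a [residue_role_map()].
#' @param smooth logical; also return the spline-interpolated curve.
#' @param n_interp points per chain for the smooth curve.
#' @return list with `displacements` (chain, resno, displacement) and
#'   `smooth` (NULL unless requested).
#' @export
residue_displacement_map <- function(structA, structB, roles, smooth = FALSE,
                                     n_interp = 200L) {
  a <- structA$atoms
  b <- structB$atoms
  key_a <- paste(a$chain, a$resno, a$icode, a$name, sep = "\r")
  key_b <- paste(b$chain, b$resno, b$icode, b$name, sep = "\r")

  spec <- roles$alignment_selection %||% selection_spec(element_classes = "calpha")
  ia <- select_atoms(structA, spec)
  match_b <- match(key_a[ia], key_b)
  ok <- !is.na(match_b)
  if (sum(ok) < 3L) stop("fewer than 3 common alignment atoms")
  sp <- kabsch_superpose(
    coords(structB)[match_b[ok], , drop = FALSE],
    coords(structA)[ia[ok], , drop = FALSE]
  )
  b_xyz <- apply_superposition(coords(structB), sp)

  ca_a <- which(a$name == "CA" & a$element == "C" & !.is_water(a$resname))
  ca_key_a <- paste(a$chain[ca_a], a$resno[ca_a], a$icode[ca_a], sep = "\r")
  ca_b <- which(b$name == "CA" & b$element == "C" & !.is_water(b$resname))
  ca_key_b <- paste(b$chain[ca_b], b$resno[ca_b], b$icode[ca_b], sep = "\r")
  m <- match(ca_key_a, ca_key_b)
  keep <- !is.na(m)
  ia_ca <- ca_a[keep]
  ib_ca <- ca_b[m[keep]]
  disp <- sqrt(rowSums((coords(structA)[ia_ca, , drop = FALSE] -
                          b_xyz[ib_ca, , drop = FALSE])^2))
  res <- data.frame(
    chain = a$chain[ia_ca], resno = a$resno[ia_ca], displacement = disp,
    stringsAsFactors = FALSE
  )
  res <- res[order(res$chain, res$resno), , drop = FALSE]
  rownames(res) <- NULL
  sm <- NULL
  if (smooth) {
    sm <- do.call(rbind, lapply(split(res, res$chain), function(df) {
      if (nrow(df) < 4L) {
        return(NULL)
      }
      # natural cubic spline over sequential residue index, per chain only
      s <- stats::spline(
        df$resno, df$displacement,
        n = n_interp, method = "natural"
      )
      data.frame(
        chain = df$chain[1L], resno = s$x, displacement = s$y,
        stringsAsFactors = FALSE
      )
    }))
    rownames(sm) <- NULL
  }
  list(displacements = res, smooth = sm)
}
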
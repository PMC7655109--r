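# Shared fixtures built in code.

fp_cfg <- fingerprint_config()

# quick atom-table row builder
atom_row <- function(name, element, resname, resno, chain, pos,
                     het = FALSE, icode = "", altloc = "", occ = 1, b = 0) {
  data.frame(
    serial = 0L, name = name, element = element, resname = resname,
    resno = resno, icode = icode, chain = chain, altloc = altloc,
    x = pos[1], y = pos[2], z = pos[3], occ = occ, b = b, het = het,
    stringsAsFactors = FALSE
  )
}

atoms_to_structure <- function(rows, id = "fixture") {
  df <- do.call(rbind, rows)
  df$serial <- seq_len(nrow(df))
  new_structure(df, identifier = id)
}

# Miniature single-chain receptor: an alignment helix (CA of residues
# 100-119), a Loop-C-like stretch 198-208 with N/CA/C backbone, the gate
# pair Arg65/Asp202 at a controlled separation, one ligand copy and a few
# waters at controlled distances.
make_receptor <- function(gate_dist = 3.5,
                          water_d = c(2.5, 2.7, 2.9, 3.6, 4.5)) {
  rows <- list()
  # alignment helix
  for (i in 0:19) {
    ang <- i * 100 * pi / 180
    rows[[length(rows) + 1L]] <- atom_row(
      "CA", "C", "GLY", 100L + i, "A",
      c(2.3 * cos(ang), 2.3 * sin(ang), 1.5 * i)
    )
  }
  # loop stretch 198-208 (second helix, offset in x)
  for (i in 0:10) {
    ang <- i * 100 * pi / 180
    base <- c(20 + 2.3 * cos(ang), 2.3 * sin(ang), 1.5 * i)
    resno <- 198L + i
    rows[[length(rows) + 1L]] <- atom_row("N", "N", "GLY", resno, "A",
                                          base + c(-0.9, -0.8, -0.5))
    rows[[length(rows) + 1L]] <- atom_row("CA", "C", "GLY", resno, "A", base)
    rows[[length(rows) + 1L]] <- atom_row("C", "C", "GLY", resno, "A",
                                          base + c(0.9, 0.8, 0.5))
  }
  # Asp202 sidechain carboxylate hanging off the loop
  ca202 <- c(20 + 2.3 * cos(4 * 100 * pi / 180),
             2.3 * sin(4 * 100 * pi / 180), 6)
  rows[[length(rows) + 1L]] <- atom_row("CB", "C", "GLY", 202L, "A",
                                        ca202 + c(0, -1.5, 0))
  od1 <- ca202 + c(0, -3.0, 0)
  rows[[length(rows) + 1L]] <- atom_row("OD1", "O", "GLY", 202L, "A", od1)
  rows[[length(rows) + 1L]] <- atom_row("OD2", "O", "GLY", 202L, "A",
                                        od1 + c(1.4, 0.6, 0))
  # Arg65: NH1 at gate_dist from OD1, other polar atoms farther
  nh1 <- od1 + c(0, -gate_dist, 0)
  rows[[length(rows) + 1L]] <- atom_row("CA", "C", "ARG", 65L, "A",
                                        nh1 + c(0, -4.5, 0))
  rows[[length(rows) + 1L]] <- atom_row("NH1", "N", "ARG", 65L, "A", nh1)
  rows[[length(rows) + 1L]] <- atom_row("NH2", "N", "ARG", 65L, "A",
                                        nh1 + c(1.8, -0.8, 0))
  rows[[length(rows) + 1L]] <- atom_row("NE", "N", "ARG", 65L, "A",
                                        nh1 + c(-1.8, -0.8, 0))
  # ligand: simple 6-atom blob, heavy atoms only
  lig0 <- c(40, 0, 0)
  lig_names <- c("L1", "L2", "L3", "L4", "L5")
  offs <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(0, 1.5, 0),
                c(0, 0, 1.5), c(-1.5, 0, 0))
  for (i in seq_along(lig_names)) {
    rows[[length(rows) + 1L]] <- atom_row(
      lig_names[i], "C", "MOL", 1L, "A", lig0 + offs[i, ], het = TRUE
    )
  }
  # waters at controlled distances from ligand atom L1
  for (i in seq_along(water_d)) {
    dirs <- rbind(c(0, 0, -1), c(0, -1, 0), c(-0.7, -0.7, 0),
                  c(0, -0.7, -0.7), c(-1, 0.3, 0.3))
    d <- dirs[i, ] / sqrt(sum(dirs[i, ]^2))
    rows[[length(rows) + 1L]] <- atom_row(
      "OW", "O", "HOH", 800L + i, "W", lig0 + water_d[i] * d, het = TRUE
    )
  }
  atoms_to_structure(rows, "mini_receptor")
}

receptor_ligand_spec <- function() {
  ligand_spec(
    resname = "MOL",
    ring_groups = list(), hbond_donors = character(0),
    hbond_acceptors = character(0), nonpolar_atoms = paste0("L", 1:5)
  )
}

receptor_roles <- function() {
  residue_role_map(
    loopC_rmsd_range = c(200L, 205L),
    loopC_dihedral_residues = c(208L, 199L, 198L, 203L),
    gate_pair = list(
      res1 = list(resno = 65L, atoms = c("NE", "NH1", "NH2")),
      res2 = list(resno = 202L, atoms = c("OD1", "OD2"))
    ),
    alignment_selection = selection_spec(
      atom_names = "CA", residue_ranges = list(c(100L, 119L))
    )
  )
}

# replicate a single-chain scene into n spatially separated pseudo-subunits
replicate_scene <- function(scene, n = 5L, spacing = 120) {
  a <- scene$structure$atoms
  stopifnot(all(a$chain %in% c("A", "W")))
  copies <- lapply(seq_len(n), function(k) {
    b <- a
    b$chain[b$chain == "A"] <- LETTERS[k]
    b$resno[b$resname == "HOH"] <- b$resno[b$resname == "HOH"] + k * 1000L
    b$x <- b$x + (k - 1L) * spacing
    b
  })
  df <- do.call(rbind, copies)
  df$serial <- seq_len(nrow(df))
  new_structure(df, identifier = "replicated_scene")
}

# constant-coordinate trajectory from a structure
still_trajectory <- function(st, n_frames, stride_ps = 500) {
  new_trajectory(
    st, rep(list(coords(st)), n_frames), stride_ps * seq_len(n_frames)
  )
}
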
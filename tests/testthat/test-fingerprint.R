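# classify_residue_frame and its elementary criteria.

simple_pair <- function(d, res_el = "C", lig_extra = NULL) {
  # ligand methyl carbon at origin, residue atom at distance d on x
  rows <- list(
    atom_row("C1", "C", "LIG", 900L, "A", c(0, 0, 0), het = TRUE),
    atom_row("CB", res_el, "ALA", 10L, "A", c(d, 0, 0))
  )
  atoms_to_structure(c(rows, lig_extra))
}

min_lig <- function(donors = character(0), acceptors = character(0)) {
  ligand_spec(
    resname = "LIG", nonpolar_atoms = "C1",
    hbond_donors = donors, hbond_acceptors = acceptors
  )
}

test_that("apolar cutoff is 4.5 angstrom, inclusive, carbons only", {
  cfg <- fingerprint_config()
  st <- simple_pair(4.49)
  expect_equal(
    as_bitstring(classify_residue_frame(st, min_lig(), "A", 10L, config = cfg)),
    "100000000"
  )
  st <- simple_pair(4.51)
  expect_equal(
    as_bitstring(classify_residue_frame(st, min_lig(), "A", 10L, config = cfg)),
    "000000000"
  )
  # a ligand nitrogen is not a nonpolar atom: no bit at 4.0
  st <- atoms_to_structure(list(
    atom_row("N1", "N", "LIG", 900L, "A", c(0, 0, 0), het = TRUE),
    atom_row("CB", "C", "ALA", 10L, "A", c(4.0, 0, 0))
  ))
  lig <- ligand_spec(resname = "LIG", hbond_donors = "N1")
  expect_equal(
    as_bitstring(classify_residue_frame(st, lig, "A", 10L)), "000000000"
  )
})

test_that("planted carboxylate-amine geometry sets the negative bit", {
  sc <- build_pocket_scene(
    pocket_scene_spec(list(list(type = "ELEC_PROT_NEG", distance = 3.8)),
                      seed = 2)
  )
  bits <- classify_residue_frame(
    sc$structure, sc$ligand, sc$truth$chain[1], sc$truth$resno[1]
  )
  expect_true(bits["ELEC_PROT_NEG"])
  expect_equal(sum(bits), 1L)
})

test_that("aromatic contacts split face-to-face vs edge-to-face at 45 deg", {
  cfg <- fingerprint_config()
  mkring <- function(center, normal, phase = 0) {
    fr <- channelsift:::.frame3(normal)
    pts <- t(vapply(0:5, function(k) {
      a <- k * pi / 3 + phase
      center + 1.39 * (cos(a) * fr$e1 + sin(a) * fr$e2)
    }, numeric(3)))
    list(geom = ring_geometry(pts), coords = pts)
  }
  r1 <- mkring(c(0, 0, 0), c(0, 0, 1))
  r2 <- mkring(c(0, 0, 3.6), c(sin(5 * pi / 180), 0, cos(5 * pi / 180)))
  expect_equal(
    aromatic_contact(r1$geom, r2$geom, r1$coords, r2$coords, cfg),
    "face_to_face"
  )
  # perpendicular ring whose lowest atom sits 3.9 above a ring-1 atom
  r3 <- mkring(r1$coords[1, ] + c(0, 0, 3.9 + 1.39), c(1, 0, 0),
               phase = pi / 2)
  expect_equal(min_distance(r1$coords, r3$coords)$distance, 3.9,
               tolerance = 1e-6)
  expect_equal(
    aromatic_contact(r1$geom, r3$geom, r1$coords, r3$coords, cfg),
    "edge_to_face"
  )
  # beyond the 4 angstrom gate: no contact regardless of geometry
  r4 <- mkring(c(0, 0, 4.2), c(0, 0, 1))
  expect_equal(
    aromatic_contact(r1$geom, r4$geom, r1$coords, r4$coords, cfg),
    "none"
  )
})

test_that("hydrogen bond needs 3.5 A heavy distance and 120 deg angle", {
  cfg <- fingerprint_config()
  don <- c(0, 0, 0)
  mk_h <- function(angle) channelsift:::.h_for_angle(don, c(2.8, 0, 0), angle)
  expect_true(hydrogen_bond(don, c(2.8, 0, 0), rbind(mk_h(165)), cfg))
  expect_false(hydrogen_bond(don, c(3.6, 0, 0), NULL, cfg))
  h95 <- channelsift:::.h_for_angle(don, c(3.0, 0, 0), 95)
  expect_false(hydrogen_bond(don, c(3.0, 0, 0), rbind(h95), cfg))
  # distance-only fallback without hydrogens
  expect_true(hydrogen_bond(don, c(3.0, 0, 0), NULL, cfg))
})

test_that("Trp contributes both indole rings independently", {
  # place the ligand ring stacked over the *benzene* half of an indole
  benz_center <- c(0, 0, 0)
  benz <- t(vapply(0:5, function(k) {
    a <- k * pi / 3
    benz_center + c(1.39 * cos(a), 1.39 * sin(a), 0)
  }, numeric(3)))
  # pyrrole half fused at the CD2-CE2 edge, far from the ligand ring
  pyr_off <- c(2.4, 0, 0)
  pyr <- rbind(
    benz[1, ], benz[2, ],
    benz_center + pyr_off + c(0.8, 1.1, 0),
    benz_center + pyr_off + c(1.4, 0, 0),
    benz_center + pyr_off + c(0.8, -1.1, 0)
  )
  rows <- list()
  nms <- c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3")
  for (i in 1:6) {
    rows[[length(rows) + 1L]] <- atom_row(nms[i], "C", "TRP", 10L, "A",
                                          benz[i, ])
  }
  rows[[length(rows) + 1L]] <- atom_row("CD1", "C", "TRP", 10L, "A", pyr[3, ])
  rows[[length(rows) + 1L]] <- atom_row("NE1", "N", "TRP", 10L, "A", pyr[4, ])
  rows[[length(rows) + 1L]] <- atom_row("CG", "C", "TRP", 10L, "A", pyr[5, ])
  # ligand ring parallel, 3.5 above the benzene half
  for (k in 0:5) {
    a <- k * pi / 3
    rows[[length(rows) + 1L]] <- atom_row(
      paste0("C", k + 1), "C", "LIG", 900L, "A",
      c(1.39 * cos(a), 1.39 * sin(a), 3.5), het = TRUE
    )
  }
  st <- atoms_to_structure(rows)
  lig <- ligand_spec(resname = "LIG", ring_groups = list(paste0("C", 1:6)),
                     nonpolar_atoms = paste0("C", 1:6))
  bits <- classify_residue_frame(st, lig, "A", 10L)
  expect_true(bits["AROM_FTF"])
})

test_that("water bridges follow the constructed chains", {
  cfg <- fingerprint_config()
  mk <- function(extra_waters = list()) {
    rows <- c(
      list(
        atom_row("O1", "O", "LIG", 900L, "A", c(0, 0, 0), het = TRUE),
        atom_row("OG", "O", "SER", 10L, "A", c(5.6, 0, 0)),
        atom_row("HG", "H", "SER", 10L, "A", c(6.56, 0, 0))
      ),
      extra_waters
    )
    atoms_to_structure(rows)
  }
  w <- function(x, n) atom_row("OW", "O", "HOH", n, "W", c(x, 0, 0),
                               het = TRUE)
  lig <- ligand_spec(resname = "LIG", hbond_acceptors = "O1")

  st1 <- mk(list(w(2.8, 801L)))
  b1 <- classify_residue_frame(st1, lig, "A", 10L)
  expect_true(b1["WATER1"])
  expect_false(b1["WATER2"])

  # two waters in file order: one order-2 bridge, no order-1
  st2 <- atoms_to_structure(list(
    atom_row("O1", "O", "LIG", 900L, "A", c(0, 0, 0), het = TRUE),
    atom_row("OG", "O", "SER", 10L, "A", c(8.4, 0, 0)),
    atom_row("HG", "H", "SER", 10L, "A", c(9.36, 0, 0)),
    w(2.8, 801L), w(5.6, 802L)
  ))
  b2 <- classify_residue_frame(st2, lig, "A", 10L)
  expect_false(b2["WATER1"])
  expect_true(b2["WATER2"])

  # chain through three waters: exceeds the maximum order, nothing reported
  st3 <- atoms_to_structure(list(
    atom_row("O1", "O", "LIG", 900L, "A", c(0, 0, 0), het = TRUE),
    atom_row("OG", "O", "SER", 10L, "A", c(11.2, 0, 0)),
    atom_row("HG", "H", "SER", 10L, "A", c(12.16, 0, 0)),
    w(2.8, 801L), w(5.6, 802L), w(8.4, 803L)
  ))
  b3 <- classify_residue_frame(st3, lig, "A", 10L)
  expect_false(any(b3[c("WATER1", "WATER2")]))
})

test_that("bridge enumeration equals the exhaustive oracle with decoys", {
  for (seed in c(4, 8, 15)) {
    sc <- build_pocket_scene(
      pocket_scene_spec(
        list(list(type = "WATER1"), list(type = "WATER2")),
        n_waters = 20L, box = 18, seed = seed
      )
    )
    st <- sc$structure
    a <- st$atoms
    waters <- which(a$resname == "HOH" & a$element == "O")
    lig_polar <- which(a$resname == "LIG" & a$element %in% c("N", "O"))
    attr(lig_polar, "donor") <- a$name[lig_polar] == "N1"
    attr(lig_polar, "acceptor") <- a$name[lig_polar] != "N1"
    for (k in 1:2) {
      ridx <- which(a$chain == sc$truth$chain[k] &
                      a$resno == sc$truth$resno[k] & a$resname != "HOH")
      rp <- channelsift:::.residue_polar(a, ridx)
      got <- water_bridges(st, lig_polar, rp, waters)
      want <- oracle_bridge_paths(st, lig_polar, as.integer(rp), waters)
      if (is.null(want)) {
        expect_equal(nrow(got), 0L)
      } else {
        expect_equal(nrow(got), nrow(want))
        expect_equal(got$order, unname(want[, 1]))
        expect_equal(got$water1, unname(want[, 3]))
      }
      expect_false(any(got$order > 2))
    }
  }
})

test_that("water-bridge detection ignores water list order", {
  sc <- build_pocket_scene(
    pocket_scene_spec(list(list(type = "WATER2")), n_waters = 6L, seed = 9)
  )
  st <- sc$structure
  a <- st$atoms
  waters <- which(a$resname == "HOH" & a$element == "O")
  lig_polar <- which(a$resname == "LIG" & a$element %in% c("N", "O"))
  ridx <- which(a$chain == sc$truth$chain[1] & a$resno == sc$truth$resno[1] &
                  a$resname != "HOH")
  rp <- channelsift:::.residue_polar(a, ridx)
  b1 <- water_bridges(st, lig_polar, rp, waters)
  b2 <- water_bridges(st, lig_polar, rp, rev(waters))
  expect_equal(b1, b2)
})

test_that("enlarging any cutoff never clears a distance-based bit", {
  base_cfg <- fingerprint_config()
  wide_cfg <- fingerprint_config(
    apolar_cutoff = 5.5, aromatic_cutoff = 5.0, electrostatic_cutoff = 5.0,
    hbond_heavy_cutoff = 4.2
  )
  for (seed in c(1, 2, 3)) {
    for (tp in c("APOLAR", "HB_PROT_DONOR", "ELEC_PROT_POS", "WATER1")) {
      sc <- build_pocket_scene(
        pocket_scene_spec(list(list(type = tp)), seed = seed)
      )
      b0 <- classify_residue_frame(
        sc$structure, sc$ligand, sc$truth$chain[1], sc$truth$resno[1],
        config = base_cfg
      )
      b1 <- classify_residue_frame(
        sc$structure, sc$ligand, sc$truth$chain[1], sc$truth$resno[1],
        config = wide_cfg
      )
      expect_true(all(b1[b0])) # every set bit stays set
    }
  }
})

test_that("annotations referencing missing atoms fail loudly", {
  st <- simple_pair(4.0)
  lig <- ligand_spec(resname = "LIG", nonpolar_atoms = c("C1", "C99"))
  expect_error(classify_residue_frame(st, lig, "A", 10L), "C99")
})

test_that("fingerprint_trajectory strides by time and tracks planted frames", {
  sc <- build_pocket_scene(
    pocket_scene_spec(list(list(type = "APOLAR")), seed = 6)
  )
  st <- sc$structure
  a <- st$atoms
  ridx <- which(a$chain == sc$truth$chain[1] & a$resno == sc$truth$resno[1])
  base <- coords(st)
  off <- base
  off[ridx, 1] <- off[ridx, 1] - 50
  # interaction present in frames 1-5 only, out of 10
  frames <- c(rep(list(base), 5), rep(list(off), 5))
  traj <- new_trajectory(st, frames, 500 * (1:10))
  fp <- fingerprint_trajectory(
    traj, sc$ligand,
    residues = data.frame(chain = sc$truth$chain[1],
                          resno = sc$truth$resno[1])
  )
  series <- as.integer(fp$bits[1, "APOLAR", , 1])
  expect_equal(series, c(rep(1L, 5), rep(0L, 5)))

  # stride keeps frames at multiples of the stride time
  fp2 <- fingerprint_trajectory(
    traj, sc$ligand, stride_ps = 1000,
    residues = data.frame(chain = sc$truth$chain[1],
                          resno = sc$truth$resno[1])
  )
  expect_equal(fp2$times, c(1000, 2000, 3000, 4000, 5000))

  expect_error(
    fingerprint_trajectory(traj, ligand_spec(resname = "XXX")),
    "not found|no ligand"
  )
})
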
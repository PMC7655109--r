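# Ground-truth-labelled synthetic fixtures.
#
# Scenes are miniature two-chain binding pockets built from ideal-geometry
# residue stubs around a rigid model ligand. Every planted interaction is
# realized at its stated distance/angle, decoys sit outside all cutoffs,
# and the expected bitset is derived from the planted parameters by the
# stated threshold rules (plus carbon-carbon and donor-H-acceptor geometry
# read directly off the emitted coordinates, since e.g. an aromatic stack
# necessarily implies apolar contact) - never by running the classifier.

# ---- the model ligand ---------------------------------------------------

# Rigid ligand "LIG": aromatic 6-ring, protonated amine N1 (+, donor,
# 3 explicit H), carbonyl acceptor O1, carboxylate (-, acceptors O2/O3),
# aliphatic carbon C7. All carbons are nonpolar atoms.
.ligand_atoms <- function(chain = "A", resno = 900L) {
  ring <- t(vapply(0:5, function(k) {
    a <- k * pi / 3
    c(1.39 * cos(a), 1.39 * sin(a), 0)
  }, numeric(3)))
  pos <- rbind(
    ring,
    c(-3.2, 0, 0),                     # C7
    c(3.2, 0, 0),                      # N1
    c(4.2, 0, 0),                      # HN1
    c(3.2, 0, 0) + c(-0.33, 0.94, 0),  # HN2
    c(3.2, 0, 0) + c(-0.33, -0.47, 0.82), # HN3
    c(0, 2.6, 0),                      # C8
    c(0, 3.83, 0),                     # O1
    c(0, -2.6, 0),                     # C9
    c(0.9, -3.4, 0),                   # O2
    c(-0.9, -3.4, 0)                   # O3
  )
  nm <- c(paste0("C", 1:6), "C7", "N1", "HN1", "HN2", "HN3",
          "C8", "O1", "C9", "O2", "O3")
  el <- c(rep("C", 7), "N", "H", "H", "H", "C", "O", "C", "O", "O")
  data.frame(
    serial = seq_along(nm), name = nm, element = el, resname = "LIG",
    resno = resno, icode = "", chain = chain, altloc = "",
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    occ = 1, b = 0, het = TRUE, stringsAsFactors = FALSE
  )
}

#' Chemistry annotations of the synthetic model ligand
#' @param chain chain carrying the ligand copy.
#' @return a [ligand_spec()].
#' @export
synthetic_ligand_spec <- function(chain = NULL) {
  ligand_spec(
    resname = "LIG", chain = chain,
    ring_groups = list(paste0("C", 1:6)),
    hbond_donors = "N1",
    hbond_acceptors = c("O1", "O2", "O3"),
    positive_groups = list("N1"),
    negative_groups = list(c("O2", "O3")),
    nonpolar_atoms = paste0("C", 1:9)
  )
}

# ---- residue stubs ------------------------------------------------------

# orthonormal frame completing a direction vector
.frame3 <- function(d, e1_hint = NULL) {
  d <- .unit(d)
  e <- if (is.null(e1_hint)) diag(3L)[, which.min(abs(d))] else e1_hint
  e1 <- .unit(e - sum(e * d) * d)
  e2 <- .cross3(d, e1)
  list(d = d, e1 = e1, e2 = e2)
}

# generic outward backbone behind a sidechain tip; every atom strictly
# farther from the ligand than the tip. CB leaves at an angle so it never
# clashes with a tip hydrogen placed along fr$d.
.backbone_behind <- function(tip, fr, offset = 1.45) {
  cb <- tip + offset * (0.70 * fr$d + 0.714 * fr$e1)
  ca <- cb + 1.52 * (0.80 * fr$d + 0.60 * fr$e1)
  n <- ca + 1.46 * (0.76 * fr$d - 0.65 * fr$e1)
  c_ <- ca + 1.52 * (0.60 * fr$d + 0.80 * fr$e2)
  o <- c_ + 1.23 * (0.55 * fr$d + 0.84 * fr$e2)
  list(CB = cb, CA = ca, N = n, C = c_, O = o)
}

.res_df <- function(names, elements, positions, resname, resno, chain) {
  pos <- do.call(rbind, positions)
  data.frame(
    serial = seq_along(names), name = names, element = elements,
    resname = resname, resno = resno, icode = "", chain = chain,
    altloc = "", x = pos[, 1], y = pos[, 2], z = pos[, 3],
    occ = 1, b = 0, het = FALSE, stringsAsFactors = FALSE
  )
}

.angle_at <- function(apex, a, b) {
  v1 <- a - apex
  v2 <- b - apex
  acos(max(-1, min(1, sum(v1 * v2) / (.vnorm(v1) * .vnorm(v2))))) * 180 / pi
}

# hydrogen position giving a prescribed donor-H-acceptor angle
.h_for_angle <- function(donor, acceptor, angle_deg, bond = 1.0) {
  if (angle_deg >= 179.99) {
    return(donor + bond * .unit(acceptor - donor))
  }
  fr <- .frame3(acceptor - donor)
  f <- function(g) {
    h <- donor + bond * (cos(g) * fr$d + sin(g) * fr$e1)
    .angle_at(h, donor, acceptor) - angle_deg
  }
  g <- stats::uniroot(f, c(1e-6, pi - 1e-6), tol = 1e-12)$root
  donor + bond * (cos(g) * fr$d + sin(g) * fr$e1)
}

# water stub: O at `o`, first H aimed at `at1`, second H at `at2` (or at
# the ideal 104.5 degree position when NULL)
.water_df <- function(o, at1, at2 = NULL, resno, chain = "W") {
  h1 <- o + 0.96 * .unit(at1 - o)
  if (is.null(at2)) {
    fr <- .frame3(at1 - o)
    a <- 104.5 * pi / 180
    h2 <- o + 0.96 * (cos(a) * fr$d + sin(a) * fr$e1)
  } else {
    h2 <- o + 0.96 * .unit(at2 - o)
  }
  .res_df(
    c("OW", "HW1", "HW2"), c("O", "H", "H"), list(o, h1, h2),
    "HOH", resno, chain
  )
}

# ---- scene specification ------------------------------------------------

#' Specify a synthetic pocket scene
#'
#' @param planted list of plant descriptions, each a list with `type` (one
#'   of [fingerprint_bits]) and optional geometric parameters: `distance`
#'   (key contact distance, angstrom), `angle` (donor-H-acceptor angle for
#'   hydrogen-bond plants, ring-normal angle for aromatic plants),
#'   `distances` (per-link distances for water bridges).
#' @param n_decoy_residues glycine decoys placed outside all cutoffs.
#' @param n_waters decoy waters placed outside hydrogen-bond range of every
#'   polar atom.
#' @param box half-width of the decoy placement box (angstrom).
#' @param seed mandatory integer seed.
#' @return object of class `pocket_scene_spec`.
#' @export
pocket_scene_spec <- function(planted, n_decoy_residues = 0L, n_waters = 0L,
                              box = 25, seed) {
  if (missing(seed)) stop("seed is mandatory")
  types <- vapply(planted, `[[`, character(1), "type")
  bad <- setdiff(types, fingerprint_bits)
  if (length(bad)) stop("unknown interaction type: ", paste(bad, collapse = ", "))
  if (anyDuplicated(types)) {
    stop("at most one plant per interaction type and scene")
  }
  structure(
    list(
      planted = planted, n_decoy_residues = as.integer(n_decoy_residues),
      n_waters = as.integer(n_waters), box = box, seed = as.integer(seed)
    ),
    class = "pocket_scene_spec"
  )
}

# default plant geometries; every default satisfies its rule
.plant_defaults <- list(
  APOLAR = list(distance = 4.2),
  AROM_FTF = list(distance = 3.6, angle = 5),
  AROM_ETF = list(distance = 3.9, angle = 90),
  HB_PROT_DONOR = list(distance = 2.8, angle = 165),
  HB_PROT_ACCEPTOR = list(distance = 2.9, angle = 170),
  ELEC_PROT_POS = list(distance = 3.8),
  ELEC_PROT_NEG = list(distance = 3.8),
  WATER1 = list(distances = c(2.8, 2.8)),
  WATER2 = list(distances = c(2.8, 2.8, 2.8))
)

# sector directions / ligand anchors keyed by type; sectors are separated
# so simultaneous plants cannot touch each other's cutoff shells
.plant_geometry <- list(
  APOLAR = list(anchor = "C7", dir = c(-1, 0, 0)),
  AROM_FTF = list(dir = c(0, 0, 1)),
  AROM_ETF = list(dir = c(0, 0, -1)),
  HB_PROT_DONOR = list(anchor = "O1", dir = c(0, 1, 0)),
  HB_PROT_ACCEPTOR = list(anchor = "N1", dir = c(1, 0, 0)),
  ELEC_PROT_POS = list(anchor = "O2", dir = c(0, -1, 0)),
  ELEC_PROT_NEG = list(anchor = "N1", dir = c(0, 0, 1)),
  WATER1 = list(anchor = "O2", dir = c(0.894, -0.447, 0)),
  WATER2 = list(anchor = "O3", dir = c(-0.894, -0.447, 0))
)

#' Build a synthetic pocket scene with exact expected bitsets
#'
#' Emits a miniature principal/complementary pocket: the rigid model
#' ligand, one ideal-geometry residue per planted interaction (alternating
#' between the two chains), optional glycine and water decoys, and the
#' exact bitset each residue must produce. Infeasible geometry (unintended
#' contacts between plants) raises an error before the scene is returned.
#'
#' @param spec a [pocket_scene_spec()].
#' @param config the [fingerprint_config()] whose thresholds define the
#'   expected bits.
#' @return list with `structure`, `ligand` (a [ligand_spec()]), `truth`
#'   (data.frame: label, chain, resno + the nine bits), and `plants`
#'   (per-plant metadata used by [build_pocket_trajectory()]).
#' @export
build_pocket_scene <- function(spec, config = fingerprint_config()) {
  stopifnot(inherits(spec, "pocket_scene_spec"))
  lig <- .ligand_atoms()
  lig_pos <- function(nm) as.numeric(lig[lig$name == nm, c("x", "y", "z")])
  pieces <- list(lig)
  plants <- list()
  truth <- list()
  resno <- 10L
  wat_no <- 500L
  chains <- c("A", "B")

  for (k in seq_along(spec$planted)) {
    p <- spec$planted[[k]]
    defs <- .plant_defaults[[p$type]]
    for (nm in names(defs)) if (is.null(p[[nm]])) p[[nm]] <- defs[[nm]]
    geo <- .plant_geometry[[p$type]]
    ch <- chains[(k - 1L) %% 2L + 1L]
    bits <- stats::setNames(rep(FALSE, 9L), fingerprint_bits)
    atoms_here <- NULL
    waters_here <- NULL
    dir <- geo$dir

    if (p$type == "APOLAR") {
      fr <- .frame3(dir)
      tip <- lig_pos("C7") + p$distance * fr$d
      bb <- .backbone_behind(tip, fr, offset = 0)
      atoms_here <- .res_df(
        c("CB", "CA", "N", "C", "O"), c("C", "C", "N", "C", "O"),
        c(list(tip), bb[c("CA", "N", "C", "O")]),
        "ALA", resno, ch
      )
      bits["APOLAR"] <- p$distance <= config$apolar_cutoff
    } else if (p$type %in% c("AROM_FTF", "AROM_ETF")) {
      theta <- p$angle * pi / 180
      normal <- cos(theta) * c(0, 0, sign(dir[3])) + sin(theta) * c(1, 0, 0)
      ring_local <- t(vapply(0:5, function(kk) {
        a <- kk * pi / 3
        c(1.39 * cos(a), 1.39 * sin(a), 0)
      }, numeric(3)))
      rf <- .frame3(normal)
      ring0 <- ring_local %*% rbind(rf$e1, rf$e2, rf$d)
      lig_ring <- as.matrix(lig[lig$name %in% paste0("C", 1:6),
                                c("x", "y", "z")])
      # push along dir until the realized minimum inter-ring atom distance
      # equals the requested one
      f <- function(h) {
        min(.cross_dist(sweep(ring0, 2L, h * dir, "+"), lig_ring)) -
          p$distance
      }
      h <- stats::uniroot(f, c(0.6, 30), tol = 1e-12)$root
      ring <- sweep(ring0, 2L, h * dir, "+")
      fr2 <- .frame3(dir)
      bb <- .backbone_behind(ring[1L, ] + 1.5 * dir, fr2, offset = 0)
      atoms_here <- .res_df(
        c("CG", "CD1", "CE1", "CZ", "CE2", "CD2", "CB", "CA", "N", "C", "O"),
        c(rep("C", 6), "C", "C", "N", "C", "O"),
        c(lapply(1:6, function(i) ring[i, ]),
          bb[c("CB", "CA", "N", "C", "O")]),
        "PHE", resno, ch
      )
      fold <- min(p$angle %% 180, 180 - p$angle %% 180)
      contact <- p$distance <= config$aromatic_cutoff
      bits["AROM_FTF"] <- contact && fold <= config$ftf_normal_angle_max
      bits["AROM_ETF"] <- contact && fold > config$ftf_normal_angle_max
    } else if (p$type == "HB_PROT_DONOR") {
      # serine donates: OG-HG aimed at the ligand carbonyl O1
      fr <- .frame3(dir)
      og <- lig_pos(geo$anchor) + p$distance * fr$d
      hg <- .h_for_angle(og, lig_pos(geo$anchor), p$angle)
      bb <- .backbone_behind(og, fr)
      atoms_here <- .res_df(
        c("OG", "HG", "CB", "CA", "N", "C", "O"),
        c("O", "H", "C", "C", "N", "C", "O"),
        c(list(og, hg), bb[c("CB", "CA", "N", "C", "O")]),
        "SER", resno, ch
      )
      bits["HB_PROT_DONOR"] <- p$distance <= config$hbond_heavy_cutoff &&
        p$angle >= config$hbond_angle_min
    } else if (p$type == "HB_PROT_ACCEPTOR") {
      # serine accepts from the ligand amine; the requested angle is set at
      # hydrogen HN1, and the truth accounts for all three amine hydrogens
      n1 <- lig_pos("N1")
      h1 <- lig_pos("HN1")
      fr <- .frame3(.unit(h1 - n1), e1_hint = c(0, -0.707, -0.707))
      f <- function(g) {
        og <- n1 + p$distance * (cos(g) * fr$d + sin(g) * fr$e1)
        .angle_at(h1, n1, og) - p$angle
      }
      g <- stats::uniroot(f, c(1e-6, pi - 1e-6), tol = 1e-12)$root
      og <- n1 + p$distance * (cos(g) * fr$d + sin(g) * fr$e1)
      fr2 <- .frame3(og - n1)
      hg <- og + 0.96 * fr2$d # points away from the ligand
      bb <- .backbone_behind(og, fr2)
      atoms_here <- .res_df(
        c("OG", "HG", "CB", "CA", "N", "C", "O"),
        c("O", "H", "C", "C", "N", "C", "O"),
        c(list(og, hg), bb[c("CB", "CA", "N", "C", "O")]),
        "SER", resno, ch
      )
      hs <- list(h1, lig_pos("HN2"), lig_pos("HN3"))
      best <- max(vapply(hs, function(h) .angle_at(h, n1, og), numeric(1)))
      bits["HB_PROT_ACCEPTOR"] <- p$distance <= config$hbond_heavy_cutoff &&
        best >= config$hbond_angle_min
    } else if (p$type == "ELEC_PROT_POS") {
      fr <- .frame3(dir)
      nh1 <- lig_pos(geo$anchor) + p$distance * fr$d
      cz <- nh1 + 1.33 * fr$d
      nh2 <- cz + 1.33 * (0.5 * fr$d + 0.866 * fr$e1)
      ne <- cz + 1.33 * (0.5 * fr$d - 0.866 * fr$e1)
      # guanidinium hydrogens point sideways, never toward the ligand
      atoms_here <- .res_df(
        c("NH1", "HH11", "HH12", "CZ", "NH2", "NE", "HE", "CD",
          "CB", "CA", "N", "C", "O"),
        c("N", "H", "H", "C", "N", "N", "H", "C", "C", "C", "N", "C", "O"),
        c(
          list(
            nh1, nh1 + fr$e2, nh1 - fr$e2, cz, nh2, ne, ne + fr$e2,
            ne + 1.46 * fr$d
          ),
          .backbone_behind(ne + 1.96 * fr$d, fr, offset = 1.0)[
            c("CB", "CA", "N", "C", "O")
          ]
        ),
        "ARG", resno, ch
      )
      bits["ELEC_PROT_POS"] <- p$distance <= config$electrostatic_cutoff
    } else if (p$type == "ELEC_PROT_NEG") {
      fr <- .frame3(dir)
      od1 <- lig_pos(geo$anchor) + p$distance * fr$d
      cg <- od1 + 1.25 * fr$d
      od2 <- cg + 1.25 * (0.4 * fr$d + 0.917 * fr$e1)
      bb <- .backbone_behind(cg + 0.3 * fr$d, fr, offset = 1.3)
      atoms_here <- .res_df(
        c("OD1", "CG", "OD2", "CB", "CA", "N", "C", "O"),
        c("O", "C", "O", "C", "C", "N", "C", "O"),
        c(list(od1, cg, od2), bb[c("CB", "CA", "N", "C", "O")]),
        "ASP", resno, ch
      )
      bits["ELEC_PROT_NEG"] <- p$distance <= config$electrostatic_cutoff
    } else if (p$type %in% c("WATER1", "WATER2")) {
      anchor <- lig_pos(geo$anchor)
      fr <- .frame3(dir)
      dists <- p$distances
      turn <- 104.5 * pi / 180
      nodes <- list(anchor)
      direction <- fr$d
      sign_lat <- 1
      for (li in seq_along(dists)) {
        nodes[[li + 1L]] <- nodes[[li]] + dists[li] * direction
        # zigzag with proper in-plane rotations: each node's bend is the
        # ideal water angle and alternating turns keep the chain extended
        w <- fr$e1 - sum(fr$e1 * direction) * direction
        w <- sign_lat * .unit(w)
        direction <- cos(pi - turn) * direction + sin(pi - turn) * w
        sign_lat <- -sign_lat
      }
      n_wat <- length(dists) - 1L
      waters_here <- do.call(rbind, lapply(seq_len(n_wat), function(wi) {
        .water_df(
          nodes[[wi + 1L]], at1 = nodes[[wi]], at2 = nodes[[wi + 2L]],
          resno = wat_no + wi
        )
      }))
      wat_no <- wat_no + n_wat
      tip <- nodes[[length(nodes)]]
      fr2 <- .frame3(tip - nodes[[length(nodes) - 1L]])
      bb <- .backbone_behind(tip, fr2)
      atoms_here <- .res_df(
        c("OG", "HG", "CB", "CA", "N", "C", "O"),
        c("O", "H", "C", "C", "N", "C", "O"),
        c(list(tip, tip + 0.96 * fr2$d), bb[c("CB", "CA", "N", "C", "O")]),
        "SER", resno, ch
      )
      all_ok <- all(dists <= config$hbond_heavy_cutoff)
      bits[if (p$type == "WATER1") "WATER1" else "WATER2"] <- all_ok
    }

    plants[[k]] <- list(
      type = p$type, label = paste0(atoms_here$resname[1L], resno),
      chain = ch, resno = resno, dir = dir,
      water_resnos = if (is.null(waters_here)) integer(0) else {
        unique(waters_here$resno)
      }
    )
    truth[[k]] <- bits
    pieces <- c(pieces, list(atoms_here),
                if (!is.null(waters_here)) list(waters_here))
    resno <- resno + 1L
  }

  # implied apolar contacts: any residue carbon within the apolar cutoff of
  # a ligand carbon sets APOLAR regardless of what was planted
  atoms <- do.call(rbind, pieces)
  lig_c <- as.matrix(atoms[atoms$resname == "LIG" & atoms$element == "C",
                           c("x", "y", "z")])
  for (k in seq_along(plants)) {
    ridx <- which(atoms$resno == plants[[k]]$resno &
                    atoms$chain == plants[[k]]$chain &
                    atoms$resname != "HOH")
    rc <- as.matrix(atoms[ridx[atoms$element[ridx] == "C"],
                          c("x", "y", "z"), drop = FALSE])
    if (nrow(rc) && min(.cross_dist(rc, lig_c)) <= config$apolar_cutoff) {
      truth[[k]]["APOLAR"] <- TRUE
    }
  }

  decoys <- .place_decoys(spec, atoms)
  atoms <- rbind(atoms, decoys$residues, decoys$waters)
  atoms$serial <- seq_len(nrow(atoms))

  st <- new_structure(atoms, identifier = sprintf("scene_seed%d", spec$seed))
  .validate_scene(st, plants, truth, config)

  truth_df <- do.call(rbind, lapply(seq_along(plants), function(k) {
    data.frame(
      label = plants[[k]]$label, chain = plants[[k]]$chain,
      resno = plants[[k]]$resno, t(truth[[k]]),
      stringsAsFactors = FALSE
    )
  }))
  if (!is.null(decoys$residues)) {
    for (rn in unique(decoys$residues$resno)) {
      truth_df <- rbind(truth_df, data.frame(
        label = paste0("GLY", rn), chain = "A", resno = rn,
        t(stats::setNames(rep(FALSE, 9L), fingerprint_bits)),
        stringsAsFactors = FALSE
      ))
    }
  }
  rownames(truth_df) <- NULL
  list(
    structure = st, ligand = synthetic_ligand_spec(),
    truth = truth_df, plants = plants
  )
}

# random far-field decoys: glycines >= 7 A from the ligand and >= 4 A from
# everything already placed; waters additionally >= 4.2 A from every polar
# atom so they can never join a hydrogen-bond network
.place_decoys <- function(spec, atoms) {
  env <- new.env()
  env$lig_xyz <- as.matrix(atoms[atoms$resname == "LIG", c("x", "y", "z")])
  env$polar <- as.matrix(atoms[atoms$element %in% c("N", "O", "S"),
                               c("x", "y", "z")])
  env$placed <- as.matrix(atoms[, c("x", "y", "z")])
  draw_point <- function(min_lig, min_all, min_polar = NULL) {
    for (try in 1:4000) {
      pnt <- stats::runif(3, -spec$box, spec$box)
      if (min(.cross_dist(rbind(pnt), env$lig_xyz)) < min_lig) next
      if (min(.cross_dist(rbind(pnt), env$placed)) < min_all) next
      if (!is.null(min_polar) && nrow(env$polar) &&
          min(.cross_dist(rbind(pnt), env$polar)) < min_polar) {
        next
      }
      return(pnt)
    }
    stop("could not place decoy; box too small")
  }
  with_seed(spec$seed, {
    res_out <- NULL
    wat_out <- NULL
    if (spec$n_decoy_residues > 0L) {
      res_list <- vector("list", spec$n_decoy_residues)
      for (i in seq_len(spec$n_decoy_residues)) {
        pnt <- draw_point(min_lig = 7, min_all = 4)
        fr <- .frame3(pnt - colMeans(env$lig_xyz))
        bb <- .backbone_behind(pnt, fr, offset = 0)
        df <- .res_df(
          c("CA", "N", "C", "O"), c("C", "N", "C", "O"),
          bb[c("CA", "N", "C", "O")], "GLY", 50L + i, "A"
        )
        res_list[[i]] <- df
        env$placed <- rbind(env$placed, as.matrix(df[, c("x", "y", "z")]))
        env$polar <- rbind(env$polar, as.matrix(
          df[df$element %in% c("N", "O"), c("x", "y", "z")]
        ))
      }
      res_out <- do.call(rbind, res_list)
    }
    if (spec$n_waters > 0L) {
      wat_list <- vector("list", spec$n_waters)
      for (i in seq_len(spec$n_waters)) {
        pnt <- draw_point(min_lig = 6, min_all = 4, min_polar = 4.2)
        df <- .water_df(pnt, at1 = pnt + c(1, 0, 0), resno = 700L + i)
        wat_list[[i]] <- df
        env$placed <- rbind(env$placed, as.matrix(df[, c("x", "y", "z")]))
        env$polar <- rbind(env$polar, rbind(pnt))
      }
      wat_out <- do.call(rbind, wat_list)
    }
    list(residues = res_out, waters = wat_out)
  })
}

# feasibility validation with raw distance arithmetic: no unintended short
# contact may contradict the declared truth
.validate_scene <- function(st, plants, truth, config) {
  a <- st$atoms
  xyz <- coords(st)
  lig_polar <- which(a$resname == "LIG" & a$element %in% c("N", "O"))
  hb_cut <- config$hbond_heavy_cutoff

  for (k in seq_along(plants)) {
    pl <- plants[[k]]
    ridx <- which(a$chain == pl$chain & a$resno == pl$resno &
                    a$resname != "HOH")
    rp <- ridx[a$element[ridx] %in% c("N", "O", "S")]
    if (length(rp)) {
      d <- .cross_dist(xyz[rp, , drop = FALSE],
                       xyz[lig_polar, , drop = FALSE])
      wants_hb <- truth[[k]]["HB_PROT_DONOR"] || truth[[k]]["HB_PROT_ACCEPTOR"]
      if (any(d <= hb_cut) && !wants_hb &&
          !pl$type %in% c("HB_PROT_DONOR", "HB_PROT_ACCEPTOR")) {
        stop(
          "infeasible scene: plant ", pl$type,
          " places polar atoms in direct hydrogen-bond range of the ligand"
        )
      }
    }
    # a plant's bridge waters may only touch their own chain partners
    if (length(pl$water_resnos)) {
      w_o <- which(a$resno %in% pl$water_resnos & a$resname == "HOH" &
                     a$element == "O")
      own_polar <- c(rp, w_o, lig_polar)
      other_polar <- setdiff(
        which(a$element %in% c("N", "O", "S")), own_polar
      )
      if (length(other_polar)) {
        d <- .cross_dist(xyz[w_o, , drop = FALSE],
                         xyz[other_polar, , drop = FALSE])
        if (any(d <= hb_cut)) {
          stop(
            "infeasible scene: bridge waters of plant ", pl$type,
            " are in hydrogen-bond range of another plant"
          )
        }
      }
    }
  }
  invisible(TRUE)
}

# ---- Markov-switching pocket trajectories -------------------------------

#' Occupancy schedule for a synthetic trajectory
#'
#' @param labels residue labels of the scene plants to toggle.
#' @param p01,p10 per-label transition probabilities (recycled).
#' @param n_frames number of frames.
#' @param stride_ps inter-frame time step (default 500 ps).
#' @param seed integer seed.
#' @return object of class `occupancy_schedule`.
#' @export
occupancy_schedule <- function(labels, p01, p10, n_frames,
                               stride_ps = 500, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (anyDuplicated(labels)) {
    stop("conflicting schedules: duplicated residue label")
  }
  structure(
    data.frame(
      label = labels,
      p01 = rep_len(p01, length(labels)),
      p10 = rep_len(p10, length(labels)),
      stringsAsFactors = FALSE
    ),
    n_frames = as.integer(n_frames), stride_ps = stride_ps,
    seed = as.integer(seed),
    class = c("occupancy_schedule", "data.frame")
  )
}

#' Build a Markov-switching trajectory from a pocket scene
#'
#' Per frame, each scheduled plant is either engaged (its planted geometry)
#' or disengaged (the residue and its bridge waters translated 50 angstrom
#' outward, beyond every cutoff), following an independently simulated
#' two-state Markov chain. The exact state series is returned as ground
#' truth.
#'
#' @param scene result of [build_pocket_scene()].
#' @param schedule an [occupancy_schedule()].
#' @return list with `trajectory` and `states` (frame x label 0/1 matrix).
#' @export
build_pocket_trajectory <- function(scene, schedule) {
  stopifnot(inherits(schedule, "occupancy_schedule"))
  st <- scene$structure
  a <- st$atoms
  base <- coords(st)
  n <- attr(schedule, "n_frames")
  labels <- schedule$label
  plant_of <- lapply(labels, function(lb) {
    hit <- Filter(function(p) p$label == lb, scene$plants)
    if (!length(hit)) stop("schedule references unknown plant label: ", lb)
    hit[[1L]]
  })
  states <- vapply(seq_along(labels), function(i) {
    simulate_markov_chain(
      n, schedule$p01[i], schedule$p10[i],
      init = 1L, seed = attr(schedule, "seed") + i
    )
  }, integer(n))
  if (is.null(dim(states))) states <- matrix(states, nrow = n)
  colnames(states) <- labels
  move_idx <- lapply(plant_of, function(pl) {
    c(
      which(a$chain == pl$chain & a$resno == pl$resno & a$resname != "HOH"),
      which(a$resno %in% pl$water_resnos & a$resname == "HOH")
    )
  })
  dirs <- lapply(plant_of, function(pl) .unit(pl$dir))
  frames <- lapply(seq_len(n), function(f) {
    xyz <- base
    for (i in seq_along(labels)) {
      if (states[f, i] == 0L) {
        xyz[move_idx[[i]], ] <- sweep(
          xyz[move_idx[[i]], , drop = FALSE], 2L, 50 * dirs[[i]], "+"
        )
      }
    }
    xyz
  })
  times <- attr(schedule, "stride_ps") * seq_len(n)
  list(trajectory = new_trajectory(st, frames, times), states = states)
}

# ---- analytic pore structures -------------------------------------------

#' Build a pore-lining pseudo-atom structure with known radius profile
#'
#' Stacks rings of carbon pseudo-atoms whose centers sit at
#' `radius_fn(z) + vdw` from the z axis, so the accessible radius at z is
#' `radius_fn(z)` up to a discreteness correction. The exact on-axis
#' accessible radius (minimum over emitted atoms of center distance minus
#' vdw) is returned as the analytic reference.
#'
#' @param radius_fn function z -> lining radius (angstrom), positive.
#' @param lining_density atoms per angstrom of ring arc (default 1.5).
#' @param vdw van der Waals radius of the pseudo-atoms (default 1.7, the
#'   Bondi carbon radius).
#' @param z_range `c(min, max)` axial extent.
#' @param ring_spacing axial distance between rings (default 0.5).
#' @param seed integer seed (kept for interface symmetry; the lattice is
#'   deterministic).
#' @return list with `structure`, `analytic_radius` (function of z), and
#'   `analytic_min` (list with z, radius, discreteness_gap).
#' @export
build_pore_structure <- function(radius_fn, lining_density = 1.5, vdw = 1.7,
                                 z_range = c(-15, 15), ring_spacing = 0.5,
                                 seed = 1) {
  zs <- seq(z_range[1L], z_range[2L], by = ring_spacing)
  rows <- vector("list", length(zs))
  serial <- 0L
  for (ri in seq_along(zs)) {
    z <- zs[ri]
    r_line <- radius_fn(z)
    if (r_line <= 0) stop("radius_fn must be positive over z_range")
    r_atom <- r_line + vdw
    n_at <- max(6L, ceiling(lining_density * 2 * pi * r_atom))
    ang <- (seq_len(n_at) - 1L) * 2 * pi / n_at
    rows[[ri]] <- data.frame(
      serial = serial + seq_len(n_at),
      name = paste0("C", seq_len(n_at)),
      element = "C", resname = "POR", resno = ri, icode = "",
      chain = "P", altloc = "",
      x = r_atom * cos(ang), y = r_atom * sin(ang), z = z,
      occ = 1, b = 0, het = FALSE, stringsAsFactors = FALSE
    )
    serial <- serial + n_at
  }
  atoms <- do.call(rbind, rows)
  st <- new_structure(atoms, identifier = "synthetic_pore")
  xyz <- coords(st)
  analytic_radius <- function(z) {
    vapply(z, function(zz) {
      min(sqrt(xyz[, 1]^2 + xyz[, 2]^2 + (xyz[, 3] - zz)^2)) - vdw
    }, numeric(1))
  }
  fine <- seq(z_range[1L], z_range[2L], by = ring_spacing / 2)
  prof <- analytic_radius(fine)
  gap <- max(abs(prof - vapply(fine, radius_fn, numeric(1))))
  if (gap > 0.05) {
    warning(sprintf(
      "lining density gives a discreteness gap of %.3f angstrom", gap
    ), call. = FALSE)
  }
  list(
    structure = st,
    analytic_radius = analytic_radius,
    analytic_min = list(
      z = fine[which.min(prof)], radius = min(prof), discreteness_gap = gap
    )
  )
}
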
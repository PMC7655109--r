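test_that("fixed-column ATOM parsing follows the PDB layout", {
  line <- "ATOM      1  N   ALA A   7      11.000  22.000  33.000  1.00 20.00           N"
  traj <- read_structure(line)
  a <- traj$topology$atoms
  expect_equal(nrow(a), 1L)
  expect_equal(a$name, "N")
  expect_equal(a$element, "N")
  expect_equal(a$resname, "ALA")
  expect_equal(a$resno, 7L)
  expect_equal(a$chain, "A")
  expect_equal(unname(coords(traj$topology)[1, ]), c(11, 22, 33))
  expect_equal(length(traj$frames), 1L)
})

test_that("MODEL/ENDMDL delimits frames; inconsistent models error", {
  mk <- function(n) {
    sprintf(
      "ATOM  %5d  CA  GLY A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
      seq_len(n), seq_len(n), seq_len(n) * 2, 0, 0, 1, 0
    )
  }
  two <- c("MODEL        1", mk(3), "ENDMDL",
           "MODEL        2", mk(3), "ENDMDL")
  traj <- read_structure(two)
  expect_equal(length(traj$frames), 2L)
  expect_equal(traj$times, c(500, 1000))

  bad <- c("MODEL        1", mk(3), "ENDMDL",
           "MODEL        2", mk(2), "ENDMDL")
  expect_error(read_structure(bad, strict = TRUE), "model 2")
})

test_that("malformed lines error in strict mode, warn otherwise", {
  lines <- c(
    "ATOM      1  CA  GLY A   1       1.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A   x       bad coords here"
  )
  expect_error(read_structure(lines, strict = TRUE), "malformed")
  expect_warning(traj <- read_structure(lines, strict = FALSE), "malformed")
  expect_equal(nrow(traj$topology$atoms), 1L)
})

test_that("element falls back to name-based inference", {
  lines <- c(
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00",
    "ATOM      2 FE   HEM A   2       5.000   0.000   0.000  1.00  0.00",
    "ATOM      3 1HB  ALA A   3       9.000   0.000   0.000  1.00  0.00",
    "ATOM      4  OW  HOH W   4      13.000   0.000   0.000  1.00  0.00"
  )
  a <- read_structure(lines)$topology$atoms
  expect_equal(a$element, c("C", "Fe", "H", "O"))
})

test_that("altlocs collapse to highest occupancy, ties to letter A", {
  lines <- c(
    "ATOM      1  CA AGLY A   1       0.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BGLY A   1       1.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CB AGLY A   1       3.000   0.000   0.000  0.50  0.00           C",
    "ATOM      4  CB BGLY A   1       4.000   0.000   0.000  0.50  0.00           C"
  )
  a <- read_structure(lines)$topology$atoms
  expect_equal(nrow(a), 2L)
  expect_equal(a$x[a$name == "CA"], 1.0) # occupancy 0.6 wins
  expect_equal(a$x[a$name == "CB"], 3.0) # tie -> altloc A
})

test_that("write/read round-trip preserves identity and coordinates", {
  scene <- build_pocket_scene(
    pocket_scene_spec(
      list(list(type = "WATER1"), list(type = "APOLAR")),
      n_decoy_residues = 4L, n_waters = 3L, seed = 11
    )
  )
  st <- scene$structure
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(st, path)
  back <- frame_structure(read_structure(path), 1L)
  expect_equal(nrow(back$atoms), nrow(st$atoms))
  expect_equal(back$atoms$name, st$atoms$name)
  expect_equal(back$atoms$resname, st$atoms$resname)
  expect_equal(back$atoms$resno, st$atoms$resno)
  expect_equal(back$atoms$chain, st$atoms$chain)
  expect_lt(max(abs(coords(back) - coords(st))), 5e-4 + 1e-12)

  # multi-model trajectories survive too
  traj <- still_trajectory(st, 3L)
  path2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(traj, path2)
  back2 <- read_structure(path2)
  expect_equal(length(back2$frames), 3L)
})

test_that("selection resolves the documented examples", {
  st <- make_receptor()
  idx <- select_atoms(st, selection_spec(
    atom_names = "CA", residue_ranges = list(c(200, 205))
  ))
  expect_length(idx, 6L)

  wat <- select_atoms(st, selection_spec(element_classes = "water_oxygen"))
  expect_length(wat, 5L)

  expect_identical(select_atoms(st, selection_spec()), integer(0))

  expect_warning(
    none <- select_atoms(st, selection_spec(chains = "Z")),
    "unknown chain"
  )
  expect_length(none, 0L)
})

test_that("selection is idempotent and monotone under added constraints", {
  st <- build_pocket_scene(
    pocket_scene_spec(list(list(type = "HB_PROT_DONOR")),
                      n_decoy_residues = 3L, seed = 5)
  )$structure
  broad <- select_atoms(st, selection_spec(element_classes = "heavy"))
  narrower <- select_atoms(st, selection_spec(
    element_classes = "heavy", chains = "A"
  ))
  narrowest <- select_atoms(st, selection_spec(
    element_classes = "heavy", chains = "A", atom_names = "CA"
  ))
  expect_true(all(narrower %in% broad))
  expect_true(all(narrowest %in% narrower))
  expect_identical(
    select_atoms(st, selection_spec(element_classes = "heavy")), broad
  )
})

test_that("bond inference matches covalent geometry and brute force", {
  two_c <- function(d) {
    atoms_to_structure(list(
      atom_row("C1", "C", "UNK", 1L, "A", c(0, 0, 0)),
      atom_row("C2", "C", "UNK", 1L, "A", c(d, 0, 0))
    ))
  }
  expect_equal(nrow(infer_bonds(two_c(1.52))), 1L)
  expect_equal(nrow(infer_bonds(two_c(3.0))), 0L)

  # benzene-geometry ring: 6 bonds forming one cycle
  ring <- atoms_to_structure(lapply(0:5, function(k) {
    a <- k * pi / 3
    atom_row(paste0("C", k + 1), "C", "BNZ", 1L, "A",
             c(1.39 * cos(a), 1.39 * sin(a), 0))
  }))
  b <- infer_bonds(ring)
  expect_equal(nrow(b), 6L)
  deg <- table(c(b[, 1], b[, 2]))
  expect_true(all(deg == 2L)) # single cycle

  # brute-force equality on a generated scene
  st <- build_pocket_scene(
    pocket_scene_spec(list(list(type = "WATER2")), n_waters = 2L, seed = 3)
  )$structure
  got <- infer_bonds(st)
  a <- st$atoms
  xyz <- coords(st)
  crad <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05)
  expected <- list()
  watres <- function(i) a$resname[i] %in% c("HOH")
  for (i in seq_len(nrow(a) - 1)) {
    for (j in (i + 1):nrow(a)) {
      d <- odist(xyz[i, ], xyz[j, ])
      cut <- crad[a$element[i]] + crad[a$element[j]] + 0.45
      if (a$element[i] == "H" || a$element[j] == "H") cut <- min(cut, 1.25)
      if (a$element[i] == "H" && a$element[j] == "H") next
      same_res <- a$chain[i] == a$chain[j] & a$resno[i] == a$resno[j] &
        a$resname[i] == a$resname[j]
      if ((watres(i) || watres(j)) && !same_res) next
      if (d <= cut) expected[[length(expected) + 1L]] <- c(i, j)
    }
  }
  expected <- do.call(rbind, expected)
  expect_equal(nrow(got), nrow(expected))
  expect_true(all(got == expected))

  clash <- atoms_to_structure(list(
    atom_row("C1", "C", "UNK", 1L, "A", c(0, 0, 0)),
    atom_row("C2", "C", "UNK", 1L, "A", c(0.3, 0, 0))
  ))
  expect_error(infer_bonds(clash), "closer than 0.5")
})
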
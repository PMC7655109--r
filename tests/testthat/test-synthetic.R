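# generators: planted scenes, Markov trajectories, analytic pores.

test_that("single plants produce exactly their planted bitset", {
  for (tp in fingerprint_bits) {
    sc <- build_pocket_scene(pocket_scene_spec(list(list(type = tp)),
                                               seed = 1))
    bits <- classify_residue_frame(
      sc$structure, sc$ligand, sc$truth$chain[1], sc$truth$resno[1]
    )
    want <- unlist(sc$truth[1, fingerprint_bits])
    expect_equal(unname(bits), unname(want), label = tp)
    expect_true(bits[tp], label = tp)
  }
})

test_that("sub-threshold plants are labelled and classified as misses", {
  cases <- list(
    list(type = "APOLAR", distance = 4.6),
    list(type = "HB_PROT_DONOR", distance = 3.6),
    list(type = "HB_PROT_DONOR", distance = 3.0, angle = 95),
    list(type = "ELEC_PROT_POS", distance = 4.1),
    list(type = "AROM_FTF", distance = 4.2, angle = 5),
    list(type = "WATER1", distances = c(2.8, 3.7))
  )
  for (cs in cases) {
    sc <- build_pocket_scene(pocket_scene_spec(list(cs), seed = 2))
    expect_false(sc$truth[[cs$type]][1])
    bits <- classify_residue_frame(
      sc$structure, sc$ligand, sc$truth$chain[1], sc$truth$resno[1]
    )
    expect_equal(
      unname(bits), unname(unlist(sc$truth[1, fingerprint_bits]))
    )
  }
})

test_that("decoy-laden scenes still match ground truth exactly", {
  sc <- build_pocket_scene(pocket_scene_spec(
    list(list(type = "APOLAR"), list(type = "HB_PROT_DONOR"),
         list(type = "WATER1")),
    n_decoy_residues = 8L, n_waters = 10L, box = 20, seed = 7
  ))
  for (i in seq_len(nrow(sc$truth))) {
    bits <- classify_residue_frame(
      sc$structure, sc$ligand, sc$truth$chain[i], sc$truth$resno[i]
    )
    expect_equal(
      unname(bits), unname(unlist(sc$truth[i, fingerprint_bits])),
      label = sc$truth$label[i]
    )
  }
})

test_that("generators are seed-deterministic", {
  spec <- pocket_scene_spec(list(list(type = "WATER2")),
                            n_decoy_residues = 5L, n_waters = 5L, seed = 42)
  s1 <- build_pocket_scene(spec)
  s2 <- build_pocket_scene(spec)
  expect_identical(coords(s1$structure), coords(s2$structure))
  expect_identical(s1$truth, s2$truth)
  expect_error(pocket_scene_spec(list(list(type = "APOLAR"))),
               "seed is mandatory")

  p1 <- build_pore_structure(function(z) 3, z_range = c(-3, 3))
  p2 <- build_pore_structure(function(z) 3, z_range = c(-3, 3))
  expect_identical(coords(p1$structure), coords(p2$structure))
})

test_that("scenes survive bond inference and structure round-trips", {
  sc <- build_pocket_scene(pocket_scene_spec(
    list(list(type = "AROM_ETF"), list(type = "ELEC_PROT_NEG")),
    n_decoy_residues = 4L, n_waters = 4L, seed = 12
  ))
  expect_silent(b <- infer_bonds(sc$structure))
  expect_gt(nrow(b), 10)
  lines <- write_structure(sc$structure)
  back <- read_structure(lines)
  expect_equal(nrow(back$topology$atoms), nrow(sc$structure$atoms))
})

test_that("absorbing schedules keep the planted bit set in every frame", {
  sc <- build_pocket_scene(pocket_scene_spec(list(list(type = "APOLAR")),
                                             seed = 3))
  lbl <- sc$truth$label[1]
  sch <- occupancy_schedule(lbl, p01 = 0, p10 = 0, n_frames = 12, seed = 5)
  bt <- build_pocket_trajectory(sc, sch)
  expect_true(all(bt$states == 1L))
  fp <- fingerprint_trajectory(
    bt$trajectory, sc$ligand,
    residues = data.frame(chain = sc$truth$chain[1],
                          resno = sc$truth$resno[1])
  )
  expect_true(all(fp$bits[lbl, "APOLAR", , 1]))
})

test_that("simulated occupancy matches its binomial expectation", {
  s <- simulate_markov_chain(2000, p01 = 0.5, p10 = 0.5, seed = 8)
  se <- sqrt(0.25 / 2000)
  expect_lt(abs(mean(s) - 0.5), 3 * se)
  # absorbing cases
  expect_true(all(simulate_markov_chain(50, 0, 0, init = 1L, seed = 1) == 1L))
  expect_true(all(simulate_markov_chain(50, 0, 0, init = 0L, seed = 1) == 0L))
})

test_that("trajectory states drive the classified bits frame by frame", {
  sc <- build_pocket_scene(pocket_scene_spec(
    list(list(type = "HB_PROT_DONOR"), list(type = "WATER1")), seed = 21
  ))
  sch <- occupancy_schedule(
    sc$truth$label[1:2], p01 = c(0.4, 0.2), p10 = c(0.4, 0.3),
    n_frames = 30, seed = 77
  )
  bt <- build_pocket_trajectory(sc, sch)
  fp <- fingerprint_trajectory(
    bt$trajectory, sc$ligand,
    residues = data.frame(chain = sc$truth$chain[1:2],
                          resno = sc$truth$resno[1:2])
  )
  for (i in 1:2) {
    bit <- c("HB_PROT_DONOR", "WATER1")[i]
    got <- as.integer(fp$bits[sc$truth$label[i], bit, , 1])
    expect_equal(got, unname(bt$states[, i]))
  }
  expect_error(
    occupancy_schedule(rep(sc$truth$label[1], 2), 0.1, 0.1, 10, seed = 1),
    "duplicated"
  )
})

test_that("pore structures scale linearly and locate step constrictions", {
  base <- build_pore_structure(function(z) 2, lining_density = 2,
                               z_range = c(-4, 4))
  dbl <- build_pore_structure(function(z) 4, lining_density = 2,
                              z_range = c(-4, 4))
  pb <- pore_profile(base$structure, axis = c(0, 0, 1), anchor = c(0, 0, 0),
                     z_range = c(-3, 3))
  pd <- pore_profile(dbl$structure, axis = c(0, 0, 1), anchor = c(0, 0, 0),
                     z_range = c(-3, 3))
  expect_lt(max(abs(pd$samples$radius - 2 * pb$samples$radius)), 0.2)

  step_fn <- function(z) if (abs(z - 1) < 1) 2.0 else 4.0
  stp <- suppressWarnings(build_pore_structure(
    step_fn, lining_density = 2, z_range = c(-4, 4)
  ))
  ps <- pore_profile(stp$structure, axis = c(0, 0, 1), anchor = c(0, 0, 0),
                     z_range = c(-3, 3))
  expect_lt(abs(ps$minimum$z - 1), 1 + 1e-9)
  expect_equal(ps$minimum$radius, 2.0, tolerance = 0.1)

  expect_error(
    build_pore_structure(function(z) z, z_range = c(-2, 2)),
    "positive"
  )
  expect_warning(
    build_pore_structure(function(z) 3, lining_density = 0.15,
                         z_range = c(-2, 2), ring_spacing = 2),
    "discreteness gap"
  )
})
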
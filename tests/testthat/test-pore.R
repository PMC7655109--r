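# maximal-sphere pore profiling.

test_that("pore_radius_at solves simple symmetric planes exactly", {
  # three atoms at 120 degrees on a circle of radius 5: optimum at center
  tri <- atoms_to_structure(lapply(0:2, function(k) {
    a <- k * 2 * pi / 3
    atom_row(paste0("C", k + 1), "C", "POR", 1L, "P",
             c(5 * cos(a), 5 * sin(a), 0))
  }))
  r <- pore_radius_at(tri, 0, c(0, 0, 1), c(0, 0, 0))
  expect_equal(r$radius, 5 - 1.7, tolerance = 1e-6)
  expect_false(r$unbounded)

  # dense ring: radius -> R - vdw
  ring <- atoms_to_structure(lapply(0:59, function(k) {
    a <- k * 2 * pi / 60
    atom_row(paste0("C", k + 1), "C", "POR", 1L, "P",
             c(5 * cos(a), 5 * sin(a), 0))
  }))
  r2 <- pore_radius_at(ring, 0, c(0, 0, 1), c(0, 0, 0))
  expect_equal(r2$radius, 3.3, tolerance = 0.1)

  # empty plane: capped and flagged unbounded
  r3 <- pore_radius_at(tri, 50, c(0, 0, 1), c(0, 0, 0))
  expect_true(r3$unbounded)
  expect_equal(r3$radius, pore_config()$max_radius)
})

test_that("in-plane optimum matches a dense 2-D grid search", {
  # irregular but enclosing fixture: a perturbed octagon with mixed
  # elements and out-of-plane offsets, so the optimum is interior
  set.seed(55)
  els <- c("C", "O", "N", "C", "C", "O", "C", "N")
  st <- atoms_to_structure(lapply(0:7, function(k) {
    a <- k * pi / 4
    r <- 4.0 + 0.6 * sin(3 * a + 0.5)
    atom_row(paste0("A", k + 1), els[k + 1], "POR", 1L, "P",
             c(r * cos(a) + 0.2 * k %% 3 * 0.1, r * sin(a),
               0.3 * cos(2 * a)))
  }))
  got <- pore_radius_at(st, 0, c(0, 0, 1), c(0, 0, 0))
  want <- oracle_pore_grid(st, 0, c(0, 0, 1), c(0, 0, 0),
                           extent = 3, resolution = 0.05)
  expect_gte(got$radius + 1e-9, want) # grid can only underestimate
  expect_lt(abs(got$radius - want), 0.06)
})

test_that("profiles recover planted analytic radii", {
  cyl <- build_pore_structure(function(z) 4.0, lining_density = 2,
                              z_range = c(-6, 6))
  pp <- pore_profile(cyl$structure, axis = c(0, 0, 1), anchor = c(0, 0, 0),
                     z_range = c(-5, 5))
  expect_lt(max(pp$samples$radius) - min(pp$samples$radius), 0.1)
  expect_lt(max(abs(pp$samples$radius - cyl$analytic_radius(pp$samples$z))),
            0.05)

  hour <- suppressWarnings(build_pore_structure(
    function(z) 1.3 + 3 * abs(z) / 8, lining_density = 2,
    z_range = c(-8, 8)
  ))
  pph <- pore_profile(hour$structure, axis = c(0, 0, 1),
                      anchor = c(0, 0, 0), z_range = c(-6, 6),
                      roles = residue_role_map(
                        pore_marker_residues = c(waist = 17L)
                      ))
  expect_equal(pph$minimum$z, 0, tolerance = 0.5 + 1e-9)
  expect_lt(
    max(abs(pph$samples$radius - hour$analytic_radius(pph$samples$z))), 0.1
  )
  # ring 17 sits at z = 0 for this lattice: the waist marker is found
  expect_equal(pph$minimum$marker, "waist")

  # removing half the lining atoms never shrinks the radius anywhere
  thin <- hour$structure
  thin$atoms <- thin$atoms[seq_len(nrow(thin$atoms)) %% 2L == 0L, ]
  ppt <- pore_profile(thin, axis = c(0, 0, 1), anchor = c(0, 0, 0),
                      z_range = c(-6, 6))
  expect_true(all(ppt$samples$radius >= pph$samples$radius - 1e-9))
})

test_that("profiles are rigid-equivariant and bit-identical on reruns", {
  cyl <- build_pore_structure(function(z) 3.0, lining_density = 2,
                              z_range = c(-4, 4))
  p1 <- pore_profile(cyl$structure, axis = c(0, 0, 1), anchor = c(0, 0, 0),
                     z_range = c(-3, 3))
  p2 <- pore_profile(cyl$structure, axis = c(0, 0, 1), anchor = c(0, 0, 0),
                     z_range = c(-3, 3))
  expect_identical(p1$samples, p2$samples)

  set.seed(13)
  for (i in 1:3) {
    tf <- random_rigid_transform()
    st2 <- cyl$structure
    coords(st2) <- tf$apply(coords(cyl$structure))
    ax <- as.numeric(c(0, 0, 1) %*% tf$rotation)
    an <- as.numeric(c(0, 0, 0) %*% tf$rotation + tf$translation)
    p3 <- pore_profile(st2, axis = ax, anchor = an, z_range = c(-3, 3))
    expect_lt(max(abs(p3$samples$radius - p1$samples$radius)), 1e-6)
  }
})

test_that("principal axis recovers the symmetry axis of an elongated pore", {
  cyl <- build_pore_structure(function(z) 4.0, lining_density = 1.5,
                              z_range = c(-12, 12))
  pa <- principal_axis(cyl$structure)
  expect_gt(abs(pa$axis[3]), 0.999)
})

test_that("profile statistics reduce a common z grid", {
  cyl <- build_pore_structure(function(z) 3.0, lining_density = 2,
                              z_range = c(-3, 3))
  p <- pore_profile(cyl$structure, axis = c(0, 0, 1), anchor = c(0, 0, 0),
                    z_range = c(-2, 2))
  s0 <- profile_statistics(list(p, p, p))
  expect_true(all(s0$sd_radius == 0))
  expect_true(all(s0$n_frames == 3))

  q <- p
  q$samples$radius[3] <- q$samples$radius[3] + 0.2
  r <- p
  r$samples$radius[3] <- r$samples$radius[3] - 0.2
  s1 <- profile_statistics(list(q, r))
  expect_equal(s1$sd_radius[3], 0.2 * sqrt(2), tolerance = 1e-12)
  expect_equal(s1$mean_radius[3], p$samples$radius[3], tolerance = 1e-12)

  bad <- p
  bad$samples <- bad$samples[-1, ]
  expect_error(profile_statistics(list(p, bad)), "common z grid")
  expect_error(profile_statistics(list(p)), "at least 2")
})

test_that("strip_for_pore removes solvent, ions and the named ligand", {
  sc <- build_pocket_scene(
    pocket_scene_spec(list(list(type = "APOLAR")), n_waters = 3L, seed = 4)
  )
  st <- sc$structure
  ion <- atom_row("NA", "Na", "NA", 999L, "I", c(50, 50, 50), het = TRUE)
  st$atoms <- rbind(st$atoms, ion)
  st$atoms$serial <- seq_len(nrow(st$atoms))
  stripped <- strip_for_pore(st, ligand_resnames = "LIG")
  expect_false(any(stripped$atoms$resname %in% c("HOH", "LIG", "NA")))
  expect_true(all(stripped$atoms$resname %in% c("ALA")))
})
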
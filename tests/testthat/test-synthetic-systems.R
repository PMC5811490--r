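neu <- elk_peptides()[["neu"]]

test_that("ideal helix has canonical rise, twist periodicity and sidechains", {
  h <- build_ideal_helix(neu)
  ca <- h[h$role == "BACKBONE_CA", ]
  expect_equal(max(ca$z) - min(ca$z), 17 * 1.5)
  # residues 18 apart share an azimuth (1800 degrees is a full number of turns)
  h2 <- build_ideal_helix(strrep("L", 19))
  ca2 <- h2[h2$role == "BACKBONE_CA", ]
  az <- atan2(ca2$y, ca2$x)
  expect_equal(az[19], az[1], tolerance = 1e-10)
  # sidechain pseudo-atoms share their residue's azimuth: Lys amines sit at
  # the wheel angles of the Lys residues, opposite the Leu cluster
  wl <- wheel_layout(neu)
  nz <- h[h$role == "LYS_NZ", ]
  nz_az <- (atan2(nz$y, nz$x) * 180 / pi) %% 360
  expect_equal(unname(sort(nz_az)), sort(wl$angle[wl$residue == "K"]),
    tolerance = 1e-8
  )
  leu_mean <- face_azimuth(neu)
  lys_mean <- (atan2(mean(sin(nz_az * pi / 180)), mean(cos(nz_az * pi / 180))) *
    180 / pi) %% 360
  dihedral <- abs(((lys_mean - leu_mean + 180) %% 360) - 180)
  expect_gt(dihedral, 90) # amine cluster faces away from the Leu face
})

test_that("membrane patch honours composition, leaflet ordering and height", {
  patch <- build_membrane_patch(neu, n_popc = 90, n_chol = 10, height = 10)
  # composition: one phosphate per POPC, 45 + 5 molecules per leaflet
  expect_equal(length(select_atoms(patch, "role:P")), 90)
  upper_p <- sum(patch$role == "LIPID_P" & patch$z > 0)
  expect_equal(upper_p, 45)
  chol_chains <- unique(patch$chain[substr(patch$chain, 1, 1) == "C"])
  expect_equal(length(chol_chains), 10)
  # per-leaflet depth ordering: |choline N| > |P| > |C2|
  for (s in c(1, -1)) {
    side <- patch[sign(patch$z) == s, ]
    expect_gt(
      min(abs(side$z[side$role == "LIPID_CHOLINE_N"])),
      max(abs(side$z[side$role == "LIPID_P"]))
    )
    expect_gt(
      min(abs(side$z[side$role == "LIPID_P"])),
      max(abs(side$z[side$role == "LIPID_C2_OLEOYL"]))
    )
  }
  # constructed height is recovered exactly at zero noise
  traj <- synthesize_trajectory(patch, sigma = 0, n_frames = 3)
  expect_equal(peptide_height_series(traj, "P1"), rep(10, 3))
  expect_equal(peptide_height_series(traj, "P2"), rep(10, 3))
  # peptides lie flat: the first-to-last C-alpha axis lies in the bilayer
  # plane up to the azimuthal offset between the terminal residues
  ax <- pepdisc:::helix_axis(patch[patch$chain == "P1", ])
  expect_lt(abs(ax[3]), 0.2)
  # hydrophobic face toward the bilayer interior: Leu sidechains sit below
  # the backbone for the upper-leaflet peptide
  p1 <- patch[patch$chain == "P1", ]
  expect_lt(
    mean(p1$z[p1$role == "LEU_SIDECHAIN_C"]),
    mean(p1$z[p1$role == "BACKBONE_CA"])
  )
  expect_error(build_membrane_patch(neu, n_popc = 0, n_chol = 0), "zero lipids")
})

test_that("edge slab places upright peptides on the two exposed edges", {
  slab <- build_edge_slab(neu,
    n_popc = 80, n_chol = 8, n_peptides = 8,
    arrangement = "mixed"
  )
  expect_equal(length(select_atoms(slab, "role:P")), 80)
  chains <- unique(slab$chain[substr(slab$chain, 1, 1) == "P"])
  expect_equal(length(chains), 8)
  centres <- vapply(chains, function(ch) {
    pepdisc:::backbone_centre(slab[slab$chain == ch, ])[1]
  }, numeric(1))
  expect_equal(sum(centres > 0), 4) # 4 peptides per edge
  # upright: axis along the bilayer normal
  axes <- lapply(chains, function(ch) {
    pepdisc:::helix_axis(slab[slab$chain == ch, ])
  })
  expect_true(all(vapply(axes, function(a) abs(a[3]) > 0.99, logical(1))))
  # mixed arrangement: parallel edge and antiparallel edge
  dots_edge2 <- vapply(6:8, function(i) {
    sum(axes[[i]] * axes[[i - 1]])
  }, numeric(1))
  expect_true(all(dots_edge2 < 0)) # consecutive flipped on edge two
  expect_true(sum(axes[[1]] * axes[[2]]) > 0) # same direction on edge one
  # the periodic edge length is honoured in the box
  expect_equal(frame_box(slab)[2], 70)
  expect_equal(frame_periodic(slab), c(FALSE, TRUE, FALSE))
  expect_error(
    build_edge_slab(neu, n_peptides = 14, edge_length = 70),
    "edge length"
  )
})

test_that("nanodisc builder is deterministic and supports both placements", {
  fence <- build_nanodisc(neu, placement = "picket_fence")
  chains <- unique(fence$chain[substr(fence$chain, 1, 1) == "P"])
  expect_equal(length(chains), 24)
  expect_equal(length(select_atoms(fence, "role:P")), 150)
  radius <- sqrt(83 * 65 / pi)
  for (ch in chains[1:6]) {
    a <- pepdisc:::helix_axis(fence[fence$chain == ch, ])
    expect_gt(abs(a[3]), cos(15 * pi / 180)) # within 15 deg of the normal
    ctr <- pepdisc:::backbone_centre(fence[fence$chain == ch, ])
    expect_equal(sqrt(ctr[1]^2 + ctr[2]^2), radius + 4, tolerance = 1e-6)
  }
  # the inertia estimator recovers the constructed lipid disc diameter
  est <- disc_diameter(fence)
  expect_equal(est$diameter, 2 * radius, tolerance = 0.02)
  # random surface placement: seeded and reproducible
  r1 <- build_nanodisc(neu, placement = "random_surface", seed = 7)
  r2 <- build_nanodisc(neu, placement = "random_surface", seed = 7)
  r3 <- build_nanodisc(neu, placement = "random_surface", seed = 8)
  expect_identical(r1, r2)
  expect_false(identical(r1$x, r3$x))
  expect_error(build_nanodisc(neu, placement = "random_surface"), "seed")
})

test_that("synthesized trajectories are seeded, noisy and scriptable", {
  patch <- build_membrane_patch(neu)
  expect_identical(
    synthesize_trajectory(patch, 0, 3)$x,
    rep(patch$x, 3)
  )
  t1 <- synthesize_trajectory(patch, 0.5, 4, seed = 3)
  t2 <- synthesize_trajectory(patch, 0.5, 4, seed = 3)
  expect_identical(t1, t2)
  expect_error(synthesize_trajectory(patch, 0.5, 4), "seed")
  # scripted contact pair: schedule 1,1,1,0,1 at 10 ps gives runs 30, 10 ps
  pair <- new_frame(tibble::tibble(
    role = c("LYS_NZ", "LIPID_P"), chain = c("P1", "L1"),
    resid = 1L, resname = c("LYS", "POP"),
    x = c(0, 20), y = 0, z = 0
  ))
  script <- tibble::tibble(
    atom_a = 1L, atom_b = 2L, cutoff = 4.6,
    schedule = list(c(TRUE, TRUE, TRUE, FALSE, TRUE))
  )
  traj <- synthesize_trajectory(pair, 0, 5, dt = 10, contact_script = script)
  cs <- contact_series(traj, "lys_phosphate")
  expect_equal(cs$counts, c(1L, 1L, 1L, 0L, 1L))
  expect_equal(suppressWarnings(contact_lifetimes(cs)), 20)
})
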
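test_that("the ideal ring has exact hexagonal COM geometry", {
  ring <- build_ideal_ring()  # default: n = 6, R = 35
  asg <- assign_domains(ring$structure, ring$topology)
  coms <- domain_coms(ring$structure, asg)
  ord <- ring$topology$ring_order
  n <- length(ord)
  for (k in seq_len(n)) {
    a <- ord[k]; b <- ord[k %% n + 1L]; c <- ord[(k + 1L) %% n + 1L]
    expect_equal(com_distance(coms[a, ], coms[b, ]), 35, tolerance = 1e-6)
    expect_equal(com_angle(coms[a, ], coms[b, ], coms[c, ]), 120,
                 tolerance = 1e-6)
  }
  expect_equal(handedness_sum(ring$structure, asg, ring$topology), 0,
               tolerance = 1e-6)
})

test_that("ring generation is deterministic given the seed", {
  r1 <- build_ideal_ring(seed = 42)
  r2 <- build_ideal_ring(seed = 42)
  expect_identical(r1$structure$xyz, r2$structure$xyz)
  r3 <- build_ideal_ring(seed = 43)
  expect_false(identical(r1$structure$xyz, r3$structure$xyz))
})

test_that("spiral deformations inject exact torsion changes", {
  ring <- build_ideal_ring(seed = 2)
  asg <- assign_domains(ring$structure, ring$topology)
  rh <- apply_deformation(ring$structure, ring$topology, "rh_spiral",
                          twist = 20)
  expect_equal(handedness_sum(rh, asg, ring$topology), 60, tolerance = 1e-6)
  lh <- apply_deformation(ring$structure, ring$topology, "lh_spiral",
                          twist = 20)
  expect_equal(handedness_sum(lh, asg, ring$topology), -60, tolerance = 1e-6)
  # each individual window changed by exactly the twist
  coms <- domain_coms(rh, asg, atoms = ring$structure$atoms)
  for (q in ring$topology$torsion_quadruples)
    expect_equal(com_dihedral(coms[q[1], ], coms[q[2], ], coms[q[3], ],
                              coms[q[4], ]), 20, tolerance = 1e-6)
})

test_that("planar opening widens the interface by exactly the gap, in plane", {
  ring <- build_ideal_ring(seed = 2)
  asg <- assign_domains(ring$structure, ring$topology)
  oi <- ring$topology$open_interface
  c0 <- domain_coms(ring$structure, asg)
  po <- apply_deformation(ring$structure, ring$topology, "planar_open",
                          gap = 20)
  c1 <- domain_coms(po, asg)
  expect_equal(com_distance(c1[oi[1], ], c1[oi[2], ]) -
                 com_distance(c0[oi[1], ], c0[oi[2], ]), 20,
               tolerance = 1e-6)
  expect_equal(handedness_sum(po, asg, ring$topology), 0, tolerance = 1e-6)
})

test_that("in-plane hinging opens the designated COM angle exactly", {
  ring <- build_ideal_ring(seed = 2)
  asg <- assign_domains(ring$structure, ring$topology)
  triple <- c("B1", "B2", "B3")
  ia <- apply_deformation(ring$structure, ring$topology, "in_plane_angle",
                          increment = 7, angle_triple = triple)
  c1 <- domain_coms(ia, asg)
  expect_equal(com_angle(c1[triple[1], ], c1[triple[2], ], c1[triple[3], ]),
               127, tolerance = 1e-6)  # 120 + 7
  expect_equal(handedness_sum(ia, asg, ring$topology), 0, tolerance = 1e-6)
})

test_that("every deformation is exactly invertible", {
  ring <- build_ideal_ring(seed = 6)
  s <- ring$structure; topo <- ring$topology
  rh <- apply_deformation(s, topo, "rh_spiral", twist = 17)
  back <- apply_deformation(rh, topo, "lh_spiral", twist = 17)
  expect_lt(max(abs(back$xyz - s$xyz)), 1e-9)
  po <- apply_deformation(s, topo, "planar_open", gap = 12)
  back2 <- apply_deformation(po, topo, "planar_open", gap = -12)
  expect_lt(max(abs(back2$xyz - s$xyz)), 1e-9)
  ia <- apply_deformation(s, topo, "in_plane_angle", increment = 9)
  back3 <- apply_deformation(ia, topo, "in_plane_angle", increment = -9)
  expect_lt(max(abs(back3$xyz - s$xyz)), 1e-9)
})

test_that("left- and right-handed spirals are COM-level mirror images", {
  ring <- build_ideal_ring(seed = 4)
  asg <- assign_domains(ring$structure, ring$topology)
  rh <- apply_deformation(ring$structure, ring$topology, "rh_spiral",
                          twist = 15)
  lh <- apply_deformation(ring$structure, ring$topology, "lh_spiral",
                          twist = 15)
  # z-reflected right-handed COMs superpose exactly onto the left-handed COMs
  crh <- domain_coms(rh, asg) %*% diag(c(1, 1, -1))
  clh <- domain_coms(lh, asg)
  expect_lt(kabsch_superpose(crh, clh)$rmsd, 1e-9)
  expect_equal(handedness_sum(lh, asg, ring$topology),
               -handedness_sum(rh, asg, ring$topology), tolerance = 1e-9)
})

test_that("noiseless trajectories recover the injected rotations exactly", {
  ring <- build_ideal_ring(seed = 8)
  asg <- assign_domains(ring$structure, ring$topology)
  tr <- generate_trajectory(ring$structure, ring$topology,
                            rotation_mean = 10, rotation_sd = 0,
                            noise_sd = 0, n_frames = 5, seed = 1)
  rs <- rotation_series(tr, asg, c("A1", "A2"))
  expect_equal(rs$values, rep(10, 5), tolerance = 1e-9)
  # ground-truth draws match recovered per-frame rotations
  tr2 <- generate_trajectory(ring$structure, ring$topology,
                             rotation_mean = 13.9, rotation_sd = 4.4,
                             noise_sd = 0, n_frames = 50, seed = 5)
  rs2 <- rotation_series(tr2, asg, c("A1", "A2"))
  gt <- attr(tr2, "ground_truth")
  expect_lt(max(abs(rs2$values - gt$applied_rotation_deg)), 1e-6)
})

test_that("trajectory generation validates inputs and is deterministic", {
  ring <- build_ideal_ring()
  expect_error(generate_trajectory(ring$structure, ring$topology,
                                   rotation_sd = -1), "non-negative")
  expect_error(generate_trajectory(ring$structure, ring$topology,
                                   n_frames = 1), "n_frames")
  t1 <- generate_trajectory(ring$structure, ring$topology, n_frames = 3,
                            seed = 9, noise_sd = 0.2)
  t2 <- generate_trajectory(ring$structure, ring$topology, n_frames = 3,
                            seed = 9, noise_sd = 0.2)
  expect_identical(t1$frames, t2$frames)
})
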
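test_that("COM distance matches hand values and the norm oracle", {
  expect_equal(com_distance(c(0, 0, 0), c(0, 0, 0)), 0)
  expect_equal(com_distance(c(0, 0, 0), c(3, 4, 0)), 5)
  set.seed(2)
  for (rep in 1:20) {
    p <- rnorm(3, sd = 10); q <- rnorm(3, sd = 10)
    expect_equal(com_distance(p, q), sqrt(sum((p - q)^2)), tolerance = 1e-12)
  }
})

test_that("COM angle covers collinear, right-angle and degenerate cases", {
  expect_equal(com_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)), 180)
  expect_equal(com_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)), 90)
  expect_error(com_angle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)), "degenerate")
})

test_that("dihedral follows the IUPAC sign convention", {
  expect_equal(com_dihedral(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)), 0)
  expect_equal(com_dihedral(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(2, 1, 0)), 180)
  # p4 rotated by +25 deg about the p2->p3 axis from the cis configuration
  p2 <- c(1, 0, 0); p3 <- c(1, 1, 0); p4 <- c(0, 1, 0)
  R <- clampring:::rotation_matrix(p3 - p2, 25)
  p4r <- as.numeric(R %*% (p4 - p3)) + p3
  expect_equal(com_dihedral(c(0, 0, 0), p2, p3, p4r), 25, tolerance = 1e-9)
  expect_error(com_dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "collinear")
})

test_that("dihedral equals the brute-force oracle on 1000 random instances", {
  set.seed(11)
  worst <- 0
  for (rep in 1:1000) {
    p <- matrix(rnorm(12, sd = 5), 4, 3)
    v <- try(com_dihedral(p[1, ], p[2, ], p[3, ], p[4, ]), silent = TRUE)
    if (inherits(v, "try-error")) next
    worst <- max(worst, abs(v - dihedral_oracle(p[1, ], p[2, ], p[3, ], p[4, ])))
  }
  expect_lt(worst, 1e-9)
})

test_that("Kabsch recovers exact rigid transforms", {
  set.seed(4)
  X <- matrix(rnorm(30, sd = 5), 10, 3)
  f0 <- kabsch_superpose(X, X)
  expect_equal(f0$rmsd, 0, tolerance = 1e-12)
  expect_equal(f0$R, diag(3), tolerance = 1e-9)
  R <- random_rotation()
  t <- rnorm(3, sd = 20)
  Y <- X %*% t(R) + matrix(t, 10, 3, byrow = TRUE)
  fit <- kabsch_superpose(X, Y)
  expect_lt(max(abs(fit$R - R)), 1e-9)
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(det(fit$R), 1, tolerance = 1e-9)
})

test_that("Kabsch RMSD matches the quaternion oracle on random clouds", {
  set.seed(21)
  for (rep in 1:200) {
    X <- matrix(rnorm(30, sd = 4), 10, 3)
    Y <- X %*% t(random_rotation()) + matrix(rnorm(30, sd = 0.6), 10, 3)
    expect_equal(kabsch_superpose(X, Y)$rmsd, horn_rmsd(X, Y),
                 tolerance = 1e-9)
  }
})

test_that("superposed RMSD never exceeds the raw RMSD", {
  set.seed(8)
  for (rep in 1:50) {
    X <- matrix(rnorm(24, sd = 5), 8, 3)
    Y <- matrix(rnorm(24, sd = 5), 8, 3)
    raw <- sqrt(mean(rowSums((X - Y)^2)))
    expect_lte(kabsch_superpose(X, Y)$rmsd, raw + 1e-12)
  }
})

test_that("degenerate superposition inputs error", {
  expect_error(kabsch_superpose(matrix(0, 2, 3), matrix(0, 2, 3)), "3 points")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "degenerate")
})

test_that("RMSD100 normalisation matches its closed form", {
  expect_equal(rmsd100(1.7, 100), 1.7)
  expect_equal(rmsd100(2.0, 200), 2.0 / (1 + log(2)))
  expect_equal(rmsd100(0, 350), 0)
  # monotone decreasing in N at fixed RMSD
  ns <- c(50, 100, 200, 500, 1000)
  vals <- rmsd100(rep(2, length(ns)), ns)
  expect_true(all(diff(vals) < 0))
  expect_error(rmsd100(1, 0), "positive")
  expect_error(rmsd100(1, 20), "undefined")
})

test_that("handedness sum is additive, zero when planar, odd under mirror", {
  ring <- build_ideal_ring(seed = 7)
  asg <- assign_domains(ring$structure, ring$topology)
  topo <- ring$topology
  expect_equal(handedness_sum(ring$structure, asg, topo), 0, tolerance = 1e-6)
  rh <- apply_deformation(ring$structure, topo, "rh_spiral", twist = 20)
  expect_equal(handedness_sum(rh, asg, topo), 60, tolerance = 1e-6)
  # additivity: the sum equals the three individually computed torsions
  coms <- domain_coms(rh, asg, atoms = ring$structure$atoms)
  tors <- vapply(topo$torsion_quadruples, function(q)
    com_dihedral(coms[q[1], ], coms[q[2], ], coms[q[3], ], coms[q[4], ]),
    numeric(1))
  expect_identical(handedness_sum(rh, asg, topo), sum(tors))
  # chirality antisymmetry under z-reflection
  mir <- rh$xyz %*% diag(c(1, 1, -1))
  expect_equal(handedness_sum(mir, asg, topo, atoms = ring$structure$atoms),
               -handedness_sum(rh, asg, topo), tolerance = 1e-9)
})

test_that("metrics are invariant under global rigid motion", {
  ring <- build_ideal_ring(seed = 13)
  s <- apply_deformation(ring$structure, ring$topology, "rh_spiral",
                         twist = 12)
  asg <- assign_domains(s, ring$topology)
  coms <- domain_coms(s, asg)
  set.seed(5)
  R <- random_rotation(); t <- rnorm(3, sd = 30)
  xr <- s$xyz %*% t(R) + matrix(t, nrow(s$xyz), 3, byrow = TRUE)
  cr <- domain_coms(xr, asg, atoms = s$atoms)
  expect_equal(com_distance(cr["A1", ], cr["A2", ]),
               com_distance(coms["A1", ], coms["A2", ]), tolerance = 1e-9)
  expect_equal(com_angle(cr["A1", ], cr["A2", ], cr["A3", ]),
               com_angle(coms["A1", ], coms["A2", ], coms["A3", ]),
               tolerance = 1e-9)
  expect_equal(handedness_sum(xr, asg, ring$topology, atoms = s$atoms),
               handedness_sum(s, asg, ring$topology), tolerance = 1e-9)
})

test_that("inter-domain rotation recovers constructed rotations with sign", {
  ring <- build_ideal_ring(seed = 3)
  asg <- assign_domains(ring$structure, ring$topology)
  ref <- ring$structure$xyz
  ii <- asg[["A1"]]; jj <- asg[["A2"]]
  ci <- domain_com(ring$structure, asg, "A1")
  cj <- domain_com(ring$structure, asg, "A2")
  # both domains co-rotated rigidly -> relative rotation 0
  R <- random_rotation()
  cur <- ref %*% t(R)
  expect_equal(inter_domain_rotation(ref[ii, ], cur[ii, ], ref[jj, ],
                                     cur[jj, ]), 0, tolerance = 1e-7)
  # j rotated +15 deg about the i->j axis, i fixed
  cur2 <- ref
  cur2[jj, ] <- clampring:::.rotate_about(ref[jj, , drop = FALSE], cj,
                                          cj - ci, 15)
  got <- inter_domain_rotation(ref[ii, ], cur2[ii, ], ref[jj, ], cur2[jj, ])
  expect_equal(got, 15, tolerance = 1e-7)
  # mirroring flips the sign, preserves magnitude
  M <- diag(c(1, 1, -1))
  got_m <- inter_domain_rotation(ref[ii, ] %*% M, cur2[ii, ] %*% M,
                                 ref[jj, ] %*% M, cur2[jj, ] %*% M)
  expect_equal(got_m, -15, tolerance = 1e-7)
})
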
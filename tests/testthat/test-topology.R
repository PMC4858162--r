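test_that("topology validation enforces the ring invariants", {
  dom <- data.frame(label = c("A1", "A2", "A3", "B1"), chain = "A",
                    start = c(1, 11, 21, 31), end = c(10, 20, 30, 40))
  ok <- clamp_topology("t", dom, c("A1", "A2", "A3", "B1"),
                       c("B1", "A1"),
                       list(c("A1", "A2", "A3", "B1"),
                            c("A2", "A3", "B1", "A1"),
                            c("A3", "B1", "A1", "A2")))
  expect_s3_class(ok, "clamp_topology")
  # non-adjacent open interface
  expect_error(clamp_topology("t", dom, c("A1", "A2", "A3", "B1"),
                              c("A1", "A3"), NULL), "adjacent")
  # label missing from ring order
  expect_error(clamp_topology("t", dom, c("A1", "A2", "A3"), NULL, NULL),
               "exactly once")
  # quadruple with a repeat
  expect_error(clamp_topology("t", dom, c("A1", "A2", "A3", "B1"), NULL,
                              list(c("A1", "A1", "A2", "A3"),
                                   c("A1", "A2", "A3", "B1"),
                                   c("A2", "A3", "B1", "A1"))), "distinct")
})

test_that("topology YAML round-trips", {
  ring <- build_ideal_ring()
  f <- withr::local_tempfile(fileext = ".yaml")
  write_topology(ring$topology, f)
  t2 <- read_topology(f)
  expect_equal(t2$ring_order, ring$topology$ring_order)
  expect_equal(t2$open_interface, ring$topology$open_interface)
  expect_equal(t2$torsion_quadruples, ring$topology$torsion_quadruples)
  expect_equal(t2$domains$start, ring$topology$domains$start)
})

test_that("shipped crystal topologies parse and are structurally sound", {
  for (nm in c("1ok7", "1plq", "1b77")) {
    topo <- default_topology(nm)
    expect_length(topo$ring_order, 6L)
    expect_length(topo$torsion_quadruples, 3L)
  }
  mono <- default_topology("1jql")
  expect_length(mono$ring_order, 3L)
  expect_null(mono$open_interface)
})

test_that("domain assignment partitions the ring atoms", {
  ring <- build_ideal_ring(atoms_per_domain = 15L)
  asg <- assign_domains(ring$structure, ring$topology)
  expect_length(asg, 6L)
  sizes <- lengths(asg)
  expect_true(all(sizes == 15L))
  all_idx <- unlist(asg)
  expect_equal(anyDuplicated(all_idx), 0L)            # disjoint
  expect_setequal(all_idx, seq_len(nrow(ring$structure$xyz)))  # coverage
})

test_that("assignment fails loudly for an absent chain", {
  ring <- build_ideal_ring()
  topo <- ring$topology
  topo$domains$chain[1] <- "Z"
  expect_error(assign_domains(ring$structure, topo), "A1")
})

test_that("centre of mass is the mass-weighted mean", {
  atoms <- data.frame(chain = "A", resno = 1:2, insert = "", resid = "GLY",
                      elety = "CA", elesy = c("C", "O"), mass = c(12, 16))
  s <- clamp_structure(atoms, rbind(c(0, 0, 0), c(7, 0, 0)))
  asg <- structure(list(D = 1:2), class = "domain_assignment")
  expect_equal(domain_com(s, asg, "D"), c(4, 0, 0))  # 16*7/28
  # single atom and symmetric pair
  asg1 <- structure(list(D = 1L), class = "domain_assignment")
  s1 <- clamp_structure(atoms[1, ], rbind(c(1, 2, 3)))
  expect_equal(domain_com(s1, asg1, "D"), c(1, 2, 3))
  atoms$mass <- c(10, 10)
  s2 <- clamp_structure(atoms, rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(domain_com(s2, asg, "D"), c(1, 0, 0))
})

test_that("COM is equivariant under rigid motion", {
  ring <- build_ideal_ring(seed = 9)
  asg <- assign_domains(ring$structure, ring$topology)
  set.seed(1)
  for (rep in 1:5) {
    R <- random_rotation()
    t <- rnorm(3, sd = 10)
    xr <- ring$structure$xyz %*% t(R) +
      matrix(t, nrow(ring$structure$xyz), 3, byrow = TRUE)
    for (d in c("A1", "B2")) {
      c0 <- domain_com(ring$structure, asg, d)
      c1 <- domain_com(xr, asg, d, atoms = ring$structure$atoms)
      expect_lt(max(abs(c1 - (as.numeric(R %*% c0) + t))), 1e-9)
    }
  }
})

test_that("hydrogens are excluded from the default COM", {
  atoms <- data.frame(chain = "A", resno = 1:3, insert = "", resid = "GLY",
                      elety = c("CA", "CB", "H"), elesy = c("C", "C", "H"),
                      mass = c(12, 12, 1))
  s <- clamp_structure(atoms, rbind(c(0, 0, 0), c(2, 0, 0), c(100, 0, 0)))
  asg <- structure(list(D = 1:3), class = "domain_assignment")
  expect_equal(domain_com(s, asg, "D"), c(1, 0, 0))
})
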
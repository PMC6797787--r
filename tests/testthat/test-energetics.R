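test_that("gas-phase terms reproduce definitions and the scalar oracle", {
  ## single bond at its equilibrium length: zero energy
  ff_b <- toy_forcefield(2, bonds = data.frame(i = 1, j = 2, k = 100,
                                               r_eq = 3.8))
  led <- gas_phase_energy(rbind(c(0, 0, 0), c(3.8, 0, 0)), ff_b)
  expect_equal(led$total, 0)
  ## two unit charges 1 A apart: the Coulomb scale constant itself
  ff_c <- toy_forcefield(2, atoms = data.frame(charge = c(1, 1)))
  led_c <- gas_phase_energy(rbind(c(0, 0, 0), c(1, 0, 0)), ff_c)
  expect_equal(led_c$total, 332.0637)
  ## 5-atom mixed fixture vs term-by-term scalar evaluation
  set.seed(31)
  coords <- matrix(runif(15, 0, 8), 5, 3)
  ff <- toy_forcefield(5,
    bonds = data.frame(i = c(1, 2), j = c(2, 3), k = c(50, 80),
                       r_eq = c(3.8, 3.5)),
    atoms = data.frame(charge = c(0.3, -0.2, 0, 0.5, -0.1),
                       eps = c(0.1, 0, 0.2, 0.15, 0.05),
                       sigma = c(3.5, 4, 4.2, 3.8, 4)),
    go = data.frame(i = 1, j = 5, eps = 1.2, r0 = 5))
  led5 <- gas_phase_energy(coords, ff)
  expect_equal(led5$total, oracle_gas_energy(coords, ff), tolerance = 1e-12)
  ## ledger conservation: itemized terms sum to the total
  expect_equal(sum(led5$terms$value), led5$total,
               tolerance = 1e-10 * max(1, abs(led5$total)))
  expect_error(gas_phase_energy(matrix(0, 3, 3), ff), "parameterization")
})

test_that("surrogate solvation is residue-decomposable and tagged", {
  ch <- generate_toy_chain(6, "helix")
  ## all charges zero and gamma = 0: exactly zero
  s0 <- solvation_energy(ch$frame, ch$topology, ch$ff, gamma = 0)
  expect_equal(s0$total, 0)
  expect_identical(s0$backend, "surrogate")
  ## charged 3-residue fixture: per-residue sums equal the total
  top <- make_bead_topology(3)
  ff <- toy_forcefield(3, atoms = data.frame(charge = c(0.5, -0.5, 0.3),
                                             radius = c(2, 2.2, 1.8)))
  coords <- rbind(c(0, 0, 0), c(4, 0, 0), c(0, 5, 0))
  s <- solvation_energy(coords, top, ff)
  expect_equal(sum(s$per_residue), s$total,
               tolerance = 1e-10 * max(1, abs(s$total)))
  ## scalar re-evaluation of the screened-pair + self terms (gamma = 0)
  sg0 <- solvation_energy(coords, top, ff, gamma = 0)
  C <- 332.0637; tau <- 1 - 1 / 78.5
  q <- ff$atoms$charge; R <- ff$atoms$radius
  e <- -0.5 * C * tau * sum(q^2 / R)
  for (i in 1:2) for (j in (i + 1):3) {
    r <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    fgb <- sqrt(r^2 + R[i] * R[j] * exp(-r^2 / (4 * R[i] * R[j])))
    e <- e - C * tau * q[i] * q[j] / fgb
  }
  expect_equal(sg0$total, e, tolerance = 1e-12)
})

test_that("table backend looks up per-frame solvation records", {
  tab <- data.frame(frame = 0:1, E_u = c(0, 0), G_solv = c(-100, -90))
  s <- solvation_energy(backend = "table", table = tab, frame_index = 0)
  expect_equal(s$total, -100)
  expect_identical(s$backend, "table")
  expect_error(solvation_energy(backend = "table", table = tab,
                                frame_index = 7), "missing-energy")
})

test_that("effective energy composes E_u and G_solv", {
  tab <- data.frame(frame = 0, E_u = 0, G_solv = -25)
  ff_b <- toy_forcefield(2, bonds = data.frame(i = 1, j = 2, k = 100,
                                               r_eq = 3.8))
  top <- make_bead_topology(2)
  coords <- rbind(c(0, 0, 0), c(4.8, 0, 0))  # stretched: E_u = 0.5*100*1
  f <- effective_energy(coords, top, ff_b, backend = "table", table = tab,
                        frame_index = 0)
  expect_equal(f, 50 - 25)
  ## surrogate route equals the sum of the two parts called independently
  fx <- generate_complex_fixture(seed = 2, n_frames = 1)
  x <- frame_coords(fx$ensemble, 1)
  expect_equal(effective_energy(x, fx$ensemble$topology, fx$ff),
               gas_phase_energy(x, fx$ff)$total +
                 solvation_energy(x, fx$ensemble$topology, fx$ff)$total)
})

test_that("binding potential follows its defining arithmetic", {
  ## non-interacting limit: two far-apart neutral chains
  top <- ffl_topology(data.frame(name = "CA", element = "C",
                                 chain = c("A", "B"), resno = c(1, 1),
                                 resname = "GLY"))
  part <- complex_partition("A", "B")
  ff0 <- toy_forcefield(2)
  far <- rbind(c(0, 0, 0), c(100, 0, 0))
  bp0 <- binding_potential(far, top, part, ff0)
  expect_equal(bp0$dfint, 0, tolerance = 1e-12)
  ## arithmetic of the definition via the table backend
  ffq <- toy_forcefield(2, atoms = data.frame(charge = c(1, -1)))
  r <- 332.0637 / 20   # distance at which direct Coulomb = -20 kcal/mol
  tab <- data.frame(frame = 0, E_u = 0, G_solv = NA, G_solv_AB = -300,
                    G_solv_A = -180, G_solv_B = -115)
  bp <- binding_potential(rbind(c(0, 0, 0), c(r, 0, 0)), top, part, ffq,
                          backend = "table", table = tab, frame_index = 0)
  expect_equal(bp$dE_int, -20)
  expect_equal(bp$dG_solv, -5)
  expect_equal(bp$dfint, -25)
})

test_that("direct interaction equals the brute-force cross-pair oracle", {
  fx <- generate_complex_fixture(seed = 13, n_frames = 3)
  in_a <- fx$ensemble$topology$atoms$chain %in% fx$partition$A
  for (k in 1:3) {
    x <- frame_coords(fx$ensemble, k)
    bp <- binding_potential(x, fx$ensemble$topology, fx$partition, fx$ff)
    expect_equal(bp$dE_int, oracle_cross_energy(x, fx$ff, in_a),
                 tolerance = 1e-10)
  }
})

test_that("binding potential is partner-symmetric and rigid-motion invariant", {
  fx <- generate_complex_fixture(seed = 17, n_frames = 1)
  x <- frame_coords(fx$ensemble, 1)
  top <- fx$ensemble$topology
  bp_ab <- binding_potential(x, top, fx$partition, fx$ff)
  swapped <- complex_partition(fx$partition$B, fx$partition$A)
  bp_ba <- binding_potential(x, top, swapped, fx$ff)
  expect_equal(bp_ab$dfint, bp_ba$dfint, tolerance = 1e-12)
  expect_equal(bp_ab$dE_int, bp_ba$dE_int, tolerance = 1e-12)
  moved <- random_rigid(x, seed = 9)
  bp_m <- binding_potential(moved, top, fx$partition, fx$ff)
  expect_equal(bp_m$dfint, bp_ab$dfint, tolerance = 1e-8)
  ## gas-phase energy is likewise invariant
  expect_equal(gas_phase_energy(moved, fx$ff)$total,
               gas_phase_energy(x, fx$ff)$total, tolerance = 1e-8)
})

test_that("the binding potential of an apolar complex vanishes at 100 A", {
  fx <- generate_complex_fixture(seed = 23, n_frames = 1, charge = 0)
  top <- fx$ensemble$topology
  x <- frame_coords(fx$ensemble, 1)
  nb <- sum(top$atoms$chain %in% fx$partition$B)
  x[top$atoms$chain %in% fx$partition$B, 1] <-
    x[top$atoms$chain %in% fx$partition$B, 1] + 100
  bp <- binding_potential(x, top, fx$partition, fx$ff)
  expect_lt(abs(bp$dfint), 1e-6)
  ## with charges, the screened tail decays but does not vanish
  fxq <- generate_complex_fixture(seed = 23, n_frames = 1, charge = 0.3)
  xq0 <- frame_coords(fxq$ensemble, 1)
  bq0 <- binding_potential(xq0, fxq$ensemble$topology, fxq$partition, fxq$ff)
  xq <- xq0
  sel <- fxq$ensemble$topology$atoms$chain %in% fxq$partition$B
  xq[sel, 1] <- xq[sel, 1] + 100
  bq <- binding_potential(xq, fxq$ensemble$topology, fxq$partition, fxq$ff)
  expect_lt(abs(bq$dfint), abs(bq0$dfint) / 10)
})

test_that("bound effective energy adds the binding potential to the partner", {
  fx <- generate_complex_fixture(seed = 5, n_frames = 1)
  top <- fx$ensemble$topology
  x <- frame_coords(fx$ensemble, 1)
  pa <- which(top$atoms$chain %in% fx$partition$A)
  f_a <- effective_energy(x[pa, ], subset_forcefield(fx$ff, pa)$n_atoms |>
                            make_bead_topology(),
                          subset_forcefield(fx$ff, pa))
  bp <- binding_potential(x, top, fx$partition, fx$ff)
  f_bound <- bound_effective_energy(x, top, fx$partition, fx$ff)
  expect_equal(f_bound, f_a + bp$dfint, tolerance = 1e-10)
  ## table-mode arithmetic: dfint = -25, f_partner = -15 -> -40
  top2 <- ffl_topology(data.frame(name = "CA", element = "C",
                                  chain = c("A", "B"), resno = c(1, 1),
                                  resname = "GLY"))
  part <- complex_partition("A", "B")
  ffq <- toy_forcefield(2, atoms = data.frame(charge = c(1, -1)))
  r <- 332.0637 / 20
  tab <- data.frame(frame = 0, E_u = 0, G_solv = NA, G_solv_AB = -300,
                    G_solv_A = -15, G_solv_B = -280)
  f2 <- bound_effective_energy(rbind(c(0, 0, 0), c(r, 0, 0)), top2, part,
                               ffq, backend = "table", table = tab,
                               frame_index = 0)
  ## dG_solv = -300 + 15 + 280 = -5; dfint = -25; f_A = 0 + (-15)
  expect_equal(f2, -40)
})
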
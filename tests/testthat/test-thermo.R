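test_that("ensemble averages and block errors behave", {
  expect_equal(ensemble_average_f(c(-10, -20))$mean, -15)
  expect_equal(ensemble_average_f(rep(4.2, 50))$se, 0)
  gs <- withr::with_seed(3, rnorm(1e4, -31.7, 2))
  est <- ensemble_average_f(gs)
  expect_lt(abs(est$mean - (-31.7)), 3 * est$se)
  expect_error(ensemble_average_f(numeric(0)), "missing-energy")
})

test_that("quasi-harmonic entropy matches the closed form on a 1D oscillator", {
  ## one atom fluctuating along x only: a single genuine mode
  kq <- 2; temperature <- 300
  s2 <- kB * temperature / kq
  x <- withr::with_seed(5, rnorm(5000, 0, sqrt(s2)))
  xyz <- cbind(x, 0, 0)
  est <- config_entropy(xyz, temperature = temperature, superpose = FALSE)
  expect_equal(est$n_modes, 1)
  ## closed-form Gaussian entropy at the sample variance
  closed <- temperature * 0.5 * kB * log(2 * pi * exp(1) * var(x))
  expect_lt(abs(est$TS - closed), 1e-6)
  expect_identical(est$method, "quasi-harmonic")
})

test_that("entropy rises with temperature and frozen ensembles error", {
  draw <- function(temperature) {
    s2 <- kB * temperature / 2
    x <- withr::with_seed(8, matrix(rnorm(3000, 0, sqrt(s2)), ncol = 3))
    config_entropy(x, temperature = temperature, superpose = FALSE)$TS
  }
  expect_gt(draw(600), draw(300))
  frozen <- matrix(1.5, nrow = 10, ncol = 3)
  expect_error(config_entropy(frozen, temperature = 300, superpose = FALSE),
               "degenerate-ensemble")
  expect_error(config_entropy(frozen[1, , drop = FALSE], temperature = 300),
               "at least two frames")
})

test_that("closure: <f> - T S_config matches -kB T ln Z for a Gaussian toy", {
  kq <- 2; temperature <- 300
  s2 <- kB * temperature / kq
  n <- 2e5
  x <- withr::with_seed(13, matrix(rnorm(3 * n, 0, sqrt(s2)), ncol = 3))
  f <- 0.5 * kq * rowSums(x^2)
  est <- config_entropy(x, temperature = temperature, superpose = FALSE)
  lhs <- mean(f) - est$TS
  rhs <- -kB * temperature * (3 / 2) * log(2 * pi * s2)  # -kB T ln Z, 3 dof
  expect_lt(abs(lhs - rhs), 1e-2)
})

test_that("external entropy matches its closed-form Gaussian-volume oracle", {
  temperature <- 300
  v <- external_entropy_gaussian(c(1, 1, 1), c(0.1, 0.1, 0.1), temperature)
  ## independent scalar evaluation of the same closed form
  v_t <- (2 * pi * exp(1))^1.5 * 1 * 1 * 1
  v_r <- (2 * pi * exp(1))^1.5 * 0.1^3
  oracle <- 0.0019872041 * temperature *
    (log(v_t / 1660.5391) + log(v_r / (8 * pi^2)))
  expect_equal(v, oracle, tolerance = 1e-12)
  ## doubling all widths makes the loss less negative
  v2 <- external_entropy_gaussian(c(2, 2, 2), c(0.2, 0.2, 0.2), temperature)
  expect_gt(v2, v)
  ## floor guard on (near-)rigid complexes
  expect_error(external_entropy_gaussian(c(1e-5, 1, 1), NULL, 300),
               "floor")
})

test_that("external entropy is estimated from bound-ensemble fluctuations", {
  ## single-bead partners: translation-only, known sd
  top <- ffl_topology(data.frame(name = "CA", element = "C",
                                 chain = c("A", "B"), resno = c(1, 1),
                                 resname = "GLY"))
  part <- complex_partition("A", "B")
  sd_true <- 0.8
  rel <- withr::with_seed(17, matrix(rnorm(3 * 4000, 0, sd_true), ncol = 3))
  frames <- lapply(seq_len(4000), function(k) rbind(c(0, 0, 0),
                                                    c(10, 0, 0) + rel[k, ]))
  ens <- ffl_ensemble(top, frames, temperature = 300)
  ext <- external_entropy(ens, part)
  expect_null(ext$sd_rot)
  expect_equal(mean(ext$sd_trans), sd_true, tolerance = 0.05)
  expect_equal(ext$TdS_ext,
               external_entropy_gaussian(ext$sd_trans, NULL, 300),
               tolerance = 1e-12)
  expect_error(external_entropy(ffl_ensemble(top, frames[1:5]), part),
               "sampling error")
})

test_that("the standard binding free energy assembles its components", {
  bfe <- assemble_binding_free_energy(d_mean_f = -30, TdS_config = -10,
                                      TdS_ext = -5, temperature = 300)
  expect_equal(bfe$dG0_bind, -15)
  ## antisymmetry under exchanging complex and reference roles
  bfe_swap <- assemble_binding_free_energy(30, 10, 5, temperature = 300)
  expect_equal(bfe_swap$dG0_bind, -bfe$dG0_bind)
})

test_that("a harmonic two-bead dimer reproduces the analytic dG0", {
  kspr <- 1; temperature <- 300
  s2 <- kB * temperature / kspr
  top2 <- ffl_topology(data.frame(name = "CA", element = "C",
                                  chain = c("A", "B"), resno = c(1, 1),
                                  resname = "GLY"))
  top1 <- make_bead_topology(1)
  part <- complex_partition("A", "B")
  nb <- 4000
  rel <- withr::with_seed(23, matrix(rnorm(3 * nb, 0, sqrt(s2)), ncol = 3))
  frames <- lapply(seq_len(nb), function(k) rbind(c(0, 0, 0), rel[k, ]))
  cpx <- ffl_ensemble(top2, frames, temperature = temperature)
  cpx <- attach_energy(cpx, data.frame(frame = cpx$frame_index,
                                       E_u = 0.5 * kspr * rowSums(rel^2),
                                       G_solv = 0))
  free1 <- function() {
    e <- ffl_ensemble(top1, replicate(20, matrix(0, 1, 3), simplify = FALSE),
                      temperature = temperature)
    attach_energy(e, data.frame(frame = e$frame_index, E_u = 0, G_solv = 0))
  }
  bfe <- standard_binding_free_energy(cpx, free1(), free1(), part)
  exact <- -kB * temperature * log((2 * pi * s2)^1.5 / 1660.5391)
  expect_lt(abs(bfe$dG0_bind - exact), 0.2)
  ## single-bead partners carry no internal entropy
  expect_equal(bfe$TdS_config, 0)
  ## with zero d<f> and dS_config, dG0 = -T dS_ext
  expect_equal(bfe$dG0_bind, bfe$d_mean_f - bfe$TdS_ext, tolerance = 1e-12)
})

test_that("temperature mismatches across ensembles are rejected", {
  top1 <- make_bead_topology(1)
  mk <- function(temperature) {
    e <- ffl_ensemble(top1, replicate(12, matrix(rnorm(3), 1, 3),
                                      simplify = FALSE),
                      temperature = temperature)
    attach_energy(e, data.frame(frame = e$frame_index, E_u = 0, G_solv = 0))
  }
  top2 <- ffl_topology(data.frame(name = "CA", element = "C",
                                  chain = c("A", "B"), resno = c(1, 1),
                                  resname = "GLY"))
  cpx <- ffl_ensemble(top2, replicate(12, rbind(c(0, 0, 0), rnorm(3) + 5),
                                      simplify = FALSE), temperature = 300)
  cpx <- attach_energy(cpx, data.frame(frame = cpx$frame_index, E_u = 0,
                                       G_solv = 0))
  expect_error(standard_binding_free_energy(cpx, mk(300), mk(310),
                                            complex_partition("A", "B")),
               "consistency error")
})

test_that("error propagation enlarges the entropy-difference uncertainty", {
  ## four nearly cancelling entropy terms: the quadrature SE of the
  ## difference exceeds every individual SE
  ses <- c(0.11, 0.12, 0.1, 0.09)
  prop <- sqrt(sum(ses^2))
  expect_true(all(prop > ses))
  ## and the assembled object reports it
  bfe <- assemble_binding_free_energy(-30, -10, -5, temperature = 300,
                                      d_mean_f_se = 0.5, TdS_config_se = prop)
  expect_equal(bfe$dG0_bind_se, sqrt(0.5^2 + prop^2))
})
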
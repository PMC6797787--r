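test_that("landscape binning references, averages, and reports SEs", {
  ## constant f: every occupied bin is zero after referencing
  sam <- data.frame(Q = runif(200), f = 7.5)
  lb <- bin_landscape(sam)$bins
  expect_true(all(abs(lb$f_ref[lb$n > 0]) < 1e-12))
  ## two samples in one bin: mean and two-point SE
  ls2 <- suppressWarnings(bin_landscape(data.frame(Q = c(0.05, 0.05),
                                                   f = c(1, 3)),
                                        bin_width = 0.1))
  occ <- ls2$bins[ls2$bins$n > 0, ]
  expect_equal(nrow(occ), 1)
  expect_equal(occ$f_mean, 2)
  expect_equal(occ$f_se, 1)
  ## half-open bins, Q = 1 lands in the closed last bin
  lsq <- bin_landscape(data.frame(Q = c(0.05, 1.0), f = c(0, 0)),
                       bin_width = 0.05)
  expect_equal(sum(lsq$bins$n), 2)
  expect_equal(lsq$bins$n[20], 1)
  expect_warning(bin_landscape(data.frame(Q = 0.5, f = 1)), "single-bin")
})

test_that("bin means match an independent group-by oracle at n = 1e4", {
  set.seed(11)
  sam <- data.frame(Q = runif(1e4), f = rnorm(1e4, -20, 5))
  lb <- bin_landscape(sam)$bins
  oracle <- oracle_bin_means(sam$Q, sam$f, 0.05)
  expect_equal(unname(lb$f_mean[lb$n > 0]), unname(oracle),
               tolerance = 1e-12)
  ## conservation: count-weighted mean of bin means equals the grand mean
  occ <- lb$n > 0
  expect_equal(sum(lb$f_mean[occ] * lb$n[occ]) / sum(lb$n), mean(sam$f),
               tolerance = 1e-12)
})

test_that("F(Q) follows -kB T ln P with its conventions", {
  ## uniform counts over 10 bins: flat profile at zero
  q <- rep(seq(0.05, 0.95, by = 0.1), each = 10)
  pr <- free_energy_profile(q, bin_width = 0.1, temperature = 300)
  expect_true(all(abs(pr$bins$F[pr$bins$n > 0]) < 1e-12))
  expect_equal(sum(pr$bins$P), 1)
  ## 75:25 over two bins at 300 K: dF = -kB*300*ln(25/75)
  q2 <- c(rep(0.1, 75), rep(0.9, 25))
  pr2 <- free_energy_profile(q2, bin_width = 0.2, temperature = 300)
  occF <- pr2$bins$F[pr2$bins$n > 0]
  expect_equal(diff(occF), 0.0019872041 * 300 * log(3), tolerance = 1e-10)
  expect_equal(round(diff(occF), 3), 0.655)
  ## duplication invariance of F
  pr2d <- free_energy_profile(rep(q2, 2), bin_width = 0.2, temperature = 300)
  expect_equal(pr2d$bins$F, pr2$bins$F)
  ## single-bin input: zero there, undefined elsewhere
  pr1 <- free_energy_profile(rep(0.3, 5))
  expect_equal(pr1$bins$F[pr1$bins$n > 0], 0)
  expect_true(all(is.na(pr1$bins$F[pr1$bins$n == 0])))
})

test_that("entropy profile is the referenced difference f(Q) - F(Q)", {
  ## f = F everywhere -> TS identically zero
  q <- c(rep(0.1, 30), rep(0.9, 10))
  pr <- free_energy_profile(q, bin_width = 0.2, temperature = 300)
  fvals <- pr$bins$F[match(round(q, 1), round(pr$bins$q_mid, 1))]
  ls <- bin_landscape(data.frame(Q = q, f = fvals), bin_width = 0.2,
                      temperature = 300)
  ts <- config_entropy_profile(ls, pr)
  expect_true(all(abs(ts$TS_config) < 1e-9))
  ## worked two-bin subtraction: f = (-10, -20), F = (0, 1) -> second = -11
  ls2 <- bin_landscape(data.frame(Q = c(rep(0.1, 3), rep(0.9, 1)),
                                  f = c(rep(-10, 3), -20)),
                       bin_width = 0.2, temperature = 300)
  q75 <- c(rep(0.1, 3), 0.9)
  pr2 <- free_energy_profile(q75, bin_width = 0.2, temperature = 300)
  ## overwrite F to the worked values via a profile with matching counts
  pr2$bins$F[pr2$bins$n > 0] <- c(0, 1)
  ts2 <- config_entropy_profile(ls2, pr2)
  expect_equal(ts2$TS_config, c(0, -11))
})

test_that("entropy profile recovers an analytic two-state construction", {
  ## two states: unfolded (70%, f ~ 0) and folded (30%, f ~ -10)
  set.seed(41)
  n_u <- 7000; n_f <- 3000; temperature <- 300
  q <- c(runif(n_u, 0.10, 0.15), runif(n_f, 0.85, 0.90))
  f <- c(rnorm(n_u, 0, 0.5), rnorm(n_f, -10, 0.5))
  ls <- bin_landscape(data.frame(Q = q, f = f), temperature = temperature)
  pr <- free_energy_profile(q, temperature = temperature)
  ts <- config_entropy_profile(ls, pr)
  ## analytic: dTS = df - dF with df = -10, dF = -kB T ln(n_f/n_u)
  expected <- -10 - (-0.0019872041 * temperature * log(n_f / n_u))
  expect_equal(ts$TS_config[nrow(ts)] - ts$TS_config[1], expected,
               tolerance = 0.05)
})

test_that("slope fitting recovers exact lines and known slopes", {
  ## exact line sampled densely: slope recovered, SE zero
  q <- rep(seq(0.005, 0.995, by = 0.005), times = 50)
  sam <- data.frame(frame = seq_along(q) - 1, Q = q, f = 5 - 50 * q)
  fit <- fit_slope(sam)
  expect_equal(fit$slope, -50, tolerance = 1e-9)
  expect_equal(fit$slope_se, 0, tolerance = 1e-9)
  ## constant f: zero slope
  expect_equal(fit_slope(data.frame(Q = q, f = 2))$slope, 0,
               tolerance = 1e-12)
  ## noisy parameter recovery within 3 reported SE
  sam2 <- generate_slope_samples(-48.2, 3, 50000, seed = 7)
  fit2 <- fit_slope(sam2)
  expect_lt(abs(fit2$slope - (-48.2)), 3 * fit2$slope_se)
  ## slope value (not its block SE) is frame-order invariant
  perm <- withr::with_seed(3, sample(nrow(sam2)))
  fit_perm <- fit_slope(sam2[perm, ])
  expect_equal(fit_perm$slope, fit2$slope, tolerance = 1e-9)
  ## degenerate blocks are reported, not silently fitted
  tiny <- data.frame(Q = c(0.1, 0.9, 0.1, 0.9), f = c(0, -5, 0, -5))
  suppressWarnings(
    expect_error(fit_slope(rbind(tiny, data.frame(Q = 0.1, f = 0)),
                           n_blocks = 5), "block-degenerate"))
})

test_that("block SE on iid data is consistent with the analytic LS error", {
  sam <- generate_slope_samples(-30, 3, 40000, seed = 19)
  fit <- fit_slope(sam)
  ## analytic SE of the unweighted fit through 20 bin means
  lb <- bin_landscape(sam)$bins
  occ <- lb$n > 0
  sig <- 3 / sqrt(lb$n[occ])
  X <- cbind(1, lb$q_mid[occ])
  cov_beta <- solve(crossprod(X)) %*% t(X) %*% diag(sig^2) %*% X %*%
    solve(crossprod(X))
  se_analytic <- sqrt(cov_beta[2, 2])
  expect_gt(fit$slope_se, se_analytic / 2)
  expect_lt(fit$slope_se, se_analytic * 2)
})

test_that("free-energy gain converts slopes to per-contact-fraction gains", {
  fit <- list(slope = -48.2)
  expect_equal(round(free_energy_gain(fit, 0.1), 1), 4.8)
  expect_equal(free_energy_gain(list(slope = 0), 0.5), 0)
  expect_equal(free_energy_gain(list(slope = -24.4), 0.5), 12.2)
  expect_error(free_energy_gain(fit, 0), "delta_q")
  expect_error(free_energy_gain(fit, 1.5), "delta_q")
})

test_that("funnel surface revolves the referenced landscape", {
  ## linear landscape -> cone with apex at Q = 1
  q <- rep(seq(0.025, 0.975, by = 0.05), times = 20)
  ls <- bin_landscape(data.frame(Q = q, f = -50 * q))
  mesh <- funnel_surface(ls, azimuthal_resolution = 12)
  ring_r <- as.numeric(tapply(sqrt(mesh$x^2 + mesh$y^2), mesh$q_mid, mean))
  expect_equal(ring_r, 1 - sort(unique(mesh$q_mid)), tolerance = 1e-9)
  ## ring heights equal the referenced landscape values
  occ <- ls$bins[ls$bins$n > 0, ]
  ring_z <- as.numeric(unlist(tapply(mesh$z, mesh$q_mid, unique)))
  expect_equal(ring_z, occ$f_ref, tolerance = 1e-12)
  ## constant landscape -> flat disk at z = 0
  ls0 <- bin_landscape(data.frame(Q = q, f = 3))
  mesh0 <- funnel_surface(ls0)
  expect_true(all(abs(mesh0$z) < 1e-12))
})

test_that("funnel_fit objects expose the standard modelling methods", {
  sam <- generate_slope_samples(-40, 2, 8000, seed = 12, intercept = 4)
  fit <- funnel_fit(f ~ Q, sam)
  co <- coef(fit)
  expect_named(co, c("intercept", "slope"))
  expect_lt(abs(co[["slope"]] - (-40)), 3 * fit$slope$slope_se)
  expect_equal(predict(fit, data.frame(Q = c(0, 1))),
               c(co[["intercept"]], co[["intercept"]] + co[["slope"]]))
  expect_equal(length(residuals(fit)), nrow(sam))
  expect_lt(abs(mean(residuals(fit))), 0.1)
  sims <- simulate(fit, nsim = 2, seed = 99)
  expect_length(sims, 2)
  expect_identical(names(sims[[1]]), c("frame", "Q", "f"))
  refit <- funnel_fit(f ~ Q, sims[[1]])
  expect_lt(abs(coef(refit)[["slope"]] - co[["slope"]]), 1)
  expect_output(print(fit), "slope")
  expect_output(print(summary(fit)), "gain per 10%")
  pdf(NULL); on.exit(dev.off())
  expect_no_error(suppressWarnings(plot(fit)))
})
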
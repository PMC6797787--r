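#' Ensemble average of the effective energy
#'
#' Arithmetic mean of the per-frame effective energies with a
#' block-analysis standard error (contiguous equal blocks in frame order).
#'
#' @param x an [ffl_ensemble()] with energies attached, or a numeric
#'   vector of per-frame f values.
#' @param n_blocks number of blocks for the error estimate.
#' @return list with `mean`, `se`, `n_frames`.
#' @export
ensemble_average_f <- function(x, n_blocks = 5L) {
  f <- if (inherits(x, "ffl_ensemble")) ensemble_f(x) else as.numeric(x)
  if (!length(f)) stop("missing-energy error: no f values")
  list(mean = mean(f), se = block_se(f, n_blocks), n_frames = length(f))
}

#' Quasi-harmonic configurational entropy
#'
#' Estimates `T S_config` from the covariance of the (optionally
#' least-squares superposed) Cartesian coordinates, treating the sampled
#' distribution as Gaussian:
#' `S = (kB / 2) * sum_m ln(2 pi e lambda_m)` over the covariance
#' eigenvalues `lambda_m` above `mode_tol` (superposition leaves the six
#' rigid-body modes near zero; they are dropped automatically).  This is
#' the classical quasi-harmonic estimator on unit-mass Cartesian
#' coordinates, consistent with the configurational partition function
#' `Z = integral dr exp(-f(r)/kB T)` in Angstrom units, so that
#' `<f> - T S_config` estimates `-kB T ln Z`.
#'
#' @param x an [ffl_ensemble()], or an n_frames x 3N coordinate matrix.
#' @param temperature temperature in K (taken from the ensemble when
#'   omitted).
#' @param superpose remove rigid-body motion by least-squares fitting all
#'   frames to their mean structure first (default TRUE; disable for
#'   fixtures whose coordinates are already internal).
#' @param mode_tol eigenvalue floor (A^2): modes below it are treated as
#'   rigid-body/degenerate and dropped.
#' @param n_blocks blocks for the standard error (NA when blocks are too
#'   short for a full-rank covariance).
#' @return `ffl_entropy`: list with `TS` (kcal/mol), `S` (kcal/mol/K),
#'   `se` (on `TS`), `method = "quasi-harmonic"`, `n_frames`, `n_modes`.
#' @export
config_entropy <- function(x, temperature = NULL, superpose = TRUE,
                           mode_tol = 1e-8, n_blocks = 5L) {
  if (inherits(x, "ffl_ensemble")) {
    temperature <- temperature %||% x$temperature
    xyz <- x$xyz
  } else {
    xyz <- as.matrix(x)
    if (is.null(temperature)) stop("temperature required for raw coordinates")
  }
  nf <- nrow(xyz)
  if (nf < 2L) stop("degenerate-ensemble error: need at least two frames")
  if (superpose && ncol(xyz) >= 9L) xyz <- superpose_frames(xyz)
  ts_of <- function(m) {
    ev <- eigen(stats::cov(m), symmetric = TRUE, only.values = TRUE)$values
    keep <- ev > mode_tol
    if (!any(keep)) return(NULL)
    list(S = 0.5 * kB * sum(log(2 * pi * exp(1) * ev[keep])),
         n_modes = sum(keep))
  }
  full <- ts_of(xyz)
  if (is.null(full))
    stop("degenerate-ensemble error: no coordinate mode above mode_tol; ",
         "the ensemble is (nearly) frozen -- sample more frames")
  TS <- temperature * full$S
  se <- NA_real_
  if (n_blocks >= 2L && nf >= 2L * n_blocks) {
    bts <- vapply(block_indices(nf, n_blocks), function(idx) {
      b <- ts_of(xyz[idx, , drop = FALSE])
      if (is.null(b) || b$n_modes != full$n_modes) return(NA_real_)
      temperature * b$S
    }, numeric(1))
    if (!anyNA(bts)) se <- stats::sd(bts) / sqrt(n_blocks)
  }
  structure(list(TS = TS, S = full$S, se = se, method = "quasi-harmonic",
                 temperature = temperature, n_frames = nf,
                 n_modes = full$n_modes),
            class = "ffl_entropy")
}

#' @export
print.ffl_entropy <- function(x, ...) {
  cat(sprintf("T S_config = %.4f kcal/mol (%s, %d modes, %d frames)\n",
              x$TS, x$method, x$n_modes, x$n_frames))
  invisible(x)
}

## Two-pass least-squares superposition onto the mean structure
## (bio3d Kabsch fit on all atoms).
superpose_frames <- function(xyz) {
  inds <- seq_len(ncol(xyz))
  fitted <- bio3d::fit.xyz(fixed = xyz[1L, ], mobile = xyz,
                           fixed.inds = inds, mobile.inds = inds)
  bio3d::fit.xyz(fixed = colMeans(fitted), mobile = fitted,
                 fixed.inds = inds, mobile.inds = inds)
}

#' External (translational + rotational) entropy of binding, closed form
#'
#' Gaussian-fluctuation-volume estimate referenced to the 1 M standard
#' state: the bound complex restricts the partners' relative translation
#' to an effective volume `V_t = (2 pi e)^{3/2} sd_x sd_y sd_z` (vs the
#' standard-state volume 1660.5 A^3) and, for partners with orientational
#' degrees of freedom, the relative orientation to
#' `V_r = (2 pi e)^{3/2} sd_a sd_b sd_c` (vs the full 8 pi^2):
#' `T dS_ext = kB T [ln(V_t / V0) + ln(V_r / 8 pi^2)]`.
#'
#' @param sd_trans length-3 standard deviations of the relative
#'   center-of-mass displacement along its principal axes, A.
#' @param sd_rot length-3 standard deviations of the relative-orientation
#'   rotation vector, radians; NULL for partners without orientational
#'   degrees of freedom (single-bead partners).
#' @param temperature temperature, K.
#' @param standard_volume standard-state volume per molecule, A^3.
#' @return `T dS_ext` in kcal/mol (negative: binding loses entropy).
#' @export
external_entropy_gaussian <- function(sd_trans, sd_rot = NULL,
                                      temperature = 300,
                                      standard_volume = STANDARD_VOLUME) {
  if (any(c(sd_trans, sd_rot) < 1e-3))
    stop("degenerate fluctuation: a standard deviation is below the 1e-3 ",
         "floor; the Gaussian-volume estimate would diverge")
  lt <- sum(0.5 * log(2 * pi * exp(1) * sd_trans^2)) - log(standard_volume)
  lr <- if (!is.null(sd_rot))
    sum(0.5 * log(2 * pi * exp(1) * sd_rot^2)) - log(8 * pi^2)
  else 0
  kB * temperature * (lt + lr)
}

#' External entropy from a bound-complex ensemble
#'
#' Measures the relative center-of-mass fluctuations (principal-axis
#' standard deviations of `COM_B - COM_A`, after superposing every frame
#' on partner A) and, when both partners have >= 3 atoms, the
#' relative-orientation fluctuations of partner B (rotation vector of the
#' Kabsch rotation onto its mean structure), then applies
#' [external_entropy_gaussian()].
#'
#' @param ensemble complex [ffl_ensemble()] (>= 10 frames).
#' @param partition an [complex_partition()].
#' @param temperature temperature in K (ensemble's by default).
#' @param standard_volume standard-state volume per molecule, A^3.
#' @return list with `TdS_ext` (kcal/mol), `sd_trans`, `sd_rot`.
#' @export
external_entropy <- function(ensemble, partition, temperature = NULL,
                             standard_volume = STANDARD_VOLUME) {
  top <- ensemble$topology
  check_partition(partition, top)
  temperature <- temperature %||% ensemble$temperature
  nf <- n_frames(ensemble)
  if (nf < 10L) stop("sampling error: need >= 10 frames for the ",
                     "external-entropy estimate")
  pa <- partition_atoms(partition, top)
  ## superpose on partner A so its frame defines the lab frame
  xyz <- ensemble$xyz
  if (length(pa$A) >= 3L) {
    ainds <- as.vector(rbind(3L * (pa$A - 1L) + 1L, 3L * (pa$A - 1L) + 2L,
                             3L * (pa$A - 1L) + 3L))
    xyz <- bio3d::fit.xyz(fixed = xyz[1L, ], mobile = xyz,
                          fixed.inds = ainds, mobile.inds = ainds)
  }
  com <- function(idx, row) {
    m <- matrix(row, ncol = 3L, byrow = TRUE)[idx, , drop = FALSE]
    colMeans(m)
  }
  rel <- t(apply(xyz, 1L, function(row) com(pa$B, row) - com(pa$A, row)))
  ev_t <- eigen(stats::cov(rel), symmetric = TRUE, only.values = TRUE)$values
  sd_trans <- sqrt(pmax(ev_t, 0))
  sd_rot <- NULL
  if (length(pa$A) >= 3L && length(pa$B) >= 3L) {
    bmats <- lapply(seq_len(nf), function(k)
      matrix(xyz[k, ], ncol = 3L, byrow = TRUE)[pa$B, , drop = FALSE])
    bmean <- Reduce(`+`, bmats) / nf
    rotvecs <- t(vapply(bmats, function(m) rotation_vector(kabsch(bmean, m)),
                        numeric(3)))
    ev_r <- eigen(stats::cov(rotvecs), symmetric = TRUE,
                  only.values = TRUE)$values
    sd_rot <- sqrt(pmax(ev_r, 0))
  }
  TdS <- external_entropy_gaussian(sd_trans, sd_rot, temperature,
                                   standard_volume)
  list(TdS_ext = TdS, sd_trans = sd_trans, sd_rot = sd_rot,
       temperature = temperature)
}

## Optimal rotation taking m (after centering) onto ref (Kabsch).
kabsch <- function(ref, m) {
  a <- scale(m, scale = FALSE); b <- scale(ref, scale = FALSE)
  s <- svd(crossprod(a, b))
  d <- sign(det(s$v %*% t(s$u)))
  s$v %*% diag(c(1, 1, d)) %*% t(s$u)
}

## axis * angle representation of a rotation matrix
rotation_vector <- function(R) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(R)) - 1) / 2)))
  if (ang < 1e-12) return(c(0, 0, 0))
  ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
    (2 * sin(ang))
  ax * ang
}

#' Standard binding free energy
#'
#' Assembles `dG0_bind = d<f> - T dS_config - T dS_ext` from a complex
#' ensemble and the two free-partner ensembles, with
#' `dX = X_complex - (X_A + X_B)`.  `d<f>` uses the attached energies;
#' `T dS_config` is the change in internal quasi-harmonic entropy
#' (each partner superposed on itself, in the complex and free), with
#' partners of fewer than two atoms carrying zero internal entropy;
#' `T dS_ext` comes from [external_entropy()].  Standard errors are
#' propagated in quadrature.
#'
#' @param complex_ens complex [ffl_ensemble()] with energies.
#' @param free_a,free_b free-partner ensembles with energies.
#' @param partition an [complex_partition()] of the complex topology.
#' @param temperature temperature, K; must be consistent across
#'   ensembles.
#' @param n_blocks blocks for the error estimates.
#' @param include_config_entropy set FALSE for rigid-partner fixtures
#'   (forces `T dS_config = 0`).
#' @param standard_volume standard-state volume, A^3 (1 M).
#' @return `ffl_bindfe`: list with `d_mean_f`, `TdS_config`, `TdS_ext`,
#'   `dG0_bind`, their `se`, `temperature`, `standard_volume` and the
#'   per-system components.
#' @export
standard_binding_free_energy <- function(complex_ens, free_a, free_b,
                                         partition, temperature = NULL,
                                         n_blocks = 5L,
                                         include_config_entropy = TRUE,
                                         standard_volume = STANDARD_VOLUME) {
  temps <- c(complex_ens$temperature, free_a$temperature, free_b$temperature)
  if (max(temps) - min(temps) > 1e-9)
    stop("consistency error: ensembles carry different temperatures: ",
         paste(temps, collapse = ", "))
  temperature <- temperature %||% temps[1L]
  fC <- ensemble_average_f(complex_ens, n_blocks)
  fA <- ensemble_average_f(free_a, n_blocks)
  fB <- ensemble_average_f(free_b, n_blocks)
  d_mean_f <- fC$mean - (fA$mean + fB$mean)
  d_mean_f_se <- sqrt(sum(c(fC$se, fA$se, fB$se)^2, na.rm = TRUE))
  TdS_config <- 0; TdS_config_se <- 0
  if (include_config_entropy) {
    pa <- partition_atoms(partition, complex_ens$topology)
    int_S <- function(ens, idx = NULL) {
      sub <- if (is.null(idx)) ens else subset_atoms(ens, idx)
      if (n_atoms(sub$topology) < 2L)
        return(list(TS = 0, se = 0))      # single bead: no internal modes
      est <- config_entropy(sub, temperature = temperature,
                            superpose = TRUE, n_blocks = n_blocks)
      list(TS = est$TS, se = est$se)
    }
    sCA <- int_S(complex_ens, pa$A); sCB <- int_S(complex_ens, pa$B)
    sA <- int_S(free_a); sB <- int_S(free_b)
    TdS_config <- (sCA$TS + sCB$TS) - (sA$TS + sB$TS)
    TdS_config_se <- sqrt(sum(c(sCA$se, sCB$se, sA$se, sB$se)^2, na.rm = TRUE))
  }
  ext <- external_entropy(complex_ens, partition, temperature,
                          standard_volume)
  dG0 <- d_mean_f - TdS_config - ext$TdS_ext
  structure(list(d_mean_f = d_mean_f, d_mean_f_se = d_mean_f_se,
                 TdS_config = TdS_config, TdS_config_se = TdS_config_se,
                 TdS_ext = ext$TdS_ext,
                 dG0_bind = dG0,
                 dG0_bind_se = sqrt(d_mean_f_se^2 + TdS_config_se^2),
                 temperature = temperature,
                 standard_volume = standard_volume,
                 components = list(f_complex = fC, f_A = fA, f_B = fB,
                                   external = ext),
                 entropy_method = if (include_config_entropy)
                   "quasi-harmonic" else "rigid"),
            class = "ffl_bindfe")
}

#' Assemble a standard binding free energy from precomputed components
#'
#' Component-level constructor mirroring the thermodynamic ledger:
#' `dG0_bind = d_mean_f - TdS_config - TdS_ext`, with standard errors
#' propagated in quadrature.  Useful when the components come from
#' external tables rather than from ensembles.
#'
#' @param d_mean_f,TdS_config,TdS_ext components in kcal/mol.
#' @param temperature temperature, K.
#' @param d_mean_f_se,TdS_config_se standard errors (kcal/mol).
#' @param standard_volume standard-state volume, A^3.
#' @return an `ffl_bindfe` object.
#' @export
assemble_binding_free_energy <- function(d_mean_f, TdS_config, TdS_ext,
                                         temperature = 300,
                                         d_mean_f_se = 0, TdS_config_se = 0,
                                         standard_volume = STANDARD_VOLUME) {
  structure(list(d_mean_f = d_mean_f, d_mean_f_se = d_mean_f_se,
                 TdS_config = TdS_config, TdS_config_se = TdS_config_se,
                 TdS_ext = TdS_ext,
                 dG0_bind = d_mean_f - TdS_config - TdS_ext,
                 dG0_bind_se = sqrt(d_mean_f_se^2 + TdS_config_se^2),
                 temperature = temperature,
                 standard_volume = standard_volume,
                 components = list(), entropy_method = "supplied"),
            class = "ffl_bindfe")
}

#' @export
print.ffl_bindfe <- function(x, ...) {
  cat("standard binding free energy (1 M standard state)\n")
  cat(sprintf("  d<f>       : %8.3f +/- %.3f kcal/mol\n",
              x$d_mean_f, x$d_mean_f_se))
  cat(sprintf("  T dS_config: %8.3f +/- %.3f kcal/mol (%s)\n",
              x$TdS_config, x$TdS_config_se, x$entropy_method))
  cat(sprintf("  T dS_ext   : %8.3f kcal/mol\n", x$TdS_ext))
  cat(sprintf("  dG0_bind   : %8.3f +/- %.3f kcal/mol\n",
              x$dG0_bind, x$dG0_bind_se))
  invisible(x)
}
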
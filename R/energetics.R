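#' Gas-phase energy of a frame under a toy force field
#'
#' `E_u = sum bonds + sum LJ + sum Coulomb + sum Go`.  Every pair term is
#' itemized in the returned ledger, which is what makes exact per-residue
#' decomposition possible downstream.  Nonbonded (LJ/Coulomb) terms run
#' over all atom pairs except directly bonded ones; no distance cutoffs
#' are applied.
#'
#' @param frame N x 3 coordinates (A).
#' @param ff an [toy_forcefield()].
#' @return `ffl_ledger`: list with `total` (kcal/mol) and `terms`
#'   (data.frame `type`, `i`, `j`, `value`).
#' @export
gas_phase_energy <- function(frame, ff) {
  stopifnot(inherits(ff, "ffl_forcefield"))
  frame <- as.matrix(frame)
  if (nrow(frame) != ff$n_atoms)
    stop("parameterization error: frame has ", nrow(frame),
         " atoms, force field covers ", ff$n_atoms)
  terms <- list()
  if (nrow(ff$bonds)) {
    r <- pair_dist(frame, ff$bonds$i, ff$bonds$j)
    terms$bond <- data.frame(type = "bond", i = ff$bonds$i, j = ff$bonds$j,
                             value = 0.5 * ff$bonds$k * (r - ff$bonds$r_eq)^2)
  }
  nb <- nonbonded_pairs(ff)
  if (nrow(nb)) {
    r <- pair_dist(frame, nb$i, nb$j)
    qq <- ff$atoms$charge[nb$i] * ff$atoms$charge[nb$j]
    has_c <- qq != 0
    if (any(has_c))
      terms$coulomb <- data.frame(type = "coulomb", i = nb$i[has_c],
                                  j = nb$j[has_c],
                                  value = ff$coulomb_scale * qq[has_c] / r[has_c])
    epsij <- sqrt(ff$atoms$eps[nb$i] * ff$atoms$eps[nb$j])
    has_lj <- epsij > 0
    if (any(has_lj)) {
      sij <- 0.5 * (ff$atoms$sigma[nb$i] + ff$atoms$sigma[nb$j])
      sr6 <- (sij[has_lj] / r[has_lj])^6
      terms$lj <- data.frame(type = "lj", i = nb$i[has_lj], j = nb$j[has_lj],
                             value = 4 * epsij[has_lj] * (sr6^2 - sr6))
    }
  }
  if (nrow(ff$go)) {
    r <- pair_dist(frame, ff$go$i, ff$go$j)
    sr <- ff$go$r0 / r
    terms$go <- data.frame(type = "go", i = ff$go$i, j = ff$go$j,
                           value = ff$go$eps * (5 * sr^12 - 6 * sr^10))
  }
  terms <- if (length(terms)) do.call(rbind, unname(terms))
           else data.frame(type = character(0), i = integer(0),
                           j = integer(0), value = numeric(0))
  rownames(terms) <- NULL
  structure(list(total = sum(terms$value), terms = terms),
            class = "ffl_ledger")
}

## all i<j pairs minus directly bonded ones
nonbonded_pairs <- function(ff) {
  n <- ff$n_atoms
  if (n < 2L) return(data.frame(i = integer(0), j = integer(0)))
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pairs <- data.frame(i = idx[, 1L], j = idx[, 2L])
  if (nrow(ff$bonds)) {
    bonded <- paste(ff$bonds$i, ff$bonds$j)
    pairs <- pairs[!(paste(pairs$i, pairs$j) %in% bonded), , drop = FALSE]
  }
  pairs
}

#' @export
print.ffl_ledger <- function(x, ...) {
  cat(sprintf("energy ledger: total %.6f kcal/mol over %d terms\n",
              x$total, nrow(x$terms)))
  if (nrow(x$terms))
    print(tapply(x$terms$value, x$terms$type, sum))
  invisible(x)
}

#' Solvation free energy of a frame
#'
#' Two backends.  `"table"` looks the value up in a precomputed per-frame
#' energy table (the intended carrier for solvation free energies computed
#' by an external solver such as an integral-equation theory; that solver
#' itself is out of scope here).  `"surrogate"` evaluates a simplified
#' pairwise implicit-solvent model -- a generalized-Born-style screened
#' electrostatic term plus a sphere-overlap exposed-area term -- whose
#' every term is attributable to residues.  The surrogate is a stand-in
#' for testing and fixtures, and is tagged as such in all outputs.
#'
#' Surrogate form, with dielectric `eps_w`, conversion `C`, Born radii
#' `R_i` and `tau = 1 - 1/eps_w`:
#' self terms `-C/2 * tau * q_i^2 / R_i`; pair terms
#' `-C * tau * q_i q_j / f_GB(r)` with
#' `f_GB = sqrt(r^2 + R_i R_j exp(-r^2 / (4 R_i R_j)))`; and a nonpolar
#' term `gamma * A_i` per atom, where `A_i` is a sphere-overlap proxy for
#' the solvent-exposed area (occlusion has finite range
#' `R_i + R_j + 2 * probe`).  Pair terms are split half/half between the
#' two residues involved; self and area terms belong to their own residue.
#'
#' @param frame N x 3 coordinates (A).
#' @param topology an [ffl_topology()] (surrogate backend; used for the
#'   residue attribution).
#' @param ff an [toy_forcefield()] carrying charges and radii (surrogate).
#' @param backend `"surrogate"` or `"table"`.
#' @param table energy table (data.frame from [read_energy_table()]) for
#'   the table backend.
#' @param frame_index 0-based frame index to look up in `table`.
#' @param eps_w effective solvent dielectric (surrogate).
#' @param gamma surface-tension coefficient, kcal/mol/A^2 (surrogate).
#' @param probe water probe radius, A (surrogate).
#' @return `ffl_solvation`: list with `total` (kcal/mol), `per_residue`
#'   (named by `chain:resno`; NULL for totals-only table rows), `backend`.
#' @export
solvation_energy <- function(frame = NULL, topology = NULL, ff = NULL,
                             backend = c("surrogate", "table"),
                             table = NULL, frame_index = NULL,
                             eps_w = 78.5, gamma = 0.005, probe = 1.4) {
  backend <- match.arg(backend)
  if (backend == "table") {
    if (is.null(table) || is.null(frame_index))
      stop("table backend needs 'table' and 'frame_index'")
    row <- match(frame_index, table$frame)
    if (is.na(row))
      stop("missing-energy error: no table row for frame ", frame_index)
    per_res <- NULL
    res_cols <- grep("^res_", names(table), value = TRUE)
    if (length(res_cols)) {
      per_res <- as.numeric(table[row, res_cols])
      ## res_<chain>_<resno> -> "<chain>:<resno>"
      names(per_res) <- sub("_", ":", sub("^res_", "", res_cols))
    }
    return(structure(list(total = table$G_solv[row], per_residue = per_res,
                          backend = "table"), class = "ffl_solvation"))
  }
  if (is.null(frame) || is.null(topology) || is.null(ff))
    stop("surrogate backend needs frame, topology and ff")
  frame <- as.matrix(frame)
  n <- nrow(frame)
  if (n != ff$n_atoms || n != n_atoms(topology))
    stop("parameterization error: frame/topology/force-field atom counts differ")
  q <- ff$atoms$charge; R <- ff$atoms$radius
  tau <- 1 - 1 / eps_w
  C <- ff$coulomb_scale
  res <- topology$residues
  contrib <- stats::setNames(numeric(nrow(res)),
                             paste(res$chain, res$resno, sep = ":"))
  ridx <- topology$atoms$ridx
  ## Born self terms
  self <- -0.5 * C * tau * q^2 / R
  for (k in seq_len(n)) contrib[ridx[k]] <- contrib[ridx[k]] + self[k]
  ## pair screening
  if (n >= 2L) {
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    qq <- q[idx[, 1L]] * q[idx[, 2L]]
    keep <- qq != 0
    if (any(keep)) {
      ii <- idx[keep, 1L]; jj <- idx[keep, 2L]
      r <- pair_dist(frame, ii, jj)
      rr <- R[ii] * R[jj]
      fgb <- sqrt(r^2 + rr * exp(-r^2 / (4 * rr)))
      pv <- -C * tau * qq[keep] / fgb
      half <- 0.5 * pv
      for (k in seq_along(pv)) {
        contrib[ridx[ii[k]]] <- contrib[ridx[ii[k]]] + half[k]
        contrib[ridx[jj[k]]] <- contrib[ridx[jj[k]]] + half[k]
      }
    }
  }
  ## nonpolar sphere-overlap exposed-area proxy
  if (gamma != 0) {
    d <- cross_dist(frame, frame)
    rc <- outer(R, R, "+") + 2 * probe
    occ <- 1 - d / rc
    occ[occ < 0] <- 0
    occ <- occ^2
    diag(occ) <- 0
    area <- 4 * pi * (R + probe)^2 * pmax(0, 1 - rowSums(occ))
    av <- gamma * area
    for (k in seq_len(n)) contrib[ridx[k]] <- contrib[ridx[k]] + av[k]
  }
  structure(list(total = sum(contrib), per_residue = contrib,
                 backend = "surrogate"), class = "ffl_solvation")
}

## residue key ("chain:resno") of each atom
residue_keys <- function(topology)
  paste(topology$atoms$chain, topology$atoms$resno, sep = ":")

#' @export
print.ffl_solvation <- function(x, ...) {
  cat(sprintf("solvation energy (%s backend): %.6f kcal/mol\n",
              x$backend, x$total))
  invisible(x)
}

#' Per-frame effective energy f(r)
#'
#' `f(r) = E_u(r) + G_solv(r)`: gas-phase energy plus solvation free
#' energy of a single configuration.  Carries no configurational entropy.
#'
#' @inheritParams solvation_energy
#' @param ff an [toy_forcefield()].
#' @param ... further arguments to [solvation_energy()].
#' @return f in kcal/mol.
#' @export
effective_energy <- function(frame, topology, ff,
                             backend = c("surrogate", "table"), ...) {
  backend <- match.arg(backend)
  eu <- gas_phase_energy(frame, ff)$total
  gs <- solvation_energy(frame = frame, topology = topology, ff = ff,
                         backend = backend, ...)$total
  eu + gs
}

#' Effective-energy series for an ensemble
#'
#' Evaluates `E_u` and `G_solv` for every frame and attaches the result as
#' the ensemble's energy table.
#'
#' @param ensemble an [ffl_ensemble()].
#' @param ff an [toy_forcefield()].
#' @param backend `"surrogate"` or `"table"`.
#' @param table per-frame energy table for the table backend.  Supplying a
#'   table together with `backend = "surrogate"` is an error (the table is
#'   authoritative; conflicts are not resolved silently).
#' @param ... surrogate parameters passed to [solvation_energy()].
#' @return the ensemble with an energy table (`frame`, `E_u`, `G_solv`, `f`).
#' @export
effective_energy_series <- function(ensemble, ff,
                                    backend = c("surrogate", "table"),
                                    table = NULL, ...) {
  backend <- match.arg(backend)
  if (backend == "surrogate" && !is.null(table))
    stop("conflicting solvation sources: a precomputed table was supplied ",
         "together with the surrogate backend; choose one")
  nf <- n_frames(ensemble)
  eu <- numeric(nf); gs <- numeric(nf)
  for (k in seq_len(nf)) {
    x <- frame_coords(ensemble, k)
    eu[k] <- gas_phase_energy(x, ff)$total
    gs[k] <- if (backend == "table")
      solvation_energy(backend = "table", table = table,
                       frame_index = ensemble$frame_index[k])$total
    else
      solvation_energy(frame = x, topology = ensemble$topology, ff = ff,
                       backend = "surrogate", ...)$total
  }
  attach_energy(ensemble, data.frame(frame = ensemble$frame_index,
                                     E_u = eu, G_solv = gs))
}
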
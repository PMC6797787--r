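#' Restrict a toy force field to an atom subset
#'
#' Keeps per-atom parameters of the selected atoms and every bond/Go term
#' with both endpoints inside the subset, reindexed to the subset.
#'
#' @param ff an [toy_forcefield()].
#' @param atom_idx integer atom positions (1-based) to keep.
#' @return an `ffl_forcefield` over `length(atom_idx)` atoms.
#' @export
subset_forcefield <- function(ff, atom_idx) {
  remap <- match(seq_len(ff$n_atoms), atom_idx)
  take_pairs <- function(df) {
    if (!nrow(df)) return(df)
    keep <- !is.na(remap[df$i]) & !is.na(remap[df$j])
    df <- df[keep, , drop = FALSE]
    df$i <- remap[df$i]; df$j <- remap[df$j]
    rownames(df) <- NULL
    df
  }
  toy_forcefield(n_atoms = length(atom_idx),
                 bonds = take_pairs(ff$bonds),
                 atoms = ff$atoms[atom_idx, , drop = FALSE],
                 go = take_pairs(ff$go),
                 coulomb_scale = ff$coulomb_scale)
}

#' Solvent-averaged binding potential of one complex frame
#'
#' `dfint = dE_int + dG_solv`, where `dE_int` is the sum of all
#' inter-partner pair terms of the gas-phase ledger and
#' `dG_solv = G_solv(AB) - [G_solv(A) + G_solv(B)]`, the three solvation
#' energies evaluated at identical coordinates.  With the surrogate
#' backend (or a table carrying per-residue columns) the result also
#' carries the exact per-residue attribution used by the site-directed
#' decomposition: each inter-partner pair term is split half/half between
#' the two residues, and each residue's solvation part is its `G_solv(AB)`
#' contribution minus its contribution in the free partner.
#'
#' @param frame N x 3 complex coordinates (A).
#' @param topology complex [ffl_topology()].
#' @param partition an [complex_partition()].
#' @param ff complex-wide [toy_forcefield()].
#' @param backend `"surrogate"` or `"table"`.
#' @param table complex-mode energy table with columns `G_solv_AB`,
#'   `G_solv_A`, `G_solv_B` (and optionally `res_<chain>_<resno>` triples
#'   is not supported -- per-residue table mode expects columns holding
#'   the already-differenced per-residue `dG_solv`).
#' @param frame_index 0-based index for table lookup.
#' @param per_residue also return per-residue direct/solvation parts.
#' @param ... surrogate parameters for [solvation_energy()].
#' @return `ffl_binding`: list with `dfint`, `dE_int`, `dG_solv`
#'   (kcal/mol), `frame_index`, and optionally `residue` (data.frame
#'   `key`, `direct`, `solvation`, `total`).
#' @export
binding_potential <- function(frame, topology, partition, ff,
                              backend = c("surrogate", "table"),
                              table = NULL, frame_index = NULL,
                              per_residue = FALSE, ...) {
  backend <- match.arg(backend)
  check_partition(partition, topology)
  frame <- as.matrix(frame)
  pa <- partition_atoms(partition, topology)
  in_a <- seq_len(n_atoms(topology)) %in% pa$A
  ## direct inter-partner interaction from the gas-phase ledger
  led <- gas_phase_energy(frame, ff)
  tt <- led$terms
  cross <- in_a[tt$i] != in_a[tt$j]
  dE_int <- sum(tt$value[cross])
  rkey <- residue_keys(topology)
  res_names <- paste(topology$residues$chain, topology$residues$resno, sep = ":")
  direct <- stats::setNames(numeric(length(res_names)), res_names)
  if (any(cross)) {
    ct <- tt[cross, , drop = FALSE]
    for (k in seq_len(nrow(ct))) {
      direct[rkey[ct$i[k]]] <- direct[rkey[ct$i[k]]] + 0.5 * ct$value[k]
      direct[rkey[ct$j[k]]] <- direct[rkey[ct$j[k]]] + 0.5 * ct$value[k]
    }
  }
  ## solvent-induced part at identical coordinates
  solv <- stats::setNames(numeric(length(res_names)), res_names)
  if (backend == "table") {
    if (is.null(table) || is.null(frame_index))
      stop("table backend needs 'table' and 'frame_index'")
    need <- c("G_solv_AB", "G_solv_A", "G_solv_B")
    miss <- setdiff(need, names(table))
    if (length(miss))
      stop("missing-energy error: complex table lacks column(s) ",
           paste(miss, collapse = ", "))
    row <- match(frame_index, table$frame)
    if (is.na(row))
      stop("missing-energy error: no table row for frame ", frame_index)
    dG_solv <- table$G_solv_AB[row] - table$G_solv_A[row] - table$G_solv_B[row]
    res_cols <- grep("^res_", names(table), value = TRUE)
    if (length(res_cols)) {
      keys <- sub("_", ":", sub("^res_", "", res_cols))
      unknown <- setdiff(keys, res_names)
      if (length(unknown))
        stop("per-residue table column(s) reference unknown residue(s): ",
             paste(unknown, collapse = ", "))
      solv[keys] <- as.numeric(table[row, res_cols])
    } else if (per_residue) {
      stop("decomposition-unsupported: table backend without per-residue ",
           "columns cannot attribute dG_solv to residues (totals only)")
    }
  } else {
    s_ab <- solvation_energy(frame, topology, ff, backend = "surrogate", ...)
    top_a <- subtopology(topology, pa$A); top_b <- subtopology(topology, pa$B)
    s_a <- solvation_energy(frame[pa$A, , drop = FALSE], top_a,
                            subset_forcefield(ff, pa$A),
                            backend = "surrogate", ...)
    s_b <- solvation_energy(frame[pa$B, , drop = FALSE], top_b,
                            subset_forcefield(ff, pa$B),
                            backend = "surrogate", ...)
    dG_solv <- s_ab$total - s_a$total - s_b$total
    solv[names(s_ab$per_residue)] <- s_ab$per_residue
    solv[names(s_a$per_residue)] <- solv[names(s_a$per_residue)] - s_a$per_residue
    solv[names(s_b$per_residue)] <- solv[names(s_b$per_residue)] - s_b$per_residue
  }
  out <- list(dfint = dE_int + dG_solv, dE_int = dE_int, dG_solv = dG_solv,
              frame_index = frame_index)
  if (per_residue)
    out$residue <- data.frame(key = res_names, direct = unname(direct),
                              solvation = unname(solv),
                              total = unname(direct + solv),
                              stringsAsFactors = FALSE)
  structure(out, class = "ffl_binding")
}

subtopology <- function(topology, atom_idx) {
  atoms <- topology$atoms[atom_idx, c("serial", "name", "element",
                                      "chain", "resno", "resname")]
  rownames(atoms) <- NULL
  ffl_topology(atoms)
}

#' @export
print.ffl_binding <- function(x, ...) {
  cat(sprintf("binding potential: dfint = %.6f (dE_int = %.6f, dG_solv = %.6f) kcal/mol\n",
              x$dfint, x$dE_int, x$dG_solv))
  invisible(x)
}

#' Effective energy of the folding partner in the bound state
#'
#' For a complex frame, `f = f_partner + dfint`: the effective energy of
#' the designated folding partner evaluated as an isolated subsystem, plus
#' the solvent-averaged binding potential.  The other partner's
#' self-energy is deliberately excluded, so the bound landscape is
#' directly comparable to the free-partner landscape.
#'
#' @inheritParams binding_potential
#' @param ... passed through to the solvation backend.
#' @return f in kcal/mol.
#' @export
bound_effective_energy <- function(frame, topology, partition, ff,
                                   backend = c("surrogate", "table"),
                                   table = NULL, frame_index = NULL, ...) {
  backend <- match.arg(backend)
  check_partition(partition, topology)
  pa <- partition_atoms(partition, topology)
  fold <- if (partition$folding_partner == "A") pa$A else pa$B
  sub_ff <- subset_forcefield(ff, fold)
  sub_top <- subtopology(topology, fold)
  frame <- as.matrix(frame)
  f_part <- if (backend == "table") {
    if (is.null(table) || is.null(frame_index))
      stop("table backend needs 'table' and 'frame_index'")
    part_col <- paste0("G_solv_", partition$folding_partner)
    if (!part_col %in% names(table))
      stop("missing-energy error: table lacks column ", part_col)
    row <- match(frame_index, table$frame)
    if (is.na(row))
      stop("missing-energy error: no table row for frame ", frame_index)
    gas_phase_energy(frame[fold, , drop = FALSE], sub_ff)$total +
      table[[part_col]][row]
  } else {
    effective_energy(frame[fold, , drop = FALSE], sub_top, sub_ff,
                     backend = "surrogate", ...)
  }
  bp <- binding_potential(frame, topology, partition, ff, backend = backend,
                          table = table, frame_index = frame_index, ...)
  f_part + bp$dfint
}
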
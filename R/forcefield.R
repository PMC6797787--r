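#' Construct a toy force field
#'
#' Minimal gas-phase energy model for bead/toy systems: harmonic bonds,
#' per-atom Lennard-Jones and partial charges, and optional Go contact
#' terms restricted to native pairs.  Used both by the Monte-Carlo
#' generator and by the energy/decomposition machinery; it is a desk-scale
#' surrogate for a biomolecular force field, not an import of one.
#'
#' @param n_atoms number of atoms covered.
#' @param bonds data.frame `i`, `j` (1-based atom indices), `k`
#'   (kcal/mol/A^2), `r_eq` (A); energy `0.5*k*(r - r_eq)^2`.
#' @param atoms per-atom data.frame `charge` (e), `eps` (kcal/mol), `sigma`
#'   (A), `radius` (A, Born-style radius for the solvation surrogate);
#'   missing columns default to charge 0, eps 0, sigma 4, radius 2.
#' @param go data.frame `i`, `j`, `eps` (kcal/mol), `r0` (A); 12-10 Go
#'   potential `eps*(5*(r0/r)^12 - 6*(r0/r)^10)` with minimum `-eps` at `r0`.
#' @param coulomb_scale electrostatic conversion factor, kcal A/(mol e^2).
#' @return `ffl_forcefield` object.
#' @export
toy_forcefield <- function(n_atoms, bonds = NULL, atoms = NULL, go = NULL,
                           coulomb_scale = COULOMB_CONST) {
  empty_pairs <- function(extra) {
    df <- data.frame(i = integer(0), j = integer(0))
    for (e in extra) df[[e]] <- numeric(0)
    df
  }
  bonds <- if (is.null(bonds)) empty_pairs(c("k", "r_eq")) else as.data.frame(bonds)
  go <- if (is.null(go)) empty_pairs(c("eps", "r0")) else as.data.frame(go)
  defaults <- data.frame(charge = rep(0, n_atoms), eps = 0, sigma = 4, radius = 2)
  if (!is.null(atoms)) {
    atoms <- as.data.frame(atoms)
    if (nrow(atoms) != n_atoms)
      stop("parameterization error: atoms table has ", nrow(atoms),
           " rows for ", n_atoms, " atoms")
    for (cn in intersect(names(atoms), names(defaults))) defaults[[cn]] <- atoms[[cn]]
  }
  for (df_name in c("bonds", "go")) {
    df <- get(df_name)
    if (nrow(df)) {
      if (any(df$i < 1 | df$j < 1 | df$i > n_atoms | df$j > n_atoms))
        stop("parameterization error: ", df_name, " pair index out of range")
      swap <- df$i > df$j
      tmp <- df$i[swap]; df$i[swap] <- df$j[swap]; df$j[swap] <- tmp
      assign(df_name, df)
    }
  }
  if (nrow(bonds) && any(bonds$k < 0)) stop("bond force constants must be >= 0")
  if (any(defaults$eps < 0)) stop("LJ well depths must be >= 0")
  if (any(defaults$sigma <= 0)) stop("LJ sigma must be > 0")
  if (any(defaults$radius <= 0)) stop("parameter error: zero or negative radius")
  structure(list(n_atoms = as.integer(n_atoms), bonds = bonds,
                 atoms = defaults, go = go, coulomb_scale = coulomb_scale),
            class = "ffl_forcefield")
}

#' @export
print.ffl_forcefield <- function(x, ...) {
  cat("funnelscape toy force field:", x$n_atoms, "atoms,",
      nrow(x$bonds), "bonds,", nrow(x$go), "Go contacts,",
      sum(x$atoms$charge != 0), "charged atoms\n")
  invisible(x)
}

#' Write / read a toy force field as YAML
#'
#' Sections `n_atoms`, `bonds`, `atoms`, `go`, `coulomb_scale`; pair tables
#' as row lists.
#'
#' @param ff an [toy_forcefield()] object.
#' @param path YAML file.
#' @return `read_forcefield` returns an `ffl_forcefield`.
#' @export
write_forcefield <- function(ff, path) {
  stopifnot(inherits(ff, "ffl_forcefield"))
  obj <- list(n_atoms = ff$n_atoms,
              coulomb_scale = ff$coulomb_scale,
              bonds = lapply(seq_len(nrow(ff$bonds)), function(r) as.list(ff$bonds[r, ])),
              atoms = lapply(seq_len(nrow(ff$atoms)), function(r) as.list(ff$atoms[r, ])),
              go = lapply(seq_len(nrow(ff$go)), function(r) as.list(ff$go[r, ])))
  yaml::write_yaml(obj, path, precision = 17)
  invisible(path)
}

#' @rdname write_forcefield
#' @export
read_forcefield <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- yaml::read_yaml(path)
  rowbind <- function(lst) if (length(lst)) do.call(rbind.data.frame, lst) else NULL
  toy_forcefield(n_atoms = obj$n_atoms,
                 bonds = rowbind(obj$bonds),
                 atoms = rowbind(obj$atoms),
                 go = rowbind(obj$go),
                 coulomb_scale = obj$coulomb_scale %||% COULOMB_CONST)
}
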
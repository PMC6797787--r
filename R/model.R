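#' Molecular data model: topology, frames, ensembles
#'
#' The shared containers used by every analysis stage.  A topology lists
#' atoms and residues; a frame is an N x 3 coordinate matrix in Angstrom;
#' an ensemble bundles a topology with an ordered set of frames (stored as
#' an n_frames x 3N coordinate matrix, bio3d convention), a temperature and
#' an optional per-frame energy table.
#'
#' @param atoms data.frame with columns `name` (atom name), `element`,
#'   `chain`, `resno` (residue number within the chain) and `resname`
#'   (3-letter residue name).  A `serial` column is added if absent.
#' @param residue_class optional data.frame with columns `chain`, `resno`,
#'   `class` overriding the default neutral/charged classification.
#' @return `ffl_topology` object: list with `atoms` (with an additional
#'   global residue index column `ridx`), `residues` (chain, resno, resname,
#'   class), and `chains` (chain ids in order of first appearance).
#' @export
ffl_topology <- function(atoms, residue_class = NULL) {
  need <- c("name", "element", "chain", "resno", "resname")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("topology atoms missing column(s): ",
                         paste(miss, collapse = ", "))
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (is.null(atoms$serial)) atoms$serial <- seq_len(nrow(atoms))
  if (nrow(atoms) == 0L) stop("empty structure: no atoms")
  key <- paste(atoms$chain, atoms$resno, sep = "\r")
  ridx <- match(key, unique(key))
  atoms$ridx <- ridx
  first <- !duplicated(key)
  residues <- data.frame(chain = atoms$chain[first],
                         resno = atoms$resno[first],
                         resname = atoms$resname[first],
                         stringsAsFactors = FALSE)
  ## residue numbers must increase within a chain
  for (ch in unique(residues$chain)) {
    rn <- residues$resno[residues$chain == ch]
    if (any(diff(rn) <= 0))
      stop("residue numbers not strictly increasing in chain ", ch)
  }
  residues$class <- classify_residues(residues, residue_class)
  structure(list(atoms = atoms, residues = residues,
                 chains = unique(atoms$chain)),
            class = "ffl_topology")
}

## Default neutral/charged classification.  Charged: Asp, Glu, Lys, Arg and
## phosphoserine (SEP); His is treated as neutral.  Overridable per residue
## via a class table (chain, resno, class).
classify_residues <- function(residues, override = NULL) {
  charged_set <- c("ASP", "GLU", "LYS", "ARG", "SEP")
  cls <- ifelse(toupper(residues$resname) %in% charged_set,
                "charged", "neutral")
  if (!is.null(override)) {
    need <- c("chain", "resno", "class")
    if (!all(need %in% names(override)))
      stop("residue-class table needs columns: chain, resno, class")
    bad <- setdiff(unique(override$class), c("neutral", "charged"))
    if (length(bad)) stop("unknown residue class: ", paste(bad, collapse = ", "))
    key <- paste(residues$chain, residues$resno)
    okey <- paste(override$chain, override$resno)
    hit <- match(key, okey)
    cls[!is.na(hit)] <- override$class[hit[!is.na(hit)]]
  }
  cls
}

#' @export
print.ffl_topology <- function(x, ...) {
  cat("funnelscape topology:", nrow(x$atoms), "atoms,",
      nrow(x$residues), "residues, chains:",
      paste(x$chains, collapse = ", "), "\n")
  invisible(x)
}

n_atoms <- function(topology) nrow(topology$atoms)

validate_frame <- function(coords, topology) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("frame coordinates must be N x 3")
  if (nrow(coords) != n_atoms(topology))
    stop("topology mismatch: frame has ", nrow(coords), " atoms, topology ",
         n_atoms(topology))
  if (!all(is.finite(coords))) stop("non-finite coordinates in frame")
  unname(coords)
}

#' Construct a conformational ensemble
#'
#' @param topology an [ffl_topology()].
#' @param frames a list of N x 3 coordinate matrices, a single matrix, or an
#'   n_frames x 3N matrix (row-per-frame, bio3d xyz convention).
#' @param temperature simulation temperature in K.
#' @param energy optional data.frame joining per-frame energies: columns
#'   `frame` (0-based index), `E_u`, `G_solv`, optionally `dfint`.
#' @param metadata free-form list recorded with the ensemble (e.g. the
#'   stride at which frames were taken).
#' @return `ffl_ensemble`: list with `topology`, `xyz` (n_frames x 3N),
#'   `frame_index` (0-based), `temperature`, `energy`, `metadata`.
#' @export
ffl_ensemble <- function(topology, frames, temperature = 300,
                         energy = NULL, metadata = list()) {
  stopifnot(inherits(topology, "ffl_topology"))
  if (temperature <= 0) stop("temperature must be > 0")
  na <- n_atoms(topology)
  if (is.list(frames) && !is.data.frame(frames)) {
    xyz <- t(vapply(frames, function(f) as.numeric(t(validate_frame(f, topology))),
                    numeric(3L * na)))
  } else {
    frames <- as.matrix(frames)
    if (ncol(frames) == 3L && nrow(frames) == na) {
      xyz <- matrix(as.numeric(t(validate_frame(frames, topology))), nrow = 1L)
    } else if (ncol(frames) == 3L * na) {
      xyz <- unname(frames)
    } else stop("topology mismatch: cannot interpret frame matrix of dim ",
                nrow(frames), " x ", ncol(frames))
  }
  if (nrow(xyz) < 1L) stop("ensemble needs at least one frame")
  if (!all(is.finite(xyz))) stop("non-finite coordinates in ensemble")
  ens <- structure(list(topology = topology, xyz = xyz,
                        frame_index = seq_len(nrow(xyz)) - 1L,
                        temperature = temperature, energy = NULL,
                        metadata = metadata),
                   class = "ffl_ensemble")
  if (!is.null(energy)) ens <- attach_energy(ens, energy)
  ens
}

#' @export
print.ffl_ensemble <- function(x, ...) {
  cat("funnelscape ensemble:", n_frames(x), "frames,",
      n_atoms(x$topology), "atoms, T =", x$temperature, "K",
      if (!is.null(x$energy)) "(energies attached)", "\n")
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ensemble an [ffl_ensemble()].
#' @export
n_frames <- function(ensemble) nrow(ensemble$xyz)

#' Extract one frame's coordinates
#' @param ensemble an [ffl_ensemble()].
#' @param i frame position (1-based) or 0-based `frame_index` when
#'   `by_index = TRUE`.
#' @param by_index interpret `i` as the stored 0-based frame index.
#' @return N x 3 coordinate matrix (Angstrom).
#' @export
frame_coords <- function(ensemble, i, by_index = FALSE) {
  if (by_index) {
    i <- match(i, ensemble$frame_index)
    if (is.na(i)) stop("frame index not present in ensemble")
  }
  matrix(ensemble$xyz[i, ], ncol = 3L, byrow = TRUE)
}

#' Join per-frame energy records onto an ensemble
#'
#' @param ensemble an [ffl_ensemble()].
#' @param energy data.frame with columns `frame` (matching the ensemble's
#'   0-based frame indices), `E_u` and `G_solv` in kcal/mol (optional
#'   further columns are kept).
#' @return the ensemble with `$energy` set, rows aligned to frame order,
#'   and a derived `f = E_u + G_solv` column.
#' @export
attach_energy <- function(ensemble, energy) {
  stopifnot(inherits(ensemble, "ffl_ensemble"))
  need <- c("frame", "E_u", "G_solv")
  miss <- setdiff(need, names(energy))
  if (length(miss)) stop("energy table missing column(s): ",
                         paste(miss, collapse = ", "))
  hit <- match(ensemble$frame_index, energy$frame)
  if (anyNA(hit))
    stop("missing energy record for frame(s): ",
         paste(utils::head(ensemble$frame_index[is.na(hit)], 5), collapse = ", "))
  en <- energy[hit, , drop = FALSE]
  rownames(en) <- NULL
  en$f <- en$E_u + en$G_solv
  ensemble$energy <- en
  ensemble
}

## Per-frame effective energies; errors if absent.
ensemble_f <- function(ensemble) {
  if (is.null(ensemble$energy))
    stop("ensemble carries no energy records; attach_energy() first")
  ensemble$energy$f
}

#' Restrict an ensemble to a subset of atoms
#' @param ensemble an [ffl_ensemble()].
#' @param atom_idx integer atom positions (1-based) to keep.
#' @return an [ffl_ensemble()] over the selected atoms (energies dropped).
#' @export
subset_atoms <- function(ensemble, atom_idx) {
  top <- ensemble$topology
  atoms <- top$atoms[atom_idx, , drop = FALSE]
  rownames(atoms) <- NULL
  sub_top <- ffl_topology(atoms[, c("serial", "name", "element",
                                    "chain", "resno", "resname")])
  cols <- as.vector(rbind(3L * (atom_idx - 1L) + 1L,
                          3L * (atom_idx - 1L) + 2L,
                          3L * (atom_idx - 1L) + 3L))
  ffl_ensemble(sub_top, ensemble$xyz[, cols, drop = FALSE],
               temperature = ensemble$temperature,
               metadata = ensemble$metadata)
}

#' Define a two-partner partition of a complex
#'
#' @param chains_a,chains_b chain ids of the two binding partners; together
#'   they must cover every chain of the topology, disjointly.
#' @param folding_partner which partner ("A" or "B") is the chain whose
#'   folding landscape is being constructed (the disordered partner).
#' @return `ffl_partition` object.
#' @export
complex_partition <- function(chains_a, chains_b, folding_partner = "A") {
  if (!length(chains_a) || !length(chains_b))
    stop("both partners need at least one chain")
  if (length(intersect(chains_a, chains_b)))
    stop("partner chain sets must be disjoint")
  if (!folding_partner %in% c("A", "B"))
    stop("folding_partner must be 'A' or 'B'")
  structure(list(A = chains_a, B = chains_b,
                 folding_partner = folding_partner),
            class = "ffl_partition")
}

check_partition <- function(partition, topology) {
  stopifnot(inherits(partition, "ffl_partition"))
  all_ch <- topology$chains
  cover <- c(partition$A, partition$B)
  if (!setequal(cover, all_ch))
    stop("partition does not exhaustively cover chains: topology has {",
         paste(all_ch, collapse = ","), "}, partition covers {",
         paste(cover, collapse = ","), "}")
  invisible(TRUE)
}

partition_atoms <- function(partition, topology) {
  list(A = which(topology$atoms$chain %in% partition$A),
       B = which(topology$atoms$chain %in% partition$B))
}
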
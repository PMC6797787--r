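#' Read a reference structure from a PDB file
#'
#' Parses ATOM/HETATM records via bio3d.  Multi-model files return the
#' first model; atom order, chain ids and coordinates (Angstrom, PDB
#' fixed-width precision) are preserved.
#'
#' @param path PDB file.
#' @param residue_class optional residue-class table (see [ffl_topology()]).
#' @return list with `topology` ([ffl_topology()]) and `frame` (N x 3
#'   coordinate matrix of the first model).
#' @export
read_structure <- function(path, residue_class = NULL) {
  parsed <- parse_pdb(path, multi = FALSE)
  list(topology = parsed$topology,
       frame = matrix(parsed$xyz[1L, ], ncol = 3L, byrow = TRUE))
}

#' Read a trajectory from a multi-model PDB file
#'
#' Frames are returned in file order with 0-based sequential frame indices.
#' If `topology` is supplied, the file's atom count must match it.
#'
#' @param path multi-model PDB file.
#' @param topology optional [ffl_topology()] the frames must conform to;
#'   defaults to the topology parsed from the file itself.
#' @param temperature ensemble temperature in K, recorded on the result.
#' @param stride keep every `stride`-th model (recorded in metadata).
#' @param residue_class optional residue-class table.
#' @return an [ffl_ensemble()].
#' @export
read_trajectory <- function(path, topology = NULL, temperature = 300,
                            stride = 1L, residue_class = NULL) {
  parsed <- parse_pdb(path, multi = TRUE, residue_class = residue_class)
  if (!is.null(topology)) {
    if (ncol(parsed$xyz) != 3L * n_atoms(topology))
      stop("topology mismatch: trajectory has ", ncol(parsed$xyz) / 3,
           " atoms per frame, topology ", n_atoms(topology))
  } else topology <- parsed$topology
  keep <- seq(1L, nrow(parsed$xyz), by = stride)
  ffl_ensemble(topology, parsed$xyz[keep, , drop = FALSE],
               temperature = temperature,
               metadata = list(source = path, stride = as.integer(stride)))
}

## Shared PDB parsing: light pre-scan for line-numbered errors that bio3d
## would swallow, then bio3d::read.pdb for the actual parse.
parse_pdb <- function(path, multi = FALSE, residue_class = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1L, 6L)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) stop("empty structure: no ATOM/HETATM records in ", path)
  bad <- which(is_atom & nchar(lines) < 54L)
  if (length(bad))
    stop("malformed ATOM record at line ", bad[1L], " of ", path,
         " (record shorter than coordinate fields)")
  coords_txt <- substr(lines[is_atom], 31L, 54L)
  co <- suppressWarnings(as.numeric(c(substr(coords_txt, 1L, 8L),
                                      substr(coords_txt, 9L, 16L),
                                      substr(coords_txt, 17L, 24L))))
  if (anyNA(co)) {
    bad_row <- ((which(is.na(co)) - 1L) %% sum(is_atom)) + 1L
    stop("malformed ATOM record at line ", which(is_atom)[bad_row[1L]],
         " of ", path, " (non-numeric coordinate)")
  }
  pdb <- bio3d::read.pdb(path, multi = multi, verbose = FALSE)
  at <- pdb$atom
  chain <- ifelse(is.na(at$chain) | at$chain == "", "A", at$chain)
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem) | elem == ""))
    elem <- guess_element(at$elety)
  else {
    fill <- is.na(elem) | elem == ""
    elem[fill] <- guess_element(at$elety[fill])
  }
  topology <- ffl_topology(data.frame(serial = at$eleno, name = at$elety,
                                      element = elem, chain = chain,
                                      resno = at$resno, resname = at$resid,
                                      stringsAsFactors = FALSE),
                           residue_class = residue_class)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  xyz <- unname(as.matrix(xyz))
  if (!multi) xyz <- xyz[1L, , drop = FALSE]
  list(topology = topology, xyz = xyz)
}

guess_element <- function(name) {
  sym <- sub("^[0-9']*", "", trimws(name))
  sym <- toupper(substr(sym, 1L, 1L))
  sym[sym == ""] <- "X"
  sym
}

#' Write a structure or trajectory as a (multi-model) PDB file
#'
#' @param topology an [ffl_topology()].
#' @param xyz one N x 3 frame, a list of frames, or an n_frames x 3N matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pdb_frames <- function(topology, xyz, path) {
  if (is.list(xyz) && !is.data.frame(xyz)) {
    xyz <- t(vapply(xyz, function(f) as.numeric(t(validate_frame(f, topology))),
                    numeric(3L * n_atoms(topology))))
  } else {
    xyz <- as.matrix(xyz)
    if (ncol(xyz) == 3L) xyz <- matrix(as.numeric(t(xyz)), nrow = 1L)
  }
  at <- topology$atoms
  bio3d::write.pdb(file = path, xyz = xyz, resno = at$resno,
                   resid = at$resname, elety = at$name, chain = at$chain)
  invisible(path)
}
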
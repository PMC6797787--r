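#' Read a per-frame energy table
#'
#' Tab-separated table with header columns `frame`, `E_u`, `G_solv`
#' (kcal/mol by contract); optional columns `dfint` (the solvent-averaged
#' binding potential), complex-mode solvation columns `G_solv_AB`,
#' `G_solv_A`, `G_solv_B`, and per-residue columns named `res_<chain>_<resno>`.
#'
#' @param path TSV file.
#' @return data.frame, one row per record, numeric columns validated.
#' @export
read_energy_table <- function(path) {
  df <- read_tsv(path)
  need <- c("frame", "E_u", "G_solv")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("energy table schema error: missing column(s) ",
         paste(miss, collapse = ", "), " in ", path)
  for (cn in setdiff(names(df), character())) {
    x <- df[[cn]]
    if (is.character(x)) {
      conv <- suppressWarnings(as.numeric(x))
      if (anyNA(conv) & !anyNA(x))
        stop("energy table parse error: non-numeric value in column '", cn,
             "', row ", which(is.na(conv))[1L], " of ", path)
      df[[cn]] <- conv
    }
    if (any(!is.finite(df[[cn]]) & !is.na(df[[cn]])))
      stop("non-finite value in energy table column '", cn, "'")
  }
  df$frame <- as.integer(df$frame)
  df
}

#' Write a per-frame energy table
#'
#' Serializes at 17 significant digits so write-then-read is bit-identical.
#'
#' @param energy data.frame with at least `frame`, `E_u`, `G_solv`.
#' @param path output TSV.
#' @export
write_energy_table <- function(energy, path) {
  need <- c("frame", "E_u", "G_solv")
  miss <- setdiff(need, names(energy))
  if (length(miss)) stop("energy table missing column(s): ",
                         paste(miss, collapse = ", "))
  write_tsv(energy, path)
}

#' Read a residue charge-class table
#'
#' TSV with columns `chain`, `resno` (or `resindex`), `class`
#' (neutral|charged); used to override the default classification in
#' [ffl_topology()].
#'
#' @param path TSV file.
#' @return data.frame with columns chain, resno, class.
#' @export
read_residue_classes <- function(path) {
  df <- read_tsv(path)
  if ("resindex" %in% names(df) && !"resno" %in% names(df))
    names(df)[names(df) == "resindex"] <- "resno"
  need <- c("chain", "resno", "class")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("residue-class table missing column(s): ",
                         paste(miss, collapse = ", "))
  bad <- setdiff(unique(df$class), c("neutral", "charged"))
  if (length(bad)) stop("unknown residue class: ", paste(bad, collapse = ", "))
  df$chain <- as.character(df$chain)
  df$resno <- as.integer(df$resno)
  df
}
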
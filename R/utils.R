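#' @importFrom graphics abline arrows
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a local, explicit RNG seed
#'
#' Saves and restores the global `.Random.seed`, so generator calls never
#' perturb (and are never perturbed by) surrounding RNG state.  Every
#' stochastic routine in the package takes an explicit seed and runs through
#' this helper; there is no wall-clock seeding anywhere.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_local_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Deterministic TSV writer: '.' decimal, header row, doubles at 17
## significant digits so write-then-read is exact.
write_tsv <- function(df, path) {
  stopifnot(is.data.frame(df))
  fmt_col <- function(x) {
    if (is.double(x)) {
      out <- sprintf("%.17g", x)
      out[is.na(x)] <- "NA"
      out
    } else as.character(x)
  }
  cells <- vapply(df, fmt_col, character(nrow(df)))
  if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L)
  if (nrow(df) == 0L) cells <- matrix(character(0), ncol = ncol(df))
  lines <- c(paste(names(df), collapse = "\t"),
             apply(cells, 1L, paste, collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

## Mean and block-analysis standard error of a series, blocks being
## contiguous equal segments in the given order.
block_se <- function(x, n_blocks = 5L) {
  n <- length(x)
  if (n < n_blocks || n_blocks < 2L) return(NA_real_)
  idx <- block_indices(n, n_blocks)
  bm <- vapply(idx, function(i) mean(x[i]), numeric(1))
  stats::sd(bm) / sqrt(n_blocks)
}

block_indices <- function(n, n_blocks) {
  stopifnot(n_blocks >= 1L, n >= n_blocks)
  bounds <- floor(seq(0L, n, length.out = n_blocks + 1L))
  lapply(seq_len(n_blocks), function(b) (bounds[b] + 1L):bounds[b + 1L])
}

## All pairwise distances between rows of two coordinate matrices (Nx3).
cross_dist <- function(xa, xb) {
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * tcrossprod(xa, xb)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

## Distances for a list of index pairs within one coordinate matrix.
pair_dist <- function(x, i, j) {
  sqrt(rowSums((x[i, , drop = FALSE] - x[j, , drop = FALSE])^2))
}
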
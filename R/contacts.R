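#' Native contact set
#'
#' Heavy-atom pair contacts taken from a reference (native) structure,
#' together with the parameters of the smooth switching function that
#' defines the fraction-of-native-contacts order parameter Q.
#'
#' @param contacts data.frame `i`, `j` (1-based atom indices, i < j), `r0`
#'   (native distance, A).
#' @param beta_sw switching steepness, 1/A.
#' @param lambda switching-scale factor (>= 1); the switch midpoint for a
#'   contact sits at `lambda * r0`.
#' @param cutoff,min_seq_sep the extraction parameters, recorded as
#'   metadata on the set.
#' @return `ffl_contacts` object.
#' @export
native_contact_set <- function(contacts, beta_sw = 5, lambda = 1.8,
                               cutoff = NA_real_, min_seq_sep = NA_integer_) {
  contacts <- as.data.frame(contacts)
  if (nrow(contacts)) {
    stopifnot(all(contacts$i < contacts$j), all(contacts$r0 > 0))
    ord <- order(contacts$i, contacts$j)
    contacts <- contacts[ord, , drop = FALSE]
    rownames(contacts) <- NULL
  }
  if (beta_sw <= 0) stop("beta_sw must be > 0")
  if (lambda < 1) stop("lambda must be >= 1")
  structure(list(contacts = contacts, beta_sw = beta_sw, lambda = lambda,
                 cutoff = cutoff, min_seq_sep = min_seq_sep),
            class = "ffl_contacts")
}

#' @export
print.ffl_contacts <- function(x, ...) {
  cat("funnelscape native contacts:", nrow(x$contacts), "pairs",
      sprintf("(beta_sw = %g 1/A, lambda = %g, cutoff = %g A, minsep = %s)\n",
              x$beta_sw, x$lambda, x$cutoff, x$min_seq_sep))
  invisible(x)
}

#' Extract native contacts from a reference structure
#'
#' A pair of heavy atoms is a native contact when the two atoms are closer
#' than `cutoff` in the reference (closed interval: pairs exactly at the
#' cutoff are included) and belong to residues at least `min_seq_sep` apart
#' in sequence.  Atoms on distinct chains are always sequence-eligible
#' (inter-molecular contacts use an effective separation of 0).
#'
#' @param reference N x 3 reference coordinates (A).
#' @param topology an [ffl_topology()].
#' @param cutoff distance cutoff, A.
#' @param min_seq_sep minimum residue separation within a chain.
#' @param beta_sw,lambda switching parameters stored on the result
#'   (see [native_contact_set()]).
#' @param intermolecular_only keep only pairs spanning two chains (used
#'   when defining the bound-state contact set of a complex).
#' @return an `ffl_contacts` set, ordered by (i, j).
#' @export
extract_native_contacts <- function(reference, topology, cutoff = 4.5,
                                    min_seq_sep = 4L, beta_sw = 5,
                                    lambda = 1.8,
                                    intermolecular_only = FALSE) {
  reference <- validate_frame(reference, topology)
  at <- topology$atoms
  heavy <- which(toupper(at$element) != "H")
  if (length(heavy) < 2L) stop("fewer than two heavy atoms in reference")
  xs <- reference[heavy, , drop = FALSE]
  d <- cross_dist(xs, xs)
  ridx <- at$ridx[heavy]
  chain <- at$chain[heavy]
  same_chain <- outer(chain, chain, "==")
  sep_ok <- (!same_chain) | (abs(outer(ridx, ridx, "-")) >= min_seq_sep)
  if (intermolecular_only) sep_ok <- sep_ok & !same_chain
  hit <- which(upper.tri(d) & d <= cutoff & sep_ok, arr.ind = TRUE)
  if (nrow(hit) == 0L)
    warning("empty contact set: no pairs within ", cutoff,
            " A at sequence separation >= ", min_seq_sep)
  contacts <- data.frame(i = heavy[hit[, 1L]], j = heavy[hit[, 2L]],
                         r0 = d[hit])
  native_contact_set(contacts, beta_sw = beta_sw, lambda = lambda,
                     cutoff = cutoff, min_seq_sep = as.integer(min_seq_sep))
}

#' Fraction of native contacts of a single frame
#'
#' Smooth switching form
#' `Q = (1/N) * sum_(i,j) 1 / (1 + exp(beta_sw * (r_ij - lambda * r0_ij)))`,
#' continuous, bounded in (0, 1), and monotonically non-increasing in every
#' contact distance.
#'
#' @param frame N x 3 coordinates (A).
#' @param contacts an `ffl_contacts` set.
#' @return Q, dimensionless.
#' @export
compute_q <- function(frame, contacts) {
  stopifnot(inherits(contacts, "ffl_contacts"))
  cc <- contacts$contacts
  if (nrow(cc) == 0L) stop("undefined Q: empty native contact set")
  frame <- as.matrix(frame)
  r <- pair_dist(frame, cc$i, cc$j)
  mean(1 / (1 + exp(contacts$beta_sw * (r - contacts$lambda * cc$r0))))
}

#' Q for every frame of an ensemble
#'
#' @param ensemble an [ffl_ensemble()].
#' @param contacts an `ffl_contacts` set.
#' @return data.frame with columns `frame` (the ensemble's 0-based frame
#'   index) and `Q`, in frame order.
#' @export
compute_q_series <- function(ensemble, contacts) {
  stopifnot(inherits(ensemble, "ffl_ensemble"), inherits(contacts, "ffl_contacts"))
  cc <- contacts$contacts
  if (nrow(cc) == 0L) stop("undefined Q: empty native contact set")
  ci <- 3L * (cc$i - 1L); cj <- 3L * (cc$j - 1L)
  xyz <- ensemble$xyz
  dx <- xyz[, ci + 1L, drop = FALSE] - xyz[, cj + 1L, drop = FALSE]
  dy <- xyz[, ci + 2L, drop = FALSE] - xyz[, cj + 2L, drop = FALSE]
  dz <- xyz[, ci + 3L, drop = FALSE] - xyz[, cj + 3L, drop = FALSE]
  r <- sqrt(dx * dx + dy * dy + dz * dz)
  sw <- 1 / (1 + exp(contacts$beta_sw *
                       sweep(r, 2L, contacts$lambda * cc$r0, "-")))
  data.frame(frame = ensemble$frame_index, Q = rowMeans(sw))
}

#' Resolve a selection token to atom indices
#'
#' Selection mini-language: each token is `chain:resno[:atomname]`, e.g.
#' `"A:5:CA"` or `"B:12"` (all atoms of the residue).  A vector of tokens
#' selects the union.
#'
#' @param topology an [ffl_topology()].
#' @param tokens character vector of selection tokens.
#' @return integer atom indices (1-based).
#' @export
select_atoms <- function(topology, tokens) {
  at <- topology$atoms
  out <- integer(0)
  unmatched <- character(0)
  for (tok in tokens) {
    parts <- strsplit(tok, ":", fixed = TRUE)[[1L]]
    if (length(parts) < 2L) { unmatched <- c(unmatched, tok); next }
    hit <- at$chain == parts[1L] & at$resno == as.integer(parts[2L])
    if (length(parts) >= 3L) hit <- hit & at$name == parts[3L]
    if (!any(hit)) { unmatched <- c(unmatched, tok); next }
    out <- c(out, which(hit))
  }
  if (length(unmatched))
    stop("selection error: unmatched token(s): ",
         paste(unmatched, collapse = ", "))
  sort(unique(out))
}

#' Geometric contact / hydrogen-bond population over an ensemble
#'
#' The fraction of frames in which any atom pair between the two
#' selections satisfies the geometric criterion: donor-acceptor heavy-atom
#' distance <= `d_max`, and, when a hydrogen selection is supplied,
#' donor-H-acceptor angle >= `theta_min` for the closest donor-acceptor
#' pair.  Without hydrogens (the usual case for bead models and heavy-atom
#' PDBs) the distance criterion alone is applied.
#'
#' @param ensemble an [ffl_ensemble()].
#' @param sel_i,sel_j selection token vectors (see [select_atoms()]) for
#'   the two sides (e.g. donor and acceptor heavy atoms).
#' @param d_max distance criterion, A.
#' @param sel_h optional selection for the donor hydrogen(s).
#' @param theta_min angle criterion, degrees.
#' @return `ffl_population`: list with `descriptor`, `fraction` in [0, 1],
#'   `n_frames`.
#' @export
contact_population <- function(ensemble, sel_i, sel_j, d_max = 3.5,
                               sel_h = NULL, theta_min = 120) {
  top <- ensemble$topology
  ai <- select_atoms(top, sel_i)
  aj <- select_atoms(top, sel_j)
  ah <- if (!is.null(sel_h)) select_atoms(top, sel_h) else integer(0)
  nf <- n_frames(ensemble)
  ok <- logical(nf)
  for (fr in seq_len(nf)) {
    x <- frame_coords(ensemble, fr)
    d <- cross_dist(x[ai, , drop = FALSE], x[aj, , drop = FALSE])
    hit <- which(d <= d_max, arr.ind = TRUE)
    if (nrow(hit) == 0L) next
    if (length(ah) == 0L) { ok[fr] <- TRUE; next }
    ## angle check on the closest qualifying pair, best hydrogen
    best <- hit[which.min(d[hit]), ]
    don <- x[ai[best[1L]], ]; acc <- x[aj[best[2L]], ]
    ang <- max(vapply(ah, function(h) {
      v1 <- don - x[h, ]; v2 <- acc - x[h, ]
      cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      acos(pmin(1, pmax(-1, cosang))) * 180 / pi
    }, numeric(1)))
    ok[fr] <- ang >= theta_min
  }
  structure(list(descriptor = paste(paste(sel_i, collapse = ","), "--",
                                    paste(sel_j, collapse = ",")),
                 fraction = mean(ok), n_frames = nf),
            class = "ffl_population")
}

#' @export
print.ffl_population <- function(x, ...) {
  cat(sprintf("contact population %s: %.1f%% of %d frames\n",
              x$descriptor, 100 * x$fraction, x$n_frames))
  invisible(x)
}
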
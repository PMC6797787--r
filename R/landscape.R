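#' Reduce (Q, f) samples to the landscape f(Q)
#'
#' Bins Q into half-open intervals `[low, high)` of width `bin_width`
#' (the last bin is closed at Q = 1) and takes the arithmetic mean of f in
#' each occupied bin.  Reported free energies are referenced to the
#' lowest-Q occupied bin (the unfolded anchor, f(Q = 0)).  Empty bins are
#' kept as gaps -- nothing is interpolated.
#'
#' @param samples data.frame with columns `Q` (in [0, 1]) and `f`
#'   (kcal/mol); a `frame` column, if present, is ignored here.
#' @param bin_width bin width in Q (default 0.05, i.e. 20 bins).
#' @param temperature temperature in K, recorded on the landscape.
#' @return `ffl_landscape`: list with `bins` (data.frame `q_low`, `q_high`,
#'   `q_mid`, `n`, `f_mean` raw mean, `f_ref` referenced mean, `f_se`),
#'   `reference_offset`, `temperature`, `bin_width`.
#' @export
bin_landscape <- function(samples, bin_width = 0.05, temperature = 300) {
  samples <- as.data.frame(samples)
  if (!all(c("Q", "f") %in% names(samples)))
    stop("samples need columns Q and f")
  if (nrow(samples) < 1L) stop("need at least one (Q, f) sample")
  if (any(samples$Q < 0 | samples$Q > 1)) stop("Q outside [0, 1]")
  bins <- q_bins(bin_width)
  b <- assign_bins(samples$Q, bin_width, nrow(bins))
  n <- tabulate(b, nbins = nrow(bins))
  f_mean <- rep(NA_real_, nrow(bins))
  f_se <- rep(NA_real_, nrow(bins))
  agg_m <- tapply(samples$f, b, mean)
  f_mean[as.integer(names(agg_m))] <- agg_m
  agg_s <- tapply(samples$f, b, function(v)
    if (length(v) >= 2L) stats::sd(v) / sqrt(length(v)) else NA_real_)
  f_se[as.integer(names(agg_s))] <- agg_s
  q_mean <- rep(NA_real_, nrow(bins))
  agg_q <- tapply(samples$Q, b, mean)
  q_mean[as.integer(names(agg_q))] <- agg_q
  occ <- which(n > 0L)
  if (length(occ) == 1L)
    warning("single-bin landscape: all samples fall in one Q bin; ",
            "slope undefined downstream")
  ref <- f_mean[occ[1L]]
  bins$n <- n
  bins$q_mean <- q_mean
  bins$f_mean <- f_mean
  bins$f_ref <- f_mean - ref
  bins$f_se <- f_se
  structure(list(bins = bins, reference_offset = ref,
                 temperature = temperature, bin_width = bin_width),
            class = "ffl_landscape")
}

q_bins <- function(bin_width) {
  edges <- seq(0, 1, by = bin_width)
  if (abs(edges[length(edges)] - 1) > 1e-12) edges <- c(edges, 1)
  data.frame(q_low = edges[-length(edges)], q_high = edges[-1L],
             q_mid = (edges[-length(edges)] + edges[-1L]) / 2)
}

## half-open [low, high) bins; Q = 1 goes into the last bin
assign_bins <- function(q, bin_width, nb) {
  b <- findInterval(q, seq(0, 1, by = bin_width),
                    rightmost.closed = FALSE, left.open = FALSE)
  pmin(b, nb)
}

#' @export
print.ffl_landscape <- function(x, ...) {
  occ <- x$bins[x$bins$n > 0L, ]
  cat(sprintf("funnelscape landscape: %d/%d occupied bins (width %g), T = %g K\n",
              nrow(occ), nrow(x$bins), x$bin_width, x$temperature))
  print(occ[, c("q_mid", "n", "f_ref", "f_se")], row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.ffl_landscape <- function(x, ...) x$bins

#' Free-energy profile F(Q) from the Q distribution
#'
#' `F(Q) = -kB T ln P(Q)` with P from normalized bin counts, offset so the
#' minimum of F is zero.  This profile reflects the probability of
#' observing a given Q and differs from the landscape f(Q) by the
#' configurational-entropy term.
#'
#' @param q_samples numeric vector of Q values in [0, 1].
#' @param bin_width bin width in Q.
#' @param temperature temperature in K.
#' @return `ffl_profile`: list with `bins` (data.frame `q_low`, `q_high`,
#'   `q_mid`, `n`, `P`, `F`), `temperature`, `bin_width`.  Empty bins
#'   carry `F = NA`.
#' @export
free_energy_profile <- function(q_samples, bin_width = 0.05,
                                temperature = 300) {
  q_samples <- as.numeric(q_samples)
  if (length(q_samples) < 1L) stop("need at least one Q sample")
  if (any(q_samples < 0 | q_samples > 1)) stop("Q outside [0, 1]")
  bins <- q_bins(bin_width)
  b <- assign_bins(q_samples, bin_width, nrow(bins))
  n <- tabulate(b, nbins = nrow(bins))
  P <- n / sum(n)
  F <- ifelse(n > 0L, -kB * temperature * log(P), NA_real_)
  F <- F - min(F, na.rm = TRUE)
  bins$n <- n; bins$P <- P; bins$F <- F
  structure(list(bins = bins, temperature = temperature,
                 bin_width = bin_width), class = "ffl_profile")
}

#' @export
print.ffl_profile <- function(x, ...) {
  occ <- x$bins[x$bins$n > 0L, ]
  cat(sprintf("free-energy profile F(Q): %d occupied bins, T = %g K\n",
              nrow(occ), x$temperature))
  print(occ[, c("q_mid", "n", "P", "F")], row.names = FALSE)
  invisible(x)
}

#' Configurational-entropy profile T S_config(Q)
#'
#' Uses the identity `F(Q) = f(Q) - T S_config(Q)`: per bin occupied in
#' both inputs, `T S_config(Q) = f(Q) - F(Q)`.  Both inputs carry their
#' own reference conventions (the landscape is referenced to its lowest-Q
#' occupied bin, the profile to its minimum), so the entropy profile is
#' defined up to an additive constant; it is reported re-referenced to the
#' lowest-Q shared bin.
#'
#' @param landscape an [bin_landscape()] result.
#' @param profile an [free_energy_profile()] result (same bin width).
#' @return data.frame `q_mid`, `n`, `TS_config` (kcal/mol) over shared
#'   occupied bins.
#' @export
config_entropy_profile <- function(landscape, profile) {
  stopifnot(inherits(landscape, "ffl_landscape"), inherits(profile, "ffl_profile"))
  if (abs(landscape$bin_width - profile$bin_width) > 1e-12)
    stop("landscape and profile use different bin widths")
  lb <- landscape$bins; pb <- profile$bins
  shared <- which(lb$n > 0L & pb$n > 0L)
  if (!length(shared)) stop("empty-overlap error: no bin occupied in both inputs")
  ts <- lb$f_ref[shared] - pb$F[shared]
  ts <- ts - ts[1L]
  data.frame(q_mid = lb$q_mid[shared], n = lb$n[shared], TS_config = ts)
}

#' Funnel slope with block-analysis errors
#'
#' Fits an unweighted least-squares line to the occupied-bin points
#' (mean Q, mean f) of the landscape.  Using each bin's mean Q rather
#' than its midpoint keeps the fit exact when the samples lie exactly on
#' a line, whatever the Q distribution.  The standard error of the
#' slope comes from block analysis: the samples are split, in the given
#' frame order, into `n_blocks` contiguous equal segments; each block is
#' binned and fitted identically, and the SE is the standard deviation of
#' the per-block slopes divided by sqrt(n_blocks).
#'
#' @param samples data.frame with columns `Q`, `f` and optionally `frame`
#'   (rows are taken to be in frame order).
#' @param bin_width bin width in Q.
#' @param n_blocks number of contiguous blocks for the error estimate.
#' @param q_range optional c(min, max): restrict the fit to bins whose
#'   midpoint lies inside the range (default: all occupied bins).
#' @param weighted count-weighted fit instead of the default unweighted
#'   fit to the displayed f(Q) curve.
#' @return `ffl_slopefit`: list with `slope`, `intercept`, `slope_se`
#'   (kcal/mol per unit Q), `n_blocks`, `bin_width`, `q_range`, `n_bins`,
#'   `n_samples`.
#' @export
fit_slope <- function(samples, bin_width = 0.05, n_blocks = 5L,
                      q_range = NULL, weighted = FALSE) {
  samples <- as.data.frame(samples)
  if (!all(c("Q", "f") %in% names(samples)))
    stop("samples need columns Q and f")
  one_fit <- function(df) {
    ls <- bin_landscape(df, bin_width = bin_width)$bins
    occ <- ls$n > 0L
    if (!is.null(q_range))
      occ <- occ & ls$q_mid >= q_range[1L] & ls$q_mid <= q_range[2L]
    if (sum(occ) < 2L) return(NULL)
    w <- if (weighted) ls$n[occ] else rep(1, sum(occ))
    fit <- stats::lm.wfit(cbind(1, ls$q_mean[occ]), ls$f_mean[occ], w)
    c(intercept = fit$coefficients[[1L]], slope = fit$coefficients[[2L]],
      n_bins = sum(occ))
  }
  full <- one_fit(samples)
  if (is.null(full))
    stop("slope undefined: fewer than two occupied bins in fit range")
  n <- nrow(samples)
  slope_se <- NA_real_
  if (n_blocks >= 2L && n >= n_blocks) {
    bslopes <- vapply(block_indices(n, n_blocks), function(idx) {
      bf <- one_fit(samples[idx, , drop = FALSE])
      if (is.null(bf))
        stop("block-degenerate error: a block spans fewer than two ",
             "occupied bins; use fewer blocks")
      bf[["slope"]]
    }, numeric(1))
    slope_se <- stats::sd(bslopes) / sqrt(n_blocks)
  }
  structure(list(slope = full[["slope"]], intercept = full[["intercept"]],
                 slope_se = slope_se, n_blocks = as.integer(n_blocks),
                 bin_width = bin_width,
                 q_range = q_range %||% c(0, 1),
                 n_bins = as.integer(full[["n_bins"]]), n_samples = n),
            class = "ffl_slopefit")
}

#' @export
print.ffl_slopefit <- function(x, ...) {
  cat(sprintf("funnel slope: %.4g +/- %.2g kcal/mol per unit Q (%d bins, %d blocks)\n",
              x$slope, x$slope_se, x$n_bins, x$n_blocks))
  invisible(x)
}

#' Free-energy gain for forming a fraction of native contacts
#'
#' The magnitude of the free-energy decrease when a fraction `delta_q` of
#' the native contacts forms, `|slope| * delta_q`.  A slope of -48.2
#' kcal/mol, for example, means forming 10% of the native contacts gains
#' 4.8 kcal/mol.
#'
#' @param fit an [fit_slope()] result (or any object with `$slope`).
#' @param delta_q fraction of native contacts formed, in (0, 1].
#' @return gain in kcal/mol (positive for a funneled landscape).
#' @export
free_energy_gain <- function(fit, delta_q) {
  if (!is.numeric(delta_q) || delta_q <= 0 || delta_q > 1)
    stop("delta_q must lie in (0, 1]")
  slope <- fit$slope
  if (is.list(slope)) slope <- slope$slope   # funnel_fit carries a slopefit
  abs(slope) * delta_q
}

#' 3D funnel surface of revolution
#'
#' Rotates the referenced landscape curve about the Q axis: each occupied
#' bin becomes a ring at radius proportional to (1 - Q) and height equal
#' to the referenced f(Q), so the native state (Q = 1) sits at the funnel
#' apex.
#'
#' @param landscape an [bin_landscape()] result.
#' @param azimuthal_resolution number of points around each ring.
#' @param radius_scale radius at Q = 0.
#' @return data.frame mesh with columns `q_mid`, `phi`, `x`, `y`, `z`.
#' @export
funnel_surface <- function(landscape, azimuthal_resolution = 60L,
                           radius_scale = 1) {
  stopifnot(inherits(landscape, "ffl_landscape"))
  occ <- landscape$bins[landscape$bins$n > 0L, ]
  if (nrow(occ) < 2L) stop("need at least two occupied bins for a surface")
  phi <- seq(0, 2 * pi, length.out = azimuthal_resolution + 1L)[-1L]
  rings <- lapply(seq_len(nrow(occ)), function(k) {
    r <- radius_scale * (1 - occ$q_mid[k])
    data.frame(q_mid = occ$q_mid[k], phi = phi,
               x = r * cos(phi), y = r * sin(phi), z = occ$f_ref[k])
  })
  do.call(rbind, rings)
}
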
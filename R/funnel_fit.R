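#' Fit a folding funnel to (Q, f) samples
#'
#' The package's central estimator.  Given per-frame samples of the order
#' parameter Q and the effective energy f (kcal/mol), it constructs the
#' Q-binned landscape f(Q) referenced to the unfolded anchor, the
#' probability-derived free-energy profile F(Q), the
#' configurational-entropy profile connecting the two, and the funnel
#' slope (the global funneledness) with a block-analysis standard error.
#'
#' @param formula a formula `f ~ Q` naming the energy and order-parameter
#'   columns of `data`.
#' @param data data.frame holding the samples, in frame order; an optional
#'   `frame` column is carried through to outputs.
#' @param bin_width Q bin width (default 0.05).
#' @param n_blocks contiguous blocks for the slope error (default 5).
#' @param temperature temperature in K (default 300).
#' @param q_range optional fit range in Q (see [fit_slope()]).
#' @param weighted count-weighted slope fit (default unweighted).
#' @return an object of class `funnel_fit` with components `landscape`,
#'   `profile`, `entropy`, `slope` and the call;  supports `print()`,
#'   `summary()`, `coef()` (intercept and slope of the funnel line),
#'   `predict()` (referenced f at given Q), `residuals()` (sample f minus
#'   the funnel line), `simulate()` and `plot()`.
#' @examples
#' sam <- generate_slope_samples(slope = -48.2, noise_sd = 3,
#'                               n = 5000, seed = 1)
#' fit <- funnel_fit(f ~ Q, sam)
#' coef(fit)
#' free_energy_gain(fit, 0.1)
#' @export
funnel_fit <- function(formula, data, bin_width = 0.05, n_blocks = 5L,
                       temperature = 300, q_range = NULL, weighted = FALSE) {
  mf <- stats::model.frame(formula, data)
  samples <- data.frame(Q = mf[[2L]], f = mf[[1L]])
  if ("frame" %in% names(data)) samples$frame <- data$frame
  landscape <- bin_landscape(samples, bin_width = bin_width,
                             temperature = temperature)
  profile <- free_energy_profile(samples$Q, bin_width = bin_width,
                                 temperature = temperature)
  entropy <- tryCatch(config_entropy_profile(landscape, profile),
                      error = function(e) NULL)
  slope <- fit_slope(samples, bin_width = bin_width, n_blocks = n_blocks,
                     q_range = q_range, weighted = weighted)
  structure(list(landscape = landscape, profile = profile,
                 entropy = entropy, slope = slope, samples = samples,
                 temperature = temperature, call = match.call()),
            class = "funnel_fit")
}

#' @export
print.funnel_fit <- function(x, ...) {
  cat("Folding funnel fit\n")
  cat("  samples:", nrow(x$samples), " bins occupied:",
      sum(x$landscape$bins$n > 0L), "/", nrow(x$landscape$bins), "\n")
  cat(sprintf("  slope: %.4g +/- %.2g kcal/mol per unit Q\n",
              x$slope$slope, x$slope$slope_se))
  invisible(x)
}

#' @export
summary.funnel_fit <- function(object, ...) {
  s <- object$slope
  out <- list(slope = s$slope, slope_se = s$slope_se,
              intercept = s$intercept,
              gain_per_10pct = free_energy_gain(s, 0.1),
              n_samples = nrow(object$samples),
              n_bins = s$n_bins, n_blocks = s$n_blocks,
              bin_width = s$bin_width, temperature = object$temperature)
  class(out) <- "summary.funnel_fit"
  out
}

#' @export
print.summary.funnel_fit <- function(x, ...) {
  cat("Folding funnel fit summary\n")
  cat(sprintf("  slope      : %.4g +/- %.2g kcal/mol per unit Q (%d blocks)\n",
              x$slope, x$slope_se, x$n_blocks))
  cat(sprintf("  intercept  : %.4g kcal/mol\n", x$intercept))
  cat(sprintf("  gain per 10%% native contacts: %.2f kcal/mol\n",
              x$gain_per_10pct))
  cat(sprintf("  %d samples in %d occupied bins (width %g), T = %g K\n",
              x$n_samples, x$n_bins, x$bin_width, x$temperature))
  invisible(x)
}

#' @export
coef.funnel_fit <- function(object, ...) {
  c(intercept = object$slope$intercept, slope = object$slope$slope)
}

#' @export
predict.funnel_fit <- function(object, newdata = NULL, ...) {
  q <- if (is.null(newdata)) object$samples$Q
       else if (is.data.frame(newdata)) newdata$Q else as.numeric(newdata)
  object$slope$intercept + object$slope$slope * q
}

#' @export
residuals.funnel_fit <- function(object, ...) {
  object$samples$f - predict(object, object$samples$Q)
}

#' @export
simulate.funnel_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(seed)) stop("simulate.funnel_fit requires an explicit seed")
  n <- nrow(object$samples)
  sd_res <- stats::sd(residuals(object))
  with_local_seed(seed, {
    lapply(seq_len(nsim), function(k) {
      q <- sample(object$samples$Q, n, replace = TRUE)
      data.frame(frame = seq_len(n) - 1L, Q = q,
                 f = object$slope$intercept + object$slope$slope * q +
                   stats::rnorm(n, 0, sd_res))
    })
  })
}

#' @export
plot.funnel_fit <- function(x, ...) {
  lb <- x$landscape$bins
  occ <- lb$n > 0L
  plot(lb$q_mid[occ], lb$f_ref[occ], pch = 19,
       xlab = "Q (fraction of native contacts)",
       ylab = "f(Q) - f(Q = 0)  [kcal/mol]",
       main = "Folding free-energy landscape", ...)
  se <- lb$f_se[occ]
  ok <- !is.na(se)
  arrows(lb$q_mid[occ][ok], (lb$f_ref[occ] - se)[ok],
         lb$q_mid[occ][ok], (lb$f_ref[occ] + se)[ok],
         angle = 90, code = 3, length = 0.02)
  abline(a = x$slope$intercept - x$landscape$reference_offset,
         b = x$slope$slope, lty = 2)
  invisible(x)
}
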
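#' Normalize raw fluorescence to percent cleavage
#'
#' Converts raw fluorescence to percent by setting the average fluorescence
#' of the RNase-treated (fully cleaved) control to 100 and the no-enzyme
#' control to 0, then averages the replicate traces pointwise.
#'
#' @param series A `fluorescence_series` (see [simulate_fluorescence()]):
#'   list with `label`, `times`, and a replicates x times `values` matrix.
#' @param positive_mean Mean raw fluorescence of RNase-treated reactions.
#' @param negative_mean Mean raw fluorescence of no-enzyme reactions.
#' @return A list with `label`, `times` and `percent` (replicate-averaged).
#' @export
normalize_percent <- function(series, positive_mean, negative_mean) {
  if (!is.finite(positive_mean) || !is.finite(negative_mean) ||
      positive_mean <= negative_mean)
    stop("degenerate normalization references: positive_mean must exceed negative_mean")
  pct <- 100 * (series$values - negative_mean) / (positive_mean - negative_mean)
  list(label = series$label, times = series$times, percent = colMeans(pct))
}

#' Fit the integrated first-order rate equation
#'
#' Least-squares fit of F(t) = Fmax * (1 - exp(-k t)) to a percent-cleavage
#' time course (no offset term; the model is forced through F(0) = 0).
#' Initial guesses: Fmax from the maximum observed value; k from ln(2) over
#' the first time the trace crosses Fmax/2 (falling back to 1/t_max).
#' Fitting uses Levenberg-Marquardt least squares with bounds
#' Fmax in [0, 200] (noise can push percentages above 100), k >= 0; if that
#' fails to converge a Nelder-Mead minimization of the RSS is used and the
#' fit is flagged unconverged.
#'
#' @param times Strictly increasing times, minutes.
#' @param percent_values Percent cleavage values (one per time point).
#' @return A list of class `kinetic_fit`: `f_max` (percent), `k` (per min),
#'   `v0 = f_max * k` (percent/min), `rss`, `n_points`, `converged`.
#' @export
fit_exponential <- function(times, percent_values) {
  if (length(times) < 3) stop("need at least 3 points")
  if (is.unsorted(times, strictly = TRUE)) stop("times must be strictly increasing")
  if (length(times) != length(percent_values)) stop("times/values length mismatch")
  y <- as.numeric(percent_values)
  if (all(abs(y) < .Machine$double.eps)) {
    warning("all-zero data; returning k = 0")
    return(kinetic_fit(0, 0, 0, length(y), TRUE))
  }
  fmax0 <- max(y, 1e-6)
  above <- which(y >= fmax0 / 2 & times > 0)
  k0 <- if (length(above) > 0) log(2) / times[above[1]] else 1 / max(times)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ fmax * (1 - exp(-k * t)),
      data = list(y = y, t = times),
      start = list(fmax = fmax0, k = k0),
      lower = c(0, 0), upper = c(200, Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                           ptol = 1e-14)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    est <- stats::coef(fit)
    return(kinetic_fit(est[["fmax"]], est[["k"]],
                       sum(stats::residuals(fit)^2), length(y), TRUE))
  }
  # fallback: direct RSS minimization from the same initial guesses
  rssfun <- function(par) sum((y - par[1] * (1 - exp(-par[2] * times)))^2)
  opt <- stats::optim(c(fmax0, k0), rssfun, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  warning("Levenberg-Marquardt fit did not converge (initial guesses Fmax = ",
          signif(fmax0, 4), ", k = ", signif(k0, 4),
          "); reporting Nelder-Mead minimum")
  kinetic_fit(max(opt$par[1], 0), max(opt$par[2], 0), opt$value, length(y),
              FALSE)
}

kinetic_fit <- function(f_max, k, rss, n_points, converged) {
  structure(list(f_max = f_max, k = k, v0 = f_max * k, rss = rss,
                 n_points = n_points, converged = converged),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("kinetic_fit: Fmax = %.4g%%, k = %.4g /min, v0 = %.4g %%/min (rss %.3g, n %d%s)\n",
              x$f_max, x$k, x$v0, x$rss, x$n_points,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Initial reaction velocity
#'
#' The derivative of F(t) = Fmax * (1 - exp(-k t)) at t = 0, i.e. the
#' product Fmax * k, used to compare cleavage activity across probe
#' sequences.
#'
#' @param f_max Presumed maximum fluorescence, percent (>= 0).
#' @param k Observed rate constant, per minute (>= 0).
#' @return Initial velocity in percent/min.
#' @examples
#' initial_velocity(84.23, 6.73e-2) # 5.669 (to printed precision)
#' @export
initial_velocity <- function(f_max, k) {
  if (any(f_max < 0) || any(k < 0)) stop("f_max and k must be >= 0")
  f_max * k
}

#' Split motifs into primary and suboptimal by initial velocity
#'
#' Sorts motifs by initial velocity (descending) and takes as primary the
#' largest prefix whose smallest velocity is at least `fold_threshold` times
#' the largest velocity outside the prefix. If no prefix achieves the
#' separation, no motif is called primary. Ties are never split: a prefix
#' boundary requires a strict decrease.
#'
#' @param motifs Character vector of motif names.
#' @param v0 Numeric vector of initial velocities (same length).
#' @param fold_threshold Required fold separation (default 5).
#' @return A list with `primary` and `suboptimal` data.frames (columns
#'   `motif`, `v0`, sorted by descending v0).
#' @export
rank_motifs <- function(motifs, v0, fold_threshold = 5) {
  if (length(motifs) != length(v0)) stop("motifs/v0 length mismatch")
  if (length(motifs) < 2) stop("need at least 2 motifs to rank")
  ord <- order(-v0, motifs)
  d <- data.frame(motif = motifs[ord], v0 = v0[ord])
  n <- nrow(d)
  split_at <- 0L
  for (j in seq_len(n - 1)) {
    if (d$v0[j] > d$v0[j + 1] && d$v0[j] >= fold_threshold * d$v0[j + 1])
      split_at <- j
  }
  list(primary = d[seq_len(split_at), , drop = FALSE],
       suboptimal = d[setdiff(seq_len(n), seq_len(split_at)), , drop = FALSE])
}
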
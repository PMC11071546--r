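#' Raw LOO importance log-ratios for one observation
#'
#' The importance ratio between the LOO posterior for observation i and the
#' full-data posterior is proportional to 1/likelihood of the held-out point,
#' so the unnormalized log-ratio is simply the negated pointwise
#' log-likelihood, one entry per posterior draw. No shifting is applied here;
#' normalization happens at the self-normalization boundary.
#'
#' @param loglik_column numeric vector, `loglik_column[k]` the log-likelihood
#'   of the held-out observation under draw k.
#' @return `-loglik_column`.
#' @export
raw_loo_log_ratios <- function(loglik_column) {
  bad <- which(!is.finite(loglik_column))
  if (length(bad)) {
    stop("non-finite log-likelihood at draw ", bad[1L], call. = FALSE)
  }
  -loglik_column
}

#' Self-normalize log importance ratios onto the simplex
#'
#' Computes `w_k = exp(r_k - logsumexp(r))`. Invariant to additive shifts of
#' the log-ratios, which is what cancels every unknown normalizing constant in
#' the pipeline.
#'
#' @param log_ratios numeric vector of unnormalized log importance ratios;
#'   `-Inf` entries are allowed (zero weight) but at least one entry must be
#'   finite.
#' @return A weight vector summing to one.
#' @export
self_normalize <- function(log_ratios) {
  if (anyNA(log_ratios) || any(log_ratios == Inf)) {
    stop("log ratios must not contain NA or +Inf", call. = FALSE)
  }
  m <- max(log_ratios)
  if (!is.finite(m)) stop("degenerate weights: all log ratios are -Inf", call. = FALSE)
  w <- exp(log_ratios - m)
  w / sum(w)
}

#' Fit a generalized Pareto distribution to tail excesses
#'
#' Profile-posterior point estimate of the two-parameter GPD (shape k, scale
#' sigma) from excesses over a tail threshold, with a weakly informative
#' regularization of the shape toward 0.5 that stabilizes small tails. The
#' shape convention is the one standard in importance-sampling diagnostics:
#' k > 0 means a polynomial tail (k >= 1: infinite variance), k = 0 the
#' exponential limit, k < 0 a bounded tail.
#'
#' @param tail_excesses positive excesses of the largest weights over the
#'   tail threshold.
#' @param prior_adjust apply the shape regularization toward 0.5 (default).
#' @param min_grid_pts grid resolution constant of the profile search.
#' @return A list with `khat`, `sigma` and `n` (the tail size used). Fewer
#'   than 5 excesses returns `khat = NA` (insufficient tail, no fit).
#' @export
fit_gpd <- function(tail_excesses, prior_adjust = TRUE, min_grid_pts = 30L) {
  x <- tail_excesses[is.finite(tail_excesses)]
  if (any(x < 0)) stop("tail excesses must be non-negative", call. = FALSE)
  x <- sort.int(x)
  N <- length(x)
  if (N < 5L || x[N] <= 0) {
    return(list(khat = NA_real_, sigma = NA_real_, n = N))
  }
  M <- min_grid_pts + floor(sqrt(N))
  jj <- seq_len(M)
  xstar <- x[floor(N / 4 + 0.5)]
  if (xstar <= 0) xstar <- min(x[x > 0])
  # profile grid over b = k/sigma; prior scale constant 3 as in the standard rule
  b <- 1 / x[N] + (1 - sqrt(M / (jj - 0.5))) / (3 * xstar)
  k_b <- vapply(b, function(bi) mean(log1p(-bi * x)), 0.0)
  ok <- is.finite(k_b) & k_b != 0 & b != 0
  b <- b[ok]; k_b <- k_b[ok]
  l_b <- N * (log(-b / k_b) - k_b - 1)
  w <- exp(l_b - max(l_b))
  b_hat <- sum(b * w) / sum(w)
  khat <- mean(log1p(-b_hat * x))
  sigma <- -khat / b_hat
  if (prior_adjust) khat <- (khat * N + 5) / (N + 10)
  list(khat = khat, sigma = sigma, n = N)
}

# inverse CDF of the GPD (threshold 0): used for smoothing and by test oracles
qgpd <- function(p, khat, sigma) {
  if (abs(khat) < 1e-12) -sigma * log1p(-p) else sigma * expm1(-khat * log1p(-p)) / khat
}

# tail size rule M = ceiling(min(0.2 s, 3 sqrt(s)))
psis_tail_size <- function(s) as.integer(ceiling(min(0.2 * s, 3 * sqrt(s))))

#' Pareto-smooth a self-normalized weight vector
#'
#' Replaces the largest M weights by expected order statistics (rank
#' quantiles) of a generalized Pareto distribution fitted to their excesses
#' over the tail threshold (the (s-M)-th order statistic), caps them at the
#' largest raw weight, and renormalizes. The fitted shape is reported as the
#' k-hat reliability diagnostic. Draw order is preserved.
#'
#' With fewer than 25 draws smoothing is skipped and the weights are returned
#' raw, with k-hat from whatever tail is available. A degenerate tail (no
#' variation above the threshold) reports the stable sentinel `khat = -Inf`:
#' constant weights are the best case, not a failure.
#'
#' @param weights self-normalized weight vector (sums to one).
#' @return An object of class `is_weights` with fields `log_ratios`,
#'   `weights`, `khat`, `gpd_scale`, `n_tail`, `smoothed`.
#' @export
pareto_smooth <- function(weights) {
  s <- length(weights)
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8) {
    stop("weights must be a self-normalized simplex vector", call. = FALSE)
  }
  res <- list(log_ratios = log(weights), weights = weights,
              khat = NA_real_, gpd_scale = NA_real_,
              n_tail = 0L, smoothed = FALSE)
  M <- psis_tail_size(s)
  if (s < 25L) {
    # too few draws to smooth; still report a k-hat if a tail exists
    ord <- order(weights)
    if (M >= 1L && M < s) {
      cut <- weights[ord[s - M]]
      exc <- weights[weights > cut] - cut
      if (length(exc) && max(exc) > 0) {
        fit <- fit_gpd(exc)
        res$khat <- fit$khat; res$gpd_scale <- fit$sigma; res$n_tail <- fit$n
      } else res$khat <- -Inf
    }
    class(res) <- "is_weights"
    return(res)
  }
  ord <- order(weights)
  cut <- weights[ord[s - M]]
  tail_idx <- which(weights > cut)
  n_tail <- length(tail_idx)
  if (n_tail == 0L || max(weights[tail_idx]) - cut <= 0) {
    res$khat <- -Inf
    class(res) <- "is_weights"
    return(res)
  }
  exc <- weights[tail_idx] - cut
  fit <- fit_gpd(exc)
  res$n_tail <- n_tail
  if (!is.finite(fit$khat)) {
    res$khat <- if (is.na(fit$khat)) NA_real_ else fit$khat
    class(res) <- "is_weights"
    return(res)
  }
  # rank quantiles (j - 0.5)/n_tail of the fitted GPD, capped at the raw max
  rk <- rank(weights[tail_idx], ties.method = "first")
  q <- qgpd((rk - 0.5) / n_tail, fit$khat, fit$sigma) + cut
  q <- pmin(q, max(weights))
  sm <- weights
  sm[tail_idx] <- q
  # log_ratios keeps the unnormalized replacement (each entry <= the raw
  # max by construction); weights renormalize it back onto the simplex
  res$log_ratios <- log(sm)
  res$weights <- sm / sum(sm)
  res$khat <- fit$khat
  res$gpd_scale <- fit$sigma
  res$smoothed <- TRUE
  class(res) <- "is_weights"
  res
}

#' @export
print.is_weights <- function(x, ...) {
  cat(sprintf("<is_weights> s = %d, khat = %s, tail = %d, smoothed = %s\n",
              length(x$weights),
              if (is.na(x$khat)) "NA" else sprintf("%.3f", x$khat),
              x$n_tail, x$smoothed))
  invisible(x)
}

#' Tail-shape diagnostic of a log-ratio vector
#'
#' Convenience composition: self-normalize, select the weight tail, fit the
#' generalized Pareto distribution, return the shape estimate k-hat. Values
#' above 0.7 signal an unreliable importance sampler for that observation.
#'
#' @param log_ratios unnormalized log importance ratios.
#' @return k-hat (possibly `-Inf` for a degenerate, i.e. perfectly stable,
#'   tail, or `NA` when the tail is too small to fit).
#' @export
khat_of <- function(log_ratios) {
  pareto_smooth(self_normalize(log_ratios))$khat
}
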
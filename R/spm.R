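as_curve_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  stopifnot(is.matrix(x), is.numeric(x))
  x
}

#' Pointwise two-sample t field over 1D curves
#'
#' At every node the usual pooled-variance two-sample t statistic of
#' group A minus group B is computed; residual curves (each curve minus
#' its group mean) feed the smoothness estimate.
#'
#' @param group_a,group_b matrices of curves, one row per curve, equal
#'   number of columns; at least two rows each.
#' @return list with `t` (length-Q t trajectory), `df`
#'   (`n1 + n2 - 2`), `residuals` ((n1+n2) x Q matrix), `n1`, `n2`.
#' @export
t_field <- function(group_a, group_b) {
  a <- as_curve_matrix(group_a); b <- as_curve_matrix(group_b)
  stopifnot(ncol(a) == ncol(b), nrow(a) >= 2, nrow(b) >= 2, ncol(a) >= 2)
  n1 <- nrow(a); n2 <- nrow(b)
  ma <- colMeans(a); mb <- colMeans(b)
  ra <- sweep(a, 2, ma); rb <- sweep(b, 2, mb)
  df <- n1 + n2 - 2L
  s2 <- (colSums(ra^2) + colSums(rb^2)) / df
  if (any(s2 <= 0)) {
    abort(paste0("zero pooled variance at node(s): ",
                 paste(head(which(s2 <= 0), 5), collapse = ", ")))
  }
  list(t = (ma - mb) / sqrt(s2 * (1 / n1 + 1 / n2)),
       df = df, residuals = rbind(ra, rb), n1 = n1, n2 = n2)
}

#' Residual-field smoothness (FWHM, in nodes)
#'
#' Residual curves are normalized pointwise by the pooled residual SD;
#' the average squared gradient `v` of the normalized field (unit node
#' spacing) gives `fwhm = sqrt(4 log 2 / v)`, the full width at half
#' maximum of the Gaussian autocorrelation that would produce that
#' gradient variance. Clamped to `[1, Q]`.
#'
#' @param residuals matrix of residual curves (rows = curves).
#' @param df error degrees of freedom used for the pooled SD; defaults
#'   to `nrow(residuals) - 2` (two-group design).
#' @return FWHM in nodes.
#' @export
estimate_fwhm <- function(residuals, df = nrow(residuals) - 2L) {
  r <- as_curve_matrix(residuals)
  stopifnot(nrow(r) >= 2, ncol(r) >= 3, df >= 1)
  q <- ncol(r)
  sdp <- sqrt(colSums(r^2) / df)
  if (all(sdp == 0)) abort("all-zero residuals: smoothness undefined")
  z <- sweep(r, 2, pmax(sdp, .Machine$double.eps), "/")
  dz <- z[, -1, drop = FALSE] - z[, -q, drop = FALSE]
  v <- mean(dz^2)
  min(max(sqrt(4 * log(2) / v), 1), q)
}

#' Random-field-theory critical threshold for a 1D t field
#'
#' Solves for the height `u` at which the expected Euler characteristic
#' of the thresholded t field equals `alpha`:
#' `P(T_df > u) + R * sqrt(4 log 2) / (2 pi) * (1 + u^2/df)^(-(df-1)/2) = alpha`,
#' with resel count `R = (Q - 1) / fwhm`. For a two-sided test on `|t|`
#' call this with `alpha / 2`.
#'
#' @param df degrees of freedom.
#' @param fwhm residual smoothness in nodes.
#' @param Q number of nodes.
#' @param alpha significance level for the one-sided excursion.
#' @return critical threshold `t*`.
#' @export
rft_threshold <- function(df, fwhm, Q, alpha = 0.05) {
  stopifnot(df >= 1, fwhm > 0, Q >= 2, alpha > 0, alpha < 1)
  R <- (Q - 1) / fwhm
  ec <- function(u) {
    pt(u, df, lower.tail = FALSE) +
      R * sqrt(4 * log(2)) / (2 * pi) * (1 + u^2 / df)^(-(df - 1) / 2)
  }
  lo <- 0; hi <- 100
  while (ec(hi) > alpha && hi < 1e6) hi <- hi * 10
  if (ec(hi) > alpha) abort("no RFT threshold below t = 1e6")
  if (ec(lo) < alpha) abort("expected Euler characteristic below alpha at t = 0")
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (ec(mid) > alpha) lo <- mid else hi <- mid
    if (hi - lo < 1e-10) break
  }
  (lo + hi) / 2
}

#' Two-sample SPM t test on 1D curves
#'
#' Composes [t_field()], [estimate_fwhm()] and [rft_threshold()] and
#' reports suprathreshold clusters: maximal runs of nodes where
#' `|t| > t*`. Inference is two-sided; the threshold solves the
#' Euler-characteristic equation at `alpha / 2` per tail. When
#' `balance_seed` is given and the groups are unbalanced, the larger
#' group is randomly subsampled (seeded, reproducible) to the smaller
#' size before testing.
#'
#' @inheritParams t_field
#' @param alpha familywise significance level.
#' @param balance_seed optional integer; subsample the larger group to
#'   balance the design.
#' @return a `swing_spm` object: list with `t`, `df`, `fwhm`,
#'   `threshold`, `alpha`, `clusters` (tibble of node ranges), `n1`,
#'   `n2`, `metadata`.
#' @export
spm_ttest2 <- function(group_a, group_b, alpha = 0.05, balance_seed = NULL) {
  a <- as_curve_matrix(group_a); b <- as_curve_matrix(group_b)
  balanced <- FALSE
  if (!is.null(balance_seed) && nrow(a) != nrow(b)) {
    m <- min(nrow(a), nrow(b))
    withr::with_seed(balance_seed, {
      if (nrow(a) > m) a <- a[sort(sample.int(nrow(a), m)), , drop = FALSE]
      if (nrow(b) > m) b <- b[sort(sample.int(nrow(b), m)), , drop = FALSE]
    })
    balanced <- TRUE
  }
  tf <- t_field(a, b)
  fwhm <- estimate_fwhm(tf$residuals, df = tf$df)
  thr <- rft_threshold(tf$df, fwhm, ncol(a), alpha / 2)
  clusters <- logical_clusters(abs(tf$t) > thr)
  structure(list(t = tf$t, df = tf$df, fwhm = fwhm, threshold = thr,
                 alpha = alpha, clusters = clusters,
                 n1 = nrow(a), n2 = nrow(b),
                 metadata = list(sidedness = "two-sided",
                                 balance_seed = balance_seed,
                                 balanced = balanced)),
            class = "swing_spm")
}

#' @export
print.swing_spm <- function(x, ...) {
  cat(sprintf("<swing_spm> two-sample SPM{t}, Q = %d, df = %d\n",
              length(x$t), x$df))
  cat(sprintf("  FWHM = %.2f nodes, |t| threshold = %.3f (alpha = %g)\n",
              x$fwhm, x$threshold, x$alpha))
  if (nrow(x$clusters) == 0) {
    cat("  no suprathreshold clusters\n")
  } else {
    cat(sprintf("  %d suprathreshold cluster(s): %s\n", nrow(x$clusters),
                paste(sprintf("[%d, %d]", x$clusters$start, x$clusters$end),
                      collapse = ", ")))
  }
  invisible(x)
}

#' @rdname spm_ttest2
#' @param x a `swing_spm`.
#' @param ... unused.
#' @method tidy swing_spm
#' @export
tidy.swing_spm <- function(x, ...) {
  q <- length(x$t)
  sig <- rep(FALSE, q)
  if (nrow(x$clusters) > 0) {
    for (j in seq_len(nrow(x$clusters))) {
      sig[x$clusters$start[j]:x$clusters$end[j]] <- TRUE
    }
  }
  tibble(node = seq_len(q), t = x$t, threshold = x$threshold,
         significant = sig)
}

#' @rdname spm_ttest2
#' @method glance swing_spm
#' @export
glance.swing_spm <- function(x, ...) {
  tibble(df = x$df, fwhm = x$fwhm, threshold = x$threshold, alpha = x$alpha,
         n_clusters = nrow(x$clusters), n1 = x$n1, n2 = x$n2)
}

#' Nonparametric maximum-statistic permutation threshold
#'
#' The (1 - alpha) quantile of the maximum over nodes of `|t|` across
#' group-label permutations: the validation oracle for
#' [rft_threshold()]. All distinct label assignments are enumerated when
#' there are at most `n_perm` of them; otherwise `n_perm` seeded random
#' permutations are drawn.
#'
#' @inheritParams spm_ttest2
#' @param n_perm maximum number of permutations (>= 100).
#' @param seed integer seed for the random draw.
#' @return the permutation threshold `t*`.
#' @export
permutation_threshold <- function(group_a, group_b, alpha = 0.05,
                                  n_perm = 2000, seed = 1) {
  stopifnot(n_perm >= 100)
  a <- as_curve_matrix(group_a); b <- as_curve_matrix(group_b)
  x <- rbind(a, b)
  n <- nrow(x); n1 <- nrow(a)
  n_distinct <- choose(n, n1)
  if (n_distinct < 1 / alpha) {
    abort(sprintf("only %d distinct label permutations; need at least %g",
                  n_distinct, 1 / alpha))
  }
  max_abs_t <- function(idx_a) {
    tf <- t_field(x[idx_a, , drop = FALSE], x[-idx_a, , drop = FALSE])
    max(abs(tf$t))
  }
  if (n_distinct <= n_perm) {
    sets <- combn(n, n1)
    stat <- apply(sets, 2, max_abs_t)
  } else {
    stat <- withr::with_seed(seed, {
      vapply(seq_len(n_perm),
             function(i) max_abs_t(sample.int(n, n1)), numeric(1))
    })
  }
  unname(quantile(stat, 1 - alpha, type = 7))
}

#' Smooth 1D Gaussian noise curves
#'
#' White Gaussian node noise convolved with a Gaussian kernel of known
#' FWHM and rescaled to unit pointwise variance — the null model used to
#' validate the smoothness estimator and the RFT threshold.
#'
#' @param n number of curves.
#' @param Q nodes per curve.
#' @param fwhm smoothing kernel full width at half maximum (nodes).
#' @param seed optional integer seed.
#' @return an `n` x `Q` matrix.
#' @export
smooth_gaussian_curves <- function(n, Q, fwhm, seed = NULL) {
  gen <- function() {
    sigma <- fwhm / sqrt(8 * log(2))
    half <- ceiling(4 * sigma)
    kern <- stats::dnorm(-half:half, sd = sigma)
    kern <- kern / sqrt(sum(kern^2))   # unit output variance
    pad <- Q + 2 * half
    z <- matrix(rnorm(n * pad), n, pad)
    t(apply(z, 1, function(r) {
      stats::convolve(r, kern, type = "filter")[seq_len(Q)]
    }))
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}
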
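## The gamma statistic of node-time concentration and its Monte-Carlo
## pure-birth test.

#' Gamma statistic
#'
#' Standardised measure of whether internal nodes concentrate early
#' (gamma < 0, the early-burst signature) or late (gamma > 0) relative to
#' the constant-rate expectation. With g_k the duration during which the
#' reconstructed tree has exactly k lineages (k = 2..n) and
#' T = sum k * g_k,
#' \deqn{\gamma = \frac{\frac{1}{n-2}\sum_{i=2}^{n-1}\sum_{k=2}^{i} k g_k
#'   - T/2}{T\sqrt{1/(12(n-2))}}.}
#' The statistic is invariant to rescaling all branch lengths.
#'
#' @param x a \code{timetree} or a descending vector of branching times.
#' @return the gamma value (dimensionless).
#' @export
gamma_statistic <- function(x) {
  bt <- if (inherits(x, "phylo")) branching_times(x) else
    sort(as.numeric(x), decreasing = TRUE)
  n <- length(bt) + 1L
  if (n < 3L) stop("gamma requires at least 3 tips")
  ## g_k: interval with k lineages runs from the (k-1)-th oldest node down
  ## to the k-th oldest node (or the present for k = n)
  ages <- c(bt, 0)
  g <- ages[1:(n - 1L)] - ages[2:n]     # g_2 .. g_n
  k <- 2:n
  kg <- k * g
  T <- sum(kg)
  cum <- cumsum(kg)                     # sum_{k=2}^{i} k g_k at i = 2..n
  num <- sum(cum[1:(n - 2L)]) / (n - 2L) - T / 2
  num / (T * sqrt(1 / (12 * (n - 2L))))
}

#' Monte-Carlo pure-birth test of the gamma statistic
#'
#' Tests the observed gamma against pure-birth trees conditioned on the
#' same number of tips. Gamma is scale-invariant, so the null speciation
#' rate is irrelevant; nulls are drawn as pure-birth branching times
#' (inter-node durations with k lineages exponential with rate k). The
#' default one-sided lower-tail p-value targets the directional early-burst
#' hypothesis and uses the (r + 1)/(N + 1) correction, so an exact zero is
#' never reported.
#'
#' @param tree a \code{timetree} (or branching-time vector).
#' @param n_null number of null replicates (warning below 100).
#' @param seed integer seed.
#' @param alternative \code{"less"} (early burst, default), \code{"greater"}
#'   or \code{"two.sided"}.
#' @return object of class \code{"gamma_test"}: list with \code{gamma},
#'   \code{p_value}, \code{n_null}, \code{ntip}, \code{null_gamma}.
#' @export
gamma_test <- function(tree, n_null = 1000, seed = NULL,
                       alternative = c("less", "greater", "two.sided")) {
  alternative <- match.arg(alternative)
  bt <- if (inherits(tree, "phylo")) branching_times(tree) else
    sort(as.numeric(tree), decreasing = TRUE)
  n <- length(bt) + 1L
  if (n < 3L) stop("gamma requires at least 3 tips")
  if (n_null < 100) warning("fewer than 100 null replicates: p-value resolution is coarse")
  obs <- gamma_statistic(bt)
  null_gamma <- with_seed(seed, {
    vapply(seq_len(n_null),
           function(i) gamma_statistic(yule_branching_times(n)),
           numeric(1))
  })
  p <- switch(alternative,
    less = (1 + sum(null_gamma <= obs)) / (n_null + 1),
    greater = (1 + sum(null_gamma >= obs)) / (n_null + 1),
    two.sided = min(1, 2 * min(
      (1 + sum(null_gamma <= obs)) / (n_null + 1),
      (1 + sum(null_gamma >= obs)) / (n_null + 1))))
  structure(list(gamma = obs, p_value = p, n_null = n_null, ntip = n,
                 alternative = alternative, null_gamma = null_gamma),
            class = "gamma_test")
}

#' @export
print.gamma_test <- function(x, ...) {
  cat(sprintf("Gamma test: gamma = %.4f, p = %.4g (%s, %d tips, %d nulls)\n",
              x$gamma, x$p_value, x$alternative, x$ntip, x$n_null))
  invisible(x)
}

#' Lineage-through-time curve
#'
#' @param tree a \code{timetree}.
#' @return data.frame with node ages (descending) and the number of
#'   lineages alive immediately after each branching event.
#' @export
ltt_curve <- function(tree) {
  bt <- branching_times(tree)
  data.frame(age = c(bt, 0),
             lineages = c(seq_along(bt) + 1L, length(bt) + 1L))
}
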
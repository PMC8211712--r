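## Changes-through-time (CTT) curves: mean number of character changes per
## unit of available branch length in each time bin, with null envelopes
## from simulation under the fitted transition matrix.

#' Changes-through-time curve from stochastic maps
#'
#' Per age bin: mean change count across maps divided by the total edge
#' length present in the bin. Bins partition [0, crown age].
#'
#' @param maps a \code{stoch_map_list} (or list of \code{stoch_map}).
#' @param n_bins number of equal-width bins (default 50).
#' @return object of class \code{"ctt"}: data.frame-like list with bin
#'   edges, per-bin rate, mean change count and edge length, plus the
#'   number of maps used.
#' @export
ctt_curve <- function(maps, n_bins = 50) {
  if (!length(maps)) stop("need at least one map")
  if (n_bins < 2) stop("need at least 2 bins")
  tree <- maps[[1]]$tree
  crown <- tree_height(tree)
  breaks <- seq(0, crown, length.out = n_bins + 1)
  elen <- edge_length_in_bins(tree, breaks)
  counts <- numeric(n_bins)
  for (m in maps) {
    ch <- map_changes(m)
    if (nrow(ch)) {
      b <- pmin(pmax(findInterval(ch$age, breaks, rightmost.closed = TRUE),
                     1L), n_bins)
      counts <- counts + tabulate(b, n_bins)
    }
  }
  mean_counts <- counts / length(maps)
  rate <- ifelse(elen > 0, mean_counts / elen, 0)
  structure(list(breaks = breaks, rate = rate, mean_changes = mean_counts,
                 edge_length = elen, n_maps = length(maps)),
            class = "ctt")
}

#' @export
print.ctt <- function(x, ...) {
  cat(sprintf(
    "CTT curve: %d bins over [0, %.3g] My, %.3g changes/map (mean of %d maps)\n",
    length(x$rate), max(x$breaks), sum(x$mean_changes), x$n_maps))
  invisible(x)
}

## forward (unconditioned) histories under Q: the literal null of the
## simulated-map test
forward_history_curves <- function(tree, model, n_sims, n_bins, seeds) {
  vapply(seq_len(n_sims), function(i) {
    h <- sim_discrete(tree, model$Q, root_dist = model$root_prior,
                      seed = seeds[[i]])
    ctt_curve(list(h), n_bins = n_bins)$rate
  }, numeric(n_bins))
}

#' Null-envelope test of a changes-through-time curve
#'
#' Compares the observed CTT curve against curves simulated under the
#' fitted transition matrix via the rank envelope test. Two null
#' conventions are available: \code{"forward"} (default) simulates free
#' character histories from the root (root state from the model's prior,
#' unconditioned on tips), one per replicate; \code{"conditional"} is the
#' full parametric bootstrap -- each replicate simulates tip data under Q
#' and rebuilds the mean curve from stochastic maps conditioned on those
#' simulated tips, making the null replicate exchangeable with the
#' observed statistic (used for calibration).
#'
#' @param tree a \code{timetree}.
#' @param model a fitted \code{\link{fit_mk}} object.
#' @param observed a \code{\link{ctt_curve}} result.
#' @param n_sims number of null replicates (warning below 100).
#' @param seed integer seed.
#' @param null_type \code{"forward"} or \code{"conditional"}.
#' @return object of class \code{"ctt_test"}: the observed curve, null
#'   curve matrix, rank-envelope p-interval and a verdict string
#'   (\code{"random"} / \code{"non-random"} / \code{"ambiguous"}).
#' @export
ctt_null_test <- function(tree, model, observed, n_sims = 1000,
                          seed = NULL, null_type = c("forward", "conditional")) {
  null_type <- match.arg(null_type)
  tree <- as_timetree(tree)
  if (n_sims < 100) warning("fewer than 100 null simulations: coarse p resolution")
  n_bins <- length(observed$rate)
  seeds <- child_seeds(seed, 2 * n_sims + 1)
  if (null_type == "forward") {
    nulls <- forward_history_curves(tree, model, n_sims, n_bins, seeds)
  } else {
    nulls <- vapply(seq_len(n_sims), function(i) {
      h <- sim_discrete(tree, model$Q, root_dist = model$root_prior,
                        seed = seeds[[i]])
      tips <- map_tip_states(h)
      mm <- sample_stochastic_maps(tree, model, tips,
                                   n_maps = observed$n_maps,
                                   seed = seeds[[n_sims + i]])
      ctt_curve(mm, n_bins = n_bins)$rate
    }, numeric(n_bins))
  }
  env <- rank_envelope_test(observed$rate, t(nulls))
  verdict <- if (env$p < 0.05) "non-random" else "random"
  structure(list(observed = observed, nulls = t(nulls),
                 p_interval = env$p_interval, p = env$p, rank = env$rank,
                 verdict = verdict),
            class = "ctt_test")
}

#' @export
print.ctt_test <- function(x, ...) {
  cat(sprintf("CTT rank envelope test: p-interval [%.4g, %.4g] -> %s\n",
              x$p_interval[1], x$p_interval[2], x$verdict))
  invisible(x)
}
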
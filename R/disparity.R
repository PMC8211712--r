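## Disparity-through-time analysis: relative subclade disparity at each
## divergence event, Brownian-motion nulls, the morphological disparity
## index (MDI) and global envelope significance tests.

#' Morphological disparity of a set of species
#'
#' Mean squared Euclidean distance among all unordered pairs of species in
#' trait space; zero for a single species.
#'
#' @param values species x trait matrix (or vector for one trait).
#' @return scalar disparity.
#' @export
disparity <- function(values) {
  x <- as.matrix(values)
  m <- nrow(x)
  if (m == 0) stop("empty species set")
  if (m == 1) return(0)
  ## sum over unordered pairs of |xi - xj|^2 = m * sum |xi - xbar|^2
  ctr <- sweep(x, 2, colMeans(x))
  (2 / (m - 1)) * sum(ctr^2)
}

#' Disparity-through-time curve
#'
#' At each divergence event (internal node, visited from the root by age)
#' the curve value is the mean relative disparity of the lineages present
#' at that event: each lineage crossing that age defines a subclade whose
#' disparity is divided by the disparity of the whole clade; single-species
#' lineages contribute zero. The curve starts at 1 at the root (the whole
#' clade is one lineage) and time runs on a relative axis from 0 (root) to
#' 1 (present). Species missing any trait are dropped and the tree is
#' pruned to the covered tips.
#'
#' @param tree a \code{timetree}.
#' @param traits species x trait matrix with rownames; rows with missing
#'   values are dropped (listwise).
#' @return object of class \code{"dtt"}: data.frame with \code{age},
#'   \code{rel_time} and \code{disparity}, plus attributes \code{tree} and
#'   \code{traits} (the pruned inputs).
#' @export
dtt_curve <- function(tree, traits) {
  pr <- prune_to_traits(tree, traits)
  tree <- pr$tree; X <- pr$traits
  n <- nrow(X)
  total <- disparity(X)
  if (total <= 0) stop("whole-clade disparity is zero: degenerate traits")
  val <- dtt_values(tree, X, total)
  structure(
    data.frame(age = val$age,
               rel_time = (val$age[1] - val$age) / val$age[1],
               disparity = val$mean_rel),
    class = c("dtt", "data.frame"),
    tree = tree, traits = X, total_disparity = total)
}

## drop species with any missing trait, prune tree, align
prune_to_traits <- function(tree, traits) {
  X <- as.matrix(traits)
  if (is.null(rownames(X))) stop("'traits' needs species rownames")
  X <- X[stats::complete.cases(X), , drop = FALSE]
  keep <- intersect(tree$tip.label, rownames(X))
  if (length(keep) < 3) stop("traits must cover at least 3 tips of the tree")
  if (length(keep) < length(tree$tip.label)) {
    tree <- as_timetree(ape::drop.tip(tree, setdiff(tree$tip.label, keep)))
  }
  list(tree = tree, traits = X[tree$tip.label, , drop = FALSE])
}

## core DTT computation; per-subclade disparities via postorder
## accumulation of sums and sums of squares (O(n) per event set)
dtt_values <- function(tree, X, total) {
  n <- nrow(X)
  nn <- n + tree$Nnode
  p <- ncol(X)
  ages <- node_ages(tree)
  ## postorder accumulations per node: count, sum, sum of squares
  cnt <- numeric(nn); sx <- matrix(0, nn, p); sxx <- numeric(nn)
  cnt[1:n] <- 1
  sx[1:n, ] <- X
  sxx[1:n] <- rowSums(X^2)
  child_of <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  for (nd in postorder_nodes(tree)) {
    for (e in child_of[[as.character(nd)]]) {
      ch <- tree$edge[e, 2]
      cnt[nd] <- cnt[nd] + cnt[ch]
      sx[nd, ] <- sx[nd, ] + sx[ch, ]
      sxx[nd] <- sxx[nd] + sxx[ch]
    }
  }
  ## disparity of the clade under node v from the accumulators:
  ## sum_i |xi - xbar|^2 = sxx - |sx|^2 / m ; disparity = 2/(m-1) * that
  clade_disp <- function(v) {
    m <- cnt[v]
    if (m < 2) return(0)
    (2 / (m - 1)) * (sxx[v] - sum(sx[v, ]^2) / m)
  }
  disp <- vapply(seq_len(nn), clade_disp, numeric(1))
  ## events ordered old -> young (ties broken root-first so zero-length
  ## edges expand parents before children); the lineage set entering each
  ## event is tracked by replacing the parent with its children
  depth <- node_topo_depth(tree)
  inode <- (n + 1):nn
  ord <- inode[order(-ages[inode], depth[inode])]
  root <- n + 1L
  active <- root
  mean_rel <- numeric(length(ord))
  age_out <- numeric(length(ord))
  for (i in seq_along(ord)) {
    nd <- ord[i]
    age_out[i] <- ages[nd]
    mean_rel[i] <- mean(disp[active]) / total
    kids <- tree$edge[child_of[[as.character(nd)]], 2]
    active <- c(active[active != nd], kids)
  }
  ## the curve ends at the present, where every lineage is a singleton
  list(age = c(age_out, 0), mean_rel = c(mean_rel, 0))
}

## number of edges between each node and the root
node_topo_depth <- function(tree) {
  n <- length(tree$tip.label)
  d <- integer(n + tree$Nnode)
  pre <- ape::reorder.phylo(tree, "cladewise")
  for (j in seq_len(nrow(pre$edge))) {
    d[pre$edge[j, 2]] <- d[pre$edge[j, 1]] + 1L
  }
  d
}

#' Brownian-motion null curves for a DTT analysis
#'
#' Estimates the multivariate Brownian rate matrix from the data by
#' phylogenetically independent contrasts, simulates tip data under it,
#' and recomputes the DTT curve for every simulation.
#'
#' @param tree a \code{timetree}.
#' @param traits species x trait matrix.
#' @param n_sims number of simulations.
#' @param seed integer seed.
#' @return matrix (n_sims x events) of null DTT curves, with the rate
#'   matrix as attribute \code{"rate_matrix"}.
#' @export
dtt_null <- function(tree, traits, n_sims = 1000, seed = NULL) {
  if (n_sims < 1) stop("'n_sims' must be positive")
  pr <- prune_to_traits(tree, traits)
  tree <- pr$tree; X <- pr$traits
  R <- bm_rate_matrix(tree, X)
  C <- shared_time_matrix(tree)
  cC <- chol(C)
  cR <- chol(R + diag(1e-12, ncol(R)))
  n <- nrow(X); p <- ncol(X)
  with_seed(seed, {
    t(vapply(seq_len(n_sims), function(i) {
      Z <- matrix(stats::rnorm(n * p), n, p)
      Y <- crossprod(cC, Z) %*% cR
      rownames(Y) <- rownames(C)
      tot <- disparity(Y)
      dtt_values(tree, Y[tree$tip.label, , drop = FALSE], tot)$mean_rel
    }, numeric(n)))
  })
}

## ML/contrast estimate of the multivariate BM rate matrix
bm_rate_matrix <- function(tree, X) {
  pics <- apply(X, 2, function(y) ape::pic(y[tree$tip.label], tree))
  pics <- as.matrix(pics)
  crossprod(pics) / nrow(pics)
}

#' Morphological disparity index
#'
#' Trapezoidal integral over relative time of (observed - mean null)
#' disparity. The Monte-Carlo p-value compares the observed MDI with the
#' distribution of null MDIs (each null curve scored against the mean of
#' the remaining nulls); both the two-sided and the upper-tail one-sided
#' p-value are reported.
#'
#' @param observed a \code{\link{dtt_curve}} result (or numeric curve).
#' @param null_curves matrix of null curves (rows = simulations) on the
#'   same event grid.
#' @param rel_time relative times of the grid (taken from \code{observed}
#'   when it is a \code{dtt} object).
#' @return list with \code{mdi}, \code{p_two_sided}, \code{p_greater}.
#' @export
mdi <- function(observed, null_curves, rel_time = NULL) {
  if (inherits(observed, "dtt")) {
    rel_time <- observed$rel_time
    obs <- observed$disparity
  } else {
    obs <- as.numeric(observed)
  }
  if (is.null(rel_time)) stop("'rel_time' required for a bare curve")
  null_curves <- as.matrix(null_curves)
  if (ncol(null_curves) != length(obs)) stop("curve grids do not match")
  nm <- colMeans(null_curves)
  integ <- function(y) {
    dx <- diff(rel_time)
    sum(dx * (y[-1] + y[-length(y)]) / 2)
  }
  m_obs <- integ(obs - nm)
  N <- nrow(null_curves)
  m_null <- vapply(seq_len(N), function(i) {
    others <- colMeans(null_curves[-i, , drop = FALSE])
    integ(null_curves[i, ] - others)
  }, numeric(1))
  list(mdi = m_obs,
       p_two_sided = (1 + sum(abs(m_null) >= abs(m_obs))) / (N + 1),
       p_greater = (1 + sum(m_null >= m_obs)) / (N + 1),
       null_mdi = m_null)
}

#' Rank envelope test of a functional summary statistic
#'
#' Global test of a whole curve against simulated null curves. Each
#' curve's extreme rank is the minimum over grid points of its pointwise
#' rank counted from below or above among all N + 1 curves (ties share
#' ranks); smaller rank = more extreme. The p-interval is
#' \deqn{[(1 + \#\{null: rank < rank_{obs}\})/(N+1),\;
#'        (1 + \#\{null: rank \le rank_{obs}\})/(N+1)].}
#'
#' @param observed numeric curve.
#' @param null_curves matrix (rows = simulations) on the same grid.
#' @return list with \code{rank} (observed extreme rank), \code{p_interval}
#'   and the null ranks.
#' @export
rank_envelope_test <- function(observed, null_curves) {
  null_curves <- as.matrix(null_curves)
  if (ncol(null_curves) != length(observed)) stop("curve grids do not match")
  A <- rbind(as.numeric(observed), null_curves)  # (N+1) x grid
  N <- nrow(null_curves)
  ## grid points where every curve is identical carry no ordering
  ## information (e.g. fixed endpoints); drop them
  keep <- apply(A, 2, function(v) max(v) - min(v) > 0)
  if (!any(keep)) {
    return(list(rank = NA, p_interval = c(1 / (N + 1), 1),
                null_ranks = rep(NA, N)))
  }
  A <- A[, keep, drop = FALSE]
  lo <- apply(A, 2, function(v) rank(v, ties.method = "min"))
  hi <- apply(-A, 2, function(v) rank(v, ties.method = "min"))
  depth <- pmin(lo, hi)                          # pointwise extremeness
  ext <- apply(depth, 1, min)                    # extreme rank per curve
  r_obs <- ext[1]; r_null <- ext[-1]
  p_lo <- (1 + sum(r_null < r_obs)) / (N + 1)
  p_hi <- (1 + sum(r_null <= r_obs)) / (N + 1)
  ## extreme-rank-length refinement: ties in the extreme rank (frequent
  ## for discrete-valued curves) are broken by comparing the sorted
  ## pointwise depth vectors lexicographically; the refinement uses
  ## conservative (shared-maximum) tie ranks, so a curve tied with many
  ## others at a common value is not counted as extreme there
  lo_c <- apply(A, 2, function(v) rank(v, ties.method = "max"))
  hi_c <- apply(-A, 2, function(v) rank(v, ties.method = "max"))
  depth_c <- pmin(lo_c, hi_c)
  M <- t(apply(depth_c, 1, sort))
  obs_v <- M[1, ]
  leq_obs <- vapply(seq_len(N), function(i) {
    v <- M[i + 1, ]
    d <- which(v != obs_v)
    if (!length(d)) TRUE else v[d[1]] < obs_v[d[1]]
  }, logical(1))
  p_erl <- (1 + sum(leq_obs)) / (N + 1)
  list(rank = r_obs, p_interval = c(p_lo, p_hi), p = p_erl,
       null_ranks = r_null)
}

#' Pointwise envelope of null curves
#'
#' The simple pairwise variant: per grid point 2.5/97.5 percentile band of
#' the nulls and the exceedance pattern of the observed curve.
#'
#' @param observed numeric curve.
#' @param null_curves matrix of null curves.
#' @param level coverage level (default 0.95).
#' @return data.frame with lower, upper, observed and outside flags.
#' @export
pointwise_envelope <- function(observed, null_curves, level = 0.95) {
  null_curves <- as.matrix(null_curves)
  a <- (1 - level) / 2
  lo <- apply(null_curves, 2, stats::quantile, probs = a)
  hi <- apply(null_curves, 2, stats::quantile, probs = 1 - a)
  data.frame(lower = lo, upper = hi, observed = as.numeric(observed),
             outside = observed < lo | observed > hi)
}

#' Full disparity-through-time test
#'
#' Convenience wrapper: observed curve, BM nulls, MDI and rank envelope
#' p-interval in one call.
#'
#' @param tree a \code{timetree}.
#' @param traits species x trait matrix.
#' @param n_sims number of BM null simulations.
#' @param seed integer seed.
#' @return object of class \code{"dtt_test"}.
#' @export
dtt_test <- function(tree, traits, n_sims = 1000, seed = NULL) {
  obs <- dtt_curve(tree, traits)
  nulls <- dtt_null(attr(obs, "tree"), attr(obs, "traits"),
                    n_sims = n_sims, seed = seed)
  m <- mdi(obs, nulls)
  env <- rank_envelope_test(obs$disparity, nulls)
  structure(list(observed = obs, nulls = nulls, mdi = m$mdi,
                 mdi_p = m$p_two_sided, mdi_p_greater = m$p_greater,
                 p_interval = env$p_interval),
            class = "dtt_test")
}

#' @export
print.dtt_test <- function(x, ...) {
  cat(sprintf(
    "DTT: MDI = %.4g (two-sided p = %.3g), rank envelope p-interval [%.4g, %.4g]\n",
    x$mdi, x$mdi_p, x$p_interval[1], x$p_interval[2]))
  invisible(x)
}
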
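## Shared internal helpers.

## Run an expression under a local RNG seed without disturbing the caller's
## random state. All stochastic operations in the package funnel through
## this, so results are reproducible from explicit seeds only.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(expr)
}

## Derive a stream of child seeds from one master seed (kept below 2^31).
child_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  as.list((as.double(seed) * 48271 + 7 * seq_len(n)) %% 2147483629)
}

#' Akaike weights
#'
#' Relative model support \eqn{w_i = \exp(-\Delta_i/2) / \sum_j
#' \exp(-\Delta_j/2)} computed from AIC values (or directly from AIC
#' differences). Invariant to adding a constant to all AICs.
#'
#' @param aic numeric vector of AIC values or AIC differences.
#' @return numeric vector of weights summing to 1.
#' @export
akaike_weights <- function(aic) {
  if (!length(aic)) stop("empty AIC vector")
  delta <- aic - min(aic)
  w <- exp(-delta / 2)
  w / sum(w)
}

## Edge-indexed tabulation of the tree used throughout the package:
## per edge the ages of its older (parent) and younger (child) end.
edge_ages <- function(tree) {
  ages <- node_ages(tree)
  data.frame(
    parent = tree$edge[, 1],
    child = tree$edge[, 2],
    age_top = ages[tree$edge[, 1]],
    age_bottom = ages[tree$edge[, 2]],
    length = tree$edge.length
  )
}

## Total edge length present in each age bin [edges[i], edges[i+1]).
edge_length_in_bins <- function(tree, breaks) {
  ea <- edge_ages(tree)
  vapply(seq_len(length(breaks) - 1L), function(i) {
    lo <- breaks[i]; hi <- breaks[i + 1L]
    sum(pmax(0, pmin(ea$age_top, hi) - pmax(ea$age_bottom, lo)))
  }, numeric(1))
}

## Matrix of shared path lengths from the root (BM covariance, unit rate)
## in time units; rows/cols ordered as tip labels.
shared_time_matrix <- function(tree) {
  C <- ape::vcv(tree)
  C[tree$tip.label, tree$tip.label]
}

## postorder list of internal nodes (children before parents)
postorder_nodes <- function(tree) {
  po <- ape::reorder.phylo(tree, "postorder")
  unique(po$edge[, 1])
}

stop_if_not_scalar <- function(x, name) {
  if (length(x) != 1 || !is.finite(x)) {
    stop("'", name, "' must be a finite scalar")
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
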
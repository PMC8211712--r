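## Stochastic character mapping: sampling full discrete-character
## histories consistent with tip states and a fitted Mk model, and
## summaries built on them.

new_stoch_map <- function(tree, states, maps, node_states) {
  structure(list(tree = tree, states = states, maps = maps,
                 node_states = node_states),
            class = "stoch_map")
}

#' @export
print.stoch_map <- function(x, ...) {
  cat(sprintf("Stochastic character map: %d states, %d changes\n",
              length(x$states), nrow(map_changes(x))))
  invisible(x)
}

#' Tip states of a character map
#' @param map a \code{stoch_map}.
#' @export
map_tip_states <- function(map) {
  n <- length(map$tree$tip.label)
  s <- map$states[map$node_states[seq_len(n)]]
  names(s) <- map$tree$tip.label
  s
}

#' Character changes on a map, with their ages
#' @param map a \code{stoch_map}.
#' @return data.frame with \code{edge}, \code{age}, \code{from}, \code{to}.
#' @export
map_changes <- function(map) {
  ea <- edge_ages(map$tree)
  out <- list()
  for (e in seq_along(map$maps)) {
    m <- map$maps[[e]]
    if (length(m) < 2) next
    bounds <- ea$age_top[e] - cumsum(m)
    st <- names(m)
    out[[length(out) + 1]] <- data.frame(
      edge = e, age = bounds[-length(bounds)],
      from = st[-length(st)], to = st[-1],
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(edge = integer(0), age = numeric(0),
                      from = character(0), to = character(0)))
  }
  do.call(rbind, out)
}

#' Sample stochastic character maps
#'
#' Samples full character histories conditioned on the tip states under a
#' fitted Mk model: node states are drawn from their joint conditional
#' distribution (pruning pass, then root-to-tip sampling), and
#' within-branch histories conditioned on both endpoints are drawn by
#' uniformization (with the virtual-jump chain sampled exactly).
#'
#' @param tree a \code{timetree}.
#' @param model a \code{\link{fit_mk}} fit (or list with \code{Q},
#'   \code{root_prior}).
#' @param tip_states named character vector (NA = missing).
#' @param n_maps number of maps.
#' @param seed integer seed.
#' @return list of \code{\link{new_stoch_map}} objects (class
#'   \code{"stoch_map_list"}).
#' @export
sample_stochastic_maps <- function(tree, model, tip_states, n_maps = 100,
                                   seed = NULL) {
  tree <- as_timetree(tree)
  Q <- validate_Q(model$Q)
  states <- rownames(Q)
  S <- length(states)
  prior <- if (!is.null(model$root_prior)) model$root_prior else rep(1 / S, S)
  full <- rep(NA_character_, length(tree$tip.label))
  names(full) <- tree$tip.label
  full[names(tip_states)] <- as.character(tip_states)
  L <- tip_likelihoods(tree, full, states)
  P <- edge_P_matrices(Q, tree$edge.length)
  pr <- mk_pruning(tree, L, P, prior)
  if (!is.finite(pr$loglik)) stop("tip states have zero likelihood under the model")
  n <- length(tree$tip.label)
  root <- n + 1L
  pre <- ape::reorder.phylo(tree, "cladewise")
  eo <- match(paste(pre$edge[, 1], pre$edge[, 2]),
              paste(tree$edge[, 1], tree$edge[, 2]))

  ## uniformization setup
  Om <- max(-diag(Q)) * 1.05 + 1e-9
  B <- diag(S) + Q / Om
  Bpow <- list(diag(S), B)            # B^0, B^1, grown on demand
  getB <- function(m) {
    while (length(Bpow) < m + 1L) {
      Bpow[[length(Bpow) + 1L]] <<- Bpow[[length(Bpow)]] %*% B
    }
    Bpow[[m + 1L]]
  }

  sample_path <- function(i, j, t) {
    ## number of uniformized jumps given endpoints: accumulate the
    ## Poisson-weighted series until its tail is negligible
    lam <- Om * t
    pois <- exp(-lam)
    terms <- pois * (i == j)          # m = 0 term
    cum_pois <- pois
    probs <- terms
    mtop <- 0
    while (cum_pois < 1 - 1e-12 && mtop < 500) {
      mtop <- mtop + 1
      pois <- pois * lam / mtop
      cum_pois <- cum_pois + pois
      probs[mtop + 1] <- pois * getB(mtop)[i, j]
    }
    pij <- sum(probs)
    u <- stats::runif(1) * pij
    cs <- cumsum(probs)
    m <- findInterval(u, cs, left.open = TRUE)
    if (m > mtop) m <- mtop
    if (m == 0) return(list(states = i, times = numeric(0)))
    ## jump chain conditioned on endpoints
    s <- integer(m + 1); s[1] <- i; s[m + 1] <- j
    if (m > 1) {
      for (l in 2:m) {
        w <- B[s[l - 1], ] * getB(m - l + 1)[, j]
        s[l] <- sample.int(S, 1, prob = w)
      }
    }
    times <- sort(stats::runif(m)) * t
    keep <- c(TRUE, s[-1] != s[-(m + 1)])[-1]
    list(states = c(i, s[-1][keep]), times = times[keep])
  }

  with_seed(seed, {
    lapply(seq_len(n_maps), function(rep) {
      node_state <- integer(n + tree$Nnode)
      w <- prior * pr$partial[root, ]
      node_state[root] <- sample.int(S, 1, prob = w)
      maps <- vector("list", nrow(tree$edge))
      for (e in eo) {
        par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
        i <- node_state[par]
        w <- P[[e]][i, ] * part_row(pr$partial, L, ch, n)
        jst <- sample.int(S, 1, prob = w)
        node_state[ch] <- jst
        path <- sample_path(i, jst, tree$edge.length[e])
        k <- length(path$states)
        dur <- diff(c(0, path$times, tree$edge.length[e]))
        m <- dur; names(m) <- states[path$states]
        maps[[e]] <- m
      }
      new_stoch_map(tree, states, maps, node_state)
    }) -> out
    class(out) <- "stoch_map_list"
    out
  })
}

part_row <- function(partial, L, node, n) {
  if (node <= n) L[node, ] else partial[node, ]
}

#' Ancestral state frequencies across stochastic maps
#'
#' Empirical per-node state frequencies across a set of maps; rows sum
#' to 1. Converges to the exact marginal probabilities as the number of
#' maps grows.
#'
#' @param maps a \code{stoch_map_list}.
#' @return matrix (internal nodes x states).
#' @export
ancestral_state_frequencies <- function(maps) {
  stopifnot(length(maps) >= 1)
  tree <- maps[[1]]$tree
  states <- maps[[1]]$states
  n <- length(tree$tip.label)
  nodes <- (n + 1):(n + tree$Nnode)
  F <- matrix(0, length(nodes), length(states),
              dimnames = list(as.character(nodes), states))
  for (m in maps) {
    idx <- m$node_states[nodes]
    F[cbind(seq_along(nodes), idx)] <- F[cbind(seq_along(nodes), idx)] + 1
  }
  F / length(maps)
}
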
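## Mk (continuous-time Markov) models for discrete characters on a tree:
## pruning-algorithm likelihood, maximum-likelihood rate estimation and
## exact marginal ancestral-state probabilities.

## tip likelihood matrix from a named state vector; missing tips (NA)
## contribute a row of ones (equal probability for each state)
tip_likelihoods <- function(tree, tip_states, states) {
  n <- length(tree$tip.label)
  L <- matrix(1, n, length(states), dimnames = list(tree$tip.label, states))
  x <- tip_states[tree$tip.label]
  obs <- !is.na(x)
  bad <- setdiff(unique(x[obs]), states)
  if (length(bad)) stop("unknown states: ", paste(bad, collapse = ", "))
  L[obs, ] <- 0
  L[cbind(which(obs), match(x[obs], states))] <- 1
  L
}

## transition probability matrices for all edges given Q (eigen-based;
## falls back to scaling-and-squaring if the decomposition is unstable)
edge_P_matrices <- function(Q, lens) {
  S <- nrow(Q)
  eg <- eigen(Q)
  if (all(abs(Im(eg$values)) < 1e-9) &&
      abs(det(eg$vectors)) > 1e-12) {
    V <- Re(eg$vectors); lam <- Re(eg$values); Vi <- solve(V)
    lapply(lens, function(t) {
      P <- V %*% (exp(lam * t) * Vi)
      P[P < 0] <- 0
      P / rowSums(P)
    })
  } else {
    lapply(lens, function(t) mat_exp(Q * t))
  }
}

## Pade-free matrix exponential by scaling and squaring of a Taylor series
mat_exp <- function(A, order = 12) {
  nrm <- max(abs(A))
  s <- max(0L, ceiling(log2(max(nrm, 1e-16))) + 2L)
  A <- A / 2^s
  X <- diag(nrow(A)); term <- diag(nrow(A))
  for (i in seq_len(order)) {
    term <- term %*% A / i
    X <- X + term
  }
  for (i in seq_len(s)) X <- X %*% X
  X
}

## pruning pass: per-node scaled partial likelihoods and the total
## log-likelihood under a root prior
mk_pruning <- function(tree, L_tips, P, root_prior) {
  n <- nrow(L_tips); S <- ncol(L_tips)
  nn <- n + tree$Nnode
  part <- matrix(0, nn, S)
  part[seq_len(n), ] <- L_tips
  logscale <- 0
  child_of <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  for (nd in postorder_nodes(tree)) {
    acc <- rep(1, S)
    for (e in child_of[[as.character(nd)]]) {
      ch <- tree$edge[e, 2]
      acc <- acc * drop(P[[e]] %*% part[ch, ])
    }
    sc <- sum(acc)
    if (sc <= 0 || !is.finite(sc)) return(list(loglik = -Inf))
    part[nd, ] <- acc / sc
    logscale <- logscale + log(sc)
  }
  root <- n + 1L
  list(loglik = logscale + log(sum(root_prior * part[root, ])),
       partial = part, logscale = logscale)
}

#' Mk model log-likelihood
#'
#' Felsenstein pruning likelihood of tip states under a rate matrix Q.
#' Missing tips contribute equal likelihood for every state; the root
#' prior is flat by default.
#'
#' @param tree a \code{timetree}.
#' @param tip_states named character vector (NA = missing).
#' @param Q rate matrix with state dimnames.
#' @param root_prior prior over states at the root (default flat).
#' @return log-likelihood.
#' @export
mk_loglik <- function(tree, tip_states, Q, root_prior = NULL) {
  Q <- validate_Q(Q)
  states <- rownames(Q)
  if (is.null(root_prior)) root_prior <- rep(1 / length(states), length(states))
  L <- tip_likelihoods(tree, tip_states, states)
  P <- edge_P_matrices(Q, tree$edge.length)
  mk_pruning(tree, L, P, root_prior)$loglik
}

## build Q from a parameter vector under a structure
mk_build_Q <- function(rates, S, structure, states) {
  Q <- matrix(0, S, S, dimnames = list(states, states))
  if (structure == "ER") {
    Q[] <- rates[1]
  } else if (structure == "SYM") {
    Q[upper.tri(Q)] <- rates
    Q <- Q + t(Q)
  } else {
    Q[row(Q) != col(Q)] <- rates   # column-major over off-diagonals
  }
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

mk_n_rates <- function(S, structure) {
  switch(structure, ER = 1L, SYM = S * (S - 1L) / 2L, ARD = S * (S - 1L))
}

#' Fit an Mk model of discrete-character evolution
#'
#' Maximum-likelihood estimation of the transition rate matrix by the
#' pruning algorithm, with a flat root prior. Species with unknown state
#' are retained and contribute equal likelihood for every state.
#'
#' @param tree a \code{timetree}.
#' @param tip_states named character vector of observed states (NA or
#'   absent = missing).
#' @param structure \code{"SYM"} (symmetric, the default, matching a
#'   reversible process with flat base frequencies), \code{"ER"} (equal
#'   rates) or \code{"ARD"} (all rates different).
#' @param states optional complete state set (defaults to the observed
#'   states, sorted).
#' @param n_starts deterministic multi-starts for the rate optimisation.
#' @return object of class \code{"mk_model"}: \code{Q}, \code{states},
#'   \code{structure}, \code{logLik}, \code{k}, \code{AIC},
#'   \code{root_prior}.
#' @export
fit_mk <- function(tree, tip_states, structure = c("SYM", "ER", "ARD"),
                   states = NULL, n_starts = 3) {
  structure <- match.arg(structure)
  tree <- as_timetree(tree)
  tip_states <- tip_states[!is.na(tip_states)]
  if (length(unique(tip_states)) < 2) {
    stop("need at least 2 distinct observed states")
  }
  if (is.null(states)) states <- sort(unique(as.character(tip_states)))
  S <- length(states)
  full <- rep(NA_character_, length(tree$tip.label))
  names(full) <- tree$tip.label
  full[names(tip_states)] <- as.character(tip_states)
  L <- tip_likelihoods(tree, full, states)
  prior <- rep(1 / S, S)
  nr <- mk_n_rates(S, structure)
  TL <- sum(tree$edge.length)

  negll <- function(lr) {
    Q <- mk_build_Q(exp(lr), S, structure, states)
    P <- edge_P_matrices(Q, tree$edge.length)
    ll <- mk_pruning(tree, L, P, prior)$loglik
    if (!is.finite(ll)) 1e10 else -ll
  }
  q0 <- S / TL
  best <- NULL
  for (f in c(1, 0.1, 10)[seq_len(n_starts)]) {
    o <- tryCatch(
      stats::nlminb(rep(log(q0 * f), nr), negll,
                    lower = rep(log(1e-8), nr), upper = rep(log(100), nr),
                    control = list(iter.max = 500)),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$objective < best$objective)) {
      best <- o
    }
  }
  if (is.null(best)) stop("Mk optimisation failed")
  Q <- mk_build_Q(exp(best$par), S, structure, states)
  ll <- -best$objective
  structure(list(Q = Q, states = states, structure = structure,
                 logLik = ll, k = nr, AIC = 2 * nr - 2 * ll,
                 root_prior = prior),
            class = "mk_model")
}

#' @export
print.mk_model <- function(x, ...) {
  cat(sprintf("Mk model (%s), %d states, logLik = %.3f\n",
              x$structure, length(x$states), x$logLik))
  print(round(x$Q, 5))
  invisible(x)
}

#' Transition probability matrix over a time interval
#' @param Q rate matrix.
#' @param t elapsed time (My).
#' @export
transition_probability <- function(Q, t) {
  Q <- validate_Q(Q)
  P <- edge_P_matrices(Q, t)[[1]]
  dimnames(P) <- dimnames(Q)
  P
}

#' Exact marginal ancestral-state probabilities under an Mk model
#'
#' Standard two-pass (inside/outside) computation of per-node marginal
#' posterior state probabilities.
#'
#' @param tree a \code{timetree}.
#' @param tip_states named character vector (NA = missing).
#' @param model a fitted \code{\link{fit_mk}} object (or a list with
#'   \code{Q} and \code{root_prior}).
#' @return matrix (internal nodes x states) of marginal probabilities,
#'   rows summing to 1; rownames are node numbers.
#' @export
mk_marginals <- function(tree, tip_states, model) {
  tree <- as_timetree(tree)
  Q <- validate_Q(model$Q)
  states <- rownames(Q)
  prior <- if (!is.null(model$root_prior)) model$root_prior else
    rep(1 / length(states), length(states))
  full <- rep(NA_character_, length(tree$tip.label))
  names(full) <- tree$tip.label
  full[names(tip_states)] <- as.character(tip_states)
  L <- tip_likelihoods(tree, full, states)
  P <- edge_P_matrices(Q, tree$edge.length)
  pr <- mk_pruning(tree, L, P, prior)
  n <- length(tree$tip.label); nn <- n + tree$Nnode
  S <- length(states)
  ## outside pass: D[v] = partial likelihood of everything except v's subtree
  D <- matrix(0, nn, S)
  root <- n + 1L
  D[root, ] <- prior
  child_of <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  for (nd in rev(postorder_nodes(tree))) {
    edges <- child_of[[as.character(nd)]]
    msgs <- lapply(edges, function(e)
      drop(P[[e]] %*% pr$partial[tree$edge[e, 2], ]))
    for (i in seq_along(edges)) {
      e <- edges[i]
      ch <- tree$edge[e, 2]
      rest <- D[nd, ]
      for (j in seq_along(edges)) if (j != i) rest <- rest * msgs[[j]]
      Dch <- drop(crossprod(P[[e]], rest))   # sum_i rest_i P_ij
      s <- sum(Dch)
      D[ch, ] <- if (s > 0) Dch / s else Dch
    }
  }
  marg <- pr$partial * D
  marg <- marg / rowSums(marg)
  out <- marg[(n + 1):nn, , drop = FALSE]
  dimnames(out) <- list(as.character((n + 1):nn), states)
  out
}
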
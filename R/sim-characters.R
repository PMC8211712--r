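## Exact simulation of discrete and continuous characters along a time tree.

#' Simulate a discrete character under a continuous-time Markov process
#'
#' Exact Gillespie simulation along every branch. Returns the tip states
#' together with the full event history (the ground truth used by recovery
#' tests and by the changes-through-time machinery).
#'
#' @param tree a \code{timetree}.
#' @param Q rate matrix (1/My): rows sum to zero, off-diagonals
#'   non-negative; dimnames give the state labels.
#' @param root_dist probability distribution over states at the root
#'   (default uniform).
#' @param seed integer seed.
#' @return a \code{\link{stoch_map}} object (tip states in
#'   \code{$tip_states}, per-edge histories in \code{$maps}).
#' @export
sim_discrete <- function(tree, Q, root_dist = NULL, seed = NULL) {
  tree <- as_timetree(tree)
  Q <- validate_Q(Q)
  S <- nrow(Q)
  states <- rownames(Q)
  if (is.null(root_dist)) root_dist <- rep(1 / S, S)
  stopifnot(length(root_dist) == S, all(root_dist >= 0))
  root_dist <- root_dist / sum(root_dist)

  with_seed(seed, {
    n <- length(tree$tip.label)
    root <- n + 1L
    node_state <- integer(n + tree$Nnode)
    node_state[root] <- sample.int(S, 1, prob = root_dist)
    pre <- ape::reorder.phylo(tree, "cladewise")
    maps <- vector("list", nrow(tree$edge))
    o <- match(paste(pre$edge[, 1], pre$edge[, 2]),
               paste(tree$edge[, 1], tree$edge[, 2]))
    for (j in seq_len(nrow(pre$edge))) {
      e <- o[j]
      from <- tree$edge[e, 1]; to <- tree$edge[e, 2]
      len <- tree$edge.length[e]
      s <- node_state[from]
      seg <- numeric(0); lab <- integer(0)
      t0 <- 0
      repeat {
        r <- -Q[s, s]
        dt <- if (r > 0) stats::rexp(1, r) else Inf
        if (t0 + dt >= len) { seg <- c(seg, len - t0); lab <- c(lab, s); break }
        seg <- c(seg, dt); lab <- c(lab, s)
        t0 <- t0 + dt
        p <- Q[s, ]; p[s] <- 0
        s <- sample.int(S, 1, prob = p)
      }
      m <- seg; names(m) <- states[lab]
      maps[[e]] <- m
      node_state[to] <- s
    }
    new_stoch_map(tree, states, maps, node_state)
  })
}

validate_Q <- function(Q) {
  Q <- as.matrix(Q)
  if (nrow(Q) != ncol(Q)) stop("Q must be square")
  off <- Q; diag(off) <- 0
  if (any(off < 0)) stop("Q off-diagonal rates must be non-negative")
  if (any(abs(rowSums(Q)) > 1e-8 * (1 + max(abs(Q))))) {
    stop("rows of Q must sum to zero")
  }
  if (is.null(rownames(Q))) {
    rownames(Q) <- colnames(Q) <- as.character(seq_len(nrow(Q)))
  }
  Q
}

#' Specify a continuous trait-evolution process for simulation
#'
#' @param Sigma trait rate (drift) matrix, positive definite; a scalar is
#'   taken as a 1-trait rate.
#' @param mode one of \code{"BM"}, \code{"EB"} (or \code{"ACDC"}, the same
#'   transform with the exponent allowed positive) and \code{"OU"}.
#' @param r EB/ACDC exponent (1/My): instantaneous rate at time t since the
#'   root is multiplied by \code{exp(r * t)}.
#' @param alpha OU attraction (1/My), required for \code{mode = "OU"}.
#' @param theta OU optimum vector (defaults to the root state).
#' @param root root state vector (default zeros).
#' @param shift_age optional age (My) of a process shift applied on every
#'   lineage; \code{shift} gives the second-phase spec (same fields).
#' @param shift a \code{trait_sim_spec} for the post-shift phase.
#' @return an object of class \code{"trait_sim_spec"}.
#' @export
trait_sim_spec <- function(Sigma, mode = c("BM", "EB", "ACDC", "OU"),
                           r = 0, alpha = NULL, theta = NULL, root = NULL,
                           shift_age = NULL, shift = NULL) {
  mode <- match.arg(mode)
  if (mode == "ACDC") mode <- "EB"
  Sigma <- as.matrix(Sigma)
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("Sigma must be positive definite")
  if (mode == "OU") {
    if (is.null(alpha) || alpha <= 0) stop("OU requires alpha > 0")
  }
  p <- nrow(Sigma)
  if (is.null(root)) root <- rep(0, p)
  if (is.null(theta)) theta <- root
  stopifnot(length(root) == p, length(theta) == p)
  if (!is.null(shift) && is.null(shift_age)) {
    stop("'shift' requires 'shift_age'")
  }
  structure(list(Sigma = Sigma, mode = mode, r = r, alpha = alpha,
                 theta = theta, root = root, shift_age = shift_age,
                 shift = shift),
            class = "trait_sim_spec")
}

#' Simulate continuous traits along a time tree
#'
#' Exact simulation: BM increments are Gaussian with variance Sigma times
#' elapsed time; EB/ACDC rescales time by the integral of
#' \code{exp(r * time-since-root)}; OU uses the exact transition
#' distribution. A process shift at \code{shift_age} switches every lineage
#' to the second-phase parameters at that age.
#'
#' @param tree a \code{timetree}.
#' @param model a \code{\link{trait_sim_spec}}.
#' @param seed integer seed.
#' @return list with \code{tips} (species x trait matrix) and
#'   \code{node_values} (ancestral values, the ground truth).
#' @export
sim_traits <- function(tree, model, seed = NULL) {
  tree <- as_timetree(tree)
  stopifnot(inherits(model, "trait_sim_spec"))
  p <- nrow(model$Sigma)
  Tmax <- tree_height(tree)
  ages <- node_ages(tree)

  step <- function(x, spec, u1, u2) {
    ## advance one lineage from time-since-root u1 to u2 under 'spec'
    dt <- u2 - u1
    if (dt <= 0) return(x)
    if (spec$mode == "BM") {
      x + drop(crossprod(chol(spec$Sigma * dt), stats::rnorm(p)))
    } else if (spec$mode == "EB") {
      w <- if (abs(spec$r) < 1e-12) dt else
        (exp(spec$r * u2) - exp(spec$r * u1)) / spec$r
      x + drop(crossprod(chol(spec$Sigma * w), stats::rnorm(p)))
    } else {
      a <- spec$alpha
      m <- spec$theta + (x - spec$theta) * exp(-a * dt)
      v <- (1 - exp(-2 * a * dt)) / (2 * a)
      m + drop(crossprod(chol(spec$Sigma * v), stats::rnorm(p)))
    }
  }

  with_seed(seed, {
    n <- length(tree$tip.label)
    root <- n + 1L
    vals <- matrix(NA_real_, n + tree$Nnode, p)
    vals[root, ] <- model$root
    pre <- ape::reorder.phylo(tree, "cladewise")
    o <- match(paste(pre$edge[, 1], pre$edge[, 2]),
               paste(tree$edge[, 1], tree$edge[, 2]))
    s_u <- if (is.null(model$shift_age)) Inf else Tmax - model$shift_age
    for (j in seq_len(nrow(pre$edge))) {
      e <- o[j]
      from <- tree$edge[e, 1]; to <- tree$edge[e, 2]
      u1 <- Tmax - ages[from]; u2 <- Tmax - ages[to]
      x <- vals[from, ]
      if (u1 < s_u && u2 > s_u && !is.null(model$shift)) {
        x <- step(x, model, u1, s_u)
        x <- step(x, model$shift, s_u, u2)
      } else if (u1 >= s_u && !is.null(model$shift)) {
        x <- step(x, model$shift, u1, u2)
      } else {
        x <- step(x, model, u1, u2)
      }
      vals[to, ] <- x
    }
    tips <- vals[seq_len(n), , drop = FALSE]
    rownames(tips) <- tree$tip.label
    colnames(tips) <- colnames(model$Sigma)
    list(tips = tips, node_values = vals)
  })
}

#' Simulate traits under a painted multi-optimum Ornstein-Uhlenbeck process
#'
#' The optimum switches with the regime painted on each branch; attraction
#' and drift are shared across regimes. The root starts at the optimum of
#' the root regime.
#'
#' @param tree a \code{timetree}.
#' @param painting a \code{\link{regime_painting}} covering every branch.
#' @param optima regime x trait matrix of optima (rownames = regime ids).
#' @param alpha OU attraction (1/My).
#' @param Sigma trait drift matrix.
#' @param seed integer seed.
#' @return species x trait matrix.
#' @export
sim_regime_traits <- function(tree, painting, optima, alpha, Sigma,
                              seed = NULL) {
  tree <- as_timetree(tree)
  stopifnot(inherits(painting, "regime_painting"))
  if (length(painting$regime) != nrow(tree$edge)) {
    stop("painting must cover every branch")
  }
  optima <- as.matrix(optima)
  if (is.null(rownames(optima))) stop("'optima' needs regime rownames")
  miss <- setdiff(unique(c(painting$root_regime, painting$regime)),
                  rownames(optima))
  if (length(miss)) stop("optima missing for regimes: ",
                         paste(miss, collapse = ", "))
  Sigma <- as.matrix(Sigma)
  p <- ncol(optima)
  stopifnot(alpha > 0, nrow(Sigma) == p)

  with_seed(seed, {
    n <- length(tree$tip.label)
    root <- n + 1L
    vals <- matrix(NA_real_, n + tree$Nnode, p)
    vals[root, ] <- optima[painting$root_regime, ]
    R <- chol(Sigma)
    pre <- ape::reorder.phylo(tree, "cladewise")
    o <- match(paste(pre$edge[, 1], pre$edge[, 2]),
               paste(tree$edge[, 1], tree$edge[, 2]))
    for (j in seq_len(nrow(pre$edge))) {
      e <- o[j]
      from <- tree$edge[e, 1]; to <- tree$edge[e, 2]
      dt <- tree$edge.length[e]
      th <- optima[painting$regime[e], ]
      m <- th + (vals[from, ] - th) * exp(-alpha * dt)
      v <- (1 - exp(-2 * alpha * dt)) / (2 * alpha)
      vals[to, ] <- m + drop(crossprod(R * sqrt(v), stats::rnorm(p)))
    }
    tips <- vals[seq_len(n), , drop = FALSE]
    rownames(tips) <- tree$tip.label
    colnames(tips) <- colnames(optima)
    tips
  })
}
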
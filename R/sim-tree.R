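## Forward birth-death tree simulation, with optional diversity dependence
## and a single rate shift at a fixed age.
##
## The per-lineage speciation rate at standing diversity N is
##   lambda(N) = max(0, lambda0 - (lambda0 - mu) * N / K),
## the linear diversity-dependent form; K = Inf recovers constant rates.
## Simulations start from two crown lineages and are conditioned on the
## survival of both (resimulating on failure, capped number of retries).

#' Specify a birth-death simulation
#'
#' @param lambda0 speciation rate at low diversity (1/My).
#' @param mu extinction rate (1/My).
#' @param K carrying capacity (species); \code{Inf} disables diversity
#'   dependence.
#' @param ntip target number of surviving tips (exact), or \code{NULL}.
#' @param crown_age fixed crown age in My, or \code{NULL}. At least one of
#'   \code{ntip}, \code{crown_age} must be given. When both are given the
#'   simulation runs for \code{crown_age} My and is conditioned (by
#'   resimulation) on exactly \code{ntip} survivors.
#' @param shift_age age (My before present) of a rate shift, or \code{NULL}.
#'   Requires \code{crown_age} so the shift can be placed in absolute time.
#' @param lambda2,mu2,K2 post-shift rates; default to the pre-shift values.
#' @param max_retries resimulation cap.
#' @return an object of class \code{"sim_spec"}.
#' @export
simulation_spec <- function(lambda0, mu = 0, K = Inf, ntip = NULL,
                            crown_age = NULL, shift_age = NULL,
                            lambda2 = lambda0, mu2 = mu, K2 = K,
                            max_retries = 10000) {
  stopifnot(lambda0 >= 0, mu >= 0, K > 0, lambda2 >= 0, mu2 >= 0, K2 > 0)
  if (is.null(ntip) && is.null(crown_age)) {
    stop("give a target 'ntip', a 'crown_age', or both")
  }
  if (!is.null(ntip) && ntip < 2) stop("'ntip' must be at least 2")
  if (!is.null(shift_age)) {
    if (is.null(crown_age)) {
      stop("'shift_age' requires 'crown_age' (shifts are placed in absolute time)")
    }
    if (shift_age <= 0 || shift_age >= crown_age) {
      stop("'shift_age' must lie strictly inside (0, crown_age)")
    }
  }
  structure(list(lambda0 = lambda0, mu = mu, K = K, ntip = ntip,
                 crown_age = crown_age, shift_age = shift_age,
                 lambda2 = lambda2, mu2 = mu2, K2 = K2,
                 max_retries = max_retries),
            class = "sim_spec")
}

#' Simulate an ultrametric tree under a (possibly diversity-dependent,
#' possibly shifted) birth-death process
#'
#' Forward Gillespie simulation from two crown lineages; extinct lineages
#' are pruned and the result is conditioned on survival of both crown
#' lineages (and on the exact tip count when \code{spec$ntip} is set) by
#' resimulation. With a tip-count target and no fixed crown age, the
#' present is placed an exponential waiting time after the tip count is
#' first reached (the memoryless stopping rule).
#'
#' @param spec a \code{\link{simulation_spec}}.
#' @param seed integer seed; all randomness is local to the call.
#' @return a \code{timetree}.
#' @export
sim_tree <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "sim_spec"))
  with_seed(seed, {
    for (try in seq_len(spec$max_retries)) {
      res <- sim_tree_once(spec)
      if (!is.null(res)) return(res)
    }
    stop("no accepted simulation in ", spec$max_retries,
         " retries; the target may be unreachable under these rates")
  })
}

## one unconditioned forward pass; NULL when the run misses the target
sim_tree_once <- function(spec) {
  fixed_T <- !is.null(spec$crown_age)
  horizon <- if (fixed_T) spec$crown_age else Inf
  shift_t <- if (!is.null(spec$shift_age)) spec$crown_age - spec$shift_age else Inf

  nmax <- 4096L
  parent <- integer(nmax); btime <- numeric(nmax); dtime <- rep(NA_real_, nmax)
  alive <- logical(nmax)
  parent[1:2] <- 0L; btime[1:2] <- 0; alive[1:2] <- TRUE
  nlin <- 2L
  live <- c(1L, 2L)

  t <- 0
  reached <- FALSE
  repeat {
    N <- length(live)
    if (N == 0L) return(NULL)
    in2 <- t >= shift_t
    la0 <- if (in2) spec$lambda2 else spec$lambda0
    mu <- if (in2) spec$mu2 else spec$mu
    K <- if (in2) spec$K2 else spec$K
    la <- max(0, la0 - (la0 - mu) * N / K)
    rate <- N * (la + mu)
    dt <- if (rate > 0) stats::rexp(1, rate) else Inf
    t_next <- t + dt

    ## tip-count target without a fixed horizon: first passage + tail
    if (!fixed_T && reached) {
      t <- t_next  ## present = time of the (uncut) next event
      break
    }
    if (t < shift_t && t_next > shift_t && shift_t < horizon) {
      t <- shift_t
      next
    }
    if (t_next >= horizon) {
      t <- horizon
      break
    }
    t <- t_next
    if (stats::runif(1) < la / (la + mu)) {
      who <- live[sample.int(N, 1)]
      nlin <- nlin + 1L
      if (nlin > nmax) {
        nmax <- nmax * 2L
        length(parent) <- nmax; length(btime) <- nmax
        length(dtime) <- nmax; length(alive) <- nmax
      }
      parent[nlin] <- who; btime[nlin] <- t; alive[nlin] <- TRUE
      live <- c(live, nlin)
    } else {
      who <- sample.int(N, 1)
      id <- live[who]
      alive[id] <- FALSE; dtime[id] <- t
      live <- live[-who]
    }
    if (!is.null(spec$ntip) && !fixed_T && length(live) >= spec$ntip) {
      reached <- TRUE
    }
    if (length(live) > 100000L) return(NULL)
  }

  if (length(live) < 2L) return(NULL)
  if (!is.null(spec$ntip) && length(live) != spec$ntip) return(NULL)
  ## both crown lineages must have surviving descendants
  anc <- function(id) { while (parent[id] != 0L) id <- parent[id]; id }
  crowns <- unique(vapply(live, anc, integer(1)))
  if (length(crowns) < 2L) return(NULL)

  phy <- lineages_to_phylo(parent[1:nlin], btime[1:nlin], dtime[1:nlin], t)
  extinct <- phy$tip.label[grepl("^x", phy$tip.label)]
  if (length(extinct)) phy <- ape::drop.tip(phy, extinct)
  if (is.null(phy) || length(phy$tip.label) < 2L) return(NULL)
  as_timetree(phy)
}

## Build a phylo (including extinct tips, labelled "x<i>") from lineage
## records: each lineage is a chain broken at its birth events.
lineages_to_phylo <- function(parent, btime, dtime, present) {
  kids <- split(seq_along(parent), parent)
  rec <- function(id, from) {
    ev <- kids[[as.character(id)]]
    ev <- ev[btime[ev] > from + 0 & parent[ev] == id]
    ev <- ev[order(btime[ev])]
    end <- if (is.na(dtime[id])) present else dtime[id]
    if (!length(ev)) {
      lab <- if (is.na(dtime[id])) paste0("t", id) else paste0("x", id)
      return(paste0(lab, ":", format(end - from, digits = 12)))
    }
    tb <- btime[ev[1]]
    paste0("(", rec(id, tb), ",", rec(ev[1], tb), "):",
           format(tb - from, digits = 12))
  }
  txt <- paste0("(", rec(1L, 0), ",", rec(2L, 0), ");")
  ape::read.tree(text = txt)
}

## Branching times (ages, descending) of a pure-birth tree conditioned on
## n tips: inter-event durations with k lineages are Exp(k * lambda),
## including the final interval with n lineages. Used for gamma-test nulls,
## where only the branching times matter.
yule_branching_times <- function(n, lambda = 1) {
  g <- stats::rexp(n - 1L, rate = (2:n) * lambda)
  rev(cumsum(rev(g)))[1:(n - 1L)]
}
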
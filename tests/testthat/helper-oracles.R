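## Independent oracles and small fixtures used across the test files.

## three- and four-tip reference trees
tree3 <- function() read_timetree("((A:1,B:1):1,C:2);")
tree4 <- function() read_timetree("((A:1,B:1):1,(C:1,D:1):1);")

## Brute-force likelihood of branching times under the diversity-dependent
## birth-death process, by dense matrix-exponential propagation of the
## truncated master equation over the hidden-lineage count (independent of
## the package's ODE integrator). Unconditioned density.
dd_expm_oracle <- function(bt, lambda0, mu, K, H = 60) {
  stopifnot(requireNamespace("Matrix", quietly = TRUE))
  lam <- function(N) pmax(0, lambda0 - (lambda0 - mu) * N / K)
  bt <- sort(bt, decreasing = TRUE)
  n <- length(bt) + 1L
  y <- c(1, rep(0, H - 1))
  k <- 2L
  ev <- c(bt[-1], 0)
  cur <- bt[1]
  for (j in seq_along(ev)) {
    d <- cur - ev[j]
    ## generator over hidden count 0..H-1
    A <- matrix(0, H, H)
    for (m in 0:(H - 1)) {
      N <- k + m
      if (m > 0) A[m + 1, m] <- (N - 1 + k) * lam(N - 1)
      if (m < H - 1) A[m + 1, m + 2] <- (m + 1) * mu
      A[m + 1, m + 1] <- -(N * lam(N) + N * mu)
    }
    y <- as.numeric(Matrix::expm(A * d) %*% y)
    cur <- ev[j]
    if (j < length(ev)) {
      y <- y * lam(k + 0:(H - 1))
      k <- k + 1L
    }
  }
  log(y[1])
}

## mean pairwise squared distance by explicit double loop
disparity_loops <- function(X) {
  X <- as.matrix(X)
  m <- nrow(X)
  if (m < 2) return(0)
  tot <- 0; np <- 0
  for (i in 1:(m - 1)) for (j in (i + 1):m) {
    tot <- tot + sum((X[i, ] - X[j, ])^2)
    np <- np + 1
  }
  tot / np
}

## exact Mk likelihood by enumeration over all internal-state assignments
mk_enum_loglik <- function(tree, tips, Q, prior = NULL) {
  states <- rownames(Q)
  S <- length(states)
  if (is.null(prior)) prior <- rep(1 / S, S)
  P <- lapply(tree$edge.length, function(t) as.matrix(Matrix::expm(Q * t)))
  n <- length(tree$tip.label)
  tipidx <- match(tips[tree$tip.label], states)
  combs <- expand.grid(rep(list(seq_len(S)), tree$Nnode))
  tot <- 0
  for (r in seq_len(nrow(combs))) {
    st <- c(tipidx, as.integer(combs[r, ]))
    pr <- prior[st[n + 1]]
    for (e in seq_len(nrow(tree$edge))) {
      pr <- pr * P[[e]][st[tree$edge[e, 1]], st[tree$edge[e, 2]]]
    }
    tot <- tot + pr
  }
  log(tot)
}

## symmetric 2-state rate matrix
q2 <- function(q) {
  matrix(c(-q, q, q, -q), 2, dimnames = list(c("a", "b"), c("a", "b")))
}
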
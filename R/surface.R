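## Convergence detection on the macroevolutionary adaptive landscape:
## forward stepwise-AICc addition of multi-optimum Ornstein-Uhlenbeck
## (Hansen) regime shifts, followed by backward collapse of similar
## regimes; regimes reached by more than one shift are convergent.

#' A regime painting of a tree
#'
#' Assigns a regime identifier to every branch. A shift on an edge paints
#' that edge and all its descendants until overridden by a later shift, so
#' regimes are contiguous from shift points toward the tips.
#'
#' @param tree a \code{timetree}.
#' @param shift_edges integer vector of edge indices carrying regime
#'   shifts (may be empty); each shift opens a new regime.
#' @param regime_of_shift optional regime ids for the shifts (defaults to
#'   \code{"R1"}, \code{"R2"}, ... with the root regime \code{"R0"}).
#' @return object of class \code{"regime_painting"}: \code{regime}
#'   (per-edge character vector), \code{root_regime}, \code{shift_edges}.
#' @export
regime_painting <- function(tree, shift_edges = integer(0),
                            regime_of_shift = NULL) {
  tree <- as_timetree(tree)
  ne <- nrow(tree$edge)
  stopifnot(all(shift_edges >= 1), all(shift_edges <= ne))
  if (is.null(regime_of_shift)) {
    regime_of_shift <- sprintf("R%d", seq_along(shift_edges))
  }
  stopifnot(length(regime_of_shift) == length(shift_edges))
  regime <- rep("R0", ne)
  pre <- ape::reorder.phylo(tree, "cladewise")
  o <- match(paste(pre$edge[, 1], pre$edge[, 2]),
             paste(tree$edge[, 1], tree$edge[, 2]))
  parent_edge <- match(tree$edge[, 1], tree$edge[, 2])   # NA at root edges
  for (j in o) {
    sh <- match(j, shift_edges)
    if (!is.na(sh)) {
      regime[j] <- regime_of_shift[sh]
    } else if (!is.na(parent_edge[j])) {
      regime[j] <- regime[parent_edge[j]]
    }
  }
  structure(list(regime = regime, root_regime = "R0",
                 shift_edges = shift_edges, tree = tree),
            class = "regime_painting")
}

## Hansen weight matrix: per tip, the weight each regime's optimum
## receives in the tip expectation, for attraction alpha. The root state
## sits at the root regime's optimum, so the residual weight e^{-alpha T}
## is added to the root regime.
hansen_weights <- function(tree, painting, alpha, regimes) {
  n <- length(tree$tip.label)
  ages <- node_ages(tree)
  T <- max(ages)
  W <- matrix(0, n, length(regimes), dimnames = list(tree$tip.label, regimes))
  ## walk root-to-tip accumulating per-edge weight factors
  pre <- ape::reorder.phylo(tree, "cladewise")
  o <- match(paste(pre$edge[, 1], pre$edge[, 2]),
             paste(tree$edge[, 1], tree$edge[, 2]))
  ## per-node accumulated weights (rows reused down the tree)
  nn <- n + tree$Nnode
  acc <- matrix(0, nn, length(regimes), dimnames = list(NULL, regimes))
  acc[n + 1L, match(painting$root_regime, regimes)] <- exp(-alpha * T)
  for (j in o) {
    e <- j
    par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    w <- acc[par, ]
    ## edge spans ages [age_ch, age_par]; weight of this segment at a tip
    ## below: e^{-alpha * age_ch} - e^{-alpha * age_par}; the decay to the
    ## actual tip (age 0 for ultrametric trees) is already absorbed
    ## because ages are measured from the present
    seg <- exp(-alpha * ages[ch]) - exp(-alpha * ages[par])
    w[painting$regime[e]] <- w[painting$regime[e]] + seg
    acc[ch, ] <- w
  }
  W[] <- acc[seq_len(n), ]
  W
}

## OU covariance on an ultrametric tree (unit sigma^2, fixed root):
## V_ij = e^{-alpha d_ij} (1 - e^{-2 alpha t_a}) / (2 alpha)
ou_covariance <- function(C, T, alpha) {
  d <- 2 * (T - C)      # patristic separation between tips
  exp(-alpha * d) * (1 - exp(-2 * alpha * C)) / (2 * alpha)
}

#' Hansen (multi-optimum OU) model log-likelihood
#'
#' Each trait evolves as an OU process whose optimum follows the regime
#' painting; per trait its own attraction and drift, optima per regime,
#' traits independent given the painting. Tip expectations are the
#' Hansen weighted mixtures of the optima along each root-to-tip path.
#'
#' @param tree a \code{timetree}.
#' @param traits species x trait matrix.
#' @param painting a \code{\link{regime_painting}}.
#' @param alpha,sigma2 per-trait vectors of attraction and drift.
#' @param theta regime x trait matrix of optima.
#' @return total log-likelihood (sum over traits).
#' @export
hansen_loglik <- function(tree, traits, painting, alpha, sigma2, theta) {
  tree <- as_timetree(tree)
  X <- as.matrix(traits)[tree$tip.label, , drop = FALSE]
  p <- ncol(X)
  stopifnot(length(alpha) == p, length(sigma2) == p)
  if (any(alpha <= 0) || any(sigma2 <= 0)) stop("alpha and sigma2 must be > 0")
  regimes <- rownames(theta)
  C <- shared_time_matrix(tree)
  T <- tree_height(tree)
  ll <- 0
  for (i in seq_len(p)) {
    W <- hansen_weights(tree, painting, alpha[i], regimes)
    mu <- drop(W %*% theta[, i])
    V <- sigma2[i] * ou_covariance(C, T, alpha[i])
    U <- chol(V + diag(1e-12, nrow(V)))
    r <- backsolve(U, X[, i] - mu, transpose = TRUE)
    ll <- ll - 0.5 * (nrow(X) * log(2 * pi) + 2 * sum(log(diag(U))) +
                        sum(r^2))
  }
  ll
}

## Precomputed search context: per candidate attraction value, the
## Cholesky factor of the unit-rate OU covariance and the standardised
## data. The attraction is profiled over this fixed log-spaced grid, which
## keeps every candidate evaluation down to a small GLS solve.
hansen_context <- function(tree, X, alpha_grid) {
  C <- shared_time_matrix(tree)
  T <- tree_height(tree)
  n <- nrow(X)
  per_alpha <- lapply(alpha_grid, function(a) {
    V0 <- ou_covariance(C, T, a)
    U <- chol(V0 + diag(1e-10, n))
    list(alpha = a, U = U, logdet = 2 * sum(log(diag(U))),
         Xs = backsolve(U, X, transpose = TRUE))
  })
  list(tree = tree, X = X, n = n, p = ncol(X), T = T,
       alpha_grid = alpha_grid, per_alpha = per_alpha)
}

## per-trait profiled fit for a fixed painting: alpha on the context grid,
## sigma^2 and the regime optima profiled analytically
hansen_fit_painting <- function(ctx, painting) {
  n <- ctx$n; p <- ctx$p
  regimes <- unique(c(painting$root_regime, painting$regime))
  W_by_alpha <- lapply(ctx$per_alpha, function(pa)
    hansen_weights(ctx$tree, painting, pa$alpha, regimes))
  alpha <- numeric(p); sigma2 <- numeric(p)
  theta <- matrix(NA_real_, length(regimes), p,
                  dimnames = list(regimes, colnames(ctx$X)))
  ll <- 0
  for (i in seq_len(p)) {
    best <- NULL
    for (g in seq_along(ctx$per_alpha)) {
      pa <- ctx$per_alpha[[g]]
      Ws <- backsolve(pa$U, W_by_alpha[[g]], transpose = TRUE)
      fit <- tryCatch(stats::lm.fit(Ws, pa$Xs[, i]), error = function(e) NULL)
      if (is.null(fit)) next
      s2 <- sum(fit$residuals^2) / n
      if (!is.finite(s2) || s2 <= 0) next
      obj <- 0.5 * (n * log(2 * pi) + n * log(s2) + pa$logdet + n)
      if (is.null(best) || obj < best$obj) {
        best <- list(obj = obj, s2 = s2, th = fit$coefficients,
                     alpha = pa$alpha)
      }
    }
    if (is.null(best)) return(list(logLik = -Inf, AICc = Inf))
    alpha[i] <- best$alpha
    sigma2[i] <- best$s2
    th <- best$th
    th[is.na(th)] <- mean(ctx$X[, i])   # unidentified regime: fall back
    theta[, i] <- th
    ll <- ll - best$obj
  }
  ## parameter count: per trait alpha + sigma2, plus an optimum per
  ## regime per trait (shift locations are not counted, following the
  ## stepwise-AIC convention)
  k <- 2 * p + length(regimes) * p
  nobs <- n * p
  aicc <- 2 * k - 2 * ll + 2 * k * (k + 1) / max(nobs - k - 1, 1)
  list(logLik = ll, alpha = alpha, sigma2 = sigma2, theta = theta,
       k = k, AICc = aicc, regimes = regimes)
}

#' Forward phase: stepwise addition of adaptive-peak shifts
#'
#' Starts from a single regime and, at each step, evaluates opening a new
#' regime on every branch, accepting the shift that most improves the
#' small-sample corrected AIC; stops when no addition improves it.
#'
#' @param tree a \code{timetree}.
#' @param traits species x trait matrix (typically the first two
#'   phylogenetic PC scores).
#' @param max_shifts cap on accepted shifts.
#' @param alpha_grid multi-start grid for the per-trait attraction.
#' @return object of class \code{"surface_forward"}: list of accepted
#'   fits (first element = single-regime fit), final painting, and the
#'   AICc sequence.
#' @export
surface_forward <- function(tree, traits, max_shifts = 30,
                            alpha_grid = NULL) {
  tree <- as_timetree(tree)
  X <- as.matrix(traits)[tree$tip.label, , drop = FALSE]
  if (any(is.na(X))) stop("traits must be complete on the tree's tips")
  if (is.null(alpha_grid)) {
    alpha_grid <- exp(seq(log(0.5 / tree_height(tree)), log(3),
                          length.out = 10))
  }
  ctx <- hansen_context(tree, X, alpha_grid)
  ne <- nrow(tree$edge)

  shifts <- integer(0)
  cur <- regime_painting(tree, shifts)
  fit <- hansen_fit_painting(ctx, cur)
  seq_fits <- list(fit)
  aicc_seq <- fit$AICc
  repeat {
    if (length(shifts) >= max_shifts) break
    cand <- setdiff(seq_len(ne), shifts)
    best <- NULL; best_edge <- NA
    for (e in cand) {
      pj <- regime_painting(tree, c(shifts, e))
      fj <- hansen_fit_painting(ctx, pj)
      if (is.null(best) || fj$AICc < best$AICc) {
        best <- fj; best_edge <- e
      }
    }
    if (is.null(best) || best$AICc >= fit$AICc - 1e-9) break
    shifts <- c(shifts, best_edge)
    fit <- best
    seq_fits[[length(seq_fits) + 1]] <- fit
    aicc_seq <- c(aicc_seq, fit$AICc)
  }
  structure(list(fits = seq_fits, shifts = shifts,
                 painting = regime_painting(tree, shifts),
                 final = fit, aicc = aicc_seq, tree = tree, traits = X,
                 alpha_grid = alpha_grid),
            class = "surface_forward")
}

#' Backward phase: collapse similar adaptive peaks
#'
#' Greedily merges pairs of regimes (forcing a shared optimum) while the
#' small-sample corrected AIC improves, then classifies each surviving
#' regime as convergent (reached by more than one shift, counting the
#' root origin) or unique.
#'
#' @param forward a \code{\link{surface_forward}} result.
#' @return object of class \code{"surface_result"} with the final
#'   painting, per-regime optima and the counts summary.
#' @export
surface_backward <- function(forward) {
  tree <- forward$tree; X <- forward$traits
  ctx <- hansen_context(tree, X, forward$alpha_grid)
  shifts <- forward$shifts
  labels <- paste0("R", seq_along(shifts))
  fit <- forward$final
  repaint <- function(labels) {
    regime_painting(tree, shifts, regime_of_shift = labels)
  }
  cur_paint <- repaint(labels)
  repeat {
    regs <- unique(c("R0", labels))
    if (length(regs) < 2) break
    pairs <- utils::combn(regs, 2)
    best <- NULL; best_lab <- NULL
    for (j in seq_len(ncol(pairs))) {
      a <- pairs[1, j]; b <- pairs[2, j]
      lab2 <- labels
      if (a == "R0" || b == "R0") {
        src <- if (a == "R0") b else a
        lab2[lab2 == src] <- "R0"
      } else {
        lab2[lab2 == b] <- a
      }
      pj <- repaint(lab2)
      fj <- hansen_fit_painting(ctx, pj)
      if (is.null(best) || fj$AICc < best$AICc) {
        best <- fj; best_lab <- lab2
      }
    }
    if (is.null(best) || best$AICc >= fit$AICc - 1e-9) break
    labels <- best_lab
    fit <- best
    cur_paint <- repaint(labels)
  }
  origins <- c("R0", labels)             # one origin per shift plus root
  tab <- table(origins)
  distinct <- length(tab)
  convergent <- sum(tab > 1)
  unique_regimes <- sum(tab == 1)
  structure(list(painting = cur_paint, fit = fit,
                 n_shifts = length(shifts),
                 shift_regimes = labels,
                 n_regimes = distinct,
                 n_convergent = convergent,
                 n_unique = unique_regimes,
                 aicc = fit$AICc),
            class = "surface_result")
}

#' Run the full convergence analysis (forward + backward)
#'
#' @param tree a \code{timetree}.
#' @param traits species x trait matrix.
#' @param max_shifts cap on accepted shifts.
#' @return a \code{surface_result} with the forward object attached.
#' @export
run_surface <- function(tree, traits, max_shifts = 30) {
  fw <- surface_forward(tree, traits, max_shifts = max_shifts)
  res <- surface_backward(fw)
  res$forward <- fw
  res
}

#' @export
print.surface_result <- function(x, ...) {
  cat(sprintf(
    "Adaptive-peak analysis: %d shifts, %d regimes (%d convergent, %d unique), AICc = %.2f\n",
    x$n_shifts, x$n_regimes, x$n_convergent, x$n_unique, x$aicc))
  invisible(x)
}
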
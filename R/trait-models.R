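## Multivariate models of continuous trait evolution with an optional
## fixed-time mode shift: BM, EB/ACDC and OU phases, shared or independent
## drift matrices, compared by AIC.
##
## Tip covariance is assembled additively over the two time slices: each
## phase's process contributes the covariance it accumulates over its own
## slice of shared history. A slice element at time u from the root (tree
## height T) contributes, per unit rate,
##   BM:  du
##   EB:  exp(r u) du                (global clock from the root)
##   OU:  exp(-2 alpha (T - u)) du   (decay toward the present),
## so a shift with identical phase parameters is exactly the no-shift
## model.

#' Specify a multivariate trait-evolution model
#'
#' @param mode1 first-phase mode: \code{"BM"}, \code{"EB"} (ACDC when the
#'   exponent is allowed positive) or \code{"OU"}.
#' @param mode2 second-phase mode, or \code{NULL} for no shift.
#' @param shift_age age (My) of the mode shift (required with
#'   \code{mode2}); typically fixed at the diversification shift estimate.
#' @param independent_drift logical: second phase gets its own rate
#'   matrix.
#' @param name optional label.
#' @return object of class \code{"trait_model_spec"}.
#' @export
trait_model <- function(mode1 = c("BM", "EB", "OU"), mode2 = NULL,
                        shift_age = NULL, independent_drift = FALSE,
                        name = NULL) {
  mode1 <- match.arg(mode1)
  if (!is.null(mode2)) {
    mode2 <- match.arg(mode2, c("BM", "EB", "OU"))
    if (is.null(shift_age)) stop("'mode2' requires 'shift_age'")
    stopifnot(shift_age > 0)
  } else if (independent_drift) {
    stop("'independent_drift' requires a second phase")
  }
  if (is.null(name)) {
    long <- c(BM = "Brownian motion", EB = "early burst",
              OU = "Ornstein-Uhlenbeck")
    name <- if (is.null(mode2)) long[[mode1]] else
      paste0(long[[mode1]], " to ", long[[mode2]],
             if (independent_drift) " with independent drift" else "")
  }
  structure(list(mode1 = mode1, mode2 = mode2, shift_age = shift_age,
                 independent_drift = independent_drift, name = name),
            class = "trait_model_spec")
}

#' The full shift-model comparison set
#'
#' The three single-mode models plus every ordered mode pair, each with
#' shared and with independent drift (15 models).
#'
#' @param shift_age fixed shift age in My.
#' @return named list of \code{\link{trait_model}} specs.
#' @export
trait_model_set <- function(shift_age) {
  modes <- c("BM", "EB", "OU")
  specs <- lapply(modes, trait_model)
  for (m1 in modes) for (m2 in setdiff(modes, m1)) {
    specs <- c(specs,
               list(trait_model(m1, m2, shift_age, FALSE),
                    trait_model(m1, m2, shift_age, TRUE)))
  }
  names(specs) <- vapply(specs, `[[`, "", "name")
  specs
}

## unit-rate covariance structure of one phase over its time window
## [b1, b2] (times from the root), given the shared-time matrix C and
## tree height T
phase_structure <- function(C, T, b1, b2, mode, par) {
  ## shared time within the window runs from b1 to min(C, b2)
  hi <- pmin(C, b2)
  if (mode == "BM") {
    S <- pmax(hi - b1, 0)
  } else if (mode == "EB") {
    r <- par
    if (abs(r) < 1e-10) {
      S <- pmax(hi - b1, 0)
    } else {
      S <- (exp(r * hi) - exp(r * b1)) / r
      S[hi <= b1] <- 0
    }
  } else {
    a <- par
    S <- (exp(-2 * a * (T - hi)) - exp(-2 * a * (T - b1))) / (2 * a)
    S[hi <= b1] <- 0
  }
  S
}

#' Tip covariance structure under a trait-evolution model
#'
#' Builds the per-phase unit-rate structure matrices and, given drift
#' matrices, the full Kronecker covariance of the stacked tip data.
#'
#' @param tree a \code{timetree}.
#' @param spec a \code{\link{trait_model}}.
#' @param pars list with \code{Sigma1}, optionally \code{Sigma2},
#'   \code{r1}, \code{alpha1}, \code{r2}, \code{alpha2} as the spec
#'   requires.
#' @return list with phase structures \code{S1}, \code{S2} (NULL without
#'   shift) and the full covariance \code{V}.
#' @export
model_covariance <- function(tree, spec, pars) {
  tree <- as_timetree(tree)
  C <- shared_time_matrix(tree)
  T <- tree_height(tree)
  par1 <- switch(spec$mode1, EB = pars$r1, OU = pars$alpha1, NULL)
  if (spec$mode1 == "OU" && (is.null(pars$alpha1) || pars$alpha1 <= 0)) {
    stop("OU phase requires alpha > 0")
  }
  if (is.null(spec$mode2)) {
    S1 <- phase_structure(C, T, 0, T, spec$mode1, par1)
    V <- kronecker(as.matrix(pars$Sigma1), S1)
    return(list(S1 = S1, S2 = NULL, V = V))
  }
  b <- T - spec$shift_age
  if (b <= 0 || spec$shift_age >= T) stop("shift age outside (0, crown age)")
  par2 <- switch(spec$mode2, EB = pars$r2, OU = pars$alpha2, NULL)
  S1 <- phase_structure(C, T, 0, b, spec$mode1, par1)
  S2 <- phase_structure(C, T, b, T, spec$mode2, par2)
  Sig2 <- if (spec$independent_drift) pars$Sigma2 else pars$Sigma1
  V <- kronecker(as.matrix(pars$Sigma1), S1) +
    kronecker(as.matrix(Sig2), S2)
  list(S1 = S1, S2 = S2, V = V)
}

## log-likelihood with GLS-profiled mean; returns list(ll, mean)
trait_model_loglik <- function(V, X) {
  n <- nrow(X); p <- ncol(X)
  y <- as.vector(X)
  U <- tryCatch(chol(V + diag(1e-10, n * p)), error = function(e) NULL)
  if (is.null(U)) return(list(ll = -Inf))
  D <- kronecker(diag(p), rep(1, n))
  Ds <- backsolve(U, D, transpose = TRUE)
  ys <- backsolve(U, y, transpose = TRUE)
  m <- qr.solve(Ds, ys)
  r <- ys - Ds %*% m
  ll <- -0.5 * (n * p * log(2 * pi) + 2 * sum(log(diag(U))) + sum(r^2))
  list(ll = ll, mean = drop(m))
}

## parameter packing: Sigma via log-sd / z-transformed correlations
pack_sigma <- function(p) p * (p + 1) / 2
unpack_sigma <- function(theta, p) {
  L <- diag(exp(theta[seq_len(p)]), p)
  if (p > 1) {
    off <- theta[(p + 1):(p * (p + 1) / 2)]
    L[lower.tri(L)] <- off
  }
  tcrossprod(L)
}

#' Fit a multivariate trait-evolution model by maximum likelihood
#'
#' The mean vector is profiled by GLS; drift matrices, EB exponents and OU
#' attractions are optimised by bounded quasi-Newton with multi-starts on
#' the mode parameters.
#'
#' @param tree a \code{timetree}.
#' @param traits species x trait matrix (complete data on the tree's tips;
#'   typically the first two phylogenetic PC scores).
#' @param spec a \code{\link{trait_model}}.
#' @return object of class \code{"trait_model_fit"} with \code{estimates},
#'   \code{logLik}, \code{k}, \code{AIC}, \code{converged}.
#' @export
fit_trait_model <- function(tree, traits, spec) {
  tree <- as_timetree(tree)
  X <- as.matrix(traits)
  X <- X[stats::complete.cases(X), , drop = FALSE]
  keep <- intersect(tree$tip.label, rownames(X))
  if (length(keep) < length(tree$tip.label)) {
    tree <- as_timetree(ape::drop.tip(tree, setdiff(tree$tip.label, keep)))
  }
  X <- X[tree$tip.label, , drop = FALSE]
  n <- nrow(X); p <- ncol(X)
  C <- shared_time_matrix(tree)
  T <- tree_height(tree)
  ns <- pack_sigma(p)

  has2 <- !is.null(spec$mode2)
  nmode1 <- spec$mode1 %in% c("EB", "OU")
  nmode2 <- has2 && spec$mode2 %in% c("EB", "OU")
  ind <- isTRUE(spec$independent_drift)
  npar <- ns + (if (ind) ns else 0) + nmode1 + nmode2

  unpack <- function(theta) {
    i <- 0
    Sigma1 <- unpack_sigma(theta[1:ns], p); i <- ns
    Sigma2 <- NULL
    if (ind) { Sigma2 <- unpack_sigma(theta[i + 1:ns], p); i <- i + ns }
    out <- list(Sigma1 = Sigma1, Sigma2 = Sigma2)
    if (spec$mode1 == "EB") { out$r1 <- theta[i + 1]; i <- i + 1 }
    if (spec$mode1 == "OU") { out$alpha1 <- exp(theta[i + 1]); i <- i + 1 }
    if (has2) {
      if (spec$mode2 == "EB") { out$r2 <- theta[i + 1]; i <- i + 1 }
      if (spec$mode2 == "OU") { out$alpha2 <- exp(theta[i + 1]); i <- i + 1 }
    }
    out
  }

  negll <- function(theta) {
    pars <- unpack(theta)
    V <- tryCatch(model_covariance(tree, spec, pars)$V,
                  error = function(e) NULL)
    if (is.null(V)) return(1e10)
    ll <- trait_model_loglik(V, X)$ll
    if (!is.finite(ll)) 1e10 else -ll
  }

  ## starts: drift from the contrast BM estimate; spread of mode params
  R0 <- bm_rate_matrix(tree, X)
  sd0 <- sqrt(pmax(diag(R0), 1e-8))
  th_sigma <- c(log(sd0), rep(0, ns - p))
  base <- c(th_sigma, if (ind) th_sigma)
  mvals <- function(active, mode) {
    if (!active) 0 else if (mode == "EB") c(-0.15, 0.05, -0.5) else c(-2, 0, 2)
  }
  mode_starts <- expand.grid(m1 = mvals(nmode1, spec$mode1),
                             m2 = mvals(nmode2, spec$mode2 %||% "BM"))
  start1 <- function(v, mode) if (mode == "OU") log(0.2) + v else v

  lower <- rep(-Inf, npar); upper <- rep(Inf, npar)
  i <- ns + (if (ind) ns else 0)
  if (nmode1) {
    if (spec$mode1 == "EB") { lower[i + 1] <- -2; upper[i + 1] <- 2 }
    else { lower[i + 1] <- log(1e-4); upper[i + 1] <- log(20) }
    i <- i + 1
  }
  if (nmode2) {
    if (spec$mode2 == "EB") { lower[i + 1] <- -2; upper[i + 1] <- 2 }
    else { lower[i + 1] <- log(1e-4); upper[i + 1] <- log(20) }
  }

  best <- NULL
  for (s in seq_len(nrow(mode_starts))) {
    th <- base
    if (nmode1) th <- c(th, start1(mode_starts$m1[s], spec$mode1))
    if (nmode2) th <- c(th, start1(mode_starts$m2[s], spec$mode2))
    o <- tryCatch(
      stats::nlminb(th, negll, lower = lower, upper = upper,
                    control = list(iter.max = 500, eval.max = 1000)),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$objective < best$objective)) {
      best <- o
    }
  }
  if (is.null(best)) stop("trait-model optimisation failed")
  pars <- unpack(best$par)
  V <- model_covariance(tree, spec, pars)$V
  fitm <- trait_model_loglik(V, X)
  ll <- -best$objective
  k <- npar + p                         # profiled mean counts as p params
  structure(list(spec = spec, estimates = c(pars, list(mean = fitm$mean)),
                 logLik = ll, k = k, AIC = 2 * k - 2 * ll, ntip = n,
                 converged = best$objective < 1e9),
            class = "trait_model_fit")
}

#' @export
print.trait_model_fit <- function(x, ...) {
  cat(sprintf("%s: logLik = %.3f, k = %d, AIC = %.2f\n",
              x$spec$name, x$logLik, x$k, x$AIC))
  invisible(x)
}

#' Compare trait-evolution model fits
#'
#' @param fits list of \code{trait_model_fit}.
#' @return a \code{model_table} (see \code{\link{compare_models}}).
#' @export
compare_trait_models <- function(fits) compare_models(fits)
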
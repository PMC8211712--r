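## Maximum-likelihood fitting and AIC comparison of the birth-death model
## family: constant rates, diversity dependence, and a single shift (in
## speciation rate, extinction rate and/or carrying capacity) at an
## estimated time.

#' Specify a diversification model
#'
#' Builds a model specification in the standard shifted diversity-dependent
#' family. Pre-shift parameters are \code{lambda1, mu1, K1}; post-shift
#' parameters either get their own free value or are tied to the pre-shift
#' one, according to \code{shift}:
#' \describe{
#'   \item{\code{"none"}}{no shift; a single-phase (possibly
#'     diversity-dependent) process.}
#'   \item{\code{"lambda"}}{speciation rate shifts; \code{mu2 = mu1},
#'     \code{K2 = K1}.}
#'   \item{\code{"lambda_K"}}{speciation rate and carrying capacity shift.}
#'   \item{\code{"lambda_mu_K"}}{all three parameters shift.}
#'   \item{\code{"mu_K"}}{extinction rate and carrying capacity shift;
#'     \code{lambda2 = lambda1}.}
#'   \item{\code{"K"}}{carrying capacity shifts only.}
#' }
#'
#' @param shift which parameters shift (see Details).
#' @param dd logical: diversity dependence (finite carrying capacity K). If
#'   \code{FALSE}, K is fixed at infinity.
#' @param mu either \code{"free"} or a fixed non-negative value (fixing
#'   \code{mu = 0} gives the pure-birth members of the family, for which
#'   the likelihood is analytic).
#' @param t_shift either \code{"free"} (profiled over a grid, then refined)
#'   or a fixed age in My.
#' @param name optional label.
#' @return an object of class \code{"div_model_spec"}.
#' @export
diversification_model <- function(shift = c("none", "lambda", "lambda_K",
                                            "lambda_mu_K", "mu_K", "K"),
                                  dd = TRUE, mu = "free",
                                  t_shift = "free", name = NULL) {
  shift <- match.arg(shift)
  if (!identical(mu, "free")) {
    stopifnot(is.numeric(mu), mu >= 0)
  }
  if (!identical(t_shift, "free")) {
    stopifnot(is.numeric(t_shift), t_shift > 0)
  }
  if (!dd && shift %in% c("lambda_K", "mu_K", "K", "lambda_mu_K")) {
    ## shifts in K make no sense without diversity dependence; K-only
    ## rows still shift mu/K, so require dd
    if (shift != "lambda_mu_K") stop("shift in K requires dd = TRUE")
  }
  if (is.null(name)) {
    name <- switch(shift,
      none = if (dd) "diversity dependent, no shift" else "constant-rate birth-death",
      lambda = "shift in speciation rate",
      lambda_K = "shift in speciation rate and carrying capacity",
      lambda_mu_K = "shift in speciation, extinction and carrying capacity",
      mu_K = "shift in extinction rate and carrying capacity",
      K = "shift in carrying capacity")
  }
  structure(list(shift = shift, dd = dd, mu = mu, t_shift = t_shift,
                 name = name),
            class = "div_model_spec")
}

#' The standard six-model comparison set
#'
#' The shifted diversity-dependent family usually screened when testing for
#' a diversification-rate shift: shifts in speciation rate, speciation rate
#' + carrying capacity, all three parameters, extinction rate + carrying
#' capacity, carrying capacity alone, and the no-shift diversity-dependent
#' model.
#'
#' @param mu \code{"free"} or a fixed value applied to every member.
#' @return named list of \code{\link{diversification_model}} specs.
#' @export
diversification_model_set <- function(mu = "free") {
  specs <- list(
    diversification_model("lambda", mu = mu),
    diversification_model("lambda_K", mu = mu),
    diversification_model("lambda_mu_K", mu = mu),
    diversification_model("mu_K", mu = mu),
    diversification_model("K", mu = mu),
    diversification_model("none", mu = mu)
  )
  names(specs) <- vapply(specs, `[[`, "", "name")
  specs
}

## which of la1, mu1, K1, la2, mu2, K2 are free / tied for a spec
spec_layout <- function(spec) {
  free <- c(la1 = TRUE, mu1 = identical(spec$mu, "free"), K1 = spec$dd,
            la2 = FALSE, mu2 = FALSE, K2 = FALSE)
  tie <- c(la2 = "la1", mu2 = "mu1", K2 = "K1")
  if (spec$shift != "none") {
    if (spec$shift %in% c("lambda", "lambda_K", "lambda_mu_K")) {
      free["la2"] <- TRUE
    }
    if (spec$shift == "lambda_mu_K" && identical(spec$mu, "free")) {
      free["mu2"] <- TRUE
    }
    if (spec$shift == "mu_K" && identical(spec$mu, "free")) {
      free["mu2"] <- TRUE
    }
    if (spec$shift %in% c("lambda_K", "lambda_mu_K", "mu_K", "K") && spec$dd) {
      free["K2"] <- TRUE
    }
  }
  list(free = free, tie = tie)
}

## full parameter list from the free vector (log-scale lambda/K, identity mu)
spec_params <- function(spec, theta, t_shift) {
  lay <- spec_layout(spec)
  p <- c(la1 = NA, mu1 = NA, K1 = NA, la2 = NA, mu2 = NA, K2 = NA)
  j <- 0
  for (nm in names(lay$free)) {
    if (lay$free[[nm]]) {
      j <- j + 1
      p[nm] <- if (nm %in% c("mu1", "mu2")) theta[j] else exp(theta[j])
    }
  }
  if (!identical(spec$mu, "free")) p["mu1"] <- spec$mu
  if (!spec$dd) p["K1"] <- Inf
  for (nm in c("la2", "mu2", "K2")) {
    if (is.na(p[nm])) p[nm] <- p[[lay$tie[[nm]]]]
  }
  c(as.list(p), list(t_shift = t_shift))
}

## log-likelihood dispatcher for a full parameter list
div_loglik <- function(bt, p) {
  hasK <- is.finite(p$K1) || is.finite(p$K2)
  shift <- !is.null(p$t_shift) && is.finite(p$t_shift) && p$t_shift > 0 &&
    p$t_shift < bt[1]
  mu0 <- p$mu1 == 0 && p$mu2 == 0
  if (!shift) {
    if (!hasK) return(crbd_loglik(bt, p$la1, p$mu1))
    return(dd_loglik(bt, p$la1, p$mu1, p$K1))
  }
  if (mu0) {
    ## analytic piecewise pure-birth (diversity dependent or not);
    ## interval entry 1 is the youngest (post-shift) phase
    return(dd_loglik_pb(bt, c(p$la2, p$la1), c(p$K2, p$K1),
                        breaks = p$t_shift))
  }
  if (!hasK) {
    return(shifted_bd_loglik(bt, breaks = p$t_shift,
                             lambda = c(p$la2, p$la1),
                             mu = c(p$mu2, p$mu1)))
  }
  dd_loglik_ode(bt, lambda0 = p$la1, mu = p$mu1, K = p$K1,
                breaks = p$t_shift, lambda2 = p$la2, mu2 = p$mu2,
                K2 = p$K2)
}

#' Fit a diversification model by maximum likelihood
#'
#' Free parameters are optimised by bounded quasi-Newton from several
#' deterministic starting points; a free shift time is profiled over a grid
#' (0.5 My steps across the central 90 percent of the crown age) and then
#' refined locally.
#'
#' @param tree a \code{timetree}, or a descending branching-time vector.
#' @param spec a \code{\link{diversification_model}}.
#' @param grid_step grid resolution for the shift-time profile (My).
#' @param n_starts number of deterministic multi-starts.
#' @return object of class \code{"div_model_fit"}: the spec, ML estimates,
#'   log-likelihood, number of free parameters \code{k}, AIC and a
#'   convergence flag.
#' @export
fit_diversification <- function(tree, spec, grid_step = 0.5, n_starts = 8) {
  stopifnot(inherits(spec, "div_model_spec"))
  bt <- if (inherits(tree, "phylo")) branching_times(tree) else
    sort(as.numeric(tree), decreasing = TRUE)
  n <- length(bt) + 1L
  crown <- bt[1]
  lay <- spec_layout(spec)
  nfree <- sum(lay$free)

  negll <- function(theta, ts) {
    p <- spec_params(spec, theta, ts)
    if (p$la1 <= 0 || p$la2 <= 0 || p$mu1 < 0 || p$mu2 < 0) return(1e10)
    if (!is.finite(p$K1) && p$la1 <= p$mu1) return(1e10)
    if (!is.finite(p$K2) && p$la2 <= p$mu2) return(1e10)
    ll <- tryCatch(suppressWarnings(div_loglik(bt, p)),
                   error = function(e) -Inf)
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  ## deterministic multi-starts: speciation near the pure-birth estimate,
  ## K spread from just above n to effectively infinite
  la_hat <- max((n - 2) / sum(bt), 1e-4)
  la_grid <- la_hat * c(0.5, 1, 2, 4)
  K_grid <- c(1.2 * n, 3 * n, 10 * n, 100 * n)
  starts <- list()
  for (i in seq_len(n_starts)) {
    la0 <- la_grid[(i - 1) %% 4 + 1]
    K0 <- K_grid[((i - 1) %/% 4) %% 4 + 1]
    th <- numeric(0)
    for (nm in names(lay$free)) {
      if (!lay$free[[nm]]) next
      th <- c(th, switch(nm,
        la1 = log(la0), la2 = log(la0 * 1.5),
        mu1 = 0.1 * la0 * (i %% 2), mu2 = 0.05 * la0,
        K1 = log(K0), K2 = log(K0)))
    }
    starts[[i]] <- th
  }

  lower <- rep(-Inf, nfree); upper <- rep(Inf, nfree)
  j <- 0
  for (nm in names(lay$free)) {
    if (!lay$free[[nm]]) next
    j <- j + 1
    if (nm %in% c("mu1", "mu2")) { lower[j] <- 0; upper[j] <- 5 }
    else if (nm %in% c("la1", "la2")) { lower[j] <- log(1e-5); upper[j] <- log(20) }
    else { lower[j] <- log(2.001); upper[j] <- log(1e8) }
  }

  run_at <- function(ts, inits) {
    best <- NULL
    for (th in inits) {
      o <- tryCatch(
        stats::nlminb(th, negll, ts = ts, lower = lower, upper = upper,
                      control = list(iter.max = 400, eval.max = 800)),
        error = function(e) NULL)
      if (is.null(o)) next
      if (is.null(best) || o$objective < best$objective) best <- o
    }
    best
  }

  free_ts <- spec$shift != "none" && identical(spec$t_shift, "free")
  if (spec$shift == "none") {
    sol <- run_at(NA_real_, starts)
    ts_hat <- NA_real_
  } else if (!free_ts) {
    sol <- run_at(spec$t_shift, starts)
    ts_hat <- spec$t_shift
  } else {
    grid <- seq(0.05 * crown, 0.95 * crown, by = grid_step)
    best <- NULL; ts_hat <- NA_real_
    warm <- starts
    for (ts in grid) {
      o <- run_at(ts, warm)
      if (!is.null(o)) {
        warm <- c(list(o$par), starts[1])
        if (is.null(best) || o$objective < best$objective) {
          best <- o; ts_hat <- ts
        }
      }
    }
    if (is.null(best)) stop("no successful optimisation on the shift grid")
    ## local refinement of the shift time around the best grid point
    f_ts <- function(ts) run_at(ts, list(best$par))$objective
    opt <- stats::optimize(f_ts, c(max(0.01 * crown, ts_hat - grid_step),
                                   min(0.99 * crown, ts_hat + grid_step)))
    if (opt$objective < best$objective) {
      ts_hat <- opt$minimum
      best <- run_at(ts_hat, list(best$par))
    }
    sol <- best
  }
  if (is.null(sol)) stop("optimisation failed for all starting points")

  k <- nfree + as.integer(free_ts)
  est <- spec_params(spec, sol$par, ts_hat)
  ll <- -sol$objective
  structure(list(spec = spec, estimates = est, logLik = ll, k = k,
                 AIC = 2 * k - 2 * ll, ntip = n,
                 converged = is.finite(ll) && sol$objective < 1e9),
            class = "div_model_fit")
}

#' @export
print.div_model_fit <- function(x, ...) {
  cat(sprintf("%s: logLik = %.3f, k = %d, AIC = %.2f\n",
              x$spec$name, x$logLik, x$k, x$AIC))
  e <- x$estimates
  cat(sprintf("  la1 = %.4g, mu1 = %.4g, K1 = %.4g", e$la1, e$mu1, e$K1))
  if (x$spec$shift != "none") {
    cat(sprintf(" | la2 = %.4g, mu2 = %.4g, K2 = %.4g, t-shift = %.2f",
                e$la2, e$mu2, e$K2, e$t_shift))
  }
  cat("\n")
  invisible(x)
}

#' Compare fitted models by AIC
#'
#' @param fits list of \code{div_model_fit} (or any objects with
#'   \code{$AIC}, \code{$logLik}, \code{$k} and a name); non-converged fits
#'   are dropped with a warning.
#' @return data.frame of class \code{"model_table"} sorted by AIC, with
#'   \code{dAIC} and Akaike weights \code{AICw}.
#' @export
compare_models <- function(fits) {
  if (!length(fits)) stop("empty fit list")
  ok <- vapply(fits, function(f) isTRUE(f$converged) || is.null(f$converged),
               logical(1))
  if (!all(ok)) {
    warning(sum(!ok), " non-converged fit(s) excluded from the comparison")
  }
  fits <- fits[ok]
  if (!length(fits)) stop("no converged fits to compare")
  nm <- names(fits)
  if (is.null(nm)) {
    nm <- vapply(fits, function(f)
      if (!is.null(f$spec$name)) f$spec$name else "model", "")
  }
  tab <- data.frame(
    model = nm,
    logLik = vapply(fits, function(f) as.numeric(f$logLik), numeric(1)),
    k = vapply(fits, function(f) as.numeric(f$k), numeric(1)),
    AIC = vapply(fits, function(f) as.numeric(f$AIC), numeric(1)),
    stringsAsFactors = FALSE
  )
  tab <- tab[order(tab$AIC), ]
  tab$dAIC <- tab$AIC - tab$AIC[1]
  tab$AICw <- akaike_weights(tab$AIC)
  rownames(tab) <- NULL
  class(tab) <- c("model_table", "data.frame")
  tab
}
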
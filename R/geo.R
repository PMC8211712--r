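## Ancestral geographic reconstruction: longitude/latitude embedded on the
## unit sphere as 3-D Cartesian coordinates, each axis evolving by
## Brownian motion; ancestral positions are sampled from the exact
## conditional Gaussian given the tips and projected back to the sphere.
## Credible regions discard the 5% of samples farthest (great-circle) from
## the centroid.

#' Spherical coordinate conversions
#'
#' \code{to_cartesian} maps (longitude, latitude) in decimal degrees to a
#' unit 3-vector; \code{from_cartesian} renormalises and inverts.
#'
#' @param lon,lat coordinates in decimal degrees.
#' @return \code{to_cartesian}: n x 3 matrix; \code{from_cartesian}:
#'   data.frame with \code{lon}, \code{lat}.
#' @export
to_cartesian <- function(lon, lat) {
  if (any(lon < -180 | lon > 180)) stop("longitude outside [-180, 180]")
  if (any(lat < -90 | lat > 90)) stop("latitude outside [-90, 90]")
  lo <- lon * pi / 180; la <- lat * pi / 180
  cbind(x = cos(la) * cos(lo), y = cos(la) * sin(lo), z = sin(la))
}

#' @rdname to_cartesian
#' @param v n x 3 matrix of Cartesian coordinates.
#' @export
from_cartesian <- function(v) {
  v <- matrix(v, ncol = 3)
  nrm <- sqrt(rowSums(v^2))
  if (any(nrm < 1e-12)) stop("zero vector cannot be projected to the sphere")
  v <- v / nrm
  data.frame(lon = atan2(v[, 2], v[, 1]) * 180 / pi,
             lat = asin(pmin(pmax(v[, 3], -1), 1)) * 180 / pi)
}

## REML Brownian rate from contrasts, averaged over the three axes
geo_bm_rate <- function(tree, xyz) {
  rates <- apply(xyz, 2, function(y) mean(ape::pic(y, tree)^2))
  mean(rates)
}

## covariance (shared root-path time) between arbitrary points on the
## tree: each point is (edge = 0 for a node, position age) -- represented
## by the age and the node *below* it (for along-branch points)
point_cov <- function(tree, nodes_below, ages_at) {
  ## shared time between two points = time from root to their MRCA along
  ## the tree, capped by each point's own depth
  n <- length(tree$tip.label)
  anc <- ancestor_list(tree)
  T <- tree_height(tree)
  depth <- T - ages_at
  m <- length(nodes_below)
  V <- matrix(0, m, m)
  for (i in seq_len(m)) for (j in i:m) {
    a <- mrca_of(anc, nodes_below[i], nodes_below[j])
    ta <- T - a$age
    V[i, j] <- V[j, i] <- min(ta, depth[i], depth[j])
  }
  V
}

## per-node ancestor paths with ages
ancestor_list <- function(tree) {
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  ages <- node_ages(tree)
  parent <- rep(NA_integer_, nn)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  paths <- vector("list", nn)
  for (v in seq_len(nn)) {
    p <- v
    while (!is.na(p)) { paths[[v]] <- c(paths[[v]], p); p <- parent[p] }
  }
  list(paths = paths, ages = ages)
}

mrca_of <- function(anc, a, b) {
  pa <- anc$paths[[a]]; pb <- anc$paths[[b]]
  common <- intersect(pa, pb)
  ## first common ancestor along a's path
  m <- pa[match(TRUE, pa %in% pb)]
  list(node = m, age = anc$ages[m])
}

#' Reconstruct ancestral geographic positions
#'
#' Fits a Brownian-motion rate to the sphere-embedded coordinates (REML
#' from contrasts, shared across the three axes) and samples ancestral
#' positions at the requested targets from the exact conditional Gaussian
#' given the tips, projecting each sample back onto the sphere. Targets
#' are internal nodes and/or a time slice: an age in My yields one target
#' per lineage crossing that age.
#'
#' @param tree a \code{timetree}.
#' @param coords data.frame with columns \code{lon}, \code{lat} and
#'   rownames (or a \code{tip} column) giving tip labels.
#' @param nodes integer vector of internal node numbers (default: the
#'   root).
#' @param at_age optional age (My): reconstruct every lineage crossing
#'   this age.
#' @param n_draws posterior draws per target.
#' @param seed integer seed.
#' @return list of \code{\link{credible_region}} objects, one per target,
#'   named by node or \code{"age<t>@<edge>"}.
#' @export
geo_reconstruct <- function(tree, coords, nodes = NULL, at_age = NULL,
                            n_draws = 1000, seed = NULL) {
  tree <- as_timetree(tree)
  if (!is.null(coords$tip)) rownames(coords) <- coords$tip
  sp <- intersect(tree$tip.label, rownames(coords))
  if (length(sp) < 3) stop("need coordinates for at least 3 tips")
  if (length(sp) < length(tree$tip.label)) {
    tree <- as_timetree(ape::drop.tip(tree, setdiff(tree$tip.label, sp)))
  }
  xyz <- to_cartesian(coords[tree$tip.label, "lon"],
                      coords[tree$tip.label, "lat"])
  rownames(xyz) <- tree$tip.label
  n <- length(tree$tip.label)
  rate <- geo_bm_rate(tree, xyz)
  crown <- tree_height(tree)

  targets <- list()
  if (is.null(nodes) && is.null(at_age)) nodes <- n + 1L
  if (!is.null(nodes)) {
    for (nd in nodes) {
      targets[[as.character(nd)]] <- list(node_below = nd,
                                          age = node_ages(tree)[nd])
    }
  }
  if (!is.null(at_age)) {
    if (at_age >= crown) stop("target age is older than the crown")
    ea <- edge_ages(tree)
    cross <- which(ea$age_top > at_age & ea$age_bottom <= at_age)
    for (e in cross) {
      targets[[sprintf("age%g@%d", at_age, e)]] <-
        list(node_below = ea$child[e], age = at_age)
    }
  }

  ## joint covariance of (targets, tips) under unit-rate BM
  nodes_below <- c(vapply(targets, `[[`, 0, "node_below"), seq_len(n))
  ages_at <- c(vapply(targets, `[[`, 0, "age"), rep(0, n))
  V <- point_cov(tree, nodes_below, ages_at) * rate
  m <- length(targets)
  Vtt <- V[seq_len(m), seq_len(m), drop = FALSE]
  Vtx <- V[seq_len(m), m + seq_len(n), drop = FALSE]
  Vxx <- V[m + seq_len(n), m + seq_len(n), drop = FALSE]
  ## GLS root mean per axis
  U <- chol(Vxx + diag(1e-10 * max(Vxx), n))
  ones <- rep(1, n)
  a <- gls_fit(cbind(ones), xyz, Vxx + diag(1e-10 * max(Vxx), n))
  Xc <- xyz - ones %*% a
  iVx <- backsolve(U, backsolve(U, Xc, transpose = TRUE))
  mean_t <- matrix(rep(a, each = m), m, 3) + Vtx %*% iVx
  K <- backsolve(U, t(Vtx), transpose = TRUE)   # U'^{-1} Vxt
  cond_V <- Vtt - crossprod(K)
  ## flat prior on the ancestral mean: add the GLS prediction-variance
  ## term, so the root itself carries the usual (1' Vxx^-1 1)^-1 variance
  ones_s <- backsolve(U, ones, transpose = TRUE)
  h <- 1 - drop(crossprod(K, ones_s))
  cond_V <- cond_V + (h %o% h) / sum(ones_s^2)
  cond_V <- (cond_V + t(cond_V)) / 2
  with_seed(seed, {
    draws <- array(0, c(n_draws, m, 3))
    ev <- eigen(cond_V, symmetric = TRUE)
    L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), m)
    for (ax in 1:3) {
      Z <- matrix(stats::rnorm(n_draws * m), m, n_draws)
      draws[, , ax] <- t(mean_t[, ax] + L %*% Z)
    }
    out <- lapply(seq_len(m), function(i) {
      credible_region(draws[, i, , drop = TRUE])
    })
    names(out) <- names(targets)
    for (i in seq_len(m)) {
      out[[i]]$target <- names(targets)[i]
      out[[i]]$age <- ages_at[i]
      out[[i]]$conditional_mean <- from_cartesian(matrix(mean_t[i, ], 1))
      out[[i]]$rate <- rate
    }
    out
  })
}

#' 95% centroid-trimmed credible region of spherical samples
#'
#' The centroid is the normalised mean vector; the 5% of samples with the
#' largest great-circle (angular) distance from it are discarded.
#'
#' @param samples n x 3 matrix of Cartesian samples (rows renormalised).
#' @param keep fraction of samples retained (default 0.95).
#' @return object of class \code{"geo_region"}: \code{centroid} (lon/lat),
#'   \code{retained} (lon/lat data.frame), \code{retained_xyz}.
#' @export
credible_region <- function(samples, keep = 0.95) {
  v <- matrix(samples, ncol = 3)
  if (nrow(v) < 20) stop("need at least 20 samples")
  v <- v / sqrt(rowSums(v^2))
  ctr <- colMeans(v)
  if (sqrt(sum(ctr^2)) < 1e-6) stop("antipodally balanced samples: centroid undefined")
  ctr <- ctr / sqrt(sum(ctr^2))
  ang <- acos(pmin(pmax(v %*% ctr, -1), 1))
  n_keep <- ceiling(keep * nrow(v))
  idx <- order(ang)[seq_len(n_keep)]
  structure(list(centroid = from_cartesian(matrix(ctr, 1)),
                 centroid_xyz = ctr,
                 retained_xyz = v[idx, , drop = FALSE],
                 retained = from_cartesian(v[idx, , drop = FALSE]),
                 n_total = nrow(v), n_retained = n_keep),
            class = "geo_region")
}

#' @export
print.geo_region <- function(x, ...) {
  cat(sprintf(
    "Credible region: centroid (%.3f, %.3f), %d of %d samples retained\n",
    x$centroid$lon, x$centroid$lat, x$n_retained, x$n_total))
  invisible(x)
}
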
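## Phylogenetic size correction, phylogenetic PCA, the node height test
## and Ward clustering of morphotypes.

## GLS solve against the BM covariance C via its Cholesky factor
gls_fit <- function(X, y, C) {
  U <- chol(C)
  Xs <- backsolve(U, X, transpose = TRUE)
  ys <- backsolve(U, y, transpose = TRUE)
  qr.solve(Xs, ys)
}

#' Phylogenetic size correction by generalised least squares
#'
#' Regresses a trait on body size under Brownian-motion covariance
#' (GLS with covariance proportional to shared path length) and returns
#' the phylogenetically corrected residuals. On a star phylogeny this
#' reduces exactly to ordinary least squares.
#'
#' @param tree a \code{timetree}.
#' @param y named response trait vector.
#' @param x named predictor (body length) vector.
#' @param log_transform regress on \code{log(x)} instead of \code{x}.
#' @return named residual vector over the species shared by tree and data.
#' @export
pgls_residuals <- function(tree, y, x, log_transform = FALSE) {
  sp <- intersect(tree$tip.label, intersect(names(y), names(x)))
  sp <- sp[!is.na(y[sp]) & !is.na(x[sp])]
  if (length(sp) < 3) stop("fewer than 3 species shared by tree and data")
  if (length(sp) < length(tree$tip.label)) {
    tree <- as_timetree(ape::drop.tip(tree, setdiff(tree$tip.label, sp)))
  }
  sp <- tree$tip.label
  xv <- if (log_transform) log(x[sp]) else x[sp]
  X <- cbind(intercept = 1, x = xv)
  if (qr(X)$rank < 2) stop("singular design (constant predictor)")
  C <- shared_time_matrix(tree)
  beta <- gls_fit(X, y[sp], C)
  res <- y[sp] - drop(X %*% beta)
  names(res) <- sp
  res
}

#' Phylogenetic principal component analysis
#'
#' Eigen-decomposition of the evolutionary (Brownian) trait covariance
#' matrix estimated by GLS; scores are the data centred on the GLS
#' phylogenetic mean projected on the eigenvectors. On a star phylogeny
#' this reduces to ordinary covariance PCA.
#'
#' @param tree a \code{timetree}.
#' @param traits species x trait matrix (complete cases used).
#' @return object of class \code{"phylo_pca"}: \code{values},
#'   \code{vectors}, \code{scores}, \code{cum_var}, \code{mean}.
#' @export
phylo_pca <- function(tree, traits) {
  X <- as.matrix(traits)
  if (ncol(X) < 2) stop("need at least 2 traits")
  X <- X[stats::complete.cases(X), , drop = FALSE]
  keep <- intersect(tree$tip.label, rownames(X))
  if (length(keep) < 3) stop("need at least 3 species")
  if (length(keep) < length(tree$tip.label)) {
    tree <- as_timetree(ape::drop.tip(tree, setdiff(tree$tip.label, keep)))
  }
  X <- X[tree$tip.label, , drop = FALSE]
  n <- nrow(X)
  C <- shared_time_matrix(tree)
  U <- chol(C)
  ones <- rep(1, n)
  a <- gls_fit(cbind(ones), X, C)            # GLS phylogenetic mean
  Xc <- X - ones %*% a
  Xs <- backsolve(U, Xc, transpose = TRUE)
  R <- crossprod(Xs) / (n - 1)               # evolutionary covariance
  eg <- eigen(R, symmetric = TRUE)
  rk <- sum(eg$values > max(eg$values) * 1e-10)
  if (rk < ncol(X)) {
    warning("rank-deficient trait data: ", ncol(X) - rk,
            " axis/axes dropped")
  }
  vec <- eg$vectors[, seq_len(rk), drop = FALSE]
  val <- eg$values[seq_len(rk)]
  dimnames(vec) <- list(colnames(X), paste0("PC", seq_len(rk)))
  scores <- Xc %*% vec
  structure(list(values = val, vectors = vec, scores = scores,
                 cum_var = cumsum(val) / sum(eg$values[eg$values > 0]),
                 mean = drop(a)),
            class = "phylo_pca")
}

#' @export
print.phylo_pca <- function(x, ...) {
  cat("Phylogenetic PCA\n")
  cat("  eigenvalues:", paste(signif(x$values, 4), collapse = ", "), "\n")
  cat("  cumulative variance:",
      paste(sprintf("%.1f%%", 100 * x$cum_var), collapse = ", "), "\n")
  invisible(x)
}

#' Node height test for rate change through time
#'
#' Regresses the absolute standardised independent contrast of a trait on
#' the height (distance from the root) of the node generating it; a
#' significant positive slope indicates rates increasing toward the
#' present.
#'
#' @param tree a \code{timetree}.
#' @param trait named trait vector.
#' @return object of class \code{"node_height_test"}: \code{slope},
#'   \code{p_value}, the fitted \code{lm}, and the per-node data.
#' @export
node_height_test <- function(tree, trait) {
  sp <- intersect(tree$tip.label, names(trait))
  sp <- sp[!is.na(trait[sp])]
  if (length(sp) < 4) stop("need at least 4 tips (3 contrasts)")
  if (length(sp) < length(tree$tip.label)) {
    tree <- as_timetree(ape::drop.tip(tree, setdiff(tree$tip.label, sp)))
  }
  pic <- ape::pic(trait[tree$tip.label], tree)
  n <- length(tree$tip.label)
  ages <- node_ages(tree)
  height <- max(ages) - ages[(n + 1):(n + tree$Nnode)]
  d <- data.frame(node = (n + 1):(n + tree$Nnode),
                  height = height, abs_contrast = abs(pic))
  fit <- stats::lm(abs_contrast ~ height, data = d)
  sm <- summary(fit)
  structure(list(slope = sm$coefficients["height", "Estimate"],
                 p_value = sm$coefficients["height", "Pr(>|t|)"],
                 fit = fit, data = d),
            class = "node_height_test")
}

#' @export
print.node_height_test <- function(x, ...) {
  cat(sprintf("Node height test: slope = %.4g, p = %.4g (%d contrasts)\n",
              x$slope, x$p_value, nrow(x$data)))
  invisible(x)
}

#' Ward clustering of species in trait space
#'
#' Agglomerative hierarchical clustering with Ward's criterion on
#' Euclidean distances (\code{hclust} method \code{"ward.D2"}), cut into
#' \code{k} morphotype groups. Species order gives deterministic
#' tie-breaking.
#'
#' @param traits species x trait matrix (complete cases used).
#' @param k number of clusters.
#' @return object of class \code{"ward_clusters"}: \code{labels} (named
#'   integer vector) and \code{dendrogram} (the \code{hclust} object).
#' @export
ward_clusters <- function(traits, k) {
  X <- as.matrix(traits)
  X <- X[stats::complete.cases(X), , drop = FALSE]
  if (k > nrow(X)) stop("k exceeds the number of species")
  hc <- stats::hclust(stats::dist(X), method = "ward.D2")
  labels <- stats::cutree(hc, k = k)
  structure(list(labels = labels, dendrogram = hc, k = k),
            class = "ward_clusters")
}

#' @export
print.ward_clusters <- function(x, ...) {
  cat(sprintf("Ward clustering: %d clusters, sizes %s\n", x$k,
              paste(table(x$labels), collapse = ", ")))
  invisible(x)
}
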
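## Time-calibrated tree data model built on ape's "phylo" class.
##
## A "timetree" is a rooted, binary, ultrametric phylo object with branch
## lengths in millions of years. Node ages are measured backward from the
## present: tips sit at age 0 and the crown node at the tree height.

#' Validate a phylogeny as an ultrametric time tree
#'
#' Checks that a \code{phylo} object is rooted, has branch lengths, unique
#' tip labels and is ultrametric within a relative tolerance, resolves any
#' polytomies into zero-length binary splits, and returns it with class
#' \code{"timetree"} prepended.
#'
#' @param phy an object of class \code{phylo}.
#' @param ultrametric logical; if \code{TRUE} (default) non-ultrametric
#'   trees are rejected.
#' @param tol relative ultrametricity tolerance: the maximum allowed tip-age
#'   deviation as a fraction of tree height.
#' @return the validated tree, of class \code{c("timetree", "phylo")}.
#' @export
as_timetree <- function(phy, ultrametric = TRUE, tol = 1e-6) {
  if (!inherits(phy, "phylo")) stop("'phy' must be a \"phylo\" object")
  if (is.null(phy$edge.length)) stop("tree has no branch lengths")
  if (any(is.na(phy$edge.length))) stop("tree has missing branch lengths")
  if (any(phy$edge.length < 0)) stop("tree has negative branch lengths")
  if (anyDuplicated(phy$tip.label)) {
    stop("duplicate tip labels: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]),
               collapse = ", "))
  }
  n <- length(phy$tip.label)
  if (n < 2) stop("tree must have at least 2 tips")
  if (!ape::is.rooted(phy)) stop("tree must be rooted")
  if (!ape::is.binary(phy)) {
    warning("polytomies resolved to zero-length binary splits")
    ## deterministic resolution: rotate children into lexicographic order
    ## by tip label before resolving
    phy <- ape::rotateConstr(phy, sort(phy$tip.label))
    phy <- ape::multi2di(phy, random = FALSE)
  }
  ages <- node_ages(phy)
  height <- max(ages)
  if (height <= 0) stop("tree height must be positive")
  dev <- max(abs(ages[seq_len(n)]))
  if (ultrametric && dev > tol * height) {
    stop(sprintf(
      "tree is not ultrametric: max tip-age deviation %.3g exceeds %.3g",
      dev, tol * height))
  }
  ## snap tips exactly to age zero so downstream arithmetic is clean
  phy <- set_tip_ages_zero(phy)
  class(phy) <- unique(c("timetree", class(phy)))
  phy
}

#' Read a time-calibrated tree from Newick or Nexus text
#'
#' Accepts a file path or a literal Newick string. Nexus files (detected by
#' a leading \code{#NEXUS}) are parsed with \code{\link[ape]{read.nexus}},
#' everything else with \code{\link[ape]{read.tree}}.
#'
#' @param source file path or Newick string.
#' @param ultrametric,tol passed to \code{\link{as_timetree}}.
#' @return a \code{timetree} (or a list of them for multi-tree input).
#' @export
read_timetree <- function(source, ultrametric = TRUE, tol = 1e-6) {
  is_path <- length(source) == 1L && !grepl("\\(", source) &&
    file.exists(source)
  if (is_path) {
    first <- readLines(source, n = 1L, warn = FALSE)
    phy <- if (grepl("^\\s*#NEXUS", first, ignore.case = TRUE)) {
      ape::read.nexus(source)
    } else {
      ape::read.tree(source)
    }
  } else {
    phy <- ape::read.tree(text = source)
  }
  if (is.null(phy)) stop("could not parse tree from 'source'")
  if (inherits(phy, "multiPhylo")) {
    return(lapply(unclass(phy), as_timetree,
                  ultrametric = ultrametric, tol = tol))
  }
  as_timetree(phy, ultrametric = ultrametric, tol = tol)
}

#' Write a time tree to a Newick file
#'
#' @param tree a \code{timetree}.
#' @param file output path; if missing, the Newick string is returned.
#' @export
write_timetree <- function(tree, file = "") {
  ape::write.tree(tree, file = file, digits = 12)
}

## Ages of all nodes (tips first, then internal nodes), measured backward
## from the most distant tip. Internal helper; exact for ultrametric trees.
node_ages <- function(phy) {
  depths <- ape::node.depth.edgelength(phy)
  max(depths) - depths
}

## Force exact zero tip ages by absorbing rounding error into pendant edges.
set_tip_ages_zero <- function(phy) {
  ages <- node_ages(phy)
  n <- length(phy$tip.label)
  tip_edge <- match(seq_len(n), phy$edge[, 2])
  phy$edge.length[tip_edge] <- phy$edge.length[tip_edge] + ages[seq_len(n)]
  phy
}

#' Tree height (crown age) in millions of years
#' @param tree a \code{timetree}.
#' @export
tree_height <- function(tree) max(node_ages(tree))

#' Branching times of an ultrametric tree
#'
#' Ages (My before present) of the n-1 internal nodes, sorted descending;
#' the first element is the crown age.
#'
#' @param tree a \code{timetree}.
#' @return numeric vector of length \code{n - 1}.
#' @export
branching_times <- function(tree) {
  tree <- as_timetree(tree)
  n <- length(tree$tip.label)
  ages <- node_ages(tree)[(n + 1):(n + tree$Nnode)]
  sort(ages, decreasing = TRUE)
}

#' Number of ancestral lineages crossing a given age
#'
#' Counts the lineages of the reconstructed tree alive at age \code{t}
#' (My before present). Just below the crown node the count is 2; at the
#' present it equals the number of tips. Ages exactly at a branching event
#' count the post-event (younger side) lineages.
#'
#' @param tree a \code{timetree}.
#' @param t age in My, between 0 and the crown age.
#' @export
lineages_at_time <- function(tree, t) {
  bt <- branching_times(tree)
  crown <- bt[1]
  if (any(t < 0 | t > crown)) stop("'t' must lie in [0, crown age]")
  ## ages exactly at an event count the post-event (younger) side, so
  ## the count is 2 at the crown age itself
  vapply(t, function(ti) sum(bt >= ti) + 1L, integer(1))
}

#' Extract the subtree spanned by a monophyletic set of tips
#'
#' The tip set must form a clade; the returned subtree is rooted at their
#' most recent common ancestor with all node ages preserved.
#'
#' @param tree a \code{timetree}.
#' @param tips character vector of tip labels.
#' @return a \code{timetree}.
#' @export
extract_clade <- function(tree, tips) {
  tree <- as_timetree(tree)
  tips <- unique(tips)
  miss <- setdiff(tips, tree$tip.label)
  if (length(miss)) stop("tips not in tree: ", paste(miss, collapse = ", "))
  if (length(tips) < 2) stop("a clade needs at least 2 tips")
  mrca <- ape::getMRCA(tree, tips)
  desc <- tree$tip.label[clade_tips(tree, mrca)]
  intruders <- setdiff(desc, tips)
  if (length(intruders)) {
    stop("tip set is not monophyletic; intruding tips: ",
         paste(intruders, collapse = ", "))
  }
  as_timetree(ape::extract.clade(tree, mrca))
}

#' Test whether a tip set is monophyletic on a tree
#' @param tree a \code{timetree}.
#' @param tips character vector of tip labels.
#' @export
is_clade <- function(tree, tips) {
  tips <- unique(tips)
  if (!all(tips %in% tree$tip.label)) return(FALSE)
  if (length(tips) < 2) return(TRUE)
  mrca <- ape::getMRCA(tree, tips)
  length(clade_tips(tree, mrca)) == length(tips)
}

## indices of tips descended from an internal node
clade_tips <- function(phy, node) {
  n <- length(phy$tip.label)
  if (node <= n) return(node)
  desc <- integer(0)
  stack <- node
  children <- split(phy$edge[, 2], phy$edge[, 1])
  while (length(stack)) {
    nd <- stack[[1]]; stack <- stack[-1]
    kids <- children[[as.character(nd)]]
    tipk <- kids[kids <= n]
    desc <- c(desc, tipk)
    stack <- c(stack, kids[kids > n])
  }
  sort(desc)
}

#' Validate a named list of clades against a tree
#'
#' Each clade must be monophyletic and the clades pairwise disjoint.
#'
#' @param tree a \code{timetree}.
#' @param clades named list of character vectors of tip labels.
#' @return the clade list, invisibly, after validation.
#' @export
validate_clades <- function(tree, clades) {
  stopifnot(is.list(clades), !is.null(names(clades)))
  all_tips <- unlist(clades)
  if (anyDuplicated(all_tips)) {
    stop("clades are not pairwise disjoint: ",
         paste(unique(all_tips[duplicated(all_tips)]), collapse = ", "))
  }
  for (nm in names(clades)) {
    if (!is_clade(tree, clades[[nm]])) {
      stop("clade '", nm, "' is not monophyletic on the tree")
    }
  }
  invisible(clades)
}

#' Read a tab-separated tip-data table
#'
#' Standard exchange format: tab-separated with a header, first column the
#' tip label. \code{"?"} and empty strings are read as missing.
#'
#' @param file path to the table.
#' @return a data.frame with rownames set to the tip labels.
#' @export
read_tip_table <- function(file) {
  x <- utils::read.delim(file, header = TRUE, sep = "\t",
                         na.strings = c("NA", "?", ""),
                         stringsAsFactors = FALSE, check.names = FALSE)
  rownames(x) <- x[[1]]
  x[-1]
}

#' @export
print.timetree <- function(x, ...) {
  cat(sprintf("Time-calibrated tree: %d tips, crown age %.4g My\n",
              length(x$tip.label), tree_height(x)))
  invisible(x)
}
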
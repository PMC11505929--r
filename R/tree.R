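#' Dated phylogenetic trees
#'
#' A `dated_tree` is an [ape::read.tree()]-style `phylo` object augmented with
#' node ages in Ma before present (root oldest, all tips at age 0). Branch
#' lengths are in Myr and always equal the age difference between the parent
#' and child node. All rates in the package are per Myr.
#'
#' @param phy a rooted `phylo` object with branch lengths.
#' @param tip_tol absolute tolerance for tip ages (default `1e-6 *` root age).
#' @param nonultrametric what to do with trees whose tips are not
#'   contemporaneous: `"reject"` (error) or `"repair"` (reset tip ages to 0 by
#'   rescaling terminal branches).
#' @return an object of class `c("dated_tree", "phylo")` with a `node.ages`
#'   component (length `Ntip + Nnode`, in Ma).
#' @export
dated_tree <- function(phy, tip_tol = NULL,
                       nonultrametric = c("reject", "repair")) {
  nonultrametric <- match.arg(nonultrametric)
  if (!inherits(phy, "phylo")) stop("'phy' must be a \"phylo\" object")
  if (is.null(phy$edge.length)) stop("tree has no branch lengths")
  if (!ape::is.rooted(phy)) stop("tree must be rooted")
  if (anyDuplicated(phy$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "))
  ntip <- length(phy$tip.label)
  depth <- ape::node.depth.edgelength(phy)
  root_age <- max(depth[seq_len(ntip)])
  if (root_age <= 0) stop("tree has zero height")
  ages <- root_age - depth
  if (is.null(tip_tol)) tip_tol <- 1e-6 * root_age
  tip_ages <- ages[seq_len(ntip)]
  if (any(abs(tip_ages) > tip_tol)) {
    if (nonultrametric == "reject") {
      bad <- phy$tip.label[abs(tip_ages) > tip_tol]
      stop("tree is not ultrametric within tolerance ", format(tip_tol),
           "; offending tips: ", paste(utils::head(bad, 5L), collapse = ", "))
    }
    # repair: clamp tips to the present and stretch terminal branches
    ages[seq_len(ntip)] <- 0
  } else {
    ages[seq_len(ntip)] <- 0
  }
  # re-derive branch lengths exactly from ages
  el <- ages[phy$edge[, 1L]] - ages[phy$edge[, 2L]]
  if (any(el < -1e-6 * root_age))
    stop("negative branch length after dating: parent younger than child")
  el[el < 0] <- 0
  phy$edge.length <- el
  phy$node.ages <- ages
  ## cache the postorder edge ordering (used by every likelihood pass);
  ## postorder edge lengths are always re-derived from node ages
  po <- ape::reorder.phylo(phy, "postorder")
  key <- paste(phy$edge[, 1L], phy$edge[, 2L])
  phy$po_edge <- po$edge
  phy$po_map <- match(paste(po$edge[, 1L], po$edge[, 2L]), key)
  class(phy) <- c("dated_tree", "phylo")
  phy
}

#' @rdname dated_tree
#' @param tree a `dated_tree`.
#' @export
node_ages <- function(tree) {
  stopifnot(inherits(tree, "dated_tree"))
  tree$node.ages
}

#' @rdname dated_tree
#' @export
root_age <- function(tree) {
  stopifnot(inherits(tree, "dated_tree"))
  tree$node.ages[length(tree$tip.label) + 1L]
}

#' @export
print.dated_tree <- function(x, ...) {
  cat("Dated tree:", length(x$tip.label), "tips, root age",
      format(root_age(x), digits = 6), "Ma\n")
  invisible(x)
}

#' Samples of dated trees
#'
#' A `tree_sample` is an ordered list of [dated_tree()] objects sharing one
#' tip-label set, typically equally weighted draws from a molecular-clock
#' posterior (the habitat-preference study saved 1000 dated trees from its
#' relaxed-clock chain).
#'
#' @param trees a list of `dated_tree` objects (or a `multiPhylo`).
#' @param weights optional per-tree weights (default uniform).
#' @param ... arguments passed to [dated_tree()] when elements need dating.
#' @return an object of class `tree_sample`.
#' @export
tree_sample <- function(trees, weights = NULL, ...) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- lapply(unclass(trees), function(t)
    if (inherits(t, "dated_tree")) t else dated_tree(t, ...))
  if (length(trees) == 0L) stop("empty tree sample")
  tips0 <- sort(trees[[1L]]$tip.label)
  for (i in seq_along(trees)) {
    ti <- sort(trees[[i]]$tip.label)
    if (!identical(ti, tips0)) {
      off <- c(setdiff(ti, tips0), setdiff(tips0, ti))
      stop("tree ", i, " has a mismatched taxon set; offending taxa: ",
           paste(utils::head(off, 5L), collapse = ", "))
    }
  }
  if (is.null(weights)) weights <- rep(1 / length(trees), length(trees))
  if (length(weights) != length(trees) || any(weights < 0))
    stop("invalid tree weights")
  weights <- weights / sum(weights)
  structure(list(trees = trees, weights = weights), class = "tree_sample")
}

#' @export
print.tree_sample <- function(x, ...) {
  cat("Tree sample:", length(x$trees), "dated trees,",
      length(x$trees[[1L]]$tip.label), "tips; root ages ",
      format(min(vapply(x$trees, root_age, 0)), digits = 5), "-",
      format(max(vapply(x$trees, root_age, 0)), digits = 5), " Ma\n", sep = "")
  invisible(x)
}

#' @export
length.tree_sample <- function(x) length(x$trees)

#' @export
`[[.tree_sample` <- function(x, i) x$trees[[i]]

## coerce a single tree or a tree_sample to a tree_sample
as_tree_sample <- function(x, ...) {
  if (inherits(x, "tree_sample")) x
  else tree_sample(x, ...)
}

#' Read a sample of dated trees from a newick file
#'
#' Node ages are reconstructed by root-to-tip accumulation of branch lengths
#' (in Myr). Trees failing the ultrametricity tolerance are rejected (default)
#' or repaired by resetting tip ages to 0.
#'
#' @param path newick file; one or more rooted trees with branch lengths.
#'   Square-bracket comments are ignored; quoted labels are accepted.
#' @param max_trees read at most this many trees.
#' @param nonultrametric `"reject"` or `"repair"`, see [dated_tree()].
#' @return a [tree_sample()].
#' @export
read_tree_sample <- function(path, max_trees = Inf,
                             nonultrametric = c("reject", "repair")) {
  nonultrametric <- match.arg(nonultrametric)
  trees <- tryCatch(ape::read.tree(path), error = function(e) e)
  if (inherits(trees, "error")) {
    # locate the offending line for a friendlier parse error
    lines <- readLines(path, warn = FALSE)
    for (i in seq_along(lines)) {
      if (!grepl(";", lines[i])) next
      ok <- tryCatch({ape::read.tree(text = lines[i]); TRUE},
                     error = function(e) FALSE)
      if (!ok) stop("unparseable newick at line ", i, " of ", path)
    }
    stop("unparseable newick in ", path, ": ", conditionMessage(trees))
  }
  if (is.null(trees)) stop("no trees found in ", path)
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (is.finite(max_trees) && length(trees) > max_trees)
    trees <- trees[seq_len(max_trees)]
  tree_sample(trees, nonultrametric = nonultrametric)
}

#' Write a tree sample to a newick file
#'
#' @param sample a [tree_sample()] or single [dated_tree()].
#' @param path output file.
#' @param digits significant digits for branch lengths (default 10).
#' @export
write_tree_sample <- function(sample, path, digits = 10) {
  sample <- as_tree_sample(sample)
  phys <- lapply(sample$trees, function(t) {
    t$node.ages <- NULL
    class(t) <- "phylo"
    t
  })
  class(phys) <- "multiPhylo"
  ape::write.tree(phys, file = path, digits = digits)
  invisible(path)
}

#' Drop taxa from a dated tree
#'
#' Dropped tips and the resulting degree-2 internal nodes are removed; the
#' ages of all retained nodes are unchanged and branch lengths are re-derived
#' from ages.
#'
#' @param tree a [dated_tree()].
#' @param drop character vector of tip labels to remove (may be empty).
#' @return a [dated_tree()].
#' @export
prune_taxa <- function(tree, drop) {
  stopifnot(inherits(tree, "dated_tree"))
  if (length(drop) == 0L) return(tree)
  unknown <- setdiff(drop, tree$tip.label)
  if (length(unknown))
    stop("unknown taxa: ", paste(unknown, collapse = ", "))
  keep_n <- length(tree$tip.label) - length(unique(drop))
  if (keep_n < 2L) stop("pruning would leave fewer than 2 tips")
  phy <- tree
  phy$node.ages <- NULL
  class(phy) <- "phylo"
  out <- ape::drop.tip(phy, drop)
  dated_tree(out)
}

## internal: postorder edges, their lengths (from node ages when cached), and
## the mapping of postorder rows back to tree$edge rows
postorder_edges <- function(tree) {
  if (!is.null(tree$po_edge) && !is.null(tree$node.ages)) {
    el <- tree$node.ages[tree$po_edge[, 1L]] -
      tree$node.ages[tree$po_edge[, 2L]]
    return(list(edge = tree$po_edge, el = el, map = tree$po_map))
  }
  po <- ape::reorder.phylo(tree, "postorder")
  key <- paste(tree$edge[, 1L], tree$edge[, 2L])
  list(edge = po$edge, el = po$edge.length,
       map = match(paste(po$edge[, 1L], po$edge[, 2L]), key))
}

## internal: total tree length (sum of branch lengths, Myr)
tree_length <- function(tree) sum(tree$edge.length)

## internal: bipartition key for each edge (sorted tip labels below the edge)
edge_bipartitions <- function(tree) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  below <- vector("list", nn)
  for (i in seq_len(ntip)) below[[i]] <- tree$tip.label[i]
  po <- postorder_edges(tree)
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1L]; c <- po$edge[k, 2L]
    below[[p]] <- c(below[[p]], below[[c]])
  }
  vapply(tree$edge[, 2L], function(n) paste(sort(below[[n]]), collapse = "|"),
         character(1))
}
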
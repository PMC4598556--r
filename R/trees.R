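#' Read a time-calibrated tree
#'
#' Reads a rooted, time-calibrated phylogeny from Newick or NEXUS (TREES
#' block, optional TRANSLATE table; square-bracket comments are ignored).
#' Branch lengths are interpreted as time in Myr. The tree is validated:
#' branch lengths must be present and non-negative on every edge, and tip
#' labels must be unique.
#'
#' @param path path to the tree file.
#' @param format `"auto"` (detect from a leading `#NEXUS`), `"newick"` or
#'   `"nexus"`.
#' @param quiet suppress the one-line summary message.
#' @return an object of class `phylo` (the package's time-tree container).
#' @examples
#' tf <- tempfile(fileext = ".nwk")
#' writeLines("((A:1,B:1):1,C:2);", tf)
#' tr <- read_tree(tf)
#' @export
read_tree <- function(path, format = c("auto", "newick", "nexus"),
                      quiet = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("tree file not found: ", path)
  if (format == "auto") {
    first <- trimws(readLines(path, n = 1L, warn = FALSE))
    format <- if (grepl("^#NEXUS", first, ignore.case = TRUE)) "nexus" else "newick"
  }
  tree <- if (format == "nexus") ape::read.nexus(path) else ape::read.tree(path)
  if (is.null(tree)) stop("could not parse tree file: ", path)
  if (inherits(tree, "multiPhylo")) {
    if (length(tree) > 1L)
      warning("file contains ", length(tree), " trees; using the first")
    tree <- tree[[1L]]
  }
  validate_timetree(tree)
  if (!quiet)
    message(sprintf("read_tree: %d tips, depth %.6g Myr",
                    ape::Ntip(tree), tree_depth(tree)))
  tree
}

#' Write a tree to Newick or NEXUS
#'
#' @param tree a `phylo` object.
#' @param path output path.
#' @param format `"newick"` or `"nexus"`.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path, format = c("newick", "nexus")) {
  format <- match.arg(format)
  validate_timetree(tree)
  if (format == "nexus") ape::write.nexus(tree, file = path)
  else ape::write.tree(tree, file = path)
  invisible(path)
}

# Validates the time-tree invariants shared by all tree-consuming
# operations; polytomies are allowed here and rejected where they matter
# (vcv_matrix, sister-pair extraction).
validate_timetree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  bad <- which(is.na(tree$edge.length))
  if (length(bad))
    stop("missing branch length on edge to node(s): ",
         paste(node_label(tree, tree$edge[bad, 2]), collapse = ", "))
  neg <- which(tree$edge.length < 0)
  if (length(neg))
    stop("negative branch length on edge to node(s): ",
         paste(node_label(tree, tree$edge[neg, 2]), collapse = ", "))
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup))
    stop("duplicate tip labels: ", paste(dup, collapse = ", "))
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  invisible(tree)
}

node_label <- function(tree, node) {
  ifelse(node <= ape::Ntip(tree), tree$tip.label[node],
         paste0("node#", node))
}

tree_depth <- function(tree) {
  nd <- ape::node.depth.edgelength(tree)
  max(nd[seq_len(ape::Ntip(tree))])
}

#' Node ages (time before present)
#'
#' Ages are measured backward from the present: tips of an ultrametric tree
#' sit at age 0 and the root at the total tree depth. Trees whose tip depths
#' differ by more than `tol` (relative to the maximum depth) trigger a
#' warning and the deepest tip defines the present.
#'
#' @param tree a `phylo` object.
#' @param tol relative ultrametricity tolerance.
#' @return numeric vector of ages indexed by node number (tips first).
#' @export
node_ages <- function(tree, tol = 1e-6) {
  nd <- ape::node.depth.edgelength(tree)
  tipd <- nd[seq_len(ape::Ntip(tree))]
  depth <- max(tipd)
  if (depth > 0 && (depth - min(tipd)) / depth > tol)
    warning(sprintf(
      "tree is not ultrametric (tip depth range %.4g of max depth %.4g); ages measured from the deepest tip",
      depth - min(tipd), depth))
  depth - nd
}

tips_under <- function(tree, node) {
  if (node <= ape::Ntip(tree)) return(tree$tip.label[node])
  ape::extract.clade(tree, node)$tip.label
}

#' Stem and crown age of a clade
#'
#' The stem age is the time from the present back to the clade's split from
#' its sister lineage (the start of its stem branch); the crown age is the
#' age of the most recent common ancestor of its extant members, defined
#' only for clades with at least two tips.
#'
#' @param tree a `phylo` object.
#' @param tips character vector of tip labels; must be exactly the tip set
#'   of one monophyletic clade in the tree.
#' @param clade_id label for the clade; defaults to the sorted tip labels
#'   joined with `"+"`.
#' @return a list with `clade_id`, `stem_age` (Myr) and `crown_age` (Myr,
#'   `NA` for single-tip clades).
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' stem_age(tr, c("A", "B"))  # stem 2, crown 1
#' @export
stem_age <- function(tree, tips, clade_id = paste(sort(tips), collapse = "+")) {
  validate_timetree(tree)
  if (!is.character(tips) || length(tips) < 1L)
    stop("'tips' must be a non-empty character vector")
  unknown <- setdiff(tips, tree$tip.label)
  if (length(unknown))
    stop("tips not in tree: ", paste(unknown, collapse = ", "))
  ages <- node_ages(tree)
  if (length(tips) == 1L) {
    node <- match(tips, tree$tip.label)
    crown <- NA_real_
  } else {
    node <- ape::getMRCA(tree, tips)
    intruders <- setdiff(tips_under(tree, node), tips)
    if (length(intruders))
      stop("tip set is not monophyletic; intruding tips: ",
           paste(intruders, collapse = ", "))
    crown <- ages[node]
  }
  parent <- tree$edge[tree$edge[, 2] == node, 1]
  if (length(parent) == 0L) {
    if (is.null(tree$root.edge))
      stop("clade spans the entire tree and the tree carries no root edge; ",
           "stem age undefined")
    stem <- ages[node] + tree$root.edge
  } else {
    stem <- ages[parent]
  }
  list(clade_id = clade_id, stem_age = stem, crown_age = crown)
}

#' Stem age of every tip
#'
#' For a tree whose tips are already one exemplar per clade, each clade's
#' stem age is the age of its exemplar's parent node. Returns a named
#' vector in tip order.
#'
#' @param tree a `phylo` object.
#' @return named numeric vector of stem ages (Myr).
#' @export
tip_stem_ages <- function(tree) {
  ages <- node_ages(tree)
  ntip <- ape::Ntip(tree)
  parent <- tree$edge[match(seq_len(ntip), tree$edge[, 2]), 1]
  stats::setNames(ages[parent], tree$tip.label)
}

#' Prune a tree to one exemplar tip per clade
#'
#' Deletes all tips of each clade except one and relabels the survivor with
#' the clade id. Because every member of a clade shares the same path from
#' the present back to the clade's origin, the choice of exemplar does not
#' affect stem ages or among-clade covariances; the lexicographically first
#' tip is kept for determinism. Tips not assigned to any clade are dropped
#' (with a message).
#'
#' @param tree a `phylo` object.
#' @param clade_map data frame with columns `tip_label` and `clade_id`.
#' @param quiet suppress messages about dropped tips.
#' @return a `phylo` with one tip per clade, labeled by clade id.
#' @export
prune_to_exemplars <- function(tree, clade_map, quiet = FALSE) {
  validate_timetree(tree)
  if (!is.data.frame(clade_map) ||
      !all(c("tip_label", "clade_id") %in% names(clade_map)))
    stop("'clade_map' must be a data frame with columns tip_label, clade_id")
  clade_map$tip_label <- as.character(clade_map$tip_label)
  clade_map$clade_id <- as.character(clade_map$clade_id)
  dup <- unique(clade_map$tip_label[duplicated(clade_map$tip_label)])
  if (length(dup))
    stop("overlapping clades: tip(s) assigned to more than one clade: ",
         paste(dup, collapse = ", "))
  unknown <- setdiff(clade_map$tip_label, tree$tip.label)
  if (length(unknown))
    stop("clade_map tips not in tree: ", paste(unknown, collapse = ", "))
  unmapped <- setdiff(tree$tip.label, clade_map$tip_label)
  if (length(unmapped) && !quiet)
    message("prune_to_exemplars: dropping ", length(unmapped),
            " tip(s) not assigned to any clade")
  exemplar <- vapply(split(clade_map$tip_label, clade_map$clade_id),
                     function(x) sort(x)[1L], character(1))
  pruned <- ape::keep.tip(tree, unname(exemplar))
  pruned$tip.label <- names(exemplar)[match(pruned$tip.label, exemplar)]
  pruned
}

#' Brownian phylogenetic covariance matrix
#'
#' Entry (i, j) is the shared path length (Myr) from the root to the most
#' recent common ancestor of tips i and j; the diagonal holds root-to-tip
#' path lengths. Under Brownian motion with rate sigma^2 the trait
#' covariance of two tips is sigma^2 times this entry.
#'
#' @param tree a rooted, binary `phylo` with branch lengths.
#' @param resolve_polytomies if `TRUE`, polytomies are resolved arbitrarily
#'   with zero-length branches (logged); otherwise they are an error.
#' @return a symmetric positive semi-definite matrix with tip-label
#'   dimnames and attribute `lambda = "raw"`.
#' @export
vcv_matrix <- function(tree, resolve_polytomies = FALSE) {
  validate_timetree(tree)
  if (!ape::is.binary(tree)) {
    if (resolve_polytomies) {
      message("vcv_matrix: resolving polytomies arbitrarily with zero-length branches")
      tree <- ape::multi2di(tree)
    } else {
      stop("tree contains polytomies; rerun with resolve_polytomies = TRUE ",
           "to resolve them arbitrarily with zero-length branches")
    }
  }
  C <- ape::vcv(tree)
  attr(C, "lambda") <- "raw"
  C
}

#' Pagel's lambda transform of a phylogenetic covariance matrix
#'
#' Multiplies off-diagonal entries by `lambda`, leaving the diagonal
#' unchanged. `lambda = 1` returns the matrix untouched (full Brownian
#' structure); `lambda = 0` yields a diagonal matrix (star phylogeny,
#' phylogenetically independent residuals). For lambda in \[0, 1\] on an
#' ultrametric tree the result remains positive semi-definite.
#'
#' @param C covariance matrix from [vcv_matrix()].
#' @param lambda scalar in \[0, 1\].
#' @return the transformed matrix, attribute `lambda` set to the value.
#' @export
apply_lambda <- function(C, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda < 0 || lambda > 1)
    stop("'lambda' must be a single value in [0, 1]")
  Cl <- C * lambda
  diag(Cl) <- diag(C)
  attr(Cl, "lambda") <- lambda
  Cl
}
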
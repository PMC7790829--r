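#' Dated phylogenetic trees
#'
#' A `dated_tree` couples an [ape::phylo] topology with absolute node ages
#' (Ma before present, larger = older). Branch durations (Myr) are the edge
#' lengths of the underlying `phylo` and must equal the parent-child age
#' difference. All likelihood, binning and simulation machinery in the
#' package operates on this class.
#'
#' @param phy an [ape::phylo] object with edge lengths (Myr).
#' @param root_age age of the root node in Ma before present. If `NULL`,
#'   the root is placed so that the shallowest tip sits at 0 Ma.
#' @param node_age optional numeric vector of ages for all
#'   `Ntip + Nnode` nodes (tips first, ape numbering). Overrides
#'   `root_age`; must be consistent with the edge lengths.
#'
#' @return an object of class `dated_tree`: a list with elements `phy`
#'   (the `phylo`), `node_age` (ages for all nodes, tips first) and
#'   `root_age`.
#' @export
#' @examples
#' phy <- ape::read.tree(text = "((A:10,B:10):20,C:30);")
#' tr <- dated_tree(phy, root_age = 40)
#' tip_ages(tr)
dated_tree <- function(phy, root_age = NULL, node_age = NULL) {
  if (!inherits(phy, "phylo")) stop("`phy` must be an ape 'phylo' object")
  if (is.null(phy$edge.length)) stop("`phy` must have edge lengths")
  if (anyDuplicated(phy$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]),
               collapse = ", "))
  n_all <- ape::Ntip(phy) + phy$Nnode
  depths <- node_depths(phy)
  if (is.null(node_age)) {
    if (is.null(root_age)) root_age <- max(depths[seq_len(ape::Ntip(phy))])
    node_age <- root_age - depths
  } else {
    if (length(node_age) != n_all) stop("`node_age` has the wrong length")
    root_age <- node_age[ape::Ntip(phy) + 1L]
  }
  obj <- structure(list(phy = phy, node_age = node_age, root_age = root_age),
                   class = "dated_tree")
  validate_dated_tree(obj)
  obj
}

#' @rdname dated_tree
#' @param x,tree a `dated_tree`.
#' @export
is_dated_tree <- function(x) inherits(x, "dated_tree")

#' @rdname dated_tree
#' @export
tip_ages <- function(tree) {
  stopifnot(is_dated_tree(tree))
  setNames(tree$node_age[seq_len(ape::Ntip(tree$phy))], tree$phy$tip.label)
}

#' @rdname dated_tree
#' @export
branch_durations <- function(tree) {
  stopifnot(is_dated_tree(tree))
  tree$phy$edge.length
}

#' @export
print.dated_tree <- function(x, ...) {
  cat(sprintf("Dated phylogenetic tree: %d tips, root at %.3f Ma\n",
              ape::Ntip(x$phy), x$root_age))
  cat(sprintf("  tip ages span %.3f-%.3f Ma\n",
              min(tip_ages(x)), max(tip_ages(x))))
  invisible(x)
}

# Root-to-node path lengths (Myr) for every node, tips first.
node_depths <- function(phy) {
  n_tip <- ape::Ntip(phy)
  depths <- numeric(n_tip + phy$Nnode)
  edge <- reorder_edges(phy)
  # preorder: parents before children
  for (e in rev(seq_len(nrow(edge$edge)))) {
    par <- edge$edge[e, 1L]; chi <- edge$edge[e, 2L]
    depths[chi] <- depths[par] + edge$edge.length[e]
  }
  depths
}

# phylo edges in postorder (children before parents) without mutating input.
reorder_edges <- function(phy) {
  po <- ape::reorder.phylo(phy, "postorder")
  list(edge = po$edge, edge.length = po$edge.length)
}

validate_dated_tree <- function(tree, strict_positive = FALSE) {
  phy <- tree$phy
  age <- tree$node_age
  edge <- phy$edge
  dur <- age[edge[, 1L]] - age[edge[, 2L]]
  if (any(dur < -1e-8))
    stop("node ages violate parent >= child on ",
         sum(dur < -1e-8), " edge(s)")
  if (max(abs(dur - phy$edge.length)) > 1e-6)
    stop("edge lengths inconsistent with node ages")
  if (strict_positive && any(phy$edge.length <= 0))
    stop("tree has non-positive branch durations after dating")
  invisible(tree)
}

#' Read an occurrence table
#'
#' Occurrence tables give, for each taxon, its first (FAD) and last (LAD)
#' appearance ages in Ma. The CSV must have columns `taxon`, `fad_ma`,
#' `lad_ma`.
#'
#' @param path path to a CSV file.
#' @return a data frame with columns `taxon`, `fad_ma`, `lad_ma`, validated
#'   so that `fad_ma >= lad_ma >= 0`.
#' @export
read_occurrences <- function(path) {
  occ <- read.csv(path, stringsAsFactors = FALSE)
  as_occurrences(occ)
}

#' @rdname read_occurrences
#' @param occ a data frame with columns `taxon`, `fad_ma`, `lad_ma`.
#' @export
as_occurrences <- function(occ) {
  need <- c("taxon", "fad_ma", "lad_ma")
  if (!all(need %in% names(occ)))
    stop("occurrence table needs columns: ", paste(need, collapse = ", "))
  occ <- occ[, need]
  if (any(occ$lad_ma < 0) || any(occ$fad_ma < occ$lad_ma))
    stop("occurrence table must satisfy fad_ma >= lad_ma >= 0")
  if (anyDuplicated(occ$taxon))
    stop("duplicate taxa in occurrence table")
  occ
}
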
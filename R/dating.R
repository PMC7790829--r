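#' Date a fossil tree by the equal method
#'
#' Time-scales a cladogram from taxon occurrence ranges. Each tip is placed
#' at its first appearance (FAD); each internal node starts at the oldest
#' age among its descendant tips; the root is pushed back by
#' `root_buffer_myr` beyond the oldest FAD; and every remaining
#' zero-duration branch is removed by locating the nearest ancestral branch
#' with positive duration and dividing its time span equally among itself
#' and the consecutive zero-duration branches below it on that root-to-tip
#' path. The result has strictly positive branch durations.
#'
#' @param topology a `phylo` or [dated_tree]; only the topology is used.
#' @param occurrences occurrence table (see [read_occurrences()]) covering
#'   every tip.
#' @param root_buffer_myr time (Myr) added above the oldest first
#'   appearance to date the root; must be positive.
#' @return a [dated_tree] with strictly positive branch durations.
#' @export
#' @examples
#' phy <- ape::read.tree(text = "((A,B),C);")
#' occ <- data.frame(taxon = c("A", "B", "C"),
#'                   fad_ma = c(100, 100, 150), lad_ma = c(95, 90, 140))
#' tr <- equal_dating(phy, occ, root_buffer_myr = 10)
#' tr$root_age  # 160
equal_dating <- function(topology, occurrences, root_buffer_myr = 5) {
  phy <- if (is_dated_tree(topology)) topology$phy else topology
  if (!inherits(phy, "phylo")) stop("`topology` must be a phylo or dated_tree")
  if (root_buffer_myr <= 0) stop("`root_buffer_myr` must be positive")
  occ <- as_occurrences(occurrences)

  n_tip <- ape::Ntip(phy)
  missing <- setdiff(phy$tip.label, occ$taxon)
  if (length(missing))
    stop("tips missing from occurrence table: ",
         paste(missing, collapse = ", "))
  fad <- occ$fad_ma[match(phy$tip.label, occ$taxon)]

  n_all <- n_tip + phy$Nnode
  root <- n_tip + 1L
  age <- numeric(n_all)
  age[seq_len(n_tip)] <- fad

  po <- ape::reorder.phylo(phy, "postorder")$edge
  for (e in seq_len(nrow(po)))  # internal node = oldest descendant tip
    age[po[e, 1L]] <- max(age[po[e, 1L]], age[po[e, 2L]])
  age[root] <- max(fad) + root_buffer_myr

  parent <- integer(n_all)
  parent[phy$edge[, 2L]] <- phy$edge[, 1L]

  # resolve zero-duration branches, scanning in preorder until none remain
  pre <- rev(seq_len(nrow(po)))
  repeat {
    fixed <- FALSE
    for (e in pre) {
      v <- po[e, 2L]; p <- po[e, 1L]
      if (age[p] - age[v] > 0) next
      # walk up to the nearest ancestor edge with positive duration
      b <- p
      while (b != root && age[parent[b]] - age[b] <= 0) b <- parent[b]
      a <- parent[b]
      # chain of zero-duration edges from b down to v
      chain <- v; w <- p
      while (w != b) { chain <- c(w, chain); w <- parent[w] }
      chain <- c(b, chain)       # ages of all but the last get re-spaced
      span <- age[a] - age[v]
      m <- length(chain)         # segments = m (edge a->b plus m-1 zeros)
      age[chain[-m]] <- age[a] - span * seq_len(m - 1L) / m
      fixed <- TRUE
      break
    }
    if (!fixed) break
  }

  phy$edge.length <- age[phy$edge[, 1L]] - age[phy$edge[, 2L]]
  out <- dated_tree(phy, node_age = age)
  validate_dated_tree(out, strict_positive = TRUE)
  out
}

#' Trim a dated tree to a taxon subset
#'
#' Returns the induced subtree on `taxa`: other tips are dropped, degree-2
#' internal nodes are suppressed with their branch durations summed, and
#' all retained node ages are preserved (the new root is the most recent
#' common ancestor of `taxa`, at its original age).
#'
#' @param tree a [dated_tree].
#' @param taxa character vector of tip labels to keep (non-empty subset of
#'   the tree's tips).
#' @return a [dated_tree] on `taxa`.
#' @export
trim_to <- function(tree, taxa) {
  stopifnot(is_dated_tree(tree))
  if (length(taxa) == 0) stop("`taxa` must be non-empty")
  bad <- setdiff(taxa, tree$phy$tip.label)
  if (length(bad)) stop("taxa not in tree: ", paste(bad, collapse = ", "))
  if (setequal(taxa, tree$phy$tip.label)) return(tree)
  phy2 <- ape::keep.tip(tree$phy, taxa)
  old_tip_age <- tip_ages(tree)[phy2$tip.label]
  depths <- node_depths(phy2)
  root_age <- unname(old_tip_age[1L]) + depths[1L]
  dated_tree(phy2, root_age = root_age)
}

#' Lineages or branches present in a time bin
#'
#' Membership of taxa (or branches) in a half-open time bin
#' `[old, young)` Ma, under three modes: `"empirical"` uses the observed
#' `[FAD, LAD]` range; `"ghost"` extends each taxon's range back to the age
#' of its parent node on the dated tree (its ghost range); `"branches"`
#' returns the indices of tree edges whose `[parent age, child age]` span
#' intersects the bin (the substrate for evolutionary-rate series).
#'
#' @param tree a [dated_tree].
#' @param occurrences occurrence table covering the tree's tips (not needed
#'   in `"branches"` mode).
#' @param bin numeric length-2, `c(old_ma, young_ma)` with `old > young`.
#' @param mode membership mode; see Details.
#' @return character vector of taxon names, or integer edge indices in
#'   `"branches"` mode. A bin outside the tree's span yields an empty set.
#' @export
lineages_in_bin <- function(tree, occurrences = NULL, bin,
                            mode = c("empirical", "ghost", "branches")) {
  stopifnot(is_dated_tree(tree))
  mode <- match.arg(mode)
  old <- bin[1L]; young <- bin[2L]
  if (old <= young) stop("bin must be c(old, young) with old > young")

  if (mode == "branches") {
    page <- tree$node_age[tree$phy$edge[, 1L]]
    cage <- tree$node_age[tree$phy$edge[, 2L]]
    return(which(page > young & cage <= old))
  }

  occ <- as_occurrences(occurrences)
  tips <- tree$phy$tip.label
  missing <- setdiff(tips, occ$taxon)
  if (length(missing))
    stop("tips missing from occurrence table: ",
         paste(missing, collapse = ", "))
  i <- match(tips, occ$taxon)
  fad <- occ$fad_ma[i]; lad <- occ$lad_ma[i]
  if (mode == "ghost") {
    parent <- tree$phy$edge[, 1L][match(seq_along(tips), tree$phy$edge[, 2L])]
    fad <- pmax(fad, tree$node_age[parent])
  }
  tips[fad > young & lad <= old]
}
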
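#' Read and write phylogenetic trees
#'
#' Thin wrappers around ape's Newick and NEXUS parsers that return the
#' package's [dated_tree] class. A file whose tree carries branch lengths is
#' returned dated (anchored so that the shallowest tip sits at 0 Ma unless
#' `root_age` is given); a topology without branch lengths is returned as a
#' bare `phylo` and must be dated with [equal_dating()] before use.
#'
#' @param path file path.
#' @param format `"newick"` or `"nexus"`; the default guesses from the file
#'   extension (`.nex`/`.nxs` -> NEXUS).
#' @param root_age optional root age in Ma used to anchor node ages.
#' @return a [dated_tree], or a `phylo` when the file has no branch lengths.
#' @export
read_tree <- function(path, format = c("auto", "newick", "nexus"),
                      root_age = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(nex|nxs|nexus)$", path, ignore.case = TRUE))
      "nexus" else "newick"
  phy <- tryCatch(
    if (format == "nexus") ape::read.nexus(path) else ape::read.tree(path),
    error = function(e) stop("failed to parse ", format, " file '", path,
                             "': ", conditionMessage(e), call. = FALSE))
  if (inherits(phy, "multiPhylo")) phy <- phy[[1L]]
  if (is.null(phy))
    stop("failed to parse ", format, " file '", path, "'", call. = FALSE)
  if (anyDuplicated(phy$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]),
               collapse = ", "))
  if (is.null(phy$edge.length)) return(phy)
  dated_tree(phy, root_age = root_age)
}

#' @rdname read_tree
#' @param tree a [dated_tree] or `phylo`.
#' @export
write_tree <- function(tree, path, format = c("auto", "newick", "nexus")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(nex|nxs|nexus)$", path, ignore.case = TRUE))
      "nexus" else "newick"
  phy <- if (is_dated_tree(tree)) tree$phy else tree
  if (format == "nexus") ape::write.nexus(phy, file = path)
  else ape::write.tree(phy, file = path)
  invisible(path)
}
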
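# Tree ingestion and the phylogenetic covariance matrix.
#
# Trees are ape "phylo" objects throughout. All likelihood computations
# consume the n x n phylogenetic covariance matrix C whose entries are the
# shared root-to-tip path lengths between species pairs.

#' Read and validate a rooted newick tree
#'
#' Parses a newick string (or file) into an [ape::read.tree()] `phylo` object
#' and enforces the contract the downstream rate analyses rely on: unique,
#' non-empty tip labels; a branch length on every edge; no negative branch
#' lengths; at least one positive branch length. Polytomies and quoted labels
#' are allowed; a root edge, if present, is ignored. Zero-length terminal
#' branches are accepted here — two tips at zero patristic distance only
#' become an error when the covariance matrix is factorised at fit time.
#'
#' @param file Path to a file containing one newick tree. Exactly one of
#'   `file` and `text` must be given.
#' @param text A newick string.
#' @param strict Logical; if `TRUE` a missing trailing semicolon is an error,
#'   otherwise it is repaired with a warning.
#' @return An object of class `phylo`.
#' @examples
#' tr <- read_newick(text = "((A:1,B:1):1,C:2);")
#' tr$tip.label
#' @export
read_newick <- function(file = NULL, text = NULL, strict = FALSE) {
  if (is.null(text) == is.null(file))
    stop_input("supply exactly one of 'file' or 'text'")
  if (!is.null(file)) {
    if (!file.exists(file)) stop_input("tree file not found: %s", file)
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  text <- trimws(text)
  if (!nzchar(text)) stop_input("empty newick string")

  # Cheap structural scan so parse errors can name an offending position.
  depth <- 0L
  in_quote <- FALSE
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  for (k in seq_along(chars)) {
    ch <- chars[k]
    if (ch == "'") in_quote <- !in_quote
    if (in_quote) next
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop_input("malformed newick: unbalanced ')' at position %d", k)
    }
  }
  if (depth > 0L)
    stop_input("malformed newick: %d unclosed '(' at end of string", depth)

  if (!grepl(";\\s*$", text)) {
    if (strict)
      stop_input("malformed newick: missing trailing ';' (strict mode)")
    warning("newick string lacks a trailing ';'; one was appended",
            call. = FALSE)
    text <- paste0(text, ";")
  }

  tree <- tryCatch(ape::read.tree(text = text), error = function(e) NULL,
                   warning = function(w) NULL)
  if (is.null(tree) || !inherits(tree, "phylo"))
    stop_input("malformed newick: could not be parsed as a tree")
  tree$root.edge <- NULL
  validate_phylogeny(tree)
  tree
}

# Invariant checks shared by every entry point that accepts a tree.
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop_input("not a 'phylo' tree object")
  labs <- tree$tip.label
  if (any(!nzchar(trimws(labs))))
    stop_input("every tip must have a non-empty label")
  dup <- unique(labs[duplicated(labs)])
  if (length(dup))
    stop_input("duplicate tip label(s): %s", paste(dup, collapse = ", "))
  bl <- tree$edge.length
  n_edge <- if (is.null(tree$edge)) length(labs) else nrow(tree$edge)
  if (is.null(bl) || length(bl) != n_edge || anyNA(bl))
    stop_input("branch length required on every edge")
  if (any(bl < 0)) stop_input("negative branch length(s) found")
  if (!any(bl > 0)) stop_input("all branch lengths are zero")
  invisible(tree)
}

#' Prune a tree to a subset of taxa
#'
#' Returns the induced subtree on `keep`, with unbranched internal nodes
#' suppressed and their branch lengths summed, so every root-to-tip and
#' tip-to-tip path length among the kept taxa is unchanged. Analyses routinely
#' run on nested species subsets (complete cases differ per trait set), and
#' pruning then taking the covariance must equal subsetting the full
#' covariance matrix.
#'
#' @param tree A `phylo` object.
#' @param keep Character vector of tip labels to retain (at least 2).
#' @return The pruned `phylo` object.
#' @examples
#' tr <- read_newick(text = "((A:1,B:1):1,C:2);")
#' prune_to_taxa(tr, c("A", "C"))
#' @export
prune_to_taxa <- function(tree, keep) {
  validate_phylogeny(tree)
  keep <- as.character(keep)
  missing <- setdiff(keep, tree$tip.label)
  if (length(missing))
    stop_input("taxa not in tree: %s", paste(missing, collapse = ", "))
  if (length(unique(keep)) < 2)
    stop_input("at least 2 taxa must be kept (got %d)", length(unique(keep)))
  pruned <- ape::keep.tip(tree, keep)
  # keep.tip reroots at the MRCA of the kept tips; retain the root-ward stem
  # as a root edge so root-to-tip path lengths are conserved (the covariance
  # of the pruned tree must equal the submatrix of the full covariance).
  stem <- ape::node.depth.edgelength(tree)[ape::getMRCA(tree, keep)]
  if (stem > 0) pruned$root.edge <- stem
  pruned
}

#' Phylogenetic covariance matrix of a tree
#'
#' The n x n matrix `C` with `C[i,i]` the root-to-tip path length of taxon i
#' and `C[i,j]` the shared path length from the root to the most recent common
#' ancestor of taxa i and j — the among-species covariance structure a
#' Brownian-motion trait accrues on the tree. An ultrametric tree gives a
#' constant diagonal; a star tree gives a diagonal matrix; rescaling all
#' branch lengths by c rescales `C` by exactly c.
#'
#' @param tree A `phylo` object with branch lengths.
#' @param order Optional character vector, a permutation of the tip labels,
#'   giving the row/column order of the result.
#' @return A symmetric numeric matrix with taxon dimnames.
#' @examples
#' phylo_covariance(read_newick(text = "((A:1,B:1):1,C:2);"))
#' @export
phylo_covariance <- function(tree, order = NULL) {
  validate_phylogeny(tree)
  C <- ape::vcv(tree)
  # a root edge (e.g. the stem retained by prune_to_taxa) is shared history
  # of every tip: it adds to all entries, diagonal included
  if (!is.null(tree$root.edge) && tree$root.edge > 0) C <- C + tree$root.edge
  if (!is.null(order)) {
    order <- as.character(order)
    if (length(order) != nrow(C) || !setequal(order, rownames(C)))
      stop_input("'order' must be a permutation of the tree's tip labels")
    C <- C[order, order, drop = FALSE]
  }
  C
}
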
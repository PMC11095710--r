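#' Read a phylogenetic tree from a newick file
#'
#' Thin wrapper around [ape::read.tree()] that enforces the invariants the
#' downstream analyses rely on: unique tip labels, non-negative branch
#' lengths, and (optionally) ultrametricity for trees whose branch lengths
#' are in units of time.
#'
#' @param path Path to a newick file, or a newick string via `text =`.
#' @param dated Logical; if `TRUE` the tree must be ultrametric within a
#'   relative tolerance of `1e-6` (branch lengths in Mya).
#' @param text Optional newick string, used instead of `path`.
#' @return An object of class `"phylo"`.
#' @export
read_newick <- function(path, dated = FALSE, text = NULL) {
  tree <- if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text)
  if (is.null(tree)) stop("file does not parse as newick: ", path)
  validate_tree(tree, dated = dated)
  tree
}

#' Write a tree to newick with canonical child ordering
#'
#' Children of every node are rotated into a deterministic order (by the
#' lexicographically smallest tip label in each subtree) so that
#' write-then-read round-trips are byte-stable. Branch lengths are written
#' with 10 significant digits.
#'
#' @param tree A `"phylo"` object.
#' @param path Output file; if `NULL` the newick string is returned.
#' @return The newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, path = NULL) {
  tree <- canonicalize_tree(tree)
  s <- ape::write.tree(tree, digits = 10)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}

#' @rdname write_newick
#' @export
canonicalize_tree <- function(tree) {
  tree <- ape::reorder.phylo(tree, "cladewise")
  n_tip <- length(tree$tip.label)
  # smallest tip label below each node, then rotate children into that order
  key <- character(n_tip + tree$Nnode)
  key[seq_len(n_tip)] <- tree$tip.label
  po <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(nrow(po))) {
    p <- po[i, 1]; ch <- po[i, 2]
    if (key[p] == "" || key[ch] < key[p]) key[p] <- key[ch]
  }
  tree <- ape::rotateConstr(tree, sort(tree$tip.label))
  # rotateConstr orders children by constraint; re-read to normalize memory layout
  ape::read.tree(text = ape::write.tree(tree, digits = 10))
}

validate_tree <- function(tree, dated = FALSE) {
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  if (any(tree$edge.length < 0))
    stop("negative branch lengths are not allowed")
  if (dated && !ape::is.ultrametric(tree, tol = 1e-6, option = 2))
    stop("tree flagged as dated is not ultrametric (relative tolerance 1e-6)")
  invisible(tree)
}

#' Read / write a binary fragmentation trait
#'
#' The trait file is a headered two-column TSV (`sample`, `state`) with
#' states coded 0 = single-chromosome, 1 = fragmented.
#'
#' @param path TSV file path.
#' @return A named integer vector of 0/1 states.
#' @export
read_trait <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("sample", "state") %in% names(d)))
    stop("trait file must have columns 'sample' and 'state'")
  if (anyDuplicated(d$sample))
    stop("duplicate samples in trait file")
  if (!all(d$state %in% c(0L, 1L)))
    stop("trait states must be 0 (single) or 1 (fragmented)")
  stats::setNames(as.integer(d$state), d$sample)
}

#' @rdname read_trait
#' @param trait Named 0/1 vector.
#' @export
write_trait <- function(trait, path) {
  utils::write.table(
    data.frame(sample = names(trait), state = as.integer(trait)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# check that every tip is scored and states are 0/1; returns trait ordered as tips
match_trait <- function(tree, trait) {
  if (!all(tree$tip.label %in% names(trait)))
    stop("tips without a trait state: ",
         paste(setdiff(tree$tip.label, names(trait)), collapse = ", "))
  x <- as.integer(trait[tree$tip.label])
  if (!all(x %in% c(0L, 1L))) stop("trait states must be 0 or 1")
  names(x) <- tree$tip.label
  x
}
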
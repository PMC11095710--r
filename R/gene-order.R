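#' Gene-boundary (adjacency) set of a chromosome set
#'
#' Each chromosome contributes the boundaries between consecutive genes,
#' plus the wrap-around boundary if it is circular. By default a boundary
#' is an unordered pair of unsigned gene names (matching manual boundary
#' comparison on gene identity), which is automatically invariant to the
#' rotation and global strand flip of a circular chromosome. With
#' `use_orientation = TRUE`, chromosomes are first put in canonical
#' direction (reading starts at `cox1` if present, else at the
#' lexicographically smallest gene, with that gene on the + strand) and
#' boundaries are ordered, signed pairs.
#'
#' @param cs A `chromosome_set` (see [chromosome_sets()]).
#' @param use_orientation Use ordered, strand-aware boundaries.
#' @return Character vector of canonical boundary tokens (a set: sorted,
#'   unique).
#' @export
adjacencies <- function(cs, use_orientation = FALSE) {
  out <- character(0)
  for (ch in cs$chromosomes) {
    g <- ch$genes; s <- ch$strands
    n <- length(g)
    if (n < 2) next
    if (use_orientation) {
      start <- if ("cox1" %in% g) "cox1" else sort(g)[1]
      i <- match(start, g)
      if (s[i] < 0) { g <- rev(g); s <- -rev(s); i <- match(start, g) }
      if (ch$circular && i > 1) {
        idx <- c(i:n, seq_len(i - 1)); g <- g[idx]; s <- s[idx]
      }
      tok <- paste0(g, ifelse(s < 0, "-", "+"))
      b <- paste(tok[-n], tok[-1], sep = ">")
      if (ch$circular) b <- c(b, paste(tok[n], tok[1], sep = ">"))
    } else {
      a <- g[-n]; bb <- g[-1]
      if (ch$circular) { a <- c(a, g[n]); bb <- c(bb, g[1]) }
      b <- paste(pmin(a, bb), pmax(a, bb), sep = "|")
    }
    out <- c(out, b)
  }
  sort(unique(out))
}

# genes participating in a boundary token
.boundary_genes <- function(b, use_orientation = FALSE) {
  if (use_orientation) sub("[+-]$", "", strsplit(b, ">", fixed = TRUE)[[1]])
  else strsplit(b, "|", fixed = TRUE)[[1]]
}

#' Reconstruct ancestral adjacency sets by per-adjacency parsimony
#'
#' Every boundary observed in any tip is treated as an independent binary
#' presence/absence character and reconstructed with Fitch parsimony
#' (up- and down-pass). At each internal node, boundaries whose most
#' parsimonious state set includes "present" are candidates; they are then
#' filtered to a structurally consistent set (each gene can neighbour at
#' most two others; with orientation, each gene end is used at most once)
#' by greedy selection in descending tip support, ties broken
#' lexicographically.
#'
#' @param tree `"phylo"` whose tips match the sample ids.
#' @param css Named list of `chromosome_set`s covering all tips.
#' @param use_orientation Boundary convention, as in [adjacencies()].
#' @return A list: `node_adjacencies` (per ape node id, character vector),
#'   `tip_adjacencies`, and the resolved tree.
#' @export
reconstruct_ancestral_adjacencies <- function(tree, css,
                                              use_orientation = FALSE) {
  miss <- setdiff(tree$tip.label, names(css))
  if (length(miss)) stop("tips without genome data: ", paste(miss, collapse = ", "))
  if (!ape::is.binary.phylo(tree)) tree <- ape::multi2di(tree)
  tip_adj <- lapply(css[tree$tip.label], adjacencies,
                    use_orientation = use_orientation)
  universe <- sort(unique(unlist(tip_adj)))
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  ch <- .tree_children(tree)
  po_nodes <- unique(ape::reorder.phylo(tree, "postorder")$edge[, 1])
  # clade tip lists for support counting
  tipsets <- vector("list", n_node)
  for (i in seq_len(n_tip)) tipsets[[i]] <- i
  for (v in po_nodes) tipsets[[v]] <- unlist(tipsets[ch$kids[[v]]])
  node_adj <- vector("list", n_node)
  cand <- matrix(FALSE, n_node, length(universe))
  supp <- matrix(0L, n_node, length(universe))
  for (j in seq_along(universe)) {
    pres <- vapply(tip_adj, function(a) universe[j] %in% a, logical(1))
    mpr <- .fitch_mpr(tree, as.integer(pres), ch, po_nodes)
    cand[, j] <- bitwAnd(mpr, 2L) > 0L      # "present" in some MP labeling
    for (v in po_nodes) supp[v, j] <- sum(pres[tipsets[[v]]])
  }
  for (v in po_nodes) {
    js <- which(cand[v, ])
    js <- js[order(-supp[v, js], universe[js])]
    used <- new.env(parent = emptyenv())
    keep <- character(0)
    for (j in js) {
      b <- universe[j]
      ends <- .boundary_ends(b, use_orientation)
      if (any(vapply(ends, function(e)
        (get0(e, envir = used, ifnotfound = 0L)) >=
          (if (use_orientation) 1L else 2L), logical(1)))) next
      for (e in ends) assign(e, get0(e, envir = used, ifnotfound = 0L) + 1L,
                             envir = used)
      keep <- c(keep, b)
    }
    node_adj[[v]] <- sort(keep)
  }
  for (i in seq_len(n_tip)) node_adj[[i]] <- tip_adj[[i]]
  list(node_adjacencies = node_adj, tip_adjacencies = tip_adj, tree = tree)
}

# gene "ends" touched by a boundary token; unsigned mode counts whole genes
# (degree cap 2), oriented mode counts signed gene sides (cap 1)
.boundary_ends <- function(b, use_orientation) {
  if (!use_orientation) return(strsplit(b, "|", fixed = TRUE)[[1]])
  p <- strsplit(b, ">", fixed = TRUE)[[1]]
  g <- sub("[+-]$", "", p); s <- sub("^.*([+-])$", "\\1", p)
  # the downstream end of the first gene and the upstream end of the second
  c(paste0(g[1], if (s[1] == "+") ":tail" else ":head"),
    paste0(g[2], if (s[2] == "+") ":head" else ":tail"))
}

# Fitch MPR state sets (bitmask 1 = absent, 2 = present, 3 = either) for a
# binary character over the tips
.fitch_mpr <- function(tree, x, ch = NULL, po_nodes = NULL) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  if (is.null(ch)) ch <- .tree_children(tree)
  if (is.null(po_nodes))
    po_nodes <- unique(ape::reorder.phylo(tree, "postorder")$edge[, 1])
  U <- integer(n_node)
  U[seq_len(n_tip)] <- x + 1L
  union_node <- logical(n_node)
  for (v in po_nodes) {
    kids <- ch$kids[[v]]
    m <- U[kids[1]]
    for (k in kids[-1]) {
      inter <- bitwAnd(m, U[k])
      if (inter != 0L) m <- inter else { m <- bitwOr(m, U[k]); union_node[v] <- TRUE }
    }
    U[v] <- m
  }
  FF <- integer(n_node)
  FF[n_tip + 1L] <- U[n_tip + 1L]
  FF[seq_len(n_tip)] <- U[seq_len(n_tip)]
  for (v in rev(po_nodes)) {
    for (k in ch$kids[[v]]) {
      if (k <= n_tip) next
      if (bitwAnd(U[k], FF[v]) == FF[v]) FF[k] <- FF[v]
      else if (union_node[k]) FF[k] <- bitwOr(U[k], FF[v])
      else {
        subun <- Reduce(bitwOr, U[ch$kids[[k]]])
        FF[k] <- bitwOr(U[k], bitwAnd(FF[v], subun))
      }
    }
  }
  FF
}

#' Shared-boundary rearrangement score of a tip against an ancestor
#'
#' `B` boundaries shared with the reconstructed ancestor divided by the
#' tip's own annotated gene count `G` (lower scores mean more
#' rearrangement).
#'
#' @param cs Tip `chromosome_set`.
#' @param ancestor Character vector: ancestral adjacency set.
#' @param use_orientation Boundary convention, as in [adjacencies()].
#' @return A list: `B`, `G`, `score = B/G`.
#' @export
rearrangement_score <- function(cs, ancestor, use_orientation = FALSE) {
  if (cs$G == 0) stop("sample ", cs$sample, " has no annotated genes")
  B <- length(intersect(adjacencies(cs, use_orientation), ancestor))
  list(B = B, G = cs$G, score = B / cs$G)
}

#' Rearrangement contrast for matched pairs
#'
#' Scores each pair member against the ancestral adjacency set
#' reconstructed at the pair's MRCA; the member with the lower shared-
#' boundary score is the more rearranged one, and the pair is won by the
#' fragmented side when the fragmented member is more rearranged.
#'
#' @param pairs A `"matched_pairs"` table (selection tree stored in its
#'   attribute must match `recon$tree`).
#' @param recon Output of [reconstruct_ancestral_adjacencies()].
#' @param css Named list of tip `chromosome_set`s.
#' @param use_orientation Boundary convention.
#' @return The pair table with `value_frag`, `value_single` (scores) and
#'   `winner` (more rearranged side; `"tie"` when equal).
#' @export
rearrangement_contrast <- function(pairs, recon, css,
                                   use_orientation = FALSE) {
  tree <- recon$tree
  vf <- vs <- numeric(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    t1 <- match(pairs$tip_frag[i], tree$tip.label)
    t0 <- match(pairs$tip_single[i], tree$tip.label)
    m <- ape::getMRCA(tree, c(t1, t0))
    anc <- recon$node_adjacencies[[m]]
    vf[i] <- rearrangement_score(css[[pairs$tip_frag[i]]], anc,
                                 use_orientation)$score
    vs[i] <- rearrangement_score(css[[pairs$tip_single[i]]], anc,
                                 use_orientation)$score
  }
  pairs$value_frag <- vf
  pairs$value_single <- vs
  pairs$winner <- ifelse(vf < vs, "fragmented",       # lower = more rearranged
                  ifelse(vf > vs, "single", "tie"))
  pairs
}
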
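#' Select phylogenetically independent fragmented/non-fragmented pairs
#'
#' A post-order greedy scan locates minimal clades that contain tips of
#' both trait states and share no tips with previously selected clades;
#' each yields one pair. If both sides of the minimal clade are single
#' tips, the pair is a sister pair. Otherwise one representative per side
#' is chosen: in `"branch-length"` mode, the tip whose path length to the
#' clade's MRCA is the within-side median (lower median for even counts);
#' in `"rearrangement"` mode, the tip whose annotated-gene count is nearest
#' to the opposing member's (when both sides hold several tips, the
#' smaller side is fixed first by its median gene count). All ties break
#' to the lexicographically smallest tip label. Selected clades are
#' consumed, which makes the tip-to-MRCA paths of distinct pairs
#' edge-disjoint.
#'
#' @param tree `"phylo"` used for pair selection.
#' @param trait Named 0/1 vector (1 = fragmented); both states required.
#' @param mode `"branch-length"` or `"rearrangement"`.
#' @param gene_counts Named per-tip annotated gene counts (rearrangement
#'   mode only).
#' @return A `data.frame` of class `"matched_pairs"` with columns
#'   `tip_frag`, `tip_single`, `mrca` (ape node id in `tree`).
#' @export
select_pairs <- function(tree, trait, mode = c("branch-length", "rearrangement"),
                         gene_counts = NULL) {
  mode <- match.arg(mode)
  if (mode == "rearrangement" && is.null(gene_counts))
    stop("gene_counts is required in rearrangement mode")
  x <- match_trait(tree, trait)
  if (length(unique(x)) < 2) {
    warning("no clade contains both states: empty pair set")
    return(.empty_pairs(tree))
  }
  n_tip <- length(tree$tip.label)
  po_nodes <- unique(ape::reorder.phylo(tree, "postorder")$edge[, 1])
  ch <- .tree_children(tree)
  depth <- ape::node.depth.edgelength(tree)   # root-to-node path lengths
  tipsets <- vector("list", n_tip + tree$Nnode)
  for (i in seq_len(n_tip)) tipsets[[i]] <- i
  consumed <- logical(n_tip)
  rows <- list()
  for (v in po_nodes) {
    tipsets[[v]] <- unlist(tipsets[ch$kids[[v]]])
    tv <- tipsets[[v]]
    if (any(consumed[tv])) next
    st <- x[tv]
    if (!(any(st == 0L) && any(st == 1L))) next
    side1 <- tv[x[tv] == 1L]                  # fragmented tips
    side0 <- tv[x[tv] == 0L]
    if (mode == "branch-length") {
      rep1 <- .median_tip(tree, side1, depth[side1] - depth[v])
      rep0 <- .median_tip(tree, side0, depth[side0] - depth[v])
    } else {
      gc1 <- gene_counts[tree$tip.label[side1]]
      gc0 <- gene_counts[tree$tip.label[side0]]
      if (length(side1) == 1L) {
        rep1 <- side1
        rep0 <- .nearest_tip(tree, side0, gc0, gc1)
      } else if (length(side0) == 1L) {
        rep0 <- side0
        rep1 <- .nearest_tip(tree, side1, gc1, gc0)
      } else if (length(side1) <= length(side0)) {
        rep1 <- .median_tip(tree, side1, gc1)
        rep0 <- .nearest_tip(tree, side0, gc0,
                             gene_counts[tree$tip.label[rep1]])
      } else {
        rep0 <- .median_tip(tree, side0, gc0)
        rep1 <- .nearest_tip(tree, side1, gc1,
                             gene_counts[tree$tip.label[rep0]])
      }
    }
    rows[[length(rows) + 1]] <- data.frame(
      tip_frag = tree$tip.label[rep1],
      tip_single = tree$tip.label[rep0],
      mrca = v, stringsAsFactors = FALSE)
    consumed[tv] <- TRUE
  }
  if (length(rows) == 0) {
    warning("no clade contains both states: empty pair set")
    return(.empty_pairs(tree))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("matched_pairs", "data.frame")
  attr(out, "tree") <- tree
  out
}

.empty_pairs <- function(tree) {
  out <- data.frame(tip_frag = character(0), tip_single = character(0),
                    mrca = integer(0))
  class(out) <- c("matched_pairs", "data.frame")
  attr(out, "tree") <- tree
  out
}

# tip whose value is the (lower) median; ties -> smallest label
.median_tip <- function(tree, tips, values) {
  ord <- order(values, tree$tip.label[tips])
  tips[ord][ceiling(length(tips) / 2)]
}

.nearest_tip <- function(tree, tips, values, target) {
  d <- abs(values - target)
  ord <- order(d, tree$tip.label[tips])
  tips[ord][1]
}

#' Branch-length contrast for matched pairs
#'
#' For each pair, sums branch lengths from each member to the pair's MRCA
#' on a comparison tree (same topology and labels as the selection tree,
#' typically with substitutions-per-site lengths) and scores which member
#' is longer.
#'
#' @param pairs A `"matched_pairs"` table from [select_pairs()].
#' @param tree_subst Comparison `"phylo"` sharing topology/labels.
#' @return The pair table with added columns `value_frag`, `value_single`,
#'   `winner` (`"fragmented"`, `"single"` or `"tie"`).
#' @export
branch_length_contrast <- function(pairs, tree_subst) {
  miss <- setdiff(c(pairs$tip_frag, pairs$tip_single), tree_subst$tip.label)
  if (length(miss)) stop("tips missing from comparison tree: ",
                         paste(miss, collapse = ", "))
  depth <- ape::node.depth.edgelength(tree_subst)
  vf <- vs <- numeric(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    t1 <- match(pairs$tip_frag[i], tree_subst$tip.label)
    t0 <- match(pairs$tip_single[i], tree_subst$tip.label)
    m <- ape::getMRCA(tree_subst, c(t1, t0))
    vf[i] <- depth[t1] - depth[m]
    vs[i] <- depth[t0] - depth[m]
  }
  pairs$value_frag <- vf
  pairs$value_single <- vs
  pairs$winner <- ifelse(vf > vs, "fragmented",
                  ifelse(vf < vs, "single", "tie"))
  pairs
}

#' Two-tailed sign test
#'
#' Default is the normal approximation without continuity correction,
#' `z = (k - n/2) / sqrt(n/4)`; the exact two-tailed binomial p-value
#' (`2 * min(P(X <= k), P(X >= k))`, capped at 1) is also reported.
#'
#' @param k Number of pairs won by the focal (fragmented) side.
#' @param n Number of informative pairs (ties excluded), >= 1.
#' @param method `"normal"` (default) or `"exact"`: which p-value `p`
#'   reports.
#' @return A list of class `"sign_test"`: `k`, `n`, `z`, `p_normal`,
#'   `p_exact`, `p`, `method`.
#' @export
sign_test <- function(k, n, method = c("normal", "exact")) {
  method <- match.arg(method)
  if (n < 1) stop("n must be >= 1")
  if (k < 0 || k > n) stop("k must be between 0 and n")
  z <- (k - n / 2) / sqrt(n / 4)
  p_normal <- 2 * stats::pnorm(-abs(z))
  p_exact <- min(1, 2 * min(stats::pbinom(k, n, 0.5),
                            1 - stats::pbinom(k - 1, n, 0.5)))
  structure(list(k = k, n = n, z = z, p_normal = p_normal,
                 p_exact = p_exact,
                 p = if (method == "normal") p_normal else p_exact,
                 method = method),
            class = "sign_test")
}

#' @export
print.sign_test <- function(x, ...) {
  cat(sprintf("sign test: %d of %d pairs, z = %.4f\n", x$k, x$n, x$z))
  cat(sprintf("  p (normal, two-tailed) = %.4g; p (exact binomial) = %.4g\n",
              x$p_normal, x$p_exact))
  invisible(x)
}

#' Sign test over a contrast table
#'
#' Drops ties and tests whether the fragmented member wins more often than
#' expected by chance.
#'
#' @param contrasts Output of [branch_length_contrast()] or
#'   [rearrangement_contrast()].
#' @inheritParams sign_test
#' @export
pair_sign_test <- function(contrasts, method = c("normal", "exact")) {
  inf <- contrasts$winner != "tie"
  sign_test(sum(contrasts$winner[inf] == "fragmented"), sum(inf),
            method = match.arg(method))
}
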
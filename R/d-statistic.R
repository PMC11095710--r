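# sum of sister-clade differences for the D statistic: equal-weights nodal
# averaging down the tree, then sum over internal nodes of |v_left - v_right|.
# x may be a matrix (tips x nsim); returns one d per column.
.d_sum <- function(tree, x) {
  n_tip <- length(tree$tip.label)
  x <- as.matrix(x)
  n_node <- n_tip + tree$Nnode
  V <- matrix(0, n_node, ncol(x))
  V[seq_len(n_tip), ] <- x
  po <- ape::reorder.phylo(tree, "postorder")$edge
  d <- numeric(ncol(x))
  # children come in consecutive postorder edge pairs on a binary tree
  po_nodes <- unique(po[, 1])
  kid <- split(po[, 2], po[, 1])
  for (v in po_nodes) {
    k <- kid[[as.character(v)]]
    d <- d + abs(V[k[1], ] - V[k[2], ])
    V[v, ] <- (V[k[1], ] + V[k[2], ]) / 2
  }
  d
}

#' Fritz-Purvis D statistic for a binary trait
#'
#' Measures phylogenetic signal of a binary trait, scaled so that a
#' phylogenetically random trait has expectation ~1 and a trait generated
#' by thresholding a Brownian process has expectation ~0. The observed sum
#' of sister-clade differences `d_obs` is contrasted against two simulated
#' nulls with matched prevalence: tip-label permutation and Brownian
#' threshold. Multifurcations are resolved arbitrarily with zero-length
#' branches.
#'
#' @param tree Dated `"phylo"` with >= 4 tips.
#' @param trait Named 0/1 vector; must be non-constant.
#' @param n_sim Simulations per null (default 1000).
#' @param seed Optional integer seed.
#' @return A list of class `"dstat"`: `d_obs`, `mean_d_random`,
#'   `mean_d_brownian`, `D`, `p_random` (fraction of random-null d <=
#'   d_obs), `p_brownian`, `n_sim`.
#' @export
d_statistic <- function(tree, trait, n_sim = 1000, seed = NULL) {
  if (length(tree$tip.label) < 4) stop("tree must have >= 4 tips")
  if (!ape::is.binary.phylo(tree)) tree <- ape::multi2di(tree)
  if (tree$Nnode < 2) stop("star tree: D undefined")
  x <- match_trait(tree, trait)
  if (length(unique(x)) < 2) stop("signal undefined for a constant trait")
  if (!is.null(seed)) set.seed(seed)
  n_tip <- length(x)
  n1 <- sum(x)
  d_obs <- .d_sum(tree, x)
  # random null: permute tip states (prevalence preserved)
  perm <- replicate(n_sim, sample(x))
  d_rand <- .d_sum(tree, perm)
  # Brownian null: continuous BM, thresholded at observed prevalence
  Z <- .bm_tips(tree, n_sim)
  thr <- apply(Z, 2, function(z) z >= sort(z, decreasing = TRUE)[n1])
  d_brown <- .d_sum(tree, thr + 0)
  mr <- mean(d_rand); mb <- mean(d_brown)
  if (abs(mr - mb) < .Machine$double.eps) stop("degenerate nulls: D undefined")
  structure(list(d_obs = d_obs,
                 mean_d_random = mr, mean_d_brownian = mb,
                 D = (d_obs - mb) / (mr - mb),
                 p_random = mean(d_rand <= d_obs),
                 p_brownian = mean(d_brown <= d_obs),
                 n_sim = n_sim),
            class = "dstat")
}

#' @export
print.dstat <- function(x, ...) {
  cat(sprintf("D = %.4f (d_obs = %.3f; random mean %.3f, Brownian mean %.3f)\n",
              x$D, x$d_obs, x$mean_d_random, x$mean_d_brownian))
  cat(sprintf("P(random structure) = %.4g, P(Brownian) = %.4g  [%d sims]\n",
              x$p_random, x$p_brownian, x$n_sim))
  invisible(x)
}

# n_sim Brownian tip realizations (unit rate) via the tree covariance
.bm_tips <- function(tree, n_sim) {
  V <- ape::vcv(tree)
  # zero-length resolutions can make V only positive semidefinite
  U <- chol(V + diag(1e-10 * max(diag(V)), nrow(V)))
  t(U) %*% matrix(stats::rnorm(nrow(V) * n_sim), nrow(V), n_sim)
}
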
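# children list (and matching edge lengths) per internal node
.tree_children <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  kids <- vector("list", n_node)
  klen <- vector("list", n_node)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1]
    kids[[p]] <- c(kids[[p]], tree$edge[i, 2])
    klen[[p]] <- c(klen[[p]], tree$edge.length[i])
  }
  list(kids = kids, klen = klen)
}

# normalized down-pass partials per node plus P-matrices per edge
.mk_down <- function(tree, x, q01, q10) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  ch <- .tree_children(tree)
  D <- matrix(0, n_node, 2)
  D[cbind(seq_len(n_tip), x + 1L)] <- 1
  po_nodes <- unique(ape::reorder.phylo(tree, "postorder")$edge[, 1])
  for (v in po_nodes) {
    d <- c(1, 1)
    for (j in seq_along(ch$kids[[v]])) {
      c_ <- ch$kids[[v]][j]
      P <- .mk_pmat(q01, q10, ch$klen[[v]][j])
      d <- d * as.vector(P %*% D[c_, ])
    }
    D[v, ] <- d / max(sum(d), .Machine$double.xmin)
  }
  list(D = D, ch = ch, po_nodes = po_nodes)
}

#' Marginal ancestral state probabilities under an Mk model
#'
#' Per-node marginal probabilities of states 0/1 computed by combining the
#' pruning partials below each node with the partials of the rest of the
#' tree (the re-rooting method). The root uses the chosen prior.
#'
#' @inheritParams mk_loglik
#' @param fit Optionally an `"mk_fit"`; its rates and root prior are used.
#' @return A matrix (`n_node` x 2, columns `"0"`, `"1"`): tips first, then
#'   internal nodes in ape numbering. Rows sum to 1.
#' @export
marginal_states <- function(tree, trait, q01 = NULL, q10 = NULL,
                            root_prior = "flat", fit = NULL) {
  if (!is.null(fit)) { q01 <- fit$q01; q10 <- fit$q10; root_prior <- fit$root_prior }
  x <- match_trait(tree, trait)
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  dn <- .mk_down(tree, x, q01, q10)
  D <- dn$D; ch <- dn$ch
  root <- n_tip + 1L
  prior <- .mk_root_prior(q01, q10, root_prior)
  FF <- matrix(0, n_node, 2)
  FF[root, ] <- prior
  for (v in rev(dn$po_nodes)) {           # preorder over internal nodes
    kids <- ch$kids[[v]]
    msg <- vapply(seq_along(kids), function(j)
      as.vector(.mk_pmat(q01, q10, ch$klen[[v]][j]) %*% D[kids[j], ]),
      numeric(2))                          # 2 x nkids, message from each child
    for (j in seq_along(kids)) {
      others <- apply(msg[, -j, drop = FALSE], 1, prod)
      up <- FF[v, ] * others               # outside info at v, by state of v
      f <- as.vector(t(.mk_pmat(q01, q10, ch$klen[[v]][j])) %*% up)
      FF[kids[j], ] <- f / max(sum(f), .Machine$double.xmin)
    }
  }
  m <- FF * D
  m[root, ] <- prior * D[root, ]
  m <- m / rowSums(m)
  colnames(m) <- c("0", "1")
  rownames(m) <- c(tree$tip.label, rep("", tree$Nnode))
  m
}

#' Stochastic character mapping by backward filtering / forward sampling
#'
#' Node states are drawn exactly from their joint conditional distribution
#' given the tip data; within-branch histories are then sampled conditional
#' on branch endpoints by uniformization (no rejection). Under an
#' irreversible model no sampled map contains a 1->0 transition.
#'
#' @inheritParams marginal_states
#' @param n_sim Number of maps (default 1000).
#' @param seed Optional integer seed.
#' @return An object of class `"stochastic_maps"`: `node_freq` (per-node
#'   relative frequency of each state across maps), `counts` (per-map
#'   `n01`, `n10` transition counts), `n_sim`, rates.
#' @export
stochastic_map <- function(tree, trait, q01 = NULL, q10 = NULL,
                           root_prior = "flat", fit = NULL,
                           n_sim = 1000, seed = NULL) {
  if (!is.null(fit)) { q01 <- fit$q01; q10 <- fit$q10; root_prior <- fit$root_prior }
  if (q01 <= 0 && q10 <= 0) stop("model must have at least one positive rate")
  if (!is.null(seed)) set.seed(seed)
  x <- match_trait(tree, trait)
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  dn <- .mk_down(tree, x, q01, q10)
  D <- dn$D
  root <- n_tip + 1L
  prior <- .mk_root_prior(q01, q10, root_prior)
  edge <- tree$edge; elen <- tree$edge.length
  tree_cw <- ape::reorder.phylo(tree, "cladewise")
  ord <- match(paste(tree_cw$edge[, 1], tree_cw$edge[, 2]),
               paste(edge[, 1], edge[, 2]))
  Pm <- lapply(seq_len(nrow(edge)), function(i) .mk_pmat(q01, q10, elen[i]))
  omega <- max(q01, q10)
  R <- if (omega > 0)
    diag(2) + matrix(c(-q01, q10, q01, -q10), 2, 2) / omega else diag(2)
  node_freq <- matrix(0, n_node, 2)
  counts <- matrix(0L, n_sim, 2, dimnames = list(NULL, c("n01", "n10")))
  states <- integer(n_node)
  for (s_i in seq_len(n_sim)) {
    w <- prior * D[root, ]
    states[root] <- (stats::runif(1) < w[2] / sum(w)) + 0L
    n01 <- 0L; n10 <- 0L
    for (i in ord) {
      j <- states[edge[i, 1]] + 1L
      w <- Pm[[i]][j, ] * D[edge[i, 2], ]
      st <- (stats::runif(1) < w[2] / sum(w)) + 0L
      states[edge[i, 2]] <- st
      jm <- .unif_jumps(j - 1L, st, elen[i], q01, q10, omega, R, Pm[[i]])
      n01 <- n01 + jm[1]; n10 <- n10 + jm[2]
    }
    node_freq[cbind(seq_len(n_node), states + 1L)] <-
      node_freq[cbind(seq_len(n_node), states + 1L)] + 1
    counts[s_i, ] <- c(n01, n10)
  }
  node_freq <- node_freq / n_sim
  colnames(node_freq) <- c("0", "1")
  rownames(node_freq) <- c(tree$tip.label, rep("", tree$Nnode))
  structure(list(node_freq = node_freq,
                 counts = as.data.frame(counts),
                 n_sim = n_sim, q01 = q01, q10 = q10,
                 root_prior = root_prior),
            class = "stochastic_maps")
}

#' @export
print.stochastic_maps <- function(x, ...) {
  cat(sprintf("stochastic maps: %d simulations (q01 = %.4g, q10 = %.4g)\n",
              x$n_sim, x$q01, x$q10))
  cat(sprintf("  transitions 0->1: median %g [%g, %g]; 1->0: median %g\n",
              stats::median(x$counts$n01),
              stats::quantile(x$counts$n01, 0.05),
              stats::quantile(x$counts$n01, 0.95),
              stats::median(x$counts$n10)))
  invisible(x)
}

# sample the number of real 0->1 / 1->0 jumps on one branch, conditional on
# endpoint states a -> b over duration t, by uniformization
.unif_jumps <- function(a, b, t, q01, q10, omega, R, Pt) {
  if (omega == 0 || t == 0) return(c(0L, 0L))
  ai <- a + 1L; bi <- b + 1L
  pt <- Pt[ai, bi]
  lam <- omega * t
  # sample N (number of uniformized events) by sequential inversion
  u <- stats::runif(1) * pt
  Rpow <- list(diag(2))                       # R^0
  n <- 0L; acc <- stats::dpois(0, lam) * Rpow[[1]][ai, bi]
  while (acc < u && n < 100000L) {
    n <- n + 1L
    Rpow[[n + 1L]] <- Rpow[[n]] %*% R
    acc <- acc + stats::dpois(n, lam) * Rpow[[n + 1L]][ai, bi]
  }
  if (n == 0L) return(c(0L, 0L))
  # sample the embedded chain states given N = n and endpoints
  z <- integer(n + 1L); z[1] <- ai; z[n + 1L] <- bi
  if (n > 1L) for (k in 2:n) {
    wts <- R[z[k - 1L], ] * Rpow[[n - k + 2L]][, bi]
    z[k] <- (stats::runif(1) < wts[2] / sum(wts)) + 1L
  }
  d <- diff(z)
  c(sum(d == 1L), sum(d == -1L))
}

#' Fitch parsimony ancestral states
#'
#' Up-pass/down-pass Fitch sets for the binary trait; the total change
#' count equals the number of union events in the up-pass. Multifurcations
#' are resolved arbitrarily with zero-length branches first.
#'
#' @inheritParams mk_loglik
#' @return A list of class `"parsimony_recon"`: `node_sets` (character,
#'   one of `"0"`, `"1"`, `"01"`, tips first then internal nodes of the
#'   resolved tree), `changes` (minimum number of state changes), and the
#'   resolved tree used.
#' @export
parsimony_states <- function(tree, trait) {
  if (!ape::is.binary.phylo(tree)) tree <- ape::multi2di(tree)
  x <- match_trait(tree, trait)
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  ch <- .tree_children(tree)
  U <- integer(n_node)               # bitmask: 1 = {0}, 2 = {1}, 3 = {0,1}
  U[seq_len(n_tip)] <- x + 1L
  union_node <- logical(n_node)
  po_nodes <- unique(ape::reorder.phylo(tree, "postorder")$edge[, 1])
  changes <- 0L
  for (v in po_nodes) {
    kids <- ch$kids[[v]]
    m <- U[kids[1]]
    for (k in kids[-1]) {
      inter <- bitwAnd(m, U[k])
      if (inter != 0L) m <- inter
      else { m <- bitwOr(m, U[k]); changes <- changes + 1L; union_node[v] <- TRUE }
    }
    U[v] <- m
  }
  FF <- integer(n_node)
  root <- n_tip + 1L
  FF[root] <- U[root]
  for (v in rev(po_nodes)) {
    for (k in ch$kids[[v]]) {
      if (k <= n_tip) { FF[k] <- U[k]; next }
      if (bitwAnd(U[k], FF[v]) == FF[v]) {
        FF[k] <- FF[v]
      } else if (union_node[k]) {
        FF[k] <- bitwOr(U[k], FF[v])
      } else {
        kk <- ch$kids[[k]]
        subun <- Reduce(bitwOr, U[kk])
        FF[k] <- bitwOr(U[k], bitwAnd(FF[v], subun))
      }
    }
  }
  setchr <- c("0", "1", "01")
  structure(list(node_sets = setchr[FF], changes = changes, tree = tree),
            class = "parsimony_recon")
}
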
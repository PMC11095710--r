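# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's pruning/Fitch code paths: likelihoods are enumerated
# over all internal-state assignments, parsimony by exhaustive labeling.

oracle_pmat <- function(q01, q10, t) {
  s <- q01 + q10
  if (s == 0 || t == 0) return(diag(2))
  e <- exp(-s * t)
  matrix(c((q10 + q01 * e) / s, q10 * (1 - e) / s,
           q01 * (1 - e) / s, (q01 + q10 * e) / s), 2, 2)
}

# full enumeration over 2^Nnode internal assignments
oracle_mk_lik_terms <- function(tree, x, q01, q10, prior = c(0.5, 0.5)) {
  nt <- length(tree$tip.label)
  nn <- tree$Nnode
  terms <- matrix(0, 2^nn, nt + nn + 1)
  for (idx in 0:(2^nn - 1)) {
    st <- c(x, as.integer(intToBits(idx))[1:nn])
    lik <- prior[st[nt + 1] + 1]
    for (e in seq_len(nrow(tree$edge)))
      lik <- lik * oracle_pmat(q01, q10, tree$edge.length[e])[
        st[tree$edge[e, 1]] + 1, st[tree$edge[e, 2]] + 1]
    terms[idx + 1, ] <- c(st, lik)
  }
  terms
}

oracle_mk_loglik <- function(tree, x, q01, q10, prior = c(0.5, 0.5)) {
  log(sum(oracle_mk_lik_terms(tree, x, q01, q10, prior)[, length(x) + tree$Nnode + 1]))
}

oracle_mk_marginals <- function(tree, x, q01, q10, prior = c(0.5, 0.5)) {
  terms <- oracle_mk_lik_terms(tree, x, q01, q10, prior)
  n_all <- length(x) + tree$Nnode
  post <- matrix(0, n_all, 2)
  for (r in seq_len(nrow(terms)))
    post[cbind(seq_len(n_all), terms[r, 1:n_all] + 1)] <-
      post[cbind(seq_len(n_all), terms[r, 1:n_all] + 1)] + terms[r, n_all + 1]
  post / rowSums(post)
}

# exhaustive minimum parsimony change count, and per-node MPR membership
oracle_parsimony <- function(tree, x) {
  nt <- length(tree$tip.label)
  nn <- tree$Nnode
  best <- Inf
  costs <- numeric(2^nn)
  for (idx in 0:(2^nn - 1)) {
    st <- c(x, as.integer(intToBits(idx))[1:nn])
    ch <- sum(st[tree$edge[, 1]] != st[tree$edge[, 2]])
    costs[idx + 1] <- ch
    best <- min(best, ch)
  }
  in_mpr <- matrix(FALSE, nn, 2)
  for (idx in which(costs == best) - 1) {
    st <- as.integer(intToBits(idx))[1:nn]
    in_mpr[cbind(seq_len(nn), st + 1)] <- TRUE
  }
  list(changes = best, mpr_internal = in_mpr)
}

# exhaustive minimum-change ancestral adjacency presence per internal node,
# filtered with the same greedy consistency rule as the implementation
oracle_ancestral_adjacencies <- function(tree, css, use_orientation = FALSE) {
  tip_adj <- lapply(css[tree$tip.label], adjacencies,
                    use_orientation = use_orientation)
  universe <- sort(unique(unlist(tip_adj)))
  nt <- length(tree$tip.label)
  nn <- tree$Nnode
  cand <- matrix(FALSE, nt + nn, length(universe))
  supp <- matrix(0L, nt + nn, length(universe))
  clade_tips <- lapply(seq_len(nt + nn), function(v) {
    if (v <= nt) v
    else which(tree$tip.label %in% ape::extract.clade(tree, v)$tip.label)
  })
  for (j in seq_along(universe)) {
    pres <- vapply(tip_adj, function(a) universe[j] %in% a, logical(1))
    orc <- oracle_parsimony(tree, as.integer(pres))
    cand[(nt + 1):(nt + nn), j] <- orc$mpr_internal[, 2]
    for (v in (nt + 1):(nt + nn))
      supp[v, j] <- sum(pres[clade_tips[[v]]])
  }
  lapply((nt + 1):(nt + nn), function(v) {
    js <- which(cand[v, ])
    js <- js[order(-supp[v, js], universe[js])]
    used <- list()
    keep <- character(0)
    for (j in js) {
      b <- universe[j]
      genes <- strsplit(b, "|", fixed = TRUE)[[1]]
      deg <- vapply(genes, function(g)
        if (is.null(used[[g]])) 0L else used[[g]], integer(1))
      if (any(deg >= 2L)) next
      for (g in genes) used[[g]] <- deg[[g]] + 1L
      keep <- c(keep, b)
    }
    sort(keep)
  })
}

# all tree edges on the path from a tip to an ancestor node
path_edges <- function(tree, tip, anc) {
  out <- integer(0)
  v <- tip
  while (v != anc) {
    e <- which(tree$edge[, 2] == v)
    out <- c(out, e)
    v <- tree$edge[e, 1]
  }
  out
}

# brute-force check that all pair tip->MRCA paths are pairwise edge-disjoint
pairs_edge_disjoint <- function(tree, pairs) {
  if (nrow(pairs) < 2) return(TRUE)
  sets <- lapply(seq_len(nrow(pairs)), function(i) {
    t1 <- match(pairs$tip_frag[i], tree$tip.label)
    t0 <- match(pairs$tip_single[i], tree$tip.label)
    m <- ape::getMRCA(tree, c(t1, t0))
    c(path_edges(tree, t1, m), path_edges(tree, t0, m))
  })
  for (i in seq_along(sets)) for (j in seq_along(sets)) {
    if (j <= i) next
    if (length(intersect(sets[[i]], sets[[j]])) > 0) return(FALSE)
  }
  TRUE
}

# quadratic longest-common-substring oracle
oracle_lcs_length <- function(a, b) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  prev <- integer(length(b)); best <- 0L
  for (i in seq_along(a)) {
    cur <- integer(length(b))
    match_i <- a[i] == b
    cur[match_i] <- c(0L, prev)[which(match_i)] + 1L
    best <- max(best, cur)
    prev <- cur
  }
  best
}

# one Brownian tip realization on a tree (unit rate), named by tip
bm_draw <- function(tree) {
  V <- ape::vcv(tree)
  stats::setNames(as.vector(t(chol(V)) %*% rnorm(nrow(V))), rownames(V))
}

# small genome-table fixture writer
write_gt <- function(rows) {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("sample\tchromosome\tgenes\tcircular\tlength_bp", rows), f)
  f
}
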
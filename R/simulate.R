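#' Simulate a dated birth-death tree
#'
#' Forward constant-rate birth-death simulation started from two crown
#' lineages, run until the number of surviving lineages first reaches
#' `n_tips`, then extended by one final exponential waiting time at the
#' full event rate (so that for a pure-birth process the expected crown
#' height is `sum(1/(birth * k))` for `k = 2..n_tips`). Histories in which
#' the clade dies out before reaching `n_tips` are rejected and resimulated.
#'
#' @param n_tips Number of surviving tips (>= 2).
#' @param birth,death Speciation and extinction rates per lineage per Mya;
#'   `birth > death >= 0`.
#' @param seed Optional integer seed.
#' @param max_tries Rejection cap for histories that go extinct.
#' @return An ultrametric `"phylo"` tree with tips `t1..tn` and branch
#'   lengths in Mya.
#' @export
sim_bd_tree <- function(n_tips, birth = 0.1, death = 0, seed = NULL,
                        max_tries = 1000L) {
  if (n_tips < 2) stop("n_tips must be >= 2")
  if (birth <= death) stop("birth rate must exceed death rate")
  if (birth <= 0 || death < 0) stop("rates must be non-negative, birth > 0")
  if (!is.null(seed)) set.seed(seed)
  for (try in seq_len(max_tries)) {
    tr <- .sim_bd_once(n_tips, birth, death)
    if (!is.null(tr)) return(tr)
  }
  stop("failed to reach ", n_tips, " surviving tips in ", max_tries, " tries")
}

.sim_bd_once <- function(n_tips, birth, death) {
  # node records; id 1 = crown root with children 2, 3
  parent <- c(NA, 1L, 1L)
  birth_t <- c(0, 0, 0)
  len <- c(0, NA, NA)
  alive <- c(FALSE, TRUE, TRUE)
  is_tip <- c(FALSE, TRUE, TRUE)   # currently childless
  t <- 0
  n_alive <- 2L
  if (n_tips > 2) repeat {
    rate <- n_alive * (birth + death)
    t <- t + stats::rexp(1, rate)
    x <- which(alive)[sample.int(n_alive, 1)]
    if (stats::runif(1) < birth / (birth + death)) {
      # speciation: x becomes internal, two new lineages
      len[x] <- t - birth_t[x]
      alive[x] <- FALSE; is_tip[x] <- FALSE
      for (k in 1:2) {
        parent <- c(parent, x); birth_t <- c(birth_t, t)
        len <- c(len, NA); alive <- c(alive, TRUE); is_tip <- c(is_tip, TRUE)
      }
      n_alive <- n_alive + 1L
      if (n_alive == n_tips) break
    } else {
      len[x] <- t - birth_t[x]
      alive[x] <- FALSE               # extinct tip
      n_alive <- n_alive - 1L
      if (n_alive == 0L) return(NULL)
    }
  }
  # final waiting period at n_tips lineages, cut before the next event
  t <- t + stats::rexp(1, n_alive * (birth + death))
  len[alive] <- t - birth_t[alive]
  tree <- .records_to_phylo(parent, len, is_tip)
  survivors <- tree$tip.label[tree$tip.label %in% paste0("n", which(alive))]
  if (any(!alive & is_tip)) {
    tree <- ape::drop.tip(tree, setdiff(tree$tip.label, survivors))
  }
  tree$tip.label <- paste0("t", seq_along(tree$tip.label))
  tree
}

# convert parent/length/tip-flag records (internal ids) to an ape phylo
.records_to_phylo <- function(parent, len, is_tip) {
  n <- length(parent)
  tips <- which(is_tip)
  internals <- which(!is_tip)
  new_id <- integer(n)
  new_id[tips] <- seq_along(tips)
  new_id[internals] <- length(tips) + seq_along(internals)
  has_parent <- which(!is.na(parent))
  edge <- cbind(new_id[parent[has_parent]], new_id[has_parent])
  structure(list(edge = edge, edge.length = len[has_parent],
                 tip.label = paste0("n", tips),
                 Nnode = length(internals)),
            class = "phylo", order = "cladewise")
}

#' Simulate a binary trait under a two-state Markov model
#'
#' Exact continuous-time simulation by exponential jump sampling along each
#' branch (preorder), recording the full state painting of every branch.
#' State 0 = single-chromosome, 1 = fragmented.
#'
#' @param tree A dated `"phylo"` tree.
#' @param q01,q10 Transition rates 0->1 and 1->0 per Mya.
#' @param root_state `0`, `1`, or `"stationary"` (sample from the stationary
#'   distribution of the rate matrix).
#' @param seed Optional integer seed.
#' @return A list of class `"trait_sim"` with elements `trait` (named 0/1
#'   vector over tips), `node_states`, `paintings` (per edge, in
#'   `tree$edge` row order: parent-end state, jump times measured from the
#'   parent end, and the state after each jump), `n01`, `n10` (true
#'   transition counts), and the generating rates.
#' @export
sim_binary_trait <- function(tree, q01, q10, root_state = "stationary",
                             seed = NULL) {
  if (q01 < 0 || q10 < 0) stop("rates must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  s <- q01 + q10
  root <- length(tree$tip.label) + 1L
  if (identical(root_state, "stationary")) {
    if (s == 0) stop("both rates are zero: root state must be given explicitly")
    root_state <- stats::rbinom(1, 1, q01 / s)
  }
  n_node <- length(tree$tip.label) + tree$Nnode
  node_state <- rep(NA_integer_, n_node)
  node_state[root] <- as.integer(root_state)
  edge <- tree$edge
  # preorder: cladewise edge order guarantees parents precede children
  tree_cw <- ape::reorder.phylo(tree, "cladewise")
  ord <- match(paste(tree_cw$edge[, 1], tree_cw$edge[, 2]),
               paste(edge[, 1], edge[, 2]))
  paintings <- vector("list", nrow(edge))
  n01 <- 0L; n10 <- 0L
  for (i in ord) {
    st <- node_state[edge[i, 1]]
    tlen <- tree$edge.length[i]
    jumps <- numeric(0); states <- integer(0)
    pos <- 0; cur <- st
    repeat {
      r <- if (cur == 0L) q01 else q10
      if (r == 0) break
      w <- stats::rexp(1, r)
      if (pos + w > tlen) break
      pos <- pos + w
      cur <- 1L - cur
      jumps <- c(jumps, pos); states <- c(states, cur)
    }
    n01 <- n01 + sum(states == 1L)
    n10 <- n10 + sum(states == 0L)
    paintings[[i]] <- list(parent_state = st, jumps = jumps, states = states)
    node_state[edge[i, 2]] <- cur
  }
  trait <- stats::setNames(node_state[seq_along(tree$tip.label)],
                           tree$tip.label)
  structure(list(trait = trait, node_states = node_state,
                 paintings = paintings, n01 = n01, n10 = n10,
                 q01 = q01, q10 = q10, tree = tree),
            class = "trait_sim")
}

# per-edge durations spent in each state, from a trait_sim painting
painting_durations <- function(tree, sim) {
  edge_len <- tree$edge.length
  t(vapply(seq_along(sim$paintings), function(i) {
    p <- sim$paintings[[i]]
    if (is.null(p)) stop("painting absent for edge ", i)
    bounds <- c(0, p$jumps, edge_len[i])
    states <- c(p$parent_state, p$states)
    durs <- diff(bounds)
    c(sum(durs[states == 0L]), sum(durs[states == 1L]))
  }, numeric(2)))
}

#' Paint substitution-rate branch lengths onto a dated tree
#'
#' Converts time branch lengths into expected substitutions per site: each
#' branch length is the sum over its trait-painted segments of
#' `duration * base_rate`, multiplied by `multiplier` on segments painted
#' fragmented. Optional multiplicative lognormal noise (mean one) emulates
#' finite-alignment estimation error.
#'
#' @param tree Dated `"phylo"`.
#' @param sim A `"trait_sim"` from [sim_binary_trait()] on the same tree.
#' @param base_rate Substitutions/site/Mya on single-chromosome segments.
#' @param multiplier Rate multiplier (> 0) on fragmented segments.
#' @param sigma Standard deviation (log scale) of the lognormal jitter; 0
#'   disables noise.
#' @param seed Optional integer seed.
#' @return The tree with branch lengths in substitutions/site.
#' @export
sim_branch_lengths <- function(tree, sim, base_rate = 0.01, multiplier = 1,
                               sigma = 0, seed = NULL) {
  if (multiplier <= 0) stop("multiplier must be > 0")
  if (!is.null(seed)) set.seed(seed)
  durs <- painting_durations(tree, sim)
  len <- base_rate * (durs[, 1] + multiplier * durs[, 2])
  if (sigma > 0)
    len <- len * exp(stats::rnorm(length(len), -sigma^2 / 2, sigma))
  out <- tree
  out$edge.length <- len
  out
}

#' Simulate gene-order evolution with rearrangement and fission
#'
#' Starting from a circular ancestral gene order at the root, events occur
#' along each branch as a Poisson process whose rate is multiplied by
#' `frag_multiplier` on branch segments painted fragmented (when a
#' `trait_sim` painting is supplied). Events are (i) a move of a random
#' contiguous block of 1-3 genes to a random position (possibly another
#' chromosome) with random orientation, and (ii) a fission of a circular
#' chromosome into two circles at two random gene boundaries. Gene content
#' is conserved.
#'
#' @param tree Dated `"phylo"`.
#' @param ancestral_order Character vector of gene names (circular order at
#'   the root, all on the + strand).
#' @param rearr_rate,fission_rate Event rates per Mya.
#' @param frag_multiplier Event-rate multiplier on fragmented segments.
#' @param sim Optional `"trait_sim"`; required when `frag_multiplier != 1`.
#' @param seed Optional integer seed.
#' @return A list of class `"gene_order_sim"` with `table` (tip
#'   `genome_table`), `node_orders` (per-node chromosome lists, tips and
#'   internal nodes), and `edge_events` (realized event count per edge).
#' @export
sim_gene_orders <- function(tree, ancestral_order, rearr_rate = 0.02,
                            fission_rate = 0.005, frag_multiplier = 1,
                            sim = NULL, seed = NULL) {
  if (length(ancestral_order) == 0) stop("ancestral order must be non-empty")
  if (frag_multiplier != 1 && is.null(sim))
    stop("a trait painting (sim) is required when frag_multiplier != 1")
  if (!is.null(seed)) set.seed(seed)
  root <- length(tree$tip.label) + 1L
  n_node <- length(tree$tip.label) + tree$Nnode
  node_orders <- vector("list", n_node)
  node_orders[[root]] <- list(list(genes = ancestral_order,
                                   strands = rep(1L, length(ancestral_order)),
                                   circular = TRUE))
  eff_dur <- if (is.null(sim)) tree$edge.length else {
    durs <- painting_durations(tree, sim)
    durs[, 1] + frag_multiplier * durs[, 2]
  }
  edge <- tree$edge
  tree_cw <- ape::reorder.phylo(tree, "cladewise")
  ord <- match(paste(tree_cw$edge[, 1], tree_cw$edge[, 2]),
               paste(edge[, 1], edge[, 2]))
  total_rate <- rearr_rate + fission_rate
  edge_events <- integer(nrow(edge))
  for (i in ord) {
    chroms <- node_orders[[edge[i, 1]]]
    n_ev <- if (total_rate > 0) stats::rpois(1, total_rate * eff_dur[i]) else 0L
    edge_events[i] <- n_ev
    for (e in seq_len(n_ev)) {
      fission_ok <- any(vapply(chroms, function(c)
        c$circular && length(c$genes) >= 2, logical(1)))
      p_fis <- if (fission_ok) fission_rate / total_rate else 0
      chroms <- if (stats::runif(1) < p_fis) .apply_fission(chroms)
                else .apply_move(chroms)
    }
    node_orders[[edge[i, 2]]] <- chroms
  }
  tips <- seq_along(tree$tip.label)
  css <- lapply(tips, function(i)
    as_chromosome_set(tree$tip.label[i], node_orders[[i]]))
  structure(list(table = as_genome_table(css), node_orders = node_orders,
                 edge_events = edge_events, tree = tree),
            class = "gene_order_sim")
}

.apply_move <- function(chroms) {
  sizes <- vapply(chroms, function(c) length(c$genes), integer(1))
  ci <- sample.int(length(chroms), 1, prob = sizes)
  ch <- chroms[[ci]]
  n <- length(ch$genes)
  k <- sample.int(min(3L, n), 1)
  start <- sample.int(n, 1)
  idx <- ((start - 1 + seq_len(k) - 1) %% n) + 1   # wraps on circles
  if (!ch$circular) idx <- idx[idx >= start][seq_len(min(k, n - start + 1))]
  block <- list(genes = ch$genes[idx], strands = ch$strands[idx])
  ch$genes <- ch$genes[-idx]; ch$strands <- ch$strands[-idx]
  if (stats::runif(1) < 0.5) {   # invert the block
    block$genes <- rev(block$genes); block$strands <- -rev(block$strands)
  }
  chroms[[ci]] <- ch
  if (length(ch$genes) == 0) chroms <- chroms[-ci]
  if (length(chroms) == 0)   # the block was the whole genome: keep it intact
    return(list(list(genes = block$genes, strands = block$strands,
                     circular = TRUE)))
  # insertion slot: any chromosome, any position
  sizes2 <- vapply(chroms, function(c) length(c$genes), integer(1))
  cj <- sample.int(length(chroms), 1, prob = sizes2 + 1)
  tgt <- chroms[[cj]]
  pos <- sample.int(length(tgt$genes) + 1, 1) - 1   # insert after pos
  tgt$genes <- append(tgt$genes, block$genes, after = pos)
  tgt$strands <- append(tgt$strands, block$strands, after = pos)
  chroms[[cj]] <- tgt
  chroms
}

.apply_fission <- function(chroms) {
  ok <- which(vapply(chroms, function(c)
    c$circular && length(c$genes) >= 2, logical(1)))
  ci <- ok[sample.int(length(ok), 1)]
  ch <- chroms[[ci]]
  n <- length(ch$genes)
  cuts <- sort(sample.int(n, 2))   # cut after positions cuts[1], cuts[2]
  i1 <- (cuts[1] + 1):cuts[2]
  i2 <- setdiff(seq_len(n), i1)
  # keep original relative order on the circle for the wrap-around piece
  i2 <- c(i2[i2 > cuts[2]], i2[i2 <= cuts[1]])
  chroms[[ci]] <- list(genes = ch$genes[i1], strands = ch$strands[i1],
                       circular = TRUE)
  chroms[[length(chroms) + 1]] <- list(genes = ch$genes[i2],
                                       strands = ch$strands[i2],
                                       circular = TRUE)
  chroms
}

#' Simulate a random genome sequence
#'
#' @param length_bp Sequence length.
#' @param at Target AT fraction (default 0.75, typical of insect
#'   mitogenomes).
#' @param seed Optional integer seed.
#' @return A single character string of A/C/G/T.
#' @export
sim_genome_seq <- function(length_bp, at = 0.75, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- c(A = at / 2, C = (1 - at) / 2, G = (1 - at) / 2, T = at / 2)
  paste(sample(names(p), length_bp, replace = TRUE, prob = p), collapse = "")
}

#' Simulate uniform-coverage sequencing reads from a (circular) genome
#'
#' Read start positions are uniform on the molecule; on a circular genome
#' reads may span the origin. Sequencing error is an independent per-base
#' substitution to a random different base. Half of the reads are drawn
#' from the reverse strand.
#'
#' @param genome Genome sequence (character string), length > `read_len`.
#' @param read_len Read length in bp (default 150).
#' @param coverage Target fold coverage (> 0).
#' @param error_rate Per-base substitution error probability.
#' @param circular If `FALSE`, no read spans the sequence ends.
#' @param seed Optional integer seed.
#' @return A named character vector of read sequences.
#' @export
sim_reads <- function(genome, read_len = 150L, coverage = 50,
                      error_rate = 0, circular = TRUE, seed = NULL) {
  L <- nchar(genome)
  if (L <= read_len) stop("genome length must exceed read_len")
  if (coverage <= 0) stop("coverage must be > 0")
  if (!is.null(seed)) set.seed(seed)
  n <- max(1L, round(L * coverage / read_len))
  starts <- if (circular) sample.int(L, n, replace = TRUE)
            else sample.int(L - read_len + 1L, n, replace = TRUE)
  doubled <- if (circular) paste0(genome, genome) else genome
  reads <- substring(doubled, starts, starts + read_len - 1L)
  rev <- stats::runif(n) < 0.5
  if (any(rev)) reads[rev] <- .revcomp_chr(reads[rev])
  if (error_rate > 0) {
    m <- matrix(unlist(strsplit(reads, "")), nrow = read_len)
    err <- which(stats::runif(length(m)) < error_rate)
    if (length(err)) {
      bases <- c("A", "C", "G", "T")
      m[err] <- vapply(m[err], function(b)
        sample(setdiff(bases, b), 1), character(1))
      reads <- apply(m, 2, paste, collapse = "")
    }
  }
  stats::setNames(reads, sprintf("read%06d", seq_len(n)))
}

.revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Write / read reads as FASTQ
#'
#' @param reads Named character vector of read sequences.
#' @param path FASTQ file path.
#' @return `read_fastq` returns a named character vector of sequences.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads)
  q <- Biostrings::BStringSet(vapply(Biostrings::width(x), function(w)
    paste(rep("I", w), collapse = ""), character(1)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  stats::setNames(as.character(x), names(x))
}

#' Write / read contigs as FASTA
#'
#' @param contigs Named character vector of sequences.
#' @param path FASTA file path.
#' @export
write_fasta <- function(contigs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(contigs), path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}
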
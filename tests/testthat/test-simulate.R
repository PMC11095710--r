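test_that("birth-death trees are ultrametric, reproducible, and match the Yule height expectation", {
  tr <- sim_bd_tree(2, 0.5, 0, seed = 1)
  expect_equal(length(tr$tip.label), 2)
  d <- ape::node.depth.edgelength(tr)
  expect_equal(d[1], d[2])

  expect_identical(write_newick(sim_bd_tree(40, 0.2, 0.05, seed = 9)),
                   write_newick(sim_bd_tree(40, 0.2, 0.05, seed = 9)))
  expect_error(sim_bd_tree(10, 0.1, 0.2), "exceed")

  # crown height under pure birth: E = sum_{k=2..n} 1/(b k)
  b <- 0.1; n <- 200
  set.seed(42)
  reps <- 500
  h <- replicate(reps, {
    t <- sim_bd_tree(n, b, 0)
    max(ape::node.depth.edgelength(t))
  })
  expected <- sum(1 / (b * (2:n)))
  se <- stats::sd(h) / sqrt(reps)
  expect_lt(abs(mean(h) - expected), 3 * se)
})

test_that("binary trait simulation is exact and its truth is consistent", {
  tr <- sim_bd_tree(30, 0.2, 0, seed = 3)
  s0 <- sim_binary_trait(tr, 0, 0, root_state = 0, seed = 1)
  expect_true(all(s0$trait == 0))
  expect_equal(s0$n01 + s0$n10, 0)
  expect_error(sim_binary_trait(tr, 0, 0), "root state")

  # irreversible: no 1->0 jump in any painting
  s1 <- sim_binary_trait(tr, 0.2, 0, root_state = 0, seed = 2)
  expect_equal(s1$n10, 0)
  expect_true(all(unlist(lapply(s1$paintings, function(p)
    if (length(p$states)) p$states == 1L else TRUE))))

  # transition counts consistent with paintings and Poisson expectation
  set.seed(7)
  tr2 <- sim_bd_tree(200, 0.1, 0, seed = 5)
  total_len <- sum(tr2$edge.length)
  q <- 0.05
  reps <- 200
  counts <- replicate(reps, {
    s <- sim_binary_trait(tr2, q, q, root_state = 0)
    s$n01 + s$n10
  })
  expected <- q * total_len   # per-rate jump intensity along the whole tree
  se <- stats::sd(counts) / sqrt(reps)
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("painted branch lengths scale exactly with the multiplier", {
  tr <- sim_bd_tree(20, 0.2, 0, seed = 13)
  s <- sim_binary_trait(tr, 0.1, 0.1, root_state = 0, seed = 4)
  t1 <- sim_branch_lengths(tr, s, base_rate = 0.01, multiplier = 1, sigma = 0)
  expect_equal(t1$edge.length, 0.01 * tr$edge.length)

  # all-fragmented history: every branch exactly multiplier times larger
  sf <- sim_binary_trait(tr, 0, 0, root_state = 1, seed = 1)
  a <- sim_branch_lengths(tr, sf, base_rate = 0.01, multiplier = 1, sigma = 0)
  b <- sim_branch_lengths(tr, sf, base_rate = 0.01, multiplier = 3, sigma = 0)
  expect_equal(b$edge.length, 3 * a$edge.length)
  expect_error(sim_branch_lengths(tr, s, multiplier = 0), "> 0")
})

test_that("gene-order evolution conserves gene content and event rates", {
  tr <- sim_bd_tree(12, 0.2, 0, seed = 21)
  anc <- mito_gene_order()
  g0 <- sim_gene_orders(tr, anc, rearr_rate = 0, fission_rate = 0, seed = 1)
  for (cs in chromosome_sets(g0$table))
    expect_identical(cs$chromosomes[[1]]$genes, anc)

  g <- sim_gene_orders(tr, anc, rearr_rate = 0.05, fission_rate = 0.02, seed = 2)
  for (cs in chromosome_sets(g$table))
    expect_setequal(unlist(lapply(cs$chromosomes, `[[`, "genes")), anc)

  # realized event counts match the Poisson intensity per branch
  set.seed(9)
  tr3 <- sim_bd_tree(10, 0.2, 0, seed = 31)
  rate <- 0.06
  reps <- 500
  tot <- replicate(reps, sum(sim_gene_orders(tr3, anc, rearr_rate = rate,
                                             fission_rate = 0)$edge_events))
  expected <- rate * sum(tr3$edge.length)
  se <- stats::sd(tot) / sqrt(reps)
  expect_lt(abs(mean(tot) - expected), 3 * se)
})

test_that("fission partitions a circle into two circles", {
  tr2 <- ape::read.tree(text = "(A:10,B:10);")
  anc6 <- paste0("g", 1:6)
  found <- FALSE
  for (seed in 1:50) {
    g <- sim_gene_orders(tr2, anc6, rearr_rate = 0, fission_rate = 0.02,
                         seed = seed)
    for (cs in chromosome_sets(g$table)) {
      if (length(cs$chromosomes) == 2) {
        found <- TRUE
        expect_true(all(vapply(cs$chromosomes, `[[`, logical(1), "circular")))
        expect_setequal(unlist(lapply(cs$chromosomes, `[[`, "genes")), anc6)
      }
    }
    if (found) break
  }
  expect_true(found)
})

test_that("simulated reads behave like uniform circular coverage", {
  g <- sim_genome_seq(5000, seed = 8)
  reads <- sim_reads(g, read_len = 150, coverage = 50, error_rate = 0, seed = 3)
  expect_equal(length(reads), 1667, tolerance = 0.1)
  # every error-free read is a substring of the doubled genome (either strand)
  doubled <- paste0(g, g)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(doubled)))
  hits <- vapply(reads[1:200], function(r)
    grepl(r, doubled, fixed = TRUE) || grepl(r, rc, fixed = TRUE), logical(1))
  expect_true(all(hits))

  # linear mode: no read spans the ends
  rl <- sim_reads(g, coverage = 20, circular = FALSE, seed = 4)
  expect_true(all(vapply(rl, function(r)
    grepl(r, g, fixed = TRUE) ||
      grepl(r, as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(g))), fixed = TRUE), logical(1))))
  expect_error(sim_reads(g, coverage = 0), "coverage")

  # fastq round trip
  f <- tempfile(fileext = ".fastq")
  write_fastq(reads[1:10], f)
  expect_identical(unname(read_fastq(f)), unname(reads[1:10]))
})
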
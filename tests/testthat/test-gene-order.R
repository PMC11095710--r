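cs_from_rows <- function(rows) chromosome_sets(read_genome_table(write_gt(rows)))

test_that("adjacency sets follow the circular/linear conventions", {
  css <- cs_from_rows(c("S1\tchr1\tcox1+ trnY+ nad2+\tTRUE\t4000",
                        "S2\tchr1\tcox1+ trnY+ nad2+\tFALSE\t4000"))
  expect_equal(adjacencies(css$S1),
               c("cox1|nad2", "cox1|trnY", "nad2|trnY"))
  expect_equal(adjacencies(css$S2), c("cox1|trnY", "nad2|trnY"))

  # rotation and strand-flip invariance, unsigned and oriented
  rot <- cs_from_rows("S1\tchr1\tnad2+ cox1+ trnY+\tTRUE\t4000")
  flip <- cs_from_rows("S1\tchr1\tnad2- trnY- cox1-\tTRUE\t4000")
  for (o in c(FALSE, TRUE)) {
    expect_identical(adjacencies(rot$S1, o), adjacencies(css$S1, o))
    expect_identical(adjacencies(flip$S1, o), adjacencies(css$S1, o))
  }
  # orientation-aware boundaries distinguish inverted genes
  inv <- cs_from_rows("S1\tchr1\tcox1+ trnY- nad2+\tTRUE\t4000")
  expect_false(identical(adjacencies(inv$S1, TRUE), adjacencies(css$S1, TRUE)))
  expect_identical(adjacencies(inv$S1), adjacencies(css$S1))
})

test_that("ancestral adjacency reconstruction matches Fitch logic on small cases", {
  tr3 <- read_newick(text = "((A:1,B:1):1,C:2);")
  rows <- c("A\tchr1\tg1+ g2+ g3+ g4+\tTRUE\t4000",
            "B\tchr1\tg1+ g2+ g3+ g4+\tTRUE\t4000",
            "C\tchr1\tg1+ g2+ g3+ g4+\tTRUE\t4000")
  css <- cs_from_rows(rows)
  rec <- reconstruct_ancestral_adjacencies(tr3, css)
  expect_identical(rec$node_adjacencies[[4]], adjacencies(css$A))

  # adjacency in 2 of 3 ingroup tips plus the outgroup: present at ancestor
  tr4 <- read_newick(text = "(((A:1,B:1):1,C:2):1,O:3);")
  css4 <- cs_from_rows(c("A\tchr1\tg1+ g2+ g3+ g4+\tTRUE\t4000",
                         "B\tchr1\tg1+ g2+ g3+ g4+\tTRUE\t4000",
                         "C\tchr1\tg2+ g1+ g3+ g4+\tTRUE\t4000",
                         "O\tchr1\tg1+ g2+ g3+ g4+\tTRUE\t4000"))
  rec4 <- reconstruct_ancestral_adjacencies(tr4, css4)
  ing_anc <- rec4$node_adjacencies[[6]]   # ancestor of (A,B,C)
  expect_true("g1|g2" %in% ing_anc)
})

test_that("ancestral adjacencies equal the exhaustive minimum-change oracle", {
  set.seed(41)
  genes <- paste0("g", 1:6)
  for (rep in 1:8) {
    tr <- sim_bd_tree(sample(4:6, 1), 0.2, 0)
    go <- sim_gene_orders(tr, genes, rearr_rate = 0.04, fission_rate = 0.01)
    css <- chromosome_sets(go$table)
    rec <- reconstruct_ancestral_adjacencies(tr, css)
    orc <- oracle_ancestral_adjacencies(tr, css)
    nt <- length(tr$tip.label)
    for (v in seq_len(tr$Nnode))
      expect_identical(rec$node_adjacencies[[nt + v]], orc[[v]])
  }
})

test_that("rearrangement scores follow the shared-boundary definition", {
  anc_genes <- paste0("g", 1:36)
  rows <- paste0("T1\tchr1\t", paste0(anc_genes, "+", collapse = " "),
                 "\tTRUE\t15000")
  css <- cs_from_rows(rows)
  anc <- adjacencies(css$T1)
  sc <- rearrangement_score(css$T1, anc)
  expect_equal(sc$B, 36)
  expect_equal(sc$score, 1.0)
  # half the boundaries shared
  expect_equal(rearrangement_score(css$T1, anc[1:18])$score, 0.5)

  # fission at two boundaries removes exactly 2 and adds 2 new ones
  tr2 <- ape::read.tree(text = "(A:10,B:10);")
  go <- NULL
  for (seed in 1:80) {
    g <- sim_gene_orders(tr2, anc_genes, rearr_rate = 0, fission_rate = 0.01,
                         seed = seed)
    ev <- tapply(g$edge_events, g$tree$edge[, 2], sum)
    css2 <- chromosome_sets(g$table)
    nchrom <- vapply(css2, function(c) length(c$chromosomes), integer(1))
    one_fission <- which(nchrom == 2 &
                           vapply(names(nchrom), function(n)
                             sum(g$edge_events[g$tree$edge[, 2] ==
                                 match(n, g$tree$tip.label)]) == 1, logical(1)))
    if (length(one_fission)) { go <- g; tip <- names(one_fission)[1]; break }
  }
  expect_false(is.null(go))
  cs_tip <- chromosome_sets(go$table)[[tip]]
  b_shared <- length(intersect(adjacencies(cs_tip), anc))
  expect_equal(b_shared, 34)   # 36 - 2 boundaries broken by one fission
  expect_equal(rearrangement_score(cs_tip, anc)$score, 34 / 36)

  expect_error(rearrangement_score(structure(list(sample = "x", G = 0),
                                             class = "chromosome_set"), anc),
               "no annotated genes")
})

test_that("fragmented lineages score as more rearranged under elevated event rates", {
  # irreversible fragmentation histories (the regime the trait models assume)
  # with a 5x event multiplier: the fragmented member should carry the lower
  # shared-boundary score in at least 80% of informative pairs
  set.seed(55)
  wins <- 0; informative <- 0
  for (rep in 1:100) {
    tr <- sim_bd_tree(40, 0.12, 0)
    s <- sim_binary_trait(tr, 0.02, 0, root_state = 0)
    if (length(unique(s$trait)) < 2) next
    go <- sim_gene_orders(tr, mito_gene_order(), rearr_rate = 0.01,
                          fission_rate = 0.004, frag_multiplier = 5, sim = s)
    css <- chromosome_sets(go$table)
    gc <- vapply(css, `[[`, numeric(1), "G")
    pp <- suppressWarnings(select_pairs(tr, s$trait, "rearrangement", gc))
    if (nrow(pp) == 0) next
    rec <- reconstruct_ancestral_adjacencies(tr, css)
    res <- rearrangement_contrast(pp, rec, css)
    informative <- informative + sum(res$winner != "tie")
    wins <- wins + sum(res$winner == "fragmented")
  }
  expect_gt(informative, 50)
  expect_gte(wins / informative, 0.8)
})
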
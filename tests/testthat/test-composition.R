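test_that("fourfold-site classifier matches the genetic code exactly", {
  # glycine family: third positions fourfold
  cl <- classify_fourfold_sites("GGAGGTGGCGGG")
  expect_true(all(cl$fourfold[cl$codon_pos == 3]))
  expect_false(any(cl$fourfold[cl$codon_pos != 3]))
  # AGN is a serine family under the invertebrate mitochondrial code
  expect_true(classify_fourfold_sites("AGAGGA")$fourfold[3])
  # ... but not under the standard code (AGA = stop-adjacent Arg family split)
  expect_false(classify_fourfold_sites("AGAGGA", code = "1")$fourfold[3])
  # ATA (Met) vs ATT/ATC (Ile): not fourfold
  expect_false(classify_fourfold_sites("ATAGGA")$fourfold[3])
  expect_error(classify_fourfold_sites("TAAGGA"), "stop codon at codon 1")
  expect_error(classify_fourfold_sites("GGAA"), "divisible")

  # exhaustive 64-codon oracle via an independent translation implementation
  skip_if_not_installed("seqinr")
  for (code in c("5", "1")) {
    numcode <- as.integer(code)
    codons <- apply(expand.grid(B1 = c("A", "C", "G", "T"),
                                B2 = c("A", "C", "G", "T"),
                                B3 = c("A", "C", "G", "T")), 1,
                    function(r) paste(r, collapse = ""))
    for (cd in codons) {
      fam <- vapply(c("A", "C", "G", "T"), function(b)
        seqinr::translate(strsplit(paste0(substr(cd, 1, 2), b), "")[[1]],
                          numcode = numcode), character(1))
      want <- length(unique(fam)) == 1 && fam[1] != "*"
      got <- tryCatch(classify_fourfold_sites(paste0(cd, "GGA"),
                                              code = code)$fourfold[3],
                      error = function(e) NA)   # internal stop codons
      if (!is.na(got)) expect_equal(got, want, info = paste(code, cd))
    }
  }
})

test_that("AT content follows its definition and handles ambiguity codes", {
  expect_equal(at_content("ATAT"), 100)
  expect_equal(at_content("GCGC"), 0)
  expect_equal(at_content("ATGC"), 50)
  expect_equal(at_content("ATNNGC"), 50)   # N excluded from both sides
  expect_error(at_content("NNN"), "unambiguous")
})

test_that("composition tables are exact on a constructed two-gene genome", {
  # gene1 on +: TTA TTT (Leu Phe), gene2 on -: revcomp(GGA CCA) at 13..24
  g1 <- "TTATTT"
  g2rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString("GGACCA")))
  contig <- paste0(g1, "CGCGCG", g2rc)
  ann <- data.frame(sample = "S1", contig = "c1", gene = c("nad2", "cox1"),
                    start = c(1, 13), end = c(6, 18),
                    strand = c("+", "-"), stringsAsFactors = FALSE)
  ct <- composition_table(c(c1 = contig), ann)
  p <- ct$partitions
  expect_equal(p$all_sites, at_content(contig))
  # coding = TTATTT + GGACCA
  coding <- paste0("TTATTT", "GGACCA")
  expect_equal(p$coding, at_content(coding))
  expect_equal(p$pos1, at_content(c("T", "T", "G", "C")))
  expect_equal(p$pos3, at_content(c("A", "T", "A", "A")))
  # per-gene values; strand flip leaves AT% unchanged
  expect_equal(ct$per_gene$at[ct$per_gene$gene == "cox1"], at_content("GGACCA"))
  expect_equal(at_content("GGACCA"), at_content(g2rc))

  # coding AT% is the length-weighted mean of per-gene AT% (exact nesting)
  lens <- c(6, 6)
  expect_equal(p$coding, sum(ct$per_gene$at * lens) / sum(lens))

  ann_bad <- ann; ann_bad$end[1] <- 5
  expect_error(composition_table(c(c1 = contig), ann_bad), "nad2")
})

test_that("fourfold AT exceeds overall third-position AT on suitable synthetic genomes", {
  # codons: fourfold families get AT-rich third positions, two-fold families
  # GC third positions, so the fourfold partition must be more AT-rich
  set.seed(90)
  ff <- c("GG", "GC", "CG", "GT", "CC")   # fourfold contexts under code 5
  tf <- c("TT", "CA", "AA")               # families that are not fourfold
  codons <- c(paste0(sample(ff, 60, TRUE), sample(c("A", "T"), 60, TRUE)),
              paste0(sample(tf, 40, TRUE), sample(c("G", "A"), 40, TRUE)))
  cds <- paste(sample(codons), collapse = "")
  cl <- classify_fourfold_sites(cds)
  bases <- strsplit(cds, "")[[1]]
  expect_gt(at_content(bases[cl$fourfold]),
            at_content(bases[cl$codon_pos == 3]) - 1e-9)
})

test_that("phylogenetic ANOVA is calibrated and detects planted shifts", {
  set.seed(33)
  tr <- sim_bd_tree(60, 0.1, 0, seed = 91)
  V <- ape::vcv(tr)
  U <- chol(V)
  g <- stats::setNames(sample(rep(0:1, 30)), tr$tip.label)

  # no effect, phylogenetic trait: p should not be extreme-small typically
  y0 <- stats::setNames(as.vector(t(U) %*% rnorm(60)), rownames(V))
  pa0 <- phyl_anova(tr, g, y0, n_sim = 300, seed = 1)
  expect_true(pa0$p > 0 && pa0$p <= 1)

  # exactly equal group means: F_obs = 0, so p = 1
  yeq <- rnorm(60, 0, 1e-3)
  yeq <- yeq - ave(yeq, g[tr$tip.label])   # center within groups
  yeq <- stats::setNames(yeq + 1, tr$tip.label)
  pa1 <- phyl_anova(tr, g, yeq, n_sim = 200, seed = 2)
  expect_equal(pa1$p, 1)

  # planted 2 SD shift: detected
  y2 <- y0 + 2 * stats::sd(y0) * g[names(y0)]
  pa2 <- phyl_anova(tr, g, y2, n_sim = 300, seed = 3)
  expect_lt(pa2$p, 0.05)

  expect_error(phyl_anova(tr, g, stats::setNames(rep(1, 60), tr$tip.label)),
               "zero variance")
})

test_that("PGLS matches GLS theory and recovers simulated slopes", {
  set.seed(44)
  # star tree: Brownian PGLS equals ordinary least squares
  star <- ape::stree(10, "star")
  star$edge.length <- rep(1, 10)
  x <- stats::setNames(rnorm(10), star$tip.label)
  y <- stats::setNames(2 * x + rnorm(10, 0, 0.3), star$tip.label)
  pf <- pgls_fit(star, x, y, "Brownian")
  ols <- stats::lm(y ~ x)
  expect_equal(pf$slope, unname(coef(ols)[2]), tolerance = 1e-10)
  expect_equal(pf$intercept, unname(coef(ols)[1]), tolerance = 1e-10)

  # agreement with an independent GLS implementation under Brownian V
  skip_if_not_installed("nlme")
  tr <- sim_bd_tree(40, 0.1, 0, seed = 92)
  V <- ape::vcv(tr); U <- chol(V)
  xb <- stats::setNames(as.vector(t(U) %*% rnorm(40)), rownames(V))
  yb <- stats::setNames(2 * xb[tr$tip.label] +
                          as.vector(t(U) %*% rnorm(40))[match(tr$tip.label, rownames(V))] * 0.5,
                        tr$tip.label)
  pfb <- pgls_fit(tr, xb, yb, "Brownian")
  d <- data.frame(x = xb[tr$tip.label], y = yb[tr$tip.label])
  rownames(d) <- tr$tip.label
  gf <- suppressWarnings(nlme::gls(y ~ x, data = d,
                  correlation = ape::corBrownian(1, tr, form = ~1),
                  method = "ML"))
  expect_equal(pfb$slope, unname(coef(gf)[2]), tolerance = 1e-6)
  expect_equal(pfb$logL, as.numeric(stats::logLik(gf)), tolerance = 1e-6)

  # Pagel lambda: 0 for white-noise residuals, near 1 for Brownian residuals
  yw <- stats::setNames(2 * xb[tr$tip.label] + rnorm(40, 0, 0.5), tr$tip.label)
  expect_lte(pgls_fit(tr, xb, yw, "Pagel")$lambda, 0.1)
  expect_gte(pgls_fit(tr, xb, yb, "Pagel")$lambda, 0.5)
  expect_error(pgls_fit(tr, xb[1:3], yb, "Brownian"), "named over all tips")
})

test_that("per-gene rank-sum wrapper adjusts p-values", {
  per_gene <- data.frame(
    sample = rep(paste0("s", 1:8), 2),
    gene = rep(c("cox1", "atp8"), each = 8),
    at = c(rnorm(8, 60, 1), rnorm(8, 75, 1)))
  out <- gene_at_comparisons(per_gene)
  expect_equal(nrow(out), 1)
  expect_lt(out$p, 0.01)
  expect_gte(out$p_adj, out$p)
})
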
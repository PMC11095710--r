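#' Classify codon sites of an in-frame coding sequence
#'
#' Third codon positions are fourfold degenerate when all four completions
#' of the codon's first two bases encode the same amino acid under the
#' genetic code in force (default: NCBI translation table 5, invertebrate
#' mitochondrial). Positions 1 and 2 are never fourfold.
#'
#' @param cds In-frame coding sequence (character string), length divisible
#'   by 3, no internal stop codons.
#' @param code NCBI genetic code id (default `"5"`); passed to
#'   [Biostrings::getGeneticCode()].
#' @return A `data.frame` with one row per site: `pos` (1-based),
#'   `codon_pos` (1/2/3), `fourfold` (logical).
#' @export
classify_fourfold_sites <- function(cds, code = "5") {
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n %% 3 != 0) stop("sequence length not divisible by 3")
  gc <- Biostrings::getGeneticCode(code)
  codons <- substring(cds, seq(1, n, 3), seq(3, n, 3))
  aa <- gc[codons]
  internal_stops <- which(aa == "*" & seq_along(codons) < length(codons))
  if (length(internal_stops))
    stop("internal stop codon at codon ", internal_stops[1])
  ff_family <- .fourfold_families(gc)
  fourfold3 <- substr(codons, 1, 2) %in% ff_family & !is.na(aa)
  data.frame(pos = seq_len(n),
             codon_pos = rep(1:3, length.out = n),
             fourfold = as.vector(rbind(FALSE, FALSE, fourfold3)))
}

# the set of first-two-base contexts whose four completions share one aa
.fourfold_families <- function(gc) {
  ctx <- unique(substr(names(gc), 1, 2))
  ctx[vapply(ctx, function(p) {
    aas <- gc[paste0(p, c("A", "C", "G", "T"))]
    !anyNA(aas) && length(unique(aas)) == 1 && aas[1] != "*"
  }, logical(1))]
}

#' AT content of a sequence
#'
#' `100 * (A + T) / (A + C + G + T)`; ambiguity codes are excluded from
#' both numerator and denominator.
#'
#' @param seq Sequence as a character string or character vector of bases.
#' @return AT percentage in `[0, 100]`.
#' @export
at_content <- function(seq) {
  b <- if (length(seq) == 1L && nchar(seq[1]) > 1L)
    strsplit(toupper(seq), "")[[1]] else toupper(seq)
  n_at <- sum(b %in% c("A", "T"))
  n_tot <- sum(b %in% c("A", "C", "G", "T"))
  if (n_tot == 0) stop("no unambiguous bases")
  100 * n_at / n_tot
}

#' Partitioned AT-content table for annotated mitogenomes
#'
#' For each sample, computes the AT percentage of six partitions: all
#' sites, concatenated protein-coding sequence, codon positions 1-3, and
#' fourfold degenerate sites, plus per-gene AT content. Minus-strand genes
#' are reverse-complemented before framing.
#'
#' @param contigs Named character vector of contig sequences (or FASTA
#'   path); names are `<sample>` ids or arbitrary when `annotations$contig`
#'   gives the mapping.
#' @param annotations `data.frame` with columns `sample`, `contig`, `gene`,
#'   `start`, `end`, `strand` (1-based inclusive coordinates; strand `"+"`
#'   or `"-"`).
#' @param code Genetic code id (default `"5"`).
#' @return A list: `partitions` (`data.frame`, one row per sample with
#'   columns `all_sites`, `coding`, `pos1`, `pos2`, `pos3`, `fourfold`) and
#'   `per_gene` (long `data.frame`: `sample`, `gene`, `at`).
#' @export
composition_table <- function(contigs, annotations, code = "5") {
  if (is.character(contigs) && length(contigs) == 1 && file.exists(contigs))
    contigs <- read_fasta(contigs)
  samples <- unique(annotations$sample)
  part <- list(); pg <- list()
  for (s in samples) {
    ann <- annotations[annotations$sample == s, , drop = FALSE]
    seqs <- contigs[unique(ann$contig)]
    if (anyNA(names(seqs)) || any(!nzchar(names(seqs))))
      stop("annotation references missing contig for sample ", s)
    all_sites <- at_content(paste(seqs, collapse = ""))
    cds_all <- character(0)
    for (i in seq_len(nrow(ann))) {
      g <- substr(contigs[[ann$contig[i]]], ann$start[i], ann$end[i])
      if (ann$strand[i] == "-") g <- .revcomp_chr(g)
      if (nchar(g) %% 3 != 0)
        stop("gene ", ann$gene[i], " in sample ", s, " is out of frame")
      cds_all <- c(cds_all, g)
      pg[[length(pg) + 1]] <- data.frame(sample = s, gene = ann$gene[i],
                                         at = at_content(g),
                                         stringsAsFactors = FALSE)
    }
    coding <- paste(cds_all, collapse = "")
    cl <- classify_fourfold_sites(coding, code)
    bases <- strsplit(coding, "")[[1]]
    part[[length(part) + 1]] <- data.frame(
      sample = s,
      all_sites = all_sites,
      coding = at_content(bases),
      pos1 = at_content(bases[cl$codon_pos == 1]),
      pos2 = at_content(bases[cl$codon_pos == 2]),
      pos3 = at_content(bases[cl$codon_pos == 3]),
      fourfold = if (any(cl$fourfold)) at_content(bases[cl$fourfold]) else NA_real_,
      stringsAsFactors = FALSE)
  }
  list(partitions = do.call(rbind, part), per_gene = do.call(rbind, pg))
}

#' Phylogenetic ANOVA by Brownian simulation
#'
#' Classical one-way F statistic for a two-group comparison, with the null
#' distribution obtained by simulating Brownian traits on the tree (rate
#' estimated from the data by the mean squared phylogenetically independent
#' contrast) while holding group labels fixed. The p-value is the
#' upper-tail fraction with add-one smoothing.
#'
#' @param tree `"phylo"`.
#' @param groups Named 0/1 vector over tips.
#' @param values Named numeric vector over tips.
#' @param n_sim Number of Brownian null simulations (default 1000).
#' @param seed Optional integer seed.
#' @return A list of class `"phyl_anova"`: `F_obs`, `p`, `n_sim`,
#'   `F_null`.
#' @export
phyl_anova <- function(tree, groups, values, n_sim = 1000, seed = NULL) {
  g <- match_trait(tree, groups)
  v <- values[tree$tip.label]
  if (anyNA(v)) stop("values missing for some tips")
  if (stats::var(v) == 0) stop("zero variance in values")
  if (length(unique(g)) < 2) stop("both groups must be non-empty")
  if (!is.null(seed)) set.seed(seed)
  F_obs <- .anova_f(v, g)
  rtree <- if (ape::is.binary.phylo(tree)) tree else ape::multi2di(tree)
  sig2 <- mean(ape::pic(v, rtree)^2)
  Z <- .bm_tips(rtree, n_sim) * sqrt(sig2)
  g_ord <- g[rownames(ape::vcv(rtree))]
  F_null <- apply(Z, 2, .anova_f, g = g_ord)
  structure(list(F_obs = F_obs, F_null = F_null,
                 p = (1 + sum(F_null >= F_obs)) / (1 + n_sim),
                 n_sim = n_sim),
            class = "phyl_anova")
}

#' @export
print.phyl_anova <- function(x, ...) {
  cat(sprintf("phylogenetic ANOVA: F = %.4f, p = %.4g (%d Brownian sims)\n",
              x$F_obs, x$p, x$n_sim))
  invisible(x)
}

.anova_f <- function(v, g) {
  n <- length(v)
  m <- tapply(v, g, mean)
  nk <- tapply(v, g, length)
  ssb <- sum(nk * (m - mean(v))^2)
  ssw <- sum((v - m[as.character(g)])^2)
  k <- length(m)
  (ssb / (k - 1)) / (ssw / (n - k))
}

#' Phylogenetic generalized least squares regression
#'
#' GLS fit of `y ~ x` with residual covariance from shared branch lengths.
#' Under `correlation = "Brownian"` the covariance is the tree variance-
#' covariance matrix; under `"Pagel"` the off-diagonal entries are scaled
#' by lambda, estimated by profile maximum likelihood on `[0, 1]`.
#'
#' @param tree `"phylo"`.
#' @param x,y Named numeric vectors over tips.
#' @param correlation `"Brownian"` or `"Pagel"`.
#' @param lambda Fix lambda instead of estimating it (Pagel mode).
#' @return A list of class `"pgls_fit"`: `intercept`, `slope`, `lambda`,
#'   `logL`, `se_slope`, `t_slope`, `p_slope`, `df_residual`.
#' @export
pgls_fit <- function(tree, x, y, correlation = c("Brownian", "Pagel"),
                     lambda = NULL) {
  correlation <- match.arg(correlation)
  tips <- tree$tip.label
  if (!all(tips %in% names(x)) || !all(tips %in% names(y)))
    stop("x and y must be named over all tips")
  x <- x[tips]; y <- y[tips]
  if (length(tips) < 4) stop("need >= 4 tips")
  V0 <- ape::vcv(tree)
  lam_v <- function(lam) {
    V <- V0 * lam
    diag(V) <- diag(V0)
    V
  }
  fit_at <- function(V) {
    n <- length(y)
    X <- cbind(1, x)
    ch <- chol(V)
    Xs <- backsolve(ch, X, transpose = TRUE)
    ys <- backsolve(ch, y, transpose = TRUE)
    qr_ <- qr(Xs)
    beta <- qr.coef(qr_, ys)
    if (anyNA(beta)) stop("singular design")
    res <- ys - Xs %*% beta
    sig2 <- sum(res^2) / n                        # ML variance
    logL <- -0.5 * (n * log(2 * pi * sig2) + 2 * sum(log(diag(ch))) + n)
    XtX_inv <- chol2inv(qr.R(qr_))
    se <- sqrt(diag(XtX_inv) * sum(res^2) / (n - 2))
    list(beta = beta, logL = logL, se = se, n = n)
  }
  if (correlation == "Brownian") {
    lam_hat <- 1
    f <- fit_at(V0)
  } else if (!is.null(lambda)) {
    lam_hat <- lambda
    f <- fit_at(lam_v(lambda))
  } else {
    prof <- function(l) fit_at(lam_v(l))$logL
    opt <- stats::optimize(prof, c(0, 1), maximum = TRUE, tol = 1e-6)
    lam_hat <- opt$maximum
    for (b in c(0, 1)) if (prof(b) > opt$objective + 1e-9) lam_hat <- b
    f <- fit_at(lam_v(lam_hat))
  }
  t_slope <- f$beta[2] / f$se[2]
  structure(list(intercept = unname(f$beta[1]), slope = unname(f$beta[2]),
                 lambda = lam_hat, logL = f$logL,
                 se_slope = unname(f$se[2]), t_slope = unname(t_slope),
                 p_slope = 2 * stats::pt(-abs(t_slope), f$n - 2),
                 df_residual = f$n - 2,
                 correlation = correlation),
            class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf("PGLS (%s%s): y = %.4g + %.4g x; slope p = %.4g, logL = %.4f\n",
              x$correlation,
              if (x$correlation == "Pagel") sprintf(", lambda = %.3f", x$lambda) else "",
              x$intercept, x$slope, x$p_slope, x$logL))
  invisible(x)
}

#' Pairwise rank-sum comparison of per-gene AT content
#'
#' Convenience wrapper: Wilcoxon rank-sum tests between genes on the long
#' per-gene AT table, with Holm adjustment.
#'
#' @param per_gene `data.frame` with columns `sample`, `gene`, `at` (from
#'   [composition_table()]).
#' @return A `data.frame`: `gene1`, `gene2`, `p`, `p_adj`.
#' @export
gene_at_comparisons <- function(per_gene) {
  genes <- sort(unique(per_gene$gene))
  rows <- list()
  for (i in seq_along(genes)) for (j in seq_along(genes)) {
    if (j <= i) next
    a <- per_gene$at[per_gene$gene == genes[i]]
    b <- per_gene$at[per_gene$gene == genes[j]]
    p <- suppressWarnings(stats::wilcox.test(a, b)$p.value)
    rows[[length(rows) + 1]] <- data.frame(gene1 = genes[i], gene2 = genes[j],
                                           p = p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, "holm")
  out
}
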
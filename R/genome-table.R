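#' Read a mitogenome structure table
#'
#' The table is a headered TSV with one chromosome (fragment) per row and
#' columns `sample`, `chromosome`, `genes`, `circular`, `length_bp`.
#' `genes` is a space-separated list of oriented gene tokens, e.g.
#' `"cox1+ trnY+ nad2-"`; `circular` is `TRUE`/`FALSE`. This mirrors the
#' spreadsheet convention of one fragment per line.
#'
#' @param path TSV file path.
#' @return A `data.frame` of class `"genome_table"` with the columns above.
#' @export
read_genome_table <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                         stringsAsFactors = FALSE)
  validate_genome_table(d)
}

#' @rdname read_genome_table
#' @param tbl A genome table `data.frame`.
#' @export
write_genome_table <- function(tbl, path) {
  utils::write.table(tbl, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_genome_table <- function(d) {
  need <- c("sample", "chromosome", "genes", "circular", "length_bp")
  if (!all(need %in% names(d)))
    stop("genome table must have columns: ", paste(need, collapse = ", "))
  d$circular <- as.logical(d$circular)
  for (s in unique(d$sample)) {
    rows <- d[d$sample == s, , drop = FALSE]
    toks <- unlist(lapply(rows$genes, parse_gene_tokens))
    if (length(toks) == 0) stop("sample ", s, " has an empty gene list")
    gn <- names(toks)
    if (anyDuplicated(gn))
      stop("sample ", s, " has duplicated gene(s): ",
           paste(unique(gn[duplicated(gn)]), collapse = ", "))
  }
  class(d) <- c("genome_table", "data.frame")
  d
}

# "cox1+ trnY+ nad2-" -> named integer strand vector c(cox1=1, trnY=1, nad2=-1)
parse_gene_tokens <- function(s) {
  if (is.na(s) || !nzchar(trimws(s))) stop("empty gene list")
  toks <- strsplit(trimws(s), "[[:space:]]+")[[1]]
  toks <- toks[nzchar(toks)]
  if (length(toks) == 0) stop("empty gene list")
  strand <- ifelse(grepl("-$", toks), -1L,
            ifelse(grepl("\\+$", toks), 1L, 1L))
  gene <- sub("[+-]$", "", toks)
  if (any(!nzchar(gene))) stop("malformed gene token in: ", s)
  stats::setNames(strand, gene)
}

format_gene_tokens <- function(genes, strands) {
  paste0(genes, ifelse(strands < 0, "-", "+"), collapse = " ")
}

#' Convert a genome table into per-sample chromosome sets
#'
#' @param tbl A `genome_table` (see [read_genome_table()]).
#' @return A named list of `chromosome_set` objects; each holds the sample
#'   id, a list of chromosomes (ordered `genes`, `strands`, `circular`
#'   flag, `length_bp`), and the total annotated gene count `G`.
#' @export
chromosome_sets <- function(tbl) {
  tbl <- validate_genome_table(as.data.frame(tbl))
  out <- lapply(split(tbl, tbl$sample), function(rows) {
    chroms <- lapply(seq_len(nrow(rows)), function(i) {
      toks <- parse_gene_tokens(rows$genes[i])
      list(genes = names(toks), strands = unname(toks),
           circular = as.logical(rows$circular[i]),
           length_bp = rows$length_bp[i], id = rows$chromosome[i])
    })
    structure(list(sample = rows$sample[1], chromosomes = chroms,
                   G = sum(lengths(lapply(chroms, `[[`, "genes")))),
              class = "chromosome_set")
  })
  out[unique(tbl$sample)]
}

#' @export
print.chromosome_set <- function(x, ...) {
  cat("chromosome_set:", x$sample, "-", length(x$chromosomes),
      "chromosome(s),", x$G, "genes\n")
  for (ch in x$chromosomes)
    cat("  ", ch$id, if (ch$circular) "(circular)" else "(linear)", ":",
        format_gene_tokens(ch$genes, ch$strands), "\n")
  invisible(x)
}

# build a one-sample chromosome_set from a list of chromosomes
as_chromosome_set <- function(sample, chromosomes) {
  for (i in seq_along(chromosomes)) {
    ch <- chromosomes[[i]]
    if (is.null(ch$strands)) ch$strands <- rep(1L, length(ch$genes))
    if (is.null(ch$circular)) ch$circular <- TRUE
    if (is.null(ch$id)) ch$id <- paste0("chr", i)
    if (is.null(ch$length_bp)) ch$length_bp <- NA_integer_
    chromosomes[[i]] <- ch
  }
  genes <- unlist(lapply(chromosomes, `[[`, "genes"))
  if (anyDuplicated(genes))
    stop("duplicated gene(s) within sample ", sample, ": ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  structure(list(sample = sample, chromosomes = chromosomes, G = length(genes)),
            class = "chromosome_set")
}

# chromosome_set list -> genome_table data.frame
as_genome_table <- function(css) {
  rows <- do.call(rbind, lapply(css, function(cs) {
    do.call(rbind, lapply(cs$chromosomes, function(ch) {
      data.frame(sample = cs$sample, chromosome = ch$id,
                 genes = format_gene_tokens(ch$genes, ch$strands),
                 circular = ch$circular,
                 length_bp = if (is.null(ch$length_bp)) NA else ch$length_bp,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(rows) <- NULL
  class(rows) <- c("genome_table", "data.frame")
  rows
}
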
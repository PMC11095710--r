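#' Find a matching end k-mer on a contig
#'
#' Searches for the longest exact match between a prefix and a suffix of
#' the contig, for k from `k_max` down to `k_min`. Such a match suggests
#' the assembler duplicated the junction of a circular molecule; splicing
#' then trims one copy.
#'
#' @param contig Sequence (character string), length > `2 * k_max`.
#' @param k_max Maximum k-mer length (default 40).
#' @param k_min Minimum k-mer length considered evidence (default 10).
#' @return The matched k (integer), or `0L` when no prefix/suffix match of
#'   length >= `k_min` exists.
#' @export
find_end_junction <- function(contig, k_max = 40L, k_min = 10L) {
  L <- nchar(contig)
  if (L <= 2 * k_max) stop("contig shorter than 2 * k_max")
  for (k in seq(k_max, k_min)) {
    if (substr(contig, 1L, k) == substr(contig, L - k + 1L, L)) return(k)
  }
  0L
}

#' Read-connectivity profile across a spliced contig junction
#'
#' Implements the splice-and-remap circularity check: the contig (after
#' trimming a matched end k-mer, if any) is rotated by half its length so
#' that its original 3' and 5' ends become adjacent in the middle of the
#' spliced sequence. Reads are aligned to the spliced sequence (ungapped,
#' both strands, at least `min_identity` matching bases, seeded on an exact
#' `tb_width`-bp read prefix). The connectivity at position p is the number
#' of aligned reads covering p with at least `flank` aligned bases on each
#' side, so connectivity across the splice point measures direct read
#' support for the end-to-end adjacency.
#'
#' @param contig Sequence (character string).
#' @param reads Named character vector of uniform-length reads, or a FASTQ
#'   path.
#' @param junction_k End k-mer length to trim before splicing (e.g. from
#'   [find_end_junction()]); 0 means no trimming.
#' @param min_identity Minimum fraction of matching bases per read.
#' @param flank Minimum aligned bases required on each side of a position
#'   (default 20).
#' @param tb_width Exact-match seed width at the read 5' end.
#' @return An object of class `"connectivity_profile"`: `connectivity` and
#'   `coverage` (per-position integer vectors over the spliced sequence),
#'   `splice_point` (position after which the original ends meet),
#'   `window` (indices of splice +/- read length), `median_coverage`
#'   (whole-contig), `read_len`, `n_mapped`.
#' @export
connectivity_profile <- function(contig, reads, junction_k = 0L,
                                 min_identity = 0.95, flank = 20L,
                                 tb_width = 25L) {
  if (is.character(reads) && length(reads) == 1 && file.exists(reads))
    reads <- read_fastq(reads)
  if (length(reads) == 0) stop("no reads supplied")
  rl <- unique(nchar(reads))
  if (length(rl) != 1) stop("reads must have uniform length")
  L0 <- nchar(contig)
  if (L0 <= 2 * rl) stop("contig must be longer than twice the read length")
  circ <- if (junction_k > 0) substr(contig, 1L, L0 - junction_k) else contig
  L <- nchar(circ)
  mid <- L %/% 2L
  spliced <- paste0(substr(circ, mid + 1L, L), substr(circ, 1L, mid))
  splice_point <- L - mid   # ends meet between positions splice_point, +1
  max_mm <- floor((1 - min_identity) * rl)
  subj <- Biostrings::DNAString(spliced)
  dcov <- numeric(L + 1L); dcon <- numeric(L + 1L)
  n_mapped <- 0L
  for (strand in 1:2) {
    rset <- Biostrings::DNAStringSet(reads)
    if (strand == 2) rset <- Biostrings::reverseComplement(rset)
    pd <- Biostrings::PDict(rset, tb.start = 1L, tb.width = tb_width)
    hits <- Biostrings::matchPDict(pd, subj, max.mismatch = max_mm)
    st <- Biostrings::startIndex(hits)
    for (s in st) {
      if (is.null(s) || length(s) == 0) next
      s <- s[1]
      n_mapped <- n_mapped + 1L
      e <- s + rl - 1L
      dcov[s] <- dcov[s] + 1; dcov[e + 1L] <- dcov[e + 1L] - 1
      cs <- s + flank; ce <- e - flank
      if (cs <= ce) { dcon[cs] <- dcon[cs] + 1; dcon[ce + 1L] <- dcon[ce + 1L] - 1 }
    }
  }
  if (n_mapped == 0) stop("no coverage: no reads align to the spliced contig")
  coverage <- cumsum(dcov)[seq_len(L)]
  connectivity <- cumsum(dcon)[seq_len(L)]
  window <- max(1L, splice_point - rl):min(L, splice_point + rl)
  structure(list(connectivity = connectivity, coverage = coverage,
                 splice_point = splice_point, window = window,
                 median_coverage = stats::median(coverage),
                 read_len = rl, n_mapped = n_mapped,
                 spliced = spliced),
            class = "connectivity_profile")
}

#' @export
print.connectivity_profile <- function(x, ...) {
  w20 <- max(1L, x$splice_point - 20L):min(length(x$connectivity),
                                           x$splice_point + 20L)
  cat(sprintf(paste0("connectivity profile: splice at %d, %d reads mapped, ",
                     "median coverage %g\n  min connectivity (splice +/- 20 bp): %g\n"),
              x$splice_point, x$n_mapped, x$median_coverage,
              min(x$connectivity[w20])))
  invisible(x)
}

#' Call contig circularity from a connectivity profile
#'
#' A contig is called circular when the minimum connectivity within
#' `splice +/- 20` bp is at least `min_ratio` times the median whole-contig
#' coverage.
#'
#' @param profile A `"connectivity_profile"`.
#' @param min_ratio Fraction of median coverage required (default 0.25).
#' @return A list: `circular` (logical), `reason`, `min_connectivity`,
#'   `threshold`.
#' @export
call_circular <- function(profile, min_ratio = 0.25) {
  w <- max(1L, profile$splice_point - 20L):
       min(length(profile$connectivity), profile$splice_point + 20L)
  mc <- min(profile$connectivity[w])
  thr <- min_ratio * profile$median_coverage
  if (mc >= thr && mc > 0)
    list(circular = TRUE,
         reason = sprintf("junction connectivity %g >= %.3g (%.2f x median coverage)",
                          mc, thr, min_ratio),
         min_connectivity = mc, threshold = thr)
  else
    list(circular = FALSE,
         reason = if (mc == 0) "no spanning support at the splice point"
                  else sprintf("junction connectivity %g below %.3g", mc, thr),
         min_connectivity = mc, threshold = thr)
}

#' Scan for mononucleotide repeats
#'
#' Maximal single-base runs of at least `min_len` bp, reported with
#' 1-based start coordinates.
#'
#' @param contig Sequence (character string).
#' @param min_len Minimum run length (default 18).
#' @return A `data.frame`: `start`, `base`, `length`.
#' @export
scan_mononucleotide_repeats <- function(contig, min_len = 18L) {
  r <- rle(strsplit(contig, "")[[1]])
  ends <- cumsum(r$lengths)
  keep <- r$lengths >= min_len
  data.frame(start = (ends - r$lengths + 1L)[keep],
             base = r$values[keep],
             length = r$lengths[keep],
             stringsAsFactors = FALSE)
}

#' Find long exact segments shared between contigs
#'
#' Reports maximal exact substrings strictly longer than `min_len` shared
#' between distinct contigs (k-mer anchoring on diagonals with
#' `k = min_len + 1`, so any shared segment longer than `min_len` is
#' found). Matches on either strand of the second contig are reported.
#'
#' @param contigs Named character vector of sequences (>= 2), or FASTA
#'   path.
#' @param min_len Segments must be strictly longer than this (default 150,
#'   one read length).
#' @return A `data.frame`: `contig1`, `contig2`, `start1`, `start2`,
#'   `length`, `strand2`.
#' @export
find_shared_segments <- function(contigs, min_len = 150L) {
  if (is.character(contigs) && length(contigs) == 1 && file.exists(contigs))
    contigs <- read_fasta(contigs)
  if (length(contigs) < 2) stop("need at least two contigs")
  k <- min_len + 1L
  out <- list()
  nm <- names(contigs)
  for (i in seq_along(contigs)) for (j in seq_along(contigs)) {
    if (j <= i) next
    for (strand in c("+", "-")) {
      b <- if (strand == "+") contigs[[j]] else .revcomp_chr(contigs[[j]])
      seg <- .diagonal_segments(contigs[[i]], b, k)
      if (nrow(seg) == 0) next
      if (strand == "-")   # map back to forward coordinates of contig j
        seg$start2 <- nchar(b) - (seg$start2 + seg$length - 1L) + 1L
      out[[length(out) + 1]] <- data.frame(
        contig1 = nm[i], contig2 = nm[j],
        start1 = seg$start1, start2 = seg$start2,
        length = seg$length, strand2 = strand, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(contig1 = character(0), contig2 = character(0),
                      start1 = integer(0), start2 = integer(0),
                      length = integer(0), strand2 = character(0)))
  do.call(rbind, out)
}

# maximal runs of matching k-mers on diagonals between sequences a and b
.diagonal_segments <- function(a, b, k) {
  la <- nchar(a); lb <- nchar(b)
  if (la < k || lb < k)
    return(data.frame(start1 = integer(0), start2 = integer(0),
                      length = integer(0)))
  ka <- substring(a, seq_len(la - k + 1L), seq_len(la - k + 1L) + k - 1L)
  kb <- substring(b, seq_len(lb - k + 1L), seq_len(lb - k + 1L) + k - 1L)
  ia <- split(seq_along(ka), ka)
  hit_b <- which(kb %in% names(ia))
  if (length(hit_b) == 0)
    return(data.frame(start1 = integer(0), start2 = integer(0),
                      length = integer(0)))
  pa <- integer(0); pb <- integer(0)
  for (p in hit_b) {
    q <- ia[[kb[p]]]
    pa <- c(pa, q); pb <- c(pb, rep(p, length(q)))
  }
  diag <- pa - pb
  ord <- order(diag, pb)
  pa <- pa[ord]; pb <- pb[ord]; diag <- diag[ord]
  new_run <- c(TRUE, diff(pb) != 1L | diff(diag) != 0L)
  run_id <- cumsum(new_run)
  starts <- which(new_run)
  lens <- tabulate(run_id)
  data.frame(start1 = pa[starts], start2 = pb[starts],
             length = lens + k - 1L)
}
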
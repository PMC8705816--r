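# Shared seed-and-extend local alignment machinery used by the ANI,
# protospacer and intergenomic-distance stages. Sequences are handled as
# plain character strings; hot loops work on raw vectors.

VALID_DNA <- c("A", "C", "G", "T", "N")

#' Reverse complement of a DNA string
#'
#' @param seq DNA string over A/C/G/T/N.
#' @return The reverse complement as a character string.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Assert a sequence is uppercase DNA over {A,C,G,T,N}; ambiguity codes other
# than N are rejected so downstream identity arithmetic stays unambiguous.
check_dna <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) || !nzchar(seq))
    stop(what, " must be a non-empty DNA string", call. = FALSE)
  bad <- gsub("[ACGTN]", "", seq)
  if (nzchar(bad))
    stop(what, " contains invalid characters: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ","), call. = FALSE)
  invisible(seq)
}

# All k-mer start positions in `seq`, as a list kmer -> integer positions.
kmer_index <- function(seq, k) {
  n <- nchar(seq) - k + 1L
  if (n < 1L) return(list())
  kms <- substring(seq, seq_len(n), seq_len(n) + k - 1L)
  keep <- !grepl("N", kms, fixed = TRUE)
  split(seq_len(n)[keep], kms[keep])
}

# Exact k-mer seed matches of query against a prebuilt subject index.
# Returns data.frame(q, s) of 1-based start positions.
seed_matches <- function(query, index, k, max_per_kmer = 500L) {
  n <- nchar(query) - k + 1L
  if (n < 1L || length(index) == 0L)
    return(data.frame(q = integer(), s = integer()))
  kms <- substring(query, seq_len(n), seq_len(n) + k - 1L)
  hit <- index[kms]
  len <- lengths(hit)
  len[is.na(names(hit))] <- 0L
  use <- len > 0L & len <= max_per_kmer
  if (!any(use)) return(data.frame(q = integer(), s = integer()))
  data.frame(q = rep.int(seq_len(n)[use], len[use]),
             s = unlist(hit[use], use.names = FALSE))
}

# Disjoint maximal-scoring segments of a score vector (recursive best-segment
# extraction). Returns data.frame(start, end, score) in 1-based coordinates
# relative to `sc`.
maximal_segments <- function(sc, min_score) {
  out <- list()
  stack <- list(c(1L, length(sc)))
  while (length(stack)) {
    rng <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    lo <- rng[1]; hi <- rng[2]
    if (hi < lo) next
    v <- sc[lo:hi]
    cs <- cumsum(v)
    pre <- c(0, cs[-length(cs)])
    cmin <- cummin(pre)
    f <- cs - cmin
    i <- which.max(f)
    if (f[i] < min_score) next
    j <- max(which(pre[seq_len(i)] == cmin[i]))
    out[[length(out) + 1L]] <- c(lo + j - 1L, lo + i - 1L, f[i])
    stack[[length(stack) + 1L]] <- c(lo, lo + j - 2L)
    stack[[length(stack) + 1L]] <- c(lo + i, hi)
  }
  if (!length(out))
    return(data.frame(start = integer(), end = integer(), score = numeric()))
  m <- do.call(rbind, out)
  data.frame(start = as.integer(m[, 1]), end = as.integer(m[, 2]),
             score = m[, 3])
}

# Ungapped HSPs of `a` against one strand of `b` by per-diagonal scanning of
# exact seed matches. Coordinates are on the forward orientation of the
# strings as passed in.
diagonal_hsps <- function(a, b, k = 11L, match = 2, mismatch = -3,
                          min_score = 20, pad = 2000L, index = NULL) {
  ar <- charToRaw(a); br <- charToRaw(b)
  la <- length(ar); lb <- length(br)
  if (is.null(index)) index <- kmer_index(b, k)
  seeds <- seed_matches(a, index, k)
  empty <- data.frame(qstart = integer(), qend = integer(),
                      sstart = integer(), send = integer(),
                      length = integer(), idents = integer(), score = numeric())
  if (!nrow(seeds)) return(empty)
  rawN <- charToRaw("N")
  d <- seeds$s - seeds$q
  res <- list()
  for (dd in unique(d)) {
    qs <- seeds$q[d == dd]
    q0 <- max(1L, 1L - dd, min(qs) - pad)
    q1 <- min(la, lb - dd, max(qs) + 10L + pad)
    if (q1 < q0) next
    aslice <- ar[q0:q1]
    bslice <- br[(q0 + dd):(q1 + dd)]
    eq <- (aslice == bslice) & aslice != rawN
    segs <- maximal_segments(ifelse(eq, match, mismatch), min_score)
    if (!nrow(segs)) next
    segs$idents <- vapply(seq_len(nrow(segs)), function(i)
      sum(eq[segs$start[i]:segs$end[i]]), integer(1))
    res[[length(res) + 1L]] <- data.frame(
      qstart = q0 + segs$start - 1L, qend = q0 + segs$end - 1L,
      sstart = q0 + dd + segs$start - 1L, send = q0 + dd + segs$end - 1L,
      length = segs$end - segs$start + 1L, idents = segs$idents,
      score = segs$score)
  }
  if (!length(res)) return(empty)
  do.call(rbind, res)
}

# Both-strand HSP scan; minus-strand subject coordinates are mapped back to
# the forward strand of b. Greedy non-overlap selection (highest score first,
# reject any HSP overlapping an accepted one on either sequence).
hsp_scan <- function(a, b, k = 11L, match = 2, mismatch = -3,
                     min_score = 20, pad = 2000L) {
  fw <- diagonal_hsps(a, b, k, match, mismatch, min_score, pad)
  if (nrow(fw)) fw$strand <- "+"
  brc <- revcomp(b)
  rv <- diagonal_hsps(a, brc, k, match, mismatch, min_score, pad)
  if (nrow(rv)) {
    lb <- nchar(b)
    s0 <- lb - rv$send + 1L
    rv$send <- lb - rv$sstart + 1L
    rv$sstart <- s0
    rv$strand <- "-"
  }
  hsps <- rbind(fw, rv)
  if (!nrow(hsps)) return(hsps)
  hsps <- hsps[order(-hsps$score, hsps$qstart, hsps$sstart), , drop = FALSE]
  keep <- logical(nrow(hsps))
  q_acc <- s_acc <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(nrow(hsps))) {
    qi <- c(hsps$qstart[i], hsps$qend[i])
    si <- c(hsps$sstart[i], hsps$send[i])
    ovl <- function(acc, iv) nrow(acc) > 0 &&
      any(acc[, 1] <= iv[2] & acc[, 2] >= iv[1])
    if (!ovl(q_acc, qi) && !ovl(s_acc, si)) {
      keep[i] <- TRUE
      q_acc <- rbind(q_acc, qi)
      s_acc <- rbind(s_acc, si)
    }
  }
  out <- hsps[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Affine-gap local alignment of DNA strings (match +2, mismatch -3,
# gap open 5, gap extend 2 as costs). Identity is identical columns over all
# alignment columns, gaps included.
local_align_nt <- function(a, b, match = 2, mismatch = -3,
                           gap_open = 5, gap_extend = 2) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "local",
    substitutionMatrix = mat, gapOpening = gap_open, gapExtension = gap_extend)
  pr <- as.data.frame(Biostrings::pattern(aln)@range)
  sr <- as.data.frame(Biostrings::subject(aln)@range)
  alen <- nchar(as.character(Biostrings::alignedPattern(aln)))
  nid <- Biostrings::nmatch(aln)
  list(score = Biostrings::score(aln), alen = alen, nid = nid,
       identity = if (alen > 0) nid / alen else 0,
       qstart = pr$start, qend = pr$end, sstart = sr$start, send = sr$end)
}

# BLOSUM62 local alignment of protein strings (gap open 11, extend 1).
local_align_aa <- function(a, b, gap_open = 11, gap_extend = 1) {
  blosum <- get_blosum62()
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = blosum, gapOpening = gap_open,
    gapExtension = gap_extend)
  alen <- nchar(as.character(Biostrings::alignedPattern(aln)))
  nid <- Biostrings::nmatch(aln)
  list(score = Biostrings::score(aln), alen = alen, nid = nid,
       identity = if (alen > 0) nid / alen else 0)
}

.pkg_cache <- new.env(parent = emptyenv())

get_blosum62 <- function() {
  if (is.null(.pkg_cache$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pkg_cache$BLOSUM62 <- e$BLOSUM62
  }
  .pkg_cache$BLOSUM62
}

# Karlin-Altschul statistics. Raw scores are converted to bit scores
# S' = (lambda * S - ln K) / ln 2 and E = m * n * 2^-S'.

#' Bit score and E-value for protein local alignment scores
#'
#' Uses ungapped BLOSUM62 Karlin-Altschul parameters lambda = 0.267,
#' K = 0.041. `m` is the query length and `n` the effective database length
#' (sum of subject lengths).
#'
#' @param score raw alignment score.
#' @param m,n query and database lengths in residues.
#' @return A list with `bits` and `evalue`.
#' @export
evalue_protein <- function(score, m, n) {
  bits <- (0.267 * score - log(0.041)) / log(2)
  list(bits = bits, evalue = m * n * 2^(-bits))
}

#' Bit score and E-value for nucleotide local alignment scores
#'
#' Uses ungapped nucleotide Karlin-Altschul parameters lambda = 0.625,
#' K = 0.41.
#'
#' @inheritParams evalue_protein
#' @return A list with `bits` and `evalue`.
#' @export
evalue_nucleotide <- function(score, m, n) {
  bits <- (0.625 * score - log(0.41)) / log(2)
  list(bits = bits, evalue = m * n * 2^(-bits))
}
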
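# Fragment-based average nucleotide identity (ANIb convention: 1020 bp
# fragments, 30% identity / 70% coverage acceptance) and single-linkage
# clustering at a 0.9 cut-off.

# Candidate subject window for a query fragment from exact 11-mer seeds:
# the modal diagonal band, padded. A band supported by fewer than 4 seeds
# is rejected: a fragment that can be accepted at all retains dozens of
# exact 11-mers, while chance seeds between unrelated sequences rarely
# co-occur on one band.
ani_window <- function(seeds, flen, slen, pad = 600L, min_band = 4L) {
  d <- seeds$s - seeds$q
  d0 <- as.integer(names(which.max(table(d))))
  band <- abs(d - d0) <= 200L
  if (sum(band) < min_band) return(NULL)
  lo <- max(1L, d0 + 1L - pad)
  hi <- min(slen, d0 + flen + pad)
  c(lo, hi)
}

align_fragment <- function(frag, subject, index, k = 11L) {
  # Best local alignment of a fragment against one strand of the subject;
  # exact containment is short-circuited (via the k-mer index when one is
  # available), otherwise seeds locate a banded window. Returns NULL when
  # no seed anchors the fragment.
  flen <- nchar(frag)
  slen <- nchar(subject)
  if (is.null(index)) {
    if (regexpr(frag, subject, fixed = TRUE) > 0L)
      return(list(score = 2 * flen, identity = 1, span = flen, alen = flen))
    al <- local_align_nt(frag, subject)
    return(list(score = al$score, identity = al$identity,
                span = al$qend - al$qstart + 1L, alen = al$alen))
  }
  if (flen >= k) {
    for (p in index[[substr(frag, 1L, k)]])
      if (p + flen - 1L <= slen &&
          substring(subject, p, p + flen - 1L) == frag)
        return(list(score = 2 * flen, identity = 1, span = flen,
                    alen = flen))
  }
  seeds <- seed_matches(frag, index, k)
  if (!nrow(seeds)) return(NULL)
  w <- ani_window(seeds, flen, slen)
  if (is.null(w)) return(NULL)
  al <- local_align_nt(frag, substring(subject, w[1], w[2]))
  list(score = al$score, identity = al$identity,
       span = al$qend - al$qstart + 1L, alen = al$alen)
}

#' Fragment-based average nucleotide identity between two sequences
#'
#' The query `a` is chopped into consecutive `fragment_len`-bp pieces (one
#' whole-sequence fragment when shorter). Each fragment is locally aligned
#' (match +2, mismatch -3, gap open 5, gap extend 2) against `b` on both
#' strands; a fragment is accepted when its alignment identity (identical
#' columns over all alignment columns) is at least `min_identity` and its
#' aligned span covers at least `min_cov` of the fragment. ANI is the mean
#' identity over accepted fragments; coverage is the accepted aligned
#' query length over `nchar(a)`. With no accepted fragments both are 0.
#'
#' @param a,b DNA strings.
#' @param fragment_len fragment size in bp (default 1020).
#' @param min_identity fragment acceptance identity (default 0.3).
#' @param min_cov fragment acceptance span fraction (default 0.7).
#' @return List with `ani`, `coverage`, `n_fragments`, `n_accepted`.
#' @export
pairwise_ani <- function(a, b, fragment_len = 1020L, min_identity = 0.3,
                         min_cov = 0.7, .index = NULL) {
  check_dna(a, "query"); check_dna(b, "subject")
  la <- nchar(a)
  starts <- seq(1L, la, by = fragment_len)
  ends <- pmin(starts + fragment_len - 1L, la)
  frags <- substring(a, starts, ends)
  brc <- if (is.null(.index)) revcomp(b) else .index$rc
  idx_f <- if (!is.null(.index)) .index$fwd else
    if (nchar(b) > 5000L) kmer_index(b, 11L) else NULL
  idx_r <- if (!is.null(.index)) .index$rev else
    if (nchar(b) > 5000L) kmer_index(brc, 11L) else NULL
  idents <- spans <- numeric(0)
  for (fr in frags) {
    best <- NULL
    for (st in 1:2) {
      al <- align_fragment(fr, if (st == 1) b else brc,
                           if (st == 1) idx_f else idx_r)
      if (!is.null(al) && (is.null(best) || al$score > best$score))
        best <- al
    }
    if (is.null(best)) next
    if (best$identity >= min_identity && best$span >= min_cov * nchar(fr)) {
      idents <- c(idents, best$identity)
      spans <- c(spans, best$span)
    }
  }
  if (!length(idents))
    return(list(ani = 0, coverage = 0, n_fragments = length(frags),
                n_accepted = 0L))
  list(ani = mean(idents), coverage = sum(spans) / la,
       n_fragments = length(frags), n_accepted = length(idents))
}

#' Symmetric ANI matrix over prophage regions
#'
#' Entry (i, j) is the arithmetic mean of `pairwise_ani(i, j)` and
#' `pairwise_ani(j, i)`; the diagonal is 1. A companion coverage matrix is
#' symmetrised the same way.
#'
#' @param seqs named character vector (or list) of region sequences
#'   (>= 2).
#' @param ... passed to [pairwise_ani()].
#' @return List with `ani` and `coverage` matrices (region ids as
#'   dimnames).
#' @export
ani_matrix <- function(seqs, ...) {
  seqs <- unlist(seqs)
  n <- length(seqs)
  stopifnot(n >= 2L, !is.null(names(seqs)))
  ids <- names(seqs)
  A <- Cv <- matrix(0, n, n, dimnames = list(ids, ids))
  diag(A) <- 1; diag(Cv) <- 1
  idx <- lapply(seqs, function(s) {
    rc <- revcomp(s)
    big <- nchar(s) > 5000L
    list(rc = rc, fwd = if (big) kmer_index(s, 11L),
         rev = if (big) kmer_index(rc, 11L))
  })
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ij <- pairwise_ani(seqs[[i]], seqs[[j]], ..., .index = idx[[j]])
      ji <- pairwise_ani(seqs[[j]], seqs[[i]], ..., .index = idx[[i]])
      A[i, j] <- A[j, i] <- (ij$ani + ji$ani) / 2
      Cv[i, j] <- Cv[j, i] <- (ij$coverage + ji$coverage) / 2
    }
  }
  list(ani = A, coverage = Cv)
}

#' Cluster regions by ANI threshold
#'
#' Single-linkage clustering: connected components of the graph with an
#' edge wherever ANI >= `threshold`. Clusters are ordered by decreasing
#' size, ties by their lexicographically smallest member; members are
#' sorted within each cluster.
#'
#' @param mat symmetric ANI matrix (or the list from [ani_matrix()]).
#' @param threshold clustering cut-off (default 0.9).
#' @return List of character vectors of region ids.
#' @export
cluster_by_ani <- function(mat, threshold = 0.9) {
  if (is.list(mat) && !is.matrix(mat)) mat <- mat$ani
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat))
  ids <- rownames(mat)
  adj <- mat >= threshold
  diag(adj) <- TRUE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "max")
  comp <- igraph::components(g)$membership
  cl <- split(ids, comp)
  cl <- lapply(cl, sort)
  ord <- order(-lengths(cl), vapply(cl, `[`, "", 1L))
  unname(cl[ord])
}
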
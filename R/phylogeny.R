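# Genome-BLAST distance phylogeny: intergenomic distances from
# non-overlapping HSPs (formula variants d0/d4/d6), neighbor-joining trees
# with midpoint rooting, and link-fraction (OPTSIL-style) clustering.

#' GBDP distance formulas
#'
#' With sequence lengths `L1`, `L2`, total HSP alignment length `H` and
#' total identical columns `I`:
#' `d0 = 1 - 2H/(L1+L2)` (coverage), `d4 = 1 - I/H` (identity within
#' matches; 1 when `H = 0`) and `d6 = 1 - 2I/(L1+L2)` (combined). All are
#' clamped to `[0, 1]`.
#'
#' @param H total HSP alignment length.
#' @param I total identical columns.
#' @param L1,L2 sequence lengths.
#' @return List with `d0`, `d4`, `d6`.
#' @export
gbdp_formulas <- function(H, I, L1, L2) {
  clamp <- function(x) min(1, max(0, x))
  list(d0 = clamp(1 - 2 * H / (L1 + L2)),
       d4 = if (H == 0) 1 else clamp(1 - I / H),
       d6 = clamp(1 - 2 * I / (L1 + L2)))
}

#' Intergenomic GBDP distance between two sequences
#'
#' HSPs are found with the package's seed-and-extend nucleotide aligner on
#' both strands, greedily made non-overlapping on both sequences (highest
#' score first), filtered at `evalue_max`, and summarised through
#' [gbdp_formulas()]. Arguments are canonicalised internally (longer/
#' lexicographically smaller sequence first) so the distance is exactly
#' symmetric.
#'
#' @param a,b non-empty DNA strings.
#' @param k seed length (default 11).
#' @param evalue_max HSP significance cut-off (default 1e-3).
#' @return List with `d0`, `d4`, `d6`, `n_hsps`, `H` (total HSP length)
#'   and `I` (total identities).
#' @export
gbdp_distance <- function(a, b, k = 11L, evalue_max = 1e-3) {
  check_dna(a, "a"); check_dna(b, "b")
  if (nchar(b) > nchar(a) || (nchar(b) == nchar(a) && b < a)) {
    tmp <- a; a <- b; b <- tmp
  }
  L1 <- nchar(a); L2 <- nchar(b)
  # raw score needed for E <= evalue_max under the nucleotide
  # Karlin-Altschul parameters (lambda 0.625, K 0.41)
  bits_needed <- log2(as.numeric(L1) * L2 / evalue_max)
  min_score <- max(20, ceiling((bits_needed * log(2) + log(0.41)) / 0.625))
  hsps <- hsp_scan(a, b, k = k, min_score = min_score)
  H <- sum(hsps$length)
  I <- sum(hsps$idents)
  c(gbdp_formulas(H, I, L1, L2),
    list(n_hsps = nrow(hsps), H = H, I = I))
}

#' Pairwise GBDP distance matrices over a sequence set
#'
#' @param seqs named character vector of sequences (>= 2).
#' @param ... passed to [gbdp_distance()].
#' @return List of three symmetric matrices `d0`, `d4`, `d6` with zero
#'   diagonals.
#' @export
gbdp_matrix <- function(seqs, ...) {
  seqs <- unlist(seqs)
  n <- length(seqs)
  stopifnot(n >= 2L, !is.null(names(seqs)))
  ids <- names(seqs)
  out <- lapply(c(d0 = "d0", d4 = "d4", d6 = "d6"), function(f)
    matrix(0, n, n, dimnames = list(ids, ids)))
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n) {
      d <- gbdp_distance(seqs[[i]], seqs[[j]], ...)
      for (f in c("d0", "d4", "d6"))
        out[[f]][i, j] <- out[[f]][j, i] <- d[[f]]
    }
  out
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining agglomeration; negative branch lengths are
#' clamped to zero. NJ recovers any additive (tree-realisable) matrix
#' exactly, which is what makes it unit-testable here.
#'
#' @param mat symmetric distance matrix with zero diagonal, >= 3 taxa.
#' @return An [ape::phylo] tree.
#' @export
nj_tree <- function(mat) {
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat))
  if (nrow(mat) < 3L)
    stop("neighbor joining needs at least 3 taxa", call. = FALSE)
  if (max(abs(mat - t(mat))) > 1e-8 || any(diag(mat) != 0))
    stop("distance matrix must be symmetric with zero diagonal",
         call. = FALSE)
  tr <- ape::nj(stats::as.dist(mat))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Midpoint-root a tree
#'
#' Places the root at the midpoint of the longest leaf-to-leaf path.
#' Idempotent: rooting an already midpoint-rooted tree leaves it
#' unchanged (up to representation).
#'
#' @param tree an [ape::phylo] tree with >= 2 leaves.
#' @return A rooted [ape::phylo] tree.
#' @export
midpoint_root <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  phangorn::midpoint(tree)
}

#' Link-fraction clustering of a distance matrix
#'
#' Agglomerative merging in which two clusters fuse iff the fraction of
#' cross-pairs with distance <= `t` is at least `F`; among fusable pairs
#' the one with the smallest mean cross-distance is merged first (ties by
#' lexicographic pair order). With `F = 1` this is complete linkage at
#' `t`.
#'
#' @param mat symmetric distance matrix.
#' @param t distance threshold.
#' @param F fraction of links required for cluster fusion (0 < F <= 1;
#'   default 0.5).
#' @return Named integer membership vector.
#' @export
link_clusters <- function(mat, t, F = 0.5) {
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat), F > 0, F <= 1)
  ids <- rownames(mat)
  clusters <- as.list(seq_len(nrow(mat)))
  repeat {
    best <- NULL
    for (i in seq_along(clusters))
      for (j in seq_along(clusters)) {
        if (j <= i) next
        cross <- mat[clusters[[i]], clusters[[j]], drop = FALSE]
        frac <- mean(cross <= t)
        if (frac >= F) {
          m <- mean(cross)
          if (is.null(best) || m < best$m) best <- list(i = i, j = j, m = m)
        }
      }
    if (is.null(best)) break
    clusters[[best$i]] <- sort(c(clusters[[best$i]], clusters[[best$j]]))
    clusters[[best$j]] <- NULL
  }
  membership <- integer(nrow(mat))
  ord <- order(vapply(clusters, min, 0L))
  clusters <- clusters[ord]
  for (ci in seq_along(clusters)) membership[clusters[[ci]]] <- ci
  names(membership) <- ids
  membership
}
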
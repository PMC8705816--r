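# Protein similarity graph over prophage ORFs, Markov clustering (MCL,
# implemented from scratch on column-stochastic matrices), the binary
# gene-family presence/absence matrix, and the intersection with ANI
# clusters that picks out clusters of interest.

#' All-vs-all protein comparison
#'
#' Scores protein pairs with BLOSUM62 local alignment (gap open 11, extend
#' 1), converts raw scores to bit scores with ungapped Karlin-Altschul
#' parameters (lambda = 0.267, K = 0.041) and keeps an edge when
#' `E = m * n_db * 2^-S'` is at most `evalue_max`, with `m` the query
#' length and `n_db` the summed protein length of the dataset. Edge weight
#' is `-log10(E)`, capped at `weight_cap`.
#'
#' By default pairs sharing no exact amino-acid 5-mer are skipped (a word
#' heuristic: alignments strong enough to pass E <= 1e-5 carry runs of
#' identities that almost surely contain an exact 5-mer, while unrelated
#' proteins rarely share one). Set `prefilter = FALSE` to score every
#' pair. Alignments are batched per subject protein.
#'
#' @param orfs data.frame with `orf_id` and `protein` columns (>= 2 rows).
#' @param evalue_max edge significance cut-off (default 1e-5).
#' @param prefilter skip pairs without a shared 5-mer.
#' @param weight_cap maximum edge weight (default 200).
#' @return List of class `similarity_graph` with `nodes` (ids) and `edges`
#'   (data.frame: a, b, score, bits, evalue, weight).
#' @export
all_vs_all_protein <- function(orfs, evalue_max = 1e-5, prefilter = TRUE,
                               weight_cap = 200) {
  stopifnot(is.data.frame(orfs), nrow(orfs) >= 2L,
            all(c("orf_id", "protein") %in% names(orfs)))
  ids <- orfs$orf_id
  prot <- orfs$protein
  n_db <- sum(nchar(prot))
  pairs <- if (prefilter) {
    w <- 5L
    kms <- lapply(prot, function(p) {
      np <- nchar(p) - w + 1L
      if (np < 1L) return(character())
      unique(substring(p, seq_len(np), seq_len(np) + w - 1L))
    })
    kidx <- split(rep(seq_along(prot), lengths(kms)),
                  unlist(kms, use.names = FALSE))
    pl <- lapply(kidx, function(v) {
      if (length(v) < 2L || length(v) > 200L) return(NULL)
      t(utils::combn(v, 2L))
    })
    pm <- do.call(rbind, pl)
    if (is.null(pm)) matrix(integer(), ncol = 2) else unique(pm)
  } else {
    t(utils::combn(seq_along(prot), 2L))
  }
  rows <- list()
  if (nrow(pairs)) {
    blosum <- get_blosum62()
    for (j in sort(unique(pairs[, 2]))) {
      is <- sort(pairs[pairs[, 2] == j, 1])
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::AAStringSet(prot[is]), Biostrings::AAString(prot[j]),
        type = "local", substitutionMatrix = blosum, gapOpening = 11,
        gapExtension = 1)
      sc <- Biostrings::score(aln)
      ev <- evalue_protein(sc, nchar(prot[is]), n_db)
      keep <- ev$evalue <= evalue_max
      if (any(keep))
        rows[[length(rows) + 1L]] <- data.frame(
          a = ids[is[keep]], b = ids[j], score = sc[keep],
          bits = ev$bits[keep], evalue = ev$evalue[keep],
          weight = pmin(weight_cap, -log10(pmax(ev$evalue[keep], 1e-300))),
          stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(rows)) do.call(rbind, rows) else
    data.frame(a = character(), b = character(), score = numeric(),
               bits = numeric(), evalue = numeric(), weight = numeric(),
               stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  structure(list(nodes = ids, edges = edges), class = "similarity_graph")
}

#' Markov clustering of a weighted similarity graph
#'
#' From-scratch MCL: the weighted adjacency matrix plus self-loops is
#' column-normalised, then expansion (matrix self-product) and inflation
#' (entrywise power `inflation`, column renormalisation) alternate, with
#' entries below `prune` removed, until the largest entry change is below
#' `tol` or `max_iter` iterations. Clusters are the connected components
#' of the non-zero structure of the limit matrix. Node order never
#' affects the result.
#'
#' Self-loops are set to each node's maximum incident edge weight (1 for
#' isolated nodes), the usual damping that stops the walk on a
#' heavy-edged pair from oscillating with period 2; on unit-weight graphs
#' this reduces to unit self-loops.
#'
#' @param graph a `similarity_graph` (or a list with `nodes` and `edges`).
#' @param inflation inflation exponent (default 2).
#' @param prune entries below this are zeroed each iteration.
#' @param tol convergence tolerance on the max entry change.
#' @param max_iter iteration cap; non-convergence is flagged, not silent.
#' @return List with `clusters` (list of node-id vectors, largest first),
#'   `membership` (named integer vector), `converged`, `iterations`.
#' @export
mcl <- function(graph, inflation = 2.0, prune = 1e-6, tol = 1e-9,
                max_iter = 200L) {
  nodes <- sort(unique(graph$nodes))
  n <- length(nodes)
  if (n == 0L) stop("empty graph", call. = FALSE)
  M <- matrix(0, n, n, dimnames = list(nodes, nodes))
  e <- graph$edges
  if (!is.null(e) && nrow(e)) {
    ia <- match(e$a, nodes); ib <- match(e$b, nodes)
    for (r in seq_along(ia)) {
      M[ia[r], ib[r]] <- M[ia[r], ib[r]] + e$weight[r]
      M[ib[r], ia[r]] <- M[ib[r], ia[r]] + e$weight[r]
    }
  }
  loops <- apply(M, 2, max)
  diag(M) <- pmax(loops, 1)
  normalise <- function(X) {
    cs <- colSums(X)
    cs[cs == 0] <- 1
    sweep(X, 2L, cs, "/")
  }
  M <- normalise(M)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    M2 <- M %*% M            # expansion
    M2 <- M2^inflation       # inflation
    M2[M2 < prune] <- 0
    M2 <- normalise(M2)
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("MCL did not converge within ", max_iter, " iterations",
            call. = FALSE)
  g <- igraph::graph_from_adjacency_matrix(
    (M > 0) | (t(M) > 0), mode = "max")
  comp <- igraph::components(g)$membership
  cl <- split(nodes, comp)
  cl <- lapply(cl, sort)
  ord <- order(-lengths(cl), vapply(cl, `[`, "", 1L))
  cl <- unname(cl[ord])
  membership <- integer(n)
  names(membership) <- nodes
  for (i in seq_along(cl)) membership[cl[[i]]] <- i
  list(clusters = cl, membership = membership, converged = converged,
       iterations = iter)
}

#' Binary gene-family presence/absence matrix
#'
#' Rows are prophage (region) ids, columns are gene families; an entry is
#' 1 iff the prophage contributes at least one ORF to the family. Rows and
#' columns are sorted for deterministic output.
#'
#' @param orfs data.frame with `orf_id` and `region_id`.
#' @param membership named integer vector mapping `orf_id` to family index
#'   (from [mcl()]).
#' @return Binary integer matrix.
#' @export
presence_absence <- function(orfs, membership) {
  fam <- membership[orfs$orf_id]
  if (any(is.na(fam)))
    stop("ORFs without a family assignment: ",
         paste(utils::head(orfs$orf_id[is.na(fam)], 3L), collapse = ","),
         call. = FALSE)
  if (any(is.na(orfs$region_id) | !nzchar(orfs$region_id)))
    stop("orphan ORF without a region", call. = FALSE)
  regions <- sort(unique(orfs$region_id))
  fam_ids <- sort(unique(as.integer(fam)))
  m <- matrix(0L, length(regions), length(fam_ids),
              dimnames = list(regions, sprintf("F%04d", fam_ids)))
  m[cbind(match(orfs$region_id, regions), match(as.integer(fam), fam_ids))] <- 1L
  m
}

row_jaccard <- function(x, y) {
  u <- sum(x | y)
  if (u == 0) return(0)
  sum(x & y) / u
}

flank_signature <- function(genome, start, end, window = 2000L) {
  fx <- genome$features
  left <- fx$product[fx$end >= start - window & fx$end < start]
  right <- fx$product[fx$start > end & fx$start <= end + window]
  list(left = sort(left), right = sort(right))
}

#' Select clusters of interest from the ANI/gene-family intersection
#'
#' An ANI cluster is selected iff it (a) has at least two members, (b) has
#' mean pairwise row-Jaccard similarity over the presence/absence matrix
#' of at least `jaccard_min`, (c) contains at least one `likely_complete`
#' member, and (d) all members are at least `min_length` bp. The
#' `shared_integration` flag is set when two or more members have
#' identical flanking-feature products on both sides (2 kb window), in
#' either orientation.
#'
#' @param ani_clusters partition from [cluster_by_ani()].
#' @param pa presence/absence matrix from [presence_absence()].
#' @param regions region table from [detect_prophages()].
#' @param genomes named list of [genome_record] (for flank signatures);
#'   `NULL` disables the shared-integration check.
#' @param jaccard_min gene-sharing threshold (default 0.5).
#' @param min_length member length floor in bp (default 13000).
#' @return data.frame of selected clusters: `cluster_id`, `members`,
#'   `n_members`, `has_complete`, `shared_integration`, `mean_jaccard`,
#'   `rationale`.
#' @export
select_clusters <- function(ani_clusters, pa, regions, genomes = NULL,
                            jaccard_min = 0.5, min_length = 13000L) {
  rows <- list()
  for (ci in seq_along(ani_clusters)) {
    members <- ani_clusters[[ci]]
    if (length(members) < 2L) next
    reg <- regions[match(members, regions$name), , drop = FALSE]
    if (any(is.na(reg$name))) next
    if (any(reg$length < min_length)) next
    if (!any(reg$completeness == "likely_complete")) next
    pr <- utils::combn(members, 2L)
    jac <- vapply(seq_len(ncol(pr)), function(k) {
      a <- pr[1, k]; b <- pr[2, k]
      if (!a %in% rownames(pa) || !b %in% rownames(pa)) return(0)
      row_jaccard(pa[a, ] > 0, pa[b, ] > 0)
    }, 0)
    mj <- mean(jac)
    if (mj < jaccard_min) next
    shared <- FALSE
    if (!is.null(genomes)) {
      sigs <- lapply(seq_len(nrow(reg)), function(i) {
        g <- genomes[[reg$genome_id[i]]]
        if (is.null(g)) return(NULL)
        flank_signature(g, reg$start[i], reg$end[i])
      })
      ok <- !vapply(sigs, is.null, TRUE)
      sigs <- sigs[ok]
      if (length(sigs) >= 2L) {
        key <- vapply(sigs, function(s) {
          fwd <- paste(paste(s$left, collapse = ";"),
                       paste(s$right, collapse = ";"), sep = "|")
          rev <- paste(paste(s$right, collapse = ";"),
                       paste(s$left, collapse = ";"), sep = "|")
          min(fwd, rev)
        }, "")
        shared <- anyDuplicated(key) > 0L
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      cluster_id = ci, members = paste(members, collapse = ","),
      n_members = length(members),
      has_complete = TRUE, shared_integration = shared, mean_jaccard = mj,
      rationale = sprintf(
        "%d members, all >= %d bp, >=1 likely_complete, mean Jaccard %.2f%s",
        length(members), min_length, mj,
        if (shared) ", shared integration flanks" else ""),
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(cluster_id = integer(), members = character(),
                      n_members = integer(), has_complete = logical(),
                      shared_integration = logical(), mean_jaccard = numeric(),
                      rationale = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
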
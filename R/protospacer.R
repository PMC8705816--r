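# Spacer-to-prophage (protospacer) mapping: exact 11-mer seeds locate
# candidate loci, a gapped local alignment scores each locus, and hits are
# filtered at the significance cut-offs (E <= 0.01, identity >= 98%).

empty_hits <- function() {
  data.frame(spacer_id = character(), region = character(),
             sstart = integer(), send = integer(), strand = character(),
             identity = numeric(), alen = integer(), score = numeric(),
             evalue = numeric(), stringsAsFactors = FALSE)
}

# Cluster seed subject positions into loci (break when consecutive
# positions are more than one spacer length apart).
seed_loci <- function(spos, slen) {
  spos <- sort(unique(spos))
  run <- cumsum(c(TRUE, diff(spos) > slen + 20L))
  lapply(split(spos, run), range)
}

#' Map spacers onto prophage regions
#'
#' Seed-and-extend protospacer search: exact 11-bp seeds on both strands
#' locate candidate loci in each region; each locus is scored with an
#' affine-gap local alignment (match +2, mismatch -3, gap open 5, extend
#' 2). E-values use ungapped nucleotide Karlin-Altschul parameters
#' (lambda = 0.625, K = 0.41) with `m` the spacer length and `n` the
#' summed region length. Hits are kept when E <= `evalue_max` and
#' identity (identical columns over alignment columns, gaps included) >=
#' `identity_min`; the best hit per locus is reported.
#'
#' @param spacers data.frame with `spacer_id` and `sequence` (typically
#'   the representatives from [dedupe_spacers()]).
#' @param region_seqs named character vector of region sequences.
#' @param evalue_max significance cut-off (default 0.01).
#' @param identity_min identity cut-off (default 0.98).
#' @return data.frame with `spacer_id`, `region`, `sstart`, `send`
#'   (forward-strand region coordinates), `strand`, `identity`, `alen`,
#'   `score`, `evalue`.
#' @export
match_spacers <- function(spacers, region_seqs, evalue_max = 0.01,
                          identity_min = 0.98) {
  stopifnot(is.data.frame(spacers), nrow(spacers) >= 1L,
            length(region_seqs) >= 1L, !is.null(names(region_seqs)))
  n_total <- sum(nchar(region_seqs))
  rows <- list()
  for (ri in seq_along(region_seqs)) {
    rseq <- region_seqs[[ri]]
    rname <- names(region_seqs)[ri]
    rlen <- nchar(rseq)
    idx_f <- kmer_index(rseq, 11L)
    rrc <- revcomp(rseq)
    idx_r <- kmer_index(rrc, 11L)
    for (si in seq_len(nrow(spacers))) {
      sseq <- spacers$sequence[si]
      slen <- nchar(sseq)
      for (strand in c("+", "-")) {
        subj <- if (strand == "+") rseq else rrc
        idx <- if (strand == "+") idx_f else idx_r
        seeds <- seed_matches(sseq, idx, 11L)
        if (!nrow(seeds)) next
        for (locus in seed_loci(seeds$s, slen)) {
          w0 <- max(1L, locus[1] - slen - 10L)
          w1 <- min(nchar(subj), locus[2] + slen + 10L)
          al <- local_align_nt(sseq, substring(subj, w0, w1))
          ev <- evalue_nucleotide(al$score, slen, n_total)
          if (ev$evalue > evalue_max || al$identity < identity_min) next
          s0 <- w0 + al$sstart - 1L
          s1 <- w0 + al$send - 1L
          if (strand == "-") {
            tmp <- rlen - s1 + 1L
            s1 <- rlen - s0 + 1L
            s0 <- tmp
          }
          rows[[length(rows) + 1L]] <- data.frame(
            spacer_id = spacers$spacer_id[si], region = rname,
            sstart = s0, send = s1, strand = strand,
            identity = al$identity, alen = al$alen, score = al$score,
            evalue = ev$evalue, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) return(empty_hits())
  hits <- do.call(rbind, rows)
  # best hit per (spacer, region, locus): drop hits overlapping a kept,
  # higher-scoring hit of the same spacer in the same region
  hits <- hits[order(hits$spacer_id, hits$region, -hits$score,
                     hits$sstart), , drop = FALSE]
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    if (!keep[i]) next
    j <- which(keep & seq_len(nrow(hits)) > i &
                 hits$spacer_id == hits$spacer_id[i] &
                 hits$region == hits$region[i] &
                 hits$sstart <= hits$send[i] & hits$send >= hits$sstart[i])
    keep[j] <- FALSE
  }
  hits <- hits[keep, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Merge hits into unique targeted sequences
#'
#' Subject intervals are merged per region whenever they overlap by at
#' least 1 bp; the merged intervals are the operational "unique
#' sequences".
#'
#' @param hits data.frame from [match_spacers()].
#' @return List with `count` and `intervals` (data.frame: region, start,
#'   end, n_hits).
#' @export
unique_hit_sequences <- function(hits) {
  if (!nrow(hits))
    return(list(count = 0L,
                intervals = data.frame(region = character(),
                                       start = integer(), end = integer(),
                                       n_hits = integer())))
  out <- lapply(split(hits, hits$region), function(h) {
    ir <- IRanges::IRanges(start = h$sstart, end = h$send)
    red <- IRanges::reduce(ir)
    data.frame(region = h$region[1], start = IRanges::start(red),
               end = IRanges::end(red),
               n_hits = IRanges::countOverlaps(red, ir))
  })
  iv <- do.call(rbind, out)
  iv <- iv[order(iv$region, iv$start), , drop = FALSE]
  rownames(iv) <- NULL
  list(count = nrow(iv), intervals = iv)
}

#' Assign protospacer hits to targeted genes
#'
#' Each hit is assigned to the ORF with maximal overlap (ties to the
#' leftmost ORF); hits overlapping no ORF are reported as intergenic.
#' Genes are aggregated with supporting-hit and distinct-spacer counts.
#'
#' @param hits data.frame from [match_spacers()].
#' @param orfs data.frame from [find_orfs()] over the same regions; an
#'   optional `product` column is propagated.
#' @return data.frame with `region`, `orf_id`, `product`, `start`, `end`,
#'   `n_supporting_hits`, `n_distinct_spacers`.
#' @export
targeted_genes <- function(hits, orfs) {
  if (!nrow(hits))
    return(data.frame(region = character(), orf_id = character(),
                      product = character(), start = integer(),
                      end = integer(), n_supporting_hits = integer(),
                      n_distinct_spacers = integer(),
                      stringsAsFactors = FALSE))
  assigned <- character(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    ro <- orfs[orfs$region_id == hits$region[i], , drop = FALSE]
    if (!nrow(ro)) { assigned[i] <- "intergenic"; next }
    ov <- pmin(ro$end, hits$send[i]) - pmax(ro$start, hits$sstart[i]) + 1L
    ov[ov < 0L] <- 0L
    if (max(ov) == 0L) { assigned[i] <- "intergenic"; next }
    best <- which(ov == max(ov))
    best <- best[which.min(ro$start[best])]
    assigned[i] <- ro$orf_id[best]
  }
  hits$orf_id <- assigned
  agg <- lapply(split(hits, paste(hits$region, hits$orf_id, sep = "\r")),
                function(h) {
    oid <- h$orf_id[1]
    ro <- orfs[orfs$orf_id == oid, , drop = FALSE]
    data.frame(region = h$region[1], orf_id = oid,
               product = if (nrow(ro) && "product" %in% names(ro))
                 ro$product[1] else NA_character_,
               start = if (nrow(ro)) ro$start[1] else min(h$sstart),
               end = if (nrow(ro)) ro$end[1] else max(h$send),
               n_supporting_hits = nrow(h),
               n_distinct_spacers = length(unique(h$spacer_id)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$region, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
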
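# CRISPR repeat-spacer array detection by exact-seed chaining and maximal
# extension of identical repeat copies, plus greedy non-redundant spacer
# clustering.

#' Detect CRISPR repeat-spacer arrays
#'
#' Exact `dr_min`-mer seeds locate repeated words; runs of occurrences
#' whose periods are compatible with a repeat-spacer structure are chained
#' and the repeat is extended maximally while all copies stay identical. A
#' candidate is accepted when the repeat length lies in
#' `[dr_min, dr_max]`, every gap (spacer) lies in `[sp_min, sp_max]` and
#' there are at least `min_copies` copies. A truncated terminal copy of at
#' least half the repeat length is recognised as a copy. Overlapping
#' candidates are resolved by most copies, then longest repeat, then
#' leftmost position. Arrays are reported on the forward strand with
#' spacers left to right.
#'
#' @param genome a [genome_record].
#' @param dr_min,dr_max direct-repeat length bounds (default 23-55).
#' @param sp_min,sp_max spacer length bounds (default 25-60).
#' @param min_copies minimum repeat copies (default 3).
#' @return List of arrays; each is a list with `genome_id`, `start`,
#'   `end`, `repeat_seq`, `copy_starts`, `copy_lens` and `spacers`
#'   (data.frame: spacer_id, sequence, start, end, index).
#' @export
find_arrays <- function(genome, dr_min = 23L, dr_max = 55L, sp_min = 25L,
                        sp_max = 60L, min_copies = 3L) {
  stopifnot(inherits(genome, "genome_record"))
  s <- genome$sequence
  n <- nchar(s)
  if (n < dr_min * min_copies) return(list())
  ch <- strsplit(s, "")[[1]]
  idx <- kmer_index(s, dr_min)
  idx <- idx[lengths(idx) >= min_copies]
  cands <- list()
  for (pos in idx) {
    pos <- sort(pos)
    delta <- diff(pos)
    ok <- delta >= dr_min + sp_min & delta <= dr_max + sp_max
    run <- cumsum(c(TRUE, !ok))
    for (ix in split(seq_along(pos), run)) {
      if (length(ix) < min_copies) next
      st <- pos[ix]
      L <- dr_min
      # maximal left extension (all copies must stay identical)
      repeat {
        cand <- st - 1L
        if (any(cand < 1L) || L + 1L > dr_max) break
        gaps <- diff(st) - L
        if (any(gaps - 1L < sp_min)) break
        if (length(unique(ch[cand])) > 1L) break
        st <- cand
        L <- L + 1L
      }
      # maximal right extension
      repeat {
        cand <- st + L
        if (any(cand > n) || L + 1L > dr_max) break
        gaps <- diff(st) - L
        if (any(gaps - 1L < sp_min)) break
        if (length(unique(ch[cand])) > 1L) break
        L <- L + 1L
      }
      gaps <- diff(st) - L
      if (L < dr_min || L > dr_max) next
      if (any(gaps < sp_min) || any(gaps > sp_max)) next
      rep_seq <- substr(s, st[1], st[1] + L - 1L)
      copies <- st
      copy_lens <- rep(L, length(st))
      # truncated terminal copy (>= 50% of the repeat) after one more spacer
      last_end <- st[length(st)] + L - 1L
      for (g in sp_min:sp_max) {
        t0 <- last_end + g + 1L
        for (tl in seq(L, ceiling(L / 2))) {
          if (t0 + tl - 1L > n) next
          if (substr(s, t0, t0 + tl - 1L) ==
              substr(rep_seq, 1L, tl) &&
              (tl == L || t0 + tl > n ||
                 substr(s, t0 + tl, t0 + tl) != substr(rep_seq, tl + 1L, tl + 1L))) {
            copies <- c(copies, t0)
            copy_lens <- c(copy_lens, tl)
            break
          }
        }
        if (length(copies) > length(st)) break
      }
      cands[[length(cands) + 1L]] <- list(
        start = copies[1], end = copies[length(copies)] +
          copy_lens[length(copy_lens)] - 1L,
        repeat_seq = rep_seq, copy_starts = copies, copy_lens = copy_lens)
    }
  }
  if (!length(cands)) return(list())
  key <- vapply(cands, function(a)
    paste(a$start, a$end, nchar(a$repeat_seq), length(a$copy_starts)), "")
  cands <- cands[!duplicated(key)]
  ord <- order(-vapply(cands, function(a) length(a$copy_starts), 0L),
               -vapply(cands, function(a) nchar(a$repeat_seq), 0L),
               vapply(cands, function(a) a$start, 0L))
  cands <- cands[ord]
  chosen <- list()
  occ <- matrix(numeric(0), ncol = 2)
  for (a in cands) {
    if (nrow(occ) && any(occ[, 1] <= a$end & occ[, 2] >= a$start)) next
    chosen[[length(chosen) + 1L]] <- a
    occ <- rbind(occ, c(a$start, a$end))
  }
  chosen <- chosen[order(vapply(chosen, function(a) a$start, 0L))]
  lapply(seq_along(chosen), function(ai) {
    a <- chosen[[ai]]
    cs <- a$copy_starts
    cl <- a$copy_lens
    nsp <- length(cs) - 1L
    sp <- data.frame(
      spacer_id = sprintf("%s|arr%d|%d", genome$id, ai, seq_len(nsp)),
      sequence = substring(s, cs[-length(cs)] + cl[-length(cl)],
                           cs[-1] - 1L),
      start = cs[-length(cs)] + cl[-length(cl)],
      end = cs[-1] - 1L, index = seq_len(nsp), stringsAsFactors = FALSE)
    list(genome_id = genome$id, start = a$start, end = a$end,
         repeat_seq = a$repeat_seq, copy_starts = cs, copy_lens = cl,
         spacers = sp)
  })
}

#' Flatten detected arrays to a spacer table
#'
#' @param arrays output of [find_arrays()], possibly concatenated across
#'   genomes.
#' @return data.frame with `spacer_id`, `genome_id`, `array`, `index`,
#'   `sequence`, `start`, `end`.
#' @export
spacer_table <- function(arrays) {
  if (!length(arrays))
    return(data.frame(spacer_id = character(), genome_id = character(),
                      array = integer(), index = integer(),
                      sequence = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  do.call(rbind, lapply(seq_along(arrays), function(ai) {
    a <- arrays[[ai]]
    data.frame(spacer_id = a$spacers$spacer_id, genome_id = a$genome_id,
               array = ai, index = a$spacers$index,
               sequence = a$spacers$sequence, start = a$spacers$start,
               end = a$spacers$end, stringsAsFactors = FALSE)
  }))
}

# Best ungapped identity between two sequences over the shorter length,
# maximised over all offsets and both strands.
ungapped_identity <- function(a, b) {
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  na <- nchar(a); nb <- nchar(b)
  av <- charToRaw(a)
  best <- 0
  for (s in c(b, revcomp(b))) {
    sv <- charToRaw(s)
    for (off in 0:(nb - na)) {
      m <- sum(av == sv[(off + 1L):(off + na)])
      if (m / na > best) best <- m / na
    }
  }
  best
}

#' Non-redundant spacer set by greedy incremental clustering
#'
#' Spacers are sorted by length (descending), ties broken
#' lexicographically by sequence; each spacer joins the first
#' representative with ungapped identity at least `identity_threshold`
#' over the shorter length (both strands considered), otherwise it becomes
#' a new representative. Deterministic and idempotent.
#'
#' @param spacers data.frame with `spacer_id` and `sequence` (>= 1 row).
#' @param identity_threshold clustering identity (default 0.9).
#' @return List with `representatives` (data.frame: spacer_id, sequence)
#'   and `cluster_map` (data.frame: spacer_id, representative).
#' @export
dedupe_spacers <- function(spacers, identity_threshold = 0.9) {
  stopifnot(is.data.frame(spacers), nrow(spacers) >= 1L)
  ord <- order(-nchar(spacers$sequence), spacers$sequence, spacers$spacer_id)
  sp <- spacers[ord, , drop = FALSE]
  reps <- integer(0)
  assign <- integer(nrow(sp))
  for (i in seq_len(nrow(sp))) {
    found <- 0L
    for (r in reps) {
      if (ungapped_identity(sp$sequence[i], sp$sequence[r]) >=
          identity_threshold) { found <- r; break }
    }
    if (found == 0L) { reps <- c(reps, i); found <- i }
    assign[i] <- found
  }
  list(representatives = data.frame(spacer_id = sp$spacer_id[reps],
                                    sequence = sp$sequence[reps],
                                    stringsAsFactors = FALSE),
       cluster_map = data.frame(spacer_id = sp$spacer_id,
                                representative = sp$spacer_id[assign],
                                stringsAsFactors = FALSE))
}
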
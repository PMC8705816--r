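# Six-frame ORF prediction and bacterial (table 11) translation for
# prophage regions. This is a conventional prokaryotic caller — start codons
# ATG/GTG/TTG, stops TAA/TAG/TGA, longest ORF per stop — not a statistical
# gene finder.

START_CODONS <- c("ATG", "GTG", "TTG")
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Translate DNA with the bacterial genetic code
#'
#' Table 11 translation. Codons containing N translate to `X`; internal
#' stop codons translate to `*`; a trailing stop codon is omitted. When
#' `initiator = TRUE` the first codon is translated to `M` if it is one of
#' the alternative initiators ATG/GTG/TTG.
#'
#' @param seq DNA string with length divisible by 3.
#' @param initiator treat the first codon as an initiator.
#' @return Amino-acid string.
#' @export
translate_dna <- function(seq, initiator = FALSE) {
  check_dna(seq)
  n <- nchar(seq)
  if (n %% 3L != 0L)
    stop("sequence length ", n, " is not divisible by 3", call. = FALSE)
  codons <- substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
  code <- Biostrings::GENETIC_CODE
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"
  if (initiator && codons[1] %in% START_CODONS) aa[1] <- "M"
  if (length(aa) && aa[length(aa)] == "*") aa <- aa[-length(aa)]
  paste(aa, collapse = "")
}

#' GC content of a DNA string
#'
#' `(G + C) / (A + C + G + T)`; N bases are excluded from both numerator and
#' denominator.
#'
#' @param seq non-empty DNA string.
#' @return Fraction in `[0, 1]`.
#' @export
gc_content <- function(seq) {
  check_dna(seq)
  tab <- table(strsplit(seq, "")[[1]])
  cnt <- function(b) if (b %in% names(tab)) as.numeric(tab[[b]]) else 0
  denom <- cnt("A") + cnt("C") + cnt("G") + cnt("T")
  if (denom == 0)
    stop("GC content undefined: sequence contains no unambiguous bases",
         call. = FALSE)
  (cnt("G") + cnt("C")) / denom
}

orf_frame_scan <- function(seq, frame, min_aa) {
  # ORFs in one forward frame (frame 0..2); returns start/end (1-based,
  # inclusive, including the stop codon) on the given string.
  n <- nchar(seq)
  first <- frame + 1L
  ncod <- (n - frame) %/% 3L
  if (ncod < min_aa + 1L) return(NULL)
  cs <- seq(first, by = 3L, length.out = ncod)
  codons <- substring(seq, cs, cs + 2L)
  has_n <- grepl("N", codons, fixed = TRUE)
  is_stop <- codons %in% STOP_CODONS & !has_n
  is_start <- codons %in% START_CODONS & !has_n
  stops <- which(is_stop)
  if (!length(stops)) return(NULL)
  out <- list()
  prev <- 0L
  for (st in stops) {
    win <- (prev + 1L):(st - 1L)
    if (st - 1L >= prev + 1L) {
      cand <- win[is_start[win]]
      if (length(cand)) {
        a <- cand[1]
        if (st - a >= min_aa)
          out[[length(out) + 1L]] <- c(cs[a], cs[st] + 2L)
      }
    }
    prev <- st
  }
  if (!length(out)) return(NULL)
  m <- do.call(rbind, out)
  data.frame(start = m[, 1], end = m[, 2], frame = frame)
}

#' Predict open reading frames in all six frames
#'
#' Scans both strands; within a frame the longest ORF per stop codon is
#' reported (first qualifying start codon after the previous stop). Codons
#' containing N never match start or stop codons; proteins with more than
#' 10% `X` are discarded.
#'
#' @param seq DNA string.
#' @param min_aa minimum protein length in amino acids (default 30).
#' @param region_id identifier recorded for each ORF.
#' @return data.frame with columns `orf_id`, `region_id`, `start`, `end`
#'   (1-based inclusive on the forward strand), `strand`, `frame` and
#'   `protein`. ORFs are sorted by start position.
#' @export
find_orfs <- function(seq, min_aa = 30L, region_id = "region") {
  check_dna(seq)
  n <- nchar(seq)
  res <- list()
  for (f in 0:2) {
    hits <- orf_frame_scan(seq, f, min_aa)
    if (!is.null(hits)) {
      hits$strand <- "+"
      res[[length(res) + 1L]] <- hits
    }
  }
  rc <- revcomp(seq)
  for (f in 0:2) {
    hits <- orf_frame_scan(rc, f, min_aa)
    if (!is.null(hits)) {
      s0 <- n - hits$end + 1L
      hits$end <- n - hits$start + 1L
      hits$start <- s0
      hits$strand <- "-"
      res[[length(res) + 1L]] <- hits
    }
  }
  if (!length(res))
    return(data.frame(orf_id = character(), region_id = character(),
                      start = integer(), end = integer(), strand = character(),
                      frame = integer(), protein = character(),
                      stringsAsFactors = FALSE))
  orfs <- do.call(rbind, res)
  nt <- ifelse(orfs$strand == "+",
               substring(seq, orfs$start, orfs$end),
               vapply(seq_len(nrow(orfs)), function(i)
                 revcomp(substring(seq, orfs$start[i], orfs$end[i])), ""))
  orfs$protein <- vapply(nt, translate_dna, "", initiator = TRUE,
                         USE.NAMES = FALSE)
  xfrac <- vapply(orfs$protein, function(p) {
    ch <- strsplit(p, "")[[1]]
    sum(ch == "X") / length(ch)
  }, 0, USE.NAMES = FALSE)
  orfs <- orfs[xfrac <= 0.10, , drop = FALSE]
  orfs <- orfs[order(orfs$start, orfs$end, orfs$strand), , drop = FALSE]
  rownames(orfs) <- NULL
  orfs$region_id <- region_id
  orfs$orf_id <- sprintf("%s|%d", region_id, seq_len(nrow(orfs)))
  orfs[, c("orf_id", "region_id", "start", "end", "strand", "frame",
           "protein")]
}

#' Select a non-overlapping ORF set
#'
#' Greedy selection of ORFs by decreasing length (ties by position):
#' an ORF is kept when it overlaps every previously kept ORF by at most
#' `max_overlap` bp. Long coding genes win over the spurious short ORFs
#' that six-frame scanning reports on their complementary frames, giving a
#' gene-caller-like, near-tiling ORF set for protein comparison.
#'
#' @param orfs data.frame from [find_orfs()].
#' @param max_overlap tolerated overlap between kept ORFs in bp.
#' @return Subset of `orfs`, sorted by start.
#' @export
select_orfs <- function(orfs, max_overlap = 30L) {
  if (!nrow(orfs)) return(orfs)
  ord <- order(-(orfs$end - orfs$start), orfs$start, orfs$strand)
  keep <- integer(0)
  for (i in ord) {
    if (!length(keep) ||
        all(pmin(orfs$end[keep], orfs$end[i]) -
              pmax(orfs$start[keep], orfs$start[i]) + 1L <= max_overlap))
      keep <- c(keep, i)
  }
  out <- orfs[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write ORF proteins to FASTA
#'
#' One record per ORF, id `region_id|orf_index`.
#'
#' @param orfs data.frame from [find_orfs()] (possibly several regions
#'   concatenated).
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(orfs, path) {
  aa <- Biostrings::AAStringSet(orfs$protein)
  names(aa) <- orfs$orf_id
  Biostrings::writeXStringSet(aa, path, width = 80L)
  invisible(path)
}
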
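# Independent oracles and fixture builders used across the suite.

rand_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Brute-force six-frame ORF scan, written as an explicit codon walk
# (independent of the vectorised scanner in the package). Returns
# start/end/strand on the forward strand, including the stop codon.
brute_orfs <- function(seq, min_aa = 30L) {
  starts <- c("ATG", "GTG", "TTG")
  stops <- c("TAA", "TAG", "TGA")
  scan1 <- function(s) {
    n <- nchar(s)
    out <- list()
    for (f in 0:2) {
      i <- f + 1L
      open <- NA_integer_
      while (i + 2L <= n) {
        cod <- substr(s, i, i + 2L)
        if (!grepl("N", cod, fixed = TRUE)) {
          if (is.na(open) && cod %in% starts) open <- i
          if (cod %in% stops) {
            if (!is.na(open) && (i - open) / 3L >= min_aa)
              out[[length(out) + 1L]] <- c(open, i + 2L)
            open <- NA_integer_
          }
        }
        i <- i + 3L
      }
    }
    out
  }
  fw <- scan1(seq)
  n <- nchar(seq)
  rv <- lapply(scan1(bifidophage::revcomp(seq)), function(iv)
    c(n - iv[2] + 1L, n - iv[1] + 1L))
  key <- function(l, strand) vapply(l, function(iv)
    paste(iv[1], iv[2], strand), "")
  sort(c(key(fw, "+"), key(rv, "-")))
}

# Exhaustive enumeration of repeat triples compatible with a CRISPR array:
# three identical L-mers at positions (i, i+per1, i+per1+per2) with both
# periods in [L+sp_min, L+sp_max] (the two spacers may differ in length).
# Returns the number of qualifying (position, L, per1, per2) triples.
brute_repeat_triples <- function(s, dr_min = 23L, dr_max = 55L,
                                 sp_min = 25L, sp_max = 60L) {
  n <- nchar(s)
  found <- 0L
  for (L in dr_min:dr_max) {
    m <- n - L + 1L
    kms <- substring(s, 1:m, L:n)
    pers <- (L + sp_min):(L + sp_max)
    eq <- lapply(pers, function(per) {
      k <- m - per
      if (k < 1L) integer() else which(kms[1:k] == kms[(1:k) + per])
    })
    for (p1 in seq_along(pers)) {
      if (!length(eq[[p1]])) next
      for (p2 in seq_along(pers)) {
        if (!length(eq[[p2]])) next
        found <- found + sum((eq[[p1]] + pers[p1]) %in% eq[[p2]])
      }
    }
  }
  found
}

# Plain dynamic-programming Smith-Waterman with affine gaps for short
# proteins (independent of Biostrings).
sw_protein <- function(a, b, gap_open = 11, gap_extend = 1) {
  blosum <- bifidophage:::get_blosum62()
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  M <- X <- Y <- matrix(0, n + 1L, m + 1L)
  X[] <- -Inf; Y[] <- -Inf
  best <- 0
  for (i in 2:(n + 1L)) {
    for (j in 2:(m + 1L)) {
      X[i, j] <- max(M[i - 1L, j] - gap_open - gap_extend,
                     X[i - 1L, j] - gap_extend)
      Y[i, j] <- max(M[i, j - 1L] - gap_open - gap_extend,
                     Y[i, j - 1L] - gap_extend)
      M[i, j] <- max(0, max(M[i - 1L, j - 1L], X[i - 1L, j - 1L],
                            Y[i - 1L, j - 1L]) +
                       blosum[av[i - 1L], bv[j - 1L]])
      best <- max(best, M[i, j], X[i, j], Y[i, j])
    }
  }
  best
}

# A tiny annotated genome with CDS features at given intervals.
mk_genome <- function(id = "g", len = 10000L, feats = NULL, gc = 0.5,
                      species = "breve", strain = "S") {
  genome_record(id, rand_dna(len, gc),
                features = feats %||% bifidophage:::empty_features(),
                species_label = species, strain = strain)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

cds_row <- function(start, end, product, strand = "+", kind = "CDS") {
  data.frame(kind = kind, start = start, end = end, strand = strand,
             product = product, stringsAsFactors = FALSE)
}
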
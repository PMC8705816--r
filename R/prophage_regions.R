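# Candidate prophage detection on annotated genomes, boundary refinement,
# completeness classification and nomenclature.
#
# Detection is annotation-driven: runs of CDS features whose products match
# the phage lexicon. Boundary refinement then iterates three absorption
# criteria to a fixed point: (i) flanking tRNA/integrase features, (ii)
# bridging runs of hypothetical proteins capped by a phage gene, (iii)
# putatively co-transcribed neighbours (same strand, intergenic gap < 1 kb).

#' Scan a genome for candidate prophage intervals
#'
#' Finds maximal runs of CDS features whose products match the phage
#' lexicon, where consecutive matching features are at most `max_gap` bp
#' apart; runs with at least `min_hits` matches are reported. The interval
#' spans the first to the last matching feature.
#'
#' @param genome a [genome_record].
#' @param lexicon lexicon table from [phage_lexicon()].
#' @param min_hits minimum number of matching features per run.
#' @param max_gap maximum gap (bp) between consecutive matching features.
#' @return data.frame with `start`, `end`, `n_hits`.
#' @export
scan_candidates <- function(genome, lexicon = phage_lexicon(),
                            min_hits = 4L, max_gap = 5000L) {
  stopifnot(inherits(genome, "genome_record"))
  fx <- genome$features
  empty <- data.frame(start = integer(), end = integer(), n_hits = integer())
  cds <- fx[fx$kind == "CDS", , drop = FALSE]
  if (!nrow(cds)) return(empty)
  hit <- !is.na(assign_modules(cds$product, lexicon))
  cds <- cds[hit, , drop = FALSE]
  if (!nrow(cds)) return(empty)
  cds <- cds[order(cds$start), , drop = FALSE]
  gap <- c(0L, cds$start[-1] - cds$end[-nrow(cds)] - 1L)
  run <- cumsum(gap > max_gap)
  out <- do.call(rbind, lapply(split(seq_len(nrow(cds)), run), function(ix) {
    data.frame(start = cds$start[ix[1]], end = cds$end[ix[length(ix)]],
               n_hits = length(ix))
  }))
  out <- out[out$n_hits >= min_hits, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Refine candidate prophage boundaries
#'
#' Iterates the three absorption criteria to a fixed point, independently
#' on each side: (i) a tRNA or integrase-product feature within
#' `flank_window` bp beyond the edge is absorbed; (ii) a run of
#' hypothetical-product CDS between the edge and a lexicon-matching CDS is
#' absorbed together with that CDS; (iii) the next CDS is absorbed while it
#' shares the strand of the current edge CDS and the intergenic gap is
#' below `cotx_gap` bp. Refinement only ever widens the interval and the
#' total extension per side is capped at `side_cap` bp.
#'
#' @param candidate length-2 integer vector `c(start, end)` (1-based,
#'   inclusive) or one row of [scan_candidates()] output.
#' @param genome a [genome_record].
#' @param lexicon lexicon table.
#' @param flank_window criterion-(i) search window in bp (default 2000).
#' @param cotx_gap criterion-(iii) maximum intergenic gap in bp (default
#'   1000, exclusive).
#' @param side_cap maximum extension per side in bp (default 15000).
#' @return Integer vector `c(start, end)`.
#' @export
refine_boundaries <- function(candidate, genome, lexicon = phage_lexicon(),
                              flank_window = 2000L, cotx_gap = 1000L,
                              side_cap = 15000L) {
  stopifnot(inherits(genome, "genome_record"))
  if (is.data.frame(candidate))
    candidate <- c(candidate$start[1], candidate$end[1])
  cur <- as.integer(candidate[1:2])
  n <- nchar(genome$sequence)
  if (cur[1] < 1L || cur[2] > n || cur[1] > cur[2])
    stop("candidate interval out of genome bounds", call. = FALSE)
  lo_cap <- max(1L, cur[1] - side_cap)
  hi_cap <- min(n, cur[2] + side_cap)
  fx <- genome$features
  fx <- fx[order(fx$start), , drop = FALSE]
  mods <- assign_modules(fx$product, lexicon)
  is_lex <- !is.na(mods) & fx$kind == "CDS"
  is_anchor <- fx$kind == "tRNA" |
    (fx$kind == "CDS" & !is.na(mods) & mods == "integration_excision")
  is_hyp <- fx$kind == "CDS" & is_hypothetical(fx$product)
  is_cds <- fx$kind == "CDS"
  repeat {
    prev <- cur
    # --- left side ---
    out_l <- which(fx$end < cur[1])
    # (i) flanking tRNA / integrase within the window
    a <- out_l[is_anchor[out_l] & fx$end[out_l] >= cur[1] - flank_window &
                 fx$start[out_l] >= lo_cap]
    if (length(a)) cur[1] <- min(cur[1], fx$start[a])
    # (ii) hypothetical run capped by a lexicon CDS
    out_l <- which(fx$end < cur[1] & is_cds)
    if (length(out_l)) {
      walk <- rev(out_l)  # outward: nearest first
      i <- 1L
      while (i <= length(walk) && is_hyp[walk[i]]) i <- i + 1L
      if (i > 1L && i <= length(walk) && is_lex[walk[i]] &&
          fx$start[walk[i]] >= lo_cap)
        cur[1] <- min(cur[1], fx$start[walk[i]])
    }
    # (iii) co-transcription extension
    repeat {
      inside <- which(is_cds & fx$start >= cur[1] & fx$end <= cur[2])
      if (!length(inside)) break
      edge <- inside[1]
      outw <- which(is_cds & fx$end < cur[1])
      if (!length(outw)) break
      cand <- outw[length(outw)]
      gap <- fx$start[edge] - fx$end[cand] - 1L
      if (fx$strand[cand] == fx$strand[edge] && gap < cotx_gap &&
          fx$start[cand] >= lo_cap) {
        cur[1] <- fx$start[cand]
      } else break
    }
    # --- right side ---
    out_r <- which(fx$start > cur[2])
    a <- out_r[is_anchor[out_r] & fx$start[out_r] <= cur[2] + flank_window &
                 fx$end[out_r] <= hi_cap]
    if (length(a)) cur[2] <- max(cur[2], fx$end[a])
    out_r <- which(fx$start > cur[2] & is_cds)
    if (length(out_r)) {
      walk <- out_r
      i <- 1L
      while (i <= length(walk) && is_hyp[walk[i]]) i <- i + 1L
      if (i > 1L && i <= length(walk) && is_lex[walk[i]] &&
          fx$end[walk[i]] <= hi_cap)
        cur[2] <- max(cur[2], fx$end[walk[i]])
    }
    repeat {
      inside <- which(is_cds & fx$start >= cur[1] & fx$end <= cur[2])
      if (!length(inside)) break
      edge <- inside[length(inside)]
      outw <- which(is_cds & fx$start > cur[2])
      if (!length(outw)) break
      cand <- outw[1]
      gap <- fx$start[cand] - fx$end[edge] - 1L
      if (fx$strand[cand] == fx$strand[edge] && gap < cotx_gap &&
          fx$end[cand] <= hi_cap) {
        cur[2] <- fx$end[cand]
      } else break
    }
    if (identical(cur, prev)) break
  }
  cur
}

#' Classify prophage completeness
#'
#' Three-way classification: `remnant` if the region is shorter than 13 kb
#' or lacks both the head/tail and DNA-packaging modules;
#' `likely_complete` if it is at least 30 kb, or at least 20 kb with four
#' of the five modules present and an integrase at a boundary; `partial`
#' otherwise. The remnant rule takes precedence: a long region with no
#' structural or packaging genes cannot constitute a complete phage.
#'
#' @param length region length in bp (> 0).
#' @param modules character vector of modules present (subset of the five).
#' @param boundary_integrase is an integrase located at a region boundary?
#' @return One of `"remnant"`, `"partial"`, `"likely_complete"`.
#' @export
classify_completeness <- function(length, modules,
                                  boundary_integrase = FALSE) {
  if (length <= 0) stop("zero-length region", call. = FALSE)
  modules <- intersect(modules, PHAGE_MODULES)
  structural <- c("head_tail", "dna_packaging")
  if (length < 13000 || !any(structural %in% modules)) return("remnant")
  if (length >= 30000) return("likely_complete")
  if (length >= 20000 && length(modules) >= 4L && isTRUE(boundary_integrase))
    return("likely_complete")
  "partial"
}

#' Name a prophage
#'
#' Species abbreviation + strain + `ph` + ordinal, e.g. `BifBIOML-A4ph1`
#' for the first phage predicted in the *B. bifidum* strain BIOML-A4.
#' Ordinals are assigned by ascending genomic position within the strain.
#'
#' @param species_label one of adolescentis, bifidum, breve, longum_longum,
#'   longum_infantis.
#' @param strain strain designation.
#' @param ordinal positive integer.
#' @return The prophage name.
#' @export
name_prophage <- function(species_label, strain, ordinal) {
  abbr <- c(adolescentis = "Bad", bifidum = "Bif", breve = "Bre",
            longum_longum = "Blong", longum_infantis = "Blong")
  if (!species_label %in% names(abbr))
    stop("no naming abbreviation for species label '", species_label, "'",
         call. = FALSE)
  stopifnot(ordinal >= 1L)
  sprintf("%s%sph%d", abbr[[species_label]], strain, as.integer(ordinal))
}

#' Summarise prophage region sizes
#'
#' @param lengths region lengths in bp.
#' @param n_genomes number of genomes surveyed (>= 1).
#' @param bin mode bin width in bp (default 100).
#' @return List with `count`, `min`, `max`, `median`, `mode` (most
#'   frequent `bin`-bp length bin, ties to the smallest) and
#'   `mean_per_genome` (count / n_genomes, rounded to 2 decimals).
#' @export
size_summary <- function(lengths, n_genomes, bin = 100L) {
  stopifnot(n_genomes >= 1L)
  if (!length(lengths))
    return(list(count = 0L, min = NA_real_, max = NA_real_,
                median = NA_real_, mode = NA_real_,
                mean_per_genome = 0))
  bins <- floor(lengths / bin) * bin
  tab <- table(bins)
  mode_bin <- as.numeric(names(tab)[which.max(tab)])
  list(count = length(lengths), min = min(lengths), max = max(lengths),
       median = stats::median(lengths), mode = mode_bin,
       mean_per_genome = round(length(lengths) / n_genomes, 2))
}

region_boundary_flags <- function(genome, start, end,
                                  lexicon = phage_lexicon(),
                                  integrase_window = 2000L,
                                  trna_window = 500L) {
  fx <- genome$features
  mods <- assign_modules(fx$product, lexicon)
  intg <- fx$kind == "CDS" & !is.na(mods) & mods == "integration_excision"
  inside <- fx$start >= start & fx$end <= end
  trna <- fx$kind == "tRNA"
  near_left <- fx$end >= start - trna_window & fx$start <= start + trna_window
  near_right <- fx$start <= end + trna_window & fx$end >= end - trna_window
  list(left_integrase = any(intg & inside & fx$start - start <= integrase_window),
       right_integrase = any(intg & inside & end - fx$end <= integrase_window),
       left_trna = any(trna & near_left),
       right_trna = any(trna & near_right))
}

#' Detect, refine, classify and name prophage regions
#'
#' Runs the full region-curation stage over a set of genomes: candidate
#' scan, boundary refinement, module assignment, completeness
#' classification, boundary flags and nomenclature (ordinals by ascending
#' position within each strain).
#'
#' @param genomes named list of [genome_record] objects.
#' @param lexicon lexicon table.
#' @param min_hits,max_gap candidate-scan parameters (see
#'   [scan_candidates()]).
#' @param ... passed to [refine_boundaries()].
#' @return data.frame with one row per region: `name`, `genome_id`,
#'   `start`, `end`, `length`, `gc`, `completeness`, `modules`
#'   (comma-separated), and the four boundary flags.
#' @export
detect_prophages <- function(genomes, lexicon = phage_lexicon(),
                             min_hits = 4L, max_gap = 5000L, ...) {
  rows <- list()
  for (g in genomes) {
    cands <- scan_candidates(g, lexicon, min_hits, max_gap)
    if (!nrow(cands)) next
    iv <- lapply(seq_len(nrow(cands)), function(i)
      refine_boundaries(c(cands$start[i], cands$end[i]), g, lexicon, ...))
    iv <- do.call(rbind, iv)
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    # merge any intervals that came to overlap after refinement
    merged <- list(iv[1, ])
    if (nrow(iv) > 1L)
      for (i in 2:nrow(iv)) {
        last <- merged[[length(merged)]]
        if (iv[i, 1] <= last[2])
          merged[[length(merged)]] <- c(last[1], max(last[2], iv[i, 2]))
        else merged[[length(merged) + 1L]] <- iv[i, ]
      }
    for (k in seq_along(merged)) {
      s <- merged[[k]][1]; e <- merged[[k]][2]
      fxin <- g$features[g$features$kind == "CDS" &
                           g$features$start >= s & g$features$end <= e, ]
      mods <- unique(stats::na.omit(assign_modules(fxin$product, lexicon)))
      flags <- region_boundary_flags(g, s, e, lexicon)
      cls <- classify_completeness(e - s + 1L, mods,
                                   flags$left_integrase || flags$right_integrase)
      rows[[length(rows) + 1L]] <- data.frame(
        name = name_prophage(g$species_label, g$strain, k),
        genome_id = g$id, start = s, end = e, length = e - s + 1L,
        gc = gc_content(substring(g$sequence, s, e)),
        completeness = cls, modules = paste(sort(mods), collapse = ","),
        left_integrase = flags$left_integrase,
        right_integrase = flags$right_integrase,
        left_trna = flags$left_trna, right_trna = flags$right_trna,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(name = character(), genome_id = character(),
                      start = integer(), end = integer(), length = integer(),
                      gc = numeric(), completeness = character(),
                      modules = character(), left_integrase = logical(),
                      right_integrase = logical(), left_trna = logical(),
                      right_trna = logical(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
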
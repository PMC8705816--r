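# Genome records, feature tables and the standard flat formats.
#
# Internal coordinates are 1-based inclusive throughout, the native
# convention of GFF3/GenBank and of IRanges, so emitted files need no
# conversion. Feature tables are plain data.frames with columns
# kind/start/end/strand/product.

FEATURE_KINDS <- c("CDS", "tRNA", "repeat_region", "misc")

SPECIES_LABELS <- c("adolescentis", "bifidum", "breve",
                    "longum_longum", "longum_infantis", "other")

empty_features <- function() {
  data.frame(kind = character(), start = integer(), end = integer(),
             strand = character(), product = character(),
             stringsAsFactors = FALSE)
}

#' Construct a genome record
#'
#' A genome record bundles one contig sequence with its feature annotation.
#' Multi-contig assemblies are represented as one record per contig; regions
#' never span contigs.
#'
#' @param id unique record identifier.
#' @param sequence DNA string over A/C/G/T/N (uppercase).
#' @param features data.frame with columns `kind` (CDS, tRNA, repeat_region
#'   or misc), `start`, `end` (1-based inclusive), `strand` (+/-) and
#'   `product` (free-text label).
#' @param species_label one of adolescentis, bifidum, breve, longum_longum,
#'   longum_infantis, other.
#' @param strain strain designation used in prophage nomenclature.
#' @return An object of class `genome_record`.
#' @export
genome_record <- function(id, sequence, features = empty_features(),
                          species_label = "other", strain = id) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  check_dna(sequence, paste0("sequence of '", id, "'"))
  species_label <- match.arg(species_label, SPECIES_LABELS)
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  need <- c("kind", "start", "end", "strand", "product")
  miss <- setdiff(need, names(features))
  for (m in miss) features[[m]] <- if (m %in% c("start", "end")) integer() else character()
  features <- features[, need, drop = FALSE]
  if (nrow(features)) {
    features$start <- as.integer(features$start)
    features$end <- as.integer(features$end)
    if (any(features$start > features$end))
      stop("feature with start > end in '", id, "'", call. = FALSE)
    if (any(features$start < 1L) || any(features$end > nchar(sequence)))
      stop("feature outside sequence bounds in '", id, "'", call. = FALSE)
    if (!all(features$kind %in% FEATURE_KINDS))
      stop("unknown feature kind in '", id, "'", call. = FALSE)
    cds_trna <- features$kind %in% c("CDS", "tRNA")
    if (any(!features$strand[cds_trna] %in% c("+", "-")))
      stop("CDS/tRNA feature without strand in '", id, "'", call. = FALSE)
    features <- features[order(features$start, features$end), , drop = FALSE]
    rownames(features) <- NULL
  }
  structure(list(id = id, species_label = species_label, strain = strain,
                 sequence = sequence, features = features),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s (%s, strain %s): %s bp, %d features\n",
              x$id, x$species_label, x$strain,
              format(nchar(x$sequence), big.mark = ","), nrow(x$features)))
  invisible(x)
}

#' @export
length.genome_record <- function(x) nchar(x$sequence)

species_from_organism <- function(x) {
  x <- tolower(x)
  if (grepl("adolescentis", x)) return("adolescentis")
  if (grepl("bifidum", x)) return("bifidum")
  if (grepl("breve", x)) return("breve")
  if (grepl("longum", x)) {
    if (grepl("infantis", x)) return("longum_infantis")
    return("longum_longum")
  }
  "other"
}

# Parse "key=value" tokens from a FASTA description line.
desc_token <- function(desc, key) {
  m <- regmatches(desc, regexpr(paste0(key, "=[^ ]+"), desc))
  if (!length(m)) return(NA_character_)
  sub(paste0(key, "="), "", m)
}

#' Read annotated genomes
#'
#' Reads a set of genome records from either GenBank flat files or a FASTA
#' file with a companion GFF3 annotation. Every CDS and tRNA feature in the
#' input appears in the feature table; other typed features are kept as
#' `repeat_region` or `misc`.
#'
#' @param path for `format = "genbank"`, a GenBank flat file (possibly
#'   multi-record); for `format = "fasta+gff3"`, the FASTA file.
#' @param format input format.
#' @param gff path to the GFF3 companion for `fasta+gff3`; defaults to the
#'   FASTA path with its extension replaced by `.gff3`.
#' @return A named list of [genome_record] objects.
#' @export
read_genomes <- function(path, format = c("genbank", "fasta+gff3"),
                         gff = NULL) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("input file does not exist: ", path, call. = FALSE)
  recs <- if (format == "genbank") {
    read_genbank(path)
  } else {
    if (is.null(gff)) gff <- paste0(sub("\\.(fa|fasta|fna)$", "", path), ".gff3")
    if (!file.exists(gff))
      stop("GFF3 companion file does not exist: ", gff, call. = FALSE)
    read_fasta_gff3(path, gff)
  }
  if (!length(recs))
    stop("empty dataset: no genome records in ", path, call. = FALSE)
  ids <- vapply(recs, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop("duplicate genome ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ","), call. = FALSE)
  stats::setNames(recs, ids)
}

read_fasta_gff3 <- function(fasta, gff) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  if (!length(seqs)) return(list())
  full <- names(seqs)
  ids <- sub(" .*", "", full)
  desc <- sub("^[^ ]+ ?", "", full)
  gr <- rtracklayer::import(gff, format = "gff3")
  gdf <- as.data.frame(gr)
  lapply(seq_along(seqs), function(i) {
    fx <- empty_features()
    if (nrow(gdf)) {
      sel <- gdf[as.character(gdf$seqnames) == ids[i], , drop = FALSE]
      if (nrow(sel)) {
        kind <- as.character(sel$type)
        kind[!kind %in% FEATURE_KINDS] <- "misc"
        prod <- if ("product" %in% names(sel)) as.character(sel$product)
                else rep(NA_character_, nrow(sel))
        prod[is.na(prod)] <- ""
        fx <- data.frame(kind = kind, start = sel$start, end = sel$end,
                         strand = as.character(sel$strand), product = prod,
                         stringsAsFactors = FALSE)
        fx$strand[!fx$strand %in% c("+", "-")] <- "+"
      }
    }
    sp <- desc_token(desc[i], "species")
    strain <- desc_token(desc[i], "strain")
    genome_record(
      id = ids[i],
      sequence = toupper(as.character(seqs[[i]])),
      features = fx,
      species_label = if (!is.na(sp) && sp %in% SPECIES_LABELS) sp else "other",
      strain = if (!is.na(strain)) strain else ids[i])
  })
}

# Minimal GenBank flat-file reader: LOCUS/FEATURES/ORIGIN blocks, CDS and
# tRNA features with simple or complement() locations (join() collapses to
# its overall span), /product and source /organism//strain qualifiers.
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) return(list())
  starts <- grep("^LOCUS", lines)
  if (!length(starts))
    stop("not a GenBank flat file (no LOCUS line): ", path, call. = FALSE)
  ends <- c(starts[-1] - 1L, length(lines))
  lapply(seq_along(starts), function(k) {
    block <- lines[starts[k]:ends[k]]
    parse_genbank_record(block, path)
  })
}

parse_genbank_location <- function(loc) {
  strand <- "+"
  if (grepl("complement", loc)) strand <- "-"
  nums <- as.integer(regmatches(loc, gregexpr("[0-9]+", loc))[[1]])
  if (length(nums) < 2L) return(NULL)
  list(start = min(nums), end = max(nums), strand = strand)
}

parse_genbank_record <- function(block, path) {
  id <- strsplit(trimws(block[1]), "\\s+")[[1]][2]
  if (is.na(id)) stop("unreadable LOCUS line in ", path, call. = FALSE)
  fstart <- grep("^FEATURES", block)
  ostart <- grep("^ORIGIN", block)
  if (!length(ostart))
    stop("record '", id, "' has no ORIGIN sequence in ", path, call. = FALSE)
  seq_lines <- block[(ostart + 1L):length(block)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  organism <- ""
  strain <- NA_character_
  features <- empty_features()
  if (length(fstart)) {
    fl <- block[(fstart + 1L):(ostart - 1L)]
    is_key <- grepl("^ {5}\\S", fl)
    idx <- cumsum(is_key)
    groups <- split(fl, idx)
    if (length(groups) && idx[1] == 0L) groups[["0"]] <- NULL
    rows <- list()
    for (g in groups) {
      key <- strsplit(trimws(g[1]), "\\s+")[[1]]
      kind <- key[1]
      loc <- paste0(key[2], paste(trimws(g[-1])[!grepl("^/", trimws(g[-1]))],
                                  collapse = ""))
      quals <- trimws(g[-1])[grepl("^/", trimws(g[-1]))]
      getq <- function(name) {
        q <- quals[grepl(paste0("^/", name, "="), quals)]
        if (!length(q)) return(NA_character_)
        gsub('"', "", sub(paste0("^/", name, "="), "", q[1]))
      }
      if (kind == "source") {
        org <- getq("organism"); if (!is.na(org)) organism <- org
        st <- getq("strain"); if (!is.na(st)) strain <- st
        next
      }
      if (!kind %in% c("CDS", "tRNA", "repeat_region")) next
      pl <- parse_genbank_location(loc)
      if (is.null(pl))
        stop("unparsable location '", loc, "' in record '", id, "'",
             call. = FALSE)
      prod <- getq("product")
      rows[[length(rows) + 1L]] <- data.frame(
        kind = kind, start = pl$start, end = pl$end, strand = pl$strand,
        product = if (is.na(prod)) "" else prod, stringsAsFactors = FALSE)
    }
    if (length(rows)) features <- do.call(rbind, rows)
  }
  genome_record(id = id, sequence = sequence, features = features,
                species_label = species_from_organism(organism),
                strain = if (is.na(strain)) id else strain)
}

#' Extract a subregion of a genome record
#'
#' Returns the subsequence over the 1-based inclusive interval
#' `[start, end]`. Features lying wholly inside the interval are retained
#' with shifted coordinates; features straddling a boundary are dropped.
#'
#' @param genome a [genome_record].
#' @param start,end 1-based inclusive interval bounds.
#' @return A new [genome_record] whose id is suffixed with the interval.
#' @export
slice_region <- function(genome, start, end) {
  stopifnot(inherits(genome, "genome_record"))
  n <- nchar(genome$sequence)
  if (start < 1L || end > n || start > end)
    stop("interval [", start, ",", end, "] out of bounds for '", genome$id,
         "' (1..", n, ")", call. = FALSE)
  fx <- genome$features
  keep <- fx$start >= start & fx$end <= end
  fx <- fx[keep, , drop = FALSE]
  if (nrow(fx)) {
    fx$start <- fx$start - start + 1L
    fx$end <- fx$end - start + 1L
  }
  id <- if (start == 1L && end == n) genome$id else
    sprintf("%s:%d-%d", genome$id, start, end)
  genome_record(id = id, sequence = substr(genome$sequence, start, end),
                features = fx, species_label = genome$species_label,
                strain = genome$strain)
}

regions_to_granges <- function(regions) {
  gr <- GenomicRanges::GRanges(
    seqnames = regions$genome_id,
    ranges = IRanges::IRanges(start = regions$start, end = regions$end),
    strand = "+")
  gr$type <- "sequence_feature"
  gr$source <- "bifidophage"
  gr$ID <- regions$name
  gr$Name <- regions$name
  for (col in intersect(c("completeness", "gc"), names(regions)))
    S4Vectors::mcols(gr)[[col]] <- as.character(regions[[col]])
  gr
}

#' Write prophage regions to GFF3
#'
#' One GFF3 feature line per region, 1-based inclusive coordinates, region
#' name in the `ID`/`Name` attributes. The file round-trips through
#' [read_regions()].
#'
#' @param regions data.frame with at least `name`, `genome_id`, `start`,
#'   `end` columns (e.g. the output of [detect_prophages()]).
#' @param path output GFF3 path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path) {
  regions <- as.data.frame(regions)
  if (nrow(regions) && anyDuplicated(regions$name))
    stop("duplicate region names: ",
         paste(unique(regions$name[duplicated(regions$name)]), collapse = ","),
         call. = FALSE)
  if (!nrow(regions)) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  rtracklayer::export(regions_to_granges(regions), path, format = "gff3")
  invisible(path)
}

#' Read prophage regions from GFF3
#'
#' @param path GFF3 file written by [write_regions()].
#' @return data.frame with `name`, `genome_id`, `start`, `end` columns.
#' @export
read_regions <- function(path) {
  first <- readLines(path, n = 5L)
  if (!any(grepl("\t", readLines(path), fixed = TRUE)))
    return(data.frame(name = character(), genome_id = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  nm <- if ("Name" %in% names(df)) as.character(df$Name) else as.character(df$ID)
  out <- data.frame(name = nm, genome_id = as.character(df$seqnames),
                    start = df$start, end = df$end, stringsAsFactors = FALSE)
  if ("completeness" %in% names(df)) out$completeness <- as.character(df$completeness)
  out
}

#' Write genome records to FASTA (and optionally GFF3)
#'
#' FASTA headers carry `species=` and `strain=` tokens so that a
#' write/read round trip preserves the labels.
#'
#' @param genomes list of [genome_record] objects.
#' @param fasta output FASTA path.
#' @param gff optional output GFF3 path for the combined feature tables.
#' @return `fasta`, invisibly.
#' @export
write_genomes <- function(genomes, fasta, gff = NULL) {
  seqs <- Biostrings::DNAStringSet(vapply(genomes, `[[`, "", "sequence"))
  names(seqs) <- vapply(genomes, function(g)
    sprintf("%s species=%s strain=%s", g$id, g$species_label, g$strain), "")
  Biostrings::writeXStringSet(seqs, fasta, width = 80L)
  if (!is.null(gff)) {
    grl <- lapply(genomes, function(g) {
      fx <- g$features
      if (!nrow(fx)) return(NULL)
      gr <- GenomicRanges::GRanges(
        seqnames = g$id,
        ranges = IRanges::IRanges(start = fx$start, end = fx$end),
        strand = fx$strand)
      gr$type <- fx$kind
      gr$source <- "bifidophage"
      gr$product <- fx$product
      gr$ID <- sprintf("%s.f%d", g$id, seq_len(nrow(fx)))
      gr
    })
    grl <- grl[!vapply(grl, is.null, TRUE)]
    if (length(grl)) {
      all <- suppressWarnings(do.call(c, unname(grl)))
      suppressWarnings(rtracklayer::export(all, gff, format = "gff3"))
    } else {
      writeLines("##gff-version 3", gff)
    }
  }
  invisible(fasta)
}
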
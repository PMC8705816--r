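# Deterministic simulator: host chromosomes with implanted intact and
# remnant prophages plus CRISPR repeat-spacer arrays, with full ground
# truth (implant intervals, module content, spacer provenance). All
# randomness flows through R's global RNG; generate_dataset() seeds it from
# the mandatory config seed, so identical configs give byte-identical
# output.

MODULE_PRODUCTS <- list(
  integration_excision = c("integrase", "excisionase",
                           "site-specific recombinase"),
  lysis = c("holin", "endolysin"),
  dna_replication = c("DNA primase", "replicative DNA helicase",
                      "DNA polymerase", "replication initiation protein",
                      "single-stranded DNA-binding protein"),
  head_tail = c("major capsid protein", "minor head protein",
                "tail protein", "tape measure protein", "baseplate protein",
                "scaffolding protein"),
  dna_packaging = c("terminase large subunit", "portal protein",
                    "terminase small subunit"))

HOST_PRODUCTS <- c(
  "ABC transporter permease", "MFS transporter", "30S ribosomal protein S12",
  "50S ribosomal protein L3", "elongation factor Tu", "chaperonin GroEL",
  "aminotransferase", "sugar kinase", "transcriptional regulator",
  "cell division protein FtsZ", "ATP synthase subunit beta",
  "glycosyltransferase", "hypothetical protein", "phosphoglycerate mutase",
  "two-component sensor kinase")

SPECIES_GC <- c(adolescentis = 0.590, bifidum = 0.620, breve = 0.598,
                longum_longum = 0.610, longum_infantis = 0.610, other = 0.600)

sample_dna <- function(n, gc) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# A gene body that is a clean ORF: ATG start, stop at the end, no internal
# in-frame stop codons; internal codons sampled base-by-base at the target
# GC, resampling stop codons.
sample_orf_gene <- function(len_nt, gc) {
  stopifnot(len_nt %% 3L == 0L, len_nt >= 9L)
  ncod <- len_nt %/% 3L - 2L
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  bases <- sample(c("A", "C", "G", "T"), 3L * ncod, replace = TRUE,
                  prob = probs)
  codons <- paste0(bases[seq(1, length(bases), 3)],
                   bases[seq(2, length(bases), 3)],
                   bases[seq(3, length(bases), 3)])
  bad <- which(codons %in% STOP_CODONS)
  while (length(bad)) {
    for (i in bad) {
      repeat {
        cod <- paste(sample(c("A", "C", "G", "T"), 3L, replace = TRUE,
                            prob = probs), collapse = "")
        if (!cod %in% STOP_CODONS) break
      }
      codons[i] <- cod
    }
    bad <- which(codons %in% STOP_CODONS)
  }
  paste0("ATG", paste(codons, collapse = ""),
         sample(STOP_CODONS, 1L))
}

#' Construct a phage genome template
#'
#' A template fixes the modular gene architecture of a simulated phage:
#' ordered gene modules (integration/excision first so the integrase sits at
#' a sequence boundary; head/tail and packaging adjacent), per-module gene
#' counts, a log-normal gene length distribution and the GC content.
#'
#' @param module_order ordered subset of the five modules; the
#'   integration/excision module must be first or last, and head/tail and
#'   packaging must be adjacent.
#' @param genes_per_module named integer vector of gene counts (all >= 1).
#' @param gene_len_meanlog,gene_len_sdlog log-normal parameters for gene
#'   length in nt (rounded to codons, clamped to `[150, 2400]`).
#' @param gc GC fraction of the phage.
#' @param id template identifier.
#' @return An object of class `phage_template`.
#' @export
phage_template <- function(module_order = PHAGE_MODULES,
                           genes_per_module = c(integration_excision = 2L,
                                                lysis = 2L,
                                                dna_replication = 6L,
                                                head_tail = 8L,
                                                dna_packaging = 3L),
                           gene_len_meanlog = log(900) - 0.35^2 / 2,
                           gene_len_sdlog = 0.35,
                           gc = 0.60,
                           id = "T1") {
  stopifnot(all(module_order %in% PHAGE_MODULES),
            !anyDuplicated(module_order))
  if (length(module_order) && module_order[1] != "integration_excision" &&
      module_order[length(module_order)] != "integration_excision")
    stop("integration_excision module must be first or last", call. = FALSE)
  pos_ht <- match("head_tail", module_order)
  pos_pk <- match("dna_packaging", module_order)
  if (!is.na(pos_ht) && !is.na(pos_pk) && abs(pos_ht - pos_pk) != 1L)
    stop("head_tail and dna_packaging modules must be adjacent",
         call. = FALSE)
  genes_per_module <- genes_per_module[module_order]
  if (any(is.na(genes_per_module)) || any(genes_per_module < 1L))
    stop("every module in module_order needs >= 1 gene", call. = FALSE)
  structure(list(module_order = module_order,
                 genes_per_module = genes_per_module,
                 gene_len_meanlog = gene_len_meanlog,
                 gene_len_sdlog = gene_len_sdlog,
                 gc = gc, id = id),
            class = "phage_template")
}

# Template whose expected assembled length is close to target_length.
scaled_template <- function(target_length, gc = 0.60, id = "T1") {
  n_genes <- max(10L, round(target_length / 1000))
  mins <- c(integration_excision = 1L, lysis = 2L, dna_replication = 2L,
            head_tail = 3L, dna_packaging = 2L)
  extra <- n_genes - sum(mins)
  w <- c(1, 1, 3, 4, 2)
  add <- floor(extra * w / sum(w))
  rem <- extra - sum(add)
  if (rem > 0) add[order(-(extra * w / sum(w) - add))[seq_len(rem)]] <-
      add[order(-(extra * w / sum(w) - add))[seq_len(rem)]] + 1L
  counts <- mins + as.integer(add)
  mean_len <- max(300, target_length / n_genes - 100)
  phage_template(genes_per_module = counts,
                 gene_len_meanlog = log(mean_len) - 0.3^2 / 2,
                 gene_len_sdlog = 0.3, gc = gc, id = id)
}

#' Generate a phage genome from a template
#'
#' Draws gene lengths and sequences module by module. Genes within a module
#' share a strand; the strand alternates across module boundaries. The
#' first gene of the integration/excision module is labelled `integrase`
#' and the first head/tail gene `major capsid protein`. Intergenic gaps are
#' uniform on 2-200 bp. Uses the current RNG state.
#'
#' @param template a [phage_template].
#' @return An object of class `phage_genome`: list with `sequence`,
#'   `features` (CDS table with a `module` column), `gc` and `template_id`.
#' @export
generate_phage <- function(template) {
  stopifnot(inherits(template, "phage_template"))
  rows <- list()
  pieces <- character()
  pos <- 1L
  for (mi in seq_along(template$module_order)) {
    mod <- template$module_order[mi]
    strand <- if (mi %% 2L == 1L) "+" else "-"
    k <- template$genes_per_module[[mod]]
    prods <- rep_len(MODULE_PRODUCTS[[mod]], k)
    for (g in seq_len(k)) {
      len <- round(stats::rlnorm(1, template$gene_len_meanlog,
                                 template$gene_len_sdlog))
      len <- min(2400L, max(150L, as.integer(len)))
      len <- (len %/% 3L) * 3L
      orf <- sample_orf_gene(len, template$gc)
      gene_seq <- if (strand == "+") orf else revcomp(orf)
      rows[[length(rows) + 1L]] <- data.frame(
        kind = "CDS", start = pos, end = pos + len - 1L, strand = strand,
        product = prods[g], module = mod, stringsAsFactors = FALSE)
      pieces[length(pieces) + 1L] <- gene_seq
      last <- mi == length(template$module_order) && g == k
      gap <- if (last) 0L else sample(2:200, 1L)
      if (gap > 0L) pieces[length(pieces) + 1L] <- sample_dna(gap, template$gc)
      pos <- pos + len + gap
    }
  }
  structure(list(sequence = paste(pieces, collapse = ""),
                 features = do.call(rbind, rows),
                 gc = template$gc, template_id = template$id),
            class = "phage_genome")
}

#' @export
print.phage_genome <- function(x, ...) {
  cat(sprintf("<phage_genome> template %s: %d bp, %d genes (%s)\n",
              x$template_id, nchar(x$sequence), nrow(x$features),
              paste(unique(x$features$module), collapse = ",")))
  invisible(x)
}

#' Degrade a phage genome by deleting whole modules
#'
#' Removes all genes of the dropped modules together with their trailing
#' intergenic sequence; the order of the remaining genes is preserved.
#'
#' @param phage a [phage_genome].
#' @param drop_modules non-empty proper subset of the five modules.
#' @return A degraded [phage_genome].
#' @export
degrade_prophage <- function(phage, drop_modules) {
  stopifnot(inherits(phage, "phage_genome"))
  if (!length(drop_modules))
    stop("drop_modules must be a non-empty subset of the phage modules",
         call. = FALSE)
  if (!all(drop_modules %in% PHAGE_MODULES))
    stop("unknown module in drop_modules", call. = FALSE)
  fx <- phage$features
  if (all(unique(fx$module) %in% drop_modules))
    stop("dropping all modules would leave an empty phage", call. = FALSE)
  n <- nrow(fx)
  span_start <- fx$start
  span_end <- c(fx$start[-1] - 1L, nchar(phage$sequence))
  keep <- !fx$module %in% drop_modules
  pieces <- substring(phage$sequence, span_start[keep], span_end[keep])
  widths <- span_end[keep] - span_start[keep] + 1L
  new_start <- cumsum(c(1L, widths[-length(widths)]))
  out <- fx[keep, , drop = FALSE]
  glen <- out$end - out$start
  out$start <- new_start
  out$end <- new_start + glen
  rownames(out) <- NULL
  structure(list(sequence = paste(pieces, collapse = ""), features = out,
                 gc = phage$gc, template_id = phage$template_id),
            class = "phage_genome")
}

# Insert `content` (sequence + optional feature table in content coords)
# into `genome` after position `site` (0 <= site <= length). Host features
# beyond the site are shifted; a feature straddling the site is an error.
insert_at <- function(genome, site, content_seq, content_features = NULL) {
  n <- nchar(genome$sequence)
  stopifnot(site >= 0L, site <= n)
  fx <- genome$features
  if (nrow(fx) && any(fx$start <= site & fx$end > site))
    stop("insertion site ", site, " lies inside an existing feature",
         call. = FALSE)
  len <- nchar(content_seq)
  if (nrow(fx)) {
    shift <- fx$start > site
    fx$start[shift] <- fx$start[shift] + len
    fx$end[shift] <- fx$end[shift] + len
  }
  if (!is.null(content_features) && nrow(content_features)) {
    cf <- content_features[, c("kind", "start", "end", "strand", "product")]
    cf$start <- cf$start + site
    cf$end <- cf$end + site
    fx <- rbind(fx, cf)
  }
  seq2 <- paste0(substr(genome$sequence, 1L, site), content_seq,
                 substr(genome$sequence, site + 1L, n))
  genome_record(id = genome$id, sequence = seq2, features = fx,
                species_label = genome$species_label, strain = genome$strain)
}

#' Implant a phage genome into a host chromosome
#'
#' Inserts the phage sequence and features at a feature-free site. The host
#' length grows by exactly the phage length. With `trna_adjacent = TRUE` a
#' tRNA feature is annotated on the host within 500 bp of the left implant
#' boundary.
#'
#' @param host a [genome_record].
#' @param phage a [phage_genome].
#' @param site insertion point (sequence position after which the phage is
#'   inserted); chosen uniformly among feature-free positions when `NULL`.
#' @param trna_adjacent annotate an adjacent tRNA gene.
#' @return List with `genome` (new [genome_record]) and `truth` (one-row
#'   data.frame: genome_id, start, end, intact, modules, trna_adjacent,
#'   template_id).
#' @export
implant_prophage <- function(host, phage, site = NULL, trna_adjacent = FALSE) {
  stopifnot(inherits(host, "genome_record"), inherits(phage, "phage_genome"))
  n <- nchar(host$sequence)
  if (is.null(site)) {
    occ <- host$features
    free <- rep(TRUE, n - 1L)
    if (nrow(occ))
      for (i in seq_len(nrow(occ))) {
        lo <- max(1L, occ$start[i] - 100L)
        hi <- min(n - 1L, occ$end[i] + 100L)
        free[lo:hi] <- FALSE
      }
    cand <- which(free)
    if (!length(cand))
      stop("host '", host$id, "' has no feature-free insertion site",
           call. = FALSE)
    site <- cand[sample.int(length(cand), 1L)]
  }
  genome <- insert_at(host, site, phage$sequence, phage$features)
  trna_ok <- FALSE
  if (trna_adjacent) {
    fx <- genome$features
    lo <- site - 450L
    hi <- site - 5L
    if (lo >= 1L) {
      for (s0 in seq(hi - 71L, lo, by = -15L)) {
        iv <- c(s0, s0 + 71L)
        if (!any(fx$start <= iv[2] & fx$end >= iv[1])) {
          fx <- rbind(fx, data.frame(kind = "tRNA", start = iv[1],
                                     end = iv[2], strand = "+",
                                     product = "tRNA-Met",
                                     stringsAsFactors = FALSE))
          trna_ok <- TRUE
          break
        }
      }
    }
    if (trna_ok)
      genome <- genome_record(genome$id, genome$sequence, fx,
                              genome$species_label, genome$strain)
  }
  mods <- paste(unique(phage$features$module), collapse = ",")
  truth <- data.frame(genome_id = host$id, start = site + 1L,
                      end = site + nchar(phage$sequence),
                      intact = setequal(unique(phage$features$module),
                                        PHAGE_MODULES),
                      modules = mods, trna_adjacent = trna_ok,
                      template_id = phage$template_id,
                      stringsAsFactors = FALSE)
  list(genome = genome, truth = truth)
}

#' Implant a CRISPR repeat-spacer array
#'
#' Writes a locus `R S1 R S2 ... R` (`n_spacers` spacers, `n_spacers + 1`
#' identical repeat copies) at a feature-free host site. Spacers are
#' sampled from the implant intervals recorded in `truth` (either strand)
#' and independently mutated per base at `mutation_rate`; provenance
#' (origin interval, strand, mutation count) is recorded. Truth intervals
#' downstream of the insertion are shifted accordingly.
#'
#' @param host a [genome_record] that already carries the implants in
#'   `truth`.
#' @param truth truth table rows for `host` (from [implant_prophage()]).
#' @param n_spacers number of spacers (>= 1).
#' @param mutation_rate per-base substitution probability for spacers.
#' @param site insertion point; random feature-free position when `NULL`.
#' @param array_index ordinal used in spacer ids.
#' @param repeat_len direct repeat length (23-55).
#' @param spacer_len_range spacer length range (within 25-60).
#' @return List with `genome`, updated `truth`, and `spacers` (provenance
#'   table: spacer_id, genome_id, array, index, sequence, origin_start,
#'   origin_end, strand, n_mutations).
#' @export
implant_crispr <- function(host, truth, n_spacers = 5L, mutation_rate = 0,
                           site = NULL, array_index = 1L, repeat_len = 30L,
                           spacer_len_range = c(28L, 42L)) {
  stopifnot(inherits(host, "genome_record"), n_spacers >= 1L,
            repeat_len >= 23L, repeat_len <= 55L)
  truth <- truth[truth$genome_id == host$id, , drop = FALSE]
  if (!nrow(truth))
    stop("truth table has no implant for genome '", host$id, "'",
         call. = FALSE)
  if (min(truth$end - truth$start + 1L) < max(spacer_len_range))
    stop("implant shorter than the spacer length", call. = FALSE)
  n <- nchar(host$sequence)
  if (is.null(site)) {
    occ <- rbind(host$features[, c("start", "end")],
                 data.frame(start = truth$start, end = truth$end))
    free <- rep(TRUE, n - 1L)
    for (i in seq_len(nrow(occ))) {
      lo <- max(1L, occ$start[i] - 100L)
      hi <- min(n - 1L, occ$end[i] + 100L)
      free[lo:hi] <- FALSE
    }
    cand <- which(free)
    if (!length(cand))
      stop("no feature-free site for CRISPR array in '", host$id, "'",
           call. = FALSE)
    site <- cand[sample.int(length(cand), 1L)]
  }
  rep_seq <- sample_dna(repeat_len, gc_content(host$sequence))
  sp <- vector("list", n_spacers)
  for (i in seq_len(n_spacers)) {
    slen <- if (spacer_len_range[1] == spacer_len_range[2])
      spacer_len_range[1] else
      sample(seq(spacer_len_range[1], spacer_len_range[2]), 1L)
    tr <- truth[sample.int(nrow(truth), 1L), ]
    o_start <- sample(tr$start:(tr$end - slen + 1L), 1L)
    o_end <- o_start + slen - 1L
    strand <- sample(c("+", "-"), 1L)
    s <- substring(host$sequence, o_start, o_end)
    if (strand == "-") s <- revcomp(s)
    ch <- strsplit(s, "")[[1]]
    mut <- which(stats::runif(slen) < mutation_rate)
    for (m in mut)
      ch[m] <- sample(setdiff(c("A", "C", "G", "T"), ch[m]), 1L)
    sp[[i]] <- data.frame(
      spacer_id = sprintf("%s_a%d_s%d", host$id, array_index, i),
      genome_id = host$id, array = array_index, index = i,
      sequence = paste(ch, collapse = ""), origin_start = o_start,
      origin_end = o_end, strand = strand, n_mutations = length(mut),
      stringsAsFactors = FALSE)
  }
  spacers <- do.call(rbind, sp)
  locus <- paste0(rep_seq,
                  paste(vapply(spacers$sequence,
                               function(s) paste0(s, rep_seq), ""),
                        collapse = ""))
  cf <- data.frame(kind = "repeat_region", start = 1L, end = nchar(locus),
                   strand = "+", product = "CRISPR repeat-spacer array",
                   stringsAsFactors = FALSE)
  genome <- insert_at(host, site, locus, cf)
  llen <- nchar(locus)
  shift <- truth$start > site
  truth$start[shift] <- truth$start[shift] + llen
  truth$end[shift] <- truth$end[shift] + llen
  oshift <- spacers$origin_start > site
  spacers$origin_start[oshift] <- spacers$origin_start[oshift] + llen
  spacers$origin_end[oshift] <- spacers$origin_end[oshift] + llen
  list(genome = genome, truth = truth, spacers = spacers)
}

#' Generator configuration
#'
#' Defaults describe the simulated study conditions: hosts of ~60% GC
#' carrying 0-6 implanted prophages of 4.5-51.2 kb, a fraction of which are
#' degraded remnants, plus one CRISPR array per phage-carrying genome whose
#' spacers derive from the implants.
#'
#' @param n_genomes number of host genomes.
#' @param host_length host chromosome length in bp before implantation.
#' @param host_gc named GC fractions per species label.
#' @param implants_range inclusive range for the per-genome implant count.
#' @param implant_size_range admissible phage lengths in bp.
#' @param remnant_fraction probability that an implant is a degraded
#'   remnant (structural + packaging modules deleted).
#' @param n_templates number of distinct phage templates shared across the
#'   dataset.
#' @param spacers_per_array spacers per CRISPR array.
#' @param spacer_mutation_rate per-base spacer substitution rate.
#' @param trna_fraction probability that an implant gets an adjacent tRNA.
#' @param seed mandatory RNG seed.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_genomes = 6L, host_length = 100000L,
                             host_gc = SPECIES_GC,
                             implants_range = c(0L, 6L),
                             implant_size_range = c(4500L, 51200L),
                             remnant_fraction = 0.3,
                             n_templates = 4L,
                             spacers_per_array = 5L,
                             spacer_mutation_rate = 0,
                             trna_fraction = 0.7,
                             seed = NULL) {
  if (is.null(seed)) stop("generator_config requires a seed", call. = FALSE)
  stopifnot(n_genomes >= 0L, host_length >= 20000L,
            implants_range[1] <= implants_range[2],
            implant_size_range[1] < implant_size_range[2],
            remnant_fraction >= 0, remnant_fraction <= 1)
  structure(list(n_genomes = as.integer(n_genomes),
                 host_length = as.integer(host_length),
                 host_gc = host_gc,
                 implants_range = as.integer(implants_range),
                 implant_size_range = as.integer(implant_size_range),
                 remnant_fraction = remnant_fraction,
                 n_templates = as.integer(n_templates),
                 spacers_per_array = as.integer(spacers_per_array),
                 spacer_mutation_rate = spacer_mutation_rate,
                 trna_fraction = trna_fraction,
                 seed = as.integer(seed)),
            class = "generator_config")
}

empty_truth <- function() {
  data.frame(genome_id = character(), start = integer(), end = integer(),
             intact = logical(), modules = character(),
             trna_adjacent = logical(), template_id = character(),
             stringsAsFactors = FALSE)
}

# Host chromosome: random DNA at the species GC, background genes tiled
# outside a 1.2 kb exclusion window around the planned insertion sites
# (integration loci sit clear of co-transcribed host operons, so the <1 kb
# same-strand absorption criterion cannot reach host genes). Background
# products never match the phage lexicon, so any candidate region called
# on host background is a false positive by construction.
make_host <- function(id, species, strain, length, gc, sites) {
  seqs <- sample_dna(length, gc)
  rows <- list()
  pos <- 1L
  while (pos + 1800L < length) {
    gap <- sample(200:800, 1L)
    glen <- (sample(600:1500, 1L) %/% 3L) * 3L
    s0 <- pos + gap
    e0 <- s0 + glen - 1L
    if (e0 > length - 100L) break
    clear <- !any(abs(sites - s0) < 1200L | abs(sites - e0) < 1200L |
                    (sites > s0 & sites < e0))
    if (clear)
      rows[[length(rows) + 1L]] <- data.frame(
        kind = "CDS", start = s0, end = e0,
        strand = sample(c("+", "-"), 1L),
        product = sample(HOST_PRODUCTS, 1L), stringsAsFactors = FALSE)
    pos <- e0 + 1L
  }
  fx <- if (length(rows)) do.call(rbind, rows) else empty_features()
  genome_record(id = id, sequence = seqs, features = fx,
                species_label = species, strain = strain)
}

# Well-separated insertion sites, sampled on a jittered grid. The jitter
# stays within 1.5 kb of the slot origin so that any two sites are at
# least min_sep - 1500 bp apart (adjacent implants must never fall within
# candidate-scan merging range of each other).
pick_sites <- function(n_sites, host_length, min_sep = 9000L,
                       margin = 4000L) {
  if (n_sites == 0L) return(integer())
  lo <- margin
  hi <- host_length - margin
  slots <- floor((hi - lo) / min_sep)
  if (slots < n_sites)
    stop("host too short for ", n_sites, " implants", call. = FALSE)
  chosen <- sort(sample.int(slots, n_sites))
  vapply(chosen, function(k) {
    lo + (k - 1L) * min_sep + sample.int(1500L, 1L)
  }, integer(1))
}

#' Generate a complete synthetic dataset with ground truth
#'
#' Builds `n_genomes` annotated host genomes cycling through the four
#' Bifidobacterium species labels, implants intact and remnant prophages
#' drawn from a shared template pool, adds one CRISPR array per
#' phage-carrying genome, and records full ground truth. Deterministic
#' under `config$seed`.
#'
#' Intact implants are realisations of the template pool (lengths spread
#' over the upper part of the configured size range so that a complete
#' phage is structurally classifiable); remnants are the same phages with
#' the head/tail and DNA-packaging modules deleted.
#'
#' @param config a [generator_config].
#' @return List with `genomes` (named list of [genome_record]), `truth`
#'   (implant table), `spacers` (spacer provenance table) and `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  if (config$n_genomes == 0L)
    return(list(genomes = list(), truth = empty_truth(),
                spacers = NULL, config = config))
  species_cycle <- rep_len(c("breve", "longum_longum", "bifidum",
                             "adolescentis", "longum_infantis"),
                           config$n_genomes)
  lo_intact <- max(20000L, config$implant_size_range[1])
  hi <- config$implant_size_range[2]
  targets <- round(seq(lo_intact + 2000L, hi - 4000L,
                       length.out = config$n_templates))
  pool <- vector("list", config$n_templates)
  for (t in seq_len(config$n_templates)) {
    tpl <- scaled_template(targets[t], gc = 0.60, id = sprintf("T%d", t))
    for (try in 1:10) {
      ph <- generate_phage(tpl)
      if (nchar(ph$sequence) >= config$implant_size_range[1] &&
          nchar(ph$sequence) <= hi) break
    }
    pool[[t]] <- ph
  }
  genomes <- list()
  truth_rows <- list()
  spacer_rows <- list()
  for (gi in seq_len(config$n_genomes)) {
    id <- sprintf("g%02d", gi)
    species <- species_cycle[gi]
    strain <- sprintf("S%02d", gi)
    gc <- unname(config$host_gc[[species]])
    k <- if (config$implants_range[1] == config$implants_range[2])
      config$implants_range[1] else
      sample(seq(config$implants_range[1], config$implants_range[2]), 1L)
    n_sites <- k + 1L  # one extra slot for the CRISPR array
    sites <- pick_sites(n_sites, config$host_length)
    host <- make_host(id, species, strain, config$host_length, gc, sites)
    if (k > 0L) {
      array_slot <- sample.int(n_sites, 1L)
      implant_sites <- sites[-array_slot]
      array_site <- sites[array_slot]
      offset <- 0L
      truth <- empty_truth()
      genome <- host
      for (j in seq_len(k)) {
        t_idx <- sample.int(config$n_templates, 1L)
        phage <- pool[[t_idx]]
        intact <- stats::runif(1) >= config$remnant_fraction
        if (!intact)
          phage <- degrade_prophage(phage, c("head_tail", "dna_packaging"))
        trna <- stats::runif(1) < config$trna_fraction
        res <- implant_prophage(genome, phage,
                                site = implant_sites[j] + offset,
                                trna_adjacent = trna)
        genome <- res$genome
        truth <- rbind(truth, res$truth)
        offset <- offset + nchar(phage$sequence)
      }
      # implants were inserted at ascending original sites; an implant lies
      # left of the array iff its original site < array_site
      left_len <- sum((truth$end - truth$start + 1L)[implant_sites < array_site])
      cr <- implant_crispr(genome, truth,
                           n_spacers = config$spacers_per_array,
                           mutation_rate = config$spacer_mutation_rate,
                           site = array_site + left_len,
                           array_index = 1L)
      genome <- cr$genome
      truth <- cr$truth
      spacer_rows[[length(spacer_rows) + 1L]] <- cr$spacers
      truth_rows[[length(truth_rows) + 1L]] <- truth
    } else {
      genome <- host
    }
    genomes[[id]] <- genome
  }
  truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else empty_truth()
  rownames(truth) <- NULL
  spacers <- if (length(spacer_rows)) do.call(rbind, spacer_rows) else NULL
  if (!is.null(spacers)) rownames(spacers) <- NULL
  list(genomes = genomes, truth = truth, spacers = spacers, config = config)
}

#' Write a synthetic dataset to disk
#'
#' Emits a combined FASTA + GFF3 for the genomes, the truth table TSV and
#' the spacer-provenance TSV.
#'
#' @param dataset output of [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return Character vector of the written paths, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genomes.fasta")
  gff <- file.path(dir, "genomes.gff3")
  tt <- file.path(dir, "truth.tsv")
  sp <- file.path(dir, "spacer_provenance.tsv")
  write_genomes(dataset$genomes, fa, gff)
  utils::write.table(dataset$truth, tt, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  spdf <- if (is.null(dataset$spacers)) {
    data.frame(spacer_id = character(), genome_id = character(),
               array = integer(), index = integer(), sequence = character(),
               origin_start = integer(), origin_end = integer(),
               strand = character(), n_mutations = integer())
  } else dataset$spacers
  utils::write.table(spdf, sp, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fa, gff, tt, sp))
}
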
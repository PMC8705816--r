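# End-to-end orchestration: simulate (or read) genomes, detect and curate
# prophage regions, call ORFs, cluster by ANI and gene families, detect
# CRISPR arrays, map protospacers, compute intergenomic distances and
# trees, and score predictions against generator truth. Every stage writes
# plain-text artefacts listed in a manifest; the whole bundle is
# byte-deterministic under the config seed.

#' Pipeline configuration
#'
#' Collects every stage threshold with its default so that a run is fully
#' specified by one serialisable object. Thresholds: candidate scan
#' (`min_hits`, `max_gap`), ANI (`fragment_len`, `ani_threshold`), gene
#' families (`protein_evalue`, `inflation`, `jaccard_min`), CRISPR
#' detection bounds, spacer dedup identity, protospacer significance
#' (`match_evalue`, `match_identity`) and link clustering (`link_t`,
#' `link_F`).
#'
#' @param generator a [generator_config] (used unless `input_fasta` is
#'   given).
#' @param input_fasta,input_gff optional real input (FASTA + GFF3) instead
#'   of simulation; truth-based evaluation is then skipped.
#' @param outdir output directory.
#' @param seed seed for the generator when one is not already configured.
#' @param ... stage threshold overrides (see Details).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = NULL, input_fasta = NULL,
                            input_gff = NULL, outdir = "bifidophage_out",
                            seed = 1L, ...) {
  cfg <- list(
    generator = generator %||% generator_config(seed = seed),
    input_fasta = input_fasta, input_gff = input_gff,
    outdir = outdir,
    min_hits = 4L, max_gap = 5000L,
    fragment_len = 1020L, ani_threshold = 0.9,
    protein_evalue = 1e-5, inflation = 2.0, jaccard_min = 0.5,
    dr_min = 23L, dr_max = 55L, sp_min = 25L, sp_max = 60L,
    min_copies = 3L, dedup_identity = 0.9,
    match_evalue = 0.01, match_identity = 0.98,
    hsp_evalue = 1e-3, link_t = 0.3, link_F = 0.5)
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config fields: ",
                        paste(bad, collapse = ","), call. = FALSE)
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a pipeline configuration as YAML
#'
#' @param config a [pipeline_config].
#' @param path YAML file path.
#' @return `path` (write) or the config (read).
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$generator <- unclass(x$generator)
  # yaml serialises named atomic vectors as plain sequences; keep the
  # per-species names by writing host_gc as a map
  x$generator$host_gc <- as.list(x$generator$host_gc)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  gen <- x$generator
  x$generator <- NULL
  gcfg <- do.call(generator_config, gen[names(gen) != "host_gc"])
  if (!is.null(gen$host_gc)) gcfg$host_gc <- unlist(gen$host_gc)
  do.call(pipeline_config, c(list(generator = gcfg),
                             x[names(x) != "generator"]))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_matrix_tsv <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Read a labelled square matrix written by the pipeline
#'
#' @param path matrix TSV path (first column `id`).
#' @return Numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$id
  m
}

#' Run the complete analysis pipeline
#'
#' Simulates (or reads) the genome set, then runs: candidate scan ->
#' boundary refinement -> completeness classification -> naming -> ORF
#' calling -> fragment ANI + clustering -> protein families (MCL) +
#' cluster selection -> CRISPR array detection + spacer dedup ->
#' protospacer matching + targeted genes -> GBDP distances, NJ trees and
#' link clustering -> recovery evaluation against truth (simulated input
#' only). All artefacts are written under `config$outdir` and listed in
#' `manifest.tsv` with md5 checksums; parameters and stage timings go to
#' `run_log.txt` (which is excluded from the manifest so that the
#' artefact bundle is byte-deterministic under the seed).
#'
#' @param config a [pipeline_config].
#' @return List with `manifest` (data.frame), `regions`, `metrics` (or
#'   `NULL`), and `outdir`, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c("bifidophage pipeline run",
                 paste0("seed: ", config$generator$seed),
                 paste0("config: ", paste(
                   vapply(setdiff(names(config),
                                  c("generator", "input_fasta", "input_gff",
                                    "outdir")),
                          function(k) paste0(k, "=", config[[k]]), ""),
                   collapse = " ")))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    log_lines <<- c(log_lines, sprintf("stage %s: %.2fs", name,
                                       proc.time()[["elapsed"]] - t0))
    res
  }
  files <- character()
  emit <- function(path) files <<- c(files, path)

  # --- input ---
  truth <- NULL; truth_spacers <- NULL
  if (!is.null(config$input_fasta)) {
    genomes <- stage("read", read_genomes(config$input_fasta, "fasta+gff3",
                                          gff = config$input_gff))
  } else {
    dataset <- stage("simulate", generate_dataset(config$generator))
    genomes <- dataset$genomes
    truth <- dataset$truth
    truth_spacers <- dataset$spacers
    emit(write_dataset(dataset, outdir))
  }

  # --- regions ---
  regions <- stage("regions", detect_prophages(
    genomes, min_hits = config$min_hits, max_gap = config$max_gap))
  emit(write_tsv(regions, file.path(outdir, "regions.tsv")))
  emit(write_regions(regions, file.path(outdir, "regions.gff3")))

  region_slices <- list()
  if (nrow(regions))
    for (i in seq_len(nrow(regions)))
      region_slices[[regions$name[i]]] <-
        slice_region(genomes[[regions$genome_id[i]]],
                     regions$start[i], regions$end[i])
  region_seqs <- vapply(region_slices, `[[`, "", "sequence")

  # --- ORFs (with products inherited from the annotation by max overlap) ---
  orfs <- stage("orfs", {
    ol <- lapply(names(region_slices), function(nm) {
      sl <- region_slices[[nm]]
      o <- select_orfs(find_orfs(sl$sequence, region_id = nm))
      if (nrow(o)) {
        cds <- sl$features[sl$features$kind == "CDS", , drop = FALSE]
        o$product <- vapply(seq_len(nrow(o)), function(i) {
          if (!nrow(cds)) return(NA_character_)
          ov <- pmin(cds$end, o$end[i]) - pmax(cds$start, o$start[i]) + 1L
          if (max(ov) <= 0L) return(NA_character_)
          cds$product[which.max(ov)]
        }, "")
      }
      o
    })
    ol <- ol[vapply(ol, nrow, 0L) > 0]
    if (length(ol)) do.call(rbind, ol) else
      cbind(find_orfs("ACGT", region_id = "x")[0, ],
            data.frame(product = character()))
  })
  if (nrow(orfs)) emit(write_protein_fasta(orfs, file.path(outdir, "orf_proteins.fasta")))
  else { writeLines(character(), file.path(outdir, "orf_proteins.fasta"))
         emit(file.path(outdir, "orf_proteins.fasta")) }

  # --- ANI ---
  ani_clusters <- list()
  if (length(region_seqs) >= 2L) {
    am <- stage("ani", ani_matrix(region_seqs,
                                  fragment_len = config$fragment_len))
    emit(write_matrix_tsv(am$ani, file.path(outdir, "ani_matrix.tsv")))
    ani_clusters <- cluster_by_ani(am$ani, config$ani_threshold)
  } else {
    emit(write_tsv(data.frame(id = character()),
                   file.path(outdir, "ani_matrix.tsv")))
    if (length(region_seqs) == 1L) ani_clusters <- list(names(region_seqs))
  }
  cl_df <- if (length(ani_clusters))
    data.frame(cluster = rep(seq_along(ani_clusters),
                             lengths(ani_clusters)),
               region = unlist(ani_clusters)) else
    data.frame(cluster = integer(), region = character())
  emit(write_tsv(cl_df, file.path(outdir, "ani_clusters.tsv")))

  # --- gene families ---
  pa <- NULL
  if (nrow(orfs) >= 2L) {
    fam <- stage("families", {
      graph <- all_vs_all_protein(orfs, evalue_max = config$protein_evalue)
      mc <- mcl(graph, inflation = config$inflation)
      list(graph = graph, mc = mc)
    })
    emit(write_tsv(fam$graph$edges, file.path(outdir, "family_edges.tsv")))
    emit(write_tsv(data.frame(orf_id = names(fam$mc$membership),
                              family = unname(fam$mc$membership)),
                   file.path(outdir, "families.tsv")))
    pa <- presence_absence(orfs, fam$mc$membership)
    emit(write_matrix_tsv(pa, file.path(outdir, "presence_absence.tsv")))
    sel <- select_clusters(ani_clusters, pa, regions, genomes,
                           jaccard_min = config$jaccard_min)
    emit(write_tsv(sel, file.path(outdir, "selected_clusters.tsv")))
  } else {
    for (f in c("family_edges.tsv", "families.tsv", "presence_absence.tsv",
                "selected_clusters.tsv")) {
      writeLines("# empty: fewer than 2 ORFs", file.path(outdir, f))
      emit(file.path(outdir, f))
    }
  }

  # --- CRISPR ---
  arrays <- stage("crispr", {
    al <- lapply(genomes, function(g)
      find_arrays(g, config$dr_min, config$dr_max, config$sp_min,
                  config$sp_max, config$min_copies))
    do.call(c, unname(al))
  })
  sp_tab <- spacer_table(arrays)
  arr_df <- if (length(arrays))
    data.frame(genome_id = vapply(arrays, `[[`, "", "genome_id"),
               start = vapply(arrays, function(a) a$start, 0L),
               end = vapply(arrays, function(a) a$end, 0L),
               repeat_seq = vapply(arrays, `[[`, "", "repeat_seq"),
               n_copies = vapply(arrays, function(a) length(a$copy_starts), 0L),
               n_spacers = vapply(arrays, function(a) nrow(a$spacers), 0L)) else
    data.frame(genome_id = character(), start = integer(), end = integer(),
               repeat_seq = character(), n_copies = integer(),
               n_spacers = integer())
  emit(write_tsv(arr_df, file.path(outdir, "crispr_arrays.tsv")))
  if (nrow(sp_tab)) {
    ss <- Biostrings::DNAStringSet(sp_tab$sequence)
    names(ss) <- sp_tab$spacer_id
    Biostrings::writeXStringSet(ss, file.path(outdir, "spacers.fasta"))
  } else writeLines(character(), file.path(outdir, "spacers.fasta"))
  emit(file.path(outdir, "spacers.fasta"))
  reps <- NULL
  if (nrow(sp_tab)) {
    dd <- dedupe_spacers(sp_tab, config$dedup_identity)
    reps <- dd$representatives
    emit(write_tsv(dd$cluster_map, file.path(outdir, "spacer_clusters.tsv")))
  } else {
    writeLines("spacer_id\trepresentative",
               file.path(outdir, "spacer_clusters.tsv"))
    emit(file.path(outdir, "spacer_clusters.tsv"))
  }

  # --- protospacer matching ---
  hits <- empty_hits()
  if (!is.null(reps) && length(region_seqs))
    hits <- stage("match", match_spacers(reps, region_seqs,
                                         config$match_evalue,
                                         config$match_identity))
  emit(write_tsv(hits, file.path(outdir, "protospacer_hits.tsv")))
  uh <- unique_hit_sequences(hits)
  emit(write_tsv(uh$intervals, file.path(outdir, "unique_hits.tsv")))
  tg <- targeted_genes(hits, orfs)
  emit(write_tsv(tg, file.path(outdir, "target_genes.tsv")))

  # --- phylogeny ---
  if (length(region_seqs) >= 3L) {
    dm <- stage("phylo", gbdp_matrix(region_seqs,
                                     evalue_max = config$hsp_evalue))
    for (f in c("d0", "d4", "d6")) {
      emit(write_matrix_tsv(dm[[f]], file.path(outdir,
                                               sprintf("distance_%s.tsv", f))))
      tr <- midpoint_root(nj_tree(dm[[f]]))
      ape::write.tree(tr, file.path(outdir, sprintf("tree_%s.nwk", f)))
      emit(file.path(outdir, sprintf("tree_%s.nwk", f)))
    }
    lk <- link_clusters(dm$d6, t = config$link_t, F = config$link_F)
    emit(write_tsv(data.frame(region = names(lk), cluster = unname(lk)),
                   file.path(outdir, "phylo_clusters.tsv")))
  } else {
    for (f in c("distance_d0.tsv", "distance_d4.tsv", "distance_d6.tsv",
                "tree_d0.nwk", "tree_d4.nwk", "tree_d6.nwk",
                "phylo_clusters.tsv")) {
      writeLines("# empty: fewer than 3 regions", file.path(outdir, f))
      emit(file.path(outdir, f))
    }
  }

  # --- evaluation ---
  metrics <- NULL
  if (!is.null(truth)) {
    metrics <- evaluate_recovery(regions, truth, sp_tab, truth_spacers,
                                 hits, region_seqs)
    emit(write_tsv(recovery_to_df(metrics),
                   file.path(outdir, "recovery_metrics.tsv")))
  }

  files <- unique(unlist(files))
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), , drop = FALSE]
  rownames(manifest) <- NULL
  write_tsv(manifest, file.path(outdir, "manifest.tsv"))
  writeLines(log_lines, file.path(outdir, "run_log.txt"))
  invisible(list(manifest = manifest, regions = regions, metrics = metrics,
                 outdir = outdir))
}

recovery_to_df <- function(m) {
  data.frame(metric = c("region_precision", "region_recall",
                        "mean_boundary_error_bp",
                        "intact_likely_complete", "intact_total",
                        "degraded_remnant", "degraded_total",
                        "spacer_recovery", "protospacer_recall",
                        "protospacer_precision"),
             value = c(m$region_precision, m$region_recall,
                       m$mean_boundary_error_bp,
                       m$intact_likely_complete, m$intact_total,
                       m$degraded_remnant, m$degraded_total,
                       m$spacer_recovery, m$protospacer_recall,
                       m$protospacer_precision))
}

#' Score pipeline predictions against generator truth
#'
#' Regions are matched to truth implants by >= 50% reciprocal overlap.
#' Precision is the fraction of predicted regions matching a truth
#' implant (1 by convention when there are no predictions); recall the
#' fraction of implants recovered; boundary error the mean of
#' `(|start error| + |end error|) / 2` over matches. Completeness counts
#' report how many matched intact implants were classified
#' `likely_complete` and how many matched degraded implants `remnant`.
#' Spacer recovery is the fraction of truth spacers recovered verbatim
#' (either strand) among detected spacers. Protospacer recall is the
#' fraction of mutation-free truth spacers whose origin locus is covered
#' by a hit in the region holding it; precision the fraction of hits
#' whose targeted subsequence matches a truth spacer verbatim (either
#' strand).
#'
#' @param regions region table from [detect_prophages()].
#' @param truth truth table from [generate_dataset()].
#' @param detected_spacers spacer table from [spacer_table()] (optional).
#' @param truth_spacers spacer provenance from the generator (optional).
#' @param hits protospacer hits (optional).
#' @param region_seqs named region sequences (needed for protospacer
#'   precision).
#' @return List of class `recovery_metrics`.
#' @export
evaluate_recovery <- function(regions, truth, detected_spacers = NULL,
                              truth_spacers = NULL, hits = NULL,
                              region_seqs = NULL) {
  if (nrow(regions) && nrow(truth) &&
      !any(regions$genome_id %in% truth$genome_id))
    stop("regions and truth share no genome ids", call. = FALSE)
  match_of_truth <- rep(NA_integer_, nrow(truth))
  matched_pred <- logical(nrow(regions))
  berr <- numeric(0)
  for (ti in seq_len(nrow(truth))) {
    tl <- truth$end[ti] - truth$start[ti] + 1L
    for (ri in seq_len(nrow(regions))) {
      if (regions$genome_id[ri] != truth$genome_id[ti]) next
      ov <- min(regions$end[ri], truth$end[ti]) -
        max(regions$start[ri], truth$start[ti]) + 1L
      if (ov <= 0L) next
      rl <- regions$length[ri]
      if (ov >= 0.5 * rl && ov >= 0.5 * tl) {
        match_of_truth[ti] <- ri
        matched_pred[ri] <- TRUE
        berr <- c(berr, (abs(regions$start[ri] - truth$start[ti]) +
                           abs(regions$end[ri] - truth$end[ti])) / 2)
        break
      }
    }
  }
  precision <- if (!nrow(regions)) 1 else mean(matched_pred)
  recall <- if (!nrow(truth)) 1 else mean(!is.na(match_of_truth))
  intact_idx <- which(truth$intact & !is.na(match_of_truth))
  degraded_idx <- which(!truth$intact & !is.na(match_of_truth))
  intact_lc <- sum(regions$completeness[match_of_truth[intact_idx]] ==
                     "likely_complete")
  degr_rem <- sum(regions$completeness[match_of_truth[degraded_idx]] ==
                    "remnant")
  sp_rec <- NA_real_
  if (!is.null(truth_spacers) && nrow(truth_spacers)) {
    det <- if (!is.null(detected_spacers)) detected_spacers$sequence else character()
    sp_rec <- mean(vapply(truth_spacers$sequence, function(s)
      s %in% det || revcomp(s) %in% det, TRUE))
  }
  ps_recall <- ps_prec <- NA_real_
  if (!is.null(hits) && !is.null(truth_spacers) && nrow(truth_spacers)) {
    mut_free <- truth_spacers[truth_spacers$n_mutations == 0L, , drop = FALSE]
    if (nrow(mut_free)) {
      ok <- vapply(seq_len(nrow(mut_free)), function(i) {
        g <- mut_free$genome_id[i]
        o0 <- mut_free$origin_start[i]; o1 <- mut_free$origin_end[i]
        cand <- which(regions$genome_id == g & regions$start <= o0 &
                        regions$end >= o1)
        if (!length(cand)) return(NA)  # origin implant not detected
        rn <- regions$name[cand[1]]
        rs <- regions$start[cand[1]]
        h <- hits[hits$region == rn, , drop = FALSE]
        if (!nrow(h)) return(FALSE)
        any(h$sstart + rs - 1L <= o1 & h$send + rs - 1L >= o0)
      }, TRUE)
      ps_recall <- if (all(is.na(ok))) NA_real_ else mean(ok, na.rm = TRUE)
    }
    if (nrow(hits) && !is.null(region_seqs)) {
      tseq <- truth_spacers$sequence
      ps_prec <- mean(vapply(seq_len(nrow(hits)), function(i) {
        sub <- substring(region_seqs[[hits$region[i]]], hits$sstart[i],
                         hits$send[i])
        any(vapply(tseq, function(s)
          grepl(sub, s, fixed = TRUE) || grepl(s, sub, fixed = TRUE) ||
            grepl(sub, revcomp(s), fixed = TRUE) ||
            grepl(revcomp(s), sub, fixed = TRUE), TRUE))
      }, TRUE))
    } else if (!is.null(hits) && !nrow(hits)) ps_prec <- 1
  }
  structure(list(region_precision = precision, region_recall = recall,
                 mean_boundary_error_bp = if (length(berr)) mean(berr) else NA_real_,
                 intact_likely_complete = intact_lc,
                 intact_total = length(intact_idx),
                 degraded_remnant = degr_rem,
                 degraded_total = length(degraded_idx),
                 spacer_recovery = sp_rec,
                 protospacer_recall = ps_recall,
                 protospacer_precision = ps_prec),
            class = "recovery_metrics")
}

#' @export
print.recovery_metrics <- function(x, ...) {
  cat(sprintf(paste0(
    "<recovery_metrics>\n",
    "  region precision %.3f, recall %.3f, boundary error %.1f bp\n",
    "  intact -> likely_complete: %d/%d; degraded -> remnant: %d/%d\n",
    "  spacer recovery %.3f; protospacer recall %.3f, precision %.3f\n"),
    x$region_precision, x$region_recall, x$mean_boundary_error_bp,
    x$intact_likely_complete, x$intact_total, x$degraded_remnant,
    x$degraded_total, x$spacer_recovery, x$protospacer_recall,
    x$protospacer_precision))
  invisible(x)
}
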
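test_that("phage templates enforce the modular architecture invariants", {
  expect_no_error(phage_template(module_order = c("lysis", "head_tail",
                                                  "dna_packaging",
                                                  "dna_replication",
                                                  "integration_excision")))
  expect_error(phage_template(module_order = c("lysis",
                                               "integration_excision",
                                               "head_tail", "dna_packaging",
                                               "dna_replication")),
               "first or last")
  expect_error(phage_template(module_order = c("integration_excision",
                                               "head_tail", "lysis",
                                               "dna_packaging",
                                               "dna_replication")),
               "adjacent")
  expect_error(phage_template(genes_per_module = c(integration_excision = 0L,
                                                   lysis = 2L,
                                                   dna_replication = 6L,
                                                   head_tail = 8L,
                                                   dna_packaging = 3L)),
               ">= 1 gene")
})

test_that("generated phages have one integrase, capsid genes, clean ORFs and no overlaps", {
  set.seed(10)
  ph <- generate_phage(phage_template())
  prods <- ph$features$product
  expect_equal(sum(prods == "integrase"), 1L)
  expect_gte(sum(prods == "major capsid protein"), 1L)
  expect_equal(ph$features$start[1], 1L)  # integrase at the boundary
  expect_equal(ph$features$product[1], "integrase")
  expect_equal(ph$features$end[nrow(ph$features)], nchar(ph$sequence))
  # no overlapping genes
  expect_true(all(ph$features$start[-1] > ph$features$end[-nrow(ph$features)]))
  # genes really are ORFs in the annotated frame
  for (i in c(1L, 5L, nrow(ph$features))) {
    nt <- substr(ph$sequence, ph$features$start[i], ph$features$end[i])
    if (ph$features$strand[i] == "-") nt <- revcomp(nt)
    expect_equal(substr(nt, 1, 3), "ATG")
    expect_true(substr(nt, nchar(nt) - 2, nchar(nt)) %in%
                  c("TAA", "TAG", "TGA"))
    aa <- translate_dna(nt, initiator = TRUE)
    expect_false(grepl("*", aa, fixed = TRUE))
  }
  # determinism under the RNG seed
  set.seed(10)
  ph2 <- generate_phage(phage_template())
  expect_identical(ph2$sequence, ph$sequence)
})

test_that("phages from the dataset templates respect the configured size range", {
  set.seed(2)
  sizes <- replicate(10, {
    tpl <- bifidophage:::scaled_template(sample(22000:47000, 1))
    nchar(generate_phage(tpl)$sequence)
  })
  expect_true(all(sizes >= 4500 & sizes <= 51200))
})

test_that("module degradation removes exactly the dropped gene+intergenic spans", {
  set.seed(11)
  ph <- generate_phage(phage_template())
  rem <- degrade_prophage(ph, c("head_tail", "dna_packaging"))
  expect_false(any(grepl("capsid|terminase|portal", rem$features$product)))
  expect_true(all(c("integrase", "holin") %in% rem$features$product))
  # gene order preserved
  expect_identical(rem$features$product,
                   ph$features$product[!ph$features$module %in%
                                         c("head_tail", "dna_packaging")])
  # length arithmetic: dropping lysis removes its gene+trailing-gap spans
  fx <- ph$features
  span_end <- c(fx$start[-1] - 1L, nchar(ph$sequence))
  lys <- fx$module == "lysis"
  removed <- sum(span_end[lys] - fx$start[lys] + 1L)
  rem2 <- degrade_prophage(ph, "lysis")
  expect_equal(nchar(ph$sequence) - nchar(rem2$sequence), removed)
  expect_error(degrade_prophage(ph, character()), "non-empty")
  expect_error(degrade_prophage(ph, bifidophage:::PHAGE_MODULES), "empty phage")
})

test_that("prophage implantation conserves length and places tRNA near the boundary", {
  set.seed(12)
  host <- mk_genome(len = 100000)
  ph <- generate_phage(bifidophage:::scaled_template(20000))
  res <- implant_prophage(host, ph, site = 50000L, trna_adjacent = TRUE)
  expect_equal(nchar(res$genome$sequence),
               nchar(host$sequence) + nchar(ph$sequence))
  expect_equal(res$truth$start, 50001L)
  expect_equal(res$truth$end, 50000L + nchar(ph$sequence))
  expect_identical(substr(res$genome$sequence, res$truth$start,
                          res$truth$end), ph$sequence)
  expect_true(res$truth$intact)
  tr <- res$genome$features[res$genome$features$kind == "tRNA", ]
  expect_equal(nrow(tr), 1L)
  expect_lte(res$truth$start - tr$end, 500L)
  # determinism with two implants
  set.seed(77)
  h <- mk_genome(len = 100000)
  r1 <- implant_prophage(h, ph)
  r1 <- implant_prophage(r1$genome, ph)
  set.seed(77)
  h2 <- mk_genome(len = 100000)
  r2 <- implant_prophage(h2, ph)
  r2 <- implant_prophage(r2$genome, ph)
  expect_identical(r1$truth, r2$truth)
  expect_identical(r1$genome$sequence, r2$genome$sequence)
})

test_that("CRISPR implantation writes R S1 R ... R with exact provenance", {
  set.seed(13)
  host <- mk_genome(len = 60000)
  ph <- generate_phage(bifidophage:::scaled_template(22000))
  imp <- implant_prophage(host, ph, site = 30000L)
  cr <- implant_crispr(imp$genome, imp$truth, n_spacers = 3L,
                       mutation_rate = 0, site = 10000L)
  # locus layout: 4 identical repeat copies around 3 spacers
  locus_len <- 4L * 30L + sum(nchar(cr$spacers$sequence))
  locus <- substr(cr$genome$sequence, 10001L, 10000L + locus_len)
  rep_seq <- substr(locus, 1, 30)
  expect_equal(length(gregexpr(rep_seq, locus, fixed = TRUE)[[1]]), 4L)
  # mutation-free spacers occur verbatim inside their origin interval
  for (i in 1:3) {
    o <- substr(cr$genome$sequence, cr$spacers$origin_start[i],
                cr$spacers$origin_end[i])
    if (cr$spacers$strand[i] == "-") o <- revcomp(o)
    expect_identical(cr$spacers$sequence[i], o)
    expect_gte(cr$spacers$origin_start[i], cr$truth$start)
    expect_lte(cr$spacers$origin_end[i], cr$truth$end)
  }
  expect_error(implant_crispr(host, imp$truth[0, ], 3L), "no implant")
})

test_that("spacer mutation load matches the binomial expectation", {
  set.seed(14)
  host <- mk_genome(len = 60000)
  ph <- generate_phage(bifidophage:::scaled_template(22000))
  imp <- implant_prophage(host, ph, site = 30000L)
  muts <- unlist(replicate(200, {
    cr <- implant_crispr(imp$genome, imp$truth, n_spacers = 5L,
                         mutation_rate = 0.05, site = 10000L,
                         spacer_len_range = c(33L, 33L))
    cr$spacers$n_mutations
  }, simplify = FALSE))
  # 1000 spacers of 33 bp at rate 0.05: mean 1.65, binomial 99.9% CI
  expect_equal(length(muts), 1000L)
  se <- sqrt(33 * 0.05 * 0.95 / 1000)
  expect_lt(abs(mean(muts) - 1.65), 3.3 * se)
})

test_that("dataset generation is deterministic, truth-complete and length-conserving", {
  cfg <- generator_config(n_genomes = 2L, implants_range = c(1L, 2L),
                          seed = 5L)
  ds <- generate_dataset(cfg)
  ds2 <- generate_dataset(cfg)
  expect_identical(lapply(ds$genomes, `[[`, "sequence"),
                   lapply(ds2$genomes, `[[`, "sequence"))
  expect_identical(ds$truth, ds2$truth)
  expect_identical(ds$spacers, ds2$spacers)
  # byte-identical FASTA
  tmp <- withr::local_tempdir()
  write_dataset(ds, file.path(tmp, "a"))
  write_dataset(ds2, file.path(tmp, "b"))
  expect_identical(unname(tools::md5sum(file.path(tmp, "a", "genomes.fasta"))),
                   unname(tools::md5sum(file.path(tmp, "b", "genomes.fasta"))))
  # length conservation: host + implants + CRISPR loci = final length
  for (gid in names(ds$genomes)) {
    tr <- ds$truth[ds$truth$genome_id == gid, ]
    sp <- ds$spacers[ds$spacers$genome_id == gid, ]
    locus <- if (nrow(sp)) (nrow(sp) + 1L) * 30L +
      sum(nchar(sp$sequence)) else 0L
    expect_equal(nchar(ds$genomes[[gid]]$sequence),
                 cfg$host_length + sum(tr$end - tr$start + 1L) + locus)
    expect_true(all(tr$start >= 1 & tr$end <= nchar(ds$genomes[[gid]]$sequence)))
  }
  # provenance soundness at mutation rate 0
  for (i in seq_len(nrow(ds$spacers))) {
    g <- ds$genomes[[ds$spacers$genome_id[i]]]
    o <- substr(g$sequence, ds$spacers$origin_start[i],
                ds$spacers$origin_end[i])
    if (ds$spacers$strand[i] == "-") o <- revcomp(o)
    expect_identical(ds$spacers$sequence[i], o)
  }
  # empty and all-remnant configurations
  e <- generate_dataset(generator_config(n_genomes = 0L, seed = 1L))
  expect_length(e$genomes, 0L)
  expect_equal(nrow(e$truth), 0L)
  allrem <- generate_dataset(generator_config(n_genomes = 2L,
                                              implants_range = c(1L, 2L),
                                              remnant_fraction = 1,
                                              seed = 6L))
  expect_false(any(allrem$truth$intact))
})
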
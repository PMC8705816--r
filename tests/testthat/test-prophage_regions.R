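test_that("candidate scanning finds lexicon runs and nothing else", {
  set.seed(31)
  g <- mk_genome(len = 50000, feats = rbind(
    cds_row(1000, 1900, "ABC transporter permease"),
    cds_row(3000, 3900, "sugar kinase")))
  expect_equal(nrow(scan_candidates(g)), 0L)
  # one implant -> one candidate overlapping truth
  host <- mk_genome(len = 60000)
  ph <- generate_phage(bifidophage:::scaled_template(22000))
  res <- implant_prophage(host, ph, site = 20000L)
  cands <- scan_candidates(res$genome)
  expect_equal(nrow(cands), 1L)
  expect_lt(max(res$truth$start, cands$start[1]),
            min(res$truth$end, cands$end[1]))
  # two implants far apart -> two disjoint candidates
  res2 <- implant_prophage(res$genome, ph,
                           site = 55000L + nchar(ph$sequence))
  cands2 <- scan_candidates(res2$genome)
  expect_equal(nrow(cands2), 2L)
  expect_lt(cands2$end[1], cands2$start[2])
})

test_that("boundary refinement absorbs close anchors but respects distance rules", {
  set.seed(32)
  # five same-strand phage CDS forming the candidate, plus flanking features
  feats <- rbind(
    cds_row(9000, 9800, "integrase"),               # 800 bp gap to candidate
    cds_row(10601, 11500, "holin"),
    cds_row(11601, 12500, "major capsid protein"),
    cds_row(12601, 13500, "terminase large subunit"),
    cds_row(13601, 14500, "portal protein"),
    cds_row(16100, 17000, "ABC transporter permease"))  # 1.6 kb beyond: kept out
  g <- mk_genome(len = 30000, feats = feats)
  cand <- c(10601L, 14500L)
  iv <- refine_boundaries(cand, g)
  expect_equal(iv[1], 9000L)   # integrase absorbed (criterion i)
  expect_equal(iv[2], 14500L)  # same-strand CDS 1.6 kb away not absorbed
  # a same-strand CDS 500 bp away is absorbed by co-transcription
  feats2 <- rbind(feats[-6, ], cds_row(15001, 15900, "hypothetical protein"))
  g2 <- mk_genome(len = 30000, feats = feats2)
  iv2 <- refine_boundaries(cand, g2)
  expect_equal(iv2[2], 15900L)
  # but not when it sits on the opposite strand
  feats3 <- rbind(feats[-6, ],
                  cds_row(15001, 15900, "hypothetical protein", strand = "-"))
  g3 <- mk_genome(len = 30000, feats = feats3)
  expect_equal(refine_boundaries(cand, g3)[2], 14500L)
  # hypothetical run capped by a phage gene is bridged (criterion ii)
  feats4 <- rbind(feats[-1, ],
                  cds_row(8000, 8500, "excisionase", strand = "-"),
                  cds_row(9000, 9500, "hypothetical protein", strand = "-"),
                  cds_row(9700, 10500, "hypothetical protein", strand = "-"))
  g4 <- mk_genome(len = 30000, feats = feats4)
  expect_equal(refine_boundaries(cand, g4)[1], 8000L)
})

test_that("refinement is idempotent, widening-only and capped", {
  set.seed(33)
  cfg <- generator_config(n_genomes = 2L, implants_range = c(1L, 2L),
                          seed = 33L)
  ds <- generate_dataset(cfg)
  for (g in ds$genomes) {
    cands <- scan_candidates(g)
    for (i in seq_len(nrow(cands))) {
      cand <- c(cands$start[i], cands$end[i])
      once <- refine_boundaries(cand, g)
      twice <- refine_boundaries(once, g)
      expect_identical(once, twice)
      expect_lte(once[1], cand[1])
      expect_gte(once[2], cand[2])
      expect_lte(cand[1] - once[1], 15000L)
      expect_lte(once[2] - cand[2], 15000L)
    }
  }
})

test_that("completeness classification implements the size/module rules", {
  all5 <- bifidophage:::PHAGE_MODULES
  expect_equal(classify_completeness(12000, all5, TRUE), "remnant")
  expect_equal(classify_completeness(35000, all5, TRUE), "likely_complete")
  expect_equal(classify_completeness(25000,
                                     c("integration_excision", "lysis")),
               "remnant")
  expect_equal(classify_completeness(22000, all5, TRUE), "likely_complete")
  expect_equal(classify_completeness(22000, all5, FALSE), "partial")
  expect_equal(classify_completeness(22000, setdiff(all5, "lysis"), TRUE),
               "likely_complete")
  expect_equal(classify_completeness(15000, all5, TRUE), "partial")
  expect_error(classify_completeness(0, all5), "zero-length")
  # monotone: adding a module never moves the class toward remnant
  rank <- c(remnant = 1L, partial = 2L, likely_complete = 3L)
  for (len in c(5000, 14000, 21000, 25000, 31000)) {
    for (drop in seq_along(all5)) {
      less <- classify_completeness(len, all5[-drop], TRUE)
      more <- classify_completeness(len, all5, TRUE)
      expect_gte(rank[[more]], rank[[less]])
    }
  }
})

test_that("prophage naming follows the species-strain-ordinal scheme", {
  expect_equal(name_prophage("bifidum", "BIOML-A4", 1), "BifBIOML-A4ph1")
  expect_equal(name_prophage("breve", "BR3", 5), "BreBR3ph5")
  expect_equal(name_prophage("adolescentis", "X", 2), "BadXph2")
  expect_equal(name_prophage("longum_longum", "NCC2705", 1),
               "BlongNCC2705ph1")
  expect_error(name_prophage("other", "X", 1), "abbreviation")
})

test_that("size summaries report count, quantiles, binned mode and per-genome mean", {
  s <- size_summary(c(4000, 4000, 9000), n_genomes = 2L)
  expect_equal(s$median, 4000)
  expect_equal(s$mode, 4000)
  expect_equal(s$count, 3L)
  # the published ratio: 480 regions over 585 genomes -> 0.82 per genome
  s2 <- size_summary(rep(10000, 480), n_genomes = 585L)
  expect_equal(s2$mean_per_genome, 0.82)
  s3 <- size_summary(12345, n_genomes = 1L)
  expect_equal(s3$min, s3$max)
  expect_equal(s3$median, 12345)
  expect_equal(s3$mode, 12300)
  s0 <- size_summary(numeric(0), n_genomes = 3L)
  expect_equal(s0$count, 0L)
  expect_true(is.na(s0$median))
})

test_that("detected regions on synthetic data recover truth intervals and classes", {
  cfg <- generator_config(n_genomes = 3L, implants_range = c(1L, 3L),
                          seed = 34L)
  ds <- generate_dataset(cfg)
  regs <- detect_prophages(ds$genomes)
  m <- evaluate_recovery(regs, ds$truth)
  expect_equal(m$region_precision, 1)
  expect_equal(m$region_recall, 1)
  expect_lte(m$mean_boundary_error_bp, 500)
  expect_equal(m$intact_likely_complete, m$intact_total)
  expect_equal(m$degraded_remnant, m$degraded_total)
  expect_false(anyDuplicated(regs$name) > 0)
})
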
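test_that("protospacer matching enforces both significance cut-offs", {
  set.seed(71)
  reg <- rand_dna(20000, gc = 0.6)
  sp <- substring(reg, 5001, 5033)
  sp1 <- sp
  substr(sp1, 17, 17) <- setdiff(c("A", "C", "G", "T"),
                                 substring(sp1, 17, 17))[1]
  absent <- rand_dna(33)
  hits <- match_spacers(
    data.frame(spacer_id = c("exact", "onesub", "absent"),
               sequence = c(sp, sp1, absent)),
    c(r1 = reg))
  expect_equal(hits$spacer_id, "exact")
  expect_equal(hits$identity, 1)
  expect_equal(hits$sstart, 5001L)
  expect_equal(hits$send, 5033L)
  expect_lte(hits$evalue, 0.01)
  # 32/33 = 0.970 < 0.98: the one-substitution spacer is rejected,
  # and every returned hit satisfies both cut-offs by construction
  expect_false("onesub" %in% hits$spacer_id)
  expect_false("absent" %in% hits$spacer_id)
  expect_true(all(hits$identity >= 0.98 & hits$evalue <= 0.01))
})

test_that("matching is strand-symmetric under region reverse complement", {
  set.seed(72)
  reg <- rand_dna(15000)
  sp <- substring(reg, 8001, 8035)
  h1 <- match_spacers(data.frame(spacer_id = "s", sequence = sp),
                      c(r = reg))
  h2 <- match_spacers(data.frame(spacer_id = "s", sequence = sp),
                      c(r = revcomp(reg)))
  expect_equal(nrow(h1), 1L)
  expect_equal(nrow(h2), 1L)
  n <- nchar(reg)
  expect_equal(h2$sstart, n - h1$send + 1L)
  expect_equal(h2$send, n - h1$sstart + 1L)
  expect_equal(h2$identity, h1$identity)
  expect_equal(h2$evalue, h1$evalue)
  expect_true(h1$strand != h2$strand)
})

test_that("unique hit sequences merge overlapping subject intervals", {
  h <- function(s, e) data.frame(spacer_id = "x", region = "r",
                                 sstart = s, send = e, strand = "+",
                                 identity = 1, alen = e - s + 1L,
                                 score = 60, evalue = 1e-6)
  two_same <- rbind(h(100, 132), h(100, 132))
  expect_equal(unique_hit_sequences(two_same)$count, 1L)
  disjoint <- rbind(h(100, 132), h(500, 532))
  expect_equal(unique_hit_sequences(disjoint)$count, 2L)
  chain <- rbind(h(100, 140), h(130, 170), h(160, 200))
  u <- unique_hit_sequences(chain)
  expect_equal(u$count, 1L)
  expect_equal(u$intervals$start, 100L)
  expect_equal(u$intervals$end, 200L)
  expect_equal(unique_hit_sequences(bifidophage:::empty_hits())$count, 0L)
})

test_that("hits are assigned to the maximally overlapping ORF", {
  orfs <- data.frame(orf_id = c("r|1", "r|2"), region_id = "r",
                     start = c(100L, 431L), end = c(430L, 700L),
                     strand = "+", frame = 0L, protein = "M",
                     product = c("major capsid protein", "tail protein"))
  h <- function(s, e) data.frame(spacer_id = "x", region = "r",
                                 sstart = s, send = e, strand = "+",
                                 identity = 1, alen = e - s + 1L,
                                 score = 60, evalue = 1e-6)
  # fully inside ORF 1
  tg <- targeted_genes(h(200, 232), orfs)
  expect_equal(tg$orf_id, "r|1")
  expect_equal(tg$n_supporting_hits, 1L)
  expect_equal(tg$product, "major capsid protein")
  # straddling 30 bp / 3 bp: the 30 bp side wins
  tg2 <- targeted_genes(h(401, 433), orfs)
  expect_equal(tg2$orf_id, "r|1")
  # no overlap -> intergenic
  tg3 <- targeted_genes(h(900, 932), orfs)
  expect_equal(tg3$orf_id, "intergenic")
  # aggregation counts distinct spacers
  hh <- rbind(h(200, 232), h(210, 242))
  hh$spacer_id <- c("a", "b")
  tg4 <- targeted_genes(hh, orfs)
  expect_equal(tg4$n_supporting_hits, 2L)
  expect_equal(tg4$n_distinct_spacers, 2L)
})

test_that("mutation-free implanted spacers are recovered as perfect protospacers", {
  cfg <- generator_config(n_genomes = 2L, implants_range = c(1L, 2L),
                          seed = 73L)
  ds <- generate_dataset(cfg)
  regs <- detect_prophages(ds$genomes)
  seqs <- setNames(vapply(seq_len(nrow(regs)), function(i)
    slice_region(ds$genomes[[regs$genome_id[i]]], regs$start[i],
                 regs$end[i])$sequence, ""), regs$name)
  arrays <- do.call(c, unname(lapply(ds$genomes, find_arrays)))
  st <- spacer_table(arrays)
  dd <- dedupe_spacers(st)
  hits <- match_spacers(dd$representatives, seqs)
  m <- evaluate_recovery(regs, ds$truth, st, ds$spacers, hits, seqs)
  expect_equal(m$spacer_recovery, 1)
  expect_equal(m$protospacer_recall, 1)
  expect_equal(m$protospacer_precision, 1)
  expect_true(all(hits$identity >= 0.98))
})
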
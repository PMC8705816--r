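test_that("fasta+gff3 reading attaches features per record and keeps 1-based coordinates", {
  set.seed(1)
  tmp <- withr::local_tempdir()
  fa <- file.path(tmp, "g.fasta")
  gff <- file.path(tmp, "g.gff3")
  seqs <- vapply(1:3, function(i) rand_dna(2000), "")
  writeLines(c(rbind(sprintf(">s%d species=breve strain=X%d", 1:3, 1:3),
                     seqs)), fa)
  gff_lines <- c("##gff-version 3",
    "s1\tx\tCDS\t1\t300\t.\t+\t0\tID=a1;product=integrase",
    "s1\tx\ttRNA\t400\t475\t.\t+\t.\tID=a2;product=tRNA-Met",
    "s2\tx\tCDS\t10\t90\t.\t-\t0\tID=b1;product=holin",
    "s3\tx\tCDS\t5\t64\t.\t+\t0\tID=c1;product=terminase",
    "s3\tx\tCDS\t100\t199\t.\t+\t0\tID=c2;product=portal protein")
  writeLines(gff_lines, gff)
  gs <- read_genomes(fa, "fasta+gff3", gff = gff)
  expect_named(gs, c("s1", "s2", "s3"))
  # feature counts agree with an independent text scan of the GFF3
  txt_counts <- table(vapply(strsplit(gff_lines[-1], "\t"), `[`, "", 1))
  expect_equal(vapply(gs, function(g) nrow(g$features), 0L),
               c(s1 = 2L, s2 = 1L, s3 = 2L))
  expect_equal(unname(txt_counts[c("s1", "s2", "s3")]),
               unname(table(c(rep("s1", 2), "s2", rep("s3", 2)))))
  # 1-based inclusive coordinates pass through unchanged
  expect_equal(gs$s1$features$start[1], 1L)
  expect_equal(gs$s1$features$end[1], 300L)
  expect_equal(gs$s1$features$kind, c("CDS", "tRNA"))
  expect_equal(gs$s2$features$strand, "-")
  expect_equal(gs$s1$species_label, "breve")
  expect_equal(gs$s2$strain, "X2")
})

test_that("genbank flat files parse records, organisms and feature locations", {
  tmp <- withr::local_tempdir()
  gb <- file.path(tmp, "t.gb")
  writeLines(c(
    "LOCUS       REC1            60 bp    DNA     linear   BCT 01-JAN-2000",
    "DEFINITION  test record.",
    "FEATURES             Location/Qualifiers",
    "     source          1..60",
    "                     /organism=\"Bifidobacterium longum subsp. infantis\"",
    "                     /strain=\"ATCC15697\"",
    "     CDS             1..30",
    "                     /product=\"integrase\"",
    "     tRNA            complement(40..55)",
    "                     /product=\"tRNA-Met\"",
    "ORIGIN",
    "        1 atgaaatttg gcgcgcgcgc atcgatcgat cgatcgatcg aaccggttaa ccggttaacc",
    "//"), gb)
  g <- read_genomes(gb, "genbank")[[1]]
  expect_equal(g$id, "REC1")
  expect_equal(nchar(g$sequence), 60L)
  expect_equal(g$species_label, "longum_infantis")
  expect_equal(g$strain, "ATCC15697")
  expect_equal(g$features$kind, c("CDS", "tRNA"))
  expect_equal(g$features$start, c(1L, 40L))
  expect_equal(g$features$end, c(30L, 55L))
  expect_equal(g$features$strand, c("+", "-"))
})

test_that("reading fails loudly on missing, empty or invalid input", {
  tmp <- withr::local_tempdir()
  expect_error(read_genomes(file.path(tmp, "nope.fa"), "fasta+gff3"),
               "does not exist")
  fa <- file.path(tmp, "empty.fasta")
  writeLines(character(), fa)
  writeLines("##gff-version 3", file.path(tmp, "empty.gff3"))
  expect_error(read_genomes(fa, "fasta+gff3"), "empty dataset")
  notgb <- file.path(tmp, "x.gb")
  writeLines("this is not genbank", notgb)
  expect_error(read_genomes(notgb, "genbank"), "LOCUS")
  expect_error(genome_record("g", "ACGRT"), "invalid characters")
})

test_that("slice_region keeps wholly contained features, drops straddlers, shifts coordinates", {
  g <- mk_genome(len = 1000, feats = rbind(
    cds_row(101, 200, "inside"),
    cds_row(250, 420, "straddles"),
    cds_row(450, 500, "outside")))
  # full-length slice is the identity
  full <- slice_region(g, 1, 1000)
  expect_equal(full$sequence, g$sequence)
  expect_equal(nrow(full$features), 3L)
  sl <- slice_region(g, 100, 400)
  expect_equal(nchar(sl$sequence), 301L)
  expect_equal(sl$sequence, substr(g$sequence, 100, 400))
  expect_equal(sl$features$product, "inside")
  expect_equal(sl$features$start, 2L)
  expect_equal(sl$features$end, 101L)
  expect_error(slice_region(g, 0, 10), "out of bounds")
  expect_error(slice_region(g, 900, 1100), "out of bounds")
})

test_that("region GFF3 writing round-trips intervals and names and rejects duplicates", {
  tmp <- withr::local_tempdir()
  p <- file.path(tmp, "regions.gff3")
  regs <- data.frame(name = sprintf("BreXph%d", 1:5), genome_id = "g1",
                     start = c(1L, 100L, 500L, 900L, 2000L),
                     end = c(100L, 300L, 800L, 1500L, 2500L))
  write_regions(regs, p)
  back <- read_regions(p)
  expect_equal(back$name, regs$name)
  expect_equal(back$start, regs$start)
  expect_equal(back$end, regs$end)
  expect_equal(back$genome_id, regs$genome_id)
  # a region [1,100] occupies GFF3 columns 4,5 = 1,100
  line <- grep("BreXph1", readLines(p), value = TRUE)[1]
  expect_equal(strsplit(line, "\t")[[1]][4:5], c("1", "100"))
  # empty set gives a valid header-only file
  write_regions(regs[0, ], file.path(tmp, "empty.gff3"))
  expect_equal(readLines(file.path(tmp, "empty.gff3"))[1], "##gff-version 3")
  expect_equal(nrow(read_regions(file.path(tmp, "empty.gff3"))), 0L)
  regs$name[2] <- regs$name[1]
  expect_error(write_regions(regs, p), "duplicate region names")
})

test_that("genome FASTA writing round-trips sequences, labels and features", {
  set.seed(4)
  tmp <- withr::local_tempdir()
  gs <- list(a = mk_genome("a", 500, feats = cds_row(10, 99, "holin"),
                           species = "bifidum", strain = "B1"),
             b = mk_genome("b", 700))
  write_genomes(gs, file.path(tmp, "g.fasta"), file.path(tmp, "g.gff3"))
  back <- read_genomes(file.path(tmp, "g.fasta"), "fasta+gff3")
  expect_equal(back$a$sequence, gs$a$sequence)
  expect_equal(back$a$species_label, "bifidum")
  expect_equal(back$a$strain, "B1")
  expect_equal(back$a$features$start, 10L)
  expect_equal(back$a$features$product, "holin")
})
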
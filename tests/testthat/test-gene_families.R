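test_that("protein graph keeps identical pairs and rejects unrelated pairs", {
  set.seed(51)
  aas <- rownames(bifidophage:::get_blosum62())[1:20]
  p100 <- paste(sample(aas, 100, TRUE), collapse = "")
  r1 <- paste(sample(aas, 50, TRUE), collapse = "")
  r2 <- paste(sample(aas, 50, TRUE), collapse = "")
  orfs <- data.frame(orf_id = c("x", "y", "u", "v"),
                     region_id = "r",
                     protein = c(p100, p100, r1, r2))
  g <- all_vs_all_protein(orfs, prefilter = FALSE)
  e <- g$edges
  expect_true(any((e$a == "x" & e$b == "y") | (e$a == "y" & e$b == "x")))
  xy <- e[(e$a == "x" & e$b == "y") | (e$a == "y" & e$b == "x"), ]
  expect_equal(xy$weight, max(e$weight))
  expect_false(any(e$a %in% c("u", "v") & e$b %in% c("u", "v")))
  # oracle: score the unrelated pair with an independent DP implementation
  # and evaluate the stated E formula
  sc <- sw_protein(r1, r2)
  ev <- evalue_protein(sc, 50, sum(nchar(orfs$protein)))
  expect_gt(ev$evalue, 1e-5)
  # the package's aligner agrees with the independent DP on raw score
  expect_equal(bifidophage:::local_align_aa(r1, r2)$score, sc)
  expect_error(all_vs_all_protein(orfs[1, , drop = FALSE]), "nrow")
  # prefilter does not change the edge set here
  g2 <- all_vs_all_protein(orfs, prefilter = TRUE)
  expect_equal(nrow(g2$edges), nrow(g$edges))
})

test_that("MCL partitions graphs deterministically and flags non-convergence", {
  tri2 <- list(nodes = letters[1:6],
               edges = data.frame(a = c("a", "a", "b", "d", "d", "e"),
                                  b = c("b", "c", "c", "e", "f", "f"),
                                  weight = 1))
  r <- mcl(tri2)
  expect_true(r$converged)
  expect_equal(r$clusters, list(c("a", "b", "c"), c("d", "e", "f")))
  # partition property
  expect_setequal(unlist(r$clusters), tri2$nodes)
  expect_equal(anyDuplicated(unlist(r$clusters)), 0L)
  # single node
  r1 <- mcl(list(nodes = "z", edges = NULL))
  expect_equal(r1$clusters, list("z"))
  # permutation invariance
  perm <- list(nodes = rev(tri2$nodes),
               edges = tri2$edges[sample(6), c("b", "a", "weight")])
  names(perm$edges) <- c("a", "b", "weight")
  expect_equal(mcl(perm)$clusters, r$clusters)
})

test_that("MCL limit on the 3-node path matches hand iteration and is doubly idempotent", {
  path3 <- list(nodes = c("a", "b", "c"),
                edges = data.frame(a = c("a", "b"), b = c("b", "c"),
                                   weight = 1))
  r <- mcl(path3, inflation = 2)
  # hand-run the expansion/inflation iteration on the explicit 3x3 matrix
  M <- matrix(c(1, 1, 0,
                1, 1, 1,
                0, 1, 1), 3, 3, byrow = TRUE)
  M <- sweep(M, 2, colSums(M), "/")
  for (i in 1:200) {
    M2 <- M %*% M
    M2 <- M2^2
    M2[M2 < 1e-6] <- 0
    M2 <- sweep(M2, 2, colSums(M2), "/")
    if (max(abs(M2 - M)) < 1e-9) { M <- M2; break }
    M <- M2
  }
  # doubly idempotent limit: expansion and inflation both fix M
  expect_lt(max(abs(M %*% M - M)), 1e-6)
  Minf <- M^2
  Minf <- sweep(Minf, 2, colSums(Minf), "/")
  expect_lt(max(abs(Minf - M)), 1e-6)
  # the hand-iterated attractor structure gives one cluster {a,b,c}
  hand_clusters <- length(unique(apply(M > 0, 2, function(col)
    paste(which(col), collapse = ","))))
  expect_equal(hand_clusters, 1L)
  expect_equal(r$clusters, list(c("a", "b", "c")))
})

test_that("presence/absence matrices are binary, sorted and family-complete", {
  orfs <- data.frame(orf_id = c("o1", "o2", "o3", "o4", "o5"),
                     region_id = c("rB", "rA", "rA", "rB", "rC"),
                     protein = "M")
  membership <- c(o1 = 1L, o2 = 1L, o3 = 2L, o4 = 2L, o5 = 1L)
  m <- presence_absence(orfs, membership)
  expect_equal(rownames(m), c("rA", "rB", "rC"))
  expect_equal(unname(colSums(m)), c(3L, 2L))
  expect_true(all(m %in% c(0L, 1L)))
  m1 <- presence_absence(orfs[1, , drop = FALSE], membership)
  expect_equal(dim(m1), c(1L, 1L))
  expect_equal(unname(m1[1, 1]), 1L)
  expect_error(presence_absence(data.frame(orf_id = "zz", region_id = "r"),
                                membership), "family")
  orfs$region_id[1] <- ""
  expect_error(presence_absence(orfs, membership), "orphan")
})

test_that("cluster selection applies the membership, sharing, completeness and size rules", {
  regions <- data.frame(
    name = c("p1", "p2", "q1", "q2", "s1"),
    genome_id = "g", start = 1L, end = 2L,
    length = c(30000L, 28000L, 9000L, 9500L, 31000L),
    completeness = c("likely_complete", "partial", "remnant", "remnant",
                     "likely_complete"))
  pa <- matrix(0L, 5, 4, dimnames = list(regions$name, paste0("F", 1:4)))
  pa["p1", ] <- c(1L, 1L, 1L, 0L)
  pa["p2", ] <- c(1L, 1L, 0L, 0L)
  pa["q1", ] <- c(0L, 0L, 1L, 1L)
  pa["q2", ] <- c(0L, 0L, 1L, 1L)
  sel <- select_clusters(list(c("p1", "p2"), c("q1", "q2"), "s1"),
                         pa, regions)
  # q-cluster rejected (< 13 kb), singleton rejected, p-cluster selected
  expect_equal(nrow(sel), 1L)
  expect_equal(sel$members, "p1,p2")
  expect_equal(sel$mean_jaccard, 2 / 3)
  # without a likely_complete member the p-cluster is rejected too
  regions2 <- regions
  regions2$completeness[1] <- "partial"
  expect_equal(nrow(select_clusters(list(c("p1", "p2")), pa, regions2)), 0L)
  # two identical prophages with identical flanks share integration
  set.seed(52)
  host <- mk_genome(len = 60000)
  ph <- generate_phage(bifidophage:::scaled_template(22000))
  g1 <- implant_prophage(host, ph, site = 20000L)
  g2l <- mk_genome("g2", len = 60000, strain = "T")
  g2 <- implant_prophage(g2l, ph, site = 30000L)
  regs <- detect_prophages(list(g = g1$genome, g2 = g2$genome))
  orfs <- do.call(rbind, lapply(seq_len(nrow(regs)), function(i) {
    sl <- slice_region(if (i == 1) g1$genome else g2$genome,
                       regs$start[i], regs$end[i])
    select_orfs(find_orfs(sl$sequence, region_id = regs$name[i]))
  }))
  gr <- all_vs_all_protein(orfs)
  mb <- mcl(gr)$membership
  pa2 <- presence_absence(orfs, mb)
  sel2 <- select_clusters(list(regs$name), pa2, regs,
                          genomes = list(g = g1$genome, g2 = g2$genome))
  expect_equal(nrow(sel2), 1L)
  expect_gte(sel2$mean_jaccard, 0.5)
})
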
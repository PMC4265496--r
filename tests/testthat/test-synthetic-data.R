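test_that("generators are byte-identical under a fixed seed", {
  g1 <- simulate_genome(60000, cgi = list(count = 3, length = 800,
                                          gc = 0.65), seed = 5)
  g2 <- simulate_genome(60000, cgi = list(count = 3, length = 800,
                                          gc = 0.65), seed = 5)
  expect_identical(g1$genome, g2$genome)
  d1 <- simulate_dataset(seed = 3, scale = 0.03)
  d2 <- simulate_dataset(seed = 3, scale = 0.03)
  expect_identical(d1$genome, d2$genome)
  expect_identical(d1$methylomes, d2$methylomes)
  expect_identical(d1$fragments, d2$fragments)
  d3 <- simulate_dataset(seed = 4, scale = 0.03)
  expect_false(identical(d1$genome, d3$genome))
})

test_that("genome composition matches the requested GC and CpG structure", {
  g <- simulate_genome(1e6, gc = 0.42,
                       cgi = list(count = 10, length = 1000, gc = 0.65),
                       cpg_depletion = 0, seed = 6)
  chars <- strsplit(as.character(g$genome), "")[[1]]
  expect_lt(abs(mean(chars %in% c("C", "G")) - 0.42 -
                  0.0023), 0.01)  # islands lift GC by ~10*1000/1e6*0.23
  gd <- simulate_genome(3e5, cgi = list(count = 4, length = 1000,
                                        gc = 0.65), seed = 7)
  cgs <- hmrnuc:::cg_positions(gd$genome)
  cgi <- gd$truth$cgis
  in_cgi <- rowSums(outer(cgs, cgi$start, ">=") &
                      outer(cgs, cgi$end, "<")) > 0
  rate_cgi <- sum(in_cgi) / sum(cgi$end - cgi$start)
  rate_bg <- sum(!in_cgi) / (3e5 - sum(cgi$end - cgi$start))
  expect_gt(rate_cgi, 2 * rate_bg)
})

test_that("planted methylomes separate hypo and methylated CpGs", {
  g <- simulate_genome(3e5, cgi = list(count = 4, length = 1000,
                                       gc = 0.65), seed = 8)
  me <- simulate_methylome(g$genome,
                           hmr_plan = list(n_common = 10,
                                           n_specific_a = 5,
                                           n_specific_b = 5,
                                           n_extended = 5),
                           cgis = g$truth$cgis, seed = 9)
  cp <- me$methylomes$a
  expect_gt(nrow(cp), 1000)
  hm <- me$truth$hmrs_a
  st <- findInterval(cp$pos, hm$start)
  inside <- st >= 1 & cp$pos < hm$end[pmax(st, 1)]
  expect_lt(mean(cp$level[inside]), 0.15)
  expect_gt(mean(cp$level[!inside]), 0.7)
  # boundary CpGs exist exactly at the planted boundaries
  expect_true(all(hm$boundary_5 %in% cp$pos))
  expect_true(all(hm$boundary_3 %in% cp$pos))
})

test_that("extended-pair truth respects the boundary ordering invariant", {
  d <- simulate_dataset(seed = 11, scale = 0.04)
  px <- d$truth$extended_pairs
  expect_gt(nrow(px), 0)
  expect_true(all((px$boundary2 - px$boundary1) *
                    (px$boundary3 - px$boundary2) > 0))
  expect_true(all(px$extension_length > 0))
  expect_equal(px$extension_length, abs(px$boundary3 - px$boundary2))
})

test_that("planted boundary gaps average near 150 bp and are recovered", {
  g <- simulate_genome(3e5, cgi = list(count = 3, length = 800,
                                       gc = 0.65), seed = 12)
  me <- simulate_methylome(g$genome,
                           hmr_plan = list(n_common = 14,
                                           n_specific_a = 5,
                                           n_specific_b = 5,
                                           n_extended = 0),
                           cgis = g$truth$cgis, seed = 13)
  gp <- me$truth$boundary_gaps
  expect_true(all(gp >= 100 & gp <= 200))
  hm <- me$truth$hmrs_a
  hm$cpg_pos <- lapply(seq_len(nrow(hm)), function(i) {
    p <- me$methylomes$a$pos
    p[p >= hm$start[i] & p < hm$end[i]]
  })
  st <- boundary_gap_stats(hm, me$methylomes$a)
  expect_lt(abs(st$mean - 150), 20)
})

test_that("fragments are uniform without boundary enrichment", {
  d <- simulate_dataset(seed = 14, scale = 0.04, boundary_fraction = 0)
  fr <- simulate_fragments(d$genome, d$truth, cell = "a",
                           phasing = list(fold = 0), n_fragments = 30000,
                           seed = 15)
  mids <- floor((fr$start + fr$end - 1) / 2)
  ct <- table(cut(mids, seq(0, nchar(d$genome), length.out = 41)))
  expect_gt(suppressWarnings(chisq.test(ct)$p.value), 0.01)
})

test_that("insert-length clipping leaves only 100-160 bp fragments", {
  d <- simulate_dataset(seed = 16, scale = 0.03)
  fr <- simulate_fragments(d$genome, d$truth,
                           insert = list(mean = 147, sd = 10,
                                         clip = TRUE),
                           n_fragments = 5000, seed = 17)
  len <- fr$end - fr$start
  expect_true(all(len >= 100 & len <= 160))
  expect_error(simulate_fragments(d$genome, d$truth, n_fragments = 0),
               "n_fragments")
})

test_that("planted motifs read back from the genome at the planted sites", {
  d <- simulate_dataset(seed = 18, scale = 0.04)
  mp <- d$truth$motif_positions
  expect_gt(nrow(mp), 10)
  km <- boundary_kmer_table(d$genome, mp$pos)
  expect_true(all(km == "CACGTG"))
  expect_gt(sum(mp$at_boundary), 0)
})
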
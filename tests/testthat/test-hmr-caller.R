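toy_params <- function() list(
  pi = c(0.4, 0.6),
  A = matrix(c(0.8, 0.2, 0.3, 0.7), 2, byrow = TRUE),
  emis = list(alpha = c(0.5, 8), beta = c(8, 0.5))
)

test_that("posteriors equal exhaustive path enumeration on a 3-CpG toy", {
  cpgs <- data.frame(chrom = "chr1", pos = c(10, 50, 90),
                     meth_count = c(0, 1, 9), total_count = c(10, 10, 10))
  pars <- toy_params()
  g <- posterior_states(cpgs, pars)
  expect_equal(unname(g), brute_hmm_posterior(cpgs, pars),
               tolerance = 1e-9)
  expect_true(all(abs(rowSums(g) - 1) < 1e-12))
})

test_that("EM log-likelihood is non-decreasing on random data sets", {
  for (s in 1:50) {
    cpgs <- sim_cpg_chain(150, seed = s, coverage = sample(5:20, 1))
    fit <- fit_hmm(cpgs, max_iter = 8, tol = 0)
    expect_true(all(diff(fit$logliks) > -1e-6))
  }
})

test_that("fully methylated data leaves the HYPO state unoccupied", {
  cpgs <- data.frame(chrom = "chr1", pos = seq(0, 9990, 10),
                     meth_count = 10L, total_count = 10L)
  fit <- fit_hmm(cpgs, max_iter = 20)
  g <- posterior_states(cpgs, fit$params)
  expect_lt(mean(g[, "HYPO"]), 0.01)
  expect_equal(nrow(decode_hmrs(cpgs, fit$params)), 0)
  # noisy single-regime data still yields no called HMRs
  set.seed(4)
  noisy <- data.frame(chrom = "chr1", pos = seq(0, 9990, 10),
                      meth_count = rbinom(1000, 10, 0.92),
                      total_count = 10)
  fit2 <- fit_hmm(noisy, max_iter = 20)
  expect_equal(nrow(decode_hmrs(noisy, fit2$params)), 0)
})

test_that("emission levels are recovered from a chain with known truth", {
  cpgs <- sim_cpg_chain(10000, mu = c(0.05, 0.85), stay = 0.95,
                        coverage = 10, seed = 77)
  fit <- fit_hmm(cpgs, max_iter = 25, tol = 1e-2)
  means <- hmrnuc:::bb_mean(fit$params$emis)
  expect_lt(abs(means[1] - 0.05), 0.05)
  expect_lt(abs(means[2] - 0.85), 0.05)
})

test_that("a planted unmethylated block is recovered as one clean HMR", {
  set.seed(21)
  n <- 1000
  pos <- cumsum(sample(30:120, n, TRUE))
  lev <- rep(0.9, n)
  block <- 401:430
  lev[block] <- 0.02
  tot <- rep(20L, n)
  cpgs <- data.frame(chrom = "chr1", pos = pos,
                     meth_count = rbinom(n, tot, lev), total_count = tot)
  fit <- fit_hmm(cpgs, max_iter = 30)
  hmrs <- decode_hmrs(cpgs, fit$params)
  expect_equal(nrow(hmrs), 1)
  jac <- length(intersect(hmrs$cpg_pos[[1]], pos[block])) /
    length(union(hmrs$cpg_pos[[1]], pos[block]))
  expect_gte(jac, 0.9)
})

test_that("decoded HMRs are disjoint, sorted, and split across deserts", {
  cpgs <- sim_cpg_chain(2000, seed = 5, coverage = 15)
  fit <- fit_hmm(cpgs, max_iter = 15)
  hmrs <- decode_hmrs(cpgs, fit$params)
  if (nrow(hmrs) > 1) {
    expect_true(all(diff(hmrs$start) > 0))
    expect_true(all(hmrs$start[-1] >= hmrs$end[-nrow(hmrs)]))
  }
  # a >10 kb gap inside a hypomethylated run forces a split
  pos <- c(seq(0, 90, 10), seq(20000, 20090, 10))
  cpgs2 <- data.frame(chrom = "chr1", pos = pos, meth_count = 0L,
                      total_count = 20L)
  hmrs2 <- decode_hmrs(cpgs2, toy_params(), min_cpgs = 4)
  expect_equal(nrow(hmrs2), 2)
})

test_that("flipping methylation levels maps HMRs onto methylated blocks", {
  cpgs <- sim_cpg_chain(3000, seed = 13, coverage = 15)
  fit <- fit_hmm(cpgs, max_iter = 20)
  hmrs <- decode_hmrs(cpgs, fit$params, min_cpgs = 4)
  flipped <- cpgs
  flipped$meth_count <- flipped$total_count - flipped$meth_count
  fit2 <- fit_hmm(flipped, max_iter = 20)
  hmrs2 <- decode_hmrs(flipped, fit2$params, min_cpgs = 4)
  # HMRs on flipped data sit where the original METH blocks were
  truth_meth <- cpgs$pos[cpgs$states == 2]
  hits <- vapply(seq_len(nrow(hmrs2)), function(i)
    mean(hmrs2$cpg_pos[[i]] %in% truth_meth), 0)
  expect_gt(median(hits), 0.9)
  # and do not coincide with the original HMRs
  if (nrow(hmrs) && nrow(hmrs2)) {
    ov <- cgi_overlap_fraction(hmrs[c("chrom", "start", "end")],
                               hmrs2[c("chrom", "start", "end")])
    expect_lt(ov$fraction, 0.3)
  }
})

test_that("boundary conventions pick the documented CpGs", {
  hmrs <- data.frame(chrom = "chr1", start = 200, end = 301, n_cpgs = 3,
                     mean_level = 0.02)
  hmrs$cpg_pos <- I(list(c(200, 240, 300)))
  all_cpgs <- data.frame(chrom = "chr1", pos = c(120, 200, 240, 300, 410),
                         meth_count = c(9, 0, 0, 0, 9),
                         total_count = 10)
  expect_equal(extract_boundaries(hmrs, all_cpgs, "first_unmeth",
                                  "5prime"), 200)
  expect_equal(extract_boundaries(hmrs, all_cpgs, "second_unmeth",
                                  "5prime"), 240)
  expect_equal(extract_boundaries(hmrs, all_cpgs, "adjacent_meth",
                                  "5prime"), 120)
  expect_equal(extract_boundaries(hmrs, all_cpgs, "first_unmeth",
                                  "3prime"), 300)
  expect_equal(extract_boundaries(hmrs, all_cpgs, "adjacent_meth",
                                  "3prime"), 410)
  expect_error(extract_boundaries(hmrs, all_cpgs, "nonsense"), "arg")
  # single-CpG HMR: no second unmethylated CG
  h1 <- hmrs; h1$cpg_pos <- I(list(200)); h1$n_cpgs <- 1
  expect_true(is.na(extract_boundaries(h1, all_cpgs, "second_unmeth",
                                       "5prime")))
  # chromosome start: no adjacent methylated CG upstream
  a2 <- all_cpgs[all_cpgs$pos >= 200, ]
  expect_true(is.na(extract_boundaries(hmrs, a2, "adjacent_meth",
                                       "5prime")))
})

test_that("boundary gaps summarize distances to the adjacent methylated CG", {
  hmrs <- data.frame(chrom = "chr1", start = 200, end = 301, n_cpgs = 3,
                     mean_level = 0.02)
  hmrs$cpg_pos <- I(list(c(200, 240, 300)))
  all_cpgs <- data.frame(chrom = "chr1", pos = c(120, 200, 240, 300, 410))
  st <- boundary_gap_stats(hmrs, all_cpgs)
  expect_equal(sort(st$gaps$gap), c(80, 110))
  empty <- decode_hmrs(
    data.frame(chrom = "chr1", pos = c(1, 10), meth_count = c(10, 10),
               total_count = 10), toy_params())
  st0 <- boundary_gap_stats(empty, all_cpgs)
  expect_equal(nrow(st0$gaps), 0)
  expect_true(is.na(st0$mean))
})

test_that("planted boundary-gap distribution is recovered", {
  set.seed(31)
  n <- 500
  centers <- seq(5000, by = 4000, length.out = n)
  gaps5 <- round(runif(n, 100, 200))
  gaps3 <- round(runif(n, 100, 200))
  hmrs <- data.frame(chrom = "chr1", start = centers, end = centers + 501,
                     n_cpgs = 3, mean_level = 0.02)
  hmrs$cpg_pos <- I(lapply(centers, function(s) c(s, s + 250, s + 500)))
  all_pos <- sort(c(centers, centers + 250, centers + 500,
                    centers - gaps5, centers + 500 + gaps3))
  all_cpgs <- data.frame(chrom = "chr1", pos = all_pos)
  st <- boundary_gap_stats(hmrs, all_cpgs)
  expect_equal(nrow(st$gaps), 2 * n)
  expect_lt(abs(st$mean - 150), 10)
})
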
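# Independent brute-force oracles and tiny simulators used across tests.

# O(N*W) direct convolution with a normalized truncated Gaussian kernel
brute_gauss_smooth <- function(x, sigma) {
  w <- ceiling(4 * sigma)
  k <- dnorm(-w:w, 0, sigma)
  k <- k / sum(k)
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    js <- max(1, i - w):min(n, i + w)
    out[i] <- sum(x[js] * k[js - i + w + 1])
  }
  out
}

# exhaustive path-sum posterior for a short beta-binomial HMM sequence
brute_hmm_posterior <- function(cpgs, params) {
  Tn <- nrow(cpgs)
  emis <- params$emis
  em <- function(t, s) exp(hmrnuc:::dbetabinom_log(
    cpgs$meth_count[t], cpgs$total_count[t], emis$alpha[s], emis$beta[s]))
  paths <- as.matrix(expand.grid(rep(list(1:2), Tn)))
  pp <- apply(paths, 1, function(st) {
    p <- params$pi[st[1]] * em(1, st[1])
    if (Tn > 1) for (t in 2:Tn)
      p <- p * params$A[st[t - 1], st[t]] * em(t, st[t])
    p
  })
  post <- sapply(1:Tn, function(t)
    sapply(1:2, function(s) sum(pp[paths[, t] == s])))
  t(post) / sum(pp)  # Tn x 2
}

# AUC by explicit pair counting (ties count 1/2)
brute_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# per-anchor loop metaprofile
brute_metaprofile <- function(track, anchors, flank, orient = TRUE) {
  offsets <- -flank:flank
  side <- anchors$side
  if (is.null(side)) side <- rep("5prime", nrow(anchors))
  tot <- numeric(length(offsets))
  n <- integer(length(offsets))
  for (i in seq_len(nrow(anchors))) {
    sg <- if (orient && side[i] == "3prime") -1 else 1
    v <- track_values_at(track, anchors$pos[i] + sg * offsets)
    ok <- !is.na(v)
    tot[ok] <- tot[ok] + v[ok]
    n <- n + ok
  }
  list(offsets = offsets, mean = ifelse(n > 0, tot / pmax(n, 1), NA), n = n)
}

# two-state CpG chain with known emission truth (block lengths geometric)
sim_cpg_chain <- function(n, mu = c(0.05, 0.85), stay = 0.95, rho = 0.1,
                          coverage = 10, seed = 1) {
  set.seed(seed)
  st <- integer(n)
  st[1] <- sample(1:2, 1)
  for (t in 2:n)
    st[t] <- if (runif(1) < stay) st[t - 1] else 3L - st[t - 1]
  m <- mu[st]
  tot <- pmax(rpois(n, coverage), 1L)
  p <- rbeta(n, m * (1 - rho) / rho, (1 - m) * (1 - rho) / rho)
  meth <- rbinom(n, tot, p)
  data.frame(chrom = "chr1", pos = cumsum(sample(20:150, n, TRUE)),
             meth_count = meth, total_count = tot,
             level = meth / tot, states = st)
}

random_genome <- function(n, seed, gc = 0.5) {
  set.seed(seed)
  s <- paste(sample(c("A", "C", "G", "T"), n, TRUE,
                    prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
             collapse = "")
  names(s) <- "chr1"
  s
}

make_track <- function(values, chrom = "chr1", offset = 0) {
  structure(list(chrom = chrom, offset = offset,
                 values = as.numeric(values), sigma = NA_real_,
                 n_fragments = NA_real_),
            class = "occupancy_track")
}

# GC-driven "in vivo style" occupancy: smoothed GC indicator plus noise,
# normalized to mean 1 (a sequence-driven track by construction)
gc_driven_track <- function(genome, sigma = 30, noise_sd = 0.02,
                            seed = 1) {
  gc <- as.integer(strsplit(as.character(genome[[1]]), "")[[1]] %in%
                     c("C", "G"))
  tr <- smooth_track(gc, sigma = sigma)
  set.seed(seed)
  tr$values <- pmax(tr$values + rnorm(length(tr$values), 0, noise_sd), 0)
  normalize_track(tr)
}
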
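# Two-state HMM over per-CpG (meth, total) counts with beta-binomial
# emissions. State 1 = HYPO (low methylation), state 2 = METH.

# log beta-binomial pmf, vectorized over (m, n)
dbetabinom_log <- function(m, n, alpha, beta) {
  lchoose(n, m) + lbeta(m + alpha, n - m + beta) - lbeta(alpha, beta)
}

bb_mean <- function(emis) emis$alpha / (emis$alpha + emis$beta)

# moment-matched (alpha, beta) from posterior-weighted level moments,
# discounting the expected binomial sampling variance
bb_moment_match <- function(levels, totals, w) {
  w <- w / sum(w)
  mu <- sum(w * levels)
  mu <- min(max(mu, 1e-4), 1 - 1e-4)
  v_obs <- sum(w * (levels - mu)^2)
  m1 <- sum(w / totals)
  v_beta <- (v_obs - mu * (1 - mu) * m1) / max(1 - m1, 1e-6)
  v_beta <- min(max(v_beta, 1e-8), mu * (1 - mu) * 0.95)
  s <- mu * (1 - mu) / v_beta - 1
  s <- min(max(s, BB_CONC_MIN), BB_CONC_MAX)
  list(alpha = mu * s, beta = (1 - mu) * s)
}

# bounds on the beta-binomial concentration (alpha + beta): the lower
# bound keeps emissions proper, the upper bound keeps a minimum
# overdispersion so a state cannot shave off near-duplicate level slices
# of a single methylation regime
BB_CONC_MIN <- 0.05
BB_CONC_MAX <- 1000

validate_hmm_params <- function(params) {
  stopifnot(
    abs(sum(params$pi) - 1) < 1e-9,
    all(abs(rowSums(params$A) - 1) < 1e-9),
    all(params$emis$alpha > 0), all(params$emis$beta > 0)
  )
  invisible(params)
}

split_sequences <- function(cpgs) {
  validate_cpgs(cpgs)
  split(seq_len(nrow(cpgs)), cpgs$chrom)
}

validate_cpgs <- function(cpgs) {
  stopifnot(all(c("chrom", "pos", "meth_count", "total_count") %in%
                  names(cpgs)))
  if (any(cpgs$total_count <= 0))
    stop("CpG records must have total_count > 0", call. = FALSE)
  if (any(cpgs$meth_count < 0 | cpgs$meth_count > cpgs$total_count))
    stop("meth_count must lie in [0, total_count]", call. = FALSE)
  invisible(cpgs)
}

# scaled forward-backward for one sequence. logB: T x 2 emission log-liks.
# Scalar recursions (2 states) keep the per-site loop cheap; xi is
# accumulated in closed vectorized form afterwards.
forward_backward <- function(logB, pi, A) {
  Tn <- nrow(logB)
  shift <- pmax(logB[, 1L], logB[, 2L])
  B1 <- exp(logB[, 1L] - shift)
  B2 <- exp(logB[, 2L] - shift)
  a11 <- A[1L, 1L]; a12 <- A[1L, 2L]; a21 <- A[2L, 1L]; a22 <- A[2L, 2L]
  al1 <- numeric(Tn); al2 <- numeric(Tn)
  be1 <- numeric(Tn); be2 <- numeric(Tn)
  cs <- numeric(Tn)
  x1 <- pi[1L] * B1[1L]; x2 <- pi[2L] * B2[1L]
  cs[1L] <- x1 + x2
  al1[1L] <- x1 / cs[1L]; al2[1L] <- x2 / cs[1L]
  if (Tn > 1L) for (t in 2:Tn) {
    p1 <- al1[t - 1L]; p2 <- al2[t - 1L]
    x1 <- (p1 * a11 + p2 * a21) * B1[t]
    x2 <- (p1 * a12 + p2 * a22) * B2[t]
    cs[t] <- x1 + x2
    al1[t] <- x1 / cs[t]; al2[t] <- x2 / cs[t]
  }
  be1[Tn] <- 1; be2[Tn] <- 1
  if (Tn > 1L) for (t in (Tn - 1L):1L) {
    u1 <- B1[t + 1L] * be1[t + 1L]; u2 <- B2[t + 1L] * be2[t + 1L]
    be1[t] <- (a11 * u1 + a12 * u2) / cs[t + 1L]
    be2[t] <- (a21 * u1 + a22 * u2) / cs[t + 1L]
  }
  g1 <- al1 * be1; g2 <- al2 * be2
  gs <- g1 + g2
  gamma <- cbind(g1 / gs, g2 / gs)
  xi <- matrix(0, 2L, 2L)
  if (Tn > 1L) {
    v1 <- B1[-1L] * be1[-1L] / cs[-1L]
    v2 <- B2[-1L] * be2[-1L] / cs[-1L]
    h1 <- al1[-Tn]; h2 <- al2[-Tn]
    xi <- A * rbind(c(sum(h1 * v1), sum(h1 * v2)),
                    c(sum(h2 * v1), sum(h2 * v2)))
  }
  list(gamma = gamma, xi = xi, loglik = sum(log(cs)) + sum(shift))
}

emission_logB <- function(cpgs, emis) {
  cbind(
    dbetabinom_log(cpgs$meth_count, cpgs$total_count,
                   emis$alpha[1L], emis$beta[1L]),
    dbetabinom_log(cpgs$meth_count, cpgs$total_count,
                   emis$alpha[2L], emis$beta[2L])
  )
}

hmm_estep <- function(cpgs, params) {
  seqs <- split_sequences(cpgs)
  logB <- emission_logB(cpgs, params$emis)
  gamma <- matrix(0, nrow(cpgs), 2L)
  xi <- matrix(0, 2L, 2L)
  pi1 <- c(0, 0)
  ll <- 0
  for (idx in seqs) {
    fb <- forward_backward(logB[idx, , drop = FALSE], params$pi, params$A)
    gamma[idx, ] <- fb$gamma
    xi <- xi + fb$xi
    pi1 <- pi1 + fb$gamma[1L, ]
    ll <- ll + fb$loglik
  }
  list(gamma = gamma, xi = xi, pi1 = pi1 / length(seqs), loglik = ll)
}

# emission M-step for one state: moment-matched start, then bounded
# numerical refinement of the expected log-likelihood; never accepts a
# parameter set worse than the incumbent (generalized EM).
mstep_emission <- function(cpgs, w, old) {
  qfun <- function(a, b)
    sum(w * dbetabinom_log(cpgs$meth_count, cpgs$total_count, a, b))
  mm <- bb_moment_match(cpgs$meth_count / cpgs$total_count,
                        cpgs$total_count, w)
  cands <- list(old, mm)
  # refine over (logit mean, log concentration) within the concentration
  # bounds, starting from the moment-matched estimate
  par0 <- c(qlogis(mm$alpha / (mm$alpha + mm$beta)),
            log(mm$alpha + mm$beta))
  unpack <- function(p) {
    mu <- plogis(min(max(p[1L], -12), 12))
    s <- exp(min(max(p[2L], log(BB_CONC_MIN)), log(BB_CONC_MAX)))
    list(alpha = mu * s, beta = (1 - mu) * s)
  }
  opt <- tryCatch(
    optim(par0, function(p) {
      e <- unpack(p)
      -qfun(e$alpha, e$beta)
    }, method = "Nelder-Mead", control = list(maxit = 200)),
    error = function(e) NULL)
  if (!is.null(opt)) cands <- c(cands, list(unpack(opt$par)))
  qs <- vapply(cands, function(cc) qfun(cc$alpha, cc$beta), 0)
  cands[[which.max(qs)]]
}

#' Fit the two-state methylation HMM by Baum-Welch
#'
#' Fits initial probabilities, a 2x2 transition matrix and per-state
#' beta-binomial emission parameters to an ordered collection of CpG
#' records. Each chromosome is treated as an independent sequence. The
#' emission M-step is moment-matched then refined numerically, accepting an
#' update only if it does not decrease the expected emission
#' log-likelihood, so the observed log-likelihood is non-decreasing across
#' iterations (generalized EM). After fitting, states are relabeled so that
#' state 1 (HYPO) has the lower expected methylation level.
#'
#' @param cpgs data.frame of CpG records (`chrom`, `pos`, `meth_count`,
#'   `total_count`), position-sorted within chromosome, all
#'   `total_count > 0`.
#' @param max_iter maximum EM iterations.
#' @param tol stop when the log-likelihood increment falls below this.
#' @param seed RNG seed (fitting is deterministic; kept for interface
#'   stability of seeded pipelines).
#' @return list with `params` (fields `pi`, `A`, `emis` with per-state
#'   `alpha`, `beta`), `logliks` (per-iteration), `converged`, and
#'   `flags` (character vector of warnings such as non-convergence or
#'   clamped emissions).
#' @export
fit_hmm <- function(cpgs, max_iter = 100, tol = 1e-4, seed = 1) {
  validate_cpgs(cpgs)
  if (nrow(cpgs) < 2L) stop("need >= 2 CpG records", call. = FALSE)
  check_seed(seed)
  lev <- cpgs$meth_count / cpgs$total_count
  mu_h <- min(max(unname(quantile(lev, 0.05)), 0.01), 0.35)
  mu_m <- min(max(unname(quantile(lev, 0.75)), 0.55), 0.99)
  s0 <- 9  # dispersion ~0.1
  params <- list(
    pi = c(0.5, 0.5),
    A = matrix(c(0.9, 0.1, 0.1, 0.9), 2L, 2L, byrow = TRUE),
    emis = list(alpha = c(mu_h, mu_m) * s0, beta = (1 - c(mu_h, mu_m)) * s0)
  )
  logliks <- numeric(0)
  flags <- character(0)
  converged <- FALSE
  prev <- params
  for (iter in seq_len(max_iter)) {
    E <- hmm_estep(cpgs, params)
    if (length(logliks) && E$loglik < tail(logliks, 1L) - 1e-6) {
      # numerical safety net; GEM updates should never land here
      params <- prev
      flags <- c(flags, "loglik_decrease_reverted")
      break
    }
    logliks <- c(logliks, E$loglik)
    if (length(logliks) > 1L &&
        E$loglik - logliks[length(logliks) - 1L] < tol) {
      converged <- TRUE
      break
    }
    prev <- params
    params$pi <- E$pi1 / sum(E$pi1)
    xs <- rowSums(E$xi)
    if (all(xs > 0)) params$A <- E$xi / xs
    e1 <- mstep_emission(cpgs, E$gamma[, 1L],
                         list(alpha = params$emis$alpha[1L],
                              beta = params$emis$beta[1L]))
    e2 <- mstep_emission(cpgs, E$gamma[, 2L],
                         list(alpha = params$emis$alpha[2L],
                              beta = params$emis$beta[2L]))
    params$emis <- list(alpha = c(e1$alpha, e2$alpha),
                        beta = c(e1$beta, e2$beta))
  }
  if (!converged) flags <- c(flags, "max_iter_reached")
  means <- bb_mean(params$emis)
  if (means[1L] > means[2L]) {  # relabel so HYPO is state 1
    params$pi <- rev(params$pi)
    params$A <- params$A[2:1, 2:1]
    params$emis <- list(alpha = rev(params$emis$alpha),
                        beta = rev(params$emis$beta))
  }
  if (abs(diff(bb_mean(params$emis))) < 1e-3)
    flags <- c(flags, "degenerate_states")
  validate_hmm_params(params)
  list(params = params, logliks = logliks, converged = converged,
       flags = flags)
}

#' Posterior state probabilities for each CpG
#'
#' @param cpgs CpG records as in [fit_hmm()].
#' @param params fitted `params` from [fit_hmm()].
#' @return matrix with one row per CpG and columns `HYPO`, `METH`; rows sum
#'   to 1.
#' @export
posterior_states <- function(cpgs, params) {
  validate_hmm_params(params)
  g <- hmm_estep(cpgs, params)$gamma
  colnames(g) <- c("HYPO", "METH")
  g
}

#' Call hypomethylated regions by posterior decoding
#'
#' Maximal runs of CpGs with posterior P(HYPO) > 0.5 become HMRs. Runs are
#' split where consecutive CpGs are more than `max_gap` bp apart (guards
#' against spurious mega-HMRs across unsequenced deserts) and runs with
#' fewer than `min_cpgs` CpGs are discarded. Each interval spans the first
#' to the last HYPO CpG + 1.
#'
#' @param cpgs CpG records (position-sorted within chromosome).
#' @param params fitted HMM parameters.
#' @param min_cpgs minimum CpGs per HMR.
#' @param max_gap inter-CpG distance above which a run is split (bp).
#' @return data.frame with `chrom`, `start`, `end`, `n_cpgs`, `mean_level`
#'   and a list-column `cpg_pos` of member CpG positions; disjoint and
#'   sorted.
#' @export
decode_hmrs <- function(cpgs, params, min_cpgs = 4, max_gap = 10000) {
  validate_cpgs(cpgs)
  gamma <- posterior_states(cpgs, params)
  hypo <- gamma[, 1L] > 0.5
  out <- list()
  for (idx in split(seq_len(nrow(cpgs)), cpgs$chrom)) {
    idx <- idx[order(cpgs$pos[idx])]
    h <- hypo[idx]
    if (!any(h)) next
    pos <- cpgs$pos[idx]
    lev <- cpgs$meth_count[idx] / cpgs$total_count[idx]
    # run id changes when state flips or the gap is too large
    brk <- c(TRUE, diff(h) != 0 | diff(pos) > max_gap)
    run <- cumsum(brk)
    for (r in unique(run[h])) {
      sel <- which(run == r & h)
      if (length(sel) < min_cpgs) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = cpgs$chrom[idx[1L]],
        start = pos[sel[1L]],
        end = pos[sel[length(sel)]] + 1,
        n_cpgs = length(sel),
        mean_level = mean(lev[sel]),
        stringsAsFactors = FALSE
      )
      out[[length(out)]]$cpg_pos <- I(list(pos[sel]))
    }
  }
  if (!length(out)) {
    empty <- data.frame(chrom = character(), start = numeric(),
                        end = numeric(), n_cpgs = integer(),
                        mean_level = numeric(), stringsAsFactors = FALSE)
    empty$cpg_pos <- I(list())
    return(empty)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Extract a boundary CG position under a named alignment convention
#'
#' `first_unmeth` is the outermost CpG of the HMR on the given side,
#' `second_unmeth` the next CpG inward, and `adjacent_meth` the nearest CpG
#' outside the HMR on that side. `NA` where no such CpG exists.
#'
#' @param hmrs HMR data.frame from [decode_hmrs()].
#' @param all_cpgs the full CpG record set the HMRs were called from.
#' @param mode one of `"first_unmeth"`, `"second_unmeth"`,
#'   `"adjacent_meth"`.
#' @param side `"5prime"` or `"3prime"`.
#' @return numeric vector of positions (0-based), `NA` where undefined.
#' @export
extract_boundaries <- function(hmrs, all_cpgs,
                               mode = c("first_unmeth", "second_unmeth",
                                        "adjacent_meth"),
                               side = c("5prime", "3prime")) {
  mode <- match.arg(mode)
  side <- match.arg(side)
  n <- nrow(hmrs)
  out <- rep(NA_real_, n)
  if (n == 0L) return(out)
  cpg_by_chrom <- split(all_cpgs$pos, all_cpgs$chrom)
  cpg_by_chrom <- lapply(cpg_by_chrom, sort)
  for (i in seq_len(n)) {
    cp <- sort(hmrs$cpg_pos[[i]])
    if (mode == "first_unmeth") {
      out[i] <- if (side == "5prime") cp[1L] else cp[length(cp)]
    } else if (mode == "second_unmeth") {
      if (length(cp) >= 2L)
        out[i] <- if (side == "5prime") cp[2L] else cp[length(cp) - 1L]
    } else {
      allp <- cpg_by_chrom[[hmrs$chrom[i]]]
      if (side == "5prime") {
        cand <- allp[allp < cp[1L]]
        if (length(cand)) out[i] <- max(cand)
      } else {
        cand <- allp[allp > cp[length(cp)]]
        if (length(cand)) out[i] <- min(cand)
      }
    }
  }
  out
}

#' Attach first-unmethylated-CG boundary columns to an HMR table
#'
#' Convenience wrapper adding `boundary_5` and `boundary_3`
#' (first unmethylated CG on each side).
#'
#' @inheritParams extract_boundaries
#' @return `hmrs` with the two boundary columns added.
#' @export
hmr_boundaries <- function(hmrs, all_cpgs = NULL) {
  cp <- all_cpgs %||% data.frame(chrom = character(), pos = numeric())
  hmrs$boundary_5 <- extract_boundaries(hmrs, cp, "first_unmeth", "5prime")
  hmrs$boundary_3 <- extract_boundaries(hmrs, cp, "first_unmeth", "3prime")
  hmrs
}

#' Distance from the first unmethylated CG to the adjacent methylated CG
#'
#' Summarizes, over both sides of every HMR, the bp gap between the
#' outermost HMR CpG and the nearest CpG outside the HMR. Undefined
#' boundaries (chromosome ends) are excluded.
#'
#' @inheritParams extract_boundaries
#' @return list with `gaps` (data.frame `side`, `gap`), `mean`, `median`,
#'   and `histogram` (a `hist` object, `NULL` when empty).
#' @export
boundary_gap_stats <- function(hmrs, all_cpgs) {
  sides <- c("5prime", "3prime")
  gaps <- lapply(sides, function(s) {
    fu <- extract_boundaries(hmrs, all_cpgs, "first_unmeth", s)
    am <- extract_boundaries(hmrs, all_cpgs, "adjacent_meth", s)
    data.frame(side = rep(s, length(fu)), gap = abs(fu - am))
  })
  gaps <- do.call(rbind, gaps)
  gaps <- gaps[!is.na(gaps$gap), , drop = FALSE]
  rownames(gaps) <- NULL
  list(
    gaps = gaps,
    mean = if (nrow(gaps)) mean(gaps$gap) else NA_real_,
    median = if (nrow(gaps)) median(gaps$gap) else NA_real_,
    histogram = if (nrow(gaps)) hist(gaps$gap, plot = FALSE) else NULL
  )
}
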
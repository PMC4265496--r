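# Intrinsic nucleosome occupancy scoring: reverse-complement-collapsed
# 1..4-mer frequencies (+ GC fraction) of 147-bp windows, a Lasso linear
# model fit by cyclic coordinate descent, and O(genome) per-bp scoring.

INOS_WINDOW <- 147L
INOS_HALF <- 73L
INOS_KMAX <- 4L
DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' @param s character vector of sequences over A/C/G/T/N.
#' @return reverse complement(s).
#' @export
revcomp <- function(s) {
  vapply(s, function(x) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1L]]),
          collapse = "")
  }, "", USE.NAMES = FALSE)
}

# cache for the k-mer collapsing tables
.inos_cache <- new.env(parent = emptyenv())

# For each k: code (base-4, A=0..T=3) -> global feature index; plus the
# global feature name vector (collapsed k-mers for k = 1..4, then "GC_frac").
kmer_feature_tables <- function() {
  if (!is.null(.inos_cache$tables)) return(.inos_cache$tables)
  feat_names <- character(0)
  maps <- vector("list", INOS_KMAX)
  for (k in seq_len(INOS_KMAX)) {
    grid <- do.call(expand.grid,
                    c(rep(list(DNA_BASES), k),
                      list(stringsAsFactors = FALSE)))
    # column 1 varies fastest; make column k the least significant digit
    kmers <- do.call(paste0, rev(grid))
    rc <- revcomp(kmers)
    canon <- ifelse(kmers <= rc, kmers, rc)
    feats_k <- sort(unique(canon))
    maps[[k]] <- length(feat_names) + match(canon, feats_k)
    feat_names <- c(feat_names, feats_k)
  }
  tabs <- list(maps = maps, names = c(feat_names, "GC_frac"),
               n_kmer_feats = length(feat_names))
  .inos_cache$tables <- tabs
  tabs
}

encode_seq <- function(seq) {
  enc <- match(strsplit(seq, "")[[1L]], DNA_BASES) - 1L
  enc  # N (and anything else) -> NA
}

# integer k-mer codes at every start position; NA where the k-mer hits an N
kmer_codes <- function(enc, k) {
  L <- length(enc)
  if (L < k) return(integer(0))
  codes <- enc[1:(L - k + 1L)]
  if (k > 1L) for (i in 2:k) {
    codes <- codes * 4L + enc[i:(L - k + i)]
  }
  codes
}

#' Featurize a 147-bp window
#'
#' Counts of all reverse-complement-collapsed k-mers for k = 1..4, each
#' normalized by the number of window positions for that k
#' (`147 - k + 1`), plus the window GC fraction. A k-mer and its reverse
#' complement share one feature, so the featurization of a sequence equals
#' that of its reverse complement exactly.
#'
#' @param seq a 147-bp string over A/C/G/T (N makes the window excluded:
#'   all-`NA` vector with attribute `has_n = TRUE`).
#' @return named numeric vector of features (last element `GC_frac`).
#' @export
featurize_window <- function(seq) {
  if (nchar(seq) != INOS_WINDOW)
    stop("window must be exactly ", INOS_WINDOW, " bp", call. = FALSE)
  tabs <- kmer_feature_tables()
  enc <- encode_seq(seq)
  p <- length(tabs$names)
  if (anyNA(enc)) {
    out <- rep(NA_real_, p)
    names(out) <- tabs$names
    attr(out, "has_n") <- TRUE
    return(out)
  }
  out <- numeric(p)
  for (k in seq_len(INOS_KMAX)) {
    codes <- kmer_codes(enc, k)
    idx <- tabs$maps[[k]][codes + 1L]
    cnt <- tabulate(idx, nbins = tabs$n_kmer_feats)
    out <- out + c(cnt, 0) / (INOS_WINDOW - k + 1L)
  }
  out[p] <- mean(enc == 1L | enc == 2L)
  names(out) <- tabs$names
  out
}

#' Featurize 147-bp windows centered at several positions
#'
#' @param genome a single sequence string.
#' @param centers 0-based central positions; each window spans
#'   `center - 73 .. center + 73`.
#' @return matrix, one row per center (rows of `NA` for N-containing
#'   windows), columns as in [featurize_window()].
#' @export
featurize_positions <- function(genome, centers) {
  genome <- as.character(genome[[1L]])
  L <- nchar(genome)
  if (any(centers < INOS_HALF | centers > L - INOS_HALF - 1L))
    stop("window extends beyond the sequence", call. = FALSE)
  rows <- lapply(centers, function(p)
    featurize_window(substr(genome, p - INOS_HALF + 1L,
                            p + INOS_HALF + 1L)))
  X <- do.call(rbind, rows)
  rownames(X) <- NULL
  X
}

soft_threshold <- function(z, g) sign(z) * pmax(abs(z) - g, 0)

#' Fit a Lasso linear model by cyclic coordinate descent
#'
#' Minimizes `(1/(2n)) * ||y - b0 - X w||^2 + lambda * ||w||_1`. Features
#' are standardized internally (population sd); the inverse transform is
#' folded into the returned weights and intercept, which act on raw
#' features. The penalized objective is non-increasing across coordinate
#' sweeps and the fit is deterministic given a fixed feature order.
#'
#' @param X numeric feature matrix (n x p), finite.
#' @param y numeric response of length n.
#' @param lambda L1 penalty (>= 0) on the standardized scale.
#' @param max_iter maximum full coordinate sweeps.
#' @param tol stop when the largest coefficient change in a sweep is below
#'   this.
#' @param seed recorded in the model metadata (the solver itself is
#'   deterministic).
#' @return a `lasso_model`: list with `features`, `weights` (raw scale,
#'   named), `intercept`, `lambda`, `objective` (per sweep), `n_iter`,
#'   `meta`.
#' @export
fit_lasso <- function(X, y, lambda = 0, max_iter = 1000, tol = 1e-8,
                      seed = NULL) {
  X <- as.matrix(X)
  if (!all(is.finite(X)) || !all(is.finite(y)))
    stop("non-finite values in X or y", call. = FALSE)
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 rows", call. = FALSE)
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  p <- ncol(X)
  mx <- colMeans(X)
  Xc <- sweep(X, 2L, mx)
  sx <- sqrt(colMeans(Xc^2))
  active <- sx > 1e-12
  Z <- Xc
  Z[, active] <- sweep(Xc[, active, drop = FALSE], 2L, sx[active], "/")
  Z[, !active] <- 0
  my <- mean(y)
  yc <- y - my
  beta <- numeric(p)
  r <- yc
  obj <- numeric(0)
  n_iter <- 0L
  for (sweep_i in seq_len(max_iter)) {
    delta_max <- 0
    for (j in seq_len(p)) {
      if (!active[j]) next
      zj <- Z[, j]
      rho <- mean(zj * r) + beta[j]
      bj <- soft_threshold(rho, lambda)
      if (bj != beta[j]) {
        r <- r - zj * (bj - beta[j])
        delta_max <- max(delta_max, abs(bj - beta[j]))
        beta[j] <- bj
      }
    }
    obj <- c(obj, mean(r^2) / 2 + lambda * sum(abs(beta)))
    n_iter <- sweep_i
    if (delta_max < tol) break
  }
  w <- numeric(p)
  w[active] <- beta[active] / sx[active]
  names(w) <- colnames(X)
  structure(list(
    features = colnames(X),
    weights = w,
    intercept = my - sum(w * mx),
    lambda = lambda,
    objective = obj,
    n_iter = n_iter,
    meta = list(n = n, seed = seed)
  ), class = "lasso_model")
}

#' @export
predict.lasso_model <- function(object, newdata, ...) {
  drop(as.matrix(newdata) %*% object$weights) + object$intercept
}

#' @export
print.lasso_model <- function(x, ...) {
  cat(sprintf(
    "lasso_model: %d features (%d nonzero), lambda=%g, intercept=%.4g\n",
    length(x$weights), sum(x$weights != 0), x$lambda, x$intercept))
  invisible(x)
}

#' Serialize / deserialize an INOS model as JSON
#'
#' @param model a `lasso_model`.
#' @param path file path.
#' @return `read_inos_model` returns the `lasso_model`.
#' @export
write_inos_model <- function(model, path) {
  jsonlite::write_json(
    list(features = model$features, weights = unname(model$weights),
         intercept = model$intercept, lambda = model$lambda,
         meta = model$meta),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_inos_model
#' @export
read_inos_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  w <- as.numeric(x$weights)
  names(w) <- x$features
  structure(list(features = x$features, weights = w,
                 intercept = as.numeric(x$intercept),
                 lambda = as.numeric(x$lambda),
                 objective = numeric(0), n_iter = NA_integer_,
                 meta = x$meta),
            class = "lasso_model")
}

#' Score intrinsic nucleosome occupancy at every base pair
#'
#' Applies a 147-bp window Lasso model at each position: the score at
#' 0-based position p is the model evaluated on the window
#' `p - 73 .. p + 73`. The first and last 73 bp and every window containing
#' an N are `NA`. Computed in O(genome length) by turning each k-mer weight
#' into a per-start contribution and box-summing.
#'
#' @param genome a single sequence string (or named vector of length 1).
#' @param model a `lasso_model` over the [featurize_window()] feature set.
#' @return numeric vector of scores, element `i` = 0-based position
#'   `i - 1`.
#' @export
score_inos <- function(genome, model) {
  genome <- as.character(genome[[1L]])
  L <- nchar(genome)
  if (L < INOS_WINDOW) stop("genome shorter than 147 bp", call. = FALSE)
  tabs <- kmer_feature_tables()
  if (!identical(model$features, tabs$names))
    stop("model feature set does not match featurize_window()",
         call. = FALSE)
  enc <- encode_seq(genome)
  nmask <- cumsum(c(0L, is.na(enc)))
  total <- rep(model$intercept, L)
  for (k in seq_len(INOS_KMAX)) {
    wk_by_code <- model$weights[tabs$maps[[k]]] / (INOS_WINDOW - k + 1L)
    codes <- kmer_codes(enc, k)
    contrib <- wk_by_code[codes + 1L]
    contrib[is.na(contrib)] <- 0
    S <- cumsum(c(0, contrib))
    # window starts for center c (1-based): c-73 .. c+73-k+1
    c_idx <- (INOS_HALF + 1L):(L - INOS_HALF)
    lo <- c_idx - INOS_HALF
    hi <- c_idx + INOS_HALF - k + 1L
    total[c_idx] <- total[c_idx] + (S[hi + 1L] - S[lo])
  }
  gcontrib <- as.numeric(enc == 1L | enc == 2L) *
    (model$weights[["GC_frac"]] / INOS_WINDOW)
  gcontrib[is.na(gcontrib)] <- 0
  Sg <- cumsum(c(0, gcontrib))
  c_idx <- (INOS_HALF + 1L):(L - INOS_HALF)
  total[c_idx] <- total[c_idx] +
    (Sg[c_idx + INOS_HALF + 1L] - Sg[c_idx - INOS_HALF])
  # undefined: edges and N-containing windows
  scores <- rep(NA_real_, L)
  has_n <- (nmask[c_idx + INOS_HALF + 1L] - nmask[c_idx - INOS_HALF]) > 0L
  scores[c_idx] <- ifelse(has_n, NA_real_, total[c_idx])
  scores
}

#' Train an INOS model on an occupancy track
#'
#' Samples `sample_n` positions uniformly (seeded) from positions where
#' both the 147-bp window and the track are defined, featurizes them, and
#' fits the Lasso of features on track values.
#'
#' @param genome a single sequence string.
#' @param track an `occupancy_track` defined over the genome.
#' @param sample_n number of training positions.
#' @param lambda L1 penalty.
#' @param seed RNG seed for the position sample.
#' @param max_iter,tol passed to [fit_lasso()].
#' @return a `lasso_model`.
#' @export
train_on_track <- function(genome, track, sample_n = 5000, lambda = 1e-3,
                           seed = 1, max_iter = 1000, tol = 1e-8) {
  genome <- as.character(genome[[1L]])
  L <- nchar(genome)
  seed <- check_seed(seed)
  enc <- encode_seq(genome)
  nmask <- cumsum(c(0L, is.na(enc)))
  c_idx <- (INOS_HALF + 1L):(L - INOS_HALF)
  has_n <- (nmask[c_idx + INOS_HALF + 1L] - nmask[c_idx - INOS_HALF]) > 0L
  centers0 <- c_idx[!has_n] - 1L  # 0-based
  tv <- track_values_at(track, centers0)
  centers0 <- centers0[!is.na(tv)]
  if (sample_n > length(centers0))
    stop("sample_n exceeds the number of defined positions", call. = FALSE)
  set.seed(seed)
  centers0 <- sort(sample(centers0, sample_n))
  X <- featurize_positions(genome, centers0)
  y <- track_values_at(track, centers0)
  model <- fit_lasso(X, y, lambda = lambda, max_iter = max_iter,
                     tol = tol, seed = seed)
  model$meta$sampled_positions <- sample_n
  model
}
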
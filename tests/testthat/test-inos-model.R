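test_that("window featurization counts collapsed k-mers correctly", {
  fA <- featurize_window(strrep("A", 147))
  expect_equal(unname(fA["AAAA"]), 1)           # 144/144
  expect_equal(unname(fA["GC_frac"]), 0)
  expect_equal(unname(fA["A"]), 1)
  alt <- paste(rep(c("C", "G"), length.out = 147), collapse = "")
  fCG <- featurize_window(alt)
  expect_equal(unname(fCG["CG"]), 73 / 146)
  expect_equal(unname(fCG["GC_frac"]), 1)
  expect_error(featurize_window("ACGT"), "147")
  fN <- featurize_window(paste0(strrep("A", 146), "N"))
  expect_true(all(is.na(fN)))
  expect_true(attr(fN, "has_n"))
})

test_that("featurization is exactly reverse-complement symmetric", {
  set.seed(17)
  for (i in 1:100) {
    s <- paste(sample(c("A", "C", "G", "T"), 147, TRUE), collapse = "")
    expect_identical(featurize_window(s), featurize_window(revcomp(s)))
  }
})

test_that("lasso at lambda 0 equals the normal-equations solution", {
  set.seed(23)
  X <- matrix(rnorm(50 * 5), 50, 5, dimnames = list(NULL, letters[1:5]))
  y <- rnorm(50)
  fit <- fit_lasso(X, y, lambda = 0, max_iter = 5000, tol = 1e-12)
  Xi <- cbind(1, X)
  ols <- solve(t(Xi) %*% Xi, t(Xi) %*% y)
  expect_equal(unname(fit$weights), unname(ols[-1, 1]), tolerance = 1e-6)
  expect_equal(as.numeric(fit$intercept), as.numeric(ols[1, 1]),
               tolerance = 1e-6)
})

test_that("large lambda zeroes all weights; objective never increases", {
  set.seed(24)
  n <- 80
  X <- matrix(rnorm(n * 6), n, 6)
  X <- sweep(sweep(X, 2, colMeans(X)), 2,
             sqrt(colMeans(sweep(X, 2, colMeans(X))^2)), "/")
  y <- rnorm(n)
  lam_max <- max(abs(crossprod(X, y - mean(y)))) / n
  fit <- fit_lasso(X, y, lambda = lam_max * 1.001)
  expect_true(all(fit$weights == 0))
  expect_equal(fit$intercept, mean(y))
  fit2 <- fit_lasso(X, y, lambda = lam_max / 10)
  expect_true(all(diff(fit2$objective) < 1e-12))
})

test_that("single-feature lasso equals the analytic soft-threshold", {
  set.seed(25)
  x <- rnorm(100)
  y <- 0.7 * x + rnorm(100, 0, 0.3)
  lam <- 0.1
  fit <- fit_lasso(matrix(x, ncol = 1), y, lambda = lam, tol = 1e-12)
  z <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  rho <- mean(z * (y - mean(y)))
  beta_hat <- sign(rho) * max(abs(rho) - lam, 0)
  expect_equal(unname(fit$weights[1]),
               beta_hat / sqrt(mean((x - mean(x))^2)), tolerance = 1e-9)
})

test_that("coordinate descent agrees with glmnet on a shared objective", {
  skip_if_not_installed("glmnet")
  set.seed(26)
  n <- 200
  X <- matrix(rnorm(n * 8), n, 8)
  X <- sweep(sweep(X, 2, colMeans(X)), 2,
             sqrt(colMeans(sweep(X, 2, colMeans(X))^2)), "/")
  y <- X[, 1] - 0.5 * X[, 3] + rnorm(n, 0, 0.5)
  lam <- 0.05
  fit <- fit_lasso(X, y, lambda = lam, max_iter = 5000, tol = 1e-12)
  g <- glmnet::glmnet(X, y, lambda = lam, standardize = FALSE,
                      thresh = 1e-14)
  expect_equal(unname(fit$weights), as.numeric(g$beta), tolerance = 1e-4)
})

test_that("per-bp scores match independent featurize-and-dot evaluation", {
  g <- random_genome(4000, seed = 31)
  tr <- gc_driven_track(g, seed = 32)
  mod <- train_on_track(g, tr, sample_n = 300, lambda = 1e-3, seed = 33)
  sc <- score_inos(g, mod)
  expect_true(all(is.na(sc[c(1:73, 3928:4000)])))
  set.seed(34)
  ps <- sample(100:3800, 50)
  brute <- predict(mod, featurize_positions(g, ps))
  expect_equal(sc[ps + 1], brute, tolerance = 1e-9)
})

test_that("scores are translation invariant and reverse with the strand", {
  g <- random_genome(3000, seed = 41)
  tr <- gc_driven_track(g, seed = 42)
  mod <- train_on_track(g, tr, sample_n = 200, lambda = 1e-2, seed = 43)
  # homopolymer: every window identical, score constant
  homo <- c(chr1 = strrep("A", 800))
  sch <- score_inos(homo, mod)
  expect_lt(max(sch, na.rm = TRUE) - min(sch, na.rm = TRUE), 1e-9)
  # periodic sequence: windows one period apart are identical strings
  per <- c(chr1 = paste(rep("ACGT", 200), collapse = ""))
  scp <- score_inos(per, mod)
  expect_equal(scp[200 + seq(0, 400, by = 4)],
               rep(scp[200], 101), tolerance = 1e-12)
  sc <- score_inos(g, mod)
  grc <- revcomp(as.character(g)); names(grc) <- "chr1"
  expect_equal(rev(score_inos(grc, mod)), sc, tolerance = 1e-12)
})

test_that("training recovers a planted GC-driven signal", {
  g <- random_genome(60000, seed = 51, gc = 0.45)
  # occupancy as a known linear function of window GC fraction plus noise
  gc <- strsplit(as.character(g), "")[[1]] %in% c("C", "G")
  box <- as.numeric(stats::filter(gc, rep(1 / 147, 147)))
  set.seed(52)
  v <- 1 + 3 * box + rnorm(length(box), 0, 0.05)
  v[is.na(v)] <- 1
  tr <- make_track(v)
  mod <- train_on_track(g, tr, sample_n = 2000, lambda = 1e-3, seed = 53)
  sc <- score_inos(g, mod)
  set.seed(54)
  held <- sample(setdiff(100:59900, mod$meta$sampled), 3000)
  y <- track_values_at(tr, held)
  r2 <- 1 - mean((sc[held + 1] - y)^2) / var(y)
  expect_gte(r2, 0.5)
  probe <- sample(100:59900, 500)
  X <- featurize_positions(g, probe)
  expect_gt(cor(predict(mod, X), X[, "GC_frac"]), 0.5)
})

test_that("lasso path is sparser as lambda grows; training is deterministic", {
  g <- random_genome(20000, seed = 61)
  tr <- gc_driven_track(g, seed = 62)
  nz <- sapply(c(0, 1e-4, 1e-3, 1e-2, 1e-1), function(l)
    sum(train_on_track(g, tr, sample_n = 300, lambda = l,
                       seed = 63)$weights != 0))
  expect_true(all(diff(nz) <= 0))
  m1 <- train_on_track(g, tr, sample_n = 300, lambda = 1e-3, seed = 64)
  m2 <- train_on_track(g, tr, sample_n = 300, lambda = 1e-3, seed = 64)
  expect_identical(m1$weights, m2$weights)
})

test_that("INOS models survive a JSON round trip", {
  g <- random_genome(8000, seed = 71)
  tr <- gc_driven_track(g, seed = 72)
  mod <- train_on_track(g, tr, sample_n = 200, lambda = 1e-3, seed = 73)
  f <- withr::local_tempfile()
  write_inos_model(mod, f)
  back <- read_inos_model(f)
  expect_equal(back$weights, mod$weights)
  expect_equal(back$intercept, mod$intercept)
  expect_equal(score_inos(g, back), score_inos(g, mod))
})
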
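# Brute-force oracle: per-pair Pearson statistics by explicit loops over the
# textbook formulas, independent of the vectorized implementation.
naive_assoc <- function(X, Y) {
  p <- nrow(X); q <- nrow(Y); n <- ncol(X)
  r <- t <- pv <- matrix(NA_real_, p, q)
  for (i in seq_len(p)) for (j in seq_len(q)) {
    x <- X[i, ]; y <- Y[j, ]
    rij <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    tij <- rij * sqrt((n - 2) / (1 - rij^2))
    r[i, j] <- rij; t[i, j] <- tij
    pv[i, j] <- 2 * pt(-abs(tij), n - 2)
  }
  list(r = r, t = t, pval = pv)
}

test_that("pairwise_association matches the naive loop oracle to 1e-10", {
  set.seed(21)
  X <- toy_expression(p = 20L, n = 10L)
  Y <- toy_response(q = 5L, n = 10L)
  colnames(Y) <- colnames(X)
  a <- pairwise_association(X, Y)
  o <- naive_assoc(X, Y)
  expect_lt(max(abs(a$r - o$r)), 1e-10)
  expect_lt(max(abs(a$t - o$t)), 1e-10)
  expect_lt(max(abs(a$pval - o$pval)), 1e-10)
  # z transform and sign conventions
  expect_equal(a$z, atanh(a$r) * sqrt(10 - 3), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_true(all(sign(a$z) == sign(a$r)))
})

test_that("n=5 toy vectors reproduce the closed-form statistics", {
  X <- matrix(c(1, 2, 3, 4, 5), 1, 5, dimnames = list("g", paste0("s", 1:5)))
  Y <- matrix(c(2, 1, 4, 3, 5), 1, 5, dimnames = list("d", paste0("s", 1:5)))
  a <- pairwise_association(X, Y)
  r <- 0.8  # cor((1..5),(2,1,4,3,5))
  expect_equal(unname(a$r[1, 1]), r, tolerance = 1e-12)
  expect_equal(unname(a$t[1, 1]), r * sqrt(3 / (1 - r^2)), tolerance = 1e-12)
  expect_equal(unname(a$pval[1, 1]), 2 * pt(-r * sqrt(3 / (1 - r^2)), 3),
               tolerance = 1e-12)
})

test_that("perfect association yields the smallest representable p-value", {
  X <- toy_expression(p = 3L, n = 8L)
  Y <- X[1, , drop = FALSE]
  rownames(Y) <- "d"
  a <- pairwise_association(X, Y)
  expect_equal(unname(a$r[1, 1]), 1)
  # internally clipped |r|, so the p-value is tiny but never exactly zero
  expect_lt(unname(a$pval[1, 1]), 1e-40)
  expect_true(all(a$pval > 0))
})

test_that("null p-values are uniform (KS at alpha = 0.01)", {
  set.seed(7)
  n <- 20L
  X <- matrix(rnorm(1000 * n), 1000, n,
              dimnames = list(paste0("g", 1:1000), paste0("s", 1:n)))
  Y <- matrix(rnorm(n), 1, n, dimnames = list("d", paste0("s", 1:n)))
  a <- pairwise_association(X, Y)
  expect_gt(ks.test(as.vector(a$pval), "punif")$p.value, 0.01)
})

test_that("Spearman mode is rank-invariant, covariates give partial tests", {
  set.seed(9)
  X <- toy_expression(p = 6L, n = 12L)
  Y <- toy_response(q = 3L, n = 12L)
  colnames(Y) <- colnames(X)
  a1 <- pairwise_association(X, Y, rank_based = TRUE)
  a2 <- pairwise_association(exp(X), Y^3, rank_based = TRUE)  # monotone maps
  expect_equal(a1$r, a2$r, tolerance = 1e-12)
  # against cor.test's Spearman estimate
  expect_equal(unname(a1$r[2, 3]),
               unname(cor.test(X[2, ], Y[3, ], method = "spearman")$estimate),
               tolerance = 1e-12)

  # constant covariate leaves p unchanged (to 1e-9); real covariate matches lm
  cov_const <- matrix(1, ncol(X), 1)
  a0 <- pairwise_association(X, Y)
  ac <- pairwise_association(X, Y, covariates = cov_const)
  expect_equal(ac$pval, a0$pval, tolerance = 1e-9)

  cv <- matrix(rnorm(ncol(X)), ncol(X), 1)
  ap <- pairwise_association(X, Y, covariates = cv)
  fit <- summary(lm(Y[1, ] ~ X[3, ] + cv))$coefficients
  expect_equal(unname(ap$pval[3, 1]), fit["X[3, ]", "Pr(>|t|)"],
               tolerance = 1e-9)
})

test_that("degenerate inputs are flagged or rejected", {
  X <- toy_expression(p = 4L, n = 8L)
  Y <- toy_response(q = 2L, n = 8L)
  colnames(Y) <- colnames(X)
  X[2, ] <- 3  # zero variance
  expect_warning(a <- pairwise_association(X, Y), "zero-variance")
  expect_true(all(is.na(a$r[2, ])))
  expect_error(pairwise_association(X[, 1:3], Y[, 1:3]), "4 samples")
  expect_error(pairwise_association(X[, 1:2], Y[, 1:4]), "aligned")
})

test_that("fisher_z evaluates the closed form with odd symmetry and clipping", {
  expect_identical(fisher_z(0, 30), 0)
  expect_equal(fisher_z(0.5, 30), atanh(0.5) * sqrt(27), tolerance = 1e-12)
  expect_equal(fisher_z(-0.3, 10), -fisher_z(0.3, 10), tolerance = 1e-12)
  expect_warning(z1 <- fisher_z(1, 10), "clipped")
  expect_true(is.finite(z1))
})

test_that("bh_select equals the exhaustive step-up enumeration", {
  p <- c(0.001, 0.008, 0.039, 0.041, 0.9)
  # exhaustive BH: largest k with p_(k) <= k*q/m, select the k smallest
  bh_oracle <- function(pv, q) {
    m <- length(pv)
    o <- order(pv)
    ks <- which(pv[o] <= seq_len(m) * q / m)
    if (length(ks) == 0L) integer(0L) else sort(o[seq_len(max(ks))])
  }
  expect_identical(bh_select(p, q = 0.1), bh_oracle(p, 0.1))
  set.seed(13)
  for (i in 1:20) {
    pv <- runif(50)^2
    expect_identical(bh_select(pv, q = 0.1), bh_oracle(pv, 0.1))
  }
  # edge cases
  expect_identical(bh_select(rep(1, 5), q = 0.1), integer(0L))
  expect_identical(bh_select(0.05, q = 0.1), 1L)  # m = 1: raw threshold
  expect_identical(bh_select(numeric(0L)), integer(0L))
})

test_that("bh_select on tables is monotone in q and order-invariant", {
  set.seed(17)
  X <- toy_expression(p = 30L, n = 10L)
  Y <- toy_response(q = 4L, n = 10L)
  colnames(Y) <- colnames(X)
  Y[1, ] <- X[5, ] + rnorm(10, 0, 0.1)  # plant one association
  a <- pairwise_association(X, Y)
  s1 <- bh_select(a, q = 0.05)
  s2 <- bh_select(a, q = 0.2)
  key <- function(s) paste(s$gene_id, s$drug_id)
  expect_true(all(key(s1) %in% key(s2)))
  expect_true(all(s2$q_value <= 0.2))
  # permuting genes does not change the selected pair set
  perm <- sample(nrow(X))
  ap <- pairwise_association(X[perm, ], Y)
  expect_setequal(key(bh_select(ap, q = 0.2)), key(s2))
})
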
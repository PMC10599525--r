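test_that("correlations match hand-computed values and invariances", {
  x <- c(1, 2, 3, 4, 5)
  ct <- correlate_vectors(x, 2 * x + 1)
  expect_equal(ct$estimate, 1)
  expect_lt(ct$p_value, 1e-8)

  sp <- correlate_vectors(c(1, 2, 3, 4), c(1, 3, 2, 4), method = "spearman")
  expect_equal(sp$estimate, 0.8)

  # Pearson invariant under positive affine transform; sign flips on negation
  set.seed(2); a <- rnorm(20); b <- rnorm(20)
  r0 <- correlate_vectors(a, b)$estimate
  expect_equal(correlate_vectors(3 * a + 7, b)$estimate, r0)
  expect_equal(correlate_vectors(-a, b)$estimate, -r0)
  # Spearman invariant under strictly monotone transform
  rho0 <- correlate_vectors(a, b, "spearman")$estimate
  expect_equal(correlate_vectors(exp(a), b, "spearman")$estimate, rho0)

  expect_error(correlate_vectors(rep(1, 5), 1:5), "zero variance")
  expect_error(correlate_vectors(1:2, 2:3), "at least 3")
})

test_that("orthogonal fit matches collinear lines and the eigen oracle", {
  f1 <- orthogonal_fit(c(0, 1, 2), c(0, 2, 4))
  expect_equal(f1$slope, 2)
  expect_equal(f1$intercept, 0)
  f2 <- orthogonal_fit(c(0, 2, 4), c(0, 1, 2))
  expect_equal(f2$slope, 0.5)

  set.seed(13)
  x <- rnorm(20); y <- 0.6 * x + rnorm(20, sd = 0.4)
  fit <- orthogonal_fit(x, y)
  # independent oracle: first eigenvector of the 2x2 covariance
  S <- cov(cbind(x, y))
  ev <- eigen(S)$vectors[, 1]
  expect_equal(fit$slope, ev[2] / ev[1], tolerance = 1e-10)
  # residuals orthogonal to the fitted direction
  d <- c(1, fit$slope) / sqrt(1 + fit$slope^2)
  M <- cbind(x - mean(x), y - mean(y))
  resid <- M - (M %*% d) %*% t(d)
  expect_lt(max(abs(resid %*% d)), 1e-10)
  expect_error(orthogonal_fit(c(0, 1, 0, -1), c(1, 0, -1, 0)), "isotropic")
})

test_that("pairwise synonymous differences produce 87 oriented pairs", {
  code <- genetic_code_partition()
  set.seed(4)
  x <- stats::setNames(rnorm(59), code$scored_codons)
  y <- stats::setNames(rnorm(59), code$scored_codons)
  pd <- pairwise_synonym_diffs(x, y, code)
  expect_equal(nrow(pd), 87)
  # block-size arithmetic: 9*C(2,2... choose pairs) + 3 + 5*6 + 3*15
  expect_equal(nrow(pd), 9 * 1 + 1 * 3 + 5 * 6 + 3 * 15)
  expect_true(all(pd$dx >= 0))
  # every pair is intra-block
  expect_true(all(code$block_of[pd$codon_hi] == code$block_of[pd$codon_lo]))
  # x against itself: dy == dx and r == 1
  pid <- pairwise_synonym_diffs(x, x, code)
  expect_equal(pid$dx, pid$dy)
  expect_equal(correlate_vectors(pid$dx, pid$dy)$estimate, 1)
  # 2-fold antisymmetric entries give one pair with dx = 2a
  x2 <- x; x2["AAA"] <- 0.7; x2["AAG"] <- -0.7
  pk <- pairwise_synonym_diffs(x2, y, code)
  lys <- pk[pk$block == "K", ]
  expect_equal(nrow(lys), 1)
  expect_equal(lys$dx, 1.4)
  expect_equal(lys$codon_hi, "AAA")
  expect_equal(lys$dy, unname(y["AAA"] - y["AAG"]))
})

test_that("pair counts track arbitrary partitions", {
  split_code <- genetic_code_partition(repartition = list(
    R_AG = c("AGA", "AGG"), R_CG = c("CGT", "CGC", "CGA", "CGG")
  ))
  x <- stats::setNames(seq_len(59), split_code$scored_codons)
  pd <- pairwise_synonym_diffs(x, x, split_code)
  # Arg now contributes C(2,2)... 1 + 6 pairs instead of 15
  expect_equal(nrow(pd), 87 - 15 + 1 + 6)
})

test_that("exact two-sided binomial sign test matches pmf enumeration", {
  code <- genetic_code_partition()
  # 30 A/T-ending scored codons, 22 positive
  at <- code$scored_codons[third_base(code$scored_codons) %in% c("A", "T")]
  expect_length(at, 30)
  vals <- stats::setNames(numeric(59), code$scored_codons)
  vals[at] <- -abs(rnorm(30))
  vals[at[1:22]] <- abs(rnorm(22))
  res <- sign_binomial_test(vals, at, "positive")
  expect_equal(res$k, 22)
  expect_equal(res$n, 30)
  expect_equal(signif(res$p_value, 2), 0.016)

  # exhaustive agreement with direct pmf summation, all n <= 30
  for (n in c(1, 5, 12, 29, 30)) {
    for (k in 0:n) {
      v <- stats::setNames(c(rep(1, k), rep(-1, n - k)),
                           code$scored_codons[seq_len(n)])
      p <- sign_binomial_test(v, names(v), "positive")$p_value
      expected <- min(1, 2 * min(pbinom(k, n, 0.5),
                                 1 - pbinom(k - 1, n, 0.5)))
      expect_equal(p, expected)
    }
  }
  # single trial
  expect_equal(sign_binomial_test(c(AAA = 1), "AAA", "positive")$p_value, 1)
  # zeros counted as non-matching, reported separately
  z <- sign_binomial_test(c(AAA = 0, AAG = 1, GAA = -1),
                          c("AAA", "AAG", "GAA"), "positive")
  expect_equal(z$k, 1)
  expect_equal(z$n_zero, 1)
})

test_that("multivariate OLS matches the normal-equations oracle", {
  # response equal to one predictor
  set.seed(6)
  x1 <- rnorm(30); x2 <- rnorm(30)
  f <- multivariate_fit(x1, list(a = x1, b = x2))
  expect_equal(unname(f$coefficients["a"]), 1)
  expect_equal(unname(f$coefficients["b"]), 0, tolerance = 1e-12)
  expect_equal(f$adj_r_squared, 1)

  # 6-point bivariate fit against explicit normal equations
  xa <- c(1, 2, 3, 4, 5, 6); xb <- c(2, 1, 4, 3, 6, 5)
  y <- c(1.2, 2.1, 2.8, 4.4, 5.0, 6.3)
  f2 <- multivariate_fit(y, list(xa = xa, xb = xb))
  X <- cbind(1, xa, xb)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(unname(f2$coefficients), as.vector(beta), tolerance = 1e-10)

  # quadratic term
  g <- seq(0.2, 0.8, length.out = 30)
  r <- 3 * g - 2.3 * g^2
  fq <- multivariate_fit(r, list(gc3 = g), include_quadratic = "gc3")
  expect_equal(unname(fq$coefficients["gc3"]), 3, tolerance = 1e-8)
  expect_equal(unname(fq$coefficients["gc32"]), -2.3, tolerance = 1e-8)

  # collinear design errors
  expect_error(multivariate_fit(y, list(a = xa, b = 2 * xa)), "collinear")
})

test_that("Cronbach's alpha matches hand computation and its degenerate cases", {
  m <- matrix(c(1, 2, 2, 3, 3, 5), ncol = 2, byrow = TRUE)
  a <- cronbach_alpha(m)
  expect_equal(a$alpha, 2 * (1 - (1 + 7 / 3) / (19 / 3)))
  expect_equal(a$alpha, 18 / 19)
  expect_true(a$ci_low <= a$alpha && a$alpha <= a$ci_high)

  # k duplicated copies of one item -> alpha exactly 1
  set.seed(8); item <- rnorm(12)
  dup <- cbind(item, item, item, item)
  expect_equal(cronbach_alpha(dup)$alpha, 1)

  expect_error(cronbach_alpha(matrix(1, 5, 3)), "zero total variance")
  expect_error(cronbach_alpha(matrix(rnorm(4), 2, 2)), ">= 2 items and >= 3 subjects")
})
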
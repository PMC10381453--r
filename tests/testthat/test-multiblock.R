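# Multi-block fusion: Frobenius scaling, super-matrix fit, block weights,
# correlation loadings.

test_that("Frobenius scaling divides by the root sum of squares", {
  b <- spectral_block("A", 1:2, rbind(c(3, 4), c(0, 0)),
                      data.frame(sample_id = c("s1", "s2"), replicate = 1L))
  sc <- frobenius_scale(list(A = b))
  expect_equal(unname(sc$norms), 5)
  expect_equal(sc$blocks$blocks$A$intensities, rbind(c(0.6, 0.8), c(0, 0)))

  set.seed(31)
  bs <- list(
    A = spectral_block("A", 1:6, matrix(rnorm(24), 4),
                       data.frame(sample_id = paste0("s", 1:4),
                                  replicate = 1L)),
    B = spectral_block("B", 1:3, matrix(rnorm(12), 4),
                       data.frame(sample_id = paste0("s", 1:4),
                                  replicate = 1L)))
  sc2 <- frobenius_scale(bs)
  for (b in sc2$blocks$blocks)
    expect_equal(sqrt(sum(b$intensities^2)), 1, tolerance = 1e-12)

  # two blocks equal up to a scalar are identical after scaling
  bs$B <- spectral_block("B", 1:6, 13 * bs$A$intensities, bs$A$row_keys)
  sc3 <- frobenius_scale(bs)
  expect_equal(sc3$blocks$blocks$A$intensities,
               sc3$blocks$blocks$B$intensities, tolerance = 1e-12)

  zero <- spectral_block("Z", 1:2, matrix(0, 2, 2),
                         data.frame(sample_id = c("s1", "s2"),
                                    replicate = 1L))
  expect_error(frobenius_scale(list(Z = zero)), "zero-Frobenius-norm")
})

test_that("a one-block fusion degenerates to plain PLS on the scaled block", {
  set.seed(32)
  X <- matrix(rnorm(20 * 9), 20, 9)
  y <- rep(c(0, 1), 10)
  keys <- data.frame(sample_id = paste0("s", 1:20), replicate = 1L)
  b <- spectral_block("M", 1:9, X, keys)
  mb <- fit_mbpls(list(M = b), y, A = 3)
  ref <- fit_pls(X / sqrt(sum(X^2)), y, A = 3)
  expect_equal(unname(predict(mb, list(M = b))),
               unname(predict(ref, X / sqrt(sum(X^2)))), tolerance = 1e-10)
  expect_equal(unname(mb$block_weights), matrix(1, 1, 3), tolerance = 1e-12)
})

test_that("a duplicated block carries exactly half the weight on every LV", {
  set.seed(33)
  X <- matrix(rnorm(16 * 7), 16, 7)
  y <- rep(c(0, 1), 8)
  keys <- data.frame(sample_id = paste0("s", 1:16), replicate = 1L)
  bs <- list(A = spectral_block("A", 1:7, X, keys),
             B = spectral_block("B", 1:7, X, keys))
  mb <- fit_mbpls(bs, y, A = 4)
  expect_equal(unname(mb$block_weights),
               matrix(0.5, 2, 4), tolerance = 1e-8)
  expect_equal(colSums(mb$block_weights), rep(1, 4), tolerance = 1e-12)
  expect_true(all(mb$block_weights >= 0 & mb$block_weights <= 1))
})

test_that("the block carrying the class effect dominates LV1, as X'y predicts", {
  set.seed(34)
  n <- 24
  y <- rep(c(0, 1), n / 2)
  keys <- data.frame(sample_id = paste0("s", seq_len(n)), replicate = 1L)
  mk <- function(nm, signal) {
    X <- matrix(rnorm(n * 10, sd = 1), n, 10)
    if (signal) X[, 4] <- X[, 4] + 3 * y
    spectral_block(nm, 1:10, X, keys)
  }
  bs <- list(S = mk("S", TRUE), N1 = mk("N1", FALSE), N2 = mk("N2", FALSE))
  mb <- fit_mbpls(bs, y, A = 2)
  expect_gt(mb$block_weights["S", 1], mb$block_weights["N1", 1])
  expect_gt(mb$block_weights["S", 1], mb$block_weights["N2", 1])

  # oracle: recompute w1 directly as X'y on the hand-scaled super-matrix
  Xs <- do.call(cbind, lapply(bs, function(b)
    b$intensities / sqrt(sum(b$intensities^2))))
  Xc <- scale(Xs, scale = FALSE)
  w1 <- crossprod(Xc, y - mean(y))
  w1 <- w1 / sqrt(sum(w1^2))
  shares <- c(S = sum(w1[1:10]^2), N1 = sum(w1[11:20]^2),
              N2 = sum(w1[21:30]^2))
  expect_equal(unname(mb$block_weights[, 1]), unname(shares),
               tolerance = 1e-10)
})

test_that("fusion requires sample-to-sample correspondence across blocks", {
  keys1 <- data.frame(sample_id = paste0("s", 1:4), replicate = 1L)
  keys2 <- data.frame(sample_id = paste0("s", c(1, 2, 4, 3)), replicate = 1L)
  b1 <- spectral_block("A", 1:3, matrix(rnorm(12), 4), keys1)
  b2 <- spectral_block("B", 1:3, matrix(rnorm(12), 4), keys2)
  expect_error(block_set(list(A = b1, B = b2)), "correspondence")
})

test_that("correlation loadings match a direct Pearson oracle and stay in the unit disc", {
  set.seed(35)
  X <- matrix(rnorm(30 * 15), 30, 15)
  y <- rep(c(0, 1), 15)
  X[, 1:3] <- X[, 1:3] + y
  keys <- data.frame(sample_id = paste0("s", 1:30), replicate = 1L)
  mb <- fit_mbpls(list(M = spectral_block("M", 1:15, X, keys)), y, A = 3)

  t1 <- mb$inner$T[, 1]; t2 <- mb$inner$T[, 2]
  vars <- cbind(exact_t1 = t1,
                orth = residuals(lm(rnorm(30) ~ t1 + t2)),
                chan = X[, 2],
                flat = rep(1, 30))
  cl <- correlation_loadings(mb, vars)
  expect_equal(cl$r1[1], 1, tolerance = 1e-10)
  expect_equal(cl$r2[1], 0, tolerance = 1e-10)
  expect_equal(cl$r1[2], 0, tolerance = 1e-10)
  expect_equal(cl$r2[2], 0, tolerance = 1e-10)
  expect_equal(cl$r1[3], cor(X[, 2], t1), tolerance = 1e-12)  # oracle
  expect_equal(cl$r2[3], cor(X[, 2], t2), tolerance = 1e-12)
  expect_true(is.na(cl$r1[4]) && is.na(cl$r2[4]))  # missing, not zero
  expect_identical(attr(cl, "radii"), c(0.5, 1))

  # unit-disc property over every channel of the training block
  cl_all <- correlation_loadings(mb, X)
  expect_true(all(cl_all$r1^2 + cl_all$r2^2 <= 1 + 1e-12))
})

test_that("rescaling any input block changes nothing downstream", {
  st <- generate_study(small_config(seed = 4L))
  prep <- prep_study(st, small_specs())
  design <- aligned_design(st, prep)
  y <- design$class

  mb1 <- fit_mbpls(prep, y, A = 3)
  scaled <- prep
  scaled$NIR <- spectral_block("NIR", prep$NIR$axis,
                               prep$NIR$intensities * 1e3,
                               prep$NIR$row_keys)
  mb2 <- fit_mbpls(scaled, y, A = 3)
  expect_equal(unname(predict(mb2, scaled)), unname(predict(mb1, prep)),
               tolerance = 1e-8)
  expect_equal(mb2$block_weights, mb1$block_weights, tolerance = 1e-8)
  cl1 <- correlation_loadings(mb1, prep$MIR$intensities[, 1:20])
  cl2 <- correlation_loadings(mb2, prep$MIR$intensities[, 1:20])
  expect_equal(cl2$r1, cl1$r1, tolerance = 1e-8)
  expect_equal(cl2$r2, cl1$r2, tolerance = 1e-8)
})

test_that("the E1 subgroup with a distinct effect multiplier correlates most", {
  st <- generate_study(small_config(
    seed = 9L, subgroup_multipliers = c(E1 = 2, M1 = 0.5)))
  prep <- prep_study(st, small_specs())
  design <- aligned_design(st, prep)
  mb <- fit_mbpls(prep, design$class, A = 2)
  dummies <- cbind(E1 = as.numeric(design$subgroup == "E1"),
                   M1 = as.numeric(design$subgroup == "M1"))
  cl <- correlation_loadings(mb, dummies)
  # direct Pearson oracle
  expect_equal(cl$r1[1], cor(dummies[, 1], mb$inner$T[, 1]),
               tolerance = 1e-12)
  expect_gt(max(abs(cl[1, c("r1", "r2")])), max(abs(cl[2, c("r1", "r2")])))
})
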
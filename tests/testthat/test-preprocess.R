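# Preprocessing: Savitzky-Golay, SNV, trimming, clipping, stage order.

make_block <- function(X, axis = seq_len(ncol(X))) {
  spectral_block("TEST", axis, X,
                 data.frame(sample_id = paste0("s", seq_len(nrow(X))),
                            replicate = 1L))
}

test_that("Savitzky-Golay reproduces polynomials up to its order exactly", {
  i <- 0:60
  cubic <- 2 + 0.5 * i - 0.03 * i^2 + 0.001 * i^3
  b <- make_block(rbind(cubic))
  out <- savitzky_golay(b, preprocess_spec(deriv_order = 0L, sg_window = 5L,
                                           sg_polyorder = 3L))
  expect_equal(out$intensities[1, ], cubic, tolerance = 1e-10)

  # derivative of a linear ramp r_i = 3 i is the constant 3
  ramp <- make_block(rbind(3 * i))
  out1 <- savitzky_golay(ramp, preprocess_spec(deriv_order = 1L,
                                               sg_window = 5L,
                                               sg_polyorder = 2L))
  expect_equal(out1$intensities[1, ], rep(3, length(i)), tolerance = 1e-10)
})

test_that("second SG derivative of i^2 matches a central finite-difference oracle", {
  i <- 0:50
  sq <- make_block(rbind(i^2))
  out <- savitzky_golay(sq, preprocess_spec(deriv_order = 2L, sg_window = 7L,
                                            sg_polyorder = 3L))
  # oracle: interior second central differences of i^2 are exactly 2
  x <- i^2
  oracle <- x[1:49] - 2 * x[2:50] + x[3:51]
  expect_equal(out$intensities[1, 2:50], oracle, tolerance = 1e-9)
  expect_equal(out$intensities[1, ], rep(2, 51), tolerance = 1e-9)
})

test_that("SG rejects invalid windows", {
  b <- make_block(matrix(rnorm(40), 2, 20))
  expect_error(savitzky_golay(b, preprocess_spec(sg_window = 21L)),
               "exceeds channel count")
  expect_error(preprocess_spec(sg_window = 6L), "odd")
  expect_error(preprocess_spec(sg_window = 3L, sg_polyorder = 3L),
               "smaller than sg_window")
  expect_error(preprocess_spec(deriv_order = 2L, sg_polyorder = 1L,
                               sg_window = 5L), "deriv_order")
})

test_that("SNV matches its defining transform and the [1,2,3] convention", {
  b <- make_block(rbind(c(1, 2, 3)))
  expect_equal(snv(b)$intensities[1, ], c(-1, 0, 1))

  set.seed(7)
  r <- rnorm(50, mean = 3, sd = 2)
  out <- snv(make_block(rbind(r)))$intensities[1, ]
  expect_equal(out, (r - mean(r)) / sd(r), tolerance = 1e-12)  # direct oracle

  set.seed(8)
  X <- matrix(rnorm(200), 4, 50)
  out2 <- snv(make_block(X))$intensities
  expect_equal(rowMeans(out2), rep(0, 4), tolerance = 1e-12)
  expect_equal(apply(out2, 1, sd), rep(1, 4), tolerance = 1e-12)
})

test_that("SNV is idempotent and errors on constant rows naming the row", {
  set.seed(9)
  b <- make_block(matrix(rnorm(120), 3, 40))
  once <- snv(b)
  twice <- snv(once)
  expect_equal(twice$intensities, once$intensities, tolerance = 1e-10)

  cb <- make_block(rbind(rnorm(10), rep(5, 10)))
  expect_error(snv(cb), "sample_id=s2")
})

test_that("trimming keeps the closed interval and normalises reversed bounds", {
  axis <- 400:4000  # step 1
  b <- make_block(matrix(rnorm(2 * length(axis)), 2), axis = axis)
  tr <- trim_block(b, 900, 1800)
  expect_identical(length(tr$axis), 901L)
  expect_true(all(tr$axis >= 900 & tr$axis <= 1800))

  expect_equal(trim_block(b, 4000, 400)$intensities, b$intensities)
  rev_tr <- trim_block(b, 1800, 900)
  expect_equal(rev_tr$intensities, tr$intensities)
  expect_error(trim_block(b, 5000, 6000), "retains no channels")
})

test_that("clipping deletes the stated regions and defaults to identity", {
  axis <- seq(100, 200, by = 1)
  b <- make_block(matrix(rnorm(101), 1), axis = axis)
  expect_identical(clip_block(b, NULL), b)
  cl <- clip_block(b, list(c(150, 160)))
  expect_false(any(cl$axis >= 150 & cl$axis <= 160))
  expect_identical(length(cl$axis), 90L)
})

test_that("preprocess_block applies the stages in order and logs provenance", {
  axis <- seq(400, 4000, by = 2)
  set.seed(10)
  X <- matrix(rnorm(3 * length(axis)), 3)
  b <- make_block(X, axis = axis)

  spec <- preprocess_spec(deriv_order = 0L, sg_window = 5L, apply_snv = FALSE)
  out <- preprocess_block(b, spec)
  expect_equal(out$intensities,
               savitzky_golay(b, spec)$intensities)  # SG only

  mir <- preprocess_spec(deriv_order = 2L, sg_window = 201L,
                         sg_polyorder = 3L, apply_snv = TRUE,
                         trim_lo = 900, trim_hi = 1800)
  out2 <- preprocess_block(b, mir)
  expect_true(all(out2$axis >= 900 & out2$axis <= 1800))
  # SNV precedes the trim, so trimmed rows are approximately centered only
  expect_true(all(abs(rowMeans(out2$intensities)) < 0.5))
  expect_true(any(grepl("snv", attr(out2, "provenance"))))
})

test_that("preprocessing is row-local: row permutation commutes, identical rows agree", {
  set.seed(11)
  X <- matrix(rnorm(5 * 80), 5, 80)
  X[3, ] <- X[1, ]  # duplicated spectrum
  b <- make_block(X)
  spec <- preprocess_spec(deriv_order = 1L, sg_window = 7L, apply_snv = TRUE)
  out <- preprocess_block(b, spec)
  expect_equal(out$intensities[3, ], out$intensities[1, ], tolerance = 1e-12)

  perm <- c(4, 2, 5, 1, 3)
  bp <- spectral_block("TEST", b$axis, X[perm, ], b$row_keys)
  outp <- preprocess_block(bp, spec)
  expect_equal(outp$intensities, out$intensities[perm, ], tolerance = 1e-12)
})

test_that("derivatives remove additive offsets and linear baselines", {
  set.seed(12)
  r <- rnorm(100)
  b1 <- make_block(rbind(r, r + 7))
  spec1 <- preprocess_spec(deriv_order = 1L, sg_window = 7L,
                           apply_snv = FALSE)
  d1 <- savitzky_golay(b1, spec1)$intensities
  expect_equal(d1[1, ], d1[2, ], tolerance = 1e-10)

  i <- seq_len(100)
  b2 <- make_block(rbind(r, r + 2.5 * i + 3))
  spec2 <- preprocess_spec(deriv_order = 2L, sg_window = 7L,
                           apply_snv = FALSE)
  d2 <- savitzky_golay(b2, spec2)$intensities
  expect_equal(d2[1, ], d2[2, ], tolerance = 1e-9)
})

test_that("replicate averaging yields one row per sample in first-seen order", {
  X <- rbind(c(1, 2), c(3, 4), c(10, 20), c(30, 40))
  b <- spectral_block("TEST", 1:2, X,
                      data.frame(sample_id = c("a", "a", "b", "b"),
                                 replicate = c(1L, 2L, 1L, 2L)))
  avg <- average_replicates(b)
  expect_identical(avg$row_keys$sample_id, c("a", "b"))
  expect_equal(avg$intensities, rbind(c(2, 3), c(20, 30)))
})

test_that("preprocess specs serialise to YAML and back", {
  spec <- preprocess_spec(deriv_order = 2L, sg_window = 201L,
                          sg_polyorder = 3L, trim_lo = 900, trim_hi = 1800)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_preprocess_spec(spec, path)
  expect_equal(read_preprocess_spec(path), spec)
})
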
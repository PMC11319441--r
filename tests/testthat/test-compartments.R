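# compartments: masking, ICE, distance correction, PCA scoring.

test_that("contact_matrix validates its input", {
  expect_error(contact_matrix("c", matrix(1, 2, 3), 2e5), "square")
  M <- matrix(-1, 2, 2)
  expect_error(contact_matrix("c", M, 2e5), "non-negative")
  M2 <- matrix(c(1, 2, 5, 1), 2, 2)
  expect_error(contact_matrix("c", M2, 2e5), "symmetric")
})

test_that("the default mask removes zero and low-coverage bins", {
  M <- matrix(10, 5, 5)
  M[5, ] <- 0; M[, 5] <- 0
  cm <- contact_matrix("c", M, 2e5)
  expect_true(cm$mask[5])
  expect_false(any(cm$mask[1:4]))
})

test_that("a constant matrix is already balanced", {
  cm <- contact_matrix("c", matrix(3, 4, 4), 2e5, mask = rep(FALSE, 4))
  bm <- ice_balance(cm)
  expect_true(bm$converged)
  b <- bm$bias
  expect_lt(stats::sd(b) / mean(b), 1e-12)
  s <- rowSums(bm$matrix)
  expect_lt(max(abs(s / mean(s) - 1)), 1e-5)
})

test_that("ICE recovers a planted bias vector", {
  # build a doubly-balanced B by balancing a random symmetric matrix first
  set.seed(42)
  A <- matrix(stats::runif(16, 1, 2), 4, 4)
  A <- (A + t(A)) / 2
  B <- ice_balance(contact_matrix("c", A, 2e5, mask = rep(FALSE, 4)),
                   tol = 1e-12, max_iter = 1000)$matrix
  b <- c(1, 2, 3, 4)
  M <- diag(b) %*% B %*% diag(b)
  M <- (M + t(M)) / 2
  bm <- ice_balance(contact_matrix("c", M, 2e5, mask = rep(FALSE, 4)),
                    tol = 1e-10, max_iter = 1000)
  expect_gte(stats::cor(bm$bias, b), 0.999)
  # strong proportionality too
  expect_lt(stats::sd(bm$bias / b) / mean(bm$bias / b), 1e-4)
})

test_that("ICE errors and warning paths work", {
  cm <- contact_matrix("c", matrix(1, 3, 3), 2e5, mask = rep(TRUE, 3))
  expect_error(ice_balance(cm), "all bins are masked")
  set.seed(8)
  A <- matrix(stats::runif(100, 0.5, 2), 10, 10); A <- (A + t(A)) / 2
  cm2 <- contact_matrix("c", A, 2e5, mask = rep(FALSE, 10))
  expect_warning(ice_balance(cm2, tol = 1e-14, max_iter = 1L),
                 "did not converge")
})

test_that("O/E is 1 for exact distance functions and scale-invariant", {
  n <- 30
  d <- abs(outer(1:n, 1:n, "-"))
  M <- 100 * pmax(d, 0.5)^(-1)
  bm <- list(matrix = M, mask = rep(FALSE, n))
  OE <- distance_correct(bm)
  expect_lt(max(abs(OE - 1), na.rm = TRUE), 1e-12)

  bm2 <- list(matrix = M * 2, mask = rep(FALSE, n))
  OE2 <- distance_correct(bm2)
  expect_equal(OE2, OE, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("distance correction excludes masked bins", {
  n <- 6
  M <- matrix(1, n, n)
  mask <- c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE)
  cm <- contact_matrix("c", M, 2e5, mask = mask)
  OE <- distance_correct(ice_balance(cm))
  expect_true(all(is.na(OE[3, ])))
  expect_true(all(is.na(OE[, 3])))
})

test_that("compartment_score matches an independent eigen oracle", {
  spec <- synthetic_spec(seed = 12, chrom_names = "chrZ",
                         chrom_lengths = 20e6)
  ct <- simulate_contacts(spec)
  bm <- ice_balance(ct$matrices[[1]])
  OE <- distance_correct(bm)
  tr <- suppressWarnings(compartment_score(OE, "chrZ"))
  keep <- which(!is.na(tr$score))
  sub <- OE[keep, keep]
  C <- suppressWarnings(stats::cor(sub, use = "pairwise.complete.obs"))
  C[!is.finite(C)] <- 0
  C <- (C + t(C)) / 2
  v_oracle <- svd(C)$u[, 1]
  v <- tr$score[keep]
  if (sum(v * v_oracle) < 0) v_oracle <- -v_oracle
  expect_lt(max(abs(v - v_oracle)), 1e-6)
})

test_that("orientation makes the score correlate non-negatively", {
  spec <- synthetic_spec(seed = 13, chrom_names = "chrZ",
                         chrom_lengths = 20e6)
  ct <- simulate_contacts(spec)
  truth <- ct$truth
  ref <- data.frame(chrom = truth$chrom, bin = truth$bin,
                    value = ifelse(truth$label == "A", 1, -1))
  tr <- compartment_track(ct$matrices[[1]], reference = ref)
  ok <- !is.na(tr$score)
  expect_gte(stats::cor(tr$score[ok], ref$value[ok]), 0)
  expect_true(attr(tr, "oriented"))
  # flipped reference flips the score
  ref2 <- ref; ref2$value <- -ref$value
  tr2 <- compartment_track(ct$matrices[[1]], reference = ref2)
  expect_equal(tr2$score, -tr$score, tolerance = 1e-12)
})

test_that("missing reference warns and too few bins error", {
  spec <- synthetic_spec(seed = 14, chrom_names = "chrZ",
                         chrom_lengths = 20e6)
  ct <- simulate_contacts(spec)
  expect_warning(compartment_track(ct$matrices[[1]]), "unoriented")
  small <- matrix(1, 4, 4)
  OE <- distance_correct(
    ice_balance(contact_matrix("c", small, 2e5, mask = rep(FALSE, 4))))
  expect_error(compartment_score(OE, "c"), "unmasked bins")
})

test_that("checkerboard O/E is above 1 within blocks, below across", {
  spec <- synthetic_spec(seed = 15, chrom_names = "chrZ",
                         chrom_lengths = 20e6)
  ct <- simulate_contacts(spec)
  OE <- distance_correct(ice_balance(ct$matrices[[1]]))
  lab <- ct$truth$label
  same <- outer(lab, lab, "==")
  off <- abs(row(OE) - col(OE)) > 0
  expect_gt(mean(OE[same & off], na.rm = TRUE), 1)
  expect_lt(mean(OE[!same & off], na.rm = TRUE), 1)
})
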
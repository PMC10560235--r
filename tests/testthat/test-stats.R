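test_that("cluster permutation detects a sustained effect and honors the duration rule", {
  fs <- 200
  Tn <- 200
  withr::with_seed(31, {
    A <- matrix(rnorm(96 * Tn), 96)
    B <- matrix(rnorm(96 * Tn), 96)
  })
  ## 1-SD offset over 100 ms
  eff <- 81:100
  B2 <- B
  B2[, eff] <- B2[, eff] + 1
  res <- cluster_permutation_test(A, B2, fs = fs, n_perm = 300, seed = 1)
  sig <- res$clusters[res$clusters$significant, ]
  expect_gte(nrow(sig), 1L)
  ## the detected cluster overlaps the planted window
  expect_true(any(sig$start_s < eff[20] / fs & sig$end_s > eff[1] / fs))

  ## same generator -> no significant clusters on this seed
  res0 <- cluster_permutation_test(A, B, fs = fs, n_perm = 300, seed = 1)
  expect_equal(sum(res0$clusters$significant), 0L)

  ## a 20 ms effect (4 samples at 200 Hz) is excluded by the 25 ms rule
  B3 <- B
  B3[, 101:104] <- B3[, 101:104] + 3
  res3 <- cluster_permutation_test(A, B3, fs = fs, n_perm = 300, seed = 1)
  short <- res3$clusters$duration_s < 0.025 & res3$clusters$p < 0.05
  expect_true(all(!res3$clusters$significant[short]))
  expect_error(cluster_permutation_test(A[1, , drop = FALSE], B, fs = fs),
               "2 trials")
})

test_that("Wilcoxon signed-rank matches exact enumeration for n <= 10", {
  withr::with_seed(32, {
    for (rep in 1:25) {
      n <- sample(3:10, 1)
      x <- rnorm(n)
      y <- rnorm(n)
      got <- wilcoxon_signed_rank(x, y)
      expect_equal(got$p, wilcoxon_enum_p(x, y), tolerance = 1e-12,
                   info = sprintf("rep %d n %d", rep, n))
    }
  })
})

test_that("Wilcoxon handles shifts, single pairs and degenerate input", {
  withr::with_seed(33, {
    y <- rnorm(20)
  })
  ## distinct positive shifts keep the differences tie-free
  res <- wilcoxon_signed_rank(y + seq(0.5, 2, length.out = 20), y)
  expect_lt(res$p, 0.001)
  expect_equal(res$method, "exact")
  ## one nonzero pair: exact p = 1
  x <- c(1, 2, 3); y2 <- c(1, 2, 2.5)
  expect_equal(wilcoxon_signed_rank(x, y2)$p, 1)
  expect_error(wilcoxon_signed_rank(x, x), "degenerate")
  ## large n switches to the normal approximation
  withr::with_seed(34, {
    a <- rnorm(60); b <- rnorm(60)
  })
  expect_equal(wilcoxon_signed_rank(a, b)$method, "normal approximation")
})

test_that("Wilcoxon p-values are near-uniform under the null", {
  withr::with_seed(35, {
    ps <- replicate(300, {
      x <- rnorm(15); y <- rnorm(15)
      wilcoxon_signed_rank(x, y)$p
    })
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("BH FDR matches the brute-force step-up rule", {
  res <- bh_fdr(c(0.001, 0.01, 0.02, 0.03), q = 0.05)
  expect_true(all(res$reject))
  expect_true(all(!bh_fdr(rep(1, 6), 0.05)$reject))
  withr::with_seed(36, {
    for (rep in 1:50) {
      m <- sample(1:12, 1)
      p <- runif(m)^sample(1:3, 1)
      got <- bh_fdr(p, 0.05)$reject
      expect_identical(got, bh_enum_reject(p, 0.05),
                       info = sprintf("rep %d", rep))
    }
  })
  ## monotone: lowering any p never removes a rejection
  withr::with_seed(37, {
    p <- runif(8)
  })
  base <- bh_fdr(p, 0.05)$reject
  p2 <- p; p2[3] <- p2[3] / 10
  expect_true(all(bh_fdr(p2, 0.05)$reject[base]))
  expect_equal(length(bh_fdr(numeric(), 0.05)$reject), 0L)
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})
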
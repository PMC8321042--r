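# Stage 4: slide-level features from the tile probability vector.

# naive loop-based reference implementations, kept deliberately independent
# of the vectorised package code
ref_G <- function(p) if (p >= 0.5) 1L else 0L
ref_P1 <- function(p) {
  s <- 0; for (v in p) s <- s + v
  m <- s / length(p)
  list(P1_star = m, P1 = if (m >= 0.5) 1L else 0L)
}
ref_P2 <- function(p) {
  s <- 0; for (v in p) if (ref_G(v) == 1L) s <- s + v
  if (s / length(p) >= 0.66) 1L else 0L
}
ref_P3 <- function(p) {
  k <- 0; for (v in p) k <- k + ref_G(v)
  if (k / length(p) >= 0.35) 1L else 0L
}
ref_Fh <- function(p, h) {
  k <- 0
  for (v in p) {
    inside <- v >= h && (v < h + 0.1 || (h == 0.9 && v <= 1))
    if (inside) k <- k + 1
  }
  k / length(p)
}

test_that("indicator G uses the >= 0.5 boundary", {
  expect_identical(indicator_G(0.5), 1L)
  expect_identical(indicator_G(0.4999), 0L)
  expect_identical(indicator_G(1.0), 1L)
  expect_identical(indicator_G(c(0, 0.5, 0.75)), c(0L, 1L, 1L))
  expect_error(indicator_G(1.2), "\\[0, 1\\]")
  expect_error(indicator_G(-0.1), "\\[0, 1\\]")
})

test_that("P1 is the arithmetic mean, binarised at 0.5", {
  r <- positivity_P1(c(0.9, 0.7, 0.2))
  expect_equal(r$P1_star, 0.6)
  expect_identical(r$P1, 1L)
  r <- positivity_P1(0.5)
  expect_equal(r$P1_star, 0.5); expect_identical(r$P1, 1L)
  r <- positivity_P1(c(0, 0, 0))
  expect_equal(r$P1_star, 0); expect_identical(r$P1, 0L)
})

test_that("P2 divides the masked sum by T and thresholds at 0.66", {
  expect_identical(positivity_P2(c(1, 1, 0)), 1L)             # 2/3 >= 0.66
  expect_identical(positivity_P2(c(0.9, 0.9, 0.1, 0.1)), 0L)  # 0.45
  expect_identical(positivity_P2(rep(0.49, 10)), 0L)          # mask annihilates
  # prose variant divides by the super-threshold count instead
  expect_identical(positivity_P2(c(0.9, 0.9, 0.1, 0.1), prose_variant = TRUE), 1L)
})

test_that("P3 thresholds the positive-tile fraction at 0.35 inclusively", {
  expect_identical(positivity_P3(c(0.6, 0.6, 0.4)), 1L)
  expect_identical(positivity_P3(c(0.6, 0.1, 0.1, 0.1)), 0L)
  p <- c(rep(0.7, 7), rep(0.2, 13))   # exactly 35% of 20 tiles
  expect_identical(positivity_P3(p), 1L)
})

test_that("Fh bins are half-open with a closed top bin", {
  expect_equal(frequency_Fh(c(0.55, 0.95, 0.30), 0.5), 1 / 3)
  expect_equal(frequency_Fh(0.60, 0.5), 0)     # 0.60 belongs to the next bin
  expect_equal(frequency_Fh(1.0, 0.9), 1)      # closed top bin keeps p = 1
  expect_equal(frequency_Fh(1.0, 0.9, closed_top = FALSE), 0)
  expect_error(frequency_Fh(0.5, 0.45), "h must be one of")
})

test_that("compute_features handles the saturated edge cases", {
  f <- compute_features(rep(1, 3), slide_id = "sat")
  expect_identical(c(f$P1, f$P2, f$P3), c(1L, 1L, 1L))
  expect_equal(unname(f$F["F0.9"]), 1)
  expect_equal(sum(f$F), 1)
  f <- compute_features(rep(0, 3), slide_id = "null")
  expect_identical(c(f$P1, f$P2, f$P3), c(0L, 0L, 0L))
  expect_equal(sum(f$F), 0)
  expect_error(compute_features(numeric(0), slide_id = "empty"), "empty")
})

test_that("all features match the naive loop reference on 1000 random vectors", {
  withr::with_seed(2024, {
    for (i in 1:1000) {
      T_ <- sample(1:50, 1)
      # mix smooth draws with exact boundary values so thresholds get hit
      p <- sample(c(runif(T_), 0.5, 0.66, 0.9, 1, 0))[seq_len(T_)]
      f <- compute_features(p, slide_id = "r")
      r1 <- ref_P1(p)
      # reference accumulates in plain doubles, mean() in long doubles
      expect_equal(f$P1_star, r1$P1_star, tolerance = 1e-12)
      expect_identical(f$P1, r1$P1)
      expect_identical(f$P2, ref_P2(p))
      expect_identical(f$P3, ref_P3(p))
      for (h in c(0.5, 0.6, 0.7, 0.8, 0.9)) {
        expect_identical(unname(f$F[sprintf("F%.1f", h)]), ref_Fh(p, h))
      }
    }
  })
})

test_that("features are permutation- and duplication-invariant", {
  withr::with_seed(31, {
    for (i in 1:25) {
      p <- runif(sample(2:40, 1))
      f1 <- compute_features(p, slide_id = "s")
      f2 <- compute_features(sample(p), slide_id = "s")
      f3 <- compute_features(c(p, p), slide_id = "s")
      for (f in list(f2, f3)) {
        expect_equal(f$P1_star, f1$P1_star)
        expect_identical(c(f$P1, f$P2, f$P3), c(f1$P1, f1$P2, f1$P3))
        expect_equal(f$F, f1$F)
      }
    }
  })
})

test_that("raising a single probability never decreases P1* or flips an index off", {
  withr::with_seed(57, {
    for (i in 1:40) {
      p <- runif(sample(1:30, 1))
      j <- sample(seq_along(p), 1)
      q <- p; q[j] <- min(1, p[j] + runif(1))
      f_lo <- compute_features(p, slide_id = "s")
      f_hi <- compute_features(q, slide_id = "s")
      expect_gte(f_hi$P1_star, f_lo$P1_star)
      expect_gte(f_hi$P1, f_lo$P1)
      expect_gte(f_hi$P2, f_lo$P2)
      expect_gte(f_hi$P3, f_lo$P3)
    }
  })
})

test_that("the Fh frequencies sum to the positive-tile fraction", {
  withr::with_seed(73, {
    for (i in 1:25) {
      p <- sample(c(runif(30), 0.5, 1, 0.9))[1:20]
      f <- compute_features(p, slide_id = "s")
      expect_equal(sum(f$F), mean(indicator_G(p)))
    }
  })
})
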
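test_that("centering subtracts expected counts under the background", {
  # uniform counts under a uniform background center to zero
  tcu <- count_tuples(c("ACGT", "TGCA"), max_k = 2, strand = "forward")
  m0 <- fomc(tcu, 0)
  cc <- center_counts(tcu, m0, 1)
  expect_equal(cc$centered, rep(0, 4), tolerance = 1e-12)
  expect_equal(sum(cc$probs), 1, tolerance = 1e-9)
  # worked example: counts (8,0,0,8), uniform background, N=16
  cc2 <- center_counts(c(8, 0, 0, 8), m0, 1)
  expect_equal(cc2$centered, c(4, -4, -4, 4))
  # centered values sum to ~0 for a fitted model on real counts
  reads <- random_reads(30, 40, seed = 51)
  tc <- count_tuples(reads, max_k = 4)
  m1 <- fomc(tc, 1)
  cc3 <- center_counts(tc, m1, 3)
  expect_lt(abs(sum(cc3$centered)), 1e-6 * cc3$N)
  # sample mismatch warns but proceeds
  other <- count_tuples(random_reads(5, 40, seed = 52), max_k = 4,
                        sample_id = "other")
  expect_warning(center_counts(other, m1, 2), "fitted from sample")
})

test_that("d2s reproduces hand-worked extreme cases", {
  mk <- function(cen) structure(
    list(k = 1, counts = abs(cen), probs = rep(0.25, 4), N = 16,
         centered = cen), class = "centered_counts")
  X <- mk(c(4, -4, 0, 0))
  expect_equal(d2s(X, X), 0, tolerance = 1e-12)
  # anti-correlated centered vectors hit the upper bound
  expect_equal(d2s(X, mk(c(-4, 4, 0, 0))), 1, tolerance = 1e-12)
  # disjoint supports are orthogonal: exactly 1/2
  expect_equal(d2s(mk(c(4, -4, 0, 0)), mk(c(0, 0, 4, -4))), 0.5,
               tolerance = 1e-12)
  expect_warning(v <- d2s(mk(rep(0, 4)), mk(rep(0, 4))), "zero")
  expect_equal(v, 0)
})

test_that("d2star reproduces Cauchy-Schwarz equality cases", {
  mk <- function(cen) structure(
    list(k = 1, counts = abs(cen), probs = rep(0.25, 4), N = 16,
         centered = cen), class = "centered_counts")
  X <- mk(c(4, -4, -4, 4))
  expect_equal(d2star(X, X), 0, tolerance = 1e-12)
  expect_equal(d2star(X, mk(-c(4, -4, -4, 4))), 1, tolerance = 1e-12)
  expect_equal(d2star(mk(c(4, -4, 0, 0)), mk(c(0, 0, 4, -4))), 0.5,
               tolerance = 1e-12)
  # a zero expected count with non-zero centered count is an error
  Y <- mk(c(4, -4, 0, 0)); Y$probs <- c(0, 0.5, 0.25, 0.25)
  expect_error(d2star(Y, X), "zero expected")
})

test_that("d2star under uniform backgrounds is a scaled centered cosine", {
  set.seed(61)
  for (i in 1:20) {
    cx <- rnorm(16); cy <- rnorm(16)
    mk <- function(cen, N) structure(
      list(k = 2, counts = NULL, probs = rep(1 / 16, 16), N = N,
           centered = cen), class = "centered_counts")
    v <- d2star(mk(cx, 32), mk(cy, 64))
    # with constant N*P the denominators cancel into a plain cosine
    expect_equal(v, 0.5 * (1 - sum(cx * cy) /
                             sqrt(sum(cx^2) * sum(cy^2))),
                 tolerance = 1e-12)
  }
})

test_that("d2 and Lp measures match hand arithmetic", {
  expect_equal(d2(c(1, 1), c(1, 0)), 0.5 * (1 - 1 / sqrt(2)),
               tolerance = 1e-12)
  expect_equal(d2(c(3, 1), c(3, 1)), 0, tolerance = 1e-12)
  expect_equal(d2(c(1, 0), c(0, 1)), 0.5)
  expect_error(d2(c(0, 0), c(1, 1)), "zero")
  expect_equal(lp_dissimilarity(c(1, 0), c(0, 1), "ma"), 2)
  expect_equal(lp_dissimilarity(c(1, 0), c(0, 1), "eu"), sqrt(2))
  expect_equal(lp_dissimilarity(c(1, 0), c(0, 1), "ch"), 1)
  # frequency normalisation: scale invariance in the totals
  expect_equal(lp_dissimilarity(c(5, 5), c(7.5, 2.5), "ma"), 0.5)
  expect_equal(lp_dissimilarity(c(2, 2), c(3, 1), "eu"),
               sqrt(2 * 0.25^2), tolerance = 1e-12)
  expect_equal(lp_dissimilarity(c(2, 2), c(3, 1), "ch"), 0.25)
  expect_error(lp_dissimilarity(c(0, 0), c(1, 1), "ma"), "zero")
})

test_that("mixing toward the other sample monotonically decreases d2", {
  x <- c(10, 1); y <- c(1, 10)
  a <- seq(0, 1, by = 0.1)
  vals <- vapply(a, function(w) d2((1 - w) * x + w * y, y), numeric(1))
  expect_true(all(diff(vals) < 1e-12))
})

test_that("dissimilarity contracts hold under randomised inputs", {
  set.seed(71)
  reads <- lapply(1:4, function(i) random_reads(20, 40, seed = 70 + i,
    p = c(0.2, 0.3, 0.3, 0.2)))
  tcs <- lapply(reads, count_tuples, max_k = 4)
  models <- c(lapply(tcs[1:2], fomc, order = 1),
              lapply(3:4, function(i)
                vlmc(reads[[i]], max_depth = 3, K = 2,
                     counts = tcs[[i]])))
  for (trial in 1:100) {
    mi <- sample(4, 2, replace = TRUE)
    cx <- center_counts(rpois(16, 40), models[[mi[1]]], 2)
    cy <- center_counts(rpois(16, 40), models[[mi[2]]], 2)
    for (f in list(d2s, d2star)) {
      v <- f(cx, cy)
      expect_gte(v, -1e-12); expect_lte(v, 1 + 1e-12)
      expect_equal(f(cy, cx), v, tolerance = 1e-12)
      expect_equal(f(cx, cx), 0, tolerance = 1e-12)
    }
    v <- d2(cx$counts, cy$counts)
    expect_gte(v, -1e-12); expect_lte(v, 1 + 1e-12)
    expect_equal(d2(cy$counts, cx$counts), v, tolerance = 1e-12)
  }
})

test_that("pairwise matrices are symmetric, zero-diagonal and consistent", {
  reads <- lapply(1:3, function(i) random_reads(15, 40, seed = 80 + i))
  names(reads) <- paste0("s", 1:3)
  tcs <- lapply(names(reads), function(s)
    count_tuples(reads[[s]], max_k = 4, sample_id = s))
  names(tcs) <- names(reads)
  models <- lapply(names(reads), function(s)
    vlmc(reads[[s]], max_depth = 3, K = 1, counts = tcs[[s]],
         sample_id = s))
  names(models) <- names(reads)
  m <- dissimilarity_matrix(tcs, "d2s", 3, models)
  expect_equal(unclass(m), t(unclass(m)))
  expect_equal(unname(diag(m)), rep(0, 3))
  # off-diagonal entries equal independent single-pair calls
  c1 <- center_counts(tcs$s1, models$s1, 3)
  c2 <- center_counts(tcs$s2, models$s2, 3)
  expect_equal(m["s1", "s2"], d2s(c1, c2), tolerance = 1e-12)
  # identical samples give an all-zero matrix
  m2 <- dissimilarity_matrix(list(a = tcs$s1, b = tcs$s1), "d2", 3)
  expect_true(all(abs(m2) < 1e-12))
  expect_error(dissimilarity_matrix(tcs, "d2s", 3,
                                    c(models[1:2], list(s3 = fomc(tcs$s3, 1)))),
               "mixed model classes")
  # TSV round trip
  f <- tempfile(fileext = ".tsv")
  write_diss_matrix(m, f)
  back <- read_diss_matrix(f)
  expect_equal(unclass(back)[, ], unclass(m)[, ], tolerance = 1e-12)
  expect_equal(attr(back, "measure"), "d2s")
  # PHYLIP export is parseable
  fp <- tempfile()
  write_phylip(m, fp)
  expect_equal(as.integer(readLines(fp)[1]), 3)
})
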
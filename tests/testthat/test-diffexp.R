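# Conditional NB exact test, BH adjustment, MA/heatmap/ECDF/correlation
# transforms, significance calling.

test_that("the observed mode gives p = 1 and enumeration matches brute force", {
  expect_equal(exact_nb_test(5, 5, 1e6, 1e6, phi = 0), 1)
  expect_equal(exact_nb_test(5, 5, 1e6, 1e6, phi = 0.1), 1)
  expect_equal(exact_nb_test(0, 0, 1e6, 1e6), 1)
  # phi = 0 equals the binomial conditional exact test at s = 20
  pr <- dbinom(0:20, 20, 0.5)
  expect_equal(exact_nb_test(0, 20, 1e6, 1e6, phi = 0),
               sum(pr[pr <= pr[1] * (1 + 1e-12)]), tolerance = 1e-12)
  # spot equivalence with the enumeration oracle (full sweep in acceptance)
  set.seed(12)
  for (i in 1:40) {
    s <- sample(0:30, 1)
    a <- if (s == 0) 0 else sample(0:s, 1)
    phi <- sample(c(0, 0.1, 0.5), 1)
    expect_equal(exact_nb_test(a, s - a, 1e6, 1e6, phi),
                 naive_exact_p(a, s - a, phi), tolerance = 1e-10)
  }
  expect_error(exact_nb_test(-1, 5, 1e6, 1e6), "nonnegative")
})

test_that("library sizes are equalized by geometric-mean scaling", {
  # counts proportional to their library sizes scale to an even split
  expect_equal(exact_nb_test(10, 20, 1e6, 2e6, phi = 0.1), 1)
  # the same observed counts at unequal libraries are no longer even
  expect_lt(exact_nb_test(20, 20, 1e5, 1.6e6, phi = 0), 0.05)
})

test_that("the NB exact test matches the edgeR small-p exact test", {
  cases <- list(c(10, 30), c(3, 17), c(0, 8), c(25, 25), c(40, 12),
                c(100, 180), c(7, 0))
  for (cs in cases) {
    mine <- exact_nb_test(cs[1], cs[2], 1e6, 1e6, phi = 0.1)
    ref <- edgeR::exactTestBySmallP(matrix(cs[1], 1), matrix(cs[2], 1),
                                    dispersion = 0.1)
    expect_equal(mine, as.numeric(ref), tolerance = 1e-9,
                 label = paste(cs, collapse = ","))
  }
  # binomial limit against edgeR's Poisson binomial test
  expect_equal(exact_nb_test(4, 16, 1e6, 1e6, phi = 0),
               edgeR::binomTest(4, 16, 1e6, 1e6, p = 0.5),
               tolerance = 1e-9)
})

test_that("BH adjustment matches the hand-coded step-up on random vectors", {
  expect_equal(bh_fdr(0.5), 0.5)
  expect_equal(bh_fdr(rep(0.5, 7)), rep(0.5, 7))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_fdr(c(0.5, 0)), "0, 1")
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
  set.seed(8)
  for (i in 1:60) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    p[p == 0] <- 1e-12
    expect_equal(bh_fdr(p), naive_bh(p), tolerance = 1e-12)
  }
})

test_that("MA values follow the smoothed log-ratio definition", {
  ma <- ma_values(3.9, 1.9)
  expect_equal(ma$M, 1)
  expect_equal(ma_values(7, 7)$M, 0)
  z <- ma_values(0, 0)
  expect_equal(z$M, 0)
  expect_equal(z$A, log2(0.1))
  v <- ma_values(c(1, 2), c(2, 1))
  expect_equal(v$M, c(log2(1.1 / 2.1), log2(2.1 / 1.1)))
})

test_that("heatmap matrix drops all-low rows then log-transforms", {
  rpm <- matrix(c(0.9, 0.5, 0.2,
                  1.9, 0.0, 5.0,
                  0.0, 0.0, 0.0), nrow = 3, byrow = TRUE,
                dimnames = list(c("lo", "hi", "zero"), c("g1", "g2", "g3")))
  hm <- heatmap_matrix(rpm)
  expect_equal(rownames(hm), "hi")
  expect_equal(hm["hi", "g1"], 1)             # log2(1.9 + 0.1)
  expect_equal(hm["hi", "g2"], log2(0.1))
  expect_equal(unname(hm["hi", "g3"]), log2(5.1))
})

test_that("cumulative frequency tracks the sort-based ECDF", {
  cf <- cumulative_frequency(c(0.5, 2.0))
  expect_equal(cf$frac_below_1rpm, 0.5)
  same <- cumulative_frequency(rep(3.7, 5))
  expect_equal(unique(same$table$cum_frequency), 1)
  expect_error(cumulative_frequency(numeric(0)), "empty")
  set.seed(30)
  rpms <- exp(rnorm(200, 1, 2))
  cf <- cumulative_frequency(rpms)
  v <- sort(log2(rpms + 0.1))
  expect_equal(cf$table$log2_rpm, v)
  expect_equal(cf$table$cum_frequency, rank(v, ties.method = "max") / 200)
  expect_equal(cf$frac_below_1rpm, mean(rpms < 1))
})

test_that("Pearson correlation matches the product-moment formula", {
  x <- c(4, 8, 15, 16, 23)
  expect_equal(pearson_correlation(x, x), 1)
  expect_equal(pearson_correlation(x, -x), -1)
  # hand computation: Sxy = 3, Sxx = 2, Syy = 42/9 -> r = 9/sqrt(84)
  expect_equal(pearson_correlation(c(1, 2, 3), c(1, 2, 4)), 9 / sqrt(84))
  expect_error(pearson_correlation(c(1, 1, 1), x[1:3]), "variance")
  expect_error(pearson_correlation(1:3, 1:4), "mismatch")
})

test_that("significance needs all three thresholds", {
  res <- data.frame(
    p = c(0.01, 0.01, 0.06, 0.01, 0.04),
    fdr = c(0.01, 0.01, 0.01, 0.06, 0.04),
    M = c(1.5, 0.9, 2.0, 2.0, -1.2))
  out <- call_significant(res)
  expect_equal(out$significant, c(TRUE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(out$direction, c("up", "ns", "ns", "ns", "down"))
  expect_equal(attr(out, "de_summary"), c(up = 1L, down = 1L))
  # boundary: |M| = 1 is significant (>=), p = 0.05 is not (<)
  bound <- call_significant(data.frame(p = c(0.049, 0.05),
                                       fdr = c(0.01, 0.01),
                                       M = c(1, 1)))
  expect_equal(bound$significant, c(TRUE, FALSE))
})

test_that("run_diffexp assembles a coherent table", {
  set.seed(9)
  counts_a <- setNames(rpois(50, 100), sprintf("m%02d", 1:50))
  counts_b <- counts_a
  counts_b["m01"] <- counts_a[["m01"]] * 8L   # strong planted change
  de <- run_diffexp(counts_a, counts_b, 1e6, 1e6,
                    de_config(phi = 0))
  expect_equal(nrow(de), 50L)
  expect_true(all(de$p > 0 & de$p <= 1))
  expect_equal(de$fdr, bh_fdr(de$p))
  m01 <- de[de$feature_id == "m01", ]
  expect_true(m01$significant)
  expect_equal(m01$direction, "down")  # A is the numerator of M
  expect_lt(abs(m01$M + 3), 0.3)
  # features absent from one group appear with zero counts
  de2 <- run_diffexp(c(x = 30L), c(y = 40L), 1e6, 1e6)
  expect_equal(sort(de2$feature_id), c("x", "y"))
  expect_equal(de2$countB[de2$feature_id == "x"], 0L)
})
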
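test_that("k-mer composition counts and normalizes in alphabetical order", {
  expect_equal(unname(kmer_composition("AAAA", 1)), c(1, 0, 0, 0))
  v <- kmer_composition("ACGU", 2)
  expect_equal(unname(v[c("AC", "CG", "GU")]), rep(1 / 3, 3))
  expect_equal(sum(v), 1)
  expect_equal(names(kmer_composition("ACGU", 2))[1:5],
               c("AA", "AC", "AG", "AU", "CA"))
  set.seed(8)
  for (i in 1:25) {
    w <- random_window(sample(4:40, 1))
    k <- sample(1:3, 1)
    v <- kmer_composition(w, k)
    expect_length(v, 4^k)
    expect_true(all(v >= 0))
    expect_equal(sum(v), 1)
  }
  expect_error(kmer_composition("ACG", 0), "between 1")
  expect_error(kmer_composition("ACG", 4), "between 1")
})

test_that("auto-covariance matches the hand-computed example", {
  tab <- toy_property_table(c(AC = 1, CG = 3, GA = 2))
  # profile 1, 3, 2; mean 2; lag 1: ((1-2)(3-2) + (3-2)(2-2)) / 2 = -0.5
  expect_equal(auto_covariance("ACGA", 1, 1, tab), -0.5)
  # all dinucleotides sharing one value: zero for every lag
  tabu <- toy_property_table(c(AA = 5), n_props = 2)
  expect_equal(auto_covariance("AAAAAA", 1, 1, tabu), 0)
  expect_equal(auto_covariance("AAAAAA", 1, 3, tabu), 0)
})

test_that("cross-covariance is asymmetric and rejects equal indices", {
  tab <- toy_property_table(c(AC = 1, CG = 3, GA = 2),
                            c(AC = 0, CG = 1, GA = 2))
  expect_equal(cross_covariance("ACGA", 1, 2, 1, tab), 0.5)
  expect_equal(cross_covariance("ACGA", 2, 1, 1, tab), -0.5)
  expect_error(cross_covariance("ACGA", 3, 3, 1, tab), "must differ")
})

test_that("lag bounds and standardization are enforced", {
  tab <- toy_property_table(c(AC = 1, CG = 3, GA = 2))
  expect_error(auto_covariance("ACGA", 1, 3, tab), "1 <= g <= L - 2")
  expect_error(auto_covariance("ACGA", 1, 0, tab), "1 <= g <= L - 2")
  raw <- load_property_table()
  expect_error(auto_covariance("ACGA", 1, 1, raw), "standardized")
  expect_error(cross_covariance("ACGA", 1, 2, 1, raw), "standardized")
})

test_that("closed-form AC/CC equals the brute-force loop oracle", {
  tab <- random_property_table(n_props = 4, seed = 21)
  set.seed(22)
  for (i in 1:120) {
    w <- random_window(sample(6:41, 1))
    g <- sample(1:(nchar(w) - 2), 1)
    m <- sample(1:4, 2)
    expect_equal(auto_covariance(w, m[1], g, tab),
                 loop_cov(w, m[1], m[1], g, tab), tolerance = 1e-12)
    expect_equal(cross_covariance(w, m[1], m[2], g, tab),
                 loop_cov(w, m[1], m[2], g, tab), tolerance = 1e-12)
  }
})

test_that("AC depends only on its property; CC only on its pair", {
  tab1 <- random_property_table(4, seed = 31)
  v2 <- unclass(tab1)
  v2[3, ] <- rev(v2[3, ])  # relabel an unrelated property
  tab2 <- property_table(v2, standardized = TRUE)
  w <- random_window(30, seed = 32)
  expect_equal(auto_covariance(w, 1, 2, tab1), auto_covariance(w, 1, 2, tab2))
  expect_equal(cross_covariance(w, 1, 2, 2, tab1),
               cross_covariance(w, 1, 2, 2, tab2))
  expect_false(isTRUE(all.equal(auto_covariance(w, 3, 2, tab1),
                                auto_covariance(w, 3, 2, tab2))))
})

test_that("encode_window has the fixed lag-major layout and length 100*lambda", {
  tab <- random_property_table(10, seed = 41)
  w <- random_window(41, seed = 42)
  v <- encode_window(w, tab, lambda = 5)
  expect_length(v, 500)
  expect_length(encode_window(w, tab, lambda = 1), 100)
  # AC block: components 1..10*lambda, lag-major (g outer, property inner)
  expect_equal(unname(v[1]), auto_covariance(w, 1, 1, tab))
  expect_equal(unname(v[10]), auto_covariance(w, 10, 1, tab))
  expect_equal(unname(v[11]), auto_covariance(w, 1, 2, tab))
  expect_equal(unname(v[47]), auto_covariance(w, 7, 5, tab))
  # CC block: 10*lambda + pairs in lexicographic (mu1, mu2) order per lag
  expect_equal(unname(v[51]), cross_covariance(w, 1, 2, 1, tab))
  expect_equal(unname(v[59]), cross_covariance(w, 1, 10, 1, tab))
  expect_equal(unname(v[60]), cross_covariance(w, 2, 1, 1, tab))
  expect_equal(unname(v[51 + 90]), cross_covariance(w, 1, 2, 2, tab))
  expect_equal(unname(v[500]), cross_covariance(w, 10, 9, 5, tab))
  # deterministic: equal windows give equal vectors
  expect_identical(v, encode_window(w, tab, lambda = 5))
  # optional k-mer block appends 4^k normalized frequencies
  vk <- encode_window(w, tab, lambda = 5, include_kmer = TRUE, k = 2)
  expect_length(vk, 516)
  expect_equal(sum(vk[501:516]), 1)
  expect_true(all(is.finite(v)))
})

test_that("encode_window enforces the minimum window length", {
  tab <- random_property_table(10, seed = 51)
  expect_error(encode_window("ACGUA", tab, lambda = 5), "lambda \\+ 2")
  expect_silent(encode_window("ACGUACG", tab, lambda = 5))
})

test_that("encode_benchmark produces an aligned windows-by-features matrix", {
  tab <- random_property_table(10, seed = 61)
  bm <- simulate_benchmark(n_pos = 6, n_neg = 12, xi = 6, seed = 62)
  X <- encode_benchmark(bm, tab, lambda = 3)
  expect_equal(dim(X), c(18L, 300L))
  expect_equal(as.character(attr(X, "labels")),
               as.character(bm$label))
  expect_equal(attr(X, "layout_version"), "acc-lagmajor-1")
  # row order follows the benchmark; permuting windows permutes rows
  perm <- sample(nrow(bm))
  Xp <- encode_benchmark(bm[perm, ], tab, lambda = 3)
  expect_equal(Xp, X[perm, ], ignore_attr = TRUE)
  expect_equal(X[3, ], encode_window(bm$window[3], tab, lambda = 3))
  expect_error(encode_benchmark(bm[0, ], tab), "empty")
})
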
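test_that("signed-rank test handles degenerate and textbook cases", {
  x <- c(1, 2, 3, 4, 5, 6)
  w0 <- wilcoxon_signed_rank(x, x)
  expect_true(w0$degenerate)
  expect_equal(w0$p_value, 1)

  # six all-positive differences: one-tailed mass 1/64, two-sided p = 2/64
  w <- wilcoxon_signed_rank(x + c(1, 2, 3, 4, 5, 6), x)
  expect_equal(w$method, "exact")
  expect_equal(w$p_value, 2 / 64)
  expect_equal(w$statistic, 21)

  expect_error(wilcoxon_signed_rank(1:4, 1:3), "equal length")
})

test_that("exact branch agrees with full sign enumeration", {
  set.seed(30)
  for (i in 1:25) {
    n <- sample(5:12, 1)
    d <- rnorm(n)                      # continuous: no zeros, no ties
    w <- wilcoxon_signed_rank(d, numeric(n))
    expect_equal(w$method, "exact")
    expect_equal(w$p_value, enumerate_signed_rank_p(d), tolerance = 1e-12)
  }
})

test_that("large or tied samples fall back to the corrected normal approximation", {
  set.seed(31)
  d <- rnorm(40)
  w <- wilcoxon_signed_rank(d, numeric(40))
  expect_equal(w$method, "approx")
  expect_true(w$p_value > 0 && w$p_value <= 1)

  dt <- c(1, 1, -2, 3, 4, -1, 2, 5)   # tied magnitudes
  wt <- wilcoxon_signed_rank(dt, numeric(8))
  expect_equal(wt$method, "approx")
})

test_that("posture comparison pairs units and returns one row per cell", {
  tbl <- expand.grid(participant = sprintf("P%02d", 1:8),
                     muscle = c("BB", "BR"), posture = c("SP", "NT"),
                     norm = "max", order = 2, repetition = 1:3,
                     stringsAsFactors = FALSE)
  set.seed(32)
  tbl$distance <- runif(nrow(tbl))

  res <- compare_postures(tbl, "intra")
  expect_equal(nrow(res), 2)           # BB and BR
  expect_equal(res$n_pairs, c(8, 8))

  # identical postures give p = 1
  tbl2 <- tbl
  sp_rows <- tbl2$posture == "SP"
  key <- function(d) paste(d$participant, d$muscle, d$repetition)
  tbl2$distance[!sp_rows] <-
    tbl2$distance[sp_rows][match(key(tbl2[!sp_rows, ]), key(tbl2[sp_rows, ]))]
  res2 <- compare_postures(tbl2, "intra")
  expect_true(all(res2$p_value == 1))

  # pooled aggregation pairs participant x repetition
  res3 <- compare_postures(tbl, "intra", aggregation = "pooled")
  expect_equal(res3$n_pairs, c(24, 24))

  # inter level pairs by participant pair
  itbl <- expand.grid(pair = paste0("P", 1:10, "|P", 11:20),
                      muscle = "BB", posture = c("SP", "NT"),
                      norm = "max", order = 2, stringsAsFactors = FALSE)
  itbl$distance <- runif(nrow(itbl))
  res4 <- compare_postures(itbl, "inter")
  expect_equal(res4$n_pairs, 10)
})

test_that("maximum-likelihood fits match their closed forms", {
  expect_equal(fit_distribution(c(0, 2), "normal")$params,
               c(mean = 1, sd = 1))
  lf <- fit_distribution(c(1, 2, 3, 6), "laplace")
  expect_equal(unname(lf$params["mu"]), 2.5)
  expect_equal(unname(lf$params["b"]), mean(abs(c(1, 2, 3, 6) - 2.5)))

  cc <- 3.7
  mf <- fit_distribution(rep(cc, 25), "maxwell")
  expect_equal(unname(mf$params["a"]), cc / sqrt(3))
  expect_error(fit_distribution(c(-1, 2, 3), "maxwell"), "nonnegative")

  # Monte-Carlo consistency at a = 2
  set.seed(33)
  xs <- rmaxwell(5000, a = 2)
  ahat <- fit_distribution(xs, "maxwell")$params[["a"]]
  expect_gt(ahat, 1.9)
  expect_lt(ahat, 2.1)

  # scale equivariance of the Maxwell MLE
  expect_equal(fit_distribution(5 * xs, "maxwell")$params[["a"]],
               5 * ahat, tolerance = 1e-12)
})

test_that("distribution helpers are coherent densities and quantiles", {
  xs <- seq(0, 12, by = 0.01)
  expect_equal(sum(dmaxwell(xs, 2)) * 0.01, 1, tolerance = 1e-3)
  p <- c(0.1, 0.5, 0.9)
  expect_equal(pmaxwell(qmaxwell(p, 1.5), 1.5), p, tolerance = 1e-12)
  expect_equal(plaplace(qlaplace(p, 1, 2), 1, 2), p, tolerance = 1e-12)
  xs2 <- seq(-20, 20, by = 0.01)
  expect_equal(sum(dlaplace(xs2, 1, 2)) * 0.01, 1, tolerance = 1e-3)
})

test_that("chi-square GOF is exact for perfectly binned data and permutation-invariant", {
  # place one observation at each equal-probability bin midpoint
  ft <- structure(list(family = "maxwell", params = c(a = 1), n = 100),
                  class = "emg_fit")
  n_bins <- 10
  x <- qmaxwell(rep((seq_len(n_bins) - 0.5) / n_bins, each = 10), 1)
  out <- chi_square_gof(x, ft)
  expect_equal(out$chi2, 0)
  expect_equal(out$p_value, 1)
  expect_equal(out$n_bins, 10)
  expect_equal(out$df, 10 - 1 - 1)

  set.seed(34)
  xs <- rmaxwell(400, 2)
  f1 <- chi_square_gof(xs, fit_distribution(xs, "maxwell"))
  f2 <- chi_square_gof(sample(xs), fit_distribution(sample(xs), "maxwell"))
  expect_equal(f1$chi2, f2$chi2)

  expect_error(chi_square_gof(rmaxwell(8, 1),
                              fit_distribution(rmaxwell(8, 1), "normal")),
               "too small")
})

test_that("chi-square GOF holds its size under the true model and rejects the wrong one", {
  set.seed(35)
  p_true <- numeric(30)
  p_norm <- numeric(30)
  for (i in 1:30) {
    xs <- rmaxwell(2000, 1)
    p_true[i] <- chi_square_gof(xs, fit_distribution(xs, "maxwell"))$p_value
    p_norm[i] <- chi_square_gof(xs, fit_distribution(xs, "normal"))$p_value
  }
  expect_lte(mean(p_true < 0.05), 0.15)       # near-nominal size
  expect_gt(mean(p_norm < 0.05), 0.9)         # power against the skewed truth
})
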
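test_that("surface classification compares epi/endo labels", {
  h <- generate_heart(n_subdiv = 1, seed = 1)
  epi <- which(h$mesh$labels == "epi")
  endo <- which(h$mesh$labels == "endo")
  unl <- which(h$mesh$labels == "unlabeled")
  mk <- function(est, true) structure(list(estimated_node = est,
                                           true_node = true),
                                      class = "localization_result")
  expect_true(surface_classification(mk(epi[1], epi[5]), h))
  expect_false(surface_classification(mk(epi[1], endo[1]), h))
  expect_true(surface_classification(mk(endo[3], endo[3]), h))
  expect_error(surface_classification(mk(unl[1], epi[1]), h), "label")
  expect_error(surface_classification(mk(epi[1], NULL), h), "true node")
})

test_that("wilcoxon signed-rank: hand examples and conventions", {
  expect_warning(w0 <- wilcoxon_signed_rank(1:5, 1:5), "zero")
  expect_identical(w0$p_value, 1)

  # n = 5, all differences positive and distinct: two-sided p = 2/32
  w <- wilcoxon_signed_rank(c(2, 4, 6, 8, 10), c(1, 2, 3, 4, 5))
  expect_identical(w$method, "exact")
  expect_equal(w$statistic, 15)
  expect_equal(w$p_value, 0.0625)
})

test_that("wilcoxon exact branch equals full sign-flip enumeration", {
  # independent oracle: enumerate all 2^n sign assignments of the ranked
  # absolute differences and count rank sums as or more extreme
  enum_p <- function(d) {
    d <- d[d != 0]
    n <- length(d)
    r <- rank(abs(d))
    V <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Vs <- as.vector(signs %*% r)
    p_ge <- mean(Vs >= V - 1e-12)
    p_le <- mean(Vs <= V + 1e-12)
    min(1, 2 * min(p_ge, p_le))
  }
  set.seed(42)
  for (k in 1:12) {
    n <- sample(4:10, 1)
    a <- round(rnorm(n, 0, 5), 1)
    b <- round(rnorm(n, 1, 5), 1)   # ties in |d| occur with rounding
    d <- a - b
    if (all(d == 0)) next
    w <- wilcoxon_signed_rank(a, b)
    expect_equal(w$p_value, enum_p(d), tolerance = 1e-12)
  }
  # tie-free cases also agree with the standard reference implementation
  for (k in 1:5) {
    a <- rnorm(8); b <- rnorm(8)
    w <- wilcoxon_signed_rank(a, b)
    ref <- wilcox.test(a, b, paired = TRUE, exact = TRUE)
    expect_equal(w$p_value, unname(ref$p.value), tolerance = 1e-12)
  }
})

test_that("normal approximation converges to the exact branch at n = 25", {
  set.seed(7)
  for (k in 1:10) {
    a <- rnorm(25, 0.3)
    b <- rnorm(25)
    pe <- wilcoxon_signed_rank(a, b)$p_value
    pa <- wilcoxon_signed_rank(a, b, exact_max = 10)$p_value
    expect_lt(abs(pe - pa), 0.01)
  }
})

test_that("BCa bootstrap: determinism, degenerate collapse, percentile limit", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3.5)
  ci1 <- bca_bootstrap_ci(x, "median", seed = 99)
  ci2 <- bca_bootstrap_ci(x, "median", seed = 99)
  expect_identical(c(ci1$lower, ci1$upper), c(ci2$lower, ci2$upper))
  expect_lte(ci1$lower, ci1$estimate)
  expect_gte(ci1$upper, ci1$estimate)

  const <- bca_bootstrap_ci(c(5, 5, 5, 5), "mean", seed = 1)
  expect_identical(c(const$lower, const$upper), c(5, 5))

  # symmetric sample, mean statistic: z0 ~ 0 and a = 0 by symmetry of the
  # jackknife, so the interval reduces to the plain percentile interval
  xs <- c(-4, -2, -1, 0, 1, 2, 4)
  ci <- bca_bootstrap_ci(xs, "mean", n_boot = 4000, seed = 3, keep_boots = TRUE)
  expect_lt(abs(ci$accel), 1e-10)
  expect_lt(abs(ci$z0), 0.05)
  pct <- as.numeric(quantile(ci$thetastar, c(0.025, 0.975), type = 7))
  width <- diff(pct)
  expect_lt(abs(ci$lower - pct[1]), 0.05 * width)
  expect_lt(abs(ci$upper - pct[2]), 0.05 * width)

  expect_error(bca_bootstrap_ci(c(1, 2), "mean"), "at least 3")

  # cross-check against the reference BCa implementation
  set.seed(10)
  y <- rlnorm(25)
  ours <- bca_bootstrap_ci(y, "mean", n_boot = 4000, seed = 5)
  bref <- boot::boot.ci(boot::boot(y, function(d, i) mean(d[i]), R = 4000),
                        type = "bca")$bca[4:5]
  expect_lt(abs(ours$lower - bref[1]), 0.15 * (bref[2] - bref[1]))
  expect_lt(abs(ours$upper - bref[2]), 0.15 * (bref[2] - bref[1]))
})

test_that("quartile statistics use type-7 interpolation", {
  x <- c(1, 2, 3, 4, 10)
  ci <- bca_bootstrap_ci(x, "quartile", q = 0.75, seed = 1)
  expect_identical(ci$estimate, as.numeric(quantile(x, 0.75, type = 7)))
})

test_that("scenario battery is reproducible and respects its invariants", {
  b1 <- scenario_battery(n_scenarios = 10, seed = 7, n_boot = 200)
  b2 <- scenario_battery(n_scenarios = 10, seed = 7, n_boot = 200)
  expect_identical(b1$pairs, b2$pairs)
  expect_identical(b1$stats, b2$stats)
  expect_identical(b1$wilcoxon$p_value, b2$wilcoxon$p_value)

  for (m in rownames(b1$stats)) {
    s <- b1$stats[m, ]
    expect_true(s["min"] <= s["LQ"] && s["LQ"] <= s["M"] &&
                s["M"] <= s["UQ"] && s["UQ"] <= s["max"])
  }
  expect_true(all(b1$surface_match_pct >= 0 & b1$surface_match_pct <= 100))
  expect_true(all(b1$pairs$le_fra_cc >= 0))
  expect_true(all(b1$pairs$le_fra_dtw >= 0))
  expect_error(scenario_battery(n_scenarios = 5), ">= 10")

  f <- tempfile(fileext = ".csv")
  fj <- tempfile(fileext = ".json")
  write_error_summary(b1, f, fj)
  tab <- read.csv(f)
  expect_identical(nrow(tab), 8L)
  expect_identical(tab$statistic,
                   c("m", "SD", "M", "LQ", "UQ", "min", "max", "R"))
  expect_true(file.exists(fj))
  unlink(c(f, fj))
})

test_that("homogeneous conduction collapses the battery to the inverse crime", {
  b <- scenario_battery(n_scenarios = 10, seed = 3, n_boot = 100,
                        reduction_range = c(1, 1),
                        heart_args = list(n_subdiv = 2))
  expect_true(all(b$pairs$le_fra_cc == 0))
  expect_true(all(b$pairs$le_fra_dtw == 0))
  expect_identical(b$wilcoxon$p_value, 1)
})
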
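# independent bisection oracle for the power-law root
bisect_exponent <- function(r_cca, r_ica, r_eca, lo = 0.05, hi = 50,
                            tol = 1e-10) {
  g <- function(n) (r_ica / r_cca)^n + (r_eca / r_cca)^n - 1
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

test_that("the power-law solver reproduces known exponents", {
  expect_equal(solve_exponent(c(5, 4, 3))$n, 2, tolerance = 1e-9)
  expect_equal(solve_exponent(c(1, 2^(-1 / 3), 2^(-1 / 3)))$n, 3,
               tolerance = 1e-9)
  # carotid cohort mean ratios give an exponent near 1.55
  sol <- solve_exponent(c(1, 0.67, 0.61))
  expect_equal(sol$n, bisect_exponent(1, 0.67, 0.61), tolerance = 1e-8)
  expect_equal(sol$n, 1.555, tolerance = 0.001)
})

test_that("daughters at least as large as the parent have no root", {
  expect_identical(solve_exponent(c(1, 1.1, 0.5))$status, "no_root")
  expect_identical(solve_exponent(c(1, 1.0, 0.5))$status, "no_root")
  expect_true(is.na(solve_exponent(c(1, 1.1, 0.5))$n))
  expect_error(solve_exponent(c(1, -0.5, 0.5)), "positive")
  # near-degenerate daughters push the root beyond the bracket
  expect_identical(solve_exponent(c(1, 0.999, 0.999))$status,
                   "out_of_bracket")
})

test_that("solver agrees with a dense grid-scan oracle on random triples", {
  set.seed(77)
  ngrid <- 1e6
  nseq <- seq(0.05, 50, length.out = ngrid)
  for (i in 1:100) {
    a <- runif(1, 0.3, 0.95)
    b <- runif(1, 0.3, 0.95)
    g <- a^nseq + b^nseq - 1
    j <- which(g <= 0)[1]
    # linear interpolation across the sign change
    root_grid <- nseq[j - 1] + (nseq[j] - nseq[j - 1]) *
      g[j - 1] / (g[j - 1] - g[j])
    sol <- solve_exponent(c(1, a, b))
    expect_identical(sol$status, "ok")
    expect_lt(abs(sol$n - root_grid), 1e-6)
  }
})

test_that("the solved exponent is scale invariant", {
  set.seed(8)
  for (i in 1:25) {
    tri <- c(1, runif(1, 0.4, 0.9), runif(1, 0.4, 0.9))
    n0 <- solve_exponent(tri)$n
    for (scale in c(0.037, 2, 1800)) {
      expect_equal(solve_exponent(tri * scale)$n, n0, tolerance = 1e-9)
    }
  }
})

test_that("both estimators recover noiseless cohort exponents exactly", {
  for (nstar in c(1.2, 1.58, 2, 3)) {
    coh <- sample_cohort(30, exact_exponent = nstar, noise_sd = 0,
                         seed = 100 + round(100 * nstar))
    expect_equal(as.numeric(mean_individual_exponent(coh)), nstar,
                 tolerance = 1e-6)
    f1 <- fit_cohort_exponent(coh, model_form = "parent-response")
    f2 <- fit_cohort_exponent(coh, model_form = "daughter-sum")
    expect_true(f1$converged && f2$converged)
    expect_equal(unname(coef(f1)["n"]), nstar, tolerance = 1e-6)
    expect_equal(unname(coef(f2)["n"]), nstar, tolerance = 1e-6)
  }
})

test_that("Gauss-Newton matches nls on a noisy cohort", {
  coh <- sample_cohort(100, exact_exponent = 1.3, noise_sd = 0.05,
                       seed = 42)
  f <- fit_cohort_exponent(coh)
  nf <- stats::nls(r_cca_mm ~ (r_ica_mm^n + r_eca_mm^n)^(1 / n),
                   data = coh, start = list(n = 2))
  expect_equal(unname(coef(f)["n"]), unname(coef(nf)["n"]),
               tolerance = 1e-6)
})

test_that("the linearized 95% CI is calibrated on noisy cohorts", {
  hits <- 0
  reps <- 300
  for (i in seq_len(reps)) {
    coh <- sample_cohort(100, exact_exponent = 1.3, noise_sd = 0.05,
                         seed = i)
    f <- fit_cohort_exponent(coh)
    if (f$ci95[1] <= 1.3 && 1.3 <= f$ci95[2]) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.9)
})

test_that("regression and mean-of-roots disagree under noise but not without", {
  noisy <- sample_cohort(200, exact_exponent = 1.3, noise_sd = 0.05,
                         seed = 31)
  noisy <- add_exponents(noisy)
  fit_n <- unname(coef(fit_cohort_exponent(noisy))["n"])
  mean_n <- as.numeric(mean_individual_exponent(noisy))
  expect_gt(abs(fit_n - mean_n), 1e-4)

  clean <- sample_cohort(200, exact_exponent = 1.3, noise_sd = 0,
                         seed = 31)
  expect_equal(unname(coef(fit_cohort_exponent(clean))["n"]), 1.3,
               tolerance = 1e-6)
  expect_equal(as.numeric(mean_individual_exponent(clean)), 1.3,
               tolerance = 1e-6)
})

test_that("bootstrap CI is seeded, ordered and contains the estimate", {
  coh <- sample_cohort(40, exact_exponent = 1.4, noise_sd = 0.05,
                       seed = 5)
  f1 <- fit_cohort_exponent(coh, ci = "bootstrap", boot_n = 200, seed = 9)
  f2 <- fit_cohort_exponent(coh, ci = "bootstrap", boot_n = 200, seed = 9)
  expect_identical(f1$ci95, f2$ci95)
  expect_lte(f1$ci95[1], unname(coef(f1)["n"]))
  expect_gte(f1$ci95[2], unname(coef(f1)["n"]))
})

test_that("ICA adjustment matches its closed form", {
  # closed forms computed directly from the definition
  exp2 <- 100 * (sqrt(1 - 0.61^2) / 0.67 - 1)
  exp3 <- 100 * ((1 - 0.61^3)^(1 / 3) / 0.67 - 1)
  expect_equal(ica_adjustment(c(1, 0.67, 0.61), 2), exp2,
               tolerance = 1e-12)
  expect_equal(ica_adjustment(c(1, 0.67, 0.61), 3), exp3,
               tolerance = 1e-12)
  expect_equal(exp2, 18.27, tolerance = 0.001)
  expect_equal(exp3, 36.98, tolerance = 0.001)
  # a triple already on the law needs no adjustment
  tri <- c(1, (1 - 0.61^3)^(1 / 3), 0.61)
  expect_equal(ica_adjustment(tri, 3), 0, tolerance = 1e-10)
  expect_error(ica_adjustment(c(1, 0.67, 1.2), 2), "r_eca")
})

test_that("ratio summaries are correct, scale free and degenerate-safe", {
  one <- data.frame(r_cca_mm = 1, r_ica_mm = 0.67, r_eca_mm = 0.61)
  s <- summarize_ratios(one)
  expect_equal(s["ica_cca", "mean"], 0.67, tolerance = 1e-12)
  expect_equal(s["eca_cca", "mean"], 0.61, tolerance = 1e-12)
  expect_equal(s["eca_ica", "mean"], 0.61 / 0.67, tolerance = 1e-12)
  expect_equal(s["area_ratio_sq", "mean"], 0.67^2 + 0.61^2,
               tolerance = 1e-12)
  expect_equal(s["area_ratio_sum", "mean"], 1.28, tolerance = 1e-12)

  many <- one[rep(1, 10), ]
  expect_true(all(summarize_ratios(many)$sd == 0))

  doubled <- data.frame(r_cca_mm = 2, r_ica_mm = 1.34, r_eca_mm = 1.22)
  expect_equal(summarize_ratios(doubled)$mean, s$mean, tolerance = 1e-12)
})

test_that("left/right comparison handles degenerate and regular cohorts", {
  base <- sample_cohort(20, exact_exponent = 1.5, seed = 12)
  # identical sides: t = 0, p = 1
  sym <- base
  sym[sym$side == "right", 3:5] <- sym[sym$side == "left", 3:5]
  cmp <- compare_sides(sym)
  expect_equal(cmp$t, c(0, 0))
  expect_equal(cmp$p, c(1, 1))

  # systematically larger right ICA: both radius and exponent shift
  off <- base
  off$r_ica_mm[off$side == "right"] <-
    off$r_ica_mm[off$side == "left"] * 1.08
  cmp2 <- compare_sides(off)
  expect_true(all(cmp2$p < 0.05))

  # regular noisy case agrees with stats::t.test
  set.seed(3)
  noisy <- base
  noisy$r_ica_mm <- noisy$r_ica_mm * (1 + rnorm(nrow(noisy), 0, 0.05))
  cmp3 <- compare_sides(noisy)
  tt <- t.test(noisy$r_ica_mm[noisy$side == "left"],
               noisy$r_ica_mm[noisy$side == "right"], paired = TRUE)
  expect_equal(cmp3$t[cmp3$quantity == "ica_radius"],
               unname(tt$statistic), tolerance = 1e-10)
  expect_equal(cmp3$p[cmp3$quantity == "ica_radius"], tt$p.value,
               tolerance = 1e-10)

  single <- base[1:2, ]
  expect_error(compare_sides(single), "at least 2 subjects")
})

test_that("tortuosity filtering is strict at the threshold", {
  rec <- data.frame(r_cca_mm = 1, r_ica_mm = 0.7, r_eca_mm = 0.6,
                    ica_tortuosity = c(0.099, 0.1, 0.101, 0, NA))
  kept <- filter_low_tortuosity(rec)
  expect_equal(kept$ica_tortuosity, c(0.099, 0))
  expect_error(filter_low_tortuosity(rec, threshold = 0), "> 0")
  expect_error(filter_low_tortuosity(rec[, 1:3]), "ica_tortuosity")
})

test_that("mean individual exponent excludes and counts unsolvable rows", {
  rec <- data.frame(r_cca_mm = c(5, 5, 1), r_ica_mm = c(4, 4, 1.2),
                    r_eca_mm = c(3, 3, 0.5))
  m <- mean_individual_exponent(rec)
  expect_equal(as.numeric(m), 2, tolerance = 1e-8)
  expect_equal(attr(m, "n_used"), 2L)
  expect_equal(attr(m, "n_excluded"), 1L)
  allbad <- data.frame(r_cca_mm = 1, r_ica_mm = 1.5, r_eca_mm = 1.5)
  expect_error(mean_individual_exponent(allbad), "no records")
})
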
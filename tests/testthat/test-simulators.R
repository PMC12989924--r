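test_that("censoring calibration: censored fraction equals r at beta = 0", {
  n <- 10000
  for (r in c(0.1, 0.25, 0.5)) {
    d <- simulate_ph(n / 2, n / 2, beta = 0, r = r,
                     copula = make_copula("independence"), seed = 100 + r * 100)
    expect_lt(abs(mean(d$event == 0) - r), 3 * sqrt(r * (1 - r) / n))
  }
  # exchangeable copula keeps the 0.5 calibration under dependence
  d <- simulate_ph(5000, 5000, beta = 0, r = 0.5,
                   copula = make_copula("clayton", 0.5), seed = 8)
  expect_lt(abs(mean(d$event == 0) - 0.5), 3 * sqrt(0.25 / 10000))
  # r = 0: no censoring
  d0 <- simulate_ph(50, 50, beta = 0, r = 0, seed = 1)
  expect_true(all(d0$event == 1))
})

test_that("marginals and dependence of (T, C) are as designed", {
  d <- simulate_ph(5000, 5000, beta = 0, r = 0.5,
                   copula = make_copula("clayton", 0.5), seed = 21)
  T <- attr(d, "true_T"); C <- attr(d, "true_C")
  expect_gt(suppressWarnings(ks.test(T, "pexp"))$p.value, 0.01)
  # Kendall's tau of (T, C) is invariant to the monotone marginal transforms
  idx <- 1:2000
  tau_hat <- cor(T[idx], C[idx], method = "kendall")
  expect_lt(abs(tau_hat - 0.5), 0.03)
  # beta shifts group 2 only
  d2 <- simulate_ph(200, 200, beta = -0.4, r = 0, seed = 3)
  T2 <- attr(d2, "true_T")
  expect_gt(mean(T2[201:400]), mean(T2[1:200]) * 1.1)
  # determinism
  expect_identical(simulate_ph(30, 30, beta = 0.2, r = 0.3, seed = 5),
                   simulate_ph(30, 30, beta = 0.2, r = 0.3, seed = 5))
})

test_that("non-PH Gompertz times match the closed-form survival", {
  # z = 0 arm: S(t) = exp(-(e^{gamma t} - 1)/gamma)
  n <- 1e5
  d <- simulate_nph(n, 2, beta1 = 0, beta2 = 0, gamma = 1, r = 0,
                    copula = make_copula("independence"), seed = 17)
  T <- attr(d, "true_T")[1:n]
  tg <- seq(0.05, 2, by = 0.05)
  emp <- vapply(tg, function(t) mean(T > t), 0)
  expect_lt(max(abs(emp - exp(-(exp(tg) - 1)))), 0.01)
  # beta2 = 0 keeps proportional hazards with ratio exp(beta1)
  d <- simulate_nph(n, n, beta1 = 0.7, beta2 = 0, gamma = 1, r = 0, seed = 18)
  T <- attr(d, "true_T")
  H0 <- function(t) (exp(t) - 1) # gamma = 1 cumulative baseline
  # -log S ratio at fixed t estimates the hazard ratio
  t0 <- median(T[1:n])
  r1 <- -log(mean(T[1:n] > t0)); r2 <- -log(mean(T[(n + 1):(2 * n)] > t0))
  expect_lt(abs(r2 / r1 - exp(0.7)), 0.05)
  # gamma -> 0 limit approaches the exponential model
  d <- simulate_nph(n, 2, beta1 = 0, beta2 = 0, gamma = 1e-8, r = 0, seed = 19)
  T <- attr(d, "true_T")[1:n]
  expect_gt(suppressWarnings(ks.test(T, "pexp"))$p.value, 0.01)
  expect_error(simulate_nph(10, 10, beta2 = -2, gamma = 1, r = 0, seed = 1),
               "positive")
})

test_that("pathway covariates have the designed blocks, correlation and coding", {
  n <- 10000
  cop <- make_copula("independence")
  d <- simulate_pathway(n, p = 12, q = 4, rho = 0.5, beta = 0.5, r = 0.25,
                        copula = cop, seed = 33)
  expect_identical(attr(d, "informative"), 1:8)
  zc <- attr(d, "z_continuous")
  # continuous pre-binarisation covariates: mean 0, sd 1, uniform range
  expect_lt(max(abs(colMeans(zc))), 0.05)
  expect_lt(max(abs(apply(zc, 2, sd) - 1)), 0.05)
  expect_true(all(zc > -sqrt(3) - 1e-9 & zc < sqrt(3) + 1e-9))
  # within-block correlation ~ rho, cross-block ~ 0 (pre-transformation)
  cm <- cor(zc)
  within <- c(cm[1:4, 1:4][upper.tri(diag(4))],
              cm[5:8, 5:8][upper.tri(diag(4))])
  expect_lt(max(abs(within - 0.5)), 0.05)
  cross <- cm[1:4, 5:12]
  expect_lt(max(abs(cross)), 3 / sqrt(n) + 0.02)
  # first ceiling(q/2) covariates of each block are median-binarised
  for (j in c(1, 2, 5, 6)) expect_true(all(d[[paste0("z", j)]] %in% c(0, 1)))
  expect_gt(length(unique(d$z3)), 2)
  # all covariates rounded to one decimal
  expect_equal(d$z3, round(d$z3, 1))
  # rho = 0: no correlation anywhere
  d0 <- simulate_pathway(n, p = 8, q = 2, rho = 0, beta = 0.5, r = 0,
                         copula = cop, seed = 34)
  cm0 <- cor(attr(d0, "z_continuous"))
  expect_lt(max(abs(cm0[upper.tri(cm0)])), 3 / sqrt(n))
  expect_error(simulate_pathway(100, p = 8, q = 4, rho = 0, beta = 1, r = 0,
                                copula = cop, seed = 1), "p > 2q")
})

test_that("unequal-censoring variants calibrate per group", {
  d <- simulate_unequal_censoring("group_r", n1 = 5000, n2 = 5000, beta = 0,
                                  r1 = 0.5, r2 = 0.25,
                                  copula = make_copula("independence"),
                                  seed = 44)
  expect_lt(abs(mean(d$event[d$group == 1] == 0) - 0.5), 0.03)
  expect_lt(abs(mean(d$event[d$group == 2] == 0) - 0.25), 0.03)
  expect_identical(attr(d, "config")$variant, "group_r")
  d2 <- simulate_unequal_censoring("censoring_equals_survival", n1 = 5000,
                                   n2 = 5000, beta = 0.8,
                                   copula = make_copula("independence"),
                                   seed = 45)
  # C and T exchangeable within each group: about half censored overall
  expect_lt(abs(mean(d2$event == 0) - 0.5), 0.03)
})
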
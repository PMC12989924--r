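make_two_sample <- function(n1, n2, seed, shift = 1) {
  withr::local_seed(seed)
  two_sample(surv_sample(rexp(n1), rbinom(n1, 1, 0.7)),
             surv_sample(rexp(n2) * shift, rbinom(n2, 1, 0.7)))
}

test_that("L1 is zero for identical groups and antisymmetric under swap", {
  s <- surv_sample(c(1, 2.5, 3, 4.5), c(1, 0, 1, 1))
  cop <- make_copula("clayton", 0.5)
  same <- l1_statistic(two_sample(s, s), cop)
  expect_equal(same$l1, 0)
  expect_equal(same$l1_signed, 0)
  d <- make_two_sample(8, 11, seed = 4, shift = 1.6)
  a <- l1_statistic(d, cop)
  b <- l1_statistic(two_sample(d$group2, d$group1), cop)
  expect_equal(a$l1, b$l1)
  expect_equal(a$l1_signed, -b$l1_signed)
  expect_lte(abs(a$l1_signed), a$l1 + 1e-15)
})

test_that("L1 matches a fine-grid numerical integration oracle", {
  d <- two_sample(surv_sample(c(1, 2, 3), c(1, 1, 1)),
                  surv_sample(c(2, 4, 6), c(1, 1, 1)))
  cop <- make_copula("independence")
  got <- l1_statistic(d, cop)
  want <- oracle_l1(d, cop, npoints = 2e6)
  expect_lt(abs(got$l1 - want$l1), 1e-6)
  expect_lt(abs(got$l1_signed - want$l1_signed), 1e-6)
  # signed statistic orientation: group 2 survives longer here
  expect_lt(got$l1_signed, 0)
  for (k in 1:10) {
    d <- make_two_sample(sample(4:12, 1), sample(4:12, 1), seed = 100 + k,
                         shift = runif(1, 0.5, 2))
    for (cop in list(make_copula("independence"), make_copula("clayton", 0.5),
                     make_copula("frank", 0.4))) {
      got <- l1_statistic(d, cop)
      want <- oracle_l1(d, cop) # midpoint rule, error O(t*/npoints) per jump
      expect_lt(abs(got$l1 - want$l1), 1e-4)
      expect_lt(abs(got$l1_signed - want$l1_signed), 1e-4)
    }
  }
})

test_that("Monte-Carlo p-values are valid, reproducible and scale-invariant", {
  d <- make_two_sample(10, 10, seed = 9)
  cop <- make_copula("clayton", 0.5)
  res <- permutation_test(d, cop, nperm = 200, seed = 3)
  expect_gte(res$p_value, 1 / 200)
  expect_lte(res$p_value, 1)
  # identical seed, identical result
  res2 <- permutation_test(d, cop, nperm = 200, seed = 3)
  expect_identical(res$p_value, res2$p_value)
  # common time rescaling leaves the normalised statistic and p unchanged
  d_scaled <- two_sample(surv_sample(d$group1$time * 7.3, d$group1$status),
                         surv_sample(d$group2$time * 7.3, d$group2$status))
  res3 <- permutation_test(d_scaled, cop, nperm = 200, seed = 3)
  expect_equal(res$l1, res3$l1, tolerance = 1e-12)
  expect_identical(res$p_value, res3$p_value)
  expect_error(permutation_test(d, cop, nperm = 1, seed = 1), "nperm")
})

test_that("exhaustive enumeration matches Monte-Carlo on tiny problems", {
  # n1 = n2 = 1: exactly two assignments
  d1 <- two_sample(surv_sample(1, 1L), surv_sample(2, 1L))
  ex1 <- exhaustive_permutation_test(d1, make_copula("independence"))
  expect_equal(ex1$nperm, 2)
  expect_true(ex1$p_value %in% c(0.5, 1))
  # n1 = n2 = 3, all values distinct: C(6,3) = 20 assignments
  d <- two_sample(surv_sample(c(0.7, 1.1, 2.3), c(1, 1, 0)),
                  surv_sample(c(2.0, 4.1, 6.3), c(1, 0, 1)))
  cop <- make_copula("clayton", 0.5)
  ex <- exhaustive_permutation_test(d, cop)
  expect_equal(ex$nperm, 20)
  mc <- permutation_test(d, cop, nperm = 20000, seed = 17)
  expect_lt(abs(mc$p_value - ex$p_value), 0.02)
  # Monte-Carlo within 3 binomial SEs of the exact p on random datasets
  for (k in 1:5) {
    d <- make_two_sample(5, 6, seed = 500 + k, shift = 1.5)
    ex <- exhaustive_permutation_test(d, cop) # C(11,5) = 462
    nperm <- 4620
    mc <- permutation_test(d, cop, nperm = nperm, seed = k)
    se <- sqrt(ex$p_value * (1 - ex$p_value) / nperm)
    expect_lt(abs(mc$p_value - ex$p_value), 3 * se + 1 / nperm)
  }
  # cap refusal quotes the infeasible count
  d_big <- make_two_sample(50, 50, seed = 1)
  expect_error(exhaustive_permutation_test(d_big, cop), "1.00891\\d*e\\+29")
})

test_that("the R fallback path (non-Clayton copulas) agrees with the engine", {
  d <- make_two_sample(6, 6, seed = 77, shift = 1.4)
  cop <- make_copula("clayton", 0.5)
  fk <- make_copula("frank", 0.5)
  # exhaustive test exercises both backends on the same assignments
  ex_cpp <- exhaustive_permutation_test(d, cop)
  ex_r <- exhaustive_permutation_test(d, fk)
  expect_equal(ex_cpp$nperm, ex_r$nperm)
  expect_gte(ex_r$p_value, 1 / ex_r$nperm)
  # frank Monte-Carlo path is reproducible
  p1 <- permutation_test(d, fk, nperm = 50, seed = 5)$p_value
  p2 <- permutation_test(d, fk, nperm = 50, seed = 5)$p_value
  expect_identical(p1, p2)
})

test_that("weighted logrank matches hand computation and survdiff", {
  skip_if_not_installed("survival")
  # hand-computed toy: x = (1,2,3,4), groups (1,1,2,2), all events
  d <- two_sample(surv_sample(c(1, 2), c(1, 1)), surv_sample(c(3, 4), c(1, 1)))
  # risk sets: t=1: Y=4,Y1=2,d1=1 -> O-E=0.5, V=0.25; t=2: Y=3,Y1=1,d1=1 ->
  # O-E=2/3, V=2/9; t=3: Y=2,Y1=0 -> 0; t=4: Y=1 -> 0
  U <- 0.5 + 2 / 3
  V <- 0.25 + 2 / 9
  lr <- weighted_logrank(d, "logrank")
  expect_equal(lr$statistic, U^2 / V, tolerance = 1e-10)
  # identical groups: tiny statistic, p near 1
  s <- surv_sample(c(1, 2, 3, 4, 5, 6, 7, 8), c(1, 1, 0, 1, 1, 0, 1, 1))
  same <- weighted_logrank(two_sample(s, s), "logrank")
  expect_lt(same$statistic, 1e-20)
  expect_gt(same$p_value, 0.99)
  expect_error(weighted_logrank(
    two_sample(surv_sample(1, 0L), surv_sample(2, 0L))), "events")
  # reference-implementation cross-check on 100 random datasets
  withr::local_seed(31)
  for (k in 1:100) {
    n1 <- sample(5:30, 1); n2 <- sample(5:30, 1)
    x <- c(round(rexp(n1), 1), round(rexp(n2) * 1.4, 1))
    ev <- rbinom(n1 + n2, 1, 0.7)
    if (sum(ev) < 2) next
    d <- two_sample(surv_sample(x[1:n1], ev[1:n1]),
                    surv_sample(x[-(1:n1)], ev[-(1:n1)]))
    g <- rep(1:2, c(n1, n2))
    for (w in c("logrank", "peto_peto")) {
      mine <- weighted_logrank(d, w)
      ref <- survival::survdiff(survival::Surv(x, ev) ~ g,
                                rho = if (w == "logrank") 0 else 1)
      expect_lt(abs(mine$p_value -
                      pchisq(ref$chisq, 1, lower.tail = FALSE)), 1e-8)
    }
  }
})
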
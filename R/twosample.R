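#' Two-sample data under right censoring
#'
#' @param g1,g2 \code{surv_sample} objects (or lists with time/status).
#' @return an object of class \code{two_sample}.
#' @export
two_sample <- function(g1, g2) {
  g1 <- as_surv_sample(g1); g2 <- as_surv_sample(g2)
  structure(list(group1 = g1, group2 = g2, n1 = g1$n, n2 = g2$n),
            class = "two_sample")
}

# pooled rows sorted ascending in time, events before censorings at ties;
# group = 1 for group-1 rows. This is the layout the C++ engine expects.
pooled_sorted <- function(d) {
  x <- c(d$group1$time, d$group2$time)
  ev <- c(d$group1$status, d$group2$status)
  g <- rep(c(1L, 0L), c(d$n1, d$n2))
  o <- order(x, -ev)
  list(x = x[o], status = ev[o], group = g[o])
}

theta_for_engine <- function(copula) {
  switch(copula$family,
    independence = 0,
    clayton = {
      if (copula$theta <= 0) {
        stop("the fast permutation engine covers Clayton theta > 0 and ",
             "independence; use the generic (R) path for other copulas")
      }
      copula$theta
    },
    stop("the fast permutation engine covers Clayton theta > 0 and ",
         "independence; use the generic (R) path for other copulas")
  )
}

engine_supported <- function(copula) {
  copula$family == "independence" ||
    (copula$family == "clayton" && copula$theta > 0)
}

#' Integrated CGE-distance statistics L1 and signed L1
#'
#' Computes the time-normalised integrated absolute difference of the two
#' groups' copula-graphic estimators,
#' \deqn{L_1 = \frac{1}{t^*} \int^{t^*} |\hat S_1(t) - \hat S_2(t)| \, dt,
#'   \qquad t^* = \min(\max x_1, \max x_2),}
#' together with its signed version (the same integral without absolute
#' values). The integrand is piecewise constant, so the integral is exact.
#' The lower limit is the smallest pooled observed time; both estimators equal
#' 1 before it, so this coincides with integrating from 0. A positive signed
#' value indicates longer survival in group 1.
#'
#' @param d a [two_sample()] object.
#' @param copula assumed [make_copula()] model shared by both groups.
#' @return list with elements \code{l1}, \code{l1_signed} and \code{tstar}.
#' @export
l1_statistic <- function(d, copula) {
  tstar <- min(max(d$group1$time), max(d$group2$time))
  if (tstar <= 0) stop("degenerate data: common observation window has length 0")
  s1 <- copula_graphic(d$group1, copula)
  s2 <- copula_graphic(d$group2, copula)
  brk <- sort(unique(c(0, s1$time, s2$time, tstar)))
  brk <- brk[brk <= tstar]
  if (max(brk) < tstar) brk <- c(brk, tstar)
  lo <- brk[-length(brk)]
  w <- diff(brk)
  v1 <- curve_value(s1, lo, extend = TRUE)
  v2 <- curve_value(s2, lo, extend = TRUE)
  list(l1 = sum(w * abs(v1 - v2)) / tstar,
       l1_signed = sum(w * (v1 - v2)) / tstar,
       tstar = tstar)
}

#' Monte-Carlo permutation test for equal survival under dependent censoring
#'
#' Tests H0: equal survival distributions in two groups, assuming equal
#' censoring distributions (so the pooled (time, status) pairs are
#' exchangeable under H0). The observed L1 statistic is compared with its
#' permutation distribution: each permutation re-assigns the pooled
#' (time, status) pairs jointly to groups of the original sizes. The observed
#' assignment is always one of the \code{nperm} considered permutations, so
#' the Monte-Carlo p-value
#' \deqn{p = \#\{ \pi : L_1(\pi) \ge L_1(obs) \} / nperm}
#' is at least \code{1/nperm} and the test is valid (ties count as extreme).
#'
#' For Clayton (theta > 0) and independence copulas a vectorised C++ engine
#' evaluates all permutations from one sorted pooled-time grid; other copulas
#' use an R path suitable for small problems.
#'
#' @param d a [two_sample()] object.
#' @param copula assumed [make_copula()] model.
#' @param nperm number of permutations including the observed one (>= 2).
#' @param seed integer seed.
#' @param alpha nominal level recorded in the result.
#' @return an object of class \code{cg_perm_test} with fields \code{l1},
#'   \code{l1_signed}, \code{p_value}, \code{nperm}, \code{alpha},
#'   \code{seed}, \code{copula}.
#' @export
permutation_test <- function(d, copula, nperm = 1000, seed, alpha = 0.05) {
  if (nperm < 2) stop("nperm must be at least 2")
  ps <- pooled_sorted(d)
  if (engine_supported(copula)) {
    res <- cpp_perm_test(ps$x, ps$status, ps$group,
                         theta_for_engine(copula), nperm, seed)
    out <- list(l1 = res$l1[1], l1_signed = res$l1_signed[1],
                p_value = res$p_value[1], nperm = nperm)
  } else {
    obs <- l1_statistic(d, copula)
    n <- d$n1 + d$n2
    cnt <- 1L
    for (b in seq_len(nperm - 1L)) {
      pick <- with_local_seed(derive_seed(seed, b),
                              sample.int(n, d$n1))
      dp <- two_sample(surv_sample(ps$x[pick], ps$status[pick]),
                       surv_sample(ps$x[-pick], ps$status[-pick]))
      if (l1_statistic(dp, copula)$l1 >= obs$l1) cnt <- cnt + 1L
    }
    out <- list(l1 = obs$l1, l1_signed = obs$l1_signed,
                p_value = cnt / nperm, nperm = nperm)
  }
  structure(c(out, list(alpha = alpha, seed = seed, copula = copula,
                        exhaustive = FALSE)),
            class = "cg_perm_test")
}

#' Exhaustive permutation test
#'
#' Enumerates all \code{choose(n1 + n2, n1)} distinct group assignments and
#' returns the exact permutation p-value. Refuses when the count exceeds
#' \code{cap} (use the Monte-Carlo [permutation_test()] instead).
#'
#' @param d a [two_sample()] object.
#' @param copula assumed [make_copula()] model.
#' @param cap maximum number of assignments to enumerate.
#' @param alpha nominal level recorded in the result.
#' @return a \code{cg_perm_test} object with \code{nperm} equal to the number
#'   of distinct assignments.
#' @export
exhaustive_permutation_test <- function(d, copula, cap = 1e5, alpha = 0.05) {
  ncomb <- n_assignments(d$n1, d$n2)
  if (ncomb > cap) {
    stop(sprintf(paste0("choose(%d, %d) = %.6g distinct assignments exceeds ",
                        "the cap (%g); use permutation_test()"),
                 d$n1 + d$n2, d$n1, ncomb, cap))
  }
  ps <- pooled_sorted(d)
  n <- d$n1 + d$n2
  sets <- combn(n, d$n1)
  gm <- matrix(0L, n, ncol(sets))
  gm[cbind(as.vector(sets), rep(seq_len(ncol(sets)), each = d$n1))] <- 1L
  if (engine_supported(copula)) {
    ev <- cpp_l1_eval(ps$x, ps$status, gm, theta_for_engine(copula))
    l1_all <- ev$l1[, 1]
    obs <- cpp_l1_eval(ps$x, ps$status, cbind(ps$group),
                       theta_for_engine(copula))
    l1_obs <- obs$l1[1, 1]; ls_obs <- obs$l1_signed[1, 1]
  } else {
    l1_all <- apply(gm, 2, function(g) {
      dp <- two_sample(surv_sample(ps$x[g == 1L], ps$status[g == 1L]),
                       surv_sample(ps$x[g == 0L], ps$status[g == 0L]))
      l1_statistic(dp, copula)$l1
    })
    ob <- l1_statistic(two_sample(
      surv_sample(ps$x[ps$group == 1L], ps$status[ps$group == 1L]),
      surv_sample(ps$x[ps$group == 0L], ps$status[ps$group == 0L])), copula)
    l1_obs <- ob$l1; ls_obs <- ob$l1_signed
  }
  structure(list(l1 = l1_obs, l1_signed = ls_obs,
                 p_value = mean(l1_all >= l1_obs - 1e-12),
                 nperm = ncol(gm), alpha = alpha, seed = NA_integer_,
                 copula = copula, exhaustive = TRUE),
            class = "cg_perm_test")
}

#' @export
print.cg_perm_test <- function(x, ...) {
  cat("Two-sample CGE permutation test\n")
  print(x$copula)
  cat(sprintf("L1 = %.6g, signed L1 = %.6g\n", x$l1, x$l1_signed))
  cat(sprintf("p-value = %.4g (%s, %d permutations)\n", x$p_value,
              if (isTRUE(x$exhaustive)) "exhaustive" else "Monte-Carlo",
              x$nperm))
  invisible(x)
}

#' Weighted logrank tests (logrank and Peto-Peto)
#'
#' Classical two-sample weighted logrank chi-square test with 1 degree of
#' freedom, included as the independence-censoring comparator. The Peto-Peto
#' variant weights each distinct event time by the left-continuous pooled
#' Kaplan-Meier-type survival estimate \code{S(t) = prod(1 - d/(Y + 1))}
#' over earlier event times (the convention of \code{survival::survdiff} with
#' \code{rho = 1}).
#'
#' @param d a [two_sample()] object.
#' @param weight \code{"logrank"} or \code{"peto_peto"}.
#' @return list with \code{statistic} (chi-square), \code{p_value},
#'   \code{observed}, \code{expected} (group-1 event counts).
#' @export
weighted_logrank <- function(d, weight = c("logrank", "peto_peto")) {
  weight <- match.arg(weight)
  x <- c(d$group1$time, d$group2$time)
  ev <- c(d$group1$status, d$group2$status)
  g1 <- rep(c(1L, 0L), c(d$n1, d$n2))
  if (sum(ev) == 0L) stop("weighted logrank statistic undefined without events")
  ut <- sort(unique(x[ev == 1L]))
  Y <- vapply(ut, function(t) sum(x >= t), 0)
  Y1 <- vapply(ut, function(t) sum(x >= t & g1 == 1L), 0)
  dtot <- vapply(ut, function(t) sum(x == t & ev == 1L), 0)
  d1 <- vapply(ut, function(t) sum(x == t & ev == 1L & g1 == 1L), 0)
  w <- if (weight == "logrank") rep(1, length(ut)) else {
    # left-continuous pooled Kaplan-Meier: prod over event times strictly
    # before t of (1 - d/Y); the survdiff(rho = 1) convention
    c(1, cumprod(1 - dtot / Y))[seq_along(ut)]
  }
  Eb <- d1 - dtot * Y1 / Y
  Vb <- ifelse(Y > 1, dtot * (Y1 / Y) * (1 - Y1 / Y) * (Y - dtot) / (Y - 1), 0)
  U <- sum(w * Eb)
  V <- sum(w^2 * Vb)
  if (V <= 0) stop("weighted logrank variance is zero")
  stat <- U^2 / V
  list(statistic = stat, p_value = pchisq(stat, df = 1, lower.tail = FALSE),
       score = U, variance = V)
}
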
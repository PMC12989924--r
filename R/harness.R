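#' Run a type-I-error / power simulation study for the two-sample tests
#'
#' For each scenario (row of \code{scenarios}), simulates \code{nsim}
#' proportional-hazards datasets with copula-dependent censoring, applies the
#' CGE permutation tests for each assumed tau plus the logrank and Peto-Peto
#' comparators, and tabulates rejection rates at level \code{alpha} with
#' their Monte-Carlo standard errors and per-group mean censoring fractions.
#'
#' @param scenarios data.frame with columns \code{n1}, \code{n2}, \code{beta},
#'   \code{r}, \code{family} (data-generating copula family) and \code{tau}
#'   (its theoretical Kendall tau; 0 means independence).
#' @param nsim simulated datasets per scenario.
#' @param nperm permutations per test.
#' @param alpha nominal level.
#' @param taus_assumed assumed Kendall tau grid of the CGE tests (Clayton;
#'   0 = independence).
#' @param seed integer root seed; each scenario x replicate derives its own
#'   sub-seed, so results do not depend on evaluation order.
#' @param include_comparators also run the logrank and Peto-Peto tests.
#' @return data.frame with one row per scenario x test: rejection rate,
#'   Monte-Carlo SE, and mean censoring fraction per group.
#' @export
run_power_study <- function(scenarios, nsim = 1000, nperm = 1000,
                            alpha = 0.05,
                            taus_assumed = c(0, 0.25, 0.5, 0.75),
                            seed = 1, include_comparators = TRUE) {
  thetas <- ifelse(taus_assumed == 0, 0, 2 * taus_assumed / (1 - taus_assumed))
  out <- list()
  for (sc in seq_len(nrow(scenarios))) {
    row <- scenarios[sc, ]
    gen_cop <- if (row$tau == 0) make_copula("independence") else
      make_copula(as.character(row$family), row$tau)
    rej <- matrix(0, nsim, length(thetas))
    rej_lr <- rej_pp <- numeric(nsim)
    cens1 <- cens2 <- numeric(nsim)
    for (i in seq_len(nsim)) {
      si <- derive_seed(seed, sc, i)
      dat <- simulate_ph(row$n1, row$n2, beta = row$beta, r = row$r,
                         copula = gen_cop, covariate = "binary", seed = si)
      g1 <- dat$group == 1L
      cens1[i] <- mean(dat$event[g1] == 0L)
      cens2[i] <- mean(dat$event[!g1] == 0L)
      d <- as_two_sample(dat)
      ps <- pooled_sorted(d)
      res <- cpp_perm_test(ps$x, ps$status, ps$group, thetas, nperm,
                           derive_seed(si, 999L))
      rej[i, ] <- res$p_value <= alpha
      if (include_comparators) {
        rej_lr[i] <- weighted_logrank(d, "logrank")$p_value <= alpha
        rej_pp[i] <- weighted_logrank(d, "peto_peto")$p_value <= alpha
      }
    }
    tests <- data.frame(
      test = c(paste0("cge_tau", format(taus_assumed)),
               if (include_comparators) c("logrank", "peto_peto")),
      rejection_rate = c(colMeans(rej),
                         if (include_comparators) c(mean(rej_lr),
                                                    mean(rej_pp)))
    )
    tests$monte_carlo_se <- mc_se(tests$rejection_rate, nsim)
    cbind(row[rep(1, nrow(tests)), , drop = FALSE], tests,
          data.frame(cens_frac_g1 = mean(cens1), cens_frac_g2 = mean(cens2),
                     nsim = nsim, nperm = nperm, alpha = alpha),
          row.names = NULL) -> out[[sc]]
  }
  do.call(rbind, out)
}

#' Run the survival-tree simulation study on pathway data
#'
#' Per replicate, simulates a training and a testing pathway dataset of
#' \code{n} subjects each, grows one CGE tree per assumed tau plus the
#' logrank comparator tree, and evaluates covariate-selection precision,
#' Harrell's C on terminal-node ranks, and the integrated Brier score with
#' Kaplan-Meier and with CGE (tau = theoretical tau) censoring weights on the
#' test data.
#'
#' @param n subjects per dataset.
#' @param p,q,rho,beta,r,tau_theor pathway design parameters
#'   (see [simulate_pathway()]); the generating copula is Clayton.
#' @param nsim simulation rounds.
#' @param nperm permutations per split candidate.
#' @param p_threshold splitting threshold.
#' @param taus_assumed assumed tau grid for the CGE trees.
#' @param min_child minimum child size of a split.
#' @param seed integer root seed.
#' @param include_logrank also grow the logrank comparator tree.
#' @return data.frame with one row per replicate x tree.
#' @export
run_tree_study <- function(n = 100, p = 50, q = 5, rho = 0.5, beta = 0.5,
                           r = 0.5, tau_theor = 0.25, nsim = 100,
                           nperm = 1000, p_threshold = 0.01,
                           taus_assumed = c(0, 0.25, 0.5, 0.75),
                           min_child = 2, seed = 1, include_logrank = TRUE) {
  gen_cop <- if (tau_theor == 0) make_copula("independence") else
    make_copula("clayton", tau_theor)
  weight_cop <- gen_cop
  out <- list()
  for (i in seq_len(nsim)) {
    train <- simulate_pathway(n, p, q, rho, beta, r, gen_cop,
                              seed = derive_seed(seed, i, 1L))
    test <- simulate_pathway(n, p, q, rho, beta, r, gen_cop,
                             seed = derive_seed(seed, i, 2L))
    informative <- attr(train, "informative")
    trees <- list()
    for (tau in taus_assumed) {
      cop <- if (tau == 0) make_copula("independence") else
        make_copula("clayton", tau)
      trees[[paste0("cge_tau", format(tau))]] <-
        cg_tree(train, cop, p_threshold = p_threshold, nperm = nperm,
                min_child = min_child,
                seed = derive_seed(seed, i, 3L, round(1000 * tau)))
    }
    if (include_logrank) {
      trees[["logrank"]] <- cg_tree(train, make_copula("independence"),
                                    p_threshold = p_threshold, nperm = nperm,
                                    min_child = min_child,
                                    seed = derive_seed(seed, i, 4L),
                                    split_test = "logrank")
    }
    strain <- surv_sample(train$time, train$event)
    stest <- surv_sample(test$time, test$event)
    grid <- sort(unique(c(train$time, test$time)))
    cens_km <- censoring_curve(strain)
    cens_cge <- censoring_curve(strain, weight_cop)
    for (nm in names(trees)) {
      tree <- trees[[nm]]
      covars <- test[, tree$covariates, drop = FALSE]
      nodes <- assign_node(tree, covars)
      preds <- predict(tree, covars, pmin(grid, max(test$time)))
      out[[length(out) + 1L]] <- data.frame(
        replicate = i, tree = nm, n = n,
        n_terminal = tree$n_terminal,
        precision = selection_precision(tree, informative),
        harrells_c = harrells_c(nodes, stest),
        ibs_km = as.numeric(integrated_brier(preds, stest, cens_km, grid)),
        ibs_cge = as.numeric(integrated_brier(preds, stest, cens_cge, grid)),
        cens_frac = mean(train$event == 0L))
    }
  }
  do.call(rbind, out)
}
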
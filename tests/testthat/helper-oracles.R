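# Independent oracles used across the test files. These re-derive quantities
# by brute force (enumeration, fine-grid quadrature, double loops) and never
# call the code paths they are checking.

# random right-censored sample
rand_sample <- function(n, event_p = 0.7, seed, round_digits = NULL) {
  withr::local_seed(seed)
  x <- rexp(n)
  if (!is.null(round_digits)) x <- round(x, round_digits) + 1e-9
  surv_sample(x, rbinom(n, 1, event_p))
}

# Clayton copula-graphic estimator from the closed form, written directly from
# risk counts (independent of the package's generator machinery)
oracle_clayton_cge <- function(time, status, theta, eval_times) {
  n <- length(time)
  ev <- sort(unique(time[status == 1]))
  vapply(eval_times, function(t) {
    tot <- 0
    for (s in ev[ev <= t]) {
      Y <- sum(time >= s)
      d <- sum(time == s & status == 1)
      tot <- tot + ((Y - d) / n)^(-theta) - (Y / n)^(-theta)
    }
    max(0, min(1, (1 + tot)^(-1 / theta)))
  }, 0)
}

# L1 and signed L1 by fine-grid Riemann sum over two step curves
oracle_l1 <- function(d, copula, npoints = 1e5) {
  tstar <- min(max(d$group1$time), max(d$group2$time))
  s1 <- copula_graphic(d$group1, copula)
  s2 <- copula_graphic(d$group2, copula)
  tg <- seq(0, tstar, length.out = npoints + 1)
  mid <- (tg[-1] + tg[-length(tg)]) / 2
  v1 <- curve_value(s1, mid, extend = TRUE)
  v2 <- curve_value(s2, mid, extend = TRUE)
  h <- tstar / npoints
  list(l1 = sum(abs(v1 - v2)) * h / tstar,
       l1_signed = sum(v1 - v2) * h / tstar)
}

# Harrell's C by explicit double loop over ordered pairs
oracle_harrells_c <- function(nodes, time, status) {
  cc <- dc <- tr <- 0
  n <- length(time)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (time[i] > time[j] && status[j] == 1) {
      if (nodes[i] < nodes[j]) cc <- cc + 1
      else if (nodes[i] > nodes[j]) dc <- dc + 1
      else tr <- tr + 1
    }
  }
  (cc + 0.5 * tr) / (cc + dc + tr)
}

# discretised integrated Brier score by direct double loop over the grid
oracle_ibs <- function(pred, time, status, wgrid, wx, grid) {
  xmax <- max(time)
  keep <- grid <= xmax
  grid <- grid[keep]; pred <- pred[, keep, drop = FALSE]
  wgrid <- wgrid[keep]
  n <- length(time); m <- length(grid)
  total <- 0
  for (j in seq_len(m - 1)) {
    acc <- 0
    for (i in seq_len(n)) {
      if (time[i] >= grid[j]) {
        if (wgrid[j] > 0) acc <- acc + (1 - pred[i, j])^2 / wgrid[j]
      } else if (status[i] == 1 && wx[i] > 0) {
        acc <- acc + pred[i, j]^2 / wx[i]
      }
    }
    total <- total + (grid[j + 1] - grid[j]) * acc / n
  }
  total / xmax
}

# interpret a serialized tree's rules directly (routing oracle)
oracle_route <- function(tree_json, z) {
  node <- jsonlite::fromJSON(tree_json, simplifyVector = FALSE)$root
  while (node$type == "internal") {
    goes_low <- z[[node$covariate]] <= node$cutoff
    low_right <- identical(node$low_side, "right")
    node <- if (goes_low == low_right) node$right else node$left
  }
  node$node_number
}
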
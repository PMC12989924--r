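#' Covariate-selection precision of a survival tree
#'
#' Proportion of internal nodes that split on one of the informative
#' covariates. Undefined (returns \code{NA}) for a tree without splits; such
#' trees are excluded from study averages.
#'
#' @param tree a [cg_tree()].
#' @param informative integer indices (into the tree's covariate columns) of
#'   the truly informative covariates.
#' @return a value in \code{[0, 1]}, or \code{NA} for a depth-0 tree.
#' @export
selection_precision <- function(tree, informative) {
  ints <- internal_nodes(tree)
  if (!length(ints)) return(NA_real_)
  mean(vapply(ints, function(nd) nd$covariate %in% informative, logical(1)))
}

#' Harrell's concordance index on terminal-node ranks
#'
#' Measures whether terminal-node numbers order observed survival correctly:
#' low node numbers should mean long survival. Comparable pairs are ordered
#' pairs (i, j) with \code{x_i > x_j} and an observed event for the earlier
#' subject (\code{delta_j = 1}), so subject j certainly failed before subject
#' i was last seen. With concordant (node_i < node_j), discordant
#' (node_i > node_j) and tied-rank counts CC, DC, TR,
#' \deqn{HC = (CC + 0.5 \, TR) / (CC + DC + TR).}
#'
#' @param node_numbers per-subject terminal node ranks (low = long survival).
#' @param s a [surv_sample()] of the same subjects.
#' @return concordance in \code{[0, 1]}; error when no pair is comparable.
#' @export
harrells_c <- function(node_numbers, s) {
  s <- as_surv_sample(s)
  stopifnot(length(node_numbers) == s$n, s$n >= 2)
  cmp <- outer(s$time, s$time, ">") & rep(s$status == 1L, each = s$n)
  ndi <- node_numbers[row(cmp)[cmp]]
  ndj <- node_numbers[col(cmp)[cmp]]
  if (!length(ndi)) stop("no comparable pairs (need an event before a later time)")
  cc <- sum(ndi < ndj); dc <- sum(ndi > ndj); tr <- sum(ndi == ndj)
  (cc + 0.5 * tr) / (cc + dc + tr)
}

#' Censoring-weighted integrated Brier score
#'
#' Discretised integrated Brier score for right-censored data with
#' inverse-probability-of-censoring weights,
#' \deqn{\widehat{IB} = \frac{1}{\max x} \sum_{j=1}^{m-1}
#'   (\tilde t_{j+1} - \tilde t_j) \frac{1}{n} \sum_{i=1}^n
#'   \Big[ \frac{(1 - \hat S(\tilde t_j | z_i))^2}{\hat C(\tilde t_j)}
#'   1\{x_i \ge \tilde t_j\} + \frac{\hat S(\tilde t_j | z_i)^2}{\hat C(x_i)}
#'   1\{x_i < \tilde t_j\} \delta_i \Big],}
#' where the grid contains the observed time points (the step-function
#' estimators do not move between them, so this equals the exact integral
#' when the grid holds all breakpoints). Censoring weights are evaluated as
#' left limits \code{C(t-)} by default; terms whose weight is zero are
#' dropped and counted in the \code{dropped} attribute.
#'
#' @param predictions matrix of predicted survival probabilities, one row per
#'   test subject, one column per grid point.
#' @param test a [surv_sample()] of the test subjects.
#' @param weight_curve a [step_curve()] estimate of the censoring survival
#'   function (typically [censoring_curve()] on the training data).
#' @param grid increasing evaluation times (observed train and/or test times).
#' @param left_weights evaluate the weight curve as a left limit (default);
#'   set \code{FALSE} for right-continuous evaluation.
#' @return non-negative score with attribute \code{dropped} (count of
#'   zero-weight terms).
#' @export
integrated_brier <- function(predictions, test, weight_curve, grid,
                             left_weights = TRUE) {
  test <- as_surv_sample(test)
  grid <- sort(unique(as.double(grid)))
  stopifnot(nrow(predictions) == test$n, ncol(predictions) == length(grid))
  xmax <- max(test$time)
  use <- grid <= xmax
  grid <- grid[use]
  predictions <- predictions[, use, drop = FALSE]
  m <- length(grid)
  if (m < 2) stop("need at least two grid points within the observation span")
  wg <- curve_value(weight_curve, pmin(grid, weight_curve$domain_max),
                    left = left_weights)
  wx <- curve_value(weight_curve, pmin(test$time, weight_curve$domain_max),
                    left = left_weights)
  dt <- diff(grid)
  total <- 0
  dropped <- 0L
  for (j in seq_len(m - 1)) {
    tj <- grid[j]
    atrisk <- test$time >= tj
    late <- !atrisk & test$status == 1L
    terms <- numeric(test$n)
    if (any(atrisk)) {
      if (wg[j] > 0) {
        terms[atrisk] <- (1 - predictions[atrisk, j])^2 / wg[j]
      } else {
        dropped <- dropped + sum(atrisk)
      }
    }
    if (any(late)) {
      ok <- late & wx > 0
      terms[ok] <- predictions[ok, j]^2 / wx[ok]
      dropped <- dropped + sum(late & wx <= 0)
    }
    total <- total + dt[j] * mean(terms)
  }
  structure(total / xmax, dropped = dropped)
}
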
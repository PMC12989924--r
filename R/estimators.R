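#' Right-censored survival samples
#'
#' Bundles observed times \code{x = min(T, C)} and event indicators
#' \code{delta = 1(X = T)} for one group of subjects.
#'
#' @param time non-negative finite observed times.
#' @param status event indicators, 0 = censored, 1 = event.
#' @return an object of class \code{surv_sample}.
#' @export
surv_sample <- function(time, status) {
  time <- as.double(time); status <- as.integer(status)
  if (length(time) < 1L) stop("empty survival sample")
  if (length(time) != length(status)) stop("time/status length mismatch")
  if (any(!is.finite(time)) || any(time < 0)) {
    stop("observed times must be finite and non-negative")
  }
  if (!all(status %in% c(0L, 1L))) stop("status must be 0 (censored) or 1 (event)")
  structure(list(time = time, status = status, n = length(time)),
            class = "surv_sample")
}

as_surv_sample <- function(s) {
  if (inherits(s, "surv_sample")) s else surv_sample(s$time, s$status)
}

#' @export
print.surv_sample <- function(x, ...) {
  cat(sprintf("surv_sample: n = %d, events = %d (%.1f%%)\n",
              x$n, sum(x$status), 100 * mean(x$status)))
  invisible(x)
}

# Per distinct event time: risk count just before (Y = #{X >= t}, events at a
# tied time are processed before censorings) and number of events d.
event_risk_table <- function(s) {
  n <- s$n
  ut <- sort(unique(s$time[s$status == 1L]))
  if (!length(ut)) {
    return(list(time = numeric(0), Y = integer(0), d = integer(0), n = n))
  }
  Y <- vapply(ut, function(t) sum(s$time >= t), 0L)
  d <- vapply(ut, function(t) sum(s$time == t & s$status == 1L), 0L)
  list(time = ut, Y = Y, d = d, n = n)
}

#' Naive pooled survival estimate
#'
#' The empirical proportion of observed times strictly exceeding t,
#' \code{pi_hat(t) = (1/n) * sum 1(X_i > t)}, which the copula-graphic
#' estimator splits into survival and censoring components.
#'
#' @param s a \code{surv_sample} (or list with \code{time}/\code{status}).
#' @return a [step_curve()].
#' @export
naive_survival <- function(s) {
  s <- as_surv_sample(s)
  ut <- sort(unique(s$time))
  vals <- vapply(ut, function(t) mean(s$time > t), 0)
  step_curve(ut, vals, max(s$time))
}

#' Copula-graphic estimator of the survival function
#'
#' Estimates \code{S_T} from right-censored data under an assumed Archimedean
#' copula between event and censoring times. Writing \code{Y(s)} for the
#' number at risk just before an event time s and \code{d(s)} for the events
#' at s, the estimator is
#' \deqn{\hat S(t) = \varphi^{-1}\Big(\sum_{s \le t, \; d(s) > 0}
#'   \varphi\big((Y(s)-d(s))/n\big) - \varphi\big(Y(s)/n\big)\Big),}
#' a right-continuous non-increasing step function on
#' \code{[0, max(X_1, ..., X_n)]} with \code{S(0) = 1} and downward jumps only
#' at event times. With the independence generator \code{phi(u) = -log(u)} the
#' sum telescopes to the Kaplan-Meier product-limit estimator. When the
#' largest observation is an event the final generator argument is 0; the
#' pseudo-inverse maps \code{phi(0+) = Inf} to 0, so the curve drops to zero
#' there without special-casing.
#'
#' @param s a \code{surv_sample}.
#' @param copula an [make_copula()] object.
#' @return a [step_curve()] jumping only at event times.
#' @export
copula_graphic <- function(s, copula) {
  s <- as_surv_sample(s)
  rt <- event_risk_table(s)
  if (!length(rt$time)) {
    return(step_curve(numeric(0), numeric(0), max(s$time)))
  }
  inc <- cop_generator(copula, (rt$Y - rt$d) / rt$n) -
    cop_generator(copula, rt$Y / rt$n)
  S <- cop_generator_inv(copula, cumsum(inc))
  S <- cummin(pmin(pmax(S, 0), 1))
  step_curve(rt$time, S, max(s$time))
}

#' Clayton closed-form copula-graphic estimator
#'
#' Direct evaluation of the Clayton-generator copula-graphic estimator,
#' \deqn{\hat S(t) = \Big[1 + \sum_{s \le t}\big(((Y(s)-d(s))/n)^{-\theta}
#'   - (Y(s)/n)^{-\theta}\big)\Big]^{-1/\theta},}
#' identical to [copula_graphic()] with a Clayton copula; kept as a separate
#' code path because the permutation engine uses this form. For
#' \code{theta <= 0} the generic path is used (theta = 0 meaning independence).
#'
#' @param s a \code{surv_sample}.
#' @param theta Clayton dependence parameter.
#' @return a [step_curve()].
#' @export
clayton_cge <- function(s, theta) {
  s <- as_surv_sample(s)
  if (theta <= 0) {
    cop <- if (theta == 0) make_copula("independence") else
      make_copula("clayton", theta / (theta + 2))
    return(copula_graphic(s, cop))
  }
  rt <- event_risk_table(s)
  if (!length(rt$time)) {
    return(step_curve(numeric(0), numeric(0), max(s$time)))
  }
  inc <- ((rt$Y - rt$d) / rt$n)^(-theta) - (rt$Y / rt$n)^(-theta)
  S <- (1 + cumsum(inc))^(-1 / theta)
  S <- cummin(pmin(pmax(S, 0), 1))
  step_curve(rt$time, S, max(s$time))
}

#' Kaplan-Meier product-limit estimator
#'
#' The independence special case of the copula-graphic estimator.
#'
#' @param s a \code{surv_sample}.
#' @return a [step_curve()].
#' @export
kaplan_meier <- function(s) {
  copula_graphic(s, make_copula("independence"))
}

#' Copula-graphic estimator of the censoring distribution
#'
#' Applies [copula_graphic()] with the roles of events and censorings swapped
#' (status flipped); with the independence copula this is the Kaplan-Meier
#' estimator of the censoring survival function, the usual weight curve for
#' the integrated Brier score.
#'
#' @param s a \code{surv_sample}.
#' @param copula an [make_copula()] object (default independence).
#' @return a [step_curve()] jumping only at censoring times.
#' @export
censoring_curve <- function(s, copula = make_copula("independence")) {
  s <- as_surv_sample(s)
  copula_graphic(surv_sample(s$time, 1L - s$status), copula)
}

#' Median survival time from a step curve
#'
#' Smallest time at which the curve is at or below 1/2; \code{NA} if the curve
#' never reaches it on its domain.
#'
#' @param curve a [step_curve()].
#' @return a time or \code{NA}.
#' @export
median_survival <- function(curve) {
  i <- which(curve$surv <= 0.5)
  if (!length(i)) NA_real_ else curve$time[min(i)]
}
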
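#' Right-continuous step curves
#'
#' Container for the step-function estimates produced by this package (naive
#' pooled survival, Kaplan-Meier, copula-graphic and censoring curves). A
#' curve equals 1 at t = 0, is right-continuous and non-increasing, takes
#' values in [0, 1], and is defined on \code{[0, domain_max]} where
#' \code{domain_max} is the largest observed time.
#'
#' @param time strictly increasing positive jump times.
#' @param surv curve value on \code{[time[k], time[k+1])}.
#' @param domain_max largest observed time (curve domain endpoint).
#' @return an object of class \code{step_curve}.
#' @export
step_curve <- function(time, surv, domain_max) {
  stopifnot(length(time) == length(surv),
            !is.unsorted(time, strictly = TRUE),
            all(time > 0), domain_max >= 0)
  surv <- pmin(pmax(surv, 0), 1)
  if (is.unsorted(rev(surv))) stop("step curve values must be non-increasing")
  structure(list(time = as.double(time), surv = as.double(surv),
                 domain_max = as.double(domain_max)),
            class = "step_curve")
}

#' Evaluate a step curve
#'
#' @param curve a \code{step_curve}.
#' @param t evaluation times in \code{[0, domain_max]}; evaluation beyond the
#'   domain is an error unless \code{extend = TRUE}, in which case the last
#'   value is carried forward.
#' @param left if \code{TRUE}, return the left limit (the value just before
#'   \code{t}), as used for censoring weights in the integrated Brier score.
#' @param extend allow constant extrapolation beyond \code{domain_max}.
#' @return numeric vector of curve values.
#' @export
curve_value <- function(curve, t, left = FALSE, extend = FALSE) {
  if (!extend && any(t > curve$domain_max + 1e-12)) {
    stop("evaluation beyond the curve domain [0, ", curve$domain_max, "]")
  }
  if (any(t < 0)) stop("evaluation times must be non-negative")
  idx <- findInterval(t, curve$time, left.open = left)
  c(1, curve$surv)[idx + 1L]
}

#' @export
print.step_curve <- function(x, ...) {
  cat(sprintf("step_curve on [0, %.4g] with %d jump(s)\n",
              x$domain_max, length(x$time)))
  if (length(x$time)) {
    show <- utils::head(data.frame(time = x$time, value = x$surv), 10)
    print(show, row.names = FALSE)
    if (length(x$time) > 10) cat("...\n")
  }
  invisible(x)
}
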
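#' Simulate proportional-hazards survival data with dependent censoring
#'
#' Generates two-group right-censored data from an exponential
#' proportional-hazards model. Dependent uniform pairs \code{(U, V)} are drawn
#' from \code{copula} (the survival copula of event and censoring times) and
#' inverted through the cumulative hazards:
#' \deqn{T = -\log(U) \exp(-\beta z), \qquad C = -\log(V) / \lambda_C,
#'   \qquad \lambda_C = r / (1 - r),}
#' so that for \code{beta = 0} and any exchangeable copula the expected
#' censored fraction equals \code{r}. \code{r = 0} means no censoring.
#'
#' Covariate settings (group 1 has \code{n1} subjects, group 2 \code{n2}):
#' \describe{
#'   \item{binary}{z = 0 in group 1, z = 1 in group 2.}
#'   \item{normal_mean}{z ~ N(0, 1) in group 1, N(gamma, 1) in group 2.}
#'   \item{normal_scale}{z ~ N(0, 1) in group 1, N(0, gamma^2) in group 2.}
#'   \item{poisson}{z ~ Pois(1) in group 1, Pois(1 + gamma) in group 2.}
#' }
#'
#' @param n1,n2 group sizes.
#' @param beta log hazard ratio per unit covariate.
#' @param r censoring parameter in \code{[0, 1)}.
#' @param copula survival copula of (T, C); see [make_copula()].
#' @param covariate covariate setting, see Details.
#' @param gamma distribution parameter of settings other than binary.
#' @param seed integer seed.
#' @return a \code{data.frame} with columns \code{time}, \code{event},
#'   \code{z}, \code{group}, and attributes \code{true_T}, \code{true_C},
#'   \code{config}.
#' @export
simulate_ph <- function(n1, n2, beta = 0, r = 0.5,
                        copula = make_copula("independence"),
                        covariate = c("binary", "normal_mean", "normal_scale",
                                      "poisson"),
                        gamma = NULL, seed) {
  covariate <- match.arg(covariate)
  stopifnot(n1 >= 1, n2 >= 1, r >= 0, r < 1)
  n <- n1 + n2
  uv <- copula_sample(copula, n, derive_seed(seed, 1))
  z <- with_local_seed(derive_seed(seed, 2), switch(covariate,
    binary = rep(c(0, 1), c(n1, n2)),
    normal_mean = c(rnorm(n1, 0, 1), rnorm(n2, gamma, 1)),
    normal_scale = c(rnorm(n1, 0, 1), rnorm(n2, 0, gamma)),
    poisson = c(rpois(n1, 1), rpois(n2, 1 + gamma))
  ))
  T <- -log(uv[, "u"]) * exp(-beta * z)
  C <- if (r == 0) rep(Inf, n) else -log(uv[, "v"]) * (1 - r) / r
  finish_dataset(T, C, z, rep(c(1L, 2L), c(n1, n2)),
                 config = list(model = "ph_exponential", n1 = n1, n2 = n2,
                               beta = beta, r = r, copula = copula$family,
                               tau = copula$tau, covariate = covariate,
                               gamma = gamma, seed = seed))
}

#' Simulate Gompertz non-proportional-hazards data
#'
#' Event times follow the hazard \code{h(t) = exp(gamma*t + beta1*z +
#' beta2*z*t)} for binary group covariate z, generated by inverting the
#' cumulative hazard:
#' \deqn{T = \frac{1}{\gamma + \beta_2 z} \log\big(1 - (\gamma + \beta_2 z)
#'   \exp(-\beta_1 z) \log U \big).}
#' Censoring is generated as in [simulate_ph()].
#'
#' @param n1,n2 group sizes.
#' @param beta1 time-constant log effect of group 2.
#' @param beta2 time-varying effect (beta2 != 0 breaks proportionality).
#' @param gamma Gompertz shape (> 0).
#' @param r censoring parameter in \code{[0, 1)}.
#' @param copula survival copula of (T, C).
#' @param seed integer seed.
#' @return as [simulate_ph()].
#' @export
simulate_nph <- function(n1, n2, beta1 = 0, beta2 = 0, gamma = 1, r = 0.5,
                         copula = make_copula("independence"), seed) {
  stopifnot(n1 >= 1, n2 >= 1, r >= 0, r < 1)
  n <- n1 + n2
  z <- rep(c(0, 1), c(n1, n2))
  a <- gamma + beta2 * z
  if (any(a <= 0)) stop("gamma + beta2 * z must be positive for both groups")
  uv <- copula_sample(copula, n, derive_seed(seed, 1))
  T <- log1p(-a * exp(-beta1 * z) * log(uv[, "u"])) / a
  C <- if (r == 0) rep(Inf, n) else -log(uv[, "v"]) * (1 - r) / r
  finish_dataset(T, C, z, rep(c(1L, 2L), c(n1, n2)),
                 config = list(model = "nph_gompertz", n1 = n1, n2 = n2,
                               beta1 = beta1, beta2 = beta2, gamma = gamma,
                               r = r, copula = copula$family,
                               tau = copula$tau, seed = seed))
}

#' Simulate block-correlated "pathway" covariates with survival outcomes
#'
#' Emulates gene-pathway data: \code{p} covariates, uniform with mean 0 and
#' standard deviation 1 (i.e. Uniform(-sqrt(3), sqrt(3))), arranged in two
#' informative blocks of \code{q} covariates each plus \code{p - 2q} noise
#' covariates. Within each informative block the continuous covariates have
#' pairwise Pearson correlation \code{rho}, realised by a Gaussian copula
#' with normal-scale correlation \code{2*sin(pi*rho/6)} mapped to uniform
#' margins. The first \code{ceiling(q/2)} covariates of each block are
#' binarised at their sample median (value 1 when at or above it), and all
#' covariates are rounded to one decimal, mimicking categorical clinical
#' variables and coarsened biomarkers while shrinking the survival-tree
#' cutoff grid. Survival times follow
#' \code{T = -log(U) * exp(-beta_vec' z)} with
#' \code{beta_vec = (beta * q, -beta * q, 0 * (p - 2q))}; censoring as in
#' [simulate_ph()].
#'
#' @param n subjects.
#' @param p total covariates; requires \code{p > 2q}.
#' @param q block size of each informative block.
#' @param rho within-block correlation of the continuous covariates.
#' @param beta effect size shared (with alternating sign) by the informative
#'   blocks.
#' @param r censoring parameter.
#' @param copula survival copula of (T, C).
#' @param seed integer seed.
#' @return a \code{data.frame} with columns \code{time}, \code{event},
#'   \code{z1..zp}; attribute \code{informative} gives the informative column
#'   indices (1..2q), \code{z_continuous} the pre-binarisation covariates.
#' @export
simulate_pathway <- function(n, p = 50, q = 5, rho = 0.5, beta = 0.5, r = 0.5,
                             copula = make_copula("clayton", 0.25), seed) {
  if (p <= 2 * q) stop("pathway design requires p > 2q")
  zc <- with_local_seed(derive_seed(seed, 1), {
    rg <- 2 * sin(pi * rho / 6) # normal-scale correlation targeting uniform rho
    block <- function(m) {
      if (rho == 0) return(matrix(runif(n * m, -sqrt(3), sqrt(3)), n, m))
      L <- chol(matrix(rg, m, m) + diag(1 - rg, m))
      zn <- matrix(rnorm(n * m), n, m) %*% L
      sqrt(3) * (2 * pnorm(zn) - 1)
    }
    cbind(block(q), block(q),
          matrix(runif(n * (p - 2 * q), -sqrt(3), sqrt(3)), n, p - 2 * q))
  })
  z <- zc
  nb <- ceiling(q / 2)
  for (j in c(seq_len(nb), q + seq_len(nb))) {
    z[, j] <- as.numeric(zc[, j] >= median(zc[, j]))
  }
  z <- round(z, 1)
  colnames(z) <- paste0("z", seq_len(p))
  bvec <- c(rep(beta, q), rep(-beta, q), rep(0, p - 2 * q))
  uv <- copula_sample(copula, n, derive_seed(seed, 2))
  T <- -log(uv[, "u"]) * exp(-drop(z %*% bvec))
  C <- if (r == 0) rep(Inf, n) else -log(uv[, "v"]) * (1 - r) / r
  x <- pmin(T, C)
  out <- cbind(data.frame(time = x, event = as.integer(T <= C)),
               as.data.frame(z))
  attr(out, "informative") <- seq_len(2 * q)
  attr(out, "z_continuous") <- zc
  attr(out, "true_T") <- T
  attr(out, "true_C") <- C
  attr(out, "config") <- list(model = "pathway", n = n, p = p, q = q,
                              rho = rho, beta = beta, r = r,
                              copula = copula$family, tau = copula$tau,
                              seed = seed)
  out
}

#' Simulate data with unequal censoring distributions across groups
#'
#' Sensitivity-analysis arms that break the equal-censoring assumption of the
#' permutation test:
#' \describe{
#'   \item{group_r}{censoring rates calibrated separately per group,
#'     \code{lambda_Cj = rj / (1 - rj)}.}
#'   \item{censoring_equals_survival}{censoring times generated from the same
#'     model as the survival times, \code{C = -log(V) * exp(-beta * z)}, so
#'     under H1 the censoring distributions differ between groups.}
#' }
#'
#' @param variant one of \code{"group_r"}, \code{"censoring_equals_survival"}.
#' @param n1,n2 group sizes.
#' @param beta log hazard ratio (binary group covariate).
#' @param r1,r2 group-specific censoring parameters (variant \code{group_r}).
#' @param copula survival copula of (T, C).
#' @param seed integer seed.
#' @return as [simulate_ph()]; the variant is recorded in the config.
#' @export
simulate_unequal_censoring <- function(variant = c("group_r",
                                                   "censoring_equals_survival"),
                                       n1, n2, beta = 0, r1 = 0.5, r2 = 0.25,
                                       copula = make_copula("independence"),
                                       seed) {
  variant <- match.arg(variant)
  n <- n1 + n2
  z <- rep(c(0, 1), c(n1, n2))
  uv <- copula_sample(copula, n, derive_seed(seed, 1))
  T <- -log(uv[, "u"]) * exp(-beta * z)
  C <- if (variant == "group_r") {
    rg <- rep(c(r1, r2), c(n1, n2))
    ifelse(rg == 0, Inf, -log(uv[, "v"]) * (1 - rg) / rg)
  } else {
    -log(uv[, "v"]) * exp(-beta * z)
  }
  finish_dataset(T, C, z, rep(c(1L, 2L), c(n1, n2)),
                 config = list(model = "ph_unequal_censoring",
                               variant = variant, n1 = n1, n2 = n2,
                               beta = beta, r1 = r1, r2 = r2,
                               copula = copula$family, tau = copula$tau,
                               seed = seed))
}

finish_dataset <- function(T, C, z, group, config) {
  x <- pmin(T, C)
  delta <- as.integer(T <= C) # ties (probability zero) count as events
  out <- data.frame(time = x, event = delta)
  if (!is.null(z)) out$z <- z
  if (!is.null(group)) out$group <- group
  attr(out, "true_T") <- T
  attr(out, "true_C") <- C
  attr(out, "config") <- config
  out
}

#' Split a simulated two-group dataset into a [two_sample()] object
#'
#' @param dat a data frame with columns \code{time}, \code{event},
#'   \code{group}.
#' @return a [two_sample()] object (group 1 first).
#' @export
as_two_sample <- function(dat) {
  g1 <- dat$group == 1L
  two_sample(surv_sample(dat$time[g1], dat$event[g1]),
             surv_sample(dat$time[!g1], dat$event[!g1]))
}
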
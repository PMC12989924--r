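strong_binary_data <- function(n = 100, beta = 2, seed = 1) {
  withr::local_seed(seed)
  z <- rep(c(0, 1), each = n / 2)
  data.frame(time = rexp(n) * exp(-beta * z), event = 1L, z1 = z,
             z2 = rbinom(n, 1, 0.5))
}

test_that("best_split finds a strongly separating binary covariate", {
  dat <- strong_binary_data(100, beta = 2, seed = 5)
  z <- as.matrix(dat[c("z1", "z2")])
  bs <- best_split(seq_len(100), dat$time, dat$event, z,
                   make_copula("independence"), nperm = 200, min_child = 2,
                   seed = 3)
  expect_equal(bs$covariate, 1)
  expect_equal(bs$cutoff, 0)
  expect_equal(bs$p_value, 1 / 200) # smallest attainable
  # z1 = 0 rows (group "low") survive longer (their beta*z = 0)
  expect_gt(bs$l1_signed, 0)
})

test_that("best_split returns NULL without feasible cutoffs", {
  dat <- data.frame(time = rexp(20), event = 1L, z1 = 1, z2 = 2)
  expect_null(best_split(1:20, dat$time, dat$event,
                         as.matrix(dat[c("z1", "z2")]),
                         make_copula("independence"), nperm = 50,
                         min_child = 2, seed = 1))
})

test_that("trees respect the p-value threshold and place good prognosis right", {
  dat <- strong_binary_data(100, beta = 2, seed = 11)
  tree <- cg_tree(dat, make_copula("independence"), p_threshold = 0.01,
                  nperm = 200, seed = 2)
  expect_equal(tree$n_terminal, 2)
  expect_identical(tree$root$type, "internal")
  expect_identical(tree$root$varname, "z1")
  # node 1 (rightmost) holds the longer-surviving subjects: z1 = 0
  n1_rows <- terminal_nodes(tree)[[1]]$idx
  expect_true(all(dat$z1[n1_rows] == 0))
  # medians ordered: node 1 outlives node 2
  meds <- vapply(terminal_nodes(tree), `[[`, 0, "median_survival")
  expect_gt(meds[1], meds[2])
  # p_threshold = 0 can never be met (p >= 1/nperm)
  t0 <- cg_tree(dat, make_copula("independence"), p_threshold = 0,
                nperm = 200, seed = 2)
  expect_equal(t0$n_terminal, 1)
  expect_identical(t0$root$type, "terminal")
})

test_that("terminal membership partitions the training rows", {
  withr::local_seed(8)
  dat <- data.frame(time = rexp(80), event = rbinom(80, 1, 0.7),
                    z1 = round(runif(80), 1), z2 = rbinom(80, 1, 0.5),
                    z3 = round(rnorm(80), 1))
  tree <- cg_tree(dat, make_copula("clayton", 0.5), p_threshold = 0.3,
                  nperm = 100, seed = 4)
  leaves <- terminal_nodes(tree)
  all_rows <- sort(unlist(lapply(leaves, `[[`, "idx")))
  expect_identical(all_rows, 1:80)
  expect_equal(tree$n_terminal, length(leaves))
  # every internal split satisfied the threshold
  for (nd in internal_nodes(tree)) expect_lte(nd$p_value, 0.3)
  # assign_node reproduces training membership
  nodes <- assign_node(tree, dat[c("z1", "z2", "z3")])
  for (k in seq_along(leaves)) {
    expect_true(all(nodes[leaves[[k]]$idx] == k))
  }
})

collect_numbers <- function(node) {
  if (node$type == "terminal") return(node$node_number)
  c(collect_numbers(node$left), collect_numbers(node$right))
}

test_that("routing agrees with an independent interpreter of the serialized rules", {
  withr::local_seed(12)
  dat <- data.frame(time = rexp(60), event = rbinom(60, 1, 0.8),
                    z1 = round(runif(60), 1), z2 = round(rnorm(60), 1))
  tree <- cg_tree(dat, make_copula("independence"), p_threshold = 0.5,
                  nperm = 100, seed = 3)
  js <- tree_to_json(tree)
  znew <- data.frame(z1 = round(runif(100), 2), z2 = round(rnorm(100), 2))
  got <- assign_node(tree, znew)
  want <- vapply(seq_len(100),
                 function(i) oracle_route(js, as.list(znew[i, ])), 0)
  expect_equal(got, want)
  # boundary values route to the <= side
  if (tree$root$type == "internal") {
    j <- tree$root$covariate
    zb <- znew[1, ]; zb[[j]] <- tree$root$cutoff
    side <- if (tree$root$low_side == "right") "right" else "left"
    child <- tree$root[[side]]
    sub <- collect_numbers(child)
    expect_true(assign_node(tree, zb) %in% sub)
  }
  expect_error(assign_node(tree, data.frame(z1 = NA_real_, z2 = 1)), "missing")
})

test_that("predictions equal the terminal-node CGE refit on its training rows", {
  withr::local_seed(19)
  dat <- data.frame(time = rexp(70), event = rbinom(70, 1, 0.7),
                    z1 = rbinom(70, 1, 0.5), z2 = round(runif(70), 1))
  cop <- make_copula("clayton", 0.5)
  tree <- cg_tree(dat, cop, p_threshold = 0.2, nperm = 100, seed = 6)
  ts <- c(0, quantile(dat$time, c(0.2, 0.5, 0.9)), max(dat$time) * 2)
  pr <- predict(tree, dat[c("z1", "z2")], ts)
  expect_true(all(pr >= 0 & pr <= 1))
  expect_equal(pr[, 1], rep(1, 70)) # survival 1 at t = 0
  leaves <- terminal_nodes(tree)
  nodes <- assign_node(tree, dat[c("z1", "z2")])
  for (i in c(1, 10, 33)) {
    leaf <- leaves[[nodes[i]]]
    refit <- copula_graphic(surv_sample(dat$time[leaf$idx],
                                        dat$event[leaf$idx]), cop)
    expect_equal(pr[i, ], unname(
      curve_value(refit, pmin(ts, refit$domain_max))))
  }
})

test_that("tree growth is deterministic given the seed", {
  withr::local_seed(23)
  dat <- data.frame(time = rexp(60), event = rbinom(60, 1, 0.7),
                    z1 = round(runif(60), 1), z2 = rbinom(60, 1, 0.5))
  t1 <- cg_tree(dat, make_copula("clayton", 0.25), p_threshold = 0.2,
                nperm = 150, seed = 99)
  t2 <- cg_tree(dat, make_copula("clayton", 0.25), p_threshold = 0.2,
                nperm = 150, seed = 99)
  expect_identical(as.character(tree_to_json(t1)),
                   as.character(tree_to_json(t2)))
})

test_that("the logrank comparator tree uses the same engine", {
  dat <- strong_binary_data(100, beta = 2, seed = 31)
  tr <- cg_tree(dat, p_threshold = 0.01, nperm = 200, seed = 5,
                split_test = "logrank")
  expect_equal(tr$n_terminal, 2)
  expect_identical(tr$root$varname, "z1")
  # structural parity with the CGE tree on the same data
  tc <- cg_tree(dat, make_copula("independence"), p_threshold = 0.01,
                nperm = 200, seed = 5)
  expect_identical(tr$root$varname, tc$root$varname)
  expect_identical(tr$root$cutoff, tc$root$cutoff)
  # better prognosis right: leaf 1 is the z1 = 0 group under beta > 0
  expect_true(all(dat$z1[terminal_nodes(tr)[[1]]$idx] == 0))
})

test_that("cross-validated tau selection returns sane, reproducible tables", {
  withr::local_seed(41)
  dat <- data.frame(time = rexp(90), event = rbinom(90, 1, 0.7),
                    z1 = rbinom(90, 1, 0.5), z2 = round(runif(90), 1))
  tab <- cv_select_tau(dat, tau_grid = 0.25, folds = 3, p_threshold = 0.05,
                       nperm = 100, seed = 13)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$tau, 0.25)
  expect_gte(tab$mean_harrells_c, 0)
  expect_lte(tab$mean_harrells_c, 1)
  expect_gte(tab$mean_ibs, 0)
  expect_gte(tab$mean_terminal_nodes, 1)
  tab2 <- cv_select_tau(dat, tau_grid = 0.25, folds = 3, p_threshold = 0.05,
                        nperm = 100, seed = 13)
  expect_identical(tab, tab2)
})
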